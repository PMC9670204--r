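# Internal helpers shared across modules.

`%||%` <- function(a, b) if (is.null(a)) b else a

#' @noRd
is_count <- function(x, min = 1L) {
  is.numeric(x) && length(x) == 1L && is.finite(x) && x >= min && x == round(x)
}

#' @noRd
is_number <- function(x) is.numeric(x) && length(x) == 1L && is.finite(x)

#' Derive a deterministic sub-seed for item `index` of a stream.
#'
#' Sub-streams keep item i's draws independent of how many items follow it:
#' generating n or n+1 cells/traces/samples never reshuffles the first n.
#' The constants are an LCG-style mix over the 2^31-1 Mersenne prime field;
#' the result is always a valid 32-bit seed.
#' @noRd
derive_seed <- function(seed, index, stream = 0L) {
  s <- (as.numeric(seed) %% 2147483647) * 48271 +
    as.numeric(index) * 16807 +
    as.numeric(stream) * 69621
  as.integer(s %% 2147483647)
}

#' Evaluate `expr` under a given seed, restoring the caller's RNG state.
#' @noRd
with_seed <- function(seed, expr) {
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    get(".Random.seed", envir = globalenv())
  }
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
        rm(".Random.seed", envir = globalenv())
      }
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
  })
  set.seed(seed)
  expr
}

#' Symmetric 1-D Gaussian kernel, normalised to sum 1.
#'
#' Radius is ceiling(4*sigma) pixels, so the truncated mass is < 0.01%.
#' @noRd
gaussian_kernel_1d <- function(sigma_px) {
  stopifnot(sigma_px > 0)
  r <- max(1L, as.integer(ceiling(4 * sigma_px)))
  x <- (-r):r
  k <- exp(-x^2 / (2 * sigma_px^2))
  k / sum(k)
}

#' Separable Gaussian smoothing with replicate edge padding.
#'
#' Edge rows/columns are extended (replicated) before convolution so the
#' output has no boundary attenuation; sigma_px <= 0 returns the input.
#' @noRd
smooth_gaussian <- function(mat, sigma_px) {
  if (sigma_px <= 0) return(mat)
  k <- gaussian_kernel_1d(sigma_px)
  r <- (length(k) - 1L) / 2L
  conv_cols <- function(m) {
    n <- nrow(m)
    mp <- rbind(m[rep(1L, r), , drop = FALSE], m, m[rep(n, r), , drop = FALSE])
    out <- stats::filter(mp, k, sides = 2)
    matrix(out[(r + 1L):(r + n), ], nrow = n)
  }
  t(conv_cols(t(conv_cols(mat))))
}
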