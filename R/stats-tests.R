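# Group-comparison tests for grouped scalar readouts: Wilcoxon
# rank-sum (two groups), Dunnett many-to-one (parametric), Steel many-to-one
# (rank-based), and Tukey-Kramer all-pairs.

#' @noRd
comparison_result <- function(test_name, comparisons, details = list()) {
  stopifnot(is.data.frame(comparisons),
            all(c("comparison", "statistic", "p_adjusted") %in%
                  names(comparisons)))
  structure(list(test_name = test_name, comparisons = comparisons,
                 details = details),
            class = "comparison_result")
}

#' @export
print.comparison_result <- function(x, ...) {
  cat(sprintf("<comparison_result: %s>\n", x$test_name))
  print(x$comparisons, row.names = FALSE)
  if (length(x$details)) {
    keys <- vapply(names(x$details), function(k) {
      v <- x$details[[k]]
      if (is.atomic(v) && length(v) == 1L) paste0(k, " = ", format(v))
      else NA_character_
    }, "")
    keys <- keys[!is.na(keys)]
    if (length(keys)) cat(" ", paste(keys, collapse = ", "), "\n")
  }
  invisible(x)
}

#' Coerce a named list of numerics or a (group, value) data.frame into a
#' named list, and resolve the control label.
#' @noRd
as_grouped <- function(groups, control = NULL) {
  if (is.data.frame(groups)) {
    stopifnot(all(c("group", "value") %in% names(groups)))
    groups <- split(groups$value, factor(groups$group,
                                         levels = unique(groups$group)))
  }
  stopifnot(is.list(groups), length(groups) >= 2L, !is.null(names(groups)))
  control <- control %||% names(groups)[1L]
  if (!control %in% names(groups)) stop("control group not found: ", control)
  list(groups = lapply(groups, as.numeric), control = control)
}

# --- Wilcoxon rank-sum ------------------------------------------------------

#' Wilcoxon rank-sum (Mann-Whitney) test with midrank ties
#'
#' For small samples (`n_x + n_y <= 10`) the p-value is exact: all
#' `choose(n_x + n_y, n_x)` assignments of the pooled midranks are
#' enumerated (a permutation test, valid with ties; without ties it equals
#' the classical exact distribution).  Otherwise the normal approximation
#' with tie correction and continuity correction is used.
#'
#' @param x,y numeric samples.
#' @param alternative `"two.sided"` (default), `"greater"` (x tends larger)
#'   or `"less"`.
#' @param exact force (`TRUE`) or suppress (`FALSE`) enumeration; default
#'   enumerates iff `n_x + n_y <= 10`.
#' @return a `comparison_result` whose statistic is the Mann-Whitney U of
#'   `x`; `details` records the rank sum, method and tie presence.
#' @examples
#' wilcoxon_rank_sum(c(1, 2, 3), c(4, 5, 6), alternative = "less")
#' @export
wilcoxon_rank_sum <- function(x, y,
                              alternative = c("two.sided", "greater", "less"),
                              exact = NULL) {
  alternative <- match.arg(alternative)
  if (!length(x) || !length(y)) stop("empty sample")
  nx <- length(x)
  ny <- length(y)
  n <- nx + ny
  pooled <- c(x, y)
  r <- rank(pooled)
  w <- sum(r[seq_len(nx)])
  u <- w - nx * (nx + 1) / 2
  ties <- anyDuplicated(pooled) > 0L
  exact <- exact %||% (n <= 10L)
  if (exact) {
    if (choose(n, nx) > 5e5) stop("sample too large for exact enumeration")
    sets <- utils::combn(n, nx)
    us <- colSums(matrix(r[sets], nrow = nx)) - nx * (nx + 1) / 2
    eps <- 1e-9
    p_ge <- mean(us >= u - eps)
    p_le <- mean(us <= u + eps)
    p <- switch(alternative,
                greater = p_ge, less = p_le,
                two.sided = min(1, 2 * min(p_ge, p_le)))
    method <- "exact enumeration"
  } else {
    mu <- nx * ny / 2
    tie_tab <- table(pooled)
    sigma2 <- nx * ny / 12 *
      (n + 1 - sum(tie_tab^3 - tie_tab) / (n * (n - 1)))
    z_num <- u - mu
    cc <- switch(alternative,
                 two.sided = sign(z_num) * 0.5,
                 greater = 0.5, less = -0.5)
    z <- (z_num - cc) / sqrt(sigma2)
    p <- switch(alternative,
                greater = stats::pnorm(z, lower.tail = FALSE),
                less = stats::pnorm(z),
                two.sided = min(1, 2 * stats::pnorm(-abs(z))))
    method <- "normal approximation with tie and continuity correction"
  }
  comparison_result(
    "wilcoxon_rank_sum",
    data.frame(comparison = "x vs y", statistic = u, p_adjusted = p),
    details = list(rank_sum = w, n_x = nx, n_y = ny, ties = ties,
                   alternative = alternative, method = method)
  )
}

# --- Dunnett ----------------------------------------------------------------

#' Dunnett's many-to-one comparison against a shared control
#'
#' Per-treatment statistic `d_i = (m_i - m_c) / (s_p * sqrt(1/n_i + 1/n_c))`
#' with the pooled within-group variance over all groups.  Two-sided
#' adjusted p-values come from the joint distribution of `max |T|` under
#' the equicorrelated multivariate t (correlations `lambda_i * lambda_j`,
#' `lambda_i = 1/sqrt(1 + n_c/n_i)`), evaluated by seeded Monte Carlo using
#' the one-factor representation
#' `T_i = (lambda_i Z_0 + sqrt(1 - lambda_i^2) Z_i) / sqrt(chi^2_df / df)`.
#'
#' @param groups named list of numeric vectors, or a data.frame with
#'   `group` and `value` columns.
#' @param control control group label (default: first group).
#' @param reps Monte Carlo draws.
#' @param seed integer seed for the Monte Carlo draw.
#' @return a `comparison_result` with one comparison per treatment
#'   (`k - 1` in total); `details` records df, pooled SD, lambda, reps and
#'   seed.
#' @examples
#' g <- list(ctrl = rnorm(6), a = rnorm(6, 1), b = rnorm(6))
#' dunnett(g, control = "ctrl", reps = 2e4, seed = 1)
#' @export
dunnett <- function(groups, control = NULL, reps = 1e5, seed = 1L) {
  gc <- as_grouped(groups, control)
  groups <- gc$groups
  control <- gc$control
  if (any(lengths(groups) < 2L)) stop("each group needs n >= 2")
  k <- length(groups)
  ns <- lengths(groups)
  ms <- vapply(groups, mean, 0)
  df <- sum(ns) - k
  s2 <- sum((ns - 1) * vapply(groups, stats::var, 0)) / df
  if (s2 <= 0) stop("zero pooled variance")
  trt <- setdiff(names(groups), control)
  nc <- ns[[control]]
  d <- (ms[trt] - ms[[control]]) /
    sqrt(s2 * (1 / ns[trt] + 1 / nc))
  lambda <- 1 / sqrt(1 + nc / ns[trt])
  # draw treatments in lambda order so relabelling groups cannot change
  # the Monte Carlo null draw (tied lambdas are exchangeable)
  maxT <- with_seed(seed, {
    z0 <- stats::rnorm(reps)
    s <- sqrt(stats::rchisq(reps, df) / df)
    m <- rep(-Inf, reps)
    for (li in sort(lambda)) {
      ti <- (li * z0 + sqrt(1 - li^2) * stats::rnorm(reps)) / s
      m <- pmax(m, abs(ti))
    }
    m
  })
  p <- vapply(abs(d), function(di) mean(maxT >= di), 0)
  comparison_result(
    "dunnett",
    data.frame(comparison = paste(trt, "vs", control),
               statistic = unname(d), p_adjusted = unname(p)),
    details = list(control = control, df = df, pooled_sd = sqrt(s2),
                   lambda = lambda, reps = reps, seed = seed,
                   sides = "two-sided")
  )
}

# --- Tukey-Kramer -----------------------------------------------------------

#' Tukey-Kramer all-pairs comparison
#'
#' Studentized-range statistic
#' `q_ij = |m_i - m_j| / sqrt(s_p^2/2 * (1/n_i + 1/n_j))` with the pooled
#' within-group variance; adjusted p-values from the studentized-range
#' distribution with `k` groups and pooled degrees of freedom
#' ([stats::ptukey()]).
#'
#' @param groups named list of numeric vectors, or a data.frame with
#'   `group` and `value` columns.
#' @return a `comparison_result` with one row per unordered pair.
#' @export
tukey_kramer <- function(groups) {
  gc <- as_grouped(groups)
  groups <- gc$groups
  if (any(lengths(groups) < 2L)) stop("each group needs n >= 2")
  k <- length(groups)
  ns <- lengths(groups)
  ms <- vapply(groups, mean, 0)
  df <- sum(ns) - k
  s2 <- sum((ns - 1) * vapply(groups, stats::var, 0)) / df
  if (s2 <= 0) stop("zero pooled variance")
  pairs <- utils::combn(names(groups), 2L)
  q <- apply(pairs, 2L, function(pr) {
    abs(ms[[pr[1L]]] - ms[[pr[2L]]]) /
      sqrt(s2 / 2 * (1 / ns[[pr[1L]]] + 1 / ns[[pr[2L]]]))
  })
  p <- stats::ptukey(q, nmeans = k, df = df, lower.tail = FALSE)
  comparison_result(
    "tukey_kramer",
    data.frame(comparison = paste(pairs[1L, ], "vs", pairs[2L, ]),
               statistic = q, p_adjusted = p),
    details = list(df = df, pooled_sd = sqrt(s2), k = k)
  )
}

# --- Steel ------------------------------------------------------------------

#' Steel's many-to-one rank test against a shared control
#'
#' The nonparametric analogue of Dunnett's test: for each treatment the
#' Wilcoxon rank-sum statistic versus the control is computed on that pair
#' only (midranks, tie-corrected variance) and standardized.  The joint
#' null distribution of `max |z|` is estimated by seeded permutation Monte
#' Carlo over relabellings of the pooled observations; two-sided adjusted
#' p-values use the add-one permutation estimator.
#'
#' @param groups named list of numeric vectors, or a data.frame with
#'   `group` and `value` columns.
#' @param control control group label (default: first group).
#' @param reps number of label permutations.
#' @param seed integer seed for the permutation draw.
#' @return a `comparison_result` with one comparison per treatment;
#'   `details` records reps and seed.
#' @export
steel <- function(groups, control = NULL, reps = 1e4, seed = 1L) {
  gc <- as_grouped(groups, control)
  groups <- gc$groups
  control <- gc$control
  if (any(lengths(groups) == 0L)) stop("empty group")
  trt <- setdiff(names(groups), control)
  xc <- groups[[control]]
  n_c <- length(xc)
  z_obs <- vapply(trt, function(g) {
    steel_pair_z(c(xc, groups[[g]]), n_c)
  }, 0)

  # canonical pooled layout (control first, treatments by size then
  # content) so relabelling groups cannot change the permutation draw
  canon <- trt[order(lengths(groups[trt]),
                     vapply(groups[trt], function(v) {
                       paste(format(sort(v), digits = 17), collapse = ",")
                     }, ""))]
  ordered_groups <- groups[c(control, canon)]
  pooled <- unlist(ordered_groups, use.names = FALSE)
  sizes <- lengths(ordered_groups)
  offs <- cumsum(c(0L, sizes[-length(sizes)]))
  names(offs) <- names(ordered_groups)
  slot <- function(g) offs[[g]] + seq_len(sizes[[g]])
  has_ties <- anyDuplicated(pooled) > 0L

  maxZ <- with_seed(seed, {
    perm <- vapply(seq_len(reps), function(i) sample.int(length(pooled)),
                   integer(length(pooled)))
    xp <- matrix(pooled[perm], nrow = length(pooled))
    m <- rep(-Inf, reps)
    for (g in trt) {
      sub <- xp[c(slot(control), slot(g)), , drop = FALSE]
      z <- steel_pair_z_cols(sub, n_c, has_ties)
      m <- pmax(m, abs(z))
    }
    m
  })
  p <- vapply(abs(z_obs), function(zi) {
    (1 + sum(maxZ >= zi - 1e-12)) / (reps + 1)
  }, 0)
  comparison_result(
    "steel",
    data.frame(comparison = paste(trt, "vs", control),
               statistic = unname(z_obs), p_adjusted = unname(p)),
    details = list(control = control, reps = reps, seed = seed,
                   ties = has_ties, sides = "two-sided")
  )
}

#' Standardized rank-sum of the treatment part of one pooled pair vector
#' (first n_c entries are control).  Tie-corrected; 0 when degenerate.
#' @noRd
steel_pair_z <- function(pair, n_c) {
  np <- length(pair)
  n_t <- np - n_c
  r <- rank(pair)
  w <- sum(r[(n_c + 1L):np])
  mu <- n_t * (np + 1) / 2
  tt <- table(pair)
  v <- n_c * n_t / 12 * (np + 1 - sum(tt^3 - tt) / (np * (np - 1)))
  if (v <= 0) return(0)
  (w - mu) / sqrt(v)
}

#' Column-wise version of [steel_pair_z] for a matrix of permuted pairs.
#' The no-ties fast path ranks all columns in one order() pass.
#' @noRd
steel_pair_z_cols <- function(m, n_c, has_ties) {
  np <- nrow(m)
  n_t <- np - n_c
  mu <- n_t * (np + 1) / 2
  if (!has_ties) {
    idx <- order(col(m), m)
    rk <- integer(length(m))
    rk[idx] <- rep(seq_len(np), ncol(m))
    w <- colSums(matrix(rk, np)[(n_c + 1L):np, , drop = FALSE])
    v <- n_c * n_t * (np + 1) / 12
    return((w - mu) / sqrt(v))
  }
  apply(m, 2L, function(pair) steel_pair_z(pair, n_c))
}
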