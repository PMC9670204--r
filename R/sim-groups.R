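#' Generate grouped scalar samples from stated distributions
#'
#' Calibration inputs for the group-comparison tests: each group is drawn
#' independently from its own distribution.
#'
#' @param spec named list, one entry per group, each a list with `dist`
#'   (`"normal"`, `"lognormal"` or `"uniform"`), `n` (>= 2) and the
#'   distribution's parameters (`mean`/`sd`, `meanlog`/`sdlog`, `min`/`max`).
#' @param seed integer seed; per-group sub-streams keep group i's draw
#'   stable when other groups are added.
#' @return data.frame with columns `group` and `value`.
#' @examples
#' generate_groups(list(ctrl = list(dist = "normal", n = 5),
#'                      trt  = list(dist = "normal", n = 5, mean = 1)),
#'                 seed = 1)
#' @export
generate_groups <- function(spec, seed = 1L) {
  stopifnot(is.list(spec), length(spec) >= 2L, !is.null(names(spec)))
  rows <- lapply(seq_along(spec), function(i) {
    g <- spec[[i]]
    n <- g$n %||% stop("each group needs n")
    if (!is_count(n, min = 2L)) stop("each group needs n >= 2")
    dist <- g$dist %||% "normal"
    vals <- with_seed(derive_seed(seed, i, stream = 31L), switch(
      dist,
      normal = stats::rnorm(n, g$mean %||% 0, g$sd %||% 1),
      lognormal = stats::rlnorm(n, g$meanlog %||% 0, g$sdlog %||% 1),
      uniform = stats::runif(n, g$min %||% 0, g$max %||% 1),
      stop("unknown distribution: ", dist)
    ))
    data.frame(group = names(spec)[i], value = vals)
  })
  do.call(rbind, rows)
}
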