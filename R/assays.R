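#' LDH cytotoxicity percentage
#'
#' Absorbance readings are background-subtracted and expressed relative to
#' the total releasable LDH activity:
#' `100 * (sample - background) / (total - background)`.
#' Negative results (sample below background) are clipped to 0 with a
#' warning.
#'
#' @param sample_abs absorbance of the treated wells (vectorised).
#' @param background_abs absorbance of the background control.
#' @param total_abs absorbance at total lysis; must exceed the background.
#' @return cytotoxicity percentages.
#' @examples
#' ldh_cytotoxicity(0.5, background_abs = 0.1, total_abs = 0.9)  # 50
#' @export
ldh_cytotoxicity <- function(sample_abs, background_abs, total_abs) {
  stopifnot(is.numeric(sample_abs), is_number(background_abs),
            is_number(total_abs))
  if (total_abs <= background_abs) {
    stop("total_abs must exceed background_abs")
  }
  pct <- 100 * (sample_abs - background_abs) / (total_abs - background_abs)
  if (any(pct < 0)) {
    warning("negative cytotoxicity clipped to 0 (sample below background)")
    pct <- pmax(pct, 0)
  }
  pct
}

#' Autophagic flux index from LC3-II densitometry
#'
#' Flux is read from LC3-II levels under lysosomal-degradation blockade
#' (bafilomycin A1, "BMA").  Two conventions are offered: `"level"`
#' (default) reports `LC3-II(+BMA) / loading`; `"difference"` reports
#' `(LC3-II(+BMA) - LC3-II(-BMA)) / loading`.  Both are invariant to the
#' densitometry scale (doubling every band intensity leaves the index
#' unchanged only relative to a loading control measured in the same
#' units; the index itself scales as intensity/intensity and is
#' unit-free).
#'
#' @param lc3ii_with_bma LC3-II band densitometry with bafilomycin A1.
#' @param loading loading-control densitometry (> 0).
#' @param lc3ii_without_bma LC3-II densitometry without bafilomycin A1
#'   (required for `mode = "difference"`).
#' @param mode `"level"` or `"difference"`.
#' @return data.frame with columns `flux` and `mode`.
#' @examples
#' flux_index(2, loading = 1)                       # flux 2, mode "level"
#' flux_index(2, loading = 1, lc3ii_without_bma = 2,
#'            mode = "difference")                  # flux 0
#' @export
flux_index <- function(lc3ii_with_bma, loading, lc3ii_without_bma = NULL,
                       mode = c("level", "difference")) {
  mode <- match.arg(mode)
  stopifnot(is.numeric(lc3ii_with_bma), is.numeric(loading))
  if (any(loading <= 0)) stop("loading must be > 0")
  flux <- if (mode == "level") {
    lc3ii_with_bma / loading
  } else {
    if (is.null(lc3ii_without_bma)) {
      stop("mode 'difference' needs lc3ii_without_bma")
    }
    (lc3ii_with_bma - lc3ii_without_bma) / loading
  }
  data.frame(flux = flux, mode = mode)
}
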