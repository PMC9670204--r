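#' Ratio trace from dual-excitation fluorescence channels
#'
#' @param F340,F380 equal-length non-negative fluorescence vectors.
#' @param f380_floor points with `F380 <= f380_floor` are marked missing
#'   (`NA`) and excluded from downstream detection.
#' @return numeric vector `F340/F380` with `NA` at floored points.
#' @export
compute_ratio <- function(F340, F380, f380_floor = 0) {
  if (length(F340) != length(F380)) {
    stop("F340 and F380 must have equal length")
  }
  bad <- !(F380 > f380_floor)
  if (all(bad)) stop("all F380 values are at or below the floor")
  ratio <- F340 / F380
  ratio[bad] <- NA_real_
  ratio
}

#' Running-median baseline of a ratio trace
#'
#' Median over a centred window of `window_s` seconds; windows are
#' truncated at the trace edges.  Missing points are bridged by linear
#' interpolation before the median is taken (they are never themselves
#' candidate peaks downstream).
#'
#' @param ratio numeric ratio trace (may contain `NA`).
#' @param dt_s sampling interval, seconds.
#' @param window_s window width, seconds; must be at least `3 * dt_s`.
#' @return numeric baseline, same length as `ratio`.
#' @export
estimate_baseline <- function(ratio, dt_s = 5, window_s = 60) {
  n <- length(ratio)
  if (n < 3L) stop("trace must have at least 3 samples")
  if (window_s < 3 * dt_s) stop("window_s must be at least 3 * dt_s")
  x <- bridge_na(ratio)
  half <- floor(window_s / (2 * dt_s))
  vapply(seq_len(n), function(i) {
    stats::median(x[max(1L, i - half):min(n, i + half)])
  }, 0)
}

#' @noRd
bridge_na <- function(x) {
  if (!anyNA(x)) return(x)
  idx <- which(!is.na(x))
  if (!length(idx)) stop("trace is entirely missing")
  stats::approx(idx, x[idx], xout = seq_along(x), rule = 2)$y
}

#' Detect calcium spikes in a ratio trace
#'
#' A spike is a local maximum of the baseline-subtracted ratio whose
#' excursion strictly exceeds `threshold` (the counting rule uses
#' amplitudes of more than 0.05 ratio units over a 40 min window) and
#' whose topographic prominence also exceeds `threshold`: a bump riding
#' the decaying flank of a larger transient rises only marginally above
#' the saddle separating it from that transient and is rejected, while a
#' free-standing spike keeps its full amplitude as prominence.  Maxima
#' closer together than `refractory_s` are merged, keeping the larger.
#' Missing points are never peaks.
#'
#' @param trace a `calcium_trace` (see [generate_traces()]) or a list with
#'   `time_s`, `ratio` (or `F340`/`F380`), and optionally `cell_id`.
#' @param threshold minimal amplitude, ratio units above baseline.
#' @param window_s analysis window: the first `window_s` seconds of the
#'   trace (default 2400 s = 40 min).
#' @param refractory_s minimal separation between retained peaks, seconds.
#' @param baseline_window_s window for [estimate_baseline()].
#' @return object of class `spike_set`: list with `cell_id`, `spikes`
#'   (data.frame `peak_time_s`, `amplitude`), `baseline`, and the detection
#'   `params`.  An empty spike table is a valid result.
#' @export
detect_spikes <- function(trace, threshold = 0.05, window_s = 2400,
                          refractory_s = 10, baseline_window_s = 60) {
  time_s <- trace$time_s
  ratio <- trace$ratio %||% compute_ratio(trace$F340, trace$F380)
  stopifnot(length(time_s) == length(ratio), length(time_s) >= 3L)
  dt <- stats::median(diff(time_s))
  keep <- (time_s - time_s[1L]) < window_s
  time_s <- time_s[keep]
  ratio <- ratio[keep]
  baseline <- estimate_baseline(ratio, dt_s = dt, window_s = baseline_window_s)
  excess <- ratio - baseline
  peaks <- local_maxima(excess)
  peaks <- peaks[!is.na(excess[peaks]) & excess[peaks] > threshold]
  excess_b <- bridge_na(ratio) - baseline
  peaks <- peaks[vapply(peaks, function(p) {
    peak_prominence(excess_b, p) > threshold
  }, TRUE)]
  peaks <- merge_refractory(peaks, excess[peaks], time_s, refractory_s)
  structure(
    list(
      cell_id = trace$cell_id %||% NA_character_,
      spikes = data.frame(peak_time_s = time_s[peaks],
                          amplitude = excess[peaks]),
      baseline = baseline,
      params = list(threshold = threshold, window_s = window_s,
                    refractory_s = refractory_s,
                    baseline_window_s = baseline_window_s)
    ),
    class = "spike_set"
  )
}

#' Indices of local maxima; plateaus yield their first sample, and the
#' trace ends count when they exceed their single neighbour.
#' @noRd
local_maxima <- function(x) {
  n <- length(x)
  if (n < 2L) return(integer(0))
  x0 <- ifelse(is.na(x), -Inf, x)
  left <- c(-Inf, x0[-n])
  right <- c(x0[-1L], -Inf)
  which(x0 > left & x0 >= right)
}

#' Topographic prominence of sample `p` in trace `x`: height above the
#' higher of the two saddles on the paths to nearer-higher terrain; the
#' global maximum is measured from the trace minimum.
#' @noRd
peak_prominence <- function(x, p) {
  n <- length(x)
  saddles <- numeric(0)
  for (dir in c(-1L, 1L)) {
    i <- p + dir
    m <- Inf
    while (i >= 1L && i <= n) {
      m <- min(m, x[i])
      if (x[i] > x[p]) {
        saddles <- c(saddles, m)
        break
      }
      i <- i + dir
    }
  }
  if (!length(saddles)) return(x[p] - min(x))
  x[p] - max(saddles)
}

#' Greedy refractory merge: keep the largest peak, drop any peak within
#' `refractory_s` of an already-kept one.
#' @noRd
merge_refractory <- function(peaks, amps, time_s, refractory_s) {
  if (length(peaks) <= 1L) return(peaks)
  ord <- order(-amps, peaks)
  kept <- integer(0)
  for (p in peaks[ord]) {
    if (!length(kept) ||
        all(abs(time_s[p] - time_s[kept]) >= refractory_s)) {
      kept <- c(kept, p)
    }
  }
  sort(kept)
}

#' Population spike-frequency histogram
#'
#' Bins cells by their detected spike count and reports the percentage of
#' cells per count; bin "0" is cells with no detected spikes.
#'
#' @param spike_sets list of `spike_set` objects (or an integer vector of
#'   per-cell spike counts).
#' @return object of class `spike_histogram`: data.frame with `n_spikes`
#'   and `percent` (summing to 100), with attribute `n_cells`.
#' @examples
#' spike_histogram(c(0L, 0L, 1L, 2L))  # 50% / 25% / 25%
#' @export
spike_histogram <- function(spike_sets) {
  counts <- if (is.numeric(spike_sets)) {
    as.integer(spike_sets)
  } else {
    vapply(spike_sets, function(s) nrow(s$spikes), 0L)
  }
  if (!length(counts)) stop("spike_histogram: no cells")
  bins <- 0:max(counts)
  pct <- 100 * vapply(bins, function(k) sum(counts == k), 0L) / length(counts)
  out <- data.frame(n_spikes = bins, percent = pct)
  attr(out, "n_cells") <- length(counts)
  class(out) <- c("spike_histogram", "data.frame")
  out
}
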