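#' Parameters for the ratiometric calcium trace generator
#'
#' Emulates dual-excitation (Fura-2) recordings: a baseline F340/F380 ratio
#' with Poisson-timed transient elevations decaying exponentially, sampled
#' every `dt_s` seconds (the recording protocol samples every 5 s over
#' 40 min).
#'
#' @param duration_s recording length, seconds (default 2400 = 40 min).
#' @param dt_s sampling interval, seconds (default 5).
#' @param baseline_ratio resting F340/F380 ratio.
#' @param spike_rate_per_min Poisson rate of spike onsets, events/min.
#' @param amplitude_dist `list("fixed", a = )` or
#'   `list("lognormal", meanlog = , sdlog = )`, in ratio units.
#' @param decay_tau_s exponential decay constant of each transient, seconds.
#' @param noise_sd additive Gaussian noise on the ratio trace.
#' @param n_cells number of cells (traces).
#' @param f380_level constant F380 fluorescence used to construct the raw
#'   channels (`F340 = ratio * F380`), so `F340/F380` reproduces the planted
#'   ratio trace exactly.
#' @param seed integer seed; per-cell sub-streams keep trace i stable when
#'   `n_cells` changes.
#' @return An object of class `trace_sim_params`.
#' @export
trace_sim_params <- function(duration_s = 2400,
                             dt_s = 5,
                             baseline_ratio = 1,
                             spike_rate_per_min = 0.05,
                             amplitude_dist = list("lognormal",
                                                   meanlog = log(0.12),
                                                   sdlog = 0.3),
                             decay_tau_s = 20,
                             noise_sd = 0.01,
                             n_cells = 50L,
                             f380_level = 500,
                             seed = 1L) {
  if (!is_number(dt_s) || dt_s <= 0) stop("dt_s must be > 0")
  if (!is_number(duration_s) || duration_s <= 0) stop("duration_s must be > 0")
  n_steps <- duration_s / dt_s
  if (abs(n_steps - round(n_steps)) > 1e-9) {
    stop("duration_s must be an integer multiple of dt_s")
  }
  amplitude_dist <- normalize_amplitude_dist(amplitude_dist)
  stopifnot(is_number(baseline_ratio), baseline_ratio > 0,
            is_number(spike_rate_per_min), spike_rate_per_min >= 0,
            is_number(decay_tau_s), decay_tau_s > 0,
            is_number(noise_sd), noise_sd >= 0,
            is_count(n_cells), is_number(f380_level), f380_level > 0,
            is_count(seed, min = 0L))
  structure(
    list(duration_s = duration_s, dt_s = dt_s,
         baseline_ratio = baseline_ratio,
         spike_rate_per_min = spike_rate_per_min,
         amplitude_dist = amplitude_dist, decay_tau_s = decay_tau_s,
         noise_sd = noise_sd, n_cells = as.integer(n_cells),
         f380_level = f380_level, seed = as.integer(seed)),
    class = "trace_sim_params"
  )
}

#' @noRd
normalize_amplitude_dist <- function(d) {
  if (is.numeric(d) && length(d) == 1L) d <- list("fixed", a = d)
  type <- d[[1L]]
  if (type == "fixed") {
    a <- d$a %||% d[[2L]]
    if (!is_number(a) || a <= 0) stop("fixed amplitude must be > 0")
    return(list(type = "fixed", a = a))
  }
  if (type == "lognormal") {
    stopifnot(is_number(d$meanlog), is_number(d$sdlog), d$sdlog >= 0)
    return(list(type = "lognormal", meanlog = d$meanlog, sdlog = d$sdlog))
  }
  stop("amplitude_dist must be 'fixed' or 'lognormal'")
}

#' Generate ratiometric calcium traces with planted spikes
#'
#' Each cell's ratio trace is
#' `baseline + sum_i a_i * exp(-(t - t_i)/tau) * 1[t >= t_i] + noise`.
#' Spike onsets follow a homogeneous Poisson process, snapped to the
#' sampling grid (events are only observable at frame resolution), so each
#' planted spike's rendered peak height equals its drawn amplitude exactly
#' in the noiseless case.  F340/F380 channels are constructed with constant
#' F380, so their ratio reproduces the (noisy) planted trace.
#'
#' @param params a [trace_sim_params()] object.
#' @return list of per-cell objects of class `calcium_trace`, each a list
#'   with `cell_id`, `time_s`, `F340`, `F380`, `ratio`, and
#'   `truth` = data.frame(`onset_time_s`, `amplitude`).
#' @examples
#' tr <- generate_traces(trace_sim_params(n_cells = 2, seed = 3))
#' tr[[1]]$truth
#' @export
generate_traces <- function(params) {
  stopifnot(inherits(params, "trace_sim_params"))
  time_s <- seq(0, params$duration_s - params$dt_s, by = params$dt_s)
  lapply(seq_len(params$n_cells), function(i) {
    with_seed(derive_seed(params$seed, i, stream = 11L), {
      n_spk <- stats::rpois(1L, params$spike_rate_per_min *
                              params$duration_s / 60)
      onset <- sort(stats::runif(n_spk, 0, params$duration_s))
      onset <- time_s[pmin(length(time_s),
                           findInterval(onset, time_s))]  # snap to grid
      amp <- draw_amplitudes(params$amplitude_dist, n_spk)
      ratio <- rep(params$baseline_ratio, length(time_s))
      for (j in seq_len(n_spk)) {
        after <- time_s >= onset[j]
        ratio[after] <- ratio[after] +
          amp[j] * exp(-(time_s[after] - onset[j]) / params$decay_tau_s)
      }
      if (params$noise_sd > 0) {
        ratio <- ratio + stats::rnorm(length(ratio), sd = params$noise_sd)
      }
      f380 <- rep(params$f380_level, length(time_s))
      structure(
        list(cell_id = sprintf("cell_%03d", i), time_s = time_s,
             F340 = ratio * f380, F380 = f380, ratio = ratio,
             truth = data.frame(onset_time_s = onset, amplitude = amp)),
        class = "calcium_trace"
      )
    })
  })
}

#' @noRd
draw_amplitudes <- function(dist, n) {
  if (n == 0L) return(numeric(0))
  if (dist$type == "fixed") rep(dist$a, n)
  else stats::rlnorm(n, dist$meanlog, dist$sdlog)
}
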