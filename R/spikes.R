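# Spike-train generation: spontaneous Poisson activity and the field-stimulation
# pulse-train protocol used for culture characterization.

#' Simulate a Poisson spike train with an absolute refractory period
#'
#' Homogeneous Poisson events on `[0, duration)` thinned so that every kept
#' event is at least `refractory` seconds after the previously kept one.
#' With `refractory = 0` the output is an unthinned Poisson process.
#'
#' @param rate Mean event rate, Hz (>= 0).
#' @param duration Train duration, s.
#' @param refractory Minimum inter-event gap, s (>= 0). `rate * refractory`
#'   must be < 1, otherwise the requested rate is infeasible.
#' @param seed Optional integer seed for reproducibility.
#' @return A tibble with a single column `time_s` (strictly increasing).
#' @examples
#' sim_spike_train(rate = 2, duration = 10, seed = 1)
#' @export
sim_spike_train <- function(rate, duration, refractory = 0, seed = NULL) {
  check_number(rate, "rate", lower = 0)
  check_number(duration, "duration", lower = 0, strict_lower = TRUE)
  check_number(refractory, "refractory", lower = 0)
  if (rate * refractory >= 1) {
    stop_geciq("`rate * refractory` >= 1: requested rate is infeasible under the refractory period.",
               "geciq_error_domain")
  }
  if (rate == 0) return(tibble::tibble(time_s = numeric()))
  times <- with_seed_if(seed, {
    n <- rpois(1, rate * duration)
    sort(runif(n, 0, duration))
  })
  if (refractory > 0 && length(times) > 1) {
    keep <- times[1]
    last <- times[1]
    for (t in times[-1]) {
      if (t - last >= refractory) {
        keep <- c(keep, t)
        last <- t
      }
    }
    times <- keep
  }
  tibble::tibble(time_s = times)
}

#' Build a field-stimulation schedule of pulse trains
#'
#' The default protocol mirrors the standard culture characterization
#' paradigm: trains of 1, 2, 3, 5, 10, 20, 40, 80 and 160 electrical pulses
#' delivered at 83 Hz, one train per epoch.
#'
#' @param pulse_counts Integer vector of pulses per train.
#' @param pulse_rate Within-train pulse rate, Hz.
#' @param inter_train_s Gap between the end of one train and the onset of the
#'   next, s. Chosen long enough for fluorescence to return to baseline.
#' @param t0 Onset of the first train, s.
#' @return A tibble with columns `train`, `onset_s`, `pulse_count`,
#'   `pulse_rate_hz` and a `duration_s` attribute-free total via
#'   `schedule_duration()`.
#' @export
stimulus_schedule <- function(pulse_counts = c(1, 2, 3, 5, 10, 20, 40, 80, 160),
                              pulse_rate = 83, inter_train_s = 15, t0 = 5) {
  if (any(pulse_counts < 1) || any(pulse_counts != round(pulse_counts))) {
    stop_geciq("`pulse_counts` must be positive integers.", "geciq_error_domain")
  }
  check_number(pulse_rate, "pulse_rate", lower = 0, strict_lower = TRUE)
  check_number(inter_train_s, "inter_train_s", lower = 0, strict_lower = TRUE)
  train_span <- (pulse_counts - 1) / pulse_rate
  onsets <- t0 + cumsum(c(0, head(train_span, -1) + inter_train_s))
  tibble::tibble(
    train = seq_along(pulse_counts),
    onset_s = onsets,
    pulse_count = as.integer(pulse_counts),
    pulse_rate_hz = pulse_rate
  )
}

#' Total duration implied by a stimulus schedule
#' @param schedule A tibble from [stimulus_schedule()].
#' @param tail_s Extra recording time after the last pulse, s.
#' @return Duration in seconds.
#' @export
schedule_duration <- function(schedule, tail_s = 15) {
  last <- schedule$onset_s + (schedule$pulse_count - 1) / schedule$pulse_rate_hz
  max(last) + tail_s
}

#' Expand a stimulus schedule into individual spike times
#'
#' Each train of `k` pulses at rate `r` contributes `k` events spaced `1/r`
#' seconds apart starting at the train onset. Trains must not overlap after
#' expansion.
#'
#' @param schedule A tibble with columns `onset_s`, `pulse_count`,
#'   `pulse_rate_hz` (see [stimulus_schedule()]).
#' @return A tibble with columns `time_s` and `train`.
#' @examples
#' nrow(schedule_to_spikes(stimulus_schedule()))  # 321 events
#' @export
schedule_to_spikes <- function(schedule) {
  req <- c("onset_s", "pulse_count", "pulse_rate_hz")
  if (!is.data.frame(schedule) || !all(req %in% names(schedule))) {
    stop_geciq("`schedule` must have columns onset_s, pulse_count, pulse_rate_hz.",
               "geciq_error_input")
  }
  schedule <- dplyr::arrange(schedule, .data$onset_s)
  spikes <- purrr::pmap_dfr(
    list(schedule$onset_s, schedule$pulse_count, schedule$pulse_rate_hz,
         seq_len(nrow(schedule))),
    function(onset, k, r, id) {
      tibble::tibble(time_s = onset + (seq_len(k) - 1) / r, train = id)
    })
  if (is.unsorted(spikes$time_s, strictly = TRUE)) {
    stop_geciq("expanded trains overlap; increase inter-train spacing.",
               "geciq_error_schedule")
  }
  spikes
}
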