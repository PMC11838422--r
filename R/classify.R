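# Responsiveness classifiers and orientation tuning.

#' Classify a neuron as stimulus-responsive from trial pre/post activity
#'
#' Implements the two-criterion rule used for visually evoked responses: a
#' neuron is responsive iff (1) a Wilcoxon rank-sum test between the per-trial
#' mean activity in the pre-onset and post-onset windows reaches `p < alpha`,
#' and (2) the trial-averaged peak response exceeds `amp_sd_factor` sample
#' standard deviations of the trial-averaged baseline. When trials from
#' several stimulus conditions are supplied (a `condition` column), criterion
#' (1) must hold in at least one condition; no multiple-testing correction is
#' applied by default, matching the at-least-one-direction convention, with
#' an optional Bonferroni flag.
#'
#' @param trials Tibble with columns `trial`, `time_s`, `dff` and optionally
#'   `condition`. Times are relative to stimulus onset at 0 s.
#' @param pre_window,post_window Two-element numeric `c(lo, hi)` windows in
#'   seconds (defaults `c(-2, 0)` and `c(0, 2)`).
#' @param alpha Significance level (default 0.05).
#' @param amp_sd_factor Amplitude criterion in baseline SDs (default 4).
#' @param bonferroni Apply Bonferroni correction across conditions
#'   (default FALSE).
#' @param min_trials Minimum trials per condition (default 5).
#' @return One-row tibble: `responsive`, `p` (minimal across conditions,
#'   corrected if requested), `amplitude_ok`, `n_conditions`.
#' @export
classify_responsive_pre_post <- function(trials, pre_window = c(-2, 0),
                                         post_window = c(0, 2), alpha = 0.05,
                                         amp_sd_factor = 4,
                                         bonferroni = FALSE, min_trials = 5) {
  req <- c("trial", "time_s", "dff")
  if (!is.data.frame(trials) || !all(req %in% names(trials))) {
    stop_geciq("`trials` must have columns trial, time_s, dff.",
               "geciq_error_input")
  }
  if (!"condition" %in% names(trials)) trials$condition <- 1L

  per_condition <- trials |>
    dplyr::group_by(.data$condition, .data$trial) |>
    dplyr::summarise(
      pre = mean(.data$dff[.data$time_s >= pre_window[1] &
                             .data$time_s < pre_window[2]]),
      post = mean(.data$dff[.data$time_s >= post_window[1] &
                              .data$time_s < post_window[2]]),
      .groups = "drop_last") |>
    dplyr::summarise(
      n_trials = dplyr::n(),
      p = if (all(.data$pre == .data$post)) 1 else {
        suppressWarnings(
          wilcox.test(.data$post, .data$pre, exact = NULL)$p.value)
      },
      .groups = "drop")
  if (any(per_condition$n_trials < min_trials)) {
    stop_geciq(sprintf("each condition needs >= %d trials.", min_trials),
               "geciq_error_input")
  }
  k <- nrow(per_condition)
  p_use <- if (bonferroni) pmin(per_condition$p * k, 1) else per_condition$p
  p_min <- min(p_use)

  # amplitude criterion on the trial-averaged trace (all conditions pooled)
  avg <- trials |>
    dplyr::group_by(.data$time_s) |>
    dplyr::summarise(dff = mean(.data$dff), .groups = "drop")
  base <- avg$dff[avg$time_s >= pre_window[1] & avg$time_s < pre_window[2]]
  resp <- avg$dff[avg$time_s >= post_window[1] & avg$time_s <= post_window[2]]
  base_sd <- sd(base)
  amplitude_ok <- if (is.na(base_sd) || base_sd == 0) {
    max(resp) > mean(base)
  } else {
    max(resp) - mean(base) > amp_sd_factor * base_sd
  }
  tibble::tibble(
    responsive = p_min < alpha && amplitude_ok,
    p = p_min, amplitude_ok = amplitude_ok, n_conditions = k
  )
}

#' Classify responsiveness by post-onset z-score
#'
#' A trace is responsive iff its dF/F z-score, normalized by the pre-onset
#' mean and sample SD, strictly exceeds `threshold` at any frame within
#' `window` seconds of stimulus onset (strict `>`: a step of exactly
#' `threshold` SDs is not responsive).
#'
#' @param dff_trace Tibble with `time_s` and `dff` columns (or numeric vector
#'   plus `frame_rate`).
#' @param onset_s Stimulus onset time, s.
#' @param window Post-onset window, s (default 3).
#' @param threshold Z-score threshold (default 2.5).
#' @param min_baseline_frames Minimum pre-onset frames for normalization
#'   (default 10).
#' @param frame_rate Used when `dff_trace` is a bare numeric vector.
#' @return One-row tibble: `responsive`, `max_z`.
#' @export
classify_responsive_zscore <- function(dff_trace, onset_s, window = 3,
                                       threshold = 2.5,
                                       min_baseline_frames = 10,
                                       frame_rate = NULL) {
  if (is.data.frame(dff_trace)) {
    v <- trace_values(dff_trace, "dff")
    t <- if ("time_s" %in% names(dff_trace)) dff_trace$time_s else {
      (seq_along(v) - 1) / trace_frame_rate(dff_trace, frame_rate)
    }
  } else {
    v <- as.numeric(dff_trace)
    t <- (seq_along(v) - 1) / trace_frame_rate(dff_trace, frame_rate)
  }
  base <- v[t < onset_s]
  if (length(base) < min_baseline_frames) {
    stop_geciq(sprintf("need >= %d baseline frames before onset.",
                       min_baseline_frames), "geciq_error_input")
  }
  mu <- mean(base)
  s <- sd(base)
  if (s == 0) {
    rlang::warn("zero baseline SD; z-score undefined, returning sentinel.")
    return(tibble::tibble(responsive = NA, max_z = Inf))
  }
  post <- v[t >= onset_s & t <= onset_s + window]
  if (length(post) == 0) {
    stop_geciq("no frames in the post-onset window.", "geciq_error_input")
  }
  max_z <- max((post - mu) / s)
  tibble::tibble(responsive = max_z > threshold, max_z = max_z)
}

#' Orientation selectivity index
#'
#' `OSI = (R_pref - R_orth) / (R_pref + R_orth)`, where `R_pref` is the mean
#' response at the preferred orientation (the maximum of the tuning curve)
#' and `R_orth` the response at the orientation 90 degrees away. With
#' non-negative responses the OSI lies in `[0, 1]`; a negative `R_orth` can
#' push it above 1, in which case the value is reported but flagged
#' (`gt1 = TRUE`) since such neurons are conventionally excluded.
#'
#' @param tuning Tibble with columns `orientation` (degrees, e.g. 0 to 157.5
#'   in steps of 22.5) and `response` (mean response per orientation).
#' @return One-row tibble: `osi`, `r_pref`, `r_orth`, `pref_orientation`,
#'   `gt1`.
#' @examples
#' osi(tibble::tibble(orientation = seq(0, 157.5, 22.5),
#'                    response = c(1, .6, .3, .2, .2, .2, .3, .6)))
#' @export
osi <- function(tuning) {
  if (!is.data.frame(tuning) ||
      !all(c("orientation", "response") %in% names(tuning))) {
    stop_geciq("`tuning` must have columns orientation and response.",
               "geciq_error_input")
  }
  ipref <- which.max(tuning$response)
  r_pref <- tuning$response[ipref]
  pref <- tuning$orientation[ipref]
  orth_angle <- (pref + 90) %% 180
  iorth <- which.min(abs((tuning$orientation - orth_angle + 90) %% 180 - 90))
  r_orth <- tuning$response[iorth]
  if (r_pref + r_orth == 0) {
    stop_geciq("R_pref + R_orth is zero; OSI undefined.", "geciq_error_domain")
  }
  val <- (r_pref - r_orth) / (r_pref + r_orth)
  tibble::tibble(osi = val, r_pref = r_pref, r_orth = r_orth,
                 pref_orientation = pref, gt1 = val > 1)
}
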