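# Per-event transient metrics: peak amplitude, SNR, kinetics, decay times,
# event-triggered averages, spike isolation, and the pharmacological
# dynamic-range readout.

#' Peak dF/F0 within a search window
#'
#' @param dff_trace A tibble from [dff()] (with a `dff` column) or a numeric
#'   vector of dF/F0 values.
#' @param search_window Optional integer frame indices to search (default:
#'   whole trace). Must be non-empty.
#' @return The maximum dF/F0 in the window (not clipped at zero).
#' @export
peak_dff <- function(dff_trace, search_window = NULL) {
  v <- trace_values(dff_trace, col = if (is.data.frame(dff_trace)) "dff" else "value")
  idx <- search_window %||% seq_along(v)
  idx <- idx[idx >= 1 & idx <= length(v)]
  if (length(idx) == 0) {
    stop_geciq("empty search window.", "geciq_error_input")
  }
  max(v[idx])
}

#' Peak signal-to-noise ratio of a fluorescence transient
#'
#' `SNR = dF_max / SD(noise basis)`, where `dF_max` is the maximal
#' fluorescence change over the baseline mean within `peak_window`, and the
#' noise SD is either the sample SD of the raw fluorescence in
#' `baseline_window` (`"raw_f_sd"`, the pre-stimulus-window convention) or
#' the SD of the frames whose values fall at or below the `percentile`-th
#' percentile of the entire trace (`"low_quantile_sd"`, the
#' whole-session low-quantile convention). The ratio is invariant to
#' multiplicative rescaling of the trace.
#'
#' @param trace Raw fluorescence trace (tibble or numeric vector).
#' @param baseline_window Integer frame indices of the baseline segment
#'   (>= 2 frames).
#' @param peak_window Integer frame indices to search for the peak (default:
#'   all frames after the baseline window).
#' @param noise_basis `"raw_f_sd"` or `"low_quantile_sd"`.
#' @param percentile Percentile for `low_quantile_sd` (default 20).
#' @return The SNR (dimensionless). A zero-variance noise basis returns `Inf`
#'   with a warning (flagged sentinel rather than an error).
#' @export
peak_snr <- function(trace, baseline_window, peak_window = NULL,
                     noise_basis = c("raw_f_sd", "low_quantile_sd"),
                     percentile = 20) {
  noise_basis <- match.arg(noise_basis)
  v <- trace_values(trace)
  bw <- baseline_window[baseline_window >= 1 & baseline_window <= length(v)]
  if (length(bw) < 2) {
    stop_geciq("baseline window must contain >= 2 frames.", "geciq_error_input")
  }
  pw <- peak_window %||% setdiff(seq_along(v), seq_len(max(bw)))
  if (length(pw) == 0) {
    stop_geciq("empty peak window.", "geciq_error_input")
  }
  f0 <- mean(v[bw])
  dmax <- max(v[pw]) - f0
  noise_sd <- switch(noise_basis,
    raw_f_sd = sd(v[bw]),
    low_quantile_sd = {
      thr <- quantile(v, percentile / 100, type = 7)
      low <- v[v <= thr]
      if (length(low) < 2) NA_real_ else sd(low)
    })
  if (is.na(noise_sd) || noise_sd == 0) {
    rlang::warn("noise basis has zero variance; returning infinite SNR sentinel.")
    return(Inf)
  }
  dmax / noise_sd
}

# First linear-interpolation crossing time of `level`, scanning indices `idx`
# (in order) of series (t, v); `rising` chooses upward/downward crossings.
interp_crossing <- function(t, v, idx, level, rising) {
  for (k in seq_len(length(idx) - 1L)) {
    i <- idx[k]; j <- idx[k + 1L]
    hit <- if (rising) v[i] <= level && v[j] >= level
           else v[i] >= level && v[j] <= level
    if (hit) {
      if (v[j] == v[i]) return(t[i])
      return(t[i] + (level - v[i]) * (t[j] - t[i]) / (v[j] - v[i]))
    }
  }
  NA_real_
}

#' Half-rise and half-decay times of a single fluorescence transient
#'
#' The epoch must contain a single peak. Half-rise is the time from the
#' half-maximum crossing on the rising edge to the peak; half-decay is the
#' time from the peak to the half-maximum crossing on the falling edge.
#'
#' In `"exponential"` mode (the standard single-exponential convention) the
#' rising segment is fitted with a saturating exponential and the decaying
#' segment with a decaying exponential; half-crossings are then located by
#' linear interpolation between frames on the fitted curves, and the fit R^2
#' (over both segments) is reported. Transients whose fit R^2 falls below
#' `r2_threshold` are flagged `excluded` (mirroring the fitting-coefficient
#' < 0.8 exclusion rule). `"interpolation_only"` interpolates the raw
#' samples directly and reports no fit quality.
#'
#' @param epoch A tibble with `time_s` and `dff` columns (e.g. a slice of a
#'   [dff()] trace), or numeric dF/F0 values plus `frame_rate`.
#' @param fit `"exponential"` or `"interpolation_only"`.
#' @param r2_threshold Exclusion threshold on the fit R^2 (default 0.8).
#' @param frame_rate Used only when `epoch` is a bare numeric vector.
#' @return One-row tibble: `t_half_rise_s`, `t_half_decay_s`, `fit_r2`,
#'   `excluded`.
#' @examples
#' t <- seq(0, 5, by = 0.05)
#' ep <- tibble::tibble(time_s = t,
#'                      dff = ifelse(t < 1, t, exp(-(t - 1) / 0.5)))
#' half_times(ep)
#' @export
half_times <- function(epoch, fit = c("exponential", "interpolation_only"),
                       r2_threshold = 0.8, frame_rate = NULL) {
  fit <- match.arg(fit)
  if (is.data.frame(epoch)) {
    v <- trace_values(epoch, "dff")
    t <- if ("time_s" %in% names(epoch)) epoch$time_s else {
      (seq_along(v) - 1) / trace_frame_rate(epoch, frame_rate)
    }
  } else {
    v <- as.numeric(epoch)
    t <- (seq_along(v) - 1) / trace_frame_rate(epoch, frame_rate)
  }
  n <- length(v)
  ip <- which.max(v)
  if (ip == 1L || ip == n) {
    stop_geciq("peak lies at the epoch boundary; rise or decay phase undefined.",
               "geciq_error_boundary")
  }
  peak <- v[ip]
  half <- peak / 2

  if (fit == "interpolation_only") {
    t_rise_cross <- interp_crossing(t, v, rev(seq_len(ip)), half, rising = FALSE)
    # scanning backwards from the peak finds the last upward crossing
    t_decay_cross <- interp_crossing(t, v, ip:n, half, rising = FALSE)
    return(tibble::tibble(
      t_half_rise_s = t[ip] - t_rise_cross,
      t_half_decay_s = t_decay_cross - t[ip],
      fit_r2 = NA_real_, excluded = FALSE))
  }

  rise_idx <- seq_len(ip)
  decay_idx <- ip:n
  t0 <- t[1]; tp <- t[ip]
  d_rise <- data.frame(x = t[rise_idx] - t0, y = v[rise_idx])
  d_decay <- data.frame(x = t[decay_idx] - tp, y = v[decay_idx])
  rise_fit <- tryCatch(
    minpack.lm::nlsLM(y ~ A * (1 - exp(-x / tau)), data = d_rise,
                      start = list(A = peak, tau = max((tp - t0) / 2, 1e-6)),
                      lower = c(A = 1e-12, tau = 1e-9),
                      control = minpack.lm::nls.lm.control(maxiter = 500)),
    error = function(e) NULL)
  decay_fit <- tryCatch(
    minpack.lm::nlsLM(y ~ A * exp(-x / tau), data = d_decay,
                      start = list(A = peak,
                                   tau = max((t[n] - tp) / 3, 1e-6)),
                      lower = c(A = 1e-12, tau = 1e-9),
                      control = minpack.lm::nls.lm.control(maxiter = 500)),
    error = function(e) NULL)
  if (is.null(rise_fit) || is.null(decay_fit)) {
    return(tibble::tibble(t_half_rise_s = NA_real_, t_half_decay_s = NA_real_,
                          fit_r2 = NA_real_, excluded = TRUE))
  }
  rise_hat <- fitted(rise_fit)
  decay_hat <- fitted(decay_fit)
  fit_r2 <- r_squared(c(d_rise$y, d_decay$y), c(rise_hat, decay_hat))

  # half crossings by linear interpolation between frames on the fitted curves
  rise_peak_hat <- rise_hat[length(rise_hat)]
  decay_peak_hat <- decay_hat[1]
  t_rise_cross <- interp_crossing(t[rise_idx], rise_hat,
                                  seq_along(rise_idx), rise_peak_hat / 2,
                                  rising = TRUE)
  t_decay_cross <- interp_crossing(t[decay_idx], decay_hat,
                                   seq_along(decay_idx), decay_peak_hat / 2,
                                   rising = FALSE)
  if (is.na(t_rise_cross)) t_rise_cross <- t0
  tibble::tibble(
    t_half_rise_s = tp - t_rise_cross,
    t_half_decay_s = t_decay_cross - tp,
    fit_r2 = fit_r2,
    excluded = fit_r2 < r2_threshold
  )
}

#' Full decay time of an isolated calcium spike
#'
#' Time from the transient peak to the first post-peak point at which dF/F0
#' returns to (crosses) zero, with linear interpolation at the crossing. The
#' "return to the negative of the spike" criterion is interpreted as the
#' first zero-crossing after the peak; traces that never return before the
#' epoch ends are flagged right-censored.
#'
#' @param epoch Tibble with `time_s` and `dff` columns (single spike).
#' @param frame_rate Used when `epoch` is a bare numeric vector.
#' @return One-row tibble: `full_decay_s` (NA when censored), `censored`.
#' @export
full_decay_time <- function(epoch, frame_rate = NULL) {
  if (is.data.frame(epoch)) {
    v <- trace_values(epoch, "dff")
    t <- if ("time_s" %in% names(epoch)) epoch$time_s else {
      (seq_along(v) - 1) / trace_frame_rate(epoch, frame_rate)
    }
  } else {
    v <- as.numeric(epoch)
    t <- (seq_along(v) - 1) / trace_frame_rate(epoch, frame_rate)
  }
  ip <- which.max(v)
  if (ip == length(v)) {
    return(tibble::tibble(full_decay_s = NA_real_, censored = TRUE))
  }
  cross <- interp_crossing(t, v, ip:length(v), 0, rising = FALSE)
  if (is.na(cross)) {
    tibble::tibble(full_decay_s = NA_real_, censored = TRUE)
  } else {
    tibble::tibble(full_decay_s = cross - t[ip], censored = FALSE)
  }
}

#' Keep only temporally isolated spike events
#'
#' An event is isolated when no other event occurs within `min_gap` on either
#' side (the first/last events only need one clear side).
#'
#' @param spike_times Sorted numeric vector of event times (s or frames).
#' @param min_gap Minimum separation in the same units (e.g. 1 s at 2P frame
#'   rates, 40 frames for 10 Hz wide-field data).
#' @return Integer indices of the isolated events.
#' @examples
#' isolate_single_spikes(c(1, 5, 5.5, 10), min_gap = 1)  # 1 and 4
#' @export
isolate_single_spikes <- function(spike_times, min_gap) {
  if (length(spike_times) == 0) return(integer())
  if (is.unsorted(spike_times)) {
    stop_geciq("`spike_times` must be sorted.", "geciq_error_input")
  }
  if (length(spike_times) == 1) return(1L)
  gap_prev <- c(Inf, diff(spike_times))
  gap_next <- c(diff(spike_times), Inf)
  which(gap_prev > min_gap & gap_next > min_gap)
}

#' Event-triggered average waveform
#'
#' Aligns snippets of `pre` frames before to `post` frames after each event
#' and returns the per-offset mean and sample SD across events. Events whose
#' snippet would extend beyond the trace are dropped.
#'
#' @param dff_trace Tibble with a `dff` column, or numeric vector.
#' @param events Integer frame indices of event onsets/peaks.
#' @param pre,post Frames before/after the event to include.
#' @return Tibble with `offset_frame` (-pre..post), `mean`, `sd`, `n_events`.
#' @export
event_triggered_average <- function(dff_trace, events, pre, post) {
  v <- trace_values(dff_trace, col = if (is.data.frame(dff_trace)) "dff" else "value")
  n <- length(v)
  usable <- events[events - pre >= 1 & events + post <= n]
  if (length(usable) == 0) {
    stop_geciq("no event snippet fits fully inside the trace.",
               "geciq_error_input")
  }
  offsets <- -pre:post
  snips <- vapply(usable, function(e) v[e + offsets],
                  numeric(length(offsets)))
  snips <- matrix(snips, nrow = length(offsets))
  tibble::tibble(
    offset_frame = offsets,
    mean = rowMeans(snips),
    sd = apply(snips, 1, sd),
    n_events = length(usable)
  )
}

#' Maximal pharmacological response dFmax/Fmin
#'
#' For an ionomycin-style saturating response, `F_min` is the single-frame
#' minimum before the fluorescence rise (i.e. up to the frame of the maximum
#' within the window) and `dF_max = F_max - F_min`; the statistic is
#' `dF_max / F_min`, which approaches the indicator's in-cell dynamic range
#' minus one for a full-scale response.
#'
#' @param trace Raw fluorescence trace (tibble or numeric vector).
#' @param response_window Optional integer frame indices (default: whole
#'   trace).
#' @return `(F_max - F_min) / F_min` (0 for a constant trace).
#' @export
dmax_over_fmin <- function(trace, response_window = NULL) {
  v <- trace_values(trace)
  idx <- response_window %||% seq_along(v)
  idx <- idx[idx >= 1 & idx <= length(v)]
  if (length(idx) == 0) stop_geciq("empty response window.", "geciq_error_input")
  w <- v[idx]
  imax <- which.max(w)
  f_min <- min(w[seq_len(imax)])
  if (f_min <= 0) {
    stop_geciq("F_min must be positive.", "geciq_error_domain")
  }
  (max(w) - f_min) / f_min
}
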