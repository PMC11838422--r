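# Baseline (F0) estimation and dF/F0 normalization. Each named method mirrors
# one of the F0 conventions in common use for the different imaging regimes:
# a pre-stimulus window mean (culture), a sliding low-percentile window
# (zebrafish confocal: 20th percentile over 200 frames; brainstem 2P: 10th
# percentile over 60 s), a spline fit to the whole trace (slow drift /
# photobleaching), and a short spline through the frames just before a spike
# (wide-field event analysis).

#' Estimate the fluorescence baseline F0 of a trace
#'
#' @param trace Trace tibble (`frame`, `time_s`, `value`) or numeric vector
#'   (then `frame_rate` must be given).
#' @param method One of:
#'   * `"pre_window_mean"`: mean of the `window` seconds (or frames, see
#'     `window_unit`) immediately before `event_onset`; returns a scalar.
#'   * `"sliding_percentile"`: running `percentile` over a centered window of
#'     `window` frames/seconds, truncated (not padded) at the edges; returns a
#'     per-frame baseline. Percentiles use the linear-interpolation
#'     definition (`stats::quantile` type 7).
#'   * `"spline_fit"`: smoothing spline over the whole trace; returns a
#'     per-frame baseline (captures slow drift such as photobleaching).
#'   * `"pre_spike_spline"`: polynomial spline through the `window` frames
#'     (default 3) before `event_onset`, evaluated at the onset; returns a
#'     scalar.
#' @param window Window size; seconds by default, frames when
#'   `window_unit = "frames"`. Defaults per method: 1 s for
#'   `pre_window_mean`, 200 frames for `sliding_percentile`, 3 frames for
#'   `pre_spike_spline`.
#' @param window_unit `"s"` or `"frames"`.
#' @param percentile Percentile in `[0, 100]` for `sliding_percentile`
#'   (default 20).
#' @param event_onset Frame index of the stimulus/event onset (1-based);
#'   required for the `pre_*` methods.
#' @param frame_rate Sampling rate, Hz; taken from the trace when omitted.
#' @param spar Smoothing parameter forwarded to [stats::smooth.spline()] for
#'   `spline_fit`.
#' @return A scalar (pre-window methods) or numeric vector with one baseline
#'   value per frame (sliding/spline methods). Constant input returns that
#'   constant under every method.
#' @export
estimate_baseline <- function(trace,
                              method = c("pre_window_mean",
                                         "sliding_percentile", "spline_fit",
                                         "pre_spike_spline"),
                              window = NULL, window_unit = c("s", "frames"),
                              percentile = 20, event_onset = NULL,
                              frame_rate = NULL, spar = NULL) {
  method <- match.arg(method)
  window_unit <- match.arg(window_unit)
  v <- trace_values(trace)
  n <- length(v)
  if (percentile < 0 || percentile > 100) {
    stop_geciq("`percentile` must be in [0, 100].", "geciq_error_domain")
  }
  to_frames <- function(w, default_frames) {
    if (is.null(w)) return(default_frames)
    if (window_unit == "frames") return(as.integer(round(w)))
    fr <- trace_frame_rate(trace, frame_rate)
    as.integer(round(w * fr))
  }

  if (method %in% c("pre_window_mean", "pre_spike_spline")) {
    if (is.null(event_onset)) {
      stop_geciq(sprintf("`event_onset` is required for method \"%s\".", method),
                 "geciq_error_missing_onset")
    }
    if (event_onset < 2 || event_onset > n + 1) {
      stop_geciq("`event_onset` must lie within the trace (with at least one preceding frame).",
                 "geciq_error_input")
    }
  }

  switch(method,
    pre_window_mean = {
      w <- if (is.null(window) && window_unit == "s") {
        to_frames(1, NA)
      } else {
        to_frames(window, 1L)
      }
      lo <- max(1L, event_onset - w)
      mean(v[lo:(event_onset - 1L)])
    },
    sliding_percentile = {
      w <- to_frames(window, 200L)
      if (w < 1) stop_geciq("window must be >= 1 frame.", "geciq_error_domain")
      half <- w %/% 2L
      vapply(seq_len(n), function(i) {
        lo <- max(1L, i - half)
        hi <- min(n, lo + w - 1L)
        lo <- max(1L, hi - w + 1L)  # keep full width when truncated at the end
        unname(quantile(v[lo:hi], percentile / 100, type = 7))
      }, numeric(1))
    },
    spline_fit = {
      if (n < 10) stop_geciq("spline_fit needs >= 10 frames.", "geciq_error_input")
      if (diff(range(v)) == 0) return(rep(v[1], n))
      fit <- if (is.null(spar)) {
        smooth.spline(seq_len(n), v)
      } else {
        smooth.spline(seq_len(n), v, spar = spar)
      }
      as.numeric(predict(fit, seq_len(n))$y)
    },
    pre_spike_spline = {
      w <- to_frames(window, 3L)
      lo <- max(1L, event_onset - w)
      idx <- lo:(event_onset - 1L)
      if (length(idx) == 1L) return(v[idx])
      # low-order polynomial through the pre-spike frames, read out at onset
      deg <- min(2L, length(idx) - 1L)
      fit <- lm(y ~ poly(x, deg, raw = TRUE),
                data = data.frame(x = idx, y = v[idx]))
      unname(predict(fit, newdata = data.frame(x = event_onset)))
    }
  )
}

#' Baseline-normalized fluorescence change
#'
#' Computes `dF/F0 = (F - F0) / F0` elementwise. `f0` may be a scalar or a
#' per-frame baseline of the same length as the trace.
#'
#' @param trace Trace tibble or numeric vector.
#' @param f0 Baseline (scalar or per-frame), strictly positive everywhere.
#' @return A tibble with columns `frame`, `time_s` (when available), `f0` and
#'   `dff`.
#' @examples
#' dff(c(10, 15, 30), f0 = 10)$dff  # 0, 0.5, 2
#' @export
dff <- function(trace, f0) {
  v <- trace_values(trace)
  n <- length(v)
  if (!length(f0) %in% c(1L, n)) {
    stop_geciq("`f0` must be a scalar or one value per frame.",
               "geciq_error_input")
  }
  f0v <- rep_len(as.numeric(f0), n)
  bad <- which(f0v <= 0)
  if (length(bad)) {
    stop_geciq(sprintf("non-positive baseline at frame %d.", bad[1]),
               "geciq_error_domain")
  }
  out <- tibble::tibble(frame = seq_len(n))
  if (is.data.frame(trace) && "time_s" %in% names(trace)) {
    out$time_s <- trace$time_s
  }
  out$f0 <- f0v
  out$dff <- (v - f0v) / f0v
  fr <- tryCatch(trace_frame_rate(trace), error = function(e) NULL)
  if (!is.null(fr)) attr(out, "frame_rate") <- fr
  out
}
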