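# Spike-to-calcium and calcium-to-fluorescence transduction, plus the photon
# noise model. These produce the per-neuron ground-truth signals used by the
# scene renderer and by all metric calibration tests.

#' Convert a spike train to an intracellular calcium trace
#'
#' Linear exponential-kernel surrogate: each action potential adds an
#' instantaneous increment `a_per_ap` (nM) that decays mono-exponentially
#' with time constant `tau_ca`, superimposed on the resting level:
#' `ca(t) = ca_rest + sum_i a_per_ap * exp(-(t - t_i)/tau_ca) * 1[t >= t_i]`.
#'
#' Defaults reflect neuronal physiology: a resting free calcium of 50 nM
#' (neurons rest at roughly 30-100 nM) and a 20 nM per-AP increment, which
#' together with the FRCaMPi Hill constants yield single-AP fluorescence
#' responses of order `dF/F ~ 0.8`. Indicator calcium buffering can be
#' represented by scaling `a_per_ap` down.
#'
#' @param spikes Tibble with a `time_s` column (or numeric vector of spike
#'   times, s).
#' @param duration Trace duration, s.
#' @param frame_rate Sampling rate, Hz.
#' @param ca_rest Resting free calcium, nM.
#' @param a_per_ap Calcium increment per action potential, nM.
#' @param tau_ca Calcium decay time constant, s (> 0).
#' @return A trace tibble (`frame`, `time_s`, `value` = `[Ca2+]` in nM) with a
#'   `frame_rate` attribute.
#' @examples
#' ca <- sim_calcium(tibble::tibble(time_s = 1), duration = 5, frame_rate = 20)
#' max(ca$value)  # ca_rest + a_per_ap at the spike frame
#' @export
sim_calcium <- function(spikes, duration, frame_rate = 20, ca_rest = 50,
                        a_per_ap = 20, tau_ca = 1) {
  times <- if (is.data.frame(spikes)) spikes$time_s else as.numeric(spikes)
  check_number(tau_ca, "tau_ca", lower = 0, strict_lower = TRUE)
  check_number(ca_rest, "ca_rest", lower = 0)
  n <- max(1L, floor(duration * frame_rate))
  t <- (seq_len(n) - 1) / frame_rate
  values <- rep(ca_rest, n)
  for (ti in times) {
    idx <- t >= ti
    values[idx] <- values[idx] + a_per_ap * exp(-(t[idx] - ti) / tau_ca)
  }
  out <- new_trace(values, frame_rate)
  attr(out, "ca_rest") <- ca_rest
  attr(out, "a_per_ap") <- a_per_ap
  attr(out, "tau_ca") <- tau_ca
  out
}

#' Transduce a calcium trace into indicator fluorescence
#'
#' In `equilibrium` mode the Hill curve is applied pointwise
#' ([hill_fluorescence()]): appropriate when binding kinetics are fast
#' relative to the frame interval. In `kinetic` mode the bound fraction `b`
#' follows the single-site relaxation
#' `db/dt = k_on * ca^n * (1 - b) - k_off * b` (with `kd^n = k_off / k_on`),
#' integrated with a fixed-step explicit scheme at `steps_per_frame`
#' substeps per frame, and fluorescence is the affine map of `b` onto
#' `[f_apo, f_sat]`. As `k_off` (at fixed `k_off/k_on`) grows the kinetic
#' output converges to the equilibrium output.
#'
#' @param ca Calcium trace tibble from [sim_calcium()] (nM values).
#' @param params An [indicator_params()] object.
#' @param mode `"equilibrium"` or `"kinetic"`.
#' @param k_off Unbinding rate, 1/s (kinetic mode).
#' @param k_on Binding rate per nM^n per s; defaults to `k_off / kd^n` so the
#'   equilibrium constant matches `params$kd`.
#' @param steps_per_frame Explicit-integration substeps per frame (>= 20
#'   recommended). The integration aborts with advice to decrease the step if
#'   the relaxation rate is too fast for the chosen step.
#' @return A fluorescence trace tibble (`frame`, `time_s`, `value`).
#' @export
sim_fluorescence <- function(ca, params, mode = c("equilibrium", "kinetic"),
                             k_off = 10, k_on = NULL, steps_per_frame = 20) {
  mode <- match.arg(mode)
  stopifnot(inherits(params, "indicator_params"))
  values <- trace_values(ca)
  fr <- trace_frame_rate(ca)
  if (mode == "equilibrium") {
    out <- new_trace(hill_fluorescence(values, params), fr)
    return(out)
  }
  check_number(k_off, "k_off", lower = 0, strict_lower = TRUE)
  kdn <- params$kd^params$hill_n
  if (is.null(k_on)) k_on <- k_off / kdn
  check_number(k_on, "k_on", lower = 0, strict_lower = TRUE)
  dt <- 1 / (fr * steps_per_frame)
  drive <- values^params$hill_n
  rate_max <- max(k_on * drive + k_off)
  if (rate_max * dt > 0.5) {
    stop_geciq(sprintf(
      "kinetic integration unstable (rate*dt = %.2f); increase `steps_per_frame` above %d.",
      rate_max * dt, ceiling(2 * rate_max / fr)), "geciq_error_step")
  }
  b <- drive[1] / (drive[1] + kdn)  # start at equilibrium for the first frame
  bound <- numeric(length(values))
  bound[1] <- b
  for (i in seq_along(values)[-1]) {
    for (s in seq_len(steps_per_frame)) {
      b <- b + dt * (k_on * drive[i] * (1 - b) - k_off * b)
    }
    b <- min(max(b, 0), 1)
    bound[i] <- b
  }
  new_trace(params$f_apo + (params$f_sat - params$f_apo) * bound, fr)
}

#' Add shot noise and read noise to a trace or movie
#'
#' Each sample `F` is replaced by `Poisson(photons_per_unit * F) /
#' photons_per_unit + Normal(0, read_noise_sd)`. The Poisson term models
#' photon shot noise (variance proportional to signal), the Gaussian term
#' camera read noise. As `photons_per_unit` grows the output converges to the
#' input.
#'
#' @param x A trace tibble (with a `value` column), a numeric vector, or a
#'   3-D movie array (rows x cols x frames).
#' @param photons_per_unit Detected photons per fluorescence unit (> 0).
#' @param read_noise_sd Gaussian read-noise SD, same units as the input.
#' @param seed Optional integer seed; identical seeds give identical output.
#' @return Same shape as the input, with noise applied.
#' @export
add_photon_noise <- function(x, photons_per_unit, read_noise_sd = 0,
                             seed = NULL) {
  check_number(photons_per_unit, "photons_per_unit", lower = 0,
               strict_lower = TRUE)
  check_number(read_noise_sd, "read_noise_sd", lower = 0)
  noisify <- function(v) {
    if (any(v < 0)) {
      stop_geciq("input values must be non-negative for photon noise.",
                 "geciq_error_domain")
    }
    n <- length(v)
    with_seed_if(seed, {
      shot <- rpois(n, photons_per_unit * v) / photons_per_unit
      if (read_noise_sd > 0) shot <- shot + rnorm(n, 0, read_noise_sd)
      shot
    })
  }
  if (is.data.frame(x)) {
    x$value <- noisify(x$value)
    x
  } else if (is.array(x) && length(dim(x)) == 3) {
    out <- x
    out[] <- noisify(as.numeric(x))
    out
  } else if (is.numeric(x)) {
    noisify(x)
  } else {
    stop_geciq("`x` must be a trace tibble, numeric vector or 3-D array.",
               "geciq_error_input")
  }
}
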