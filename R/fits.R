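# Nonlinear titration / decay fitting. All fits go through minpack.lm::nlsLM
# (bounded Levenberg-Marquardt least squares) with deterministic, data-driven
# starting values.

new_geci_fit <- function(params, r2, converged, model, data, extra = list()) {
  structure(
    c(list(params = params, r2 = r2, converged = converged,
           model = model, data = data), extra),
    class = "geci_fit"
  )
}

#' @export
print.geci_fit <- function(x, ...) {
  cat(sprintf("<geci_fit> model: %s | R^2 = %.4f | converged: %s\n",
              x$model, x$r2, x$converged))
  print(x$params)
  invisible(x)
}

#' Tidy a geciq fit object
#'
#' @param x A `geci_fit` object returned by one of the fitting functions.
#' @param ... Unused.
#' @return For `tidy()`, a tibble with one row per fitted parameter
#'   (`term`, `estimate`). For `glance()`, a one-row tibble with `r2`,
#'   `converged`, `model` and `nobs`.
#' @exportS3Method generics::tidy
tidy.geci_fit <- function(x, ...) x$params

#' @rdname tidy.geci_fit
#' @exportS3Method generics::glance
glance.geci_fit <- function(x, ...) {
  tibble::tibble(r2 = x$r2, converged = x$converged, model = x$model,
                 nobs = nrow(x$data))
}

r_squared <- function(observed, fitted) {
  ss_res <- sum((observed - fitted)^2)
  ss_tot <- sum((observed - mean(observed))^2)
  if (ss_tot == 0) return(ifelse(ss_res == 0, 1, -Inf))
  1 - ss_res / ss_tot
}

check_curve <- function(data, x = "x", y = "y", min_points = 3) {
  if (!is.data.frame(data) || !all(c(x, y) %in% names(data))) {
    stop_geciq(sprintf("`data` must be a data frame with columns `%s` and `%s`.",
                       x, y), "geciq_error_input")
  }
  d <- tibble::tibble(x = as.numeric(data[[x]]), y = as.numeric(data[[y]]))
  if (nrow(d) < min_points) {
    stop_geciq(sprintf("at least %d points are required.", min_points),
               "geciq_error_input")
  }
  if (any(!is.finite(d$x)) || any(!is.finite(d$y))) {
    stop_geciq("curve values must be finite.", "geciq_error_input")
  }
  if (is.unsorted(d$x, strictly = TRUE)) {
    d <- dplyr::arrange(d, x)
    if (is.unsorted(d$x, strictly = TRUE)) {
      stop_geciq("`x` values must be distinct.", "geciq_error_input")
    }
  }
  d
}

# x at which a monotone-ish curve crosses the midpoint of its y range,
# by linear interpolation; used to initialize midpoint parameters.
half_crossing <- function(x, y) {
  mid <- (min(y) + max(y)) / 2
  s <- sign(y - mid)
  idx <- which(s[-1] * s[-length(s)] <= 0)
  if (length(idx) == 0) return(x[which.min(abs(y - mid))])
  i <- idx[1]
  if (y[i + 1] == y[i]) return(x[i])
  x[i] + (mid - y[i]) * (x[i + 1] - x[i]) / (y[i + 1] - y[i])
}

#' Fit a Hill equation to a calcium titration curve
#'
#' Estimates `kd`, `hill_n`, `f_apo` and `f_sat` of
#' `F(ca) = f_apo + (f_sat - f_apo) * ca^n / (ca^n + kd^n)` by bounded
#' nonlinear least squares. Initialization is deterministic and data-driven:
#' `kd` starts at the half-range crossing of the curve (linear interpolation),
#' `hill_n` at 2, and the brightness parameters at the observed extremes.
#' Bounds are `kd` in (0, 1e6] nM, `hill_n` in (0, 10], brightness > 0.
#'
#' @param data Data frame with columns `x` (free `[Ca2+]`, nM, strictly
#'   increasing, >= 5 distinct values spanning the inflection) and `y`
#'   (fluorescence, arbitrary units).
#' @param init Optional named list overriding starting values
#'   (`kd`, `hill_n`, `f_apo`, `f_sat`).
#'
#' @return A `geci_fit` with parameter rows `kd`, `hill_n`, `f_apo`, `f_sat`
#'   and `dynamic_range` (= fitted `f_sat / f_apo`), plus `r2` and a
#'   `converged` flag. See [tidy.geci_fit()].
#' @examples
#' curve <- tibble::tibble(x = 10^seq(0, 4, length.out = 16),
#'                         y = hill_fluorescence(10^seq(0, 4, length.out = 16),
#'                                               frcampi_params()))
#' tidy(fit_hill_titration(curve))
#' @export
fit_hill_titration <- function(data, init = NULL) {
  d <- check_curve(data, min_points = 5)
  if (any(d$x < 0) || any(d$y < 0)) {
    stop_geciq("titration values must be non-negative.", "geciq_error_domain")
  }
  if (max(d$y) / max(min(d$y), .Machine$double.eps) < 1.05) {
    stop_geciq("flat titration curve: Kd is not identifiable.",
               "geciq_error_nonidentifiable")
  }
  start <- list(
    kd = max(half_crossing(d$x, d$y), min(d$x[d$x > 0])),
    hill_n = 2, f_apo = max(min(d$y), 1e-9), f_sat = max(d$y)
  )
  start[names(init)] <- init
  fit <- tryCatch(
    minpack.lm::nlsLM(
      y ~ f_apo + (f_sat - f_apo) * x^hill_n / (x^hill_n + kd^hill_n),
      data = d, start = start,
      lower = c(kd = 1e-9, hill_n = 1e-3, f_apo = 1e-12, f_sat = 1e-12),
      upper = c(kd = 1e6, hill_n = 10, f_apo = Inf, f_sat = Inf),
      control = minpack.lm::nls.lm.control(maxiter = 500)),
    error = function(e) NULL)
  if (is.null(fit)) {
    return(new_geci_fit(
      tibble::tibble(term = names(start), estimate = unlist(start)),
      r2 = NA_real_, converged = FALSE, model = "hill_titration", data = d))
  }
  est <- as.list(coef(fit))
  params <- tibble::tibble(
    term = c("kd", "hill_n", "f_apo", "f_sat", "dynamic_range"),
    estimate = c(est$kd, est$hill_n, est$f_apo, est$f_sat,
                 est$f_sat / est$f_apo)
  )
  new_geci_fit(params, r2 = r_squared(d$y, fitted(fit)), converged = TRUE,
               model = "hill_titration", data = d, extra = list(fit = fit))
}

#' Fit a pH titration (sigmoid in pH, Hill form in [H+])
#'
#' Fits `F(pH) = f_acid + (f_base - f_acid) / (1 + 10^(n * (pka - pH)))`.
#' `pka` is the pH of half-maximal fluorescence between the two fitted
#' asymptotes. Either orientation (fluorescence increasing or decreasing with
#' pH) is supported via the sign of `f_base - f_acid`.
#'
#' @param data Data frame with columns `x` (pH, strictly increasing, spanning
#'   the transition) and `y` (fluorescence).
#' @return A `geci_fit` with parameter rows `pka`, `hill_n`, `f_acid`,
#'   `f_base`.
#' @export
fit_ph_titration <- function(data) {
  d <- check_curve(data, min_points = 4)
  rng <- range(d$y)
  if (rng[2] / max(rng[1], .Machine$double.eps) < 1.05) {
    stop_geciq("flat pH curve: pKa is not identifiable.",
               "geciq_error_nonidentifiable")
  }
  increasing <- d$y[nrow(d)] >= d$y[1]
  start <- list(pka = half_crossing(d$x, d$y), hill_n = 1,
                f_acid = if (increasing) rng[1] else rng[2],
                f_base = if (increasing) rng[2] else rng[1])
  fit <- tryCatch(
    minpack.lm::nlsLM(
      y ~ f_acid + (f_base - f_acid) / (1 + 10^(hill_n * (pka - x))),
      data = d, start = start,
      lower = c(pka = 0, hill_n = 1e-3, f_acid = 0, f_base = 0),
      upper = c(pka = 14, hill_n = 10, f_acid = Inf, f_base = Inf),
      control = minpack.lm::nls.lm.control(maxiter = 500)),
    error = function(e) NULL)
  if (is.null(fit)) {
    return(new_geci_fit(
      tibble::tibble(term = names(start), estimate = unlist(start)),
      r2 = NA_real_, converged = FALSE, model = "ph_titration", data = d))
  }
  est <- as.list(coef(fit))
  params <- tibble::tibble(
    term = c("pka", "hill_n", "f_acid", "f_base"),
    estimate = c(est$pka, est$hill_n, est$f_acid, est$f_base))
  new_geci_fit(params, r2 = r_squared(d$y, fitted(fit)), converged = TRUE,
               model = "ph_titration", data = d, extra = list(fit = fit))
}

#' Fit an exponential photobleaching curve
#'
#' Fits `F(t) = A * exp(-t / tau) + C` (mono) or the sum of two such
#' components (bi) to a fluorescence-versus-time trace recorded under
#' continuous illumination. The half-life of the mono fit is `tau * log(2)`.
#'
#' @param trace Data frame with columns `time_s` and `value` (> 0), at least
#'   10 frames.
#' @param model `"mono"` (default) or `"bi"`.
#' @return A `geci_fit`; for mono fits the parameters are `amplitude`,
#'   `bleach_tau` (s), `offset` and `half_life` (s). A non-decaying trace
#'   returns `converged = FALSE` with a warning.
#' @export
fit_photobleach <- function(trace, model = c("mono", "bi")) {
  model <- match.arg(model)
  d <- check_curve(trace, x = "time_s", y = "value", min_points = 10)
  if (any(d$y <= 0)) {
    stop_geciq("photobleach trace values must be positive.",
               "geciq_error_domain")
  }
  slope <- unname(coef(lm(y ~ x, data = d))[2])
  if (!is.finite(slope) || slope >= 0 || diff(range(d$y)) == 0) {
    rlang::warn("trace does not decay; photobleach fit not performed.")
    return(new_geci_fit(tibble::tibble(term = character(), estimate = numeric()),
                        r2 = NA_real_, converged = FALSE,
                        model = paste0("photobleach_", model), data = d))
  }
  span <- diff(range(d$x))
  if (model == "mono") {
    start <- list(A = max(d$y) - min(d$y), tau = span / 3, C = min(d$y))
    fit <- tryCatch(
      minpack.lm::nlsLM(y ~ A * exp(-x / tau) + C, data = d, start = start,
                        lower = c(A = 1e-12, tau = 1e-9, C = 0),
                        control = minpack.lm::nls.lm.control(maxiter = 500)),
      error = function(e) NULL)
    if (is.null(fit)) {
      return(new_geci_fit(tibble::tibble(term = names(start),
                                         estimate = unlist(start)),
                          r2 = NA_real_, converged = FALSE,
                          model = "photobleach_mono", data = d))
    }
    est <- as.list(coef(fit))
    params <- tibble::tibble(
      term = c("amplitude", "bleach_tau", "offset", "half_life"),
      estimate = c(est$A, est$tau, est$C, est$tau * log(2)))
  } else {
    start <- list(A1 = (max(d$y) - min(d$y)) * 0.7, tau1 = span / 10,
                  A2 = (max(d$y) - min(d$y)) * 0.3, tau2 = span,
                  C = min(d$y))
    fit <- tryCatch(
      minpack.lm::nlsLM(y ~ A1 * exp(-x / tau1) + A2 * exp(-x / tau2) + C,
                        data = d, start = start,
                        lower = c(A1 = 0, tau1 = 1e-9, A2 = 0, tau2 = 1e-9,
                                  C = 0),
                        control = minpack.lm::nls.lm.control(maxiter = 1000)),
      error = function(e) NULL)
    if (is.null(fit)) {
      return(new_geci_fit(tibble::tibble(term = names(start),
                                         estimate = unlist(start)),
                          r2 = NA_real_, converged = FALSE,
                          model = "photobleach_bi", data = d))
    }
    est <- as.list(coef(fit))
    params <- tibble::tibble(
      term = c("amplitude_1", "tau_1", "amplitude_2", "tau_2", "offset"),
      estimate = c(est$A1, est$tau1, est$A2, est$tau2, est$C))
  }
  new_geci_fit(params, r2 = r_squared(d$y, fitted(fit)), converged = TRUE,
               model = paste0("photobleach_", model), data = d,
               extra = list(fit = fit))
}

#' Fit an exponential expression-decay profile along a neurite
#'
#' Fits `I(d) = exp(-d / lambda)` to a soma-normalized fluorescence profile.
#' `lambda` is both the fitted length constant and the distance `d_e_inv` at
#' which the intensity has dropped to `exp(-1)` (36.8%) of the soma value.
#'
#' @param profile Data frame with columns `arclength_um` (distance from the
#'   soma edge, increasing) and `intensity` (positive, normalized so the soma
#'   edge is ~1). At least 4 points.
#' @return A `geci_fit` with parameter rows `lambda_um` and `d_e_inv_um`
#'   (equal by construction). A non-decaying profile returns
#'   `converged = FALSE`.
#' @export
fit_neurite_decay <- function(profile) {
  d <- check_curve(profile, x = "arclength_um", y = "intensity",
                   min_points = 4)
  if (any(d$y <= 0)) {
    stop_geciq("profile intensities must be positive.", "geciq_error_domain")
  }
  slope <- unname(coef(lm(log(y) ~ x, data = d))[2])
  if (!is.finite(slope) || slope >= 0) {
    rlang::warn("profile does not decay; length constant not identifiable.")
    return(new_geci_fit(tibble::tibble(term = character(), estimate = numeric()),
                        r2 = NA_real_, converged = FALSE,
                        model = "neurite_decay", data = d))
  }
  start <- list(lambda = -1 / slope)
  fit <- tryCatch(
    minpack.lm::nlsLM(y ~ exp(-x / lambda), data = d, start = start,
                      lower = c(lambda = 1e-9),
                      control = minpack.lm::nls.lm.control(maxiter = 500)),
    error = function(e) NULL)
  if (is.null(fit)) {
    return(new_geci_fit(tibble::tibble(term = "lambda_um",
                                       estimate = start$lambda),
                        r2 = NA_real_, converged = FALSE,
                        model = "neurite_decay", data = d))
  }
  lambda <- unname(coef(fit)["lambda"])
  params <- tibble::tibble(term = c("lambda_um", "d_e_inv_um"),
                           estimate = c(lambda, lambda))
  new_geci_fit(params, r2 = r_squared(d$y, fitted(fit)), converged = TRUE,
               model = "neurite_decay", data = d, extra = list(fit = fit))
}
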