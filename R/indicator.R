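#' Biophysical constants of a calcium indicator
#'
#' Bundles the constants describing one GECI state pair: the Ca2+ dissociation
#' constant `kd` (nM), the Hill cooperativity coefficient `hill_n`, the
#' Ca2+-free (`f_apo`) and Ca2+-saturated (`f_sat`) brightness in arbitrary
#' units, and optionally the pH midpoints of the apo/sat states and a
#' mono-exponential photobleaching time constant.
#'
#' The dynamic range is defined as `f_sat / f_apo` and is always computed from
#' the brightness pair, never stored independently.
#'
#' @param name Indicator name.
#' @param kd Dissociation constant, nM. Must be positive.
#' @param hill_n Hill coefficient (dimensionless, > 0).
#' @param f_apo Ca2+-free brightness, arbitrary units (> 0).
#' @param f_sat Ca2+-saturated brightness; must be >= `f_apo`.
#' @param pka_apo,pka_sat Optional pH titration midpoints of the two states.
#' @param bleach_tau Optional mono-exponential photobleach time constant, s.
#'
#' @return An object of class `indicator_params` (a named list) with an added
#'   `dynamic_range` field equal to `f_sat / f_apo`.
#'
#' @examples
#' p <- indicator_params("FRCaMPi", kd = 81, hill_n = 3.1, f_apo = 1, f_sat = 16.3)
#' p$dynamic_range
#' @export
indicator_params <- function(name = "indicator", kd, hill_n, f_apo = 1,
                             f_sat, pka_apo = NA_real_, pka_sat = NA_real_,
                             bleach_tau = NA_real_) {
  check_number(kd, "kd", lower = 0, strict_lower = TRUE)
  check_number(hill_n, "hill_n", lower = 0, strict_lower = TRUE)
  check_number(f_apo, "f_apo", lower = 0, strict_lower = TRUE)
  check_number(f_sat, "f_sat", lower = f_apo)
  check_number(pka_apo, "pka_apo", allow_na = TRUE)
  check_number(pka_sat, "pka_sat", allow_na = TRUE)
  check_number(bleach_tau, "bleach_tau", lower = 0, strict_lower = TRUE,
               allow_na = TRUE)
  structure(
    list(name = name, kd = kd, hill_n = hill_n, f_apo = f_apo, f_sat = f_sat,
         dynamic_range = f_sat / f_apo, pka_apo = pka_apo, pka_sat = pka_sat,
         bleach_tau = bleach_tau),
    class = "indicator_params"
  )
}

#' @export
print.indicator_params <- function(x, ...) {
  cat(sprintf("<indicator_params> %s\n", x$name))
  cat(sprintf("  Kd = %g nM, Hill n = %g, F_apo = %g, F_sat = %g (DR %.3g)\n",
              x$kd, x$hill_n, x$f_apo, x$f_sat, x$dynamic_range))
  if (!is.na(x$pka_sat)) cat(sprintf("  pKa(sat) = %g\n", x$pka_sat))
  invisible(x)
}

#' @rdname indicator_params
#' @details `frcampi_params()` returns the published constants of the
#'   inverted-topology FRCaMP sensor (Kd 81 nM, Hill coefficient 3.1,
#'   16.3-fold dynamic range, saturated-state pKa 6.48) with unit apo
#'   brightness, which is the reference parameter set used throughout the
#'   package's simulations.
#' @export
frcampi_params <- function() {
  indicator_params("FRCaMPi", kd = 81, hill_n = 3.1, f_apo = 1, f_sat = 16.3,
                   pka_apo = 8.98, pka_sat = 6.48)
}

#' Hill-equation fluorescence of an indicator at a free calcium level
#'
#' Equilibrium transduction of free `[Ca2+]` to fluorescence:
#' `F(ca) = f_apo + (f_sat - f_apo) * ca^n / (ca^n + kd^n)`.
#' The curve is monotonically non-decreasing in `ca`, equals `f_apo` at zero
#' calcium and `(f_apo + f_sat)/2` at `ca = kd`.
#'
#' @param ca_free Free calcium concentration(s), nM. Must be >= 0.
#' @param params An [indicator_params()] object.
#'
#' @return Numeric vector of fluorescence values (same units as `f_apo`).
#' @examples
#' hill_fluorescence(c(0, 81, 1e9), frcampi_params())
#' @export
hill_fluorescence <- function(ca_free, params) {
  stopifnot(inherits(params, "indicator_params"))
  if (any(!is.finite(ca_free)) || any(ca_free < 0)) {
    stop_geciq("`ca_free` must be finite and non-negative (nM).",
               "geciq_error_domain")
  }
  # work on log scale to avoid overflow at extreme concentrations
  r <- (ca_free / params$kd)^params$hill_n
  occ <- ifelse(is.infinite(r), 1, r / (1 + r))
  occ[ca_free == 0] <- 0
  params$f_apo + (params$f_sat - params$f_apo) * occ
}

#' Free calcium series of an EGTA-style calibration buffer mix
#'
#' Computes the free `[Ca2+]` obtained by reciprocal dilution of a
#' chelator-only buffer with a fully Ca-loaded chelator buffer. For a mixing
#' fraction `f = ca_total / chelator_total` of the loaded buffer, the free
#' calcium is `correction * kd_chelator_eff * f / (1 - f)`. The default
#' correction factor 1.084 is the calibration adjustment commonly applied to
#' this buffer series (anchored on the GCaMP6s reference Kd).
#'
#' @param ca_total Total calcium concentrations (mM), each in
#'   `[0, chelator_total)`.
#' @param chelator_total Total chelator concentration, mM (default 10).
#' @param kd_chelator_eff Effective Ca-chelator dissociation constant, nM.
#'   There is no universal default: its value depends on ionic strength, pH
#'   and temperature, so it must be supplied.
#' @param correction Dimensionless calibration correction factor
#'   (default 1.084).
#'
#' @return A tibble with columns `ca_total_mM`, `bound_fraction` and
#'   `ca_free_nM`. `ca_free_nM` is strictly increasing whenever `ca_total` is.
#' @examples
#' free_calcium_series(c(0, 2, 5, 9), kd_chelator_eff = 315)
#' @export
free_calcium_series <- function(ca_total, chelator_total = 10,
                                kd_chelator_eff, correction = 1.084) {
  check_number(chelator_total, "chelator_total", lower = 0, strict_lower = TRUE)
  check_number(kd_chelator_eff, "kd_chelator_eff", lower = 0, strict_lower = TRUE)
  check_number(correction, "correction", lower = 0, strict_lower = TRUE)
  if (any(ca_total < 0)) {
    stop_geciq("`ca_total` must be non-negative.", "geciq_error_domain")
  }
  if (any(ca_total >= chelator_total)) {
    stop_geciq(
      "`ca_total` must be strictly below `chelator_total`: a saturated buffer has no defined free [Ca2+].",
      "geciq_error_domain")
  }
  f <- ca_total / chelator_total
  tibble::tibble(
    ca_total_mM = as.numeric(ca_total),
    bound_fraction = f,
    ca_free_nM = correction * kd_chelator_eff * f / (1 - f)
  )
}
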