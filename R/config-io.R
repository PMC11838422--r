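# Plain-text interfaces: titration CSV, fit-report JSON, YAML experiment
# config.

#' Read a titration curve from CSV
#'
#' Expects columns `x`, `y` and optionally `x_kind` (`"calcium"` for free
#' `[Ca2+]` in nM or `"ph"`).
#'
#' @param path CSV path.
#' @return A tibble with `x`, `y` and an `x_kind` attribute.
#' @export
read_titration_csv <- function(path) {
  d <- utils::read.csv(path)
  if (!all(c("x", "y") %in% names(d))) {
    stop_geciq("titration CSV needs columns `x` and `y`.", "geciq_error_input")
  }
  out <- tibble::tibble(x = as.numeric(d$x), y = as.numeric(d$y))
  attr(out, "x_kind") <- if ("x_kind" %in% names(d)) d$x_kind[1] else NA
  out
}

#' Write a fit report as JSON
#'
#' Serializes a `geci_fit` as `{params: {...}, r2, converged, model}`.
#'
#' @param fit A `geci_fit`.
#' @param path Output JSON path.
#' @return `path`, invisibly.
#' @export
write_fit_json <- function(fit, path) {
  stopifnot(inherits(fit, "geci_fit"))
  jsonlite::write_json(
    list(params = as.list(setNames(fit$params$estimate, fit$params$term)),
         r2 = fit$r2, converged = fit$converged, model = fit$model),
    path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' Read an experiment configuration from a YAML file
#'
#' The file holds overrides of [contamination_config()] entries (plus an
#' optional `seed` and an optional `indicator` block with `name`, `kd`,
#' `hill_n`, `f_apo`, `f_sat`). A packaged example lives at
#' `system.file("extdata", "contamination_default.yml", package = "geciq")`.
#'
#' @param path YAML path.
#' @return A config list as produced by [contamination_config()], with a
#'   `seed` entry when the file provides one.
#' @export
read_config_yaml <- function(path) {
  raw <- yaml::read_yaml(path)
  seed <- raw$seed
  raw$seed <- NULL
  if (!is.null(raw$indicator)) {
    raw$indicator <- do.call(indicator_params, raw$indicator)
  }
  if (!is.null(raw$fov_um)) raw$fov_um <- as.numeric(raw$fov_um)
  if (!is.null(raw$soma_radius_range)) {
    raw$soma_radius_range <- as.numeric(raw$soma_radius_range)
  }
  if (!is.null(raw$bin_edges_um)) raw$bin_edges_um <- as.numeric(raw$bin_edges_um)
  cfg <- do.call(contamination_config, raw)
  cfg$seed <- seed
  cfg
}
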