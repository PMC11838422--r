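test_that("Hill fit recovers generating parameters from a noiseless curve", {
  fit <- fit_hill_titration(make_titration_curve())
  est <- setNames(tidy(fit)$estimate, tidy(fit)$term)
  expect_true(fit$converged)
  expect_equal(unname(est["kd"]), 81, tolerance = 1e-3)
  expect_equal(unname(est["hill_n"]), 3.1, tolerance = 1e-3)
  expect_equal(unname(est["f_apo"]), 1, tolerance = 1e-3)
  expect_equal(unname(est["f_sat"]), 16.3, tolerance = 1e-3)
  expect_equal(unname(est["dynamic_range"]),
               unname(est["f_sat"] / est["f_apo"]), tolerance = 1e-9)
  expect_gt(fit$r2, 0.9999)
})

test_that("Hill fit round-trips random generating parameters", {
  for (s in 1:10) {
    withr::with_seed(s, {
      p <- indicator_params("r", kd = runif(1, 30, 500),
                            hill_n = runif(1, 1, 3.5), f_apo = 1,
                            f_sat = runif(1, 5, 25))
    })
    fit <- fit_hill_titration(make_titration_curve(p))
    est <- setNames(tidy(fit)$estimate, tidy(fit)$term)
    expect_equal(unname(est["kd"]), p$kd, tolerance = 1e-3)
    expect_equal(unname(est["hill_n"]), p$hill_n, tolerance = 1e-3)
  }
})

test_that("flat titration curves are rejected as non-identifiable", {
  flat <- tibble::tibble(x = titration_grid, y = rep(5, 16))
  expect_error(fit_hill_titration(flat),
               class = "geciq_error_nonidentifiable")
  expect_error(fit_ph_titration(tibble::tibble(x = 4:9, y = rep(2, 6))),
               class = "geciq_error_nonidentifiable")
})

test_that("Hill Kd is robust to 1% multiplicative noise", {
  errs <- vapply(1:30, function(s) {
    fit <- fit_hill_titration(make_titration_curve(noise_cv = 0.01, seed = s))
    kd <- tidy(fit)$estimate[tidy(fit)$term == "kd"]
    abs(kd - 81) / 81
  }, numeric(1))
  expect_lt(median(errs), 0.05)
})

test_that("pH titration recovers the generating pKa", {
  ph <- seq(4, 9, by = 0.25)
  curve <- tibble::tibble(x = ph, y = 1 + 15.3 / (1 + 10^(0.9 * (6.48 - ph))))
  fit <- fit_ph_titration(curve)
  est <- setNames(tidy(fit)$estimate, tidy(fit)$term)
  expect_equal(unname(est["pka"]), 6.48, tolerance = 1e-3)
  # the value at pH = pKa is the midpoint of the fitted asymptotes
  mid <- (est["f_acid"] + est["f_base"]) / 2
  pred <- est["f_acid"] + (est["f_base"] - est["f_acid"]) / 2
  expect_equal(unname(pred), unname(mid))
  # decreasing orientation works too
  fit2 <- fit_ph_titration(tibble::tibble(x = ph, y = rev(curve$y)))
  expect_true(fit2$converged)
})

test_that("pH fit tolerates 2% noise", {
  ph <- seq(4, 9, by = 0.25)
  errs <- vapply(1:30, function(s) {
    y <- withr::with_seed(s, (1 + 15.3 / (1 + 10^(6.48 - ph))) *
                            (1 + rnorm(length(ph), 0, 0.02)))
    fit <- fit_ph_titration(tibble::tibble(x = ph, y = y))
    abs(tidy(fit)$estimate[tidy(fit)$term == "pka"] - 6.48)
  }, numeric(1))
  expect_lt(median(errs), 0.05)
})

test_that("photobleach fit recovers tau and reports the half-life identity", {
  t <- seq(0, 600, by = 2)
  tr <- tibble::tibble(time_s = t, value = 5 * exp(-t / 120) + 0.3)
  fit <- fit_photobleach(tr)
  est <- setNames(tidy(fit)$estimate, tidy(fit)$term)
  expect_equal(unname(est["bleach_tau"]), 120, tolerance = 1e-4)
  expect_equal(unname(est["half_life"]), unname(est["bleach_tau"]) * log(2))
  # bi-exponential model resolves two well-separated components
  tr2 <- tibble::tibble(time_s = t,
                        value = 4 * exp(-t / 30) + 2 * exp(-t / 300) + 0.2)
  fit2 <- fit_photobleach(tr2, model = "bi")
  expect_true(fit2$converged)
  taus <- sort(tidy(fit2)$estimate[tidy(fit2)$term %in% c("tau_1", "tau_2")])
  expect_equal(taus, c(30, 300), tolerance = 0.01)
})

test_that("non-decaying photobleach traces fail gracefully", {
  tr <- tibble::tibble(time_s = 0:20, value = rep(3, 21))
  expect_warning(fit <- fit_photobleach(tr), "does not decay")
  expect_false(fit$converged)
})

test_that("neurite decay fits recover the length constant", {
  d <- seq(0, 250, by = 5)
  fit <- fit_neurite_decay(tibble::tibble(arclength_um = d,
                                          intensity = exp(-d / 50)))
  est <- setNames(tidy(fit)$estimate, tidy(fit)$term)
  expect_equal(unname(est["lambda_um"]), 50, tolerance = 1e-6)
  # d_e_inv is the e^-1 distance and equals lambda by definition
  expect_equal(unname(est["d_e_inv_um"]), unname(est["lambda_um"]))
  expect_equal(exp(-est[["d_e_inv_um"]] / est[["lambda_um"]]), exp(-1))
  # non-decaying profile is flagged, not fitted
  expect_warning(
    flat <- fit_neurite_decay(tibble::tibble(arclength_um = d,
                                             intensity = rep(1, length(d)))),
    "does not decay")
  expect_false(flat$converged)
})

test_that("tidy and glance expose fit results in broom shape", {
  fit <- fit_hill_titration(make_titration_curve())
  td <- tidy(fit)
  expect_s3_class(td, "tbl_df")
  expect_named(td, c("term", "estimate"))
  gl <- glance(fit)
  expect_equal(nrow(gl), 1)
  expect_true(all(c("r2", "converged", "nobs") %in% names(gl)))
  expect_equal(gl$nobs, 16)
})
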