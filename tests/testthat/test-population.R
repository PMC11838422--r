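long_traces <- function(M) {
  M <- unname(as.matrix(M))
  purrr::map_dfr(seq_len(ncol(M)), function(j) {
    tibble::tibble(roi = j, frame = seq_len(nrow(M)), value = M[, j])
  })
}

test_that("pairwise correlation handles exact and null cases", {
  v <- withr::with_seed(1, rnorm(100))
  cents <- tibble::tibble(roi = 1:2, x_um = c(0, 30), y_um = c(0, 40))
  same <- long_traces(cbind(v, v))
  p <- pairwise_correlation(same, cents)
  expect_equal(p$pcc, 1)
  expect_equal(p$distance_um, 50)
  neg <- long_traces(cbind(v, -v))
  expect_equal(pairwise_correlation(neg, cents)$pcc, -1)
  # independent noise: mean PCC near zero across seeds
  means <- vapply(1:50, function(s) {
    M <- withr::with_seed(s, matrix(rnorm(1000 * 2), 1000, 2))
    pairwise_correlation(long_traces(M), cents)$pcc
  }, numeric(1))
  se <- sd(means) / sqrt(length(means))
  expect_lt(abs(mean(means)), 3 * se)
})

test_that("zero-variance ROIs are skipped with a warning", {
  M <- cbind(withr::with_seed(2, rnorm(50)), rep(1, 50),
             withr::with_seed(3, rnorm(50)))
  cents <- tibble::tibble(roi = 1:3, x_um = c(0, 10, 20), y_um = 0)
  expect_warning(p <- pairwise_correlation(long_traces(M), cents),
                 "zero-variance")
  expect_equal(nrow(p), 1)
  expect_setequal(c(p$id_i, p$id_j), c(1L, 3L))
})

test_that("distance bins are half-open with dropped-pair accounting", {
  pairs <- tibble::tibble(id_i = 1:4, id_j = 5:8,
                          distance_um = c(50, 200, 399, 850),
                          pcc = c(0.8, 0.4, 0.2, 0.1), corrected = FALSE)
  prof <- bin_correlation(pairs)
  expect_equal(prof$n_pairs, c(1L, 2L, 0L))
  # the pair at exactly 200 um falls in the [200, 400) bin
  expect_equal(prof$mean_pcc[2], mean(c(0.4, 0.2)))
  expect_equal(attr(prof, "n_dropped"), 1L)
  # all pairs in one bin: bin mean equals overall mean
  one <- tibble::tibble(id_i = 1:3, id_j = 4:6, distance_um = c(10, 50, 90),
                        pcc = c(0.3, 0.5, 0.7), corrected = FALSE)
  expect_equal(bin_correlation(one)$mean_pcc[1], 0.5)
  expect_error(bin_correlation(pairs, bin_edges = c(0, 400, 200)),
               class = "geciq_error_input")
})

test_that("responsive fractions and per-FOV means are exact arithmetic", {
  expect_equal(fraction_responsive(rep(TRUE, 5)), 1)
  expect_equal(fraction_responsive(rep(FALSE, 4)), 0)
  expect_equal(fraction_responsive(c(rep(TRUE, 29), rep(FALSE, 71))), 0.29)
  expect_error(fraction_responsive(logical()), class = "geciq_error_input")
  expect_equal(per_fov_mean(930, 16), 58.125)
  expect_equal(per_fov_mean(438, 20), 21.9)
  expect_equal(per_fov_mean(0, 5), 0)
  expect_error(per_fov_mean(10, 0), class = "geciq_error_domain")
})

pipeline_cfg <- function() {
  contamination_config(n_neurons = 6, fov_um = c(64, 64), n_frames = 120,
                       photons_per_unit = 200)
}

test_that("the pipeline completes with all report sections present", {
  out <- withr::local_tempdir()
  rep <- run_pipeline(pipeline_cfg(), seed = 3, out_dir = out)
  expect_s3_class(rep, "geci_report")
  expect_equal(rep$n_rois, 6)
  expect_equal(rep$fraction_responsive, rep$n_responsive / rep$n_rois)
  expect_true(all(c("metrics", "pairs_raw", "pairs_corrected",
                    "profile_raw", "profile_corrected") %in% names(rep)))
  expect_equal(nrow(rep$pairs_raw), choose(6, 2))
  expect_true(file.exists(file.path(out, "report.json")))
  expect_true(file.exists(file.path(out, "metrics.csv")))
})

test_that("the pipeline is deterministic and validates its config", {
  r1 <- run_pipeline(pipeline_cfg(), seed = 5)
  r2 <- run_pipeline(pipeline_cfg(), seed = 5)
  expect_identical(serialize(r1, NULL), serialize(r2, NULL))
  err <- tryCatch(run_pipeline(pipeline_cfg()), error = identity)
  expect_s3_class(err, "geciq_error_config")
  expect_match(conditionMessage(err), "seed")
  expect_error(contamination_config(not_a_field = 1),
               class = "geciq_error_config")
})

test_that("packaged config and titration files load through the text interfaces", {
  cfg_path <- system.file("extdata", "contamination_default.yml",
                          package = "geciq")
  cfg <- read_config_yaml(cfg_path)
  expect_equal(cfg$seed, 1)
  expect_equal(cfg$n_neurons, 30)
  expect_equal(cfg$indicator$kd, 81)
  expect_equal(cfg$bin_edges_um, c(0, 200, 400, 800))
  tit_path <- system.file("extdata", "titration_frcampi_synthetic.csv",
                          package = "geciq")
  curve <- read_titration_csv(tit_path)
  expect_equal(attr(curve, "x_kind"), "calcium")
  fit <- fit_hill_titration(curve)
  kd <- tidy(fit)$estimate[tidy(fit)$term == "kd"]
  expect_equal(kd, 81, tolerance = 0.02)
  jf <- tempfile(fileext = ".json")
  write_fit_json(fit, jf)
  back <- jsonlite::read_json(jf)
  expect_true(back$converged)
  expect_equal(back$params$kd, kd, tolerance = 1e-8)
})

test_that("near-pair correlation grows with the shared neuropil weight", {
  m <- vapply(c(0, 0.5, 1.5), function(w) {
    mean(vapply(1:3, function(s) {
      ex <- run_contamination_experiment(
        contamination_config(n_neurons = 6, fov_um = c(64, 64),
                             n_frames = 120, neuropil_weight = w,
                             n_neurites = 0), seed = s)
      ex$non_targeted$near_pcc_raw
    }, numeric(1)))
  }, numeric(1))
  expect_true(all(diff(m) > 0))
})
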