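small_scene <- function(targeting = "non_targeted", seed = 7, n = 4,
                        fov = c(64, 64), ...) {
  build_scene(n, fov_um = fov, soma_radius_range = c(3, 4),
              neurite_length_um = 80, targeting = targeting, seed = seed, ...)
}

test_that("empty scenes and packing failures behave as specified", {
  empty <- build_scene(0, fov_um = c(32, 32))
  expect_equal(nrow(empty$neurons), 0)
  expect_true(all(empty$masks == 0))
  expect_error(build_scene(40, fov_um = c(20, 20),
                           soma_radius_range = c(5, 6), seed = 1),
               class = "geciq_error_packing")
})

test_that("neurite expression decays with the configured length constant", {
  # soma-targeted default length constant is 5x shorter than non-targeted
  nt <- small_scene("non_targeted")
  st <- small_scene("soma_targeted")
  expect_equal(unique(nt$neurons$lambda_um) / unique(st$neurons$lambda_um), 5)
  # total neurite expression mass: with unclipped neurites the targeted
  # scene carries about a fifth of the non-targeted neurite fluorescence
  big_nt <- build_scene(4, fov_um = c(512, 512), neurite_length_um = 300,
                        targeting = "non_targeted", seed = 11)
  big_st <- build_scene(4, fov_um = c(512, 512), neurite_length_um = 300,
                        targeting = "soma_targeted", seed = 11)
  expect_lt(sum(big_st$neurite_w) / sum(big_nt$neurite_w), 0.25)
  # per-pixel neurite weight never exceeds the soma-edge weight and follows
  # exp(-d/lambda): the maximum possible weight one step out is exp(-1/lambda)
  expect_lte(max(nt$neurite_w), exp(-1 / unique(nt$neurons$lambda_um)))
})

test_that("scenes are deterministic given their seed", {
  a <- small_scene(seed = 9)
  b <- small_scene(seed = 9)
  expect_identical(a$neurons, b$neurons)
  expect_identical(a$masks, b$masks)
  expect_identical(a$neurite_w, b$neurite_w)
  d1 <- tempfile(); d2 <- tempfile()
  write_scene_truth(a, d1); write_scene_truth(b, d2)
  expect_identical(readLines(paste0(d1, "_truth.json")),
                   readLines(paste0(d2, "_truth.json")))
})

test_that("a clean render reproduces a single neuron's trace exactly", {
  sc <- build_scene(1, fov_um = c(32, 32), soma_radius_range = c(3, 4),
                    n_neurites = 0, seed = 3)
  S <- matrix(withr::with_seed(1, runif(40, 1, 3)), ncol = 1)
  mv <- render_movie(sc, S, oof_weight = 0, photons_per_unit = Inf,
                     background_offset = 0.5)
  tr <- extract_traces(mv, sc$masks)
  # mean over the truth mask is affine in the input with correlation 1
  expect_equal(cor(tr$value, S[, 1]), 1)
  fit <- lm(tr$value ~ S[, 1])
  expect_equal(unname(coef(fit)[2]), 1, tolerance = 1e-8)
})

test_that("all-zero traces render a constant-offset movie", {
  sc <- small_scene()
  S <- matrix(0, 30, 4)
  mv <- render_movie(sc, S, photons_per_unit = Inf, background_offset = 2)
  expect_true(all(abs(unclass(mv) - 2) < 1e-12))
  expect_error(render_movie(sc, S[, 1:3]), class = "geciq_error_input")
})

test_that("wide-field optics induce artifactual correlation", {
  diffs <- vapply(1:10, function(s) {
    sc <- build_scene(2, fov_um = c(48, 48), soma_radius_range = c(3, 4),
                      neurite_length_um = 60, seed = s)
    S <- withr::with_seed(1000 + s,
                          matrix(runif(2 * 120, 1, 3), 120, 2))
    pcc_at <- function(oof) {
      mv <- render_movie(sc, S, oof_weight = oof, background_sigma = 16,
                         photons_per_unit = Inf)
      tr <- extract_traces(mv, sc$masks)
      cor(tr$value[tr$roi == 1], tr$value[tr$roi == 2])
    }
    pcc_at(8) - pcc_at(0)
  }, numeric(1))
  expect_gt(mean(diffs), 0)
  expect_true(all(diffs > -0.05))
})

test_that("soma-targeting raises the soma-to-neuropil ratio of renders", {
  ratios <- vapply(1:10, function(s) {
    S <- withr::with_seed(s, matrix(runif(4 * 30, 1, 3), 30, 4))
    one <- function(targ) {
      sc <- small_scene(targ, seed = 100 + s)
      mv <- render_movie(sc, S, photons_per_unit = Inf, background_offset = 0)
      img <- apply(unclass(mv), 1:2, mean)
      soma_neuropil_ratio(img, sc$masks, sc$masks == 0)
    }
    one("soma_targeted") / one("non_targeted")
  }, numeric(1))
  expect_true(all(ratios > 1))
})

test_that("rendering is deterministic for a fixed seed", {
  sc <- small_scene()
  S <- matrix(withr::with_seed(2, runif(4 * 20, 1, 2)), 20, 4)
  m1 <- render_movie(sc, S, photons_per_unit = 100, seed = 5)
  m2 <- render_movie(sc, S, photons_per_unit = 100, seed = 5)
  expect_identical(unclass(m1), unclass(m2))
})

test_that("movies and truth round-trip through disk", {
  mv <- array(sample(0:4000, 32 * 32 * 4, replace = TRUE), dim = c(32, 32, 4))
  attr(mv, "frame_rate") <- 10
  tf <- tempfile(fileext = ".tif")
  write_movie(mv, tf)
  back <- read_movie(tf)
  expect_equal(unclass(back)[, , ], mv[, , ] * 1.0, ignore_attr = TRUE)
  expect_equal(attr(back, "frame_rate"), 10)
  # float frames round-trip within encoding tolerance
  mf <- array(withr::with_seed(4, rnorm(32 * 32 * 3)), dim = c(32, 32, 3))
  tf2 <- tempfile(fileext = ".tif")
  write_movie(mf, tf2, format = "float32")
  expect_lt(max(abs(unclass(read_movie(tf2)) - mf)), 1e-6)
  # truth sidecar preserves neuron count and labels
  sc <- small_scene()
  stem <- tempfile()
  write_scene_truth(sc, stem)
  tru <- read_scene_truth(stem)
  expect_equal(nrow(tru$neurons), nrow(sc$neurons))
  expect_identical(tru$masks, sc$masks)
  # a text file is not a TIFF
  txt <- tempfile(fileext = ".tif")
  writeLines("not a tiff", txt)
  expect_error(read_movie(txt), class = "geciq_error_parse")
})
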