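test_that("trace extraction equals a brute-force pixel loop", {
  mv <- array(withr::with_seed(1, runif(16 * 16 * 10)), dim = c(16, 16, 10))
  masks <- matrix(0L, 16, 16)
  masks[3:6, 3:6] <- 1L
  masks[10:13, 9:12] <- 2L
  got <- extract_traces(mv, masks)
  for (l in 1:2) {
    idx <- which(masks == l, arr.ind = TRUE)
    oracle <- vapply(1:10, function(f) {
      mean(vapply(seq_len(nrow(idx)),
                  function(i) mv[idx[i, 1], idx[i, 2], f], numeric(1)))
    }, numeric(1))
    expect_equal(got$value[got$roi == l], oracle)
  }
  # uniform frame and tiny arithmetic case
  mv2 <- array(5, dim = c(4, 4, 3))
  m2 <- matrix(0L, 4, 4); m2[1, 1] <- 1L; m2[2, 2] <- 1L
  mv2[1, 1, ] <- 1; mv2[2, 2, ] <- 3
  expect_equal(extract_trace(mv2, m2, 1)$value, rep(2, 3))
  expect_error(extract_traces(mv2, m2, labels = 9),
               class = "geciq_error_input")
})

test_that("annulus neuropil excludes other ROIs and respects its radii", {
  mv <- array(2, dim = c(40, 40, 5))
  masks <- matrix(0L, 40, 40)
  masks[18:22, 18:22] <- 1L
  expect_equal(neuropil_annulus_trace(mv, masks, 1)$value, rep(2, 5))
  # fill a second ROI inside the annulus with a huge value: excluding it
  # keeps the median at background level
  masks2 <- masks
  masks2[18:22, 26:30] <- 2L
  mv2 <- mv
  for (f in 1:5) mv2[18:22, 26:30, f] <- 99
  expect_equal(neuropil_annulus_trace(mv2, masks2, 1)$value, rep(2, 5))
  # without labeling it as an ROI the bright block shifts annulus pixels
  mv3 <- mv
  for (f in 1:5) mv3[18:22, 24:34, f] <- 99
  expect_gt(mean(neuropil_annulus_trace(mv3, masks, 1, statistic = "mean")$value), 2)
  expect_error(neuropil_annulus_trace(mv, masks, 1, inner = 15, outer = 5),
               class = "geciq_error_domain")
})

test_that("neuropil subtraction is exact and linear", {
  expect_equal(neuropil_correct(1, 1, r = 0.7), 0.3)
  expect_equal(neuropil_correct(c(2, 4), c(1, 2), r = 0.7), c(1.3, 2.6))
  f <- c(5, 6, 7); fn <- c(1, 2, 3)
  expect_equal(neuropil_correct(f, fn, r = 0), f)
  expect_equal(neuropil_correct(3 * f, 3 * fn), 3 * neuropil_correct(f, fn))
  expect_error(neuropil_correct(1:3, 1:2), class = "geciq_error_input")
})

test_that("mask IOU counts pixels correctly and is symmetric", {
  a <- matrix(FALSE, 8, 8); a[2:3, 2:3] <- TRUE
  expect_equal(mask_iou(a, a), 1)
  b <- matrix(FALSE, 8, 8); b[6:7, 6:7] <- TRUE
  expect_equal(mask_iou(a, b), 0)
  shifted <- matrix(FALSE, 8, 8); shifted[2:3, 3:4] <- TRUE
  expect_equal(mask_iou(a, shifted), 2 / 6)
  expect_equal(mask_iou(shifted, a), mask_iou(a, shifted))
})

test_that("greedy matching equals the brute-force highest-IOU-first oracle", {
  for (s in 1:60) {
    na <- withr::with_seed(s, sample(1:6, 1))
    nb <- withr::with_seed(s + 500, sample(1:6, 1))
    A <- make_random_masks(na, seed = s)
    B <- make_random_masks(nb, seed = s + 500)
    got <- match_rois(A, B, threshold = 0.2)$pairs
    oracle <- brute_force_match(A, B, threshold = 0.2)
    expect_equal(nrow(got), nrow(oracle))
    if (nrow(got) > 0) {
      expect_equal(got$id_a, oracle$id_a)
      expect_equal(got$id_b, oracle$id_b)
      expect_equal(got$iou, oracle$iou)
    }
  }
})

test_that("matching respects the 0.5 threshold boundary", {
  # identical sets match with IOU 1
  A <- make_random_masks(3, seed = 1)
  m <- match_rois(A, A)
  expect_equal(nrow(m$pairs), 3)
  expect_true(all(m$pairs$iou == 1))
  expect_length(m$unmatched_a, 0)
  # 10x10 square vs 10x7 overlap: IOU = 70/130 ~ 0.538 matches;
  # 10x5 overlap: IOU = 50/150 ~ 0.333 does not
  base <- matrix(0L, 24, 24); base[3:12, 3:12] <- 1L
  close_ <- matrix(0L, 24, 24); close_[3:12, 6:15] <- 1L
  far <- matrix(0L, 24, 24); far[3:12, 8:17] <- 1L
  expect_equal(nrow(match_rois(base, close_)$pairs), 1)
  expect_equal(nrow(match_rois(base, far)$pairs), 0)
  # just below / at threshold behaves per the >= rule
  expect_equal(nrow(match_rois(base, close_, threshold = 0.54)$pairs), 0)
  expect_equal(nrow(match_rois(base, close_,
                               threshold = 70 / 130)$pairs), 1)
})

test_that("optimal matching can beat greedy and ties break deterministically", {
  # construct: greedy takes (1,1) IOU .6, leaving (2,?) unmatched;
  # optimal takes (1,2) .5 + (2,1) .5 for total 1.0
  edges_demo <- local({
    A <- matrix(0L, 30, 30)
    B <- matrix(0L, 30, 30)
    A[1:10, 1:6] <- 1L    # a1
    A[20:29, 1:6] <- 2L   # a2
    B[1:10, 3:8] <- 1L
    B[15:29, 1:6] <- 2L
    list(A = A, B = B)
  })
  g <- match_rois(edges_demo$A, edges_demo$B, threshold = 0.3)
  o <- match_rois(edges_demo$A, edges_demo$B, threshold = 0.3,
                  method = "optimal")
  expect_gte(sum(o$pairs$iou), sum(g$pairs$iou))
  # input-order invariance / deterministic tie-break: two identical-IOU
  # candidates resolve to the lower ids
  A <- matrix(0L, 20, 20); A[2:5, 2:5] <- 1L; A[10:13, 10:13] <- 2L
  B <- matrix(0L, 20, 20); B[2:5, 2:5] <- 1L; B[10:13, 10:13] <- 2L
  m <- match_rois(A, B)
  expect_equal(m$pairs$id_a, c(1L, 2L))
  expect_equal(m$pairs$id_b, c(1L, 2L))
})

test_that("labeling density counts covered reference ROIs", {
  centers <- cbind(seq(10, 90, length.out = 10), rep(seq(15, 85, 5), 2)[1:10])
  ref <- make_disk_masks(centers, radius = 4, dim_px = 100)
  expect_equal(labeling_density(ref, ref), 1)
  empty <- matrix(0L, 100, 100)
  expect_equal(labeling_density(empty, ref), 0)
  # 8 of 10 reference cells covered
  partial <- make_disk_masks(centers[1:8, , drop = FALSE], radius = 4,
                             dim_px = 100)
  expect_equal(labeling_density(partial, ref), 0.8)
  expect_error(labeling_density(ref, empty), class = "geciq_error_input")
})

test_that("soma-to-neuropil ratio is a simple mean ratio", {
  img <- matrix(2, 20, 20)
  soma <- matrix(0L, 20, 20); soma[5:8, 5:8] <- 1L
  neu <- matrix(0L, 20, 20); neu[15:18, 15:18] <- 1L
  expect_equal(soma_neuropil_ratio(img, soma, neu), 1)
  img[5:8, 5:8] <- 4
  expect_equal(soma_neuropil_ratio(img, soma, neu), 2)
  img0 <- img; img0[15:18, 15:18] <- 0
  expect_warning(r <- soma_neuropil_ratio(img0, soma, neu), "zero neuropil")
  expect_identical(r, Inf)
})

test_that("the threshold segmenter finds bright disks deterministically", {
  img <- matrix(0.1, 64, 64)
  disks <- make_disk_masks(cbind(c(16, 48), c(16, 48)), radius = 5,
                           dim_px = 64)
  img[disks > 0] <- 1
  seg <- simple_segment(img, smoothing_sigma = 1, min_area = 10)
  expect_equal(nrow(seg$rois), 2)
  m <- match_rois(seg$masks, disks, threshold = 0.5)
  expect_equal(nrow(m$pairs), 2)
  # blank image: empty list, not an error
  expect_equal(nrow(simple_segment(matrix(0, 32, 32))$rois), 0)
  # a disk smaller than min_area is filtered out
  small <- matrix(0.1, 64, 64)
  small[30:31, 30:31] <- 1
  expect_equal(nrow(simple_segment(small, smoothing_sigma = 0,
                                   min_area = 10)$rois), 0)
})

test_that("the segmenter recovers nearly all somas on synthetic scenes", {
  hits <- vapply(1:5, function(s) {
    sc <- build_scene(8, fov_um = c(96, 96), soma_radius_range = c(4, 5),
                      targeting = "soma_targeted", neurite_length_um = 40,
                      modality = "two_photon", min_gap_um = 5, seed = s)
    S <- withr::with_seed(s, matrix(runif(8 * 20, 2, 4), 20, 8))
    mv <- render_movie(sc, S, photons_per_unit = 500,
                       background_offset = 0.2)
    img <- apply(unclass(mv), 1:2, mean)
    seg <- simple_segment(img, smoothing_sigma = 1.5, min_area = 15)
    m <- match_rois(seg$masks, sc$masks, threshold = 0.3)
    nrow(m$pairs) / 8
  }, numeric(1))
  expect_gte(mean(hits), 0.9)
})
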