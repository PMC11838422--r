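# Shared fixture builders. Everything is generated in code; no stored data.

# The standard 16-point free-calcium measurement grid (nM) used for
# titration fixtures, spanning both sides of the FRCaMPi inflection.
titration_grid <- c(2.1, 7.9, 16.3, 35.4, 79.2, 135.5, 208.4, 312.6, 468.9,
                    731.5, 1254.6, 2817.6, 5856.0, 11858.0, 21923.7, 81276)

make_titration_curve <- function(params = frcampi_params(),
                                 x = titration_grid, noise_cv = 0,
                                 seed = NULL) {
  y <- hill_fluorescence(x, params)
  if (noise_cv > 0) {
    y <- withr::with_seed(seed, y * (1 + rnorm(length(y), 0, noise_cv)))
  }
  tibble::tibble(x = x, y = y)
}

# Single exponential-decay transient epoch: rise over `rise_s`, then decay
# with time constant `tau_s`, sampled at `frame_rate`.
make_transient_epoch <- function(peak = 1, rise_s = 0.5, tau_s = 0.5,
                                 duration_s = 5, frame_rate = 20,
                                 noise_sd = 0, seed = NULL) {
  t <- seq(0, duration_s, by = 1 / frame_rate)
  v <- ifelse(t < rise_s, peak * t / rise_s, peak * exp(-(t - rise_s) / tau_s))
  if (noise_sd > 0) {
    v <- withr::with_seed(seed, v + rnorm(length(v), 0, noise_sd))
  }
  tibble::tibble(time_s = t, dff = v)
}

# Random label image with up to `max_rois` square-ish ROIs for matching tests.
make_random_masks <- function(n_rois, dim_px = 32, size_range = c(3, 6),
                              seed = 1) {
  withr::with_seed(seed, {
    masks <- matrix(0L, dim_px, dim_px)
    for (i in seq_len(n_rois)) {
      s <- sample(size_range[1]:size_range[2], 1)
      r <- sample(1:(dim_px - s), 1)
      cc <- sample(1:(dim_px - s), 1)
      masks[r:(r + s - 1), cc:(cc + s - 1)] <- i
    }
    masks
  })
}

# Brute-force repeated-scan matcher: independently re-implements the
# highest-IOU-first pairing rule by rescanning the full pair list each step.
brute_force_match <- function(masks_a, masks_b, threshold = 0.5) {
  labs_a <- sort(setdiff(unique(as.integer(masks_a)), 0L))
  labs_b <- sort(setdiff(unique(as.integer(masks_b)), 0L))
  pairs <- data.frame(id_a = integer(), id_b = integer(), iou = numeric())
  repeat {
    best <- NULL
    for (a in setdiff(labs_a, pairs$id_a)) {
      for (b in setdiff(labs_b, pairs$id_b)) {
        v <- mask_iou(masks_a == a, masks_b == b)
        if (v >= threshold &&
            (is.null(best) || v > best$iou ||
             (v == best$iou && (a < best$id_a ||
                                (a == best$id_a && b < best$id_b))))) {
          best <- list(id_a = a, id_b = b, iou = v)
        }
      }
    }
    if (is.null(best)) break
    pairs <- rbind(pairs, as.data.frame(best))
  }
  pairs[order(pairs$id_a), ]
}

# Disk label image helper for density / segmentation fixtures.
make_disk_masks <- function(centers, radius, dim_px) {
  masks <- matrix(0L, dim_px, dim_px)
  for (i in seq_len(nrow(centers))) {
    for (r in seq_len(dim_px)) for (cc in seq_len(dim_px)) {
      if ((r - centers[i, 1])^2 + (cc - centers[i, 2])^2 <= radius^2) {
        masks[r, cc] <- i
      }
    }
  }
  masks
}
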