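# Spatial ground-truth scenes and movie rendering.
#
# A scene holds neuron geometry (somas + random-walk neurites), per-neuron
# expression weight maps, and the soma label image. Expression along a
# neurite decays as exp(-d/lambda) with d the arclength from the soma edge;
# soma-targeted sensors use a length constant 5x shorter than non-targeted
# ones, which is what confines their fluorescence to cell bodies.

#' Build a synthetic imaging scene with ground truth
#'
#' Samples non-overlapping somas in the field of view (minimum center
#' distance = sum of radii), grows random-walk neurite polylines from each
#' soma, and rasterizes per-neuron expression weight maps. The pixel weight
#' at arclength `d` from the soma edge is `exp(-d / lambda_expr)`, so at one
#' length constant the expression has dropped to `exp(-1)` (36.8%) of the
#' soma-edge value.
#'
#' Pixel conventions: 0-based pixel indices with pixel (0,0) at the top-left;
#' micron positions map to pixels via `pixel_size`; masks are sets of whole
#' pixels.
#'
#' @param n_neurons Number of neurons (>= 0).
#' @param fov_um Field of view `c(width, height)` in microns; must divide by
#'   `pixel_size` into integer image dimensions.
#' @param pixel_size Microns per pixel (default 1).
#' @param soma_radius_range Range of soma radii, microns.
#' @param n_neurites Neurites per neuron.
#' @param neurite_length_um Neurite arclength, microns.
#' @param targeting `"non_targeted"` or `"soma_targeted"`.
#' @param lambda_expr Expression length constant along neurites, microns.
#'   Default 100 for non-targeted; soma-targeted scenes default to 1/5 of
#'   that (20), the targeted-to-non-targeted ratio observed for ribo-tagged
#'   sensors.
#' @param modality `"widefield"` or `"two_photon"`; selects the rendering
#'   preset (out-of-focus mixing weight and blur).
#' @param neuropil_weight Mixing weight of an optional shared neuropil trace
#'   into non-soma pixels at render time (default 0).
#' @param brightness Per-neuron brightness scale (scalar or length
#'   `n_neurons`).
#' @param min_gap_um Extra clearance added to the sum-of-radii packing
#'   distance (default 0).
#' @param seed Integer seed; the whole scene is deterministic given the seed.
#' @param max_tries Soma packing retries per neuron before giving up.
#' @return A `geci_scene`: list with `neurons` (tibble: `id`, `x_um`, `y_um`,
#'   `radius_um`, `targeting`, `lambda_um`, `brightness`), `masks` (soma
#'   label image, 0 = background), `soma_w` and `neurite_w` (pixels x neurons
#'   weight matrices), `dims`, `pixel_size`, `fov_um`, `modality`,
#'   `neuropil_weight`, `seed`.
#' @export
build_scene <- function(n_neurons, fov_um = c(512, 512), pixel_size = 1,
                        soma_radius_range = c(4, 6), n_neurites = 4,
                        neurite_length_um = 300,
                        targeting = c("non_targeted", "soma_targeted"),
                        lambda_expr = NULL,
                        modality = c("widefield", "two_photon"),
                        neuropil_weight = 0, brightness = 1, min_gap_um = 0,
                        seed = 1, max_tries = 500) {
  targeting <- match.arg(targeting)
  modality <- match.arg(modality)
  if (n_neurons < 0) stop_geciq("`n_neurons` must be >= 0.", "geciq_error_domain")
  dims_f <- rev(fov_um) / pixel_size  # (rows, cols) = (height, width)
  if (any(abs(dims_f - round(dims_f)) > 1e-9)) {
    stop_geciq("`fov_um / pixel_size` must be integer image dimensions.",
               "geciq_error_domain")
  }
  dims <- as.integer(round(dims_f))
  lambda <- lambda_expr %||% switch(targeting, non_targeted = 100,
                                    soma_targeted = 20)
  brightness <- rep_len(brightness, max(n_neurons, 1L))
  npix <- prod(dims)

  if (n_neurons == 0) {
    return(structure(list(
      neurons = tibble::tibble(id = integer(), x_um = numeric(),
                               y_um = numeric(), radius_um = numeric(),
                               targeting = character(), lambda_um = numeric(),
                               brightness = numeric()),
      masks = matrix(0L, dims[1], dims[2]),
      soma_w = matrix(0, npix, 0), neurite_w = matrix(0, npix, 0),
      dims = dims, pixel_size = pixel_size, fov_um = fov_um,
      modality = modality, neuropil_weight = neuropil_weight, seed = seed),
      class = "geci_scene"))
  }

  scene <- with_seed_if(seed, {
    radii <- runif(n_neurons, soma_radius_range[1], soma_radius_range[2])
    xs <- numeric(0); ys <- numeric(0)
    for (i in seq_len(n_neurons)) {
      placed <- FALSE
      for (try in seq_len(max_tries)) {
        x <- runif(1, radii[i], fov_um[1] - radii[i])
        y <- runif(1, radii[i], fov_um[2] - radii[i])
        if (i == 1 ||
            all(sqrt((xs - x)^2 + (ys - y)^2) >=
                  radii[seq_len(i - 1)] + radii[i] + min_gap_um)) {
          xs <- c(xs, x); ys <- c(ys, y); placed <- TRUE; break
        }
      }
      if (!placed) {
        stop_geciq("could not pack somas without overlap; lower the neuron density.",
                   "geciq_error_packing")
      }
    }

    masks <- matrix(0L, dims[1], dims[2])
    soma_w <- matrix(0, npix, n_neurons)
    neurite_w <- matrix(0, npix, n_neurons)
    # pixel centers in microns (0-based pixel index convention)
    px_x <- (seq_len(dims[2]) - 0.5) * pixel_size
    px_y <- (seq_len(dims[1]) - 0.5) * pixel_size

    for (i in seq_len(n_neurons)) {
      # soma disk
      cols <- which(abs(px_x - xs[i]) <= radii[i])
      rows <- which(abs(px_y - ys[i]) <= radii[i])
      for (r in rows) for (cc in cols) {
        if ((px_x[cc] - xs[i])^2 + (px_y[r] - ys[i])^2 <= radii[i]^2) {
          masks[r, cc] <- i
          soma_w[(cc - 1L) * dims[1] + r, i] <- brightness[i]
        }
      }
      # random-walk neurites from the soma edge
      step <- pixel_size
      n_steps <- ceiling(neurite_length_um / step)
      for (k in seq_len(n_neurites)) {
        ang <- runif(1, 0, 2 * pi)
        px <- xs[i] + radii[i] * cos(ang)
        py <- ys[i] + radii[i] * sin(ang)
        d <- 0
        jit <- rnorm(n_steps, 0, 0.25)
        for (s in seq_len(n_steps)) {
          ang <- ang + jit[s]
          px <- px + step * cos(ang)
          py <- py + step * sin(ang)
          d <- d + step
          ci <- floor(px / pixel_size) + 1L
          ri <- floor(py / pixel_size) + 1L
          if (ri < 1L || ri > dims[1] || ci < 1L || ci > dims[2]) break
          idx <- (ci - 1L) * dims[1] + ri
          w <- brightness[i] * exp(-d / lambda)
          if (w > neurite_w[idx, i]) neurite_w[idx, i] <- w
        }
      }
    }
    # a neuron's own soma pixels are not its neurite pixels; neurites of
    # *other* neurons may cross a soma (that overlap is real contamination)
    for (i in seq_len(n_neurons)) {
      own <- which(as.integer(masks) == i)
      neurite_w[own, i] <- 0
    }
    list(xs = xs, ys = ys, radii = radii, masks = masks,
         soma_w = soma_w, neurite_w = neurite_w)
  })

  structure(list(
    neurons = tibble::tibble(
      id = seq_len(n_neurons), x_um = scene$xs, y_um = scene$ys,
      radius_um = scene$radii, targeting = targeting, lambda_um = lambda,
      brightness = brightness),
    masks = scene$masks, soma_w = scene$soma_w, neurite_w = scene$neurite_w,
    dims = dims, pixel_size = pixel_size, fov_um = fov_um,
    modality = modality, neuropil_weight = neuropil_weight, seed = seed),
    class = "geci_scene")
}

#' @export
print.geci_scene <- function(x, ...) {
  cat(sprintf("<geci_scene> %d neurons, %dx%d px (%.3g um/px), %s, %s\n",
              nrow(x$neurons), x$dims[1], x$dims[2], x$pixel_size,
              x$modality, unique(c(x$neurons$targeting, "empty"))[1]))
  invisible(x)
}

#' Optics presets for the two imaging regimes
#'
#' Wide-field epifluorescence collects a large out-of-focus, scattered
#' background (large blur and mixing weight); two-photon imaging is optically
#' sectioned (small residual mixing). The blur is a two-parameter caricature
#' (Gaussian sigma + mixing weight), not a physical PSF: it is sufficient to
#' reproduce the widefield >> two-photon contamination ordering.
#'
#' @param modality `"widefield"` or `"two_photon"`.
#' @return List with `oof_weight` and `background_sigma` (pixels).
#' @export
optics_preset <- function(modality = c("widefield", "two_photon")) {
  modality <- match.arg(modality)
  switch(modality,
         widefield = list(oof_weight = 8, background_sigma = 60),
         two_photon = list(oof_weight = 0.08, background_sigma = 2))
}

#' Render a noisy imaging movie from a scene and per-neuron traces
#'
#' Each frame is the sum of (1) in-focus soma fluorescence, (2) neurite
#' fluorescence of every neuron (the structural neuropil), (3) an
#' out-of-focus term: a Gaussian-blurred copy of every neuron's full
#' footprint mixed in with weight `oof_weight`, (4) an optional shared
#' neuropil trace mixed into all non-soma pixels with the scene's
#' `neuropil_weight`, and (5) a constant background offset. Photon shot noise
#' and read noise are then applied per pixel via [add_photon_noise()].
#'
#' Because the blur is linear and the footprints static, the out-of-focus
#' term is computed by blurring each neuron's footprint once and scaling it
#' by the neuron's trace.
#'
#' @param scene A `geci_scene` from [build_scene()].
#' @param traces Per-neuron fluorescence: a frames x neurons matrix, or a
#'   long tibble with columns `roi`, `frame`, `value`. One trace per neuron,
#'   equal lengths.
#' @param frame_rate Frames per second of the output movie.
#' @param neuropil_trace Optional shared neuropil trace (numeric vector,
#'   length = frames), mixed with weight `scene$neuropil_weight`.
#' @param oof_weight,background_sigma Override the [optics_preset()] of the
#'   scene's modality.
#' @param background_offset Constant background level, a.u.
#' @param photons_per_unit,read_noise_sd Noise model; `photons_per_unit =
#'   Inf` disables shot noise.
#' @param seed Seed for the noise draw.
#' @return A `geci_movie`: 3-D array (rows x cols x frames) with attributes
#'   `frame_rate` and `pixel_size`.
#' @export
render_movie <- function(scene, traces, frame_rate = 10,
                         neuropil_trace = NULL, oof_weight = NULL,
                         background_sigma = NULL, background_offset = 1,
                         photons_per_unit = 200, read_noise_sd = 0,
                         seed = NULL) {
  stopifnot(inherits(scene, "geci_scene"))
  S <- traces_to_matrix(traces, n_neurons = nrow(scene$neurons))
  preset <- optics_preset(scene$modality)
  oof_weight <- oof_weight %||% preset$oof_weight
  background_sigma <- background_sigma %||% preset$background_sigma
  dims <- scene$dims
  npix <- prod(dims)
  n_frames <- nrow(S)

  A <- scene$soma_w + scene$neurite_w
  if (oof_weight > 0 && ncol(A) > 0) {
    A_blur <- apply(A, 2, function(col) {
      as.numeric(gaussian_blur(matrix(col, dims[1], dims[2]),
                               sigma = background_sigma))
    })
    A_total <- scene$soma_w + scene$neurite_w + oof_weight * A_blur
  } else {
    A_total <- A
  }
  frames <- if (ncol(A_total) > 0) A_total %*% t(S) else
    matrix(0, npix, n_frames)
  if (!is.null(neuropil_trace) && scene$neuropil_weight > 0) {
    np <- as.numeric(trace_values(neuropil_trace))
    if (length(np) != n_frames) {
      stop_geciq("neuropil trace length must match the frame count.",
                 "geciq_error_input")
    }
    nonsoma <- as.numeric(scene$masks == 0)
    np_map <- nonsoma
    if (oof_weight > 0) {
      # the shared neuropil field also contributes out-of-focus light,
      # which bleeds over the somas
      np_map <- np_map + oof_weight * as.numeric(
        gaussian_blur(matrix(nonsoma, dims[1], dims[2]), background_sigma))
    }
    frames <- frames + scene$neuropil_weight * (np_map %o% np)
  }
  frames <- frames + background_offset
  movie <- array(frames, dim = c(dims[1], dims[2], n_frames))
  if (is.finite(photons_per_unit) || read_noise_sd > 0) {
    if (is.finite(photons_per_unit)) {
      movie <- add_photon_noise(movie, photons_per_unit, read_noise_sd, seed)
    } else if (read_noise_sd > 0) {
      movie <- movie + with_seed_if(seed,
        array(rnorm(length(movie), 0, read_noise_sd), dim = dim(movie)))
    }
  }
  structure(movie, frame_rate = frame_rate, pixel_size = scene$pixel_size,
            class = c("geci_movie", "array"))
}

# Gaussian blur with the kernel radius capped so the brush never exceeds the
# image (EBImage's default 3-sigma brush can outgrow small fields).
gaussian_blur <- function(img, sigma) {
  radius <- 2L * as.integer(ceiling(3 * sigma)) + 1L
  max_odd <- min(dim(img)) - (1L - min(dim(img)) %% 2L)
  radius <- min(radius, max_odd)
  as.matrix(EBImage::gblur(img, sigma = sigma, radius = radius))
}

# Accepts frames x neurons matrix or long tibble (roi, frame, value).
traces_to_matrix <- function(traces, n_neurons) {
  if (is.matrix(traces)) {
    S <- traces
  } else if (is.data.frame(traces)) {
    req <- c("roi", "frame", "value")
    if (!all(req %in% names(traces))) {
      stop_geciq("long traces need columns roi, frame, value.",
                 "geciq_error_input")
    }
    wide <- tidyr::pivot_wider(traces[req], names_from = "roi",
                               values_from = "value")
    wide <- dplyr::arrange(wide, .data$frame)
    S <- as.matrix(wide[-1])
  } else {
    stop_geciq("`traces` must be a matrix or a long tibble.",
               "geciq_error_input")
  }
  if (ncol(S) != n_neurons) {
    stop_geciq(sprintf("expected %d traces, got %d.", n_neurons, ncol(S)),
               "geciq_error_input")
  }
  if (anyNA(S)) stop_geciq("traces contain NA (unequal lengths?).",
                           "geciq_error_input")
  S
}

#' @export
print.geci_movie <- function(x, ...) {
  d <- dim(x)
  cat(sprintf("<geci_movie> %d x %d px, %d frames @ %g Hz\n",
              d[1], d[2], d[3], attr(x, "frame_rate") %||% NA))
  invisible(x)
}
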