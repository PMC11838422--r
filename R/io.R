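# Movie and ground-truth I/O: multi-page TIFF for image stacks, a label-image
# TIFF plus JSON sidecar for scene truth.

#' Write / read a movie as a multi-page TIFF
#'
#' `"uint16"` mode stores `round(value / scale)` as 16-bit samples (exact
#' round-trip for integer-valued input when `scale = 1`); `"float32"` mode
#' rescales values affinely into `[0, 1]` for storage and restores them on
#' read (round-trip within float precision). The encoding (mode, scale,
#' offset, frame rate, pixel size) is recorded in a JSON sidecar at
#' `<path>.json`.
#'
#' @param movie A `geci_movie` or 3-D array (rows x cols x frames).
#' @param path Output TIFF path.
#' @param format `"uint16"` or `"float32"`.
#' @param scale For `uint16`: fluorescence units per grey level (default 1).
#' @return `write_movie()` returns `path` invisibly; `read_movie()` returns a
#'   `geci_movie`.
#' @export
write_movie <- function(movie, path, format = c("uint16", "float32"),
                        scale = 1) {
  format <- match.arg(format)
  if (!(is.array(movie) && length(dim(movie)) == 3)) {
    stop_geciq("`movie` must be a 3-D array.", "geciq_error_input")
  }
  d <- dim(movie)
  meta <- list(format = format,
               frame_rate = attr(movie, "frame_rate"),
               pixel_size = attr(movie, "pixel_size"))
  if (format == "uint16") {
    enc <- round(unclass(movie) / scale)
    if (any(enc < 0) || any(enc > 65535)) {
      stop_geciq("values out of uint16 range after scaling; adjust `scale`.",
                 "geciq_error_domain")
    }
    pages <- lapply(seq_len(d[3]), function(k) enc[, , k] / 65535)
    tiff::writeTIFF(pages, path, bits.per.sample = 16)
    meta$scale <- scale
  } else {
    lo <- min(movie); hi <- max(movie)
    span <- if (hi > lo) hi - lo else 1
    pages <- lapply(seq_len(d[3]), function(k) (unclass(movie)[, , k] - lo) / span)
    tiff::writeTIFF(pages, path, bits.per.sample = 32)
    meta$offset <- lo
    meta$span <- span
  }
  jsonlite::write_json(meta, paste0(path, ".json"), auto_unbox = TRUE,
                       digits = NA)
  invisible(path)
}

#' @rdname write_movie
#' @export
read_movie <- function(path) {
  pages <- tryCatch(tiff::readTIFF(path, all = TRUE),
                    error = function(e) {
                      stop_geciq(sprintf("could not parse TIFF at %s: %s",
                                         path, conditionMessage(e)),
                                 "geciq_error_parse")
                    })
  meta_path <- paste0(path, ".json")
  meta <- if (file.exists(meta_path)) jsonlite::read_json(meta_path) else
    list(format = "float32", offset = 0, span = 1)
  arr <- simplify2array(pages)
  if (identical(meta$format, "uint16")) {
    arr <- round(arr * 65535) * (meta$scale %||% 1)
  } else {
    arr <- arr * (meta$span %||% 1) + (meta$offset %||% 0)
  }
  structure(arr,
            frame_rate = meta$frame_rate %||% NULL,
            pixel_size = meta$pixel_size %||% NULL,
            class = c("geci_movie", "array"))
}

#' Write / read scene ground truth (label TIFF + JSON sidecar)
#'
#' The soma label image goes to `<stem>_masks.tif` (16-bit, exact) and the
#' neuron table plus scene metadata to `<stem>_truth.json`. The expression
#' weight maps are not serialized: they are reconstructed deterministically
#' from the recorded seed and parameters via [build_scene()] when needed.
#'
#' @param scene A `geci_scene`.
#' @param stem Path stem (without extension).
#' @return `write_scene_truth()` returns `stem` invisibly;
#'   `read_scene_truth()` returns a list with `neurons` (tibble), `masks`
#'   (integer label matrix) and the scalar metadata fields.
#' @export
write_scene_truth <- function(scene, stem) {
  stopifnot(inherits(scene, "geci_scene"))
  tiff::writeTIFF(scene$masks / 65535, paste0(stem, "_masks.tif"),
                  bits.per.sample = 16)
  meta <- list(
    neurons = scene$neurons,
    fov_um = scene$fov_um, pixel_size = scene$pixel_size,
    modality = scene$modality, neuropil_weight = scene$neuropil_weight,
    seed = scene$seed, dims = scene$dims)
  jsonlite::write_json(meta, paste0(stem, "_truth.json"), auto_unbox = TRUE,
                       digits = NA, dataframe = "columns")
  invisible(stem)
}

#' @rdname write_scene_truth
#' @export
read_scene_truth <- function(stem) {
  masks <- round(tiff::readTIFF(paste0(stem, "_masks.tif")) * 65535)
  storage.mode(masks) <- "integer"
  meta <- jsonlite::read_json(paste0(stem, "_truth.json"),
                              simplifyVector = TRUE)
  list(neurons = tibble::as_tibble(meta$neurons), masks = masks,
       fov_um = meta$fov_um, pixel_size = meta$pixel_size,
       modality = meta$modality, neuropil_weight = meta$neuropil_weight,
       seed = meta$seed, dims = meta$dims)
}
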