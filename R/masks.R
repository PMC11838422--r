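# ROI-level spatial quantification. ROI sets are represented as integer label
# images (0 = background, k = ROI k), the standard segmentation output format;
# labels are unique within a set by construction.

label_pixels <- function(masks, label) which(masks == label)

#' Summary table of a label image
#'
#' @param masks Integer label matrix (0 = background).
#' @param pixel_size Microns per pixel used for centroids (default 1).
#' @return Tibble with `label`, `area_px`, `x_um`, `y_um` (centroid of pixel
#'   centers).
#' @export
mask_table <- function(masks, pixel_size = 1) {
  labs <- sort(setdiff(unique(as.integer(masks)), 0L))
  purrr::map_dfr(labs, function(l) {
    idx <- which(masks == l, arr.ind = TRUE)
    tibble::tibble(label = l, area_px = nrow(idx),
                   x_um = mean((idx[, 2] - 0.5) * pixel_size),
                   y_um = mean((idx[, 1] - 0.5) * pixel_size))
  })
}

#' Extract per-frame ROI traces from a movie
#'
#' The per-frame statistic (mean or median) over the pixels of each ROI.
#'
#' @param movie 3-D array (rows x cols x frames), e.g. from [render_movie()].
#' @param masks Integer label matrix matching the movie's spatial dimensions.
#' @param labels ROI labels to extract (default: all).
#' @param statistic `"mean"` or `"median"`.
#' @return Long tibble with columns `roi`, `frame`, `value` (and `time_s`
#'   when the movie has a frame rate).
#' @export
extract_traces <- function(movie, masks, labels = NULL,
                           statistic = c("mean", "median")) {
  statistic <- match.arg(statistic)
  d <- dim(movie)
  if (!identical(dim(masks), d[1:2])) {
    stop_geciq("mask dimensions must match the movie frames.",
               "geciq_error_input")
  }
  labels <- labels %||% sort(setdiff(unique(as.integer(masks)), 0L))
  flat <- matrix(movie, nrow = d[1] * d[2], ncol = d[3])
  fr <- attr(movie, "frame_rate")
  purrr::map_dfr(labels, function(l) {
    idx <- label_pixels(masks, l)
    if (length(idx) == 0) {
      stop_geciq(sprintf("ROI %d has an empty mask.", l), "geciq_error_input")
    }
    px <- flat[idx, , drop = FALSE]
    vals <- if (statistic == "mean") colMeans(px) else
      apply(px, 2, median)
    out <- tibble::tibble(roi = l, frame = seq_len(d[3]), value = vals)
    if (!is.null(fr)) out$time_s <- (out$frame - 1) / fr
    out
  })
}

#' @rdname extract_traces
#' @param label A single ROI label.
#' @export
extract_trace <- function(movie, masks, label,
                          statistic = c("mean", "median")) {
  extract_traces(movie, masks, labels = label, statistic = statistic)
}

#' Neuropil trace from an annulus around an ROI
#'
#' The per-frame median (or mean) over the ring of pixels whose Euclidean
#' distance (pixel center to nearest ROI pixel center) lies in
#' `(inner, outer]` pixels; pixels belonging to any ROI in the label image
#' are excluded from the annulus.
#'
#' @param movie 3-D array.
#' @param masks Integer label image (all ROIs; used both to locate the target
#'   ROI and to exclude other ROIs' pixels).
#' @param label Target ROI label.
#' @param inner,outer Annulus radii in pixels (default 5 and 15,
#'   `inner < outer`).
#' @param statistic `"median"` (default) or `"mean"`.
#' @return Tibble with `roi`, `frame`, `value` (and `time_s` when available).
#' @export
neuropil_annulus_trace <- function(movie, masks, label, inner = 5, outer = 15,
                                   statistic = c("median", "mean")) {
  statistic <- match.arg(statistic)
  if (inner >= outer) {
    stop_geciq("`inner` must be smaller than `outer`.", "geciq_error_domain")
  }
  d <- dim(movie)
  roi <- which(masks == label, arr.ind = TRUE)
  if (nrow(roi) == 0) {
    stop_geciq(sprintf("ROI %d not found in mask image.", label),
               "geciq_error_input")
  }
  # candidate pixels within the ROI bounding box grown by `outer`
  r_rng <- max(1, min(roi[, 1]) - ceiling(outer)):min(d[1], max(roi[, 1]) + ceiling(outer))
  c_rng <- max(1, min(roi[, 2]) - ceiling(outer)):min(d[2], max(roi[, 2]) + ceiling(outer))
  cand <- expand.grid(row = r_rng, col = c_rng)
  cand <- cand[masks[cbind(cand$row, cand$col)] == 0, ]  # exclude all ROIs
  if (nrow(cand) == 0) {
    stop_geciq("annulus is empty after exclusions; increase `outer`.",
               "geciq_error_input")
  }
  dist2 <- vapply(seq_len(nrow(cand)), function(i) {
    min((cand$row[i] - roi[, 1])^2 + (cand$col[i] - roi[, 2])^2)
  }, numeric(1))
  keep <- dist2 > inner^2 & dist2 <= outer^2
  if (!any(keep)) {
    stop_geciq("annulus is empty after exclusions; increase `outer`.",
               "geciq_error_input")
  }
  idx <- (cand$col[keep] - 1L) * d[1] + cand$row[keep]
  flat <- matrix(movie, nrow = d[1] * d[2], ncol = d[3])
  px <- flat[idx, , drop = FALSE]
  vals <- if (statistic == "median") apply(px, 2, median) else colMeans(px)
  out <- tibble::tibble(roi = label, frame = seq_len(d[3]), value = vals)
  fr <- attr(movie, "frame_rate")
  if (!is.null(fr)) out$time_s <- (out$frame - 1) / fr
  out
}

#' Neuropil subtraction
#'
#' `F_corrected = F_soma - r * F_neuropil`, with the standard contamination
#' coefficient `r = 0.7`.
#'
#' @param f,f_neu Soma and neuropil traces (tibbles with `value` columns or
#'   numeric vectors of equal length).
#' @param r Subtraction coefficient (default 0.7; `r = 0` is the identity).
#' @return If `f` is a tibble, the tibble with `value` replaced by the
#'   corrected trace; otherwise a numeric vector.
#' @export
neuropil_correct <- function(f, f_neu, r = 0.7) {
  vf <- trace_values(f)
  vn <- trace_values(f_neu)
  if (length(vf) != length(vn)) {
    stop_geciq("soma and neuropil traces must have equal length.",
               "geciq_error_input")
  }
  corrected <- vf - r * vn
  if (is.data.frame(f)) {
    f$value <- corrected
    f
  } else {
    corrected
  }
}

#' Intersection-over-union of two ROI masks
#'
#' @param a,b Logical matrices (or 0/1 integer matrices) of equal dimensions.
#' @return `|a \&\& b| / |a || b|` in `[0, 1]`; symmetric, and 1 iff the
#'   masks are identical (and non-empty).
#' @export
mask_iou <- function(a, b) {
  a <- as.logical(a); b <- as.logical(b)
  if (length(a) != length(b)) {
    stop_geciq("masks must have the same dimensions.", "geciq_error_input")
  }
  uni <- sum(a | b)
  if (uni == 0) return(0)
  sum(a & b) / uni
}

# IOU edge list between two label images: one row per overlapping label pair.
iou_edges <- function(masks_a, masks_b) {
  va <- as.integer(masks_a); vb <- as.integer(masks_b)
  area_a <- table(va[va > 0]); area_b <- table(vb[vb > 0])
  both <- va > 0 & vb > 0
  if (!any(both)) {
    return(tibble::tibble(id_a = integer(), id_b = integer(), iou = numeric()))
  }
  ov <- as.data.frame(table(a = va[both], b = vb[both]),
                      stringsAsFactors = FALSE)
  ov <- ov[ov$Freq > 0, ]
  inter <- ov$Freq
  aa <- as.numeric(area_a[ov$a]); bb <- as.numeric(area_b[ov$b])
  tibble::tibble(id_a = as.integer(ov$a), id_b = as.integer(ov$b),
                 iou = inter / (aa + bb - inter))
}

#' Match ROIs across two segmentations by IOU
#'
#' Pairs ROIs from two label images. `"greedy"` (default, the
#' highest-IOU-first rule): repeatedly accept the remaining pair with the
#' highest IOU at or above `threshold`, removing both ROIs; ties are broken
#' deterministically by (lower `id_a`, lower `id_b`). `"optimal"` instead
#' maximizes the total IOU over all one-to-one matchings restricted to pairs
#' at or above the threshold (exhaustive search; intended for modest set
#' sizes). Pairs with IOU below the threshold are never matched
#' (`0.49` at a `0.5` threshold stays unmatched; `0.50` matches).
#'
#' @param masks_a,masks_b Integer label images of equal dimensions.
#' @param threshold Minimum IOU for a valid pair (default 0.5).
#' @param method `"greedy"` or `"optimal"`.
#' @return List with `pairs` (tibble `id_a`, `id_b`, `iou`, sorted by
#'   `id_a`), `unmatched_a`, `unmatched_b` (integer label vectors).
#' @export
match_rois <- function(masks_a, masks_b, threshold = 0.5,
                       method = c("greedy", "optimal")) {
  method <- match.arg(method)
  if (!identical(dim(masks_a), dim(masks_b))) {
    stop_geciq("label images must have equal dimensions.", "geciq_error_input")
  }
  labs_a <- sort(setdiff(unique(as.integer(masks_a)), 0L))
  labs_b <- sort(setdiff(unique(as.integer(masks_b)), 0L))
  edges <- iou_edges(masks_a, masks_b)
  edges <- edges[edges$iou >= threshold, ]
  pairs <- tibble::tibble(id_a = integer(), id_b = integer(), iou = numeric())
  if (nrow(edges) > 0 && method == "greedy") {
    edges <- edges[order(-edges$iou, edges$id_a, edges$id_b), ]
    used_a <- integer(); used_b <- integer()
    for (i in seq_len(nrow(edges))) {
      if (edges$id_a[i] %in% used_a || edges$id_b[i] %in% used_b) next
      pairs <- dplyr::bind_rows(pairs, edges[i, ])
      used_a <- c(used_a, edges$id_a[i])
      used_b <- c(used_b, edges$id_b[i])
    }
  } else if (nrow(edges) > 0) {
    pairs <- edges[best_matching(edges), ]
  }
  pairs <- dplyr::arrange(pairs, .data$id_a)
  list(pairs = pairs,
       unmatched_a = setdiff(labs_a, pairs$id_a),
       unmatched_b = setdiff(labs_b, pairs$id_b))
}

# Exhaustive maximum-total-IOU one-to-one matching over an edge list.
# Returns row indices of the chosen edges.
best_matching <- function(edges) {
  n <- nrow(edges)
  best <- list(score = -Inf, rows = integer())
  recurse <- function(i, used_a, used_b, rows, score) {
    if (i > n) {
      if (score > best$score) best <<- list(score = score, rows = rows)
      return(invisible())
    }
    # upper bound prune: remaining edges can add at most their summed IOU
    if (score + sum(edges$iou[i:n]) <= best$score) return(invisible())
    recurse(i + 1L, used_a, used_b, rows, score)  # skip edge i
    if (!(edges$id_a[i] %in% used_a) && !(edges$id_b[i] %in% used_b)) {
      recurse(i + 1L, c(used_a, edges$id_a[i]), c(used_b, edges$id_b[i]),
              c(rows, i), score + edges$iou[i])
    }
  }
  recurse(1L, integer(), integer(), integer(), 0)
  best$rows
}

#' Labeling density of an indicator against a reference stain
#'
#' The fraction of reference ROIs (e.g. Nissl-positive cells) that have a
#' matching indicator-expressing ROI. ROIs touching the image edge are
#' removed from both sets first. The default overlap rule accepts a pair
#' when the IOU is at least `min_iou` or the indicator ROI's centroid lies
#' inside the reference ROI.
#'
#' @param geci_masks,reference_masks Integer label images of equal
#'   dimensions.
#' @param min_iou IOU component of the overlap rule (default 0.25).
#' @param remove_edge Drop ROIs touching the image border (default TRUE).
#' @return Fraction in `[0, 1]`.
#' @export
labeling_density <- function(geci_masks, reference_masks, min_iou = 0.25,
                             remove_edge = TRUE) {
  if (!identical(dim(geci_masks), dim(reference_masks))) {
    stop_geciq("label images must have equal dimensions.", "geciq_error_input")
  }
  drop_edge <- function(masks) {
    if (!remove_edge) return(masks)
    d <- dim(masks)
    edge_labels <- unique(c(masks[1, ], masks[d[1], ], masks[, 1], masks[, d[2]]))
    masks[masks %in% setdiff(edge_labels, 0L)] <- 0L
    masks
  }
  g <- drop_edge(geci_masks)
  r <- drop_edge(reference_masks)
  ref_labels <- sort(setdiff(unique(as.integer(r)), 0L))
  if (length(ref_labels) == 0) {
    stop_geciq("reference set is empty (after edge removal).",
               "geciq_error_input")
  }
  edges <- iou_edges(g, r)
  covered_iou <- unique(edges$id_b[edges$iou >= min_iou])
  # centroid containment: indicator ROI centroid inside the reference ROI
  gt <- mask_table(g)
  covered_centroid <- integer()
  if (nrow(gt) > 0) {
    rows <- pmin(pmax(ceiling(gt$y_um), 1), dim(r)[1])
    cols <- pmin(pmax(ceiling(gt$x_um), 1), dim(r)[2])
    covered_centroid <- r[cbind(rows, cols)]
  }
  covered <- union(covered_iou, setdiff(covered_centroid, 0L))
  length(intersect(ref_labels, covered)) / length(ref_labels)
}

#' Soma-to-neuropil fluorescence ratio
#'
#' Mean intensity over soma pixels divided by mean intensity over neuropil
#' pixels of a single image (e.g. a time-average). Soma-targeted indicators
#' show markedly higher ratios than non-targeted ones.
#'
#' @param image 2-D numeric matrix.
#' @param soma_masks,neuropil_masks Label images or logical matrices marking
#'   the two compartments (non-zero = included).
#' @return The ratio; a zero neuropil mean returns `Inf` with a warning.
#' @export
soma_neuropil_ratio <- function(image, soma_masks, neuropil_masks) {
  s_idx <- which(soma_masks != 0)
  n_idx <- which(neuropil_masks != 0)
  if (length(s_idx) == 0 || length(n_idx) == 0) {
    stop_geciq("both mask sets must be non-empty.", "geciq_error_input")
  }
  neu <- mean(image[n_idx])
  if (neu == 0) {
    rlang::warn("zero neuropil mean; returning infinite ratio sentinel.")
    return(Inf)
  }
  mean(image[s_idx]) / neu
}

#' Minimal threshold-based soma segmenter
#'
#' Gaussian smoothing, global threshold (Otsu or absolute), connected
#' components, area filter. Deterministic. This is a deliberately simple
#' intensity segmenter for synthetic scenes and bright somata, not a
#' replacement for learned segmentation tools.
#'
#' @param image 2-D numeric matrix.
#' @param smoothing_sigma Gaussian sigma in pixels (0 = no smoothing).
#' @param threshold `"otsu"` or an absolute intensity value.
#' @param min_area,max_area Component area limits in pixels.
#' @return List with `masks` (integer label image; empty image gives all
#'   zeros, not an error) and `rois` (the [mask_table()] of the labels).
#' @export
simple_segment <- function(image, smoothing_sigma = 2, threshold = "otsu",
                           min_area = 10, max_area = Inf) {
  if (!is.matrix(image)) {
    stop_geciq("`image` must be a 2-D matrix.", "geciq_error_input")
  }
  img <- image
  if (smoothing_sigma > 0) img <- EBImage::gblur(img, sigma = smoothing_sigma)
  if (identical(threshold, "otsu")) {
    rng <- range(img)
    if (diff(rng) == 0) {
      return(list(masks = matrix(0L, nrow(img), ncol(img)),
                  rois = mask_table(matrix(0L, 1, 1))))
    }
    norm <- (img - rng[1]) / diff(rng)
    thr_val <- EBImage::otsu(EBImage::Image(norm)) * diff(rng) + rng[1]
  } else {
    thr_val <- as.numeric(threshold)
  }
  bin <- img > thr_val
  labs <- EBImage::bwlabel(EBImage::Image(bin))
  masks <- matrix(as.integer(EBImage::imageData(labs)), nrow(img), ncol(img))
  tab <- table(masks[masks > 0])
  bad <- as.integer(names(tab[tab < min_area | tab > max_area]))
  masks[masks %in% bad] <- 0L
  # relabel sequentially
  old <- sort(setdiff(unique(as.integer(masks)), 0L))
  relabel <- setNames(seq_along(old), old)
  masks[masks > 0] <- relabel[as.character(masks[masks > 0])]
  list(masks = masks, rois = mask_table(masks))
}
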