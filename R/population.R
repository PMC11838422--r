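# Population-level statistics: pairwise correlation versus distance, distance
# binning, responsive fractions and per-FOV summaries.

#' Pairwise Pearson correlations between ROI traces with centroid distances
#'
#' Computes the Pearson correlation coefficient for every unordered pair of
#' ROIs together with the Euclidean centroid-to-centroid distance. Traces are
#' z-scored per ROI before correlation (which leaves the PCC unchanged but
#' matches the convention of correlating z-scored activity); zero-variance
#' ROIs are skipped with a warning.
#'
#' @param traces Long tibble with columns `roi`, `frame`, `value`.
#' @param centroids Tibble with columns `roi` (or `id`), `x_um`, `y_um`.
#' @param corrected Logical flag stored in the output (marks whether the
#'   traces were neuropil-subtracted); purely descriptive.
#' @return Tibble with `id_i`, `id_j` (`id_i < id_j`), `distance_um`, `pcc`,
#'   `corrected`.
#' @export
pairwise_correlation <- function(traces, centroids, corrected = FALSE) {
  req <- c("roi", "frame", "value")
  if (!is.data.frame(traces) || !all(req %in% names(traces))) {
    stop_geciq("`traces` must have columns roi, frame, value.",
               "geciq_error_input")
  }
  if ("id" %in% names(centroids) && !"roi" %in% names(centroids)) {
    centroids <- dplyr::rename(centroids, roi = "id")
  }
  wide <- tidyr::pivot_wider(traces[req], names_from = "roi",
                             values_from = "value")
  wide <- dplyr::arrange(wide, .data$frame)
  M <- as.matrix(wide[-1])
  if (ncol(M) < 2) {
    stop_geciq("need at least 2 ROI traces.", "geciq_error_input")
  }
  if (anyNA(M)) {
    stop_geciq("traces have unequal lengths.", "geciq_error_input")
  }
  sds <- apply(M, 2, sd)
  if (any(sds == 0)) {
    rlang::warn(sprintf("skipping %d zero-variance ROI(s).", sum(sds == 0)))
    M <- M[, sds > 0, drop = FALSE]
  }
  ids <- as.integer(colnames(M))
  M <- scale(M)
  C <- cor(M)
  pos <- centroids[match(ids, centroids$roi), ]
  if (anyNA(pos$x_um)) {
    stop_geciq("centroids missing for some ROIs.", "geciq_error_input")
  }
  n <- length(ids)
  pairs <- which(upper.tri(C), arr.ind = TRUE)
  tibble::tibble(
    id_i = ids[pairs[, 1]], id_j = ids[pairs[, 2]],
    distance_um = sqrt((pos$x_um[pairs[, 1]] - pos$x_um[pairs[, 2]])^2 +
                         (pos$y_um[pairs[, 1]] - pos$y_um[pairs[, 2]])^2),
    pcc = C[pairs],
    corrected = corrected
  )
}

#' Bin pairwise correlations by centroid distance
#'
#' Bins are half-open `[lo, hi)`: a pair at exactly 200 um falls in the
#' 200-400 bin. Pairs at or beyond the last edge are dropped and their count
#' reported as the `n_dropped` attribute.
#'
#' @param pairs Tibble from [pairwise_correlation()].
#' @param bin_edges Increasing numeric vector of bin edges in microns
#'   (default `c(0, 200, 400, 800)`).
#' @return Tibble with `bin_lo_um`, `bin_hi_um`, `mean_pcc`, `n_pairs`.
#' @export
bin_correlation <- function(pairs, bin_edges = c(0, 200, 400, 800)) {
  if (nrow(pairs) == 0) {
    stop_geciq("`pairs` is empty.", "geciq_error_input")
  }
  if (is.unsorted(bin_edges, strictly = TRUE)) {
    stop_geciq("`bin_edges` must be strictly increasing.", "geciq_error_input")
  }
  k <- findInterval(pairs$distance_um, bin_edges, left.open = FALSE)
  inb <- k >= 1 & pairs$distance_um < bin_edges[length(bin_edges)]
  n_bins <- length(bin_edges) - 1L
  out <- purrr::map_dfr(seq_len(n_bins), function(b) {
    sel <- inb & k == b
    tibble::tibble(bin_lo_um = bin_edges[b], bin_hi_um = bin_edges[b + 1],
                   mean_pcc = if (any(sel)) mean(pairs$pcc[sel]) else NA_real_,
                   n_pairs = sum(sel))
  })
  attr(out, "n_dropped") <- sum(!inb)
  out
}

#' Fraction of responsive cells
#'
#' @param flags Logical vector (one per ROI); must be non-empty and NA-free.
#' @return `sum(flags) / length(flags)`.
#' @examples
#' fraction_responsive(c(rep(TRUE, 29), rep(FALSE, 71)))  # 0.29
#' @export
fraction_responsive <- function(flags) {
  if (length(flags) == 0) {
    stop_geciq("`flags` is empty.", "geciq_error_input")
  }
  if (anyNA(flags)) {
    stop_geciq("`flags` contains NA.", "geciq_error_input")
  }
  sum(flags) / length(flags)
}

#' Mean count per field of view
#'
#' @param total_count Total number of items (e.g. responsive neurons pooled
#'   across sessions).
#' @param n_fov Number of fields of view (>= 1).
#' @return `total_count / n_fov` as a double.
#' @examples
#' per_fov_mean(930, 16)  # 58.125
#' @export
per_fov_mean <- function(total_count, n_fov) {
  check_number(total_count, "total_count", lower = 0)
  if (!is.numeric(n_fov) || length(n_fov) != 1 || n_fov < 1) {
    stop_geciq("`n_fov` must be >= 1.", "geciq_error_domain")
  }
  total_count / n_fov
}
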