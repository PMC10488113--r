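#' Euclidean distance map of the WGA mask
#'
#' For every pixel, the Euclidean distance (micrometres) to the nearest
#' WGA-positive pixel; WGA-positive pixels map to zero. Computed with the
#' exact Euclidean distance transform of \pkg{EBImage}.
#'
#' @param wga_mask Logical WGA mask.
#' @param pixel_size_um Pixel edge length in micrometres.
#' @return Numeric matrix of distances (micrometres). An all-false mask
#'   yields all-\code{Inf} distances, flagged with the \code{"no_wga"}
#'   attribute and a warning.
#' @export
wga_distance_map <- function(wga_mask, pixel_size_um = 0.1) {
  stopifnot(is.logical(wga_mask), length(wga_mask) > 0, pixel_size_um > 0)
  if (!any(wga_mask)) {
    warning("mask has no WGA-positive pixel: distances are infinite",
            call. = FALSE)
    return(structure(matrix(Inf, nrow(wga_mask), ncol(wga_mask)),
                     no_wga = TRUE))
  }
  d <- EBImage::distmap(EBImage::Image(!wga_mask), metric = "euclidean")
  structure(EBImage::imageData(d) * pixel_size_um, no_wga = FALSE)
}

#' Segment single myocytes by watershed on the negated WGA distance map
#'
#' Floods the negated Euclidean distance map of the WGA mask: each basin
#' around a regional distance maximum becomes one candidate cell. Maxima
#' closer than \code{h_min_um} in depth to their separating saddle are
#' merged (h-maxima suppression), which keeps the striated WGA signal of
#' t-tubules from shattering cell interiors. Watershed regions are
#' intersected with the complement of the WGA mask; regions smaller than
#' \code{min_cell_area_um2} are merged into the neighbouring label with the
#' longest shared contact, or dropped to background when no neighbour is
#' close enough. Labels are renumbered contiguously in raster order, so the
#' result is deterministic for a fixed mask and parameters.
#'
#' @param wga_mask Logical WGA mask (from [local_threshold()]).
#' @param pixel_size_um Pixel edge length in micrometres.
#' @param min_cell_area_um2 Minimum retained segment area (default 100;
#'   myocyte profiles are far larger).
#' @param h_min_um Depth of h-maxima suppression in micrometres of distance
#'   (default 5.0, about half the smallest expected myocyte width). The
#'   depth must exceed the intracellular distance-map texture carved by
#'   t-tubule puncta (one sarcomere period and more where coverage is
#'   sparse) while staying below the myocyte half-width; distinct cells are
#'   kept apart by the zero-distance ECM ridge irrespective of this value.
#' @return A \code{cell_label_map}: list with the integer \code{labels}
#'   matrix (0 = ECM/background), \code{pixel_size_um} and per-label
#'   \code{areas_px}.
#' @export
segment_cells <- function(wga_mask, pixel_size_um = 0.1,
                          min_cell_area_um2 = 100, h_min_um = 5.0) {
  stopifnot(is.logical(wga_mask))
  dist_um <- wga_distance_map(wga_mask, pixel_size_um)
  if (isTRUE(attr(dist_um, "no_wga"))) {
    warning("no WGA signal: single open region, no cells segmented",
            call. = FALSE)
    return(new_cell_label_map(matrix(0L, nrow(wga_mask), ncol(wga_mask)),
                              pixel_size_um))
  }
  if (!any(dist_um > 0)) {
    warning("no seeds found: WGA mask covers the whole image", call. = FALSE)
    return(new_cell_label_map(matrix(0L, nrow(wga_mask), ncol(wga_mask)),
                              pixel_size_um))
  }
  w <- EBImage::watershed(EBImage::Image(dist_um), tolerance = h_min_um,
                          ext = 1)
  labels <- EBImage::imageData(w)
  storage.mode(labels) <- "integer"
  labels[wga_mask] <- 0L
  labels <- merge_small_segments(labels, min_cell_area_um2, pixel_size_um)
  new_cell_label_map(relabel_raster(labels), pixel_size_um)
}

new_cell_label_map <- function(labels, pixel_size_um) {
  storage.mode(labels) <- "integer"
  structure(list(labels = labels,
                 pixel_size_um = pixel_size_um,
                 areas_px = label_counts(labels)),
            class = "cell_label_map")
}

#' @export
print.cell_label_map <- function(x, ...) {
  cat(sprintf("cell_label_map: %d cells on a %d x %d grid (%.2f um/px)\n",
              length(x$areas_px), nrow(x$labels), ncol(x$labels),
              x$pixel_size_um))
  invisible(x)
}

# Merge sub-threshold watershed regions into their dominant neighbour
# (searched within a 2-px dilation, i.e. across thin WGA barriers);
# regions with no neighbour are dropped to background. Smallest regions
# are processed first so chains of fragments coalesce onto the main body.
merge_small_segments <- function(labels, min_cell_area_um2, pixel_size_um) {
  min_px <- min_cell_area_um2 / pixel_size_um^2
  h <- nrow(labels); w <- ncol(labels)
  repeat {
    counts <- label_counts(labels)
    small <- which(counts > 0L & counts < min_px)
    if (!length(small)) break
    small <- small[order(counts[small])]
    changed <- FALSE
    for (lab in small) {
      idx <- which(labels == lab, arr.ind = TRUE)
      if (!nrow(idx)) next
      neigh <- integer(0)
      for (dr in -2:2) for (dc in -2:2) {
        if (dr == 0L && dc == 0L) next
        rr <- idx[, 1L] + dr; cc <- idx[, 2L] + dc
        okp <- rr >= 1L & rr <= h & cc >= 1L & cc <= w
        if (!any(okp)) next
        neigh <- c(neigh, labels[cbind(rr[okp], cc[okp])])
      }
      neigh <- neigh[neigh > 0L & neigh != lab]
      if (length(neigh)) {
        tab <- tabulate(neigh)
        labels[idx] <- which.max(tab)
        changed <- TRUE
      } else {
        labels[idx] <- 0L
        changed <- TRUE
      }
    }
    if (!changed) break
  }
  # after merging, regions that are still below threshold have no neighbour
  counts <- label_counts(labels)
  drop <- which(counts > 0L & counts < min_px)
  if (length(drop)) labels[labels %in% drop] <- 0L
  labels
}

#' Match detected segments against a ground-truth label map
#'
#' For each detected label, finds the ground-truth cell containing the
#' largest share of its pixels. Used to validate segmentation on synthetic
#' slices.
#'
#' @param labels A \code{cell_label_map} or integer matrix.
#' @param truth_labels Integer ground-truth label map on the same grid.
#' @return Data frame with one row per detected label: \code{label},
#'   \code{area_px}, \code{best_truth} (0 = background) and
#'   \code{overlap_frac}, the share of the label's area inside that truth
#'   cell.
#' @export
match_segments <- function(labels, truth_labels) {
  if (inherits(labels, "cell_label_map")) labels <- labels$labels
  assert_same_grid(labels, truth_labels, "label maps")
  n <- max(labels)
  if (n < 1L)
    return(data.frame(label = integer(0), area_px = integer(0),
                      best_truth = integer(0), overlap_frac = numeric(0)))
  sel <- labels > 0L
  pair <- table(factor(labels[sel], levels = seq_len(n)), truth_labels[sel])
  area <- rowSums(pair)
  truth_ids <- as.integer(colnames(pair))
  best_j <- max.col(pair, ties.method = "first")
  data.frame(label = seq_len(n),
             area_px = as.integer(area),
             best_truth = truth_ids[best_j],
             overlap_frac = pair[cbind(seq_len(n), best_j)] / pmax(area, 1L))
}
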