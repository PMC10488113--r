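#' Morphological dilation with a disk structuring element
#'
#' Dilation with the set of offsets at Euclidean distance \code{<= radius_px}
#' from the origin. Radius 0 is the identity.
#'
#' @param mask Logical mask.
#' @param radius_px Disk radius in pixels (>= 0).
#' @return Logical mask.
#' @export
dilate_mask <- function(mask, radius_px) {
  stopifnot(is.logical(mask), radius_px >= 0)
  if (radius_px == 0) return(mask)
  k <- disk_kernel(radius_px)
  out <- EBImage::imageData(EBImage::dilate(EBImage::Image(mask * 1), k))
  out > 0
}

#' Classify cell segments from RyR and dextran pixel fractions
#'
#' The binary RyR mask is dilated with radius \code{r_ryr} (default 4 px)
#' and the dextran mask with radius \code{r_dx} (default 3 px). For each
#' segment the fraction of dilated-mask-positive pixels among the segment's
#' pixels gives \code{f_ryr} and \code{f_dextran}; a segment is RyR-positive
#' when \code{f_ryr >= theta_ryr} (default 0.15) and dextran-positive when
#' \code{f_dextran >= theta_dx} (default 0.2). The four combinations map to
#' the classes \code{live} (RyR+ / Dx-), \code{dead} (RyR- / Dx+),
#' \code{double_positive} and \code{double_negative}. The undilated
#' RyR-positive percentage is reported as \code{raw_ryr_density} for
#' density-style summaries.
#'
#' @param labels A \code{cell_label_map} (from [segment_cells()]) or integer
#'   label matrix.
#' @param ryr_mask,dextran_mask Logical masks on the same grid.
#' @param theta_ryr,theta_dx Classification thresholds on the dilated pixel
#'   fractions.
#' @param r_ryr,r_dx Dilation radii in pixels.
#' @param pixel_size_um Pixel size; taken from \code{labels} when it is a
#'   \code{cell_label_map}.
#' @return Data frame of cell records: \code{cell_id}, \code{area_px},
#'   \code{area_um2}, \code{f_ryr}, \code{f_dextran},
#'   \code{raw_ryr_density} (percent), \code{class} (factor).
#' @export
classify_cells <- function(labels, ryr_mask, dextran_mask,
                           theta_ryr = 0.15, theta_dx = 0.2,
                           r_ryr = 4, r_dx = 3, pixel_size_um = NULL) {
  if (inherits(labels, "cell_label_map")) {
    pixel_size_um <- pixel_size_um %||% labels$pixel_size_um
    labels <- labels$labels
  }
  pixel_size_um <- pixel_size_um %||% 0.1
  stopifnot(is.logical(ryr_mask), is.logical(dextran_mask))
  assert_same_grid(labels, ryr_mask, "labels and RyR mask")
  assert_same_grid(labels, dextran_mask, "labels and dextran mask")
  n <- max(labels)
  if (n < 1L) return(empty_cell_records())

  ryr_dil <- dilate_mask(ryr_mask, r_ryr)
  dx_dil <- dilate_mask(dextran_mask, r_dx)

  area <- label_counts(labels, n)
  f_ryr <- label_mask_counts(labels, ryr_dil, n) / pmax(area, 1L)
  f_dx <- label_mask_counts(labels, dx_dil, n) / pmax(area, 1L)
  raw_ryr <- 100 * label_mask_counts(labels, ryr_mask, n) / pmax(area, 1L)

  ryr_pos <- f_ryr >= theta_ryr
  dx_pos <- f_dx >= theta_dx
  cls <- ifelse(ryr_pos & !dx_pos, "live",
                ifelse(!ryr_pos & dx_pos, "dead",
                       ifelse(ryr_pos & dx_pos, "double_positive",
                              "double_negative")))
  data.frame(cell_id = seq_len(n),
             area_px = as.integer(area),
             area_um2 = area * pixel_size_um^2,
             f_ryr = f_ryr,
             f_dextran = f_dx,
             raw_ryr_density = raw_ryr,
             class = factor(cls, levels = CELL_CLASSES))
}

empty_cell_records <- function() {
  data.frame(cell_id = integer(0), area_px = integer(0), area_um2 = numeric(0),
             f_ryr = numeric(0), f_dextran = numeric(0),
             raw_ryr_density = numeric(0),
             class = factor(character(0), levels = CELL_CLASSES))
}

#' Per-image summary of RyR/dextran overlap
#'
#' Pools the cell records of one image into the overlap statistics used to
#' report the mutual exclusion of the two stains: the double-positive cell
#' fraction in reference to the union of RyR- and dextran-positive cells,
#' the analogous pixel fraction on the dilated masks restricted to labelled
#' pixels, the mean dilated RyR fraction within dextran-negative and
#' dextran-positive cells (and vice versa), and the Pearson correlation of
#' the raw RyR and dextran intensities over all labelled pixels.
#'
#' @param records Cell records from [classify_cells()].
#' @param labels \code{cell_label_map} or integer label matrix.
#' @param ryr_mask,dextran_mask The undilated binary masks used for
#'   classification.
#' @param ryr_channel,dextran_channel Optional raw intensity matrices for
#'   the Pearson correlation (skipped when missing).
#' @param r_ryr,r_dx Dilation radii, as in [classify_cells()].
#' @return A list of class \code{image_summary}; undefined fractions (empty
#'   union) are \code{NA} and flagged in \code{$flags}.
#' @export
summarize_image <- function(records, labels, ryr_mask, dextran_mask,
                            ryr_channel = NULL, dextran_channel = NULL,
                            r_ryr = 4, r_dx = 3) {
  if (inherits(labels, "cell_label_map")) labels <- labels$labels
  flags <- character(0)
  n_cells <- nrow(records)
  counts <- table(records$class)

  ryr_pos <- records$class %in% c("live", "double_positive")
  dx_pos <- records$class %in% c("dead", "double_positive")
  union_cells <- sum(ryr_pos | dx_pos)
  dp_cell_frac <- if (union_cells > 0) sum(ryr_pos & dx_pos) / union_cells else {
    flags <- c(flags, "empty_cell_union"); NA_real_
  }

  lab_pos <- labels > 0L
  ryr_dil <- dilate_mask(ryr_mask, r_ryr) & lab_pos
  dx_dil <- dilate_mask(dextran_mask, r_dx) & lab_pos
  union_px <- sum(ryr_dil | dx_dil)
  dp_pixel_frac <- if (union_px > 0) sum(ryr_dil & dx_dil) / union_px else {
    flags <- c(flags, "empty_pixel_union"); NA_real_
  }

  mean_or_na <- function(x) if (length(x)) mean(x) else NA_real_
  pearson <- NA_real_
  if (!is.null(ryr_channel) && !is.null(dextran_channel) && any(lab_pos)) {
    pearson <- stats::cor(as.vector(ryr_channel[lab_pos]),
                          as.vector(dextran_channel[lab_pos]))
  }

  structure(list(
    n_cells = n_cells,
    class_counts = counts,
    class_fractions = if (n_cells > 0) counts / n_cells else counts,
    double_positive_cell_fraction = dp_cell_frac,
    double_positive_pixel_fraction = dp_pixel_frac,
    mean_f_ryr_dextran_neg = mean_or_na(records$f_ryr[!dx_pos]),
    mean_f_ryr_dextran_pos = mean_or_na(records$f_ryr[dx_pos]),
    mean_f_dextran_ryr_neg = mean_or_na(records$f_dextran[!ryr_pos]),
    mean_f_dextran_ryr_pos = mean_or_na(records$f_dextran[ryr_pos]),
    pearson_r = pearson,
    flags = flags
  ), class = "image_summary")
}

#' @export
print.image_summary <- function(x, ...) {
  cat(sprintf("image_summary: %d cells\n", x$n_cells))
  print(x$class_counts)
  cat(sprintf("double-positive: %.1f%% of cells, %.1f%% of pixels (union-referenced)\n",
              100 * x$double_positive_cell_fraction,
              100 * x$double_positive_pixel_fraction))
  if (!is.na(x$pearson_r))
    cat(sprintf("Pearson r (RyR vs dextran): %.3f\n", x$pearson_r))
  invisible(x)
}
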