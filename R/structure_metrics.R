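#' Extract the transverse tubular system of each cell
#'
#' The t-system appears as WGA-positive invaginations that interrupt the
#' cell interior. Each cell segment is morphologically closed with a disk of
#' \code{closing_radius_px}; the difference between the closed and the
#' original segment, intersected with the WGA mask, is the cell's t-system.
#' Invaginations wider than twice the closing radius are not recovered.
#'
#' @param labels \code{cell_label_map} or integer label matrix.
#' @param wga_mask Logical WGA mask on the same grid.
#' @param closing_radius_px Disk radius of the closing (default 5 px; must
#'   exceed half the tubule width). Radius 0 yields an empty t-system and a
#'   warning.
#' @return Integer matrix: 0 = no t-system, k = t-system pixel of cell k.
#' @export
extract_t_system <- function(labels, wga_mask, closing_radius_px = 5) {
  if (inherits(labels, "cell_label_map")) labels <- labels$labels
  stopifnot(is.logical(wga_mask))
  assert_same_grid(labels, wga_mask, "labels and WGA mask")
  out <- matrix(0L, nrow(labels), ncol(labels))
  if (closing_radius_px == 0) {
    warning("closing radius 0: empty t-system", call. = FALSE)
    return(out)
  }
  n <- max(labels)
  if (n < 1L) return(out)
  k <- disk_kernel(closing_radius_px)
  pad <- as.integer(ceiling(closing_radius_px)) + 1L
  for (cell in seq_len(n)) {
    cm <- labels == cell
    bb <- mask_bbox(cm, pad)
    if (is.null(bb)) next
    interior <- cm[bb$r0:bb$r1, bb$c0:bb$c1]
    closed <- EBImage::imageData(EBImage::closing(EBImage::Image(interior * 1), k)) > 0
    tsys <- closed & !interior & wga_mask[bb$r0:bb$r1, bb$c0:bb$c1]
    if (any(tsys)) {
      sub <- out[bb$r0:bb$r1, bb$c0:bb$c1]
      sub[tsys] <- cell
      out[bb$r0:bb$r1, bb$c0:bb$c1] <- sub
    }
  }
  out
}

#' T-system geometry of a single cell
#'
#' \code{delta_tt_um} is the mean Euclidean distance (micrometres) from the
#' cell's interior pixels to the nearest t-system pixel, the standard
#' measure of t-tubule coverage; \code{skeleton_density} is the pixel count
#' of the 1-px-thinned t-system divided by the total cell pixels (interior
#' plus t-system).
#'
#' @param interior Logical mask of the cell interior.
#' @param t_mask Logical mask of the cell's t-system, same grid.
#' @param pixel_size_um Pixel size in micrometres.
#' @return List with \code{delta_tt_um} (\code{NA} with
#'   \code{undefined = TRUE} when the t-system is empty) and
#'   \code{skeleton_density}.
#' @export
t_system_metrics <- function(interior, t_mask, pixel_size_um = 0.1) {
  stopifnot(is.logical(interior), is.logical(t_mask), any(interior))
  assert_same_grid(interior, t_mask, "interior and t-system masks")
  total <- sum(interior | t_mask)
  if (!any(t_mask)) {
    return(list(delta_tt_um = NA_real_, skeleton_density = 0,
                undefined = TRUE))
  }
  d <- EBImage::imageData(EBImage::distmap(EBImage::Image(!t_mask))) * pixel_size_um
  skel <- skeletonize(t_mask)
  list(delta_tt_um = mean(d[interior]),
       skeleton_density = sum(skel) / total,
       undefined = FALSE)
}

#' Per-cell t-system metrics table
#'
#' Applies [t_system_metrics()] to every cell of a label map, cropping each
#' cell to its bounding box.
#'
#' @param labels \code{cell_label_map} or integer label matrix.
#' @param t_labels Per-cell t-system label matrix from [extract_t_system()].
#' @param pixel_size_um Pixel size; taken from \code{labels} when available.
#' @return Data frame: \code{cell_id}, \code{delta_tt_um},
#'   \code{skeleton_density}, \code{t_undefined}.
#' @export
t_system_metrics_all <- function(labels, t_labels, pixel_size_um = NULL) {
  if (inherits(labels, "cell_label_map")) {
    pixel_size_um <- pixel_size_um %||% labels$pixel_size_um
    labels <- labels$labels
  }
  pixel_size_um <- pixel_size_um %||% 0.1
  assert_same_grid(labels, t_labels, "label maps")
  n <- max(labels)
  res <- data.frame(cell_id = seq_len(n), delta_tt_um = NA_real_,
                    skeleton_density = 0, t_undefined = TRUE)
  for (cell in seq_len(n)) {
    cm <- labels == cell
    tm <- t_labels == cell
    bb <- mask_bbox(cm | tm, 1L)
    if (is.null(bb)) next
    m <- t_system_metrics(cm[bb$r0:bb$r1, bb$c0:bb$c1],
                          tm[bb$r0:bb$r1, bb$c0:bb$c1], pixel_size_um)
    res$delta_tt_um[cell] <- m$delta_tt_um
    res$skeleton_density[cell] <- m$skeleton_density
    res$t_undefined[cell] <- m$undefined
  }
  res
}

#' Morphological skeleton (thinning to 1-px width)
#'
#' Zhang-Suen iterative thinning with 8-connectivity; both subiterations are
#' applied until stability, with the whole image updated in parallel per
#' subiteration, so the result is deterministic.
#'
#' @param mask Logical matrix.
#' @return Logical matrix of the 1-px-wide skeleton.
#' @export
skeletonize <- function(mask) {
  stopifnot(is.logical(mask))
  p <- mask
  shift <- function(m, dr, dc) {
    h <- nrow(m); w <- ncol(m)
    out <- matrix(FALSE, h, w)
    rs <- max(1L, 1L + dr):min(h, h + dr)
    cs <- max(1L, 1L + dc):min(w, w + dc)
    out[rs, cs] <- m[rs - dr, cs - dc]
    out
  }
  repeat {
    changed <- FALSE
    for (sub in 1:2) {
      # neighbours clockwise from north: P2..P9
      n2 <- shift(p, 1, 0);  n3 <- shift(p, 1, -1)
      n4 <- shift(p, 0, -1); n5 <- shift(p, -1, -1)
      n6 <- shift(p, -1, 0); n7 <- shift(p, -1, 1)
      n8 <- shift(p, 0, 1);  n9 <- shift(p, 1, 1)
      b <- n2 + n3 + n4 + n5 + n6 + n7 + n8 + n9
      a <- (!n2 & n3) + (!n3 & n4) + (!n4 & n5) + (!n5 & n6) +
           (!n6 & n7) + (!n7 & n8) + (!n8 & n9) + (!n9 & n2)
      if (sub == 1L) {
        cond <- p & b >= 2 & b <= 6 & a == 1 & !(n2 & n4 & n6) & !(n4 & n6 & n8)
      } else {
        cond <- p & b >= 2 & b <= 6 & a == 1 & !(n2 & n4 & n8) & !(n2 & n6 & n8)
      }
      if (any(cond)) {
        p[cond] <- FALSE
        changed <- TRUE
      }
    }
    if (!changed) break
  }
  p
}

#' Nucleus morphometry from the DAPI mask
#'
#' Nuclei are 8-connected components of the DAPI mask with area at least
#' \code{min_nucleus_area_um2}. The parent cell is the label holding the
#' majority of the nucleus pixels (0 when the nucleus overlaps no cell,
#' flagged via \code{orphan}). Axes are derived from the eigenvalues of the
#' component's second central moments (equivalent-ellipse convention, semi
#' axis \eqn{= 2\sqrt{\lambda}}); circularity is short axis / long axis.
#'
#' @param dapi_mask Logical DAPI mask.
#' @param labels \code{cell_label_map} or integer label matrix.
#' @param pixel_size_um Pixel size in micrometres.
#' @param min_nucleus_area_um2 Minimum component area (default 10, rejects
#'   speckle).
#' @return Data frame: \code{nucleus_id}, \code{parent_cell_id},
#'   \code{area_um2}, \code{long_axis_um}, \code{short_axis_um},
#'   \code{circularity}, \code{orphan}.
#' @export
nucleus_metrics <- function(dapi_mask, labels, pixel_size_um = NULL,
                            min_nucleus_area_um2 = 10) {
  if (inherits(labels, "cell_label_map")) {
    pixel_size_um <- pixel_size_um %||% labels$pixel_size_um
    labels <- labels$labels
  }
  pixel_size_um <- pixel_size_um %||% 0.1
  stopifnot(is.logical(dapi_mask))
  assert_same_grid(dapi_mask, labels, "DAPI mask and labels")
  comp <- label8(dapi_mask)
  n <- max(comp)
  out <- list()
  for (i in seq_len(n)) {
    idx <- which(comp == i, arr.ind = TRUE)
    area_um2 <- nrow(idx) * pixel_size_um^2
    if (area_um2 < min_nucleus_area_um2) next
    ax <- equivalent_ellipse_axes(idx) * pixel_size_um
    parents <- labels[idx]
    parent <- as.integer(names(which.max(table(parents))))
    out[[length(out) + 1L]] <- data.frame(
      nucleus_id = NA_integer_,
      parent_cell_id = parent,
      area_um2 = area_um2,
      long_axis_um = 2 * ax[1L],      # full axes of the equivalent ellipse
      short_axis_um = 2 * ax[2L],
      circularity = ax[2L] / ax[1L],
      orphan = parent == 0L)
  }
  if (!length(out))
    return(data.frame(nucleus_id = integer(0), parent_cell_id = integer(0),
                      area_um2 = numeric(0), long_axis_um = numeric(0),
                      short_axis_um = numeric(0), circularity = numeric(0),
                      orphan = logical(0)))
  res <- do.call(rbind, out)
  res$nucleus_id <- seq_len(nrow(res))
  res
}

# semi-axes (long, short) in pixels from second central moments
equivalent_ellipse_axes <- function(idx) {
  mu <- colMeans(idx)
  dr <- idx[, 1L] - mu[1L]; dc <- idx[, 2L] - mu[2L]
  n <- nrow(idx)
  cov <- matrix(c(sum(dr * dr), sum(dr * dc), sum(dr * dc), sum(dc * dc)) / n,
                2L, 2L)
  ev <- sort(eigen(cov, symmetric = TRUE, only.values = TRUE)$values,
             decreasing = TRUE)
  2 * sqrt(pmax(ev, 0))
}

#' RyR density and spectral regularity of a cell
#'
#' \code{density_pct} is the percentage of (undilated) RyR-mask-positive
#' pixels within the cell interior. \code{regularity} measures how much of
#' the cell's AC image energy falls into the sarcomeric spatial-frequency
#' band: intensities inside the interior are mean-subtracted (zero outside),
#' the 2D power spectrum is computed, and the power at radial spatial
#' frequencies within \code{band} (default 1/2.5 to 1/1.5 per micrometre,
#' bracketing the z-line period) is divided by the total power excluding the
#' zero-frequency term. A cell with zero AC power scores 0. Cells whose long
#' axis cannot resolve the band (shorter than two periods of the lower band
#' edge) are flagged not evaluable.
#'
#' @param ryr_channel Numeric intensity matrix.
#' @param ryr_mask Logical (undilated) RyR mask.
#' @param interior Logical mask of the cell interior, same grid.
#' @param pixel_size_um Pixel size in micrometres.
#' @param band Numeric (low, high) spatial-frequency band in 1/um.
#' @param method \code{"radial2d"} (default) integrates the 2D spectrum
#'   radially; \code{"axial1d"} projects the intensities onto the cell's
#'   long axis and uses the 1D periodogram.
#' @return List: \code{density_pct}, \code{regularity}, \code{evaluable}.
#' @export
ryr_pattern_metrics <- function(ryr_channel, ryr_mask, interior,
                                pixel_size_um = 0.1,
                                band = c(1 / 2.5, 1 / 1.5),
                                method = c("radial2d", "axial1d")) {
  method <- match.arg(method)
  stopifnot(is.logical(ryr_mask), is.logical(interior), any(interior))
  assert_same_grid(ryr_channel, interior, "channel and interior")
  assert_same_grid(ryr_channel, ryr_mask, "channel and mask")
  density_pct <- 100 * sum(ryr_mask & interior) / sum(interior)

  bb <- mask_bbox(interior, 0L)
  long_axis_um <- max(bb$r1 - bb$r0 + 1L, bb$c1 - bb$c0 + 1L) * pixel_size_um
  if (long_axis_um < 2 / band[1L]) {
    return(list(density_pct = density_pct, regularity = NA_real_,
                evaluable = FALSE))
  }
  ins <- interior[bb$r0:bb$r1, bb$c0:bb$c1]
  x <- ryr_channel[bb$r0:bb$r1, bb$c0:bb$c1]
  reg <- if (method == "radial2d") {
    spectral_band_fraction_2d(x, ins, pixel_size_um, band)
  } else {
    spectral_band_fraction_1d(x, ins, pixel_size_um, band)
  }
  list(density_pct = density_pct, regularity = reg, evaluable = TRUE)
}

spectral_band_fraction_2d <- function(x, ins, px, band) {
  v <- matrix(0, nrow(x), ncol(x))
  v[ins] <- x[ins] - mean(x[ins])
  p <- Mod(stats::fft(v))^2
  h <- nrow(v); w <- ncol(v)
  fr <- fft_freq(h) / px
  fc <- fft_freq(w) / px
  rho <- sqrt(outer(fr^2, fc^2, `+`))
  total <- sum(p) - p[1L, 1L]
  if (total <= 0) return(0)
  sum(p[rho >= band[1L] & rho <= band[2L]]) / total
}

spectral_band_fraction_1d <- function(x, ins, px, band) {
  idx <- which(ins, arr.ind = TRUE)
  ax <- principal_axis(idx)
  u <- idx[, 1L] * ax[1L] + idx[, 2L] * ax[2L]
  bins <- round(u - min(u)) + 1L
  prof <- vapply(split(x[ins], bins), mean, numeric(1))
  prof <- prof - mean(prof)
  p <- Mod(stats::fft(prof))^2
  f <- fft_freq(length(prof)) / px
  total <- sum(p) - p[1L]
  if (total <= 0) return(0)
  sum(p[abs(f) >= band[1L] & abs(f) <= band[2L]]) / total
}

principal_axis <- function(idx) {
  mu <- colMeans(idx)
  dr <- idx[, 1L] - mu[1L]; dc <- idx[, 2L] - mu[2L]
  cov <- matrix(c(sum(dr * dr), sum(dr * dc), sum(dr * dc), sum(dc * dc)),
                2L, 2L) / nrow(idx)
  eigen(cov, symmetric = TRUE)$vectors[, 1L]
}

fft_freq <- function(n) {
  k <- 0:(n - 1L)
  k[k > n / 2] <- k[k > n / 2] - n
  k / n
}

#' Per-cell structural metrics table
#'
#' Convenience wrapper combining [extract_t_system()],
#' [t_system_metrics_all()] and [ryr_pattern_metrics()] for every cell of a
#' label map.
#'
#' @param labels \code{cell_label_map} or integer label matrix.
#' @param wga_mask,ryr_mask Logical masks.
#' @param ryr_channel Raw RyR intensities.
#' @param pixel_size_um Pixel size; taken from \code{labels} when available.
#' @param closing_radius_px Closing radius for t-system extraction.
#' @param band Regularity frequency band, see [ryr_pattern_metrics()].
#' @return Data frame keyed by \code{cell_id} with t-system, density and
#'   regularity columns.
#' @export
structure_metrics_all <- function(labels, wga_mask, ryr_mask, ryr_channel,
                                  pixel_size_um = NULL, closing_radius_px = 5,
                                  band = c(1 / 2.5, 1 / 1.5)) {
  if (inherits(labels, "cell_label_map")) {
    pixel_size_um <- pixel_size_um %||% labels$pixel_size_um
    labels <- labels$labels
  }
  pixel_size_um <- pixel_size_um %||% 0.1
  tl <- extract_t_system(labels, wga_mask, closing_radius_px)
  res <- t_system_metrics_all(labels, tl, pixel_size_um)
  n <- max(labels)
  res$ryr_density_pct <- NA_real_
  res$ryr_regularity <- NA_real_
  res$regularity_evaluable <- FALSE
  for (cell in seq_len(n)) {
    cm <- labels == cell
    bb <- mask_bbox(cm, 1L)
    if (is.null(bb)) next
    sub <- function(m) m[bb$r0:bb$r1, bb$c0:bb$c1]
    pm <- ryr_pattern_metrics(sub(ryr_channel), sub(ryr_mask), sub(cm),
                              pixel_size_um, band)
    res$ryr_density_pct[cell] <- pm$density_pct
    res$ryr_regularity[cell] <- pm$regularity
    res$regularity_evaluable[cell] <- pm$evaluable
  }
  res
}
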