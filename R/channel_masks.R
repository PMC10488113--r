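#' Per-channel threshold configuration
#'
#' Builds the configuration for [local_threshold()]. The threshold is
#' histogram based: a box-mean filter is subtracted from the image and the
#' threshold \eqn{t = c\sigma + m} is computed on the residual, where
#' \eqn{\sigma} is the residual standard deviation and \eqn{m} the residual
#' histogram mode. The multiplier \code{c} defaults to the stain-specific
#' values established for confocal slice scans: 2 for DAPI, 3 for RyR, 1 for
#' WGA, 0.5 for dextran, 2 for SERCA and 4 for lipofuscin.
#'
#' @param channel Stain role, one of \code{"DAPI"}, \code{"RyR"},
#'   \code{"WGA"}, \code{"dextran"}, \code{"SERCA"}, \code{"lipofuscin"};
#'   used only to pick the default \code{c_factor}.
#' @param c_factor Positive threshold multiplier; overrides the channel
#'   default.
#' @param box_size_um Edge length of the mean-filter box in micrometres, or
#'   \code{"whole-image"} (default) to subtract the global mean. Boxes
#'   smaller than 10 um are rejected.
#' @param apply_median Median filter the mask afterwards (radius
#'   \code{median_radius_px})? Default \code{TRUE}.
#' @param median_radius_px Median filter radius in pixels, default 1.
#' @param local_sigma If \code{TRUE}, \eqn{\sigma} is computed per box
#'   window instead of globally on the residual.
#' @param threshold_on Apply the threshold to the \code{"residual"}
#'   (default) or to the \code{"original"} intensities.
#' @return A \code{threshold_config} list.
#' @seealso [local_threshold()]
#' @export
threshold_config <- function(channel = c("RyR", "WGA", "dextran", "DAPI",
                                         "SERCA", "lipofuscin"),
                             c_factor = NULL,
                             box_size_um = "whole-image",
                             apply_median = TRUE,
                             median_radius_px = 1L,
                             local_sigma = FALSE,
                             threshold_on = c("residual", "original")) {
  channel <- match.arg(channel)
  defaults <- c(DAPI = 2, RyR = 3, WGA = 1, dextran = 0.5,
                SERCA = 2, lipofuscin = 4)
  c_factor <- c_factor %||% unname(defaults[channel])
  stopifnot(is.numeric(c_factor), length(c_factor) == 1L, c_factor > 0)
  if (!identical(box_size_um, "whole-image")) {
    stopifnot(is.numeric(box_size_um), length(box_size_um) == 1L)
    if (box_size_um < 10)
      stop("box_size_um must be >= 10 um or \"whole-image\"", call. = FALSE)
  }
  structure(list(channel = channel,
                 c_factor = c_factor,
                 box_size_um = box_size_um,
                 apply_median = isTRUE(apply_median),
                 median_radius_px = as.integer(median_radius_px),
                 local_sigma = isTRUE(local_sigma),
                 threshold_on = match.arg(threshold_on)),
            class = "threshold_config")
}

#' Histogram-based local threshold of a fluorescence channel
#'
#' Subtracts a box-mean (or whole-image mean) from the intensities, computes
#' the threshold \eqn{t = c\sigma + m} on the residual, and returns the
#' binary mask of pixels with residual \eqn{\ge t}. \eqn{m} is the mode of
#' the residual histogram at unit bin width (ties broken toward the smallest
#' bin). Pixels exactly at \eqn{t} count as signal. When
#' \code{config$apply_median} is set the mask is majority filtered with
#' [median_filter_binary()].
#'
#' A constant image has zero residual everywhere, hence \eqn{\sigma = 0},
#' \eqn{m = 0}, \eqn{t = 0} and an all-signal mask; this degenerate case is
#' flagged via the \code{"degenerate"} attribute and a warning.
#'
#' @param channel Numeric intensity matrix.
#' @param config A [threshold_config()].
#' @param pixel_size_um Pixel edge length in micrometres; needed only to
#'   convert \code{box_size_um} to pixels.
#' @return Logical mask with attributes \code{threshold}, \code{sigma},
#'   \code{mode} and \code{degenerate}.
#' @export
local_threshold <- function(channel, config = threshold_config("RyR"),
                            pixel_size_um = 0.1) {
  stopifnot(is.matrix(channel), length(channel) > 0, is.numeric(channel))
  if (!inherits(config, "threshold_config"))
    stop("config must be a threshold_config", call. = FALSE)

  if (identical(config$box_size_um, "whole-image")) {
    bg <- mean(channel)
    residual <- channel - bg
  } else {
    r <- max(1L, as.integer(round(config$box_size_um / pixel_size_um / 2)))
    residual <- channel - box_mean(channel, r)
  }

  m <- residual_mode(residual)
  if (config$local_sigma && !identical(config$box_size_um, "whole-image")) {
    r <- max(1L, as.integer(round(config$box_size_um / pixel_size_um / 2)))
    mu <- box_mean(residual, r)
    sigma <- sqrt(pmax(box_mean(residual^2, r) - mu^2, 0))
  } else {
    sigma <- stats::sd(as.vector(residual))
    if (is.na(sigma)) sigma <- 0
  }
  t_val <- config$c_factor * sigma + m
  target <- if (config$threshold_on == "residual") residual else channel
  mask <- target >= t_val

  degenerate <- isTRUE(all(residual == residual[1L]))
  if (degenerate)
    warning("constant residual: degenerate all-signal mask", call. = FALSE)

  if (config$apply_median && !degenerate)
    mask <- median_filter_binary(mask, config$median_radius_px)

  structure(mask,
            threshold = if (is.matrix(t_val)) NA_real_ else t_val,
            sigma = if (is.matrix(sigma)) NA_real_ else sigma,
            mode = m,
            degenerate = degenerate)
}

# Mode of the residual histogram: integer bins (width 1) on rounded values,
# ties toward the smallest bin value.
residual_mode <- function(residual) {
  v <- round(as.vector(residual))
  tab <- table(v)
  vals <- as.numeric(names(tab))
  vals[order(-as.vector(tab), vals)][1L]
}

#' Remove lipofuscin autofluorescence from a signal mask
#'
#' Lipofuscin granules fluoresce across channels and would otherwise count
#' as stain signal; their binary mask is set-subtracted from the channel
#' mask (\code{mask & !lipofuscin_mask}).
#'
#' @param mask,lipofuscin_mask Logical masks on the same grid.
#' @return Logical mask.
#' @export
subtract_lipofuscin <- function(mask, lipofuscin_mask) {
  stopifnot(is.logical(mask), is.logical(lipofuscin_mask))
  assert_same_grid(mask, lipofuscin_mask, "masks")
  mask & !lipofuscin_mask
}

#' Majority (median) filter of a binary mask
#'
#' Each output pixel is the majority value over the square
#' \eqn{(2r+1)\times(2r+1)} neighbourhood; borders are handled by
#' reflection. For odd windows the majority is always strict, so the filter
#' is deterministic.
#'
#' @param mask Logical matrix.
#' @param radius_px Window radius in pixels (>= 1).
#' @return Logical mask.
#' @export
median_filter_binary <- function(mask, radius_px = 1L) {
  stopifnot(is.logical(mask), radius_px >= 1)
  r <- as.integer(radius_px)
  cnt <- box_sum(mask * 1, r)
  w2 <- (2L * r + 1L)^2
  cnt * 2L > w2
}
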