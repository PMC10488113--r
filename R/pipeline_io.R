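#' Pipeline run configuration
#'
#' Collects every tunable parameter of the analysis pipeline in one object
#' that serialises losslessly to YAML, so a run is fully reproducible from
#' its configuration and seed.
#'
#' @param input Path to a multi-page TIFF, or a [slice_spec()] to simulate
#'   the input.
#' @param channel_map Named integer vector mapping stain roles to TIFF
#'   pages, e.g. \code{c(WGA = 1, RyR = 2, dextran = 3, DAPI = 4)}. Ignored
#'   for simulated input.
#' @param pixel_size_um Pixel size override (required when the file carries
#'   no pixel-size metadata).
#' @param out_dir Output directory.
#' @param c_factors Named numeric per-channel threshold multipliers;
#'   defaults per [threshold_config()].
#' @param box_size_um Mean-filter box size or \code{"whole-image"}.
#' @param theta_ryr,theta_dx Classification thresholds.
#' @param r_ryr,r_dx Dilation radii (pixels).
#' @param min_cell_area_um2,h_min_um Segmentation parameters, see
#'   [segment_cells()].
#' @param closing_radius_px T-system closing radius.
#' @param min_nucleus_area_um2 Nucleus detection floor.
#' @param seed RNG seed (used only for simulated input).
#' @param verbose Print stage progress?
#' @return A \code{run_config} list.
#' @export
run_config <- function(input, channel_map = NULL, pixel_size_um = NULL,
                       out_dir = tempfile("myoslice_run_"),
                       c_factors = NULL, box_size_um = "whole-image",
                       theta_ryr = 0.15, theta_dx = 0.2,
                       r_ryr = 4, r_dx = 3,
                       min_cell_area_um2 = 100, h_min_um = 5.0,
                       closing_radius_px = 5, min_nucleus_area_um2 = 10,
                       seed = 1L, verbose = FALSE) {
  structure(list(input = input, channel_map = channel_map,
                 pixel_size_um = pixel_size_um, out_dir = out_dir,
                 c_factors = c_factors, box_size_um = box_size_um,
                 theta_ryr = theta_ryr, theta_dx = theta_dx,
                 r_ryr = r_ryr, r_dx = r_dx,
                 min_cell_area_um2 = min_cell_area_um2, h_min_um = h_min_um,
                 closing_radius_px = closing_radius_px,
                 min_nucleus_area_um2 = min_nucleus_area_um2,
                 seed = as.integer(seed), verbose = isTRUE(verbose)),
            class = "run_config")
}

#' Read a multi-page TIFF as a multi-channel slice image
#'
#' Pages are mapped to stain roles through \code{channel_map}. The pixel
#' size and channel names are read from the JSON companion file written by
#' [write_multichannel()] (\code{<path>.meta.json}) or taken from the
#' overrides; without either source the call fails.
#'
#' @param path TIFF file path.
#' @param channel_map Named integer vector (role = page index); when
#'   omitted, the channel names from the companion metadata are used.
#' @param pixel_size_um Pixel size override in micrometres.
#' @return A \code{slice_image}.
#' @export
read_multichannel <- function(path, channel_map = NULL, pixel_size_um = NULL) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  pages <- tiff::readTIFF(path, all = TRUE, info = TRUE, as.is = TRUE)
  if (!is.list(pages)) pages <- list(pages)
  meta <- read_slice_metadata(path)
  pixel_size_um <- pixel_size_um %||% meta$pixel_size_um
  if (is.null(pixel_size_um))
    stop("pixel size not in metadata; supply pixel_size_um", call. = FALSE)
  if (is.null(channel_map)) {
    if (is.null(meta$channels))
      stop("no channel names in metadata; supply channel_map", call. = FALSE)
    channel_map <- stats::setNames(seq_along(meta$channels), meta$channels)
  }
  bad <- channel_map[channel_map < 1L | channel_map > length(pages)]
  if (length(bad))
    stop("channel_map page out of range: ", paste(names(bad), collapse = ", "),
         call. = FALSE)
  chan <- lapply(channel_map, function(i) {
    m <- pages[[i]]
    if (length(dim(m)) == 3L) m <- m[, , 1L]
    matrix(as.numeric(m), nrow(m), ncol(m))
  })
  structure(list(channels = chan, pixel_size_um = pixel_size_um),
            class = "slice_image")
}

#' Write a multi-channel slice image as a multi-page 16-bit TIFF
#'
#' One page per channel. Channel names and the physical pixel size go into
#' a JSON companion file (\code{<path>.meta.json}) so that
#' [read_multichannel()] restores the image losslessly (12-bit integer
#' intensities are preserved exactly by the 16-bit encoding).
#'
#' @param image A \code{slice_image}.
#' @param path Output path.
#' @return \code{path}, invisibly.
#' @export
write_multichannel <- function(image, path) {
  stopifnot(inherits(image, "slice_image"))
  pages <- lapply(image$channels, function(m) m / 65535)
  tiff::writeTIFF(pages, path, bits.per.sample = 16L, compression = "none",
                  reduce = FALSE)
  jsonlite::write_json(list(pixel_size_um = image$pixel_size_um,
                            channels = names(image$channels)),
                       metadata_path(path), auto_unbox = TRUE, digits = NA)
  invisible(path)
}

metadata_path <- function(path) paste0(path, ".meta.json")

read_slice_metadata <- function(path) {
  mp <- metadata_path(path)
  if (!file.exists(mp)) return(list(pixel_size_um = NULL, channels = NULL))
  meta <- jsonlite::read_json(mp, simplifyVector = TRUE)
  list(pixel_size_um = meta$pixel_size_um, channels = meta$channels)
}

#' Write a binary mask (8-bit, 0/255) or label map (16-bit) as TIFF
#' @param mask Logical mask or integer label matrix.
#' @param path Output path.
#' @return \code{path}, invisibly.
#' @export
write_mask <- function(mask, path) {
  if (is.logical(mask)) {
    tiff::writeTIFF((mask * 1), path, bits.per.sample = 8L,
                    compression = "none")
  } else {
    tiff::writeTIFF(mask / 65535, path, bits.per.sample = 16L,
                    compression = "none")
  }
  invisible(path)
}

#' Run the full slice-analysis pipeline
#'
#' Executes, in order: per-channel thresholding (with lipofuscin
#' subtraction and median filtering), watershed cell segmentation on the
#' WGA distance map, viability classification, structural metrics, nucleus
#' morphometry and diagnostic accuracy, writing every artifact into
#' \code{config$out_dir}: channel masks and label map (TIFF), per-cell and
#' per-nucleus CSV, per-image summary JSON, accuracy JSON, ROC CSV, a class
#' overlay PNG (live magenta, dead green, double-positive white) and a JSON
#' provenance log with all parameters.
#'
#' @param config A [run_config()].
#' @return Invisibly, a list with the in-memory results (\code{image},
#'   \code{masks}, \code{labels}, \code{records}, \code{summary},
#'   \code{structure}, \code{nuclei}, \code{accuracy}, \code{roc},
#'   \code{paths}).
#' @export
run_pipeline <- function(config) {
  stopifnot(inherits(config, "run_config"))
  dir.create(config$out_dir, showWarnings = FALSE, recursive = TRUE)
  say <- function(...) if (config$verbose) message(sprintf(...))
  warnings_log <- character(0)
  log_warning <- function(w) {
    warnings_log <<- c(warnings_log, conditionMessage(w))
    invokeRestart("muffleWarning")
  }

  truth <- NULL
  if (inherits(config$input, "slice_spec")) {
    say("simulating slice (%d cells)", config$input$n_cells_target)
    sim <- withCallingHandlers(generate_slice(config$input),
                               warning = log_warning)
    image <- sim$image
    truth <- sim$truth
  } else {
    say("reading %s", config$input)
    image <- read_multichannel(config$input, config$channel_map,
                               config$pixel_size_um)
  }
  px <- image$pixel_size_um
  required <- c("WGA", "RyR", "dextran")
  missing <- setdiff(required, names(image$channels))
  if (length(missing))
    stop("missing required channel(s): ", paste(missing, collapse = ", "),
         call. = FALSE)

  say("thresholding channels")
  masks <- list()
  thresholds <- list()
  for (nm in intersect(c("WGA", "RyR", "dextran", "DAPI", "SERCA",
                         "lipofuscin"), names(image$channels))) {
    cfg <- threshold_config(nm, c_factor = config$c_factors[[nm]],
                            box_size_um = config$box_size_um)
    masks[[nm]] <- withCallingHandlers(
      local_threshold(image$channels[[nm]], cfg, px), warning = log_warning)
    thresholds[[nm]] <- attr(masks[[nm]], "threshold")
  }
  if (!is.null(masks$lipofuscin)) {
    for (nm in c("RyR", "dextran", "DAPI"))
      if (!is.null(masks[[nm]]))
        masks[[nm]] <- subtract_lipofuscin(masks[[nm]], masks$lipofuscin)
  }

  say("segmenting cells")
  labels <- withCallingHandlers(
    segment_cells(masks$WGA, px, config$min_cell_area_um2, config$h_min_um),
    warning = log_warning)

  say("classifying %d segments", length(labels$areas_px))
  records <- classify_cells(labels, masks$RyR, masks$dextran,
                            config$theta_ryr, config$theta_dx,
                            config$r_ryr, config$r_dx)
  summary <- summarize_image(records, labels, masks$RyR, masks$dextran,
                             image$channels$RyR, image$channels$dextran,
                             config$r_ryr, config$r_dx)

  say("structural metrics")
  structure_df <- structure_metrics_all(labels, masks$WGA, masks$RyR,
                                        image$channels$RyR, px,
                                        config$closing_radius_px)
  records <- merge(records, structure_df, by = "cell_id", all.x = TRUE,
                   sort = TRUE)

  nuclei <- if (!is.null(masks$DAPI)) {
    nucleus_metrics(masks$DAPI, labels, px, config$min_nucleus_area_um2)
  } else NULL

  accuracy <- accuracy_from_records(records)
  roc <- roc_sweep(records, theta_dx = config$theta_dx)

  # ---- artifacts ----
  paths <- list()
  for (nm in names(masks)) {
    paths[[paste0("mask_", nm)]] <-
      write_mask(structure(as.vector(masks[[nm]]),
                           dim = dim(masks[[nm]])) > 0,
                 file.path(config$out_dir, paste0("mask_", nm, ".tiff")))
  }
  paths$labels <- write_mask(labels$labels,
                             file.path(config$out_dir, "labels.tiff"))
  paths$cells <- file.path(config$out_dir, "cells.csv")
  utils::write.csv(records, paths$cells, row.names = FALSE)
  if (!is.null(nuclei)) {
    paths$nuclei <- file.path(config$out_dir, "nuclei.csv")
    utils::write.csv(nuclei, paths$nuclei, row.names = FALSE)
  }
  paths$summary <- file.path(config$out_dir, "summary.json")
  jsonlite::write_json(summary_to_list(summary), paths$summary,
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  paths$accuracy <- file.path(config$out_dir, "accuracy.json")
  jsonlite::write_json(unclass(accuracy), paths$accuracy, auto_unbox = TRUE,
                       digits = NA, pretty = TRUE)
  paths$roc <- file.path(config$out_dir, "roc.csv")
  utils::write.csv(as.data.frame(roc), paths$roc, row.names = FALSE)
  paths$overlay <- file.path(config$out_dir, "overlay.png")
  write_class_overlay(labels, records, paths$overlay)
  paths$provenance <- file.path(config$out_dir, "provenance.json")
  prov <- list(package = "myoslice",
               version = as.character(utils::packageVersion("myoslice")),
               parameters = config_to_list(config),
               thresholds = thresholds,
               n_cells = nrow(records),
               warnings = warnings_log)
  jsonlite::write_json(prov, paths$provenance, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  paths$config <- file.path(config$out_dir, "config.yaml")
  yaml::write_yaml(config_to_list(config), paths$config)

  invisible(list(image = image, truth = truth, masks = masks,
                 labels = labels, records = records, summary = summary,
                 structure = structure_df, nuclei = nuclei,
                 accuracy = accuracy, roc = roc, paths = paths,
                 warnings = warnings_log))
}

summary_to_list <- function(s) {
  out <- unclass(s)
  out$class_counts <- as.list(stats::setNames(as.integer(s$class_counts),
                                              names(s$class_counts)))
  out$class_fractions <- as.list(stats::setNames(as.numeric(s$class_fractions),
                                                 names(s$class_fractions)))
  out
}

config_to_list <- function(config) {
  out <- unclass(config)
  if (inherits(out$input, "slice_spec")) {
    out$input <- unclass(out$input)
    out$input$class_proportions <- as.list(out$input$class_proportions)
  }
  if (!is.null(out$channel_map)) out$channel_map <- as.list(out$channel_map)
  out
}

#' Class overlay image (live magenta, dead green, double-positive white)
#'
#' @param labels \code{cell_label_map} or integer label matrix.
#' @param records Cell records with \code{cell_id} and \code{class}.
#' @param path Output PNG path.
#' @return \code{path}, invisibly.
#' @export
write_class_overlay <- function(labels, records, path) {
  if (inherits(labels, "cell_label_map")) labels <- labels$labels
  n <- max(labels)
  cols <- matrix(0, max(n, 1L) + 1L, 3L)  # row i+1 = label i; background black
  pal <- c(live = "#FF00FF", dead = "#00CC00", double_positive = "#FFFFFF",
           double_negative = "#3060A0")
  if (nrow(records)) {
    rgb_vals <- t(grDevices::col2rgb(pal[as.character(records$class)]) / 255)
    cols[records$cell_id + 1L, ] <- rgb_vals
  }
  img <- array(0, dim = c(nrow(labels), ncol(labels), 3L))
  for (ch in 1:3)
    img[, , ch] <- matrix(cols[labels + 1L, ch], nrow(labels), ncol(labels))
  png::writePNG(img, path)
  invisible(path)
}
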