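#' Specification of a synthetic myocardial slice image
#'
#' Collects every parameter of the synthetic slice generator
#' [generate_slice()]: field geometry, rod-shaped cell dimensions, the four
#' viability classes and their proportions, striation and t-system
#' parameters, nucleus morphology per class, lipofuscin density, and the
#' acquisition model (background gradient, Poisson-Gaussian noise, 12-bit
#' intensity range).
#'
#' Cells are laid out as capsule-shaped rods aligned to a common fiber
#' direction, as in laminar working myocardium, and separated by a
#' WGA-positive extracellular-matrix gap. Live cells carry striated RyR
#' clusters on z-lines at \code{sarcomere_period_um}; dead cells carry a
#' homogeneous cytosolic dextran fill and no RyR; double-positive cells
#' carry both the fill and RyR clusters jittered by \code{ryr_jitter_um};
#' double-negative cells carry neither signal (stand-ins for non-myocytes).
#' Transverse t-tubules are rendered in the WGA channel as dashed lines on a
#' class-dependent fraction of z-lines.
#'
#' @param image_size_px Integer (height, width) in pixels.
#' @param pixel_size_um Pixel edge length in micrometres (default 0.1, the
#'   resolution of high-magnification confocal tile scans).
#' @param n_cells_target Number of cells to place.
#' @param cell_length_um,cell_width_um Numeric (mean, sd) of rod length and
#'   width in micrometres.
#' @param wga_thickness_um Extracellular-matrix gap between neighbouring
#'   cell interiors (micrometres).
#' @param sarcomere_period_um Z-line spacing (micrometres, default 1.9).
#' @param class_proportions Named numeric simplex over \code{live},
#'   \code{dead}, \code{double_positive}, \code{double_negative}.
#' @param t_system_density_live,t_system_density_dead Fraction of z-lines
#'   carrying a t-tubule in live and dead cells. Double-positive cells use
#'   the dead density, double-negative cells have no t-system.
#' @param ryr_jitter_um Standard deviation of the positional scrambling of
#'   RyR clusters in double-positive cells (micrometres).
#' @param nucleus_area_um2_live,nucleus_area_um2_dead Mean nucleus area per
#'   class (square micrometres).
#' @param nucleus_axis_ratio_live,nucleus_axis_ratio_dead Nucleus short/long
#'   axis ratio per class.
#' @param lipofuscin_density Autofluorescent granules per 100 square
#'   micrometres.
#' @param background_gradient_amplitude Relative amplitude of the linear
#'   background gradient.
#' @param noise_gain Photon gain of the Poisson noise component (intensity
#'   units per photon).
#' @param read_noise_sd Standard deviation of the additive Gaussian read
#'   noise (intensity units).
#' @param fiber_angle_deg Global fiber direction in degrees (from the image
#'   x-axis); per-cell orientation jitters around it.
#' @param fiber_angle_jitter_deg Standard deviation of per-cell orientation
#'   jitter (degrees).
#' @param amplitudes Named list of signal amplitudes (12-bit units):
#'   \code{wga_ecm}, \code{wga_tubule}, \code{ryr}, \code{dextran},
#'   \code{dapi}, \code{lipofuscin}, \code{background}.
#' @param seed RNG seed; identical (spec, seed) pairs reproduce output
#'   bit for bit.
#' @return A \code{slice_spec} list, validated.
#' @export
slice_spec <- function(image_size_px = c(1500L, 1500L),
                       pixel_size_um = 0.1,
                       n_cells_target = 20L,
                       cell_length_um = c(60, 8),
                       cell_width_um = c(18, 2.5),
                       wga_thickness_um = 1.2,
                       sarcomere_period_um = 1.9,
                       class_proportions = c(live = 0.45, dead = 0.45,
                                             double_positive = 0.05,
                                             double_negative = 0.05),
                       t_system_density_live = 0.9,
                       t_system_density_dead = 0.7,
                       ryr_jitter_um = 0.6,
                       nucleus_area_um2_live = 49.4,
                       nucleus_area_um2_dead = 44.0,
                       nucleus_axis_ratio_live = 0.45,
                       nucleus_axis_ratio_dead = 0.60,
                       lipofuscin_density = 0.4,
                       background_gradient_amplitude = 0.2,
                       noise_gain = 4,
                       read_noise_sd = 8,
                       fiber_angle_deg = 8,
                       fiber_angle_jitter_deg = 2.5,
                       amplitudes = list(),
                       seed = 1L) {
  amp_def <- list(wga_ecm = 1800, wga_tubule = 1200, ryr = 1600,
                  dextran = 1000, dapi = 2500, lipofuscin = 3000,
                  background = 90)
  amplitudes <- utils::modifyList(amp_def, amplitudes)
  spec <- list(image_size_px = as.integer(image_size_px),
               pixel_size_um = pixel_size_um,
               n_cells_target = as.integer(n_cells_target),
               cell_length_um = cell_length_um,
               cell_width_um = cell_width_um,
               wga_thickness_um = wga_thickness_um,
               sarcomere_period_um = sarcomere_period_um,
               class_proportions = class_proportions,
               t_system_density_live = t_system_density_live,
               t_system_density_dead = t_system_density_dead,
               ryr_jitter_um = ryr_jitter_um,
               nucleus_area_um2_live = nucleus_area_um2_live,
               nucleus_area_um2_dead = nucleus_area_um2_dead,
               nucleus_axis_ratio_live = nucleus_axis_ratio_live,
               nucleus_axis_ratio_dead = nucleus_axis_ratio_dead,
               lipofuscin_density = lipofuscin_density,
               background_gradient_amplitude = background_gradient_amplitude,
               noise_gain = noise_gain,
               read_noise_sd = read_noise_sd,
               fiber_angle_deg = fiber_angle_deg,
               fiber_angle_jitter_deg = fiber_angle_jitter_deg,
               amplitudes = amplitudes,
               seed = as.integer(seed))
  class(spec) <- "slice_spec"
  validate_slice_spec(spec)
  spec
}

validate_slice_spec <- function(spec) {
  cls <- c("live", "dead", "double_positive", "double_negative")
  p <- spec$class_proportions
  if (!all(cls %in% names(p)))
    stop("class_proportions must name live, dead, double_positive, double_negative",
         call. = FALSE)
  if (abs(sum(p) - 1) > 1e-9)
    stop("class_proportions must sum to 1", call. = FALSE)
  if (any(p < 0)) stop("class_proportions must be non-negative", call. = FALSE)
  stopifnot(length(spec$image_size_px) == 2L, all(spec$image_size_px >= 1L),
            spec$pixel_size_um > 0, spec$n_cells_target >= 0L,
            spec$cell_length_um[1] > 0, spec$cell_width_um[1] > 0,
            spec$wga_thickness_um > 0, spec$sarcomere_period_um > 0,
            spec$t_system_density_live >= 0, spec$t_system_density_live <= 1,
            spec$t_system_density_dead >= 0, spec$t_system_density_dead <= 1,
            spec$ryr_jitter_um >= 0,
            spec$nucleus_area_um2_live > 0, spec$nucleus_area_um2_dead > 0,
            spec$nucleus_axis_ratio_live > 0, spec$nucleus_axis_ratio_live <= 1,
            spec$nucleus_axis_ratio_dead > 0, spec$nucleus_axis_ratio_dead <= 1,
            spec$lipofuscin_density >= 0, spec$noise_gain > 0,
            spec$read_noise_sd >= 0)
  invisible(spec)
}

#' Down-scaled example slice specification
#'
#' A compact fixture used throughout the examples and the validation suite:
#' 0.2 um pixels and moderately sized cell profiles, so that a slice with
#' on the order of one hundred cells stays small enough for routine runs
#' while preserving every structural feature of the generator (striations,
#' t-tubules, nuclei, lipofuscin, noise).
#'
#' @param n_cells Number of cells to place (default 100).
#' @param seed RNG seed.
#' @param ... Further overrides passed to [slice_spec()].
#' @return A \code{slice_spec}.
#' @export
example_slice_spec <- function(n_cells = 100L, seed = 1L, ...) {
  side <- ceiling(sqrt(max(n_cells, 1) / 110) * 1800)
  slice_spec(image_size_px = c(side, side),
             pixel_size_um = 0.2,
             n_cells_target = n_cells,
             cell_length_um = c(40, 5),
             cell_width_um = c(14, 1.5),
             seed = seed,
             ...)
}

CELL_CLASSES <- c("live", "dead", "double_positive", "double_negative")

#' Generate a synthetic multi-channel slice image with ground truth
#'
#' Renders a stained myocardial tissue slice: capsule-shaped myocytes in a
#' staggered, fiber-aligned layout separated by WGA-positive extracellular
#' matrix, with per-class RyR striations, cytosolic dextran fill, dashed
#' transverse tubules in the WGA channel, elliptical DAPI nuclei, sparse
#' lipofuscin granules (bleeding into the RyR and dextran channels), a
#' linear background gradient and Poisson-Gaussian noise, clipped to the
#' 12-bit range [0, 4095].
#'
#' @param spec A [slice_spec()].
#' @return A list with elements
#'   \describe{
#'     \item{image}{\code{slice_image}: named channel matrices (WGA, RyR,
#'       dextran, DAPI, lipofuscin) and \code{pixel_size_um}.}
#'     \item{truth}{\code{slice_truth}: integer \code{label_map} (0 =
#'       ECM/background), \code{cells} data frame (state and geometry),
#'       \code{nuclei} data frame, per-cell \code{t_lines} positions along
#'       the cell axis (micrometres), and a \code{packing_incomplete} flag.}
#'   }
#' @examples
#' sl <- generate_slice(slice_spec(image_size_px = c(400, 400),
#'                                 n_cells_target = 4, seed = 7))
#' table(sl$truth$cells$state)
#' @export
generate_slice <- function(spec) {
  stopifnot(inherits(spec, "slice_spec"))
  validate_slice_spec(spec)
  old_seed <- get0(".Random.seed", envir = globalenv())
  on.exit(if (!is.null(old_seed)) assign(".Random.seed", old_seed, envir = globalenv()))
  set.seed(spec$seed, kind = "Mersenne-Twister", normal.kind = "Inversion",
           sample.kind = "Rejection")

  h <- spec$image_size_px[1]; w <- spec$image_size_px[2]
  px <- spec$pixel_size_um
  amp <- spec$amplitudes

  placement <- place_cells(spec)
  cells <- placement$cells
  label_map <- placement$label_map
  n_cells <- nrow(cells)

  if (spec$n_cells_target > 0L && n_cells == 0L)
    stop("image too small to place any cell", call. = FALSE)

  # states
  if (n_cells > 0L) {
    cells$state <- sample(CELL_CLASSES, n_cells, replace = TRUE,
                          prob = spec$class_proportions[CELL_CLASSES])
  } else {
    cells$state <- character(0)
  }

  chan <- list(WGA = matrix(0, h, w), RyR = matrix(0, h, w),
               dextran = matrix(0, h, w), DAPI = matrix(0, h, w),
               lipofuscin = matrix(0, h, w))

  # ECM: everything outside cell interiors is WGA-positive matrix
  chan$WGA[label_map == 0L] <- amp$wga_ecm

  t_lines <- vector("list", n_cells)
  nuclei <- list()

  for (k in seq_len(n_cells)) {
    cell <- cells[k, ]
    state <- cell$state
    interior <- placement$pixels[[k]]      # 2-col matrix of (row, col)

    zl <- zline_positions(cell, spec)

    # t-tubules (WGA channel, dashed transverse lines)
    t_density <- switch(state,
                        live = spec$t_system_density_live,
                        dead = spec$t_system_density_dead,
                        double_positive = spec$t_system_density_dead,
                        double_negative = 0)
    has_t <- stats::runif(length(zl)) < t_density
    t_lines[[k]] <- zl[has_t]
    for (u in zl[has_t]) {
      dots <- tubule_puncta(cell, u, spec)
      for (j in seq_len(nrow(dots))) {
        idx <- disk_pixels(dots[j, 1L], dots[j, 2L], dots[j, 3L], h, w)
        if (nrow(idx))
          chan$WGA[idx] <- pmax(chan$WGA[idx],
                                amp$wga_tubule * stats::runif(1, 0.7, 1.3))
      }
    }

    # RyR clusters on the z-line lattice
    if (state %in% c("live", "double_positive")) {
      jit <- if (state == "double_positive") spec$ryr_jitter_um else 0
      sig <- if (state == "double_positive") 0.30 else 0.18
      gain <- if (state == "double_positive") 0.8 else 1.0
      chan$RyR <- add_ryr_clusters(chan$RyR, cell, zl, spec,
                                   jitter_um = jit, sigma_um = sig,
                                   amplitude = amp$ryr * gain)
    }

    # cytosolic dextran fill in membrane-permeable cells
    if (state %in% c("dead", "double_positive")) {
      fill <- amp$dextran * stats::runif(1, 0.85, 1.15)
      chan$dextran[interior] <- chan$dextran[interior] + fill
    }

    # nuclei (1 or 2 per cell)
    live_like <- state == "live"
    n_area <- if (live_like) spec$nucleus_area_um2_live else spec$nucleus_area_um2_dead
    n_ratio <- if (live_like) spec$nucleus_axis_ratio_live else spec$nucleus_axis_ratio_dead
    n_nuc <- 1L + stats::rbinom(1L, 1L, 0.3)
    nuc <- place_nuclei(cell, n_nuc, n_area, n_ratio, spec)
    if (nrow(nuc)) {
      nuc$cell_id <- k
      ang <- cell$angle_deg * pi / 180
      nuc$center_r <- cell$center_r + (nuc$u * sin(ang) + nuc$v * cos(ang)) / px
      nuc$center_c <- cell$center_c + (nuc$u * cos(ang) - nuc$v * sin(ang)) / px
      for (j in seq_len(nrow(nuc))) {
        idx <- ellipse_pixels(nuc[j, ], cell, spec, label_map, k)
        if (nrow(idx)) chan$DAPI[idx] <- amp$dapi * stats::runif(1, 0.85, 1.0)
      }
      nuclei[[length(nuclei) + 1L]] <- nuc
    }
  }

  # lipofuscin granules, with autofluorescent bleed-through
  area_um2 <- h * w * px^2
  n_gran <- stats::rpois(1L, spec$lipofuscin_density * area_um2 / 100)
  if (n_gran > 0L) {
    gr <- cbind(r = stats::runif(n_gran, 1, h), c = stats::runif(n_gran, 1, w),
                rad = stats::runif(n_gran, 0.25, 0.6) / px)
    for (g in seq_len(n_gran)) {
      idx <- disk_pixels(gr[g, "r"], gr[g, "c"], gr[g, "rad"], h, w)
      if (!nrow(idx)) next
      chan$lipofuscin[idx] <- pmax(chan$lipofuscin[idx], amp$lipofuscin)
      chan$RyR[idx] <- chan$RyR[idx] + 0.5 * amp$lipofuscin
      chan$dextran[idx] <- chan$dextran[idx] + 0.4 * amp$lipofuscin
    }
  }

  # background level with a linear gradient of random direction, then noise
  theta <- stats::runif(1, 0, 2 * pi)
  proj <- outer(seq_len(h) / h - 0.5, rep(sin(theta), w)) +
          outer(rep(cos(theta), h), seq_len(w) / w - 0.5)
  bgmap <- amp$background * (1 + spec$background_gradient_amplitude * proj)
  for (nm in names(chan)) {
    img <- pmin(pmax(chan[[nm]] + bgmap, 0), 4095)
    noisy <- stats::rpois(length(img), as.vector(img) / spec$noise_gain) * spec$noise_gain +
      stats::rnorm(length(img), 0, spec$read_noise_sd)
    chan[[nm]] <- matrix(pmin(pmax(round(noisy), 0), 4095), h, w)
  }

  nuclei <- if (length(nuclei)) do.call(rbind, nuclei) else
    data.frame(nucleus_id = integer(0), cell_id = integer(0),
               center_r = numeric(0), center_c = numeric(0),
               a_um = numeric(0), b_um = numeric(0), angle_deg = numeric(0))
  if (nrow(nuclei)) nuclei$nucleus_id <- seq_len(nrow(nuclei))
  rownames(nuclei) <- NULL

  image <- structure(list(channels = chan, pixel_size_um = px),
                     class = "slice_image")
  truth <- structure(list(label_map = label_map,
                          cells = cells,
                          nuclei = nuclei,
                          t_lines = t_lines,
                          pixel_size_um = px,
                          packing_incomplete = placement$incomplete),
                     class = "slice_truth")
  if (placement$incomplete)
    warning(sprintf("placed %d of %d requested cells", n_cells,
                    spec$n_cells_target), call. = FALSE)
  list(image = image, truth = truth)
}

# ---- placement ------------------------------------------------------------

# Staggered, fiber-aligned rows of capsules with per-cell jitter; every
# candidate is still checked pixelwise against the occupancy of previously
# accepted cells (with the ECM gap as margin) and rejected on overlap.
place_cells <- function(spec) {
  h <- spec$image_size_px[1]; w <- spec$image_size_px[2]
  px <- spec$pixel_size_um
  label_map <- matrix(0L, h, w)
  cells <- NULL
  pixels <- list()
  n_target <- spec$n_cells_target
  if (n_target == 0L)
    return(list(cells = empty_cells_df(), label_map = label_map,
                pixels = list(), incomplete = FALSE))

  theta0 <- spec$fiber_angle_deg * pi / 180
  gap <- spec$wga_thickness_um
  row_pitch <- spec$cell_width_um[1] + gap
  # row axis: unit vector along fiber; normal: perpendicular
  eu <- c(cos(theta0), sin(theta0))   # (x, y) = (col, row) direction
  ev <- c(-sin(theta0), cos(theta0))
  diag_um <- sqrt((h * px)^2 + (w * px)^2)
  n_rows <- ceiling(diag_um / row_pitch) + 1L
  cx0 <- w * px / 2; cy0 <- h * px / 2

  placed <- 0L
  attempts <- 0L
  max_attempts <- 50L * n_target
  for (ri in seq_len(n_rows)) {
    v_off <- (ri - (n_rows + 1) / 2) * row_pitch
    u <- -diag_um / 2 + stats::runif(1, 0, spec$cell_length_um[1])
    while (u < diag_um / 2 && placed < n_target && attempts < max_attempts) {
      len <- truncnorm1(spec$cell_length_um[1], spec$cell_length_um[2], 0.5)
      wid <- truncnorm1(spec$cell_width_um[1], spec$cell_width_um[2], 0.5)
      ang <- theta0 + stats::rnorm(1, 0, spec$fiber_angle_jitter_deg) * pi / 180
      ucen <- u + len / 2
      cx <- cx0 + ucen * eu[1] + v_off * ev[1]
      cy <- cy0 + ucen * eu[2] + v_off * ev[2]
      cand <- capsule_pixels(cy / px, cx / px, ang, len / px, wid / px, h, w,
                             margin_px = gap / px)
      if (!is.null(cand)) attempts <- attempts + 1L   # in-bounds candidates only
      ok <- !is.null(cand) &&
        nrow(cand$inner) * px^2 >= 0.9 * capsule_area(len, wid) &&
        all(label_map[cand$outer] == 0L)
      if (ok) {
        placed <- placed + 1L
        label_map[cand$inner] <- placed
        pixels[[placed]] <- cand$inner
        cells <- rbind(cells, data.frame(
          cell_id = placed, center_r = cy / px, center_c = cx / px,
          angle_deg = ang * 180 / pi, length_um = len, width_um = wid,
          area_px = nrow(cand$inner)))
        u <- u + len + gap + abs(stats::rnorm(1, 0, 0.5))
      } else {
        u <- u + stats::runif(1, 1, 4)
      }
    }
    if (placed >= n_target) break
  }
  if (is.null(cells)) cells <- empty_cells_df()
  list(cells = cells, label_map = label_map, pixels = pixels,
       incomplete = placed < n_target)
}

empty_cells_df <- function() {
  data.frame(cell_id = integer(0), center_r = numeric(0), center_c = numeric(0),
             angle_deg = numeric(0), length_um = numeric(0),
             width_um = numeric(0), area_px = integer(0))
}

truncnorm1 <- function(mean, sd, min_frac) {
  repeat {
    x <- stats::rnorm(1, mean, sd)
    if (x >= min_frac * mean) return(x)
  }
}

capsule_area <- function(len, wid) {
  r <- wid / 2
  (len - wid) * wid + pi * r^2
}

# Pixels of a capsule (rounded rod). Returns NULL if the outer capsule
# (inner + margin) does not fit fully inside the image.
capsule_pixels <- function(r0, c0, angle, len_px, wid_px, h, w, margin_px = 0) {
  s <- max(len_px / 2 - wid_px / 2, 0)
  rad_o <- wid_px / 2 + margin_px
  ext <- len_px / 2 + margin_px + 1
  rr <- floor(r0 - ext):ceiling(r0 + ext)
  cc <- floor(c0 - ext):ceiling(c0 + ext)
  if (min(rr) < 1L || max(rr) > h || min(cc) < 1L || max(cc) > w) return(NULL)
  ca <- cos(angle); sa <- sin(angle)
  dr <- rr - r0; dc <- cc - c0
  # u along the cell axis, v across; x = col, y = row
  u <- outer(dr, dc, function(y, x) x * ca + y * sa)
  v <- outer(dr, dc, function(y, x) -x * sa + y * ca)
  du <- pmax(abs(u) - s, 0)
  d2 <- du^2 + v^2
  inner <- which(d2 <= (wid_px / 2)^2, arr.ind = TRUE)
  outer_ <- which(d2 <= rad_o^2, arr.ind = TRUE)
  to_global <- function(m) cbind(rr[m[, 1L]], cc[m[, 2L]])
  list(inner = to_global(inner), outer = to_global(outer_))
}

# z-line positions along the cell axis (cell-centred coordinates, um)
zline_positions <- function(cell, spec) {
  per <- spec$sarcomere_period_um
  half <- cell$length_um / 2 - cell$width_um / 2
  if (half < per) return(numeric(0))
  phase <- stats::runif(1, 0, per)
  zl <- seq(-half, half, by = per) + phase
  zl[zl <= half]
}

# One transverse tubule rendered as a row of puncta (dot centres and radii
# in pixel units), the appearance of the t-system in 2D confocal sections.
tubule_puncta <- function(cell, u, spec) {
  px <- spec$pixel_size_um
  hw <- cell$width_um / 2 - 0.6
  if (hw <= 0) return(matrix(numeric(0), 0, 3))
  spacing <- 0.75                         # punctum spacing along the row, um
  phase <- stats::runif(1, 0, spacing)
  vs <- seq(-hw + phase, hw, by = spacing)
  if (!length(vs)) return(matrix(numeric(0), 0, 3))
  ang <- cell$angle_deg * pi / 180
  ca <- cos(ang); sa <- sin(ang)
  rr <- cell$center_r + (u * sa + vs * ca) / px
  cc <- cell$center_c + (u * ca - vs * sa) / px
  rad <- stats::runif(length(vs), 0.18, 0.26) / px  # apparent radius, PSF blurred
  cbind(rr, cc, rad)
}

# accumulate Gaussian RyR clusters on the z-line lattice of one cell
add_ryr_clusters <- function(img, cell, zl, spec, jitter_um, sigma_um,
                             amplitude) {
  if (!length(zl)) return(img)
  px <- spec$pixel_size_um
  hw <- cell$width_um / 2 - 0.7
  if (hw <= 0) return(img)
  lat <- 0.8                                  # lateral cluster spacing, um
  vphase <- stats::runif(1, 0, lat)
  vs <- seq(-hw + vphase, hw, by = lat)
  centers <- expand.grid(u = zl, v = vs)
  n <- nrow(centers)
  if (jitter_um > 0) {
    centers$u <- centers$u + stats::rnorm(n, 0, jitter_um)
    centers$v <- centers$v + stats::rnorm(n, 0, jitter_um)
  }
  amps <- amplitude * stats::runif(n, 0.7, 1.3)
  ang <- cell$angle_deg * pi / 180
  ca <- cos(ang); sa <- sin(ang)
  rs <- cell$center_r + (centers$u * sa + centers$v * ca) / px
  cs <- cell$center_c + (centers$u * ca - centers$v * sa) / px
  sig_px <- sigma_um / px
  half <- ceiling(3 * sig_px)
  o <- -half:half
  h <- nrow(img); w <- ncol(img)
  for (i in seq_len(n)) {
    r0 <- round(rs[i]); c0 <- round(cs[i])
    rr <- r0 + o; cc <- c0 + o
    rok <- rr >= 1L & rr <= h; cok <- cc >= 1L & cc <= w
    if (!any(rok) || !any(cok)) next
    gr <- exp(-((rr[rok] - rs[i])^2) / (2 * sig_px^2))
    gc <- exp(-((cc[cok] - cs[i])^2) / (2 * sig_px^2))
    img[rr[rok], cc[cok]] <- img[rr[rok], cc[cok]] + amps[i] * outer(gr, gc)
  }
  img
}

place_nuclei <- function(cell, n_nuc, area_um2, axis_ratio, spec) {
  a <- sqrt(area_um2 / (pi * axis_ratio))   # long semi-axis, um
  b <- axis_ratio * a
  half_u <- cell$length_um / 2 - cell$width_um / 2 - a - 0.5
  half_v <- max(cell$width_um / 2 - b - 0.8, 0)
  if (half_u <= 0) return(data.frame())
  us <- if (n_nuc == 1L) stats::runif(1, -half_u, half_u) else
    c(stats::runif(1, -half_u, -0.1 * half_u), stats::runif(1, 0.1 * half_u, half_u))
  data.frame(nucleus_id = NA_integer_, cell_id = NA_integer_,
             u = us, v = stats::runif(n_nuc, -half_v, half_v),
             a_um = a * stats::runif(n_nuc, 0.9, 1.1),
             b_um = b * stats::runif(n_nuc, 0.9, 1.1),
             angle_deg = cell$angle_deg)
}

# pixels of a nucleus ellipse, clipped to the parent cell's label
ellipse_pixels <- function(nuc, cell, spec, label_map, k) {
  px <- spec$pixel_size_um
  ang <- cell$angle_deg * pi / 180
  ca <- cos(ang); sa <- sin(ang)
  r0 <- nuc$center_r
  c0 <- nuc$center_c
  ext <- nuc$a_um / px + 2
  h <- nrow(label_map); w <- ncol(label_map)
  rr <- max(1L, floor(r0 - ext)):min(h, ceiling(r0 + ext))
  cc <- max(1L, floor(c0 - ext)):min(w, ceiling(c0 + ext))
  dr <- (rr - r0) * px; dc <- (cc - c0) * px
  u <- outer(dr, dc, function(y, x) x * ca + y * sa)
  v <- outer(dr, dc, function(y, x) -x * sa + y * ca)
  ins <- (u / nuc$a_um)^2 + (v / nuc$b_um)^2 <= 1
  idx <- which(ins, arr.ind = TRUE)
  idx <- cbind(rr[idx[, 1L]], cc[idx[, 2L]])
  idx[label_map[idx] == k, , drop = FALSE]
}

disk_pixels <- function(r0, c0, rad_px, h, w) {
  rr <- max(1L, floor(r0 - rad_px)):min(h, ceiling(r0 + rad_px))
  cc <- max(1L, floor(c0 - rad_px)):min(w, ceiling(c0 + rad_px))
  d2 <- outer((rr - r0)^2, (cc - c0)^2, `+`)
  idx <- which(d2 <= rad_px^2, arr.ind = TRUE)
  cbind(rr[idx[, 1L]], cc[idx[, 2L]])
}

#' Synthetic contraction-force dataset
#'
#' Draws per-slice living-cell fractions uniformly on [0, 1] and generates
#' contraction forces from a linear model
#' \eqn{F = \mathrm{intercept} + \mathrm{slope} \cdot f + \epsilon},
#' \eqn{\epsilon \sim N(0, \mathrm{noise\_sd}^2)}; the stand-in for slice
#' force measurements used to exercise [force_regression()].
#'
#' @param n_slices Number of slices (>= 3).
#' @param intercept,slope Regression parameters (micronewtons; slope per
#'   unit living fraction).
#' @param noise_sd Gaussian noise standard deviation (micronewtons, >= 0).
#' @param seed RNG seed.
#' @return Data frame with columns \code{living_fraction} and
#'   \code{force_uN}.
#' @export
generate_force_dataset <- function(n_slices, intercept = 0, slope = 3500,
                                   noise_sd = 400, seed = 1L) {
  if (n_slices < 3) stop("n_slices must be >= 3", call. = FALSE)
  if (noise_sd < 0) stop("noise_sd must be >= 0", call. = FALSE)
  old_seed <- get0(".Random.seed", envir = globalenv())
  on.exit(if (!is.null(old_seed)) assign(".Random.seed", old_seed, envir = globalenv()))
  set.seed(seed, kind = "Mersenne-Twister", normal.kind = "Inversion",
           sample.kind = "Rejection")
  f <- stats::runif(n_slices)
  data.frame(living_fraction = f,
             force_uN = intercept + slope * f + stats::rnorm(n_slices, 0, noise_sd))
}
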