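# Independent brute-force oracles used to validate the image primitives.

# Direct evaluation of the histogram threshold t = c*sigma + m on the
# whole-image residual, without any of the package's helper machinery.
oracle_local_threshold <- function(img, c_factor) {
  res <- img - mean(img)
  sigma <- stats::sd(as.vector(res))
  v <- round(as.vector(res))
  tab <- table(v)
  vals <- as.numeric(names(tab))
  cnt <- as.vector(tab)
  m <- vals[order(-cnt, vals)][1L]
  res >= c_factor * sigma + m
}

# O(N^2) all-pairs Euclidean distance to the nearest TRUE pixel
oracle_distance_map <- function(mask, pixel_size_um) {
  pos <- which(mask, arr.ind = TRUE)
  out <- matrix(NA_real_, nrow(mask), ncol(mask))
  for (r in seq_len(nrow(mask))) {
    for (cc in seq_len(ncol(mask))) {
      out[r, cc] <- sqrt(min((pos[, 1L] - r)^2 + (pos[, 2L] - cc)^2))
    }
  }
  out * pixel_size_um
}

# Majority filter by explicit neighbourhood counting with reflected borders
oracle_median_binary <- function(mask, r) {
  h <- nrow(mask); wd <- ncol(mask)
  refl <- function(i, n) {
    i <- ifelse(i < 1L, 1L - i, i)
    ifelse(i > n, 2L * n + 1L - i, i)
  }
  out <- mask
  for (i in seq_len(h)) {
    for (j in seq_len(wd)) {
      cnt <- 0L
      for (di in -r:r) for (dj in -r:r) {
        cnt <- cnt + mask[refl(i + di, h), refl(j + dj, wd)]
      }
      out[i, j] <- cnt * 2L > (2L * r + 1L)^2
    }
  }
  out
}

# Rectangular cell crossed by transverse WGA lines, built by hand
make_lined_cell <- function(n_rows = 500, n_cols = 100, period_px = 20,
                            line_width = 2, first = 10) {
  interior <- matrix(TRUE, n_rows, n_cols)
  wga <- matrix(FALSE, n_rows, n_cols)
  rows <- seq(first, n_rows, by = period_px)
  for (r in rows) {
    rr <- r:min(r + line_width - 1L, n_rows)
    wga[rr, ] <- TRUE
    interior[rr, ] <- FALSE
  }
  list(interior = interior, wga = wga, line_rows = rows)
}

# Rectangular striated test cell: interior mask plus an intensity image of
# Gaussian clusters on a z-line lattice, optionally jittered. Rendered with
# plain loops, independent of the package's generator.
make_striated_cell <- function(length_um = 50, width_um = 20,
                               period_um = 2.0, lateral_um = 0.8,
                               sigma_um = 0.2, jitter_um = 0,
                               pixel_size_um = 0.1, pad_px = 5L,
                               seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  nl <- round(length_um / pixel_size_um)
  nw <- round(width_um / pixel_size_um)
  h <- nw + 2L * pad_px; w <- nl + 2L * pad_px
  interior <- matrix(FALSE, h, w)
  interior[pad_px + seq_len(nw), pad_px + seq_len(nl)] <- TRUE
  img <- matrix(0, h, w)
  us <- seq(period_um / 2, length_um - period_um / 2, by = period_um)
  vs <- seq(lateral_um / 2, width_um - lateral_um / 2, by = lateral_um)
  centers <- expand.grid(u = us, v = vs)
  if (jitter_um > 0) {
    centers$u <- centers$u + rnorm(nrow(centers), 0, jitter_um)
    centers$v <- centers$v + rnorm(nrow(centers), 0, jitter_um)
  }
  sig <- sigma_um / pixel_size_um
  for (i in seq_len(nrow(centers))) {
    c0 <- pad_px + centers$u[i] / pixel_size_um
    r0 <- pad_px + centers$v[i] / pixel_size_um
    if (r0 + 3 * sig < 1 || r0 - 3 * sig > h ||
        c0 + 3 * sig < 1 || c0 - 3 * sig > w) next
    rr <- max(1, floor(r0 - 3 * sig)):min(h, ceiling(r0 + 3 * sig))
    cc <- max(1, floor(c0 - 3 * sig)):min(w, ceiling(c0 + 3 * sig))
    img[rr, cc] <- img[rr, cc] +
      1000 * exp(-outer((rr - r0)^2, (cc - c0)^2, `+`) / (2 * sig^2))
  }
  list(img = img, interior = interior)
}
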