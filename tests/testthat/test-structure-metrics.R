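test_that("t-system extraction recovers intracellular WGA by closing", {
  cell <- make_lined_cell(n_rows = 120, n_cols = 40, period_px = 30,
                          line_width = 2)
  labels <- matrix(0L, 120, 40)
  labels[cell$interior] <- 1L
  tl <- extract_t_system(labels, cell$wga, closing_radius_px = 5)
  # recovered t-system equals the in-cell line pixels (away from cell ends,
  # closing cannot reach line pixels protruding past the rounded segment)
  expect_true(all(tl[tl > 0L] == 1L))
  inner_lines <- cell$wga
  inner_lines[c(1:10, 111:120), ] <- FALSE
  got <- tl > 0L
  expect_gte(sum(got & inner_lines) / sum(inner_lines), 0.95)
  # no intracellular WGA -> empty t-system
  tl0 <- extract_t_system(labels, matrix(FALSE, 120, 40), 5)
  expect_true(all(tl0 == 0L))
  # closing radius 0 is degenerate
  expect_warning(tl00 <- extract_t_system(labels, cell$wga, 0), "radius 0")
  expect_true(all(tl00 == 0L))
})

test_that("an inclusion wider than twice the closing radius is not recovered", {
  labels <- matrix(0L, 60, 60)
  labels[10:50, 10:50] <- 1L
  wga <- matrix(FALSE, 60, 60)
  wga[25:40, 10:50] <- TRUE       # 16 px wide band, closing radius 5
  labels[wga] <- 0L
  tl <- extract_t_system(labels, wga, closing_radius_px = 5)
  expect_lt(sum(tl > 0L) / sum(wga), 0.5)
})

test_that("delta TT matches the closed form for parallel t-lines", {
  # lines every 2.0 um (20 px at 0.1 um): mean distance = spacing / 4
  cell <- make_lined_cell(n_rows = 1000, n_cols = 60, period_px = 20,
                          line_width = 1)
  m <- t_system_metrics(cell$interior, cell$wga, 0.1)
  expect_equal(m$delta_tt_um, 0.5, tolerance = 0.1)  # 0.50 +/- 0.05
  expect_lt(abs(m$delta_tt_um - 0.5), 0.05)
  # doubling the line density halves the distance, monotonically
  cell2 <- make_lined_cell(n_rows = 1000, n_cols = 60, period_px = 10,
                           line_width = 1)
  m2 <- t_system_metrics(cell2$interior, cell2$wga, 0.1)
  expect_lt(m2$delta_tt_um, m$delta_tt_um)
  expect_lt(abs(m2$delta_tt_um - 0.25), 0.05)
  # saturated t-system: distance 0 everywhere
  full <- matrix(TRUE, 20, 20)
  expect_equal(t_system_metrics(full, full, 0.1)$delta_tt_um, 0)
  # empty t-system flagged undefined
  e <- t_system_metrics(full, matrix(FALSE, 20, 20), 0.1)
  expect_true(e$undefined)
  expect_true(is.na(e$delta_tt_um))
  expect_equal(e$skeleton_density, 0)
})

test_that("skeletonization thins lines to unit width and preserves length", {
  m <- matrix(FALSE, 20, 120)
  m[10, 10:110] <- TRUE          # 101 px line
  sk <- skeletonize(m)
  expect_lte(abs(sum(sk) - 101), 2)
  # thickened versions reduce to (almost) the same skeleton size
  for (wd in 2:3) {
    m2 <- matrix(FALSE, 20, 120)
    m2[10:(9 + wd), 10:110] <- TRUE
    sk2 <- skeletonize(m2)
    expect_lte(abs(sum(sk2) - sum(sk)) / sum(sk), 0.05)
  }
})

test_that("nucleus morphometry matches analytic disks and ellipses", {
  px <- 0.1
  h <- 80; w <- 80
  o_r <- matrix(rep(1:h, w), h, w); o_c <- matrix(rep(1:w, each = h), h, w)
  disk <- (o_r - 40.5)^2 + (o_c - 40.5)^2 <= (2.0 / px)^2
  labels <- matrix(1L, h, w)
  nm <- nucleus_metrics(disk, labels, px)
  expect_equal(nrow(nm), 1)
  expect_lt(abs(nm$area_um2 - 4 * pi) / (4 * pi), 0.03)
  expect_gte(nm$circularity, 0.97)
  expect_equal(nm$parent_cell_id, 1L)

  # 4 x 2 um ellipse at several orientations: circularity 0.5, rotation-stable
  circ <- vapply(c(0, 20, 45, 77), function(deg) {
    th <- deg * pi / 180
    u <- (o_c - 40.5) * cos(th) + (o_r - 40.5) * sin(th)
    v <- -(o_c - 40.5) * sin(th) + (o_r - 40.5) * cos(th)
    ell <- (u / (2 / px))^2 + (v / (1 / px))^2 <= 1
    nucleus_metrics(ell, labels, px, min_nucleus_area_um2 = 5)$circularity
  }, numeric(1))
  expect_true(all(abs(circ - 0.5) <= 0.02))
  expect_lt(max(circ) - min(circ), 0.02 * mean(circ))
})

test_that("two nuclei in one cell yield two records with the same parent", {
  labels <- matrix(0L, 60, 60); labels[5:55, 5:55] <- 1L
  dapi <- matrix(FALSE, 60, 60)
  dapi[10:25, 10:25] <- TRUE
  dapi[35:50, 35:50] <- TRUE
  nm <- nucleus_metrics(dapi, labels, 0.5)
  expect_equal(nrow(nm), 2)
  expect_equal(nm$parent_cell_id, c(1L, 1L))
  # a nucleus overlapping no cell is kept but flagged orphan
  nm2 <- nucleus_metrics(dapi, matrix(0L, 60, 60), 0.5)
  expect_true(all(nm2$orphan))
})

test_that("spectral regularity separates gratings, noise and jitter", {
  px <- 0.1
  # cosine grating at 2.0 um period filling a 50 x 20 um cell
  n_r <- 200; n_c <- 500
  interior <- matrix(TRUE, n_r, n_c)
  grating <- matrix(rep(500 + 400 * cos(2 * pi * (1:n_c) * px / 2.0),
                        each = n_r), n_r, n_c)
  m <- ryr_pattern_metrics(grating, interior, interior, px)
  expect_gte(m$regularity, 0.9)
  # constant image: zero AC power, regularity 0
  m0 <- ryr_pattern_metrics(matrix(300, n_r, n_c), interior, interior, px)
  expect_equal(m0$regularity, 0)
  # affine intensity rescaling leaves regularity unchanged
  m_af <- ryr_pattern_metrics(3.7 * grating + 123, interior, interior, px)
  expect_equal(m_af$regularity, m$regularity, tolerance = 1e-10)
  # too-small cell is flagged not evaluable
  small <- matrix(TRUE, 30, 30)
  ms <- ryr_pattern_metrics(matrix(1, 30, 30), small, small, px)
  expect_false(ms$evaluable)
  expect_true(is.na(ms$regularity))
})

test_that("jittered cluster lattices score below matched regular ones", {
  worse <- logical(20)
  for (s in 1:20) {
    reg <- make_striated_cell(jitter_um = 0, seed = s)
    jit <- make_striated_cell(jitter_um = 1.0, seed = s)
    r_reg <- ryr_pattern_metrics(reg$img, reg$interior, reg$interior, 0.1)
    r_jit <- ryr_pattern_metrics(jit$img, jit$interior, jit$interior, 0.1)
    worse[s] <- r_jit$regularity < r_reg$regularity
  }
  bt <- binom.test(sum(worse), length(worse), alternative = "greater")
  expect_lt(bt$p.value, 0.01)
})

test_that("density is the undilated positive fraction within the cell", {
  interior <- matrix(TRUE, 60, 60)
  mask <- matrix(FALSE, 60, 60); mask[1:6, ] <- TRUE  # 10% of pixels
  m <- ryr_pattern_metrics(matrix(0, 60, 60), mask, interior, 0.1)
  expect_equal(m$density_pct, 10)
})

test_that("structural metrics order the viability classes as expected", {
  an <- analysis_200()
  sm <- cached("sm200", structure_metrics_all(
    an$labels, an$masks$WGA, an$masks$RyR,
    an$slice$image$channels$RyR))
  st <- an$truth_state
  reg <- split(sm$ryr_regularity, st)
  den <- split(sm$ryr_density_pct, st)
  expect_gt(mean(reg$live, na.rm = TRUE),
            mean(reg$double_positive, na.rm = TRUE))
  expect_gt(mean(den$double_positive, na.rm = TRUE),
            mean(den$dead, na.rm = TRUE))
  # adding t-lines reduces delta TT: live cells (dense t-system) vs dead
  tt <- split(sm$delta_tt_um, st)
  expect_lt(mean(tt$live, na.rm = TRUE), mean(tt$dead, na.rm = TRUE))
})
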