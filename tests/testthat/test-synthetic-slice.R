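test_that("slice spec validation rejects inconsistent parameters", {
  expect_error(slice_spec(class_proportions = c(live = 0.6, dead = 0.6,
                                                double_positive = 0,
                                                double_negative = 0)),
               "sum to 1")
  expect_error(slice_spec(pixel_size_um = 0), "pixel_size_um")
  expect_error(slice_spec(cell_length_um = c(-5, 1)))
})

test_that("an image too small for a single cell fails explicitly", {
  spec <- slice_spec(image_size_px = c(40, 40), n_cells_target = 2, seed = 1)
  expect_error(generate_slice(spec), "too small")
})

test_that("a zero-cell spec yields background-only channels and empty truth", {
  sl <- generate_slice(slice_spec(image_size_px = c(120, 120),
                                  n_cells_target = 0, lipofuscin_density = 0,
                                  seed = 5))
  expect_true(all(sl$truth$label_map == 0L))
  expect_equal(nrow(sl$truth$cells), 0)
  amp <- slice_spec()$amplitudes$background
  for (nm in c("WGA", "RyR", "dextran", "DAPI")) {
    if (nm == "WGA") next  # ECM fills a cell-free field
    expect_lt(mean(sl$image$channels[[nm]]), amp * 1.5)
  }
})

test_that("identical spec and seed reproduce the slice bit for bit", {
  spec <- slice_spec(image_size_px = c(300, 300), n_cells_target = 3,
                     cell_length_um = c(20, 2), cell_width_um = c(8, 1),
                     seed = 99)
  a <- suppressWarnings(generate_slice(spec))  # tiny field: packing warns
  b <- suppressWarnings(generate_slice(spec))
  expect_identical(a$image$channels, b$image$channels)
  expect_identical(a$truth$label_map, b$truth$label_map)
  expect_identical(a$truth$cells, b$truth$cells)
})

test_that("realized class proportions track the requested simplex", {
  sl <- fixture_slice_excl()   # 200 cells at 50/50 live/dead
  frac_live <- mean(sl$truth$cells$state == "live")
  expect_lt(abs(frac_live - 0.5), 0.10)  # 99% binomial interval at n=200
})

test_that("live-cell RyR striations repeat at the sarcomere period", {
  an <- analysis_100()
  sl <- an$slice
  px <- sl$image$pixel_size_um
  period_px <- sl$truth$cells$length_um[1] # placeholder, replaced below
  period_px <- 1.9 / px
  live <- which(sl$truth$cells$state == "live")
  checked <- 0
  hits <- 0
  for (k in head(live, 5)) {
    cell <- sl$truth$cells[k, ]
    idx <- which(sl$truth$label_map == k, arr.ind = TRUE)
    ang <- cell$angle_deg * pi / 180
    u <- (idx[, 2] - cell$center_c) * cos(ang) + (idx[, 1] - cell$center_r) * sin(ang)
    bins <- round(u - min(u)) + 1L
    prof <- vapply(split(sl$image$channels$RyR[idx], bins), mean, numeric(1))
    ac <- stats::acf(prof, lag.max = round(1.6 * period_px), plot = FALSE)$acf[-1]
    lo <- round(0.5 * period_px)
    peak_lag <- lo - 1 + which.max(ac[lo:length(ac)])
    checked <- checked + 1
    if (abs(peak_lag - period_px) <= 1) hits <- hits + 1
  }
  expect_gte(hits, checked - 1)   # allow one short/irregular profile
})

test_that("dead cells carry no RyR signal above background", {
  an <- analysis_100()
  sl <- an$slice
  ryr <- sl$image$channels$RyR
  bg <- ryr[sl$truth$label_map == 0L]
  thr <- mean(bg) + 2 * sd(bg)
  dead <- which(sl$truth$cells$state == "dead")
  means <- vapply(dead, function(k) mean(ryr[sl$truth$label_map == k]),
                  numeric(1))
  expect_true(all(means <= thr))
})

test_that("every nucleus lies inside its parent cell's label", {
  sl <- fixture_slice_100()
  nuc <- sl$truth$nuclei
  expect_gt(nrow(nuc), 0)
  at_center <- sl$truth$label_map[cbind(round(nuc$center_r),
                                        round(nuc$center_c))]
  expect_equal(at_center, nuc$cell_id)
  # and the rendered DAPI signal stays within cells
  px <- sl$image$pixel_size_um
  dapi <- local_threshold(sl$image$channels$DAPI, threshold_config("DAPI"), px)
  expect_gt(mean(sl$truth$label_map[which(dapi)] > 0L), 0.95)
})

test_that("force dataset follows the requested linear model", {
  d <- generate_force_dataset(10, intercept = 0, slope = 1000, noise_sd = 0,
                              seed = 4)
  fit <- force_regression(d$living_fraction, d$force_uN)
  expect_equal(fit$slope, 1000, tolerance = 1e-10)
  expect_equal(fit$r_squared, 1, tolerance = 1e-12)
  expect_error(generate_force_dataset(2, 0, 1, 1), "n_slices")
  expect_silent(generate_force_dataset(3, 0, 1, 1))
  # Monte-Carlo slope recovery
  slopes <- vapply(1:200, function(s) {
    d <- generate_force_dataset(12, 500, 3500, 400, seed = s)
    force_regression(d$living_fraction, d$force_uN)$slope
  }, numeric(1))
  se <- sd(slopes) / sqrt(length(slopes))
  expect_lt(abs(mean(slopes) - 3500), 2 * se + 1e-9)
})
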