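# Shared synthetic fixtures, generated once per test run and cached so that
# several test files can reuse the expensive slices.

.fixture_cache <- new.env(parent = emptyenv())

CELL_CLASSES_test <- function() {
  c("live", "dead", "double_positive", "double_negative")
}

cached <- function(key, expr) {
  if (!exists(key, envir = .fixture_cache)) {
    assign(key, force(expr), envir = .fixture_cache)
  }
  get(key, envir = .fixture_cache)
}

# ~100-cell slice with the default class mixture (segmentation fixture)
fixture_slice_100 <- function() {
  cached("slice100", suppressWarnings(
    generate_slice(example_slice_spec(n_cells = 100, seed = 1))))
}

# 200-cell slice, default class mixture (classification fixture)
fixture_slice_200 <- function() {
  cached("slice200", suppressWarnings(
    generate_slice(example_slice_spec(n_cells = 200, seed = 2))))
}

# 200-cell slice with mutually exclusive states (live/dead only)
fixture_slice_excl <- function() {
  cached("slice_excl", suppressWarnings(generate_slice(example_slice_spec(
    n_cells = 200, seed = 3,
    class_proportions = c(live = 0.5, dead = 0.5,
                          double_positive = 0, double_negative = 0)))))
}

# Standard mask set for a generated slice (the pipeline's canonical order:
# threshold, subtract lipofuscin, median filter inside local_threshold)
fixture_masks <- function(sl) {
  px <- sl$image$pixel_size_um
  lp <- local_threshold(sl$image$channels$lipofuscin,
                        threshold_config("lipofuscin"), px)
  list(
    WGA = local_threshold(sl$image$channels$WGA, threshold_config("WGA"), px),
    RyR = subtract_lipofuscin(
      local_threshold(sl$image$channels$RyR, threshold_config("RyR"), px), lp),
    dextran = subtract_lipofuscin(
      local_threshold(sl$image$channels$dextran,
                      threshold_config("dextran"), px), lp),
    DAPI = subtract_lipofuscin(
      local_threshold(sl$image$channels$DAPI, threshold_config("DAPI"), px), lp),
    lipofuscin = lp)
}

fixture_analysis <- function(key, slice_fun) {
  cached(paste0(key, "_analysis"), {
    sl <- slice_fun()
    px <- sl$image$pixel_size_um
    masks <- fixture_masks(sl)
    labels <- segment_cells(masks$WGA, px)
    records <- classify_cells(labels, masks$RyR, masks$dextran)
    matching <- match_segments(labels, sl$truth$label_map)
    list(slice = sl, masks = masks, labels = labels, records = records,
         matching = matching,
         truth_state = sl$truth$cells$state[matching$best_truth])
  })
}

analysis_100 <- function() fixture_analysis("slice100", fixture_slice_100)
analysis_200 <- function() fixture_analysis("slice200", fixture_slice_200)
analysis_excl <- function() fixture_analysis("slice_excl", fixture_slice_excl)
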