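test_that("generators are bitwise deterministic under a fixed seed", {
  for (task in c("liver_binary", "brats_multiclass")) {
    cfg <- synthetic_config(task, n_samples = 3, size = 32, seed = 11)
    gen <- if (task == "liver_binary") generate_liver_like else generate_brats_like
    expect_identical(gen(cfg), gen(cfg))
    cfg2 <- synthetic_config(task, n_samples = 3, size = 32, seed = 12)
    expect_false(identical(gen(cfg), gen(cfg2)))
  }
})

test_that("liver-like slices have 3 channels, binary labels and bounded blob area", {
  cfg <- synthetic_config("liver_binary", n_samples = 8, size = 48,
                          foreground_fraction_range = c(0.12, 0.3), seed = 4)
  ds <- generate_liver_like(cfg)
  expect_equal(length(ds), 8L)
  for (s in ds$samples) {
    expect_equal(dim(s$image), c(48, 48, 3))
    expect_true(all(s$image >= 0 & s$image <= 1))
    expect_true(all(s$label %in% c(0L, 1L)))
    frac <- mean(s$label)
    expect_gt(frac, 0.12); expect_lt(frac, 0.3)
  }
})

test_that("brain-tumor-like slices have 12 channels and nested 4-class labels", {
  cfg <- synthetic_config("brats_multiclass", n_samples = 6, size = 48, seed = 9)
  ds <- generate_brats_like(cfg)
  for (s in ds$samples) {
    expect_equal(dim(s$image), c(48, 48, 12))
    expect_true(all(s$label %in% 0:3))
    r <- map_nested_regions(s$label)
    expect_true(all(!r$et | r$tc))
    expect_true(all(!r$tc | r$wt))
    frac <- mean(r$wt)
    expect_gt(frac, cfg$foreground_fraction_range[1])
    expect_lt(frac, cfg$foreground_fraction_range[2])
  }
})

test_that("prominent-slice selection ranks by foreground size with stated tie-break", {
  mk <- function(counts) {
    v <- array(0L, dim = c(4, 4, length(counts)))
    for (d in seq_along(counts)) if (counts[d] > 0) v[seq_len(counts[d]) + 16 * (d - 1)] <- 1L
    v
  }
  # counts 5, 9, 9, 2 -> slices 2 and 3 (tie broken by lower index), then 1
  expect_identical(select_prominent_slices(mk(c(5, 9, 9, 2)), 3), c(2L, 3L, 1L))
  expect_identical(select_prominent_slices(mk(c(1, 7, 3)), 1), 2L)
  expect_identical(select_prominent_slices(mk(c(0, 0, 0)), 3), integer(0))
  # fewer non-empty slices than requested: return all non-empty
  expect_identical(select_prominent_slices(mk(c(0, 4, 0)), 3), 2L)
  expect_error(select_prominent_slices(array(0L, c(2, 2, 0)), 1), "empty")
})

test_that("the emulated volume is selectable and lens-shaped", {
  cfg <- synthetic_config("liver_binary", n_samples = 1, size = 32, seed = 6)
  vol <- generate_liver_volume(cfg, depth = 8)
  expect_equal(dim(vol$images), c(32, 32, 3, 8))
  counts <- apply(vol$labels != 0, 3, sum)
  top <- select_prominent_slices(vol$labels, 3)
  expect_length(top, 3)
  expect_true(all(counts[top] >= sort(counts, decreasing = TRUE)[3]))
})

test_that("the enhancing-tumor filter applies the >= threshold per sample", {
  mk_sample <- function(n_et) {
    lab <- matrix(0L, 16, 16)
    if (n_et > 0) lab[seq_len(n_et)] <- 1L
    list(image = array(0.5, c(16, 16, 12)), label = lab)
  }
  ds <- lfeunet:::new_seg_dataset(lapply(c(19, 20, 0, 100), mk_sample),
                                  "brats_multiclass", 4L,
                                  c("background", "ET", "ED", "NET"))
  kept <- filter_et_slices(ds, min_et = 20)
  expect_equal(length(kept), 2L)
  expect_equal(vapply(kept$samples, function(s) sum(s$label == 1L), 0), c(20, 100))
  expect_equal(length(filter_et_slices(ds, min_et = 0)), 4L)
  # surviving count equals an explicit per-sample tally
  counts <- vapply(ds$samples, function(s) sum(s$label == 1L), 0)
  expect_equal(length(filter_et_slices(ds, 20)), sum(counts >= 20))
})

test_that("the train/validation split is a seeded partition with the right sizes", {
  cfg <- synthetic_config("liver_binary", n_samples = 20, size = 16, seed = 3)
  ds <- generate_liver_like(cfg)
  ds$samples <- rep(ds$samples, 5)  # 100 samples
  for (s in seq_along(ds$samples)) ds$samples[[s]]$id <- s
  sp <- split_dataset(ds, 0.9, seed = 21)
  expect_equal(length(sp$train), 90L)
  expect_equal(length(sp$val), 10L)
  ids <- function(d) vapply(d$samples, `[[`, 0L, "id")
  expect_length(intersect(ids(sp$train), ids(sp$val)), 0)
  expect_setequal(c(ids(sp$train), ids(sp$val)), 1:100)
  sp2 <- split_dataset(ds, 0.9, seed = 21)
  expect_identical(ids(sp$train), ids(sp2$train))
  expect_error(split_dataset(ds, 1.2), "in \\(0, 1\\)")
})

test_that("an infeasible foreground range is rejected", {
  expect_error(synthetic_config("liver_binary",
                                foreground_fraction_range = c(0.5, 0.2)),
               "lo < hi")
  expect_error(synthetic_config("liver_binary",
                                foreground_fraction_range = c(0, 0.5)),
               "lo < hi|0 <")
})
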