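test_that("simulation is deterministic given the seed", {
  a <- simulate_lot(sim_config(rng_seed = 9, n_rows = 1, n_cols = 2))
  b <- simulate_lot(sim_config(rng_seed = 9, n_rows = 1, n_cols = 2))
  expect_identical(a$truth, b$truth)
  expect_identical(sim_label_source(a)(50), sim_label_source(b)(50))
  expect_identical(sim_rgb_frame(a, 50), sim_rgb_frame(b, 50))
  c2 <- simulate_lot(sim_config(rng_seed = 10, n_rows = 1, n_cols = 2))
  expect_false(identical(a$truth, c2$truth))
})

test_that("truth lengths are non-decreasing and bounded by the logistic cap", {
  lot <- tiny_lot()
  for (sd in lot$seeds) for (r in sd$roots) {
    l <- subset(lot$truth$lengths, seed == sd$id & root == r$index)$length_mm
    expect_true(all(diff(l) >= -1e-9))
    expect_lte(max(l), r$lmax_px * lot$cfg$scale_mm_per_px + 1e-9)
  }
})

test_that("crossing bookkeeping follows the preset", {
  expect_equal(nrow(tiny_lot()$truth$crossings), 0)
  xl <- simulate_lot(sim_preset("one-crossing", rng_seed = 201))
  expect_gt(nrow(xl$truth$crossings), 0)
  expect_true(all(xl$truth$crossings$frame >= 1 &
                  xl$truth$crossings$frame <= 96))
})

test_that("label maps and RGB frames are mutually consistent", {
  lot <- tiny_lot()
  t <- 90
  labels <- sim_label_source(lot)(t)
  px <- sim_rgb_frame(lot, t, labels = labels, noise = FALSE)
  # every root pixel carries the root albedo before noise
  root_px <- which(labels == 2L)
  expect_true(all(abs(px[, , 1][root_px] - 230) < 1e-9))
  # background carries the paper colour
  bg <- which(labels == 0L)
  expect_true(all(abs(px[, , 3][bg] - 190) < 1e-9))
})

test_that("rendered root extent tracks the truth arc length", {
  lot <- tiny_lot()
  src <- sim_label_source(lot)
  roi <- lot$rois[[1]]
  r1 <- lot$seeds[[1]]$roots[[1]]
  for (t in c(60, 80, 96)) {
    lm <- crop_roi(src(t), roi)
    l_px <- subset(lot$truth$lengths, seed == 1 & root == 1 & frame == t)$length_mm /
      lot$cfg$scale_mm_per_px
    # a 3-px-wide band: pixel count / width approximates the arc length
    n_root <- sum(lm == 2L & row(lm) < 390)
    total <- sum(subset(lot$truth$lengths,
                        seed == 1 & frame == t)$length_mm) /
      lot$cfg$scale_mm_per_px
    expect_equal(n_root / 3, total, tolerance = 0.15)
  }
})

test_that("truth tables use the pipeline's output schemas", {
  tt <- truth_tables(tiny_lot())
  expect_named(tt$lengths, c("seed_id", "root_index", "frame", "hour",
                             "length_mm"))
  expect_named(tt$events, c("seed_id", "protrusion_h", "germination_2mm_h",
                            "establishment_10mm_h", "coleoptile_h",
                            "chloroplast_h"))
  expect_equal(nrow(subset(tt$lengths, seed_id == 1 & root_index == 1)), 96)
})

test_that("event-level vigor scenario carries its design and censoring", {
  ev <- simulate_vigor_events(rng_seed = 2, n_genotypes = 6, n_seeds = 10)
  expect_equal(nrow(ev), 60)
  expect_setequal(unique(ev$designed_tier), c("high", "medium", "low"))
  expect_true(all(ev$re_h >= ev$pro_h, na.rm = TRUE))
  expect_true(all(ev$se_h >= ev$re_h, na.rm = TRUE))
  expect_true(all(ev$se_h <= 96, na.rm = TRUE))
  expect_identical(ev, simulate_vigor_events(rng_seed = 2, n_genotypes = 6,
                                             n_seeds = 10))
})

test_that("an overly dense layout is rejected", {
  expect_error(sim_config(cell_px = 150), "layout overflow")
})
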