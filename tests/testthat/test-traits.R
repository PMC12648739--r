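test_that("morphology identities: disk and rectangle", {
  disk <- measure_seed_morphology(disk_mask(50), scale_mm_per_px = 0.05)
  expect_gt(disk$roundness, 0.95); expect_lt(disk$roundness, 1.05)
  expect_equal(disk$area_mm2, pi * 2.5^2, tolerance = 0.02)
  expect_equal(disk$wl_ratio, 1, tolerance = 0.03)

  rect <- measure_seed_morphology(rect_mask(20, 40), scale_mm_per_px = 0.05)
  expect_equal(rect$wl_ratio, 0.5, tolerance = 0.05)
  # 4*pi*a*b / (2a+2b)^2 with a = 2b gives 8*pi/36
  expect_equal(rect$roundness, 8 * pi / 36, tolerance = 0.05)
  expect_equal(rect$length_mm, 2, tolerance = 0.05)

  empty <- measure_seed_morphology(matrix(FALSE, 5, 5))
  expect_true(empty$flagged); expect_true(is.na(empty$area_mm2))
})

test_that("morphology is rotation-invariant within 3% at seed scale", {
  base <- measure_seed_morphology(rect_mask(40, 80), 1)
  for (ang in c(37, 64)) {
    rot <- measure_seed_morphology(rotate_mask(rect_mask(40, 80), ang, out = 200), 1)
    for (f in c("area_mm2", "length_mm", "width_mm", "perimeter_mm",
                "wl_ratio", "roundness"))
      expect_equal(rot[[f]], base[[f]], tolerance = 0.03)
  }
})

test_that("seed colour means are exact channel averages", {
  px <- array(0, c(10, 10, 3))
  px[, , 1] <- 120; px[, , 2] <- 80; px[, , 3] <- 40
  m <- matrix(TRUE, 10, 10)
  expect_equal(measure_seed_color(px, m), c(R = 120, G = 80, B = 40))

  px2 <- array(0, c(2, 2, 3)); px2[1, , ] <- 0; px2[2, , ] <- 255
  expect_equal(unname(measure_seed_color(px2, matrix(TRUE, 2, 2))),
               rep(127.5, 3))
  expect_true(all(is.na(measure_seed_color(px, matrix(FALSE, 10, 10)))))
})

test_that("change rates are percentages relative to the first frame", {
  expect_equal(change_rate_percent(c(10, 10, 10)), c(0, 0, 0))
  expect_equal(change_rate_percent(c(10, 12, 13))[2], 20)
  expect_true(all(is.na(change_rate_percent(c(0, 5)))))
})

test_that("excess green index formula", {
  expect_equal(exg(c(0, 255, 0)), 510)
  expect_equal(exg(c(80, 80, 80)), 0)
  expect_equal(exg(c(255, 0, 255)), -510)
  px <- array(c(10, 200, 30), c(1, 1, 3))
  expect_equal(as.numeric(exg(px)), 2 * 200 - 10 - 30)
})

test_that("chloroplast timing matches a direct-scan oracle on built series", {
  set.seed(8)
  nfr <- 60
  mask <- matrix(FALSE, 20, 20); mask[5:12, 8:14] <- TRUE
  frames <- lapply(1:nfr, function(t) {
    px <- array(0, c(20, 20, 3))
    col <- if (t >= 50) c(60, 200, 60) else c(220, 220, 220)
    for (k in 1:3) { ch <- matrix(30, 20, 20); ch[mask] <- col[k]; px[, , k] <- ch }
    px
  })
  masks <- rep(list(mask), nfr)
  thr <- chloroplast_threshold(list(frames[[55]]), list(mask))
  expect_equal(thr, 2 * 200 - 60 - 60)
  got <- chloroplast_time(frames, masks, hours = 0:(nfr - 1), threshold = 100)
  # oracle: first frame whose 5th-largest ExG exceeds the threshold
  oracle <- which(vapply(frames, function(px) {
    v <- sort(exg(px)[mask], decreasing = TRUE)
    v[5] > 100
  }, logical(1)))[1] - 1
  expect_equal(got, oracle)

  never <- chloroplast_time(frames[1:40], masks[1:40], 0:39, threshold = 600)
  expect_true(is.na(never))
  expect_equal(chloroplast_time(frames[50:55], masks[1:6], 0:5, 100), 0)
})

test_that("coleoptile time is the first seedling/seed overlap", {
  seed <- matrix(FALSE, 20, 20); seed[8:12, 8:12] <- TRUE
  off <- matrix(FALSE, 20, 20); off[1:2, 1:2] <- TRUE
  on <- matrix(FALSE, 20, 20); on[6:8, 9:10] <- TRUE
  masks <- c(rep(list(matrix(FALSE, 20, 20)), 45), list(on), list(on))
  expect_equal(coleoptile_time(masks, rep(list(seed), 47), 0:46), 45)
  expect_true(is.na(coleoptile_time(rep(list(off), 5), rep(list(seed), 5), 0:4)))
})

test_that("time to target length uses the first-crossing convention", {
  lens <- c(rep(0, 33), seq(1.9, 12, length.out = 30))
  hours <- seq_along(lens) - 1
  i2 <- which(lens >= 2)[1]
  expect_equal(time_to_length(lens, hours, 2), hours[i2])
  expect_true(is.na(time_to_length(pmin(lens, 8), hours, 10)))
  # truncation can only censor, never move a detected time earlier
  full <- time_to_length(lens, hours, 10)
  trunc <- time_to_length(lens[1:40], hours[1:40], 10)
  expect_true(is.na(trunc) || trunc == full)
})

test_that("the 75% lot-phase rule counts ceil(0.75 n) entered seeds", {
  h <- c(rep(40, 12), rep(NA, 3))
  expect_equal(as.numeric(lot_phase_time(h)), 40)
  expect_true(is.na(lot_phase_time(c(rep(40, 11), rep(NA, 4)))))
  expect_equal(as.numeric(lot_phase_time(17)), 17)  # n = 1: ceil(0.75) = 1
  # standardized sampling is seeded and reproducible
  hours <- c(rep(30, 20), rep(60, 10))
  a <- lot_phase_time(hours, sample_n = 15, sample_seed = 4)
  b <- lot_phase_time(hours, sample_n = 15, sample_seed = 4)
  expect_identical(as.numeric(a), as.numeric(b))
  expect_equal(attr(a, "n"), 15)
})

test_that("event recovery on a simulated lot is exact at the frame grid", {
  lot <- tiny_lot()
  src <- sim_label_source(lot)
  frames_fn <- function(t) sim_rgb_frame(lot, t)
  res <- process_lot(src, lot$rois, lot$hours, lot$cfg$scale_mm_per_px,
                     frames_fn = frames_fn)
  tru <- lot$truth$events
  expect_equal(res$events$protrusion_h, tru$pro_h)
  expect_equal(res$events$coleoptile_h, tru$coleoptile_h)
  expect_equal(res$events$chloroplast_h, tru$chloroplast_h)
  expect_true(all(abs(res$events$germination_2mm_h - tru$re_h) <= 1,
                  na.rm = TRUE))
  expect_true(all(abs(res$events$establishment_10mm_h - tru$est_h) <= 1,
                  na.rm = TRUE))
})
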