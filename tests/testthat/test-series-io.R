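test_that("load_series orders frames, assigns hours, and validates input", {
  dir <- withr::local_tempdir()
  for (k in 1:10)
    png::writePNG(array(runif(20 * 30 * 3), c(20, 30, 3)),
                  file.path(dir, sprintf("frame_%02d.png", k)))
  s <- load_series(dir, interval_h = 0.5)
  expect_equal(n_frames(s), 10)
  expect_equal(s$hours, seq(0, 4.5, by = 0.5))
  expect_equal(attr(s, "files"), sprintf("frame_%02d.png", 1:10))

  empty <- withr::local_tempdir()
  expect_error(load_series(empty), "no frames")
  png::writePNG(matrix(0.5, 5, 5), file.path(empty, "only.png"))
  expect_error(load_series(empty), "no frames")
})

test_that("a manifest overrides lexicographic frame order", {
  dir <- withr::local_tempdir()
  vals <- c(0.2, 0.8)
  png::writePNG(matrix(vals[1], 6, 6), file.path(dir, "b.png"))
  png::writePNG(matrix(vals[2], 6, 6), file.path(dir, "a.png"))
  write.csv(data.frame(filename = c("b.png", "a.png"), hour = c(0, 1)),
            file.path(dir, "manifest.csv"), row.names = FALSE)
  s <- load_series(dir)
  expect_equal(s$frames[[1]][1, 1, 1], 0.2 * 255, tolerance = 1e-6)
  expect_equal(s$hours, c(0, 1))
})

test_that("label maps round-trip through PNG exactly", {
  lm <- matrix(sample(0:3, 30 * 40, replace = TRUE), 30, 40)
  storage.mode(lm) <- "integer"
  path <- withr::local_tempfile(fileext = ".png")
  write_label_map(lm, path)
  expect_identical(read_label_map(path), lm)
  expect_error(write_label_map(matrix(5L, 2, 2), path), "invalid label")
})

test_that("crop_roi uses 0-based half-open boxes and checks bounds", {
  x <- matrix(seq_len(100 * 100), 100, 100)
  expect_equal(dim(crop_roi(x, seed_roi(1, c(0, 0, 10, 10)))), c(10, 10))
  expect_identical(crop_roi(x, seed_roi(1, c(0, 0, 100, 100))), x)
  expect_equal(crop_roi(x, seed_roi(1, c(2, 3, 5, 7)))[1, 1], x[3, 4])
  expect_error(crop_roi(x, seed_roi(1, c(90, 90, 101, 101))), "out of bounds")
})

test_that("split_masks partitions labels into the mask triplet", {
  lm <- matrix(0L, 10, 10)
  tri0 <- split_masks(lm)
  expect_false(any(tri0$seed_body) || any(tri0$full_plant) || any(tri0$seedling))

  lm[2:4, 2:4] <- 1L; lm[6:7, 2:3] <- 2L; lm[8, 8] <- 3L
  tri <- split_masks(lm)
  expect_equal(sum(tri$seed_body), 9)
  expect_equal(sum(tri$seedling), 1)
  expect_equal(sum(tri$full_plant), 9 + 4 + 1)
  expect_true(all(tri$full_plant[tri$seed_body]))
  expect_true(all(tri$full_plant[tri$seedling]))

  lm[1, 1] <- 7L
  expect_error(split_masks(lm), "7")
})

test_that("alignment recovers synthetic shifts and is idempotent", {
  set.seed(42)
  base <- array(runif(60 * 80 * 3) * 255, c(60, 80, 3))
  shifted <- germtrack:::roll_frame(base, 3, -2)
  s <- image_series(list(base, shifted))
  al <- align_series(s, "translation")
  sh <- attr(al, "shifts")
  expect_equal(c(sh$dr[2], sh$dc[2]), c(3, -2))
  expect_equal(al$frames[[2]], base)

  again <- align_series(al, "translation")
  expect_true(all(abs(attr(again, "shifts")$dr) <= 1))
  expect_true(all(abs(attr(again, "shifts")$dc) <= 1))

  none <- align_series(s, "none")
  expect_identical(none$frames, s$frames)

  same <- align_series(image_series(list(base, base)), "translation")
  expect_equal(unlist(attr(same, "shifts")[2, c("dr", "dc")]),
               c(dr = 0, dc = 0))
})

test_that("labels are transformed identically to their frames", {
  set.seed(1)
  base <- array(runif(40 * 40 * 3) * 255, c(40, 40, 3))
  lab <- matrix(sample(0:3, 1600, TRUE), 40, 40)
  s <- image_series(list(base, germtrack:::roll_frame(base, 2, 1)))
  al <- align_series(s, "translation",
                     labels = list(lab, germtrack:::roll2(lab, 2, 1)))
  expect_identical(attr(al, "labels")[[2]], lab)
})
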