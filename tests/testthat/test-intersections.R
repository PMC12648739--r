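test_that("crossing regions are detected with the right clique order", {
  xr <- detect_crossing_regions(skeletonize_mask(x_mask()))
  expect_length(xr, 1)
  expect_equal(xr[[1]]$order, 4)
  angs <- sort(unname(sapply(xr[[1]]$arms, function(a)
    (atan2(a$dir[2], -a$dir[1]) * 180 / pi) %% 360)))
  expect_equal(angs, c(45, 135, 225, 315), tolerance = 10 / 45)

  tm <- matrix(FALSE, 40, 40); tm[20, 5:35] <- TRUE; tm[20:35, 20] <- TRUE
  tr <- detect_crossing_regions(skeletonize_mask(tm))
  expect_length(tr, 1)
  expect_equal(tr[[1]]$order, 3)

  bar <- matrix(FALSE, 10, 30); bar[4:6, 5:25] <- TRUE
  expect_length(detect_crossing_regions(skeletonize_mask(bar)), 0)
})

test_that("resolution prefers pair angles closest to 180 degrees", {
  r1 <- resolve_crossing(region_from_angles(c(0, 90, 180, 270)))
  expect_equal(canon_pairs(r1$pairs), list(c(1, 3), c(2, 4)))

  r2 <- resolve_crossing(region_from_angles(c(0, 80, 185, 268)))
  expect_equal(canon_pairs(r2$pairs), list(c(1, 3), c(2, 4)))

  r3 <- resolve_crossing(region_from_angles(c(10, 150, 200)))
  expect_equal(canon_pairs(r3$pairs), list(c(1, 3)))
  expect_equal(r3$unpaired, 2)
})

test_that("resolution equals exhaustive enumeration on random arm sets", {
  set.seed(99)
  for (k in 1:200) {
    n <- sample(3:4, 1)
    angs <- sort(runif(n, 0, 360))
    # keep arms distinguishable so the optimum is unique
    if (min(diff(c(angs, angs[1] + 360))) < 8) next
    got <- resolve_crossing(region_from_angles(angs))
    want <- pairing_oracle(angs)
    expect_equal(canon_pairs(got$pairs), canon_pairs(want$pairs),
                 info = paste(round(angs, 1), collapse = ","))
    expect_equal(got$score, want$score, tolerance = 1e-6)
  }
})

test_that("pairing is invariant under global rotation of the arms", {
  set.seed(5)
  for (k in 1:50) {
    angs <- sort(runif(4, 0, 360))
    if (min(diff(c(angs, angs[1] + 360))) < 8) next
    base <- canon_pairs(resolve_crossing(region_from_angles(angs))$pairs)
    for (rot in c(17, 113, 301)) {
      got <- canon_pairs(resolve_crossing(
        region_from_angles((angs + rot) %% 360))$pairs)
      expect_equal(got, base)
    }
  }
})

test_that("ambiguous pairings fall back to the previous growth direction", {
  # near-square arms: scores of two pairings differ by < 5 degrees
  angs <- c(0, 88, 180, 269)
  reg <- region_from_angles(angs)
  down <- c(1, 0)    # a track previously growing straight down (180 deg)
  r <- resolve_crossing(reg, prev_dirs = list(down))
  expect_true(any(vapply(r$pairs, function(p) setequal(p, c(1, 3)), logical(1))))
})
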