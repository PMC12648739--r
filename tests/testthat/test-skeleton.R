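test_that("skeletonization reduces simple shapes to their topology", {
  bar <- matrix(FALSE, 10, 30); bar[4:6, 5:25] <- TRUE
  sk <- skeletonize_mask(bar)
  expect_equal(nrow(sk$endpoints), 2)
  expect_equal(nrow(sk$branch_points), 0)
  expect_lte(nrow(sk$pixels), sum(bar))

  pl <- skeletonize_mask(plus_mask())
  expect_equal(nrow(pl$endpoints), 4)
  expect_gte(nrow(pl$branch_points), 1)

  empty <- skeletonize_mask(matrix(FALSE, 5, 5))
  expect_equal(nrow(empty$pixels), 0)
  expect_equal(nrow(empty$endpoints), 0)
})

test_that("no skeleton pixel has a full 2x2 block of neighbours", {
  for (m in list(plus_mask(), x_mask(), disk_mask(20, 5))) {
    sk <- skeletonize_mask(m)$mask
    blocks <- sk[-nrow(sk), -ncol(sk)] & sk[-1, -ncol(sk)] &
              sk[-nrow(sk), -1] & sk[-1, -1]
    expect_false(any(blocks))
  }
})

test_that("skeletonizing an existing 1-px path is the identity on its pixels", {
  p <- matrix(FALSE, 20, 20)
  p[cbind(5:15, 5:15)] <- TRUE    # diagonal 1-px path
  sk <- skeletonize_mask(p)
  expect_identical(sk$mask, p)
  h <- matrix(FALSE, 10, 20); h[5, 3:17] <- TRUE
  expect_identical(skeletonize_mask(h)$mask, h)
})

test_that("endpoint/branch classification matches the neighbour-count oracle", {
  set.seed(11)
  shapes <- list(plus_mask(), x_mask(), rect_mask(6, 30))
  for (k in 1:5) {
    m <- matrix(runif(900) < 0.4, 30, 30)
    shapes[[length(shapes) + 1]] <- m
  }
  for (m in shapes) {
    sk <- skeletonize_mask(m)
    nb <- neighbor_count_oracle(sk$mask)
    expect_identical(sk$endpoints, coords <- which(sk$mask & nb == 1, arr.ind = TRUE),
                     ignore_attr = TRUE)
    expect_identical(sk$branch_points,
                     which(sk$mask & nb >= 3, arr.ind = TRUE),
                     ignore_attr = TRUE)
    # the two sets never overlap
    expect_equal(nrow(merge(as.data.frame(sk$endpoints),
                            as.data.frame(sk$branch_points))), 0)
  }
})

test_that("root tips exclude the dilated seed coat and record origins", {
  lm <- matrix(0L, 60, 60)
  lm[25:35, 25:35] <- 1L                      # seed body
  lm[cbind(36:52, 30)] <- 2L                  # one root going down
  tri <- split_masks(lm)
  sk <- skeletonize_mask(tri$full_plant & !tri$seed_body & !tri$seedling)
  det <- detect_root_tips(sk, tri, dilation_px = 3)
  expect_equal(nrow(det$tips), 1)
  expect_gt(det$tips[1, 1], 45)               # far endpoint
  expect_equal(nrow(det$origins), 1)
  expect_lt(det$origins[1, 1], 42)            # near the coat

  # a skeleton entirely inside the dilated seed yields no tips
  lm2 <- matrix(0L, 60, 60); lm2[25:35, 25:35] <- 1L; lm2[cbind(36:37, 30)] <- 2L
  tri2 <- split_masks(lm2)
  sk2 <- skeletonize_mask(tri2$full_plant & !tri2$seed_body & !tri2$seedling)
  det2 <- detect_root_tips(sk2, tri2, dilation_px = 3)
  expect_equal(nrow(det2$tips), 0)
})

test_that("emergence order: earliest frame first, clockwise angle tie-break", {
  expect_equal(assign_emergence_order(c(52, 40, 55),
                                      rbind(c(0, 1), c(1, 0), c(1, 1)),
                                      c(0, 0)),
               c(2L, 1L, 3L))
  # simultaneous emergence: 30 deg beats 200 deg clockwise from 12 o'clock
  pos <- rbind(c(-cos(200 * pi / 180), sin(200 * pi / 180)),
               c(-cos(30 * pi / 180), sin(30 * pi / 180)))
  expect_equal(assign_emergence_order(c(10, 10), pos, c(0, 0)), c(2L, 1L))
  expect_equal(assign_emergence_order(numeric(0),
                                      matrix(numeric(0), 0, 2), c(0, 0)),
               integer(0))
})
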