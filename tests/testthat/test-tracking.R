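test_that("route length accounting follows the configured step weights", {
  skm <- matrix(FALSE, 30, 120); skm[15, 10:110] <- TRUE
  rt <- germtrack:::.grid_route(skm, 15L, 10L)
  path <- germtrack:::.route_path(rt$parent, 15L, 110L)
  # a straight 100-px route at 0.05 mm/px measures 5.0 mm in raw chain units
  expect_equal(path_length_px(path, skm, "freeman") * 0.05, 5.0)
  expect_equal(path_length_px(path, skm, "corrected"), 98.0)
  # corrected weights are near-unbiased on diagonals too
  d <- matrix(FALSE, 120, 120); d[cbind(10:110, 10:110)] <- TRUE
  rtd <- germtrack:::.grid_route(d, 10L, 10L)
  pd <- germtrack:::.route_path(rtd$parent, 110L, 110L)
  expect_equal(path_length_px(pd, d, "corrected"), 100 * sqrt(2),
               tolerance = 0.01)
})

test_that("extend_track accepts the minimum-weight candidate within the gate", {
  skm <- matrix(FALSE, 30, 30)
  skm[15, 5:25] <- TRUE
  g <- init_track(1, 5, c(15, 5), 10)
  g$vertices <- rbind(c(4, 15, 10))
  g$last_dir <- c(0, 1)
  skel <- skeletonize_mask(skm)
  # on-skeleton candidate (cost 0) vs off-skeleton candidate (cost > 0)
  cands <- rbind(c(15, 20), c(19, 20))
  g2 <- extend_track(g, cands, skel, track_config(), frame = 5)
  expect_equal(attr(g2, "accepted"), 1L)
  expect_equal(unname(g2$vertices[2, 2:3]), c(15, 20))

  # perpendicular candidate: cos = 0 < 0.5 -> rejected, graph unchanged
  gp <- g
  perp <- rbind(c(12, 10))
  g3 <- extend_track(gp, perp, skel, track_config(max_route_weight = Inf),
                     frame = 5)
  expect_true(is.na(attr(g3, "accepted")))
  expect_equal(nrow(g3$vertices), 1)
  # ... accepted once the angular gate is widened past 90 degrees
  g4 <- extend_track(gp, perp, skel,
                     track_config(cos_min = -0.1, max_route_weight = Inf),
                     frame = 5)
  expect_equal(attr(g4, "accepted"), 1L)
})

test_that("route costs agree with an independent shortest-path oracle", {
  set.seed(21)
  for (k in 1:20) {
    n <- sample(15:30, 1)
    skm <- matrix(runif(n * n) < 0.25, n, n)
    src <- c(sample(n, 1), sample(n, 1))
    rt <- germtrack:::.grid_route(skm, src[1], src[2])
    # oracle: directed graph, edge weight = weight of the target pixel
    idx <- function(i, j) (j - 1) * n + i
    from <- integer(0); to <- integer(0); w <- numeric(0)
    for (i in 1:n) for (j in 1:n) for (di in -1:1) for (dj in -1:1) {
      if (di == 0 && dj == 0) next
      ii <- i + di; jj <- j + dj
      if (ii < 1 || jj < 1 || ii > n || jj > n) next
      from <- c(from, idx(i, j)); to <- c(to, idx(ii, jj))
      w <- c(w, if (skm[ii, jj]) 0 else 1)
    }
    gr <- igraph::graph_from_edgelist(cbind(from, to))
    d <- igraph::distances(gr, v = idx(src[1], src[2]), mode = "out",
                           weights = w, algorithm = "dijkstra")
    want <- matrix(d[1, ], n, n)
    expect_equal(rt$weight + 0, want, ignore_attr = TRUE)
  }
})

test_that("cumulative length is zero before emergence and non-decreasing", {
  g <- init_track(1, 40, c(10, 10), 96)
  g$length_px <- cumsum(c(rep(0, 39), rep(2, 57)))
  expect_equal(cumulative_length(g, 10, 0.05), 0)
  expect_equal(cumulative_length(g, 38, 0.05), 0)
  lens <- sapply(1:96, cumulative_length, g = g, scale_mm_per_px = 0.05)
  expect_true(all(diff(lens) >= 0))
})

test_that("growth rates: constant, linear, and logistic inflection recovery", {
  expect_equal(growth_rate_series(rep(3, 50))$rate_mm_per_h, rep(0, 50))

  lin <- growth_rate_series((0:99) * 0.2, interval_h = 1)
  expect_equal(lin$rate_mm_per_h[10:90], rep(0.2, 81), tolerance = 1e-8)

  # logistic: the rate peaks at the inflection point
  t <- 0:95
  lmax <- 12; r <- 0.12; mid <- 55
  lens <- lmax / (1 + exp(-r * (t - mid)))
  gr <- growth_rate_series(lens, interval_h = 1)
  expect_equal(which.max(gr$rate_mm_per_h) - 1, mid, tolerance = 2)
  expect_warning(growth_rate_series(c(0, 1), smooth_window = 5), "window")
})

test_that("track_seed recovers a simulated seed's roots and lengths", {
  lot <- tiny_lot()
  src <- sim_label_source(lot)
  roi <- lot$rois[[1]]
  tracks <- track_seed(function(t) split_masks(crop_roi(src(t), roi)),
                       track_config(), seed_id = 1, n_frames = 96)
  expect_equal(length(tracks), length(lot$seeds[[1]]$roots))
  for (g in tracks) {
    tru <- subset(lot$truth$lengths, seed == 1 & root == g$root_index)
    fin <- max(tru$length_mm)
    rmse <- sqrt(mean((g$length_px * 0.05 - tru$length_mm)^2))
    expect_lt(rmse / fin, 0.05)
    expect_equal(g$t_e, lot$seeds[[1]]$roots[[g$root_index]]$t_e_frame)
    expect_true(all(diff(g$length_px) >= 0))
  }
})

test_that("tracking is deterministic for identical inputs", {
  lot <- tiny_lot()
  src1 <- sim_label_source(lot); src2 <- sim_label_source(lot)
  roi <- lot$rois[[2]]
  t1 <- track_seed(function(t) split_masks(crop_roi(src1(t), roi)),
                   track_config(), seed_id = 2, n_frames = 96)
  t2 <- track_seed(function(t) split_masks(crop_roi(src2(t), roi)),
                   track_config(), seed_id = 2, n_frames = 96)
  expect_identical(t1, t2)
})
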