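test_that("uniformity score matches hand evaluation of the construction", {
  # all events in one 1-h bin: peak 1, span 1, score 1
  one <- uniformity_score(rep(30, 20))
  expect_equal(one$value, 1)

  # uniform over 0..39 h (one per hour): peak 1/40, span 29.25 bins
  u <- uniformity_score(0:39)
  expect_equal(u$peak, 1 / 40)
  expect_equal(u$span_bins, 29.25)
  expect_equal(u$value, (1 / 40) / 29.25, tolerance = 1e-9)
  expect_equal(u$value, 0.00085, tolerance = 0.01)

  # censored seeds are excluded and counted
  cen <- uniformity_score(c(rep(30, 10), rep(NA, 10)))
  expect_equal(cen$value, 1)
  expect_equal(cen$n_censored, 10)

  allc <- uniformity_score(c(NA, NA))
  expect_true(is.na(allc$value)); expect_equal(allc$n_censored, 2)
})

test_that("uniformity is bounded and monotone in span at fixed peak", {
  set.seed(13)
  for (k in 1:50) {
    h <- round(rnorm(30, 40, runif(1, 0.5, 8)))
    v <- uniformity_score(h)$value
    expect_gte(v, 0); expect_lte(v, 1)
  }
  # widening the central span at a fixed modal bin weakly lowers the score
  tight <- c(rep(30, 10), 28, 32)
  wide <- c(rep(30, 10), 20, 40)
  expect_gte(uniformity_score(tight)$value, uniformity_score(wide)$value)
  # score is 1 iff all uncensored events share one bin
  expect_lt(uniformity_score(c(rep(30, 19), 35))$value, 1)
})

test_that("speed clustering recovers well-separated genotype families", {
  set.seed(2)
  mk <- function(mid) {
    t <- 0:96
    data.frame(seed = rep(1:5, each = 97), hour = rep(t, 5),
               length_mm = rep(12 / (1 + exp(-0.15 * (t - mid))), 5) +
                 rnorm(5 * 97, 0, 0.05))
  }
  profiles <- list(A1 = build_profile(mk(30)), A2 = build_profile(mk(32)),
                   B1 = build_profile(mk(45)), B2 = build_profile(mk(46)),
                   C1 = build_profile(mk(60)), C2 = build_profile(mk(62)))
  tt2 <- c(A1 = 25, A2 = 27, B1 = 40, B2 = 41, C1 = 55, C2 = 57)
  grp <- cluster_speed_groups(profiles, k = 3, time_to_2mm = tt2)
  expect_equal(unname(grp[c("A1", "A2")]), rep("quick", 2))
  expect_equal(unname(grp[c("B1", "B2")]), rep("medium", 2))
  expect_equal(unname(grp[c("C1", "C2")]), rep("slow", 2))
  # invariant to input order
  grp2 <- cluster_speed_groups(profiles[c(5, 3, 1, 6, 2, 4)], k = 3,
                               time_to_2mm = tt2)
  expect_equal(grp2[names(grp)], grp, ignore_attr = TRUE)

  expect_equal(unname(cluster_speed_groups(profiles[1:2], k = 1)),
               rep("medium", 2), ignore_attr = TRUE)
  expect_error(cluster_speed_groups(profiles[1:2], k = 3), "k exceeds")
})

test_that("profiles average uncensored seeds and flag low support", {
  t <- 0:20
  df <- data.frame(seed = rep(1:4, each = 21), hour = rep(t, 4),
                   length_mm = rep(t * 0.3, 4))
  p <- build_profile(df)
  expect_equal(p$mean_length_mm, t * 0.3)
  expect_false(attr(p, "low_support"))
  expect_true(all(p$band_lo <= p$mean_length_mm + 1e-9))
  p2 <- build_profile(df[df$seed <= 2, ])
  expect_true(attr(p2, "low_support"))
})

test_that("event-time clustering separates designed families", {
  set.seed(31)
  ev <- c(lapply(1:3, function(i) rnorm(20, 30, 1)),
          lapply(1:3, function(i) rnorm(20, 48, 2)),
          lapply(1:3, function(i) rnorm(20, 70, 3)))
  names(ev) <- paste0("G", 1:9)
  grp <- cluster_event_times(ev)
  expect_equal(unname(grp[1:3]), rep("quick", 3))
  expect_equal(unname(grp[4:6]), rep("medium", 3))
  expect_equal(unname(grp[7:9]), rep("slow", 3))
  same <- cluster_event_times(list(a = rep(40, 10), b = rep(40, 10)))
  expect_true(all(same == "medium") || length(unique(same)) == 1)
})

test_that("vigor matrix: exact arithmetic and monotonicity", {
  sg <- expand.grid(genotype = c("A", "B"), phase = c("PRO", "RE", "SE"),
                    stringsAsFactors = FALSE)
  sg$group <- ifelse(sg$genotype == "A", "quick", "medium")
  un <- sg[, 1:2]; un$uniformity <- 0.5; un$n_censored <- 0
  vm <- vigor_matrix(sg, un)
  expect_equal(vm$matrix$phase_score,
               vm$matrix$points * vm$matrix$uniformity)
  a <- vm$overall$overall_score[vm$overall$genotype == "A"]
  expect_equal(a, 3 * 0.5 * 3)

  # dominance: improving a phase never lowers the overall score
  un2 <- un; un2$uniformity[un2$genotype == "B"] <- 0.7
  vm2 <- vigor_matrix(sg, un2)
  expect_gte(vm2$overall$overall_score[vm2$overall$genotype == "B"],
             vm$overall$overall_score[vm$overall$genotype == "B"])

  # a missing phase contributes zero and is flagged
  un3 <- un[-1, ]
  vm3 <- vigor_matrix(sg, un3)
  expect_true(any(vm3$matrix$flagged))
})

test_that("the three designed vigor tiers are recovered end-to-end", {
  ev <- simulate_vigor_events(rng_seed = 1)
  v <- vigor_from_events(ev)
  ov <- merge(v$overall, unique(ev[, c("genotype", "designed_tier")]),
              by = "genotype")
  expect_equal(mean(ov$overall_class == ov$designed_tier), 1)
})

test_that("affinity propagation finds exemplar clusters and is deterministic", {
  set.seed(77)
  x <- rbind(matrix(rnorm(20, 0, 0.3), ncol = 2),
             matrix(rnorm(20, 6, 0.3), ncol = 2),
             matrix(rnorm(20, 12, 0.3), ncol = 2))
  ap <- affinity_propagation(x)
  expect_true(ap$converged)
  expect_equal(length(unique(ap$cluster)), 3)
  expect_equal(as.vector(tapply(seq_len(30), ap$cluster, function(i)
    length(unique((i - 1) %/% 10)))), rep(1, 3))
  ap2 <- affinity_propagation(x)
  expect_identical(ap$cluster, ap2$cluster)
})
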