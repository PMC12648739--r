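## Ground-truthed synthetic germination time-lapse simulator.
##
## Seeds are ellipses on a coloured germination paper that swell during
## imbibition; each root grows along a jittered polyline whose arc length
## follows a logistic law anchored at a stochastic emergence hour;
## seedlings appear as blobs at the seed apex and later turn green. Frames
## render to RGB with Gaussian pixel noise, label maps render noise-free,
## and every quantity is recorded as exact ground truth.

with_seed <- function(seed, code) {
  old <- if (exists(".Random.seed", .GlobalEnv)) get(".Random.seed", .GlobalEnv) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, .GlobalEnv)
          else suppressWarnings(rm(".Random.seed", envir = .GlobalEnv)))
  set.seed(seed)
  force(code)
}

paper_rgb <- list(blue = c(45, 90, 190), black = c(30, 30, 32),
                  dark_red = c(120, 30, 40), light_blue = c(150, 200, 230))
seed_rgb <- c(150, 110, 70)
root_rgb <- c(230, 225, 210)
seedling_pale_rgb <- c(205, 195, 150)
seedling_green_rgb <- c(90, 170, 80)

#' Simulator configuration
#'
#' Defaults emulate the wheat study conditions: hourly frames for 96 h at
#' 0.05 mm/px (seeds of ~5,000 px), seeds on blue paper in a grid, radicle
#' emergence around the 40th hour followed by up to two lateral roots,
#' logistic length growth, coleoptile appearance and greening within the
#' 96-h horizon for most seeds.
#'
#' @param rng_seed integer seed; the simulation is deterministic given it.
#' @param n_rows,n_cols seed grid.
#' @param cell_px square cell side per seed, px.
#' @param n_frames,interval_h,scale_mm_per_px acquisition geometry.
#' @param paper_color germination-paper colour.
#' @param root_params list (one entry per root R1..R3) of lists with
#'   `p` (presence probability), `t_mean`, `t_sd` (emergence hour),
#'   `lmax_mm`, `lmax_sd`, `rate` (logistic rate /h), `rate_sd`,
#'   `m0` (hours from emergence to inflection), `m0_sd`.
#' @param fan_deg roots head within this fan (degrees) around straight
#'   down; `fan_center_deg` offsets the fan (used to steer crossings).
#' @param jitter_deg per-2-px-step heading jitter (sd, degrees).
#' @param crossing_probability probability that a seed's radicle is
#'   steered to cross its right-hand neighbour's radicle exactly once.
#' @param swell_area_factor imbibition area multiplier reached at
#'   `swell_end_h` hours.
#' @param seedling_delay_mean,seedling_delay_sd hours from radicle
#'   emergence to coleoptile appearance.
#' @param green_delay_mean,green_delay_sd hours from coleoptile appearance
#'   to chloroplast biogenesis (greening).
#' @param noise_sd Gaussian pixel noise, 8-bit units (RGB only).
#' @return a `sim_config` list.
#' @export
sim_config <- function(rng_seed = 1L, n_rows = 4, n_cols = 4, cell_px = 400,
                       n_frames = 96, interval_h = 1, scale_mm_per_px = 0.05,
                       paper_color = "blue",
                       root_params = list(
                         list(p = 1.0, t_mean = 40, t_sd = 5, lmax_mm = 13.5,
                              lmax_sd = 0.8, rate = 0.12, rate_sd = 0.015,
                              m0 = 16, m0_sd = 2),
                         list(p = 0.7, t_mean = 52, t_sd = 6, lmax_mm = 7,
                              lmax_sd = 0.8, rate = 0.12, rate_sd = 0.015,
                              m0 = 14, m0_sd = 2),
                         list(p = 0.4, t_mean = 60, t_sd = 6, lmax_mm = 5,
                              lmax_sd = 0.6, rate = 0.12, rate_sd = 0.015,
                              m0 = 12, m0_sd = 2)),
                       fan_deg = 70, fan_center_deg = 0, jitter_deg = 2,
                       crossing_probability = 0,
                       swell_area_factor = 1.3, swell_end_h = 20,
                       seedling_delay_mean = 26, seedling_delay_sd = 4,
                       green_delay_mean = 12, green_delay_sd = 3,
                       noise_sd = 8) {
  stopifnot(n_frames >= 2, crossing_probability >= 0, crossing_probability <= 1)
  cfg <- as.list(environment())
  # layout check: the longest root plus the seed must fit a cell (seeds sit
  # at row 70 of their cell; individual length draws are clamped to
  # lmax_mm + 1)
  max_reach <- max(vapply(root_params, function(r) r$lmax_mm + 1,
                          numeric(1))) / scale_mm_per_px
  if (70 + 36 + max_reach > cell_px - 2)
    stop("layout overflow: grid too dense for the configured root lengths")
  structure(cfg, class = "sim_config")
}

logistic_len <- function(hour, t_e, lmax, rate, m0) {
  tau <- hour - t_e
  s0 <- 1 / (1 + exp(rate * m0))
  l <- lmax * (1 / (1 + exp(-rate * (tau - m0))) - s0) / (1 - s0)
  ifelse(tau < 0, 0, pmax(0, l))
}

# point on the ellipse boundary in direction u (unit, rows/cols) from centre
ellipse_boundary <- function(center, axes, theta, u) {
  e1 <- c(-cos(theta), sin(theta))   # (row, col) of the major-axis direction
  e2 <- c(sin(theta), cos(theta))
  k <- 1 / sqrt((sum(u * e1) / axes[1])^2 + (sum(u * e2) / axes[2])^2)
  center + u * k
}

gen_polyline <- function(start, heading0_deg, total_len_px, jitter_deg,
                         max_dev_deg = 55, ds = 2) {
  n <- max(2L, ceiling(total_len_px / ds) + 1L)
  dev <- cumsum(stats::rnorm(n - 1, 0, jitter_deg))
  dev <- pmax(pmin(dev, max_dev_deg), -max_dev_deg)
  ang <- (heading0_deg + dev) * pi / 180
  # clockwise-from-12 convention: angle 0 = up; roots head "down" at 180
  steps <- cbind(-cos(ang), sin(ang)) * ds
  pts <- rbind(start, cbind(start[1] + cumsum(steps[, 1]),
                            start[2] + cumsum(steps[, 2])))
  list(pts = pts, cumlen = c(0, seq_len(n - 1) * ds))
}

seg_intersection <- function(p1, p2, q1, q2) {
  d1 <- p2 - p1; d2 <- q2 - q1
  den <- d1[1] * d2[2] - d1[2] * d2[1]
  if (abs(den) < 1e-12) return(NULL)
  s <- ((q1[1] - p1[1]) * d2[2] - (q1[2] - p1[2]) * d2[1]) / den
  u <- ((q1[1] - p1[1]) * d1[2] - (q1[2] - p1[2]) * d1[1]) / den
  if (s < 0 || s > 1 || u < 0 || u > 1) return(NULL)
  c(s = s, u = u)
}

polyline_crossing <- function(pl_a, pl_b) {
  # first geometric intersection between two polylines; arc lengths at it
  na <- nrow(pl_a$pts); nb <- nrow(pl_b$pts)
  for (i in seq_len(na - 1)) {
    for (j in seq_len(nb - 1)) {
      hit <- seg_intersection(pl_a$pts[i, ], pl_a$pts[i + 1, ],
                              pl_b$pts[j, ], pl_b$pts[j + 1, ])
      if (!is.null(hit))
        return(c(pl_a$cumlen[i] + hit[["s"]] * (pl_a$cumlen[i + 1] - pl_a$cumlen[i]),
                 pl_b$cumlen[j] + hit[["u"]] * (pl_b$cumlen[j + 1] - pl_b$cumlen[j])))
    }
  }
  NULL
}

#' Simulate a ground-truthed germination lot
#'
#' Deterministic given `cfg$rng_seed`. See [sim_config()] for the
#' generative model. Label maps and RGB frames are produced on demand by
#' [sim_label_source()] and [sim_rgb_frame()]; ground truth (per-root
#' emergence frames and per-frame true lengths, per-seed event hours,
#' crossing events, per-frame seed morphology) is stored in `$truth`.
#'
#' @param cfg a [sim_config()].
#' @return a `sim_lot` object; `$rois` holds per-seed [seed_roi()] boxes,
#'   `$truth$lengths` / `$truth$events` / `$truth$crossings` the truth
#'   tables.
#' @export
simulate_lot <- function(cfg = sim_config()) {
  with_seed(cfg$rng_seed, {
    n_seed <- cfg$n_rows * cfg$n_cols
    H <- cfg$n_rows * cfg$cell_px; W <- cfg$n_cols * cfg$cell_px
    hours <- (seq_len(cfg$n_frames) - 1) * cfg$interval_h
    px_per_mm <- 1 / cfg$scale_mm_per_px
    seeds <- vector("list", n_seed)
    lengths <- list(); events <- list(); crossings <- list()
    # steering: non-overlapping horizontal pairs (left member at even grid
    # column) may be steered toward each other to cross exactly once
    steer <- rep(0L, n_seed); cross_pairs <- list()
    for (s in seq_len(n_seed)) {
      gc <- (s - 1) %% cfg$n_cols
      if (gc %% 2 == 0 && gc < cfg$n_cols - 1 &&
          stats::runif(1) < cfg$crossing_probability) {
        steer[s] <- 1L; steer[s + 1L] <- -1L
        cross_pairs[[length(cross_pairs) + 1L]] <- c(s, s + 1L)
      }
    }
    for (s in seq_len(n_seed)) {
      gr <- (s - 1) %/% cfg$n_cols; gc <- (s - 1) %% cfg$n_cols
      center <- c(gr * cfg$cell_px + 70 + stats::runif(1, -6, 6),
                  gc * cfg$cell_px + cfg$cell_px / 2 + 60 * steer[s] +
                    stats::runif(1, -6, 6))
      axes0 <- c(30, 20) * stats::runif(1, 0.92, 1.08)   # semi-axes, px
      theta <- stats::runif(1, -0.5, 0.5)                # near-horizontal seed
      swell <- sqrt(cfg$swell_area_factor)
      # which roots exist; emergence hours sorted so R1 is earliest
      present <- which(stats::runif(length(cfg$root_params)) <=
                       vapply(cfg$root_params, function(r) r$p, numeric(1)))
      te <- sort(vapply(present, function(k) {
        rp <- cfg$root_params[[k]]
        min(max(rp$t_mean + stats::rnorm(1, 0, rp$t_sd), 8), cfg$n_frames - 10)
      }, numeric(1)))
      crossing_here <- steer[s] != 0L
      base_head <- 180 + cfg$fan_center_deg +
        stats::runif(1, -cfg$fan_deg / 2 + 15, cfg$fan_deg / 2 - 15)
      if (crossing_here) {
        base_head <- 180 - 55 * steer[s]  # head toward the partner
        # desynchronise the pair so the crossing forms on an existing root
        te[1] <- max(10, te[1] - 6 * steer[s])
      }
      roots <- list()
      for (ri in seq_along(present)) {
        rp <- cfg$root_params[[present[ri]]]
        head0 <- if (ri == 1) base_head else {
          side <- if (ri == 2) 1 else -1
          base_head + side * stats::runif(1, 28, 45)
        }
        lmax_mm_i <- min(max(rp$lmax_mm + stats::rnorm(1, 0, rp$lmax_sd),
                             max(0.5, rp$lmax_mm - 2)), rp$lmax_mm + 1)
        lmax_px <- lmax_mm_i * px_per_mm
        u <- c(-cos(head0 * pi / 180), sin(head0 * pi / 180))
        start <- ellipse_boundary(center, axes0 * swell, theta, u) + 0.5 * u
        pl <- gen_polyline(start, head0, lmax_px,
                           if (crossing_here && ri == 1) cfg$jitter_deg / 2 else cfg$jitter_deg)
        roots[[ri]] <- list(index = ri, t_e_hour = te[ri],
                            lmax_px = lmax_px,
                            rate = max(0.05, rp$rate + stats::rnorm(1, 0, rp$rate_sd)),
                            m0 = max(6, rp$m0 + stats::rnorm(1, 0, rp$m0_sd)),
                            polyline = pl, heading0 = head0)
      }
      # seedling
      appear_h <- if (length(roots)) round(roots[[1]]$t_e_hour +
        max(8, stats::rnorm(1, cfg$seedling_delay_mean, cfg$seedling_delay_sd))) else NA
      green_h <- if (!is.na(appear_h)) round(appear_h +
        max(3, stats::rnorm(1, cfg$green_delay_mean, cfg$green_delay_sd))) else NA
      if (!is.na(appear_h) && appear_h > max(hours)) appear_h <- NA
      if (!is.na(appear_h) && !is.na(green_h) && green_h > max(hours)) green_h <- NA
      if (is.na(appear_h)) green_h <- NA
      seeds[[s]] <- list(id = s, center = center, axes0 = axes0, theta = theta,
                         roots = roots, appear_h = appear_h, green_h = green_h,
                         crossing_steered = crossing_here)
      # truth lengths per root per frame
      for (r in roots) {
        lmm <- logistic_len(hours, r$t_e_hour, r$lmax_px * cfg$scale_mm_per_px,
                            r$rate, r$m0)
        te_frame <- which(lmm * px_per_mm >= 1)[1]
        lengths[[length(lengths) + 1L]] <- data.frame(
          seed = s, root = r$index, frame = seq_len(cfg$n_frames),
          hour = hours, length_mm = lmm)
        seeds[[s]]$roots[[r$index]]$t_e_frame <- te_frame
      }
      r1 <- if (length(roots)) {
        lmm1 <- logistic_len(hours, roots[[1]]$t_e_hour,
                             roots[[1]]$lmax_px * cfg$scale_mm_per_px,
                             roots[[1]]$rate, roots[[1]]$m0)
        list(pro = hours[which(lmm1 * px_per_mm >= 1)[1]],
             re = { i <- which(lmm1 >= 2); if (length(i)) hours[i[1]] else NA },
             est = { i <- which(lmm1 >= 10); if (length(i)) hours[i[1]] else NA })
      } else list(pro = NA, re = NA, est = NA)
      events[[s]] <- data.frame(seed = s, pro_h = r1$pro, re_h = r1$re,
                                est_h = r1$est, coleoptile_h = appear_h,
                                chloroplast_h = green_h)
    }
    # crossing events between steered neighbours (radicle vs radicle)
    for (pr in cross_pairs) {
      a <- seeds[[pr[1]]]; b <- seeds[[pr[2]]]
      if (!length(a$roots) || !length(b$roots)) next
      hit <- polyline_crossing(a$roots[[1]]$polyline, b$roots[[1]]$polyline)
      if (is.null(hit)) next
      la <- logistic_len(hours, a$roots[[1]]$t_e_hour,
                         a$roots[[1]]$lmax_px * cfg$scale_mm_per_px,
                         a$roots[[1]]$rate, a$roots[[1]]$m0) / cfg$scale_mm_per_px
      lb <- logistic_len(hours, b$roots[[1]]$t_e_hour,
                         b$roots[[1]]$lmax_px * cfg$scale_mm_per_px,
                         b$roots[[1]]$rate, b$roots[[1]]$m0) / cfg$scale_mm_per_px
      fr <- which(la >= hit[1] & lb >= hit[2])
      if (length(fr))
        crossings[[length(crossings) + 1L]] <- data.frame(
          seed_a = pr[1], seed_b = pr[2], frame = fr[1],
          s_a = unname(hit[1]), s_b = unname(hit[2]))
    }
    rois <- lapply(seq_len(n_seed), function(s) {
      gr <- (s - 1) %/% cfg$n_cols; gc <- (s - 1) %% cfg$n_cols
      pad_l <- if (length(cross_pairs) && any(vapply(cross_pairs, function(p) p[2] == s, logical(1)))) 80L else 0L
      pad_r <- if (length(cross_pairs) && any(vapply(cross_pairs, function(p) p[1] == s, logical(1)))) 80L else 0L
      seed_roi(s, c(gr * cfg$cell_px, max(0L, gc * cfg$cell_px - pad_l),
                    (gr + 1) * cfg$cell_px,
                    min(W, (gc + 1) * cfg$cell_px + pad_r)))
    })
    structure(list(cfg = cfg, seeds = seeds, dims = c(H, W), hours = hours,
                   rois = rois,
                   truth = list(lengths = do.call(rbind, lengths),
                                events = do.call(rbind, events),
                                crossings = if (length(crossings))
                                  do.call(rbind, crossings) else
                                  data.frame(seed_a = integer(0), seed_b = integer(0),
                                             frame = integer(0), s_a = numeric(0),
                                             s_b = numeric(0)))),
              class = "sim_lot")
  })
}

## Drawing helpers operate in place on an environment holding the label
## matrix (`env$m`): patching small sub-windows avoids copying the full
## frame on every primitive.

patch_ellipse <- function(env, center, axes, theta, value, over = NULL) {
  .draw_ellipse_ip(env$m, as.numeric(center), as.numeric(axes), theta,
                   as.integer(value),
                   if (is.null(over)) integer(0) else as.integer(over))
  invisible(env)
}

patch_segment <- function(env, p0, p1, halfwidth, value, over = 0L) {
  .draw_segment_ip(env$m, as.numeric(p0), as.numeric(p1), halfwidth,
                   as.integer(value), as.integer(over))
  invisible(env)
}

seedling_center <- function(seed, cfg) {
  apex <- seed$axes0[1] * sqrt(cfg$swell_area_factor)
  seed$center + c(-(apex + 6), 0)   # overlaps the seed apex
}

#' Incremental label-map source for a simulated lot
#'
#' Returns a function `f(frame)` producing the lot's full label map at a
#' frame. Sequential (non-decreasing) access draws only the increments
#' (new root growth, swelling, seedling appearance); random access replays
#' from the start.
#'
#' @param lot a `sim_lot`.
#' @return function of the frame index.
#' @export
sim_label_source <- function(lot) {
  cfg <- lot$cfg
  px_per_mm <- 1 / cfg$scale_mm_per_px
  cache <- new.env()
  reset <- function() {
    cache$m <- matrix(0L, lot$dims[1], lot$dims[2])
    cache$t <- 0L
    cache$drawn <- lapply(lot$seeds, function(sd)
      list(root_len = rep(0, length(sd$roots)), seedling = FALSE))
  }
  reset()
  function(frame) {
    stopifnot(frame >= 1, frame <= cfg$n_frames)
    if (frame < cache$t) reset()
    while (cache$t < frame) {
      t2 <- cache$t + 1L
      hour <- lot$hours[t2]
      for (si in seq_along(lot$seeds)) {
        sd <- lot$seeds[[si]]
        if (hour <= cfg$swell_end_h + cfg$interval_h) {
          f <- 1 + (cfg$swell_area_factor - 1) * min(1, hour / cfg$swell_end_h)
          patch_ellipse(cache, sd$center, sd$axes0 * sqrt(f), sd$theta, 1L)
        }
        st <- cache$drawn[[si]]
        for (ri in seq_along(sd$roots)) {
          r <- sd$roots[[ri]]
          lpx <- logistic_len(hour, r$t_e_hour, r$lmax_px * cfg$scale_mm_per_px,
                              r$rate, r$m0) * px_per_mm
          if (lpx < 1 || lpx <= st$root_len[ri]) next
          pl <- r$polyline
          i0 <- max(1L, findInterval(st$root_len[ri], pl$cumlen))
          i1 <- min(nrow(pl$pts) - 1L, findInterval(lpx, pl$cumlen))
          for (i in i0:i1) {
            pfrac0 <- pl$pts[i, ]
            pfrac1 <- if (pl$cumlen[i + 1] <= lpx) pl$pts[i + 1, ] else {
              a <- (lpx - pl$cumlen[i]) / (pl$cumlen[i + 1] - pl$cumlen[i])
              pl$pts[i, ] + a * (pl$pts[i + 1, ] - pl$pts[i, ])
            }
            patch_segment(cache, pfrac0, pfrac1, 1.5, 2L, over = 0L)
          }
          st$root_len[ri] <- lpx
        }
        if (!st$seedling && !is.na(sd$appear_h) && hour >= sd$appear_h) {
          patch_ellipse(cache, seedling_center(sd, cfg), c(14, 6), 0, 3L,
                        over = c(0L, 1L))
          st$seedling <- TRUE
        }
        cache$drawn[[si]] <- st
      }
      cache$t <- t2
    }
    # return a copy so the cached matrix stays unshared and subsequent
    # patches modify it in place instead of duplicating the whole frame
    cache$m + 0L
  }
}

#' Render one RGB frame of a simulated lot
#'
#' Colours each label class (paper, seed coat, root, seedling) with its
#' albedo; the seedling colour ramps from pale to green over 3 h around
#' the seed's greening hour; Gaussian pixel noise is added unless
#' `noise = FALSE`. Deterministic for a given lot, frame, and noise seed.
#'
#' @param lot a `sim_lot`.
#' @param frame frame index.
#' @param labels optional precomputed label map for this frame.
#' @param noise add Gaussian noise of sd `cfg$noise_sd`.
#' @return H x W x 3 array, 0..255.
#' @export
sim_rgb_frame <- function(lot, frame, labels = NULL, noise = TRUE) {
  cfg <- lot$cfg
  if (is.null(labels)) labels <- sim_label_source(lot)(frame)
  d <- dim(labels)
  px <- array(0, c(d, 3))
  base <- paper_rgb[[cfg$paper_color]]
  hour <- lot$hours[frame]
  for (k in 1:3) {
    ch <- matrix(base[k], d[1], d[2])
    ch[labels == 1L] <- seed_rgb[k]
    ch[labels == 2L] <- root_rgb[k]
    px[, , k] <- ch
  }
  if (any(labels == 3L)) {
    # per-seed greening ramp
    for (sd in lot$seeds) {
      if (is.na(sd$appear_h) || hour < sd$appear_h) next
      g <- if (!is.na(sd$green_h) && hour >= sd$green_h) 1 else 0
      col3 <- (1 - g) * seedling_pale_rgb + g * seedling_green_rgb
      cen <- seedling_center(sd, cfg)
      rr <- max(1, floor(cen[1] - 20)):min(d[1], ceiling(cen[1] + 20))
      cc <- max(1, floor(cen[2] - 20)):min(d[2], ceiling(cen[2] + 20))
      for (k in 1:3) {
        sub <- px[rr, cc, k]
        sub[labels[rr, cc] == 3L] <- col3[k]
        px[rr, cc, k] <- sub
      }
    }
  }
  if (noise && cfg$noise_sd > 0) {
    px <- px + with_seed(cfg$rng_seed * 1000L + frame,
                         array(stats::rnorm(length(px), 0, cfg$noise_sd), dim(px)))
  }
  pmax(pmin(px, 255), 0)
}

#' Named simulation presets
#'
#' `"no-crossings"`: the default 4 x 4 lot with independent seeds.
#' `"one-crossing"`: a 2 x 2 lot whose radicles are steered so each
#' horizontal pair crosses exactly once (only radicles are grown).
#' `"three-tier-vigor"`: 21 genotypes in three designed vigor tiers,
#' generated at the event level by [simulate_vigor_events()].
#'
#' @param name preset name.
#' @param rng_seed seed passed through to the config.
#' @return a `sim_config` (or, for `"three-tier-vigor"`, a list with
#'   `preset` and `rng_seed` consumed by [simulate_vigor_events()]).
#' @export
sim_preset <- function(name = c("no-crossings", "one-crossing", "three-tier-vigor"),
                       rng_seed = 1L) {
  name <- match.arg(name)
  switch(name,
    "no-crossings" = sim_config(rng_seed = rng_seed),
    "one-crossing" = sim_config(
      rng_seed = rng_seed, n_rows = 2, n_cols = 2,
      crossing_probability = 1,
      root_params = list(list(p = 1.0, t_mean = 38, t_sd = 4, lmax_mm = 12,
                              lmax_sd = 0.6, rate = 0.13, rate_sd = 0.01,
                              m0 = 15, m0_sd = 1.5)),
      seedling_delay_mean = 200),   # no seedlings in the crossing scenes
    "three-tier-vigor" = list(preset = "three-tier-vigor", rng_seed = rng_seed))
}

#' Event-level three-tier vigor scenario
#'
#' Generates per-seed phase-entry hours (PRO, RE, SE) for 21 genotypes in
#' three designed tiers of 7: fast-uniform (early, tight), middling, and
#' slow-dispersed (late, wide, with SE censoring past the horizon).
#'
#' @param rng_seed integer seed.
#' @param n_genotypes number of genotypes (multiple of 3).
#' @param n_seeds seeds per genotype (the standardized 15 by default).
#' @param horizon_h monitoring horizon; later events are censored.
#' @return data frame `genotype, designed_tier, seed, pro_h, re_h, se_h`.
#' @export
simulate_vigor_events <- function(rng_seed = 1L, n_genotypes = 21,
                                  n_seeds = 40, horizon_h = 96) {
  stopifnot(n_genotypes %% 3 == 0)
  per <- n_genotypes / 3
  with_seed(rng_seed, {
    tiers <- rep(c("high", "medium", "low"), each = per)
    out <- list()
    for (g in seq_len(n_genotypes)) {
      tier <- tiers[g]
      p <- switch(tier,
        high   = list(mu = stats::rnorm(1, 30, 1.5), sd = stats::runif(1, 0.75, 0.85),
                      lag_re = 5, lag_se = 18),
        medium = list(mu = stats::rnorm(1, 42, 2.0), sd = stats::runif(1, 1.5, 1.7),
                      lag_re = 8, lag_se = 24),
        low    = list(mu = stats::rnorm(1, 52, 3.0), sd = stats::runif(1, 3.8, 4.2),
                      lag_re = 11, lag_se = 30))
      pro <- round(stats::rnorm(n_seeds, p$mu, p$sd))
      re <- round(pro + p$lag_re + stats::rnorm(n_seeds, 0, p$sd))
      se <- round(re + p$lag_se + stats::rnorm(n_seeds, 0, 1.5 * p$sd))
      cens <- function(x) ifelse(x > horizon_h, NA_real_, x)
      out[[g]] <- data.frame(genotype = sprintf("G%02d", g),
                             designed_tier = tier, seed = seq_len(n_seeds),
                             pro_h = cens(pro), re_h = cens(pmax(re, pro)),
                             se_h = cens(pmax(se, re)))
    }
    do.call(rbind, out)
  })
}

#' Ground-truth tables in the pipeline's output schemas
#'
#' Emits the simulator's truth in the same column layout as the pipeline's
#' `lengths.csv` and `events.csv`, so recovery tests are column-wise
#' diffs.
#'
#' @param lot a `sim_lot`.
#' @return list of data frames `lengths` and `events`.
#' @export
truth_tables <- function(lot) {
  tl <- lot$truth$lengths
  lengths <- data.frame(seed_id = tl$seed, root_index = tl$root,
                        frame = tl$frame, hour = tl$hour,
                        length_mm = tl$length_mm)
  ev <- lot$truth$events
  events <- data.frame(seed_id = ev$seed, protrusion_h = ev$pro_h,
                       germination_2mm_h = ev$re_h,
                       establishment_10mm_h = ev$est_h,
                       coleoptile_h = ev$coleoptile_h,
                       chloroplast_h = ev$chloroplast_h)
  list(lengths = lengths, events = events)
}
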