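unit_vec <- function(v) {
  n <- sqrt(sum(v^2))
  if (n < 1e-12) c(0, 0) else v / n
}

vec_angle_deg <- function(a, b) {
  d <- sum(unit_vec(a) * unit_vec(b))
  acos(max(-1, min(1, d))) * 180 / pi
}

# geodesic (step-count) distances from seed pixels over a skeleton window
bfs_steps <- function(mask, seeds) {
  d <- matrix(NA_integer_, nrow(mask), ncol(mask))
  if (!nrow(seeds)) return(d)
  d[seeds] <- 0L
  frontier <- seeds
  step <- 0L
  nr <- nrow(mask); nc <- ncol(mask)
  while (nrow(frontier)) {
    step <- step + 1L
    nxt <- NULL
    for (i in seq_len(nrow(frontier))) {
      r <- frontier[i, 1]; c <- frontier[i, 2]
      for (dr in -1:1) for (dc in -1:1) {
        if (dr == 0 && dc == 0) next
        rr <- r + dr; cc <- c + dc
        if (rr < 1 || cc < 1 || rr > nr || cc > nc) next
        if (mask[rr, cc] && is.na(d[rr, cc])) {
          d[rr, cc] <- step
          nxt <- rbind(nxt, c(rr, cc))
        }
      }
    }
    frontier <- if (is.null(nxt)) matrix(integer(0), 0, 2) else nxt
  }
  d
}

#' Detect crossing regions in a root skeleton
#'
#' One region per (equivalent) branch point: the skeleton around the centre
#' is cut into arms, and each arm's direction is the unit vector from the
#' centre to the skeleton point `arm_len_px` steps along that arm (or to
#' the arm's end if shorter). Direction estimated over a short window is
#' robust to local wiggle, unlike a vector all the way to the root tip.
#' Regions with 3 or 4 arms are returned; larger tangles are excluded (and
#' counted), matching the known limitation on complex root intersections.
#'
#' @param skel a `skeleton_graph`.
#' @param arm_len_px window length for arm direction estimation.
#' @param core_radius_px pixels this close to the centre(s) form the region
#'   core and belong to no arm.
#' @return list of `crossing_region` objects: `center`, `arms` (list of
#'   `dir`, `end`), `order`.
#' @export
detect_crossing_regions <- function(skel, arm_len_px = 15, core_radius_px = 2) {
  regions <- list()
  centers <- list()
  grouped <- matrix(numeric(0), 0, 2)
  for (e in skel$equiv_points) {
    centers[[length(centers) + 1L]] <- list(point = e$point, members = e$members)
    grouped <- rbind(grouped, e$members)
  }
  # clusters of >2 mutually close branch points (a thick crossing can thin
  # into several): one candidate region at the cluster centroid
  for (tg in skel$tangles) {
    centers[[length(centers) + 1L]] <- list(point = colMeans(tg), members = tg)
    grouped <- rbind(grouped, tg)
  }
  if (nrow(skel$branch_points)) {
    for (i in seq_len(nrow(skel$branch_points))) {
      bp <- skel$branch_points[i, ]
      if (nrow(grouped) &&
          any(grouped[, 1] == bp[1] & grouped[, 2] == bp[2])) next
      centers[[length(centers) + 1L]] <- list(point = as.numeric(bp),
                                              members = rbind(bp))
    }
  }
  nr <- nrow(skel$mask); nc <- ncol(skel$mask)
  pad <- arm_len_px + core_radius_px + 3
  for (ct in centers) {
    cen <- ct$point
    r0 <- max(1, floor(cen[1]) - pad); r1 <- min(nr, ceiling(cen[1]) + pad)
    c0 <- max(1, floor(cen[2]) - pad); c1 <- min(nc, ceiling(cen[2]) + pad)
    win <- skel$mask[r0:r1, c0:c1, drop = FALSE]
    # core: skeleton pixels within core radius of any member point
    wp <- coords_of(win)
    if (!nrow(wp)) next
    mem <- cbind(ct$members[, 1] - r0 + 1, ct$members[, 2] - c0 + 1)
    core_d <- apply(wp, 1, function(p)
      min(sqrt((p[1] - mem[, 1])^2 + (p[2] - mem[, 2])^2)))
    core_px <- wp[core_d <= core_radius_px + 0.5, , drop = FALSE]
    arm_mask <- win
    arm_mask[core_px] <- FALSE
    if (!any(arm_mask)) next
    steps <- bfs_steps(win, core_px)
    lab <- .label8(arm_mask)
    cen_w <- c(cen[1] - r0 + 1, cen[2] - c0 + 1)
    arms <- list()
    for (k in sort(unique(lab[lab > 0]))) {
      ak <- coords_of(lab == k)
      sk_steps <- steps[ak]
      if (all(is.na(sk_steps))) next          # not attached to the core
      if (min(sk_steps, na.rm = TRUE) > core_radius_px + 1) next
      want <- min(arm_len_px, max(sk_steps, na.rm = TRUE))
      cand <- ak[which.min(abs(sk_steps - want)), ]
      dirv <- unit_vec(c(cand[1] - cen_w[1], cand[2] - cen_w[2]))
      arms[[length(arms) + 1L]] <- list(
        dir = dirv, end = c(cand[1] + r0 - 1, cand[2] + c0 - 1))
    }
    if (length(arms) %in% c(3L, 4L))
      regions[[length(regions) + 1L]] <- structure(
        list(center = cen, arms = arms, order = length(arms)),
        class = "crossing_region")
  }
  regions
}

pairings4 <- list(list(c(1, 2), c(3, 4)), list(c(1, 3), c(2, 4)),
                  list(c(1, 4), c(2, 3)))

#' Resolve a crossing region into arm continuations
#'
#' Arms are paired with preference for pair angles closest to 180 degrees
#' (a root passes through a crossing roughly straight). For a 4-arm region
#' the two disjoint pairs minimising the summed deviation from 180 degrees
#' are returned; for a 3-arm region the single best pair, with the third
#' arm left unpaired (a root terminus or origin). When the best and
#' second-best pairings differ by under `ambiguity_deg`, the most likely
#' growth directions recorded from previous frames (`prev_dirs`) break the
#' tie by directional consistency.
#'
#' @param region a `crossing_region`.
#' @param prev_dirs optional list of unit direction vectors of the tracks
#'   involved (last recorded growth directions).
#' @param ambiguity_deg ambiguity threshold between pairing scores.
#' @return list with `pairs` (list of index pairs into `region$arms`),
#'   `unpaired` (indices), and `score` (summed |angle - 180|).
#' @export
resolve_crossing <- function(region, prev_dirs = NULL, ambiguity_deg = 5) {
  arms <- region$arms
  k <- length(arms)
  angles <- function(i, j) vec_angle_deg(arms[[i]]$dir, arms[[j]]$dir)
  if (k == 3) {
    cand <- list(c(1, 2), c(1, 3), c(2, 3))
    dev <- vapply(cand, function(p) abs(angles(p[1], p[2]) - 180), numeric(1))
    best <- which.min(dev)
    return(list(pairs = list(cand[[best]]),
                unpaired = setdiff(1:3, cand[[best]]), score = dev[best]))
  }
  if (k != 4) stop("resolve_crossing handles 3- and 4-arm regions only")
  dev <- vapply(pairings4, function(pp)
    abs(angles(pp[[1]][1], pp[[1]][2]) - 180) +
    abs(angles(pp[[2]][1], pp[[2]][2]) - 180), numeric(1))
  # the summed deviation ties exactly between the two "crossed" pairings
  # whenever all arms fall in a half-circle; break ties by the pairing whose
  # single best pair is most collinear, then by pairing order
  best_single <- vapply(pairings4, function(pp)
    min(abs(angles(pp[[1]][1], pp[[1]][2]) - 180),
        abs(angles(pp[[2]][1], pp[[2]][2]) - 180)), numeric(1))
  ord <- order(round(dev, 6), round(best_single, 6))
  best <- ord[1]
  if (!is.null(prev_dirs) && length(prev_dirs) &&
      dev[ord[2]] - dev[ord[1]] < ambiguity_deg) {
    # consistency: for each candidate pairing, the best alignment between a
    # previous growth direction entering one arm and leaving its partner
    consistency <- vapply(pairings4, function(pp) {
      max(vapply(prev_dirs, function(pd) {
        max(vapply(pp, function(pr) {
          max(sum(-arms[[pr[1]]]$dir * pd) * sum(arms[[pr[2]]]$dir * pd),
              sum(-arms[[pr[2]]]$dir * pd) * sum(arms[[pr[1]]]$dir * pd))
        }, numeric(1)))
      }, numeric(1)))
    }, numeric(1))
    near <- which(dev - dev[ord[1]] < ambiguity_deg)
    best <- near[which.max(consistency[near])]
  }
  list(pairs = pairings4[[best]], unpaired = integer(0), score = dev[best])
}

# Does a route that enters a resolved region along direction d_in (pointing
# toward the centre) and leaves along d_out (pointing away) follow a paired
# continuation? Arms are matched by nearest direction.
crossing_pass_allowed <- function(region, resolution, d_in, d_out) {
  dirs <- vapply(region$arms, function(a) a$dir, numeric(2))
  arm_in <- which.max(colSums(dirs * (-unit_vec(d_in))))
  arm_out <- which.max(colSums(dirs * unit_vec(d_out)))
  if (arm_in == arm_out) return(TRUE)   # grazing touch, not a traversal
  any(vapply(resolution$pairs, function(p)
    setequal(p, c(arm_in, arm_out)), logical(1)))
}
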