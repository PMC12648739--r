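#' Tracking configuration
#'
#' Parameters of the temporal-graph root-tip tracker. The defaults follow
#' the method's stated settings: a candidate tip is accepted when its route
#' from the current tip has minimum weight (skeleton pixels weigh 0, all
#' others 1, 8-connected) and the turn angle is at most 60 degrees
#' (`cos_min = 0.5`); a 90-degree gate (`cos_min = 0`) is available for
#' side-view imagery conventions.
#'
#' @param cos_min minimum cosine between the previous growth direction and
#'   the direction to the candidate (0.5 = 60 degrees).
#' @param no_new_tracks_after_crossing once any crossing involves a seed's
#'   roots, newly emerged roots of that seed are not tracked.
#' @param max_missed_frames consecutive frames a tip may go undetected
#'   before the track is closed; within the cap, candidates are matched
#'   against the last accepted vertex under the same rules.
#' @param step_weights `"corrected"` (default) measures route length with
#'   the corner-corrected chain estimator `0.980 n_axial + 1.406 n_diag -
#'   0.091 n_corner`, which is unbiased to <1% on digital lines at any
#'   orientation; `"freeman"` uses raw steps of 1 and sqrt(2).
#' @param dir_min_px growth direction is taken tip-to-tip between accepted
#'   vertices; to avoid 8-neighbour quantisation noise at slow growth, the
#'   reference vertex is the most recent one at least this far back (0
#'   uses strictly the previous vertex).
#' @param max_tracks_per_seed roots tracked per seed (radicle + laterals).
#' @param dilation_px seed-coat/seedling overlap margin for tip detection.
#' @param min_root_px smallest root-mask component treated as a root.
#' @param max_route_weight candidates whose minimum-weight route costs more
#'   than this many off-skeleton pixels are not continuations of this root
#'   (guards against jumping onto another root's disjoint skeleton);
#'   `Inf` disables the guard.
#' @return a `track_config` list.
#' @export
track_config <- function(cos_min = 0.5, no_new_tracks_after_crossing = TRUE,
                         max_missed_frames = 5,
                         step_weights = c("corrected", "freeman"),
                         dir_min_px = 4, max_tracks_per_seed = 3,
                         dilation_px = 3, min_root_px = 3,
                         max_route_weight = 3) {
  stopifnot(cos_min >= -1, cos_min <= 1)
  structure(list(cos_min = cos_min,
                 no_new_tracks_after_crossing = no_new_tracks_after_crossing,
                 max_missed_frames = max_missed_frames,
                 step_weights = match.arg(step_weights),
                 dir_min_px = dir_min_px,
                 max_tracks_per_seed = max_tracks_per_seed,
                 dilation_px = dilation_px, min_root_px = min_root_px,
                 max_route_weight = max_route_weight),
            class = "track_config")
}

#' Measure the geometric length of a pixel path
#'
#' Only steps lying on the skeleton (both endpoints skeleton pixels) are
#' counted, as the off-skeleton part of a route is a search artefact, not
#' root. `"freeman"` counts 1 per axial and sqrt(2) per diagonal step;
#' `"corrected"` additionally applies the corner-corrected coefficients
#' (0.980, 1.406, -0.091 per direction change), removing the orientation-
#' dependent overestimation inherent to raw chain codes.
#'
#' @param path m x 2 matrix of (row, col) pixel coordinates.
#' @param on_mask logical matrix marking skeleton pixels; `NULL` counts
#'   every step.
#' @param step_weights `"corrected"` or `"freeman"`.
#' @return length in pixels.
#' @export
path_length_px <- function(path, on_mask = NULL,
                           step_weights = c("corrected", "freeman")) {
  step_weights <- match.arg(step_weights)
  m <- nrow(path)
  if (m < 2) return(0)
  dr <- diff(path[, 1]); dc <- diff(path[, 2])
  on <- if (is.null(on_mask)) rep(TRUE, m - 1) else
    on_mask[path[-m, , drop = FALSE]] & on_mask[path[-1, , drop = FALSE]]
  diag_step <- dr != 0 & dc != 0
  if (step_weights == "freeman")
    return(sum(on & !diag_step) + sqrt(2) * sum(on & diag_step))
  # corners: direction changes between consecutive counted steps
  dirs <- paste(dr, dc)
  ons <- which(on)
  n_corner <- if (length(ons) > 1)
    sum(dirs[ons[-length(ons)]] != dirs[ons[-1]] &
        diff(ons) == 1L) else 0L
  0.980 * sum(on & !diag_step) + 1.406 * sum(on & diag_step) -
    0.091 * n_corner
}

#' Initialise a root's temporal tracking graph
#'
#' Before emergence the graph is empty; at `t_e - 1` it holds only the
#' skeleton point at the seed coat (the root origin); accepted tip
#' positions and connecting skeleton routes accumulate from `t_e` on.
#'
#' @param seed_id seed identifier.
#' @param t_e emergence frame (1-based; first frame the root's skeleton
#'   touches the seed coat).
#' @param origin `(row, col)` skeleton point at the seed coat.
#' @param n_frames total frames in the series.
#' @return a `tracking_graph`.
#' @export
init_track <- function(seed_id, t_e, origin, n_frames, base_px = 0) {
  structure(list(seed_id = seed_id, root_index = NA_integer_, t_e = t_e,
                 origin = as.numeric(origin), base_px = base_px,
                 vertices = matrix(numeric(0), 0, 3,
                                   dimnames = list(NULL, c("frame", "row", "col"))),
                 length_px = rep(0, n_frames),
                 closed = FALSE, closed_frame = NA_integer_,
                 missed = 0L, last_dir = NULL),
            class = "tracking_graph")
}

track_last_vertex <- function(g) {
  if (nrow(g$vertices)) g$vertices[nrow(g$vertices), 2:3] else g$origin
}

track_dir <- function(g, dir_min_px) {
  nv <- nrow(g$vertices)
  if (nv == 0) return(NULL)
  cur <- g$vertices[nv, 2:3]
  pts <- rbind(g$origin, g$vertices[-nv, 2:3, drop = FALSE])
  for (i in rev(seq_len(nrow(pts)))) {
    v <- cur - pts[i, ]
    if (sqrt(sum(v^2)) >= max(dir_min_px, 1e-9)) return(unit_vec(v))
  }
  unit_vec(cur - pts[1, ])
}

#' Extend a tracking graph by one frame
#'
#' Among the candidate tips, the one minimising the weighted route cost
#' from the current tip (on-skeleton pixels cost 0, others 1, 8-connected
#' uniform-cost search; geometric length breaks ties) is accepted, subject
#' to the turn-angle gate `cos(prev dir, new dir) >= cos_min` and, where
#' the route traverses a resolved crossing, to following a paired
#' continuation. If no candidate qualifies the graph is unchanged and zero
#' growth is recorded for the frame.
#'
#' @param g a `tracking_graph` (not closed).
#' @param cands n x 2 matrix of candidate tip positions for this frame.
#' @param skel the frame's `skeleton_graph`.
#' @param cfg a [track_config()].
#' @param frame current frame index.
#' @param regions,resolutions crossing regions of this frame and their
#'   [resolve_crossing()] results (optional).
#' @return the updated graph; `attr(, "accepted")` holds the accepted
#'   candidate row index or `NA`.
#' @export
extend_track <- function(g, cands, skel, cfg, frame,
                         regions = NULL, resolutions = NULL) {
  carry <- function(gg) {
    if (frame > 1) gg$length_px[frame] <- gg$length_px[frame - 1]
    attr(gg, "accepted") <- NA_integer_
    gg
  }
  if (g$closed || is.null(cands) || nrow(cands) == 0) {
    g <- carry(g)
    if (!g$closed) g$missed <- g$missed + 1L
    return(g)
  }
  v <- track_last_vertex(g)
  # candidates at (or next to) the current tip are a stationary re-detection,
  # not growth: exclude them, but remember the tip was seen
  d2 <- sqrt((cands[, 1] - v[1])^2 + (cands[, 2] - v[2])^2)
  tip_seen <- any(d2 <= 1)
  keep_idx <- which(d2 > 1)
  cands <- cands[keep_idx, , drop = FALSE]
  if (nrow(cands) == 0) {
    g <- carry(g)
    g$missed <- if (tip_seen) 0L else g$missed + 1L
    return(g)
  }
  # route search restricted to the bounding box of skeleton, source, and
  # candidates: for 0/1 node weights, clamping any path into this box never
  # increases its weight, so the restriction is cost-exact
  vi <- as.integer(round(v))
  # re-thinning shifts the skeleton by ~1 px frame to frame; snap the route
  # source to the nearest skeleton pixel (lateral drift, not growth) so the
  # on-skeleton length accounting does not leak at the segment start
  near <- which(abs(skel$pixels[, 1] - vi[1]) <= 3 &
                abs(skel$pixels[, 2] - vi[2]) <= 3)
  if (length(near)) {
    d2n <- (skel$pixels[near, 1] - v[1])^2 + (skel$pixels[near, 2] - v[2])^2
    vi <- as.integer(skel$pixels[near[which.min(d2n)], ])
  }
  ori <- as.integer(round(g$origin))
  rr <- range(c(skel$pixels[, 1], vi[1], cands[, 1], ori[1]))
  cc <- range(c(skel$pixels[, 2], vi[2], cands[, 2], ori[2]))
  r0 <- max(1L, rr[1] - 1L); r1 <- min(nrow(skel$mask), rr[2] + 1L)
  c0 <- max(1L, cc[1] - 1L); c1 <- min(ncol(skel$mask), cc[2] + 1L)
  sub <- skel$mask[r0:r1, c0:c1, drop = FALSE]
  rt <- .grid_route(sub, vi[1] - r0 + 1L, vi[2] - c0 + 1L)
  cands_w <- cbind(cands[, 1] - r0 + 1L, cands[, 2] - c0 + 1L)
  prev <- g$last_dir
  w <- rt$weight[cands_w]; glen <- rt$glen[cands_w]
  ok <- !is.na(w) & w <= cfg$max_route_weight
  if (!is.null(prev)) {
    cosv <- vapply(seq_len(nrow(cands)), function(i) {
      dv <- unit_vec(c(cands[i, 1] - v[1], cands[i, 2] - v[2]))
      sum(dv * prev)
    }, numeric(1))
    ok <- ok & cosv >= cfg$cos_min
  }
  if (!any(ok)) {
    g <- carry(g)
    g$missed <- if (tip_seen) 0L else g$missed + 1L
    return(g)
  }
  ord <- order(w, glen)
  ord <- ord[ok[ord]]
  for (i in ord) {
    path <- .route_path(rt$parent, cands_w[i, 1], cands_w[i, 2])
    path <- cbind(path[, 1] + r0 - 1L, path[, 2] + c0 - 1L)
    if (!is.null(regions) && length(regions) &&
        !route_respects_crossings(path, regions, resolutions,
                                  prev_dir = prev)) next
    g$vertices <- rbind(g$vertices, c(frame, cands[i, 1], cands[i, 2]))
    # cumulative length: the accepted routes tile the origin -> tip skeleton
    # path, so measure it in one piece each frame; summing many short noisy
    # segments would accumulate tip-position noise as spurious length
    snap_o <- which(abs(skel$pixels[, 1] - ori[1]) <= 3 &
                    abs(skel$pixels[, 2] - ori[2]) <= 3)
    o2 <- if (length(snap_o)) {
      d2o <- (skel$pixels[snap_o, 1] - ori[1])^2 +
             (skel$pixels[snap_o, 2] - ori[2])^2
      as.integer(skel$pixels[snap_o[which.min(d2o)], ])
    } else ori
    rto <- .grid_route(sub, o2[1] - r0 + 1L, o2[2] - c0 + 1L)
    path_o <- .route_path(rto$parent, cands_w[i, 1], cands_w[i, 2])
    path_o <- cbind(path_o[, 1] + r0 - 1L, path_o[, 2] + c0 - 1L)
    total <- path_length_px(path_o, skel$mask, cfg$step_weights) +
      (if (!is.null(g$base_px)) g$base_px else 0)
    g$length_px[frame] <- max(total,
                              if (frame > 1) g$length_px[frame - 1] else 0)
    g$last_dir <- track_dir(g, cfg$dir_min_px)
    g$missed <- 0L
    attr(g, "accepted") <- keep_idx[i]
    return(g)
  }
  g <- carry(g)
  g$missed <- if (tip_seen) 0L else g$missed + 1L
  g
}

# check every resolved crossing the path traverses; when the route starts
# at (or next to) the crossing centre, the track's previous growth
# direction stands in for the entry direction
route_respects_crossings <- function(path, regions, resolutions, win = 6,
                                     prev_dir = NULL) {
  for (ri in seq_along(regions)) {
    cen <- regions[[ri]]$center
    d <- sqrt((path[, 1] - cen[1])^2 + (path[, 2] - cen[2])^2)
    i <- which.min(d)
    if (d[i] > 2.5) next
    j_out <- min(nrow(path), i + win)
    if (j_out <= i) next                 # route ends at the centre
    d_out <- c(path[j_out, 1] - cen[1], path[j_out, 2] - cen[2])
    if (i > 3) {
      j_in <- max(1, i - win)
      d_in <- c(cen[1] - path[j_in, 1], cen[2] - path[j_in, 2])
    } else if (!is.null(prev_dir)) {
      d_in <- prev_dir
    } else next                          # no usable entry direction
    if (!crossing_pass_allowed(regions[[ri]], resolutions[[ri]], d_in, d_out))
      return(FALSE)
  }
  TRUE
}

#' Cumulative tracked root length
#'
#' Sum of the accepted routes' on-skeleton lengths up to a frame, converted
#' to millimetres. Non-decreasing in the frame index; zero before the
#' emergence frame.
#'
#' @param g a `tracking_graph`.
#' @param upto_frame frame index (1-based).
#' @param scale_mm_per_px spatial scale.
#' @return length in mm.
#' @export
cumulative_length <- function(g, upto_frame, scale_mm_per_px) {
  if (upto_frame < g$t_e - 1 || upto_frame < 1) return(0)
  g$length_px[min(upto_frame, length(g$length_px))] * scale_mm_per_px
}

#' Growth rate and rate-derivative series
#'
#' Lengths are smoothed by a centred moving average, then differentiated
#' by centred finite differences over the frame interval. Applying the
#' same operator to the rate yields its derivative; the time of the
#' fastest rate change is the argmax of |derivative|.
#'
#' @param lengths_mm per-frame cumulative lengths (non-decreasing).
#' @param interval_h hours between frames.
#' @param smooth_window moving-average window in frames (shrunk, with a
#'   warning, if the series is shorter).
#' @return data frame with `rate_mm_per_h`, `rate_derivative`, and
#'   attribute `fastest_change_frame`.
#' @export
growth_rate_series <- function(lengths_mm, interval_h = 1, smooth_window = 5) {
  n <- length(lengths_mm)
  if (smooth_window > n) {
    warning("smoothing window longer than series; shrunk to series length")
    smooth_window <- n
  }
  smooth <- function(x) {
    k <- max(1L, as.integer(smooth_window))
    stats::filter(x, rep(1 / k, k), sides = 2) |>
      as.numeric() |>
      (\(y) { y[is.na(y)] <- x[is.na(y)]; y })()
  }
  cdiff <- function(x) {
    d <- numeric(n)
    if (n >= 3) d[2:(n - 1)] <- (x[3:n] - x[1:(n - 2)]) / (2 * interval_h)
    if (n >= 2) { d[1] <- (x[2] - x[1]) / interval_h
                  d[n] <- (x[n] - x[n - 1]) / interval_h }
    d
  }
  rate <- cdiff(smooth(lengths_mm))
  deriv <- cdiff(smooth(rate))
  out <- data.frame(frame = seq_len(n), rate_mm_per_h = rate,
                    rate_derivative = deriv)
  attr(out, "fastest_change_frame") <- which.max(abs(deriv))
  out
}

#' Track all roots of one seed through a frame series
#'
#' Runs the complete per-seed tracking loop: per frame, root-mask
#' skeletonisation products are scanned for seed-adjacent components (new
#' roots), crossing regions are resolved, and every open track is extended
#' by the minimum-weight route rule. Once any crossing involves the seed's
#' roots, no new tracks are opened (existing ones continue through resolved
#' crossings). A track closes when its tip reaches the ROI border or goes
#' undetected past the missed-frame cap. Root indices (1 = radicle) are
#' assigned by emergence order with the clockwise-angle tie-break.
#'
#' @param triplets list (per frame) of `mask_triplet` for this seed's ROI,
#'   or a function of the frame index returning one.
#' @param cfg a [track_config()].
#' @param seed_id id stored on the returned graphs.
#' @param n_frames number of frames (required when `triplets` is a
#'   function).
#' @param active optional logical vector: frames with no root pixels may be
#'   flagged `FALSE` and are skipped without building masks.
#' @return list of `tracking_graph`, ordered by root index.
#' @export
track_seed <- function(triplets, cfg = track_config(), seed_id = 1L,
                       n_frames = NULL, active = NULL) {
  get_tri <- if (is.function(triplets)) triplets else function(t) triplets[[t]]
  nf <- if (is.function(triplets)) n_frames else length(triplets)
  stopifnot(!is.null(nf))
  tracks <- list()
  crossing_seen <- FALSE
  claim_radius <- 8
  sb_union <- NULL
  aux_cache <- new.env()
  for (t in seq_len(nf)) {
    if (!is.null(active) && !active[t]) next
    tri <- get_tri(t)
    sb_union <- if (is.null(sb_union)) tri$seed_body else sb_union | tri$seed_body
    root_mask <- tri$full_plant & !tri$seed_body & !tri$seedling
    root_mask <- drop_small(root_mask, cfg$min_root_px)
    if (!any(root_mask)) next
    skel <- skeletonize_mask(root_mask)
    # seed body and seedling are static most of the series: cache the
    # dilated exclusion mask and seed distance map keyed on pixel counts
    key <- c(sum(tri$seed_body), sum(tri$seedling))
    if (is.null(aux_cache$key) || !identical(aux_cache$key, key)) {
      aux_cache$excl <- dilate_mask(tri$seed_body, cfg$dilation_px) |
                        dilate_mask(tri$seedling, cfg$dilation_px)
      aux_cache$dm <- seed_distmap(tri$seed_body)
      aux_cache$key <- key
    }
    det <- detect_root_tips(skel, tri, cfg$dilation_px,
                            excl = aux_cache$excl, dm = aux_cache$dm)
    regions <- detect_crossing_regions(skel)
    if (length(regions) || length(skel$tangles)) crossing_seen <- TRUE
    prev_dirs <- Filter(Negate(is.null), lapply(tracks, function(g) g$last_dir))
    resolutions <- lapply(regions, resolve_crossing, prev_dirs = prev_dirs)
    # open new tracks at seed-adjacent components not claimed yet
    may_open <- length(tracks) < cfg$max_tracks_per_seed &&
      !(crossing_seen && cfg$no_new_tracks_after_crossing)
    if (may_open && nrow(det$origins)) {
      for (i in seq_len(nrow(det$origins))) {
        o <- det$origins[i, ]
        claimed <- any(vapply(tracks, function(g)
          sqrt(sum((g$origin - o)^2)) <= claim_radius, logical(1)))
        if (!claimed && length(tracks) < cfg$max_tracks_per_seed)
          tracks[[length(tracks) + 1L]] <- init_track(
            seed_id, t, o, nf,
            base_px = max(0, aux_cache$dm[o[1], o[2]] - 0.5))
      }
    }
    if (!length(tracks)) next
    # extend open tracks; a tip accepted by one track is unavailable to the next
    taken <- integer(0)
    for (k in seq_along(tracks)) {
      g <- tracks[[k]]
      if (g$closed) next
      avail <- setdiff(seq_len(nrow(det$tips)), taken)
      cands <- det$tips[avail, , drop = FALSE]
      g <- extend_track(g, cands, skel, cfg, t, regions, resolutions)
      acc <- attr(g, "accepted")
      if (!is.na(acc)) taken <- c(taken, avail[acc])
      if (g$missed > cfg$max_missed_frames) {
        g$closed <- TRUE; g$closed_frame <- t
      }
      # close when the tip reaches the ROI border
      v <- track_last_vertex(g)
      d <- dim(tri$seed_body)
      if (!g$closed && (v[1] <= 2 || v[2] <= 2 || v[1] >= d[1] - 1 || v[2] >= d[2] - 1)) {
        g$closed <- TRUE; g$closed_frame <- t
      }
      tracks[[k]] <- g
    }
  }
  # carry cumulative lengths over trailing frames with no root mask
  for (k in seq_along(tracks)) {
    lp <- tracks[[k]]$length_px
    for (t in seq_len(nf)[-1]) if (lp[t] < lp[t - 1]) lp[t] <- lp[t - 1]
    tracks[[k]]$length_px <- lp
  }
  if (!length(tracks)) return(tracks)
  # radicle = earliest emergence; ties by clockwise angle from the centroid
  centroid <- if (!is.null(sb_union) && any(sb_union))
    colMeans(coords_of(sb_union)) else dim(get_tri(1)$seed_body) / 2
  first_pos <- t(vapply(tracks, function(g)
    if (nrow(g$vertices)) g$vertices[1, 2:3] else g$origin, numeric(2)))
  ids <- assign_emergence_order(vapply(tracks, function(g) g$t_e, numeric(1)),
                                first_pos, centroid)
  for (k in seq_along(tracks)) tracks[[k]]$root_index <- ids[k]
  tracks[order(ids)]
}
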