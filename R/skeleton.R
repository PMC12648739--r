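coords_of <- function(mask) {
  w <- which(mask, arr.ind = TRUE)
  colnames(w) <- c("row", "col")
  w
}

#' Clockwise angle from 12 o'clock
#'
#' Angle of the vector `from -> to` measured clockwise from straight up
#' (image convention: rows grow downward), in degrees 0..360.
#' @param from,to length-2 `(row, col)` points.
#' @export
clock_angle <- function(from, to) {
  (atan2(to[2] - from[2], -(to[1] - from[1])) * 180 / pi) %% 360
}

#' Skeletonize a binary mask and annotate its topology
#'
#' Topology-preserving Zhang-Suen thinning reduces the mask to a 1-px-wide
#' skeleton; endpoints (exactly one 8-neighbour on the skeleton) and branch
#' points (>= 3 such neighbours) are classified from 8-neighbour counts.
#' Pairs of branch points lying within `merge_radius` pixels of each other
#' are merged into an equivalent branch point at their midpoint (a thick
#' crossing thins into two nearby Y-junctions rather than one X-junction);
#' clusters of more than two mutually close branch points are reported in
#' `$tangles` and excluded from crossing resolution.
#'
#' @param mask logical matrix.
#' @param merge_radius px radius within which two branch points collapse to
#'   one equivalent branch point (default 5, about one root width).
#' @return a `skeleton_graph`: list with `mask` (logical skeleton),
#'   `pixels`, `endpoints`, `branch_points` (coordinate matrices),
#'   `equiv_points` (list of `point`/`members`), `tangles`.
#' @export
skeletonize_mask <- function(mask, merge_radius = 5) {
  stopifnot(is.matrix(mask))
  mode(mask) <- "logical"
  if (!any(mask)) {
    empty <- matrix(integer(0), 0, 2, dimnames = list(NULL, c("row", "col")))
    return(structure(list(mask = mask, pixels = empty, endpoints = empty,
                          branch_points = empty, equiv_points = list(),
                          tangles = list()),
                     class = "skeleton_graph"))
  }
  # thin within the mask's bounding box (plus a 1-px halo) and embed the
  # result back; thinning cost then scales with the object, not the ROI
  w <- which(mask, arr.ind = TRUE)
  r0 <- max(1L, min(w[, 1]) - 1L); r1 <- min(nrow(mask), max(w[, 1]) + 1L)
  c0 <- max(1L, min(w[, 2]) - 1L); c1 <- min(ncol(mask), max(w[, 2]) + 1L)
  sub <- .thin_zs(mask[r0:r1, c0:c1, drop = FALSE])
  sk <- mask & FALSE
  sk[r0:r1, c0:c1] <- sub
  nbs <- .nbr_count(sub)
  off <- function(m) if (nrow(m)) cbind(row = m[, 1] + r0 - 1L,
                                        col = m[, 2] + c0 - 1L) else m
  px <- off(coords_of(sub))
  ends <- off(coords_of(sub & nbs == 1L))
  bps <- off(coords_of(sub & nbs >= 3L))
  equiv <- list(); tangles <- list()
  if (nrow(bps) >= 2) {
    d <- as.matrix(stats::dist(bps))
    close_to <- lapply(seq_len(nrow(bps)), function(i)
      setdiff(which(d[i, ] <= merge_radius), i))
    used <- rep(FALSE, nrow(bps))
    for (i in seq_len(nrow(bps))) {
      if (used[i] || !length(close_to[[i]])) next
      grp <- sort(unique(c(i, unlist(close_to[c(i, close_to[[i]])]))))
      grp <- grp[!used[grp]]
      if (length(grp) == 2) {
        equiv[[length(equiv) + 1L]] <- list(
          point = colMeans(bps[grp, , drop = FALSE]),
          members = bps[grp, , drop = FALSE])
      } else if (length(grp) > 2) {
        tangles[[length(tangles) + 1L]] <- bps[grp, , drop = FALSE]
      }
      used[grp] <- TRUE
    }
  }
  structure(list(mask = sk, pixels = px, endpoints = ends,
                 branch_points = bps, equiv_points = equiv,
                 tangles = tangles),
            class = "skeleton_graph")
}

seed_distmap <- function(seed_body) {
  if (!any(seed_body)) return(matrix(Inf, nrow(seed_body), ncol(seed_body)))
  as.matrix(EBImage::distmap(EBImage::Image(1 - seed_body * 1)))
}

dilate_mask <- function(mask, px) {
  if (px <= 0 || !any(mask)) return(mask)
  as_mask(EBImage::dilate(EBImage::Image(mask * 1),
                          EBImage::makeBrush(2 * px + 1, shape = "disc")))
}

#' Detect root tips and root origins in a seed's skeleton
#'
#' Root tips are skeleton endpoints that fall outside the dilated seed-body
#' and seedling masks (skeleton fragments overlapping the seed coat or
#' seedling are not tips). For every connected skeleton component that
#' approaches the seed coat, the skeleton pixel with minimum distance to
#' the seed body is recorded as that root's origin candidate (the point
#' connecting the root to the seed coat).
#'
#' @param skel a `skeleton_graph` of the root mask.
#' @param triplet the seed's `mask_triplet`.
#' @param dilation_px dilation margin applied to seed body and seedling
#'   before the overlap test (guards against seed-boundary roughness).
#' @param origin_max_dist_px a component only yields an origin if it comes
#'   within this distance of the seed body.
#' @param excl,dm optional precomputed exclusion mask (dilated seed body |
#'   seedling) and distance map to the seed body, for callers that cache
#'   them across frames.
#' @return list with `tips` (n x 2 coordinate matrix), `origins` (m x 2,
#'   one per seed-adjacent component), and `tip_component` /
#'   `origin_component` component labels linking them.
#' @export
detect_root_tips <- function(skel, triplet, dilation_px = 3,
                             origin_max_dist_px = 6, excl = NULL, dm = NULL) {
  empty <- matrix(numeric(0), 0, 2, dimnames = list(NULL, c("row", "col")))
  if (!nrow(skel$pixels))
    return(list(tips = empty, origins = empty,
                tip_component = integer(0), origin_component = integer(0)))
  if (is.null(excl))
    excl <- dilate_mask(triplet$seed_body, dilation_px) |
            dilate_mask(triplet$seedling, dilation_px)
  keep <- !excl[skel$endpoints]
  # endpoints at the ROI border are clipping artefacts, not root tips
  d <- dim(skel$mask)
  keep <- keep & skel$endpoints[, 1] > 2 & skel$endpoints[, 2] > 2 &
          skel$endpoints[, 1] < d[1] - 1 & skel$endpoints[, 2] < d[2] - 1
  tips <- skel$endpoints[keep, , drop = FALSE]
  comp <- .label8(skel$mask)
  tip_comp <- comp[tips]
  # distance of every pixel to the seed body
  if (is.null(dm)) dm <- seed_distmap(triplet$seed_body)
  origins <- NULL; origin_comp <- integer(0)
  for (k in sort(unique(comp[comp > 0]))) {
    pk <- coords_of(comp == k & skel$mask)
    dk <- dm[pk]
    if (min(dk) <= origin_max_dist_px) {
      origins <- rbind(origins, pk[which.min(dk), ])
      origin_comp <- c(origin_comp, k)
    }
  }
  if (is.null(origins)) origins <- empty
  list(tips = tips, origins = origins,
       tip_component = tip_comp, origin_component = origin_comp)
}

#' Number roots by emergence order
#'
#' Root 1 is the radicle (earliest first-seen frame); ties are broken by
#' clockwise angle from the seed centroid starting at 12 o'clock. Tip
#' identity across frames is the tracking module's job; this operation only
#' assigns the R1/R2/R3 indices.
#'
#' @param first_seen_frame integer vector, one entry per root.
#' @param positions n x 2 matrix of first-seen tip positions.
#' @param centroid seed centroid `(row, col)`.
#' @return integer vector of tip ids (1 = radicle), same order as input.
#' @export
assign_emergence_order <- function(first_seen_frame, positions, centroid) {
  n <- length(first_seen_frame)
  if (n == 0L) return(integer(0))
  ang <- vapply(seq_len(n), function(i)
    clock_angle(centroid, positions[i, ]), numeric(1))
  ord <- order(first_seen_frame, ang)
  ids <- integer(n)
  ids[ord] <- seq_len(n)
  ids
}
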