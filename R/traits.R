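## Seed-level static and dynamic trait quantification.

# Douglas-Peucker polyline simplification (open polyline, returns indices)
dp_indices <- function(pts, tol) {
  n <- nrow(pts)
  if (n <= 2) return(seq_len(n))
  keep <- rep(FALSE, n); keep[c(1, n)] <- TRUE
  stack <- list(c(1, n))
  while (length(stack)) {
    seg <- stack[[length(stack)]]; stack[[length(stack)]] <- NULL
    i <- seg[1]; j <- seg[2]
    if (j - i < 2) next
    a <- pts[i, ]; b <- pts[j, ]
    ab <- b - a; L <- sqrt(sum(ab^2))
    idx <- (i + 1):(j - 1)
    d <- if (L < 1e-12) sqrt(rowSums((pts[idx, , drop = FALSE] -
                                      matrix(a, length(idx), 2, byrow = TRUE))^2))
         else abs((pts[idx, 1] - a[1]) * ab[2] - (pts[idx, 2] - a[2]) * ab[1]) / L
    k <- which.max(d)
    if (d[k] > tol) {
      m <- idx[k]; keep[m] <- TRUE
      stack <- c(stack, list(c(i, m), c(m, j)))
    }
  }
  which(keep)
}

poly_length <- function(pts, closed = TRUE) {
  if (closed) pts <- rbind(pts, pts[1, ])
  sum(sqrt(rowSums(diff(pts)^2)))
}

#' Perimeter of a binary object
#'
#' The ordered 8-connected boundary contour (through pixel centres) is
#' simplified by Douglas-Peucker (tolerance 1 px), removing the staircase
#' excess of raw chain codes; pi is added for the half-pixel outward offset
#' of a convex boundary. Recovers both smooth outlines (rasterised disk:
#' error < 2%) and polygonal ones (axis-aligned rectangle) without an
#' orientation-dependent bias.
#'
#' @param mask logical matrix with one object.
#' @return perimeter in pixels.
#' @export
mask_perimeter_px <- function(mask) {
  oc <- EBImage::ocontour(EBImage::bwlabel(mask * 1))
  if (!length(oc)) return(0)
  # take the longest contour (the object's outer boundary)
  pts <- oc[[which.max(vapply(oc, nrow, integer(1)))]] + 1
  if (nrow(pts) < 3) return(nrow(pts))
  # close-aware simplification: run DP on the chain split at its first point
  idx <- dp_indices(rbind(pts, pts[1, ]), tol = 1)
  poly_length(rbind(pts, pts[1, ])[idx, , drop = FALSE], closed = FALSE) + pi
}

largest_component <- function(mask) {
  lab <- .label8(mask)
  tab <- tabulate(lab[lab > 0])
  if (length(tab) <= 1) return(list(mask = mask, flagged = length(tab) == 0))
  list(mask = lab == which.max(tab), flagged = TRUE)
}

min_area_rect <- function(coords) {
  # rotating calipers over convex hull edges; +1 px for pixel extent
  h <- grDevices::chull(coords[, 2], coords[, 1])
  hp <- coords[h, , drop = FALSE]
  if (nrow(hp) == 1) return(c(length = 1, width = 1, angle = 0))
  best <- NULL
  edges <- rbind(hp, hp[1, ])
  for (i in seq_len(nrow(hp))) {
    e <- edges[i + 1, ] - edges[i, ]
    L <- sqrt(sum(e^2)); if (L < 1e-12) next
    u <- e / L; v <- c(-u[2], u[1])
    pu <- coords %*% u; pv <- coords %*% v
    du <- diff(range(pu)) + 1; dv <- diff(range(pv)) + 1
    if (is.null(best) || du * dv < best$area)
      best <- list(area = du * dv, length = max(du, dv), width = min(du, dv),
                   angle = atan2(u[1], u[2]) * 180 / pi)
  }
  c(length = best$length, width = best$width, angle = best$angle)
}

#' Seed morphology from the seed-body mask
#'
#' Area is the pixel count times scale^2; perimeter comes from
#' [mask_perimeter_px()]; length and width are the side lengths of the
#' minimum-area rotated bounding rectangle (length = longer side), making
#' the measures rotation-invariant; `wl_ratio = width / length`;
#' `roundness = 4 * pi * area / perimeter^2` (1 for a disk).
#'
#' @param seed_body logical mask (largest component is used, flagged, if
#'   several are present).
#' @param scale_mm_per_px spatial scale.
#' @return one-row data frame: `area_mm2, length_mm, width_mm,
#'   perimeter_mm, wl_ratio, roundness, flagged`; all `NA` (flagged) for an
#'   empty mask.
#' @export
measure_seed_morphology <- function(seed_body, scale_mm_per_px = 0.05) {
  if (!any(seed_body))
    return(data.frame(area_mm2 = NA_real_, length_mm = NA_real_,
                      width_mm = NA_real_, perimeter_mm = NA_real_,
                      wl_ratio = NA_real_, roundness = NA_real_,
                      flagged = TRUE))
  lc <- largest_component(seed_body)
  m <- lc$mask
  area_px <- sum(m)
  per_px <- mask_perimeter_px(m)
  rect <- min_area_rect(coords_of(m))
  s <- scale_mm_per_px
  data.frame(area_mm2 = area_px * s^2,
             length_mm = rect[["length"]] * s,
             width_mm = rect[["width"]] * s,
             perimeter_mm = per_px * s,
             wl_ratio = rect[["width"]] / rect[["length"]],
             roundness = 4 * pi * area_px / per_px^2,
             flagged = lc$flagged)
}

#' Mean seed-coat colour
#'
#' Arithmetic mean of the R, G, B channels over the mask pixels.
#' @param px H x W x 3 frame array (0..255).
#' @param mask logical matrix.
#' @return named numeric `c(R, G, B)`, `NA` for an empty mask.
#' @export
measure_seed_color <- function(px, mask) {
  if (!any(mask)) return(c(R = NA_real_, G = NA_real_, B = NA_real_))
  c(R = mean(px[, , 1][mask]), G = mean(px[, , 2][mask]),
    B = mean(px[, , 3][mask]))
}

#' Per-frame change rate relative to frame 1
#'
#' `100 * (v_t - v_1) / v_1`; all-`NA` when the first value is zero or
#' missing.
#' @param values numeric series.
#' @return percentage series.
#' @export
change_rate_percent <- function(values) {
  v0 <- values[1]
  if (is.na(v0) || v0 == 0) return(rep(NA_real_, length(values)))
  100 * (values - v0) / v0
}

#' Chloroplast-biogenesis greenness threshold
#'
#' Mean excess-green value over all seedling-mask pixels of the lot at the
#' reference hour (the 80th by convention). A per-seed variant is available
#' via `scope = "seed"`, in which case a vector of thresholds is returned.
#'
#' @param frames list of H x W x 3 frame arrays for the reference frame,
#'   one per seed ROI.
#' @param seedling_masks matching list of logical masks.
#' @param scope `"lot"` (one pooled threshold, default) or `"seed"`.
#' @return threshold(s); `NA` with a warning if no seedling pixels exist.
#' @export
chloroplast_threshold <- function(frames, seedling_masks, scope = c("lot", "seed")) {
  scope <- match.arg(scope)
  vals <- mapply(function(px, m) if (any(m)) exg(px)[m] else numeric(0),
                 frames, seedling_masks, SIMPLIFY = FALSE)
  if (scope == "seed")
    return(vapply(vals, function(v) if (length(v)) mean(v) else NA_real_,
                  numeric(1)))
  pooled <- unlist(vals)
  if (!length(pooled)) {
    warning("no seedling pixels at the reference hour; chloroplast times all censored")
    return(NA_real_)
  }
  mean(pooled)
}

#' Time of chloroplast biogenesis for one seed
#'
#' First hour at which the seed's seedling-mask pixels exceed the greenness
#' threshold. The literal "any pixel exceeds" rule is guarded by a minimum
#' exceedance count (default 5 px, shrunk to the mask size) to resist salt
#' noise.
#'
#' @param frames per-frame H x W x 3 arrays of the seed's ROI.
#' @param seedling_masks per-frame logical masks.
#' @param hours per-frame hours.
#' @param threshold greenness threshold from [chloroplast_threshold()].
#' @param min_exceed_px minimum number of exceeding pixels.
#' @return hour, or `NA` (censored) if never reached.
#' @export
chloroplast_time <- function(frames, seedling_masks, hours, threshold,
                             min_exceed_px = 5) {
  if (is.na(threshold)) return(NA_real_)
  for (t in seq_along(frames)) {
    m <- seedling_masks[[t]]
    if (!any(m)) next
    need <- min(min_exceed_px, sum(m))
    if (sum(exg(frames[[t]])[m] > threshold) >= need) return(hours[t])
  }
  NA_real_
}

#' Coleoptile-emergence time
#'
#' First hour at which the seedling mask overlaps (or, for single-label
#' maps whose classes are mutually exclusive by construction, touches
#' within 1 px of) the seed-body mask inside the ROI.
#' @param seedling_masks,seed_body_masks per-frame logical masks.
#' @param hours per-frame hours.
#' @return hour or `NA` (censored).
#' @export
coleoptile_time <- function(seedling_masks, seed_body_masks, hours) {
  for (t in seq_along(seedling_masks)) {
    m <- seedling_masks[[t]]
    if (!any(m)) next
    if (any(m & seed_body_masks[[t]]) ||
        any(dilate_mask(m, 1) & seed_body_masks[[t]])) return(hours[t])
  }
  NA_real_
}

#' First hour a root length reaches a target
#'
#' First-crossing convention at the frame grid (no sub-frame
#' interpolation): the hour of the first frame whose length is at or above
#' the target. 2 mm marks a germinated seed, 10 mm an established root
#' system.
#'
#' @param lengths_mm non-decreasing per-frame lengths.
#' @param hours per-frame hours.
#' @param target_mm target length.
#' @return hour or `NA` (censored).
#' @export
time_to_length <- function(lengths_mm, hours, target_mm) {
  i <- which(lengths_mm >= target_mm)
  if (!length(i)) return(NA_real_)
  hours[i[1]]
}

#' Lot-level phase time by the 75% rule
#'
#' A seed lot enters a phase at the first hour by which at least
#' `ceiling(threshold * n)` of its seeds have entered it. With the
#' standardized 15-seed sampling, that is 12 seeds. Censored seeds (`NA`)
#' never count as entered.
#'
#' @param entry_hours per-seed phase-entry hours (`NA` = never entered).
#' @param threshold fraction of the lot required (default 0.75).
#' @param sample_n optional standardized sample size (e.g. 15); a seeded
#'   uniform sample without replacement is taken when the lot is larger.
#' @param sample_seed RNG seed for the sampling, recorded as an attribute.
#' @return hour or `NA` (censored).
#' @export
lot_phase_time <- function(entry_hours, threshold = 0.75, sample_n = NULL,
                           sample_seed = 1L) {
  stopifnot(length(entry_hours) >= 1)
  if (!is.null(sample_n) && length(entry_hours) > sample_n) {
    entry_hours <- withr_seed_sample(entry_hours, sample_n, sample_seed)
  }
  n <- length(entry_hours)
  need <- ceiling(threshold * n)
  ok <- sort(entry_hours[!is.na(entry_hours)])
  out <- if (length(ok) >= need) ok[need] else NA_real_
  attr(out, "n") <- n
  attr(out, "sample_seed") <- if (!is.null(sample_n)) sample_seed else NULL
  out
}

withr_seed_sample <- function(x, n, seed) {
  old <- if (exists(".Random.seed", .GlobalEnv)) get(".Random.seed", .GlobalEnv) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, .GlobalEnv))
  set.seed(seed)
  x[sample.int(length(x), n)]
}
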