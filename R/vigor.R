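## Growth profiles, speed grouping, uniformity scoring, and the
## speed x uniformity vigor matrix.

#' Build a genotype's growth profile
#'
#' Per-hour mean radicle length over the genotype's uncensored seeds
#' (seeds that never germinated are counted as censored and excluded from
#' the mean), the corresponding mean growth rate, and a central dispersion
#' band (12.5-87.5 percentiles, the central 75%).
#'
#' @param lengths data frame with columns `seed`, `hour`, `length_mm`, one
#'   row per seed per hour, for one genotype.
#' @param interval_h hours between consecutive grid points.
#' @return data frame `hour, mean_length_mm, mean_rate_mm_per_h, band_lo,
#'   band_hi` with attributes `n_seeds`, `low_support`.
#' @export
build_profile <- function(lengths, interval_h = 1) {
  seeds <- unique(lengths$seed)
  hours <- sort(unique(lengths$hour))
  wide <- vapply(seeds, function(s) {
    x <- lengths[lengths$seed == s, ]
    x$length_mm[match(hours, x$hour)]
  }, numeric(length(hours)))
  wide <- matrix(wide, nrow = length(hours))
  mlen <- rowMeans(wide, na.rm = TRUE)
  band <- t(apply(wide, 1, stats::quantile, probs = c(0.125, 0.875),
                  na.rm = TRUE, names = FALSE))
  rate <- c(0, diff(mlen)) / interval_h
  out <- data.frame(hour = hours, mean_length_mm = mlen,
                    mean_rate_mm_per_h = rate,
                    band_lo = band[, 1], band_hi = band[, 2])
  attr(out, "n_seeds") <- length(seeds)
  attr(out, "low_support") <- length(seeds) < 3
  out
}

#' Cluster genotypes into germination-speed groups
#'
#' Agglomerative clustering (Ward linkage on Euclidean distance) of the
#' genotypes' mean length curves resampled to a common hour grid, cut into
#' `k` groups, which are labelled quick / medium / slow by ascending mean
#' time-to-2-mm (mean curve AUC ranks them when no times are available).
#'
#' @param profiles named list of profile data frames ([build_profile()]),
#'   one per genotype.
#' @param k number of groups (default 3; `k = 1` returns all-medium).
#' @param time_to_2mm optional named vector of per-genotype mean hours to
#'   2 mm used for labelling.
#' @return named character vector genotype -> group; attribute
#'   `degenerate` flags identical-curve inputs.
#' @export
cluster_speed_groups <- function(profiles, k = 3, time_to_2mm = NULL) {
  n <- length(profiles)
  if (k > n) stop("k exceeds the number of genotypes")
  geno <- names(profiles)
  hours <- sort(unique(unlist(lapply(profiles, function(p) p$hour))))
  curves <- t(vapply(profiles, function(p)
    stats::approx(p$hour, p$mean_length_mm, xout = hours, rule = 2)$y,
    numeric(length(hours))))
  if (k == 1) {
    out <- stats::setNames(rep("medium", n), geno)
    attr(out, "degenerate") <- FALSE
    return(out)
  }
  d <- stats::dist(curves)
  degenerate <- max(d) < 1e-9
  cl <- stats::cutree(stats::hclust(d, method = "ward.D2"), k = k)
  score <- if (!is.null(time_to_2mm)) {
    vapply(seq_len(k), function(g) mean(time_to_2mm[geno[cl == g]], na.rm = TRUE),
           numeric(1))
  } else {
    # larger area under the curve = faster growth = earlier rank
    -vapply(seq_len(k), function(g)
      mean(rowSums(curves[cl == g, , drop = FALSE])), numeric(1))
  }
  if (degenerate) score <- vapply(seq_len(k), function(g)
    min(which(cl == g)), numeric(1))
  lab <- c("quick", "medium", "slow", paste0("group", 4:10))[seq_len(k)]
  out <- stats::setNames(lab[rank(score, ties.method = "first")][cl], geno)
  attr(out, "degenerate") <- degenerate
  out
}

merge_groups_to3 <- function(cluster, centre, values) {
  # reduce >3 clusters to 3 by adjacency on the value axis: clusters are
  # ordered by centre and merged contiguously, choosing the 3-partition
  # minimising the within-group sum of squares of the member values
  k <- length(centre)
  if (k <= 3) return(cluster)
  ord <- order(centre)
  pos <- match(cluster, ord)        # contiguous rank of each item's cluster
  wss <- function(x) sum((x - mean(x))^2)
  best <- NULL; best_val <- Inf
  for (a in 1:(k - 2)) for (b in (a + 1):(k - 1)) {
    grp <- cut(pos, breaks = c(0, a, b, k), labels = FALSE)
    val <- sum(vapply(1:3, function(g) wss(values[grp == g]), numeric(1)))
    if (val < best_val) { best_val <- val; best <- grp }
  }
  best
}

#' Cluster genotypes by event-time distributions
#'
#' Affinity propagation on per-genotype summary vectors (median hour, IQR,
#' censored fraction) of an event-time distribution such as
#' chloroplast-biogenesis hours. Emerging clusters are ordered by median
#' hour into quick / medium / slow (merged down to 3 by median adjacency if
#' more emerge); non-convergence falls back, flagged, to a deterministic
#' 3-group partition.
#'
#' @param event_hours named list: genotype -> numeric event hours with `NA`
#'   for censored seeds.
#' @param horizon hour substituted for an all-censored median.
#' @return named character vector genotype -> group, with attributes
#'   `converged` and `n_clusters_raw`.
#' @export
cluster_event_times <- function(event_hours, horizon = 96) {
  stopifnot(length(event_hours) >= 2)
  geno <- names(event_hours)
  feat <- t(vapply(event_hours, function(h) {
    ok <- h[!is.na(h)]
    c(med = if (length(ok)) stats::median(ok) else horizon,
      iqr = if (length(ok) > 1) stats::IQR(ok) else 0,
      cens = mean(is.na(h)) * horizon / 4)
  }, numeric(3)))
  if (length(event_hours) == 2) {
    # two genotypes: message passing is degenerate; order them directly
    if (abs(feat[1, "med"] - feat[2, "med"]) < 1e-9)
      return(structure(stats::setNames(rep("medium", 2), geno),
                       converged = TRUE, n_clusters_raw = 1L))
    lab <- c("quick", "slow")[rank(feat[, "med"], ties.method = "first")]
    return(structure(stats::setNames(lab, geno),
                     converged = TRUE, n_clusters_raw = 2L))
  }
  ap <- affinity_propagation(feat)
  if (!ap$converged) ap <- kmedoid_fallback(feat, k = 3)
  cl <- ap$cluster
  med <- vapply(sort(unique(cl)), function(g) mean(feat[cl == g, "med"]),
                numeric(1))
  cl <- match(cl, sort(unique(cl)))
  cl <- merge_groups_to3(cl, med, feat[, "med"])
  med3 <- vapply(sort(unique(cl)), function(g) mean(feat[cl == g, "med"]),
                 numeric(1))
  cl <- match(cl, sort(unique(cl)))
  lab_all <- c("quick", "medium", "slow")
  k <- length(med3)
  lab <- if (k == 1) "medium" else if (k == 2) c("quick", "slow")[rank(med3, ties.method = "first")]
         else lab_all[rank(med3, ties.method = "first")]
  out <- stats::setNames(lab[cl], geno)
  attr(out, "converged") <- ap$converged
  attr(out, "n_clusters_raw") <- length(med)
  out
}

#' Uniformity score of event times
#'
#' The ratio of the modal-bin peak to the central 75% coverage of the
#' uncensored event-hour distribution: `peak` is the fraction of
#' uncensored seeds in the fullest histogram bin (bin width = the frame
#' interval), `span` is the 12.5-87.5 percentile range expressed in bins
#' (at least 1), and the score is `min(1, peak / span)`. It is 1 exactly
#' when all uncensored events fall in one bin and decreases as the central
#' span widens. Censored seeds are excluded from the computation and
#' reported in `n_censored`.
#'
#' @param hours event hours, `NA` = censored.
#' @param coverage central coverage of the span (default 0.75).
#' @param bin_h bin width in hours.
#' @return list with `value` (`NA` if all censored), `n_total`,
#'   `n_censored`, `peak`, `span_bins`.
#' @export
uniformity_score <- function(hours, coverage = 0.75, bin_h = 1) {
  n_total <- length(hours)
  ok <- hours[!is.na(hours)]
  n_cens <- n_total - length(ok)
  if (!length(ok))
    return(list(value = NA_real_, n_total = n_total, n_censored = n_cens,
                peak = NA_real_, span_bins = NA_real_))
  bins <- floor(ok / bin_h)
  peak <- max(tabulate(bins - min(bins) + 1L)) / length(ok)
  tail <- (1 - coverage) / 2
  q <- stats::quantile(ok, probs = c(tail, 1 - tail), names = FALSE, type = 7)
  span <- max(1, (q[2] - q[1]) / bin_h)
  list(value = min(1, peak / span), n_total = n_total, n_censored = n_cens,
       peak = peak, span_bins = span)
}

speed_points <- c(quick = 3, medium = 2, slow = 1)

#' Assemble the speed x uniformity vigor matrix
#'
#' Per genotype and phase (PRO, RE, SE), the speed group is worth 3, 2, or
#' 1 points (quick / medium / slow) and is multiplied by the phase's
#' uniformity score; the overall score is the sum over the three phases
#' (range 0-9); overall vigor classes (high / medium / low) come from
#' affinity propagation on the overall scores, merged and ordered to three
#' classes by descending score. A missing phase contributes 0 and is
#' flagged.
#'
#' @param speed_groups data frame `genotype, phase, group`.
#' @param uniformity data frame `genotype, phase, uniformity, n_censored`.
#' @return list with `matrix` (per genotype x phase rows) and `overall`
#'   (per genotype: `overall_score`, `overall_class`).
#' @export
vigor_matrix <- function(speed_groups, uniformity) {
  m <- merge(speed_groups, uniformity, by = c("genotype", "phase"),
             all = TRUE)
  m$points <- unname(speed_points[m$group])
  m$flagged <- is.na(m$points) | is.na(m$uniformity)
  m$phase_score <- ifelse(m$flagged, 0, m$points * m$uniformity)
  overall <- stats::aggregate(phase_score ~ genotype, data = m, FUN = sum)
  names(overall)[2] <- "overall_score"
  # overall classes: scores are products of points and uniformity, so they
  # separate multiplicatively; cluster on the log scale (guarded for 0)
  lsc <- log(pmax(overall$overall_score, 1e-3))
  ap <- affinity_propagation(matrix(lsc, ncol = 1))
  if (!ap$converged)
    ap <- kmedoid_fallback(matrix(lsc, ncol = 1), k = min(3, nrow(overall)))
  cl <- match(ap$cluster, sort(unique(ap$cluster)))
  centre <- vapply(sort(unique(cl)), function(g) mean(lsc[cl == g]), numeric(1))
  cl <- merge_groups_to3(cl, centre, lsc)
  cl <- match(cl, sort(unique(cl)))
  centre <- vapply(sort(unique(cl)), function(g)
    mean(overall$overall_score[cl == g]), numeric(1))
  k <- length(centre)
  lab <- if (k == 1) "medium" else if (k == 2) c("low", "high")[rank(centre, ties.method = "first")]
         else c("low", "medium", "high")[rank(centre, ties.method = "first")]
  overall$overall_class <- lab[cl]
  list(matrix = m[order(m$genotype, match(m$phase, c("PRO", "RE", "SE"))), ],
       overall = overall)
}
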