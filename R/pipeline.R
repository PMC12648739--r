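## End-to-end orchestration: label maps -> tracking -> traits -> events ->
## lot phases -> vigor, plus the file-based entry points behind the CLI.

compress_labels <- function(m) {
  idx <- which(m != 0L)
  list(dim = dim(m), idx = idx, val = as.integer(m[idx]))
}

decompress_labels <- function(z) {
  m <- matrix(0L, z$dim[1], z$dim[2])
  m[z$idx] <- z$val
  m
}

#' Run the seed-level pipeline over a label-map series
#'
#' Frame-major processing: every frame's label map is cropped to each seed
#' ROI and stored compressed; each seed is then tracked through time
#' ([track_seed()]), and per-seed lengths, growth rates, event times,
#' per-frame phases, and lot-level phase times are assembled. RGB frames
#' (needed only for colour traits and chloroplast timing) are optional.
#'
#' @param labels_fn function(frame) returning the full-frame label map.
#' @param rois list of [seed_roi()].
#' @param hours per-frame hours.
#' @param scale_mm_per_px spatial scale.
#' @param interval_h frame interval, hours.
#' @param frames_fn optional function(frame) returning the RGB array.
#' @param track_cfg a [track_config()].
#' @param ref_hour chloroplast-threshold reference hour (80 by
#'   convention; the last frame, with a warning, if the series is
#'   shorter).
#' @param compute_traits also measure per-frame seed morphology/colour.
#' @param lot_threshold lot-phase rule fraction (0.75).
#' @param sample_n,sample_seed standardized seed sampling for lot phases.
#' @return list with `tracks`, `lengths`, `events`, `phases`, `lot`, and
#'   (optionally) `traits` data frames.
#' @export
process_lot <- function(labels_fn, rois, hours, scale_mm_per_px,
                        interval_h = 1, frames_fn = NULL,
                        track_cfg = track_config(), ref_hour = 80,
                        compute_traits = FALSE, lot_threshold = 0.75,
                        sample_n = NULL, sample_seed = 1L) {
  nf <- length(hours)
  ns <- length(rois)
  store <- lapply(seq_len(ns), function(i) vector("list", nf))
  exg_store <- lapply(seq_len(ns), function(i) vector("list", nf))
  ref_frame <- which.min(abs(hours - ref_hour))
  if (abs(hours[ref_frame] - ref_hour) > interval_h / 2)
    warning("reference hour outside the series; using the closest frame")
  for (t in seq_len(nf)) {
    lm <- labels_fn(t)
    px <- if (!is.null(frames_fn)) frames_fn(t) else NULL
    for (i in seq_len(ns)) {
      cr <- crop_roi(lm, rois[[i]])
      store[[i]][[t]] <- compress_labels(cr)
      if (!is.null(px)) {
        sub <- crop_roi(px, rois[[i]])
        sm <- cr == 3L
        if (any(sm)) exg_store[[i]][[t]] <- exg(sub)[sm]
      }
    }
  }
  tri_fn <- function(i) function(t) split_masks(decompress_labels(store[[i]][[t]]))
  lengths <- list(); events <- list(); phases <- list(); traits <- list()
  all_tracks <- list()
  for (i in seq_len(ns)) {
    sid <- rois[[i]]$seed_id
    has_root <- vapply(seq_len(nf), function(t)
      any(store[[i]][[t]]$val == 2L), logical(1))
    first_fg <- which(vapply(seq_len(nf), function(t)
      length(store[[i]][[t]]$idx) > 0, logical(1)))[1]
    active <- has_root
    if (!is.na(first_fg)) active[first_fg] <- TRUE  # seed body for the cache
    tracks <- track_seed(tri_fn(i), track_cfg, seed_id = sid, n_frames = nf,
                         active = active)
    all_tracks <- c(all_tracks, tracks)
    r1_len <- rep(0, nf)
    for (g in tracks) {
      lmm <- g$length_px * scale_mm_per_px
      if (g$root_index == 1) r1_len <- lmm
      rate <- growth_rate_series(lmm, interval_h)$rate_mm_per_h
      lengths[[length(lengths) + 1L]] <- data.frame(
        seed_id = sid, root_index = g$root_index, frame = seq_len(nf),
        hour = hours, length_mm = lmm, rate_mm_per_h = rate)
    }
    seedling_any <- vapply(seq_len(nf), function(t)
      any(store[[i]][[t]]$val == 3L), logical(1))
    root_any <- vapply(seq_len(nf), function(t)
      any(store[[i]][[t]]$val == 2L), logical(1))
    # per-frame phase from the rule-based classifier
    ph <- vapply(seq_len(nf), function(t) {
      if (seedling_any[t]) "SE"
      else if (!root_any[t]) "IMB"
      else if (r1_len[t] >= 2) "RE" else "PRO"
    }, character(1))
    # monotone along the timeline by construction of its inputs; enforce
    idx <- cummax(match(ph, phase_levels))
    ph <- phase_levels[idx]
    phases[[i]] <- data.frame(seed_id = sid, frame = seq_len(nf),
                              hour = hours, phase = ph)
    tri_t <- tri_fn(i)
    coleo <- {
      first_se <- which(seedling_any)[1]
      if (is.na(first_se)) NA_real_ else {
        win <- first_se:min(nf, first_se + 5)
        coleoptile_time(lapply(win, function(t) tri_t(t)$seedling),
                        lapply(win, function(t) tri_t(t)$seed_body),
                        hours[win])
      }
    }
    events[[i]] <- data.frame(
      seed_id = sid,
      protrusion_h = if (any(root_any)) hours[which(root_any)[1]] else NA_real_,
      germination_2mm_h = time_to_length(r1_len, hours, 2),
      establishment_10mm_h = time_to_length(r1_len, hours, 10),
      coleoptile_h = coleo,
      se_h = if (any(seedling_any)) hours[which(seedling_any)[1]] else NA_real_,
      chloroplast_h = NA_real_)
    if (compute_traits) {
      px_ref <- NULL
      for (t in seq_len(nf)) {
        tri <- tri_t(t)
        mo <- measure_seed_morphology(tri$seed_body, scale_mm_per_px)
        col <- if (!is.null(frames_fn))
          measure_seed_color(crop_roi(frames_fn(t), rois[[i]]), tri$seed_body)
          else c(R = NA_real_, G = NA_real_, B = NA_real_)
        traits[[length(traits) + 1L]] <- cbind(
          data.frame(seed_id = sid, frame = t, hour = hours[t]), mo,
          data.frame(mean_R = col[["R"]], mean_G = col[["G"]], mean_B = col[["B"]]))
      }
    }
  }
  events <- do.call(rbind, events)
  # chloroplast biogenesis from the lot-wise ExG threshold
  if (!is.null(frames_fn)) {
    pooled <- unlist(lapply(exg_store, function(e) e[[ref_frame]]))
    if (!length(pooled)) {
      warning("no seedling pixels at the reference hour; chloroplast times all censored")
    } else {
      thr <- mean(pooled)
      for (i in seq_len(ns)) {
        hit <- NA_real_
        for (t in seq_len(nf)) {
          v <- exg_store[[i]][[t]]
          if (is.null(v)) next
          if (sum(v > thr) >= min(5, length(v))) { hit <- hours[t]; break }
        }
        events$chloroplast_h[i] <- hit
      }
      attr(events, "exg_threshold") <- thr
    }
  }
  # lot-level phase times via the 75% rule
  entry <- list(IMB = rep(0, ns), PRO = events$protrusion_h,
                RE = events$germination_2mm_h, SE = events$se_h)
  lot <- do.call(rbind, lapply(names(entry), function(p) {
    h <- lot_phase_time(entry[[p]], threshold = lot_threshold,
                        sample_n = sample_n, sample_seed = sample_seed)
    data.frame(phase = p, hour = as.numeric(h), n = attr(h, "n"))
  }))
  out <- list(tracks = all_tracks, lengths = do.call(rbind, lengths),
              events = events, phases = do.call(rbind, phases), lot = lot)
  if (compute_traits) out$traits <- do.call(rbind, traits)
  out
}

#' Score genotypes for vigor from phase-event tables
#'
#' Standalone vigor scoring from per-seed phase-entry hours (as produced
#' by [process_lot()] per genotype, by [simulate_vigor_events()], or
#' mapped from an external phenotyping tool's export): per phase, speed
#' groups come from event-time clustering ([cluster_event_times()]) and
#' uniformity from [uniformity_score()]; [vigor_matrix()] combines them.
#'
#' @param events data frame with columns `genotype`, `seed`, `pro_h`,
#'   `re_h`, `se_h` (`NA` = censored).
#' @param bin_h histogram bin width (the frame interval).
#' @param horizon_h monitoring horizon, hours.
#' @return list: `matrix`, `overall`, `speed_groups`, `uniformity`.
#' @export
vigor_from_events <- function(events, bin_h = 1, horizon_h = 96) {
  need <- c("genotype", "seed", "pro_h", "re_h", "se_h")
  miss <- setdiff(need, names(events))
  if (length(miss))
    stop("events table is missing column(s): ", paste(miss, collapse = ", "))
  if (!nrow(events)) stop("events table is empty")
  phases <- c(PRO = "pro_h", RE = "re_h", SE = "se_h")
  sg <- list(); un <- list()
  for (p in names(phases)) {
    by_g <- split(events[[phases[[p]]]], events$genotype)
    grp <- cluster_event_times(by_g, horizon = horizon_h)
    sg[[p]] <- data.frame(genotype = names(grp), phase = p,
                          group = unname(grp))
    un[[p]] <- do.call(rbind, lapply(names(by_g), function(g) {
      u <- uniformity_score(by_g[[g]], bin_h = bin_h)
      data.frame(genotype = g, phase = p, uniformity = u$value,
                 n_censored = u$n_censored)
    }))
  }
  speed_groups <- do.call(rbind, sg)
  uniformity <- do.call(rbind, un)
  vm <- vigor_matrix(speed_groups, uniformity)
  c(vm, list(speed_groups = speed_groups, uniformity = uniformity))
}

#' Run the full pipeline from files on disk
#'
#' The file-based entry point behind the command-line `run` subcommand:
#' loads a frame directory (optional), per-frame label maps named
#' `<frame>_labels.png` (or segments frames classically when absent), and
#' a ROI CSV, then calls [process_lot()] and writes `lengths.csv`,
#' `events.csv`, `phases.csv`, `lot.csv`, `tracks.jsonl`, optional
#' `traits.csv`, and a `manifest.json` echoing the configuration.
#'
#' @param config list (or YAML path) with paths and parameters: `frames`,
#'   `masks`, `rois`, `out`, `interval_h`, `scale_mm_per_px`,
#'   `paper_color`, plus optional overrides for tracking/trait/vigor
#'   settings.
#' @return the output directory, invisibly.
#' @export
run_pipeline <- function(config) {
  if (is.character(config)) config <- yaml::read_yaml(config)
  defaults <- list(interval_h = 1, scale_mm_per_px = 0.05,
                   paper_color = "blue", ref_hour = 80, lot_threshold = 0.75,
                   sample_n = NULL, sample_seed = 1L, cos_min = 0.5,
                   compute_traits = FALSE, align = "none")
  config <- utils::modifyList(defaults, config)
  if (config$scale_mm_per_px <= 0) stop("scale_mm_per_px must be positive")
  if (is.null(config$out)) stop("config$out is required")
  if (is.null(config$rois)) stop("config$rois is required")
  rois <- read_rois(config$rois)
  series <- NULL
  if (!is.null(config$frames)) {
    series <- load_series(config$frames, config$interval_h,
                          config$scale_mm_per_px, config$paper_color)
    if (config$align != "none") series <- align_series(series, config$align)
  }
  if (!is.null(config$masks)) {
    files <- sort(list.files(config$masks, pattern = "_labels\\.png$",
                             full.names = TRUE))
    if (!length(files)) stop("no label maps found in ", config$masks)
    labels_fn <- function(t) read_label_map(files[t])
    nf <- length(files)
  } else if (!is.null(series)) {
    cfg_seg <- seg_config(config$paper_color)
    labels_fn <- function(t) segment_frame_classical(series$frames[[t]], cfg_seg)
    nf <- n_frames(series)
  } else {
    stop("either masks (label maps) or frames (for classical segmentation) required")
  }
  hours <- if (!is.null(series)) series$hours else
    (seq_len(nf) - 1) * config$interval_h
  res <- process_lot(labels_fn, rois, hours, config$scale_mm_per_px,
                     config$interval_h,
                     frames_fn = if (!is.null(series)) function(t) series$frames[[t]] else NULL,
                     track_cfg = track_config(cos_min = config$cos_min),
                     ref_hour = config$ref_hour,
                     compute_traits = isTRUE(config$compute_traits),
                     lot_threshold = config$lot_threshold,
                     sample_n = config$sample_n,
                     sample_seed = config$sample_seed)
  dir.create(config$out, showWarnings = FALSE, recursive = TRUE)
  wr <- function(df, name) utils::write.csv(df, file.path(config$out, name),
                                            row.names = FALSE)
  wr(res$lengths, "lengths.csv"); wr(res$events, "events.csv")
  wr(res$phases, "phases.csv"); wr(res$lot, "lot.csv")
  if (!is.null(res$traits)) wr(res$traits, "traits.csv")
  write_tracks_jsonl(res$tracks, file.path(config$out, "tracks.jsonl"),
                     config$scale_mm_per_px)
  manifest <- config
  manifest$n_frames <- nf
  manifest$n_seeds <- length(rois)
  jsonlite::write_json(manifest, file.path(config$out, "manifest.json"),
                       auto_unbox = TRUE, null = "null", pretty = TRUE)
  invisible(config$out)
}
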