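#' Construct an image series from in-memory frames
#'
#' An image series is the package's container for a time-lapse acquisition:
#' a time-ordered list of H x W x 3 frames (8-bit RGB values, 0-255), the
#' interval between frames in hours, and the spatial scale in mm per pixel.
#'
#' @param frames list of H x W x 3 numeric arrays with values in 0..255.
#' @param interval_h positive interval between consecutive frames, hours.
#' @param scale_mm_per_px positive scalar, millimetres per pixel.
#' @param paper_color germination-paper colour, one of `"blue"`, `"black"`,
#'   `"dark_red"`, `"light_blue"`.
#' @param hours optional explicit elapsed hours (e.g. from a manifest);
#'   defaults to `(index - 1) * interval_h`.
#' @return an object of class `image_series`.
#' @export
image_series <- function(frames, interval_h = 1, scale_mm_per_px = 0.05,
                         paper_color = c("blue", "black", "dark_red", "light_blue"),
                         hours = NULL) {
  paper_color <- match.arg(paper_color)
  if (!is.list(frames) || length(frames) < 1L)
    stop("no frames")
  dims <- vapply(frames, function(f) dim(f)[1:2], numeric(2))
  if (any(dims[1, ] != dims[1, 1]) || any(dims[2, ] != dims[2, 1]))
    stop("shape mismatch: frames differ in dimensions")
  stopifnot(interval_h > 0, scale_mm_per_px > 0)
  if (is.null(hours)) hours <- (seq_along(frames) - 1) * interval_h
  structure(list(frames = frames, hours = hours, interval_h = interval_h,
                 scale_mm_per_px = scale_mm_per_px, paper_color = paper_color),
            class = "image_series")
}

#' @export
print.image_series <- function(x, ...) {
  d <- dim(x$frames[[1]])
  cat(sprintf("image_series: %d frames of %dx%d px, %.3g h interval, %.4g mm/px, %s paper\n",
              length(x$frames), d[1], d[2], x$interval_h, x$scale_mm_per_px,
              x$paper_color))
  invisible(x)
}

#' Number of frames in a series
#' @param x an `image_series`.
#' @export
n_frames <- function(x) length(x$frames)

read_frame_file <- function(path) {
  ext <- tolower(tools::file_ext(path))
  px <- switch(ext,
    png = png::readPNG(path),
    tif = , tiff = tiff::readTIFF(path),
    jpg = , jpeg = stop("JPEG input is not supported; convert frames to PNG or TIFF"),
    stop("unrecognised image format: ", ext))
  if (length(dim(px)) == 2L) px <- array(rep(px, 3), c(dim(px), 3))
  if (dim(px)[3] > 3L) px <- px[, , 1:3, drop = FALSE]
  px * 255
}

#' Load a time-lapse frame series from a directory
#'
#' Frames are ordered by lexicographic filename sort; a `manifest.csv`
#' (columns `filename`, `hour`) in the directory overrides both the order
#' and the per-frame hours, which is needed when the acquisition's file
#' naming scheme does not sort chronologically.
#'
#' @param directory path containing >= 2 PNG/TIFF frames.
#' @inheritParams image_series
#' @return an `image_series`.
#' @export
load_series <- function(directory, interval_h = 1, scale_mm_per_px = 0.05,
                        paper_color = "blue") {
  manifest <- file.path(directory, "manifest.csv")
  hours <- NULL
  if (file.exists(manifest)) {
    mf <- utils::read.csv(manifest, stringsAsFactors = FALSE)
    stopifnot(all(c("filename", "hour") %in% names(mf)))
    mf <- mf[order(mf$hour), , drop = FALSE]
    files <- file.path(directory, mf$filename)
    hours <- mf$hour
  } else {
    files <- list.files(directory, pattern = "\\.(png|tif|tiff)$",
                        ignore.case = TRUE, full.names = TRUE)
    files <- sort(files)
  }
  if (length(files) < 2L) stop("no frames: need at least 2 image files")
  frames <- lapply(files, read_frame_file)
  s <- image_series(frames, interval_h = interval_h,
                    scale_mm_per_px = scale_mm_per_px,
                    paper_color = paper_color, hours = hours)
  attr(s, "files") <- basename(files)
  s
}

to_gray <- function(px) {
  0.299 * px[, , 1] + 0.587 * px[, , 2] + 0.114 * px[, , 3]
}

roll2 <- function(m, dr, dc) {
  nr <- nrow(m); nc <- ncol(m)
  ri <- ((seq_len(nr) - 1 - dr) %% nr) + 1
  ci <- ((seq_len(nc) - 1 - dc) %% nc) + 1
  m[ri, ci, drop = FALSE]
}

roll_frame <- function(px, dr, dc) {
  if (length(dim(px)) == 2L) return(roll2(px, dr, dc))
  for (k in seq_len(dim(px)[3])) px[, , k] <- roll2(px[, , k], dr, dc)
  px
}

#' Estimate the integer translation between two frames by phase correlation
#'
#' @param ref,mov grayscale matrices of identical size.
#' @return integer `c(dr, dc)` such that `mov` is `ref` shifted by that
#'   amount (rows down, cols right), plus the correlation peak as an
#'   attribute.
#' @export
phase_correlate <- function(ref, mov) {
  Fa <- stats::fft(ref); Fb <- stats::fft(mov)
  R <- Fb * Conj(Fa)
  den <- Mod(R); den[den < 1e-12] <- 1e-12
  r <- Re(stats::fft(R / den, inverse = TRUE)) / length(ref)
  k <- which.max(r)
  nr <- nrow(ref)
  dr <- (k - 1) %% nr
  dc <- (k - 1) %/% nr
  if (dr > nr / 2) dr <- dr - nr
  if (dc > ncol(ref) / 2) dc <- dc - ncol(ref)
  structure(c(dr, dc), peak = max(r))
}

#' Register every frame of a series to frame 1
#'
#' Translation is estimated on the full grayscale frame by phase
#' correlation; rotation (if requested) by exhaustive search over +/- 2
#' degrees in 0.1 degree steps, maximising the correlation peak. Frames are
#' shifted by the negated estimate so that residual shifts are zero; label
#' maps, when supplied, are transformed identically. A frame whose apparent
#' shift exceeds 10% of the frame size is left unaligned with a warning and
#' flagged in the reported shift table.
#'
#' @param series an `image_series`.
#' @param mode `"translation"`, `"translation+rotation"`, or `"none"`.
#' @param labels optional list of label-map matrices, one per frame.
#' @return the aligned series; `attr(, "shifts")` holds a data frame of
#'   per-frame `(dr, dc, angle, aligned)`; if `labels` were given, the
#'   transformed maps are in `attr(, "labels")`.
#' @export
align_series <- function(series, mode = c("translation", "translation+rotation", "none"),
                         labels = NULL) {
  mode <- match.arg(mode)
  nf <- n_frames(series)
  shifts <- data.frame(frame = seq_len(nf), dr = 0L, dc = 0L, angle = 0,
                       aligned = TRUE)
  if (mode == "none") {
    attr(series, "shifts") <- shifts
    if (!is.null(labels)) attr(series, "labels") <- labels
    return(series)
  }
  ref <- to_gray(series$frames[[1]])
  lim <- 0.10 * max(dim(ref))
  for (t in 2:nf) {
    mov <- to_gray(series$frames[[t]])
    best_ang <- 0
    if (mode == "translation+rotation") {
      angles <- seq(-2, 2, by = 0.1)
      peaks <- vapply(angles, function(a) {
        rot <- if (abs(a) < 1e-9) mov else
          as.matrix(EBImage::rotate(EBImage::Image(mov / 255), a,
                                    output.dim = dim(mov), bg.col = 0)) * 255
        attr(phase_correlate(ref, rot), "peak")
      }, numeric(1))
      best_ang <- angles[which.max(peaks)]
      if (abs(best_ang) > 1e-9) {
        series$frames[[t]] <- as.array(EBImage::rotate(
          EBImage::Image(series$frames[[t]] / 255, colormode = "Color"),
          best_ang, output.dim = dim(mov), bg.col = 0)) * 255
        mov <- to_gray(series$frames[[t]])
        if (!is.null(labels))
          labels[[t]] <- round(as.matrix(EBImage::rotate(
            EBImage::Image(labels[[t]] / 255), best_ang,
            output.dim = dim(mov), bg.col = 0)) * 255)
      }
    }
    sh <- phase_correlate(ref, mov)
    if (max(abs(sh)) > lim) {
      warning(sprintf("frame %d: estimated shift (%d, %d) exceeds 10%% of frame size; left unaligned",
                      t, sh[1], sh[2]))
      shifts$aligned[t] <- FALSE
      next
    }
    shifts$dr[t] <- sh[1]; shifts$dc[t] <- sh[2]; shifts$angle[t] <- best_ang
    if (any(sh != 0)) {
      series$frames[[t]] <- roll_frame(series$frames[[t]], -sh[1], -sh[2])
      if (!is.null(labels)) labels[[t]] <- roll2(labels[[t]], -sh[1], -sh[2])
    }
  }
  attr(series, "shifts") <- shifts
  if (!is.null(labels)) attr(series, "labels") <- labels
  series
}

#' Seed region of interest
#'
#' @param seed_id integer id.
#' @param box numeric `c(row0, col0, row1, col1)`: 0-based, half-open pixel
#'   bounds (top-left origin).
#' @return a `seed_roi` object.
#' @export
seed_roi <- function(seed_id, box) {
  stopifnot(length(box) == 4, box[1] < box[3], box[2] < box[4],
            box[1] >= 0, box[2] >= 0)
  structure(list(seed_id = as.integer(seed_id), box = as.integer(box)),
            class = "seed_roi")
}

#' Crop a frame or label map to a seed ROI
#'
#' @param x matrix or H x W x 3 array.
#' @param roi a `seed_roi` (or bare 4-vector box, 0-based half-open).
#' @return the sub-raster of shape `(row1 - row0, col1 - col0)`.
#' @export
crop_roi <- function(x, roi) {
  box <- if (inherits(roi, "seed_roi")) roi$box else as.integer(roi)
  d <- dim(x)
  if (box[1] < 0 || box[2] < 0 || box[3] > d[1] || box[4] > d[2])
    stop(sprintf("ROI box (%d,%d,%d,%d) out of bounds for %dx%d raster",
                 box[1], box[2], box[3], box[4], d[1], d[2]))
  ri <- (box[1] + 1):box[3]; ci <- (box[2] + 1):box[4]
  if (length(d) == 2L) x[ri, ci, drop = FALSE] else x[ri, ci, , drop = FALSE]
}

#' Split a label map into the three per-seed binary masks
#'
#' Label encoding: 0 background, 1 seed body, 2 root, 3 seedling. The
#' returned triplet holds `seed_body` (labels == 1), `seedling`
#' (labels == 3), and `full_plant` (labels in 1..3), cropped to the ROI;
#' the containment invariants seed_body, seedling within full_plant hold by
#' construction.
#'
#' @param label_map integer matrix with values in 0..3.
#' @param roi optional `seed_roi`; when given, masks are cropped to it.
#' @return a `mask_triplet`: list of three logical matrices.
#' @export
split_masks <- function(label_map, roi = NULL) {
  bad <- setdiff(unique(as.vector(label_map)), 0:3)
  if (length(bad))
    stop("invalid label value(s): ", paste(bad, collapse = ", "))
  if (!is.null(roi)) label_map <- crop_roi(label_map, roi)
  structure(list(seed_body = label_map == 1L,
                 full_plant = label_map >= 1L & label_map <= 3L,
                 seedling  = label_map == 3L),
            class = "mask_triplet")
}

#' Read / write a label map as a single-channel 8-bit PNG
#'
#' Values 0..3 are stored verbatim in the 8-bit channel, which round-trips
#' every pixel exactly (an RGB palette encoding would not).
#'
#' @param path PNG file path.
#' @param labels integer matrix with values in 0..3.
#' @export
write_label_map <- function(labels, path) {
  bad <- setdiff(unique(as.vector(labels)), 0:3)
  if (length(bad)) stop("invalid label value(s): ", paste(bad, collapse = ", "))
  png::writePNG(labels / 255, target = path)
  invisible(path)
}

#' @rdname write_label_map
#' @export
read_label_map <- function(path) {
  m <- png::readPNG(path)
  if (length(dim(m)) == 3L) m <- m[, , 1]
  lm <- round(m * 255)
  storage.mode(lm) <- "integer"
  bad <- setdiff(unique(as.vector(lm)), 0:3)
  if (length(bad)) stop("invalid label value(s): ", paste(bad, collapse = ", "))
  lm
}

#' Read seed ROIs from CSV
#'
#' Expected columns: `seed_id, row0, col0, row1, col1` (0-based half-open).
#' @param path CSV path.
#' @return list of `seed_roi`.
#' @export
read_rois <- function(path) {
  df <- utils::read.csv(path)
  stopifnot(all(c("seed_id", "row0", "col0", "row1", "col1") %in% names(df)))
  lapply(seq_len(nrow(df)), function(i)
    seed_roi(df$seed_id[i], c(df$row0[i], df$col0[i], df$row1[i], df$col1[i])))
}

#' Write tracked roots as JSON lines
#'
#' One root per line: `seed_id`, `root_index`, `t_e` (emergence frame,
#' 1-based), the accepted tip vertices, and per-frame cumulative length in
#' mm.
#'
#' @param tracks list of `tracking_graph` objects.
#' @param path output file.
#' @param scale_mm_per_px scale used to convert lengths.
#' @export
write_tracks_jsonl <- function(tracks, path, scale_mm_per_px) {
  con <- file(path, open = "wt")
  on.exit(close(con))
  for (g in tracks) {
    rec <- list(seed_id = g$seed_id, root_index = g$root_index, t_e = g$t_e,
                vertices = if (nrow(g$vertices)) unname(apply(g$vertices, 1, as.list)) else list(),
                length_mm = round(g$length_px * scale_mm_per_px, 4))
    writeLines(jsonlite::toJSON(rec, auto_unbox = TRUE, digits = NA), con)
  }
  invisible(path)
}
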