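#' Germination phases
#'
#' Ordered phase labels: imbibition (IMB), protrusion (PRO), radicle
#' emergence (RE, radicle >= 2 mm, the "germinated" state), and seedling
#' establishment (SE).
#' @export
phase_levels <- c("IMB", "PRO", "RE", "SE")

#' Classical segmentation configuration
#'
#' Colour-threshold presets per germination-paper colour, used by the
#' deep-learning-free fallback segmenter. Hue is in degrees (0..360),
#' saturation/value in 0..1. The presets are configuration, not code:
#' override any field for a non-standard paper batch.
#'
#' @param paper_color one of `"blue"`, `"black"`, `"dark_red"`,
#'   `"light_blue"`.
#' @param exg_seedling excess-green threshold above which foreground pixels
#'   are classified as seedling.
#' @param min_component_area_px components smaller than this are removed.
#' @param seed_brush_px disc diameter for the morphological opening that
#'   separates the compact seed body from thin roots (roots ~3 px wide are
#'   erased by a 7 px disc; the seed body survives).
#' @return a `seg_config` list.
#' @export
seg_config <- function(paper_color = c("blue", "black", "dark_red", "light_blue"),
                       exg_seedling = 60, min_component_area_px = 20,
                       seed_brush_px = 7) {
  paper_color <- match.arg(paper_color)
  stopifnot(min_component_area_px >= 1)
  paper <- switch(paper_color,
    blue       = list(hue = c(190, 260), sat_min = 0.25, val = c(0.08, 1)),
    light_blue = list(hue = c(175, 255), sat_min = 0.10, val = c(0.25, 1)),
    black      = list(hue = NULL,        sat_min = NA,   val = c(0, 0.30)),
    dark_red   = list(hue = c(330, 25),  sat_min = 0.25, val = c(0.05, 0.75)))
  structure(list(paper_color = paper_color, paper = paper,
                 exg_seedling = exg_seedling,
                 min_component_area_px = as.integer(min_component_area_px),
                 seed_brush_px = as.integer(seed_brush_px)),
            class = "seg_config")
}

as_mask <- function(img) {
  m <- as.matrix(EBImage::imageData(img))
  m > 0.5
}

drop_small <- function(mask, min_area) {
  if (!any(mask) || min_area <= 1) return(mask)
  lab <- .label8(mask)
  tab <- tabulate(lab)
  keep <- which(tab >= min_area)
  matrix(lab %in% keep, nrow(mask), ncol(mask)) & mask
}

#' Excess-green index
#'
#' `ExG = 2G - R - B` on raw 8-bit channels, range -510..510. Gray pixels
#' score 0, pure green 510, magenta -510. Used both to detect green
#' seedlings during segmentation and to time chloroplast biogenesis.
#'
#' @param px H x W x 3 array (0..255), or a length-3 RGB vector.
#' @return matrix (or scalar) of ExG values.
#' @export
exg <- function(px) {
  if (is.null(dim(px))) return(2 * px[2] - px[1] - px[3])
  2 * px[, , 2] - px[, , 1] - px[, , 3]
}

#' Segment one frame into a label map without a learned model
#'
#' A classical colour-threshold fallback for when trained segmentation
#' masks are unavailable: the germination paper is matched by an HSV colour
#' model per paper preset; the remaining foreground is split into seedling
#' (high excess-green), seed body (survives a morphological opening sized
#' above root width), and root (the thin remainder). Components below the
#' configured minimum area are removed.
#'
#' @param px H x W x 3 frame array (0..255).
#' @param cfg a [seg_config()].
#' @return integer label-map matrix (0 background, 1 seed body, 2 root,
#'   3 seedling).
#' @export
segment_frame_classical <- function(px, cfg = seg_config()) {
  d <- dim(px)
  rgbm <- rbind(as.vector(px[, , 1]), as.vector(px[, , 2]), as.vector(px[, , 3]))
  hsv <- grDevices::rgb2hsv(rgbm, maxColorValue = 255)
  hue <- matrix(hsv[1, ] * 360, d[1], d[2])
  sat <- matrix(hsv[2, ], d[1], d[2])
  val <- matrix(hsv[3, ], d[1], d[2])
  pp <- cfg$paper
  paper <- val >= pp$val[1] & val <= pp$val[2]
  if (!is.null(pp$hue)) {
    hue_ok <- if (pp$hue[1] <= pp$hue[2]) hue >= pp$hue[1] & hue <= pp$hue[2]
              else hue >= pp$hue[1] | hue <= pp$hue[2]
    paper <- paper & hue_ok & sat >= pp$sat_min
  }
  fg <- !paper
  if (mean(fg) > 0.9)
    warning("paper model mismatch: >90% of pixels classified as foreground")
  fg <- drop_small(fg, cfg$min_component_area_px)
  seedling <- fg & exg(px) > cfg$exg_seedling
  seedling <- drop_small(seedling, cfg$min_component_area_px)
  body_cand <- fg & !seedling
  brush <- EBImage::makeBrush(cfg$seed_brush_px, shape = "disc")
  opened <- as_mask(EBImage::opening(EBImage::Image(body_cand * 1), brush))
  seed_body <- as_mask(EBImage::dilate(EBImage::Image(opened * 1),
                                       EBImage::makeBrush(3, "box"))) & body_cand
  seed_body <- drop_small(seed_body, cfg$min_component_area_px)
  root <- drop_small(body_cand & !seed_body, cfg$min_component_area_px)
  lab <- matrix(0L, d[1], d[2])
  lab[root] <- 2L
  lab[seed_body] <- 1L
  lab[seedling] <- 3L
  lab
}

#' Rule-based germination phase from masks and radicle length
#'
#' Trait-derived surrogate for a visual phase detector: a seed is IMB while
#' no root pixels exist, PRO once roots protrude but the radicle is under
#' 2 mm, RE from 2 mm (the ISTA "germinated" rule), and SE as soon as the
#' seedling mask is nonempty (coleoptile visible), regardless of root
#' length. Along a growing seed's timeline the returned phase index never
#' decreases.
#'
#' @param triplet a `mask_triplet`.
#' @param radicle_len_mm current radicle cumulative length, mm (>= 0).
#' @param seedling_area_px seedling mask pixel count; defaults to the
#'   triplet's.
#' @return one of [phase_levels].
#' @export
classify_phase_from_masks <- function(triplet, radicle_len_mm = 0,
                                      seedling_area_px = sum(triplet$seedling)) {
  stopifnot(radicle_len_mm >= 0)
  if (seedling_area_px > 0) return("SE")
  has_root <- any(triplet$full_plant & !triplet$seed_body & !triplet$seedling)
  if (!has_root) return("IMB")
  if (radicle_len_mm >= 2) "RE" else "PRO"
}
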