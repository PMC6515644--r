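#' @keywords internal
"_PACKAGE"

CHANNELS <- c("X34", "CD31", "GFAP", "ICAM1")
REGIONS <- c("cortex", "hippocampus", "hypothalamus")
MASK_PROVENANCE <- c("threshold_global", "threshold_bernsen", "roi",
                     "manual", "derived", "ground_truth")

#' Single-channel fluorescence image
#'
#' Container for one channel of a scanned brain section: a rectangular grid of
#' non-negative intensities plus the metadata the quantification pipeline
#' needs (channel identity, pixel size, section and animal ids).
#'
#' @param pixels Numeric matrix of intensities; rows are image rows (y, top to
#'   bottom), columns are x. All values must be finite and >= 0.
#' @param channel One of `"X34"` (fibrillar amyloid), `"CD31"` (endothelium),
#'   `"GFAP"` (astrocytes), `"ICAM1"` (vascular inflammation).
#' @param pixel_size_um Micrometres per pixel edge (> 0). Only micrometre-unit
#'   morphometry depends on it; area fractions are unit-free.
#' @param section_id,animal_id Opaque identifier strings.
#' @return An object of class `channel_image`.
#' @export
channel_image <- function(pixels, channel, pixel_size_um = 1,
                          section_id = "s1", animal_id = "a1") {
  if (!is.matrix(pixels) || !is.numeric(pixels))
    stop("`pixels` must be a numeric matrix")
  if (any(!is.finite(pixels)) || any(pixels < 0))
    stop("intensities must be finite and non-negative")
  channel <- match.arg(channel, CHANNELS)
  if (!is.numeric(pixel_size_um) || length(pixel_size_um) != 1 ||
      !is.finite(pixel_size_um) || pixel_size_um <= 0)
    stop("`pixel_size_um` must be a single positive number")
  structure(
    list(pixels = pixels, channel = channel, pixel_size_um = pixel_size_um,
         section_id = as.character(section_id),
         animal_id = as.character(animal_id)),
    class = "channel_image")
}

#' @export
print.channel_image <- function(x, ...) {
  cat(sprintf("<channel_image> %s  %dx%d px  %.3g um/px  section=%s animal=%s\n",
              x$channel, nrow(x$pixels), ncol(x$pixels), x$pixel_size_um,
              x$section_id, x$animal_id))
  invisible(x)
}

#' Binary mask aligned to a channel image
#'
#' The atom of all quantification: a logical raster the same shape as its
#' source image, tagged with how it was produced.
#'
#' @param pixels Logical matrix (coerced from numeric 0/1 if needed).
#' @param provenance How the mask was made: one of `"threshold_global"`,
#'   `"threshold_bernsen"`, `"roi"`, `"manual"`, `"derived"`,
#'   `"ground_truth"`.
#' @param label Free-text label (e.g. the marker or structure name).
#' @return An object of class `binary_mask`.
#' @export
binary_mask <- function(pixels, provenance = "derived", label = "") {
  if (is.numeric(pixels)) {
    if (any(!pixels %in% c(0, 1)))
      stop("numeric mask input must contain only 0/1")
    storage.mode(pixels) <- "logical"
  }
  if (!is.matrix(pixels) || !is.logical(pixels))
    stop("`pixels` must be a logical matrix")
  if (anyNA(pixels)) stop("mask pixels must not be NA")
  provenance <- match.arg(provenance, MASK_PROVENANCE)
  structure(list(pixels = pixels, provenance = provenance,
                 label = as.character(label)),
            class = "binary_mask")
}

#' @export
print.binary_mask <- function(x, ...) {
  cat(sprintf("<binary_mask> %s [%s]  %dx%d px  %d positive (%.2f%%)\n",
              x$label, x$provenance, nrow(x$pixels), ncol(x$pixels),
              sum(x$pixels), 100 * mean(x$pixels)))
  invisible(x)
}

# Accept either a binary_mask or a raw logical matrix in the algebra layer.
mask_px <- function(m) {
  if (inherits(m, "binary_mask")) m$pixels
  else if (is.matrix(m) && is.logical(m)) m
  else stop("expected a binary_mask or logical matrix")
}

stopifnot_same_shape <- function(...) {
  dims <- lapply(list(...), function(m) dim(mask_px(m)))
  if (!all(vapply(dims, identical, logical(1), dims[[1]])))
    stop("mask shapes do not match")
  invisible(TRUE)
}

#' Named region-of-interest polygon
#'
#' A simple (non-self-intersecting) closed polygon in 0-based pixel
#' coordinates, x right and y down, with vertices at pixel centers.
#'
#' @param region One of `"cortex"`, `"hippocampus"`, `"hypothalamus"`.
#' @param vertices Numeric n x 2 matrix of (x, y) vertices, n >= 3, in order.
#'   The closing edge from the last vertex back to the first is implicit.
#' @return An object of class `roi_polygon`.
#' @export
roi_polygon <- function(region, vertices) {
  region <- match.arg(region, REGIONS)
  vertices <- as.matrix(vertices)
  if (ncol(vertices) != 2 || nrow(vertices) < 3)
    stop("polygon needs >= 3 (x, y) vertices")
  if (any(!is.finite(vertices))) stop("polygon vertices must be finite")
  if (polygon_self_intersects(vertices))
    stop("polygon is self-intersecting")
  structure(list(region = region, vertices = unname(vertices)),
            class = "roi_polygon")
}

#' @export
print.roi_polygon <- function(x, ...) {
  cat(sprintf("<roi_polygon> %s  %d vertices\n", x$region, nrow(x$vertices)))
  invisible(x)
}

# Proper / improper segment intersection test used by the simplicity check.
# Segments are p1-p2 and p3-p4, rows of 2-vectors.
segments_intersect <- function(p1, p2, p3, p4) {
  d <- function(a, b, c) (b[1] - a[1]) * (c[2] - a[2]) - (b[2] - a[2]) * (c[1] - a[1])
  d1 <- d(p3, p4, p1); d2 <- d(p3, p4, p2)
  d3 <- d(p1, p2, p3); d4 <- d(p1, p2, p4)
  if (((d1 > 0 && d2 < 0) || (d1 < 0 && d2 > 0)) &&
      ((d3 > 0 && d4 < 0) || (d3 < 0 && d4 > 0))) return(TRUE)
  on_seg <- function(a, b, c) {
    min(a[1], b[1]) <= c[1] && c[1] <= max(a[1], b[1]) &&
      min(a[2], b[2]) <= c[2] && c[2] <= max(a[2], b[2])
  }
  (d1 == 0 && on_seg(p3, p4, p1)) || (d2 == 0 && on_seg(p3, p4, p2)) ||
    (d3 == 0 && on_seg(p1, p2, p3)) || (d4 == 0 && on_seg(p1, p2, p4))
}

polygon_self_intersects <- function(v) {
  n <- nrow(v)
  edges <- cbind(seq_len(n), c(seq_len(n)[-1], 1))
  for (i in seq_len(n)) {
    for (j in seq_len(n)) {
      if (j <= i) next
      # adjacent edges (sharing a vertex) are allowed to touch
      if (any(edges[i, ] %in% edges[j, ])) next
      if (segments_intersect(v[edges[i, 1], ], v[edges[i, 2], ],
                             v[edges[j, 1], ], v[edges[j, 2], ]))
        return(TRUE)
    }
  }
  FALSE
}

#' One quantification measurement
#'
#' A single area-fraction (or morphometry) measurement, carrying the raw
#' pixel counts so that fractions are always reconstructible. When the
#' denominator is zero the value is `NA` (never 0): an undefined fraction
#' must not bias group means.
#'
#' @param metric Metric key, e.g. `"total_area_pct.X34"`.
#' @param region ROI name, or `NA` for whole-section metrics.
#' @param animal_id,section_id Identifiers.
#' @param numerator_px,denominator_px Pixel counts; for area fractions the
#'   numerator must not exceed the denominator.
#' @param scale `"percent"` (value = 100 * num/den) or `"fraction"`.
#' @return A one-row data frame (class `quant_record` rows bind cleanly).
#' @export
quant_record <- function(metric, region, animal_id, section_id,
                         numerator_px, denominator_px,
                         scale = c("percent", "fraction")) {
  scale <- match.arg(scale)
  if (is.na(denominator_px)) denominator_px <- 0
  if (denominator_px > 0 && numerator_px > denominator_px)
    stop("numerator_px exceeds denominator_px for an area fraction")
  value <- if (denominator_px > 0) {
    r <- numerator_px / denominator_px
    if (scale == "percent") 100 * r else r
  } else NA_real_
  data.frame(animal_id = as.character(animal_id),
             section_id = as.character(section_id),
             region = as.character(region),
             metric = as.character(metric),
             numerator_px = as.numeric(numerator_px),
             denominator_px = as.numeric(denominator_px),
             scale = scale, value = value,
             stringsAsFactors = FALSE)
}
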