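# Conversion of channel intensity images into binary masks. Two schemes are
# supported, mirroring the workflow they re-implement: a single manually (or
# histogram-) chosen global cutoff applied to every image of a channel
# (X-34, GFAP, ICAM-1), and Bernsen auto-local thresholding for CD31, whose
# staining intensity varies regionally.

#' Threshold configuration
#'
#' Bundles the per-channel global cutoffs and the Bernsen parameters. The
#' Bernsen window is circular (pixel-center Euclidean distance <= radius),
#' clipped at image borders. Defaults `radius = 15` px and
#' `contrast_min = 15` grey levels follow the common auto-local-threshold
#' implementation of this method; low-contrast pixels default to background
#' so empty parenchyma does not flood the vessel mask.
#'
#' @param global_thresholds Named numeric vector, channel -> intensity cutoff.
#' @param bernsen_radius_px Window radius in pixels (>= 1).
#' @param bernsen_contrast_min Local-contrast cutoff in grey levels (>= 0).
#' @param bernsen_low_contrast_assignment `"background"` or `"foreground"`.
#' @return An object of class `threshold_config`.
#' @export
threshold_config <- function(global_thresholds = c(X34 = 128, GFAP = 128, ICAM1 = 128),
                             bernsen_radius_px = 15,
                             bernsen_contrast_min = 15,
                             bernsen_low_contrast_assignment = c("background", "foreground")) {
  if (bernsen_radius_px < 1) stop("bernsen_radius_px must be >= 1")
  if (bernsen_contrast_min < 0) stop("bernsen_contrast_min must be >= 0")
  structure(list(
    global_thresholds = global_thresholds,
    bernsen_radius_px = bernsen_radius_px,
    bernsen_contrast_min = bernsen_contrast_min,
    bernsen_low_contrast_assignment = match.arg(bernsen_low_contrast_assignment)),
    class = "threshold_config")
}

#' Apply a global intensity threshold
#'
#' A pixel is positive iff its intensity is `>= threshold` (inclusive: the
#' chosen cutoff is the lowest positive value).
#'
#' @param img A [channel_image] or numeric matrix.
#' @param threshold Intensity cutoff.
#' @return A [binary_mask] with provenance `"threshold_global"`.
#' @export
apply_global_threshold <- function(img, threshold) {
  pix <- if (inherits(img, "channel_image")) img$pixels else img
  lab <- if (inherits(img, "channel_image")) img$channel else ""
  binary_mask(pix >= threshold, "threshold_global", label = lab)
}

#' Suggest a global threshold from pooled histograms
#'
#' Computes a reproducible cutoff on the pooled intensity histogram of all
#' provided images, so that one value can be applied to every image of a
#' channel. `"otsu"` maximizes between-class variance over all integer
#' cutoffs; `"triangle"` maximizes the distance between the histogram and the
#' line joining its peak to its far empty end (suited to sparse-foreground
#' channels).
#'
#' The returned value T is on the inclusive convention of
#' [apply_global_threshold()]: positive pixels are those with intensity >= T.
#'
#' @param images A [channel_image], numeric matrix, or list of either.
#' @param method `"otsu"` or `"triangle"`.
#' @return A single intensity cutoff.
#' @export
suggest_global_threshold <- function(images, method = c("otsu", "triangle")) {
  method <- match.arg(method)
  if (inherits(images, "channel_image") || is.matrix(images)) images <- list(images)
  if (length(images) < 1) stop("need at least one image")
  vals <- unlist(lapply(images, function(im)
    as.vector(if (inherits(im, "channel_image")) im$pixels else im)))
  vals <- round(vals)
  lo <- min(vals); hi <- max(vals)
  if (hi == lo) stop("pooled histogram is constant: no valid threshold split")
  counts <- as.numeric(tabulate(vals - lo + 1L, nbins = hi - lo + 1L))
  levels <- as.numeric(lo:hi)
  if (method == "otsu") {
    # exhaustive between-class variance scan; split is (<= t) vs (> t)
    n <- sum(counts)
    w <- cumsum(counts)
    mu <- cumsum(counts * levels)
    mu_t <- mu[length(mu)]
    k <- seq_len(length(counts) - 1L)
    w0 <- w[k]; w1 <- n - w0
    valid <- w0 > 0 & w1 > 0
    bcv <- rep(-Inf, length(k))
    bcv[valid] <- ((mu_t * w0[valid] - n * mu[k][valid])^2) /
      (as.numeric(w0[valid]) * w1[valid])
    best <- which.max(bcv)
    return(levels[best] + 1)          # first positive level
  }
  # triangle method on the pooled histogram
  peak <- which.max(counts)
  nz <- which(counts > 0)
  far <- if (peak - nz[1] >= nz[length(nz)] - peak) nz[1] else nz[length(nz)]
  x1 <- peak; y1 <- counts[peak]; x2 <- far; y2 <- counts[far]
  idx <- if (x2 > x1) (x1:x2) else (x2:x1)
  d <- abs((y2 - y1) * idx - (x2 - x1) * counts[idx] + x2 * y1 - x1 * y2)
  t_bin <- idx[which.max(d)]
  levels[t_bin] + 1
}

#' Bernsen auto-local thresholding
#'
#' For each pixel p, let `lo` and `hi` be the minimum and maximum intensity in
#' the circular neighbourhood of radius r around p (clipped at image edges),
#' `mid = (lo + hi) / 2` and `contrast = hi - lo`. If
#' `contrast < contrast_min` the pixel takes the configured low-contrast
#' assignment; otherwise it is positive iff its own intensity is `>= mid`.
#'
#' The min/max filters are computed exactly as grayscale erosion/dilation
#' with a disc structuring element, which EBImage evaluates with clipped
#' (border-truncated) neighbourhoods — identical to a per-pixel scan.
#'
#' @param img A [channel_image] or numeric matrix.
#' @param cfg A [threshold_config] (radius, contrast cutoff, low-contrast
#'   assignment are taken from it).
#' @return A [binary_mask] with provenance `"threshold_bernsen"`.
#' @export
apply_bernsen_threshold <- function(img, cfg = threshold_config()) {
  pix <- if (inherits(img, "channel_image")) img$pixels else img
  lab <- if (inherits(img, "channel_image")) img$channel else ""
  r <- cfg$bernsen_radius_px
  kern <- disc_kernel(r)
  # scale to [0,1] for EBImage, then undo; rank filters commute with the
  # affine map so min/max are exact
  top <- max(pix, 1)
  lo <- EBImage::erode(pix / top, kern) * top
  hi <- EBImage::dilate(pix / top, kern) * top
  lo <- matrix(as.numeric(lo), nrow(pix), ncol(pix))
  hi <- matrix(as.numeric(hi), nrow(pix), ncol(pix))
  if (all(pix == round(pix))) {
    # undo the float round trip exactly for integer-valued images
    lo <- round(lo)
    hi <- round(hi)
  }
  mid <- (lo + hi) / 2
  contrast <- hi - lo
  low_fg <- cfg$bernsen_low_contrast_assignment == "foreground"
  out <- ifelse(contrast < cfg$bernsen_contrast_min, low_fg, pix >= mid)
  binary_mask(matrix(as.logical(out), nrow(pix), ncol(pix)),
              "threshold_bernsen", label = lab)
}

#' Convert an image to 8-bit by linear min-max rescaling
#'
#' @param img A [channel_image].
#' @return The image with intensities rescaled to integers 0..255.
#' @export
convert_to_8bit <- function(img) {
  img$pixels <- rescale_8bit(img$pixels)
  img
}
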