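# Area-fraction and colocalization metrics as boolean mask algebra within
# ROIs. Every metric reduces to pixel counts of intersections/differences of
# aligned binary masks; undefined fractions (empty denominator) are NA.

#' Rasterize an ROI polygon to a binary mask
#'
#' A pixel is inside iff its center is inside the polygon under the even-odd
#' rule; centers exactly on the boundary count as inside. Coordinates are
#' 0-based, x right / y down, with pixel centers at integer coordinates.
#'
#' @param poly A [roi_polygon].
#' @param shape Integer `(rows, cols)` of the target raster.
#' @return A [binary_mask] with provenance `"roi"`.
#' @export
rasterize_roi <- function(poly, shape) {
  if (!inherits(poly, "roi_polygon")) stop("`poly` must be a roi_polygon")
  binary_mask(polygon_grid_mask(poly$vertices, shape), "roi", label = poly$region)
}

#' Total marker area fraction within an ROI
#'
#' `value = |marker & roi| / |roi|`, reported on the percent scale: the
#' thresholded marker area normalized to the total ROI area.
#'
#' @param marker,roi [binary_mask]s (or logical matrices) of identical shape.
#' @param metric Metric key stored in the record.
#' @param region,animal_id,section_id Identifiers for the record.
#' @return A one-row [quant_record()] data frame.
#' @export
total_area_fraction <- function(marker, roi, metric = "total_area_pct",
                                region = "cortex", animal_id = "a1",
                                section_id = "s1") {
  stopifnot_same_shape(marker, roi)
  m <- mask_px(marker); r <- mask_px(roi)
  quant_record(metric, region, animal_id, section_id,
               numerator_px = sum(m & r), denominator_px = sum(r),
               scale = "percent")
}

#' Marker area fraction associated with a reference structure
#'
#' `value = |target & reference & roi| / |reference & roi|`: e.g. vascular
#' GFAP is the GFAP-positive area inside the CD31 mask normalized to the
#' CD31-positive area within the ROI; plaque-associated GFAP and vascular
#' ICAM-1 use the same construction. The reference mask is applied as-is by
#' default (`dilation_px = 0`); a dilation is available for sensitivity
#' analyses.
#'
#' @param target,reference,roi Aligned [binary_mask]s.
#' @param dilation_px Optional disc dilation of the reference (default 0).
#' @inheritParams total_area_fraction
#' @return A one-row [quant_record()] data frame.
#' @export
associated_fraction <- function(target, reference, roi,
                                metric = "associated_pct", region = "cortex",
                                animal_id = "a1", section_id = "s1",
                                dilation_px = 0) {
  stopifnot_same_shape(target, reference, roi)
  tg <- mask_px(target); rf <- mask_px(reference); r <- mask_px(roi)
  if (dilation_px > 0) rf <- dilate_disc(rf, dilation_px)
  quant_record(metric, region, animal_id, section_id,
               numerator_px = sum(tg & rf & r), denominator_px = sum(rf & r),
               scale = "percent")
}

#' Parenchymal (non-reference) marker area fraction
#'
#' The marker-positive area outside the reference structure, computed as the
#' difference between total and reference-associated positive pixels and
#' normalized to the ROI area: parenchymal ICAM-1 is total minus vascular
#' ICAM-1. The identity `|M & roi| = |M & R & roi| + |M & !R & roi|` holds
#' exactly in pixels.
#'
#' @param marker,reference,roi Aligned [binary_mask]s.
#' @inheritParams total_area_fraction
#' @return A one-row [quant_record()] data frame.
#' @export
parenchymal_fraction <- function(marker, reference, roi,
                                 metric = "parenchymal_area_pct",
                                 region = "cortex", animal_id = "a1",
                                 section_id = "s1") {
  stopifnot_same_shape(marker, reference, roi)
  m <- mask_px(marker); rf <- mask_px(reference); r <- mask_px(roi)
  total_px <- sum(m & r)
  vascular_px <- sum(m & rf & r)
  quant_record(metric, region, animal_id, section_id,
               numerator_px = total_px - vascular_px, denominator_px = sum(r),
               scale = "percent")
}

#' Aggregate per-section records to one value per animal
#'
#' The sections of an animal are combined per region and metric either as the
#' unweighted mean of per-section values with NA sections dropped (`"mean"`,
#' the default: one point per mouse) or by pooling the raw pixel counts
#' (`"pooled"`).
#'
#' @param records Data frame of [quant_record()] rows.
#' @param mode `"mean"` or `"pooled"`.
#' @return Data frame with one row per animal/region/metric and a `value`
#'   column (plus pooled counts when `mode = "pooled"`).
#' @export
aggregate_per_animal <- function(records, mode = c("mean", "pooled")) {
  mode <- match.arg(mode)
  key <- interaction(records$animal_id, records$region, records$metric,
                     drop = TRUE)
  out <- do.call(rbind, lapply(split(records, key), function(g) {
    base <- data.frame(animal_id = g$animal_id[1], region = g$region[1],
                       metric = g$metric[1], scale = g$scale[1],
                       n_sections = nrow(g), stringsAsFactors = FALSE)
    if (mode == "mean") {
      v <- g$value[!is.na(g$value)]
      base$value <- if (length(v)) mean(v) else NA_real_
    } else {
      num <- sum(g$numerator_px); den <- sum(g$denominator_px)
      base$value <- if (den > 0) {
        r <- num / den
        if (g$scale[1] == "percent") 100 * r else r
      } else NA_real_
    }
    base
  }))
  rownames(out) <- NULL
  out[order(out$metric, out$region, out$animal_id), ]
}
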