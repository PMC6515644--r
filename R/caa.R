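# Separation of vascular amyloid (cerebral amyloid angiopathy, CAA) from
# parenchymal plaques in the segmented amyloid (X-34) mask, and the CAA
# metrics. The faithful reproduction path ingests manually drawn vascular
# amyloid masks; an automated morphological surrogate classifies amyloid
# components as vascular when they are vessel-apposed or elongated.

#' Label amyloid components and compute shape features
#'
#' 8-connected components of the segmented amyloid mask with area below
#' `min_component_px` are discarded (speckle filter). For each retained
#' component the best-fit-ellipse axis ratio is computed from the second
#' central moments of its pixel coordinates (with the 1/12 px\eqn{^2}
#' single-pixel variance added, so a one-pixel-wide line has a finite,
#' large ratio).
#'
#' @param x34_mask Segmented amyloid [binary_mask] (or logical matrix).
#' @param min_component_px Minimum component area in pixels.
#' @return A list with `labels` (integer matrix, 0 = background) and
#'   `components`, a data frame with `component_id`, `area_px`,
#'   `eccentricity_ratio` (major/minor axis length ratio, >= 1).
#' @export
label_components <- function(x34_mask, min_component_px = 20) {
  m <- mask_px(x34_mask)
  lab <- label_components_8(m)
  ids <- setdiff(unique(as.vector(lab)), 0L)
  keep <- integer(0)
  rows <- list()
  relabel <- matrix(0L, nrow(m), ncol(m))
  next_id <- 0L
  for (id in sort(ids)) {
    sel <- which(lab == id)
    if (length(sel) < min_component_px) next
    next_id <- next_id + 1L
    relabel[sel] <- next_id
    yy <- (sel - 1L) %% nrow(m)        # 0-based y (row)
    xx <- (sel - 1L) %/% nrow(m)       # 0-based x (col)
    np <- length(sel)
    central_var <- function(v) if (np > 1) sum((v - mean(v))^2) / np else 0
    cxx <- central_var(xx) + 1 / 12
    cyy <- central_var(yy) + 1 / 12
    cxy <- if (np > 1) sum((xx - mean(xx)) * (yy - mean(yy))) / np else 0
    tr <- cxx + cyy
    det2 <- cxx * cyy - cxy^2
    l1 <- tr / 2 + sqrt(max(tr^2 / 4 - det2, 0))
    l2 <- tr / 2 - sqrt(max(tr^2 / 4 - det2, 0))
    ratio <- if (l2 > 0) sqrt(l1 / l2) else Inf
    rows[[length(rows) + 1L]] <- data.frame(
      component_id = next_id, area_px = length(sel),
      eccentricity_ratio = ratio)
    keep <- c(keep, next_id)
  }
  comps <- if (length(rows)) do.call(rbind, rows) else
    data.frame(component_id = integer(0), area_px = integer(0),
               eccentricity_ratio = numeric(0))
  list(labels = relabel, components = comps)
}

#' Classify amyloid components as vascular (CAA) or parenchymal
#'
#' Automated surrogate for the manual morphological discrimination of
#' vascular versus parenchymal amyloid: a component is vascular iff its
#' overlap with the (dilated) CD31 vessel mask reaches `overlap_min`, or its
#' ellipse axis ratio reaches `elongation_min` (vessel-wall amyloid tracks
#' the vessel and is elongated). The two output masks partition the retained
#' amyloid pixels.
#'
#' @param labeled Output of [label_components()].
#' @param cd31_mask Segmented vessel [binary_mask] (or logical matrix).
#' @param overlap_min Minimum fraction of component pixels inside the dilated
#'   vessel mask (default 0.5).
#' @param elongation_min Minimum major/minor axis ratio (default 3).
#' @param dilation_px Disc dilation of the vessel mask before the overlap
#'   test (default 2 px).
#' @return List with `caa_mask`, `plaque_mask` ([binary_mask]s, provenance
#'   `"derived"`) and `components` including `vessel_overlap` and
#'   `classification`.
#' @export
classify_amyloid <- function(labeled, cd31_mask, overlap_min = 0.5,
                             elongation_min = 3, dilation_px = 2) {
  stopifnot(overlap_min >= 0, overlap_min <= 1, elongation_min >= 1)
  lab <- labeled$labels
  comps <- labeled$components
  vs <- dilate_disc(mask_px(cd31_mask), dilation_px)
  caa <- matrix(FALSE, nrow(lab), ncol(lab))
  plaque <- matrix(FALSE, nrow(lab), ncol(lab))
  overlap <- numeric(nrow(comps))
  cls <- character(nrow(comps))
  for (i in seq_len(nrow(comps))) {
    sel <- lab == comps$component_id[i]
    overlap[i] <- sum(vs[sel]) / comps$area_px[i]
    vascular <- overlap[i] >= overlap_min ||
      comps$eccentricity_ratio[i] >= elongation_min
    cls[i] <- if (vascular) "vascular" else "parenchymal"
    if (vascular) caa[sel] <- TRUE else plaque[sel] <- TRUE
  }
  comps$vessel_overlap <- overlap
  comps$classification <- cls
  list(caa_mask = binary_mask(caa, "derived", "CAA"),
       plaque_mask = binary_mask(plaque, "derived", "plaque"),
       components = comps)
}

#' Ingest a manually drawn vascular-amyloid mask
#'
#' Applies the hand-drawn vascular amyloid mask back onto the segmented
#' amyloid image: the CAA mask is their intersection, so CAA is always a
#' subset of segmented amyloid.
#'
#' @param manual A [binary_mask], logical matrix, or path to a binary
#'   PNG/TIFF (non-zero = vascular amyloid).
#' @param x34_mask Segmented amyloid [binary_mask].
#' @return A [binary_mask] with provenance `"manual"`.
#' @export
ingest_manual_caa <- function(manual, x34_mask) {
  if (is.character(manual)) {
    img <- read_channel_image(manual, "X34")
    manual <- img$pixels > 0
  }
  mm <- mask_px(manual); xm <- mask_px(x34_mask)
  if (!identical(dim(mm), dim(xm))) stop("manual CAA mask shape mismatch")
  binary_mask(mm & xm, "manual", "CAA")
}

#' CAA area and CAA-associated astrogliosis metrics
#'
#' Emits, within the given ROI: `caa_area_pct` (CAA area / ROI area),
#' `caa_assoc_gfap_pct` (vascular-GFAP area inside the CAA mask / CAA area)
#' and `vgfap_assoc_caa_pct` (the reverse normalization: CAA area inside the
#' vascular-GFAP mask / vascular-GFAP area). Fractions with empty
#' denominators are NA.
#'
#' @param caa_mask CAA [binary_mask].
#' @param roi ROI [binary_mask].
#' @param vascular_gfap_mask Vascular GFAP mask (GFAP within CD31).
#' @inheritParams total_area_fraction
#' @return Data frame of three [quant_record()] rows.
#' @export
caa_metrics <- function(caa_mask, roi, vascular_gfap_mask, region = "cortex",
                        animal_id = "a1", section_id = "s1") {
  stopifnot_same_shape(caa_mask, roi, vascular_gfap_mask)
  caa <- mask_px(caa_mask); r <- mask_px(roi); vg <- mask_px(vascular_gfap_mask)
  rbind(
    quant_record("caa_area_pct", region, animal_id, section_id,
                 sum(caa & r), sum(r)),
    quant_record("caa_assoc_gfap_pct", region, animal_id, section_id,
                 sum(vg & caa & r), sum(caa & r)),
    quant_record("vgfap_assoc_caa_pct", region, animal_id, section_id,
                 sum(caa & vg & r), sum(vg & r)))
}
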