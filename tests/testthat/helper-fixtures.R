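# Shared fixtures built in code.

# Solid tube along a polyline: pixels within width/2 of the sampled path.
mk_tube_mask <- function(h, w, pts, width) {
  hit <- matrix(1, h, w)
  xi <- pmin(pmax(round(pts[, 1]), 0), w - 1) + 1
  yi <- pmin(pmax(round(pts[, 2]), 0), h - 1) + 1
  hit[cbind(yi, xi)] <- 0
  d <- matrix(as.numeric(EBImage::distmap(hit)), h, w)
  d <= width / 2
}

mk_line_pts <- function(ctr, angle_deg, half_len, by = 0.5) {
  th <- angle_deg * pi / 180
  tt <- seq(-half_len, half_len, by = by)
  cbind(ctr[1] + tt * cos(th), ctr[2] + tt * sin(th))
}

random_mask <- function(h, w, p = 0.3) matrix(stats::runif(h * w) < p, h, w)

# A small, fast section spec used where the full default study conditions
# are not the point of the test.
tiny_spec <- function(seed = 1, ...) {
  args <- list(shape_px = c(96, 96), n_plaques = 3,
               plaque_radius_range_px = c(3, 6), caa_segment_count = 1,
               caa_segment_length_px = c(15, 30), astro_count = 8,
               icam_parenchymal_blob_count = 2, seed = seed)
  do.call(section_spec, utils::modifyList(args, list(...)))
}

# Segment a generated section with the study thresholds (midpoint of
# background and amplitude; Bernsen for CD31).
segment_default <- function(sec) {
  thr <- sec$spec$background_level + sec$spec$channel_amplitudes / 2
  list(
    X34 = apply_global_threshold(sec$images$X34, thr[["X34"]]),
    CD31 = apply_bernsen_threshold(
      sec$images$CD31, threshold_config(bernsen_contrast_min = 100)),
    GFAP = apply_global_threshold(sec$images$GFAP, thr[["GFAP"]]),
    ICAM1 = apply_global_threshold(sec$images$ICAM1, thr[["ICAM1"]]))
}

# Cached 20-seed recovery study shared by the ground-truth-recovery and
# CAA-classifier acceptance checks (one computation, two assertions).
recovery_cache <- new.env(parent = emptyenv())

recovery_study <- function(seeds = 1:20) {
  key <- paste0("s", paste(range(seeds), collapse = "_"))
  if (!is.null(recovery_cache[[key]])) return(recovery_cache[[key]])
  est <- NULL; tru <- NULL; comp_n <- 0L; comp_ok <- 0L
  for (sd in seeds) {
    sec <- generate_section(section_spec(seed = sd))
    masks <- segment_default(sec)
    lab <- label_components(masks$X34, 20)
    cls <- classify_amyloid(lab, masks$CD31)
    em <- compute_section_metrics(masks, sec$rois, caa_mask = cls$caa_mask)
    tm <- sec$truth$metrics
    key2 <- paste(em$region, em$metric)
    est <- rbind(est, data.frame(key = key2, v = em$value))
    tru <- rbind(tru, data.frame(key = key2,
                                 v = tm$value[match(key2, paste(tm$region, tm$metric))]))
    gt <- sec$truth$masks
    for (i in seq_len(nrow(cls$components))) {
      px <- lab$labels == cls$components$component_id[i]
      true_vasc <- sum(px & gt$caa$pixels) > sum(px & gt$plaque$pixels)
      comp_n <- comp_n + 1L
      comp_ok <- comp_ok + ((cls$components$classification[i] == "vascular") == true_vasc)
    }
  }
  mean_by <- function(df) tapply(df$v, df$key, function(x) mean(x, na.rm = TRUE))
  e <- mean_by(est); t <- mean_by(tru)
  res <- list(est = e, tru = t[names(e)],
              rel_err = (e - t[names(e)]) / t[names(e)],
              classifier_accuracy = comp_ok / comp_n)
  recovery_cache[[key]] <- res
  res
}
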