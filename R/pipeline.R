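# Orchestration: segment each section's channels, rasterize ROIs, evaluate
# the metric panel, classify CAA, run vessel morphometry, aggregate per
# animal, and run the statistics plan — from a single config, with
# deterministic outputs.

#' Default pipeline configuration
#'
#' @param global_thresholds Named per-channel global cutoffs for X-34, GFAP
#'   and ICAM-1 (CD31 always uses Bernsen). `NA` entries are filled by
#'   pooled-histogram Otsu over all images of that channel.
#' @param bernsen `list(radius_px, contrast_min, low_contrast)` for CD31.
#'   The contrast floor must sit above the within-window background noise
#'   range (roughly eight noise standard deviations) and below the stain
#'   contrast; the default 100 grey levels suits 8-bit data with signal
#'   amplitudes near 160 and read noise near 10.
#' @param caa `list(mode, overlap_min, elongation_min, dilation_px,
#'   min_component_px)`; `mode` `"auto"` (morphological classifier) or
#'   `"manual"` (ingest drawn masks).
#' @param morphometry `list(enabled, min_branch_px)`.
#' @param aggregation `"mean"` or `"pooled"` per-animal section aggregation.
#' @param stats_plan Named vector metric -> test; see [default_stats_plan()].
#' @param alpha,posthoc_gate Omnibus gate for Sidak comparisons.
#' @param seed Seed for the blinding-code bookkeeping.
#' @return Config list.
#' @export
pipeline_config <- function(global_thresholds = c(X34 = NA, GFAP = NA, ICAM1 = NA),
                            bernsen = list(radius_px = 15, contrast_min = 100,
                                           low_contrast = "background"),
                            caa = list(mode = "auto", overlap_min = 0.5,
                                       elongation_min = 3, dilation_px = 2,
                                       min_component_px = 20),
                            morphometry = list(enabled = FALSE, min_branch_px = 10),
                            aggregation = "mean",
                            stats_plan = default_stats_plan(),
                            alpha = 0.05, posthoc_gate = TRUE, seed = 1) {
  as.list(environment())
}

#' Default metric -> test assignment
#'
#' Amyloid and CAA outcomes exist only in transgenic animals, so they are
#' compared between the two transgenic groups (unpaired t or Mann-Whitney);
#' all other metrics go through the two-way omnibus ANOVA with gated Sidak
#' comparisons.
#'
#' @return Named character vector.
#' @export
default_stats_plan <- function() {
  c("total_area_pct.X34" = "t",
    "caa_area_pct" = "mannwhitney",
    "caa_assoc_gfap_pct" = "t",
    "vgfap_assoc_caa_pct" = "t",
    "plaque_assoc_gfap_pct" = "mannwhitney")
}

#' Read a pipeline config from YAML
#'
#' @param path YAML file; keys as in [pipeline_config()], plus optional
#'   `sections` (each with `section_id`, `animal_id`, per-channel image
#'   paths, `rois` path, optional `manual_caa` path) and `design` CSV path.
#' @return Config list merged over the defaults.
#' @export
read_pipeline_config <- function(path) {
  y <- yaml::read_yaml(path)
  cfg <- pipeline_config()
  for (k in names(y)) {
    if (k %in% c("global_thresholds", "stats_plan")) {
      cfg[[k]] <- unlist(y[[k]])
    } else if (is.list(cfg[[k]]) && is.list(y[[k]])) {
      cfg[[k]] <- utils::modifyList(cfg[[k]], y[[k]])
    } else {
      cfg[[k]] <- y[[k]]
    }
  }
  cfg
}

# Resolve a section entry: load images/ROIs from disk when given as paths.
resolve_section <- function(sec, pixel_size_um = 1) {
  imgs <- sec$images
  for (ch in names(imgs)) {
    if (is.character(imgs[[ch]]))
      imgs[[ch]] <- read_channel_image(imgs[[ch]], ch, pixel_size_um,
                                       sec$section_id, sec$animal_id)
  }
  shape <- dim(imgs[[1]]$pixels)
  rois <- sec$rois
  if (is.character(rois)) rois <- read_roi(rois, shape)
  if (inherits(rois, "roi_polygon")) rois <- list(rois)
  if (is.null(names(rois)) || any(names(rois) == ""))
    names(rois) <- vapply(rois, function(r) r$region, character(1))
  manual <- sec$manual_caa
  list(section_id = sec$section_id, animal_id = sec$animal_id,
       images = imgs, rois = rois, manual_caa = manual)
}

#' Validate a pipeline input manifest
#'
#' Checks, before any computation, that every referenced file exists and
#' that every section maps to a row of the design table.
#'
#' @param sections List of section entries.
#' @param design Design table.
#' @return Invisibly TRUE; stops with a message naming the first problem.
#' @export
validate_manifest <- function(sections, design) {
  design <- validate_design(design)
  for (sec in sections) {
    for (ch in names(sec$images)) {
      p <- sec$images[[ch]]
      if (is.character(p) && !file.exists(p))
        stop("section ", sec$section_id, ": missing image file ", p)
    }
    if (is.character(sec$rois) && !file.exists(sec$rois))
      stop("section ", sec$section_id, ": missing ROI file ", sec$rois)
    if (!is.null(sec$manual_caa) && is.character(sec$manual_caa) &&
        !file.exists(sec$manual_caa))
      stop("section ", sec$section_id, ": missing manual CAA mask ", sec$manual_caa)
    if (!sec$animal_id %in% design$animal_id)
      stop("section ", sec$section_id, ": animal ", sec$animal_id,
           " not in design table")
  }
  invisible(TRUE)
}

# Segment one resolved section into per-channel masks.
segment_section <- function(sec, thresholds, bernsen) {
  cfg <- threshold_config(
    global_thresholds = thresholds,
    bernsen_radius_px = bernsen$radius_px,
    bernsen_contrast_min = bernsen$contrast_min,
    bernsen_low_contrast_assignment = bernsen$low_contrast)
  masks <- list()
  for (ch in names(sec$images)) {
    masks[[ch]] <- if (ch == "CD31") {
      apply_bernsen_threshold(sec$images[[ch]], cfg)
    } else {
      apply_global_threshold(sec$images[[ch]], thresholds[[ch]])
    }
  }
  masks
}

#' Run the full quantification pipeline
#'
#' @param sections List of section entries. Each entry has `section_id`,
#'   `animal_id`, `images` (named list, channel -> path or [channel_image]),
#'   `rois` (path or list of [roi_polygon]) and optionally `manual_caa`.
#' @param design Design table (data frame or CSV path).
#' @param config [pipeline_config()] list.
#' @param outdir Optional output directory; when given, the records,
#'   per-animal aggregates, statistics tables and a JSON run manifest are
#'   written there (deterministically: re-running with identical inputs
#'   gives byte-identical files).
#' @param pixel_size_um Pixel size attached to images read from disk.
#' @return Results bundle: `records` (per-section quant records),
#'   `per_animal`, `stats`, `morphometry` (per-section summaries, if
#'   enabled), `caa` (per-section component tables), `failures`, `config`.
#' @export
run_pipeline <- function(sections, design, config = pipeline_config(),
                         outdir = NULL, pixel_size_um = 1) {
  if (is.character(design)) design <- read_design_table(design)
  validate_manifest(sections, design)
  resolved <- lapply(sections, resolve_section, pixel_size_um = pixel_size_um)

  # fill NA global thresholds by pooled Otsu per channel
  thresholds <- config$global_thresholds
  for (ch in names(thresholds)) {
    if (is.na(thresholds[[ch]])) {
      pool <- lapply(resolved, function(s) s$images[[ch]])
      pool <- pool[!vapply(pool, is.null, logical(1))]
      thresholds[[ch]] <- suggest_global_threshold(pool, "otsu")
    }
  }

  records <- list()
  morpho <- list()
  caa_tabs <- list()
  failures <- list()
  for (sec in resolved) {
    res <- tryCatch({
      masks <- segment_section(sec, thresholds, config$bernsen)
      caa_mask <- NULL
      if (!is.null(masks$X34)) {
        if (identical(config$caa$mode, "manual") && !is.null(sec$manual_caa)) {
          caa_mask <- ingest_manual_caa(sec$manual_caa, masks$X34)
        } else {
          lab <- label_components(masks$X34, config$caa$min_component_px)
          cls <- classify_amyloid(lab, masks$CD31,
                                  overlap_min = config$caa$overlap_min,
                                  elongation_min = config$caa$elongation_min,
                                  dilation_px = config$caa$dilation_px)
          caa_mask <- cls$caa_mask
          if (nrow(cls$components) > 0)
            caa_tabs[[sec$section_id]] <- cbind(section_id = sec$section_id,
                                                cls$components)
        }
      }
      recs <- compute_section_metrics(masks, sec$rois, caa_mask = caa_mask,
                                      animal_id = sec$animal_id,
                                      section_id = sec$section_id)
      if (isTRUE(config$morphometry$enabled) && !is.null(masks$CD31)) {
        gr <- skeletonize_vessels(masks$CD31,
                                  min_branch_px = config$morphometry$min_branch_px,
                                  pixel_size_um = pixel_size_um)
        gr <- edge_tortuosity(edge_diameter(gr))
        morpho[[sec$section_id]] <- summarize_vessels(gr, sec$section_id)
      }
      recs
    }, error = function(e) e)
    if (inherits(res, "error")) {
      failures[[length(failures) + 1]] <- list(section_id = sec$section_id,
                                               stage = "quantify",
                                               message = conditionMessage(res))
    } else records[[length(records) + 1]] <- res
  }
  records <- if (length(records)) do.call(rbind, records) else NULL
  per_animal <- if (!is.null(records))
    aggregate_per_animal(records, mode = config$aggregation) else NULL

  stats_res <- NULL
  if (!is.null(per_animal)) {
    tab <- merge(per_animal, design, by = "animal_id")
    stats_res <- run_stats_plan(tab, plan = config$stats_plan,
                                alpha = config$alpha,
                                posthoc_gate = config$posthoc_gate)
  }

  bundle <- list(records = records, per_animal = per_animal,
                 stats = stats_res,
                 morphometry = if (length(morpho)) morpho else NULL,
                 caa = if (length(caa_tabs)) caa_tabs else NULL,
                 thresholds = thresholds,
                 failures = failures, config = config)
  if (!is.null(outdir)) write_results_bundle(bundle, outdir, design)
  bundle
}

# Serialize the bundle deterministically (no timestamps).
write_results_bundle <- function(bundle, outdir, design) {
  dir.create(outdir, recursive = TRUE, showWarnings = FALSE)
  if (!is.null(bundle$records))
    write_quant_csv(bundle$records, file.path(outdir, "section_records.csv"))
  if (!is.null(bundle$per_animal))
    utils::write.csv(bundle$per_animal, file.path(outdir, "per_animal.csv"),
                     row.names = FALSE, na = "NA")
  if (!is.null(bundle$stats)) {
    an <- list(); ph <- list(); tg <- list()
    for (key in names(bundle$stats)) {
      r <- bundle$stats[[key]]
      if (inherits(r$anova, "anova_table"))
        an[[key]] <- cbind(metric = r$metric, region = r$region,
                           as.data.frame(r$anova))
      if (!is.null(r$posthoc))
        ph[[key]] <- cbind(metric = r$metric, region = r$region, r$posthoc)
      if (!is.null(r$result) && is.list(r$result))
        tg[[key]] <- data.frame(metric = r$metric, region = r$region,
                                test = r$test,
                                stat = r$result$t %||% r$result$U,
                                p = r$result$p)
    }
    if (length(an)) utils::write.csv(do.call(rbind, an),
                                     file.path(outdir, "anova.csv"),
                                     row.names = FALSE, na = "NA")
    if (length(ph)) utils::write.csv(do.call(rbind, ph),
                                     file.path(outdir, "sidak_comparisons.csv"),
                                     row.names = FALSE, na = "NA")
    if (length(tg)) utils::write.csv(do.call(rbind, tg),
                                     file.path(outdir, "two_group_tests.csv"),
                                     row.names = FALSE, na = "NA")
  }
  if (!is.null(bundle$morphometry)) {
    ed <- do.call(rbind, lapply(bundle$morphometry, `[[`, "edges"))
    sm <- do.call(rbind, lapply(bundle$morphometry, `[[`, "summary"))
    utils::write.csv(ed, file.path(outdir, "vessel_edges.csv"),
                     row.names = FALSE, na = "NA")
    utils::write.csv(sm, file.path(outdir, "vessel_summary.csv"),
                     row.names = FALSE, na = "NA")
  }
  manifest <- list(
    package = "histoquant",
    version = as.character(utils::packageVersion("histoquant")),
    thresholds = as.list(bundle$thresholds),
    config = bundle$config[c("bernsen", "caa", "morphometry", "aggregation",
                             "alpha", "posthoc_gate", "seed")],
    n_sections = if (!is.null(bundle$records))
      length(unique(bundle$records$section_id)) else 0,
    failures = bundle$failures)
  jsonlite::write_json(manifest, file.path(outdir, "run_manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE, digits = NA)
  invisible(outdir)
}

#' Build pipeline section entries from a synthetic cohort
#'
#' @param cohort A [generate_cohort()] result.
#' @return List of in-memory section entries for [run_pipeline()].
#' @export
cohort_sections <- function(cohort) {
  out <- list()
  for (aid in names(cohort$sections)) {
    for (sec in cohort$sections[[aid]]) {
      out[[length(out) + 1]] <- list(
        section_id = sec$images[[1]]$section_id, animal_id = aid,
        images = sec$images, rois = sec$rois)
    }
  }
  out
}

#' Quality-control overlay images
#'
#' Tints each channel image with its mask (and, when given, colors CAA
#' components teal and parenchymal plaques green, mirroring the manual
#' discrimination display).
#'
#' @param images Named list of [channel_image]s.
#' @param masks Named list of [binary_mask]s aligned to the images.
#' @param caa Optional [classify_amyloid()] result for the amyloid overlay.
#' @param outdir Optional directory to write `<channel>_overlay.png` files.
#' @return Named list of H x W x 3 arrays in [0, 1], invisibly when written.
#' @export
make_qc_overlays <- function(images, masks, caa = NULL, outdir = NULL) {
  tint <- c(X34 = "cyan", CD31 = "red", GFAP = "green", ICAM1 = "yellow")
  out <- list()
  for (ch in names(images)) {
    base <- images[[ch]]$pixels / max(images[[ch]]$pixels, 1)
    arr <- array(rep(base, 3), c(dim(base), 3))
    if (!is.null(masks[[ch]])) {
      m <- mask_px(masks[[ch]])
      if (!identical(dim(m), dim(base))) stop("mask/image shape mismatch")
      rgb <- grDevices::col2rgb(tint[[ch]]) / 255
      for (k in 1:3) {
        plane <- arr[, , k]
        plane[m] <- 0.5 * plane[m] + 0.5 * rgb[k]
        arr[, , k] <- plane
      }
    }
    out[[ch]] <- arr
  }
  if (!is.null(caa)) {
    base <- images$X34$pixels / max(images$X34$pixels, 1)
    arr <- array(rep(base, 3), c(dim(base), 3))
    vm <- mask_px(caa$caa_mask); pm <- mask_px(caa$plaque_mask)
    teal <- c(0, 0.8, 0.8); green <- c(0, 0.9, 0)
    for (k in 1:3) {
      plane <- arr[, , k]
      plane[vm] <- 0.4 * plane[vm] + 0.6 * teal[k]
      plane[pm] <- 0.4 * plane[pm] + 0.6 * green[k]
      arr[, , k] <- plane
    }
    out$caa_classification <- arr
  }
  if (!is.null(outdir)) {
    dir.create(outdir, recursive = TRUE, showWarnings = FALSE)
    for (nm in names(out))
      png::writePNG(out[[nm]], file.path(outdir, paste0(nm, "_overlay.png")))
    return(invisible(out))
  }
  out
}
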