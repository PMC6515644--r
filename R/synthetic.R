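# Synthetic multi-channel brain-section generator with exported ground
# truth. Structures are rendered from analytic distance fields so that each
# structure's true mask is exactly the half-maximum level set of its
# intensity profile: a global threshold midway between background and peak
# then recovers the truth up to symmetric noise flips at boundaries, which is
# precisely the regime the quantification pipeline assumes.

#' Section specification for the synthetic generator
#'
#' All randomness flows from `seed`; identical specs produce byte-identical
#' sections. Densities and probabilities are in `[0, 1]`; amplitudes are on
#' the 8-bit intensity scale.
#'
#' @param shape_px Image shape `(rows, cols)`.
#' @param pixel_size_um Micrometres per pixel edge.
#' @param vessel_density Target CD31 area fraction (realized within a few
#'   relative percent by adaptively sized tube walks).
#' @param vessel_width_range_px Tube diameter range in pixels.
#' @param n_plaques Number of parenchymal amyloid plaques.
#' @param plaque_radius_range_px Plaque radius range in pixels.
#' @param caa_segment_count Number of vascular-amyloid ring segments.
#' @param caa_segment_length_px Range of ring segment lengths along a vessel.
#' @param astro_count Number of astrocytes.
#' @param astro_vessel_assoc_prob,astro_plaque_assoc_prob Probability that an
#'   astrocyte is placed within a few pixels of a vessel / of a plaque rim;
#'   otherwise placement is uniform.
#' @param astro_reactivity Multiplier on process length and count of
#'   vessel-/plaque-associated astrocytes (reactive hypertrophy).
#' @param icam_vascular_amp Relative amplitude of endothelial ICAM-1 signal.
#' @param icam_vessel_prob Probability that a vessel segment expresses ICAM-1.
#' @param icam_parenchymal_blob_count Number of parenchymal ICAM-1 blobs.
#' @param channel_amplitudes Named peak signal amplitude per channel.
#' @param background_level Constant background intensity.
#' @param noise_sd Gaussian read-noise standard deviation (SNR is
#'   amplitude / noise_sd).
#' @param psf_sigma Gaussian point-spread blur (pixels) applied to every
#'   structure field before rendering; ground-truth masks are the
#'   half-maximum level sets of the blurred fields, so segmentation at the
#'   midpoint intensity recovers them up to symmetric noise flips.
#' @param shot_noise Add a Poisson shot-noise component.
#' @param bias_field_strength Peak relative deviation of the multiplicative
#'   low-order polynomial illumination field (unit mean).
#' @param seed Integer seed fixing the entire section.
#' @return An object of class `section_spec`.
#' @export
section_spec <- function(shape_px = c(256, 256), pixel_size_um = 1,
                         vessel_density = 0.08,
                         vessel_width_range_px = c(4, 8),
                         n_plaques = 8, plaque_radius_range_px = c(4, 10),
                         caa_segment_count = 3,
                         caa_segment_length_px = c(25, 60),
                         astro_count = 35,
                         astro_vessel_assoc_prob = 0.45,
                         astro_plaque_assoc_prob = 0.25,
                         astro_reactivity = 1,
                         icam_vascular_amp = 1,
                         icam_vessel_prob = 0.4,
                         icam_parenchymal_blob_count = 6,
                         channel_amplitudes = c(X34 = 160, CD31 = 160,
                                                GFAP = 160, ICAM1 = 160),
                         background_level = 40, noise_sd = 10,
                         psf_sigma = 0.6, shot_noise = FALSE,
                         bias_field_strength = 0.08, seed = 1) {
  spec <- as.list(environment())
  probs <- c(spec$vessel_density, spec$astro_vessel_assoc_prob,
             spec$astro_plaque_assoc_prob, spec$icam_vessel_prob)
  if (any(probs < 0 | probs > 1)) stop("densities/probabilities must be in [0, 1]")
  if (spec$astro_vessel_assoc_prob + spec$astro_plaque_assoc_prob > 1)
    stop("astrocyte association probabilities must sum to <= 1")
  if (any(spec$channel_amplitudes <= spec$background_level))
    stop("channel amplitudes must exceed the background level")
  if (spec$background_level < 0) stop("background_level must be >= 0")
  structure(spec, class = "section_spec")
}

# distance of every pixel to the nearest of a set of (x, y) points (0-based
# float coords), via the Euclidean distance transform of the rasterized set.
dist_to_points <- function(pts, shape) {
  h <- shape[1]; w <- shape[2]
  if (is.null(pts) || nrow(pts) == 0) return(matrix(Inf, h, w))
  xi <- pmin(pmax(round(pts[, 1]), 0), w - 1) + 1L
  yi <- pmin(pmax(round(pts[, 2]), 0), h - 1) + 1L
  hit <- matrix(1, h, w)
  hit[cbind(yi, xi)] <- 0
  d <- EBImage::distmap(hit)
  matrix(as.numeric(d), h, w)
}

# half-maximum radial profile: 1 at d = 0, 0.5 at d = R
half_max_profile <- function(d, R) 2^(-(d / R)^2)

# biased-random-walk vessel centreline starting at the image border
walk_centreline <- function(shape, max_len) {
  h <- shape[1]; w <- shape[2]
  side <- sample.int(4, 1)
  pos <- switch(side,
    c(stats::runif(1, 2, w - 3), 1),
    c(stats::runif(1, 2, w - 3), h - 2),
    c(1, stats::runif(1, 2, h - 3)),
    c(w - 2, stats::runif(1, 2, h - 3)))
  ang <- switch(side, pi / 2, -pi / 2, 0, pi) + stats::rnorm(1, 0, 0.3)
  pts <- matrix(NA_real_, max_len, 2)
  for (i in seq_len(max_len)) {
    pts[i, ] <- pos
    ang <- ang + stats::rnorm(1, 0, 0.12)
    pos <- pos + c(cos(ang), sin(ang))
    if (pos[1] < 1 || pos[1] > w - 2 || pos[2] < 1 || pos[2] > h - 2) {
      pts <- pts[seq_len(i), , drop = FALSE]
      break
    }
  }
  pts[!is.na(pts[, 1]), , drop = FALSE]
}

# point-to-segment distances over a pixel window; seg rows are (x1,y1,x2,y2)
window_segment_dist <- function(xs, ys, segs) {
  grid_x <- matrix(rep(xs, each = length(ys)), length(ys))
  grid_y <- matrix(rep(ys, length(xs)), length(ys))
  dmin <- matrix(Inf, length(ys), length(xs))
  for (k in seq_len(nrow(segs))) {
    x1 <- segs[k, 1]; y1 <- segs[k, 2]; x2 <- segs[k, 3]; y2 <- segs[k, 4]
    vx <- x2 - x1; vy <- y2 - y1
    L2 <- vx^2 + vy^2
    t <- if (L2 > 0) pmin(pmax(((grid_x - x1) * vx + (grid_y - y1) * vy) / L2, 0), 1) else 0
    dx <- grid_x - (x1 + t * vx); dy <- grid_y - (y1 + t * vy)
    dmin <- pmin(dmin, sqrt(dx^2 + dy^2))
  }
  dmin
}

#' Generate one synthetic section with ground truth
#'
#' Renders the four channels (X-34 amyloid, CD31 endothelium, GFAP
#' astrocytes, ICAM-1) of a synthetic brain section: branching tubular
#' vessels (biased random-walk centrelines, Gaussian cross-sections),
#' radially decaying parenchymal plaques, vascular-amyloid rings along
#' chosen vessel segments, star-shaped astrocytes preferentially placed at
#' vessels and plaque rims, endothelial plus parenchymal ICAM-1, a smooth
#' multiplicative illumination bias and Gaussian read noise. Ground-truth
#' masks are the exact half-maximum level sets of the noiseless structures,
#' and the stored true metric values are the mask-algebra metrics evaluated
#' on those masks.
#'
#' @param spec A [section_spec()].
#' @param animal_id,section_id Identifiers stamped on the images.
#' @return List with `images` (named list of [channel_image]), `truth`
#'   (list: `masks`, named [binary_mask]s; `metrics`, data frame of true
#'   [quant_record()] rows), `rois` (cortex/hippocampus [roi_polygon]s) and
#'   `spec`.
#' @export
generate_section <- function(spec = section_spec(), animal_id = "a1",
                             section_id = "s1") {
  stopifnot(inherits(spec, "section_spec"))
  withr::with_seed(spec$seed, generate_section_impl(spec, animal_id, section_id))
}

generate_section_impl <- function(spec, animal_id, section_id) {
  h <- spec$shape_px[1]; w <- spec$shape_px[2]
  npx <- h * w
  psf <- function(S) {
    if (spec$psf_sigma <= 0) return(S)
    matrix(as.numeric(EBImage::gblur(S, spec$psf_sigma)), h, w)
  }

  ## ---- vasculature ----------------------------------------------------
  paths <- list()
  norm_min <- matrix(Inf, h, w)   # min over tubes of distance / (width/2)
  target_px <- spec$vessel_density * npx
  attempts <- 0
  while (sum(norm_min <= 1) < target_px) {
    attempts <- attempts + 1
    if (attempts > 80)
      stop("vessel_density unreachable in this shape after bounded attempts")
    width <- stats::runif(1, spec$vessel_width_range_px[1],
                          spec$vessel_width_range_px[2])
    deficit <- target_px - sum(norm_min <= 1)
    max_len <- max(40, min(2 * (h + w), round(deficit / width)))
    pts <- walk_centreline(c(h, w), max_len)
    if (nrow(pts) < 20) next
    d <- dist_to_points(pts, c(h, w))
    norm_min <- pmin(norm_min, d / (width / 2))
    paths[[length(paths) + 1]] <- list(pts = pts, width = width)
    # occasional branch from the parent path, capped by the remaining deficit
    branch_len <- round((target_px - sum(norm_min <= 1)) / width)
    if (stats::runif(1) < 0.4 && nrow(pts) > 40 && branch_len >= 30) {
      bi <- sample.int(nrow(pts) - 20, 1) + 10
      bang <- atan2(pts[bi + 5, 2] - pts[bi, 2], pts[bi + 5, 1] - pts[bi, 1]) +
        sample(c(-1, 1), 1) * stats::runif(1, 0.5, 1.1)
      bpts <- pts[bi, , drop = FALSE]
      pos <- pts[bi, ]; ang <- bang
      for (i in seq_len(min(round(max_len / 2), branch_len))) {
        ang <- ang + stats::rnorm(1, 0, 0.12)
        pos <- pos + c(cos(ang), sin(ang))
        if (pos[1] < 1 || pos[1] > w - 2 || pos[2] < 1 || pos[2] > h - 2) break
        bpts <- rbind(bpts, pos)
      }
      if (nrow(bpts) >= 20) {
        bw <- width * stats::runif(1, 0.6, 0.9)
        d <- dist_to_points(bpts, c(h, w))
        norm_min <- pmin(norm_min, d / (bw / 2))
        paths[[length(paths) + 1]] <- list(pts = bpts, width = bw)
      }
    }
  }
  S_cd31 <- psf(2^(-norm_min^2))
  vessel_mask <- S_cd31 >= 0.5
  dist_to_vessel <- dist_to_points(do.call(rbind, lapply(paths, `[[`, "pts")),
                                   c(h, w))

  ## ---- amyloid: plaques + CAA rings -----------------------------------
  P_raw <- matrix(0, h, w)     # parenchymal plaque field
  Rg_raw <- matrix(0, h, w)    # vascular amyloid ring field
  plaque_centers <- NULL
  n_placed <- 0
  if (spec$n_plaques > 0) {
    for (p in seq_len(spec$n_plaques)) {
      R <- stats::runif(1, spec$plaque_radius_range_px[1],
                        spec$plaque_radius_range_px[2])
      ok <- FALSE
      clear <- R + spec$vessel_width_range_px[2] / 2 + 2
      for (try in 1:200) {
        cx <- stats::runif(1, R + 2, w - R - 3)
        cy <- stats::runif(1, R + 2, h - R - 3)
        if (dist_to_vessel[round(cy) + 1, round(cx) + 1] >= clear) { ok <- TRUE; break }
      }
      if (!ok) next
      n_placed <- n_placed + 1
      plaque_centers <- rbind(plaque_centers, c(cx, cy, R))
      win <- ceiling(2.5 * R)
      xs <- max(0, round(cx) - win):min(w - 1, round(cx) + win)
      ys <- max(0, round(cy) - win):min(h - 1, round(cy) + win)
      r <- sqrt(outer(ys - cy, xs - cx, function(a, b) a^2 + b^2))
      P_raw[ys + 1, xs + 1] <- pmax(P_raw[ys + 1, xs + 1], half_max_profile(r, R))
    }
  }
  if (spec$caa_segment_count > 0 && length(paths) > 0) {
    ring_hw <- 1.0
    for (s in seq_len(spec$caa_segment_count)) {
      pidx <- sample.int(length(paths), 1)
      pp <- paths[[pidx]]
      L <- round(stats::runif(1, spec$caa_segment_length_px[1],
                              spec$caa_segment_length_px[2]))
      if (nrow(pp$pts) <= L + 2) {
        seg <- pp$pts
      } else {
        st <- sample.int(nrow(pp$pts) - L, 1)
        seg <- pp$pts[st:(st + L), , drop = FALSE]
      }
      dseg <- dist_to_points(seg, c(h, w))
      r0 <- pp$width / 2
      ring_prof <- 2^(-((dseg - r0) / ring_hw)^2)
      Rg_raw <- pmax(Rg_raw, ring_prof)
    }
  }
  S_x34 <- psf(pmax(P_raw, Rg_raw))
  plaque_mask <- psf(P_raw) >= 0.5
  caa_mask <- psf(Rg_raw) >= 0.5
  amyloid_mask <- S_x34 >= 0.5

  ## ---- astrocytes ------------------------------------------------------
  A_raw <- matrix(0, h, w)
  vessel_pts <- do.call(rbind, lapply(paths, `[[`, "pts"))
  for (a in seq_len(spec$astro_count)) {
    u <- stats::runif(1)
    assoc <- FALSE
    if (u < spec$astro_vessel_assoc_prob && !is.null(vessel_pts)) {
      ctr <- vessel_pts[sample.int(nrow(vessel_pts), 1), ] + stats::rnorm(2, 0, 2)
      assoc <- TRUE
    } else if (u < spec$astro_vessel_assoc_prob + spec$astro_plaque_assoc_prob &&
               !is.null(plaque_centers)) {
      pc <- plaque_centers[sample.int(nrow(plaque_centers), 1), ]
      th <- stats::runif(1, 0, 2 * pi)
      rr <- pc[3] + stats::runif(1, 0, 4)
      ctr <- c(pc[1] + rr * cos(th), pc[2] + rr * sin(th))
      assoc <- TRUE
    } else {
      ctr <- c(stats::runif(1, 8, w - 9), stats::runif(1, 8, h - 9))
    }
    ctr <- pmin(pmax(ctr, 4), c(w - 5, h - 5))
    react <- if (assoc) spec$astro_reactivity else 1
    n_proc <- max(3, round(stats::runif(1, 5, 7) * sqrt(react)))
    base_ang <- stats::runif(1, 0, 2 * pi)
    segs <- NULL
    for (k in seq_len(n_proc)) {
      th <- base_ang + 2 * pi * k / n_proc + stats::rnorm(1, 0, 0.2)
      L <- stats::runif(1, 6, 12) * react
      segs <- rbind(segs, c(ctr[1], ctr[2], ctr[1] + L * cos(th),
                            ctr[2] + L * sin(th)))
    }
    win <- ceiling(max(12 * react, 8)) + 4
    xs <- max(0, round(ctr[1]) - win):min(w - 1, round(ctr[1]) + win)
    ys <- max(0, round(ctr[2]) - win):min(h - 1, round(ctr[2]) + win)
    dproc <- window_segment_dist(xs, ys, segs)
    rsoma <- sqrt(outer(ys - ctr[2], xs - ctr[1], function(a, b) a^2 + b^2))
    prof <- pmax(half_max_profile(dproc, 1.2), half_max_profile(rsoma, 2.5))
    A_raw[ys + 1, xs + 1] <- pmax(A_raw[ys + 1, xs + 1], prof)
  }
  S_gfap <- psf(A_raw)
  astro_mask <- S_gfap >= 0.5
  astro_vascular_mask <- astro_mask & vessel_mask

  ## ---- ICAM-1 ----------------------------------------------------------
  V_raw <- matrix(0, h, w)
  Pb_raw <- matrix(0, h, w)
  n_icam_vessels <- max(1, round(spec$icam_vessel_prob * length(paths)))
  icam_vessel_idx <- sample.int(length(paths), min(n_icam_vessels, length(paths)))
  for (pp in paths[icam_vessel_idx]) {
    d <- dist_to_points(pp$pts, c(h, w))
    # endothelial ICAM-1 lines the inner vessel wall: narrower than CD31
    nd <- d / (0.8 * pp$width / 2)
    V_raw <- pmax(V_raw, 2^(-nd^2))
  }
  if (spec$icam_parenchymal_blob_count > 0) {
    for (b in seq_len(spec$icam_parenchymal_blob_count)) {
      R <- stats::runif(1, 2, 5)
      ok <- FALSE
      clear <- R + spec$vessel_width_range_px[2] / 2 + 2
      for (try in 1:200) {
        cx <- stats::runif(1, R + 2, w - R - 3)
        cy <- stats::runif(1, R + 2, h - R - 3)
        if (dist_to_vessel[round(cy) + 1, round(cx) + 1] >= clear) { ok <- TRUE; break }
      }
      if (!ok) next
      win <- ceiling(2.5 * R)
      xs <- max(0, round(cx) - win):min(w - 1, round(cx) + win)
      ys <- max(0, round(cy) - win):min(h - 1, round(cy) + win)
      r <- sqrt(outer(ys - cy, xs - cx, function(a, b) a^2 + b^2))
      Pb_raw[ys + 1, xs + 1] <- pmax(Pb_raw[ys + 1, xs + 1], half_max_profile(r, R))
    }
  }
  S_icam <- psf(pmax(spec$icam_vascular_amp * V_raw, Pb_raw))
  icam_vascular_mask <- psf(V_raw) >= 0.5
  icam_parench_mask <- psf(Pb_raw) >= 0.5
  icam_mask <- S_icam >= 0.5

  ## ---- rendering -------------------------------------------------------
  ux <- matrix(rep(seq(-1, 1, length.out = w), each = h), h)
  uy <- matrix(rep(seq(-1, 1, length.out = h), w), h)
  coefs <- stats::rnorm(5)
  P <- coefs[1] * ux + coefs[2] * uy + coefs[3] * ux * uy +
    coefs[4] * ux^2 + coefs[5] * uy^2
  P <- P - mean(P)
  if (max(abs(P)) > 0) P <- P / max(abs(P))
  bias <- 1 + spec$bias_field_strength * P

  structures <- list(X34 = S_x34, CD31 = S_cd31, GFAP = S_gfap, ICAM1 = S_icam)
  images <- lapply(CHANNELS, function(ch) {
    amp <- spec$channel_amplitudes[[ch]]
    clean <- bias * (spec$background_level + amp * structures[[ch]])
    if (spec$shot_noise)
      clean <- matrix(stats::rpois(npx, pmax(clean, 0)), h, w)
    img <- clean + stats::rnorm(npx, 0, spec$noise_sd)
    img <- matrix(pmin(pmax(round(img), 0), 255), h, w)
    channel_image(img, ch, spec$pixel_size_um, section_id, animal_id)
  })
  names(images) <- CHANNELS

  rois <- default_section_rois(c(h, w))
  masks <- list(
    vessel = binary_mask(vessel_mask, "ground_truth", "vessel"),
    plaque = binary_mask(plaque_mask, "ground_truth", "plaque"),
    caa = binary_mask(caa_mask, "ground_truth", "caa"),
    amyloid = binary_mask(amyloid_mask, "ground_truth", "amyloid"),
    astro = binary_mask(astro_mask, "ground_truth", "astro"),
    astro_vascular = binary_mask(astro_vascular_mask, "ground_truth", "astro_vascular"),
    icam_vascular = binary_mask(icam_vascular_mask, "ground_truth", "icam_vascular"),
    icam_parenchymal = binary_mask(icam_parench_mask, "ground_truth", "icam_parenchymal"),
    icam = binary_mask(icam_mask, "ground_truth", "icam"))
  truth_metrics <- compute_section_metrics(
    list(X34 = amyloid_mask, CD31 = vessel_mask, GFAP = astro_mask,
         ICAM1 = icam_mask),
    rois, caa_mask = caa_mask, animal_id = animal_id, section_id = section_id)

  list(images = images,
       truth = list(masks = masks, metrics = truth_metrics),
       rois = rois, spec = spec)
}

#' Default rectangular section ROIs
#'
#' A cortical band in the upper part of the section and a hippocampal band
#' below it, as simple rectangles in pixel-center coordinates.
#'
#' @param shape `(rows, cols)`.
#' @return List of two [roi_polygon]s (cortex, hippocampus).
#' @export
default_section_rois <- function(shape) {
  h <- shape[1]; w <- shape[2]
  cortex <- roi_polygon("cortex", cbind(
    c(2, w - 3, w - 3, 2), c(2, 2, round(0.55 * h), round(0.55 * h))))
  hipp <- roi_polygon("hippocampus", cbind(
    c(2, w - 3, w - 3, 2), c(round(0.6 * h), round(0.6 * h), h - 3, h - 3)))
  list(cortex = cortex, hippocampus = hipp)
}

#' Evaluate the built-in metric panel on a set of masks
#'
#' Computes, per region: total area percentages for each marker, vascular
#' GFAP and ICAM-1 (associated with CD31), plaque-associated GFAP
#' (associated with X-34), parenchymal ICAM-1 (total minus vascular), and —
#' in the cortex, where vascular amyloid occurs — the CAA panel
#' ([caa_metrics()]). Used identically for ground-truth masks and for
#' segmented masks, so true and estimated values are directly comparable.
#'
#' @param marker_masks Named list (`X34`, `CD31`, `GFAP`, `ICAM1`) of
#'   [binary_mask]s or logical matrices.
#' @param rois List of [roi_polygon]s (or [binary_mask] rasters).
#' @param caa_mask Optional CAA mask for the cortical CAA panel.
#' @param animal_id,section_id Identifiers.
#' @return Data frame of [quant_record()] rows.
#' @export
compute_section_metrics <- function(marker_masks, rois, caa_mask = NULL,
                                    animal_id = "a1", section_id = "s1") {
  shape <- dim(mask_px(marker_masks[[1]]))
  out <- list()
  for (rg in names(rois)) {
    roi <- rois[[rg]]
    roi_m <- if (inherits(roi, "roi_polygon")) rasterize_roi(roi, shape) else roi
    region <- if (inherits(roi, "roi_polygon")) roi$region else rg
    for (ch in names(marker_masks)) {
      out[[length(out) + 1]] <- total_area_fraction(
        marker_masks[[ch]], roi_m, metric = paste0("total_area_pct.", ch),
        region = region, animal_id = animal_id, section_id = section_id)
    }
    out[[length(out) + 1]] <- associated_fraction(
      marker_masks$GFAP, marker_masks$CD31, roi_m, metric = "vascular_gfap_pct",
      region = region, animal_id = animal_id, section_id = section_id)
    out[[length(out) + 1]] <- associated_fraction(
      marker_masks$ICAM1, marker_masks$CD31, roi_m, metric = "vascular_icam1_pct",
      region = region, animal_id = animal_id, section_id = section_id)
    out[[length(out) + 1]] <- associated_fraction(
      marker_masks$GFAP, marker_masks$X34, roi_m, metric = "plaque_assoc_gfap_pct",
      region = region, animal_id = animal_id, section_id = section_id)
    out[[length(out) + 1]] <- parenchymal_fraction(
      marker_masks$ICAM1, marker_masks$CD31, roi_m,
      metric = "parenchymal_icam1_pct",
      region = region, animal_id = animal_id, section_id = section_id)
    if (region == "cortex" && !is.null(caa_mask)) {
      vgfap <- mask_px(marker_masks$GFAP) & mask_px(marker_masks$CD31)
      out[[length(out) + 1]] <- caa_metrics(
        caa_mask, roi_m, vgfap, region = region,
        animal_id = animal_id, section_id = section_id)
    }
  }
  do.call(rbind, out)
}

#' Default 2x2 cohort effect configuration
#'
#' Group-level multipliers applied to the base [section_spec()], emulating
#' the pattern seen in amyloid-overexpressing mice with and without
#' apolipoprotein A-I: wild-type groups carry no amyloid and quiescent
#' astrocytes; the transgenic apoA-I-deficient group carries roughly
#' threefold parenchymal amyloid, fivefold vascular amyloid, and more
#' reactive (hypertrophic) astrocytes than its apoA-I-hemizygous
#' counterpart.
#'
#' @return Named list of per-group spec deltas.
#' @export
default_cohort_effects <- function() {
  list(
    "WT.HEM" = list(n_plaques = 0, caa_segment_count = 0,
                    astro_count_mult = 0.6, astro_reactivity = 0.8),
    "WT.KO" = list(n_plaques = 0, caa_segment_count = 0,
                   astro_count_mult = 0.6, astro_reactivity = 0.8),
    "APPPS1.HEM" = list(n_plaques_mult = 1, caa_count_mult = 1,
                        astro_count_mult = 1, astro_reactivity = 1),
    "APPPS1.KO" = list(n_plaques_mult = 3.25, caa_count_mult = 5,
                       astro_count_mult = 1.3, astro_reactivity = 1.4))
}

#' Generate a 2x2 synthetic cohort with ground truth
#'
#' Draws per-animal section specs from the base spec, the group effect
#' deltas, and lognormal between-animal variability; generates
#' `sections_per_animal` sections per animal; and returns the design table,
#' the sections, and the true per-animal metric table (unweighted mean over
#' sections of the per-section true metrics). All per-section seeds derive
#' deterministically from `seed`.
#'
#' @param n_per_group Animals per group (>= 1; the factorial stage needs
#'   >= 2).
#' @param sections_per_animal Sections per animal (default 3).
#' @param seed Master seed.
#' @param base_spec Base [section_spec()].
#' @param effects Per-group deltas, see [default_cohort_effects()]; must
#'   cover all four groups.
#' @param animal_cv Between-animal lognormal coefficient of variation
#'   applied to amyloid burden and astrocyte reactivity.
#' @return List with `design`, `sections` (nested list by animal), and
#'   `truth_table` (animal x metric x region true values, long format).
#' @export
generate_cohort <- function(n_per_group = 2, sections_per_animal = 3, seed = 1,
                            base_spec = section_spec(),
                            effects = default_cohort_effects(),
                            animal_cv = 0.25) {
  if (n_per_group < 1) stop("n_per_group must be >= 1")
  groups <- c("WT.HEM", "WT.KO", "APPPS1.HEM", "APPPS1.KO")
  if (!all(groups %in% names(effects))) stop("missing group spec in `effects`")
  n_animals <- 4 * n_per_group
  draws <- withr::with_seed(seed, list(
    section_seeds = matrix(sample.int(.Machine$integer.max - 1,
                                      n_animals * sections_per_animal),
                           n_animals, sections_per_animal),
    animal_mult = stats::rlnorm(n_animals,
                                -log(1 + animal_cv^2) / 2,
                                sqrt(log(1 + animal_cv^2))),
    sexes = sample(rep(c("F", "M"), length.out = n_animals))))
  design <- data.frame(
    animal_id = sprintf("m%02d", seq_len(n_animals)),
    app_genotype = rep(sub("\\..*", "", groups), each = n_per_group),
    apoa1_genotype = rep(sub(".*\\.", "", groups), each = n_per_group),
    sex = draws$sexes, stringsAsFactors = FALSE)
  sections <- list()
  truth_rows <- list()
  for (i in seq_len(n_animals)) {
    grp <- paste(design$app_genotype[i], design$apoa1_genotype[i], sep = ".")
    eff <- effects[[grp]]
    sp <- unclass(base_spec)
    mult <- draws$animal_mult[i]
    if (!is.null(eff$n_plaques)) sp$n_plaques <- eff$n_plaques
    if (!is.null(eff$n_plaques_mult))
      sp$n_plaques <- round(sp$n_plaques * eff$n_plaques_mult * mult)
    if (!is.null(eff$caa_segment_count)) sp$caa_segment_count <- eff$caa_segment_count
    if (!is.null(eff$caa_count_mult))
      sp$caa_segment_count <- round(sp$caa_segment_count * eff$caa_count_mult * mult)
    if (!is.null(eff$astro_count_mult))
      sp$astro_count <- round(sp$astro_count * eff$astro_count_mult)
    if (!is.null(eff$astro_reactivity))
      sp$astro_reactivity <- sp$astro_reactivity * eff$astro_reactivity * mult
    asec <- list()
    for (s in seq_len(sections_per_animal)) {
      sp$seed <- draws$section_seeds[i, s]
      spc <- do.call(section_spec, sp)
      sec <- generate_section(spc, animal_id = design$animal_id[i],
                              section_id = sprintf("%s_s%d", design$animal_id[i], s))
      asec[[s]] <- sec
      truth_rows[[length(truth_rows) + 1]] <- sec$truth$metrics
    }
    sections[[design$animal_id[i]]] <- asec
  }
  truth_records <- do.call(rbind, truth_rows)
  truth_table <- aggregate_per_animal(truth_records, mode = "mean")
  list(design = design, sections = sections,
       truth_records = truth_records, truth_table = truth_table)
}

#' Simulate a per-animal metric table without rendering images
#'
#' The truth-table shortcut for statistical calibration studies: per-animal
#' metric values are drawn directly from the cohort's between-animal model —
#' lognormal variation around the configured group means, so the true group
#' effects are exactly the configured ratios. This is the distributional
#' model `generate_cohort()` induces on true per-animal metrics, without the
#' image-rendering cost.
#'
#' @param group_means Named numeric vector of the four group means, names
#'   `WT.HEM`, `WT.KO`, `APPPS1.HEM`, `APPPS1.KO`.
#' @param n_per_group Animals per group.
#' @param cv Between-animal coefficient of variation (default 0.35, typical
#'   for histological area fractions).
#' @param seed Integer seed.
#' @return Data frame: `animal_id`, `app_genotype`, `apoa1_genotype`,
#'   `value`.
#' @export
simulate_metric_table <- function(group_means, n_per_group = 6, cv = 0.35,
                                  seed = 1) {
  groups <- c("WT.HEM", "WT.KO", "APPPS1.HEM", "APPPS1.KO")
  if (!all(groups %in% names(group_means))) stop("group_means must name all four groups")
  n <- 4 * n_per_group
  sdlog <- sqrt(log(1 + cv^2))
  vals <- withr::with_seed(seed,
    stats::rlnorm(n, -sdlog^2 / 2, sdlog)) *
    rep(as.numeric(group_means[groups]), each = n_per_group)
  data.frame(
    animal_id = sprintf("m%02d", seq_len(n)),
    app_genotype = rep(sub("\\..*", "", groups), each = n_per_group),
    apoa1_genotype = rep(sub(".*\\.", "", groups), each = n_per_group),
    value = vals, stringsAsFactors = FALSE)
}
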