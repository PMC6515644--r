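test_that("component labeling matches a flood-fill oracle and filters speckle", {
  expect_equal(nrow(label_components(matrix(FALSE, 10, 10))$components), 0)

  m <- matrix(FALSE, 20, 20)
  m[2:6, 2:6] <- TRUE          # 5x5 square
  m[12:16, 12:16] <- TRUE      # second 5x5 square
  m[10, 2] <- TRUE             # single-pixel speckle
  lab <- label_components(m, min_component_px = 4)
  expect_equal(nrow(lab$components), 2)
  expect_equal(sort(lab$components$area_px), c(25, 25))
  expect_true(all(abs(lab$components$eccentricity_ratio - 1) < 0.05))
  expect_false(any(lab$labels[10, 2] > 0))   # speckle removed

  # labeled support equals the flood-fill oracle's (8-connectivity)
  withr::with_seed(3, {
    r <- random_mask(30, 30, 0.35)
    ours <- label_components(r, min_component_px = 1)
    orac <- oracle_label8(r)
    expect_equal(max(ours$labels), max(orac))
    # same partition: every our-label maps to exactly one oracle label
    for (id in seq_len(max(ours$labels))) {
      sel <- ours$labels == id
      expect_equal(length(unique(orac[sel])), 1)
    }
  })

  # diagonal chain is one component under 8-connectivity
  dg <- matrix(FALSE, 8, 8); for (i in 1:8) dg[i, i] <- TRUE
  expect_equal(nrow(label_components(dg, 1)$components), 1)
})

test_that("elongated components have large axis ratios", {
  ln <- matrix(FALSE, 30, 30); ln[15, 3:28] <- TRUE
  comp <- label_components(ln, 5)$components
  expect_gte(comp$eccentricity_ratio, 3)
})

test_that("classification separates vessel-apposed rings from round blobs", {
  h <- 64; w <- 64
  vessel <- matrix(FALSE, h, w); vessel[, 30:35] <- TRUE     # vertical band
  x34 <- matrix(FALSE, h, w)
  x34[10:20, 5:15] <- outer(1:11, 1:11, function(a, b)
    (a - 6)^2 + (b - 6)^2 <= 25)                             # round blob far away
  x34[25:40, 29] <- TRUE; x34[25:40, 28] <- TRUE             # band hugging vessel
  lab <- label_components(x34, 10)
  cls <- classify_amyloid(lab, vessel, overlap_min = 0.5,
                          elongation_min = 3, dilation_px = 2)
  expect_equal(sort(cls$components$classification), c("parenchymal", "vascular"))
  round_id <- cls$components$classification == "parenchymal"
  expect_lt(cls$components$vessel_overlap[round_id], 0.5)

  # partition: every retained pixel in exactly one output mask
  keep <- lab$labels > 0
  expect_identical(cls$caa_mask$pixels | cls$plaque_mask$pixels, keep)
  expect_false(any(cls$caa_mask$pixels & cls$plaque_mask$pixels))
})

test_that("generator CAA rings classify as vascular, plaques as parenchymal", {
  sec <- generate_section(tiny_spec(seed = 2))
  masks <- segment_default(sec)
  lab <- label_components(masks$X34, 20)
  cls <- classify_amyloid(lab, masks$CD31)
  gt <- sec$truth$masks
  for (i in seq_len(nrow(cls$components))) {
    sel <- lab$labels == cls$components$component_id[i]
    truth <- if (sum(sel & gt$caa$pixels) > sum(sel & gt$plaque$pixels))
      "vascular" else "parenchymal"
    expect_equal(cls$components$classification[i], truth)
  }
})

test_that("manual CAA masks are intersected with segmented amyloid", {
  x34 <- matrix(FALSE, 12, 12); x34[3:8, 3:8] <- TRUE
  manual_all <- matrix(TRUE, 12, 12)
  expect_identical(ingest_manual_caa(manual_all, x34)$pixels, x34)
  expect_equal(sum(ingest_manual_caa(matrix(FALSE, 12, 12), x34)$pixels), 0)
  withr::with_seed(8, {
    man <- random_mask(12, 12)
    got <- ingest_manual_caa(man, x34)
    expect_equal(sum(got$pixels), oracle_count(man, x34))
    expect_true(all(x34[got$pixels]))    # CAA subset of segmented amyloid
  })
  expect_error(ingest_manual_caa(matrix(TRUE, 5, 5), x34), "mismatch")

  # file ingestion path
  p <- withr::local_tempfile(fileext = ".png")
  write_channel_image(binary_mask(manual_all), p)
  expect_identical(ingest_manual_caa(p, x34)$pixels, x34)
})

test_that("CAA metrics cover empty, saturated and random cases", {
  roi <- matrix(TRUE, 16, 16)
  caa <- matrix(FALSE, 16, 16)
  vg <- random_mask(16, 16)
  m0 <- caa_metrics(caa, roi, vg)
  expect_equal(m0$value[m0$metric == "caa_area_pct"], 0)
  expect_true(is.na(m0$value[m0$metric == "caa_assoc_gfap_pct"]))

  caa[4:8, 4:8] <- TRUE
  m1 <- caa_metrics(caa, roi, matrix(TRUE, 16, 16))   # vGFAP superset of CAA
  expect_equal(m1$value[m1$metric == "caa_assoc_gfap_pct"], 100)

  withr::with_seed(12, {
    caa <- random_mask(16, 16, 0.2); vg <- random_mask(16, 16, 0.3)
    m2 <- caa_metrics(caa, roi, vg)
    expect_equal(m2$numerator_px[m2$metric == "caa_area_pct"], oracle_count(caa, roi))
    expect_equal(m2$numerator_px[m2$metric == "caa_assoc_gfap_pct"],
                 oracle_count(vg, caa, roi))
    expect_equal(m2$denominator_px[m2$metric == "vgfap_assoc_caa_pct"],
                 oracle_count(vg, roi))
  })
})
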