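test_that("identical spec and seed give byte-identical sections", {
  s1 <- generate_section(tiny_spec(seed = 42))
  s2 <- generate_section(tiny_spec(seed = 42))
  for (ch in names(s1$images))
    expect_identical(s1$images[[ch]]$pixels, s2$images[[ch]]$pixels)
  for (nm in names(s1$truth$masks))
    expect_identical(s1$truth$masks[[nm]]$pixels, s2$truth$masks[[nm]]$pixels)
  expect_identical(s1$truth$metrics$value, s2$truth$metrics$value)
  s3 <- generate_section(tiny_spec(seed = 43))
  expect_false(identical(s1$images$X34$pixels, s3$images$X34$pixels))
})

test_that("spec invariants are enforced", {
  expect_error(section_spec(vessel_density = 1.2), "\\[0, 1\\]")
  expect_error(section_spec(astro_vessel_assoc_prob = 0.7,
                            astro_plaque_assoc_prob = 0.6), "sum")
  expect_error(section_spec(background_level = 200,
                            channel_amplitudes = c(X34 = 160, CD31 = 160,
                                                   GFAP = 160, ICAM1 = 160)),
               "exceed")
})

test_that("no plaques requested gives empty plaque and CAA-free amyloid", {
  sec <- generate_section(tiny_spec(seed = 3, n_plaques = 0,
                                    caa_segment_count = 0))
  expect_equal(sum(sec$truth$masks$plaque$pixels), 0)
  expect_equal(sum(sec$truth$masks$caa$pixels), 0)
  expect_equal(sum(sec$truth$masks$amyloid$pixels), 0)
})

test_that("realized vessel density tracks the request within 20 percent", {
  for (sd in 1:4) {
    sec <- generate_section(section_spec(seed = sd))
    frac <- mean(sec$truth$masks$vessel$pixels)
    expect_lt(abs(frac - 0.08) / 0.08, 0.20)
  }
})

test_that("ground-truth masks satisfy the structural containments", {
  sec <- generate_section(tiny_spec(seed = 9))
  gt <- sec$truth$masks
  expect_true(all(gt$amyloid$pixels[gt$caa$pixels]))           # caa within amyloid
  expect_true(all(gt$amyloid$pixels[gt$plaque$pixels]))
  expect_true(all(gt$astro$pixels[gt$astro_vascular$pixels]))
  expect_true(all(gt$vessel$pixels[gt$astro_vascular$pixels]))
  vals <- sec$truth$metrics$value
  vals <- vals[!is.na(vals)]
  expect_true(all(vals >= 0 & vals <= 100))
})

test_that("stored true metrics equal mask-algebra reevaluation exactly", {
  sec <- generate_section(tiny_spec(seed = 14))
  gt <- sec$truth$masks
  again <- compute_section_metrics(
    list(X34 = gt$amyloid, CD31 = gt$vessel, GFAP = gt$astro, ICAM1 = gt$icam),
    sec$rois, caa_mask = gt$caa, animal_id = "a1", section_id = "s1")
  expect_identical(again$value, sec$truth$metrics$value)
  expect_identical(again$numerator_px, sec$truth$metrics$numerator_px)
})

test_that("cohort generation is deterministic with configured group effects", {
  spec <- tiny_spec(seed = 1)
  ch1 <- generate_cohort(n_per_group = 1, sections_per_animal = 1, seed = 5,
                         base_spec = spec)
  ch2 <- generate_cohort(n_per_group = 1, sections_per_animal = 1, seed = 5,
                         base_spec = spec)
  expect_identical(ch1$truth_table, ch2$truth_table)
  expect_equal(nrow(ch1$design), 4)
  expect_setequal(unique(paste(ch1$design$app_genotype, ch1$design$apoa1_genotype)),
                  c("WT HEM", "WT KO", "APPPS1 HEM", "APPPS1 KO"))
  # wild-type groups carry no amyloid under the default effects
  wt_ids <- ch1$design$animal_id[ch1$design$app_genotype == "WT"]
  tt <- ch1$truth_table
  x34 <- tt[tt$metric == "total_area_pct.X34" & tt$animal_id %in% wt_ids, ]
  expect_true(all(x34$value == 0))

  expect_error(generate_cohort(n_per_group = 0), ">= 1")
  expect_error(generate_cohort(1, 1, 1, spec, effects = list()), "missing group")
})

test_that("configured effect multipliers shift true cohort means", {
  eff <- default_cohort_effects()
  eff$`APPPS1.KO`$astro_reactivity <- 3
  ch <- generate_cohort(n_per_group = 2, sections_per_animal = 1, seed = 11,
                        base_spec = tiny_spec(seed = 1, astro_count = 15),
                        effects = eff, animal_cv = 0.05)
  tt <- merge(ch$truth_table, ch$design, by = "animal_id")
  vg <- tt[tt$metric == "total_area_pct.GFAP" & tt$region == "cortex", ]
  m_ko <- mean(vg$value[vg$app_genotype == "APPPS1" & vg$apoa1_genotype == "KO"])
  m_hem <- mean(vg$value[vg$app_genotype == "APPPS1" & vg$apoa1_genotype == "HEM"])
  expect_gt(m_ko, 1.5 * m_hem)
})

test_that("the metric-table shortcut reproduces configured group ratios", {
  gm <- c(WT.HEM = 0.21, WT.KO = 0.30, APPPS1.HEM = 1.80, APPPS1.KO = 3.86)
  tb <- simulate_metric_table(gm, n_per_group = 4000, cv = 0.35, seed = 2)
  got <- tapply(tb$value, paste(tb$app_genotype, tb$apoa1_genotype, sep = "."),
                mean)
  expect_equal(as.numeric(got[names(gm)]), unname(gm), tolerance = 0.03)
  # deterministic and seed-sensitive
  expect_identical(simulate_metric_table(gm, 5, seed = 7),
                   simulate_metric_table(gm, 5, seed = 7))
  expect_false(identical(simulate_metric_table(gm, 5, seed = 7)$value,
                         simulate_metric_table(gm, 5, seed = 8)$value))
})
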