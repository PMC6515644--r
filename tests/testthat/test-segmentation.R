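test_that("global threshold is inclusive and total", {
  img <- channel_image(matrix(10, 6, 6), "X34")
  expect_true(all(apply_global_threshold(img, 5)$pixels))
  expect_true(all(apply_global_threshold(img, 10)$pixels))   # inclusive >=
  expect_false(any(apply_global_threshold(img, 11)$pixels))

  ramp <- matrix(0:63, 8, 8)
  expect_equal(sum(apply_global_threshold(ramp, 32)$pixels), 32)
  m <- apply_global_threshold(img, 5)
  expect_equal(m$provenance, "threshold_global")
})

test_that("global threshold masks are nested in the cutoff", {
  withr::with_seed(42, {
    for (i in 1:20) {
      img <- matrix(sample(0:255, 400, replace = TRUE), 20, 20)
      t1 <- sample(0:200, 1); t2 <- t1 + sample(0:55, 1)
      m1 <- apply_global_threshold(img, t1)$pixels
      m2 <- apply_global_threshold(img, t2)$pixels
      expect_true(all(m1 | !m2))   # mask(T2) subset of mask(T1)
    }
  })
})

test_that("pooled Otsu separates bimodal histograms and rejects constants", {
  two_peaks <- matrix(rep(c(10, 200), each = 50), 10, 10)
  t <- suggest_global_threshold(two_peaks, "otsu")
  expect_gt(t, 10); expect_lte(t, 200)
  expect_error(suggest_global_threshold(matrix(7, 5, 5)), "constant")
  expect_error(suggest_global_threshold(list()), "at least one")
})

test_that("Otsu on a Gaussian mixture matches an exhaustive variance scan", {
  imgs <- withr::with_seed(9, {
    v <- c(rnorm(3600, 20, 3), rnorm(400, 180, 3))
    list(matrix(pmin(pmax(round(v[1:2000]), 0), 255), 40, 50),
         matrix(pmin(pmax(round(v[2001:4000]), 0), 255), 40, 50))
  })
  t_impl <- suggest_global_threshold(imgs, "otsu")
  # oracle: scan every candidate cutoff on the pooled histogram
  vals <- c(imgs[[1]], imgs[[2]])
  best <- -Inf; tbest <- NA
  for (tc in 0:254) {
    lo <- vals[vals <= tc]; hi <- vals[vals > tc]
    if (!length(lo) || !length(hi)) next
    bcv <- length(lo) * length(hi) * (mean(lo) - mean(hi))^2
    if (bcv > best) { best <- bcv; tbest <- tc + 1 }
  }
  expect_equal(t_impl, tbest)
  expect_gt(t_impl, 30); expect_lt(t_impl, 170)
})

test_that("triangle threshold lands between a dominant peak and its far tail", {
  img <- withr::with_seed(4, {
    v <- c(rnorm(3800, 30, 4), runif(200, 120, 220))
    matrix(pmin(pmax(round(v), 0), 255), 40, 100)
  })
  t <- suggest_global_threshold(img, "triangle")
  expect_gt(t, 30); expect_lt(t, 220)
})

test_that("Bernsen handles constant and step-edge images as specified", {
  cfg <- threshold_config(bernsen_radius_px = 3, bernsen_contrast_min = 15)
  expect_false(any(apply_bernsen_threshold(matrix(50, 20, 20), cfg)$pixels))
  cfg_fg <- threshold_config(bernsen_radius_px = 3, bernsen_contrast_min = 15,
                             bernsen_low_contrast_assignment = "foreground")
  expect_true(all(apply_bernsen_threshold(matrix(50, 20, 20), cfg_fg)$pixels))

  step <- cbind(matrix(0, 20, 10), matrix(200, 20, 10))
  m <- apply_bernsen_threshold(step, cfg)$pixels
  expect_true(all(m[, 11:13]))       # near-edge right side positive
  expect_false(any(m[, 8:10]))       # near-edge left side negative
  expect_false(any(m[, 1:7]))        # far left: low contrast -> background
  expect_false(any(m[, 14:20]))      # far right: low contrast -> background
})

test_that("Bernsen equals the per-pixel oracle on random images", {
  withr::with_seed(11, {
    for (i in 1:6) {
      pix <- matrix(sample(0:255, 64 * 64, replace = TRUE), 64, 64)
      r <- sample(c(2, 3, 5), 1); cmin <- sample(c(0, 10, 40), 1)
      low_fg <- i %% 2 == 0
      cfg <- threshold_config(
        bernsen_radius_px = r, bernsen_contrast_min = cmin,
        bernsen_low_contrast_assignment = if (low_fg) "foreground" else "background")
      expect_identical(apply_bernsen_threshold(pix, cfg)$pixels,
                       oracle_bernsen(pix, r, cmin, low_fg))
    }
  })
})

test_that("Bernsen is invariant to a constant intensity offset", {
  withr::with_seed(13, {
    pix <- matrix(sample(0:150, 32 * 32, replace = TRUE), 32, 32)
    cfg <- threshold_config(bernsen_radius_px = 4, bernsen_contrast_min = 20)
    m0 <- apply_bernsen_threshold(pix, cfg)$pixels
    for (k in c(1, 25, 100))
      expect_identical(apply_bernsen_threshold(pix + k, cfg)$pixels, m0)
  })
})

test_that("8-bit conversion rescales min-max linearly", {
  img <- channel_image(matrix(c(100, 300, 500, 700), 2, 2), "X34")
  out <- convert_to_8bit(img)
  expect_equal(range(out$pixels), c(0, 255))
  expect_equal(out$pixels[1, 2], 170)
})
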