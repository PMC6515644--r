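test_that("a solid bar skeletonizes to a single straight edge", {
  bar <- matrix(FALSE, 40, 120); bar[17:23, 11:110] <- TRUE
  g <- skeletonize_vessels(bar, min_branch_px = 10, pixel_size_um = 1)
  expect_length(g$edges, 1)
  g <- edge_tortuosity(edge_diameter(g))
  expect_equal(g$edges[[1]]$tortuosity, 1)              # collinear chain
  expect_equal(g$edges[[1]]$diameter_um, 7, tolerance = 1e-8)
  # chain stays on the bar's central row
  expect_true(all(g$edges[[1]]$chain[, 2] == 19))
})

test_that("crossing bars produce one junction and four arms", {
  pl <- matrix(FALSE, 60, 60)
  pl[28:32, 6:55] <- TRUE
  pl[6:55, 28:32] <- TRUE
  g <- skeletonize_vessels(pl, min_branch_px = 10)
  expect_length(g$edges, 4)
  # all four arms meet at a shared node cluster
  ends <- table(unlist(lapply(g$edges, function(e) c(e$from, e$to))))
  expect_true(any(ends == 4))
})

test_that("empty masks and compact artifacts yield empty graphs", {
  expect_length(skeletonize_vessels(matrix(FALSE, 30, 30))$edges, 0)
  disk <- mk_tube_mask(40, 40, cbind(20, 20), 12)       # no elongation
  expect_length(skeletonize_vessels(disk, min_branch_px = 10)$edges, 0)
  s <- summarize_vessels(skeletonize_vessels(disk, 10))
  expect_equal(s$summary$n_edges, 0)
})

test_that("tube width is recovered within one pixel across orientations", {
  for (wd in c(3, 5, 7, 9, 11)) {
    for (ang in c(0, 30, 45, 90)) {
      m <- mk_tube_mask(128, 128, mk_line_pts(c(64, 64), ang, 45), wd)
      g <- edge_diameter(skeletonize_vessels(m, min_branch_px = 10))
      dias <- vapply(g$edges, function(e) e$diameter_um, numeric(1))
      lens <- vapply(g$edges, function(e) e$path_length_px, numeric(1))
      expect_gt(length(dias), 0)
      expect_lte(abs(stats::weighted.mean(dias, lens) - wd), 1)
    }
  }
})

test_that("tortuosity matches analytic arc/chord oracles", {
  # semicircle radius 40: tortuosity = (pi R) / (2 R) = pi/2
  th <- seq(0, pi, length.out = 600)
  m <- mk_tube_mask(128, 128, cbind(60 + 40 * cos(th), 15 + 40 * sin(th)), 5)
  g <- edge_tortuosity(skeletonize_vessels(m, min_branch_px = 10))
  lens <- vapply(g$edges, function(e) e$path_length_px, numeric(1))
  tor <- g$edges[[which.max(lens)]]$tortuosity
  expect_lt(abs(tor - pi / 2) / (pi / 2), 0.05)

  # sine tube: oracle is the quadrature arc length / chord
  A <- 12; lam <- 60
  x <- seq(10, 110, by = 0.25)
  m2 <- mk_tube_mask(128, 128, cbind(x, 64 + A * sin(2 * pi * x / lam)), 5)
  g2 <- edge_tortuosity(skeletonize_vessels(m2, min_branch_px = 10))
  lens2 <- vapply(g2$edges, function(e) e$path_length_px, numeric(1))
  tor2 <- g2$edges[[which.max(lens2)]]$tortuosity
  arc <- stats::integrate(function(x)
    sqrt(1 + (A * 2 * pi / lam * cos(2 * pi * x / lam))^2), 10, 110)$value
  expect_lt(abs(tor2 - arc / 100) / (arc / 100), 0.05)

  # every edge satisfies the tortuosity and length invariants
  for (e in c(g$edges, g2$edges)) {
    expect_gte(e$tortuosity, 1 - 1e-9)
    expect_gte(e$path_length_px, e$chord_length_px - 1e-9)
  }
})

test_that("closed loops are split at their farthest pair, not dropped", {
  th <- seq(0, 2 * pi, length.out = 700)[-700]
  ring <- mk_tube_mask(96, 96, cbind(48 + 30 * cos(th), 48 + 30 * sin(th)), 5)
  g <- edge_tortuosity(skeletonize_vessels(ring, min_branch_px = 10))
  expect_gte(length(g$edges), 2)
  for (e in g$edges) {
    expect_gt(e$chord_length_px, 0)
    expect_true(is.finite(e$tortuosity))
  }
  # two half-circles: each should be near pi/2
  lens <- vapply(g$edges, function(e) e$path_length_px, numeric(1))
  big <- order(lens, decreasing = TRUE)[1:2]
  for (i in big)
    expect_lt(abs(g$edges[[i]]$tortuosity - pi / 2) / (pi / 2), 0.10)
})

test_that("skeleton length is invariant under translation and rotation", {
  A <- 10; lam <- 50
  x <- seq(8, 88, by = 0.25)
  m <- mk_tube_mask(112, 112, cbind(x, 56 + A * sin(2 * pi * x / lam)), 5)
  total_len <- function(mask) {
    g <- skeletonize_vessels(mask, min_branch_px = 10)
    sum(vapply(g$edges, function(e) e$path_length_px, numeric(1)))
  }
  base <- total_len(m)
  shifted <- matrix(FALSE, 112, 112)
  shifted[11:112, 6:112] <- m[1:102, 1:107]
  expect_lt(abs(total_len(shifted) - base) / base, 0.02)
  rot90 <- t(m[nrow(m):1, ])
  expect_lt(abs(total_len(rot90) - base) / base, 0.02)
})

test_that("per-section summaries weight by edge path length", {
  bar <- matrix(FALSE, 50, 100)
  bar[10:14, 6:95] <- TRUE     # long, width 5
  bar[30:38, 26:55] <- TRUE    # short, width 9
  g <- edge_tortuosity(edge_diameter(skeletonize_vessels(bar, 10)))
  s <- summarize_vessels(g, section_id = "phantom")
  expect_equal(s$summary$n_edges, nrow(s$edges))
  w <- s$edges$path_length_um
  expect_equal(s$summary$mean_diameter_um,
               sum(s$edges$diameter_um * w) / sum(w))
  expect_equal(s$summary$vessel_area_fraction, mean(bar))
  unw <- summarize_vessels(g, "phantom", weighted = FALSE)
  expect_equal(unw$summary$mean_diameter_um, mean(s$edges$diameter_um))
})
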