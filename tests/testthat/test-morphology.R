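# Segmentation, the radial aspect-ratio statistic, and fluidity-class
# clustering.

test_that("segmentation finds programmed objects and tolerates blanks", {
  blank <- matrix(0.05, 128, 128)
  seg <- segment_condensates(blank)
  expect_equal(seg$n, 0)
  expect_equal(nrow(seg$objects), 0)

  sh <- gen_shapes(n_discs = 5, disc_radius = 20, dims = c(400, 400), seed = 21)
  seg <- segment_condensates(sh$image)
  expect_equal(seg$n, 5)
  # recovered areas within 5% of pi r^2
  expect_true(all(abs(seg$objects$area - pi * 20^2) / (pi * 20^2) < 0.05))

  # two touching discs merge without watershed, split with it
  img <- matrix(0, 160, 160)
  for (c0 in list(c(60, 80), c(95, 80))) {
    idx <- which((row(img) - c0[1])^2 + (col(img) - c0[2])^2 <= 20^2)
    img[idx] <- 1
  }
  expect_equal(segment_condensates(img)$n, 1)
  expect_equal(segment_condensates(img, watershed = TRUE)$n, 2)
})

test_that("aspect ratio vanishes for discs, is 1/3 for 2:1 ellipses, near 1 for rods", {
  disc <- gen_shapes(n_discs = 1, disc_radius = 35, dims = c(128, 128),
                     seed = 1)
  ar_disc <- condensate_shapes(disc$image)$aspect_ratio
  expect_lt(ar_disc, 0.05)

  ell <- gen_shapes(n_discs = 0, n_ellipses = 1, ellipse_axes = c(40, 20),
                    dims = c(160, 160), seed = 1)
  ar_ell <- condensate_shapes(ell$image)$aspect_ratio
  expect_lt(abs(ar_ell - 1 / 3), 0.03)

  rod <- gen_shapes(n_discs = 0, n_ellipses = 1, ellipse_axes = c(60, 4),
                    dims = c(200, 200), seed = 1)
  ar_rod <- condensate_shapes(rod$image, min_area = 10)$aspect_ratio
  expect_gt(ar_rod, 0.8)
})

test_that("aspect ratio is invariant under rotation and scaling", {
  ar_at <- function(axes, angle, dims = c(256, 256)) {
    sh <- gen_shapes(n_discs = 0, n_ellipses = 1, ellipse_axes = axes,
                     ellipse_angle = angle, dims = dims, seed = 1)
    condensate_shapes(sh$image)$aspect_ratio
  }
  base <- ar_at(c(40, 20), 0)
  for (th in c(pi / 6, pi / 4, 1.1)) {
    expect_lt(abs(ar_at(c(40, 20), th) - base), 0.03)
  }
  expect_lt(abs(ar_at(c(60, 30), 0) - base), 0.03)
})

test_that("degenerate single-pixel masks get aspect ratio zero", {
  m <- matrix(FALSE, 9, 9); m[5, 5] <- TRUE
  shp <- aspect_ratio(m)
  expect_identical(shp$aspect_ratio, 0)
  expect_true(shp$degenerate)
  expect_error(aspect_ratio(matrix(FALSE, 4, 4)), "empty")
})

test_that("classify_conditions recovers planted clusters and orders regions", {
  set.seed(99)
  centers <- list(I = c(0.05, 0.7), II = c(0.1, 0.1), III = c(0.5, 0.05))
  rec <- do.call(rbind, lapply(names(centers), function(nm) {
    data.frame(truth = nm,
               mean_aspect_ratio = rnorm(12, centers[[nm]][1], 0.01),
               mean_mobile_fraction = rnorm(12, centers[[nm]][2], 0.01))
  }))
  out <- classify_conditions(rec, k = 3)
  expect_equal(rand_index_adjusted(out$region, rec$truth), 1)
  # region labels follow decreasing mobile fraction
  expect_setequal(out$region[rec$truth == "I"], "I")
  expect_setequal(out$region[rec$truth == "II"], "II")
  expect_setequal(out$region[rec$truth == "III"], "III")

  # permuting the input rows permutes, but does not change, the labels
  perm <- sample(nrow(rec))
  out_p <- classify_conditions(rec[perm, ], k = 3)
  expect_identical(out_p$region, out$region[perm])

  # degenerate all-identical input is handled deterministically
  same <- data.frame(mean_aspect_ratio = rep(0.2, 5),
                     mean_mobile_fraction = rep(0.5, 5))
  r1 <- classify_conditions(same, k = 3)$region
  r2 <- classify_conditions(same, k = 3)$region
  expect_identical(r1, r2)

  expect_error(classify_conditions(rec[1:2, ], k = 3), "at least k")
})

test_that("annotate_phase_diagram flags absent cells and keeps the grid tidy", {
  grid <- gen_condition_grid(seed = 8)
  ann <- annotate_phase_diagram(grid)
  expect_identical(ann$detected, !is.na(ann$mean_mobile_fraction) &
                     !is.na(ann$mean_aspect_ratio))
  expect_identical(ann$detected, ann$detected_true)
  expect_true(all(ann$region[!ann$detected] == "no condensates"))
  expect_true(all(ann$region[ann$detected] %in% c("I", "II", "III")))

  # short DNA requires high concentrations: absences concentrate at
  # short lengths / low concentrations
  short_low <- ann$dna_length_bp == 12 & ann$dna_concentration < 1e-6
  expect_true(all(!ann$detected[short_low]))

  empty <- annotate_phase_diagram(grid[0, ])
  expect_equal(nrow(empty), 0)

  # region III fraction increases with length (noiseless construction)
  g0 <- gen_condition_grid(noise_mf = 0, noise_ar = 0, seed = 1)
  a0 <- annotate_phase_diagram(g0)
  det <- a0[a0$detected, ]
  frac3 <- tapply(det$region == "III", det$dna_length_bp, mean)
  expect_true(all(diff(frac3[order(as.numeric(names(frac3)))]) >= 0))
})
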