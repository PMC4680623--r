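test_that("scaffold and total volume are voxel counts times the voxel volume", {
  m <- array(FALSE, c(12, 12, 12)); m[seq_len(1000)] <- TRUE
  expect_equal(scaffold_volume(binary_volume(m, 17.7)), 1000 * 17.7^3)
  expect_equal(scaffold_volume(binary_volume(m, 35.4)),
               8 * scaffold_volume(binary_volume(m, 17.7)))

  cube <- array(FALSE, c(54, 54, 54)); cube[3:52, 3:52, 3:52] <- TRUE
  expect_equal(scaffold_volume(binary_volume(cube, 2)), 125000 * 8)

  # convex solid: TV == SV
  m2 <- array(FALSE, c(14, 14, 14)); m2[3:12, 3:12, 3:12] <- TRUE
  t2 <- build_ternary(binary_volume(m2, 17.7))
  expect_equal(total_volume(t2), scaffold_volume(binary_volume(m2, 17.7)))

  # hollow cube: TV 1000 v^3, SV 973 v^3
  m3 <- m2; m3[7:9, 7:9, 7:9] <- FALSE
  t3 <- build_ternary(binary_volume(m3, 17.7))
  expect_equal(total_volume(t3), 1000 * 17.7^3)
  expect_equal(scaffold_volume(binary_volume(m3, 17.7)), 973 * 17.7^3)

  # random blob: TV equals the brute-force hull-membership count
  set.seed(8)
  blob <- array(FALSE, c(9, 9, 9))
  blob[cbind(sample(2:8, 25, TRUE), sample(2:8, 25, TRUE),
             sample(2:8, 25, TRUE))] <- TRUE
  tb <- tryCatch(build_ternary(binary_volume(blob, 3)), error = function(e) NULL)
  if (!is.null(tb)) {
    pts <- which(blob, arr.ind = TRUE)
    queries <- as.matrix(expand.grid(z = 1:9, y = 1:9, x = 1:9))
    expect_equal(total_volume(tb), sum(bf_hull_membership(pts, queries)) * 27)
  }

  expect_error(scaffold_volume(binary_volume(array(FALSE, c(3, 3, 3)), 1)),
               "empty")
})

test_that("surface estimation is within 5% on analytic shapes and scales as v^2", {
  ball <- make_ball(25L)
  SSb <- scaffold_surface(binary_volume(ball, 1))
  expect_lt(abs(SSb / (4 * pi * 25^2) - 1), 0.05)

  box <- array(FALSE, c(50, 45, 40)); box[6:45, 6:40, 6:35] <- TRUE
  SSx <- scaffold_surface(binary_volume(box, 1))
  expect_lt(abs(SSx / (2 * (40 * 35 + 35 * 30 + 40 * 30)) - 1), 0.05)

  small <- make_ball(8L)
  s1 <- scaffold_surface(binary_volume(small, 1))
  s2 <- scaffold_surface(binary_volume(small, 2))
  expect_equal(s2 / s1, 4)
})

test_that("porosity and surface-to-volume obey their defining ratios", {
  expect_equal(porosity(10, 10), 0)
  expect_equal(porosity(0.4 * 5, 5), 0.6)
  expect_error(porosity(1, 0), "positive")
  expect_error(porosity(2, 1), "exceeds")

  expect_equal(surface_to_volume(6, 1), 6)
  expect_equal(surface_to_volume(12, 2), 2 * surface_to_volume(6, 2))
  expect_error(surface_to_volume(6, 0), "positive")
})

test_that("mineral density statistics match a flat-list computation and use HU when calibrated", {
  g <- voxel_grid(array(c(rep(100, 400), rep(200, 400)), c(8, 10, 10)), 17.7,
                  calibration = list(slope = 2, intercept = -100))
  m <- binary_volume(array(TRUE, c(8, 10, 10)), 17.7)
  tmd <- tissue_mineral_density(g, m)
  expect_equal(tmd$sv$mean, mean(2 * c(rep(100, 400), rep(200, 400)) - 100))
  expect_equal(tmd$unit, "HU")

  const <- voxel_grid(array(150, c(4, 4, 4)) +
                        array(rep(c(0, 1e-9), 32), c(4, 4, 4)), 17.7)
  mc <- binary_volume(array(TRUE, c(4, 4, 4)), 17.7)
  tc <- tissue_mineral_density(const, mc)
  expect_lt(tc$sv$sd, 1e-8)
  expect_equal(tc$sv$mean, 150, tolerance = 1e-9)
  expect_equal(tc$unit, "grey")

  set.seed(12)
  ph <- small_phantom(seed = 12L)
  mask <- binary_volume(ph$truth$construct, 17.7)
  tn <- tissue_mineral_density(ph$grid, mask)
  vals <- ph$grid$intensities[mask$mask]
  expect_equal(tn$sv$mean, mean(vals))
  expect_equal(tn$sv$sd, sd(vals))
  expect_equal(sum(tn$sv$hist$counts), length(vals))
})

test_that("pore summary parameters follow their definitions", {
  mk <- function(d, trimmed = TRUE) pore_distribution(
    data.frame(z = seq_along(d), y = rep(1L, length(d)),
               x = rep(1L, length(d)), zc = seq_along(d),
               yc = rep(1, length(d)), xc = rep(1, length(d)),
               radius_vox = d / 2, diameter_um = d), 1,
    trimmed = trimmed, trim_fraction = 0.05, n_untrimmed = length(d))

  one <- pore_metrics(mk(2))
  expect_equal(one$PV_um3, 4 * pi / 3)
  expect_identical(one$PN, 1L)

  two <- pore_metrics(mk(c(100, 300)))
  expect_equal(two$PS_mean_um, 200)
  expect_equal(two$PV_um3, pi / 6 * (100^3 + 300^3))

  set.seed(4)
  d <- exp(rnorm(1000, log(120), 0.4))
  pm <- pore_metrics(mk(d))
  expect_identical(pm$PN, 1000L)
  expect_equal(pm$PS_mean_um, mean(d))
  expect_equal(pm$PS_sd_um, sd(d))
  expect_equal(pm$PV_um3, sum(pi / 6 * d^3))

  expect_error(pore_metrics(mk(numeric(0))), "empty")
  expect_error(pore_metrics(mk(c(1, 2), trimmed = FALSE)), "trimmed")
})

test_that("pore size histograms use half-open bins and conserve the count", {
  mk <- function(d) pore_distribution(
    data.frame(z = seq_along(d), y = rep(1L, length(d)),
               x = rep(1L, length(d)), zc = seq_along(d),
               yc = rep(1, length(d)), xc = rep(1, length(d)),
               radius_vox = d / 2, diameter_um = d), 1,
    trimmed = TRUE, trim_fraction = 0.05, n_untrimmed = length(d))

  h <- psr_histogram(mk(c(50, 150, 250)), 100)
  expect_equal(h$counts, c(1, 1, 1))
  expect_equal(h$edges, c(0, 100, 200, 300))

  hb <- psr_histogram(mk(100), 100)
  expect_equal(hb$counts, c(0, 1))   # 100 falls in [100, 200)

  set.seed(2)
  d <- runif(500, 5, 640)
  hh <- psr_histogram(mk(d), 10)
  expect_equal(sum(hh$counts), 500)
  both <- psr_histogram(mk(d), 10, report_bins = seq(0, 700, 100))
  expect_equal(sum(both$coarse$counts), 500)
  expect_error(psr_histogram(mk(d), -1), "positive")
})

test_that("report identities hold to 1e-12 and zero pores are handled", {
  ph <- small_phantom(seed = 21L, cavities = 3L)
  res <- analyze_grid(ph$grid, mct_config(), timepoint = "T0")
  r <- res$report
  expect_lt(abs(r$P - (1 - r$SV_um3 / r$TV_um3)), 1e-12 * max(1, r$P))
  expect_lt(abs(r$SR_per_um - r$SS_um2 / r$SV_um3),
            1e-12 * max(1, r$SR_per_um))
  expect_identical(r$PN, nrow(res$pores$pores))
  expect_equal(sum(r$PSR$counts), r$PN)

  ph0 <- small_phantom(seed = 22L, cavities = 0L)
  res0 <- analyze_grid(ph0$grid, mct_config(), timepoint = "T0")
  expect_identical(res0$report$PN, 0L)
  expect_identical(res0$report$PV_um3, 0)
  expect_true(is.na(res0$report$PS_mean_um))
})
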