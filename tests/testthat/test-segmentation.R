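test_that("Otsu threshold separates two populations and matches the exhaustive scan", {
  a <- array(c(rep(10, 500), rep(200, 500)), c(10, 10, 10))
  thr <- otsu_threshold(a)
  expect_gt(thr, 10)
  expect_lte(thr, 200)
  expect_true(all((a >= thr) == (a == 200)))

  set.seed(21)
  n <- 32^3
  x <- c(rnorm(n / 2, 50, 10), rnorm(n / 2, 200, 10))
  g <- array(sample(x), c(32, 32, 32))
  expect_equal(otsu_threshold(g), bf_otsu(as.vector(g)))

  expect_error(otsu_threshold(array(5, c(4, 4, 4))), "constant")
})

test_that("centre of mass is the rounded unweighted mean index", {
  m <- array(FALSE, c(8, 8, 8)); m[3, 4, 5] <- TRUE
  expect_identical(center_of_mass(m), c(3L, 4L, 5L))

  cube <- array(FALSE, c(21, 21, 21)); cube[8:14, 8:14, 8:14] <- TRUE
  expect_identical(center_of_mass(cube), c(11L, 11L, 11L))

  two <- array(FALSE, c(5, 5, 5)); two[1, 1, 1] <- TRUE; two[3, 1, 1] <- TRUE
  expect_identical(center_of_mass(two), c(2L, 1L, 1L))

  expect_error(center_of_mass(array(FALSE, c(3, 3, 3))), "empty")
})

test_that("orthogonal slices are the three planes through the centre", {
  g <- array(seq_len(125), c(5, 5, 5))
  s <- extract_orthogonal_slices(g, c(2, 3, 4))
  expect_equal(s$transversal, g[2, , ], ignore_attr = TRUE)
  expect_equal(s$coronal, g[, 3, ], ignore_attr = TRUE)
  expect_equal(s$sagittal, g[, , 4], ignore_attr = TRUE)
  s2 <- extract_orthogonal_slices(g, c(1, 3, 3))
  expect_equal(s2$transversal, g[1, , ], ignore_attr = TRUE)
  expect_error(extract_orthogonal_slices(g, c(0, 3, 3)), "bounds")
})

test_that("fuzzy memberships separate well-split phases and match the plain FCM oracle", {
  sl <- matrix(c(rep(20, 50), rep(220, 50)), 10, 10)
  mem <- fuzzy_membership(sl, seed = 1L)
  expect_true(all(mem[sl == 220] > 0.5))
  expect_true(all(mem[sl == 20] < 0.5))

  set.seed(33)
  x <- c(rnorm(800, 50, 10), rnorm(800, 200, 10))
  init <- quantile(x, c(0.05, 0.95), names = FALSE)
  ours <- fcm_cluster(x, init)
  oracle <- bf_fcm(x, init)
  expect_lt(max(abs(ours$membership - oracle$membership)), 1e-3)
  expect_equal(ours$centers, oracle$centers, tolerance = 1e-4)

  expect_error(fuzzy_membership(matrix(3, 5, 5)), "constant")
})

test_that("fuzzy memberships agree with an independent library implementation", {
  set.seed(44)
  x <- c(rnorm(600, 60, 12), rnorm(600, 190, 12))
  init <- quantile(x, c(0.05, 0.95), names = FALSE)
  ours <- fcm_cluster(x, init)
  ref <- e1071::cmeans(matrix(x), centers = matrix(init), m = 2,
                       iter.max = 300)
  expect_equal(sort(ours$centers), sort(as.vector(ref$centers)),
               tolerance = 1e-3)
  k <- which.max(ref$centers)
  expect_lt(max(abs(ours$membership[, which.max(ours$centers)] -
                      ref$membership[, k])), 1e-2)
})

test_that("the masked slice minimum is the lowest construct intensity", {
  sl <- matrix(c(120, 121, 250, 40), 2, 2)
  mem <- matrix(c(0.9, 0.8, 0.7, 0.1), 2, 2)
  expect_equal(slice_masked_minimum(sl, mem), 120)
  expect_error(slice_masked_minimum(sl, matrix(0.4, 2, 2)),
               "no construct")

  set.seed(9)
  sl2 <- matrix(runif(400, 0, 255), 20, 20)
  mem2 <- matrix(runif(400), 20, 20)
  sel <- mem2 > 0.5
  expect_equal(slice_masked_minimum(sl2, mem2), min(sl2[sel]))
})

test_that("the global threshold is the mean of the three slice minima", {
  ph <- small_phantom(seed = 2L)
  out <- compute_global_threshold(ph$grid)
  expect_equal(out$threshold_grey, mean(out$slice_minima))
  expect_length(out$slice_minima, 3L)
  d <- dim(ph$grid$intensities)
  expect_true(all(out$com_index >= 1L & out$com_index <= d))

  # a grid whose three central slices are statistically identical by
  # symmetry: constant construct on constant background
  g <- array(30, c(21, 21, 21)); g[6:16, 6:16, 6:16] <- 210
  g[1] <- 29   # ensure two distinct values outside the construct too
  out2 <- compute_global_threshold(voxel_grid(g, 17.7))
  expect_equal(length(unique(out2$slice_minima)), 1L)
  expect_equal(out2$threshold_grey, out2$slice_minima[[1L]])
})

test_that("automatic segmentation is deterministic and misclassifies <1% on a two-phase phantom", {
  ph <- generate_phantom(phantom_spec(shape = c(48L, 48L, 48L),
                                      cavities = 3L, radius_range = c(3, 5),
                                      margin = 6L, noise_sd = 10,
                                      seed = 5L))
  out1 <- compute_global_threshold(ph$grid)
  out2 <- compute_global_threshold(ph$grid)
  expect_identical(out1, out2)

  mask <- segment_with_threshold(ph$grid, out1$threshold_grey)
  mis <- mean(mask$mask != ph$truth$construct)
  expect_lt(mis, 0.01)
  # threshold lies strictly between the two phase means
  expect_gt(out1$threshold_grey, 50)
  expect_lt(out1$threshold_grey, 200)
})

test_that("thresholding is inclusive, monotone, and reusable across time points", {
  g <- voxel_grid(array(200, c(3, 3, 3)) + array(seq(0, 1, length.out = 27),
                                                 c(3, 3, 3)), 17.7)
  m <- segment_with_threshold(g, 100)
  expect_true(all(m$mask))
  expect_error(segment_with_threshold(g, 1000), "empty")

  ph <- small_phantom(seed = 3L)
  thr <- compute_global_threshold(ph$grid)$threshold_grey
  m1 <- segment_with_threshold(ph$grid, thr)
  m2 <- segment_with_threshold(ph$grid, thr)   # T1 route: stored scalar
  expect_identical(m1$mask, m2$mask)
  expect_identical(m1$threshold_grey, thr)

  # raising the threshold never adds voxels
  prev <- segment_with_threshold(ph$grid, 80)$mask
  for (thr2 in c(120, 160, 200)) {
    cur <- segment_with_threshold(ph$grid, thr2)$mask
    expect_true(all(prev | !cur))   # cur subset of prev
    prev <- cur
  }
})

test_that("small-component removal applies the strict 0.1% rule and is idempotent", {
  m <- array(FALSE, c(4L, 50L, 60L))
  m[seq_len(9995)] <- TRUE                     # one connected 9995-voxel blob
  m[3, 45, 55] <- TRUE; m[3, 45, 56] <- TRUE   # 5-voxel isle, far away
  m[3, 46, 55] <- TRUE; m[4, 45, 55] <- TRUE; m[4, 46, 56] <- TRUE
  bv <- binary_volume(m, 17.7)
  out <- remove_small_components(bv, 0.001)
  expect_identical(sum(out$mask), 9995L)
  expect_identical(attr(out, "removed_component_count"), 1L)

  # isle at exactly 0.1% of the total is kept (strict inequality)
  m2 <- array(FALSE, c(4L, 50L, 60L))
  m2[seq_len(9990)] <- TRUE
  m2[3:4, 44:48, 55] <- TRUE                   # 10-voxel isle; 10/10000
  bv2 <- binary_volume(m2, 17.7)
  out2 <- remove_small_components(bv2, 0.001)
  expect_identical(sum(out2$mask), 10000L)
  expect_identical(attr(out2, "removed_component_count"), 0L)

  # idempotence and single-component identity
  again <- remove_small_components(out, 0.001)
  expect_identical(again$mask, out$mask)
  expect_true(sum(remove_small_components(bv, 0.001)$mask) <= sum(bv$mask))
})

test_that("in-hull despeckle fills sub-resolution voids and keeps resolvable pores", {
  m <- array(FALSE, c(20, 20, 20)); m[3:18, 3:18, 3:18] <- TRUE
  m[10, 10, 10] <- FALSE                       # 1-voxel speck
  ax <- 1:20
  m <- m & !(outer(outer((ax - 6)^2, (ax - 6)^2, `+`), (ax - 6)^2, `+`) <= 4)
  bv <- binary_volume(m, 17.7)
  tern <- build_ternary(bv)
  ds <- despeckle_in_hull(bv, tern)
  expect_identical(ds$filled_void_components, 1L)
  expect_true(ds$mask$mask[10, 10, 10])
  # the radius-2 cavity (33 voxels) survives
  expect_false(ds$mask$mask[6, 6, 6])
  expect_identical(ds$ternary$labels[6, 6, 6], 0L)
})
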