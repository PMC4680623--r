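# Fully automatic global-threshold segmentation of the scaffold construct.
#
# The threshold is derived without user interaction: an Otsu threshold seeds
# a centre-of-mass computation, three orthogonal slices through that centre
# are classified by two-cluster fuzzy c-means (run twice, per-pixel maximum
# of the construct membership), the minimum construct intensity of each
# slice is taken, and the mean of the three minima becomes the global grey
# threshold. The same threshold is re-applied to the follow-up scan of the
# same construct so both time points are segmented identically.

#' Otsu threshold of a voxel grid
#'
#' Maximizes the between-class variance over a 256-bin histogram of the full
#' volume. Used only to seed the centre-of-mass computation, not as the
#' final segmentation threshold. Ties resolve to the lowest cut.
#'
#' @param grid a [voxel_grid()] or 3D numeric array with at least two
#'   distinct grey values.
#' @return grey-value threshold; voxels with intensity `>=` the threshold
#'   form the foreground.
#' @export
otsu_threshold <- function(grid) {
  x <- if (inherits(grid, "voxel_grid")) grid$intensities else grid
  lo <- min(x)
  hi <- max(x)
  if (hi <= lo)
    stop_mct("otsu_threshold: constant-intensity volume, no foreground exists")
  nb <- 256L
  w <- (hi - lo) / nb
  idx <- pmin(floor((as.vector(x) - lo) / w), nb - 1L) + 1L
  counts <- tabulate(idx, nbins = nb)
  p <- counts / sum(counts)
  mids <- lo + (seq_len(nb) - 0.5) * w
  w0 <- cumsum(p)[-nb]                     # class {bins 1..k}
  mu0 <- cumsum(p * mids)[-nb]
  mu_t <- sum(p * mids)
  valid <- w0 > 0 & w0 < 1
  sb <- rep(-Inf, nb - 1L)
  sb[valid] <- (mu_t * w0[valid] - mu0[valid])^2 /
    (w0[valid] * (1 - w0[valid]))
  k <- which.max(sb)
  lo + k * w                                # lower edge of first upper bin
}

#' Centre of mass of a binary mask
#'
#' Unweighted mean index of the true voxels, rounded to the nearest integer
#' per axis (halves away from zero).
#'
#' @param mask a [binary_volume()] or 3D logical array.
#' @return integer index triple (1-based).
#' @export
center_of_mass <- function(mask) {
  m <- if (inherits(mask, "binary_volume")) mask$mask else mask
  idx <- which(m, arr.ind = TRUE)
  if (nrow(idx) == 0L)
    stop_mct("center_of_mass: empty mask")
  as.integer(round_half_away(colMeans(idx)))
}

#' Extract the three orthogonal slices through a point
#'
#' Returns the axis-aligned planes through `com` in transversal (slice
#' axis), coronal and sagittal orientation.
#'
#' @param grid a [voxel_grid()] or 3D array.
#' @param com integer index triple within bounds.
#' @return named list of three matrices with an `axis` attribute each.
#' @export
extract_orthogonal_slices <- function(grid, com) {
  x <- if (inherits(grid, "voxel_grid")) grid$intensities else grid
  d <- dim(x)
  if (any(com < 1L) || any(com > d))
    stop_mct("centre index out of grid bounds")
  out <- list(
    transversal = x[com[1L], , ],
    coronal     = x[, com[2L], ],
    sagittal    = x[, , com[3L]]
  )
  for (i in 1:3) attr(out[[i]], "axis") <- i
  out
}

# One plain fuzzy c-means run on a numeric vector with k = 2 clusters.
# Memberships update from centre distances, centres from fuzzified
# memberships; convergence when the largest membership change drops below
# tol. Exposed internally so tests can pin it against an independent
# fixed-point iteration.
fcm_cluster <- function(x, centers, fuzzifier = 2, tol = 1e-5,
                        max_iter = 300L) {
  stopifnot(length(centers) == 2L, is.numeric(x))
  if (centers[1L] == centers[2L])
    stop_mct("fuzzy clustering: initial centres coincide")
  expo <- 1 / (fuzzifier - 1)
  u <- NULL
  converged <- FALSE
  for (it in seq_len(max_iter)) {
    d1 <- (x - centers[1L])^2
    d2 <- (x - centers[2L])^2
    r <- (d1 / d2)^expo
    u1 <- 1 / (1 + r)
    z1 <- d1 == 0
    z2 <- d2 == 0
    u1[z2] <- 0
    u1[z1] <- 1
    u1[z1 & z2] <- 0.5
    unew <- cbind(u1, 1 - u1, deparse.level = 0)
    um <- unew^fuzzifier
    centers <- unname(colSums(um * x) / colSums(um))
    if (!is.null(u) && max(abs(unew - u)) < tol) {
      u <- unew
      converged <- TRUE
      break
    }
    u <- unew
  }
  list(centers = centers, membership = u, iterations = it,
       converged = converged)
}

#' Fuzzy c-means construct membership of a slice
#'
#' Two-cluster fuzzy c-means on the pixel intensities (fuzzifier 2 by
#' default). The clustering runs twice -- once from a deterministic
#' initialization at the 5th/95th intensity percentiles and once from two
#' random distinct pixel values under the given seed -- and the per-pixel
#' maximum of the two construct memberships is returned. The construct
#' cluster is the one with the higher final centre (the scaffold is the
#' dense phase). The doubled run guards against a bad basin of the first
#' initialization.
#'
#' @param slice 2D numeric matrix with at least 2 distinct values.
#' @param fuzzifier,tol,max_iter fuzzy c-means hyperparameters.
#' @param seed integer seed for the second run's initialization.
#' @return matrix of construct membership in `[0, 1]`, same shape as
#'   `slice`.
#' @export
fuzzy_membership <- function(slice, fuzzifier = 2, tol = 1e-5,
                             max_iter = 300L, seed = 42L) {
  x <- as.vector(slice)
  ux <- unique(x)
  if (length(ux) < 2L)
    stop_mct("fuzzy clustering failed: slice has constant intensity")
  init1 <- quantile(x, c(0.05, 0.95), names = FALSE)
  if (init1[1L] == init1[2L]) init1 <- range(x)
  init2 <- with_seed(seed, sample(ux, 2L))
  construct_mem <- function(fit) {
    k <- which.max(fit$centers)
    fit$membership[, k]
  }
  m1 <- construct_mem(fcm_cluster(x, init1, fuzzifier, tol, max_iter))
  m2 <- construct_mem(fcm_cluster(x, init2, fuzzifier, tol, max_iter))
  matrix(pmax(m1, m2), nrow = nrow(slice))
}

#' Minimum construct intensity of a classified slice
#'
#' The lowest intensity among pixels whose construct membership exceeds
#' 0.5.
#'
#' @param slice 2D numeric matrix.
#' @param membership matching construct-membership matrix.
#' @return grey scalar.
#' @export
slice_masked_minimum <- function(slice, membership) {
  stopifnot(identical(dim(slice), dim(membership)))
  sel <- membership > 0.5
  if (!any(sel))
    stop_mct("slice contains no construct: no pixel has construct ",
             "membership > 0.5")
  min(slice[sel])
}

#' Compute the automatic global segmentation threshold
#'
#' Orchestrates the full threshold derivation: Otsu seed, centre of mass of
#' the Otsu mask, three orthogonal slices, doubled fuzzy clustering per
#' slice, masked minimum per slice, mean of the three minima. No mask is
#' produced here; apply the threshold with [segment_with_threshold()].
#'
#' @param grid a [voxel_grid()].
#' @param fcm list of fuzzy c-means settings
#'   (`fuzzifier`, `tol`, `max_iter`, `seed`).
#' @return object of class `segmentation_outcome` carrying `threshold_grey`
#'   (mean of `slice_minima`), `com_index`, `slice_minima`, `otsu_grey`.
#' @export
compute_global_threshold <- function(grid,
                                     fcm = list(fuzzifier = 2, tol = 1e-5,
                                                max_iter = 300L,
                                                seed = 42L)) {
  stopifnot(inherits(grid, "voxel_grid"))
  stage <- function(name, expr)
    tryCatch(expr, error = function(e)
      stop_mct("segmentation stage '", name, "': ", conditionMessage(e)))
  otsu <- stage("otsu", otsu_threshold(grid))
  seed_mask <- stage("otsu", grid$intensities >= otsu)
  com <- stage("center_of_mass", center_of_mass(seed_mask))
  slices <- stage("orthogonal_slices", extract_orthogonal_slices(grid, com))
  minima <- vapply(slices, function(s) {
    mem <- stage("fuzzy_clustering",
                 fuzzy_membership(s, fcm$fuzzifier, fcm$tol, fcm$max_iter,
                                  fcm$seed))
    stage("masked_minimum", slice_masked_minimum(s, mem))
  }, numeric(1))
  structure(
    list(threshold_grey = mean(minima),
         com_index = com,
         slice_minima = minima,
         otsu_grey = otsu),
    class = "segmentation_outcome"
  )
}

#' @export
print.segmentation_outcome <- function(x, ...) {
  cat("segmentation_outcome: threshold", format(x$threshold_grey),
      "(slice minima", paste(signif(x$slice_minima, 6), collapse = ", "),
      ") CoM", paste(x$com_index, collapse = ","), "\n")
  invisible(x)
}

#' Threshold a grid into a construct mask
#'
#' Inclusive comparison: voxels with intensity `>=` threshold are construct.
#' The threshold is itself an observed construct intensity (a masked slice
#' minimum), so it must remain inside the construct class.
#'
#' @param grid a [voxel_grid()].
#' @param threshold grey scalar, e.g. from [compute_global_threshold()] at
#'   baseline, re-used verbatim for the follow-up scan.
#' @return a [binary_volume()] recording the threshold.
#' @export
segment_with_threshold <- function(grid, threshold) {
  stopifnot(inherits(grid, "voxel_grid"), is.numeric(threshold),
            length(threshold) == 1L)
  m <- grid$intensities >= threshold
  if (!any(m))
    stop_mct("segmentation produced an empty mask: threshold ",
             format(threshold), " exceeds all intensities")
  binary_volume(m, grid$voxel_size_um, threshold)
}

#' Remove small disconnected components from a mask
#'
#' Connected components (26-connectivity) whose voxel count is strictly
#' below `min_fraction` of the total construct volume before removal are
#' discarded as reconstruction artefacts (default 0.1%).
#'
#' @param mask a [binary_volume()].
#' @param min_fraction fraction of the pre-removal true-voxel count below
#'   which a component is dropped (strict inequality).
#' @return a [binary_volume()] with attribute `removed_component_count`.
#' @export
remove_small_components <- function(mask, min_fraction = 0.001) {
  stopifnot(inherits(mask, "binary_volume"))
  m <- mask$mask
  if (!any(m)) stop_mct("remove_small_components: empty mask")
  lab <- label3(m)
  sizes <- tabulate(lab[lab > 0L])
  total <- sum(sizes)
  drop <- which(sizes < min_fraction * total)
  if (length(drop) == length(sizes))
    stop_mct("artefact removal dissolved the construct: every component ",
             "is below ", format(min_fraction * 100), "% of the volume")
  if (length(drop) > 0L)
    m[lab %in% drop] <- FALSE
  out <- binary_volume(m, mask$voxel_size_um, mask$threshold_grey)
  attr(out, "removed_component_count") <- length(drop)
  out
}

#' Segment a construct end to end
#'
#' Convenience wrapper: derive the automatic threshold (unless an explicit
#' `threshold` is given, as for a follow-up scan), apply it, clean small
#' artefact components and fill sub-resolution void speckle.
#'
#' @param grid a [voxel_grid()].
#' @param threshold optional grey scalar to re-use instead of the automatic
#'   derivation.
#' @param fcm fuzzy c-means settings, see [compute_global_threshold()].
#' @param min_fraction artefact-removal cutoff, see
#'   [remove_small_components()].
#' @return `segmentation_outcome` with fields `mask` (cleaned
#'   [binary_volume()]) and `removed_component_count` filled in. Void
#'   speckle inside the convex hull is handled downstream by
#'   [despeckle_in_hull()] once the hull is known.
#' @export
segment_construct <- function(grid, threshold = NULL,
                              fcm = list(fuzzifier = 2, tol = 1e-5,
                                         max_iter = 300L, seed = 42L),
                              min_fraction = 0.001) {
  if (is.null(threshold)) {
    out <- compute_global_threshold(grid, fcm)
  } else {
    out <- structure(
      list(threshold_grey = threshold, com_index = NULL,
           slice_minima = NULL, otsu_grey = NULL),
      class = "segmentation_outcome"
    )
  }
  mask <- segment_with_threshold(grid, out$threshold_grey)
  mask <- remove_small_components(mask, min_fraction)
  out$removed_component_count <- attr(mask, "removed_component_count")
  out$mask <- mask
  out
}

# 26-connectivity component labelling (internal, Rcpp-backed).
label3 <- function(mask) {
  m <- if (inherits(mask, "binary_volume")) mask$mask else mask
  array(.label3_cpp(as.logical(m), dim(m)), dim(m))
}
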