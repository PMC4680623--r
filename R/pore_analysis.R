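# Pore extraction by covering radii: label the volume into construct /
# in-hull void / outside, take the Euclidean distance map of the void
# phase, and read each pore off as the largest inscribed sphere at a
# suppressed local maximum of the distance map.

#' Ternary construct / pore-space / outside labelling
#'
#' Classifies every voxel of the mask's grid as construct (1), pore space
#' (0: not construct but the voxel centre lies inside or on the convex hull
#' of the construct voxel centres), or outside the hull (`NA`). The hull is
#' computed exactly on the integer voxel coordinates; hull membership is
#' boundary-inclusive.
#'
#' @param mask a [binary_volume()] with at least 4 non-coplanar construct
#'   voxels.
#' @return object of class `ternary_volume` with fields `labels` (3D
#'   integer array over `{1, 0, NA}`) and `voxel_size_um`.
#' @export
build_ternary <- function(mask) {
  stopifnot(inherits(mask, "binary_volume"))
  m <- mask$mask
  d <- dim(m)
  ind <- which(m, arr.ind = TRUE)
  if (nrow(ind) < 4L)
    stop_mct("convex hull is degenerate: fewer than 4 construct voxels")
  # hull vertices are always the per-column extremes along axis 1
  key <- ind[, 2L] + (ind[, 3L] - 1L) * d[2L]
  o <- order(key, ind[, 1L])
  keep <- !duplicated(key[o]) | !duplicated(key[o], fromLast = TRUE)
  cand <- ind[o, , drop = FALSE][keep, , drop = FALSE]
  inside <- array(.hull_classify_cpp(cand, d), d)
  labels <- array(NA_integer_, d)
  labels[inside] <- 0L
  labels[m] <- 1L
  structure(
    list(labels = labels, voxel_size_um = mask$voxel_size_um),
    class = "ternary_volume"
  )
}

#' @export
print.ternary_volume <- function(x, ...) {
  tab <- table(factor(x$labels, levels = c(1L, 0L)), useNA = "always")
  cat("ternary_volume", paste(dim(x$labels), collapse = " x "),
      sprintf("| construct %d | pore space %d | outside hull %d\n",
              tab[1L], tab[2L], tab[3L]))
  invisible(x)
}

#' Fill sub-resolution void speckle inside the hull
#'
#' A global threshold anchored at the observed minimum construct intensity
#' of three slices inevitably leaves a small tail of construct voxels
#' below it once the full volume holds orders of magnitude more voxels
#' than the slices; these surface as isolated one-to-few-voxel "pores".
#' In-hull void components too small to contain even a unit-radius sphere
#' (fewer than 7 voxels, the digitized radius-1 ball) are below the
#' spatial resolution of the covering-radius pore model and are filled
#' into the construct phase. Resolvable pores are untouched.
#'
#' @param mask the segmentation [binary_volume()].
#' @param ternary the matching [build_ternary()] result.
#' @param max_voxels void components with at most this many voxels are
#'   filled (default 6, anything smaller than the 7-voxel unit ball); set
#'   negative to disable.
#' @return `list(mask =, ternary =, filled_void_components =)` with the
#'   speckle voxels flipped to construct in both containers (the hull is
#'   unchanged: only interior voxels flip).
#' @export
despeckle_in_hull <- function(mask, ternary, max_voxels = 6L) {
  stopifnot(inherits(mask, "binary_volume"),
            inherits(ternary, "ternary_volume"))
  lab <- ternary$labels
  if (max_voxels < 0L)
    return(list(mask = mask, ternary = ternary,
                filled_void_components = 0L))
  void <- !is.na(lab) & lab == 0L
  vl <- label3(void)
  sizes <- tabulate(vl[vl > 0L])
  small <- which(sizes <= max_voxels)
  if (length(small) > 0L) {
    flip <- array(vl %in% small, dim(lab))
    m <- mask$mask
    m[flip] <- TRUE
    mask <- binary_volume(m, mask$voxel_size_um, mask$threshold_grey)
    lab[flip] <- 1L
    ternary$labels <- lab
  }
  list(mask = mask, ternary = ternary,
       filled_void_components = length(small))
}

#' Euclidean distance map of the pore space
#'
#' For every pore-space voxel, the exact centre-to-centre Euclidean
#' distance (in voxel units) to the nearest construct voxel. Construct
#' voxels are 0; voxels outside the hull carry `NA`.
#'
#' @param ternary a [build_ternary()] result with at least one construct
#'   voxel.
#' @return 3D numeric array of distances.
#' @export
distance_map <- function(ternary) {
  stopifnot(inherits(ternary, "ternary_volume"))
  lab <- ternary$labels
  construct <- !is.na(lab) & lab == 1L
  if (!any(construct))
    stop_mct("distance_map: no construct voxels")
  d <- array(.edt3_cpp(as.logical(construct), dim(lab)), dim(lab))
  d[is.na(lab)] <- NA_real_
  d
}

#' Pore size distribution container
#'
#' An ordered table of pores, each the largest inscribed sphere of one void
#' cavity: integer centre index, covering radius in voxel units and the
#' physical diameter.
#'
#' @param pores data frame with columns `z`, `y`, `x`, `radius_vox`,
#'   `diameter_um`.
#' @param voxel_size_um voxel edge in micrometres.
#' @param trimmed logical: has the 2 x 5% tail trimming been applied?
#' @param trim_fraction the fraction trimmed from each end.
#' @param n_untrimmed pore count before trimming.
#' @return object of class `pore_distribution`.
#' @export
pore_distribution <- function(pores, voxel_size_um, trimmed = FALSE,
                              trim_fraction = NA_real_,
                              n_untrimmed = nrow(pores)) {
  stopifnot(is.data.frame(pores),
            all(c("z", "y", "x", "radius_vox", "diameter_um") %in%
                  names(pores)))
  if (nrow(pores) > 0L && any(pores$radius_vox <= 0))
    stop_mct("pore radii must be positive")
  structure(
    list(pores = pores, voxel_size_um = voxel_size_um, trimmed = trimmed,
         trim_fraction = trim_fraction, n_untrimmed = n_untrimmed),
    class = "pore_distribution"
  )
}

#' @export
print.pore_distribution <- function(x, ...) {
  cat("pore_distribution:", nrow(x$pores), "pores",
      if (x$trimmed) sprintf("(trimmed %g%% per tail from %d)",
                             100 * x$trim_fraction, x$n_untrimmed)
      else "(untrimmed)", "\n")
  if (nrow(x$pores) > 0L)
    cat("  diameters [um]:",
        paste(signif(range(x$pores$diameter_um), 4), collapse = " .. "),
        sprintf("(mean %.4g)", mean(x$pores$diameter_um)), "\n")
  invisible(x)
}

# Continuous sub-voxel refinement of one inscribed sphere. The distance
# field sampled at integer voxels under-reads the true covering radius by
# up to half the lattice diagonal (the sampling point is off the cavity
# centre); re-optimizing the centre over a +-1 voxel cube against the
# nearby construct voxel centres removes that sampling bias. Two-stage
# grid search, deterministic.
refine_pore <- function(q, v, labels) {
  d <- dim(labels)
  h <- ceiling(v) + 3L
  rg <- lapply(1:3, function(ax) max(1L, q[ax] - h):min(d[ax], q[ax] + h))
  sub <- labels[rg[[1L]], rg[[2L]], rg[[3L]], drop = FALSE]
  idx <- which(!is.na(sub) & sub == 1L, arr.ind = TRUE)
  if (nrow(idx) == 0L) return(list(center = q, radius = v))
  pts <- cbind(rg[[1L]][idx[, 1L]], rg[[2L]][idx[, 2L]], rg[[3L]][idx[, 3L]])
  near <- (pts[, 1L] - q[1L])^2 + (pts[, 2L] - q[2L])^2 +
    (pts[, 3L] - q[3L])^2 <= (v + 2)^2
  if (any(near)) pts <- pts[near, , drop = FALSE]
  eval_grid <- function(center, half, step) {
    off <- seq(-half, half, by = step)
    xg <- as.matrix(expand.grid(z = center[1L] + off,
                                y = center[2L] + off,
                                x = center[3L] + off))
    d2 <- outer(xg[, 1L], pts[, 1L], `-`)^2 +
      outer(xg[, 2L], pts[, 2L], `-`)^2 +
      outer(xg[, 3L], pts[, 3L], `-`)^2
    f <- sqrt(apply(d2, 1L, min))
    k <- which.max(f)
    list(center = xg[k, ], radius = f[k])
  }
  s1 <- eval_grid(as.numeric(q), 1.0, 0.25)
  s2 <- eval_grid(s1$center, 0.1875, 0.0625)
  if (s2$radius >= s1$radius) s2 else s1
}

#' Extract pores as suppressed distance-map maxima
#'
#' Candidate pore centres are pore-space voxels whose distance value is
#' `>=` that of all 26 neighbours; connected equal-valued plateaus merge to
#' one candidate at the rounded plateau centroid. Candidates are then swept
#' in descending distance order (ties broken lexicographically by index)
#' and accepted unless the centre already lies within the sphere of an
#' accepted pore, so each cavity contributes one pore.
#'
#' The covering radius of an accepted pore is, by default, refined to
#' sub-voxel precision: the inscribed-sphere centre is re-optimized
#' continuously within one voxel of the integer maximum, which removes the
#' systematic half-lattice-diagonal under-read of integer sampling while
#' staying inside the covering-radius model. With `refine = FALSE` the raw
#' distance value is used.
#'
#' @param edm distance field from [distance_map()].
#' @param ternary the matching [build_ternary()] result.
#' @param refine logical: sub-voxel refinement of accepted pores.
#' @return an untrimmed [pore_distribution()]; zero pores is a valid
#'   outcome. Columns `z`, `y`, `x` are the integer centre, `zc`, `yc`,
#'   `xc` the (refined) continuous centre.
#' @export
extract_pores <- function(edm, ternary, refine = TRUE) {
  stopifnot(inherits(ternary, "ternary_volume"))
  lab <- ternary$labels
  pore <- !is.na(lab) & lab == 0L
  empty <- pore_distribution(
    data.frame(z = integer(), y = integer(), x = integer(),
               zc = numeric(), yc = numeric(), xc = numeric(),
               radius_vox = numeric(), diameter_um = numeric()),
    ternary$voxel_size_um
  )
  if (!any(pore)) return(empty)

  cmp <- edm
  cmp[is.na(cmp)] <- -Inf
  nbmax <- array(-Inf, dim(cmp))
  offs <- neighbourhood26()
  for (i in seq_len(nrow(offs)))
    nbmax <- pmax(nbmax, shift3(cmp, offs[i, ], fill = -Inf))
  cand <- pore & cmp >= nbmax

  clab <- label3(cand)
  ncomp <- max(clab)
  if (ncomp == 0L) return(empty)
  ind <- which(cand, arr.ind = TRUE)
  grp <- clab[cand]
  centers <- t(vapply(seq_len(ncomp), function(g) {
    round_half_away(colMeans(ind[grp == g, , drop = FALSE]))
  }, numeric(3)))
  radii <- vapply(seq_len(ncomp), function(g)
    max(edm[cand][grp == g]), numeric(1))

  o <- order(-radii, centers[, 1L], centers[, 2L], centers[, 3L])
  centers <- centers[o, , drop = FALSE]
  radii <- radii[o]

  acc <- logical(ncomp)
  for (i in seq_len(ncomp)) {
    if (i == 1L) {
      acc[i] <- TRUE
      next
    }
    j <- which(acc)
    d2 <- (centers[j, 1L] - centers[i, 1L])^2 +
      (centers[j, 2L] - centers[i, 2L])^2 +
      (centers[j, 3L] - centers[i, 3L])^2
    acc[i] <- all(d2 > radii[j]^2)
  }
  keep <- which(acc)
  ctr <- centers[keep, , drop = FALSE]
  rad <- radii[keep]
  cc <- matrix(as.numeric(ctr), ncol = 3L)
  if (refine && length(keep) > 0L) {
    for (i in seq_along(keep)) {
      rf <- refine_pore(as.integer(ctr[i, ]), rad[i], lab)
      cc[i, ] <- rf$center
      rad[i] <- rf$radius
    }
  }
  pore_distribution(
    data.frame(z = as.integer(ctr[, 1L]),
               y = as.integer(ctr[, 2L]),
               x = as.integer(ctr[, 3L]),
               zc = cc[, 1L], yc = cc[, 2L], xc = cc[, 3L],
               radius_vox = rad,
               diameter_um = 2 * rad * ternary$voxel_size_um),
    ternary$voxel_size_um
  )
}

#' Trim the tails of a pore size distribution
#'
#' Drops the smallest and largest `floor(trim_fraction * N)` pores (default
#' 5% per tail) to remove outliers before the summary parameters are
#' computed. Stable sort by diameter. Re-trimming an already-trimmed
#' distribution is a no-op: the recorded original `N` has had its share
#' removed.
#'
#' @param dist an untrimmed [pore_distribution()].
#' @param trim_fraction fraction removed from each end.
#' @return the trimmed [pore_distribution()].
#' @export
trim_pores <- function(dist, trim_fraction = 0.05) {
  stopifnot(inherits(dist, "pore_distribution"))
  if (isTRUE(dist$trimmed)) return(dist)
  n <- nrow(dist$pores)
  if (n == 0L)
    stop_mct("cannot trim an empty pore distribution")
  k <- floor(trim_fraction * n)
  if (n - 2L * k <= 0L)
    stop_mct("trimming ", format(trim_fraction * 100),
             "% per tail would remove all ", n, " pores")
  o <- order(dist$pores$diameter_um)      # radix sort, stable
  keep <- sort(o[seq.int(k + 1L, n - k)])
  pore_distribution(dist$pores[keep, , drop = FALSE], dist$voxel_size_um,
                    trimmed = TRUE, trim_fraction = trim_fraction,
                    n_untrimmed = n)
}
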