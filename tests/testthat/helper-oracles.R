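# Independent brute-force oracles and small fixture builders. Everything
# here is deliberately written as plain, slow enumeration so it shares no
# code path with the package implementation it checks.

# O(N^2) Euclidean distance map: for every voxel, scan all construct
# voxels. Returns distances with construct voxels at 0.
bf_distance_map <- function(construct) {
  d <- dim(construct)
  pts <- which(construct, arr.ind = TRUE)
  out <- array(NA_real_, d)
  for (i in seq_len(d[1L]))
    for (j in seq_len(d[2L]))
      for (k in seq_len(d[3L])) {
        out[i, j, k] <- sqrt(min((pts[, 1L] - i)^2 + (pts[, 2L] - j)^2 +
                                   (pts[, 3L] - k)^2))
      }
  out
}

# Brute-force largest inscribed sphere of one cavity: max over the
# cavity's void voxels of the distance to the nearest construct voxel
# centre, construct scan restricted to a window around the cavity (the
# nearest construct voxel is never farther than the cavity radius + 2).
bf_inscribed_sphere <- function(construct, center, radius) {
  d <- dim(construct)
  h <- ceiling(radius) + 3L
  rg <- lapply(1:3, function(ax)
    max(1L, floor(center[ax] - h)):min(d[ax], ceiling(center[ax] + h)))
  sub <- construct[rg[[1L]], rg[[2L]], rg[[3L]], drop = FALSE]
  cpts <- which(sub, arr.ind = TRUE)
  cpts <- cbind(rg[[1L]][cpts[, 1L]], rg[[2L]][cpts[, 2L]],
                rg[[3L]][cpts[, 3L]])
  vpts <- which(!sub, arr.ind = TRUE)
  vpts <- cbind(rg[[1L]][vpts[, 1L]], rg[[2L]][vpts[, 2L]],
                rg[[3L]][vpts[, 3L]])
  keep <- (vpts[, 1L] - center[1L])^2 + (vpts[, 2L] - center[2L])^2 +
    (vpts[, 3L] - center[3L])^2 <= radius^2
  vpts <- vpts[keep, , drop = FALSE]
  best <- 0
  for (i in seq_len(nrow(vpts))) {
    dist <- sqrt(min((cpts[, 1L] - vpts[i, 1L])^2 +
                       (cpts[, 2L] - vpts[i, 2L])^2 +
                       (cpts[, 3L] - vpts[i, 3L])^2))
    if (dist > best) best <- dist
  }
  best
}

# Point-in-hull by supporting planes: enumerate all triples of construct
# points; a triple whose plane has all points on one (closed) side is a
# supporting plane; a query point is inside the hull iff it is on the
# inner side of every supporting plane. Only for small point sets.
bf_hull_membership <- function(pts, queries) {
  n <- nrow(pts)
  planes <- list()
  for (a in 1:(n - 2)) for (b in (a + 1):(n - 1)) for (cc in (b + 1):n) {
    u <- pts[b, ] - pts[a, ]
    v <- pts[cc, ] - pts[a, ]
    nrm <- c(u[2L] * v[3L] - u[3L] * v[2L],
             u[3L] * v[1L] - u[1L] * v[3L],
             u[1L] * v[2L] - u[2L] * v[1L])
    if (all(nrm == 0)) next
    s <- (pts[, 1L] - pts[a, 1L]) * nrm[1L] +
      (pts[, 2L] - pts[a, 2L]) * nrm[2L] +
      (pts[, 3L] - pts[a, 3L]) * nrm[3L]
    if (all(s <= 0)) planes[[length(planes) + 1L]] <- c(nrm, sum(nrm * pts[a, ]))
    else if (all(s >= 0)) planes[[length(planes) + 1L]] <- c(-nrm, -sum(nrm * pts[a, ]))
  }
  vapply(seq_len(nrow(queries)), function(i) {
    q <- queries[i, ]
    for (pl in planes)
      if (sum(pl[1:3] * q) > pl[4L]) return(FALSE)
    TRUE
  }, logical(1))
}

# Plain fuzzy c-means fixed-point iteration, written independently with
# explicit per-cluster loops (oracle for fcm_cluster).
bf_fcm <- function(x, centers, m = 2, tol = 1e-5, max_iter = 300L) {
  n <- length(x)
  u <- matrix(0, n, 2L)
  u_old <- matrix(Inf, n, 2L)
  for (it in seq_len(max_iter)) {
    for (i in seq_len(n)) {
      d <- c(abs(x[i] - centers[1L]), abs(x[i] - centers[2L]))
      if (d[1L] == 0 && d[2L] == 0) u[i, ] <- c(0.5, 0.5)
      else if (d[1L] == 0) u[i, ] <- c(1, 0)
      else if (d[2L] == 0) u[i, ] <- c(0, 1)
      else {
        for (k in 1:2)
          u[i, k] <- 1 / sum((d[k] / d)^(2 / (m - 1)))
      }
    }
    for (k in 1:2)
      centers[k] <- sum(u[, k]^m * x) / sum(u[, k]^m)
    if (max(abs(u - u_old)) < tol && it > 1L) break
    u_old[, ] <- u
  }
  list(centers = centers, membership = u)
}

# Exhaustive Otsu: between-class variance of every one of the 255 cuts of
# a 256-bin histogram, computed with explicit loops.
bf_otsu <- function(x) {
  lo <- min(x); hi <- max(x)
  w <- (hi - lo) / 256
  idx <- pmin(floor((x - lo) / w), 255) + 1L
  counts <- tabulate(idx, 256L)
  p <- counts / sum(counts)
  mids <- lo + (1:256 - 0.5) * w
  best <- -Inf; bestk <- NA_integer_
  for (k in 1:255) {
    w0 <- sum(p[1:k]); w1 <- 1 - w0
    if (w0 == 0 || w1 == 0) next
    mu0 <- sum(p[1:k] * mids[1:k]) / w0
    mu1 <- sum(p[(k + 1):256] * mids[(k + 1):256]) / w1
    sb <- w0 * w1 * (mu0 - mu1)^2
    if (sb > best) { best <- sb; bestk <- k }
  }
  lo + bestk * w
}

# Digitized ball mask in a cube grid, centred.
make_ball <- function(r, pad = 3L) {
  n <- 2L * r + 2L * pad + 1L
  ctr <- (n + 1) / 2
  ax <- seq_len(n)
  arr <- outer(outer((ax - ctr)^2, (ax - ctr)^2, `+`), (ax - ctr)^2, `+`) <=
    r^2
  array(arr, c(n, n, n))
}

# A small solid block with one or more spherical cavities (noise-free
# ternary-level fixture, no segmentation involved).
make_cavity_mask <- function(n, cavities) {
  m <- array(TRUE, c(n, n, n))
  ax <- seq_len(n)
  for (i in seq_len(nrow(cavities))) {
    ctr <- as.numeric(cavities[i, c("z", "y", "x")])
    r <- cavities$r[i]
    m <- m & !(outer(outer((ax - ctr[1L])^2, (ax - ctr[2L])^2, `+`),
                     (ax - ctr[3L])^2, `+`) <= r^2)
  }
  m
}

# Tiny default-ish cavity phantom for pipeline tests (fast).
small_phantom <- function(seed = 7L, cavities = 4L, noise_sd = 5) {
  generate_phantom(phantom_spec(shape = c(64L, 64L, 64L),
                                cavities = cavities,
                                radius_range = c(3, 6), margin = 8L,
                                noise_sd = noise_sd, seed = seed))
}
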