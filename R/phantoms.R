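# Synthetic two-phase phantoms with known ground truth. Two geometries:
#  * cavity phantom -- a dense rectangular block carrying non-overlapping
#    spherical cavities (ground truth for pore extraction and the
#    follow-up in-filling simulation);
#  * channel phantom -- a block pierced by a square lattice of cylindrical
#    channels, a designed-scaffold geometry at a prescribed void fraction
#    (ground truth for porosity recovery; its convex hull is exactly the
#    block, so the designed ratio is hull-independent).
# Both add seeded Gaussian noise and keep the two phases separable by
# construction (foreground mean at least 4 noise SDs above background).

#' Specification of a cavity phantom
#'
#' @param shape integer triple of grid dimensions.
#' @param voxel_size_um voxel edge in micrometres.
#' @param fg_mean,bg_mean grey means of the dense and fluid phase; must
#'   satisfy `fg_mean > bg_mean + 4 * noise_sd`.
#' @param noise_sd additive Gaussian noise SD (grey values), clipped to
#'   `[0, 255]`.
#' @param cavities either an integer count (random non-overlapping
#'   placement) or a data frame `z, y, x, r` of fixed cavities (voxel
#'   coordinates/radii).
#' @param radius_range radius range (voxels) for random placement.
#' @param margin background margin around the dense block (voxels).
#' @param min_separation minimum surface-to-surface cavity distance
#'   (voxels) for random placement.
#' @param seed RNG seed; the same spec and seed reproduce the phantom
#'   bit-identically.
#' @return object of class `phantom_spec`.
#' @export
phantom_spec <- function(shape = c(128L, 128L, 128L), voxel_size_um = 17.7,
                         fg_mean = 200, bg_mean = 50, noise_sd = 5,
                         cavities = 20L, radius_range = c(3, 8),
                         margin = 10L, min_separation = 2,
                         seed = 1L) {
  stopifnot(length(shape) == 3L, all(shape >= 8L))
  if (fg_mean <= bg_mean + 4 * noise_sd)
    stop_mct("phases not separable: need fg_mean > bg_mean + 4 * noise_sd")
  if (is.data.frame(cavities))
    stopifnot(all(c("z", "y", "x", "r") %in% names(cavities)))
  else
    stopifnot(is.numeric(cavities), length(cavities) == 1L, cavities >= 0)
  structure(
    list(shape = as.integer(shape), voxel_size_um = voxel_size_um,
         fg_mean = fg_mean, bg_mean = bg_mean, noise_sd = noise_sd,
         cavities = cavities, radius_range = radius_range,
         margin = as.integer(margin), min_separation = min_separation,
         seed = as.integer(seed)),
    class = "phantom_spec"
  )
}

# Rejection-sample non-overlapping cavities fully interior to the block.
place_cavities <- function(spec) {
  k <- spec$cavities
  if (k == 0L)
    return(data.frame(z = numeric(), y = numeric(), x = numeric(),
                      r = numeric()))
  lo <- spec$margin + 1
  hi <- spec$shape - spec$margin
  out <- matrix(NA_real_, k, 4L)
  placed <- 0L
  tries <- 0L
  while (placed < k) {
    tries <- tries + 1L
    if (tries > 1e4L)
      stop_mct("cavity placement infeasible after 10000 retries")
    r <- runif(1L, spec$radius_range[1L], spec$radius_range[2L])
    c_lo <- lo + r + 1
    c_hi <- hi - r - 1
    if (any(c_hi <= c_lo)) next
    ctr <- runif(3L, c_lo, c_hi)
    if (placed > 0L) {
      prev <- out[seq_len(placed), , drop = FALSE]
      d <- sqrt((prev[, 1L] - ctr[1L])^2 + (prev[, 2L] - ctr[2L])^2 +
                  (prev[, 3L] - ctr[3L])^2)
      if (any(d < prev[, 4L] + r + spec$min_separation)) next
    }
    placed <- placed + 1L
    out[placed, ] <- c(ctr, r)
  }
  data.frame(z = out[, 1L], y = out[, 2L], x = out[, 3L], r = out[, 4L])
}

# Carve a sphere (set value) into a logical array.
carve_sphere <- function(lab, ctr, r, value) {
  d <- dim(lab)
  rg <- lapply(1:3, function(ax)
    max(1L, floor(ctr[ax] - r)):min(d[ax], ceiling(ctr[ax] + r)))
  zz <- (rg[[1L]] - ctr[1L])^2
  yy <- (rg[[2L]] - ctr[2L])^2
  xx <- (rg[[3L]] - ctr[3L])^2
  inside <- outer(outer(zz, yy, `+`), xx, `+`) <= r^2
  sub <- lab[rg[[1L]], rg[[2L]], rg[[3L]], drop = FALSE]
  sub[inside] <- value
  lab[rg[[1L]], rg[[2L]], rg[[3L]]] <- sub
  lab
}

build_cavity_labels <- function(spec, cavities) {
  lab <- array(FALSE, spec$shape)
  lo <- spec$margin + 1L
  hi <- spec$shape - spec$margin
  lab[lo:hi[1L], lo:hi[2L], lo:hi[3L]] <- TRUE
  for (i in seq_len(nrow(cavities)))
    lab <- carve_sphere(lab, as.numeric(cavities[i, c("z", "y", "x")]),
                        cavities$r[i], FALSE)
  lab
}

render_phantom <- function(labels, spec, noise_seed, source_id) {
  vals <- ifelse(labels, spec$fg_mean, spec$bg_mean)
  if (spec$noise_sd > 0) {
    noise <- with_seed(noise_seed,
                       rnorm(length(vals), 0, spec$noise_sd))
    vals <- vals + noise
  }
  vals <- pmin(pmax(vals, 0), 255)
  voxel_grid(array(vals, spec$shape), spec$voxel_size_um,
             source_id = source_id)
}

#' Generate a cavity phantom with ground truth
#'
#' A dense block at `fg_mean` with spherical cavities at `bg_mean`,
#' surrounded by background, plus seeded Gaussian noise. Ground-truth
#' labels and the cavity table are returned alongside the grid so every
#' pipeline stage can be validated without scanner data.
#'
#' @param spec a [phantom_spec()].
#' @return object of class `mct_phantom`: `grid` ([voxel_grid()]), `truth`
#'   (`construct` logical array, `cavities` data frame,
#'   `void_fraction` = cavity voxels / block voxels) and `spec`.
#' @export
generate_phantom <- function(spec) {
  stopifnot(inherits(spec, "phantom_spec"))
  cav <- if (is.data.frame(spec$cavities)) spec$cavities
         else with_seed(spec$seed, place_cavities(spec))
  labels <- build_cavity_labels(spec, cav)
  block_vox <- prod(spec$shape - 2L * spec$margin)
  grid <- render_phantom(labels, spec, spec$seed * 2L + 1L, "phantom_T0")
  structure(
    list(grid = grid,
         truth = list(construct = labels, cavities = cav,
                      void_fraction = (block_vox - sum(labels)) / block_vox),
         spec = spec),
    class = "mct_phantom"
  )
}

#' Simulate in-vivo pore filling for the follow-up time point
#'
#' Shrinks each cavity so its volume scales by `1 - fraction` (radius by
#' the cube root); fraction 1 fills the cavity completely with the dense
#' phase. Noise is redrawn under `seed + 1`, emulating a second
#' acquisition of the same construct.
#'
#' @param phantom a [generate_phantom()] result.
#' @param fill_plan per-cavity fill fraction in `[0, 1]`, recycled if
#'   scalar.
#' @return an `mct_phantom` for the follow-up time point.
#' @export
simulate_filling <- function(phantom, fill_plan) {
  stopifnot(inherits(phantom, "mct_phantom"))
  cav <- phantom$truth$cavities
  if (is.null(cav) || nrow(cav) == 0L)
    stop_mct("simulate_filling: phantom has no cavity ground truth")
  fill <- rep_len(fill_plan, nrow(cav))
  if (any(fill < 0 | fill > 1))
    stop_mct("fill fractions must lie in [0, 1]")
  spec <- phantom$spec
  cav$r <- cav$r * (1 - fill)^(1 / 3)
  cav <- cav[cav$r > 0.5, , drop = FALSE]   # sub-voxel remnants vanish
  labels <- build_cavity_labels(spec, cav)
  block_vox <- prod(spec$shape - 2L * spec$margin)
  grid <- render_phantom(labels, spec, spec$seed * 2L + 2L, "phantom_T1")
  structure(
    list(grid = grid,
         truth = list(construct = labels, cavities = cav,
                      void_fraction = (block_vox - sum(labels)) / block_vox),
         spec = spec),
    class = "mct_phantom"
  )
}

# Voxel count of a digitized sphere of radius r at a generic sub-voxel
# centre offset.
digitized_sphere_voxels <- function(r, offset = c(0.31, 0.47, 0.63)) {
  n <- ceiling(r) + 1L
  ax <- (-n):n
  sum(outer(outer((ax - offset[1L])^2, (ax - offset[2L])^2, `+`),
            (ax - offset[3L])^2, `+`) <= r^2)
}

# Pixel count of a digitized disk of radius r at a generic sub-pixel centre.
digitized_disk_pixels <- function(r, offset = c(0.37, 0.59)) {
  n <- ceiling(r) + 1L
  ax <- (-n):n
  sum(outer((ax - offset[1L])^2, (ax - offset[2L])^2, `+`) <= r^2)
}

#' Generate a channel scaffold phantom at a prescribed porosity
#'
#' A solid block of the dense phase pierced by a square lattice of
#' cylindrical channels running through its full length -- the geometry of
#' a designed (rapid-prototyped) tissue-engineering scaffold. The channel
#' radius is solved at generation time from digitized disk areas so the
#' void fraction of the block matches `target_porosity` (default 0.60, the
#' nominal porosity of granular beta-TCP substitutes). The block edges and
#' corners stay solid, so the construct's convex hull is exactly the
#' block: the designed void fraction is also the expected measured
#' porosity, without boundary corrections.
#'
#' @param shape grid dimensions; the block (shape minus two margins)
#'   should be a multiple of `lattice_a` across the channel lattice for an
#'   exact ratio.
#' @param target_porosity designed void fraction in `(0, 1)`.
#' @param lattice_a channel lattice period in voxels.
#' @param jitter maximum absolute lateral jitter of each channel axis
#'   (voxels); keep small so walls stay connected.
#' @param margin background margin around the block.
#' @param voxel_size_um,fg_mean,bg_mean,noise_sd,seed as in
#'   [phantom_spec()].
#' @return object of class `mct_phantom`; `truth$porosity_design` is the
#'   void fraction actually achieved by the digitized channels (exact
#'   label count over the block).
#' @export
channel_phantom <- function(shape = c(128L, 128L, 128L),
                            target_porosity = 0.60, lattice_a = 27,
                            jitter = 0.25, margin = 10L,
                            voxel_size_um = 17.7,
                            fg_mean = 200, bg_mean = 50, noise_sd = 5,
                            seed = 1L) {
  stopifnot(target_porosity > 0, target_porosity < 1)
  target_void_px <- target_porosity * lattice_a^2
  rs <- seq(1, lattice_a / 2 - 0.6, by = 0.01)
  area <- vapply(rs, digitized_disk_pixels, numeric(1))
  r <- rs[which.min(abs(area - target_void_px))]
  if (lattice_a - 2 * (r + jitter) < 1.5)
    stop_mct("channel phantom: walls too thin for the solved radius; ",
             "reduce target_porosity or jitter, or increase lattice_a")

  lo <- margin + 1L
  hi <- shape - margin
  labels <- array(FALSE, shape)
  labels[lo:hi[1L], lo:hi[2L], lo:hi[3L]] <- TRUE

  cy <- seq(lo + lattice_a / 2 - 0.5, hi[2L], by = lattice_a)
  cx <- seq(lo + lattice_a / 2 - 0.5, hi[3L], by = lattice_a)
  centers <- expand.grid(y = cy, x = cx)
  centers <- with_seed(seed,
    centers + matrix(runif(2L * nrow(centers), -jitter, jitter),
                     ncol = 2L))
  yy <- seq_len(shape[2L])
  xx <- seq_len(shape[3L])
  hole <- matrix(FALSE, shape[2L], shape[3L])
  for (i in seq_len(nrow(centers)))
    hole <- hole | outer((yy - centers$y[i])^2, (xx - centers$x[i])^2,
                         `+`) <= r^2
  for (k in lo:hi[1L])
    labels[k, , ][hole] <- FALSE

  block_vox <- prod(hi - margin)
  achieved <- 1 - sum(labels) / block_vox
  spec <- phantom_spec(shape = shape, voxel_size_um = voxel_size_um,
                       fg_mean = fg_mean, bg_mean = bg_mean,
                       noise_sd = noise_sd, cavities = 0L,
                       margin = margin, seed = seed)
  grid <- render_phantom(labels, spec, seed * 2L + 1L, "channel_phantom")
  structure(
    list(grid = grid,
         truth = list(construct = labels,
                      channels = data.frame(centers, r = r),
                      porosity_design = achieved,
                      porosity_target = target_porosity),
         spec = spec),
    class = "mct_phantom"
  )
}

#' Write a phantom to disk as a TIFF stack plus ground-truth JSON
#'
#' Quantizes the grey values to 8-bit and writes one slice per file, so the
#' disk-based pipeline entry points can be exercised end to end.
#'
#' @param phantom an `mct_phantom`.
#' @param directory output directory.
#' @return the directory, invisibly.
#' @export
write_phantom_stack <- function(phantom, directory) {
  stopifnot(inherits(phantom, "mct_phantom"))
  if (!dir.exists(directory) &&
      !dir.create(directory, recursive = TRUE, showWarnings = FALSE))
    stop_mct("cannot create directory: '", directory, "'")
  vol <- round(phantom$grid$intensities)
  for (k in seq_len(dim(vol)[1L])) {
    slice <- vol[k, , ] / 255
    tiff::writeTIFF(slice, file.path(directory,
                                     sprintf("slice_%04d.tif", k)),
                    bits.per.sample = 8L)
  }
  truth <- phantom$truth
  truth$construct <- NULL                   # voxel labels stay in memory
  jsonlite::write_json(
    list(spec = unclass(phantom$spec), truth = truth),
    file.path(directory, "ground_truth.json"),
    auto_unbox = TRUE, digits = NA, dataframe = "columns")
  invisible(directory)
}
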