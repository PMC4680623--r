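# Reading and writing micro-CT reconstructions stored as stacks of
# single-slice grey-value TIFF files, plus the calibrated voxel-grid
# container every later stage consumes.

#' Calibrated 3D voxel grid
#'
#' The basic container for a micro-CT reconstruction: a 3D array of grey
#' values with an isotropic physical voxel size and an optional affine
#' grey-value to Hounsfield-unit calibration. Axis 1 is the slice axis
#' (one TIFF file per slice); axes 2 and 3 follow TIFF row/column order.
#' Indices are 1-based throughout the package.
#'
#' Isotropy is mandatory: all downstream geometry (distance maps, inscribed
#' spheres, surface estimation) assumes cubic voxels, so a single scalar
#' voxel size is the only accepted metadata. Pass anisotropic data through
#' resampling upstream.
#'
#' @param intensities 3D numeric array of grey values, each dimension at
#'   least 2, all values finite.
#' @param voxel_size_um positive scalar, edge length of a voxel in
#'   micrometres (identical along all axes).
#' @param calibration optional `list(slope =, intercept =)` mapping grey
#'   values to Hounsfield units.
#' @param source_id optional label (construct + time point).
#' @return object of class `voxel_grid`.
#' @export
voxel_grid <- function(intensities, voxel_size_um = 17.7, calibration = NULL,
                       source_id = NULL) {
  if (!is.array(intensities) || length(dim(intensities)) != 3L)
    stop_mct("intensities must be a 3D array")
  if (any(dim(intensities) < 2L))
    stop_mct("each grid dimension must span at least 2 voxels")
  if (!all(is.finite(intensities)))
    stop_mct("intensities contain non-finite values")
  if (!is.numeric(voxel_size_um) || length(voxel_size_um) != 1L ||
      !is.finite(voxel_size_um) || voxel_size_um <= 0)
    stop_mct("voxel_size_um must be a single positive scalar; ",
             "voxels have to be isotropic")
  if (!is.null(calibration)) {
    if (!is.list(calibration) ||
        !all(c("slope", "intercept") %in% names(calibration)))
      stop_mct("calibration must be list(slope =, intercept =)")
  }
  structure(
    list(intensities = intensities,
         voxel_size_um = as.numeric(voxel_size_um),
         calibration = calibration,
         source_id = source_id),
    class = "voxel_grid"
  )
}

#' @export
print.voxel_grid <- function(x, ...) {
  d <- dim(x$intensities)
  cat("voxel_grid", paste(d, collapse = " x "),
      sprintf("@ %g um/voxel", x$voxel_size_um),
      if (!is.null(x$source_id)) paste0("[", x$source_id, "]") else "",
      "\n")
  cat("  grey range:", paste(signif(range(x$intensities), 6), collapse = " .. "),
      if (is.null(x$calibration)) "(no HU calibration)" else "(HU calibrated)",
      "\n")
  invisible(x)
}

#' Binary segmentation mask
#'
#' A logical 3D array of construct voxels, carrying the voxel size and the
#' grey threshold that produced it (needed to re-apply a baseline threshold
#' to the follow-up scan of the same construct).
#'
#' @param mask 3D logical array.
#' @param voxel_size_um positive scalar voxel edge in micrometres.
#' @param threshold_grey the grey value the mask was thresholded at
#'   (`NA` if the mask was not produced by thresholding).
#' @return object of class `binary_volume`.
#' @export
binary_volume <- function(mask, voxel_size_um, threshold_grey = NA_real_) {
  if (!is.array(mask) || length(dim(mask)) != 3L || !is.logical(mask))
    stop_mct("mask must be a 3D logical array")
  if (anyNA(mask)) stop_mct("mask contains NA")
  structure(
    list(mask = mask,
         voxel_size_um = as.numeric(voxel_size_um),
         threshold_grey = as.numeric(threshold_grey)),
    class = "binary_volume"
  )
}

#' @export
print.binary_volume <- function(x, ...) {
  cat("binary_volume", paste(dim(x$mask), collapse = " x "),
      sprintf("| %d construct voxels | threshold %s\n",
              sum(x$mask), format(x$threshold_grey)))
  invisible(x)
}

# Order file names by the last integer group in the base name, so that
# "slice_2" precedes "slice_10"; ties fall back to the plain name sort.
order_by_slice_number <- function(files) {
  base <- basename(files)
  nums <- vapply(regmatches(base, gregexpr("[0-9]+", base)), function(g) {
    if (length(g) == 0L) NA_real_ else as.numeric(g[length(g)])
  }, numeric(1))
  files[order(nums, base, na.last = TRUE)]
}

read_slice <- function(path) {
  img <- tryCatch(tiff::readTIFF(path, as.is = TRUE),
                  error = function(e)
                    stop_mct("cannot read TIFF slice '", path, "': ",
                             conditionMessage(e)))
  if (is.list(img)) img <- img[[1L]]
  if (length(dim(img)) == 3L) {
    if (dim(img)[3L] == 1L) img <- img[, , 1L]
    else stop_mct("unsupported multi-channel TIFF slice: '", path,
                  "' (grey-scale single-channel expected)")
  }
  if (length(dim(img)) != 2L)
    stop_mct("unsupported TIFF sample layout in '", path, "'")
  img
}

#' Load a reconstruction from a directory of TIFF slices
#'
#' Reads every file matching `pattern`, orders slices by the last integer
#' group in the file name (numeric, not lexicographic, so `slice_2` comes
#' before `slice_10`), and stacks them along axis 1. Grey values are read
#' bit-exactly (`as.is`), no rescaling.
#'
#' @param directory path containing one 2D grey TIFF per slice.
#' @param pattern filename glob, default all TIFF extensions.
#' @param voxel_size_um isotropic voxel edge in micrometres (scanner
#'   metadata; default 17.7).
#' @param calibration optional `list(slope =, intercept =)` grey-to-HU map.
#' @param source_id label stored with the grid; defaults to the directory
#'   base name.
#' @return a [voxel_grid()] whose slice-axis index equals file order.
#' @export
load_stack <- function(directory, pattern = "*.tif*", voxel_size_um = 17.7,
                       calibration = NULL, source_id = basename(directory)) {
  if (!dir.exists(directory))
    stop_mct("input directory does not exist: '", directory, "'")
  files <- list.files(directory, pattern = utils::glob2rx(pattern),
                      full.names = TRUE)
  if (length(files) < 2L)
    stop_mct("need at least 2 slice files in '", directory,
             "' matching '", pattern, "', found ", length(files))
  files <- order_by_slice_number(files)
  first <- read_slice(files[1L])
  d23 <- dim(first)
  vol <- array(0, c(length(files), d23))
  vol[1L, , ] <- first
  for (k in seq_along(files)[-1L]) {
    s <- read_slice(files[k])
    if (!identical(dim(s), d23))
      stop_mct("slice shape mismatch: '", files[k], "' is ",
               paste(dim(s), collapse = "x"), ", expected ",
               paste(d23, collapse = "x"))
    vol[k, , ] <- s
  }
  voxel_grid(vol, voxel_size_um = voxel_size_um, calibration = calibration,
             source_id = source_id)
}

#' Write a binary mask as a TIFF slice stack
#'
#' One 8-bit grey TIFF per slice, construct voxels at 255 and background at
#' 0, named `mask_0001.tif` upward so a reload via [load_stack()] restores
#' slice order.
#'
#' @param mask a [binary_volume()].
#' @param directory output directory (created if missing).
#' @return number of slice files written, invisibly.
#' @export
save_mask <- function(mask, directory) {
  stopifnot(inherits(mask, "binary_volume"))
  if (!dir.exists(directory) &&
      !dir.create(directory, recursive = TRUE, showWarnings = FALSE))
    stop_mct("cannot create output directory: '", directory, "'")
  n <- dim(mask$mask)[1L]
  for (k in seq_len(n)) {
    slice <- mask$mask[k, , ]
    storage.mode(slice) <- "double"
    path <- file.path(directory, sprintf("mask_%04d.tif", k))
    ok <- tryCatch(tiff::writeTIFF(slice, path, bits.per.sample = 8L),
                   error = function(e)
                     stop_mct("cannot write '", path, "': ",
                              conditionMessage(e)))
    if (!isTRUE(ok == 1L) && !isTRUE(ok))
      stop_mct("writing mask slice failed: '", path, "'")
  }
  invisible(n)
}

#' Reload a mask stack written by [save_mask()]
#'
#' @param directory directory of mask slices.
#' @param voxel_size_um voxel edge in micrometres.
#' @param threshold_grey threshold to record on the reloaded mask.
#' @return a [binary_volume()].
#' @export
load_mask <- function(directory, voxel_size_um = 17.7,
                      threshold_grey = NA_real_) {
  g <- load_stack(directory, voxel_size_um = voxel_size_um)
  binary_volume(g$intensities > 0, voxel_size_um, threshold_grey)
}

#' Convert grey values to Hounsfield units
#'
#' Applies the scanner's affine calibration `HU = slope * grey + intercept`.
#' Grey values are used raw throughout segmentation; the calibration only
#' enters mineral-density reporting.
#'
#' @param value numeric scalar or vector of grey values.
#' @param calibration `list(slope =, intercept =)`.
#' @return calibrated values, same shape as `value`.
#' @export
grey_to_hu <- function(value, calibration) {
  if (is.null(calibration))
    stop_mct("no grey-to-HU calibration available; either supply ",
             "calibration = list(slope =, intercept =) or request ",
             "raw-grey reporting (raw_grey = TRUE)")
  calibration$slope * value + calibration$intercept
}
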