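# Orchestration of the three-step study workflow: per-construct analysis
# (segment, extract pores, morphometry), baseline/follow-up pairing with
# threshold re-use, and cohort summarization with paired statistics.

#' Run configuration
#'
#' Central collection of every tunable of the pipeline, serialized into the
#' outputs for provenance. `inputs` maps construct ids to their per-time-
#' point sources; each source may be a directory of TIFF slices or an
#' in-memory [voxel_grid()].
#'
#' @param inputs named list: `inputs$<id>$T0`, `inputs$<id>$T1`.
#' @param output_dir where reports and tables are written (`NULL` for
#'   in-memory operation).
#' @param voxel_size_um,calibration acquisition metadata.
#' @param fcm fuzzy c-means settings (`fuzzifier`, `tol`, `max_iter`,
#'   `seed`).
#' @param cleanup artefact removal settings (`min_fraction`).
#' @param pores pore extraction settings (`trim_fraction`).
#' @param psr pore-size histogram settings (`bin_width_um`, optional
#'   `report_bins`).
#' @param tmd mineral-density settings (`bin_width`).
#' @param stats cohort statistics settings (`alpha`, `alpha_normality`,
#'   `normality_on`).
#' @param review `"headless-accept"` (default: segmentations are accepted
#'   and a mid-slice overlay is saved for later review when an output
#'   directory is set) or `"headless-reject-on-failure"`.
#' @param save_masks also write the cleaned mask stacks.
#' @return object of class `mct_config`.
#' @export
mct_config <- function(inputs = list(), output_dir = NULL,
                       voxel_size_um = 17.7, calibration = NULL,
                       fcm = list(), cleanup = list(), pores = list(),
                       psr = list(), tmd = list(), stats = list(),
                       review = c("headless-accept",
                                  "headless-reject-on-failure"),
                       save_masks = FALSE) {
  defaults <- list(
    fcm = list(fuzzifier = 2, tol = 1e-5, max_iter = 300L, seed = 42L),
    cleanup = list(min_fraction = 0.001, despeckle_max_vox = 6L),
    pores = list(trim_fraction = 0.05),
    psr = list(bin_width_um = 10, report_bins = NULL),
    tmd = list(bin_width = 1),
    stats = list(alpha = 0.05, alpha_normality = 0.05,
                 normality_on = "samples")
  )
  structure(
    list(inputs = inputs, output_dir = output_dir,
         voxel_size_um = voxel_size_um, calibration = calibration,
         fcm = utils::modifyList(defaults$fcm, fcm),
         cleanup = utils::modifyList(defaults$cleanup, cleanup),
         pores = utils::modifyList(defaults$pores, pores),
         psr = utils::modifyList(defaults$psr, psr),
         tmd = utils::modifyList(defaults$tmd, tmd),
         stats = utils::modifyList(defaults$stats, stats),
         review = match.arg(review), save_masks = save_masks),
    class = "mct_config"
  )
}

resolve_input <- function(config, construct_id, timepoint) {
  src <- config$inputs[[construct_id]][[timepoint]]
  if (is.null(src))
    stop_mct("no input registered for construct '", construct_id,
             "' at ", timepoint)
  if (inherits(src, "voxel_grid")) return(src)
  load_stack(src, voxel_size_um = config$voxel_size_um,
             calibration = config$calibration,
             source_id = paste(construct_id, timepoint, sep = "_"))
}

#' Analyze one voxel grid in memory
#'
#' The per-construct computational core: automatic segmentation (or
#' application of a supplied threshold), artefact cleanup, ternary
#' labelling, distance map, pore extraction and trimming, morphometry.
#'
#' @param grid a [voxel_grid()].
#' @param config an [mct_config()].
#' @param threshold optional grey threshold to re-use (follow-up scans).
#' @param construct_id,timepoint labels for the report.
#' @return list: `report` ([morphometry_report()]), `segmentation`
#'   (`segmentation_outcome`), `mask`, `ternary`, `edm`, `pores_untrimmed`,
#'   `pores`.
#' @export
analyze_grid <- function(grid, config = mct_config(), threshold = NULL,
                         construct_id = grid$source_id,
                         timepoint = NA_character_) {
  stopifnot(inherits(grid, "voxel_grid"), inherits(config, "mct_config"))
  seg <- segment_construct(grid, threshold = threshold, fcm = config$fcm,
                           min_fraction = config$cleanup$min_fraction)
  ternary <- build_ternary(seg$mask)
  ds <- despeckle_in_hull(seg$mask, ternary,
                          config$cleanup$despeckle_max_vox)
  seg$mask <- ds$mask
  seg$filled_void_components <- ds$filled_void_components
  ternary <- ds$ternary
  edm <- distance_map(ternary)
  raw <- extract_pores(edm, ternary)
  trimmed <- if (nrow(raw$pores) > 0L)
    trim_pores(raw, config$pores$trim_fraction)
  else
    pore_distribution(raw$pores, raw$voxel_size_um, trimmed = TRUE,
                      trim_fraction = config$pores$trim_fraction,
                      n_untrimmed = 0L)
  report <- morphometry_report(
    grid, seg$mask, ternary, trimmed,
    construct_id = construct_id, timepoint = timepoint,
    psr_bin_width_um = config$psr$bin_width_um,
    tmd_bin_width = config$tmd$bin_width,
    report_bins = config$psr$report_bins)
  list(report = report, segmentation = seg, mask = seg$mask,
       ternary = ternary, edm = edm, pores_untrimmed = raw,
       pores = trimmed)
}

construct_outdir <- function(config, construct_id, timepoint) {
  if (is.null(config$output_dir)) return(NULL)
  d <- file.path(config$output_dir, construct_id, timepoint)
  dir.create(d, recursive = TRUE, showWarnings = FALSE)
  d
}

write_overlay <- function(grid, mask, path) {
  if (!requireNamespace("png", quietly = TRUE)) return(invisible(NULL))
  k <- dim(grid$intensities)[1L] %/% 2L
  slice <- grid$intensities[k, , ]
  rng <- range(slice)
  g <- if (diff(rng) > 0) (slice - rng[1L]) / diff(rng) else slice * 0
  rgb <- array(g, c(dim(slice), 3L))
  sel <- mask$mask[k, , ]
  r <- rgb[, , 1L]
  r[sel] <- pmin(1, r[sel] + 0.35)          # segmented voxels tinted red
  rgb[, , 1L] <- r
  png::writePNG(rgb, path)
  invisible(NULL)
}

#' Analyze one construct at one time point
#'
#' Loads the registered input, runs [analyze_grid()] and, when an output
#' directory is configured, persists the report (JSON), the pore table
#' (CSV), a mid-slice segmentation overlay (PNG, for the review step) and
#' optionally the cleaned mask stack. Stage timings are recorded on the
#' report.
#'
#' @param config an [mct_config()].
#' @param construct_id id present in `config$inputs`.
#' @param timepoint `"T0"` or `"T1"`.
#' @param threshold_override grey threshold to re-use; mandatory route for
#'   `T1` in the paired workflow.
#' @return the [morphometry_report()] (with attribute `products` carrying
#'   the intermediate stages).
#' @export
analyze_construct <- function(config, construct_id, timepoint = "T0",
                              threshold_override = NULL) {
  t0 <- proc.time()[["elapsed"]]
  grid <- resolve_input(config, construct_id, timepoint)
  res <- analyze_grid(grid, config, threshold = threshold_override,
                      construct_id = construct_id, timepoint = timepoint)
  elapsed <- proc.time()[["elapsed"]] - t0
  report <- res$report
  attr(report, "products") <- res
  attr(report, "elapsed_s") <- elapsed
  outdir <- construct_outdir(config, construct_id, timepoint)
  if (!is.null(outdir)) {
    write_report(report, file.path(outdir, "report.json"), config = config)
    write_pore_table(res$pores, construct_id, timepoint,
                     file.path(outdir, "pores.csv"))
    write_overlay(grid, res$mask, file.path(outdir, "overlay.png"))
    if (isTRUE(config$save_masks))
      save_mask(res$mask, file.path(outdir, "mask"))
  }
  report
}

#' Analyze a baseline/follow-up pair with threshold re-use
#'
#' The baseline scan (T0) is segmented automatically; its global threshold
#' is then applied verbatim to the follow-up scan (T1) of the same
#' construct so both time points are segmented identically.
#'
#' @param config an [mct_config()]; the construct needs both `T0` and `T1`
#'   inputs.
#' @param construct_id construct to analyze.
#' @return `list(T0 =, T1 =)` of cross-linked [morphometry_report()]s.
#' @export
analyze_pair <- function(config, construct_id) {
  if (is.null(config$inputs[[construct_id]]$T0) ||
      is.null(config$inputs[[construct_id]]$T1))
    stop_mct("construct '", construct_id,
             "' needs both T0 and T1 inputs for a paired analysis")
  r0 <- analyze_construct(config, construct_id, "T0")
  r1 <- analyze_construct(config, construct_id, "T1",
                          threshold_override = r0$threshold_grey)
  r0$partner <- r1$construct_id
  r1$partner <- r0$construct_id
  list(T0 = r0, T1 = r1)
}

cohort_parameters <- c("TV_um3", "SV_um3", "SS_um2", "SR_per_um", "P",
                       "PN", "PS_mean_um", "PV_um3")

#' Analyze a full cohort and summarize both time points
#'
#' Runs [analyze_pair()] for every registered construct (failures are
#' isolated: a corrupt stack yields an error record, the batch continues),
#' then -- given at least 3 complete pairs -- compares every parameter
#' between time points with the normality-routed paired test, merges the
#' pore-size and attenuation histograms, and fits the log-CDF slope.
#' With an output directory set, writes `parameters.csv` (one row per
#' construct and time point), `paired_tests.csv`, `psr_ranges.csv`
#' (100-um pore-diameter ranges with per-range paired tests),
#' `pore_histograms.csv`, `cdf_fit.csv` and `run_log.json`.
#'
#' @param config an [mct_config()] with two time points per construct.
#' @return list: `reports` (per construct, `$T0`/`$T1`), `errors`,
#'   `tests` (named [paired_compare()] results), `psr` (merged histograms,
#'   delta, CDFs, slopes), `hu` (pooled attenuation histograms),
#'   `psr_ranges` (coarse-range data frame), `stats_skipped`.
#' @export
analyze_cohort <- function(config) {
  ids <- names(config$inputs)
  if (length(ids) == 0L) stop_mct("no constructs registered in config")
  reports <- list()
  errors <- list()
  for (id in ids) {
    res <- tryCatch(analyze_pair(config, id), error = function(e)
      structure(list(construct_id = id,
                     message = conditionMessage(e)),
                class = "mct_error_record"))
    if (inherits(res, "mct_error_record")) errors[[id]] <- res
    else reports[[id]] <- res
  }
  n_pairs <- length(reports)
  out <- list(reports = reports, errors = errors,
              stats_skipped = n_pairs < 3L)
  if (n_pairs >= 3L) {
    get_par <- function(tp, par)
      vapply(reports, function(r) r[[tp]][[par]], numeric(1))
    out$tests <- lapply(cohort_parameters, function(par)
      paired_compare(get_par("T0", par), get_par("T1", par),
                     parameter = par, alpha = config$stats$alpha,
                     alpha_normality = config$stats$alpha_normality,
                     normality_on = config$stats$normality_on))
    names(out$tests) <- cohort_parameters

    diam <- function(tp) lapply(reports, function(r)
      r[[tp]]$pore_diameters_um)
    have_pores <- length(unlist(diam("T0"))) > 0L &&
      length(unlist(diam("T1"))) > 0L
    if (have_pores) {
      merged <- merge_pore_histograms(diam("T0"), diam("T1"),
                                      config$psr$bin_width_um)
      cdf0 <- empirical_cdf(merged$T0)
      cdf1 <- empirical_cdf(merged$T1)
      # the default fit range (lower half of the bins) can be void of
      # positive cumulative mass in small cohorts; report NA then
      safe_fit <- function(cdf) tryCatch(log_cdf_slope(cdf),
        error = function(e) c(slope = NA_real_, intercept = NA_real_))
      out$psr <- list(
        T0 = merged$T0, T1 = merged$T1,
        delta = delta_histogram(merged$T0, merged$T1),
        cdf_T0 = cdf0, cdf_T1 = cdf1,
        slope_T0 = safe_fit(cdf0), slope_T1 = safe_fit(cdf1))
      out$psr_ranges <- psr_range_table(reports, config)
    }
    out$hu <- hu_histogram(lapply(reports, function(r) r$T0$TMD_hist),
                           lapply(reports, function(r) r$T1$TMD_hist))
  }
  if (!is.null(config$output_dir))
    write_cohort_outputs(out, config)
  out
}

# Per-construct mean pore counts in 100-um diameter ranges, with a paired
# t-test per range across constructs.
psr_range_table <- function(reports, config) {
  all_d <- unlist(lapply(reports, function(r)
    c(r$T0$pore_diameters_um, r$T1$pore_diameters_um)))
  top <- max(100, (floor(max(all_d) / 100) + 1L) * 100)
  edges <- seq(0, top, by = 100)
  count_in <- function(d) tabulate(findInterval(d, edges),
                                   nbins = length(edges) - 1L)
  c0 <- t(vapply(reports, function(r) count_in(r$T0$pore_diameters_um),
                 numeric(length(edges) - 1L)))
  c1 <- t(vapply(reports, function(r) count_in(r$T1$pore_diameters_um),
                 numeric(length(edges) - 1L)))
  p <- vapply(seq_len(ncol(c0)), function(b) {
    if (all(c1[, b] - c0[, b] == 0)) return(NA_real_)
    tryCatch(t.test(c1[, b], c0[, b], paired = TRUE)$p.value,
             error = function(e) NA_real_)
  }, numeric(1))
  data.frame(range_lo_um = edges[-length(edges)],
             range_hi_um = edges[-1L],
             PN_T0_mean = colMeans(c0), PN_T1_mean = colMeans(c1),
             delta_percent = ifelse(colMeans(c1) > 0,
                                    100 * (1 - colMeans(c0) / colMeans(c1)),
                                    NA_real_),
             p_value = p)
}

write_cohort_outputs <- function(out, config) {
  dir.create(config$output_dir, recursive = TRUE, showWarnings = FALSE)
  rows <- do.call(rbind, unlist(lapply(out$reports, function(r)
    lapply(r, report_row)), recursive = FALSE))
  if (!is.null(rows))
    write.csv(rows, file.path(config$output_dir, "parameters.csv"),
              row.names = FALSE)
  if (!is.null(out$tests)) {
    tests <- do.call(rbind, lapply(out$tests, function(t)
      data.frame(parameter = t$parameter,
                 distribution = if (t$test_used == "paired_t") "normal"
                                else "not normal",
                 statistical_test = t$test_used,
                 p_value = t$p_value, significant = t$significant)))
    write.csv(tests, file.path(config$output_dir, "paired_tests.csv"),
              row.names = FALSE)
  }
  if (!is.null(out$psr)) {
    h <- out$psr
    write.csv(data.frame(bin_lo_um = h$T0$edges[-length(h$T0$edges)],
                         bin_hi_um = h$T0$edges[-1L],
                         count_T0 = h$T0$counts, count_T1 = h$T1$counts,
                         delta = h$delta$counts,
                         cdf_T0 = h$cdf_T0$cdf, cdf_T1 = h$cdf_T1$cdf),
              file.path(config$output_dir, "pore_histograms.csv"),
              row.names = FALSE)
    write.csv(data.frame(timepoint = c("T0", "T1"),
                         slope = c(h$slope_T0[["slope"]],
                                   h$slope_T1[["slope"]]),
                         intercept = c(h$slope_T0[["intercept"]],
                                       h$slope_T1[["intercept"]])),
              file.path(config$output_dir, "cdf_fit.csv"),
              row.names = FALSE)
    write.csv(out$psr_ranges,
              file.path(config$output_dir, "psr_ranges.csv"),
              row.names = FALSE)
  }
  log <- list(
    constructs_analyzed = names(out$reports),
    errors = lapply(out$errors, function(e)
      list(construct_id = e$construct_id, message = e$message)),
    stats_skipped = out$stats_skipped,
    config = config_provenance(config))
  jsonlite::write_json(log, file.path(config$output_dir, "run_log.json"),
                       auto_unbox = TRUE, digits = NA, null = "null")
  invisible(NULL)
}

report_row <- function(r) {
  data.frame(construct_id = r$construct_id, timepoint = r$timepoint,
             TV_um3 = r$TV_um3, SV_um3 = r$SV_um3, SS_um2 = r$SS_um2,
             SR_per_um = r$SR_per_um, P = r$P, PN = r$PN,
             PS_mean_um = r$PS_mean_um, PS_sd_um = r$PS_sd_um,
             PV_um3 = r$PV_um3, TMD_mean = r$TMD_mean, TMD_sd = r$TMD_sd,
             TMD_unit = r$TMD_unit, threshold_grey = r$threshold_grey,
             voxel_size_um = r$voxel_size_um)
}

config_provenance <- function(config) {
  prov <- unclass(config)
  prov$inputs <- lapply(prov$inputs, function(tp)
    lapply(tp, function(src)
      if (inherits(src, "voxel_grid"))
        paste0("<in-memory grid ",
               paste(dim(src$intensities), collapse = "x"), ">")
      else src))
  prov
}

#' Persist a morphometry report as JSON
#'
#' Human-readable JSON with every parameter, the threshold, the pore
#' diameters and (optionally) the full run configuration for provenance.
#'
#' @param report a [morphometry_report()].
#' @param path output file.
#' @param config optional [mct_config()] to embed.
#' @return `path`, invisibly.
#' @export
write_report <- function(report, path, config = NULL) {
  stopifnot(inherits(report, "morphometry_report"))
  x <- unclass(report)
  attributes(x) <- list(names = names(x))
  for (f in c("PSR", "TMD_hist"))
    if (!is.null(x[[f]]))
      x[[f]] <- if (inherits(x[[f]], "mct_hist"))
        list(edges = x[[f]]$edges, counts = x[[f]]$counts)
      else lapply(x[[f]], function(h)
        list(edges = h$edges, counts = h$counts))
  if (!is.null(config)) x$config <- config_provenance(config)
  jsonlite::write_json(x, path, auto_unbox = TRUE, digits = NA,
                       null = "null", na = "null")
  invisible(path)
}

#' Read back a report written by [write_report()]
#'
#' @param path JSON file.
#' @return a [morphometry_report()] (histograms restored as [mct_hist()]).
#' @export
read_report <- function(path) {
  x <- jsonlite::read_json(path, simplifyVector = TRUE)
  x$config <- NULL
  for (f in c("PSR", "TMD_hist"))
    if (!is.null(x[[f]]) && !is.null(x[[f]]$edges))
      x[[f]] <- mct_hist(edges = x[[f]]$edges, counts = x[[f]]$counts)
  class(x) <- "morphometry_report"
  x
}

write_pore_table <- function(pores, construct_id, timepoint, path) {
  df <- pores$pores
  out <- data.frame(construct_id = rep(construct_id, nrow(df)),
                    timepoint = rep(timepoint, nrow(df)),
                    z = df$z, y = df$y, x = df$x,
                    radius_vox = df$radius_vox,
                    diameter_um = df$diameter_um)
  write.csv(out, path, row.names = FALSE)
  invisible(path)
}
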