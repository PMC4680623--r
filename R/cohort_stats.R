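# Cohort-level statistics: merged pore-size and attenuation histograms,
# their baseline/follow-up deltas, the empirical CDF with its log-linear
# slope, normality-routed paired comparisons, and the cross-tool pore-
# volume deviation metric.

#' Merge pore size distributions across a cohort
#'
#' Pools the pore diameters of all constructs of each time point onto one
#' shared set of half-open bins spanning zero to the global maximum.
#'
#' @param diameters_t0,diameters_t1 lists of per-construct diameter vectors
#'   (micrometres); at least one non-empty construct per time point.
#' @param bin_width_um shared bin width.
#' @return `list(T0 =, T1 =)` of [mct_hist()] on identical edges.
#' @export
merge_pore_histograms <- function(diameters_t0, diameters_t1,
                                  bin_width_um = 10) {
  pool0 <- unlist(diameters_t0, use.names = FALSE)
  pool1 <- unlist(diameters_t1, use.names = FALSE)
  if (length(pool0) == 0L || length(pool1) == 0L)
    stop_mct("merge_pore_histograms: empty pore pool for a time point")
  top <- (floor(max(pool0, pool1) / bin_width_um) + 1L) * bin_width_um
  edges <- seq(0, top, by = bin_width_um)
  list(T0 = mct_hist(pool0, edges = edges),
       T1 = mct_hist(pool1, edges = edges))
}

#' Per-bin histogram delta (follow-up minus baseline)
#'
#' @param h_t0,h_t1 two [mct_hist()] on identical edges.
#' @return [mct_hist()] of signed counts `T1 - T0`.
#' @export
delta_histogram <- function(h_t0, h_t1) {
  stopifnot(inherits(h_t0, "mct_hist"), inherits(h_t1, "mct_hist"))
  if (!isTRUE(all.equal(h_t0$edges, h_t1$edges)))
    stop_mct("delta_histogram: bin edges differ")
  mct_hist(edges = h_t0$edges, counts = h_t1$counts - h_t0$counts)
}

#' Empirical cumulative distribution of a histogram
#'
#' @param h an [mct_hist()] with positive total count.
#' @return object of class `mct_cdf`: `edges`, `mids`, `cdf` (nondecreasing
#'   cumulative fraction per bin, terminal value 1).
#' @export
empirical_cdf <- function(h) {
  stopifnot(inherits(h, "mct_hist"))
  tot <- sum(h$counts)
  if (tot <= 0) stop_mct("empirical_cdf: histogram is empty")
  structure(list(edges = h$edges, mids = h$mids,
                 cdf = cumsum(h$counts) / tot),
            class = "mct_cdf")
}

#' Log-linear slope of the cumulative pore size distribution
#'
#' Least-squares line through `(bin centre, log cdf)` over the chosen bins;
#' by default the lower half of the bin range (only bins with positive
#' cumulative mass enter, since log 0 is undefined). The steeper the slope,
#' the larger the contribution of small pores to the distribution. Natural
#' logarithm.
#'
#' @param cdf an [empirical_cdf()] result.
#' @param fit_range optional integer bin indices to fit over.
#' @return `c(slope =, intercept =)` (slope per micrometre).
#' @export
log_cdf_slope <- function(cdf, fit_range = NULL) {
  stopifnot(inherits(cdf, "mct_cdf"))
  nb <- length(cdf$cdf)
  if (is.null(fit_range)) fit_range <- seq_len(floor(nb / 2))
  fit_range <- fit_range[fit_range >= 1L & fit_range <= nb]
  fit_range <- fit_range[cdf$cdf[fit_range] > 0]
  if (length(fit_range) < 2L)
    stop_mct("log_cdf_slope: fewer than 2 usable bins in the fit range")
  xs <- cdf$mids[fit_range]
  ys <- log(cdf$cdf[fit_range])
  fit <- stats::lm.fit(cbind(1, xs), ys)
  c(slope = unname(fit$coefficients[2L]),
    intercept = unname(fit$coefficients[1L]))
}

# Add histograms whose edges are aligned to multiples of a common width.
align_and_pool <- function(hists) {
  w <- hists[[1L]]$edges[2L] - hists[[1L]]$edges[1L]
  for (h in hists) {
    wk <- h$edges[2L] - h$edges[1L]
    if (abs(wk - w) > 1e-9 * w)
      stop_mct("cannot pool histograms with different bin widths")
    if (abs(h$edges[1L] / w - round(h$edges[1L] / w)) > 1e-9)
      stop_mct("cannot pool histograms whose edges are not width-aligned")
  }
  lo <- min(vapply(hists, function(h) h$edges[1L], numeric(1)))
  hi <- max(vapply(hists, function(h) h$edges[length(h$edges)], numeric(1)))
  edges <- seq(lo, hi, by = w)
  counts <- numeric(length(edges) - 1L)
  for (h in hists) {
    k0 <- round((h$edges[1L] - lo) / w)
    idx <- k0 + seq_along(h$counts)
    counts[idx] <- counts[idx] + h$counts
  }
  mct_hist(edges = edges, counts = counts)
}

#' Pooled attenuation histograms of the segmented voxels
#'
#' Combines the per-construct mineral-density histograms (segmented-voxel
#' support) of each time point onto shared bins and forms the follow-up
#' minus baseline delta. Only voxels segmented as construct contribute.
#'
#' @param hists_t0,hists_t1 lists of per-construct [mct_hist()] (the
#'   `TMD_hist` field of the reports), equal bin width.
#' @return `list(T0, T1, delta)` of [mct_hist()] on identical edges.
#' @export
hu_histogram <- function(hists_t0, hists_t1) {
  if (length(hists_t0) == 0L || length(hists_t1) == 0L)
    stop_mct("hu_histogram: missing mineral-density histograms")
  p0 <- align_and_pool(hists_t0)
  p1 <- align_and_pool(hists_t1)
  pooled <- align_and_pool(list(mct_hist(edges = p0$edges,
                                         counts = 0 * p0$counts),
                                mct_hist(edges = p1$edges,
                                         counts = 0 * p1$counts)))
  expand <- function(h) align_and_pool(list(h, pooled))
  h0 <- expand(p0)
  h1 <- expand(p1)
  list(T0 = h0, T1 = h1, delta = delta_histogram(h0, h1))
}

#' Normality-routed paired comparison of two time points
#'
#' Tests each sample (baseline values and follow-up values across the
#' matched constructs) for normality with the Shapiro-Wilk test. If both
#' pass at `alpha_normality` the paired two-sample t-test is used,
#' otherwise the Wilcoxon signed-rank test; significance at `alpha`
#' (two-sided). Alternatively the paired differences can be tested for
#' normality (`normality_on = "differences"`). A comparison whose paired
#' differences are all zero is flagged degenerate and reported
#' non-significant.
#'
#' @param values_t0,values_t1 matched per-construct parameter values
#'   (>= 3 pairs).
#' @param parameter label carried into the result.
#' @param alpha significance level.
#' @param alpha_normality Shapiro-Wilk level for routing.
#' @param normality_on `"samples"` (default) or `"differences"`.
#' @return object of class `paired_test_result` with fields
#'   `normality_p`, `test_used` (`"paired_t"` or
#'   `"wilcoxon_signed_rank"`), `p_value`, `significant`, `degenerate`.
#' @export
paired_compare <- function(values_t0, values_t1, parameter = "",
                           alpha = 0.05, alpha_normality = 0.05,
                           normality_on = c("samples", "differences")) {
  normality_on <- match.arg(normality_on)
  if (length(values_t0) != length(values_t1))
    stop_mct("paired_compare: unmatched sample lengths")
  n <- length(values_t0)
  if (n < 3L) stop_mct("paired_compare: need at least 3 matched pairs")
  sw <- function(v) {
    tryCatch(shapiro.test(v)$p.value, error = function(e) 0)
  }
  normality_p <- if (normality_on == "samples")
    c(T0 = sw(values_t0), T1 = sw(values_t1))
  else
    c(diff = sw(values_t1 - values_t0))
  normal <- all(normality_p >= alpha_normality)
  test_used <- if (normal) "paired_t" else "wilcoxon_signed_rank"
  diffs <- values_t1 - values_t0
  degenerate <- all(diffs == 0)
  p_value <- if (degenerate) {
    1
  } else if (normal) {
    t.test(values_t1, values_t0, paired = TRUE)$p.value
  } else {
    suppressWarnings(
      wilcox.test(values_t1, values_t0, paired = TRUE)$p.value)
  }
  structure(
    list(parameter = parameter, values_t0 = values_t0,
         values_t1 = values_t1, normality_p = normality_p,
         normality_on = normality_on, test_used = test_used,
         p_value = p_value, alpha = alpha,
         significant = is.finite(p_value) && p_value < alpha,
         degenerate = degenerate),
    class = "paired_test_result"
  )
}

#' @export
print.paired_test_result <- function(x, ...) {
  cat(sprintf("paired comparison %s: %s, p = %.4g%s%s\n",
              x$parameter, x$test_used, x$p_value,
              if (x$significant) " (significant)" else "",
              if (x$degenerate) " [degenerate: all differences zero]"
              else ""))
  invisible(x)
}

#' Cross-tool pore-volume deviation
#'
#' Signed fractional deviation between this pipeline's total pore volume
#' and a reference tool's:
#' `deviation = 0.5 - pv_ours / (pv_ours + pv_reference)`. Equal inputs
#' give zero; swapping the arguments flips the sign exactly.
#'
#' @param pv_ours,pv_reference positive total pore volumes (same units).
#' @return signed deviation in `(-0.5, 0.5)`.
#' @export
deviation_metric <- function(pv_ours, pv_reference) {
  if (any(!is.finite(c(pv_ours, pv_reference))) ||
      any(c(pv_ours, pv_reference) <= 0))
    stop_mct("deviation_metric: pore volumes must be positive")
  0.5 - pv_ours / (pv_ours + pv_reference)
}
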