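# Internal helpers shared across modules.

# Round to nearest integer, halves away from zero (fixed rule so centre
# indices are reproducible across platforms; base round() goes to even).
round_half_away <- function(x) {
  sign(x) * floor(abs(x) + 0.5)
}

# Evaluate `code` under a private RNG stream, restoring the caller's
# .Random.seed afterwards so library calls never perturb user randomness.
with_seed <- function(seed, code) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (had) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  force(code)
}

# Shift a 3D array by an integer offset, filling exposed voxels with `fill`.
# out[i, j, k] == a[i + d1, j + d2, k + d3] where defined.
shift3 <- function(a, d, fill = 0) {
  dm <- dim(a)
  out <- array(fill, dm)
  src <- dst <- vector("list", 3L)
  for (ax in 1:3) {
    if (d[ax] >= 0) {
      n <- dm[ax] - d[ax]
      if (n <= 0) return(out)
      dst[[ax]] <- seq_len(n)
      src[[ax]] <- seq_len(n) + d[ax]
    } else {
      n <- dm[ax] + d[ax]
      if (n <= 0) return(out)
      dst[[ax]] <- seq_len(n) - d[ax]
      src[[ax]] <- seq_len(n)
    }
  }
  out[dst[[1]], dst[[2]], dst[[3]]] <- a[src[[1]], src[[2]], src[[3]]]
  out
}

# The 26 neighbourhood offsets of a voxel.
neighbourhood26 <- function() {
  off <- as.matrix(expand.grid(d1 = -1:1, d2 = -1:1, d3 = -1:1))
  off[rowSums(off != 0) > 0, , drop = FALSE]
}

#' Half-open histogram container
#'
#' Counts over half-open bins `[edges[k], edges[k + 1])`. All histogram-based
#' summaries in the package (pore-size ranges, attenuation distributions,
#' cohort merges) share this container so bin conventions stay consistent.
#'
#' @param x numeric values to bin, or `NULL` to wrap precomputed `counts`.
#' @param edges strictly increasing numeric bin edges.
#' @param counts optional precomputed counts (length `length(edges) - 1`).
#' @return an object of class `mct_hist` with fields `edges`, `counts`,
#'   `mids`.
#' @export
mct_hist <- function(x = NULL, edges, counts = NULL) {
  stopifnot(is.numeric(edges), length(edges) >= 2L, all(diff(edges) > 0))
  if (is.null(counts)) {
    stopifnot(is.numeric(x))
    if (any(x < edges[1L] | x >= edges[length(edges)]))
      stop("values outside the histogram range [",
           edges[1L], ", ", edges[length(edges)], ")")
    idx <- findInterval(x, edges)
    counts <- tabulate(idx, nbins = length(edges) - 1L)
  }
  stopifnot(length(counts) == length(edges) - 1L)
  structure(
    list(edges = edges,
         counts = as.numeric(counts),
         mids = (edges[-length(edges)] + edges[-1L]) / 2),
    class = "mct_hist"
  )
}

#' @export
print.mct_hist <- function(x, ...) {
  cat("mct_hist:", length(x$counts), "bins, width",
      format(x$edges[2L] - x$edges[1L]), ", total count", sum(x$counts), "\n")
  invisible(x)
}

stop_mct <- function(...) stop(..., call. = FALSE)
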