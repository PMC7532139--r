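#' Histogram differential-entropy configuration
#'
#' @param n_bins Number of bins (default 60, the reporting default; the
#'   conventional sweep is 15 to 120 in steps of 15).
#' @param bin_range `"data"` (span the observed range of each series, the
#'   default) or `"fixed"` (use `fixed_range`, e.g. the correlation scale
#'   `[-1, 1]`).
#' @param fixed_range Length-2 numeric range used when
#'   `bin_range = "fixed"`.
#' @return An `entropy_config` list.
#' @export
entropy_config <- function(n_bins = 60, bin_range = c("data", "fixed"),
                           fixed_range = c(-1, 1)) {
  bin_range <- match.arg(bin_range)
  n_bins <- as.integer(n_bins)
  if (n_bins < 1) stop("n_bins must be positive")
  if (bin_range == "fixed" && diff(fixed_range) <= 0)
    stop("fixed_range must have positive width")
  structure(list(n_bins = n_bins, bin_range = bin_range,
                 fixed_range = as.numeric(fixed_range)),
            class = "entropy_config")
}

#' Histogram approximation to differential entropy
#'
#' Computes `H(X) = -sum_i f(x_i) * log(f(x_i) / w(x_i))` in nats, where
#' `f(x_i)` are the empirical bin proportions of the discretized series
#' (summing to 1) and `w(x_i)` is the bin width. Empty bins contribute 0
#' (the limit x * log(x) -> 0). For uniform-width bins this equals the
#' Shannon entropy of the bin proportions plus `log(w)`, so the bin-width
#' term corrects the plain discretized entropy onto the differential scale.
#'
#' @param x Numeric series. A warning is emitted when `length(x) < n_bins`.
#' @param config An [entropy_config()].
#' @return Entropy in nats, or `NA` with attribute `flagged = TRUE` when
#'   the binning range has zero width (constant series under data-range
#'   binning), where the estimator is undefined.
#' @examples
#' set.seed(1)
#' entropy_hist(runif(1e5), entropy_config(60, "fixed", c(0, 1)))  # ~ 0
#' @export
entropy_hist <- function(x, config = entropy_config()) {
  stopifnot(inherits(config, "entropy_config"))
  x <- x[!is.na(x)]
  n <- length(x)
  if (n == 0) stop("empty series")
  if (n < config$n_bins)
    warning("series length (", n, ") below the number of bins (",
            config$n_bins, "); the entropy estimate will be coarse")
  rng <- if (config$bin_range == "fixed") config$fixed_range else range(x)
  if (diff(rng) <= 0)
    return(structure(NA_real_, flagged = TRUE))
  breaks <- seq(rng[1], rng[2], length.out = config$n_bins + 1L)
  idx <- findInterval(x, breaks, rightmost.closed = TRUE, all.inside = TRUE)
  f <- tabulate(idx, nbins = config$n_bins) / n
  w <- diff(breaks)
  nz <- f > 0
  -sum(f[nz] * log(f[nz] / w[nz]))
}

#' Entropy across a sweep of bin counts
#'
#' Recomputes [entropy_hist()] for each bin count in `bins` (default the
#' conventional 15-120 sweep in steps of 15), e.g. to verify that results
#' are stable to the binning choice.
#'
#' @param x Numeric series.
#' @param bins Integer vector of bin counts.
#' @param bin_range,fixed_range Passed to [entropy_config()].
#' @return Named numeric vector of entropies (names = bin counts).
#' @export
entropy_sweep <- function(x, bins = seq(15L, 120L, by = 15L),
                          bin_range = "data", fixed_range = c(-1, 1)) {
  out <- vapply(bins, function(b) {
    as.numeric(entropy_hist(x, entropy_config(b, bin_range, fixed_range)))
  }, numeric(1))
  names(out) <- bins
  out
}

#' Entropic functional connectivity (entropy of edge correlations)
#'
#' Entry (i, j) is the histogram differential entropy (in nats) of that
#' edge's conditional-correlation series. By default the entropy is taken
#' on the raw correlation scale with per-edge data-range binning. Edges for
#' which the estimator is undefined (zero-width range) are propagated as
#' missing and counted in the `n_flagged` attribute; a warning is raised
#' when more than 1% of edges are flagged.
#'
#' @param edge_series An `edge_series_set` from [dcc_scan()].
#' @param config An [entropy_config()].
#' @param scale `"r"` (default) or `"z"` to take the entropy of the
#'   Fisher-z-transformed correlation series instead.
#' @return A [connectivity_matrix()] with measure `"efc_H"` (diagonal `NA`).
#' @export
entropic_fc <- function(edge_series, config = entropy_config(),
                        scale = c("r", "z")) {
  stopifnot(inherits(edge_series, "edge_series_set"))
  scale <- match.arg(scale)
  s <- edge_series$series
  if (scale == "z") s <- atanh(pmin(pmax(s, -0.999999), 0.999999))
  h <- apply(s, 2, function(col) as.numeric(entropy_hist(col, config)))
  n_flag <- sum(is.na(h))
  if (n_flag > 0.01 * length(h))
    warning("entropic_fc: ", n_flag, " of ", length(h),
            " edges flagged (undefined entropy)")
  m <- edge_vec_to_matrix(h, edge_series$node_ids)
  connectivity_matrix(m, "efc_H",
                      participant = edge_series$participant,
                      drug = edge_series$drug, half = edge_series$half,
                      n_flagged = n_flag)
}
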