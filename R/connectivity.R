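#' Construct a scan timeseries
#'
#' The atomic input of the pipeline: one scan's T x N matrix of
#' region-of-interest timeseries, with participant / drug-condition /
#' scan-half metadata.
#'
#' @param data Numeric T x N matrix, no missing values, every column with
#'   nonzero variance.
#' @param node_ids Node labels (default taken from column names).
#' @param participant,drug,half Metadata strings.
#' @return A `scan_timeseries` (numeric matrix with metadata attributes).
#' @export
scan_timeseries <- function(data, node_ids = colnames(data),
                            participant = NA_character_,
                            drug = NA_character_, half = NA_character_) {
  data <- as.matrix(data)
  storage.mode(data) <- "double"
  if (anyNA(data)) stop("scan contains missing values")
  if (is.null(node_ids)) node_ids <- sprintf("N%03d", seq_len(ncol(data)))
  if (length(node_ids) != ncol(data))
    stop("node_ids length does not match number of columns")
  sds <- apply(data, 2, stats::sd)
  if (any(sds == 0))
    stop("constant (zero-variance) timeseries for node(s): ",
         paste(node_ids[sds == 0], collapse = ", "))
  colnames(data) <- node_ids
  structure(data, class = c("scan_timeseries", "matrix", "array"),
            participant = participant, drug = drug, half = half)
}

#' @export
print.scan_timeseries <- function(x, ...) {
  cat("<scan_timeseries> ", nrow(x), " timepoints x ", ncol(x), " nodes",
      if (!is.na(attr(x, "participant")))
        paste0(" [", attr(x, "participant"), " ", attr(x, "drug"), " ",
               attr(x, "half"), "]"),
      "\n", sep = "")
  invisible(x)
}

scan_meta <- function(scan) {
  list(participant = attr(scan, "participant"),
       drug = attr(scan, "drug"), half = attr(scan, "half"))
}

#' Split a scan into first and second halves
#'
#' Rows `1..floor(T/2)` form the first half and the remainder the second,
#' so that concatenating the halves restores the original scan. Used to
#' convert a single drug-session scan into the two cells of the
#' drug-by-time design (peak drug effects occupy roughly the first half of
#' a 20-minute scan).
#'
#' @param scan A [scan_timeseries()] with at least 60 timepoints (so each
#'   half supports DCC estimation).
#' @return List with elements `first` and `second`, each a
#'   `scan_timeseries` with the `half` attribute set.
#' @export
split_halves <- function(scan) {
  n_t <- nrow(scan)
  if (n_t < 60)
    stop("scan has ", n_t, " timepoints; at least 60 required so each half ",
         "supports DCC estimation")
  cut <- n_t %/% 2
  meta <- scan_meta(scan)
  list(first = scan_timeseries(scan[seq_len(cut), , drop = FALSE],
                               participant = meta$participant,
                               drug = meta$drug, half = "first"),
       second = scan_timeseries(scan[(cut + 1):n_t, , drop = FALSE],
                                participant = meta$participant,
                                drug = meta$drug, half = "second"))
}

#' Construct a connectivity matrix
#'
#' @param values Symmetric N x N numeric matrix.
#' @param measure One of `"sfc_r"`, `"sfc_z"`, `"dfc_var"`, `"efc_H"`.
#' @param participant,drug,half Metadata strings.
#' @param n_flagged Number of edges flagged (set missing) during estimation.
#' @return A `connectivity_matrix`.
#' @export
connectivity_matrix <- function(values,
                                measure = c("sfc_r", "sfc_z", "dfc_var",
                                            "efc_H"),
                                participant = NA_character_,
                                drug = NA_character_, half = NA_character_,
                                n_flagged = 0L) {
  measure <- match.arg(measure)
  values <- as.matrix(values)
  if (nrow(values) != ncol(values)) stop("connectivity matrix must be square")
  if (max(abs(values - t(values)), na.rm = TRUE) > 1e-8)
    stop("connectivity matrix must be symmetric")
  if (measure == "sfc_r") {
    off <- values[upper.tri(values)]
    if (any(abs(off[!is.na(off)]) > 1 + 1e-12))
      stop("sfc_r entries must lie in [-1, 1]")
  }
  if (measure == "dfc_var") {
    off <- values[upper.tri(values)]
    if (any(off[!is.na(off)] < 0)) stop("dfc_var entries must be >= 0")
  }
  structure(values, class = c("connectivity_matrix", "matrix", "array"),
            measure = measure, participant = participant, drug = drug,
            half = half, n_flagged = as.integer(n_flagged))
}

#' @export
print.connectivity_matrix <- function(x, ...) {
  cat("<connectivity_matrix> ", attr(x, "measure"), ", ", nrow(x), " nodes",
      if (!is.na(attr(x, "participant")))
        paste0(" [", attr(x, "participant"), " ", attr(x, "drug"), " ",
               attr(x, "half"), "]"),
      if (attr(x, "n_flagged") > 0)
        paste0(" (", attr(x, "n_flagged"), " flagged edges)"),
      "\n", sep = "")
  invisible(x)
}

fc_measure <- function(m) attr(m, "measure")

#' Static functional connectivity
#'
#' Pearson correlation between the timeseries of all pairwise node
#' combinations (N nodes give N(N-1)/2 unique edges; 268 nodes give
#' 35,778).
#'
#' @param scan A [scan_timeseries()] with at least 3 timepoints.
#' @return A [connectivity_matrix()] with measure `"sfc_r"`, unit diagonal.
#' @export
static_fc <- function(scan) {
  if (!inherits(scan, "scan_timeseries")) scan <- scan_timeseries(scan)
  if (nrow(scan) < 3) stop("at least 3 timepoints required")
  m <- stats::cor(unclass(scan))
  meta <- scan_meta(scan)
  connectivity_matrix(m, "sfc_r", participant = meta$participant,
                      drug = meta$drug, half = meta$half)
}

#' Fisher z-transform
#'
#' `z = atanh(r)`: variance-stabilising transform applied to all
#' correlations before statistics. For a `connectivity_matrix` of measure
#' `sfc_r`, off-diagonal entries are transformed and the (undefined)
#' diagonal is set to `NA`; the result has measure `sfc_z`.
#'
#' @param r Numeric vector/matrix with values strictly inside (-1, 1), or a
#'   `connectivity_matrix` of measure `sfc_r`.
#' @return Same shape as the input.
#' @examples
#' fisher_z(0.5)  # 0.5 * log(3)
#' @export
fisher_z <- function(r) {
  if (inherits(r, "connectivity_matrix")) {
    if (fc_measure(r) != "sfc_r")
      stop("fisher_z on a connectivity matrix requires measure 'sfc_r'")
    v <- unclass(r)
    off <- v[upper.tri(v) | lower.tri(v)]
    if (any(abs(off[!is.na(off)]) >= 1))
      stop("correlations of magnitude >= 1 cannot be z-transformed")
    v[upper.tri(v) | lower.tri(v)] <- atanh(off)
    diag(v) <- NA_real_
    return(connectivity_matrix(v, "sfc_z",
                               participant = attr(r, "participant"),
                               drug = attr(r, "drug"), half = attr(r, "half"),
                               n_flagged = attr(r, "n_flagged")))
  }
  if (any(abs(r[!is.na(r)]) >= 1))
    stop("correlations of magnitude >= 1 cannot be z-transformed")
  atanh(r)
}

#' Split-half reliability of a connectivity measure
#'
#' Pearson correlation between the vectorised upper triangles of two
#' connectivity matrices (same measure, same node set), e.g. the first- and
#' second-half matrices of one scan.
#'
#' @param matrix_first,matrix_second [connectivity_matrix()] objects.
#' @return Correlation coefficient (numeric scalar).
#' @export
split_half_reliability <- function(matrix_first, matrix_second) {
  if (fc_measure(matrix_first) != fc_measure(matrix_second))
    stop("matrices measure different quantities")
  if (!identical(dim(matrix_first), dim(matrix_second)) ||
      !identical(colnames(matrix_first), colnames(matrix_second)))
    stop("matrices must share the same node set")
  a <- matrix_first[upper.tri(matrix_first)]
  b <- matrix_second[upper.tri(matrix_second)]
  ok <- stats::complete.cases(a, b)
  stats::cor(a[ok], b[ok])
}
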