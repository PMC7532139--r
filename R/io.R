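# Tabular I/O. Everything is TSV with a single header row; square matrices
# carry node ids as both header and first column, so outputs are
# language-agnostic and diff-able.

write_tsv <- function(df, path) {
  utils::write.table(df, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = TRUE)
}

read_tsv <- function(path) {
  if (!file.exists(path)) stop("input file not found: ", path)
  utils::read.table(path, sep = "\t", header = TRUE,
                    stringsAsFactors = FALSE, check.names = FALSE)
}

#' Write a study to disk as delimited text
#'
#' One TSV per scan (T rows x N node columns), plus `design.tsv`
#' (participant, drug, half, filename) and `network_map.tsv`
#' (node_id, network).
#'
#' @param study An `fc_study` from [simulate_study()].
#' @param dir Output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_study <- function(study, dir) {
  stopifnot(inherits(study, "fc_study"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  dt <- study$design_table
  dt$filename <- paste0("scan_", gsub(".", "_", dt$key, fixed = TRUE), ".tsv")
  for (r in seq_len(nrow(dt))) {
    scan <- study$scans[[dt$key[r]]]
    write_tsv(as.data.frame(unclass(scan)), file.path(dir, dt$filename[r]))
  }
  write_tsv(dt[, c("participant", "drug", "half", "filename")],
            file.path(dir, "design.tsv"))
  write_tsv(data.frame(node_id = study$scheme$node_id,
                       network = as.character(study$scheme$network)),
            file.path(dir, "network_map.tsv"))
  invisible(dir)
}

#' Read a study from disk
#'
#' Reads the `design.tsv` / `network_map.tsv` / per-scan TSV layout written
#' by [write_study()] (or user data in the same format).
#'
#' @param dir Directory containing `design.tsv`, `network_map.tsv` and the
#'   scan files it names.
#' @param split Logical: if `TRUE`, each listed scan is one full session
#'   (no `half` column needed) and is split into first/second halves with
#'   [split_halves()].
#' @return An `fc_study`.
#' @export
read_study <- function(dir, split = FALSE) {
  dt <- read_tsv(file.path(dir, "design.tsv"))
  nm <- read_tsv(file.path(dir, "network_map.tsv"))
  need <- if (split) c("participant", "drug", "filename")
          else c("participant", "drug", "half", "filename")
  miss <- setdiff(need, names(dt))
  if (length(miss))
    stop("design.tsv is missing column(s): ", paste(miss, collapse = ", "))
  scheme <- network_scheme(nm$node_id, nm$network)
  scans <- list()
  rows <- list()
  for (r in seq_len(nrow(dt))) {
    path <- file.path(dir, dt$filename[r])
    m <- as.matrix(read_tsv(path))
    if (!identical(colnames(m), scheme$node_id))
      stop("scan ", dt$filename[r],
           " columns do not match network_map.tsv node ids")
    if (split) {
      full <- scan_timeseries(m, participant = dt$participant[r],
                              drug = dt$drug[r])
      hs <- split_halves(full)
      for (hf in c("first", "second")) {
        key <- paste(dt$participant[r], dt$drug[r], hf, sep = ".")
        scans[[key]] <- hs[[hf]]
        rows[[length(rows) + 1L]] <-
          data.frame(participant = dt$participant[r], drug = dt$drug[r],
                     half = hf, key = key, stringsAsFactors = FALSE)
      }
    } else {
      key <- paste(dt$participant[r], dt$drug[r], dt$half[r], sep = ".")
      scans[[key]] <- scan_timeseries(m, participant = dt$participant[r],
                                      drug = dt$drug[r], half = dt$half[r])
      rows[[length(rows) + 1L]] <-
        data.frame(participant = dt$participant[r], drug = dt$drug[r],
                   half = dt$half[r], key = key, stringsAsFactors = FALSE)
    }
  }
  structure(list(scans = scans, design_table = do.call(rbind, rows),
                 scheme = scheme,
                 params = list(timepoints_per_half = nrow(scans[[1]]))),
            class = "fc_study")
}

#' Write a connectivity matrix as a square TSV
#'
#' @param matrix A [connectivity_matrix()].
#' @param path Output file.
#' @return `path`, invisibly.
#' @export
write_matrix_tsv <- function(matrix, path) {
  df <- data.frame(node_id = rownames(matrix),
                   as.data.frame(unclass(matrix)), check.names = FALSE)
  write_tsv(df, path)
  invisible(path)
}

#' Read a square matrix TSV written by [write_matrix_tsv()]
#'
#' @param path Input file.
#' @param measure Measure label to attach.
#' @param participant,drug,half Metadata.
#' @return A [connectivity_matrix()].
#' @export
read_matrix_tsv <- function(path, measure, participant = NA_character_,
                            drug = NA_character_, half = NA_character_) {
  df <- read_tsv(path)
  m <- as.matrix(df[, -1, drop = FALSE])
  rownames(m) <- df[[1]]
  connectivity_matrix(m, measure, participant = participant, drug = drug,
                      half = half)
}

# long-format edge table for a list of connectivity matrices
edge_long_table <- function(matrices) {
  do.call(rbind, lapply(matrices, function(m) {
    ei <- edge_index(colnames(m))
    data.frame(participant = attr(m, "participant"),
               drug = attr(m, "drug"), half = attr(m, "half"),
               node_i = ei$node_i, node_j = ei$node_j,
               measure = fc_measure(m),
               value = upper_vec(unclass(m)),
               row.names = NULL, stringsAsFactors = FALSE)
  }))
}
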