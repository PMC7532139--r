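#' Node-to-network assignment scheme
#'
#' A network scheme maps each node (atlas region) to one of K functional
#' networks. With K networks there are K within-network edge sets and
#' K(K-1)/2 between-network pairs, giving K + K(K-1)/2 "interactions"
#' (36 for the default 8-network scheme).
#'
#' @param node_ids Character vector of node identifiers (unique).
#' @param networks Character vector, same length, the network label of each
#'   node. The order of first appearance fixes the network ordering unless
#'   `levels` is given.
#' @param levels Optional character vector fixing the network order.
#'
#' @return An object of class `network_scheme`: a data.frame with columns
#'   `node_id` and `network` (factor), plus attribute `networks` (ordered
#'   labels).
#' @examples
#' sch <- network_scheme(paste0("n", 1:6), rep(c("A", "B"), each = 3))
#' network_pairs(sch)
#' @export
network_scheme <- function(node_ids, networks, levels = NULL) {
  node_ids <- as.character(node_ids)
  networks <- as.character(networks)
  if (length(node_ids) != length(networks))
    stop("node_ids and networks must have the same length")
  if (anyDuplicated(node_ids))
    stop("duplicated node ids in scheme")
  if (anyNA(networks) || any(networks == ""))
    stop("every node must be mapped to a network")
  if (is.null(levels)) levels <- unique(networks)
  if (!all(networks %in% levels))
    stop("network labels outside the supplied levels")
  empty <- setdiff(levels, networks)
  if (length(empty))
    stop("empty network(s): ", paste(empty, collapse = ", "))
  out <- data.frame(node_id = node_ids,
                    network = factor(networks, levels = levels),
                    stringsAsFactors = FALSE)
  structure(out, networks = levels,
            class = c("network_scheme", "data.frame"))
}

#' Default 8-network scheme
#'
#' Builds an equal-sized assignment of `n_nodes` nodes to the eight canonical
#' resting-state networks (medial frontal, frontoparietal, default mode,
#' subcortical-cerebellum, somatosensory-motor, medial visual, occipital
#' pole, lateral visual), in contiguous blocks.
#'
#' @param n_nodes Number of nodes; must be divisible by the number of
#'   networks.
#' @param networks Network labels, default the 8 canonical abbreviations.
#' @return A [network_scheme()].
#' @export
default_scheme <- function(n_nodes = 40,
                           networks = c("MF", "FP", "DM", "SubC",
                                        "SM", "MedV", "OccP", "LatV")) {
  k <- length(networks)
  if (n_nodes %% k != 0)
    stop("n_nodes must be divisible by ", k)
  network_scheme(sprintf("N%03d", seq_len(n_nodes)),
                 rep(networks, each = n_nodes / k),
                 levels = networks)
}

#' @export
print.network_scheme <- function(x, ...) {
  nets <- attr(x, "networks")
  cat("<network_scheme> ", nrow(x), " nodes in ", length(nets),
      " networks: ", paste(nets, collapse = ", "), "\n", sep = "")
  invisible(x)
}

scheme_networks <- function(scheme) attr(scheme, "networks")

#' Between-network pairs of a scheme
#'
#' @param scheme A [network_scheme()].
#' @return A data.frame with columns `net_a`, `net_b` (one row per unordered
#'   pair, in canonical order) — 28 rows for 8 networks.
#' @export
network_pairs <- function(scheme) {
  nets <- scheme_networks(scheme)
  if (length(nets) < 2)
    return(data.frame(net_a = character(0), net_b = character(0),
                      stringsAsFactors = FALSE))
  cmb <- utils::combn(nets, 2)
  data.frame(net_a = cmb[1, ], net_b = cmb[2, ], stringsAsFactors = FALSE)
}

#' Interaction labels of a scheme
#'
#' The K within-network plus K(K-1)/2 between-network interaction labels,
#' e.g. `within:DM`, `between:DM:FP`.
#'
#' @param scheme A [network_scheme()].
#' @return Character vector (length 36 for the default scheme).
#' @export
interaction_labels <- function(scheme) {
  nets <- scheme_networks(scheme)
  pr <- network_pairs(scheme)
  between <- if (nrow(pr)) paste0("between:", pr$net_a, ":", pr$net_b)
             else character(0)
  c(paste0("within:", nets), between)
}

# Canonical edge enumeration: column-major upper triangle, i < j, matching
# m[upper.tri(m)].
edge_index <- function(node_ids) {
  n <- length(node_ids)
  idx <- which(upper.tri(diag(n)), arr.ind = TRUE)
  data.frame(i = idx[, 1], j = idx[, 2],
             node_i = node_ids[idx[, 1]], node_j = node_ids[idx[, 2]],
             stringsAsFactors = FALSE)
}

edge_names <- function(node_ids) {
  ei <- edge_index(node_ids)
  paste(ei$node_i, ei$node_j, sep = "|")
}

# upper-triangle vectorisation of a square matrix, canonical edge order
upper_vec <- function(m) {
  v <- m[upper.tri(m)]
  if (!is.null(colnames(m))) names(v) <- edge_names(colnames(m))
  v
}

# inverse of upper_vec: build a symmetric matrix from an edge vector
edge_vec_to_matrix <- function(v, node_ids, diag_value = NA_real_) {
  n <- length(node_ids)
  m <- matrix(diag_value, n, n, dimnames = list(node_ids, node_ids))
  m[upper.tri(m)] <- v
  m[lower.tri(m)] <- t(m)[lower.tri(m)]
  m
}

# per-edge interaction label (within:X or between:A:B) for the canonical
# edge order of node_ids under scheme
edge_interactions <- function(scheme, node_ids = scheme$node_id) {
  map <- stats::setNames(as.character(scheme$network), scheme$node_id)
  if (!all(node_ids %in% names(map)))
    stop("nodes missing from scheme: ",
         paste(utils::head(setdiff(node_ids, names(map)), 5), collapse = ", "))
  ei <- edge_index(node_ids)
  a <- map[ei$node_i]; b <- map[ei$node_j]
  nets <- scheme_networks(scheme)
  ia <- match(a, nets); ib <- match(b, nets)
  lo <- pmin(ia, ib); hi <- pmax(ia, ib)
  ifelse(lo == hi, paste0("within:", nets[lo]),
         paste0("between:", nets[lo], ":", nets[hi]))
}
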