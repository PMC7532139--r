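#' Build a block-structured network correlation matrix
#'
#' Constructs an N x N correlation matrix whose entries are constant within
#' each (network_i, network_j) block: `within_rho` on within-network
#' off-diagonals and `between_rho` on between-network entries. Block-filled
#' matrices are frequently slightly indefinite, so the result is repaired to
#' the nearest positive semi-definite matrix by eigenvalue clipping and
#' re-normalised to unit diagonal.
#'
#' @param scheme A [network_scheme()].
#' @param within_rho Single value or named vector (one per network) of
#'   within-network correlations, each in (-1, 1).
#' @param between_rho Single value, named vector (names `"A:B"` in canonical
#'   pair order), or K x K matrix of between-network correlations.
#' @param max_repair_dev Maximum tolerated absolute deviation between a
#'   requested block value and its post-repair block mean before the request
#'   is declared contradictory (default 0.1).
#'
#' @return Symmetric unit-diagonal positive semi-definite matrix with node
#'   ids as dimnames.
#' @examples
#' sch <- default_scheme(16, networks = c("A", "B", "C", "D"))
#' C <- make_network_covariance(sch, within_rho = 0.5, between_rho = 0.1)
#' @export
make_network_covariance <- function(scheme, within_rho, between_rho,
                                    max_repair_dev = 0.1) {
  nets <- scheme_networks(scheme)
  k <- length(nets)
  within_rho <- expand_named(within_rho, nets, "within_rho")
  B <- between_matrix(between_rho, nets)
  if (any(abs(within_rho) >= 1) || any(abs(B[upper.tri(B)]) >= 1))
    stop("all rho values must lie strictly inside (-1, 1)")
  diag(B) <- within_rho
  g <- match(as.character(scheme$network), nets)
  target <- B[g, g, drop = FALSE]
  diag(target) <- 1
  dimnames(target) <- list(scheme$node_id, scheme$node_id)
  out <- psd_repair(target)
  # verify the repair did not meaningfully move any requested block
  lab <- edge_interactions(scheme)
  dev <- abs(upper_vec(out) - upper_vec(target))
  bad <- unique(lab[dev > max_repair_dev])
  if (length(bad))
    stop("requested block correlations are contradictory (not jointly PSD); ",
         "offending blocks: ", paste(bad, collapse = ", "))
  out
}

expand_named <- function(x, nms, what) {
  if (length(x) == 1L && is.null(names(x)))
    return(stats::setNames(rep(as.numeric(x), length(nms)), nms))
  if (is.null(names(x)) && length(x) == length(nms))
    return(stats::setNames(as.numeric(x), nms))
  if (!all(nms %in% names(x)))
    stop(what, " must name every network")
  stats::setNames(as.numeric(x[nms]), nms)
}

between_matrix <- function(between_rho, nets) {
  k <- length(nets)
  B <- matrix(0, k, k, dimnames = list(nets, nets))
  if (is.matrix(between_rho)) {
    stopifnot(all(dim(between_rho) == k))
    B[] <- as.numeric(between_rho)
    B[lower.tri(B)] <- t(B)[lower.tri(B)]
    return(B)
  }
  if (length(between_rho) == 1L && is.null(names(between_rho))) {
    B[] <- as.numeric(between_rho)
    return(B)
  }
  cmb <- utils::combn(nets, 2)
  keys <- paste(cmb[1, ], cmb[2, ], sep = ":")
  if (!all(keys %in% names(between_rho)))
    stop("between_rho must name every network pair as 'A:B'")
  for (m in seq_along(keys)) {
    B[cmb[1, m], cmb[2, m]] <- B[cmb[2, m], cmb[1, m]] <-
      as.numeric(between_rho[[keys[m]]])
  }
  B
}

#' Repair a symmetric matrix to positive semi-definiteness
#'
#' Clips eigenvalues below `eps` up to `eps`, reconstructs, and re-normalises
#' to unit diagonal (so the result remains a correlation matrix).
#'
#' @param m Symmetric matrix.
#' @param eps Eigenvalue floor (default 1e-8).
#' @return Symmetric unit-diagonal PSD matrix.
#' @export
psd_repair <- function(m, eps = 1e-8) {
  e <- eigen(m, symmetric = TRUE)
  if (min(e$values) >= eps) return(m)
  v <- pmax(e$values, eps)
  out <- e$vectors %*% (v * t(e$vectors))
  d <- sqrt(diag(out))
  out <- out / tcrossprod(d)
  diag(out) <- 1
  out <- (out + t(out)) / 2
  dimnames(out) <- dimnames(m)
  out
}

#' Simulate one scan of autocorrelated multivariate timeseries
#'
#' Draws a T x N matrix of BOLD-like timeseries: correlated Gaussian
#' innovations (target correlation `corr`, or per-regime targets) passed
#' through a node-wise AR(1) filter with coefficient `ar`. Because every
#' node shares the same AR coefficient, the stationary cross-correlation of
#' the output equals the innovation correlation, so the sample correlation
#' converges to the target as T grows.
#'
#' @param corr Target N x N correlation matrix (symmetric, unit diagonal,
#'   PSD). Ignored when `regimes` is given.
#' @param n_time Number of timepoints T (>= 30).
#' @param ar Lag-1 autocorrelation phi in `[0, 0.95]` (default 0.4).
#' @param noise_sd Innovation standard deviation (default 1).
#' @param seed Optional integer seed; identical inputs give bit-identical
#'   output. The caller's RNG state is restored on exit.
#' @param regimes Optional list of `list(start, end, corr)` blocks whose
#'   intervals partition `1:n_time`; data within each block follow that
#'   block's correlation.
#' @param node_ids Node labels for the columns (default `N001...`).
#' @param participant,drug,half Optional metadata attached to the scan.
#'
#' @return A `scan_timeseries`: T x N numeric matrix with metadata
#'   attributes.
#' @export
simulate_scan <- function(corr, n_time, ar = 0.4, noise_sd = 1, seed = NULL,
                          regimes = NULL, node_ids = NULL,
                          participant = NA_character_, drug = NA_character_,
                          half = NA_character_) {
  if (n_time < 30)
    stop("n_time must be at least 30 for downstream DCC estimation")
  if (ar < 0 || ar > 0.95) stop("ar must lie in [0, 0.95]")
  if (is.null(regimes)) regimes <- list(list(start = 1, end = n_time, corr = corr))
  check_regimes(regimes, n_time)
  n <- ncol(regimes[[1]]$corr)
  if (is.null(node_ids)) {
    node_ids <- colnames(regimes[[1]]$corr)
    if (is.null(node_ids)) node_ids <- sprintf("N%03d", seq_len(n))
  }
  if (!is.null(seed)) {
    if (exists(".Random.seed", envir = .GlobalEnv, inherits = FALSE)) {
      old <- get(".Random.seed", envir = .GlobalEnv)
      on.exit(assign(".Random.seed", old, envir = .GlobalEnv), add = TRUE)
    }
    set.seed(as.integer(seed))
  }
  eps <- matrix(NA_real_, n_time, n)
  for (rg in regimes) {
    C <- rg$corr
    ev <- min(eigen(C, symmetric = TRUE, only.values = TRUE)$values)
    if (ev < -1e-10)
      stop("target correlation matrix is not PSD; repair it upstream ",
           "(min eigenvalue ", signif(ev, 3), ")")
    R <- chol(C + diag(1e-10, n))
    len <- rg$end - rg$start + 1
    eps[rg$start:rg$end, ] <- (matrix(stats::rnorm(len * n), len, n) %*% R) *
      noise_sd
  }
  if (ar > 0) {
    # stationary start: x_1 has the full stationary variance
    x <- eps
    x[1, ] <- eps[1, ] / sqrt(1 - ar^2)
    for (k in seq_len(n)) {
      x[, k] <- stats::filter(c(x[1, k], eps[-1, k]), ar,
                              method = "recursive",
                              init = 0)
    }
    # filter above adds ar * 0 to row 1, so row 1 is the stationary draw
    eps <- x
  }
  scan_timeseries(eps, node_ids, participant = participant, drug = drug,
                  half = half)
}

check_regimes <- function(regimes, n_time) {
  ends <- 0L
  for (rg in regimes) {
    if (rg$start != ends + 1L)
      stop("regime intervals must partition 1:n_time without gaps")
    if (rg$end < rg$start) stop("regime with end < start")
    ends <- rg$end
  }
  if (ends != n_time)
    stop("regime intervals must end at n_time (", n_time, ")")
  invisible(TRUE)
}

#' Study design for a 2 x 2 within-subject simulation
#'
#' Describes a placebo-controlled within-subject design: each participant
#' contributes exactly four cells (2 drug conditions x 2 scan halves).
#'
#' @param n_participants Number of participants (default 12) or a character
#'   vector of identifiers.
#' @param n_nodes Number of nodes (default 40).
#' @param timepoints_per_half Timepoints per scan half T (default 400,
#'   minimum 30).
#' @param scheme A [network_scheme()]; default [default_scheme()] with
#'   `n_nodes` nodes in 8 networks.
#' @param seed Integer seed for [simulate_study()].
#' @return An object of class `study_design`.
#' @export
study_design <- function(n_participants = 12, n_nodes = 40,
                         timepoints_per_half = 400,
                         scheme = default_scheme(n_nodes), seed = 1L) {
  participants <- if (is.character(n_participants)) n_participants
                  else sprintf("P%02d", seq_len(n_participants))
  if (timepoints_per_half < 30)
    stop("timepoints_per_half must be at least 30 (DCC estimation)")
  if (nrow(scheme) != n_nodes && !is.character(n_participants))
    n_nodes <- nrow(scheme)
  cells <- expand.grid(half = c("first", "second"),
                       drug = c("placebo", "drug"),
                       stringsAsFactors = FALSE)[, c("drug", "half")]
  structure(list(participants = participants,
                 cells = cells,
                 timepoints_per_half = as.integer(timepoints_per_half),
                 n_nodes = nrow(scheme),
                 scheme = scheme,
                 seed = as.integer(seed)),
            class = "study_design")
}

#' @export
print.study_design <- function(x, ...) {
  cat("<study_design> ", length(x$participants), " participants x 4 cells, ",
      x$n_nodes, " nodes, T = ", x$timepoints_per_half, " per half\n", sep = "")
  invisible(x)
}

#' Specify a condition effect on network correlations
#'
#' Declares an additive shift, on the Fisher-z scale, of the within-network
#' (or between-network-pair) correlations of the named networks in one
#' design cell. Used by [simulate_study()] to inject known drug effects.
#'
#' @param networks Networks affected; for `scope = "between"` a data.frame
#'   with columns `net_a`, `net_b` or a character vector `"A:B"`.
#' @param delta_z Shift applied to atanh(rho) (e.g. -0.10 lowers the
#'   correlation).
#' @param drug,half The design cell affected.
#' @param scope `"within"` or `"between"`.
#' @return A data.frame of effect rows; rows from several calls can be
#'   `rbind`-ed.
#' @export
condition_effect <- function(networks, delta_z, drug = "drug",
                             half = "first", scope = c("within", "between")) {
  scope <- match.arg(scope)
  if (scope == "within") {
    data.frame(scope = scope, net_a = networks, net_b = NA_character_,
               drug = drug, half = half, delta_z = delta_z,
               stringsAsFactors = FALSE)
  } else {
    if (is.character(networks)) {
      parts <- strsplit(networks, ":", fixed = TRUE)
      networks <- data.frame(net_a = vapply(parts, `[`, "", 1),
                             net_b = vapply(parts, `[`, "", 2))
    }
    data.frame(scope = scope, net_a = networks$net_a, net_b = networks$net_b,
               drug = drug, half = half, delta_z = delta_z,
               stringsAsFactors = FALSE)
  }
}

#' Specify time-varying correlation regimes for selected cells
#'
#' In the named cells, the correlation matrix alternates every `period`
#' timepoints between two states with all off-diagonal correlations shifted
#' by +/- `amplitude` on the Fisher-z scale, producing genuinely time-varying
#' connectivity that dynamic (variance) measures should detect.
#'
#' @param cells Cell labels affected, e.g. `"drug.first"` (see
#'   [cell_levels()]).
#' @param period Regime length in timepoints (default 50).
#' @param amplitude Alternating shift on atanh(rho) (default 0.3).
#' @return A list consumed by [simulate_study()].
#' @export
regime_spec <- function(cells, period = 50, amplitude = 0.3) {
  stopifnot(all(cells %in% CELL_LEVELS), period >= 10, amplitude >= 0)
  list(cells = cells, period = as.integer(period), amplitude = amplitude)
}

#' Simulate a complete 2 x 2 within-subject connectivity study
#'
#' Generates four scans (2 drug conditions x 2 scan halves) for every
#' participant, with block (network) covariance structure, node-wise AR(1)
#' temporal autocorrelation, participant-level random effects (a small
#' uniform jitter on the block correlations, shared across that
#' participant's cells so paired contrasts are unbiased), optional injected
#' condition effects, and optional time-varying correlation regimes.
#'
#' @param design A [study_design()].
#' @param effect Optional effect table from [condition_effect()]; `NULL`
#'   simulates a null study in which all four cells share the same truth.
#' @param regime Optional [regime_spec()].
#' @param within_rho,between_rho Baseline block correlations (defaults 0.40
#'   within-network, 0.10 between-network).
#' @param ar AR(1) coefficient (default 0.4).
#' @param noise_sd Innovation standard deviation (default 1).
#' @param participant_jitter Half-width of the uniform jitter on block rho
#'   (default 0.05), clipped so correlations stay inside (-0.95, 0.95).
#' @param seed Integer seed (default taken from the design). Participants
#'   use deterministic substreams derived from it.
#'
#' @return An `fc_study`: list with `scans` (named list of
#'   `scan_timeseries`, keys `participant.drug.half`), `design_table`
#'   (participant, drug, half, key), `scheme`, and `params`.
#' @examples
#' des <- study_design(n_participants = 3, n_nodes = 8,
#'                     timepoints_per_half = 60,
#'                     scheme = default_scheme(8, networks = c("A", "B")))
#' st <- simulate_study(des, seed = 7)
#' length(st$scans)  # 12
#' @export
simulate_study <- function(design, effect = NULL, regime = NULL,
                           within_rho = 0.40, between_rho = 0.10,
                           ar = 0.4, noise_sd = 1,
                           participant_jitter = 0.05, seed = design$seed) {
  stopifnot(inherits(design, "study_design"))
  scheme <- design$scheme
  nets <- scheme_networks(scheme)
  pr <- network_pairs(scheme)
  if (!is.null(effect)) {
    bad <- setdiff(c(effect$net_a, stats::na.omit(effect$net_b)), nets)
    if (length(bad))
      stop("effect names networks absent from the scheme: ",
           paste(bad, collapse = ", "))
  }
  w0 <- expand_named(within_rho, nets, "within_rho")
  b0 <- between_matrix(between_rho, nets)
  n_t <- design$timepoints_per_half
  scans <- list()
  rows <- list()
  for (p_idx in seq_along(design$participants)) {
    pid <- design$participants[p_idx]
    jit <- participant_block_jitter(seed, p_idx, nets, pr, participant_jitter)
    for (c_idx in seq_len(nrow(design$cells))) {
      drug <- design$cells$drug[c_idx]
      half <- design$cells$half[c_idx]
      cellkey <- cell_label(drug, half)
      wb <- apply_cell_effect(w0, b0, effect, drug, half, nets, pr)
      w <- clip_rho(wb$w + jit$w)
      b <- clip_rho(wb$b + jit$b)
      regimes <- NULL
      if (!is.null(regime) && cellkey %in% regime$cells) {
        regimes <- build_regimes(scheme, w, b, n_t, regime)
      }
      corr <- make_network_covariance(scheme, w, rho_mat_to_named(b, pr))
      scan_seed <- substream_seed(seed, p_idx, c_idx)
      scans[[paste(pid, cellkey, sep = ".")]] <-
        simulate_scan(corr, n_t, ar = ar, noise_sd = noise_sd,
                      seed = scan_seed, regimes = regimes,
                      node_ids = scheme$node_id,
                      participant = pid, drug = drug, half = half)
      rows[[length(rows) + 1L]] <-
        data.frame(participant = pid, drug = drug, half = half,
                   key = paste(pid, cellkey, sep = "."),
                   stringsAsFactors = FALSE)
    }
  }
  structure(list(scans = scans,
                 design_table = do.call(rbind, rows),
                 scheme = scheme,
                 params = list(within_rho = w0, between_rho = b0, ar = ar,
                               noise_sd = noise_sd,
                               participant_jitter = participant_jitter,
                               timepoints_per_half = n_t, seed = seed)),
            class = "fc_study")
}

#' @export
print.fc_study <- function(x, ...) {
  cat("<fc_study> ", length(x$scans), " scans (",
      length(unique(x$design_table$participant)), " participants x 4 cells), ",
      nrow(x$scheme), " nodes, T = ", x$params$timepoints_per_half,
      " per half\n", sep = "")
  invisible(x)
}

substream_seed <- function(seed, p_idx, c_idx) {
  as.integer((as.numeric(seed) + 7919 * p_idx + 104729 * c_idx) %% 2147483647)
}

participant_block_jitter <- function(seed, p_idx, nets, pr, width) {
  if (exists(".Random.seed", envir = .GlobalEnv, inherits = FALSE)) {
    old <- get(".Random.seed", envir = .GlobalEnv)
    on.exit(assign(".Random.seed", old, envir = .GlobalEnv), add = TRUE)
  }
  set.seed(substream_seed(seed, p_idx, 0L))
  w <- stats::setNames(stats::runif(length(nets), -width, width), nets)
  k <- length(nets)
  b <- matrix(0, k, k, dimnames = list(nets, nets))
  for (m in seq_len(nrow(pr))) {
    v <- stats::runif(1, -width, width)
    b[pr$net_a[m], pr$net_b[m]] <- b[pr$net_b[m], pr$net_a[m]] <- v
  }
  list(w = w, b = b)
}

apply_cell_effect <- function(w0, b0, effect, drug, half, nets, pr) {
  w <- w0; b <- b0
  if (!is.null(effect)) {
    sel <- effect$drug == drug & effect$half == half
    for (r in which(sel)) {
      if (effect$scope[r] == "within") {
        nm <- effect$net_a[r]
        w[nm] <- tanh(atanh(w[nm]) + effect$delta_z[r])
      } else {
        a <- effect$net_a[r]; bn <- effect$net_b[r]
        b[a, bn] <- b[bn, a] <- tanh(atanh(b[a, bn]) + effect$delta_z[r])
      }
    }
  }
  list(w = w, b = b)
}

clip_rho <- function(x, lim = 0.95) pmin(pmax(x, -lim), lim)

rho_mat_to_named <- function(b, pr) {
  stats::setNames(b[cbind(pr$net_a, pr$net_b)],
                  paste(pr$net_a, pr$net_b, sep = ":"))
}

build_regimes <- function(scheme, w, b, n_t, regime) {
  pr <- network_pairs(scheme)
  shift <- function(x, dz) tanh(atanh(clip_rho(x)) + dz)
  corr_hi <- make_network_covariance(scheme, shift(w, regime$amplitude),
                                     rho_mat_to_named(shift(b, regime$amplitude), pr))
  corr_lo <- make_network_covariance(scheme, shift(w, -regime$amplitude),
                                     rho_mat_to_named(shift(b, -regime$amplitude), pr))
  starts <- seq(1L, n_t, by = regime$period)
  lapply(seq_along(starts), function(i) {
    list(start = starts[i], end = min(starts[i] + regime$period - 1L, n_t),
         corr = if (i %% 2 == 1) corr_hi else corr_lo)
  })
}
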