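#' Aggregate a connectivity matrix to network interactions
#'
#' Averages all within-network edges for each network and all
#' between-network edges for each network pair, giving K + K(K-1)/2
#' interaction values (36 for the default 8-network scheme). Static
#' connectivity must be supplied on the Fisher-z scale (`sfc_z`); pass the
#' matrix through [fisher_z()] first.
#'
#' @param matrix A [connectivity_matrix()] (measure `sfc_z`, `dfc_var` or
#'   `efc_H`).
#' @param scheme A [network_scheme()] covering the matrix's nodes.
#' @return Data.frame with one row per interaction: `interaction`, `type`
#'   (within/between), `value` (mean over the edge set, missing edges
#'   excluded), `n_edges`, `n_missing`, plus the matrix's metadata columns.
#' @export
aggregate_networks <- function(matrix, scheme) {
  stopifnot(inherits(matrix, "connectivity_matrix"))
  if (fc_measure(matrix) == "sfc_r")
    stop("static connectivity must be aggregated on the Fisher-z scale; ",
         "apply fisher_z() first")
  node_ids <- colnames(matrix)
  counts <- table(scheme$network[match(node_ids, scheme$node_id)])
  single <- names(counts)[counts < 2]
  if (length(single))
    stop("network(s) with a single node have no within-network edges: ",
         paste(single, collapse = ", "))
  lab <- edge_interactions(scheme, node_ids)
  v <- upper_vec(unclass(matrix))
  labs <- interaction_labels(scheme)
  agg_mean <- vapply(labs, function(L) mean(v[lab == L], na.rm = TRUE),
                     numeric(1))
  n_edges <- vapply(labs, function(L) sum(lab == L), numeric(1))
  n_missing <- vapply(labs, function(L) sum(is.na(v[lab == L])), numeric(1))
  data.frame(interaction = labs,
             type = ifelse(startsWith(labs, "within"), "within", "between"),
             value = agg_mean, n_edges = n_edges, n_missing = n_missing,
             measure = fc_measure(matrix),
             participant = attr(matrix, "participant"),
             drug = attr(matrix, "drug"), half = attr(matrix, "half"),
             row.names = NULL, stringsAsFactors = FALSE)
}

#' Network summary over a set of connectivity matrices
#'
#' Convenience wrapper applying [aggregate_networks()] to every matrix in a
#' list and binding the rows (one row per matrix x interaction).
#'
#' @param matrices List of [connectivity_matrix()] objects.
#' @param scheme A [network_scheme()].
#' @return Long data.frame (see [aggregate_networks()]).
#' @export
network_summary <- function(matrices, scheme) {
  do.call(rbind, lapply(matrices, aggregate_networks, scheme = scheme))
}

#' 2 x 2 repeated-measures ANOVA (drug by time)
#'
#' Within-subjects ANOVA for a 2 x 2 design with one observation per cell
#' per participant. Each effect is tested through its per-participant
#' contrast score (e.g. the interaction score
#' `(drug.first - drug.second) - (placebo.first - placebo.second)`) with a
#' paired t-test against zero, reported as `F = t^2` on (1, n-1) degrees of
#' freedom — the standard equivalence for single-df within-subject effects.
#' Partial eta squared is `F / (F + df_error)`.
#'
#' @param values Data.frame with columns `participant`, `drug`
#'   (placebo/drug), `half` (first/second), `value`, complete cells,
#'   >= 3 participants.
#' @return Data.frame with one row per effect (`drug`, `time`,
#'   `interaction`): `F`, `df1`, `df2`, `p`, `pes` (partial eta squared).
#' @examples
#' d <- expand.grid(participant = paste0("P", 1:6),
#'                  drug = c("placebo", "drug"),
#'                  half = c("first", "second"))
#' d$value <- rnorm(nrow(d))
#' rm_anova_2x2(d)
#' @export
rm_anova_2x2 <- function(values) {
  cells <- cell_matrix(values)
  n <- nrow(cells)
  if (n < 3) stop("at least 3 participants required")
  scores <- cbind(
    drug = (cells[, "drug.first"] + cells[, "drug.second"]) / 2 -
           (cells[, "placebo.first"] + cells[, "placebo.second"]) / 2,
    time = (cells[, "placebo.first"] + cells[, "drug.first"]) / 2 -
           (cells[, "placebo.second"] + cells[, "drug.second"]) / 2,
    interaction = (cells[, "drug.first"] - cells[, "drug.second"]) -
                  (cells[, "placebo.first"] - cells[, "placebo.second"]))
  out <- lapply(colnames(scores), function(eff) {
    s <- scores[, eff]
    if (stats::sd(s) == 0 && mean(s) == 0) {
      Fv <- 0
    } else if (stats::sd(s) == 0) {
      stop("zero-variance contrast for effect '", eff, "'")
    } else {
      Fv <- (mean(s) / (stats::sd(s) / sqrt(n)))^2
    }
    data.frame(effect = eff, F = Fv, df1 = 1, df2 = n - 1,
               p = stats::pf(Fv, 1, n - 1, lower.tail = FALSE),
               pes = Fv / (Fv + (n - 1)),
               stringsAsFactors = FALSE)
  })
  do.call(rbind, out)
}

cell_matrix <- function(values) {
  stopifnot(all(c("participant", "drug", "half", "value") %in% names(values)))
  key <- cell_label(values$drug, values$half)
  if (!all(key %in% CELL_LEVELS))
    stop("drug must be placebo/drug and half first/second")
  wide <- stats::reshape(
    data.frame(participant = values$participant, key = key,
               value = values$value, stringsAsFactors = FALSE),
    idvar = "participant", timevar = "key", direction = "wide")
  m <- as.matrix(wide[, paste0("value.", CELL_LEVELS), drop = FALSE])
  colnames(m) <- CELL_LEVELS
  rownames(m) <- wide$participant
  if (anyNA(m)) stop("incomplete cells: every participant needs all 4 cells")
  m
}

#' Paired contrast with Cohen's d
#'
#' Paired t-test between two per-participant vectors, with the
#' within-subject effect size `d = mean(diff) / sd(diff)` and the 95%
#' confidence interval of the mean difference.
#'
#' @param values_a,values_b Numeric vectors of equal length >= 3, paired by
#'   participant.
#' @return Data.frame: `mean_diff`, `t`, `df`, `p` (two-sided), `d`,
#'   `ci_lo`, `ci_hi`.
#' @examples
#' paired_contrast(c(2, 3, 4, 5), c(1, 1, 1, 1))  # t = 3.873, d = 1.936
#' @export
paired_contrast <- function(values_a, values_b) {
  if (length(values_a) != length(values_b)) stop("unequal lengths")
  n <- length(values_a)
  if (n < 3) stop("at least 3 pairs required")
  d <- values_a - values_b
  sdd <- stats::sd(d)
  if (sdd == 0) {
    if (mean(d) != 0) stop("zero-variance differences")
    # identical inputs: a zero effect, not a degenerate one
    return(data.frame(mean_diff = 0, t = 0, df = n - 1, p = 1, d = 0,
                      ci_lo = 0, ci_hi = 0))
  }
  tv <- mean(d) / (sdd / sqrt(n))
  half <- stats::qt(0.975, n - 1) * sdd / sqrt(n)
  data.frame(mean_diff = mean(d), t = tv, df = n - 1,
             p = 2 * stats::pt(-abs(tv), n - 1), d = mean(d) / sdd,
             ci_lo = mean(d) - half, ci_hi = mean(d) + half)
}

#' Holm-Bonferroni step-down correction
#'
#' @param pvals Numeric p-values in `[0, 1]`.
#' @param alpha Family-wise error rate (default 0.05).
#' @return Data.frame: `p`, `p_holm` (adjusted, monotone in rank),
#'   `reject`.
#' @export
holm_bonferroni <- function(pvals, alpha = 0.05) {
  if (any(pvals < 0 | pvals > 1, na.rm = TRUE))
    stop("p-values must lie in [0, 1]")
  adj <- stats::p.adjust(pvals, method = "holm")
  data.frame(p = pvals, p_holm = adj, reject = adj <= alpha)
}

#' Two-stage edge-wise thresholding and drug contrast
#'
#' Stage 1: within each of the four design cells, a one-sample t-test of
#' each edge's Fisher-z value against zero across participants; edges with
#' `p < alpha / E` (Bonferroni over all E edges) in any cell are kept.
#' Stage 2: on the union of surviving edges, paired t-tests between drug
#' conditions (drug vs placebo, separately per scan half) at uncorrected
#' `alpha`.
#'
#' @param z_cells Named list with elements `placebo.first`,
#'   `placebo.second`, `drug.first`, `drug.second`; each a participants x
#'   edges matrix of Fisher-z values (same column order, >= 3 rows).
#' @param alpha Significance level (default 0.05).
#' @return List: `bonferroni_p` (the per-edge stage-1 threshold
#'   `alpha / E`), `stage1` (per-cell logical survival matrix and `union`
#'   edge names), `stage2` (per-half data.frame of surviving edges with
#'   `t`, `p`, `direction`).
#' @export
edge_threshold_contrast <- function(z_cells, alpha = 0.05) {
  stopifnot(all(CELL_LEVELS %in% names(z_cells)))
  z_cells <- z_cells[CELL_LEVELS]
  E <- ncol(z_cells[[1]])
  n <- nrow(z_cells[[1]])
  if (n < 3) stop("at least 3 participants required")
  thr <- alpha / E
  p1 <- vapply(z_cells, function(m) col_t_onesample(m)$p,
               numeric(E))
  keep <- p1 < thr
  rownames(keep) <- colnames(z_cells[[1]])
  union_edges <- rownames(keep)[rowSums(keep) > 0]
  stage2 <- lapply(c("first", "second"), function(hf) {
    dm <- z_cells[[cell_label("drug", hf)]][, union_edges, drop = FALSE]
    pm <- z_cells[[cell_label("placebo", hf)]][, union_edges, drop = FALSE]
    tt <- col_t_onesample(dm - pm)
    sig <- which(tt$p < alpha)
    data.frame(edge = union_edges[sig], half = rep(hf, length(sig)),
               t = tt$t[sig], p = tt$p[sig],
               direction = ifelse(tt$t[sig] > 0, "drug>placebo",
                                  "drug<placebo"),
               row.names = NULL, stringsAsFactors = FALSE)
  })
  list(bonferroni_p = thr,
       stage1 = list(survived = keep, union = union_edges),
       stage2 = do.call(rbind, stage2))
}

# vectorised two-sided one-sample t-test over columns
col_t_onesample <- function(m) {
  n <- nrow(m)
  mu <- colMeans(m)
  s <- sqrt(colSums(sweep(m, 2, mu)^2) / (n - 1))
  tv <- mu / (s / sqrt(n))
  tv[s == 0 & mu == 0] <- 0
  p <- 2 * stats::pt(-abs(tv), n - 1)
  p[!is.finite(tv)] <- 0   # infinite t: identical nonzero values
  list(t = tv, p = p)
}

#' Area under a drug-strength rating curve
#'
#' Trapezoidal area of subjective drug-strength ratings (0-10 scale)
#' against time, restricted to `[first observed time, t_max]` minutes. No
#' point is extrapolated before the first rating; if ratings straddle
#' `t_max` the curve is linearly interpolated at `t_max`.
#'
#' @param times Rating times in minutes, strictly increasing.
#' @param ratings Ratings in `[0, 10]`, same length.
#' @param t_max Upper limit in minutes (default 20, the scan duration).
#' @return Area (rating x minutes).
#' @examples
#' auc_drug_strength(c(1:5, 10, 15, 20), rep(10, 8))  # 190
#' @export
auc_drug_strength <- function(times, ratings, t_max = 20) {
  stopifnot(length(times) == length(ratings))
  if (is.unsorted(times, strictly = TRUE)) stop("times must be strictly increasing")
  if (any(ratings < 0 | ratings > 10)) stop("ratings must lie in [0, 10]")
  keep <- times <= t_max
  if (sum(keep) < 2) stop("need at least 2 ratings at or before t_max")
  tt <- times[keep]; rr <- ratings[keep]
  if (any(!keep) && max(tt) < t_max) {
    nxt <- which(!keep)[1]
    rr <- c(rr, stats::approx(times[c(nxt - 1, nxt)],
                              ratings[c(nxt - 1, nxt)], xout = t_max)$y)
    tt <- c(tt, t_max)
  }
  pracma::trapz(tt, rr)
}

#' Correlate per-participant connectivity change with drug-strength AUC
#'
#' Pearson correlation (with two-sided p) between a per-participant
#' connectivity change score and the per-participant area under the
#' drug-strength curve.
#'
#' @param delta_conn,auc Numeric vectors of equal length >= 4.
#' @return Data.frame: `r`, `df`, `p`.
#' @export
change_vs_auc <- function(delta_conn, auc) {
  if (length(delta_conn) != length(auc)) stop("unequal lengths")
  if (length(auc) < 4) stop("at least 4 participants required")
  if (stats::sd(delta_conn) == 0 || stats::sd(auc) == 0)
    stop("zero variance in one of the inputs")
  ct <- stats::cor.test(delta_conn, auc, method = "pearson")
  data.frame(r = unname(ct$estimate), df = unname(ct$parameter),
             p = ct$p.value)
}
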