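#' Leave-two-participant-out folds
#'
#' Enumerates all unordered pairs of participants; each fold tests on one
#' pair and trains on the complement (66 folds for 12 participants).
#'
#' @param participants Character vector of >= 3 participant ids.
#' @return List of folds, each `list(train, test)` of participant ids.
#' @export
enumerate_folds <- function(participants) {
  participants <- as.character(participants)
  if (length(participants) < 3) stop("at least 3 participants required")
  cmb <- utils::combn(participants, 2, simplify = FALSE)
  lapply(cmb, function(pair)
    list(train = setdiff(participants, pair), test = pair))
}

#' Assemble connectome features from connectivity matrices
#'
#' Vectorises the upper triangle of one connectivity matrix per
#' (participant, design cell) into a feature matrix with one row per
#' observation, the input of [run_cv()]. Static connectivity should be
#' supplied on the Fisher-z scale. Edge columns that are missing (flagged)
#' in any matrix are dropped and counted.
#'
#' @param matrices List of [connectivity_matrix()] objects with complete
#'   participant/drug/half metadata; every participant must contribute all
#'   four cells.
#' @return A `connectome_features`: list with `x` (rows =
#'   participant x cell, columns = edges named `"node_i|node_j"`), `labels`
#'   (factor over [cell_levels()]), `participant`, `measure`,
#'   `n_dropped_edges`.
#' @export
connectome_features <- function(matrices) {
  stopifnot(length(matrices) > 0,
            all(vapply(matrices, inherits, TRUE, "connectivity_matrix")))
  measure <- unique(vapply(matrices, fc_measure, ""))
  if (length(measure) != 1)
    stop("all matrices must share one measure (got: ",
         paste(measure, collapse = ", "), ")")
  x <- t(vapply(matrices, function(m) upper_vec(unclass(m)),
                numeric(sum(upper.tri(matrices[[1]])))))
  colnames(x) <- edge_names(colnames(matrices[[1]]))
  participant <- vapply(matrices, function(m) attr(m, "participant"), "")
  cellkey <- vapply(matrices, function(m)
    cell_label(attr(m, "drug"), attr(m, "half")), "")
  if (!all(cellkey %in% CELL_LEVELS))
    stop("matrices carry unknown drug/half metadata")
  tab <- table(participant, cellkey)
  if (any(tab != 1) || ncol(tab) != 4)
    stop("every participant must contribute exactly one matrix per cell")
  rownames(x) <- paste(participant, cellkey, sep = ".")
  bad <- colSums(is.na(x)) > 0
  if (any(bad)) x <- x[, !bad, drop = FALSE]
  structure(list(x = x,
                 labels = factor(cellkey, levels = CELL_LEVELS),
                 participant = participant,
                 measure = measure,
                 n_dropped_edges = sum(bad)),
            class = "connectome_features")
}

#' @export
print.connectome_features <- function(x, ...) {
  cat("<connectome_features> ", nrow(x$x), " observations x ", ncol(x$x),
      " edges (", x$measure, ")",
      if (x$n_dropped_edges > 0)
        paste0(", ", x$n_dropped_edges, " edges dropped"),
      "\n", sep = "")
  invisible(x)
}

#' Restrict features to one network interaction
#'
#' Keeps only the edge columns whose two nodes fall within the given
#' network (`"within:DM"`) or across the given pair (`"between:DM:FP"`).
#'
#' @param features A [connectome_features()].
#' @param scheme A [network_scheme()].
#' @param interaction One label from [interaction_labels()].
#' @return A `connectome_features` with the restricted columns.
#' @export
mask_features <- function(features, scheme, interaction) {
  node_ids <- scheme$node_id
  lab <- edge_interactions(scheme, node_ids)
  names(lab) <- edge_names(node_ids)
  keep <- names(lab)[lab == interaction]
  keep <- intersect(keep, colnames(features$x))
  out <- features
  out$x <- features$x[, keep, drop = FALSE]
  out
}

#' Combine feature sets from several measures
#'
#' Column-concatenates feature matrices (same observations) after scaling
#' each measure's block to unit overall standard deviation, so that no
#' measure dominates by scale before the in-fold standardization.
#'
#' @param ... Two or more [connectome_features()] with identical rows.
#' @return A `connectome_features` with measure `"combined"`.
#' @export
combine_features <- function(...) {
  fl <- list(...)
  stopifnot(length(fl) >= 2)
  rn <- rownames(fl[[1]]$x)
  blocks <- lapply(fl, function(f) {
    stopifnot(identical(rownames(f$x), rn))
    b <- f$x / stats::sd(f$x)
    colnames(b) <- paste(f$measure, colnames(b), sep = ":")
    b
  })
  out <- fl[[1]]
  out$x <- do.call(cbind, blocks)
  out$measure <- "combined"
  out$n_dropped_edges <- sum(vapply(fl, `[[`, 0L, "n_dropped_edges"))
  out
}

#' Fit a PLS discriminant-analysis model
#'
#' PLS regression of the one-hot-encoded cell labels on the features,
#' standardized (mean 0, sd 1) using the training rows only. Zero-variance
#' training columns are dropped before fitting and recorded. The fit is
#' deterministic given the data.
#'
#' @param x Training feature matrix (rows = observations).
#' @param y Factor of cell labels.
#' @param ncomp Number of PLS components (default 3, fixed a priori; capped
#'   at `min(nrow - 1, ncol)`).
#' @return A `pls_da_model` wrapping the fitted model, the retained columns
#'   and the component count used.
#' @export
pls_da_fit <- function(x, y, ncomp = 3) {
  stopifnot(is.factor(y), nrow(x) == length(y))
  if (is.null(colnames(x))) colnames(x) <- paste0("f", seq_len(ncol(x)))
  sds <- apply(x, 2, stats::sd)
  dropped <- colnames(x)[sds == 0]
  keep <- colnames(x)[sds > 0]
  if (length(keep) < 1) stop("no non-degenerate features to train on")
  ncomp_used <- min(ncomp, nrow(x) - 1L, length(keep))
  fit <- mixOmics::plsda(x[, keep, drop = FALSE], y, ncomp = ncomp_used,
                         scale = TRUE)
  structure(list(fit = fit, keep = keep, dropped = dropped,
                 ncomp = ncomp_used, levels = levels(y)),
            class = "pls_da_model")
}

#' Predict design cells from a PLS-DA model
#'
#' Test rows are standardized with the training parameters; the predicted
#' label is the arg-max of the predicted one-hot responses at the model's
#' component count, with ties broken by the fixed order of
#' [cell_levels()].
#'
#' @param model A [pls_da_fit()] result.
#' @param newx Feature matrix with the training columns.
#' @return Factor of predicted labels.
#' @export
pls_da_predict <- function(model, newx) {
  stopifnot(inherits(model, "pls_da_model"))
  if (is.null(colnames(newx))) colnames(newx) <- paste0("f", seq_len(ncol(newx)))
  pr <- stats::predict(model$fit, newx[, model$keep, drop = FALSE])
  scores <- pr$predict[, , model$ncomp, drop = FALSE]
  dim(scores) <- dim(pr$predict)[1:2]
  colnames(scores) <- dimnames(pr$predict)[[2]]
  scores <- scores[, model$levels, drop = FALSE]
  argmax_labels(scores, model$levels)
}

# arg-max decision rule; which.max breaks ties by the first (fixed) label
argmax_labels <- function(scores, levels) {
  idx <- apply(scores, 1, which.max)
  factor(levels[idx], levels = levels)
}

#' Leave-two-participant-out cross-validated classification
#'
#' For every unordered pair of participants, trains a PLS-DA model on the
#' remaining participants' connectomes and classifies the held-out pair's
#' four cells each (8 test rows per fold). Predictions are pooled over all
#' folds into a 4 x 4 confusion matrix (chance level for the balanced
#' four-class problem is 25%).
#'
#' @param features A [connectome_features()] with complete cells.
#' @param ncomp PLS components (default 3).
#' @return A `classification_report`: list with `confusion` (counts, rows =
#'   true cell), `proportions` (row-normalised), `n_folds`, `accuracy`
#'   (overall, in 0-1), `predictions` (per-fold log), `measure`, `ncomp`.
#' @export
run_cv <- function(features, ncomp = 3) {
  stopifnot(inherits(features, "connectome_features"))
  participants <- unique(features$participant)
  folds <- enumerate_folds(participants)
  lev <- levels(features$labels)
  confusion <- matrix(0L, 4, 4, dimnames = list(true = lev, predicted = lev))
  logs <- vector("list", length(folds))
  for (k in seq_along(folds)) {
    tr <- features$participant %in% folds[[k]]$train
    te <- features$participant %in% folds[[k]]$test
    model <- pls_da_fit(features$x[tr, , drop = FALSE],
                        droplevels(features$labels[tr]), ncomp)
    # refit factor to the full level set for the confusion matrix
    pred <- factor(as.character(pls_da_predict(model,
                                               features$x[te, , drop = FALSE])),
                   levels = lev)
    truth <- features$labels[te]
    confusion <- confusion + unclass(table(truth, pred))
    logs[[k]] <- data.frame(fold = k,
                            participant = features$participant[te],
                            true = as.character(truth),
                            predicted = as.character(pred),
                            stringsAsFactors = FALSE)
  }
  structure(list(confusion = confusion,
                 proportions = confusion / rowSums(confusion),
                 n_folds = length(folds),
                 accuracy = sum(diag(confusion)) / sum(confusion),
                 predictions = do.call(rbind, logs),
                 measure = features$measure,
                 ncomp = ncomp),
            class = "classification_report")
}

#' @export
print.classification_report <- function(x, ...) {
  cat("<classification_report> ", x$measure, ", ", x$n_folds,
      " folds, accuracy ", sprintf("%.1f%%", 100 * x$accuracy),
      " (chance 25%)\n", sep = "")
  print(x$confusion)
  invisible(x)
}

#' Discrimination score (d-prime) for one design cell
#'
#' `d' = qnorm(hit) - qnorm(fa)` where the hit rate is the proportion of
#' the target cell's observations classified as the target and the
#' false-alarm rate the proportion of non-target observations classified
#' as the target, pooled over folds. Extreme rates are corrected before the
#' inverse-normal transform: 0 becomes `1/(2n)` and 1 becomes `1 - 1/(2n)`,
#' with n the count in the rate's denominator.
#'
#' @param report A [run_cv()] result.
#' @param target Target cell label (default `"drug.first"`, the
#'   peak-effect cell).
#' @return Data.frame: `target`, `hit`, `fa` (uncorrected rates),
#'   `d_prime`.
#' @export
d_prime <- function(report, target = "drug.first") {
  conf <- report$confusion
  stopifnot(target %in% rownames(conf))
  n_t <- sum(conf[target, ])
  n_nt <- sum(conf) - n_t
  hit <- conf[target, target] / n_t
  fa <- sum(conf[rownames(conf) != target, target]) / n_nt
  dp <- stats::qnorm(rate_correct(hit, n_t)) -
        stats::qnorm(rate_correct(fa, n_nt))
  data.frame(target = target, hit = hit, fa = fa, d_prime = dp,
             stringsAsFactors = FALSE)
}

rate_correct <- function(r, n) {
  if (r <= 0) return(1 / (2 * n))
  if (r >= 1) return(1 - 1 / (2 * n))
  r
}

#' Classification sweep over all network interactions
#'
#' Repeats the leave-two-participant-out classification with features
#' restricted to each of the K + K(K-1)/2 network interactions (36 for the
#' default scheme) and reports the discrimination of the target cell.
#' Below-chance discrimination is additionally reported floored at zero
#' (`d_prime_floored`) for display; raw values are retained.
#'
#' @param features A [connectome_features()] (whole-brain).
#' @param scheme A [network_scheme()].
#' @param ncomp PLS components (default 3).
#' @param target Target cell (default `"drug.first"`).
#' @return Data.frame with one row per interaction: `interaction`, `type`,
#'   `n_features`, `accuracy`, `hit`, `fa`, `d_prime`, `d_prime_floored`.
#'   Interactions with fewer than 2 usable features are skipped with a
#'   message.
#' @export
network_model_sweep <- function(features, scheme, ncomp = 3,
                                target = "drug.first") {
  labs <- interaction_labels(scheme)
  rows <- lapply(labs, function(L) {
    f <- mask_features(features, scheme, L)
    if (ncol(f$x) < 2) {
      message("network_model_sweep: skipping ", L, " (", ncol(f$x),
              " usable features)")
      return(NULL)
    }
    rep <- run_cv(f, ncomp)
    dp <- d_prime(rep, target)
    data.frame(interaction = L,
               type = if (startsWith(L, "within")) "within" else "between",
               n_features = ncol(f$x), accuracy = rep$accuracy,
               hit = dp$hit, fa = dp$fa, d_prime = dp$d_prime,
               d_prime_floored = max(dp$d_prime, 0),
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
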