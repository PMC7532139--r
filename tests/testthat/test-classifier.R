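test_that("leave-two-out folds enumerate all participant pairs", {
  p12 <- paste0("P", 1:12)
  folds <- enumerate_folds(p12)
  expect_length(folds, 66L)
  expect_length(enumerate_folds(paste0("P", 1:4)), 6L)
  for (n in c(4, 7, 12)) {
    ids <- paste0("P", seq_len(n))
    fl <- enumerate_folds(ids)
    expect_length(fl, choose(n, 2))
    appearances <- table(unlist(lapply(fl, `[[`, "test")))
    expect_true(all(appearances == n - 1))   # each id in n-1 test pairs
    expect_true(all(vapply(fl, function(f)
      length(intersect(f$train, f$test)) == 0, logical(1))))
  }
  expect_error(enumerate_folds(c("a", "b")), "at least 3")
})

# deterministic toy features: cell-specific mean shifts + small noise
separable_features <- function(n_participants = 6, n_feat = 12, shift = 5,
                               noise = 0.3, seed = 51) {
  set.seed(seed)
  cells <- cell_levels()
  centers <- matrix(rnorm(4 * n_feat, sd = shift), 4, n_feat,
                    dimnames = list(cells, NULL))
  rows <- list(); labels <- c(); part <- c()
  for (p in paste0("P", seq_len(n_participants))) {
    for (cl in cells) {
      rows[[length(rows) + 1]] <- centers[cl, ] + rnorm(n_feat, sd = noise)
      labels <- c(labels, cl); part <- c(part, p)
    }
  }
  x <- do.call(rbind, rows)
  colnames(x) <- paste0("f", seq_len(n_feat))
  rownames(x) <- paste(part, labels, sep = ".")
  structure(list(x = x, labels = factor(labels, levels = cells),
                 participant = part, measure = "sfc_z",
                 n_dropped_edges = 0L),
            class = "connectome_features")
}

test_that("PLS-DA separates cell-specific mean shifts perfectly", {
  f <- separable_features()
  model <- pls_da_fit(f$x, f$labels, ncomp = 3)
  expect_identical(as.character(pls_da_predict(model, f$x)),
                   as.character(f$labels))   # 100% training accuracy
  # a class centroid is classified as its class
  cen <- t(vapply(levels(f$labels), function(cl)
    colMeans(f$x[f$labels == cl, ]), numeric(ncol(f$x))))
  expect_identical(as.character(pls_da_predict(model, cen)),
                   levels(f$labels))
  # whole-pipeline: strongly separable study classifies near-perfectly
  rep <- run_cv(f)
  expect_gt(rep$accuracy, 0.9)
  expect_gt(rep$proportions["drug.first", "drug.first"], 0.8)
  expect_identical(sum(rep$confusion), 8L * rep$n_folds)
})

test_that("degenerate and duplicated features do not corrupt predictions", {
  f <- separable_features()
  x0 <- cbind(f$x, flat = 0)   # zero-variance column is dropped
  model <- pls_da_fit(x0, f$labels)
  expect_identical(model$dropped, "flat")
  # duplicating every column leaves predictions unchanged
  xdup <- cbind(f$x, f$x)
  colnames(xdup) <- paste0("g", seq_len(ncol(xdup)))
  m1 <- pls_da_fit(f$x, f$labels)
  m2 <- pls_da_fit(xdup, f$labels)
  xt <- f$x[1:8, , drop = FALSE]
  xt_dup <- cbind(xt, xt); colnames(xt_dup) <- colnames(xdup)
  expect_identical(as.character(pls_da_predict(m1, xt)),
                   as.character(pls_da_predict(m2, xt_dup)))
})

test_that("held-out data never leak into training", {
  f <- separable_features()
  tr <- f$participant != "P1"
  model <- pls_da_fit(f$x[tr, ], droplevels(f$labels[tr]))
  te <- f$x[!tr, , drop = FALSE]
  p1 <- pls_da_predict(model, te)
  # each test row is scored independently of its neighbours
  p3 <- pls_da_predict(model, te[c(1, 3), , drop = FALSE])
  expect_identical(as.character(p3), as.character(p1[c(1, 3)]))

  # perturbing one participant's data leaves the predictions of the other
  # member of its test pairs unchanged (those folds train on neither)
  r1 <- run_cv(f)$predictions
  f2 <- f
  f2$x[f2$participant == "P1", ] <- f2$x[f2$participant == "P1", ] * 10 + 3
  r2 <- run_cv(f2)$predictions
  p1_folds <- unique(r1$fold[r1$participant == "P1"])
  keep <- r1$fold %in% p1_folds & r1$participant != "P1"
  expect_identical(r1$predicted[keep], r2$predicted[keep])
})

test_that("tied one-hot scores resolve to the first cell in fixed order", {
  lev <- cell_levels()
  scores <- rbind(c(0.25, 0.25, 0.25, 0.25),
                  c(0.1, 0.4, 0.4, 0.1),
                  c(0, 0, 0, 1))
  colnames(scores) <- lev
  pred <- fcpipe:::argmax_labels(scores, lev)
  expect_identical(as.character(pred),
                   c("placebo.first", "placebo.second", "drug.second"))
})

test_that("label permutation drives cross-validated accuracy to chance", {
  f <- separable_features(n_participants = 8)
  set.seed(53)
  accs <- vapply(1:4, function(i) {
    fp <- f
    # permute cell labels within participant: breaks the label-feature link
    for (p in unique(fp$participant)) {
      idx <- which(fp$participant == p)
      fp$labels[idx] <- fp$labels[sample(idx)]
      rownames(fp$x)[idx] <- paste(p, fp$labels[idx], sep = ".")
    }
    run_cv(fp)$accuracy
  }, numeric(1))
  expect_lt(abs(mean(accs) - 0.25), 0.15)
})

test_that("d-prime follows the inverse-normal closed form with corrections", {
  mk_report <- function(conf) {
    dimnames(conf) <- list(true = cell_levels(), predicted = cell_levels())
    structure(list(confusion = conf), class = "classification_report")
  }
  # hit = fa gives 0
  conf <- matrix(25L, 4, 4)
  expect_equal(d_prime(mk_report(conf))$d_prime, 0, tolerance = 1e-12)

  # hit = .84, fa = .16 gives ~1.989
  conf <- matrix(0L, 4, 4)
  conf[3, 3] <- 84L; conf[3, 1] <- 16L           # target row: drug.first
  conf[1, 3] <- 48L; conf[1, 1] <- 252L          # 48 / 300 = 0.16
  conf[2, 2] <- 1L; conf[4, 4] <- 1L
  dp <- d_prime(mk_report(conf))
  expect_equal(dp$hit, 0.84)
  expect_equal(dp$fa, 48 / 302, tolerance = 0.01)
  expect_equal(dp$d_prime, qnorm(0.84) - qnorm(dp$fa), tolerance = 1e-10)

  # perfect hit rate is shrunk to 1 - 1/(2n) before the transform
  conf <- matrix(0L, 4, 4)
  conf[3, 3] <- 132L
  conf[1, 1] <- conf[2, 2] <- conf[4, 4] <- 132L
  dp1 <- d_prime(mk_report(conf))
  expect_equal(qnorm(1 - 1 / 264) - qnorm(1 / (2 * 396)), dp1$d_prime,
               tolerance = 1e-10)

  # monotone: increasing hit at fixed fa increases d-prime
  dps <- vapply(seq(10, 90, by = 10), function(h) {
    conf <- matrix(10L, 4, 4)
    conf[3, 3] <- as.integer(h)
    d_prime(mk_report(conf))$d_prime
  }, numeric(1))
  expect_true(all(diff(dps) > 0))
})

test_that("the network sweep finds an effect planted in one interaction", {
  # truth injected only in within-A edges
  eff <- condition_effect("A", delta_z = -0.35)
  st <- tiny_study(seed = 54, n_participants = 8, n_per = 5,
                   timepoints = 150, effect = eff)
  feats <- connectome_features(study_sfc_z(st))
  sweep <- network_model_sweep(feats, st$scheme)
  expect_identical(sweep$interaction,
                   c("within:A", "within:B", "between:A:B"))
  expect_identical(sweep$interaction[which.max(sweep$d_prime)], "within:A")
  expect_true(all(sweep$d_prime_floored >= 0))
  expect_true(all(sweep$d_prime_floored >= sweep$d_prime))
})

test_that("feature assembly validates completeness and drops missing edges", {
  st <- tiny_study(seed = 55, n_participants = 4, timepoints = 80)
  mats <- study_sfc_z(st)
  f <- connectome_features(mats)
  expect_identical(dim(f$x), c(16L, 28L))   # 4x4 rows, C(8,2) edges
  expect_identical(levels(f$labels), cell_levels())
  expect_error(connectome_features(mats[-1]), "exactly one matrix")

  # an edge missing in one matrix is dropped everywhere
  m <- unclass(mats[[1]]); m[1, 2] <- m[2, 1] <- NA
  mats[[1]] <- connectivity_matrix(
    m, "sfc_z", participant = attr(mats[[1]], "participant"),
    drug = attr(mats[[1]], "drug"), half = attr(mats[[1]], "half"))
  f2 <- connectome_features(mats)
  expect_identical(f2$n_dropped_edges, 1L)
  expect_identical(ncol(f2$x), 27L)

  # combining measures concatenates standardized blocks
  fb <- f; fb$measure <- "dfc_var"; fb$x <- fb$x * 100
  fc <- combine_features(f, fb)
  expect_identical(ncol(fc$x), 56L)
  expect_identical(fc$measure, "combined")
})
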