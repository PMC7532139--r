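test_that("network aggregation averages the right edge sets", {
  # 2 networks of 3 and 2 nodes: within-A 3 edges, within-B 1, between 6
  sch <- network_scheme(paste0("n", 1:5), c("A", "A", "A", "B", "B"))
  m <- matrix(2, 5, 5, dimnames = list(paste0("n", 1:5), paste0("n", 1:5)))
  diag(m) <- NA
  cm <- connectivity_matrix(m, "dfc_var", participant = "P1",
                            drug = "drug", half = "first")
  agg <- aggregate_networks(cm, sch)
  expect_identical(nrow(agg), 3L)
  expect_equal(agg$n_edges[agg$interaction == "within:A"], 3)
  expect_equal(agg$n_edges[agg$interaction == "within:B"], 1)
  expect_equal(agg$n_edges[agg$interaction == "between:A:B"], 6)
  expect_true(all(agg$value == 2))   # constant edges average to the constant

  # scaling all edges scales every interaction mean (linearity)
  cm3 <- connectivity_matrix(m * 3, "dfc_var")
  expect_equal(aggregate_networks(cm3, sch)$value, agg$value * 3)

  # default 8-network scheme yields 36 interaction rows
  sch8 <- default_scheme(16, networks = paste0("net", 1:8))
  m8 <- matrix(rnorm(256), 16, 16,
               dimnames = list(sch8$node_id, sch8$node_id))
  m8 <- (m8 + t(m8)) / 2; diag(m8) <- NA
  expect_identical(nrow(aggregate_networks(connectivity_matrix(m8, "efc_H"),
                                           sch8)), 36L)

  # raw-correlation input and single-node networks are refused
  r <- static_fc(matrix(rnorm(100), 20, 5))
  expect_error(aggregate_networks(r, sch), "Fisher-z")
  sch_bad <- network_scheme(paste0("n", 1:5), c("A", "A", "A", "A", "B"))
  expect_error(aggregate_networks(cm, sch_bad), "single node")
})

test_that("missing edges are excluded from the aggregate with a count", {
  sch <- network_scheme(paste0("n", 1:4), c("A", "A", "A", "A"))
  m <- matrix(1, 4, 4, dimnames = list(sch$node_id, sch$node_id))
  m[1, 2] <- m[2, 1] <- NA; m[1, 3] <- m[3, 1] <- 5; diag(m) <- NA
  agg <- aggregate_networks(connectivity_matrix(m, "efc_H"), sch)
  expect_equal(agg$n_missing, 1)
  expect_equal(agg$value, (5 + 4 * 1) / 5)
})

test_that("the 2x2 repeated-measures ANOVA matches its oracles", {
  make_df <- function(vals) {
    d <- expand.grid(participant = paste0("P", 1:8),
                     drug = c("placebo", "drug"),
                     half = c("first", "second"),
                     stringsAsFactors = FALSE)
    d$value <- vals
    d
  }

  # identical cells: all effects F = 0
  d0 <- make_df(rep(3, 32))
  expect_true(all(rm_anova_2x2(d0)$F == 0))

  set.seed(31)
  for (rep_i in 1:5) {
    d <- make_df(rnorm(32))
    an <- rm_anova_2x2(d)

    # F equals the squared paired t on the per-participant contrast scores
    wide <- fcpipe:::cell_matrix(d)
    inter <- (wide[, "drug.first"] - wide[, "drug.second"]) -
             (wide[, "placebo.first"] - wide[, "placebo.second"])
    t_inter <- mean(inter) / (sd(inter) / sqrt(8))
    expect_equal(an$F[an$effect == "interaction"], t_inter^2,
                 tolerance = 1e-10)
    drg <- rowMeans(wide[, c("drug.first", "drug.second")]) -
           rowMeans(wide[, c("placebo.first", "placebo.second")])
    t_drug <- mean(drg) / (sd(drg) / sqrt(8))
    expect_equal(an$F[an$effect == "drug"], t_drug^2, tolerance = 1e-10)

    # independent oracle: base R within-subjects aov
    d$participant <- factor(d$participant)
    d$drug <- factor(d$drug); d$half <- factor(d$half)
    fit <- summary(stats::aov(value ~ drug * half +
                                Error(participant / (drug * half)),
                              data = d))
    f_aov <- c(drug = fit[["Error: participant:drug"]][[1]]["drug", "F value"],
               time = fit[["Error: participant:half"]][[1]]["half", "F value"],
               interaction = fit[["Error: participant:drug:half"]][[1]][
                 "drug:half", "F value"])
    expect_equal(an$F, unname(f_aov[an$effect]), tolerance = 1e-8)

    # partial eta squared from F and error df
    expect_equal(an$pes, an$F / (an$F + 7), tolerance = 1e-12)
  }
})

test_that("the interaction test has nominal type-I error under the null", {
  set.seed(32)
  rej <- vapply(1:1000, function(i) {
    d <- expand.grid(participant = paste0("P", 1:12),
                     drug = c("placebo", "drug"),
                     half = c("first", "second"),
                     stringsAsFactors = FALSE)
    d$value <- rnorm(48)
    an <- rm_anova_2x2(d)
    an$p[an$effect == "interaction"] < 0.05
  }, logical(1))
  expect_lt(abs(mean(rej) - 0.05), 0.025)
})

test_that("paired contrasts report t, Cohen's d and their symmetries", {
  res <- paired_contrast(c(2, 3, 4, 5), c(1, 1, 1, 1))   # diffs 1..4
  expect_equal(res$t, 2.5 / (sd(1:4) / 2), tolerance = 1e-12)
  expect_equal(res$t, 3.872983, tolerance = 1e-6)
  expect_equal(res$d, 1.936492, tolerance = 1e-6)
  expect_equal(res$mean_diff, 2.5)

  same <- paired_contrast(1:4, 1:4)
  expect_identical(c(same$t, same$d), c(0, 0))

  a <- rnorm(6); b <- rnorm(6)
  expect_equal(paired_contrast(a, b)$t, -paired_contrast(b, a)$t)
  expect_equal(paired_contrast(a, b)$d, -paired_contrast(b, a)$d)
  expect_error(paired_contrast(c(1, 2, 3), c(0, 1, 2)), "zero-variance")
})

test_that("Holm-Bonferroni steps down correctly and dominates Bonferroni", {
  expect_false(any(holm_bonferroni(rep(1, 5))$reject))
  one <- holm_bonferroni(0.04, alpha = 0.05)
  expect_true(one$reject)
  expect_equal(one$p_holm, 0.04)

  hb <- holm_bonferroni(c(0.001, 0.02, 0.04), alpha = 0.05)
  expect_equal(hb$p_holm, c(0.003, 0.04, 0.04))
  expect_true(all(hb$reject))

  set.seed(33)
  for (i in 1:200) {
    p <- runif(10)^2
    holm_rej <- holm_bonferroni(p)$reject
    bonf_rej <- p.adjust(p, "bonferroni") <= 0.05
    expect_true(all(holm_rej[bonf_rej]))   # Holm rejects a superset
  }
  expect_error(holm_bonferroni(c(0.2, 1.4)), "\\[0, 1\\]")
})

test_that("edge thresholding keeps real edges then contrasts conditions", {
  expect_equal(0.05 / 35778, 1.3975e-6, tolerance = 1e-3)

  # all-zero data survives nothing
  zero <- matrix(0, 6, 10, dimnames = list(NULL, paste0("e", 1:10)))
  cells0 <- setNames(rep(list(zero), 4), cell_levels())
  res0 <- edge_threshold_contrast(cells0)
  expect_length(res0$stage1$union, 0L)

  # strong within-network truth: survivors are predominantly within-network
  eff <- condition_effect("A", delta_z = -0.25)
  st <- tiny_study(seed = 41, n_participants = 8, n_per = 6,
                   timepoints = 200, effect = eff, within_rho = 0.6,
                   between_rho = 0.05)
  z <- study_sfc_z(st)
  cells <- fcpipe:::z_cell_matrices(z)
  res <- edge_threshold_contrast(cells)
  expect_equal(res$bonferroni_p, 0.05 / ncol(cells[[1]]))
  lab <- fcpipe:::edge_interactions(st$scheme)
  names(lab) <- fcpipe:::edge_names(st$scheme$node_id)
  surv <- lab[res$stage1$union]
  expect_gt(mean(startsWith(surv, "within")), 0.8)
  # the injected drug-first attenuation shows up in stage 2
  s2 <- res$stage2
  expect_gt(sum(s2$half == "first" & s2$direction == "drug<placebo"), 0)
})

test_that("drug-strength AUC integrates the rating curve to 20 minutes", {
  times <- c(1, 2, 3, 4, 5, 10, 15, 20)
  expect_equal(auc_drug_strength(times, rep(10, 8)), 190)
  expect_equal(auc_drug_strength(times, rep(0, 8)), 0)
  expect_equal(auc_drug_strength(times, c(10, 10, 10, 10, 10, 0, 0, 0)), 65)
  # ratings straddling t_max are interpolated at the boundary
  expect_equal(auc_drug_strength(c(1, 10, 30), c(10, 10, 10), t_max = 20),
               190)
  expect_error(auc_drug_strength(c(1, 25), c(5, 5), t_max = 20), "at least 2")
  expect_error(auc_drug_strength(c(1, 1), c(5, 5)), "increasing")
  expect_error(auc_drug_strength(1:3, c(5, 11, 2)), "\\[0, 10\\]")
})

test_that("connectivity-change vs AUC correlation recovers known coupling", {
  x <- rnorm(12)
  expect_equal(change_vs_auc(x, x)$r, 1)
  expect_equal(change_vs_auc(x, -x)$r, -1)
  set.seed(34)
  est <- vapply(1:200, function(i) {
    auc <- rnorm(12)
    delta <- -0.5 * auc + sqrt(1 - 0.25) * rnorm(12)
    change_vs_auc(delta, auc)$r
  }, numeric(1))
  expect_lt(abs(mean(est) + 0.5), 0.1)
  expect_error(change_vs_auc(rep(1, 12), rnorm(12)), "zero variance")
})
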