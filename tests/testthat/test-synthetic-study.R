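test_that("block covariance construction honors requested correlations", {
  sch8 <- default_scheme(16, networks = paste0("n", 1:8))

  # zero correlation everywhere gives the identity
  expect_equal(make_network_covariance(sch8, 0, 0),
               diag(16), ignore_attr = TRUE)

  # direct 2-network construction
  sch2 <- default_scheme(4, networks = c("A", "B"))
  C <- make_network_covariance(sch2, 0.5, 0.1)
  expect_equal(unname(diag(C)), rep(1, 4))
  expect_equal(unname(C[1, 2]), 0.5, tolerance = 1e-10)
  expect_equal(unname(C[3, 4]), 0.5, tolerance = 1e-10)
  expect_equal(unname(C[1, 3]), 0.1, tolerance = 1e-10)
  expect_true(isSymmetric(C))
  expect_gte(min(eigen(C, symmetric = TRUE, only.values = TRUE)$values), 0)

  # 8 networks give 28 distinct between-network blocks
  expect_identical(nrow(network_pairs(sch8)), 28L)
  expect_identical(length(interaction_labels(sch8)), 36L)
})

test_that("contradictory block requests fail naming the blocks", {
  sch3 <- default_scheme(6, networks = c("A", "B", "C"))
  expect_error(
    make_network_covariance(sch3, within_rho = 0.9,
                            between_rho = c("A:B" = 0.9, "A:C" = 0.9,
                                            "B:C" = -0.9)),
    "contradictory")
  expect_error(make_network_covariance(sch3, 1.2, 0), "inside")
})

test_that("simulated scans recover their target correlation", {
  # identity target: off-diagonal sample correlations are small at T = 5000
  sch <- default_scheme(6, networks = c("A", "B"))
  I6 <- make_network_covariance(sch, 0, 0)
  sc <- simulate_scan(I6, 5000, ar = 0, seed = 101)
  r <- cor(unclass(sc))
  expect_lt(max(abs(r[upper.tri(r)])), 0.08)

  # one-edge target rho = 0.6
  C2 <- matrix(c(1, 0.6, 0.6, 1), 2)
  sc2 <- simulate_scan(C2, 5000, ar = 0, seed = 102)
  expect_lt(abs(cor(unclass(sc2))[1, 2] - 0.6), 0.05)

  # seeded determinism
  sc3 <- simulate_scan(C2, 5000, ar = 0, seed = 102)
  expect_identical(unclass(sc2), unclass(sc3))

  # AR(1) preserves the cross-correlation
  sc4 <- simulate_scan(C2, 5000, ar = 0.4, seed = 103)
  expect_lt(abs(cor(unclass(sc4))[1, 2] - 0.6), 0.07)
  expect_gt(cor(sc4[-1, 1], sc4[-5000, 1]), 0.3)   # lag-1 autocorrelation

  expect_error(simulate_scan(C2, 20, seed = 1), "at least 30")
  bad <- matrix(c(1, 2, 2, 1), 2)
  expect_error(simulate_scan(bad, 100, seed = 1), "PSD")
})

test_that("sample correlation converges to the target as T doubles", {
  C <- make_network_covariance(default_scheme(4, networks = c("A", "B")),
                               0.5, 0.1)
  frob <- function(n_t, seed) {
    sc <- simulate_scan(C, n_t, ar = 0, seed = seed)
    sqrt(sum((cor(unclass(sc)) - C)^2))
  }
  d_short <- vapply(1:20, function(s) frob(150, 200 + s), numeric(1))
  d_long <- vapply(1:20, function(s) frob(600, 400 + s), numeric(1))
  expect_lt(mean(d_long), mean(d_short))
})

test_that("regime-switching data follow each regime's correlation", {
  C_hi <- matrix(c(1, 0.7, 0.7, 1), 2)
  C_lo <- diag(2)
  sc <- simulate_scan(NULL, 2000, ar = 0, seed = 55,
                      regimes = list(list(start = 1, end = 1000, corr = C_hi),
                                     list(start = 1001, end = 2000,
                                          corr = C_lo)))
  r1 <- cor(sc[1:1000, 1], sc[1:1000, 2])
  r2 <- cor(sc[1001:2000, 1], sc[1001:2000, 2])
  expect_lt(abs(r1 - 0.7), 0.07)
  expect_lt(abs(r2), 0.07)

  expect_error(
    simulate_scan(NULL, 100, seed = 1,
                  regimes = list(list(start = 1, end = 40, corr = C_lo),
                                 list(start = 45, end = 100, corr = C_lo))),
    "partition")
})

test_that("simulate_study emits a complete, deterministic design", {
  st <- tiny_study(seed = 21, n_participants = 5)
  expect_length(st$scans, 20L)   # 5 participants x 4 cells
  expect_identical(nrow(st$design_table), 20L)
  expect_setequal(unique(st$design_table$drug), c("placebo", "drug"))
  tab <- table(st$design_table$participant)
  expect_true(all(tab == 4))

  st2 <- tiny_study(seed = 21, n_participants = 5)
  expect_identical(lapply(st$scans, unclass), lapply(st2$scans, unclass))

  st3 <- tiny_study(seed = 22, n_participants = 5)
  expect_false(identical(unclass(st$scans[[1]]), unclass(st3$scans[[1]])))

  expect_error(simulate_study(study_design(3, 8, 100, two_net_scheme()),
                              effect = condition_effect("ZZ", -0.1)),
               "absent")
})

test_that("an injected within-network drug effect is recoverable downstream", {
  # within-A rho 0.5 under placebo vs 0.3 in the drug-first cell
  eff <- condition_effect("A", delta_z = atanh(0.3) - atanh(0.5),
                          drug = "drug", half = "first")
  st <- tiny_study(seed = 31, n_participants = 12, timepoints = 400,
                   effect = eff, within_rho = 0.5)
  summ <- network_summary(study_sfc_z(st), st$scheme)
  wA <- summ[summ$interaction == "within:A", ]
  pf <- wA$value[wA$drug == "placebo" & wA$half == "first"]
  df <- wA$value[wA$drug == "drug" & wA$half == "first"]
  res <- paired_contrast(pf, df)
  expect_gt(res$t, 0)
  expect_lt(res$p, 0.001)
})
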