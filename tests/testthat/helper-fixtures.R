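# Shared fixtures: all synthetic, generated in code at test time.

two_net_scheme <- function(n_per = 4) {
  network_scheme(sprintf("N%03d", seq_len(2 * n_per)),
                 rep(c("A", "B"), each = n_per))
}

# small complete study for classifier / stats tests
tiny_study <- function(seed = 11, n_participants = 6, n_per = 4,
                       timepoints = 120, effect = NULL, ...) {
  scheme <- two_net_scheme(n_per)
  des <- study_design(n_participants = n_participants,
                      n_nodes = nrow(scheme),
                      timepoints_per_half = timepoints,
                      scheme = scheme, seed = seed)
  simulate_study(des, effect = effect, ...)
}

# fisher-z static connectivity for every scan of a study
study_sfc_z <- function(study) {
  lapply(study$scans, function(s) fisher_z(static_fc(s)))
}

# bivariate series with fixed correlation (optionally per-regime)
corr_pair <- function(n, rho, seed = 1) {
  set.seed(seed)
  x <- stats::rnorm(n)
  e <- stats::rnorm(n)
  if (length(rho) == 1) rho <- rep(rho, n)
  y <- rho * x + sqrt(1 - rho^2) * e
  cbind(x, y)
}

# fast DCC control for short test series
fast_dcc <- function() dcc_control(maxit = 200)
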