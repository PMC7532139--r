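# Bivariate DCC(1,1)-GARCH(1,1) estimation for edge-wise time-resolved
# correlation. Two-stage Gaussian quasi-maximum likelihood:
#   stage 1  per series:  h_t = omega + alpha * eps^2_{t-1} + beta * h_{t-1}
#   stage 2  on standardized residuals z_t:
#            Q_t = (1 - a - b) * Sbar + a * z_{t-1} z'_{t-1} + b * Q_{t-1}
#            R_t = Q_t[1,2] / sqrt(Q_t[1,1] * Q_t[2,2])
# Both recursions are linear in their lagged term and are evaluated with
# stats::filter(method = "recursive"), so likelihood evaluations are
# vectorized. Optimization is derivative-free Nelder-Mead from a fixed
# multi-start grid, which makes estimates deterministic.

#' DCC estimation control settings
#'
#' @param garch_alpha0,garch_beta0 Start grids for the GARCH(1,1) ARCH and
#'   persistence parameters (all combinations are tried).
#' @param dcc_starts Matrix-like list of (a, b) starting pairs for the
#'   correlation stage; the fixed default covers low/mid news and
#'   persistence values plus the constant-correlation corner (0, 0).
#' @param maxit Nelder-Mead iteration cap per start.
#' @param reltol Nelder-Mead relative convergence tolerance.
#' @param ewma_lambda Decay of the exponentially-weighted moving
#'   correlation used as fallback when QML estimation fails (default 0.94).
#' @return List of settings for [dcc_edge()] / [dcc_scan()].
#' @export
dcc_control <- function(garch_alpha0 = c(0.05, 0.15),
                        garch_beta0 = c(0.5, 0.85),
                        dcc_starts = list(c(0.02, 0.5), c(0.02, 0.85),
                                          c(0.1, 0.5), c(0.1, 0.85),
                                          c(0, 0)),
                        maxit = 500, reltol = 1e-8, ewma_lambda = 0.94) {
  list(garch_alpha0 = garch_alpha0, garch_beta0 = garch_beta0,
       dcc_starts = dcc_starts, maxit = as.integer(maxit), reltol = reltol,
       ewma_lambda = ewma_lambda)
}

# conditional-variance recursion; returns h_1..h_T with h_1 = init
garch11_filter <- function(eps, omega, alpha, beta, init = stats::var(eps)) {
  n <- length(eps)
  rest <- stats::filter(omega + alpha * eps[-n]^2, beta,
                        method = "recursive", init = init)
  c(init, as.numeric(rest))
}

garch11_nll <- function(par, eps, v) {
  omega <- par[1]; alpha <- par[2]; beta <- par[3]
  if (omega <= 0 || alpha < 0 || beta < 0 || alpha + beta >= 0.999)
    return(1e10)
  h <- garch11_filter(eps, omega, alpha, beta, init = v)
  if (any(h <= 0) || any(!is.finite(h))) return(1e10)
  0.5 * sum(log(h) + eps^2 / h)
}

#' Fit a GARCH(1,1) model by Gaussian quasi-maximum likelihood
#'
#' The series is mean-centered; no ARMA mean model is used. Parameters are
#' estimated by Nelder-Mead from a fixed multi-start grid, with the
#' conditional variance initialised at the sample variance.
#'
#' @param x Numeric series, length >= 30, non-constant.
#' @param control A [dcc_control()].
#' @return List with `omega`, `alpha`, `beta`, `h` (conditional variances),
#'   `z` (standardized residuals, rescaled to unit sample variance),
#'   `loglik`, and `converged`.
#' @export
garch11_fit <- function(x, control = dcc_control()) {
  if (length(x) < 30) stop("series too short for GARCH estimation (T < 30)")
  eps <- x - mean(x)
  v <- stats::var(eps)
  if (v == 0) stop("constant series")
  best <- NULL
  for (a0 in control$garch_alpha0) {
    for (b0 in control$garch_beta0) {
      p0 <- c(v * (1 - a0 - b0), a0, b0)
      fit <- tryCatch(
        stats::optim(p0, garch11_nll, eps = eps, v = v,
                     method = "Nelder-Mead",
                     control = list(maxit = control$maxit,
                                    reltol = control$reltol)),
        error = function(e) NULL)
      if (is.null(fit) || !is.finite(fit$value)) next
      if (is.null(best) || fit$value < best$value - 1e-9 ||
          (abs(fit$value - best$value) <= 1e-9 &&
           sum(fit$par[2:3]) < sum(best$par[2:3]))) {
        best <- fit
      }
    }
  }
  if (is.null(best) || best$value >= 1e10)
    return(list(converged = FALSE, omega = v, alpha = 0, beta = 0,
                h = rep(v, length(eps)), z = eps / stats::sd(eps),
                loglik = NA_real_))
  par <- best$par
  h <- garch11_filter(eps, par[1], par[2], par[3], init = v)
  z <- eps / sqrt(h)
  z <- z / stats::sd(z)   # exact unit variance for correlation targeting
  list(omega = par[1], alpha = par[2], beta = par[3], h = h, z = z,
       loglik = -best$value, converged = TRUE)
}

# DCC(1,1) pseudo-correlation recursion on standardized residuals.
# Returns R_1..R_T (R_1 from Q_1 = Sbar).
dcc_filter <- function(z1, z2, a, b, s12) {
  n <- length(z1)
  cst <- 1 - a - b
  q11 <- c(1, as.numeric(stats::filter(cst + a * z1[-n]^2, b,
                                       method = "recursive", init = 1)))
  q22 <- c(1, as.numeric(stats::filter(cst + a * z2[-n]^2, b,
                                       method = "recursive", init = 1)))
  q12 <- c(s12, as.numeric(stats::filter(cst * s12 + a * z1[-n] * z2[-n], b,
                                         method = "recursive", init = s12)))
  q12 / sqrt(q11 * q22)
}

dcc_nll <- function(par, z1, z2, s12) {
  a <- par[1]; b <- par[2]
  if (a < 0 || b < 0 || a + b >= 0.997) return(1e10)
  r <- dcc_filter(z1, z2, a, b, s12)
  om <- 1 - r^2
  if (any(om <= 0) || any(!is.finite(om))) return(1e10)
  0.5 * sum(log(om) + (z1^2 + z2^2 - 2 * r * z1 * z2) / om)
}

# exponentially-weighted moving correlation (RiskMetrics-style) fallback
ewma_corr <- function(x, y, lambda = 0.94) {
  x <- x - mean(x); y <- y - mean(y)
  n <- length(x)
  s11 <- c(stats::var(x),
           as.numeric(stats::filter((1 - lambda) * x[-n]^2, lambda,
                                    method = "recursive", init = stats::var(x))))
  s22 <- c(stats::var(y),
           as.numeric(stats::filter((1 - lambda) * y[-n]^2, lambda,
                                    method = "recursive", init = stats::var(y))))
  s12 <- c(stats::cov(x, y),
           as.numeric(stats::filter((1 - lambda) * x[-n] * y[-n], lambda,
                                    method = "recursive",
                                    init = stats::cov(x, y))))
  pmin(pmax(s12 / sqrt(s11 * s22), -0.999), 0.999)
}

#' Time-resolved correlation of one edge via DCC-GARCH
#'
#' Two-stage estimation: GARCH(1,1) per series (quasi-maximum likelihood on
#' the mean-centered series), then DCC(1,1) on the standardized residuals
#' with correlation targeting (the unconditional matrix is the sample
#' correlation of the residuals). If estimation fails, the edge falls back
#' to an exponentially-weighted moving correlation and is flagged.
#'
#' @param x,y Numeric series of equal length T >= 30, non-constant.
#' @param control A [dcc_control()].
#' @param garch_x,garch_y Optional pre-computed [garch11_fit()] results
#'   (used by [dcc_scan()] to fit each node once).
#' @return An `edge_correlation`: list with `series` (length-T conditional
#'   correlations in (-1, 1)), `a`, `b` (DCC parameters), `garch_x`,
#'   `garch_y` (per-node GARCH parameters), `flagged`, `method`.
#' @examples
#' set.seed(1)
#' z <- matrix(rnorm(400), 200, 2) %*% chol(matrix(c(1, .6, .6, 1), 2))
#' ec <- dcc_edge(z[, 1], z[, 2])
#' mean(ec$series)
#' @export
dcc_edge <- function(x, y, control = dcc_control(),
                     garch_x = NULL, garch_y = NULL) {
  if (length(x) != length(y)) stop("series lengths differ")
  if (length(x) < 30) stop("series too short for DCC estimation (T < 30)")
  if (stats::sd(x) == 0 || stats::sd(y) == 0) stop("constant input series")
  if (is.null(garch_x)) garch_x <- garch11_fit(x, control)
  if (is.null(garch_y)) garch_y <- garch11_fit(y, control)
  fit <- dcc_fit_pair(garch_x$z, garch_y$z, control)
  if (!garch_x$converged || !garch_y$converged || !fit$converged) {
    r <- ewma_corr(x, y, control$ewma_lambda)
    return(structure(list(series = r, a = NA_real_, b = NA_real_,
                          garch_x = garch_x[c("omega", "alpha", "beta")],
                          garch_y = garch_y[c("omega", "alpha", "beta")],
                          flagged = TRUE, method = "ewma"),
                     class = "edge_correlation"))
  }
  structure(list(series = fit$series, a = fit$a, b = fit$b,
                 garch_x = garch_x[c("omega", "alpha", "beta")],
                 garch_y = garch_y[c("omega", "alpha", "beta")],
                 flagged = FALSE, method = "dcc"),
            class = "edge_correlation")
}

dcc_fit_pair <- function(z1, z2, control = dcc_control()) {
  s12 <- stats::cor(z1, z2)
  best <- NULL
  for (p0 in control$dcc_starts) {
    fit <- tryCatch(
      stats::optim(p0, dcc_nll, z1 = z1, z2 = z2, s12 = s12,
                   method = "Nelder-Mead",
                   control = list(maxit = control$maxit,
                                  reltol = control$reltol)),
      error = function(e) NULL)
    if (is.null(fit) || !is.finite(fit$value)) next
    # ties broken by the smallest a + b (least persistent model)
    if (is.null(best) || fit$value < best$value - 1e-6 ||
        (abs(fit$value - best$value) <= 1e-6 &&
         sum(fit$par) < sum(best$par))) {
      best <- fit
    }
  }
  if (is.null(best) || best$value >= 1e10)
    return(list(converged = FALSE))
  a <- max(best$par[1], 0); b <- max(best$par[2], 0)
  r <- dcc_filter(z1, z2, a, b, s12)
  list(a = a, b = b, series = r, loglik = -best$value, converged = TRUE)
}

#' @export
print.edge_correlation <- function(x, ...) {
  cat("<edge_correlation> T = ", length(x$series), ", method = ", x$method,
      if (x$method == "dcc")
        sprintf(", a = %.3f, b = %.3f", x$a, x$b),
      if (x$flagged) " [flagged]", "\n", sep = "")
  invisible(x)
}

#' Edge-wise DCC correlation series for a whole scan
#'
#' Fits one GARCH(1,1) model per node (each node is fit once and its
#' standardized residuals reused), then one bivariate DCC(1,1) model per
#' edge, i.e. N(N-1)/2 independent bivariate fits.
#'
#' @param scan A [scan_timeseries()].
#' @param control A [dcc_control()].
#' @return An `edge_series_set`: list with `series` (T x E matrix of
#'   conditional correlations, canonical edge order), `params` (data.frame
#'   edge, a, b, method, flagged), `node_ids`, and scan metadata.
#' @export
dcc_scan <- function(scan, control = dcc_control()) {
  if (!inherits(scan, "scan_timeseries")) scan <- scan_timeseries(scan)
  node_ids <- colnames(scan)
  n <- length(node_ids)
  garch <- lapply(seq_len(n), function(k) garch11_fit(scan[, k], control))
  ei <- edge_index(node_ids)
  en <- paste(ei$node_i, ei$node_j, sep = "|")
  series <- matrix(NA_real_, nrow(scan), nrow(ei),
                   dimnames = list(NULL, en))
  params <- data.frame(edge = en, a = NA_real_, b = NA_real_,
                       method = NA_character_, flagged = NA,
                       stringsAsFactors = FALSE)
  for (m in seq_len(nrow(ei))) {
    ec <- dcc_edge(scan[, ei$i[m]], scan[, ei$j[m]], control,
                   garch_x = garch[[ei$i[m]]], garch_y = garch[[ei$j[m]]])
    series[, m] <- ec$series
    params$a[m] <- ec$a; params$b[m] <- ec$b
    params$method[m] <- ec$method; params$flagged[m] <- ec$flagged
  }
  n_flag <- sum(params$flagged)
  if (n_flag > 0)
    message("dcc_scan: ", n_flag, " of ", nrow(ei),
            " edges fell back to EWMA correlation")
  meta <- scan_meta(scan)
  structure(list(series = series, params = params, node_ids = node_ids,
                 participant = meta$participant, drug = meta$drug,
                 half = meta$half),
            class = "edge_series_set")
}

#' @export
print.edge_series_set <- function(x, ...) {
  cat("<edge_series_set> ", ncol(x$series), " edges x T = ", nrow(x$series),
      ", ", sum(x$params$flagged), " flagged\n", sep = "")
  invisible(x)
}

#' Dynamic functional connectivity (variance of edge correlations)
#'
#' Entry (i, j) is the sample variance (denominator T - 1) of that edge's
#' conditional-correlation series.
#'
#' @param edge_series An `edge_series_set` from [dcc_scan()].
#' @return A [connectivity_matrix()] with measure `"dfc_var"` (diagonal
#'   `NA`). Edges that used the EWMA fallback retain their variance; the
#'   matrix records their count in the `n_flagged` attribute.
#' @export
dynamic_fc <- function(edge_series) {
  stopifnot(inherits(edge_series, "edge_series_set"))
  v <- apply(edge_series$series, 2, stats::var)
  m <- edge_vec_to_matrix(v, edge_series$node_ids)
  connectivity_matrix(m, "dfc_var",
                      participant = edge_series$participant,
                      drug = edge_series$drug, half = edge_series$half,
                      n_flagged = sum(edge_series$params$flagged))
}
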