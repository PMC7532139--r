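# Pipeline orchestration: each stage reads its parameters from one
# RunConfig object, writes TSV artifacts plus a serialized copy of the
# config into its output directory, and logs one structured line.

#' Pipeline run configuration
#'
#' Central parameter object for the command-line pipeline; every stage
#' reads its settings only from this object, and a YAML copy is written
#' into every output directory.
#'
#' @param data_dir Directory with `design.tsv`, `network_map.tsv` and scan
#'   TSVs ([write_study()] layout).
#' @param out_dir Root output directory.
#' @param measures Connectivity measures to compute, subset of
#'   `c("sfc", "dfc", "efc")`.
#' @param split Whether input scans are full sessions to be split into
#'   halves (default `FALSE`: one scan per cell).
#' @param n_bins,bin_range Entropy settings (see [entropy_config()]).
#' @param efc_scale `"r"` or `"z"`: scale of the correlation series for the
#'   entropy (default `"r"`).
#' @param alpha Significance level for the statistics stage (default
#'   0.05).
#' @param ncomp PLS-DA components (default 3).
#' @param sweep Whether the classification stage also runs the 36-model
#'   network sweep (default `TRUE`).
#' @param seed Global seed; the simulate stage and any stochastic step
#'   derive their streams from it.
#' @param simulate Optional list of arguments forwarded to
#'   [study_design()] / [simulate_study()] by [pipe_simulate()] (e.g.
#'   `n_participants`, `n_nodes`, `timepoints_per_half`, `within_rho`,
#'   `effect_delta_z`, `effect_network`).
#' @return A `run_config` list.
#' @export
run_config <- function(data_dir = NULL, out_dir = "fcpipe_out",
                       measures = c("sfc", "dfc", "efc"),
                       split = FALSE, n_bins = 60, bin_range = "data",
                       efc_scale = "r", alpha = 0.05, ncomp = 3,
                       sweep = TRUE, seed = 1L, simulate = list()) {
  measures <- match.arg(measures, several.ok = TRUE)
  stopifnot(alpha > 0, alpha < 1, ncomp >= 1)
  structure(list(data_dir = data_dir, out_dir = out_dir,
                 measures = measures, split = isTRUE(split),
                 n_bins = as.integer(n_bins), bin_range = bin_range,
                 efc_scale = efc_scale, alpha = alpha,
                 ncomp = as.integer(ncomp), sweep = isTRUE(sweep),
                 seed = as.integer(seed), simulate = simulate),
            class = "run_config")
}

#' Read / write a run configuration as YAML
#'
#' @param path YAML file.
#' @param config A [run_config()].
#' @return `read_config` returns a `run_config`; `write_config` returns
#'   `path` invisibly.
#' @export
read_config <- function(path) {
  vals <- yaml::read_yaml(path)
  do.call(run_config, vals[intersect(names(vals),
                                     names(formals(run_config)))])
}

#' @rdname read_config
#' @export
write_config <- function(config, path) {
  yaml::write_yaml(unclass(config), path)
  invisible(path)
}

stage_dir <- function(config, stage) {
  d <- file.path(config$out_dir, stage)
  dir.create(d, recursive = TRUE, showWarnings = FALSE)
  write_config(config, file.path(d, "run_config.yaml"))
  d
}

stage_log <- function(stage, ...) {
  message("[", stage, "] ", ...)
}

#' Stage 1: simulate a synthetic study
#'
#' Generates a study from `config$simulate` (defaults: 12 participants, 40
#' nodes in 8 networks, T = 400 per half, null effect) and writes it in
#' the [write_study()] layout under `out_dir/scans`.
#'
#' @param config A [run_config()].
#' @return The simulated `fc_study`, invisibly.
#' @export
pipe_simulate <- function(config) {
  sim <- config$simulate
  des <- study_design(
    n_participants = sim$n_participants %||% 12,
    n_nodes = sim$n_nodes %||% 40,
    timepoints_per_half = sim$timepoints_per_half %||% 400,
    seed = config$seed)
  effect <- NULL
  if (!is.null(sim$effect_delta_z))
    effect <- condition_effect(sim$effect_network %||% "DM",
                               sim$effect_delta_z)
  study <- simulate_study(des, effect = effect,
                          within_rho = sim$within_rho %||% 0.40,
                          between_rho = sim$between_rho %||% 0.10,
                          ar = sim$ar %||% 0.4,
                          seed = config$seed)
  d <- file.path(config$out_dir, "scans")
  dir.create(d, recursive = TRUE, showWarnings = FALSE)
  write_study(study, d)
  write_config(config, file.path(d, "run_config.yaml"))
  stage_log("simulate", length(study$scans), " scans, seed ", config$seed)
  invisible(study)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Stage 2: connectivity matrices per scan
#'
#' Computes the requested measures for each (participant, drug, half)
#' scan: static connectivity on both the r and Fisher-z scales and, when
#' requested, the DCC-based dynamic (variance) and entropic matrices.
#' Writes one square TSV per scan and measure plus a long-format edge
#' table.
#'
#' @param config A [run_config()]; `data_dir` defaults to
#'   `out_dir/scans`.
#' @param study Optional in-memory `fc_study` (skips reading
#'   `data_dir`).
#' @return Named list `measure -> list of connectivity matrices`,
#'   invisibly.
#' @export
pipe_connectivity <- function(config, study = NULL) {
  if (is.null(study))
    study <- read_study(config$data_dir %||% file.path(config$out_dir, "scans"),
                        split = config$split)
  d <- stage_dir(config, "connectivity")
  out <- list()
  need_dcc <- any(c("dfc", "efc") %in% config$measures)
  ecfg <- entropy_config(config$n_bins, config$bin_range)
  n_flagged <- 0L
  for (key in names(study$scans)) {
    scan <- study$scans[[key]]
    fname <- gsub(".", "_", key, fixed = TRUE)
    if ("sfc" %in% config$measures) {
      r <- static_fc(scan)
      z <- fisher_z(r)
      out$sfc_r[[key]] <- r
      out$sfc_z[[key]] <- z
      write_matrix_tsv(r, file.path(d, paste0(fname, "_sfc_r.tsv")))
      write_matrix_tsv(z, file.path(d, paste0(fname, "_sfc_z.tsv")))
    }
    if (need_dcc) {
      es <- dcc_scan(scan)
      n_flagged <- n_flagged + sum(es$params$flagged)
      if ("dfc" %in% config$measures) {
        v <- dynamic_fc(es)
        out$dfc_var[[key]] <- v
        write_matrix_tsv(v, file.path(d, paste0(fname, "_dfc_var.tsv")))
      }
      if ("efc" %in% config$measures) {
        h <- entropic_fc(es, ecfg, scale = config$efc_scale)
        out$efc_H[[key]] <- h
        write_matrix_tsv(h, file.path(d, paste0(fname, "_efc_H.tsv")))
      }
    }
  }
  long <- edge_long_table(unlist(out, recursive = FALSE, use.names = FALSE))
  write_tsv(long, file.path(d, "edges_long.tsv"))
  stage_log("connectivity", length(study$scans), " scans, measures: ",
            paste(config$measures, collapse = ","),
            if (need_dcc) paste0(", ", n_flagged, " flagged DCC edges"))
  invisible(out)
}

#' Stage 3: network-level statistics
#'
#' Aggregates each measure to the network interactions, runs the drug-by-
#' time repeated-measures ANOVA and the drug contrast per scan half for
#' every interaction, applies Holm-Bonferroni over the 36 interaction
#' p-values within each effect, builds the t-value matrices, and runs the
#' two-stage edge thresholding on static connectivity.
#'
#' @param config A [run_config()].
#' @param matrices Output of [pipe_connectivity()] (recomputed from
#'   `config` when `NULL`).
#' @param study Optional `fc_study` for the scheme (otherwise read from
#'   disk).
#' @return List with `summary` (long network summary), `stats` (tidy
#'   statistics table), `edges` (edge-threshold results), invisibly.
#' @export
pipe_networks <- function(config, matrices = NULL, study = NULL) {
  if (is.null(study))
    study <- read_study(config$data_dir %||% file.path(config$out_dir, "scans"),
                        split = config$split)
  if (is.null(matrices)) matrices <- pipe_connectivity(config, study)
  d <- stage_dir(config, "networks")
  scheme <- study$scheme
  use <- setdiff(names(matrices), "sfc_r")   # statistics use the z scale
  summaries <- lapply(use, function(ms)
    network_summary(matrices[[ms]], scheme))
  names(summaries) <- use
  all_summary <- do.call(rbind, summaries)
  write_tsv(all_summary, file.path(d, "network_summary.tsv"))
  stats_rows <- list()
  for (ms in use) {
    sm <- summaries[[ms]]
    for (L in unique(sm$interaction)) {
      sub <- sm[sm$interaction == L, ]
      an <- rm_anova_2x2(sub)
      an$measure <- ms; an$interaction <- L; an$statistic <- "F"
      stats_rows[[length(stats_rows) + 1L]] <- an
      for (hf in c("first", "second")) {
        a <- sub$value[sub$drug == "drug" & sub$half == hf]
        b <- sub$value[sub$drug == "placebo" & sub$half == hf]
        names(a) <- sub$participant[sub$drug == "drug" & sub$half == hf]
        pc <- paired_contrast(a, b[match(names(a),
          sub$participant[sub$drug == "placebo" & sub$half == hf])])
        stats_rows[[length(stats_rows) + 1L]] <-
          data.frame(effect = paste0("drug_contrast_", hf), F = pc$t^2,
                     df1 = 1, df2 = pc$df, p = pc$p, pes = NA_real_,
                     measure = ms, interaction = L, statistic = "t",
                     t = pc$t, d = pc$d, stringsAsFactors = FALSE)
      }
    }
  }
  stats <- do.call(rbind, lapply(stats_rows, function(x) {
    if (!"t" %in% names(x)) { x$t <- NA_real_; x$d <- NA_real_ }
    x
  }))
  # Holm-Bonferroni across the interactions, within measure x effect
  stats$p_holm <- NA_real_; stats$reject <- NA
  for (ms in unique(stats$measure)) {
    for (eff in unique(stats$effect)) {
      sel <- stats$measure == ms & stats$effect == eff
      hb <- holm_bonferroni(stats$p[sel], config$alpha)
      stats$p_holm[sel] <- hb$p_holm
      stats$reject[sel] <- hb$reject
    }
  }
  write_tsv(stats, file.path(d, "network_stats.tsv"))
  # t-value matrices (network x network, within on the diagonal)
  for (ms in use) {
    for (hf in c("first", "second")) {
      tm <- t_matrix_from_stats(stats, scheme, ms,
                                paste0("drug_contrast_", hf))
      df <- data.frame(network = rownames(tm), as.data.frame(tm),
                       check.names = FALSE)
      write_tsv(df, file.path(d, paste0("tmatrix_", ms, "_", hf, ".tsv")))
    }
  }
  edges <- NULL
  if ("sfc_z" %in% names(matrices)) {
    z_cells <- z_cell_matrices(matrices$sfc_z)
    edges <- edge_threshold_contrast(z_cells, config$alpha)
    if (nrow(edges$stage2))
      write_tsv(edges$stage2, file.path(d, "edge_survivors.tsv"))
  }
  stage_log("networks", nrow(stats), " statistic rows, alpha = ",
            config$alpha)
  invisible(list(summary = all_summary, stats = stats, edges = edges))
}

t_matrix_from_stats <- function(stats, scheme, measure, effect) {
  nets <- scheme_networks(scheme)
  tm <- matrix(NA_real_, length(nets), length(nets),
               dimnames = list(nets, nets))
  sel <- stats$measure == measure & stats$effect == effect
  for (r in which(sel)) {
    L <- strsplit(stats$interaction[r], ":", fixed = TRUE)[[1]]
    if (L[1] == "within") {
      tm[L[2], L[2]] <- stats$t[r]
    } else {
      tm[L[2], L[3]] <- tm[L[3], L[2]] <- stats$t[r]
    }
  }
  tm
}

# stack per-cell participant x edge z matrices for edge thresholding
z_cell_matrices <- function(z_list) {
  participants <- unique(vapply(z_list, function(m) attr(m, "participant"), ""))
  out <- lapply(CELL_LEVELS, function(cl) {
    rows <- lapply(participants, function(p) {
      key <- paste(p, cl, sep = ".")
      upper_vec(unclass(z_list[[key]]))
    })
    m <- do.call(rbind, rows)
    rownames(m) <- participants
    m
  })
  names(out) <- CELL_LEVELS
  out
}

#' Stage 4: connectome-based classification
#'
#' Builds per-measure connectome features (static connectivity on the
#' Fisher-z scale), runs the leave-two-participant-out PLS-DA
#' cross-validation on the whole-brain connectome of each measure, and
#' (optionally) the 36-interaction network-model sweep. Writes confusion
#' matrices, the tidy d-prime table, and the per-fold prediction log.
#'
#' @param config A [run_config()].
#' @param matrices Output of [pipe_connectivity()] (recomputed when
#'   `NULL`).
#' @param study Optional `fc_study` for the scheme.
#' @return List per measure with the whole-brain `classification_report`
#'   and, when `config$sweep`, the sweep table, invisibly.
#' @export
pipe_classify <- function(config, matrices = NULL, study = NULL) {
  if (is.null(study))
    study <- read_study(config$data_dir %||% file.path(config$out_dir, "scans"),
                        split = config$split)
  if (is.null(matrices)) matrices <- pipe_connectivity(config, study)
  d <- stage_dir(config, "classify")
  use <- setdiff(names(matrices), "sfc_r")
  out <- list()
  dprime_rows <- list()
  for (ms in use) {
    feats <- connectome_features(matrices[[ms]])
    rep <- run_cv(feats, config$ncomp)
    dp <- d_prime(rep)
    cm <- data.frame(true = rownames(rep$confusion),
                     as.data.frame(unclass(rep$confusion)),
                     check.names = FALSE)
    write_tsv(cm, file.path(d, paste0("confusion_", ms, ".tsv")))
    write_tsv(rep$predictions, file.path(d, paste0("predictions_", ms, ".tsv")))
    dprime_rows[[length(dprime_rows) + 1L]] <-
      data.frame(measure = ms, interaction = "whole-brain",
                 n_features = ncol(feats$x), accuracy = rep$accuracy,
                 hit = dp$hit, fa = dp$fa, d_prime = dp$d_prime,
                 d_prime_floored = max(dp$d_prime, 0),
                 stringsAsFactors = FALSE)
    out[[ms]] <- list(report = rep)
    if (config$sweep) {
      sw <- network_model_sweep(feats, study$scheme, config$ncomp)
      sw$measure <- ms
      dprime_rows[[length(dprime_rows) + 1L]] <-
        sw[, c("measure", "interaction", "n_features", "accuracy", "hit",
               "fa", "d_prime", "d_prime_floored")]
      out[[ms]]$sweep <- sw
    }
  }
  dtab <- do.call(rbind, dprime_rows)
  write_tsv(dtab, file.path(d, "dprime.tsv"))
  stage_log("classify", length(use), " measures, ncomp = ", config$ncomp)
  out$dprime <- dtab
  invisible(out)
}

#' Stage 5: assemble a run summary
#'
#' Collects the network statistics, edge-survivor lists, confusion
#' matrices and d-prime tables written by earlier stages into one summary
#' TSV under `out_dir/report`.
#'
#' @param config A [run_config()].
#' @return Data.frame summary, invisibly.
#' @export
pipe_report <- function(config) {
  d <- stage_dir(config, "report")
  rows <- list()
  sp <- file.path(config$out_dir, "networks", "network_stats.tsv")
  if (file.exists(sp)) {
    st <- read_tsv(sp)
    sig <- st[!is.na(st$reject) & st$reject, , drop = FALSE]
    rows[[length(rows) + 1L]] <- data.frame(
      section = "network_stats",
      item = "tests surviving Holm-Bonferroni",
      value = nrow(sig), detail = paste0("of ", nrow(st)),
      stringsAsFactors = FALSE)
    if (nrow(sig)) {
      rows[[length(rows) + 1L]] <- data.frame(
        section = rep("network_stats", nrow(sig)),
        item = paste0(sig$measure, " ", sig$interaction, " ", sig$effect),
        value = sig$F, detail = paste0("p_holm=", signif(sig$p_holm, 3)),
        stringsAsFactors = FALSE)
    }
  }
  dp <- file.path(config$out_dir, "classify", "dprime.tsv")
  if (file.exists(dp)) {
    dt <- read_tsv(dp)
    rows[[length(rows) + 1L]] <- data.frame(
      section = "classification",
      item = paste0(dt$measure, " ", dt$interaction),
      value = dt$d_prime,
      detail = sprintf("accuracy=%.3f hit=%.3f fa=%.3f", dt$accuracy,
                       dt$hit, dt$fa),
      stringsAsFactors = FALSE)
  }
  ep <- file.path(config$out_dir, "networks", "edge_survivors.tsv")
  if (file.exists(ep)) {
    ed <- read_tsv(ep)
    rows[[length(rows) + 1L]] <- data.frame(
      section = "edges",
      item = paste0("stage2 survivors (", c("first", "second"), " half)"),
      value = c(sum(ed$half == "first"), sum(ed$half == "second")),
      detail = "", stringsAsFactors = FALSE)
  }
  if (!length(rows))
    stop("no stage outputs found under ", config$out_dir,
         "; run the earlier stages first")
  summary <- do.call(rbind, rows)
  write_tsv(summary, file.path(d, "summary.tsv"))
  stage_log("report", nrow(summary), " summary rows")
  invisible(summary)
}
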