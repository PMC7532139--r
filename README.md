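# fcpipe

Static, dynamic, and entropic functional-connectivity pipelines for
within-subject pharmacological neuroimaging designs.

## The problem

Placebo-controlled pharmaco-fMRI studies ask how a drug reshapes the
coupling between brain regions. A single correlation per region pair
("static" connectivity) misses two aspects of that coupling: how much it
*fluctuates* over a scan and how *unpredictable* its distribution of
states is. `fcpipe` computes all three measures from region-of-interest
timeseries and carries them through the statistics and classification
analyses typical of such studies:

* **sFC** — static functional connectivity: Pearson *r* between the
  timeseries of every node pair, analysed as *z* = arctanh(*r*).
* **dFC** — dynamic functional connectivity: each edge's time-resolved
  conditional correlation *R_t* is estimated with a bivariate DCC-GARCH
  model (GARCH(1,1) per node, DCC(1,1) per edge, two-stage Gaussian
  quasi-maximum likelihood), and dFC is var(*R_t*). Unlike sliding
  windows, DCC needs no arbitrary window length.
* **eFC** — entropic functional connectivity: a bin-width-corrected
  histogram estimate of the differential entropy of the same series,
  *H*(X) = −Σᵢ f(xᵢ) ln( f(xᵢ) / w(xᵢ) ) in nats, with f the bin
  proportions and w the bin width (default 60 bins).

Downstream, edges are averaged to a node→network scheme (8 networks give
8 within-network sets plus 28 between-network pairs, 36 "interactions"),
each interaction is tested with a 2×2 within-subject drug-by-time ANOVA
(partial η², Holm–Bonferroni over the 36 comparisons), individual edges
are thresholded by Bonferroni-corrected one-sample t-tests and contrasted
between drug conditions, and vectorised connectomes are classified with
PLS discriminant analysis under leave-two-participant-out
cross-validation (12 participants → 66 folds), summarised by confusion
matrices and the signal-detection discrimination score
d′ = Φ⁻¹(hit) − Φ⁻¹(false alarm).

Because such studies rarely deposit raw data, the package ships a
synthetic-study generator with known ground truth (block network
covariance, AR(1) temporal autocorrelation, participant random effects,
injectable condition effects, optional time-varying correlation regimes)
so every stage can be validated end to end.

## Worked example

```r
library(fcpipe)

# a 12-participant study in which the drug lowers within-DMN coupling
# (z shift -0.10) during the first scan half
des <- study_design(n_participants = 12, n_nodes = 40,
                    timepoints_per_half = 400, seed = 2001)
eff <- condition_effect("DM", delta_z = -0.10, drug = "drug", half = "first")
st  <- simulate_study(des, effect = eff)

z <- lapply(st$scans, function(s) fisher_z(static_fc(s)))   # sFC (z scale)
summ <- network_summary(z, st$scheme)

dm <- summ[summ$interaction == "within:DM", ]
rm_anova_2x2(dm)
#>        effect        F df1 df2            p       pes
#> 1        drug 47.34795   1  11 2.653264e-05 0.8114758
#> 2        time 39.20484   1  11 6.161269e-05 0.7808976
#> 3 interaction 35.26608   1  11 9.752542e-05 0.7622448

paired_contrast(dm$value[dm$drug == "placebo" & dm$half == "first"],
                dm$value[dm$drug == "drug" & dm$half == "first"])
#>   mean_diff        t df            p        d      ci_lo     ci_hi
#> 1 0.1024004 7.556198 11 1.119141e-05 2.181287 0.07257301 0.1322278
```

The interaction F(1, 11) tests whether the drug effect differs between
scan halves; the paired contrast shows a strong first-half attenuation
of within-DMN connectivity (Cohen's d ≈ 2.2 here, because the injected
effect is recovered almost noiselessly at T = 400). The
classification sweep then identifies *where* the signal lives:

```r
feats <- connectome_features(z)
sweep <- network_model_sweep(feats, st$scheme)
head(sweep[order(-sweep$d_prime), c("interaction", "d_prime", "hit", "fa")], 3)
#>          interaction   d_prime       hit         fa
#> 3          within:DM 3.3671305 0.9772727 0.08585859
#> 34 between:MedV:OccP 0.6425737 0.5151515 0.27272727
#> 2          within:FP 0.6314597 0.5227273 0.28282828
```

The within-DMN model attains the top d′ by a wide margin, as it should
when the truth is injected only there.

## Command-line pipeline

```sh
Rscript inst/cli/fcpipe.R simulate     --out-dir run1 --seed 1
Rscript inst/cli/fcpipe.R connectivity --out-dir run1 --measures sfc,dfc,efc
Rscript inst/cli/fcpipe.R networks     --out-dir run1
Rscript inst/cli/fcpipe.R classify     --out-dir run1
Rscript inst/cli/fcpipe.R report      --out-dir run1
```

All inputs and outputs are TSV (scans, design table, network map, square
matrices, tidy statistics, confusion matrices, d′ tables); every stage
writes a YAML copy of its configuration, and reruns with the same seed
and config are byte-identical.

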