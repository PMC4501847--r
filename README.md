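# apavar

Cell-to-cell variability in alternative polyadenylation (APA) isoform
choice from single-cell 3' tag sequencing.

## What it is for

Most genes carry several polyadenylation (PA) sites; each transcript
commits to one, so every cell splits a gene's mRNA pool between 3'
isoforms. In single-cell 3' tag data the observed split is a noisy readout
of the cell's underlying *isoform preference*: molecule numbers fluctuate
(expression noise), molecules are allocated to isoforms at random even
under a fixed preference (partitioning noise), and only ~5% of molecules
are captured and sequenced (technical noise). `apavar` is for researchers
who want to know whether, after accounting for all three noise layers,
cells of a homogeneous population still differ in their isoform
preferences — and whether such differences are coordinated across genes.

The package provides:

* a **read-tag pipeline** — UMI collapsing (Hamming-distance merging),
  internal-priming filters, greedy PA-site discovery with a 12-bp merge
  window, 20-kb downstream gene assignment, per-cell molecule count
  matrices (`run_pa_pipeline()` and its individual steps);
* **capture-efficiency calibration** from RNA spike-ins, as an
  origin-constrained regression of observed on known molecule counts
  (`estimate_capture_efficiency()`), plus the binomial-subsampling noise
  simulation (`simulate_subsampling_correlation()`);
* the **hierarchical Bayesian preference model**: observed totals
  `K_gc ~ NegBin(mu_g * beta_c, cv_g)` and splits
  `k1 | K ~ Binomial(K, p_gc)` with `logit p_gc ~ N(eta_g, sigma^2)`;
  `sigma = 0` is the shared-preference model, and the posterior of
  `sigma^2` quantifies true preference variability. Fitting is by MCMC
  (JAGS) on the exact collapsed likelihood, with DIC model comparison
  (`fit_preference_model()`, `compute_dic()`);
* a **one-factor extension** that clusters cells by coordinated shifts in
  isoform preference, independent of expression level
  (`fit_factor_model()`, `detect_correlated_component()`,
  `project_preferences_pca()`);
* **frequentist companions**: per-gene partition-null variance tests with a
  binomial enrichment test, a bootstrap-calibrated Kolmogorov-Smirnov test
  for direct (smFISH-style) molecule counts, and Fisher tests for 3' UTR
  lengthening between pooled populations.

Everything takes and returns tibbles, chains with the pipe, and has
broom-style `tidy()`/`glance()` and `autoplot()` methods. A thin CLI lives
in `exec/apavar`. The methods vignette
(`vignettes/isoform-preference-variability.Rmd`) documents the model,
priors, numerical choices and limitations.

## Worked example

Simulate a study at realistic scale (80 two-isoform genes, 30 cells,
capture efficiencies around 5.4%, true preference SD 0.7 on the logit
scale, i.e. variance 0.49), then fit both models:

```r
library(apavar)

sim <- simulate_study(n_genes = 80, n_cells = 30, sigma = 0.7, seed = 42)
eff <- tibble::tibble(cell_id = sim$truth$cells, beta = sim$truth$beta)

fit <- fit_preference_model(sim$counts, beta = eff, model = "variable",
                            chains = 2, adapt = 500, burn = 500,
                            iter = 1500, thin = 3, seed = 42)
fit
#> Hierarchical isoform preference fit (variable preference)
#>   genes: 80, cells: 30, kept draws: 1000
#>   preference variance (posterior mean of sigma^2): 0.5568
#>   max split-Rhat: 1.013
```

The posterior mean of the preference variance, 0.56, recovers the
generating value 0.49 at this modest data size; the remaining gap shrinks
with more genes and cells (at 493 genes it is a few percent). Model
comparison strongly prefers the variable-preference model on these data:

```r
sh <- fit_preference_model(sim$counts, beta = eff, model = "shared",
                           chains = 2, adapt = 500, burn = 500,
                           iter = 1500, thin = 3, seed = 42)
compute_dic(sh)$dic - compute_dic(fit)$dic
#> [1] 2258.7
```

(positive = variable preferred). The frequentist check agrees — most genes'
observed ratio variance exceeds the random-partitioning null:

```r
nt <- partition_null_variance_test(sim$counts, n_sim = 1000, seed = 42)
sum(nt$exceeds); nrow(nt)
#> [1] 74
#> [1] 80
enrichment_binomial_test(nt$exceeds)
#> [1] 2.7e-16
```

`autoplot(fit)` shows the posterior of `sigma^2`; `plot_variance_test(nt)`
contrasts observed and null variances per gene.

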