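# marshBN

Habitat-association analysis of tidal-marsh small-mammal trap surveys with
discrete Bayesian networks.

The endangered salt marsh harvest mouse (*Reithrodontomys raviventris*,
code RERA) is endemic to San Francisco Bay tidal marshes. Surveys of its
habitat produce per-trap-night case files — one record per trap per night,
with the capture outcome (one of nine small-mammal species, or `TRAP` for
no capture) and environmental covariates of the trap location: elevation,
tidal datums (MHW/MHHW), vegetation cover and height of the dominant
plants (typically pickleweed, *Salicornia pacifica*), distances to levees,
water, bay, urban areas, agriculture and roads, and marsh patch sizes.
Such data are zero-inflated (~73% empty traps), unevenly sampled, and
collinear, which frustrates classical occupancy models. This package
implements the alternative: tree-augmented naive Bayes (TAN) classifiers
learned from the case file, evaluated as a multi-model suite, and probed
with information-theoretic sensitivity analysis. It is written for
quantitative ecologists who want that workflow end-to-end, reproducibly,
with every step testable against a synthetic survey generator.

## What it computes

* **TAN models.** For response $C$ and discretized covariates $X_i$, links
  $C \to X_i$ plus a maximum-weight spanning tree over the covariates
  weighted by class-conditional mutual information
  $I(X_i;X_j\mid C)$ (bits). A TAN over $k \ge 2$ covariates has $2k-1$
  links; its probability-value count is
  $\sum_v |states(v)|\prod_{p\in pa(v)}|states(p)|$. CPTs are
  additive-smoothed frequency counts; inference is exact, with missing
  evidence marginalized over the covariate tree.
* **Discretization** into at most 5 states per covariate with ≥ 20
  training cases per state (equal-frequency seeding, support-driven
  merging).
* **Screening**: all pairwise Pearson correlations among the 13 continuous
  landscape covariates, with greedy elimination of covariates in flagged
  pairs (|r| > 0.75, p < .05).
* **Evaluation**: confusion tables with predicted-class denominators —
  Type I (false presence) = FP / all predicted-presence, Type II (false
  nonpresence) = FN / all predicted-nonpresence — overall multiclass
  error, spherical payoff $\mathrm{mean}(p_{true}/\lVert p\rVert_2)$,
  stratified 4-fold cross-validation, and entropy-reduction sensitivity
  $I(C;X)$.
* **The 38-model suite**: 19 covariate-set combinations (trap design,
  latitude–longitude, vegetation, elevation, distances, patch size) × two
  responses (RERA presence; all nine species), Pareto-ranked by accuracy
  and complexity.
* **Species habitat comparison**: Welch t tests with Bonferroni adjustment
  and variance-ratio F tests between capture sites of two species.
* **Synthetic surveys**: a seeded generator with a latent-Gaussian copula
  for correlated covariates and planted logistic habitat effects on RERA,
  so every stage above can be exercised and validated offline.

## Worked example

```r
library(marshBN)

cfg <- sim_config(n_sites = 6, traps_per_site = 25, nights = 20, seed = 33)
cf  <- simulate_trap_survey(cfg)
cf
#> Trap-survey case file: 3000 cases, 32 catalog covariates
#> Outcomes: TRAP=2223, MICA=350, RERA=187, MUMU=109, PEMA=99, SOOR=19, REME=7, RANO=5, RE=1

screen_covariates(cf)
#> Correlation screen: 78 pairs, 6 flagged
#> Eliminated: Dist_Ag, Dist_Urban, MHHW
#> Retained: 10 covariates

mc      <- to_model_cases(cf, response_spec("rera_presence"))
covs    <- variant_covariates(suite_spec(), 7)        # patch-size variant
schemes <- fit_schemes(mc, covs)
cases   <- discretize_cases(mc, schemes, response_spec("rera_presence")$states)
fit     <- learn_cpts(learn_tan_structure(cases, covs), cases)
evaluate_model(fit, cases)
#> Model evaluation (777 cases, focal RERA): overall 22.7%, Type I 40.7%, Type II 21.2%, spherical payoff 0.821
#> Complexity: 3 nodes / 3 links / 62 probabilities

sensitivity_report(fit)
#>             covariate entropy_reduction
#> 1 Patch_Size_Expanded       0.053619380
#> 2          Patch_Size       0.007452496
```

Reading the output: the correlation screen drops the tidal-datum duplicate
(MHHW) and the urban/agriculture distance pair, leaving 10 covariates. The
patch-size model is a 3-node TAN with 62 probability values. Its overall
calibration error (22.7%) sits near the always-nonpresence floor (the RERA
share of captures), Type I error is the fraction of predicted presences
that were wrong, and the sensitivity table ranks expanded patch size —
the generator's planted driver — first.

The full analysis is scripted under `analysis/`:

```sh
Rscript analysis/01_simulate.R           # synthetic survey -> results/cases.csv
Rscript analysis/02_screen.R             # 78 correlations, greedy elimination
Rscript analysis/03_suite.R              # the 38-model suite + frontier
Rscript analysis/04_validate.R           # 4-fold CV + sensitivity of selected models
Rscript analysis/05_species_comparison.R # RERA vs MICA habitat attributes
```

Stages read their inputs from `results/`, so run them in order. A
YAML-configured one-shot driver is also available:
`run_pipeline(read_run_config("config.yaml"))`.

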