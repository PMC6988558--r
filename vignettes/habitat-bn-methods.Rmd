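---
title: "Bayesian-network habitat association analysis for tidal-marsh trap surveys"
author: "marshBN"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Bayesian-network habitat association analysis for tidal-marsh trap surveys}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(marshBN)
```

## The problem and the modelling approach

Monitoring of the endangered salt marsh harvest mouse (*Reithrodontomys
raviventris*, code RERA) in San Francisco Bay tidal marshes yields
per-trap-night records: a trap is set for one night, and the outcome is
either a capture of one of nine small-mammal species or an empty trap
(`TRAP`). Capture rates are low (roughly 73% of trap nights are empty and
RERA makes up about a fifth of the captures), effort is uneven across sites
and years, animals are not individually marked across efforts, and the
environmental covariates are strongly collinear. Those properties make
classical occupancy models a poor fit, which is why this package models the
data with discrete Bayesian networks (BNs): probabilistic classifiers that
tolerate missing covariate values, collinearity, and zero-inflated outcomes,
and whose conditional-probability tables (CPTs) are learned directly from
the case file by frequency counting.

Two response variables are analysed:

* `rera_presence` — two states, `RERA` vs `NOTRERA` (any other capture);
* `all_species` — the nine capture species, including the genus-level
  `RE` record for *Reithrodontomys* captures not assignable to species.

Empty trap nights never enter the models: `to_model_cases()` reduces a
survey case file to its capture records (and relabels them for the binary
response). The nine-state vocabulary keeps `RE` as its own state because the
site-level capture table has nine capture rows and the probability-count
arithmetic of the two-covariate nine-state model (279 CPT cells) requires a
nine-state response.

## Model form: naive Bayes and its tree augmentation

For response $C$ and discretized covariates $X_1,\dots,X_k$, a naive BN
links $C \to X_i$ for every $i$ and assumes the $X_i$ conditionally
independent given $C$. The tree-augmented naive Bayes (TAN) form relaxes
that by allowing each covariate one extra covariate parent, with the extra
links forming the maximum-weight spanning tree over the class-conditional
mutual information

$$I(X_i;X_j \mid C)=\sum_{x_i,x_j,c} P(x_i,x_j,c)\,
\log_2\frac{P(x_i,x_j\mid c)}{P(x_i\mid c)P(x_j\mid c)},$$

estimated from the cases complete in all three variables
(`conditional_mutual_information()`, bits). The tree is built by Kruskal's
algorithm on the negated weights; ties are broken by lexicographic edge
name and the tree is oriented outward from the first covariate in catalog
order, so structures are exactly reproducible. A TAN over $k \ge 2$
covariates always has $2k-1$ links; the number of probability values is
$\sum_v |states(v)| \prod_{p \in parents(v)} |states(p)|$, counting the
response prior. Those two identities generate the complexity bookkeeping
(`complexity()`) reported for every model.

CPT learning (`learn_cpts()`) is additive-smoothed frequency counting:
each row is $(n_{x,pa}+\alpha)/(n_{pa}+\alpha|states|)$, with available-case
counting per CPT family (a case missing a value contributes to every family
it is complete for) and uniform rows for never-observed parent
configurations. The default $\alpha=1$ is a mild uniform prior emulating an
experience-table initialisation; $\alpha=0$ gives pure empirical
frequencies and is used by the oracle tests. No EM is attempted: missing
data are rare outside the vegetation covariates, and available-case
counting keeps learning deterministic and auditable.

Inference (`posterior()`) is exact. Given the class, the covariates form a
forest, so missing evidence is summed out by a single child-to-parent
message pass; the tests verify the factored posterior against brute-force
enumeration of the full joint on randomly generated small models.
Prediction is the posterior argmax with ties going to the earlier response
state.

## Discretization

Continuous covariates are cut into at most five ordered states
(`fit_scheme()`). Seeding is by equal-frequency quantiles — the support
requirement ("about 20 or more training cases per state") is a frequency
criterion, and equal-width bins on skewed distance covariates would starve
the tails — with the initial state count capped at
$\lfloor n/\texttt{min\_support}\rfloor$ so that small samples start from
fewer bins; smallest-support bins are then merged into their lower-count
neighbour until every state is supported. Cut values snap to midpoints
between adjacent distinct data values, intervals are half-open $[a,b)$ with
terminal clamping (a boundary value belongs to the upper bin; out-of-range
values join the terminal bins), and missing values stay missing.
Categorical covariates pass through with native labels, capped at the five
most frequent plus `other`. The choice of an unsupervised, response-blind
discretizer is deliberate: supervised (entropy-based) cuts would leak the
response into the covariate representation that the suite then evaluates.

## Covariate screening and the model suite

Before modelling, the 13 continuous landscape covariates (elevation,
tidal-datum, distance, and patch-size variables; vegetation covariates are
too sparse to screen) go through all 78 pairwise Pearson correlations.
Pairs with $p<.05$ and $|r|>0.75$ flag their covariates, and
`screen_covariates()` eliminates greedily: repeatedly drop the covariate in
the most flagged pairs, breaking ties by larger mean $|r|$ and then by
dropping the covariate later in catalog order (so the first-listed variable
of a tied pair — e.g. MHW over MHHW — is kept). Under the generator's
default correlation structure this removes MHHW and the urban- and
agriculture-distance covariates, a 13-to-10 reduction.

The suite (`suite_spec()`, `build_suite()`) evaluates 19 combinations of
seven covariate sets — C1 trap design (site, year, session, layout, trap
position), C2 latitude–longitude, C3 dominant-plant vegetation, C4 extended
vegetation, C5 elevation, C6 distances, C7 patch sizes — for each response:
38 TAN models. Set sizes are chosen so the variant node counts match the
published evaluation tables (C1 five covariates, C3 four, C4 twelve, C5
four, C6 four, C7 two); the distance-only variants (models 6 and 25) use
the documented single-covariate form, distance to paved roads, because the
published two-node complexity of those models is inconsistent with a
four-covariate distance set. Both facts are configuration, not code:
`set_overrides` and `single_covariate_variants` let a user restate them.

## Evaluation metrics

`evaluate_model()` runs a model over every case and partitions error with
the predicted-class denominators used throughout the analysis:

* Type I (false presence) $=\;$ #(predicted focal, actually not) / #(predicted focal);
* Type II (false nonpresence) $=\;$ #(predicted non-focal, actually focal) / #(predicted non-focal);
* overall error is plain misclassification and stays multiclass for the
  nine-state response while Type I/II binarize on RERA — the only reading
  under which a nine-state model can show ~49% overall error beside a 20%
  Type II error.

A model that never predicts presence has an empty Type I denominator; the
rate is reported as 0 with an explicit `undefined` flag, matching the
convention of printing 0% for such models. On a 3,339-case composition with
669 focal positives, the always-nonpresence baseline therefore scores 0%
Type I, 20% Type II, and 20% overall — the structural floor any useful
model must beat.

Spherical payoff is the mean over cases of
$p_{true}/\lVert p\rVert_2$ for the case's posterior $p$: 1 for certain
correct posteriors, 0 for certain wrong ones, $1/\sqrt2 \approx 0.707$ for
uniform binary posteriors. For nine-state models it is computed on the full
nine-state posterior; a RERA-binarized alternative would give different
values and is intentionally not the default.

Cross-validation (`kfold_cv()`, default $k=4$, seed 42) assigns shuffled
cases round-robin to folds, continuing the cycle across outcome classes so
per-class and overall fold sizes both differ by at most one; structure and
CPTs are relearned on each training split and the held-out confusion tables
are pooled before computing metrics. Entropy-reduction sensitivity
(`entropy_reduction()`) is the mutual information $I(C;X)$ under the
model's own joint, obtained by exact marginalization, and is bounded by the
response entropy $H(C)$.

Model ranking (`rank_models()`) keeps the non-dominated set under Type I
error, overall error, spherical payoff, and probability count, with a 0.01
indifference tolerance on the three accuracy metrics. Domination requires
an accuracy improvement beyond tolerance; complexity only vetoes (a bigger
model cannot dominate) and breaks the final advisory selection
(`select_models()`: minimal Type I, then overall error, then probability
count). Applied to the published RERA-presence evaluation table, this rule
keeps the three reported best models (location-only, road-distance-only,
patch-size-only) on the frontier. Model selection here is acknowledged to
be partly subjective; the frontier is the objective output, the selection a
convenience.

## The synthetic survey generator

`simulate_trap_survey()` emulates the survey's statistical structure so the
whole pipeline is testable without the deposited data: about 12,400 trap
nights (6 sites × 45 traps × 46 nights), empty-trap probability 0.731, the
published nine-species capture mix (RERA 669/3,339), and location-level
covariates drawn once per trap and replicated over nights. Correlated
continuous covariates are realized through a latent Gaussian copula: a
target correlation matrix (identity plus configured blocks) is Cholesky
factored, latent normals transformed to uniforms, and each margin shaped by
its configured quantile function. Non-positive-definite targets are
rejected. The default blocks plant the tidal-datum pair (MHW–MHHW, $r=.99$)
and an urban/agriculture/road/bay distance cluster whose implied
cross-correlations are spelled out to keep the matrix feasible; these
produce the 13→10 screening reduction described above. Distance margins are
near-Gaussian with a rare zero clamp because strongly skewed margins
mathematically cannot carry $|r| \approx 0.9$ (copula correlations attenuate
through skewed marginals); patch sizes, which sit in no block, stay
lognormal. Default marginal locations and spreads are chosen as typical of
North-Bay marshes (e.g. pickleweed cover centred at 86%, mean height 37 cm,
MHW near 1.8 m); they are configuration, not estimates.

RERA presence is planted through a logistic tilt: given a capture, the RERA
share of the mix becomes
$\operatorname{logit}^{-1}(\operatorname{logit}(q_{RERA})+\beta^\top z)$
with $z$ the location's standardized covariates, and the other species are
scaled proportionally. The default drivers are expanded patch size,
distance to roads, and longitude — the habitat story the analysis should
recover. `planted_truth()` exposes exactly the configured coefficients for
parameter-recovery tests. With nonzero effects the *marginal* RERA share
exceeds its configured 20% (Jensen's inequality on the logistic); tests of
the 20% share therefore use the null-effect configuration, and margin
arithmetic uses the published tables directly.

What the generator does **not** emulate: spatial marsh geometry and tide
dynamics, temporal trends, trap-level autocorrelation beyond the shared
location covariates, and observation error in covariates. Passing tests on
synthetic data therefore demonstrate correctness of the machinery and
recoverability of planted structure, not ecological validity on real
surveys.

## Numerical and design choices

* Log base 2 throughout; information quantities are in bits.
* Posterior computation works in log space with a floor at the smallest
  positive double before exponentiation, so long products cannot underflow.
* Welch's unequal-variance t is used for the species comparison (the safer
  default when only "unpaired" is specified); `variance_f()` reports the
  larger/smaller variance ratio with a two-sided p so users can check the
  equal-variance assumption. The Bonferroni multiplier is the number of
  covariates in the comparison, not the number of tests in the study.
  With groups ordered (MICA, RERA), negative t marks RERA-higher variables.
* Case files serialize as CSV with `*` (or empty) for missing; schemes and
  models serialize as JSON with exact round-trips.
* Problem sizes in the shipped analysis scripts: the full synthetic survey
  (12,420 trap nights, ~3,300 capture cases) for the suite and validation
  stages; the test suite exercises the same code on a 3,000-night survey,
  which is ample for every structural property checked.

## Known limitations

* Exact inference relies on the TAN forest structure; general DAGs are out
  of scope, as are structure scores (hill-climbing, AIC-style criteria —
  the latter are not applicable to BN classifier selection here).
* Discretization is unsupervised; the exact bin edges of the original
  analysis are unrecoverable without the deposited data, so published
  per-model error percentages are emulated structurally (baselines,
  complexity laws, margins) rather than numerically.
* Available-case CPT learning is biased when missingness is informative;
  the generator's missingness is benign (vegetation plots sparse at
  random).
* The greedy screening rule reproduces the reported eliminations under the
  default correlation structure, but other flagged-pair graphs may admit
  several defensible elimination orders; the rule is deterministic, not
  unique.
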