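#!/usr/bin/env Rscript
# Stage 4: validity of the selected RERA-presence models: stratified 4-fold
# cross-validation (overfit check: CV metrics should track calibration
# metrics) and entropy-reduction sensitivity of each selected model.

library(marshBN)

cf <- read_case_file("results/cases.csv")
suite <- build_suite(cf, suite_spec(cf$catalog))
mc <- to_model_cases(cf, response_spec("rera_presence"))
spec <- suite_spec(cf$catalog)

sel <- intersect(suite$selected, 1:19)
if (!length(sel)) sel <- intersect(suite$frontier, 1:19)
cv_rows <- NULL
for (id in sel) {
  covs <- variant_covariates(spec, id)
  schemes <- fit_schemes(mc, covs)
  cases <- discretize_cases(mc, schemes, response_spec("rera_presence")$states)
  ev <- kfold_cv(cases, covs, k = 4, seed = 42)
  calib <- suite$rows[suite$rows$id == id, ]
  cat(sprintf("model %d: calibration overall %.1f%% vs CV %.1f%%; Type I %.1f%% vs %.1f%%\n",
              id, 100 * calib$overall_error, 100 * ev$overall_error,
              100 * calib$type1_error, 100 * ev$type1_error))
  cv_rows <- rbind(cv_rows, data.frame(
    id = id, cv_overall = ev$overall_error, cv_type1 = ev$type1_error,
    cv_type2 = ev$type2_error, cv_spherical = ev$spherical_payoff,
    calib_overall = calib$overall_error))
}
write.csv(cv_rows, "results/crossvalidation.csv", row.names = FALSE)

sens <- NULL
for (id in suite$selected) {
  rep_ <- sensitivity_report(suite$models[[as.character(id)]])
  cat("model", id, "entropy reduction ranking:",
      paste(rep_$covariate, collapse = " > "), "\n")
  sens <- rbind(sens, cbind(id = id, rep_))
}
write.csv(sens, "results/sensitivity.csv", row.names = FALSE)
cat("Wrote results/crossvalidation.csv and results/sensitivity.csv\n")
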