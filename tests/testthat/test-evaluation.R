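test_that("error partitioning uses predicted-class denominators", {
  m <- forced_prediction_model()
  # actual x signal counts force the confusion table:
  # TP 10 (RERA,pos), FP 5 (NOTRERA,pos), FN 2 (RERA,neg), TN 83
  cases <- data.frame(
    signal = factor(rep(c("pos", "pos", "neg", "neg"), c(10, 5, 2, 83)),
                    levels = c("pos", "neg")),
    outcome = factor(rep(c("RERA", "NOTRERA", "RERA", "NOTRERA"),
                         c(10, 5, 2, 83)), levels = c("RERA", "NOTRERA")))
  ev <- evaluate_model(m, cases)
  expect_equal(ev$n_cases, 100)
  expect_equal(sum(ev$confusion), 100)
  expect_equal(ev$type1_error, 5 / 15)
  expect_equal(ev$type2_error, 2 / 85)
  expect_equal(ev$overall_error, 7 / 100)
  expect_length(ev$undefined, 0)
  # perfect predictor
  perfect <- cases[cases$outcome == "RERA" & cases$signal == "pos" |
                     cases$outcome == "NOTRERA" & cases$signal == "neg", ]
  evp <- evaluate_model(m, perfect)
  expect_equal(evp$overall_error, 0)
  expect_equal(evp$type1_error, 0)
  expect_equal(evp$type2_error, 0)
  expect_error(evaluate_model(m, cases[0, ]), "empty")
})

test_that("an always-nonpresence baseline shows the 0/20/20 pattern", {
  cf <- margins_to_cases()
  mc <- to_model_cases(cf, response_spec("rera_presence"))
  cases <- data.frame(outcome = factor(mc$cases$outcome,
                                       levels = c("RERA", "NOTRERA")))
  cases$x <- factor("all")  # uninformative covariate
  fit <- learn_cpts(learn_tan_structure(cases, "x"), cases)
  ev <- evaluate_model(fit, cases)
  expect_equal(ev$type1_error, 0)
  expect_equal(ev$undefined, "type1")  # never predicts presence
  expect_equal(round(100 * ev$type2_error), 20)
  expect_equal(round(100 * ev$overall_error), 20)
  expect_equal(ev$overall_error, 669 / 3339)
})

test_that("spherical payoff matches its closed forms", {
  m <- forced_prediction_model()
  sure <- function(p) array(c(p, 1 - p, 1 - p, p), c(2, 2),
                            dimnames = dimnames(m$cpts$signal))
  cases <- data.frame(signal = factor(c("pos", "neg", "pos"),
                                      levels = c("pos", "neg")),
                      outcome = factor(c("RERA", "NOTRERA", "RERA"),
                                       levels = c("RERA", "NOTRERA")))
  m$cpts$signal <- sure(1)           # posteriors certain and correct
  expect_equal(spherical_payoff(m, cases), 1)
  wrong <- cases
  wrong$outcome <- factor(c("NOTRERA", "RERA", "NOTRERA"),
                          levels = c("RERA", "NOTRERA"))
  expect_equal(spherical_payoff(m, wrong), 0)
  m$cpts$signal <- sure(0.5)         # uniform posterior every case
  expect_equal(spherical_payoff(m, cases), 1 / sqrt(2))
})

test_that("cross-validation folds are stratified and near-equal", {
  cases <- composition_cases()       # 669 of 3,339 focal
  ev <- kfold_cv(cases, "x", k = 4, seed = 42)
  folds <- attr(ev, "folds")
  expect_equal(sort(folds, decreasing = TRUE), c(835, 835, 835, 834))
  expect_equal(sum(ev$confusion), 3339)
  # per-fold focal count within one case of proportional prevalence
  fa <- attr(ev, "fold_assignment")
  focal_by_fold <- tapply(cases$outcome == "RERA", fa, sum)
  expect_true(all(abs(focal_by_fold - folds * 669 / 3339) <= 1))
  # deterministic given the seed
  ev2 <- kfold_cv(cases, "x", k = 4, seed = 42)
  expect_equal(ev$confusion, ev2$confusion)
  expect_equal(ev$spherical_payoff, ev2$spherical_payoff)
  # an uninformative covariate cross-validates like the baseline
  expect_equal(ev$overall_error, 669 / 3339, tolerance = 0.01)
  expect_error(kfold_cv(cases, "x", k = 1), "k >= 2")
})

test_that("leave-one-out is the k = n edge of the fold scheme", {
  small <- data.frame(
    x = factor(rep(c("lo", "hi"), 6), levels = c("lo", "hi")),
    outcome = factor(rep(c("RERA", "NOTRERA"), each = 6),
                     levels = c("RERA", "NOTRERA")))
  ev <- kfold_cv(small, "x", k = nrow(small), seed = 1)
  expect_equal(attr(ev, "folds"), rep(1L, 12))
  expect_equal(sum(ev$confusion), 12)
})

test_that("entropy reduction matches mutual-information closed forms", {
  m <- forced_prediction_model()
  flat <- array(c(0.6, 0.4, 0.6, 0.4), c(2, 2),
                dimnames = dimnames(m$cpts$signal))
  m$cpts$signal <- flat              # covariate independent of response
  expect_equal(entropy_reduction(m, "signal"), 0, tolerance = 1e-12)
  m$cpts$signal <- array(c(1, 0, 0, 1), c(2, 2),
                         dimnames = dimnames(m$cpts$signal))
  expect_equal(entropy_reduction(m, "signal"), 1)  # deterministic copy: H(Q)
  # hand-built joint (0.4, 0.1, 0.1, 0.4)
  m$cpts$signal <- array(c(0.8, 0.2, 0.2, 0.8), c(2, 2),
                         dimnames = dimnames(m$cpts$signal))
  joint <- c(0.4, 0.1, 0.1, 0.4)
  pq <- c(0.5, 0.5); pf <- c(0.5, 0.5)
  brute <- sum(joint * log2(joint / c(0.25, 0.25, 0.25, 0.25)))
  expect_equal(entropy_reduction(m, "signal"), brute)
  expect_error(entropy_reduction(m, "nosuch"), "not in model")
})

test_that("model-based entropy reduction equals empirical MI for naive fits", {
  for (s in 1:4) {
    set.seed(s)
    n <- 500
    cases <- data.frame(
      x = factor(sample(c("a", "b", "c"), n, TRUE)),
      outcome = factor(sample(c("RERA", "NOTRERA"), n, TRUE, c(0.35, 0.65)),
                       levels = c("RERA", "NOTRERA")))
    fit <- learn_cpts(learn_tan_structure(cases, "x"), cases, alpha = 0)
    # empirical MI of the observed (outcome, x) table
    tab <- table(cases$outcome, cases$x) / n
    mi <- 0
    for (i in seq_len(nrow(tab))) for (j in seq_len(ncol(tab)))
      if (tab[i, j] > 0)
        mi <- mi + tab[i, j] * log2(tab[i, j] /
                                      (sum(tab[i, ]) * sum(tab[, j])))
    expect_equal(entropy_reduction(fit, "x"), mi, tolerance = 1e-10)
  }
})

test_that("sensitivity reports are sorted and bounded by response entropy", {
  rs <- random_small_model(55)
  rep_ <- sensitivity_report(rs$model)
  expect_equal(nrow(rep_), length(rs$model$nodes))
  expect_true(all(diff(rep_$entropy_reduction) <= 1e-12))
  H <- attr(rep_, "response_entropy")
  expect_true(all(rep_$entropy_reduction >= -1e-12))
  expect_true(all(rep_$entropy_reduction <= H + 1e-12))
})
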