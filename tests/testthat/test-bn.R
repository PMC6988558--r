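test_that("conditional mutual information matches closed forms", {
  # xj independent of xi given c: CMI = 0
  grid <- expand.grid(a = c("a1", "a2"), b = c("b1", "b2"),
                      outcome = c("c1", "c2"), stringsAsFactors = FALSE)
  ind <- grid[rep(seq_len(8), times = rep(c(9, 3, 3, 1), 2)), ]
  expect_equal(conditional_mutual_information(ind, "a", "b"), 0,
               tolerance = 1e-12)
  # xj an exact copy of a uniform binary xi: CMI = H(Xi|C) = 1 bit
  copy <- data.frame(a = rep(c("a1", "a2"), 50),
                     outcome = rep(c("c1", "c2"), each = 50))
  copy$b <- copy$a
  expect_equal(conditional_mutual_information(copy, "a", "b"), 1)
  # 2x2x2 counts (4,1,1,4) per class vs brute-force sum
  cnt <- data.frame(a = rep(rep(c("a1", "a2"), 2), times = c(4, 1, 1, 4)),
                    b = rep(rep(c("b1", "b2"), each = 2), times = c(4, 1, 1, 4)))
  cases <- rbind(cbind(cnt, outcome = "c1"), cbind(cnt, outcome = "c2"))
  tab <- table(cases$a, cases$b, cases$outcome) / nrow(cases)
  brute <- 0
  for (i in 1:2) for (j in 1:2) for (k in 1:2) {
    pij_c <- tab[i, j, k] / sum(tab[, , k])
    pi_c <- sum(tab[i, , k]) / sum(tab[, , k])
    pj_c <- sum(tab[, j, k]) / sum(tab[, , k])
    if (tab[i, j, k] > 0)
      brute <- brute + tab[i, j, k] * log2(pij_c / (pi_c * pj_c))
  }
  expect_equal(conditional_mutual_information(cases, "a", "b"), brute)
  expect_error(conditional_mutual_information(
    data.frame(a = NA_character_, b = "b1", outcome = "c1"), "a", "b"),
    "complete")
})

test_that("TAN structures obey the link-count law", {
  set.seed(2)
  for (k in c(1, 2, 3, 5, 8)) {
    n <- 200
    cases <- as.data.frame(lapply(seq_len(k), function(i)
      factor(sample(c("lo", "hi"), n, TRUE))))
    names(cases) <- paste0("x", seq_len(k))
    cases$outcome <- factor(sample(c("RERA", "NOTRERA"), n, TRUE))
    skel <- learn_tan_structure(cases, paste0("x", seq_len(k)))
    expect_equal(nrow(skel$links), if (k >= 2) 2 * k - 1 else 1)
    expect_equal(length(skel$nodes) + 1, k + 1)
    # every covariate has the response as parent; at most one covariate parent
    for (nm in names(skel$nodes)) {
      expect_true("outcome" %in% skel$parents[[nm]])
      expect_lte(length(skel$parents[[nm]]), 2)
    }
    # acyclic within covariates: following parents terminates at the root
    for (nm in names(skel$nodes)) {
      seen <- character(); cur <- nm
      repeat {
        p <- setdiff(skel$parents[[cur]], "outcome")
        if (!length(p)) break
        expect_false(p %in% seen)
        seen <- c(seen, p); cur <- p
      }
    }
  }
})

test_that("structure induction is deterministic including MST ties", {
  set.seed(6)
  n <- 150
  cases <- data.frame(a = factor(sample(c("x", "y"), n, TRUE)),
                      outcome = factor(sample(c("RERA", "NOTRERA"), n, TRUE)))
  cases$b <- cases$a  # ties: b and c are identical copies of a
  cases$c <- cases$a
  s1 <- learn_tan_structure(cases, c("a", "b", "c"))
  s2 <- learn_tan_structure(cases, c("a", "b", "c"))
  expect_identical(s1$links, s2$links)
  expect_identical(s1$parents, s2$parents)
})

test_that("CPT learning reproduces frequencies and smooths correctly", {
  cases <- data.frame(
    x = factor(c("s1", "s1", "s1", "s2", "s1", "s2", "s2", "s2"),
               levels = c("s1", "s2")),
    outcome = factor(rep(c("RERA", "NOTRERA"), each = 4),
                     levels = c("RERA", "NOTRERA")))
  skel <- learn_tan_structure(cases, "x")
  # alpha 0: counts 3 of 4 -> 0.75
  fit0 <- learn_cpts(skel, cases, alpha = 0)
  expect_equal(unname(fit0$cpts$x[, "RERA"]), c(0.75, 0.25))
  # alpha 1: counts (3,1) -> (4/6, 2/6)
  fit1 <- learn_cpts(skel, cases, alpha = 1)
  expect_equal(unname(fit1$cpts$x[, "RERA"]), c(4 / 6, 2 / 6))
  # rows always normalize for any alpha
  for (al in c(0, 0.5, 1, 5)) {
    rs <- random_small_model(40 + al)
    fit <- learn_cpts(learn_tan_structure(rs$cases,
                                          setdiff(names(rs$cases), "outcome")),
                      rs$cases, alpha = al)
    for (nm in names(fit$nodes)) {
      sums <- apply(fit$cpts[[nm]], seq_along(dim(fit$cpts[[nm]]))[-1], sum)
      expect_true(all(abs(sums - 1) < 1e-9))
    }
  }
  # unseen parent configuration -> uniform row
  cases2 <- data.frame(
    x = factor(c("s1", "s2"), levels = c("s1", "s2")),
    outcome = factor(c("RERA", "RERA"), levels = c("RERA", "NOTRERA")))
  fit2 <- learn_cpts(learn_tan_structure(cases2, "x"), cases2, alpha = 0)
  expect_equal(unname(fit2$cpts$x[, "NOTRERA"]), c(0.5, 0.5))
})

test_that("posterior matches Bayes rule and the prior without evidence", {
  m <- forced_prediction_model()
  m$cpts$outcome <- c(RERA = 0.2, NOTRERA = 0.8)
  m$cpts$signal <- array(c(0.9, 0.1, 0.3, 0.7), c(2, 2),
                         dimnames = dimnames(m$cpts$signal))
  expect_equal(unname(posterior(m, list())), c(0.2, 0.8))
  p <- posterior(m, list(signal = "pos"))
  expect_equal(unname(p), c(0.18, 0.24) / 0.42, tolerance = 1e-12)
  expect_equal(predict(m, list(signal = "pos")), "NOTRERA")
  expect_error(posterior(m, list(signal = "sideways")), "invalid")
  expect_error(posterior(m, list(ghost = "pos")), "unknown")
})

test_that("factored posterior equals brute-force joint enumeration", {
  for (s in 1:8) {
    rs <- random_small_model(s)
    covs <- names(rs$model$nodes)
    # full evidence, partial evidence, and no evidence
    evs <- list(
      stats::setNames(lapply(covs, function(nm)
        sample(rs$model$nodes[[nm]], 1)), covs),
      stats::setNames(lapply(covs, function(nm)
        if (runif(1) < 0.5) NA else sample(rs$model$nodes[[nm]], 1)), covs),
      list())
    for (ev in evs) {
      expect_equal(unname(posterior(rs$model, ev)),
                   unname(brute_force_posterior(rs$model, ev)),
                   tolerance = 1e-10)
    }
  }
})

test_that("prediction breaks ties toward the earlier response state", {
  m <- forced_prediction_model()
  m$cpts$signal <- array(rep(0.5, 4), c(2, 2),
                         dimnames = dimnames(m$cpts$signal))
  expect_equal(predict(m, list(signal = "pos")), "RERA")  # uniform posterior
  cases <- data.frame(signal = factor(c("pos", "neg"),
                                      levels = c("pos", "neg")))
  expect_equal(predict(m, cases), c("RERA", "RERA"))
})

test_that("complexity counts nodes, links, and every CPT cell", {
  set.seed(30)
  mk_cases <- function(k, resp_states, n = 900) {
    cases <- as.data.frame(lapply(seq_len(k), function(i)
      factor(sample(paste0("s", 1:5), n, TRUE), levels = paste0("s", 1:5))))
    names(cases) <- paste0("x", seq_len(k))
    cases$outcome <- factor(sample(resp_states, n, TRUE),
                            levels = resp_states)
    cases
  }
  # naive, binary response, one 5-state covariate: 2 + 2*5 = 12
  c1 <- mk_cases(1, c("RERA", "NOTRERA"))
  m1 <- learn_cpts(learn_tan_structure(c1, "x1"), c1)
  expect_equal(complexity(m1), list(n_nodes = 2L, n_links = 1L,
                                    n_probabilities = 12L))
  # TAN, binary response, two 5-state covariates: 2 + 10 + 50 = 62
  c2 <- mk_cases(2, c("RERA", "NOTRERA"))
  m2 <- learn_cpts(learn_tan_structure(c2, c("x1", "x2")), c2)
  expect_equal(complexity(m2), list(n_nodes = 3L, n_links = 3L,
                                    n_probabilities = 62L))
  # TAN, 9-state response, two 5-state covariates: 9 + 45 + 225 = 279
  c9 <- mk_cases(2, paste0("sp", 1:9), n = 2000)
  m9 <- learn_cpts(learn_tan_structure(c9, c("x1", "x2")), c9)
  expect_equal(complexity(m9)$n_probabilities, 279L)
})

test_that("model JSON serialization round-trips exactly", {
  rs <- random_small_model(99)
  path <- withr::local_tempfile(fileext = ".json")
  write_bn(rs$model, path)
  back <- read_bn(path)
  expect_equal(back$response, rs$model$response)
  expect_equal(back$nodes, rs$model$nodes)
  expect_equal(back$parents, rs$model$parents)
  for (nm in names(rs$model$cpts))
    expect_equal(back$cpts[[nm]], rs$model$cpts[[nm]])
  ev <- stats::setNames(lapply(names(back$nodes), function(nm)
    back$nodes[[nm]][1]), names(back$nodes))
  expect_equal(posterior(back, ev), posterior(rs$model, ev))
})
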