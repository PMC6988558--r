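test_that("the default suite spec defines the 38-model grid", {
  spec <- suite_spec()
  expect_equal(nrow(spec$variants), 38)
  expect_equal(sum(spec$variants$response == "rera_presence"), 19)
  expect_equal(spec$variants$id, c(1:19, 20:38))
  # location-only variants use latitude and longitude alone
  expect_setequal(variant_covariates(spec, 2), c("latitude", "longitude"))
  expect_setequal(variant_covariates(spec, 21), c("latitude", "longitude"))
  # the distance-only variants take the documented single-covariate form
  expect_equal(variant_covariates(spec, 6), "Dist_Road")
  expect_equal(variant_covariates(spec, 25), "Dist_Road")
  # patch-size variant: the two patch covariates
  expect_setequal(variant_covariates(spec, 7),
                  c("Patch_Size", "Patch_Size_Expanded"))
  # expected node counts per variant (covariates + response)
  expected_nodes <- c(6, 3, 5, 13, 5, 2, 3, 9, 7, 7, 13, 11, 11, 15, 18,
                      16, 16, 20, 23)
  got <- vapply(1:19, function(id)
    length(variant_covariates(spec, id)) + 1L, 0L)
  expect_equal(got, expected_nodes)
  # both responses share covariate structure
  got2 <- vapply(20:38, function(id)
    length(variant_covariates(spec, id)) + 1L, 0L)
  expect_equal(got2, expected_nodes)
})

test_that("the fitted suite has 38 models with lawful link counts", {
  cs <- cached_suite()
  rows <- cs$suite$rows
  expect_equal(nrow(rows), 38)
  expect_equal(sum(rows$response == "rera_presence"), 19)
  k <- rows$n_nodes - 1
  expect_equal(rows$n_links, ifelse(k >= 2, 2 * k - 1, 1))
  # suite determinism: same case file in, same report out
  again <- build_suite(cs$cf)
  expect_equal(again$rows, rows)
  # complexity of the single-covariate distance variant is minimal
  m6 <- cs$suite$models[["6"]]
  cx <- complexity(m6)
  expect_equal(cx$n_nodes, 2)
  expect_equal(cx$n_links, 1)
})

test_that("an unknown covariate is reported with its variant", {
  cf <- tiny_case_file()
  spec <- suite_spec()
  expect_error(build_suite(cf, spec), "missing from case file")
})

test_that("Pareto ranking excludes dominated rows and keeps the best", {
  rows <- data.frame(
    id = 1:3, response = "rera_presence",
    n_probabilities = c(100, 100, 50),
    overall_error = c(0.30, 0.20, 0.20),
    type1_error = c(0.50, 0.10, 0.10),
    type2_error = 0.2,
    spherical_payoff = c(0.6, 0.8, 0.8))
  fr <- rank_models(rows)
  expect_false(1 %in% fr)   # strictly worse everywhere
  expect_true(3 %in% fr)
  expect_equal(rank_models(rows[3, ]), 3)
  expect_equal(select_models(rows), 3)  # fewer probabilities wins the tie
})

test_that("the printed complexity/accuracy pattern puts 2, 6, 7 on the frontier", {
  # the published RERA-presence evaluation rows, used as plain inputs
  rows <- data.frame(
    id = 1:19, response = "rera_presence",
    n_nodes = c(6, 3, 5, 13, 5, 2, 3, 9, 7, 7, 13, 11, 11, 15, 18, 16, 16, 20, 23),
    n_links = c(9, 3, 7, 22, 7, 1, 3, 15, 11, 11, 23, 19, 19, 27, 33, 29,
                29, 37, 43),
    n_probabilities = c(1400, 62, 272, 902, 170, 12, 62, 370, 262, 280, 682,
                        572, 612, 792, 4620, 4260, 4100, 5140, 1642),
    overall_error = c(19, 20, 20, 44, 20, 20, 20, 21, 21, 21, 22, 21, 21, 22,
                      19, 19, 19, 19, 47) / 100,
    type1_error = c(22, 0, 100, 79, 0, 0, 0, 56, 56, 56, 57, 56, 56, 57, 34,
                    33, 34, 35, 76) / 100,
    type2_error = c(19, 20, 20, 20, 20, 20, 20, 17, 17, 18, 17, 17, 18, 17,
                    19, 19, 19, 19, 15) / 100,
    spherical_payoff = c(0.849, 0.833, 0.828, 0.688, 0.832, 0.826, 0.832,
                         0.829, 0.827, 0.827, 0.825, 0.819, 0.819, 0.813,
                         0.840, 0.840, 0.841, 0.839, 0.634))
  fr <- rank_models(rows)
  expect_true(all(c(2, 6, 7) %in% fr))
  expect_false(4 %in% fr)
  expect_false(19 %in% fr)
  sel <- select_models(rows, fr)
  expect_equal(sel, 6)  # lowest-complexity member of the zero-Type-I group
})

test_that("suite reports round-trip through CSV", {
  cs <- cached_suite()
  path <- withr::local_tempfile(fileext = ".csv")
  paths <- write_suite_report(cs$suite, path)
  expect_length(paths, 2)
  back <- utils::read.csv(paths[1])
  expect_equal(nrow(back), 19)
  rera <- cs$suite$rows[cs$suite$rows$response == "rera_presence", ]
  expect_equal(back$overall_error, rera$overall_error)
  expect_equal(back$probabilities, rera$n_probabilities)
  # empty rows give a header-only file
  write_suite_report(cs$suite$rows[0, ], path)
  expect_equal(nrow(utils::read.csv(path)), 0)
})

test_that("a planted patch-size effect is recovered by the C7 variant", {
  cfg <- sim_config(n_sites = 6, traps_per_site = 25, nights = 20, seed = 77,
                    effects = c(Patch_Size_Expanded = 2.5))
  cf <- simulate_trap_survey(cfg)
  mc <- to_model_cases(cf, response_spec("rera_presence"))
  baseline <- mean(mc$cases$outcome == "RERA")  # majority-class error
  spec <- suite_spec()
  covs <- variant_covariates(spec, 7)
  schemes <- fit_schemes(mc, covs)
  cases <- discretize_cases(mc, schemes, response_spec("rera_presence")$states)
  fit <- learn_cpts(learn_tan_structure(cases, covs), cases)
  ev <- evaluate_model(fit, cases)
  expect_lt(ev$overall_error, baseline)
  sens <- sensitivity_report(fit)
  expect_equal(sens$covariate[1], planted_truth(cfg)$covariate)
  # and the full suite places the patch-size variant on the frontier
  suite <- build_suite(cf)
  expect_true(7 %in% suite$frontier)
})
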