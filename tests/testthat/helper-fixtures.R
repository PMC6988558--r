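# Shared fixtures and independent oracles for the test suite.

# A tiny catalog with two continuous and one categorical covariate.
tiny_catalog <- function() {
  covariate_catalog(
    covariate_def("elev", "elevation", "cm", "continuous", "C5"),
    covariate_def("dist", "distance", "m", "continuous", "C6"),
    covariate_def("veg", "dominant cover", "categorical", "categorical", "C3",
                  levels = c("pickleweed", "bare", "grass")))
}

# Deterministic 100-case file exercising values and missingness.
tiny_case_file <- function(n = 100, seed = 11) {
  set.seed(seed)
  df <- data.frame(
    site = sample(default_site_names(), n, TRUE),
    year = as.character(sample(1998:2014, n, TRUE)),
    session = sample(c("spring", "summer", "fall"), n, TRUE),
    layout = sample(c("grid", "transect", "random"), n, TRUE),
    latitude = round(runif(n, 37.9, 38.2), 5),
    longitude = round(runif(n, -122.5, -122.0), 5),
    elev = round(rnorm(n, 180, 30), 2),
    dist = round(rlnorm(n, log(200), 0.6), 2),
    veg = sample(c("pickleweed", "bare", "grass"), n, TRUE),
    outcome = sample(c("TRAP", "RERA", "MICA", "MUMU"), n, TRUE,
                     c(0.7, 0.1, 0.15, 0.05)),
    stringsAsFactors = FALSE)
  df$elev[sample(n, 6)] <- NA
  df$veg[sample(n, 4)] <- NA
  case_file(df, tiny_catalog())
}

# Brute-force posterior by full joint enumeration; independent of the
# message-passing implementation.
brute_force_posterior <- function(model, evidence = list()) {
  covs <- names(model$nodes)
  grid <- expand.grid(model$nodes, stringsAsFactors = FALSE)
  ev <- evidence[!vapply(evidence, function(x) is.na(x), TRUE)]
  keep <- rep(TRUE, nrow(grid))
  for (nm in names(ev)) keep <- keep & grid[[nm]] == ev[[nm]]
  grid <- grid[keep, , drop = FALSE]
  states <- model$response$states
  p <- vapply(seq_along(states), function(ci) {
    tot <- 0
    for (r in seq_len(nrow(grid))) {
      pr <- model$cpts[[model$response$name]][ci]
      for (nm in covs) {
        pars <- model$parents[[nm]]
        cpt <- model$cpts[[nm]]
        xi <- match(grid[[nm]][r], model$nodes[[nm]])
        cov_par <- setdiff(pars, model$response$name)
        pr <- pr * if (length(cov_par)) {
          cpt[xi, ci, match(grid[[cov_par]][r], model$nodes[[cov_par]])]
        } else cpt[xi, ci]
      }
      tot <- tot + pr
    }
    tot
  }, 0)
  p / sum(p)
}

# Random fitted TAN over <= 4 covariates with 2-3 states each.
random_small_model <- function(seed, n = 300, k = NULL) {
  set.seed(seed)
  if (is.null(k)) k <- sample(2:4, 1)
  cases <- as.data.frame(lapply(seq_len(k), function(i)
    factor(sample(letters[seq_len(sample(2:3, 1))], n, TRUE))))
  names(cases) <- paste0("x", seq_len(k))
  cases$outcome <- factor(sample(c("RERA", "NOTRERA"), n, TRUE, c(0.3, 0.7)),
                          levels = c("RERA", "NOTRERA"))
  skel <- learn_tan_structure(cases, paste0("x", seq_len(k)))
  list(model = learn_cpts(skel, cases, alpha = 1), cases = cases)
}

# A manually specified model whose prediction equals its single covariate's
# state: used to force arbitrary confusion tables.
forced_prediction_model <- function() {
  cpt <- array(c(0.99, 0.01, 0.01, 0.99), c(2, 2),
               dimnames = list(signal = c("pos", "neg"),
                               outcome = c("RERA", "NOTRERA")))
  structure(list(response = list(name = "outcome",
                                 states = c("RERA", "NOTRERA")),
                 nodes = list(signal = c("pos", "neg")),
                 parents = list(signal = "outcome"),
                 links = cbind(from = "outcome", to = "signal"),
                 cpts = list(outcome = c(RERA = 0.5, NOTRERA = 0.5),
                             signal = cpt),
                 meta = list()),
            class = "bn_model")
}

# Discretized capture-case table emulating the published composition:
# n_pos focal cases of n total, one uninformative covariate.
composition_cases <- function(n_pos = 669, n = 3339, seed = 5) {
  set.seed(seed)
  data.frame(
    x = factor(sample(c("lo", "hi"), n, TRUE)),
    outcome = factor(rep(c("RERA", "NOTRERA"), c(n_pos, n - n_pos)),
                     levels = c("RERA", "NOTRERA")))
}

# Simulated suite shared across acceptance-scale tests (built once).
.suite_cache <- new.env(parent = emptyenv())
cached_suite <- function() {
  if (is.null(.suite_cache$suite)) {
    cfg <- sim_config(n_sites = 6, traps_per_site = 25, nights = 20, seed = 33)
    cf <- simulate_trap_survey(cfg)
    .suite_cache$cf <- cf
    .suite_cache$suite <- build_suite(cf)
  }
  list(cf = .suite_cache$cf, suite = .suite_cache$suite)
}
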