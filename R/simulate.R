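#' Default capture-outcome composition
#'
#' Proportions of the nine capture species among capture trap nights,
#' matching the published composition (RERA 669 of 3,339 captures, i.e. 20%).
#' @return Named probability vector over the nine species states, summing
#'   to 1.
#' @export
default_capture_mix <- function() {
  counts <- c(MICA = 1565, MUMU = 555, PEMA = 433, RANO = 14, RARA = 1,
              RE = 3, REME = 34, RERA = 669, SOOR = 65)
  counts / sum(counts)
}

.default_covariate_spec <- function() {
  norm <- function(mean, sd, lo = -Inf, hi = Inf)
    list(dist = "normal", mean = mean, sd = sd, lo = lo, hi = hi)
  lnorm <- function(med, sdlog) list(dist = "lognormal", meanlog = log(med), sdlog = sdlog)
  unif <- function(min, max) list(dist = "uniform", min = min, max = max)
  cat_ <- function(levels, prob) list(dist = "categorical", levels = levels, prob = prob)
  plant1 <- cat_(c("pickleweed", "bare", "saltgrass", "alkali_heath", "other"),
                 c(0.54, 0.24, 0.09, 0.05, 0.08))
  plant23 <- cat_(c("bare", "pickleweed", "saltgrass", "alkali_heath", "other"),
                  c(0.35, 0.25, 0.15, 0.10, 0.15))
  list(
    latitude = unif(37.90, 38.25), longitude = unif(-122.55, -121.95),
    P1_Dom = plant1,
    P1_V_PERC = norm(86, 15, 0, 100), P1_V1_MAX = norm(45, 12, 1, Inf),
    P1_V1_AVG = norm(37, 10, 1, Inf),
    P2_Dom = plant23,
    P2_V_PERC = norm(25, 12, 0, 100), P2_V1_MAX = norm(22, 8, 1, Inf),
    P2_V1_AVG = norm(16, 6, 1, Inf),
    P3_Dom = plant23,
    P3_V_PERC = norm(10, 6, 0, 100), P3_V1_MAX = norm(14, 6, 1, Inf),
    P3_V1_AVG = norm(10, 4, 1, Inf),
    Marsh_Elev = norm(180, 30), MHW = norm(1.80, 0.15),
    Elev_MHW = norm(0.05, 0.25), MHHW = norm(1.92, 0.15),
    Elev_MHHW = norm(-0.07, 0.25),
    # distances: near-Gaussian with a rare zero clamp, so the copula's
    # latent correlations carry through to the observed Pearson r almost
    # unattenuated (heavily skewed marginals cannot realize |r| near 0.9)
    Dist_Levee = norm(120, 45, 0), Dist_Water = norm(90, 35, 0),
    Dist_Bay = norm(600, 220, 0), Dist_Urban = norm(1600, 550, 0),
    Dist_Ag = norm(1400, 500, 0), Dist_Road = norm(1000, 380, 0),
    Patch_Size = lnorm(15, 1.0), Patch_Size_Expanded = lnorm(25, 1.0))
}

.default_correlation_blocks <- function() {
  # the urban/agriculture/road/bay distance cluster needs its implied
  # cross-correlations spelled out to stay jointly positive definite
  list(list(vars = c("MHW", "MHHW"), r = 0.99),
       list(vars = c("Dist_Urban", "Dist_Ag"), r = -0.90),
       list(vars = c("Dist_Urban", "Dist_Road"), r = 0.82),
       list(vars = c("Dist_Ag", "Dist_Bay"), r = 0.80),
       list(vars = c("Dist_Ag", "Dist_Road"), r = -0.74),
       list(vars = c("Dist_Urban", "Dist_Bay"), r = -0.72),
       list(vars = c("Dist_Road", "Dist_Bay"), r = -0.60))
}

#' Configuration of the synthetic trap survey
#'
#' Defaults emulate the study conditions: about 12,400 trap nights across six
#' sites, 73.1% of nights with no capture, the published nine-species capture
#' composition (RERA 20% of captures), strongly correlated covariate pairs
#' (MHW with MHHW; the urban / agriculture / road distance cluster), and
#' RERA presence tilted by patch size, distance to roads, and longitude.
#'
#' @param n_sites,traps_per_site,nights Survey dimensions; total trap nights
#'   = `n_sites * traps_per_site * nights`.
#' @param seed Integer seed; the same configuration and seed yield an
#'   identical case file.
#' @param p_empty Probability a trap night yields no capture.
#' @param capture_mix Named probability vector over the nine species states.
#' @param covariate_spec Per-covariate marginal distributions
#'   (`normal`/`lognormal`/`uniform`/`categorical` with parameters).
#' @param correlation_blocks List of `list(vars = c(a, b), r = target)` pairs
#'   realized through a latent Gaussian copula.
#' @param effects Named log-odds coefficients tilting the RERA share of the
#'   capture mix, applied to within-sample standardized covariate values.
#' @param missing_rate Named per-covariate missingness probabilities
#'   (defaults: 5% on the sparse vegetation covariates).
#' @return A `sim_config` list.
#' @export
sim_config <- function(n_sites = 6, traps_per_site = 45, nights = 46,
                       seed = 1L,
                       p_empty = 0.731,
                       capture_mix = default_capture_mix(),
                       covariate_spec = .default_covariate_spec(),
                       correlation_blocks = .default_correlation_blocks(),
                       effects = c(Patch_Size_Expanded = 1.0,
                                   Dist_Road = 0.8, longitude = 0.6),
                       missing_rate = NULL) {
  if (abs(sum(capture_mix) - 1) > 1e-9) stop("capture_mix must sum to 1")
  if (p_empty < 0 || p_empty > 1) stop("p_empty must lie in [0, 1]")
  for (b in correlation_blocks)
    if (abs(b$r) > 1) stop("correlation target |r| must be <= 1")
  if (is.null(missing_rate)) {
    veg <- grep("^P[123]_V", names(covariate_spec), value = TRUE)
    missing_rate <- stats::setNames(rep(0.05, length(veg)), veg)
  }
  structure(list(n_sites = n_sites, traps_per_site = traps_per_site,
                 nights = nights, seed = as.integer(seed), p_empty = p_empty,
                 capture_mix = capture_mix, covariate_spec = covariate_spec,
                 correlation_blocks = correlation_blocks,
                 effects = effects, missing_rate = missing_rate),
            class = "sim_config")
}

# Correlation matrix over the continuous covariates: identity plus the
# configured blocks. Rejected if not positive definite.
.copula_correlation <- function(vars, blocks) {
  R <- diag(length(vars))
  dimnames(R) <- list(vars, vars)
  for (b in blocks) {
    if (!all(b$vars %in% vars)) next
    R[b$vars[1], b$vars[2]] <- R[b$vars[2], b$vars[1]] <- b$r
  }
  ev <- min(eigen(R, symmetric = TRUE, only.values = TRUE)$values)
  if (ev <= 1e-10)
    stop("infeasible correlation matrix: requested blocks are not jointly ",
         "positive definite (min eigenvalue ", format(ev), ")")
  R
}

.q_marginal <- function(u, spec) {
  switch(spec$dist,
         normal = {
           v <- stats::qnorm(u, spec$mean, spec$sd)
           pmin(pmax(v, spec$lo %||% -Inf), spec$hi %||% Inf)
         },
         lognormal = stats::qlnorm(u, spec$meanlog, spec$sdlog),
         uniform = stats::qunif(u, spec$min, spec$max),
         stop("unknown marginal distribution: ", spec$dist))
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Generate a synthetic trap-survey case file
#'
#' Covariates are drawn once per trap location (latent-Gaussian copula for
#' the correlated continuous variables, independent draws for categorical
#' ones) and replicated over nights. Each trap night is empty with
#' probability `p_empty`; otherwise a species is drawn from the capture mix
#' with the RERA share tilted by the configured logistic effects on that
#' location's standardized covariates and the remaining species scaled
#' proportionally.
#'
#' @param cfg A [sim_config()].
#' @return A `case_file`; deterministic given `cfg$seed`.
#' @export
simulate_trap_survey <- function(cfg = sim_config()) {
  stopifnot(inherits(cfg, "sim_config"))
  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv())
  on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()))
  set.seed(cfg$seed)

  catalog <- default_catalog()
  spec <- cfg$covariate_spec
  cont <- names(spec)[vapply(spec, function(s) s$dist != "categorical", TRUE)]
  catv <- setdiff(names(spec), cont)
  n_loc <- cfg$n_sites * cfg$traps_per_site

  # location-level continuous covariates through the copula
  R <- .copula_correlation(cont, cfg$correlation_blocks)
  L <- chol(R)
  z <- matrix(stats::rnorm(n_loc * length(cont)), n_loc) %*% L
  u <- stats::pnorm(z)
  loc <- as.data.frame(lapply(stats::setNames(seq_along(cont), cont),
                              function(j) .q_marginal(u[, j], spec[[cont[j]]])))
  for (nm in catv)
    loc[[nm]] <- sample(spec[[nm]]$levels, n_loc, TRUE, spec[[nm]]$prob)

  sites <- default_site_names()[seq_len(cfg$n_sites)]
  loc$site <- rep(sites, each = cfg$traps_per_site)
  loc$trap_id <- paste0("T", rep(seq_len(cfg$traps_per_site), cfg$n_sites))
  site_layout <- stats::setNames(
    sample(c("grid", "grid", "grid", "transect", "random",
             "transect")[seq_len(cfg$n_sites)]), sites)
  loc$layout <- site_layout[loc$site]

  # RERA tilt from standardized covariates at each location
  eta <- rep(stats::qlogis(cfg$capture_mix[["RERA"]]), n_loc)
  for (nm in names(cfg$effects)) {
    v <- loc[[nm]]
    if (is.null(v)) stop("effect on unknown covariate: ", nm)
    z_v <- (v - mean(v)) / stats::sd(v)
    eta <- eta + cfg$effects[[nm]] * z_v
  }
  p_rera_loc <- stats::plogis(eta)

  # expand to trap nights
  idx <- rep(seq_len(n_loc), times = cfg$nights)
  n <- length(idx)
  site_year0 <- sample(1998:2012, cfg$n_sites, TRUE)
  night_no <- rep(seq_len(cfg$nights), each = n_loc)
  year <- site_year0[match(loc$site[idx], sites)] +
    (night_no - 1) %% 3  # three survey years per site
  session <- c("spring", "summer", "fall")[1 + (night_no - 1) %% 3]

  empty <- stats::runif(n) < cfg$p_empty
  p_rera <- rep(p_rera_loc, times = cfg$nights)
  outcome <- rep("TRAP", n)
  cap <- which(!empty)
  is_rera <- stats::runif(length(cap)) < p_rera[cap]
  others <- cfg$capture_mix[setdiff(names(cfg$capture_mix), "RERA")]
  outcome[cap] <- ifelse(is_rera, "RERA",
                         sample(names(others), length(cap), TRUE,
                                others / sum(others)))

  df <- loc[idx, , drop = FALSE]
  df$year <- as.character(year)  # categorical design covariate
  df$session <- session
  df$outcome <- outcome
  # per-covariate missingness (vegetation plots are sparse)
  for (nm in names(cfg$missing_rate)) {
    miss <- stats::runif(n) < cfg$missing_rate[[nm]]
    df[[nm]][miss] <- NA
  }
  front <- c("site", "year", "session", "layout", "trap_id",
             "latitude", "longitude")
  df <- df[c(front, setdiff(names(df), c(front, "outcome")), "outcome")]
  rownames(df) <- NULL
  case_file(df, catalog)
}

#' True drivers planted in a simulation configuration
#'
#' @param cfg A [sim_config()].
#' @return A data.frame of the nonzero response effects (`covariate`,
#'   `coefficient`); empty when no effect is planted. Invariant to the seed.
#' @export
planted_truth <- function(cfg) {
  stopifnot(inherits(cfg, "sim_config"))
  eff <- cfg$effects[cfg$effects != 0]
  data.frame(covariate = names(eff), coefficient = unname(eff),
             stringsAsFactors = FALSE)
}
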