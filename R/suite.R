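#' Covariate-set combinations of the model suite
#'
#' The default suite evaluates 19 covariate-set combinations for each of the
#' two responses (38 models): ids 1-19 predict RERA presence, ids 20-38 the
#' nine-species outcome. Set definitions come from the catalog's set labels;
#' the distance-only variants (6 and 25) use the documented single-covariate
#' form (distance to paved roads) rather than the full distance set.
#'
#' @param catalog A `covariate_catalog` supplying C1..C7 membership.
#' @param set_overrides Named list replacing the covariate list of any set.
#' @return A `suite_spec`: `variants` (data.frame id, response, sets),
#'   `set_definitions` (named list C1..C7), `single_covariate_variants`.
#' @export
suite_spec <- function(catalog = default_catalog(), set_overrides = list()) {
  sets <- lapply(stats::setNames(paste0("C", 1:7), paste0("C", 1:7)),
                 function(s) catalog$name[vapply(catalog$sets,
                                                 function(x) s %in% x, TRUE)])
  for (nm in names(set_overrides)) sets[[nm]] <- set_overrides[[nm]]
  combos <- list(
    "C1", "C2", "C3", "C4", "C5", "C6", "C7",
    c("C5", "C6"), c("C6", "C7"), c("C5", "C7"),
    c("C3", "C5", "C6"), c("C3", "C6", "C7"), c("C3", "C5", "C7"),
    c("C3", "C5", "C6", "C7"),
    c("C1", "C3", "C5", "C6"), c("C1", "C3", "C6", "C7"),
    c("C1", "C3", "C5", "C7"), c("C1", "C3", "C5", "C6", "C7"),
    c("C4", "C5", "C6", "C7"))
  variants <- data.frame(
    id = c(1:19, 20:38),
    response = rep(c("rera_presence", "all_species"), each = 19),
    stringsAsFactors = FALSE)
  variants$sets <- c(combos, combos)
  structure(list(variants = variants, set_definitions = sets,
                 single_covariate_variants =
                   list(`6` = "Dist_Road", `25` = "Dist_Road")),
            class = "suite_spec")
}

#' Covariates used by one suite variant
#' @param spec A `suite_spec`.
#' @param id Variant id.
#' @return Character vector of covariate names, in catalog-set order.
#' @export
variant_covariates <- function(spec, id) {
  row <- match(id, spec$variants$id)
  if (is.na(row)) stop("unknown variant id ", id)
  ov <- spec$single_covariate_variants[[as.character(id)]]
  if (!is.null(ov)) return(ov)
  unique(unlist(spec$set_definitions[spec$variants$sets[[row]]]))
}

#' Fit and evaluate the whole model suite
#'
#' Fits one TAN model per variant on the model cases of its response and
#' evaluates calibration performance on the same cases (the calibration
#' convention of the analysis).
#'
#' @param cf A survey `case_file` (TRAP rows are removed per response via
#'   [to_model_cases()]).
#' @param spec A [suite_spec()].
#' @param max_states,min_support Discretization settings.
#' @param alpha CPT smoothing weight.
#' @param focal_state Focal state for Type I/II errors.
#' @return A `suite_result`: `rows` (one evaluation row per model),
#'   `models` (named list of fitted `bn_model`s), `frontier` ids,
#'   `selected` ids.
#' @export
build_suite <- function(cf, spec = suite_spec(cf$catalog), max_states = 5,
                        min_support = 20, alpha = 1, focal_state = "RERA") {
  ids <- spec$variants$id
  rows <- vector("list", length(ids))
  models <- vector("list", length(ids))
  names(models) <- as.character(ids)
  cases_by_resp <- list()
  for (mode in unique(spec$variants$response)) {
    mc <- to_model_cases(cf, response_spec(mode))
    all_covs <- unique(unlist(c(spec$set_definitions,
                                spec$single_covariate_variants)))
    missing_cov <- setdiff(all_covs, names(mc$cases))
    if (length(missing_cov))
      stop("covariate(s) missing from case file: ",
           paste(missing_cov, collapse = ", "))
    schemes <- fit_schemes(mc, all_covs, max_states, min_support)
    cases_by_resp[[mode]] <- discretize_cases(
      mc, schemes, response_states = response_spec(mode)$states)
  }
  for (i in seq_along(ids)) {
    id <- ids[i]
    mode <- spec$variants$response[i]
    covs <- variant_covariates(spec, id)
    cases <- cases_by_resp[[mode]]
    skel <- learn_tan_structure(cases, covs)
    fit <- learn_cpts(skel, cases, alpha = alpha)
    fit$meta <- list(id = id, response = mode,
                     sets = spec$variants$sets[[i]])
    ev <- evaluate_model(fit, cases, focal_state = focal_state)
    models[[i]] <- fit
    rows[[i]] <- data.frame(
      id = id, response = mode,
      n_nodes = ev$complexity$n_nodes, n_links = ev$complexity$n_links,
      n_probabilities = ev$complexity$n_probabilities,
      overall_error = ev$overall_error, type1_error = ev$type1_error,
      type2_error = ev$type2_error, spherical_payoff = ev$spherical_payoff,
      type1_undefined = "type1" %in% ev$undefined,
      stringsAsFactors = FALSE)
  }
  rows <- do.call(rbind, rows)
  frontier <- rank_models(rows)
  structure(list(rows = rows, models = models, frontier = frontier,
                 selected = select_models(rows, frontier)),
            class = "suite_result")
}

#' @export
print.suite_result <- function(x, ...) {
  cat("Model suite:", nrow(x$rows), "fitted models\n")
  cat("Frontier:", paste(x$frontier, collapse = ", "), "\n")
  cat("Selected:", paste(x$selected, collapse = ", "), "\n")
  invisible(x)
}

#' Pareto frontier of suite rows
#'
#' Non-dominated models under: minimize Type I error, minimize overall
#' error, maximize spherical payoff, minimize probability count. Model `j`
#' dominates model `i` when it is no worse on every objective (within the
#' indifference tolerance `eps` on the three accuracy metrics, and not more
#' probability values) and strictly better beyond `eps` on at least one
#' accuracy metric. Complexity therefore vetoes domination by bigger models
#' and breaks the final selection, but equal-accuracy models of different
#' sizes all stay on the frontier. Frontiers are computed within each
#' response separately when both are present.
#'
#' @param rows `suite_result$rows` (or a compatible data.frame).
#' @param eps Indifference tolerance on rates and payoff (default 0.01).
#' @return Integer vector of non-dominated model ids.
#' @export
rank_models <- function(rows, eps = 0.01) {
  stopifnot(nrow(rows) >= 1)
  if (is.null(rows$response)) rows$response <- "all"
  out <- integer()
  for (resp in unique(rows$response)) {
    rr <- rows[rows$response == resp, , drop = FALSE]
    acc <- cbind(rr$type1_error, rr$overall_error, -rr$spherical_payoff)
    np <- rr$n_probabilities
    dominated <- vapply(seq_len(nrow(rr)), function(i) {
      for (j in seq_len(nrow(rr))) {
        if (i == j) next
        no_worse <- all(acc[j, ] <= acc[i, ] + eps) && np[j] <= np[i]
        better <- any(acc[j, ] < acc[i, ] - eps)
        if (no_worse && better) return(TRUE)
      }
      FALSE
    }, TRUE)
    out <- c(out, rr$id[!dominated])
  }
  sort(out)
}

#' Advisory best-model pick from a frontier
#'
#' Frontier members ordered by lowest Type I error, then lowest overall
#' error, then fewest probability values; all members tied with the best on
#' these keys (within `eps` on the rates) are selected. Selection beyond the
#' frontier is advisory, not an assertion.
#'
#' @param rows Suite rows.
#' @param frontier Ids from [rank_models()].
#' @param eps Indifference tolerance.
#' @return Integer vector of selected ids.
#' @export
select_models <- function(rows, frontier = rank_models(rows), eps = 0.01) {
  if (is.null(rows$response)) rows$response <- "all"
  out <- integer()
  for (resp in unique(rows$response)) {
    fr <- rows[rows$id %in% frontier & rows$response == resp, , drop = FALSE]
    if (!nrow(fr)) next
    best_t1 <- min(fr$type1_error)
    fr <- fr[fr$type1_error <= best_t1 + eps, , drop = FALSE]
    best_ov <- min(fr$overall_error)
    fr <- fr[fr$overall_error <= best_ov + eps, , drop = FALSE]
    best_np <- min(fr$n_probabilities)
    out <- c(out, fr$id[fr$n_probabilities == best_np])
  }
  sort(out)
}

#' Write the suite report
#'
#' One CSV per response mirroring the complexity/accuracy table layout:
#' columns model, nodes, links, probabilities, overall_error, type1, type2,
#' spherical_payoff.
#'
#' @param result A `suite_result` (or its `rows`).
#' @param path Output CSV path; with both responses present, two files are
#'   written with `_rera` / `_all` suffixes and the paths returned.
#' @return Written path(s), invisibly.
#' @export
write_suite_report <- function(result, path) {
  rows <- if (inherits(result, "suite_result")) result$rows else result
  fmt <- function(rr) data.frame(
    model = rr$id, nodes = rr$n_nodes, links = rr$n_links,
    probabilities = rr$n_probabilities,
    overall_error = rr$overall_error, type1 = rr$type1_error,
    type2 = rr$type2_error, spherical_payoff = rr$spherical_payoff)
  resp <- unique(rows$response)
  if (length(resp) <= 1) {
    utils::write.csv(fmt(rows), path, row.names = FALSE)
    return(invisible(path))
  }
  paths <- character()
  for (r in resp) {
    suffix <- if (r == "rera_presence") "_rera" else "_all"
    p <- sub("(\\.[^.]+)$", paste0(suffix, "\\1"), path)
    utils::write.csv(fmt(rows[rows$response == r, ]), p, row.names = FALSE)
    paths <- c(paths, p)
  }
  invisible(paths)
}
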