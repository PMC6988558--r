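#' Case file of per-trap-night records
#'
#' A case file couples an ordered table of trap-night cases with a covariate
#' catalog. Each case carries the design fields (`site`, `year`, `session`,
#' `layout`, `latitude`, `longitude`), the trap-night `outcome` (a species
#' code or `"TRAP"` for no capture), and one column per catalog covariate.
#' Missing covariate values stay `NA`; they are never imputed.
#'
#' @param cases A data.frame with column `outcome` plus covariate columns.
#' @param catalog A `covariate_catalog`.
#' @return A `case_file` object (list with `cases`, `catalog`).
#' @export
case_file <- function(cases, catalog) {
  stopifnot(is.data.frame(cases), inherits(catalog, "covariate_catalog"))
  if (!"outcome" %in% names(cases)) stop("cases must have an 'outcome' column")
  known <- c(outcome_labels(), "RERA", "NOTRERA")
  bad <- which(!cases$outcome %in% known)
  if (length(bad))
    stop("unknown outcome label '", cases$outcome[bad[1]], "' at row ", bad[1])
  extra <- setdiff(names(cases),
                   c("outcome", catalog$name,
                     c("site", "year", "session", "layout", "latitude", "longitude")))
  if (length(extra))
    stop("covariate column(s) absent from catalog: ", paste(extra, collapse = ", "))
  structure(list(cases = cases, catalog = catalog), class = "case_file")
}

#' @export
print.case_file <- function(x, ...) {
  n <- nrow(x$cases)
  cat("Trap-survey case file: ", n, " cases, ",
      nrow(x$catalog), " catalog covariates\n", sep = "")
  tab <- sort(table(x$cases$outcome), decreasing = TRUE)
  cat("Outcomes:", paste(names(tab), tab, sep = "=", collapse = ", "), "\n")
  invisible(x)
}

#' Number of cases
#' @param cf A `case_file`.
#' @return Integer count of trap-night cases.
#' @export
n_cases <- function(cf) nrow(cf$cases)

#' Read a case file from CSV
#'
#' One header row; one data row per trap night. Missing values may be encoded
#' as an empty field or `"*"` (the dialect written by [write_case_file()]).
#'
#' @param path CSV path.
#' @param catalog Covariate catalog the columns must belong to.
#' @return A `case_file`; row order preserved, missingness preserved.
#' @export
read_case_file <- function(path, catalog = default_catalog()) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE, check.names = FALSE,
                        na.strings = c("", "*"), colClasses = "character")
  if (!"outcome" %in% names(df)) stop("case file lacks an 'outcome' column")
  bad <- which(!df$outcome %in% outcome_labels() & !df$outcome %in% c("RERA", "NOTRERA"))
  if (length(bad))
    stop("unknown outcome label '", df$outcome[bad[1]], "' at row ", bad[1])
  kind <- stats::setNames(catalog$kind, catalog$name)
  for (nm in names(df)) {
    numeric_col <- nm %in% c("latitude", "longitude") ||
      (nm %in% catalog$name && kind[[nm]] == "continuous")
    if (numeric_col) df[[nm]] <- as.numeric(df[[nm]])
  }
  case_file(df, catalog)
}

#' Write a case file to CSV
#'
#' Missing values are written as `"*"`; [read_case_file()] reads them back as
#' missing, so write-then-read is the identity on values and missingness.
#'
#' @param cf A `case_file`.
#' @param path Output CSV path.
#' @return `path`, invisibly.
#' @export
write_case_file <- function(cf, path) {
  df <- cf$cases
  for (nm in names(df)) {
    v <- as.character(df[[nm]])
    v[is.na(v)] <- "*"
    df[[nm]] <- v
  }
  utils::write.csv(df, path, row.names = FALSE, quote = TRUE)
  invisible(path)
}

#' Reduce a survey case file to model cases
#'
#' Model case files contain capture records only: trap nights with no capture
#' (`TRAP`) are dropped. Under the `rera_presence` response every non-RERA
#' capture is relabeled `NOTRERA`; under `all_species` the nine species codes
#' are kept as-is. Order is preserved and the operation is idempotent.
#'
#' @param cf A `case_file`.
#' @param resp A [response_spec()].
#' @return A `case_file` whose outcomes all lie in `resp$states`.
#' @export
to_model_cases <- function(cf, resp = response_spec("rera_presence")) {
  stopifnot(inherits(resp, "response_spec"))
  keep <- cf$cases$outcome != "TRAP"
  cases <- cf$cases[keep, , drop = FALSE]
  if (resp$mode == "rera_presence") {
    cases$outcome <- ifelse(cases$outcome == "RERA", "RERA", "NOTRERA")
  } else {
    bad <- which(!cases$outcome %in% resp$states)
    if (length(bad))
      stop("outcome '", cases$outcome[bad[1]],
           "' is not an all-species state (was to_model_cases already applied ",
           "with rera_presence?)")
  }
  rownames(cases) <- NULL
  case_file(cases, cf$catalog)
}

#' Outcome / effort margins of a case file
#'
#' Counts of cases by grouping keys, with rates per 100 trap nights computed
#' against the total trap nights of each non-outcome group (the convention of
#' per-100-trap-night capture tables).
#'
#' @param cf A `case_file`.
#' @param by Grouping keys, subset of `site`, `year`, `outcome`, `layout`.
#' @return A data.frame of `by` columns plus `n` and `rate_per_100`
#'   (1 decimal).
#' @export
summarize_margins <- function(cf, by = "outcome") {
  stopifnot(all(by %in% c("site", "year", "outcome", "layout")))
  df <- cf$cases
  counts <- stats::aggregate(list(n = rep(1L, nrow(df))), df[by], FUN = sum)
  effort_keys <- setdiff(by, "outcome")
  if (length(effort_keys)) {
    eff <- stats::aggregate(list(trap_nights = rep(1L, nrow(df))),
                            df[effort_keys], FUN = sum)
    counts <- merge(counts, eff, by = effort_keys, sort = FALSE)
  } else {
    counts$trap_nights <- nrow(df)
  }
  counts$rate_per_100 <- round(100 * counts$n / counts$trap_nights, 1)
  ord <- do.call(order, counts[by])
  counts <- counts[ord, , drop = FALSE]
  rownames(counts) <- NULL
  counts
}

#' Expand published margins into a case file
#'
#' Builds a deterministic case file whose site-by-outcome margins equal a
#' printed capture table: one row per trap night, covariate columns absent.
#' Used to exercise counting, relabeling, and baseline-model arithmetic on
#' the study's published composition without the deposited data.
#'
#' @param margins As returned by [study_margins()]; only `captures` is used.
#' @param catalog Covariate catalog to attach.
#' @return A `case_file` with columns `site` and `outcome`.
#' @export
margins_to_cases <- function(margins = study_margins(),
                             catalog = default_catalog()) {
  cap <- margins$captures
  sites <- setdiff(names(cap), "species")
  rows <- list()
  for (s in sites) {
    n <- cap[[s]]
    keep <- n > 0
    rows[[s]] <- data.frame(
      site = s,
      outcome = rep(cap$species[keep], n[keep]),
      stringsAsFactors = FALSE)
  }
  df <- do.call(rbind, rows)
  rownames(df) <- NULL
  case_file(df, catalog)
}
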