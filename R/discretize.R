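#' Fit a discretization scheme for one continuous covariate
#'
#' Bins are seeded at equal-frequency (quantile) cuts with at most
#' `max_states` states and no more states than the data can support at
#' `min_support` values per state; smallest-support bins are then merged with
#' their lower-count neighbour until every state holds at least `min_support`
#' training values or a single state remains. Cut values are snapped to
#' midpoints between adjacent distinct data values, so every observation maps
#' unambiguously to one state.
#'
#' @param values Numeric training series; missing values are ignored for
#'   fitting. At least one non-missing value is required.
#' @param max_states Maximum number of states (default 5).
#' @param min_support Minimum training values per state (default 20).
#' @param variable Name recorded in the scheme.
#' @return A `discretization_scheme`: `variable`, `boundaries` (ascending),
#'   `states` ("[a,b)"-style labels), `support` (per-state training counts).
#' @export
fit_scheme <- function(values, max_states = 5, min_support = 20,
                       variable = deparse(substitute(values))) {
  v <- sort(values[!is.na(values)])
  n <- length(v)
  if (n < 1) stop("need at least one non-missing value")
  distinct <- unique(v)

  k0 <- max(1L, min(as.integer(max_states), n %/% max(1L, min_support),
                    length(distinct)))
  # candidate boundaries: midpoints between adjacent distinct values nearest
  # the equal-frequency split points
  boundaries <- numeric(0)
  if (k0 > 1) {
    mids <- (distinct[-length(distinct)] + distinct[-1]) / 2
    for (j in seq_len(k0 - 1)) {
      cut <- round(j * n / k0)
      left <- v[cut]; right <- v[min(cut + 1L, n)]
      b <- if (left < right) (left + right) / 2
      else mids[which.min(abs(mids - left))]  # ties straddle the cut
      boundaries <- c(boundaries, b)
    }
    boundaries <- sort(unique(boundaries))
  }
  support <- .bin_counts(v, boundaries)

  # merge until all states carry enough support
  while (length(support) > 1 && min(support) < min_support) {
    i <- which.min(support)  # leftmost smallest
    if (i == 1) j <- 2
    else if (i == length(support)) j <- i - 1
    else j <- if (support[i - 1] <= support[i + 1]) i - 1 else i + 1
    lo <- min(i, j)
    support[lo] <- support[i] + support[j]
    support <- support[-(lo + 1)]
    boundaries <- boundaries[-lo]
  }

  structure(list(variable = variable,
                 boundaries = boundaries,
                 states = .state_labels(boundaries),
                 support = unname(support)),
            class = "discretization_scheme")
}

.bin_counts <- function(sorted_values, boundaries) {
  idx <- findInterval(sorted_values, boundaries) + 1L
  tabulate(idx, nbins = length(boundaries) + 1L)
}

.state_labels <- function(boundaries) {
  k <- length(boundaries) + 1L
  if (k == 1) return("all")
  b <- signif(boundaries, 6)
  lab <- character(k)
  lab[1] <- paste0("<", b[1])
  if (k > 2)
    lab[2:(k - 1)] <- paste0("[", b[-length(b)], ",", b[-1], ")")
  lab[k] <- paste0(">=", b[length(b)])
  lab
}

#' @export
print.discretization_scheme <- function(x, ...) {
  cat("Discretization of ", x$variable, ": ", length(x$states),
      " state(s)\n", sep = "")
  print(data.frame(state = x$states, support = x$support), row.names = FALSE)
  invisible(x)
}

#' Map values to discrete states
#'
#' Half-open `[a, b)` intervals; values below the first cut fall in the first
#' state and values at or above the last cut in the last state, so any real
#' value (including ones outside the training range) maps to a state.
#' Missing stays missing.
#'
#' @param scheme A [fit_scheme()] result.
#' @param value Numeric vector (may contain `NA`).
#' @return Character vector of state labels with `NA` preserved.
#' @export
apply_scheme <- function(scheme, value) {
  idx <- findInterval(value, scheme$boundaries) + 1L
  out <- scheme$states[idx]
  out[is.na(value)] <- NA_character_
  out
}

#' Categorical pass-through scheme
#'
#' Categorical covariates keep their native labels, capped at the
#' `max_levels` most frequent plus `"other"` when more occur in training.
#'
#' @param values Character training series.
#' @param max_levels Cap on retained native labels (default 5).
#' @param variable Name recorded in the scheme.
#' @return A `categorical_scheme` with `states` and per-state `support`.
#' @export
fit_categorical_scheme <- function(values, max_levels = 5,
                                   variable = deparse(substitute(values))) {
  v <- values[!is.na(values)]
  if (!length(v)) stop("need at least one non-missing value")
  tab <- sort(table(v), decreasing = TRUE)
  keep <- names(tab)[seq_len(min(max_levels, length(tab)))]
  states <- if (length(tab) > length(keep)) c(keep, "other") else keep
  mapped <- ifelse(v %in% keep, v, "other")
  support <- as.integer(table(factor(mapped, levels = states)))
  structure(list(variable = variable, states = states, keep = keep,
                 support = support),
            class = "categorical_scheme")
}

#' @rdname apply_scheme
#' @export
apply_categorical_scheme <- function(scheme, value) {
  out <- ifelse(value %in% scheme$keep, value, "other")
  out[is.na(value)] <- NA_character_
  out
}

#' Fit schemes for every covariate used in modelling
#'
#' @param cf A `case_file` of model cases.
#' @param covariates Covariate names; kinds are taken from the catalog
#'   (`site`, `year`, `session`, `layout`, `trap_id` are categorical,
#'   coordinates continuous).
#' @param max_states,min_support Passed to [fit_scheme()].
#' @return Named list of schemes.
#' @export
fit_schemes <- function(cf, covariates, max_states = 5, min_support = 20) {
  kinds <- stats::setNames(cf$catalog$kind, cf$catalog$name)
  out <- lapply(stats::setNames(covariates, covariates), function(nm) {
    v <- cf$cases[[nm]]
    if (is.null(v)) stop("covariate ", nm, " absent from case file")
    if (identical(unname(kinds[nm]), "categorical"))
      fit_categorical_scheme(as.character(v), max_levels = max_states,
                             variable = nm)
    else fit_scheme(as.numeric(v), max_states, min_support, variable = nm)
  })
  out
}

#' Discretize model cases under fitted schemes
#'
#' @param cf A `case_file`.
#' @param schemes Named scheme list from [fit_schemes()].
#' @param response_states Ordered response state labels; by default inferred
#'   from the outcomes present (RERA/NOTRERA for binarized cases, otherwise
#'   the nine species states). The order fixes prediction tie-breaking.
#' @return A data.frame of factor columns (state labels; `NA` preserved)
#'   plus an `outcome` factor, suitable for structure and CPT learning.
#' @export
discretize_cases <- function(cf, schemes, response_states = NULL) {
  out <- lapply(schemes, function(sch) {
    v <- cf$cases[[sch$variable]]
    lab <- if (inherits(sch, "categorical_scheme"))
      apply_categorical_scheme(sch, as.character(v))
    else apply_scheme(sch, as.numeric(v))
    factor(lab, levels = sch$states)
  })
  out <- as.data.frame(out, check.names = FALSE)
  if (is.null(response_states)) {
    oc <- unique(cf$cases$outcome)
    response_states <- if (all(oc %in% c("RERA", "NOTRERA")))
      response_spec("rera_presence")$states
    else response_spec("all_species")$states
  }
  out$outcome <- factor(cf$cases$outcome, levels = response_states)
  out
}

#' Write / read discretization schemes as JSON
#'
#' @param schemes Named scheme list.
#' @param path JSON file path.
#' @return `path` (write) or the scheme list (read).
#' @export
write_schemes <- function(schemes, path) {
  ser <- lapply(schemes, function(s) {
    c(unclass(s), list(type = if (inherits(s, "categorical_scheme"))
      "categorical" else "continuous"))
  })
  jsonlite::write_json(ser, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname write_schemes
#' @export
read_schemes <- function(path) {
  raw <- jsonlite::read_json(path, simplifyVector = TRUE)
  lapply(raw, function(s) {
    type <- s$type; s$type <- NULL
    if (type == "categorical") {
      structure(list(variable = s$variable, states = s$states, keep = s$keep,
                     support = as.integer(s$support)),
                class = "categorical_scheme")
    } else {
      structure(list(variable = s$variable,
                     boundaries = as.numeric(s$boundaries %||% numeric()),
                     states = s$states, support = as.integer(s$support)),
                class = "discretization_scheme")
    }
  })
}
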