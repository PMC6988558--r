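#' Pearson correlation with pairwise-complete observations
#'
#' @param x,y Numeric series of equal length; pairs with a missing value in
#'   either series are dropped.
#' @return List `(r, p, n)`; `p` from the t transform on `n - 2` df.
#' @export
pearson_r <- function(x, y) {
  ok <- stats::complete.cases(x, y)
  x <- x[ok]; y <- y[ok]
  n <- length(x)
  if (n < 3) stop("need at least 3 pairwise-complete observations")
  if (stats::sd(x) == 0 || stats::sd(y) == 0)
    stop("undefined correlation: a series has zero variance")
  ct <- stats::cor.test(x, y, method = "pearson")
  list(r = unname(ct$estimate), p = ct$p.value, n = n)
}

#' Correlation screen with greedy covariate elimination
#'
#' Evaluates all `choose(k, 2)` pairwise Pearson correlations among the given
#' continuous covariates and flags pairs that are both significant at `alpha`
#' and above `r_thresh` in absolute value. Covariates are then eliminated
#' greedily: while any retained pair is flagged, remove the covariate in the
#' most flagged pairs (ties: larger mean absolute r over its flagged pairs,
#' then the covariate later in catalog order is removed, keeping the
#' first-listed variable).
#'
#' @param cf A `case_file`.
#' @param covariates Continuous covariate names to screen (default: the 13
#'   landscape covariates of [screening_covariates()]).
#' @param r_thresh Absolute correlation threshold (default 0.75).
#' @param alpha Significance level (default 0.05).
#' @return A `correlation_screen` list: `pairs` (data.frame a, b, r, p, n,
#'   flagged), `flagged`, `eliminated`, `retained`.
#' @export
screen_covariates <- function(cf, covariates = screening_covariates(),
                              r_thresh = 0.75, alpha = 0.05) {
  stopifnot(length(covariates) >= 2)
  kinds <- stats::setNames(cf$catalog$kind, cf$catalog$name)
  if (any(kinds[covariates] != "continuous"))
    stop("screening requires continuous covariates")
  cmb <- utils::combn(covariates, 2)
  pairs <- data.frame(a = cmb[1, ], b = cmb[2, ], r = NA_real_,
                      p = NA_real_, n = NA_integer_, stringsAsFactors = FALSE)
  for (i in seq_len(nrow(pairs))) {
    pr <- pearson_r(cf$cases[[pairs$a[i]]], cf$cases[[pairs$b[i]]])
    pairs$r[i] <- pr$r; pairs$p[i] <- pr$p; pairs$n[i] <- pr$n
  }
  pairs$flagged <- pairs$p < alpha & abs(pairs$r) > r_thresh

  eliminated <- character()
  repeat {
    live <- pairs$flagged & !(pairs$a %in% eliminated) &
      !(pairs$b %in% eliminated)
    if (!any(live)) break
    involved <- c(pairs$a[live], pairs$b[live])
    deg <- table(involved)
    cand <- names(deg)[deg == max(deg)]
    if (length(cand) > 1) {
      meanr <- vapply(cand, function(v) {
        sel <- live & (pairs$a == v | pairs$b == v)
        mean(abs(pairs$r[sel]))
      }, 0)
      cand <- cand[meanr == max(meanr)]
    }
    # remaining tie: drop the covariate listed later in catalog order
    cand <- cand[order(match(cand, covariates))]
    eliminated <- c(eliminated, cand[length(cand)])
  }
  structure(list(pairs = pairs,
                 flagged = pairs[pairs$flagged, c("a", "b", "r", "p", "n")],
                 eliminated = eliminated,
                 retained = setdiff(covariates, eliminated)),
            class = "correlation_screen")
}

#' @export
print.correlation_screen <- function(x, ...) {
  cat("Correlation screen: ", nrow(x$pairs), " pairs, ",
      sum(x$pairs$flagged), " flagged\n", sep = "")
  if (length(x$eliminated))
    cat("Eliminated:", paste(x$eliminated, collapse = ", "), "\n")
  cat("Retained: ", length(x$retained), " covariates\n", sep = "")
  invisible(x)
}

#' Welch unpaired two-sample t test
#'
#' `t = (mean(a) - mean(b)) / se` with the Welch-Satterthwaite df, so a
#' negative statistic means the second group has the higher mean.
#'
#' @param a,b Numeric series (missing values dropped); each needs at least
#'   two values, and at least one group must have positive variance.
#' @return List `(t, df, p)`; `p` two-sided.
#' @export
welch_t <- function(a, b) {
  a <- a[!is.na(a)]; b <- b[!is.na(b)]
  if (length(a) < 2 || length(b) < 2)
    stop("each group needs at least 2 non-missing values")
  if (stats::var(a) == 0 && stats::var(b) == 0) {
    if (mean(a) == mean(b)) return(list(t = 0, df = length(a) + length(b) - 2, p = 1))
    stop("degenerate: both groups have zero variance and different means")
  }
  ht <- stats::t.test(a, b, var.equal = FALSE)
  list(t = unname(ht$statistic), df = unname(ht$parameter), p = ht$p.value)
}

#' Variance-ratio F test
#'
#' Under the reporting convention `F = larger variance / smaller variance`,
#' so `F >= 1`; the two-sided p-value doubles the upper tail.
#'
#' @param a,b Numeric series (missing values dropped).
#' @return List `(F, df1, df2, p)` with df ordered to match the ratio.
#' @export
variance_f <- function(a, b) {
  a <- a[!is.na(a)]; b <- b[!is.na(b)]
  va <- stats::var(a); vb <- stats::var(b)
  if (is.na(va) || is.na(vb) || va == 0 || vb == 0)
    stop("variance F test undefined: a group has zero variance")
  if (va >= vb) {
    Fv <- va / vb; df1 <- length(a) - 1; df2 <- length(b) - 1
  } else {
    Fv <- vb / va; df1 <- length(b) - 1; df2 <- length(a) - 1
  }
  p <- min(1, 2 * stats::pf(Fv, df1, df2, lower.tail = FALSE))
  list(F = Fv, df1 = df1, df2 = df2, p = p)
}

#' Compare habitat attributes between two species
#'
#' For each covariate, a Welch t test between the trap nights where each
#' species was captured, with Bonferroni adjustment over the covariates
#' compared. The winner (`higher_mean`) is reported only when the adjusted
#' p-value is below `alpha`; otherwise `"nd"` (no significant difference).
#' With `a = "MICA"`, `b = "RERA"` a negative t means RERA sites had the
#' higher mean.
#'
#' @param cf A `case_file` (survey or model cases).
#' @param species_a,species_b Outcome labels; both must occur in `cf`.
#' @param covariates Continuous covariate names to compare.
#' @param alpha Significance level applied to adjusted p-values.
#' @return A data.frame: `variable`, `t`, `df`, `p_adj`, `higher_mean`.
#' @export
compare_species <- function(cf, species_a, species_b,
                            covariates, alpha = 0.05) {
  oc <- cf$cases$outcome
  for (s in c(species_a, species_b))
    if (!any(oc == s)) stop("species ", s, " absent from case file")
  m <- length(covariates)
  rows <- lapply(covariates, function(v) {
    a <- cf$cases[[v]][oc == species_a]
    b <- cf$cases[[v]][oc == species_b]
    wt <- welch_t(a, b)
    p_adj <- min(1, m * wt$p)
    higher <- if (p_adj < alpha) {
      if (wt$t > 0) species_a else species_b
    } else "nd"
    data.frame(variable = v, t = wt$t, df = wt$df, p_adj = p_adj,
               higher_mean = higher, stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}
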