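#' Calibration evaluation of a fitted model
#'
#' Runs the model over every case and partitions classification error with
#' predicted-class denominators: Type I (false presence) is the number of
#' cases predicted in the focal state whose actual outcome differs, divided
#' by all cases predicted focal; Type II (false nonpresence) is the number of
#' cases predicted non-focal whose actual outcome is focal, divided by all
#' cases predicted non-focal. Overall error stays multiclass for multi-state
#' responses; only Type I/II binarize on the focal state. An error rate with
#' an empty denominator is reported as 0 and flagged in `undefined`.
#'
#' @param model A fitted `bn_model`.
#' @param cases Discretized case table with an `outcome` column sharing the
#'   model's response states.
#' @param focal_state Focal response state (default `"RERA"`).
#' @return A `model_evaluation`: `n_cases`, `confusion` (actual x predicted),
#'   `overall_error`, `type1_error`, `type2_error`, `spherical_payoff`,
#'   `complexity`, `focal_state`, `undefined`.
#' @export
evaluate_model <- function(model, cases, focal_state = "RERA") {
  if (!nrow(cases)) stop("empty case set")
  states <- model$response$states
  stopifnot(focal_state %in% states)
  actual <- factor(as.character(cases$outcome), levels = states)
  if (anyNA(actual)) stop("cases contain outcomes outside the model's states")
  post <- posterior_cases(model, cases)
  predicted <- factor(states[max.col(post, ties.method = "first")],
                      levels = states)
  confusion <- table(actual = actual, predicted = predicted)
  n <- nrow(cases)

  overall <- sum(confusion) - sum(diag(confusion))
  pred_pos <- predicted == focal_state
  act_pos <- actual == focal_state
  undefined <- character()
  t1_den <- sum(pred_pos); t2_den <- sum(!pred_pos)
  if (t1_den == 0) { type1 <- 0; undefined <- c(undefined, "type1") }
  else type1 <- sum(pred_pos & !act_pos) / t1_den
  if (t2_den == 0) { type2 <- 0; undefined <- c(undefined, "type2") }
  else type2 <- sum(!pred_pos & act_pos) / t2_den

  sp <- spherical_payoff_scores(post, actual)
  structure(list(n_cases = n, confusion = confusion,
                 overall_error = overall / n,
                 type1_error = type1, type2_error = type2,
                 spherical_payoff = sp,
                 complexity = complexity(model),
                 focal_state = focal_state, undefined = undefined),
            class = "model_evaluation")
}

#' @export
print.model_evaluation <- function(x, ...) {
  cx <- x$complexity
  cat(sprintf(
    "Model evaluation (%d cases, focal %s): overall %.1f%%, Type I %.1f%%, Type II %.1f%%, spherical payoff %.3f\n",
    x$n_cases, x$focal_state, 100 * x$overall_error, 100 * x$type1_error,
    100 * x$type2_error, x$spherical_payoff))
  cat(sprintf("Complexity: %d nodes / %d links / %d probabilities\n",
              cx$n_nodes, cx$n_links, cx$n_probabilities))
  if (length(x$undefined))
    cat("Undefined (empty denominator, reported 0):",
        paste(x$undefined, collapse = ", "), "\n")
  invisible(x)
}

#' Spherical payoff of a fitted model over cases
#'
#' Mean over cases of `p_true / sqrt(sum_j p_j^2)` where `p` is the model's
#' posterior for the case. Equals 1 exactly when every posterior puts
#' probability 1 on the true state, and 0 when every posterior is certain
#' and wrong.
#'
#' @param model A fitted `bn_model`.
#' @param cases Discretized case table with `outcome`.
#' @return Value in `[0, 1]`.
#' @export
spherical_payoff <- function(model, cases) {
  if (!nrow(cases)) stop("need at least one case")
  states <- model$response$states
  actual <- factor(as.character(cases$outcome), levels = states)
  post <- posterior_cases(model, cases)
  spherical_payoff_scores(post, actual)
}

#' @rdname spherical_payoff
#' @param post Posterior matrix (cases x states).
#' @param actual Factor of true states with levels in the matrix's column
#'   order.
#' @export
spherical_payoff_scores <- function(post, actual) {
  p_true <- post[cbind(seq_len(nrow(post)), as.integer(actual))]
  mean(p_true / sqrt(rowSums(post^2)))
}

#' Stratified k-fold cross-validation
#'
#' Splits the cases into `k` folds stratified by outcome (fold sizes differ
#' by at most one, per-fold class composition within one case of
#' proportional); for each fold the TAN structure and CPTs are relearned on
#' the remaining folds and the held-out fold is predicted. Confusion tables
#' are summed over folds and the error metrics computed once on the pooled
#' table.
#'
#' @param cases Discretized case table (factors plus `outcome`).
#' @param covariates Covariate columns to model.
#' @param k Number of folds (default 4); `2 <= k <= n`.
#' @param seed Integer seed controlling fold assignment (default 42).
#' @param focal_state Focal response state.
#' @param alpha CPT smoothing weight.
#' @param tree `TRUE` for TAN, `FALSE` for naive Bayes.
#' @return A `model_evaluation` over the pooled held-out predictions, with a
#'   `folds` attribute giving fold sizes. Complexity reports the model fitted
#'   on all cases.
#' @export
kfold_cv <- function(cases, covariates, k = 4, seed = 42,
                     focal_state = "RERA", alpha = 1, tree = TRUE) {
  n <- nrow(cases)
  stopifnot(k >= 2, n >= k)
  fold <- integer(n)
  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv())
  on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()))
  set.seed(seed)
  # round-robin assignment continued across classes: per-class and overall
  # fold sizes both differ by at most one
  ptr <- sample.int(k, 1L) - 1L
  for (cls in levels(cases$outcome)) {
    idx <- which(cases$outcome == cls)
    if (!length(idx)) next
    idx <- sample(idx)
    fold[idx] <- 1L + (ptr + seq_along(idx) - 1L) %% k
    ptr <- (ptr + length(idx)) %% k
  }
  if (any(tabulate(fold, k) == 0))
    stop("a fold received no cases; reduce k")

  states <- levels(cases$outcome)
  confusion <- NULL
  post_all <- matrix(NA_real_, n, length(states))
  pred_all <- character(n)
  for (f in seq_len(k)) {
    train <- cases[fold != f, , drop = FALSE]
    test <- cases[fold == f, , drop = FALSE]
    skel <- learn_tan_structure(train, covariates, tree = tree)
    fit <- learn_cpts(skel, train, alpha = alpha)
    post <- posterior_cases(fit, test)
    # held-out states are mapped through the full state space
    pm <- matrix(0, nrow(test), length(states))
    pm[, match(fit$response$states, states)] <- post
    post_all[fold == f, ] <- pm
    pred_all[fold == f] <- states[max.col(pm, ties.method = "first")]
  }
  actual <- cases$outcome
  predicted <- factor(pred_all, levels = states)
  confusion <- table(actual = actual, predicted = predicted)
  overall <- (sum(confusion) - sum(diag(confusion))) / n
  pred_pos <- predicted == focal_state
  act_pos <- actual == focal_state
  undefined <- character()
  if (!sum(pred_pos)) { type1 <- 0; undefined <- "type1" }
  else type1 <- sum(pred_pos & !act_pos) / sum(pred_pos)
  if (!sum(!pred_pos)) { type2 <- 0; undefined <- c(undefined, "type2") }
  else type2 <- sum(!pred_pos & act_pos) / sum(!pred_pos)
  full <- learn_cpts(learn_tan_structure(cases, covariates, tree = tree),
                     cases, alpha = alpha)
  out <- structure(list(n_cases = n, confusion = confusion,
                        overall_error = overall, type1_error = type1,
                        type2_error = type2,
                        spherical_payoff =
                          spherical_payoff_scores(post_all, actual),
                        complexity = complexity(full),
                        focal_state = focal_state, undefined = undefined),
                   class = "model_evaluation")
  attr(out, "folds") <- tabulate(fold, k)
  attr(out, "fold_assignment") <- fold
  out
}

#' Entropy reduction of the response by one covariate
#'
#' Mutual information `I(C; X) = H(C) - H(C | X)` in bits under the model's
#' own joint distribution, obtained by exact enumeration: for each covariate
#' state, `P(C, X = x)` is computed by marginalizing all other covariates
#' over the covariate tree.
#'
#' @param model A fitted `bn_model`.
#' @param covariate A covariate node name.
#' @return Value in `[0, H(C)]` bits.
#' @export
entropy_reduction <- function(model, covariate) {
  if (!covariate %in% names(model$nodes))
    stop("covariate ", covariate, " not in model")
  states <- model$nodes[[covariate]]
  prior <- model$cpts[[model$response$name]]
  joint <- matrix(0, length(prior), length(states))
  for (s in seq_along(states)) {
    ev <- stats::setNames(list(states[s]), covariate)
    lik <- vapply(seq_along(prior), function(ci)
      exp(.class_loglik(model, ev, ci)), 0)
    joint[, s] <- prior * lik
  }
  joint <- joint / sum(joint)
  p_c <- rowSums(joint); p_x <- colSums(joint)
  nz <- joint > 0
  denom <- outer(p_c, p_x)
  sum(joint[nz] * log2(joint[nz] / denom[nz]))
}

#' Entropy-reduction sensitivity report
#'
#' @param model A fitted `bn_model`.
#' @return A `sensitivity_report` data.frame (`covariate`,
#'   `entropy_reduction` in bits) sorted descending, with the response
#'   entropy `H(C)` as attribute `response_entropy`.
#' @export
sensitivity_report <- function(model) {
  covs <- names(model$nodes)
  er <- vapply(covs, function(nm) entropy_reduction(model, nm), 0)
  out <- data.frame(covariate = covs, entropy_reduction = unname(er),
                    stringsAsFactors = FALSE)
  out <- out[order(-out$entropy_reduction, out$covariate), , drop = FALSE]
  rownames(out) <- NULL
  prior <- model$cpts[[model$response$name]]
  nzp <- prior[prior > 0]
  attr(out, "response_entropy") <- -sum(nzp * log2(nzp))
  class(out) <- c("sensitivity_report", "data.frame")
  out
}
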