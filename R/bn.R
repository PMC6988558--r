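#' Class-conditional mutual information between two discretized covariates
#'
#' `I(Xi; Xj | C)` in bits, from empirical frequencies over the cases
#' complete in all three variables; `0 * log 0` terms contribute zero.
#'
#' @param cases Discretized case table ([discretize_cases()]): factor columns
#'   plus `outcome`.
#' @param xi,xj Covariate column names.
#' @param response Response column name (default `"outcome"`).
#' @return Nonnegative value in bits.
#' @export
conditional_mutual_information <- function(cases, xi, xj,
                                           response = "outcome") {
  ok <- stats::complete.cases(cases[[xi]], cases[[xj]], cases[[response]])
  if (!any(ok)) stop("no cases complete in ", xi, ", ", xj, " and ", response)
  tab <- table(cases[[xi]][ok], cases[[xj]][ok], cases[[response]][ok])
  n <- sum(tab)
  p_ijc <- tab / n
  p_ic <- apply(tab, c(1, 3), sum) / n
  p_jc <- apply(tab, c(2, 3), sum) / n
  p_c <- apply(tab, 3, sum) / n
  tot <- 0
  for (c_ in seq_along(p_c)) {
    pij <- p_ijc[, , c_]
    denom <- outer(p_ic[, c_], p_jc[, c_]) / max(p_c[c_], .Machine$double.xmin)
    nz <- pij > 0
    tot <- tot + sum(pij[nz] * log2(pij[nz] / denom[nz]))
  }
  max(tot, 0)
}

#' Induce a tree-augmented naive Bayes structure
#'
#' Links run from the response to every covariate; covariates are further
#' joined by the maximum-weight spanning tree over pairwise class-conditional
#' mutual information (the Chow-Liu tree given the class), oriented outward
#' from `root`. For `k >= 2` covariates the structure has `2k - 1` links.
#' MST ties are broken deterministically by lexicographic edge name.
#'
#' @param cases Discretized case table.
#' @param covariates Covariate column names (length >= 1).
#' @param response Response column name.
#' @param root Covariate used as tree root; default the first covariate.
#' @param tree For `naive = TRUE`-style plain structures set `tree = FALSE`
#'   to skip the covariate tree (naive Bayes).
#' @return A `bn_model` skeleton (no CPTs yet): `response` (name, states),
#'   `nodes` (named list of state vectors), `parents` (named list), `links`
#'   (two-column matrix from, to).
#' @export
learn_tan_structure <- function(cases, covariates, response = "outcome",
                                root = covariates[1], tree = TRUE) {
  stopifnot(length(covariates) >= 1, root %in% covariates)
  resp_states <- .node_states(cases[[response]])
  nodes <- lapply(stats::setNames(covariates, covariates),
                  function(nm) .node_states(cases[[nm]]))
  parents <- lapply(stats::setNames(covariates, covariates),
                    function(nm) response)

  if (tree && length(covariates) >= 2) {
    cmb <- utils::combn(covariates, 2)
    w <- vapply(seq_len(ncol(cmb)), function(i)
      conditional_mutual_information(cases, cmb[1, i], cmb[2, i], response),
      0)
    # Kruskal on negated weights with lexicographic tie-break
    ord <- order(-w, cmb[1, ], cmb[2, ])
    comp <- stats::setNames(seq_along(covariates), covariates)
    und <- list()
    for (i in ord) {
      a <- cmb[1, i]; b <- cmb[2, i]
      if (comp[a] != comp[b]) {
        und[[length(und) + 1L]] <- c(a, b)
        comp[comp == comp[b]] <- comp[a]
      }
    }
    # orient outward from root by BFS over the undirected tree
    adj <- lapply(stats::setNames(vector("list", length(covariates)),
                                  covariates), function(x) character())
    for (e in und) {
      adj[[e[1]]] <- c(adj[[e[1]]], e[2])
      adj[[e[2]]] <- c(adj[[e[2]]], e[1])
    }
    seen <- root; queue <- root
    while (length(queue)) {
      cur <- queue[1]; queue <- queue[-1]
      for (nb in adj[[cur]]) {
        if (nb %in% seen) next
        parents[[nb]] <- c(response, cur)
        seen <- c(seen, nb); queue <- c(queue, nb)
      }
    }
  }

  links <- do.call(rbind, c(list(matrix(character(), 0, 2)), lapply(
    covariates, function(nm)
      cbind(parents[[nm]], rep(nm, length(parents[[nm]]))))))
  colnames(links) <- c("from", "to")
  structure(list(response = list(name = response, states = resp_states),
                 nodes = nodes, parents = parents, links = links,
                 cpts = NULL, meta = list()),
            class = "bn_model")
}

.node_states <- function(x) {
  if (is.factor(x)) levels(x) else sort(unique(as.character(x[!is.na(x)])))
}

#' @export
print.bn_model <- function(x, ...) {
  k <- length(x$nodes)
  cat("Discrete Bayesian network: response '", x$response$name, "' (",
      length(x$response$states), " states), ", k, " covariate node(s), ",
      nrow(x$links), " links", if (is.null(x$cpts)) " [skeleton]", "\n",
      sep = "")
  invisible(x)
}

#' Learn conditional probability tables from cases
#'
#' Frequency counting with optional additive smoothing: each CPT row is
#' `(count + alpha) / (total + alpha * n_states)`. Counts for a node use the
#' cases complete in that node and all its parents (available-case analysis);
#' never-observed parent configurations get a uniform row.
#'
#' @param skeleton A [learn_tan_structure()] result.
#' @param cases Discretized case table.
#' @param alpha Smoothing weight; `alpha = 0` reproduces empirical
#'   conditional frequencies exactly on complete data. Default 1.
#' @return The `bn_model` with `cpts` filled in: for the response a named
#'   probability vector, for each covariate an array with the child states on
#'   the first dimension and parent states on the remaining ones. Every row
#'   sums to 1.
#' @export
learn_cpts <- function(skeleton, cases, alpha = 1) {
  stopifnot(inherits(skeleton, "bn_model"), alpha >= 0)
  m <- skeleton
  resp <- m$response$name
  y <- factor(cases[[resp]], levels = m$response$states)
  cnt <- table(y)
  pr <- (as.numeric(cnt) + alpha) / (sum(cnt) + alpha * length(cnt))
  if (sum(cnt) == 0 && alpha == 0) pr <- rep(1 / length(cnt), length(cnt))
  m$cpts <- list()
  m$cpts[[resp]] <- stats::setNames(pr / sum(pr), m$response$states)

  for (nm in names(m$nodes)) {
    pars <- m$parents[[nm]]
    dims <- c(list(m$nodes[[nm]]),
              lapply(pars, function(p) .model_states(m, p)))
    vars <- c(nm, pars)
    fac <- lapply(seq_along(vars), function(i)
      factor(cases[[vars[i]]], levels = dims[[i]]))
    ok <- stats::complete.cases(as.data.frame(fac))
    tab <- table(lapply(fac, function(f) f[ok]))
    tab <- tab + alpha
    tot <- apply(tab, seq_along(dims)[-1], sum)
    cpt <- sweep(tab, seq_along(dims)[-1], tot, "/")
    # zero-total rows (alpha = 0, unseen configuration) become uniform
    if (any(tot == 0)) {
      k <- length(dims[[1]])
      cpt <- array(cpt, dim = dim(tab))
      flat <- matrix(cpt, nrow = k)
      bad <- which(rep(tot == 0, each = 1))
      flat[, bad] <- 1 / k
      cpt <- array(flat, dim = dim(tab))
    }
    cpt <- array(as.numeric(cpt), dim = vapply(dims, length, 0L),
                 dimnames = stats::setNames(dims, vars))
    m$cpts[[nm]] <- cpt
  }
  m
}

.model_states <- function(m, node) {
  if (node == m$response$name) m$response$states else m$nodes[[node]]
}

#' Posterior distribution of the response given (possibly partial) evidence
#'
#' Computes `P(C | evidence)` exactly. Evidence may omit any covariates
#' (including `NA` entries): missing nodes are summed out along the
#' class-conditional covariate tree by message passing, which is exact
#' because given the class the covariates form a forest.
#'
#' @param model A fitted `bn_model`.
#' @param evidence Named list/vector of state labels (or `NA`) for some or
#'   all covariate nodes.
#' @return Named probability vector over response states (sums to 1).
#' @export
posterior <- function(model, evidence = list()) {
  stopifnot(!is.null(model$cpts))
  ev <- evidence[!is.na(evidence)]
  unknown <- setdiff(names(ev), names(model$nodes))
  if (length(unknown)) stop("evidence on unknown node(s): ",
                            paste(unknown, collapse = ", "))
  for (nm in names(ev))
    if (!ev[[nm]] %in% model$nodes[[nm]])
      stop("state '", ev[[nm]], "' invalid for node ", nm)
  resp_states <- model$response$states
  loglik <- vapply(seq_along(resp_states), function(ci)
    .class_loglik(model, ev, ci), 0)
  w <- model$cpts[[model$response$name]] * exp(loglik - max(loglik))
  w / sum(w)
}

# log P(evidence | C = class ci): eliminate covariates children-first along
# the tree. message[[node]] is a function of the node's covariate parent
# state (or a scalar for response-only parents).
.class_loglik <- function(model, ev, ci) {
  covs <- names(model$nodes)
  # children before parents: order by tree depth, deepest first
  depth <- vapply(covs, function(nm) {
    d <- 0L; cur <- nm
    repeat {
      p <- setdiff(model$parents[[cur]], model$response$name)
      if (!length(p)) return(d)
      d <- d + 1L; cur <- p
    }
  }, 0L)
  msgs <- lapply(stats::setNames(covs, covs),
                 function(nm) rep(1, length(model$nodes[[nm]])))
  total_log <- 0
  for (nm in covs[order(-depth)]) {
    cpt <- model$cpts[[nm]]
    pars <- model$parents[[nm]]
    cov_par <- setdiff(pars, model$response$name)
    k <- length(model$nodes[[nm]])
    # P(x_nm | parents, c) as matrix child x (cov-parent states or 1)
    mat <- if (length(cov_par)) {
      if (which(pars == model$response$name) == 1L)
        matrix(cpt[, ci, ], nrow = k)
      else matrix(cpt[, , ci], nrow = k)
    } else matrix(cpt[, ci], nrow = k)
    inc <- msgs[[nm]]  # product of child messages, per state of nm
    if (!is.na(st <- .ev_state(ev, nm, model))) {
      vals <- mat[st, ] * inc[st]
    } else {
      vals <- as.numeric(inc %*% mat)
    }
    if (length(cov_par)) {
      msgs[[cov_par]] <- msgs[[cov_par]] * vals
    } else {
      total_log <- total_log + log(max(vals, .Machine$double.xmin))
    }
  }
  total_log
}

.ev_state <- function(ev, nm, model) {
  if (!nm %in% names(ev)) return(NA_integer_)
  match(ev[[nm]], model$nodes[[nm]])
}

#' Predict the response state
#'
#' Argmax of [posterior()]; ties go to the earlier response state.
#'
#' @param object A fitted `bn_model`.
#' @param evidence Evidence as in [posterior()], or a discretized case table
#'   (data.frame) for vectorized prediction.
#' @param ... Unused.
#' @return A single state label, or a character vector for a case table.
#' @export
predict.bn_model <- function(object, evidence = list(), ...) {
  if (is.data.frame(evidence)) {
    post <- posterior_cases(object, evidence)
    return(object$response$states[max.col(post, ties.method = "first")])
  }
  p <- posterior(object, evidence)
  names(p)[which.max(p)]
}

#' Posterior matrix over a discretized case table
#'
#' Row `i` is `P(C | evidence in case i)`. Complete cases are computed
#' vectorized; cases with missing covariates fall back to exact
#' marginalization via [posterior()].
#'
#' @param model A fitted `bn_model`.
#' @param cases Discretized case table containing the model's covariate
#'   columns.
#' @return Numeric matrix, `nrow(cases)` x response states.
#' @export
posterior_cases <- function(model, cases) {
  covs <- names(model$nodes)
  n <- nrow(cases)
  resp_states <- model$response$states
  idx <- lapply(stats::setNames(covs, covs), function(nm)
    match(as.character(cases[[nm]]), model$nodes[[nm]]))
  complete <- Reduce(`&`, lapply(idx, function(i) !is.na(i)), rep(TRUE, n))
  loglik <- matrix(0, n, length(resp_states))
  for (ci in seq_along(resp_states)) {
    acc <- log(model$cpts[[model$response$name]][ci])
    ll <- rep(acc, n)
    for (nm in covs) {
      cpt <- model$cpts[[nm]]
      pars <- model$parents[[nm]]
      cov_par <- setdiff(pars, model$response$name)
      if (length(cov_par)) {
        resp_first <- which(pars == model$response$name) == 1L
        sub <- if (resp_first) cpt[, ci, , drop = FALSE] else cpt[, , ci, drop = FALSE]
        sub <- matrix(sub, nrow = dim(cpt)[1])
        v <- sub[cbind(idx[[nm]], idx[[cov_par]])]
      } else {
        v <- cpt[idx[[nm]], ci]
      }
      ll <- ll + log(pmax(v, .Machine$double.xmin))
    }
    loglik[, ci] <- ll
  }
  post <- matrix(NA_real_, n, length(resp_states),
                 dimnames = list(NULL, resp_states))
  if (any(complete)) {
    lm_ <- loglik[complete, , drop = FALSE]
    lm_ <- exp(lm_ - apply(lm_, 1, max))
    post[complete, ] <- lm_ / rowSums(lm_)
  }
  for (i in which(!complete)) {
    ev <- lapply(covs, function(nm) as.character(cases[[nm]][i]))
    names(ev) <- covs
    post[i, ] <- posterior(model, ev)
  }
  post
}

#' Model complexity: nodes, links, probability values
#'
#' Probability values count every CPT cell including the response prior:
#' for each node, `|states| * prod(|parent states|)`.
#'
#' @param model A `bn_model` (skeleton or fitted).
#' @return List `(n_nodes, n_links, n_probabilities)`.
#' @export
complexity <- function(model) {
  n_nodes <- 1L + length(model$nodes)
  n_links <- nrow(model$links)
  n_prob <- length(model$response$states)
  for (nm in names(model$nodes)) {
    par_card <- prod(vapply(model$parents[[nm]],
                            function(p) length(.model_states(model, p)), 0L))
    n_prob <- n_prob + length(model$nodes[[nm]]) * par_card
  }
  list(n_nodes = n_nodes, n_links = as.integer(n_links),
       n_probabilities = as.integer(n_prob))
}

#' Write / read a fitted model as JSON
#'
#' Round-trip exact: states, links, parents, and CPT values are preserved.
#'
#' @param model A fitted `bn_model`.
#' @param path JSON path.
#' @return `path` (write) or the `bn_model` (read).
#' @export
write_bn <- function(model, path) {
  ser <- list(
    response = model$response,
    nodes = model$nodes,
    parents = model$parents,
    links = as.data.frame(model$links),
    meta = model$meta,
    cpts = lapply(model$cpts, function(x) {
      if (is.null(dim(x))) list(dim = length(x), dimnames = list(names(x)),
                                values = as.numeric(x))
      else list(dim = dim(x), dimnames = dimnames(x),
                values = as.numeric(x))
    }))
  jsonlite::write_json(ser, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname write_bn
#' @export
read_bn <- function(path) {
  raw <- jsonlite::read_json(path, simplifyVector = TRUE)
  cpts <- lapply(raw$cpts, function(ct) {
    if (length(ct$dim) == 1L)
      stats::setNames(as.numeric(ct$values), unlist(ct$dimnames))
    else array(as.numeric(ct$values), dim = unlist(ct$dim),
               dimnames = ct$dimnames)
  })
  nodes <- lapply(raw$nodes, as.character)
  parents <- lapply(raw$parents, as.character)
  links <- as.matrix(raw$links)
  colnames(links) <- c("from", "to")
  structure(list(response = list(name = raw$response$name,
                                 states = as.character(raw$response$states)),
                 nodes = nodes, parents = parents, links = links,
                 cpts = cpts,
                 meta = raw$meta),
            class = "bn_model")
}
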