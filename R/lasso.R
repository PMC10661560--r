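#' Build the genes x factors binding matrix
#'
#' @param target_sets named list: factor id -> character vector of target
#'   gene ids (peak multiplicity is irrelevant, entries are binary).
#' @param genes character vector of all gene ids (matrix rows, in order).
#' @return binary matrix with `genes` as rownames and factor ids as
#'   colnames; `A[i, j] = 1` iff factor j targets gene i.
#' @export
build_binding_matrix <- function(target_sets, genes) {
  if (is.null(names(target_sets)) || any(!nzchar(names(target_sets)))) {
    stop("target_sets must be a named list of gene-id vectors")
  }
  A <- matrix(0L, length(genes), length(target_sets),
              dimnames = list(genes, names(target_sets)))
  for (f in names(target_sets)) {
    tg <- unique(as.character(target_sets[[f]]))
    bad <- setdiff(tg, genes)
    if (length(bad)) {
      stop("target gene absent from gene list: ", bad[1L],
           " (factor ", f, ")")
    }
    A[tg, f] <- 1L
  }
  A
}

.check_xy <- function(X, y) {
  if (!is.matrix(X)) stop("X must be a matrix")
  y <- as.numeric(y)
  if (length(y) != nrow(X)) stop("X and y are not conformable")
  if (!all(y %in% c(0, 1))) stop("y must be binary (0/1)")
  if (length(unique(y)) < 2L) {
    stop("degenerate outcome: y has no variation")
  }
  y
}

#' Largest penalty with any active coefficient
#'
#' At `lambda >= lambda_max` the L1-penalized logistic fit with an
#' unpenalized intercept is the null model (all slopes zero, intercept at
#' the outcome log-odds).
#'
#' @param X binary predictor matrix; @param y binary outcome.
#' @return lambda_max on the objective scale used by
#'   [fit_penalized_logistic()] (mean negative log-likelihood + penalty).
#' @export
lambda_max <- function(X, y) {
  y <- .check_xy(X, y)
  max(abs(crossprod(X, y - mean(y)))) / nrow(X)
}

#' Log-spaced penalty grid
#'
#' @param X,y data; @param n_lambda grid size (default 100);
#' @param min_ratio smallest lambda as a fraction of lambda_max
#'   (default 1e-4).
#' @return decreasing numeric vector of length `n_lambda`.
#' @export
lambda_grid <- function(X, y, n_lambda = 100, min_ratio = 1e-4) {
  lmax <- lambda_max(X, y)
  exp(seq(log(lmax), log(lmax * min_ratio), length.out = n_lambda))
}

#' L1-penalized logistic regression (single penalty)
#'
#' Minimizes the mean binomial negative log-likelihood plus
#' `lambda * sum(|beta_j|)` with an unpenalized intercept, by iteratively
#' reweighted least squares with cyclic coordinate descent and a
#' backtracking safeguard (the objective is non-increasing across
#' iterations). Deterministic: coordinates are visited in fixed column
#' order, so duplicated columns always resolve the same way.
#'
#' @param X numeric matrix, genes x factors (binary in the intended use,
#'   any numeric works); column names are factor ids.
#' @param y binary outcome per row (1 = non-sc homoeolog, 0 = sc-triad in
#'   the regulator screen).
#' @param lambda penalty (>= 0).
#' @param standardize scale columns to unit (population) SD before
#'   fitting and back-transform the coefficients; off by default because
#'   binary incidence columns already share a scale.
#' @param ... solver controls: `max_outer`, `max_inner`, `tol`.
#' @return object of class `penalized_fit`: `coefficients` (named, on the
#'   original scale), `intercept`, `lambda`, `objective`, `kkt`,
#'   `converged`.
#' @export
fit_penalized_logistic <- function(X, y, lambda, standardize = FALSE, ...) {
  y <- .check_xy(X, y)
  if (lambda < 0) stop("lambda must be >= 0")
  path <- .fit_path(X, y, lambda, standardize = standardize, ...)
  structure(
    list(coefficients = path$beta[, 1L], intercept = path$gamma[1L],
         lambda = lambda, objective = path$objective[1L],
         kkt = path$kkt[1L], converged = path$converged[1L]),
    class = "penalized_fit"
  )
}

# path fit with optional standardization; lambdas must be decreasing
.fit_path <- function(X, y, lambdas, standardize = FALSE, max_outer = 100,
                      max_inner = 1000, tol = 1e-10) {
  scale_j <- rep(1, ncol(X))
  Xf <- X
  if (standardize) {
    n <- nrow(X)
    scale_j <- sqrt(colMeans(X^2) - colMeans(X)^2)
    scale_j[scale_j == 0] <- 1
    Xf <- sweep(X, 2L, scale_j, "/")
  }
  res <- .lasso_logistic_path_cpp(Xf, y, as.numeric(lambdas),
                                  max_outer, max_inner, tol)
  beta <- res$beta / scale_j
  rownames(beta) <- colnames(X)
  list(beta = beta, gamma = res$gamma, objective = res$objective,
       kkt = res$kkt, converged = res$converged)
}

.binomial_deviance <- function(y, eta) {
  p <- 1 / (1 + exp(-eta))
  p <- pmin(pmax(p, 1e-12), 1 - 1e-12)
  -2 * mean(y * log(p) + (1 - y) * log(1 - p))
}

# fold assignment depends only on the supplied seed, not the caller's
# RNG state (saved and restored around the draw)
.stratified_folds <- function(y, k, seed) {
  if (k < 2L) stop("k must be >= 2")
  old <- if (exists(".Random.seed", globalenv())) {
    get(".Random.seed", globalenv())
  }
  on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()))
  set.seed(seed)
  fold <- integer(length(y))
  for (cls in unique(y)) {
    idx <- which(y == cls)
    idx <- idx[sample.int(length(idx))]
    fold[idx] <- rep_len(seq_len(k), length(idx))
  }
  for (f in seq_len(k)) {
    held <- y[fold == f]
    if (length(unique(held)) < 2L) {
      stop("fold ", f, " holds a single outcome class; use smaller k")
    }
  }
  fold
}

#' Cross-validated penalty selection for the regulator screen
#'
#' Stratified k-fold cross-validation over a decreasing penalty grid,
#' choosing the penalty minimizing mean held-out binomial deviance
#' (`lambda_min`; set `one_se = TRUE` for the conservative
#' one-standard-error rule), then refitting on all data at the chosen
#' penalty. Degenerate predictor columns (all-0 / all-1) are dropped
#' before fitting with a warning; duplicated columns are kept but flagged
#' as aliased in the result.
#'
#' @param X binary binding matrix, genes x factors (colnames = factors).
#' @param y binary outcome per gene.
#' @param k folds (default 10; `k = nrow(X)` gives leave-one-out, for
#'   which stratification degenerates gracefully).
#' @param lambdas penalty grid (default [lambda_grid()] with 100 values).
#' @param seed integer seed controlling fold assignment only.
#' @param one_se choose the largest penalty within one SE of the minimum.
#' @param standardize see [fit_penalized_logistic()].
#' @return object of class `cv_penalized_fit`: `lambda`, `cvm`, `cvse`,
#'   `lambda_min`, `lambda_choice`, `fit` (the refit `penalized_fit`),
#'   `folds`, `seed`, `dropped` (degenerate columns), `aliased` (list of
#'   identical-column groups).
#' @export
cross_validate_select <- function(X, y, k = 10, lambdas = NULL, seed = 1,
                                  one_se = FALSE, standardize = FALSE) {
  y <- .check_xy(X, y)
  if (is.null(colnames(X))) {
    colnames(X) <- paste0("factor_", seq_len(ncol(X)))
  }
  rng_range <- apply(X, 2L, function(cl) max(cl) - min(cl))
  dropped <- colnames(X)[rng_range == 0]
  if (length(dropped)) {
    warning("dropping degenerate (constant) columns: ",
            paste(dropped, collapse = ", "))
    X <- X[, rng_range > 0, drop = FALSE]
  }
  key <- apply(X, 2L, paste, collapse = "")
  aliased <- unname(split(colnames(X), key))
  aliased <- aliased[vapply(aliased, length, integer(1)) > 1L]

  if (is.null(lambdas)) lambdas <- lambda_grid(X, y)
  lambdas <- sort(as.numeric(lambdas), decreasing = TRUE)

  k <- min(k, nrow(X))
  fold <- if (k == nrow(X)) seq_len(nrow(X)) else .stratified_folds(y, k, seed)
  dev <- matrix(NA_real_, k, length(lambdas))
  for (f in seq_len(k)) {
    tr <- fold != f
    path <- .fit_path(X[tr, , drop = FALSE], y[tr], lambdas,
                      standardize = standardize)
    eta <- X[!tr, , drop = FALSE] %*% path$beta
    eta <- sweep(eta, 2L, path$gamma, "+")
    dev[f, ] <- vapply(seq_along(lambdas), function(l) {
      .binomial_deviance(y[!tr], eta[, l])
    }, numeric(1))
  }
  cvm <- colMeans(dev)
  cvse <- apply(dev, 2L, stats::sd) / sqrt(k)
  i_min <- which.min(cvm)
  lambda_min <- lambdas[i_min]
  lambda_choice <- if (one_se) {
    max(lambdas[cvm <= cvm[i_min] + cvse[i_min]])
  } else {
    lambda_min
  }
  # refit on all data, warm-started down the path to the chosen lambda
  full <- .fit_path(X, y, lambdas[lambdas >= lambda_choice],
                    standardize = standardize)
  l_idx <- sum(lambdas >= lambda_choice)
  fit <- structure(
    list(coefficients = full$beta[, l_idx], intercept = full$gamma[l_idx],
         lambda = lambda_choice, objective = full$objective[l_idx],
         kkt = full$kkt[l_idx], converged = full$converged[l_idx]),
    class = "penalized_fit"
  )
  structure(
    list(lambda = lambdas, cvm = cvm, cvse = cvse,
         lambda_min = lambda_min, lambda_choice = lambda_choice,
         fit = fit, folds = fold, seed = seed, dropped = dropped,
         aliased = aliased),
    class = "cv_penalized_fit"
  )
}

#' Rank trans-factors by penalized coefficient
#'
#' Orders factors by signed coefficient for the non-sc orientation (a
#' positive coefficient means preferential binding at non-sc homoeologs);
#' the companion sc-triad orientation is the same model with the outcome
#' inverted, which for a logistic model exactly negates every
#' coefficient, so both rankings come from one fit. Ties in coefficient
#' are broken by factor id (lexicographic). Factors whose binding columns
#' are identical are flagged aliased.
#'
#' @param cv a `cv_penalized_fit` (or bare `penalized_fit`).
#' @return data.frame `factor_id, beta, selected, aliased, rank_non_sc,
#'   rank_sc` sorted by `rank_non_sc`.
#' @export
rank_factors <- function(cv) {
  fit <- if (inherits(cv, "cv_penalized_fit")) cv$fit else cv
  if (!isTRUE(fit$converged)) {
    warning("solver did not flag convergence at the chosen penalty")
  }
  beta <- fit$coefficients
  ids <- names(beta)
  aliased_ids <- if (inherits(cv, "cv_penalized_fit")) {
    unlist(cv$aliased, use.names = FALSE)
  } else {
    character(0)
  }
  out <- data.frame(
    factor_id = ids, beta = unname(beta), selected = beta != 0,
    aliased = ids %in% aliased_ids, stringsAsFactors = FALSE
  )
  ord_non_sc <- order(-out$beta, out$factor_id)
  ord_sc <- order(out$beta, out$factor_id)
  out$rank_non_sc <- NA_integer_; out$rank_sc <- NA_integer_
  out$rank_non_sc[ord_non_sc] <- seq_len(nrow(out))
  out$rank_sc[ord_sc] <- seq_len(nrow(out))
  out <- out[ord_non_sc, , drop = FALSE]
  rownames(out) <- NULL
  out
}
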