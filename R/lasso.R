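# L1-constrained logistic regression: shrinkage path, entry-order factor
# ranking, and nested cross-validation for the constraint budget.
#
# The constrained problem max loglik s.t. sum|beta| <= t is solved in the
# equivalent Lagrangian (penalised) form by coordinate descent (src/), with a
# bisection from penalty to budget; the reported t is the achieved sum of
# absolute standardised coefficients.  Columns are standardised to unit
# variance for penalisation and coefficients are mapped back to the original
# covariate scale for reporting.  The intercept is never penalised.

standardize_design <- function(X) {
  n <- nrow(X)
  m <- colMeans(X)
  s <- sqrt(colMeans(sweep(X, 2, m)^2))
  active <- s > 1e-12
  Xs <- sweep(sweep(X[, active, drop = FALSE], 2, m[active]), 2, s[active],
              "/")
  list(Xs = Xs, center = m, scale = s, active = active)
}

lambda_max_of <- function(Xs, y) {
  n <- length(y)
  if (ncol(Xs) == 0) return(0)
  max(abs(crossprod(Xs, y - mean(y)) / n))
}

# Solve the penalised problem along a non-increasing lambda sequence.
# Returns coefficients on both the standardised and original scales.
lasso_engine <- function(X, y, lambda, tol = 1e-9, maxit = 200) {
  p <- ncol(X)
  std <- standardize_design(X)
  nlam <- length(lambda)
  beta_std <- matrix(0, p, nlam, dimnames = list(colnames(X), NULL))
  if (ncol(std$Xs) > 0) {
    sol <- cd_logistic(std$Xs, y, lambda, tol = tol, maxit = maxit)
    beta_std[std$active, ] <- sol$beta
    b0_std <- sol$intercept
    converged <- as.logical(sol$converged)
  } else {
    pb <- mean(y)
    b0_std <- rep(qlogis(min(max(pb, 1e-10), 1 - 1e-10)), nlam)
    converged <- rep(TRUE, nlam)
  }
  beta <- beta_std
  beta[std$active, ] <- beta_std[std$active, , drop = FALSE] /
    std$scale[std$active]
  intercept <- b0_std - as.numeric(crossprod(
    std$center[std$active],
    beta[std$active, , drop = FALSE]))
  list(lambda = lambda, beta_std = beta_std, beta = beta,
       intercept = intercept, t = colSums(abs(beta_std)),
       converged = converged)
}

#' Fit an L1-budget-constrained logistic regression
#'
#' Maximises the binomial log-likelihood subject to
#' \eqn{\sum_j |\beta_j| \le t} on the standardised-covariate scale, with an
#' unpenalised intercept.  Internally the equivalent penalised problem is
#' solved by coordinate descent and the penalty is mapped to the requested
#' budget by bisection; the achieved budget is reported back.  Coefficients
#' are returned on the original covariate scale (and on the standardised
#' scale as `coefficients_std`).
#'
#' At `t = 0` all penalised coefficients are exactly zero and the intercept
#' equals the logit of the event rate; for `t` at least the unconstrained
#' MLE budget the fit coincides with the MLE.
#'
#' @param design an `ntcp_design` from [build_design_matrix()], or a numeric
#'   matrix.
#' @param y 0/1 outcome vector.
#' @param t non-negative budget on the standardised coefficient L1 norm.
#' @param tol,maxit coordinate-descent convergence controls.
#' @return object of class `lasso_fit`: `intercept`, `coefficients`,
#'   `coefficients_std`, requested `t`, `t_achieved`, `lambda`, `converged`.
#' @examples
#' coh <- generate_cohort(synthetic_config(n_patients = 300, seed = 11))
#' ep <- derive_endpoint(coh, "12m")
#' d <- build_design_matrix(ep$data, c("dmean_c", "dmean_i", "smoking"))
#' fit_lasso(d, ep$data$outcome, t = 0.2)
#' @export
fit_lasso <- function(design, y, t, tol = 1e-9, maxit = 200) {
  X <- if (inherits(design, "ntcp_design")) design$X else design
  stopifnot(t >= 0, nrow(X) == length(y), all(y %in% c(0, 1)))
  y <- as.numeric(y)
  std <- standardize_design(X)
  lam_max <- lambda_max_of(std$Xs, y)
  solve_at <- function(lam) lasso_engine(X, y, lam, tol = tol, maxit = maxit)
  pack <- function(sol, i = 1) {
    structure(list(intercept = sol$intercept[i],
                   coefficients = sol$beta[, i],
                   coefficients_std = sol$beta_std[, i],
                   t = t, t_achieved = sol$t[i], lambda = sol$lambda[i],
                   converged = sol$converged[i]),
              class = "lasso_fit")
  }
  if (t <= 1e-12 || lam_max == 0) {
    sol <- solve_at(lam_max * 1.0001 + 1e-6)
    out <- pack(sol)
    out$coefficients[] <- 0
    out$coefficients_std[] <- 0
    out$t_achieved <- 0
    return(out)
  }
  mle <- solve_at(0)
  if (!mle$converged)
    stop("coordinate descent failed to converge at the unconstrained limit")
  if (t >= mle$t[1] - 1e-10) return(pack(mle))
  lo <- 0; hi <- lam_max            # g(lambda) = achieved budget, decreasing
  sol_hi <- NULL
  for (iter in 1:60) {
    mid <- (lo + hi) / 2
    sol <- solve_at(mid)
    if (sol$t[1] > t) lo <- mid else { hi <- mid; sol_hi <- sol }
    if (hi - lo < 1e-12 * lam_max) break
  }
  if (is.null(sol_hi)) sol_hi <- solve_at(hi)
  out <- pack(sol_hi)
  if (!out$converged)
    stop("coordinate descent failed to converge (lambda = ", out$lambda, ")")
  out
}

#' @export
print.lasso_fit <- function(x, ...) {
  nz <- sum(x$coefficients_std != 0)
  cat(sprintf(
    "L1-constrained logistic fit: t = %.4g (achieved %.4g), %d nonzero\n",
    x$t, x$t_achieved, nz))
  invisible(x)
}

#' Compute the LASSO shrinkage path
#'
#' Fits the penalised logistic regression along a decreasing penalty
#' sequence (warm starts), from the smallest penalty that zeroes every
#' coefficient down to `lambda_min_ratio` of it, and reports the path
#' indexed by the achieved L1 budget `t` (increasing).  The coefficient
#' trajectories along `t` are the shrinkage path diagram; the order in which
#' factors first leave zero ranks them ([rank_factors()]).
#'
#' Alternatively an explicit increasing grid of budgets `t_grid` can be
#' supplied; each is then solved by [fit_lasso()].
#'
#' @param design `ntcp_design` or numeric matrix.
#' @param y 0/1 outcomes.
#' @param t_grid optional increasing budget grid.
#' @param nlambda number of penalty values (default 100).
#' @param lambda_min_ratio smallest penalty as a fraction of the
#'   all-zero penalty (default 1e-3).
#' @param tol,maxit solver controls.
#' @return object of class `lasso_path`: `t` (achieved budgets), `lambda`,
#'   `intercept`, `beta` (columns of the design x grid, original scale),
#'   `beta_std`, `assign` (factor behind each design column), `df`
#'   (nonzero count per grid point).
#' @examples
#' coh <- generate_cohort(synthetic_config(n_patients = 300, seed = 5))
#' ep <- derive_endpoint(coh, "12m")
#' d <- build_design_matrix(ep$data, names(xer_coding()))
#' path <- compute_path(d, ep$data$outcome, nlambda = 40)
#' rank_factors(path)
#' @export
compute_path <- function(design, y, t_grid = NULL, nlambda = 100,
                         lambda_min_ratio = 1e-3, tol = 1e-9, maxit = 200) {
  X <- if (inherits(design, "ntcp_design")) design$X else design
  assign <- if (inherits(design, "ntcp_design")) design$assign
    else colnames(X)
  y <- as.numeric(y)
  stopifnot(nrow(X) == length(y))
  if (!is.null(t_grid)) {
    stopifnot(length(t_grid) >= 1, !is.unsorted(t_grid))
    fits <- lapply(t_grid, function(tt)
      fit_lasso(design, y, tt, tol = tol, maxit = maxit))
    beta <- sapply(fits, `[[`, "coefficients")
    beta_std <- sapply(fits, `[[`, "coefficients_std")
    if (is.null(dim(beta))) {
      beta <- matrix(beta, ncol = length(fits),
                     dimnames = list(colnames(X), NULL))
      beta_std <- matrix(beta_std, ncol = length(fits),
                         dimnames = list(colnames(X), NULL))
    }
    out <- list(t = vapply(fits, `[[`, 0, "t_achieved"),
                lambda = vapply(fits, `[[`, 0, "lambda"),
                intercept = vapply(fits, `[[`, 0, "intercept"),
                beta = beta, beta_std = beta_std)
  } else {
    std <- standardize_design(X)
    lam_max <- lambda_max_of(std$Xs, y)
    if (lam_max == 0) lam_max <- 1e-3
    lambda <- exp(seq(log(lam_max), log(lam_max * lambda_min_ratio),
                      length.out = nlambda))
    sol <- lasso_engine(X, y, lambda, tol = tol, maxit = maxit)
    out <- list(t = sol$t, lambda = sol$lambda, intercept = sol$intercept,
                beta = sol$beta, beta_std = sol$beta_std)
  }
  out$assign <- assign
  out$columns <- colnames(X)
  out$df <- colSums(out$beta_std != 0)
  structure(out, class = "lasso_path")
}

#' @export
print.lasso_path <- function(x, ...) {
  cat(sprintf(
    "LASSO shrinkage path: %d grid points, t in [%.4g, %.4g], %d columns\n",
    length(x$t), min(x$t), max(x$t), nrow(x$beta)))
  invisible(x)
}

#' Plot the shrinkage path diagram
#'
#' Coefficient trajectories (standardised scale) against the L1 budget `t`.
#'
#' @param x a `lasso_path`.
#' @param label label curves with their column names.
#' @param ... passed to [matplot()].
#' @importFrom graphics matplot text
#' @export
plot.lasso_path <- function(x, label = TRUE, ...) {
  matplot(x$t, t(x$beta_std), type = "l", lty = 1,
          xlab = "L1 budget t (standardised scale)",
          ylab = "standardised coefficient", ...)
  if (label && nrow(x$beta_std)) {
    last <- ncol(x$beta_std)
    text(max(x$t), x$beta_std[, last], rownames(x$beta_std),
         pos = 4, cex = 0.6, xpd = NA)
  }
  invisible(x)
}

#' Export a shrinkage path as a tidy table
#'
#' @param path a `lasso_path`.
#' @param file optional CSV destination.
#' @return data frame with columns `t`, `lambda`, `column`, `factor`,
#'   `coefficient` (original scale), `coefficient_std`.
#' @export
path_to_table <- function(path, file = NULL) {
  stopifnot(inherits(path, "lasso_path"))
  ng <- length(path$t)
  p <- nrow(path$beta)
  out <- data.frame(t = rep(path$t, each = p),
                    lambda = rep(path$lambda, each = p),
                    column = rep(rownames(path$beta), ng),
                    factor = rep(path$assign, ng),
                    coefficient = as.vector(path$beta),
                    coefficient_std = as.vector(path$beta_std))
  if (!is.null(file)) write.csv(out, file, row.names = FALSE)
  out
}

#' Rank prognostic factors by order of entry along the shrinkage path
#'
#' A factor enters the model at the smallest budget `t` at which any of its
#' design columns becomes nonzero (a categorical factor enters with its
#' first indicator).  Factors are ranked by entry budget; ties -- and
#' factors that never enter within the grid -- are ordered by the largest
#' absolute standardised coefficient at the least-constrained end of the
#' path.
#'
#' @param path a `lasso_path` (computed on all candidate factors).
#' @param tol nonzero threshold on standardised coefficients.
#' @return data frame of class `lasso_ranking` with columns `rank`,
#'   `factor`, `entry_t` (`NA` if never entered), `max_abs_std`.
#' @export
rank_factors <- function(path, tol = 1e-8) {
  stopifnot(inherits(path, "lasso_path"))
  factors <- unique(path$assign)
  last <- ncol(path$beta_std)
  info <- lapply(factors, function(f) {
    rows <- which(path$assign == f)
    nz <- colSums(abs(path$beta_std[rows, , drop = FALSE]) > tol) > 0
    idx <- if (any(nz)) which(nz)[1] else NA_integer_
    list(entry_t = if (is.na(idx)) NA_real_ else path$t[idx],
         entry_idx = idx,
         max_abs_std = max(abs(path$beta_std[rows, last])))
  })
  entry_t <- vapply(info, `[[`, 0, "entry_t")
  entry_idx <- vapply(info, function(z)
    if (is.na(z$entry_idx)) Inf else as.numeric(z$entry_idx), 0)
  mag <- vapply(info, `[[`, 0, "max_abs_std")
  ord <- order(entry_idx, -mag)
  out <- data.frame(rank = seq_along(factors), factor = factors[ord],
                    entry_t = entry_t[ord], max_abs_std = mag[ord],
                    stringsAsFactors = FALSE)
  class(out) <- c("lasso_ranking", "data.frame")
  out
}

#' Aggregate entry-order ranking over bootstrap resamples
#'
#' Recomputes the shrinkage path on bootstrap resamples of the cohort and
#' ranks factors by their mean entry rank across resamples -- the bootstrap
#' variant of [rank_factors()] for when a single-path ranking is considered
#' too data-sensitive.
#'
#' @param design `ntcp_design` or matrix.
#' @param y 0/1 outcomes.
#' @param n_boot number of bootstrap resamples.
#' @param seed integer seed.
#' @param nlambda,lambda_min_ratio path controls.
#' @return `lasso_ranking` data frame with `mean_rank` instead of `entry_t`.
#' @export
bootstrap_rank <- function(design, y, n_boot = 200, seed = 1, nlambda = 50,
                           lambda_min_ratio = 1e-3) {
  X <- if (inherits(design, "ntcp_design")) design$X else design
  assign <- if (inherits(design, "ntcp_design")) design$assign
    else colnames(X)
  factors <- unique(assign)
  y <- as.numeric(y)
  ranks <- with_seed(seed, {
    sapply(seq_len(n_boot), function(b) {
      repeat {
        idx <- sample.int(length(y), replace = TRUE)
        if (length(unique(y[idx])) == 2) break
      }
      d <- list(X = X[idx, , drop = FALSE], assign = assign)
      class(d) <- "ntcp_design"
      r <- rank_factors(compute_path(d, y[idx], nlambda = nlambda,
                                     lambda_min_ratio = lambda_min_ratio))
      r$rank[match(factors, r$factor)]
    })
  })
  mean_rank <- rowMeans(ranks)
  ord <- order(mean_rank)
  out <- data.frame(rank = seq_along(factors), factor = factors[ord],
                    mean_rank = mean_rank[ord], stringsAsFactors = FALSE)
  class(out) <- c("lasso_ranking", "data.frame")
  out
}

stratified_folds <- function(y, k, seed) {
  fold <- integer(length(y))
  with_seed(seed, {
    for (cls in unique(y)) {
      idx <- which(y == cls)
      fold[idx] <- sample(rep_len(seq_len(k), length(idx)))
    }
  })
  fold
}

cv_deviance_curve <- function(X, y, lambda, fold, tol, maxit) {
  k <- max(fold)
  dev <- matrix(NA_real_, k, length(lambda))
  for (f in seq_len(k)) {
    tr <- fold != f
    sol <- lasso_engine(X[tr, , drop = FALSE], y[tr], lambda,
                        tol = tol, maxit = maxit)
    eta <- sweep(X[!tr, , drop = FALSE] %*% sol$beta, 2, sol$intercept, "+")
    p <- plogis(eta)
    p <- pmin(pmax(p, 1e-12), 1 - 1e-12)
    yv <- y[!tr]
    dev[f, ] <- -2 * colMeans(yv * log(p) + (1 - yv) * log(1 - p))
  }
  colMeans(dev)
}

#' Select the constraint budget by nested stratified cross-validation
#'
#' Inner 10-fold cross-validation picks the penalty (equivalently the budget
#' `t`) minimising the mean validation deviance; the outer folds document
#' how stable the selected factor subset is (each outer training set runs
#' its own inner CV and reports the subset chosen there).  The final subset
#' is read off the full-data path at the budget chosen by inner CV on the
#' full data.
#'
#' @param design `ntcp_design` or matrix.
#' @param y 0/1 outcomes.
#' @param folds number of folds (default 10, both levels).
#' @param seed integer seed governing all fold draws.
#' @param nlambda,lambda_min_ratio,tol,maxit path/solver controls.
#' @return object of class `lasso_cv`: `chosen_t`, `chosen_lambda`,
#'   `lambda`, `t`, `cv_deviance` (mean curve on the full data),
#'   `final_factors`, `outer_subsets` (list of factor subsets, one per outer
#'   fold), `folds`, `seed`.
#' @export
nested_cv_select <- function(design, y, folds = 10, seed = 1, nlambda = 100,
                             lambda_min_ratio = 1e-3, tol = 1e-8,
                             maxit = 200) {
  X <- if (inherits(design, "ntcp_design")) design$X else design
  assign <- if (inherits(design, "ntcp_design")) design$assign
    else colnames(X)
  y <- as.numeric(y)
  if (sum(y) < folds || sum(1 - y) < folds)
    stop("too few events or non-events for ", folds, " stratified folds")
  std <- standardize_design(X)
  lam_max <- lambda_max_of(std$Xs, y)
  lambda <- exp(seq(log(lam_max), log(lam_max * lambda_min_ratio),
                    length.out = nlambda))
  subset_at <- function(Xd, yd, lam) {
    sol <- lasso_engine(Xd, yd, lam, tol = tol, maxit = maxit)
    i <- length(lam)
    unique(assign[abs(sol$beta_std[, i]) > 1e-8])
  }
  # outer folds: inner CV inside each outer training set
  outer_fold <- stratified_folds(y, folds, substream(seed, 1))
  outer_subsets <- vector("list", folds)
  for (f in seq_len(folds)) {
    tr <- outer_fold != f
    Xtr <- X[tr, , drop = FALSE]; ytr <- y[tr]
    inner_fold <- stratified_folds(ytr, folds, substream(seed, 100 + f))
    cvc <- cv_deviance_curve(Xtr, ytr, lambda, inner_fold, tol, maxit)
    lam_f <- lambda[which.min(cvc)]
    outer_subsets[[f]] <- subset_at(Xtr, ytr, lambda[lambda >= lam_f])
  }
  # full-data inner CV for the reported budget and final subset
  full_fold <- stratified_folds(y, folds, substream(seed, 2))
  cv_full <- cv_deviance_curve(X, y, lambda, full_fold, tol, maxit)
  best <- which.min(cv_full)
  sol <- lasso_engine(X, y, lambda[seq_len(best)], tol = tol, maxit = maxit)
  chosen_t <- sol$t[best]
  final_factors <- unique(assign[abs(sol$beta_std[, best]) > 1e-8])
  structure(list(chosen_t = chosen_t, chosen_lambda = lambda[best],
                 lambda = lambda, t = sol$t[best], cv_deviance = cv_full,
                 final_factors = final_factors,
                 outer_subsets = outer_subsets, folds = folds, seed = seed),
            class = "lasso_cv")
}

#' @export
print.lasso_cv <- function(x, ...) {
  cat(sprintf(
    "Nested %d-fold CV: chosen t = %.4g (lambda = %.4g)\n",
    x$folds, x$chosen_t, x$chosen_lambda))
  cat("  final factors:", paste(x$final_factors, collapse = ", "), "\n")
  invisible(x)
}
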