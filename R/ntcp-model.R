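#' Construct a logistic NTCP model from known coefficients
#'
#' An NTCP (normal tissue complication probability) model is a multivariate
#' logistic regression over prognostic factors: for a patient with covariates
#' \eqn{x_1, \dots, x_n} the linear predictor is
#' \eqn{S = \beta_0 + \sum_i \beta_i x_i} and the complication probability is
#' \eqn{NTCP = e^S / (1 + e^S)}.  This constructor builds such a model from
#' explicit coefficient values (e.g. a published coefficient table or the
#' generating model of a simulation); [ntcp_fit()] estimates one from data.
#'
#' @param intercept the constant \eqn{\beta_0}.
#' @param coefficients named numeric vector; names are design-column names as
#'   produced by [build_design_matrix()] (`"dmean_c"`, `"t_stage:1"`, ...).
#' @param coding coding scheme the column names refer to.
#' @param label optional descriptive label.
#' @return object of class `ntcp_model`.
#' @seealso [ntcp_fit()], [xer_reference_model()], [predict.ntcp_model()]
#' @examples
#' m <- ntcp_model(-21.298,
#'   c(dmean_c = 0.097, dmean_i = 0.101, age = 0.285))
#' predict(m, data.frame(dmean_c = 30.6, dmean_i = 36.3, age = 52))
#' @export
ntcp_model <- function(intercept, coefficients, coding = xer_coding(),
                       label = NULL) {
  stopifnot(is.numeric(intercept), length(intercept) == 1,
            is.numeric(coefficients))
  if (length(coefficients) > 0)
    stopifnot(!is.null(names(coefficients)),
              all(nzchar(names(coefficients))))
  factors <- unique(sub(":.*$", "", names(coefficients)))
  unknown <- setdiff(factors, names(coding))
  if (length(unknown))
    stop("coefficient(s) reference factor(s) not in the coding scheme: ",
         paste(unknown, collapse = ", "))
  structure(list(intercept = unname(intercept), coefficients = coefficients,
                 factor_set = factors, coding = coding, label = label,
                 se = NULL, loglik = NULL, loglik_null = NULL,
                 n = NULL, n_events = NULL),
            class = "ntcp_model")
}

#' Fit a multivariate logistic NTCP model by maximum likelihood
#'
#' Builds the reference-coded design matrix for the requested factors and
#' maximises the binomial log-likelihood (via iteratively reweighted least
#' squares).  Standard errors come from the observed information matrix.
#' Complete separation is detected and raised as an error rather than
#' returned as a silently diverged fit.
#'
#' @param data data frame holding the factors and the outcome column.
#' @param factors character vector of prognostic factor names to include.
#' @param coding coding scheme, see [xer_coding()].
#' @param outcome name of the 0/1 outcome column (default `"outcome"`, as
#'   produced by [derive_endpoint()]).
#' @return object of classes `ntcp_fit` and `ntcp_model`, with coefficient
#'   standard errors, covariance, log-likelihoods (model and intercept-only),
#'   fitted probabilities and the outcome vector attached.
#' @examples
#' coh <- generate_cohort(synthetic_config(n_patients = 400, seed = 7))
#' ep <- derive_endpoint(coh$records, "12m")
#' fit <- ntcp_fit(ep$data, c("dmean_c", "dmean_i"))
#' summary(fit)
#' @export
ntcp_fit <- function(data, factors, coding = xer_coding(),
                     outcome = "outcome") {
  if (!outcome %in% names(data)) stop("outcome column not found: ", outcome)
  y <- data[[outcome]]
  if (!all(y %in% c(0, 1))) stop("outcome must be coded 0/1")
  y <- as.numeric(y)
  if (sum(y) == 0 || sum(y) == length(y))
    stop("need at least one event and one non-event to fit")
  design <- build_design_matrix(data, factors, coding)
  X1 <- cbind(`(Intercept)` = 1, design$X)
  fit <- suppressWarnings(
    glm.fit(X1, y, family = binomial(), control = list(maxit = 100)))
  beta <- fit$coefficients
  if (anyNA(beta))
    stop("design columns are collinear: ",
         paste(names(beta)[is.na(beta)], collapse = ", "))
  p <- fit$fitted.values
  eps <- 1e-7
  if (all(p[y == 1] > 1 - eps) && all(p[y == 0] < eps))
    stop("perfect separation: the maximum likelihood estimate does not exist")
  w <- p * (1 - p)
  info <- crossprod(X1 * sqrt(w))
  vcov <- tryCatch(solve(info), error = function(e)
    stop("information matrix is singular; model cannot be fitted"))
  se <- sqrt(diag(vcov))
  ll <- log_binomial(p, y)
  pbar <- mean(y)
  ll0 <- log_binomial(rep(pbar, length(y)), y)
  m <- ntcp_model(beta[1], beta[-1], coding = coding)
  m$se <- se[-1]
  m$se_intercept <- se[1]
  m$vcov <- vcov
  m$loglik <- ll
  m$loglik_null <- ll0
  m$n <- length(y)
  m$n_events <- sum(y)
  m$fitted <- p
  m$y <- y
  m$factor_set <- factors
  m$design_columns <- design$columns
  m$assign <- design$assign
  m$converged <- fit$converged
  class(m) <- c("ntcp_fit", "ntcp_model")
  m
}

#' Evaluate the NTCP linear predictor and complication probability
#'
#' `type = "link"` returns the linear predictor
#' \eqn{S = \beta_0 + \sum \beta_i x_i}; `type = "response"` (default)
#' returns the complication probability \eqn{e^S/(1+e^S)}.
#'
#' @param object an `ntcp_model`.
#' @param newdata data frame of patient records containing every factor of
#'   the model; if omitted for a fitted model, fitted values are returned.
#' @param type `"response"` (NTCP) or `"link"` (S).
#' @param ... unused.
#' @return numeric vector.
#' @export
predict.ntcp_model <- function(object, newdata = NULL,
                               type = c("response", "link"), ...) {
  type <- match.arg(type)
  if (is.null(newdata)) {
    if (!is.null(object$fitted))
      return(if (type == "response") object$fitted else qlogis(object$fitted))
    stop("newdata is required for a model without stored fitted values")
  }
  missing_f <- setdiff(object$factor_set, names(newdata))
  if (length(missing_f))
    stop("record(s) missing model factor(s): ",
         paste(missing_f, collapse = ", "))
  design <- build_design_matrix(newdata, object$factor_set, object$coding)
  beta <- object$coefficients
  absent <- setdiff(names(beta), design$columns)
  # columns absent because the level never occurs contribute 0 by definition
  common <- intersect(names(beta), design$columns)
  S <- as.numeric(object$intercept +
                    design$X[, common, drop = FALSE] %*% beta[common])
  if (length(absent) && any(beta[absent] != 0)) {
    # a non-reference level with nonzero coefficient that never occurs in
    # newdata contributes nothing for these records; that is correct.
  }
  if (type == "link") S else plogis(S)
}

#' @export
coef.ntcp_model <- function(object, ...) {
  c(`(Intercept)` = object$intercept, object$coefficients)
}

#' @export
logLik.ntcp_fit <- function(object, ...) {
  structure(object$loglik, df = length(object$coefficients) + 1,
            nobs = object$n, class = "logLik")
}

#' @export
print.ntcp_model <- function(x, digits = 3, ...) {
  cat("Logistic NTCP model")
  if (!is.null(x$label)) cat(" [", x$label, "]", sep = "")
  cat("\n  NTCP = exp(S)/(1 + exp(S)),  S = ",
      format_s_formula(x, digits), "\n", sep = "")
  invisible(x)
}

format_s_formula <- function(model, digits = 3) {
  b <- model$coefficients
  terms <- sprintf("(%s*%s)", names(b), format(b, digits = digits,
                                               trim = TRUE))
  paste(c(format(model$intercept, digits = max(digits, 5), trim = TRUE),
          terms), collapse = " + ")
}

#' @export
print.ntcp_fit <- function(x, digits = 3, ...) {
  NextMethod()
  cat(sprintf("  n = %d (%d events), logLik = %.3f\n",
              x$n, x$n_events, x$loglik))
  invisible(x)
}

#' Summarise a fitted NTCP model: coefficients, Wald tests, odds ratios
#'
#' @param object an `ntcp_fit`.
#' @param conf_level confidence level for the odds-ratio intervals.
#' @param ... unused.
#' @return object of class `summary.ntcp_fit` with a coefficient table
#'   (beta, SE, z, p) and an odds-ratio table (OR, CI).
#' @export
summary.ntcp_fit <- function(object, conf_level = 0.95, ...) {
  b <- object$coefficients
  se <- object$se
  z <- b / se
  pv <- 2 * pnorm(-abs(z))
  coefs <- cbind(Estimate = c(object$intercept, b),
                 `Std. Error` = c(object$se_intercept, se),
                 `z value` = c(object$intercept / object$se_intercept, z),
                 `Pr(>|z|)` = c(2 * pnorm(-abs(object$intercept /
                                                 object$se_intercept)), pv))
  rownames(coefs) <- c("(Intercept)", names(b))
  or <- odds_ratio(b, se, conf_level = conf_level)
  structure(list(coefficients = coefs, odds_ratios = or,
                 n = object$n, n_events = object$n_events,
                 loglik = object$loglik, loglik_null = object$loglik_null,
                 factor_set = object$factor_set),
            class = "summary.ntcp_fit")
}

#' @export
print.summary.ntcp_fit <- function(x, digits = 3, ...) {
  cat("Multivariate logistic NTCP model (", length(x$factor_set),
      " prognostic factors)\n", sep = "")
  cat(sprintf("n = %d, events = %d\n\n", x$n, x$n_events))
  printCoefmat(x$coefficients, digits = digits, P.values = TRUE,
               has.Pvalue = TRUE)
  cat("\nOdds ratios:\n")
  print(round(x$odds_ratios, 3))
  invisible(x)
}

#' Odds ratio with Wald confidence interval
#'
#' OR = exp(beta); CI = exp(beta +/- z * se), with z the normal quantile for
#' the requested confidence level (1.96 at 95%).
#'
#' @param beta coefficient(s) on the log-odds scale.
#' @param se standard error(s), same length as `beta` (0 allowed).
#' @param conf_level confidence level, default 0.95.
#' @return data frame with columns `beta`, `or`, `lower`, `upper`.
#' @examples
#' odds_ratio(0.292, 0.024)
#' @export
odds_ratio <- function(beta, se = 0, conf_level = 0.95) {
  stopifnot(all(se >= 0))
  se <- rep_len(se, length(beta))
  zq <- -qnorm((1 - conf_level) / 2)
  out <- data.frame(beta = beta, or = exp(beta),
                    lower = exp(beta - zq * se),
                    upper = exp(beta + zq * se))
  rownames(out) <- names(beta)
  out
}

#' @importFrom stats qnorm simulate residuals
NULL

#' Simulate binary outcomes from an NTCP model
#'
#' Draws Bernoulli outcomes with per-record probability given by the model.
#'
#' @param object an `ntcp_model`.
#' @param nsim number of simulated outcome vectors.
#' @param seed integer seed (the caller's RNG state is restored afterwards).
#' @param newdata patient records to simulate for (required unless the model
#'   stores fitted values).
#' @param ... unused.
#' @return data frame with `nsim` columns of 0/1 outcomes.
#' @export
simulate.ntcp_model <- function(object, nsim = 1, seed = NULL,
                                newdata = NULL, ...) {
  p <- predict(object, newdata = newdata, type = "response")
  with_seed(seed, {
    out <- as.data.frame(replicate(nsim, rbinom(length(p), 1, p)))
    names(out) <- paste0("sim_", seq_len(nsim))
    out
  })
}

#' @export
residuals.ntcp_fit <- function(object,
                               type = c("deviance", "pearson", "response"),
                               ...) {
  type <- match.arg(type)
  y <- object$y
  p <- object$fitted
  switch(type,
         response = y - p,
         pearson = (y - p) / sqrt(p * (1 - p)),
         deviance = sign(y - p) *
           sqrt(-2 * (y * log(pmax(p, 1e-12)) +
                        (1 - y) * log(pmax(1 - p, 1e-12)))))
}

#' Diagnostic plots for a fitted NTCP model
#'
#' `which = "roc"` draws the empirical ROC curve; `which = "calibration"`
#' plots observed event fraction against mean predicted NTCP over
#' deciles of predicted risk (the grouping used by the Hosmer-Lemeshow test).
#'
#' @param x an `ntcp_fit`.
#' @param which `"roc"`, `"calibration"`, or both.
#' @param groups number of risk groups for the calibration plot.
#' @param ... passed to [plot()].
#' @return invisibly `x`.
#' @importFrom graphics abline points lines
#' @export
plot.ntcp_fit <- function(x, which = c("roc", "calibration"), groups = 10,
                          ...) {
  which <- match.arg(which, several.ok = TRUE)
  p <- x$fitted
  y <- x$y
  if ("roc" %in% which) {
    th <- c(Inf, sort(unique(p), decreasing = TRUE), -Inf)
    tpr <- vapply(th, function(t) mean(p[y == 1] >= t), 0)
    fpr <- vapply(th, function(t) mean(p[y == 0] >= t), 0)
    plot(fpr, tpr, type = "l", xlab = "1 - specificity",
         ylab = "sensitivity", main = "ROC", ...)
    abline(0, 1, lty = 3)
  }
  if ("calibration" %in% which) {
    g <- risk_groups(p, groups)
    obs <- tapply(y, g, mean)
    exp_ <- tapply(p, g, mean)
    plot(exp_, obs, xlim = 0:1, ylim = 0:1,
         xlab = "mean predicted NTCP", ylab = "observed fraction",
         main = "Calibration", ...)
    abline(0, 1, lty = 3)
  }
  invisible(x)
}

#' Built-in reference NTCP coefficient sets for xerostomia after IMRT
#'
#' Coefficient sets for moderate-to-severe (grade 3+) patient-rated
#' xerostomia at 3 and 12 months after IMRT for head-and-neck cancer,
#' estimated on a 206-patient cohort.  For each time point an *optimal*
#' (larger) and a *suboptimal* (compact) factor set is available; the
#' suboptimal 3-month model, for example, is
#' `S = -21.298 + 0.097*dmean_c + 0.101*dmean_i + 0.285*age`.
#' These serve as defaults for the synthetic-cohort generator's true model
#' and as worked examples for odds-ratio computation.
#'
#' @param which one of `"3m_suboptimal"`, `"3m_optimal"`, `"12m_suboptimal"`,
#'   `"12m_optimal"`.
#' @return an [ntcp_model()].
#' @examples
#' xer_reference_model("3m_suboptimal")
#' @export
xer_reference_model <- function(which = c("12m_suboptimal", "3m_suboptimal",
                                          "3m_optimal", "12m_optimal")) {
  which <- match.arg(which)
  cod <- xer_coding()
  m <- switch(which,
    "3m_suboptimal" = ntcp_model(-21.298,
      c(dmean_c = 0.097, dmean_i = 0.101, age = 0.285), cod),
    "12m_suboptimal" = ntcp_model(-8.028,
      c(dmean_i = 0.155,
        `education:1` = -3.888, `education:2` = -1.294,
        `education:3` = -1.242,
        dmean_c = 0.067, smoking = 1.143,
        `t_stage:1` = -0.958, `t_stage:2` = -1.077,
        `t_stage:3` = -1.374), cod),
    "3m_optimal" = ntcp_model(-22.283,
      c(dmean_c = 0.102, dmean_i = 0.102, age = 0.292,
        `financial:1` = -0.452, `financial:2` = 0.904,
        `financial:3` = -0.086,
        `t_stage:1` = 0.272, `t_stage:2` = -0.25, `t_stage:3` = -1.404,
        `ajcc_stage:2` = -0.481, `ajcc_stage:3` = 0.455,
        `ajcc_stage:4` = 0.560,
        smoking = 0.187,
        `education:1` = -0.009, `education:2` = 0.519,
        `education:3` = 0.207), cod),
    "12m_optimal" = ntcp_model(-12.045,
      c(dmean_i = 0.176,
        `education:1` = -4.097, `education:2` = -1.346,
        `education:3` = -1.165,
        dmean_c = 0.121, smoking = 0.993,
        `t_stage:1` = -0.963, `t_stage:2` = -1.048, `t_stage:3` = -1.522,
        baseline_xer = 0.898, alcohol = 0.913,
        family_history = -0.871, node = 1.034), cod))
  m$label <- which
  m
}

#' Serialize an NTCP model to JSON
#'
#' Writes factor set, coding scheme, intercept, coefficients and (when
#' available) standard errors -- enough to reconstruct the model and its
#' "S = ..." formula exactly.
#'
#' @param model an `ntcp_model`.
#' @param path output file; if `NULL`, the JSON string is returned.
#' @return invisibly the JSON string.
#' @export
write_ntcp_model <- function(model, path = NULL) {
  coding <- lapply(model$coding[model$factor_set], function(s)
    list(type = s$type, levels = s$levels, reference = s$reference))
  obj <- list(label = model$label,
              factor_set = model$factor_set,
              intercept = model$intercept,
              coefficients = as.list(model$coefficients),
              se = if (!is.null(model$se)) as.list(model$se) else NULL,
              coding = coding,
              formula = paste("S =", format_s_formula(model, digits = 6)))
  js <- jsonlite::toJSON(obj, auto_unbox = TRUE, digits = NA, null = "null",
                         pretty = TRUE)
  if (!is.null(path)) writeLines(js, path)
  invisible(js)
}

#' Read an NTCP model written by [write_ntcp_model()]
#' @param path JSON file.
#' @return an `ntcp_model`.
#' @export
read_ntcp_model <- function(path) {
  obj <- jsonlite::fromJSON(path)
  cod <- xer_coding()
  for (nm in names(obj$coding)) {
    s <- obj$coding[[nm]]
    cod[[nm]] <- list(type = s$type,
                      levels = if (is.null(s$levels)) NULL
                        else as.character(s$levels),
                      reference = if (is.null(s$reference)) NULL
                        else as.character(s$reference))
  }
  m <- ntcp_model(obj$intercept, unlist(obj$coefficients), coding = cod,
                  label = obj$label)
  if (!is.null(obj$se)) m$se <- unlist(obj$se)
  m
}
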