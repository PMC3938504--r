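# Model performance suite: discrimination (AUC with bootstrap CI),
# calibration (Hosmer-Lemeshow), overall accuracy (Brier / scaled Brier),
# explained variation (Nagelkerke R2) and the omnibus likelihood-ratio test.

#' Area under the ROC curve (Mann-Whitney concordance)
#'
#' The probability that a randomly chosen event receives a higher prediction
#' than a randomly chosen non-event, with ties counted 1/2 -- computed from
#' midranks, which is exactly the pairwise concordance count.
#'
#' @param predictions numeric predictions (any monotone score).
#' @param outcomes 0/1 outcomes; both classes must be present.
#' @return AUC in `[0, 1]`.
#' @examples
#' auc_concordance(c(0.1, 0.4, 0.35, 0.8), c(0, 0, 1, 1))
#' @export
auc_concordance <- function(predictions, outcomes) {
  stopifnot(length(predictions) == length(outcomes),
            all(outcomes %in% c(0, 1)))
  n1 <- sum(outcomes == 1)
  n0 <- sum(outcomes == 0)
  if (n1 == 0 || n0 == 0)
    stop("AUC requires both outcome classes to be present")
  r <- rank(predictions)
  (sum(r[outcomes == 1]) - n1 * (n1 + 1) / 2) / (n1 * n0)
}

#' Percentile bootstrap confidence interval for the AUC
#'
#' Stratified resampling: events and non-events are resampled separately so
#' every bootstrap cohort keeps both classes and the original prevalence.
#'
#' @param predictions,outcomes as in [auc_concordance()].
#' @param n_boot number of bootstrap resamples (>= 100; default 2000).
#' @param seed integer seed.
#' @param conf_level confidence level (default 0.95).
#' @return named numeric `c(lower, upper)` with attribute `auc`.
#' @export
auc_ci_boot <- function(predictions, outcomes, n_boot = 2000, seed = 1,
                        conf_level = 0.95) {
  stopifnot(n_boot >= 100)
  a <- auc_concordance(predictions, outcomes)
  i1 <- which(outcomes == 1)
  i0 <- which(outcomes == 0)
  boots <- with_seed(seed, vapply(seq_len(n_boot), function(b) {
    idx <- c(sample(i1, length(i1), replace = TRUE),
             sample(i0, length(i0), replace = TRUE))
    auc_concordance(predictions[idx], outcomes[idx])
  }, 0))
  alpha <- (1 - conf_level) / 2
  ci <- unname(quantile(boots, c(alpha, 1 - alpha)))
  structure(c(lower = ci[1], upper = ci[2]), auc = a)
}

risk_groups <- function(predictions, groups) {
  br <- unique(quantile(predictions, probs = seq(0, 1, length.out =
                                                   groups + 1)))
  if (length(br) < 3) return(factor(rep(1, length(predictions))))
  cut(predictions, breaks = br, include.lowest = TRUE, labels = FALSE)
}

#' Hosmer-Lemeshow goodness-of-fit test
#'
#' Groups subjects into (by default ten) groups by quantiles of predicted
#' risk ("deciles of risk") and compares observed with expected event counts:
#' \deqn{C = \sum_g (O_g - E_g)^2 / (n_g \bar\pi_g (1 - \bar\pi_g))}
#' referred to a chi-square distribution with `groups - 2` degrees of freedom
#' (the standard reference for models evaluated on their development data;
#' the degrees of freedom are configurable via `df`).
#'
#' Groups whose expected count is degenerate (mean predicted risk 0 or 1) are
#' merged with their neighbour, with a warning; duplicated quantile breaks
#' likewise reduce the effective number of groups.
#'
#' @param predictions predicted probabilities in `[0, 1]`.
#' @param outcomes 0/1 outcomes.
#' @param groups number of risk groups (default 10); `n >= groups` required.
#' @param df degrees of freedom; default `NULL` means effective groups - 2.
#' @return list of class `hl_test`: `statistic`, `p_value`, `df`, `groups`
#'   (the per-group table).
#' @examples
#' set.seed(1)
#' p <- runif(500)
#' y <- rbinom(500, 1, p)
#' hosmer_lemeshow(p, y)
#' @export
hosmer_lemeshow <- function(predictions, outcomes, groups = 10, df = NULL) {
  stopifnot(length(predictions) == length(outcomes),
            all(predictions >= 0 & predictions <= 1),
            all(outcomes %in% c(0, 1)))
  if (length(predictions) < groups)
    stop("need at least as many observations as groups")
  g <- risk_groups(predictions, groups)
  tab <- data.frame(
    n = as.vector(tapply(outcomes, g, length)),
    observed = as.vector(tapply(outcomes, g, sum)),
    pbar = as.vector(tapply(predictions, g, mean)))
  # merge degenerate groups (expected count 0 or n) with their neighbour
  degen <- tab$pbar <= 0 | tab$pbar >= 1
  while (any(degen) && nrow(tab) > 1) {
    warning("merging a risk group with degenerate expected count")
    i <- which(degen)[1]
    j <- if (i == 1) 2 else i - 1
    tab$pbar[j] <- (tab$pbar[i] * tab$n[i] + tab$pbar[j] * tab$n[j]) /
      (tab$n[i] + tab$n[j])
    tab$n[j] <- tab$n[j] + tab$n[i]
    tab$observed[j] <- tab$observed[j] + tab$observed[i]
    tab <- tab[-i, , drop = FALSE]
    degen <- tab$pbar <= 0 | tab$pbar >= 1
  }
  tab$expected <- tab$n * tab$pbar
  stat <- sum((tab$observed - tab$expected)^2 /
                (tab$n * tab$pbar * (1 - tab$pbar)))
  if (is.null(df)) df <- max(nrow(tab) - 2, 1)
  p <- pchisq(stat, df, lower.tail = FALSE)
  structure(list(statistic = stat, p_value = p, df = df, groups = tab),
            class = "hl_test")
}

#' @export
print.hl_test <- function(x, ...) {
  cat(sprintf("Hosmer-Lemeshow: C = %.3f, df = %d, p = %.4f\n",
              x$statistic, x$df, x$p_value))
  invisible(x)
}

#' Brier score and scaled Brier score
#'
#' Brier = mean squared error of probabilistic predictions,
#' \eqn{\mathrm{mean}((p - y)^2)}.  The scaled Brier score normalises by the
#' Brier score of the non-informative prevalence predictor,
#' \eqn{1 - \mathrm{Brier}/(\bar p (1 - \bar p))} with \eqn{\bar p} the event
#' prevalence: 1 for perfect predictions, 0 for predicting the prevalence
#' for everyone.
#'
#' @param predictions probabilities in `[0, 1]`.
#' @param outcomes 0/1 outcomes.
#' @return for `scaled_brier()`, the scaled score (<= 1); for `brier_score()`
#'   the raw mean squared error.
#' @examples
#' scaled_brier(c(0.2, 0.8), c(0, 1))
#' @export
scaled_brier <- function(predictions, outcomes) {
  b <- brier_score(predictions, outcomes)
  pbar <- mean(outcomes)
  if (pbar == 0 || pbar == 1) {
    warning("scaled Brier score undefined for a one-class outcome")
    return(NA_real_)
  }
  1 - b / (pbar * (1 - pbar))
}

#' @rdname scaled_brier
#' @export
brier_score <- function(predictions, outcomes) {
  stopifnot(length(predictions) == length(outcomes),
            all(predictions >= 0 & predictions <= 1),
            all(outcomes %in% c(0, 1)))
  mean((predictions - outcomes)^2)
}

#' Nagelkerke pseudo-R2
#'
#' Cox-Snell \eqn{R^2 = 1 - \exp(2(\ell_0 - \ell_m)/n)} rescaled by its
#' attainable maximum \eqn{1 - \exp(2 \ell_0 / n)}, so the result lies in
#' `[0, 1]`.
#'
#' @param ll_model maximised log-likelihood of the fitted model.
#' @param ll_null log-likelihood of the intercept-only model; must not
#'   exceed `ll_model` (a worse-than-null fit signals a bug upstream).
#' @param n number of observations.
#' @return R2 in `[0, 1]`.
#' @export
nagelkerke_r2 <- function(ll_model, ll_null, n) {
  if (ll_model < ll_null - 1e-8)
    stop("ll_model < ll_null: fitted model is worse than the null model")
  cs <- 1 - exp(2 * (ll_null - ll_model) / n)
  cs_max <- 1 - exp(2 * ll_null / n)
  if (cs_max <= 0) return(0)
  min(cs / cs_max, 1)
}

#' Omnibus likelihood-ratio test against the intercept-only model
#'
#' Statistic \eqn{2(\ell_m - \ell_0)} referred to a chi-square distribution
#' with degrees of freedom equal to the number of added parameters (each
#' indicator column of a categorical factor counts one).
#'
#' @param ll_model,ll_null log-likelihoods as in [nagelkerke_r2()].
#' @param df number of model parameters beyond the intercept (>= 1).
#' @return list with `statistic`, `df`, `p_value`.
#' @export
omnibus_test <- function(ll_model, ll_null, df) {
  stopifnot(df >= 1)
  stat <- 2 * (ll_model - ll_null)
  if (stat < -1e-8) stop("negative likelihood-ratio statistic")
  stat <- max(stat, 0)
  list(statistic = stat, df = df,
       p_value = pchisq(stat, df, lower.tail = FALSE))
}

#' Full performance report for a fitted NTCP model
#'
#' Computes the standard performance row for a fitted model on its own
#' development data (apparent performance): AUC with stratified percentile
#' bootstrap CI, Brier and scaled Brier score, Nagelkerke R2, omnibus
#' likelihood-ratio p, and the Hosmer-Lemeshow statistic and p.
#'
#' @param model an [ntcp_fit()] result.
#' @param n_boot bootstrap resamples for the AUC CI.
#' @param seed seed for the bootstrap.
#' @param groups Hosmer-Lemeshow risk groups.
#' @param conf_level AUC CI level.
#' @param label optional method label (e.g. `"lasso-suboptimal"`).
#' @return object of class `ntcp_evaluation` (also a one-row data frame via
#'   [as.data.frame()]): `label`, `n_factors`, `auc`, `auc_lower`,
#'   `auc_upper`, `brier`, `scaled_brier`, `nagelkerke_r2`, `omnibus_p`,
#'   `hl_statistic`, `hl_p`, `n`, `n_events`.
#' @examples
#' coh <- generate_cohort(synthetic_config(n_patients = 400, seed = 9))
#' ep <- derive_endpoint(coh, "12m")
#' fit <- ntcp_fit(ep$data, c("dmean_i", "dmean_c", "smoking"))
#' evaluate_model(fit, n_boot = 200, seed = 1)
#' @export
evaluate_model <- function(model, n_boot = 2000, seed = 1, groups = 10,
                           conf_level = 0.95, label = NULL) {
  stopifnot(inherits(model, "ntcp_fit"))
  p <- model$fitted
  y <- model$y
  ci <- auc_ci_boot(p, y, n_boot = n_boot, seed = seed,
                    conf_level = conf_level)
  hl <- hosmer_lemeshow(p, y, groups = groups)
  om <- omnibus_test(model$loglik, model$loglik_null,
                     df = length(model$coefficients))
  structure(list(label = if (is.null(label)) "ntcp_fit" else label,
                 n_factors = length(model$factor_set),
                 auc = attr(ci, "auc"),
                 auc_lower = unname(ci["lower"]),
                 auc_upper = unname(ci["upper"]),
                 brier = brier_score(p, y),
                 scaled_brier = scaled_brier(p, y),
                 nagelkerke_r2 = nagelkerke_r2(model$loglik,
                                               model$loglik_null, model$n),
                 omnibus_p = om$p_value,
                 hl_statistic = hl$statistic,
                 hl_p = hl$p_value,
                 n = model$n, n_events = model$n_events),
            class = "ntcp_evaluation")
}

#' @export
as.data.frame.ntcp_evaluation <- function(x, ...) {
  data.frame(label = x$label, n_factors = x$n_factors,
             auc = x$auc, auc_lower = x$auc_lower, auc_upper = x$auc_upper,
             brier = x$brier, scaled_brier = x$scaled_brier,
             nagelkerke_r2 = x$nagelkerke_r2, omnibus_p = x$omnibus_p,
             hl_statistic = x$hl_statistic, hl_p = x$hl_p,
             n = x$n, n_events = x$n_events, stringsAsFactors = FALSE)
}

#' @export
print.ntcp_evaluation <- function(x, ...) {
  cat(sprintf("%s (%d factors, n = %d, %d events)\n", x$label, x$n_factors,
              x$n, x$n_events))
  cat(sprintf("  AUC %.2f (%.2f-%.2f)  scaled Brier %.2f  R2(Nagelkerke) %.3f\n",
              x$auc, x$auc_lower, x$auc_upper, x$scaled_brier,
              x$nagelkerke_r2))
  cat(sprintf("  Omnibus p %s  Hosmer-Lemeshow p %.3f\n",
              format.pval(x$omnibus_p, digits = 3), x$hl_p))
  invisible(x)
}
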