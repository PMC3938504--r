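# Model-size selection: the compact-model stopping rule (Hosmer-Lemeshow
# calibration gate followed by an AUC-gain criterion along the LASSO
# ranking) and the bootstrap forward-likelihood comparator.

#' Select a compact ("suboptimal") model along a factor ranking
#'
#' Walks the ranked factors in order, fitting the maximum-likelihood
#' logistic model on each prefix.  The first prefix whose Hosmer-Lemeshow
#' p-value reaches `hl_threshold` is accepted as the starting model; from
#' there, the next ranked factor is added as long as the AUC gain over the
#' currently accepted model is at least `auc_gain_threshold` (relative gain
#' `(AUC_new - AUC_cur)/AUC_cur` by default, absolute gain optionally), and
#' selection stops at the first addition that fails this.  If no prefix ever
#' passes the calibration gate the trace reports "no calibrated model"
#' rather than silently falling back.
#'
#' @param ranking a [rank_factors()] result or character vector of factor
#'   names in rank order.
#' @param data included-patient data frame with an outcome column (see
#'   [derive_endpoint()]).
#' @param coding coding scheme.
#' @param outcome outcome column name.
#' @param hl_threshold Hosmer-Lemeshow p-value gate (default 0.05).
#' @param auc_gain_threshold minimum AUC gain to keep adding factors
#'   (default 0.05, i.e. 5%).
#' @param gain one of `"relative"` (default) or `"absolute"`.
#' @param groups Hosmer-Lemeshow risk groups.
#' @param max_size largest prefix size to examine (default: all ranked
#'   factors).
#' @return object of class `selection_trace`: `steps` (data frame with
#'   `size`, `factor_added`, `hl_p`, `auc`, `accepted`), `chosen` (character
#'   vector of selected factors, or `NULL` if no calibrated model),
#'   `status`, `method_label = "lasso-suboptimal"`.
#' @examples
#' coh <- generate_cohort(synthetic_config(n_patients = 400, seed = 2))
#' ep <- derive_endpoint(coh, "12m")
#' d <- build_design_matrix(ep$data, names(xer_coding()))
#' rk <- rank_factors(compute_path(d, ep$data$outcome, nlambda = 40))
#' select_suboptimal(rk, ep$data)
#' @export
select_suboptimal <- function(ranking, data, coding = xer_coding(),
                              outcome = "outcome", hl_threshold = 0.05,
                              auc_gain_threshold = 0.05,
                              gain = c("relative", "absolute"),
                              groups = 10, max_size = NULL) {
  gain <- match.arg(gain)
  ranked <- if (inherits(ranking, "lasso_ranking")) ranking$factor
    else as.character(ranking)
  stopifnot(length(ranked) >= 1)
  y <- data[[outcome]]
  if (length(unique(y)) < 2) stop("cohort must contain both outcome classes")
  if (is.null(max_size)) max_size <- length(ranked)
  steps <- data.frame(size = integer(0), factor_added = character(0),
                      hl_p = numeric(0), auc = numeric(0),
                      accepted = logical(0), stringsAsFactors = FALSE)
  evaluate_prefix <- function(k) {
    fit <- ntcp_fit(data, ranked[seq_len(k)], coding = coding,
                    outcome = outcome)
    p <- fit$fitted
    hl <- suppressWarnings(hosmer_lemeshow(p, fit$y, groups = groups))
    list(hl_p = hl$p_value, auc = auc_concordance(p, fit$y))
  }
  accepted_size <- NA_integer_
  accepted_auc <- NA_real_
  gate_passed <- FALSE
  for (k in seq_len(max_size)) {
    ev <- evaluate_prefix(k)
    acc <- FALSE
    if (!gate_passed) {
      if (ev$hl_p >= hl_threshold) {
        gate_passed <- TRUE
        accepted_size <- k
        accepted_auc <- ev$auc
        acc <- TRUE
      }
    } else {
      g <- if (gain == "relative") (ev$auc - accepted_auc) / accepted_auc
        else ev$auc - accepted_auc
      if (g >= auc_gain_threshold) {
        accepted_size <- k
        accepted_auc <- ev$auc
        acc <- TRUE
      }
    }
    steps <- rbind(steps, data.frame(size = k, factor_added = ranked[k],
                                     hl_p = ev$hl_p, auc = ev$auc,
                                     accepted = acc,
                                     stringsAsFactors = FALSE))
    if (gate_passed && !acc) break
  }
  status <- if (!gate_passed) "no_calibrated_model" else "ok"
  chosen <- if (gate_passed) ranked[seq_len(accepted_size)] else NULL
  structure(list(steps = steps, chosen = chosen, status = status,
                 hl_threshold = hl_threshold,
                 auc_gain_threshold = auc_gain_threshold, gain = gain,
                 method_label = "lasso-suboptimal"),
            class = "selection_trace")
}

#' @export
print.selection_trace <- function(x, digits = 3, ...) {
  cat("Model-size selection trace [", x$method_label, "]\n", sep = "")
  print(x$steps, digits = digits, row.names = FALSE)
  if (is.null(x$chosen)) {
    cat("status:", x$status, "\n")
  } else {
    cat("chosen (", length(x$chosen), " factors): ",
        paste(x$chosen, collapse = ", "), "\n", sep = "")
  }
  invisible(x)
}

#' Bootstrap forward selection on out-of-sample likelihood
#'
#' The forward-selection comparator: within each bootstrap resample of the
#' cohort, factors are added greedily by training log-likelihood, giving a
#' nested sequence of models of every order; each order's predictions are
#' scored by their mean log-likelihood on the out-of-bag records.  The model
#' order with the highest mean out-of-bag log-likelihood across bootstraps
#' is chosen, and the final factor set consists of the factors most
#' frequently selected at that order.
#'
#' Bootstrap resamples that contain only one outcome class are redrawn (with
#' a retry cap).
#'
#' @param data included-patient data frame with outcome column.
#' @param candidates candidate factor names.
#' @param coding coding scheme.
#' @param outcome outcome column name.
#' @param n_boot number of bootstrap resamples (2000 for a full analysis;
#'   scale down for exploration).
#' @param seed integer seed.
#' @param max_order largest model order examined (default: all candidates).
#' @param retry_cap redraw limit for degenerate resamples.
#' @return object of class `selection_trace`: `steps` (data frame with
#'   `size` and mean out-of-bag log-likelihood `oob_ll`), `chosen`,
#'   `chosen_order`, `inclusion_freq` (per factor, at the chosen order),
#'   `method_label = "forward-LL"`.
#' @export
forward_select_ll <- function(data, candidates, coding = xer_coding(),
                              outcome = "outcome", n_boot = 2000, seed = 1,
                              max_order = NULL, retry_cap = 100) {
  stopifnot(length(candidates) >= 1)
  y <- as.numeric(data[[outcome]])
  design <- build_design_matrix(data, candidates, coding)
  X <- design$X
  n <- length(y)
  if (is.null(max_order)) max_order <- length(candidates)
  max_order <- min(max_order, length(candidates))
  cols_of <- function(fs) which(design$assign %in% fs)
  fit_ll <- function(idx, fs) {
    Xs <- cbind(1, X[idx, cols_of(fs), drop = FALSE])
    f <- tryCatch(
      suppressWarnings(glm.fit(Xs, y[idx], family = binomial(),
                               control = list(maxit = 50))),
      error = function(e) NULL)
    if (is.null(f) || anyNA(f$coefficients)) return(NULL)
    f$coefficients
  }
  oob_ll_matrix <- matrix(NA_real_, n_boot, max_order)
  sel_sets <- vector("list", n_boot)
  with_seed(seed, {
    for (b in seq_len(n_boot)) {
      tries <- 0
      repeat {
        idx <- sample.int(n, replace = TRUE)
        oob <- setdiff(seq_len(n), unique(idx))
        if (length(unique(y[idx])) == 2 && length(oob) > 0 &&
            length(unique(y[oob])) >= 1) break
        tries <- tries + 1
        if (tries > retry_cap)
          stop("could not draw a non-degenerate bootstrap resample")
      }
      current <- character(0)
      remaining <- candidates
      sets_b <- vector("list", max_order)
      for (m in seq_len(max_order)) {
        best_ll <- -Inf; best_f <- NULL; best_coef <- NULL
        for (f in remaining) {
          cf <- fit_ll(idx, c(current, f))
          if (is.null(cf)) next
          eta <- cf[1] + X[idx, cols_of(c(current, f)), drop = FALSE] %*%
            cf[-1]
          ll <- log_binomial(plogis(eta), y[idx])
          if (ll > best_ll) { best_ll <- ll; best_f <- f; best_coef <- cf }
        }
        if (is.null(best_f)) break
        current <- c(current, best_f)
        remaining <- setdiff(remaining, best_f)
        sets_b[[m]] <- current
        eta_oob <- best_coef[1] +
          X[oob, cols_of(current), drop = FALSE] %*% best_coef[-1]
        oob_ll_matrix[b, m] <- log_binomial(plogis(eta_oob), y[oob]) /
          length(oob)
      }
      sel_sets[[b]] <- sets_b
    }
  })
  mean_oob <- colMeans(oob_ll_matrix, na.rm = TRUE)
  chosen_order <- which.max(mean_oob)
  at_order <- lapply(sel_sets, function(s)
    if (length(s) >= chosen_order) s[[chosen_order]] else NULL)
  at_order <- at_order[!vapply(at_order, is.null, TRUE)]
  freq <- sort(table(unlist(at_order)), decreasing = TRUE)
  chosen <- names(freq)[seq_len(min(chosen_order, length(freq)))]
  steps <- data.frame(size = seq_len(max_order), oob_ll = mean_oob)
  structure(list(steps = steps, chosen = chosen,
                 chosen_order = chosen_order,
                 inclusion_freq = freq / length(at_order),
                 n_boot = n_boot, seed = seed, status = "ok",
                 method_label = "forward-LL"),
            class = "selection_trace")
}
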