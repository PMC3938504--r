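# Independent oracles and fixture builders used across the suite.
# Every oracle here is deliberately brute-force / closed-form and shares no
# code with the implementation it checks.

# Log-likelihood of a logistic model evaluated directly.
oracle_loglik <- function(b0, beta, X, y) {
  eta <- b0 + as.matrix(X) %*% beta
  p <- 1 / (1 + exp(-eta))
  p <- pmin(pmax(p, 1e-12), 1 - 1e-12)
  sum(y * log(p) + (1 - y) * log(1 - p))
}

# Brute-force 2-parameter MLE (intercept + one covariate) by iterated grid
# refinement of the log-likelihood surface.
oracle_mle_grid <- function(x, y, lim = 8, steps = 5) {
  c0 <- c(0, 0); half <- lim
  for (s in seq_len(steps)) {
    g0 <- seq(c0[1] - half, c0[1] + half, length.out = 41)
    g1 <- seq(c0[2] - half, c0[2] + half, length.out = 41)
    ll <- outer(g0, g1, Vectorize(function(a, b)
      oracle_loglik(a, b, cbind(x), y)))
    best <- which(ll == max(ll), arr.ind = TRUE)[1, ]
    c0 <- c(g0[best[1]], g1[best[2]])
    half <- half / 10
  }
  c0
}

# Constrained-likelihood profile over a 2-D coefficient grid: maximise the
# log-likelihood subject to |b1| + |b2| <= t (standardised covariates),
# profiling the intercept on a fine grid.
oracle_lasso_2d <- function(X, y, t, ngrid = 81) {
  Xs <- scale(X, scale = apply(X, 2, function(c) sqrt(mean((c - mean(c))^2))))
  g <- seq(-t, t, length.out = ngrid)
  b0g <- seq(-3, 3, length.out = 61)
  best <- list(ll = -Inf)
  for (b1 in g) for (b2 in g) {
    if (abs(b1) + abs(b2) > t + 1e-12) next
    lls <- vapply(b0g, function(b0)
      oracle_loglik(b0, c(b1, b2), Xs, y), 0)
    if (max(lls) > best$ll)
      best <- list(ll = max(lls), b = c(b1, b2))
  }
  best
}

# AUC by explicit enumeration of all event/non-event pairs.
oracle_auc_pairs <- function(pred, y) {
  ev <- pred[y == 1]; nev <- pred[y == 0]
  s <- 0
  for (a in ev) for (b in nev)
    s <- s + (a > b) + 0.5 * (a == b)
  s / (length(ev) * length(nev))
}

# Minimal cohort data frame with every factor at its reference level.
reference_record <- function(n = 1, dmean_c = 30, dmean_i = 35, age = 50) {
  out <- data.frame(id = sprintf("R%03d", seq_len(max(n, 1))),
                    dmean_c = dmean_c, dmean_i = dmean_i, age = age,
                    gender = 0, education = 0, marriage = 0, smoking = 0,
                    alcohol = 0, ajcc_stage = 1, t_stage = 4, node = 0,
                    chemo = 0, baseline_xer = 0, family_history = 0,
                    financial = 0, treatment_mode = 0,
                    baseline_xer_score = 0, stringsAsFactors = FALSE)
  out[seq_len(n), , drop = FALSE]
}

# Cohort transcribing published-style endpoint counts: `n` assessed patients
# of whom `n_base` have baseline grade 3+ xerostomia and `n_event` of the
# rest have a grade 3+ follow-up score.
counts_cohort <- function(n, n_base, n_event, timepoint = "3m") {
  rec <- reference_record(n)
  rec$baseline_xer_score <- c(rep(66, n_base), rep(0, n - n_base))
  col <- paste0("xer_score_", timepoint)
  rec[[col]] <- c(rep(0, n_base), rep(66, n_event),
                  rep(0, n - n_base - n_event))
  rec
}

# Small two-covariate synthetic dataset with one strong and one null effect.
toy_signal_data <- function(n = 60, seed = 99, beta = 2) {
  set.seed(seed)
  x1 <- rnorm(n); x2 <- rnorm(n)
  y <- rbinom(n, 1, plogis(beta * x1))
  list(X = cbind(strong = x1, null = x2), y = y)
}

true_3m_factors <- c("dmean_c", "dmean_i", "age")
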