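# L1-constrained logistic regression: boundary behaviour, budget mapping,
# path continuity, ranking, cross-validation.

toy <- toy_signal_data()

test_that("t = 0 fully constrains: all coefficients zero, intercept = logit rate", {
  f <- fit_lasso(toy$X, toy$y, t = 0)
  expect_true(all(f$coefficients == 0))
  expect_equal(unname(f$intercept), qlogis(mean(toy$y)), tolerance = 1e-6)
  expect_equal(f$t_achieved, 0)
})

test_that("an inactive constraint reproduces the unpenalised MLE", {
  g <- glm(toy$y ~ toy$X, family = binomial())
  f <- fit_lasso(toy$X, toy$y, t = 1e6)
  expect_lt(max(abs(c(f$intercept, f$coefficients) - coef(g))), 1e-4)
})

test_that("every fit satisfies the standardised L1 budget", {
  for (t in c(0.1, 0.5, 1, 2)) {
    f <- fit_lasso(toy$X, toy$y, t = t)
    expect_lte(sum(abs(f$coefficients_std)), t + 1e-8)
    expect_equal(f$t_achieved, sum(abs(f$coefficients_std)))
  }
})

test_that("the strong covariate enters before the null covariate", {
  # oracle: profile of the constrained likelihood over a 2-D grid
  t_small <- 0.3
  f <- fit_lasso(toy$X, toy$y, t = t_small)
  expect_gt(abs(f$coefficients_std["strong"]), 0)
  expect_equal(unname(f$coefficients_std["null"]), 0)
  orc <- oracle_lasso_2d(toy$X, toy$y, t_small)
  expect_equal(unname(f$coefficients_std), orc$b, tolerance = 0.02)
})

test_that("the solved budget matches the requested budget", {
  f <- fit_lasso(toy$X, toy$y, t = 0.4)
  expect_equal(f$t_achieved, 0.4, tolerance = 1e-3)
})

test_that("a length-one grid yields a single-fit path", {
  p <- compute_path(toy$X, toy$y, t_grid = 0.25)
  expect_length(p$t, 1)
  expect_lte(sum(abs(p$beta_std[, 1])), 0.25 + 1e-8)
})

test_that("all-null covariates give identically zero traces", {
  # paired design: each covariate row appears once with y = 0 and once with
  # y = 1, so the MLE (and every constrained fit) is exactly zero
  set.seed(3)
  X <- matrix(rnorm(100 * 3), 100, 3, dimnames = list(NULL, c("a", "b", "c")))
  X2 <- rbind(X, X)
  y <- rep(c(0, 1), each = 100)
  p <- compute_path(X2, y, nlambda = 30)
  expect_lt(max(abs(p$beta_std)), 1e-6)
})

test_that("warm-start path agrees with cold restarts along the grid", {
  coh <- generate_cohort(synthetic_config(n_patients = 400, seed = 17))
  ep <- derive_endpoint(coh, "12m")
  d <- suppressMessages(
    build_design_matrix(ep$data, c("dmean_i", "dmean_c", "smoking", "age")))
  y <- ep$data$outcome
  p <- compute_path(d, y, nlambda = 40)
  for (i in c(5, 20, 35)) {
    cold <- ntcplasso:::lasso_engine(d$X, y, p$lambda[i])
    expect_lt(max(abs(cold$beta_std[, 1] - p$beta_std[, i])), 1e-6)
  }
  # continuity: no jumps between adjacent grid points
  jumps <- apply(abs(diff(t(p$beta_std))), 1, max)
  expect_lt(max(jumps), 0.35)
  # training deviance non-increasing as the budget grows
  dev <- vapply(seq_along(p$t), function(i) {
    eta <- p$intercept[i] + d$X %*% p$beta[, i]
    -2 * sum(y * log(plogis(eta)) + (1 - y) * log(1 - plogis(eta)))
  }, 0)
  expect_true(all(diff(dev) < 1e-6))
  # nonzero count non-decreasing along the grid (up to tolerance)
  expect_true(all(diff(p$df) >= -1))
})

test_that("coefficients agree with an independent penalised solver", {
  skip_if_not_installed("glmnet")
  coh <- generate_cohort(synthetic_config(n_patients = 500, seed = 23))
  ep <- derive_endpoint(coh, "12m")
  d <- suppressMessages(
    build_design_matrix(ep$data, c("dmean_i", "dmean_c", "smoking", "age")))
  y <- ep$data$outcome
  lam <- c(0.1, 0.05, 0.01)
  ours <- ntcplasso:::lasso_engine(d$X, y, lam)
  g <- glmnet::glmnet(d$X, y, family = "binomial", lambda = lam,
                      standardize = TRUE, thresh = 1e-12)
  expect_lt(max(abs(ours$beta - as.matrix(g$beta))), 2e-3)
  expect_lt(max(abs(ours$intercept - as.numeric(g$a0))), 2e-3)
})

test_that("entry order ranks truly predictive factors first", {
  cfg <- synthetic_config(n_patients = 5000, seed = 404, timepoint = "3m")
  ep <- derive_endpoint(generate_cohort(cfg), "3m")
  d <- suppressMessages(
    build_design_matrix(ep$data, names(xer_coding())))
  p <- compute_path(d, ep$data$outcome, nlambda = 60)
  rk <- rank_factors(p)
  expect_equal(nrow(rk), 16)             # one row per candidate factor
  expect_setequal(rk$factor[1:3], true_3m_factors)
  # never-entered factors are ranked last with NA entry budget
  if (anyNA(rk$entry_t))
    expect_true(all(which(is.na(rk$entry_t)) > max(which(!is.na(rk$entry_t)))))
})

test_that("bootstrap-aggregated ranking also recovers the true factors", {
  cfg <- synthetic_config(n_patients = 1500, seed = 808, timepoint = "3m")
  ep <- derive_endpoint(generate_cohort(cfg), "3m")
  d <- suppressMessages(build_design_matrix(ep$data, names(xer_coding())))
  rk <- bootstrap_rank(d, ep$data$outcome, n_boot = 20, seed = 6,
                       nlambda = 30)
  expect_setequal(rk$factor[1:3], true_3m_factors)
  rk2 <- bootstrap_rank(d, ep$data$outcome, n_boot = 20, seed = 6,
                        nlambda = 30)
  expect_identical(rk, rk2)
})

test_that("nested CV is deterministic and needs enough events per fold", {
  coh <- generate_cohort(synthetic_config(n_patients = 400, seed = 55))
  ep <- derive_endpoint(coh, "12m")
  d <- suppressMessages(
    build_design_matrix(ep$data, c("dmean_i", "dmean_c", "smoking")))
  y <- ep$data$outcome
  cv1 <- nested_cv_select(d, y, folds = 5, seed = 2, nlambda = 25)
  cv2 <- nested_cv_select(d, y, folds = 5, seed = 2, nlambda = 25)
  expect_identical(cv1[c("chosen_t", "final_factors", "outer_subsets")],
                   cv2[c("chosen_t", "final_factors", "outer_subsets")])
  expect_true(cv1$chosen_lambda %in% cv1$lambda)
  few <- ep$data[c(which(y == 1)[1:3], which(y == 0)[1:40]), ]
  dfew <- suppressMessages(
    build_design_matrix(few, c("dmean_i", "dmean_c")))
  expect_error(nested_cv_select(dfew, few$outcome, folds = 10),
               "too few")
})

test_that("nested CV keeps the generating factors in the selected subset", {
  hits <- 0; n_seeds <- 20
  for (s in seq_len(n_seeds)) {
    cfg <- synthetic_config(n_patients = 1000, seed = 7000 + s,
                            timepoint = "3m")
    ep <- derive_endpoint(generate_cohort(cfg), "3m")
    d <- suppressMessages(build_design_matrix(ep$data, names(xer_coding())))
    cv <- nested_cv_select(d, ep$data$outcome, seed = s, nlambda = 40)
    if (all(true_3m_factors %in% cv$final_factors)) hits <- hits + 1
  }
  expect_gte(hits, 0.9 * n_seeds)
})
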