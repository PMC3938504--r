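# The logistic NTCP core: linear predictor, probability, ML fitting,
# odds ratios, model object behaviour.

test_that("linear predictor sums intercept and coefficient terms", {
  m3 <- xer_reference_model("3m_suboptimal")
  rec <- reference_record(1, dmean_c = 30.6, dmean_i = 36.3, age = 52)
  # independent term-by-term arithmetic
  s_oracle <- -21.298 + 30.6 * 0.097 + 36.3 * 0.101 + 52 * 0.285
  expect_equal(predict(m3, rec, type = "link"), s_oracle, tolerance = 1e-12)
  expect_equal(predict(m3, rec, type = "response"),
               exp(s_oracle) / (1 + exp(s_oracle)), tolerance = 1e-12)

  # all categorical factors at reference, doses/age zero: only the constant
  m12 <- xer_reference_model("12m_suboptimal")
  rec0 <- reference_record(1, dmean_c = 0, dmean_i = 0, age = 0)
  expect_equal(predict(m12, rec0, type = "link"), -8.028)
})

test_that("ntcp probability is the logistic transform, strictly in (0,1)", {
  m <- ntcp_model(0, c(dmean_c = 1))
  rec <- reference_record(1, dmean_c = 0)
  expect_equal(predict(m, rec), 0.5)   # S = 0
  big <- predict(m, reference_record(1, dmean_c = 30))
  expect_true(big > 1 - 1e-6 && big < 1)
  # monotone approach to 1 (within the representable range of the logistic)
  ps <- predict(m, reference_record(5, dmean_c = c(1, 3, 9, 18, 30)))
  expect_true(all(diff(ps) > 0))
})

test_that("predict errors when a model factor is missing from the record", {
  m <- xer_reference_model("3m_suboptimal")
  rec <- reference_record(1)
  rec$age <- NULL
  expect_error(predict(m, rec), "age")
})

test_that("intercept-only fit returns logit of the event rate", {
  d <- data.frame(outcome = rep(c(0, 1), c(30, 10)))
  fit <- ntcp_fit(d, character(0))
  expect_equal(unname(fit$intercept), qlogis(0.25), tolerance = 1e-8)
  expect_length(fit$coefficients, 0)
})

test_that("ML estimates match a brute-force likelihood grid on small data", {
  set.seed(7)
  for (rep in 1:3) {
    n <- 40
    x <- rbinom(n, 1, 0.5)
    y <- rbinom(n, 1, plogis(-0.5 + 1.5 * x))
    if (length(unique(y)) < 2 || length(unique(y[x == 0])) < 2 ||
        length(unique(y[x == 1])) < 2) next
    d <- data.frame(smoking = x, outcome = y)
    fit <- ntcp_fit(d, "smoking")
    oracle <- oracle_mle_grid(x, y)
    expect_lt(abs(unname(fit$intercept) - oracle[1]), 5e-4)
    expect_lt(abs(unname(fit$coefficients["smoking"]) - oracle[2]), 5e-4)
  }
})

test_that("fitting a generated cohort recovers the generating coefficients", {
  truth <- xer_reference_model("12m_suboptimal")
  coh <- generate_cohort(synthetic_config(n_patients = 5000, seed = 314))
  ep <- derive_endpoint(coh, "12m")
  fit <- ntcp_fit(ep$data, truth$factor_set)
  nm <- names(truth$coefficients)
  est <- fit$coefficients[nm]
  se <- fit$se[nm]
  in_ci <- abs(est - truth$coefficients[nm]) <= 1.96 * se
  within_10 <- abs(est - truth$coefficients[nm]) <=
    0.10 * abs(truth$coefficients[nm])
  expect_true(all(in_ci | within_10))
})

test_that("perfect separation raises a diagnostic error", {
  d <- data.frame(dmean_c = c(10, 40), outcome = c(0, 1))
  expect_error(ntcp_fit(d, "dmean_c"), "separation")
})

test_that("exactly collinear columns are rejected", {
  d <- reference_record(30)
  d$dmean_c <- rnorm(30, 30)
  d$dmean_i <- 2 * d$dmean_c
  d$outcome <- rep(c(0, 1), 15)
  expect_error(ntcp_fit(d, c("dmean_c", "dmean_i")), "collinear")
})

test_that("odds ratios are exp(beta) with 1.96-SE Wald intervals", {
  expect_equal(round(odds_ratio(0.292)$or, 3), 1.339)
  expect_equal(round(odds_ratio(1.034)$or, 3), 2.812)
  o <- odds_ratio(0, 0.5)
  expect_equal(o$or, 1)
  expect_equal(log(o$lower), -log(o$upper))  # symmetric on the log scale
  o2 <- odds_ratio(0.292, 0.024)
  expect_equal(o2$lower, exp(0.292 - 1.96 * 0.024), tolerance = 1e-6)
  expect_error(odds_ratio(1, -0.1))
})

test_that("NTCP increases in any factor with positive coefficient", {
  m <- xer_reference_model("3m_suboptimal")  # all three coefficients > 0
  base <- reference_record(1)
  for (f in c("dmean_c", "dmean_i", "age")) {
    lo <- base; hi <- base
    hi[[f]] <- hi[[f]] + 5
    expect_true(predict(m, hi) > predict(m, lo), label = f)
  }
})

test_that("model JSON serialisation round-trips and stores the S formula", {
  coh <- generate_cohort(synthetic_config(n_patients = 400, seed = 21))
  ep <- derive_endpoint(coh, "12m")
  fit <- ntcp_fit(ep$data, c("dmean_i", "smoking", "t_stage"))
  path <- withr::local_tempfile(fileext = ".json")
  write_ntcp_model(fit, path)
  back <- read_ntcp_model(path)
  expect_equal(back$intercept, fit$intercept)
  expect_equal(back$coefficients, fit$coefficients)
  expect_equal(back$factor_set, fit$factor_set)
  expect_match(jsonlite::fromJSON(path)$formula, "^S = ")
  rec <- ep$data[3, ]
  expect_equal(predict(back, rec), unname(predict(fit, rec)))
})

test_that("simulate draws Bernoulli outcomes reproducibly", {
  m <- xer_reference_model("3m_suboptimal")
  rec <- reference_record(200, dmean_c = 30.6, dmean_i = 36.3, age = 52)
  s1 <- simulate(m, nsim = 2, seed = 5, newdata = rec)
  s2 <- simulate(m, nsim = 2, seed = 5, newdata = rec)
  expect_identical(s1, s2)
  expect_true(all(unlist(s1) %in% 0:1))
  # event rate near the common probability
  p <- predict(m, rec[1, ])
  expect_lt(abs(mean(s1$sim_1) - p), 3 * sqrt(p * (1 - p) / 200))
})

test_that("residuals and summary expose the usual fitted-model surface", {
  coh <- generate_cohort(synthetic_config(n_patients = 500, seed = 33))
  ep <- derive_endpoint(coh, "12m")
  fit <- ntcp_fit(ep$data, c("dmean_i", "dmean_c"))
  r <- residuals(fit)
  expect_equal(length(r), fit$n)
  expect_equal(sum(residuals(fit, "response")), 0, tolerance = 1e-6)
  s <- summary(fit)
  expect_equal(rownames(s$coefficients),
               c("(Intercept)", "dmean_i", "dmean_c"))
  expect_equal(s$odds_ratios$or, unname(exp(fit$coefficients)))
  expect_output(print(s), "Odds ratios")
})
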