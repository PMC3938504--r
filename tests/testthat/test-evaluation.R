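# Performance metrics: discrimination, calibration, accuracy, explained
# variation.

test_that("AUC handles perfect, random and tied predictions", {
  expect_equal(auc_concordance(c(0.9, 0.8, 0.2, 0.1), c(1, 1, 0, 0)), 1)
  expect_equal(auc_concordance(rep(0.4, 10), rep(c(0, 1), 5)), 0.5)
  # derived by enumerating all four event/non-event pairs: 3 concordant
  expect_equal(auc_concordance(c(0.1, 0.4, 0.35, 0.8), c(0, 0, 1, 1)), 0.75)
  expect_error(auc_concordance(c(0.1, 0.2), c(1, 1)), "both outcome classes")
})

test_that("AUC equals brute-force pair enumeration", {
  set.seed(11)
  for (rep in 1:5) {
    n <- sample(20:200, 1)
    pred <- round(runif(n), 2)       # rounding forces ties
    y <- rbinom(n, 1, 0.4)
    if (length(unique(y)) < 2) next
    expect_equal(auc_concordance(pred, y), oracle_auc_pairs(pred, y))
  }
})

test_that("AUC is invariant under strictly monotone transforms", {
  set.seed(12)
  pred <- runif(80)
  y <- rbinom(80, 1, pred)
  a <- auc_concordance(pred, y)
  expect_equal(auc_concordance(qlogis(pred), y), a)
  expect_equal(auc_concordance(pred^3, y), a)
  expect_equal(auc_concordance(rank(pred), y), a)
})

test_that("AUC agrees with an independent implementation", {
  skip_if_not_installed("pROC")
  set.seed(13)
  pred <- runif(150)
  y <- rbinom(150, 1, pred)
  expect_equal(auc_concordance(pred, y),
               as.numeric(pROC::auc(pROC::roc(y, pred, quiet = TRUE))))
})

test_that("bootstrap AUC CI is deterministic, tight at large n, sane at 1", {
  set.seed(14)
  n <- 10000
  x <- rnorm(n)
  y <- rbinom(n, 1, plogis(3 * x))   # well separated
  p <- plogis(3 * x)
  ci1 <- auc_ci_boot(p, y, n_boot = 200, seed = 5)
  ci2 <- auc_ci_boot(p, y, n_boot = 200, seed = 5)
  expect_identical(ci1, ci2)
  expect_lt(ci1["upper"] - ci1["lower"], 0.05)
  expect_true(ci1["lower"] <= attr(ci1, "auc") &&
                attr(ci1, "auc") <= ci1["upper"])
  # degenerate perfect separation: upper bound is 1
  ci3 <- auc_ci_boot(c(0.1, 0.2, 0.8, 0.9), c(0, 0, 1, 1), n_boot = 100,
                     seed = 1)
  expect_equal(unname(ci3["upper"]), 1)
})

test_that("Hosmer-Lemeshow matches the two-group hand computation", {
  pred <- c(0.2, 0.2, 0.2, 0.2, 0.8, 0.8, 0.8, 0.8)
  y <- c(0, 0, 1, 1, 0, 1, 1, 1)
  hl <- hosmer_lemeshow(pred, y, groups = 2)
  # by hand: group1 O=2,E=0.8,n=4,pbar=0.2; group2 O=3,E=3.2,n=4,pbar=0.8
  stat <- (2 - 0.8)^2 / (4 * 0.2 * 0.8) + (3 - 3.2)^2 / (4 * 0.8 * 0.2)
  expect_equal(hl$statistic, stat)
  expect_equal(hl$df, 1)  # effective groups 2, floor of df at 1
  expect_equal(hl$p_value, pchisq(stat, 1, lower.tail = FALSE))
})

test_that("constant predictions collapse to one risk stratum", {
  y <- rep(c(0, 1), c(14, 6))
  pred <- rep(0.25, 20)
  hl <- hosmer_lemeshow(pred, y, groups = 10)
  expect_equal(hl$statistic, (6 - 20 * 0.25)^2 / (20 * 0.25 * 0.75))
})

test_that("HL p-values are near-uniform for a correctly specified model", {
  # 200 replicates of fitting the true model family; rejection at 5% should
  # occur for about 5% of replicates
  n <- 500
  rejections <- 0
  reps <- 200
  set.seed(2718)
  for (r in seq_len(reps)) {
    x <- rnorm(n)
    y <- rbinom(n, 1, plogis(-0.4 + 0.9 * x))
    d <- data.frame(dmean_c = x + 31, outcome = y)  # keep doses positive
    fit <- ntcp_fit(d, "dmean_c")
    hl <- hosmer_lemeshow(fit$fitted, y)
    if (hl$p_value < 0.05) rejections <- rejections + 1
  }
  expect_lt(abs(rejections / reps - 0.05), 0.04 + 1e-9)
})

test_that("scaled Brier score: perfect 1, prevalence predictor exactly 0", {
  expect_equal(scaled_brier(c(0, 0, 1, 1), c(0, 0, 1, 1)), 1)
  # hand-computed two-term case: Brier = 0.04, reference = 0.25
  expect_equal(scaled_brier(c(0.2, 0.8), c(0, 1)), 1 - 0.04 / 0.25)
  # the prevalence predictor scores exactly 0 on any dataset
  set.seed(15)
  for (rep in 1:5) {
    y <- rbinom(50, 1, runif(1, 0.2, 0.8))
    if (length(unique(y)) < 2) next
    expect_equal(scaled_brier(rep(mean(y), 50), y), 0)
  }
  expect_warning(out <- scaled_brier(c(0.1, 0.2), c(0, 0)), "one-class")
  expect_true(is.na(out))
})

test_that("Nagelkerke R2 normalises Cox-Snell onto [0, 1]", {
  expect_equal(nagelkerke_r2(-40, -40, 100), 0)
  # saturated fit: ll_model -> 0 gives the attainable maximum, R2 = 1
  expect_equal(nagelkerke_r2(0, -60, 100), 1)
  expect_error(nagelkerke_r2(-50, -40, 100), "worse than the null")
  # independent likelihood computation on a small fit
  coh <- generate_cohort(synthetic_config(n_patients = 300, seed = 19))
  ep <- derive_endpoint(coh, "12m")
  fit <- ntcp_fit(ep$data, c("dmean_i", "smoking"))
  d <- suppressMessages(build_design_matrix(ep$data, c("dmean_i", "smoking")))
  ll_direct <- oracle_loglik(fit$intercept, fit$coefficients, d$X,
                             ep$data$outcome)
  pbar <- mean(ep$data$outcome)
  ll0_direct <- sum(dbinom(ep$data$outcome, 1, pbar, log = TRUE))
  expect_equal(nagelkerke_r2(fit$loglik, fit$loglik_null, fit$n),
               nagelkerke_r2(ll_direct, ll0_direct, fit$n), tolerance = 1e-6)
})

test_that("omnibus test is a likelihood-ratio chi-square on added df", {
  expect_equal(omnibus_test(-40, -40, 3)$p_value, 1)
  out <- omnibus_test(-30, -40, 2)
  expect_equal(out$statistic, 20)
  expect_equal(out$p_value, pchisq(20, 2, lower.tail = FALSE))
  expect_error(omnibus_test(-41, -40, 1), "negative")
  # strong signal at n = 1000: p far below 0.001
  coh <- generate_cohort(synthetic_config(n_patients = 1000, seed = 20))
  ep <- derive_endpoint(coh, "12m")
  fit <- ntcp_fit(ep$data, c("dmean_i", "education"))
  df_added <- length(fit$coefficients)   # dummies each count one df
  expect_equal(df_added, 1 + sum(grepl("^education:", names(fit$coefficients))))
  expect_lt(omnibus_test(fit$loglik, fit$loglik_null, df_added)$p_value,
            1e-3)
})

test_that("evaluate_model assembles a consistent report", {
  coh <- generate_cohort(synthetic_config(n_patients = 600, seed = 29))
  ep <- derive_endpoint(coh, "12m")
  fit <- ntcp_fit(ep$data, c("dmean_i", "dmean_c", "smoking"))
  ev <- evaluate_model(fit, n_boot = 150, seed = 4, label = "demo")
  expect_s3_class(ev, "ntcp_evaluation")
  expect_true(ev$auc_lower <= ev$auc && ev$auc <= ev$auc_upper)
  expect_lte(ev$scaled_brier, 1)
  expect_true(ev$nagelkerke_r2 >= 0 && ev$nagelkerke_r2 <= 1)
  expect_equal(ev$auc, auc_concordance(fit$fitted, fit$y))
  df <- as.data.frame(ev)
  expect_equal(df$n_factors, 3)
  expect_equal(df$n, fit$n)
})
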