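#' Default factor marginals for synthetic xerostomia cohorts
#'
#' Per-factor marginal distributions emulating the covariate structure of an
#' IMRT head-and-neck cohort at the chosen follow-up time point.  Continuous
#' factors (mean parotid doses in Gy, age in years) are specified by their
#' observed range and median and are sampled from a scaled Beta distribution
#' on `[min, max]` whose mode sits at the median; categorical factors carry
#' observed level frequencies.
#'
#' @param timepoint `"3m"` or `"12m"`; the two time points have slightly
#'   different category frequencies (the 12-month cohort is smaller).
#' @return named list of marginal specs (class `xer_marginals`): continuous
#'   entries have `min`, `max`, `median`; categorical entries have `levels`
#'   and `freq` (frequencies summing to 1).
#' @examples
#' xer_marginals("3m")$dmean_c
#' @export
xer_marginals <- function(timepoint = c("12m", "3m")) {
  timepoint <- match.arg(timepoint)
  cont <- function(min, max, median) list(min = min, max = max,
                                          median = median)
  cat_ <- function(levels, counts)
    list(levels = as.character(levels), freq = counts / sum(counts))
  m <- if (timepoint == "3m") list(
    dmean_c = cont(4.9, 68.3, 30.6),
    dmean_i = cont(12.2, 70, 36.3),
    age = cont(26, 89, 51.7),
    gender = cat_(0:1, c(25, 160)),
    education = cat_(0:3, c(11, 32, 110, 32)),
    marriage = cat_(0:1, c(32, 153)),
    smoking = cat_(0:1, c(60, 125)),
    alcohol = cat_(0:1, c(73, 112)),
    ajcc_stage = cat_(1:4, c(22, 18, 38, 107)),
    t_stage = cat_(1:4, c(41, 64, 15, 65)),
    node = cat_(0:1, c(19, 166)),
    chemo = cat_(0:1, c(33, 152)),
    baseline_xer = cat_(0:1, c(75, 110)),
    family_history = cat_(0:1, c(134, 51)),
    financial = cat_(0:3, c(63, 94, 21, 7)),
    treatment_mode = cat_(0:1, c(88, 93))
  ) else list(
    dmean_c = cont(4.9, 68.3, 31.4),
    dmean_i = cont(12.2, 70, 36.6),
    age = cont(26, 89, 50.4),
    gender = cat_(0:1, c(17, 100)),
    education = cat_(0:3, c(5, 12, 74, 26)),
    marriage = cat_(0:1, c(20, 97)),
    smoking = cat_(0:1, c(45, 72)),
    alcohol = cat_(0:1, c(51, 66)),
    ajcc_stage = cat_(1:4, c(9, 16, 27, 65)),
    t_stage = cat_(1:4, c(31, 37, 9, 40)),
    node = cat_(0:1, c(12, 105)),
    chemo = cat_(0:1, c(20, 97)),
    baseline_xer = cat_(0:1, c(54, 63)),
    family_history = cat_(0:1, c(83, 34)),
    financial = cat_(0:3, c(40, 56, 17, 4)),
    treatment_mode = cat_(0:1, c(66, 48))
  )
  structure(m, class = "xer_marginals", timepoint = timepoint)
}

#' Configuration for the synthetic-cohort generator
#'
#' Bundles everything [generate_cohort()] needs: cohort size, seed, per-factor
#' marginals, the true (generating) NTCP model, the fraction of patients with
#' grade 3+ xerostomia already at baseline, and the follow-up time point the
#' simulated Likert score is attached to.
#'
#' Defaults emulate the 12-month study conditions: marginals from
#' [xer_marginals("12m")][xer_marginals()], true model
#' [`xer_reference_model("12m_suboptimal")`][xer_reference_model()], and a
#' baseline grade 3+ prevalence of 8.6% (the 3-month figure is 10.2%).
#'
#' @param n_patients non-negative integer.
#' @param seed integer master seed; sub-streams for factor sampling, outcome
#'   draws and baseline injection are derived from it deterministically.
#' @param timepoint `"3m"` or `"12m"` (which Likert column receives scores).
#' @param factor_marginals see [xer_marginals()].
#' @param true_model `ntcp_model` used to generate outcomes.
#' @param baseline_grade3_prevalence fraction in `[0, 1]` of records given a
#'   baseline xerostomia score of 66 (these are later excluded by
#'   [derive_endpoint()]).
#' @param beta_concentration concentration of the scaled Beta used for the
#'   continuous factors (larger = tighter around the median); default 6.
#' @return list of class `synthetic_config`.
#' @export
synthetic_config <- function(n_patients, seed,
                             timepoint = c("12m", "3m"),
                             factor_marginals = NULL,
                             true_model = NULL,
                             baseline_grade3_prevalence = NULL,
                             beta_concentration = 6) {
  timepoint <- match.arg(timepoint)
  stopifnot(length(n_patients) == 1, n_patients >= 0,
            n_patients == round(n_patients))
  if (is.null(factor_marginals)) factor_marginals <- xer_marginals(timepoint)
  if (is.null(true_model))
    true_model <- xer_reference_model(paste0(timepoint, "_suboptimal"))
  if (is.null(baseline_grade3_prevalence))
    baseline_grade3_prevalence <- if (timepoint == "3m") 0.102 else 0.086
  stopifnot(baseline_grade3_prevalence >= 0, baseline_grade3_prevalence <= 1)
  for (nm in names(factor_marginals)) {
    sp <- factor_marginals[[nm]]
    if (!is.null(sp$freq) && abs(sum(sp$freq) - 1) > 1e-9)
      stop("category frequencies of ", nm, " do not sum to 1")
  }
  unknown <- setdiff(true_model$factor_set, names(factor_marginals))
  if (length(unknown))
    stop("true model uses factor(s) absent from factor_marginals: ",
         paste(unknown, collapse = ", "))
  structure(list(n_patients = as.integer(n_patients), seed = as.integer(seed),
                 timepoint = timepoint, factor_marginals = factor_marginals,
                 true_model = true_model,
                 baseline_grade3_prevalence = baseline_grade3_prevalence,
                 beta_concentration = beta_concentration),
            class = "synthetic_config")
}

# Scaled Beta draw on [min, max] with mode at the observed median.
draw_continuous <- function(n, spec, concentration) {
  m <- (spec$median - spec$min) / (spec$max - spec$min)
  a <- 1 + concentration * m
  b <- 1 + concentration * (1 - m)
  spec$min + (spec$max - spec$min) * rbeta(n, a, b)
}

#' Generate a synthetic patient cohort
#'
#' Draws the 16 candidate prognostic factors independently from the
#' configured marginals, computes each patient's true NTCP under the
#' generating model, draws the binary grade 3+ xerostomia outcome as
#' Bernoulli(true NTCP), maps it onto the four-point Likert scale (events
#' get 66 or 100, non-events 0 or 33), and finally injects baseline grade 3+
#' xerostomia at the configured prevalence.
#'
#' Reproducible: the same configuration (including seed) yields an identical
#' cohort.
#'
#' @param config a [synthetic_config()].
#' @return list of class `ntcp_cohort` with elements `records` (data frame in
#'   the cohort schema of [read_cohort()], plus a `baseline_xer` binary
#'   column), `true_probabilities`, `outcome_true` (the generating Bernoulli
#'   draws) and `config`.
#' @examples
#' coh <- generate_cohort(synthetic_config(n_patients = 100, seed = 42))
#' mean(coh$true_probabilities)
#' @export
generate_cohort <- function(config) {
  stopifnot(inherits(config, "synthetic_config"))
  n <- config$n_patients
  marg <- config$factor_marginals
  score_col <- paste0("xer_score_", config$timepoint)
  other_col <- paste0("xer_score_", setdiff(c("3m", "12m"), config$timepoint))
  if (n == 0) {
    rec <- data.frame(id = character(0))
    for (nm in names(marg)) rec[[nm]] <- numeric(0)
    rec$baseline_xer_score <- numeric(0)
    rec[[score_col]] <- numeric(0)
    rec[[other_col]] <- numeric(0)
    return(structure(list(records = rec, true_probabilities = numeric(0),
                          outcome_true = integer(0), config = config),
                     class = "ntcp_cohort"))
  }
  rec <- with_seed(substream(config$seed, 1), {
    out <- data.frame(id = sprintf("P%05d", seq_len(n)),
                      stringsAsFactors = FALSE)
    for (nm in names(marg)) {
      sp <- marg[[nm]]
      out[[nm]] <- if (!is.null(sp$freq))
        as.integer(sample(sp$levels, n, replace = TRUE, prob = sp$freq))
      else draw_continuous(n, sp, config$beta_concentration)
    }
    out
  })
  # baseline Likert score from the binary baseline-xerostomia factor
  # (0 = none, 1 = "a little" = 33); grade 3+ baselines are injected below
  rec$baseline_xer_score <- ifelse(rec$baseline_xer == 1, 33, 0)
  p_true <- predict(config$true_model, rec, type = "response")
  y <- with_seed(substream(config$seed, 2), rbinom(n, 1, p_true))
  rec[[score_col]] <- with_seed(substream(config$seed, 3),
    ifelse(y == 1, sample(c(66, 100), n, replace = TRUE),
           sample(c(0, 33), n, replace = TRUE)))
  rec[[other_col]] <- NA_real_
  cohort <- structure(list(records = rec, true_probabilities = p_true,
                           outcome_true = y, config = config),
                      class = "ntcp_cohort")
  inject_baseline_grade3(cohort, config$baseline_grade3_prevalence,
                         seed = substream(config$seed, 4))
}

#' @export
print.ntcp_cohort <- function(x, ...) {
  cat(sprintf("Synthetic NTCP cohort: %d patients, time point %s\n",
              nrow(x$records), x$config$timepoint))
  if (nrow(x$records))
    cat(sprintf("  mean true NTCP %.3f, empirical event rate %.3f\n",
                mean(x$true_probabilities), mean(x$outcome_true)))
  invisible(x)
}

#' Inject baseline grade 3+ xerostomia into a cohort
#'
#' Sets the baseline xerostomia score of exactly `round(prevalence * n)`
#' randomly chosen records to 66 (moderate) and caps every other record's
#' baseline score at 33, so the cohort's baseline grade 3+ prevalence is
#' exactly the requested one.  These records are subsequently excluded by
#' [derive_endpoint()], mirroring how patients already symptomatic before
#' radiotherapy are removed from the analysis population.
#'
#' @param cohort an `ntcp_cohort`.
#' @param prevalence fraction in `[0, 1]`.
#' @param seed integer seed for the record draw.
#' @return the modified `ntcp_cohort`.
#' @examples
#' coh <- generate_cohort(synthetic_config(n_patients = 206, seed = 1,
#'   baseline_grade3_prevalence = 0))
#' coh <- inject_baseline_grade3(coh, 21 / 206, seed = 2)
#' sum(coh$records$baseline_xer_score >= 66)
#' @export
inject_baseline_grade3 <- function(cohort, prevalence, seed) {
  stopifnot(inherits(cohort, "ntcp_cohort"),
            prevalence >= 0, prevalence <= 1)
  n <- nrow(cohort$records)
  k <- round(prevalence * n)
  cohort$records$baseline_xer_score <-
    pmin(cohort$records$baseline_xer_score, 33)
  if (k > 0) {
    idx <- with_seed(seed, sample.int(n, k))
    cohort$records$baseline_xer_score[idx] <- 66
    cohort$records$baseline_xer[idx] <- 1L
  }
  cohort
}
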