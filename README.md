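# ntcplasso

Multivariate logistic NTCP (normal tissue complication probability) models
for patient-rated xerostomia after intensity-modulated radiotherapy (IMRT)
for head-and-neck cancer, with LASSO-based prognostic-factor ranking and
selection.

Irradiating the parotid glands suppresses salivary flow; the resulting dry
mouth (xerostomia) is the study endpoint, assessed by the patient on a
four-point quality-of-life Likert item (0/33/66/100) before treatment and
at 3 and 12 months after.  The package is for radiation-oncology and
biostatistics users who want to build, select, and evaluate NTCP models of
the form

    NTCP = exp(S) / (1 + exp(S)),   S = b0 + sum_i b_i * x_i

over 16 candidate prognostic factors: mean dose to the contralateral and
ipsilateral parotid glands (Gy), age, and 13 coded clinical factors.  It
provides:

* **Endpoint derivation** (`derive_endpoint()`): grade 3+ xerostomia =
  Likert score 66 or 100 at follow-up, with patients already grade 3+ at
  baseline excluded.
* **Model fitting** (`ntcp_fit()`): reference-coded design matrices,
  maximum-likelihood logistic fits with Wald tests and odds-ratio tables,
  and the usual methods (`summary`, `predict`, `plot`, `simulate`,
  `residuals`), plus JSON model serialisation.
* **Factor ranking** (`compute_path()`, `rank_factors()`): an
  L1-constrained (LASSO) shrinkage path computed by coordinate descent;
  factors are ranked by the budget at which they first enter.  Budget
  selection by nested stratified 10-fold CV (`nested_cv_select()`).
* **Model-size selection** (`select_suboptimal()`): a Hosmer-Lemeshow
  calibration gate (p >= 0.05) followed by a <5% AUC-gain stopping rule;
  and a bootstrap forward-selection comparator scored by out-of-bag
  likelihood (`forward_select_ll()`).
* **Evaluation** (`evaluate_model()`): AUC (Mann-Whitney) with stratified
  bootstrap CI, Brier and scaled Brier score, Nagelkerke R2, omnibus
  likelihood-ratio test, Hosmer-Lemeshow test.
* **Synthetic cohorts** (`generate_cohort()`): cohorts emulating the
  covariate structure of an IMRT head-and-neck cohort, with outcomes drawn
  from a known generating NTCP model — the basis of all validation.
* **Pipeline** (`run_pipeline()`): all of the above end to end from one
  config, writing CSV/JSON artifacts.

## Worked example

```r
library(ntcplasso)

coh <- generate_cohort(synthetic_config(n_patients = 1000, seed = 42))
ep  <- derive_endpoint(coh, "12m")
ep
#> Grade 3+ xerostomia endpoint at 12m
#>   assessed:            1000
#>   excluded (baseline): 86
#>   included:            914
#>   events:              293 (29.3% of assessed)
```

Of 1000 simulated patients, 86 were excluded for baseline grade 3+
xerostomia; 293 of the remaining 914 developed moderate-to-severe
xerostomia at 12 months.  Fit the compact reference factor set and
evaluate:

```r
fit <- ntcp_fit(ep$data, c("dmean_i", "education", "dmean_c",
                           "smoking", "t_stage"))
fit
#> Logistic NTCP model
#>   NTCP = exp(S)/(1 + exp(S)),  S = -7.9041 + (dmean_i*0.1352)
#>     + (education:1*-3.8705) + (education:2*-1.0294) + (education:3*-1.1225)
#>     + (dmean_c*0.0727) + (smoking*1.2108) + (t_stage:1*-0.4212)
#>     + (t_stage:2*-0.5793) + (t_stage:3*-0.7653)
#>   n = 914 (293 events), logLik = -392.798

evaluate_model(fit, n_boot = 200, seed = 1)
#> ntcp_fit (5 factors, n = 914, 293 events)
#>   AUC 0.86 (0.83-0.88)  scaled Brier 0.35  R2(Nagelkerke) 0.457
#>   Omnibus p <2e-16  Hosmer-Lemeshow p 0.320
```

The fitted coefficients sit close to the generating model (ipsilateral
dose 0.135 vs 0.155 per Gy, smoking 1.21 vs 1.14); AUC 0.86 says a random
event outranks a random non-event 86% of the time, scaled Brier 0.35 means
mean squared prediction error is 35% below the prevalence-only predictor,
and the Hosmer-Lemeshow p of 0.32 shows no evidence of miscalibration.

Rank all 16 candidates and select a compact model:

```r
d    <- build_design_matrix(ep$data, names(xer_coding()))
rk   <- rank_factors(compute_path(d, ep$data$outcome))
head(rk, 4)
#>   rank    factor   entry_t max_abs_std
#> 1    1   dmean_i 0.1036524   1.3497332
#> 2    2   dmean_c 0.5292571   0.7766114
#> 3    3 education 0.6424845   1.1781156
#> 4    4   smoking 0.8080586   0.5918242

select_suboptimal(rk, ep$data)
#> Model-size selection trace [lasso-suboptimal]
#>  size factor_added  hl_p   auc accepted
#>     1      dmean_i 0.460 0.768     TRUE
#>     2      dmean_c 0.494 0.801    FALSE
#> chosen (1 factors): dmean_i
```

The ipsilateral dose model already passes the calibration gate, and adding
the contralateral dose raises the AUC by only 4.3% relative — below the 5%
rule — so the stopping rule settles on one factor for this cohort; the
trace records every examined size.

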