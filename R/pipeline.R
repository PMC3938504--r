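# Cohort file I/O and the end-to-end analysis pipeline.

cohort_columns <- c("id", "dmean_c_gy", "dmean_i_gy", "age", "gender",
                    "education", "marriage", "smoking", "alcohol",
                    "ajcc_stage", "t_stage", "node", "chemo",
                    "baseline_xer_score", "family_history", "financial",
                    "treatment_mode", "xer_score_3m", "xer_score_12m")

# internal (analysis) names <-> file header
file_to_internal <- c(dmean_c_gy = "dmean_c", dmean_i_gy = "dmean_i")

level_sets <- function() {
  cod <- xer_coding()
  out <- lapply(cod, function(s) s$levels)
  out[!vapply(out, is.null, TRUE)]
}

#' Read a patient cohort from CSV
#'
#' Reads the cohort file format: one row per patient, comma-separated,
#' UTF-8, `"."` decimal, with the exact header
#' `id, dmean_c_gy, dmean_i_gy, age, gender, education, marriage, smoking,
#' alcohol, ajcc_stage, t_stage, node, chemo, baseline_xer_score,
#' family_history, financial, treatment_mode, xer_score_3m, xer_score_12m`.
#' Likert score columns must contain 0/33/66/100 or be empty (missing
#' follow-up).  Categorical codes are validated against the declared level
#' sets and all row-level problems are reported together.
#'
#' @param path CSV file.
#' @return data frame in the internal analysis schema (doses as `dmean_c`,
#'   `dmean_i`, in Gy).
#' @seealso [write_cohort()]
#' @export
read_cohort <- function(path) {
  if (!file.exists(path)) stop("cohort file not found: ", path)
  df <- read.csv(path, stringsAsFactors = FALSE,
                 colClasses = c(id = "character"))
  if (!identical(names(df), cohort_columns))
    stop("cohort header mismatch; expected exactly: ",
         paste(cohort_columns, collapse = ", "))
  names(df)[match(names(file_to_internal), names(df))] <- file_to_internal
  if (nrow(df) == 0) return(df)
  problems <- character(0)
  note <- function(rows, col, what)
    problems <<- c(problems, sprintf("column %s, row(s) %s: %s", col,
                                     paste(head(rows, 5), collapse = ","),
                                     what))
  for (col in c("dmean_c", "dmean_i", "age")) {
    bad <- which(!is.finite(df[[col]]) | df[[col]] <= 0)
    if (length(bad)) note(bad, col, "must be a positive number")
  }
  lv <- level_sets()
  for (col in names(lv)) {
    if (col %in% c("baseline_xer")) next
    if (!col %in% names(df)) next
    bad <- which(!as.character(df[[col]]) %in% lv[[col]])
    if (length(bad))
      note(bad, col, paste0("level outside {",
                            paste(lv[[col]], collapse = ","), "}"))
  }
  for (col in c("baseline_xer_score", "xer_score_3m", "xer_score_12m")) {
    v <- df[[col]]
    bad <- which(!is.na(v) & !v %in% c(0, 33, 66, 100))
    if (length(bad)) note(bad, col, "Likert score must be 0/33/66/100")
  }
  bad <- which(is.na(df$baseline_xer_score))
  if (length(bad)) note(bad, "baseline_xer_score", "baseline score required")
  if (length(problems))
    stop("invalid cohort file:\n  ", paste(problems, collapse = "\n  "))
  df$baseline_xer <- as.integer(df$baseline_xer_score >= 33)
  df
}

#' Write a patient cohort to CSV
#'
#' Inverse of [read_cohort()]: writes the exact cohort header with doses
#' renamed back to `dmean_c_gy` / `dmean_i_gy`.  Missing follow-up scores
#' are written as empty fields.
#'
#' @param records data frame in the internal schema, or an `ntcp_cohort`.
#' @param path destination CSV file.
#' @return invisibly `path`.
#' @export
write_cohort <- function(records, path) {
  if (inherits(records, "ntcp_cohort")) records <- records$records
  out <- records
  for (fcol in names(file_to_internal)) {
    icol <- file_to_internal[[fcol]]
    names(out)[names(out) == icol] <- fcol
  }
  miss <- setdiff(cohort_columns, names(out))
  for (col in miss) out[[col]] <- rep(NA, nrow(out))
  out <- out[, cohort_columns, drop = FALSE]
  write.csv(out, path, row.names = FALSE, quote = FALSE, na = "")
  invisible(path)
}

#' Run the full NTCP analysis pipeline
#'
#' Orchestrates every stage end to end on one cohort and time point:
#' endpoint derivation, shrinkage-path computation and factor ranking,
#' nested-CV (optimal) and calibration-gated (suboptimal) model-size
#' selection, the bootstrap forward-likelihood comparator, maximum-
#' likelihood fits of the selected models with odds-ratio tables, and a
#' performance report row per model.  All artifacts are written to
#' `out_dir` as CSV/JSON; every seed and threshold used is logged.
#'
#' @param config named list (or path to a JSON/YAML file holding one) with
#'   elements: `input` (cohort CSV path) *or* `synthetic` (arguments for
#'   [synthetic_config()]); `timepoint` (`"3m"`/`"12m"`); `out_dir`;
#'   optional `seed` (default 1), `hl_threshold` (0.05),
#'   `auc_gain_threshold` (0.05), `nlambda` (100), `cv_folds` (10),
#'   `n_boot_forward` (2000), `n_boot_auc` (2000), `run_forward` (TRUE).
#' @param quiet suppress progress logging.
#' @return invisibly, a list with the endpoint, ranking, traces, fitted
#'   models and evaluation table.
#' @export
run_pipeline <- function(config, quiet = FALSE) {
  if (is.character(config) && length(config) == 1) {
    config <- if (grepl("\\.ya?ml$", config)) {
      if (!requireNamespace("yaml", quietly = TRUE))
        stop("yaml package required to read YAML configs")
      yaml::read_yaml(config)
    } else jsonlite::fromJSON(config)
  }
  stopifnot(is.list(config))
  say <- function(...) if (!quiet) message("[ntcplasso] ", sprintf(...))
  getd <- function(nm, default) if (is.null(config[[nm]])) default
    else config[[nm]]
  seed <- getd("seed", 1L)
  timepoint <- match.arg(getd("timepoint", "12m"), c("3m", "12m"))
  hl_threshold <- getd("hl_threshold", 0.05)
  auc_gain <- getd("auc_gain_threshold", 0.05)
  nlambda <- getd("nlambda", 100)
  cv_folds <- getd("cv_folds", 10)
  n_boot_forward <- getd("n_boot_forward", 2000)
  n_boot_auc <- getd("n_boot_auc", 2000)
  out_dir <- getd("out_dir", ".")
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)

  say("seed = %d, timepoint = %s, hl_threshold = %g, auc_gain = %g",
      seed, timepoint, hl_threshold, auc_gain)
  records <- if (!is.null(config$input)) {
    say("reading cohort from %s", config$input)
    read_cohort(config$input)
  } else if (!is.null(config$synthetic)) {
    args <- config$synthetic
    args$timepoint <- timepoint
    if (is.null(args$seed)) args$seed <- substream(seed, 10)
    say("generating synthetic cohort (n = %d, seed = %d)",
        args$n_patients, args$seed)
    generate_cohort(do.call(synthetic_config, args))
  } else stop("config needs either `input` or `synthetic`")

  ep <- derive_endpoint(records, timepoint)
  say("endpoint: %d assessed, %d excluded at baseline, %d events",
      ep$n_assessed, ep$n_excluded_baseline, ep$n_events)
  write.csv(endpoint_summary(ep),
            file.path(out_dir, "endpoint_summary.csv"), row.names = FALSE)

  factors <- names(xer_coding())
  design <- build_design_matrix(ep$data, factors)
  y <- ep$data$outcome

  say("computing shrinkage path (nlambda = %d)", nlambda)
  path <- compute_path(design, y, nlambda = nlambda)
  path_to_table(path, file.path(out_dir, "lasso_path.csv"))
  ranking <- rank_factors(path)
  jsonlite::write_json(ranking$factor,
                       file.path(out_dir, "ranking.json"))

  say("nested %d-fold CV for the optimal subset (seed = %d)",
      cv_folds, substream(seed, 20))
  cv <- nested_cv_select(design, y, folds = cv_folds,
                         seed = substream(seed, 20), nlambda = nlambda)
  say("suboptimal selection (HL gate %.2f, AUC gain %.2f)",
      hl_threshold, auc_gain)
  sub_trace <- select_suboptimal(ranking, ep$data,
                                 hl_threshold = hl_threshold,
                                 auc_gain_threshold = auc_gain)
  traces <- list(`lasso-optimal` = list(factors = cv$final_factors,
                                        chosen_t = cv$chosen_t),
                 `lasso-suboptimal` = list(factors = sub_trace$chosen,
                                           status = sub_trace$status,
                                           steps = sub_trace$steps))
  if (isTRUE(getd("run_forward", TRUE))) {
    say("bootstrap forward selection (n_boot = %d, seed = %d)",
        n_boot_forward, substream(seed, 30))
    fwd <- forward_select_ll(ep$data, factors, n_boot = n_boot_forward,
                             seed = substream(seed, 30))
    traces$`forward-LL` <- list(factors = fwd$chosen,
                                chosen_order = fwd$chosen_order,
                                steps = fwd$steps)
  }
  jsonlite::write_json(traces, file.path(out_dir, "selection_traces.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE,
                       dataframe = "rows")

  models <- list()
  evals <- list()
  for (lab in names(traces)) {
    fs <- traces[[lab]]$factors
    if (is.null(fs) || !length(fs)) next
    fit <- ntcp_fit(ep$data, fs)
    fit$label <- lab
    models[[lab]] <- fit
    write_ntcp_model(fit, file.path(out_dir, paste0("model_", lab, ".json")))
    s <- summary(fit)
    write.csv(cbind(term = rownames(s$odds_ratios), s$odds_ratios),
              file.path(out_dir, paste0("odds_ratios_", lab, ".csv")),
              row.names = FALSE)
    evals[[lab]] <- as.data.frame(
      evaluate_model(fit, n_boot = n_boot_auc,
                     seed = substream(seed, 40), label = lab))
  }
  eval_table <- do.call(rbind, evals)
  if (!is.null(eval_table))
    write.csv(eval_table, file.path(out_dir, "performance.csv"),
              row.names = FALSE)
  say("done; artifacts in %s", out_dir)
  invisible(list(endpoint = ep, ranking = ranking, path = path, cv = cv,
                 traces = traces, models = models,
                 performance = eval_table))
}
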