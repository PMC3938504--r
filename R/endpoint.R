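#' Dichotomise a four-point Likert xerostomia score at grade 3+
#'
#' The quality-of-life xerostomia item is scored none (0), a little (33),
#' quite a lot (66), a lot (100).  Grade 3+ (moderate-to-severe) xerostomia
#' corresponds to the two highest scores, 66 and 100.
#'
#' @param score numeric vector with values in \{0, 33, 66, 100\}.
#' @return logical vector: `TRUE` iff the score is 66 or 100.
#' @examples
#' likert_to_grade3plus(c(0, 33, 66, 100))
#' @export
likert_to_grade3plus <- function(score) {
  bad <- !is.na(score) & !score %in% c(0, 33, 66, 100)
  if (any(bad))
    stop("invalid Likert score(s): ", paste(unique(score[bad]), collapse = ", "),
         " (must be 0, 33, 66 or 100)")
  score %in% c(66, 100)
}

#' Derive the binary grade 3+ xerostomia endpoint from a cohort
#'
#' Applies the study-population logic: patients with grade 3+ xerostomia
#' already at baseline (baseline score >= 66) are excluded; every remaining
#' patient's outcome is the grade 3+ dichotomisation of their follow-up score
#' at the requested time point.  Patients with no follow-up score at that
#' time point are dropped with a warning (they were never assessed), not
#' imputed.
#'
#' The returned data also carries a `baseline_xer` column (0 = no baseline
#' xerostomia, 1 = "a little", i.e. baseline score 33), the binary clinical
#' factor used by the NTCP models: after exclusion no included patient can
#' have a baseline score above 33.
#'
#' @param records data frame of patient records (cohort schema, see
#'   [read_cohort()]), or an `ntcp_cohort`.
#' @param timepoint `"3m"` or `"12m"`.
#' @return object of class `xer_endpoint`: list with `data` (included
#'   records + `outcome` column), `n_assessed`, `n_excluded_baseline`,
#'   `n_events`, `timepoint`.
#' @examples
#' coh <- generate_cohort(synthetic_config(n_patients = 200, seed = 3))
#' ep <- derive_endpoint(coh, "12m")
#' ep
#' @export
derive_endpoint <- function(records, timepoint = c("12m", "3m")) {
  timepoint <- match.arg(timepoint)
  if (inherits(records, "ntcp_cohort")) records <- records$records
  stopifnot(is.data.frame(records))
  col <- paste0("xer_score_", timepoint)
  if (nrow(records) == 0) {
    records$outcome <- integer(0)
    return(structure(list(data = records, n_assessed = 0L,
                          n_excluded_baseline = 0L, n_events = 0L,
                          timepoint = timepoint), class = "xer_endpoint"))
  }
  if (!col %in% names(records))
    stop("no follow-up score column ", col, " in records")
  if (!"baseline_xer_score" %in% names(records))
    stop("records lack a baseline_xer_score column")
  missing_fu <- is.na(records[[col]])
  if (any(missing_fu)) {
    warning(sum(missing_fu), " record(s) without a ", timepoint,
            " follow-up score were dropped: ",
            paste(head(records$id[missing_fu], 5), collapse = ", "),
            if (sum(missing_fu) > 5) ", ..." else "")
    records <- records[!missing_fu, , drop = FALSE]
  }
  n_assessed <- nrow(records)
  base3 <- likert_to_grade3plus(records$baseline_xer_score)
  included <- records[!base3, , drop = FALSE]
  included$outcome <- as.integer(likert_to_grade3plus(included[[col]]))
  included$baseline_xer <- as.integer(included$baseline_xer_score == 33)
  structure(list(data = included,
                 n_assessed = n_assessed,
                 n_excluded_baseline = sum(base3),
                 n_events = sum(included$outcome),
                 timepoint = timepoint),
            class = "xer_endpoint")
}

#' @export
print.xer_endpoint <- function(x, ...) {
  cat(sprintf("Grade 3+ xerostomia endpoint at %s\n", x$timepoint))
  cat(sprintf("  assessed:            %d\n", x$n_assessed))
  cat(sprintf("  excluded (baseline): %d\n", x$n_excluded_baseline))
  cat(sprintf("  included:            %d\n", nrow(x$data)))
  cat(sprintf("  events:              %d (%.1f%% of assessed)\n",
              x$n_events, 100 * x$n_events / max(x$n_assessed, 1)))
  invisible(x)
}

#' Endpoint counts as a one-row summary table
#'
#' @param endpoint an `xer_endpoint`.
#' @return data frame with columns `timepoint`, `n_assessed`, `n_events`,
#'   `n_no_event`, `n_excluded_baseline`, `n_included`,
#'   `event_rate_assessed_pct` (events as a percentage of all assessed
#'   patients, the convention of cohort characteristic tables).
#' @export
endpoint_summary <- function(endpoint) {
  stopifnot(inherits(endpoint, "xer_endpoint"))
  n_inc <- nrow(endpoint$data)
  data.frame(timepoint = endpoint$timepoint,
             n_assessed = endpoint$n_assessed,
             n_events = endpoint$n_events,
             n_no_event = n_inc - endpoint$n_events,
             n_excluded_baseline = endpoint$n_excluded_baseline,
             n_included = n_inc,
             event_rate_assessed_pct =
               100 * endpoint$n_events / max(endpoint$n_assessed, 1))
}
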