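#' Factor coding schemes for NTCP design matrices
#'
#' A coding scheme declares, for every candidate prognostic factor, whether it
#' is continuous, binary, or categorical, its admissible levels, and -- for
#' categorical factors -- the reference level against which indicator (dummy)
#' columns are formed.  [xer_coding()] returns the default scheme for the 16
#' candidate factors of the xerostomia NTCP analysis: two mean parotid doses
#' (Gy), age (years), and 13 coded clinical factors.
#'
#' Reference levels default to the conventions used by the shipped reference
#' models ([xer_reference_model()]): T stage is referenced at T4, education at
#' elementary (0), AJCC stage at stage 1, financial status at the lowest
#' bracket.  Any reference can be overridden via `reference`.
#'
#' @param reference named list overriding the reference level of individual
#'   categorical factors, e.g. `list(t_stage = "1")`.
#' @return An object of class `ntcp_coding`: a named list with one entry per
#'   factor, each holding `type` (`"continuous"`, `"binary"` or
#'   `"categorical"`), `levels` and `reference`.
#' @examples
#' cod <- xer_coding()
#' cod$t_stage
#' xer_coding(reference = list(t_stage = "1"))$t_stage$reference
#' @export
xer_coding <- function(reference = list()) {
  cont <- function() list(type = "continuous", levels = NULL, reference = NULL)
  bin <- function() list(type = "binary", levels = c("0", "1"), reference = "0")
  cat_ <- function(levels, ref = levels[1])
    list(type = "categorical", levels = as.character(levels),
         reference = as.character(ref))
  scheme <- list(
    dmean_c = cont(), dmean_i = cont(), age = cont(),
    gender = bin(),
    education = cat_(0:3, 0),
    marriage = bin(), smoking = bin(), alcohol = bin(),
    ajcc_stage = cat_(1:4, 1),
    t_stage = cat_(1:4, 4),
    node = bin(), chemo = bin(), baseline_xer = bin(),
    family_history = bin(),
    financial = cat_(0:3, 0),
    treatment_mode = bin()
  )
  for (nm in names(reference)) {
    if (is.null(scheme[[nm]]))
      stop("unknown factor in `reference`: ", nm)
    ref <- as.character(reference[[nm]])
    if (!ref %in% scheme[[nm]]$levels)
      stop("reference level ", ref, " is not a declared level of ", nm)
    scheme[[nm]]$reference <- ref
  }
  structure(scheme, class = "ntcp_coding")
}

#' @export
print.ntcp_coding <- function(x, ...) {
  cat("NTCP factor coding scheme (", length(x), " factors)\n", sep = "")
  for (nm in names(x)) {
    f <- x[[nm]]
    if (f$type == "continuous") {
      cat(sprintf("  %-15s continuous\n", nm))
    } else {
      cat(sprintf("  %-15s %s {%s}, ref = %s\n", nm, f$type,
                  paste(f$levels, collapse = ","), f$reference))
    }
  }
  invisible(x)
}

# Design-column names produced by a factor under a coding scheme.
factor_columns <- function(name, spec) {
  if (spec$type == "categorical")
    paste0(name, ":", setdiff(spec$levels, spec$reference))
  else
    name
}

#' Build a reference-coded design matrix
#'
#' Expands patient records into the numeric design matrix on which the NTCP
#' models operate.  Continuous factors (doses in Gy, age in years) pass
#' through untransformed so fitted coefficients stay on their natural scales;
#' binary factors become single 0/1 columns; categorical factors expand to
#' reference-coded indicator columns, one per non-reference level.
#'
#' Indicator columns whose level never occurs in `data` are dropped with a
#' message (they would be identically zero and make the fit singular).
#'
#' @param data data frame of patient records; must contain every factor in
#'   `factors`.
#' @param factors character vector of factor names to include, in order.
#' @param coding an [xer_coding()] scheme (or compatible `ntcp_coding`).
#' @return list of class `ntcp_design` with elements `X` (numeric matrix),
#'   `assign` (factor name behind each column), `columns` (column names) and
#'   `dropped` (names of empty indicator columns removed).
#' @examples
#' coh <- generate_cohort(synthetic_config(n_patients = 20, seed = 1))
#' ep <- derive_endpoint(coh$records, "12m")
#' d <- build_design_matrix(ep$data, c("dmean_c", "t_stage"), xer_coding())
#' head(d$X)
#' @export
build_design_matrix <- function(data, factors, coding = xer_coding()) {
  stopifnot(is.data.frame(data))
  missing_f <- setdiff(factors, names(data))
  if (length(missing_f))
    stop("factors absent from data: ", paste(missing_f, collapse = ", "))
  cols <- list()
  assign <- character(0)
  dropped <- character(0)
  for (nm in factors) {
    spec <- coding[[nm]]
    if (is.null(spec)) stop("factor not in coding scheme: ", nm)
    v <- data[[nm]]
    if (spec$type == "continuous") {
      if (!is.numeric(v)) stop("factor ", nm, " must be numeric")
      if (anyNA(v)) stop("missing values in continuous factor ", nm)
      cols[[nm]] <- as.numeric(v)
      assign <- c(assign, nm)
    } else {
      vc <- as.character(v)
      bad <- !vc %in% spec$levels
      if (any(bad))
        stop("unseen level(s) in factor ", nm, ": ",
             paste(unique(vc[bad]), collapse = ", "),
             " (rows ", paste(head(which(bad), 5), collapse = ", "), ")")
      if (spec$type == "binary") {
        cols[[nm]] <- as.numeric(vc != spec$reference)
        assign <- c(assign, nm)
      } else {
        for (lev in setdiff(spec$levels, spec$reference)) {
          cn <- paste0(nm, ":", lev)
          col <- as.numeric(vc == lev)
          if (nrow(data) > 0 && all(col == 0)) {
            dropped <- c(dropped, cn)
            next
          }
          cols[[cn]] <- col
          assign <- c(assign, nm)
        }
      }
    }
  }
  if (length(dropped))
    message("dropping empty indicator column(s): ",
            paste(dropped, collapse = ", "))
  X <- if (length(cols)) do.call(cbind, cols) else
    matrix(numeric(0), nrow = nrow(data), ncol = 0)
  if (length(cols)) colnames(X) <- names(cols)
  structure(list(X = X, assign = assign, columns = colnames(X),
                 factors = factors, coding = coding, dropped = dropped),
            class = "ntcp_design")
}

# Decode one design row back to factor values (round-trip check support).
decode_design_row <- function(design, i) {
  x <- design$X[i, ]
  out <- list()
  for (nm in design$factors) {
    spec <- design$coding[[nm]]
    if (spec$type == "continuous") {
      out[[nm]] <- unname(x[nm])
    } else if (spec$type == "binary") {
      out[[nm]] <- spec$levels[1 + (x[nm] != 0)]
    } else {
      dums <- grep(paste0("^", nm, ":"), names(x), value = TRUE)
      on <- dums[x[dums] != 0]
      out[[nm]] <- if (length(on)) sub(paste0("^", nm, ":"), "", on[1])
        else spec$reference
    }
  }
  out
}
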