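#' Construct a two-arm trial dataset
#'
#' Bundles per-patient records of a two-arm trial (treatment arm, baseline
#' and week-8 MADRS scores, baseline moderator candidates) with the variable
#' specifications that govern downstream handling.
#'
#' @param patients data.frame with columns `patient_id`, `arm` (values
#'   "CBASP" or "ESC_CM"), `madrs_baseline`, `madrs_week8` (NA for
#'   non-completers) and one column per baseline variable.
#' @param variables data.frame with columns `name` and `kind`
#'   (nominal/ordinal/metric); defaults to [baseline_variables()].
#'   Variables absent from `patients` are dropped with a warning.
#' @return An object of class `trial_dataset`.
#' @export
trial_dataset <- function(patients, variables = baseline_variables()) {
  stopifnot(is.data.frame(patients))
  req <- c("patient_id", "arm", "madrs_baseline", "madrs_week8")
  miss <- setdiff(req, names(patients))
  if (length(miss))
    stop("patients is missing columns: ", paste(miss, collapse = ", "),
         call. = FALSE)
  if (anyDuplicated(patients$patient_id))
    stop("patient_id values must be unique", call. = FALSE)
  if (!all(patients$arm %in% ARM_LEVELS))
    stop("arm must be one of ", paste(ARM_LEVELS, collapse = ", "),
         call. = FALSE)
  absent <- setdiff(variables$name, names(patients))
  if (length(absent)) {
    warning("variables not present in data dropped: ",
            paste(absent, collapse = ", "), call. = FALSE)
    variables <- variables[!variables$name %in% absent, , drop = FALSE]
  }
  bad <- !is.na(patients$madrs_baseline) & patients$madrs_baseline <= 0
  if (any(bad))
    stop("madrs_baseline must be > 0 for analyzable patients", call. = FALSE)
  for (i in seq_len(nrow(variables)))
    check_variable_values(patients[[variables$name[i]]],
                          variables$kind[i], variables$name[i])
  patients$arm <- factor(patients$arm, levels = ARM_LEVELS)
  structure(list(patients = patients, variables = variables),
            class = "trial_dataset")
}

#' @export
print.trial_dataset <- function(x, ...) {
  tab <- table(x$patients$arm)
  cat("Two-arm trial dataset: ", nrow(x$patients), " patients (",
      paste(names(tab), tab, sep = " = ", collapse = ", "), ")\n", sep = "")
  cat("Completers (week-8 score present): ",
      sum(!is.na(x$patients$madrs_week8)), "\n", sep = "")
  cat("Baseline variables: ", paste(x$variables$name, collapse = ", "),
      "\n", sep = "")
  invisible(x)
}

#' Percent change in MADRS from baseline to week 8
#'
#' Computes `(week8 - baseline) / baseline * 100`. Negative values reflect a
#' reduction in depression severity, zero no change, positive values a
#' worsening. The quantity is scale-free: rescaling both scores by a common
#' positive factor leaves it unchanged.
#'
#' @param madrs_baseline,madrs_week8 numeric vectors of MADRS total scores.
#' @return numeric vector of percent changes.
#' @export
#' @examples
#' percent_change(30, 15)  # -50
percent_change <- function(madrs_baseline, madrs_week8) {
  if (any(!is.na(madrs_baseline) & madrs_baseline <= 0))
    stop("percent change undefined for baseline score <= 0", call. = FALSE)
  (madrs_week8 - madrs_baseline) / madrs_baseline * 100
}

#' Restrict a trial dataset to acute-phase completers
#'
#' Keeps only patients with a week-8 MADRS score; the analysis of moderator
#' effects is defined on completers.
#'
#' @param dataset a [trial_dataset()].
#' @return A `trial_dataset` of completers, with attribute `n_dropped`.
#' @export
filter_completers <- function(dataset) {
  stopifnot(inherits(dataset, "trial_dataset"))
  keep <- !is.na(dataset$patients$madrs_week8)
  if (!any(keep)) stop("no completers in dataset", call. = FALSE)
  out <- dataset
  out$patients <- dataset$patients[keep, , drop = FALSE]
  rownames(out$patients) <- NULL
  attr(out, "n_dropped") <- sum(!keep)
  out
}

#' Derive outcome classifications for each completer
#'
#' For every patient with both scores, computes the percent change and the
#' clinical status flags: response (>= 50.0% reduction, boundary inclusive),
#' remission (week-8 MADRS <= 9), and 20% improvement (>= 20.0% reduction).
#' Patients below the 20% improvement bound are the augmentation candidates
#' of the original trial design. Patients missing the week-8 score are
#' excluded with a warning.
#'
#' @param dataset a [trial_dataset()].
#' @return data.frame with columns `patient_id`, `arm`, `pct_change`,
#'   `responder`, `remitter`, `improver_20pct`.
#' @export
classify_outcomes <- function(dataset) {
  stopifnot(inherits(dataset, "trial_dataset"))
  p <- dataset$patients
  drop <- is.na(p$madrs_week8)
  if (any(drop)) {
    warning(sum(drop), " patient(s) without week-8 score excluded from ",
            "outcome classification", call. = FALSE)
    p <- p[!drop, , drop = FALSE]
  }
  pc <- percent_change(p$madrs_baseline, p$madrs_week8)
  data.frame(
    patient_id = p$patient_id,
    arm = p$arm,
    pct_change = pc,
    responder = pc <= -50.0,
    remitter = p$madrs_week8 <= 9,
    improver_20pct = pc <= -20.0,
    stringsAsFactors = FALSE
  )
}

#' Read a trial table from delimited text
#'
#' Reads a CSV with one row per patient. Column names can be remapped via
#' `mapping`, a named character vector `c(internal_name = "file_column")`
#' covering any columns whose names differ from the internal ones
#' (`patient_id`, `arm`, `madrs_baseline`, `madrs_week8` and the names in
#' [baseline_variables()]). Arm labels are remapped via `arm_labels`,
#' a named character vector `c(CBASP = "label", ESC_CM = "label")`.
#'
#' @param path path to the CSV file.
#' @param mapping optional named character vector of column renames.
#' @param arm_labels optional named character vector of arm label renames.
#' @param na_strings values interpreted as missing (default empty and "NA").
#' @param variables variable specification, defaults to
#'   [baseline_variables()].
#' @return A [trial_dataset()].
#' @export
read_trial <- function(path, mapping = NULL,
                       arm_labels = c(CBASP = "CBASP", ESC_CM = "ESC_CM"),
                       na_strings = c("", "NA"),
                       variables = baseline_variables()) {
  df <- utils::read.csv(path, na.strings = na_strings,
                        stringsAsFactors = FALSE)
  if (!is.null(mapping)) {
    for (internal in names(mapping)) {
      j <- match(mapping[[internal]], names(df))
      if (is.na(j))
        stop("mapped column '", mapping[[internal]], "' not found in ",
             path, call. = FALSE)
      names(df)[j] <- internal
    }
  }
  lab <- match(df$arm, arm_labels)
  if (anyNA(lab))
    stop("unrecognized arm label(s): ",
         paste(unique(df$arm[is.na(lab)]), collapse = ", "), call. = FALSE)
  df$arm <- names(arm_labels)[lab]
  trial_dataset(df, variables = variables)
}

#' Write outcome classifications to CSV
#'
#' @param outcomes data.frame from [classify_outcomes()].
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_outcomes <- function(outcomes, path) {
  utils::write.csv(outcomes, path, row.names = FALSE)
  invisible(path)
}
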