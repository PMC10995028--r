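#' Canonical baseline variables of the PDD trial
#'
#' The eleven baseline variables considered as candidate moderators of the
#' CBASP versus ESC/CM treatment effect: demographics (female gender, age),
#' clinical characteristics (early illness onset before age 21, baseline
#' MADRS severity, number of previous suicide attempts, Axis-I and Axis-II
#' comorbidity), childhood and life trauma (moderate-to-severe childhood
#' trauma flag, number of adverse life events), and treatment history
#' (previous psychotherapies and previous antidepressant treatments, both
#' coded ordinally 0 to 5 where 5 means "more than 5").
#'
#' Variable kinds drive how each variable is handled downstream:
#' \describe{
#'   \item{nominal}{binary 0/1 indicator; compared between subgroups by
#'     Fisher's exact test.}
#'   \item{ordinal}{integer codes 0--5; enters pair averages and the lasso
#'     as integer codes, dichotomized at >= 1 for subgroup comparison.}
#'   \item{metric}{real-valued; compared by pooled-variance t-test.}
#' }
#'
#' @return A data.frame with columns `name`, `kind` and `description`,
#'   one row per variable.
#' @export
#' @examples
#' baseline_variables()
baseline_variables <- function() {
  data.frame(
    name = c("female", "age", "early_onset", "madrs_baseline",
             "suicide_attempts", "axis1", "axis2", "trauma",
             "adverse_events", "prev_psychotherapies", "prev_antidepressants"),
    kind = c("nominal", "metric", "nominal", "metric",
             "metric", "nominal", "nominal", "nominal",
             "metric", "ordinal", "ordinal"),
    description = c(
      "Female gender (yes/no)",
      "Age in years",
      "Illness onset before age 21 (yes/no)",
      "Clinician-rated MADRS total score at baseline",
      "Self-reported number of previous suicide attempts",
      "Comorbidity of >= 1 Axis-I disorder (yes/no)",
      "Comorbidity of >= 1 Axis-II disorder (yes/no)",
      "Moderate-to-severe childhood trauma on >= 1 CTQ dimension (yes/no)",
      "Number of self-reported major psychosocial stressors over the lifetime",
      "Number of previous psychotherapies (0-5, 5 = more than 5)",
      "Number of previous antidepressant treatments (0-5, 5 = more than 5)"
    ),
    stringsAsFactors = FALSE
  )
}

#' @rdname baseline_variables
#' @format NULL
#' @export
ARM_LEVELS <- c("CBASP", "ESC_CM")

# internal: validate one variable column against its kind
check_variable_values <- function(x, kind, name) {
  ok <- x[!is.na(x)]
  if (kind == "nominal" && !all(ok %in% c(0, 1)))
    stop("nominal variable '", name, "' must be coded 0/1", call. = FALSE)
  if (kind == "ordinal" && !all(ok %in% 0:5))
    stop("ordinal variable '", name, "' must take integer values 0-5",
         call. = FALSE)
  if (kind == "metric" && !is.numeric(x))
    stop("metric variable '", name, "' must be numeric", call. = FALSE)
  invisible(TRUE)
}
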