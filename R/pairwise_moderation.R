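#' Build the all-pairs dataset across arms
#'
#' Pairs every CBASP patient with every ESC/CM patient. For each pair the
#' outcome difference is `pct_change(ESC/CM) - pct_change(CBASP)`, so that a
#' negative Spearman correlation with a baseline-variable average reads
#' "higher values or presence of the moderator favor ESC/CM" and a positive
#' one "favor CBASP". Each variable's pair value is the average of the two
#' members' values, missing whenever either member's value is missing.
#'
#' @param dataset a [trial_dataset()] of completers.
#' @param outcomes data.frame from [classify_outcomes()].
#' @return data.frame with columns `cbasp_id`, `esc_id`, `outcome_diff` and
#'   one average column per baseline variable; `n_cbasp * n_esc` rows.
#' @export
build_pairs <- function(dataset, outcomes = classify_outcomes(dataset)) {
  stopifnot(inherits(dataset, "trial_dataset"))
  p <- dataset$patients[dataset$patients$patient_id %in% outcomes$patient_id,
                        , drop = FALSE]
  y <- outcomes$pct_change[match(p$patient_id, outcomes$patient_id)]
  iC <- which(p$arm == "CBASP")
  iE <- which(p$arm == "ESC_CM")
  if (!length(iC) || !length(iE))
    stop("both arms must be non-empty to build pairs", call. = FALSE)
  idx <- expand.grid(c = iC, e = iE, KEEP.OUT.ATTRS = FALSE)
  pairs <- data.frame(
    cbasp_id = p$patient_id[idx$c],
    esc_id = p$patient_id[idx$e],
    outcome_diff = y[idx$e] - y[idx$c],
    stringsAsFactors = FALSE
  )
  for (v in dataset$variables$name)
    pairs[[v]] <- (p[[v]][idx$c] + p[[v]][idx$e]) / 2
  attr(pairs, "variables") <- dataset$variables$name
  attr(pairs, "arm_sizes") <- c(n_cbasp = length(iC), n_esc = length(iE))
  pairs
}

#' Moderator effect size of one baseline variable
#'
#' Spearman rank correlation (average ranks for ties) between the pair
#' outcome difference and the pair average of the variable, over pairs with
#' complete data on both. Ranges over [-1, 1]; with the pairing sign
#' convention of [build_pairs()], negative values indicate a superiority of
#' ESC/CM and positive values a superiority of CBASP for higher values or
#' presence of the moderator. Invariant under strictly increasing
#' transformations of either quantity.
#'
#' A constant variable or constant outcome difference makes the correlation
#' undefined; the effect is then flagged degenerate with rho recorded as 0.
#'
#' @param pairs data.frame from [build_pairs()].
#' @param variable name of the variable column.
#' @return list with `variable`, `rho`, `n_pairs_used`, `degenerate`.
#' @export
moderator_effect_size <- function(pairs, variable) {
  x <- pairs[[variable]]
  if (is.null(x)) stop("no such variable: ", variable, call. = FALSE)
  ok <- !is.na(x) & !is.na(pairs$outcome_diff)
  x <- x[ok]
  d <- pairs$outcome_diff[ok]
  if (length(x) < 3)
    stop("fewer than 3 complete pairs for '", variable, "'", call. = FALSE)
  if (length(unique(x)) < 2 || length(unique(d)) < 2) {
    warning("degenerate effect size for '", variable,
            "': constant variable or outcome difference", call. = FALSE)
    return(list(variable = variable, rho = 0, n_pairs_used = length(x),
                degenerate = TRUE))
  }
  list(variable = variable,
       rho = stats::cor(x, d, method = "spearman"),
       n_pairs_used = length(x),
       degenerate = FALSE)
}

#' Bootstrap confidence interval for a moderator effect size
#'
#' Percentile 95% interval over `n_reps` replications. Each replication
#' resamples patients with replacement within each arm (arm sizes
#' preserved), rebuilds all cross-arm pairs, and recomputes the Spearman
#' effect size. Replications with a degenerate correlation are skipped; if
#' more than half are skipped the interval is refused.
#'
#' @param dataset a [trial_dataset()] of completers.
#' @param outcomes data.frame from [classify_outcomes()].
#' @param variable variable name (a baseline variable, or any per-patient
#'   column present in the dataset such as a composite moderator).
#' @param n_reps number of bootstrap replications (default 100).
#' @param seed integer seed.
#' @return numeric vector `c(ci_low, ci_high)` with attribute `n_skipped`.
#' @export
bootstrap_ci <- function(dataset, outcomes, variable, n_reps = 100,
                         seed = 1L) {
  stopifnot(n_reps >= 2)
  p <- dataset$patients[dataset$patients$patient_id %in% outcomes$patient_id,
                        , drop = FALSE]
  y <- outcomes$pct_change[match(p$patient_id, outcomes$patient_id)]
  x <- p[[variable]]
  if (is.null(x)) stop("no such variable: ", variable, call. = FALSE)
  iC <- which(p$arm == "CBASP")
  iE <- which(p$arm == "ESC_CM")
  set.seed(seed)
  rhos <- rep(NA_real_, n_reps)
  for (b in seq_len(n_reps)) {
    bC <- sample(iC, replace = TRUE)
    bE <- sample(iE, replace = TRUE)
    idx <- expand.grid(c = bC, e = bE, KEEP.OUT.ATTRS = FALSE)
    avg <- (x[idx$c] + x[idx$e]) / 2
    d <- y[idx$e] - y[idx$c]
    ok <- !is.na(avg) & !is.na(d)
    if (sum(ok) < 3 || length(unique(avg[ok])) < 2 ||
        length(unique(d[ok])) < 2) next
    rhos[b] <- stats::cor(avg[ok], d[ok], method = "spearman")
  }
  skipped <- sum(is.na(rhos))
  if (skipped > n_reps / 2)
    stop("more than half of bootstrap replications degenerate for '",
         variable, "'", call. = FALSE)
  if (skipped > 0)
    warning(skipped, " degenerate bootstrap replication(s) skipped for '",
            variable, "'", call. = FALSE)
  ci <- unname(stats::quantile(rhos, c(0.025, 0.975), na.rm = TRUE))
  structure(c(ci_low = ci[1], ci_high = ci[2]), n_skipped = skipped)
}

#' Effect sizes, intervals and preselection status for all variables
#'
#' Computes, for every baseline variable, the moderator effect size over
#' the paired dataset, its 95% bootstrap confidence interval, patient-level
#' valid/missing counts, and the two preselection flags: the
#' missing-data rule (at least `min_valid` valid cases or no more than
#' `max_missing` missing cases) and the effect-size threshold
#' `|rho| >= threshold` (inclusive). A variable is selected for the
#' composite moderator when it passes both.
#'
#' @inheritParams bootstrap_ci
#' @param threshold effect-size magnitude cutoff (default 0.20).
#' @param min_valid,max_missing missing-data preselection rule
#'   (defaults 50 and 3).
#' @return data.frame with one row per variable: `variable`, `rho`,
#'   `ci_low`, `ci_high`, `n_pairs_used`, `n_valid`, `n_missing`,
#'   `degenerate`, `preselected_missingness`, `selected_by_threshold`,
#'   `selected`.
#' @export
moderator_effects <- function(dataset, outcomes = classify_outcomes(dataset),
                              n_reps = 100, seed = 1L, threshold = 0.20,
                              min_valid = 50, max_missing = 3) {
  pairs <- build_pairs(dataset, outcomes)
  vars <- dataset$variables$name
  p <- dataset$patients[dataset$patients$patient_id %in% outcomes$patient_id,
                        , drop = FALSE]
  rows <- lapply(seq_along(vars), function(i) {
    v <- vars[i]
    eff <- moderator_effect_size(pairs, v)
    ci <- bootstrap_ci(dataset, outcomes, v, n_reps = n_reps,
                       seed = seed + i - 1L)
    n_missing <- sum(is.na(p[[v]]))
    data.frame(variable = v, rho = eff$rho,
               ci_low = ci[["ci_low"]], ci_high = ci[["ci_high"]],
               n_pairs_used = eff$n_pairs_used,
               n_valid = nrow(p) - n_missing, n_missing = n_missing,
               degenerate = eff$degenerate,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  out$preselected_missingness <-
    out$n_valid >= min_valid | out$n_missing <= max_missing
  out$selected_by_threshold <- abs(out$rho) >= threshold & !out$degenerate
  out$selected <- out$preselected_missingness & out$selected_by_threshold
  out
}

#' Apply the preselection rules to a computed effects table
#'
#' @param effects data.frame from [moderator_effects()] (the rule columns
#'   are recomputed from `rho`, `n_valid`, `n_missing`).
#' @inheritParams moderator_effects
#' @return character vector of selected variable names.
#' @export
preselect_variables <- function(effects, threshold = 0.20, min_valid = 50,
                                max_missing = 3) {
  keep <- (effects$n_valid >= min_valid | effects$n_missing <= max_missing) &
    abs(effects$rho) >= threshold & !effects$degenerate
  effects$variable[keep]
}

#' Diagnostic screen for outliers and skewness
#'
#' Reports, for the outcome and each metric baseline variable, the number
#' of univariate outliers (|z| > 3) and the sample skewness. The screen is
#' diagnostic only: nothing is removed.
#'
#' @param dataset a [trial_dataset()] of completers.
#' @param outcomes data.frame from [classify_outcomes()].
#' @return data.frame with columns `variable`, `n_outliers`, `skewness`.
#' @export
screen_outliers <- function(dataset, outcomes = classify_outcomes(dataset)) {
  metric <- dataset$variables$name[dataset$variables$kind == "metric"]
  cols <- c(list(pct_change = outcomes$pct_change),
            lapply(stats::setNames(metric, metric),
                   function(v) dataset$patients[[v]]))
  rows <- lapply(names(cols), function(nm) {
    x <- cols[[nm]][!is.na(cols[[nm]])]
    z <- (x - mean(x)) / stats::sd(x)
    data.frame(variable = nm, n_outliers = sum(abs(z) > 3),
               skewness = e1071::skewness(x), stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}
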