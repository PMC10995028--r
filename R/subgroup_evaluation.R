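CLUSTER_LEVELS <- c("BeESC_TrESC", "BeCBASP_TrCBASP",
                    "BeCBASP_TrESC", "BeESC_TrCBASP")

#' Stratify patients into the four subgroup-by-treatment clusters
#'
#' Crosses each patient's benefit subgroup with the arm they were actually
#' randomized to. The first two clusters are the matched patients (treated
#' with their likely more beneficial condition), the last two the
#' mismatched ones.
#'
#' @param subgroups data.frame from [assign_subgroups()].
#' @param outcomes data.frame from [classify_outcomes()] (provides the arm).
#' @return data.frame with columns `patient_id`, `cluster` (factor over
#'   BeESC_TrESC, BeCBASP_TrCBASP, BeCBASP_TrESC, BeESC_TrCBASP) and
#'   `matched` (logical).
#' @export
stratify_clusters <- function(subgroups, outcomes) {
  df <- merge(subgroups, outcomes[, c("patient_id", "arm")],
              by = "patient_id")
  be_esc <- df$subgroup == "benefit_ESC_CM"
  tr_esc <- df$arm == "ESC_CM"
  cl <- ifelse(be_esc & tr_esc, "BeESC_TrESC",
        ifelse(!be_esc & !tr_esc, "BeCBASP_TrCBASP",
        ifelse(!be_esc & tr_esc, "BeCBASP_TrESC", "BeESC_TrCBASP")))
  data.frame(patient_id = df$patient_id,
             cluster = factor(cl, levels = CLUSTER_LEVELS),
             matched = be_esc == tr_esc,
             stringsAsFactors = FALSE)
}

# internal: summary row for one group of patients
summarize_group <- function(label, p, o) {
  n <- nrow(p)
  msd <- function(x) if (n >= 2) stats::sd(x) else NA_real_
  if (n == 0)
    return(data.frame(cluster = label, n = 0L,
                      madrs_baseline_mean = NA_real_,
                      madrs_baseline_sd = NA_real_,
                      madrs_week8_mean = NA_real_, madrs_week8_sd = NA_real_,
                      pct_change_mean = NA_real_, pct_change_sd = NA_real_,
                      response_rate = NA_real_, remission_rate = NA_real_,
                      stringsAsFactors = FALSE))
  data.frame(
    cluster = label, n = n,
    madrs_baseline_mean = mean(p$madrs_baseline),
    madrs_baseline_sd = msd(p$madrs_baseline),
    madrs_week8_mean = mean(p$madrs_week8),
    madrs_week8_sd = msd(p$madrs_week8),
    pct_change_mean = mean(o$pct_change),
    pct_change_sd = msd(o$pct_change),
    response_rate = 100 * mean(o$responder),
    remission_rate = 100 * mean(o$remitter),
    stringsAsFactors = FALSE
  )
}

#' Outcome summaries for each cluster and the matched/mismatched pools
#'
#' Per-cluster and pooled means and SDs of the baseline MADRS, the week-8
#' MADRS and the percent change, plus response and remission rates in
#' percent. Rates are computed from unrounded counts.
#'
#' @param dataset a [trial_dataset()].
#' @param outcomes data.frame from [classify_outcomes()].
#' @param clusters data.frame from [stratify_clusters()].
#' @return data.frame with one row per cluster (empty clusters keep n = 0
#'   and absent statistics) and two pooled rows labeled `matched` and
#'   `mismatched`.
#' @export
cluster_outcomes <- function(dataset, outcomes, clusters) {
  rows <- lapply(c(as.list(CLUSTER_LEVELS),
                   list(c("BeESC_TrESC", "BeCBASP_TrCBASP"),
                        c("BeCBASP_TrESC", "BeESC_TrCBASP"))),
                 function(members) {
    label <- if (length(members) == 1) members
             else if ("BeESC_TrESC" %in% members) "matched" else "mismatched"
    ids <- clusters$patient_id[clusters$cluster %in% members]
    p <- dataset$patients[dataset$patients$patient_id %in% ids, ,
                          drop = FALSE]
    o <- outcomes[outcomes$patient_id %in% ids, , drop = FALSE]
    summarize_group(label, p, o)
  })
  do.call(rbind, rows)
}

#' Pool cluster summary rows exactly from their summary statistics
#'
#' Combines per-cluster n, means, SDs and rates into the pooled group
#' without access to patient-level data: means and rates pool as
#' n-weighted averages, and the pooled SD uses the exact two-level
#' variance decomposition
#' \deqn{s^2 = \frac{\sum_i (n_i - 1) s_i^2 + \sum_i n_i (m_i - m)^2}{N - 1}.}
#' Applied to a trial's printed per-cluster rows this reproduces its
#' printed pooled rows; applied to [cluster_outcomes()] rows it equals the
#' direct patient-level computation (an exact identity).
#'
#' @param summaries data.frame in the column layout of
#'   [cluster_outcomes()].
#' @param members character vector of `cluster` values to pool.
#' @param label label for the pooled row.
#' @return A one-row data.frame in the same layout.
#' @export
pool_cluster_summaries <- function(summaries, members, label = "pooled") {
  s <- summaries[summaries$cluster %in% members, , drop = FALSE]
  stopifnot(nrow(s) >= 1)
  N <- sum(s$n)
  wmean <- function(m) sum(s$n * m) / N
  psd <- function(m, sd) {
    M <- wmean(m)
    sqrt((sum((s$n - 1) * sd^2) + sum(s$n * (m - M)^2)) / (N - 1))
  }
  data.frame(
    cluster = label, n = N,
    madrs_baseline_mean = wmean(s$madrs_baseline_mean),
    madrs_baseline_sd = psd(s$madrs_baseline_mean, s$madrs_baseline_sd),
    madrs_week8_mean = wmean(s$madrs_week8_mean),
    madrs_week8_sd = psd(s$madrs_week8_mean, s$madrs_week8_sd),
    pct_change_mean = wmean(s$pct_change_mean),
    pct_change_sd = psd(s$pct_change_mean, s$pct_change_sd),
    response_rate = wmean(s$response_rate),
    remission_rate = wmean(s$remission_rate),
    stringsAsFactors = FALSE
  )
}

#' Pooled-variance two-sample t comparison from summary statistics
#'
#' Difference in means with the Student (equal-variance) 95% confidence
#' interval and p-value, computable directly from printed group summaries.
#'
#' @param n1,mean1,sd1 size, mean and SD of group 1.
#' @param n2,mean2,sd2 size, mean and SD of group 2.
#' @return list with `difference`, `ci_low`, `ci_high`, `p_value`, `df`.
#' @export
t_test_from_summary <- function(n1, mean1, sd1, n2, mean2, sd2) {
  df <- n1 + n2 - 2
  sp <- sqrt(((n1 - 1) * sd1^2 + (n2 - 1) * sd2^2) / df)
  se <- sp * sqrt(1 / n1 + 1 / n2)
  diff <- mean1 - mean2
  tq <- stats::qt(0.975, df)
  list(difference = diff, ci_low = diff - tq * se, ci_high = diff + tq * se,
       p_value = 2 * stats::pt(-abs(diff / se), df), df = df)
}

#' Fisher-exact comparison of two proportions
#'
#' Difference in percentages with a Wald 95% interval and the two-sided
#' Fisher exact p-value (point-probability method, as in
#' [stats::fisher.test()]).
#'
#' @param x1,n1 events and size of group 1.
#' @param x2,n2 events and size of group 2.
#' @return list with `difference` (percentage points), `ci_low`,
#'   `ci_high`, `p_value`.
#' @export
prop_diff_fisher <- function(x1, n1, x2, n2) {
  p1 <- x1 / n1
  p2 <- x2 / n2
  se <- sqrt(p1 * (1 - p1) / n1 + p2 * (1 - p2) / n2)
  p <- stats::fisher.test(matrix(c(x1, n1 - x1, x2, n2 - x2), nrow = 2,
                                 byrow = TRUE))$p.value
  list(difference = 100 * (p1 - p2),
       ci_low = 100 * (p1 - p2 - 1.96 * se),
       ci_high = 100 * (p1 - p2 + 1.96 * se),
       p_value = p)
}

#' Compare baseline variables between the two benefit subgroups
#'
#' Metric variables are compared by pooled-variance two-sample t-tests
#' (difference in means, Student 95% CI); nominal variables by Fisher's
#' exact test with a Wald interval for the difference in percentages;
#' ordinal treatment-history variables are dichotomized at >= 1 and
#' compared like nominal ones. The difference is always
#' `benefit_ESC_CM` minus `benefit_CBASP`. Zero-variance metric variables
#' are flagged and left untested.
#'
#' @param dataset a [trial_dataset()].
#' @param subgroups data.frame from [assign_subgroups()].
#' @return data.frame with one row per variable: `variable`, `test`,
#'   `summary_esc`, `summary_cbasp` (mean or percentage), `difference`,
#'   `ci_low`, `ci_high`, `p_value`.
#' @export
compare_subgroup_baselines <- function(dataset, subgroups) {
  df <- merge(dataset$patients, subgroups[, c("patient_id", "subgroup")],
              by = "patient_id")
  g1 <- df$subgroup == "benefit_ESC_CM"
  if (!any(g1) || all(g1))
    stop("both subgroups must be non-empty", call. = FALSE)
  rows <- lapply(seq_len(nrow(dataset$variables)), function(i) {
    v <- dataset$variables$name[i]
    kind <- dataset$variables$kind[i]
    x1 <- df[[v]][g1 & !is.na(df[[v]])]
    x2 <- df[[v]][!g1 & !is.na(df[[v]])]
    if (kind == "metric") {
      if (stats::sd(x1) == 0 && stats::sd(x2) == 0)
        return(data.frame(variable = v, test = "degenerate",
                          summary_esc = mean(x1), summary_cbasp = mean(x2),
                          difference = mean(x1) - mean(x2),
                          ci_low = NA_real_, ci_high = NA_real_,
                          p_value = NA_real_, stringsAsFactors = FALSE))
      r <- t_test_from_summary(length(x1), mean(x1), stats::sd(x1),
                               length(x2), mean(x2), stats::sd(x2))
      data.frame(variable = v, test = "two-sample-t",
                 summary_esc = mean(x1), summary_cbasp = mean(x2),
                 difference = r$difference, ci_low = r$ci_low,
                 ci_high = r$ci_high, p_value = r$p_value,
                 stringsAsFactors = FALSE)
    } else {
      b1 <- if (kind == "ordinal") as.numeric(x1 >= 1) else x1
      b2 <- if (kind == "ordinal") as.numeric(x2 >= 1) else x2
      r <- prop_diff_fisher(sum(b1), length(b1), sum(b2), length(b2))
      data.frame(variable = v, test = "Fisher-exact",
                 summary_esc = 100 * mean(b1), summary_cbasp = 100 * mean(b2),
                 difference = r$difference, ci_low = r$ci_low,
                 ci_high = r$ci_high, p_value = r$p_value,
                 stringsAsFactors = FALSE)
    }
  })
  do.call(rbind, rows)
}

#' Sub-analysis of augmentation candidates
#'
#' Augmentation candidates are patients whose symptom severity did not
#' drop by at least 20.0% in the acute phase (in the original trial design
#' they received the other condition on top from week 8 on). Reports how
#' many candidates there are and how they split into mismatched versus
#' matched initial treatment.
#'
#' @param outcomes data.frame from [classify_outcomes()].
#' @param clusters data.frame from [stratify_clusters()].
#' @return list with `n_candidates`, `n_mismatched`, `n_matched`,
#'   `share_mismatched` (percent, NA when there are no candidates) and the
#'   candidate `cluster` breakdown table.
#' @export
augmentation_analysis <- function(outcomes, clusters) {
  df <- merge(outcomes, clusters, by = "patient_id")
  cand <- df[!df$improver_20pct, , drop = FALSE]
  n <- nrow(cand)
  list(
    n_candidates = n,
    n_mismatched = sum(!cand$matched),
    n_matched = sum(cand$matched),
    share_mismatched = if (n > 0) 100 * sum(!cand$matched) / n else NA_real_,
    by_cluster = table(cand$cluster)
  )
}
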