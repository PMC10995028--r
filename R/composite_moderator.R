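#' Lasso regression with k-fold cross-validation on the paired dataset
#'
#' Regresses the pair outcome difference on the pair averages of the
#' preselected variables under an L1 penalty, choosing the tuning parameter
#' lambda that minimizes the k-fold cross-validated mean-squared prediction
#' error (MSPE). Predictors are standardized internally for the penalty;
#' the returned coefficients are on the original variable scale, refit on
#' all pairs at the optimal lambda. Folds are a random near-equal partition
#' of the pair records given `seed`; a `grouped` option instead keeps all
#' pairs sharing a CBASP patient in one fold, since pair records that share
#' a patient are statistically dependent.
#'
#' @param pairs data.frame from [build_pairs()].
#' @param variables character vector of (preselected) variable names.
#' @param k number of folds (default 10).
#' @param seed integer seed for the fold assignment.
#' @param one_se use the 1-SE rule instead of the strict MSPE minimum.
#' @param lambda optional user lambda grid; by default a log-spaced grid
#'   descending from the smallest lambda that zeroes all coefficients.
#' @param grouped form folds by CBASP patient rather than by pair record.
#' @return Object of class `lasso_cv_fit`: `lambda` (grid), `cv_mspe`,
#'   `lambda_opt`, `coefficients` (named, zeros retained), `intercept`,
#'   `nonzero` (names of surviving moderators), `k`, `seed`, `n_pairs`.
#' @export
fit_lasso_cv <- function(pairs, variables, k = 10, seed = 1L,
                         one_se = FALSE, lambda = NULL, grouped = FALSE) {
  stopifnot(length(variables) >= 1)
  cols <- c("outcome_diff", variables)
  cc <- stats::complete.cases(pairs[, cols, drop = FALSE])
  d <- pairs[cc, , drop = FALSE]
  n <- nrow(d)
  if (n < k)
    stop("fewer complete pair records (", n, ") than folds (", k, ")",
         call. = FALSE)
  X <- as.matrix(d[, variables, drop = FALSE])
  # glmnet requires >= 2 columns; pad a constant column it will zero out
  padded <- ncol(X) == 1
  if (padded) X <- cbind(X, .pad. = 0)
  y <- d$outcome_diff
  set.seed(seed)
  foldid <- if (grouped) {
    ids <- unique(d$cbasp_id)
    grp <- stats::setNames(sample(rep_len(seq_len(k), length(ids))), ids)
    unname(grp[d$cbasp_id])
  } else sample(rep_len(seq_len(k), n))
  cv <- glmnet::cv.glmnet(X, y, lambda = lambda, foldid = foldid,
                          standardize = TRUE, family = "gaussian")
  lambda_opt <- if (one_se) cv$lambda.1se else cv$lambda.min
  beta <- as.matrix(stats::coef(cv, s = lambda_opt))
  coefs <- stats::setNames(beta[variables, 1], variables)
  nonzero <- names(coefs)[coefs != 0]
  if (!length(nonzero))
    stop("no moderator survives: all lasso coefficients are zero at ",
         "the optimal lambda", call. = FALSE)
  structure(list(lambda = cv$lambda, cv_mspe = cv$cvm,
                 lambda_opt = lambda_opt, coefficients = coefs,
                 intercept = beta["(Intercept)", 1], nonzero = nonzero,
                 k = k, seed = as.integer(seed), n_pairs = n),
            class = "lasso_cv_fit")
}

#' @export
print.lasso_cv_fit <- function(x, ...) {
  cat("Lasso fit with ", x$k, "-fold CV on ", x$n_pairs, " pairs\n",
      sep = "")
  cat("lambda_opt = ", signif(x$lambda_opt, 4), " (MSPE ",
      signif(x$cv_mspe[which(x$lambda == x$lambda_opt)], 4), ")\n", sep = "")
  cat("surviving moderators:\n")
  print(round(x$coefficients[x$nonzero], 3))
  invisible(x)
}

#' Compile the composite moderator M* for each patient
#'
#' M* is the weighted sum of the surviving moderators (no intercept),
#' computed for every patient with complete data on all weighted variables;
#' patients missing any weighted variable are excluded and counted.
#'
#' @param dataset a [trial_dataset()].
#' @param weights named numeric vector of moderator weights (zeros are
#'   ignored), e.g. `coefficients` of a [fit_lasso_cv()] fit.
#' @return data.frame with columns `patient_id`, `m_star`; attribute
#'   `excluded` holds the ids of patients without complete data.
#' @export
compute_m_star <- function(dataset, weights) {
  stopifnot(inherits(dataset, "trial_dataset"))
  w <- weights[weights != 0]
  if (!length(w)) stop("weights must contain a nonzero entry", call. = FALSE)
  missing_vars <- setdiff(names(w), names(dataset$patients))
  if (length(missing_vars))
    stop("weighted variables absent from dataset: ",
         paste(missing_vars, collapse = ", "), call. = FALSE)
  X <- as.matrix(dataset$patients[, names(w), drop = FALSE])
  m <- drop(X %*% w)
  ok <- !is.na(m)
  if (!any(ok))
    stop("no patient has complete data on all weighted variables",
         call. = FALSE)
  structure(
    data.frame(patient_id = dataset$patients$patient_id[ok],
               m_star = m[ok], stringsAsFactors = FALSE),
    excluded = dataset$patients$patient_id[!ok]
  )
}

#' Treatment-by-M* interaction regression on the unpaired dataset
#'
#' Ordinary least squares of the percent-change outcome on M*, the
#' treatment indicator (T = 1 for CBASP, 0 for ESC/CM) and their
#' interaction.
#'
#' @param dataset a [trial_dataset()].
#' @param outcomes data.frame from [classify_outcomes()].
#' @param m_star data.frame from [compute_m_star()].
#' @return Object of class `interaction_fit` with the four coefficients,
#'   the standard error of the interaction, R-squared, the outcome SD,
#'   the fitted model frame and `n`.
#' @export
fit_interaction_model <- function(dataset, outcomes, m_star) {
  df <- merge(m_star, outcomes[, c("patient_id", "arm", "pct_change")],
              by = "patient_id")
  df$treat <- as.numeric(df$arm == "CBASP")
  if (nrow(df) < 4 || length(unique(df$treat)) < 2)
    stop("need >= 4 patients with M* spanning both arms", call. = FALSE)
  fit <- stats::lm(pct_change ~ m_star * treat, data = df)
  co <- stats::coef(fit)
  if (anyNA(co)) stop("design matrix is rank-deficient", call. = FALSE)
  sm <- summary(fit)
  structure(list(
    beta_intercept = unname(co["(Intercept)"]),
    beta_mstar = unname(co["m_star"]),
    beta_treatment = unname(co["treat"]),
    beta_interaction = unname(co["m_star:treat"]),
    se_interaction = sm$coefficients["m_star:treat", "Std. Error"],
    p_interaction = sm$coefficients["m_star:treat", "Pr(>|t|)"],
    r_squared = sm$r.squared,
    outcome_sd = stats::sd(df$pct_change),
    n = nrow(df),
    data = df
  ), class = "interaction_fit")
}

#' @export
print.interaction_fit <- function(x, ...) {
  cat("Outcome ~ M* x treatment (T = 1 CBASP), n = ", x$n, "\n", sep = "")
  cat(sprintf("  interaction beta = %.3f (SE %.3f, p = %.3g), R^2 = %.3f\n",
              x$beta_interaction, x$se_interaction, x$p_interaction,
              x$r_squared))
  invisible(x)
}

#' Predicted percent change for each arm at given M* values
#'
#' @param fit an [fit_interaction_model()] result.
#' @param m_star numeric vector of M* values.
#' @return data.frame with columns `m_star`, `pred_cbasp`, `pred_esc`.
#' @export
predict_arms <- function(fit, m_star) {
  data.frame(
    m_star = m_star,
    pred_cbasp = fit$beta_intercept + fit$beta_treatment +
      (fit$beta_mstar + fit$beta_interaction) * m_star,
    pred_esc = fit$beta_intercept + fit$beta_mstar * m_star
  )
}

#' Moderator effect size of the composite moderator
#'
#' Treats M* as a baseline variable: rebuilds the paired dataset over the
#' patients with an M* value and computes the Spearman effect size with its
#' 95% bootstrap confidence interval, under the same contract as the
#' single-variable operations.
#'
#' @inheritParams fit_interaction_model
#' @param n_reps bootstrap replications (default 100).
#' @param seed integer seed.
#' @return list with `variable`, `rho`, `ci_low`, `ci_high`,
#'   `n_pairs_used`, `degenerate`.
#' @export
composite_effect_size <- function(dataset, outcomes, m_star, n_reps = 100,
                                  seed = 1L) {
  keep <- dataset$patients$patient_id %in% m_star$patient_id
  ds <- dataset
  ds$patients <- dataset$patients[keep, , drop = FALSE]
  ds$patients$m_star <-
    m_star$m_star[match(ds$patients$patient_id, m_star$patient_id)]
  add <- ds$variables[1, , drop = FALSE]
  add[1, ] <- NA
  add$name <- "m_star"
  add$kind <- "metric"
  ds$variables <- rbind(ds$variables, add)
  out <- outcomes[outcomes$patient_id %in% m_star$patient_id, , drop = FALSE]
  pairs <- build_pairs(ds, out)
  eff <- moderator_effect_size(pairs, "m_star")
  ci <- bootstrap_ci(ds, out, "m_star", n_reps = n_reps, seed = seed)
  c(eff, list(ci_low = ci[["ci_low"]], ci_high = ci[["ci_high"]]))
}

#' M* value at which the two arms' predicted outcomes intersect
#'
#' Solves `beta_treatment + beta_interaction * m = 0`. Refused when the
#' interaction coefficient is negligible relative to the outcome scale
#' (near-parallel lines, no qualitative interaction).
#'
#' @param fit an [fit_interaction_model()] result.
#' @param tol relative tolerance; the interaction must exceed
#'   `tol * outcome SD` in magnitude.
#' @return The cross-point, a single number.
#' @export
find_cross_point <- function(fit, tol = 1e-8) {
  if (abs(fit$beta_interaction) < tol * fit$outcome_sd)
    stop("no qualitative interaction: predicted arm lines are ",
         "near-parallel", call. = FALSE)
  -fit$beta_treatment / fit$beta_interaction
}

#' Assign patients to benefit subgroups by their side of the cross-point
#'
#' The side of the cross-point on which the predicted ESC/CM outcome is
#' lower (a larger symptom reduction) is labeled `benefit_ESC_CM`, the
#' other `benefit_CBASP`. With the fitted lines, CBASP minus ESC/CM
#' predicted outcome equals `beta_interaction * (m - cross_point)`, so the
#' orientation is the sign of the interaction coefficient: for a positive
#' orientation, M* above the cross-point favors ESC/CM; for a negative
#' one, M* below it does. Patients exactly at the cross-point are assigned
#' to `benefit_ESC_CM` by convention and counted.
#'
#' @param m_star data.frame from [compute_m_star()].
#' @param cross_point the cross-point from [find_cross_point()].
#' @param orientation sign of the interaction coefficient (any nonzero
#'   number; only the sign is used).
#' @return data.frame with columns `patient_id`, `m_star`, `subgroup`
#'   (factor `benefit_ESC_CM`/`benefit_CBASP`); attribute
#'   `n_at_cross_point`. A single-sided split triggers a warning.
#' @export
assign_subgroups <- function(m_star, cross_point, orientation) {
  stopifnot(is.finite(cross_point), orientation != 0)
  side <- sign(orientation) * (m_star$m_star - cross_point)
  sub <- ifelse(side >= 0, "benefit_ESC_CM", "benefit_CBASP")
  out <- data.frame(patient_id = m_star$patient_id,
                    m_star = m_star$m_star,
                    subgroup = factor(sub, levels = c("benefit_ESC_CM",
                                                      "benefit_CBASP")),
                    stringsAsFactors = FALSE)
  if (length(unique(sub)) == 1)
    warning("all patients fall on one side of the cross-point",
            call. = FALSE)
  attr(out, "n_at_cross_point") <- sum(side == 0)
  out
}

#' Cohen's d from group summary statistics
#'
#' Standardized mean difference `(mean1 - mean2) / pooled SD` with a 95%
#' normal-approximation interval, `SE(d) = sqrt((n1 + n2)/(n1 n2) +
#' d^2 / (2 (n1 + n2)))`.
#'
#' @param n1,mean1,sd1 size, mean and SD of group 1.
#' @param n2,mean2,sd2 size, mean and SD of group 2.
#' @return list with `d`, `ci_low`, `ci_high`.
#' @export
cohens_d_from_summary <- function(n1, mean1, sd1, n2, mean2, sd2) {
  sp <- sqrt(((n1 - 1) * sd1^2 + (n2 - 1) * sd2^2) / (n1 + n2 - 2))
  d <- (mean1 - mean2) / sp
  se <- sqrt((n1 + n2) / (n1 * n2) + d^2 / (2 * (n1 + n2)))
  list(d = d, ci_low = d - 1.96 * se, ci_high = d + 1.96 * se)
}

#' Within-subgroup treatment effect sizes
#'
#' For each benefit subgroup, Cohen's d of the percent-change outcome
#' between arms, `(mean ESC/CM - mean CBASP) / pooled SD` (the same
#' subtraction order as the pair outcome difference), with its 95%
#' normal-approximation interval. A subgroup lacking two patients in each
#' arm yields NA and a warning.
#'
#' @param dataset a [trial_dataset()].
#' @param outcomes data.frame from [classify_outcomes()].
#' @param subgroups data.frame from [assign_subgroups()].
#' @return data.frame with one row per subgroup: `subgroup`, `n_esc`,
#'   `n_cbasp`, `d`, `ci_low`, `ci_high`.
#' @export
subgroup_cohens_d <- function(dataset, outcomes, subgroups) {
  df <- merge(subgroups, outcomes[, c("patient_id", "arm", "pct_change")],
              by = "patient_id")
  rows <- lapply(levels(df$subgroup), function(sg) {
    s <- df[df$subgroup == sg, , drop = FALSE]
    yE <- s$pct_change[s$arm == "ESC_CM"]
    yC <- s$pct_change[s$arm == "CBASP"]
    if (length(yE) < 2 || length(yC) < 2) {
      warning("subgroup '", sg, "' lacks >= 2 patients in each arm; ",
              "effect size undefined", call. = FALSE)
      return(data.frame(subgroup = sg, n_esc = length(yE),
                        n_cbasp = length(yC), d = NA_real_,
                        ci_low = NA_real_, ci_high = NA_real_))
    }
    cd <- cohens_d_from_summary(length(yE), mean(yE), stats::sd(yE),
                                length(yC), mean(yC), stats::sd(yC))
    data.frame(subgroup = sg, n_esc = length(yE), n_cbasp = length(yC),
               d = cd$d, ci_low = cd$ci_low, ci_high = cd$ci_high)
  })
  do.call(rbind, rows)
}
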