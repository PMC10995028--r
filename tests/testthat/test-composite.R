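make_signal_trial <- function(seed = 1, sigma = 2) {
  # two genuine moderators (age, trauma) planted symmetrically so the pair
  # outcome difference is linear in the pair averages; everything else noise
  cfg <- generator_config(delta = c(age = -1.2, trauma = 30),
                          gamma = c(age = 0.6, trauma = -15),
                          tau = 30, mu0 = -40, sigma = sigma,
                          latent_cor = 0)
  generate_trial(cfg, seed = seed)
}

test_that("a penalty at or above lambda_max zeroes every coefficient", {
  ds <- make_signal_trial(seed = 2)
  pairs <- build_pairs(ds)
  expect_error(
    fit_lasso_cv(pairs, c("age", "trauma", "female"), k = 5, seed = 1,
                 lambda = c(1e7, 1e6, 1e5)),
    "no moderator survives")
})

test_that("as the penalty vanishes the lasso approaches the OLS solution", {
  ds <- make_signal_trial(seed = 3, sigma = 1)
  pairs <- build_pairs(ds)
  vars <- c("age", "trauma", "female", "adverse_events")
  fit <- fit_lasso_cv(pairs, vars, k = 10, seed = 4,
                      lambda = c(1e-6, 1e-7))
  ols <- stats::lm(stats::reformulate(vars, "outcome_diff"), data = pairs)
  expect_equal(unname(fit$coefficients[vars]),
               unname(stats::coef(ols)[vars]), tolerance = 1e-4)
  expect_equal(fit$intercept, unname(stats::coef(ols)[1]), tolerance = 1e-4)
})

test_that("true moderators survive the lasso and noise is mostly zeroed", {
  hits_true <- 0; clean <- 0; n_seeds <- 9
  for (s in seq_len(n_seeds)) {
    ds <- make_signal_trial(seed = 100 + s, sigma = 0.1)
    pairs <- build_pairs(ds)
    vars <- c("age", "trauma", "female", "madrs_baseline", "axis1",
              "adverse_events", "prev_psychotherapies")
    fit <- fit_lasso_cv(pairs, vars, k = 10, seed = 200 + s)
    if (all(c("age", "trauma") %in% fit$nonzero)) hits_true <- hits_true + 1
    if (length(fit$nonzero) == 2) clean <- clean + 1
  }
  expect_gt(hits_true, n_seeds / 2)
  expect_gt(clean, n_seeds / 2)
})

test_that("a single selected variable is handled and MSPE curve is coherent", {
  ds <- make_signal_trial(seed = 5, sigma = 2)
  pairs <- build_pairs(ds)
  fit <- fit_lasso_cv(pairs, "age", k = 10, seed = 6)
  expect_equal(fit$nonzero, "age")
  opt <- fit$cv_mspe[which(fit$lambda == fit$lambda_opt)]
  expect_equal(opt, min(fit$cv_mspe))
  expect_equal(length(fit$lambda), length(fit$cv_mspe))
  # fewer records than folds is refused
  expect_error(fit_lasso_cv(pairs[1:5, ], "age", k = 10, seed = 1),
               "folds")
})

test_that("M* is the plain weighted sum and excludes incomplete patients", {
  ds <- random_trial(n_cbasp = 27, n_esc = 26, seed = 8)
  # identity: unit weight on age
  ms <- compute_m_star(ds, c(age = 1))
  expect_equal(ms$m_star, ds$patients$age)
  # published seven-variable weight set applied to a constructed patient:
  # 2.817*40 - 31.344*1 - 65.803*1 - 8.806*1 - 9.782*2 + 56.434*0 + 12.629*1
  w <- c(age = 2.817, female = -31.344, trauma = -65.803,
         suicide_attempts = -8.806, adverse_events = -9.782,
         early_onset = 56.434, prev_antidepressants = 12.629)
  one <- ds
  one$patients <- one$patients[1, ]
  one$patients[, names(w)] <- as.list(c(40, 1, 1, 1, 2, 0, 1))
  expect_equal(compute_m_star(one, w)$m_star, -0.208, tolerance = 1e-9)
  # 53 completers with 3 incomplete on a weighted variable -> 50 values
  ds$patients$trauma[c(4, 20, 40)] <- NA
  ms3 <- compute_m_star(ds, c(age = 1, trauma = -10))
  expect_equal(nrow(ms3), 50)
  expect_equal(length(attr(ms3, "excluded")), 3)
  expect_error(compute_m_star(ds, c(age = 0)), "nonzero")
})

test_that("interaction model recovers exact linear structure and matches normal equations", {
  # exact generating model: y = a + b m + c T + d mT, no noise
  a <- -10; b <- 0.5; c <- -25; d <- 1.5
  ds <- random_trial(n_cbasp = 5, n_esc = 5, seed = 14)
  m <- seq(-10, 35, length.out = 10)
  treat <- as.numeric(ds$patients$arm == "CBASP")
  out <- data.frame(patient_id = ds$patients$patient_id,
                    arm = ds$patients$arm,
                    pct_change = a + b * m + c * treat + d * m * treat)
  ms <- data.frame(patient_id = ds$patients$patient_id, m_star = m)
  fit <- suppressWarnings(fit_interaction_model(ds, out, ms))
  expect_equal(fit$beta_intercept, a, tolerance = 1e-9)
  expect_equal(fit$beta_mstar, b, tolerance = 1e-9)
  expect_equal(fit$beta_treatment, c, tolerance = 1e-9)
  expect_equal(fit$beta_interaction, d, tolerance = 1e-9)
  expect_equal(fit$r_squared, 1, tolerance = 1e-9)
  # independent normal-equations oracle on a noisy 6-patient toy
  ds6 <- random_trial(n_cbasp = 3, n_esc = 3, seed = 15)
  m6 <- c(2, 5, 1, 8, 3, 9)
  t6 <- as.numeric(ds6$patients$arm == "CBASP")
  y6 <- c(-30, -10, -45, 12, -20, 3)
  out6 <- data.frame(patient_id = ds6$patients$patient_id,
                     arm = ds6$patients$arm, pct_change = y6)
  fit6 <- fit_interaction_model(ds6, out6,
                                data.frame(patient_id = ds6$patients$patient_id,
                                           m_star = m6))
  beta <- oracle_ols(cbind(1, m6, t6, m6 * t6), y6)
  expect_equal(c(fit6$beta_intercept, fit6$beta_mstar, fit6$beta_treatment,
                 fit6$beta_interaction), unname(beta), tolerance = 1e-9)
})

test_that("without a planted interaction the fitted interaction is null on average", {
  ts <- vapply(1:8, function(s) {
    cfg <- generator_config(gamma = c(age = 0.5), mu0 = -40, sigma = 15,
                            latent_cor = 0)
    ds <- generate_trial(cfg, seed = 400 + s)
    out <- classify_outcomes(ds)
    ms <- compute_m_star(ds, c(age = 1))
    fit <- fit_interaction_model(ds, out, ms)
    fit$beta_interaction / fit$se_interaction
  }, numeric(1))
  expect_lt(mean(abs(ts)), 2)
})

test_that("cross-point arithmetic and self-consistency", {
  expect_equal(find_cross_point(fake_interaction_fit(0, 2)), 0)
  expect_equal(find_cross_point(fake_interaction_fit(-10, 0.5)), 20)
  expect_error(find_cross_point(fake_interaction_fit(5, 1e-12)),
               "near-parallel")
  set.seed(31)
  for (i in 1:20) {
    fit <- fake_interaction_fit(runif(1, -50, 50), runif(1, -3, 3),
                                runif(1, -30, 10), runif(1, -2, 2))
    cp <- find_cross_point(fit)
    pred <- predict_arms(fit, cp)
    expect_lt(abs(pred$pred_cbasp - pred$pred_esc), 1e-9)
  }
})

test_that("subgroup labels always point to the arm with the better prediction", {
  set.seed(32)
  for (i in 1:20) {
    fit <- fake_interaction_fit(runif(1, -50, 50), runif(1, -3, 3),
                                runif(1, -30, 10), runif(1, -2, 2))
    cp <- find_cross_point(fit)
    ms <- data.frame(patient_id = sprintf("p%02d", 1:15),
                     m_star = c(runif(14, cp - 30, cp + 30), cp))
    sub <- suppressWarnings(
      assign_subgroups(ms, cp, fit$beta_interaction))
    pred <- predict_arms(fit, ms$m_star)
    want <- ifelse(pred$pred_esc <= pred$pred_cbasp,
                   "benefit_ESC_CM", "benefit_CBASP")
    # the planted tie point is compared separately: float rounding makes
    # the two predictions differ by ~1e-15 there in either direction
    expect_equal(as.character(sub$subgroup[1:14]), want[1:14])
    expect_equal(as.character(sub$subgroup[15]), "benefit_ESC_CM")
    expect_gte(attr(sub, "n_at_cross_point"), 1)
  }
  # single-sided split warns
  ms1 <- data.frame(patient_id = c("a", "b"), m_star = c(5, 6))
  expect_warning(assign_subgroups(ms1, 0, 1), "one side")
})

test_that("M* is equivariant under positive rescaling of the weights", {
  ds <- make_signal_trial(seed = 16, sigma = 5)
  out <- classify_outcomes(ds)
  w <- c(age = -1.1, trauma = 28)
  run <- function(wts) {
    ms <- compute_m_star(ds, wts)
    fit <- fit_interaction_model(ds, out, ms)
    cp <- find_cross_point(fit)
    list(ms = ms, cp = cp,
         sub = assign_subgroups(ms, cp, fit$beta_interaction))
  }
  base <- run(w)
  scaled <- run(3 * w)
  expect_equal(scaled$ms$m_star, 3 * base$ms$m_star)
  expect_equal(scaled$cp, 3 * base$cp)
  expect_identical(scaled$sub$subgroup, base$sub$subgroup)
})

test_that("composite effect size reduces to the single-variable case and is seeded", {
  ds <- make_signal_trial(seed = 17, sigma = 10)
  out <- classify_outcomes(ds)
  pairs <- build_pairs(ds, out)
  single <- moderator_effect_size(pairs, "age")
  comp <- composite_effect_size(ds, out, compute_m_star(ds, c(age = 1)),
                                n_reps = 30, seed = 3)
  expect_equal(comp$rho, single$rho, tolerance = 1e-12)
  comp2 <- composite_effect_size(ds, out, compute_m_star(ds, c(age = 1)),
                                 n_reps = 30, seed = 3)
  expect_equal(comp[c("rho", "ci_low", "ci_high")],
               comp2[c("rho", "ci_low", "ci_high")])
})

test_that("within-subgroup Cohen's d matches hand-worked pooled-SD values", {
  r <- cohens_d_from_summary(10, -50, 25, 10, 0, 25)
  expect_equal(r$d, -2)
  # 4 + 4 toy, fully hand-computed: pooled SD = sqrt(1300/3)
  ds <- random_trial(n_cbasp = 4, n_esc = 4, seed = 18)
  out <- data.frame(patient_id = ds$patients$patient_id,
                    arm = ds$patients$arm,
                    pct_change = NA_real_)
  out$pct_change[out$arm == "ESC_CM"] <- c(-60, -40, -30, -10)
  out$pct_change[out$arm == "CBASP"] <- c(-20, 0, 10, 30)
  sub <- data.frame(patient_id = ds$patients$patient_id,
                    m_star = 0,
                    subgroup = factor(rep("benefit_ESC_CM", 8),
                                      levels = c("benefit_ESC_CM",
                                                 "benefit_CBASP")))
  res <- suppressWarnings(subgroup_cohens_d(ds, out, sub))
  row <- res[res$subgroup == "benefit_ESC_CM", ]
  expect_equal(row$d, -40 / sqrt(1300 / 3), tolerance = 1e-12)
  se <- sqrt(8 / 16 + row$d^2 / 16)
  expect_equal(row$ci_low, row$d - 1.96 * se, tolerance = 1e-12)
  # identical arm distributions give d = 0
  out0 <- out
  out0$pct_change[out0$arm == "ESC_CM"] <- c(-30, -10, 0, 20)
  out0$pct_change[out0$arm == "CBASP"] <- c(-30, -10, 0, 20)
  res0 <- suppressWarnings(subgroup_cohens_d(ds, out0, sub))
  expect_equal(res0$d[res0$subgroup == "benefit_ESC_CM"], 0)
})
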