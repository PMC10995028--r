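# builders and independent oracles shared across tests

# minimal trial with a single metric variable and hand-chosen outcomes:
# percent changes are CBASP: -50, -10 and ESC/CM: -40, 0
toy_trial_2x2 <- function() {
  trial_dataset(
    data.frame(
      patient_id = c("C1", "C2", "E1", "E2"),
      arm = c("CBASP", "CBASP", "ESC_CM", "ESC_CM"),
      madrs_baseline = c(30, 30, 30, 30),
      madrs_week8 = c(15, 27, 18, 30),
      age = c(30, 50, 40, 20),
      stringsAsFactors = FALSE
    ),
    variables = data.frame(name = "age", kind = "metric",
                           description = "age", stringsAsFactors = FALSE)
  )
}

# random small trial over the full variable panel
random_trial <- function(n_cbasp = 10, n_esc = 10, seed = 1, sigma = 20,
                         delta = NULL, gamma = NULL, tau = 0) {
  cfg <- generator_config(n_cbasp = n_cbasp, n_esc = n_esc, sigma = sigma,
                          delta = delta, gamma = gamma, tau = tau,
                          latent_cor = 0)
  generate_trial(cfg, seed = seed)
}

# Spearman via explicit average ranks and the Pearson product-moment sums,
# independent of stats::cor(method = "spearman")
oracle_spearman <- function(x, y) {
  rx <- rank(x, ties.method = "average")
  ry <- rank(y, ties.method = "average")
  sum((rx - mean(rx)) * (ry - mean(ry))) /
    sqrt(sum((rx - mean(rx))^2) * sum((ry - mean(ry))^2))
}

# least squares by explicit normal equations
oracle_ols <- function(X, y) drop(solve(t(X) %*% X, t(X) %*% y))

# two-sided Fisher exact p by exhaustive hypergeometric enumeration
# (point-probability method): sum of P(k) over all tables with
# P(k) <= P(observed), margins fixed
oracle_fisher_p <- function(x1, n1, x2, n2) {
  m <- x1 + x2
  ks <- max(0, m - n2):min(m, n1)
  pk <- stats::dhyper(ks, n1, n2, m)
  p_obs <- stats::dhyper(x1, n1, n2, m)
  sum(pk[pk <= p_obs * (1 + 1e-7)])
}

# direct bootstrap-distribution oracle: many replications of the
# resample-within-arm / re-pair / Spearman scheme, coded independently
oracle_bootstrap_rhos <- function(dataset, outcomes, variable, n_reps,
                                  seed) {
  p <- dataset$patients
  y <- outcomes$pct_change[match(p$patient_id, outcomes$patient_id)]
  iC <- which(p$arm == "CBASP")
  iE <- which(p$arm == "ESC_CM")
  set.seed(seed)
  replicate(n_reps, {
    bC <- sample(iC, replace = TRUE)
    bE <- sample(iE, replace = TRUE)
    avg <- outer(p[[variable]][bC], p[[variable]][bE], "+") / 2
    d <- outer(y[bC], y[bE], function(a, b) b - a)
    oracle_spearman(as.vector(avg), as.vector(d))
  })
}

# interaction_fit object with chosen coefficients, for cross-point tests
fake_interaction_fit <- function(beta_treatment, beta_interaction,
                                 beta_intercept = 0, beta_mstar = 0,
                                 outcome_sd = 1) {
  structure(list(beta_intercept = beta_intercept, beta_mstar = beta_mstar,
                 beta_treatment = beta_treatment,
                 beta_interaction = beta_interaction,
                 se_interaction = NA_real_, r_squared = NA_real_,
                 outcome_sd = outcome_sd, n = NA_integer_),
            class = "interaction_fit")
}
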