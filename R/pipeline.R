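#' Configuration for the end-to-end pipeline
#'
#' Defaults equal the analysis settings of the 8-week CBASP versus ESC/CM
#' moderator analysis: effect-size threshold |rho| >= 0.20, missing-data
#' rule (>= 50 valid or <= 3 missing), 100 bootstrap replications, 10 CV
#' folds. Three independent seeds control the three stochastic stages
#' (generation, bootstrap, fold assignment) so each can be varied alone.
#'
#' @param input either a path to a trial CSV or a [generator_config()].
#' @param mapping,arm_labels passed to [read_trial()] for CSV input.
#' @param threshold,min_valid,max_missing preselection rules.
#' @param n_boot bootstrap replications for confidence intervals.
#' @param k_folds cross-validation folds.
#' @param seed_generator,seed_boot,seed_folds stage seeds.
#' @param grouped_folds use patient-grouped CV folds (see
#'   [fit_lasso_cv()]).
#' @param one_se use the 1-SE lambda rule instead of the MSPE minimum.
#' @param output_dir directory for the report bundle; NULL suppresses all
#'   file output.
#' @return An object of class `pipeline_config`.
#' @export
pipeline_config <- function(input, mapping = NULL,
                            arm_labels = c(CBASP = "CBASP",
                                           ESC_CM = "ESC_CM"),
                            threshold = 0.20, min_valid = 50,
                            max_missing = 3, n_boot = 100, k_folds = 10,
                            seed_generator = 1L, seed_boot = 2L,
                            seed_folds = 3L, grouped_folds = FALSE,
                            one_se = FALSE, output_dir = NULL) {
  structure(as.list(environment()), class = "pipeline_config")
}

# internal: run one stage, prefixing errors with the stage name
run_stage <- function(name, expr) {
  tryCatch(expr, error = function(e)
    stop("stage '", name, "': ", conditionMessage(e), call. = FALSE))
}

#' Run the composite-moderator pipeline end to end
#'
#' Loads or generates the trial, restricts to completers, classifies
#' outcomes, screens for outliers, computes the per-variable moderator
#' effect sizes with bootstrap intervals, preselects variables, fits the
#' lasso with k-fold cross-validation on the paired dataset, compiles M*,
#' fits the treatment-by-M* interaction, locates the cross-point, assigns
#' benefit subgroups, and evaluates the four subgroup-by-treatment
#' clusters, the matched/mismatched pools, the subgroup baseline
#' comparison and the augmentation sub-analysis.
#'
#' When `output_dir` is set, writes `effects.csv`,
#' `subgroup_comparison.csv`, `cluster_outcomes.csv`, `model_report.json`
#' and `log.txt`. Identical configuration and seeds produce byte-identical
#' reports. Patient counts are reconciled in the log at every filtering
#' step. Stage errors propagate with the stage name; a null trial with no
#' moderator passing preselection (or none surviving the lasso) stops with
#' a "no moderator survives" message.
#'
#' @param config a [pipeline_config()].
#' @return Invisibly, a list bundle with every intermediate and final
#'   result (dataset, outcomes, effects, lasso fit, m_star, interaction
#'   fit, cross_point, subgroups, clusters, cluster summaries, baseline
#'   comparison, Cohen's d table, augmentation summary, log lines).
#' @export
run_pipeline <- function(config) {
  stopifnot(inherits(config, "pipeline_config"))
  log <- character()
  say <- function(...) log <<- c(log, paste0(...))

  dataset <- run_stage("load", {
    if (inherits(config$input, "generator_config")) {
      say("generated synthetic trial (seed ", config$seed_generator, ")")
      generate_trial(config$input, seed = config$seed_generator)
    } else {
      say("read trial from ", config$input)
      read_trial(config$input, mapping = config$mapping,
                 arm_labels = config$arm_labels)
    }
  })
  n_in <- nrow(dataset$patients)
  completers <- run_stage("completers", filter_completers(dataset))
  n_dropped <- attr(completers, "n_dropped")
  tab <- table(completers$patients$arm)
  say("patients: ", n_in, " = ", nrow(completers$patients),
      " completers + ", n_dropped, " dropped (no week-8 score)")
  say("arms among completers: CBASP = ", tab[["CBASP"]],
      ", ESC_CM = ", tab[["ESC_CM"]])

  outcomes <- run_stage("outcomes", classify_outcomes(completers))
  screen <- run_stage("outlier_screen", screen_outliers(completers, outcomes))
  say("outlier screen: ", sum(screen$n_outliers), " value(s) with |z| > 3")

  effects <- run_stage("effect_sizes",
    moderator_effects(completers, outcomes, n_reps = config$n_boot,
                      seed = config$seed_boot, threshold = config$threshold,
                      min_valid = config$min_valid,
                      max_missing = config$max_missing))
  selected <- effects$variable[effects$selected]
  say("preselected ", length(selected), " of ", nrow(effects),
      " variables at |rho| >= ", config$threshold, ": ",
      paste(selected, collapse = ", "))
  if (!length(selected))
    run_stage("preselection",
              stop("no moderator survives: no variable passes preselection",
                   call. = FALSE))

  pairs <- run_stage("pairs", build_pairs(completers, outcomes))
  say("paired dataset: ", nrow(pairs), " cross-arm pairs")
  lasso <- run_stage("lasso_cv",
    fit_lasso_cv(pairs, selected, k = config$k_folds,
                 seed = config$seed_folds, one_se = config$one_se,
                 grouped = config$grouped_folds))
  say("lasso-CV: lambda_opt = ", signif(lasso$lambda_opt, 6), ", ",
      length(lasso$nonzero), " moderator(s) survive: ",
      paste(lasso$nonzero, collapse = ", "))

  m_star <- run_stage("m_star", compute_m_star(completers,
                                               lasso$coefficients))
  say("M* calculable for ", nrow(m_star), " patients; ",
      length(attr(m_star, "excluded")), " excluded for missing data")
  interaction <- run_stage("interaction",
    fit_interaction_model(completers, outcomes, m_star))
  comp_es <- run_stage("composite_effect_size",
    composite_effect_size(completers, outcomes, m_star,
                          n_reps = config$n_boot, seed = config$seed_boot))
  say(sprintf("composite effect size rho = %.3f (95%% CI %.3f; %.3f)",
              comp_es$rho, comp_es$ci_low, comp_es$ci_high))
  cross_point <- run_stage("cross_point", find_cross_point(interaction))
  subgroups <- run_stage("subgroups",
    assign_subgroups(m_star, cross_point, interaction$beta_interaction))
  say(sprintf("cross-point at M* = %.4f; subgroups: benefit_ESC_CM = %d, benefit_CBASP = %d",
              cross_point, sum(subgroups$subgroup == "benefit_ESC_CM"),
              sum(subgroups$subgroup == "benefit_CBASP")))

  clusters <- run_stage("clusters", stratify_clusters(subgroups, outcomes))
  summaries <- run_stage("cluster_outcomes",
    cluster_outcomes(completers, outcomes, clusters))
  comparison <- run_stage("baseline_comparison",
    compare_subgroup_baselines(completers, subgroups))
  cohens <- run_stage("cohens_d",
    subgroup_cohens_d(completers, outcomes, subgroups))
  augmentation <- run_stage("augmentation",
    augmentation_analysis(outcomes, clusters))
  say("matched n = ", sum(clusters$matched), ", mismatched n = ",
      sum(!clusters$matched), "; M* patients total = ", nrow(clusters))
  say("augmentation candidates (< 20% reduction): ",
      augmentation$n_candidates, " (", augmentation$n_mismatched,
      " mismatched)")

  bundle <- list(dataset = completers, outcomes = outcomes,
                 outlier_screen = screen, effects = effects,
                 selected = selected, pairs_n = nrow(pairs), lasso = lasso,
                 m_star = m_star, interaction = interaction,
                 composite_effect = comp_es, cross_point = cross_point,
                 subgroups = subgroups, clusters = clusters,
                 cluster_summaries = summaries, comparison = comparison,
                 cohens_d = cohens, augmentation = augmentation, log = log)

  if (!is.null(config$output_dir))
    run_stage("report", write_report_bundle(bundle, config))
  invisible(bundle)
}

# internal: write the report files of a pipeline bundle
write_report_bundle <- function(bundle, config) {
  dir.create(config$output_dir, showWarnings = FALSE, recursive = TRUE)
  path <- function(f) file.path(config$output_dir, f)
  utils::write.csv(bundle$effects, path("effects.csv"), row.names = FALSE)
  utils::write.csv(bundle$comparison, path("subgroup_comparison.csv"),
                   row.names = FALSE)
  utils::write.csv(bundle$cluster_summaries, path("cluster_outcomes.csv"),
                   row.names = FALSE)
  report <- list(
    seeds = list(generator = config$seed_generator,
                 bootstrap = config$seed_boot, folds = config$seed_folds),
    n_completers = nrow(bundle$dataset$patients),
    n_pairs = bundle$pairs_n,
    selected_variables = bundle$selected,
    lambda_opt = bundle$lasso$lambda_opt,
    mspe_curve = data.frame(lambda = bundle$lasso$lambda,
                            mspe = bundle$lasso$cv_mspe),
    weights = as.list(bundle$lasso$coefficients[bundle$lasso$nonzero]),
    interaction = bundle$interaction[c("beta_intercept", "beta_mstar",
                                       "beta_treatment", "beta_interaction",
                                       "se_interaction", "r_squared")],
    composite_effect_size = bundle$composite_effect[c("rho", "ci_low",
                                                      "ci_high")],
    cross_point = bundle$cross_point,
    subgroup_sizes = as.list(table(bundle$subgroups$subgroup)),
    cohens_d = bundle$cohens_d,
    augmentation = bundle$augmentation[c("n_candidates", "n_mismatched",
                                         "n_matched", "share_mismatched")]
  )
  jsonlite::write_json(report, path("model_report.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  writeLines(bundle$log, path("log.txt"))
  invisible(config$output_dir)
}
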