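# modstar

Composite-moderator subgroup identification for two-arm randomized
trials, built around an 8-week comparison of psychotherapy (CBASP) versus
escitalopram plus clinical management (ESC/CM) in persistent depressive
disorder. The package is for biostatisticians and trialists who want to
ask *"which patients benefit more from which arm?"* when the average
treatment contrast is flat.

## The method

The outcome is the percent change in the MADRS depression score from
baseline to week 8 (negative = improvement). The workflow:

1. **Pairwise moderator effect sizes.** Every CBASP patient is paired
   with every ESC/CM patient. For each baseline variable, the moderator
   effect size is the Spearman correlation between the pair outcome
   difference `y_ESC − y_CBASP` and the pair average of the variable;
   negative values mean higher values/presence favor ESC/CM, positive
   favor CBASP. 95% intervals come from a 100-replication bootstrap that
   resamples patients within arms and re-pairs.
2. **Composite moderator M\*.** Variables with |ρ| ≥ 0.20 (and ≥ 50
   valid or ≤ 3 missing cases) enter a lasso regression of the pair
   outcome difference on the pair averages, with λ chosen by 10-fold
   cross-validation (smallest mean-squared prediction error). The
   surviving weights define `M* = Σ w_k x_k` per patient.
3. **Cross-point subgrouping.** OLS of the outcome on
   `{1, M*, T, M*·T}` (T = 1 for CBASP) locates the cross-point
   `−β_T / β_int` where the arms' predicted outcomes intersect; patients
   on either side form the `benefit_ESC_CM` and `benefit_CBASP`
   subgroups.
4. **Evaluation.** Subgroup × randomized-arm clusters, matched vs
   mismatched pools (exact summary-statistic pooling), subgroup baseline
   comparisons (pooled-variance t / Fisher exact with Wald intervals),
   within-subgroup Cohen's d, and the augmentation sub-analysis (how
   many <20%-improvers had been mismatched).

A synthetic trial generator reproduces the statistical shape of the
completer sample (arm sizes 27/26, realistic marginals, a latent factor
coupling the trauma-related variables, configurable treatment ×
moderator interactions), so the entire pipeline is testable without
patient-level data. See the methods vignette
(`vignettes/composite-moderator-method.Rmd`) for the model, conventions
and design choices.

## Worked example

```r
library(modstar)
cfg <- read_generator_config(system.file("extdata", "demo_config.yaml",
                                         package = "modstar"))
bundle <- run_pipeline(pipeline_config(input = cfg, seed_generator = 7))
cat(bundle$log, sep = "\n")
```

```
generated synthetic trial (seed 7)
patients: 53 = 53 completers + 0 dropped (no week-8 score)
arms among completers: CBASP = 27, ESC_CM = 26
outlier screen: 0 value(s) with |z| > 3
preselected 6 of 11 variables at |rho| >= 0.2: female, age, suicide_attempts, axis1, trauma, adverse_events
paired dataset: 702 cross-arm pairs
lasso-CV: lambda_opt = 0.0528182, 6 moderator(s) survive: female, age, suicide_attempts, axis1, trauma, adverse_events
M* calculable for 53 patients; 0 excluded for missing data
composite effect size rho = 0.654 (95% CI 0.466; 0.795)
cross-point at M* = 19.0847; subgroups: benefit_ESC_CM = 31, benefit_CBASP = 22
matched n = 24, mismatched n = 29; M* patients total = 53
augmentation candidates (< 20% reduction): 28 (23 mismatched)
```

The demo config plants a qualitative interaction (trauma, female gender
and suicide attempts favoring ESC/CM; older age favoring CBASP), and the
pipeline recovers it: the six preselected effect sizes run from −0.49
(female) to +0.29 (age), the composite moderator correlates at 0.654
with the pair outcome differences — larger than any single variable —
and the interaction regression gives β = −1.004 (SE 0.157, R² = 0.476).
Matched patients improved by 28.8% on average while mismatched patients
improved by only 9.1%, and 23 of the 28 augmentation candidates (82%)
had been mismatched. Within-subgroup treatment effects are large in
opposite directions (Cohen's d −1.45 in the ESC/CM-benefit subgroup,
+1.35 in the CBASP-benefit subgroup). Because the trial is small
(n = 53), the selected moderator list varies across generator seeds —
the instability the vignette discusses.

`run_pipeline()` with an `output_dir` additionally writes `effects.csv`,
`subgroup_comparison.csv`, `cluster_outcomes.csv`, `model_report.json`
and a `log.txt` whose counts reconcile every filtering step;
`plot_predicted_outcomes()` draws the two arms' predicted outcomes
across M* with the cross-point.

Analyzing your own trial: `read_trial("trial.csv", mapping = ...,
arm_labels = ...)` reads a one-row-per-patient CSV (see
`?baseline_variables` for the expected variables), and
`pipeline_config(input = "trial.csv", ...)` runs the same pipeline on
it.

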