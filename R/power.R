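#' Simulation-based power for the gene-environment interaction test
#'
#' Estimates the rejection probability of the multiplicative-interaction test
#' by repeated simulation: each replicate generates an application record and
#' a cohort under the configuration, assesses exposure, fits the interaction
#' model, and tests the product term at level `alpha`. The estimate is the
#' fraction of replicates with interaction p below `alpha`, with an exact
#' (Clopper-Pearson) binomial confidence interval. Replicates failing with
#' separation or inestimable cells are counted separately; more than 20%
#' failures raises an unstable-design error.
#'
#' @param config a [sim_config()]; its `beta["bge"]` is the effect under
#'   which power is estimated (0 gives the type-I error rate).
#' @param alpha significance level.
#' @param n_replicates number of simulated cohorts (>= 100 for production
#'   estimates; smaller values are permitted for smoke tests).
#' @param model genetic model passed to [gxe_analysis()].
#' @param chemical_class class analysed; defaults to the focal class.
#' @param use_true_exposure fit against the generator's recorded true
#'   exposure instead of running the observed exposure-assessment pipeline
#'   (faster; isolates the estimation machinery from exposure
#'   misclassification).
#' @param exposure_cfg an [exposure_config()] for the observed pipeline.
#' @param seed master seed; defaults to `config$seed`.
#' @return A list of class `power_result`: `power`, `ci_low`, `ci_high`,
#'   `n_evaluated`, `n_failed`, `alpha`, `p_values`.
#' @export
estimate_power <- function(config, alpha = 0.05, n_replicates = 200L,
                           model = c("additive", "homozygote_contrast"),
                           chemical_class = NULL, use_true_exposure = FALSE,
                           exposure_cfg = exposure_config(), seed = NULL) {
  model <- match.arg(model)
  if (alpha <= 0 || alpha >= 1) stop(config_error("alpha must lie in (0, 1)"))
  if (n_replicates < 1L) stop(config_error("n_replicates must be positive"))
  if (is.null(chemical_class)) chemical_class <- config$focal_class
  if (is.null(seed)) seed <- config$seed

  pvals <- rep(NA_real_, n_replicates)
  n_failed <- 0L
  for (i in seq_len(n_replicates)) {
    rep_seed <- stage_seed(seed, paste0("power_rep_", i))
    res <- tryCatch({
      p <- replicate_interaction_p(config, model, chemical_class,
                                   use_true_exposure, exposure_cfg, rep_seed)
      p
    }, ambientgxe_model_error = function(e) NA_real_)
    if (is.na(res)) n_failed <- n_failed + 1L else pvals[i] <- res
  }
  n_eval <- n_replicates - n_failed
  if (n_failed > 0.2 * n_replicates)
    stop(model_error(sprintf(
      "unstable design: %d of %d replicates failed (separation/inestimable)",
      n_failed, n_replicates), subclass = "ambientgxe_unstable_design"))
  hits <- sum(pvals < alpha, na.rm = TRUE)
  bt <- binom.test(hits, n_eval)
  structure(list(power = hits / n_eval,
                 ci_low = bt$conf.int[1], ci_high = bt$conf.int[2],
                 n_evaluated = n_eval, n_failed = n_failed, alpha = alpha,
                 model = model, chemical_class = chemical_class,
                 p_values = pvals),
            class = "power_result")
}

# One simulation replicate: generate, assess exposure, fit, return the Wald
# interaction p-value.
replicate_interaction_p <- function(config, model, chemical_class,
                                    use_true_exposure, exposure_cfg, rep_seed) {
  apps <- generate_applications(config, seed = stage_seed(rep_seed, "applications"))
  cohort <- generate_cohort(config, apps, seed = rep_seed)
  if (use_true_exposure) {
    ce <- true_exposure_table(cohort, chemical_class)
  } else {
    prof <- compute_exposure_profiles(apps, cohort$addresses, cohort$subjects,
                                      exposure_cfg)
    keep <- !cohort$subjects$subject_id %in% prof$excluded$subject_id
    ce <- compute_class_exposure(prof$profiles, cohort$subjects[keep, ],
                                 unique(apps[, c("pesticide_id", "chemical_class")]),
                                 exposure_cfg)$class_exposure
  }
  gxe_analysis(cohort$subjects, ce, chemical_class, model)$interaction_p_wald
}

#' Class-exposure table from the generator's recorded true exposure
#'
#' @param cohort a [generate_cohort()] result.
#' @param chemical_class label for the exposure column (the generator's focal
#'   class).
#' @return A table compatible with [gxe_analysis()].
#' @export
true_exposure_table <- function(cohort, chemical_class = NULL) {
  if (is.null(chemical_class)) chemical_class <- cohort$config$focal_class
  data.table::data.table(
    subject_id = cohort$subjects$subject_id,
    chemical_class = chemical_class,
    n_pesticides_exposed = NA_integer_,
    category = ifelse(cohort$subjects$true_exposed == 1L, "any", "none"),
    exposed = cohort$subjects$true_exposed)
}

#' @export
print.power_result <- function(x, ...) {
  cat(sprintf("Interaction-test power (%s, %s): %.3f (95%% CI %.3f, %.3f)\n",
              x$chemical_class, x$model, x$power, x$ci_low, x$ci_high))
  cat(sprintf("  alpha = %g, %d replicates evaluated, %d failed\n",
              x$alpha, x$n_evaluated, x$n_failed))
  invisible(x)
}
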