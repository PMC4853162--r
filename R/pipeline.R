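#' Run the full synthetic study end to end
#'
#' Executes simulate, exposure assessment, genotype summaries, demographic
#' comparisons, and the association stage (all chemical classes crossed with
#' the additive and homozygote-contrast genetic models), and assembles a run
#' manifest with the configuration hash, seed, per-stage row counts and
#' every exclusion with its reason. All randomness flows from the single
#' master seed recorded in the manifest, so a rerun with the same
#' configuration reproduces every table bit for bit.
#'
#' @param config a [sim_config()].
#' @param exposure_cfg an [exposure_config()].
#' @param out_dir optional directory; when given, all tables are written as
#'   CSV and the manifest as YAML.
#' @return A list of class `pipeline_result`: `applications`, `cohort`,
#'   `exposure` (profiles/coverage/excluded), `class_exposure`, `genetics`,
#'   `demographics`, `marginal`, `gxe` (per class x model: a `gxe_table` or
#'   an error record), and `manifest`.
#' @export
run_pipeline <- function(config, exposure_cfg = exposure_config(),
                         out_dir = NULL) {
  validate_sim_config(config)

  stage <- function(name, expr) {
    tryCatch(expr, error = function(e) {
      stop(model_error(sprintf("pipeline stage '%s' failed: %s", name,
                               conditionMessage(e))))
    })
  }

  applications <- stage("simulate", generate_applications(config))
  cohort <- stage("simulate", generate_cohort(config, applications))
  subjects <- cohort$subjects

  expo <- stage("exposure",
                compute_exposure_profiles(applications, cohort$addresses,
                                          subjects, exposure_cfg))
  analysed <- subjects[!subjects$subject_id %in% expo$excluded$subject_id, ]
  classes <- intersect(CHEMICAL_CLASSES, names(config$classes))
  ce <- stage("exposure",
              compute_class_exposure(expo$profiles, analysed,
                                     unique(applications[, c("pesticide_id",
                                                             "chemical_class")]),
                                     exposure_cfg, all_classes = classes))

  genetics <- stage("genetics", genetics_summary(analysed))
  demographics <- list(
    age = demographics_compare(analysed, "age_years"),
    sex = demographics_compare(analysed, "sex"),
    smoking = demographics_compare(analysed, "smoker_ever"))

  marginal <- stage("association", marginal_genotype_analysis(analysed))

  gxe <- list()
  for (cl in classes) {
    for (mod in c("additive", "homozygote_contrast")) {
      key <- paste(cl, mod, sep = ".")
      gxe[[key]] <- tryCatch(
        gxe_analysis(analysed, ce$class_exposure, cl, mod),
        ambientgxe_model_error = function(e)
          list(error = conditionMessage(e), chemical_class = cl, model = mod))
    }
  }

  exclusions <- data.table::as.data.table(expo$excluded)
  manifest <- list(
    config_hash = config_hash(config),
    seed = config$seed,
    package_version = as.character(utils::packageVersion("ambientgxe")),
    counts = list(
      applications = nrow(applications),
      subjects_in = nrow(subjects),
      subjects_analysed = nrow(analysed),
      subjects_excluded = nrow(exclusions),
      exposure_profile_rows = nrow(expo$profiles)),
    exclusions = if (nrow(exclusions)) as.list(table(exclusions$reason)) else list(),
    undefined_exposure_classes = ce$undefined_classes,
    gxe_errors = names(Filter(function(g) !is.null(g$error), gxe)))

  result <- structure(list(applications = applications, cohort = cohort,
                           exposure = expo, class_exposure = ce,
                           genetics = genetics, demographics = demographics,
                           marginal = marginal, gxe = gxe, manifest = manifest),
                      class = "pipeline_result")
  if (!is.null(out_dir)) write_pipeline_outputs(result, out_dir)
  result
}

write_pipeline_outputs <- function(result, out_dir) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  write_cohort_csvs(result$cohort, result$applications, out_dir)
  data.table::fwrite(result$exposure$profiles,
                     file.path(out_dir, "exposure_profiles.csv"))
  data.table::fwrite(result$class_exposure$class_exposure,
                     file.path(out_dir, "class_exposure.csv"))
  data.table::fwrite(result$class_exposure$thresholds,
                     file.path(out_dir, "thresholds.csv"))
  gs <- result$genetics
  data.table::fwrite(data.table::data.table(
    group = c("cases", "controls"),
    n_AA = c(gs$cases$n_AA, gs$controls$n_AA),
    n_AG = c(gs$cases$n_AG, gs$controls$n_AG),
    n_GG = c(gs$cases$n_GG, gs$controls$n_GG),
    allele_freq = c(gs$allele_freq_cases, gs$allele_freq_controls),
    hwe_chisq_p = c(NA, gs$hwe_controls_chisq$p),
    hwe_exact_p = c(NA, gs$hwe_controls_exact$p)),
    file.path(out_dir, "genetics_summary.csv"))
  data.table::fwrite(as.data.frame(result$marginal),
                     file.path(out_dir, "table1.csv"))
  for (key in names(result$gxe)) {
    g <- result$gxe[[key]]
    if (!is.null(g$error)) next
    tab <- g$cells
    tab$interaction_p_wald <- g$interaction_p_wald
    tab$interaction_p_lrt <- g$interaction_p_lrt
    data.table::fwrite(tab, file.path(out_dir, paste0("table2_", key, ".csv")))
  }
  yaml::write_yaml(result$manifest, file.path(out_dir, "manifest.yaml"))
  invisible(out_dir)
}

#' @export
print.pipeline_result <- function(x, ...) {
  m <- x$manifest
  cat("Pipeline run", m$config_hash, "(seed", m$seed, ")\n")
  cat(sprintf("  %d applications; %d subjects in, %d analysed, %d excluded\n",
              m$counts$applications, m$counts$subjects_in,
              m$counts$subjects_analysed, m$counts$subjects_excluded))
  cat(sprintf("  controls HWE: chi-square p = %.3f, exact p = %.3f\n",
              x$genetics$hwe_controls_chisq$p, x$genetics$hwe_controls_exact$p))
  for (key in names(x$gxe)) {
    g <- x$gxe[[key]]
    if (!is.null(g$error)) {
      cat(sprintf("  %s: inestimable (%s)\n", key, g$error))
    } else {
      cat(sprintf("  %s: interaction p (Wald) = %.4g, (LRT) = %.4g\n",
                  key, g$interaction_p_wald, g$interaction_p_lrt))
    }
  }
  invisible(x)
}
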