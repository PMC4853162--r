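#' @keywords internal
# Build the adjustment columns (age continuous, sex and ever-smoking as
# indicators) from a subject table; returns a matrix, possibly with 0 columns.
covariate_matrix <- function(subjects, covariates) {
  cols <- list()
  if ("age" %in% covariates) cols$age <- subjects$age_years
  if ("sex" %in% covariates) cols$sex_male <- as.numeric(subjects$sex == "male")
  if ("smoking" %in% covariates) cols$smoker <- as.numeric(subjects$smoker_ever)
  if (!length(cols)) return(matrix(numeric(0), nrow = nrow(subjects), ncol = 0))
  do.call(cbind, cols)
}

complete_rows <- function(...) {
  m <- cbind(...)
  if (is.null(m)) return(logical(0))
  rowSums(is.na(m)) == 0
}

#' Marginal genotype association (additive, homozygote, recessive)
#'
#' Fits covariate-adjusted logistic models of case status on genotype under
#' three codings and reports odds ratios in the layout of a marginal-effects
#' table: the additive per-allele OR and its square (two-allele contrast),
#' the AA-versus-GG homozygote contrast, and the recessive (AA+AG versus GG)
#' contrast.
#'
#' @param subjects subject table (`status`, `genotype`, covariate columns).
#' @param covariates subset of `c("age", "sex", "smoking")`.
#' @return A data.frame of class `marginal_table` with one row per contrast
#'   (`or`, `ci_low`, `ci_high`, `p`, `n`), and attribute `n_excluded`.
#' @export
marginal_genotype_analysis <- function(subjects,
                                       covariates = c("age", "sex", "smoking")) {
  y_all <- as.numeric(subjects$status == "case")
  cv_all <- covariate_matrix(subjects, covariates)

  one_fit <- function(model) {
    g <- code_genotype(subjects$genotype, model)
    keep <- complete_rows(g, y_all, cv_all)
    x <- cbind(intercept = 1, genotype = g[keep],
               cv_all[keep, , drop = FALSE])
    list(fit = fit_logistic(x, y_all[keep]), n = sum(keep),
         p_terms = ncol(x))
  }

  add <- one_fit("additive")
  hom <- one_fit("homozygote_contrast")
  rec <- one_fit("recessive")

  contrast_for <- function(f, k) {
    cv <- rep(0, f$p_terms)
    cv[2] <- k
    cv
  }
  rows <- list(
    additive_one_allele = wald_or(add$fit, contrast_for(add, 1)),
    additive_two_alleles = wald_or(add$fit, contrast_for(add, 2)),
    homozygote_AA_vs_GG = wald_or(hom$fit, contrast_for(hom, 1)),
    recessive_GG_vs_AA_AG = wald_or(rec$fit, contrast_for(rec, 1))
  )
  ns <- c(add$n, add$n, hom$n, rec$n)
  out <- data.frame(
    contrast = names(rows),
    or = vapply(rows, `[[`, numeric(1), "or"),
    ci_low = vapply(rows, `[[`, numeric(1), "ci_low"),
    ci_high = vapply(rows, `[[`, numeric(1), "ci_high"),
    p = vapply(rows, `[[`, numeric(1), "p"),
    n = ns, row.names = NULL)
  attr(out, "n_excluded") <- nrow(subjects) - add$n
  class(out) <- c("marginal_table", "data.frame")
  out
}

#' Gene-environment interaction analysis for one chemical class
#'
#' Fits the multiplicative-interaction logistic model
#' `logit P(case) = b0 + bg*G + be*E + bge*G*E + covariates`, with `G` the
#' additive risk-allele count (or the 0/1 homozygote contrast, dropping AG
#' carriers) and `E` the binary class-level exposure indicator, and lays the
#' result out as a stratified table: genotype ORs among the unexposed,
#' exposure OR in the reference genotype, and joint-effect ORs
#' `exp(be + k*bg + k*bge)` for `k` risk alleles, all against the
#' unexposed-AA reference cell. The interaction p-value is the two-sided
#' Wald test on the product term; a likelihood-ratio p-value is reported
#' alongside.
#'
#' @param subjects subject table.
#' @param class_exposure class-exposure table from
#'   [compute_class_exposure()] (or any table with `subject_id`,
#'   `chemical_class`, `exposed`).
#' @param chemical_class which class to analyse.
#' @param model `"additive"` or `"homozygote_contrast"`.
#' @param covariates subset of `c("age", "sex", "smoking")`.
#' @return A list of class `gxe_table`: `cells` (genotype x exposure rows
#'   with counts, column proportions, OR, CI, p), `interaction_p_wald`,
#'   `interaction_p_lrt`, `fit`, `n_analysed`, `n_excluded`.
#' @export
gxe_analysis <- function(subjects, class_exposure, chemical_class,
                         model = c("additive", "homozygote_contrast"),
                         covariates = c("age", "sex", "smoking")) {
  model <- match.arg(model)
  ce <- data.table::as.data.table(class_exposure)
  sel <- ce[["chemical_class"]] == chemical_class
  ce <- ce[which(sel), ]
  if (nrow(ce) == 0L)
    stop(data_error(paste("no class-exposure rows for", chemical_class)))
  sub <- merge(data.table::as.data.table(subjects), ce[, c("subject_id", "exposed")],
               by = "subject_id")

  g <- code_genotype(sub$genotype, model)
  e <- as.numeric(sub$exposed)
  y <- as.numeric(sub$status == "case")
  cv <- covariate_matrix(sub, covariates)
  keep <- complete_rows(g, e, y, cv)
  n_excluded <- nrow(sub) - sum(keep)
  g <- g[keep]; e <- e[keep]; y <- y[keep]
  cv <- cv[keep, , drop = FALSE]
  sub <- sub[keep]

  # inestimability: the product term needs both exposure levels and at least
  # two genotype levels within each
  cells <- table(genotype = sub$genotype, exposed = e)
  if (length(unique(e)) < 2L)
    stop(model_error(sprintf("exposure does not vary for %s: interaction inestimable",
                             chemical_class),
                     subclass = "ambientgxe_inestimable"))
  for (ee in c(0, 1)) {
    lv <- sum(cells[, as.character(ee)] > 0)
    if (lv < 2L) {
      empty <- rownames(cells)[cells[, as.character(ee)] == 0]
      stop(model_error(sprintf(
        "interaction inestimable for %s: empty cell(s) %s among the %s",
        chemical_class, paste(empty, collapse = ","),
        if (ee == 1) "exposed" else "unexposed"),
        subclass = "ambientgxe_inestimable"))
    }
  }

  x <- cbind(intercept = 1, genotype = g, exposed = e, gxe = g * e, cv)
  fit <- fit_logistic(x, y)
  p_lrt <- lrt_p(x, y, "gxe")
  wald_ge <- wald_or(fit, as.numeric(colnames(x) == "gxe"))

  genos <- if (model == "additive") c(AA = 0, AG = 1, GG = 2) else c(AA = 0, GG = 1)
  cell_rows <- list()
  for (gn in names(genos)) {
    for (ee in c(0L, 1L)) {
      k <- genos[[gn]]
      cvec <- rep(0, ncol(x))
      names(cvec) <- colnames(x)
      cvec["genotype"] <- k
      cvec["exposed"] <- ee
      cvec["gxe"] <- k * ee
      est <- wald_or(fit, cvec)
      nc <- sum(sub$genotype == gn & e == ee & y == 1)
      nk <- sum(sub$genotype == gn & e == ee & y == 0)
      cell_rows[[length(cell_rows) + 1L]] <- data.frame(
        genotype = gn, exposed = ee, n_cases = nc, n_controls = nk,
        or = est$or, ci_low = est$ci_low, ci_high = est$ci_high, p = est$p)
    }
  }
  cells_df <- do.call(rbind, cell_rows)
  for (ee in c(0L, 1L)) {
    i <- cells_df$exposed == ee
    cells_df$pct_cases[i] <- cells_df$n_cases[i] / sum(cells_df$n_cases[i])
    cells_df$pct_controls[i] <- cells_df$n_controls[i] / sum(cells_df$n_controls[i])
  }

  structure(list(chemical_class = chemical_class, model = model,
                 covariates = covariates, cells = cells_df,
                 interaction_p_wald = wald_ge$p, interaction_p_lrt = p_lrt,
                 interaction_or = wald_ge$or, fit = fit,
                 n_analysed = sum(keep), n_excluded = n_excluded),
            class = "gxe_table")
}

#' @export
print.gxe_table <- function(x, ...) {
  cat(sprintf("Gene-environment interaction: %s, %s model (n = %d, %d excluded)\n",
              x$chemical_class, x$model, x$n_analysed, x$n_excluded))
  tab <- x$cells
  tab$or <- sprintf("%.2f (%.2f, %.2f)", tab$or, tab$ci_low, tab$ci_high)
  tab$counts <- sprintf("%d (%.2f) / %d (%.2f)", tab$n_cases, tab$pct_cases,
                        tab$n_controls, tab$pct_controls)
  print(tab[, c("genotype", "exposed", "counts", "or", "p")], row.names = FALSE)
  cat(sprintf("Interaction p: Wald = %.4g, LRT = %.4g\n",
              x$interaction_p_wald, x$interaction_p_lrt))
  invisible(x)
}

#' Case-control comparison of a demographic variable
#'
#' Two-sided pooled-variance t-test for continuous variables, Pearson
#' chi-square (no continuity correction) for categorical ones.
#'
#' @param subjects subject table with a `status` column.
#' @param variable column name to compare.
#' @return A list with `statistic`, `df`, `p`, `method`.
#' @export
demographics_compare <- function(subjects, variable) {
  v <- subjects[[variable]]
  if (is.null(v)) stop(data_error(paste("no such column:", variable)))
  grp <- subjects$status
  if (is.numeric(v)) {
    if (min(table(grp[!is.na(v)])) < 2L)
      stop(data_error("each group needs at least 2 observations"))
    tt <- t.test(v[grp == "case"], v[grp == "control"], var.equal = TRUE)
    list(statistic = unname(tt$statistic), df = unname(tt$parameter),
         p = tt$p.value, method = "pooled_t")
  } else {
    tab <- table(grp, v)
    if (min(rowSums(tab)) < 2L)
      stop(data_error("each group needs at least 2 observations"))
    ct <- suppressWarnings(chisq.test(tab, correct = FALSE))
    list(statistic = unname(ct$statistic), df = unname(ct$parameter),
         p = ct$p.value, method = "chi_square")
  }
}

#' Spearman rank correlation of genotype with expression (cis-eQTL)
#'
#' Tie-corrected Spearman correlation between the additive genotype code and
#' an expression measure, with the t-approximation p-value and an optional
#' permutation p-value.
#'
#' @param genotype_code numeric additive codes (0/1/2).
#' @param expression numeric expression values.
#' @param n_perm number of permutations for an optional permutation p-value
#'   (0 to skip).
#' @param seed optional seed for the permutations.
#' @return A list of class `eqtl_result`: `rho`, `p`, `n`, optionally
#'   `p_perm`.
#' @export
spearman_eqtl <- function(genotype_code, expression, n_perm = 0L, seed = NULL) {
  keep <- !is.na(genotype_code) & !is.na(expression)
  g <- genotype_code[keep]; x <- expression[keep]
  if (length(g) < 4L) stop(data_error("need at least 4 paired observations"))
  if (sd(x) == 0 || sd(g) == 0)
    stop(model_error("constant input: correlation undefined",
                     subclass = "ambientgxe_degenerate_test"))
  ct <- suppressWarnings(cor.test(g, x, method = "spearman", exact = FALSE))
  out <- list(rho = unname(ct$estimate), p = ct$p.value, n = length(g))
  if (n_perm > 0L) {
    if (!is.null(seed)) set.seed(seed)
    obs <- abs(out$rho)
    hits <- 0L
    for (i in seq_len(n_perm)) {
      r <- suppressWarnings(stats::cor(g, sample(x), method = "spearman"))
      if (abs(r) >= obs - 1e-12) hits <- hits + 1L
    }
    out$p_perm <- (1 + hits) / (n_perm + 1)
  }
  class(out) <- "eqtl_result"
  out
}

#' @export
print.eqtl_result <- function(x, ...) {
  cat(sprintf("Spearman eQTL: rho = %.3f, p = %.4g (n = %d)\n", x$rho, x$p, x$n))
  if (!is.null(x$p_perm)) cat(sprintf("  permutation p = %.4g\n", x$p_perm))
  invisible(x)
}
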