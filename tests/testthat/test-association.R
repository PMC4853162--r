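test_that("marginal genotype table obeys the additive-model structure", {
  subj <- quick_subjects(1200, seed = 3)
  tab <- marginal_genotype_analysis(subj)
  expect_equal(tab$contrast[1:2], c("additive_one_allele", "additive_two_alleles"))
  # OR for two alleles is exactly the square of the one-allele OR
  expect_equal(tab$or[2], tab$or[1]^2, tolerance = 1e-10)
  expect_true(all(tab$ci_low <= tab$or & tab$or <= tab$ci_high))
  # heterozygotes are dropped from the homozygote contrast
  expect_equal(tab$n[3], sum(subj$genotype != "AG"))
})

test_that("a purely recessive risk pattern yields a recessive OR above 1", {
  set.seed(99)
  n <- 1500
  subj <- quick_subjects(n, seed = 99)
  risk <- plogis(-0.8 + 1.2 * (subj$genotype == "GG"))
  subj$status <- ifelse(runif(n) < risk, "case", "control")
  tab <- marginal_genotype_analysis(subj)
  rec <- tab[tab$contrast == "recessive_GG_vs_AA_AG", ]
  expect_gt(rec$or, 1)
  expect_gt(rec$ci_low, 1)
})

test_that("null additive fits cover OR 1 at close to the nominal rate", {
  covered <- 0L
  n_rep <- 100L
  for (i in seq_len(n_rep)) {
    subj <- quick_subjects(500, seed = 1000 + i)
    tab <- marginal_genotype_analysis(subj)
    one <- tab[tab$contrast == "additive_one_allele", ]
    if (one$ci_low <= 1 && 1 <= one$ci_high) covered <- covered + 1L
  }
  expect_gte(covered / n_rep, 0.88)
  expect_lte(covered / n_rep, 0.995)
})

make_exposure_table <- function(subj, exposed, class = "pyrethroid") {
  data.frame(subject_id = subj$subject_id, chemical_class = class,
             n_pesticides_exposed = exposed, category = NA,
             exposed = as.integer(exposed))
}

test_that("gxe table has unit reference cell and coherent joint effects", {
  set.seed(7)
  n <- 3000
  subj <- quick_subjects(n, seed = 7)
  e <- rbinom(n, 1, 0.3)
  g <- code_genotype(subj$genotype, "additive")
  subj$status <- ifelse(runif(n) < plogis(-0.5 + 0.1 * g + 0.2 * e + 0.35 * g * e),
                        "case", "control")
  res <- gxe_analysis(subj, make_exposure_table(subj, e), "pyrethroid", "additive")
  cells <- res$cells
  ref <- cells[cells$genotype == "AA" & cells$exposed == 0, ]
  expect_identical(ref$or, 1)
  expect_identical(c(ref$ci_low, ref$ci_high), c(1, 1))
  # joint-effect coherence: OR(GG,1) = OR(AG,1)^2 / OR(AA,1) under the
  # additive interaction parameterisation
  or_aa1 <- cells$or[cells$genotype == "AA" & cells$exposed == 1]
  or_ag1 <- cells$or[cells$genotype == "AG" & cells$exposed == 1]
  or_gg1 <- cells$or[cells$genotype == "GG" & cells$exposed == 1]
  expect_equal(or_gg1, or_ag1^2 / or_aa1, tolerance = 1e-9)
  # unexposed genotype ORs square as well
  or_ag0 <- cells$or[cells$genotype == "AG" & cells$exposed == 0]
  or_gg0 <- cells$or[cells$genotype == "GG" & cells$exposed == 0]
  expect_equal(or_gg0, or_ag0^2, tolerance = 1e-9)
  # counts partition the cohort
  expect_equal(sum(cells$n_cases + cells$n_controls), n)
})

test_that("exposure unrelated to status and genotype gives near-null ORs", {
  set.seed(31)
  n <- 4000
  subj <- quick_subjects(n, p_case = 0.5, seed = 31)
  e <- rbinom(n, 1, 0.35)
  res <- gxe_analysis(subj, make_exposure_table(subj, e), "pyrethroid", "additive")
  expect_true(all(res$cells$or > 0.6 & res$cells$or < 1.6))
  expect_gt(res$interaction_p_wald, 0.001)
})

test_that("homozygote-contrast model drops heterozygotes", {
  subj <- quick_subjects(2000, seed = 11)
  e <- rbinom(2000, 1, 0.3)
  res <- gxe_analysis(subj, make_exposure_table(subj, e), "pyrethroid",
                      "homozygote_contrast")
  expect_equal(res$n_analysed, sum(subj$genotype != "AG"))
  expect_setequal(unique(res$cells$genotype), c("AA", "GG"))
})

test_that("an empty genotype-exposure cell raises an inestimability error", {
  subj <- quick_subjects(400, seed = 13)
  e <- as.integer(subj$genotype == "AA" & runif(400) < 0.5)
  expect_error(
    gxe_analysis(subj, make_exposure_table(subj, e), "pyrethroid", "additive"),
    "empty cell", class = "ambientgxe_inestimable")
  expect_error(
    gxe_analysis(subj, make_exposure_table(subj, rep(0L, 400)), "pyrethroid",
                 "additive"),
    class = "ambientgxe_inestimable")
})

test_that("Wald and likelihood-ratio interaction p-values broadly agree", {
  set.seed(17)
  n <- 2000
  subj <- quick_subjects(n, seed = 17)
  e <- rbinom(n, 1, 0.35)
  g <- code_genotype(subj$genotype, "additive")
  subj$status <- ifelse(runif(n) < plogis(-0.2 + 0.1 * g * e), "case", "control")
  res <- gxe_analysis(subj, make_exposure_table(subj, e), "pyrethroid", "additive")
  ratio <- res$interaction_p_wald / res$interaction_p_lrt
  expect_gt(ratio, 1 / 1.5)
  expect_lt(ratio, 1.5)
})

test_that("demographic comparisons reproduce hand-computed statistics", {
  subj <- data.frame(status = rep(c("case", "control"), each = 3),
                     age_years = c(1, 2, 3, 4, 5, 6))
  res <- demographics_compare(subj, "age_years")
  expect_equal(res$statistic, -3.674, tolerance = 1e-3)
  expect_equal(res$df, 4)
  expect_equal(res$p, 2 * pt(res$statistic, 4))
  expect_equal(res$p, 0.0214, tolerance = 5e-3)

  same <- data.frame(status = rep(c("case", "control"), each = 3),
                     age_years = rep(c(1, 2, 3), 2))
  res2 <- demographics_compare(same, "age_years")
  expect_equal(res2$statistic, 0)
  expect_equal(res2$p, 1)

  bal <- data.frame(status = rep(c("case", "control"), each = 100),
                    sex = rep(rep(c("male", "female"), each = 50), 2))
  res3 <- demographics_compare(bal, "sex")
  expect_equal(res3$statistic, 0)
  expect_equal(res3$p, 1)
  expect_error(demographics_compare(subj, "nope"), class = "ambientgxe_data_error")
})

test_that("Spearman eQTL statistic handles monotone and tied data", {
  g <- c(0, 0, 1, 1, 2, 2)
  # expression strictly increasing in genotype (tie patterns aligned)
  expect_equal(spearman_eqtl(g, c(1, 1, 2, 2, 3, 3))$rho, 1)
  expect_equal(spearman_eqtl(g, c(3, 3, 2, 2, 1, 1))$rho, -1)
  # monotone but with within-genotype scatter: rho stays below 1 only
  # through the tie correction, and keeps the sign
  expect_gt(spearman_eqtl(g, c(1, 2, 3, 4, 5, 6))$rho, 0.9)
  expect_error(spearman_eqtl(g, rep(2, 6)), class = "ambientgxe_degenerate_test")
  expect_error(spearman_eqtl(c(0, 1), c(1, 2)), class = "ambientgxe_data_error")
})

test_that("permutation p-value matches exhaustive enumeration on a tied example", {
  g <- c(0, 0, 1, 1, 2, 2)
  x <- c(1.2, 0.8, 1.1, 1.9, 2.2, 1.9)  # ties present
  res <- spearman_eqtl(g, x, n_perm = 4000, seed = 5)
  # exhaustive oracle over all 720 orderings of the expression values
  perms <- function(v) {
    if (length(v) == 1) return(list(v))
    out <- list()
    for (i in seq_along(v)) out <- c(out, lapply(perms(v[-i]), function(p) c(v[i], p)))
    out
  }
  all_p <- perms(x)
  obs <- abs(suppressWarnings(cor(g, x, method = "spearman")))
  exact <- mean(vapply(all_p, function(p)
    abs(suppressWarnings(cor(g, p, method = "spearman"))) >= obs - 1e-12,
    logical(1)))
  expect_lt(abs(res$p_perm - exact), 0.04)
  expect_equal(res$rho, suppressWarnings(cor(g, x, method = "spearman")))
})
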