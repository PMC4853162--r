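#' Genotype counts at a biallelic locus
#'
#' @param n_AA,n_AG,n_GG non-negative genotype counts, or pass a character
#'   vector of genotype labels as `n_AA`.
#' @return A list of class `genotype_counts` with the three counts, the
#'   total, and the genotype proportions.
#' @export
genotype_counts <- function(n_AA, n_AG = NULL, n_GG = NULL) {
  if (is.character(n_AA)) {
    g <- n_AA
    bad <- setdiff(unique(g), c("AA", "AG", "GG", NA))
    if (length(bad))
      stop(data_error(paste("unknown genotype labels:", paste(bad, collapse = ", "))))
    n_AA <- sum(g == "AA", na.rm = TRUE)
    n_AG <- sum(g == "AG", na.rm = TRUE)
    n_GG <- sum(g == "GG", na.rm = TRUE)
  }
  n <- c(AA = n_AA, AG = n_AG, GG = n_GG)
  if (any(n < 0) || any(n != round(n))) stop(data_error("counts must be non-negative integers"))
  total <- sum(n)
  structure(list(n_AA = n[["AA"]], n_AG = n[["AG"]], n_GG = n[["GG"]],
                 total = total, proportions = if (total > 0) n / total else n * NA),
            class = "genotype_counts")
}

#' @export
print.genotype_counts <- function(x, ...) {
  cat(sprintf("Genotype counts (n = %d): AA %d (%.2f) / AG %d (%.2f) / GG %d (%.2f)\n",
              x$total, x$n_AA, x$proportions[["AA"]], x$n_AG,
              x$proportions[["AG"]], x$n_GG, x$proportions[["GG"]]))
  invisible(x)
}

#' Risk (G) allele frequency
#'
#' @param counts a [genotype_counts()].
#' @return `(2 n_GG + n_AG) / (2 total)`.
#' @export
allele_freq <- function(counts) {
  if (counts$total == 0) stop(data_error("empty genotype counts"))
  (2 * counts$n_GG + counts$n_AG) / (2 * counts$total)
}

#' Hardy-Weinberg chi-square goodness-of-fit test
#'
#' Pearson chi-square of the three observed genotype counts against the
#' Hardy-Weinberg expectations `n(1-q)^2, 2nq(1-q), nq^2` computed from the
#' sample allele frequency; 1 degree of freedom, no continuity correction.
#'
#' @param counts a [genotype_counts()].
#' @return A list of class `hwe_result` with `chi2`, `df`, `p`, `method`.
#' @export
hwe_chisq <- function(counts) {
  if (counts$total == 0) stop(data_error("empty genotype counts"))
  q <- allele_freq(counts)
  if (q == 0 || q == 1)
    stop(model_error("monomorphic sample: Hardy-Weinberg test degenerate",
                     subclass = "ambientgxe_degenerate_test"))
  n <- counts$total
  expected <- n * c((1 - q)^2, 2 * q * (1 - q), q^2)
  observed <- c(counts$n_AA, counts$n_AG, counts$n_GG)
  chi2 <- sum((observed - expected)^2 / expected)
  structure(list(chi2 = chi2, df = 1L, p = pchisq(chi2, 1L, lower.tail = FALSE),
                 method = "chi_square", expected = expected),
            class = "hwe_result")
}

#' Exact Hardy-Weinberg test
#'
#' Exact conditional test: given the observed allele counts, the p-value is
#' the total probability of all heterozygote counts whose conditional
#' probability does not exceed that of the observed count. Probabilities are
#' computed from the closed-form conditional distribution via log-factorials,
#' so the enumeration is exact at any sample size used here.
#'
#' @param counts a [genotype_counts()].
#' @return A list of class `hwe_result` with `p`, `method = "exact"`, and the
#'   conditional distribution over heterozygote counts.
#' @export
hwe_exact <- function(counts) {
  if (counts$total == 0) stop(data_error("empty genotype counts"))
  n <- counts$total
  n_g <- 2 * counts$n_GG + counts$n_AG    # minor-or-not, just one allele
  n_a <- 2 * n - n_g
  rare <- min(n_g, n_a)
  if (rare == 0)
    return(structure(list(chi2 = NA_real_, df = NA_integer_, p = 1,
                          method = "exact"), class = "hwe_result"))
  # heterozygote counts share the parity of the rarer allele count
  het <- seq(rare %% 2L, rare, by = 2L)
  logp <- lgamma(n + 1) - lgamma((n_g - het) / 2 + 1) - lgamma(het + 1) -
    lgamma((n_a - het) / 2 + 1) + het * log(2) +
    lgamma(n_g + 1) + lgamma(n_a + 1) - lgamma(2 * n + 1)
  prob <- exp(logp - max(logp))
  prob <- prob / sum(prob)
  obs <- prob[match(counts$n_AG, het)]
  p <- min(1, sum(prob[prob <= obs * (1 + 1e-12)]))
  structure(list(chi2 = NA_real_, df = NA_integer_, p = p, method = "exact",
                 het_counts = het, het_probs = prob),
            class = "hwe_result")
}

#' @export
print.hwe_result <- function(x, ...) {
  if (x$method == "chi_square")
    cat(sprintf("Hardy-Weinberg chi-square test: chi2 = %.4f, df = %d, p = %.4g\n",
                x$chi2, x$df, x$p))
  else
    cat(sprintf("Hardy-Weinberg exact test: p = %.4g\n", x$p))
  invisible(x)
}

#' Numeric genotype coding under a genetic model
#'
#' Additive: count of G alleles (0/1/2). Recessive: 1 for GG, else 0.
#' Homozygote contrast: AA = 0, GG = 1, AG excluded (`NA`).
#'
#' @param genotype character vector of `"AA"`, `"AG"`, `"GG"`.
#' @param model `"additive"`, `"recessive"`, or `"homozygote_contrast"`.
#' @return Numeric vector; `NA` marks subjects excluded under the model.
#' @export
code_genotype <- function(genotype,
                          model = c("additive", "recessive", "homozygote_contrast")) {
  model <- match.arg(model)
  bad <- setdiff(unique(genotype[!is.na(genotype)]), c("AA", "AG", "GG"))
  if (length(bad))
    stop(data_error(paste("unknown genotype labels:", paste(bad, collapse = ", "))))
  switch(model,
    additive = c(AA = 0, AG = 1, GG = 2)[genotype],
    recessive = c(AA = 0, AG = 0, GG = 1)[genotype],
    homozygote_contrast = c(AA = 0, AG = NA, GG = 1)[genotype]
  )
}

#' Genotype and Hardy-Weinberg summary for a cohort
#'
#' @param subjects subject table (needs `status`, `genotype`).
#' @return A list with per-status [genotype_counts()], allele frequencies,
#'   and both Hardy-Weinberg tests on the controls.
#' @export
genetics_summary <- function(subjects) {
  cases <- genotype_counts(subjects$genotype[subjects$status == "case"])
  controls <- genotype_counts(subjects$genotype[subjects$status == "control"])
  list(cases = cases, controls = controls,
       allele_freq_cases = allele_freq(cases),
       allele_freq_controls = allele_freq(controls),
       hwe_controls_chisq = hwe_chisq(controls),
       hwe_controls_exact = hwe_exact(controls))
}
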