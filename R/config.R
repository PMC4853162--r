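#' @importFrom stats plogis qlogis rbinom rnorm runif rlnorm median pchisq pt
#'   pnorm qnorm sd binom.test chisq.test t.test cor.test rpois
#' @importFrom utils modifyList
#' @import data.table
NULL

# Chemical classes recognised throughout the pipeline.
CHEMICAL_CLASSES <- c("organophosphate", "dithiocarbamate", "pyrethroid", "paraquat")

# Pyrethroid active ingredients used for synthetic application records.
PYRETHROID_NAMES <- c(
  "fenvalerate", "permethrin", "phenothrin", "resmethrin", "flucythrinate",
  "cypermethrin", "s-cypermethrin", "tau-fluvalinate", "fenpropathrin",
  "lambda-cyhalothrin", "bifenthrin", "esfenvalerate", "tralomethrin"
)

#' Derive a per-stage RNG seed from a master seed
#'
#' Each generator stage draws from its own stream, derived deterministically
#' from the master seed and a fixed stage label, so that changing one stage's
#' parameters does not perturb the randomness of other stages.
#'
#' @param seed master integer seed.
#' @param label character stage label (e.g. `"applications"`).
#' @return An integer seed in `[1, 2^31 - 2]`.
#' @export
stage_seed <- function(seed, label) {
  stopifnot(is.numeric(seed), length(seed) == 1L, is.character(label))
  m <- 2147483647
  h <- 0
  for (ch in utf8ToInt(label)) h <- (h * 31 + ch) %% m
  s <- (abs(as.numeric(seed)) + h) %% m
  if (s == 0) s <- 1
  # Lehmer scramble so that labels with nearby hashes (e.g. numbered
  # replicate labels) do not yield additively structured seeds
  for (k in 1:3) s <- (48271 * s) %% m
  as.integer(s)
}

#' Simulation configuration for the synthetic cohort generator
#'
#' Bundles every parameter of the synthetic study: cohort size, risk-allele
#' frequency, the spatial application process per chemical class, address
#' missingness, and the disease-model coefficients on the log-odds scale
#' (`logit P = b0 + bg*G + be*E + bge*G*E + bage*age + bsex*male +
#' bsmoke*smoker`, with `G` the additive risk-allele count and `E` the binary
#' ambient-exposure indicator for the focal chemical class).
#'
#' Defaults emulate a population-based case-control study of ambient pesticide
#' exposure: 465 cases and 497 controls, risk-allele frequency 0.42 (so control
#' genotypes land near 0.35/0.46/0.19 for AA/AG/GG), roughly 30% of subjects
#' living in the agricultural zone where applications occur, index years
#' 2000-2007 so the exposure window 1974..(index - 10) spans 17-24 years.
#'
#' @param n_cases,n_controls cohort sizes to sample.
#' @param risk_allele_freq frequency `q` of the risk (G) allele; genotypes are
#'   drawn in Hardy-Weinberg proportions.
#' @param region numeric length-4 `c(xmin, xmax, ymin, ymax)` in metres.
#' @param ag_zone like `region`; the sub-rectangle receiving applications.
#' @param p_rural probability that a subject's residence lies inside the
#'   agricultural zone (governs exposure prevalence).
#' @param start_year first year of the application record.
#' @param index_year_range range of subject index years (diagnosis for cases,
#'   interview for controls).
#' @param classes named list per chemical class with elements
#'   `events_per_year`, `n_pesticides`, `pounds_meanlog`, `pounds_sdlog`,
#'   `acres_meanlog`, `acres_sdlog`.
#' @param address_missing_rate per (subject, year, setting) probability that
#'   the geocode is missing.
#' @param occupational_sd standard deviation (metres) of workplace location
#'   around the residence.
#' @param beta named numeric disease-model coefficients: `b0`, `bg`, `be`,
#'   `bge`, `bage`, `bsex`, `bsmoke` (log-odds scale; `bage` multiplies age in
#'   years).
#' @param age_mean,age_sd,age_range age distribution (truncated normal).
#' @param p_male,p_smoker covariate prevalences.
#' @param focal_class chemical class whose exposure enters the disease model.
#' @param source_multiplier source-population size as a multiple of
#'   `n_cases + n_controls`.
#' @param seed master integer seed.
#' @return A validated list of class `sim_config`.
#' @export
sim_config <- function(n_cases = 465L,
                       n_controls = 497L,
                       risk_allele_freq = 0.42,
                       region = c(0, 20000, 0, 20000),
                       ag_zone = c(0, 7000, 0, 20000),
                       p_rural = 0.30,
                       start_year = 1974L,
                       index_year_range = c(2000L, 2007L),
                       classes = default_class_params(),
                       address_missing_rate = 0.10,
                       occupational_sd = 1000,
                       beta = c(b0 = -2.2, bg = log(1.03), be = log(0.83),
                                bge = log(1.65), bage = 0.0, bsex = 0.3,
                                bsmoke = -0.3),
                       age_mean = 66, age_sd = 10, age_range = c(35, 95),
                       p_male = 0.55, p_smoker = 0.45,
                       focal_class = "pyrethroid",
                       source_multiplier = 8,
                       seed = 1L) {
  cfg <- list(
    n_cases = as.integer(n_cases), n_controls = as.integer(n_controls),
    risk_allele_freq = risk_allele_freq, region = as.numeric(region),
    ag_zone = as.numeric(ag_zone), p_rural = p_rural,
    start_year = as.integer(start_year),
    index_year_range = as.integer(index_year_range),
    classes = classes, address_missing_rate = address_missing_rate,
    occupational_sd = occupational_sd, beta = beta,
    age_mean = age_mean, age_sd = age_sd, age_range = as.numeric(age_range),
    p_male = p_male, p_smoker = p_smoker, focal_class = focal_class,
    source_multiplier = source_multiplier, seed = as.integer(seed)
  )
  class(cfg) <- "sim_config"
  validate_sim_config(cfg)
  cfg
}

#' Default per-class application-process parameters
#'
#' Rates are commercial application events per year across the agricultural
#' zone; pounds and acres are log-normal. Paraquat is a single active
#' ingredient; the pyrethroid class carries the 13 named active ingredients.
#'
#' @return Named list keyed by chemical class.
#' @export
default_class_params <- function() {
  base <- list(pounds_meanlog = log(50), pounds_sdlog = 1,
               acres_meanlog = log(20), acres_sdlog = 0.7)
  list(
    organophosphate = c(list(events_per_year = 120, n_pesticides = 12L), base),
    dithiocarbamate = c(list(events_per_year = 50, n_pesticides = 6L), base),
    pyrethroid      = c(list(events_per_year = 80, n_pesticides = 13L), base),
    paraquat        = c(list(events_per_year = 40, n_pesticides = 1L), base)
  )
}

#' Validate a simulation configuration
#'
#' @param cfg a `sim_config` list.
#' @return `cfg`, invisibly; stops with a `config` error on violation.
#' @export
validate_sim_config <- function(cfg) {
  fail <- function(msg) stop(config_error(msg))
  if (!is.list(cfg)) fail("config must be a list")
  req <- c("n_cases", "n_controls", "risk_allele_freq", "region", "ag_zone",
           "p_rural", "start_year", "index_year_range", "classes",
           "address_missing_rate", "beta", "focal_class", "source_multiplier",
           "seed")
  miss <- setdiff(req, names(cfg))
  if (length(miss)) fail(paste("missing config fields:", paste(miss, collapse = ", ")))
  if (cfg$n_cases <= 0 || cfg$n_controls <= 0) fail("cohort counts must be positive")
  q <- cfg$risk_allele_freq
  if (!is.numeric(q) || q < 0 || q > 1) fail("risk_allele_freq must lie in [0, 1]")
  if (length(cfg$region) != 4 ||
      cfg$region[2] <= cfg$region[1] || cfg$region[4] <= cfg$region[3])
    fail("region must be c(xmin, xmax, ymin, ymax) with positive area")
  m <- cfg$address_missing_rate
  if (m < 0 || m >= 1) fail("address_missing_rate must lie in [0, 1)")
  if (cfg$p_rural < 0 || cfg$p_rural > 1) fail("p_rural must lie in [0, 1]")
  if (min(cfg$index_year_range) < 1984)
    fail("index years must be >= 1984 so the window 1974..(index - 10) is non-empty")
  bn <- c("b0", "bg", "be", "bge", "bage", "bsex", "bsmoke")
  if (!all(bn %in% names(cfg$beta))) fail("beta must carry b0, bg, be, bge, bage, bsex, bsmoke")
  if (!cfg$focal_class %in% CHEMICAL_CLASSES)
    fail(paste("focal_class must be one of:", paste(CHEMICAL_CLASSES, collapse = ", ")))
  for (cl in names(cfg$classes)) {
    p <- cfg$classes[[cl]]
    if (!cl %in% CHEMICAL_CLASSES) fail(paste("unknown chemical class:", cl))
    if (p$events_per_year < 0) fail("events_per_year must be >= 0")
    if (p$n_pesticides < 1) fail("n_pesticides must be >= 1")
  }
  invisible(cfg)
}

#' Read or write a simulation configuration as YAML
#'
#' The on-disk format is a nested key/value document mirroring the
#' [sim_config()] arguments; it is validated on read.
#'
#' @param path file path.
#' @param cfg a `sim_config`.
#' @return `read_config()` returns a validated `sim_config`.
#' @export
read_config <- function(path) {
  raw <- yaml::read_yaml(path)
  base <- sim_config()
  cfg <- modifyList(unclass(base), raw)
  cfg$beta <- unlist(cfg$beta)
  cfg$n_cases <- as.integer(cfg$n_cases)
  cfg$n_controls <- as.integer(cfg$n_controls)
  cfg$start_year <- as.integer(cfg$start_year)
  cfg$index_year_range <- as.integer(cfg$index_year_range)
  cfg$seed <- as.integer(cfg$seed)
  class(cfg) <- "sim_config"
  validate_sim_config(cfg)
  cfg
}

#' @rdname read_config
#' @export
write_config <- function(cfg, path) {
  validate_sim_config(cfg)
  out <- unclass(cfg)
  out$beta <- as.list(out$beta)
  yaml::write_yaml(out, path)
  invisible(path)
}

# Condition constructors: distinct classes so callers (and the CLI exit codes)
# can tell configuration, data, and model failures apart.
config_error <- function(msg) {
  structure(class = c("ambientgxe_config_error", "error", "condition"),
            list(message = msg, call = sys.call(-1)))
}
data_error <- function(msg) {
  structure(class = c("ambientgxe_data_error", "error", "condition"),
            list(message = msg, call = sys.call(-1)))
}
model_error <- function(msg, subclass = NULL) {
  structure(class = c(subclass, "ambientgxe_model_error", "error", "condition"),
            list(message = msg, call = sys.call(-1)))
}

# FNV-1a hash of a character vector, reported as hex; used to fingerprint the
# configuration in the run manifest without extra dependencies.
fnv1a_hash <- function(x) {
  bytes <- utf8ToInt(paste(x, collapse = "\n"))
  h <- 2166136261
  for (b in bytes) {
    h <- bitwXor(as.integer(h %% 2^31), b)
    h <- (h * 16777619) %% 2^31
  }
  sprintf("%08x", as.integer(h))
}

#' Fingerprint a configuration
#'
#' @param cfg a `sim_config`.
#' @return Hex string hash of the YAML rendering of `cfg`.
#' @export
config_hash <- function(cfg) {
  out <- unclass(cfg)
  out$beta <- as.list(out$beta)
  fnv1a_hash(yaml::as.yaml(out))
}

#' @export
print.sim_config <- function(x, ...) {
  cat("Synthetic cohort configuration\n")
  cat(sprintf("  cohort: %d cases / %d controls (source x%.1f)\n",
              x$n_cases, x$n_controls, x$source_multiplier))
  cat(sprintf("  risk allele freq: %.3f; focal class: %s\n",
              x$risk_allele_freq, x$focal_class))
  cat(sprintf("  region: [%g, %g] x [%g, %g] m; P(rural) = %.2f\n",
              x$region[1], x$region[2], x$region[3], x$region[4], x$p_rural))
  cat(sprintf("  years: %d..%d (index %d-%d); address missingness %.2f\n",
              x$start_year, max(x$index_year_range), x$index_year_range[1],
              x$index_year_range[2], x$address_missing_rate))
  cat("  beta:", paste(sprintf("%s=%.3f", names(x$beta), x$beta), collapse = " "), "\n")
  cat(sprintf("  seed: %d\n", x$seed))
  invisible(x)
}
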