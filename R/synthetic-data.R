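#' Generate synthetic commercial pesticide-application records
#'
#' Emulates a mandated pesticide-use-report table: one row per commercial
#' application event with the active ingredient, chemical class, calendar
#' year, planar location (metres), pounds applied and acres treated. Events
#' form a homogeneous Poisson process in time (`events_per_year` per class)
#' and are placed uniformly over the agricultural zone; pounds and acres are
#' log-normal. Pyrethroid events draw their active-ingredient names from the
#' thirteen pyrethroids tracked by the pipeline
#' (fenvalerate, permethrin, ...); other classes use generated names.
#'
#' @param config a [sim_config()].
#' @param region numeric `c(xmin, xmax, ymin, ymax)` in metres; defaults to
#'   the configuration's agricultural zone.
#' @param seed integer seed; defaults to the `"applications"` stage stream of
#'   the master seed.
#' @return A `data.table` with columns `pesticide_id`, `chemical_class`,
#'   `year`, `x_m`, `y_m`, `pounds`, `acres`.
#' @export
generate_applications <- function(config, region = NULL, seed = NULL) {
  validate_sim_config(config)
  if (is.null(region)) region <- config$ag_zone
  if (length(region) != 4 || region[2] <= region[1] || region[4] <= region[3])
    stop(config_error("application region must have positive area"))
  if (is.null(seed)) seed <- stage_seed(config$seed, "applications")

  years <- seq(config$start_year, max(config$index_year_range))
  n_years <- length(years)
  out <- vector("list", length(config$classes))
  set.seed(seed)
  for (i in seq_along(config$classes)) {
    cl <- names(config$classes)[i]
    p <- config$classes[[cl]]
    if (p$events_per_year < 0) stop(config_error("events_per_year must be >= 0"))
    n <- rpois(1L, p$events_per_year * n_years)
    if (n == 0L) next
    ids <- pesticide_names(cl, p$n_pesticides)
    out[[i]] <- data.table::data.table(
      pesticide_id = sample(ids, n, replace = TRUE),
      chemical_class = cl,
      year = sample(years, n, replace = TRUE),
      x_m = runif(n, region[1], region[2]),
      y_m = runif(n, region[3], region[4]),
      pounds = rlnorm(n, p$pounds_meanlog, p$pounds_sdlog),
      acres = rlnorm(n, p$acres_meanlog, p$acres_sdlog)
    )
  }
  out <- data.table::rbindlist(out)
  if (nrow(out) == 0L)
    out <- data.table::data.table(pesticide_id = character(), chemical_class = character(),
                                  year = integer(), x_m = numeric(), y_m = numeric(),
                                  pounds = numeric(), acres = numeric())
  data.table::setorder(out, chemical_class, pesticide_id, year)
  out[]
}

pesticide_names <- function(chemical_class, n) {
  switch(chemical_class,
    pyrethroid = PYRETHROID_NAMES[seq_len(min(n, length(PYRETHROID_NAMES)))],
    paraquat = "paraquat",
    sprintf("%s_%02d", chemical_class, seq_len(n))
  )
}

#' Draw genotypes in Hardy-Weinberg proportions
#'
#' Genotypes at a biallelic locus (alleles A and G, G the risk allele) drawn
#' with `P(AA) = (1-q)^2`, `P(AG) = 2q(1-q)`, `P(GG) = q^2`.
#'
#' @param n number of subjects.
#' @param q risk (G) allele frequency in `[0, 1]`.
#' @param seed optional integer seed.
#' @return Character vector of `"AA"`, `"AG"`, `"GG"`.
#' @export
generate_genotypes <- function(n, q, seed = NULL) {
  if (!is.numeric(q) || length(q) != 1L || is.na(q) || q < 0 || q > 1)
    stop(config_error("allele frequency q must lie in [0, 1]"))
  if (!is.null(seed)) set.seed(seed)
  sample(c("AA", "AG", "GG"), n, replace = TRUE,
         prob = c((1 - q)^2, 2 * q * (1 - q), q^2))
}

#' Generate a synthetic case-control cohort with address histories
#'
#' Simulates a source population (covariates, genotypes, residential and
#' occupational addresses), assigns each subject a true ambient-exposure
#' indicator for the focal chemical class by running the buffer-sum /
#' window-average / median-dichotomization procedure on the full-information
#' source population, draws disease status from the logistic model
#' `logit P = b0 + bg*G + be*E + bge*G*E + bage*age + bsex*male + bsmoke*smoker`,
#' and then samples exactly `n_cases` cases and `n_controls` controls without
#' replacement (the outcome-dependent sampling of a retrospective design).
#'
#' The returned subject table records the true exposure indicator
#' (`true_exposed`) and the generating coefficients (attribute `beta`) so that
#' parameter-recovery experiments can fit against the truth.
#'
#' @param config a [sim_config()].
#' @param applications application table from [generate_applications()]; may
#'   be empty only when all exposure effects are zero.
#' @param seed master seed; defaults to `config$seed`.
#' @return A list of class `cohort` with elements `subjects` (one row per
#'   sampled subject), `addresses` (one row per subject x year x setting, with
#'   `x_m`/`y_m` `NA` for un-geocoded years), and `config`.
#' @export
generate_cohort <- function(config, applications, seed = NULL) {
  validate_sim_config(config)
  if (is.null(seed)) seed <- config$seed
  focal <- applications[applications$chemical_class == config$focal_class, ]
  if (nrow(focal) == 0L && (config$beta[["be"]] != 0 || config$beta[["bge"]] != 0))
    stop(config_error("no applications for the focal class but exposure effects are non-zero"))

  n_target <- config$n_cases + config$n_controls
  n_source <- as.integer(ceiling(config$source_multiplier * n_target))

  # covariates ----------------------------------------------------------
  set.seed(stage_seed(seed, "covariates"))
  age <- pmin(pmax(rnorm(n_source, config$age_mean, config$age_sd),
                   config$age_range[1]), config$age_range[2])
  male <- rbinom(n_source, 1L, config$p_male)
  smoker <- rbinom(n_source, 1L, config$p_smoker)
  index_year <- sample(seq(config$index_year_range[1], config$index_year_range[2]),
                       n_source, replace = TRUE)

  genotype <- generate_genotypes(n_source, config$risk_allele_freq,
                                 seed = stage_seed(seed, "genotypes"))
  g_add <- code_genotype(genotype, "additive")

  # addresses -----------------------------------------------------------
  set.seed(stage_seed(seed, "addresses"))
  rural <- rbinom(n_source, 1L, config$p_rural) == 1L
  res <- place_residences(n_source, rural, config$region, config$ag_zone)
  occ_x <- pmin(pmax(res$x + rnorm(n_source, 0, config$occupational_sd),
                     config$region[1]), config$region[2])
  occ_y <- pmin(pmax(res$y + rnorm(n_source, 0, config$occupational_sd),
                     config$region[3]), config$region[4])

  points <- data.table::data.table(
    idx = rep(seq_len(n_source), 2L),
    setting = rep(c("residential", "occupational"), each = n_source),
    x = c(res$x, occ_x), y = c(res$y, occ_y),
    index_year = rep(index_year, 2L)
  )

  # true exposure for the focal class (full information, no missingness)
  e_true <- true_class_exposure(points, focal, config)

  # disease model -------------------------------------------------------
  b <- config$beta
  lp <- b[["b0"]] + b[["bg"]] * g_add + b[["be"]] * e_true +
    b[["bge"]] * g_add * e_true + b[["bage"]] * age +
    b[["bsex"]] * male + b[["bsmoke"]] * smoker
  set.seed(stage_seed(seed, "status"))
  case <- rbinom(n_source, 1L, plogis(lp)) == 1L

  if (sum(case) < config$n_cases)
    stop(data_error(sprintf(
      "source population yielded %d cases but %d requested; increase source_multiplier or the baseline risk",
      sum(case), config$n_cases)))
  if (sum(!case) < config$n_controls)
    stop(data_error(sprintf(
      "source population yielded %d controls but %d requested; increase source_multiplier or lower the baseline risk",
      sum(!case), config$n_controls)))

  set.seed(stage_seed(seed, "sampling"))
  keep <- c(sample(which(case), config$n_cases),
            sample(which(!case), config$n_controls))
  keep <- sort(keep)

  subjects <- data.table::data.table(
    subject_id = sprintf("S%05d", seq_along(keep)),
    status = ifelse(case[keep], "case", "control"),
    age_years = age[keep],
    sex = ifelse(male[keep] == 1L, "male", "female"),
    smoker_ever = smoker[keep] == 1L,
    index_year = index_year[keep],
    genotype = genotype[keep],
    true_exposed = e_true[keep],
    rural = rural[keep]
  )

  addresses <- build_address_table(subjects, res$x[keep], res$y[keep],
                                   occ_x[keep], occ_y[keep], config, seed)

  structure(list(subjects = subjects, addresses = addresses, config = config),
            class = "cohort", beta = b, seed = seed,
            source_prevalence = mean(case), source_exposed = mean(e_true))
}

# Residences: rural subjects uniform in the agricultural zone, others uniform
# over the rest of the region (vectorized rejection sampling).
place_residences <- function(n, rural, region, ag_zone) {
  x <- runif(n, region[1], region[2])
  y <- runif(n, region[3], region[4])
  in_ag <- function(x, y) x >= ag_zone[1] & x <= ag_zone[2] &
    y >= ag_zone[3] & y <= ag_zone[4]
  x[rural] <- runif(sum(rural), ag_zone[1], ag_zone[2])
  y[rural] <- runif(sum(rural), ag_zone[3], ag_zone[4])
  bad <- which(!rural & in_ag(x, y))
  tries <- 0L
  while (length(bad) && tries < 1000L) {
    x[bad] <- runif(length(bad), region[1], region[2])
    y[bad] <- runif(length(bad), region[3], region[4])
    bad <- bad[in_ag(x[bad], y[bad])]
    tries <- tries + 1L
  }
  if (length(bad))
    stop(config_error("agricultural zone covers the region; cannot place non-rural residences"))
  list(x = x, y = y)
}

# Long address-history table with independent Bernoulli missingness per
# (subject, year, setting); locations are constant over years in the
# synthetic world, but the table format supports moving addresses.
build_address_table <- function(subjects, res_x, res_y, occ_x, occ_y,
                                config, seed) {
  n <- nrow(subjects)
  n_years <- subjects$index_year - config$start_year + 1L
  sub_rep <- rep.int(seq_len(n), n_years)
  year <- sequence(n_years) - 1L + config$start_year
  adr <- data.table::data.table(
    subject_id = rep(subjects$subject_id[sub_rep], 2L),
    year = rep(year, 2L),
    setting = rep(c("residential", "occupational"), each = length(year)),
    x_m = c(res_x[sub_rep], occ_x[sub_rep]),
    y_m = c(res_y[sub_rep], occ_y[sub_rep])
  )
  set.seed(stage_seed(seed, "missingness"))
  miss <- rbinom(nrow(adr), 1L, config$address_missing_rate) == 1L
  adr[miss, c("x_m", "y_m") := list(NA_real_, NA_real_)]
  data.table::setorder(adr, subject_id, setting, year)
  adr[]
}

# True exposure classification on the full-information source population:
# window averages from constant address points, per-(pesticide, setting)
# medians among positive values across the whole source population (status
# does not exist yet at generation time), then the class-level rule.
true_class_exposure <- function(points, focal_apps, config) {
  n <- max(points$idx)
  if (nrow(focal_apps) == 0L) return(integer(n))
  wa <- window_averages_for_points(points, focal_apps, config$start_year,
                                   lag_years = 10L, radius_m = 500)
  if (nrow(wa) == 0L) return(integer(n))
  wa <- wa[wa$window_average > 0, ]
  thr <- wa[, list(threshold = stats::median(window_average)),
            by = c("pesticide_id", "setting")]
  wa <- merge(wa, thr, by = c("pesticide_id", "setting"))
  wa$high <- wa$window_average >= wa$threshold
  # combine settings: exposed to a pesticide if high at either address
  per_pest <- wa[, list(high = any(high)), by = c("idx", "pesticide_id")]
  counts <- per_pest[, list(n_high = sum(high)), by = "idx"]
  e <- integer(n)
  if (config$focal_class == "pyrethroid") {
    e[counts$idx[counts$n_high >= 1L]] <- 1L
  } else if (config$focal_class == "paraquat") {
    e[counts$idx[counts$n_high >= 1L]] <- 1L
  } else {
    pos <- counts$n_high[counts$n_high >= 1L]
    if (length(pos)) {
      med <- stats::median(pos)
      e[counts$idx[counts$n_high >= med]] <- 1L
    }
  }
  e
}

# Grid-binning neighbour search: all (point, record) pairs within radius r,
# optionally requiring integer keys (e.g. calendar year) to match. Points and
# records are bucketed into r-sized cells so only the 3x3 neighbourhood of
# each cell is compared; exact squared-distance filtering follows.
radius_pairs <- function(px, py, ax, ay, r, pkey = NULL, akey = NULL) {
  if (!length(px) || !length(ax))
    return(data.table::data.table(pt = integer(), app = integer()))
  P <- data.table::data.table(pt = seq_along(px),
                              cx = as.integer(floor(px / r)),
                              cy = as.integer(floor(py / r)),
                              k = if (is.null(pkey)) 0L else as.integer(pkey))
  A <- data.table::data.table(app = seq_along(ax),
                              cx = as.integer(floor(ax / r)),
                              cy = as.integer(floor(ay / r)),
                              k = if (is.null(akey)) 0L else as.integer(akey))
  out <- vector("list", 9L)
  i <- 0L
  for (dx in -1:1) for (dy in -1:1) {
    i <- i + 1L
    Ashift <- data.table::data.table(app = A$app, cx = A$cx + dx,
                                     cy = A$cy + dy, k = A$k)
    m <- merge(P, Ashift, by = c("cx", "cy", "k"), allow.cartesian = TRUE)
    if (nrow(m)) out[[i]] <- m[, c("pt", "app")]
  }
  cand <- data.table::rbindlist(out)
  if (nrow(cand) == 0L) return(cand)
  keep <- (px[cand$pt] - ax[cand$app])^2 + (py[cand$pt] - ay[cand$app])^2 <= r^2
  cand[keep]
}

# Vectorized window averages for constant address points (no missingness):
# mean over the window [start_year, index_year - lag] of annual buffer sums of
# pounds-per-acre within radius_m. Only strictly positive rows are returned.
window_averages_for_points <- function(points, apps, start_year, lag_years,
                                       radius_m) {
  lpa <- apps$pounds / apps$acres
  pairs <- radius_pairs(points$x, points$y, apps$x_m, apps$y_m, radius_m)
  if (nrow(pairs) == 0L)
    return(data.table::data.table(idx = integer(), setting = character(),
                                  pesticide_id = character(),
                                  window_average = numeric()))
  pairs[, `:=`(idx = points$idx[pt], setting = points$setting[pt],
               index_year = points$index_year[pt],
               year = apps$year[app], pesticide_id = apps$pesticide_id[app],
               lpa = lpa[app])]
  pairs <- pairs[year >= start_year & year <= index_year - lag_years]
  if (nrow(pairs) == 0L)
    return(data.table::data.table(idx = integer(), setting = character(),
                                  pesticide_id = character(),
                                  window_average = numeric()))
  out <- pairs[, list(total = sum(lpa), index_year = index_year[1L]),
               by = c("idx", "setting", "pesticide_id")]
  out[, window_average := total / (index_year - lag_years - start_year + 1L)]
  out[, c("total", "index_year") := NULL]
  out[]
}

#' @export
print.cohort <- function(x, ...) {
  s <- x$subjects
  cat(sprintf("Synthetic case-control cohort: %d cases, %d controls\n",
              sum(s$status == "case"), sum(s$status == "control")))
  cat(sprintf("  genotypes: AA %d / AG %d / GG %d; true exposed: %.1f%%\n",
              sum(s$genotype == "AA"), sum(s$genotype == "AG"),
              sum(s$genotype == "GG"), 100 * mean(s$true_exposed)))
  cat(sprintf("  address rows: %d (%.1f%% un-geocoded)\n", nrow(x$addresses),
              100 * mean(is.na(x$addresses$x_m))))
  invisible(x)
}

#' Write or read the pipeline's CSV tables
#'
#' `write_cohort_csvs()` writes `applications.csv`, `addresses.csv` and
#' `subjects.csv` with fixed headers; `read_cohort_csvs()` reads them back.
#' Missing geocodes are empty fields in `addresses.csv`.
#'
#' @param cohort a `cohort` from [generate_cohort()].
#' @param applications application table.
#' @param dir output directory (created if needed).
#' @return The directory (write) or a list with `applications`, `addresses`,
#'   `subjects` (read).
#' @export
write_cohort_csvs <- function(cohort, applications, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  data.table::fwrite(applications, file.path(dir, "applications.csv"))
  data.table::fwrite(cohort$addresses, file.path(dir, "addresses.csv"))
  subj <- cohort$subjects[, c("subject_id", "status", "age_years", "sex",
                              "smoker_ever", "index_year", "genotype")]
  data.table::fwrite(subj, file.path(dir, "subjects.csv"))
  invisible(dir)
}

#' @rdname write_cohort_csvs
#' @export
read_cohort_csvs <- function(dir) {
  list(
    applications = data.table::fread(file.path(dir, "applications.csv")),
    addresses = data.table::fread(file.path(dir, "addresses.csv")),
    subjects = data.table::fread(file.path(dir, "subjects.csv"))
  )
}
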