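#' Exposure-assessment configuration
#'
#' Parameters of the ambient-exposure procedure: the buffer radius around an
#' address within which applications count, the first year of the application
#' record, the lag subtracted from the index year to close the exposure
#' window, how residential and occupational exposure are combined, and
#' whether per-pesticide "exposed" means at-or-above the exposed-control
#' median (`"median"`, the default) or any non-zero contact (`"any"`).
#'
#' @param radius_m buffer radius in metres (closed disc).
#' @param start_year first year of the exposure window.
#' @param lag_years years before the index year at which the window ends;
#'   the window is `[start_year, index_year - lag_years]`, both inclusive.
#' @param combine_settings one of `"either"`, `"both"`, `"residential_only"`,
#'   `"occupational_only"`.
#' @param pesticide_rule `"median"` or `"any"`.
#' @return A list of class `exposure_config`.
#' @export
exposure_config <- function(radius_m = 500, start_year = 1974L,
                            lag_years = 10L,
                            combine_settings = c("either", "both",
                                                 "residential_only",
                                                 "occupational_only"),
                            pesticide_rule = c("median", "any")) {
  if (radius_m <= 0) stop(config_error("radius_m must be positive"))
  if (lag_years < 0) stop(config_error("lag_years must be >= 0"))
  structure(list(radius_m = radius_m, start_year = as.integer(start_year),
                 lag_years = as.integer(lag_years),
                 combine_settings = match.arg(combine_settings),
                 pesticide_rule = match.arg(pesticide_rule)),
            class = "exposure_config")
}

#' Annual buffer sum of pounds-per-acre at an address
#'
#' Sums `pounds / acres` over all application records of one pesticide in one
#' calendar year whose location lies within the buffer radius (boundary
#' inclusive) of the query point. An empty sum is 0.
#'
#' @param applications application table (`pesticide_id`, `year`, `x_m`,
#'   `y_m`, `pounds`, `acres`).
#' @param point numeric `c(x, y)` in metres; must be non-missing.
#' @param year calendar year.
#' @param pesticide_id active-ingredient identifier.
#' @param cfg an [exposure_config()].
#' @return Pounds-per-acre sum (numeric scalar).
#' @export
annual_buffer_sum <- function(applications, point, year, pesticide_id,
                              cfg = exposure_config()) {
  if (length(point) != 2L || anyNA(point))
    stop(data_error("query point must be a non-missing (x, y) pair"))
  sel <- applications$pesticide_id == pesticide_id & applications$year == year
  if (!any(sel)) return(0)
  dx <- applications$x_m[sel] - point[1]
  dy <- applications$y_m[sel] - point[2]
  inside <- (dx * dx + dy * dy) <= cfg$radius_m^2
  if (!any(inside)) return(0)
  sum(applications$pounds[sel][inside] / applications$acres[sel][inside])
}

#' Impute un-geocoded years of a yearly exposure series
#'
#' Years with a missing value (no geocoded address) are replaced by the mean
#' of all recorded years of the series; recorded years are unchanged. The
#' result carries a logical `imputed` attribute marking filled years.
#'
#' @param yearly_values numeric vector named by year, `NA` for missing years.
#' @return The completed vector with attribute `imputed`.
#' @export
impute_missing_years <- function(yearly_values) {
  miss <- is.na(yearly_values)
  if (all(miss))
    stop(model_error("all years missing: exposure undefined for this series",
                     subclass = "ambientgxe_undefined_exposure"))
  out <- yearly_values
  out[miss] <- mean(yearly_values[!miss])
  attr(out, "imputed") <- miss
  out
}

#' Study-window average of a yearly exposure series
#'
#' Arithmetic mean of the (imputed) yearly pounds-per-acre values over the
#' window `[start_year, index_year - lag_years]`, both endpoints inclusive.
#'
#' @param yearly_values numeric vector named by calendar year (complete over
#'   the window).
#' @param index_year the subject's index year (diagnosis or interview).
#' @param cfg an [exposure_config()].
#' @return Pounds-per-acre per year (numeric scalar).
#' @export
window_average <- function(yearly_values, index_year, cfg = exposure_config()) {
  last <- index_year - cfg$lag_years
  if (last < cfg$start_year)
    stop(data_error(sprintf(
      "invalid window: index year %d with lag %d ends before start year %d",
      index_year, cfg$lag_years, cfg$start_year)))
  window <- seq(cfg$start_year, last)
  yrs <- as.integer(names(yearly_values))
  if (!all(window %in% yrs))
    stop(data_error("yearly series does not cover the exposure window"))
  mean(yearly_values[match(window, yrs)])
}

#' Window-average exposure profiles for a cohort
#'
#' The observed exposure-assessment pipeline: for every subject, setting and
#' pesticide, annual buffer sums at the geocoded address of each recorded
#' year are averaged over the exposure window, with un-geocoded years imputed
#' at the subject's recorded-year mean (equivalently: the mean over recorded
#' window years). Subjects with no recorded window year at either setting
#' have undefined exposure and are returned in `excluded`.
#'
#' @param applications application table.
#' @param addresses address-history table (`subject_id`, `year`, `setting`,
#'   `x_m`, `y_m`; `NA` coordinates mark un-geocoded years).
#' @param subjects subject table (needs `subject_id`, `index_year`).
#' @param cfg an [exposure_config()].
#' @return A list with `profiles` (strictly positive window averages:
#'   `subject_id`, `setting`, `pesticide_id`, `window_average`), `coverage`
#'   (recorded/missing window-year counts per subject and setting) and
#'   `excluded` (`subject_id`, `reason`).
#' @export
compute_exposure_profiles <- function(applications, addresses, subjects,
                                      cfg = exposure_config()) {
  adr <- data.table::as.data.table(addresses)
  sub <- data.table::as.data.table(subjects)
  apps <- data.table::as.data.table(applications)
  adr <- merge(adr, sub[, c("subject_id", "index_year")], by = "subject_id")
  adr <- adr[year >= cfg$start_year & year <= index_year - cfg$lag_years]

  coverage <- adr[, list(n_recorded = sum(!is.na(x_m)),
                         n_missing = sum(is.na(x_m))),
                  by = c("subject_id", "setting")]
  tot <- coverage[, list(n_recorded = sum(n_recorded)), by = "subject_id"]
  excluded <- data.table::data.table(
    subject_id = tot$subject_id[tot$n_recorded == 0L],
    reason = "no_recorded_address_years")

  rec <- adr[!is.na(x_m)]
  pairs <- match_pairs_by_year(rec, apps, cfg$radius_m)
  if (nrow(pairs)) {
    sums <- pairs[, list(total = sum(lpa)),
                  by = c("subject_id", "setting", "pesticide_id")]
    sums <- merge(sums, coverage, by = c("subject_id", "setting"))
    # imputing missing years at the recorded-year mean and averaging over the
    # full window reduces to the mean over recorded window years
    sums[, window_average := total / n_recorded]
    profiles <- sums[window_average > 0,
                     c("subject_id", "setting", "pesticide_id", "window_average")]
  } else {
    profiles <- data.table::data.table(subject_id = character(),
                                       setting = character(),
                                       pesticide_id = character(),
                                       window_average = numeric())
  }
  list(profiles = profiles[order(subject_id, setting, pesticide_id)],
       coverage = coverage, excluded = excluded)
}

# Proximity matching between recorded address rows and application records in
# the same calendar year (grid-binned neighbour search); returns one row per
# (address-row, application) pair within the radius, carrying pounds-per-acre.
match_pairs_by_year <- function(rec, apps, radius_m) {
  hit <- radius_pairs(rec$x_m, rec$y_m, apps$x_m, apps$y_m, radius_m,
                      pkey = rec$year, akey = apps$year)
  if (nrow(hit) == 0L)
    return(data.table::data.table(subject_id = character(), setting = character(),
                                  pesticide_id = character(), lpa = numeric()))
  data.table::data.table(
    subject_id = rec$subject_id[hit$pt],
    setting = rec$setting[hit$pt],
    pesticide_id = apps$pesticide_id[hit$app],
    lpa = apps$pounds[hit$app] / apps$acres[hit$app])
}

#' Dichotomize one pesticide's window averages at the exposed-control median
#'
#' The threshold is the sample median of window averages among controls with
#' strictly positive exposure; a subject is `high` iff their value is at or
#' above it. Values of exactly zero are `unexposed`; positive values below
#' the threshold are `exposed_low`.
#'
#' @param values numeric window averages, one per subject.
#' @param is_control logical, same length.
#' @return A list with `label` (factor `unexposed`/`exposed_low`/`high`) and
#'   `threshold`.
#' @export
dichotomize_pesticide <- function(values, is_control) {
  stopifnot(length(values) == length(is_control))
  exposed_ctrl <- values[is_control & values > 0]
  if (length(exposed_ctrl) == 0L)
    stop(model_error("no exposed control: dichotomization threshold undefined",
                     subclass = "ambientgxe_threshold_undefined"))
  thr <- stats::median(exposed_ctrl)
  label <- ifelse(values >= thr, "high",
                  ifelse(values > 0, "exposed_low", "unexposed"))
  list(label = factor(label, levels = c("unexposed", "exposed_low", "high")),
       threshold = thr)
}

#' Class-level exposure category from per-pesticide exposure counts
#'
#' For organophosphates and dithiocarbamates a subject is `high` iff their
#' count of class pesticides with high exposure is at or above the median
#' count among controls with at least one; pyrethroid exposure is `any` iff
#' the count is one or more; paraquat (a single agent) is `exposed` iff its
#' own label is high.
#'
#' @param counts integer per-subject counts of class pesticides at/above
#'   their thresholds.
#' @param is_control logical, same length.
#' @param chemical_class one of the four recognised classes.
#' @return A list with `category` (factor, levels depending on class),
#'   `exposed` (0/1 analysis coding) and `threshold` (class count threshold,
#'   `NA` for pyrethroid/paraquat).
#' @export
classify_class_exposure <- function(counts, is_control, chemical_class) {
  stopifnot(length(counts) == length(is_control))
  chemical_class <- match.arg(chemical_class, CHEMICAL_CLASSES)
  if (chemical_class == "pyrethroid") {
    exposed <- as.integer(counts >= 1L)
    return(list(category = factor(ifelse(exposed == 1L, "any", "none"),
                                  levels = c("none", "any")),
                exposed = exposed, threshold = NA_real_))
  }
  if (chemical_class == "paraquat") {
    exposed <- as.integer(counts >= 1L)
    return(list(category = factor(ifelse(exposed == 1L, "exposed", "unexposed"),
                                  levels = c("unexposed", "exposed")),
                exposed = exposed, threshold = NA_real_))
  }
  ctrl_counts <- counts[is_control & counts >= 1L]
  if (length(ctrl_counts) == 0L)
    stop(model_error(sprintf("no control exposed to any %s: class threshold undefined",
                             chemical_class),
                     subclass = "ambientgxe_threshold_undefined"))
  thr <- stats::median(ctrl_counts)
  exposed <- as.integer(counts >= thr)
  list(category = factor(ifelse(exposed == 1L, "high", "low_or_none"),
                         levels = c("low_or_none", "high")),
       exposed = exposed, threshold = thr)
}

#' Full exposure classification for a cohort
#'
#' Runs per-pesticide dichotomization (thresholds from exposed controls, per
#' pesticide and setting), combines settings, counts class pesticides each
#' subject is exposed to, and applies the class-level category rule.
#'
#' @param profiles positive window averages from
#'   [compute_exposure_profiles()].
#' @param subjects subject table (needs `subject_id`, `status`).
#' @param pesticide_classes mapping table (`pesticide_id`,
#'   `chemical_class`), e.g. `unique(applications[, c("pesticide_id",
#'   "chemical_class")])`.
#' @param cfg an [exposure_config()].
#' @param all_classes chemical classes to report; defaults to those present
#'   in `pesticide_classes`. Classes without any application still get rows
#'   (all counts zero).
#' @return A list with `class_exposure` (one row per subject x class:
#'   `n_pesticides_exposed`, `category`, `exposed`), `thresholds`
#'   (per-pesticide and per-setting medians), and `undefined_classes`
#'   (classes with no exposed control, for which every subject is coded
#'   unexposed and downstream fits are inestimable).
#' @export
compute_class_exposure <- function(profiles, subjects, pesticide_classes,
                                   cfg = exposure_config(),
                                   all_classes = NULL) {
  sub <- data.table::as.data.table(subjects)
  prof <- data.table::as.data.table(profiles)
  pc <- unique(data.table::as.data.table(pesticide_classes)[
    , c("pesticide_id", "chemical_class")])
  is_ctrl <- sub$status == "control"
  names(is_ctrl) <- sub$subject_id

  prof <- switch(cfg$combine_settings,
    residential_only = prof[setting == "residential"],
    occupational_only = prof[setting == "occupational"],
    prof)

  # per-(pesticide, setting) thresholds among exposed controls
  prof[, control := is_ctrl[subject_id]]
  thr <- prof[control == TRUE & window_average > 0,
              list(threshold = stats::median(window_average)),
              by = c("pesticide_id", "setting")]
  prof <- merge(prof, thr, by = c("pesticide_id", "setting"), all.x = TRUE)
  if (cfg$pesticide_rule == "any") {
    prof[, high := window_average > 0]
  } else {
    prof[, high := !is.na(threshold) & window_average >= threshold]
  }

  per_pest <- if (cfg$combine_settings == "both") {
    p <- prof[, list(high = all(c("residential", "occupational") %in% setting[high])),
              by = c("subject_id", "pesticide_id")]
    p
  } else {
    prof[, list(high = any(high)), by = c("subject_id", "pesticide_id")]
  }
  per_pest <- merge(per_pest, pc, by = "pesticide_id")
  counts <- per_pest[high == TRUE, list(n = .N),
                     by = c("subject_id", "chemical_class")]

  if (is.null(all_classes))
    all_classes <- intersect(CHEMICAL_CLASSES, unique(pc$chemical_class))
  if (!length(all_classes))
    stop(data_error("no chemical classes to classify"))
  grid <- data.table::CJ(subject_id = sub$subject_id,
                         chemical_class = all_classes)
  grid <- merge(grid, counts, by = c("subject_id", "chemical_class"), all.x = TRUE)
  grid[is.na(n), n := 0L]

  out <- vector("list", 0L)
  undefined <- character()
  for (cl in unique(grid$chemical_class)) {
    g <- grid[chemical_class == cl]
    cls <- tryCatch(
      classify_class_exposure(g$n, is_ctrl[g$subject_id], cl),
      ambientgxe_threshold_undefined = function(e) NULL)
    if (is.null(cls)) {
      undefined <- c(undefined, cl)
      cls <- list(category = factor(rep(NA_character_, nrow(g))),
                  exposed = rep(0L, nrow(g)), threshold = NA_real_)
    }
    out[[cl]] <- data.table::data.table(
      subject_id = g$subject_id, chemical_class = cl,
      n_pesticides_exposed = g$n,
      category = as.character(cls$category), exposed = cls$exposed)
  }
  list(class_exposure = data.table::rbindlist(out),
       thresholds = thr, undefined_classes = undefined)
}
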