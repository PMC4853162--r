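# Shared fixtures and independent oracles for the test suite.

# Configuration with a single active chemical class (pyrethroids by default),
# used by the simulation-heavy tests to keep replicates cheap.
single_class_config <- function(events_per_year = 40, class = "pyrethroid", ...) {
  cl <- default_class_params()
  for (nm in names(cl)) cl[[nm]]$events_per_year <- 0
  cl[[class]]$events_per_year <- events_per_year
  sim_config(classes = cl, focal_class = class, ...)
}

# Null disease-model coefficients (intercept only).
null_beta <- function(b0 = 0) {
  c(b0 = b0, bg = 0, be = 0, bge = 0, bage = 0, bsex = 0, bsmoke = 0)
}

# Brute-force buffer sum: plain double loop over every application record.
# Deliberately naive and independent of the package's neighbour search.
brute_buffer_sum <- function(applications, point, year, pesticide_id, radius) {
  total <- 0
  for (i in seq_len(nrow(applications))) {
    row <- applications[i, ]
    if (row$pesticide_id != pesticide_id) next
    if (row$year != year) next
    d <- sqrt((row$x_m - point[1])^2 + (row$y_m - point[2])^2)
    if (d <= radius) total <- total + row$pounds / row$acres
  }
  total
}

# Exact Hardy-Weinberg enumeration oracle built on the recurrence between
# successive heterozygote counts (independent of the package's log-factorial
# route). Returns the exact conditional p-value.
hwe_enum_p <- function(n_AA, n_AG, n_GG) {
  n <- n_AA + n_AG + n_GG
  n_g <- 2 * n_GG + n_AG
  n_a <- 2 * n - n_g
  rare <- min(n_g, n_a)
  if (rare == 0) return(1)
  het <- seq(rare %% 2, rare, by = 2)
  # unnormalised probabilities via the ratio
  # P(h+2)/P(h) = 4 * nAA(h) * nGG(h) / ((h+2)(h+1))
  w <- numeric(length(het))
  w[1] <- 1
  for (i in seq_along(het)[-1]) {
    h <- het[i - 1]
    naa <- (n_a - h) / 2
    ngg <- (n_g - h) / 2
    w[i] <- w[i - 1] * 4 * naa * ngg / ((h + 2) * (h + 1))
  }
  w <- w / sum(w)
  obs <- w[match(n_AG, het)]
  sum(w[w <= obs * (1 + 1e-12)])
}

# Woolf's closed-form log odds ratio and standard error for a 2x2 table
# (exposed cases a, exposed controls b, unexposed cases c, unexposed controls d).
woolf_2x2 <- function(a, b, c, d) {
  list(log_or = log((a * d) / (b * c)),
       se = sqrt(1 / a + 1 / b + 1 / c + 1 / d))
}

# Expand a 2x2 table of counts into subject-level outcome and exposure vectors.
expand_2x2 <- function(exp_case, exp_ctrl, unexp_case, unexp_ctrl) {
  y <- c(rep(1, exp_case), rep(0, exp_ctrl), rep(1, unexp_case), rep(0, unexp_ctrl))
  e <- c(rep(1, exp_case + exp_ctrl), rep(0, unexp_case + unexp_ctrl))
  list(y = y, e = e)
}

# Minimal synthetic subject table with independently drawn covariates, used
# where the spatial machinery is irrelevant.
quick_subjects <- function(n, q = 0.42, p_case = 0.5, seed = 1) {
  set.seed(seed)
  data.frame(
    subject_id = sprintf("Q%05d", seq_len(n)),
    status = ifelse(runif(n) < p_case, "case", "control"),
    age_years = rnorm(n, 66, 10),
    sex = ifelse(runif(n) < 0.5, "male", "female"),
    smoker_ever = runif(n) < 0.45,
    index_year = sample(2000:2007, n, replace = TRUE),
    genotype = generate_genotypes(n, q),
    stringsAsFactors = FALSE)
}
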