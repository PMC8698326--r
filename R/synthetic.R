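# Synthetic cohort generator ---------------------------------------------
#
# Emulates the statistical structure the analysis pipeline assumes: a
# two-era mixture of beverage classes, log-normal hair concentrations
# censored at the quantification limit, a Gaussian-copula nicotine/
# cotinine dependence that strengthens with age, a NE-SW caffeine
# gradient in the later era, and a pipe-ownership model tied to tobacco
# load and to distance from the south-western entry route.  All defaults
# are synthetic, fitted by eye to the reference cohort's strata; they are
# not estimates from the source data.

#' Specification for the synthetic cohort generator
#'
#' @param n_individuals Cohort size (default 200).
#' @param prop_after_1800 Era mixture: probability of the later era
#'   (default 15/47, the reference cohort's share).
#' @param beverage_probs 2 x 7 matrix of beverage-class probabilities
#'   (rows `before_1800`, `after_1800`; columns the drink labels).  Rows
#'   must sum to 1.  Defaults follow the reference cohort's era trends
#'   (green tea common only before 1800, black tea dominant after).
#' @param conc_meanlog,conc_sdlog Log-normal location/scale (log pg/mg)
#'   per analyte for a "present" analyte.
#' @param black_tea_boost Added to the methylxanthine meanlog for
#'   black-tea drinkers of the later era (heavy users).
#' @param nic_cot_corr_by_age Target nicotine/cotinine correlation (on
#'   the latent normal scale) per age class, increasing with age.
#' @param censor_at_pg_mg Censoring limit per analyte (pg/mg): simulated
#'   values below it are reported as non-detects.
#' @param geo List with `lat_range`, `lon_range` (uniform site rhomboid),
#'   `gradient_ref` (point the gradient points away from; default the NE
#'   gateway), `gradient_strength` (drop in caffeine meanlog across the
#'   distance span, log units), `gradient_era`, and `access` (intercept
#'   and slope, on the logit scale, of the probability that
#'   caffeine-bearing beverages are available as a function of normalized
#'   distance from `gradient_ref`; gradient-era individuals draw their
#'   beverage class conditional on that availability, so both the share
#'   of caffeine consumers and the consumed amount decline away from the
#'   entry point).  Setting `gradient_strength = 0` and `access = NULL`
#'   disables the gradient.
#' @param pipe_model List with `intercept`, `b_tobacco` (per log pg/mg of
#'   tobacco index) and `b_sw` (pull towards the south-western corner) on
#'   the logit scale.
#' @param seed Integer seed; the whole generation is a pure function of
#'   the spec (including its seed).
#' @return A validated list of class `xeno_genspec`.
#' @export
generator_spec <- function(n_individuals = 200,
                           prop_after_1800 = 15 / 47,
                           beverage_probs = NULL,
                           conc_meanlog = c(theobromine = 4.6,
                                            caffeine = 3.6,
                                            theophylline = 3.4,
                                            nicotine = 4.2, cotinine = 4.6),
                           conc_sdlog = c(theobromine = 1.0, caffeine = 1.0,
                                          theophylline = 0.9,
                                          nicotine = 1.1, cotinine = 1.3),
                           black_tea_boost = 1.5,
                           nic_cot_corr_by_age = c("0-15" = 0.35,
                                                   "15-30" = 0.50,
                                                   "30-50" = 0.65,
                                                   ">50" = 0.90),
                           censor_at_pg_mg = c(theobromine = 10,
                                               caffeine = 10,
                                               theophylline = 10,
                                               nicotine = 10, cotinine = 10),
                           geo = list(lat_range = c(61, 67),
                                      lon_range = c(117, 145),
                                      gradient_ref = c(lat = 66.45,
                                                       lon = 143.22),
                                      gradient_strength = 3.0,
                                      gradient_era = "after_1800",
                                      access = c(intercept = 3.5,
                                                 slope = 9)),
                           pipe_model = list(intercept = -5, b_tobacco = 0.6,
                                             b_sw = 1.5),
                           seed = 1L) {
  if (is.null(beverage_probs)) {
    beverage_probs <- rbind(
      before_1800 = c(herbal_tea = 0.16, green_tea = 0.25, black_tea = 0.19,
                      coffee = 0.04, coffee_and_theophylline = 0.06,
                      theophylline_only = 0.05, nothing = 0.25),
      after_1800 = c(herbal_tea = 0.20, green_tea = 0.00, black_tea = 0.53,
                     coffee = 0.13, coffee_and_theophylline = 0.07,
                     theophylline_only = 0.07, nothing = 0.00))
  }
  stopifnot(
    n_individuals >= 1,
    prop_after_1800 >= 0, prop_after_1800 <= 1,
    identical(colnames(beverage_probs), XENO_DRINKS),
    all(abs(rowSums(beverage_probs) - 1) < 1e-8),
    all(beverage_probs >= 0),
    all(conc_sdlog > 0),
    all(nic_cot_corr_by_age > -1), all(nic_cot_corr_by_age < 1),
    all(censor_at_pg_mg > 0)
  )
  structure(list(
    n_individuals = as.integer(n_individuals),
    prop_after_1800 = prop_after_1800,
    beverage_probs = beverage_probs,
    conc_meanlog = conc_meanlog, conc_sdlog = conc_sdlog,
    black_tea_boost = black_tea_boost,
    nic_cot_corr_by_age = nic_cot_corr_by_age,
    censor_at_pg_mg = censor_at_pg_mg,
    geo = geo, pipe_model = pipe_model,
    seed = as.integer(seed)
  ), class = "xeno_genspec")
}

# Which methylxanthines a beverage class carries.
DRINK_PRESENCE <- list(
  herbal_tea = "theobromine",
  green_tea = c("theobromine", "caffeine"),
  black_tea = c("theobromine", "caffeine", "theophylline"),
  coffee = "caffeine",
  coffee_and_theophylline = c("caffeine", "theophylline"),
  theophylline_only = "theophylline",
  nothing = character()
)

#' Generate a synthetic cohort with geography
#'
#' Draws a cohort from a [generator_spec()]: era and beverage class per
#' individual, log-normal concentrations for the class's analytes,
#' copula-correlated nicotine/cotinine, uniform sites with a NE-SW
#' caffeine gradient in the configured era, pipe ownership from the
#' logistic pipe model, and censoring of values below the per-analyte
#' limit (reported as non-detects).  Identical spec (including seed)
#' gives identical output.
#'
#' @param spec A `xeno_genspec`.
#' @param dir Optional output directory; when given, `cohort.csv`,
#'   `sites.csv` and `truth.json` are written there.
#' @return List of class `xeno_simulation` with `cohort` (an
#'   `xeno_cohort`), `sites` (tibble `sample_id, site_label, lat_deg,
#'   lon_deg, region`), and `truth` (latent classes, era, age, latent
#'   parameters, seed).
#' @export
#' @examples
#' sim <- generate_cohort(generator_spec(n_individuals = 50, seed = 7))
#' table(sim$truth$drink_class)
generate_cohort <- function(spec, dir = NULL) {
  stopifnot(inherits(spec, "xeno_genspec"))
  old <- get_rng_state(); on.exit(set_rng_state(old))
  set.seed(spec$seed)
  n <- spec$n_individuals
  ages <- names(spec$nic_cot_corr_by_age)

  era <- sample(c("before_1800", "after_1800"), n, replace = TRUE,
                prob = c(1 - spec$prop_after_1800, spec$prop_after_1800))
  dating_start <- ifelse(era == "after_1800",
                         sample(c(1800L, 1850L), n, replace = TRUE),
                         sample(c(1700L, 1750L), n, replace = TRUE))
  dating_end <- dating_start + 50L
  age_class <- sample(ages, n, replace = TRUE,
                      prob = c(0.2, 0.27, 0.3, 0.23))
  sex <- sample(c("M", "F", "Indet"), n, replace = TRUE,
                prob = c(0.45, 0.45, 0.10))
  drink <- vapply(era, function(e) {
    sample(XENO_DRINKS, 1, prob = spec$beverage_probs[e, ])
  }, "")

  # sites: uniform in the study rhomboid
  lat <- runif(n, spec$geo$lat_range[1], spec$geo$lat_range[2])
  lon <- runif(n, spec$geo$lon_range[1], spec$geo$lon_range[2])
  d_ne <- great_circle_km(lat, lon, spec$geo$gradient_ref[["lat"]],
                          spec$geo$gradient_ref[["lon"]])
  d_ne_norm <- (d_ne - min(d_ne)) / max(diff(range(d_ne)), 1e-9)
  region <- ifelse(lat >= mean(spec$geo$lat_range),
                   ifelse(lon >= mean(spec$geo$lon_range), "North", "West"),
                   ifelse(lon >= mean(spec$geo$lon_range), "East", "South"))

  # trade-route availability: in the gradient era the chance of drinking a
  # caffeine-bearing beverage at all declines with distance from the
  # gradient reference; the beverage class is drawn conditionally on that
  caffeinated <- vapply(DRINK_PRESENCE, function(p) "caffeine" %in% p,
                        TRUE)
  if (!is.null(spec$geo$access)) {
    p_access <- stats::plogis(spec$geo$access[["intercept"]] -
                                spec$geo$access[["slope"]] * d_ne_norm)
    for (i in which(era == spec$geo$gradient_era)) {
      has_caf <- runif(1) < p_access[i]
      pr <- spec$beverage_probs[era[i], ]
      pr[caffeinated != has_caf] <- 0
      if (sum(pr) > 0) drink[i] <- sample(XENO_DRINKS, 1, prob = pr)
    }
  }

  conc <- matrix(NA_real_, n, length(XENO_ANALYTES),
                 dimnames = list(NULL, XENO_ANALYTES))
  for (i in seq_len(n)) {
    present <- DRINK_PRESENCE[[drink[i]]]
    for (a in present) {
      mu <- spec$conc_meanlog[[a]]
      if (drink[i] == "black_tea" && era[i] == "after_1800") {
        mu <- mu + spec$black_tea_boost
      }
      if (a == "caffeine" && era[i] == spec$geo$gradient_era) {
        mu <- mu + spec$geo$gradient_strength * (1 - d_ne_norm[i]) # NE high
      }
      conc[i, a] <- rlnorm(1, mu, spec$conc_sdlog[[a]])
    }
  }
  # nicotine/cotinine via Gaussian copula at the age-specific correlation
  for (i in seq_len(n)) {
    rho <- spec$nic_cot_corr_by_age[[age_class[i]]]
    z1 <- rnorm(1)
    z2 <- rho * z1 + sqrt(1 - rho^2) * rnorm(1)
    conc[i, "nicotine"] <- exp(spec$conc_meanlog[["nicotine"]] +
                                 spec$conc_sdlog[["nicotine"]] * z1)
    conc[i, "cotinine"] <- exp(spec$conc_meanlog[["cotinine"]] +
                                 spec$conc_sdlog[["cotinine"]] * z2)
  }
  # censor below the limit -> non-detect
  for (a in XENO_ANALYTES) {
    v <- conc[, a]
    v[!is.na(v) & v < spec$censor_at_pg_mg[[a]]] <- NA_real_
    conc[, a] <- v
  }

  tob_idx <- (ifelse(is.na(conc[, "nicotine"]), 0, conc[, "nicotine"]) +
                ifelse(is.na(conc[, "cotinine"]), 0, conc[, "cotinine"])) / 2
  sw <- c(lat = spec$geo$lat_range[1], lon = spec$geo$lon_range[1])
  d_sw <- great_circle_km(lat, lon, sw[["lat"]], sw[["lon"]])
  d_sw_norm <- (d_sw - min(d_sw)) / max(diff(range(d_sw)), 1e-9)
  logit_pipe <- spec$pipe_model$intercept +
    spec$pipe_model$b_tobacco * log1p(tob_idx) -
    spec$pipe_model$b_sw * d_sw_norm
  pipe <- ifelse(rbinom(n, 1, stats::plogis(logit_pipe)) == 1,
                 "simple", "none")

  cohort <- tibble::tibble(
    sample_id = seq_len(n),
    name = sprintf("SIM-%03d", seq_len(n)),
    dating_start = dating_start, dating_end = dating_end,
    sex = factor(sex, levels = XENO_SEX),
    age_class = factor(age_class, levels = XENO_AGE),
    pipe = factor(pipe, levels = XENO_PIPE),
    shaman = runif(n) < 0.1,
    anthracosis = factor("unassessed", levels = XENO_ANTHRACOSIS)
  )
  for (a in XENO_ANALYTES) {
    cohort[[a]] <- round(conc[, a], 1) # reported precision: 0.1 pg/mg
  }
  cohort <- new_cohort(cohort)

  sites <- tibble::tibble(sample_id = seq_len(n),
                          site_label = sprintf("site-%03d", seq_len(n)),
                          lat_deg = lat, lon_deg = lon, region = region)
  truth <- list(n = n, seed = spec$seed, spec = spec,
                era = era, age_class = age_class, drink_class = drink,
                nic_cot_corr_targets = spec$nic_cot_corr_by_age,
                gradient = list(analyte = "caffeine",
                                era = spec$geo$gradient_era,
                                strength = spec$geo$gradient_strength,
                                ref = spec$geo$gradient_ref))
  out <- structure(list(cohort = cohort, sites = sites, truth = truth),
                   class = "xeno_simulation")
  if (!is.null(dir)) {
    dir.create(dir, showWarnings = FALSE, recursive = TRUE)
    write_cohort(cohort, file.path(dir, "cohort.csv"))
    write.csv(sites, file.path(dir, "sites.csv"), row.names = FALSE)
    tr <- truth; tr$spec <- NULL # the spec is not JSON-trivial; keep latents
    jsonlite::write_json(tr, file.path(dir, "truth.json"),
                         auto_unbox = TRUE, digits = NA)
  }
  out
}

#' Check recovery of the generator's latent structure
#'
#' Runs the analysis pipeline on a simulated cohort and compares against
#' the recorded truth: beverage-classifier accuracy vs latent classes
#' (censoring can legitimately erase analytes, so accuracy below 1 is
#' expected at realistic censoring), rank-correlation recovery of the
#' age-specific nicotine/cotinine dependence, and detection of the
#' caffeine gradient against its reference point.
#'
#' @param sim An `xeno_simulation` from [generate_cohort()].
#' @return List with `class_accuracy`, `corr_recovery` (tibble per age
#'   class: target, estimate, error), and `gradient` (rs, p against the
#'   gradient reference in the gradient era).
#' @export
truth_check <- function(sim) {
  stopifnot(inherits(sim, "xeno_simulation"))
  if (!identical(sim$truth$n, nrow(sim$cohort))) {
    stop("truth record does not match cohort size", call. = FALSE)
  }
  calls <- classify_cohort(sim$cohort)
  acc <- mean(as.character(calls$drink) == sim$truth$drink_class)
  est <- corr_by_age_class(sim$cohort, method = "spearman")
  targets <- sim$truth$nic_cot_corr_targets
  corr_recovery <- tibble::tibble(
    age_class = est$age_class,
    n = est$n,
    target = unname(targets[est$age_class]),
    estimate = est$r,
    error = est$r - unname(targets[est$age_class]))
  ref <- as.list(setNames(sim$truth$gradient$ref[c("lat", "lon")],
                          c("lat_deg", "lon_deg")))
  grad <- distance_correlation(sim$cohort, sim$sites, ref,
                               analyte = sim$truth$gradient$analyte,
                               era = sim$truth$gradient$era)
  list(class_accuracy = acc, corr_recovery = corr_recovery,
       gradient = list(rs = grad$rs, p = grad$p, n = grad$n))
}
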