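# Analytical-method validation: weighted quadratic calibration and
# SFTA-style acceptance checks (bias / precision thresholds).

#' Fit a 1/x weighted quadratic calibration curve
#'
#' Fits `response = a*conc^2 + b*conc + c` by weighted least squares with
#' weights `1/conc`, the standard weighting for LC-MS/MS calibration where
#' response variance grows with concentration.  The coefficient of
#' determination is computed on the weighted fit (weighted total sum of
#' squares), and the curve is flagged acceptable iff `r2 >= 0.99`.
#'
#' @param conc Nominal concentrations (ng/mg), all `> 0`, at least 5
#'   distinct levels.
#' @param response Analyte-to-internal-standard peak-area ratios.
#' @param analyte Optional analyte label carried in the result.
#' @return An object of class `xeno_calibration`: list with `coefficients`
#'   (`c`, `b`, `a` as intercept, linear, quadratic), `r2`, `acceptable`,
#'   `analyte`, and the underlying `lm` fit.
#' @export
fit_calibration <- function(conc, response, analyte = NA_character_) {
  stopifnot(length(conc) == length(response))
  if (any(conc <= 0)) stop("calibration concentrations must be > 0")
  if (length(unique(conc)) < 5) {
    stop("at least 5 distinct calibration levels are required")
  }
  w <- 1 / conc
  fit <- lm(response ~ conc + I(conc^2), weights = w)
  fitted <- predict(fit)
  wmean <- sum(w * response) / sum(w)
  ss_res <- sum(w * (response - fitted)^2)
  ss_tot <- sum(w * (response - wmean)^2)
  r2 <- if (ss_tot > 0) 1 - ss_res / ss_tot else 1
  structure(list(
    coefficients = setNames(coef(fit), c("intercept", "linear", "quadratic")),
    r2 = r2,
    acceptable = r2 >= 0.99,
    analyte = analyte,
    weights = w,
    fit = fit
  ), class = "xeno_calibration")
}

#' Back-calculate concentration from a calibration curve
#'
#' Inverts the fitted quadratic; when the quadratic term is negligible the
#' linear inversion is used.  Of the two quadratic roots the one on the
#' increasing branch (standard for calibration) is returned.
#'
#' @param curve An `xeno_calibration`.
#' @param response Response ratios to invert.
#' @return Concentrations (ng/mg).
#' @export
back_calculate <- function(curve, response) {
  cf <- curve$coefficients
  a <- cf[["quadratic"]]; b <- cf[["linear"]]; c0 <- cf[["intercept"]]
  if (abs(a) < 1e-12) return((response - c0) / b)
  disc <- b^2 - 4 * a * (c0 - response)
  disc[disc < 0] <- NA_real_
  r1 <- (-b + sqrt(disc)) / (2 * a)
  r2 <- (-b - sqrt(disc)) / (2 * a)
  # keep the root on the increasing branch (derivative 2*a*x + b > 0)
  ifelse(2 * a * r1 + b > 0, r1, r2)
}

#' Validate an analytical method from replicate measurements
#'
#' Computes per-level relative bias, intra-day and inter-day precision
#' from a replicate table (concentration level x day x replicate), using
#' back-calculated concentrations from a fitted calibration curve.
#' Acceptance follows the usual forensic-toxicology rule: |bias| and CVs
#' below 25% at the LLOQ level and below 20% at all other levels.
#'
#' Intra-day CV is the within-day relative standard deviation pooled
#' across days; inter-day CV is the RSD of the day means.
#'
#' @param replicates Data frame with columns `level_ng_mg`, `day`,
#'   `replicate`, `response`.  At least 3 levels, 2 days and 2 replicates
#'   per day.
#' @param curve An `xeno_calibration` used for back-calculation.
#' @param lloq_level The level treated as the LLOQ (default: lowest).
#' @return An object of class `xeno_validation`: per-level tibble with
#'   `bias_pct`, `cv_intra_pct`, `cv_inter_pct`, `pass`, plus overall
#'   `pass` and `lloq_estimate` (lowest level passing the 25% rule).
#' @export
validate_method <- function(replicates, curve,
                            lloq_level = min(replicates$level_ng_mg)) {
  need <- c("level_ng_mg", "day", "replicate", "response")
  if (!all(need %in% names(replicates))) {
    stop("replicate table needs columns: ", paste(need, collapse = ", "))
  }
  levels_ <- sort(unique(replicates$level_ng_mg))
  if (length(levels_) < 3) stop("at least 3 concentration levels required")
  replicates$conc_bc <- back_calculate(curve, replicates$response)

  per_level <- lapply(levels_, function(lv) {
    d <- replicates[replicates$level_ng_mg == lv, ]
    days <- unique(d$day)
    if (length(days) < 2) stop("at least 2 days required at level ", lv)
    if (any(table(d$day) < 2)) stop("at least 2 replicates/day at level ", lv)
    bias <- 100 * (mean(d$conc_bc) - lv) / lv
    # pooled within-day RSD
    wd_var <- sum(vapply(days, function(dd) {
      x <- d$conc_bc[d$day == dd]
      (length(x) - 1) * stats::var(x)
    }, 0.0)) / sum(table(d$day) - 1)
    cv_intra <- 100 * sqrt(wd_var) / mean(d$conc_bc)
    day_means <- vapply(days, function(dd) mean(d$conc_bc[d$day == dd]), 0.0)
    cv_inter <- 100 * sd(day_means) / mean(day_means)
    lim <- if (lv == lloq_level) 25 else 20
    tibble::tibble(level_ng_mg = lv, bias_pct = bias,
                   cv_intra_pct = cv_intra, cv_inter_pct = cv_inter,
                   threshold_pct = lim,
                   pass = abs(bias) < lim & cv_intra < lim & cv_inter < lim)
  })
  per_level <- do.call(rbind, per_level)
  pass25 <- abs(per_level$bias_pct) < 25 & per_level$cv_intra_pct < 25 &
    per_level$cv_inter_pct < 25
  lloq_est <- if (any(pass25)) min(per_level$level_ng_mg[pass25]) else NA_real_
  structure(list(per_level = per_level, pass = all(per_level$pass),
                 lloq_estimate = lloq_est),
            class = "xeno_validation")
}
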