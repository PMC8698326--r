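# Era-stratified descriptive statistics, methylxanthine-combination
# contingency tests, and logistic-regression analyses.

mx_pattern <- function(cohort) {
  # detection pattern of (theobromine, caffeine, theophylline)
  paste0(detected(cohort$theobromine) + 0L,
         detected(cohort$caffeine) + 0L,
         detected(cohort$theophylline) + 0L)
}

#' Era-stratified detection summary
#'
#' Per-analyte detection counts, per-era methylxanthine combination
#' counts, and detected-only medians/ranges per analyte and era.  Medians
#' deliberately use detected values only (censored cells carry no
#' magnitude); combination counts use detection flags.
#'
#' @param cohort An `xeno_cohort`.
#' @return An object of class `xeno_detection_summary`: list with
#'   `counts` (analyte, n_detected), `era_combos` (era, all_three,
#'   tb_caf_only, tb_only, none, n), and `stats` (analyte x era
#'   detected-only n/median/min/max, `NA` when nothing is detected).
#' @export
#' @examples
#' s <- detection_summary(load_cohort())
#' s$counts
detection_summary <- function(cohort) {
  counts <- tibble::tibble(
    analyte = XENO_ANALYTES,
    n_detected = vapply(XENO_ANALYTES,
                        function(a) sum(detected(cohort[[a]])), 0L)
  )
  era <- if (nrow(cohort)) era_of(cohort) else
    factor(character(), levels = c("before_1800", "after_1800"))
  pat <- mx_pattern(cohort)
  era_combos <- do.call(rbind, lapply(levels(era), function(e) {
    p <- pat[era == e]
    tibble::tibble(era = e,
                   all_three = sum(p == "111"),
                   tb_caf_only = sum(p == "110"),
                   tb_only = sum(p == "100"),
                   none = sum(p == "000"),
                   n = length(p))
  }))
  stats_tab <- do.call(rbind, lapply(XENO_ANALYTES, function(a) {
    do.call(rbind, lapply(levels(era), function(e) {
      v <- cohort[[a]][era == e]
      v <- v[detected(v)]
      tibble::tibble(analyte = a, era = e, n_detected = length(v),
                     median = if (length(v)) median(v) else NA_real_,
                     min = if (length(v)) min(v) else NA_real_,
                     max = if (length(v)) max(v) else NA_real_)
    }))
  }))
  structure(list(counts = counts, era_combos = era_combos,
                 stats = stats_tab),
            class = "xeno_detection_summary")
}

#' Methylxanthine combination counts within one era
#'
#' @param cohort An `xeno_cohort`.
#' @param era `"before_1800"` or `"after_1800"`.
#' @return Tibble of the 8 detection patterns of (theobromine, caffeine,
#'   theophylline) with counts; era size as attribute `era_size`.
#' @export
combo_counts <- function(cohort, era = c("before_1800", "after_1800")) {
  era <- match.arg(era)
  keep <- era_of(cohort) == era
  pat <- mx_pattern(cohort)[keep]
  keys <- names(DRINK_RULES)
  lab <- c("000" = "none", "100" = "TB", "010" = "CAF", "001" = "TP",
           "110" = "TB+CAF", "101" = "TB+TP", "011" = "CAF+TP",
           "111" = "TB+CAF+TP")
  out <- tibble::tibble(
    pattern = unname(lab[keys]),
    count = vapply(keys, function(k) sum(pat == k), 0L, USE.NAMES = FALSE)
  )
  attr(out, "era_size") <- sum(keep)
  out
}

#' Era-contrast contingency test on methylxanthine combinations
#'
#' Builds the 2x2 table era (before/after 1800) x contrast membership and
#' runs a two-sided Fisher exact test (p from summing hypergeometric
#' probabilities no larger than that of the observed table).  Contrasts:
#' * `tb_only_vs_rest` - among individuals carrying at least one
#'   methylxanthine, the theobromine-only pattern vs all other patterns
#'   (restricting to carriers is what reproduces the published p = 1);
#' * `tbcaf_vs_all3` - among individuals with either pattern, exactly
#'   theobromine+caffeine vs all three;
#' * `all3_vs_none` - among individuals with either pattern, all three vs
#'   none.
#'
#' @param cohort An `xeno_cohort`.
#' @param contrast One of the three contrasts above.
#' @return An object of class `xeno_contingency`: list with `table`
#'   (2x2), `odds_ratio` (conditional MLE), `p` and `contrast`.
#' @export
combo_era_test <- function(cohort,
                           contrast = c("tb_only_vs_rest", "tbcaf_vs_all3",
                                        "all3_vs_none")) {
  contrast <- match.arg(contrast)
  pat <- mx_pattern(cohort)
  era <- era_of(cohort)
  sel <- switch(contrast,
    tb_only_vs_rest = pat != "000",
    tbcaf_vs_all3 = pat %in% c("110", "111"),
    all3_vs_none = pat %in% c("111", "000"))
  member <- switch(contrast,
    tb_only_vs_rest = pat == "100",
    tbcaf_vs_all3 = pat == "110",
    all3_vs_none = pat == "111")
  tab <- table(era = era[sel], member = factor(member[sel],
                                               levels = c(TRUE, FALSE)))
  if (any(rowSums(tab) == 0)) {
    stop("contrast '", contrast, "' has an empty era margin", call. = FALSE)
  }
  ft <- fisher.test(tab)
  structure(list(table = tab, odds_ratio = unname(ft$estimate),
                 p = ft$p.value, contrast = contrast),
            class = "xeno_contingency")
}

#' Logistic regression of a binary outcome on analyte concentrations
#'
#' Maximum-likelihood fit (IRLS via [stats::glm()]) of `era_after_1800`
#' (1 for individuals dated after 1800) or `shaman` on a set of analyte
#' predictors, with non-detects as 0.  Wald z and two-sided normal p per
#' coefficient; quasi-separation is detected from degenerate fitted
#' probabilities and reported as a warning and a flag, never silently.
#'
#' @param cohort An `xeno_cohort`.
#' @param outcome `"era_after_1800"` or `"shaman"`.
#' @param predictors Analyte names (default the three methylxanthines in
#'   the published order: theophylline, theobromine, caffeine).
#' @param nd_policy Only `"zero"` is meaningful for regression.
#' @param exclude_outliers Drop the canonical outlier ids first.
#' @param era_subset Optionally restrict to one era before fitting
#'   (`"before_1800"`/`"after_1800"`); only sensible with
#'   `outcome = "shaman"` or custom outcomes.
#' @return An object of class `xeno_logistic`: list with `coefficients`
#'   (term, estimate, std_error, z, p), `converged`, `separation`, `n`,
#'   and the underlying `glm` object as `fit`.
#' @export
#' @examples
#' f <- fit_logistic(load_cohort())
#' f$coefficients
fit_logistic <- function(cohort, outcome = c("era_after_1800", "shaman"),
                         predictors = c("theophylline", "theobromine",
                                        "caffeine"),
                         nd_policy = "zero",
                         exclude_outliers = FALSE,
                         era_subset = NULL) {
  outcome <- match.arg(outcome)
  stopifnot(identical(nd_policy, "zero"),
            all(predictors %in% XENO_ANALYTES))
  d <- cohort
  if (exclude_outliers) {
    d <- d[!(d$sample_id %in% outlier_ids(cohort)), , drop = FALSE]
  }
  if (!is.null(era_subset)) d <- d[era_of(d) == era_subset, , drop = FALSE]
  y <- switch(outcome,
              era_after_1800 = as.integer(era_of(d) == "after_1800"),
              shaman = as.integer(d$shaman))
  if (length(unique(y)) < 2) {
    stop("outcome '", outcome, "' has a single class; nothing to fit",
         call. = FALSE)
  }
  X <- analyte_matrix(d, predictors, nd_policy = "zero")
  zv <- apply(X, 2, function(col) stats::var(col) == 0)
  if (any(zv)) {
    stop("zero-variance predictor(s): ",
         paste(predictors[zv], collapse = ", "), call. = FALSE)
  }
  df <- data.frame(y = y, X)
  fit <- suppressWarnings(
    glm(y ~ ., data = df, family = binomial(), control = list(maxit = 100)))
  mu <- fit$fitted.values
  separation <- any(mu < 1e-8 | mu > 1 - 1e-8)
  if (separation) {
    warning("quasi-separation detected: some fitted probabilities are ",
            "numerically 0 or 1; coefficients may be unstable",
            call. = FALSE)
  }
  s <- summary(fit)$coefficients
  structure(list(
    coefficients = tibble::tibble(
      term = rownames(s), estimate = unname(s[, 1]),
      std_error = unname(s[, 2]), z = unname(s[, 3]), p = unname(s[, 4])),
    converged = fit$converged,
    separation = separation,
    n = nrow(df),
    fit = fit
  ), class = "xeno_logistic")
}
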