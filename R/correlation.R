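# Nicotine/cotinine correlation by age class and between-class
# comparison via the Fisher r-to-z transform and Zou's interval.

#' Nicotine/cotinine correlation within each age class
#'
#' Correlations are computed on raw concentrations with non-detects as 0.
#' Although the published methods name the Spearman coefficient, the
#' published per-class values are reproduced exactly by the Pearson
#' coefficient on these data, so `method = "pearson"` is the default; the
#' rank-based version remains available.
#'
#' @param cohort An `xeno_cohort`.
#' @param method `"pearson"` (default, matches the published values) or
#'   `"spearman"` (midrank ties).
#' @param with_outliers Keep (`TRUE`) or remove (`FALSE`) the canonical
#'   outlier ids before computing.
#' @return Tibble with `age_class`, `n`, `r` (`NA` when a class has fewer
#'   than 3 members).  Unknown-age individuals are excluded.
#' @export
#' @examples
#' corr_by_age_class(load_cohort())
corr_by_age_class <- function(cohort, method = c("pearson", "spearman"),
                              with_outliers = TRUE) {
  method <- match.arg(method)
  d <- cohort[cohort$age_class != "unknown", , drop = FALSE]
  if (!with_outliers) {
    d <- d[!(d$sample_id %in% outlier_ids(cohort)), , drop = FALSE]
  }
  classes <- setdiff(levels(cohort$age_class), "unknown")
  out <- lapply(classes, function(cl) {
    dd <- d[d$age_class == cl, , drop = FALSE]
    nic <- ifelse(is.na(dd$nicotine), 0, dd$nicotine)
    cot <- ifelse(is.na(dd$cotinine), 0, dd$cotinine)
    r <- if (nrow(dd) >= 3) cor(nic, cot, method = method) else NA_real_
    tibble::tibble(age_class = cl, n = nrow(dd), r = r)
  })
  do.call(rbind, out)
}

#' Compare two independent correlations with the Fisher r-to-z transform
#'
#' `z = (atanh(r1) - atanh(r2)) / sqrt(1/(n1-3) + 1/(n2-3))` with normal
#' tail probabilities.  The lower-tail one-sided p tests the alternative
#' that the first correlation is smaller (e.g. children below adults).
#'
#' @param r1,n1 First correlation and its sample size.
#' @param r2,n2 Second correlation and its sample size.
#' @return List with `z`, `p_less`, `p_greater`, `p_two_sided`.
#' @export
#' @examples
#' fisher_z_compare(0.5555, 8, 0.9183, 10)$z
fisher_z_compare <- function(r1, n1, r2, n2) {
  stopifnot(n1 > 3, n2 > 3)
  if (abs(r1) >= 1 || abs(r2) >= 1) {
    stop("|r| must be < 1 (atanh transform is infinite at 1)",
         call. = FALSE)
  }
  z <- (atanh(r1) - atanh(r2)) / sqrt(1 / (n1 - 3) + 1 / (n2 - 3))
  list(z = z,
       p_less = pnorm(z),
       p_greater = pnorm(z, lower.tail = FALSE),
       p_two_sided = 2 * pnorm(-abs(z)))
}

#' Zou's confidence interval for a difference of two correlations
#'
#' Builds the per-group Fisher-z confidence limits, back-transforms them,
#' and combines: with group limits (l1, u1) and (l2, u2),
#' `L = r1 - r2 - sqrt((r1 - l1)^2 + (u2 - r2)^2)` and
#' `U = r1 - r2 + sqrt((u1 - r1)^2 + (r2 - l2)^2)`.  The interval always
#' contains `r1 - r2`.
#'
#' @inheritParams fisher_z_compare
#' @param conf Confidence level (default 0.95).
#' @return Numeric vector `c(lower, upper)`.
#' @export
zou_interval <- function(r1, n1, r2, n2, conf = 0.95) {
  stopifnot(n1 > 3, n2 > 3, conf > 0, conf < 1)
  if (abs(r1) >= 1 || abs(r2) >= 1) {
    stop("|r| must be < 1 (atanh transform is infinite at 1)",
         call. = FALSE)
  }
  q <- qnorm(1 - (1 - conf) / 2)
  ci <- function(r, n) tanh(atanh(r) + c(-1, 1) * q / sqrt(n - 3))
  c1 <- ci(r1, n1); c2 <- ci(r2, n2)
  diff <- r1 - r2
  c(lower = diff - sqrt((r1 - c1[1])^2 + (c2[2] - r2)^2),
    upper = diff + sqrt((c1[2] - r1)^2 + (r2 - c2[1])^2))
}

#' Age-class co-correlation comparison table
#'
#' Compares the child class (0-15) against each older class, with and
#' without the canonical outliers: Fisher-z statistic, one-sided
#' (child-less-than-adult) and two-sided p, and Zou's 95% interval.
#'
#' @param cohort An `xeno_cohort`.
#' @param method Passed to [corr_by_age_class()].
#' @return Tibble with one row per (outlier handling x comparison).
#' @export
age_class_comparison <- function(cohort, method = c("pearson", "spearman")) {
  method <- match.arg(method)
  out <- list()
  for (wo in c(TRUE, FALSE)) {
    tab <- corr_by_age_class(cohort, method = method, with_outliers = wo)
    ref <- tab[tab$age_class == "0-15", ]
    for (cl in setdiff(tab$age_class, "0-15")) {
      other <- tab[tab$age_class == cl, ]
      cmp <- fisher_z_compare(ref$r, ref$n, other$r, other$n)
      ci <- zou_interval(ref$r, ref$n, other$r, other$n)
      out[[length(out) + 1L]] <- tibble::tibble(
        with_outliers = wo,
        comparison = paste("0-15 vs", cl),
        n1 = ref$n, n2 = other$n, r1 = ref$r, r2 = other$r,
        z = cmp$z, p_one_sided = cmp$p_less, p_two_sided = cmp$p_two_sided,
        zou_lower = ci[["lower"]], zou_upper = ci[["upper"]])
    }
  }
  do.call(rbind, out)
}
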