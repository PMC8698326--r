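# Independent oracles used across the suite.  These are deliberately
# definition-based re-implementations, never calls into the package.

# Pearson correlation straight from the mean-centred dot-product definition.
oracle_pearson <- function(x, y) {
  cx <- x - mean(x)
  cy <- y - mean(y)
  sum(cx * cy) / sqrt(sum(cx^2) * sum(cy^2))
}

# Spearman = Pearson on midranks.
oracle_spearman <- function(x, y) {
  oracle_pearson(rank(x), rank(y))
}

# Two-sided Fisher exact p by brute-force enumeration of all 2x2 tables
# with the observed margins: sum the hypergeometric probabilities of every
# table at most as probable as the observed one.
oracle_fisher_2x2 <- function(tab) {
  a <- tab[1, 1]
  r1 <- sum(tab[1, ]); r2 <- sum(tab[2, ]); c1 <- sum(tab[, 1])
  n <- r1 + r2
  support <- max(0, c1 - r2):min(r1, c1)
  probs <- vapply(support, function(k) {
    exp(lchoose(r1, k) + lchoose(r2, c1 - k) - lchoose(n, c1))
  }, 0.0)
  p_obs <- probs[match(a, support)]
  sum(probs[probs <= p_obs * (1 + 1e-7)])
}

# Weighted quadratic least squares via the normal equations.
oracle_wls_quadratic <- function(x, y, w) {
  X <- cbind(1, x, x^2)
  solve(t(X) %*% (w * X), t(X) %*% (w * y))[, 1]
}

# Great-circle distance by the spherical law of cosines (second formula,
# independent of the haversine used in the package).
oracle_gc_km <- function(lat1, lon1, lat2, lon2) {
  r <- pi / 180
  d <- sin(lat1 * r) * sin(lat2 * r) +
    cos(lat1 * r) * cos(lat2 * r) * cos((lon2 - lon1) * r)
  6371 * acos(pmin(1, pmax(-1, d)))
}

# Reference points reused across geo tests.
NE_GATEWAY <- list(lat_deg = 66 + 27 / 60, lon_deg = 143 + 13.2 / 60)

# A small synthetic site table on a lat/lon grid for n individuals.
make_sites <- function(n, seed = 99) {
  set.seed(seed)
  data.frame(sample_id = seq_len(n),
             site_label = sprintf("s%02d", seq_len(n)),
             lat_deg = runif(n, 61, 67),
             lon_deg = runif(n, 117, 145),
             region = sample(c("North", "East", "West", "South"), n,
                             replace = TRUE))
}

# Minimal cohort builder for unit tests: analyte values given as a named
# list of vectors (NA = non-detect), everything else defaulted.
make_cohort <- function(panel, dating_start = NULL, dating_end = NULL,
                        age_class = NULL, pipe = NULL) {
  n <- length(panel[[1]])
  df <- data.frame(
    sample_id = seq_len(n),
    name = sprintf("T%02d", seq_len(n)),
    dating_start = if (is.null(dating_start)) rep(1700L, n) else dating_start,
    dating_end = if (is.null(dating_end)) rep(1750L, n) else dating_end,
    sex = "F",
    age_class = if (is.null(age_class)) "30-50" else age_class,
    pipe = if (is.null(pipe)) "none" else pipe,
    shaman = "FALSE",
    anthracosis = "unassessed"
  )
  for (a in analytes()) {
    v <- if (a %in% names(panel)) panel[[a]] else rep(NA_real_, n)
    df[[a]] <- ifelse(is.na(v), "ND", format(v, scientific = FALSE))
  }
  f <- tempfile(fileext = ".csv")
  write.csv(df, f, row.names = FALSE, quote = FALSE)
  load_cohort(f)
}
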