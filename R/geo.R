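# Geography-aware association machinery: great-circle distances, rank
# correlation of concentrations (or pipe presence) against distance to a
# reference point, permutation ANOVA over regions, and the 10% value-
# perturbation robustness test.

#' Great-circle distance in kilometres
#'
#' Haversine distance on a sphere of radius 6371 km (within 0.5% of the
#' ellipsoidal distance at regional scales).
#'
#' @param lat1,lon1,lat2,lon2 Coordinates in decimal degrees; vectors are
#'   recycled.
#' @return Distance(s) in km.
#' @export
#' @examples
#' great_circle_km(62.03, 129.73, 59.36, 143.24)  # Yakutsk - Okhotsk
great_circle_km <- function(lat1, lon1, lat2, lon2) {
  stopifnot(all(abs(c(lat1, lat2)) <= 90), all(abs(c(lon1, lon2)) <= 180))
  geosphere::distHaversine(cbind(lon1, lat1), cbind(lon2, lat2),
                           r = 6371) # radius already in km
}

#' Historical gateway reference points into Yakutia
#'
#' The five compass gateways published with the geographic analysis
#' (coordinates converted from degrees-minutes-seconds).  The named
#' trading settlements (Yakutsk, Okhotsk, Zachiversk, Verkhoyansk,
#' Kiakhta, Nertchinsk, Verkhnevilyuysk) have no published coordinates
#' and must be supplied by the user as additional reference rows.
#'
#' @return Tibble with `label`, `lat_deg`, `lon_deg`.
#' @export
yakutia_gateways <- function() {
  tibble::tibble(
    label = c("NE", "E", "SE", "W", "NW"),
    lat_deg = c(66 + 27 / 60, 64 + 10.2 / 60, 63 + 34.2 / 60,
                62 + 15 / 60, 66 + 45.6 / 60),
    lon_deg = c(143 + 13.2 / 60, 145 + 7.8 / 60, 126 + 30 / 60,
                116 + 9.6 / 60, 123 + 22.2 / 60)
  )
}

# Spearman rank correlation with the sampling scheme used throughout:
# exact p for small tie-free samples, t-approximation otherwise.
spearman_test <- function(x, y) {
  n <- length(x)
  exact <- n <= 9 && !anyDuplicated(x) && !anyDuplicated(y)
  ct <- suppressWarnings(cor.test(x, y, method = "spearman", exact = exact))
  list(rs = unname(ct$estimate), p = ct$p.value, n = n)
}

join_sites <- function(cohort, sites, era = NULL) {
  need <- c("sample_id", "lat_deg", "lon_deg")
  if (!all(need %in% names(sites))) {
    stop("sites table needs columns: ", paste(need, collapse = ", "),
         call. = FALSE)
  }
  m <- match(cohort$sample_id, sites$sample_id)
  if (anyNA(m)) {
    stop("no site for sample_id(s): ",
         paste(cohort$sample_id[is.na(m)], collapse = ", "), call. = FALSE)
  }
  d <- cohort
  d$lat_deg <- sites$lat_deg[m]
  d$lon_deg <- sites$lon_deg[m]
  if (!is.null(era)) d <- d[era_of(d) == era, , drop = FALSE]
  d
}

#' Rank correlation between analyte concentration and distance to a point
#'
#' Spearman correlation between per-individual concentration (non-detects
#' as 0) and great-circle distance from each individual's site to a
#' reference point, as used to probe trade-route gradients.
#'
#' @param cohort An `xeno_cohort`.
#' @param sites Data frame `sample_id, lat_deg, lon_deg` (extra columns
#'   ignored); one site per individual.
#' @param reference List or one-row data frame with `lat_deg`, `lon_deg`
#'   (e.g. one row of [yakutia_gateways()]).
#' @param analyte One of [analytes()].
#' @param era Optional era filter (`"before_1800"`/`"after_1800"`).
#' @return An object of class `xeno_geo`: list with `analyte`,
#'   `reference`, `rs`, `p`, `n`.  `rs` is `NA` (with a warning) when the
#'   concentrations are all equal.
#' @export
distance_correlation <- function(cohort, sites, reference, analyte,
                                 era = NULL) {
  stopifnot(analyte %in% XENO_ANALYTES)
  d <- join_sites(cohort, sites, era)
  if (nrow(d) < 5) stop("need at least 5 located individuals", call. = FALSE)
  conc <- ifelse(is.na(d[[analyte]]), 0, d[[analyte]])
  dist <- great_circle_km(d$lat_deg, d$lon_deg,
                          reference$lat_deg, reference$lon_deg)
  if (stats::var(conc) == 0) {
    warning("all concentrations equal; correlation undefined", call. = FALSE)
    return(structure(list(analyte = analyte, reference = reference,
                          rs = NA_real_, p = NA_real_, n = nrow(d)),
                     class = "xeno_geo"))
  }
  st <- spearman_test(conc, dist)
  structure(list(analyte = analyte, reference = reference,
                 rs = st$rs, p = st$p, n = st$n),
            class = "xeno_geo")
}

#' One-way permutation ANOVA
#'
#' The observed one-way F statistic is referred to its permutation null
#' distribution obtained by shuffling group labels uniformly;
#' `p = (1 + #[F* >= F_obs]) / (1 + n_perm)` (add-one correction so p is
#' never exactly 0).
#'
#' @param values Numeric response.
#' @param groups Group labels (e.g. the four archaeological regions).
#' @param n_perm Number of permutations (default 10000).
#' @param seed Optional integer seed for reproducibility.
#' @return List with `F_obs`, `p`, `n_perm`.
#' @export
permutation_anova <- function(values, groups, n_perm = 10000, seed = NULL) {
  groups <- as.factor(as.character(groups))
  if (nlevels(groups) < 2) stop("need at least 2 groups", call. = FALSE)
  if (any(table(groups) < 2)) {
    stop("every group needs at least 2 members", call. = FALSE)
  }
  if (!is.null(seed)) {
    old <- get_rng_state(); on.exit(set_rng_state(old))
    set.seed(seed)
  }
  g <- as.integer(groups)
  k <- nlevels(groups)
  n <- length(values)
  sizes <- tabulate(g, k)
  gtot <- sum(values)
  sstot <- sum(values^2) - gtot^2 / n
  f_stat <- function(v) {
    gs <- rowsum(v, g)
    ssb <- sum(gs^2 / sizes) - gtot^2 / n
    ssw <- sstot - ssb
    if (ssw <= 0) return(Inf)
    (ssb / (k - 1)) / (ssw / (n - k))
  }
  f_obs <- f_stat(values)
  if (sstot == 0) return(list(F_obs = 0, p = 1, n_perm = n_perm))
  exceed <- 0L
  for (i in seq_len(n_perm)) {
    if (f_stat(values[sample.int(n)]) >= f_obs) exceed <- exceed + 1L
  }
  list(F_obs = if (is.infinite(f_obs) && sstot == 0) 0 else f_obs,
       p = (1 + exceed) / (1 + n_perm), n_perm = n_perm)
}

# Save/restore the RNG so seeded helpers do not disturb the caller's stream.
get_rng_state <- function() {
  if (exists(".Random.seed", envir = globalenv())) {
    get(".Random.seed", envir = globalenv())
  } else NULL
}
set_rng_state <- function(state) {
  if (is.null(state)) {
    if (exists(".Random.seed", envir = globalenv())) {
      rm(".Random.seed", envir = globalenv())
    }
  } else {
    assign(".Random.seed", state, envir = globalenv())
  }
}

#' Perturbation-robustness of a distance association
#'
#' Each replicate selects `ceiling(fraction * n)` individuals uniformly at
#' random, permutes their values among themselves (the rest untouched),
#' and recomputes the association with distance to the reference point.
#' For an analyte the reported robustness is the proportion of replicates
#' with `|rs| > threshold` (default 0.5); for pipe presence it is the
#' proportion with an association p-value below `alpha` (default 0.05).
#'
#' @param cohort An `xeno_cohort`.
#' @param sites Sites table as in [distance_correlation()].
#' @param reference Reference point with `lat_deg`, `lon_deg`.
#' @param analyte One of [analytes()], or `"pipes"` for the binary
#'   pipe-presence indicator.
#' @param era Optional era filter.
#' @param fraction Fraction of values permuted per replicate, in (0, 1].
#' @param n_rep Number of replicates (default 10000).
#' @param threshold Absolute-rs threshold for analytes.
#' @param alpha Significance level for the pipes mode.
#' @param seed Optional integer seed.
#' @return List with `robustness`, `rs_obs` (or `p_obs` for pipes),
#'   `n_rep`, `mode`.
#' @export
perturbation_robustness <- function(cohort, sites, reference, analyte,
                                    era = NULL, fraction = 0.10,
                                    n_rep = 10000, threshold = 0.5,
                                    alpha = 0.05, seed = NULL) {
  if (fraction <= 0 || fraction > 1) {
    stop("fraction must be in (0, 1]", call. = FALSE)
  }
  d <- join_sites(cohort, sites, era)
  if (nrow(d) < 5) stop("need at least 5 located individuals", call. = FALSE)
  dist <- great_circle_km(d$lat_deg, d$lon_deg,
                          reference$lat_deg, reference$lon_deg)
  pipes_mode <- identical(analyte, "pipes")
  x <- if (pipes_mode) {
    as.numeric(d$pipe != "none")
  } else {
    stopifnot(analyte %in% XENO_ANALYTES)
    ifelse(is.na(d[[analyte]]), 0, d[[analyte]])
  }
  if (stats::var(x) == 0) {
    stop("values are constant; association undefined", call. = FALSE)
  }
  if (!is.null(seed)) {
    old <- get_rng_state(); on.exit(set_rng_state(old))
    set.seed(seed)
  }
  n <- length(x)
  m <- ceiling(fraction * n)
  rank_dist <- rank(dist)
  hit <- logical(n_rep)
  for (i in seq_len(n_rep)) {
    xi <- x
    if (m > 1) {
      idx <- sample.int(n, m)
      xi[idx] <- xi[idx[sample.int(m)]]
    }
    if (pipes_mode) {
      if (stats::var(xi) == 0) { hit[i] <- FALSE; next }
      hit[i] <- spearman_test(xi, dist)$p < alpha
    } else {
      rs <- cor(rank(xi), rank_dist)
      hit[i] <- abs(rs) > threshold
    }
  }
  obs <- spearman_test(x, dist)
  out <- list(robustness = mean(hit), n_rep = n_rep,
              mode = if (pipes_mode) "pipes" else "analyte",
              rs_obs = obs$rs)
  if (pipes_mode) out$p_obs <- obs$p
  out
}

#' Association between pipe presence and distance to a reference point
#'
#' Spearman rank correlation of the 0/1 pipe-presence indicator against
#' great-circle distance, the probe used for pre-1800 tobacco diffusion
#' from the south-western trade routes.
#'
#' @inheritParams distance_correlation
#' @return An `xeno_geo` object (analyte slot is `"pipes"`).
#' @export
pipes_association <- function(cohort, sites, reference, era = NULL) {
  d <- join_sites(cohort, sites, era)
  ind <- as.numeric(d$pipe != "none")
  if (all(ind == 1) || all(ind == 0)) {
    stop("need at least one pipe and one non-pipe individual",
         call. = FALSE)
  }
  dist <- great_circle_km(d$lat_deg, d$lon_deg,
                          reference$lat_deg, reference$lon_deg)
  st <- spearman_test(ind, dist)
  structure(list(analyte = "pipes", reference = reference,
                 rs = st$rs, p = st$p, n = st$n),
            class = "xeno_geo")
}
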