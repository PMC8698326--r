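test_that("great-circle distances match an independent formula", {
  expect_equal(great_circle_km(62, 130, 62, 130), 0)
  # antipodal points: half the sphere circumference
  expect_equal(great_circle_km(0, 0, 0, 180), pi * 6371, tolerance = 1e-9)
  # Yakutsk -> Okhotsk against the spherical law of cosines
  d1 <- great_circle_km(62.03, 129.73, 59.36, 143.24)
  d2 <- oracle_gc_km(62.03, 129.73, 59.36, 143.24)
  expect_lt(abs(d1 - d2) / d2, 1e-3)

  set.seed(17)
  lat <- runif(20, -80, 80); lon <- runif(20, -170, 170)
  d_pkg <- great_circle_km(lat[1:10], lon[1:10], lat[11:20], lon[11:20])
  d_ora <- oracle_gc_km(lat[1:10], lon[1:10], lat[11:20], lon[11:20])
  expect_equal(d_pkg, d_ora, tolerance = 1e-6)

  expect_error(great_circle_km(95, 0, 0, 0))
})

test_that("the gateway reference list carries the published coordinates", {
  g <- yakutia_gateways()
  expect_identical(g$label, c("NE", "E", "SE", "W", "NW"))
  ne <- g[g$label == "NE", ]
  expect_equal(ne$lat_deg, 66.45)       # 66 deg 27' 0''
  expect_equal(ne$lon_deg, 143.22)      # 143 deg 13' 12''
  expect_equal(g$lon_deg[g$label == "W"], 116.16) # 116 deg 9' 36''
})

test_that("distance correlation recovers monotone structure", {
  n <- 12
  sites <- data.frame(sample_id = 1:n, lat_deg = seq(62, 66, length.out = n),
                      lon_deg = seq(120, 140, length.out = n))
  ref <- list(lat_deg = 66.45, lon_deg = 143.22)
  d <- great_circle_km(sites$lat_deg, sites$lon_deg, ref$lat_deg, ref$lon_deg)
  conc <- max(d) - d + 1 # strictly decreasing with distance
  ch <- make_cohort(list(caffeine = conc))
  res <- distance_correlation(ch, sites, ref, "caffeine")
  expect_equal(res$rs, -1)
  expect_lt(res$p, 0.01)

  expect_warning(
    res0 <- distance_correlation(make_cohort(list(caffeine = rep(7, n))),
                                 sites, ref, "caffeine"),
    "undefined")
  expect_true(is.na(res0$rs))

  expect_error(distance_correlation(ch[1:3, ], sites[1:3, ], ref,
                                    "caffeine"), "at least 5")
})

test_that("distance-correlation p-values are uniform under independence", {
  # concentrations independent of distance: the p-value follows U(0,1)
  set.seed(40)
  ref <- list(lat_deg = 66.45, lon_deg = 143.22)
  n <- 100
  pvals <- replicate(200, {
    sites <- data.frame(sample_id = 1:n, lat_deg = runif(n, 61, 67),
                        lon_deg = runif(n, 117, 145))
    ch <- make_cohort(list(caffeine = rlnorm(n, 3, 1)))
    distance_correlation(ch, sites, ref, "caffeine")$p
  })
  ks <- suppressWarnings(ks.test(pvals, "punif"))
  expect_gt(ks$p.value, 0.001)
  expect_lt(abs(mean(pvals < 0.05) - 0.05), 0.05)
})

test_that("permutation ANOVA: nulls, separation, and degenerate input", {
  # identical values everywhere
  null0 <- permutation_anova(rep(3, 12), rep(c("a", "b", "c"), each = 4),
                             n_perm = 200, seed = 1)
  expect_equal(null0$F_obs, 0)
  expect_equal(null0$p, 1)

  # clearly separated groups
  set.seed(6)
  v <- c(rnorm(20), rnorm(20, 5))
  g <- rep(c("a", "b"), each = 20)
  sep <- permutation_anova(v, g, n_perm = 5000, seed = 2)
  expect_lte(sep$p, 0.001)
  # permutation p never exactly 0 under the add-one rule
  expect_gte(sep$p, 1 / 5001)

  # F statistic agrees with aov on the same data
  f_aov <- summary(aov(v ~ g))[[1]]$`F value`[1]
  expect_equal(sep$F_obs, f_aov, tolerance = 1e-10)

  expect_error(permutation_anova(1:5, rep("a", 5)), "2 groups")
  expect_error(permutation_anova(1:4, c("a", "a", "a", "b")), "2 members")
})

test_that("permutation p-values are invariant to monotone transforms of ranks", {
  set.seed(12)
  v <- rlnorm(24, 2, 1)
  g <- rep(c("a", "b", "c"), each = 8)
  # same permutations (same seed) on a rank-preserving transform change F
  # but the observed Spearman-style geo statistics depend on ranks only
  sites <- data.frame(sample_id = 1:24, lat_deg = runif(24, 61, 67),
                      lon_deg = runif(24, 117, 145))
  ref <- list(lat_deg = 66.45, lon_deg = 143.22)
  ch1 <- make_cohort(list(caffeine = v))
  ch2 <- make_cohort(list(caffeine = exp(v / max(v)) * 100))
  r1 <- distance_correlation(ch1, sites, ref, "caffeine")
  r2 <- distance_correlation(ch2, sites, ref, "caffeine")
  expect_equal(r1$rs, r2$rs, tolerance = 1e-12)
  expect_equal(r1$p, r2$p, tolerance = 1e-12)
})

test_that("perturbation robustness has the right limiting behaviour", {
  ref <- list(lat_deg = 66.45, lon_deg = 143.22)
  n <- 30
  sites <- data.frame(sample_id = 1:n, lat_deg = seq(62, 66, length.out = n),
                      lon_deg = seq(120, 140, length.out = n))
  d <- great_circle_km(sites$lat_deg, sites$lon_deg, ref$lat_deg, ref$lon_deg)

  # strict monotone relation stays |rs| > 0.5 under 10% perturbation
  ch <- make_cohort(list(caffeine = max(d) - d + 1))
  rob <- perturbation_robustness(ch, sites, ref, "caffeine",
                                 n_rep = 2000, seed = 3)
  expect_gt(rob$robustness, 0.95)
  expect_equal(rob$rs_obs, -1)

  # independent data stay near 0
  set.seed(44)
  ch0 <- make_cohort(list(caffeine = rlnorm(n, 3, 1)))
  rob0 <- perturbation_robustness(ch0, sites, ref, "caffeine",
                                  n_rep = 2000, seed = 4)
  expect_lt(rob0$robustness, 0.05)

  # a fraction selecting <= 1 individual makes every replicate the observed
  rob1 <- perturbation_robustness(ch, sites, ref, "caffeine",
                                  fraction = 1 / n, n_rep = 50, seed = 5)
  expect_equal(rob1$robustness, 1) # observed |rs| = 1 > 0.5 always

  expect_error(perturbation_robustness(ch, sites, ref, "caffeine",
                                       fraction = 0), "fraction")
  expect_error(perturbation_robustness(ch, sites, ref, "caffeine",
                                       fraction = 1.5), "fraction")
})

test_that("full perturbation converges to the unconditional null", {
  # fraction = 1 shuffles everything: robustness approximates the null
  # probability of |rs| > 0.5, which is small for n = 30
  ref <- list(lat_deg = 66.45, lon_deg = 143.22)
  n <- 30
  sites <- data.frame(sample_id = 1:n, lat_deg = seq(62, 66, length.out = n),
                      lon_deg = seq(120, 140, length.out = n))
  d <- great_circle_km(sites$lat_deg, sites$lon_deg, ref$lat_deg, ref$lon_deg)
  ch <- make_cohort(list(caffeine = max(d) - d + 1))
  rob <- perturbation_robustness(ch, sites, ref, "caffeine", fraction = 1,
                                 n_rep = 4000, seed = 6)
  expect_lt(rob$robustness, 0.02)
})

test_that("pipe-distance association points the right way", {
  n <- 20
  sites <- data.frame(sample_id = 1:n, lat_deg = seq(62, 66, length.out = n),
                      lon_deg = seq(120, 140, length.out = n))
  ref <- list(lat_deg = 66.45, lon_deg = 143.22)
  d <- great_circle_km(sites$lat_deg, sites$lon_deg, ref$lat_deg, ref$lon_deg)
  pipe <- ifelse(rank(d) <= 6, "simple", "none") # pipes at the 6 nearest
  ch <- make_cohort(list(nicotine = rep(100, n)), pipe = pipe)
  res <- pipes_association(ch, sites, ref)
  expect_lt(res$rs, 0)
  expect_identical(res$analyte, "pipes")

  chx <- make_cohort(list(nicotine = rep(100, n)), pipe = rep("none", n))
  expect_error(pipes_association(chx, sites, ref), "at least one pipe")
})

test_that("pipes robustness counts significant replicates", {
  n <- 40
  sites <- data.frame(sample_id = 1:n, lat_deg = seq(62, 66, length.out = n),
                      lon_deg = seq(120, 140, length.out = n))
  ref <- list(lat_deg = 66.45, lon_deg = 143.22)
  d <- great_circle_km(sites$lat_deg, sites$lon_deg, ref$lat_deg, ref$lon_deg)
  pipe <- ifelse(rank(d) <= 12, "simple", "none")
  ch <- make_cohort(list(nicotine = rep(100, n)), pipe = pipe)
  rob <- perturbation_robustness(ch, sites, ref, "pipes",
                                 n_rep = 500, seed = 7)
  expect_identical(rob$mode, "pipes")
  expect_gt(rob$robustness, 0.9)
  expect_lt(rob$p_obs, 0.05)
})
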