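test_that("detection summary matches the published cohort counts", {
  s <- detection_summary(load_cohort())

  counts <- setNames(s$counts$n_detected, s$counts$analyte)
  expect_identical(counts[["theobromine"]], 31L)
  expect_identical(counts[["caffeine"]], 29L)
  expect_identical(counts[["theophylline"]], 19L)

  ec <- s$era_combos
  pre <- ec[ec$era == "before_1800", ]
  post <- ec[ec$era == "after_1800", ]
  expect_identical(pre$n, 32L)
  expect_identical(pre$all_three, 6L)
  expect_identical(pre$tb_caf_only, 9L)
  expect_identical(pre$none, 8L)
  expect_identical(post$n, 15L)
  expect_identical(post$all_three, 8L)
  expect_identical(post$none, 0L)

  caf <- s$stats[s$stats$analyte == "caffeine", ]
  expect_equal(caf$median[caf$era == "before_1800"], 28)
  expect_equal(caf$median[caf$era == "after_1800"], 55)
  expect_equal(caf$min[caf$era == "before_1800"], 11)
  expect_equal(caf$max[caf$era == "before_1800"], 252)
})

test_that("an all-censored cohort reports zero counts and absent medians", {
  ch <- make_cohort(list(theobromine = c(NA_real_, NA_real_)))
  s <- detection_summary(ch)
  expect_true(all(s$counts$n_detected == 0L))
  expect_true(all(is.na(s$stats$median)))
})

test_that("detected-only medians are scale-equivariant, counts invariant", {
  ch <- load_cohort()
  s1 <- detection_summary(ch)
  ch2 <- ch
  for (a in analytes()) ch2[[a]] <- ch2[[a]] * 1000 # pg/mg -> fg/mg
  s2 <- detection_summary(ch2)
  expect_identical(s1$counts, s2$counts)
  expect_identical(s1$era_combos, s2$era_combos)
  expect_equal(s2$stats$median, s1$stats$median * 1000)
})

test_that("combo_counts tabulates the methylxanthine patterns", {
  cc_pre <- combo_counts(load_cohort(), "before_1800")
  expect_identical(attr(cc_pre, "era_size"), 32L)
  expect_identical(cc_pre$count[cc_pre$pattern == "TB+CAF+TP"], 6L)
  expect_identical(cc_pre$count[cc_pre$pattern == "TB+CAF"], 9L)
  expect_identical(cc_pre$count[cc_pre$pattern == "none"], 8L)
  expect_identical(sum(cc_pre$count), 32L)

  one <- make_cohort(list(theobromine = 12))
  cc1 <- combo_counts(one, "before_1800")
  expect_identical(cc1$count[cc1$pattern == "TB"], 1L)
  expect_identical(sum(cc1$count), 1L)
})

test_that("era contrast tests agree with hypergeometric enumeration", {
  ch <- load_cohort()
  for (contrast in c("tb_only_vs_rest", "tbcaf_vs_all3", "all3_vs_none")) {
    res <- combo_era_test(ch, contrast)
    expect_equal(res$p, oracle_fisher_2x2(res$table), tolerance = 1e-10)
    expect_true(res$p > 0 && res$p <= 1)
  }
  # the theobromine-only contrast shows no era difference (published p = 1)
  expect_equal(combo_era_test(ch, "tb_only_vs_rest")$p, 1, tolerance = 5e-3)
  # the all-three vs none table is the published 6/8 vs 8/0 split
  expect_identical(as.vector(combo_era_test(ch, "all3_vs_none")$table),
                   c(6L, 8L, 8L, 0L))
})

test_that("fisher enumeration oracle sanity: balanced table gives p = 1", {
  tab <- matrix(c(5, 5, 5, 5), 2)
  expect_equal(oracle_fisher_2x2(tab), 1, tolerance = 1e-12)
  expect_equal(fisher.test(tab)$p.value, 1, tolerance = 1e-12)
})

test_that("random 2x2 tables: fisher.test equals the enumeration oracle", {
  set.seed(5)
  for (i in 1:25) {
    tab <- matrix(rpois(4, 6), 2)
    if (any(rowSums(tab) == 0) || any(colSums(tab) == 0)) next
    expect_equal(fisher.test(tab)$p.value, oracle_fisher_2x2(tab),
                 tolerance = 1e-8)
  }
})

test_that("era logistic fit matches the published caffeine coefficient", {
  f <- suppressWarnings(fit_logistic(load_cohort()))
  co <- f$coefficients
  expect_identical(co$term,
                   c("(Intercept)", "theophylline", "theobromine",
                     "caffeine"))
  caf <- co[co$term == "caffeine", ]
  expect_equal(caf$estimate, 0.006761, tolerance = 1e-4 / 0.006761)
  expect_true(f$converged)
  expect_identical(f$n, 47L)

  # score equations at the optimum: X' (y - mu) = 0
  X <- cbind(1, analyte_matrix(load_cohort(),
                               c("theophylline", "theobromine", "caffeine")))
  y <- as.integer(era_of(load_cohort()) == "after_1800")
  mu <- f$fit$fitted.values
  expect_lt(max(abs(t(X) %*% (y - mu))), 1e-6)
  # fitted probabilities average to the outcome rate
  expect_equal(mean(mu), mean(y), tolerance = 1e-10)
})

test_that("degenerate logistic inputs are rejected or flagged", {
  ch <- load_cohort()
  pre <- ch[era_of(ch) == "before_1800", ]
  expect_error(suppressWarnings(fit_logistic(pre)), "single class")

  zv <- make_cohort(list(theobromine = c(5, 5, 5, 5),
                         caffeine = c(1, 2, 3, 4),
                         theophylline = c(4, 3, 2, 1)),
                    dating_start = c(1700L, 1700L, 1800L, 1800L),
                    dating_end = c(1750L, 1750L, 1850L, 1850L))
  expect_error(suppressWarnings(fit_logistic(zv)), "zero-variance")

  # perfectly separating predictor must be flagged, not silently returned
  sep <- make_cohort(list(caffeine = c(1, 2, 3, 100, 200, 300),
                          theobromine = c(5, 6, 4, 5, 6, 4),
                          theophylline = c(2, 3, 4, 2, 3, 4)),
                     dating_start = rep(c(1700L, 1800L), each = 3),
                     dating_end = rep(c(1750L, 1850L), each = 3))
  expect_warning(fsep <- fit_logistic(sep), "separation")
  expect_true(fsep$separation)
})

test_that("logistic coefficients are recovered from simulated data", {
  set.seed(99)
  n <- 5000
  caf <- rlnorm(n, 3.5, 1)
  tb <- rlnorm(n, 4, 1)
  eta <- -1 + 0.01 * caf + 0.005 * tb
  y <- rbinom(n, 1, plogis(eta))
  # piggyback on the cohort container: era encodes the outcome
  ch <- make_cohort(list(caffeine = caf, theobromine = tb,
                         theophylline = runif(n, 1, 2)),
                    dating_start = ifelse(y == 1, 1800L, 1700L),
                    dating_end = ifelse(y == 1, 1850L, 1750L))
  f <- suppressWarnings(fit_logistic(ch))
  co <- f$coefficients
  for (row in list(c("caffeine", 0.01), c("theobromine", 0.005))) {
    est <- co[co$term == row[1], ]
    expect_lt(abs(est$estimate - as.numeric(row[2])), 3 * est$std_error)
  }
})
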