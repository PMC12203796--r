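test_that("normality gate levels and power are sensible", {
  expect_error(normality_gate(c(1, 2)), "at least 3")
  expect_warning(g <- normality_gate(rep(5, 10)), "constant")
  expect_false(g$normal)
  # level: ~95% of Gaussian samples pass the gate
  pass <- vapply(1:100, function(s)
    normality_gate(with_seed(s, rnorm(50)))$normal, logical(1))
  expect_gte(sum(pass), 90)
  # power: strongly log-normal samples (n = 26) usually fail it
  fail <- vapply(1:100, function(s)
    !normality_gate(with_seed(1000 + s, exp(rnorm(26, sd = 1.5))))$normal,
    logical(1))
  expect_gte(sum(fail), 70)
})

test_that("compare_groups picks the gated test and responds to shifts", {
  a <- with_seed(1, rnorm(25, 10, 2))
  b <- with_seed(2, rnorm(25, 10, 2))
  cmp <- compare_groups(a, b)
  expect_equal(cmp$test, "t")
  expect_gt(cmp$p_value, 0.05)
  expect_equal(cmp$group_a$style, "mean_sd")
  # identical groups, rank branch: p = 1
  x <- exp(with_seed(3, rnorm(30, sd = 1.5)))
  cmpw <- compare_groups(x, x)
  expect_equal(cmpw$test, "wilcoxon")
  expect_equal(cmpw$p_value, 1)
  expect_equal(cmpw$group_a$style, "median_iqr")
  # shifting one group farther moves the t-test p monotonically toward 0
  ps <- vapply(c(0, 0.5, 1, 2, 4), function(sh)
    compare_groups(a, b + sh)$p_value, numeric(1))
  expect_true(all(diff(ps) < 0))
  expect_error(compare_groups(numeric(0), b), "empty")
})

test_that("two-sample gate keeps its type-I error near nominal", {
  # null: both groups N(0,1); mixed t / rank decisions by the gate
  rej <- vapply(1:1000, function(s) {
    with_seed(s, {
      a <- rnorm(15); b <- rnorm(15)
      suppressWarnings(compare_groups(a, b)$p_value) < 0.05
    })
  }, logical(1))
  expect_gte(mean(rej), 0.03)
  expect_lte(mean(rej), 0.07)
})

test_that("power at the half-width effect size (printed group summaries)", {
  # groups simulated at means/SDs/ns 0.978+-0.184 (n=25) vs 0.826+-0.243
  # (n=11); the empirical rejection rate of the Welch t-test must match
  # the analytic noncentral-t power (independent closed-form oracle)
  hit <- vapply(1:200, function(s) {
    with_seed(s, {
      a <- rnorm(25, 0.978, 0.184)
      b <- rnorm(11, 0.826, 0.243)
      t.test(a, b)$p.value < 0.05
    })
  }, logical(1))
  se2a <- 0.184^2 / 25; se2b <- 0.243^2 / 11
  ncp <- (0.978 - 0.826) / sqrt(se2a + se2b)
  df <- (se2a + se2b)^2 / (se2a^2 / 24 + se2b^2 / 10)   # Welch-Satterthwaite
  crit <- qt(0.975, df)
  power <- pt(crit, df, ncp, lower.tail = FALSE) + pt(-crit, df, ncp)
  expect_lt(abs(mean(hit) - power), 0.08)
  expect_gt(mean(hit), 0.25)   # the printed effect is clearly detectable
})

test_that("Bonferroni maps the printed raw p to the printed corrected p", {
  expect_equal(bonferroni(0.016, 3), 0.048)
  expect_equal(bonferroni(0.5, 3), 1)
  expect_equal(bonferroni(0, 7), 0)
  expect_error(bonferroni(1.2, 3), "outside")
  expect_error(bonferroni(c(0.1, 0.2), 1), "smaller")
})

test_that("Benjamini-Hochberg matches hand computation and references", {
  expect_equal(benjamini_hochberg(c(0.01, 0.02, 0.03, 0.04)), rep(0.04, 4))
  expect_equal(benjamini_hochberg(0.2), 0.2)
  expect_equal(benjamini_hochberg(rep(1, 5)), rep(1, 5))
  expect_identical(benjamini_hochberg(numeric(0)), numeric(0))
  for (s in 1:20) {
    p <- with_seed(s, runif(12))
    got <- benjamini_hochberg(p)
    expect_equal(got, bh_reference(p))             # enumeration oracle
    expect_equal(got, stats::p.adjust(p, "BH"))    # reference implementation
    # bounded by raw p below and Bonferroni above, monotone in rank
    expect_true(all(got >= p - 1e-15))
    expect_true(all(got <= bonferroni(p, 12) + 1e-15))
    expect_true(all(diff(got[order(p)]) > -1e-15))
  }
})

test_that("tiered correction assigns Bonferroni and BH by hypothesis tier", {
  cmps <- list(
    compare_groups(with_seed(1, rnorm(20, 1)), with_seed(2, rnorm(20)),
                   variable = "hw", tier = "primary"),
    compare_groups(with_seed(3, rnorm(20)), with_seed(4, rnorm(20)),
                   variable = "amp", tier = "secondary"),
    compare_groups(with_seed(5, rnorm(20)), with_seed(6, rnorm(20)),
                   variable = "rise", tier = "secondary"))
  out <- correct_comparisons(cmps, m_primary = 3, m_secondary = 12)
  expect_equal(out[[1]]$correction, "bonferroni")
  expect_equal(out[[1]]$p_corrected, min(1, out[[1]]$p_value * 3))
  expect_equal(out[[2]]$correction, "benjamini_hochberg")
  # BH family padded to 12 tests: corrected p >= raw p always
  for (i in 2:3) expect_gte(out[[i]]$p_corrected, out[[i]]$p_value)
})

test_that("proportions test matches intuition and the exact oracle", {
  eq <- wilson_proportions_test(30, 100, 15, 50)
  expect_equal(eq$p_value, 1)
  big <- wilson_proportions_test(50, 100, 80, 100)
  expect_lt(big$p_value, 0.001)
  # symmetry
  ab <- wilson_proportions_test(12, 40, 22, 45)
  ba <- wilson_proportions_test(22, 45, 12, 40)
  expect_equal(ab$p_value, ba$p_value)
  expect_error(wilson_proportions_test(5, 0, 1, 10))
  # Wilson intervals contain the point estimate and sit in [0, 1]
  ci <- ab$wilson_ci
  expect_true(all(ci[, "lower"] <= ab$proportions & ab$proportions <= ci[, "upper"]))
  expect_true(all(ci >= 0 & ci <= 1))
  # decision agreement with the exact binomial brute force on a small grid
  n1 <- n2 <- 25
  disagree <- 0; boundary_disagree <- 0; total <- 0
  for (k1 in seq(0, 25, by = 5)) for (k2 in seq(0, 25, by = 2)) {
    total <- total + 1
    p_pkg <- wilson_proportions_test(k1, n1, k2, n2)$p_value
    p_ex <- exact_prop_p(k1, n1, k2, n2)
    if ((p_pkg < 0.05) != (p_ex < 0.05)) {
      disagree <- disagree + 1
      if (abs(p_ex - 0.05) > 0.03) boundary_disagree <- boundary_disagree + 1
    }
  }
  expect_lte(disagree / total, 0.1)   # rare, near-threshold cases only
  expect_equal(boundary_disagree, 0)  # never off the 0.05 boundary zone
})

test_that("PV+ density analysis reproduces configured effects", {
  # identical groups: F ~ 0, zero percent difference
  d0 <- data.frame(animal = rep(c("a1", "a2", "b1", "b2"), each = 3),
                   genotype = rep(c("WT", "TS"), each = 6),
                   count = rep(c(90, 100, 110), 4), area_mm2 = 1)
  r0 <- pv_density_analysis(d0)
  expect_lt(r0$F_statistic, 1e-20)
  expect_equal(r0$percent_difference, 0)
  # doubling every area at fixed density leaves all outputs unchanged
  cfg <- section_sim_config(sections_per_animal = 30, seed = 4)
  sec <- generate_pv_sections(cfg)
  r1 <- pv_density_analysis(sec)
  sec2 <- sec; sec2$area_mm2 <- sec2$area_mm2 * 2; sec2$count <- sec2$count * 2
  r2 <- pv_density_analysis(sec2)
  expect_equal(r1$F_statistic, r2$F_statistic)
  expect_equal(r1$percent_difference, r2$percent_difference)
  # configured densities 93.3 vs 114.9 -> percent difference near 23%
  big <- generate_pv_sections(section_sim_config(sections_per_animal = 200,
                                                 seed = 5))
  rb <- pv_density_analysis(big)
  expect_equal(rb$percent_difference, (114.9 - 93.3) / 93.3 * 100,
               tolerance = 0.05)
  expect_error(pv_density_analysis(transform(d0, area_mm2 = 0)), "area")
})

test_that("section generator obeys its contracts", {
  expect_error(section_sim_config(sections_per_animal = 5))
  expect_error(section_sim_config(mean_density = c(WT = -1, TS = 100)))
  cfg <- section_sim_config(seed = 11)
  a <- generate_pv_sections(cfg); b <- generate_pv_sections(cfg)
  expect_identical(a, b)
  # area fixed at 1 mm^2: density equals count exactly
  cfg1 <- section_sim_config(section_area_mean = 1, section_area_sd = 0, seed = 2)
  s1 <- generate_pv_sections(cfg1)
  expect_identical(s1$density, as.numeric(s1$count))
  # many sections, no overdispersion: group means within 3% of configured
  huge <- generate_pv_sections(section_sim_config(sections_per_animal = 400,
                                                  seed = 3))
  m <- tapply(huge$density, huge$genotype, mean)
  expect_lt(abs(m["WT"] - 93.3) / 93.3, 0.03)
  expect_lt(abs(m["TS"] - 114.9) / 114.9, 0.03)
})

test_that("two-significant-figure reporting helper", {
  expect_equal(signif2(0.048123), 0.048)
  expect_equal(signif2(227203), 230000)
  expect_equal(percent_difference(0.8255, 0.9784), 19)
  expect_equal(percent_difference(0.8255, 0.9784, digits = NULL),
               (0.9784 - 0.8255) / 0.8255 * 100)
})
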