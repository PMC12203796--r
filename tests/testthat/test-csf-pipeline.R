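test_that("compute_dff recovers step changes and rejects bad baselines", {
  fr <- 9.6
  n <- 600
  flat <- matrix(100, 1, n)
  ds <- fluorescence_dataset(flat, fr, "a1", "WT", is_dff = FALSE)
  expect_equal(unname(compute_dff(ds)$traces[1, ]), rep(0, n))
  # step 100 -> 120 at frame 400: plateau dF/F = 0.2 while the baseline
  # window still covers pre-step frames
  stepped <- matrix(c(rep(100, 400), rep(120, 200)), 1)
  ds2 <- fluorescence_dataset(stepped, fr, "a1", "WT", is_dff = FALSE)
  out <- compute_dff(ds2)$traces[1, ]
  expect_equal(unname(out[405:500]), rep(0.2, 96), tolerance = 1e-9)
  # non-positive baseline: cell dropped with a warning naming it
  bad <- rbind(good = rep(100, n), bad = c(rep(-1, n)))
  ds3 <- fluorescence_dataset(bad, fr, "a1", "WT", is_dff = FALSE)
  expect_warning(out3 <- compute_dff(ds3), "bad")
  expect_equal(rownames(out3$traces), "good")
  # dF/F input passes through untouched
  ds4 <- fluorescence_dataset(matrix(rnorm(50), 1), fr, "a1", "WT", is_dff = TRUE)
  expect_identical(compute_dff(ds4), ds4)
})

test_that("trial responses are window-mean differences", {
  cfg <- calcium_sim_config(n_animals_per_genotype = c(WT = 1, TS = 1),
                            cells_per_animal = 2, noise_sd = 0, seed = 6)
  sched <- generate_stimulus_schedule(cfg)
  nf <- attr(sched, "n_frames")
  # flat trace -> all evoked responses 0
  flat <- fluorescence_dataset(matrix(0.3, 2, nf), cfg$frame_rate, "a1", "WT")
  tr <- trial_responses(flat, sched)
  expect_equal(tr$evoked, rep(0, nrow(tr)))
  expect_equal(nrow(tr), 2 * nrow(sched))
  # an epoch beyond the trace is dropped with a warning
  short <- fluorescence_dataset(matrix(0.3, 2, nf - 100), cfg$frame_rate, "a1", "WT")
  expect_warning(tr2 <- trial_responses(short, sched), "outside")
  expect_lt(nrow(tr2), nrow(tr))
})

test_that("responsiveness classification implements both rules", {
  # all-zero responses: nonresponsive
  expect_false(classify_responsive(rep(0, 5)))
  # the worked example: all-positive responses, exact p = 1/32 < 0.05
  ev <- c(0.5, 0.6, 0.4, 0.55, 0.5)
  expect_equal(permutation_p_onesided(ev), 1 / 32)
  expect_true(classify_responsive(ev))
  # amplitude floor dominates a significant permutation p
  expect_false(classify_responsive(c(0.04, 0.042, 0.038, 0.041, 0.039)))
  # fewer than 3 repeats: nonresponsive with a warning
  expect_warning(out <- classify_responsive(c(0.5, 0.6)), "repeats")
  expect_false(out)
  # permutation p is a valid p-value: never below 1/2^n, at most 1
  for (s in 1:20) {
    x <- with_seed(s, rnorm(5))
    p <- permutation_p_onesided(x)
    expect_gte(p, 1 / 32); expect_lte(p, 1)
  }
})

test_that("min_responsive_contrast takes the literal minimum", {
  grid <- c(1, 0.5, 0.25, 0.125, 0.067, 0.034)
  r <- grid %in% c(1, 0.5, 0.25)
  expect_equal(min_responsive_contrast(r, grid), 0.25)
  expect_equal(log2(1 / 0.25), 2)
  # non-monotone pattern honoured: responsive at 100% and 12.5% only
  r2 <- grid %in% c(1, 0.125)
  expect_equal(min_responsive_contrast(r2, grid), 0.125)
  expect_equal(min_responsive_contrast(rep(FALSE, 6), grid), NA_real_)
})

test_that("noiseless pipeline equals ground truth exactly (oracle equivalence)", {
  cfg <- calcium_sim_config(n_animals_per_genotype = c(WT = 1, TS = 1),
                            cells_per_animal = 25, noise_sd = 0,
                            fraction_nonresponsive = 0.3, seed = 11)
  sched <- generate_stimulus_schedule(cfg)
  sim <- generate_calcium_dataset(cfg, sched)
  tab <- build_cs_table(sim$datasets, sched)
  m <- merge(as.data.frame(tab), sim$truth[, c("cell", "sf", "category")],
             by = c("cell", "sf"), suffixes = c("_pipe", "_true"))
  expect_equal(nrow(m), 2 * 25 * 7)
  expect_identical(as.character(m$category_pipe), as.character(m$category_true))
  # category for c_min = 0.034 is the maximum numeric level
  expect_equal(max(log2(1 / cfg$contrast_grid)), log2(1 / 0.034))
  expect_equal(levels(tab$category)[7], format_cs(log2(1 / 0.034)))
  # a cell NR at all SFs is never flagged visually responsive
  nr_all <- tapply(tab$category == "NR", tab$cell, all)
  expect_true(all(!tab$visually_responsive[nr_all[tab$cell]]))
})

test_that("population CSF summarises non-NR cells and reports NR fraction", {
  tab <- data.frame(cell = rep(sprintf("c%02d", 1:6), each = 2),
                    animal = "a1", genotype = "WT",
                    sf = rep(c(0.014, 0.128), 6),
                    c_min = rep(c(0.25, NA), 6),
                    visually_responsive = TRUE)
  tab$category <- factor(ifelse(is.na(tab$c_min), "NR", "2"),
                         levels = c("NR", "0", "1", "2"), ordered = TRUE)
  pop <- population_csf(tab, "animal")
  low <- pop[pop$sf == 0.014, ]
  expect_equal(low$mean_cs, 2)
  expect_equal(low$q25, 2); expect_equal(low$q75, 2)    # IQR width 0
  expect_equal(low$fraction_nr, 0)
  hi <- pop[pop$sf == 0.128, ]
  expect_true(is.na(hi$mean_cs))
  expect_equal(hi$fraction_nr, 1)
  # single cell: degenerate IQR equals its value
  one <- population_csf(tab[tab$cell == "c01", ], "animal")
  expect_equal(one[one$sf == 0.014, "q25"], one[one$sf == 0.014, "q75"])
})

test_that("responding proportions are correct fractions", {
  tab <- data.frame(cell = rep(c("c1", "c2", "c3", "c4"), each = 2),
                    animal = "a1",
                    genotype = rep(c("WT", "WT", "TS", "TS"), each = 2),
                    sf = rep(c(0.014, 0.128), 4),
                    c_min = c(1, NA, 0.5, NA, NA, 0.5, NA, NA),
                    visually_responsive = c(TRUE, TRUE, TRUE, TRUE,
                                            TRUE, TRUE, FALSE, FALSE))
  tab$category <- factor(ifelse(is.na(tab$c_min), "NR", "x"),
                         levels = c("NR", "x"), ordered = TRUE)
  expect_equal(proportion_responding(tab, 0.014, "WT"), 1.0)
  expect_equal(proportion_responding(tab, 0.128, "WT"), 0.0)
  expect_equal(proportion_responding(tab, 0.128, "TS"), 1.0)
  expect_error(proportion_responding(tab[0, ], 0.014), "empty")
})
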