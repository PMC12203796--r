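test_that("compute_dvdt handles ramps, constants, and sinusoids", {
  dt <- 0.02
  ramp <- seq(0, 100, by = 1)               # 1 mV per sample at 50 kHz
  expect_equal(compute_dvdt(ramp, dt), rep(50, length(ramp)))
  expect_equal(compute_dvdt(rep(-70, 50), dt), rep(0, 50))
  # sine of known frequency: max |dV/dt| = 2*pi*f*A
  f_khz <- 0.2; A <- 10
  t <- seq(0, 20, by = dt)
  v <- A * sin(2 * pi * f_khz * t)
  expect_equal(max(abs(compute_dvdt(v, t))), 2 * pi * f_khz * A,
               tolerance = 0.01)
  expect_error(compute_dvdt(c(1, 2), dt), "3 samples")
  expect_error(compute_dvdt(1:10, c(0, cumsum(runif(9)))), "non-uniform")
})

test_that("detect_aps finds template APs and nothing else", {
  cfg <- ephys_sim_config(current_steps = c(-50, 150, 250),
                          rheobase_pA = 150, noise_sd = 0, seed = 2)
  sim <- generate_current_clamp_recording(cfg)
  ss <- sim$sweeps
  dt <- 1000 / ss$sampling_rate
  expect_identical(detect_aps(ss$voltage[1, ], ss$time), integer(0))
  for (s in 2:3) {
    pk <- detect_aps(ss$voltage[s, ], ss$time)
    tr <- sim$truth$sweeps[[s]]
    expect_length(pk, tr$n_aps)
    expect_lt(max(abs(ss$time[pk] - tr$peak_times)), dt + 1e-9)
  }
  # 250 pA sweep carries 3 template APs
  expect_equal(sim$truth$sweeps[[3]]$n_aps, 3)
})

test_that("noise-only traces yield no detections (false-positive check)", {
  dt <- 0.02
  hits <- vapply(1:100, function(s) {
    v <- with_seed(s, -70 + rnorm(2500, 0, 0.5))
    length(detect_aps(v, dt))
  }, numeric(1))
  expect_identical(sum(hits), 0)
})

test_that("detection is monotone: adding an AP never lowers the count", {
  shape_fn <- get("ap_template_shape", envir = asNamespace("v1phys"))
  sh <- shape_fn(list(threshold_mV = -44, amplitude_mV = 65,
                      half_width_ms = 0.9, rise_fraction = 0.3), -60)
  dt <- 0.02
  t <- seq(0, 100, by = dt)
  for (s in 1:5) {
    v <- with_seed(s, -60 + rnorm(length(t), 0, 0.3))
    n0 <- length(detect_aps(v, dt))
    at <- 20 + 10 * s
    idx <- which(t >= at + sh$t_foot & t <= at + sh$t_end)
    v2 <- v
    v2[idx] <- sh$value(t[idx] - at) + v[idx] + 60   # add the spike bump
    expect_gte(length(detect_aps(v2, dt)), n0 + 1)
  }
})

test_that("ap_threshold recovers the configured threshold and is grid-stable", {
  for (rate in c(50000, 100000)) {
    cfg <- ephys_sim_config(sampling_rate = rate,
                            current_steps = c(-50, 150), rheobase_pA = 150,
                            noise_sd = 0, seed = 3)
    sim <- generate_current_clamp_recording(cfg)
    v <- sim$sweeps$voltage[2, ]
    pk <- detect_aps(v, sim$sweeps$time)
    thr <- ap_threshold(v, sim$sweeps$time, pk[1])
    expect_equal(thr$threshold_mV, -44, tolerance = 0.1)
    if (rate == 50000) thr50 <- thr
    else expect_lt(abs(thr$threshold_mV - thr50$threshold_mV), 0.05)
  }
  # a trace whose dV/dt never reaches the criterion is malformed
  slow <- -70 + 10 * (1 - exp(-(seq(0, 50, by = 0.02)) / 10))
  expect_error(ap_threshold(slow, 0.02, which.max(slow)),
               class = "malformed_ap")
})

test_that("ap_features matches similar-triangles geometry on a triangular spike", {
  dt <- 0.02
  t <- seq(0, 30, by = dt)
  v <- rep(-20, length(t))                      # baseline below 0 threshold
  # symmetric triangle: rise 0 -> 60 in 1 ms, fall 60 -> 0 in 1 ms
  up <- t >= 10 & t <= 11
  down <- t > 11 & t <= 12
  v[up] <- -20 + 80 * (t[up] - 10)              # 80 mV/ms upstroke
  v[down] <- 60 - 80 * (t[down] - 11)
  v <- pmin(v, 60)
  pk <- which.max(v)
  f <- ap_features(v, dt, pk)
  # threshold = where dV/dt crosses 15.2 ~ instantly at the kink (~ -20)
  expect_equal(f$threshold_potential, -20, tolerance = 0.8)
  # half-width: time above midpoint of a symmetric triangle = half the base
  expect_equal(f$half_width, 1.0, tolerance = 0.05)
  expect_equal(f$total_rise_time, 1.0, tolerance = 0.05)
  expect_equal(f$total_fall_time, 1.0, tolerance = 0.05)
})

test_that("noiseless template features are recovered within tolerance", {
  # oracle-equivalence invariant: every extracted field matches the
  # closed-form template value within one sample period / 0.1 mV
  for (hw in c(0.826, 0.978)) {
    cfg <- ephys_sim_config(current_steps = c(-50, 150), rheobase_pA = 150,
                            ap_template = list(threshold_mV = -44,
                                               amplitude_mV = 65,
                                               half_width_ms = hw,
                                               rise_fraction = 0.3),
                            noise_sd = 0, seed = 4)
    sim <- generate_current_clamp_recording(cfg)
    f <- first_ap_features(sim$sweeps)
    tf <- sim$truth$template_features
    dt <- 1000 / cfg$sampling_rate
    expect_equal(f$threshold_potential, tf$threshold_potential, tolerance = 0.1)
    expect_equal(f$amplitude, tf$amplitude, tolerance = 0.1)
    expect_equal(f$half_width, tf$half_width, tolerance = dt)
    expect_equal(f$total_rise_time, tf$total_rise_time, tolerance = dt)
    expect_equal(f$total_fall_time, tf$total_fall_time, tolerance = 2 * dt)
    expect_equal(f$max_rate_rise, tf$max_rate_rise, tolerance = 0.01 * tf$max_rate_rise)
    expect_equal(f$max_rate_fall, tf$max_rate_fall, tolerance = 0.01 * tf$max_rate_fall)
  }
})

test_that("grid refinement: halving the sample interval is stable", {
  hw50 <- hw100 <- NULL
  for (rate in c(50000, 100000)) {
    cfg <- ephys_sim_config(sampling_rate = rate,
                            current_steps = c(-50, 150), rheobase_pA = 150,
                            noise_sd = 0, seed = 5)
    sim <- generate_current_clamp_recording(cfg)
    f <- first_ap_features(sim$sweeps)
    if (rate == 50000) hw50 <- f$half_width else hw100 <- f$half_width
  }
  expect_lt(abs(hw50 - hw100), 0.02)
})

test_that("half-width is unbiased under realistic noise (25-cell cohort)", {
  hws <- vapply(1:25, function(s) {
    cfg <- ephys_sim_config(current_steps = c(-50, 150), rheobase_pA = 150,
                            ap_template = list(threshold_mV = -44,
                                               amplitude_mV = 65,
                                               half_width_ms = 0.978,
                                               rise_fraction = 0.3),
                            noise_sd = 0.3, seed = s)
    first_ap_features(generate_current_clamp_recording(cfg)$sweeps)$half_width
  }, numeric(1))
  expect_lt(abs(mean(hws) - 0.978) / 0.978, 0.05)
})

test_that("passive properties recover the configured RC membrane", {
  cfg <- ephys_sim_config(membrane_R = 100, membrane_C = 150, noise_sd = 0,
                          seed = 6)
  pp <- passive_properties(generate_current_clamp_recording(cfg)$sweeps)
  expect_lt(abs(pp$input_resistance - 100) / 100, 0.01)
  expect_lt(abs(pp$time_constant - 15) / 15, 0.01)
  expect_lt(abs(pp$capacitance - 150) / 150, 0.01)
  # cap = tau / R_in by construction (exact)
  expect_equal(pp$capacitance, pp$time_constant / pp$input_resistance * 1000,
               tolerance = 1e-9)
  expect_equal(pp$rheobase, 150)
  expect_lt(pp$voltage_sag, 0.05)     # no sag component simulated
  expect_lt(abs(pp$rebound), 0.05)
})

test_that("passive extraction errors and missing values behave as specified", {
  cfg <- fast_ephys_cfg(noise_sd = 0, seed = 8)
  ss <- generate_current_clamp_recording(cfg)$sweeps
  # remove the -50 pA sweep
  ss2 <- sweep_set(ss$time, ss$voltage[-1, , drop = FALSE], ss$current_pA[-1],
                   ss$step_window, ss$sampling_rate)
  expect_error(passive_properties(ss2), "-50 pA")
  # a recording with no APs at all
  cfg3 <- ephys_sim_config(current_steps = c(-50, 0, 50), rheobase_pA = 50,
                           noise_sd = 0, seed = 9)
  sim3 <- generate_current_clamp_recording(cfg3)
  sub <- sweep_set(sim3$sweeps$time, sim3$sweeps$voltage[1:2, ],
                   sim3$sweeps$current_pA[1:2], sim3$sweeps$step_window,
                   sim3$sweeps$sampling_rate)
  expect_error(first_ap_features(sub), class = "no_ap_cell")
})
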