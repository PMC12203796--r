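# Synthetic current-clamp recordings: an RC membrane driven by a family of
# current steps, with analytically defined action-potential templates
# spliced in at and above rheobase.  Every template quantity that the
# extractor measures (threshold by the 15.2 mV/ms rule, amplitude,
# half-width, rise/fall times, max rates) has a closed form, so extraction
# can be tested against exact ground truth.

DVDT_THRESHOLD <- 15.2  # mV/ms; upstroke velocity defining AP threshold

#' Configuration for the current-clamp simulator
#'
#' Defaults mirror a standard step protocol: 50 kHz sampling, 200 ms steps
#' from -50 to 650 pA in 50 pA increments, holding potential -70 mV.
#'
#' @param sampling_rate Hz.
#' @param step_duration ms.
#' @param inter_step_interval ms between step onsets (metadata only; sweeps
#'   are stored as episodes).
#' @param current_steps pA, strictly increasing.
#' @param holding_potential mV.
#' @param membrane_R input resistance, MOhm.
#' @param membrane_C capacitance, pF.
#' @param ap_template list with `threshold_mV`, `amplitude_mV`
#'   (threshold-to-peak), `half_width_ms`, `rise_fraction` (fraction of the
#'   half-width elapsed between threshold-to-half-height crossing on the
#'   rising edge; controls rise/fall asymmetry).
#' @param rheobase_pA smallest current step that fires; must be one of
#'   `current_steps`.
#' @param noise_sd mV of white Gaussian noise added to every sample.
#' @param seed integer seed.
#' @return validated list of class `ephys_sim_config`.
#' @export
ephys_sim_config <- function(sampling_rate = 50000, step_duration = 200,
                             inter_step_interval = 2000,
                             current_steps = seq(-50, 650, by = 50),
                             holding_potential = -70,
                             membrane_R = 100, membrane_C = 150,
                             ap_template = list(threshold_mV = -44,
                                                amplitude_mV = 65,
                                                half_width_ms = 0.9,
                                                rise_fraction = 0.3),
                             rheobase_pA = 150, noise_sd = 0, seed = 1L) {
  cfg <- list(sampling_rate = sampling_rate, step_duration = step_duration,
              inter_step_interval = inter_step_interval,
              current_steps = current_steps,
              holding_potential = holding_potential,
              membrane_R = membrane_R, membrane_C = membrane_C,
              ap_template = ap_template, rheobase_pA = rheobase_pA,
              noise_sd = noise_sd, seed = as.integer(seed))
  stopifnot(sampling_rate > 0, step_duration > 0,
            all(diff(current_steps) > 0),
            membrane_R > 0, membrane_C > 0, noise_sd >= 0,
            ap_template$half_width_ms > 0, ap_template$amplitude_mV > 0,
            ap_template$rise_fraction > 0, ap_template$rise_fraction < 1)
  if (!rheobase_pA %in% current_steps)
    stop("rheobase_pA must be one of current_steps")
  class(cfg) <- "ephys_sim_config"
  cfg
}

# Closed-form piecewise AP template.  Time is measured from the threshold
# crossing (t = 0, V = threshold, dV/dt = exactly 15.2 mV/ms).  Pieces:
#   exponential foot -> quadratic blend spanning the threshold (dV/dt is
#   LINEAR in t through the crossing, so central differences recover the
#   threshold essentially exactly) -> second quadratic blend -> linear
#   rise -> parabolic peak -> linear fall -> exponential tail.
# Returns segment parameters plus the exact feature values the extractor
# should recover.
ap_template_shape <- function(template, v_base) {
  Vth <- template$threshold_mV
  A <- template$amplitude_mV
  w <- template$half_width_ms
  rho <- template$rise_fraction
  s0 <- DVDT_THRESHOLD
  if (v_base >= Vth - 2) stop("local baseline must sit below threshold")
  gam <- 0.06    # ms; half-duration of the threshold-spanning blend
  frac1 <- 0.3   # slope swing of that blend: s0*(1 -/+ frac1)
  d2 <- 0.1     # ms; duration of the second (acceleration) blend
  a1 <- frac1 * s0 / gam
  s_lo <- s0 * (1 - frac1)
  s_hi <- s0 * (1 + frac1)
  gam2 <- gam + d2
  if (rho * w <= gam2 + 0.01)
    stop("half_width/rise_fraction too small for the template's blend widths")
  C1 <- s0 * gam + a1 * gam^2 / 2 + d2 * s_hi / 2
  Sr <- (A / 2 - C1) / (rho * w - gam - d2 / 2)     # max rate of rise, mV/ms
  if (Sr <= s_hi) stop("rise_fraction/half_width give a rise slower than the threshold blend")
  a2 <- (Sr - s_hi) / d2
  v_g1 <- Vth + s0 * gam + a1 * gam^2 / 2            # end of blend 1
  v_g2 <- Vth + C1 + d2 * Sr / 2                     # end of blend 2
  Vp <- Vth + A
  q <- Sr^2 / A                                      # peak curvature, mV/ms^2
  va <- Vp - A / 4                                   # linear rise -> parabola
  ta <- gam2 + (va - v_g2) / Sr
  tp <- ta + Sr / (2 * q)                            # peak time
  t_rise_half <- rho * w                             # by construction
  D <- t_rise_half + w - tp
  disc <- D^2 - A / (2 * q)
  if (D <= 0 || disc <= 0)
    stop("half_width too short for this amplitude/rise_fraction")
  Sf <- 2 * q * (D - sqrt(disc))                     # max rate of fall, mV/ms
  tb <- tp + Sf / (2 * q)
  vb <- Vp - Sf^2 / (4 * q)
  Vm <- Vth + A / 4                                  # linear fall -> tail
  tm <- tb + (vb - Vm) / Sf
  Vend <- min(v_base, Vth - 5)
  tau_f <- (Vm - Vend) / Sf
  t_thr_return <- tm + tau_f * log((Vm - Vend) / (Vth - Vend))
  # foot: exponential asymptoting to the local baseline, slope-matched to
  # the start of blend 1
  v_mg <- Vth - s0 * gam + a1 * gam^2 / 2            # value at t = -gam
  if (v_mg <= v_base + 0.5) stop("threshold too close to local baseline")
  k <- s_lo / (v_mg - v_base)
  t_foot <- -gam - log((v_mg - v_base) / 0.02) / k
  t_end <- tm + tau_f * log((Vm - Vend) / 0.02)      # within 0.02 mV of Vend

  value <- function(t) {
    v <- numeric(length(t))
    i <- t < t_foot
    v[i] <- v_base
    i <- t >= t_foot & t < -gam
    v[i] <- v_base + (s_lo / k) * exp(k * (t[i] + gam))
    i <- t >= -gam & t < gam
    v[i] <- Vth + s0 * t[i] + a1 * t[i]^2 / 2
    i <- t >= gam & t < gam2
    v[i] <- v_g1 + s_hi * (t[i] - gam) + a2 * (t[i] - gam)^2 / 2
    i <- t >= gam2 & t < ta
    v[i] <- v_g2 + Sr * (t[i] - gam2)
    i <- t >= ta & t < tb
    v[i] <- Vp - q * (t[i] - tp)^2
    i <- t >= tb & t < tm
    v[i] <- vb - Sf * (t[i] - tb)
    i <- t >= tm
    v[i] <- Vend + (Vm - Vend) * exp(-(t[i] - tm) / tau_f)
    v
  }

  list(value = value, t_foot = t_foot, t_end = t_end,
       features = list(threshold_potential = Vth, amplitude = A,
                       half_width = w, peak_time = tp,
                       total_rise_time = tp,
                       total_fall_time = t_thr_return - tp,
                       max_rate_rise = Sr * 1000,   # mV/s
                       max_rate_fall = Sf * 1000))
}

#' Simulate a current-clamp step recording with analytic ground truth
#'
#' Sub-rheobase sweeps follow the RC step response
#' \eqn{V(t) = V_0 + IR(1 - e^{-t/\tau})}, \eqn{\tau = RC}.  Sweeps at and
#' above `rheobase_pA` depolarise toward a plateau capped 8 mV below
#' threshold and fire template APs (one more AP per 50 pA above rheobase,
#' 20 ms apart, as many as fit in the step).  The template's upstroke
#' velocity first exceeds 15.2 mV/ms exactly at the configured threshold
#' voltage; its full width at half-height equals `half_width_ms` before
#' noise.
#'
#' @param cfg an [ephys_sim_config()].
#' @return list with `sweeps` (a [sweep_set()]) and `truth` (template
#'   features, per-sweep spike threshold/peak times, passive parameters).
#' @export
generate_current_clamp_recording <- function(cfg) {
  stopifnot(inherits(cfg, "ephys_sim_config"))
  rate_khz <- cfg$sampling_rate / 1000
  dt <- 1 / rate_khz                       # ms
  pre <- 100; post <- 200
  dur <- cfg$step_duration
  t_on <- pre; t_off <- pre + dur
  n <- round((pre + dur + post) / dt)
  time <- (seq_len(n) - 1) * dt
  tau <- cfg$membrane_R * cfg$membrane_C / 1000   # ms (MOhm * pF / 1000)
  Vh <- cfg$holding_potential
  tmpl <- cfg$ap_template
  Vth <- tmpl$threshold_mV

  old_seed <- if (exists(".Random.seed", .GlobalEnv)) get(".Random.seed", .GlobalEnv) else NULL
  on.exit(if (!is.null(old_seed)) assign(".Random.seed", old_seed, .GlobalEnv))
  set.seed(cfg$seed)

  volt <- matrix(NA_real_, length(cfg$current_steps), n)
  truth_sweeps <- vector("list", length(cfg$current_steps))
  shape_features <- NULL

  for (s in seq_along(cfg$current_steps)) {
    I <- cfg$current_steps[s]
    dV <- I * cfg$membrane_R / 1000        # mV
    spiking <- I >= cfg$rheobase_pA
    dV_eff <- if (spiking) min(dV, (Vth - 8) - Vh) else dV
    v <- rep(Vh, n)
    in_step <- time >= t_on & time < t_off
    v[in_step] <- Vh + dV_eff * (1 - exp(-(time[in_step] - t_on) / tau))
    v_off <- Vh + dV_eff * (1 - exp(-dur / tau))
    after <- time >= t_off
    v[after] <- Vh + (v_off - Vh) * exp(-(time[after] - t_off) / tau)

    thr_times <- numeric(0); peak_times <- numeric(0)
    if (spiking) {
      base_at <- function(t) Vh + dV_eff * (1 - exp(-(t - t_on) / tau))
      t_s1 <- t_on + max(3 * tau, 10)
      isi <- 20
      n_spk <- 1 + floor((I - cfg$rheobase_pA) / 50)
      n_fit <- max(1, 1 + floor((t_off - 10 - t_s1) / isi))
      n_spk <- min(n_spk, n_fit)
      t_prev_end <- -Inf; v_prev_end <- NA
      for (j in seq_len(n_spk)) {
        t_sj <- t_s1 + (j - 1) * isi
        # the foot duration depends on the local baseline; iterate to
        # make the foot start exactly on the running trace
        base_j <- function(t) {
          if (j == 1 || t > t_prev_end + 1e-9 || is.na(v_prev_end)) base_at(t) else v_prev_end
        }
        v0 <- base_at(t_sj - 1)
        for (it in 1:4) {
          sh <- ap_template_shape(tmpl, v0)
          v0 <- base_at(t_sj + sh$t_foot)
        }
        sh <- ap_template_shape(tmpl, v0)
        if (is.null(shape_features)) shape_features <- sh$features
        idx <- which(time >= t_sj + sh$t_foot & time <= t_sj + sh$t_end)
        v[idx] <- sh$value(time[idx] - t_sj)
        # relax from the tail back toward the plateau until the next event
        tail_end_t <- t_sj + sh$t_end
        tail_end_v <- sh$value(sh$t_end)
        nxt <- if (j < n_spk) t_s1 + j * isi - 2 else t_off
        idx2 <- which(time > tail_end_t & time < nxt)
        if (length(idx2)) {
          plateau <- base_at(time[idx2])
          v[idx2] <- plateau + (tail_end_v - base_at(tail_end_t)) *
            exp(-(time[idx2] - tail_end_t) / (tau / 4))
        }
        thr_times <- c(thr_times, t_sj)
        peak_times <- c(peak_times, t_sj + sh$features$peak_time)
      }
    }
    if (cfg$noise_sd > 0) v <- v + rnorm(n, 0, cfg$noise_sd)
    volt[s, ] <- v
    truth_sweeps[[s]] <- list(current_pA = I, n_aps = length(thr_times),
                              threshold_times = thr_times, peak_times = peak_times,
                              steady_state_deflection = dV_eff)
  }

  ss <- sweep_set(time = time, voltage = volt, current_pA = cfg$current_steps,
                  step_window = c(t_on, t_off), sampling_rate = cfg$sampling_rate)
  truth <- list(config = cfg, tau_ms = tau,
                input_resistance_Mohm = cfg$membrane_R,
                capacitance_pF = cfg$membrane_C,
                rheobase_pA = cfg$rheobase_pA,
                template_features = shape_features,
                sweeps = truth_sweeps)
  list(sweeps = ss, truth = truth)
}
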