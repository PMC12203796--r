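# Passive-membrane and action-potential feature extraction from
# current-clamp step recordings.
#
# Conventions (documented in the methods vignette):
#  * AP threshold: membrane potential at which dV/dt first reaches
#    15.2 mV/ms on the upstroke, linearly interpolated at the crossing.
#  * Amplitude is threshold-to-peak; half-height = threshold + amplitude/2.
#  * Half-width: time above half-height, sub-sample interpolated.
#  * Max rates of rise/fall are reported in mV/s.

#' Container for a set of current-clamp sweeps
#'
#' @param time ms, shared uniform time base.
#' @param voltage mV matrix, one row per sweep.
#' @param current_pA injected current per sweep.
#' @param step_window c(start, end) of the current step, ms.
#' @param sampling_rate Hz.
#' @return object of class `sweep_set`.
#' @export
sweep_set <- function(time, voltage, current_pA, step_window, sampling_rate) {
  voltage <- as.matrix(voltage)
  stopifnot(length(time) == ncol(voltage),
            length(current_pA) == nrow(voltage),
            length(step_window) == 2, step_window[1] < step_window[2],
            step_window[1] >= min(time), step_window[2] <= max(time) + 1e-9,
            sampling_rate > 0)
  dts <- diff(time)
  if (max(abs(dts - dts[1])) > 1e-6 * dts[1]) stop("non-uniform time base")
  structure(list(time = time, voltage = voltage, current_pA = current_pA,
                 step_window = step_window, sampling_rate = sampling_rate),
            class = "sweep_set")
}

#' @export
print.sweep_set <- function(x, ...) {
  cat("sweep_set:", nrow(x$voltage), "sweeps x", ncol(x$voltage), "samples @",
      x$sampling_rate / 1000, "kHz; steps",
      paste(range(x$current_pA), collapse = ".."), "pA\n")
  invisible(x)
}

#' First time derivative of a voltage trace
#'
#' Central differences in the interior, one-sided at the ends; same length
#' as the input.
#'
#' @param voltage mV vector.
#' @param time ms vector (uniform) or a single sample interval in ms.
#' @return dV/dt in mV/ms.
#' @export
compute_dvdt <- function(voltage, time) {
  n <- length(voltage)
  if (n < 3) stop("need at least 3 samples")
  if (length(time) == 1) {
    dt <- time
  } else {
    stopifnot(length(time) == n)
    dts <- diff(time)
    if (max(abs(dts - dts[1])) > 1e-6 * dts[1]) stop("non-uniform time base")
    dt <- dts[1]
  }
  d <- numeric(n)
  d[2:(n - 1)] <- (voltage[3:n] - voltage[1:(n - 2)]) / (2 * dt)
  d[1] <- (voltage[2] - voltage[1]) / dt
  d[n] <- (voltage[n] - voltage[n - 1]) / dt
  d
}

#' Detect action potentials in a single sweep
#'
#' An AP is an upward crossing of the dV/dt criterion followed, within
#' `peak_window_ms`, by a local maximum above `peak_floor` (rejects
#' subthreshold depolarisations).  A refractory period suppresses repeat
#' detections of the same event.
#'
#' @param voltage mV vector (one sweep).
#' @param time ms vector or sample interval (ms).
#' @param slope_criterion mV/ms (default 15.2).
#' @param peak_floor minimum peak voltage, mV (default -10).
#' @param peak_window_ms window after the crossing searched for the peak.
#' @param refractory_ms minimum separation between detections.
#' @return integer vector of peak sample indices (possibly empty).
#' @export
detect_aps <- function(voltage, time, slope_criterion = 15.2, peak_floor = -10,
                       peak_window_ms = 5, refractory_ms = 2) {
  dt <- if (length(time) == 1) time else diff(time)[1]
  d <- compute_dvdt(voltage, time)
  n <- length(voltage)
  up <- which(d[-1] >= slope_criterion & d[-n] < slope_criterion) + 1L
  peaks <- integer(0)
  last_t <- -Inf
  wlen <- max(1L, round(peak_window_ms / dt))
  for (i in up) {
    if ((i - 1) * dt < last_t + refractory_ms) next
    j <- min(n, i + wlen)
    win <- voltage[i:j]
    pk <- i - 1L + which.max(win)
    if (voltage[pk] < peak_floor) next
    # require a genuine local maximum (not the rising edge of the window)
    if (pk == j && j < n) next
    if (length(peaks) && pk == peaks[length(peaks)]) next
    peaks <- c(peaks, pk)
    last_t <- (pk - 1) * dt
  }
  peaks
}

#' AP threshold by the upstroke-velocity criterion
#'
#' Scans backward from the peak for the last sample where dV/dt is below
#' the criterion, then linearly interpolates voltage and time at the exact
#' crossing.
#'
#' @inheritParams detect_aps
#' @param peak_index sample index of the AP peak (from [detect_aps()]).
#' @return list with `threshold_mV`, `threshold_time_ms`, `index` (last
#'   sub-criterion sample).
#' @export
ap_threshold <- function(voltage, time, peak_index, slope_criterion = 15.2) {
  dt <- if (length(time) == 1) time else diff(time)[1]
  tt <- if (length(time) == 1) (seq_along(voltage) - 1) * dt else time
  d <- compute_dvdt(voltage, time)
  # near the peak dV/dt is again below the criterion: first walk back into
  # the upstroke, then find the last sub-criterion sample before it
  i <- peak_index
  while (i > 1 && d[i] < slope_criterion) i <- i - 1L
  if (i == 1)
    stop(malformed_ap_error("dV/dt never reaches the threshold criterion before the peak"))
  while (i > 1 && d[i] >= slope_criterion) i <- i - 1L
  if (d[i] >= slope_criterion)
    stop(malformed_ap_error("no sub-criterion sample before the upstroke"))
  frac <- (slope_criterion - d[i]) / (d[i + 1] - d[i])
  list(threshold_mV = voltage[i] + frac * (voltage[i + 1] - voltage[i]),
       threshold_time_ms = tt[i] + frac * dt,
       index = i)
}

malformed_ap_error <- function(msg) {
  structure(class = c("malformed_ap", "error", "condition"),
            list(message = msg, call = sys.call(-1)))
}

no_ap_error <- function(msg) {
  structure(class = c("no_ap_cell", "error", "condition"),
            list(message = msg, call = sys.call(-1)))
}

# interpolated time at which the trace crosses `level` between samples
# i and i+1
.cross_time <- function(voltage, tt, i, level) {
  frac <- (level - voltage[i]) / (voltage[i + 1] - voltage[i])
  tt[i] + frac * (tt[i + 1] - tt[i])
}

#' Waveform features of one action potential
#'
#' @inheritParams ap_threshold
#' @param search_end_ms optional absolute time limiting the
#'   return-to-threshold search (defaults to the end of the sweep).
#' @return object of class `ap_features`: `threshold_potential`,
#'   `amplitude`, `half_width`, `max_rate_rise`, `max_rate_fall` (mV/s),
#'   `total_rise_time`, `total_fall_time` (NA when the membrane never
#'   returns to threshold before `search_end_ms`), `peak_time`.
#' @export
ap_features <- function(voltage, time, peak_index, slope_criterion = 15.2,
                        search_end_ms = NULL) {
  dt <- if (length(time) == 1) time else diff(time)[1]
  tt <- if (length(time) == 1) (seq_along(voltage) - 1) * dt else time
  thr <- ap_threshold(voltage, time, peak_index, slope_criterion)
  vpk <- voltage[peak_index]
  amp <- vpk - thr$threshold_mV
  if (amp <= 0) stop(malformed_ap_error("non-positive amplitude"))
  half <- thr$threshold_mV + amp / 2
  n <- length(voltage)
  i_end <- if (is.null(search_end_ms)) n else max(which(tt <= search_end_ms))

  # rising half-height crossing: last sample below `half` before the peak
  ir <- peak_index
  while (ir > 1 && voltage[ir - 1] >= half) ir <- ir - 1L
  ir <- ir - 1L
  if (ir < 1) stop(malformed_ap_error("no rising half-height crossing"))
  t_rise_half <- .cross_time(voltage, tt, ir, half)
  # falling half-height crossing: first sample below `half` after the peak
  if.. <- which(voltage[(peak_index + 1):i_end] < half)
  if (!length(if..)) stop(malformed_ap_error("no falling half-height crossing"))
  jf <- peak_index + if..[1] - 1L
  t_fall_half <- .cross_time(voltage, tt, jf, half)

  # return to threshold potential (may genuinely not happen)
  jr <- which(voltage[(peak_index + 1):i_end] <= thr$threshold_mV)
  if (length(jr)) {
    j <- peak_index + jr[1] - 1L
    t_return <- .cross_time(voltage, tt, j, thr$threshold_mV)
    total_fall <- t_return - tt[peak_index]
    ret_idx <- j + 1L
  } else {
    total_fall <- NA_real_
    ret_idx <- i_end
  }

  d <- compute_dvdt(voltage, time)
  seg <- thr$index:ret_idx
  structure(list(threshold_potential = thr$threshold_mV,
                 amplitude = amp,
                 half_width = t_fall_half - t_rise_half,
                 max_rate_rise = max(d[seg]) * 1000,
                 max_rate_fall = -min(d[seg]) * 1000,
                 total_rise_time = tt[peak_index] - thr$threshold_time_ms,
                 total_fall_time = total_fall,
                 peak_time = tt[peak_index],
                 peak_potential = vpk,
                 source_sweep = NA_integer_),
            class = "ap_features")
}

#' @export
print.ap_features <- function(x, ...) {
  cat("AP features: threshold", signif(x$threshold_potential, 4), "mV,",
      "amplitude", signif(x$amplitude, 4), "mV,",
      "half-width", signif(x$half_width, 4), "ms\n")
  invisible(x)
}

#' Passive membrane properties from the -50 pA sweep
#'
#' Input resistance from the steady-state deflection (last 25% of the
#' step), the membrane time constant from a single-exponential fit to the
#' onset transient, capacitance as tau/R, voltage sag and post-step
#' rebound, and rheobase as the smallest current step containing at least
#' one detected AP.
#'
#' @param sweeps a [sweep_set()] containing a -50 pA sweep.
#' @param ... detection parameters passed to [detect_aps()].
#' @return object of class `passive_properties` with fields
#'   `input_resistance` (MOhm), `capacitance` (pF), `time_constant` (ms),
#'   `voltage_sag` (mV, positive), `rebound` (mV), `rheobase` (pA).
#' @export
passive_properties <- function(sweeps, ...) {
  stopifnot(inherits(sweeps, "sweep_set"))
  s <- which(sweeps$current_pA == -50)
  if (!length(s)) stop("no -50 pA sweep in this recording")
  s <- s[1]
  tt <- sweeps$time
  v <- sweeps$voltage[s, ]
  on <- sweeps$step_window[1]; off <- sweeps$step_window[2]
  dur <- off - on
  base_idx <- tt >= on - 50 & tt < on
  if (!any(base_idx)) base_idx <- tt < on
  v_base <- mean(v[base_idx])
  steady_idx <- tt >= off - 0.25 * dur & tt < off
  v_steady <- mean(v[steady_idx])
  r_in <- (v_steady - v_base) / (-50) * 1000          # mV/pA -> MOhm

  # tau: single-exponential fit to the onset transient
  fit_idx <- tt >= on & tt < off
  td <- tt[fit_idx] - on
  vd <- v[fit_idx]
  tau <- tryCatch({
    # log-linear start value from the early transient
    resid0 <- (vd - v_steady) / (v_base - v_steady)
    ok <- resid0 > 0.05 & td < dur / 2
    tau0 <- if (sum(ok) > 5) {
      -1 / coef(lm(log(resid0[ok]) ~ td[ok]))[2]
    } else dur / 10
    if (!is.finite(tau0) || tau0 <= 0) tau0 <- dur / 10
    fit <- nls(vd ~ vs + (v_base - vs) * exp(-td / tau),
               start = list(vs = v_steady, tau = tau0),
               control = nls.control(maxiter = 200, warnOnly = TRUE, scaleOffset = 1))
    unname(coef(fit)["tau"])
  }, error = function(e) {
    warning("exponential fit for tau failed: ", conditionMessage(e))
    NA_real_
  })
  cap <- if (is.na(tau)) NA_real_ else tau / r_in * 1000   # ms/MOhm -> pF

  in_step <- tt >= on & tt < off
  sag <- abs(min(v[in_step]) - v_steady)
  rebound <- max(v[tt >= off]) - v_base

  rheo <- NA_real_
  for (i in order(sweeps$current_pA)) {
    if (sweeps$current_pA[i] <= 0) next
    pk <- detect_aps(sweeps$voltage[i, ], tt, ...)
    if (length(pk)) { rheo <- sweeps$current_pA[i]; break }
  }

  structure(list(input_resistance = r_in, capacitance = cap,
                 time_constant = tau, voltage_sag = sag, rebound = rebound,
                 rheobase = rheo),
            class = "passive_properties")
}

#' @export
print.passive_properties <- function(x, ...) {
  cat("Passive properties: R_in", signif(x$input_resistance, 4), "MOhm,",
      "tau", signif(x$time_constant, 4), "ms,",
      "cap", signif(x$capacitance, 4), "pF,",
      "rheobase", x$rheobase, "pA\n")
  invisible(x)
}

#' Features of the first AP fired during the step protocol
#'
#' Sweeps are scanned in order of increasing current; the first detected
#' AP (chronologically first in the first spiking sweep) is measured.
#'
#' @inheritParams passive_properties
#' @return an [ap_features()] object with `source_sweep` set.
#' @export
first_ap_features <- function(sweeps, ...) {
  stopifnot(inherits(sweeps, "sweep_set"))
  for (i in order(sweeps$current_pA)) {
    pk <- detect_aps(sweeps$voltage[i, ], sweeps$time, ...)
    if (length(pk)) {
      f <- ap_features(sweeps$voltage[i, ], sweeps$time, pk[1],
                       search_end_ms = sweeps$step_window[2])
      f$source_sweep <- i
      return(f)
    }
  }
  stop(no_ap_error("no-AP cell: no action potentials detected in any sweep"))
}
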