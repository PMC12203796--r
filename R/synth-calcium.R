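# Synthetic two-photon calcium imaging: per-neuron log-Gaussian spatial
# frequency tuning x Naka-Rushton contrast response, convolved with a
# double-exponential indicator kernel, plus Gaussian noise.  Ground truth
# carries each cell's ordinal contrast-sensitivity category per SF,
# computed from the noiseless trace with the same window-mean response
# definition the pipeline uses.

#' Configuration for the calcium-imaging simulator
#'
#' Defaults mirror the experimental design being emulated: 7 spatial
#' frequencies x 6 contrasts, 5 repeats, 3 s stimulus + 3 s baseline at a
#' 9.6 Hz effective frame rate.  Tuning defaults put the second genotype's
#' SF preference about 1.3 octaves above the first's, which produces the
#' qualitative low-SF/mid-SF response asymmetry between cohorts.
#'
#' @param n_animals_per_genotype named vector of animals per genotype
#'   (default `c(WT = 4, TS = 5)`).
#' @param cells_per_animal cells per animal (desk-scale default 100; the
#'   emulated experiment had roughly 800).
#' @param sf_grid cycles/degree.
#' @param contrast_grid fractions in (0, 1].
#' @param n_repeats repeats of each unique stimulus.
#' @param stim_duration_s,baseline_duration_s seconds.
#' @param frame_rate Hz.
#' @param tuning list: `sf_pref_log_mean` (log2 cpd, per genotype),
#'   `sf_pref_log_sd` (octaves), `tuning_bandwidth_octaves`, `c50` (per
#'   genotype), `hill_n`, `r_max` (peak evoked dF/F).
#' @param indicator_kernel list: `rise_ms`, `decay_ms`.
#' @param noise_sd dF/F units.
#' @param fraction_nonresponsive fraction of cells with `r_max = 0`.
#' @param detection_margin evoked dF/F amplitude the pipeline requires to
#'   call a response (ground-truth categories use the same margin).
#' @param detection_alpha significance level of the pipeline's permutation
#'   test, mirrored by the ground-truth categories.
#' @param seed integer seed.
#' @return validated list of class `calcium_sim_config`.
#' @export
calcium_sim_config <- function(n_animals_per_genotype = c(WT = 4, TS = 5),
                               cells_per_animal = 100,
                               sf_grid = c(0.014, 0.031, 0.064, 0.128,
                                           0.236, 0.383, 0.512),
                               contrast_grid = c(1, 0.5, 0.25, 0.125, 0.067, 0.034),
                               n_repeats = 5,
                               stim_duration_s = 3, baseline_duration_s = 3,
                               frame_rate = 9.6,
                               tuning = list(),
                               indicator_kernel = list(rise_ms = 45, decay_ms = 400),
                               noise_sd = 0.05,
                               fraction_nonresponsive = 0.3,
                               detection_margin = 0.05,
                               detection_alpha = 0.05,
                               seed = 1L) {
  gt <- names(n_animals_per_genotype) %||% c("WT", "TS")
  tuning <- modifyList(list(
    sf_pref_log_mean = setNames(c(log2(0.02), log2(0.05)), gt),
    sf_pref_log_sd = 1.5,
    tuning_bandwidth_octaves = 1.5,
    c50 = setNames(c(0.15, 0.15), gt),
    hill_n = 2, r_max = 0.5), tuning)
  cfg <- list(n_animals_per_genotype = n_animals_per_genotype,
              cells_per_animal = cells_per_animal,
              sf_grid = sf_grid, contrast_grid = contrast_grid,
              n_repeats = n_repeats, stim_duration_s = stim_duration_s,
              baseline_duration_s = baseline_duration_s,
              frame_rate = frame_rate, tuning = tuning,
              indicator_kernel = indicator_kernel, noise_sd = noise_sd,
              fraction_nonresponsive = fraction_nonresponsive,
              detection_margin = detection_margin,
              detection_alpha = detection_alpha, seed = as.integer(seed))
  stopifnot(all(contrast_grid > 0), all(contrast_grid <= 1),
            all(sf_grid > 0), n_repeats >= 1,
            fraction_nonresponsive >= 0, fraction_nonresponsive <= 1,
            frame_rate > 0, stim_duration_s > 0, baseline_duration_s > 0,
            length(n_animals_per_genotype) == 2, noise_sd >= 0)
  class(cfg) <- "calcium_sim_config"
  cfg
}

#' Build the pseudo-random stimulus schedule
#'
#' Every (SF, contrast) pair appears exactly once per repeat block, in a
#' seeded random order per block.  The timeline is a lead-in baseline
#' followed by stimulus/baseline pairs, so each presentation has an
#' immediately preceding baseline window.  Frame indices are 0-based and
#' windows half-open.
#'
#' @param cfg a [calcium_sim_config()].
#' @return data.frame of class `stimulus_schedule` with one row per
#'   presentation: `presentation`, `block`, `sf`, `contrast`, `onset_s`,
#'   `offset_s`, `onset_frame`, `offset_frame`, `baseline_onset_frame`.
#'   Attributes: `frame_rate`, `n_frames`, `schedule_duration_s` (sum of
#'   presentation durations), `lead_in_s`.
#' @export
generate_stimulus_schedule <- function(cfg) {
  stopifnot(inherits(cfg, "calcium_sim_config"))
  stim <- expand.grid(sf = cfg$sf_grid, contrast = cfg$contrast_grid,
                      KEEP.OUT.ATTRS = FALSE)
  ns <- nrow(stim)
  old_seed <- if (exists(".Random.seed", .GlobalEnv)) get(".Random.seed", .GlobalEnv) else NULL
  on.exit(if (!is.null(old_seed)) assign(".Random.seed", old_seed, .GlobalEnv))
  set.seed(cfg$seed)
  ord <- unlist(lapply(seq_len(cfg$n_repeats), function(b) sample.int(ns)))
  sched <- stim[ord, , drop = FALSE]
  sched$block <- rep(seq_len(cfg$n_repeats), each = ns)
  np <- nrow(sched)
  trial_dur <- cfg$stim_duration_s + cfg$baseline_duration_s
  lead_in <- cfg$baseline_duration_s
  sched$presentation <- seq_len(np)
  sched$onset_s <- lead_in + (sched$presentation - 1) * trial_dur
  sched$offset_s <- sched$onset_s + cfg$stim_duration_s
  fr <- cfg$frame_rate
  sched$onset_frame <- as.integer(floor(sched$onset_s * fr + 1e-9))
  sched$offset_frame <- as.integer(floor(sched$offset_s * fr + 1e-9))
  sched$baseline_onset_frame <-
    as.integer(floor((sched$onset_s - cfg$baseline_duration_s) * fr + 1e-9))
  rownames(sched) <- NULL
  sched <- sched[, c("presentation", "block", "sf", "contrast", "onset_s", "offset_s",
                     "onset_frame", "offset_frame", "baseline_onset_frame")]
  attr(sched, "frame_rate") <- fr
  attr(sched, "lead_in_s") <- lead_in
  attr(sched, "schedule_duration_s") <- np * trial_dur
  attr(sched, "n_frames") <- as.integer(ceiling((lead_in + np * trial_dur) * fr))
  class(sched) <- c("stimulus_schedule", "data.frame")
  sched
}

#' Expected evoked amplitude surface of one model neuron
#'
#' Log-Gaussian SF tuning times Naka-Rushton contrast response:
#' \eqn{r(sf, c) = r_{max} \exp\{-\log_2(sf/pref)^2 / (2 bw^2)\}
#'   \cdot c^n / (c^n + c_{50}^n)}.
#'
#' @param sf,contrast numeric vectors (recycled against each other).
#' @param sf_pref preferred SF, cpd.
#' @param bandwidth tuning bandwidth, octaves.
#' @param c50 semi-saturation contrast.
#' @param hill_n Hill exponent.
#' @param r_max peak evoked amplitude (dF/F).
#' @return evoked amplitude(s).
#' @export
neuron_response <- function(sf, contrast, sf_pref, bandwidth, c50, hill_n, r_max) {
  r_max * exp(-log2(sf / sf_pref)^2 / (2 * bandwidth^2)) *
    contrast^hill_n / (contrast^hill_n + c50^hill_n)
}

# double-exponential indicator kernel sampled at the frame interval,
# normalised to unit integral so a sustained rate r plateaus at r
.indicator_kernel <- function(rise_ms, decay_ms, frame_rate) {
  dt <- 1 / frame_rate
  tmax <- 6 * decay_ms / 1000
  t <- seq(0, tmax, by = dt)
  h <- exp(-t / (decay_ms / 1000)) - exp(-t / (rise_ms / 1000))
  h / (sum(h) * dt)
}

# noiseless dF/F trace for one cell given its response surface over the
# schedule (rate boxcars convolved with the indicator kernel)
.cell_trace <- function(resp_per_presentation, sched, n_frames, kern, frame_rate) {
  rate <- numeric(n_frames)
  for (p in seq_len(nrow(sched))) {
    f0 <- sched$onset_frame[p] + 1L
    f1 <- sched$offset_frame[p]
    rate[f0:f1] <- resp_per_presentation[p]
  }
  y <- stats::convolve(rate, rev(kern), type = "open")[seq_len(n_frames)]
  y / frame_rate
}

# exact one-sided sign-permutation p-value (inline enumeration, kept
# independent of the pipeline's implementation)
.perm_p <- function(x) {
  n <- length(x)
  if (n > 12) return(stats::t.test(x, alternative = "greater")$p.value)
  signs <- as.matrix(expand.grid(rep(list(c(-1, 1)), n)))
  mean(as.vector(signs %*% x) / n >= mean(x) - 1e-12)
}

# window-mean evoked responses, computed independently of the pipeline
# (plain loop; used for ground truth)
.window_means <- function(trace, sched) {
  vapply(seq_len(nrow(sched)), function(p) {
    stim <- (sched$onset_frame[p] + 1L):sched$offset_frame[p]
    base <- (sched$baseline_onset_frame[p] + 1L):sched$onset_frame[p]
    mean(trace[stim]) - mean(trace[base])
  }, numeric(1))
}

#' Simulate a calcium-imaging cohort with ground-truth categories
#'
#' Each animal shares the schedule; each cell gets a preferred SF drawn
#' from its genotype's log-normal distribution (a configurable fraction is
#' nonresponsive, `r_max = 0`).  The ground-truth ordinal category of a
#' cell at an SF is the contrast sensitivity \eqn{\log_2(1/c_{min})} where
#' \eqn{c_{min}} is the lowest grid contrast that the detection criterion
#' (mean evoked amplitude at least `detection_margin` AND exact sign
#' permutation p below `detection_alpha`) accepts on the noiseless trace
#' ("NR" when none is accepted).  This is the pipeline's measurement
#' definition evaluated without noise: stimulus carryover into the
#' following baseline makes even noiseless trials vary, so the permutation
#' component matters at near-margin amplitudes.
#'
#' @param cfg a [calcium_sim_config()].
#' @param schedule a schedule from [generate_stimulus_schedule()].
#' @return list with `datasets` (list of [fluorescence_dataset()] objects,
#'   one per animal) and `truth` (data.frame: cell, animal, genotype,
#'   nonresponsive flag, sf_pref, per-SF `c_min` and `category`).
#' @export
generate_calcium_dataset <- function(cfg, schedule) {
  stopifnot(inherits(cfg, "calcium_sim_config"),
            inherits(schedule, "stimulus_schedule"))
  n_frames <- attr(schedule, "n_frames")
  fr <- attr(schedule, "frame_rate")
  if (max(schedule$offset_frame) > n_frames)
    stop("schedule overflows the configured trace length")
  kern <- .indicator_kernel(cfg$indicator_kernel$rise_ms,
                            cfg$indicator_kernel$decay_ms, fr)
  gt_names <- names(cfg$n_animals_per_genotype)
  lv <- cs_levels(cfg$contrast_grid)

  old_seed <- if (exists(".Random.seed", .GlobalEnv)) get(".Random.seed", .GlobalEnv) else NULL
  on.exit(if (!is.null(old_seed)) assign(".Random.seed", old_seed, .GlobalEnv))
  set.seed(cfg$seed + 1L)

  datasets <- list()
  truth_rows <- list()
  cell0 <- 0L
  for (g in seq_along(gt_names)) {
    gname <- gt_names[g]
    for (a in seq_len(cfg$n_animals_per_genotype[g])) {
      aid <- sprintf("%s_%02d", gname, a)
      nc <- cfg$cells_per_animal
      traces <- matrix(0, nc, n_frames)
      ids <- sprintf("cell_%06d", cell0 + seq_len(nc))
      cell0 <- cell0 + nc
      nonresp <- runif(nc) < cfg$fraction_nonresponsive
      sf_pref <- 2^rnorm(nc, cfg$tuning$sf_pref_log_mean[gname],
                         cfg$tuning$sf_pref_log_sd)
      for (i in seq_len(nc)) {
        rmax <- if (nonresp[i]) 0 else cfg$tuning$r_max
        resp <- neuron_response(schedule$sf, schedule$contrast, sf_pref[i],
                                cfg$tuning$tuning_bandwidth_octaves,
                                cfg$tuning$c50[gname], cfg$tuning$hill_n, rmax)
        clean <- .cell_trace(resp, schedule, n_frames, kern, fr)
        # ground truth from the noiseless trace
        wm <- .window_means(clean, schedule)
        ev <- tapply(wm, list(schedule$sf, schedule$contrast), mean)
        pv <- tapply(wm, list(schedule$sf, schedule$contrast), .perm_p)
        cmin <- vapply(rownames(ev), function(sfl) {
          ok <- ev[sfl, ] >= cfg$detection_margin & pv[sfl, ] < cfg$detection_alpha
          resp_c <- as.numeric(colnames(ev))[ok]
          if (length(resp_c)) min(resp_c) else NA_real_
        }, numeric(1))
        truth_rows[[ids[i]]] <- data.frame(
          cell = ids[i], animal = aid, genotype = gname,
          nonresponsive = nonresp[i], sf_pref = sf_pref[i],
          sf = as.numeric(rownames(ev)), c_min = unname(cmin),
          category = ifelse(is.na(cmin), "NR",
                            format_cs(log2(1 / cmin))),
          stringsAsFactors = FALSE)
        traces[i, ] <- clean
      }
      if (cfg$noise_sd > 0)
        traces <- traces + matrix(rnorm(length(traces), 0, cfg$noise_sd), nrow = nc)
      rownames(traces) <- ids
      datasets[[aid]] <- fluorescence_dataset(traces, frame_rate = fr,
                                              animal = aid, genotype = gname,
                                              is_dff = TRUE)
    }
  }
  truth <- do.call(rbind, truth_rows)
  rownames(truth) <- NULL
  truth$category <- factor(truth$category, levels = lv, ordered = TRUE)
  list(datasets = datasets, truth = truth)
}
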