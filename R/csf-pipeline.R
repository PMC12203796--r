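# Contrast-sensitivity pipeline: fluorescence traces + stimulus epochs ->
# per-trial evoked responses -> responsiveness classification -> ordinal
# contrast-sensitivity categories -> population CSFs and responding
# proportions.
#
# Responsiveness criterion (configurable): one-sided exact sign-permutation
# test of the evoked responses against zero at alpha = 0.05 AND a mean
# evoked amplitude of at least 0.05 dF/F.

#' Container for a fluorescence trace matrix
#'
#' @param traces cells x frames matrix (rownames = cell ids; generated if
#'   absent).
#' @param frame_rate Hz.
#' @param animal,genotype,fov metadata strings.
#' @param is_dff `TRUE` when the traces are already dF/F; `FALSE` for raw
#'   fluorescence (convert with [compute_dff()]).
#' @return object of class `fluorescence_dataset`.
#' @export
fluorescence_dataset <- function(traces, frame_rate, animal, genotype,
                                 fov = "fov1", is_dff = TRUE) {
  traces <- as.matrix(traces)
  stopifnot(frame_rate > 0, !anyNA(traces))
  if (is.null(rownames(traces)))
    rownames(traces) <- sprintf("cell_%06d", seq_len(nrow(traces)))
  structure(list(traces = traces,
                 frame_times = (seq_len(ncol(traces)) - 1) / frame_rate,
                 frame_rate = frame_rate, animal = animal,
                 genotype = genotype, fov = fov, is_dff = is_dff),
            class = "fluorescence_dataset")
}

#' @export
print.fluorescence_dataset <- function(x, ...) {
  cat("fluorescence_dataset:", nrow(x$traces), "cells x", ncol(x$traces),
      "frames @", x$frame_rate, "Hz;", x$animal, "(", x$genotype, ")\n")
  invisible(x)
}

#' Convert raw fluorescence to dF/F
#'
#' dF/F = (F - F0)/F0 with F0 a rolling 10th-percentile baseline over a
#' trailing window (default 30 s).  Datasets already flagged dF/F pass
#' through unchanged.  Cells whose baseline is non-positive anywhere are
#' dropped with a warning naming them.
#'
#' @param dataset a [fluorescence_dataset()].
#' @param window_s baseline window, seconds.
#' @param prob baseline percentile (default 0.1).
#' @return a [fluorescence_dataset()] with `is_dff = TRUE`.
#' @export
compute_dff <- function(dataset, window_s = 30, prob = 0.1) {
  stopifnot(inherits(dataset, "fluorescence_dataset"))
  if (dataset$is_dff) return(dataset)
  w <- max(2L, round(window_s * dataset$frame_rate))
  out <- dataset$traces
  bad <- character(0)
  for (i in seq_len(nrow(out))) {
    f0 <- roll_quantile_cpp(dataset$traces[i, ], w, prob)
    if (any(f0 <= 0)) { bad <- c(bad, rownames(out)[i]); next }
    out[i, ] <- (dataset$traces[i, ] - f0) / f0
  }
  if (length(bad)) {
    warning("dropped ", length(bad), " cell(s) with non-positive baseline: ",
            paste(head(bad, 5), collapse = ", "),
            if (length(bad) > 5) ", ...")
    out <- out[setdiff(rownames(out), bad), , drop = FALSE]
  }
  dataset$traces <- out
  dataset$is_dff <- TRUE
  dataset
}

#' Per-trial evoked responses
#'
#' For each presentation, evoked response = mean dF/F over the stimulus
#' frames minus the mean over the immediately preceding baseline frames.
#' Frame indices in `epochs` are 0-based, windows half-open.
#'
#' @param dataset a dF/F [fluorescence_dataset()].
#' @param epochs a [generate_stimulus_schedule()] data.frame or any
#'   data.frame with columns `presentation`, `sf`, `contrast`, `block`,
#'   `onset_frame`, `offset_frame`, `baseline_onset_frame`.
#' @return data.frame: `cell`, `animal`, `genotype`, `sf`, `contrast`,
#'   `block`, `evoked`.
#' @export
trial_responses <- function(dataset, epochs) {
  stopifnot(inherits(dataset, "fluorescence_dataset"))
  if (!dataset$is_dff) stop("run compute_dff() first")
  need <- c("presentation", "sf", "contrast", "block",
            "onset_frame", "offset_frame", "baseline_onset_frame")
  stopifnot(all(need %in% names(epochs)))
  nf <- ncol(dataset$traces)
  ok <- epochs$offset_frame <= nf & epochs$baseline_onset_frame >= 0 &
    epochs$onset_frame < epochs$offset_frame
  if (!all(ok)) {
    warning("dropping ", sum(!ok), " presentation(s) outside the trace")
    epochs <- epochs[ok, , drop = FALSE]
  }
  np <- nrow(epochs)
  nc <- nrow(dataset$traces)
  ev <- matrix(NA_real_, nc, np)
  for (p in seq_len(np)) {
    stim <- (epochs$onset_frame[p] + 1L):epochs$offset_frame[p]
    base <- (epochs$baseline_onset_frame[p] + 1L):epochs$onset_frame[p]
    ev[, p] <- rowMeans(dataset$traces[, stim, drop = FALSE]) -
      rowMeans(dataset$traces[, base, drop = FALSE])
  }
  data.frame(cell = rep(rownames(dataset$traces), np),
             animal = dataset$animal, genotype = dataset$genotype,
             sf = rep(epochs$sf, each = nc),
             contrast = rep(epochs$contrast, each = nc),
             block = rep(epochs$block, each = nc),
             evoked = as.vector(ev), stringsAsFactors = FALSE)
}

#' Classify one cell-stimulus pair as responsive
#'
#' Responsive iff (a) a one-sided exact sign-permutation test of the
#' evoked responses against zero gives p < `alpha` and (b) the mean evoked
#' response is at least `amplitude_floor`.  With fewer than 3 repeats the
#' pair is treated as nonresponsive with a warning.
#'
#' @param evoked numeric vector of per-repeat evoked responses.
#' @param alpha significance level (default 0.05).
#' @param amplitude_floor minimum mean evoked dF/F (default 0.05).
#' @return logical.
#' @export
classify_responsive <- function(evoked, alpha = 0.05, amplitude_floor = 0.05) {
  n <- length(evoked)
  if (n < 3) {
    warning("fewer than 3 repeats; treated as nonresponsive")
    return(FALSE)
  }
  mean(evoked) >= amplitude_floor &&
    permutation_p_onesided(evoked) < alpha
}

#' One-sided sign-permutation p-value for a mean greater than zero
#'
#' Exact over all 2^n sign assignments for n <= 12; one-sided one-sample
#' t approximation beyond that (documented fallback; the design uses
#' n = 5 repeats).
#'
#' @param x numeric vector.
#' @return p-value.
#' @export
permutation_p_onesided <- function(x) {
  n <- length(x)
  obs <- mean(x)
  if (n <= 12) {
    signs <- as.matrix(expand.grid(rep(list(c(-1, 1)), n)))
    perm <- as.vector(signs %*% x) / n
    mean(perm >= obs - 1e-12)
  } else {
    if (sd(x) == 0) return(if (obs > 0) 0 else 1)
    t.test(x, alternative = "greater")$p.value
  }
}

#' Ordinal category labels for a contrast grid
#'
#' @param contrast_grid contrast fractions in (0, 1].
#' @return character levels, `"NR"` first, then contrast sensitivities
#'   \eqn{\log_2(1/c)} in increasing order.
#' @export
cs_levels <- function(contrast_grid) {
  cs <- sort(log2(1 / contrast_grid))
  c("NR", format_cs(cs))
}

#' @rdname cs_levels
#' @param cs numeric contrast sensitivities.
#' @export
format_cs <- function(cs) trimws(formatC(cs, format = "fg", digits = 6))

#' Minimum responsive contrast at one SF
#'
#' The smallest grid contrast classified responsive, taken literally (no
#' monotonic fill-in across intermediate contrasts); `NA` when no contrast
#' is responsive.
#'
#' @param responsive logical vector, one per contrast.
#' @param contrasts matching contrast fractions.
#' @return smallest responsive contrast, or `NA_real_`.
#' @export
min_responsive_contrast <- function(responsive, contrasts) {
  stopifnot(length(responsive) == length(contrasts))
  hit <- contrasts[responsive]
  if (length(hit)) min(hit) else NA_real_
}

#' Build the per-cell contrast-sensitivity table
#'
#' Runs [trial_responses()], classifies every (cell, SF, contrast) triple,
#' applies [min_responsive_contrast()] per (cell, SF), and flags a cell
#' visually responsive iff it responds to at least one of the stimuli.
#'
#' @param datasets a [fluorescence_dataset()] or list of them.
#' @param epochs stimulus epochs (see [trial_responses()]).
#' @param alpha,amplitude_floor passed to [classify_responsive()].
#' @return data.frame of class `cs_table`: `cell`, `animal`, `genotype`,
#'   `sf`, `c_min`, `category` (ordered factor, `"NR"` lowest),
#'   `visually_responsive`.
#' @export
build_cs_table <- function(datasets, epochs, alpha = 0.05, amplitude_floor = 0.05) {
  if (inherits(datasets, "fluorescence_dataset")) datasets <- list(datasets)
  lv <- cs_levels(sort(unique(epochs$contrast)))
  out <- list()
  for (ds in datasets) {
    tr <- trial_responses(ds, epochs)
    dt <- data.table::as.data.table(tr)
    resp <- dt[, .(mean_ev = mean(evoked), p = permutation_p_onesided(evoked),
                   n_rep = .N),
               by = .(cell, animal, genotype, sf, contrast)]
    few <- resp$n_rep < 3
    if (any(few)) warning(sum(few), " cell-stimulus pairs with < 3 repeats treated nonresponsive")
    resp[, responsive := !few & mean_ev >= amplitude_floor & p < alpha]
    cs <- resp[, .(c_min = min_responsive_contrast(responsive, contrast)),
               by = .(cell, animal, genotype, sf)]
    vr <- resp[, .(visually_responsive = any(responsive)), by = .(cell)]
    cs <- merge(cs, vr, by = "cell", sort = FALSE)
    out[[ds$animal]] <- cs
  }
  res <- as.data.frame(data.table::rbindlist(out))
  res$category <- factor(ifelse(is.na(res$c_min), "NR", format_cs(log2(1 / res$c_min))),
                         levels = lv, ordered = TRUE)
  res <- res[order(res$cell, res$sf), ]
  rownames(res) <- NULL
  class(res) <- c("cs_table", "data.frame")
  res
}

#' Population contrast sensitivity function
#'
#' Mean and interquartile range of the numeric contrast sensitivity over
#' non-NR cells, per group and SF, with the fraction of NR cells reported
#' alongside.  Only visually responsive cells enter.
#'
#' @param cs_table a [build_cs_table()] result.
#' @param group_by `"animal"` (default) or `"genotype"`.
#' @return data.frame: group, `sf`, `mean_cs`, `q25`, `q75`,
#'   `fraction_nr`, `n_cells`.
#' @export
population_csf <- function(cs_table, group_by = c("animal", "genotype")) {
  group_by <- match.arg(group_by)
  d <- cs_table[cs_table$visually_responsive, , drop = FALSE]
  if (!nrow(d)) stop("no visually responsive cells")
  d$cs <- ifelse(d$category == "NR", NA_real_, log2(1 / d$c_min))
  dt <- data.table::as.data.table(d)
  data.table::setnames(dt, group_by, ".group")
  agg <- dt[, {
    num <- cs[!is.na(cs)]
    list(mean_cs = if (length(num)) mean(num) else NA_real_,
         q25 = if (length(num)) unname(quantile(num, 0.25)) else NA_real_,
         q75 = if (length(num)) unname(quantile(num, 0.75)) else NA_real_,
         fraction_nr = mean(is.na(cs)),
         n_cells = .N)
  }, by = .(.group, sf)]
  agg <- as.data.frame(agg)
  names(agg)[1] <- group_by
  agg[order(agg[[1]], agg$sf), , drop = FALSE]
}

#' Proportion of visually responsive cells responding at an SF
#'
#' Numerator: visually responsive cells with a non-NR category at `sf`;
#' denominator: all visually responsive cells in the cohort.
#'
#' @param cs_table a [build_cs_table()] result.
#' @param sf spatial frequency (must match a value in the table).
#' @param cohort optional genotype restriction.
#' @return fraction in `[0, 1]`.
#' @export
proportion_responding <- function(cs_table, sf, cohort = NULL) {
  d <- cs_table[cs_table$visually_responsive, , drop = FALSE]
  if (!is.null(cohort)) d <- d[d$genotype == cohort, , drop = FALSE]
  cells <- unique(d$cell)
  if (!length(cells)) stop("empty cohort")
  at_sf <- d[abs(as.numeric(d$sf) - as.numeric(sf)) < 1e-9, , drop = FALSE]
  sum(at_sf$category != "NR") / length(cells)
}
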