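# Group-comparison and multiplicity layer: Shapiro-Wilk-gated two-sample
# tests, Bonferroni (primary hypotheses) and Benjamini-Hochberg (secondary
# hypotheses) corrections, a two-sample test of equal proportions with
# Wilson score intervals, and the PV+ cell density analysis.

#' Normality gate for choosing test and summary style
#'
#' Shapiro-Wilk at alpha = 0.05: p > 0.05 means "normal" (report mean and
#' SD, compare by t-test), otherwise "non-normal" (median and IQR, rank
#' test).  A constant vector is non-normal with a warning.
#'
#' @param values numeric vector, n >= 3.
#' @param alpha gate level.
#' @return list: `normal` (logical), `p_value`, `W`.
#' @export
normality_gate <- function(values, alpha = 0.05) {
  values <- values[!is.na(values)]
  if (length(values) < 3) stop("need at least 3 observations for the normality gate")
  if (stats::var(values) == 0) {
    warning("constant vector; treated as non-normal")
    return(list(normal = FALSE, p_value = NA_real_, W = NA_real_))
  }
  sw <- shapiro.test(values)
  list(normal = sw$p.value > alpha, p_value = sw$p.value, W = unname(sw$statistic))
}

.summarise_group <- function(x, normal) {
  x <- x[!is.na(x)]
  if (normal) {
    list(style = "mean_sd", center = mean(x), spread = sd(x), n = length(x))
  } else {
    q <- unname(quantile(x, c(0.25, 0.75)))
    list(style = "median_iqr", center = median(x), spread_lo = q[1],
         spread_hi = q[2], n = length(x))
  }
}

#' Two-sample genotype comparison with a normality gate
#'
#' Both groups pass the Shapiro-Wilk gate: Welch t-test with mean/SD
#' summaries; otherwise a rank test with median/IQR summaries.  The rank
#' test defaults to the rank-sum (Mann-Whitney) test appropriate for
#' independent samples; a paired signed-rank option is provided.
#' Summaries are rounded to 2 significant figures in the printed report.
#'
#' @param a,b numeric samples.
#' @param variable name for reporting.
#' @param tier `"primary"` or `"secondary"` hypothesis tier.
#' @param rank_test `"ranksum"` (default) or `"signedrank"` (requires
#'   equal lengths).
#' @param welch use Welch's t-test (default) rather than pooled-variance.
#' @return list of class `group_comparison`: test used, statistic, raw p,
#'   per-group summaries; corrected p filled in by [correct_comparisons()].
#' @export
compare_groups <- function(a, b, variable = "value",
                           tier = c("secondary", "primary"),
                           rank_test = c("ranksum", "signedrank"),
                           welch = TRUE) {
  tier <- match.arg(tier)
  rank_test <- match.arg(rank_test)
  a <- a[!is.na(a)]; b <- b[!is.na(b)]
  if (!length(a) || !length(b)) stop("empty group")
  ga <- normality_gate(a); gb <- normality_gate(b)
  normal <- ga$normal && gb$normal
  if (normal) {
    tt <- t.test(a, b, var.equal = !welch)
    test <- "t"; stat <- unname(tt$statistic); p <- tt$p.value
  } else if (rank_test == "ranksum") {
    wt <- suppressWarnings(wilcox.test(a, b))
    test <- "wilcoxon"; stat <- unname(wt$statistic); p <- wt$p.value
  } else {
    stopifnot(length(a) == length(b))
    wt <- suppressWarnings(wilcox.test(a, b, paired = TRUE))
    test <- "wilcoxon_signedrank"; stat <- unname(wt$statistic); p <- wt$p.value
  }
  structure(list(variable = variable, tier = tier, test = test,
                 statistic = stat, p_value = p, p_corrected = NA_real_,
                 correction = NA_character_,
                 group_a = .summarise_group(a, normal),
                 group_b = .summarise_group(b, normal),
                 normal = normal),
            class = "group_comparison")
}

#' @export
print.group_comparison <- function(x, ...) {
  s <- function(g) if (g$style == "mean_sd")
    paste0(signif2(g$center), " +/- ", signif2(g$spread), " (n=", g$n, ")")
  else paste0(signif2(g$center), " [IQR ", signif2(g$spread_lo), "-",
              signif2(g$spread_hi), "] (n=", g$n, ")")
  cat(x$variable, " [", x$tier, "]: ", s(x$group_a), " vs ", s(x$group_b),
      "; ", x$test, "-test p = ", signif2(x$p_value),
      if (!is.na(x$p_corrected)) paste0(", corr. p = ", signif2(x$p_corrected)),
      "\n", sep = "")
  invisible(x)
}

#' Bonferroni correction
#'
#' `min(1, p * m)` elementwise; `m` defaults to the number of p-values and
#' may be larger (a prespecified family size).
#'
#' @param p_values raw p-values in `[0, 1]`.
#' @param m family size, at least `length(p_values)`.
#' @return corrected p-values.
#' @export
bonferroni <- function(p_values, m = length(p_values)) {
  if (any(p_values < 0 | p_values > 1, na.rm = TRUE)) stop("p-values outside [0, 1]")
  if (m < length(p_values)) stop("m smaller than the number of p-values")
  pmin(1, p_values * m)
}

#' Benjamini-Hochberg step-up adjustment
#'
#' p * m / rank with downward cumulative-minimum monotonisation and a cap
#' at 1; ties handled stably.
#'
#' @param p_values raw p-values in `[0, 1]`.
#' @return adjusted p-values, same order as the input.
#' @export
benjamini_hochberg <- function(p_values) {
  if (!length(p_values)) return(numeric(0))
  if (any(p_values < 0 | p_values > 1, na.rm = TRUE)) stop("p-values outside [0, 1]")
  m <- length(p_values)
  ord <- order(p_values)
  ranked <- p_values[ord] * m / seq_len(m)
  adj <- rev(cummin(rev(ranked)))
  out <- numeric(m)
  out[ord] <- pmin(1, adj)
  out
}

#' Assign corrected p-values to a set of comparisons
#'
#' Primary-tier comparisons get Bonferroni with `m_primary`; secondary
#' tier gets Benjamini-Hochberg over `m_secondary` (the BH family may be
#' declared larger than the comparisons supplied, in which case the
#' missing members are counted at p = 1).
#'
#' @param comparisons list of [compare_groups()] results.
#' @param m_primary Bonferroni family size (default 3).
#' @param m_secondary BH family size (default 12).
#' @return the list with `p_corrected`/`correction` filled in.
#' @export
correct_comparisons <- function(comparisons, m_primary = 3, m_secondary = 12) {
  tiers <- vapply(comparisons, `[[`, character(1), "tier")
  praw <- vapply(comparisons, `[[`, numeric(1), "p_value")
  if (any(tiers == "primary")) {
    idx <- which(tiers == "primary")
    corr <- bonferroni(praw[idx], max(m_primary, length(idx)))
    for (j in seq_along(idx)) {
      comparisons[[idx[j]]]$p_corrected <- corr[j]
      comparisons[[idx[j]]]$correction <- "bonferroni"
    }
  }
  if (any(tiers == "secondary")) {
    idx <- which(tiers == "secondary")
    fam <- c(praw[idx], rep(1, max(0, m_secondary - length(idx))))
    corr <- benjamini_hochberg(fam)[seq_along(idx)]
    for (j in seq_along(idx)) {
      comparisons[[idx[j]]]$p_corrected <- corr[j]
      comparisons[[idx[j]]]$correction <- "benjamini_hochberg"
    }
  }
  comparisons
}

#' Two-sample test of equal proportions with Wilson score intervals
#'
#' Chi-squared test of equal proportions with continuity correction (the
#' conventional "test of equal proportions"), plus a Wilson score interval
#' for each group.
#'
#' @param k1,n1,k2,n2 successes and totals per group.
#' @param conf confidence level for the Wilson intervals.
#' @return list: `statistic` (X-squared), `p_value`, `proportions`,
#'   `wilson_ci` (2 x 2 matrix).
#' @export
wilson_proportions_test <- function(k1, n1, k2, n2, conf = 0.95) {
  stopifnot(n1 >= 1, n2 >= 1, k1 >= 0, k2 >= 0, k1 <= n1, k2 <= n2)
  if (k1 / n1 == k2 / n2) {
    # exactly equal sample proportions: statistic 0, p = 1 (uncorrected;
    # prop.test's statistic is 0/0 when both proportions are 0 or 1)
    pt <- list(statistic = 0, p.value = 1)
  } else {
    pt <- suppressWarnings(prop.test(c(k1, k2), c(n1, n2), correct = TRUE))
  }
  z <- qnorm(1 - (1 - conf) / 2)
  wilson <- function(k, n) {
    p <- k / n
    den <- 1 + z^2 / n
    ctr <- (p + z^2 / (2 * n)) / den
    hw <- z * sqrt(p * (1 - p) / n + z^2 / (4 * n^2)) / den
    c(lower = ctr - hw, upper = ctr + hw)
  }
  list(statistic = unname(pt$statistic), p_value = pt$p.value,
       proportions = c(p1 = k1 / n1, p2 = k2 / n2),
       wilson_ci = rbind(group1 = wilson(k1, n1), group2 = wilson(k2, n2)))
}

#' PV+ cell density comparison between genotypes
#'
#' Section-level one-way ANOVA of density (count/area) on genotype, group
#' means with SEM, and the percent difference of the second genotype
#' relative to the first.  An animal-level sensitivity analysis (mean
#' density per animal, Welch t-test) is reported alongside and flagged
#' advisory: sections within an animal are pseudoreplicates.
#'
#' @param sections data.frame with columns `animal`, `genotype`, `count`,
#'   `area_mm2` (zero-area sections are rejected).
#' @return list of class `density_comparison`: `F_statistic`, `p_value`,
#'   `group_means`, `group_sem`, `percent_difference`,
#'   `animal_level` (advisory t-test).
#' @export
pv_density_analysis <- function(sections) {
  stopifnot(all(c("animal", "genotype", "count", "area_mm2") %in% names(sections)))
  if (any(sections$area_mm2 <= 0)) stop("zero or negative section area")
  d <- as.data.frame(sections)
  d$density <- d$count / d$area_mm2
  d$genotype <- factor(d$genotype)
  if (nlevels(d$genotype) != 2) stop("need exactly 2 genotypes")
  if (any(table(d$genotype) < 2)) stop("need >= 2 sections per genotype")
  fit <- aov(density ~ genotype, data = d)
  an <- anova(fit)
  means <- tapply(d$density, d$genotype, mean)
  sems <- tapply(d$density, d$genotype, function(x) sd(x) / sqrt(length(x)))
  pct <- (means[2] - means[1]) / means[1] * 100
  per_animal <- tapply(d$density, list(d$animal, d$genotype), mean)
  g1 <- per_animal[!is.na(per_animal[, 1]), 1]
  g2 <- per_animal[!is.na(per_animal[, 2]), 2]
  animal_level <- if (length(g1) >= 2 && length(g2) >= 2) {
    tryCatch({
      tt <- t.test(g2, g1)
      list(p_value = tt$p.value, t_statistic = unname(tt$statistic),
           note = "advisory: animal-level reanalysis (sections are pseudoreplicates)")
    }, error = function(e) list(p_value = NA_real_, t_statistic = NA_real_,
                                note = paste("animal-level test unavailable:",
                                             conditionMessage(e))))
  } else NULL
  structure(list(F_statistic = an[["F value"]][1], p_value = an[["Pr(>F)"]][1],
                 group_means = means, group_sem = sems,
                 percent_difference = unname(pct),
                 n_sections = table(d$genotype),
                 animal_level = animal_level),
            class = "density_comparison")
}

#' @export
print.density_comparison <- function(x, ...) {
  cat("PV+ density ANOVA: F =", signif2(x$F_statistic),
      "p =", signif2(x$p_value), "\n")
  cat("  means:", paste(names(x$group_means), signif2(x$group_means),
                        "+/-", signif2(x$group_sem), collapse = "; "), "\n")
  cat("  percent difference:", signif2(x$percent_difference), "%\n")
  invisible(x)
}

#' Percent difference between two group means
#'
#' `(b - a)/a * 100`; with `digits` significant figures applied to the
#' result (the package's reporting rule is 2).
#'
#' @param a reference mean.
#' @param b comparison mean.
#' @param digits significant figures (NULL for unrounded).
#' @return percent difference.
#' @export
percent_difference <- function(a, b, digits = 2) {
  out <- (b - a) / a * 100
  if (!is.null(digits)) signif(out, digits) else out
}
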