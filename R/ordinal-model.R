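# Cumulative link mixed model (CLMM) for ordinal contrast-sensitivity
# categories: P(Y <= k | u_a) = F(theta_k - x'beta - u_a), with a single
# per-animal random intercept u_a ~ N(0, sigma_u^2) integrated out of the
# likelihood by adaptive Gauss-Hermite quadrature (1 node = Laplace).

#' Assemble an ordinal dataset for the cumulative link mixed model
#'
#' Converts a contrast-sensitivity table (see [build_cs_table()]) into the
#' modelling frame used by [fit_clmm()]: one row per (cell, spatial
#' frequency), ordinal response `category` with "NR" as the lowest level.
#'
#' @param cs_table data.frame with columns `cell`, `animal`, `genotype`,
#'   `sf`, `category` (ordered factor whose lowest level is `"NR"`), and
#'   optionally `visually_responsive`.
#' @param drop_nr drop rows in the "NR" category instead of modelling them
#'   as the lowest ordinal level (default `FALSE`; the default keeps
#'   nonresponding cells informative).
#' @param responsive_only keep only visually responsive cells when the
#'   `visually_responsive` flag is present (default `TRUE`).
#' @return data.frame with columns `cell`, `animal`, `genotype` (factor),
#'   `sf` (factor), `category` (ordered factor).
#' @export
ordinal_dataset <- function(cs_table, drop_nr = FALSE, responsive_only = TRUE) {
  stopifnot(all(c("cell", "animal", "genotype", "sf", "category") %in% names(cs_table)))
  d <- as.data.frame(cs_table)
  if (responsive_only && "visually_responsive" %in% names(d)) {
    d <- d[d$visually_responsive, , drop = FALSE]
  }
  if (!is.ordered(d$category)) {
    lv <- unique(as.character(d$category))
    num <- suppressWarnings(as.numeric(lv[lv != "NR"]))
    lv <- c(if ("NR" %in% lv) "NR", lv[lv != "NR"][order(num)])
    d$category <- factor(as.character(d$category), levels = lv, ordered = TRUE)
  }
  if (drop_nr) {
    d <- d[d$category != "NR", , drop = FALSE]
    d$category <- droplevels(d$category)
  }
  # WT is the conventional reference level when both labels are present
  gl <- unique(as.character(d$genotype))
  d$genotype <- if (setequal(gl, c("WT", "TS"))) factor(d$genotype, c("WT", "TS"))
                else factor(d$genotype)
  d$sf <- factor(d$sf)
  d$animal <- factor(d$animal)
  droplevels(d)
}

#' Fit a cumulative link mixed model with a per-animal random intercept
#'
#' Fits \eqn{P(Y \le k \mid u_a) = F(\theta_k - x'\beta - u_a)} with
#' \eqn{u_a \sim N(0, \sigma_u^2)}, maximising the marginal likelihood in
#' which each animal's random intercept is integrated out by adaptive
#' Gauss-Hermite quadrature centred on the conditional mode (the log
#' integrand is concave for both supported links, so the mode search is a
#' plain Newton iteration).  `nAGQ = 1` is the Laplace approximation.
#' Optimisation is quasi-Newton (BFGS) on an unconstrained parameterisation
#' (first threshold, log threshold increments, coefficients, log sigma),
#' started from a fixed-effects proportional-odds fit.
#'
#' @param data data.frame from [ordinal_dataset()] (columns `animal`,
#'   `category`, and the covariates named in `formula_terms`).
#' @param formula_terms one-sided formula for the fixed effects
#'   (default `~ genotype * sf`).
#' @param link `"logit"` (default) or `"probit"`.
#' @param nAGQ number of quadrature nodes (default 15; 1 = Laplace).
#' @param sigma_u `NULL` to estimate the random-intercept SD, or a fixed
#'   non-negative value (0 reduces the model to a plain proportional-odds
#'   regression on the pooled data).
#' @param start optional list with elements `theta`, `beta`, `sigma_u`
#'   overriding the default starting values.
#' @param control passed to [stats::optim()] (`maxit`, `reltol`).
#' @param hessian compute the fixed-effect covariance by numeric
#'   differentiation (default `TRUE`; simulation studies that only need
#'   the log-likelihood can skip it).
#' @return object of class `clmm_fit`: coefficients `beta`, thresholds
#'   `theta`, `sigma_u`, `logLik`, `vcov_beta`, convergence diagnostics.
#' @seealso [anova_deviance()], [cox_snell_r2()], [marginal_contrasts()]
#' @export
fit_clmm <- function(data, formula_terms = ~ genotype * sf, link = c("logit", "probit"),
                     nAGQ = 15, sigma_u = NULL, start = NULL, control = list(),
                     hessian = TRUE) {
  link <- match.arg(link)
  stopifnot(is.data.frame(data), "animal" %in% names(data), "category" %in% names(data))
  data <- droplevels(data)
  y <- as.integer(data$category)
  K <- nlevels(data$category)
  if (K < 2) stop("need at least 2 observed ordinal levels")
  mt <- stats::terms(formula_terms)
  mf <- stats::model.frame(mt, data)
  Xfull <- stats::model.matrix(mt, mf)
  has_int <- "(Intercept)" %in% colnames(Xfull)
  X <- if (has_int) Xfull[, -1, drop = FALSE] else Xfull
  p <- ncol(X)
  animal <- factor(data$animal)
  nanim <- nlevels(animal)
  if ("genotype" %in% names(data)) {
    per_gt <- tapply(animal, data$genotype, function(a) length(unique(a)))
    if (any(per_gt < 2, na.rm = TRUE))
      warning("fewer than 2 animals in a genotype group; sigma_u weakly identified")
  }
  estimate_sigma <- is.null(sigma_u)
  sigma_fixed <- if (estimate_sigma) -1 else sigma_u
  if (!estimate_sigma) stopifnot(sigma_u >= 0)

  # starting values: fixed-effects proportional-odds fit
  th0 <- be0 <- NULL
  if (!is.null(start)) {
    th0 <- start$theta; be0 <- start$beta
  }
  if (is.null(th0) || is.null(be0)) {
    po <- tryCatch({
      dd <- cbind(mf, .y = data$category)
      MASS::polr(stats::as.formula(paste(".y ~", paste(attr(mt, "term.labels"), collapse = "+"))),
                 data = dd, method = if (link == "logit") "logistic" else "probit")
    }, error = function(e) NULL)
    if (!is.null(po)) {
      if (is.null(th0)) th0 <- as.numeric(po$zeta)
      if (is.null(be0)) {
        be0 <- setNames(numeric(p), colnames(X))
        be0[names(coef(po))] <- coef(po)
      }
    } else {
      cum <- cumsum(tabulate(y, K))[seq_len(K - 1)] / length(y)
      cum <- pmin(pmax(cum, 1e-3), 1 - 1e-3)
      if (is.null(th0)) th0 <- if (link == "logit") stats::qlogis(cum) else qnorm(cum)
      if (is.null(be0)) be0 <- numeric(p)
    }
  }
  th0 <- sort(as.numeric(th0))
  d0 <- pmax(diff(th0), 1e-3)
  sig0 <- if (!is.null(start$sigma_u)) start$sigma_u else 0.1
  par0 <- c(th0[1], if (K > 2) log(d0), as.numeric(be0),
            if (estimate_sigma) log(max(sig0, 1e-3)))

  gh <- gauss_hermite(nAGQ)
  link_code <- if (link == "logit") 0L else 1L
  an0 <- as.integer(animal) - 1L
  fn <- function(par) clmm_nll_cpp(par, y, X, an0, nanim, K, gh$nodes, gh$weights,
                                   link_code, sigma_fixed, as.integer(estimate_sigma))
  gr <- function(par) clmm_nll_grad_cpp(par, y, X, an0, nanim, K, gh$nodes, gh$weights,
                                        link_code, sigma_fixed, as.integer(estimate_sigma))
  ctl <- modifyList(list(maxit = 400, reltol = 1e-10), control)
  opt <- optim(par0, fn, gr, method = "BFGS", control = ctl)
  if (opt$convergence != 0)
    warning("CLMM optimiser did not report convergence (code ", opt$convergence,
            "); gradient norm ", format(sqrt(sum(gr(opt$par)^2)), digits = 3))

  par <- opt$par
  theta <- cumsum(c(par[1], if (K > 2) exp(par[2:(K - 1)])))
  beta <- setNames(par[K:(K - 1 + p)], colnames(X))
  sig <- if (estimate_sigma) exp(par[K + p]) else sigma_u
  H <- if (hessian) tryCatch(optimHess(par, fn, gr), error = function(e) NULL) else NULL
  Vint <- if (!is.null(H)) tryCatch(solve(H), error = function(e) NULL) else NULL
  vcov_beta <- if (!is.null(Vint)) Vint[K:(K - 1 + p), K:(K - 1 + p), drop = FALSE] else NULL
  if (!is.null(vcov_beta)) dimnames(vcov_beta) <- list(names(beta), names(beta))

  structure(list(
    beta = beta, theta = theta, sigma_u = sig, logLik = -opt$value,
    vcov_beta = vcov_beta, vcov_internal = Vint, par_internal = par,
    convergence = opt$convergence, counts = opt$counts,
    gradient_norm = sqrt(sum(gr(par)^2)),
    n = length(y), n_cells = length(unique(data$cell %||% seq_along(y))),
    n_animals = nanim, K = K, nAGQ = nAGQ, link = link,
    estimate_sigma = estimate_sigma,
    terms = mt, xlevels = stats::.getXlevels(mt, mf),
    category_levels = levels(data$category),
    call = match.call()
  ), class = "clmm_fit")
}

#' @export
logLik.clmm_fit <- function(object, ...) {
  structure(object$logLik,
            df = length(object$par_internal), nobs = object$n, class = "logLik")
}

#' @export
coef.clmm_fit <- function(object, ...) object$beta

#' @export
vcov.clmm_fit <- function(object, ...) object$vcov_beta

#' @export
print.clmm_fit <- function(x, ...) {
  cat("Cumulative link mixed model (", x$link, " link, nAGQ = ", x$nAGQ, ")\n", sep = "")
  cat("  n =", x$n, "observations,", x$n_animals, "animals, K =", x$K, "levels\n")
  cat("  logLik =", format(x$logLik, digits = 8),
      " sigma_u =", format(x$sigma_u, digits = 4), "\n")
  cat("Thresholds:\n"); print(signif(x$theta, 4))
  cat("Coefficients:\n"); print(signif(x$beta, 4))
  invisible(x)
}

#' Likelihood-ratio (analysis of deviance) test between nested CLMM fits
#'
#' @param full,reduced fitted models from [fit_clmm()] on the same data,
#'   `reduced` nested in `full` (e.g. without the genotype-by-SF
#'   interaction).
#' @return list of class `deviance_test`: `chisq`, `df`, `p_value`, and the
#'   models' log-likelihoods.
#' @export
anova_deviance <- function(full, reduced) {
  stopifnot(inherits(full, "clmm_fit"), inherits(reduced, "clmm_fit"))
  if (full$n != reduced$n) stop("models fitted to different numbers of observations")
  df <- length(full$beta) - length(reduced$beta)
  if (df <= 0) stop("'full' has no more fixed parameters than 'reduced'")
  chisq <- 2 * (full$logLik - reduced$logLik)
  if (chisq < -1e-6)
    warning("full model has lower likelihood than reduced; refit with better starts")
  chisq <- max(chisq, 0)
  structure(list(chisq = chisq, df = df, p_value = pchisq(chisq, df, lower.tail = FALSE),
                 logLik_full = full$logLik, logLik_reduced = reduced$logLik),
            class = "deviance_test")
}

#' @export
print.deviance_test <- function(x, ...) {
  cat("Analysis of deviance: chi^2 =", signif(x$chisq, 4), "df =", x$df,
      "p =", format(x$p_value, digits = 3), "\n")
  invisible(x)
}

#' Cox-Snell pseudo-R-squared
#'
#' \eqn{1 - \exp\{(2/n)(\ell_0 - \ell_1)\}} comparing a fitted model with
#' the null model (thresholds + random intercept only) on the same data.
#'
#' @param full fitted model of interest.
#' @param null null model (same data, intercepts/random effect only).
#' @return pseudo-R-squared in [0, 1).
#' @export
cox_snell_r2 <- function(full, null) {
  stopifnot(inherits(full, "clmm_fit"), inherits(null, "clmm_fit"))
  if (full$n != null$n) stop("models fitted to different data")
  1 - exp((2 / full$n) * (null$logLik - full$logLik))
}

#' Genotype contrasts on the latent scale at each spatial frequency
#'
#' For each SF level, the difference of the latent-scale linear predictor
#' between the second and first genotype level (conventionally TS - WT),
#' with delta-method standard errors from the fixed-effect covariance, a
#' normal Z ratio, two-sided p, and Benjamini-Hochberg correction across
#' the SF levels tested.
#'
#' @param fit converged [fit_clmm()] fit whose terms involve factors
#'   `genotype` and `sf`.
#' @param sf_levels SF levels to test (default: all levels in the fit).
#' @return data.frame with columns `sf`, `estimate`, `se`, `z_ratio`,
#'   `p_value`, `p_corrected`.
#' @export
marginal_contrasts <- function(fit, sf_levels = NULL) {
  stopifnot(inherits(fit, "clmm_fit"))
  if (is.null(fit$vcov_beta)) stop("fixed-effect covariance unavailable (singular Hessian)")
  gl <- fit$xlevels[["genotype"]]
  sl <- fit$xlevels[["sf"]]
  if (is.null(gl) || is.null(sl)) stop("fit must include 'genotype' and 'sf' factors")
  if (length(gl) != 2) stop("genotype must have exactly 2 levels")
  if (is.null(sf_levels)) sf_levels <- sl
  sf_levels <- as.character(sf_levels)
  stopifnot(all(sf_levels %in% sl))
  grid <- function(g) {
    nd <- data.frame(genotype = factor(g, levels = gl),
                     sf = factor(sf_levels, levels = sl))
    mm <- stats::model.matrix(stats::delete.response(fit$terms), nd, xlev = fit$xlevels)
    mm[, names(fit$beta), drop = FALSE]
  }
  L <- grid(gl[2]) - grid(gl[1])           # rows: sf levels
  est <- drop(L %*% fit$beta)
  se <- sqrt(pmax(diag(L %*% fit$vcov_beta %*% t(L)), 0))
  z <- ifelse(se > 0, est / se, 0)
  praw <- 2 * pnorm(-abs(z))
  data.frame(sf = sf_levels, estimate = est, se = se, z_ratio = z,
             p_value = praw, p_corrected = benjamini_hochberg(praw),
             row.names = NULL)
}

#' Simulate an ordinal contrast-sensitivity cohort from the CLMM itself
#'
#' Draws (cell, SF) ordinal categories directly from the cumulative link
#' mixed model: latent value \eqn{x'\beta + u_a + \epsilon} with logistic
#' (or normal) noise cut at the thresholds.  Used for parameter-recovery
#' and type-I-error studies of [fit_clmm()].
#'
#' @param n_animals named vector, animals per genotype
#'   (default `c(WT = 4, TS = 5)`).
#' @param cells_per_animal cells per animal; each cell contributes one row
#'   per SF level.
#' @param sf_levels character or numeric vector of SF levels.
#' @param theta increasing thresholds (length K-1).
#' @param beta_genotype main effect of the second genotype level.
#' @param beta_sf effects of non-reference SF levels (length
#'   `length(sf_levels) - 1`).
#' @param beta_interaction genotype-by-SF interaction effects (same
#'   length as `beta_sf`).
#' @param sigma_u random-intercept SD between animals.
#' @param link `"logit"` or `"probit"`.
#' @param seed integer seed.
#' @return data.frame with columns `cell`, `animal`, `genotype`, `sf`,
#'   `category` (ordered factor `1...K`), plus attribute `truth` holding
#'   the generating parameters.
#' @export
simulate_ordinal_cohort <- function(n_animals = c(WT = 4, TS = 5),
                                    cells_per_animal = 300,
                                    sf_levels = c("0.014", "0.031", "0.064", "0.128",
                                                  "0.236", "0.383", "0.512"),
                                    theta = c(-1.5, -0.5, 0.5, 1.5, 2.5, 3.5),
                                    beta_genotype = -0.5,
                                    beta_sf = seq(-0.4, by = -0.4,
                                                  length.out = length(sf_levels) - 1),
                                    beta_interaction = rep(0.8, length(sf_levels) - 1),
                                    sigma_u = 0.5, link = c("logit", "probit"),
                                    seed = 1L) {
  link <- match.arg(link)
  stopifnot(length(n_animals) == 2, all(diff(theta) > 0),
            length(beta_sf) == length(sf_levels) - 1,
            length(beta_interaction) == length(sf_levels) - 1)
  gl <- names(n_animals) %||% c("WT", "TS")
  withr_seed <- function(expr) { # local RNG, restore afterwards
    old <- if (exists(".Random.seed", .GlobalEnv)) get(".Random.seed", .GlobalEnv) else NULL
    on.exit(if (!is.null(old)) assign(".Random.seed", old, .GlobalEnv))
    set.seed(seed); expr
  }
  withr_seed({
    rows <- list()
    cell0 <- 0L
    for (g in seq_along(gl)) {
      for (a in seq_len(n_animals[g])) {
        aid <- sprintf("%s_%02d", gl[g], a)
        u <- rnorm(1, 0, sigma_u)
        cells <- cell0 + seq_len(cells_per_animal)
        cell0 <- cell0 + cells_per_animal
        d <- expand.grid(cell = sprintf("cell_%05d", cells),
                         sf = sf_levels, KEEP.OUT.ATTRS = FALSE,
                         stringsAsFactors = FALSE)
        sfi <- match(d$sf, sf_levels) - 1L     # 0 = reference level
        eta <- ifelse(g == 2, beta_genotype, 0) +
          ifelse(sfi > 0, beta_sf[pmax(sfi, 1)], 0) +
          ifelse(g == 2 & sfi > 0, beta_interaction[pmax(sfi, 1)], 0)
        eps <- if (link == "logit") stats::rlogis(nrow(d)) else rnorm(nrow(d))
        lat <- eta + u + eps
        d$category <- 1L + rowSums(outer(lat, theta, `>`))
        d$animal <- aid
        d$genotype <- gl[g]
        rows[[aid]] <- d
      }
    }
    out <- do.call(rbind, rows)
    row.names(out) <- NULL
    out$category <- factor(out$category, levels = seq_len(length(theta) + 1),
                           ordered = TRUE)
    out$genotype <- factor(out$genotype, levels = gl)
    out$sf <- factor(out$sf, levels = sf_levels)
    out$animal <- factor(out$animal)
    attr(out, "truth") <- list(theta = theta, beta_genotype = beta_genotype,
                               beta_sf = beta_sf, beta_interaction = beta_interaction,
                               sigma_u = sigma_u, link = link, seed = seed)
    out
  })
}
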