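# Independent oracles used across the suite.  These deliberately avoid the
# package's own code paths: dense-grid evaluation of the AP template,
# adaptive 1-d integration for the CLMM marginal likelihood, and
# enumeration-based references for the multiplicity and proportion tests.

# --- dense-grid measurement of an arbitrary waveform ------------------------
# Measures threshold (first dV/dt crossing), amplitude, half-width, rise and
# fall times from a finely sampled trace by brute force.
measure_waveform_dense <- function(value_fn, t_lo, t_hi, dt = 1e-4,
                                   criterion = 15.2) {
  t <- seq(t_lo, t_hi, by = dt)
  v <- value_fn(t)
  d <- c(NA, diff(v) / dt)
  cross <- which(d[-1] >= criterion & d[-length(d)] < criterion)[1] + 1L
  v_thr <- v[cross]
  t_thr <- t[cross]
  ipk <- which.max(v)
  amp <- v[ipk] - v_thr
  half <- v_thr + amp / 2
  above <- which(v >= half)
  hw <- (max(above) - min(above)) * dt
  ret <- which(t > t[ipk] & v <= v_thr)[1]
  list(threshold = v_thr, amplitude = amp, half_width = hw,
       rise_time = t[ipk] - t_thr,
       fall_time = if (is.na(ret)) NA_real_ else t[ret] - t[ipk],
       max_rise = max(d, na.rm = TRUE), max_fall = -min(d, na.rm = TRUE))
}

# --- plain-R CLMM marginal log-likelihood by adaptive integration -----------
clmm_loglik_dense <- function(theta, beta, sigma, data,
                              formula_terms = ~ genotype * sf,
                              link = "logit") {
  data <- droplevels(data)
  X <- stats::model.matrix(formula_terms, data)[, -1, drop = FALSE]
  eta <- drop(X %*% beta[colnames(X)])
  y <- as.integer(data$category)
  th <- c(-Inf, theta, Inf)
  F <- if (link == "logit") stats::plogis else stats::pnorm
  ll <- 0
  for (a in levels(factor(data$animal))) {
    i <- data$animal == a
    # substitute u = sigma z so the integrand is well-conditioned even for
    # tiny random-effect SDs
    f <- Vectorize(function(z) {
      u <- sigma * z
      p <- F(th[y[i] + 1] - eta[i] - u) - F(th[y[i]] - eta[i] - u)
      prod(p) * stats::dnorm(z)
    })
    ll <- ll + log(stats::integrate(f, -12, 12, rel.tol = 1e-12)$value)
  }
  ll
}

# --- exact two-sample binomial test by enumeration --------------------------
# Unconditional brute force over the joint null with the pooled MLE:
# p-value = P(|p1hat - p2hat| >= observed) under Binom(n1, p) x Binom(n2, p).
exact_prop_p <- function(k1, n1, k2, n2) {
  p0 <- (k1 + k2) / (n1 + n2)
  obs <- abs(k1 / n1 - k2 / n2)
  pk1 <- stats::dbinom(0:n1, n1, p0)
  pk2 <- stats::dbinom(0:n2, n2, p0)
  diff <- abs(outer(0:n1 / n1, 0:n2 / n2, `-`))
  sum(outer(pk1, pk2) * (diff >= obs - 1e-12))
}

# BH by direct definition (checked against the package implementation)
bh_reference <- function(p) {
  m <- length(p)
  ord <- order(p, seq_along(p))
  adj <- numeric(m)
  for (i in seq_len(m)) {
    k <- ord[i]
    adj[k] <- min(1, min(p[ord[i:m]] * m / (i:m)))
  }
  adj
}

# run an expression with a local RNG seed, restoring global state
with_seed <- function(seed, expr) {
  old <- if (exists(".Random.seed", .GlobalEnv)) get(".Random.seed", .GlobalEnv) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, .GlobalEnv) else
    rm(".Random.seed", envir = .GlobalEnv))
  set.seed(seed)
  expr
}

# small ephys config used in several tests (2 sweeps keeps it fast)
fast_ephys_cfg <- function(...) {
  ephys_sim_config(current_steps = c(-50, 100, 150, 200),
                   rheobase_pA = 150, ...)
}
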