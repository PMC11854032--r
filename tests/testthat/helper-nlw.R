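# Shared fixtures: admissible parameter generators and small oracles.

# Random admissible NLW parameter vectors spanning light and heavy
# shapes, with c*beta on both sides of 1. The shape product is kept
# above ~0.3: smaller values put an integrable but numerically brutal
# singularity at the support endpoint that adaptive quadrature cannot
# certify at the tolerances these tests demand.
random_nlw_params <- function(n, seed = 1) {
  set.seed(seed)
  lapply(seq_len(n), function(i) {
    nlw_params(alpha = exp(runif(1, -1, 1)),
               beta = runif(1, 0.55, 2.8),
               lambda = runif(1, -0.5, 2),
               theta = runif(1, 0.3, 3),
               c = runif(1, 0.55, 2.8))
  })
}

# Published point estimates used as fixed evaluation anchors,
# canonical order (alpha, lambda, theta, beta, c).
pub_est_failure <- c(0.0636, 0.6008, 1.4638, 1.5414, 2.0284)
pub_est_gauge <- c(5.4361, -1.8154, 3.1189, 4.3767, 0.4850)
pub_est_strength <- c(2.0395, 1.5950, 3.4368, 3.9508, 3.0019)
pub_est_grades <- c(0.2493, -3.8664, 7.1817, 1.7261, 0.6840)

# Central finite-difference gradient, the oracle for the analytic score.
fd_gradient <- function(f, x, h = 1e-6) {
  vapply(seq_along(x), function(i) {
    hi <- h * max(1, abs(x[i]))
    xp <- x; xp[i] <- xp[i] + hi
    xm <- x; xm[i] <- xm[i] - hi
    (f(xp) - f(xm)) / (2 * hi)
  }, numeric(1))
}

# Integrate an NLW density over its support, split at the median so the
# possible endpoint singularity (c*beta < 1) sits in its own panel.
integrate_density <- function(p, rel.tol = 1e-9) {
  dfun <- function(x) dnlw(x, p$alpha, p$beta, p$lambda, p$theta, p$c)
  med <- nlw_median(p)
  integrate(dfun, -p$lambda, med, rel.tol = rel.tol)$value +
    integrate(dfun, med, Inf, rel.tol = rel.tol)$value
}
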