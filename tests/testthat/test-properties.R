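# Quadrature is the authoritative oracle throughout; closed forms and
# series representations are cross-checked against it.

test_that("raw moments match shifted-exponential and Rayleigh closed forms", {
  # beta = c = theta = 1: X + lambda ~ exponential(alpha)
  expect_equal(nlw_moment(nlw_params(2, 1, 1, 1, 1), 1), 1 / 2 - 1,
               tolerance = 1e-8)
  # alpha = 1/2, beta = 2, c = 1, lambda = 0: Rayleigh with scale theta
  th <- 1.7
  expect_equal(nlw_moment(nlw_params(0.5, 2, 0, th, 1), 1),
               th * sqrt(pi / 2), tolerance = 1e-8)
  expect_equal(nlw_moment(nlw_params(1.2, 1.5, 0.3, 2, 0.8), 0), 1,
               tolerance = 1e-10)
})

test_that("series representation agrees with quadrature inside its convergence domain and signals outside", {
  # concentrated well inside |x| < lambda: the binomial expansion converges
  p <- nlw_params(alpha = 1, beta = 4, lambda = 10, theta = 10, c = 5)
  expect_equal(nlw_moment(p, 1, "series"), nlw_moment(p, 1),
               tolerance = 1e-4)
  expect_equal(nlw_pwm(p, 1, 2, method = "series"), nlw_pwm(p, 1, 2),
               tolerance = 1e-3)
  # a spread-out distribution: the partial sums never settle
  psp <- nlw_params(1.65, 1.98, 0.055, 0.59, 2.5)
  expect_error(nlw_moment(psp, 1, "series"), "Cauchy")
  expect_error(nlw_moment(nlw_params(1, 1, -0.5, 1, 1), 1, "series"),
               "lambda > 0")
})

test_that("moments shift correctly under a location change", {
  p0 <- nlw_params(1.4, 1.2, 0.117, 1.27, 1.45)
  delta <- 0.8
  p1 <- nlw_params(1.4, 1.2, 0.117 + delta, 1.27, 1.45)   # X1 = X0 - delta
  m1 <- nlw_moment(p0, 1); m2 <- nlw_moment(p0, 2)
  expect_equal(nlw_moment(p1, 1), m1 - delta, tolerance = 1e-8)
  expect_equal(nlw_moment(p1, 2), m2 - 2 * delta * m1 + delta^2,
               tolerance = 1e-7)
})

test_that("mean and variance agree with a Monte Carlo oracle and variance is shift-invariant", {
  p <- nlw_params(1.9, 1.2, 0.07, 2.5, 1.9)
  mv <- nlw_mean_variance(p)
  x <- rnlw(2e5, p$alpha, p$beta, p$lambda, p$theta, p$c, seed = 31)
  se_mean <- sd(x) / sqrt(length(x))
  expect_lt(abs(mv[["mean"]] - mean(x)), 3 * se_mean)
  se_var <- sd((x - mean(x))^2) / sqrt(length(x))
  expect_lt(abs(mv[["variance"]] - var(x)), 3 * se_var)
  p_shift <- nlw_params(1.9, 1.2, 5, 2.5, 1.9)
  expect_equal(nlw_mean_variance(p_shift)[["variance"]], mv[["variance"]],
               tolerance = 1e-6)
  expect_equal(nlw_mean_variance(nlw_params(3, 1, 0, 1, 1))[["variance"]],
               1 / 9, tolerance = 1e-7)
})

test_that("generating functions normalize, differentiate to the mean, and respect existence", {
  p <- nlw_params(1.65, 1.98, 0.055, 0.59, 2.5)
  expect_equal(nlw_mgf(p, 0), 1, tolerance = 1e-9)
  expect_equal(nlw_cf(p, 0), 1 + 0i, tolerance = 1e-9)
  h <- 1e-5
  expect_equal((nlw_mgf(p, h) - nlw_mgf(p, -h)) / (2 * h),
               nlw_moment(p, 1), tolerance = 1e-4)
  # shifted-exponential closed form, boundary tail case c*beta = 1
  pe <- nlw_params(2, 1, 0.5, 1, 1)
  expect_equal(nlw_mgf(pe, 0.7), exp(-0.7 * 0.5) * 2 / (2 - 0.7),
               tolerance = 1e-8)
  expect_error(nlw_mgf(pe, 2.5), "diverges")           # t >= alpha/theta
  expect_error(nlw_mgf(nlw_params(1, 0.5, 0, 1, 1), 0.1), "diverges")
  expect_silent(nlw_mgf(nlw_params(1, 0.5, 0, 1, 1), -0.3))
})

test_that("probability-weighted moments reduce to raw moments and to 1/(s+1)", {
  p <- nlw_params(0.9, 1.6, 0.4, 1.2, 1.1)
  expect_equal(nlw_pwm(p, 2, 0), nlw_moment(p, 2), tolerance = 1e-8)
  for (s in 0:3)
    expect_equal(nlw_pwm(p, 0, s), 1 / (s + 1), tolerance = 1e-8)
})

test_that("order-statistic densities normalize and hit the boundary cases", {
  p <- nlw_params(1.4, 1.2, 0.117, 1.27, 1.45)
  xs <- seq(-0.1, 4, length.out = 50)
  expect_equal(dorder_nlw(xs, p, 1, 1),
               dnlw(xs, p$alpha, p$beta, p$lambda, p$theta, p$c))
  F <- pnlw(xs, p$alpha, p$beta, p$lambda, p$theta, p$c)
  f <- dnlw(xs, p$alpha, p$beta, p$lambda, p$theta, p$c)
  expect_equal(dorder_nlw(xs, p, 5, 5), 5 * F^4 * f, tolerance = 1e-12)
  for (n in 1:6) for (r in seq_len(n)) {
    tot <- integrate(function(x) dorder_nlw(x, p, r, n), -p$lambda, Inf,
                     rel.tol = 1e-8)$value
    expect_equal(tot, 1, tolerance = 1e-6)
  }
  expect_error(dorder_nlw(1, p, 0, 5), "1 <= r <= n")
  expect_error(dorder_nlw(1, p, 6, 5), "1 <= r <= n")
})

test_that("Renyi entropy closed form matches quadrature and limits to Shannon", {
  p <- nlw_params(1.65, 1.98, 0.055, 0.59, 2.5)
  expect_equal(nlw_renyi(p, 2), nlw_renyi(p, 2, "quadrature"),
               tolerance = 1e-6)
  expect_equal(nlw_renyi(p, 0.5), nlw_renyi(p, 0.5, "quadrature"),
               tolerance = 1e-6)
  # location invariance
  p_shift <- nlw_params(1.65, 1.98, 3, 0.59, 2.5)
  expect_equal(nlw_renyi(p_shift, 2), nlw_renyi(p, 2), tolerance = 1e-12)
  # u -> 1 limit
  expect_equal(nlw_renyi(p, 1.001), nlw_shannon(p), tolerance = 1e-2)
  expect_error(nlw_renyi(p, 1), "u")
  # heavy endpoint singularity (c*beta = 1/4): f^2 is not integrable
  expect_error(nlw_renyi(nlw_params(1, 0.25, 0, 1, 1), 2), "diverges")
})

test_that("Shannon entropy matches the exponential closed form and a sampling oracle", {
  expect_equal(nlw_shannon(nlw_params(1.3, 1, 0, 1, 1)), 1 - log(1.3),
               tolerance = 1e-8)
  p <- nlw_params(1.9, 1.2, 0.07, 2.5, 1.9)
  expect_equal(nlw_shannon(p), nlw_shannon(p, "closed"), tolerance = 1e-8)
  x <- rnlw(2e5, p$alpha, p$beta, p$lambda, p$theta, p$c, seed = 17)
  nlp <- -dnlw(x, p$alpha, p$beta, p$lambda, p$theta, p$c, log = TRUE)
  expect_lt(abs(nlw_shannon(p) - mean(nlp)), 3 * sd(nlp) / sqrt(length(x)))
  p_shift <- nlw_params(1.9, 1.2, 4, 2.5, 1.9)
  expect_equal(nlw_shannon(p_shift), nlw_shannon(p), tolerance = 1e-8)
})

test_that("quantile shape measures recompute from the quantile function and shift-invariance holds", {
  p <- nlw_params(1.9, 1.2, 0.07, 2.5, 1.9)
  q <- function(u) qnlw(u, p$alpha, p$beta, p$lambda, p$theta, p$c)
  expect_equal(nlw_quantile_skewness(p),
               (q(0.75) - 2 * q(0.5) + q(0.25)) / (q(0.75) - q(0.5)))
  expect_equal(nlw_quantile_kurtosis(p),
               (q(0.875) - q(0.625) - q(0.375) + q(0.125)) /
                 (q(0.75) - q(0.5)))
  expect_equal(nlw_quantile_skewness(p, standard = TRUE),
               (q(0.75) - 2 * q(0.5) + q(0.25)) / (q(0.75) - q(0.25)))
  expect_equal(nlw_quantile_kurtosis(p, standard = TRUE),
               (q(0.875) - q(0.625) + q(0.375) - q(0.125)) /
                 (q(0.75) - q(0.25)))
  p_shift <- nlw_params(1.9, 1.2, 2.07, 2.5, 1.9)
  expect_equal(nlw_quantile_skewness(p_shift), nlw_quantile_skewness(p),
               tolerance = 1e-10)
  expect_equal(nlw_quantile_kurtosis(p_shift, standard = TRUE),
               nlw_quantile_kurtosis(p, standard = TRUE),
               tolerance = 1e-10)
})

test_that("quantile skewness vanishes at a numerically symmetric shape", {
  # the shape product at which the Weibull quartile spacing is symmetric,
  # located independently from base quantile arithmetic
  g <- function(k) {
    q <- function(p) (-log(1 - p))^(1 / k)
    q(0.75) - 2 * q(0.5) + q(0.25)
  }
  k0 <- uniroot(g, c(2, 5), tol = 1e-12)$root
  p <- nlw_params(alpha = 1, beta = k0 / 1.3, lambda = 0.4, theta = 1,
                  c = 1.3)
  expect_equal(nlw_quantile_skewness(p), 0, tolerance = 1e-6)
  expect_equal(nlw_quantile_skewness(p, standard = TRUE), 0,
               tolerance = 1e-6)
})
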