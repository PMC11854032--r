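#' The New Lomax-Weibull (NLW) Distribution
#'
#' Density, distribution function, survival function, hazard rate, quantile
#' function and random generation for the new Lomax-Weibull distribution
#' with Weibull baseline rate `alpha` and shape `beta`, location `lambda`,
#' scale `theta` and shape `c`.
#'
#' The distribution function is
#' \deqn{F(x) = 1 - \exp\{-\alpha ((x+\lambda)/\theta)^{c\beta}\},
#'       \quad x \ge -\lambda,}
#' obtained by feeding the exponentiated reciprocal hazard of a Lomax
#' distribution, \eqn{m^c(x) = ((x+\lambda)/\theta)^c}, through a Weibull
#' baseline. Writing \eqn{k = c\beta} and \eqn{s = \alpha/\theta^{k}},
#' \eqn{F(x) = 1 - \exp\{-s (x+\lambda)^{k}\}}: the family is a
#' three-parameter location-power-rate Weibull in disguise, and only
#' \eqn{(\lambda, k, s)} are identifiable.
#'
#' The hazard rate \eqn{h(x) = (\alpha\beta c/\theta)
#' ((x+\lambda)/\theta)^{c\beta-1}} is increasing for \eqn{c\beta > 1},
#' constant for \eqn{c\beta = 1} and decreasing for \eqn{c\beta < 1}.
#' At \eqn{x = -\lambda} with \eqn{c\beta < 1} the density diverges;
#' `dnlw` returns `Inf` there.
#'
#' `snlw` evaluates the survival function directly from the exponential
#' form (not as `1 - pnlw`) so the extreme upper tail keeps full relative
#' precision; `pnlw` uses `expm1` for the same reason in the lower tail.
#'
#' @param x,q numeric vector of evaluation points (all finite).
#' @param p vector of probabilities in `[0, 1)`.
#' @param n number of draws.
#' @param alpha,beta positive Weibull baseline rate and shape.
#' @param lambda real location shift; support is `[-lambda, Inf)`.
#' @param theta positive scale.
#' @param c positive shape.
#' @param log,log.p logical; if `TRUE`, probabilities/densities are
#'   returned on the log scale.
#' @param lower.tail logical; if `TRUE` (default), probabilities are
#'   \eqn{P(X \le x)}.
#' @param seed optional integer; if supplied, the draws are reproducible
#'   and the caller's random number generator state is left untouched.
#' @return `dnlw` the density, `pnlw` the distribution function, `snlw`
#'   the survival function, `hnlw` the hazard rate, `qnlw` the quantile
#'   function, `rnlw` a vector of `n` draws.
#' @examples
#' ## Rayleigh special case: alpha = 1/2, beta = 2, c = 1
#' pnlw(1, alpha = 0.5, beta = 2, theta = 1)   # 1 - exp(-0.5)
#' qnlw(0.5, alpha = 1, beta = 1, c = 1)       # exponential median log(2)
#' x <- rnlw(500, alpha = 1.9, beta = 1.2, lambda = 0.07, theta = 2.5,
#'           c = 1.9, seed = 1)
#' @name nlw
NULL

.nlw_check_par <- function(alpha, beta, lambda, theta, c) {
  if (!all(is.finite(base::c(alpha, beta, lambda, theta, c))))
    stop("NLW parameters must be finite", call. = FALSE)
  if (alpha <= 0 || beta <= 0 || theta <= 0 || c <= 0)
    stop("'alpha', 'beta', 'theta' and 'c' must be > 0", call. = FALSE)
  invisible(TRUE)
}

.nlw_check_x <- function(x) {
  if (!is.numeric(x) || anyNA(x) || !all(is.finite(x)))
    stop("evaluation points must be finite numbers", call. = FALSE)
  invisible(TRUE)
}

#' @rdname nlw
#' @export
dnlw <- function(x, alpha = 1, beta = 1, lambda = 0, theta = 1, c = 1,
                 log = FALSE) {
  .nlw_check_par(alpha, beta, lambda, theta, c)
  .nlw_check_x(x)
  k <- c * beta
  y <- (x + lambda) / theta
  ld <- rep(-Inf, length(x))
  pos <- y > 0
  ld[pos] <- log(alpha * beta * c / theta) + (k - 1) * log(y[pos]) -
    alpha * y[pos]^k
  at0 <- y == 0
  if (any(at0))
    ld[at0] <- if (k < 1) Inf else if (k == 1) log(alpha * beta * c / theta) else -Inf
  if (log) ld else exp(ld)
}

#' @rdname nlw
#' @export
pnlw <- function(q, alpha = 1, beta = 1, lambda = 0, theta = 1, c = 1,
                 lower.tail = TRUE, log.p = FALSE) {
  .nlw_check_par(alpha, beta, lambda, theta, c)
  .nlw_check_x(q)
  k <- c * beta
  y <- pmax((q + lambda) / theta, 0)
  lsf <- -alpha * y^k                       # log survival, exact
  if (lower.tail) {
    if (log.p) log(-expm1(lsf)) else -expm1(lsf)
  } else {
    if (log.p) lsf else exp(lsf)
  }
}

#' @rdname nlw
#' @export
snlw <- function(q, alpha = 1, beta = 1, lambda = 0, theta = 1, c = 1) {
  pnlw(q, alpha, beta, lambda, theta, c, lower.tail = FALSE)
}

#' @rdname nlw
#' @export
hnlw <- function(x, alpha = 1, beta = 1, lambda = 0, theta = 1, c = 1) {
  .nlw_check_par(alpha, beta, lambda, theta, c)
  .nlw_check_x(x)
  if (any(x <= -lambda))
    stop("hazard is defined for x > -lambda only", call. = FALSE)
  k <- c * beta
  (alpha * beta * c / theta) * ((x + lambda) / theta)^(k - 1)
}

#' @rdname nlw
#' @export
qnlw <- function(p, alpha = 1, beta = 1, lambda = 0, theta = 1, c = 1) {
  .nlw_check_par(alpha, beta, lambda, theta, c)
  if (!is.numeric(p) || anyNA(p) || any(p < 0) || any(p >= 1))
    stop("probabilities must lie in [0, 1)", call. = FALSE)
  k <- c * beta
  theta * (-log1p(-p) / alpha)^(1 / k) - lambda
}

#' @rdname nlw
#' @export
rnlw <- function(n, alpha = 1, beta = 1, lambda = 0, theta = 1, c = 1,
                 seed = NULL) {
  .nlw_check_par(alpha, beta, lambda, theta, c)
  if (!is.numeric(n) || length(n) != 1L || n < 1)
    stop("'n' must be a positive count", call. = FALSE)
  if (!is.null(seed)) {
    old <- if (exists(".Random.seed", envir = globalenv()))
      get(".Random.seed", envir = globalenv()) else NULL
    on.exit(if (!is.null(old)) assign(".Random.seed", old, envir = globalenv()))
    set.seed(seed)
  }
  qnlw(runif(n), alpha, beta, lambda, theta, c)
}

#' Median of the NLW distribution
#'
#' Closed form `theta * (log(2)/alpha)^(1/(c*beta)) - lambda`, the
#' quantile function evaluated at one half.
#'
#' @param p an `"nlw_params"` object (or numeric `(alpha, lambda, theta,
#'   beta, c)`).
#' @return The median, a single number.
#' @export
nlw_median <- function(p) {
  p <- as_nlw_params(p)
  p$theta * (log(2) / p$alpha)^(1 / (p$c * p$beta)) - p$lambda
}
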