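#' Parameter vector of the new Lomax-Weibull distribution
#'
#' Constructs and validates the five-parameter vector of the NLW
#' distribution. `alpha` and `beta` are the rate and shape of the Weibull
#' baseline, `lambda` is a real location shift, `theta` a positive scale and
#' `c` a positive shape introduced by the exponentiated reciprocal-hazard
#' transform. The support of the distribution is `[-lambda, Inf)`.
#'
#' The model is over-parameterized: the distribution depends on the five
#' raw parameters only through the identifiable triple
#' `(lambda, k = c*beta, s = alpha/theta^(c*beta))`. Use
#' [nlw_functionals()] to extract it.
#'
#' @param alpha positive Weibull baseline rate.
#' @param beta positive Weibull baseline shape.
#' @param lambda real location shift; the support lower endpoint is
#'   `-lambda`.
#' @param theta positive scale.
#' @param c positive shape.
#' @return An object of class `"nlw_params"`: a named list with the five
#'   parameters.
#' @examples
#' p <- nlw_params(alpha = 1.65, beta = 1.98, lambda = 0.055,
#'                 theta = 0.59, c = 2.5)
#' nlw_functionals(p)
#' @export
nlw_params <- function(alpha, beta, lambda = 0, theta = 1, c = 1) {
  vals <- list(alpha = alpha, beta = beta, lambda = lambda,
               theta = theta, c = c)
  for (nm in names(vals)) {
    v <- vals[[nm]]
    if (!is.numeric(v) || length(v) != 1L || !is.finite(v))
      stop("'", nm, "' must be a single finite number", call. = FALSE)
  }
  if (alpha <= 0) stop("'alpha' must be > 0", call. = FALSE)
  if (beta <= 0) stop("'beta' must be > 0", call. = FALSE)
  if (theta <= 0) stop("'theta' must be > 0", call. = FALSE)
  if (c <= 0) stop("'c' must be > 0", call. = FALSE)
  structure(vals, class = "nlw_params")
}

#' Coerce to an NLW parameter object
#'
#' Numeric vectors of length five are interpreted in the canonical order
#' `(alpha, lambda, theta, beta, c)`, the order in which the parameters
#' appear in published estimate tables for this model.
#'
#' @param x an `"nlw_params"` object or numeric vector of length 5 in the
#'   order `(alpha, lambda, theta, beta, c)`.
#' @return An `"nlw_params"` object.
#' @export
as_nlw_params <- function(x) {
  if (inherits(x, "nlw_params")) return(x)
  if (is.numeric(x) && length(x) == 5L)
    return(nlw_params(alpha = x[[1L]], lambda = x[[2L]], theta = x[[3L]],
                      beta = x[[4L]], c = x[[5L]]))
  stop("cannot coerce to 'nlw_params': supply an nlw_params object or a ",
       "numeric vector (alpha, lambda, theta, beta, c)", call. = FALSE)
}

#' @rdname as_nlw_params
#' @param p an `"nlw_params"` object.
#' @return `nlw_par_vector()` returns the named numeric vector
#'   `c(alpha, lambda, theta, beta, c)`.
#' @export
nlw_par_vector <- function(p) {
  p <- as_nlw_params(p)
  base::c(alpha = p$alpha, lambda = p$lambda, theta = p$theta,
          beta = p$beta, c = p$c)
}

#' Identifiable functionals of the NLW parameterization
#'
#' Only `lambda`, `k = c*beta` and `s = alpha/theta^(c*beta)` enter the
#' CDF: any two parameter vectors sharing this triple define the same
#' distribution. Estimator comparisons should be read on this scale.
#'
#' @param p an `"nlw_params"` object (or coercible).
#' @return Named numeric vector `c(lambda, k, s)`.
#' @export
nlw_functionals <- function(p) {
  p <- as_nlw_params(p)
  k <- p$c * p$beta
  base::c(lambda = p$lambda, k = k, s = p$alpha / p$theta^k)
}

#' @export
print.nlw_params <- function(x, digits = 4, ...) {
  cat("NLW parameters (support [", format(-x$lambda, digits = digits),
      ", Inf))\n", sep = "")
  print(round(nlw_par_vector(x), digits))
  fn <- nlw_functionals(x)
  cat("identifiable functionals: lambda =", format(fn[["lambda"]], digits = digits),
      " k = c*beta =", format(fn[["k"]], digits = digits),
      " s = alpha/theta^k =", format(fn[["s"]], digits = digits), "\n")
  invisible(x)
}
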