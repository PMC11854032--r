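# Monte Carlo harness comparing the five estimators on data simulated
# from the NLW by inverse-transform sampling.

# The four published truth vectors, canonical order (alpha, lambda,
# theta, beta, c).
.nlw_sim_sets <- list(
  I   = base::c(alpha = 1.65, lambda = 0.055, theta = 0.59,  beta = 1.98, c = 2.5),
  II  = base::c(alpha = 1.9,  lambda = 0.07,  theta = 2.5,   beta = 1.2,  c = 1.9),
  III = base::c(alpha = 1.4,  lambda = 0.117, theta = 1.27,  beta = 1.2,  c = 1.45),
  IV  = base::c(alpha = 26.4, lambda = 11.7,  theta = 12.77, beta = 15.2, c = 33.45))

#' Define a Monte Carlo estimator-comparison scenario
#'
#' A scenario is a truth vector (one of the four standard sets I-IV or an
#' explicit [nlw_params()] value), a grid of sample sizes, a replicate
#' count, the estimation methods to compare and a seed. The standard
#' design uses sample sizes 20, 50, 100, 200, 300 and 500 with 1000
#' repetitions; smaller `reps` keep desk-scale runtimes.
#'
#' @param set one of `"I"`, `"II"`, `"III"`, `"IV"`, or `NULL` when
#'   `truth` is given.
#' @param truth an [nlw_params()] object (ignored when `set` is given).
#' @param n integer vector of sample sizes (each at least 5).
#' @param reps Monte Carlo replicates per sample size.
#' @param methods subset of `c("mle", "pe", "lse", "wls", "cvm")`.
#' @param seed integer seed controlling the whole scenario.
#' @return An object of class `"nlw_scenario"`.
#' @examples
#' sc <- nlw_scenario("I", n = base::c(20, 50), reps = 5, seed = 7)
#' @export
nlw_scenario <- function(set = NULL, truth = NULL,
                         n = base::c(20L, 50L, 100L, 200L, 300L, 500L),
                         reps = 1000L,
                         methods = base::c("mle", "pe", "lse", "wls", "cvm"),
                         seed = 1L) {
  if (!is.null(set)) {
    if (!is.character(set) || length(set) != 1L ||
        !set %in% names(.nlw_sim_sets))
      stop("unknown parameter set '", paste(set, collapse = ","),
           "'; available: ", paste(names(.nlw_sim_sets), collapse = ", "),
           call. = FALSE)
    truth <- as_nlw_params(unname(.nlw_sim_sets[[set]]))
  } else {
    if (is.null(truth)) stop("supply 'set' or 'truth'", call. = FALSE)
    truth <- as_nlw_params(truth)
    set <- "custom"
  }
  methods <- match.arg(methods, several.ok = TRUE)
  stopifnot(is.numeric(n), all(n >= 5), is.numeric(reps), reps >= 1)
  structure(list(set = set, truth = truth, n = as.integer(sort(n)),
                 reps = as.integer(reps), methods = methods,
                 seed = as.integer(seed)),
            class = "nlw_scenario")
}

#' @export
print.nlw_scenario <- function(x, ...) {
  cat("NLW simulation scenario, set", x$set, "\n")
  print(nlw_par_vector(x$truth))
  cat("n:", paste(x$n, collapse = ", "), " reps:", x$reps,
      " methods:", paste(x$methods, collapse = ", "),
      " seed:", x$seed, "\n")
  invisible(x)
}

#' Bias and mean squared error of a set of estimates
#'
#' Averages over Monte Carlo replicates:
#' `bias = mean(estimates) - truth` and
#' `mse = mean((estimates - truth)^2)`.
#'
#' @param estimates numeric vector of replicate estimates (non-empty).
#' @param truth the true value.
#' @return Named numeric vector `c(bias, mse)`.
#' @export
bias_mse <- function(estimates, truth) {
  stopifnot(is.numeric(estimates), length(estimates) >= 1L,
            is.numeric(truth), length(truth) == 1L)
  base::c(bias = mean(estimates) - truth,
          mse = mean((estimates - truth)^2))
}

#' Run a Monte Carlo estimator-comparison scenario
#'
#' For each replicate at each sample size, a sample is drawn from the
#' truth by inverse-transform sampling and fitted with every requested
#' method using the same data-driven initialization as [nlw_fit()]
#' (never the truth). Mean estimate, bias, mean squared error and median
#' squared error are aggregated per (n, method, parameter), both for the
#' five raw parameters and for the identifiable functionals
#' `lambda`, `k = c*beta` and `s = alpha/theta^k` on which the model is
#' actually identified. Replicate fit failures are counted and excluded
#' from aggregates, never fatal. The run is deterministic given the
#' scenario seed.
#'
#' @param scenario an [nlw_scenario()] object.
#' @param n_starts multistart count per fit (kept small by default: the
#'   harness performs thousands of fits).
#' @param maxit optimizer iteration cap per fit.
#' @param verbose logical; progress messages.
#' @return An object of class `"nlw_sim_study"`: a list with the
#'   scenario, a long `summary` data frame (columns `set`, `n`,
#'   `method`, `parameter`, `truth`, `est`, `bias`, `mse`, `medse`,
#'   `reps_completed`, `failure_count`) and an `estimates` data frame of
#'   raw replicate estimates.
#' @examples
#' sc <- nlw_scenario("I", n = 30, reps = 3, methods = "mle", seed = 7)
#' run_scenario(sc)$summary
#' @export
run_scenario <- function(scenario, n_starts = 2L, maxit = 600L,
                         verbose = FALSE) {
  stopifnot(inherits(scenario, "nlw_scenario"))
  tr <- scenario$truth
  truth_all <- base::c(nlw_par_vector(tr), nlw_functionals(tr)[base::c("k", "s")])
  set.seed(scenario$seed)
  est_rows <- list()
  for (n in scenario$n) {
    if (verbose) message("n = ", n)
    for (rep in seq_len(scenario$reps)) {
      x <- rnlw(n, tr$alpha, tr$beta, tr$lambda, tr$theta, tr$c)
      for (m in scenario$methods) {
        fit <- tryCatch(
          nlw_fit(x, method = m, n_starts = n_starts, maxit = maxit,
                  se = FALSE),
          error = function(e) NULL, warning = function(w) NULL)
        ok <- !is.null(fit) && !is.null(fit$params) &&
          is.finite(fit$objective)
        est <- if (ok)
          base::c(nlw_par_vector(fit$params),
                  fit$functionals[base::c("k", "s")])
        else rep(NA_real_, 7L)
        est_rows[[length(est_rows) + 1L]] <- data.frame(
          set = scenario$set, n = n, method = m, rep = rep,
          parameter = names(truth_all), estimate = unname(est),
          failed = !ok)
      }
    }
  }
  estimates <- do.call(rbind, est_rows)
  key <- interaction(estimates$n, estimates$method, estimates$parameter,
                     drop = TRUE)
  summ <- do.call(rbind, lapply(split(estimates, key), function(d) {
    p <- d$parameter[1L]
    tv <- truth_all[[p]]
    good <- d$estimate[!d$failed & is.finite(d$estimate)]
    fc <- sum(d$failed)
    if (length(good)) {
      bm <- bias_mse(good, tv)
      data.frame(set = d$set[1L], n = d$n[1L], method = d$method[1L],
                 parameter = p, truth = tv, est = mean(good),
                 bias = bm[["bias"]], mse = bm[["mse"]],
                 medse = median((good - tv)^2),
                 reps_completed = length(good), failure_count = fc)
    } else {
      data.frame(set = d$set[1L], n = d$n[1L], method = d$method[1L],
                 parameter = p, truth = tv, est = NA_real_,
                 bias = NA_real_, mse = NA_real_, medse = NA_real_,
                 reps_completed = 0L, failure_count = fc)
    }
  }))
  ord <- order(summ$n, summ$method,
               match(summ$parameter, names(truth_all)))
  summ <- summ[ord, , drop = FALSE]
  rownames(summ) <- NULL
  structure(list(scenario = scenario, summary = summ,
                 estimates = estimates),
            class = "nlw_sim_study")
}

#' Long-format summary table of a simulation study
#'
#' @param result an `"nlw_sim_study"` object from [run_scenario()].
#' @return The long summary `data.frame` (one row per
#'   set/n/method/parameter cell).
#' @export
summary_table <- function(result) {
  stopifnot(inherits(result, "nlw_sim_study"))
  result$summary
}

#' @rdname summary_table
#' @param path output CSV path.
#' @return `write_sim_csv` returns `path` invisibly.
#' @export
write_sim_csv <- function(result, path) {
  utils::write.csv(summary_table(result), path, row.names = FALSE)
  invisible(path)
}

#' @export
print.nlw_sim_study <- function(x, ...) {
  s <- x$scenario
  cat("NLW simulation study, set", s$set, "-", s$reps, "reps,",
      length(s$n), "sample size(s),", length(s$methods), "method(s)\n")
  cat("failures:", sum(x$summary$failure_count) / 7L, "fit(s)\n")
  invisible(x)
}
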