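# Hurwitz zeta: sum_{k=0}^inf (k + q)^-s for s > 1. Direct summation of
# the first K terms plus an Euler-Maclaurin tail correction
#   integral + half-term + derivative term,
# accurate to well below 1e-10 for K = 1e4.
hurwitz_zeta <- function(s, q) {
  stopifnot(s > 1, q > 0)
  K <- 1e4
  k <- seq(0, K - 1)
  head_sum <- sum((k + q)^(-s))
  a <- K + q
  head_sum + a^(1 - s) / (s - 1) + 0.5 * a^(-s) + s * a^(-s - 1) / 12
}

new_tail_fit <- function(model, params, loglik_vec, data, xmin, flags = character(0)) {
  structure(list(model = model, params = params,
                 loglik = sum(loglik_vec), loglik_vec = loglik_vec,
                 data = data, xmin = xmin, n_tail = length(data),
                 flags = flags),
            class = "tail_fit")
}

#' @export
print.tail_fit <- function(x, ...) {
  par_str <- paste(sprintf("%s = %.4g", names(x$params), x$params),
                   collapse = ", ")
  cat(sprintf("Discrete %s fit: %s (xmin = %d, n_tail = %d)\n",
              x$model, par_str, x$xmin, x$n_tail))
  cat(sprintf("  log-likelihood: %.4f\n", x$loglik))
  if (length(x$flags)) cat("  flags:", paste(x$flags, collapse = "; "), "\n")
  invisible(x)
}

#' @export
coef.tail_fit <- function(object, ...) object$params

#' @export
logLik.tail_fit <- function(object, ...) {
  structure(object$loglik, df = length(object$params),
            nobs = object$n_tail, class = "logLik")
}

#' @export
summary.tail_fit <- function(object, ...) {
  print(object)
  invisible(object)
}

# log pmf of the zeta (discrete power-law) distribution on k >= xmin
dpowerlaw_log <- function(k, alpha, xmin) {
  -alpha * log(k) - log(hurwitz_zeta(alpha, xmin))
}

logsumexp <- function(x) {
  m <- max(x)
  if (!is.finite(m)) return(m)
  m + log(sum(exp(x - m)))
}

# discretized density pmfs: continuous log-density evaluated at the
# integers and renormalized over k >= xmin, all in log space. Summation
# runs to a truncation bound, with an upper-tail correction from the
# continuous CDF for the mass beyond it.
discrete_density_logpmf <- function(log_dens, log_upper_tail, xmin, kmax_obs) {
  bound <- max(10 * kmax_obs, 1e4)
  k <- seq.int(xmin, bound)
  log_norm <- logsumexp(c(log_dens(k), log_upper_tail(bound + 0.5)))
  function(kk) log_dens(kk) - log_norm
}

check_tail_input <- function(sizes, xmin) {
  if (!length(sizes) || any(sizes < 1) || any(sizes != round(sizes)))
    stop("sizes must be positive integers")
  tail_obs <- sizes[sizes >= xmin]
  if (length(tail_obs) < 2L) stop("fewer than 2 observations in the tail")
  if (length(unique(tail_obs)) < 2L)
    stop("degenerate tail: all observations equal")
  sort(tail_obs)
}

# KS distance between the empirical tail CDF and a fitted discrete CDF
ks_distance <- function(tail_obs, logpmf_fun) {
  ks <- seq.int(min(tail_obs), max(tail_obs))
  fitted_cdf <- cumsum(exp(logpmf_fun(ks)))
  emp_cdf <- stats::ecdf(tail_obs)(ks)
  max(abs(emp_cdf - fitted_cdf))
}

#' Fit a discrete power law to family sizes
#'
#' Maximum-likelihood fit of the zeta distribution
#' p(k) = k^-alpha / zeta(alpha, xmin) over the tail k >= xmin, with alpha
#' found by bounded one-dimensional optimization on (1, 20]. With
#' `xmin = "auto"` every candidate xmin (the unique observed values, each
#' leaving a tail of at least 10 observations) is tried and the one
#' minimizing the Kolmogorov-Smirnov distance between the empirical and
#' fitted tail CDFs is kept, after which alpha is refit.
#'
#' @param sizes Positive integer vector of family sizes.
#' @param xmin Integer lower bound of the fitted tail, or `"auto"`.
#' @return A `tail_fit` object (model `"powerlaw"`, parameter `alpha`).
#' @export
fit_powerlaw_discrete <- function(sizes, xmin = 1L) {
  if (identical(xmin, "auto")) {
    cand <- sort(unique(sizes))
    cand <- cand[vapply(cand, function(x)
      sum(sizes >= x) >= 10L && length(unique(sizes[sizes >= x])) >= 2L,
      logical(1))]
    if (!length(cand)) cand <- min(sizes)
    ks <- vapply(cand, function(x) {
      f <- fit_powerlaw_discrete(sizes, xmin = x)
      ks_distance(f$data, function(k) dpowerlaw_log(k, f$params[["alpha"]], x))
    }, numeric(1))
    xmin <- cand[which.min(ks)]
  }
  xmin <- as.integer(xmin)
  tail_obs <- check_tail_input(sizes, xmin)
  nll <- function(alpha) -sum(dpowerlaw_log(tail_obs, alpha, xmin))
  opt <- optimize(nll, interval = c(1 + 1e-6, 20), tol = 1e-8)
  alpha <- opt$minimum
  flags <- character(0)
  if (alpha > 20 - 1e-3 || alpha < 1 + 1e-4)
    flags <- "alpha at search bound"
  new_tail_fit("powerlaw", c(alpha = alpha),
               dpowerlaw_log(tail_obs, alpha, xmin), tail_obs, xmin, flags)
}

#' Fit a discrete lognormal to family sizes
#'
#' Lognormal density evaluated at the integers and renormalized over
#' k >= xmin (summation to a truncation bound with a continuous upper-tail
#' correction); (mu, sigma) by bounded numerical MLE.
#'
#' @inheritParams fit_powerlaw_discrete
#' @return A `tail_fit` object (model `"lognormal"`, parameters `mu`,
#'   `sigma`).
#' @export
fit_lognormal_discrete <- function(sizes, xmin = 1L) {
  xmin <- as.integer(xmin)
  tail_obs <- check_tail_input(sizes, xmin)
  make_logpmf <- function(mu, sigma)
    discrete_density_logpmf(
      function(k) dlnorm(k, mu, sigma, log = TRUE),
      function(b) plnorm(b, mu, sigma, lower.tail = FALSE, log.p = TRUE),
      xmin, max(tail_obs))
  nll <- function(par) {
    mu <- par[1]; sigma <- exp(par[2])
    -sum(make_logpmf(mu, sigma)(tail_obs))
  }
  init <- c(mean(log(tail_obs)), log(max(stats::sd(log(tail_obs)), 0.1)))
  opt <- optim(init, nll, method = "L-BFGS-B",
               lower = c(-10, log(1e-3)), upper = c(15, log(10)))
  mu <- opt$par[1]; sigma <- exp(opt$par[2])
  flags <- character(0)
  if (sigma <= 1e-3 * (1 + 1e-6))
    stop("lognormal sigma at search floor: degenerate input")
  new_tail_fit("lognormal", c(mu = mu, sigma = sigma),
               make_logpmf(mu, sigma)(tail_obs), tail_obs, xmin, flags)
}

#' Fit a discrete exponential (geometric-type) law to family sizes
#'
#' p(k) proportional to exp(-lambda k) over integers k >= xmin, i.e. a
#' geometric law with success probability 1 - exp(-lambda); lambda by
#' bounded numerical MLE.
#'
#' @inheritParams fit_powerlaw_discrete
#' @return A `tail_fit` object (model `"exponential"`, parameter
#'   `lambda`).
#' @export
fit_exponential_discrete <- function(sizes, xmin = 1L) {
  xmin <- as.integer(xmin)
  tail_obs <- check_tail_input(sizes, xmin)
  # normalizer: sum_{k>=xmin} e^{-lambda k} = e^{-lambda xmin}/(1 - e^{-lambda})
  logpmf <- function(k, lambda)
    -lambda * k - (-lambda * xmin - log(1 - exp(-lambda)))
  nll <- function(lambda) -sum(logpmf(tail_obs, lambda))
  opt <- optimize(nll, interval = c(1e-8, 50), tol = 1e-10)
  lambda <- opt$minimum
  flags <- if (lambda > 50 - 1e-3) "lambda at search bound" else character(0)
  new_tail_fit("exponential", c(lambda = lambda),
               logpmf(tail_obs, lambda), tail_obs, xmin, flags)
}

#' Vuong's likelihood-ratio test for non-nested discrete models
#'
#' Compares two fits of the same observation vector via the per-observation
#' log-likelihood differences d_i: the statistic sum(d) / (sd(d) * sqrt(n))
#' is standard normal under model equivalence; the p-value is two-sided.
#' A positive statistic favors `fit_a`. When p < `alpha_level` the verdict
#' names the favored model, otherwise `"indistinguishable"`.
#'
#' @param fit_a,fit_b `tail_fit` objects fitted on the identical
#'   observation vector (same xmin, same tail).
#' @param alpha_level Significance threshold for the verdict.
#' @return Object of class `vuong_result`: list with `statistic`,
#'   `p_value`, `favored`, `model_a`, `model_b`, `n`.
#' @export
vuong_test <- function(fit_a, fit_b, alpha_level = 0.05) {
  if (!identical(fit_a$data, fit_b$data) || fit_a$xmin != fit_b$xmin)
    stop("fits must share the identical observation vector and xmin")
  d <- fit_a$loglik_vec - fit_b$loglik_vec
  n <- length(d)
  s <- stats::sd(d)
  if (s == 0 || !is.finite(s)) {
    stat <- 0; p <- 1
  } else {
    stat <- sum(d) / (s * sqrt(n))
    p <- 2 * pnorm(-abs(stat))
  }
  favored <- if (p < alpha_level) {
    if (stat > 0) fit_a$model else fit_b$model
  } else "indistinguishable"
  structure(list(statistic = stat, p_value = p, favored = favored,
                 model_a = fit_a$model, model_b = fit_b$model, n = n),
            class = "vuong_result")
}

#' @export
print.vuong_result <- function(x, ...) {
  cat(sprintf("Vuong test %s vs %s (n = %d): statistic = %.3f, p = %.4g -> %s\n",
              x$model_a, x$model_b, x$n, x$statistic, x$p_value, x$favored))
  invisible(x)
}

#' Bootstrap stability of tail-fit parameters
#'
#' Nonparametric bootstrap: resamples the sizes with replacement,
#' refits the chosen model at the same xmin, and reports percentile
#' intervals (2.5%, 97.5%) per parameter. Degenerate resamples that fail
#' to fit are counted and reported, never silently dropped; more than 50%
#' failures is an error.
#'
#' @param sizes Positive integer family sizes.
#' @param model `"powerlaw"`, `"lognormal"` or `"exponential"`.
#' @param xmin Tail lower bound.
#' @param n_replicates Number of bootstrap replicates (default 1000).
#' @param seed Optional integer seed.
#' @return Object of class `bootstrap_summary`: list with `model`,
#'   `n_replicates`, `n_failed`, `estimates` (replicate x parameter
#'   matrix), `intervals` (parameter x c(low, high)), `point` (full-data
#'   estimates), `seed`.
#' @export
bootstrap_stability <- function(sizes, model = c("powerlaw", "lognormal",
                                                 "exponential"),
                                xmin = 1L, n_replicates = 1000L, seed = NULL) {
  model <- match.arg(model)
  if (n_replicates < 1L) stop("n_replicates must be >= 1")
  if (!is.null(seed)) set.seed(seed)
  fitter <- switch(model,
                   powerlaw = fit_powerlaw_discrete,
                   lognormal = fit_lognormal_discrete,
                   exponential = fit_exponential_discrete)
  point <- fitter(sizes, xmin = xmin)$params
  est <- matrix(NA_real_, n_replicates, length(point),
                dimnames = list(NULL, names(point)))
  n_failed <- 0L
  for (r in seq_len(n_replicates)) {
    resample <- sample(sizes, length(sizes), replace = TRUE)
    fit <- tryCatch(fitter(resample, xmin = xmin), error = function(e) NULL)
    if (is.null(fit)) n_failed <- n_failed + 1L
    else est[r, ] <- fit$params
  }
  if (n_failed > n_replicates / 2)
    stop("more than half of bootstrap replicates failed (", n_failed,
         "/", n_replicates, ")")
  ok <- est[!is.na(est[, 1]), , drop = FALSE]
  intervals <- t(apply(ok, 2, quantile, probs = c(0.025, 0.975), names = FALSE))
  colnames(intervals) <- c("low", "high")
  structure(list(model = model, n_replicates = n_replicates,
                 n_failed = n_failed, estimates = est,
                 intervals = intervals, point = point, seed = seed),
            class = "bootstrap_summary")
}

#' @export
print.bootstrap_summary <- function(x, ...) {
  cat(sprintf("Bootstrap stability (%s, %d replicates, %d failed):\n",
              x$model, x$n_replicates, x$n_failed))
  for (p in rownames(x$intervals))
    cat(sprintf("  %s = %.4g  [%.4g, %.4g]\n", p, x$point[[p]],
                x$intervals[p, "low"], x$intervals[p, "high"]))
  invisible(x)
}

#' Compare heavy-tail models of family sizes
#'
#' Fits power-law, lognormal and exponential models at a common xmin
#' (chosen by the power-law KS criterion when `xmin = "auto"`), runs all
#' pairwise Vuong tests, and returns a verdict table.
#'
#' @param sizes Positive integer family sizes.
#' @param xmin Common tail bound or `"auto"`.
#' @param alpha_level Significance threshold for verdicts.
#' @return Object of class `tail_comparison`: list with `fits` (named
#'   list of `tail_fit`), `tests` (data frame of pairwise Vuong results),
#'   `xmin`, `best` (model with highest log-likelihood).
#' @export
compare_models <- function(sizes, xmin = "auto", alpha_level = 0.05) {
  if (!length(sizes)) stop("sizes must be non-empty")
  pl <- fit_powerlaw_discrete(sizes, xmin = xmin)
  xmin_common <- pl$xmin
  fits <- list(powerlaw = pl,
               lognormal = fit_lognormal_discrete(sizes, xmin = xmin_common),
               exponential = fit_exponential_discrete(sizes, xmin = xmin_common))
  pairs <- utils::combn(names(fits), 2)
  tests <- do.call(rbind, lapply(seq_len(ncol(pairs)), function(i) {
    a <- pairs[1, i]; b <- pairs[2, i]
    v <- vuong_test(fits[[a]], fits[[b]], alpha_level)
    data.frame(model_a = a, model_b = b, statistic = v$statistic,
               p_value = v$p_value, favored = v$favored,
               stringsAsFactors = FALSE)
  }))
  lls <- vapply(fits, `[[`, numeric(1), "loglik")
  structure(list(fits = fits, tests = tests, xmin = xmin_common,
                 best = names(which.max(lls))),
            class = "tail_comparison")
}

#' @export
print.tail_comparison <- function(x, ...) {
  cat("Heavy-tail model comparison (xmin =", x$xmin, ")\n")
  for (f in x$fits) print(f)
  print(x$tests, row.names = FALSE)
  cat("highest log-likelihood:", x$best, "\n")
  invisible(x)
}
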