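test_that("power-law MLE recovers alpha and matches a grid-search oracle", {
  s <- simulate_gcf_sizes(list(law = "powerlaw", alpha = 2.5), 10000,
                          seed = 11)
  fit <- fit_powerlaw_discrete(s)
  expect_gt(fit$params[["alpha"]], 2.4)
  expect_lt(fit$params[["alpha"]], 2.6)
  expect_equal(fit$loglik, sum(fit$loglik_vec), tolerance = 1e-9)
  # dense grid-search oracle on a fixed 500-point sample
  s500 <- simulate_gcf_sizes(list(law = "powerlaw", alpha = 2.2), 500,
                             seed = 12)
  fit500 <- fit_powerlaw_discrete(s500)
  grid <- seq(1.01, 5, by = 1e-3)
  ll <- vapply(grid, function(a)
    sum(-a * log(s500)) - length(s500) * log(gcfkit:::hurwitz_zeta(a, 1)),
    numeric(1))
  expect_lt(abs(fit500$params[["alpha"]] - grid[which.max(ll)]), 2e-3)
  expect_error(fit_powerlaw_discrete(c(1, 1, 1, 1)), "degenerate")
})

test_that("automatic xmin minimizes the tail KS distance", {
  set.seed(13)
  # body contamination below k = 3 + clean power-law tail
  s <- c(rep(1L, 300), rep(2L, 250),
         simulate_gcf_sizes(list(law = "powerlaw", alpha = 2.5), 2000) + 2L)
  fit <- fit_powerlaw_discrete(s, xmin = "auto")
  expect_gte(fit$xmin, 2)
  expect_equal(fit$n_tail, sum(s >= fit$xmin))
})

test_that("discrete lognormal and exponential fits recover parameters", {
  ln <- simulate_gcf_sizes(list(law = "lognormal", mu = 1, sigma = 0.6),
                           10000, seed = 12)
  fl <- fit_lognormal_discrete(ln)
  expect_gt(fl$params[["mu"]], 0.9)
  expect_lt(fl$params[["mu"]], 1.1)
  set.seed(13)
  ge <- 1L + rgeom(10000, 1 - exp(-0.5))
  fe <- fit_exponential_discrete(ge)
  expect_gt(fe$params[["lambda"]], 0.45)
  expect_lt(fe$params[["lambda"]], 0.55)
  expect_error(fit_lognormal_discrete(rep(3L, 50)), "degenerate")
})

test_that("every fitted pmf sums to 1 over its support", {
  s <- simulate_gcf_sizes(list(law = "lognormal", mu = 1, sigma = 0.7), 500,
                          seed = 14)
  pl <- fit_powerlaw_discrete(s)
  a <- pl$params[["alpha"]]
  # partial sum plus an integral bracket of the remaining tail mass
  partial <- sum(exp(gcfkit:::dpowerlaw_log(1:2e5, a, 1)))
  tail_hi <- (2e5)^(1 - a) / (a - 1) / gcfkit:::hurwitz_zeta(a, 1)
  expect_lte(partial, 1 + 1e-9)
  expect_lt(1 - partial, tail_hi + 1e-9)
  # zeta normalizer against the independent Riemann-zeta route
  skip_if_not_installed("pracma")
  expect_equal(gcfkit:::hurwitz_zeta(a, 1), pracma::zeta(a),
               tolerance = 1e-10)
  ln <- fit_lognormal_discrete(s)
  lp <- gcfkit:::discrete_density_logpmf(
    function(k) dlnorm(k, ln$params[["mu"]], ln$params[["sigma"]], log = TRUE),
    function(b) plnorm(b, ln$params[["mu"]], ln$params[["sigma"]],
                       lower.tail = FALSE, log.p = TRUE),
    1, max(s))
  expect_equal(sum(exp(lp(1:1e5))), 1, tolerance = 1e-6)
  ex <- fit_exponential_discrete(s)
  lam <- ex$params[["lambda"]]
  expect_equal(sum(exp(-lam * (1:2000)) * (1 - exp(-lam)) / exp(-lam)), 1,
               tolerance = 1e-6)
})

test_that("the MLE beats perturbed parameters on the same data", {
  s <- simulate_gcf_sizes(list(law = "powerlaw", alpha = 2.3), 2000,
                          seed = 15)
  fit <- fit_powerlaw_discrete(s)
  a <- fit$params[["alpha"]]
  for (da in c(-0.1, 0.1))
    expect_gte(fit$loglik,
               sum(gcfkit:::dpowerlaw_log(fit$data, a + da, fit$xmin)))
  fl <- fit_lognormal_discrete(s)
  perturbed <- function(dmu, dsig) {
    mu <- fl$params[["mu"]] + dmu
    sg <- fl$params[["sigma"]] + dsig
    lp <- gcfkit:::discrete_density_logpmf(
      function(k) dlnorm(k, mu, sg, log = TRUE),
      function(b) plnorm(b, mu, sg, lower.tail = FALSE, log.p = TRUE),
      fl$xmin, max(fl$data))
    sum(lp(fl$data))
  }
  for (d in list(c(0.1, 0), c(-0.1, 0), c(0, 0.1), c(0, -0.1)))
    expect_gte(fl$loglik, perturbed(d[1], d[2]))
})

test_that("Vuong statistic follows the direct formula and its contracts", {
  s <- simulate_gcf_sizes(list(law = "lognormal", mu = 1, sigma = 0.8), 500,
                          seed = 16)
  a <- fit_powerlaw_discrete(s)
  b <- fit_lognormal_discrete(s)
  v <- vuong_test(a, b)
  # spreadsheet-style oracle on the stored per-observation differences
  d <- a$loglik_vec - b$loglik_vec
  expect_equal(v$statistic, mean(d) * sqrt(length(d)) / sd(d),
               tolerance = 1e-12)
  expect_equal(v$p_value, 2 * pnorm(-abs(v$statistic)), tolerance = 1e-12)
  # hand-specified differences
  d5 <- c(0.2, -0.1, 0.3, 0.2, -0.2)
  expect_equal(mean(d5) * sqrt(5) / sd(d5), 0.8251370, tolerance = 1e-6)
  # identical fits: statistic 0, p 1
  v0 <- vuong_test(a, a)
  expect_equal(v0$statistic, 0)
  expect_equal(v0$p_value, 1)
  # antisymmetry
  v_ba <- vuong_test(b, a)
  expect_equal(v_ba$statistic, -v$statistic)
  expect_equal(v_ba$p_value, v$p_value)
  # order invariance of the statistic
  set.seed(17)
  p <- sample(length(s))
  a2 <- fit_powerlaw_discrete(s[p])
  b2 <- fit_lognormal_discrete(s[p])
  expect_equal(vuong_test(a2, b2)$statistic, v$statistic, tolerance = 1e-6)
  # mismatched observation vectors are rejected
  expect_error(vuong_test(a, fit_lognormal_discrete(s[-1])), "identical")
})

test_that("Vuong antisymmetry holds across random fit pairs", {
  for (seed in 101:110) {
    s <- simulate_gcf_sizes(list(law = "lognormal", mu = 0.8, sigma = 0.9),
                            300, seed = seed)
    a <- fit_powerlaw_discrete(s)
    b <- fit_lognormal_discrete(s)
    c <- fit_exponential_discrete(s)
    for (pair in list(list(a, b), list(a, c), list(b, c))) {
      v1 <- vuong_test(pair[[1]], pair[[2]])
      v2 <- vuong_test(pair[[2]], pair[[1]])
      expect_equal(v1$statistic, -v2$statistic, tolerance = 1e-12)
      expect_equal(v1$p_value, v2$p_value, tolerance = 1e-12)
    }
  }
})

test_that("bootstrap stability intervals behave and are deterministic", {
  s <- simulate_gcf_sizes(list(law = "powerlaw", alpha = 2.5), 5000,
                          seed = 18)
  bs <- bootstrap_stability(s, "powerlaw", n_replicates = 200, seed = 19)
  expect_equal(bs$n_failed, 0L)
  expect_lte(bs$intervals["alpha", "low"], 2.5)
  expect_gte(bs$intervals["alpha", "high"], 2.5)
  expect_lte(bs$intervals["alpha", "low"], bs$intervals["alpha", "high"])
  bs2 <- bootstrap_stability(s, "powerlaw", n_replicates = 200, seed = 19)
  expect_identical(bs$estimates, bs2$estimates)
  one <- bootstrap_stability(s[1:200], "powerlaw", n_replicates = 1, seed = 20)
  expect_equal(one$intervals["alpha", "low"], one$intervals["alpha", "high"])
  expect_equal(unname(one$intervals["alpha", "low"]),
               unname(one$estimates[1, "alpha"]))
  # mostly-degenerate data: replicate failures must surface as an error
  expect_error(
    bootstrap_stability(c(1L, 2L), "powerlaw", n_replicates = 11, seed = 21),
    "failed")
})

test_that("model comparison favors the generating law", {
  ln <- simulate_gcf_sizes(list(law = "lognormal", mu = 1, sigma = 0.6),
                           10000, seed = 22)
  cmp <- compare_models(ln, xmin = 1)
  row <- cmp$tests[cmp$tests$model_a == "powerlaw" &
                     cmp$tests$model_b == "lognormal", ]
  expect_equal(row$favored, "lognormal")
  expect_lt(row$p_value, 0.05)
  # power-law data: power law must not be rejected against lognormal
  pw <- simulate_gcf_sizes(list(law = "powerlaw", alpha = 2.5), 10000,
                           seed = 23)
  cmp2 <- compare_models(pw, xmin = 1)
  row2 <- cmp2$tests[cmp2$tests$model_a == "powerlaw" &
                       cmp2$tests$model_b == "lognormal", ]
  expect_true(row2$favored %in% c("powerlaw", "indistinguishable"))
  # minimal input: clean fit or clean error, never silent NaN
  tiny <- c(1L, 2L, 5L)
  cmp3 <- compare_models(tiny, xmin = 1)
  expect_true(all(is.finite(vapply(cmp3$fits, `[[`, numeric(1), "loglik"))))
})
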