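# Analytic 2-D standard normal target used throughout: the sampler, run in
# linear coordinates on a wide box, must reproduce its mean and covariance.
gauss_prior <- function() data.frame(name = c("x", "y"), lower = c(-10, -10),
                                     upper = c(10, 10),
                                     log = c(FALSE, FALSE))
gauss_lp <- function(v) -sum(v^2) / 2

test_that("adaptive Metropolis reproduces an analytic 2-D Gaussian", {
  cfg <- mcmc_config(burn = 1000, adapt = 2000, production = 10000,
                     chains = 2, seed = 31)
  s <- run_mcmc(gauss_lp, gauss_prior(), cfg)
  pooled <- pooled_draws(s)
  for (p in c("x", "y")) {
    ess <- ess_bulk(param_matrix <- sapply(s$draws, function(m) m[, p]))
    mcse <- sd(pooled[, p]) / sqrt(ess)
    expect_lt(abs(mean(pooled[, p])), 3 * mcse)
  }
  cv <- cov(pooled)
  expect_lt(max(abs(cv - diag(2))), 0.1)
  # acceptance rates are sane and all draws satisfy the box prior
  for (ch in seq_along(s$draws)) {
    expect_true(all(s$draws[[ch]] >= -10 & s$draws[[ch]] <= 10))
    expect_gt(s$accept[[ch]]["production"], 0)
    expect_lt(s$accept[[ch]]["production"], 1)
  }
})

test_that("a vanishing proposal scale freezes the chain", {
  cfg <- mcmc_config(burn = 0, adapt = 0, production = 200, chains = 1,
                     seed = 2, init_scale = 1e-12)
  s <- run_mcmc(gauss_lp, gauss_prior(), cfg)
  expect_gt(s$accept[[1]]["production"], 0.99)
  expect_lt(max(apply(s$draws[[1]], 2, sd)), 1e-6)
})

test_that("identical seeds give identical chains", {
  cfg <- mcmc_config(burn = 100, adapt = 100, production = 500, chains = 1,
                     seed = 77)
  s1 <- run_chain(gauss_lp, gauss_prior(), cfg)
  s2 <- run_chain(gauss_lp, gauss_prior(), cfg)
  expect_identical(s1$draws, s2$draws)
  expect_identical(s1$lp, s2$lp)
})

test_that("rhat separates mixed from unmixed chains", {
  set.seed(41)
  good <- cbind(rnorm(2000), rnorm(2000))
  expect_lt(rhat(good) - 1, 0.01)
  bad <- cbind(rnorm(2000, -10), rnorm(2000, 10))
  expect_gt(rhat(bad), 1.1)
  expect_warning(r <- rhat(matrix(1, 100, 2)), "constant")
  expect_true(is.na(r))
  expect_error(rhat(matrix(rnorm(10), ncol = 1)), "at least 2 chains")
})

test_that("effective sample size is calibrated on iid draws", {
  set.seed(42)
  x <- cbind(rnorm(5000), rnorm(5000))
  expect_equal(ess_bulk(x), 10000, tolerance = 0.2)
  expect_gt(ess_tail(x), 0.5 * 10000)
  # strongly autocorrelated chains have far fewer effective draws
  ar <- replicate(2, as.numeric(arima.sim(list(ar = 0.95), 5000)))
  expect_lt(ess_bulk(ar), 1500)
})

test_that("posterior predictive bands are nested with the median inside", {
  # fabricated posterior: a handful of d3/u3 draws around the reference
  draws <- cbind(d3 = c(8e-4, 1e-3, 1.2e-3, 9e-4),
                 u3 = c(8e-4, 1e-3, 1.1e-3, 1.2e-3))
  s <- structure(list(draws = list(draws)), class = "posterior_sample")
  pb <- posterior_predictive(s, times = c(300, 1800), variants = "WT",
                             levels = c(0.5, 0.95), max_draws = 10)
  band <- pb$bands$WT$pERK1_2_wt
  expect_true(all(band$bands[["50%"]]$lower >= band$bands[["95%"]]$lower))
  expect_true(all(band$bands[["50%"]]$upper <= band$bands[["95%"]]$upper))
  expect_true(all(band$median >= band$bands[["95%"]]$lower))
  expect_true(all(band$median <= band$bands[["95%"]]$upper))
  # identical draws collapse every band onto the median
  same <- structure(list(draws = list(draws[c(1, 1, 1), ])),
                    class = "posterior_sample")
  pb2 <- posterior_predictive(same, times = c(300), variants = "KO",
                              levels = c(0.95), max_draws = 10)
  b2 <- pb2$bands$KO$MEK_pRDS
  expect_equal(b2$bands[["95%"]]$lower, b2$median)
  expect_equal(b2$bands[["95%"]]$upper, b2$median)
})

test_that("constraint satisfaction fractions respect mirrored pairs", {
  draws <- cbind(d3 = c(8e-4, 1e-3, 1.2e-3, 9e-4),
                 u3 = c(8e-4, 1e-3, 1.1e-3, 1.2e-3))
  s <- structure(list(draws = list(draws)), class = "posterior_sample")
  props <- property_set(list(
    parse_property("WT.pEGFR at time=300 >= KO.pEGFR at time=300"),
    parse_property("WT.pEGFR at time=300 < KO.pEGFR at time=300"),
    parse_property("WT.pERK1_2_wt at time=300 >= WT.pERK1_2_wt at time=300")))
  fr <- constraint_satisfaction_fraction(s, props, max_draws = 4)
  expect_equal(nrow(fr), 3)
  expect_true(all(fr$fraction >= 0 & fr$fraction <= 1))
  # mirrored statements partition the draws
  expect_equal(fr$fraction[1] + fr$fraction[2], 1)
  # a self-comparison is an exact tie, satisfied by H(0) = 1 for every draw
  expect_equal(fr$fraction[3], 1)
})
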