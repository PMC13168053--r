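test_that("quantitative sum-of-squares handles missing records", {
  expect_equal(f_quant(c(0.5), c(0.1)), 0.16)
  expect_equal(f_quant(c(0.5, NA, 0.2), c(0.5, 9, 0.2)), 0)
  expect_equal(f_quant(rep(NA_real_, 4), rnorm(4)), 0)
  expect_equal(gaussian_nll(rep(NA_real_, 4), rnorm(4), 1), 0)
})

test_that("gaussian_nll matches a per-record normal log-density oracle", {
  expect_equal(gaussian_nll(0.3, 0.3, 1), 0.5 * log(2 * pi))
  set.seed(7)
  for (i in 1:20) {
    n <- sample(3:25, 1)
    y <- runif(n); f <- runif(n); s <- runif(1, 0.05, 3)
    y[sample(n, sample(0:2, 1))] <- NA
    oracle <- -sum(dnorm(y[!is.na(y)], f[!is.na(y)], s, log = TRUE))
    expect_equal(gaussian_nll(y, f, s), oracle, tolerance = 1e-12)
  }
  expect_error(gaussian_nll(0.5, 0.4, 0), "sigma")
})

test_that("logistic link is symmetric, saturating, and 1/2 at zero", {
  expect_equal(logistic_prob(0, 3), 0.5)
  expect_equal(logistic_prob(1e6, 1), 1)
  set.seed(8)
  d <- rnorm(100, 0, 50); s <- runif(100, 0.01, 10)
  expect_equal(logistic_prob(d, s) + logistic_prob(-d, s), rep(1, 100))
  expect_error(logistic_prob(1, -1), "s must be")
})

test_that("qual_nll equals the Bernoulli product oracle and stays stable", {
  expect_equal(qual_nll(0, 1, 1), log(2))
  set.seed(9)
  for (i in 1:20) {
    m <- sample(2:30, 1)
    d <- rnorm(m, 0, 5); s <- runif(m, 0.1, 4); z <- rbinom(m, 1, 0.5)
    # Bernoulli pmf oracle; the complement probability is computed directly
    # from the mirrored logistic so the oracle itself does not cancel
    oracle <- -sum(log(ifelse(z == 1, logistic_prob(d, s),
                              logistic_prob(-d, s))))
    expect_equal(qual_nll(d, s, z), oracle, tolerance = 1e-10)
  }
  # saturated consistent statement contributes essentially nothing
  expect_lt(qual_nll(50, 1, 1), 1e-20)
  # saturated inconsistent statement grows linearly, no overflow
  expect_equal(qual_nll(-1e6, 1, 1), 1e6, tolerance = 1e-10)
})

test_that("hinge penalty is zero iff the sign agrees with the outcome", {
  expect_equal(qual_penalty(3, 1), 0)
  expect_equal(qual_penalty(3, 0), 3)
  expect_equal(qual_penalty(-3, 1), 3)
  expect_equal(qual_penalty(-3, 0), 0)
  # multiplying all weights by k scales Fqual by exactly k
  set.seed(10)
  d <- rnorm(50); z <- rbinom(50, 1, 0.5); w <- runif(50, 0.1, 2)
  expect_equal(qual_penalty(d, z, 7 * w), 7 * qual_penalty(d, z, w))
})

test_that("the logistic term brackets the hinge term within log(2)", {
  set.seed(11)
  n <- 1e4
  # |delta/s| spans deep saturation (up to 25, where the gap is ~1e-11)
  # while staying above the cancellation floor of the two O(|delta/s|)
  # terms, so strict positivity is meaningful in floating point
  s <- runif(n, 0.1, 5); d <- runif(n, -25, 25) * s; z <- rbinom(n, 1, 0.5)
  gap <- qual_nll(d, s, z, terms = TRUE) -
    qual_penalty(d, z, w = 1 / s, terms = TRUE)
  expect_true(all(gap > 0))
  expect_true(all(gap <= log(2) + 1e-12))
  # the bound is attained in the limit delta -> 0
  expect_equal(qual_nll(0, 1, 1) - qual_penalty(0, 1, 1), log(2))
})

test_that("minimizing F tracks the exact likelihood when penalties dominate", {
  # random problem instances with |delta/s| >= 10 and a fixed sigma: the
  # objective and the exact -log L must rank parameter proposals identically
  set.seed(12)
  m <- 40; n <- 10; sigma <- sqrt(0.5)  # Fquant/(2 sigma^2) = Fquant
  s <- rep(1, m)
  ranks <- replicate(50, {
    d <- sample(c(-1, 1), m, TRUE) * runif(m, 10, 100)
    z <- rbinom(m, 1, 0.5)
    y <- runif(n); f <- runif(n)
    Fobj <- f_quant(y, f) + qual_penalty(d, z, 1 / s)
    nll <- gaussian_nll(y, f, sigma) + qual_nll(d, s, z)
    c(Fobj, nll)
  })
  expect_equal(cor(ranks[1, ], ranks[2, ], method = "spearman"), 1)
})

test_that("objective breakdown composes and decomposes consistently", {
  b <- det_bundle(); prob <- det_problem()
  # the effective ground truth is an exact global minimizer
  bd <- objective_breakdown(b$truth_effective$theta, prob)
  expect_equal(bd$total, 0, tolerance = 1e-8)
  expect_equal(bd$Fqual, 0)
  expect_equal(bd$n, 18L)
  # at a perturbed point the decomposition still holds exactly
  th <- b$truth_effective$theta
  th["d3"] <- 3e-3; th["u3"] <- 4e-4
  bd2 <- objective_breakdown(th, prob)
  expect_identical(bd2$total, bd2$Fquant + bd2$Fqual)
  expect_equal(bd2$Fquant, sum(bd2$residuals2))
  expect_equal(bd2$Fqual, sum(bd2$penalties))
  expect_true(all(bd2$penalties >= 0))
  expect_identical(total_objective(th, prob), bd2$total)
  # empty problem evaluates to zero
  empty <- cascade_problem(NULL, property_set(list()))
  expect_equal(total_objective(make_theta(), empty), 0)
})

test_that("model_output applies the scaling factor linearly", {
  th <- make_theta()
  cond <- list(variant = "WT", observable = "pERK1_2_wt", time = 300)
  f1 <- model_output(th, cond)
  th2 <- th; th2["ScalepERK"] <- 2 * th2["ScalepERK"]
  expect_equal(model_output(th2, cond), 2 * f1)
  expect_error(model_output(th, list(variant = "WT", observable = "MEK_pRDS",
                                     time = 300)), "scaling factor")
})

test_that("log-posterior is flat-prior consistent inside the box", {
  b <- det_bundle(); prob <- det_problem()
  pin <- b$truth_effective$theta
  pr <- bundle_bayes_bounds(b)
  mid <- setNames(sqrt(pr$lower * pr$upper), pr$name)
  mid["sigma"] <- 1
  expect_equal(log_posterior(setNames(pr$lower - 1e-9, pr$name), prob, pr, pin),
               -Inf)
  lp1 <- log_posterior(mid, prob, pr, pin)
  mid2 <- mid; mid2["d3"] <- mid["d3"] * 1.5
  lp2 <- log_posterior(mid2, prob, pr, pin)
  th1 <- pin; th1[names(mid)] <- mid
  th2 <- pin; th2[names(mid2)] <- mid2
  # posterior ratio equals likelihood ratio under the flat prior
  expect_equal(lp1 - lp2,
               neg_log_lik(th2, prob) - neg_log_lik(th1, prob),
               tolerance = 1e-8)
})
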