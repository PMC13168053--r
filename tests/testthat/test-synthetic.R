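test_that("bundles have the study shape", {
  b <- det_bundle()
  expect_equal(nrow(b$data), 18)
  expect_equal(attr(b$data, "n"), 18)
  expect_true(all(b$data$variant == "WT"))
  expect_length(b$props, 90)
  expect_equal(nrow(default_templates()), 90)
  # five variants are exercised by the statements
  vs <- unique(unlist(lapply(b$props$props, function(p)
    c(p$left$variant, p$right$variant))))
  expect_setequal(vs, variant_ids())
})

test_that("noise-free data are exactly the normalized model outputs", {
  b <- det_bundle()
  # each observable series peaks at exactly 1 after max-normalization
  for (o in c("pEGFR", "pSOS1", "pERK1_2_wt"))
    expect_equal(max(b$exp[[o]]), 1)
  expect_true(all(b$data$value > 0 & b$data$value <= 1))
  # the effective ground truth reproduces the data to machine precision
  bd <- objective_breakdown(b$truth_effective$theta, det_problem())
  expect_lt(bd$total, 1e-10)
  expect_equal(bd$Fqual, 0)
})

test_that("generated noise matches the declared Gaussian scale", {
  truth <- ground_truth(sigma = 0.5)
  set.seed(77)
  base <- gen_quant(ground_truth(sigma = 0))
  resid <- replicate(300, {
    g <- gen_quant(truth)
    # undo the per-series normalization to recover the injected noise
    unlist(lapply(c("pEGFR", "pSOS1", "pERK1_2_wt"), function(o)
      g$exp[[o]] * g$norm[[o]] - base$exp[[o]] * base$norm[[o]]))
  })
  expect_equal(sd(resid), 0.5, tolerance = 0.05)
  expect_lt(abs(mean(resid)), 0.05)
})

test_that("stochastic statement outcomes follow the logistic flip rate", {
  # one template with a scale comparable to the true difference, so the flip
  # probability is far from 0 and 1
  tpl <- data.frame(l_variant = "WT", l_obs = "pERK1_2_wt", l_time = 300,
                    r_variant = "KO", r_obs = "pERK1_2_wt", r_time = 300,
                    stringsAsFactors = FALSE)
  tr <- lapply(c("WT", "KO"), function(v)
    simulate_cascade(build_network(v), default_params(), 300))
  delta <- tr[[1]]$observables$pERK1_2_wt - tr[[2]]$observables$pERK1_2_wt
  s_star <- abs(delta)  # p = plogis(+-1) ~ 0.73
  truth <- ground_truth(sigma = 1, s = s_star)
  p_true <- logistic_prob(delta, s_star)
  set.seed(13)
  z <- replicate(200, gen_qual(truth, tpl, mode = "stochastic")$props[[1]]$z)
  expect_lt(abs(mean(z) - p_true), 3 * sqrt(p_true * (1 - p_true) / 200))
  # deterministic mode is noise-free: outcome equals the Heaviside sign
  zd <- gen_qual(truth, tpl, mode = "deterministic")$props[[1]]$z
  expect_equal(zd, as.integer(delta >= 0))
})

test_that("bundles regenerate byte-identically from seed and manifest", {
  d1 <- tempfile(); d2 <- tempfile()
  b1 <- make_bundle(seed = 42, truth = ground_truth(sigma = 1),
                    qual_mode = "deterministic")
  b2 <- make_bundle(seed = 42, truth = ground_truth(sigma = 1),
                    qual_mode = "deterministic")
  write_bundle(b1, d1); write_bundle(b2, d2)
  for (f in c("WT.exp", "synthetic.prop", "manifest.json"))
    expect_identical(readLines(file.path(d1, f)),
                     readLines(file.path(d2, f)))
  # manifest round-trip regenerates the same bundle
  b3 <- read_bundle(d1)
  expect_equal(b3$exp, b1$exp)
  expect_equal(vapply(b3$props$props, format, character(1)),
               vapply(b1$props$props, format, character(1)))
  expect_equal(b3$truth_effective$theta, b1$truth_effective$theta)
  # EXP writer/reader round-trip, including missing values
  bm <- make_bundle(seed = 9, truth = ground_truth(sigma = 0.2),
                    n_missing = 3)
  f <- tempfile(fileext = ".exp")
  write_exp(bm$exp, f)
  expect_true(any(grepl("nan", readLines(f))))
  back <- read_exp(f)
  expect_equal(back, bm$exp, tolerance = 1e-12, ignore_attr = TRUE)
  expect_equal(attr(quant_dataset(back), "n"), 15)
})

test_that("ground truth must respect the optimization box", {
  th <- make_theta()
  th["d3"] <- 1  # far outside its box
  expect_error(ground_truth(theta = th), "outside optimization bounds")
  expect_silent(ground_truth(theta = th, check = FALSE))
})
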