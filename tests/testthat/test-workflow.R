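write_config <- function(lines) {
  f <- tempfile(fileext = ".conf")
  writeLines(lines, f)
  f
}

test_that("configuration validation catches structural mistakes", {
  d <- tempfile(); dir.create(d)
  bundle_dir <- file.path(d, "bundle")
  write_bundle(det_bundle(), bundle_dir)
  exp_path <- file.path(bundle_dir, "WT.exp")
  prop_path <- file.path(bundle_dir, "synthetic.prop")

  ok <- load_config(write_config(c("algorithm check",
                                   paste("exp WT", exp_path),
                                   paste("prop WT", prop_path))))
  expect_s3_class(ok, "run_config")
  expect_equal(ok$algorithm, "check")

  expect_error(load_config(write_config("frobnicate 1")), "unknown config key")
  expect_error(load_config(write_config(c("algorithm check",
                                          paste("exp KO", exp_path)))),
               "only the WT variant")
  expect_error(load_config(write_config(c("algorithm fit",
                                          "adjust d3 1e-2 1e-5"))),
               "lower must be < upper")
  expect_error(load_config(write_config(c("algorithm fit",
                                          "adjust zz 1e-5 1e-2"))),
               "unknown adjustable parameter")
  expect_error(load_config(write_config(c("algorithm check",
                                          "exp WT /no/such/file.exp"))),
               "not found")
  expect_error(load_config(write_config("seed 3")), "must set 'algorithm'")
})

test_that("synth and check stages close the loop at the ground truth", {
  d <- tempfile()
  synth_cfg <- write_config(c("algorithm synth", "seed 5", "sigma 0",
                              paste("output_dir", d)))
  res <- run_stage(synth_cfg)
  expect_true(file.exists(file.path(d, "WT.exp")))
  expect_true(file.exists(file.path(d, "synthetic.prop")))
  expect_true(file.exists(file.path(d, "run_manifest.json")))

  # check at the effective ground truth: everything satisfied, objective ~ 0
  eff <- res$result$truth_effective$theta
  d2 <- tempfile()
  check_cfg <- write_config(c(
    "algorithm check",
    paste("exp WT", file.path(d, "WT.exp")),
    paste("prop WT", file.path(d, "synthetic.prop")),
    sprintf("theta ScalepEGFR %.17g", eff[["ScalepEGFR"]]),
    sprintf("theta ScalepERK %.17g", eff[["ScalepERK"]]),
    sprintf("theta ScalepSOS1 %.17g", eff[["ScalepSOS1"]]),
    paste("output_dir", d2)))
  chk <- run_stage(check_cfg)$result
  expect_equal(chk$satisfied, 90L)
  expect_equal(chk$n_statements, 90L)
  expect_lt(chk$breakdown$total, 1e-6)
  summ <- jsonlite::read_json(file.path(d2, "check_summary.json"))
  expect_equal(summ$satisfied, 90L)

  # satisfied counts are invariant to statement order
  shuf <- file.path(d, "shuffled.prop")
  set.seed(3)
  writeLines(sample(readLines(file.path(d, "synthetic.prop"))), shuf)
  check_cfg2 <- write_config(c(
    "algorithm check",
    paste("prop WT", shuf),
    sprintf("theta ScalepEGFR %.17g", eff[["ScalepEGFR"]]),
    sprintf("theta ScalepERK %.17g", eff[["ScalepERK"]]),
    sprintf("theta ScalepSOS1 %.17g", eff[["ScalepSOS1"]]),
    paste("output_dir", tempfile())))
  expect_equal(run_stage(check_cfg2)$result$satisfied, 90L)
})

test_that("fit stage artifacts are reproducible for a fixed seed", {
  d <- tempfile()
  write_bundle(det_bundle(), d)
  mk <- function(out) write_config(c(
    "algorithm fit", "seed 11",
    paste("exp WT", file.path(d, "WT.exp")),
    paste("prop WT", file.path(d, "synthetic.prop")),
    "adjust d3 8e-5 3e-2",
    "population 6", "generations 4",
    paste("output_dir", out)))
  o1 <- tempfile(); o2 <- tempfile()
  r1 <- run_stage(mk(o1)); r2 <- run_stage(mk(o2))
  expect_identical(readLines(file.path(o1, "fit_runs.csv")),
                   readLines(file.path(o2, "fit_runs.csv")))
  expect_identical(r1$result$theta, r2$result$theta)
  man <- jsonlite::read_json(file.path(o1, "run_manifest.json"))
  expect_equal(man$algorithm, "fit")
  expect_gt(man$n_objective_evaluations, 0)
})

test_that("sample stage writes chains, diagnostics, and band files", {
  d <- tempfile()
  write_bundle(det_bundle(), d)
  eff <- det_bundle()$truth_effective$theta
  out <- tempfile()
  cfg <- write_config(c(
    "algorithm sample", "seed 8",
    paste("exp WT", file.path(d, "WT.exp")),
    paste("prop WT", file.path(d, "synthetic.prop")),
    "adjust d3 1e-5 1e-1",
    "adjust sigma 1e-1 1e1",
    sprintf("theta ScalepEGFR %.17g", eff[["ScalepEGFR"]]),
    sprintf("theta ScalepERK %.17g", eff[["ScalepERK"]]),
    sprintf("theta ScalepSOS1 %.17g", eff[["ScalepSOS1"]]),
    "burn 50", "adapt 100", "production 300", "chains 2",
    "rtol 1e-5", "atol 1",
    paste("output_dir", out)))
  res <- run_stage(cfg)
  expect_true(file.exists(file.path(out, "chain1.csv")))
  expect_true(file.exists(file.path(out, "chain2.csv")))
  dg <- jsonlite::read_json(file.path(out, "diagnostics.json"),
                            simplifyVector = TRUE)
  expect_setequal(dg$diagnostics$parameter, c("d3", "sigma"))
  for (v in variant_ids()) {
    bf <- file.path(out, sprintf("bands_%s.csv", v))
    expect_true(file.exists(bf))
    tab <- read.csv(bf, check.names = FALSE)
    expect_true(all(tab$median >= tab[["lower_95%"]] - 1e-9))
    expect_true(all(tab$median <= tab[["upper_95%"]] + 1e-9))
  }
  ch <- read.csv(file.path(out, "chain1.csv"))
  expect_equal(nrow(ch), 300)
  expect_true(all(ch$d3 >= 1e-5 & ch$d3 <= 1e-1))
})
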