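test_that("the comparison grammar parses its canonical forms", {
  pr <- parse_property("WT.MEK_pRDS at time=300 < N78G.MEK_pRDS at time=300")
  expect_equal(pr$left, list(variant = "WT", observable = "MEK_pRDS",
                             time = 300))
  expect_equal(pr$right$variant, "N78G")
  expect_equal(pr$op, "<")
  expect_equal(pr$z, 0L)
  # no spaces around the operator
  pr2 <- parse_property("N78G.pERK1_2_wt at time=300>T292D.pERK1_2_wt at time=300")
  expect_equal(pr2$z, 1L)
  expect_equal(pr2$op, ">")
  # weight annotation overrides the default 1/scale
  pr3 <- parse_property("WT.pEGFR at time=60 >= KO.pEGFR at time=60 weight=2.5")
  expect_equal(pr3$w, 2.5)
  expect_equal(parse_property("WT.pEGFR at time=60 <= KO.pEGFR at time=60",
                              scale = 4)$w, 0.25)
})

test_that("malformed or unknown statements are rejected with context", {
  expect_error(parse_property("WT.pEGFR at 300 < KO.pEGFR at time=300",
                              line_no = 7), "line 7")
  expect_error(parse_property("WT.bogus at time=300 < WT.bogus at time=300"),
               "unknown observable")
  expect_error(parse_property("XX.pEGFR at time=300 < WT.pEGFR at time=300"),
               "unknown variant")
})

test_that("format/parse round-trips and PROP files ignore comments", {
  lines <- c("WT.MEK_pRDS at time=300 < N78G.MEK_pRDS at time=300",
             "T292D.pERK1_2_wt at time=1800 >= KO.pERK1_2_wt at time=3600")
  for (l in lines) {
    pr <- parse_property(l)
    re <- parse_property(format(pr))
    expect_equal(re[c("left", "right", "op", "z")],
                 pr[c("left", "right", "op", "z")])
  }
  f <- tempfile(fileext = ".prop")
  writeLines(c("# header comment", "", lines, "   "), f)
  ps <- read_prop(f)
  expect_length(ps, 2)
  f2 <- tempfile(fileext = ".prop")
  write_prop(ps, f2)
  expect_equal(readLines(f2), vapply(ps$props, format, character(1)))
})

test_that("evaluation uses the Heaviside tie convention H(0) = 1", {
  trajs <- list(WT = toy_trajectory(300, list(pEGFR = 5)),
                KO = toy_trajectory(300, list(pEGFR = 5)))
  tie_ge <- parse_property("WT.pEGFR at time=300 >= KO.pEGFR at time=300")
  tie_lt <- parse_property("WT.pEGFR at time=300 < KO.pEGFR at time=300")
  expect_true(evaluate_property(tie_ge, trajs)$satisfied)
  expect_false(evaluate_property(tie_lt, trajs)$satisfied)
  expect_equal(evaluate_property(tie_ge, trajs)$delta, 0)
})

test_that("satisfaction is antisymmetric under side swap for delta != 0", {
  set.seed(42)
  for (i in 1:20) {
    a <- runif(1, 0, 100); b <- runif(1, 0, 100)
    if (a == b) next
    trajs <- list(WT = toy_trajectory(300, list(pSOS1 = a)),
                  KO = toy_trajectory(300, list(pSOS1 = b)))
    for (op in c("<", ">", "<=", ">=")) {
      mirror <- c("<" = ">", ">" = "<", "<=" = ">=", ">=" = "<=")[[op]]
      p1 <- parse_property(sprintf(
        "WT.pSOS1 at time=300 %s KO.pSOS1 at time=300", op))
      p2 <- parse_property(sprintf(
        "KO.pSOS1 at time=300 %s WT.pSOS1 at time=300", mirror))
      expect_equal(evaluate_property(p1, trajs)$satisfied,
                   evaluate_property(p2, trajs)$satisfied)
    }
    # exactly one of {A < B, A >= B} holds for any delta
    plt <- parse_property("WT.pSOS1 at time=300 < KO.pSOS1 at time=300")
    pge <- parse_property("WT.pSOS1 at time=300 >= KO.pSOS1 at time=300")
    expect_equal(evaluate_property(plt, trajs)$satisfied +
                   evaluate_property(pge, trajs)$satisfied, 1)
  }
})

test_that("count_satisfied sums verdicts and reports each statement", {
  expect_equal(count_satisfied(property_set(list()), list())$n_satisfied, 0L)
  trajs <- list(WT = toy_trajectory(300, list(pEGFR = 10)),
                KO = toy_trajectory(300, list(pEGFR = 3)))
  ps <- property_set(list(
    parse_property("WT.pEGFR at time=300 > KO.pEGFR at time=300"),
    parse_property("WT.pEGFR at time=300 < KO.pEGFR at time=300")))
  cs <- count_satisfied(ps, trajs)
  expect_equal(cs$n_satisfied, 1L)
  expect_equal(nrow(cs$report), 2)
  expect_equal(cs$report$delta, c(7, 7))
  expect_equal(cs$report$satisfied, c(TRUE, FALSE))
  # missing time on the grid is an evaluation error
  bad <- parse_property("WT.pEGFR at time=60 < KO.pEGFR at time=300")
  expect_error(evaluate_property(bad, trajs), "not on the")
})
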