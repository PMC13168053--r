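#' Reference parameter set for the MEK-isoform ERK cascade
#'
#' Returns the original rate constants and initial copy numbers of the
#' MEK-isoform model as a named numeric vector.  Units: s^-1 for unimolecular
#' rate constants, (molecules x s)^-1 for bimolecular rate constants,
#' molecules/cell for initial copy numbers.  The six parameters governing
#' constitutive EGFR/SOS1 turnover (`s1`, `d1`, `s2`, `d2`) and the
#' pre-stimulus ligand-engagement rate (`c1`, `c1init`) are carried for
#' completeness but are inert in simulation: the pre-stimulus state equals the
#' initial copy numbers and ligand engagement switches to `c1L` at t = 0.
#'
#' @return Named numeric vector with 46 entries (class `cascade_params`).
#' @export
default_params <- function() {
  p <- c(
    # stimulus and receptor module
    c1L  = 2.0e-2,  c2 = 2.0e-7,  t1 = 1.0e2,  d3 = 1.0e-3,
    b1   = 4.0e-8,  n1 = 2.0e-3,
    # MEK dimerization
    b2 = 1.0e-5, n2 = 1.0e-3, b3 = 1.0e-5, n3 = 3.0e-2, b4 = 1.0e-5, n4 = 1.0e-3,
    # RAS/RAF
    a1 = 1.5e-7, i1 = 2.0e-2, a2 = 4.0e-8, i2 = 1.0e-2,
    # MEK activation sites
    p1 = 1.5e-7, u1 = 5.0e-3,
    # ERK activation
    p2a = 1.0e-6, p2b = 5.0e-6, u2 = 2.0e-2,
    # feedback on SOS1 and MEK1 T292
    p3 = 2.0e-9, u3 = 1.0e-3, p4 = 1.2e-9, u4 = 2.0e-4,
    # PHP phosphatase
    b5 = 4.0e-9, n5 = 2.0e-4, u5 = 2.0e1,
    # fixed/inert quantities
    s1 = 2.5, d1 = 5.0e-6, s2 = 1.0, d2 = 5.0e-6, c1 = 2.0e-2, c1init = 0.0,
    MEK1_fraction = 6.7e-1, X = 5.0,
    # initial copy numbers
    EGFR0 = 5.0e5, SOS10 = 2.0e5, RAS0 = 5.0e5, RAF0 = 5.0e5,
    MEK_tot0 = 2.0e5, MEK10 = 1.34e5, MEK1_T292p0 = 0.0, MEK20 = 6.6e4,
    ERK0 = 3.0e6, PHP_MEK0 = 3.0e6
  )
  class(p) <- c("cascade_params", "numeric")
  p
}

#' Names of the parameters held fixed during calibration
#'
#' The 18 quantities never adjusted in fitting: turnover/stimulus bookkeeping
#' parameters and the initial copy numbers defining the resting cell.
#'
#' @return Character vector of 18 parameter names.
#' @export
fixed_param_names <- function() {
  c("s1", "d1", "s2", "d2", "c1", "c1init", "MEK1_fraction", "X",
    "EGFR0", "SOS10", "RAS0", "RAF0", "MEK_tot0", "MEK10", "MEK1_T292p0",
    "MEK20", "ERK0", "PHP_MEK0")
}

#' The five cell-line variants
#' @return Character vector `c("WT","KO","N78G","T292A","T292D")`.
#' @export
variant_ids <- function() c("WT", "KO", "N78G", "T292A", "T292D")

#' Transform a parameter set to a cell-line variant
#'
#' * `WT`: unchanged.
#' * `KO` (MEK1 knockout): `MEK10 = 0`.
#' * `N78G` (no MEK1 homo- or heterodimerization): `b2 = 0`, `b4 = 0`.
#' * `T292A` (no ERK-mediated feedback phosphorylation of MEK1): `p4 = 0`.
#' * `T292D` (phosphomimetic): all MEK1 starts T292-phosphorylated
#'   (`MEK1_T292p0 = MEK10`) and the mark is permanent (`u4 = 0`).
#'
#' @param base Named parameter vector as from [default_params()].
#' @param variant One of [variant_ids()].
#' @return Transformed parameter vector.
#' @export
apply_variant <- function(base, variant) {
  variant <- match.arg(variant, variant_ids())
  p <- base
  switch(variant,
    WT = p,
    KO = { p["MEK10"] <- 0; p },
    N78G = { p[c("b2", "b4")] <- 0; p },
    T292A = { p["p4"] <- 0; p },
    T292D = { p["MEK1_T292p0"] <- p[["MEK10"]]; p["u4"] <- 0; p }
  )
}

#' Box constraints for maximum-likelihood optimization
#'
#' Bounds for the 28 adjustable rate constants plus the three scaling factors
#' that map WT copy numbers onto relative-intensity measurements (31 rows).
#'
#' @return data.frame with columns `name`, `lower`, `upper`.
#' @export
optim_bounds <- function() {
  b <- rbind(
    c("c1L", 9.0e-4, 4.0e-2), c("c2", 9.0e-9, 4.0e-6), c("t1", 99, 101),
    c("d3", 8.0e-5, 3.0e-2),  c("b1", 2.0e-9, 6.0e-7), c("n1", 9.0e-5, 4.0e-2),
    c("b2", 8.0e-7, 3.0e-4),  c("n2", 8.0e-5, 3.0e-2), c("b3", 8.0e-7, 3.0e-4),
    c("n3", 1.0e-3, 5.0e-1),  c("b4", 8.0e-7, 3.0e-4), c("n4", 8.0e-5, 3.0e-2),
    c("a1", 1.27e-8, 1.29e-6), c("i1", 9.0e-4, 4.0e-1), c("a2", 2.0e-9, 6.0e-7),
    c("i2", 8.0e-4, 3.0e-1),  c("p1", 8.0e-9, 4.0e-6), c("u1", 3.0e-4, 7.0e-2),
    c("p2a", 8.0e-8, 3.0e-5), c("p2b", 1.0e-6, 5.0e-4), c("u2", 9.0e-4, 4.0e-1),
    c("p3", 9.0e-11, 4.0e-8), c("u3", 8.0e-5, 3.0e-2), c("p4", 9.0e-11, 3.0e-8),
    c("u4", 9.0e-6, 4.0e-3),  c("b5", 2.0e-10, 6.0e-8), c("n5", 9.0e-6, 4.0e-3),
    c("u5", 19, 21),
    c("ScalepEGFR", 3.0e-5, 6.0e-5), c("ScalepERK", 2.0e-6, 5.0e-6),
    c("ScalepSOS1", 9.0e-5, 3.0e-4)
  )
  data.frame(name = b[, 1], lower = as.numeric(b[, 2]),
             upper = as.numeric(b[, 3]), stringsAsFactors = FALSE)
}

#' Best-fit parameter values from the global fit of the published study shape
#'
#' Point estimates for the 31 adjustable parameters plus the noise scale
#' `sigma`, useful as a pinning set for reduced analyses.
#'
#' @return Named numeric vector of length 32.
#' @export
bestfit_params <- function() {
  c(c1L = 7.4e-3, c2 = 9.3e-9, t1 = 9.9e1, d3 = 2.0e-3, b1 = 2.4e-8,
    n1 = 6.5e-4, b2 = 4.2e-6, n2 = 2.6e-4, b3 = 9.9e-5, n3 = 8.0e-2,
    b4 = 2.9e-4, n4 = 3.5e-3, a1 = 2.3e-7, i1 = 3.9e-1, a2 = 3.3e-8,
    i2 = 2.7e-2, p1 = 3.5e-6, u1 = 9.5e-4, p2a = 5.2e-7, p2b = 2.3e-5,
    u2 = 6.7e-2, p3 = 1.1e-9, u3 = 2.6e-4, p4 = 6.5e-10, u4 = 3.2e-4,
    b5 = 1.7e-8, n5 = 3.9e-3, u5 = 1.9e1,
    ScalepEGFR = 1.1e-4, ScalepERK = 3.2e-6, ScalepSOS1 = 1.1e-4,
    sigma = 1.1)
}

#' Box prior for Bayesian uncertainty quantification
#'
#' Default sampled set: the two rate constants found practically identifiable
#' and most relevant to receptor decay and feedback reversal (`d3`, `u3`),
#' the three scaling factors, and the noise scale `sigma`.
#'
#' @return data.frame with columns `name`, `lower`, `upper`.
#' @export
bayes_bounds <- function() {
  data.frame(
    name  = c("d3", "u3", "ScalepEGFR", "ScalepERK", "ScalepSOS1", "sigma"),
    lower = c(1e-5, 1e-5, 3e-5, 2e-6, 9e-5, 1e-1),
    upper = c(1e-1, 1e-1, 6e-5, 5e-6, 3e-4, 1e1),
    stringsAsFactors = FALSE
  )
}

#' Scaling-factor lookup for quantitative observables
#'
#' Maps each scaled observable name to the name of its scaling factor.
#' Qualitative comparisons use raw copy numbers and need no entry.
#'
#' @return Named character vector.
#' @export
scale_map <- function() {
  c(pEGFR = "ScalepEGFR", pERK1_2_wt = "ScalepERK", pSOS1 = "ScalepSOS1")
}

#' Observables produced by every simulation
#' @return Character vector of the four observable names.
#' @export
observable_names <- function() c("MEK_pRDS", "pERK1_2_wt", "pEGFR", "pSOS1")

# Validate a parameter vector: complete, non-negative.
check_params <- function(p) {
  need <- names(default_params())
  miss <- setdiff(need, names(p))
  if (length(miss) > 0)
    stop("parameter set incomplete, missing: ", paste(miss, collapse = ", "))
  if (any(!is.finite(p[need])) || any(p[need] < 0))
    stop("parameters must be finite and non-negative")
  invisible(TRUE)
}
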