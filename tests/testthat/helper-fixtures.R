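# Shared fixtures, built lazily and cached for the whole test session.

.fixtures <- new.env(parent = emptyenv())

# Noise-free, fully deterministic study-shaped bundle: the effective ground
# truth is an exact global minimizer (objective 0).
det_bundle <- function() {
  if (is.null(.fixtures$det_bundle))
    .fixtures$det_bundle <- make_bundle(seed = 5,
                                        truth = ground_truth(sigma = 0),
                                        qual_mode = "deterministic")
  .fixtures$det_bundle
}

det_problem <- function() {
  if (is.null(.fixtures$det_problem)) {
    b <- det_bundle()
    .fixtures$det_problem <- cascade_problem(b$data, b$props,
                                             rtol = 1e-6, atol = 1e-2)
  }
  .fixtures$det_problem
}

# Minimal hand-built trajectory stand-in for property evaluation tests:
# a list with `time` and an `observables` data.frame, like the real thing.
toy_trajectory <- function(time, values) {
  obs <- data.frame(time = time)
  for (o in observable_names())
    obs[[o]] <- if (o %in% names(values)) values[[o]] else 0
  list(time = time, observables = obs)
}
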