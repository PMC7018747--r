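# Shared fixtures. Everything is generated in code; heavy end-to-end runs
# are computed once per session and cached.

.cache <- new.env(parent = emptyenv())

cached <- function(key, expr) {
  if (!exists(key, envir = .cache)) assign(key, force(expr), envir = .cache)
  get(key, envir = .cache)
}

const_policy <- function(step = 3, max_angle = 60)
  increment_policy("constant", step, max_angle)

# Small asymmetric test volume (no rotational symmetry), for refinement and
# FSC tests where the C6 subunit's z-rotation gauge would be degenerate.
asymmetric_blob <- function(box = 16, seed = 1) {
  set.seed(seed)
  vol <- array(0, rep(box, 3))
  ctr <- rep((box + 1) / 2, 3)
  for (i in 1:5) {
    p <- ctr + runif(3, -box / 5, box / 5)
    vol <- tiltbench:::add_blob(vol, p, runif(1, 0.8, 1.6), runif(1, 0.5, 1.5))
  }
  vol
}

# Desk-scale configuration used by the end-to-end acceptance experiments.
accept_config <- function(...) {
  benchmark_config(dim_vox = 96, voxel_size = 1.33 * 12, box = 24,
                   mask_radius_frac = 0.3, symmetries = c(1, 3, 6),
                   seed = 1, ...)
}

# Shared heavy run: replicated three-scheme benchmark (paired replicates,
# FSC curves averaged across replicates), reused by the ordering, symmetry
# and ranking-consistency tests.
scheme_benchmark_fixture <- function() {
  cached("scheme_benchmark", run_scheme_benchmark_replicated(accept_config(),
                                                             n_rep = 6))
}
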