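# Shared fixtures: small, fast problems built in code.

# A small strong-signal paired dataset from the package generator:
# two blocks wide enough that per-feature loadings stay well away from
# the near-l0 clip thresholds of the tiny-gamma grids.
small_sim <- function(seed = 1L, n = 60L, p = 50L, q = 60L,
                      signal_scale = 3) {
  sig <- block_signals(p, q, n_blocks = 2L,
                       block_width = round(c(p, q) / 8), seed = seed)
  sim_scca_data(sim_design(n = n, p = p, q = q, true_u = sig$u,
                           true_v = sig$v,
                           signal_scale = signal_scale, seed = seed))
}

# Pure-noise paired matrices (no shared structure).
noise_views <- function(seed = 1L, n = 30L, p = 12L, q = 15L) {
  set.seed(seed)
  list(X = matrix(rnorm(n * p), n, p), Y = matrix(rnorm(n * q), n, q))
}

# Admissible (lam, gamma) pairs per family for grid-style tests.
family_params <- function(family) {
  gam <- switch(family,
                l1      = NA_real_,
                lgamma  = c(0.1, 0.3, 0.5),
                scad    = c(2.1, 3.7, 10),
                geman   = c(0.01, 0.1, 1),
                laplace = c(0.01, 0.1, 1),
                mcp     = c(0.1, 1, 3),
                etp     = c(0.5, 10, 100),
                log     = c(0.5, 10, 100))
  expand.grid(lam = c(0.5, 1, 2), gamma = gam)
}

spec_for <- function(family, lam = 1, gamma = NA_real_) {
  if (family == "l1" || is.na(gamma)) penalty_spec(family, lam = lam)
  else penalty_spec(family, lam = lam, gamma = gamma)
}
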