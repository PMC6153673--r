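# Shared fixtures: the reference parameter sets used throughout
# (beta = 0.6, gamma = 0.1, M = 100 unless stated otherwise).

spec_neutral <- function(M = 100) {
  model_spec(a = 1, b = 1, c = 1, d = 1, beta = 0.6, gamma = 0.1, M = M)
}

spec_coex <- function(bc = 1.1) {
  model_spec(a = 1, b = bc, c = bc, d = 1, beta = 0.6, gamma = 0.1, M = 100)
}

spec_coord <- function(bc = 0.9) spec_coex(bc)

spec_dom <- function(cd = 0.975) {
  model_spec(a = 1, b = 1, c = cd, d = cd, beta = 0.6, gamma = 0.1, M = 100)
}

# psi solutions are deterministic and moderately expensive; cache per call
# signature across test files.
.psi_cache <- new.env(parent = emptyenv())
cached_psi <- function(spec, regime = NULL, z_max = NULL, n_grid = 2000) {
  key <- paste(spec$a, spec$b, spec$c, spec$d, spec$beta_X, spec$gamma_X,
               spec$M, regime %||% "auto", z_max %||% "def", n_grid,
               sep = "|")
  if (is.null(.psi_cache[[key]])) {
    .psi_cache[[key]] <- solve_psi(spec, regime = regime, z_max = z_max,
                                   n_grid = n_grid)
  }
  .psi_cache[[key]]
}

`%||%` <- function(x, y) if (is.null(x)) y else x

# random interior-equilibrium specs (coexistence or coordination)
random_interior_spec <- function(coexistence = TRUE) {
  a <- runif(1, 0.9, 1.1)
  d <- runif(1, 0.9, 1.1)
  gap_c <- runif(1, 0.02, 0.08)
  gap_b <- runif(1, 0.02, 0.08)
  if (coexistence) {
    model_spec(a = a, b = d + gap_b, c = a + gap_c, d = d,
               beta = 0.6, gamma = 0.1, M = 100)
  } else {
    model_spec(a = a, b = d - gap_b, c = a - gap_c, d = d,
               beta = 0.6, gamma = 0.1, M = 100)
  }
}
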