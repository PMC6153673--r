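# Independent numerical oracles, deliberately on different machinery than
# the implementation paths they check.

# Numerical root of the deterministic right-hand side with both types
# present (oracle for the closed-form interior fixed point). For X, Y > 0
# the right-hand side vanishes iff both per-capita growth brackets vanish;
# Newton iterates on those brackets (the interior root is a repeller of
# plain Newton on the X,Y-weighted field, whose basin is captured by the
# boundary equilibria).
newton_fixed_point <- function(spec, X_init = 30, Y_init = 30,
                               tol = 1e-12, max_iter = 100) {
  brackets <- function(v) {
    c(spec$beta_X - spec$gamma_X - v[1] / (spec$a * spec$M) -
        v[2] / (spec$b * spec$M),
      spec$beta_Y - spec$gamma_Y - v[1] / (spec$c * spec$M) -
        v[2] / (spec$d * spec$M))
  }
  v <- c(X_init, Y_init)
  for (i in seq_len(max_iter)) {
    f <- brackets(v)
    if (max(abs(f)) < tol) break
    h <- 1e-6 * pmax(abs(v), 1)
    J <- matrix(0, 2, 2)
    for (j in 1:2) {
      vp <- v; vp[j] <- vp[j] + h[j]
      J[, j] <- (brackets(vp) - f) / h[j]
    }
    v <- v - solve(J, f)
  }
  stopifnot(max(abs(deterministic_rhs(v[1], v[2], spec))) < 1e-6)
  v
}

# Linear shooting (superposition) oracle for the psi boundary-value
# problem: backward IVP integration of a particular and a homogeneous
# solution from z_top, combined to meet the regularity condition at z_min.
solve_psi_shooting <- function(spec, regime = "internal", z_top = 2,
                               z_min = 1e-3, n_out = 2001) {
  beta <- spec$beta_X; gamma <- spec$gamma_X; d <- spec$d; M <- spec$M
  if (regime == "internal") {
    k0 <- 1 / (3 * (beta + gamma) * d)
    coef <- function(z) list(
      A = z * ((beta + gamma) * d + z) / (2 * M),
      B = z * ((beta - gamma) * d - z),
      C = -3 / (z * M) * ((beta + gamma) * d + z),
      D = z + 1 / M)
  } else {
    k0 <- 1 / ((beta + gamma) * d)
    coef <- function(z) list(
      A = z * (beta + gamma + z / d) / (2 * M),
      B = z * (beta - gamma - z / d),
      C = -(beta + gamma + z / d) / (z * M),
      D = (z + 1 / M) / d)
  }
  slope <- 1 / (z_top - (beta - gamma) * d)
  rhs <- function(z, y, parms) {
    co <- coef(z)
    list(c(y[2], -(co$D * parms + co$B * y[2] + co$C * y[1]) / co$A))
  }
  times <- seq(z_top, z_min, length.out = n_out)
  solp <- deSolve::lsoda(c(0, slope), times, rhs, parms = 1,
                         rtol = 1e-11, atol = 1e-12)
  solh <- deSolve::lsoda(c(1, 0), times, rhs, parms = 0,
                         rtol = 1e-11, atol = 1e-12)
  alpha <- (k0 * z_min - solp[nrow(solp), 2]) / solh[nrow(solh), 2]
  data.frame(z = rev(solp[, 1]),
             psi = rev(solp[, 2] + alpha * solh[, 2]))
}
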