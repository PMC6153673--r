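#' Weak-selection fixation probability
#'
#' First-order approximation of the mutant fixation probability
#' `phi(p, z)` around the neutral value `p`, with the game-class-specific
#' first-order term:
#' \itemize{
#' \item coexistence/coordination (interior equilibrium `p*`):
#'   \deqn{\varphi = p + p(1-p)(1 - p/p^*)(1 - d/b)\,\psi(z)}
#' \item dominance: \deqn{\varphi = p + p(1-p)(1 - d/b)\,\psi(z)}
#' \item neutral: \eqn{\varphi = p} (the selection factor `1 - d/b`
#'   vanishes).
#' }
#' The boundary values `phi(0, z) = 0` and `phi(1, z) = 1` are exact, and at
#' the interior equilibrium `phi(p*, z) = p*` exactly. The first-order
#' formula can leave `[0, 1]` outside the weak-selection regime; the result
#' carries both the raw and the clamped value plus a breakdown flag from
#' [weak_selection_diagnostics()] (any condition magnitude above 0.1).
#'
#' @param p initial mutant fraction(s) in `[0, 1]`.
#' @param z initial scaled total population size(s) (> 0); `p` and `z` are
#'   recycled to a common length.
#' @param spec a `model_spec` with common rates.
#' @param psi optional pre-solved [solve_psi()] solution; solved on the fly
#'   (regime matching the game class) when omitted. A regime mismatch
#'   between `psi` and the game class is an error.
#' @return An object of class `"weak_selection_result"`: `phi` (clamped to
#'   `[0,1]`), `raw`, `selection` (`1 - d/b`), `regime`, `p`, `z`,
#'   `conditions` (diagnostics vector), `conditions_violated` flag.
#' @export
phi_weak_selection <- function(p, z, spec, psi = NULL) {
  validate_model(spec, weak_selection = TRUE)
  stopifnot(all(p >= 0), all(p <= 1), all(z > 0))
  cls <- classify_game(spec)
  regime <- switch(cls,
                   coexistence = "internal", coordination = "internal",
                   neutral = "neutral", "dominance")
  if (regime == "neutral") {
    raw <- rep_len(p, max(length(p), length(z)))
    return(structure(list(phi = raw, raw = raw, selection = 0,
                          regime = "neutral", p = p, z = z,
                          conditions = weak_selection_diagnostics(spec),
                          conditions_violated = FALSE),
                     class = "weak_selection_result"))
  }
  if (is.null(psi)) {
    psi <- solve_psi(spec, regime = regime,
                     z_max = max(10 * spec$d * (spec_beta(spec) -
                                                  spec_gamma(spec)),
                                 1.05 * max(z)))
  } else if (psi$regime != regime) {
    stop("psi solved for the ", psi$regime, " regime but spec is ", cls,
         call. = FALSE)
  } else if (psi$d != spec$d || psi$beta != spec_beta(spec) ||
             psi$gamma != spec_gamma(spec) || psi$M != spec$M) {
    stop("psi solved for different model constants (d, beta, gamma, M) ",
         "than this spec", call. = FALSE)
  }
  n <- max(length(p), length(z))
  p <- rep_len(p, n); z <- rep_len(z, n)
  s <- 1 - spec$d / spec$b
  psz <- psi_eval(psi, z)
  first_order <- if (regime == "internal") {
    p_star <- internal_fixed_point(spec)$p_star
    p * (1 - p) * (1 - p / p_star) * s * psz
  } else {
    p * (1 - p) * s * psz
  }
  raw <- p + first_order
  structure(list(phi = pmin(pmax(raw, 0), 1), raw = raw, selection = s,
                 regime = regime, p = p, z = z,
                 conditions = weak_selection_diagnostics(spec),
                 conditions_violated = weak_selection_violated(spec)),
            class = "weak_selection_result")
}

#' @export
print.weak_selection_result <- function(x, ...) {
  cat(sprintf("<weak_selection_result> %s regime, selection 1-d/b = %.4g%s\n",
              x$regime, x$selection,
              if (x$conditions_violated) " [weak-selection conditions violated]"
              else ""))
  print(data.frame(p = x$p, z = x$z, phi = x$phi, raw = x$raw))
  invisible(x)
}

#' Fixation probability near the interior equilibrium
#'
#' Expansion of the weak-selection formula around `p = p* + epsilon`:
#' \deqn{\varphi(p^*+\varepsilon, z) = (p^*+\varepsilon)\left(1 -
#'   \frac{\varepsilon}{p^*}(1 - p^* - \varepsilon)(1 - d/b)\psi(z)\right).}
#' Around a stable equilibrium (`d < b`, coexistence) positive deviations
#' fix less often than neutral and negative ones more often; around an
#' unstable equilibrium (`d > b`, coordination) the pattern reverses.
#'
#' @param epsilon deviation(s) from `p*`; `p* + epsilon` must lie in
#'   `[0, 1]`.
#' @param z scaled total size(s).
#' @param spec a `model_spec` with an interior equilibrium.
#' @param psi optional internal-regime `psi_solution`.
#' @return Numeric vector of probabilities (unclamped first-order values).
#' @export
phi_near_equilibrium <- function(epsilon, z, spec, psi = NULL) {
  cls <- classify_game(spec)
  if (!cls %in% c("coexistence", "coordination")) {
    stop("defined only for specs with an interior equilibrium (got ", cls,
         ")", call. = FALSE)
  }
  validate_model(spec, weak_selection = TRUE)
  p_star <- internal_fixed_point(spec)$p_star
  stopifnot(all(p_star + epsilon >= 0), all(p_star + epsilon <= 1),
            all(z > 0))
  if (is.null(psi)) {
    psi <- solve_psi(spec, regime = "internal",
                     z_max = max(10 * spec$d * (spec_beta(spec) -
                                                  spec_gamma(spec)),
                                 1.05 * max(z)))
  }
  s <- 1 - spec$d / spec$b
  (p_star + epsilon) *
    (1 - (epsilon / p_star) * (1 - p_star - epsilon) * s * psi_eval(psi, z))
}

#' Apply the transformed generator to a gridded (p, z) surface
#'
#' Evaluates the infinitesimal generator of the diffusion in the
#' fraction/size coordinates `(p, z)` on a gridded surface by central finite
#' differences (nonuniform grids supported). The five terms (drift in p,
#' drift in z, diffusion in p, mixed derivative, diffusion in z) are
#' implemented as written for the interior form, which requires the
#' interior equilibrium `p*`; neutral specs are handled as the
#' `1 - d/b -> 0` limit (all `p*`-carrying terms vanish). Dominance specs
#' are rejected.
#'
#' A fixation-probability surface makes this residual vanish; applying it to
#' the first-order weak-selection surface leaves a residual of second order
#' in the selection strength `1 - d/b` (the basis of the error-order test).
#'
#' @param phi matrix of surface values, `length(p_grid)` rows by
#'   `length(z_grid)` columns.
#' @param p_grid,z_grid strictly increasing grids (at least 3 points each;
#'   interior points of both grids are where the residual is returned).
#' @param spec a `model_spec` with common rates (interior-equilibrium or
#'   neutral game class).
#' @return Matrix of residual values at the interior grid points
#'   (`(length(p_grid)-2) x (length(z_grid)-2)`), with `dimnames` giving the
#'   p and z coordinates.
#' @export
generator_apply <- function(phi, p_grid, z_grid, spec) {
  validate_model(spec, weak_selection = TRUE)
  cls <- classify_game(spec)
  if (cls %in% c("dominance_mutant", "dominance_wildtype")) {
    stop("interior form of the generator requires an interior equilibrium; ",
         "spec is a dominance game", call. = FALSE)
  }
  if (length(p_grid) < 3 || length(z_grid) < 3) {
    stop("grid too coarse for the central-difference stencil", call. = FALSE)
  }
  stopifnot(is.matrix(phi), nrow(phi) == length(p_grid),
            ncol(phi) == length(z_grid), all(diff(p_grid) > 0),
            all(diff(z_grid) > 0), all(z_grid > 0))
  beta <- spec_beta(spec); gamma <- spec_gamma(spec)
  d <- spec$d; b <- spec$b; a <- spec$a; cc <- spec$c; M <- spec$M
  s <- 1 - d / b
  inv_pstar <- if (cls == "neutral") 0 else
    1 / internal_fixed_point(spec)$p_star
  # s * inv_pstar appears only multiplied by s-free factors below; for the
  # neutral limit s = 0 kills those terms so inv_pstar's value is moot.

  np <- length(p_grid); nz <- length(z_grid)
  ip <- 2:(np - 1); iz <- 2:(nz - 1)
  wp <- fd_weights(p_grid); wz <- fd_weights(z_grid)

  stencil1 <- function(f, w, idx) # first derivative along rows (p)
    w$d1$l * f[idx - 1, , drop = FALSE] + w$d1$c * f[idx, , drop = FALSE] +
    w$d1$r * f[idx + 1, , drop = FALSE]
  stencil2 <- function(f, w, idx)
    w$d2$l * f[idx - 1, , drop = FALSE] + w$d2$c * f[idx, , drop = FALSE] +
    w$d2$r * f[idx + 1, , drop = FALSE]

  # p-direction derivatives on interior p rows (all z columns)
  dphi_dp <- stencil1(phi, wp, ip)
  d2phi_dp2 <- stencil2(phi, wp, ip)
  # z-direction: operate on transposed matrices
  tphi <- t(phi)
  dphi_dz <- t(stencil1(tphi, wz, iz))
  d2phi_dz2 <- t(stencil2(tphi, wz, iz))
  # restrict to interior x interior
  dphi_dp <- dphi_dp[, iz, drop = FALSE]
  d2phi_dp2 <- d2phi_dp2[, iz, drop = FALSE]
  dphi_dz <- dphi_dz[ip, , drop = FALSE]
  d2phi_dz2 <- d2phi_dz2[ip, , drop = FALSE]
  # mixed derivative: p-stencil applied to the z-derivative surface
  dphi_dz_full <- t(stencil1(tphi, wz, iz))      # all p rows, interior z
  d2phi_dpdz <- stencil1(dphi_dz_full, wp, ip)

  p <- p_grid[ip]; z <- z_grid[iz]
  P <- matrix(p, length(ip), length(iz))
  Z <- matrix(z, length(ip), length(iz), byrow = TRUE)

  quad_minus <- 1 - P * (2 - d / cc - d / b) + s * P^2 * inv_pstar
  quad_pp <- d / b + P * (1 + d / a - 2 * d / b) - s * P^2 * inv_pstar

  res <- (P * (1 - P) / d) * s * (1 - P * inv_pstar) * (Z + 1 / M) * dphi_dp +
    Z * (beta - gamma - (Z / d) * quad_minus) * dphi_dz +
    (P * (1 - P) / (2 * Z * M)) * (beta + gamma + (Z / d) * quad_pp) *
      d2phi_dp2 +
    (P * (1 - P) * Z / (d * M)) * s * (P * inv_pstar - 1) * d2phi_dpdz +
    (Z / (2 * M)) * (beta + gamma + (Z / d) * quad_minus) * d2phi_dz2
  dimnames(res) <- list(p = signif(p, 8), z = signif(z, 8))
  res
}

#' First-order fixation surface on a grid
#'
#' Convenience builder for [generator_apply()]: evaluates the
#' weak-selection formula on the tensor grid `p_grid x z_grid`.
#'
#' @inheritParams generator_apply
#' @param psi optional pre-solved `psi_solution`.
#' @return Matrix of `phi` values (raw first-order, unclamped).
#' @export
weak_selection_surface <- function(p_grid, z_grid, spec, psi = NULL) {
  res <- phi_weak_selection(rep(p_grid, times = length(z_grid)),
                            rep(z_grid, each = length(p_grid)),
                            spec, psi = psi)
  matrix(res$raw, nrow = length(p_grid), ncol = length(z_grid))
}
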