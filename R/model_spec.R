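#' Define a two-type competitive Lotka-Volterra model
#'
#' Builds and validates the full parameterization of the reaction system:
#' per-capita birth rates (`beta_X`, `beta_Y`), per-capita death rates
#' (`gamma_X`, `gamma_Y`), the population scale `M` and the four competition
#' payoffs `a, b, c, d`. Competition events occur at the inverse-payoff rates
#' `1/(aM)` (X-X), `1/(bM)` (X dies meeting Y), `1/(cM)` (Y dies meeting X)
#' and `1/(dM)` (Y-Y), so payoffs must be strictly positive.
#'
#' `beta` / `gamma` are convenience arguments setting both types at once;
#' type-specific values override them. The weak-selection theory additionally
#' requires equal birth and death rates across types and a viable population
#' (`beta > gamma`); operations that rely on it call
#' [validate_model()] with `weak_selection = TRUE`.
#'
#' @param a,b,c,d competition payoffs (dimensionless, > 0). `a`, `b` are the
#'   mutant's payoffs against mutant and wild-type; `c`, `d` the wild-type's
#'   against mutant and wild-type.
#' @param beta,gamma common per-capita birth/death rate (1/time) for both
#'   types.
#' @param beta_X,beta_Y,gamma_X,gamma_Y type-specific rates, overriding
#'   `beta`/`gamma`.
#' @param M population scale (> 0); the monomorphic mutant equilibrium holds
#'   about `a (beta - gamma) M` individuals.
#' @return An object of class `"model_spec"` (a validated named list).
#' @examples
#' spec <- model_spec(a = 1, b = 1.1, c = 1.1, d = 1,
#'                    beta = 0.6, gamma = 0.1, M = 100)
#' classify_game(spec)
#' @export
model_spec <- function(a = 1, b = 1, c = 1, d = 1,
                       beta = NULL, gamma = NULL,
                       beta_X = NULL, beta_Y = NULL,
                       gamma_X = NULL, gamma_Y = NULL,
                       M = 100) {
  if (is.null(beta_X)) beta_X <- if (!is.null(beta)) beta else 0.6
  if (is.null(beta_Y)) beta_Y <- if (!is.null(beta)) beta else 0.6
  if (is.null(gamma_X)) gamma_X <- if (!is.null(gamma)) gamma else 0.1
  if (is.null(gamma_Y)) gamma_Y <- if (!is.null(gamma)) gamma else 0.1
  spec <- structure(list(a = a, b = b, c = c, d = d,
                         beta_X = beta_X, beta_Y = beta_Y,
                         gamma_X = gamma_X, gamma_Y = gamma_Y,
                         M = M),
                    class = "model_spec")
  validate_model(spec)
}

#' Validate a model specification
#'
#' Checks the type invariants of a [model_spec()]: strictly positive payoffs
#' (they appear as divisors in the competition rates), non-negative birth and
#' death rates and positive `M`. With `weak_selection = TRUE` it additionally
#' requires equal birth rates and equal death rates across types (the
#' analytic theory assumes a single `beta` and `gamma`) and errors otherwise
#' with condition class `"lvfix_unequal_rates"`. A non-viable net growth rate
#' (`beta <= gamma`) triggers a warning, not an error: the simulator can run
#' such models, the analytic machinery cannot.
#'
#' @param spec a `model_spec`.
#' @param weak_selection require the common-rate assumptions of the analytic
#'   theory.
#' @return `spec`, unchanged, invisibly usable in pipes.
#' @export
validate_model <- function(spec, weak_selection = FALSE) {
  stopifnot(inherits(spec, "model_spec") || is.list(spec))
  pay <- unlist(spec[c("a", "b", "c", "d")])
  if (any(!is.finite(pay)) || any(pay <= 0)) {
    stop("nonpositive payoff: a, b, c, d must be finite and > 0 ",
         "(competition rates are 1/(aM) etc.)", call. = FALSE)
  }
  rates <- unlist(spec[c("beta_X", "beta_Y", "gamma_X", "gamma_Y")])
  if (any(!is.finite(rates)) || any(rates < 0)) {
    stop("birth/death rates must be finite and >= 0", call. = FALSE)
  }
  if (!is.finite(spec$M) || spec$M <= 0) {
    stop("population scale M must be > 0", call. = FALSE)
  }
  if (weak_selection) {
    if (spec$beta_X != spec$beta_Y || spec$gamma_X != spec$gamma_Y) {
      stop(structure(class = c("lvfix_unequal_rates", "error", "condition"),
                     list(message = paste0(
                            "weak-selection theory requires equal birth and ",
                            "death rates across types"),
                          call = NULL)))
    }
    if (spec$beta_X <= spec$gamma_X) {
      stop("weak-selection theory requires a viable population (beta > gamma)",
           call. = FALSE)
    }
  }
  if (spec$beta_X <= spec$gamma_X || spec$beta_Y <= spec$gamma_Y) {
    warning("non-viable: beta <= gamma for at least one type", call. = FALSE)
  }
  if (!inherits(spec, "model_spec")) class(spec) <- "model_spec"
  spec
}

#' @export
print.model_spec <- function(x, ...) {
  cat("<model_spec>\n")
  cat(sprintf("  payoffs      a=%g b=%g c=%g d=%g  (%s)\n",
              x$a, x$b, x$c, x$d, classify_game(x)))
  cat(sprintf("  birth/death  beta_X=%g beta_Y=%g gamma_X=%g gamma_Y=%g\n",
              x$beta_X, x$beta_Y, x$gamma_X, x$gamma_Y))
  cat(sprintf("  scale        M=%g\n", x$M))
  invisible(x)
}

# common-rate shortcuts (valid after weak-selection validation)
spec_beta <- function(spec) spec$beta_X
spec_gamma <- function(spec) spec$gamma_X

#' Classify the evolutionary game encoded by the payoffs
#'
#' Payoff orderings determine the deterministic phase portrait:
#' `coexistence` (`a < c` and `b > d`, stable interior equilibrium),
#' `coordination` (`a > c` and `b < d`, unstable interior equilibrium),
#' and dominance otherwise: `dominance_mutant` when the mutant's payoffs
#' weakly dominate (`a >= c` and `b >= d`, not all four equal),
#' `dominance_wildtype` symmetrically. Exact neutrality (`neutral`) requires
#' `a = b = c = d`. Boundary ties (`a = c` or `b = d`, not all equal) are
#' assigned to the dominance classes, where the dominance-regime
#' approximation remains valid; the residual tie `a = c` and `b = d` with
#' unequal diagonal is labelled `dominance_mutant` (its first-order selection
#' term vanishes since `b = d`).
#'
#' @param spec a `model_spec`.
#' @return A single string, one of `"coexistence"`, `"coordination"`,
#'   `"dominance_mutant"`, `"dominance_wildtype"`, `"neutral"`.
#' @export
classify_game <- function(spec) {
  a <- spec$a; b <- spec$b; c <- spec$c; d <- spec$d
  if (a == b && b == c && c == d) return("neutral")
  if (a < c && b > d) return("coexistence")
  if (a > c && b < d) return("coordination")
  if (a >= c && b >= d) return("dominance_mutant")
  "dominance_wildtype"
}

#' Interior equilibrium of the deterministic dynamics
#'
#' For coexistence and coordination games the deterministic system has an
#' interior fixed point
#' \deqn{(X^*, Y^*) = \left(\frac{ac(b-d)}{bc-ad}(\beta_X-\gamma_X)M,\;
#'       \frac{bd(c-a)}{bc-ad}(\beta_Y-\gamma_Y)M\right)}
#' with mutant fraction
#' \deqn{p^* = \frac{ac(b-d)}{ac(b-d) + bd(c-a)}.}
#' The closed formulas are used directly (no root finding). For symmetric
#' games (`a = d`, `b = c`) `p* = 1/2` exactly.
#'
#' @param spec a `model_spec`.
#' @return A list with fields `X_star`, `Y_star` (individual counts),
#'   `p_star` (mutant fraction), `z_star` (scaled total size
#'   `(X*+Y*)/M`).
#' @export
internal_fixed_point <- function(spec) {
  cls <- classify_game(spec)
  if (!cls %in% c("coexistence", "coordination")) {
    stop("no interior equilibrium for ", cls, " specs", call. = FALSE)
  }
  a <- spec$a; b <- spec$b; c <- spec$c; d <- spec$d
  den <- b * c - a * d
  X_star <- a * c * (b - d) / den * (spec$beta_X - spec$gamma_X) * spec$M
  Y_star <- b * d * (c - a) / den * (spec$beta_Y - spec$gamma_Y) * spec$M
  p_star <- a * c * (b - d) / (a * c * (b - d) + b * d * (c - a))
  list(X_star = X_star, Y_star = Y_star, p_star = p_star,
       z_star = (X_star + Y_star) / spec$M)
}

#' Deterministic right-hand side of the mean-field dynamics
#'
#' \deqn{dX/dt = X(\beta_X - \gamma_X - X/(aM) - Y/(bM)), \quad
#'       dY/dt = Y(\beta_Y - \gamma_Y - X/(cM) - Y/(dM)).}
#'
#' @param X,Y abundances (counts; non-negative, need not be integer).
#' @param spec a `model_spec`.
#' @return Named numeric vector `c(dX, dY)`.
#' @export
deterministic_rhs <- function(X, Y, spec) {
  dX <- X * (spec$beta_X - spec$gamma_X - X / (spec$a * spec$M) -
               Y / (spec$b * spec$M))
  dY <- Y * (spec$beta_Y - spec$gamma_Y - X / (spec$c * spec$M) -
               Y / (spec$d * spec$M))
  c(dX = dX, dY = dY)
}

#' Integrate the deterministic dynamics
#'
#' Solves the mean-field ODE system with an adaptive stiff-capable solver
#' (`deSolve::lsoda`), relative tolerance `1e-8` by default.
#'
#' @param spec a `model_spec`.
#' @param X0,Y0 initial counts (>= 0).
#' @param t_end final time (> 0).
#' @param n_out number of output times (including 0).
#' @param rtol,atol solver tolerances.
#' @return A data frame with columns `time`, `X`, `Y`.
#' @export
integrate_deterministic <- function(spec, X0, Y0, t_end, n_out = 201,
                                    rtol = 1e-8, atol = 1e-10) {
  stopifnot(t_end > 0, X0 >= 0, Y0 >= 0)
  times <- seq(0, t_end, length.out = n_out)
  rhs <- function(t, state, parms) {
    list(deterministic_rhs(state[1], state[2], spec))
  }
  sol <- deSolve::lsoda(c(X = X0, Y = Y0), times, rhs, parms = NULL,
                        rtol = rtol, atol = atol)
  if (attr(sol, "istate")[1] < 0) {
    stop("deterministic ODE solver failed: istate = ",
         attr(sol, "istate")[1], call. = FALSE)
  }
  out <- as.data.frame(sol)
  # clip solver-level negative round-off; dynamics preserve non-negativity
  out$X <- pmax(out$X, 0)
  out$Y <- pmax(out$Y, 0)
  out
}

#' Scaled coordinates of a population state
#'
#' Converts counts to the scaled variables `x = X/M`, `y = Y/M` and the
#' fraction/size coordinates `p = x/(x+y)`, `z = x + y` used by the
#' weak-selection theory.
#'
#' @param X,Y counts (>= 0, not both 0).
#' @param spec a `model_spec`.
#' @return List with `x`, `y`, `p`, `z`.
#' @export
scaled_state <- function(X, Y, spec) {
  stopifnot(X >= 0, Y >= 0, X + Y > 0)
  x <- X / spec$M; y <- Y / spec$M
  list(x = x, y = y, p = x / (x + y), z = x + y)
}

#' Weak-selection condition magnitudes
#'
#' The first-order approximation is derived under smallness conditions on
#' combinations of the payoffs; this reports their magnitudes (absolute
#' values) so callers can decide thresholds:
#' \itemize{
#' \item `cond_i`: \eqn{(1-d/b)^2}
#' \item `cond_ii`: \eqn{|(1-d/b)(2-d/c-d/b)|}
#' \item `cond_iii`: \eqn{|(1-d/b)(1+d/a-2d/b)|}
#' \item `cond_iv`: \eqn{|(1-d/b)(1/p^*-2)|} (interior-equilibrium games
#'   only; `NA` otherwise)
#' \item `cond_v`: \eqn{|(1-d/b)(1 + (db/ac)\,(c-a)/(b-d))|} (dominance
#'   regime; `NA` when `b = d`)
#' }
#'
#' @param spec a `model_spec`.
#' @return Named numeric vector of the five magnitudes.
#' @export
weak_selection_diagnostics <- function(spec) {
  a <- spec$a; b <- spec$b; c <- spec$c; d <- spec$d
  s <- 1 - d / b
  cls <- classify_game(spec)
  cond_iv <- NA_real_
  if (cls %in% c("coexistence", "coordination")) {
    p_star <- internal_fixed_point(spec)$p_star
    cond_iv <- abs(s * (1 / p_star - 2))
  }
  cond_v <- if (b == d) NA_real_ else
    abs(s * (1 + (d * b / (a * c)) * (c - a) / (b - d)))
  c(cond_i = s^2,
    cond_ii = abs(s * (2 - d / c - d / b)),
    cond_iii = abs(s * (1 + d / a - 2 * d / b)),
    cond_iv = cond_iv,
    cond_v = cond_v)
}

#' Flag weak-selection breakdown
#'
#' TRUE when any condition magnitude relevant for the spec's game class
#' exceeds `threshold` (default 0.1): conditions (i)-(iv) for games with an
#' interior equilibrium, (i)-(iii) plus (v) for dominance games, none for
#' exact neutrality.
#' @param spec a `model_spec`.
#' @param threshold magnitude above which a condition counts as violated.
#' @return Logical scalar.
#' @export
weak_selection_violated <- function(spec, threshold = 0.1) {
  diag <- weak_selection_diagnostics(spec)
  cls <- classify_game(spec)
  keep <- switch(cls,
                 neutral = character(),
                 coexistence = ,
                 coordination = c("cond_i", "cond_ii", "cond_iii",
                                  "cond_iv"),
                 c("cond_i", "cond_ii", "cond_iii", "cond_v"))
  any(diag[keep] > threshold, na.rm = TRUE)
}
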