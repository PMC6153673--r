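#' One-dimensional diffusion on a bounded interval
#'
#' Container for a scalar diffusion `dq = drift(q) dt + sqrt(variance(q)) dW`
#' on `[q_lo, q_hi]` with absorbing endpoints, as used by the
#' scale-function hitting-probability machinery.
#'
#' @param drift function of `q` returning the infinitesimal drift.
#' @param variance function of `q` returning the infinitesimal variance
#'   (must be positive on the open interval).
#' @param q_lo,q_hi domain endpoints.
#' @param description tag describing the model.
#' @return Object of class `"diffusion_model_1d"`.
#' @export
diffusion_model_1d <- function(drift, variance, q_lo = 0, q_hi = 1,
                               description = "") {
  stopifnot(is.function(drift), is.function(variance), q_hi > q_lo)
  structure(list(drift = drift, variance = variance,
                 q_lo = q_lo, q_hi = q_hi, description = description),
            class = "diffusion_model_1d")
}

#' @export
print.diffusion_model_1d <- function(x, ...) {
  cat(sprintf("<diffusion_model_1d> on [%g, %g] %s\n", x$q_lo, x$q_hi,
              x$description))
  invisible(x)
}

#' Hitting probability of the upper boundary via the scale function
#'
#' For a 1-D diffusion with drift `m(q)` and variance `v(q)`, the
#' probability of hitting `q_hi` before `q_lo` from `q0` is
#' `S(q0)/S(q_hi)` where the scale function is
#' \deqn{S(q) = \int_{q_{lo}}^{q} \exp\left(-\int \frac{2 m(u)}{v(u)} du
#'  \right) du.}
#' The inner integral is accumulated relative to the domain midpoint and the
#' outer integrand exponentiated after subtracting its maximum (log-domain
#' stabilization), with adaptive Gauss-Kronrod quadrature on the open
#' interval (endpoint singularities of `2m/v` are permitted as long as the
#' scale density stays integrable).
#'
#' @param model a [diffusion_model_1d()].
#' @param q0 starting point(s) in `[q_lo, q_hi]`.
#' @param rel.tol quadrature relative tolerance.
#' @return Probability vector; endpoints map to exactly 0 and 1.
#' @export
scale_fixation_probability <- function(model, q0, rel.tol = 1e-10) {
  stopifnot(inherits(model, "diffusion_model_1d"),
            all(q0 >= model$q_lo), all(q0 <= model$q_hi))
  lo <- model$q_lo; hi <- model$q_hi
  mid <- (lo + hi) / 2
  chi <- function(u) 2 * model$drift(u) / model$variance(u)
  # B(u) = int_mid^u chi; scale density exp(-B) (constant offset cancels)
  Bfun <- function(u) {
    vapply(u, function(ui) {
      if (ui == mid) return(0)
      val <- tryCatch(
        stats::integrate(chi, mid, ui, rel.tol = rel.tol,
                         abs.tol = 0, stop.on.error = TRUE)$value,
        error = function(e) stop("inner scale integral failed near q = ",
                                 signif(ui, 6), ": ", conditionMessage(e),
                                 call. = FALSE))
      val
    }, numeric(1))
  }
  # probe the log-density to centre the exponentials
  probe <- seq(lo, hi, length.out = 65)[-c(1, 65)]
  Bp <- Bfun(probe)
  if (any(!is.finite(Bp))) {
    stop("non-integrable scale density on the interval", call. = FALSE)
  }
  Bmin <- min(Bp)
  dens <- function(u) exp(-(Bfun(u) - Bmin))
  seg <- function(from, to) {
    if (to <= from) return(0)
    stats::integrate(dens, from, to, rel.tol = rel.tol,
                     abs.tol = 0)$value
  }
  total <- seg(lo, hi)
  if (!is.finite(total) || total <= 0) {
    stop("non-integrable scale density on the interval", call. = FALSE)
  }
  vapply(q0, function(q) {
    if (q <= lo) return(0)
    if (q >= hi) return(1)
    min(max(seg(lo, q) / total, 0), 1)
  }, numeric(1))
}

#' Projected one-dimensional diffusion along the slow manifold
#'
#' Center-manifold (fast-ecology / slow-evolution timescale separation)
#' reduction of the two-type system to the mutant manifold coordinate
#' `q = x / (a(beta - gamma))` on `[0, 1]`:
#' \deqn{dq = q(1-q)\left(\frac{1}{d}-\frac{1}{b}
#'   -\left(\frac{1}{a}+\frac{1}{d}-\frac{1}{b}-\frac{1}{c}\right)q\right)dt
#'   + \sqrt{\frac{2\beta q(1-q)}{M(\beta-\gamma)^2}}\,dW_t.}
#' For neutral payoffs the drift vanishes identically; for
#' frequency-independent payoffs (`a = b`, `c = d`) it reduces to
#' `q(1-q)(1/d - 1/b)`.
#'
#' @param spec a `model_spec` with common rates, `beta > gamma`.
#' @return A [diffusion_model_1d()] on `[0, 1]`.
#' @export
cm_projected_model <- function(spec) {
  validate_model(spec, weak_selection = TRUE)
  a <- spec$a; b <- spec$b; cc <- spec$c; d <- spec$d
  beta <- spec_beta(spec); gamma <- spec_gamma(spec)
  M <- spec$M
  lin <- 1 / d - 1 / b
  quad <- 1 / a + 1 / d - 1 / b - 1 / cc
  diffusion_model_1d(
    drift = function(q) q * (1 - q) * (lin - quad * q),
    variance = function(q) 2 * beta * q * (1 - q) / (M * (beta - gamma)^2),
    q_lo = 0, q_hi = 1,
    description = "center-manifold projected competition diffusion")
}

#' Fixation probability from the projected diffusion
#'
#' Maps the initial condition `(p, z)` onto the slow manifold and evaluates
#' the scale-function hitting probability of the projected model. The
#' default `"frequency"` mapping sets `q0 = p`: the fast ecological
#' relaxation approximately conserves the slow variable, the mutant
#' frequency, and on the manifold (total size `a(beta-gamma)` in scaled
#' units) the manifold coordinate `q = x/(a(beta-gamma))` coincides with
#' the frequency. The `"manifold"` mapping instead reads the coordinate off
#' the unrelaxed state, `q0 = p z / (a(beta-gamma))`; it agrees with
#' `"frequency"` exactly on the manifold (`z = a(beta-gamma)`) but degrades
#' off it (and can leave `[0, 1]`, in which case it is clamped with a
#' warning). Either way, starts far from the manifold are where this
#' projection is least trustworthy.
#'
#' @param p initial mutant fraction(s).
#' @param z initial scaled total size(s).
#' @param spec a `model_spec` with common rates.
#' @param mapping `"frequency"` (default) or `"manifold"`, see above.
#' @param rel.tol quadrature tolerance passed on.
#' @return Probability vector.
#' @export
phi_constable_mckane <- function(p, z, spec,
                                 mapping = c("frequency", "manifold"),
                                 rel.tol = 1e-10) {
  mapping <- match.arg(mapping)
  stopifnot(all(p >= 0), all(p <= 1), all(z > 0))
  model <- cm_projected_model(spec)
  n <- max(length(p), length(z))
  p <- rep_len(p, n); z <- rep_len(z, n)
  q0 <- if (mapping == "frequency") p else
    p * z / (spec$a * (spec_beta(spec) - spec_gamma(spec)))
  if (any(q0 > 1) || any(q0 < 0)) {
    warning("manifold coordinate q0 outside [0, 1]; clamped", call. = FALSE)
    q0 <- pmin(pmax(q0, 0), 1)
  }
  scale_fixation_probability(model, q0, rel.tol = rel.tol)
}
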