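#' Translate model parameters to classical population-genetics quantities
#'
#' The literature formulas below describe a beneficial mutant in a
#' logistically growing population. Their parameters map onto this model as
#' `s = 1/d - 1/b` (selection acts through competitive death rates),
#' `K = (beta - gamma) a M` (carrying capacity), `r = beta - gamma`
#' (logistic growth rate), `b_birth = beta`, `xi = 0` (no neutral
#' replacement mechanism exists here) and the effective-size factor
#' `Q = K zM (s + r) / (sK + r zM)`. The translation is exact for
#' frequency-independent payoffs (`a = b`, `c = d`); other specs are allowed
#' with a warning since selection is then frequency-dependent and the
#' mapping only approximate.
#'
#' @param spec a `model_spec` with common rates.
#' @param z initial scaled total population size (the classical formulas
#'   start from a single mutant among `zM` individuals).
#' @return Named list `s`, `K`, `r`, `b_birth`, `xi`, `Q`, `zM`.
#' @export
translate_params <- function(spec, z) {
  validate_model(spec, weak_selection = TRUE)
  stopifnot(z > 0)
  if (spec$a != spec$b || spec$c != spec$d) {
    warning("parameter translation assumes frequency-independent payoffs ",
            "(a = b, c = d)", call. = FALSE)
  }
  beta <- spec_beta(spec); gamma <- spec_gamma(spec)
  s <- 1 / spec$d - 1 / spec$b
  r <- beta - gamma
  K <- r * spec$a * spec$M
  zM <- z * spec$M
  Q <- K * zM * (s + r) / (s * K + r * zM)
  list(s = s, K = K, r = r, b_birth = beta, xi = 0, Q = Q, zM = zM)
}

#' Otto-Whitlock fixation probability (logistic growth)
#'
#' Diffusion-approximation result for a single beneficial mutant in a
#' logistically growing population:
#' \deqn{\varphi_{OW}(1/(zM)) = \frac{2 s K (s + r)}{s K + r zM}.}
#' Valid only for an advantageous mutant (`s > 0`).
#'
#' @inheritParams translate_params
#' @return Single-mutant fixation probability.
#' @export
phi_otto_whitlock <- function(spec, z) {
  tr <- translate_params(spec, z)
  if (tr$s <= 0) {
    stop("approximation requires an advantageous mutant (s > 0)",
         call. = FALSE)
  }
  2 * tr$s * tr$K * (tr$s + tr$r) / (tr$s * tr$K + tr$r * tr$zM)
}

#' Kimura-Ohta fixation probability
#'
#' Kolmogorov-backward-equation result with effective-size factor `Q`:
#' \deqn{\varphi_{KO}(1/(zM)) = \frac{1 - e^{-4 Q s/(zM)}}{1 - e^{-4 Q s}},}
#' evaluated with `expm1` for stability at small `s`; the `s -> 0` limit
#' `1/(zM)` is returned exactly at `s = 0`.
#'
#' @inheritParams translate_params
#' @return Single-mutant fixation probability.
#' @export
phi_kimura_ohta <- function(spec, z) {
  tr <- translate_params(spec, z)
  if (tr$s == 0) return(1 / tr$zM)
  expm1(-4 * tr$Q * tr$s / tr$zM) / expm1(-4 * tr$Q * tr$s)
}

#' Uecker-Hermisson fixation probability (branching approximation)
#'
#' Branching-process result for logistic growth and constant selective
#' advantage; the single-mutant value is
#' \deqn{\varphi_{UH}(1/(zM)) = \frac{s(r+s)}{s(r+s) + (b+\xi)(s + r zM/K)
#'   + r zM (r+s)/K}}
#' and for a general initial fraction `p`
#' \deqn{\varphi_{UH}(p, z) = 1 - (1 - \varphi_{UH}(1/(zM)))^{p zM},}
#' with the (possibly non-integer) exponent `p zM` evaluated as a real
#' power via `log1p`/`expm1`. Requires `s > 0`; at `p = 1/(zM)` the general
#' form reduces exactly to the single-mutant value.
#'
#' @inheritParams translate_params
#' @param p initial mutant fraction(s); default `1/(zM)` (single mutant).
#' @return Fixation probability vector.
#' @export
phi_uecker_hermisson <- function(spec, z, p = NULL) {
  tr <- translate_params(spec, z)
  if (tr$s <= 0) {
    stop("branching approximation requires a beneficial mutant (s > 0)",
         call. = FALSE)
  }
  s <- tr$s; r <- tr$r
  phi1 <- s * (r + s) /
    (s * (r + s) + (tr$b_birth + tr$xi) * (s + r * tr$zM / tr$K) +
       r * tr$zM * (r + s) / tr$K)
  if (is.null(p)) return(phi1)
  stopifnot(all(p >= 0), all(p <= 1))
  expo <- p * tr$zM
  # a unit exponent must reduce to the single-mutant value exactly
  ifelse(expo == 1, phi1, -expm1(expo * log1p(-phi1)))
}
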