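---
title: "Fixation probabilities under demographic fluctuations: methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Fixation probabilities under demographic fluctuations: methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(lvfix)
```

# The model

Two types — a mutant $X$ and a wild-type $Y$ — evolve in continuous time in
a well-mixed population. Each individual reproduces at per-capita rate
$\beta$ and dies spontaneously at rate $\gamma$; in addition, pairwise
competition kills one member of the pair at rates that are inverse payoffs
of a $2\times 2$ game: $X\!+\!X \to X$ at $1/(aM)$, $X\!+\!Y \to Y$ at
$1/(bM)$ (the mutant dies), $X\!+\!Y \to X$ at $1/(cM)$ (the resident
dies), $Y\!+\!Y \to Y$ at $1/(dM)$. The scale parameter $M$ controls the
stationary population size: a monomorphic mutant population fluctuates
around $a(\beta-\gamma)M$ individuals, so payoffs are reflected in carrying
capacities. Because competition removes individuals without replacement,
the total population size fluctuates stochastically — there is no fixed-
$N$ constraint anywhere in the model.

In the large-$M$ limit the mean-field ODEs are the classical competitive
Lotka–Volterra equations; for payoff orderings $a<c,\,b>d$ (coexistence)
and $a>c,\,b<d$ (coordination) they carry an interior equilibrium whose
mutant fraction is
$p^* = ac(b-d)\,/\,(ac(b-d)+bd(c-a))$, stable in the first case and
unstable in the second. Dominance orderings have no interior equilibrium.
`classify_game()` resolves boundary ties ($a=c$ or $b=d$, not all four
payoffs equal) into the dominance classes, because the dominance-regime
approximation below remains valid on those boundaries while the
interior-equilibrium regime does not; the doubly-tied case $a=c,\ b=d$
(unequal diagonal) is labelled `dominance_mutant` by convention — its
first-order selection term vanishes anyway. Exact neutrality requires
$a=b=c=d$.

All analytic machinery assumes both types share $\beta$ and $\gamma$ with
$\beta > \gamma$ (selection acts only through competition); the simulator
and the deterministic integrator accept unequal rates, and every analytic
entry point validates and refuses them with a dedicated error class.

# Weak selection and the amplitude function

In the coordinates $p = x/(x+y)$ (mutant fraction) and $z = x+y$ (scaled
total size), the fixation probability of the mutant solves a degenerate
elliptic boundary-value problem driven by the generator of the diffusion
approximation. When the payoff matrix is a small perturbation of a neutral
matrix — quantified by the condition magnitudes reported by
`weak_selection_diagnostics()` — the solution separates to first order in
the selection strength $s = 1-d/b$:

$$\varphi(p,z) = p + p(1-p)\Big(1-\frac{p}{p^*}\Big)\,s\,\psi(z) + O(s^2)$$

for interior-equilibrium games, and
$\varphi_{dom} = p + p(1-p)\,s\,\psi(z) + O(s^2)$ for dominance games
(condition (iv) on $p^*$ is replaced by a dominance-specific condition
(v)). The amplitude $\psi(z)$ is independent of $p$ and solves a singular
second-order linear ODE in $z$; the two regimes carry different
$d$-scalings of their drift and inhomogeneous terms and both are
implemented exactly as stated in their own form, not harmonized into one
equation (`psi_ode_residual()` exposes the raw left-hand sides). Structural
facts used as test invariants: $\psi > 0$ for all $z>0$, and $\psi$ grows
with $z$ — larger initial populations weight the competition processes,
which is where the types differ, more heavily.

Two immediate consequences are checked property-style across payoff
sweeps: for $p<p^*$ the mutant beats the neutral baseline iff $b>d$
(performance against the resident decides), and $\partial\varphi/\partial a
> 0$ (a larger own-type payoff never hurts). The latter only concerns games
with an interior equilibrium; in the dominance formula $a$ does not appear.

## Numerical solution of the ψ boundary-value problem

The ODE is singular at $z=0$ and advection-dominated for moderate $M$, so
the package discretizes it with second-order finite differences on a graded
grid (quadratically clustered toward the origin, 2,000 points by default on
$(10^{-3}, z_{\max}]$) and solves the banded linear system sparsely. The
boundary conditions reconstruct the unique bounded solution:

* **Regularity at the origin.** A Frobenius expansion of either regime
  around $z=0$ forces $\psi \approx z/(3(\beta+\gamma)d)$ (interior
  regime) resp. $\psi \approx z/(d(\beta+\gamma))$ (dominance regime);
  this is imposed as a Dirichlet value at $z_{\min}=10^{-3}$. The
  dominance regime has a resonant quadratic homogeneous mode at the
  origin, so its linear asymptote is only approached loosely at
  $z\sim 10^{-3}$; solutions at $z \ge 0.1$ change by under $5\cdot
  10^{-6}$ relative when $z_{\min}$ is moved to $10^{-5}$, so the
  placement is immaterial for everything the amplitude is used for.
* **Far field.** For $z \gg d(\beta-\gamma)$ the first-derivative term
  balances the inhomogeneity, giving the Robin condition
  $\psi'(z_{\max}) = 1/(z_{\max}-d(\beta-\gamma))$, imposed with a
  second-order one-sided stencil. The default
  $z_{\max} = 10\,d(\beta-\gamma)$ is far above the carrying-capacity
  scale; doubling it moves the solution on the lower half of the grid by
  less than $10^{-4}$ relative (tested).

The on-grid finite-difference residual is checked after every solve
(typically $\sim 10^{-11}$), and the solved grid is verified against the
positivity and monotonicity guarantees — a violation raises an error with
grid diagnostics instead of returning a corrupt object. Discretization
accuracy is established in the test suite against an independent linear
shooting oracle: a particular and a homogeneous solution of the same ODE
are integrated backwards from $z=2$ with `deSolve` and superposed to meet
the regularity condition; the two methods agree to better than $10^{-4}$
relative on $[0.1, 2]$. (Shooting itself is only usable on short domains:
the fast homogeneous mode grows like $e^{2M\int (z-d(\beta-\gamma))/\dots}$
and destroys the superposition by cancellation for larger $z$ — the same
mechanism that makes the discretized system badly conditioned for
$M \gtrsim 1000$, which the solver surfaces as an error rather than
returning noise.)

Between grid points $\psi$ is interpolated with shape-preserving
(Fritsch–Carlson) monotone cubics so positivity and monotonicity survive
interpolation.

## First-order surface and honest breakdown

`phi_weak_selection()` evaluates the regime-appropriate formula; the
boundary values $\varphi(0,\cdot)=0$, $\varphi(1,\cdot)=1$ and the
identity $\varphi(p^*,z)=p^*$ hold exactly by construction. Outside the
weak-selection regime the first-order value can leave $[0,1]$; results
carry both the raw and the clamped value together with a breakdown flag
raised when any condition magnitude relevant for the game class exceeds
0.1. The flag deliberately uses conditions (i)–(iv) for interior games and
(i)–(iii)+(v) for dominance games: (iv) and (v) are regime-specific and
meaningless for the other class.

`generator_apply()` implements the transformed generator in $(p,z)$
coordinates — five terms, evaluated with central finite differences on
(possibly nonuniform) tensor grids — and is used as a residual oracle: the
residual of the first-order surface must shrink quadratically in $s$.
Halving $1-d/b$ from $b=1.04$ to $b=1.02$ (with $a=d=1$, $c=b$) reduces
the maximal residual by a factor of $3.85 \approx (s_{1.04}/s_{1.02})^2$,
confirming the error order numerically.

# Exact simulation

The stochastic process itself is simulated with the direct Gillespie
method in C++: exponential waiting times with the total propensity,
categorical reaction choice, one uniform each per event. Design choices:

* **Pair counting.** Intra-type competition uses distinct-pair
  propensities $X(X-1)/(aM)$ — standard mass-action kinetics for a
  bimolecular reaction. The alternative $X^2$ convention differs by
  $O(X/M)$ and vanishes in the scaling limit; it is available via
  `combinatorics = "naive"` for sensitivity checks, and the two are
  indistinguishable at $M=100$ within Monte Carlo error.
* **Reproducibility.** Each replicate runs its own PCG32 stream derived
  from the user's master seed and the replicate index, independent of R's
  RNG state. Identical `(spec, X0, Y0, seed, stream)` give byte-identical
  trajectories, and enlarging `n_runs` extends the ensemble without
  reshuffling earlier replicates.
* **Timeouts.** Runs hitting the event budget (default $10^7$) are a
  third outcome class, excluded from estimates with a warning — never
  silently folded into loss — and an all-timeout batch is an error.
  Absorption is almost surely finite here (competition caps the
  population), and 1,000 neutral replicates at the default budget produce
  zero timeouts in the test suite.

Fixation means the wild-type count hits zero while mutants remain.
Estimates come with Wilson score intervals. A `stop_on_absorption = FALSE`
mode keeps the reaction system running past fixation, which the tests use
to verify that a monomorphic population fluctuates around the carrying
capacity $a(\beta-\gamma)M$.

# Diffusion level

`simulate_sde()` is an Euler–Maruyama discretization (Itô convention) of
the two-dimensional diffusion approximation with independent Brownian
motions and $1/\sqrt{M}$ noise; a coordinate stepping below zero is set to
zero and frozen. The default step $dt = 10^{-3}$ keeps the discretization
bias of fixation frequencies within the 0.03 band asserted against the
exact simulator. Euler–Maruyama with absorbing truncation was chosen as
the simplest scheme consistent with the Itô interpretation; its bias is
acknowledged in the looser tolerance rather than hidden behind a
higher-order scheme.

For one-dimensional diffusions, `scale_fixation_probability()` computes
hitting probabilities through the scale function
$S(q)=\int \exp(-\int 2\mu/\sigma^2)$, with the inner integral accumulated
relative to the domain midpoint and the outer integrand exponentiated
after subtracting its maximum (log-domain stabilization), using adaptive
Gauss–Kronrod quadrature at $10^{-10}$ relative tolerance. Against the
logistic closed form of the constant-selection model the solver is
accurate to machine precision.

`cm_projected_model()` is the fast–slow (center-manifold) projection of
the two-type system onto the frequency-like coordinate
$q = x/(a(\beta-\gamma))$, a one-dimensional diffusion on $[0,1]$ whose
drift vanishes identically for neutral payoffs and loses its quadratic
term for frequency-independent payoffs ($a=b$, $c=d$).

**Initial-condition mapping.** `phi_constable_mckane()` must place a
general initial condition $(p, z)$ on the manifold. The default is the
frequency projection $q_0 = p$: the fast ecological relaxation
approximately conserves the slow variable, and on the manifold itself
($z = a(\beta-\gamma)$) the coordinate $q$ *is* the mutant frequency. The
alternative of reading the manifold coordinate off the unrelaxed state,
$q_0 = pz/(a(\beta-\gamma))$, is retained as `mapping = "manifold"`; it
agrees with the default exactly on the manifold but deteriorates sharply
off it (at $z = 0.75$ it clamps at $q_0=1$ for $p > 2/3$ and disagrees
with both the weak-selection curve and simulations by several tenths),
so it is not the default. With the frequency projection the projected
prediction and the weak-selection formula agree within 0.02 across the
tested coexistence/coordination grids — both approaches are least
trustworthy for starts far from the manifold, where neither mapping
represents the transient faithfully.

# Classical comparison formulas

For a frequency-independent dominant mutant ($a=b$, $c=d$) the model maps
onto classical logistic-growth settings via $s = 1/d - 1/b$ (selection
acts through competitive death rates), $r = \beta-\gamma$,
$K = (\beta-\gamma)aM$, birth rate $\beta$, and no neutral replacement
($\xi = 0$); the Kimura–Ohta effective-size factor is
$Q = KzM(s+r)/(sK+rzM)$. `phi_otto_whitlock()`, `phi_kimura_ohta()` and
`phi_uecker_hermisson()` evaluate the corresponding closed forms with
`expm1`/`log1p` arithmetic (the exponents are small at $s\sim 0.025$), and
the general-frequency branching form $1-(1-\varphi_1)^{pzM}$ allows real
exponents, reducing *exactly* to the single-mutant value at $p = 1/(zM)$.
The translated birth-rate symbol collides with the payoff $b$; it is
stored as `b_birth`.

These formulas carry their own validity regimes ($s>0$ always;
$Ms \gtrsim 10$ for the branching forms, versus $Ms < 1$ here), and the
package enforces only the hard constraint $s>0$. Measured against exact
simulation at the benchmark set ($c=d=0.975$, $M=100$): the
weak-selection value is closest to the simulated fixation probability,
the Otto–Whitlock and Kimura–Ohta values overshoot it, and the
Uecker–Hermisson value *undershoots* it — at this very weak selection the
branching regime does not apply. At $c=d=0.9$ ($Ms \approx 11$) the
branching value crosses to the expected overshoot of both the simulation
and the (there degrading) first-order formula; the test suite pins this
regime-dependence rather than a blanket ordering.

# Experiments, CLI and reproducibility

`run_experiment()` exposes ten preset parameter grids (`fig1` … `fig10`)
covering the amplitude-function table, symmetric and asymmetric
interior-equilibrium games, dominance games, the projected-diffusion
comparison, the literature benchmark, a sample trajectory, and
single-mutant sweeps over the initial population size. Presets whose
reference descriptions leave payoff values to a figure body use
representative choices recorded in the preset table. Default replication
is 10,000 runs per cell — a desk-scale choice whose confidence intervals
are about $\sqrt{10}$ wider than the 100,000-replicate reference curves;
`--n-runs` overrides it. Initial counts are
$X_0 = \mathrm{round}(pzM)$, $Y_0 = \mathrm{round}((1-p)zM)$, and the
realized counts are reported alongside each row. Output CSVs carry the
full spec, seed and package version as `#` comment headers; reruns with
identical configuration and seed are byte-identical.

The CLI (`inst/cli/lvfix.R`, or `run_cli()` programmatically) dispatches
the subcommands `simulate`, `estimate`, `phi`, `psi`, `compare` and
`experiment`; flat YAML config files supply model keys with CLI flags
taking precedence, and unknown keys or flags are errors, not guesses.

# What the tests do and do not show

The study conditions throughout are $\beta=0.6$, $\gamma=0.1$, $M=100$
(the scale where demographic fluctuations matter most and where the
approximation is designed to work). Simulation-based checks run 10,000
replicates (neutral fixation) and 20,000 replicates per cell (symmetric
games at $z=0.75$, $p\in\{0.2,0.5,0.8\}$), against a theory-vs-simulation
band of $\max(0.02,\,3\,\mathrm{SE})$; the measured worst gap is below
0.01. These sizes establish agreement at the stated band, not the
$10^{-3}$-level agreement that the 100,000-replicate reference curves
could resolve.

Known limitations worth restating: the first-order formula degrades
visibly once $|1-d/b| \gtrsim 0.1$ (flagged, clamped, but still reported);
the ψ solver refuses $M \gtrsim 1000$ rather than silently losing
accuracy; the projection mapping is unreliable far from the manifold; and
the fixed-$N$ intuition of the one-third rule does not transfer — in this
model the sign of the selection effect is governed by $b-d$ alone, not by
the location of the interior equilibrium.
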