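#' Reaction propensities of the eight-reaction system
#'
#' Returns the instantaneous rates of the four birth/death reactions and the
#' four pairwise competition reactions at a state `(X, Y)`:
#' `beta_X X`, `beta_Y Y`, `gamma_X X`, `gamma_Y Y`, `X(X-1)/(aM)`,
#' `XY/(bM)` (removes one X), `XY/(cM)` (removes one Y), `Y(Y-1)/(dM)`.
#' Intra-type competition counts distinct pairs (`X(X-1)`) by default; the
#' mass-action alternative `X^2` (differing by `O(X/M)`, vanishing in the
#' scaling limit) is available via `combinatorics = "naive"`.
#'
#' @param X,Y non-negative integer counts.
#' @param spec a `model_spec`.
#' @param combinatorics `"distinct"` (default, `X(X-1)`) or `"naive"`
#'   (`X^2`) intra-type pair counting.
#' @return Named numeric vector of the 8 propensities, in the order
#'   `birth_X, birth_Y, death_X, death_Y, comp_XX, comp_XY_bM, comp_XY_cM,
#'   comp_YY`.
#' @export
reaction_propensities <- function(X, Y, spec, combinatorics = c("distinct",
                                                                "naive")) {
  combinatorics <- match.arg(combinatorics)
  stopifnot(X >= 0, Y >= 0)
  XX <- if (combinatorics == "distinct") X * (X - 1) else X^2
  YY <- if (combinatorics == "distinct") Y * (Y - 1) else Y^2
  M <- spec$M
  c(birth_X = spec$beta_X * X,
    birth_Y = spec$beta_Y * Y,
    death_X = spec$gamma_X * X,
    death_Y = spec$gamma_Y * Y,
    comp_XX = max(XX, 0) / (spec$a * M),
    comp_XY_bM = X * Y / (spec$b * M),
    comp_XY_cM = X * Y / (spec$c * M),
    comp_YY = max(YY, 0) / (spec$d * M))
}

#' Simulate one trajectory to absorption (exact Gillespie)
#'
#' Runs the direct stochastic simulation algorithm: exponential waiting time
#' with the total propensity, categorical reaction choice proportional to
#' the propensities, until the mutant count X or the wild-type count Y hits
#' zero. Fixation of the mutant means the final state has `Y = 0, X > 0`.
#' Identical `(spec, X0, Y0, seed, stream)` give byte-identical trajectories
#' (the RNG is an embedded PCG32, independent of R's RNG state).
#'
#' @param spec a `model_spec`.
#' @param X0,Y0 initial counts, `X0 + Y0 > 0`.
#' @param seed master seed (non-negative integer).
#' @param stream RNG stream index (replicates use streams `1..n`).
#' @param max_events event budget; exceeding it yields `outcome = "timeout"`
#'   (never silently truncated into loss/fixation).
#' @param t_max optional wall-clock (model time) cap, `Inf` to disable.
#' @param record record the trajectory (`time, X, Y` per event).
#' @param thin with `record = TRUE`, keep every `thin`-th event (the
#'   absorption event is always kept).
#' @param combinatorics see [reaction_propensities()].
#' @param avg_window optional numeric `c(t0, t1)`: also return the
#'   waiting-time-weighted time average of X over that window.
#' @param stop_on_absorption stop at the first absorption (default). With
#'   `FALSE` the reaction system keeps running to `t_max`/`max_events`
#'   (useful for stationary statistics of a monomorphic population); the
#'   reported `outcome`/`t_abs` still refer to the first absorption.
#' @return A list (class `"absorption_record"`) with `outcome`
#'   (`"fixation"`, `"loss"` or `"timeout"`), `t_abs`, `n_events`, final
#'   `X`, `Y`, optionally `trajectory` (data frame) and `x_time_avg`.
#' @export
run_to_absorption <- function(spec, X0, Y0, seed = 1L, stream = 1L,
                              max_events = 1e7, t_max = Inf,
                              record = FALSE, thin = 1L,
                              combinatorics = c("distinct", "naive"),
                              avg_window = NULL, stop_on_absorption = TRUE) {
  combinatorics <- match.arg(combinatorics)
  stopifnot(X0 + Y0 > 0, X0 >= 0, Y0 >= 0,
            X0 == round(X0), Y0 == round(Y0))
  aw <- if (is.null(avg_window)) c(-1, -1) else avg_window
  res <- .ssa_run_cpp(unclass(spec), X0, Y0, seed, stream, max_events,
                      if (is.finite(t_max)) t_max else -1,
                      record, as.integer(thin),
                      combinatorics == "distinct", aw[1], aw[2],
                      stop_on_absorption)
  res$outcome <- c("loss", "fixation", "timeout")[res$outcome + 1L]
  class(res) <- "absorption_record"
  res
}

#' @export
print.absorption_record <- function(x, ...) {
  cat(sprintf("<absorption_record> %s at t = %.4g after %g events (X=%g, Y=%g)\n",
              x$outcome, x$t_abs, x$n_events, x$X, x$Y))
  invisible(x)
}

#' Wilson score confidence interval for a binomial proportion
#'
#' @param n_success,n number of successes and trials.
#' @param level confidence level.
#' @return Numeric `c(low, high)`.
#' @export
wilson_interval <- function(n_success, n, level = 0.95) {
  z <- stats::qnorm(1 - (1 - level) / 2)
  p <- n_success / n
  den <- 1 + z^2 / n
  ctr <- (p + z^2 / (2 * n)) / den
  hw <- z * sqrt(p * (1 - p) / n + z^2 / (4 * n^2)) / den
  c(low = max(0, ctr - hw), high = min(1, ctr + hw))
}

#' Monte Carlo estimate of the mutant fixation probability
#'
#' Runs `n_runs` independent replicates of [run_to_absorption()] (replicate
#' `i` uses RNG stream `i` of the master seed, so enlarging `n_runs` extends
#' rather than reshuffles the ensemble) and returns the fixation fraction
#' with a Wilson confidence interval. Timeouts are counted separately and
#' excluded from the estimate with a warning; a batch consisting only of
#' timeouts is an error.
#'
#' @inheritParams run_to_absorption
#' @param n_runs number of replicates (>= 1).
#' @param ci_level confidence level of the Wilson interval.
#' @return A list of class `"fixation_estimate"` with `n_runs`, `n_fixed`,
#'   `n_timeout`, `p_hat`, `ci` (`low`, `high`), `ci_level`, `seed`, `spec`,
#'   `x0`, `y0`.
#' @export
estimate_fixation_probability <- function(spec, X0, Y0, n_runs = 10000,
                                          seed = 1L, ci_level = 0.95,
                                          max_events = 1e7, t_max = Inf,
                                          combinatorics = c("distinct",
                                                            "naive")) {
  combinatorics <- match.arg(combinatorics)
  stopifnot(n_runs >= 1, X0 + Y0 > 0, X0 >= 0, Y0 >= 0)
  outcomes <- .ssa_batch_cpp(unclass(spec), X0, Y0, seed, as.integer(n_runs),
                             max_events,
                             if (is.finite(t_max)) t_max else -1,
                             combinatorics == "distinct")
  n_fixed <- sum(outcomes == 1L)
  n_timeout <- sum(outcomes == 2L)
  n_eff <- n_runs - n_timeout
  if (n_eff == 0) {
    stop("all replicates timed out; increase max_events/t_max", call. = FALSE)
  }
  if (n_timeout > 0) {
    warning(n_timeout, " replicates timed out and were excluded",
            call. = FALSE)
  }
  p_hat <- n_fixed / n_eff
  structure(list(n_runs = n_runs, n_fixed = n_fixed, n_timeout = n_timeout,
                 p_hat = p_hat,
                 ci = wilson_interval(n_fixed, n_eff, ci_level),
                 ci_level = ci_level, seed = seed,
                 spec = spec, x0 = X0, y0 = Y0),
            class = "fixation_estimate")
}

#' @export
print.fixation_estimate <- function(x, ...) {
  cat(sprintf(
    "<fixation_estimate> p_hat = %.4f [%.4f, %.4f] (%g%% Wilson), %d/%d fixed%s\n",
    x$p_hat, x$ci["low"], x$ci["high"], 100 * x$ci_level,
    x$n_fixed, x$n_runs,
    if (x$n_timeout > 0) sprintf(", %d timeouts", x$n_timeout) else ""))
  invisible(x)
}

#' Write a simulated trajectory as CSV
#'
#' Plain CSV with header `time,X,Y`, one row per (possibly thinned) event,
#' times printed with 9 significant digits.
#' @param rec an `absorption_record` with a recorded trajectory, or the
#'   trajectory data frame itself.
#' @param path output file.
#' @export
write_trajectory_csv <- function(rec, path) {
  tr <- if (is.data.frame(rec)) rec else rec$trajectory
  if (is.null(tr)) stop("no trajectory recorded; rerun with record = TRUE",
                        call. = FALSE)
  tr$time <- signif(tr$time, 9)
  utils::write.csv(tr, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Serialize a fixation estimate to JSON
#'
#' @param est a `fixation_estimate`.
#' @param path optional output file; if `NULL`, the JSON string is returned.
#' @export
fixation_estimate_json <- function(est, path = NULL) {
  obj <- list(params = unclass(est$spec), x0 = est$x0, y0 = est$y0,
              n_runs = est$n_runs, n_fixed = est$n_fixed,
              n_timeout = est$n_timeout, p_hat = est$p_hat,
              ci = as.list(est$ci), ci_level = est$ci_level,
              seed = est$seed, tool_version = lvfix_version())
  js <- jsonlite::toJSON(obj, auto_unbox = TRUE, digits = NA, pretty = TRUE)
  if (is.null(path)) return(js)
  writeLines(js, path)
  invisible(path)
}

#' Euler-Maruyama simulation of the diffusion approximation
#'
#' Simulates the Ito SDE approximation of the reaction system in the scaled
#' variables `x = X/M`, `y = Y/M`: drift `x((beta-gamma) - x/a - y/b)` and
#' noise `sqrt(x(beta+gamma+x/a+y/b)/M)` for x (resp. with `c`, `d` for y),
#' with independent Brownian motions. A coordinate that steps below 0 is set
#' to 0 and frozen (absorbing boundary).
#'
#' @param spec a `model_spec`.
#' @param x0,y0 initial scaled abundances (>= 0).
#' @param dt time step (default 1e-3).
#' @param t_end final time.
#' @param seed,stream RNG seed/stream (embedded PCG32).
#' @param thin keep every `thin`-th step in the returned path.
#' @return List with `path` (data frame `time, x, y`), `x_final`, `y_final`.
#' @export
simulate_sde <- function(spec, x0, y0, dt = 1e-3, t_end = 100,
                         seed = 1L, stream = 1L, thin = 1L) {
  stopifnot(dt > 0, x0 >= 0, y0 >= 0, t_end > 0)
  .sde_path_cpp(unclass(spec), x0, y0, dt, t_end, seed, stream,
                as.integer(thin))
}

#' Fixation frequency from Euler-Maruyama paths
#'
#' Companion to [estimate_fixation_probability()] at the SDE level: runs
#' `n_paths` independent Euler-Maruyama paths until one coordinate is
#' absorbed at 0 and returns the fraction fixing (y absorbed first).
#'
#' @inheritParams simulate_sde
#' @param n_paths number of independent paths.
#' @param ci_level Wilson interval level.
#' @return A `fixation_estimate` (timeouts are paths still polymorphic at
#'   `t_end`).
#' @export
estimate_fixation_sde <- function(spec, x0, y0, dt = 1e-3, t_end = 2000,
                                  n_paths = 5000, seed = 1L,
                                  ci_level = 0.95) {
  outcomes <- .sde_batch_cpp(unclass(spec), x0, y0, dt, t_end, seed,
                             as.integer(n_paths))
  n_fixed <- sum(outcomes == 1L)
  n_timeout <- sum(outcomes == 2L)
  n_eff <- n_paths - n_timeout
  if (n_eff == 0) stop("all SDE paths still polymorphic at t_end",
                       call. = FALSE)
  if (n_timeout > 0) {
    warning(n_timeout, " SDE paths unabsorbed at t_end, excluded",
            call. = FALSE)
  }
  structure(list(n_runs = n_paths, n_fixed = n_fixed, n_timeout = n_timeout,
                 p_hat = n_fixed / n_eff,
                 ci = wilson_interval(n_fixed, n_eff, ci_level),
                 ci_level = ci_level, seed = seed, spec = spec,
                 x0 = x0, y0 = y0),
            class = "fixation_estimate")
}
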