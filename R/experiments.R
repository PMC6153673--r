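#' Evaluate fixation-probability methods over (p, z) points
#'
#' Computes, for one model spec, any subset of the implemented predictions
#' and the Monte Carlo estimate on a set of initial conditions, returning
#' the standard comparison table with columns
#' `p, z, phi_weak, phi_cm, phi_ow, phi_ko, phi_uh, phi_sim,
#' phi_sim_ci_lo, phi_sim_ci_hi` (simulation columns present only when
#' `"sim"` is requested) plus the integer initial counts `x0`, `y0` used by
#' the simulator (`X0 = round(p z M)`, `Y0 = round((1-p) z M)`). A method
#' that fails for a cell (e.g. Otto-Whitlock for a deleterious mutant)
#' records `NA` there with a logged message and the run continues.
#'
#' @param spec a `model_spec`.
#' @param p,z initial fractions and scaled sizes (recycled to a common
#'   length).
#' @param methods subset of `c("weak", "cm", "ow", "ko", "uh", "sim")`.
#' @param n_runs simulation replicates per cell (when `"sim"` requested).
#' @param seed master seed; cell `i` uses seed `seed + i`.
#' @param psi optional pre-solved `psi_solution` for the weak-selection
#'   column.
#' @param quiet suppress per-cell failure messages.
#' @return Data frame in the comparison schema.
#' @export
compare_methods <- function(spec, p, z,
                            methods = c("weak", "cm", "ow", "ko", "uh"),
                            n_runs = 10000, seed = 1L, psi = NULL,
                            quiet = FALSE) {
  methods <- match.arg(methods, c("weak", "cm", "ow", "ko", "uh", "sim"),
                       several.ok = TRUE)
  n <- max(length(p), length(z))
  p <- rep_len(p, n); z <- rep_len(z, n)
  out <- data.frame(p = p, z = z)
  cell <- function(fun, label) {
    vapply(seq_len(n), function(i) {
      tryCatch(fun(i), error = function(e) {
        if (!quiet) message("cell (p=", p[i], ", z=", z[i], ") ", label,
                            ": ", conditionMessage(e))
        NA_real_
      })
    }, numeric(1))
  }
  if ("weak" %in% methods) {
    if (is.null(psi) && classify_game(spec) != "neutral") {
      psi <- tryCatch(
        solve_psi(spec, z_max = max(10 * spec$d *
                                      (spec_beta(spec) - spec_gamma(spec)),
                                    1.05 * max(z))),
        error = function(e) {
          if (!quiet) message("psi solve failed: ", conditionMessage(e))
          NULL
        })
    }
    out$phi_weak <- cell(function(i)
      phi_weak_selection(p[i], z[i], spec, psi = psi)$phi, "phi_weak")
  }
  if ("cm" %in% methods) {
    out$phi_cm <- cell(function(i)
      suppressWarnings(phi_constable_mckane(p[i], z[i], spec)), "phi_cm")
  }
  if ("ow" %in% methods) {
    out$phi_ow <- cell(function(i)
      suppressWarnings(phi_otto_whitlock(spec, z[i])), "phi_ow")
  }
  if ("ko" %in% methods) {
    out$phi_ko <- cell(function(i)
      suppressWarnings(phi_kimura_ohta(spec, z[i])), "phi_ko")
  }
  if ("uh" %in% methods) {
    out$phi_uh <- cell(function(i)
      suppressWarnings(phi_uecker_hermisson(spec, z[i], p[i])), "phi_uh")
  }
  X0 <- round(p * z * spec$M)
  Y0 <- round((1 - p) * z * spec$M)
  if ("sim" %in% methods) {
    sims <- lapply(seq_len(n), function(i) {
      tryCatch(estimate_fixation_probability(spec, X0[i], Y0[i],
                                             n_runs = n_runs,
                                             seed = seed + i),
               error = function(e) {
                 if (!quiet) message("cell (p=", p[i], ", z=", z[i],
                                     ") sim: ", conditionMessage(e))
                 NULL
               })
    })
    out$phi_sim <- vapply(sims, function(s)
      if (is.null(s)) NA_real_ else s$p_hat, numeric(1))
    out$phi_sim_ci_lo <- vapply(sims, function(s)
      if (is.null(s)) NA_real_ else unname(s$ci["low"]), numeric(1))
    out$phi_sim_ci_hi <- vapply(sims, function(s)
      if (is.null(s)) NA_real_ else unname(s$ci["high"]), numeric(1))
  }
  out$x0 <- X0
  out$y0 <- Y0
  out
}

#' Write a result table as CSV with metadata header
#'
#' Plain comma-separated table preceded by `#`-prefixed comment lines
#' recording the model spec, seed and tool version, so reruns are fully
#' identified by the file itself.
#'
#' @param df data frame.
#' @param path output file.
#' @param spec optional `model_spec` recorded in the header.
#' @param seed optional seed recorded in the header.
#' @param extra named character vector of extra metadata lines.
#' @export
write_result_csv <- function(df, path, spec = NULL, seed = NULL,
                             extra = NULL) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(paste0("# lvfix ", lvfix_version()), con)
  if (!is.null(spec)) {
    writeLines(paste0("# spec: ",
                      paste(names(unclass(spec)), unlist(unclass(spec)),
                            sep = "=", collapse = " ")), con)
  }
  if (!is.null(seed)) writeLines(paste0("# seed: ", seed), con)
  for (nm in names(extra)) {
    writeLines(paste0("# ", nm, ": ", extra[[nm]]), con)
  }
  utils::write.csv(df, con, row.names = FALSE, quote = FALSE)
  invisible(path)
}

# Figure-style experiment presets. Caption-printed parameters are verbatim;
# payoff values the captions leave to the figure body ("as given in the
# figure") use the representative choices listed here.
experiment_presets_def <- function() {
  base <- list(beta = 0.6, gamma = 0.1, M = 100)
  p_sweep <- seq(0.1, 0.9, by = 0.1)
  z_sweep <- seq(0.25, 2, by = 0.25)
  list(
    fig1 = list(kind = "psi",
                specs = list(list(a = 1, b = 1, c = 1, d = 1)),
                z = seq(0.05, 5, by = 0.05), methods = character(),
                note = "amplitude function psi(z), internal regime"),
    fig2 = list(kind = "phi",
                specs = list(list(a = 1, b = 0.9, c = 0.9, d = 1),
                             list(a = 1, b = 1.1, c = 1.1, d = 1)),
                p = p_sweep, z = 0.75, methods = c("weak", "sim"),
                note = "symmetric coexistence/coordination vs neutral"),
    fig3 = list(kind = "phi",
                specs = list(list(a = 1, b = 1.1, c = 1.05, d = 1),
                             list(a = 1, b = 0.9, c = 0.95, d = 1)),
                p = p_sweep, z = 0.75, methods = c("weak", "sim"),
                note = "asymmetric games (representative b, c)"),
    fig4 = list(kind = "phi",
                specs = list(list(a = 1, b = 1, c = 0.975, d = 0.975),
                             list(a = 1, b = 1, c = 1.025, d = 1.025)),
                p = p_sweep, z = 0.5, methods = c("weak", "sim"),
                note = "dominance games (representative c = d)"),
    fig5 = list(kind = "phi",
                specs = list(list(a = 1, b = 1, c = 0.975, d = 0.975)),
                p = NULL, z = z_sweep,
                methods = c("weak", "ow", "ko", "uh", "sim"),
                single_mutant = TRUE,
                note = "single mutant, literature comparisons"),
    fig6 = list(kind = "trajectory",
                specs = list(list(a = 1, b = 1.1, c = 1.1, d = 1)),
                X0 = 100, Y0 = 100, t_max = 100,
                methods = character(),
                note = "sample path, coexistence game (representative payoffs)"),
    fig7 = list(kind = "phi",
                specs = list(list(a = 1, b = 0.9, c = 0.9, d = 1),
                             list(a = 1, b = 1.1, c = 1.1, d = 1)),
                p = p_sweep, z = c(0.2, 0.75),
                methods = c("weak", "cm", "sim"),
                note = "weak-selection vs projected diffusion"),
    fig8 = list(kind = "phi",
                specs = list(list(a = 1, b = 1, c = 0.975, d = 0.975)),
                p = p_sweep, z = 0.1,
                methods = c("weak", "cm", "uh", "sim"),
                note = "dominance, off-manifold start (representative c = d)"),
    fig9 = list(kind = "phi",
                specs = list(list(a = 1, b = 0.9, c = 0.9, d = 1),
                             list(a = 1, b = 1.1, c = 1.1, d = 1)),
                p = NULL, z = z_sweep, methods = c("weak", "sim"),
                single_mutant = TRUE,
                note = "single mutant under varying initial size"),
    fig10 = list(kind = "phi",
                 specs = c(
                   lapply(c(0.95, 1.0, 1.05, 1.1), function(cv)
                     list(a = 1, b = 1.1, c = cv, d = 1)),
                   lapply(c(0.95, 1.0, 1.05, 1.1), function(bv)
                     list(a = 1, b = bv, c = 1.1, d = 1))),
                 p = NULL, z = 0.75, methods = "weak",
                 single_mutant = TRUE,
                 note = "phi depends on b and d, not on c")
  ) |> lapply(function(pr) { pr$base <- base; pr$n_runs <- 10000; pr })
}

#' List the available experiment presets
#'
#' Preset parameter grids mirror the package's reference figures: symmetric
#' and asymmetric interior-equilibrium games, dominance games, single-mutant
#' sweeps over the initial population size, and the literature comparison
#' set. Default replication is 10,000 runs per cell (a desk-scale stand-in
#' for the 100,000 used for the reference curves; confidence intervals are
#' about sqrt(10) wider).
#'
#' @return Named list of preset definitions.
#' @export
experiment_presets <- function() experiment_presets_def()

#' Run a preset experiment
#'
#' Evaluates the preset's analytic methods (and optionally the stochastic
#' simulation) over its parameter grid and returns (and optionally writes)
#' the comparison-schema table. Deterministic under a fixed seed.
#'
#' @param name preset name (`fig1` ... `fig10`).
#' @param n_runs override the preset's replication per cell.
#' @param seed master seed.
#' @param sim include the Monte Carlo column where the preset defines it.
#' @param out optional CSV output path (written with metadata header).
#' @param quiet suppress per-cell failure messages.
#' @return Data frame (with a `game` column identifying the payoff set).
#' @export
run_experiment <- function(name, n_runs = NULL, seed = 1L, sim = FALSE,
                           out = NULL, quiet = FALSE) {
  presets <- experiment_presets_def()
  if (!name %in% names(presets)) {
    stop("unknown preset '", name, "'; available: ",
         paste(names(presets), collapse = ", "), call. = FALSE)
  }
  pr <- presets[[name]]
  if (is.null(n_runs)) n_runs <- pr$n_runs
  mk <- function(pp) do.call(model_spec, c(pp, pr$base))
  if (pr$kind == "psi") {
    spec <- mk(pr$specs[[1]])
    psi <- solve_psi(spec, regime = "internal",
                     z_max = max(pr$z) * 1.0001)
    df <- data.frame(z = pr$z, psi = psi_eval(psi, pr$z))
    if (!is.null(out)) write_result_csv(df, out, spec = spec, seed = seed)
    return(df)
  }
  if (pr$kind == "trajectory") {
    spec <- mk(pr$specs[[1]])
    rec <- run_to_absorption(spec, pr$X0, pr$Y0, seed = seed,
                             t_max = pr$t_max, record = TRUE)
    df <- rec$trajectory
    if (!is.null(out)) write_result_csv(df, out, spec = spec, seed = seed)
    return(df)
  }
  methods <- pr$methods
  if (!sim) methods <- setdiff(methods, "sim")
  tabs <- lapply(seq_along(pr$specs), function(k) {
    spec <- mk(pr$specs[[k]])
    zz <- pr$z
    pp <- if (isTRUE(pr$single_mutant)) 1 / (zz * spec$M) else pr$p
    grid <- expand.grid(p = pp, z = zz)
    if (isTRUE(pr$single_mutant)) {
      grid <- data.frame(p = 1 / (zz * spec$M), z = zz)
    }
    df <- compare_methods(spec, grid$p, grid$z, methods = methods,
                          n_runs = n_runs, seed = seed + 1000 * k,
                          quiet = quiet)
    # semicolon-separated so the label survives inside a CSV cell
    df$game <- sprintf("a=%g;b=%g;c=%g;d=%g", spec$a, spec$b, spec$c,
                       spec$d)
    df
  })
  df <- do.call(rbind, tabs)
  if (!is.null(out)) {
    write_result_csv(df, out, spec = NULL, seed = seed,
                     extra = c(preset = name, note = pr$note,
                               n_runs = n_runs))
  }
  df
}
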