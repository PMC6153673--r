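test_that("model validation enforces the type invariants", {
  expect_s3_class(spec_neutral(), "model_spec")
  expect_error(model_spec(a = 0), "nonpositive payoff")
  expect_error(model_spec(a = -1), "nonpositive payoff")
  expect_error(model_spec(beta = -0.5), "rates")
  expect_error(model_spec(M = 0), "M must be")
  expect_warning(model_spec(beta = 0.1, gamma = 0.6), "non-viable")
  uneq <- model_spec(beta_X = 0.6, beta_Y = 0.7, gamma = 0.1)
  expect_error(validate_model(uneq, weak_selection = TRUE),
               class = "lvfix_unequal_rates")
  expect_error(
    validate_model(suppressWarnings(model_spec(beta = 0.1, gamma = 0.6)),
                   weak_selection = TRUE),
    "viable")
})

test_that("game classification follows the payoff orderings", {
  expect_identical(classify_game(spec_coex(1.1)), "coexistence")
  expect_identical(classify_game(spec_coord(0.9)), "coordination")
  expect_identical(classify_game(spec_dom(0.975)), "dominance_mutant")
  expect_identical(classify_game(spec_neutral()), "neutral")
  expect_identical(
    classify_game(model_spec(a = 0.975, b = 0.975, c = 1, d = 1)),
    "dominance_wildtype")
  # boundary ties go to the dominance classes
  expect_identical(classify_game(model_spec(a = 1, b = 1.1, c = 1, d = 1)),
                   "dominance_mutant")
  expect_identical(classify_game(model_spec(a = 1, b = 0.9, c = 1, d = 1)),
                   "dominance_wildtype")
})

test_that("label swap (a,b,c,d) -> (d,c,b,a) exchanges the type roles", {
  swap <- function(s) model_spec(a = s$d, b = s$c, c = s$b, d = s$a,
                                 beta = s$beta_X, gamma = s$gamma_X,
                                 M = s$M)
  cases <- list(spec_coex(1.1), spec_coord(0.9), spec_dom(0.975),
                model_spec(a = 1, b = 1.1, c = 1.05, d = 1),
                model_spec(a = 0.95, b = 0.9, c = 1.02, d = 1.01))
  map <- c(coexistence = "coexistence", coordination = "coordination",
           dominance_mutant = "dominance_wildtype",
           dominance_wildtype = "dominance_mutant", neutral = "neutral")
  for (s in cases) {
    expect_identical(classify_game(swap(s)),
                     unname(map[classify_game(s)]))
  }
})

test_that("interior fixed point matches the closed formulas and the ODE", {
  # symmetric games sit exactly at one half
  expect_identical(internal_fixed_point(spec_coord(0.9))$p_star, 0.5)
  expect_identical(internal_fixed_point(spec_coex(1.1))$p_star, 0.5)
  expect_error(internal_fixed_point(spec_neutral()), "no interior")
  expect_error(internal_fixed_point(spec_dom()), "no interior")

  sp <- model_spec(a = 1, b = 1.1, c = 1.05, d = 1,
                   beta = 0.6, gamma = 0.1, M = 100)
  fp <- internal_fixed_point(sp)
  # a root of the deterministic right-hand side (scaled units)
  expect_lt(max(abs(deterministic_rhs(fp$X_star, fp$Y_star, sp))) / sp$M,
            1e-9)
  # independent 2-D Newton oracle
  nt <- newton_fixed_point(sp)
  expect_equal(c(fp$X_star, fp$Y_star), nt, tolerance = 1e-8)
  expect_equal(fp$p_star, fp$X_star / (fp$X_star + fp$Y_star),
               tolerance = 1e-12)
})

test_that("p* is homogeneous of degree zero in the payoffs", {
  set.seed(71)
  for (i in 1:10) {
    sp <- random_interior_spec(coexistence = i %% 2 == 0)
    kappa <- runif(1, 0.2, 5)
    sp2 <- model_spec(a = kappa * sp$a, b = kappa * sp$b, c = kappa * sp$c,
                      d = kappa * sp$d, beta = 0.6, gamma = 0.1, M = 100)
    expect_equal(internal_fixed_point(sp2)$p_star,
                 internal_fixed_point(sp)$p_star, tolerance = 1e-12)
  }
})

test_that("deterministic right-hand side has the stated zeros", {
  sp <- spec_neutral()
  expect_identical(unname(deterministic_rhs(0, 40, sp)[1]), 0)
  # monomorphic equilibrium X = a(beta-gamma)M
  expect_equal(unname(deterministic_rhs(50, 0, sp)[1]), 0, tolerance = 1e-12)
})

test_that("deterministic integration converges to the attractors", {
  sp <- spec_coex(1.1)
  fp <- internal_fixed_point(sp)
  tr <- integrate_deterministic(sp, 20, 70, t_end = 1000)
  n <- nrow(tr)
  expect_lt(abs(tr$X[n] - fp$X_star), 1e-6 * sp$M)
  expect_lt(abs(tr$Y[n] - fp$Y_star), 1e-6 * sp$M)
  # starting on the fixed point stays there
  tr2 <- integrate_deterministic(sp, fp$X_star, fp$Y_star, t_end = 50)
  expect_lt(max(abs(tr2$X - fp$X_star)), 1e-5)
  # single-type reduction follows the closed-form logistic solution
  spn <- spec_neutral()
  K <- 1 * (0.6 - 0.1) * 100
  r <- 0.5
  tr3 <- integrate_deterministic(spn, 5, 0, t_end = 30)
  logistic <- K / (1 + (K - 5) / 5 * exp(-r * tr3$time))
  expect_equal(tr3$X, logistic, tolerance = 1e-6)
  expect_true(all(tr3$Y == 0))
})

test_that("scaled coordinates satisfy p z = x and (1-p) z = y", {
  st <- scaled_state(30, 45, spec_neutral())
  expect_equal(st$p * st$z, st$x, tolerance = 1e-15)
  expect_equal((1 - st$p) * st$z, st$y, tolerance = 1e-15)
  expect_equal(st$z, 0.75)
})

test_that("weak-selection condition magnitudes are as defined", {
  expect_true(all(weak_selection_diagnostics(spec_neutral())
                  [c("cond_i", "cond_ii", "cond_iii")] == 0))
  d <- weak_selection_diagnostics(spec_coex(1.1))
  expect_equal(unname(d["cond_i"]), (1 - 1 / 1.1)^2, tolerance = 1e-14)
  # symmetric game: 1/p* = 2 so cond_iv vanishes
  expect_equal(unname(d["cond_iv"]), 0, tolerance = 1e-14)
  dd <- weak_selection_diagnostics(spec_dom(0.975))
  expect_true(is.na(dd["cond_iv"]))
  expect_true(is.finite(dd["cond_v"]) && dd["cond_v"] < 0.1)
  expect_true(is.na(weak_selection_diagnostics(spec_neutral())["cond_v"]))
  expect_false(weak_selection_violated(spec_coex(1.1)))
  expect_true(weak_selection_violated(spec_coex(1.8)))
})
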