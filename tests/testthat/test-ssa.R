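test_that("propensities implement the eight reaction rates", {
  sp <- spec_neutral()
  w0 <- reaction_propensities(0, 40, sp)
  expect_true(all(w0[c("birth_X", "death_X", "comp_XX", "comp_XY_bM",
                       "comp_XY_cM")] == 0))
  expect_equal(unname(w0["birth_Y"]), 0.6 * 40)
  # a single individual has no intra-type pair
  expect_identical(unname(reaction_propensities(1, 0, sp)["comp_XX"]), 0)
  # full vector by hand at (X=10, Y=5), neutral payoffs, M=100
  w <- reaction_propensities(10, 5, sp)
  expect_equal(unname(w),
               c(6.0, 3.0, 1.0, 0.5, 10 * 9 / 100, 50 / 100, 50 / 100,
                 5 * 4 / 100),
               tolerance = 1e-15)
  # naive mass-action variant uses X^2
  wn <- reaction_propensities(10, 5, sp, combinatorics = "naive")
  expect_equal(unname(wn["comp_XX"]), 1.0)
})

test_that("absorption at the start is reported as such", {
  sp <- spec_neutral()
  r0 <- run_to_absorption(sp, 0, 10, seed = 1)
  expect_identical(r0$outcome, "loss")
  expect_identical(r0$t_abs, 0)
  expect_identical(r0$n_events, 0)
  r1 <- run_to_absorption(sp, 10, 0, seed = 1)
  expect_identical(r1$outcome, "fixation")
  expect_identical(r1$n_events, 0)
  expect_error(run_to_absorption(sp, 0, 0, seed = 1))
})

test_that("identical seeds give identical trajectories, streams differ", {
  sp <- spec_coex(1.1)
  r1 <- run_to_absorption(sp, 20, 20, seed = 42, record = TRUE)
  r2 <- run_to_absorption(sp, 20, 20, seed = 42, record = TRUE)
  expect_identical(r1$trajectory, r2$trajectory)
  expect_identical(r1$outcome, r2$outcome)
  r3 <- run_to_absorption(sp, 20, 20, seed = 42, stream = 2, record = TRUE)
  expect_false(isTRUE(all.equal(r1$trajectory$time, r3$trajectory$time)))
})

test_that("every event moves one individual and absorption is one-sided", {
  sp <- spec_coord(0.9)
  r <- run_to_absorption(sp, 15, 15, seed = 7, record = TRUE)
  tr <- r$trajectory
  dX <- diff(tr$X); dY <- diff(tr$Y)
  expect_true(all(abs(dX) + abs(dY) == 1))
  expect_true(all(diff(tr$time) > 0))
  expect_true(all(tr$X >= 0 & tr$Y >= 0))
  expect_false(any(tr$X == 0 & tr$Y == 0))
  n <- nrow(tr)
  expect_true(xor(tr$X[n] == 0, tr$Y[n] == 0))
})

test_that("event budget exhaustion is reported as timeout", {
  sp <- spec_neutral()
  r <- run_to_absorption(sp, 25, 25, seed = 3, max_events = 10)
  expect_identical(r$outcome, "timeout")
  expect_identical(r$n_events, 10)
  # a batch that can never absorb raises rather than reporting nonsense
  expect_error(
    suppressWarnings(
      estimate_fixation_probability(sp, 25, 25, n_runs = 20, seed = 3,
                                    max_events = 10)),
    "timed out")
})

test_that("absorption is effectively always reached for viable rates", {
  sp <- spec_neutral()
  outcomes <- vapply(1:1000, function(i)
    run_to_absorption(sp, 25, 25, seed = 1234, stream = i,
                      max_events = 1e7)$outcome, character(1))
  expect_identical(sum(outcomes == "timeout"), 0L)
})

test_that("the neutral estimator is consistent with p0 = X0/(X0+Y0)", {
  sp <- spec_neutral()
  est <- estimate_fixation_probability(sp, 20, 60, n_runs = 10000,
                                       seed = 2024)
  p0 <- 0.25
  se <- sqrt(p0 * (1 - p0) / est$n_runs)
  expect_lt(abs(est$p_hat - p0), 3 * se)
  expect_true(est$ci["low"] <= est$p_hat && est$p_hat <= est$ci["high"])
  # X0 = 0 fixes nothing, exactly
  expect_identical(estimate_fixation_probability(sp, 0, 10, n_runs = 50,
                                                 seed = 1)$p_hat, 0)
})

test_that("monomorphic runs fluctuate around the carrying capacity", {
  sp <- spec_neutral()
  means <- vapply(1:16, function(i)
    run_to_absorption(sp, 50, 0, seed = 88, stream = i, t_max = 1100,
                      avg_window = c(100, 1100),
                      stop_on_absorption = FALSE)$x_time_avg, numeric(1))
  se <- sd(means) / sqrt(length(means))
  expect_lt(abs(mean(means) - 50), 3 * se + 1e-9)
})

test_that("coexistence games lift fixation above neutral for p below 1/2", {
  sp <- spec_coex(1.1)
  est <- estimate_fixation_probability(sp, 25, 50, n_runs = 20000,
                                       seed = 99)
  expect_gt(est$ci["low"], 25 / 75)
})

test_that("trajectory CSV and estimate JSON round-trip", {
  sp <- spec_neutral()
  r <- run_to_absorption(sp, 10, 10, seed = 5, record = TRUE)
  f <- tempfile(fileext = ".csv")
  write_trajectory_csv(r, f)
  back <- read.csv(f)
  expect_identical(names(back), c("time", "X", "Y"))
  expect_identical(nrow(back), nrow(r$trajectory))
  expect_equal(back$X, r$trajectory$X)

  est <- estimate_fixation_probability(sp, 10, 10, n_runs = 100, seed = 5)
  js <- jsonlite::fromJSON(fixation_estimate_json(est))
  expect_equal(js$p_hat, est$p_hat)
  expect_equal(js$n_runs, est$n_runs)
  expect_equal(js$x0, 10)
  expect_true(js$ci$low <= js$p_hat && js$p_hat <= js$ci$high)
  expect_true(nzchar(js$tool_version))
})

test_that("run_past-absorption mode keeps simulating the survivor", {
  sp <- spec_neutral()
  r <- run_to_absorption(sp, 25, 25, seed = 17, t_max = 300,
                         stop_on_absorption = FALSE, record = TRUE)
  expect_true(r$outcome %in% c("fixation", "loss"))
  expect_gt(max(r$trajectory$time), r$t_abs)
})
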