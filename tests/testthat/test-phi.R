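test_that("neutral payoffs reproduce phi = p for all initial conditions", {
  sp <- spec_neutral()
  p <- seq(0, 1, by = 0.1)
  res <- phi_weak_selection(p, 0.75, sp)
  expect_identical(res$regime, "neutral")
  expect_equal(res$phi, p, tolerance = 1e-15)
  expect_identical(res$selection, 0)
})

test_that("the fixation probability equals p* at the interior equilibrium", {
  set.seed(303)
  for (i in 1:6) {
    sp <- random_interior_spec(coexistence = i %% 2 == 0)
    psi <- solve_psi(sp, n_grid = 400)
    p_star <- internal_fixed_point(sp)$p_star
    res <- phi_weak_selection(p_star, c(0.3, 0.75, 1.5), sp, psi = psi)
    expect_equal(res$phi, rep(p_star, 3), tolerance = 1e-13)
  }
})

test_that("boundaries are exact and clamping reports breakdown honestly", {
  sp <- spec_coex(1.1)
  psi <- cached_psi(sp, regime = "internal")
  res <- phi_weak_selection(c(0, 1), 0.75, sp, psi = psi)
  expect_identical(res$phi, c(0, 1))
  # immoderate selection: flag raised, clamped value still a probability
  strong <- spec_coord(0.5)
  ress <- phi_weak_selection(seq(0.05, 0.95, by = 0.05), 0.75, strong)
  expect_true(ress$conditions_violated)
  expect_true(all(ress$phi >= 0 & ress$phi <= 1))
  expect_true(any(ress$raw != ress$phi))
})

test_that("symmetric games reduce to the (1 - 2p) form", {
  sp <- spec_coex(1.1)   # a = d, b = c so p* = 1/2
  psi <- cached_psi(sp, regime = "internal")
  p <- seq(0.05, 0.95, by = 0.05)
  general <- phi_weak_selection(p, 0.75, sp, psi = psi)$raw
  s <- 1 - 1 / 1.1
  symmetric <- p + p * (1 - p) * (1 - 2 * p) * s * psi_eval(psi, 0.75)
  expect_equal(general, symmetric, tolerance = 1e-14)
})

test_that("dominance games use the p*-free first-order term", {
  sp <- spec_dom(0.975)
  psi <- cached_psi(sp, regime = "dominance")
  p <- c(0.1, 0.4, 0.8)
  res <- phi_weak_selection(p, 0.5, sp, psi = psi)
  expect_identical(res$regime, "dominance")
  s <- 1 - 0.975 / 1
  expect_equal(res$raw,
               p + p * (1 - p) * s * psi_eval(psi, 0.5),
               tolerance = 1e-14)
  # the mutant is favored at every frequency
  expect_true(all(res$raw > p))
})

test_that("a psi solved for the wrong regime is rejected", {
  psi_dom <- cached_psi(spec_dom(0.975), regime = "dominance")
  expect_error(phi_weak_selection(0.3, 0.5, spec_coex(1.1), psi = psi_dom),
               "regime")
})

test_that("near-equilibrium expansion matches the first-order formula", {
  sp <- spec_coex(1.1)
  psi <- cached_psi(sp, regime = "internal")
  p_star <- internal_fixed_point(sp)$p_star
  expect_equal(phi_near_equilibrium(0, 0.75, sp, psi = psi), p_star,
               tolerance = 1e-15)
  eps <- c(-0.15, -0.05, 0.05, 0.15)
  near <- phi_near_equilibrium(eps, 0.75, sp, psi = psi)
  direct <- phi_weak_selection(p_star + eps, 0.75, sp, psi = psi)$raw
  expect_equal(near, direct, tolerance = 1e-13)
  # stable equilibrium (b > d): above-p* starts fix less than neutral
  expect_lt(near[3], p_star + 0.05)
  # unstable equilibrium (b < d): above-p* starts fix more than neutral
  spc <- spec_coord(0.9)
  psic <- cached_psi(spc, regime = "internal")
  expect_gt(phi_near_equilibrium(0.05, 0.75, spc, psi = psic), 0.55)
  expect_error(phi_near_equilibrium(0.05, 0.75, spec_dom(0.975)),
               "interior")
})

test_that("the generator annihilates constants and the neutral solution", {
  sp <- spec_neutral()
  pg <- seq(0.1, 0.9, length.out = 21)
  zg <- seq(0.2, 1.5, length.out = 21)
  const <- matrix(0.4, 21, 21)
  expect_lt(max(abs(generator_apply(const, pg, zg, sp))), 1e-12)
  lin <- matrix(pg, 21, 21)
  expect_lt(max(abs(generator_apply(lin, pg, zg, sp))), 1e-11)
  expect_error(generator_apply(matrix(1, 2, 2), pg[1:2], zg[1:2], sp),
               "coarse")
  expect_error(generator_apply(const, pg, zg, spec_dom(0.975)),
               "dominance")
})

test_that("the generator residual of the first-order surface is second
           order in the selection strength", {
  resmax <- function(bb) {
    sp <- model_spec(a = 1, b = bb, c = bb, d = 1, beta = 0.6,
                     gamma = 0.1, M = 100)
    psi <- cached_psi(sp, regime = "internal")
    zi <- psi$z_grid[psi$z_grid >= 0.2 & psi$z_grid <= 2]
    pg <- seq(0.05, 0.95, length.out = 61)
    surf <- weak_selection_surface(pg, zi, sp, psi = psi)
    max(abs(generator_apply(surf, pg, zi, sp)))
  }
  ratio <- resmax(1.04) / resmax(1.02)
  expect_gt(ratio, 3)
  expect_lt(ratio, 5)
})

test_that("fixation rises above neutral iff b exceeds d (payoff sweep)", {
  psi_int <- cached_psi(spec_neutral(), regime = "internal")
  psi_dom <- cached_psi(spec_neutral(), regime = "dominance")  # d = 1
  z <- 0.75
  for (a in c(0.9, 1.0, 1.1)) for (cc in c(0.9, 1.0, 1.1))
    for (b in c(0.95, 1.05)) {
      sp <- model_spec(a = a, b = b, c = cc, d = 1, beta = 0.6,
                       gamma = 0.1, M = 100)
      cls <- classify_game(sp)
      interior <- cls %in% c("coexistence", "coordination")
      psi <- if (interior) psi_int else psi_dom
      p <- seq(0.05, 0.95, by = 0.1)
      if (interior) p <- p[p < internal_fixed_point(sp)$p_star]
      res <- phi_weak_selection(p, z, sp, psi = psi)
      expect_true(all(sign(res$raw - p) == sign(b - 1)),
                  label = sprintf("sign at a=%g c=%g b=%g", a, cc, b))
      if (interior) {
        # fixation probability increases with the payoff a
        sp2 <- model_spec(a = a + 1e-4, b = b, c = cc, d = 1, beta = 0.6,
                          gamma = 0.1, M = 100)
        if (classify_game(sp2) == cls) {
          res2 <- phi_weak_selection(p, z, sp2, psi = psi)
          expect_true(all(res2$raw > res$raw),
                      label = sprintf("dphi/da at a=%g c=%g b=%g", a, cc, b))
        }
      }
    }
})
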