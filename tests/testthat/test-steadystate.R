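# Steady-state flux balance: the quadratic root, the full steady-state
# solution and the two asymptotic regimes.

test_that("fixation rate follows Michaelis-Menten kinetics", {
  expect_equal(fixation_rate(44, vmax = 1, k = 44), 0.5)
  expect_identical(fixation_rate(0, vmax = 7, k = 44), 0)
  expect_equal(fixation_rate(16.93, vmax = 1, k = 44), 0.2778,
               tolerance = 1e-3)
  expect_error(fixation_rate(-1), class = "diatomccm_error")
})

test_that("steady-state plastid CO2 matches the hand-solved quadratic", {
  # b = 44 + 44 - 64.59 = 23.41; sqrt(b^2 + 4*44*64.59) = 109.16
  expect_equal(steady_state_co2p(64.59, vmax_over_d = 44, k = 44),
               42.87, tolerance = 0.05 / 42.87)
  # no fixation: plastid equilibrates with the middle space
  expect_equal(steady_state_co2p(c(0, 17, 870), vmax = 0, d = 2),
               c(0, 17, 870))
  # overwhelming uptake draws the plastid down to ~0
  expect_lt(steady_state_co2p(100, vmax_over_d = 1e6, k = 44), 0.01)
})

test_that("D = 0 is a documented limit, not a division error", {
  expect_identical(steady_state_co2p(100, vmax = 1, d = 0), 0)
  expect_identical(steady_state_co2p(100, vmax = 0, d = 0), 100)
  ss <- solve_steady_state(co2_m = 100, vmax = 1, d = 0)
  expect_identical(ss$co2_p, 0)
  expect_identical(ss$vcfix, 0)
  expect_identical(ss$diffusive_flux, 0)
})

test_that("kinetics are accepted as a (vmax, d) pair or the ratio alone", {
  co2_m <- c(5, 64.59, 410)
  via_ratio <- steady_state_co2p(co2_m, vmax_over_d = 44)
  via_pair <- steady_state_co2p(co2_m, vmax = 88, d = 2)
  expect_equal(via_ratio, via_pair, tolerance = 1e-12)
  expect_error(steady_state_co2p(1, vmax = 1, d = 1, vmax_over_d = 1),
               class = "diatomccm_error")
  expect_error(steady_state_co2p(1, vmax = 1), class = "diatomccm_error")
  expect_error(steady_state_co2p(-1, vmax_over_d = 1),
               class = "diatomccm_error")
})

test_that("the root satisfies its quadratic and stays in [0, co2_m]", {
  draws <- draw_params(1000, seed = 7)
  co2_p <- steady_state_co2p(draws$co2_m, vmax_over_d = draws$vmax_over_d,
                             k = draws$k)
  expect_true(all(co2_p >= 0 & co2_p <= draws$co2_m))
  b <- draws$vmax_over_d + draws$k - draws$co2_m
  residual <- co2_p^2 + b * co2_p - draws$k * draws$co2_m
  expect_true(all(abs(residual) <= 1e-9 * pmax(1, draws$co2_m^2)))
  # the rejected root is negative whenever co2_m > 0
  rejected <- (-b - sqrt(b^2 + 4 * draws$k * draws$co2_m)) / 2
  expect_true(all(rejected < 0))
})

test_that("the stable root form keeps accuracy at extreme Vmax/D", {
  # cancellation-free identity: co2_p * (co2_p + b) = k * co2_m
  for (ratio in c(1e6, 1e9, 1e12)) {
    co2_p <- steady_state_co2p(100, vmax_over_d = ratio, k = 44)
    expect_gt(co2_p, 0)
    b <- ratio + 44 - 100
    expect_equal(co2_p * (co2_p + b), 44 * 100, tolerance = 1e-12)
  }
})

test_that("fixation equals diffusive influx at steady state", {
  draws <- draw_params(1000, seed = 11)
  ss <- solve_steady_state(co2_m = draws$co2_m,
                           vmax_over_d = draws$vmax_over_d, k = draws$k)
  expect_equal(ss$vcfix, ss$diffusive_flux, tolerance = 1e-9)
  expect_equal(
    solve_steady_state(co2_m = 64.59, vmax = 44, d = 1, k = 44)$vcfix,
    21.72, tolerance = 1e-3
  )
  zero <- solve_steady_state(co2_m = 0, vmax = 3, d = 1)
  expect_identical(zero$co2_p, 0)
  expect_identical(zero$vcfix, 0)
})

test_that("steady state is monotone in each parameter", {
  base <- list(co2_m = 64.59, ratio = 44, k = 44)
  grid <- seq(0.2, 5, by = 0.2)
  vc <- function(co2_m = base$co2_m, ratio = base$ratio, k = base$k) {
    solve_steady_state(co2_m = co2_m, vmax_over_d = ratio, k = k)$vcfix
  }
  expect_true(all(diff(vc(co2_m = base$co2_m * grid)) > 0))
  expect_true(all(diff(vc(ratio = base$ratio * grid)) > 0))
  expect_true(all(diff(vc(k = base$k * grid)) < 0))
  # vcfix non-decreasing in D at fixed vmax; co2_p non-increasing in vmax
  vc_d <- vapply(grid, function(s) {
    solve_steady_state(co2_m = 64.59, vmax = 44, d = s, k = 44)$vcfix
  }, numeric(1))
  expect_true(all(diff(vc_d) > 0))
  co2p_v <- steady_state_co2p(64.59, vmax = 44 * grid, d = 1, k = 44)
  expect_true(all(diff(co2p_v) < 0))
})

test_that("asymptotic limits bound and approximate the exact solution", {
  expect_equal(vcfix_uptake_limit(44, vmax = 3, k = 44), 1.5)
  expect_equal(vcfix_uptake_limit(16.93, vmax = 1, k = 44), 0.2778,
               tolerance = 1e-3)
  expect_identical(vcfix_diffusion_limit(0, d = 5), 0)
  expect_equal(vcfix_diffusion_limit(64.59, d = 1), 64.59)

  co2_m <- c(17, 64.59, 410, 870)
  # Vmax << D: plastid tracks the middle space
  low <- solve_steady_state(co2_m = co2_m, vmax_over_d = 1e-6 * 44, k = 44)
  expect_equal(low$vcfix, vcfix_uptake_limit(co2_m, vmax = 1e-6 * 44, k = 44),
               tolerance = 1e-4)
  # Vmax >> D: every incoming molecule is fixed
  high <- solve_steady_state(co2_m = co2_m, vmax_over_d = 1e6 * 44, k = 44)
  expect_equal(high$vcfix, vcfix_diffusion_limit(co2_m, d = 1),
               tolerance = 1e-3)

  # sandwich at any finite ratio
  draws <- draw_params(500, seed = 3)
  ss <- solve_steady_state(co2_m = draws$co2_m,
                           vmax_over_d = draws$vmax_over_d, k = draws$k)
  upper <- pmin(
    vcfix_uptake_limit(draws$co2_m, vmax = draws$vmax_over_d, k = draws$k),
    vcfix_diffusion_limit(draws$co2_m, d = 1)
  )
  expect_true(all(ss$vcfix <= upper * (1 + 1e-12)))
})

test_that("solve_steady_state takes conditions from a piped data frame", {
  grid <- tidyr::expand_grid(co2_m = c(17, 410), vmax_over_d = c(0.1, 44))
  ss <- solve_steady_state(grid)
  expect_equal(nrow(ss), 4L)
  expect_equal(ss$co2_p,
               steady_state_co2p(grid$co2_m,
                                 vmax_over_d = grid$vmax_over_d))
})
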