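test_that("conformational partition follows the flip-flop equilibrium", {
  p <- ah_params(n_sites = 4, alpha = 2, ligand = 1)
  ## level 0 with ligand 1: equilibrium constant 1, equal split
  expect_equal(ah_partition(0.6, 0, p), c(0.3, 0.3))
  expect_equal(ah_partition(0, 2, p), c(0, 0))
  ## generic constant: S/T ratio fixed by c = L * exp(-alpha * i)
  st <- ah_partition(1, 1, p, ligand = 5)
  cc <- 5 * exp(-2)
  expect_equal(st[2] / st[1], cc, tolerance = 1e-12)
  ## oracle: long integration of the bare two-state flip-flop kinetics
  ## dS/dt = T - c*S must settle at T/S = c
  two_state <- rk4(function(y) c(y[2] - cc * y[1], cc * y[1] - y[2]),
                   c(1, 0), t_end = 40)
  expect_equal(two_state[2] / two_state[1], cc, tolerance = 1e-6)
})

test_that("A-H dynamics conserve receptor mass and need the co-factor", {
  p <- ah_params(n_sites = 4, K_base = 1e-2, E_total = 0)
  y <- c(0.2, 0.3, 0.1, 0.2, 0.2)
  expect_equal(ah_rhs(y, p)$dy, rep(0, 5))  # everything is catalysed
  p2 <- ah_params(n_sites = 4, K_base = 1e-2, E_total = 0.3)
  set.seed(4)
  for (rep in 1:6) {
    y <- random_state(5)
    expect_lt(abs(sum(ah_rhs(y, p2)$dy)), 1e-14)
  }
})

test_that("saturating co-factor reduces to first-order two-state kinetics", {
  ## with E >> K_i every receptor is catalyst-bound, so fluxes become
  ## k_up * T_i and k_down * S_i -- the original first-order scheme
  p <- ah_params(n_sites = 3, k_up = 1, k_down = 1, K_base = 1e-6,
                 theta = 0.5, alpha = 1, ligand = 2, E_total = 100)
  y <- c(0.4, 0.3, 0.2, 0.1)
  s <- 1 / (1 + 2 * exp(-(0:3)))
  S <- y * s; Tf <- y - S
  up <- Tf[1:3]; down <- S[2:4]
  expected <- c(-up[1] + down[1],
                up[1] - up[2] + down[2] - down[1],
                up[2] - up[3] + down[3] - down[2],
                up[3] - down[3])
  expect_equal(ah_rhs(y, p)$dy, expected, tolerance = 1e-4)
})

test_that("reduced A-H matches the full mass-action model", {
  p <- ah_params(n_sites = 3, K_base = 1e-2, theta = 1, alpha = 2,
                 ligand = 10, E_total = 0.2)
  y0 <- c(0.4, 0.3, 0.2, 0.1)
  red <- simulate_ah(p, x0 = y0, t_end = 30, points_per_decade = 60,
                     t_first = 1e-3)
  full <- simulate_full_ah(p, k_on = 1e4, k_flip = 1e4, y0 = y0,
                           times = c(0, 10^seq(-3, log10(30),
                                               length.out = 100)))
  lev <- stats::approx(red$times, red$modification_level,
                       xout = full$times, rule = 2)$y
  expect_lt(max(abs(lev - full$modification_level)), 0.01)
})

test_that("constant environment leaves the adapted state stationary", {
  p <- ah_params(n_sites = 4, K_base = 1e-3, theta = 1, alpha = 2,
                 ligand = 50, E_total = 0.05)
  y_ss <- steady_state(p, state_unmodified(p), t_block = 100, max_t = 1e8)
  tr <- simulate_ah(p, x0 = y_ss, t_end = 1e4, points_per_decade = 15)
  expect_lt(max(abs(sweep(tr$states, 2, y_ss))), 1e-6)
})

test_that("activity responds instantly to a ligand switch, modification slowly", {
  p <- preset("ah")
  p$n_sites <- 6; p <- do.call(ah_params, p[c("n_sites", "k_up", "k_down",
                                              "K_base", "theta", "alpha",
                                              "ligand", "S_total", "E_total")])
  y0 <- steady_state(p, state_unmodified(p), t_block = 100, max_t = 1e9)
  act_pre <- sum(y0 * kinmem:::.ah_active_frac(p, p$ligand))
  prot <- stimulus_protocol(1e-3, t_on = 0, duration = Inf, target = "ligand")
  tr <- simulate_ah(p, x0 = y0, protocol = prot, t_end = 1e9,
                    points_per_decade = 15, stop_below = 1e-3)
  ## activity jump at the first positive output time (adiabatic flip-flop)
  expect_gt(abs(tr$activity[2] - act_pre), 0.1)
  ## modification level has barely moved at that time
  expect_lt(abs(tr$modification_level[2] - tr$modification_level[1]), 1e-3)
})
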