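test_that("chain right-hand side conserves mass and respects boundaries", {
  p <- chain_params(n_sites = 4, k_mod = 0.3, k_demod = 1, K_base = 1e-2,
                    theta = 1, E_total = 0.2)
  set.seed(1)
  for (rep in 1:10) {
    x <- random_state(5)
    r <- chain_rhs(x, p, input_rate = stats::runif(1, 0, 2))
    expect_lt(abs(sum(r$dx)), 1e-14)
  }
})

test_that("without catalyst the chain is a pure forward cascade", {
  p <- chain_params(n_sites = 3, k_mod = 0.5, E_total = 0)
  x <- c(0.4, 0.3, 0.2, 0.1)
  r <- chain_rhs(x, p)
  ## matches the first-order forward chain exactly
  up <- 0.5 * x[1:3]
  expect_equal(r$dx, c(-up[1], up[1] - up[2], up[2] - up[3], up[3]))
})

test_that("absorbing state has zero derivative", {
  p <- chain_params(n_sites = 3, k_mod = 0, E_total = 0.1)
  r <- chain_rhs(c(1, 0, 0, 0), p)
  expect_equal(r$dx, rep(0, 4))
})

test_that("N=1 enzyme-limited demodification is zero order at rate k*E_total", {
  ## the catalyst is fully sequestered, so the flux equals k_demod * E_total
  p <- chain_params(n_sites = 1, k_mod = 0, k_demod = 1, K_base = 1e-4,
                    theta = 1, S_total = 1, E_total = 1e-3)
  r <- chain_rhs(c(0, 1), p)
  expect_equal(r$dx[2], -p$k_demod * p$E_total, tolerance = 0.05)
})

test_that("catalyst-saturated trajectories match the matrix-exponential chain", {
  p <- chain_params(n_sites = 5, k_mod = 0, k_demod = 1, K_base = 1e-6,
                    theta = 0.5, S_total = 1, E_total = 100)
  tr <- simulate_chain(p, t_end = 40, points_per_decade = 60, t_first = 1e-2)
  times <- tr$times
  oracle <- linear_chain_solution(rep(0, 5), rep(1, 5),
                                  state_fully_modified(p), times)
  lev_oracle <- as.numeric(oracle %*% (0:5)) / 5
  expect_lt(max(abs(tr$modification_level - lev_oracle)), 1e-3)
})

test_that("pure demodification gives monotone non-increasing modified mass", {
  p <- chain_params(n_sites = 4, k_mod = 0, K_base = 1e-3, theta = 1,
                    E_total = 0.05)
  tr <- simulate_chain(p, t_end = 1e6, points_per_decade = 20)
  expect_true(all(diff(tr$modified_mass) <= 1e-9))
})

test_that("trajectories conserve substrate and keep free catalyst in range", {
  p <- preset("fig2")
  tr <- simulate_chain(p, t_end = 1e6, points_per_decade = 15)
  expect_lt(max(abs(rowSums(tr$states) - p$S_total)), 1e-8 * p$S_total)
  expect_true(all(tr$states >= 0))
  expect_true(all(tr$free_catalyst >= 0 &
                    tr$free_catalyst <= p$E_total + 1e-12))
})

test_that("stimulus window raises the modification level and then releases", {
  p <- preset("fig2")
  prot <- stimulus_protocol(magnitude = 1, t_on = 0, duration = 3)
  tr <- simulate_chain(p, x0 = state_unmodified(p), protocol = prot,
                       t_end = 50, points_per_decade = 40, t_first = 1e-2)
  in_window <- tr$times <= 3 & tr$times > 0
  expect_gt(max(tr$modification_level[in_window]), 0.1)
  ## modification keeps no new source after the window: level non-increasing
  after <- tr$times >= 3.01
  expect_true(all(diff(tr$modification_level[after]) <= 1e-9))
})

test_that("free-fraction modification switch slows the uncatalysed flux", {
  pt <- chain_params(n_sites = 2, k_mod = 1, K_base = 1e-3, theta = 0,
                     E_total = 0.5,
                     modification_substrate = "as_printed_total")
  pf <- chain_params(n_sites = 2, k_mod = 1, K_base = 1e-3, theta = 0,
                     E_total = 0.5,
                     modification_substrate = "free_fraction")
  x <- c(1, 0, 0)
  up_total <- chain_rhs(x, pt)$dx[2]
  up_free <- chain_rhs(x, pf)$dx[2]
  expect_gt(up_total, up_free)  # only the unbound fraction reacts
})
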