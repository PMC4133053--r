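test_that("relaxation time of a pure exponential is ln(1/threshold)", {
  t <- 10^seq(-3, 2, length.out = 400)
  traj <- synthetic_trajectory(t, exp(-t))
  expect_equal(relaxation_time(traj, 0.01), log(100), tolerance = 1e-3)
})

test_that("relaxation time interpolates log-linearly between brackets", {
  ## two-point bracket (1, 0.02), (10, 0.005) with threshold 0.01:
  ## ln tau = 0 + (0.02-0.01)/(0.02-0.005) * ln 10  =>  tau = 10^(2/3)
  traj <- synthetic_trajectory(c(0.1, 1, 10), c(0.03, 0.02, 0.005))
  expect_equal(relaxation_time(traj, 0.01), 10^(2 / 3), tolerance = 1e-10)
})

test_that("relaxation time flags non-crossing and already-low trajectories", {
  t <- 10^seq(-2, 4, length.out = 50)
  expect_identical(relaxation_time(synthetic_trajectory(t, rep(0.8, 50)),
                                   0.01), Inf)
  expect_identical(relaxation_time(synthetic_trajectory(t, rep(0.001, 50)),
                                   0.01), 0)
})

test_that("relaxation time warns on re-crossing and returns the first one", {
  t <- c(1, 2, 4, 8, 16)
  m <- c(0.05, 0.008, 0.02, 0.009, 0.001)
  expect_warning(tau <- relaxation_time(synthetic_trajectory(t, m), 0.01),
                 "re-crosses")
  expect_lt(tau, 2)
})

test_that("decay classifier recognises the canonical curve shapes", {
  s_exp <- classify_decay(make_fixture("exponential"))
  expect_identical(s_exp$decay_class, "exponential")
  expect_gt(s_exp$fit_r2_exp, 0.999)

  s_log <- classify_decay(make_fixture("logarithmic"))
  expect_identical(s_log$decay_class, "logarithmic")
  expect_gt(s_log$fit_r2_log, 0.99)
  expect_lt(s_log$log_slope, 0)

  ## insufficient decay -> "none"
  t <- 10^seq(-2, 3, length.out = 100)
  s_none <- classify_decay(synthetic_trajectory(t, 1 - 0.1 * t / max(t)))
  expect_identical(s_none$decay_class, "none")
})

test_that("classification is invariant under uniform time rescaling", {
  t <- 10^seq(-3, 6, length.out = 300)
  for (kind in c("exponential", "logarithmic")) {
    f <- make_fixture(kind)
    s1 <- classify_decay(f)
    s2 <- classify_decay(synthetic_trajectory(f$times * 100,
                                              f$modification_level))
    expect_identical(s1$decay_class, s2$decay_class)
    expect_equal(s1$log_slope, s2$log_slope, tolerance = 1e-6)
  }
})

test_that("plateau counter finds staircase flats and no flats in smooth decays", {
  expect_identical(plateau_count(make_fixture("staircase")), 3L)
  expect_identical(plateau_count(make_fixture("exponential")), 0L)
  expect_identical(plateau_count(make_fixture("logarithmic")), 0L)
})

test_that("site relaxation order is a permutation with a monotonicity label", {
  p <- chain_params(n_sites = 1, E_total = 1)
  t <- 10^seq(-2, 2, length.out = 60)
  traj <- synthetic_trajectory(t, exp(-t))
  ord <- site_relaxation_order(traj, 0.01)
  expect_identical(ord$order, 1L)        # single site: trivial permutation
  expect_identical(ord$label, "ascending")
  ## chain run at high catalyst: descending completion
  ph <- preset("fig2"); ph$E_total <- 10
  trh <- simulate_chain(ph, t_end = 1e4, points_per_decade = 60,
                        stop_below = 1e-4)
  oh <- site_relaxation_order(trh)
  expect_setequal(oh$order, 1:10)
  expect_identical(oh$label, "descending")
})

test_that("asymptotic estimator requires heterogeneity and scales with 1/E", {
  p0 <- chain_params(n_sites = 5, theta = 0, E_total = 1e-3)
  expect_error(asymptotic_level(p0, 1:10), "theta")
  p <- chain_params(n_sites = 5, theta = 1, E_total = 1e-3)
  t <- c(0, 10^seq(0, 9, length.out = 200))
  lev1 <- asymptotic_level(p, t)
  p2 <- p; p2$E_total <- 2e-3
  lev2 <- asymptotic_level(p2, t / 2)   # doubling E halves all timescales
  expect_equal(lev1, lev2, tolerance = 1e-12)
  expect_equal(lev1[1], 1, tolerance = 1e-6)
  expect_true(all(diff(lev1) <= 0))
})

test_that("asymptotic estimator N=1 reduces to the zero-order crossover", {
  p <- chain_params(n_sites = 1, k_demod = 2, S_total = 1, E_total = 0.01)
  t_star <- (1 - 0.01) / (2 * 0.01)
  lev <- asymptotic_level(p, c(0, t_star / 2, t_star))
  ## linear decay at rate k*E until the substrate reaches the catalyst level
  expect_equal(lev[2], 1 - 2 * 0.01 * t_star / 2, tolerance = 1e-12)
  expect_equal(lev[3], 0.01, tolerance = 1e-9)
  ## catalyst-rich: plain exponential at the catalytic rate
  pr <- chain_params(n_sites = 1, k_demod = 2, S_total = 1, E_total = 10)
  expect_equal(asymptotic_level(pr, 1), exp(-2), tolerance = 1e-12)
})

test_that("terminal rate recovers the slowest eigenvalue of a known chain", {
  ## gamma-tail decay with unit rates: the asymptotic rate is exactly 1
  times <- c(0, 10^seq(-2, log10(60), length.out = 300))
  states <- linear_chain_solution(rep(0, 5), rep(1, 5), c(0, 0, 0, 0, 0, 1),
                                  times)
  p <- chain_params(n_sites = 5, S_total = 1, E_total = 0)
  traj <- kinmem:::.make_traj("oracle", times, states, p, no_stimulus(),
                              rep(0, length(times)))
  expect_equal(terminal_rate(traj), 1, tolerance = 0.02)
})
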