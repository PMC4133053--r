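test_that("free catalyst solver handles the trivial limits", {
  p <- chain_params(n_sites = 3, E_total = 0.5)
  expect_equal(free_catalyst_chain(rep(0, 4), p), 0.5)
  p0 <- chain_params(n_sites = 3, E_total = 0)
  expect_equal(free_catalyst_chain(c(0.2, 0.3, 0.1, 0.4), p0), 0)
})

test_that("single-level case reproduces the analytic quadratic root", {
  ## with one occupied level, K = 1, x = 1, E_total = 1 the conservation
  ## relation reduces to E^2 + E - 1 = 0, E_free = (sqrt(5) - 1) / 2
  p <- chain_params(n_sites = 1, K_base = 1, theta = 0, E_total = 1)
  expect_equal(free_catalyst_chain(c(0, 1), p), (sqrt(5) - 1) / 2,
               tolerance = 1e-12)
})

test_that("solver agrees with a dense residual scan on random instances", {
  set.seed(42)
  for (rep in 1:40) {
    n <- sample(1:10, 1)
    p <- chain_params(n_sites = n,
                      K_base = 10^stats::runif(1, -5, 0),
                      theta = stats::runif(1, 0, 2),
                      S_total = 1,
                      E_total = 10^stats::runif(1, -3, 1))
    x <- random_state(n + 1)
    Ef <- free_catalyst_chain(x, p)
    ## residual within stated tolerance
    resid <- Ef + sum(x * Ef / (p$K + Ef)) - p$E_total
    expect_lt(abs(resid), 1e-12 * max(p$E_total, 1))
    ## solution inside its box and matching the brute-force scan
    expect_gte(Ef, 0); expect_lte(Ef, p$E_total)
    expect_equal(Ef, dense_scan_free(x, p$K, p$E_total), tolerance = 1e-9)
  }
})

test_that("sequestration is monotone: more substrate means less free catalyst", {
  set.seed(7)
  for (rep in 1:10) {
    n <- 5
    p <- chain_params(n_sites = n, K_base = 1e-3, theta = 1, E_total = 0.3)
    x <- random_state(n + 1)
    Ef <- free_catalyst_chain(x, p)
    i <- sample(n + 1, 1)
    x2 <- x; x2[i] <- x2[i] + 0.5
    expect_lt(free_catalyst_chain(x2, p), Ef)
  }
})

test_that("negative inputs are rejected", {
  p <- chain_params(n_sites = 2)
  expect_error(free_catalyst_chain(c(-0.1, 0, 0), p), "non-negative")
  expect_error(chain_params(n_sites = 0), "integer")
  expect_error(chain_params(n_sites = 2, k_demod = -1), "k_demod")
})

test_that("two-catalyst solver satisfies both conservation relations", {
  set.seed(11)
  for (rep in 1:20) {
    n <- sample(1:6, 1)
    p <- kp_params(n_sites = n,
                   K_kin_base = 10^stats::runif(1, -4, -1), theta_kin = 1,
                   K_pho_base = 10^stats::runif(1, -4, -1), theta_pho = 1,
                   K_total = 10^stats::runif(1, -3, 1),
                   P_total = 10^stats::runif(1, -3, 1))
    x <- random_state(n + 1)
    f <- free_catalysts_kp(x, p)
    expect_true(all(f >= 0))
    expect_lte(f[1], p$K_total); expect_lte(f[2], p$P_total)
    expect_lt(max(abs(kp_residuals(f, x, p))),
              1e-10 * max(p$K_total, p$P_total, 1))
  }
})

test_that("two-catalyst solver: trivial and degenerate reductions", {
  p <- kp_params(n_sites = 3, K_total = 0.4, P_total = 0.7)
  expect_equal(free_catalysts_kp(rep(0, 4), p), c(0.4, 0.7))
  ## P_total = 0 reduces to the single-catalyst chain solution
  p0 <- kp_params(n_sites = 3, K_kin_base = 1e-3, theta_kin = 1.2,
                  K_total = 0.2, P_total = 0)
  x <- c(0.1, 0.4, 0.3, 0.2)
  f <- free_catalysts_kp(x, p0)
  pc <- chain_params(n_sites = 3, K_base = 1e-3, theta = 1.2, E_total = 0.2)
  expect_equal(f[2], 0)
  expect_equal(f[1], free_catalyst_chain(x, pc), tolerance = 1e-9)
})

test_that("symmetric kinase/phosphatase parameters give equal free levels", {
  set.seed(3)
  p <- kp_params(n_sites = 4, K_kin_base = 1e-3, theta_kin = 0.8,
                 K_pho_base = 1e-3, theta_pho = 0.8,
                 K_total = 0.15, P_total = 0.15)
  for (rep in 1:5) {
    x <- random_state(5)
    f <- free_catalysts_kp(x, p)
    expect_equal(f[1], f[2], tolerance = 1e-9)
    ## cross-check against 2-D brute-force grid refinement
    g <- grid_refine_kp(x, p)
    expect_equal(f[1], g[1], tolerance = 1e-5)
    expect_equal(f[2], g[2], tolerance = 1e-5)
  }
})

test_that("A-H free-co-factor solver pools conformations with equal constants", {
  p <- ah_params(n_sites = 3, K_base = 0.01, theta = 1, E_total = 0.2)
  expect_equal(free_catalyst_ah(rep(0, 4), p), 0.2)
  ## single occupied level equals the chain solution on the pooled total
  pc <- chain_params(n_sites = 3, K_base = 0.01, theta = 1, E_total = 0.2)
  y <- c(0, 0.8, 0, 0)
  expect_equal(free_catalyst_ah(y, p), free_catalyst_chain(y, pc),
               tolerance = 1e-12)
  ## generic 3-level state against the brute-force scan
  y2 <- c(0.2, 0.3, 0.1, 0.4)
  expect_equal(free_catalyst_ah(y2, p),
               dense_scan_free(y2, p$K, p$E_total), tolerance = 1e-9)
})
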