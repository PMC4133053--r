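## Independent oracles used across the test files.

## Brute-force root location for the scalar free-catalyst conservation law:
## dense geometric scan of the monotone residual followed by repeated
## bracket refinement (no Newton, independent of the package solver).
dense_scan_free <- function(x, K, E_total, refinements = 60) {
  if (E_total == 0) return(0)
  resid <- function(E) E + sum(x * E / (K + E)) - E_total
  lo <- 0; hi <- E_total
  for (r in seq_len(refinements)) {
    grid <- seq(lo, hi, length.out = 33)
    vals <- vapply(grid, resid, numeric(1))
    k <- which(vals > 0)[1]
    if (is.na(k) || k == 1L) return(grid[1])
    lo <- grid[k - 1L]; hi <- grid[k]
  }
  (lo + hi) / 2
}

## 2-D brute-force refinement for the kinase-phosphatase conservation system
grid_refine_kp <- function(x, p, refinements = 40) {
  resid <- function(Kf, Pf) kinmem::kp_residuals(c(Kf, Pf), x, p)
  loK <- 0; hiK <- p$K_total; loP <- 0; hiP <- p$P_total
  for (r in seq_len(refinements)) {
    gK <- seq(loK, hiK, length.out = 9)
    gP <- seq(loP, hiP, length.out = 9)
    best <- c(Inf, NA, NA)
    for (a in gK) for (b in gP) {
      v <- max(abs(resid(a, b)))
      if (v < best[1]) best <- c(v, a, b)
    }
    dK <- (hiK - loK) / 8; dP <- (hiP - loP) / 8
    loK <- max(0, best[2] - dK); hiK <- min(p$K_total, best[2] + dK)
    loP <- max(0, best[3] - dP); hiP <- min(p$P_total, best[3] + dP)
  }
  c(best[2], best[3])
}

## random nonnegative state summing to S_total
random_state <- function(n_levels, S_total = 1) {
  w <- stats::runif(n_levels)
  S_total * w / sum(w)
}

## spread-top initial condition (top level dominant, the rest uniform)
spread_top_state <- function(p, top_frac = 0.5) {
  x <- rep(p$S_total * (1 - top_frac) / p$n_sites, p$n_sites + 1L)
  x[p$n_sites + 1L] <- p$S_total * top_frac
  x
}

## crude fixed-step RK4 integrator, independent of deSolve, for tiny cases
rk4 <- function(f, y0, t_end, n_steps = 4000) {
  h <- t_end / n_steps
  y <- y0
  for (i in seq_len(n_steps)) {
    k1 <- f(y); k2 <- f(y + h / 2 * k1)
    k3 <- f(y + h / 2 * k2); k4 <- f(y + h * k3)
    y <- y + h / 6 * (k1 + 2 * k2 + 2 * k3 + k4)
  }
  y
}
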