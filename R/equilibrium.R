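## Fast-equilibrium conservation-law solvers.
##
## Under the adiabatic (fast binding/unbinding) approximation the free
## catalyst concentration is the root of the conservation relation
##   E_total = E_free + sum_i x_i * E_free / (K_i + E_free),
## which is strictly increasing in E_free, so the root in [0, E_total] is
## unique. Solved by bisection (guaranteed bracketing) followed by Newton
## polish to machine precision.

## residual g(E) = E + sum x_i E/(K_i+E) - E_total and its derivative
.free_resid <- function(E, x, K, E_total) {
  E + sum(x * E / (K + E)) - E_total
}
.free_resid_d <- function(E, x, K) {
  1 + sum(x * K / (K + E)^2)
}

## core scalar solve shared by the chain and A-H solvers
.solve_free <- function(x, K, E_total, tol = 1e-12, guess = NULL) {
  if (E_total == 0) return(0)
  if (sum(x) == 0) return(E_total)
  lo <- 0; hi <- E_total
  E <- if (!is.null(guess) && is.finite(guess) && guess > 0 && guess < E_total)
    guess else E_total / 2
  scale <- max(E_total, 1)
  for (iter in 1:200) {
    g <- .free_resid(E, x, K, E_total)
    if (abs(g) <= tol * scale) return(E)
    if (g > 0) hi <- E else lo <- E
    step <- g / .free_resid_d(E, x, K)
    Enew <- E - step
    ## Newton when it stays inside the bracket, bisection otherwise
    E <- if (Enew > lo && Enew < hi) Enew else (lo + hi) / 2
  }
  ## the residual is monotone; reaching here means tol was not met only by
  ## floating-point limits -- return the bracket midpoint
  if (abs(.free_resid(E, x, K, E_total)) > 1e-9 * scale)
    stop("free-catalyst solve failed to converge", call. = FALSE)
  E
}

#' Free catalyst concentration in the chained modification model
#'
#' Solves the conservation relation
#' `E_total = E_free + sum_i x_i * E_free / (K_i + E_free)` for the unique
#' free-catalyst concentration in `[0, E_total]`, given the fast
#' binding/unbinding equilibrium at every modification level.
#'
#' @param x state vector of total concentrations per modification level.
#' @param p a [chain_params()] object.
#' @param tol relative residual tolerance (default 1e-12).
#' @param guess optional warm-start value.
#' @return the free catalyst concentration `E_free`.
#' @examples
#' p <- chain_params(n_sites = 1, K_base = 1, theta = 0, E_total = 1)
#' free_catalyst_chain(c(0, 1), p)  # (sqrt(5)-1)/2
#' @export
free_catalyst_chain <- function(x, p, tol = 1e-12, guess = NULL) {
  x <- chain_state(x, p)
  .solve_free(x, p$K, p$E_total, tol = tol, guess = guess)
}

#' Free catalyst concentration in the extended Asakura-Honda model
#'
#' As [free_catalyst_chain()], with binding summed over both conformational
#' states; because the two forms share the same dissociation constant at each
#' level, the pooled per-level concentrations enter the conservation relation
#' directly.
#'
#' @param y pooled state vector (S_i + T_i per level).
#' @param p an [ah_params()] object.
#' @inheritParams free_catalyst_chain
#' @return the free co-factor concentration.
#' @export
free_catalyst_ah <- function(y, p, tol = 1e-12, guess = NULL) {
  if (length(y) != p$n_sites + 1L)
    stop_domain("state must have length n_sites + 1 = %d", p$n_sites + 1L)
  if (any(!is.finite(y)) || any(y < 0))
    stop_domain("state concentrations must be finite and non-negative")
  .solve_free(as.numeric(y), p$K, p$E_total, tol = tol, guess = guess)
}

#' Free kinase and phosphatase concentrations
#'
#' Jointly solves the two conservation relations of the kinase-phosphatase
#' model. Each substrate level partitions among free, kinase-bound and
#' phosphatase-bound forms:
#' `x_i = f_i * (1 + K_free/Kk_i + P_free/Kp_i)`, so
#' `K_total = K_free + sum_i x_i (K_free/Kk_i) / (1 + K_free/Kk_i + P_free/Kp_i)`
#' and symmetrically for the phosphatase. Solved by alternating damped
#' per-coordinate scalar solves (each coordinate map is monotone), with at
#' most 200 outer iterations.
#'
#' @param x state vector of total concentrations per phosphorylation level.
#' @param p a [kp_params()] object.
#' @param tol relative residual tolerance (default 1e-10).
#' @param guess optional length-2 warm start `c(K_free, P_free)`.
#' @return numeric vector `c(K_free, P_free)`.
#' @export
free_catalysts_kp <- function(x, p, tol = 1e-10, guess = NULL) {
  if (length(x) != p$n_sites + 1L)
    stop_domain("state must have length n_sites + 1 = %d", p$n_sites + 1L)
  if (any(!is.finite(x)) || any(x < 0))
    stop_domain("state concentrations must be finite and non-negative")
  x <- as.numeric(x)
  Kt <- p$K_total; Pt <- p$P_total
  if (Kt == 0 && Pt == 0) return(c(0, 0))
  scale <- max(Kt, Pt, 1)

  ## scalar residual in one free concentration with the other held fixed;
  ## monotone increasing, root bracketed in [0, total]
  solve_one <- function(total, Kown, other_ratio, start) {
    if (total == 0) return(0)
    resid <- function(E) {
      denom <- 1 + E / Kown + other_ratio
      E + sum(x * (E / Kown) / denom) - total
    }
    lo <- 0; hi <- total
    E <- if (is.finite(start) && start > 0 && start < total) start else total / 2
    for (i in 1:200) {
      g <- resid(E)
      if (abs(g) <= 0.01 * tol * scale) return(E)
      if (g > 0) hi <- E else lo <- E
      eps <- max(1e-9 * max(E, total * 1e-6), 1e-300)
      d <- (resid(E + eps) - g) / eps
      Enew <- if (d > 0) E - g / d else NA_real_
      E <- if (is.finite(Enew) && Enew > lo && Enew < hi) Enew else (lo + hi) / 2
    }
    E
  }

  Kf <- if (!is.null(guess)) guess[1] else Kt / 2
  Pf <- if (!is.null(guess)) guess[2] else Pt / 2
  if (Kt == 0) Kf <- 0
  if (Pt == 0) Pf <- 0
  for (iter in 1:200) {
    Kf_new <- solve_one(Kt, p$K_kin, Pf / p$K_pho, Kf)
    Pf_new <- solve_one(Pt, p$K_pho, Kf_new / p$K_kin, Pf)
    ## mild damping stabilises strongly sequestered cases
    Kf2 <- 0.5 * (Kf + Kf_new); Pf2 <- 0.5 * (Pf + Pf_new)
    rK <- kp_residuals(c(Kf_new, Pf_new), x, p)
    if (max(abs(rK)) <= tol * scale) return(c(Kf_new, Pf_new))
    Kf <- Kf2; Pf <- Pf2
  }
  r <- kp_residuals(c(Kf, Pf), x, p)
  if (max(abs(r)) > 1e-8 * scale)
    stop(sprintf(
      "kinase-phosphatase free-catalyst solve did not converge (residuals %.3g, %.3g)",
      r[1], r[2]), call. = FALSE)
  c(Kf, Pf)
}

#' Residuals of the kinase/phosphatase conservation relations
#'
#' @param free length-2 vector `c(K_free, P_free)`.
#' @param x state vector.
#' @param p a [kp_params()] object.
#' @return length-2 vector of residuals (solved values give ~0).
#' @export
kp_residuals <- function(free, x, p) {
  Kf <- free[1]; Pf <- free[2]
  denom <- 1 + Kf / p$K_kin + Pf / p$K_pho
  c(Kf + sum(x * (Kf / p$K_kin) / denom) - p$K_total,
    Pf + sum(x * (Pf / p$K_pho) / denom) - p$P_total)
}
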