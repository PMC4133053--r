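## Full mass-action reference models with explicit complex species and
## finite association/dissociation rates. These validate the adiabatic
## (fast-equilibrium) reduction: as k_on grows with k_off_i = k_on * K_i
## fixed by detailed balance, the pooled trajectories converge to the
## reduced models. Restricted to small N and short horizons (stiffness grows
## with k_on).

#' Full mass-action parameters for the chained modification model
#'
#' @param p a [chain_params()] object.
#' @param k_on association rate scale; per-level dissociation rates are
#'   `k_off_i = k_on * K_i` so the reduced model's equilibrium constants are
#'   matched by construction.
#' @return an object of class `full_chain_params`.
#' @export
full_chain_params <- function(p, k_on = 1e4) {
  if (!inherits(p, "chain_params")) stop_domain("p must be chain_params")
  if (!is.numeric(k_on) || k_on <= 0 || !is.finite(k_on))
    stop_domain("k_on must be a finite positive rate")
  structure(c(unclass(p), list(k_on = k_on, k_off = k_on * p$K)),
            class = c("full_chain_params"))
}

## shared integration helper for the explicit-species models
.ode_full <- function(y0, times, deriv, rtol = 1e-10, atol = 1e-13) {
  sol <- deSolve::ode(y = y0, times = times, parms = NULL,
                      func = function(t, y, parms) list(deriv(pmax(y, 0))),
                      method = "lsoda", rtol = rtol, atol = atol,
                      maxsteps = 500000)
  if (attr(sol, "istate")[1] < 0)
    stop("full mass-action integration failed", call. = FALSE)
  unclass(sol)
}

#' Simulate the full mass-action chained modification model
#'
#' Explicit species: free substrates F_i, substrate-catalyst complexes C_i,
#' free catalyst E. Binding/unbinding at finite rates, demodification from
#' the complex (`C_i -> F_{i-1} + E`), uncatalysed modification acting on the
#' free substrate. Substrate and catalyst totals are conserved.
#'
#' @param fp a [full_chain_params()] object.
#' @param x0 pooled initial state (starts unbound).
#' @param t_end final time; `times` optional explicit grid.
#' @param input_rate constant additive stimulus on the modification rate.
#' @return a `kinmem_trajectory` of the pooled per-level totals, with the
#'   explicit species matrix in `$species`.
#' @export
simulate_full_chain <- function(fp, x0 = NULL, t_end = 50, times = NULL,
                                input_rate = 0) {
  n <- fp$n_sites
  if (is.null(x0)) { x0 <- numeric(n + 1); x0[n + 1] <- fp$S_total }
  if (is.null(times)) times <- .log_grid(t_end, t_first = t_end * 1e-8,
                                         points_per_decade = 30)
  nv <- n + 1L
  k_up <- fp$k_mod + input_rate
  deriv <- function(y) {
    F <- y[1:nv]; C <- y[(nv + 1):(2 * nv)]; E <- y[2 * nv + 1]
    bind <- fp$k_on * F * E - fp$k_off * C
    cat_flux <- fp$k_demod * C            # C_i -> F_{i-1} + E (i >= 1)
    cat_flux[1] <- 0
    mod_flux <- k_up * F                  # F_i -> F_{i+1} (i < N)
    mod_flux[nv] <- 0
    dF <- -bind - mod_flux +
      c(0, mod_flux[-nv]) +               # inflow from below
      c(cat_flux[-1], 0)                  # demod product from above
    dC <- bind - cat_flux
    dE <- -sum(bind) + sum(cat_flux)
    c(dF, dC, dE)
  }
  y0 <- c(x0, numeric(nv), fp$E_total)
  m <- .ode_full(y0, times, deriv)
  F <- m[, 2:(nv + 1), drop = FALSE]
  C <- m[, (nv + 2):(2 * nv + 1), drop = FALSE]
  E <- m[, 2 * nv + 2]
  ## conservation check
  s_tot <- rowSums(F) + rowSums(C)
  e_tot <- E + rowSums(C)
  if (max(abs(s_tot - sum(x0))) > 1e-8 * max(sum(x0), 1) ||
      max(abs(e_tot - fp$E_total)) > 1e-8 * max(fp$E_total, 1))
    warning("mass-action conservation drift above 1e-8 relative")
  pooled <- F + C
  pcopy <- chain_params(n_sites = n, k_mod = fp$k_mod, k_demod = fp$k_demod,
                        K_base = fp$K_base, theta = fp$theta,
                        S_total = fp$S_total, E_total = fp$E_total)
  traj <- .make_traj("full_chain", m[, 1], pooled, pcopy, no_stimulus(), E,
                     extra = list(species = m[, -1]))
  traj
}

#' Simulate the full mass-action kinase-phosphatase model
#'
#' Explicit species: free substrates, kinase complexes, phosphatase
#' complexes, free kinase and phosphatase. `k_off` values follow from `k_on`
#' and the dissociation-constant ladders.
#'
#' @param p a [kp_params()] object.
#' @param k_on association rate scale (shared by both catalysts).
#' @param x0 pooled initial state.
#' @param t_end,times output grid controls.
#' @return a `kinmem_trajectory` of pooled totals with two-column free
#'   catalyst.
#' @export
simulate_full_kp <- function(p, k_on = 1e4, x0 = NULL, t_end = 50,
                             times = NULL) {
  n <- p$n_sites; nv <- n + 1L
  if (is.null(x0)) x0 <- state_unmodified(p)
  if (is.null(times)) times <- .log_grid(t_end, t_first = t_end * 1e-8,
                                         points_per_decade = 30)
  koffK <- k_on * p$K_kin; koffP <- k_on * p$K_pho
  deriv <- function(y) {
    F <- y[1:nv]; CK <- y[(nv + 1):(2 * nv)]; CP <- y[(2 * nv + 1):(3 * nv)]
    EK <- y[3 * nv + 1]; EP <- y[3 * nv + 2]
    bindK <- k_on * F * EK - koffK * CK
    bindP <- k_on * F * EP - koffP * CP
    kin_flux <- p$k_kin * CK; kin_flux[nv] <- 0   # CK_i -> F_{i+1} + K
    pho_flux <- p$k_pho * CP; pho_flux[1] <- 0    # CP_i -> F_{i-1} + P
    dF <- -bindK - bindP + c(0, kin_flux[-nv]) + c(pho_flux[-1], 0)
    dCK <- bindK - kin_flux
    dCP <- bindP - pho_flux
    dEK <- -sum(bindK) + sum(kin_flux)
    dEP <- -sum(bindP) + sum(pho_flux)
    c(dF, dCK, dCP, dEK, dEP)
  }
  y0 <- c(x0, numeric(2 * nv), p$K_total, p$P_total)
  m <- .ode_full(y0, times, deriv)
  F <- m[, 2:(nv + 1), drop = FALSE]
  CK <- m[, (nv + 2):(2 * nv + 1), drop = FALSE]
  CP <- m[, (2 * nv + 2):(3 * nv + 1), drop = FALSE]
  free <- cbind(K_free = m[, 3 * nv + 2], P_free = m[, 3 * nv + 3])
  .make_traj("full_kp", m[, 1], F + CK + CP, p, no_stimulus(), free,
             extra = list(species = m[, -1]))
}

#' Simulate the full mass-action extended Asakura-Honda model
#'
#' Explicit species: free receptors in both conformations (S_i, T_i), their
#' co-factor complexes, and the free co-factor. Conformational flip-flop
#' occurs at finite rate `k_flip` with equilibrium `T_i/S_i` set by the
#' ligand; modification is catalysed from the T complex, demodification from
#' the S complex.
#'
#' @param p an [ah_params()] object.
#' @param k_on association rate scale; `k_flip` flip-flop rate scale.
#' @param y0 pooled initial state.
#' @param t_end,times output grid controls.
#' @param ligand ligand level (defaults to `p$ligand`).
#' @return a `kinmem_trajectory` of pooled totals with `activity`.
#' @export
simulate_full_ah <- function(p, k_on = 1e4, k_flip = 1e4, y0 = NULL,
                             t_end = 50, times = NULL, ligand = p$ligand) {
  n <- p$n_sites; nv <- n + 1L
  if (is.null(y0)) y0 <- state_unmodified(p)
  if (is.null(times)) times <- .log_grid(t_end, t_first = t_end * 1e-8,
                                         points_per_decade = 30)
  koff <- k_on * p$K
  cc <- ligand * exp(-p$alpha * (0:n))   # T/S equilibrium constants
  s0 <- 1 / (1 + cc)
  deriv <- function(y) {
    S <- y[1:nv]; Tf <- y[(nv + 1):(2 * nv)]
    CS <- y[(2 * nv + 1):(3 * nv)]; CT <- y[(3 * nv + 1):(4 * nv)]
    E <- y[4 * nv + 1]
    flip <- k_flip * (cc * S - Tf)       # S_i -> T_i net
    bindS <- k_on * S * E - koff * CS
    bindT <- k_on * Tf * E - koff * CT
    up <- p$k_up * CT; up[nv] <- 0       # CT_i -> T_{i+1} + E
    down <- p$k_down * CS; down[1] <- 0  # CS_i -> S_{i-1} + E
    dS <- -flip - bindS + c(down[-1], 0)
    dT <- flip - bindT + c(0, up[-nv])
    dCS <- bindS - down
    dCT <- bindT - up
    dE <- -sum(bindS) - sum(bindT) + sum(up) + sum(down)
    c(dS, dT, dCS, dCT, dE)
  }
  ## start at conformational equilibrium, unbound
  init <- c(y0 * s0, y0 * (1 - s0), numeric(2 * nv), p$E_total)
  m <- .ode_full(init, times, deriv)
  S <- m[, 2:(nv + 1), drop = FALSE]
  Tf <- m[, (nv + 2):(2 * nv + 1), drop = FALSE]
  CS <- m[, (2 * nv + 2):(3 * nv + 1), drop = FALSE]
  CT <- m[, (3 * nv + 2):(4 * nv + 1), drop = FALSE]
  E <- m[, 4 * nv + 2]
  pooled <- S + Tf + CS + CT
  act <- rowSums(S + CS) / p$S_total
  .make_traj("full_ah", m[, 1], pooled, p, no_stimulus(), E,
             extra = list(species = m[, -1], activity = act))
}

#' Exact solution of a linear (first-order) modification chain
#'
#' Closed-form oracle for the catalyst-saturated limit: the tridiagonal rate
#' matrix with constant up- and down-rates is exponentiated exactly.
#'
#' @param rates_up length-N vector of rates for level `i-1 -> i`.
#' @param rates_down length-N vector of rates for level `i -> i-1`.
#' @param x0 initial state (length N+1).
#' @param times output times.
#' @return matrix of states, one row per time.
#' @export
linear_chain_solution <- function(rates_up, rates_down, x0, times) {
  n <- length(rates_up)
  if (length(rates_down) != n || length(x0) != n + 1L)
    stop_domain("inconsistent chain dimensions")
  if (any(rates_up < 0) || any(rates_down < 0))
    stop_domain("rates must be non-negative")
  A <- matrix(0, n + 1L, n + 1L)
  for (j in seq_len(n)) {
    A[j + 1L, j] <- A[j + 1L, j] + rates_up[j]
    A[j, j] <- A[j, j] - rates_up[j]
    A[j, j + 1L] <- A[j, j + 1L] + rates_down[j]
    A[j + 1L, j + 1L] <- A[j + 1L, j + 1L] - rates_down[j]
  }
  out <- t(vapply(times, function(tt)
    as.numeric(Matrix::expm(A * tt) %*% x0), numeric(n + 1L)))
  out
}
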