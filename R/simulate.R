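## Right-hand sides and stiff integration for the three reduced models.
##
## All three models share the structure: a ladder of total per-level
## concentrations, fluxes between adjacent levels, and free catalyst
## concentration(s) recomputed algebraically at every evaluation from the
## conservation law (adiabatic elimination of binding/unbinding).

## net bond fluxes -> level derivatives; bond i carries flux from level i-1
## to level i (up positive). dx_i = inflow - outflow, conservative by
## construction.
.ladder_dx <- function(up, down, n) {
  ## up: length n (flux i-1 -> i for i = 1..n), down: length n (flux i -> i-1)
  bond <- up - down
  c(-bond[1], bond[-n] - bond[-1], bond[n])
  ## equivalent to dx_i = bond_i - bond_{i+1} with bond_0 = bond_{n+1} = 0
}

#' Right-hand side of the chained modification model
#'
#' Forward (uncatalysed) modification at rate `k_mod + input_rate`, backward
#' demodification at rate `k_demod * x_i * E_free / (K_i + E_free)` with the
#' free catalyst from [free_catalyst_chain()]. Boundary levels have one-sided
#' fluxes; the component sum is zero (conservation).
#'
#' @param x state vector (levels 0..N).
#' @param p a [chain_params()] object.
#' @param input_rate current additive stimulus on the modification rate.
#' @param E_free optional precomputed free-catalyst value.
#' @return list with `dx` (derivatives) and `E_free`.
#' @export
chain_rhs <- function(x, p, input_rate = 0, E_free = NULL) {
  x <- chain_state(x, p)
  if (input_rate < 0) stop_domain("input_rate must be >= 0")
  n <- p$n_sites
  Ef <- if (is.null(E_free)) free_catalyst_chain(x, p) else E_free
  bound_frac <- Ef / (p$K + Ef)
  k_up <- p$k_mod + input_rate
  up_sub <- if (p$modification_substrate == "free_fraction")
    x * (1 - bound_frac) else x
  up <- k_up * up_sub[1:n]                       # flux i-1 -> i, i = 1..n
  down <- p$k_demod * x[2:(n + 1)] * bound_frac[2:(n + 1)]  # flux i -> i-1
  list(dx = .ladder_dx(up, down, n), E_free = Ef)
}

#' Right-hand side of the kinase-phosphatase model
#'
#' Forward flux proportional to the kinase-bound fraction of each level,
#' backward flux proportional to the phosphatase-bound fraction, with the
#' two free-catalyst concentrations from [free_catalysts_kp()].
#'
#' @param x state vector (levels 0..N).
#' @param p a [kp_params()] object.
#' @param free optional precomputed `c(K_free, P_free)`.
#' @return list with `dx`, `K_free`, `P_free`.
#' @export
kp_rhs <- function(x, p, free = NULL) {
  n <- p$n_sites
  if (is.null(free)) free <- free_catalysts_kp(x, p)
  Kf <- free[1]; Pf <- free[2]
  denom <- 1 + Kf / p$K_kin + Pf / p$K_pho
  kin_bound <- x * (Kf / p$K_kin) / denom
  pho_bound <- x * (Pf / p$K_pho) / denom
  up <- p$k_kin * kin_bound[1:n]
  down <- p$k_pho * pho_bound[2:(n + 1)]
  list(dx = .ladder_dx(up, down, n), K_free = Kf, P_free = Pf)
}

#' Conformational partition of a pooled receptor level
#'
#' Fast flip-flop fixes the ratio `T_i / S_i = ligand * exp(-alpha * i)`;
#' the pooled level concentration is split accordingly.
#'
#' @param y_i pooled concentration of level `level`.
#' @param level modification level (0-based).
#' @param p an [ah_params()] object.
#' @param ligand ligand level (defaults to `p$ligand`).
#' @return numeric vector `c(S_i, T_i)`.
#' @export
ah_partition <- function(y_i, level, p, ligand = p$ligand) {
  if (y_i < 0) stop_domain("level concentration must be >= 0")
  cc <- ligand * exp(-p$alpha * level)
  S <- y_i / (1 + cc)
  c(S, y_i - S)
}

## vectorised active fraction s_i = S_i / y_i at each level
.ah_active_frac <- function(p, ligand) {
  1 / (1 + ligand * exp(-p$alpha * (0:p$n_sites)))
}

#' Right-hand side of the extended Asakura-Honda model
#'
#' Modification is catalysed on the inactive (T) conformation, demodification
#' on the active (S) conformation, both by the shared co-factor; the
#' catalyst-bound fraction at level i is `E_free / (K_i + E_free)` of the
#' pooled level, partitioned between conformations by the flip-flop
#' equilibrium.
#'
#' @param y pooled state vector (levels 0..N).
#' @param p an [ah_params()] object.
#' @param ligand current ligand level (defaults to `p$ligand`).
#' @param E_free optional precomputed free-co-factor value.
#' @return list with `dy`, `E_free`, `activity` (fraction of receptors in the
#'   active conformation).
#' @export
ah_rhs <- function(y, p, ligand = p$ligand, E_free = NULL) {
  n <- p$n_sites
  Ef <- if (is.null(E_free)) free_catalyst_ah(y, p) else E_free
  bound_frac <- Ef / (p$K + Ef)
  s <- .ah_active_frac(p, ligand)
  S <- y * s; Tf <- y - S
  up <- p$k_up * Tf[1:n] * bound_frac[1:n]
  down <- p$k_down * S[2:(n + 1)] * bound_frac[2:(n + 1)]
  list(dy = .ladder_dx(up, down, n), E_free = Ef,
       activity = sum(S) / max(sum(y), .Machine$double.xmin))
}

## ---------------------------------------------------------------------------
## Integration machinery

## log-spaced output grid including t = 0
.log_grid <- function(t_end, t_first = NULL, points_per_decade = 40) {
  if (is.null(t_first)) t_first <- max(t_end * 1e-12, 1e-6)
  t_first <- min(t_first, t_end / 10)
  n_dec <- log10(t_end) - log10(t_first)
  n <- max(2L, ceiling(n_dec * points_per_decade))
  c(0, 10^seq(log10(t_first), log10(t_end), length.out = n))
}

## split [0, t_end] into constant-input segments given a stimulus window
.segments <- function(protocol, t_end) {
  t_on <- protocol$t_on; t_off <- t_on + protocol$duration
  cuts <- sort(unique(pmin(pmax(c(0, t_on, t_off, t_end), 0), t_end)))
  segs <- list()
  for (i in seq_len(length(cuts) - 1L)) {
    a <- cuts[i]; b <- cuts[i + 1L]
    if (b <= a) next
    active <- (a >= t_on && a < t_off)
    segs[[length(segs) + 1L]] <- list(t0 = a, t1 = b, active = active)
  }
  if (length(segs) == 0L) segs <- list(list(t0 = 0, t1 = t_end, active = FALSE))
  segs
}

## Piecewise stiff integration with optional early stop when the modified
## mass falls below `stop_below` (root finding, applied in every segment).
.integrate_ladder <- function(deriv, x0, times, segs, rtol, atol, S_total,
                              stop_below = NULL) {
  out_times <- numeric(0)
  out_states <- NULL
  state <- x0
  rootfun <- if (!is.null(stop_below))
    function(t, y, parms) sum(pmax(y[-1], 0)) - stop_below
  ode_fn <- function(t, y, parms) deriv(t, y)
  for (seg in segs) {
    tt <- times[times >= seg$t0 & times <= seg$t1]
    tt <- sort(unique(c(seg$t0, tt, seg$t1)))
    if (length(tt) < 2L) tt <- c(seg$t0, seg$t1)
    assign("seg_active", seg$active, envir = environment(deriv))
    sol <- if (is.null(rootfun)) {
      deSolve::ode(y = state, times = tt, func = ode_fn, parms = NULL,
                   method = "lsoda", rtol = rtol, atol = atol,
                   maxsteps = 100000)
    } else {
      deSolve::lsodar(y = state, times = tt, func = ode_fn, parms = NULL,
                      rtol = rtol, atol = atol, rootfunc = rootfun,
                      maxsteps = 100000)
    }
    if (attr(sol, "istate")[1] < 0)
      stop(sprintf("stiff integration failed near t = %.6g", max(sol[, 1])),
           call. = FALSE)
    m <- unclass(sol)
    keep <- if (length(out_times)) m[, 1] > seg$t0 else rep(TRUE, nrow(m))
    out_times <- c(out_times, m[keep, 1])
    out_states <- rbind(out_states, m[keep, -1, drop = FALSE])
    state <- m[nrow(m), -1]
    negmin <- min(state)
    if (negmin < -1e-7 * max(S_total, 1))
      warning(sprintf("negative state component %.3g encountered", negmin))
    state <- pmax(state, 0)
    if (!is.null(stop_below) && sum(state[-1]) <= stop_below * (1 + 1e-9))
      break
  }
  list(times = out_times, states = pmax(out_states, 0))
}

## assemble the common trajectory fields
.make_traj <- function(model, times, states, p, protocol, free, extra = NULL) {
  n <- p$n_sites
  lev <- as.numeric(states %*% (0:n)) / (n * p$S_total)
  traj <- c(list(model = model, times = times, states = states,
                 free_catalyst = free,
                 modification_level = lev,
                 modified_mass = rowSums(states[, -1, drop = FALSE]),
                 params = p, protocol = protocol),
            extra)
  class(traj) <- "kinmem_trajectory"
  traj
}

#' @export
print.kinmem_trajectory <- function(x, ...) {
  cat(sprintf("kinmem trajectory (%s model): %d time points, t in [%g, %g]\n",
              x$model, length(x$times), min(x$times), max(x$times)))
  cat(sprintf("  modification level: %.4g -> %.4g\n",
              x$modification_level[1], tail(x$modification_level, 1)))
  invisible(x)
}

#' @export
as.data.frame.kinmem_trajectory <- function(x, ...) {
  n <- x$params$n_sites
  df <- data.frame(time = x$times)
  st <- as.data.frame(x$states)
  names(st) <- paste0("x_", 0:n)
  df <- cbind(df, st)
  if (is.matrix(x$free_catalyst)) {
    df$K_free <- x$free_catalyst[, 1]; df$P_free <- x$free_catalyst[, 2]
  } else df$E_free <- x$free_catalyst
  df$modification_level <- x$modification_level
  df$modified_mass <- x$modified_mass
  if (!is.null(x$activity)) df$activity <- x$activity
  df
}

#' Simulate the chained modification model
#'
#' Integrates the stiff reduced ODE system with a stimulus window during
#' which the modification rate is raised by `protocol$magnitude`. Output
#' times are log-spaced to resolve dynamics spanning many decades.
#'
#' @param p a [chain_params()] object.
#' @param x0 initial state (default: fully modified).
#' @param protocol a [stimulus_protocol()] (default: none).
#' @param t_end final time.
#' @param points_per_decade output-grid density.
#' @param t_first first positive output time.
#' @param rtol,atol integrator tolerances.
#' @param stop_below optional early-exit threshold on the modified mass.
#' @return a `kinmem_trajectory`.
#' @export
simulate_chain <- function(p, x0 = state_fully_modified(p),
                           protocol = no_stimulus(), t_end = 1e8,
                           points_per_decade = 40, t_first = NULL,
                           rtol = 1e-8, atol = 1e-12, stop_below = NULL) {
  if (t_end <= 0) stop_domain("t_end must be > 0")
  x0 <- chain_state(x0, p)
  guess_env <- new.env(parent = emptyenv())
  guess_env$g <- NULL
  seg_active <- FALSE
  deriv <- function(t, y) {
    y <- pmax(y, 0)
    Ef <- .solve_free(y, p$K, p$E_total, guess = guess_env$g)
    guess_env$g <- Ef
    inp <- if (seg_active) protocol$magnitude else 0
    list(chain_rhs(y, p, input_rate = inp, E_free = Ef)$dx)
  }
  times <- .log_grid(t_end, t_first, points_per_decade)
  res <- .integrate_ladder(deriv, x0, times, .segments(protocol, t_end),
                           rtol, atol, p$S_total, stop_below)
  free <- vapply(seq_len(nrow(res$states)), function(i)
    .solve_free(res$states[i, ], p$K, p$E_total), numeric(1))
  .make_traj("chain", res$times, res$states, p, protocol, free)
}

#' Simulate the kinase-phosphatase model
#'
#' The stimulus raises the total kinase by `protocol$magnitude` during its
#' window (kinase-rich stimulation); outside the window the baseline
#' `p$K_total` applies.
#'
#' @inheritParams simulate_chain
#' @param p a [kp_params()] object.
#' @return a `kinmem_trajectory` with a two-column `free_catalyst`
#'   (kinase, phosphatase).
#' @export
simulate_kp <- function(p, x0 = state_unmodified(p),
                        protocol = no_stimulus(), t_end = 1e8,
                        points_per_decade = 40, t_first = NULL,
                        rtol = 1e-8, atol = 1e-12, stop_below = NULL) {
  if (t_end <= 0) stop_domain("t_end must be > 0")
  guess_env <- new.env(parent = emptyenv()); guess_env$g <- NULL
  seg_active <- FALSE
  p_stim <- p; p_stim$K_total <- p$K_total + max(protocol$magnitude, 0)
  deriv <- function(t, y) {
    y <- pmax(y, 0)
    pp <- if (seg_active) p_stim else p
    free <- free_catalysts_kp(y, pp, guess = guess_env$g)
    guess_env$g <- free
    list(kp_rhs(y, pp, free = free)$dx)
  }
  times <- .log_grid(t_end, t_first, points_per_decade)
  res <- .integrate_ladder(deriv, as.numeric(x0), times,
                           .segments(protocol, t_end),
                           rtol, atol, p$S_total, stop_below)
  ## free catalysts on the output grid, under the baseline parameters
  free <- t(vapply(seq_len(nrow(res$states)), function(i) {
    tt <- res$times[i]
    on <- tt >= protocol$t_on && tt < protocol$t_on + protocol$duration
    free_catalysts_kp(res$states[i, ], if (on) p_stim else p)
  }, numeric(2)))
  colnames(free) <- c("K_free", "P_free")
  .make_traj("kp", res$times, res$states, p, protocol, free)
}

#' Simulate the extended Asakura-Honda model
#'
#' The stimulus switches the ligand level to `protocol$magnitude` during its
#' window (use `duration = Inf` for a persistent environmental change, the
#' attractant-to-repellant protocol). Records the receptor activity (fraction
#' in the active conformation) alongside the modification level.
#'
#' @inheritParams simulate_chain
#' @param p an [ah_params()] object.
#' @return a `kinmem_trajectory` with an `activity` component.
#' @export
simulate_ah <- function(p, x0 = state_unmodified(p),
                        protocol = no_stimulus(), t_end = 1e8,
                        points_per_decade = 40, t_first = NULL,
                        rtol = 1e-8, atol = 1e-12, stop_below = NULL) {
  if (t_end <= 0) stop_domain("t_end must be > 0")
  guess_env <- new.env(parent = emptyenv()); guess_env$g <- NULL
  seg_active <- FALSE
  if (protocol$target != "ligand" && protocol$magnitude > 0)
    warning("A-H stimuli act on the ligand; treating magnitude as a ligand level")
  deriv <- function(t, y) {
    y <- pmax(y, 0)
    L <- if (seg_active) protocol$magnitude else p$ligand
    Ef <- .solve_free(y, p$K, p$E_total, guess = guess_env$g)
    guess_env$g <- Ef
    list(ah_rhs(y, p, ligand = L, E_free = Ef)$dy)
  }
  times <- .log_grid(t_end, t_first, points_per_decade)
  res <- .integrate_ladder(deriv, as.numeric(x0), times,
                           .segments(protocol, t_end),
                           rtol, atol, p$S_total, stop_below)
  free <- vapply(seq_len(nrow(res$states)), function(i)
    .solve_free(res$states[i, ], p$K, p$E_total), numeric(1))
  act <- vapply(seq_len(nrow(res$states)), function(i) {
    tt <- res$times[i]
    on <- tt >= protocol$t_on && tt < protocol$t_on + protocol$duration
    L <- if (on) protocol$magnitude else p$ligand
    s <- .ah_active_frac(p, L)
    sum(res$states[i, ] * s) / p$S_total
  }, numeric(1))
  .make_traj("ah", res$times, res$states, p, protocol, free,
             extra = list(activity = act))
}

#' Integrate a model to its steady state
#'
#' Repeated stiff integration over doubling time blocks until the state stops
#' changing (relative change per unit time below `tol`), used for
#' steady-state preparation (e.g. relaxation at a kinase-rich condition)
#' rather than algebraic fixed-point solving.
#'
#' @param p parameter object (`chain_params`, `kp_params` or `ah_params`).
#' @param x0 initial state.
#' @param tol relative state change per unit time considered converged.
#' @param t_block initial block length (doubles each round).
#' @param max_t give up (with a warning) beyond this total time.
#' @return the steady state vector.
#' @export
steady_state <- function(p, x0, tol = 1e-10, t_block = 100, max_t = 1e9) {
  sim <- switch(class(p)[1],
                chain_params = simulate_chain,
                kp_params = simulate_kp,
                ah_params = simulate_ah,
                stop_domain("unknown parameter class"))
  state <- as.numeric(x0); t_tot <- 0
  repeat {
    traj <- sim(p, x0 = state, t_end = t_block, points_per_decade = 8)
    new_state <- traj$states[nrow(traj$states), ]
    delta <- max(abs(new_state - state)) / (t_block * max(p$S_total, 1))
    state <- new_state; t_tot <- t_tot + t_block
    if (delta < tol) break
    if (t_tot >= max_t) {
      warning("steady_state: not converged within max_t")
      break
    }
    t_block <- t_block * 2
  }
  state
}
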