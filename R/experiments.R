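## Scripted sweeps: relaxation time versus catalyst abundance, site-number
## dependence, and stimulus magnitude x duration memory maps.

## run one relaxation (or post-stimulus relaxation) and summarise it
.relax_run <- function(p, x0, threshold, cap, points_per_decade = 32) {
  ## the integrator stops by root finding exactly at the threshold crossing,
  ## so tau is the event time rather than a grid interpolation
  traj <- simulate_chain_like(p, x0, cap, points_per_decade,
                              stop_below = threshold)
  m_end <- traj$modified_mass[length(traj$times)]
  tau <- if (m_end <= threshold * (1 + 1e-6)) max(traj$times) else Inf
  summ <- classify_decay(traj, threshold)
  summ$tau <- tau
  list(traj = traj, tau = tau, class = summ$decay_class, summ = summ)
}

## dispatch on parameter class so sweeps work for all three models
simulate_chain_like <- function(p, x0, t_end, points_per_decade = 24,
                                stop_below = NULL, protocol = no_stimulus()) {
  sim <- switch(class(p)[1],
                chain_params = simulate_chain,
                kp_params = simulate_kp,
                ah_params = simulate_ah,
                stop_domain("unknown parameter class"))
  sim(p, x0 = x0, protocol = protocol, t_end = t_end,
      points_per_decade = points_per_decade, stop_below = stop_below)
}

## set the swept catalyst field for a given model
.set_catalyst <- function(p, value, param = NULL) {
  field <- if (!is.null(param)) param
  else switch(class(p)[1], chain_params = "E_total", kp_params = "P_total",
              ah_params = "E_total")
  p[[field]] <- value
  p
}

#' Sweep the relaxation time over catalyst abundance
#'
#' Runs one relaxation per grid point (from the fully modified state for the
#' chain and kinase-phosphatase models; for the Asakura-Honda model from the
#' attractant-adapted state after a switch to the repellant ligand) and
#' records the relaxation time and decay class. Also locates the empirical
#' critical point: the grid interval of maximal `|d ln tau / d ln E|`.
#'
#' @param p parameter object; the swept field is `E_total` (chain, A-H) or
#'   `P_total` (kinase-phosphatase), overridable via `param`.
#' @param E_grid catalyst concentrations (geometric grid recommended).
#' @param threshold relaxation-time threshold (absolute concentration).
#' @param cap maximum integration time; runs that never cross report
#'   `tau = cap` flagged as lower bounds.
#' @param param optional name of the swept field.
#' @param prepare optional function `p -> x0` giving the initial state.
#' @return data.frame with columns `catalyst`, `tau`, `tau_is_lower_bound`,
#'   `class`, plus attributes `critical` (list with `E_crit`, `sharpness`)
#'   and `S_total`.
#' @export
sweep_catalyst <- function(p, E_grid, threshold = 0.01 * p$S_total,
                           cap = 1e10, param = NULL, prepare = NULL) {
  rows <- lapply(E_grid, function(E) {
    pe <- .set_catalyst(p, E, param)
    out <- tryCatch({
      x0 <- if (is.null(prepare)) state_fully_modified(pe) else prepare(pe)
      r <- .relax_run(pe, x0, threshold, cap)
      data.frame(catalyst = E,
                 tau = if (is.finite(r$tau)) r$tau else cap,
                 tau_is_lower_bound = !is.finite(r$tau),
                 class = r$class, stringsAsFactors = FALSE)
    }, error = function(e) {
      warning(sprintf("sweep point %g failed: %s", E, conditionMessage(e)))
      data.frame(catalyst = E, tau = NA_real_, tau_is_lower_bound = NA,
                 class = NA_character_, stringsAsFactors = FALSE)
    })
    out
  })
  tbl <- do.call(rbind, rows)
  tbl <- tbl[order(tbl$catalyst), ]
  attr(tbl, "S_total") <- p$S_total
  attr(tbl, "critical") <- critical_point(tbl)
  tbl
}

#' Empirical critical point of a catalyst sweep
#'
#' @param tbl a [sweep_catalyst()] table.
#' @return list with `E_crit` (geometric midpoint of the steepest interval),
#'   `sharpness` (max `|d ln tau / d ln E|`), or NULL for < 2 usable points.
#' @export
critical_point <- function(tbl) {
  ok <- is.finite(tbl$tau) & tbl$tau > 0
  if (sum(ok) < 2L) return(NULL)
  E <- tbl$catalyst[ok]; tau <- tbl$tau[ok]
  slope <- abs(diff(log(tau)) / diff(log(E)))
  k <- which.max(slope)
  list(E_crit = sqrt(E[k] * E[k + 1L]), sharpness = slope[k])
}

#' Power-law scaling of the relaxation time below the critical point
#'
#' OLS slope of `ln tau` against `ln catalyst` restricted to catalyst
#' concentrations at or below `S_total / 10` (the enzyme-limited branch,
#' where the relaxation time is inversely proportional to the catalyst).
#'
#' @param tbl a [sweep_catalyst()] table.
#' @param S_total total substrate (defaults to the table's attribute).
#' @return the fitted log-log slope.
#' @export
scaling_below_critical <- function(tbl, S_total = attr(tbl, "S_total")) {
  ok <- is.finite(tbl$tau) & tbl$tau > 0 & !tbl$tau_is_lower_bound &
    tbl$catalyst <= S_total / 10
  if (sum(ok) < 3L)
    stop("need at least 3 finite points below S_total/10", call. = FALSE)
  .fit_slope(log(tbl$catalyst[ok]), log(tbl$tau[ok]))
}

#' Relaxation time versus number of modification sites
#'
#' For each site number, measures the fast-phase relaxation rate (terminal
#' exponential rate at the catalyst-rich concentration `E_fast`, reported as
#' `tau_fast = 1/rate`) and the slow-phase threshold relaxation time at the
#' catalyst-poor concentration `E_slow`.
#'
#' @param p a [chain_params()] template (its `n_sites` is replaced).
#' @param N_list site numbers to test.
#' @param E_fast,E_slow catalyst totals of the two phases.
#' @param threshold relaxation threshold.
#' @param cap maximum integration time for the slow runs.
#' @return data.frame with columns `n_sites`, `tau_fast`, `tau_slow`.
#' @export
sweep_sites <- function(p, N_list, E_fast = 100 * p$S_total,
                        E_slow = 1e-3 * p$S_total,
                        threshold = 0.01 * p$S_total, cap = 1e10) {
  rows <- lapply(N_list, function(N) {
    pn <- chain_params(n_sites = N, k_mod = p$k_mod, k_demod = p$k_demod,
                       K_base = p$K_base, theta = p$theta,
                       S_total = p$S_total, E_total = E_fast)
    fast <- simulate_chain(pn, t_end = 200, points_per_decade = 60,
                           t_first = 1e-3)
    tau_fast <- 1 / terminal_rate(fast)
    pn$E_total <- E_slow
    slow <- .relax_run(pn, state_fully_modified(pn), threshold, cap)
    data.frame(n_sites = N, tau_fast = tau_fast,
               tau_slow = if (is.finite(slow$tau)) slow$tau else NA_real_)
  })
  do.call(rbind, rows)
}

#' Kinetic memory map over stimulus magnitude and duration
#'
#' From the unmodified low state, applies a stimulus of magnitude I for
#' duration T_dur, then follows the return relaxation. Records the
#' relaxation time (measured from the end of the stimulus; 0 when the
#' stimulus never drives the modified mass above the threshold) and the peak
#' modification level.
#'
#' @param p a [chain_params()] object (catalyst-poor for memory).
#' @param I_grid stimulus magnitudes (additive modification-rate increments).
#' @param Tdur_grid stimulus durations.
#' @param threshold relaxation threshold.
#' @param cap maximum relaxation integration time.
#' @return list with matrices `tau` and `peak_level` (rows = magnitudes,
#'   columns = durations) and the grids.
#' @export
memory_map <- function(p, I_grid, Tdur_grid,
                       threshold = 0.01 * p$S_total, cap = 1e10) {
  tau <- matrix(NA_real_, length(I_grid), length(Tdur_grid),
                dimnames = list(I = signif(I_grid, 4),
                                Tdur = signif(Tdur_grid, 4)))
  peak <- tau
  for (a in seq_along(I_grid)) {
    for (b in seq_along(Tdur_grid)) {
      I <- I_grid[a]; Td <- Tdur_grid[b]
      if (I <= 0 || Td <= 0) { tau[a, b] <- 0; peak[a, b] <- 0; next }
      prot <- stimulus_protocol(I, t_on = 0, duration = Td)
      up <- simulate_chain(p, x0 = state_unmodified(p), protocol = prot,
                           t_end = Td, points_per_decade = 30,
                           t_first = min(1e-3, Td / 50))
      x_after <- up$states[nrow(up$states), ]
      peak_up <- max(up$modification_level)
      if (sum(x_after[-1]) < threshold) {
        tau[a, b] <- 0
        peak[a, b] <- peak_up
        next
      }
      down <- simulate_chain(p, x0 = x_after, t_end = cap,
                             points_per_decade = 24,
                             stop_below = threshold)
      m_end <- down$modified_mass[length(down$times)]
      tau[a, b] <- if (m_end <= threshold * (1 + 1e-6))
        max(down$times) else Inf
      peak[a, b] <- max(peak_up, down$modification_level)
    }
  }
  list(tau = tau, peak_level = peak, I_grid = I_grid, Tdur_grid = Tdur_grid,
       threshold = threshold)
}
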