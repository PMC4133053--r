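## Shared validation helpers -------------------------------------------------

stop_domain <- function(...) stop(sprintf(...), call. = FALSE)

check_nonneg <- function(value, field) {
  if (!is.numeric(value) || length(value) != 1L || is.na(value) || value < 0)
    stop_domain("field '%s' must be a single non-negative number", field)
  as.numeric(value)
}

check_count <- function(value, field, min = 1L) {
  if (!is.numeric(value) || length(value) != 1L || is.na(value) ||
      value < min || value != round(value))
    stop_domain("field '%s' must be an integer >= %d", field, min)
  as.integer(value)
}

#' Dissociation-constant ladder
#'
#' Modification lowers the binding energy between substrate and catalyst
#' linearly per site, so the dissociation constant grows exponentially with
#' the modification level: K_i = K_base * exp(theta * i).
#'
#' @param K_base base dissociation constant at modification level 0.
#' @param theta per-modification increment of log K (dimensionless, >= 0).
#' @param n_sites number of modification sites N.
#' @return numeric vector of length `n_sites + 1` with K_0 ... K_N.
#' @export
dissociation_constants <- function(K_base, theta, n_sites) {
  K_base * exp(theta * (0:n_sites))
}

## Chained modification model -----------------------------------------------

#' Parameters of the chained modification model
#'
#' A substrate with `n_sites` modification sites is modified without catalyst
#' at first-order rate `k_mod` (stimuli add to this rate) and demodified by a
#' catalyst at catalytic rate `k_demod`, with level-dependent dissociation
#' constants `K_i = K_base * exp(theta * i)`.
#'
#' @param n_sites number of modification sites N (>= 1).
#' @param k_mod baseline uncatalysed modification rate (often 0; the stimulus
#'   adds to it).
#' @param k_demod catalytic demodification rate constant (site-independent).
#' @param K_base dissociation constant at level 0.
#' @param theta heterogeneity exponent of the dissociation constants (>= 0).
#' @param S_total conserved total substrate concentration.
#' @param E_total conserved total catalyst concentration.
#' @param modification_substrate `"as_printed_total"` applies the uncatalysed
#'   modification rate to the total level-i pool (free + complexed);
#'   `"free_fraction"` applies it only to the catalyst-free fraction.
#' @return an object of class `chain_params`.
#' @export
chain_params <- function(n_sites, k_mod = 0, k_demod = 1, K_base = 1e-4,
                         theta = 1, S_total = 1, E_total = 1e-3,
                         modification_substrate = c("as_printed_total",
                                                    "free_fraction")) {
  p <- list(
    n_sites = check_count(n_sites, "n_sites"),
    k_mod   = check_nonneg(k_mod, "k_mod"),
    k_demod = check_nonneg(k_demod, "k_demod"),
    K_base  = check_nonneg(K_base, "K_base"),
    theta   = check_nonneg(theta, "theta"),
    S_total = check_nonneg(S_total, "S_total"),
    E_total = check_nonneg(E_total, "E_total"),
    modification_substrate = match.arg(modification_substrate)
  )
  p$K <- dissociation_constants(p$K_base, p$theta, p$n_sites)
  structure(p, class = c("chain_params", "kinmem_params"))
}

#' @export
print.chain_params <- function(x, ...) {
  cat("Chained modification model parameters\n")
  cat(sprintf("  N = %d sites; k_mod = %g, k_demod = %g\n",
              x$n_sites, x$k_mod, x$k_demod))
  cat(sprintf("  K_i = %g * exp(%g * i)  (K_N = %g)\n",
              x$K_base, x$theta, x$K[x$n_sites + 1L]))
  cat(sprintf("  S_total = %g, E_total = %g\n", x$S_total, x$E_total))
  invisible(x)
}

#' Validate a chained-model state vector
#'
#' A state is the vector of total concentrations per modification level,
#' X_0 ... X_N (free substrate plus substrate-catalyst complex).
#'
#' @param x numeric vector of length `n_sites + 1`.
#' @param p a `chain_params` object.
#' @return the state, as a plain numeric vector.
#' @export
chain_state <- function(x, p) {
  if (length(x) != p$n_sites + 1L)
    stop_domain("state must have length n_sites + 1 = %d", p$n_sites + 1L)
  if (any(!is.finite(x)) || any(x < 0))
    stop_domain("state concentrations must be finite and non-negative")
  as.numeric(x)
}

#' Fully modified initial state
#'
#' All substrate mass at the top modification level, the standard initial
#' condition for relaxation runs.
#' @param p a `chain_params`, `kp_params` or `ah_params` object.
#' @return numeric state vector.
#' @export
state_fully_modified <- function(p) {
  x <- numeric(p$n_sites + 1L)
  x[p$n_sites + 1L] <- p$S_total
  x
}

#' Fully unmodified initial state
#' @param p a parameter object with `n_sites` and `S_total`.
#' @return numeric state vector with all mass at level 0.
#' @export
state_unmodified <- function(p) {
  x <- numeric(p$n_sites + 1L)
  x[1L] <- p$S_total
  x
}

## Kinase-phosphatase model --------------------------------------------------

#' Parameters of the kinase-phosphatase model
#'
#' A substrate with `n_sites` phosphosites; phosphorylation is catalysed by a
#' kinase, dephosphorylation by a phosphatase, each with exponentially
#' increasing dissociation constants.
#'
#' @param n_sites number of phosphosites.
#' @param k_kin,k_pho catalytic rates of the kinase and phosphatase.
#' @param K_kin_base,theta_kin kinase dissociation constant at level 0 and its
#'   exponential increment.
#' @param K_pho_base,theta_pho the same for the phosphatase.
#' @param S_total total substrate; `K_total` total kinase; `P_total` total
#'   phosphatase.
#' @return an object of class `kp_params`.
#' @export
kp_params <- function(n_sites, k_kin = 1, k_pho = 1,
                      K_kin_base = 1e-4, theta_kin = 1,
                      K_pho_base = 1e-4, theta_pho = 1,
                      S_total = 1, K_total = 0, P_total = 1e-3) {
  p <- list(
    n_sites = check_count(n_sites, "n_sites"),
    k_kin = check_nonneg(k_kin, "k_kin"),
    k_pho = check_nonneg(k_pho, "k_pho"),
    K_kin_base = check_nonneg(K_kin_base, "K_kin_base"),
    theta_kin = check_nonneg(theta_kin, "theta_kin"),
    K_pho_base = check_nonneg(K_pho_base, "K_pho_base"),
    theta_pho = check_nonneg(theta_pho, "theta_pho"),
    S_total = check_nonneg(S_total, "S_total"),
    K_total = check_nonneg(K_total, "K_total"),
    P_total = check_nonneg(P_total, "P_total")
  )
  p$K_kin <- dissociation_constants(p$K_kin_base, p$theta_kin, p$n_sites)
  p$K_pho <- dissociation_constants(p$K_pho_base, p$theta_pho, p$n_sites)
  structure(p, class = c("kp_params", "kinmem_params"))
}

#' @export
print.kp_params <- function(x, ...) {
  cat("Kinase-phosphatase model parameters\n")
  cat(sprintf("  N = %d sites; k_kin = %g, k_pho = %g\n",
              x$n_sites, x$k_kin, x$k_pho))
  cat(sprintf("  kinase K_i = %g*exp(%g i); phosphatase K_i = %g*exp(%g i)\n",
              x$K_kin_base, x$theta_kin, x$K_pho_base, x$theta_pho))
  cat(sprintf("  S_total = %g, K_total = %g, P_total = %g\n",
              x$S_total, x$K_total, x$P_total))
  invisible(x)
}

## Extended Asakura-Honda model ----------------------------------------------

#' Parameters of the extended Asakura-Honda receptor model
#'
#' A two-conformation receptor (S = active, T = inactive) with `n_sites`
#' modification sites. Conformational flip-flop is fast and ligand dependent:
#' T_i / S_i = ligand * exp(-alpha * i), so ligand (attractant) pushes the
#' receptor towards the inactive form and modification restores activity.
#' Modification (on the T form) and demodification (on the S form) are both
#' catalysed by one shared co-factor with equal dissociation constants
#' K_i = K_base * exp(theta * i) for the two forms.
#'
#' @param n_sites number of modification sites.
#' @param k_up,k_down catalytic modification / demodification rates.
#' @param K_base,theta shared dissociation-constant ladder of the co-factor.
#' @param alpha per-modification decrement of the log flip-flop constant.
#' @param ligand ligand level entering the flip-flop equilibrium.
#' @param S_total total receptor; `E_total` total co-factor.
#' @return an object of class `ah_params`.
#' @export
ah_params <- function(n_sites, k_up = 1, k_down = 1, K_base = 1e-4,
                      theta = 1, alpha = 2, ligand = 1e5,
                      S_total = 1, E_total = 1e-3) {
  p <- list(
    n_sites = check_count(n_sites, "n_sites"),
    k_up = check_nonneg(k_up, "k_up"),
    k_down = check_nonneg(k_down, "k_down"),
    K_base = check_nonneg(K_base, "K_base"),
    theta = check_nonneg(theta, "theta"),
    alpha = check_nonneg(alpha, "alpha"),
    ligand = check_nonneg(ligand, "ligand"),
    S_total = check_nonneg(S_total, "S_total"),
    E_total = check_nonneg(E_total, "E_total")
  )
  p$K <- dissociation_constants(p$K_base, p$theta, p$n_sites)
  structure(p, class = c("ah_params", "kinmem_params"))
}

#' @export
print.ah_params <- function(x, ...) {
  cat("Extended Asakura-Honda model parameters\n")
  cat(sprintf("  N = %d sites; k_up = %g, k_down = %g; alpha = %g\n",
              x$n_sites, x$k_up, x$k_down, x$alpha))
  cat(sprintf("  K_i = %g * exp(%g * i); ligand = %g\n",
              x$K_base, x$theta, x$ligand))
  cat(sprintf("  S_total = %g, E_total = %g\n", x$S_total, x$E_total))
  invisible(x)
}

## Stimulus protocol ----------------------------------------------------------

#' Stimulus protocol
#'
#' A time-windowed additive perturbation: for the chain model the stimulus
#' adds `magnitude` to the modification rate; for the kinase-phosphatase
#' model it raises the total kinase; for the Asakura-Honda model it switches
#' the ligand level to `magnitude` during the window.
#'
#' @param magnitude size of the perturbation (rate increment, kinase total
#'   increment, or ligand level depending on `target`).
#' @param t_on time the stimulus switches on.
#' @param duration stimulus duration T_dur (>= 0).
#' @param target one of `"modification_rate"`, `"total_kinase"`, `"ligand"`.
#' @return an object of class `stimulus_protocol`.
#' @export
stimulus_protocol <- function(magnitude = 0, t_on = 0, duration = 0,
                              target = c("modification_rate", "total_kinase",
                                         "ligand")) {
  target <- match.arg(target)
  if (target != "ligand") check_nonneg(magnitude, "magnitude")
  structure(list(magnitude = as.numeric(magnitude),
                 t_on = check_nonneg(t_on, "t_on"),
                 duration = check_nonneg(duration, "duration"),
                 target = target),
            class = "stimulus_protocol")
}

#' No-stimulus protocol shorthand
#' @return a `stimulus_protocol` with zero magnitude and duration.
#' @export
no_stimulus <- function() stimulus_protocol(0, 0, 0)
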