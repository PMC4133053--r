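## Observables: relaxation time, decay classification, per-site relaxation
## ordering, plateau detection, and the asymptotic eigenmode estimator of
## the slow (logarithmic) relaxation.

#' Relaxation time of a trajectory
#'
#' The first time the total modified substrate (`modified_mass`) falls below
#' `threshold`, interpolated linearly in (ln t, value). Returns `Inf` when
#' the threshold is never crossed before the end of the run, and 0 when the
#' trajectory starts below the threshold.
#'
#' @param traj a `kinmem_trajectory` (or any list with `times` and
#'   `modified_mass`).
#' @param threshold absolute concentration threshold (default
#'   `0.01 * S_total`).
#' @return the relaxation time tau (possibly `Inf` or 0).
#' @export
relaxation_time <- function(traj, threshold = 0.01 * traj$params$S_total) {
  t <- traj$times; m <- traj$modified_mass
  if (m[1] < threshold) return(0)
  below <- which(m < threshold)
  if (length(below) == 0L) return(Inf)
  k <- below[1]
  if (any(m[seq(k, length(m))] >= threshold))
    warning("modified mass re-crosses the threshold; returning first crossing")
  t0 <- t[k - 1L]; t1 <- t[k]
  frac <- (m[k - 1L] - threshold) / (m[k - 1L] - m[k])
  if (t0 > 0) exp(log(t0) + frac * (log(t1) - log(t0)))
  else t0 + frac * (t1 - t0)
}

## R-squared of an OLS fit y ~ x, NA-safe
.r2 <- function(x, y) {
  ok <- is.finite(x) & is.finite(y)
  if (sum(ok) < 3L) return(NA_real_)
  f <- stats::lm.fit(cbind(1, x[ok]), y[ok])
  tss <- sum((y[ok] - mean(y[ok]))^2)
  if (tss == 0) return(NA_real_)
  1 - sum(f$residuals^2) / tss
}

.fit_slope <- function(x, y) {
  ok <- is.finite(x) & is.finite(y)
  if (sum(ok) < 2L) return(NA_real_)
  unname(stats::lm.fit(cbind(1, x[ok]), y[ok])$coefficients[2])
}

#' Classify the decay of a relaxation trajectory
#'
#' Fits three candidate laws to the modification level on an interior window
#' (excluding the first and last 10% of the decay range): exponential
#' (`ln y` vs `t`), stretched exponential (`ln(-ln(y/y0))` vs `ln t`) and
#' logarithmic (`y` vs `ln t`). The class is chosen by R-squared: an
#' exponential within `margin` of the best fit wins (it is nested in the
#' stretched family), then a logarithmic fit within `margin`; a curve best
#' described by the stretched-exponential form alone is labelled
#' `"intermediate"`. Trajectories that have decayed by less than half of the
#' initial level are labelled `"none"`.
#'
#' Also computes the relaxation time, the per-site completion order and the
#' plateau count, returning the full relaxation summary.
#'
#' @param traj a `kinmem_trajectory`.
#' @param threshold threshold for [relaxation_time()] and
#'   [site_relaxation_order()].
#' @param margin R-squared margin for class selection (default 0.02).
#' @return an object of class `relaxation_summary` with fields `tau`,
#'   `decay_class`, `fit_r2_exp`, `fit_r2_str`, `fit_r2_log`, `log_slope`,
#'   `site_order`, `order_label`, `plateau_count`.
#' @export
classify_decay <- function(traj, threshold = 0.01 * traj$params$S_total,
                           margin = 0.02) {
  t <- traj$times; y <- traj$modification_level
  y0 <- y[1]; yend <- y[length(y)]
  rng <- max(y) - min(y)
  res <- list(tau = relaxation_time(traj, threshold),
              decay_class = "none",
              fit_r2_exp = NA_real_, fit_r2_str = NA_real_,
              fit_r2_log = NA_real_, log_slope = NA_real_,
              site_order = tryCatch(site_relaxation_order(traj, threshold),
                                    error = function(e) NULL),
              plateau_count = plateau_count(traj))
  class(res) <- "relaxation_summary"
  if (y0 <= 0 || (y0 - yend) / y0 < 0.5) return(res)
  ## decay interval: from 5% to 95% of the value range, then trimmed by 10%
  ## of its ln-t width on each side (fit windows live in ln t)
  core <- which(y <= max(y) - 0.05 * rng & y >= min(y) + 0.05 * rng & t > 0)
  if (length(core) < 5L) return(res)
  la <- log(t[core[1]]); lb <- log(t[core[length(core)]])
  W <- lb - la
  win <- which(t > 0 & log(t) >= la + 0.1 * W & log(t) <= lb - 0.1 * W)
  if (length(win) < 5L) return(res)
  tw <- t[win]; yw <- y[win]
  ypos <- yw > 0
  res$fit_r2_exp <- .r2(tw[ypos], log(yw[ypos]))
  yfrac <- yw / max(y)
  str_ok <- ypos & yfrac < 1
  res$fit_r2_str <- .r2(log(tw[str_ok]), log(-log(yfrac[str_ok])))
  res$fit_r2_log <- .r2(log(tw), yw)
  res$log_slope <- .fit_slope(log(tw), yw)
  r2 <- c(exp = res$fit_r2_exp, str = res$fit_r2_str, log = res$fit_r2_log)
  if (all(is.na(r2))) return(res)
  best <- max(r2, na.rm = TRUE)
  res$decay_class <-
    if (isTRUE(r2["exp"] >= best - margin)) "exponential"
    else if (isTRUE(r2["log"] >= best - margin)) "logarithmic"
    else "intermediate"
  res
}

#' @export
print.relaxation_summary <- function(x, ...) {
  cat(sprintf("relaxation summary: tau = %.4g, class = %s\n",
              x$tau, x$decay_class))
  cat(sprintf("  R2 exp/stretched/log = %.4f / %.4f / %.4f; log slope %.4g\n",
              x$fit_r2_exp, x$fit_r2_str, x$fit_r2_log, x$log_slope))
  if (!is.null(x$site_order))
    cat(sprintf("  site order: %s (%s); plateaus: %d\n",
                paste(x$site_order$order, collapse = " "),
                x$site_order$label, x$plateau_count))
  invisible(x)
}

#' Per-site relaxation completion order
#'
#' For each modification level i >= 1, the completion time is the last time
#' `x_i` exceeds `threshold * S_total` (interpolated in ln t). Sites are
#' ranked by completion time; the label reports whether completion times are
#' monotone in the site index: `"ascending"` (site 1 completes first, the
#' enzyme-limited competition order), `"descending"` (site N first, the
#' first-order-kinetics order) or `"mixed"`.
#'
#' @param traj a `kinmem_trajectory`.
#' @param threshold relative threshold (fraction of `S_total`).
#' @return list with `completion` (times per site), `order` (site indices
#'   sorted by completion time) and `label`.
#' @export
site_relaxation_order <- function(traj, threshold = 0.01) {
  p <- traj$params; n <- p$n_sites
  thr <- threshold * p$S_total
  t <- traj$times
  comp <- vapply(seq_len(n), function(i) {
    x <- traj$states[, i + 1L]
    above <- which(x > thr)
    if (length(above) == 0L) return(0)
    k <- above[length(above)]
    if (k == length(t)) return(Inf)
    frac <- (x[k] - thr) / (x[k] - x[k + 1L])
    if (t[k] > 0) exp(log(t[k]) + frac * (log(t[k + 1L]) - log(t[k])))
    else t[k] + frac * (t[k + 1L] - t[k])
  }, numeric(1))
  d <- diff(comp)
  label <- if (n == 1L) "ascending"
  else if (all(d >= 0)) "ascending"
  else if (all(d <= 0)) "descending"
  else "mixed"
  list(completion = comp, order = order(comp), label = label)
}

#' Count plateaus in a relaxation curve
#'
#' Number of maximal intervals, of width at least `min_decades` decades in
#' ln t, on which the local slope of the modification level against ln t is
#' below `slope_frac` of the median decay slope. The leading stretch before
#' decay begins and the trailing equilibrium stretch are excluded.
#'
#' @param traj a `kinmem_trajectory`.
#' @param min_decades minimum plateau width in decades (default 0.5).
#' @param slope_frac slope threshold as a fraction of the median decay slope.
#' @param values optional series to analyse in place of the modification
#'   level (e.g. a single `x_i` column, the per-site relaxation curves of
#'   which show the glassy plateaus).
#' @return integer plateau count.
#' @export
plateau_count <- function(traj, min_decades = 0.5, slope_frac = 0.05,
                          values = NULL) {
  t <- traj$times
  y <- if (is.null(values)) traj$modification_level else values
  pos <- t > 0
  t <- t[pos]; y <- y[pos]
  rng <- max(y) - min(y)
  if (rng <= 0) return(0L)
  ## clip the pre-decay and post-decay stretches (2% of the range), keeping
  ## interior plateaus intact
  i0 <- which(y <= max(y) - 0.02 * rng)[1]
  i1 <- rev(which(y >= min(y) + 0.02 * rng))[1]
  if (is.na(i0) || is.na(i1) || i1 - i0 < 5L) return(0L)
  lt <- log(t[i0:i1]); yy <- y[i0:i1]
  ## resample on a uniform ln-t grid
  grid <- seq(lt[1], lt[length(lt)], by = log(10) / 25)
  if (length(grid) < 5L) return(0L)
  yg <- stats::approx(lt, yy, xout = grid, rule = 2)$y
  sl <- abs(diff(yg)) / diff(grid)[1]
  ## characteristic decay slope: median over the actively decaying segments
  ## (bins at or above 20% of the mean slope), so that long plateaus cannot
  ## drag the reference slope down to their own level
  decaying <- sl >= 0.2 * mean(sl)
  med <- stats::median(sl[decaying])
  if (!is.finite(med) || med == 0) return(0L)
  flat <- sl < slope_frac * med
  r <- rle(flat)
  widths <- r$lengths[r$values] * diff(grid)[1]
  sum(widths >= min_decades * log(10))
}

#' Asymptotic estimate of the slow relaxation curve
#'
#' In the enzyme-limited regime the relaxation of each modification level is
#' approximately a single eigenmode whose rate is set by its efflux: level i
#' loses mass at rate `lambda_i = (k_demod * E_total / S_total) * exp(-theta
#' * i)` (the free catalyst being sequestered by the strongly binding,
#' weakly modified substrate pool). The total modification level is then a
#' superposition of exponentially distributed mode timescales, which decays
#' logarithmically in time over the window spanned by the mode rates.
#'
#' For `n_sites = 1` the estimate reduces to the zero-order / first-order
#' crossover: constant-rate decay `-k_demod * E_total` while the substrate
#' exceeds the catalyst, exponential decay at rate `k_demod` once below it.
#'
#' @param p a [chain_params()] object with `theta > 0` (for `n_sites > 1`).
#' @param times evaluation times.
#' @param weights initial mass fractions per level i = 1..N (default
#'   uniform, the non-singular initial condition of the estimate).
#' @return predicted modification level at `times` (normalised to start
#'   at 1).
#' @export
asymptotic_level <- function(p, times, weights = NULL) {
  n <- p$n_sites
  if (n == 1L) {
    x0 <- p$S_total
    if (p$E_total >= x0) return(exp(-p$k_demod * times))
    t_star <- (x0 - p$E_total) / (p$k_demod * p$E_total)
    lev <- ifelse(times <= t_star,
                  (x0 - p$k_demod * p$E_total * times) / x0,
                  p$E_total * exp(-p$k_demod * (times - t_star)) / x0)
    return(pmax(lev, 0))
  }
  if (p$theta <= 0)
    stop_domain("asymptotic estimate requires theta > 0")
  if (is.null(weights)) weights <- rep(1 / n, n)
  if (length(weights) != n) stop_domain("weights must have length n_sites")
  lambda <- (p$k_demod * p$E_total / p$S_total) * exp(-p$theta * (1:n))
  lev <- vapply(times, function(tt)
    sum((1:n) / n * weights * exp(-lambda * tt)), numeric(1))
  lev / sum((1:n) / n * weights)
}

#' Asymptotic (slowest-mode) decay rate of a trajectory tail
#'
#' Estimates the terminal exponential rate of the modified-mass decay by
#' extrapolating the local logarithmic slope `d ln m / dt` against `1/t`
#' (quadratic fit), which removes the polynomial prefactor of a relaxation
#' cascade and recovers the slowest eigenvalue. This is the N-independent
#' relaxation-rate observable of the catalyst-saturated fast phase.
#'
#' @param traj a `kinmem_trajectory`.
#' @param frac use the tail where the modified mass is below `frac` of its
#'   initial value.
#' @param floor ignore masses below this (integration noise).
#' @return the asymptotic decay rate (1/tau of the terminal exponential).
#' @export
terminal_rate <- function(traj, frac = 0.05, floor = 1e-9) {
  t <- traj$times; m <- traj$modified_mass
  ok <- which(m < frac * m[1] & m > floor * m[1] & t > 0)
  if (length(ok) < 8L)
    stop("trajectory tail too short to estimate the terminal rate",
         call. = FALSE)
  t <- t[ok]; m <- m[ok]
  s <- diff(log(m)) / diff(t)
  tm <- (t[-1] + t[-length(t)]) / 2
  u <- 1 / tm
  fit <- stats::lm.fit(cbind(1, u, u^2), s)
  -unname(fit$coefficients[1])
}
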