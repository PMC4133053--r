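## Presets, configuration, TSV/JSON input-output and synthetic fixtures.

## Packaged parameter presets: the package's dimensionless reference
## conditions for the three models (see the methods vignette for the
## reasoning behind each value).
.presets <- function() list(
  fig2 = chain_params(n_sites = 10, k_mod = 0, k_demod = 1, K_base = 1e-4,
                      theta = 1, S_total = 1, E_total = 1e-3),
  fig2_theta0 = chain_params(n_sites = 10, k_mod = 0, k_demod = 1,
                             K_base = 1e-4, theta = 0, S_total = 1,
                             E_total = 1e-3),
  highcat = chain_params(n_sites = 5, k_mod = 0, k_demod = 1, K_base = 1e-6,
                         theta = 0.5, S_total = 1, E_total = 100),
  kp = kp_params(n_sites = 5, k_kin = 1, k_pho = 1, K_kin_base = 1e-4,
                 theta_kin = 1, K_pho_base = 1e-4, theta_pho = 1,
                 S_total = 1, K_total = 0, P_total = 1e-3),
  ah = ah_params(n_sites = 10, k_up = 1, k_down = 1, K_base = 1e-4,
                 theta = 1, alpha = 2, ligand = 1e5, S_total = 1,
                 E_total = 1e-3),
  ah_theta0 = ah_params(n_sites = 10, k_up = 1, k_down = 1, K_base = 1e-4,
                        theta = 0, alpha = 2, ligand = 1e5, S_total = 1,
                        E_total = 1e-3)
)

#' Packaged parameter presets
#'
#' `preset("fig2")` is the reference slow-relaxation condition of the
#' chained modification model; `"highcat"` the catalyst-saturated fast
#' phase; `"kp"` and `"ah"` the kinase-phosphatase and extended
#' Asakura-Honda reference conditions; `"*_theta0"` variants have uniform
#' dissociation constants.
#'
#' @param name preset name; see [preset_names()].
#' @return a parameter object.
#' @export
preset <- function(name) {
  ps <- .presets()
  if (!name %in% names(ps))
    stop_domain("unknown preset '%s'; available: %s", name,
                paste(names(ps), collapse = ", "))
  ps[[name]]
}

#' @rdname preset
#' @export
preset_names <- function() names(.presets())

## ---------------------------------------------------------------------------
## Configuration files (YAML)

.known_run_keys <- c("t_end", "threshold", "points_per_decade", "cap",
                     "rtol", "atol")
.known_stim_keys <- c("magnitude", "t_on", "duration", "target")

#' Load and validate a model configuration file
#'
#' YAML key-value config with top-level keys `model` (`chain`, `kp` or
#' `ah`), optional `preset` (expanded first, then overridden by `params`),
#' `params` (fields of the corresponding parameter constructor), `stimulus`
#' and `run` (`t_end`, `threshold`, `points_per_decade`, `cap`, `rtol`,
#' `atol`). Unknown keys are rejected with an itemised error.
#'
#' @param path config file path.
#' @return list with `params`, `protocol`, `run`.
#' @export
load_config <- function(path) {
  if (!file.exists(path)) stop_domain("config file '%s' not found", path)
  cfg <- yaml::read_yaml(path)
  known_top <- c("model", "preset", "params", "stimulus", "run")
  bad <- setdiff(names(cfg), known_top)
  if (length(bad))
    stop_domain("unknown config keys: %s", paste(bad, collapse = ", "))
  if (!is.null(cfg$preset)) {
    p <- preset(cfg$preset)
  } else {
    if (is.null(cfg$model))
      stop_domain("config must name a 'model' or a 'preset'")
    ctor <- switch(cfg$model, chain = chain_params, kp = kp_params,
                   ah = ah_params,
                   stop_domain("unknown model '%s'", cfg$model))
    p <- do.call(ctor, cfg$params %||% list())
    cfg$params <- NULL
  }
  if (!is.null(cfg$params)) {
    ctor <- switch(class(p)[1], chain_params = chain_params,
                   kp_params = kp_params, ah_params = ah_params)
    fields <- setdiff(names(formals(ctor)), "modification_substrate")
    bad <- setdiff(names(cfg$params), names(formals(ctor)))
    if (length(bad))
      stop_domain("unknown params keys: %s", paste(bad, collapse = ", "))
    base <- p[intersect(fields, names(p))]
    base[names(cfg$params)] <- cfg$params
    p <- do.call(ctor, base)
  }
  protocol <- if (!is.null(cfg$stimulus)) {
    bad <- setdiff(names(cfg$stimulus), .known_stim_keys)
    if (length(bad))
      stop_domain("unknown stimulus keys: %s", paste(bad, collapse = ", "))
    do.call(stimulus_protocol, cfg$stimulus)
  } else no_stimulus()
  run <- cfg$run %||% list()
  bad <- setdiff(names(run), .known_run_keys)
  if (length(bad))
    stop_domain("unknown run keys: %s", paste(bad, collapse = ", "))
  list(params = p, protocol = protocol, run = run)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

## ---------------------------------------------------------------------------
## TSV trajectory and sweep output (17 significant digits, diffable)

.write_tsv <- function(df, path) {
  num <- vapply(df, is.numeric, logical(1))
  df[num] <- lapply(df[num], function(z) sprintf("%.17g", z))
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Write a trajectory to TSV
#'
#' Columns: time, per-level totals `x_0..x_N`, free catalyst(s),
#' modification level, modified mass, and (A-H) activity; full numeric
#' precision.
#'
#' @param traj a `kinmem_trajectory`.
#' @param path output file.
#' @return the path, invisibly.
#' @export
write_trajectory <- function(traj, path) {
  .write_tsv(as.data.frame(traj), path)
}

#' Read a trajectory written by [write_trajectory()]
#'
#' @param path TSV file.
#' @param params optional parameter object to re-attach.
#' @return a `kinmem_trajectory` (synthetic parameter stub when `params` is
#'   missing).
#' @export
read_trajectory <- function(path, params = NULL) {
  df <- utils::read.table(path, header = TRUE, sep = "\t")
  xcols <- grep("^x_", names(df))
  n <- length(xcols) - 1L
  S <- sum(unlist(df[1, xcols]))
  if (is.null(params))
    params <- chain_params(n_sites = max(n, 1L), S_total = S,
                           E_total = if ("E_free" %in% names(df))
                             max(df$E_free) else 0)
  free <- if (all(c("K_free", "P_free") %in% names(df)))
    cbind(K_free = df$K_free, P_free = df$P_free) else df$E_free
  traj <- .make_traj(if (!is.null(df$activity)) "ah" else "chain",
                     df$time, as.matrix(df[, xcols]), params,
                     no_stimulus(), free,
                     extra = if (!is.null(df$activity))
                       list(activity = df$activity))
  traj$modification_level <- df$modification_level
  traj$modified_mass <- df$modified_mass
  traj
}

#' Write a run manifest
#'
#' JSON echo of the configuration, package version and wall time, sufficient
#' to re-run the computation identically.
#'
#' @param path output file.
#' @param config list of configuration values to echo.
#' @param wall_time elapsed seconds.
#' @return the path, invisibly.
#' @export
write_manifest <- function(path, config, wall_time = NA_real_) {
  manifest <- list(
    package = "kinmem",
    version = as.character(utils::packageVersion("kinmem")),
    r_version = R.version.string,
    wall_time_s = wall_time,
    config = config
  )
  jsonlite::write_json(manifest, path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE, null = "null")
  invisible(path)
}

## ---------------------------------------------------------------------------
## Synthetic fixtures for the analysis module

#' Synthetic relaxation-curve fixtures
#'
#' Deterministic synthetic trajectories with known decay class, for testing
#' the observables: `"exponential"` (`exp(-t)`), `"logarithmic"`
#' (`max(0, 1 - 0.1 ln(1+t))`), `"staircase"` (three flat steps in ln t),
#' and `"power"` (`(1+t)^-1`). Optional multiplicative noise is reproducible
#' given `seed`.
#'
#' @param kind fixture kind.
#' @param seed RNG seed (used only when `noise > 0`).
#' @param n number of log-spaced time points.
#' @param noise relative noise amplitude.
#' @param t_max last time point.
#' @return a synthetic `kinmem_trajectory`.
#' @export
make_fixture <- function(kind = c("exponential", "logarithmic", "staircase",
                                  "power"),
                         seed = 1, n = 300, noise = 0, t_max = 1e6) {
  kind <- match.arg(kind)
  times <- 10^seq(-4, log10(t_max), length.out = n)
  level <- switch(kind,
    exponential = exp(-times),
    logarithmic = pmax(0, 1 - 0.1 * log1p(times)),
    power = 1 / (1 + times),
    staircase = {
      ## three interior flats (3/4, 1/2, 1/4) joined by steep logistic drops
      lt <- log10(times)
      stepfun <- function(x, c0) 1 / (1 + exp(10 * (x - c0)))
      (stepfun(lt, -2) + stepfun(lt, 0) + stepfun(lt, 2) +
         stepfun(lt, 4.5)) / 4
    })
  if (noise > 0) {
    set.seed(seed)
    level <- pmax(level * (1 + noise * stats::rnorm(n)), 0)
  }
  synthetic_trajectory(times, level)
}

#' Wrap a bare (time, level) curve as a trajectory
#'
#' Builds a minimal single-site trajectory whose modification level and
#' modified mass equal `level`, so the analysis functions can be applied to
#' synthetic or external curves.
#'
#' @param times strictly increasing times.
#' @param level curve values in `[0, 1]`.
#' @param S_total nominal total substrate (default 1).
#' @return a `kinmem_trajectory` with `model = "synthetic"`.
#' @export
synthetic_trajectory <- function(times, level, S_total = 1) {
  stopifnot(length(times) == length(level), all(diff(times) > 0))
  p <- chain_params(n_sites = 1, S_total = S_total, E_total = 0)
  states <- cbind(S_total * (1 - level), S_total * level)
  .make_traj("synthetic", times, states, p, no_stimulus(),
             rep(0, length(times)))
}
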