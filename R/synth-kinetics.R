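#' Generate a synthetic Ca2+ titration dataset
#'
#' Emulates a steady-state fluorescence titration of a reconstituted
#' thin-filament preparation: microliter Ca2+ additions trace out a Hill
#' (sigmoidal) fluorescence curve, measured over several replicate
#' titrations with additive Gaussian instrument noise.
#'
#' The noiseless curve is
#' \deqn{F(Ca) = F_{min} + (F_{max} - F_{min}) \frac{Ca^n}{K_d^n + Ca^n}}
#' so that \eqn{F(K_d)} sits exactly at the half-maximal fluorescence
#' change.
#'
#' @param true_kd True dissociation constant (uM), the Ca2+ concentration
#'   at half-maximal fluorescence change.
#' @param hill_n True Hill coefficient (dimensionless).
#' @param f_min,f_max Fluorescence at zero and saturating Ca2+ (a.u.).
#' @param ca_grid Strictly increasing vector of free Ca2+ concentrations
#'   (uM). Default: 12 log-spaced points spanning `true_kd / 30` to
#'   `true_kd * 30`.
#' @param n_replicates Number of replicate titrations (>= 1).
#' @param noise_sd Additive Gaussian noise SD (a.u.); 0 gives the exact
#'   closed-form curve.
#' @param seed Integer seed; identical arguments give identical output.
#' @param construct_label Label carried through to fits and reports.
#'
#' @return An object of class `titration_dataset`: a list with `data`
#'   (data.frame `ca_uM`, `fluor`, `replicate`), `construct_label`, and
#'   `truth` (the generating parameters).
#' @export
#' @examples
#' td <- gen_titration(true_kd = 1, hill_n = 1, noise_sd = 0, seed = 1)
#' fit_hill(td)$kd
gen_titration <- function(true_kd, hill_n = 1.5, f_min = 0, f_max = 1,
                          ca_grid = NULL, n_replicates = 6, noise_sd = 0.02,
                          seed = 1, construct_label = "construct") {
  check_number(true_kd, "true_kd", 0, strict_lower = TRUE)
  check_number(hill_n, "hill_n", 0, strict_lower = TRUE)
  check_number(noise_sd, "noise_sd", 0)
  check_number(n_replicates, "n_replicates", 1)
  if (f_max <= f_min) stop_invalid("`f_max` must exceed `f_min`")
  if (is.null(ca_grid))
    ca_grid <- exp(seq(log(true_kd / 30), log(true_kd * 30), length.out = 12))
  if (length(ca_grid) == 0L) stop_invalid("`ca_grid` must be non-empty")
  if (any(ca_grid <= 0)) stop_invalid("all `ca_grid` values must be > 0")
  if (is.unsorted(ca_grid, strictly = TRUE))
    stop_invalid("`ca_grid` must be strictly increasing")

  curve <- hill_curve(ca_grid, true_kd, hill_n, f_min, f_max)
  old <- local_seed(seed)
  on.exit(restore_seed(old))
  data <- do.call(rbind, lapply(seq_len(n_replicates), function(r) {
    data.frame(ca_uM = ca_grid,
               fluor = curve + rnorm(length(ca_grid), 0, noise_sd),
               replicate = r)
  }))
  structure(list(data = data, construct_label = construct_label,
                 truth = list(kind = "titration", true_kd = true_kd,
                              hill_n = hill_n, f_min = f_min, f_max = f_max,
                              noise_sd = noise_sd, n_replicates = n_replicates,
                              seed = seed)),
            class = "titration_dataset")
}

hill_curve <- function(ca, kd, n, f_min, f_max) {
  f_min + (f_max - f_min) * ca^n / (kd^n + ca^n)
}

#' Generate synthetic stopped-flow Ca2+ dissociation traces
#'
#' Emulates a stopped-flow experiment in which Ca2+-saturated labelled
#' thin filament is rapidly mixed with excess chelator: fluorescence
#' relaxes as a single exponential \eqn{F(t) = A e^{-k t} + C} with time
#' measured from mixing. The instrument cannot observe the first
#' `dead_time` milliseconds, so the recorded trace starts at `dead_time`
#' (default 1.1 ms) -- the pre-dead-time segment is truncated, as in the
#' real apparatus.
#'
#' @param true_koff True dissociation rate (s^-1).
#' @param amplitude Exponential amplitude A (a.u.) at t = 0 (mixing).
#' @param offset Fluorescence plateau C (a.u.).
#' @param t_end End of recording (ms). Default: `dead_time` plus eight
#'   half-lives.
#' @param dt Sampling interval (ms). Default: `(t_end - dead_time)/400`.
#' @param dead_time Instrument dead time (ms), default 1.1.
#' @param n_traces Number of repeated shots (>= 1).
#' @param noise_sd Additive Gaussian noise SD (a.u.).
#' @param seed Integer seed.
#' @param construct_label Label carried through to fits and reports.
#'
#' @return An object of class `stopped_flow_dataset`: list with `traces`
#'   (data.frame `t_ms`, `fluor`, `trace_id`), `dead_time`,
#'   `construct_label`, `truth`.
#' @export
#' @examples
#' sf <- gen_stopped_flow(true_koff = 100, noise_sd = 0, n_traces = 5)
#' fit_exp_decay(sf)$koff
gen_stopped_flow <- function(true_koff, amplitude = 1, offset = 0.1,
                             t_end = NULL, dt = NULL, dead_time = 1.1,
                             n_traces = 5, noise_sd = 0.01, seed = 1,
                             construct_label = "construct") {
  check_number(true_koff, "true_koff", 0, strict_lower = TRUE)
  check_number(dead_time, "dead_time", 0)
  check_number(noise_sd, "noise_sd", 0)
  check_number(n_traces, "n_traces", 1)
  k_ms <- true_koff / 1000          # rate in ms^-1
  if (is.null(t_end)) t_end <- dead_time + 8 * log(2) / k_ms
  if (t_end <= dead_time) stop_invalid("`t_end` must exceed `dead_time`")
  if (is.null(dt)) dt <- (t_end - dead_time) / 400
  check_number(dt, "dt", 0, strict_lower = TRUE)

  t <- seq(dead_time, t_end, by = dt)
  clean <- amplitude * exp(-k_ms * t) + offset
  old <- local_seed(seed)
  on.exit(restore_seed(old))
  traces <- do.call(rbind, lapply(seq_len(n_traces), function(i) {
    data.frame(t_ms = t, fluor = clean + rnorm(length(t), 0, noise_sd),
               trace_id = i)
  }))
  structure(list(traces = traces, dead_time = dead_time,
                 construct_label = construct_label,
                 truth = list(kind = "stopped_flow", true_koff = true_koff,
                              amplitude = amplitude, offset = offset,
                              dead_time = dead_time, noise_sd = noise_sd,
                              n_traces = n_traces, seed = seed)),
            class = "stopped_flow_dataset")
}

# Seed hygiene: generators must not disturb the caller's RNG stream, and
# identical seeds must give identical data regardless of what ran before.
local_seed <- function(seed) {
  old <- if (exists(".Random.seed", globalenv(), inherits = FALSE))
    get(".Random.seed", globalenv()) else NULL
  set.seed(as.integer(seed))
  old
}

restore_seed <- function(old) {
  if (is.null(old)) {
    if (exists(".Random.seed", globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  } else assign(".Random.seed", old, envir = globalenv())
}
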