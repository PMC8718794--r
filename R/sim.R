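#' Net Ca2+ flux onto troponin
#'
#' \deqn{J_{trpn} = k_{on} (B_t - [CaT]_i) [Ca^{2+}]_i - k_{off} [CaT]_i}
#' Positive flux moves Ca onto troponin. Units uM/ms.
#'
#' @param ca_cyto Cytosolic free Ca2+ (uM), >= 0.
#' @param ca_trpn Troponin-bound Ca2+ (uM), in \[0, b_total\].
#' @param p A `troponin_params` list with `k_on` ((uM ms)^-1), `k_off`
#'   (ms^-1), `b_total` (uM), e.g. `make_default_params()$troponin`.
#' @return Flux (uM/ms), vectorised over the concentration arguments.
#' @export
#' @examples
#' p <- make_default_params()$troponin
#' troponin_flux(0, 7, list(k_on = p$k_on, k_off = 0.5, b_total = 70))  # -3.5
troponin_flux <- function(ca_cyto, ca_trpn, p) {
  if (any(ca_cyto < 0)) stop_invalid("`ca_cyto` must be >= 0")
  if (any(ca_trpn < 0) || any(ca_trpn > p$b_total))
    stop(errorCondition("`ca_trpn` outside [0, b_total]",
                        class = c("alternans_invariant_violation", "error", "condition")))
  p$k_on * (p$b_total - ca_trpn) * ca_cyto - p$k_off * ca_trpn
}

#' Default CRU-network simulation parameters
#'
#' The `control` variant uses the measured troponin kinetics (k_off =
#' 0.5 ms^-1); `reduced_koff` slows Ca2+ unbinding to 0.1 ms^-1 and is
#' otherwise identical -- a single-parameter perturbation. k_on is
#' 0.0327 (uM ms)^-1 and the SERCA K_D is 0.25 uM in both variants. The
#' test lattice is 20 x 5 x 5 CRUs; the full lattice is 100 x 20 x 10 =
#' 20,000 CRUs. All remaining rate constants are this model's own
#' calibrated closure (spark ignition/termination, SR refill, coupling);
#' see the methods vignette for the calibration procedure.
#'
#' @param variant `"control"` or `"reduced_koff"`.
#' @param scale `"test"` (20 x 5 x 5) or `"full"` (100 x 20 x 10).
#' @return Object of class `sim_params`: nested list with `lattice`,
#'   `troponin`, `serca`, `spark`, `other_fluxes`, `buffers`,
#'   `voltage_mode`, `dt`, `init`.
#' @export
#' @examples
#' make_default_params("control")$troponin$k_off       # 0.5
#' make_default_params("reduced_koff")$troponin$k_off  # 0.1
make_default_params <- function(variant = c("control", "reduced_koff"),
                                scale = c("test", "full")) {
  variant <- match.arg(variant)
  scale <- match.arg(scale)
  lat <- if (scale == "full") list(nx = 100, ny = 20, nz = 10)
         else list(nx = 20, ny = 5, nz = 5)
  structure(list(
    lattice = c(lat, list(coupling_cyto = 0.3, coupling_sr = 0.01)),
    troponin = list(k_on = 0.0327,
                    k_off = if (variant == "control") 0.5 else 0.1,
                    b_total = 70),
    serca = list(v_max = 0.28, kd = 0.25, hill = 2),
    spark = list(ignition_rate_base = 5e-5,      # ms^-1 at c = c_ref
                 ignition_ca_exponent = 6,
                 c_ref = 0.15,                   # uM
                 release_conductance = 8e-3,     # ms^-1
                 spark_termination_jsr_fraction = 0.2,
                 refractory_tau = 140,           # ms (channel-level timer)
                 refrac_ca_half = 0.145,         # uM; Ca-gated refractory recovery
                 recovery_fraction = 0,          # optional hard JSR refill gate
                 luminal_ref = 600,              # uM JSR reference load
                 luminal_exponent = 2),          # steepness of luminal regulation
    other_fluxes = list(leak_rate = 4e-5,        # ms^-1 (NSR -> cytosol)
                        leak_boost = 50,         # store-overload leak strength
                        leak_ceiling = 800,      # uM NSR soft ceiling
                        tau_refill = 40,         # ms (NSR -> JSR)
                        ncx_scale = 0.088,       # ms^-1 efflux on free Ca
                        background_influx = 0.01,# uM/ms
                        trigger_flux = 1.75,     # uM/ms during the stimulus
                        trigger_duration = 2,    # ms
                        trigger_ignition_rate = 3), # ms^-1 during stimulus
    buffers = list(cyto_b = 8, cyto_k = 0.6,     # fast cytosolic buffer
                   jsr_b = 400, jsr_k = 600,     # calsequestrin
                   lambda_nsr = 0.05, lambda_jsr = 0.02), # volume fractions
    voltage = list(v_rest = -80, v_peak = 30, apd_clamp = 250),
    voltage_mode = "clamped_waveform",
    dt = 0.02,
    init = list(ca_cyto = 0.1, ca_nsr = 450),
    variant = variant, scale = scale
  ), class = "sim_params")
}

# flatten nested params into the list the C++ core expects
par_flat <- function(p, pcl = NULL) {
  apd <- p$voltage$apd_clamp
  if (!is.null(pcl)) apd <- min(apd, 0.75 * pcl)
  list(nx = p$lattice$nx, ny = p$lattice$ny, nz = p$lattice$nz,
       kon = p$troponin$k_on, koff = p$troponin$k_off, bt = p$troponin$b_total,
       vmax = p$serca$v_max, kserca = p$serca$kd, hserca = p$serca$hill,
       gleak = p$other_fluxes$leak_rate,
       leak_boost = p$other_fluxes$leak_boost,
       leak_ceiling = p$other_fluxes$leak_ceiling,
       grel = p$spark$release_conductance,
       tau_tr = p$other_fluxes$tau_refill,
       dc = p$lattice$coupling_cyto, dn = p$lattice$coupling_sr,
       k0 = p$spark$ignition_rate_base, gamma = p$spark$ignition_ca_exponent,
       c_ref = p$spark$c_ref,
       kstim = p$other_fluxes$trigger_ignition_rate,
       stim_dur = p$other_fluxes$trigger_duration,
       astim = p$other_fluxes$trigger_flux,
       gncx = p$other_fluxes$ncx_scale, jbg = p$other_fluxes$background_influx,
       term_frac = p$spark$spark_termination_jsr_fraction,
       refrac_tau = p$spark$refractory_tau,
       refrac_ca_half = p$spark$refrac_ca_half,
       recover_frac = p$spark$recovery_fraction,
       lum_ref = p$spark$luminal_ref, lum_exp = p$spark$luminal_exponent,
       lambda_n = p$buffers$lambda_nsr, lambda_j = p$buffers$lambda_jsr,
       bm = p$buffers$cyto_b, km = p$buffers$cyto_k,
       bc = p$buffers$jsr_b, kc = p$buffers$jsr_k,
       v_rest = p$voltage$v_rest, v_peak = p$voltage$v_peak, apd_clamp = apd,
       voltage_mode = if (identical(p$voltage_mode, "clamped_waveform")) 0L else 1L,
       dt = p$dt)
}

#' Initial cell state for a CRU-network simulation
#'
#' All CRUs start at the same diastolic point: cytosolic free Ca at
#' `p$init$ca_cyto`, troponin at its binding equilibrium for that Ca,
#' both SR compartments at `p$init$ca_nsr` free Ca, no sparks, no
#' refractoriness.
#'
#' @param p A `sim_params`.
#' @return Object of class `cell_state`.
#' @export
new_cell_state <- function(p) {
  n <- p$lattice$nx * p$lattice$ny * p$lattice$nz
  c0 <- p$init$ca_cyto
  kd_trpn <- p$troponin$k_off / p$troponin$k_on
  b0 <- p$troponin$b_total * c0 / (c0 + kd_trpn)
  u0 <- c0 + p$buffers$cyto_b * c0 / (p$buffers$cyto_k + c0)
  j0 <- p$init$ca_nsr
  w0 <- j0 + p$buffers$jsr_b * j0 / (p$buffers$jsr_k + j0)
  structure(list(u = rep(u0, n), b = rep(b0, n), nsr = rep(j0, n),
                 w = rep(w0, n), active = integer(n), refrac = numeric(n),
                 jstart = numeric(n), v = p$voltage$v_rest, time = 0),
            class = "cell_state")
}

#' Extract free concentrations from a cell state
#'
#' Inverts the rapid-buffer relations to report per-CRU free cytosolic
#' and junctional-SR Ca alongside the stored pools.
#' @param state A `cell_state`.
#' @param p The `sim_params` it was created with.
#' @return List with vectors `ca_cyto`, `ca_trpn`, `ca_nsr`, `ca_jsr`.
#' @export
state_concentrations <- function(state, p) {
  inv <- function(u, B, K) {
    b2 <- K + B - u
    0.5 * (-b2 + sqrt(b2^2 + 4 * K * pmax(u, 0)))
  }
  list(ca_cyto = inv(state$u, p$buffers$cyto_b, p$buffers$cyto_k),
       ca_trpn = state$b,
       ca_nsr = state$nsr,
       ca_jsr = inv(state$w, p$buffers$jsr_b, p$buffers$jsr_k))
}

#' Advance a cell state
#'
#' Integrates the lattice forward by `t_ms` milliseconds (explicit Euler
#' for the deterministic fluxes, per-step Bernoulli spark draws) with no
#' pacing stimuli. Set `stochastic = FALSE` to freeze spark ignition
#' (deterministic relaxation).
#'
#' @param state A `cell_state`.
#' @param p A `sim_params`.
#' @param t_ms Time to advance (ms); default one step `p$dt`.
#' @param seed Integer seed for the spark draws.
#' @param closed_cell Disable sarcolemmal fluxes (trigger, exchanger,
#'   background influx)?
#' @param stochastic Allow spark ignition?
#' @return The advanced `cell_state`.
#' @export
step_cell <- function(state, p, t_ms = p$dt, seed = 1, closed_cell = TRUE,
                      stochastic = TRUE) {
  out <- cru_run_cpp(par_flat(p), numeric(0), t_ms, as.integer(seed),
                     closed_cell, t_ms, unclass(state), stochastic)
  structure(out$state, class = "cell_state")
}

#' Pacing protocol description
#'
#' @param pcl Pacing cycle length (ms), > 0.
#' @param n_beats Total paced beats.
#' @param n_discard Leading beats discarded before analysis
#'   (pre-pacing to approach the stationary alternans pattern).
#' @return Object of class `pacing_protocol`.
#' @export
pacing_protocol <- function(pcl, n_beats = 20, n_discard = 18) {
  check_number(pcl, "pcl", 0, strict_lower = TRUE)
  if (n_beats <= n_discard) stop_invalid("`n_beats` must exceed `n_discard`")
  structure(list(pcl = pcl, n_beats = n_beats, n_discard = n_discard),
            class = "pacing_protocol")
}

#' Run a paced CRU-network simulation
#'
#' Applies the trigger stimulus every PCL milliseconds for
#' `protocol$n_beats` beats, recording whole-cell mean voltage,
#' cytosolic free Ca, SR free Ca, total Ca, and the per-beat peak
#' cytosolic Ca. The first `n_discard` beats are marked as pre-pacing;
#' `peaks` holds the analysed (retained) beats and `peaks_all` every
#' beat.
#'
#' @param p A `sim_params`.
#' @param protocol A `pacing_protocol`.
#' @param seed Integer seed for spark stochasticity.
#' @param record_dt Trace sampling interval (ms).
#' @param state Optional starting `cell_state` (default
#'   [new_cell_state()]).
#' @return Object of class `sim_trace`: `time` (ms), `v` (mV), `ca`,
#'   `ca_sr`, `total_ca` (uM), `peaks`, `peaks_all`, `diastolic_sr`
#'   (end-diastolic SR free Ca per retained beat), `capture_ok`,
#'   `protocol`, `params`.
#' @export
run_paced <- function(p, protocol, seed = 1, record_dt = 1, state = NULL) {
  if (!inherits(protocol, "pacing_protocol")) stop_invalid("need a `pacing_protocol`")
  state <- state %||% new_cell_state(p)
  stim <- 10 + (seq_len(protocol$n_beats) - 1) * protocol$pcl
  t_end <- 10 + protocol$n_beats * protocol$pcl
  out <- cru_run_cpp(par_flat(p, protocol$pcl), stim, t_end, as.integer(seed),
                     FALSE, record_dt, unclass(state), TRUE)
  keep <- seq_len(protocol$n_beats) > protocol$n_discard
  peaks_all <- out$beat_peak
  # end-diastolic SR: last recorded sample before each retained stimulus end
  beat_end <- c(stim[-1], t_end)
  diast_sr <- vapply(beat_end, function(te) {
    out$ca_sr[max(which(out$time <= te))]
  }, numeric(1))
  diastolic <- min(out$ca, na.rm = TRUE)
  captured <- peaks_all > 1.05 * diastolic
  res <- structure(list(time = out$time, v = out$v, ca = out$ca,
                        ca_sr = out$ca_sr, total_ca = out$total_ca,
                        peaks = peaks_all[keep], peaks_all = peaks_all,
                        diastolic_sr = diast_sr[keep],
                        capture_ok = mean(captured) >= 0.5,
                        protocol = protocol, seed = seed, params = p),
                   class = "sim_trace")
  if (!res$capture_ok)
    warning(sprintf("failed capture: no Ca transient evoked on %d of %d beats",
                    sum(!captured), length(captured)))
  res
}

#' Relative total-Ca drift of a closed-cell run
#'
#' `max |total Ca(t) - total Ca(0)| / total Ca(0)` over a recorded
#' trace. For a run with sarcolemmal fluxes disabled this measures the
#' integrator's mass-conservation error.
#'
#' @param trace A `sim_trace` or any list with a `total_ca` series.
#' @return Dimensionless relative drift.
#' @export
check_conservation <- function(trace) {
  tot <- trace$total_ca
  max(abs(tot - tot[1])) / tot[1]
}

#' Run a closed-cell simulation
#'
#' Integrates with all sarcolemmal fluxes disabled (no trigger, no
#' exchanger, no background influx); sparks remain stochastic. Used with
#' [check_conservation()] as the mass-conservation oracle.
#'
#' @param p A `sim_params`.
#' @param t_ms Duration (ms).
#' @param seed Integer seed.
#' @param record_dt Sampling interval (ms).
#' @param stochastic Allow spark ignition?
#' @param state Optional starting state.
#' @return A `sim_trace` (no beats).
#' @export
run_closed <- function(p, t_ms, seed = 1, record_dt = 1, stochastic = TRUE,
                       state = NULL) {
  state <- state %||% new_cell_state(p)
  out <- cru_run_cpp(par_flat(p), numeric(0), t_ms, as.integer(seed),
                     TRUE, record_dt, unclass(state), stochastic)
  structure(list(time = out$time, v = out$v, ca = out$ca, ca_sr = out$ca_sr,
                 total_ca = out$total_ca, peaks = numeric(0),
                 state = structure(out$state, class = "cell_state"),
                 params = p),
            class = "sim_trace")
}

#' Scan pacing cycle lengths for Ca2+ alternans (bifurcation diagram)
#'
#' Runs [run_paced()] at each PCL on the grid, stores the last two
#' per-beat peak cytosolic Ca values, and flags alternans when their
#' relative difference `|p1 - p2| / mean` exceeds `threshold` (default
#' 5%). With several seeds the flag is a majority vote and the reported
#' peaks come from the first seed. The onset boundary is the smallest
#' PCL whose flag is FALSE.
#'
#' @param p A `sim_params`.
#' @param pcl_grid PCL grid (ms); default 300-700 in 50-ms steps.
#' @param protocol Template protocol; its `pcl` is replaced per grid
#'   point. Default 20 beats, 18 discarded.
#' @param seeds Integer vector of seeds (default 1).
#' @param threshold Alternans flag threshold on the relative peak
#'   difference.
#' @return Object of class `bifurcation_result`: data.frame `table`
#'   (`pcl`, `peak1`, `peak2`, `flag`, `votes`), `onset` (ms, NA if
#'   alternans persists across the grid), `threshold`, `seeds`.
#' @export
scan_pcl <- function(p, pcl_grid = seq(300, 700, by = 50), protocol = NULL,
                     seeds = 1L, threshold = 0.05) {
  if (!length(pcl_grid)) stop_invalid("`pcl_grid` must be non-empty")
  proto <- protocol %||% pacing_protocol(pcl_grid[1])
  rows <- lapply(pcl_grid, function(pcl) {
    pr <- pacing_protocol(pcl, proto$n_beats, proto$n_discard)
    flags <- logical(length(seeds))
    pk <- NULL
    for (si in seq_along(seeds)) {
      tr <- tryCatch(suppressWarnings(run_paced(p, pr, seed = seeds[si])),
                     error = function(e) e)
      if (inherits(tr, "error")) {
        warning(sprintf("PCL %g ms, seed %d failed: %s", pcl, seeds[si],
                        conditionMessage(tr)))
        flags[si] <- NA
        next
      }
      last2 <- tail(tr$peaks, 2)
      flags[si] <- abs(diff(last2)) / mean(last2) > threshold
      if (si == 1) pk <- last2
    }
    votes <- mean(flags, na.rm = TRUE)
    data.frame(pcl = pcl, peak1 = pk[1] %||% NA_real_,
               peak2 = pk[2] %||% NA_real_,
               flag = votes > 0.5, votes = votes)
  })
  tab <- do.call(rbind, rows)
  no_alt <- tab$pcl[!tab$flag]
  structure(list(table = tab,
                 onset = if (length(no_alt)) min(no_alt) else NA_real_,
                 threshold = threshold, seeds = seeds,
                 variant = p$variant %||% NA_character_),
            class = "bifurcation_result")
}

#' @export
print.bifurcation_result <- function(x, ...) {
  cat(sprintf("PCL scan (%s, %d seed%s): alternans at {%s} ms; onset (no alternans) at %s ms\n",
              x$variant, length(x$seeds), if (length(x$seeds) > 1) "s" else "",
              paste(x$table$pcl[x$table$flag], collapse = ", "),
              format(x$onset)))
  print(x$table, row.names = FALSE)
  invisible(x)
}

#' @export
print.sim_params <- function(x, ...) {
  cat(sprintf("CRU-network parameters: %s variant, %d x %d x %d lattice (%d CRUs)\n",
              x$variant, x$lattice$nx, x$lattice$ny, x$lattice$nz,
              x$lattice$nx * x$lattice$ny * x$lattice$nz))
  cat(sprintf("  troponin: k_on %.4g (uM ms)^-1, k_off %.3g ms^-1, B_t %g uM\n",
              x$troponin$k_on, x$troponin$k_off, x$troponin$b_total))
  cat(sprintf("  SERCA: v_max %.3g uM/ms, K_D %.3g uM, h %g; dt %g ms\n",
              x$serca$v_max, x$serca$kd, x$serca$hill, x$dt))
  invisible(x)
}
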