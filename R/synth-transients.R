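#' Generate a synthetic paced dual-channel transient train
#'
#' Emulates an optical-mapping recording of a field-stimulated
#' cardiomyocyte monolayer: a voltage-sensitive channel and a
#' Ca2+-sensitive channel sampled on a uniform grid (default 100
#' frames/s), paced at a fixed rate for a fixed duration with stimulus
#' timestamps attached.
#'
#' Each evoked beat is a pulse with a fast linear upstroke (5 ms, far
#' shorter than APD30) followed by a monotone piecewise-linear
#' repolarisation constrained to pass exactly through the requested 30%
#' and 80% recovery times, so a noiseless train analysed with
#' [analyze_trace()] returns the requested durations to within one
#' interpolated sample interval. Alternate beats are scaled by
#' `1 +/- alternans_ratio / 2` to emulate period-2 amplitude alternans,
#' and beats listed in `skipped_beats` are omitted entirely (the stimulus
#' remains, the transient does not), emulating loss of 1:1 entrainment.
#'
#' @param rate Pacing rate (beats/min). Default 55.
#' @param duration Paced interval (s). Default 20.
#' @param frame_rate Sampling rate (frames/s). Default 100.
#' @param apd30,apd80 Requested voltage-channel durations at 30% and 80%
#'   recovery (ms), measured from the upstroke.
#' @param catd30,catd80 Same for the Ca2+ channel (ms).
#' @param alternans_ratio Fractional peak-amplitude alternation in
#'   \[0, 1): even/odd beats scaled by `1 -/+ alternans_ratio/2`.
#' @param skipped_beats Integer indices (1-based, in stimulus order) of
#'   beats that fail to evoke a transient.
#' @param noise_sd Additive Gaussian noise, as a fraction of the transient
#'   amplitude.
#' @param polarity Length-2 vector (voltage, Ca) of +1/-1: sign of the
#'   fluorescence deflection on depolarisation (some potentiometric dyes
#'   dim on depolarisation).
#' @param baseline_s Quiescent baseline before the first stimulus (s),
#'   used downstream to estimate F0 and noise. Default 0.5.
#' @param f0 Resting fluorescence level (a.u.).
#' @param dff_amplitude Full transient amplitude as a fraction of `f0`.
#' @param seed Integer seed.
#'
#' @return An object of class `transient_trace`: list with `time` (s),
#'   `v`, `ca` (raw fluorescence, a.u.), `stimulus_times` (s),
#'   `frame_rate`, `polarity`, and `truth`.
#' @export
#' @examples
#' tr <- gen_transient_train(rate = 60, duration = 20, noise_sd = 0)
#' length(tr$stimulus_times)  # exactly 20
gen_transient_train <- function(rate = 55, duration = 20, frame_rate = 100,
                                apd30 = 210, apd80 = 300,
                                catd30 = 250, catd80 = 420,
                                alternans_ratio = 0, skipped_beats = integer(),
                                noise_sd = 0, polarity = c(1, 1),
                                baseline_s = 0.5, f0 = 100,
                                dff_amplitude = 0.5, seed = 1) {
  check_number(rate, "rate", 0, strict_lower = TRUE)
  check_number(duration, "duration", 0, strict_lower = TRUE)
  check_number(frame_rate, "frame_rate", 0, strict_lower = TRUE)
  check_number(alternans_ratio, "alternans_ratio", 0)
  check_number(noise_sd, "noise_sd", 0)
  if (alternans_ratio >= 1) stop_invalid("`alternans_ratio` must be in [0, 1)")
  pcl_ms <- 60000 / rate
  for (nm in c("apd30", "apd80", "catd30", "catd80"))
    check_number(get(nm), nm, 0, strict_lower = TRUE)
  if (apd30 >= apd80) stop_invalid("`apd30` must be < `apd80`")
  if (catd30 >= catd80) stop_invalid("`catd30` must be < `catd80`")
  if (apd80 >= pcl_ms || catd80 >= pcl_ms)
    stop_invalid("80% recovery durations must be shorter than the cycle length")
  polarity <- rep_len(polarity, 2L)
  if (!all(polarity %in% c(-1, 1))) stop_invalid("`polarity` entries must be +1 or -1")

  n_beats <- floor(rate * duration / 60 + 1e-9)
  stim_s <- baseline_s + (seq_len(n_beats) - 1) * pcl_ms / 1000
  total_s <- baseline_s + duration
  time <- seq(0, total_s, by = 1 / frame_rate)
  t_ms <- time * 1000

  amp_scale <- 1 + ifelse(seq_len(n_beats) %% 2 == 1, 1, -1) * alternans_ratio / 2
  amp_scale[skipped_beats[skipped_beats <= n_beats]] <- 0

  v_wave  <- sum_pulses(t_ms, stim_s * 1000, amp_scale, apd30, apd80, pcl_ms)
  ca_wave <- sum_pulses(t_ms, stim_s * 1000, amp_scale, catd30, catd80, pcl_ms)

  amp_abs <- f0 * dff_amplitude
  old <- local_seed(seed)
  on.exit(restore_seed(old))
  v  <- f0 + polarity[1] * amp_abs * v_wave  + rnorm(length(time), 0, noise_sd * amp_abs)
  ca <- f0 + polarity[2] * amp_abs * ca_wave + rnorm(length(time), 0, noise_sd * amp_abs)

  structure(list(time = time, v = v, ca = ca, stimulus_times = stim_s,
                 frame_rate = frame_rate, polarity = polarity,
                 truth = list(kind = "transient_train", rate = rate,
                              duration = duration, apd30 = apd30, apd80 = apd80,
                              catd30 = catd30, catd80 = catd80,
                              alternans_ratio = alternans_ratio,
                              skipped_beats = as.integer(skipped_beats),
                              n_beats = n_beats, noise_sd = noise_sd,
                              polarity = polarity, f0 = f0,
                              dff_amplitude = dff_amplitude, seed = seed)),
            class = "transient_trace")
}

# One normalised pulse per stimulus, amplitude-scaled per beat.
# Shape (t in ms from upstroke): linear rise over 5 ms to the peak, then
# piecewise-linear decay through (d30, 0.70) and (d80, 0.20), continuing
# at the final slope to zero. Monotone after the peak, so the 30%/80%
# recovery levels are crossed exactly once, at d30 and d80.
sum_pulses <- function(t_ms, stim_ms, amp_scale, d30, d80, pcl_ms) {
  rise <- 5
  d30 <- max(d30, rise + 1)
  d_end <- min(d80 + 0.4 * (d80 - d30), 0.98 * pcl_ms)
  out <- numeric(length(t_ms))
  for (k in seq_along(stim_ms)) {
    a <- amp_scale[k]
    if (a == 0) next
    tt <- t_ms - stim_ms[k]
    idx <- which(tt >= 0 & tt < d_end + 1)
    if (!length(idx)) next
    tk <- tt[idx]
    y <- numeric(length(tk))
    y[tk < rise] <- tk[tk < rise] / rise
    seg <- tk >= rise & tk < d30
    y[seg] <- 1 - 0.30 * (tk[seg] - rise) / (d30 - rise)
    seg <- tk >= d30 & tk < d80
    y[seg] <- 0.70 - 0.50 * (tk[seg] - d30) / (d80 - d30)
    seg <- tk >= d80 & tk < d_end
    y[seg] <- pmax(0, 0.20 - 0.20 * (tk[seg] - d80) / (d_end - d80))
    out[idx] <- out[idx] + a * y
  }
  out
}
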