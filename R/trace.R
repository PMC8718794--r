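#' Normalise a fluorescence channel to dF/F0
#'
#' Computes `polarity * (F - F0) / F0` with F0 the mean over a quiescent
#' baseline window preceding the first stimulus, so the result has
#' baseline about 0 and upward transient deflections regardless of dye
#' polarity. Downstream duration metrics are invariant to affine
#' transforms of the raw intensity once this step is applied.
#'
#' @param trace A `transient_trace`.
#' @param baseline_window Length-2 interval (s) used for F0; default
#'   `c(0, first stimulus)`.
#' @param channel `"v"` or `"ca"`.
#' @return List with `time`, `y` (normalised), `noise_sd` (baseline SD of
#'   the normalised signal), `baseline_window`.
#' @export
normalize_dff <- function(trace, baseline_window = NULL, channel = c("v", "ca")) {
  channel <- match.arg(channel)
  y <- trace[[channel]]
  pol <- trace$polarity[if (channel == "v") 1 else 2]
  bw <- baseline_window %||% c(trace$time[1], trace$stimulus_times[1])
  if (bw[2] > trace$stimulus_times[1] + 1e-9)
    stop_invalid("baseline window must precede the first stimulus")
  sel <- trace$time >= bw[1] & trace$time < bw[2]
  if (!any(sel)) stop_invalid("baseline window contains no samples")
  f0 <- mean(y[sel])
  if (f0 <= 0)
    stop(errorCondition("baseline fluorescence F0 <= 0; cannot normalise",
                        class = c("alternans_normalization_error", "error", "condition")))
  yn <- pol * (y - f0) / f0
  list(time = trace$time, y = yn, noise_sd = sd(yn[sel]), baseline_window = bw)
}

#' Segment a paced trace into per-beat windows
#'
#' Windows are stimulus-aligned half-open intervals `[s_i, s_{i+1})`
#' (the last window extends one median cycle length and is dropped if it
#' runs past the record). A beat is emitted only when a well-formed
#' transient is detected: peak above baseline by at least four baseline
#' noise SDs. Activation time is the midpoint of the largest first
#' difference after the stimulus -- more robust at 100 frames/s than a
#' fixed-threshold crossing.
#'
#' @param trace A `transient_trace`.
#' @param stimulus_times Stimulus timestamps (s); default those stored in
#'   the trace.
#' @param channel `"v"` or `"ca"`.
#' @param detection_k Detection threshold in baseline-noise SDs (default 4).
#' @return List of beats, each a list with `index` (stimulus index),
#'   `t` (s), `y` (normalised), `activation_time` (s), `baseline`,
#'   `peak`, `amplitude`.
#' @export
segment_beats <- function(trace, stimulus_times = NULL, channel = c("v", "ca"),
                          detection_k = 4) {
  channel <- match.arg(channel)
  stim <- stimulus_times %||% trace$stimulus_times
  if (length(stim) < 1) stop_invalid("need at least one stimulus")
  nd <- normalize_dff(trace, channel = channel)
  thr <- detection_k * max(nd$noise_sd, 0, na.rm = TRUE)
  pcl <- if (length(stim) > 1) median(diff(stim)) else
    max(nd$time) - stim[1]
  ends <- c(stim[-1], stim[length(stim)] + pcl)
  beats <- list()
  for (i in seq_along(stim)) {
    if (ends[i] > max(nd$time) + 1e-9) next  # window spans the record end
    sel <- which(nd$time >= stim[i] & nd$time < ends[i])
    if (length(sel) < 4) next
    y <- nd$y[sel]; t <- nd$time[sel]
    base <- min(mean(head(y, 3)), mean(tail(y, max(3, length(y) %/% 10))))
    pk_i <- which.max(y)
    # a well-formed transient clears the threshold on several consecutive
    # frames; single-sample noise spikes do not
    if (!(y[pk_i] - base > thr) || sum(y - base > thr) < 3) next
    dif <- diff(y[seq_len(pk_i)])
    act <- if (length(dif) && max(dif) > 0) {
      up <- which.max(dif)
      (t[up] + t[up + 1]) / 2
    } else {
      # upstroke fell between the stimulus and the first frame of the
      # window; the stimulus-aligned window start is the best estimate
      t[1]
    }
    beats[[length(beats) + 1L]] <-
      list(index = i, t = t, y = y, activation_time = act,
           baseline = base, peak = y[pk_i],
           amplitude = y[pk_i] - base)
  }
  beats
}

#' Transient duration at a fractional recovery level
#'
#' Time (ms) from the activation time to the first post-peak crossing of
#' `peak - fraction * (peak - baseline)`, with linear interpolation
#' between samples (sub-frame precision at 100 frames/s). Returns NA if
#' the signal never recovers to the level inside the beat window; such
#' beats are excluded from averages and counted as irregular.
#'
#' @param beat A beat from [segment_beats()].
#' @param fraction Recovery fraction, e.g. 0.30 or 0.80.
#' @return Duration (ms), or NA if unrecovered.
#' @export
duration_at_recovery <- function(beat, fraction) {
  check_number(fraction, "fraction", 0, 1)
  if (beat$amplitude <= 0) stop_invalid("beat has non-positive amplitude")
  level <- beat$peak - fraction * (beat$peak - beat$baseline)
  pk <- which.max(beat$y)
  ys <- beat$y[pk:length(beat$y)]
  ts <- beat$t[pk:length(beat$t)]
  below <- which(ys <= level)
  below <- below[below > 1]
  if (!length(below)) return(NA_real_)
  j <- below[1]
  # linear interpolation inside [j-1, j]
  t_cross <- ts[j - 1] + (level - ys[j - 1]) / (ys[j] - ys[j - 1]) * (ts[j] - ts[j - 1])
  (t_cross - beat$activation_time) * 1000
}

#' Action-potential triangulation index
#'
#' `(APD80 - APD30) / APD80`: the fraction of late repolarisation in the
#' total duration. Larger values indicate a more triangulated action
#' potential, a recognised arrhythmia-risk marker.
#'
#' @param apd30,apd80 Durations (ms) at 30% and 80% repolarisation.
#' @return Dimensionless index in \[0, 1).
#' @export
#' @examples
#' triangulation_index(210, 300)  # 0.3
triangulation_index <- function(apd30, apd80) {
  if (any(apd30 <= 0) || any(apd80 <= 0))
    stop_invalid("durations must be positive")
  if (any(apd30 > apd80))
    stop_invalid("apd30 must not exceed apd80")
  (apd80 - apd30) / apd80
}

#' Amplitude alternans metric on a per-beat peak sequence
#'
#' `ratio = |mean(odd-beat peaks) - mean(even-beat peaks)| / mean(all)`.
#' The even/odd phase assignment is arbitrary; the absolute difference
#' makes the metric phase-invariant. The flag is set when the ratio
#' exceeds `threshold` (default 5%).
#'
#' @param peaks Numeric vector of per-beat peak amplitudes (>= 4).
#' @param threshold Flag threshold on the ratio.
#' @return List with `ratio` and `flag`.
#' @export
#' @examples
#' alternans_metric(c(1.2, 0.8, 1.2, 0.8))
alternans_metric <- function(peaks, threshold = 0.05) {
  if (length(peaks) < 4)
    stop(errorCondition("need >= 4 peaks for an alternans estimate",
                        class = c("alternans_insufficient_data", "error", "condition")))
  odd <- peaks[seq(1, length(peaks), by = 2)]
  even <- peaks[seq(2, length(peaks), by = 2)]
  ratio <- abs(mean(odd) - mean(even)) / mean(peaks)
  list(ratio = ratio, flag = ratio > threshold)
}

#' Entrainment and rhythm classification of a paced trace
#'
#' A recording is entrained when every stimulus evokes exactly one
#' well-formed transient. `n_irregular` counts stimuli with missing or
#' malformed (never-recovering) transients; alternans fields come from
#' [alternans_metric()] on the detected peak sequence (NA with fewer
#' than 4 beats).
#'
#' @param trace A `transient_trace`.
#' @param stimulus_times Stimulus timestamps (s); default from the trace.
#' @param channel Channel to classify (default voltage).
#' @param alternans_threshold Threshold passed to [alternans_metric()].
#' @return Object of class `rhythm_report`: `n_stimuli`, `n_transients`,
#'   `n_irregular`, `entrained`, `alternans_ratio`, `alternans_flag`.
#' @export
entrainment_check <- function(trace, stimulus_times = NULL, channel = c("v", "ca"),
                              alternans_threshold = 0.05) {
  channel <- match.arg(channel)
  stim <- stimulus_times %||% trace$stimulus_times
  beats <- segment_beats(trace, stim, channel = channel)
  # a beat is malformed if it never recovers to 80% inside its window
  recovered <- vapply(beats, function(b) !is.na(duration_at_recovery(b, 0.80)),
                      logical(1))
  n_stim <- length(stim)
  n_tr <- length(beats)
  n_irr <- (n_stim - n_tr) + sum(!recovered)
  peaks <- vapply(beats[recovered], `[[`, numeric(1), "peak")
  alt <- if (length(peaks) >= 4) alternans_metric(peaks, alternans_threshold)
         else list(ratio = NA_real_, flag = NA)
  structure(list(n_stimuli = n_stim, n_transients = n_tr, n_irregular = n_irr,
                 entrained = n_irr == 0 && n_tr == n_stim,
                 alternans_ratio = alt$ratio, alternans_flag = alt$flag),
            class = "rhythm_report")
}

#' @export
print.rhythm_report <- function(x, ...) {
  cat(sprintf("Rhythm: %d stimuli, %d transients, %d irregular; entrained: %s; alternans ratio %.3g (flag %s)\n",
              x$n_stimuli, x$n_transients, x$n_irregular, x$entrained,
              x$alternans_ratio, x$alternans_flag))
  invisible(x)
}

#' Convert pacing cycle length to rate and back
#'
#' `bpm = 60000 / PCL(ms)`.
#' @param pcl Pacing cycle length (ms).
#' @return Rate in beats/min.
#' @export
#' @examples
#' pcl_to_bpm(500)  # 120
pcl_to_bpm <- function(pcl) {
  if (any(pcl <= 0)) stop_invalid("`pcl` must be > 0")
  60000 / pcl
}

#' @rdname pcl_to_bpm
#' @param bpm Rate in beats/min.
#' @export
bpm_to_pcl <- function(bpm) {
  if (any(bpm <= 0)) stop_invalid("`bpm` must be > 0")
  60000 / bpm
}

#' Per-beat metrics for both channels of a paced trace
#'
#' Runs segmentation on the voltage and Ca channels and computes, per
#' accepted beat, APD and CaTD at the requested recovery fractions, the
#' triangulation index, and amplitudes.
#'
#' @param trace A `transient_trace`.
#' @param fractions Recovery fractions, default `c(0.30, 0.80)`.
#' @return data.frame with one row per stimulus index present in either
#'   channel: `beat`, `apd30`, `apd80` (or `apd<f>` per requested
#'   fraction), `catd*`, `triangulation`, `v_amplitude`, `ca_amplitude`.
#' @export
analyze_trace <- function(trace, fractions = c(0.30, 0.80)) {
  vb <- segment_beats(trace, channel = "v")
  cb <- segment_beats(trace, channel = "ca")
  fr_name <- function(prefix) paste0(prefix, sprintf("%02d", round(fractions * 100)))
  all_idx <- sort(union(vapply(vb, `[[`, integer(1), "index"),
                        vapply(cb, `[[`, integer(1), "index")))
  rows <- lapply(all_idx, function(i) {
    row <- list(beat = i)
    b <- Filter(function(x) x$index == i, vb)
    for (k in seq_along(fractions))
      row[[fr_name("apd")[k]]] <- if (length(b)) duration_at_recovery(b[[1]], fractions[k]) else NA_real_
    row$v_amplitude <- if (length(b)) b[[1]]$amplitude else NA_real_
    b <- Filter(function(x) x$index == i, cb)
    for (k in seq_along(fractions))
      row[[fr_name("catd")[k]]] <- if (length(b)) duration_at_recovery(b[[1]], fractions[k]) else NA_real_
    row$ca_amplitude <- if (length(b)) b[[1]]$amplitude else NA_real_
    as.data.frame(row)
  })
  out <- do.call(rbind, rows)
  if (!is.null(out) && all(c("apd30", "apd80") %in% names(out))) {
    ok <- !is.na(out$apd30) & !is.na(out$apd80) & out$apd30 <= out$apd80
    out$triangulation <- ifelse(ok, (out$apd80 - out$apd30) / out$apd80, NA_real_)
  }
  out
}

#' Summarise per-beat metrics by pacing rate and group
#'
#' Produces mean +/- SEM of each metric per (group, rate), pairwise
#' unpaired Student's t-tests between the two groups at each rate, and a
#' per-group across-rate one-way ANOVA with Tukey correction.
#'
#' @param metrics Long data.frame with columns `group`, `rate_bpm`, and
#'   one or more numeric metric columns.
#' @param metric_cols Metric column names; default all numeric columns
#'   except `rate_bpm`.
#' @param alpha Significance level for flags.
#' @return List with `summary` (data.frame), `between_groups`
#'   (data.frame of per-rate t-tests), `across_rates` (per group, per
#'   metric Tukey tables).
#' @export
summarize_by_frequency <- function(metrics, metric_cols = NULL, alpha = 0.05) {
  if (!all(c("group", "rate_bpm") %in% names(metrics)))
    stop_invalid("`metrics` needs columns group, rate_bpm")
  metric_cols <- metric_cols %||%
    setdiff(names(metrics)[vapply(metrics, is.numeric, logical(1))],
            c("rate_bpm", "beat"))
  sem <- function(x) sd(x) / sqrt(length(x))
  summ <- do.call(rbind, lapply(metric_cols, function(mc) {
    d <- metrics[!is.na(metrics[[mc]]), ]
    if (!nrow(d)) return(NULL)
    ag <- aggregate(d[[mc]], by = list(group = d$group, rate_bpm = d$rate_bpm),
                    FUN = function(x) c(mean = mean(x), sem = sem(x), n = length(x)))
    data.frame(metric = mc, group = ag$group, rate_bpm = ag$rate_bpm,
               mean = ag$x[, "mean"], sem = ag$x[, "sem"], n = ag$x[, "n"])
  }))
  groups <- unique(metrics$group)
  rates <- sort(unique(metrics$rate_bpm))
  between <- NULL
  if (length(groups) == 2) {
    between <- do.call(rbind, lapply(metric_cols, function(mc) {
      do.call(rbind, lapply(rates, function(r) {
        a <- metrics[[mc]][metrics$group == groups[1] & metrics$rate_bpm == r]
        b <- metrics[[mc]][metrics$group == groups[2] & metrics$rate_bpm == r]
        a <- a[!is.na(a)]; b <- b[!is.na(b)]
        if (length(a) < 2 || length(b) < 2) {
          warning(sprintf("skipping %s at %g bpm: empty or singleton group", mc, r))
          return(NULL)
        }
        if (sd(a) == 0 && sd(b) == 0 && mean(a) == mean(b)) {
          tt <- list(statistic = 0, parameter = length(a) + length(b) - 2, p.value = 1)
        } else tt <- t.test(a, b, var.equal = TRUE)
        data.frame(metric = mc, rate_bpm = r,
                   mean_1 = mean(a), mean_2 = mean(b),
                   t = unname(tt$statistic), df = unname(tt$parameter),
                   p = tt$p.value, significant = tt$p.value <= alpha)
      }))
    }))
  }
  across <- lapply(setNames(as.character(groups), groups), function(g) {
    lapply(setNames(metric_cols, metric_cols), function(mc) {
      d <- metrics[metrics$group == g & !is.na(metrics[[mc]]), ]
      if (length(unique(d$rate_bpm)) < 2 || nrow(d) < 3) return(NULL)
      d$rate_f <- factor(d$rate_bpm)
      fit <- aov(d[[mc]] ~ rate_f, data = d)
      list(anova_p = summary(fit)[[1]][["Pr(>F)"]][1],
           tukey = TukeyHSD(fit)$rate_f)
    })
  })
  list(summary = summ, between_groups = between, across_rates = across)
}
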