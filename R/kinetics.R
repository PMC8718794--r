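#' Fit the Hill equation to a Ca2+ titration
#'
#' Nonlinear least squares of
#' \deqn{F(Ca) = F_{min} + (F_{max} - F_{min}) \frac{Ca^n}{K_d^n + Ca^n}}
#' fitted independently to each replicate titration
#' (Levenberg-Marquardt, analytically seeded, with a log-spaced
#' multistart fallback). The reported Kd is the mean of the
#' per-replicate estimates and its SEM the standard error across
#' replicates, matching the replicate-then-aggregate convention of
#' steady-state fluorescence titrations.
#'
#' @param data A `titration_dataset` or a data.frame with columns
#'   `ca_uM`, `fluor`, `replicate`.
#' @param fix_hill_n If non-NULL, the Hill coefficient is held at this
#'   value rather than fitted.
#' @return Object of class `hill_fit`: `kd` (uM), `kd_sem` (NA with a
#'   single replicate), `hill_n`, `f_min`, `f_max`, `per_replicate`
#'   (data.frame), `n_replicates`, `construct_label`.
#' @export
#' @examples
#' fit_hill(gen_titration(true_kd = 2, noise_sd = 0, seed = 1))$kd
fit_hill <- function(data, fix_hill_n = NULL) {
  label <- if (inherits(data, "titration_dataset")) data$construct_label else ""
  d <- if (inherits(data, "titration_dataset")) data$data else as.data.frame(data)
  if (!all(c("ca_uM", "fluor", "replicate") %in% names(d)))
    stop_invalid("need columns ca_uM, fluor, replicate")
  if (any(d$ca_uM <= 0)) stop_invalid("all Ca concentrations must be > 0")

  reps <- split(d, d$replicate)
  fits <- lapply(names(reps), function(r) {
    dr <- reps[[r]]
    if (length(unique(dr$ca_uM)) < 4)
      stop_invalid(sprintf("replicate %s has < 4 distinct Ca points", r))
    fit_hill_one(dr$ca_uM, dr$fluor, fix_hill_n, r)
  })
  per <- do.call(rbind, fits)
  n <- nrow(per)
  structure(list(kd = mean(per$kd),
                 kd_sem = if (n >= 2) sd(per$kd) / sqrt(n) else NA_real_,
                 hill_n = mean(per$hill_n),
                 f_min = mean(per$f_min), f_max = mean(per$f_max),
                 per_replicate = per, n_replicates = n,
                 construct_label = label),
            class = "hill_fit")
}

fit_hill_one <- function(ca, f, fix_n, rep_id) {
  f_min0 <- min(f); f_max0 <- max(f)
  # Kd seed: Ca at half-span, by interpolation on the sorted means
  mid <- (f_min0 + f_max0) / 2
  ord <- order(ca)
  kd0 <- tryCatch(exp(approx(f[ord], log(ca[ord]), xout = mid, ties = mean)$y),
                  error = function(e) NA_real_)
  if (!is.finite(kd0)) kd0 <- exp(mean(log(range(ca))))
  starts <- expand.grid(kd = unique(c(kd0, exp(seq(log(min(ca)), log(max(ca)),
                                                  length.out = 5)))),
                        n = if (is.null(fix_n)) c(1, 0.5, 2, 4) else fix_n)
  lo_ca <- min(ca) / 100; hi_ca <- max(ca) * 100
  for (i in seq_len(nrow(starts))) {
    fit <- tryCatch({
      if (is.null(fix_n)) {
        minpack.lm::nlsLM(
          f ~ fmin + (fmax - fmin) * ca^n / (kd^n + ca^n),
          start = list(fmin = f_min0, fmax = f_max0,
                       kd = starts$kd[i], n = starts$n[i]),
          lower = c(-Inf, -Inf, lo_ca, 0.1), upper = c(Inf, Inf, hi_ca, 10),
          control = minpack.lm::nls.lm.control(maxiter = 200))
      } else {
        n_fixed <- fix_n
        minpack.lm::nlsLM(
          f ~ fmin + (fmax - fmin) * ca^n_fixed / (kd^n_fixed + ca^n_fixed),
          start = list(fmin = f_min0, fmax = f_max0, kd = starts$kd[i]),
          lower = c(-Inf, -Inf, lo_ca), upper = c(Inf, Inf, hi_ca),
          control = minpack.lm::nls.lm.control(maxiter = 200))
      }
    }, error = function(e) NULL)
    if (!is.null(fit)) {
      p <- coef(fit)
      return(data.frame(replicate = rep_id, kd = unname(p["kd"]),
                        hill_n = if (is.null(fix_n)) unname(p["n"]) else fix_n,
                        f_min = unname(p["fmin"]), f_max = unname(p["fmax"]),
                        rss = sum(residuals(fit)^2)))
    }
  }
  stop_fit(sprintf("Hill fit failed to converge for replicate %s after multistart", rep_id),
           diagnostics = list(replicate = rep_id, starts = starts))
}

#' Pointwise average of stopped-flow traces
#'
#' Averages repeated shots on their common time grid (the shots of one
#' acquisition share the instrument clock). Fewer than five traces
#' triggers a warning -- an averaged rate is conventionally taken over at
#' least five shots -- but the mean is still returned.
#'
#' @param data A `stopped_flow_dataset`.
#' @return data.frame with columns `t_ms`, `fluor`.
#' @export
average_traces <- function(data) {
  tr <- if (inherits(data, "stopped_flow_dataset")) data$traces else as.data.frame(data)
  ids <- unique(tr$trace_id)
  if (length(ids) < 5)
    warning("fewer than 5 traces averaged (", length(ids), ")")
  grids <- split(tr$t_ms, tr$trace_id)
  t0 <- grids[[1]]
  if (!all(vapply(grids, function(g) length(g) == length(t0) && max(abs(g - t0)) < 1e-9,
                  logical(1))))
    stop_invalid("traces do not share a common time grid")
  m <- rowMeans(matrix(tr$fluor[order(tr$trace_id)], nrow = length(t0)))
  data.frame(t_ms = t0, fluor = m)
}

#' Fit a single-exponential decay to stopped-flow data
#'
#' Fits \eqn{F(t) = A e^{-k t} + C} on the recorded window (t >=
#' dead time; t measured from mixing) and reports the dissociation rate
#' in s^-1. With `average_first = TRUE` (the default) the shots are
#' averaged before fitting -- the convention for stopped-flow
#' acquisition; passing `sets` (a list of trace-id groups) fits one
#' average per set, and the SEM is taken across sets. With
#' `average_first = FALSE` every trace is fitted individually.
#'
#' @param data A `stopped_flow_dataset`.
#' @param average_first Average traces before fitting?
#' @param sets Optional list of trace-id vectors defining repeated
#'   averaged sets.
#' @return Object of class `exp_decay_fit`: `koff` (s^-1), `koff_sem`,
#'   `amplitude` (extrapolated to t = 0), `offset`, `n_fits`,
#'   `construct_label`.
#' @export
#' @examples
#' fit_exp_decay(gen_stopped_flow(120, noise_sd = 0))$koff
fit_exp_decay <- function(data, average_first = TRUE, sets = NULL) {
  if (!inherits(data, "stopped_flow_dataset"))
    stop_invalid("`data` must be a stopped_flow_dataset")
  tr <- data$traces
  fit1 <- function(sub) {
    avg <- suppressWarnings(average_traces(list(traces = sub) |>
                                             structure(class = "stopped_flow_dataset")))
    fit_exp_one(avg$t_ms, avg$fluor)
  }
  if (!is.null(sets)) {
    fits <- lapply(sets, function(ids) fit1(tr[tr$trace_id %in% ids, ]))
  } else if (average_first) {
    fits <- list(fit_exp_one_avg(data))
  } else {
    fits <- lapply(split(tr, tr$trace_id), function(s) fit_exp_one(s$t_ms, s$fluor))
  }
  ks <- vapply(fits, `[[`, numeric(1), "koff")
  structure(list(koff = mean(ks),
                 koff_sem = if (length(ks) >= 2) sd(ks) / sqrt(length(ks)) else NA_real_,
                 amplitude = mean(vapply(fits, `[[`, numeric(1), "amplitude")),
                 offset = mean(vapply(fits, `[[`, numeric(1), "offset")),
                 n_fits = length(ks),
                 construct_label = data$construct_label %||% ""),
            class = "exp_decay_fit")
}

fit_exp_one_avg <- function(data) {
  avg <- tryCatch(average_traces(data), warning = function(w) {
    suppressWarnings(average_traces(data))
  })
  fit_exp_one(avg$t_ms, avg$fluor)
}

fit_exp_one <- function(t, f) {
  c0 <- mean(tail(f, max(3, length(f) %/% 20)))
  a1 <- f[1] - c0
  if (a1 <= 0) stop_fit("trace does not decay (non-positive fitted amplitude)")
  # rate seed from the empirical half-decay time past the first sample
  half <- which(f - c0 <= a1 / 2)[1]
  k0 <- if (!is.na(half) && t[half] > t[1]) log(2) / (t[half] - t[1]) else 1 / diff(range(t))
  fit <- tryCatch(
    minpack.lm::nlsLM(f ~ A * exp(-k * t) + C,
                      start = list(A = a1 * exp(k0 * t[1]), k = k0, C = c0),
                      lower = c(1e-12, 1e-9, -Inf),
                      control = minpack.lm::nls.lm.control(maxiter = 200)),
    error = function(e) NULL)
  if (is.null(fit)) {
    # multistart over a log-spaced rate grid
    for (k0 in 10^seq(-4, 1, by = 0.5)) {
      fit <- tryCatch(
        minpack.lm::nlsLM(f ~ A * exp(-k * t) + C,
                          start = list(A = max(a1, 1e-6) * exp(k0 * t[1]), k = k0, C = c0),
                          lower = c(1e-12, 1e-9, -Inf),
                          control = minpack.lm::nls.lm.control(maxiter = 200)),
        error = function(e) NULL)
      if (!is.null(fit)) break
    }
  }
  if (is.null(fit)) stop_fit("single-exponential fit failed to converge")
  p <- coef(fit)
  if (p["A"] <= 0) stop_fit("trace does not decay (non-positive fitted amplitude)")
  list(koff = unname(p["k"]) * 1000, amplitude = unname(p["A"]),
       offset = unname(p["C"]))
}

#' Two-group comparison of per-replicate parameter estimates
#'
#' Unpaired two-sided Student's t-test (pooled variance) between two
#' groups of replicate estimates, with the fold ratio of the group
#' means. Zero variance in both groups with equal means yields p = 1 by
#' convention.
#'
#' @param group_a,group_b Numeric vectors of per-replicate estimates
#'   (each >= 2 values).
#' @param alpha Significance level, default 0.05.
#' @return Object of class `group_comparison`: `estimate_a`,
#'   `estimate_b`, `fold_ratio` (a/b), `t_stat`, `df`, `p_value`,
#'   `significant`.
#' @export
compare_parameters <- function(group_a, group_b, alpha = 0.05) {
  if (length(group_a) < 2 || length(group_b) < 2)
    stop_invalid("each group needs >= 2 values")
  if (sd(group_a) == 0 && sd(group_b) == 0 && mean(group_a) == mean(group_b)) {
    t_stat <- 0; df <- length(group_a) + length(group_b) - 2; p <- 1
  } else {
    ht <- t.test(group_a, group_b, var.equal = TRUE)
    t_stat <- unname(ht$statistic); df <- unname(ht$parameter); p <- ht$p.value
  }
  structure(list(estimate_a = mean(group_a), estimate_b = mean(group_b),
                 fold_ratio = mean(group_a) / mean(group_b),
                 t_stat = t_stat, df = df, p_value = p,
                 significant = p <= alpha, alpha = alpha),
            class = "group_comparison")
}

#' @export
print.hill_fit <- function(x, ...) {
  cat(sprintf("Hill fit%s: Kd = %.4g +/- %s uM (n = %d), n_H = %.3g\n",
              if (nzchar(x$construct_label)) paste0(" [", x$construct_label, "]") else "",
              x$kd, if (is.na(x$kd_sem)) "NA" else sprintf("%.2g", x$kd_sem),
              x$n_replicates, x$hill_n))
  invisible(x)
}

#' @export
print.exp_decay_fit <- function(x, ...) {
  cat(sprintf("Exponential decay fit%s: koff = %.4g +/- %s s^-1 (n = %d fits)\n",
              if (nzchar(x$construct_label)) paste0(" [", x$construct_label, "]") else "",
              x$koff, if (is.na(x$koff_sem)) "NA" else sprintf("%.2g", x$koff_sem),
              x$n_fits))
  invisible(x)
}

#' @export
print.group_comparison <- function(x, ...) {
  cat(sprintf("Two-group comparison: %.4g vs %.4g (fold %.3g), t = %.4g, df = %.3g, p = %.3g%s\n",
              x$estimate_a, x$estimate_b, x$fold_ratio, x$t_stat, x$df, x$p_value,
              if (x$significant) " *" else ""))
  invisible(x)
}
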