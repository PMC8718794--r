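#' Write a synthetic dataset to delimited text with a ground-truth sidecar
#'
#' Each dataset kind is written as plain CSV in the column layout its
#' reader expects; the generating parameters (ground truth) go to
#' `<path>.truth.json`. Transient trains additionally write a
#' `<path>.stim.csv` sidecar with the stimulus timestamps.
#'
#' @param x A `titration_dataset`, `stopped_flow_dataset`,
#'   `transient_trace` or `count_matrix`.
#' @param path Output CSV path.
#' @return `path`, invisibly.
#' @export
write_synth <- function(x, path) UseMethod("write_synth")

write_truth <- function(x, path) {
  if (!is.null(x$truth))
    jsonlite::write_json(x$truth, paste0(path, ".truth.json"),
                         auto_unbox = TRUE, digits = NA)
}

#' @export
write_synth.titration_dataset <- function(x, path) {
  write.csv(x$data, path, row.names = FALSE)
  write_truth(x, path)
  invisible(path)
}

#' @export
write_synth.stopped_flow_dataset <- function(x, path) {
  write.csv(x$traces, path, row.names = FALSE)
  write_truth(x, path)
  invisible(path)
}

#' @export
write_synth.transient_trace <- function(x, path) {
  write.csv(data.frame(t_s = x$time, v_channel = x$v, ca_channel = x$ca),
            path, row.names = FALSE)
  write.csv(data.frame(stim_s = x$stimulus_times),
            sub("\\.csv$", "", path) |> paste0(".stim.csv"), row.names = FALSE)
  write_truth(x, path)
  invisible(path)
}

#' @export
write_synth.count_matrix <- function(x, path) {
  # group labels as a header row above the counts, as panel exports do
  tab <- rbind(group = as.character(x$groups), x$counts)
  df <- data.frame(gene = rownames(tab), tab, check.names = FALSE)
  write.csv(df, path, row.names = FALSE)
  write_truth(x, path)
  invisible(path)
}

#' Read a titration CSV (columns ca_uM, fluor, replicate)
#' @param path CSV path.
#' @param construct_label Optional label.
#' @return A `titration_dataset` (without ground truth).
#' @export
read_titration <- function(path, construct_label = basename(path)) {
  d <- read.csv(path)
  need <- c("ca_uM", "fluor", "replicate")
  if (!all(need %in% names(d)))
    stop_invalid(sprintf("titration file must have columns %s",
                         paste(need, collapse = ", ")))
  structure(list(data = d[need], construct_label = construct_label, truth = NULL),
            class = "titration_dataset")
}

#' Read stopped-flow traces (columns t_ms, fluor, trace_id)
#' @param path CSV path.
#' @param dead_time Instrument dead time (ms).
#' @param construct_label Optional label.
#' @return A `stopped_flow_dataset`.
#' @export
read_stopped_flow <- function(path, dead_time = 1.1, construct_label = basename(path)) {
  d <- read.csv(path)
  need <- c("t_ms", "fluor", "trace_id")
  if (!all(need %in% names(d)))
    stop_invalid(sprintf("stopped-flow file must have columns %s",
                         paste(need, collapse = ", ")))
  structure(list(traces = d[need], dead_time = dead_time,
                 construct_label = construct_label, truth = NULL),
            class = "stopped_flow_dataset")
}

#' Read a transient train CSV plus its stimulus sidecar
#' @param path CSV path (columns t_s, v_channel, ca_channel).
#' @param stim_path Stimulus sidecar; default `<path minus .csv>.stim.csv`.
#' @param frame_rate Frames/s; inferred from the time column if NULL.
#' @param polarity Length-2 polarity (voltage, Ca).
#' @return A `transient_trace`.
#' @export
read_transient_train <- function(path, stim_path = NULL, frame_rate = NULL,
                                 polarity = c(1, 1)) {
  d <- read.csv(path)
  need <- c("t_s", "v_channel", "ca_channel")
  if (!all(need %in% names(d)))
    stop_invalid(sprintf("transient file must have columns %s",
                         paste(need, collapse = ", ")))
  stim_path <- stim_path %||% paste0(sub("\\.csv$", "", path), ".stim.csv")
  stim <- read.csv(stim_path)$stim_s
  if (is.null(frame_rate))
    frame_rate <- 1 / median(diff(d$t_s))
  structure(list(time = d$t_s, v = d$v_channel, ca = d$ca_channel,
                 stimulus_times = stim, frame_rate = frame_rate,
                 polarity = rep_len(polarity, 2L), truth = NULL),
            class = "transient_trace")
}

#' Read a count matrix CSV with a group-label header row
#' @param path CSV path as written by [write_synth()].
#' @param housekeeping Housekeeping gene names; default [HOUSEKEEPING_GENES]
#'   intersected with the genes present.
#' @return A `count_matrix`.
#' @export
read_counts <- function(path, housekeeping = NULL) {
  d <- read.csv(path, check.names = FALSE)
  if (names(d)[1] != "gene" || d$gene[1] != "group")
    stop_invalid("count file must start with a 'group' label row")
  groups <- factor(unlist(d[1, -1]), levels = unique(unlist(d[1, -1])))
  counts <- as.matrix(d[-1, -1])
  mode(counts) <- "numeric"
  rownames(counts) <- d$gene[-1]
  housekeeping <- housekeeping %||% intersect(HOUSEKEEPING_GENES, rownames(counts))
  structure(list(counts = counts, groups = groups, housekeeping = housekeeping,
                 truth = NULL),
            class = "count_matrix")
}
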