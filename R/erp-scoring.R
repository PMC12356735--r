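#' Feedback-locked EEG epochs
#'
#' Container for a trial x channel x time amplitude array (microvolts) with
#' its sampling rate, epoch window relative to feedback onset, channel roles
#' (which channel carries the frontocentral FRN/P3a site and which the
#' centroparietal P3b site), per-trial artifact-rejection mask, and the keys
#' that join epochs back to the behavioral events table.
#'
#' @param data Numeric array `trial x channel x time` in microvolts.
#' @param sampling_rate Sampling rate in Hz.
#' @param epoch_window Length-2 numeric, ms relative to feedback onset
#'   (default `c(-200, 600)`, i.e. 800 ms epochs).
#' @param channel_roles Named character vector mapping roles
#'   (`"frn_p3a_site"`, `"p3b_site"`) to channel names; channel names must
#'   match `dimnames(data)[[2]]`.
#' @param trial_keys Data.frame with one row per trial (join keys such as
#'   `participant_id`, `session`, `trial_index`).
#' @param rejection_mask Logical per-trial flag (TRUE = rejected); defaults
#'   to all retained.
#' @return A list of class `epoch_set`.
#' @export
epoch_set <- function(data, sampling_rate = 1000,
                      epoch_window = c(-200, 600),
                      channel_roles = c(frn_p3a_site = "FCz", p3b_site = "Pz"),
                      trial_keys = NULL, rejection_mask = NULL) {
  stopifnot(length(dim(data)) == 3L)
  n_time <- dim(data)[3]
  expected <- diff(epoch_window) * sampling_rate / 1000
  if (n_time != expected)
    stop("epoch_set: time axis has ", n_time, " samples; window of ",
         diff(epoch_window), " ms at ", sampling_rate, " Hz requires ",
         expected, call. = FALSE)
  if (epoch_window[1] >= 0)
    stop("epoch_set: epoch window must include a pre-onset baseline interval",
         call. = FALSE)
  if (is.null(dimnames(data)[[2]]))
    dimnames(data)[[2]] <- paste0("ch", seq_len(dim(data)[2]))
  missing_roles <- setdiff(channel_roles, dimnames(data)[[2]])
  if (length(missing_roles))
    stop("epoch_set: channels not present: ",
         paste(missing_roles, collapse = ", "), call. = FALSE)
  if (is.null(rejection_mask)) rejection_mask <- rep(FALSE, dim(data)[1])
  structure(list(data = data, sampling_rate = sampling_rate,
                 epoch_window = epoch_window, channel_roles = channel_roles,
                 trial_keys = trial_keys, rejection_mask = rejection_mask),
            class = "epoch_set")
}

#' Time axis of an epoch set
#'
#' Sample times in ms relative to feedback onset; the first sample sits at
#' the window start, the last one sampling interval before the window end.
#'
#' @param epochs An [epoch_set()].
#' @return Numeric vector of times in ms.
#' @export
epoch_times <- function(epochs) {
  step <- 1000 / epochs$sampling_rate
  seq(epochs$epoch_window[1], epochs$epoch_window[2] - step, by = step)
}

#' Cut feedback-locked epochs from continuous signals and baseline-correct
#'
#' Epochs span `epoch_window` ms around each feedback onset. The per-epoch,
#' per-channel mean over the pre-onset baseline interval
#' (`[epoch_window[1], 0)` ms) is subtracted. Onsets too close to the edges
#' of the recording are dropped (recorded in the `"dropped"` attribute).
#'
#' @param continuous Numeric matrix `channel x time` (rownames = channel
#'   names), sampled at `sampling_rate`.
#' @param onsets_ms Feedback-onset times in ms from the start of the signal.
#' @param sampling_rate Hz.
#' @param epoch_window ms relative to onset, default `c(-200, 600)`.
#' @param channel_roles As in [epoch_set()].
#' @param trial_keys Optional per-onset join keys (rows matching
#'   `onsets_ms`); dropped rows are removed.
#' @return An [epoch_set()].
#' @export
segment_and_baseline <- function(continuous, onsets_ms, sampling_rate = 1000,
                                 epoch_window = c(-200, 600),
                                 channel_roles = c(frn_p3a_site = "FCz",
                                                   p3b_site = "Pz"),
                                 trial_keys = NULL) {
  step <- 1000 / sampling_rate
  n_time <- as.integer(round(diff(epoch_window) / step))
  n_total <- ncol(continuous)
  onset_idx <- as.integer(round(onsets_ms / step)) + 1L
  first <- onset_idx + as.integer(round(epoch_window[1] / step))
  ok <- first >= 1L & (first + n_time - 1L) <= n_total
  if (any(!ok))
    warning(sum(!ok), " epoch(s) dropped: onset too close to recording edge")
  first <- first[ok]

  n_chan <- nrow(continuous)
  dat <- array(NA_real_, dim = c(length(first), n_chan, n_time),
               dimnames = list(NULL, rownames(continuous), NULL))
  n_base <- as.integer(round(-epoch_window[1] / step))
  for (i in seq_along(first)) {
    seg <- continuous[, first[i]:(first[i] + n_time - 1L), drop = FALSE]
    base <- rowMeans(seg[, seq_len(n_base), drop = FALSE])
    dat[i, , ] <- seg - base
  }
  if (!is.null(trial_keys)) trial_keys <- trial_keys[ok, , drop = FALSE]
  es <- epoch_set(dat, sampling_rate, epoch_window, channel_roles, trial_keys)
  attr(es, "dropped") <- which(!ok)
  es
}

#' Amplitude-based artifact rejection
#'
#' A trial is rejected when any scored channel violates any of: absolute
#' sample-to-sample voltage step above 50 microvolts/ms; any absolute value
#' above 100 microvolts; a max-minus-min difference above 100 microvolts
#' within the epoch; or activity (max-minus-min) below 0.1 microvolts inside
#' any sliding 100-ms window (1-sample stride).
#'
#' @param epochs An [epoch_set()].
#' @param channels Channels to screen; defaults to the scored role channels.
#' @param max_step Threshold in microvolts per ms.
#' @param max_abs Absolute-amplitude threshold in microvolts.
#' @param max_diff Within-epoch range threshold in microvolts.
#' @param min_activity Low-activity threshold in microvolts.
#' @param activity_window_ms Width of the low-activity window, ms.
#' @return Logical rejection mask, one flag per trial (TRUE = rejected).
#' @export
reject_artifacts <- function(epochs, channels = unname(epochs$channel_roles),
                             max_step = 50, max_abs = 100, max_diff = 100,
                             min_activity = 0.1, activity_window_ms = 100) {
  chan_idx <- match(channels, dimnames(epochs$data)[[2]])
  step_ms <- 1000 / epochs$sampling_rate
  w <- as.integer(round(activity_window_ms / step_ms))
  n_trials <- dim(epochs$data)[1]
  n_time <- dim(epochs$data)[3]

  reject_one <- function(x) {
    if (any(abs(diff(x)) / step_ms > max_step)) return(TRUE)
    if (any(abs(x) > max_abs)) return(TRUE)
    rng <- range(x)
    if (rng[2] - rng[1] > max_diff) return(TRUE)
    if (n_time >= w) {
      run_max <- zoo::rollmax(x, w)
      run_min <- -zoo::rollmax(-x, w)
      if (any(run_max - run_min < min_activity)) return(TRUE)
    }
    FALSE
  }

  mask <- logical(n_trials)
  for (i in seq_len(n_trials))
    for (ci in chan_idx) {
      if (reject_one(epochs$data[i, ci, ])) { mask[i] <- TRUE; break }
    }
  mask
}

#' FRN peak latency in a condition-average waveform
#'
#' The FRN peak is the most negative strict local minimum (a sample strictly
#' below both neighbors) with latency strictly inside the search window;
#' window endpoints are excluded and ties go to the earliest latency. `NA`
#' when no local minimum exists, which downstream scoring propagates as
#' outlier coding.
#'
#' @param average Numeric vector: condition-average time series at the
#'   frontocentral site.
#' @param times Sample times in ms (same length as `average`).
#' @param window Search window in ms post-feedback, default `c(200, 350)`.
#' @return Peak latency in ms, or `NA_real_`.
#' @export
frn_peak_latency <- function(average, times, window = c(200, 350)) {
  stopifnot(length(average) == length(times))
  n <- length(average)
  idx <- which(times > window[1] & times < window[2])
  idx <- idx[idx > 1L & idx < n]
  if (!length(idx)) return(NA_real_)
  is_min <- average[idx] < average[idx - 1L] & average[idx] < average[idx + 1L]
  cand <- idx[is_min]
  if (!length(cand)) return(NA_real_)
  times[cand[which.min(average[cand])]]
}

#' Single-trial FRN amplitude
#'
#' Mean amplitude over the 40-ms window from 20 ms before to 20 ms after the
#' condition-average peak latency. Missing latency yields a missing amplitude.
#'
#' @param epoch Numeric vector: single-trial time series at the
#'   frontocentral site.
#' @param times Sample times in ms.
#' @param peak_latency Latency from [frn_peak_latency()], ms.
#' @param half_width Half window width in ms (default 20).
#' @return Mean amplitude in microvolts, or `NA_real_`.
#' @export
single_trial_frn <- function(epoch, times, peak_latency, half_width = 20) {
  if (is.na(peak_latency)) return(NA_real_)
  sel <- times >= peak_latency - half_width & times <= peak_latency + half_width
  mean(epoch[sel])
}

#' P3 mean amplitude
#'
#' Mean amplitude in a fixed post-feedback window (default 300-500 ms);
#' applied at the frontocentral site for the P3a and the centroparietal site
#' for the P3b.
#'
#' @param epoch Numeric vector: single-trial time series.
#' @param times Sample times in ms.
#' @param window Scoring window in ms, default `c(300, 500)`.
#' @return Mean amplitude in microvolts.
#' @export
p3_amplitude <- function(epoch, times, window = c(300, 500)) {
  mean(epoch[times >= window[1] & times <= window[2]])
}

#' Score single-trial FRN, P3a and P3b amplitudes for an epoch set
#'
#' Retained trials are grouped into conditions by the supplied factors; the
#' FRN peak latency is localized in each condition-average waveform at the
#' frontocentral site and then applied to that condition's single trials.
#' Conditions whose average has no detectable peak have their trials flagged
#' as outliers with missing FRN amplitudes. P3a (frontocentral) and P3b
#' (centroparietal) are fixed-window means and never depend on the peak.
#'
#' @param epochs An [epoch_set()]; `trial_keys` must contain the columns in
#'   `condition_by`.
#' @param condition_by Character vector of `trial_keys` columns defining the
#'   per-person conditions for peak detection (default feedback timing x
#'   valence x learnability; `trial_keys` holds one participant-session or a
#'   `participant_id` column should be included here when it holds several).
#' @param rejection_mask Logical mask; defaults to `epochs$rejection_mask`.
#' @param frn_window,p3_window Scoring windows in ms.
#' @return Data.frame (one row per retained trial): the `trial_keys` columns
#'   plus `frn_amplitude`, `frn_peak_latency`, `p3a_amplitude`,
#'   `p3b_amplitude`, `outlier_flag`.
#' @export
score_epochs <- function(epochs,
                         condition_by = c("session", "feedback_valence",
                                          "learnability"),
                         rejection_mask = NULL,
                         frn_window = c(200, 350), p3_window = c(300, 500)) {
  if (is.null(rejection_mask)) rejection_mask <- epochs$rejection_mask
  keys <- epochs$trial_keys
  if (is.null(keys))
    stop("score_epochs: epochs carry no trial_keys", call. = FALSE)
  missing_cols <- setdiff(condition_by, names(keys))
  if (length(missing_cols))
    stop("score_epochs: trial_keys lack condition columns: ",
         paste(missing_cols, collapse = ", "), call. = FALSE)

  times <- epoch_times(epochs)
  frn_ch <- match(epochs$channel_roles[["frn_p3a_site"]],
                  dimnames(epochs$data)[[2]])
  p3b_ch <- match(epochs$channel_roles[["p3b_site"]],
                  dimnames(epochs$data)[[2]])

  keep <- which(!rejection_mask)
  out <- keys[keep, , drop = FALSE]
  out$frn_amplitude <- NA_real_
  out$frn_peak_latency <- NA_real_
  out$p3a_amplitude <- NA_real_
  out$p3b_amplitude <- NA_real_
  out$outlier_flag <- FALSE

  cond <- interaction(keys[keep, condition_by, drop = FALSE], drop = TRUE)
  for (lev in levels(cond)) {
    rows <- which(cond == lev)
    trials <- keep[rows]
    avg <- colMeans(matrix(epochs$data[trials, frn_ch, ],
                           nrow = length(trials)))
    lat <- frn_peak_latency(avg, times, frn_window)
    out$frn_peak_latency[rows] <- lat
    if (is.na(lat)) {
      out$outlier_flag[rows] <- TRUE
    } else {
      out$frn_amplitude[rows] <- vapply(trials, function(tr)
        single_trial_frn(epochs$data[tr, frn_ch, ], times, lat), numeric(1))
    }
    out$p3a_amplitude[rows] <- vapply(trials, function(tr)
      p3_amplitude(epochs$data[tr, frn_ch, ], times, p3_window), numeric(1))
    out$p3b_amplitude[rows] <- vapply(trials, function(tr)
      p3_amplitude(epochs$data[tr, p3b_ch, ], times, p3_window), numeric(1))
  }
  rownames(out) <- NULL
  out
}

#' Optional continuous-signal preprocessing
#'
#' Zero-phase Butterworth band-pass (default 0.1-30 Hz, order 2) with an
#' optional 50 Hz notch, and mastoid re-referencing (subtracting the mean of
#' the named mastoid channels from every other channel). Requires the
#' `signal` package for the filters. These mimic standard continuous-EEG
#' preprocessing; synthetic data is generated artifact-light so they are off
#' the default path.
#'
#' @param continuous Numeric matrix `channel x time`.
#' @param sampling_rate Hz.
#' @param band Band edges in Hz, default `c(0.1, 30)`.
#' @param notch Notch center in Hz, or `NULL` to skip.
#' @return Filtered matrix of the same shape.
#' @export
bandpass_filter <- function(continuous, sampling_rate = 1000,
                            band = c(0.1, 30), notch = 50) {
  if (!requireNamespace("signal", quietly = TRUE))
    stop("bandpass_filter requires the 'signal' package", call. = FALSE)
  ny <- sampling_rate / 2
  bp <- signal::butter(2, band / ny, type = "pass")
  out <- t(apply(continuous, 1, function(x) signal::filtfilt(bp, x)))
  if (!is.null(notch) && notch < ny) {
    bs <- signal::butter(2, c(notch - 1, notch + 1) / ny, type = "stop")
    out <- t(apply(out, 1, function(x) signal::filtfilt(bs, x)))
  }
  dimnames(out) <- dimnames(continuous)
  out
}

#' @rdname bandpass_filter
#' @param mastoids Channel names to average as the reference.
#' @export
rereference_mastoids <- function(continuous, mastoids = c("M1", "M2")) {
  idx <- match(mastoids, rownames(continuous))
  if (anyNA(idx))
    stop("rereference_mastoids: mastoid channels not found", call. = FALSE)
  ref <- colMeans(continuous[idx, , drop = FALSE])
  out <- sweep(continuous, 2, ref)
  out[-idx, , drop = FALSE]
}

#' Write / read an epoch set as a long-format TSV plus JSON sidecar
#'
#' The TSV holds one row per (trial, channel, sample) amplitude; the sidecar
#' stores sampling rate, epoch window, channel roles, rejection mask and the
#' trial keys. The round trip is lossless up to numeric formatting.
#'
#' @param epochs An [epoch_set()].
#' @param path Path of the TSV file; the sidecar is written with extension
#'   `.json` alongside.
#' @return `path` invisibly (`write_epochs`); an `epoch_set` (`read_epochs`).
#' @export
write_epochs <- function(epochs, path) {
  d <- dim(epochs$data)
  long <- data.frame(
    trial = rep(seq_len(d[1]), times = d[2] * d[3]),
    channel = rep(rep(dimnames(epochs$data)[[2]], each = d[1]), times = d[3]),
    sample = rep(seq_len(d[3]), each = d[1] * d[2]),
    amplitude = as.vector(epochs$data)
  )
  utils::write.table(long, path, sep = "\t", quote = FALSE, row.names = FALSE)
  side <- list(sampling_rate = epochs$sampling_rate,
               epoch_window = epochs$epoch_window,
               channel_roles = as.list(epochs$channel_roles),
               rejection_mask = epochs$rejection_mask,
               trial_keys = epochs$trial_keys,
               dim = d, channels = dimnames(epochs$data)[[2]])
  jsonlite::write_json(side, sub("\\.tsv$", ".json", path),
                       auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname write_epochs
#' @export
read_epochs <- function(path) {
  side <- jsonlite::read_json(sub("\\.tsv$", ".json", path),
                              simplifyVector = TRUE)
  long <- utils::read.delim(path)
  d <- side$dim
  dat <- array(long$amplitude, dim = d,
               dimnames = list(NULL, side$channels, NULL))
  keys <- side$trial_keys
  if (!is.null(keys)) keys <- as.data.frame(keys)
  epoch_set(dat, side$sampling_rate, side$epoch_window,
            unlist(side$channel_roles), keys,
            as.logical(side$rejection_mask))
}
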