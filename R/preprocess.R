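#' Preprocessing configuration
#'
#' The offline analysis chain applied to each recording, in fixed order:
#' zero-phase band-pass filter, re-reference to the linked mastoids, epoch,
#' baseline-correct, reject artifact trials.
#'
#' @param band_low_hz,band_high_hz Band-pass edges (Hz). Defaults 1 and 30.
#' @param filter_order Butterworth order (applied forward-backward, so the
#'   effective order doubles). Default 4.
#' @param bandpass Set `FALSE` to skip filtering (e.g. for noiseless
#'   parameter-recovery runs, where a 1 Hz high-pass would only distort the
#'   injected kernels).
#' @param reference Re-referencing scheme.
#' @param epoch_window_ms Half-open epoch window `[tmin, tmax)` in ms;
#'   default `c(-100, 400)` gives 500-ms epochs with a 100-ms baseline.
#' @param rejection_threshold_uv Absolute amplitude threshold (microvolts);
#'   a trial is rejected iff some scalp channel strictly exceeds it.
#' @param rejection_mode `"absolute"` (|value| > threshold at any sample) or
#'   `"peak_to_peak"` (per-channel range > threshold).
#' @return An object of class `preprocess_config`.
#' @export
preprocess_config <- function(band_low_hz = 1, band_high_hz = 30,
                              filter_order = 4, bandpass = TRUE,
                              reference = c("linked_mastoids", "average", "nose"),
                              epoch_window_ms = c(-100, 400),
                              rejection_threshold_uv = 70,
                              rejection_mode = c("absolute", "peak_to_peak")) {
  reference <- match.arg(reference)
  rejection_mode <- match.arg(rejection_mode)
  if (band_low_hz <= 0 || band_high_hz <= band_low_hz) {
    abort("Need 0 < band_low_hz < band_high_hz.")
  }
  if (rejection_threshold_uv <= 0) abort("`rejection_threshold_uv` must be > 0.")
  if (epoch_window_ms[1] > 0 || epoch_window_ms[2] <= 0) {
    abort("Epoch window must satisfy tmin <= 0 < tmax.")
  }
  structure(
    list(band_low_hz = band_low_hz, band_high_hz = band_high_hz,
         filter_order = filter_order, bandpass = bandpass,
         reference = reference, epoch_window_ms = epoch_window_ms,
         rejection_threshold_uv = rejection_threshold_uv,
         rejection_mode = rejection_mode),
    class = "preprocess_config"
  )
}

butter_coefs <- function(low, high, order, fs) {
  nyq <- fs / 2
  if (low <= 0 || high >= nyq) {
    abort(sprintf("Band edges must lie inside (0, %g) Hz.", nyq))
  }
  signal::butter(order, c(low, high) / nyq, type = "pass")
}

filt_rows <- function(mat, bf) {
  t(apply(mat, 1, function(row) signal::filtfilt(bf, row)))
}

#' Zero-phase band-pass filter
#'
#' Applies a Butterworth band-pass forward and backward (zero phase lag) to
#' each channel. Works on a channels x samples matrix, an `eeg_recording`,
#' or an `epoch_set` (per trial and channel). DC is rejected by
#' construction; output length equals input length.
#'
#' @param x Matrix, `eeg_recording`, or `epoch_set`.
#' @param low,high Band edges in Hz.
#' @param order Butterworth order.
#' @param sampling_rate_hz Required when `x` is a bare matrix.
#' @return Same type as `x`.
#' @export
bandpass_filter <- function(x, low = 1, high = 30, order = 4,
                            sampling_rate_hz = NULL) {
  UseMethod("bandpass_filter")
}

#' @export
bandpass_filter.matrix <- function(x, low = 1, high = 30, order = 4,
                                   sampling_rate_hz = NULL) {
  if (is.null(sampling_rate_hz)) abort("Provide `sampling_rate_hz` for a matrix.")
  filt_rows(x, butter_coefs(low, high, order, sampling_rate_hz))
}

#' @export
bandpass_filter.numeric <- function(x, low = 1, high = 30, order = 4,
                                    sampling_rate_hz = NULL) {
  if (is.null(sampling_rate_hz)) abort("Provide `sampling_rate_hz` for a vector.")
  as.numeric(signal::filtfilt(butter_coefs(low, high, order, sampling_rate_hz), x))
}

#' @export
bandpass_filter.eeg_recording <- function(x, low = 1, high = 30, order = 4,
                                          sampling_rate_hz = NULL) {
  bf <- butter_coefs(low, high, order, x$sampling_rate_hz)
  x$data <- filt_rows(x$data, bf)
  x$provenance <- c(x$provenance, sprintf("bandpass[%g-%g Hz]", low, high))
  x
}

#' @export
bandpass_filter.epoch_set <- function(x, low = 1, high = 30, order = 4,
                                      sampling_rate_hz = NULL) {
  bf <- butter_coefs(low, high, order, x$sampling_rate_hz)
  d <- dim(x$data)
  flat <- matrix(aperm(x$data, c(3, 1, 2)), nrow = d[3])  # samples x (trial*channel)
  flat <- apply(flat, 2, function(col) signal::filtfilt(bf, col))
  x$data <- aperm(array(flat, c(d[3], d[1], d[2])), c(2, 3, 1))
  x$provenance <- c(x$provenance, sprintf("bandpass[%g-%g Hz]", low, high))
  x
}

#' Re-reference a recording or epoch set
#'
#' `linked_mastoids` subtracts the instantaneous mean of A1 and A2 from
#' every channel; `average` subtracts the spatial mean of all channels.
#' Both are idempotent and preserve all pairwise channel differences.
#'
#' @param x An `eeg_recording` or `epoch_set`.
#' @param scheme `"linked_mastoids"` or `"average"`.
#' @return Same type as `x`, with an updated reference tag.
#' @export
rereference <- function(x, scheme = c("linked_mastoids", "average")) {
  scheme <- match.arg(scheme)
  if (inherits(x, "eeg_recording")) {
    x$data <- reref_signal(x$data, x$montage, scheme)
  } else if (inherits(x, "epoch_set")) {
    ref <- if (scheme == "linked_mastoids") {
      require_channels(x$montage, c("A1", "A2"))
      i <- match(c("A1", "A2"), x$montage$name)
      (x$data[, i[1], , drop = FALSE] + x$data[, i[2], , drop = FALSE]) / 2
    } else {
      arr <- apply(x$data, c(1, 3), mean)                 # trials x samples
      array(arr, c(dim(x$data)[1], 1L, dim(x$data)[3]))
    }
    for (ch in seq_len(dim(x$data)[2])) {
      x$data[, ch, ] <- x$data[, ch, ] - ref[, 1L, ]
    }
  } else {
    abort("`x` must be an `eeg_recording` or `epoch_set`.")
  }
  x$reference <- scheme
  x$provenance <- c(x$provenance, sprintf("rereference[%s]", scheme))
  x
}

reref_signal <- function(mat, montage, scheme) {
  if (scheme == "linked_mastoids") {
    require_channels(montage, c("A1", "A2"))
    i <- match(c("A1", "A2"), montage$name)
    ref <- colMeans(mat[i, , drop = FALSE])
  } else {
    ref <- colMeans(mat)
  }
  sweep(mat, 2, ref)
}

#' Extract epochs from a continuous recording
#'
#' One trial per selected event (all events in the simple condition; only
#' triplet-first tones, `triplet_pos == 1`, in the pattern condition), with
#' the half-open window `epoch_window_ms` relative to the event onset.
#' Events whose window would leave the recording are dropped with a
#' warning. If the recording carries an artifact plan, the planned bursts
#' are injected into their single target trial here.
#'
#' @param recording An `eeg_recording`.
#' @param events Event table.
#' @param epoch_window_ms Half-open window `[tmin, tmax)` in ms.
#' @return An `epoch_set` (codes and triplet positions carried per trial).
#' @export
epoch_recording <- function(recording, events, epoch_window_ms = c(-100, 400)) {
  fs <- recording$sampling_rate_hz
  n_pre <- round(-epoch_window_ms[1] / 1000 * fs)
  n_tot <- round(diff(epoch_window_ms) / 1000 * fs)
  offset <- attr(recording, "onset_offset_samples") %||% 0L

  sel <- if (identical(recording$condition, "pattern")) {
    which(!is.na(events$triplet_pos) & events$triplet_pos == 1L)
  } else {
    seq_len(nrow(events))
  }
  onsets <- events$onset_sample[sel] + offset
  start <- onsets - n_pre
  stop_ <- onsets + (n_tot - n_pre) - 1L
  ok <- start >= 0L & stop_ < ncol(recording$data)
  if (any(!ok)) {
    warn(sprintf("Dropped %d event(s) too close to the recording edge.", sum(!ok)))
  }
  sel <- sel[ok]
  start <- start[ok]
  n_trials <- length(sel)
  if (n_trials == 0) {
    data <- array(numeric(0), c(0L, nrow(recording$montage), n_tot))
  } else {
    idx <- as.vector(outer(seq_len(n_tot) - 1L, start, `+`)) + 1L
    block <- recording$data[, idx, drop = FALSE]                 # ch x (samp*trial)
    data <- aperm(array(block, c(nrow(block), n_tot, n_trials)), c(3, 1, 2))
  }

  ep <- epoch_set(
    data, fs, n_pre, recording$montage,
    condition = recording$condition,
    code = events$code[sel],
    triplet_pos = events$triplet_pos[sel],
    reference = recording$reference,
    subject_id = recording$subject_id,
    gender = recording$gender,
    provenance = c(recording$provenance, "epoch")
  )

  mp <- recording$mmn_plan
  if (!is.null(mp) && n_trials > 0) {
    t_ms <- times_ms(ep)
    kern <- -mp$scale * gaussian_kernel_ms(t_ms, mp$latency_ms, mp$sigma_ms)
    bump <- outer(mp$weights, kern)                    # channels x samples
    for (row in mp$event_rows) {
      tr <- match(row, sel)
      if (is.na(tr)) next
      ep$data[tr, , ] <- ep$data[tr, , ] + bump
    }
  }

  plan <- recording$artifact_plan
  if (!is.null(plan) && nrow(plan) > 0 && n_trials > 0) {
    t_ms <- times_ms(ep)
    for (i in seq_len(nrow(plan))) {
      tr <- match(plan$event_row[i], sel)
      if (is.na(tr)) next
      ch <- match(plan$channel[i], recording$montage$name)
      half <- plan$duration_ms[i] / 2
      k <- which(t_ms >= plan$center_ms[i] - half & t_ms <= plan$center_ms[i] + half)
      ph <- (t_ms[k] - plan$center_ms[i]) / 1000
      burst <- plan$amplitude_uv[i] *
        sin(2 * pi * plan$freq_hz[i] * ph + pi / 2) *
        (0.5 + 0.5 * cos(pi * (t_ms[k] - plan$center_ms[i]) / half))
      ep$data[tr, ch, k] <- ep$data[tr, ch, k] + burst
    }
    ep$provenance <- c(ep$provenance, "inject_artifacts")
  }
  ep
}

#' Baseline-correct epochs
#'
#' Subtracts, per trial and channel, the mean over the pre-stimulus window
#' `[tmin, 0)` ms.
#'
#' @param epochs An `epoch_set`.
#' @return The corrected `epoch_set`.
#' @export
baseline_correct <- function(epochs) {
  if (epochs$n_pre < 1) abort("No pre-stimulus samples to baseline on.")
  base <- epochs$data[, , seq_len(epochs$n_pre), drop = FALSE]
  means <- rowMeans(base, dims = 2)          # trials x channels
  epochs$data <- epochs$data - as.vector(means) # recycles over samples
  epochs$provenance <- c(epochs$provenance, "baseline")
  epochs
}

#' Reject artifact trials by amplitude threshold
#'
#' Marks a trial rejected iff any scalp channel (mastoids and any channels
#' in `exclude` are ignored) strictly exceeds the threshold: absolute
#' amplitude in `"absolute"` mode, per-channel peak-to-peak range in
#' `"peak_to_peak"` mode. Counts are reported via a message.
#'
#' @param epochs A baseline-corrected `epoch_set`.
#' @param threshold_uv Threshold in microvolts (default 70).
#' @param mode `"absolute"` or `"peak_to_peak"`.
#' @param exclude Channels excluded from the criterion.
#' @param quiet Suppress the count message.
#' @return The `epoch_set` with an updated rejection mask.
#' @export
reject_artifacts <- function(epochs, threshold_uv = 70,
                             mode = c("absolute", "peak_to_peak"),
                             exclude = c("A1", "A2"), quiet = FALSE) {
  mode <- match.arg(mode)
  if (threshold_uv <= 0) abort("`threshold_uv` must be > 0.")
  keep_ch <- !(epochs$montage$name %in% exclude)
  x <- epochs$data[, keep_ch, , drop = FALSE]
  stat <- if (mode == "absolute") {
    apply(abs(x), 1, max)
  } else {
    apply(x, 1, function(tr) max(apply(tr, 1, function(ch) diff(range(ch)))))
  }
  epochs$rejected <- stat > threshold_uv
  if (!quiet) {
    inform(sprintf("reject_artifacts: %d/%d trial(s) rejected (%s, +/-%g uV) [%s/%s]",
                   sum(epochs$rejected), length(stat), mode, threshold_uv,
                   epochs$subject_id, epochs$condition))
  }
  epochs$provenance <- c(epochs$provenance,
                         sprintf("reject[%s>%g]", mode, threshold_uv))
  epochs
}

#' Run the full preprocessing chain on a recording
#'
#' Filter -> re-reference -> epoch -> baseline-correct -> reject, in that
#' order, recorded in the result's provenance.
#'
#' @param recording An `eeg_recording`.
#' @param events Event table for the recording.
#' @param cfg A [preprocess_config()].
#' @param quiet Suppress per-stage messages.
#' @return A preprocessed `epoch_set`.
#' @export
preprocess_recording <- function(recording, events, cfg = preprocess_config(),
                                 quiet = FALSE) {
  stopifnot(inherits(cfg, "preprocess_config"))
  x <- recording
  if (isTRUE(cfg$bandpass)) {
    x <- bandpass_filter(x, cfg$band_low_hz, cfg$band_high_hz, cfg$filter_order)
  }
  if (cfg$reference != "nose") {
    x <- rereference(x, cfg$reference)
  }
  ep <- epoch_recording(x, events, cfg$epoch_window_ms)
  ep <- baseline_correct(ep)
  reject_artifacts(ep, cfg$rejection_threshold_uv, cfg$rejection_mode,
                   quiet = quiet)
}
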