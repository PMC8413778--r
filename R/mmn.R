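#' Average retained trials into an evoked response
#'
#' @param epochs An `epoch_set`.
#' @param label Stimulus code to average (`"standard"` or `"deviant"`); if
#'   `NULL`, all retained trials are averaged.
#' @return An object of class `mmn_evoked`: channels x samples matrix plus
#'   timing metadata and `n_trials_averaged`.
#' @export
average_evoked <- function(epochs, label = NULL) {
  keep <- !epochs$rejected
  if (!is.null(label)) keep <- keep & epochs$code == label
  if (!any(keep)) {
    abort(sprintf("No retained '%s' trials for subject %s / condition %s.",
                  label %||% "any", epochs$subject_id, epochs$condition))
  }
  tp <- unique(epochs$triplet_pos[keep])
  structure(
    list(data = colMeans(epochs$data[keep, , , drop = FALSE], dims = 1),
         sampling_rate_hz = epochs$sampling_rate_hz,
         n_pre = epochs$n_pre,
         montage = epochs$montage,
         condition = epochs$condition,
         label = label %||% "all",
         n_trials_averaged = sum(keep),
         triplet_first_only = length(tp) == 1L && identical(tp, 1L),
         subject_id = epochs$subject_id,
         gender = epochs$gender,
         reference = epochs$reference),
    class = "mmn_evoked"
  )
}

#' @export
print.mmn_evoked <- function(x, ...) {
  cat(sprintf("<evoked '%s': %d channels x %d samples, n = %d trials>\n",
              x$label, nrow(x$data), ncol(x$data), x$n_trials_averaged))
  invisible(x)
}

#' Tidy an evoked response
#' @param x An `mmn_evoked`.
#' @param ... Unused.
#' @return Tibble with `channel`, `time_ms`, `value_uv`.
#' @export
tidy.mmn_evoked <- function(x, ...) {
  t_ms <- times_ms(x)
  tibble::tibble(
    channel = rep(x$montage$name, times = ncol(x$data)),
    time_ms = rep(t_ms, each = nrow(x$data)),
    value_uv = as.vector(x$data)
  )
}

new_difference_wave <- function(standard, deviant, kind) {
  if (!identical(dim(standard$data), dim(deviant$data)) ||
      !identical(standard$montage$name, deviant$montage$name)) {
    abort("Standard and deviant evokeds must share montage and shape.")
  }
  if (standard$sampling_rate_hz != deviant$sampling_rate_hz ||
      standard$n_pre != deviant$n_pre) {
    abort("Standard and deviant evokeds must share timing.")
  }
  structure(
    list(standard = standard, deviant = deviant,
         diff = deviant$data - standard$data,
         kind = kind,
         sampling_rate_hz = standard$sampling_rate_hz,
         n_pre = standard$n_pre,
         montage = standard$montage,
         subject_id = standard$subject_id,
         gender = standard$gender),
    class = "difference_wave"
  )
}

#' Simple (frequency) MMN difference wave
#'
#' The MMN waveform of the frequency oddball condition: the deviant evoked
#' response minus the standard evoked response, element by element.
#'
#' @param standard,deviant `mmn_evoked` objects from the same epochs.
#' @return A `difference_wave` with elements `standard`, `deviant`, `diff`.
#' @export
simple_mmn <- function(standard, deviant) {
  new_difference_wave(standard, deviant, "simple")
}

#' Pattern MMN difference wave
#'
#' The pattern oddball MMN: response to the first tone of the deviant
#' (falling) triplet minus the response to the first tone of the standard
#' (rising) triplet. Both inputs must have been averaged from
#' triplet-first epochs only.
#'
#' @param standard_first_tone,deviant_first_tone `mmn_evoked` objects built
#'   exclusively from `triplet_pos == 1` epochs.
#' @return A `difference_wave`.
#' @export
pattern_mmn <- function(standard_first_tone, deviant_first_tone) {
  if (!isTRUE(standard_first_tone$triplet_first_only) ||
      !isTRUE(deviant_first_tone$triplet_first_only)) {
    abort("Pattern MMN requires evokeds averaged from triplet-first epochs only.")
  }
  new_difference_wave(standard_first_tone, deviant_first_tone, "pattern")
}

#' @export
print.difference_wave <- function(x, ...) {
  cat(sprintf("<%s MMN difference wave: %d channels x %d samples (%d std / %d dev trials)>\n",
              x$kind, nrow(x$diff), ncol(x$diff),
              x$standard$n_trials_averaged, x$deviant$n_trials_averaged))
  invisible(x)
}

#' Tidy a difference wave
#' @param x A `difference_wave`.
#' @param ... Unused.
#' @return Long tibble with `channel`, `time_ms`, `standard_uv`,
#'   `deviant_uv`, `diff_uv`.
#' @export
tidy.difference_wave <- function(x, ...) {
  t_ms <- times_ms(x)
  tibble::tibble(
    channel = rep(x$montage$name, times = ncol(x$diff)),
    time_ms = rep(t_ms, each = nrow(x$diff)),
    standard_uv = as.vector(x$standard$data),
    deviant_uv = as.vector(x$deviant$data),
    diff_uv = as.vector(x$diff)
  )
}

channel_trace <- function(dw, electrode) {
  i <- match(electrode, dw$montage$name)
  if (is.na(i)) abort(sprintf("Electrode '%s' not in montage.", electrode))
  dw$diff[i, ]
}

#' Peak latency of the MMN
#'
#' Latency (ms) of the most negative sample of the difference wave at one
#' electrode within a closed search window; ties resolve to the earliest
#' sample. A flat trace in the window returns the window start with the
#' `no_unique_peak` attribute set.
#'
#' @param dw A `difference_wave`.
#' @param electrode Electrode label; default `"Fz"`.
#' @param window Search window in ms, default `c(100, 250)`.
#' @return Latency in ms (scalar) with attribute `no_unique_peak`.
#' @export
peak_latency <- function(dw, electrode = "Fz", window = c(100, 250)) {
  tr <- channel_trace(dw, electrode)
  t_ms <- times_ms(dw)
  idx <- window_sample_idx(t_ms, window[1], window[2])
  if (!length(idx)) abort("Search window lies outside the epoch.")
  seg <- tr[idx]
  flat <- diff(range(seg)) == 0
  lat <- if (flat) t_ms[idx[1]] else t_ms[idx[which.min(seg)]]
  structure(lat, no_unique_peak = flat)
}

#' Mean MMN amplitude around the individual peak
#'
#' Mean of the difference wave over a window of `width_ms` centered on the
#' individual peak latency (inclusive at sample resolution). Reported in
#' the negativity-positive convention — the negated signed mean — so a
#' negative (MMN-like) deflection yields a positive number as printed in
#' group tables, while a positive-going window mean yields a negative
#' number. Negation, unlike an absolute value, keeps the measure linear,
#' so group means of individual measures equal the measure of the group
#' mean. The raw signed mean is kept in the `signed` attribute. Windows
#' extending past the epoch are clamped and flagged.
#'
#' @param dw A `difference_wave`.
#' @param electrode Electrode label.
#' @param peak_latency_ms Peak latency from [peak_latency()].
#' @param width_ms Window width in ms, default 50 (i.e. peak +/- 25 ms).
#' @return Amplitude in microvolts (negativity-positive), with attributes
#'   `signed`, `clamped`, `window`.
#' @export
mean_amplitude <- function(dw, electrode = "Fz", peak_latency_ms,
                           width_ms = 50) {
  tr <- channel_trace(dw, electrode)
  t_ms <- times_ms(dw)
  half <- width_ms / 2
  lo <- peak_latency_ms - half
  hi <- peak_latency_ms + half
  clamped <- lo < t_ms[1] - 1e-9 || hi > t_ms[length(t_ms)] + 1e-9
  lo <- max(lo, t_ms[1])
  hi <- min(hi, t_ms[length(t_ms)])
  idx <- window_sample_idx(t_ms, lo, hi)
  signed <- mean(tr[idx])
  structure(-signed, signed = signed, clamped = clamped,
            window = c(lo, hi))
}

#' Per-subject MMN measures at one electrode
#'
#' Bundles [peak_latency()] and [mean_amplitude()] into one tidy row, the
#' unit of all downstream group statistics.
#'
#' @param dw A `difference_wave`.
#' @param electrode Electrode label, default `"Fz"`.
#' @param window Peak search window (ms).
#' @param width_ms Mean-amplitude window width (ms).
#' @return One-row tibble: `subject_id`, `gender`, `condition`,
#'   `electrode`, `peak_latency_ms`, `mean_amplitude_uv`
#'   (negativity-positive),
#'   `amplitude_signed_uv`, `window_start_ms`, `window_end_ms`,
#'   `n_trials_standard`, `n_trials_deviant`, `clamped`, `no_unique_peak`.
#' @export
measure_mmn <- function(dw, electrode = "Fz", window = c(100, 250),
                        width_ms = 50) {
  lat <- peak_latency(dw, electrode, window)
  amp <- mean_amplitude(dw, electrode, as.numeric(lat), width_ms)
  tibble::tibble(
    subject_id = dw$subject_id,
    gender = dw$gender,
    condition = dw$kind,
    electrode = electrode,
    peak_latency_ms = as.numeric(lat),
    mean_amplitude_uv = as.numeric(amp),
    amplitude_signed_uv = attr(amp, "signed"),
    window_start_ms = attr(amp, "window")[1],
    window_end_ms = attr(amp, "window")[2],
    n_trials_standard = dw$standard$n_trials_averaged,
    n_trials_deviant = dw$deviant$n_trials_averaged,
    clamped = attr(amp, "clamped"),
    no_unique_peak = attr(lat, "no_unique_peak")
  )
}

#' Derive the MMN difference wave from a preprocessed epoch set
#'
#' Averages standards and deviants over retained trials and subtracts. In
#' the pattern condition the epoch set must already be time-locked to
#' triplet-first tones (as produced by [epoch_recording()]).
#'
#' @param epochs A preprocessed `epoch_set` containing both codes.
#' @return A `difference_wave`.
#' @export
derive_mmn <- function(epochs) {
  std <- average_evoked(epochs, "standard")
  dev <- average_evoked(epochs, "deviant")
  if (identical(epochs$condition, "pattern")) {
    pattern_mmn(std, dev)
  } else {
    simple_mmn(std, dev)
  }
}
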