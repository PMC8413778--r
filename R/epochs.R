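#' Construct an epoch set
#'
#' The pipeline's working currency: a trials x channels x samples array of
#' voltages (microvolts) together with timing metadata, per-trial stimulus
#' codes, a rejection mask, and the montage. Sample 0 of the post-stimulus
#' part sits at time 0 ms; the window is half-open `[tmin, tmax)`.
#'
#' @param data Numeric array, trials x channels x samples.
#' @param sampling_rate_hz Sampling rate in Hz.
#' @param n_pre Number of pre-stimulus samples (time 0 is sample `n_pre`,
#'   0-based).
#' @param montage Montage tibble; `dim(data)[2]` must equal `nrow(montage)`.
#' @param condition Condition label, e.g. `"simple"` or `"pattern"`.
#' @param code Character vector of per-trial stimulus codes
#'   (`"standard"`/`"deviant"`).
#' @param triplet_pos Integer vector of per-trial triplet positions (or `NA`).
#' @param rejected Logical rejection mask (default: none rejected).
#' @param reference Reference tag (`"nose"`, `"linked_mastoids"`, `"average"`).
#' @param subject_id,gender Optional subject metadata.
#' @param provenance Character vector of processing steps applied, in order.
#' @return An object of class `epoch_set`.
#' @export
epoch_set <- function(data, sampling_rate_hz, n_pre, montage,
                      condition = "simple",
                      code = rep("standard", dim(data)[1]),
                      triplet_pos = rep(NA_integer_, dim(data)[1]),
                      rejected = rep(FALSE, dim(data)[1]),
                      reference = "nose",
                      subject_id = NA_character_,
                      gender = NA_character_,
                      provenance = character()) {
  if (length(dim(data)) != 3L) {
    abort("`data` must be a 3-D array: trials x channels x samples.")
  }
  if (dim(data)[2] != nrow(montage)) {
    abort(sprintf("Channel mismatch: data has %d channels, montage %d.",
                  dim(data)[2], nrow(montage)))
  }
  n_trials <- dim(data)[1]
  stopifnot(length(code) == n_trials, length(rejected) == n_trials,
            length(triplet_pos) == n_trials)
  dimnames(data) <- list(NULL, montage$name, NULL)
  structure(
    list(data = data,
         sampling_rate_hz = sampling_rate_hz,
         n_pre = as.integer(n_pre),
         montage = montage,
         condition = condition,
         code = code,
         triplet_pos = as.integer(triplet_pos),
         rejected = as.logical(rejected),
         reference = reference,
         subject_id = subject_id,
         gender = gender,
         provenance = provenance),
    class = "epoch_set"
  )
}

#' @export
print.epoch_set <- function(x, ...) {
  d <- dim(x$data)
  cat(sprintf(
    "<epoch_set: %d trials (%d retained) x %d channels x %d samples>\n",
    d[1], sum(!x$rejected), d[2], d[3]))
  cat(sprintf("  subject: %s  condition: %s  reference: %s\n",
              x$subject_id, x$condition, x$reference))
  cat(sprintf("  fs = %g Hz, window [%.1f, %.1f) ms\n",
              x$sampling_rate_hz, min(times_ms(x)),
              max(times_ms(x)) + 1000 / x$sampling_rate_hz))
  if (length(x$provenance)) {
    cat("  provenance:", paste(x$provenance, collapse = " -> "), "\n")
  }
  invisible(x)
}

n_trials <- function(epochs) dim(epochs$data)[1]
n_retained <- function(epochs) sum(!epochs$rejected)

times_ms <- function(x) {
  n_samples <- if (inherits(x, "epoch_set")) {
    dim(x$data)[3]
  } else if (inherits(x, "difference_wave")) {
    ncol(x$diff)
  } else {
    ncol(x$data)
  }
  epoch_times_ms(n_samples, x$n_pre, x$sampling_rate_hz)
}

#' Tidy an epoch set into a long tibble
#'
#' @param x An `epoch_set`.
#' @param ... Unused.
#' @return Tibble with columns `trial`, `code`, `rejected`, `channel`,
#'   `time_ms`, `value_uv`.
#' @export
tidy.epoch_set <- function(x, ...) {
  d <- dim(x$data)
  t_ms <- times_ms(x)
  tibble::tibble(
    trial = rep(seq_len(d[1]), times = d[2] * d[3]),
    code = rep(x$code, times = d[2] * d[3]),
    rejected = rep(x$rejected, times = d[2] * d[3]),
    channel = rep(rep(x$montage$name, each = d[1]), times = d[3]),
    time_ms = rep(t_ms, each = d[1] * d[2]),
    value_uv = as.vector(x$data)
  )
}

#' Split an epoch set by stimulus code
#'
#' @param epochs An `epoch_set`.
#' @return Named list of `epoch_set`s, one per stimulus code present.
#' @export
split_epochs <- function(epochs) {
  codes <- unique(epochs$code)
  out <- lapply(codes, function(cd) subset_epochs(epochs, epochs$code == cd))
  setNames(out, codes)
}

subset_epochs <- function(epochs, keep) {
  epochs$data <- epochs$data[keep, , , drop = FALSE]
  epochs$code <- epochs$code[keep]
  epochs$triplet_pos <- epochs$triplet_pos[keep]
  epochs$rejected <- epochs$rejected[keep]
  epochs
}

#' Continuous multichannel recording
#'
#' A channels x samples matrix of voltages (microvolts) with sampling-rate
#' and montage metadata, as produced by the synthetic-data module before
#' epoching.
#'
#' @param data Numeric matrix, channels x samples.
#' @param sampling_rate_hz Sampling rate in Hz.
#' @param montage Montage tibble.
#' @param reference Reference tag.
#' @param condition Condition label carried through to epochs.
#' @param subject_id,gender Optional subject metadata.
#' @param artifact_plan Optional tibble describing per-trial artifact bursts
#'   to inject at epoch extraction (see [generate_subject_recording()]).
#' @param provenance Character vector of processing steps applied.
#' @return An object of class `eeg_recording`.
#' @export
eeg_recording <- function(data, sampling_rate_hz, montage,
                          reference = "nose", condition = "simple",
                          subject_id = NA_character_, gender = NA_character_,
                          artifact_plan = NULL, provenance = character()) {
  if (!is.matrix(data) || nrow(data) != nrow(montage)) {
    abort("`data` must be a channels x samples matrix matching the montage.")
  }
  rownames(data) <- montage$name
  structure(
    list(data = data, sampling_rate_hz = sampling_rate_hz,
         montage = montage, reference = reference, condition = condition,
         subject_id = subject_id, gender = gender,
         artifact_plan = artifact_plan, provenance = provenance),
    class = "eeg_recording"
  )
}

#' @export
print.eeg_recording <- function(x, ...) {
  cat(sprintf("<eeg_recording: %d channels x %d samples (%.1f s at %g Hz)>\n",
              nrow(x$data), ncol(x$data),
              ncol(x$data) / x$sampling_rate_hz, x$sampling_rate_hz))
  cat(sprintf("  subject: %s  condition: %s  reference: %s\n",
              x$subject_id, x$condition, x$reference))
  invisible(x)
}
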