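#' Write / read an epoch set as delimited text plus JSON sidecar
#'
#' The native on-disk format is language-agnostic and inspectable: a TSV
#' matrix `<prefix>_data.tsv` with one row per (trial, channel) pair —
#' trial-major, i.e. row `(t - 1) * n_channels + c` holds trial `t`,
#' channel `c` — and columns `s1...sK` for the samples, together with a
#' JSON sidecar `<prefix>_meta.json` holding `sampling_rate_hz`,
#' `channel_names`, `units`, `tmin_ms`, `condition`, per-trial labels and
#' the rejection mask. Doubles are written with 17 significant digits, so
#' `read_epochs(write_epochs(x))` is bit-exact.
#'
#' @param epochs An `epoch_set`.
#' @param prefix File prefix (no extension).
#' @param path Prefix used when writing.
#' @return `write_epochs()` returns `prefix` invisibly; `read_epochs()`
#'   returns the reconstructed `epoch_set`.
#' @export
write_epochs <- function(epochs, prefix) {
  d <- dim(epochs$data)
  flat <- matrix(aperm(epochs$data, c(2, 1, 3)), nrow = d[1] * d[2])
  # %.17g guarantees the decimal text parses back to the identical double
  lines <- c(paste(paste0("s", seq_len(d[3])), collapse = "\t"),
             apply(matrix(sprintf("%.17g", flat), nrow = nrow(flat)), 1,
                   paste, collapse = "\t"))
  writeLines(lines, paste0(prefix, "_data.tsv"))
  meta <- list(
    n_trials = d[1], n_channels = d[2], n_samples = d[3],
    sampling_rate_hz = epochs$sampling_rate_hz,
    n_pre = epochs$n_pre,
    tmin_ms = -epochs$n_pre / epochs$sampling_rate_hz * 1000,
    units = "uV",
    channel_names = epochs$montage$name,
    montage_x = epochs$montage$x,
    montage_y = epochs$montage$y,
    condition = epochs$condition,
    code = epochs$code,
    triplet_pos = epochs$triplet_pos,
    rejected = epochs$rejected,
    reference = epochs$reference,
    subject_id = epochs$subject_id,
    gender = epochs$gender,
    provenance = epochs$provenance
  )
  jsonlite::write_json(meta, paste0(prefix, "_meta.json"),
                       auto_unbox = TRUE, digits = NA, null = "null", na = "null")
  invisible(prefix)
}

#' @rdname write_epochs
#' @export
read_epochs <- function(path) {
  meta_path <- paste0(path, "_meta.json")
  data_path <- paste0(path, "_data.tsv")
  if (!file.exists(meta_path)) abort(sprintf("Missing sidecar: %s", meta_path))
  meta <- jsonlite::read_json(meta_path, simplifyVector = TRUE)
  for (key in c("sampling_rate_hz", "n_trials", "n_channels", "n_samples",
                "channel_names")) {
    if (is.null(meta[[key]])) {
      abort(sprintf("Sidecar %s is missing required key `%s`.", meta_path, key))
    }
  }
  # utils::read.delim parses doubles with correctly-rounded strtod, which
  # the fast readr parser does not guarantee; exactness matters here.
  flat <- as.matrix(utils::read.delim(data_path, colClasses = "numeric"))
  expected <- c(meta$n_trials * meta$n_channels, meta$n_samples)
  if (!identical(dim(flat), as.integer(expected))) {
    abort(sprintf("Epoch matrix shape mismatch in %s: expected %d x %d, found %d x %d.",
                  data_path, expected[1], expected[2], nrow(flat), ncol(flat)))
  }
  data <- aperm(array(flat, c(meta$n_channels, meta$n_trials, meta$n_samples)),
                c(2, 1, 3))
  tp <- meta$triplet_pos
  if (is.list(tp)) {
    tp <- vapply(tp, function(v) if (is.null(v)) NA_integer_ else as.integer(v),
                 integer(1))
  }
  tp <- suppressWarnings(as.integer(tp))
  montage <- new_montage(
    tibble::tibble(name = meta$channel_names, x = meta$montage_x, y = meta$montage_y),
    reference = meta$reference %||% "nose")
  epoch_set(
    data, meta$sampling_rate_hz, meta$n_pre, montage,
    condition = meta$condition,
    code = meta$code,
    triplet_pos = tp,
    rejected = meta$rejected,
    reference = meta$reference,
    subject_id = meta$subject_id %||% NA_character_,
    gender = meta$gender %||% NA_character_,
    provenance = meta$provenance %||% character()
  )
}

#' Write / read the tidy measures table
#'
#' @param measures Measures tibble (one row per subject x condition).
#' @param path CSV path.
#' @export
write_measures <- function(measures, path) {
  readr::write_csv(measures, path, progress = FALSE)
  invisible(path)
}

#' @rdname write_measures
#' @export
read_measures <- function(path) {
  readr::read_csv(path, show_col_types = FALSE, progress = FALSE)
}

#' Read a study configuration from YAML
#'
#' Top-level keys mirror the arguments of [study_config()]; `cells` is a
#' list of records with `gender`, `condition`, `latency_mean`,
#' `latency_sd`, `amplitude_mean`, `amplitude_sd`. A file containing only
#' `preset: reference` (plus overrides) expands to
#' [reference_study_config()].
#'
#' @param path YAML file path.
#' @return A `study_config`.
#' @export
read_study_config <- function(path) {
  y <- yaml::read_yaml(path)
  if (identical(y$preset, "reference")) {
    y$preset <- NULL
    return(do.call(reference_study_config, y))
  }
  if (!is.null(y$cells)) {
    y$cells <- dplyr::bind_rows(lapply(y$cells, tibble::as_tibble))
  }
  do.call(study_config, y)
}
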