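#' Run the full study pipeline on synthetic data
#'
#' Streams subject by subject through the whole chain — stimulus sequence,
#' continuous synthesis, preprocessing, difference waves, per-subject
#' measures and scalp maps — then computes the group statistics: per
#' condition a stimulus-type (deviant, standard) x gender mixed ANOVA on
#' mean amplitudes in the individual MMN window, condition x gender mixed
#' ANOVAs on MMN amplitude and peak latency, post hoc paired and
#' independent t-tests on peak latency, and the DISS randomization test per
#' condition. Fully deterministic given the configuration and seed.
#'
#' @param study A [study_config()] (the seed inside it drives all
#'   synthesis).
#' @param prep A [preprocess_config()].
#' @param n_perm Permutations for the DISS tests.
#' @param quiet Suppress per-stage messages.
#' @return An object of class `run_report`; see Details. All embedded
#'   tables carry `config_hash` and `seed` attributes.
#' @export
run_study <- function(study, prep = preprocess_config(), n_perm = 10000,
                      quiet = TRUE) {
  stopifnot(inherits(study, "study_config"), inherits(prep, "preprocess_config"))
  profiles <- draw_subject_profiles(study)
  ids <- unique(profiles$subject_id)
  if (length(unique(profiles$gender)) < 2) {
    abort("Group statistics need both genders present; got a single group.")
  }
  seeds <- matrix(derive_seeds(study$seed, 4L * length(ids)), ncol = 4L)
  hash <- config_hash(list(study = study[setdiff(names(study), "montage")],
                           prep = unclass(prep), n_perm = n_perm))

  counts <- list(); meas <- list(); maps <- list(); stim_amp <- list()
  fz <- NULL
  for (i in seq_along(ids)) {
    draws <- profiles[profiles$subject_id == ids[i], ]
    prof <- profile_from_draws(draws, study)
    for (k in 1:2) {
      cn <- c("simple", "pattern")[k]
      ev <- generate_stimulus_sequence(sequence_config(
        cn, n_deviants = study$n_deviants, p_deviant = study$p_deviant,
        soa_ms = study$soa_ms, tone_duration_ms = study$tone_duration_ms,
        sampling_rate_hz = study$sampling_rate_hz, seed = seeds[i, k]))
      rec <- generate_subject_recording(
        prof, ev, study$montage, fwhm_ms = study$fwhm_ms,
        amplitude_mode = study$amplitude_mode,
        epoch_window_ms = prep$epoch_window_ms, seed = seeds[i, k + 2L])
      ep <- preprocess_recording(rec, ev, prep, quiet = quiet)
      counts[[length(counts) + 1L]] <- tibble::tibble(
        subject_id = ids[i], gender = prof$gender, condition = cn,
        presented = n_trials(ep) + attr(ep, "dropped_edge") %||% 0L,
        retained = n_retained(ep), rejected = sum(ep$rejected))
      dw <- derive_mmn(ep)
      m <- measure_mmn(dw)
      meas[[length(meas) + 1L]] <- m
      mp <- subject_topomap(dw, m)
      mp$subject_id <- ids[i]
      mp$gender <- prof$gender
      mp$condition <- cn
      maps[[length(maps) + 1L]] <- mp
      if (is.null(fz)) fz <- match("Fz", study$montage$name)
      t_ms <- times_ms(dw)
      win <- window_sample_idx(t_ms, m$window_start_ms, m$window_end_ms)
      stim_amp[[length(stim_amp) + 1L]] <- tibble::tibble(
        subject_id = rep(ids[i], 2), gender = rep(prof$gender, 2),
        condition = rep(cn, 2), stimulus = c("standard", "deviant"),
        amplitude_uv = c(mean(dw$standard$data[fz, win]),
                         mean(dw$deviant$data[fz, win])))
    }
  }
  trial_counts <- dplyr::bind_rows(counts)
  measures <- dplyr::bind_rows(meas)
  maps_tbl <- dplyr::bind_rows(maps)
  stim_amp_tbl <- dplyr::bind_rows(stim_amp)

  cell_summary <- measures |>
    dplyr::group_by(.data$gender, .data$condition) |>
    dplyr::summarise(
      n = dplyr::n(),
      amplitude_mean_uv = mean(.data$mean_amplitude_uv),
      amplitude_sem_uv = sd(.data$mean_amplitude_uv) / sqrt(dplyr::n()),
      latency_mean_ms = mean(.data$peak_latency_ms),
      latency_sem_ms = sd(.data$peak_latency_ms) / sqrt(dplyr::n()),
      .groups = "drop")

  anovas <- list(
    amplitude_stimulus_by_gender = lapply(
      setNames(c("simple", "pattern"), c("simple", "pattern")),
      function(cn) mixed_anova_2x2(
        dplyr::filter(stim_amp_tbl, .data$condition == cn),
        dv = "amplitude_uv", within = "stimulus")),
    amplitude_condition_by_gender = mixed_anova_2x2(measures, "mean_amplitude_uv"),
    latency_condition_by_gender = mixed_anova_2x2(measures, "peak_latency_ms")
  )

  wide_lat <- tidyr::pivot_wider(
    measures[, c("subject_id", "gender", "condition", "peak_latency_ms")],
    names_from = "condition", values_from = "peak_latency_ms")
  tt <- list()
  for (g in c("female", "male")) {
    wl <- wide_lat[wide_lat$gender == g, ]
    tt[[paste0("latency_paired_", g)]] <- paired_t(wl$simple, wl$pattern)
  }
  for (cn in c("simple", "pattern")) {
    tt[[paste0("latency_gender_", cn)]] <- independent_t(
      wide_lat[[cn]][wide_lat$gender == "female"],
      wide_lat[[cn]][wide_lat$gender == "male"])
  }
  ttests <- dplyr::bind_rows(lapply(tt, tidy), .id = "contrast")

  diss_seeds <- derive_seeds(study$seed + 1L, 2L)
  diss_tests <- list(
    simple = diss_permutation_test(
      dplyr::rename(dplyr::filter(maps_tbl, .data$condition == "simple"),
                    group = "gender"), n_perm = n_perm, seed = diss_seeds[1]),
    pattern = diss_permutation_test(
      dplyr::rename(dplyr::filter(maps_tbl, .data$condition == "pattern"),
                    group = "gender"), n_perm = n_perm, seed = diss_seeds[2])
  )

  out <- list(
    trial_counts = stamp_provenance(trial_counts, hash, study$seed),
    measures = stamp_provenance(measures, hash, study$seed),
    maps = stamp_provenance(maps_tbl, hash, study$seed),
    cell_summary = stamp_provenance(cell_summary, hash, study$seed),
    anovas = anovas,
    ttests = stamp_provenance(ttests, hash, study$seed),
    diss = diss_tests,
    config_hash = hash,
    seed = study$seed
  )
  class(out) <- "run_report"
  out
}

#' @export
print.run_report <- function(x, ...) {
  cat("MMN study run report\n")
  cat(sprintf("  %d subjects, config hash %s, seed %d\n",
              length(unique(x$measures$subject_id)), x$config_hash, x$seed))
  cat(sprintf("  trials retained: %d / %d\n",
              sum(x$trial_counts$retained), sum(x$trial_counts$presented)))
  cat("\nCell summary (mean amplitude uV / peak latency ms, SEM):\n")
  print(as.data.frame(x$cell_summary), digits = 4, row.names = FALSE)
  cat("\nGender x condition ANOVA on peak latency:\n")
  print(x$anovas$latency_condition_by_gender)
  cat("\nPost hoc t-tests on peak latency:\n")
  print(as.data.frame(x$ttests), digits = 3, row.names = FALSE)
  cat(sprintf("\nDISS (female vs male): simple %.3f (p = %.3g), pattern %.3f (p = %.3g)\n",
              x$diss$simple$diss_observed, x$diss$simple$p_value,
              x$diss$pattern$diss_observed, x$diss$pattern$p_value))
  invisible(x)
}

#' Serialize a run report to JSON
#'
#' Null distributions are summarized (mean and 95th percentile) rather than
#' dumped in full; set `keep_null = TRUE` to include them.
#'
#' @param report A `run_report`.
#' @param path Output path.
#' @param keep_null Include the full DISS null distributions.
#' @export
write_run_report <- function(report, path, keep_null = FALSE) {
  j <- list(
    config_hash = report$config_hash,
    seed = report$seed,
    trial_counts = report$trial_counts,
    cell_summary = report$cell_summary,
    measures = report$measures,
    anovas = lapply(report$anovas, function(a) {
      if (inherits(a, "mmn_anova")) tidy(a) else lapply(a, tidy)
    }),
    ttests = report$ttests,
    diss = lapply(report$diss, function(d) {
      out <- tidy(d)
      if (keep_null) out$null_distribution <- list(d$null_distribution)
      out
    })
  )
  jsonlite::write_json(j, path, auto_unbox = TRUE, digits = NA, na = "null")
  invisible(path)
}
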