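#' Subject profile for the synthetic-data generator
#'
#' Holds one simulated participant's MMN parameters: per-condition peak
#' latency (ms) and amplitude (microvolts, magnitude of the negativity),
#' background noise level, and the fraction of trials carrying an injected
#' artifact burst.
#'
#' @param subject_id Subject label.
#' @param gender `"female"` or `"male"`.
#' @param mmn_latency_ms Named numeric, latency per condition, e.g.
#'   `c(simple = 173.6, pattern = 150.1)`. Valid profiles lie in [100, 250].
#' @param mmn_amplitude_uv Named numeric, MMN magnitude per condition (the
#'   kernel is negative-going; this is its positive magnitude).
#' @param noise_sd_uv Marginal standard deviation of the background noise.
#' @param artifact_trial_fraction Fraction of epochs receiving an injected
#'   high-amplitude burst.
#' @return An object of class `subject_profile`.
#' @export
subject_profile <- function(subject_id, gender = c("female", "male"),
                            mmn_latency_ms, mmn_amplitude_uv,
                            noise_sd_uv = 10, artifact_trial_fraction = 0) {
  gender <- match.arg(gender)
  if (any(mmn_latency_ms < 100 | mmn_latency_ms > 250)) {
    abort("`mmn_latency_ms` must lie within [100, 250] ms for a valid profile.")
  }
  assert_scalar_number(noise_sd_uv, "noise_sd_uv", lower = 0)
  assert_scalar_number(artifact_trial_fraction, "artifact_trial_fraction",
                       lower = 0, upper = 1)
  structure(
    list(subject_id = subject_id, gender = gender,
         mmn_latency_ms = mmn_latency_ms,
         mmn_amplitude_uv = mmn_amplitude_uv,
         noise_sd_uv = noise_sd_uv,
         artifact_trial_fraction = artifact_trial_fraction),
    class = "subject_profile"
  )
}

# Cosine-tapered spatial weight over planar montage distance from a center;
# exactly zero beyond `radius`, so occipital sites and the mastoids carry no
# MMN signal by construction.
cosine_taper_weights <- function(montage, center, radius) {
  d <- sqrt((montage$x - center[1])^2 + (montage$y - center[2])^2)
  w <- ifelse(d >= radius, 0, cos(pi / 2 * d / radius)^2)
  w
}

# Fronto-central MMN scalp profile, normalized to 1 at Fz so the configured
# amplitude is realized exactly at the measurement electrode.
mmn_spatial_weights <- function(montage) {
  require_channels(montage, "Fz")
  w <- cosine_taper_weights(montage, center = c(0, 0.35), radius = 1.1)
  w / w[match("Fz", montage$name)]
}

# Broader central profile for the obligatory P1-N1-P2 response to every tone.
# It is identical for standards and deviants and therefore cancels exactly in
# the deviant-minus-standard difference wave.
erp_spatial_weights <- function(montage) {
  w <- cosine_taper_weights(montage, center = c(0, 0.15), radius = 1.8)
  w / max(w)
}

# Obligatory auditory response template: sum of Gaussian kernels
# (peak_ms, sd_ms, amplitude_uv).
p1_n1_p2_components <- function() {
  tibble::tribble(
    ~peak_ms, ~sd_ms, ~amplitude_uv,
    55,       12,      1.2,
    105,      16,     -2.5,
    180,      22,      1.8
  )
}

gaussian_kernel_ms <- function(t_ms, peak_ms, sd_ms) {
  exp(-((t_ms - peak_ms)^2) / (2 * sd_ms^2))
}

# Discrete-grid calibration of the MMN kernel scale. Computes the unit
# Gaussian on the exact epoch sample grid, applies the same baseline
# subtraction and window selection as the measurement stage, and returns the
# scale that makes the recovered measure equal `amplitude_uv` exactly in the
# noiseless, unfiltered case.
mmn_kernel_scale <- function(amplitude_uv, latency_ms, sigma_ms,
                             sampling_rate_hz,
                             epoch_window_ms = c(-100, 400),
                             search_window_ms = c(100, 250),
                             mean_window_width_ms = 50,
                             amplitude_mode = c("window_mean", "peak")) {
  amplitude_mode <- match.arg(amplitude_mode)
  n_pre <- round(-epoch_window_ms[1] / 1000 * sampling_rate_hz)
  n_tot <- round(diff(epoch_window_ms) / 1000 * sampling_rate_hz)
  t_ms <- epoch_times_ms(n_tot, n_pre, sampling_rate_hz)
  g <- gaussian_kernel_ms(t_ms, latency_ms, sigma_ms)
  base_idx <- which(t_ms < 0)
  g_base <- if (length(base_idx)) mean(g[base_idx]) else 0
  win_idx <- window_sample_idx(t_ms, search_window_ms[1], search_window_ms[2])
  if (!length(win_idx)) abort("Search window contains no samples.")
  peak_j <- win_idx[which.max(g[win_idx])]
  factor <- if (amplitude_mode == "peak") {
    g[peak_j] - g_base
  } else {
    half <- mean_window_width_ms / 2
    lo <- max(t_ms[peak_j] - half, t_ms[1])
    hi <- min(t_ms[peak_j] + half, t_ms[length(t_ms)])
    mw <- window_sample_idx(t_ms, lo, hi)
    mean(g[mw]) - g_base
  }
  if (factor <= 1e-12) abort("Degenerate MMN kernel calibration (factor <= 0).")
  list(scale = amplitude_uv / factor, peak_time_ms = t_ms[peak_j])
}

# Add a Gaussian bump (evaluated in ms) to a sampled time course, in place.
add_gaussian <- function(x, center_sample, sd_ms, amp, sampling_rate_hz) {
  sd_samp <- sd_ms / 1000 * sampling_rate_hz
  lo <- max(1L, floor(center_sample - 5 * sd_samp))
  hi <- min(length(x), ceiling(center_sample + 5 * sd_samp))
  if (lo > hi) return(x)
  k <- lo:hi
  t_rel <- (k - center_sample) / sampling_rate_hz * 1000
  x[k] <- x[k] + amp * gaussian_kernel_ms(t_rel, 0, sd_ms)
  x
}

# Spatially correlated AR(1) noise: channels x samples. Marginal SD equals
# `noise_sd_uv`; channel correlation follows a squared-exponential kernel
# over planar montage distance; temporal correlation is AR(1).
colored_noise <- function(n_samples, montage, noise_sd_uv,
                          ar_coef = 0.95, spatial_length = 0.6) {
  n_ch <- nrow(montage)
  if (noise_sd_uv == 0) return(matrix(0, n_ch, n_samples))
  d <- as.matrix(stats::dist(cbind(montage$x, montage$y)))
  K <- exp(-d^2 / (2 * spatial_length^2)) + diag(1e-8, n_ch)
  L <- chol(K)
  z <- matrix(rnorm(n_ch * n_samples), n_ch, n_samples)
  e <- crossprod(L, z) * noise_sd_uv * sqrt(1 - ar_coef^2)
  t(apply(e, 1, function(row) {
    as.numeric(stats::filter(row, ar_coef, method = "recursive"))
  }))
}

#' Synthesize a continuous nose-referenced recording for one subject
#'
#' Every tone evokes the same P1-N1-P2 template; each deviant epoch
#' additionally contains a negative Gaussian MMN kernel peaking
#' `mmn_latency_ms` after the unit's first tone, weighted by a
#' fronto-central scalp profile that is exactly zero at occipital sites and
#' the mastoids. Background noise is AR(1) in time with spatially
#' correlated channel loadings. The MMN kernel and the artifact bursts are
#' planned here but injected trial-locked at epoch extraction, so each
#' affects exactly its own trial: with a 180-ms SOA and 500-ms epochs,
#' anything written into the continuous trace would bleed into the
#' neighbouring epochs (including their baselines).
#'
#' @param profile A [subject_profile()].
#' @param events Event table from [generate_stimulus_sequence()].
#' @param montage Montage tibble (must contain Fz, A1, A2).
#' @param fwhm_ms Full width at half maximum of the MMN Gaussian kernel.
#' @param amplitude_mode `"window_mean"`: the kernel is scaled so the
#'   pipeline's 50-ms window mean recovers `mmn_amplitude_uv` exactly;
#'   `"peak"`: the most negative sample equals `-mmn_amplitude_uv`.
#' @param epoch_window_ms,search_window_ms,mean_window_width_ms Epoching and
#'   measurement conventions used for amplitude calibration; keep in sync
#'   with the preprocessing configuration.
#' @param ar_coef,spatial_length Noise model parameters.
#' @param artifact_amplitude_uv Peak amplitude of injected artifact bursts.
#' @param seed Integer seed.
#' @return An `eeg_recording` with attribute `onset_offset_samples` and, if
#'   `artifact_trial_fraction > 0`, an `artifact_plan` tibble.
#' @export
generate_subject_recording <- function(profile, events, montage = montage_1020_32(),
                                       fwhm_ms = 60,
                                       amplitude_mode = c("window_mean", "peak"),
                                       epoch_window_ms = c(-100, 400),
                                       search_window_ms = c(100, 250),
                                       mean_window_width_ms = 50,
                                       ar_coef = 0.95, spatial_length = 0.6,
                                       artifact_amplitude_uv = 150,
                                       seed = 1L) {
  amplitude_mode <- match.arg(amplitude_mode)
  require_channels(montage, c("Fz", "A1", "A2"))
  condition <- attr(events, "condition") %||% "simple"
  fs <- attr(events, "sampling_rate_hz")
  if (is.null(fs)) abort("`events` must carry a `sampling_rate_hz` attribute.")
  if (condition == "pattern" && any(is.na(events$triplet_pos))) {
    abort("Pattern-condition events must all carry `triplet_pos`.")
  }
  lat <- profile$mmn_latency_ms[condition]
  amp <- profile$mmn_amplitude_uv[condition]
  if (is.na(lat) || is.na(amp)) {
    abort(sprintf("Profile has no MMN parameters for condition '%s'.", condition))
  }
  sigma_ms <- fwhm_ms / (2 * sqrt(2 * log(2)))

  offset <- round(0.8 * fs)
  n_samples <- offset + max(events$onset_sample) + round(1.0 * fs)
  onsets <- events$onset_sample + offset

  # Unanalyzed boundary standards flank the stream so every analyzed epoch
  # has the full neighbour-tone context (as inside a continuous block);
  # without them the obligatory responses would not cancel exactly in the
  # averages of edge trials.
  soa_samp <- round((attr(events, "soa_ms") %||% 180) * fs / 1000)
  pad <- c(offset - (3:1) * soa_samp,
           offset + max(events$onset_sample) + (1:3) * soa_samp)

  # Fz-referenced unit time courses, later spread over the scalp profiles.
  erp_tc <- numeric(n_samples)
  comps <- p1_n1_p2_components()
  for (i in seq_len(nrow(comps))) {
    mu <- c(onsets, pad) + comps$peak_ms[i] / 1000 * fs
    for (m in mu) {
      erp_tc <- add_gaussian(erp_tc, m, comps$sd_ms[i], comps$amplitude_uv[i], fs)
    }
  }

  is_unit_start <- is.na(events$triplet_pos) | events$triplet_pos == 1L
  dev_units <- which(events$code == "deviant" & is_unit_start)
  cal <- mmn_kernel_scale(amp, lat, sigma_ms, fs, epoch_window_ms,
                          search_window_ms, mean_window_width_ms,
                          amplitude_mode)

  w_erp <- erp_spatial_weights(montage)
  w_mmn <- mmn_spatial_weights(montage)
  sig <- outer(w_erp, erp_tc)

  # The deviance response is modeled trial-locked: each deviant epoch
  # receives the kernel at extraction time. With a 180-ms SOA and 500-ms
  # epochs a kernel written into the continuous trace would bleed into the
  # neighbouring standards' epochs (including their baselines), making the
  # generated effect structure impossible to state exactly.
  mmn_plan <- list(event_rows = dev_units, latency_ms = lat,
                   sigma_ms = sigma_ms, scale = cal$scale, weights = w_mmn)

  res <- with_seed(seed, {
    noise <- colored_noise(n_samples, montage, profile$noise_sd_uv,
                           ar_coef, spatial_length)
    sel <- which(is_unit_start)
    n_art <- round(profile$artifact_trial_fraction * length(sel))
    plan <- NULL
    if (n_art > 0) {
      rows <- sort(sample(sel, n_art))
      plan <- tibble::tibble(
        event_row = rows,
        channel = sample(scalp_channels(montage), n_art, replace = TRUE),
        amplitude_uv = artifact_amplitude_uv,
        freq_hz = 10,
        center_ms = 150,
        duration_ms = 80
      )
    }
    list(noise = noise, plan = plan)
  })
  plan <- res$plan
  data <- sig + res$noise

  rec <- eeg_recording(data, fs, montage, reference = "nose",
                       condition = condition,
                       subject_id = profile$subject_id,
                       gender = profile$gender,
                       artifact_plan = plan,
                       provenance = "synthesize")
  attr(rec, "onset_offset_samples") <- offset
  rec$mmn_plan <- mmn_plan
  rec
}

#' Generate raw epochs for one subject
#'
#' Convenience wrapper: synthesizes the continuous recording and extracts
#' raw (unfiltered, nose-referenced, not baseline-corrected) epochs, one per
#' unit onset. Use [preprocess_recording()] for the full preprocessing
#' chain.
#'
#' @inheritParams generate_subject_recording
#' @param epoch_window_ms Epoch window, half-open, in ms.
#' @return An `epoch_set` with per-trial stimulus codes; split standards
#'   from deviants with [split_epochs()].
#' @export
generate_subject_epochs <- function(profile, events, montage = montage_1020_32(),
                                    fwhm_ms = 60,
                                    amplitude_mode = c("window_mean", "peak"),
                                    epoch_window_ms = c(-100, 400),
                                    seed = 1L, ...) {
  rec <- generate_subject_recording(profile, events, montage,
                                    fwhm_ms = fwhm_ms,
                                    amplitude_mode = amplitude_mode,
                                    epoch_window_ms = epoch_window_ms,
                                    seed = seed, ...)
  epoch_recording(rec, events, epoch_window_ms = epoch_window_ms)
}
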