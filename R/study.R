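#' Study-level configuration for the synthetic-data generator
#'
#' Describes a two-condition (simple and pattern oddball), two-gender study:
#' group sizes, the cell means and between-subject SDs of MMN peak latency
#' and mean amplitude, the stimulus design, and the noise model.
#'
#' Between-subject latency draws come from truncated normal distributions
#' on [100, 250] ms whose parent parameters are solved so that the
#' truncated distribution has exactly the configured mean and SD.
#' Amplitude draws come from moment-matched gamma distributions: a
#' measurable MMN has a strictly positive magnitude, and the gamma family
#' accommodates cells whose SD exceeds their mean (coefficient of
#' variation above 1), which no normal truncated at zero can represent.
#' Within each subject the two conditions' values are coupled through a
#' Gaussian copula with correlation `within_subject_r`, preserving the
#' configured marginals.
#'
#' @param n_female,n_male Group sizes.
#' @param cells Tibble with columns `gender`, `condition`, `latency_mean`,
#'   `latency_sd`, `amplitude_mean`, `amplitude_sd` (8 rows for the full
#'   2 x 2 design; SDs between-subject).
#' @param within_subject_r Copula correlation between a subject's two
#'   condition values (same for latency and amplitude).
#' @param noise_sd_uv Background noise SD per trial (microvolts).
#' @param artifact_trial_fraction Fraction of trials with injected bursts.
#' @param n_deviants,p_deviant,soa_ms,tone_duration_ms Stimulus design.
#' @param sampling_rate_hz Sampling rate of the synthetic recordings.
#' @param fwhm_ms MMN kernel width.
#' @param amplitude_mode See [generate_subject_recording()].
#' @param montage Montage tibble.
#' @param seed Master seed; all subject-level seeds derive from it.
#' @return An object of class `study_config`.
#' @export
study_config <- function(n_female, n_male, cells,
                         within_subject_r = 0.5,
                         noise_sd_uv = 10,
                         artifact_trial_fraction = 0,
                         n_deviants = 200, p_deviant = 0.16,
                         soa_ms = 180, tone_duration_ms = 50,
                         sampling_rate_hz = 512,
                         fwhm_ms = 60,
                         amplitude_mode = c("window_mean", "peak"),
                         montage = montage_1020_32(),
                         seed = 1L) {
  amplitude_mode <- match.arg(amplitude_mode)
  if (!is.numeric(n_female) || !is.numeric(n_male) ||
      n_female < 0 || n_male < 0 || n_female + n_male < 2) {
    abort("Need `n_female` + `n_male` >= 2.")
  }
  needed <- c("gender", "condition", "latency_mean", "latency_sd",
              "amplitude_mean", "amplitude_sd")
  if (!all(needed %in% names(cells))) {
    abort(sprintf("`cells` must have columns: %s.", paste(needed, collapse = ", ")))
  }
  if (any(cells$latency_sd < 0) || any(cells$amplitude_sd < 0)) {
    abort("Cell SDs must be >= 0.")
  }
  assert_scalar_number(within_subject_r, "within_subject_r", lower = -1, upper = 1)
  structure(
    list(n_female = as.integer(n_female), n_male = as.integer(n_male),
         cells = tibble::as_tibble(cells),
         within_subject_r = within_subject_r,
         noise_sd_uv = noise_sd_uv,
         artifact_trial_fraction = artifact_trial_fraction,
         n_deviants = as.integer(n_deviants), p_deviant = p_deviant,
         soa_ms = soa_ms, tone_duration_ms = tone_duration_ms,
         sampling_rate_hz = sampling_rate_hz, fwhm_ms = fwhm_ms,
         amplitude_mode = amplitude_mode, montage = montage,
         seed = as.integer(seed)),
    class = "study_config"
  )
}

#' Reference study preset
#'
#' The study conditions the generator emulates: 14 females and 15 males,
#' 200 deviants per condition at deviant probability .16, SOA 180 ms, with
#' cell means of MMN peak latency and mean amplitude set to the reference
#' group values and between-subject SDs reconstructed as SEM * sqrt(n).
#'
#' @param n_female,n_male Group sizes (defaults 14 and 15). The cell SDs
#'   are always reconstructed from the reference SEMs at the reference
#'   group sizes, so shrinking the groups changes only how many subjects
#'   are drawn, not the population they are drawn from.
#' @param ... Overrides passed to [study_config()] (e.g. `n_deviants`,
#'   `noise_sd_uv`, `seed`).
#' @return A `study_config`.
#' @examples
#' cfg <- reference_study_config(seed = 7)
#' cfg$n_female + cfg$n_male  # 29
#' @export
reference_study_config <- function(n_female = 14, n_male = 15, ...) {
  n_f <- 14
  n_m <- 15
  cells <- tibble::tribble(
    ~gender,  ~condition, ~latency_mean, ~latency_sem, ~amplitude_mean, ~amplitude_sem,
    "female", "simple",   173.55,        9.06,          1.89,            0.25,
    "male",   "simple",   142.58,        6.76,          1.48,            0.23,
    "female", "pattern",  150.11,        8.32,          1.03,            0.10,
    "male",   "pattern",  158.08,        7.49,          0.79,            0.22
  )
  n_per <- ifelse(cells$gender == "female", n_f, n_m)
  cells$latency_sd <- cells$latency_sem * sqrt(n_per)
  cells$amplitude_sd <- cells$amplitude_sem * sqrt(n_per)
  study_config(n_female = n_female, n_male = n_male,
               cells = cells[, c("gender", "condition", "latency_mean",
                                 "latency_sd", "amplitude_mean", "amplitude_sd")],
               ...)
}

# ---- truncated-normal moment matching -------------------------------------

# Mean and SD of N(mu, sigma^2) truncated to [lower, upper].
truncnorm_moments <- function(mu, sigma, lower, upper) {
  a <- (lower - mu) / sigma
  b <- (upper - mu) / sigma
  Z <- pnorm(b) - pnorm(a)
  pa <- dnorm(a); pb <- dnorm(b)
  m <- mu + sigma * (pa - pb) / Z
  v <- sigma^2 * (1 + (ifelse(is.finite(a), a * pa, 0) -
                         ifelse(is.finite(b), b * pb, 0)) / Z -
                    ((pa - pb) / Z)^2)
  c(mean = m, sd = sqrt(pmax(v, 0)))
}

# Solve for parent (mu, sigma) such that the truncated distribution has the
# requested mean and SD. Returns list(mu, sigma, lower, upper). Solutions
# are cached (the same study cells recur across simulation replicates).
.truncnorm_cache <- new.env(parent = emptyenv())

match_truncnorm <- function(mean, sd, lower = -Inf, upper = Inf) {
  if (sd == 0) return(list(mu = mean, sigma = 0, lower = lower, upper = upper))
  # Untruncated tail mass negligible: keep parent parameters as-is.
  p_out <- pnorm(lower, mean, sd) + pnorm(upper, mean, sd, lower.tail = FALSE)
  if (p_out < 1e-12) return(list(mu = mean, sigma = sd, lower = lower, upper = upper))
  key <- paste(mean, sd, lower, upper, sep = "|")
  hit <- .truncnorm_cache[[key]]
  if (!is.null(hit)) return(hit)
  obj <- function(par) {
    mo <- truncnorm_moments(par[1], exp(par[2]), lower, upper)
    ((mo["mean"] - mean) / sd)^2 + ((mo["sd"] - sd) / sd)^2
  }
  fit <- optim(c(mean, log(sd)), obj, method = "Nelder-Mead",
               control = list(reltol = 1e-15, maxit = 5000))
  if (fit$value > 1e-10) {
    abort(sprintf(
      "Cannot match a truncated normal on [%.3g, %.3g] to mean %.4g, sd %.4g.",
      lower, upper, mean, sd))
  }
  out <- list(mu = fit$par[1], sigma = exp(fit$par[2]), lower = lower, upper = upper)
  .truncnorm_cache[[key]] <- out
  out
}

# Quantile transform: uniform u -> matched truncated normal draw.
qtruncnorm <- function(u, m) {
  if (m$sigma == 0) return(rep(m$mu, length(u)))
  plo <- pnorm(m$lower, m$mu, m$sigma)
  phi <- pnorm(m$upper, m$mu, m$sigma)
  qnorm(plo + u * (phi - plo), m$mu, m$sigma)
}

# Gamma parameters with the requested mean and SD (positive support).
match_gamma <- function(mean, sd) {
  if (mean <= 0) abort("Amplitude cell means must be positive.")
  list(shape = (mean / sd)^2, rate = mean / sd^2, mean = mean, sd = sd)
}

qgamma_matched <- function(u, m) {
  if (m$sd == 0) return(rep(m$mean, length(u)))
  stats::qgamma(u, shape = m$shape, rate = m$rate)
}

# ---- subject draws ---------------------------------------------------------

#' Draw per-subject MMN parameters for a study
#'
#' @param study A [study_config()].
#' @return Tibble with one row per subject x condition: `subject_id`,
#'   `gender`, `condition`, `mmn_latency_ms`, `mmn_amplitude_uv`.
#' @export
draw_subject_profiles <- function(study) {
  stopifnot(inherits(study, "study_config"))
  r <- study$within_subject_r
  conds <- c("simple", "pattern")
  with_seed(study$seed, {
    rows <- list()
    for (g in c("female", "male")) {
      n_g <- if (g == "female") study$n_female else study$n_male
      if (n_g == 0) next
      cell <- lapply(conds, function(cn) {
        ci <- study$cells[study$cells$gender == g & study$cells$condition == cn, ]
        if (nrow(ci) != 1) abort(sprintf("Missing cell for %s/%s.", g, cn))
        list(lat = match_truncnorm(ci$latency_mean, ci$latency_sd, 100, 250),
             amp = match_gamma(ci$amplitude_mean, ci$amplitude_sd))
      })
      names(cell) <- conds
      # Gaussian copula across the two conditions, separately for latency
      # and amplitude; marginals stay exactly the matched truncated normals.
      z_lat <- copula_pair(n_g, r)
      z_amp <- copula_pair(n_g, r)
      for (k in seq_along(conds)) {
        cn <- conds[k]
        rows[[length(rows) + 1L]] <- tibble::tibble(
          subject_id = sprintf("%s%02d", substr(g, 1, 1), seq_len(n_g)),
          gender = g,
          condition = cn,
          mmn_latency_ms = qtruncnorm(pnorm(z_lat[, k]), cell[[cn]]$lat),
          mmn_amplitude_uv = qgamma_matched(pnorm(z_amp[, k]), cell[[cn]]$amp)
        )
      }
    }
    dplyr::bind_rows(rows)
  })
}

# n pairs of standard normals with correlation r.
copula_pair <- function(n, r) {
  z1 <- rnorm(n)
  z2 <- r * z1 + sqrt(1 - r^2) * rnorm(n)
  cbind(z1, z2)
}

profile_from_draws <- function(draws, study) {
  sid <- draws$subject_id[1]
  subject_profile(
    subject_id = sid,
    gender = draws$gender[1],
    mmn_latency_ms = setNames(draws$mmn_latency_ms, draws$condition),
    mmn_amplitude_uv = setNames(draws$mmn_amplitude_uv, draws$condition),
    noise_sd_uv = study$noise_sd_uv,
    artifact_trial_fraction = study$artifact_trial_fraction
  )
}

# Deterministic sub-seeds (< 2^31) for each subject x condition x purpose.
derive_seeds <- function(master_seed, n) {
  with_seed(master_seed, sample.int(.Machine$integer.max - 1L, n))
}

#' Generate a full synthetic study
#'
#' Draws subject profiles from the configured cell distributions and
#' synthesizes raw epochs for every subject in both conditions. Fully
#' reproducible from the study seed. For large designs prefer streaming
#' subject-by-subject with [run_study()], or write each subject to disk via
#' `out_dir`.
#'
#' @param study A [study_config()].
#' @param out_dir Optional directory: per-subject epoch files are written
#'   (see [write_epochs()]) instead of kept in memory, and the returned
#'   object's `subjects` element holds file prefixes.
#' @return A list of class `study_dataset` with elements `profiles`
#'   (tibble), `subjects` (named list: per subject, per condition, an
#'   `epoch_set` or a file prefix) and `config`.
#' @export
generate_study <- function(study, out_dir = NULL) {
  stopifnot(inherits(study, "study_config"))
  profiles <- draw_subject_profiles(study)
  ids <- unique(profiles$subject_id)
  seeds <- matrix(derive_seeds(study$seed, 4L * length(ids)), ncol = 4L)
  subjects <- list()
  for (i in seq_along(ids)) {
    draws <- profiles[profiles$subject_id == ids[i], ]
    prof <- profile_from_draws(draws, study)
    per_cond <- list()
    for (k in 1:2) {
      cn <- c("simple", "pattern")[k]
      ev <- generate_stimulus_sequence(sequence_config(
        cn, n_deviants = study$n_deviants, p_deviant = study$p_deviant,
        soa_ms = study$soa_ms, tone_duration_ms = study$tone_duration_ms,
        sampling_rate_hz = study$sampling_rate_hz, seed = seeds[i, k]))
      ep <- generate_subject_epochs(
        prof, ev, study$montage, fwhm_ms = study$fwhm_ms,
        amplitude_mode = study$amplitude_mode, seed = seeds[i, k + 2L])
      if (is.null(out_dir)) {
        per_cond[[cn]] <- ep
      } else {
        prefix <- file.path(out_dir, sprintf("%s_%s", ids[i], cn))
        write_epochs(ep, prefix)
        per_cond[[cn]] <- prefix
      }
    }
    subjects[[ids[i]]] <- per_cond
  }
  structure(list(profiles = profiles, subjects = subjects, config = study),
            class = "study_dataset")
}

# The exact Fz difference trace a noiseless, unfiltered pipeline run
# produces for one subject-condition: the calibrated kernel after per-trial
# baseline correction (standards cancel to zero).
analytic_diff_trace <- function(latency_ms, amplitude_uv, study,
                                epoch_window_ms = c(-100, 400)) {
  fs <- study$sampling_rate_hz
  sigma_ms <- study$fwhm_ms / (2 * sqrt(2 * log(2)))
  n_pre <- round(-epoch_window_ms[1] / 1000 * fs)
  n_tot <- round(diff(epoch_window_ms) / 1000 * fs)
  t_ms <- epoch_times_ms(n_tot, n_pre, fs)
  cal <- mmn_kernel_scale(amplitude_uv, latency_ms, sigma_ms, fs,
                          epoch_window_ms,
                          amplitude_mode = study$amplitude_mode)
  g <- gaussian_kernel_ms(t_ms, latency_ms, sigma_ms)
  g_base <- mean(g[t_ms < 0])
  list(trace = -cal$scale * (g - g_base), n_pre = n_pre, fs = fs)
}

# Wrap a single-channel trace as a difference_wave so the real measurement
# functions run on it unchanged.
trace_as_dw <- function(trace, n_pre, fs, subject_id, gender, condition) {
  mont <- new_montage(tibble::tibble(name = "Fz", x = 0, y = 0.5))
  ev <- list(data = matrix(trace, nrow = 1), n_trials_averaged = 1L)
  structure(
    list(standard = ev, deviant = ev,
         diff = matrix(trace, nrow = 1, dimnames = list("Fz", NULL)),
         kind = condition, sampling_rate_hz = fs, n_pre = n_pre,
         montage = mont, subject_id = subject_id, gender = gender),
    class = "difference_wave"
  )
}

#' Measures a noiseless pipeline run would recover
#'
#' The generative model of the measurement stage: for each drawn subject
#' the exact difference trace a noiseless, unfiltered pipeline would
#' produce at Fz is written down in closed form and the package's own
#' [peak_latency()] / [mean_amplitude()] are applied to it. Equivalence
#' with the full epoch-level pipeline is verified in the test suite; this
#' path is used for replicate-level recovery and power studies where
#' thousands of full syntheses would be wasteful.
#'
#' @param study A [study_config()].
#' @return Measures tibble: `subject_id`, `gender`, `condition`,
#'   `peak_latency_ms`, `mean_amplitude_uv`.
#' @export
simulate_measures <- function(study) {
  profiles <- draw_subject_profiles(study)
  out <- purrr::pmap(profiles, function(subject_id, gender, condition,
                                        mmn_latency_ms, mmn_amplitude_uv) {
    tr <- analytic_diff_trace(mmn_latency_ms, mmn_amplitude_uv, study)
    dw <- trace_as_dw(tr$trace, tr$n_pre, tr$fs, subject_id, gender, condition)
    m <- measure_mmn(dw)
    m[, c("subject_id", "gender", "condition", "peak_latency_ms",
          "mean_amplitude_uv")]
  })
  dplyr::bind_rows(out)
}
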