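# Shared fixture builders. Everything is generated in code; no data files.

# A quick noiseless subject at given per-condition parameters.
fix_profile <- function(lat_simple = 160, lat_pattern = 150,
                        amp_simple = 1.5, amp_pattern = 1.0,
                        noise = 0, artifacts = 0,
                        gender = "female", id = "s1") {
  subject_profile(id, gender,
                  mmn_latency_ms = c(simple = lat_simple, pattern = lat_pattern),
                  mmn_amplitude_uv = c(simple = amp_simple, pattern = amp_pattern),
                  noise_sd_uv = noise, artifact_trial_fraction = artifacts)
}

# Small epoch set filled with a constant or supplied array.
fix_epochs <- function(n_trials = 4, value = 0, fs = 512,
                       montage = montage_1020_32(),
                       code = rep("standard", n_trials)) {
  n_pre <- round(0.1 * fs)
  n_tot <- round(0.5 * fs)
  data <- array(value, c(n_trials, nrow(montage), n_tot))
  epoch_set(data, fs, n_pre, montage, code = code,
            subject_id = "fx", gender = "female")
}

# Nearest epoch-grid latency (ms) to a target, within the search window.
fix_grid_latency <- function(lat, fs = 512, window = c(100, 250)) {
  n_pre <- round(0.1 * fs)
  t_ms <- ((seq_len(round(0.5 * fs)) - 1) - n_pre) / fs * 1000
  t_in <- t_ms[t_ms >= window[1] - 1e-9 & t_ms <= window[2] + 1e-9]
  t_in[which.min(abs(t_in - lat))]
}

# Random long-format topomap table for two groups.
fix_maps <- function(n_a = 5, n_b = 5, n_el = 30, seed = 1,
                     shift_b = 0, flip_b = FALSE) {
  set.seed(seed)
  ids <- c(sprintf("a%02d", seq_len(n_a)), sprintf("b%02d", seq_len(n_b)))
  grp <- rep(c("A", "B"), c(n_a, n_b))
  base <- rnorm(n_el)
  rows <- lapply(seq_along(ids), function(i) {
    v <- base + rnorm(n_el)
    if (grp[i] == "B") {
      if (flip_b) v <- -base + rnorm(n_el)
      v <- v + shift_b
    }
    tibble::tibble(subject_id = ids[i], group = grp[i],
                   electrode = paste0("e", seq_len(n_el)), value = v)
  })
  dplyr::bind_rows(rows)
}

# Long-format 2x2 measures table with configurable cell means.
fix_measures <- function(n_f = 4, n_m = 4, means = c(0, 0, 0, 0), sd = 1,
                         seed = 1) {
  set.seed(seed)
  grid <- tidyr::expand_grid(
    subject_id = sprintf("s%02d", seq_len(n_f + n_m)),
    condition = c("simple", "pattern"))
  grid$gender <- ifelse(as.integer(sub("s", "", grid$subject_id)) <= n_f,
                        "female", "male")
  mu <- ifelse(grid$gender == "female",
               ifelse(grid$condition == "simple", means[1], means[2]),
               ifelse(grid$condition == "simple", means[3], means[4]))
  grid$value <- mu + rnorm(nrow(grid), sd = sd)
  grid
}
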