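#' Oddball sequence configuration
#'
#' Describes one oddball block: the simple (frequency) condition presents a
#' stream of single tones of which a rare fraction are deviants of a higher
#' pitch; the pattern condition presents a stream of contiguous three-tone
#' triplets, rising in pitch for standards (1131, 1198, 1269 Hz) and falling
#' for deviants (1269, 1198, 1131 Hz).
#'
#' @param condition `"simple"` or `"pattern"`.
#' @param n_deviants Number of deviant units (tones in the simple condition,
#'   whole triplets in the pattern condition). Default 200.
#' @param p_deviant Deviant probability per unit. Default 0.16.
#' @param soa_ms Stimulus-onset asynchrony between consecutive tones in ms.
#'   Default 180.
#' @param tone_duration_ms Tone-burst duration in ms. Default 50.
#' @param sampling_rate_hz Sampling rate used to express onsets in samples.
#' @param first_unit_standard If `TRUE` (default) the stream never opens with
#'   a deviant, so the regularity is established before its first violation.
#' @param seed Integer seed controlling deviant placement.
#' @return An object of class `sequence_config`.
#' @export
sequence_config <- function(condition = c("simple", "pattern"),
                            n_deviants = 200,
                            p_deviant = 0.16,
                            soa_ms = 180,
                            tone_duration_ms = 50,
                            sampling_rate_hz = 512,
                            first_unit_standard = TRUE,
                            seed = 1L) {
  condition <- match.arg(condition)
  if (!is_count(n_deviants)) abort("`n_deviants` must be a positive integer.")
  assert_scalar_number(p_deviant, "p_deviant")
  if (p_deviant <= 0 || p_deviant >= 1) {
    abort("`p_deviant` must lie strictly between 0 and 1.")
  }
  assert_scalar_number(soa_ms, "soa_ms", lower = 1e-9)
  assert_scalar_number(tone_duration_ms, "tone_duration_ms", lower = 0)
  if (soa_ms <= tone_duration_ms) {
    abort("`soa_ms` must exceed `tone_duration_ms`.")
  }
  assert_scalar_number(sampling_rate_hz, "sampling_rate_hz", lower = 1e-9)
  structure(
    list(condition = condition, n_deviants = as.integer(n_deviants),
         p_deviant = p_deviant, soa_ms = soa_ms,
         tone_duration_ms = tone_duration_ms,
         sampling_rate_hz = sampling_rate_hz,
         first_unit_standard = isTRUE(first_unit_standard),
         seed = as.integer(seed)),
    class = "sequence_config"
  )
}

# Tone frequencies (Hz) of the two conditions.
simple_freqs <- c(standard = 1131, deviant = 1269)
pattern_standard_freqs <- c(1131, 1198, 1269)   # rising
pattern_deviant_freqs <- c(1269, 1198, 1131)    # falling

# Uniform draw of k deviant positions among n units with no two adjacent,
# optionally excluding position 1. Classical bijection: choosing k
# non-adjacent positions out of n is equivalent to choosing k unrestricted
# positions out of n - k + 1 and spreading them.
draw_deviant_positions <- function(n_units, k, exclude_first = TRUE) {
  offset <- if (exclude_first) 1L else 0L
  n_eff <- n_units - offset
  m <- n_eff - k + 1L
  if (m < k) {
    abort(sprintf(
      "Cannot place %d non-adjacent deviant units among %d available positions.",
      k, n_eff))
  }
  q <- sort(sample.int(m, k))
  q + seq_len(k) - 1L + offset
}

#' Generate an oddball stimulus sequence
#'
#' Builds the event table for one block: `round(n_deviants / p_deviant)`
#' units, of which exactly `n_deviants` are deviants placed uniformly at
#' random subject to the constraint that no two deviant units are adjacent.
#' In the pattern condition each unit is a contiguous three-tone triplet and
#' every tone of the stream appears as one event row.
#'
#' @param cfg A [sequence_config()].
#' @return A tibble with columns `onset_sample` (0-based, strictly
#'   increasing), `code` (`"standard"`/`"deviant"`), `triplet_pos` (1-3 in
#'   the pattern condition, `NA` otherwise) and `frequency_hz`. Attributes:
#'   `n_units`, `realized_p_deviant`, `condition`, `sampling_rate_hz`,
#'   `soa_ms`, `seed`.
#' @examples
#' ev <- generate_stimulus_sequence(sequence_config("simple", seed = 1))
#' sum(ev$code == "deviant")  # 200
#' nrow(ev)                   # 1250
#' @export
generate_stimulus_sequence <- function(cfg) {
  stopifnot(inherits(cfg, "sequence_config"))
  if (cfg$condition == "simple" && cfg$p_deviant >= 0.5) {
    abort("`p_deviant` >= 0.5 violates oddball rarity in the simple condition.")
  }
  n_units <- as.integer(round(cfg$n_deviants / cfg$p_deviant))
  realized_p <- cfg$n_deviants / n_units

  dev_pos <- with_seed(cfg$seed,
    draw_deviant_positions(n_units, cfg$n_deviants,
                           exclude_first = cfg$first_unit_standard))
  unit_code <- rep("standard", n_units)
  unit_code[dev_pos] <- "deviant"

  fs <- cfg$sampling_rate_hz
  # Constant integer-sample spacing keeps the stream strictly isochronous
  # on the sampling grid (the realized SOA is recorded below).
  soa_samples <- round(cfg$soa_ms * fs / 1000)
  if (cfg$condition == "simple") {
    tone_idx <- seq_len(n_units) - 1L
    tab <- tibble::tibble(
      onset_sample = as.integer(tone_idx * soa_samples),
      code = unit_code,
      triplet_pos = NA_integer_,
      frequency_hz = unname(simple_freqs[unit_code])
    )
  } else {
    n_tones <- 3L * n_units
    tone_idx <- seq_len(n_tones) - 1L
    code <- rep(unit_code, each = 3L)
    pos <- rep(1:3, times = n_units)
    freq <- ifelse(code == "deviant",
                   pattern_deviant_freqs[pos],
                   pattern_standard_freqs[pos])
    tab <- tibble::tibble(
      onset_sample = as.integer(tone_idx * soa_samples),
      code = code,
      triplet_pos = pos,
      frequency_hz = freq
    )
  }
  attr(tab, "n_units") <- n_units
  attr(tab, "realized_p_deviant") <- realized_p
  attr(tab, "condition") <- cfg$condition
  attr(tab, "sampling_rate_hz") <- fs
  attr(tab, "soa_ms") <- cfg$soa_ms
  attr(tab, "realized_soa_ms") <- soa_samples / fs * 1000
  attr(tab, "tone_duration_ms") <- cfg$tone_duration_ms
  attr(tab, "seed") <- cfg$seed
  tab
}

# Number of deviant UNITS in an event table (a pattern triplet counts once).
count_deviant_units <- function(events) {
  sum(events$code == "deviant" &
        (is.na(events$triplet_pos) | events$triplet_pos == 1L))
}

#' Read / write an event table
#'
#' Events are stored as TSV with columns `onset_sample`, `code`,
#' `triplet_pos`, `frequency_hz`.
#'
#' @param path File path.
#' @param events An event table from [generate_stimulus_sequence()].
#' @export
read_events <- function(path) {
  readr::read_tsv(path, col_types = readr::cols(
    onset_sample = readr::col_integer(),
    code = readr::col_character(),
    triplet_pos = readr::col_integer(),
    frequency_hz = readr::col_double()
  ))
}

#' @rdname read_events
#' @export
write_events <- function(events, path) {
  readr::write_tsv(events, path)
  invisible(path)
}
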