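fs <- 512

# Difference wave carrying an arbitrary Fz trace, all other channels zero.
dw_with_trace <- function(trace, kind = "simple") {
  mont <- montage_1020_32()
  n <- length(trace)
  std <- array(0, c(2, nrow(mont), n))
  ep <- epoch_set(abind_trials(std, trace, mont), fs, round(0.1 * fs), mont,
                  condition = kind,
                  code = c("standard", "deviant"),
                  triplet_pos = if (kind == "pattern") c(1L, 1L) else
                    rep(NA_integer_, 2),
                  subject_id = "fx", gender = "female")
  derive_mmn(ep)
}

abind_trials <- function(arr, trace, mont) {
  arr[2, match("Fz", mont$name), ] <- trace
  arr
}

test_that("averaging uses retained trials only and respects labels", {
  ep <- fix_epochs(n_trials = 4, code = c("standard", "standard",
                                          "deviant", "deviant"))
  ep$data[1, , ] <- 1; ep$data[2, , ] <- 5
  ep$data[3, , ] <- -2; ep$data[4, , ] <- 10
  ep$rejected <- c(FALSE, TRUE, FALSE, FALSE)
  expect_equal(unique(as.vector(average_evoked(ep, "standard")$data)), 1)
  expect_equal(unique(as.vector(average_evoked(ep, "deviant")$data)), 4)
  ep$rejected <- rep(TRUE, 4)
  expect_error(average_evoked(ep, "standard"), "No retained")
})

test_that("averaging error shrinks as 1/sqrt(n)", {
  set.seed(10)
  mont <- montage_1020_32()
  n_samp <- 64
  template <- sin(seq(0, 2 * pi, length.out = n_samp))
  make_avg <- function(n) {
    data <- array(rep(template, each = n * nrow(mont)),
                  c(n, nrow(mont), n_samp)) +
      array(rnorm(n * nrow(mont) * n_samp, sd = 4), c(n, nrow(mont), n_samp))
    ep <- epoch_set(data, fs, 10, mont, code = rep("standard", n))
    sqrt(mean((average_evoked(ep, "standard")$data[4, ] - template)^2))
  }
  r50 <- mean(replicate(12, make_avg(50)))
  r200 <- mean(replicate(12, make_avg(200)))
  expect_equal(r50 / r200, 2, tolerance = 0.35)
})

test_that("difference waves subtract exactly and compose back", {
  ep <- fix_epochs(n_trials = 2, code = c("standard", "deviant"))
  set.seed(11)
  ep$data <- array(rnorm(length(ep$data)), dim(ep$data))
  dw <- derive_mmn(ep)
  expect_identical(dw$diff, dw$deviant$data - dw$standard$data)
  expect_equal(dw$diff + dw$standard$data, dw$deviant$data, tolerance = 1e-12)
  # deviant == standard -> all-zero difference
  ep$data[2, , ] <- ep$data[1, , ]
  expect_true(all(derive_mmn(ep)$diff == 0))
})

test_that("pattern MMN demands triplet-first provenance", {
  ep <- fix_epochs(n_trials = 2, code = c("standard", "deviant"))
  ep$condition <- "pattern"
  ep$triplet_pos <- c(2L, 1L)
  expect_error(derive_mmn(ep), "triplet-first")
  ep$triplet_pos <- c(1L, 1L)
  expect_s3_class(derive_mmn(ep), "difference_wave")
})

test_that("peak latency finds the most negative sample, earliest on ties", {
  t_ms <- ((seq_len(256) - 1) - 51) / fs * 1000
  g <- function(mu) -exp(-((t_ms - mu)^2) / (2 * 25.48^2))
  dw <- dw_with_trace(g(150))
  expect_equal(as.numeric(peak_latency(dw)), fix_grid_latency(150))

  # two equal minima: the earlier wins
  two <- g(120) + g(200)
  tr <- two
  # force exact equality at the two minima samples
  i1 <- which.min(abs(t_ms - 120)); i2 <- which.min(abs(t_ms - 200))
  tr[i1] <- -5; tr[i2] <- -5
  dw2 <- dw_with_trace(tr)
  expect_equal(as.numeric(peak_latency(dw2)), t_ms[i1])

  # flat trace: window start plus a flag
  dwf <- dw_with_trace(rep(0, 256))
  lat <- peak_latency(dwf)
  expect_true(attr(lat, "no_unique_peak"))
  expect_equal(as.numeric(lat), t_ms[t_ms >= 100][1])

  # invariant to positive rescaling
  dw3 <- dw_with_trace(3.7 * g(171))
  expect_equal(as.numeric(peak_latency(dw3)), as.numeric(peak_latency(dw_with_trace(g(171)))))

  expect_error(peak_latency(dw, electrode = "XX"), "not in montage")
})

test_that("mean amplitude matches the Gaussian window oracle", {
  t_ms <- ((seq_len(256) - 1) - 51) / fs * 1000
  sigma <- 60 / (2 * sqrt(2 * log(2)))
  # constant -2 segment -> 2.0 in the negativity-positive convention
  dw <- dw_with_trace(rep(-2, 256))
  expect_equal(as.numeric(mean_amplitude(dw, "Fz", 150)), 2)

  tr <- -exp(-((t_ms - 160)^2) / (2 * sigma^2))
  dw2 <- dw_with_trace(tr)
  lat <- as.numeric(peak_latency(dw2))
  amp <- mean_amplitude(dw2, "Fz", lat)
  # closed-form continuous oracle: (1/50) * integral over [lat-25, lat+25];
  # tolerance covers the 512-Hz sampling discretization of the window mean
  oracle <- sigma * sqrt(2 * pi) / 50 *
    (pnorm((lat + 25 - 160) / sigma) - pnorm((lat - 25 - 160) / sigma))
  expect_equal(as.numeric(amp), oracle, tolerance = 0.01)
  # unimodal window: mean magnitude below peak magnitude
  expect_lt(as.numeric(amp), max(abs(tr)))
  expect_equal(attr(amp, "signed"), -as.numeric(amp))

  # window clamped at the epoch edge is flagged
  ampc <- mean_amplitude(dw2, "Fz", peak_latency_ms = 390)
  expect_true(attr(ampc, "clamped"))
})

test_that("measure_mmn bundles latency and amplitude with flags", {
  prof <- fix_profile(lat_simple = 142.58, amp_simple = 1.48)
  ev <- generate_stimulus_sequence(sequence_config("simple", n_deviants = 6,
                                                   seed = 15))
  ep <- baseline_correct(generate_subject_epochs(prof, ev, seed = 16))
  m <- measure_mmn(derive_mmn(ep))
  expect_equal(m$peak_latency_ms, fix_grid_latency(142.58))
  expect_equal(m$mean_amplitude_uv, 1.48, tolerance = 1e-9)
  expect_false(m$clamped)
  expect_false(m$no_unique_peak)
  expect_equal(m$window_end_ms - m$window_start_ms, 50)
})
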