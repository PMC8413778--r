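fs <- 512

test_that("band-pass has the right gain profile", {
  t <- seq(0, 8, by = 1 / fs)
  mid <- 1537:2560  # interior segment, clear of filter transients
  s10 <- sin(2 * pi * 10 * t)
  s100 <- sin(2 * pi * 100 * t)
  g10 <- sd(bandpass_filter(s10, sampling_rate_hz = fs)[mid]) / sd(s10[mid])
  g100 <- sd(bandpass_filter(s100, sampling_rate_hz = fs)[mid]) / sd(s100[mid])
  expect_gte(g10, 0.95); expect_lte(g10, 1.05)
  expect_lt(g100, 0.1)
  dc <- bandpass_filter(rep(1, length(t)), sampling_rate_hz = fs)
  expect_lt(max(abs(dc[mid])), 0.01)
  expect_equal(length(dc), length(t))
})

test_that("filtering is linear and rejects bad band edges", {
  set.seed(1)
  x <- rnorm(2048); y <- rnorm(2048)
  lhs <- bandpass_filter(2 * x + 3 * y, sampling_rate_hz = fs)
  rhs <- 2 * bandpass_filter(x, sampling_rate_hz = fs) +
    3 * bandpass_filter(y, sampling_rate_hz = fs)
  # the 1-Hz pole pair sits close to the unit circle, so the recursive
  # filter amplifies rounding differences between the two evaluation
  # orders, worst at the boundary transients
  expect_lt(max(abs(lhs - rhs)), 1e-5)
  expect_error(bandpass_filter(x, low = 1, high = 300, sampling_rate_hz = fs),
               "inside")
})

test_that("re-referencing subtracts the mastoid mean and is idempotent", {
  ep <- fix_epochs(n_trials = 3)
  set.seed(2)
  ep$data <- array(rnorm(length(ep$data)), dim(ep$data))
  i <- match(c("A1", "A2"), ep$montage$name)

  # zero mastoids: no change
  ep0 <- ep
  ep0$data[, i, ] <- 0
  expect_equal(rereference(ep0)$data, ep0$data, tolerance = 1e-12)

  r1 <- rereference(ep)
  r2 <- rereference(r1)
  expect_equal(r1$data, r2$data, tolerance = 1e-12)
  expect_equal(r1$reference, "linked_mastoids")

  # pairwise channel differences preserved exactly
  d_before <- ep$data[1, 4, ] - ep$data[1, 9, ]
  d_after <- r1$data[1, 4, ] - r1$data[1, 9, ]
  expect_equal(d_before, d_after, tolerance = 1e-12)

  # average reference: spatial mean per sample is ~0
  ra <- rereference(ep, "average")
  sm <- apply(ra$data, c(1, 3), mean)
  expect_lt(max(abs(sm)), 1e-10)
})

test_that("epoching yields 256 samples with 51 pre-stimulus at 512 Hz", {
  mont <- montage_1020_32()
  rec <- eeg_recording(matrix(0, nrow(mont), 4000), fs, mont)
  events <- tibble::tibble(onset_sample = c(100L, 1000L, 2000L),
                           code = c("standard", "deviant", "standard"),
                           triplet_pos = NA_integer_,
                           frequency_hz = 1131)
  ep <- epoch_recording(rec, events)
  expect_equal(dim(ep$data), c(3L, 32L, 256L))
  expect_equal(ep$n_pre, 51L)

  # event too close to the start is dropped with a warning, not an error
  events2 <- tibble::tibble(onset_sample = c(10L, 1000L),
                            code = c("standard", "standard"),
                            triplet_pos = NA_integer_, frequency_hz = 1131)
  expect_warning(ep2 <- epoch_recording(rec, events2), "edge")
  expect_equal(dim(ep2$data)[1], 1L)

  # empty selection: empty epoch set, averaging then errors
  ep3 <- epoch_recording(rec, events[0, ])
  expect_equal(dim(ep3$data)[1], 0L)
  expect_error(average_evoked(ep3), "No retained")
})

test_that("pattern epoching keeps only triplet-first events", {
  mont <- montage_1020_32()
  rec <- eeg_recording(matrix(0, nrow(mont), 5000), fs, mont,
                       condition = "pattern")
  ev <- generate_stimulus_sequence(sequence_config("pattern", n_deviants = 3,
                                                   p_deviant = 0.3, seed = 2))
  ev$onset_sample <- ev$onset_sample + 200L
  ep <- epoch_recording(rec, ev)
  expect_equal(dim(ep$data)[1], sum(ev$triplet_pos == 1))
  expect_true(all(ep$triplet_pos == 1))
})

test_that("baseline correction zeroes the pre-stimulus mean", {
  ep <- fix_epochs(n_trials = 5)
  set.seed(3)
  ep$data <- array(rnorm(length(ep$data), mean = 7), dim(ep$data))
  bc <- baseline_correct(ep)
  base_means <- rowMeans(bc$data[, , 1:bc$n_pre, drop = FALSE], dims = 2)
  expect_lt(max(abs(base_means)), 1e-10)

  # constant offset removed exactly
  ep2 <- fix_epochs(n_trials = 1, value = 3.2)
  expect_equal(max(abs(baseline_correct(ep2)$data)), 0, tolerance = 1e-12)

  ep3 <- fix_epochs(n_trials = 1)
  ep3$n_pre <- 0L
  expect_error(baseline_correct(ep3), "pre-stimulus")
})

test_that("artifact rejection uses a strict threshold on scalp channels", {
  ep <- fix_epochs(n_trials = 3)
  fc1 <- match("FC1", ep$montage$name)
  a1 <- match("A1", ep$montage$name)
  ep$data[1, fc1, 100] <- 71
  ep$data[2, fc1, 100] <- 70       # exactly at threshold: retained
  ep$data[3, a1, 100] <- 500       # mastoid: excluded from the criterion
  r <- reject_artifacts(ep, quiet = TRUE)
  expect_equal(r$rejected, c(TRUE, FALSE, FALSE))
  expect_error(reject_artifacts(ep, threshold_uv = 0), "> 0")
})

test_that("rejection count is monotone in the threshold", {
  ep <- fix_epochs(n_trials = 40)
  set.seed(4)
  ep$data <- array(rnorm(length(ep$data), sd = 30), dim(ep$data))
  kept <- vapply(c(100, 70, 50, 30),
                 function(th) sum(!reject_artifacts(ep, th, quiet = TRUE)$rejected),
                 numeric(1))
  expect_true(all(diff(kept) <= 0))
})

test_that("exactly k injected excursion trials are rejected at low noise", {
  prof <- fix_profile(noise = 2, artifacts = 0.15)
  ev <- generate_stimulus_sequence(sequence_config("simple", n_deviants = 10,
                                                   seed = 5))
  rec <- generate_subject_recording(prof, ev, seed = 6)
  k <- nrow(rec$artifact_plan)
  ep <- preprocess_recording(rec, ev, preprocess_config(), quiet = TRUE)
  expect_equal(sum(ep$rejected), k)
  expect_equal(which(ep$rejected), rec$artifact_plan$event_row)
})

test_that("the chain order is recorded in provenance", {
  prof <- fix_profile(noise = 1)
  ev <- generate_stimulus_sequence(sequence_config("simple", n_deviants = 3,
                                                   seed = 7))
  rec <- generate_subject_recording(prof, ev, seed = 8)
  ep <- preprocess_recording(rec, ev, preprocess_config(), quiet = TRUE)
  steps <- grep("bandpass|rereference|^epoch$|baseline|reject", ep$provenance)
  expect_equal(ep$provenance[steps[1:4]],
               c("bandpass[1-30 Hz]", "rereference[linked_mastoids]",
                 "epoch", "baseline"))
  expect_match(ep$provenance[length(ep$provenance)], "reject")
})
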