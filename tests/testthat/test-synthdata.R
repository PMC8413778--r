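test_that("noiseless forcing: difference wave is the injected kernel", {
  prof <- fix_profile(lat_simple = 150, amp_simple = 1)
  ev <- generate_stimulus_sequence(sequence_config("simple", n_deviants = 10,
                                                   seed = 3))
  ep <- generate_subject_epochs(prof, ev, amplitude_mode = "peak", seed = 4)
  ep <- baseline_correct(ep)
  dw <- derive_mmn(ep)
  tr <- dw$diff[match("Fz", dw$montage$name), ]
  t_ms <- ((seq_along(tr) - 1) - ep$n_pre) / 512 * 1000
  expect_equal(min(tr), -1, tolerance = 1e-12)
  expect_equal(t_ms[which.min(tr)], fix_grid_latency(150), tolerance = 1e-9)
})

test_that("window-mean mode recovers the configured amplitude exactly", {
  prof <- fix_profile(lat_simple = 173.55, amp_simple = 1.89,
                      lat_pattern = 150.11, amp_pattern = 1.03)
  prep <- preprocess_config(bandpass = FALSE)
  for (cn in c("simple", "pattern")) {
    ev <- generate_stimulus_sequence(sequence_config(cn, n_deviants = 8,
                                                     seed = 5))
    rec <- generate_subject_recording(prof, ev, seed = 6)
    m <- measure_mmn(derive_mmn(preprocess_recording(rec, ev, prep,
                                                     quiet = TRUE)))
    expect_equal(m$peak_latency_ms,
                 fix_grid_latency(prof$mmn_latency_ms[cn]), tolerance = 1e-9)
    expect_equal(m$mean_amplitude_uv,
                 unname(prof$mmn_amplitude_uv[cn]), tolerance = 1e-9)
  }
})

test_that("injected artifact trials survive filtering and are countable", {
  prof <- fix_profile(noise = 2, artifacts = 0.1)
  ev <- generate_stimulus_sequence(sequence_config("simple", n_deviants = 16,
                                                   seed = 9))
  rec <- generate_subject_recording(prof, ev, seed = 10)
  k <- nrow(rec$artifact_plan)
  expect_equal(k, round(0.1 * nrow(ev)))
  ep <- preprocess_recording(rec, ev, preprocess_config(), quiet = TRUE)
  expect_gte(sum(ep$rejected), k)
})

test_that("epoch generation is deterministic and byte-identical on disk", {
  prof <- fix_profile(noise = 3)
  ev <- generate_stimulus_sequence(sequence_config("simple", n_deviants = 4,
                                                   seed = 11))
  e1 <- generate_subject_epochs(prof, ev, seed = 12)
  e2 <- generate_subject_epochs(prof, ev, seed = 12)
  expect_identical(e1$data, e2$data)

  d <- withr::local_tempdir()
  write_epochs(e1, file.path(d, "a"))
  write_epochs(e2, file.path(d, "b"))
  expect_identical(readLines(file.path(d, "a_data.tsv")),
                   readLines(file.path(d, "b_data.tsv")))
})

test_that("montage and condition mismatches are rejected", {
  prof <- fix_profile()
  ev <- generate_stimulus_sequence(sequence_config("simple", n_deviants = 3,
                                                   seed = 13))
  bad <- montage_1020_32()[1:10, ]  # drops A1/A2 and class attrs survive
  expect_error(generate_subject_recording(prof, ev, montage = bad), "A1")
  prof_np <- subject_profile("x", "male", c(simple = 150), c(simple = 1),
                             noise_sd_uv = 0)
  evp <- generate_stimulus_sequence(sequence_config("pattern", n_deviants = 3,
                                                    seed = 14))
  expect_error(generate_subject_recording(prof_np, evp), "pattern")
})

test_that("study draws respect configured cell moments and group sizes", {
  cfg <- reference_study_config(seed = 21)
  prof <- draw_subject_profiles(cfg)
  expect_equal(length(unique(prof$subject_id)), 29)
  expect_equal(sum(prof$gender == "female" & prof$condition == "simple"), 14)
  expect_true(all(prof$mmn_latency_ms >= 100 & prof$mmn_latency_ms <= 250))
  expect_true(all(prof$mmn_amplitude_uv > 0))

  # moment recovery over many draws (one cell, many seeds)
  draws <- unlist(lapply(1:150, function(s) {
    p <- draw_subject_profiles(reference_study_config(seed = 3000 + s))
    p$mmn_latency_ms[p$gender == "male" & p$condition == "simple"]
  }))
  expect_equal(mean(draws), 142.58, tolerance = 0.02)
  expect_equal(sd(draws), 6.76 * sqrt(15), tolerance = 0.05)
})

test_that("simulate_measures equals the noiseless epoch-level pipeline", {
  cfg <- reference_study_config(n_female = 2, n_male = 2, n_deviants = 6,
                                noise_sd_uv = 0, seed = 31)
  sm <- simulate_measures(cfg)
  ds <- generate_study(cfg)
  for (sid in names(ds$subjects)) {
    for (cn in c("simple", "pattern")) {
      ep <- reject_artifacts(baseline_correct(ds$subjects[[sid]][[cn]]),
                             quiet = TRUE)
      m <- measure_mmn(derive_mmn(ep))
      row <- sm[sm$subject_id == sid & sm$condition == cn, ]
      expect_equal(m$peak_latency_ms, row$peak_latency_ms, tolerance = 1e-9)
      expect_equal(m$mean_amplitude_uv, row$mean_amplitude_uv,
                   tolerance = 1e-9)
    }
  }
})

test_that("a single-gender study generates but group statistics refuse", {
  cfg <- reference_study_config(n_female = 0, n_male = 4, n_deviants = 4,
                                noise_sd_uv = 0, seed = 41)
  prof <- draw_subject_profiles(cfg)
  expect_equal(unique(prof$gender), "male")
  expect_error(run_study(cfg), "single group")
})
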