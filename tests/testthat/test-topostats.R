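test_that("GFP is the spatial SD of the average-referenced map", {
  expect_equal(gfp(c(1, -1)), 1)
  set.seed(1)
  v <- rnorm(32)
  oracle <- sqrt(mean((v - mean(v))^2))
  expect_equal(gfp(v), oracle, tolerance = 1e-12)
  expect_equal(gfp(3 * v), 3 * gfp(v), tolerance = 1e-12)  # homogeneity
  expect_equal(gfp(rep(2, 30)), 0)
  expect_error(gfp(5), "at least 2")
})

test_that("DISS hits its analytic bounds and the correlation identity", {
  set.seed(2)
  u <- rnorm(30); names(u) <- paste0("e", 1:30)
  expect_equal(diss(u, u), 0, tolerance = 1e-12)
  expect_equal(diss(u, -u), 2, tolerance = 1e-12)

  # orthogonal (after average reference) maps give sqrt(2)
  a <- c(1, -1, 0, 0); b <- c(0, 0, 1, -1)
  expect_equal(diss(a, b), sqrt(2), tolerance = 1e-12)

  # invariances: symmetry, positive rescaling, common offsets
  v <- rnorm(30); names(v) <- names(u)
  expect_equal(diss(u, v), diss(v, u), tolerance = 1e-12)
  expect_equal(diss(2.5 * u, v + 7), diss(u, v), tolerance = 1e-12)

  expect_error(diss(rep(1, 30), v), "uniform")
  expect_error(diss(u[1:10], v), "electrode set")
})

test_that("subject maps peak fronto-centrally for a synthetic MMN", {
  prof <- fix_profile(lat_simple = 160, amp_simple = 2)
  ev <- generate_stimulus_sequence(sequence_config("simple", n_deviants = 6,
                                                   seed = 3))
  ep <- baseline_correct(generate_subject_epochs(prof, ev, seed = 4))
  dw <- derive_mmn(ep)
  m <- measure_mmn(dw)
  map <- subject_topomap(dw, m)
  expect_equal(nrow(map), 30)          # mastoids excluded
  expect_false(any(c("A1", "A2") %in% map$electrode))
  expect_equal(map$electrode[which.max(abs(map$value))], "Fz")

  # constant-in-time difference: window and peak-sample modes agree
  ep2 <- fix_epochs(n_trials = 2, code = c("standard", "deviant"))
  ep2$data[2, , ] <- 1.5
  dw2 <- derive_mmn(ep2)
  m2 <- measure_mmn(dw2)
  expect_equal(subject_topomap(dw2, m2, "window")$value,
               subject_topomap(dw2, m2, "peak")$value, tolerance = 1e-12)
})

test_that("permutation test is exact on identical groups and reproducible", {
  maps <- fix_maps(n_a = 5, n_b = 5, seed = 5)
  # make B an exact copy of A's subject maps
  mb <- maps[maps$group == "A", ]
  mb$subject_id <- sub("a", "b", mb$subject_id)
  mb$group <- "B"
  ident <- dplyr::bind_rows(maps[maps$group == "A", ], mb)
  r <- diss_permutation_test(ident, n_perm = 300, seed = 6)
  expect_equal(r$diss_observed, 0, tolerance = 1e-12)
  expect_equal(r$p_value, 1)

  r1 <- diss_permutation_test(maps, n_perm = 300, seed = 7)
  r2 <- diss_permutation_test(maps, n_perm = 300, seed = 7)
  expect_identical(r1$null_distribution, r2$null_distribution)
  expect_equal(length(r1$null_distribution), 300)

  expect_error(diss_permutation_test(fix_maps(n_a = 1, n_b = 5)), "at least 2")
  expect_warning(diss_permutation_test(maps, n_perm = 50, seed = 8), "100")
})

test_that("opposite-polarity group maps are detected with high power", {
  maps <- fix_maps(n_a = 8, n_b = 8, seed = 9, flip_b = TRUE)
  r <- diss_permutation_test(maps, n_perm = 1000, seed = 10)
  expect_gt(r$diss_observed, 1.5)
  expect_lt(r$p_value, 0.01)
})

test_that("DISS stays within [0, 2] over random maps", {
  set.seed(11)
  for (i in 1:200) {
    u <- rnorm(30); v <- rnorm(30)
    d <- diss(u, v)
    expect_gte(d, 0); expect_lte(d, 2)
  }
})

test_that("tidy and autoplot summarize a permutation result", {
  r <- diss_permutation_test(fix_maps(seed = 12), n_perm = 200, seed = 13)
  td <- tidy(r)
  expect_named(td, c("statistic", "p.value", "n_permutations", "null_mean",
                     "null_q95"))
  p <- autoplot(r)
  expect_s3_class(p, "ggplot")
})
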