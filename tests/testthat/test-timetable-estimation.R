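bank <- make_template_bank()

test_that("timetables are sorted by peak time and reject degenerate genes", {
  sim <- generate_timecourse(synthetic_config(n_rhythmic = 40,
                                              n_arrhythmic = 5,
                                              n_stresslike = 0, seed = 13))
  res <- analyze_matrix(sim$matrix, sim$schedule, bank)
  ids <- res$gene_id[res$valid]
  tt <- build_timetable(sim$matrix, res, ids)
  expect_s3_class(tt, "molecular_timetable")
  expect_false(is.unsorted(tt$peak_time_h))
  expect_true(all(tt$sd > 0))
  expect_setequal(tt$gene_id, ids)

  invalid <- res$gene_id[!res$valid][1]
  expect_error(build_timetable(sim$matrix, res, c(ids[1], invalid)), invalid)

  path <- withr::local_tempfile(fileext = ".tsv")
  write_timetable(tt, path)
  expect_equal(read_timetable(path)$peak_time_h, tt$peak_time_h)
})

test_that("normalization z-scores each timetable gene", {
  sim <- generate_timecourse(synthetic_config(n_rhythmic = 30,
                                              n_arrhythmic = 0,
                                              n_stresslike = 0, seed = 14))
  res <- analyze_matrix(sim$matrix, sim$schedule, bank)
  tt <- build_timetable(sim$matrix, res, res$gene_id)
  z <- normalize_expression(sim$matrix, tt)
  expect_identical(expr_units(z), "normalized")
  expect_identical(rownames(z), tt$gene_id)
  expect_equal(rowMeans(z), setNames(rep(0, 30), rownames(z)),
               tolerance = 1e-12)
  expect_equal(sqrt(rowMeans(z^2)), setNames(rep(1, 30), rownames(z)),
               tolerance = 1e-12)
  # location and positive-scale invariance of the input
  shifted <- expression_matrix(sim$matrix + 100, "rpkm")
  tt2 <- build_timetable(shifted, res, res$gene_id)
  expect_equal(unclass(normalize_expression(shifted, tt2)), unclass(z),
               tolerance = 1e-9, ignore_attr = TRUE)
  scaled <- expression_matrix(sim$matrix * 3, "rpkm")
  tt3 <- build_timetable(scaled, res, res$gene_id)
  expect_equal(unclass(normalize_expression(scaled, tt3)), unclass(z),
               tolerance = 1e-9, ignore_attr = TRUE)
})

test_that("profiles trace a cosine over molecular peak time", {
  sim <- generate_timecourse(synthetic_config(n_rhythmic = 60,
                                              n_arrhythmic = 0,
                                              n_stresslike = 0,
                                              noise_rel = 0, seed = 15))
  res <- analyze_matrix(sim$matrix, sim$schedule, bank)
  tt <- build_timetable(sim$matrix, res, res$gene_id)
  z <- normalize_expression(sim$matrix, tt)
  sid <- sim$schedule$sample_id[5]
  prof <- build_profile(z, tt, sid)
  expect_equal(nrow(prof), nrow(tt))
  # z-scored noiseless cosine traces sqrt(2) * cos(2pi(phi - t)/24), up to
  # the small per-gene re-weighting from the 25th sample repeating a phase
  t5 <- sim$schedule$clock_hour[5]
  ideal <- sqrt(2) * cos(2 * pi * (prof$peak_time_h - t5) / 24)
  expect_lt(max(abs(prof$z - ideal)), 0.1)
  expect_gt(cor(prof$z, ideal), 0.999)
  expect_error(build_profile(z, tt, "nope"), "unknown sample")
})

test_that("internal time is read off a clean profile exactly", {
  set.seed(16)
  phi <- sample(seq(0, 24 - 1 / 60, by = 1 / 60), 143)
  prof <- make_profile(phi, cos(2 * pi * (phi - 9) / 24))
  est <- estimate_internal_time(prof, bank)
  expect_equal(est$internal_time_h, 9)
  expect_equal(est$fit_correlation, 1, tolerance = 1e-12)
  expect_equal(est$measurement_noise_pct, 0, tolerance = 1e-9)
  expect_equal(est$fitted_amplitude, 1, tolerance = 1e-9)
  expect_equal(measurement_noise(prof, est), est$measurement_noise_pct,
               tolerance = 1e-9)

  # shifting every peak phase by +2 h shifts the estimate by +2 h
  prof2 <- make_profile((phi + 2) %% 24, prof$z)
  expect_equal(estimate_internal_time(prof2, bank)$internal_time_h, 11)

  expect_error(estimate_internal_time(make_profile(c(1, 2, 3), rep(0.5, 3))),
               "degenerate")
  expect_error(estimate_internal_time(make_profile(c(1, 1, 1), c(0, 1, 2))),
               "distinct")
})

test_that("estimates rotate with a global rotation of timetable phases", {
  set.seed(17)
  phi <- runif(50, 0, 24)
  z <- cos(2 * pi * (phi - 4) / 24) + rnorm(50, 0, 0.3)
  base <- estimate_internal_time(make_profile(phi, z), bank)
  for (delta in c(3, 10.5, 20)) {
    rot <- estimate_internal_time(make_profile((phi + delta) %% 24, z), bank)
    expect_equal(circ_abs(rot$internal_time_h,
                          (base$internal_time_h + delta) %% 24), 0,
                 tolerance = 1e-9)
    expect_equal(rot$measurement_noise_pct, base$measurement_noise_pct,
                 tolerance = 1e-6)
  }
})

test_that("the profile crest advances with sampling time", {
  sim <- generate_timecourse(synthetic_config(n_rhythmic = 80,
                                              n_arrhythmic = 0,
                                              n_stresslike = 0,
                                              noise_rel = 0, seed = 18))
  res <- analyze_matrix(sim$matrix, sim$schedule, bank)
  tt <- build_timetable(sim$matrix, res, res$gene_id)
  z <- normalize_expression(sim$matrix, tt)
  ests <- estimate_internal_times(z, tt, bank)
  d <- internal_external_difference(ests, sim$schedule)
  # noiseless estimates track the clock to within the small bias induced by
  # the repeated start phase in the 25-sample design
  expect_lt(max(abs(d$diff_h)), 0.25)
  # consecutive samples sit ~2 h apart on the dial
  gaps <- circ_abs(ests$internal_time_h[-1], ests$internal_time_h[-25])
  expect_true(all(abs(gaps - 2) < 0.25))
})

test_that("internal-external differences use the circular convention", {
  sched <- make_schedule()
  ests <- data.frame(sample_id = sched$sample_id,
                     internal_time_h = sched$clock_hour)
  expect_equal(internal_external_difference(ests, sched)$diff_h, rep(0, 25))
  ests$internal_time_h <- (sched$clock_hour + 2) %% 24
  expect_equal(internal_external_difference(ests, sched)$diff_h, rep(2, 25))
  one <- data.frame(sample_id = "X", internal_time_h = 1)
  sch1 <- sample_schedule("X", 0, start_clock = 23)
  expect_equal(internal_external_difference(one, sch1)$diff_h, 2)
})

test_that("measurement noise is non-decreasing in injected noise", {
  set.seed(19)
  phi <- runif(150, 0, 24)
  signal <- cos(2 * pi * (phi - 7) / 24)
  mean_noise <- vapply(c(0.1, 0.3, 0.6, 1.0), function(sd) {
    mean(vapply(1:20, function(i) {
      prof <- make_profile(phi, signal + rnorm(150, 0, sd))
      estimate_internal_time(prof, bank)$measurement_noise_pct
    }, numeric(1)))
  }, numeric(1))
  expect_false(is.unsorted(mean_noise))
})
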