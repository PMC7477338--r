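test_that("point-collapsed ranges pin parameters exactly", {
  ranges <- parameter_ranges(
    drive_gain_e = r_uniform(1, 1),
    drive_width_e = r_uniform(5, 5),
    drive_gain_i = r_uniform(0.6, 0.6),
    drive_width_i = r_uniform(1.5, 1.5),
    sat_constant = r_uniform(20, 20),
    exponent = r_uniform(1.2, 1.2),
    response_scale = r_uniform(15, 15),
    spontaneous_rate = r_uniform(2, 2),
    direction_modulation_depth = r_uniform(0, 0)
  )
  truth <- sample_population(1, ranges = ranges, seed = 1)
  expect_equal(truth$drive_width_e, 5)
  expect_equal(truth$drive_width_i, 1.5)
  expect_equal(truth$sat_constant, 20)
  expect_equal(truth$exponent, 1.2)
  expect_equal(truth$response_scale, 15)
})

test_that("invalid range bounds raise configuration errors", {
  expect_error(r_uniform(5, 1), "invalid uniform range")
  expect_error(r_lognormal(-2, 0.3), "invalid log-normal")
  expect_error(sample_population(3, ranges = list(bad = 1), seed = 1))
  expect_error(sample_population(3, seed = NULL), "seed")
})

test_that("sampling and simulation are seed-deterministic", {
  a <- sample_population(50, seed = 7)
  b <- sample_population(50, seed = 7)
  expect_identical(a, b)
  p <- quick_protocol()
  ta <- simulate_trials(a[1:4, ], p, seed = 3)
  tb <- simulate_trials(b[1:4, ], p, seed = 3)
  expect_identical(ta$spike_times, tb$spike_times)
  tc <- simulate_trials(a[1:4, ], p, seed = 4)
  expect_false(identical(ta$spike_times, tc$spike_times))
})

test_that("population drive optima land in the calibrated band", {
  truth <- sample_population(200, seed = 3)
  # independent dense-grid argmax of each unit's drive
  f <- seq(0.05, 32, by = 0.001)
  fo <- vapply(seq_len(200), function(i) {
    d <- dog_direct(f, truth$drive_gain_e[i], truth$drive_width_e[i],
                    truth$drive_gain_i[i], truth$drive_width_i[i])
    f[which.max(d)]
  }, double(1))
  expect_equal(fo, truth$drive_f_opt, tolerance = 0.02)
  expect_gt(median(fo), 2)
  expect_lt(median(fo), 4)
})

test_that("trial table covers the full block-shuffled protocol", {
  p <- quick_protocol()
  truth <- sample_population(3, p, seed = 2)
  trials <- simulate_trials(truth, p, seed = 2)
  expect_equal(nrow(trials), 3 * 6 * 5 * 2 * 3)
  counts <- dplyr::count(trials, unit_id, tf_hz, contrast_pct, direction_deg)
  expect_true(all(counts$n == p$repeats))
  # within each block every combination appears exactly once
  n_block <- 6 * 5 * 2
  one <- dplyr::filter(trials, unit_id == 1, trial_index <= n_block)
  expect_equal(nrow(dplyr::distinct(one, tf_hz, contrast_pct, direction_deg)),
               n_block)
  # block order is shuffled, not the factorial enumeration order
  expect_false(all(diff(order(one$tf_hz, one$contrast_pct)) == 1))
  expect_true(all(vapply(trials$spike_times, function(s) !is.unsorted(s),
                         logical(1))))
  expect_true(all(vapply(trials$spike_times, function(s) {
    length(s) == 0 || (min(s) >= -p$gap_duration && max(s) < p$stimulus_duration)
  }, logical(1))))
})

test_that("zero response scale leaves only spontaneous spiking", {
  ranges <- parameter_ranges(response_scale = r_uniform(0, 0),
                             spontaneous_rate = r_uniform(3, 3))
  p <- quick_protocol()
  truth <- sample_population(1, p, ranges = ranges, seed = 5)
  trials <- simulate_trials(truth, p, seed = 5)
  resp <- aggregate_conditions(trials, p)
  expect_lt(abs(mean(resp$mean_rate)), 0.5)
})

test_that("weak saturation makes the evoked rate near-linear in contrast", {
  unit <- list(drive_gain_e = 1, drive_width_e = 5, drive_gain_i = 0.6,
               drive_width_i = 1.5, sat_constant = 5000, exponent = 1,
               response_scale = 1000, spontaneous_rate = 0)
  cc <- c(10, 30, 50, 70, 90)
  r <- mean_rate_surface(unit, rep(2, 5), cc)
  # exact closed-form surface, transcribed independently
  d <- dog_direct(2, 1, 5, 0.6, 1.5)
  expect_equal(r, 1000 * cc * d / (5000 + cc * d), tolerance = 1e-12)
  # near-linearity: ratios follow contrast ratios to < 2%
  expect_equal(r / r[1], cc / cc[1], tolerance = 0.02)
})

test_that("long-run empirical mean matches the analytic surface", {
  # one condition simulated with many repeats
  p <- stimulus_protocol(temporal_frequencies = 2, contrasts = 50,
                         directions = 0, repeats = 2000)
  ranges <- parameter_ranges(
    drive_width_e = r_uniform(5, 5), drive_gain_i = r_uniform(0.6, 0.6),
    drive_width_i = r_uniform(1.5, 1.5), sat_constant = r_uniform(25, 25),
    exponent = r_uniform(1.3, 1.3), response_scale = r_uniform(20, 20),
    spontaneous_rate = r_uniform(2, 2)
  )
  truth <- sample_population(1, p, ranges, seed = 9)
  trials <- simulate_trials(truth, p, seed = 9)
  rates <- vapply(trials$spike_times, evoked_rate, double(1),
                  stimulus_duration = 2)
  analytic <- mean_rate_surface(truth[1, ], 2, 50)
  se <- sd(rates) / sqrt(length(rates))
  expect_lt(abs(mean(rates) - analytic), 3 * se)
})
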