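test_that("dog_value matches its closed forms and the direct formula", {
  expect_equal(dog_value(0, 10, 5, 4, 1.5), 6)
  expect_equal(dog_value(5, 8, 5, 0, 1), 8 * exp(-0.5))
  set.seed(21)
  for (i in 1:20) {
    re <- runif(1, 0.5, 30); we <- runif(1, 0.5, 20)
    ri <- runif(1, 0, 20); wi <- runif(1, 0.1, 10)
    f <- runif(5, 0, 30)
    expect_equal(dog_value(f, re, we, ri, wi), dog_direct(f, re, we, ri, wi))
  }
})

test_that("explained variance follows its defining formula", {
  expect_equal(explained_variance(c(1, 2, 3), c(1, 2, 3)), 1)
  expect_equal(explained_variance(rep(2, 3), c(1, 2, 3)), 0)
  expect_true(is.na(explained_variance(c(1, 2), c(3, 3))))
  set.seed(22)
  f <- rnorm(10); r <- rnorm(10)
  expect_equal(explained_variance(f, r),
               1 - sum((f - r)^2) / sum((r - mean(r))^2))
})

test_that("noiseless d.o.G. data are recovered as a curve", {
  freqs <- c(0.5, 1, 2, 4, 8, 16)
  gen <- list(re = 12, we = 4.7, ri = 8, wi = 1.5)
  rates <- dog_direct(freqs, gen$re, gen$we, gen$ri, gen$wi)
  fit <- fit_dog(rates, freqs)
  expect_true(fit$accepted)
  expect_gt(fit$explained_variance, 0.9999)
  # function-value match on the measurement grid (parameters may trade off)
  expect_equal(dog_value(freqs, fit$gain_e, fit$width_e, fit$gain_i,
                         fit$width_i),
               rates, tolerance = 1e-3)
})

test_that("degenerate inputs yield flagged, well-defined fits", {
  freqs <- c(0.5, 1, 2, 4, 8, 16)
  flat <- fit_dog(rep(3, 6), freqs)
  expect_true(is.na(flat$explained_variance))
  expect_lte(flat$sse, sum((3 - mean(rep(3, 6)))^2) + 1e-6)
  neg <- fit_dog(rep(-2, 6), freqs)
  expect_s3_class(neg, "dog_fit")
})

test_that("monotone-decreasing data give a low-pass fit at the grid edge", {
  freqs <- c(0.5, 1, 2, 4, 8, 16)
  rates <- 10 * exp(-0.5 * freqs^2 / 2^2) + 0.01
  fit <- fit_dog(rates, freqs)
  expect_true(fit$accepted)
  expect_equal(fit$f_opt, 0.05, tolerance = 1e-6)
  expect_identical(fit$pass_class, "low")
  expect_true(is.na(fit$f_low_half))
})

test_that("characteristics agree with the 1e-3 Hz brute-force scan", {
  set.seed(23)
  n_checked <- 0
  while (n_checked < 25) {
    re <- runif(1, 2, 20); we <- runif(1, 1, 15)
    ri <- runif(1, 0.2, 0.95) * re; wi <- runif(1, 0.1, 0.9) * we
    ch <- tf_characteristics(re, we, ri, wi)
    bf <- bf_characteristics(re, we, ri, wi)
    if (is.na(bf$f_opt)) next
    expect_equal(ch$f_opt, bf$f_opt, tolerance = 2e-3)
    if (!is.na(bf$f_low_half)) {
      expect_equal(ch$f_low_half, bf$f_low_half, tolerance = 2e-3)
    } else {
      expect_true(is.na(ch$f_low_half))
    }
    if (!is.na(bf$f_high_half)) {
      expect_equal(ch$f_high_half, bf$f_high_half, tolerance = 2e-3)
    }
    n_checked <- n_checked + 1
  }
})

test_that("a pure Gaussian has the analytic half-width and no low crossing", {
  we <- 3
  ch <- tf_characteristics(10, we, 0, 1)
  expect_equal(ch$f_opt, 0.05)  # low edge of the search grid
  expect_true(is.na(ch$f_low_half))
  # analytic crossing of half the value at the grid's low edge:
  # exp(-f^2/2w^2) = exp(-lo^2/2w^2)/2  =>  f = sqrt(2 ln2 w^2 + lo^2)
  expect_equal(ch$f_high_half, sqrt(2 * log(2) * we^2 + 0.05^2),
               tolerance = 1e-6)
})

test_that("characteristics are invariant to curve scale", {
  ch1 <- tf_characteristics(10, 5, 6, 1.2)
  for (k in c(0.1, 3, 40)) {
    chk <- tf_characteristics(10 * k, 5, 6 * k, 1.2)
    expect_equal(chk$f_opt, ch1$f_opt, tolerance = 1e-6)
    expect_equal(chk$f_low_half, ch1$f_low_half, tolerance = 1e-6)
    expect_equal(chk$f_high_half, ch1$f_high_half, tolerance = 1e-6)
    expect_equal(chk$r_max, k * ch1$r_max, tolerance = 1e-6)
  }
})

test_that("band/low classification follows the half-maximum rule", {
  # Gaussian centred on zero: response at 0.5 Hz far above half-maximum
  lowpass <- list(gain_e = 10, width_e = 4, gain_i = 0, width_i = 1)
  expect_identical(classify_pass(lowpass), "low")
  # narrow band curve peaked near 4 Hz, tiny response at 0.5 Hz
  bandpass <- list(gain_e = 10, width_e = 6, gain_i = 9.8, width_i = 2.5)
  expect_lt(dog_value(0.5, 10, 6, 9.8, 2.5),
            0.5 * tf_characteristics(10, 6, 9.8, 2.5)$r_max)
  expect_identical(classify_pass(bandpass), "band")
  # ground-truth agreement on a generated population's drives
  truth <- sample_population(60, seed = 13)
  for (i in seq_len(20)) {
    fit <- list(gain_e = truth$drive_gain_e[i], width_e = truth$drive_width_e[i],
                gain_i = truth$drive_gain_i[i], width_i = truth$drive_width_i[i])
    ch <- tf_characteristics(fit$gain_e, fit$width_e, fit$gain_i, fit$width_i)
    truth_class <- if (dog_direct(0.5, fit$gain_e, fit$width_e, fit$gain_i,
                                  fit$width_i) < 0.5 * ch$r_max) "band" else "low"
    expect_identical(classify_pass(fit), truth_class)
  }
})

test_that("the rejection rule triggers exactly at its printed thresholds", {
  mk <- function(ge, we, gi, wi) {
    structure(list(gain_e = ge, width_e = we, gain_i = gi, width_i = wi),
              class = "dog_fit")
  }
  reject <- function(f) f$gain_e < 1e-4 || f$gain_i < 1e-4 || f$width_e > 160
  expect_false(reject(mk(1e-4, 5, 1e-4, 1)))
  expect_true(reject(mk(1e-4 - 1e-9, 5, 1, 1)))
  expect_true(reject(mk(1, 5, 1e-4 - 1e-9, 1)))
  expect_false(reject(mk(1, 160, 1, 1)))
  expect_true(reject(mk(1, 160 + 1e-9, 1, 1)))
  # and the fitter applies the same rule: force a one-Gaussian optimum
  freqs <- c(0.5, 1, 2, 4, 8, 16)
  fit <- fit_dog(dog_direct(freqs, 10, 4, 0, 1), freqs)
  if (fit$gain_i < 1e-4) expect_false(fit$accepted)
})

test_that("median fitted optimum recovers the generating median under noise", {
  p <- stimulus_protocol(contrasts = 90, directions = c(0, 90, 180, 270),
                         repeats = 5)
  study <- simulate_study(100, p, seed = 31)
  resp <- inclusion_filter(aggregate_conditions(study$trials, p))
  fits <- fit_tf_tuning(resp, contrasts = 90)
  fits <- dplyr::filter(fits, accepted)
  expect_gt(nrow(fits), 60)
  med_fit <- median(fits$f_opt, na.rm = TRUE)
  med_true <- median(study$truth$drive_f_opt)
  expect_lt(abs(med_fit - med_true) / med_true, 0.2)
})
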