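# canonical static parameter set used across these tests: moderate
# saturation and a band-pass drive
static_params <- list(r_max = 37, sigma = 6.9, n = 0.87, t_gain_e = 1,
                      t_width_e = 4.7, t_gain_i = 0.66, t_width_i = 1.5)

test_that("population surface averages units cell-wise", {
  base <- tidyr::expand_grid(tf_hz = c(1, 4), contrast_pct = c(10, 90))
  one <- dplyr::mutate(base, unit_id = 1L, mean_rate = c(1, 2, 3, 4),
                       sem = 0, n_trials = 10L)
  surf1 <- population_surface(one)
  expect_equal(surf1$mean_rate, c(1, 2, 3, 4))
  two <- dplyr::bind_rows(one,
    dplyr::mutate(base, unit_id = 2L, mean_rate = -c(1, 2, 3, 4),
                  sem = 0, n_trials = 10L))
  expect_equal(population_surface(two)$mean_rate, rep(0, 4))
  # random collection vs a direct mean
  set.seed(51)
  many <- dplyr::bind_rows(lapply(1:5, function(u) {
    dplyr::mutate(base, unit_id = u, mean_rate = rnorm(4), sem = 0,
                  n_trials = 10L)
  }))
  surf <- population_surface(many)
  direct <- tapply(many$mean_rate, list(many$tf_hz, many$contrast_pct), mean)
  expect_equal(surf$mean_rate[surf$tf_hz == 1 & surf$contrast_pct == 10],
               direct["1", "10"])
  expect_equal(surf$mean_rate[surf$tf_hz == 4 & surf$contrast_pct == 90],
               direct["4", "90"])
  # heterogeneous grids are rejected
  expect_error(population_surface(dplyr::bind_rows(one, one[1:2, ])), "grid")
})

test_that("model_surface matches the printed formulas and their limits", {
  p <- static_params
  set.seed(52)
  for (i in 1:15) {
    f <- runif(1, 0.5, 16); cc <- runif(1, 5, 95)
    tt <- dog_direct(f, 1, p$t_width_e, p$t_gain_i, p$t_width_i)
    expect_equal(model_surface("static", p, f, cc),
                 p$r_max * cc^p$n / (p$sigma^p$n / tt + cc^p$n))
    ps <- c(p, list(tau = 0.11))
    expect_equal(model_surface("shunting", ps, f, cc),
                 p$r_max * cc^p$n / ((p$sigma + 0.11 * f)^p$n / tt + cc^p$n))
    expect_equal(model_surface("linear", p, f, cc), p$r_max * cc * tt)
  }
  # saturation ceiling: contrast to infinity approaches r_max
  expect_equal(model_surface("static", p, 2, 1e9), p$r_max, tolerance = 1e-4)
  # shunting with tau = 0 is the static model everywhere
  p0 <- c(p, list(tau = 0))
  grid <- expand.grid(f = c(0.5, 2, 8), cc = c(10, 50, 90))
  expect_equal(model_surface("shunting", p0, grid$f, grid$cc),
               model_surface("static", p, grid$f, grid$cc))
})

test_that("static model nests the linear model in the weak-saturation limit", {
  p <- static_params
  grid <- expand.grid(f = c(0.5, 1, 2, 4, 8, 16), cc = c(10, 30, 50, 70, 90))
  lin <- model_surface("linear", utils::modifyList(p, list(r_max = 1)),
                       grid$f, grid$cc)
  # sigma -> infinity, n = 1, r_max rescaled by sigma
  big <- 1e8
  approx_lin <- model_surface(
    "static", list(r_max = big, sigma = big, n = 1, t_gain_e = 1,
                   t_width_e = p$t_width_e, t_gain_i = p$t_gain_i,
                   t_width_i = p$t_width_i),
    grid$f, grid$cc)
  expect_equal(approx_lin, lin, tolerance = 1e-6)
})

test_that("fits to noiseless model-generated surfaces recover the surface", {
  surf <- make_static_surface(static_params)
  fit <- fit_population(surf, "static")
  expect_gt(fit$explained_variance, 0.999)
  expect_equal(fit$surface$fitted, surf$mean_rate,
               tolerance = 0.02 * max(surf$mean_rate))
  # linear-generated surface: linear fit wins after parameter adjustment
  lin_params <- list(r_max = 0.3, t_gain_e = 1, t_width_e = 4.7,
                     t_gain_i = 0.66, t_width_i = 1.5)
  grid <- tidyr::expand_grid(tf_hz = c(0.5, 1, 2, 4, 8, 16),
                             contrast_pct = c(10, 30, 50, 70, 90))
  grid$mean_rate <- model_surface("linear", lin_params, grid$tf_hz,
                                  grid$contrast_pct)
  grid$sem <- 0
  class(grid) <- c("population_surface", class(grid))
  linfit <- fit_population(grid, "linear")
  statfit <- fit_population(grid, "static")
  expect_gt(linfit$explained_variance, 0.9999)
  expect_gte(linfit$adjusted_explained_variance + 1e-9,
             statfit$adjusted_explained_variance)
})

test_that("shunting with free T reproduces the static optimum exactly", {
  # absorption identity: replacing T by T (sigma + tau f)^n / sigma^n turns
  # a shunting surface into the corresponding static one
  p <- static_params
  freqs <- c(0.5, 1, 2, 4, 8, 16)
  tt <- dog_direct(freqs, 1, p$t_width_e, p$t_gain_i, p$t_width_i)
  tau <- 0.3
  shunt <- list(r_max = p$r_max, sigma = p$sigma, n = p$n, tau = tau,
                t_values = setNames(tt, freqs))
  absorbed <- list(r_max = p$r_max, sigma = p$sigma, n = p$n,
                   t_values = setNames(
                     tt * p$sigma^p$n / (p$sigma + tau * freqs)^p$n, freqs))
  grid <- expand.grid(f = freqs, cc = c(10, 30, 50, 70, 90))
  expect_equal(model_surface("shunting", shunt, grid$f, grid$cc),
               model_surface("static", absorbed, grid$f, grid$cc),
               tolerance = 1e-12)
})

test_that("unit fits: the normalization model dominates the linear model on model-true data", {
  surf <- make_static_surface(static_params)
  unit <- dplyr::mutate(tibble::as_tibble(surf), unit_id = 1L, n_trials = 40L)
  stat <- fit_unit(unit, "static")
  lin <- fit_unit(unit, "linear")
  expect_gte(stat$explained_variance, lin$explained_variance)
  expect_equal(stat$n_par, 7)
  expect_equal(lin$n_par, 5)
  expect_equal(stat$adjusted_explained_variance,
               1 - (1 - stat$explained_variance) * 29 / (30 - 7 - 1))
  # all-equal responses: explained variance undefined
  flat <- dplyr::mutate(unit, mean_rate = 5)
  ffit <- fit_unit(flat, "static")
  expect_true(is.na(ffit$explained_variance))
})

test_that("the static-model theorems hold on fitted surfaces", {
  surf <- make_static_surface(static_params)
  fit <- fit_population(surf, "static")
  chk <- opt_invariance_check(fit)
  expect_lt(chk$max_deviation, 1e-2)
  expect_lt(chk$max_derivative_relerr, 1e-6)
  # relative response: constantly 1 at the optimum, strictly increasing
  # with contrast at suboptimal frequencies
  dense_c <- c(10, 30, 50, 70, 90)
  fopt <- chk$argmax$f_peak[1]
  for (f in c(0.5, 16)) {
    rel <- vapply(dense_c, function(cc) {
      model_surface("static", fit$params, f, cc) /
        model_surface("static", fit$params, fopt, cc)
    }, double(1))
    expect_true(all(diff(rel) > 0))
  }
})

test_that("ratio diagnostic matches its closed form and detects slopes", {
  p <- static_params
  freqs <- c(0.5, 1, 2, 4, 8, 16)
  contrasts <- c(10, 30, 50, 70, 90)
  surf <- make_static_surface(p, freqs, contrasts)
  out <- ratio_diagnostic(surf)
  t_lo <- dog_direct(0.5, 1, p$t_width_e, p$t_gain_i, p$t_width_i)
  t_hi <- dog_direct(8, 1, p$t_width_e, p$t_gain_i, p$t_width_i)
  closed <- (p$sigma^p$n / t_lo + contrasts^p$n) /
    (p$sigma^p$n / t_hi + contrasts^p$n)
  expect_equal(out$ratio, closed, tolerance = 1e-9)
  # linear model: the ratio is exactly constant in contrast
  lin <- make_static_surface(p, freqs, contrasts)
  lin$mean_rate <- model_surface(
    "linear", list(r_max = 0.5, t_gain_e = 1, t_width_e = p$t_width_e,
                   t_gain_i = p$t_gain_i, t_width_i = p$t_width_i),
    lin$tf_hz, lin$contrast_pct)
  rl <- ratio_diagnostic(lin)
  expect_equal(diff(range(rl$ratio)), 0, tolerance = 1e-12)
  expect_equal(attr(rl, "slope"), 0, tolerance = 1e-12)
  # constructed counterexample: low-frequency relative response falling
  # with contrast produces a positive ratio slope
  fall <- lin
  fall$mean_rate <- fall$mean_rate *
    ifelse(fall$tf_hz == 0.5, 1 / (1 + 0.01 * fall$contrast_pct), 1)
  expect_gt(attr(ratio_diagnostic(fall), "slope"), 0)
})

test_that("relative response is 1 at the optimum and monotone off it", {
  surf <- make_static_surface(static_params)
  # grid optimum of the generating drive
  prof <- surf$mean_rate[surf$contrast_pct == 90]
  f_star <- surf$tf_hz[surf$contrast_pct == 90][which.max(prof)]
  rel_opt <- relative_response(surf, f_star)
  expect_equal(rel_opt$relative, rep(1, 5))
  rel_lo <- relative_response(surf, 0.5)
  expect_true(all(diff(rel_lo$relative) > 0))
})
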