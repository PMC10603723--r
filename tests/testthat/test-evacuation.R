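test_that("percent stomach content is the %BW ratio", {
  expect_equal(percent_stomach_content(0, 50), 0)
  expect_equal(percent_stomach_content(1, 50), 2)
  expect_equal(percent_stomach_content(2.5, 100), 2.5)
  expect_equal(percent_stomach_content(c(1, 2), c(50, 50)), c(2, 4))
  expect_error(percent_stomach_content(1, 0), "positive")
  expect_error(percent_stomach_content(1, -5), "positive")
  expect_error(percent_stomach_content(-1, 50), ">= 0")
})

test_that("noiseless exponential series are recovered exactly", {
  cases <- list(c(S0 = 7.23, R = 0.12), c(S0 = 9.09, R = 0.19),
                c(S0 = 3.5, R = 1.2), c(S0 = 120, R = 0.01))
  for (cs in cases) {
    tb <- tibble::tibble(time_h = 0:10, content = cs["S0"] * exp(-cs["R"] * 0:10))
    fit <- fit_evacuation(tb)
    expect_equal(fit$S0, unname(cs["S0"]), tolerance = 1e-12)
    expect_equal(fit$R, unname(cs["R"]), tolerance = 1e-12)
    expect_equal(fit$r_squared, 1)
  }
})

test_that("constant content gives zero evacuation", {
  tb <- tibble::tibble(time_h = 0:10, content = 4.2)
  fit <- fit_evacuation(tb)
  expect_equal(fit$R, 0)
  expect_equal(fit$S0, 4.2)
})

test_that("fit matches an independent normal-equations OLS oracle", {
  set.seed(11)
  for (rep in 1:20) {
    t <- rep(0:10, each = 5)
    content <- exp(rnorm(length(t), mean = 2 - 0.15 * t, sd = 0.3))
    fit <- fit_evacuation(tibble::tibble(time_h = t, content = content))
    ref <- oracle_ols(t, log(content))
    expect_equal(fit$R, -unname(ref["slope"]), tolerance = 1e-12)
    expect_equal(fit$S0, exp(unname(ref["intercept"])), tolerance = 1e-12)
  }
})

test_that("aggregation over hourly means is invariant on noiseless data", {
  t <- rep(0:10, each = 10)
  tb <- tibble::tibble(time_h = t, content = 9.09 * exp(-0.19 * t))
  f_fish <- fit_evacuation(tb)
  f_mean <- fit_evacuation(tb, aggregate = "hourly_mean")
  expect_equal(f_fish$R, f_mean$R, tolerance = 1e-12)
  expect_equal(f_mean$n_obs, 11)
})

test_that("rescaling content leaves R unchanged and scales S0", {
  set.seed(4)
  t <- rep(0:10, each = 3)
  content <- 7 * exp(-0.2 * t) * exp(rnorm(length(t), 0, 0.1))
  f1 <- fit_evacuation(tibble::tibble(time_h = t, content = content))
  fk <- fit_evacuation(tibble::tibble(time_h = t, content = 3.7 * content))
  expect_equal(fk$R, f1$R, tolerance = 1e-12)
  expect_equal(fk$S0, 3.7 * f1$S0, tolerance = 1e-12)
})

test_that("grams vs %BW normalization follows the `normalize` switch", {
  obs <- simulate_evacuation_trial(
    sim_config(true_R = 0.19, s0_mean = 9.09, obs_noise_cv = 0, w0_cv = 0.2,
               seed = 8L)
  )
  f_pct <- fit_evacuation(obs)                     # %BW default
  expect_equal(f_pct$R, 0.19, tolerance = 1e-10)
  expect_equal(f_pct$S0, 9.09, tolerance = 1e-10)
  expect_equal(f_pct$content_units, "%BW")
  f_raw <- fit_evacuation(obs, normalize = FALSE)  # raw grams keep weight scatter
  expect_equal(f_raw$content_units, "g")
  expect_equal(f_raw$R, 0.19, tolerance = 0.05)
})

test_that("zero contents are dropped with a warning, or offset on request", {
  tb <- tibble::tibble(time_h = c(0:5, 6), content = c(5 * exp(-0.4 * 0:5), 0))
  expect_warning(fit <- fit_evacuation(tb), "zero-content")
  expect_equal(fit$R, 0.4, tolerance = 1e-12)
  expect_silent(f2 <- fit_evacuation(tb, zero_policy = "offset"))
  expect_equal(f2$n_obs, 7)
  expect_error(fit_evacuation(tibble::tibble(time_h = 0:5, content = 0)),
               "no evacuable content")
  expect_error(fit_evacuation(tibble::tibble(time_h = c(0, 1), content = c(2, 1))),
               "3 distinct time points")
})

test_that("predict_content evaluates the fitted curve", {
  tb <- tibble::tibble(time_h = 0:10, content = 7.23 * exp(-0.12 * 0:10))
  fit <- fit_evacuation(tb)
  expect_equal(predict_content(fit, 0), 7.23, tolerance = 1e-10)
  f2 <- structure(list(S0 = 10, R = 0.5), class = "evacuation_fit")
  expect_equal(predict_content(f2, 2), 10 * exp(-1))
  expect_equal(predict_content(f2, 2), 3.678794, tolerance = 1e-6)
  expect_lt(predict_content(f2, 100), 1e-15)
  expect_error(predict_content(f2, -1), ">= 0")
})
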