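test_that("identical seed and config give bit-identical tables", {
  cfg <- sim_config(seed = 42L, obs_noise_cv = 0.25, s0_cv = 0.3, w0_cv = 0.15)
  for (f in list(simulate_evacuation_trial, simulate_diel_experiment)) {
    a <- f(cfg)
    b <- f(cfg)
    expect_identical(serialize(a, NULL), serialize(b, NULL))
  }
  g1 <- simulate_group_experiment(c(10, 26), c(30, 70), seed = 7L)
  g2 <- simulate_group_experiment(c(10, 26), c(30, 70), seed = 7L)
  expect_identical(serialize(g1, NULL), serialize(g2, NULL))
})

test_that("evacuation trial follows the exponential decay law exactly without noise", {
  # closed form: s(t) = s0 * exp(-R t)
  cfg <- sim_config(true_R = 0.3, s0_mean = 10, s0_cv = 0, obs_noise_cv = 0,
                    w0_cv = 0, w0_mean = 50, n_fish = 1)
  obs <- simulate_evacuation_trial(cfg, times = c(0, 2))
  pct <- percent_stomach_content(obs$stomach_content_g, obs$body_weight_g)
  expect_equal(pct[obs$time_h == 0], 10)                    # no decay at t = 0
  expect_equal(pct[obs$time_h == 2], 10 * exp(-0.6))        # 5.488116...
  expect_equal(pct[obs$time_h == 2], 5.488116, tolerance = 1e-6)
})

test_that("per-fish heterogeneity and noise stay positive and centred", {
  cfg <- sim_config(seed = 9L, obs_noise_cv = 0.2, s0_cv = 0.2, n_fish = 200)
  obs <- simulate_evacuation_trial(cfg, times = 0:3)
  expect_true(all(obs$stomach_content_g >= 0))
  expect_true(all(obs$body_weight_g > 0))
  # mean-one noise: observed %BW at t=0 centred on s0_mean
  pct0 <- percent_stomach_content(
    obs$stomach_content_g[obs$time_h == 0], obs$body_weight_g[obs$time_h == 0]
  )
  expect_equal(mean(pct0), cfg$s0_mean, tolerance = 0.1)
})

test_that("diel series decays monotonically in expectation without feeding", {
  cfg <- sim_config(feeding_schedule = NULL, s0_mean = 8, obs_noise_cv = 0,
                    s0_cv = 0, w0_cv = 0, true_Gd = 0, seed = 3L)
  diel <- simulate_diel_experiment(cfg, sample_days = 0, n_per_time = 1)
  pct <- percent_stomach_content(diel$stomach_content_g, diel$body_weight_g)
  expect_true(all(diff(pct[order(diel$time_h)]) < 0))
})

test_that("meals add instantaneously and evacuate exponentially between", {
  cfg <- sim_config(feeding_schedule = 12, meal_size = 4, s0_mean = 6,
                    true_R = 0.2, obs_noise_cv = 0, s0_cv = 0, w0_cv = 0,
                    true_Gd = 0, seed = 1L)
  diel <- simulate_diel_experiment(cfg, sample_times = c(0, 11, 12, 13),
                                   sample_days = 0, n_per_time = 1)
  pct <- percent_stomach_content(diel$stomach_content_g, diel$body_weight_g)
  names(pct) <- diel$time_h
  expect_equal(unname(pct["11"]), 6 * exp(-0.2 * 11))
  expect_equal(unname(pct["12"]), 6 * exp(-0.2 * 12) + 4)   # post-meal
  expect_equal(unname(pct["13"]), (6 * exp(-0.2 * 12) + 4) * exp(-0.2))
})

test_that("body weights compound daily at the configured growth rate", {
  cfg <- sim_config(true_Gd = 3.8, w0_mean = 28.85, w0_cv = 0,
                    obs_noise_cv = 0, seed = 5L, duration_days = 30)
  diel <- simulate_diel_experiment(cfg)
  expect_setequal(unique(diel$day), c(0, 6, 12, 18, 24))
  for (d in unique(diel$day)) {
    expect_equal(unique(diel$body_weight_g[diel$day == d]),
                 28.85 * (1 + 3.8 / 100)^d)
  }
  # linear mode
  cfg_lin <- sim_config(true_Gd = 2, w0_mean = 40, w0_cv = 0,
                        obs_noise_cv = 0, growth_model = "linear", seed = 5L)
  diel_lin <- simulate_diel_experiment(cfg_lin, sample_days = c(0, 10))
  expect_equal(unique(diel_lin$body_weight_g[diel_lin$day == 10]),
               40 * (1 + 0.02 * 10))
})

test_that("diel design matches the default sampling layout", {
  diel <- simulate_diel_experiment(sim_config(seed = 2L))
  expect_equal(nrow(diel), 9 * 5 * 5)                       # times x fish x days
  expect_false(any(duplicated(diel$fish_id)))               # destructive sampling
  expect_error(simulate_diel_experiment(sim_config(), sample_times = c(-1, 3)),
               "clock hours")
})

test_that("group experiment flags undersized groups and honours truth without noise", {
  n_mat <- matrix(12, 3, 8)
  n_mat[2, 4] <- 5
  grp <- simulate_group_experiment(c(10, 18, 26), seq(30, 170, by = 20),
                                   n_per_group = n_mat, min_n = 10,
                                   noise_cv = 0, seed = 1L)
  expect_equal(sum(grp$excluded), 1)
  expect_true(grp$excluded[grp$temperature_C == 18 & grp$weight_class_g == 90])
  expect_equal(grp$Gd, grp$true_Gd)
  expect_equal(grp$Cd, grp$true_Cd)

  single <- simulate_group_experiment(20, 50, n_per_group = 15, noise_cv = 0,
                                      gd_fun = function(t, w) 5,
                                      cd_fun = function(t, w) 20, seed = 1L)
  expect_equal(single$Gd, 5)
  expect_equal(single$Cd, 20)
  expect_false(single$excluded)
})

test_that("configuration errors are caught", {
  expect_error(sim_config(true_R = 0), "positive")
  expect_error(sim_config(true_R = -0.1), "positive")
  expect_error(sim_config(obs_noise_cv = -1), ">= 0")
  expect_error(sim_config(feeding_schedule = c(25)), "\\[0, 24\\)")
  expect_error(sim_config(n_fish = 0), "at least 1")
  expect_error(simulate_group_experiment(numeric(0), 30), "one temperature")
  expect_error(simulate_group_experiment(10, c(30, 30)), "strictly increasing")
})
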