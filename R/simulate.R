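#' Simulate a gastric evacuation trial
#'
#' Individual-based simulation of the classic post-satiation evacuation
#' design: fish are fed to satiation at time zero, feeding then stops,
#' and batches of `config$n_fish` fish are destructively sampled at each
#' requested hour. Each fish's true stomach content (in %BW) decays
#' exponentially, `s(t) = s0 * exp(-true_R * t)`; the observed stomach
#' weight in grams is `s(t)/100 * body_weight` times mean-one lognormal
#' observation noise. The daily feeding schedule in `config` is not used
#' here: the trial is defined by a single satiation meal at t = 0.
#'
#' @param config A [sim_config()].
#' @param times Numeric vector of sampling times, hours since satiation.
#'   Default `0:10` (11 hourly batches).
#' @return A tibble of per-fish observations with columns `fish_id`,
#'   `condition`, `day`, `time_h`, `body_weight_g`, `stomach_content_g`,
#'   `fork_length_cm`, `temperature_C`.
#' @examples
#' obs <- simulate_evacuation_trial(
#'   sim_config(true_R = 0.19, s0_mean = 9.09, obs_noise_cv = 0)
#' )
#' fit_evacuation(obs)
#' @export
simulate_evacuation_trial <- function(config, times = 0:10) {
  stopifnot(inherits(config, "sim_config"))
  if (length(times) < 1 || any(times < 0)) {
    stop("`times` must be non-negative hours since satiation.", call. = FALSE)
  }
  withr::with_seed(config$seed, {
    n_tot <- length(times) * config$n_fish
    w <- lognormal_mean_cv(n_tot, config$w0_mean, config$w0_cv)
    s0 <- lognormal_mean_cv(n_tot, config$s0_mean, config$s0_cv)
    noise <- lognormal_noise(n_tot, config$obs_noise_cv)
    t_h <- rep(times, each = config$n_fish)
    pct_true <- s0 * exp(-config$true_R * t_h)
    tibble::tibble(
      fish_id = sprintf("E%03d", seq_len(n_tot)),
      condition = config$condition,
      day = 0L,
      time_h = t_h,
      body_weight_g = w,
      stomach_content_g = pct_true / 100 * w * noise,
      fork_length_cm = fork_length_from_weight(w),
      temperature_C = config$temperature
    )
  })
}

# True population stomach-content trajectory (%BW) under instantaneous
# meals and continuous exponential evacuation. `t_abs` is hours since
# day-0 midnight; meals recur daily at the scheduled clock hours. An
# observation at exactly a meal time sees the post-meal content.
stomach_trajectory <- function(t_abs, s0, rate, meals, n_days) {
  if (nrow(meals) == 0) return(s0 * exp(-rate * t_abs))
  event_t <- as.vector(outer(meals$time_h, 24 * (seq_len(n_days) - 1), `+`))
  event_m <- rep(meals$meal_pct_bw, times = n_days)
  vapply(t_abs, function(t) {
    past <- event_t <= t
    s0 * exp(-rate * t) + sum(event_m[past] * exp(-rate * (t - event_t[past])))
  }, numeric(1))
}

#' Simulate a diel stomach-content sampling experiment
#'
#' Emulates repeated 24-h destructive sampling: on each sampling day,
#' `n_per_time` fish are drawn at each clock time in `sample_times`.
#' Between meals the population stomach content (%BW) decays
#' exponentially at `config$true_R`; each scheduled meal adds its size
#' instantaneously. Body weight grows at `config$true_Gd` %BW/day
#' (compounded daily by default). The trajectory is continuous across
#' days, so after roughly one day of feeding the diel cycle reaches its
#' periodic steady state.
#'
#' @param config A [sim_config()].
#' @param sample_times Clock hours in `[0, 24]` sampled on each sampling
#'   day. Default `seq(0, 24, by = 3)` (9 times).
#' @param sample_days 0-based day indices of the sampling days. Default:
#'   every 6 days over `config$duration_days` (days 0, 6, 12, 18, 24 for
#'   a 30-day experiment).
#' @param n_per_time Fish sampled per clock time. Default 5.
#' @return A tibble of per-fish observations (same columns as
#'   [simulate_evacuation_trial()]); `time_h` holds the clock hour and
#'   `day` the sampling day.
#' @examples
#' diel <- simulate_diel_experiment(sim_config(obs_noise_cv = 0))
#' dplyr::count(diel, day)
#' @export
simulate_diel_experiment <- function(config,
                                     sample_times = seq(0, 24, by = 3),
                                     sample_days = NULL,
                                     n_per_time = 5) {
  stopifnot(inherits(config, "sim_config"))
  if (any(sample_times < 0 | sample_times > 24)) {
    stop("`sample_times` must be clock hours in [0, 24].", call. = FALSE)
  }
  if (is.null(sample_days)) {
    sample_days <- seq(0, config$duration_days - 1, by = 6)
  }
  if (any(sample_days < 0)) stop("`sample_days` must be >= 0.", call. = FALSE)
  n_days_traj <- max(sample_days) + 2L  # meals through the last 24:00 sample

  withr::with_seed(config$seed, {
    grid <- expand.grid(time_h = sample_times, day = as.integer(sample_days))
    grid <- grid[order(grid$day, grid$time_h), ]
    n_tot <- nrow(grid) * n_per_time
    day <- rep(grid$day, each = n_per_time)
    clock <- rep(grid$time_h, each = n_per_time)
    t_abs <- day * 24 + clock

    pct_true <- stomach_trajectory(t_abs, config$s0_mean, config$true_R,
                                   config$feeding_schedule, n_days_traj)
    w0 <- lognormal_mean_cv(n_tot, config$w0_mean, config$w0_cv)
    w <- body_weight_at_day(w0, day, config$true_Gd, config$growth_model)
    noise <- lognormal_noise(n_tot, config$obs_noise_cv)

    tibble::tibble(
      fish_id = sprintf("D%04d", seq_len(n_tot)),
      condition = config$condition,
      day = day,
      time_h = clock,
      body_weight_g = w,
      stomach_content_g = pct_true / 100 * w * noise,
      fork_length_cm = fork_length_from_weight(w),
      temperature_C = config$temperature
    )
  })
}

# Temperature responses anchored at the three determined experimental
# temperatures (10, 18, 26 degC); natural-spline interpolated between.
default_cd_fun <- function(temperature, weight_class) {
  f <- stats::splinefun(c(10, 18, 26), c(22.39, 119.78, 110.54),
                        method = "natural")
  pmax(f(temperature), 1e-6) + 0 * weight_class
}

default_gd_fun <- function(temperature, weight_class) {
  f <- stats::splinefun(c(10, 18, 26), c(7.34, 18.80, 22.36),
                        method = "natural")
  # heavier fish convert less efficiently: mild negative allometry on growth
  pmax(f(temperature), 1e-6) * (weight_class / 90)^-0.25
}

#' Simulate a temperature-by-weight-class group experiment
#'
#' Generates per-group daily growth rate (`Gd`) and daily ingestion rate
#' (`Cd`) summaries over a grid of water temperatures and body-weight
#' classes, mimicking the design in which fish spanning 30-170 g are
#' binned into weight classes and held at controlled temperatures.
#' Per-fish rates are lognormal around the configured group truth;
#' groups with fewer than `min_n` fish are flagged `excluded` (the
#' field-standard minimum sample size rule).
#'
#' @param temps Water temperatures, deg C (>= 1).
#' @param weight_classes Strictly increasing body-weight class centres, g.
#' @param n_per_group Fish per group: a scalar, or a
#'   `length(temps) x length(weight_classes)` matrix.
#' @param gd_fun,cd_fun Functions `(temperature, weight_class)` returning
#'   the true group `Gd` and `Cd`. Defaults interpolate the temperature
#'   response between the three determined experimental temperatures and
#'   apply a mild negative weight-allometry to growth.
#' @param noise_cv Between-fish CV of the lognormal rate variation;
#'   0 makes every group summary equal its configured truth.
#' @param min_n Minimum fish per group; smaller groups are flagged
#'   `excluded = TRUE`. Default 10.
#' @param seed Integer RNG seed.
#' @return A tibble with one row per (temperature, weight class):
#'   `temperature_C`, `weight_class_g`, `n`, `Gd`, `Gd_sd`, `Cd`,
#'   `Cd_sd`, `true_Gd`, `true_Cd`, `excluded`.
#' @examples
#' grp <- simulate_group_experiment(c(10, 18, 26), seq(30, 170, 20),
#'                                  noise_cv = 0)
#' head(grp)
#' @export
simulate_group_experiment <- function(temps, weight_classes,
                                      n_per_group = 12,
                                      gd_fun = default_gd_fun,
                                      cd_fun = default_cd_fun,
                                      noise_cv = 0.2,
                                      min_n = 10,
                                      seed = 1L) {
  if (length(temps) < 1) stop("Need at least one temperature.", call. = FALSE)
  if (length(weight_classes) < 1) stop("Need at least one weight class.", call. = FALSE)
  if (is.unsorted(weight_classes, strictly = TRUE)) {
    stop("`weight_classes` must be strictly increasing (overlapping or duplicated class bounds).",
         call. = FALSE)
  }
  nt <- length(temps); nw <- length(weight_classes)
  if (is.matrix(n_per_group)) {
    if (!all(dim(n_per_group) == c(nt, nw))) {
      stop("`n_per_group` matrix must be temps x weight_classes.", call. = FALSE)
    }
    n_mat <- n_per_group
  } else {
    n_mat <- matrix(n_per_group, nt, nw)
  }

  withr::with_seed(seed, {
    rows <- vector("list", nt * nw)
    k <- 0
    for (i in seq_len(nt)) {
      for (j in seq_len(nw)) {
        k <- k + 1
        n <- n_mat[i, j]
        gd_true <- gd_fun(temps[i], weight_classes[j])
        cd_true <- cd_fun(temps[i], weight_classes[j])
        gd_i <- lognormal_mean_cv(n, gd_true, noise_cv)
        cd_i <- lognormal_mean_cv(n, cd_true, noise_cv)
        rows[[k]] <- tibble::tibble(
          temperature_C = temps[i],
          weight_class_g = weight_classes[j],
          n = as.integer(n),
          Gd = if (noise_cv == 0) gd_true else mean(gd_i),
          Gd_sd = if (n > 1) stats::sd(gd_i) else NA_real_,
          Cd = if (noise_cv == 0) cd_true else mean(cd_i),
          Cd_sd = if (n > 1) stats::sd(cd_i) else NA_real_,
          true_Gd = gd_true,
          true_Cd = cd_true,
          excluded = n < min_n
        )
      }
    }
    dplyr::bind_rows(rows)
  })
}
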