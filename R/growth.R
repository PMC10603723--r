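#' Fit the daily growth rate
#'
#' Ordinary least squares of body weight on experiment day. The daily
#' growth rate `Gd` is the regression slope in g/day; with
#' `units = "percent_bw"` the slope is rescaled by the mean observed
#' weight (`100 * slope / mean weight`, %BW/day). By default the
#' regression runs on per-sampling-day mean weights, matching the
#' granularity of a repeated-sampling design; `by = "fish"` uses every
#' individual observation.
#'
#' @param observations Data frame with `day` and `body_weight_g` columns.
#' @param by `"mean"` (regress day means, default) or `"fish"`.
#' @param units `"g_per_day"` (default) or `"percent_bw"`.
#' @return An object of class `growth_fit`: list with `G_d`, `intercept`
#'   (g at day 0), `r_squared`, `n_obs`, `units`.
#' @examples
#' tb <- tibble::tibble(day = c(0, 30), body_weight_g = c(28.85, 88.51))
#' fit_growth(tb)$G_d  # two-point slope, 1.989 g/day
#' @export
fit_growth <- function(observations,
                       by = c("mean", "fish"),
                       units = c("g_per_day", "percent_bw")) {
  by <- match.arg(by)
  units <- match.arg(units)
  if (!all(c("day", "body_weight_g") %in% names(observations))) {
    stop("`observations` needs `day` and `body_weight_g` columns.", call. = FALSE)
  }
  day <- observations$day
  w <- observations$body_weight_g
  if (any(w <= 0)) stop("body weights must be positive.", call. = FALSE)
  if (by == "mean") {
    m <- tapply(w, day, mean)
    day <- as.numeric(names(m)); w <- as.numeric(m)
  }
  if (length(unique(day)) < 2) {
    stop("need at least 2 distinct days to fit a growth rate.", call. = FALSE)
  }
  fit <- stats::lm(w ~ day)
  co <- stats::coef(fit)
  slope <- unname(co[2])
  r2 <- r_squared_ols(w, stats::fitted(fit))
  structure(
    list(
      G_d = if (units == "percent_bw") 100 * slope / mean(w) else slope,
      intercept = unname(co[1]),
      r_squared = r2,
      n_obs = length(w),
      units = if (units == "percent_bw") "%BW/day" else "g/day"
    ),
    class = "growth_fit"
  )
}

#' @export
print.growth_fit <- function(x, ...) {
  cat("<growth_fit>\n")
  cat(sprintf("  Gd = %.4g %s (intercept %.4g g), R^2 = %.3f, n = %d\n",
              x$G_d, x$units, x$intercept, x$r_squared, x$n_obs))
  invisible(x)
}
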