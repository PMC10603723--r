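#' Stomach content as percent body weight
#'
#' Normalizes stomach-content weight by fish body weight, the standard
#' rescaling that removes between-individual size differences before the
#' evacuation regression.
#'
#' @param stomach_content Stomach-content weight, g (>= 0). Vectorized.
#' @param body_weight Body weight, g (> 0). Vectorized.
#' @return `100 * stomach_content / body_weight`, %BW.
#' @examples
#' percent_stomach_content(1, 50)   # 2 %BW
#' percent_stomach_content(2.5, 100)
#' @export
percent_stomach_content <- function(stomach_content, body_weight) {
  if (any(!is.finite(body_weight)) || any(body_weight <= 0)) {
    stop("`body_weight` must be positive.", call. = FALSE)
  }
  if (any(stomach_content < 0)) {
    stop("`stomach_content` must be >= 0.", call. = FALSE)
  }
  100 * stomach_content / body_weight
}

#' Fit the exponential gastric evacuation model
#'
#' Estimates the instantaneous gastric evacuation rate `R` by ordinary
#' least squares of the natural logarithm of stomach content on time:
#' `ln s(t) = ln S0 - R * t`. `R` is reported as a positive per-hour
#' rate (the negated slope) and `S0 = exp(intercept)` is the content at
#' time zero. The fit is exact closed-form OLS; no iterative nonlinear
#' fitting is involved.
#'
#' Zero stomach contents cannot enter the logarithm. The default policy
#' drops them with a warning; `zero_policy = "offset"` instead adds half
#' the smallest positive observed content to every record.
#'
#' @param observations A data frame with a time column (`time_h`) and
#'   either a `content` column or the pair `stomach_content_g` +
#'   `body_weight_g` (normalized to %BW when `normalize = TRUE`, raw
#'   grams otherwise).
#' @param normalize Use %BW-normalized content (default) rather than raw
#'   grams. Ignored when a `content` column is supplied.
#' @param zero_policy `"drop"` (default) or `"offset"`; see Details.
#' @param aggregate `"fish"` fits all individual observations (default);
#'   `"hourly_mean"` first averages content within each time point.
#' @return An object of class `evacuation_fit`: list with `S0`, `R`,
#'   `r_squared`, `n_obs`, `residuals` (log-scale), `content_units`.
#' @examples
#' tb <- tibble::tibble(time_h = 0:10, content = 7.23 * exp(-0.12 * 0:10))
#' fit_evacuation(tb)
#' @export
fit_evacuation <- function(observations,
                           normalize = TRUE,
                           zero_policy = c("drop", "offset"),
                           aggregate = c("fish", "hourly_mean")) {
  zero_policy <- match.arg(zero_policy)
  aggregate <- match.arg(aggregate)
  if (!"time_h" %in% names(observations)) {
    stop("`observations` needs a `time_h` column.", call. = FALSE)
  }
  if ("content" %in% names(observations)) {
    content <- observations$content
    units <- "as supplied"
  } else if (all(c("stomach_content_g", "body_weight_g") %in% names(observations))) {
    content <- if (normalize) {
      percent_stomach_content(observations$stomach_content_g,
                              observations$body_weight_g)
    } else {
      observations$stomach_content_g
    }
    units <- if (normalize) "%BW" else "g"
  } else {
    stop("`observations` needs a `content` column or `stomach_content_g` + `body_weight_g`.",
         call. = FALSE)
  }
  time_h <- observations$time_h
  keep <- is.finite(content) & is.finite(time_h)
  content <- content[keep]; time_h <- time_h[keep]
  if (length(content) == 0 || all(content == 0)) {
    stop("no evacuable content: all stomach contents are zero.", call. = FALSE)
  }
  if (any(content == 0)) {
    if (zero_policy == "drop") {
      n0 <- sum(content == 0)
      warning(sprintf("dropping %d zero-content record(s) before the log-linear fit", n0),
              call. = FALSE)
      time_h <- time_h[content > 0]; content <- content[content > 0]
    } else {
      content <- content + min(content[content > 0]) / 2
    }
  }
  if (aggregate == "hourly_mean") {
    m <- tapply(content, time_h, mean)
    time_h <- as.numeric(names(m)); content <- as.numeric(m)
  }
  if (length(unique(time_h)) < 3) {
    stop("need at least 3 distinct time points to fit the evacuation model.",
         call. = FALSE)
  }
  fit <- stats::lm(log(content) ~ time_h)
  co <- stats::coef(fit)
  structure(
    list(
      S0 = exp(unname(co[1])),
      R = -unname(co[2]),
      r_squared = r_squared_ols(log(content), stats::fitted(fit)),
      n_obs = length(content),
      residuals = unname(stats::residuals(fit)),
      content_units = units
    ),
    class = "evacuation_fit"
  )
}

# R^2 without summary.lm (which warns on numerically perfect fits);
# a zero-variance response is a perfect fit by convention.
r_squared_ols <- function(y, fitted) {
  ss_tot <- sum((y - mean(y))^2)
  if (ss_tot == 0) return(1)
  max(0, 1 - sum((y - fitted)^2) / ss_tot)
}

#' Evaluate a fitted evacuation curve
#'
#' @param fit An [fit_evacuation()] result.
#' @param time_h Non-negative times, hours.
#' @return Predicted content `S0 * exp(-R * time_h)` in the fit's units.
#' @examples
#' f <- structure(list(S0 = 10, R = 0.5), class = "evacuation_fit")
#' predict_content(f, 2)  # 10 * exp(-1)
#' @export
predict_content <- function(fit, time_h) {
  stopifnot(inherits(fit, "evacuation_fit"))
  if (any(time_h < 0)) stop("`time_h` must be >= 0.", call. = FALSE)
  fit$S0 * exp(-fit$R * time_h)
}

#' @export
predict.evacuation_fit <- function(object, time_h = 0:10, ...) {
  predict_content(object, time_h)
}

#' @export
print.evacuation_fit <- function(x, ...) {
  cat("<evacuation_fit>\n")
  cat(sprintf("  S(t) = %.4g * exp(-%.4g t)   [%s]\n", x$S0, x$R, x$content_units))
  cat(sprintf("  R = %.4g /h, S0 = %.4g, R^2 = %.3f, n = %d\n",
              x$R, x$S0, x$r_squared, x$n_obs))
  invisible(x)
}
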