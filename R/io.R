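#' Read a fish observation table
#'
#' Strict CSV reader for per-fish observation records (the simulator's
#' output format, or equivalently structured field data): UTF-8,
#' comma-separated, `.` decimal mark, mandatory header. Required
#' columns: `fish_id`, `condition`, `day`, `time_h`, `body_weight_g`,
#' `stomach_content_g`, `temperature_C`; extra columns are kept.
#' Malformed numeric fields and physically impossible values are
#' reported with their row numbers; nothing is coerced silently.
#'
#' @param path Path to a CSV file.
#' @return A tibble of validated observations.
#' @export
read_observations <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  required <- c(fish_id = "c", condition = "c", day = "i", time_h = "d",
                body_weight_g = "d", stomach_content_g = "d",
                temperature_C = "d")
  hdr <- names(readr::read_csv(path, n_max = 0, col_types = readr::cols(),
                               show_col_types = FALSE))
  missing <- setdiff(names(required), hdr)
  if (length(missing) > 0) {
    stop("missing required column(s): ", paste(missing, collapse = ", "),
         "\nexpected schema: ", paste(names(required), collapse = ", "),
         call. = FALSE)
  }
  spec <- readr::cols(.default = readr::col_guess())
  spec$cols <- lapply(stats::setNames(required, names(required)), function(t) {
    switch(t, c = readr::col_character(), i = readr::col_integer(),
           d = readr::col_double())
  })
  tb <- readr::read_csv(path, col_types = spec, locale = readr::locale(decimal_mark = "."),
                        show_col_types = FALSE)
  probs <- readr::problems(tb)
  if (nrow(probs) > 0) {
    stop("malformed field(s) at row(s) ",
         paste(unique(probs$row), collapse = ", "),
         " of ", path, " (strict dialect: '.' decimal mark, no coercion).",
         call. = FALSE)
  }
  bad_w <- which(!is.finite(tb$body_weight_g) | tb$body_weight_g <= 0)
  if (length(bad_w) > 0) {
    stop("non-positive body weight at row(s): ", paste(bad_w, collapse = ", "),
         call. = FALSE)
  }
  bad_s <- which(!is.finite(tb$stomach_content_g) | tb$stomach_content_g < 0)
  if (length(bad_s) > 0) {
    stop("negative stomach content at row(s): ", paste(bad_s, collapse = ", "),
         call. = FALSE)
  }
  tb
}

#' Write a table or fit summary to CSV
#'
#' Writes data frames (and one-row summaries of `evacuation_fit` /
#' `growth_fit` objects) as strict CSV. Round-trips with
#' [read_observations()] for observation tables.
#'
#' @param x A data frame, `evacuation_fit` or `growth_fit`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_table <- function(x, path) {
  if (inherits(x, "evacuation_fit")) {
    x <- tibble::tibble(S0 = x$S0, R = x$R, r_squared = x$r_squared,
                        n_obs = x$n_obs, content_units = x$content_units)
  } else if (inherits(x, "growth_fit")) {
    x <- tibble::tibble(G_d = x$G_d, intercept = x$intercept,
                        r_squared = x$r_squared, n_obs = x$n_obs,
                        units = x$units)
  }
  if (!is.data.frame(x)) stop("`x` must be a data frame or fit object.", call. = FALSE)
  readr::write_csv(x, path)
  invisible(path)
}

#' Write / read an efficiency surface as CSV
#'
#' The surface is stored as a matrix CSV (first column `temperature_C`,
#' remaining columns one per weight class) with a companion `_mask.csv`
#' holding the determined flags in the same layout.
#'
#' @param surface An `efficiency_surface`.
#' @param path Output path for the value matrix; the mask goes to
#'   `sub("\\.csv$", "_mask.csv", path)`.
#' @return `path`, invisibly.
#' @export
write_surface <- function(surface, path) {
  stopifnot(inherits(surface, "efficiency_surface"))
  df <- data.frame(temperature_C = surface$temp_axis, surface$values,
                   check.names = FALSE)
  names(df)[-1] <- surface$weight_axis
  readr::write_csv(df, path)
  mask <- data.frame(temperature_C = surface$temp_axis, surface$determined,
                     check.names = FALSE)
  names(mask)[-1] <- surface$weight_axis
  readr::write_csv(mask, sub("\\.csv$", "_mask.csv", path))
  invisible(path)
}

#' @rdname write_surface
#' @param path_values,path_mask Paths written by [write_surface()].
#' @export
read_surface <- function(path_values,
                         path_mask = sub("\\.csv$", "_mask.csv", path_values)) {
  v <- readr::read_csv(path_values, show_col_types = FALSE)
  m <- readr::read_csv(path_mask, show_col_types = FALSE)
  surf <- efficiency_surface(v$temperature_C, as.numeric(names(v)[-1]))
  vals <- as.matrix(v[, -1])
  dimnames(vals) <- dimnames(surf$values)
  surf$values <- vals
  surf$determined <- unname(as.matrix(m[, -1]) > 0)
  surf
}
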