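#' Temperature-by-body-weight conversion-efficiency surface
#'
#' A rectangular grid of ecological conversion efficiencies over water
#' temperature (rows) and body-weight class (columns). Cells filled from
#' determined experimental groups are flagged in `determined`; the
#' remaining cells are `NA` until [interpolate_surface()] completes the
#' grid.
#'
#' @param temp_axis Strictly increasing temperatures, deg C.
#' @param weight_axis Strictly increasing body-weight classes, g.
#' @return An empty `efficiency_surface` (all cells `NA`).
#' @seealso [build_surface()], [interpolate_surface()], [extract_profile()]
#' @export
efficiency_surface <- function(temp_axis, weight_axis) {
  if (length(temp_axis) < 2 || is.unsorted(temp_axis, strictly = TRUE)) {
    stop("`temp_axis` must be strictly increasing with >= 2 levels.", call. = FALSE)
  }
  if (length(weight_axis) < 2 || is.unsorted(weight_axis, strictly = TRUE)) {
    stop("`weight_axis` must be strictly increasing with >= 2 levels.", call. = FALSE)
  }
  nt <- length(temp_axis); nw <- length(weight_axis)
  structure(
    list(
      temp_axis = as.numeric(temp_axis),
      weight_axis = as.numeric(weight_axis),
      values = matrix(NA_real_, nt, nw,
                      dimnames = list(paste0(temp_axis, "C"),
                                      paste0(weight_axis, "g"))),
      determined = matrix(FALSE, nt, nw)
    ),
    class = "efficiency_surface"
  )
}

#' Fill determined cells of an efficiency surface
#'
#' Places determined conversion-efficiency records onto the grid. Every
#' record must map to a unique grid cell; off-grid temperatures or
#' weight classes and duplicate cells are errors, never silently
#' snapped.
#'
#' @param records Data frame with columns `temperature_C`,
#'   `weight_class_g` and `e_g` (percent). Rows with `excluded = TRUE`
#'   (if present) are skipped.
#' @param temp_axis,weight_axis Grid axes (see [efficiency_surface()]).
#' @return An `efficiency_surface` with determined cells filled and
#'   masked.
#' @examples
#' grid <- reference_efficiency_grid()
#' s <- build_surface(grid[grid$determined, ],
#'                    temp_axis = c(10, 14, 18, 22, 26),
#'                    weight_axis = seq(30, 170, by = 20))
#' sum(s$determined)  # 17
#' @export
build_surface <- function(records, temp_axis, weight_axis) {
  surf <- efficiency_surface(temp_axis, weight_axis)
  need <- c("temperature_C", "weight_class_g", "e_g")
  if (!all(need %in% names(records))) {
    stop("`records` needs columns: ", paste(need, collapse = ", "), call. = FALSE)
  }
  if ("excluded" %in% names(records)) {
    records <- records[!records$excluded, , drop = FALSE]
  }
  for (r in seq_len(nrow(records))) {
    i <- match(records$temperature_C[r], surf$temp_axis)
    j <- match(records$weight_class_g[r], surf$weight_axis)
    if (is.na(i) || is.na(j)) {
      stop(sprintf("record %d (%g degC, %g g) is off-grid.", r,
                   records$temperature_C[r], records$weight_class_g[r]),
           call. = FALSE)
    }
    if (surf$determined[i, j]) {
      stop(sprintf("duplicate record for cell (%g degC, %g g).",
                   surf$temp_axis[i], surf$weight_axis[j]), call. = FALSE)
    }
    surf$values[i, j] <- records$e_g[r]
    surf$determined[i, j] <- TRUE
  }
  surf
}

# Natural cubic spline through (x, y) evaluated at xout, with linear
# extrapolation beyond the knot range (the natural boundary condition).
natural_spline_eval <- function(x, y, xout) {
  if (length(x) < 2) stop("need >= 2 knots for spline interpolation.", call. = FALSE)
  if (length(x) == 2) {
    # natural cubic through 2 points degenerates to the straight line
    return(y[1] + (y[2] - y[1]) / (x[2] - x[1]) * (xout - x[1]))
  }
  stats::splinefun(x, y, method = "natural")(xout)
}

#' Complete an efficiency surface by two-pass spline interpolation
#'
#' Fills the empty cells of a partially determined surface with natural
#' cubic splines applied in two separable 1D passes. With the default
#' `order = "rows_first"`: pass 1 completes every row (temperature
#' level) that has determined cells by splining along the weight axis;
#' pass 2 then fills the remaining rows column-by-column by splining
#' along the temperature axis through the pass-1-completed rows. Cells
#' outside a pass's knot range are extended linearly (the natural
#' boundary condition). Determined cells are never altered: this is
#' interpolation, not smoothing.
#'
#' @param surface An `efficiency_surface` from [build_surface()].
#' @param order `"rows_first"` (default) or `"cols_first"`; the
#'   alternative order is provided for sensitivity analysis.
#' @return The surface with all cells filled (`determined` unchanged).
#' @examples
#' grid <- reference_efficiency_grid()
#' s <- build_surface(grid[grid$determined, ], c(10, 14, 18, 22, 26),
#'                    seq(30, 170, by = 20))
#' filled <- interpolate_surface(s)
#' filled$values["10C", "30g"]  # 33.70, a determined knot
#' @export
interpolate_surface <- function(surface, order = c("rows_first", "cols_first")) {
  stopifnot(inherits(surface, "efficiency_surface"))
  order <- match.arg(order)
  v <- surface$values
  det <- surface$determined
  axes <- list(rows = surface$weight_axis, cols = surface$temp_axis)

  fill_lines <- function(v, det, along_rows) {
    n_line <- if (along_rows) nrow(v) else ncol(v)
    for (k in seq_len(n_line)) {
      line_det <- if (along_rows) det[k, ] else det[, k]
      line_val <- if (along_rows) v[k, ] else v[, k]
      if (!any(line_det)) next
      if (sum(line_det) < 2) {
        stop(sprintf("%s %d has a single determined cell: cannot spline.",
                     if (along_rows) "row" else "column", k), call. = FALSE)
      }
      ax <- if (along_rows) axes$rows else axes$cols
      miss <- !line_det
      line_val[miss] <- natural_spline_eval(ax[line_det], line_val[line_det], ax[miss])
      if (along_rows) v[k, ] <- line_val else v[, k] <- line_val
    }
    v
  }
  fill_rest <- function(v, along_rows) {
    n_line <- if (along_rows) nrow(v) else ncol(v)
    for (k in seq_len(n_line)) {
      line_val <- if (along_rows) v[k, ] else v[, k]
      have <- !is.na(line_val)
      if (all(have)) next
      if (sum(have) < 2) {
        stop(sprintf("%s %d has fewer than 2 knots after the first pass.",
                     if (along_rows) "row" else "column", k), call. = FALSE)
      }
      ax <- if (along_rows) axes$rows else axes$cols
      line_val[!have] <- natural_spline_eval(ax[have], line_val[have], ax[!have])
      if (along_rows) v[k, ] <- line_val else v[, k] <- line_val
    }
    v
  }

  if (order == "rows_first") {
    v <- fill_lines(v, det, along_rows = TRUE)   # complete determined rows
    v <- fill_rest(v, along_rows = FALSE)        # fill remaining rows by column
  } else {
    v <- fill_lines(v, det, along_rows = FALSE)
    v <- fill_rest(v, along_rows = TRUE)
  }
  surface$values <- v
  surface
}

#' Extract an iso-temperature efficiency profile
#'
#' Evaluates the filled surface at an arbitrary temperature by splining
#' each weight column along the temperature axis. At a grid temperature
#' this returns that row exactly; off-knot temperatures (e.g. 25 deg C
#' between the 22 and 26 deg C rows) are interpolated.
#'
#' @param surface A filled `efficiency_surface`.
#' @param temperature Temperature at which to extract, deg C.
#' @param allow_extrapolation Permit temperatures outside the axis range
#'   (linear extension). Default FALSE: extrapolation is an error.
#' @return A tibble with columns `weight_class_g`, `e_g`.
#' @examples
#' grid <- reference_efficiency_grid()
#' s <- interpolate_surface(build_surface(grid[grid$determined, ],
#'        c(10, 14, 18, 22, 26), seq(30, 170, by = 20)))
#' extract_profile(s, 25)
#' @export
extract_profile <- function(surface, temperature, allow_extrapolation = FALSE) {
  stopifnot(inherits(surface, "efficiency_surface"))
  if (length(temperature) != 1 || !is.finite(temperature)) {
    stop("`temperature` must be a single finite value.", call. = FALSE)
  }
  rng <- range(surface$temp_axis)
  if (!allow_extrapolation && (temperature < rng[1] || temperature > rng[2])) {
    stop(sprintf("temperature %.2f degC is outside the surface range [%g, %g]; set `allow_extrapolation = TRUE` to extend.",
                 temperature, rng[1], rng[2]), call. = FALSE)
  }
  if (anyNA(surface$values)) {
    stop("surface has unfilled cells; run `interpolate_surface()` first.", call. = FALSE)
  }
  e_g <- vapply(seq_along(surface$weight_axis), function(j) {
    natural_spline_eval(surface$temp_axis, surface$values[, j], temperature)
  }, numeric(1))
  tibble::tibble(weight_class_g = surface$weight_axis, e_g = e_g)
}

#' Packaged reference grid of chub mackerel conversion efficiencies
#'
#' The published 5 x 8 temperature-by-weight grid of ecological
#' conversion efficiencies for chub mackerel (temperatures 10-26 deg C,
#' weight classes 30-170 g). 17 cells were determined experimentally
#' (`determined = TRUE`); the remaining 23 are the published spline
#' estimates, bundled for comparison against this package's
#' interpolation.
#'
#' @return A tibble: `temperature_C`, `weight_class_g`, `e_g`,
#'   `determined`.
#' @examples
#' grid <- reference_efficiency_grid()
#' sum(grid$determined)  # 17
#' @export
reference_efficiency_grid <- function() {
  path <- system.file("extdata", "conversion_efficiency_grid.csv",
                      package = "fishration", mustWork = TRUE)
  readr::read_csv(path, col_types = readr::cols(
    temperature_C = readr::col_double(),
    weight_class_g = readr::col_double(),
    e_g = readr::col_double(),
    determined = readr::col_logical()
  ))
}

#' @export
print.efficiency_surface <- function(x, ...) {
  cat(sprintf("<efficiency_surface> %d temperatures x %d weight classes, %d determined, %d unfilled\n",
              length(x$temp_axis), length(x$weight_axis),
              sum(x$determined), sum(is.na(x$values))))
  print(round(x$values, 2))
  invisible(x)
}

#' @export
as.matrix.efficiency_surface <- function(x, ...) x$values
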