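ref_axes <- list(temp = c(10, 14, 18, 22, 26), weight = seq(30, 170, by = 20))

ref_surface <- function(filled = FALSE) {
  grid <- reference_efficiency_grid()
  s <- build_surface(grid[grid$determined, ], ref_axes$temp, ref_axes$weight)
  if (filled) interpolate_surface(s) else s
}

test_that("building the reference grid fills exactly the determined cells", {
  s <- ref_surface()
  expect_equal(sum(s$determined), 17)
  expect_equal(sum(is.na(s$values)), 40 - 17)
  expect_equal(s$values["10C", "30g"], 33.70)
  expect_equal(s$values["18C", "170g"], 8.97)
})

test_that("duplicate and off-grid records are rejected", {
  rec <- tibble::tibble(temperature_C = c(10, 10), weight_class_g = c(30, 30),
                        e_g = c(1, 2))
  expect_error(build_surface(rec, ref_axes$temp, ref_axes$weight), "duplicate")
  off <- tibble::tibble(temperature_C = 12, weight_class_g = 30, e_g = 1)
  expect_error(build_surface(off, ref_axes$temp, ref_axes$weight), "off-grid")
  expect_error(efficiency_surface(c(10, 10), c(30, 50)), "strictly increasing")
})

test_that("interpolation preserves every determined knot exactly", {
  s <- ref_surface()
  filled <- interpolate_surface(s)
  expect_false(anyNA(filled$values))
  expect_identical(filled$values[s$determined], s$values[s$determined])
  expect_identical(filled$determined, s$determined)
})

test_that("record order does not change the surface", {
  grid <- reference_efficiency_grid()
  det <- grid[grid$determined, ]
  s1 <- interpolate_surface(build_surface(det, ref_axes$temp, ref_axes$weight))
  s2 <- interpolate_surface(build_surface(det[rev(seq_len(nrow(det))), ],
                                          ref_axes$temp, ref_axes$weight))
  expect_identical(s1$values, s2$values)
})

test_that("spline fill reproduces data linear in temperature exactly", {
  # values linear in T per column: the natural cubic through collinear
  # knots is the straight line, so pass 2 must be exact
  tax <- c(10, 14, 18, 22, 26); wax <- c(30, 50, 70)
  truth <- outer(tax, wax, function(t, w) 2 * t + 0.1 * w)
  rec <- expand.grid(temperature_C = c(10, 18, 26), weight_class_g = wax)
  rec$e_g <- 2 * rec$temperature_C + 0.1 * rec$weight_class_g
  filled <- interpolate_surface(build_surface(rec, tax, wax))
  expect_equal(filled$values, truth, ignore_attr = TRUE, tolerance = 1e-12)
})

test_that("both passes match the tridiagonal natural-spline oracle", {
  set.seed(31)
  for (rep in 1:25) {
    inst <- random_surface_instance()
    s <- build_surface(instance_records(inst), inst$temp_axis, inst$weight_axis)
    filled <- interpolate_surface(s)
    ref <- oracle_fill_surface(inst$values, inst$determined,
                               inst$temp_axis, inst$weight_axis)
    expect_equal(unname(filled$values), ref, tolerance = 1e-10)
  }
})

test_that("a single-knot line is an error, not a guess", {
  rec <- tibble::tibble(temperature_C = c(10, 10, 18), weight_class_g = c(30, 50, 30),
                        e_g = c(1, 2, 3))
  expect_error(interpolate_surface(build_surface(rec, c(10, 14, 18), c(30, 50))),
               "single determined cell")
})

test_that("profiles at grid temperatures equal the matrix rows", {
  filled <- ref_surface(filled = TRUE)
  p18 <- extract_profile(filled, 18)
  expect_equal(p18$e_g, unname(filled$values["18C", ]), tolerance = 1e-12)
})

test_that("the 25 degC profile interpolates between bracketing rows and declines with weight", {
  filled <- ref_surface(filled = TRUE)
  p25 <- extract_profile(filled, 25)
  # oracle per column through the five filled rows
  ref <- vapply(seq_along(ref_axes$weight), function(j) {
    oracle_natural_spline(ref_axes$temp, filled$values[, j], 25)
  }, numeric(1))
  expect_equal(p25$e_g, ref, tolerance = 1e-10)
  # qualitative: efficiency declines with body weight from 90 g up
  heavy <- p25$e_g[p25$weight_class_g >= 90]
  expect_true(all(diff(heavy) < 0))
})

test_that("extrapolation in temperature requires an explicit opt-in", {
  filled <- ref_surface(filled = TRUE)
  expect_error(extract_profile(filled, 30), "outside the surface range")
  expect_silent(extract_profile(filled, 30, allow_extrapolation = TRUE))
  expect_error(extract_profile(ref_surface(), 18), "unfilled")
})

test_that("alternative fill order also honours knots", {
  # a grid whose every column has >= 2 knots, so the column-first pass is legal
  tax <- c(10, 14, 18, 22, 26); wax <- c(30, 50, 70)
  rec <- expand.grid(temperature_C = c(10, 18, 26), weight_class_g = wax)
  rec$e_g <- 30 - rec$temperature_C / 2 + sqrt(rec$weight_class_g)
  s <- build_surface(rec, tax, wax)
  filled <- interpolate_surface(s, order = "cols_first")
  expect_identical(filled$values[s$determined], s$values[s$determined])
  expect_false(anyNA(filled$values))
})
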