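test_that("strip areas match trapezoid geometry and reject bad input", {
  expect_equal(strip_area(0, 1, 2, 4), 3)
  expect_equal(strip_area(0, 1, 0, 0), 0)
  expect_equal(strip_area(2, 2.25, 0.4, 0.4), 0.1)
  expect_error(strip_area(1, 1, 0.2, 0.2), "exceed")
  expect_error(strip_area(0, 1, -0.1, 0.2), "nonnegative")
})

test_that("strip centroids reproduce rectangle, triangle, and trapezoid", {
  rect <- strip_centroid(0, 1, 0.5, 0.5)
  expect_identical(rect$x_bar, 0.5)
  expect_identical(rect$y_bar, 0.25)
  tri <- strip_centroid(0, 1, 0, 0.9)
  expect_equal(tri$x_bar, 2 / 3)
  expect_equal(tri$y_bar, 0.3)
  # general trapezoid, expected value frozen from the dense-region oracle
  trap <- strip_centroid(0, 1, 2, 4)
  expect_equal(trap$x_bar, 5 / 9, tolerance = 1e-12)
  expect_equal(trap$y_bar, 14 / 9, tolerance = 1e-12)
  oracle <- centroid_oracle_dense(growth_curve("trap", c(0, 1), c(2, 4)),
                                  refinement = 2000L)
  expect_equal(trap$x_bar, oracle$x_bar, tolerance = 1e-6)
  expect_equal(trap$y_bar, oracle$y_bar, tolerance = 1e-6)
})

test_that("strip y-centroid agrees with the symmetric closed form on random strips", {
  set.seed(7)
  for (i in 1:50) {
    y0 <- runif(1, 0, 3); y1 <- runif(1, 0, 3)
    got <- strip_centroid(0, runif(1, 0.1, 5), y0, y1)
    expect_equal(got$y_bar, trapezoid_ybar_symmetric(y0, y1),
                 tolerance = 1e-14)
  }
})

test_that("degenerate strips carry NA coordinates and zero weight", {
  degen <- strip_centroid(0, 1, 0, 0)
  expect_true(is.na(degen$x_bar) && is.na(degen$y_bar))
  # a curve with an internal all-zero interval still has a defined centroid
  cv <- growth_curve("z", 0:4, c(0.4, 0, 0, 0, 0.4))
  cen <- curve_centroid(cv)
  expect_true(is.finite(cen$x_bar) && is.finite(cen$y_bar))
  expect_equal(cen$x_bar, 2, tolerance = 1e-12) # symmetric mass
  oracle <- centroid_oracle_dense(cv, 2000L)
  expect_equal(cen$y_bar, oracle$y_bar, tolerance = 1e-6)
})

test_that("curve centroids match closed forms for rectangle and triangle", {
  cen <- curve_centroid(flat_curve(0.4, 0:3))
  expect_equal(cen$x_bar, 1.5)
  expect_equal(cen$y_bar, 0.2)
  expect_equal(cen$area, 1.2)
  tri <- curve_centroid(growth_curve("tri", c(0, 2), c(0, 0.6)))
  expect_equal(tri$x_bar, 4 / 3)
  expect_equal(tri$y_bar, 0.2)
  expect_equal(tri$area, 0.6)
  zero <- curve_centroid(growth_curve("none", 0:3, rep(0, 4)))
  expect_identical(zero$area, 0)
  expect_true(is.na(zero$x_bar))
})

test_that("dense-region oracle recovers closed forms and converges quadratically", {
  rect <- centroid_oracle_dense(flat_curve(0.4, 0:3), 1000L)
  expect_equal(rect$x_bar, 1.5, tolerance = 1e-6)
  expect_equal(rect$y_bar, 0.2, tolerance = 1e-6)
  expect_equal(rect$area, 1.2, tolerance = 1e-9)
  tri <- centroid_oracle_dense(growth_curve("tri", c(0, 2), c(0, 0.6)), 1000L)
  expect_equal(tri$x_bar, 4 / 3, tolerance = 1e-6)
  expect_equal(tri$y_bar, 0.2, tolerance = 1e-6)

  set.seed(11)
  cv <- random_piecewise_curve(default_time_grid(12, 0.5))
  exact <- curve_centroid(cv)
  err <- function(refn) {
    o <- centroid_oracle_dense(cv, refn)
    abs(o$y_bar - exact$y_bar)
  }
  e10 <- err(10L); e100 <- err(100L)
  expect_lt(e100, e10 / 20) # ~quadratic: factor 100 expected
})

test_that("curve centroid agrees with the oracle on mixed rising/falling curves", {
  cv <- growth_curve("mixed", c(0, 1.5, 3, 4, 6, 8),
                     c(0.1, 0.8, 0.3, 0.0, 0.9, 0.2))
  exact <- curve_centroid(cv)
  oracle <- centroid_oracle_dense(cv, 4000L)
  expect_equal(exact$x_bar, oracle$x_bar, tolerance = 1e-7)
  expect_equal(exact$y_bar, oracle$y_bar, tolerance = 1e-7)
  expect_equal(exact$area, oracle$area, tolerance = 1e-12)
})

test_that("centroid coordinates stay inside the curve's bounding box", {
  set.seed(3)
  for (i in 1:25) {
    cv <- random_piecewise_curve(default_time_grid(24, 0.5))
    cen <- curve_centroid(cv)
    if (cen$area == 0) next
    expect_gte(cen$x_bar, min(cv$times))
    expect_lte(cen$x_bar, max(cv$times))
    expect_gte(cen$y_bar, 0)
    expect_lte(cen$y_bar, max(cv$ods))
  }
})

test_that("centroid index hits its definitional anchors", {
  ctrl <- flat_curve(0.4, 0:3, "ctrl")
  expect_identical(centroid_index(ctrl, ctrl)$ci, 0)
  zero <- growth_curve("zero", 0:3, rep(0, 4))
  expect_identical(centroid_index(zero, ctrl)$ci, 1)
  half <- flat_curve(0.2, 0:3, "half")
  expect_equal(centroid_index(half, ctrl)$ci, 0.5, tolerance = 1e-14)
})

test_that("centroid index fails cleanly on degenerate controls", {
  treated <- flat_curve(0.2, 0:3)
  zero_ctrl <- growth_curve("zc", 0:3, rep(0, 4))
  expect_error(centroid_index(treated, zero_ctrl), "degenerate")
  off_grid <- growth_curve("og", c(0, 2, 4, 6), rep(0.2, 4))
  expect_error(centroid_index(off_grid, flat_curve()), "time grid")
})

test_that("CI is bounded by 1, invariant to common scaling, monotone in suppression", {
  set.seed(19)
  times <- default_time_grid(48, 0.5)
  for (i in 1:40) {
    pair <- random_pair(times)
    res <- centroid_index(pair$treated, pair$control)
    expect_lte(res$ci, 1)
    # sign characterization: CI < 0 iff treated centroid product exceeds ctrl's
    prod_t <- res$treated_centroid$x_bar * res$treated_centroid$y_bar
    prod_c <- res$control_centroid$x_bar * res$control_centroid$y_bar
    expect_identical(res$ci < 0, prod_t > prod_c)
    # common scaling leaves CI untouched
    k <- runif(1, 0.2, 5)
    scaled <- centroid_index(
      growth_curve("t", times, pair$treated$ods * k),
      growth_curve("c", times, pair$control$ods * k))
    expect_equal(scaled$ci, res$ci, tolerance = 1e-12)
    # shrinking only the treated curve raises CI strictly
    shrunk <- centroid_index(
      growth_curve("t", times, pair$treated$ods * 0.5), pair$control)
    if (res$treated_centroid$area > 0) expect_gt(shrunk$ci, res$ci)
  }
})
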