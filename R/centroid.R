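#' Area of one trapezoidal strip
#'
#' One time interval of an OD series, together with the time axis, bounds a
#' trapezoidal strip with parallel vertical sides `y_prev` and `y` and width
#' `x - x_prev`. Its area is `(y_prev + y)/2 * (x - x_prev)` — the trapezoid
#' rule applied to a single interval. Vectorized over all arguments.
#'
#' @param x_prev,x Interval endpoints in hours, `x > x_prev`.
#' @param y_prev,y Nonnegative OD readings at the endpoints.
#' @return Strip area in OD·hours.
#' @examples
#' strip_area(0, 1, 2, 4)        # 3
#' strip_area(2, 2.25, 0.4, 0.4) # 0.1 (15-min rectangle)
#' @export
strip_area <- function(x_prev, x, y_prev, y) {
  if (any(x <= x_prev)) stop("`x` must exceed `x_prev`", call. = FALSE)
  if (any(y_prev < 0) || any(y < 0)) {
    stop("OD values must be nonnegative", call. = FALSE)
  }
  (y_prev + y) / 2 * (x - x_prev)
}

#' Centroid of one trapezoidal strip
#'
#' Closed-form centroid of the trapezoid with vertical sides `y_prev` at
#' `x_prev` and `y` at `x`:
#' \deqn{\bar{x}_j = x_{j-1} + \frac{(x_j - x_{j-1})(y_{j-1} + 2 y_j)}
#'   {3 (y_{j-1} + y_j)}, \qquad
#'   \bar{y}_j = \frac{1}{3}\left(y_j + \frac{y_{j-1}^2}{y_{j-1}+y_j}\right).}
#' A degenerate strip (`y_prev + y == 0`) has zero area and no defined
#' centroid; it is signalled with `NA` coordinates and callers drop it from
#' area-weighted sums, where its weight is zero anyway. Vectorized.
#'
#' @inheritParams strip_area
#' @return A list with numeric elements `x_bar` and `y_bar` (`NA` for
#'   degenerate strips).
#' @examples
#' strip_centroid(0, 1, 0.5, 0.5) # rectangle: (0.5, 0.25)
#' strip_centroid(0, 1, 0, 0.9)   # right triangle: (2/3, 0.3)
#' @export
strip_centroid <- function(x_prev, x, y_prev, y) {
  if (any(x <= x_prev)) stop("`x` must exceed `x_prev`", call. = FALSE)
  if (any(y_prev < 0) || any(y < 0)) {
    stop("OD values must be nonnegative", call. = FALSE)
  }
  s <- y_prev + y
  x_bar <- x_prev + (x - x_prev) * (y_prev + 2 * y) / (3 * s)
  y_bar <- (y + y_prev^2 / s) / 3
  degen <- s == 0
  x_bar[degen] <- NA_real_
  y_bar[degen] <- NA_real_
  list(x_bar = x_bar, y_bar = y_bar)
}

#' Centroid of the region under a growth curve
#'
#' Treats the piecewise-linear OD series as the upper boundary of a region
#' above the time axis, splits that region into one trapezoidal strip per time
#' interval, and combines the strips' areas and centroids into the composite
#' centroid:
#' \deqn{\bar{x} = \frac{\sum_j \bar{x}_j A_j}{A}, \qquad
#'   \bar{y} = \frac{\sum_j \bar{y}_j A_j}{A}, \qquad A = \sum_j A_j.}
#' For a piecewise-linear curve this decomposition is exact, not an
#' approximation. Zero-area strips contribute nothing. If the whole curve has
#' zero area the centroid is undefined: `area` is 0 and the coordinates `NA`.
#'
#' @param curve A [growth_curve()] with nonnegative ODs.
#' @return An object of class `centroid`: list with `x_bar` (h), `y_bar` (OD),
#'   `area` (OD·h), and `sample_id`.
#' @examples
#' cv <- growth_curve("ctrl", 0:3, rep(0.4, 4))
#' curve_centroid(cv) # x_bar 1.5, y_bar 0.2, area 1.2
#' @export
curve_centroid <- function(curve) {
  stopifnot_curve(curve)
  if (any(curve$ods < 0)) {
    stop("curve '", curve$sample_id,
         "' has negative OD; apply clamp_nonnegative() first", call. = FALSE)
  }
  n <- length(curve$times)
  x0 <- curve$times[-n]; x1 <- curve$times[-1L]
  y0 <- curve$ods[-n]; y1 <- curve$ods[-1L]
  a_j <- strip_area(x0, x1, y0, y1)
  area <- sum(a_j)
  if (area == 0) {
    return(structure(list(x_bar = NA_real_, y_bar = NA_real_, area = 0,
                          sample_id = curve$sample_id), class = "centroid"))
  }
  cen <- strip_centroid(x0, x1, y0, y1)
  keep <- a_j > 0
  structure(list(x_bar = sum(cen$x_bar[keep] * a_j[keep]) / area,
                 y_bar = sum(cen$y_bar[keep] * a_j[keep]) / area,
                 area = area, sample_id = curve$sample_id),
            class = "centroid")
}

#' @export
print.centroid <- function(x, ...) {
  if (x$area == 0) {
    cat(sprintf("<centroid> '%s': undefined (zero area)\n", x$sample_id))
  } else {
    cat(sprintf("<centroid> '%s': t_bar = %.4f h, y_bar = %.4f OD, area = %.4f OD·h\n",
                x$sample_id, x$x_bar, x$y_bar, x$area))
  }
  invisible(x)
}

#' Centroid Index of a treated curve against a control
#'
#' The Centroid Index scores how strongly a phage (or cocktail) suppresses its
#' host by comparing curve centroids:
#' \deqn{\mathrm{CI}_i = 1 - \frac{\bar{x}_i \bar{y}_i}
#'   {\bar{x}_\mathrm{ctrl}\, \bar{y}_\mathrm{ctrl}}.}
#' CI is 1 for complete suppression (defined as the continuous limit when the
#' treated curve has zero area), 0 when the treated curve matches the control,
#' and negative when the treated centroid product exceeds the control's —
#' e.g. growth above the control, or substantial regrowth late in incubation
#' pushing \eqn{\bar{x}_i} out. Unlike the area-based Virulence Index, CI is
#' sensitive to *when* the bacterial mass occurs, not only to how much of it
#' there is.
#'
#' @param treated,control [growth_curve()] objects on one shared time grid
#'   (see [align_time_grids()]). The control must have positive area and
#'   positive centroid coordinate product.
#' @return An object of class `ci_result`: list with `ci`,
#'   `treated_centroid`, `control_centroid`, `treated_id`, `control_id`.
#' @examples
#' ctrl <- growth_curve("ctrl", 0:3, rep(0.4, 4))
#' half <- growth_curve("phage", 0:3, rep(0.2, 4))
#' centroid_index(half, ctrl)$ci # 0.5
#' @export
centroid_index <- function(treated, control) {
  stopifnot_curve(treated, "treated")
  stopifnot_curve(control, "control")
  if (length(treated$times) != length(control$times) ||
      any(abs(treated$times - control$times) > 1e-9)) {
    stop("treated and control curves are not on the same time grid; ",
         "use align_time_grids()", call. = FALSE)
  }
  ctrl_cen <- curve_centroid(control)
  if (ctrl_cen$area == 0 ||
      !is.finite(ctrl_cen$x_bar * ctrl_cen$y_bar) ||
      ctrl_cen$x_bar * ctrl_cen$y_bar <= 0) {
    stop("control curve '", control$sample_id,
         "' is degenerate (zero area or zero centroid product); CI undefined",
         call. = FALSE)
  }
  tr_cen <- curve_centroid(treated)
  ci <- if (tr_cen$area == 0) {
    1 # complete suppression: continuous limit of the index
  } else {
    1 - (tr_cen$x_bar * tr_cen$y_bar) / (ctrl_cen$x_bar * ctrl_cen$y_bar)
  }
  structure(list(ci = ci, treated_centroid = tr_cen,
                 control_centroid = ctrl_cen,
                 treated_id = treated$sample_id,
                 control_id = control$sample_id),
            class = "ci_result")
}

#' @export
print.ci_result <- function(x, ...) {
  cat(sprintf("<ci_result> CI(%s vs %s) = %.4f\n",
              x$treated_id, x$control_id, x$ci))
  invisible(x)
}

#' Dense-grid centroid oracle
#'
#' Independent check of [curve_centroid()]: computes the area and the first
#' moments of the region under the piecewise-linear curve by brute-force
#' midpoint quadrature, subdividing every original time interval into
#' `refinement` subintervals and treating each thin slice as a rectangle of
#' height equal to the interpolated OD at its midpoint,
#' \deqn{A = \int y\,\mathrm{d}x, \quad Q_y = \int x\,y\,\mathrm{d}x, \quad
#'   Q_x = \int \tfrac{1}{2} y^2\,\mathrm{d}x,}
#' with \eqn{\bar{x} = Q_y/A} and \eqn{\bar{y} = Q_x/A}. The quadrature error
#' vanishes as `refinement^-2`, so agreement with the closed-form strip
#' decomposition at large `refinement` validates the latter. This function is
#' a test oracle, deliberately sharing no code with [curve_centroid()].
#'
#' @param curve A [growth_curve()] with nonnegative ODs.
#' @param refinement Integer >= 2, subdivisions per original interval.
#' @return A `centroid` object (coordinates `NA` when the area is zero).
#' @export
centroid_oracle_dense <- function(curve, refinement = 1000L) {
  stopifnot_curve(curve)
  refinement <- as.integer(refinement)
  if (is.na(refinement) || refinement < 2L) {
    stop("`refinement` must be an integer >= 2", call. = FALSE)
  }
  if (any(curve$ods < 0)) stop("ODs must be nonnegative", call. = FALSE)
  n <- length(curve$times)
  area <- 0; q_y <- 0; q_x <- 0
  for (j in seq_len(n - 1L)) {
    h <- (curve$times[j + 1L] - curve$times[j]) / refinement
    xm <- curve$times[j] + (seq_len(refinement) - 0.5) * h
    frac <- (xm - curve$times[j]) / (curve$times[j + 1L] - curve$times[j])
    ym <- curve$ods[j] + frac * (curve$ods[j + 1L] - curve$ods[j])
    area <- area + sum(ym) * h
    q_y <- q_y + sum(xm * ym) * h
    q_x <- q_x + sum(ym^2 / 2) * h
  }
  if (area == 0) {
    return(structure(list(x_bar = NA_real_, y_bar = NA_real_, area = 0,
                          sample_id = curve$sample_id), class = "centroid"))
  }
  structure(list(x_bar = q_y / area, y_bar = q_x / area, area = area,
                 sample_id = curve$sample_id), class = "centroid")
}
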