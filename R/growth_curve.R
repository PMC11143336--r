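#' Construct a growth curve
#'
#' A `growth_curve` holds one sample's optical-density (OD) time series on a
#' strictly increasing time grid. Times are always stored in hours; OD is
#' dimensionless absorbance. This is the unit of analysis for every metric in
#' the package: the time grid supplies the strip widths and the OD readings the
#' strip heights of the discretized centroid computation.
#'
#' @param sample_id Character scalar labelling the sample (well or condition).
#' @param times Numeric vector of time points in hours, strictly increasing,
#'   length at least 2.
#' @param ods Numeric vector of OD readings, same length as `times`. Negative
#'   values are permitted at construction (raw blank-subtracted data); all
#'   analysis functions require nonnegative OD, enforced via
#'   [clamp_nonnegative()].
#' @return An object of class `growth_curve`: a list with elements
#'   `sample_id`, `times`, `ods`.
#' @examples
#' gc <- growth_curve("ctrl", times = 0:4, ods = c(0.1, 0.2, 0.4, 0.6, 0.65))
#' print(gc)
#' @export
growth_curve <- function(sample_id, times, ods) {
  if (!is.character(sample_id) || length(sample_id) != 1L || is.na(sample_id)) {
    stop("`sample_id` must be a single non-NA character string", call. = FALSE)
  }
  times <- as.numeric(times)
  ods <- as.numeric(ods)
  if (length(times) != length(ods)) {
    stop("`times` and `ods` must have equal length (sample '", sample_id, "')",
         call. = FALSE)
  }
  if (length(times) < 2L) {
    stop("growth curve '", sample_id, "' needs at least 2 time points",
         call. = FALSE)
  }
  if (anyNA(times) || anyNA(ods)) {
    stop("growth curve '", sample_id, "' contains missing values",
         call. = FALSE)
  }
  if (any(diff(times) <= 0)) {
    stop("`times` must be strictly increasing (sample '", sample_id, "')",
         call. = FALSE)
  }
  structure(list(sample_id = sample_id, times = times, ods = ods),
            class = "growth_curve")
}

#' @export
print.growth_curve <- function(x, ...) {
  cat(sprintf("<growth_curve> '%s': %d points, t = [%g, %g] h, OD = [%g, %g]\n",
              x$sample_id, length(x$times), min(x$times), max(x$times),
              min(x$ods), max(x$ods)))
  invisible(x)
}

#' @export
as.data.frame.growth_curve <- function(x, ...) {
  data.frame(sample = x$sample_id, time = x$times, od = x$ods,
             stringsAsFactors = FALSE)
}

is_growth_curve <- function(x) inherits(x, "growth_curve")

stopifnot_curve <- function(x, arg = "curve") {
  if (!is_growth_curve(x)) {
    stop("`", arg, "` must be a growth_curve object", call. = FALSE)
  }
  invisible(x)
}

#' Clamp OD readings at a floor
#'
#' Replaces every OD below `floor` by `floor`. Blank subtraction can push
#' readings slightly negative; the centroid and area computations require
#' nonnegative OD (the region under the curve must be a genuine area), so
#' negative readings are clamped rather than dropped — dropping would break
#' time-grid alignment across samples. Idempotent.
#'
#' @param curve A [growth_curve()].
#' @param floor Nonnegative scalar; default 0.
#' @return A `growth_curve` with `ods >= floor`. The number of clamped points
#'   is reported via `message()` when positive.
#' @export
clamp_nonnegative <- function(curve, floor = 0) {
  stopifnot_curve(curve)
  if (!is.numeric(floor) || length(floor) != 1L || is.na(floor) || floor < 0) {
    stop("`floor` must be a single nonnegative number", call. = FALSE)
  }
  n_clamped <- sum(curve$ods < floor)
  if (n_clamped > 0L) {
    message(sprintf("clamp_nonnegative: %d of %d OD values in '%s' raised to %g",
                    n_clamped, length(curve$ods), curve$sample_id, floor))
    curve$ods[curve$ods < floor] <- floor
  }
  curve
}

#' Subtract a blank from a growth curve
#'
#' Standard plate-reader preprocessing: removes the media/plate background from
#' a sample's OD readings. The blank may be a single scalar OD (e.g. the mean
#' of blank wells) or a full blank curve on the identical time grid. The result
#' is clamped at 0 so downstream areas stay nonnegative.
#'
#' @param curve A [growth_curve()].
#' @param blank Scalar OD, or a `growth_curve` sharing `curve`'s time grid.
#' @return The blank-corrected, zero-clamped `growth_curve`.
#' @export
subtract_blank <- function(curve, blank) {
  stopifnot_curve(curve)
  if (is_growth_curve(blank)) {
    if (length(blank$times) != length(curve$times) ||
        any(abs(blank$times - curve$times) > 1e-9)) {
      stop("blank curve time grid does not match sample '", curve$sample_id,
           "'", call. = FALSE)
    }
    curve$ods <- curve$ods - blank$ods
  } else if (is.numeric(blank) && length(blank) == 1L && !is.na(blank)) {
    curve$ods <- curve$ods - blank
  } else {
    stop("`blank` must be a scalar OD or a growth_curve", call. = FALSE)
  }
  clamp_nonnegative(curve, floor = 0)
}

#' Put two growth curves on a common time grid
#'
#' The Centroid Index and Virulence Index compare a treated curve against a
#' control over a shared grid. In `strict` mode the grids must already be
#' identical (within 1e-9 h). In `interpolate` mode both curves are linearly
#' interpolated onto the union of their time points restricted to the
#' intersection of their time ranges; linear interpolation is exact for the
#' piecewise-linear curves all metrics here assume, so a curve's centroid is
#' unchanged by refinement of its own grid.
#'
#' @param a,b [growth_curve()] objects with overlapping time ranges.
#' @param mode `"strict"` (default) or `"interpolate"`.
#' @return A list of the two aligned curves, names `a` and `b`.
#' @export
align_time_grids <- function(a, b, mode = c("strict", "interpolate")) {
  stopifnot_curve(a, "a")
  stopifnot_curve(b, "b")
  mode <- match.arg(mode)
  same <- length(a$times) == length(b$times) &&
    all(abs(a$times - b$times) <= 1e-9)
  if (same) {
    return(list(a = a, b = b))
  }
  if (mode == "strict") {
    stop("time grids of '", a$sample_id, "' and '", b$sample_id,
         "' differ; use mode = \"interpolate\" or resample upstream",
         call. = FALSE)
  }
  lo <- max(min(a$times), min(b$times))
  hi <- min(max(a$times), max(b$times))
  if (hi <= lo) {
    stop("curves '", a$sample_id, "' and '", b$sample_id,
         "' have no overlapping time range", call. = FALSE)
  }
  grid <- sort(unique(c(a$times, b$times)))
  grid <- grid[grid >= lo & grid <= hi]
  if (length(grid) < 2L) {
    stop("fewer than 2 common time points between '", a$sample_id, "' and '",
         b$sample_id, "'", call. = FALSE)
  }
  interp <- function(cv) {
    growth_curve(cv$sample_id, grid,
                 stats::approx(cv$times, cv$ods, xout = grid)$y)
  }
  list(a = interp(a), b = interp(b))
}

#' Aggregate replicate growth curves
#'
#' Combines replicate wells into a single condition-level curve by pointwise
#' mean or median. All curves must share an identical time grid. Note the
#' package default elsewhere is metric-first (compute CI/VI per replicate and
#' summarize across replicates); curve-first averaging via this function is the
#' alternative policy.
#'
#' @param curves List of [growth_curve()] objects on one time grid.
#' @param method `"mean"` (default) or `"median"`.
#' @param label Sample id for the aggregated curve; defaults to the first
#'   curve's id.
#' @return A single `growth_curve`.
#' @export
aggregate_replicates <- function(curves, method = c("mean", "median"),
                                 label = NULL) {
  method <- match.arg(method)
  if (!is.list(curves) || length(curves) == 0L) {
    stop("`curves` must be a nonempty list of growth_curve objects",
         call. = FALSE)
  }
  lapply(curves, stopifnot_curve)
  ref <- curves[[1L]]
  for (cv in curves[-1L]) {
    if (length(cv$times) != length(ref$times) ||
        any(abs(cv$times - ref$times) > 1e-9)) {
      stop("replicate '", cv$sample_id, "' is not on the same time grid as '",
           ref$sample_id, "'", call. = FALSE)
    }
  }
  od_mat <- vapply(curves, function(cv) cv$ods, numeric(length(ref$times)))
  od_mat <- matrix(od_mat, nrow = length(ref$times))
  agg <- if (method == "mean") rowMeans(od_mat) else
    apply(od_mat, 1L, stats::median)
  growth_curve(label %||% ref$sample_id, ref$times, agg)
}

`%||%` <- function(x, y) if (is.null(x)) y else x
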