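#' Area under a growth curve
#'
#' Trapezoid-rule integral of OD over time — the sum of the strip areas used
#' by the centroid computation, so [curve_centroid()]`$area` and this function
#' agree to machine precision.
#'
#' @param curve A [growth_curve()] with nonnegative ODs.
#' @return Area in OD·hours.
#' @export
area_under_curve <- function(curve) {
  stopifnot_curve(curve)
  n <- length(curve$times)
  sum(strip_area(curve$times[-n], curve$times[-1L],
                 curve$ods[-n], curve$ods[-1L]))
}

#' Virulence Index of a treated curve against a control
#'
#' The classical area-ratio phage efficiency score:
#' \deqn{\mathrm{VI} = 1 - \frac{\mathrm{AUC}_\mathrm{treated}}
#'   {\mathrm{AUC}_\mathrm{control}}.}
#' VI is 0 when treated and control match, 1 for complete suppression. Because
#' it depends only on the total area, it cannot distinguish two treated curves
#' whose bacterial mass occurs at different times but integrates to the same
#' value — the blind spot the Centroid Index addresses.
#'
#' @param treated,control [growth_curve()] objects on one shared time grid;
#'   the control must have positive area.
#' @return An object of class `vi_result`: list with `vi`, `treated_area`,
#'   `control_area`, `treated_id`, `control_id`.
#' @export
virulence_index <- function(treated, control) {
  stopifnot_curve(treated, "treated")
  stopifnot_curve(control, "control")
  if (length(treated$times) != length(control$times) ||
      any(abs(treated$times - control$times) > 1e-9)) {
    stop("treated and control curves are not on the same time grid; ",
         "use align_time_grids()", call. = FALSE)
  }
  a_t <- area_under_curve(treated)
  a_c <- area_under_curve(control)
  if (a_c <= 0) {
    stop("control curve '", control$sample_id,
         "' has zero area; VI undefined", call. = FALSE)
  }
  structure(list(vi = 1 - a_t / a_c, treated_area = a_t, control_area = a_c,
                 treated_id = treated$sample_id,
                 control_id = control$sample_id),
            class = "vi_result")
}

#' @export
print.vi_result <- function(x, ...) {
  cat(sprintf("<vi_result> VI(%s vs %s) = %.4f\n",
              x$treated_id, x$control_id, x$vi))
  invisible(x)
}

#' Maximum specific growth rate
#'
#' Slides a window of `window` consecutive points along the curve and fits a
#' least-squares line to ln(OD) versus time within each window; the maximum
#' slope over all windows whose ODs all exceed `od_floor` is the maximum
#' specific growth rate (per hour). Pure exponential growth at rate r yields
#' exactly r for any window; a constant curve yields 0. `od_floor` keeps
#' near-blank readings out of the log.
#'
#' @param curve A [growth_curve()].
#' @param window Integer >= 2, points per fit window (default 5).
#' @param od_floor Positive OD threshold (default 0.01).
#' @return List with `mu_max` (per hour), `window_start` and `window_end`
#'   (hours) of the steepest window.
#' @export
mu_max <- function(curve, window = 5L, od_floor = 0.01) {
  stopifnot_curve(curve)
  window <- as.integer(window)
  if (is.na(window) || window < 2L) {
    stop("`window` must be an integer >= 2", call. = FALSE)
  }
  if (!is.numeric(od_floor) || od_floor <= 0) {
    stop("`od_floor` must be > 0", call. = FALSE)
  }
  ok <- curve$ods > od_floor
  n <- length(curve$times)
  best <- -Inf; best_i <- NA_integer_
  for (i in seq_len(n - window + 1L)) {
    idx <- i:(i + window - 1L)
    if (!all(ok[idx])) next
    tt <- curve$times[idx]
    ly <- log(curve$ods[idx])
    slope <- stats::cov(tt, ly) / stats::var(tt)
    if (slope > best) {
      best <- slope
      best_i <- i
    }
  }
  if (!is.finite(best)) {
    stop("mu_max not estimable for '", curve$sample_id, "': fewer than ",
         window, " consecutive points with OD > ", od_floor, call. = FALSE)
  }
  list(mu_max = best,
       window_start = curve$times[best_i],
       window_end = curve$times[best_i + window - 1L])
}

#' Rank treatments by a metric
#'
#' Orders conditions from most to least efficient under a metric. CI and VI
#' rank descending (higher index = stronger suppression); mu_max ranks
#' ascending (a lower growth rate under treatment = stronger suppression).
#' Values within `tie_tol` of each other chain into a tie group sharing the
#' best (smallest) rank in the group; ties are flagged. The default tolerance
#' 5e-3 corresponds to agreement at two printed decimals.
#'
#' @param values Named numeric vector (names are condition labels), or a
#'   data frame with columns `condition` and `value`.
#' @param metric One of `"CI"`, `"VI"`, `"mu_max"`; recorded in the output and
#'   sets the sort direction.
#' @param tie_tol Nonnegative tolerance below which adjacent values tie.
#' @return A data frame of class `ranking_table` with columns
#'   `condition`, `metric`, `value`, `rank`, `tied`.
#' @examples
#' rank_treatments(c(A = 0.8, B = 0.3, C = 0.55), "CI")
#' @export
rank_treatments <- function(values, metric = c("CI", "VI", "mu_max"),
                            tie_tol = 5e-3) {
  metric <- match.arg(metric)
  if (is.data.frame(values)) {
    labels <- as.character(values$condition)
    vals <- as.numeric(values$value)
  } else {
    labels <- names(values)
    vals <- as.numeric(values)
  }
  if (length(vals) == 0L) stop("`values` is empty", call. = FALSE)
  if (is.null(labels) || any(!nzchar(labels))) {
    stop("every value needs a condition label", call. = FALSE)
  }
  decreasing <- metric %in% c("CI", "VI")
  ord <- order(vals, decreasing = decreasing)
  vals <- vals[ord]; labels <- labels[ord]
  k <- length(vals)
  # chain adjacent values closer than tie_tol into shared-rank groups
  group <- integer(k); group[1L] <- 1L
  if (k > 1L) {
    for (i in 2:k) {
      group[i] <- if (abs(vals[i] - vals[i - 1L]) <= tie_tol)
        group[i - 1L] else group[i - 1L] + 1L
    }
  }
  rank <- stats::ave(seq_len(k), group, FUN = min)
  tied <- stats::ave(seq_len(k), group, FUN = length) > 1L
  structure(data.frame(condition = labels, metric = metric, value = vals,
                       rank = as.integer(rank), tied = tied,
                       stringsAsFactors = FALSE),
            class = c("ranking_table", "data.frame"))
}
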