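#' Default assay time grid
#'
#' The package's reference microplate schedule: 0 to 96 hours sampled every
#' 15 minutes — 385 points — matching long phage–host co-incubations with
#' slow-growing hosts where late regrowth is the phenomenon of interest.
#'
#' @param t_end End of incubation in hours (default 96).
#' @param step Sampling interval in hours (default 0.25, i.e. 15 min).
#' @return Numeric time vector.
#' @export
default_time_grid <- function(t_end = 96, step = 0.25) {
  seq(0, t_end, by = step)
}

#' Parameters of a logistic growth curve
#'
#' @param n0 Initial OD, `0 < n0 <= k`.
#' @param k Carrying-capacity OD.
#' @param r Intrinsic growth rate per hour, `> 0`.
#' @return A `logistic_params` list.
#' @export
logistic_params <- function(n0 = 0.1, k = 1.0, r = 0.25) {
  if (!(n0 > 0 && n0 <= k)) stop("need 0 < n0 <= k", call. = FALSE)
  if (!(r > 0)) stop("`r` must be > 0", call. = FALSE)
  structure(list(n0 = n0, k = k, r = r), class = "logistic_params")
}

logistic_od <- function(p, t) {
  p$k / (1 + ((p$k - p$n0) / p$n0) * exp(-p$r * t))
}

#' Sample a logistic growth curve
#'
#' The canonical uninfected-control shape: lag, exponential phase, plateau at
#' the carrying capacity. OD(t) = k / (1 + ((k - n0)/n0) exp(-r t)), so
#' OD(0) = n0 exactly and OD -> k as t grows.
#'
#' @param p A [logistic_params()].
#' @param times Time grid in hours (default [default_time_grid()]).
#' @param sample_id Label for the curve.
#' @return A [growth_curve()].
#' @export
logistic_curve <- function(p, times = default_time_grid(),
                           sample_id = "control") {
  if (!inherits(p, "logistic_params")) {
    stop("`p` must be a logistic_params object", call. = FALSE)
  }
  growth_curve(sample_id, times, logistic_od(p, times))
}

#' Parameters of a lysis-then-regrowth curve
#'
#' Phenomenological description of a phage-treated culture: logistic growth up
#' to the onset of lysis, exponential OD decay while the phage clears the
#' culture, then (optionally) regrowth of resistant cells rising toward a
#' fraction of the original carrying capacity.
#'
#' @param growth A [logistic_params()] for the pre-lysis phase.
#' @param t_lysis Lysis onset (h), `>= 0`.
#' @param decay Lysis decay rate per hour, `> 0`.
#' @param regrow_frac Fraction of `k` the regrowth approaches, in `[0, 1]`;
#'   0 disables regrowth.
#' @param t_regrow Regrowth onset (h), `> t_lysis`.
#' @param regrow_rate Regrowth rate per hour, `> 0`.
#' @return A `lysis_regrowth_params` list.
#' @export
lysis_regrowth_params <- function(growth = logistic_params(),
                                  t_lysis = 8, decay = 0.5,
                                  regrow_frac = 0, t_regrow = 48,
                                  regrow_rate = 0.2) {
  if (!inherits(growth, "logistic_params")) {
    stop("`growth` must be a logistic_params object", call. = FALSE)
  }
  if (!(t_lysis >= 0)) stop("`t_lysis` must be >= 0", call. = FALSE)
  if (!(t_regrow > t_lysis)) stop("need t_regrow > t_lysis", call. = FALSE)
  if (!(decay > 0) || !(regrow_rate > 0)) {
    stop("rates must be > 0", call. = FALSE)
  }
  if (regrow_frac < 0 || regrow_frac > 1) {
    stop("`regrow_frac` must be in [0, 1]", call. = FALSE)
  }
  structure(list(growth = growth, t_lysis = t_lysis, decay = decay,
                 regrow_frac = regrow_frac, t_regrow = t_regrow,
                 regrow_rate = regrow_rate),
            class = "lysis_regrowth_params")
}

#' Sample a lysis-then-regrowth curve
#'
#' Piecewise construction, continuous at both junctions: logistic growth until
#' `t_lysis`; exponential decay toward 0 at rate `decay`; from `t_regrow`, a
#' logistic rise from the decayed OD toward `regrow_frac * k` at
#' `regrow_rate`. If the regrowth target does not exceed the OD at regrowth
#' onset (in particular when `regrow_frac = 0`) the decay simply continues, so
#' the curve is monotone non-increasing after `t_lysis`. All ODs stay within
#' `[0, k]`.
#'
#' @param p A [lysis_regrowth_params()].
#' @param times Time grid in hours.
#' @param sample_id Label for the curve.
#' @return A [growth_curve()].
#' @export
lysis_regrowth_curve <- function(p, times = default_time_grid(),
                                 sample_id = "treated") {
  if (!inherits(p, "lysis_regrowth_params")) {
    stop("`p` must be a lysis_regrowth_params object", call. = FALSE)
  }
  g <- p$growth
  od_at <- function(t) {
    if (t <= p$t_lysis) return(logistic_od(g, t))
    y_l <- logistic_od(g, p$t_lysis)
    decay_od <- function(tt) y_l * exp(-p$decay * (tt - p$t_lysis))
    if (t <= p$t_regrow) return(decay_od(t))
    y_r <- decay_od(p$t_regrow)
    k2 <- p$regrow_frac * g$k
    if (k2 <= y_r || y_r <= 0) return(decay_od(t)) # no regrowth possible
    k2 / (1 + ((k2 - y_r) / y_r) * exp(-p$regrow_rate * (t - p$t_regrow)))
  }
  growth_curve(sample_id, times, vapply(times, od_at, numeric(1L)))
}

#' Area-matched curve pair
#'
#' Returns the base curve together with its time-reflection about the grid
#' midpoint: the reflected curve has identical OD values at mirrored times, so
#' the two members have exactly equal trapezoidal area (bit-identical on a
#' uniform grid) while their bacterial mass sits at opposite ends of the
#' incubation. The area-ratio Virulence Index cannot tell the members apart;
#' the Centroid Index scores whichever member carries its mass later (the one
#' with the larger centroid time) strictly lower.
#'
#' @param base A [growth_curve()].
#' @return List of two curves: `original` (the base) and `reflected` (its
#'   time-reflection, suffix `"_reflected"`).
#' @export
area_matched_pair <- function(base) {
  stopifnot_curve(base, "base")
  t0 <- base$times[1L]
  t1 <- base$times[length(base$times)]
  reflected <- growth_curve(paste0(base$sample_id, "_reflected"),
                            t0 + t1 - rev(base$times), rev(base$ods))
  list(original = base, reflected = reflected)
}

#' Add seeded Gaussian noise to a curve
#'
#' Adds zero-mean Gaussian perturbations of standard deviation `sigma` to the
#' ODs, then clamps at 0 (plate readers do not report negative absorbance).
#' The same seed always reproduces the same curve; the caller's RNG state is
#' left untouched.
#'
#' @param curve A [growth_curve()].
#' @param sigma Noise SD in OD units, `>= 0`.
#' @param seed Integer seed.
#' @return A noisy `growth_curve`.
#' @export
add_noise <- function(curve, sigma, seed) {
  stopifnot_curve(curve)
  if (!is.numeric(sigma) || sigma < 0) stop("`sigma` must be >= 0",
                                            call. = FALSE)
  if (sigma == 0) return(curve)
  old_seed <- if (exists(".Random.seed", envir = globalenv()))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (is.null(old_seed)) {
      if (exists(".Random.seed", envir = globalenv()))
        rm(".Random.seed", envir = globalenv())
    } else {
      assign(".Random.seed", old_seed, envir = globalenv())
    }
  })
  set.seed(as.integer(seed))
  curve$ods <- pmax(0, curve$ods + stats::rnorm(length(curve$ods), 0, sigma))
  curve
}

#' Pair of curves with identical maximum specific growth rate
#'
#' Builds two treated curves sharing an identical exponential segment (rate
#' `r`) up to `divergence_time`; afterwards one plateaus at the OD reached at
#' divergence while the other keeps rising at rate `r/2` until it saturates at
#' four times that OD (capped at `k`). Because every later log-slope is
#' strictly below `r`, both members have the same mu_max to machine precision
#' — yet their centroids, and hence their CI against any common control,
#' differ. A divergence time beyond the grid yields two identical curves.
#'
#' @param r Shared exponential rate per hour, `> 0`.
#' @param divergence_time Time (h) at which the curves part.
#' @param times Time grid in hours.
#' @param n0 OD at time 0 (default 0.05).
#' @param k Upper OD bound (default 1.5).
#' @return List of two curves, `plateau` and `riser`.
#' @export
mu_max_twin_pair <- function(r, divergence_time, times = default_time_grid(),
                             n0 = 0.05, k = 1.5) {
  if (!(r > 0)) stop("`r` must be > 0", call. = FALSE)
  shared <- function(t) pmin(n0 * exp(r * t), k)
  y_d <- shared(divergence_time)
  od_plateau <- shared(pmin(times, divergence_time))
  od_riser <- ifelse(times <= divergence_time,
                     shared(times),
                     pmin(y_d * exp(0.5 * r * (times - divergence_time)),
                          min(4 * y_d, k)))
  list(plateau = growth_curve("twin_plateau", times, od_plateau),
       riser = growth_curve("twin_riser", times, od_riser))
}

#' Random nonnegative piecewise-linear growth curve
#'
#' Draws a handful of random knots (uniform heights up to `max_od`), linearly
#' interpolates them onto `times`, and returns the result as a growth curve.
#' Used throughout the test-suite and validation runs as an arbitrary-shape
#' generator with no model assumptions; uses the current RNG stream, so wrap
#' calls in `set.seed()` for reproducibility.
#'
#' @param times Time grid in hours.
#' @param n_knots Integer >= 2 number of random knots (default 8).
#' @param max_od Maximum knot height (default 1.5).
#' @param sample_id Label for the curve.
#' @return A [growth_curve()].
#' @export
random_piecewise_curve <- function(times = default_time_grid(), n_knots = 8L,
                                   max_od = 1.5, sample_id = "random") {
  n_knots <- as.integer(n_knots)
  if (is.na(n_knots) || n_knots < 2L) {
    stop("`n_knots` must be an integer >= 2", call. = FALSE)
  }
  t0 <- times[1L]; t1 <- times[length(times)]
  knot_t <- c(t0, sort(stats::runif(max(0L, n_knots - 2L), t0, t1)), t1)
  knot_y <- stats::runif(length(knot_t), 0, max_od)
  growth_curve(sample_id, times,
               stats::approx(knot_t, knot_y, xout = times)$y)
}
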