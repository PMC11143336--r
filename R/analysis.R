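#' Build an analysis configuration
#'
#' Collects every knob of the end-to-end workflow (ingestion -> metrics ->
#' ranking -> report files) into one validated object. A configuration can
#' also be read from a YAML file with [read_analysis_config()]; command-line
#' flags override file values in the bundled CLI.
#'
#' @param input Path to the plate-reader table.
#' @param layout `"wide"` or `"long"`.
#' @param control Character vector of control sample id(s); required.
#' @param replicates Named list: condition label -> character vector of member
#'   sample ids. Samples not listed form singleton conditions named after
#'   themselves.
#' @param blank Blank specification: `NULL` (none), a numeric scalar OD, or
#'   the sample id of a blank well (used as a blank curve, then dropped).
#' @param time_unit `"h"` or `"min"`.
#' @param rezero_time Logical; subtract each sample's first time point.
#' @param metrics Character subset of `c("CI", "VI", "mu_max")`, nonempty.
#' @param out Output directory (created if needed).
#' @param plot Logical; also write a curve plot with centroid markers.
#' @param replicate_policy `"metric_first"` (default: compute metrics per
#'   replicate, summarize mean and SD per condition) or `"curve_first"`
#'   (average replicate curves, then compute metrics once per condition).
#' @param seed Integer seed (used by the synthetic-fixture generator).
#' @return An `analysis_config` list.
#' @export
analysis_config <- function(input, layout = "wide", control,
                            replicates = list(), blank = NULL,
                            time_unit = "h", rezero_time = FALSE,
                            metrics = c("CI", "VI", "mu_max"),
                            out = "phagemetrics_out", plot = FALSE,
                            replicate_policy = c("metric_first",
                                                 "curve_first"),
                            seed = 1L) {
  if (missing(control) || length(control) == 0L || !all(nzchar(control))) {
    stop("`control` must name at least one control sample", call. = FALSE)
  }
  metrics <- match.arg(metrics, c("CI", "VI", "mu_max"), several.ok = TRUE)
  if (length(metrics) == 0L) stop("`metrics` must be nonempty", call. = FALSE)
  layout <- match.arg(layout, c("wide", "long"))
  time_unit <- match.arg(time_unit, c("h", "min"))
  replicate_policy <- match.arg(replicate_policy)
  structure(list(input = input, layout = layout,
                 control = as.character(control), replicates = replicates,
                 blank = blank, time_unit = time_unit,
                 rezero_time = isTRUE(rezero_time), metrics = metrics,
                 out = out, plot = isTRUE(plot),
                 replicate_policy = replicate_policy,
                 seed = as.integer(seed)),
            class = "analysis_config")
}

#' Read an analysis configuration from a YAML file
#'
#' @param path YAML file whose keys mirror the arguments of
#'   [analysis_config()].
#' @param overrides Named list of values taking precedence over the file.
#' @return An `analysis_config`.
#' @export
read_analysis_config <- function(path, overrides = list()) {
  vals <- yaml::read_yaml(path)
  vals <- utils::modifyList(vals, overrides[!vapply(overrides, is.null,
                                                    logical(1L))])
  do.call(analysis_config, vals)
}

condition_of <- function(sample_id, replicates) {
  for (cond in names(replicates)) {
    if (sample_id %in% replicates[[cond]]) return(cond)
  }
  sample_id
}

#' Run the full growth-curve analysis workflow
#'
#' Reads the plate table, applies blank subtraction and nonnegativity
#' clamping, aggregates control wells into a single control curve (pointwise
#' mean — the index definitions take one control centroid), computes the
#' requested metrics for every non-control sample against that control, and
#' writes result files to the output directory:
#' \describe{
#'   \item{`metrics_per_sample.csv`}{columns `sample, condition, x_bar, y_bar,
#'     area, CI, VI, mu_max` (unrequested metric columns are `NA`; the control
#'     row has `NA` CI/VI). CI and VI are reported to 4 decimals.}
#'   \item{`condition_summary.csv`}{per condition and metric: mean, SD, n over
#'     replicates (metric-first policy) or the single curve-first value.}
#'   \item{`ranking_<metric>.csv`}{one [rank_treatments()] table per metric,
#'     on the condition-level values.}
#'   \item{`curves.pdf`}{optional plot of all curves with diamond centroid
#'     markers (when `plot = TRUE`); never affects the tables.}
#' }
#'
#' @param config An [analysis_config()].
#' @return Invisibly, a list with the per-sample metric data frame
#'   (`per_sample`), the condition summary (`summary`), the ranking tables
#'   (`rankings`), and the paths written (`files`).
#' @export
run_analysis <- function(config) {
  if (!inherits(config, "analysis_config")) {
    stop("`config` must be an analysis_config", call. = FALSE)
  }
  exp0 <- read_plate_table(config$input, layout = config$layout,
                           time_unit = config$time_unit,
                           rezero_time = config$rezero_time)
  curves <- exp0$curves
  # blank handling: scalar, or a dedicated blank well removed from analysis
  if (!is.null(config$blank)) {
    if (is.character(config$blank)) {
      if (!config$blank %in% names(curves)) {
        stop("blank sample '", config$blank, "' not found in input",
             call. = FALSE)
      }
      blank <- curves[[config$blank]]
      curves[[config$blank]] <- NULL
    } else {
      blank <- as.numeric(config$blank)
    }
    curves <- lapply(curves, subtract_blank, blank = blank)
  } else {
    curves <- lapply(curves, clamp_nonnegative)
  }
  missing_ctrl <- setdiff(config$control, names(curves))
  if (length(missing_ctrl) > 0L) {
    stop("control sample(s) not found: ",
         paste(missing_ctrl, collapse = ", "), call. = FALSE)
  }
  control <- aggregate_replicates(curves[config$control], method = "mean",
                                  label = "control")
  treated_ids <- setdiff(names(curves), config$control)

  one_row <- function(cv, condition) {
    cen <- curve_centroid(cv)
    row <- data.frame(sample = cv$sample_id, condition = condition,
                      x_bar = cen$x_bar, y_bar = cen$y_bar, area = cen$area,
                      CI = NA_real_, VI = NA_real_, mu_max = NA_real_,
                      stringsAsFactors = FALSE)
    is_ctrl <- cv$sample_id %in% c(config$control, "control")
    if ("CI" %in% config$metrics && !is_ctrl) {
      row$CI <- round(centroid_index(cv, control)$ci, 4L)
    }
    if ("VI" %in% config$metrics && !is_ctrl) {
      row$VI <- round(virulence_index(cv, control)$vi, 4L)
    }
    if ("mu_max" %in% config$metrics) {
      row$mu_max <- tryCatch(mu_max(cv)$mu_max, error = function(e) {
        message("mu_max not estimable for '", cv$sample_id, "'")
        NA_real_
      })
    }
    row
  }

  if (config$replicate_policy == "curve_first") {
    cond_of <- vapply(treated_ids, condition_of, character(1L),
                      replicates = config$replicates)
    rows <- lapply(unique(cond_of), function(cond) {
      members <- treated_ids[cond_of == cond]
      cv <- aggregate_replicates(curves[members], method = "mean",
                                 label = cond)
      one_row(cv, cond)
    })
  } else {
    rows <- lapply(treated_ids, function(id) {
      one_row(curves[[id]], condition_of(id, config$replicates))
    })
  }
  per_sample <- do.call(rbind, c(list(one_row(control, "control")), rows))
  rownames(per_sample) <- NULL

  long <- do.call(rbind, lapply(config$metrics, function(m) {
    data.frame(condition = per_sample$condition, metric = m,
               value = per_sample[[m]], stringsAsFactors = FALSE)
  }))
  long <- long[!is.na(long$value) & long$condition != "control", ]
  agg <- function(f) stats::aggregate(value ~ condition + metric, long, f)
  summary_df <- agg(mean)
  names(summary_df)[3L] <- "mean"
  summary_df$sd <- agg(function(v) if (length(v) > 1L) stats::sd(v) else NA_real_)$value
  summary_df$n <- agg(length)$value
  summary_df <- summary_df[order(summary_df$metric, summary_df$condition), ]

  dir.create(config$out, recursive = TRUE, showWarnings = FALSE)
  files <- character()
  p <- file.path(config$out, "metrics_per_sample.csv")
  utils::write.csv(per_sample, p, row.names = FALSE)
  files <- c(files, p)
  p <- file.path(config$out, "condition_summary.csv")
  utils::write.csv(summary_df, p, row.names = FALSE)
  files <- c(files, p)

  rankings <- list()
  for (m in config$metrics) {
    vals <- summary_df[summary_df$metric == m, ]
    if (nrow(vals) == 0L) next
    rk <- rank_treatments(stats::setNames(vals$mean, vals$condition),
                          metric = m)
    rankings[[m]] <- rk
    p <- file.path(config$out, paste0("ranking_", m, ".csv"))
    utils::write.csv(rk, p, row.names = FALSE)
    files <- c(files, p)
  }

  if (config$plot) {
    p <- file.path(config$out, "curves.pdf")
    plot_curves(c(list(control), curves[treated_ids]), file = p)
    files <- c(files, p)
  }
  invisible(list(per_sample = per_sample, summary = summary_df,
                 rankings = rankings, files = files))
}

#' Plot growth curves with centroid markers
#'
#' Draws every curve as a line and overlays each curve's centroid as a
#' diamond of the matching colour — the visual summary of where each
#' culture's bacterial mass sits in time and density.
#'
#' @param curves List of [growth_curve()] objects.
#' @param file Optional output file (pdf/png by extension); `NULL` returns the
#'   plot object without writing.
#' @return The ggplot object, invisibly.
#' @export
plot_curves <- function(curves, file = NULL) {
  lapply(curves, stopifnot_curve)
  long <- do.call(rbind, lapply(curves, as.data.frame))
  cens <- do.call(rbind, lapply(curves, function(cv) {
    cen <- curve_centroid(cv)
    if (cen$area == 0) return(NULL)
    data.frame(sample = cv$sample_id, x_bar = cen$x_bar, y_bar = cen$y_bar)
  }))
  gp <- ggplot2::ggplot(long, ggplot2::aes(x = time, y = od,
                                           colour = sample)) +
    ggplot2::geom_line() +
    ggplot2::labs(x = "Time (h)", y = "OD", colour = "Sample") +
    ggplot2::theme_minimal()
  if (!is.null(cens)) {
    gp <- gp + ggplot2::geom_point(
      data = cens,
      ggplot2::aes(x = x_bar, y = y_bar, colour = sample),
      shape = 18, size = 4)
  }
  if (!is.null(file)) {
    ggplot2::ggsave(file, gp, width = 8, height = 5)
  }
  invisible(gp)
}

#' Generate a synthetic plate fixture
#'
#' Writes a wide-layout CSV of one logistic control plus several
#' lysis-then-regrowth treated conditions with mild measurement noise, on the
#' default 0–96 h / 15-min grid. Deterministic for a given seed, so repeated
#' calls produce byte-identical files. The conditions span the behaviours the
#' metrics must separate: strong lysis without regrowth, lysis with late
#' regrowth, lysis with early full regrowth, and a weak phage.
#'
#' @param path Output CSV path.
#' @param seed Integer seed for the noise draws.
#' @param times Time grid in hours.
#' @param sigma Noise SD in OD units (default 0.005).
#' @return `path`, invisibly.
#' @export
generate_fixtures <- function(path, seed = 1L, times = default_time_grid(),
                              sigma = 0.005) {
  seed <- as.integer(seed)
  ctrl_p <- logistic_params(n0 = 0.1, k = 1.0, r = 0.25)
  specs <- list(
    control = logistic_curve(ctrl_p, times, "control"),
    lysis_clean = lysis_regrowth_curve(
      lysis_regrowth_params(ctrl_p, t_lysis = 6, decay = 0.2,
                            regrow_frac = 0),
      times, "lysis_clean"),
    late_regrowth = lysis_regrowth_curve(
      lysis_regrowth_params(ctrl_p, t_lysis = 6, decay = 0.2,
                            regrow_frac = 0.8, t_regrow = 60,
                            regrow_rate = 0.8),
      times, "late_regrowth"),
    early_regrowth = lysis_regrowth_curve(
      lysis_regrowth_params(ctrl_p, t_lysis = 6, decay = 0.2,
                            regrow_frac = 1, t_regrow = 20,
                            regrow_rate = 0.4),
      times, "early_regrowth"),
    weak_phage = lysis_regrowth_curve(
      lysis_regrowth_params(logistic_params(n0 = 0.1, k = 0.8, r = 0.2),
                            t_lysis = 30, decay = 0.05, regrow_frac = 0),
      times, "weak_phage"))
  noisy <- Map(function(cv, i) add_noise(cv, sigma, seed + i),
               specs, seq_along(specs) - 1L)
  experiment <- plate_experiment(noisy, control_ids = "control")
  write_plate_table(experiment, path, layout = "wide")
}
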