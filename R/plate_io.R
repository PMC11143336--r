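#' Construct a plate experiment
#'
#' A `plate_experiment` bundles the labelled growth curves of one microplate
#' assay together with the designation of the uninfected control sample(s) and
#' optional replicate groupings (condition label -> member sample ids).
#'
#' @param curves Named list of [growth_curve()] objects (names must equal the
#'   curves' `sample_id`s; unnamed lists are named automatically).
#' @param control_ids Character vector of sample ids that are uninfected
#'   controls. May be empty at construction and set later.
#' @param replicate_groups Named list mapping a condition label to a character
#'   vector of member sample ids.
#' @param metadata Named list of free-form annotations (MOI, cocktail, ...).
#' @return An object of class `plate_experiment`.
#' @export
plate_experiment <- function(curves, control_ids = character(),
                             replicate_groups = list(), metadata = list()) {
  if (!is.list(curves) || length(curves) == 0L) {
    stop("`curves` must be a nonempty list of growth_curve objects",
         call. = FALSE)
  }
  lapply(curves, stopifnot_curve)
  ids <- vapply(curves, function(cv) cv$sample_id, character(1L))
  if (anyDuplicated(ids)) {
    stop("duplicate sample ids: ",
         paste(unique(ids[duplicated(ids)]), collapse = ", "), call. = FALSE)
  }
  names(curves) <- ids
  control_ids <- as.character(control_ids)
  missing_ctrl <- setdiff(control_ids, ids)
  if (length(missing_ctrl) > 0L) {
    stop("control id(s) not found among samples: ",
         paste(missing_ctrl, collapse = ", "), call. = FALSE)
  }
  for (grp in names(replicate_groups)) {
    missing_rep <- setdiff(replicate_groups[[grp]], ids)
    if (length(missing_rep) > 0L) {
      stop("replicate group '", grp, "' references unknown sample(s): ",
           paste(missing_rep, collapse = ", "), call. = FALSE)
    }
  }
  structure(list(curves = curves, control_ids = control_ids,
                 replicate_groups = replicate_groups, metadata = metadata),
            class = "plate_experiment")
}

#' @export
print.plate_experiment <- function(x, ...) {
  cat(sprintf("<plate_experiment> %d samples (%s), %d control(s), %d replicate group(s)\n",
              length(x$curves),
              paste(utils::head(names(x$curves), 6L), collapse = ", "),
              length(x$control_ids), length(x$replicate_groups)))
  invisible(x)
}

detect_sep <- function(path) {
  header <- readLines(path, n = 1L)
  if (lengths(regmatches(header, gregexpr("\t", header))) >
      lengths(regmatches(header, gregexpr(",", header)))) "\t" else ","
}

#' Read a plate-reader OD table
#'
#' Parses a delimited-text plate-reader export into a [plate_experiment()].
#' Two layouts are supported: `wide` (one time column plus one OD column per
#' sample) and `long` (one row per time/sample/OD triple). Times are converted
#' to hours; rows are sorted by time per sample; duplicated (sample, time)
#' rows are an error.
#'
#' @param path Path to a UTF-8 comma- or tab-delimited text file with header.
#' @param layout `"wide"` or `"long"`.
#' @param column_map Named list identifying columns. For wide layout:
#'   `time` (the time column name; every other column is a sample). For long
#'   layout: `time`, `sample`, `od`. Defaults: `list(time = "time",
#'   sample = "sample", od = "od")`.
#' @param sep Field separator; `NULL` (default) autodetects comma vs tab from
#'   the header line.
#' @param time_unit `"h"` (default) or `"min"`; minute times are divided by 60.
#' @param rezero_time If `TRUE`, subtract the first time point of each sample
#'   from its grid so it starts at 0. Default `FALSE`: the centroid time
#'   coordinate depends on the time origin, so the origin in the file is
#'   preserved unless explicitly rezeroed.
#' @param control_ids,replicate_groups,metadata Passed to
#'   [plate_experiment()].
#' @return A `plate_experiment`.
#' @export
read_plate_table <- function(path, layout = c("wide", "long"),
                             column_map = list(), sep = NULL,
                             time_unit = c("h", "min"), rezero_time = FALSE,
                             control_ids = character(),
                             replicate_groups = list(), metadata = list()) {
  layout <- match.arg(layout)
  time_unit <- match.arg(time_unit)
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  sep <- sep %||% detect_sep(path)
  cmap <- utils::modifyList(list(time = "time", sample = "sample", od = "od"),
                            column_map)
  df <- utils::read.table(path, header = TRUE, sep = sep,
                          stringsAsFactors = FALSE, check.names = FALSE,
                          colClasses = "character", encoding = "UTF-8")
  as_num <- function(x, what) {
    out <- suppressWarnings(as.numeric(x))
    bad <- which(is.na(out) & !is.na(x) & nzchar(trimws(x)))
    if (length(bad) > 0L) {
      stop("non-numeric ", what, " value '", x[bad[1L]], "' at data row ",
           bad[1L], call. = FALSE)
    }
    out
  }
  if (layout == "wide") {
    if (!cmap$time %in% names(df)) {
      stop("wide layout: time column '", cmap$time, "' not found; columns are: ",
           paste(names(df), collapse = ", "), call. = FALSE)
    }
    times <- as_num(df[[cmap$time]], "time")
    if (anyNA(times)) stop("missing time value in column '", cmap$time, "'",
                           call. = FALSE)
    sample_cols <- setdiff(names(df), cmap$time)
    if (length(sample_cols) == 0L) {
      stop("wide layout: no sample columns beside '", cmap$time, "'",
           call. = FALSE)
    }
    if (anyDuplicated(times)) {
      stop("duplicated time value ", times[duplicated(times)][1L],
           " in wide table", call. = FALSE)
    }
    ord <- order(times)
    long <- do.call(rbind, lapply(sample_cols, function(sc) {
      data.frame(sample = sc, time = times[ord],
                 od = as_num(df[[sc]], paste0("OD (column '", sc, "')"))[ord],
                 stringsAsFactors = FALSE)
    }))
  } else {
    need <- c(cmap$time, cmap$sample, cmap$od)
    missing_cols <- setdiff(need, names(df))
    if (length(missing_cols) > 0L) {
      stop("long layout: missing column(s): ",
           paste(missing_cols, collapse = ", "), call. = FALSE)
    }
    long <- data.frame(sample = df[[cmap$sample]],
                       time = as_num(df[[cmap$time]], "time"),
                       od = as_num(df[[cmap$od]], "OD"),
                       stringsAsFactors = FALSE)
    if (anyDuplicated(long[c("sample", "time")])) {
      dup <- long[duplicated(long[c("sample", "time")]), ][1L, ]
      stop("duplicated (sample, time) row: ", dup$sample, " @ ", dup$time,
           call. = FALSE)
    }
  }
  long <- long[stats::complete.cases(long), , drop = FALSE]
  if (time_unit == "min") long$time <- long$time / 60
  curves <- lapply(split(long, long$sample), function(d) {
    if (nrow(d) < 2L) {
      stop("sample '", d$sample[1L], "' has fewer than 2 time points",
           call. = FALSE)
    }
    d <- d[order(d$time), ]
    tt <- d$time
    if (rezero_time) tt <- tt - tt[1L]
    growth_curve(d$sample[1L], tt, d$od)
  })
  # preserve file column order for wide layout
  if (layout == "wide") curves <- curves[sample_cols]
  plate_experiment(curves, control_ids = control_ids,
                   replicate_groups = replicate_groups, metadata = metadata)
}

#' Write a plate experiment as a delimited table
#'
#' Writes either the long layout (`sample,time,od`) or, when all curves share
#' one time grid, the wide layout (one `time` column plus one column per
#' sample). Values are printed with enough digits that
#' [read_plate_table()] round-trips the experiment bit-exactly.
#'
#' @param experiment A [plate_experiment()].
#' @param path Output file path.
#' @param layout `"long"` (default) or `"wide"`.
#' @return `path`, invisibly.
#' @export
write_plate_table <- function(experiment, path, layout = c("long", "wide")) {
  if (!inherits(experiment, "plate_experiment")) {
    stop("`experiment` must be a plate_experiment", call. = FALSE)
  }
  layout <- match.arg(layout)
  fmt <- function(x) formatC(x, digits = 17, format = "g")
  if (layout == "long") {
    long <- do.call(rbind, lapply(experiment$curves, as.data.frame))
    out <- data.frame(sample = long$sample, time = fmt(long$time),
                      od = fmt(long$od))
  } else {
    ref <- experiment$curves[[1L]]
    for (cv in experiment$curves) {
      if (length(cv$times) != length(ref$times) ||
          any(cv$times != ref$times)) {
        stop("wide layout requires one shared time grid", call. = FALSE)
      }
    }
    out <- data.frame(time = fmt(ref$times))
    for (cv in experiment$curves) out[[cv$sample_id]] <- fmt(cv$ods)
  }
  utils::write.csv(out, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}
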