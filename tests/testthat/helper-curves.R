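# Shared fixtures: small analytic curves and seeded random generators.

flat_curve <- function(od = 0.4, times = 0:3, id = "flat") {
  growth_curve(id, times, rep(od, length(times)))
}

# a random nonnegative piecewise-linear treated/control pair on `times`
random_pair <- function(times = default_time_grid()) {
  list(treated = random_piecewise_curve(times, sample_id = "treated"),
       control = random_piecewise_curve(times, sample_id = "control"))
}

# closed-form trapezoid centroid height, used as the algebraic cross-check of
# the strip formula: (y0^2 + y0*y1 + y1^2) / (3 (y0 + y1))
trapezoid_ybar_symmetric <- function(y0, y1) {
  (y0^2 + y0 * y1 + y1^2) / (3 * (y0 + y1))
}

write_wide_fixture <- function(path = tempfile(fileext = ".csv")) {
  writeLines(c("time,ctrl,phageA",
               "0,0.1,0.1",
               "1,0.4,0.2",
               "2,0.8,0.15"), path)
  path
}

write_long_fixture <- function(path = tempfile(fileext = ".csv")) {
  writeLines(c("sample,time,od",
               "s1,0,0.1", "s1,1,0.3", "s1,2,0.6", "s1,3,0.7",
               "s2,0,0.1", "s2,1,0.15", "s2,2,0.2", "s2,3,0.1"), path)
  path
}

# Rscript invocation of the installed CLI, isolated library paths included
run_cli <- function(args) {
  script <- system.file("cli", "phagemetrics.R", package = "phagemetrics")
  stopifnot(nzchar(script))
  rscript <- file.path(R.home("bin"), "Rscript")
  out <- suppressWarnings(system2(
    rscript, c(script, args), stdout = TRUE, stderr = TRUE,
    env = paste0("R_LIBS=", paste(.libPaths(),
                                  collapse = .Platform$path.sep))))
  status <- attr(out, "status")
  if (is.null(status)) status <- 0L
  list(status = status, output = paste(out, collapse = "\n"))
}
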