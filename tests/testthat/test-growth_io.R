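test_that("wide and long plate tables parse into per-sample curves", {
  exp_w <- read_plate_table(write_wide_fixture(), layout = "wide")
  expect_s3_class(exp_w, "plate_experiment")
  expect_named(exp_w$curves, c("ctrl", "phageA"))
  expect_length(exp_w$curves$ctrl$times, 3L)
  expect_equal(exp_w$curves$phageA$ods, c(0.1, 0.2, 0.15))

  exp_l <- read_plate_table(write_long_fixture(), layout = "long")
  expect_named(exp_l$curves, c("s1", "s2"))
  expect_length(exp_l$curves$s1$times, 4L)
  expect_equal(exp_l$curves$s2$ods, c(0.1, 0.15, 0.2, 0.1))
})

test_that("parsing rejects malformed tables with informative errors", {
  dup <- tempfile(fileext = ".csv")
  writeLines(c("time,a,b", "0,0.1,0.1", "1,0.2,0.2", "1,0.3,0.3"), dup)
  expect_error(read_plate_table(dup, "wide"), "duplicated time")

  nonnum <- tempfile(fileext = ".csv")
  writeLines(c("time,a", "0,0.1", "1,oops"), nonnum)
  expect_error(read_plate_table(nonnum, "wide"), "non-numeric")

  short <- tempfile(fileext = ".csv")
  writeLines(c("sample,time,od", "s1,0,0.1"), short)
  expect_error(read_plate_table(short, "long"), "fewer than 2")

  missing_col <- tempfile(fileext = ".csv")
  writeLines(c("when,a", "0,0.1", "1,0.2"), missing_col)
  expect_error(read_plate_table(missing_col, "wide"), "time column")
  expect_error(read_plate_table(missing_col, "long"), "missing column")
})

test_that("minute times convert to hours and rezeroing shifts the origin", {
  p <- tempfile(fileext = ".csv")
  writeLines(c("time,a", "60,0.1", "120,0.2", "180,0.3"), p)
  exp_min <- read_plate_table(p, "wide", time_unit = "min")
  expect_equal(exp_min$curves$a$times, c(1, 2, 3))
  exp_rz <- read_plate_table(p, "wide", time_unit = "min", rezero_time = TRUE)
  expect_equal(exp_rz$curves$a$times, c(0, 1, 2))
})

test_that("write/read round-trips an experiment bit-exactly in both layouts", {
  set.seed(42)
  times <- default_time_grid(t_end = 12, step = 0.25)
  curves <- list(random_piecewise_curve(times, sample_id = "c1"),
                 random_piecewise_curve(times, sample_id = "c2"),
                 random_piecewise_curve(times, sample_id = "c3"))
  experiment <- plate_experiment(curves, control_ids = "c1")
  for (layout in c("long", "wide")) {
    p <- tempfile(fileext = ".csv")
    write_plate_table(experiment, p, layout = layout)
    back <- read_plate_table(p, layout = layout)
    for (id in names(experiment$curves)) {
      expect_identical(back$curves[[id]]$times, experiment$curves[[id]]$times,
                       label = paste(layout, id, "times"))
      expect_identical(back$curves[[id]]$ods, experiment$curves[[id]]$ods,
                       label = paste(layout, id, "ods"))
    }
  }
})

test_that("blank subtraction handles scalars, curves, and grid mismatches", {
  cv <- growth_curve("s", c(0, 1), c(0.30, 0.50))
  expect_equal(subtract_blank(cv, 0.10)$ods, c(0.20, 0.40))
  low <- growth_curve("s", c(0, 1), c(0.05, 0.50))
  expect_equal(suppressMessages(subtract_blank(low, 0.10))$ods, c(0.00, 0.40))
  blank_cv <- growth_curve("blank", c(0, 1), c(0.1, 0.1))
  expect_equal(subtract_blank(cv, blank_cv)$ods, c(0.20, 0.40))
  off_grid <- growth_curve("blank", c(0, 2), c(0.1, 0.1))
  expect_error(subtract_blank(cv, off_grid), "grid")
})

test_that("clamping is idempotent and respects a nonzero floor", {
  cv <- growth_curve("s", 0:2, c(-0.01, 0.2, 0.5))
  once <- suppressMessages(clamp_nonnegative(cv))
  expect_equal(once$ods, c(0, 0.2, 0.5))
  expect_identical(clamp_nonnegative(once)$ods, once$ods)
  floor_cv <- growth_curve("s", 0:2, c(0, 0.0005, 0.2))
  expect_equal(suppressMessages(clamp_nonnegative(floor_cv, 0.001))$ods,
               c(0.001, 0.001, 0.2))
  untouched <- growth_curve("s", 0:2, c(0.1, 0.2, 0.3))
  expect_identical(clamp_nonnegative(untouched)$ods, untouched$ods)
})

test_that("time-grid alignment interpolates exactly and flags disjoint ranges", {
  a <- growth_curve("a", c(0, 1, 2), c(0.1, 0.5, 0.3))
  b <- growth_curve("b", c(0, 0.5, 1, 2), c(0.2, 0.2, 0.4, 0.6))
  expect_identical(align_time_grids(a, a, "strict")$a$ods, a$ods)
  expect_error(align_time_grids(a, b, "strict"), "differ")
  al <- align_time_grids(a, b, "interpolate")
  expect_equal(al$a$times, c(0, 0.5, 1, 2))
  expect_equal(al$b$times, c(0, 0.5, 1, 2))
  # linear interpolation is exact for piecewise-linear curves: same centroid
  cen_before <- curve_centroid(a)
  cen_after <- curve_centroid(al$a)
  expect_equal(cen_after$x_bar, cen_before$x_bar, tolerance = 1e-12)
  expect_equal(cen_after$area, cen_before$area, tolerance = 1e-12)
  disjoint <- growth_curve("d", c(5, 6), c(0.1, 0.1))
  expect_error(align_time_grids(a, disjoint, "interpolate"), "overlap")
})

test_that("replicate aggregation averages pointwise and commutes with blanks", {
  c1 <- growth_curve("r1", c(0, 1), c(0.1, 0.3))
  c2 <- growth_curve("r2", c(0, 1), c(0.3, 0.5))
  expect_equal(aggregate_replicates(list(c1, c2), "mean")$ods, c(0.2, 0.4))
  expect_equal(aggregate_replicates(list(c1), "mean")$ods, c1$ods)
  c3 <- growth_curve("r3", c(0, 1), c(0.9, 0.9))
  expect_equal(aggregate_replicates(list(c1, c2, c3), "median")$ods[1L], 0.3)
  off <- growth_curve("r4", c(0, 2), c(0.1, 0.1))
  expect_error(aggregate_replicates(list(c1, off)), "time grid")
  # mean aggregation commutes with a shared scalar blank (no clamping active)
  agg_then_blank <- subtract_blank(aggregate_replicates(list(c1, c2)), 0.05)
  blank_then_agg <- aggregate_replicates(
    list(subtract_blank(c1, 0.05), subtract_blank(c2, 0.05)))
  expect_equal(agg_then_blank$ods, blank_then_agg$ods)
})

test_that("plate_experiment validates control and replicate membership", {
  cv <- flat_curve()
  expect_error(plate_experiment(list(cv), control_ids = "nope"), "control")
  expect_error(plate_experiment(list(cv), replicate_groups = list(g = "x")),
               "unknown sample")
  expect_error(plate_experiment(list(cv, cv)), "duplicate")
})
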