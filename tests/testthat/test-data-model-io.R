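test_that("screening metadata survives a write/read round trip field-for-field", {
  tz <- "Etc/GMT-1"
  scr <- data.frame(
    screening_id = c("S001", "S002", "S003"),
    film_title = c("A", "B", "A"),
    age_class = factor(c("0", "12", "0"), levels = c("0", "6", "12", "16")),
    room_id = c("room1", "room2", "room1"),
    start_time = as.POSIXct(c("2013-12-01 10:00:00", "2013-12-01 13:00:00",
                              "2013-12-02 10:00:00"), tz = tz),
    end_time = as.POSIXct(c("2013-12-01 11:40:00", "2013-12-01 15:05:00",
                            "2013-12-02 11:40:00"), tz = tz),
    viewer_count = c(40L, 75L, 12L),
    under12_count = c(10L, NA, 0L),
    excluded = c(FALSE, TRUE, FALSE),
    stringsAsFactors = FALSE)
  path <- withr::local_tempfile(fileext = ".tsv")
  write_screenings(scr, path)
  back <- read_screenings(path)
  expect_equal(back, scr)
})

test_that("metadata reader reports missing columns and bad rows precisely", {
  path <- withr::local_tempfile(fileext = ".tsv")
  writeLines(c("film_title\tage_class\tstart_time\tend_time",
               "A\t0\t2013-12-01 10:00:00\t2013-12-01 11:00:00"), path)
  expect_error(read_screenings(path), "viewer_count")

  writeLines(c("film_title\tage_class\tstart_time\tend_time\tviewer_count",
               "A\t0\t2013-12-01 10:00:00\t2013-12-01 11:00:00\t30",
               "B\t6\t2013-12-01 12:00:00\t2013-12-01 13:00:00\tabc"), path)
  expect_error(read_screenings(path), "row 2.*abc")

  writeLines(c("film_title\tage_class\tstart_time\tend_time\tviewer_count",
               "A\t0\tnot-a-time\t2013-12-01 11:00:00\t30"), path)
  expect_error(read_screenings(path), "row 1.*timestamp")

  writeLines(c("film_title\tage_class\tstart_time\tend_time\tviewer_count",
               "A\t3\t2013-12-01 10:00:00\t2013-12-01 11:00:00\t30"), path)
  expect_error(read_screenings(path), "age class")
})

test_that("compound tables parse one series per column with units and exact values", {
  tz <- "Etc/GMT-1"
  time <- as.POSIXct("2013-12-01 10:00:00", tz = tz) + 30 * 0:3
  sl <- list(
    "m69.0699" = compound_series(time, c(1.5, 2.25, 3.125, 2.0),
                                 compound_id = "m69.0699"),
    "CO2" = compound_series(time, c(400, 410, 420, 415),
                            compound_id = "CO2", unit = "ppm"))
  path <- withr::local_tempfile(fileext = ".tsv")
  write_compound_table(sl, path)
  back <- read_compound_table(path)
  expect_named(back, c("m69.0699", "CO2"))
  expect_equal(length(back$`m69.0699`$value), 4L)
  expect_equal(back$`m69.0699`$value, sl$`m69.0699`$value, tolerance = 1e-9)
  expect_equal(back$`m69.0699`$unit, "ppb")
  expect_equal(back$CO2$unit, "ppm")
})

test_that("a wide compound table yields one series per compound column", {
  tz <- "Etc/GMT-1"
  time <- as.POSIXct("2013-12-01 10:00:00", tz = tz) + 30 * 0:4
  sl <- lapply(1:66, function(i)
    compound_series(time, seq(0, 2, length.out = 5) + i,
                    compound_id = sprintf("m%03d", i)))
  names(sl) <- sprintf("m%03d", 1:66)
  path <- withr::local_tempfile(fileext = ".tsv")
  write_compound_table(sl, path)
  expect_length(read_compound_table(path), 66L)
})

test_that("non-monotone or duplicated timestamps are format errors", {
  path <- withr::local_tempfile(fileext = ".tsv")
  writeLines(c("timestamp\tm69.0699",
               "2013-12-01 10:00:00\t1",
               "2013-12-01 10:00:30\t2",
               "2013-12-01 10:00:30\t3"), path)
  expect_error(read_compound_table(path), "duplicated timestamp.*10:00:30")
  writeLines("timestamp\tm69.0699", path)
  expect_error(read_compound_table(path), "empty")
})

test_that("screening windows are closed intervals on the unchanged grid", {
  time <- grid_s(24 * 60)   # 24 h at 30 s
  s <- compound_series(time, sin(time / 600), compound_id = "x")
  full <- slice_screening(s, start = time[1], end = time[length(time)])
  expect_equal(full$value, s$value)

  win <- slice_screening(s, start = 3600, end = 3600 + 90 * 60)
  expect_length(win$value, 181L)  # 90 min inclusive of both boundary samples
  expect_equal(win$step_s, 30)

  expect_error(slice_screening(s, start = 1e7, end = 1e7 + 100), "overlap")
})

test_that("short NA gaps are interpolated, long gaps flag exclusion", {
  v <- sin(seq(0, 5, length.out = 50))
  v[10:12] <- NA
  s <- compound_series(grid_s(24.5), v)
  f <- fill_gaps(s, max_gap_steps = 3L)
  expect_false(attr(f, "excluded"))
  expect_equal(attr(f, "n_filled"), 3L)
  expect_false(anyNA(f$value))

  v[20:24] <- NA
  s2 <- compound_series(grid_s(24.5), v)
  f2 <- fill_gaps(s2, max_gap_steps = 3L)
  expect_true(attr(f2, "excluded"))
})
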