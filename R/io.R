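#' Dialect of the tab-separated study files
#'
#' Column names, separator, timestamp format and unit conventions of the
#' metadata ("ticket sales") and compound tables. The defaults match the
#' layout this package writes; all names are configurable because the
#' measurement campaign's own files may use different headers.
#'
#' @param sep field separator.
#' @param col_film,col_class,col_room,col_start,col_end,col_viewers
#'   metadata column names.
#' @param col_under12 optional column with the count of viewers under 12
#'   (known from discounted ticket sales); may be absent from a file.
#' @param col_excluded optional logical column flagging screenings
#'   discarded by quality control.
#' @param col_timestamp name of the compound table's timestamp column.
#' @param co2_id compound column measured in ppm rather than ppb.
#' @param time_format timestamp format string.
#' @param tz timezone of the naive local timestamps (UTC+1 for the
#'   cinema data; no timezone math is performed).
#' @return a named list of dialect settings.
#' @export
io_dialect <- function(sep = "\t",
                       col_film = "film_title", col_class = "age_class",
                       col_room = "room_id", col_start = "start_time",
                       col_end = "end_time", col_viewers = "viewer_count",
                       col_under12 = "under12_count",
                       col_excluded = "excluded",
                       col_timestamp = "timestamp",
                       co2_id = "CO2",
                       time_format = "%Y-%m-%d %H:%M:%S",
                       tz = "Etc/GMT-1") {
  list(sep = sep, col_film = col_film, col_class = col_class,
       col_room = col_room, col_start = col_start, col_end = col_end,
       col_viewers = col_viewers, col_under12 = col_under12,
       col_excluded = col_excluded, col_timestamp = col_timestamp,
       co2_id = co2_id, time_format = time_format, tz = tz)
}

age_classes <- function() c("0", "6", "12", "16")

parse_dialect_time <- function(x, dialect) {
  as.POSIXct(as.character(x), format = dialect$time_format, tz = dialect$tz)
}

#' Read a screening-metadata table
#'
#' Reads the tab-separated ticket-sales metadata: one row per screening
#' with film title, FSK age class, screening window, and audience size.
#'
#' @param path path to the file.
#' @param dialect an [io_dialect()].
#' @param exclusions character vector of `screening_id`s to flag as
#'   excluded (manual QC list), in addition to any excluded column.
#' @return a data frame of screening records with columns
#'   `screening_id`, `film_title`, `age_class` (factor with levels
#'   0/6/12/16), `room_id`, `start_time`, `end_time`, `viewer_count`,
#'   `under12_count` (NA when unknown) and `excluded`.
#' @export
read_screenings <- function(path, dialect = io_dialect(), exclusions = NULL) {
  if (!file.exists(path)) stop(sprintf("metadata file not found: %s", path))
  raw <- utils::read.delim(path, sep = dialect$sep, header = TRUE,
                           colClasses = "character", check.names = FALSE,
                           stringsAsFactors = FALSE)
  if (nrow(raw) == 0L) stop("metadata table is empty")
  need <- c(dialect$col_film, dialect$col_class, dialect$col_start,
            dialect$col_end, dialect$col_viewers)
  missing_cols <- setdiff(need, names(raw))
  if (length(missing_cols))
    stop(sprintf("metadata is missing mandatory column(s): %s",
                 paste(missing_cols, collapse = ", ")))

  n <- nrow(raw)
  viewers_chr <- raw[[dialect$col_viewers]]
  viewers <- suppressWarnings(as.integer(viewers_chr))
  bad <- which(is.na(viewers) | viewers != suppressWarnings(as.numeric(viewers_chr)))
  if (length(bad))
    stop(sprintf("row %d: viewer count '%s' is not a non-negative integer",
                 bad[1L], viewers_chr[bad[1L]]))

  start <- parse_dialect_time(raw[[dialect$col_start]], dialect)
  end <- parse_dialect_time(raw[[dialect$col_end]], dialect)
  for (what in c("start", "end")) {
    tms <- if (what == "start") start else end
    bad <- which(is.na(tms))
    if (length(bad))
      stop(sprintf("row %d: unparsable %s timestamp '%s'", bad[1L], what,
                   raw[[if (what == "start") dialect$col_start else dialect$col_end]][bad[1L]]))
  }
  if (any(end <= start)) {
    i <- which(end <= start)[1L]
    stop(sprintf("row %d: end_time is not after start_time", i))
  }

  cls <- as.character(raw[[dialect$col_class]])
  if (!all(cls %in% age_classes())) {
    i <- which(!cls %in% age_classes())[1L]
    stop(sprintf("row %d: age class '%s' is not one of %s", i, cls[i],
                 paste(age_classes(), collapse = "/")))
  }

  under12 <- rep(NA_integer_, n)
  if (dialect$col_under12 %in% names(raw)) {
    u <- raw[[dialect$col_under12]]
    under12 <- suppressWarnings(as.integer(u))
    under12[u == "" | is.na(u)] <- NA_integer_
    over <- which(!is.na(under12) & under12 > viewers)
    if (length(over))
      stop(sprintf("row %d: under-12 count exceeds viewer count", over[1L]))
  }

  excluded <- rep(FALSE, n)
  if (dialect$col_excluded %in% names(raw))
    excluded <- as.logical(raw[[dialect$col_excluded]]) %in% TRUE

  sid <- if ("screening_id" %in% names(raw)) raw[["screening_id"]] else
    sprintf("S%03d", seq_len(n))
  if (!is.null(exclusions)) excluded <- excluded | sid %in% exclusions

  room <- if (dialect$col_room %in% names(raw)) raw[[dialect$col_room]] else
    rep("room1", n)

  data.frame(
    screening_id = sid,
    film_title = raw[[dialect$col_film]],
    age_class = factor(cls, levels = age_classes()),
    room_id = room,
    start_time = start, end_time = end,
    viewer_count = viewers, under12_count = under12,
    excluded = excluded,
    stringsAsFactors = FALSE)
}

#' Write a screening-metadata table
#'
#' Inverse of [read_screenings()]: the round trip preserves every field.
#'
#' @param screenings a screening data frame as returned by
#'   [read_screenings()].
#' @param path output path.
#' @param dialect an [io_dialect()].
#' @return the path, invisibly.
#' @export
write_screenings <- function(screenings, path, dialect = io_dialect()) {
  out <- data.frame(
    screening_id = screenings$screening_id,
    check.names = FALSE, stringsAsFactors = FALSE)
  out[[dialect$col_film]] <- screenings$film_title
  out[[dialect$col_class]] <- as.character(screenings$age_class)
  out[[dialect$col_room]] <- screenings$room_id
  out[[dialect$col_start]] <- format(screenings$start_time, dialect$time_format)
  out[[dialect$col_end]] <- format(screenings$end_time, dialect$time_format)
  out[[dialect$col_viewers]] <- screenings$viewer_count
  out[[dialect$col_under12]] <- ifelse(is.na(screenings$under12_count), "",
                                       as.character(screenings$under12_count))
  out[[dialect$col_excluded]] <- screenings$excluded
  utils::write.table(out, path, sep = dialect$sep, quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' Read a compound mixing-ratio table
#'
#' The compound table has a timestamp first column and one column per
#' compound; all compounds are in ppb except the CO2 column (ppm). No
#' resampling is performed on ingest: sample counts and values are
#' preserved exactly.
#'
#' @param path path to the tab-separated table.
#' @param dialect an [io_dialect()].
#' @return a named list of [compound_series()], one per compound column.
#' @export
read_compound_table <- function(path, dialect = io_dialect()) {
  if (!file.exists(path)) stop(sprintf("compound table not found: %s", path))
  raw <- utils::read.delim(path, sep = dialect$sep, header = TRUE,
                           check.names = FALSE, stringsAsFactors = FALSE)
  if (nrow(raw) == 0L || ncol(raw) < 2L)
    stop("compound table is empty or has no compound columns")
  tcol <- names(raw)[1L]
  time <- parse_dialect_time(raw[[tcol]], dialect)
  if (any(is.na(time)))
    stop(sprintf("unparsable timestamp '%s' in compound table",
                 raw[[tcol]][which(is.na(time))[1L]]))
  d <- diff(as.numeric(time))
  if (any(d == 0))
    stop(sprintf("duplicated timestamp in compound table: %s",
                 format(time[which(d == 0)[1L] + 1L])))
  if (any(d < 0))
    stop(sprintf("timestamps are not monotone increasing at %s",
                 format(time[which(d < 0)[1L] + 1L])))
  ids <- names(raw)[-1L]
  out <- lapply(ids, function(id) {
    compound_series(time, as.numeric(raw[[id]]), compound_id = id,
                    unit = if (identical(id, dialect$co2_id)) "ppm" else "ppb")
  })
  names(out) <- ids
  out
}

#' Write a compound mixing-ratio table
#'
#' @param series_list named list of [compound_series()] sharing one
#'   time grid.
#' @param path output path.
#' @param dialect an [io_dialect()].
#' @return the path, invisibly.
#' @export
write_compound_table <- function(series_list, path, dialect = io_dialect()) {
  stopifnot(length(series_list) >= 1L)
  time <- series_list[[1L]]$time
  for (s in series_list)
    if (length(s$value) != length(time))
      stop("all series in a compound table must share one time grid")
  out <- data.frame(format(time, dialect$time_format),
                    check.names = FALSE, stringsAsFactors = FALSE)
  names(out) <- dialect$col_timestamp
  for (id in names(series_list))
    out[[id]] <- format(series_list[[id]]$value, digits = 10, trim = TRUE,
                        scientific = FALSE)
  utils::write.table(out, path, sep = dialect$sep, quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' Bundle screenings and compound traces into a study object
#'
#' @param screenings screening data frame ([read_screenings()]).
#' @param compounds named list of [compound_series()] spanning the
#'   study's time range.
#' @return an object of class `voc_study`.
#' @export
voc_study <- function(screenings, compounds) {
  stopifnot(is.data.frame(screenings), is.list(compounds))
  units <- vapply(compounds, function(s) s$unit, character(1))
  structure(list(screenings = screenings, compounds = compounds,
                 units = units),
            class = "voc_study")
}

#' @export
print.voc_study <- function(x, ...) {
  cat(sprintf("<voc_study> %d screenings of %d films, %d compound trace(s)\n",
              nrow(x$screenings), length(unique(x$screenings$film_title)),
              length(x$compounds)))
  tab <- table(x$screenings$age_class)
  cat("  screenings per class:",
      paste(sprintf("FSK %s: %d", names(tab), as.integer(tab)), collapse = ", "),
      "\n")
  if (any(x$screenings$excluded))
    cat(sprintf("  %d screening(s) flagged excluded\n", sum(x$screenings$excluded)))
  invisible(x)
}

#' Read a study (metadata plus compound table) from disk
#'
#' @param metadata_path path to the screening metadata file.
#' @param compounds_path path to the compound table.
#' @param dialect an [io_dialect()].
#' @param exclusions passed to [read_screenings()].
#' @return a [voc_study()].
#' @export
read_study <- function(metadata_path, compounds_path,
                       dialect = io_dialect(), exclusions = NULL) {
  voc_study(read_screenings(metadata_path, dialect, exclusions),
            read_compound_table(compounds_path, dialect))
}
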