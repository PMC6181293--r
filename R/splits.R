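#' Film list of the cinema measurement campaigns
#'
#' The 11 films measured over the winter 2013/2014 and 2015/2016
#' campaigns, with their FSK age classes and screening counts
#' (51 + 35 + 44 + 5 = 135 screenings in total). Encoded here so the
#' split-enumeration logic can be exercised without the measurement
#' files.
#'
#' @return a data frame with columns `film_title`, `age_class`,
#'   `n_screenings`.
#' @export
cinema_film_summary <- function() {
  data.frame(
    film_title = c("Help I've shrunk my teacher", "I'm off then",
                   "Buddy", "Walking with Dinosaurs 3D",
                   "The Secret Life of Walter Mitty",
                   "The Starving Games", "Hunger Games: Catching Fire",
                   "Star Wars: The Force Awakens",
                   "The Counselor", "Machete Kills",
                   "Paranormal Activity: Ghost Dimension"),
    age_class = factor(c("0", "0", "6", "6", "6", "12", "12", "12",
                         "16", "16", "16"), levels = age_classes()),
    n_screenings = c(18L, 33L, 10L, 12L, 13L, 2L, 8L, 34L, 1L, 1L, 3L),
    stringsAsFactors = FALSE)
}

# internal: per-film summary from either a screenings table (one row
# per screening) or a pre-aggregated film summary with n_screenings.
film_summary <- function(screenings) {
  if (!is.factor(screenings$age_class))
    screenings$age_class <- factor(as.character(screenings$age_class),
                                   levels = age_classes())
  if ("n_screenings" %in% names(screenings)) {
    out <- screenings[, c("film_title", "age_class", "n_screenings")]
  } else {
    agg <- stats::aggregate(list(n_screenings = screenings$film_title),
                            by = list(film_title = screenings$film_title,
                                      age_class = screenings$age_class),
                            FUN = length)
    out <- agg[order(agg$age_class, agg$film_title), ]
  }
  out[out$n_screenings > 0L, , drop = FALSE]
}

#' Enumerate leave-one-film-out-per-class train/test combinations
#'
#' For each age class one film (or joint film group) is chosen as the
#' test set and the class's remaining films train; the plan is the
#' Cartesian product of the per-class options. Eligible test films are
#' those with at least `min_test_screenings` screenings — except in a
#' class containing the `always_together` group: there the group forms
#' one joint test option and every remaining film of that class is an
#' option regardless of its screening count (when the group trains,
#' some other film of the class must be tested). With the measured film
#' list this yields 2 x 3 x 2 x 2 = 24 combinations.
#'
#' @param screenings screening records ([read_screenings()]) or a film
#'   summary with an `n_screenings` column ([cinema_film_summary()]).
#' @param min_test_screenings test-set eligibility threshold.
#' @param always_together character vector of films always placed in
#'   the same set and evaluated jointly.
#' @return an object of class `split_plan`: a list with `combos` (each
#'   a named list mapping age class to its test films) and the per-class
#'   `options`.
#' @export
enumerate_splits <- function(screenings, min_test_screenings = 8L,
                             always_together = c("The Counselor", "Machete Kills")) {
  fs <- film_summary(screenings)
  classes <- levels(droplevels(fs$age_class))
  options <- list()
  for (cl in classes) {
    sub <- fs[fs$age_class == cl, , drop = FALSE]
    grouped <- intersect(always_together, sub$film_title)
    if (length(grouped) >= 2L) {
      rest <- setdiff(sub$film_title, grouped)
      opts <- c(list(grouped), as.list(rest))
    } else {
      elig <- sub$film_title[sub$n_screenings >= min_test_screenings]
      opts <- as.list(elig)
    }
    if (!length(opts))
      stop(sprintf("age class %s has no eligible test film (threshold %d screenings)",
                   cl, min_test_screenings))
    options[[cl]] <- opts
  }
  idx <- expand.grid(lapply(options, seq_along), KEEP.OUT.ATTRS = FALSE)
  combos <- lapply(seq_len(nrow(idx)), function(i) {
    stats::setNames(lapply(classes, function(cl) options[[cl]][[idx[i, cl]]]),
                    classes)
  })
  structure(list(combos = combos, options = options, classes = classes),
            class = "split_plan")
}

#' @export
print.split_plan <- function(x, ...) {
  cat(sprintf("<split_plan> %d train/test combinations (%s options per class)\n",
              length(x$combos),
              paste(vapply(x$options, length, integer(1)), collapse = " x ")))
  invisible(x)
}

#' @export
length.split_plan <- function(x) length(x$combos)

#' Drop low-attendance screenings
#'
#' @param screenings screening records.
#' @param min_viewers screenings with fewer viewers are removed
#'   (0 keeps everything).
#' @return the filtered screening data frame.
#' @export
attendance_filter <- function(screenings, min_viewers = 0L) {
  stopifnot(min_viewers >= 0L)
  screenings[screenings$viewer_count >= min_viewers, , drop = FALSE]
}
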