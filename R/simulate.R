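#' Class profile for the synthetic-study generator
#'
#' Describes one age class's films and audiences: how many films, how
#' often each was screened, audience sizes, and the emission behaviour
#' that encodes class identity — a constant per-person baseline
#' emission plus transient scene-locked emission bursts whose rate and
#' amplitude statistics differ between classes. Film identity is a
#' fixed burst schedule shared by all screenings of that film; class
#' identity is the schedule's rate/amplitude statistics.
#'
#' @param age_class one of "0", "6", "12", "16".
#' @param n_films films in the class (ignored when `film_titles` is
#'   given).
#' @param screenings_per_film scalar or one count per film (recycled).
#' @param film_titles optional explicit film titles.
#' @param film_length_min range of film lengths, minutes.
#' @param viewer_range range of audience sizes (uniform integer).
#' @param event_rate_per_hour mean scene-locked bursts per hour.
#' @param event_amplitude_mean mean burst emission amplitude, ppb m^3/h
#'   per person (gamma-distributed across events).
#' @param event_amplitude_shape gamma shape of the amplitude
#'   distribution.
#' @param event_duration_min range of burst durations, minutes.
#' @param baseline_emission constant per-person emission rate,
#'   ppb m^3/h.
#' @param under12_fraction fraction of the audience younger than 12.
#' @return an object of class `class_profile`.
#' @export
class_profile <- function(age_class, n_films = 2L,
                          screenings_per_film = 10L,
                          film_titles = NULL,
                          film_length_min = c(90, 120),
                          viewer_range = c(20L, 120L),
                          event_rate_per_hour = 10,
                          event_amplitude_mean = 2000,
                          event_amplitude_shape = 16,
                          event_duration_min = c(1, 3),
                          baseline_emission = 150,
                          under12_fraction = 0) {
  age_class <- match.arg(as.character(age_class), age_classes())
  stopifnot(event_rate_per_hour >= 0, event_amplitude_mean >= 0,
            baseline_emission >= 0,
            under12_fraction >= 0, under12_fraction <= 1,
            all(screenings_per_film >= 1L))
  if (is.null(film_titles))
    film_titles <- sprintf("FSK%s film %d", age_class, seq_len(n_films))
  structure(list(age_class = age_class, film_titles = film_titles,
                 screenings_per_film = screenings_per_film,
                 film_length_min = film_length_min,
                 viewer_range = viewer_range,
                 event_rate_per_hour = event_rate_per_hour,
                 event_amplitude_mean = event_amplitude_mean,
                 event_amplitude_shape = event_amplitude_shape,
                 event_duration_min = event_duration_min,
                 baseline_emission = baseline_emission,
                 under12_fraction = under12_fraction),
            class = "class_profile")
}

#' Default four-class profiles with a geometric amplitude separation
#'
#' One profile per age class; burst amplitudes grow by `separation`
#' from class to class (separation 1 gives identical, structureless
#' profiles — the null configuration).
#'
#' @param separation amplitude ratio between consecutive classes.
#' @param base_amplitude burst amplitude of FSK 0, ppb m^3/h per
#'   person.
#' @param n_films films per class (recycled over the four classes).
#' @param screenings_per_film screenings per film.
#' @param ... further arguments passed to every [class_profile()].
#' @return a list of four [class_profile()] objects.
#' @export
default_profiles <- function(separation = 5, base_amplitude = 200,
                             n_films = c(2L, 3L, 2L, 2L),
                             screenings_per_film = 10L, ...) {
  n_films <- rep_len(n_films, 4L)
  amps <- base_amplitude * separation^(0:3)
  profiles <- Map(function(cl, nf, a)
    class_profile(cl, n_films = nf,
                  screenings_per_film = screenings_per_film,
                  event_amplitude_mean = a, ...),
    age_classes(), n_films, amps)
  names(profiles) <- age_classes()
  profiles
}

#' Synthetic-study specification
#'
#' Everything [generate_study()] needs: the class profiles, the room,
#' the compounds to emit (each a list with `id`, optional `name`, an
#' emission `scale` factor and an additive Gaussian measurement noise
#' `noise_sd` on the raw trace, ppb), the sampling cadence, and the
#' end-of-film exit spike (the burst of isoprene released when the
#' audience stands up and walks out, removed downstream by the tail
#' trim).
#'
#' @param profiles list of [class_profile()] objects.
#' @param room a [room_params()].
#' @param compounds list of per-compound settings.
#' @param cadence_s sampling step, seconds.
#' @param exit_spike add the end-of-film emission burst.
#' @param exit_spike_emission per-person emission of the exit burst,
#'   ppb m^3/h, over the final 2 minutes.
#' @param child_emission_factor per-person emission of an under-12
#'   viewer relative to an adult.
#' @param baseline_lead_min empty-room samples generated before each
#'   first screening of a block (gives the pre-entry baseline window).
#' @param gap_min gap between consecutive screenings.
#' @param start timestamp of the first screening (naive local time).
#' @param seed integer seed; the generated study is a pure function of
#'   the spec.
#' @return an object of class `study_spec`.
#' @export
study_spec <- function(profiles = default_profiles(),
                       room = room_params(),
                       compounds = list(list(id = "m69.0699",
                                             name = "isoprene",
                                             scale = 1, noise_sd = 0.02)),
                       cadence_s = 30,
                       exit_spike = TRUE,
                       exit_spike_emission = 2000,
                       child_emission_factor = 0.5,
                       baseline_lead_min = 10,
                       gap_min = 30,
                       start = "2013-12-01 10:00:00",
                       seed = 1L) {
  stopifnot(length(profiles) >= 2L, cadence_s > 0)
  structure(list(profiles = profiles, room = room, compounds = compounds,
                 cadence_s = cadence_s, exit_spike = exit_spike,
                 exit_spike_emission = exit_spike_emission,
                 child_emission_factor = child_emission_factor,
                 baseline_lead_min = baseline_lead_min,
                 gap_min = gap_min, start = start,
                 seed = as.integer(seed)),
            class = "study_spec")
}

# internal: exact stepwise one-box response to a piecewise-constant
# per-interval emission series (ppb m^3/h). emission has one value per
# interval between consecutive samples (length n - 1).
box_response <- function(emission, c0, c_in, room, dt_s) {
  k <- room$ventilation_rate / room$volume
  a <- exp(-k * dt_s / 3600)
  z <- (1 - a) * (c_in + emission / room$ventilation_rate)
  c(c0, as.numeric(stats::filter(z, filter = a, method = "recursive",
                                 init = c0)))
}

# internal: draw a film's fixed event schedule from its class profile
draw_film_schedule <- function(profile) {
  L <- round(stats::runif(1, profile$film_length_min[1L],
                          profile$film_length_min[2L]))
  n_ev <- stats::rpois(1, profile$event_rate_per_hour * L / 60)
  events <- if (n_ev > 0) data.frame(
    time_min = sort(stats::runif(n_ev, 2, max(3, L - 8))),
    amplitude = stats::rgamma(n_ev, shape = profile$event_amplitude_shape,
                              scale = profile$event_amplitude_mean /
                                profile$event_amplitude_shape),
    duration_min = stats::runif(n_ev, profile$event_duration_min[1L],
                                profile$event_duration_min[2L]))
  else data.frame(time_min = numeric(), amplitude = numeric(),
                  duration_min = numeric())
  list(length_min = L, events = events)
}

# internal: per-person emission rate on each grid interval of one
# screening window (relative minutes from screening start).
screening_emission <- function(mid_min, schedule, profile, spec) {
  e <- rep(profile$baseline_emission, length(mid_min))
  ev <- schedule$events
  if (nrow(ev)) for (j in seq_len(nrow(ev))) {
    inb <- mid_min >= ev$time_min[j] &
      mid_min < ev$time_min[j] + ev$duration_min[j]
    e[inb] <- e[inb] + ev$amplitude[j]
  }
  if (spec$exit_spike) {
    inb <- mid_min >= schedule$length_min - 2 & mid_min < schedule$length_min
    e[inb] <- e[inb] + spec$exit_spike_emission
  }
  e
}

#' Simulate one screening in isolation
#'
#' Forward model of a single screening starting from an empty room at
#' the inflow mixing ratio: the trace is the one-box response to
#' N_eff x (baseline + scene-locked bursts), where N_eff discounts
#' under-12 viewers by the child emission factor, plus additive
#' Gaussian measurement noise. The grid extends `baseline_lead_min`
#' before the start (empty room) so the pre-entry baseline is
#' estimable.
#'
#' @param profile a [class_profile()].
#' @param schedule a film schedule (`length_min`, `events` data frame)
#'   as drawn by [generate_study()]; fixed per film so peaks recur at
#'   the same times in every screening of the film.
#' @param spec a [study_spec()].
#' @param viewer_count audience size.
#' @param under12_count viewers younger than 12.
#' @param start_time screening start (naive local time POSIXct).
#' @param compound which entry of `spec$compounds` to emit.
#' @param noise add the measurement noise (uses the current RNG
#'   stream).
#' @return a list with the [compound_series()] `series` and the
#'   screening record fields.
#' @export
simulate_screening <- function(profile, schedule, spec,
                               viewer_count, under12_count = 0L,
                               start_time = as.POSIXct("2013-12-01 10:00:00",
                                                       tz = "Etc/GMT-1"),
                               compound = 1L, noise = TRUE) {
  comp <- spec$compounds[[compound]]
  dt <- spec$cadence_s
  lead_n <- round(spec$baseline_lead_min * 60 / dt)
  n_film <- round(schedule$length_min * 60 / dt)
  time <- start_time + dt * seq(-lead_n, n_film)
  rel_min <- (seq(-lead_n, n_film) * dt) / 60
  mid_min <- (rel_min[-1L] + rel_min[-length(rel_min)]) / 2
  n_eff <- viewer_count - under12_count +
    spec$child_emission_factor * under12_count
  e <- numeric(length(mid_min))
  inside <- mid_min >= 0
  e[inside] <- n_eff * comp$scale *
    screening_emission(mid_min[inside], schedule, profile, spec)
  c_in <- spec$room$inflow_mixing_ratio
  v <- box_response(e, c0 = c_in, c_in = c_in, room = spec$room, dt_s = dt)
  if (noise) v <- v + stats::rnorm(length(v), sd = comp$noise_sd)
  series <- compound_series(time, v, compound_id = comp$id,
                            unit = if (identical(comp$id, "CO2")) "ppm" else "ppb",
                            name = comp$name)
  list(series = series,
       record = data.frame(film_title = NA_character_,
                           age_class = profile$age_class,
                           start_time = start_time,
                           end_time = start_time + n_film * dt,
                           viewer_count = viewer_count,
                           under12_count = under12_count,
                           stringsAsFactors = FALSE))
}

#' Generate a complete synthetic study
#'
#' Draws, under a single seed, every film's fixed event schedule, every
#' screening's audience, and the measurement noise, then simulates one
#' continuous compound trace per compound over the whole campaign
#' timeline (screenings back to back with `gap_min` gaps; the room
#' relaxes toward the inflow value between screenings). The output is
#' readable by the package's own readers, and two generations from one
#' spec are identical.
#'
#' @param spec a [study_spec()].
#' @param dir optional directory: when given, `metadata.tsv` and
#'   `compounds.tsv` are written there in the study-file dialect.
#' @param dialect an [io_dialect()] used when writing.
#' @return a [voc_study()]; when `dir` is given, the file paths are in
#'   attribute `paths`.
#' @export
generate_study <- function(spec, dir = NULL, dialect = io_dialect()) {
  stopifnot(inherits(spec, "study_spec"))
  set.seed(spec$seed)
  dt <- spec$cadence_s
  start0 <- as.POSIXct(spec$start, tz = dialect$tz)

  # film schedules (fixed per film), then the screening timeline
  films <- list()
  for (pr in spec$profiles) {
    spf <- rep_len(pr$screenings_per_film, length(pr$film_titles))
    for (fi in seq_along(pr$film_titles)) {
      n_scr <- spf[fi]
      films[[pr$film_titles[fi]]] <- list(
        title = pr$film_titles[fi], profile = pr,
        schedule = draw_film_schedule(pr), n_screenings = n_scr)
    }
  }
  scr_films <- unlist(lapply(films, function(f) rep(f$title, f$n_screenings)))
  scr_films <- sample(scr_films)   # interleave screenings across films

  records <- list()
  t_cursor <- start0
  for (i in seq_along(scr_films)) {
    f <- films[[scr_films[i]]]
    pr <- f$profile
    n <- round(stats::runif(1, pr$viewer_range[1L], pr$viewer_range[2L]))
    u12 <- round(pr$under12_fraction * n)
    n_film <- round(f$schedule$length_min * 60 / dt)
    records[[i]] <- data.frame(
      screening_id = sprintf("S%03d", i),
      film_title = f$title, age_class = pr$age_class,
      room_id = "room1",
      start_time = t_cursor, end_time = t_cursor + n_film * dt,
      viewer_count = n, under12_count = u12, excluded = FALSE,
      stringsAsFactors = FALSE)
    t_cursor <- t_cursor + n_film * dt + round(spec$gap_min * 60 / dt) * dt
  }
  screenings <- do.call(rbind, records)
  screenings$age_class <- factor(screenings$age_class, levels = age_classes())

  # one continuous grid over the campaign
  g0 <- as.numeric(start0) - round(spec$baseline_lead_min * 60 / dt) * dt
  g1 <- as.numeric(max(screenings$end_time))
  tnum <- seq(g0, g1, by = dt)
  time <- as.POSIXct(tnum, origin = "1970-01-01", tz = dialect$tz)
  mid <- (tnum[-1L] + tnum[-length(tnum)]) / 2

  # per-person emission profile of the campaign (shared by compounds
  # up to their scale factors)
  e_person <- numeric(length(mid))
  for (i in seq_len(nrow(screenings))) {
    rec <- screenings[i, ]
    f <- films[[rec$film_title]]
    sel <- which(mid >= as.numeric(rec$start_time) &
                   mid < as.numeric(rec$end_time))
    if (!length(sel)) next
    n_eff <- rec$viewer_count - rec$under12_count +
      spec$child_emission_factor * rec$under12_count
    rel <- (mid[sel] - as.numeric(rec$start_time)) / 60
    e_person[sel] <- n_eff *
      screening_emission(rel, f$schedule, f$profile, spec)
  }

  compounds <- list()
  for (comp in spec$compounds) {
    v <- box_response(comp$scale * e_person,
                      c0 = spec$room$inflow_mixing_ratio,
                      c_in = spec$room$inflow_mixing_ratio,
                      room = spec$room, dt_s = dt)
    v <- v + stats::rnorm(length(v), sd = comp$noise_sd)
    compounds[[comp$id]] <- compound_series(
      time, v, compound_id = comp$id,
      unit = if (identical(comp$id, dialect$co2_id)) "ppm" else "ppb",
      name = comp$name)
  }

  study <- voc_study(screenings, compounds)
  if (!is.null(dir)) {
    if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
    mp <- file.path(dir, "metadata.tsv")
    cp <- file.path(dir, "compounds.tsv")
    write_screenings(screenings, mp, dialect)
    write_compound_table(compounds, cp, dialect)
    attr(study, "paths") <- c(metadata = mp, compounds = cp)
  }
  attr(study, "films") <- films
  study
}

#' Spec whose film list and screening counts mirror the measured
#' campaign
#'
#' Eleven films named as in the measurement campaign with screening
#' counts 18/33, 10/12/13, 2/8/34 and 1/1/3 per class, so the split
#' enumeration on the generated metadata reproduces the campaign's 24
#' train/test combinations.
#'
#' @param ... further arguments passed to [study_spec()].
#' @return a [study_spec()].
#' @export
study_spec_campaign <- function(...) {
  fs <- cinema_film_summary()
  amps <- c("0" = 200, "6" = 1000, "12" = 5000, "16" = 25000)
  profiles <- lapply(age_classes(), function(cl) {
    sub <- fs[fs$age_class == cl, ]
    class_profile(cl, film_titles = sub$film_title,
                  screenings_per_film = sub$n_screenings,
                  event_amplitude_mean = amps[[cl]])
  })
  names(profiles) <- age_classes()
  study_spec(profiles = profiles, ...)
}
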