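test_that("study generation is a pure function of the spec", {
  spec <- study_spec(profiles = default_profiles(
    n_films = 1L, screenings_per_film = 2L, film_length_min = c(30, 35)),
    seed = 5)
  s1 <- generate_study(spec)
  s2 <- generate_study(spec)
  expect_equal(s1$screenings, s2$screenings)
  expect_equal(s1$compounds$m69.0699$value, s2$compounds$m69.0699$value)

  d1 <- withr::local_tempdir(); d2 <- withr::local_tempdir()
  generate_study(spec, dir = d1)
  generate_study(spec, dir = d2)
  for (f in c("metadata.tsv", "compounds.tsv"))
    expect_identical(readLines(file.path(d1, f)), readLines(file.path(d2, f)))
})

test_that("the generated study has the specified population structure", {
  spec <- study_spec(profiles = default_profiles(
    n_films = 2L, screenings_per_film = 10L, film_length_min = c(30, 40)),
    seed = 2)
  st <- generate_study(spec)
  expect_equal(nrow(st$screenings), 80L)
  expect_equal(as.vector(table(st$screenings$age_class)), rep(20L, 4L))
  expect_equal(length(unique(st$screenings$film_title)), 8L)
  expect_true(all(st$screenings$end_time > st$screenings$start_time))
  # written files are readable by the package's own readers
  d <- withr::local_tempdir()
  generate_study(spec, dir = d)
  back <- read_study(file.path(d, "metadata.tsv"), file.path(d, "compounds.tsv"))
  expect_equal(back$screenings, st$screenings)
  expect_equal(length(back$compounds$m69.0699$value),
               length(st$compounds$m69.0699$value))
})

test_that("a null film produces a pure box-model trace with near-zero residuals", {
  prof <- class_profile("0", event_rate_per_hour = 0, baseline_emission = 150)
  spec <- study_spec(profiles = list(prof, class_profile("6")),
                     compounds = list(list(id = "m69.0699", name = NULL,
                                           scale = 1, noise_sd = 0)),
                     exit_spike = FALSE)
  sched <- list(length_min = 60, events = data.frame(
    time_min = numeric(), amplitude = numeric(), duration_min = numeric()))
  sim <- simulate_screening(prof, sched, spec, viewer_count = 50,
                            noise = FALSE)
  win <- slice_screening(sim$series, start = sim$record$start_time,
                         end = sim$record$end_time)
  win <- normalize_per_person(trim_tail(win, 5), 50)
  fit <- fit_box_model(win, spec$room)
  res <- compute_residuals(win, fit)
  expect_lt(max(abs(res$residuals)), 1e-9)
  expect_equal(fit$emission_rate, 150, tolerance = 1e-3)
})

test_that("per-person normalization aligns screenings of one film across audiences", {
  prof <- class_profile("12", event_amplitude_mean = 5000)
  spec <- study_spec(profiles = list(prof, class_profile("0")),
                     compounds = list(list(id = "m69.0699", name = NULL,
                                           scale = 1, noise_sd = 0)))
  set.seed(77)
  sched <- list(length_min = 60, events = data.frame(
    time_min = c(15, 40), amplitude = c(4000, 6000), duration_min = c(2, 2)))
  a <- simulate_screening(prof, sched, spec, viewer_count = 30, noise = FALSE)
  b <- simulate_screening(prof, sched, spec, viewer_count = 90, noise = FALSE)
  pa <- normalize_per_person(a$series, 30)
  pb <- normalize_per_person(b$series, 90)
  expect_equal(pa$value, pb$value, tolerance = 1e-12)
})

test_that("the tail trim removes the exit spike by construction", {
  prof <- class_profile("0", event_rate_per_hour = 0)
  spec <- study_spec(profiles = list(prof, class_profile("6")),
                     compounds = list(list(id = "m69.0699", name = NULL,
                                           scale = 1, noise_sd = 0)),
                     exit_spike = TRUE, exit_spike_emission = 50000)
  sched <- list(length_min = 60, events = data.frame(
    time_min = numeric(), amplitude = numeric(), duration_min = numeric()))
  sim <- simulate_screening(prof, sched, spec, viewer_count = 50, noise = FALSE)
  win <- slice_screening(sim$series, start = sim$record$start_time,
                         end = sim$record$end_time)
  # untrimmed: the spike dominates the end of the trace
  expect_gt(max(win$value), 2 * win$value[round(length(win$value) / 2)])
  trimmed <- normalize_per_person(trim_tail(win, 5), 50)
  fit <- fit_box_model(trimmed, spec$room)
  res <- compute_residuals(trimmed, fit)
  expect_lt(max(abs(res$residuals)), 1e-9)
})

test_that("a campaign-shaped spec reproduces the 24 train/test combinations", {
  spec <- study_spec_campaign()
  # profiles mirror the measured film list
  fs <- do.call(rbind, lapply(spec$profiles, function(p)
    data.frame(film_title = p$film_titles, age_class = p$age_class,
               n_screenings = rep_len(p$screenings_per_film,
                                      length(p$film_titles)))))
  expect_equal(sum(fs$n_screenings), 135L)
  plan <- enumerate_splits(fs)
  expect_length(plan, 24L)
})

test_that("noise monotonically degrades class recovery", {
  # small replicate studies are noisy, so each level averages two
  # independent study draws
  level_auc <- function(sig) {
    mean(vapply(c(30, 31), function(seed) {
      st <- quick_study(seed = seed, separation = 5, noise_sd = sig)
      ft <- feature_table(st)
      pl <- enumerate_splits(st$screenings, min_test_screenings = 1,
                             always_together = character())
      ev <- evaluate_compound(ft, pl, model_config(n_trees = 100, seed = 1))
      mean(ev$auc_summary$mean_auc)
    }, numeric(1)))
  }
  aucs <- vapply(c(0.02, 3, 30), level_auc, numeric(1))
  expect_true(all(diff(aucs) < 0))
  expect_gt(aucs[1], 0.8)
  expect_lt(aucs[3], 0.7)
})
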