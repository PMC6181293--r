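room <- room_params()   # V = 6500 m^3, Q = 1300 m^3/h

test_that("tail trim removes exactly the final minutes", {
  s <- compound_series(grid_s(100), seq_len(201))   # spans 100 min
  t5 <- trim_tail(s, 5)
  expect_length(t5$value, 191L)
  expect_equal(diff(range(as.numeric(t5$time))) / 60, 95)
  expect_equal(trim_tail(s, 0)$value, s$value)
  short <- compound_series(grid_s(4), seq_len(9))
  expect_error(trim_tail(short, 5), "shorter")
})

test_that("per-person normalization divides by the audience size", {
  s <- compound_series(c(0, 30), c(10, 20))
  expect_equal(normalize_per_person(s, 10)$value, c(1, 2))
  expect_equal(normalize_per_person(s, 1)$value, s$value)
  expect_error(normalize_per_person(s, 0), "positive")
})

test_that("box-model prediction has the analytic steady state and time constant", {
  time <- grid_s(48 * 60)
  r0 <- room_params(inflow_mixing_ratio = 2)
  eq <- predict_box_model(r0, E = 0, C0 = 2, time)
  expect_equal(eq$value, rep(2, length(time)), tolerance = 1e-12)

  # steady-state excess E/Q: E = 1300 ppb m^3/h, Q = 1300 m^3/h -> 1 ppb
  p <- predict_box_model(room, E = 1300, C0 = 0, time)
  expect_equal(p$value[length(time)], 1.0, tolerance = 1e-3)

  # relaxation time constant V/Q = 5 h: at t = 5 h the remaining
  # distance to steady state is 1/e of the initial distance
  c_ss <- 1.0
  at5h <- p$value[which(as.numeric(p$time) == 5 * 3600)]
  expect_equal((c_ss - at5h) / (c_ss - 0), exp(-1), tolerance = 1e-9)

  # monotone approach from either side
  expect_true(all(diff(p$value) > 0))
  down <- predict_box_model(room, E = 0, C0 = 3, time)
  expect_true(all(diff(down$value) < 0))
})

test_that("fitting recovers the generating parameters on noise-free traces", {
  time <- grid_s(100)
  r1 <- room_params(inflow_mixing_ratio = 1)
  for (E in c(0.1, 1, 10)) {
    for (C0 in c(0, 1, 2)) {
      s <- predict_box_model(r1, E, C0, time)
      fit <- fit_box_model(s, r1)
      expect_equal(fit$emission_rate, E, tolerance = 1e-6)
      expect_equal(fit$initial_value, C0, tolerance = 1e-6)
      expect_lt(fit$rms_misfit, 1e-9)
    }
  }
})

test_that("degenerate and noisy fits behave as documented", {
  time <- grid_s(100)
  zero <- compound_series(time, rep(0, length(time)))
  fit <- fit_box_model(zero, room)
  expect_equal(fit$emission_rate, 0)
  expect_equal(fit$rms_misfit, 0)

  set.seed(4)
  sigma <- 0.01
  truth <- predict_box_model(room, E = 5, C0 = 0.2, time)
  noisy <- compound_series(time, truth$value + rnorm(length(time), sd = sigma))
  nf <- fit_box_model(noisy, room)
  expect_gt(nf$rms_misfit, sigma / 2)
  expect_lt(nf$rms_misfit, sigma * 2)

  expect_error(fit_box_model(compound_series(grid_s(2), 1:5), room),
               "at least 10")
})

test_that("the emission-rate bound clamps at zero unless negative rates are allowed", {
  time <- grid_s(100)
  r1 <- room_params(inflow_mixing_ratio = 1)
  # declining trace below the inflow level implies deposition (E < 0)
  decl <- compound_series(time, 1 - 0.3 * (1 - exp(-as.numeric(time) / 18000)))
  bounded <- fit_box_model(decl, r1)
  expect_equal(bounded$emission_rate, 0)
  free <- fit_box_model(decl, r1, allow_negative_E = TRUE)
  expect_lt(free$emission_rate, 0)
  expect_lt(free$rms_misfit, bounded$rms_misfit)
})

test_that("residuals are the exact difference and reconstruct the input", {
  time <- grid_s(90)
  model <- predict_box_model(room, E = 2.5, C0 = 0.1, time)
  fit <- fit_box_model(model, room)
  res <- compute_residuals(model, fit)
  expect_lt(max(abs(res$residuals)), 1e-9)
  expect_equal(res$film_length_min, 90)

  # inject a localized bump: it reappears in the residuals and the
  # subtraction conserves the measurement exactly
  bumped <- model
  bumped$value[40:44] <- bumped$value[40:44] + 0.3
  fit2 <- fit_box_model(bumped, room)
  res2 <- compute_residuals(bumped, fit2)
  expect_equal(bumped$value, fit2$fitted + res2$residuals, tolerance = 1e-12)
  perturb <- 0.3 * 5 / length(time)
  expect_equal(mean(res2$residuals[40:44]), 0.3,
               tolerance = perturb * 5 + 1e-6)
  expect_error(compute_residuals(trim_tail(bumped, 5), fit2), "length")
})

test_that("the pre-entry baseline estimator takes the window median", {
  time <- grid_s(30)
  v <- rep(1.5, length(time)); v[5] <- 9   # a stray spike
  s <- compound_series(time, v)
  expect_equal(estimate_inflow(s, start_time = 12 * 60, minutes = 10), 1.5)
  expect_true(is.na(estimate_inflow(s, start_time = -600, minutes = 5)))
})
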