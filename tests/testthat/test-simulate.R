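default_cell <- function(age = "P8", subtype = "I") {
  p <- cell_param_defaults()
  row <- p[p$age_group == age & p$subtype == subtype, ]
  row$a_floor <- 0
  row
}

test_that("sensitivity follows the Naka-Rushton form", {
  expect_equal(sensitivity(12, ir_half = 12, hill_n = 1), 0.5)
  expect_equal(sensitivity(1e6, ir_half = 12, hill_n = 1), 1) # saturation
  irs <- seq(8, 18, by = 0.25)
  s <- sensitivity(irs, ir_half = 12.6, hill_n = 0.9)
  expect_true(all(diff(s) > 0)) # monotone increasing
  expect_true(all(s >= 0 & s <= 1))
  # adaptation shift moves the curve right
  expect_lt(
    sensitivity(12, 12, 1, s_shift = 0.5),
    sensitivity(12, 12, 1)
  )
  expect_error(sensitivity(Inf, 12, 1), class = "iprgclight_input_error")
})

test_that("a rate trace with no events sits at the dark baseline", {
  cell <- default_cell()
  cell$baseline_rate <- 0.7
  tr <- simulate_rate_trace(cell, event_tbl(0, 1)[0, ], dt = 0.1, duration = 30)
  expect_true(all(abs(tr$rate_hz - 0.7) < 1e-9))
})

test_that("without adaptation the lit rate asymptotes to r_max * sensitivity", {
  cell <- default_cell()
  cell$adapt_tau <- 1e12
  cell$shift_gain <- 0
  tr <- simulate_rate_trace(cell, event_tbl(0, 600), dt = 0.1, duration = 600)
  s <- sensitivity(13.6, cell$ir_half, cell$hill_n)
  expect_equal(tail(tr$rate_hz, 1), cell$r_max * s, tolerance = 1e-3)
})

test_that("rates are non-negative and traces deterministic", {
  cell <- default_cell()
  ev <- dplyr::bind_rows(event_tbl(10, 70), event_tbl(200, 260, ir = 12.0))
  tr1 <- simulate_rate_trace(cell, ev, duration = 400)
  tr2 <- simulate_rate_trace(cell, ev, duration = 400)
  expect_identical(tr1, tr2)
  expect_true(all(tr1$rate_hz >= 0))
})

test_that("full dark re-adaptation restores the response within 6 recovery taus", {
  cell <- default_cell()
  gap <- 6 * cell$recover_tau
  ev <- dplyr::bind_rows(
    event_tbl(10, 70),
    event_tbl(10 + 60 + gap, 70 + 60 + gap)
  )
  dur <- 80 + 60 + gap
  tr <- simulate_rate_trace(cell, ev, dt = 0.05, duration = dur)
  int1 <- sum(tr$rate_hz[tr$time_s >= 10 & tr$time_s < 70]) * 0.05
  int2 <- sum(tr$rate_hz[tr$time_s >= 10 + 60 + gap &
    tr$time_s < 70 + 60 + gap]) * 0.05
  expect_equal(int2, int1, tolerance = 0.01) # within 1%
})

test_that("overlapping epochs and out-of-range events are rejected", {
  cell <- default_cell()
  ov <- dplyr::bind_rows(event_tbl(0, 60), event_tbl(30, 90))
  expect_error(simulate_rate_trace(cell, ov, duration = 100),
    class = "iprgclight_validation_error"
  )
  expect_error(
    simulate_rate_trace(cell, event_tbl(0, 60), duration = 30),
    class = "iprgclight_input_error"
  )
})

test_that("the Poisson sampler has the right mean and is seed-stable", {
  expect_length(sample_spike_train(rep(0, 100), 0.1, seed = 1), 0)
  expect_error(sample_spike_train(c(1, -1), 0.1, seed = 1),
    class = "iprgclight_input_error"
  )
  rate <- rep(10, 600) # 10 Hz for 60 s at dt = 0.1 -> expect 600 spikes
  counts <- vapply(
    1:500,
    function(s) length(sample_spike_train(rate, 0.1, seed = s)),
    numeric(1)
  )
  se <- sqrt(600 / 500) # Poisson variance = mean
  expect_lt(abs(mean(counts) - 600), 3 * se)
  expect_identical(
    sample_spike_train(rate, 0.1, seed = 42),
    sample_spike_train(rate, 0.1, seed = 42)
  )
  expect_true(!is.unsorted(sample_spike_train(rate, 0.1, seed = 7)))
})

test_that("a brighter probe partially overrides adaptation", {
  # after a 1-h exposure and partial dark recovery, a +1 log unit probe
  # must yield strictly more expected spikes than the standard probe
  cell <- default_cell("P30", "II")
  base <- dplyr::bind_rows(event_tbl(0, 3600), event_tbl(4800, 4860, ir = 13.6))
  bright <- dplyr::bind_rows(event_tbl(0, 3600), event_tbl(4800, 4860, ir = 14.6))
  tr_b <- simulate_rate_trace(cell, base, duration = 5000)
  tr_h <- simulate_rate_trace(cell, bright, duration = 5000)
  in_probe <- tr_b$time_s >= 4800 & tr_b$time_s < 4860
  expect_gt(sum(tr_h$rate_hz[in_probe]), sum(tr_b$rate_hz[in_probe]))
})

test_that("chromophore supplementation changes no output", {
  cfg <- population_config("P30",
    n_retinas = 2, cells_per_retina = 3,
    seed = 5
  )
  pr <- protocol_one_min_recovery(1)
  rec_off <- generate_protocol_recording(cfg, pr, chromophore_supplement = FALSE)
  rec_on <- generate_protocol_recording(cfg, pr, chromophore_supplement = TRUE)
  expect_identical(rec_off$spikes, rec_on$spikes)
  expect_identical(rec_off$events, rec_on$events)
})

test_that("protocol recordings have the published population scale", {
  cfg <- population_config("P8", n_retinas = 5, cells_per_retina = 20.2, seed = 2)
  rec <- generate_protocol_recording(cfg, protocol_single_pulse())
  # ~101 cells from 5 retinas, Poisson spread
  expect_lt(abs(nrow(rec$cells) - 101), 3 * sqrt(101))
  expect_error(
    generate_protocol_recording(cfg, "one_hour_exposure"),
    class = "iprgclight_input_error"
  ) # protocols must be constructed, not named
})

test_that("recovery protocols end in a KCl epoch that healthy cells answer", {
  cfg <- population_config("P8", n_retinas = 2, cells_per_retina = 8, seed = 3)
  rec <- generate_protocol_recording(cfg, protocol_one_hour_exposure())
  expect_equal(tail(rec$events$kind, 1), "kcl")
  tc <- one_hour_timecourse(rec)
  kcl <- dplyr::filter(tc$kcl, !is.na(kcl_percent))
  # the bulk of simulated cells pass the 10% health criterion
  expect_gt(mean(kcl_qc(kcl$kcl_percent)), 0.8)
})

test_that("an empty population still yields a valid stimulus log", {
  cfg <- population_config("P8", n_retinas = 0, seed = 1)
  rec <- generate_protocol_recording(cfg, protocol_one_min_recovery(2))
  expect_equal(nrow(rec$spikes), 0)
  expect_silent(validate_event_table(rec$events))
})

test_that("the simulated P8 one-hour cohort reproduces the firing-pattern mix", {
  # most P8 cells stop firing by 30 min; only a minority of Type I cells
  # keep firing continuously or intermittently through the hour
  cfg <- population_config("P8", n_retinas = 3, cells_per_retina = 12, seed = 8)
  rec <- generate_protocol_recording(cfg, protocol_one_hour_exposure())
  tc <- one_hour_timecourse(rec)
  tab <- table(tc$patterns$pattern)
  expect_gt(tab[["transient"]] / sum(tab), 0.5)
})
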