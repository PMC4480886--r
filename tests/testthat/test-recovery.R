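test_that("recovery ratios are simple percent arithmetic", {
  expect_equal(recovery_ratio(900, 1000), 90)
  expect_equal(recovery_ratio(1000, 1000), 100)
  expect_equal(recovery_ratio(9, 6), 150) # latency lengthened to 150%
  expect_true(is.na(recovery_ratio(10, 0)))
})

test_that("recovery percents are invariant to rescaling all counts", {
  withr::with_seed(3, {
    test <- runif(20, 0, 500)
    base <- runif(20, 1, 500)
    for (k in c(0.5, 2, 17)) {
      expect_equal(
        recovery_ratio(k * test, k * base),
        recovery_ratio(test, base)
      )
    }
  })
})

test_that("the fatigue filter keeps only the first two recovery cycles", {
  expect_true(all(fatigue_filter(c(1, 2))))
  expect_equal(fatigue_filter(1:4), c(TRUE, TRUE, FALSE, FALSE))
  expect_true(fatigue_filter(NA)) # baseline-only exposure
})

test_that("firing patterns partition all block configurations", {
  expect_equal(firing_pattern(rep(1L, 12)), "continuous")
  blocks <- rep(0L, 12)
  blocks[c(1:4, 9)] <- 5L
  expect_equal(firing_pattern(blocks), "intermittent")
  blocks2 <- rep(0L, 12)
  blocks2[1:4] <- 5L
  expect_equal(firing_pattern(blocks2), "transient")
  expect_error(firing_pattern(rep(1L, 11)), class = "iprgclight_input_error")

  # exhaustive: every 0/1 block pattern gets exactly one label, agreeing
  # with the independently stated partition
  for (code in 0:(2^12 - 1)) {
    blocks <- as.integer(intToBits(code)[1:12])
    expect_equal(firing_pattern(blocks), oracle_pattern(blocks))
  }
})

test_that("KCl QC excludes below-threshold cells, keeping the boundary", {
  expect_false(kcl_qc(5))
  expect_true(kcl_qc(64))
  expect_true(kcl_qc(10)) # "less than 10%" excludes; exactly 10% is kept
  expect_false(kcl_qc(NA))
  expect_true(kcl_qc(NA, missing = "include"))
})

test_that("one-min recovery pairs tests with the baseline pulse", {
  # deterministic spikes: baseline 600, test 450 -> 75%
  times <- c(uniform_train(10, 60, 120), uniform_train(7.5, 240, 300))
  rec <- list(
    spikes = spike_tbl(times),
    events = dplyr::bind_rows(
      event_tbl(60, 120), event_tbl(240, 300),
      event_tbl(420, 480, kind = "kcl")
    ),
    metadata = list(duration_s = 500)
  )
  out <- one_min_recovery(rec)
  ts <- out[out$metric == "total_spikes", ]
  expect_equal(ts$percent, 75)
  expect_equal(ts$recovery_interval_min, 2)
  expect_false(ts$excluded)
})

test_that("a cell silent in the test pulse keeps its 0% point", {
  times <- uniform_train(10, 60, 120)
  rec <- list(
    spikes = spike_tbl(times),
    events = dplyr::bind_rows(event_tbl(60, 120), event_tbl(180, 240)),
    metadata = list(duration_s = 300)
  )
  out <- one_min_recovery(rec)
  ts <- out[out$metric == "total_spikes", ]
  expect_equal(ts$percent, 0)
  expect_false(ts$excluded)
})

test_that("cycles beyond the fatigue limit are excluded with a reason", {
  times <- c(
    uniform_train(10, 60, 120), uniform_train(9, 240, 300),
    uniform_train(8, 420, 480), uniform_train(7, 600, 660)
  )
  rec <- list(
    spikes = spike_tbl(times),
    events = dplyr::bind_rows(
      event_tbl(60, 120), event_tbl(240, 300),
      event_tbl(420, 480), event_tbl(600, 660)
    ),
    metadata = list(duration_s = 700)
  )
  out <- one_min_recovery(rec)
  ts <- out[out$metric == "total_spikes", ]
  expect_equal(ts$excluded, c(FALSE, FALSE, TRUE))
  expect_match(ts$reason[3], "fatigue")
})

test_that("P8 populations recover essentially completely by a 6-min interval", {
  cfg <- population_config("P8", n_retinas = 3, cells_per_retina = 15, seed = 23)
  rec <- generate_protocol_recording(cfg, protocol_one_min_recovery(6))
  out <- dplyr::filter(
    one_min_recovery(rec), !excluded, metric == "total_spikes"
  )
  # complete recovery up to Poisson counting noise: the ratio of a fully
  # dark-re-adapted test response to its own baseline centres on 100%
  expect_gte(median(out$percent, na.rm = TRUE), 95)
})

test_that("a missing baseline pulse is a protocol error", {
  rec <- list(
    spikes = spike_tbl(uniform_train(5, 0, 60)),
    events = event_tbl(0, 60),
    metadata = list(duration_s = 100)
  )
  expect_error(one_min_recovery(rec), class = "iprgclight_protocol_error")
})

test_that("the one-hour timecourse analyses blocks, recovery and KCl", {
  cfg <- population_config("P8", n_retinas = 2, cells_per_retina = 6, seed = 17)
  rec <- generate_protocol_recording(cfg, protocol_one_hour_exposure())
  tc <- one_hour_timecourse(rec)
  expect_s3_class(tc, "iprgc_timecourse")
  n_cells <- nrow(rec$cells)
  expect_equal(nrow(tc$blocks), 12 * n_cells)
  expect_setequal(unique(tc$recovery$time_min), seq(10, 60, by = 10))
  expect_equal(nrow(tc$kcl), n_cells)
  expect_true(all(tc$patterns$pattern %in%
    c("transient", "intermittent", "continuous")))
  # off-latency has no baseline within the exposure: percent undefined
  off <- tc$recovery[tc$recovery$metric == "off_latency_s", ]
  expect_true(all(is.na(off$percent)))
  expect_true(all(!is.na(off$value[!off$excluded])))
})

test_that("a recording without KCl warns and marks percents missing", {
  cfg <- population_config("P8", n_retinas = 1, cells_per_retina = 4, seed = 18)
  pr <- protocol_one_hour_exposure()
  pr$events <- pr$events[pr$events$kind != "kcl", ]
  rec <- generate_protocol_recording(cfg, pr)
  expect_warning(tc <- one_hour_timecourse(rec), class = "iprgclight_qc_warning")
  expect_true(all(is.na(tc$kcl$kcl_percent)))
})

test_that("an everywhere-silent cell yields an all-zero flagged timecourse", {
  cfg <- population_config("P8", n_retinas = 1, cells_per_retina = 3, seed = 19)
  rec <- generate_protocol_recording(cfg, protocol_one_hour_exposure())
  # silence one cell entirely
  mute <- rec$cells$cell_id[1]
  rec$spikes <- rec$spikes[rec$spikes$cell_id != mute, ]
  tc <- one_hour_timecourse(rec)
  expect_equal(sum(tc$blocks$spikes[tc$blocks$cell_id == mute]), 0)
  expect_equal(tc$patterns$pattern[tc$patterns$cell_id == mute], "transient")
  muted_rows <- tc$recovery[tc$recovery$cell_id == mute, ]
  expect_true(all(muted_rows$excluded))
  expect_true(all(muted_rows$reason == "non-responsive at baseline"))
})
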