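#' Percent recovery of a response metric
#'
#' `100 * test / baseline`. For spike-count and firing-rate metrics 100%
#' means the response regained its pre-exposure magnitude; for latency
#' metrics 100% means the pre-exposure timing (values above 100% are
#' longer latencies). A non-positive baseline leaves the ratio undefined
#' (`NA`): such cells are excluded from recovery statistics with a reason
#' code by the higher-level functions.
#'
#' @param test metric value during the test response.
#' @param baseline metric value during the baseline response.
#' @return percent recovery (>= 0, may exceed 100), or `NA`.
#' @export
recovery_ratio <- function(test, baseline) {
  ifelse(
    is.na(baseline) | baseline <= 0,
    NA_real_,
    100 * test / baseline
  )
}

#' Fatigue filter for repeated recovery cycles
#'
#' Cells from older retinas fatigue after repeated exposure cycles,
#' recovering to only 40-60% of baseline after 3-4 trials regardless of
#' the interval; only data from the first `max_cycles` recovery cycles
#' are therefore analysed.
#'
#' @param cycle integer vector of recovery-cycle indices (1 = first test
#'   after baseline; 0 or NA = the baseline pulse itself).
#' @param max_cycles largest cycle retained (default 2).
#' @return logical vector: keep this measurement?
#' @export
fatigue_filter <- function(cycle, max_cycles = 2) {
  is.na(cycle) | cycle <= max_cycles
}

RECOVERY_METRICS <- c(
  "total_spikes", "peak_firing_hz", "on_latency_s", "off_latency_s",
  "initial_spikes", "steady_state_spikes"
)

#' Recovery curve for the 1-min exposure protocol
#'
#' Pairs every test pulse of a [protocol_one_min_recovery()] recording
#' with the first (baseline) pulse and reports, per cell and metric, the
#' percent recovery at each dark interval. Cells that were non-responsive
#' during the baseline pulse are excluded (percent recovery is undefined),
#' and measurements beyond the fatigue limit are dropped.
#'
#' @param recording an `iprgc_recording` (or a list with `spikes` and
#'   `events`).
#' @param bin_width,silence_s feature-extraction parameters.
#' @param max_cycles fatigue limit (see [fatigue_filter()]).
#' @return tidy tibble: `retina_id, cell_id, cycle,
#'   recovery_interval_min, metric, value, baseline, percent, excluded,
#'   reason`.
#' @export
one_min_recovery <- function(recording, bin_width = 1, silence_s = 5,
                             max_cycles = 2) {
  feats <- recording_features(recording, bin_width, silence_s)
  events <- validate_event_table(recording$events)
  light <- events %>% filter(.data$kind == "light")
  if (nrow(light) < 2) {
    abort("Protocol error: need a baseline pulse plus at least one test pulse.",
      class = "iprgclight_protocol_error"
    )
  }
  baseline <- feats %>% filter(.data$epoch == 1)
  tests <- feats %>% filter(.data$epoch > 1)
  intervals <- (light$onset_s[-1] - light$offset_s[-nrow(light)]) / 60

  out <- tests %>%
    mutate(cycle = .data$epoch - 1L) %>%
    percentify_with_meta(baseline) %>%
    mutate(
      recovery_interval_min = intervals[.data$cycle],
      excluded = case_when(
        !.data$baseline_responsive ~ TRUE,
        is.na(.data$baseline) | .data$baseline <= 0 ~ TRUE,
        !fatigue_filter(.data$cycle, max_cycles) ~ TRUE,
        TRUE ~ FALSE
      ),
      reason = case_when(
        !.data$baseline_responsive ~ "non-responsive at baseline",
        is.na(.data$baseline) | .data$baseline <= 0 ~ "zero baseline metric",
        !fatigue_filter(.data$cycle, max_cycles) ~
          sprintf("beyond fatigue limit (%d cycles)", as.integer(max_cycles)),
        TRUE ~ NA_character_
      )
    ) %>%
    select(
      "retina_id", "cell_id", "cycle", "recovery_interval_min",
      "metric", "value", "baseline", "percent", "excluded", "reason"
    )
  out
}

percentify_with_meta <- function(test_features, baseline_features) {
  responsive <- baseline_features %>%
    select("cell_id", baseline_responsive = "responsive")
  test_long <- test_features %>%
    select(
      "retina_id", "cell_id", "cycle", all_of(RECOVERY_METRICS)
    ) %>%
    tidyr::pivot_longer(all_of(RECOVERY_METRICS),
      names_to = "metric", values_to = "value"
    )
  base_long <- baseline_features %>%
    select("cell_id", all_of(RECOVERY_METRICS)) %>%
    tidyr::pivot_longer(all_of(RECOVERY_METRICS),
      names_to = "metric", values_to = "baseline"
    )
  test_long %>%
    left_join(base_long, by = c("cell_id", "metric")) %>%
    left_join(responsive, by = "cell_id") %>%
    mutate(percent = recovery_ratio(.data$value, .data$baseline))
}

#' Exposure and recovery timecourse for the 1-h protocol
#'
#' Analyses a [protocol_one_hour_exposure()] recording per cell:
#' * spike counts in 1-min blocks taken every 5 min across the 1-h
#'   exposure (block starts at minutes 0, 5, ..., 55);
#' * the firing pattern over the exposure (transient / intermittent /
#'   continuous, see [firing_pattern()]);
#' * percent recovery of the six response metrics at every post-exposure
#'   test pulse, relative to the first minute of the exposure (the
#'   per-cell baseline). The baseline minute has no light offset, so
#'   off-latency has no baseline and its recovery is reported as the
#'   absolute value with `percent = NA`;
#' * the KCl health check: firing during the terminal KCl epoch as a
#'   percent of first-minute firing. A missing KCl event yields a QC
#'   warning and `NA` percents.
#'
#' @param recording an `iprgc_recording` of the 1-h protocol.
#' @param bin_width,silence_s feature-extraction parameters.
#' @return list of tibbles: `blocks` (cell x block spike counts),
#'   `patterns` (cell firing pattern), `recovery` (tidy percent-recovery
#'   rows incl. `time_min`), `kcl` (cell KCl percent). Class
#'   `iprgc_timecourse`.
#' @export
one_hour_timecourse <- function(recording, bin_width = 1, silence_s = 5) {
  events <- validate_event_table(recording$events)
  spikes <- validate_spike_table(recording$spikes)
  exp_idx <- which(events$kind == "light" &
    (events$offset_s - events$onset_s) >= 1800)
  if (length(exp_idx) != 1) {
    abort("Expected exactly one long (>= 30 min) exposure epoch.",
      class = "iprgclight_protocol_error"
    )
  }
  exp_on <- events$onset_s[exp_idx]
  exp_off <- events$offset_s[exp_idx]
  cells <- recording_cells(recording, spikes)
  by_cell <- split(spikes$spike_time_s, spikes$cell_id)

  block_starts <- exp_on + 300 * (0:11)
  blocks <- purrr::map_dfr(seq_len(nrow(cells)), function(i) {
    st <- by_cell[[cells$cell_id[i]]] %||% numeric(0)
    tibble(
      retina_id = cells$retina_id[i], cell_id = cells$cell_id[i],
      block = 1:12, block_start_min = (block_starts - exp_on) / 60,
      spikes = vapply(
        block_starts,
        function(b) sum(st >= b & st < b + 60), integer(1)
      )
    )
  })

  patterns <- blocks %>%
    group_by(.data$retina_id, .data$cell_id) %>%
    summarise(pattern = firing_pattern(.data$spikes), .groups = "drop")

  # baseline: minute 1 of the exposure, measured as epoch features over
  # [exp_on, exp_on + 60); the light continues so there is no off tail
  baseline <- purrr::map_dfr(seq_len(nrow(cells)), function(i) {
    st <- by_cell[[cells$cell_id[i]]] %||% numeric(0)
    minute1 <- st[st >= exp_on & st < exp_on + 60]
    psth <- compute_psth(minute1, exp_on, exp_on + 60, bin_width)
    tibble(
      retina_id = cells$retina_id[i], cell_id = cells$cell_id[i],
      on_latency_s = if (length(minute1) > 0) {
        psth$bin_mid[which.max(psth$count)] - exp_on
      } else {
        NA_real_
      },
      peak_firing_hz = max(psth$rate),
      off_latency_s = NA_real_,
      total_spikes = length(minute1),
      initial_spikes = sum(minute1 < exp_on + 30),
      steady_state_spikes = sum(minute1 >= exp_on + 30),
      responsive = length(minute1) > 0
    )
  })

  pulse_idx <- which(events$kind == "light" & events$onset_s > exp_off)
  feats <- response_features(spikes, events,
    t_end = max(events$offset_s) + 60,
    bin_width = bin_width, silence_s = silence_s,
    cells = cells[c("retina_id", "cell_id")]
  )
  pulse_epochs <- match(pulse_idx, which(events$kind == "light"))
  pulse_times <- tibble(
    cycle = seq_along(pulse_idx),
    time_min = (events$onset_s[pulse_idx] - exp_off) / 60
  )
  recovery <- feats %>%
    filter(.data$epoch %in% pulse_epochs) %>%
    mutate(cycle = match(.data$epoch, pulse_epochs)) %>%
    percentify_with_meta(baseline) %>%
    left_join(pulse_times, by = "cycle") %>%
    mutate(
      excluded = !.data$baseline_responsive |
        (is.na(.data$baseline) & .data$metric != "off_latency_s"),
      reason = case_when(
        !.data$baseline_responsive ~ "non-responsive at baseline",
        is.na(.data$baseline) & .data$metric != "off_latency_s" ~
          "zero baseline metric",
        TRUE ~ NA_character_
      )
    ) %>%
    select(
      "retina_id", "cell_id", "cycle", "time_min", "metric",
      "value", "baseline", "percent", "excluded", "reason"
    )

  kcl_idx <- which(events$kind == "kcl")
  if (length(kcl_idx) == 0) {
    warn("QC: recording has no terminal KCl event; kcl_percent is missing.",
      class = "iprgclight_qc_warning"
    )
    kcl <- baseline %>%
      select("retina_id", "cell_id") %>%
      mutate(kcl_spikes = NA_integer_, kcl_percent = NA_real_)
  } else {
    k_on <- events$onset_s[kcl_idx[1]]
    k_off <- events$offset_s[kcl_idx[1]]
    kcl <- purrr::map_dfr(seq_len(nrow(cells)), function(i) {
      st <- by_cell[[cells$cell_id[i]]] %||% numeric(0)
      n_kcl <- sum(st >= k_on & st < k_off)
      tibble(
        retina_id = cells$retina_id[i], cell_id = cells$cell_id[i],
        kcl_spikes = n_kcl,
        kcl_percent = recovery_ratio(n_kcl, baseline$total_spikes[i])
      )
    })
  }

  structure(
    list(
      blocks = blocks, patterns = patterns, baseline = baseline,
      recovery = recovery, kcl = kcl
    ),
    class = "iprgc_timecourse"
  )
}

recording_features <- function(recording, bin_width, silence_s) {
  response_features(
    recording$spikes, recording$events,
    t_end = recording$metadata$duration_s %||% NULL,
    bin_width = bin_width, silence_s = silence_s,
    cells = recording_cells(recording, recording$spikes)[
      c("retina_id", "cell_id")
    ]
  )
}

recording_cells <- function(recording, spikes) {
  if (!is.null(recording$cells) && nrow(recording$cells) > 0) {
    recording$cells[c("retina_id", "cell_id")]
  } else {
    distinct(spikes, .data$retina_id, .data$cell_id)
  }
}

#' Firing pattern over a 1-h exposure
#'
#' Classifies a cell's firing across the twelve 1-min exposure blocks:
#' `continuous` = spikes in every block; `intermittent` = at least one
#' spiking block at or after the 30-min mark (blocks 7-12) but not all
#' blocks; `transient` = otherwise (firing confined to the early
#' exposure). The partition is total and exclusive.
#'
#' @param block_spikes integer vector of spike counts for the 12 blocks
#'   (block starts at minutes 0, 5, ..., 55).
#' @return one of "continuous", "intermittent", "transient".
#' @export
firing_pattern <- function(block_spikes) {
  if (length(block_spikes) != 12 || any(block_spikes < 0)) {
    abort("`block_spikes` must be 12 non-negative counts.",
      class = "iprgclight_input_error"
    )
  }
  if (all(block_spikes > 0)) {
    "continuous"
  } else if (any(block_spikes[7:12] > 0)) {
    "intermittent"
  } else {
    "transient"
  }
}

#' KCl health check
#'
#' Cells firing during terminal KCl depolarization at less than
#' `threshold` percent of their first-minute light response are judged
#' unhealthy and excluded from analysis (a response of exactly the
#' threshold is kept). A missing KCl measurement is excluded by default.
#'
#' @param kcl_percent KCl firing as percent of first-minute firing.
#' @param threshold exclusion threshold in percent (default 10).
#' @param missing what to do with `NA` values: "exclude" (default) or
#'   "include".
#' @return logical vector: keep this cell?
#' @export
kcl_qc <- function(kcl_percent, threshold = 10,
                   missing = c("exclude", "include")) {
  missing <- match.arg(missing)
  keep_na <- missing == "include"
  ifelse(is.na(kcl_percent), keep_na, kcl_percent >= threshold)
}
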