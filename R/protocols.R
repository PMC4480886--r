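#' Stimulus protocols
#'
#' Constructors for the light-exposure protocols used throughout the
#' package. Each returns an `iprgc_protocol`: a validated stimulus-event
#' table (see [read_event_table()] for the column convention) plus a
#' recording duration. All light pulses are 480 nm; irradiance is given as
#' log10(photons cm^-2 s^-1).
#'
#' * `protocol_one_min_recovery()`: a 1-min baseline pulse at IR 13.6,
#'   then `n_cycles` repeats of (dark interval of `interval_min` minutes,
#'   1-min test pulse with the same light), then a terminal KCl
#'   depolarization as a health check.
#' * `protocol_one_hour_exposure()`: a continuous 1-h pulse at IR 13.6,
#'   1-h of dark recovery probed with a 1-min test pulse beginning 10 min
#'   into recovery and every 10 min thereafter, then terminal KCl. The
#'   `probe_ir` argument lets the recovery probes be brighter than the
#'   exposure light (e.g. +1 log unit) to test adaptation against bleaching.
#' * `protocol_subtyping()`: the classification pulses. P8 cells receive a
#'   1-min pulse at IR 12.0 followed, after dark re-adaptation, by a 1-min
#'   pulse at IR 13.6. Post-eye-opening cells receive a single 1-min pulse
#'   at IR 13.0.
#' * `protocol_single_pulse()`: one 1-min pulse, used for age-specific
#'   response-dynamics cohorts.
#'
#' @param interval_min dark recovery interval in minutes (1 to 10).
#' @param n_cycles number of recovery cycles (interval + test pulse).
#' @param ir,exposure_ir,probe_ir log10 irradiance of the pulses.
#' @param age_group "P8" or a post-eye-opening age ("P15"/"P30").
#' @param lead_in_s initial darkness before the first pulse (s).
#' @param wavelength_nm stimulus wavelength.
#' @return an `iprgc_protocol` object.
#' @name protocols
NULL

new_protocol <- function(name, events, duration_s) {
  events <- validate_event_table(events)
  if (max(events$offset_s) > duration_s) {
    abort("Protocol events extend past the recording duration.",
      class = "iprgclight_input_error"
    )
  }
  structure(
    list(name = name, events = events, duration_s = duration_s),
    class = "iprgc_protocol"
  )
}

light_event <- function(onset, offset, ir, wavelength_nm = 480) {
  tibble(
    kind = "light", onset_s = onset, offset_s = offset,
    ir = ir, wavelength_nm = wavelength_nm
  )
}

kcl_event <- function(onset, offset) {
  tibble(
    kind = "kcl", onset_s = onset, offset_s = offset,
    ir = NA_real_, wavelength_nm = NA_real_
  )
}

#' @rdname protocols
#' @export
protocol_one_min_recovery <- function(interval_min = 1, n_cycles = 1,
                                      ir = 13.6, lead_in_s = 60,
                                      wavelength_nm = 480) {
  if (interval_min <= 0 || n_cycles < 1) {
    abort("Need interval_min > 0 and n_cycles >= 1.",
      class = "iprgclight_input_error"
    )
  }
  events <- light_event(lead_in_s, lead_in_s + 60, ir, wavelength_nm)
  t <- lead_in_s + 60
  for (k in seq_len(n_cycles)) {
    t <- t + interval_min * 60
    events <- bind_rows(events, light_event(t, t + 60, ir, wavelength_nm))
    t <- t + 60
  }
  events <- bind_rows(events, kcl_event(t + 120, t + 180))
  new_protocol(
    sprintf("one_min_recovery_%gmin", interval_min),
    events, t + 180 + 60
  )
}

#' @rdname protocols
#' @export
protocol_one_hour_exposure <- function(exposure_ir = 13.6, probe_ir = exposure_ir,
                                       lead_in_s = 60, wavelength_nm = 480) {
  on <- lead_in_s
  events <- light_event(on, on + 3600, exposure_ir, wavelength_nm)
  recovery_start <- on + 3600
  for (k in 1:6) {
    p <- recovery_start + 600 * k
    events <- bind_rows(events, light_event(p, p + 60, probe_ir, wavelength_nm))
  }
  kcl_on <- recovery_start + 600 * 6 + 60 + 120
  events <- bind_rows(events, kcl_event(kcl_on, kcl_on + 60))
  new_protocol("one_hour_exposure", events, kcl_on + 120)
}

#' @rdname protocols
#' @export
protocol_subtyping <- function(age_group = "P8", lead_in_s = 60,
                               wavelength_nm = 480) {
  age_group <- match.arg(age_group, c("P8", "P15", "P30"))
  if (age_group == "P8") {
    # dim pulse first, long dark gap, then the bright reference pulse
    e1 <- light_event(lead_in_s, lead_in_s + 60, 12.0, wavelength_nm)
    on2 <- lead_in_s + 60 + 600
    e2 <- light_event(on2, on2 + 60, 13.6, wavelength_nm)
    new_protocol("subtyping_p8", bind_rows(e1, e2), on2 + 60 + 240)
  } else {
    e1 <- light_event(lead_in_s, lead_in_s + 60, 13.0, wavelength_nm)
    new_protocol("subtyping_peo", e1, lead_in_s + 60 + 240)
  }
}

#' @rdname protocols
#' @export
protocol_single_pulse <- function(ir = 13.6, lead_in_s = 60,
                                  wavelength_nm = 480) {
  new_protocol(
    "single_pulse",
    light_event(lead_in_s, lead_in_s + 60, ir, wavelength_nm),
    lead_in_s + 60 + 240
  )
}

#' @export
print.iprgc_protocol <- function(x, ...) {
  cat("<iprgc_protocol>", x$name, "\n")
  cat("  duration:", x$duration_s, "s;", nrow(x$events), "events\n")
  invisible(x)
}
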