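#' Irradiance sensitivity of a simulated cell
#'
#' Naka-Rushton (Hill-type) sensitivity on the log10 irradiance axis:
#' \deqn{S(ir) = 1 / (1 + 10^{hill\_n (ir\_half + s\_shift - ir)})}
#' giving the fraction of maximal drive a stimulus of log irradiance `ir`
#' produces. `s_shift` is the adaptation-induced rightward shift of the
#' half-max point (log units): an adapted cell behaves as if every light
#' were dimmer.
#'
#' @param ir log10 irradiance (photons cm^-2 s^-1); must be finite.
#' @param ir_half log10 irradiance of half-maximal response.
#' @param hill_n sensitivity slope (> 0).
#' @param s_shift adaptation shift in log units (>= 0).
#' @return fraction of maximal drive in \[0, 1\], monotone nondecreasing
#'   in `ir`.
#' @examples
#' sensitivity(12.0, ir_half = 12.0, hill_n = 1) # 0.5 by definition
#' @export
sensitivity <- function(ir, ir_half, hill_n, s_shift = 0) {
  if (any(!is.finite(ir))) {
    abort("`ir` must be finite.", class = "iprgclight_input_error")
  }
  if (any(hill_n <= 0)) {
    abort("`hill_n` must be > 0.", class = "iprgclight_input_error")
  }
  if (any(s_shift < 0)) {
    abort("`s_shift` must be >= 0.", class = "iprgclight_input_error")
  }
  1 / (1 + 10^(hill_n * (ir_half + s_shift - ir)))
}

# Core rate-model integrator, vectorised over cells.
#
# Discrete exponential-update integration of the firing-rate model on a
# regular grid of width dt. Per cell states: adaptation gain a in [0,1]
# (1 = dark adapted) and firing rate r (Hz). Within a light epoch, a cell
# is driven only after a sensitivity-dependent onset delay
# d = lat_scale * (1/S0 - 1) computed at epoch onset; while driven:
#   a   -> relaxes toward its floor with time constant adapt_tau / S(t)
#          (dim lights adapt slowly),
#   r   -> relaxes toward r_max * S(t) * a + baseline with latency_tau,
# where S(t) uses the instantaneous shift s_shift = shift_gain * (1 - a).
# Outside light (and before the delay elapses), a recovers toward 1 with
# recover_tau and r decays toward baseline with off_tau. A KCl epoch
# clamps the drive to kcl_rate (1-s rise), bypassing phototransduction.
#
# Returns list(time, rate) with rate a steps x cells matrix. Deterministic.
simulate_rate_matrix <- function(cells, events, dt = 0.1, duration = NULL) {
  events <- validate_event_table(events)
  duration <- duration %||%
    (if (nrow(events) > 0) max(events$offset_s) + 60 else 60)
  if (dt <= 0 || duration <= 0) {
    abort("Need dt > 0 and duration > 0.", class = "iprgclight_input_error")
  }
  if (nrow(events) > 0 && max(events$offset_s) > duration) {
    abort("Events must lie within [0, duration].",
      class = "iprgclight_input_error"
    )
  }

  n_steps <- floor(duration / dt)
  time <- (seq_len(n_steps) - 1) * dt
  n <- nrow(cells)
  rate <- matrix(0, nrow = n_steps, ncol = n)
  if (n == 0) {
    return(list(time = time, rate = rate))
  }

  # map each step to an event row (0 = darkness); events are non-overlapping
  ev_of_step <- integer(n_steps)
  for (i in seq_len(nrow(events))) {
    idx <- which(time >= events$onset_s[i] & time < events$offset_s[i])
    ev_of_step[idx] <- i
  }

  a <- rep(1, n)
  r <- cells$baseline_rate
  drive_start <- rep(Inf, n) # absolute time each cell's drive begins
  cur_ev <- 0L
  a_floor <- cells$a_floor %||% rep(0, n)

  exp_rec <- exp(-dt / cells$recover_tau)
  exp_off <- exp(-dt / cells$off_tau)
  exp_lat <- exp(-dt / cells$latency_tau)
  exp_kcl <- exp(-dt / 1) # fixed 1-s KCl rise

  for (s in seq_len(n_steps)) {
    ev <- ev_of_step[s]
    if (ev != cur_ev) {
      cur_ev <- ev
      if (ev > 0 && events$kind[ev] == "light") {
        s0 <- sensitivity(
          events$ir[ev], cells$ir_half, cells$hill_n,
          cells$shift_gain * (1 - a)
        )
        drive_start <- events$onset_s[ev] + cells$lat_scale * (1 / s0 - 1)
      } else {
        drive_start <- rep(Inf, n)
      }
    }
    if (ev > 0 && events$kind[ev] == "kcl") {
      a <- 1 + (a - 1) * exp_rec
      r <- cells$kcl_rate + (r - cells$kcl_rate) * exp_kcl
    } else if (ev > 0) {
      driven <- time[s] >= drive_start
      sens <- sensitivity(
        events$ir[ev], cells$ir_half, cells$hill_n,
        cells$shift_gain * (1 - a)
      )
      a_next <- ifelse(
        driven,
        a_floor + (a - a_floor) * exp(-dt * sens / cells$adapt_tau),
        1 + (a - 1) * exp_rec
      )
      target <- cells$baseline_rate + cells$r_max * sens * a_next
      r <- ifelse(
        driven,
        target + (r - target) * exp_lat,
        cells$baseline_rate + (r - cells$baseline_rate) * exp_off
      )
      a <- a_next
    } else {
      a <- 1 + (a - 1) * exp_rec
      r <- cells$baseline_rate + (r - cells$baseline_rate) * exp_off
    }
    rate[s, ] <- r
  }
  rate[rate < 0] <- 0
  list(time = time, rate = rate)
}

#' Deterministic firing-rate trace for one simulated cell
#'
#' Integrates the latency/adaptation/recovery rate model for a single cell
#' over a stimulus-event table. See the package vignette for the model.
#'
#' @param params one-row data frame of cell parameters (as one row of
#'   [simulate_population()] output, or of [cell_param_defaults()]).
#' @param events stimulus-event table (validated; non-overlapping).
#' @param dt integration step (s).
#' @param duration recording length (s); defaults to last offset + 60 s.
#' @return tibble with columns `time_s` and `rate_hz`; rate is >= 0
#'   everywhere and the trace is deterministic given its inputs.
#' @export
simulate_rate_trace <- function(params, events, dt = 0.1, duration = NULL) {
  params <- as_tibble(params)
  if (nrow(params) != 1) {
    abort("`params` must describe exactly one cell.",
      class = "iprgclight_input_error"
    )
  }
  params <- fill_sim_defaults(params)
  out <- simulate_rate_matrix(params, events, dt = dt, duration = duration)
  tibble(time_s = out$time, rate_hz = out$rate[, 1])
}

# columns that have convenient defaults when a caller passes a bare
# parameter row (e.g. straight from cell_param_defaults())
fill_sim_defaults <- function(cells) {
  for (col in c("a_floor", "shift_gain", "kcl_rate", "lat_scale")) {
    if (!col %in% names(cells)) cells[[col]] <- 0
  }
  cells
}

#' Sample spike times from a rate trace
#'
#' Inhomogeneous Poisson sampling on the integration grid: each step of
#' width `dt` contributes `Poisson(rate * dt)` spikes placed uniformly
#' within the step, so the expected total count equals `sum(rate * dt)`.
#' No refractory period is imposed; at the firing rates modelled here
#' (tens of Hz) refractory corrections are negligible at 1-s analysis bins.
#'
#' @param rate numeric vector of rates (Hz), all >= 0.
#' @param dt step width (s).
#' @param seed integer seed; identical seeds give identical spike trains.
#' @param t0 time of the first step's left edge (s).
#' @return sorted numeric vector of spike times (s).
#' @export
sample_spike_train <- function(rate, dt, seed, t0 = 0) {
  if (any(!is.finite(rate)) || any(rate < 0)) {
    abort("Rates must be finite and >= 0.", class = "iprgclight_input_error")
  }
  withr::with_seed(as.integer(seed), {
    counts <- rpois(length(rate), rate * dt)
    total <- sum(counts)
    if (total == 0) {
      return(numeric(0))
    }
    starts <- t0 + (seq_along(rate) - 1) * dt
    # quantised to 1 us: the canonical file precision
    sort(round(rep(starts, counts) + runif(total) * dt, 6))
  })
}

#' Simulate a full multi-cell protocol recording
#'
#' Draws a population of cells, integrates every cell's rate trace over the
#' protocol's stimulus log, and samples spikes. The returned recording
#' bundles the spike table, the stimulus-event table (including the
#' terminal KCl depolarization for the recovery protocols) and the
#' generating per-cell parameters.
#'
#' The `chromophore_supplement` flag models retinoid (9-cis-retinal)
#' supplementation during recovery. Melanopsin is a bistable,
#' bleach-resistant pigment, so chromophore availability does not limit
#' recovery in this model and the flag changes no output; it exists so that
#' supplementation "experiments" can be scripted against the simulator.
#'
#' @param config a [population_config()].
#' @param protocol an `iprgc_protocol` (see [protocols]).
#' @param params parameter table, defaults to [cell_param_defaults()].
#' @param dt integration step (s).
#' @param chromophore_supplement logical; see Details.
#' @return an `iprgc_recording`: list with `spikes`, `events`, `cells`,
#'   and `metadata`.
#' @export
generate_protocol_recording <- function(config, protocol,
                                        params = cell_param_defaults(),
                                        dt = 0.1,
                                        chromophore_supplement = FALSE) {
  stopifnot(inherits(config, "population_config"))
  if (!inherits(protocol, "iprgc_protocol")) {
    abort("Unknown protocol: pass an object built by a protocol_*() constructor.",
      class = "iprgclight_input_error"
    )
  }
  cells <- simulate_population(config, params)
  traces <- simulate_rate_matrix(cells, protocol$events,
    dt = dt, duration = protocol$duration_s
  )
  spike_list <- lapply(seq_len(nrow(cells)), function(j) {
    sample_spike_train(traces$rate[, j], dt, derive_seed(config$seed, 1000L + j))
  })
  spikes <- tibble(
    retina_id = rep(cells$retina_id, lengths(spike_list)),
    cell_id = rep(cells$cell_id, lengths(spike_list)),
    spike_time_s = unlist(spike_list) %||% numeric(0)
  )
  structure(
    list(
      spikes = validate_spike_table(spikes),
      events = protocol$events,
      cells = cells,
      metadata = list(
        age_group = config$age_group,
        protocol = protocol$name,
        seed = config$seed,
        dt = dt,
        duration_s = protocol$duration_s,
        chromophore_supplement = chromophore_supplement
      )
    ),
    class = "iprgc_recording"
  )
}

#' @export
print.iprgc_recording <- function(x, ...) {
  cat(
    "<iprgc_recording>", x$metadata$protocol, "-", x$metadata$age_group, "\n",
    " cells:", nrow(x$cells), " spikes:", nrow(x$spikes),
    " duration:", x$metadata$duration_s, "s\n"
  )
  invisible(x)
}
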