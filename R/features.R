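#' Peri-stimulus time histogram
#'
#' Bins spike times into half-open bins \code{[edge_i, edge_{i+1})} of
#' width `bin_width` over \code{[t0, t1)}. If the window length is not a
#' multiple of the bin width, the trailing partial bin is dropped.
#'
#' @param spike_times numeric vector of spike times (s).
#' @param t0,t1 window bounds (s), `t1 > t0`.
#' @param bin_width bin width (s), > 0.
#' @return tibble with `bin_start`, `bin_end`, `bin_mid`, `count`, `rate`
#'   (Hz = count / bin_width).
#' @export
compute_psth <- function(spike_times, t0, t1, bin_width = 1) {
  if (bin_width <= 0 || t1 <= t0) {
    abort("Need bin_width > 0 and t1 > t0.", class = "iprgclight_input_error")
  }
  n_bins <- floor((t1 - t0) / bin_width + 1e-9)
  if (n_bins < 1) {
    abort("Window shorter than one bin.", class = "iprgclight_input_error")
  }
  edges <- t0 + (0:n_bins) * bin_width
  inside <- spike_times >= t0 & spike_times < edges[n_bins + 1]
  idx <- floor((spike_times[inside] - t0) / bin_width) + 1
  idx[idx > n_bins] <- n_bins # guard against floating-point edge cases
  counts <- tabulate(idx, nbins = n_bins)
  tibble(
    bin_start = edges[1:n_bins],
    bin_end = edges[2:(n_bins + 1)],
    bin_mid = edges[1:n_bins] + bin_width / 2,
    count = counts,
    rate = counts / bin_width
  )
}

#' On-latency of a light response
#'
#' Time from lights-on to the peak firing rate, operationalised as the
#' center of the maximum-count PSTH bin within the light epoch; ties are
#' broken toward the earliest bin. A cell with no spikes during the epoch
#' has no defined latency and returns `NA` (non-responsive).
#'
#' @param spike_times spike times (s).
#' @param onset,offset light epoch bounds (s).
#' @param bin_width PSTH bin width (s), default 1.
#' @return latency in seconds, or `NA_real_` for a non-responsive cell.
#' @export
on_latency <- function(spike_times, onset, offset, bin_width = 1) {
  psth <- compute_psth(spike_times, onset, offset, bin_width)
  if (sum(psth$count) == 0) {
    return(NA_real_)
  }
  psth$bin_mid[which.max(psth$count)] - onset
}

#' Off-latency of a light response
#'
#' Persistence of firing after lights-off: the time from light offset to
#' the last spike preceding the first fully spike-free window of
#' `silence_s` seconds after offset. With no post-offset spikes before the
#' first silent window the off-latency is 0. If the observation window
#' ends before any silent window is seen, the value is right-censored:
#' `off_latency` is then the elapsed time to the last observed spike and
#' `censored` is `TRUE`.
#'
#' @param spike_times spike times (s).
#' @param offset light offset (s).
#' @param t_end end of the usable observation window (s): the recording
#'   end or the onset of the next stimulus epoch.
#' @param silence_s length of the spike-free window that terminates a
#'   response (s); 5 s by default, short against reported off-latencies.
#' @return tibble with `off_latency` (s) and `censored` (logical).
#' @export
off_latency <- function(spike_times, offset, t_end, silence_s = 5) {
  if (t_end <= offset) {
    abort("`t_end` must exceed `offset`.", class = "iprgclight_input_error")
  }
  post <- sort(spike_times[spike_times > offset & spike_times <= t_end])
  pts <- c(offset, post)
  gaps <- diff(c(pts, t_end))
  silent <- which(gaps >= silence_s)
  if (length(silent) == 0) {
    return(tibble(
      off_latency = if (length(post) > 0) max(post) - offset else 0,
      censored = TRUE
    ))
  }
  tibble(off_latency = pts[silent[1]] - offset, censored = FALSE)
}

#' Per-response features for every cell and light epoch
#'
#' Computes the six response metrics for each (cell, light epoch) pair of
#' a recording: on-latency, peak firing rate, off-latency, and the total,
#' initial (first 30 s) and steady-state (second 30 s) spike counts. The
#' total count includes the post-offset tail up to response termination
#' (offset + off-latency); firing after light-off is part of the response.
#' Cells with no spikes during an epoch are flagged non-responsive
#' (`responsive = FALSE`, latency metrics `NA`).
#'
#' @param spikes spike table (retina_id, cell_id, spike_time_s).
#' @param events stimulus-event table; only light epochs yield features.
#' @param t_end recording end (s); defaults to the last event offset plus
#'   the largest observed spike time margin.
#' @param bin_width PSTH bin width (s).
#' @param silence_s off-latency silence criterion (s).
#' @param cells optional tibble (retina_id, cell_id) of all recorded
#'   cells, so that cells that never spiked still appear (flagged
#'   non-responsive); defaults to the cells present in `spikes`.
#' @return tibble with one row per cell x light epoch:
#'   `retina_id, cell_id, epoch, onset_s, ir, on_latency_s,
#'   peak_firing_hz, off_latency_s, off_censored, total_spikes,
#'   initial_spikes, steady_state_spikes, responsive`.
#' @export
response_features <- function(spikes, events, t_end = NULL,
                              bin_width = 1, silence_s = 5, cells = NULL) {
  spikes <- validate_spike_table(spikes)
  events <- validate_event_table(events)
  t_end <- t_end %||% max(
    events$offset_s,
    if (nrow(spikes) > 0) max(spikes$spike_time_s) else 0
  )
  light_idx <- which(events$kind == "light")
  cells <- cells %||% distinct(spikes, .data$retina_id, .data$cell_id)
  if (nrow(cells) == 0 || length(light_idx) == 0) {
    return(empty_features())
  }

  by_cell <- split(spikes$spike_time_s, spikes$cell_id)
  purrr::map_dfr(seq_len(nrow(cells)), function(i) {
    st <- by_cell[[cells$cell_id[i]]] %||% numeric(0)
    purrr::map_dfr(seq_along(light_idx), function(k) {
      e <- light_idx[k]
      onset <- events$onset_s[e]
      offset <- events$offset_s[e]
      # tail observation stops at the next epoch (or recording end)
      next_onset <- if (e < nrow(events)) events$onset_s[e + 1] else t_end
      epoch_spikes <- sum(st >= onset & st < offset)
      if (epoch_spikes == 0) {
        return(tibble(
          retina_id = cells$retina_id[i], cell_id = cells$cell_id[i],
          epoch = k, onset_s = onset, ir = events$ir[e],
          on_latency_s = NA_real_, peak_firing_hz = 0,
          off_latency_s = NA_real_, off_censored = FALSE,
          total_spikes = 0L, initial_spikes = 0L, steady_state_spikes = 0L,
          responsive = FALSE
        ))
      }
      psth <- compute_psth(st, onset, offset, bin_width)
      off <- off_latency(st, offset, next_onset, silence_s)
      total_end <- if (off$censored) next_onset else offset + off$off_latency
      tibble(
        retina_id = cells$retina_id[i], cell_id = cells$cell_id[i],
        epoch = k, onset_s = onset, ir = events$ir[e],
        on_latency_s = psth$bin_mid[which.max(psth$count)] - onset,
        peak_firing_hz = max(psth$rate),
        off_latency_s = off$off_latency,
        off_censored = off$censored,
        total_spikes = sum(st >= onset & st <= total_end),
        initial_spikes = sum(st >= onset & st < onset + 30),
        steady_state_spikes = sum(st >= onset + 30 & st < onset + 60),
        responsive = TRUE
      )
    })
  })
}

empty_features <- function() {
  tibble(
    retina_id = character(0), cell_id = character(0), epoch = integer(0),
    onset_s = numeric(0), ir = numeric(0), on_latency_s = numeric(0),
    peak_firing_hz = numeric(0), off_latency_s = numeric(0),
    off_censored = logical(0), total_spikes = integer(0),
    initial_spikes = integer(0), steady_state_spikes = integer(0),
    responsive = logical(0)
  )
}
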