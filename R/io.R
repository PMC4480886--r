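#' Read and write spike tables
#'
#' Spike tables are plain UTF-8 CSV files with the fixed header
#' `retina_id,cell_id,spike_time_s`. Spike times are decimal seconds from
#' recording start; within each cell they must be nondecreasing and
#' non-negative. Validation is total: a file that fails any check loads
#' nothing.
#'
#' @param path file path.
#' @param spikes a spike tibble with the columns above.
#' @return `read_spike_table()` returns a validated tibble;
#'   `write_spike_table()` returns `path` invisibly.
#' @export
read_spike_table <- function(path) {
  tbl <- readr::read_csv(
    path,
    col_types = readr::cols(
      retina_id = readr::col_character(),
      cell_id = readr::col_character(),
      spike_time_s = readr::col_double()
    ),
    show_col_types = FALSE, progress = FALSE
  )
  check_columns(tbl, c("retina_id", "cell_id", "spike_time_s"), path)
  validate_spike_table(tbl)
}

#' @rdname read_spike_table
#' @details The canonical writer quantises spike times to 1 microsecond,
#'   far below any physiological timescale here, so that write/read
#'   cycles are byte-stable.
#' @export
write_spike_table <- function(spikes, path) {
  spikes <- validate_spike_table(spikes)
  out <- spikes[c("retina_id", "cell_id", "spike_time_s")]
  out$spike_time_s <- round(out$spike_time_s, 6)
  readr::write_csv(out, path, progress = FALSE)
  invisible(path)
}

#' Validate a spike table in memory
#'
#' @param spikes tibble with columns retina_id, cell_id, spike_time_s.
#' @return the validated tibble (invisibly usable in pipes).
#' @export
validate_spike_table <- function(spikes) {
  check_columns(spikes, c("retina_id", "cell_id", "spike_time_s"))
  if (nrow(spikes) == 0) {
    return(as_tibble(spikes))
  }
  if (any(!is.finite(spikes$spike_time_s)) || any(spikes$spike_time_s < 0)) {
    abort("Spike times must be finite and >= 0.",
      class = "iprgclight_validation_error"
    )
  }
  bad <- spikes %>%
    group_by(.data$cell_id) %>%
    summarise(ok = !is.unsorted(.data$spike_time_s), .groups = "drop") %>%
    filter(!.data$ok)
  if (nrow(bad) > 0) {
    abort(
      paste0(
        "Spike times regress within cell(s): ",
        toString(bad$cell_id)
      ),
      class = "iprgclight_validation_error"
    )
  }
  as_tibble(spikes)
}

#' Read and write stimulus-event tables
#'
#' Event tables are CSVs with header `kind,onset_s,offset_s,ir,wavelength_nm`.
#' `kind` is "light" or "kcl"; `ir` is log10(photons cm^-2 s^-1) and is
#' required (finite) for light events. Epochs are half-open
#' \code{[onset, offset)}: abutting events are legal, overlapping ones are
#' not, and a zero-duration event is an error.
#'
#' @param path file path.
#' @param events an event tibble with the columns above.
#' @return `read_event_table()` returns a validated, onset-sorted tibble.
#' @export
read_event_table <- function(path) {
  tbl <- readr::read_csv(
    path,
    col_types = readr::cols(
      kind = readr::col_character(),
      onset_s = readr::col_double(),
      offset_s = readr::col_double(),
      ir = readr::col_double(),
      wavelength_nm = readr::col_double()
    ),
    show_col_types = FALSE, progress = FALSE
  )
  check_columns(tbl, c("kind", "onset_s", "offset_s", "ir", "wavelength_nm"), path)
  validate_event_table(tbl)
}

#' @rdname read_event_table
#' @export
write_event_table <- function(events, path) {
  events <- validate_event_table(events)
  out <- events[c("kind", "onset_s", "offset_s", "ir", "wavelength_nm")]
  out$onset_s <- round(out$onset_s, 6)
  out$offset_s <- round(out$offset_s, 6)
  readr::write_csv(out, path, progress = FALSE)
  invisible(path)
}

#' Validate a stimulus-event table in memory
#'
#' @param events tibble with columns kind, onset_s, offset_s, ir,
#'   wavelength_nm.
#' @return the validated tibble, sorted by onset.
#' @export
validate_event_table <- function(events) {
  check_columns(events, c("kind", "onset_s", "offset_s", "ir", "wavelength_nm"))
  events <- as_tibble(events)
  if (nrow(events) == 0) {
    return(events)
  }
  if (!all(events$kind %in% c("light", "kcl"))) {
    abort("Event kind must be 'light' or 'kcl'.",
      class = "iprgclight_validation_error"
    )
  }
  if (any(!is.finite(events$onset_s)) || any(!is.finite(events$offset_s)) ||
    any(events$onset_s < 0)) {
    abort("Event onsets/offsets must be finite with onset >= 0.",
      class = "iprgclight_validation_error"
    )
  }
  if (any(events$offset_s <= events$onset_s)) {
    abort("Every event needs offset > onset (no zero-duration epochs).",
      class = "iprgclight_validation_error"
    )
  }
  light <- events$kind == "light"
  if (any(light & !is.finite(events$ir))) {
    abort("Light events must carry a finite log10 irradiance.",
      class = "iprgclight_validation_error"
    )
  }
  events <- arrange(events, .data$onset_s)
  if (nrow(events) > 1) {
    overlap <- which(events$onset_s[-1] < events$offset_s[-nrow(events)])
    if (length(overlap) > 0) {
      i <- overlap[1]
      abort(
        sprintf("Events %d and %d overlap in time.", i, i + 1L),
        class = "iprgclight_validation_error"
      )
    }
  }
  events
}

check_columns <- function(tbl, required, path = NULL) {
  missing <- setdiff(required, names(tbl))
  if (length(missing) > 0) {
    where <- if (is.null(path)) "table" else paste0("file '", path, "'")
    abort(
      paste0("Malformed ", where, ": missing column(s) ", toString(missing)),
      class = "iprgclight_format_error"
    )
  }
  invisible(tbl)
}

#' Write all tables of a simulated recording
#'
#' @param recording an `iprgc_recording` from [generate_protocol_recording()].
#' @param dir output directory (created if needed).
#' @param prefix file-name prefix.
#' @return named character vector of the written paths, invisibly.
#' @export
write_recording <- function(recording, dir, prefix = "recording") {
  stopifnot(inherits(recording, "iprgc_recording"))
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  paths <- c(
    spikes = file.path(dir, paste0(prefix, "_spikes.csv")),
    events = file.path(dir, paste0(prefix, "_events.csv")),
    cells = file.path(dir, paste0(prefix, "_cells.csv"))
  )
  write_spike_table(recording$spikes, paths[["spikes"]])
  write_event_table(recording$events, paths[["events"]])
  readr::write_csv(recording$cells, paths[["cells"]], progress = FALSE)
  invisible(paths)
}
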