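#' Default generative parameters for simulated ipRGCs
#'
#' One row per (age group, electrophysiologic subtype) combination. The
#' defaults are calibrated so that simulated populations reproduce the
#' published median response features of developing ipRGCs (on-latency,
#' peak firing, off-latency and total spikes per 1-min stimulus) and the
#' qualitative recovery ordering of the subtypes. Type I rows exist only at
#' P8: Type I cells are not detectable after eye opening.
#'
#' Columns (units):
#' \describe{
#'   \item{r_max}{peak firing capacity (Hz)}
#'   \item{ir_half}{log10 irradiance of half-maximal sensitivity}
#'   \item{hill_n}{sensitivity slope of the Naka-Rushton curve (>0)}
#'   \item{latency_tau}{rise time constant toward peak rate (s)}
#'   \item{lat_scale}{scale of the sensitivity-dependent onset delay (s);
#'     delay = lat_scale * (1/sensitivity - 1), so dim stimuli respond late}
#'   \item{adapt_tau}{adaptation decay time constant in light at full drive (s)}
#'   \item{recover_tau}{dark-recovery time constant of the adaptation gain (s)}
#'   \item{off_tau}{post-offset firing persistence time constant (s)}
#'   \item{baseline_rate}{dark firing rate (Hz)}
#'   \item{shift_gain}{adaptation-induced rightward shift of ir_half,
#'     in log units per unit of lost gain: s_shift = shift_gain * (1 - a)}
#'   \item{kcl_rate}{firing rate driven by terminal KCl depolarization (Hz)}
#'   \item{persist_prob}{probability a cell carries a non-zero adaptation
#'     floor, letting it fire throughout very long exposures}
#'   \item{persist_floor}{median adaptation floor of such persistent cells}
#' }
#'
#' @param path optional path to an alternative parameter CSV with the same
#'   columns; defaults to the table shipped with the package.
#' @return a tibble, one row per (age_group, subtype).
#' @export
cell_param_defaults <- function(path = NULL) {
  path <- path %||% system.file("extdata", "cell_params.csv",
    package = "iprgclight", mustWork = TRUE
  )
  params <- readr::read_csv(path, show_col_types = FALSE, progress = FALSE)
  validate_cell_params(params)
  params
}

validate_cell_params <- function(params) {
  required <- c(
    "age_group", "subtype", "r_max", "ir_half", "hill_n", "latency_tau",
    "lat_scale", "adapt_tau", "recover_tau", "off_tau", "baseline_rate",
    "shift_gain", "kcl_rate", "persist_prob", "persist_floor"
  )
  missing <- setdiff(required, names(params))
  if (length(missing) > 0) {
    abort(
      paste0("Parameter table is missing columns: ", toString(missing)),
      class = "iprgclight_format_error"
    )
  }
  taus <- c("latency_tau", "adapt_tau", "recover_tau", "off_tau")
  if (any(as.matrix(params[taus]) <= 0)) {
    abort("All time constants must be > 0.", class = "iprgclight_input_error")
  }
  if (any(params$hill_n <= 0)) {
    abort("`hill_n` must be > 0.", class = "iprgclight_input_error")
  }
  if (any(params$baseline_rate < 0) || any(params$r_max <= params$baseline_rate)) {
    abort("Need r_max > baseline_rate >= 0.", class = "iprgclight_input_error")
  }
  if (any(params$subtype == "I" & params$age_group %in% c("P15", "P30"))) {
    abort("Type I rows are not allowed after eye opening (P15/P30).",
      class = "iprgclight_input_error"
    )
  }
  invisible(params)
}

# Published recordable-cohort structure: cells per retina and the observed
# subtype composition of each age's recordable population.
default_subtype_mix <- function(age_group) {
  switch(age_group,
    P8  = c(I = 40 / 60, II = 13 / 60, III = 7 / 60),
    P15 = c(II = 13 / 25, III = 12 / 25),
    P30 = c(II = 13 / 25, III = 12 / 25),
    abort(paste0("No default subtype mix for age ", age_group),
      class = "iprgclight_input_error"
    )
  )
}

#' Configure a simulated ipRGC population
#'
#' Bundles the scale and composition of a simulated multi-retina recording:
#' how many retinas, the mean recordable cells per retina, the subtype mix,
#' the age group, a coefficient of variation applied to the generative cell
#' parameters, and the seed controlling all randomness.
#'
#' Defaults mirror the recordable populations of the source experiments:
#' 5 P8 retinas averaging 20.2 cells each, with P8 subtype proportions
#' 40:13:7 (Type I:II:III); post-eye-opening retinas average ~2.5 (P15) or
#' 2.0 (P30) cells and contain only Types II and III.
#'
#' @param age_group one of "P8", "P15", "P30".
#' @param n_retinas number of retinas (>= 0).
#' @param cells_per_retina mean recordable cells per retina (>= 0).
#' @param subtype_mix named numeric vector of subtype proportions summing
#'   to 1; defaults to the age-specific observed mix.
#' @param param_jitter coefficient of variation applied multiplicatively to
#'   positive cell parameters (irradiance half-max is jittered additively on
#'   the log-irradiance scale with sd = 0.5 * param_jitter).
#' @param seed integer seed; every downstream random draw derives from it.
#' @return a `population_config` list.
#' @export
population_config <- function(age_group = "P8",
                              n_retinas = 5,
                              cells_per_retina = switch(age_group,
                                P8 = 20.2, P15 = 2.5, P30 = 2.0
                              ),
                              subtype_mix = NULL,
                              param_jitter = 0.2,
                              seed = 1L) {
  age_group <- match.arg(age_group, c("P8", "P15", "P30"))
  subtype_mix <- subtype_mix %||% default_subtype_mix(age_group)
  if (is.null(names(subtype_mix)) || !all(names(subtype_mix) %in% SUBTYPES)) {
    abort("`subtype_mix` must be named with subtypes I/II/III.",
      class = "iprgclight_input_error"
    )
  }
  if (any(subtype_mix < 0) || any(subtype_mix > 1) ||
    abs(sum(subtype_mix) - 1) > 1e-9) {
    abort("Subtype proportions must lie in [0,1] and sum to 1 (tol 1e-9).",
      class = "iprgclight_input_error"
    )
  }
  if (age_group %in% c("P15", "P30") && ("I" %in% names(subtype_mix)) &&
    subtype_mix[["I"]] > 0) {
    abort("Type I cells are absent from P15/P30 populations.",
      class = "iprgclight_input_error"
    )
  }
  if (n_retinas < 0 || cells_per_retina < 0) {
    abort("Counts must be >= 0.", class = "iprgclight_input_error")
  }
  if (param_jitter < 0) {
    abort("`param_jitter` must be >= 0.", class = "iprgclight_input_error")
  }
  structure(
    list(
      age_group = age_group, n_retinas = as.integer(n_retinas),
      cells_per_retina = cells_per_retina, subtype_mix = subtype_mix,
      param_jitter = param_jitter, seed = as.integer(seed)
    ),
    class = "population_config"
  )
}

#' Draw a population of simulated cells
#'
#' Samples per-retina cell counts (Poisson around the configured mean),
#' assigns subtypes by the configured mix, and jitters the generative
#' parameters cell by cell so that no two cells are identical. Persistent
#' (adaptation-floor) cells are drawn with probability `persist_prob`.
#'
#' @param config a [population_config()].
#' @param params parameter table as from [cell_param_defaults()].
#' @return tibble with one row per cell: ids, subtype, and its generative
#'   parameters.
#' @export
simulate_population <- function(config, params = cell_param_defaults()) {
  stopifnot(inherits(config, "population_config"))
  validate_cell_params(params)
  age_params <- params %>% filter(.data$age_group == config$age_group)
  needed <- names(config$subtype_mix)[config$subtype_mix > 0]
  if (!all(needed %in% age_params$subtype)) {
    abort(
      paste0(
        "Parameter table lacks rows for age ", config$age_group,
        " subtype(s): ", toString(setdiff(needed, age_params$subtype))
      ),
      class = "iprgclight_input_error"
    )
  }

  withr::with_seed(derive_seed(config$seed, 101L), {
    n_cells <- rpois(config$n_retinas, config$cells_per_retina)
    if (config$n_retinas == 0 || sum(n_cells) == 0) {
      return(empty_population(age_params))
    }
    retina_id <- rep(sprintf("retina_%02d", seq_len(config$n_retinas)), n_cells)
    total <- sum(n_cells)
    subtype <- sample(
      names(config$subtype_mix), total,
      replace = TRUE, prob = config$subtype_mix
    )
    cells <- age_params[match(subtype, age_params$subtype), ] %>%
      mutate(
        retina_id = retina_id,
        cell_id = sprintf("cell_%04d", seq_len(total)),
        .before = 1
      )

    cv <- config$param_jitter
    mult_cols <- c(
      "r_max", "latency_tau", "lat_scale", "adapt_tau", "recover_tau",
      "off_tau", "kcl_rate"
    )
    for (col in mult_cols) {
      cells[[col]] <- jitter_lognormal(cells[[col]], cv)
    }
    cells$ir_half <- cells$ir_half + rnorm(total, sd = 0.5 * cv)
    cells$hill_n <- jitter_lognormal(cells$hill_n, 0.5 * cv)
    persistent <- runif(total) < cells$persist_prob
    cells$a_floor <- ifelse(
      persistent,
      jitter_lognormal(cells$persist_floor, 1),
      0
    )
    cells %>% select(-"persist_prob", -"persist_floor")
  })
}

empty_population <- function(age_params) {
  cols <- age_params %>%
    select(-"persist_prob", -"persist_floor") %>%
    slice(0) %>%
    mutate(a_floor = numeric(0))
  mutate(cols,
    retina_id = character(0), cell_id = character(0),
    .before = 1
  )
}
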