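COUNT_CLASSES <- c(
  "mel_smi_neg", "mel_smi_pos", "smi_only", "m1", "m2", "m3", "m1_displaced"
)

#' Cell densities per marker class
#'
#' Converts a per-sample count table (see [generate_anatomy_tables()])
#' into cells mm^-2, adding the derived classes `mel_total`
#' (melanopsin+/SMI- plus melanopsin+/SMI+) and `smi_total`
#' (melanopsin+/SMI+ plus SMI-only).
#'
#' @param counts count table: one row per sample with `area_mm2` and one
#'   column per marker class.
#' @return tidy tibble: `sample_id, age_group, quadrant, class, count,
#'   density` (cells mm^-2).
#' @export
cell_density <- function(counts) {
  if (any(counts$area_mm2 <= 0)) {
    abort("Sampled area must be > 0.", class = "iprgclight_input_error")
  }
  present <- intersect(COUNT_CLASSES, names(counts))
  if (any(as.matrix(counts[present]) < 0)) {
    abort("Counts must be >= 0.", class = "iprgclight_input_error")
  }
  counts %>%
    mutate(
      mel_total = .data$mel_smi_neg + .data$mel_smi_pos,
      smi_total = .data$mel_smi_pos + .data$smi_only
    ) %>%
    tidyr::pivot_longer(
      all_of(c(present, "mel_total", "smi_total")),
      names_to = "class", values_to = "count"
    ) %>%
    mutate(density = .data$count / .data$area_mm2) %>%
    select("sample_id", "age_group", "quadrant", "class", "count", "density")
}

#' Mean density per age and marker class
#'
#' @param density_long output of [cell_density()].
#' @return tibble: `age_group, class, mean_density, sem, n`.
#' @export
density_summary <- function(density_long) {
  density_long %>%
    group_by(.data$age_group, .data$class) %>%
    summarise(
      mean_density = mean(.data$density),
      sem = sd(.data$density) / sqrt(n()),
      n = n(),
      .groups = "drop"
    )
}

#' Percent change between two densities
#'
#' `round(100 * (earlier - later) / earlier)` to the nearest integer,
#' matching the reporting precision of developmental density decreases
#' (e.g. 173 -> 143 cells mm^-2 is a 17% decrease). Positive values are
#' decreases; increases come out negative.
#'
#' @param earlier density at the earlier age (> 0).
#' @param later density at the later age.
#' @return integer percent change, `NA` when `earlier` is not positive.
#' @export
percent_change <- function(earlier, later) {
  ifelse(
    is.na(earlier) | earlier <= 0,
    NA_integer_,
    as.integer(round(100 * (earlier - later) / earlier))
  )
}

#' Pairwise developmental percent changes
#'
#' Applies [percent_change()] to the mean densities of every ordered age
#' pair within each marker class.
#'
#' @param summary output of [density_summary()].
#' @param ages age ordering (earliest first).
#' @return tibble: `class, from_age, to_age, from_density, to_density,
#'   percent_change`.
#' @export
age_percent_changes <- function(summary,
                                ages = c("P8", "P15", "P30", "P150")) {
  ages <- intersect(ages, unique(summary$age_group))
  pairs <- tidyr::expand_grid(from_age = ages, to_age = ages) %>%
    filter(match(.data$from_age, ages) < match(.data$to_age, ages))
  wide <- summary %>% select("age_group", "class", "mean_density")
  pairs %>%
    left_join(wide,
      by = c(from_age = "age_group"), relationship = "many-to-many"
    ) %>%
    rename(from_density = "mean_density") %>%
    left_join(
      wide %>% rename(to_density = "mean_density"),
      by = c(to_age = "age_group", "class")
    ) %>%
    mutate(
      percent_change = percent_change(.data$from_density, .data$to_density)
    ) %>%
    select(
      "class", "from_age", "to_age", "from_density", "to_density",
      "percent_change"
    )
}

#' Fraction of SMI-32+ cells that are melanopsin+
#'
#' Per-sample percentage of SMI-32-positive cells co-labeled for
#' melanopsin, averaged over samples within each age with its standard
#' error. Samples with no SMI-32+ cells carry no information about the
#' fraction and are skipped (with a message).
#'
#' @param counts count table with `mel_smi_pos` and `smi_only` columns.
#' @return tibble: `age_group, mean_percent, sem, n`.
#' @export
comelanopsin_fraction <- function(counts) {
  per_sample <- counts %>%
    mutate(smi_total = .data$mel_smi_pos + .data$smi_only)
  skipped <- sum(per_sample$smi_total == 0)
  if (skipped > 0) {
    message(skipped, " sample(s) with zero SMI-32+ cells skipped.")
  }
  per_sample %>%
    filter(.data$smi_total > 0) %>%
    mutate(pct = 100 * .data$mel_smi_pos / .data$smi_total) %>%
    group_by(.data$age_group) %>%
    summarise(
      mean_percent = mean(.data$pct),
      sem = sd(.data$pct) / sqrt(n()),
      n = n(),
      .groups = "drop"
    )
}

#' Relative melanopsin staining intensity
#'
#' Normalises background-subtracted intensities within each image to the
#' brightest background-subtracted soma of that image (by the staining
#' premise, an M1 cell; a violation raises a data-integrity warning).
#' Dendritic measurements are averaged per cell (3 dendrites for M1 and
#' M4 cells, 2 for M2 cells, following the measurement convention).
#'
#' @param intensity intensity table: `image_id, cell_id, subtype,
#'   structure, mean_intensity, background` (see
#'   [generate_anatomy_tables()]).
#' @return tibble: `image_id, age_group (if present), cell_id, subtype,
#'   structure, rel_intensity` with `rel_intensity` in \[0, 1\] for
#'   invariant-satisfying inputs.
#' @export
relative_intensity <- function(intensity) {
  if (any(intensity$mean_intensity < intensity$background) ||
    any(intensity$background < 0)) {
    abort("Need mean_intensity >= background >= 0.",
      class = "iprgclight_input_error"
    )
  }
  age_col <- intersect("age_group", names(intensity))
  intensity %>%
    mutate(net = .data$mean_intensity - .data$background) %>%
    group_by(.data$image_id) %>%
    group_modify(function(df, key) {
      soma <- df$structure == "soma"
      if (!any(soma)) {
        abort(paste0("Image without any soma measurement: ", key$image_id),
          class = "iprgclight_validation_error"
        )
      }
      top <- which(soma)[which.max(df$net[soma])]
      if (df$subtype[top] != "M1") {
        warn(
          paste0(
            "Data integrity: brightest soma in image ", key$image_id,
            " is ", df$subtype[top], ", not M1."
          ),
          class = "iprgclight_qc_warning"
        )
      }
      norm <- df$net[top]
      df$rel_intensity <- if (norm > 0) df$net / norm else 0
      df
    }) %>%
    ungroup() %>%
    group_by(across(all_of(c(
      "image_id", age_col, "cell_id", "subtype", "structure"
    )))) %>%
    summarise(rel_intensity = mean(.data$rel_intensity), .groups = "drop")
}
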