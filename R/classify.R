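#' Irradiance response ratio
#'
#' Ratio of a cell's response at the dim calibration light (IR 12.0) to
#' its response at the bright reference light (IR 13.6). Cells responding
#' at the dim light with more than 10% of their bright-light response are
#' the highly sensitive Type I cells.
#'
#' @param response_ir12 response magnitude at IR 12.0 (>= 0).
#' @param response_ir136 response magnitude at IR 13.6.
#' @return the fraction, or `NA` when the IR 13.6 response is absent
#'   (<= 0): such a cell is non-responsive and unclassifiable.
#' @export
irradiance_ratio <- function(response_ir12, response_ir136) {
  ifelse(
    is.na(response_ir136) | response_ir136 <= 0,
    NA_real_,
    response_ir12 / response_ir136
  )
}

#' Electrophysiologic subtype rules
#'
#' `classify_p8()` applies the pre-eye-opening rules, measured at the
#' calibration irradiances IR 12.0 and 13.6:
#' * on-latency <= 12 s at IR 12.0 -> Type III;
#' * on-latency > 12 s and dim/bright response ratio > 0.10 -> Type I;
#' * on-latency > 12 s and ratio <= 0.10 -> Type II.
#'
#' Boundary cases follow the rules literally: a latency of exactly 12 s is
#' Type III and a ratio of exactly 0.10 is Type II. A cell that does not
#' respond at IR 12.0 at all (`NA` latency) cannot satisfy the Type III
#' rule and is classified through its ratio (0 when it responded at 13.6);
#' a missing ratio (no IR 13.6 response) is unclassifiable.
#'
#' `classify_peo()` applies the post-eye-opening rules (single pulse at
#' IR 13.0): latency <= 12 s -> Type III, otherwise Type II. Type I cells
#' are not present after eye opening.
#'
#' @param on_latency_ir12,on_latency on-latency (s) at the calibration
#'   irradiance; `NA` = no response at that light.
#' @param ratio dim/bright response ratio from [irradiance_ratio()].
#' @param latency_cut latency criterion (s), 12 by default.
#' @param ratio_cut sensitivity criterion, 0.10 by default.
#' @return character vector of labels in
#'   `c("I", "II", "III", "unclassifiable")`.
#' @export
classify_p8 <- function(on_latency_ir12, ratio,
                        latency_cut = 12, ratio_cut = 0.10) {
  case_when(
    !is.na(on_latency_ir12) & on_latency_ir12 <= latency_cut ~ "III",
    is.na(ratio) ~ "unclassifiable",
    ratio > ratio_cut ~ "I",
    TRUE ~ "II"
  )
}

#' @rdname classify_p8
#' @export
classify_peo <- function(on_latency, latency_cut = 12) {
  case_when(
    is.na(on_latency) ~ "unclassifiable",
    on_latency <= latency_cut ~ "III",
    TRUE ~ "II"
  )
}

#' Classify every cell of a subtyping recording
#'
#' Takes the feature table of a classification protocol recording (see
#' [protocol_subtyping()]) and assigns each cell a Type I/II/III label.
#' For P8, features must contain one epoch at IR 12.0 and one at IR 13.6;
#' the response magnitude entering the irradiance ratio is `total_spikes`
#' by default (`peak_firing_hz` is available as an alternative). For
#' post-eye-opening ages a single epoch at IR 13.0 is used and no ratio is
#' needed.
#'
#' @param features output of [response_features()] on the subtyping
#'   recording.
#' @param age_group "P8", "P15" or "P30".
#' @param metric response magnitude for the ratio: "total_spikes" or
#'   "peak_firing_hz".
#' @param latency_cut,ratio_cut rule thresholds.
#' @return tibble: `retina_id, cell_id, on_latency_cal, ratio, label,
#'   rule` where `rule` records which criterion fired.
#' @export
classify_cells <- function(features, age_group,
                           metric = c("total_spikes", "peak_firing_hz"),
                           latency_cut = 12, ratio_cut = 0.10) {
  age_group <- match.arg(age_group, c("P8", "P15", "P30"))
  metric <- match.arg(metric)
  if (age_group == "P8") {
    dim_f <- features %>% filter(abs(.data$ir - 12.0) < 0.05)
    bright_f <- features %>% filter(abs(.data$ir - 13.6) < 0.05)
    if (nrow(dim_f) == 0 || nrow(bright_f) == 0) {
      abort("P8 classification needs epochs at IR 12.0 and IR 13.6.",
        class = "iprgclight_input_error"
      )
    }
    merged <- dim_f %>%
      select("retina_id", "cell_id",
        on_latency_cal = "on_latency_s", dim_resp = all_of(metric)
      ) %>%
      left_join(
        bright_f %>%
          select("cell_id", bright_resp = all_of(metric)),
        by = "cell_id"
      ) %>%
      mutate(
        ratio = irradiance_ratio(.data$dim_resp, .data$bright_resp),
        label = classify_p8(.data$on_latency_cal, .data$ratio,
          latency_cut, ratio_cut
        ),
        rule = case_when(
          .data$label == "III" ~ sprintf("on-latency <= %g s at IR 12.0", latency_cut),
          .data$label == "I" ~ sprintf("ratio > %g at IR 12.0 vs 13.6", ratio_cut),
          .data$label == "II" ~ sprintf("ratio <= %g at IR 12.0 vs 13.6", ratio_cut),
          TRUE ~ "no IR 13.6 response"
        )
      )
    merged %>% select(
      "retina_id", "cell_id", "on_latency_cal", "ratio", "label", "rule"
    )
  } else {
    cal_f <- features %>% filter(abs(.data$ir - 13.0) < 0.05)
    if (nrow(cal_f) == 0) {
      abort("Post-eye-opening classification needs an epoch at IR 13.0.",
        class = "iprgclight_input_error"
      )
    }
    cal_f %>%
      mutate(
        on_latency_cal = .data$on_latency_s,
        ratio = NA_real_,
        label = classify_peo(.data$on_latency_s, latency_cut),
        rule = case_when(
          .data$label == "III" ~ sprintf("on-latency <= %g s at IR 13.0", latency_cut),
          .data$label == "II" ~ sprintf("on-latency > %g s at IR 13.0", latency_cut),
          TRUE ~ "no IR 13.0 response"
        )
      ) %>%
      select("retina_id", "cell_id", "on_latency_cal", "ratio", "label", "rule")
  }
}
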