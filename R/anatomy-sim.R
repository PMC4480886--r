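#' Default anatomy calibration tables
#'
#' `anatomy_density_defaults()` holds per-age mean cell densities
#' (cells mm^-2) and their standard errors for the marker classes counted
#' in flat-mount retinas: melanopsin+/SMI-32- (M1/M2/M3 cells),
#' melanopsin+/SMI-32+ (presumed M4 cells), SMI-32-only cells, and the
#' morphologic subclasses M1, M2, M3 and displaced M1. Derived classes
#' (total melanopsin+, total SMI-32+) are sums of these.
#'
#' `anatomy_intensity_defaults()` holds target relative melanopsin
#' staining intensities (fraction of the brightest soma in the same image,
#' which is always an M1 cell) per age, subtype (M1/M2/M4) and structure
#' (soma/dendrite). M4 dendritic intensity falls roughly 8-fold between P8
#' and the post-eye-opening ages; M4 somata drop ~30%; M2 somata stay near
#' 30% of M1 values.
#'
#' @param path optional alternative CSV with the same columns.
#' @return a tibble.
#' @export
anatomy_density_defaults <- function(path = NULL) {
  path <- path %||% system.file("extdata", "anatomy_density.csv",
    package = "iprgclight", mustWork = TRUE
  )
  readr::read_csv(path, show_col_types = FALSE, progress = FALSE)
}

#' @rdname anatomy_density_defaults
#' @export
anatomy_intensity_defaults <- function(path = NULL) {
  path <- path %||% system.file("extdata", "anatomy_intensity.csv",
    package = "iprgclight", mustWork = TRUE
  )
  readr::read_csv(path, show_col_types = FALSE, progress = FALSE)
}

#' Generate synthetic anatomy tables
#'
#' Emulates the tabular output of melanopsin/SMI-32 immunohistochemistry:
#' a per-sample cell-count table (one sampled region per retinal quadrant,
#' default area 1.29 mm^2) and a per-cell staining-intensity table with
#' background measurements.
#'
#' Counts are drawn per sample around the configured densities with
#' per-sample standard deviation `sem * sqrt(16)` (so that a 16-sample
#' age group reproduces the configured standard error), truncated at zero
#' and converted to integer cells over the sampled area. A zero-SEM
#' configuration therefore yields identical samples.
#'
#' The intensity table guarantees, by construction, that within each image
#' the maximum background-subtracted soma intensity belongs to an M1 cell.
#' Dendrite measurements follow the field convention of 3 dendrites per M1
#' and M4 cell and 2 per M2 cell.
#'
#' @param seed integer seed.
#' @param ages age groups to generate.
#' @param n_samples count samples per age (4 quadrants x retinas).
#' @param area_mm2 sampled region area (mm^2).
#' @param images_per_age confocal images per age for intensity data.
#' @param cells_per_subtype cells measured per subtype per image.
#' @param density_config,intensity_config calibration tables; see
#'   [anatomy_density_defaults()].
#' @return list with `counts` (one row per sample, one column per marker
#'   class) and `intensity` (one row per measured structure with
#'   `mean_intensity` and `background` in arbitrary units).
#' @export
generate_anatomy_tables <- function(seed = 1L,
                                    ages = c("P8", "P15", "P30", "P150"),
                                    n_samples = 16,
                                    area_mm2 = 1.29,
                                    images_per_age = 4,
                                    cells_per_subtype = 6,
                                    density_config = anatomy_density_defaults(),
                                    intensity_config = anatomy_intensity_defaults()) {
  if (any(density_config$mean_density < 0) || any(density_config$sem < 0)) {
    abort("Densities and SEMs must be >= 0.", class = "iprgclight_input_error")
  }
  if (area_mm2 <= 0) {
    abort("`area_mm2` must be > 0.", class = "iprgclight_input_error")
  }
  counts <- withr::with_seed(
    derive_seed(seed, 201L),
    generate_count_table(ages, n_samples, area_mm2, density_config)
  )
  intensity_ages <- intersect(ages, unique(intensity_config$age_group))
  intensity <- withr::with_seed(
    derive_seed(seed, 202L),
    generate_intensity_table(
      intensity_ages, images_per_age, cells_per_subtype, intensity_config
    )
  )
  list(counts = counts, intensity = intensity)
}

generate_count_table <- function(ages, n_samples, area_mm2, config) {
  quadrants <- c("dorsal", "ventral", "nasal", "temporal")
  purrr::map_dfr(ages, function(age) {
    cfg <- config %>% filter(.data$age_group == age)
    if (nrow(cfg) == 0) {
      abort(paste0("No density configuration for age ", age),
        class = "iprgclight_input_error"
      )
    }
    purrr::map_dfr(seq_len(n_samples), function(i) {
      # per-sample sd referenced to the 16-sample design of the calibration
      dens <- pmax(0, rnorm(nrow(cfg), cfg$mean_density, cfg$sem * sqrt(16)))
      cts <- as.integer(round(dens * area_mm2))
      row <- as_tibble(setNames(as.list(cts), cfg$class))
      mutate(row,
        sample_id = sprintf("%s_s%02d", age, i),
        age_group = age,
        quadrant = quadrants[(i - 1) %% 4 + 1],
        area_mm2 = area_mm2,
        .before = 1
      )
    })
  })
}

generate_intensity_table <- function(ages, images_per_age, cells_per_subtype,
                                     config) {
  n_dendrites <- c(M1 = 3, M2 = 2, M4 = 3)
  rows <- purrr::map_dfr(ages, function(age) {
    cfg <- config %>% filter(.data$age_group == age)
    purrr::map_dfr(seq_len(images_per_age), function(img) {
      scale_au <- runif(1, 150, 250)
      image_id <- sprintf("%s_img%d", age, img)
      per_cell <- purrr::map_dfr(c("M1", "M2", "M4"), function(st) {
        purrr::map_dfr(seq_len(cells_per_subtype), function(ci) {
          cell_id <- sprintf("%s_%s_c%d", image_id, st, ci)
          # the first M1 cell is pinned at relative intensity 1: the
          # normalisation reference ("brightest soma, always an M1")
          soma_rel <- if (st == "M1" && ci == 1) {
            1.0
          } else {
            rel_of(cfg, st, "soma") * rlnorm(1, -0.02, 0.2)
          }
          dend_rel <- rel_of(cfg, st, "dendrite") *
            rlnorm(n_dendrites[[st]], -0.02, 0.2)
          tibble(
            age_group = age,
            image_id = image_id,
            cell_id = cell_id,
            subtype = st,
            structure = c("soma", rep("dendrite", n_dendrites[[st]])),
            rel = c(soma_rel, dend_rel)
          )
        })
      })
      per_cell %>%
        mutate(
          background = pmax(0, rnorm(n(), 10, 1)),
          mean_intensity = .data$background + scale_au * .data$rel
        ) %>%
        select(-"rel")
    })
  })
  enforce_m1_brightest(rows)
}

rel_of <- function(cfg, subtype, structure) {
  v <- cfg$rel_intensity[cfg$subtype == subtype & cfg$structure == structure]
  if (length(v) != 1) {
    abort("Intensity configuration must have one row per subtype x structure.",
      class = "iprgclight_input_error"
    )
  }
  v
}

# Guarantee the stated premise of the normalisation: within each image the
# brightest background-subtracted soma belongs to an M1 cell. If noise put
# a non-M1 soma on top, its value is swapped with the brightest M1 soma,
# preserving the value distribution.
enforce_m1_brightest <- function(intensity) {
  if (nrow(intensity) == 0) {
    return(tibble(
      age_group = character(0), image_id = character(0),
      cell_id = character(0), subtype = character(0),
      structure = character(0), background = numeric(0),
      mean_intensity = numeric(0)
    ))
  }
  intensity %>%
    group_by(.data$image_id) %>%
    group_modify(function(df, key) {
      soma <- which(df$structure == "soma")
      val <- df$mean_intensity - df$background
      top <- soma[which.max(val[soma])]
      if (df$subtype[top] != "M1") {
        m1s <- soma[df$subtype[soma] == "M1"]
        top_m1 <- m1s[which.max(val[m1s])]
        tmp <- df$mean_intensity[top]
        df$mean_intensity[top] <- df$background[top] +
          (df$mean_intensity[top_m1] - df$background[top_m1])
        df$mean_intensity[top_m1] <- df$background[top_m1] +
          (tmp - df$background[top])
      }
      df
    }) %>%
    ungroup()
}
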