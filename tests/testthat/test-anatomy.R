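count_row <- function(...) {
  defaults <- list(
    sample_id = "s1", age_group = "P8", quadrant = "dorsal", area_mm2 = 1.29,
    mel_smi_neg = 0L, mel_smi_pos = 0L, smi_only = 0L,
    m1 = 0L, m2 = 0L, m3 = 0L, m1_displaced = 0L
  )
  args <- list(...)
  defaults[names(args)] <- args
  tibble::as_tibble(defaults)
}

test_that("densities are counts over area, with additive derived classes", {
  row <- count_row(mel_smi_neg = 150L, mel_smi_pos = 73L)
  d <- cell_density(row)
  # 223 melanopsin+ cells over 1.29 mm^2 -> 172.9 mm^-2
  expect_equal(d$density[d$class == "mel_total"], 172.9, tolerance = 1e-3)
  expect_equal(
    d$density[d$class == "mel_total"],
    d$density[d$class == "mel_smi_neg"] + d$density[d$class == "mel_smi_pos"]
  )
  expect_equal(d$density[d$class == "m1"], 0)
  expect_error(cell_density(count_row(area_mm2 = 0)),
    class = "iprgclight_input_error"
  )
  # density scales linearly with counts
  d2 <- cell_density(count_row(mel_smi_neg = 300L, mel_smi_pos = 146L))
  expect_equal(
    d2$density[d2$class == "mel_total"],
    2 * d$density[d$class == "mel_total"]
  )
})

test_that("percent changes reproduce the published developmental decreases", {
  expect_equal(percent_change(173, 143), 17L)
  expect_equal(percent_change(173, 129), 25L)
  expect_equal(percent_change(143, 129), 10L)
  expect_equal(percent_change(116, 108), 7L)
  expect_equal(percent_change(57, 23), 60L)
  expect_equal(percent_change(35, 23), 34L)
  expect_equal(percent_change(76, 58), 24L)
  expect_equal(percent_change(76, 54), 29L)
  expect_equal(percent_change(5, 5), 0L)
  expect_true(is.na(percent_change(0, 10)))
  # a density increase comes out negative
  expect_lt(percent_change(100, 120), 0)
})

test_that("co-labeling fractions average per-sample percentages", {
  tbl <- count_row(mel_smi_pos = 57L, smi_only = 19L)
  out <- comelanopsin_fraction(tbl)
  expect_equal(out$mean_percent, 100 * 57 / 76, tolerance = 1e-9)
  all_co <- count_row(mel_smi_pos = 40L, smi_only = 0L)
  expect_equal(comelanopsin_fraction(all_co)$mean_percent, 100)
  # zero-SMI samples are skipped, not divided by
  expect_message(
    out2 <- comelanopsin_fraction(dplyr::bind_rows(tbl, count_row())),
    "skipped"
  )
  expect_equal(out2$n, 1)
})

test_that("relative intensities normalise to the brightest M1 soma", {
  img <- tibble::tibble(
    image_id = "i1",
    cell_id = c("m1a", "m2a", "m2a"),
    subtype = c("M1", "M2", "M2"),
    structure = c("soma", "soma", "dendrite"),
    mean_intensity = c(200, 60, 30),
    background = c(0, 0, 0)
  )
  out <- relative_intensity(img)
  expect_equal(out$rel_intensity[out$cell_id == "m1a"], 1) # self-normalised
  expect_equal(
    out$rel_intensity[out$cell_id == "m2a" & out$structure == "soma"], 0.30
  )
  # all signal at background -> all zero
  flat <- img
  flat$mean_intensity <- flat$background + 0
  expect_true(all(relative_intensity(flat)$rel_intensity == 0))
  # a brightest non-M1 soma violates the stated premise
  bad <- img
  bad$mean_intensity[2] <- 500
  expect_warning(relative_intensity(bad), class = "iprgclight_qc_warning")
  expect_error(
    relative_intensity(dplyr::mutate(img, background = mean_intensity + 1)),
    class = "iprgclight_input_error"
  )
})

test_that("dendrites are averaged per cell before reporting", {
  img <- tibble::tibble(
    image_id = "i1",
    cell_id = c("m1a", "m4a", "m4a", "m4a"),
    subtype = c("M1", "M4", "M4", "M4"),
    structure = c("soma", "dendrite", "dendrite", "dendrite"),
    mean_intensity = c(100, 10, 20, 30),
    background = 0
  )
  out <- relative_intensity(img)
  expect_equal(
    out$rel_intensity[out$subtype == "M4" & out$structure == "dendrite"],
    mean(c(10, 20, 30)) / 100
  )
})

test_that("generated count tables track the configured densities", {
  tabs <- generate_anatomy_tables(seed = 7, ages = "P8", n_samples = 16)
  d <- cell_density(tabs$counts)
  mel <- d$density[d$class == "mel_total"]
  # sample mean within 3 SE of the configured 173 mm^-2
  expect_lt(abs(mean(mel) - 173), 3 * 9)
  expect_equal(length(mel), 16)
  expect_error(
    generate_anatomy_tables(
      seed = 1,
      density_config = dplyr::mutate(anatomy_density_defaults(),
        mean_density = -1
      )
    ),
    class = "iprgclight_input_error"
  )
})

test_that("zero-SEM tables are identical across samples and reproduce the printed percent changes", {
  cfg0 <- dplyr::mutate(anatomy_density_defaults(), sem = 0)
  tabs <- generate_anatomy_tables(seed = 1, n_samples = 4, density_config = cfg0)
  counts <- dplyr::select(tabs$counts, -sample_id, -quadrant)
  per_age <- split(counts, counts$age_group)
  for (a in per_age) expect_equal(nrow(dplyr::distinct(a)), 1)

  pc <- age_percent_changes(density_summary(cell_density(tabs$counts)))
  want <- tibble::tribble(
    ~class, ~from_age, ~to_age, ~expected,
    "mel_total", "P8", "P15", 17,
    "mel_total", "P8", "P30", 25,
    "mel_total", "P15", "P30", 10,
    "mel_smi_neg", "P8", "P15", 7,
    "mel_smi_pos", "P8", "P30", 60,
    "mel_smi_pos", "P15", "P30", 34,
    "smi_total", "P8", "P15", 24,
    "smi_total", "P8", "P30", 29
  )
  got <- dplyr::inner_join(want, pc, by = c("class", "from_age", "to_age"))
  # integer cell counts over 1.29 mm^2 quantise densities slightly
  expect_true(all(abs(got$percent_change - got$expected) <= 1))
})

test_that("the intensity table keeps its invariants and the M4 dendrite drop", {
  tabs <- generate_anatomy_tables(seed = 9)
  int <- tabs$intensity
  expect_true(all(int$mean_intensity >= int$background))
  expect_true(all(int$background >= 0))
  ri <- relative_intensity(int)
  expect_true(all(ri$rel_intensity >= 0 & ri$rel_intensity <= 1))

  m4d <- ri %>%
    dplyr::filter(subtype == "M4", structure == "dendrite") %>%
    dplyr::group_by(age_group) %>%
    dplyr::summarise(m = mean(rel_intensity))
  ratio <- m4d$m[m4d$age_group == "P8"] / m4d$m[m4d$age_group == "P30"]
  expect_gt(ratio, 6) # ~8-fold developmental decrease
  expect_lt(ratio, 10)

  # within every image the brightest soma is an M1 cell, by construction
  brightest <- int %>%
    dplyr::filter(structure == "soma") %>%
    dplyr::group_by(image_id) %>%
    dplyr::slice_max(mean_intensity - background, n = 1)
  expect_true(all(brightest$subtype == "M1"))
})

test_that("P150-like tables give the small published co-labeling fraction", {
  tabs <- generate_anatomy_tables(seed = 13, ages = "P150", n_samples = 16)
  out <- comelanopsin_fraction(tabs$counts)
  # printed-density arithmetic: ~1.1 of ~60 SMI+ cells mm^-2 -> ~2%
  expect_gt(out$mean_percent, 0.8)
  expect_lt(out$mean_percent, 4)
})
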