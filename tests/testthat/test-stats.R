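grouped <- function(...) {
  groups <- list(...)
  tibble::tibble(
    value = unlist(groups),
    group = rep(paste0("g", seq_along(groups)), lengths(groups))
  )
}

test_that("median and IQR use linear-interpolation quartiles", {
  out <- median_iqr(1:9)
  expect_equal(out$median, 5)
  expect_equal(out$q1, 3)
  expect_equal(out$q3, 7)
  single <- median_iqr(4.2)
  expect_equal(unlist(single[c("median", "q1", "q3")]),
    c(median = 4.2, q1 = 4.2, q3 = 4.2)
  )
  expect_error(median_iqr(numeric(0)), class = "iprgclight_input_error")
})

test_that("Kruskal-Wallis matches the hand rank formula and handles flats", {
  df <- grouped(c(1, 2, 3), c(4, 5, 6), c(7, 8, 9))
  out <- kw_test(df, value, group)
  expect_equal(out$statistic, oracle_kw_h(list(1:3, 4:6, 7:9)))
  expect_equal(out$statistic, 7.2, tolerance = 1e-9)

  flat <- grouped(rep(5, 4), rep(5, 4), rep(5, 4))
  out_flat <- kw_test(flat, value, group)
  expect_equal(out_flat$statistic, 0)
  expect_equal(out_flat$p_value, 1)

  # permutation invariance within groups
  df_shuffled <- grouped(c(3, 1, 2), c(6, 4, 5), c(9, 7, 8))
  expect_equal(kw_test(df_shuffled, value, group)$statistic, out$statistic)

  expect_error(kw_test(grouped(1:3), value, group),
    class = "iprgclight_input_error"
  )
})

test_that("Mann-Whitney exact p-values match wilcoxon conventions", {
  df <- grouped(c(1, 2, 3), c(4, 5, 6))
  out <- pairwise_mw(df, value, group, m = 1)
  expect_equal(unname(out$statistic), 0) # complete separation
  expect_equal(out$p_value, 0.1) # 2/20 assignments as extreme
  expect_equal(out$method, "exact")

  same <- grouped(c(1, 3, 5, 7), c(2, 4, 6, 8))
  out2 <- pairwise_mw(same, value, group, m = 3)
  expect_equal(out2$p_adjusted, min(1, 3 * out2$p_value))
})

test_that("exact p-values agree with full permutation enumeration", {
  withr::with_seed(71, {
    for (n1 in 2:5) {
      for (n2 in 2:5) {
        x <- runif(n1) # continuous draws: tie-free
        y <- runif(n2) + 0.3
        got <- pairwise_mw(grouped(x, y), value, group, m = 1)
        expect_equal(got$p_value, oracle_mw_exact(x, y),
          tolerance = 1e-12,
          info = sprintf("n1=%d n2=%d", n1, n2)
        )
      }
    }
  })
})

test_that("large or tied samples fall back to the corrected normal approximation", {
  withr::with_seed(72, {
    x <- rnorm(20)
    y <- rnorm(25, 0.5)
    out <- pairwise_mw(grouped(x, y), value, group)
    expect_equal(out$method, "normal approximation")
    tied <- grouped(c(1, 1, 2, 3), c(2, 2, 3, 4))
    out2 <- pairwise_mw(tied, value, group)
    expect_equal(out2$method, "normal approximation")
    expect_true(out2$p_value >= 0 && out2$p_value <= 1)
  })
})

test_that("Bonferroni never decreases a p-value and caps at 1", {
  expect_equal(bonferroni(0.02, 3), 0.06)
  expect_equal(bonferroni(0.5, 3), 1)
  p <- runif(100)
  expect_true(all(bonferroni(p, 3) >= p))
  expect_true(all(bonferroni(p, 3) <= 1))
  expect_error(bonferroni(0.1, 0), class = "iprgclight_input_error")
})

test_that("one-way ANOVA runs through the grouped interface", {
  df <- grouped(rnorm(10), rnorm(10, 2), rnorm(10, 4))
  out <- grouped_anova(df, value, group)
  expect_equal(out$df1, 2)
  expect_lt(out$p_value, 0.05)
})

test_that("the mixed model recovers degenerate fixed effects exactly", {
  # constant response -> all slopes zero
  df <- tidyr::expand_grid(subject = paste0("s", 1:6), time = c(10, 20, 30)) %>%
    dplyr::mutate(group = rep(c("P8", "P30"), each = 9), value = 42)
  # zero-variance data triggers benign optimizer convergence warnings
  fit <- suppressWarnings(fit_recovery_lmm(df, value, group, time, subject))
  est <- tidy(fit)
  expect_equal(est$estimate[est$term == "(Intercept)"], 42, tolerance = 1e-6)
  expect_true(all(abs(est$estimate[est$term != "(Intercept)"]) < 1e-6))

  # noiseless linear time effect -> slope recovered exactly
  df2 <- tidyr::expand_grid(subject = paste0("s", 1:6), time = c(10, 20, 30)) %>%
    dplyr::mutate(value = 5 + 0.8 * time)
  fit2 <- suppressWarnings(fit_recovery_lmm(df2, value, subject, time, subject))
  est2 <- tidy(fit2)
  expect_equal(est2$estimate[est2$term == "time"], 0.8, tolerance = 1e-6)

  expect_error(
    fit_recovery_lmm(
      dplyr::filter(df, subject == "s1"), value, group, time, subject
    ),
    class = "iprgclight_input_error"
  )
})

test_that("glance reports the variance components", {
  df <- simulate_lmm_dataset(n_subjects = 30, sd_subject = 3, seed = 5)
  fit <- fit_recovery_lmm(df, value, group, time, subject)
  g <- glance(fit)
  expect_true(g$sd_subject > 0)
  expect_equal(g$n_subjects, 30)
  expect_true(is.finite(g$AIC))
})

test_that("the random-intercept SD is recovered from simulated data", {
  sds <- vapply(1:10, function(s) {
    df <- simulate_lmm_dataset(n_subjects = 40, sd_subject = 2, seed = s)
    glance(fit_recovery_lmm(df, value, group, time, subject))$sd_subject
  }, numeric(1))
  expect_lt(abs(mean(sds) - 2) / 2, 0.25)
})
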