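#' Median and interquartile range
#'
#' Summary convention for response features: median with linear
#' interpolation (type-7) quartiles.
#'
#' @param x non-empty numeric vector (`NA` dropped).
#' @param type quantile algorithm (see [stats::quantile()]).
#' @return tibble: `median, q1, q3, n`.
#' @export
median_iqr <- function(x, type = 7) {
  x <- x[!is.na(x)]
  if (length(x) == 0) {
    abort("`x` must contain at least one non-missing value.",
      class = "iprgclight_input_error"
    )
  }
  q <- quantile(x, c(0.25, 0.5, 0.75), type = type, names = FALSE)
  tibble(median = q[2], q1 = q[1], q3 = q[3], n = length(x))
}

check_groups <- function(data, value, group, min_groups = 2) {
  v <- dplyr::pull(data, {{ value }})
  g <- factor(dplyr::pull(data, {{ group }}))
  keep <- !is.na(v) & !is.na(g)
  v <- v[keep]
  g <- droplevels(g[keep])
  if (nlevels(g) < min_groups || any(table(g) == 0)) {
    abort("Need at least two non-empty groups.",
      class = "iprgclight_input_error"
    )
  }
  list(value = v, group = g)
}

#' Kruskal-Wallis rank test across groups
#'
#' First rung of the comparison ladder: an omnibus rank test (with tie
#' correction, chi-square p-value) across age groups or subtypes.
#' Significant omnibus tests are followed by pairwise Mann-Whitney tests
#' with Bonferroni correction ([pairwise_mw()]).
#'
#' @param data a data frame.
#' @param value,group columns (tidy-eval) holding the metric and the
#'   grouping factor.
#' @return one-row tibble: `statistic, df, p_value, n, method`.
#' @export
kw_test <- function(data, value, group) {
  x <- check_groups(data, {{ value }}, {{ group }})
  if (length(x$value) < 3) {
    abort("Need a total of at least 3 observations.",
      class = "iprgclight_input_error"
    )
  }
  if (length(unique(x$value)) == 1) {
    # all observations identical: no rank separation at all
    return(tibble(
      statistic = 0, df = nlevels(x$group) - 1, p_value = 1,
      n = length(x$value), method = "Kruskal-Wallis"
    ))
  }
  res <- kruskal.test(x$value, x$group)
  tibble(
    statistic = unname(res$statistic),
    df = unname(res$parameter),
    p_value = res$p.value,
    n = length(x$value),
    method = "Kruskal-Wallis"
  )
}

#' Pairwise Mann-Whitney tests with Bonferroni correction
#'
#' Two-tailed Mann-Whitney (Wilcoxon rank-sum) tests for every pair of
#' groups. Exact p-values are used for small tie-free groups (both sizes
#' <= `exact_max_n`); otherwise the normal approximation with tie
#' correction. Corrected p-values are `min(1, m * p)` with `m` the
#' number of planned comparisons (3 for the three developmental ages).
#'
#' @inheritParams kw_test
#' @param m number of comparisons for the Bonferroni correction;
#'   defaults to the number of pairs actually tested.
#' @param exact_max_n largest per-group size for exact p-values.
#' @return tibble, one row per pair: `group1, group2, n1, n2, statistic
#'   (U), p_value, p_adjusted, correction, m, method`.
#' @export
pairwise_mw <- function(data, value, group, m = NULL, exact_max_n = 8) {
  x <- check_groups(data, {{ value }}, {{ group }})
  lv <- levels(x$group)
  pairs <- utils::combn(lv, 2, simplify = FALSE)
  m <- m %||% length(pairs)
  purrr::map_dfr(pairs, function(p) {
    a <- x$value[x$group == p[1]]
    b <- x$value[x$group == p[2]]
    ties <- anyDuplicated(c(a, b)) > 0
    use_exact <- length(a) <= exact_max_n && length(b) <= exact_max_n && !ties
    res <- suppressWarnings(
      wilcox.test(a, b, alternative = "two.sided", exact = use_exact)
    )
    tibble(
      group1 = p[1], group2 = p[2],
      n1 = length(a), n2 = length(b),
      statistic = unname(res$statistic),
      p_value = res$p.value,
      p_adjusted = bonferroni(res$p.value, m),
      correction = "bonferroni", m = m,
      method = if (use_exact) "exact" else "normal approximation"
    )
  })
}

#' Bonferroni correction
#'
#' @param p p-value(s).
#' @param m number of comparisons.
#' @return `min(1, m * p)`, never smaller than `p`.
#' @export
bonferroni <- function(p, m) {
  if (any(m < 1)) {
    abort("`m` must be >= 1.", class = "iprgclight_input_error")
  }
  pmin(1, m * p)
}

#' One-way ANOVA through the grouped interface
#'
#' Used for density comparisons, where the omnibus test reported is a
#' standard one-way ANOVA rather than a rank test.
#'
#' @inheritParams kw_test
#' @return one-row tibble: `statistic (F), df1, df2, p_value, method`.
#' @export
grouped_anova <- function(data, value, group) {
  x <- check_groups(data, {{ value }}, {{ group }})
  fit <- aov(x$value ~ x$group)
  s <- summary(fit)[[1]]
  tibble(
    statistic = s[["F value"]][1],
    df1 = s[["Df"]][1], df2 = s[["Df"]][2],
    p_value = s[["Pr(>F)"]][1],
    method = "one-way ANOVA"
  )
}

#' Linear mixed model for longitudinal recovery data
#'
#' Recovery timecourses are repeated measures with missing cells
#' (unresponsive cells at single timepoints) and unbalanced group sizes,
#' so group/time effects are assessed with a linear mixed model: fixed
#' effects for group (age or subtype), recovery time and their
#' interaction, and a random intercept per subject. Fitting is delegated
#' to [lme4::lmer()]; the contract here is the model structure, not the
#' optimizer.
#'
#' @param data a long-format data frame.
#' @param value,group,time,subject columns (tidy-eval): response,
#'   grouping factor, recovery time, and subject id for the random
#'   intercept.
#' @return an `iprgc_lmm` object; see [tidy.iprgc_lmm()] and
#'   [glance.iprgc_lmm()].
#' @export
fit_recovery_lmm <- function(data, value, group, time, subject) {
  df <- tibble(
    value = dplyr::pull(data, {{ value }}),
    group = factor(dplyr::pull(data, {{ group }})),
    time = dplyr::pull(data, {{ time }}),
    subject = factor(dplyr::pull(data, {{ subject }}))
  ) %>% filter(!is.na(.data$value))
  if (nlevels(droplevels(df$subject)) < 2) {
    abort("Random intercept needs at least two subjects.",
      class = "iprgclight_input_error"
    )
  }
  has_group <- nlevels(droplevels(df$group)) >= 2
  form <- if (has_group) {
    value ~ group * time + (1 | subject)
  } else {
    value ~ time + (1 | subject)
  }
  fit <- lme4::lmer(form, data = df, REML = TRUE)
  structure(
    list(fit = fit, formula = form, n = nrow(df),
         n_subjects = nlevels(droplevels(df$subject))),
    class = "iprgc_lmm"
  )
}

#' @export
print.iprgc_lmm <- function(x, ...) {
  cat("<iprgc_lmm> ", deparse(x$formula), "\n")
  cat("  n =", x$n, "observations,", x$n_subjects, "subjects\n")
  print(tidy(x))
  invisible(x)
}

#' Tidy the fixed effects of a recovery mixed model
#'
#' @param x an `iprgc_lmm` from [fit_recovery_lmm()].
#' @param ... unused.
#' @return tibble: `term, estimate, std_error, statistic`.
#' @exportS3Method generics::tidy
tidy.iprgc_lmm <- function(x, ...) {
  co <- summary(x$fit)$coefficients
  tibble(
    term = rownames(co),
    estimate = as.numeric(co[, "Estimate"]),
    std_error = as.numeric(co[, "Std. Error"]),
    statistic = as.numeric(co[, "t value"])
  )
}

#' One-row summary of a recovery mixed model
#'
#' @param x an `iprgc_lmm`.
#' @param ... unused.
#' @return tibble with fit summaries, including the random-intercept
#'   standard deviation `sd_subject` and residual `sd_residual`.
#' @exportS3Method generics::glance
glance.iprgc_lmm <- function(x, ...) {
  vc <- as.data.frame(lme4::VarCorr(x$fit))
  tibble(
    nobs = x$n,
    n_subjects = x$n_subjects,
    sd_subject = vc$sdcor[vc$grp == "subject"][1],
    sd_residual = vc$sdcor[vc$grp == "Residual"][1],
    logLik = as.numeric(logLik(x$fit)),
    AIC = AIC(x$fit),
    BIC = BIC(x$fit)
  )
}

#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' Simulate a longitudinal recovery dataset with known parameters
#'
#' Generates subject-level repeated measures for exercising the mixed
#' model: per-subject random intercepts with standard deviation
#' `sd_subject`, fixed group and time effects, Gaussian residuals, and a
#' fraction of missing cells (the reason a mixed model is used instead of
#' repeated-measures ANOVA).
#'
#' @param n_subjects number of subjects (split evenly across groups).
#' @param groups group labels.
#' @param times measurement times (minutes of recovery).
#' @param intercept,group_effects,time_slope,interaction fixed-effect
#'   generating values; `group_effects` is a per-group offset vector
#'   (first = reference = 0) and `interaction` a per-group extra time
#'   slope.
#' @param sd_subject random-intercept standard deviation.
#' @param sd_residual residual standard deviation.
#' @param missing_frac fraction of cells dropped at random.
#' @param seed integer seed.
#' @return tibble: `subject, group, time, value`.
#' @export
simulate_lmm_dataset <- function(n_subjects = 40,
                                 groups = c("P8", "P30"),
                                 times = seq(10, 60, by = 10),
                                 intercept = 50,
                                 group_effects = c(0, -30),
                                 time_slope = 0.8,
                                 interaction = c(0, -0.4),
                                 sd_subject = 2,
                                 sd_residual = 1,
                                 missing_frac = 0.1,
                                 seed = 1L) {
  stopifnot(length(group_effects) == length(groups),
            length(interaction) == length(groups))
  withr::with_seed(as.integer(seed), {
    subj_group <- rep(groups, length.out = n_subjects)
    u <- rnorm(n_subjects, 0, sd_subject)
    df <- tidyr::expand_grid(
      subject = seq_len(n_subjects),
      time = times
    ) %>%
      mutate(
        group = subj_group[.data$subject],
        g_idx = match(.data$group, groups),
        value = intercept + group_effects[.data$g_idx] +
          (time_slope + interaction[.data$g_idx]) * .data$time +
          u[.data$subject] + rnorm(n(), 0, sd_residual),
        subject = sprintf("s%03d", .data$subject)
      ) %>%
      select("subject", "group", "time", "value")
    df[runif(nrow(df)) >= missing_frac, ]
  })
}
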