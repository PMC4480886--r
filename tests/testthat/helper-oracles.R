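# Independent oracles, coded without reference to the package internals.

# Truth table for the electrophysiologic subtype rules, written as a
# direct transcription of the published criteria (independent of
# classify_p8's case_when ordering).
oracle_subtype_p8 <- function(latency, ratio) {
  if (!is.na(latency) && latency <= 12) {
    return("III")
  }
  # latency > 12 s, or no response at the dim light at all
  if (is.na(ratio)) {
    return("unclassifiable")
  }
  if (ratio > 0.10) "I" else "II"
}

oracle_subtype_peo <- function(latency) {
  if (is.na(latency)) {
    return("unclassifiable")
  }
  if (latency <= 12) "III" else "II"
}

# Brute-force spike counting by explicit loops over the raw spike list.
oracle_count <- function(times, lo, hi, closed_right = FALSE) {
  n <- 0L
  for (t in times) {
    if (t >= lo && (if (closed_right) t <= hi else t < hi)) n <- n + 1L
  }
  n
}

oracle_psth_counts <- function(times, t0, bin_width, n_bins) {
  counts <- integer(n_bins)
  for (b in seq_len(n_bins)) {
    counts[b] <- oracle_count(times, t0 + (b - 1) * bin_width, t0 + b * bin_width)
  }
  counts
}

# Exact two-tailed Mann-Whitney p-value by full enumeration of all
# choose(n1+n2, n1) group assignments of the pooled sample.
oracle_mw_exact <- function(x, y) {
  pooled <- c(x, y)
  n1 <- length(x)
  r <- rank(pooled)
  u_obs <- sum(r[seq_len(n1)]) - n1 * (n1 + 1) / 2
  combs <- utils::combn(length(pooled), n1)
  u_all <- apply(combs, 2, function(idx) {
    sum(r[idx]) - n1 * (n1 + 1) / 2
  })
  mu <- n1 * length(y) / 2
  # two-sided: double the smaller tail, capped at 1 (matches the exact
  # Wilcoxon convention for tie-free data)
  p_lo <- mean(u_all <= u_obs)
  p_hi <- mean(u_all >= u_obs)
  min(1, 2 * min(p_lo, p_hi))
}

# Kruskal-Wallis H from the textbook rank formula (no ties).
oracle_kw_h <- function(groups) {
  pooled <- unlist(groups)
  n <- length(pooled)
  r <- rank(pooled)
  idx <- rep(seq_along(groups), lengths(groups))
  h <- 0
  for (g in seq_along(groups)) {
    rg <- r[idx == g]
    h <- h + length(rg) * (mean(rg) - (n + 1) / 2)^2
  }
  12 / (n * (n + 1)) * h
}

# Firing-pattern partition, restated independently.
oracle_pattern <- function(blocks) {
  spiking <- blocks > 0
  if (all(spiking)) {
    "continuous"
  } else if (any(spiking[7:12])) {
    "intermittent"
  } else {
    "transient"
  }
}

# small deterministic spike train builders
uniform_train <- function(rate_hz, t0, t1) {
  if (rate_hz <= 0) {
    return(numeric(0))
  }
  seq(t0, t1, by = 1 / rate_hz)[-1] - 1 / (2 * rate_hz)
}

spike_tbl <- function(times, cell = "c1", retina = "r1") {
  tibble::tibble(retina_id = retina, cell_id = cell, spike_time_s = times)
}

event_tbl <- function(onset, offset, ir = 13.6, kind = "light") {
  tibble::tibble(
    kind = kind, onset_s = onset, offset_s = offset,
    ir = ifelse(kind == "light", ir, NA_real_),
    wavelength_nm = ifelse(kind == "light", 480, NA_real_)
  )
}
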