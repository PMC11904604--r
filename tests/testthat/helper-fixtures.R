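# Shared fixtures and independent oracles used across the suite.

random_peptide_sequence <- function(len) {
  paste(sample(residue_alphabet(), len, replace = TRUE), collapse = "")
}

# Independent neutral-mass oracle: explicit per-residue lookup and a plain
# loop, sharing nothing with peptide_mass() beyond the constants' sources.
oracle_neutral_mass <- function(sequence, conv) {
  total <- conv$water_mass
  for (r in strsplit(sequence, "")[[1]])
    total <- total + conv$residue_table[[r]]
  total
}

# Brute-force EP15-A3 variance components via explicit double loops.
oracle_precision <- function(panel) {
  d <- nrow(panel); n <- ncol(panel)
  grand <- sum(panel) / (d * n)
  ssw <- 0
  for (i in seq_len(d)) {
    m_i <- sum(panel[i, ]) / n
    for (j in seq_len(n)) ssw <- ssw + (panel[i, j] - m_i)^2
  }
  ssb <- 0
  for (i in seq_len(d)) ssb <- ssb + (sum(panel[i, ]) / n - grand)^2
  ms_w <- ssw / (d * (n - 1))
  ms_b <- n * ssb / (d - 1)
  v_w <- ms_w
  v_b <- max((ms_b - ms_w) / n, 0)
  list(grand = grand,
       cv_intra = 100 * sqrt(v_w) / grand,
       cv_inter = 100 * sqrt(v_b) / grand,
       cv_total = 100 * sqrt(v_w + v_b) / grand)
}

# Brute-force LLOQ: for every level, explicitly check that it and every
# higher level are below threshold; return the lowest such level.
oracle_lloq <- function(levels, cvs, threshold) {
  best <- NA_real_
  for (i in seq_along(levels)) {
    ok <- TRUE
    for (j in seq_along(levels))
      if (levels[j] >= levels[i] && cvs[j] >= threshold) ok <- FALSE
    if (ok && (is.na(best) || levels[i] < best)) best <- levels[i]
  }
  best
}

# Analytic Gaussian trace on a regular grid.
gaussian_trace <- function(area, apex = 11.55, sigma = 0.05,
                           from = 11.0, to = 12.2, dwell = 0.02) {
  tt <- seq(from, to, by = dwell)
  data.frame(time_min = tt,
             intensity = area / (sigma * sqrt(2 * pi)) *
               exp(-(tt - apex)^2 / (2 * sigma^2)))
}

two_point_curve <- function() {
  fit_calibration(data.frame(molar_ratio = c(1, 6),
                             response_ratio = c(1, 6)))
}
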