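# fixtures built in code; no data files

tiny_db <- function() {
  as_compound_db(data.frame(
    compound_id = c("F1", "F2", "ISO_A", "ISO_B", "STD1"),
    name = c("glutarate", "mass_only_entry", "hexoseA", "hexoseB",
             "standard_cpd"),
    formula = c("C5H8O4", NA, "C6H12O6", "C6H12O6", "C4H9NO2"),
    neutral_mass = c(NA, 132.053000, NA, NA, NA),
    class_label = c("others", "others", "lipids", "lipids", "others"),
    is_standard = c(FALSE, FALSE, FALSE, FALSE, TRUE),
    stringsAsFactors = FALSE
  ))
}

tiny_design <- function(n_bio = 1L, n_tech = 3L, genotypes = "WT",
                        organ = "kidney") {
  g <- expand.grid(technical_replicate = seq_len(n_tech),
                   biological_replicate = seq_len(n_bio),
                   genotype = genotypes, stringsAsFactors = FALSE)
  as_sample_design(data.frame(
    sample_id = sprintf("%s_b%d_t%d", g$genotype, g$biological_replicate,
                        g$technical_replicate),
    genotype = g$genotype, treatment = "none",
    biological_replicate = g$biological_replicate,
    technical_replicate = g$technical_replicate,
    organ = organ, stringsAsFactors = FALSE
  ))
}

tiny_peaks <- function(design, areas) {
  n <- nrow(areas)
  df <- data.frame(peak_id = sprintf("P%d", seq_len(n)),
                   mz = seq(100, 100 + n - 1),
                   rt = rep(5, n), polarity = "positive",
                   height = rep(5000, n), stringsAsFactors = FALSE)
  colnames(areas) <- design$sample_id
  cbind(df, as.data.frame(areas, check.names = FALSE))
}

# synthetic match table for fitting the error mixture directly
make_matches <- function(e_best, e_second) {
  data.frame(peak_id = sprintf("P%d", seq_along(e_best)),
             e_best = e_best, e_second = e_second,
             within_window = TRUE, is_standard_match = FALSE,
             n_isomers = 1L, best_formula = "X", best_compound_id = "X",
             adduct = "[M+H]+", stringsAsFactors = FALSE)
}

# independent brute-force q-value oracle: for each p_i, the minimum over all
# thresholds t = p_j >= p_i of pi0 * m * t / #{p <= t}
brute_qvalues <- function(p, lambda = 0.5, pi0 = NULL) {
  m <- length(p)
  if (is.null(pi0)) pi0 <- min(1, sum(p > lambda) / (m * (1 - lambda)))
  q <- numeric(m)
  for (i in seq_len(m)) {
    ts <- p[p >= p[i]]
    q[i] <- min(1, min(vapply(ts, function(t) {
      pi0 * m * t / sum(p <= t)
    }, numeric(1))))
  }
  q
}
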