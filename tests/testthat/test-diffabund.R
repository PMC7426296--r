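test_that("peak areas aggregate by compound identity", {
  design <- tiny_design(n_bio = 2, n_tech = 1)
  peaks <- tiny_peaks(design, matrix(c(100, 50, 7, 10, 20, 3),
                                     nrow = 3))
  ids <- data.frame(peak_id = c("P1", "P2", "P3"),
                    compound_id = c("X", "X", "Y"),
                    formula = c("C2H4", "C2H4", "C3H6"),
                    adduct = "[M+H]+", ppm_error = 0, posterior = 0.9,
                    status = c("assigned", "assigned", "unassigned"),
                    stringsAsFactors = FALSE)
  cm <- aggregate_by_compound(ids, peaks, sample_cols = design$sample_id)
  expect_equal(dim(cm$areas), c(1L, 2L))  # unassigned peak excluded
  expect_equal(unname(cm$areas["X", ]), c(150, 30))
  expect_equal(cm$compounds$n_peaks, 2L)

  ids$status <- "unassigned"
  expect_warning(empty <- aggregate_by_compound(ids, peaks,
                                                sample_cols = design$sample_id),
                 "no assigned")
  expect_equal(nrow(empty$areas), 0L)
})

test_that("log2 transform applies the percentile fudge factor", {
  m <- matrix(c(412, 0, 300, 1000), 2)
  tr <- log_transform(m, fudge = 100)
  expect_equal(tr$log2[1, 1], 9)            # log2(512)
  expect_lt(abs(tr$log2[2, 1] - 6.6439), 1e-4)  # log2(100)
  # computed fudge is the linear-interpolation 10th percentile
  m2 <- matrix(1:10, 2)
  tr2 <- log_transform(m2)
  expect_equal(tr2$fudge, unname(quantile(1:10, 0.1)))
  expect_true(all(tr2$log2 >= log2(tr2$fudge)))
  expect_error(log_transform(matrix(0, 2, 2)), "log2 undefined")
})

test_that("two-group t statistics match the closed-form oracle", {
  log2mat <- rbind(a = c(1, 2, 3, 4, 5, 6), b = rep(2, 6))
  rawmat <- rbind(a = c(100, 100, 100, 1100, 1100, 1100), b = rep(5, 6))
  colnames(log2mat) <- colnames(rawmat) <- paste0("s", 1:6)
  groups <- setNames(rep(c("WT", "KO"), each = 3), colnames(log2mat))
  res <- differential_test(log2mat, rawmat, groups, "WT", "KO")
  # {1,2,3} vs {4,5,6}: pooled-variance t with df 4
  expect_lt(abs(res$t_statistic[1] - (-3.674)), 0.001)
  expect_lt(abs(res$p_value[1] - 0.0213), 0.0005)
  expect_equal(res$fold_change[1], 100 / 1100)
  # identical groups: t = 0, p = 1, Fc = 1
  expect_equal(res$t_statistic[2], 0)
  expect_equal(res$p_value[2], 1)
  expect_equal(res$fold_change[2], 1)
  # raw-scale means 100 vs 1100 give an 11-fold change in the KO direction
  res2 <- differential_test(log2mat, rawmat, groups, "KO", "WT")
  expect_equal(res2$fold_change[1], 11)
})

test_that("swapping contrast arms inverts Fc and t but keeps p and q", {
  set.seed(31)
  log2mat <- matrix(rnorm(120), 10,
                    dimnames = list(paste0("c", 1:10), paste0("s", 1:12)))
  rawmat <- 2^log2mat
  groups <- setNames(rep(c("WT", "KO"), each = 6), colnames(log2mat))
  a <- differential_test(log2mat, rawmat, groups, "KO", "WT")
  b <- differential_test(log2mat, rawmat, groups, "WT", "KO")
  expect_equal(a$fold_change, 1 / b$fold_change)
  expect_equal(a$t_statistic, -b$t_statistic)
  expect_equal(a$p_value, b$p_value)
  expect_equal(storey_qvalues(a$p_value), storey_qvalues(b$p_value))
})

test_that("q-values follow the fixed-lambda procedure", {
  expect_equal(storey_qvalues(c(0.01, 0.02, 0.5, 0.9)),
               c(0.02, 0.02, 1 / 3, 0.45), tolerance = 1e-12)
  expect_equal(storey_qvalues(rep(1, 5)), rep(1, 5))
  expect_equal(storey_qvalues(0.04, pi0 = 1), 0.04)
  expect_error(storey_qvalues(c(0.2, 1.2)), "\\[0, 1\\]")
  # monotone in p and equal to the brute-force oracle on random vectors
  set.seed(41)
  for (i in 1:25) {
    p <- runif(sample(5:40, 1))
    q <- storey_qvalues(p)
    expect_true(all(q >= 0 & q <= 1))
    expect_true(all(diff(q[order(p)]) >= -1e-15))
    expect_equal(q, brute_qvalues(p), tolerance = 1e-12)
  }
})

test_that("significance rule combines q and fold-change thresholds", {
  res <- data.frame(
    compound_id = paste0("c", 1:6),
    fold_change = c(1.3, 0.8, 1.1, 2.0, 1.25, 0.5),
    log2fc = log2(c(1.3, 0.8, 1.1, 2.0, 1.25, 0.5)),
    p_value = c(0.001, 0.002, 0.001, 0.2, 0.01, 0.04),
    q_value = c(0.10, 0.10, 0.10, 0.30, 0.14, 0.16),
    class_label = c("lipids", "lipids", "others", "others",
                    "acylcarnitines", "others"),
    stringsAsFactors = FALSE
  )
  got <- significance_filter(res, q_threshold = 0.15, fc_threshold = 1.2)
  # brute-force re-application of the rule
  manual <- res$q_value <= 0.15 & pmax(res$fold_change,
                                       1 / res$fold_change) >= 1.2
  expect_equal(got$significant, manual)
  cnt <- attr(got, "counts")
  expect_equal(cnt$n_significant, sum(manual))
  expect_equal(cnt$n_up, 2L)    # c1 and c5 up
  expect_equal(cnt$n_down, 1L)  # c2 down (1/Fc = 1.25)

  v <- volcano_table(got)
  expect_equal(v$neg_log10_p[1], 3)  # p = 0.001
  cs <- class_summary(got)
  expect_equal(sum(cs$fraction), 1)
  # empty heatmap and summary when nothing is significant
  none <- significance_filter(res, q_threshold = 1e-6)
  expect_equal(nrow(class_summary(none)), 0L)
  hm <- heatmap_matrix(matrix(0, 6, 2, dimnames = list(res$compound_id, NULL)),
                       none)
  expect_equal(nrow(hm), 0L)
})

test_that("spiked fold changes are recovered end to end at study power", {
  # 5 compounds at 2-fold in 100 nulls, n = 6 vs 6, within-group CV 20%
  set.seed(51)
  hits <- 0L
  n_rep <- 50L
  sdlog <- sqrt(log(1 + 0.2^2))
  for (r in seq_len(n_rep)) {
    m <- 105L
    base <- rlnorm(m, log(5e4), 1)
    raw <- matrix(rlnorm(m * 12, meanlog = -sdlog^2 / 2, sdlog = sdlog),
                  m, 12) * base
    raw[1:5, 7:12] <- raw[1:5, 7:12] * 2
    dimnames(raw) <- list(paste0("c", 1:m), paste0("s", 1:12))
    tr <- log_transform(raw)
    groups <- setNames(rep(c("WT", "KO"), each = 6), colnames(raw))
    res <- differential_test(tr$log2, raw, groups, "KO", "WT")
    res$q_value <- storey_qvalues(res$p_value)
    res <- significance_filter(res, 0.15, 1.2)
    hits <- hits + sum(res$significant[1:5])
  }
  expect_gte(hits / (5 * n_rep), 0.9)
})
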