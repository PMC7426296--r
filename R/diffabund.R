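# Per-compound quantification and two-group differential statistics:
# summed peak areas per identified compound, log2 transform with a
# 10th-percentile fudge factor, equal-variance two-sample t tests, Storey
# q-values and the combined q / fold-change significance rule.

#' Aggregate identified peaks into a compound-by-sample matrix
#'
#' Sums the area values of all peaks sharing a compound identity in each
#' sample (abundant species elute over several peaks); peaks that are not
#' `assigned` or `standard` are excluded.
#'
#' @param identifications Output of [assign_identifications()].
#' @param peaks Peak table whose area columns are biological samples (after
#'   [collapse_technical()]).
#' @param db Optional `compound_db` used to attach `class_label`.
#' @param sample_cols Area column names; defaults to all columns after the
#'   peak metadata.
#' @return A list of class `compound_matrix`: `areas` (matrix, compounds x
#'   samples) and `compounds` (data frame with `compound_id`, `formula`,
#'   `class_label`, `n_peaks`).
#' @export
aggregate_by_compound <- function(identifications, peaks, db = NULL,
                                  sample_cols = NULL) {
  if (is.null(sample_cols)) {
    sample_cols <- setdiff(names(peaks),
                           c("peak_id", "mz", "rt", "polarity", "height"))
  }
  keep <- identifications$status %in% c("assigned", "standard")
  ids <- identifications[keep, , drop = FALSE]
  if (nrow(ids) == 0L) {
    warning("no assigned peaks; returning an empty compound matrix")
    return(structure(list(
      areas = matrix(numeric(0), nrow = 0, ncol = length(sample_cols),
                     dimnames = list(NULL, sample_cols)),
      compounds = data.frame(compound_id = character(0),
                             formula = character(0),
                             class_label = character(0),
                             n_peaks = integer(0))),
      class = "compound_matrix"))
  }
  rows <- match(ids$peak_id, peaks$peak_id)
  if (any(is.na(rows))) stop("identifications refer to unknown peak_id")
  areas <- as.matrix(peaks[rows, sample_cols, drop = FALSE])
  agg <- rowsum(areas, group = ids$compound_id)
  comp <- data.frame(
    compound_id = rownames(agg),
    formula = ids$formula[match(rownames(agg), ids$compound_id)],
    n_peaks = as.integer(table(ids$compound_id)[rownames(agg)]),
    stringsAsFactors = FALSE
  )
  comp$class_label <- if (!is.null(db)) {
    lab <- db$class_label[match(comp$compound_id, db$compound_id)]
    ifelse(is.na(lab), "others", lab)
  } else "others"
  structure(list(areas = agg, compounds = comp), class = "compound_matrix")
}

#' Log2 transform with a percentile fudge factor
#'
#' Adds a small constant `c` equal to the 10th percentile of all values in
#' the stratum (linear-interpolation percentile, `stats::quantile` type 7)
#' before taking `log2`, taming fold changes of low-abundance peaks.
#'
#' @param x Numeric matrix of raw areas, or a `compound_matrix`.
#' @param percentile Percentile defining the fudge factor (default 0.10).
#' @param fudge Override the computed fudge factor.
#' @return A list: `log2` (transformed matrix), `fudge`, `percentile`.
#' @export
log_transform <- function(x, percentile = 0.10, fudge = NULL) {
  if (inherits(x, "compound_matrix")) x <- x$areas
  if (is.null(fudge)) {
    fudge <- as.numeric(stats::quantile(x, probs = percentile, type = 7,
                                        names = FALSE))
  }
  if (fudge < 0) stop("fudge factor must be non-negative")
  if (any(x + fudge <= 0)) {
    stop("zero values with a zero fudge factor: log2 undefined")
  }
  list(log2 = log2(x + fudge), fudge = fudge, percentile = percentile)
}

#' Two-group differential test per compound
#'
#' Equal-variance two-sample t test (two-sided) on the log2-transformed
#' values; the fold change `Fc` is the ratio of raw-scale group means
#' (numerator over denominator). `log2fc` is the difference of transformed
#' group means. Welch and paired variants are available for sensitivity
#' checks.
#'
#' @param log2mat Transformed matrix from [log_transform()].
#' @param rawmat Raw area matrix on the same rows/columns.
#' @param groups Named character vector mapping column names to group labels.
#' @param numerator,denominator Group labels contrasted as
#'   numerator/denominator.
#' @param compounds Optional compound annotation data frame (joined by
#'   `compound_id` = rownames).
#' @param variant `"equal_variance"` (default), `"welch"` or `"paired"`.
#' @return Data frame with per-compound group means, `fold_change`,
#'   `log2fc`, `t_statistic`, `p_value` and a `degenerate` flag for rows with
#'   zero variance in both arms.
#' @export
differential_test <- function(log2mat, rawmat, groups, numerator, denominator,
                              compounds = NULL,
                              variant = c("equal_variance", "welch",
                                          "paired")) {
  variant <- match.arg(variant)
  cols_n <- names(groups)[groups == numerator]
  cols_d <- names(groups)[groups == denominator]
  if (length(cols_n) < 2L || length(cols_d) < 2L) {
    stop("each contrast arm needs at least 2 biological replicates")
  }
  if (variant == "paired" && length(cols_n) != length(cols_d)) {
    stop("paired test requires equal arm sizes")
  }
  m <- nrow(log2mat)
  res <- data.frame(
    compound_id = rownames(log2mat),
    mean_num = rowMeans(rawmat[, cols_n, drop = FALSE]),
    mean_den = rowMeans(rawmat[, cols_d, drop = FALSE]),
    log2fc = rowMeans(log2mat[, cols_n, drop = FALSE]) -
      rowMeans(log2mat[, cols_d, drop = FALSE]),
    t_statistic = NA_real_, p_value = NA_real_, degenerate = FALSE,
    stringsAsFactors = FALSE, row.names = NULL
  )
  res$fold_change <- res$mean_num / res$mean_den
  for (i in seq_len(m)) {
    x <- log2mat[i, cols_n]
    y <- log2mat[i, cols_d]
    if (stats::var(x) == 0 && stats::var(y) == 0) {
      if (isTRUE(all.equal(mean(x), mean(y)))) {
        res$t_statistic[i] <- 0
        res$p_value[i] <- 1
      } else {
        res$degenerate[i] <- TRUE
      }
      next
    }
    tt <- switch(variant,
      equal_variance = stats::t.test(x, y, var.equal = TRUE),
      welch = stats::t.test(x, y, var.equal = FALSE),
      paired = stats::t.test(x, y, paired = TRUE)
    )
    res$t_statistic[i] <- unname(tt$statistic)
    res$p_value[i] <- tt$p.value
  }
  if (!is.null(compounds)) {
    j <- match(res$compound_id, compounds$compound_id)
    res$formula <- compounds$formula[j]
    res$class_label <- compounds$class_label[j]
  }
  res
}

#' Storey q-values
#'
#' Implements the q-value procedure with a fixed-lambda null-proportion
#' estimate: `pi0 = #\{p > lambda\} / (m (1 - lambda))` capped at 1, and
#' `q_(i) = min_{j >= i} pi0 * m * p_(j) / j` on the sorted p-values.
#'
#' @param p P-values in `[0, 1]`.
#' @param lambda Tuning parameter for the null-proportion estimate
#'   (default 0.5).
#' @param pi0 Optional override of the estimated null proportion.
#' @return Q-values in `[0, 1]`, monotone in `p`.
#' @examples
#' storey_qvalues(c(0.01, 0.02, 0.5, 0.9)) # 0.02 0.02 0.3333 0.45
#' @export
storey_qvalues <- function(p, lambda = 0.5, pi0 = NULL) {
  if (length(p) == 0L) return(numeric(0))
  if (any(is.na(p)) || any(p < 0 | p > 1)) stop("p-values must lie in [0, 1]")
  m <- length(p)
  if (is.null(pi0)) {
    pi0 <- min(1, sum(p > lambda) / (m * (1 - lambda)))
  }
  o <- order(p)
  q_sorted <- pi0 * m * p[o] / seq_len(m)
  q_sorted <- rev(cummin(rev(q_sorted)))
  q_sorted <- pmin(q_sorted, 1)
  q <- numeric(m)
  q[o] <- q_sorted
  q
}

#' Combined q-value / fold-change significance rule
#'
#' Flags compounds with `q <= q_threshold` and
#' `max(Fc, 1/Fc) >= fc_threshold` (a minimal relative change in either
#' direction), and records the regulation direction.
#'
#' @param results Differential results carrying `q_value` and `fold_change`.
#' @param q_threshold FDR threshold (0.15 for a sparse tissue data set, 0.05
#'   for plasma-scale data).
#' @param fc_threshold Minimal fold change (default 1.2, i.e. a 20% change).
#' @return `results` with `significant` and `direction` columns; counts of
#'   up/down-regulated compounds in the `"counts"` attribute.
#' @export
significance_filter <- function(results, q_threshold = 0.15,
                                fc_threshold = 1.2) {
  if (is.null(results$q_value)) stop("results carry no q_value column")
  fc <- results$fold_change
  sig <- !is.na(results$q_value) & results$q_value <= q_threshold &
    pmax(fc, 1 / fc) >= fc_threshold
  results$significant <- sig
  results$direction <- ifelse(!sig, NA_character_,
                              ifelse(fc >= 1, "up", "down"))
  attr(results, "counts") <- list(
    n_significant = sum(sig),
    n_up = sum(sig & fc >= 1),
    n_down = sum(sig & fc < 1)
  )
  results
}

#' Volcano-plot table
#'
#' @param results Filtered differential results.
#' @return Data frame `compound_id`, `log2fc`, `neg_log10_p`, `significant`,
#'   `direction`.
#' @export
volcano_table <- function(results) {
  data.frame(
    compound_id = results$compound_id,
    log2fc = results$log2fc,
    neg_log10_p = -log10(results$p_value),
    significant = results$significant,
    direction = results$direction,
    stringsAsFactors = FALSE
  )
}

#' Heatmap matrix of significant compounds grouped by class
#'
#' @param log2mat Transformed matrix (rows = compounds).
#' @param results Filtered differential results with `class_label`.
#' @return Matrix of transformed values, rows ordered by class then
#'   compound id; empty when nothing is significant.
#' @export
heatmap_matrix <- function(log2mat, results) {
  sig <- results[results$significant, , drop = FALSE]
  if (nrow(sig) == 0L) {
    return(log2mat[integer(0), , drop = FALSE])
  }
  cls <- if (!is.null(sig$class_label)) sig$class_label else
    rep("others", nrow(sig))
  ord <- order(cls, sig$compound_id)
  log2mat[sig$compound_id[ord], , drop = FALSE]
}

#' Class composition of the significant compounds
#'
#' @param results Filtered differential results with `class_label`.
#' @return Data frame `class_label`, `n`, `fraction`; fractions sum to 1
#'   over significant compounds (empty when nothing is significant).
#' @export
class_summary <- function(results) {
  sig <- results[results$significant, , drop = FALSE]
  if (nrow(sig) == 0L) {
    return(data.frame(class_label = character(0), n = integer(0),
                      fraction = numeric(0)))
  }
  cls <- if (!is.null(sig$class_label)) sig$class_label else
    rep("others", nrow(sig))
  tab <- table(cls)
  data.frame(class_label = names(tab), n = as.integer(tab),
             fraction = as.numeric(tab) / nrow(sig),
             stringsAsFactors = FALSE, row.names = NULL)
}
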