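# Taxon-level 16S comparison: rank aggregation of relative abundances,
# one-sided equal-variance group tests ranked by percent change, and
# parent-to-child taxonomy flows for Sankey-style summaries.

.TAXO_RANKS <- c("domain", "phylum", "class", "order", "family", "genus",
                 "species")

# Greengenes-style prefixes ("k__Bacteria") accepted and stripped
.parse_taxonomy <- function(strings) {
  parts <- strsplit(as.character(strings), ";", fixed = TRUE)
  out <- matrix("", nrow = length(parts), ncol = 7L,
                dimnames = list(NULL, .TAXO_RANKS))
  for (i in seq_along(parts)) {
    p <- trimws(parts[[i]])
    p <- sub("^[a-zA-Z]__", "", p)
    k <- min(length(p), 7L)
    if (k > 0L) out[i, seq_len(k)] <- p[seq_len(k)]
  }
  out
}

#' Construct a taxon-by-sample table
#'
#' @param abund Numeric matrix (taxa x samples) of counts or relative
#'   abundances.
#' @param taxonomy Character vector of semicolon-separated taxonomy paths
#'   (domain to species, Greengenes prefixes accepted), one per row.
#' @return A list of class `taxon_table`: `abund`, `taxonomy` and the parsed
#'   7-rank matrix `ranks`.
#' @export
as_taxon_table <- function(abund, taxonomy) {
  abund <- as.matrix(abund)
  if (nrow(abund) != length(taxonomy)) {
    stop("taxonomy length must match the number of rows")
  }
  if (any(abund < 0)) stop("negative abundances")
  structure(list(abund = abund,
                 taxonomy = as.character(taxonomy),
                 ranks = .parse_taxonomy(taxonomy)),
            class = "taxon_table")
}

#' Read a taxon table from delimited text
#'
#' The file must contain a `taxonomy` column (semicolon-separated ranks);
#' all remaining columns are taken as samples.
#'
#' @param path Delimited text file.
#' @return A `taxon_table`.
#' @export
read_taxon_table <- function(path) {
  d <- .read_delim_auto(path)
  if (is.null(d)) stop(sprintf("empty taxon table: %s", path))
  tcol <- which(tolower(names(d)) == "taxonomy")
  if (length(tcol) != 1L) stop("taxon table needs a 'taxonomy' column")
  abund <- as.matrix(d[, -tcol, drop = FALSE])
  as_taxon_table(abund, d[[tcol]])
}

#' Convert counts to per-sample relative abundances
#'
#' @param t A `taxon_table`.
#' @return A `taxon_table` whose columns sum to 1.
#' @export
as_relative <- function(t) {
  cs <- colSums(t$abund)
  if (any(cs <= 0)) stop("sample with zero total abundance")
  t$abund <- sweep(t$abund, 2L, cs, "/")
  t
}

#' Aggregate a taxon table at a taxonomic rank
#'
#' Sums abundances over all taxa sharing the taxonomy-path prefix up to the
#' requested rank; per-sample column totals are conserved.
#'
#' @param t A `taxon_table`.
#' @param rank One of `"domain"`, `"phylum"`, `"class"`, `"order"`,
#'   `"family"`, `"genus"`, `"species"`.
#' @return The aggregated `taxon_table`.
#' @export
aggregate_taxa <- function(t, rank) {
  r <- match(rank, .TAXO_RANKS)
  if (is.na(r)) stop(sprintf("unknown rank '%s'", rank))
  key <- apply(t$ranks[, seq_len(r), drop = FALSE], 1L, paste,
               collapse = ";")
  agg <- rowsum(t$abund, group = key)
  as_taxon_table(agg, rownames(agg))
}

#' Two-group taxon comparison
#'
#' Computes per-taxon percent change of the alternate group relative to the
#' reference, `(mean_alt - mean_ref) / mean_ref * 100`, with a one-sided
#' equal-variance t test taken in the direction of the observed change (an
#' anti-conservative convention: the direction is chosen from the data).
#' Counts are converted to relative abundances per sample before testing.
#' Taxa are ranked by absolute percent change.
#'
#' @param t A `taxon_table`.
#' @param groups Named character vector mapping sample (column) names to
#'   group labels.
#' @param ref,alt Reference and alternate group labels.
#' @param p_threshold One-sided significance threshold (default 0.1).
#' @param normalize Convert to relative abundances first (default `TRUE`).
#' @return Data frame `taxonomy`, `mean_ref`, `mean_alt`, `percent_change`,
#'   `t_statistic`, `p_one_sided`, `flagged`, ranked by |percent change|.
#' @export
compare_taxa_groups <- function(t, groups, ref = "WT", alt = "KO",
                                p_threshold = 0.1, normalize = TRUE) {
  cols_r <- names(groups)[groups == ref]
  cols_a <- names(groups)[groups == alt]
  if (length(cols_r) < 2L || length(cols_a) < 2L) {
    stop("each group needs at least 2 samples")
  }
  if (normalize) t <- as_relative(t)
  A <- t$abund
  n <- nrow(A)
  res <- data.frame(
    taxonomy = t$taxonomy,
    mean_ref = rowMeans(A[, cols_r, drop = FALSE]),
    mean_alt = rowMeans(A[, cols_a, drop = FALSE]),
    percent_change = NA_real_, t_statistic = NA_real_,
    p_one_sided = NA_real_, flagged = FALSE,
    stringsAsFactors = FALSE
  )
  res$percent_change <- ifelse(res$mean_ref > 0,
                               (res$mean_alt - res$mean_ref) /
                                 res$mean_ref * 100, NA_real_)
  df <- length(cols_r) + length(cols_a) - 2L
  for (i in seq_len(n)) {
    x <- A[i, cols_a]
    y <- A[i, cols_r]
    sp2 <- ((length(x) - 1) * stats::var(x) +
              (length(y) - 1) * stats::var(y)) / df
    if (sp2 == 0) {
      if (isTRUE(all.equal(mean(x), mean(y)))) {
        res$t_statistic[i] <- 0
        res$p_one_sided[i] <- 0.5
      }
      next
    }
    tt <- (mean(x) - mean(y)) / sqrt(sp2 * (1 / length(x) + 1 / length(y)))
    res$t_statistic[i] <- tt
    # one-sided in the direction of the observed change
    res$p_one_sided[i] <- stats::pt(abs(tt), df, lower.tail = FALSE)
  }
  res$flagged <- !is.na(res$p_one_sided) & res$p_one_sided < p_threshold &
    !is.na(res$percent_change)
  res[order(-abs(res$percent_change), na.last = TRUE), , drop = FALSE]
}

#' Taxonomy-flow edge list (Sankey decomposition)
#'
#' For each adjacent rank pair, builds parent-to-child edges whose weight is
#' the group-mean relative abundance carried by the child; ranks missing in
#' a lineage are labelled `unclassified`, so child weights always sum to the
#' parent weight.
#'
#' @param t A `taxon_table`.
#' @param samples Column names to average over (default: all).
#' @param normalize Convert to relative abundances first (default `TRUE`).
#' @return Data frame `rank`, `parent`, `child`, `weight`.
#' @export
sankey_flows <- function(t, samples = NULL, normalize = TRUE) {
  if (normalize) t <- as_relative(t)
  if (is.null(samples)) samples <- colnames(t$abund)
  w <- rowMeans(t$abund[, samples, drop = FALSE])
  ranks <- t$ranks
  ranks[ranks == ""] <- "unclassified"
  edges <- list()
  for (r in 1:6) {
    parent <- apply(ranks[, seq_len(r), drop = FALSE], 1L, paste,
                    collapse = ";")
    child <- apply(ranks[, seq_len(r + 1L), drop = FALSE], 1L, paste,
                   collapse = ";")
    agg <- rowsum(w, group = child)
    key <- rownames(agg)
    edges[[r]] <- data.frame(
      rank = .TAXO_RANKS[r + 1L],
      parent = parent[match(key, child)],
      child = key,
      weight = as.numeric(agg),
      stringsAsFactors = FALSE
    )
  }
  out <- do.call(rbind, edges)
  rownames(out) <- NULL
  out
}
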