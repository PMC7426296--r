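make_taxa <- function() {
  tax <- c("Bacteria;P1;C1;O1;Fam1;GenA;sp1",
           "Bacteria;P1;C1;O1;Fam1;GenA;sp2",
           "Bacteria;P1;C1;O1;Fam2;GenB;sp3")
  ab <- matrix(c(0.1, 0.2, 0.7,
                 0.2, 0.2, 0.6,
                 0.15, 0.25, 0.6), nrow = 3,
               dimnames = list(NULL, c("s1", "s2", "s3")))
  as_taxon_table(ab, tax)
}

test_that("taxonomy parsing strips Greengenes prefixes from files", {
  path <- withr::local_tempfile(fileext = ".tsv")
  writeLines(c("taxonomy\ts1\ts2",
               "k__Bacteria;p__Firmicutes;c__Clostridia\t3\t5",
               "k__Bacteria;p__Bacteroidetes\t7\t5"), path)
  tt <- read_taxon_table(path)
  expect_equal(tt$ranks[1, "phylum"], c(phylum = "Firmicutes"))
  expect_equal(tt$ranks[2, "class"], c(class = ""))
  rel <- as_relative(tt)
  expect_equal(unname(colSums(rel$abund)), c(1, 1))
})

test_that("rank aggregation sums abundances and conserves column totals", {
  tt <- make_taxa()
  gen <- aggregate_taxa(tt, "genus")
  expect_equal(nrow(gen$abund), 2L)  # two species of GenA merge
  i <- grep("GenA", gen$taxonomy)
  expect_equal(unname(gen$abund[i, "s1"]), 0.3)
  expect_equal(colSums(gen$abund), colSums(tt$abund))
  # aggregation at the table's own rank is the identity on abundances
  sp <- aggregate_taxa(tt, "species")
  expect_equal(sort(unname(rowSums(sp$abund))),
               sort(unname(rowSums(tt$abund))))
  expect_error(aggregate_taxa(tt, "kingdom"), "unknown rank")
})

test_that("group comparison computes percent change and one-sided p", {
  # two complementary taxa so normalization is a no-op
  x <- c(0.10, 0.12, 0.11); y <- c(0.15, 0.16, 0.17)
  ab <- rbind(c(x, y), 1 - c(x, y))
  colnames(ab) <- c(paste0("w", 1:3), paste0("k", 1:3))
  tt <- as_taxon_table(ab, c("Bacteria;P;C;O;F;G1;s", "Bacteria;P;C;O;F;G2;s"))
  groups <- setNames(rep(c("WT", "KO"), each = 3), colnames(ab))
  res <- compare_taxa_groups(tt, groups)
  i <- grep("G1", res$taxonomy)
  expect_lt(abs(res$percent_change[i] - 45.45), 0.1)
  expect_lt(res$p_one_sided[i], 0.01)
  expect_true(res$flagged[i])

  # identical groups: percent change 0, one-sided p = 0.5 at t = 0
  ab2 <- rbind(rep(c(0.4, 0.3, 0.5), 2), 1 - rep(c(0.4, 0.3, 0.5), 2))
  colnames(ab2) <- colnames(ab)
  tt2 <- as_taxon_table(ab2, tt$taxonomy)
  res2 <- compare_taxa_groups(tt2, groups)
  expect_equal(res2$percent_change, c(0, 0))
  expect_equal(res2$p_one_sided, c(0.5, 0.5))

  # antisymmetry: swapping labels flips the sign, keeps |t| and p
  sw <- compare_taxa_groups(tt, groups, ref = "KO", alt = "WT")
  j <- match(res$taxonomy, sw$taxonomy)
  expect_equal(sign(sw$percent_change[j]), -sign(res$percent_change))
  expect_equal(abs(sw$t_statistic[j]), abs(res$t_statistic))
  expect_equal(sw$p_one_sided[j], res$p_one_sided)

  # WT mean of zero flags the taxon with undefined percent change
  ab3 <- rbind(c(0, 0, 0, 0.1, 0.2, 0.1), c(1, 1, 1, 0.9, 0.8, 0.9))
  colnames(ab3) <- colnames(ab)
  res3 <- compare_taxa_groups(as_taxon_table(ab3, tt$taxonomy), groups)
  expect_true(any(is.na(res3$percent_change)))
})

test_that("aggregating before comparison equals comparing aggregated sums", {
  tt <- make_taxa()
  groups <- setNames(c("WT", "WT", "KO"), colnames(tt$abund))
  # degenerate group sizes are rejected
  expect_error(compare_taxa_groups(tt, groups), "at least 2")
  ab <- cbind(tt$abund, s4 = c(0.3, 0.3, 0.4))
  tt4 <- as_taxon_table(ab, tt$taxonomy)
  g4 <- setNames(rep(c("WT", "KO"), each = 2), colnames(ab))
  direct <- compare_taxa_groups(aggregate_taxa(tt4, "family"), g4)
  byhand <- as_taxon_table(rowsum(ab, group = c("f1", "f1", "f2")),
                           c("Bacteria;P1;C1;O1;Fam1",
                             "Bacteria;P1;C1;O1;Fam2"))
  manual <- compare_taxa_groups(byhand, g4)
  expect_equal(sort(direct$percent_change), sort(manual$percent_change))
  expect_equal(sort(direct$p_one_sided), sort(manual$p_one_sided))
})

test_that("sankey flows conserve mass from parent to children", {
  # single lineage: a chain of equal weights
  one <- as_taxon_table(matrix(c(1, 1), 1, dimnames = list(NULL, c("a", "b"))),
                        "Bacteria;P;C;O;F;G;s")
  e1 <- sankey_flows(one)
  expect_equal(e1$weight, rep(1, 6))

  tt <- make_taxa()
  edges <- sankey_flows(tt)
  # hand-constructed family level flow: Fam1 carries GenA's two species
  fam1 <- edges[edges$rank == "family" & grepl("Fam1", edges$child), ]
  expect_equal(fam1$weight, mean(colSums(tt$abund[1:2, ])))
  # conservation at every internal node
  for (p in unique(edges$parent)) {
    kids <- edges[edges$parent == p, ]
    up <- edges[edges$child == p, ]
    if (nrow(up)) expect_equal(sum(kids$weight), up$weight)
  }
  # missing tail ranks become explicit unclassified children
  part <- as_taxon_table(matrix(c(1, 1), 1,
                                dimnames = list(NULL, c("a", "b"))),
                         "Bacteria;P1;C1")
  expect_true(any(grepl("unclassified", sankey_flows(part)$child)))
})
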