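test_that("generation is byte-identical under a fixed seed", {
  cfg <- sim_config(seed = 5, n_compounds = 60, n_decoy_db_entries = 200,
                    n_peaks = 80, n_bio_replicates = 2,
                    n_tech_replicates = 2)
  a <- simulate_database(cfg); b <- simulate_database(cfg)
  expect_identical(a, b)
  d <- simulate_design(cfg)
  p1 <- simulate_peaks(cfg, a, d); p2 <- simulate_peaks(cfg, b, d)
  expect_identical(p1, p2)
  t1 <- simulate_taxa(cfg); t2 <- simulate_taxa(cfg)
  expect_identical(t1, t2)
  cfg2 <- sim_config(seed = 6, n_compounds = 60, n_decoy_db_entries = 200,
                     n_peaks = 80, n_bio_replicates = 2,
                     n_tech_replicates = 2)
  expect_false(identical(simulate_database(cfg2), a))
})

test_that("database carries the configured isomer collisions and validates", {
  cfg <- sim_config(seed = 3, n_compounds = 100, isomer_fraction = 0.1,
                    n_decoy_db_entries = 50)
  db <- simulate_database(cfg)
  real <- db$formula[!is.na(db$formula)]
  expect_equal(sum(table(real) >= 2), 10L)  # floor(100 * 0.1)
  cfg0 <- sim_config(seed = 3, n_compounds = 100, isomer_fraction = 0)
  expect_false(anyDuplicated(
    na.omit(simulate_database(cfg0)$formula)) > 0)
  # revalidates cleanly and masses agree with the formulas
  revalidated <- as_compound_db(as.data.frame(db)[, 1:6])
  i <- which(!is.na(db$formula))[1:10]
  expect_equal(db$neutral_mass[i],
               vapply(db$formula[i], monoisotopic_mass, numeric(1)),
               tolerance = 1e-9, ignore_attr = TRUE)
})

test_that("generated peak tables pass ingestion validation and filters", {
  cfg <- sim_config(seed = 2, n_compounds = 50, n_decoy_db_entries = 100,
                    n_peaks = 60, n_bio_replicates = 2, n_tech_replicates = 2)
  db <- simulate_database(cfg)
  design <- simulate_design(cfg)
  pk <- simulate_peaks(cfg, db, design)
  path <- withr::local_tempfile(fileext = ".tsv")
  write.table(pk$peaks, path, sep = "\t", quote = FALSE, row.names = FALSE)
  got <- read_peak_table(path, design)
  expect_equal(nrow(got), 60L)
  expect_equal(nrow(filter_peaks(got)), 60L)  # defaults keep everything
})

test_that("in the no-noise limit every peak matches its source compound", {
  cfg <- sim_config(seed = 4, n_compounds = 80, n_decoy_db_entries = 0,
                    n_peaks = 150, pi1_true = 1, true_error_sd = 1e-4,
                    n_bio_replicates = 2, n_tech_replicates = 1)
  db <- simulate_database(cfg)
  pk <- simulate_peaks(cfg, db, simulate_design(cfg))
  m <- match_candidates(pk$peaks, db, adducts = cfg$adduct_names)
  expect_true(all(m$best_formula == pk$truth$true_formula))
  expect_lt(max(abs(m$e_best)), 0.01)
})

test_that("antibiotics suppress bacterial-origin compounds by the set factor", {
  cfg <- sim_config(seed = 9, n_compounds = 150, n_decoy_db_entries = 0,
                    n_peaks = 600, bacterial_fraction = 0.3,
                    treatments = c("none", "abx"), organ = "plasma",
                    n_bio_replicates = 3, n_tech_replicates = 1,
                    group_effects = list())
  db <- simulate_database(cfg)
  design <- simulate_design(cfg)
  pk <- simulate_peaks(cfg, db, design)
  bact <- pk$truth$class_label == "bacterial origin"
  pre <- design$sample_id[design$treatment == "none"]
  post <- design$sample_id[design$treatment == "abx"]
  ratio <- rowMeans(as.matrix(pk$peaks[bact, pre])) /
    rowMeans(as.matrix(pk$peaks[bact, post]))
  expect_gt(median(ratio), 50)
  expect_lt(median(ratio), 200)  # nominal factor 100 within sampling error
})

test_that("an 11-fold spike is realized in the raw group means", {
  cfg <- sim_config(seed = 1, n_peaks = 800, n_decoy_db_entries = 0)
  db <- simulate_database(cfg)
  design <- simulate_design(cfg)
  pk <- simulate_peaks(cfg, db, design)
  col <- collapse_technical(pk$peaks, design)
  bd <- collapse_design(design)
  target <- pk$effects[[1]]$compound
  rows <- which(pk$truth$true_compound_id == target)
  expect_gt(length(rows), 0L)  # effect targets always emit a peak
  v <- colSums(as.matrix(col[rows, bd$sample_id, drop = FALSE]))
  fc <- mean(v[bd$genotype == "KO"]) / mean(v[bd$genotype == "WT"])
  expect_lt(abs(fc - 11) / 11, 0.2)
})

test_that("taxon compositions are simplex draws with the configured shifts", {
  cfg <- sim_config(seed = 8, taxa = list(n_taxa = 30, n_per_group = 25,
                                          base_concentration = 200,
                                          shifted_genera = c(Genus01 = 2)))
  tx <- simulate_taxa(cfg)
  expect_equal(unname(colSums(tx$table$abund)), rep(1, 50))
  cmp <- compare_taxa_groups(tx$table, tx$groups)
  i <- grep("Genus01;", cmp$taxonomy)
  expect_true(cmp$flagged[i])
  expect_gt(cmp$percent_change[i], 0)

  # no shifted genera: percent changes stay near zero
  cfg0 <- sim_config(seed = 8, taxa = list(n_taxa = 30, n_per_group = 25,
                                           base_concentration = 200,
                                           shifted_genera = numeric(0)))
  tx0 <- simulate_taxa(cfg0)
  cmp0 <- compare_taxa_groups(tx0$table, tx0$groups)
  expect_lt(abs(mean(cmp0$percent_change)), 15)
})
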