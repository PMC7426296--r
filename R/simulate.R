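# Seeded synthetic-data generator. Emulates the statistical structure of an
# untargeted LC-MS study: a formula-mass database with isomer collisions and
# mass-only decoy entries, peaks whose best-match errors mix a tight true
# component with a broad false component, log-normal abundances with
# multiplicative technical noise and group effects (including suppression of
# bacterial-origin compounds under antibiotics), and Dirichlet taxon tables
# with genus-level shifts.

#' Simulation configuration
#'
#' Defaults reproduce the emulated study design: six biological and three
#' technical replicates per genotype, a 2-ppm true mass-error component
#' carrying 60% of peaks against a +/-50 ppm false component, and a single
#' compound spiked 11-fold in the knockout group (a glutarate-like effect).
#' The decoy-entry default emulates the unique-formula scale of a merged
#' composite metabolite database over a 50-1700 Da span.
#'
#' @param seed Integer seed; each sub-generator derives its own stream.
#' @param n_compounds Real (formula-bearing) compounds in the database.
#' @param isomer_fraction Fraction of formulas hosting two compounds.
#' @param n_decoy_db_entries Mass-only decoy entries.
#' @param standard_fraction Fraction of real compounds with isotopic
#'   standards.
#' @param pi1_true Fraction of peaks generated from a database compound.
#' @param true_error_sd SD of the true mass-error component (ppm).
#' @param null_error_range Half-width of the false-error range (ppm).
#' @param n_peaks Number of peaks.
#' @param polarity Ionization mode of the generated table.
#' @param adduct_names Charge-carrier species used to ionize generated
#'   peaks (default protonation only, so identification errors reflect mass
#'   coincidence rather than charge-carrier ambiguity).
#' @param adduct_probs Sampling weights over `adduct_names`.
#' @param organ Organ tag ("kidney" or "plasma").
#' @param treatments Treatment arms in the design (e.g. `c("none", "abx")`).
#' @param n_bio_replicates,n_tech_replicates Replication per
#'   genotype/treatment cell.
#' @param bio_cv,tech_cv Biological and technical coefficients of variation
#'   (multiplicative, log-normal).
#' @param base_log_mean,base_log_sd Log-scale location and compound-to-
#'   compound spread of mean peak areas.
#' @param group_effects List of effects, each
#'   `list(compound = id or "auto", column, level, fold)`: samples with
#'   `design[[column]] == level` have the compound multiplied by `fold`.
#' @param bacterial_fraction Fraction of compounds of bacterial origin.
#' @param abx_suppression_factor Division factor applied to bacterial-origin
#'   compounds in antibiotic-treated samples.
#' @param taxa List: `n_taxa`, `n_per_group`, `base_concentration`
#'   (Dirichlet precision), `shifted_genera` (named numeric vector of
#'   concentration fold effects in the KO group).
#' @return A validated list of class `sim_config`.
#' @export
sim_config <- function(seed = 1L,
                       n_compounds = 400L,
                       isomer_fraction = 0.10,
                       n_decoy_db_entries = 10000L,
                       standard_fraction = 0.05,
                       pi1_true = 0.6,
                       true_error_sd = 2,
                       null_error_range = 50,
                       n_peaks = 2000L,
                       polarity = "positive",
                       adduct_names = "[M+H]+",
                       adduct_probs = NULL,
                       organ = "kidney",
                       treatments = "none",
                       n_bio_replicates = 6L,
                       n_tech_replicates = 3L,
                       bio_cv = 0.2,
                       tech_cv = 0.1,
                       base_log_mean = log(5e4),
                       base_log_sd = 1.2,
                       group_effects = list(list(compound = "auto",
                                                 column = "genotype",
                                                 level = "KO", fold = 11)),
                       bacterial_fraction = 0.10,
                       abx_suppression_factor = 100,
                       taxa = list(n_taxa = 40L, n_per_group = 7L,
                                   base_concentration = 100,
                                   shifted_genera = c(Genus01 = 2,
                                                      Genus02 = 2,
                                                      Genus03 = 0.5))) {
  cfg <- as.list(environment())
  fr <- c(isomer_fraction = isomer_fraction, pi1_true = pi1_true,
          standard_fraction = standard_fraction,
          bacterial_fraction = bacterial_fraction)
  if (any(fr < 0 | fr > 1)) stop("fractions must lie in [0, 1]")
  if (true_error_sd <= 0 || null_error_range <= 0) {
    stop("error scales must be positive")
  }
  if (bio_cv < 0 || tech_cv < 0) stop("coefficients of variation must be >= 0")
  if (is.null(cfg$adduct_probs)) {
    cfg$adduct_probs <- rep(1 / length(adduct_names), length(adduct_names))
  }
  cfg$seed <- as.integer(seed)
  class(cfg) <- "sim_config"
  cfg
}

.cv_to_sdlog <- function(cv) sqrt(log(1 + cv^2))

# one lognormal multiplicative-noise draw per matrix cell
.lnoise <- function(n, cv) {
  if (cv <= 0) return(rep(1, n))
  s <- .cv_to_sdlog(cv)
  stats::rlnorm(n, meanlog = -s^2 / 2, sdlog = s)
}

#' Simulate a sample design
#'
#' Full factorial genotype (WT/KO) x treatment x biological x technical
#' replicates.
#'
#' @param cfg A `sim_config`.
#' @return A sample design data frame (see [as_sample_design()]).
#' @export
simulate_design <- function(cfg) {
  g <- expand.grid(technical_replicate = seq_len(cfg$n_tech_replicates),
                   biological_replicate = seq_len(cfg$n_bio_replicates),
                   treatment = cfg$treatments,
                   genotype = c("WT", "KO"),
                   stringsAsFactors = FALSE)
  d <- data.frame(
    sample_id = sprintf("%s_%s_b%d_t%d", g$genotype, g$treatment,
                        g$biological_replicate, g$technical_replicate),
    genotype = g$genotype, treatment = g$treatment,
    biological_replicate = g$biological_replicate,
    technical_replicate = g$technical_replicate,
    organ = cfg$organ,
    stringsAsFactors = FALSE
  )
  as_sample_design(d)
}

# vectorized formula mass from element count columns
.mass_from_counts <- function(cnt) {
  ms <- .isotope_masses
  with(cnt, C * ms[["C"]] + H * ms[["H"]] + N * ms[["N"]] + O * ms[["O"]] +
         S * ms[["S"]] + P * ms[["P"]])
}

#' Simulate a compound database
#'
#' Plausible CHNOPS formulas with computed monoisotopic masses, a configured
#' fraction of isomer collisions (formulas hosting two compound records),
#' class labels, isotopic-standard flags, and mass-only decoy entries at
#' uniform random masses.
#'
#' @param cfg A `sim_config`.
#' @return A `compound_db` data frame.
#' @export
simulate_database <- function(cfg) {
  set.seed(cfg$seed)
  n <- cfg$n_compounds
  formulas <- character(0)
  masses <- numeric(0)
  while (length(formulas) < n) {
    k <- max(2L * n, 200L)
    cnt <- data.frame(
      C = sample(3:40, k, replace = TRUE),
      H = NA_integer_, N = sample(0:4, k, replace = TRUE),
      O = sample(0:12, k, replace = TRUE),
      S = sample(0:2, k, replace = TRUE, prob = c(0.85, 0.12, 0.03)),
      P = sample(0:1, k, replace = TRUE, prob = c(0.95, 0.05))
    )
    cnt$H <- cnt$C + floor(stats::runif(k, 0, cnt$C + 3))
    mass <- .mass_from_counts(cnt)
    f <- sprintf("C%dH%d%s%s%s%s", cnt$C, cnt$H,
                 ifelse(cnt$N > 0, paste0("N", ifelse(cnt$N > 1, cnt$N, "")), ""),
                 ifelse(cnt$O > 0, paste0("O", ifelse(cnt$O > 1, cnt$O, "")), ""),
                 ifelse(cnt$P > 0, "P", ""),
                 ifelse(cnt$S > 0, paste0("S", ifelse(cnt$S > 1, cnt$S, "")), ""))
    keep <- mass >= 60 & mass <= 1600 & !duplicated(f) & !(f %in% formulas)
    formulas <- c(formulas, f[keep])
    masses <- c(masses, mass[keep])
  }
  formulas <- formulas[seq_len(n)]
  masses <- masses[seq_len(n)]

  classes <- sample(
    c("bacterial origin", "tryptophan metabolism", "acylcarnitines",
      "lipids", "glycine conjugates", "others"),
    n, replace = TRUE,
    prob = c(cfg$bacterial_fraction,
             (1 - cfg$bacterial_fraction) * c(0.10, 0.15, 0.20, 0.05, 0.50))
  )
  db <- data.frame(
    compound_id = sprintf("C%04d", seq_len(n)),
    name = sprintf("compound_%04d", seq_len(n)),
    formula = formulas,
    neutral_mass = masses,
    class_label = classes,
    is_standard = stats::runif(n) < cfg$standard_fraction,
    stringsAsFactors = FALSE
  )
  n_iso <- floor(n * cfg$isomer_fraction)
  if (n_iso > 0) {
    pick <- sample.int(n, n_iso)
    iso <- db[pick, , drop = FALSE]
    iso$compound_id <- sprintf("I%04d", seq_len(n_iso))
    iso$name <- paste0(iso$name, "_isomer")
    iso$is_standard <- FALSE
    db <- rbind(db, iso)
  }
  nd <- cfg$n_decoy_db_entries
  if (nd > 0) {
    decoys <- data.frame(
      compound_id = sprintf("D%05d", seq_len(nd)),
      name = sprintf("decoy_%05d", seq_len(nd)),
      formula = NA_character_,
      neutral_mass = stats::runif(nd, 50, 1700),
      class_label = "decoy",
      is_standard = FALSE,
      stringsAsFactors = FALSE
    )
    db <- rbind(db, decoys)
  }
  rownames(db) <- NULL
  as_compound_db(db)
}

# resolve "auto" effect targets to concrete compound ids
.resolve_effects <- function(effects, db) {
  real <- db[!is.na(db$formula) & !db$is_standard &
               db$class_label == "others", , drop = FALSE]
  single <- !(real$formula %in% db$formula[duplicated(db$formula) &
                                             !is.na(db$formula)])
  pool <- real$compound_id[single]
  k <- 0L
  lapply(effects, function(e) {
    if (identical(e$compound, "auto")) {
      k <<- k + 1L
      if (k > length(pool)) stop("not enough eligible compounds for effects")
      e$compound <- pool[k]
    }
    if (!e$compound %in% db$compound_id) {
      stop(sprintf("effect target '%s' not in database", e$compound))
    }
    e
  })
}

#' Simulate a peak table with ground truth
#'
#' A fraction `pi1_true` of peaks ionizes a real database compound with a
#' `N(0, true_error_sd)` ppm mass error; the remainder are spurious features
#' at masses uniform between the database entries, so their best matches
#' populate the false component of the error mixture. Per-sample areas are
#' log-normal around a compound baseline
#' with configured group effects, antibiotic suppression of bacterial-origin
#' compounds, biological variation, and multiplicative technical noise.
#'
#' @param cfg A `sim_config`.
#' @param db Database from [simulate_database()].
#' @param design Design from [simulate_design()].
#' @return A list: `peaks` (peak table with per-sample areas), `truth`
#'   (`peak_id`, `true_compound_id`, `true_formula`, `class_label`) and
#'   `effects` (resolved effect list).
#' @export
simulate_peaks <- function(cfg, db, design) {
  set.seed(cfg$seed + 1L)
  if (!all(design$organ == cfg$organ)) stop("design organ mismatch")
  effects <- .resolve_effects(cfg$group_effects, db)

  n <- cfg$n_peaks
  n_true <- round(n * cfg$pi1_true)
  real_rows <- which(!is.na(db$formula))
  src <- rep(NA_integer_, n)
  if (n_true > 0) {
    src[seq_len(n_true)] <- sample(real_rows, n_true, replace = TRUE)
    # every effect target contributes at least one true peak
    for (i in seq_along(effects)) {
      row <- match(effects[[i]]$compound, db$compound_id)
      if (!row %in% src[seq_len(n_true)]) src[i] <- row
    }
  }
  adt <- adduct_table(include_chloride = TRUE)
  adt <- adt[match(cfg$adduct_names, adt$name), , drop = FALSE]
  a_idx <- sample.int(nrow(adt), n, replace = TRUE, prob = cfg$adduct_probs)

  neutral <- numeric(n)
  is_true <- !is.na(src)
  neutral[is_true] <- db$neutral_mass[src[is_true]] *
    (1 + stats::rnorm(sum(is_true), 0, cfg$true_error_sd) * 1e-6)
  n_false <- sum(!is_true)
  if (n_false > 0) {
    # spurious features: masses uniform between database entries, so their
    # best matches populate a broad null
    neutral[!is_true] <- stats::runif(n_false, min(db$neutral_mass),
                                      max(db$neutral_mass))
  }
  mz <- neutral / adt$charge[a_idx] + adt$mass_shift[a_idx]

  base <- stats::rlnorm(n, cfg$base_log_mean, cfg$base_log_sd)
  ns <- nrow(design)
  mu <- matrix(base, nrow = n, ncol = ns)
  for (e in effects) {
    prow <- which(is_true & db$compound_id[src] == e$compound)
    scol <- which(design[[e$column]] == e$level)
    if (length(prow) && length(scol)) mu[prow, scol] <- mu[prow, scol] * e$fold
  }
  bact <- which(is_true & db$class_label[src] == "bacterial origin")
  abx <- which(design$treatment == "abx")
  if (length(bact) && length(abx)) {
    mu[bact, abx] <- mu[bact, abx] / cfg$abx_suppression_factor
  }
  # biological variation shared across technical replicates of a bio sample
  bio_ids <- unique(design$bio_id)
  bio_noise <- matrix(.lnoise(n * length(bio_ids), cfg$bio_cv),
                      nrow = n, dimnames = list(NULL, bio_ids))
  areas <- mu * bio_noise[, design$bio_id, drop = FALSE] *
    matrix(.lnoise(n * ns, cfg$tech_cv), nrow = n)
  colnames(areas) <- design$sample_id

  peaks <- data.frame(
    peak_id = sprintf("P%05d", seq_len(n)),
    mz = mz,
    rt = stats::runif(n, 2.05, 12.95),
    polarity = cfg$polarity,
    height = pmax(1001, round(base * stats::runif(n, 0.3, 1.5))),
    stringsAsFactors = FALSE
  )
  peaks <- cbind(peaks, as.data.frame(areas, check.names = FALSE))
  truth <- data.frame(
    peak_id = peaks$peak_id,
    true_compound_id = ifelse(is_true, db$compound_id[src], ""),
    true_formula = ifelse(is_true, db$formula[src], ""),
    class_label = ifelse(is_true, db$class_label[src], ""),
    stringsAsFactors = FALSE
  )
  list(peaks = peaks, truth = truth, effects = effects)
}

#' Simulate a 16S taxon table
#'
#' Per-sample compositions are Dirichlet draws around a shared base
#' composition; genera listed in `cfg$taxa$shifted_genera` have their
#' Dirichlet concentration multiplied by the effect size in the KO group.
#' Taxonomy paths are synthesized over the seven standard ranks.
#'
#' @param cfg A `sim_config`.
#' @return A list: `table` (a `taxon_table`), `groups` (named vector mapping
#'   samples to WT/KO), `truth` (the shifted genera and effects).
#' @export
simulate_taxa <- function(cfg) {
  set.seed(cfg$seed + 2L)
  tx <- cfg$taxa
  n <- tx$n_taxa
  genus <- sprintf("Genus%02d", seq_len(n))
  fam <- sprintf("Family%02d", (seq_len(n) - 1L) %/% 3L + 1L)
  ord <- sprintf("Order%02d", (seq_len(n) - 1L) %/% 6L + 1L)
  cls <- sprintf("Class%02d", (seq_len(n) - 1L) %/% 12L + 1L)
  phy <- sprintf("Phylum%02d", (seq_len(n) - 1L) %/% 20L + 1L)
  taxonomy <- paste("Bacteria", phy, cls, ord, fam, genus,
                    paste0(tolower(genus), "_sp"), sep = ";")

  base <- sort(stats::rgamma(n, shape = 1), decreasing = TRUE)
  base <- base / sum(base)
  alpha_wt <- tx$base_concentration * base
  alpha_ko <- alpha_wt
  shift <- tx$shifted_genera
  j <- match(names(shift), genus)
  if (any(is.na(j))) stop("shifted genus not among simulated genera")
  alpha_ko[j] <- alpha_ko[j] * shift

  m <- tx$n_per_group
  rdirichlet <- function(k, alpha) {
    g <- matrix(stats::rgamma(k * length(alpha), shape = alpha),
                nrow = length(alpha))
    sweep(g, 2L, colSums(g), "/")
  }
  A <- cbind(rdirichlet(m, alpha_wt), rdirichlet(m, alpha_ko))
  colnames(A) <- c(sprintf("WT_s%d", seq_len(m)), sprintf("KO_s%d", seq_len(m)))
  groups <- stats::setNames(rep(c("WT", "KO"), each = m), colnames(A))
  list(table = as_taxon_table(A, taxonomy),
       groups = groups,
       truth = list(shifted_genera = shift))
}

#' Write a complete synthetic dataset to disk
#'
#' Emits the same delimited formats the pipeline reads: `database.tsv`,
#' `design.tsv`, `peaks.tsv`, `taxa.tsv`, `taxa_groups.tsv` and
#' `ground_truth.tsv`.
#'
#' @param cfg A `sim_config`.
#' @param dir Output directory (created if missing).
#' @return Invisibly, a named list of file paths.
#' @export
simulate_dataset <- function(cfg, dir) {
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  db <- simulate_database(cfg)
  design <- simulate_design(cfg)
  pk <- simulate_peaks(cfg, db, design)
  tx <- simulate_taxa(cfg)
  paths <- list(
    db = file.path(dir, "database.tsv"),
    design = file.path(dir, "design.tsv"),
    peaks = file.path(dir, "peaks.tsv"),
    taxa = file.path(dir, "taxa.tsv"),
    taxa_groups = file.path(dir, "taxa_groups.tsv"),
    truth = file.path(dir, "ground_truth.tsv")
  )
  dbout <- db
  dbout$formula_key <- NULL
  .write_tsv(dbout, paths$db)
  .write_tsv(design[, setdiff(names(design), "bio_id")], paths$design)
  .write_tsv(pk$peaks, paths$peaks)
  taxdf <- cbind(data.frame(taxonomy = tx$table$taxonomy,
                            stringsAsFactors = FALSE),
                 as.data.frame(tx$table$abund, check.names = FALSE))
  .write_tsv(taxdf, paths$taxa)
  .write_tsv(data.frame(sample_id = names(tx$groups),
                        genotype = unname(tx$groups)), paths$taxa_groups)
  .write_tsv(pk$truth, paths$truth)
  invisible(paths)
}
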