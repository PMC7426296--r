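# Stage orchestration behind the command-line interface: a single YAML
# config drives the simulate / annotate / diff / taxa subcommands, every run
# writes a manifest (config hash, seed, versions) for bit-exact reruns.

#' Default pipeline configuration
#'
#' Thresholds and filters default to the emulated study's analysis settings:
#' posterior 0.8, q-value 0.15 (kidney) or 0.05 (plasma), fold change 1.2,
#' taxa one-sided p 0.1, retention time 2-13 min, height 1000 counts,
#' H+/Na+/K+ adducts at charge up to 2, 50 ppm capture window.
#'
#' @param ... Named overrides merged (recursively) over the defaults.
#' @return A config list of class `pipeline_config`.
#' @export
pipeline_config <- function(...) {
  cfg <- list(
    paths = list(db = NULL, peaks = NULL, design = NULL, taxa = NULL,
                 taxa_groups = NULL, outdir = "."),
    thresholds = list(posterior = 0.8,
                      q = list(kidney = 0.15, plasma = 0.05),
                      fc = 1.2, taxa_p = 0.1),
    filters = list(rt_min = 2, rt_max = 13, min_height = 1000),
    adducts = c("[M+H]+", "[M+2H]2+", "[M+Na]+", "[M+K]+"),
    capture_window_ppm = 50,
    stats = list(t_variant = "equal_variance", lambda = 0.5,
                 fudge_percentile = 0.10, min_matches = 50),
    contrasts = list(list(name = "KO_vs_WT", column = "genotype",
                          numerator = "KO", denominator = "WT")),
    taxa_rank = "genus",
    simulate = list(),
    seed = 1L
  )
  cfg <- utils::modifyList(cfg, list(...))
  .validate_pipeline_config(cfg)
}

.validate_pipeline_config <- function(cfg) {
  known <- c("paths", "thresholds", "filters", "adducts",
             "capture_window_ppm", "stats", "contrasts", "taxa_rank",
             "simulate", "seed")
  bad <- setdiff(names(cfg), known)
  if (length(bad)) {
    stop(sprintf("unknown config key(s): %s", paste(bad, collapse = ", ")))
  }
  p <- cfg$thresholds$posterior
  if (!is.numeric(p) || p <= 0 || p > 1) {
    stop("thresholds$posterior must lie in (0, 1]")
  }
  if (any(unlist(cfg$thresholds$q) <= 0)) stop("q thresholds must be positive")
  class(cfg) <- "pipeline_config"
  cfg
}

#' Read a pipeline configuration from YAML
#'
#' Keys present in the file override the defaults of [pipeline_config()];
#' unknown keys are an error.
#'
#' @param path YAML file.
#' @param seed Optional seed override.
#' @return A `pipeline_config`.
#' @export
read_pipeline_config <- function(path, seed = NULL) {
  user <- yaml::read_yaml(path)
  cfg <- utils::modifyList(unclass(pipeline_config()), user)
  if (!is.null(seed)) cfg$seed <- as.integer(seed)
  .validate_pipeline_config(cfg)
}

#' Write a run manifest
#'
#' Records the configuration, seed, package and R versions and md5 checksums
#' of the written outputs, enabling bit-exact reruns of deterministic stages.
#'
#' @param outdir Output directory.
#' @param config The `pipeline_config` used.
#' @param stage Stage name.
#' @param files Character vector of output paths.
#' @return Invisibly, the manifest path.
#' @export
write_manifest <- function(outdir, config, stage, files) {
  manifest <- list(
    stage = stage,
    seed = config$seed,
    r_version = as.character(getRversion()),
    package_version = as.character(utils::packageVersion("metabomix")),
    config = unclass(config),
    outputs = as.list(tools::md5sum(files))
  )
  path <- file.path(outdir, sprintf("manifest_%s.yaml", stage))
  yaml::write_yaml(manifest, path)
  invisible(path)
}

.outdir <- function(config) {
  d <- config$paths$outdir
  if (is.null(d)) d <- "."
  if (!dir.exists(d)) dir.create(d, recursive = TRUE)
  d
}

#' Run the simulate stage
#'
#' Generates a synthetic dataset under `paths$outdir` using the `simulate`
#' section of the config (overrides of [sim_config()] arguments) and the
#' pipeline seed.
#'
#' @param config A `pipeline_config` or path to a YAML config.
#' @return Invisibly, the written file paths.
#' @export
run_simulate <- function(config) {
  if (is.character(config)) config <- read_pipeline_config(config)
  out <- .outdir(config)
  scfg <- do.call(sim_config, c(list(seed = config$seed), config$simulate))
  paths <- simulate_dataset(scfg, out)
  write_manifest(out, config, "simulate", unlist(paths))
  invisible(paths)
}

#' Run the annotation stage
#'
#' Reads the database, design and peak table, applies retention-time/height
#' filtering, fits the mass-error mixture per ionization mode and writes
#' `identifications.tsv` plus a `mixture_report.tsv` of fitted parameters.
#'
#' @param config A `pipeline_config` or path to a YAML config.
#' @return Invisibly, the annotation result of [annotate_peaks()].
#' @export
run_annotate <- function(config) {
  if (is.character(config)) config <- read_pipeline_config(config)
  out <- .outdir(config)
  db <- read_compound_db(config$paths$db)
  design <- read_sample_design(config$paths$design)
  peaks <- read_peak_table(config$paths$peaks, design)
  peaks <- filter_peaks(peaks, config$filters$rt_min, config$filters$rt_max,
                        config$filters$min_height)
  if (nrow(peaks) == 0L) {
    warning("no peaks left after filtering; writing empty identifications")
    ident_path <- file.path(out, "identifications.tsv")
    .write_tsv(data.frame(peak_id = character(0)), ident_path)
    return(invisible(NULL))
  }
  organ <- unique(design$organ)[1]
  ann <- annotate_peaks(peaks, db, adducts = config$adducts,
                        capture_window_ppm = config$capture_window_ppm,
                        threshold = config$thresholds$posterior,
                        min_n = config$stats$min_matches, organ = organ)
  ident_path <- file.path(out, "identifications.tsv")
  .write_tsv(ann$identifications, ident_path)
  rep <- do.call(rbind, lapply(ann$models, function(m) {
    data.frame(stratum = m$fitted_on, pi1 = m$pi1, mu1 = m$mu1,
               sigma1 = m$sigma1, kde_bandwidth = m$bw, n_peaks = m$n_best,
               n_iterations = m$n_iter, converged = m$converged)
  }))
  rep_path <- file.path(out, "mixture_report.tsv")
  .write_tsv(rep, rep_path)
  write_manifest(out, config, "annotate", c(ident_path, rep_path))
  invisible(ann)
}

#' Run the differential-abundance stage
#'
#' Collapses technical replicates, aggregates identified peaks per compound,
#' log2-transforms with the percentile fudge factor, and runs each
#' configured contrast: equal-variance t tests, Storey q-values and the
#' q / fold-change significance rule (q threshold chosen by organ). Writes
#' one `differential_<contrast>.tsv`, `volcano_<contrast>.tsv` and
#' `class_summary_<contrast>.tsv` per contrast.
#'
#' @param config A `pipeline_config` or path to a YAML config.
#' @return Invisibly, a list of filtered result tables per contrast.
#' @export
run_diff <- function(config) {
  if (is.character(config)) config <- read_pipeline_config(config)
  out <- .outdir(config)
  db <- read_compound_db(config$paths$db)
  design <- read_sample_design(config$paths$design)
  peaks <- read_peak_table(config$paths$peaks, design)
  peaks <- filter_peaks(peaks, config$filters$rt_min, config$filters$rt_max,
                        config$filters$min_height)
  ident_path <- file.path(out, "identifications.tsv")
  if (!file.exists(ident_path)) {
    stop("no identifications found; run the annotate stage first")
  }
  idents <- .read_delim_auto(ident_path)
  if (is.null(idents) || nrow(idents) == 0L) {
    stop("identifications table is empty; run the annotate stage first")
  }
  collapsed <- collapse_technical(peaks, design)
  bio_design <- collapse_design(design)
  cm <- aggregate_by_compound(idents, collapsed, db = db,
                              sample_cols = bio_design$sample_id)
  tr <- log_transform(cm, percentile = config$stats$fudge_percentile)
  organ <- unique(design$organ)[1]
  qthr <- config$thresholds$q[[organ]]
  if (is.null(qthr)) qthr <- config$thresholds$q[[1]]
  results <- list()
  files <- character(0)
  for (ct in config$contrasts) {
    groups <- stats::setNames(bio_design[[ct$column]], bio_design$sample_id)
    res <- differential_test(tr$log2, cm$areas, groups,
                             numerator = ct$numerator,
                             denominator = ct$denominator,
                             compounds = cm$compounds,
                             variant = config$stats$t_variant)
    ok <- !res$degenerate
    res$q_value <- NA_real_
    res$q_value[ok] <- storey_qvalues(res$p_value[ok],
                                      lambda = config$stats$lambda)
    res <- significance_filter(res, q_threshold = qthr,
                               fc_threshold = config$thresholds$fc)
    f1 <- file.path(out, sprintf("differential_%s.tsv", ct$name))
    f2 <- file.path(out, sprintf("volcano_%s.tsv", ct$name))
    f3 <- file.path(out, sprintf("class_summary_%s.tsv", ct$name))
    .write_tsv(res, f1)
    .write_tsv(volcano_table(res), f2)
    .write_tsv(class_summary(res), f3)
    files <- c(files, f1, f2, f3)
    results[[ct$name]] <- res
  }
  write_manifest(out, config, "diff", files)
  invisible(results)
}

#' Run the 16S taxa-comparison stage
#'
#' Aggregates the taxon table at the configured rank, compares groups with
#' one-sided equal-variance t tests ranked by percent change, and writes the
#' ranked table plus per-group Sankey edge lists.
#'
#' @param config A `pipeline_config` or path to a YAML config.
#' @return Invisibly, the ranked comparison table.
#' @export
run_taxa <- function(config) {
  if (is.character(config)) config <- read_pipeline_config(config)
  out <- .outdir(config)
  if (is.null(config$paths$taxa)) stop("no taxa input configured")
  tt <- read_taxon_table(config$paths$taxa)
  g <- .read_delim_auto(config$paths$taxa_groups)
  if (is.null(g)) stop("no taxa_groups input configured")
  groups <- stats::setNames(g$genotype, g$sample_id)
  agg <- aggregate_taxa(tt, config$taxa_rank)
  cmp <- compare_taxa_groups(agg, groups, ref = "WT", alt = "KO",
                             p_threshold = config$thresholds$taxa_p)
  f1 <- file.path(out, "taxa_comparison.tsv")
  .write_tsv(cmp, f1)
  files <- f1
  for (grp in unique(unname(groups))) {
    edges <- sankey_flows(tt, samples = names(groups)[groups == grp])
    f <- file.path(out, sprintf("sankey_%s.tsv", grp))
    .write_tsv(edges, f)
    files <- c(files, f)
  }
  write_manifest(out, config, "taxa", files)
  invisible(cmp)
}
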