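# Delimited-text ingestion of compound databases, sample designs and peak
# tables, plus the two extraction-level reductions: retention-time/height
# filtering and geometric-mean collapsing of technical replicates.

.read_delim_auto <- function(path) {
  if (!file.exists(path)) stop(sprintf("file not found: %s", path))
  first <- readLines(path, n = 1L)
  if (length(first) == 0L) return(NULL)
  sep <- if (grepl("\t", first)) "\t" else ","
  utils::read.table(path, header = TRUE, sep = sep, quote = "\"",
                    stringsAsFactors = FALSE, check.names = FALSE,
                    comment.char = "")
}

.write_tsv <- function(df, path) {
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
}

#' Validate a compound database
#'
#' Checks and normalizes a data frame of reference compounds. `neutral_mass`
#' is computed from `formula` where absent; entries without a formula (e.g.
#' mass-only decoy records) must supply a mass and are treated as their own
#' match identity. A `formula_key` column is added: the identity under which
#' the matcher groups isomers ("up to unique formula").
#'
#' @param db Data frame with columns `compound_id`, `name`, `formula`, and
#'   optionally `neutral_mass`, `class_label`, `is_standard`.
#' @return The validated data frame (class `compound_db`).
#' @export
as_compound_db <- function(db) {
  req <- c("compound_id", "name", "formula")
  miss <- setdiff(req, names(db))
  if (length(miss)) {
    stop(sprintf("compound database missing column(s): %s",
                 paste(miss, collapse = ", ")))
  }
  if (nrow(db) == 0L) stop("empty compound database")
  if (anyDuplicated(db$compound_id)) stop("duplicate compound_id in database")
  db$formula <- as.character(db$formula)
  has_f <- !is.na(db$formula) & nzchar(db$formula)
  if (is.null(db$neutral_mass)) db$neutral_mass <- NA_real_
  need <- has_f & is.na(db$neutral_mass)
  if (any(need)) {
    db$neutral_mass[need] <- vapply(db$formula[need], monoisotopic_mass,
                                    numeric(1))
  }
  if (any(is.na(db$neutral_mass))) {
    stop("database entries without formula must provide neutral_mass")
  }
  if (any(db$neutral_mass <= 0)) stop("non-positive neutral_mass in database")
  if (is.null(db$class_label)) db$class_label <- "others"
  db$class_label[is.na(db$class_label) | !nzchar(db$class_label)] <- "others"
  if (is.null(db$is_standard)) db$is_standard <- FALSE
  db$is_standard <- as.logical(db$is_standard)
  db$is_standard[is.na(db$is_standard)] <- FALSE
  db$formula_key <- ifelse(has_f, db$formula,
                           paste0("m:", db$compound_id))
  class(db) <- c("compound_db", class(db))
  db
}

#' Read a compound database from delimited text
#'
#' @param path TSV/CSV file with the columns described in [as_compound_db()].
#' @return A validated `compound_db` data frame.
#' @export
read_compound_db <- function(path) {
  db <- .read_delim_auto(path)
  if (is.null(db)) stop(sprintf("empty database file: %s", path))
  as_compound_db(db)
}

#' Read a sample design table
#'
#' @param path Delimited file with columns `sample_id`, `genotype`,
#'   `treatment`, `biological_replicate`, `technical_replicate`, `organ`.
#' @return The validated design data frame. A `bio_id` column identifying
#'   each biological sample (genotype x treatment x biological replicate) is
#'   added.
#' @export
read_sample_design <- function(path) {
  d <- .read_delim_auto(path)
  if (is.null(d)) stop(sprintf("empty design file: %s", path))
  as_sample_design(d)
}

#' @rdname read_sample_design
#' @param design A data frame with the design columns.
#' @export
as_sample_design <- function(design) {
  req <- c("sample_id", "genotype", "treatment", "biological_replicate",
           "technical_replicate", "organ")
  miss <- setdiff(req, names(design))
  if (length(miss)) {
    stop(sprintf("sample design missing column(s): %s",
                 paste(miss, collapse = ", ")))
  }
  if (anyDuplicated(design$sample_id)) stop("duplicate sample_id in design")
  design$bio_id <- paste(design$genotype, design$treatment,
                         design$biological_replicate, sep = ".")
  design
}

#' Read and validate a peak table
#'
#' The file must contain `peak_id`, `mz`, `rt`, `polarity`, `height` plus one
#' area column per `sample_id` of the design.
#'
#' @param path Delimited text file.
#' @param design Sample design (see [read_sample_design()]).
#' @param mz_range Allowed scan range for m/z (instrument default 50-1700).
#' @return A data frame of peaks with per-sample areas.
#' @export
read_peak_table <- function(path, design, mz_range = c(50, 1700)) {
  pk <- .read_delim_auto(path)
  if (is.null(pk) || nrow(pk) == 0L) {
    warning(sprintf("peak table '%s' is empty", path))
    cols <- c("peak_id", "mz", "rt", "polarity", "height", design$sample_id)
    pk <- as.data.frame(stats::setNames(
      rep(list(character(0)), length(cols)), cols))
    return(pk)
  }
  validate_peak_table(pk, design, mz_range = mz_range)
}

#' @rdname read_peak_table
#' @param peaks A peak-table data frame.
#' @export
validate_peak_table <- function(peaks, design, mz_range = c(50, 1700)) {
  meta <- c("peak_id", "mz", "rt", "polarity", "height")
  miss <- setdiff(meta, names(peaks))
  if (length(miss)) {
    stop(sprintf("peak table missing column(s): %s",
                 paste(miss, collapse = ", ")))
  }
  missing_samples <- setdiff(design$sample_id, names(peaks))
  if (length(missing_samples)) {
    stop(sprintf("peak table is missing sample column(s): %s",
                 paste(missing_samples, collapse = ", ")))
  }
  if (anyDuplicated(peaks$peak_id)) stop("duplicate peak_id in peak table")
  areas <- as.matrix(peaks[, design$sample_id, drop = FALSE])
  if (!is.numeric(areas)) stop("non-numeric peak areas")
  if (any(is.na(areas))) stop("missing peak areas (encode absent peaks as 0)")
  if (any(areas < 0)) stop("negative peak area")
  if (any(peaks$mz < mz_range[1] | peaks$mz > mz_range[2])) {
    stop(sprintf("m/z outside scan range %g-%g", mz_range[1], mz_range[2]))
  }
  peaks
}

#' Filter peaks on retention time and height
#'
#' Keeps peaks with `rt_min <= rt <= rt_max` and `height > min_height`
#' (strict inequality). Defaults reproduce a 2-13 min window with a
#' 1000-count absolute height floor.
#'
#' @param peaks Peak table.
#' @param rt_min,rt_max Retention-time window in minutes.
#' @param min_height Minimum absolute height in counts (exclusive).
#' @return The filtered peak table (a row subset of the input).
#' @export
filter_peaks <- function(peaks, rt_min = 2, rt_max = 13, min_height = 1000) {
  keep <- peaks$rt >= rt_min & peaks$rt <= rt_max & peaks$height > min_height
  peaks[keep, , drop = FALSE]
}

#' Geometric mean with zero handling
#'
#' Geometric mean over the positive values only; zeros are dropped (a zero
#' would otherwise erase real signal from the remaining injections). Returns
#' 0 when all values are zero.
#'
#' @param x Non-negative numeric vector.
#' @return Scalar geometric mean.
#' @export
geometric_mean <- function(x) {
  if (any(x < 0)) stop("negative values in geometric mean")
  pos <- x[x > 0]
  if (length(pos) == 0L) return(0)
  exp(mean(log(pos)))
}

#' Collapse technical replicates by geometric mean
#'
#' Replaces the per-injection area columns with one column per biological
#' sample, each the geometric mean of its technical replicates (zeros
#' dropped, see [geometric_mean()]). The number of zero areas dropped is
#' recorded in the `"n_zero_dropped"` attribute.
#'
#' @param peaks Peak table with one column per `design$sample_id`.
#' @param design Sample design with technical replicates annotated.
#' @return Peak table with area columns named by `bio_id`.
#' @export
collapse_technical <- function(peaks, design) {
  design <- if (is.null(design$bio_id)) as_sample_design(design) else design
  bio <- unique(design$bio_id)
  areas <- as.matrix(peaks[, design$sample_id, drop = FALSE])
  out <- matrix(0, nrow = nrow(peaks), ncol = length(bio),
                dimnames = list(NULL, bio))
  n_zero <- 0L
  for (b in bio) {
    cols <- design$sample_id[design$bio_id == b]
    if (length(cols) == 0L) stop(sprintf("no technical replicates for %s", b))
    sub <- areas[, cols, drop = FALSE]
    n_zero <- n_zero + sum(sub == 0 & rowSums(sub > 0) > 0)
    out[, b] <- apply(sub, 1L, geometric_mean)
  }
  res <- cbind(peaks[, c("peak_id", "mz", "rt", "polarity", "height")],
               as.data.frame(out, check.names = FALSE))
  attr(res, "n_zero_dropped") <- n_zero
  res
}

#' Biological-sample design after technical collapsing
#'
#' One row per biological sample, with `sample_id` set to the `bio_id` used
#' by [collapse_technical()].
#'
#' @param design Sample design.
#' @return Collapsed design data frame.
#' @export
collapse_design <- function(design) {
  design <- if (is.null(design$bio_id)) as_sample_design(design) else design
  d <- design[!duplicated(design$bio_id),
              c("bio_id", "genotype", "treatment", "biological_replicate",
                "organ")]
  d$sample_id <- d$bio_id
  rownames(d) <- NULL
  d
}
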