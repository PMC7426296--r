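# Compound identification by neutral-mass matching with an empirical-Bayes
# mixture posterior. The false-match error distribution is learned from the
# second-best (nearest distinct-formula) database matches of all peaks: for a
# peak sitting on a genuine database mass, the distance to the next distinct
# formula has the same distribution as the best-match error of a spurious
# peak, which makes the second-best errors a data-driven null.

#' Match peaks against a compound database
#'
#' For each peak, every (adduct, charge) hypothesis in `adducts` compatible
#' with the peak's polarity is converted to a neutral-mass hypothesis and
#' compared to every database formula. The best match is the
#' minimum-|ppm-error| formula over all hypotheses; the second-best match is
#' the minimum-error formula distinct from the best one and is recorded
#' without any window so it can populate the null distribution. Ties are
#' broken by database order.
#'
#' @param peaks Peak table with `peak_id`, `mz`, `polarity` columns. If
#'   `premassed = TRUE` the `mz` column is taken to be an already neutralized
#'   mass and a single identity hypothesis is used.
#' @param db A `compound_db` (see [as_compound_db()]).
#' @param adducts Adduct data frame (default: [adduct_table()] restricted per
#'   peak polarity), or a character vector of adduct names.
#' @param capture_window_ppm Best matches beyond this absolute error are not
#'   eligible for assignment or mixture fitting (default 50 ppm, wide enough
#'   for the mixture to see false matches).
#' @param standard_window_ppm Window within which a best match to an isotopic
#'   standard entry is taken as a standard-based identification.
#' @param premassed Set `TRUE` when the peak table reports neutralized masses
#'   rather than raw m/z.
#' @return A data frame of match results, one row per peak: best formula,
#'   compound id(s), adduct, signed ppm errors `e_best` / `e_second`,
#'   isomer count, standard flag and window eligibility.
#' @export
match_candidates <- function(peaks, db, adducts = NULL,
                             capture_window_ppm = 50,
                             standard_window_ppm = 10,
                             premassed = FALSE) {
  if (!inherits(db, "compound_db")) db <- as_compound_db(db)
  if (nrow(db) == 0L) stop("empty compound database")
  if (is.character(adducts)) {
    tab <- adduct_table(include_chloride = TRUE)
    bad <- setdiff(adducts, tab$name)
    if (length(bad)) stop(sprintf("unknown adduct(s): %s",
                                  paste(bad, collapse = ", ")))
    adducts <- tab[match(adducts, tab$name), , drop = FALSE]
  }
  if (is.null(adducts)) adducts <- adduct_table()

  # one row per distinct formula identity, sorted by mass
  first <- !duplicated(db$formula_key)
  fm <- data.frame(key = db$formula_key[first],
                   mass = db$neutral_mass[first],
                   db_index = which(first),
                   stringsAsFactors = FALSE)
  cnt <- table(db$formula_key)
  fm$n_compounds <- as.integer(cnt[fm$key])
  std <- tapply(db$is_standard, db$formula_key, any)
  fm$is_standard <- as.logical(std[fm$key])
  ids <- tapply(db$compound_id, db$formula_key,
                function(x) paste(x, collapse = ";"))
  fm$compound_ids <- as.character(ids[fm$key])
  fm <- fm[order(fm$mass, fm$db_index), , drop = FALSE]
  nf <- nrow(fm)

  n <- nrow(peaks)
  res <- data.frame(
    peak_id = peaks$peak_id, mz = peaks$mz,
    polarity = if (premassed) rep("neutral", n) else peaks$polarity,
    best_formula = NA_character_, best_compound_id = NA_character_,
    best_mass = NA_real_, adduct = NA_character_, charge = NA_integer_,
    e_best = NA_real_, n_isomers = NA_integer_,
    is_standard_match = FALSE,
    second_formula = NA_character_, e_second = NA_real_,
    within_window = FALSE,
    stringsAsFactors = FALSE
  )
  if (n == 0L) return(res)

  for (i in seq_len(n)) {
    if (premassed) {
      hyp <- data.frame(name = "[M]", mass_shift = 0, charge = 1L)
    } else {
      hyp <- adducts[adducts$polarity == res$polarity[i], , drop = FALSE]
      if (nrow(hyp) == 0L) next
    }
    M <- hyp$charge * (peaks$mz[i] - hyp$mass_shift)
    ok <- which(M > 0)
    if (length(ok) == 0L) next
    # two nearest formulas per hypothesis suffice: the closest distinct
    # formula is always at rank 1 or 2 of some hypothesis
    cand_idx <- integer(0); cand_err <- numeric(0); cand_hyp <- integer(0)
    for (h in ok) {
      j <- findInterval(M[h], fm$mass)
      a1 <- min(max(j, 1L), nf)
      a2 <- min(j + 1L, nf)
      if (a2 == a1) a2 <- max(a1 - 1L, 1L)
      ks <- unique(c(a1, a2))
      cand_idx <- c(cand_idx, ks)
      cand_err <- c(cand_err, (M[h] - fm$mass[ks]) / fm$mass[ks] * 1e6)
      cand_hyp <- c(cand_hyp, rep(h, length(ks)))
    }
    ord <- order(abs(cand_err), fm$db_index[cand_idx], cand_hyp)
    b <- ord[1L]
    bi <- cand_idx[b]
    res$best_formula[i] <- fm$key[bi]
    res$best_compound_id[i] <- fm$compound_ids[bi]
    res$best_mass[i] <- fm$mass[bi]
    res$adduct[i] <- hyp$name[cand_hyp[b]]
    res$charge[i] <- hyp$charge[cand_hyp[b]]
    res$e_best[i] <- cand_err[b]
    res$n_isomers[i] <- fm$n_compounds[bi]
    res$within_window[i] <- abs(cand_err[b]) <= capture_window_ppm
    res$is_standard_match[i] <- fm$is_standard[bi] &&
      abs(cand_err[b]) <= standard_window_ppm
    distinct <- ord[fm$key[cand_idx[ord]] != fm$key[bi]]
    if (length(distinct)) {
      s <- distinct[1L]
      res$second_formula[i] <- fm$key[cand_idx[s]]
      res$e_second[i] <- cand_err[s]
    }
  }
  res
}

#' Fit the true/false mass-error mixture
#'
#' Decomposes the best-match signed ppm-error distribution into a true
#' component `f1` (Gaussian, location/scale free) and a false component `f0`
#' (kernel density of all second-best errors, held fixed) by
#' expectation-maximization on the likelihood
#' `pi1 * f1(e) + (1 - pi1) * f0(e)`. Initialization is deterministic
#' (`pi1 = 0.5`, `mu1 = 0`, `sigma1 = median |e_best|`); convergence when the
#' log-likelihood changes by less than `tol` or after `max_iter` iterations.
#'
#' @param matches Match results from [match_candidates()] (columns `e_best`,
#'   `e_second`, `within_window`, `is_standard_match`), or any data frame
#'   with those columns.
#' @param min_n Minimum number of matches with both best and second-best
#'   errors (default 50).
#' @param max_iter,tol EM stopping rule.
#' @param fitted_on Optional label of the stratum (e.g. "kidney/positive").
#' @return An object of class `error_mixture` with elements `pi1`, `mu1`,
#'   `sigma1`, the kernel bandwidth `bw`, the second-best errors defining
#'   `f0`, the final log-likelihood and iteration count.
#' @export
fit_error_mixture <- function(matches, min_n = 50, max_iter = 500,
                              tol = 1e-8, fitted_on = NA_character_) {
  e2 <- matches$e_second[!is.na(matches$e_second)]
  # the capture window gates assignment only; the mixture is fitted on all
  # best-match errors so the false component is fully represented
  use <- !is.na(matches$e_best) & !is.na(matches$e_second) &
    !matches$is_standard_match
  e1 <- matches$e_best[use]
  if (sum(use) < min_n) {
    stop(sprintf("too few matches with best and second-best errors (%d < %d)",
                 sum(use), min_n))
  }
  if (stats::sd(e2) == 0) {
    stop("degenerate null: all second-best errors identical")
  }
  bw <- tryCatch(stats::bw.SJ(e2), error = function(e) stats::bw.nrd0(e2))
  f0e <- pmax(.kde_eval(e1, e2, bw), 1e-300)

  pi1 <- 0.5
  mu1 <- 0
  s1 <- max(stats::median(abs(e1)), 1e-3)
  ll_old <- -Inf
  converged <- FALSE
  it <- 0L
  for (it in seq_len(max_iter)) {
    f1e <- stats::dnorm(e1, mu1, s1)
    num <- pi1 * f1e
    den <- num + (1 - pi1) * f0e
    den[den <= 0] <- .Machine$double.xmin
    w <- num / den
    ll <- sum(log(den))
    if (is.finite(ll_old) && abs(ll - ll_old) < tol) {
      converged <- TRUE
      break
    }
    ll_old <- ll
    pi1 <- min(max(mean(w), 1e-6), 1 - 1e-6)
    sw <- sum(w)
    if (sw > 0) {
      mu1 <- sum(w * e1) / sw
      s1 <- max(sqrt(sum(w * (e1 - mu1)^2) / sw), 1e-3)
    }
  }
  structure(list(pi1 = pi1, mu1 = mu1, sigma1 = s1, bw = bw,
                 e_second = e2, n_best = length(e1), n_second = length(e2),
                 loglik = ll, n_iter = it, converged = converged,
                 fitted_on = fitted_on),
            class = "error_mixture")
}

# gaussian KDE evaluated at x, chunked to bound memory
.kde_eval <- function(x, centers, bw) {
  out <- numeric(length(x))
  if (length(x) == 0L) return(out)
  step <- max(1L, floor(5e6 / max(length(centers), 1L)))
  for (i in seq(1L, length(x), by = step)) {
    idx <- i:min(i + step - 1L, length(x))
    d <- stats::dnorm(outer(x[idx], centers, "-"), sd = bw)
    out[idx] <- rowMeans(d)
  }
  out
}

#' Evaluate the fitted component densities
#'
#' @param model An `error_mixture` fit.
#' @param x Signed ppm errors.
#' @return Density values.
#' @export
f0_density <- function(model, x) .kde_eval(x, model$e_second, model$bw)

#' @rdname f0_density
#' @export
f1_density <- function(model, x) stats::dnorm(x, model$mu1, model$sigma1)

#' @export
print.error_mixture <- function(x, ...) {
  cat("<error_mixture>",
      if (!is.na(x$fitted_on)) paste0(" [", x$fitted_on, "]"), "\n",
      sprintf("  pi1 = %.4f, f1 = N(%.3f, %.3f^2) ppm\n",
              x$pi1, x$mu1, x$sigma1),
      sprintf("  f0: KDE of %d second-best errors (bw %.3f)\n",
              x$n_second, x$bw),
      sprintf("  fit on %d best-match errors, %d EM iterations%s\n",
              x$n_best, x$n_iter,
              if (x$converged) "" else " (not converged)"),
      sep = "")
  invisible(x)
}

#' Posterior probability of true identification
#'
#' The plain two-component Bayes rule
#' `pi1 * f1 / (pi1 * f1 + (1 - pi1) * f0)`, exposed so that posteriors can
#' be computed directly from known densities.
#'
#' @param pi1 Mixing weight of the true component.
#' @param f1,f0 Density values at the observed error.
#' @return Posterior probabilities in `[0, 1]`; 0 (with a warning) where both
#'   densities vanish.
#' @export
identification_posterior <- function(pi1, f1, f0) {
  num <- pi1 * f1
  den <- num + (1 - pi1) * f0
  out <- ifelse(den > 0, num / den, 0)
  if (any(den <= 0)) {
    warning("both component densities vanish at some errors; posterior set to 0")
  }
  out
}

#' Compute identification posteriors for matched peaks
#'
#' @param model An `error_mixture` fit.
#' @param matches Match results (uses `e_best`), or a numeric vector of
#'   signed ppm errors.
#' @return Posterior probability per peak (`NA` where no best match exists).
#' @export
compute_posteriors <- function(model, matches) {
  e <- if (is.numeric(matches)) matches else matches$e_best
  out <- rep(NA_real_, length(e))
  ok <- !is.na(e)
  out[ok] <- identification_posterior(model$pi1,
                                      f1_density(model, e[ok]),
                                      f0_density(model, e[ok]))
  out
}

#' Apply the assignment rules
#'
#' Standard-based matches are identified with full confidence (posterior 1).
#' Otherwise a peak is `assigned` when its posterior reaches `threshold`
#' (inclusive) and its formula maps to a single database compound;
#' `ambiguous_isomer_removed` when the formula is shared by two or more
#' compounds; `unassigned` otherwise (including best matches outside the
#' capture window).
#'
#' @param matches Match results from [match_candidates()].
#' @param posteriors Posteriors from [compute_posteriors()].
#' @param threshold Assignment threshold in (0, 1], default 0.8.
#' @return A data frame `peak_id`, `compound_id`, `formula`, `adduct`,
#'   `ppm_error`, `posterior`, `status`, with a `summary` attribute holding
#'   the fraction of peaks identified and the maximum absolute ppm error
#'   among assignments.
#' @export
assign_identifications <- function(matches, posteriors, threshold = 0.8) {
  if (!(is.numeric(threshold) && length(threshold) == 1L &&
        threshold > 0 && threshold <= 1)) {
    stop("posterior threshold must be in (0, 1]")
  }
  n <- nrow(matches)
  status <- rep("unassigned", n)
  post <- posteriors
  std <- matches$is_standard_match
  status[std] <- "standard"
  post[std] <- 1
  eligible <- !std & matches$within_window & !is.na(post) & post >= threshold
  multi <- !is.na(matches$n_isomers) & matches$n_isomers >= 2L
  status[eligible & !multi] <- "assigned"
  status[eligible & multi] <- "ambiguous_isomer_removed"
  out <- data.frame(
    peak_id = matches$peak_id,
    compound_id = matches$best_compound_id,
    formula = matches$best_formula,
    adduct = matches$adduct,
    ppm_error = matches$e_best,
    posterior = post,
    status = status,
    stringsAsFactors = FALSE
  )
  assigned <- status %in% c("assigned", "standard")
  attr(out, "summary") <- list(
    n_peaks = n,
    fraction_identified = mean(assigned),
    n_assigned = sum(status == "assigned"),
    n_standard = sum(status == "standard"),
    n_isomer_removed = sum(status == "ambiguous_isomer_removed"),
    max_abs_ppm_assigned = if (any(status == "assigned")) {
      max(abs(out$ppm_error[status == "assigned"]))
    } else NA_real_
  )
  out
}

#' Annotate a peak table (per-polarity strata)
#'
#' Convenience wrapper running [match_candidates()], [fit_error_mixture()],
#' [compute_posteriors()] and [assign_identifications()] separately for each
#' ionization mode present in the data, mirroring separate processing of
#' positive- and negative-mode acquisitions.
#'
#' @inheritParams match_candidates
#' @inheritParams assign_identifications
#' @inheritParams fit_error_mixture
#' @param organ Optional organ label used to tag the fitted models.
#' @return A list with `identifications` (row-bound across strata),
#'   `models` (one `error_mixture` per polarity) and `matches`.
#' @export
annotate_peaks <- function(peaks, db, adducts = NULL,
                           capture_window_ppm = 50, threshold = 0.8,
                           min_n = 50, organ = NA_character_,
                           premassed = FALSE) {
  pols <- unique(as.character(peaks$polarity))
  idents <- list()
  models <- list()
  matches <- list()
  for (p in pols) {
    sub <- peaks[peaks$polarity == p, , drop = FALSE]
    m <- match_candidates(sub, db, adducts = adducts,
                          capture_window_ppm = capture_window_ppm,
                          premassed = premassed)
    fit <- fit_error_mixture(m, min_n = min_n,
                             fitted_on = paste(organ, p, sep = "/"))
    post <- compute_posteriors(fit, m)
    idents[[p]] <- assign_identifications(m, post, threshold = threshold)
    models[[p]] <- fit
    matches[[p]] <- m
  }
  summaries <- lapply(idents, attr, "summary")
  out <- list(identifications = do.call(rbind, c(idents, make.row.names = FALSE)),
              models = models,
              matches = do.call(rbind, c(matches, make.row.names = FALSE)))
  attr(out$identifications, "summary") <- summaries
  out
}
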