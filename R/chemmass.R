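# Monoisotopic masses of the most abundant isotope of each element,
# in unified atomic mass units. Values from the AME2020 atomic mass
# evaluation / CODATA; truncation at 1e-8 u is far below instrument accuracy.
.isotope_masses <- c(
  H  = 1.00782503,
  B  = 11.00930540,
  C  = 12.00000000,
  N  = 14.00307401,
  O  = 15.99491462,
  F  = 18.99840322,
  Na = 22.98976928,
  Mg = 23.98504170,
  Si = 27.97692653,
  P  = 30.97376163,
  S  = 31.97207100,
  Cl = 34.96885268,
  K  = 38.96370668,
  Ca = 39.96259098,
  Mn = 54.93804510,
  Fe = 55.93493750,
  Co = 58.93319500,
  Ni = 57.93534290,
  Cu = 62.92959720,
  Zn = 63.92914220,
  As = 74.92159650,
  Se = 79.91652130,
  Br = 78.91833710,
  I  = 126.90447300,
  Li = 7.01600455
)

# electron-corrected charge-carrier masses
.PROTON_MASS <- 1.00727646
.ELECTRON_MASS <- 0.00054858

#' Parse a chemical formula string
#'
#' Parses Hill-style element+count notation (e.g. `"C5H8O4"`) into element
#' counts. Isotopic labels and charge annotations are not supported.
#'
#' @param text A single formula string. Whitespace is ignored; an empty
#'   string yields the empty formula (mass 0).
#' @return An object of class `chem_formula`: a named integer vector of
#'   element counts.
#' @examples
#' parse_formula("C5H8O4")
#' parse_formula("H2O")
#' @export
parse_formula <- function(text) {
  if (!is.character(text) || length(text) != 1L || is.na(text)) {
    stop("formula must be a single character string")
  }
  s <- gsub("[[:space:]]", "", text)
  counts <- integer(0)
  pos <- 1L
  n <- nchar(s)
  while (pos <= n) {
    m <- regmatches(
      substr(s, pos, n),
      regexpr("^([A-Z][a-z]?)([0-9]*)", substr(s, pos, n))
    )
    if (length(m) == 0L || !nzchar(m)) {
      stop(sprintf("malformed formula '%s': unexpected token at position %d",
                   text, pos))
    }
    sym <- sub("^([A-Z][a-z]?).*$", "\\1", m)
    num <- sub("^[A-Z][a-z]?", "", m)
    if (!sym %in% names(.isotope_masses)) {
      stop(sprintf("unknown element '%s' in formula '%s' at position %d",
                   sym, text, pos))
    }
    k <- if (nzchar(num)) as.integer(num) else 1L
    counts[sym] <- (if (sym %in% names(counts)) counts[[sym]] else 0L) + k
    pos <- pos + nchar(m)
  }
  structure(counts, class = "chem_formula")
}

#' Render a chemical formula in Hill order
#'
#' Carbon first, then hydrogen, then the remaining elements alphabetically;
#' when no carbon is present all elements are alphabetical. Inverse of
#' [parse_formula()].
#'
#' @param x A `chem_formula` object.
#' @param ... Unused.
#' @return A formula string.
#' @export
format.chem_formula <- function(x, ...) {
  x <- x[x > 0]
  if (length(x) == 0L) return("")
  syms <- names(x)
  if ("C" %in% syms) {
    ord <- c(intersect(c("C", "H"), syms), sort(setdiff(syms, c("C", "H"))))
  } else {
    ord <- sort(syms)
  }
  paste0(ord, ifelse(x[ord] > 1L, x[ord], ""), collapse = "")
}

#' @export
print.chem_formula <- function(x, ...) {
  cat("<chem_formula> ", format(x), "\n", sep = "")
  invisible(x)
}

#' Monoisotopic mass of a chemical formula
#'
#' Sum over elements of count times the mass of the element's most abundant
#' isotope, from the bundled isotope table.
#'
#' @param f A `chem_formula` object or a formula string.
#' @return Neutral monoisotopic mass in Da.
#' @examples
#' monoisotopic_mass("C5H8O4") # glutaric acid, 132.042259
#' @export
monoisotopic_mass <- function(f) {
  if (is.character(f)) f <- parse_formula(f)
  if (length(f) == 0L) return(0)
  if (any(f < 0)) stop("negative element count")
  sum(.isotope_masses[names(f)] * as.numeric(f))
}

#' Electrospray adduct species
#'
#' The default table covers the cationizing species of a typical positive-mode
#' acquisition (protonation, sodiation, potassiation at charge 1 and 2) and
#' deprotonation for negative mode. `mass_shift` is the signed, per-charge,
#' electron-corrected mass shift in Da, so that the neutral mass is recovered
#' as `charge * (mz - mass_shift)`.
#'
#' @param polarity `"positive"`, `"negative"`, or `"both"`.
#' @param include_chloride Also include the chloride attachment species
#'   `[M+Cl]-` (off by default).
#' @return A data frame with columns `name`, `mass_shift`, `charge`,
#'   `polarity`.
#' @export
adduct_table <- function(polarity = c("both", "positive", "negative"),
                         include_chloride = FALSE) {
  polarity <- match.arg(polarity)
  tab <- data.frame(
    name = c("[M+H]+", "[M+2H]2+", "[M+Na]+", "[M+2Na]2+",
             "[M+K]+", "[M+2K]2+", "[M-H]-"),
    mass_shift = c(.PROTON_MASS, .PROTON_MASS,
                   .isotope_masses[["Na"]] - .ELECTRON_MASS,
                   .isotope_masses[["Na"]] - .ELECTRON_MASS,
                   .isotope_masses[["K"]] - .ELECTRON_MASS,
                   .isotope_masses[["K"]] - .ELECTRON_MASS,
                   -.PROTON_MASS),
    charge = c(1L, 2L, 1L, 2L, 1L, 2L, 1L),
    polarity = c(rep("positive", 6L), "negative"),
    stringsAsFactors = FALSE
  )
  if (include_chloride) {
    tab <- rbind(tab, data.frame(
      name = "[M+Cl]-",
      mass_shift = .isotope_masses[["Cl"]] + .ELECTRON_MASS,
      charge = 1L, polarity = "negative",
      stringsAsFactors = FALSE
    ))
  }
  if (polarity != "both") tab <- tab[tab$polarity == polarity, , drop = FALSE]
  rownames(tab) <- NULL
  tab
}

.resolve_adduct <- function(adduct) {
  if (is.character(adduct) && length(adduct) == 1L) {
    tab <- adduct_table(include_chloride = TRUE)
    i <- match(adduct, tab$name)
    if (is.na(i)) stop(sprintf("unknown adduct '%s'", adduct))
    return(tab[i, , drop = FALSE])
  }
  stopifnot(all(c("mass_shift", "charge") %in% names(adduct)))
  adduct
}

#' Recover a neutral mass from an observed m/z
#'
#' Inverts the ionization equation for a given charge-carrying species:
#' `M = charge * (mz - mass_shift)`. For deprotonation the (negative) shift
#' makes this `mz + proton_mass` at charge 1.
#'
#' @param mz Observed mass-to-charge ratio (> 0); vectorized.
#' @param adduct Adduct name (see [adduct_table()]) or a list/one-row data
#'   frame with `mass_shift` and `charge`.
#' @return Neutral mass in Da.
#' @examples
#' neutral_mass_from_mz(133.049535, "[M+H]+")
#' @export
neutral_mass_from_mz <- function(mz, adduct) {
  if (any(!is.finite(mz)) || any(mz <= 0)) stop("mz must be positive")
  a <- .resolve_adduct(adduct)
  a$charge[[1]] * (mz - a$mass_shift[[1]])
}

#' Predicted m/z of a neutral mass under an adduct
#'
#' Forward ionization equation, the inverse of [neutral_mass_from_mz()].
#'
#' @param mass Neutral mass in Da (> 0); vectorized.
#' @inheritParams neutral_mass_from_mz
#' @return m/z value.
#' @export
mz_from_neutral_mass <- function(mass, adduct) {
  if (any(!is.finite(mass)) || any(mass <= 0)) stop("mass must be positive")
  a <- .resolve_adduct(adduct)
  mass / a$charge[[1]] + a$mass_shift[[1]]
}

#' Signed mass error in parts per million
#'
#' `(observed - theoretical) / theoretical * 1e6`, the matching statistic of
#' the identification model.
#'
#' @param observed Observed neutral mass in Da; vectorized.
#' @param theoretical Theoretical (database) mass in Da, > 0.
#' @return Signed ppm error.
#' @examples
#' ppm_error(132.044901, 132.042259) # ~ +20 ppm
#' @export
ppm_error <- function(observed, theoretical) {
  if (any(!is.finite(theoretical)) || any(theoretical <= 0)) {
    stop("theoretical mass must be positive")
  }
  (observed - theoretical) / theoretical * 1e6
}
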