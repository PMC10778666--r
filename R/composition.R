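# Elemental compositions are named integer vectors over C,H,N,O,S,Cl.
# Cl never occurs in a neutral metabolite composition here: it only enters
# through the chloride adduct, whose stoichiometry is handled in ion_mz().

#' Parse a molecular formula string
#'
#' Converts a formula such as `"C6H12O6"` into a full named count vector
#' over the supported elements (C, H, N, O, S, Cl).  Element symbols may
#' appear in any order; missing elements get count 0.
#'
#' @param formula Character scalar, e.g. `"C11H12N2O2"`.
#' @return Named integer vector with one entry per supported element.
#' @examples
#' parse_formula("C6H12O6")
#' @export
parse_formula <- function(formula) {
  if (is.numeric(formula) && !is.null(names(formula))) {
    return(as_composition(formula))
  }
  stopifnot(is.character(formula), length(formula) == 1L, !is.na(formula))
  s <- gsub("\\s", "", formula)
  m <- gregexpr("([A-Z][a-z]?)([0-9]*)", s)[[1]]
  toks <- regmatches(s, gregexpr("([A-Z][a-z]?)([0-9]*)", s))[[1]]
  if (sum(nchar(toks)) != nchar(s) || length(toks) == 0L) {
    stop("cannot parse formula '", formula, "'", call. = FALSE)
  }
  counts <- stats::setNames(integer(length(.ELEMENTS)), .ELEMENTS)
  for (tok in toks) {
    el <- sub("[0-9]*$", "", tok)
    n <- sub("^[A-Za-z]+", "", tok)
    n <- if (nzchar(n)) as.integer(n) else 1L
    if (!el %in% .ELEMENTS) {
      stop("unknown element symbol '", el, "' in formula '", formula, "'",
           call. = FALSE)
    }
    counts[el] <- counts[el] + n
  }
  if (sum(counts) < 1L) stop("empty composition", call. = FALSE)
  counts
}

# Coerce a partial named count vector into the full element layout.
as_composition <- function(x) {
  if (is.character(x)) return(parse_formula(x))
  stopifnot(is.numeric(x), !is.null(names(x)))
  bad <- setdiff(names(x), .ELEMENTS)
  if (length(bad)) {
    stop("unknown element symbol(s): ", paste(bad, collapse = ", "),
         call. = FALSE)
  }
  if (any(x < 0) || any(x != round(x))) {
    stop("element counts must be non-negative integers", call. = FALSE)
  }
  counts <- stats::setNames(integer(length(.ELEMENTS)), .ELEMENTS)
  counts[names(x)] <- as.integer(x)
  if (sum(counts) < 1L) stop("empty composition", call. = FALSE)
  counts
}

#' Format a composition in Hill order
#'
#' Carbon first, hydrogen second, remaining elements alphabetically;
#' elements with count 0 are omitted and unit counts drop the digit.
#'
#' @param composition Formula string or named count vector.
#' @return Character scalar, e.g. `"C6H12O6"`.
#' @export
format_formula <- function(composition) {
  x <- as_composition(composition)
  ord <- c("C", "H", sort(setdiff(.ELEMENTS, c("C", "H"))))
  x <- x[ord]
  x <- x[x > 0L]
  paste0(names(x), ifelse(x == 1L, "", x), collapse = "")
}

#' Monoisotopic mass of a neutral composition
#'
#' Sum of element counts times the frozen monoisotopic atomic masses
#' ([mass_constants()]).
#'
#' @param composition Formula string or named count vector.
#' @return Mass in Da.
#' @examples
#' monoisotopic_mass("C6H12O6")  # 180.063388
#' @export
monoisotopic_mass <- function(composition) {
  x <- as_composition(composition)
  sum(x * .MONOISOTOPIC[names(x)])
}

#' m/z of a singly charged negative-mode ion
#'
#' Computes the m/z of the adduct ion of a neutral composition.  For a
#' singly charged anion the ion mass is the neutral mass plus the adduct
#' mass delta plus (by default) one electron mass; at FT-ICR accuracy the
#' electron term is not negligible (2.5 ppm at m/z 215).
#'
#' @param composition Neutral formula string or named count vector.  The
#'   neutral must supply the atoms the adduct removes (at least one H for
#'   deprotonation; an H2O plus an H for the dehydrated species).
#' @param adduct One of `"deprotonated"`, `"deprotonated-dehydrated"`,
#'   `"chloride"`.
#' @param electron Include the electron mass of the acquired charge
#'   (default `TRUE`).
#' @return m/z in Da (charge 1-).
#' @examples
#' ion_mz("C6H12O6", "chloride")       # 215.03279
#' ion_mz("C11H12N2O2", "deprotonated") # 203.08260
#' @export
ion_mz <- function(composition, adduct = "deprotonated", electron = TRUE) {
  x <- as_composition(composition)
  a <- .match_adduct(adduct)
  if (x[["H"]] < a$min_H || x[["O"]] < a$min_O) {
    stop("adduct '", adduct, "' is chemically impossible for ",
         format_formula(x), ": requires >= ", a$min_H, " H and >= ",
         a$min_O, " O in the neutral", call. = FALSE)
  }
  monoisotopic_mass(x) + a$delta + if (electron) .ELECTRON_MASS else 0
}

#' Reconstruct a neutral mass from an observed ion m/z
#'
#' Inverts the adduct arithmetic of [ion_mz()]; the round trip
#' `neutral_mass(ion_mz(x, a), a) == monoisotopic_mass(x)` is exact to
#' machine precision.
#'
#' @param mz Observed m/z (Da, charge 1-).
#' @inheritParams ion_mz
#' @return Neutral monoisotopic mass in Da.
#' @export
neutral_mass <- function(mz, adduct = "deprotonated", electron = TRUE) {
  a <- .match_adduct(adduct)
  mz - a$delta - if (electron) .ELECTRON_MASS else 0
}

#' Relative mass error in parts per million
#'
#' Defined as the ratio of the difference between two masses
#' (mz1 - mz2) to the first mass, times 1e6.  Signed; `mz1` is
#' conventionally the experimental mass.
#'
#' @param mz1,mz2 Masses in Da; `mz1 > 0`.
#' @return Signed error in ppm (vectorised).
#' @export
ppm_error <- function(mz1, mz2) {
  if (any(mz1 <= 0)) stop("mz1 must be positive", call. = FALSE)
  (mz1 - mz2) / mz1 * 1e6
}

#' Compound class of a composition
#'
#' CHO / CHNO / CHOS / CHNOS by presence of N and S; compositions lacking
#' any of C, H or O are reported as `"unclassified"`, never dropped.
#'
#' @param composition Formula string or named count vector.
#' @return Character scalar.
#' @export
chemical_class <- function(composition) {
  x <- as_composition(composition)
  if (x[["C"]] < 1L || x[["H"]] < 1L || x[["O"]] < 1L) return("unclassified")
  has_n <- x[["N"]] > 0L
  has_s <- x[["S"]] > 0L
  if (has_n && has_s) "CHNOS" else if (has_n) "CHNO" else if (has_s) "CHOS" else "CHO"
}

#' van Krevelen coordinates
#'
#' O/C and H/C atomic ratios, the axes of the van Krevelen diagram used
#' to map compound families in complex-mixture MS.
#'
#' @param composition Formula string or named count vector with C > 0.
#' @return Named numeric vector `c(o_to_c, h_to_c)`.
#' @export
van_krevelen <- function(composition) {
  x <- as_composition(composition)
  if (x[["C"]] < 1L) stop("van Krevelen ratios need at least one carbon",
                          call. = FALSE)
  c(o_to_c = x[["O"]] / x[["C"]], h_to_c = x[["H"]] / x[["C"]])
}

#' Rings plus double-bond equivalents
#'
#' RDBE = C - H/2 + N/2 + 1 over C,H,N,O,S; a standard plausibility
#' descriptor for candidate formulas (half-integer values indicate an
#' impossible even-electron neutral).
#'
#' @param composition Formula string or named count vector.
#' @return Numeric scalar (possibly half-integer).
#' @export
rdbe <- function(composition) {
  x <- as_composition(composition)
  x[["C"]] - x[["H"]] / 2 + x[["N"]] / 2 + 1
}
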