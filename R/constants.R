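# Monoisotopic masses of the lightest stable isotopes (1H, 12C, 14N, 16O,
# 32S, 35Cl), in Da, from the IUPAC/CODATA atomic-mass evaluation; 12C is
# exactly 12 by definition.  Single source of truth for every m/z computed
# in the package -- no module keeps its own copy.
.MONOISOTOPIC <- c(
  C  = 12.0,
  H  = 1.00782503207,
  N  = 14.0030740048,
  O  = 15.9949146196,
  S  = 31.97207100,
  Cl = 34.96885268
)

# CODATA electron mass in Da; a singly charged anion carries one extra
# electron, which matters at FT-ICR accuracy (~2.5 ppm at m/z 215).
.ELECTRON_MASS <- 0.000548579909

.ELEMENTS <- names(.MONOISOTOPIC)

# Negative-mode adducts.  `delta` is the mass change from the neutral to
# the ion EXCLUDING the electron; `d<El>` the stoichiometry change; the
# preconditions say which atoms the neutral must supply.
.ADDUCTS <- data.frame(
  name     = c("deprotonated", "deprotonated-dehydrated", "chloride"),
  ion_tag  = c("[M-H]-", "[M-H-H2O]-", "[M+Cl]-"),
  dH       = c(-1L, -3L, 0L),
  dO       = c(0L, -1L, 0L),
  dCl      = c(0L, 0L, 1L),
  min_H    = c(1L, 3L, 0L),
  min_O    = c(0L, 1L, 0L),
  stringsAsFactors = FALSE
)
.ADDUCTS$delta <- .ADDUCTS$dH * .MONOISOTOPIC[["H"]] +
  .ADDUCTS$dO * .MONOISOTOPIC[["O"]] +
  .ADDUCTS$dCl * .MONOISOTOPIC[["Cl"]]

#' Monoisotopic mass constants
#'
#' The frozen table of monoisotopic atomic masses used throughout the
#' package, plus the electron mass.  All ion m/z arithmetic in the package
#' derives from this single table.
#'
#' @return Named numeric vector of atomic masses in Da (elements C, H, N,
#'   O, S, Cl) with the electron mass appended as `"e"`.
#' @examples
#' mass_constants()[["C"]]  # exactly 12
#' @export
mass_constants <- function() {
  c(.MONOISOTOPIC, e = .ELECTRON_MASS)
}

#' Negative-mode adduct table
#'
#' The three singly charged negative-mode ion species handled by the
#' package: `[M-H]-` (deprotonated), `[M-H-H2O]-` (deprotonated after
#' water loss) and `[M+Cl]-` (chloride attachment).
#'
#' @return A data frame with one row per adduct: `name`, `ion_tag`, the
#'   stoichiometry deltas (`dH`, `dO`, `dCl`), the atoms the neutral must
#'   supply (`min_H`, `min_O`) and the mass delta in Da (`delta`,
#'   excluding the electron).
#' @export
adducts <- function() .ADDUCTS

.match_adduct <- function(name) {
  i <- match(name, .ADDUCTS$name)
  if (is.na(i)) {
    stop("unknown adduct '", name, "'; expected one of: ",
         paste(.ADDUCTS$name, collapse = ", "), call. = FALSE)
  }
  .ADDUCTS[i, , drop = FALSE]
}
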