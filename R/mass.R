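#' Monoisotopic atomic masses and adduct arithmetic
#'
#' Helpers for converting between measured mass-to-charge ratios and neutral
#' monoisotopic masses under the two proton adducts used throughout the
#' package: protonation `[M+H]+` in positive ion mode and deprotonation
#' `[M-H]-` in negative mode. The electron mass is neglected; its
#' contribution (~0.5 mDa) is far below the 15 ppm annotation tolerance at
#' the masses considered here.
#'
#' @name mass-arithmetic
NULL

# CODATA proton mass, Da.
PROTON_MASS <- 1.00727646

# Monoisotopic masses of the elements accepted in molecular formulas (Da).
MONOISOTOPIC_MASSES <- c(
  C  = 12.0,
  H  = 1.00782503,
  N  = 14.00307401,
  O  = 15.99491462,
  P  = 30.97376163,
  S  = 31.97207100,
  Se = 73.92247640,
  F  = 18.99840322,
  Cl = 34.96885268,
  Br = 78.91833760,
  I  = 126.90447300,
  Na = 22.98976928,
  K  = 38.96370668,
  Si = 27.97692653
)

#' Monoisotopic mass of a molecular formula
#'
#' Parses a flat molecular formula (element symbols with optional integer
#' counts, e.g. `"C15H14O7"`) and returns the sum of count times the
#' monoisotopic atomic mass of each element.
#'
#' @param formula Character scalar molecular formula.
#' @return Monoisotopic mass in Da.
#' @examples
#' monoisotopic_mass("H2O")        # 18.0105646
#' monoisotopic_mass("C15H14O7")   # epigallocatechin, 306.074
#' @export
monoisotopic_mass <- function(formula) {
  if (!is.character(formula) || length(formula) != 1L || is.na(formula) ||
      !nzchar(formula))
    abort_format("`formula` must be a non-empty character scalar")
  tokens <- gregexpr("[A-Z][a-z]?[0-9]*", formula)[[1]]
  parts <- regmatches(formula, list(tokens))[[1]]
  if (sum(nchar(parts)) != nchar(formula))
    abort_format("cannot parse molecular formula '%s'", formula)
  mass <- 0
  for (p in parts) {
    sym <- sub("[0-9]*$", "", p)
    cnt <- sub("^[A-Za-z]+", "", p)
    n <- if (nzchar(cnt)) as.numeric(cnt) else 1
    if (!sym %in% names(MONOISOTOPIC_MASSES))
      abort_format("unknown element symbol '%s' in formula '%s'", sym, formula)
    mass <- mass + n * MONOISOTOPIC_MASSES[[sym]]
  }
  mass
}

#' Neutral monoisotopic mass from a measured m/z
#'
#' Inverts the proton adduct: positive mode assumes `[M+H]+` so the neutral
#' mass is `mz - m_proton`; negative mode assumes `[M-H]-` so it is
#' `mz + m_proton`.
#'
#' @param mz Measured mass-to-charge ratio (Th).
#' @param mode `"positive"` or `"negative"`.
#' @return Neutral mass in Da.
#' @export
neutral_mass_from_mz <- function(mz, mode = c("positive", "negative")) {
  mode <- match.arg(mode)
  if (!is.numeric(mz) || any(!is.finite(mz)) || any(mz <= 0))
    abort_validation("`mz` must be positive and finite")
  m <- if (mode == "positive") mz - PROTON_MASS else mz + PROTON_MASS
  if (any(m <= 0))
    abort_domain("neutral mass is non-positive for m/z %g in %s mode",
                 mz[which(m <= 0)[1]], mode)
  m
}

#' Theoretical m/z of a neutral mass under the mode's proton adduct
#' @param mass Neutral monoisotopic mass (Da).
#' @param mode Ion mode.
#' @return m/z in Th.
#' @export
mz_from_neutral_mass <- function(mass, mode = c("positive", "negative")) {
  mode <- match.arg(mode)
  if (mode == "positive") mass + PROTON_MASS else mass - PROTON_MASS
}
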