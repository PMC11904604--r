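# Elemental masses. Monoisotopic values are CODATA/AME exact isotope masses;
# average values are the CIAAW abridged standard atomic weights.
.element_mono <- c(C = 12, H = 1.0078250319, N = 14.0030740052,
                   O = 15.9949146221, S = 31.97207069)
.element_avg  <- c(C = 12.011, H = 1.008, N = 14.007, O = 15.999, S = 32.06)
.c13_mass <- 13.0033548378

# Residue (amino acid minus water) elemental compositions, columns C,H,N,O,S.
.residue_composition <- rbind(
  G = c(2, 3, 1, 1, 0),  A = c(3, 5, 1, 1, 0),  S = c(3, 5, 1, 2, 0),
  P = c(5, 7, 1, 1, 0),  V = c(5, 9, 1, 1, 0),  T = c(4, 7, 1, 2, 0),
  C = c(3, 5, 1, 1, 1),  L = c(6, 11, 1, 1, 0), I = c(6, 11, 1, 1, 0),
  N = c(4, 6, 2, 2, 0),  D = c(4, 5, 1, 3, 0),  Q = c(5, 8, 2, 2, 0),
  K = c(6, 12, 2, 1, 0), E = c(5, 7, 1, 3, 0),  M = c(5, 9, 1, 1, 1),
  H = c(6, 7, 3, 1, 0),  F = c(9, 9, 1, 1, 0),  R = c(6, 12, 4, 1, 0),
  Y = c(9, 9, 1, 2, 0),  W = c(11, 10, 2, 1, 0))
colnames(.residue_composition) <- c("C", "H", "N", "O", "S")

#' The 20 standard one-letter residue codes
#'
#' @return Character vector of the 20 residue codes covered by the mass
#'   tables.
#' @export
residue_alphabet <- function() rownames(.residue_composition)

#' Create a mass convention for peptide and fragment-ion arithmetic
#'
#' A mass convention bundles the residue mass table, the water and proton
#' masses, and the mass shifts of isotope labels, under either monoisotopic
#' or average (chemical) atomic masses. Triple-quadrupole MRM assays at unit
#' resolution quote m/z values that may follow either convention, so both
#' are supported; monoisotopic is the default.
#'
#' The `13C6` label shift is the mass difference produced by replacing six
#' carbons of a residue with pure carbon-13: +6.0201 Da against monoisotopic
#' (12C) carbon, +5.9541 Da against natural-abundance average carbon.
#'
#' @param kind `"monoisotopic"` (default) or `"average"`.
#' @return An object of class `mass_convention`: a list with elements
#'   `kind`, `proton_mass`, `water_mass`, `residue_table` (named numeric,
#'   Da per residue), and `label_shift_table` (named numeric, Da per label
#'   kind).
#' @examples
#' conv <- mass_convention("average")
#' conv$residue_table[["G"]]
#' @export
mass_convention <- function(kind = c("monoisotopic", "average")) {
  kind <- match.arg(kind)
  el <- if (kind == "monoisotopic") .element_mono else .element_avg
  residue_table <- drop(.residue_composition %*% el[colnames(.residue_composition)])
  label_shift_table <- c("13C6" = 6 * (.c13_mass - el[["C"]]))
  structure(
    list(kind = kind,
         proton_mass = 1.00727646688,
         water_mass = 2 * el[["H"]] + el[["O"]],
         residue_table = residue_table,
         label_shift_table = label_shift_table),
    class = "mass_convention")
}

#' @export
print.mass_convention <- function(x, ...) {
  cat(sprintf("<mass_convention: %s; water %.5f Da; proton %.5f Da>\n",
              x$kind, x$water_mass, x$proton_mass))
  invisible(x)
}

#' Round half-up at a fixed number of decimals
#'
#' m/z values are reported at one decimal using half-up rounding (the
#' convention of instrument software), not the round-half-even rule of
#' [round()].
#'
#' @param x Numeric vector.
#' @param digits Number of decimal places (default 1).
#' @return `x` rounded half-up.
#' @examples
#' round_half_up(267.25, 1)  # 267.3, where round() would give 267.2
#' @export
round_half_up <- function(x, digits = 1) {
  p <- 10^digits
  floor(x * p + 0.5) / p
}

# classed error helpers shared across modules
.stop_invalid <- function(msg) {
  stop(errorCondition(msg, class = c("mrmquant_invalid_input", "mrmquant_error")))
}
.stop_not_found <- function(msg) {
  stop(errorCondition(msg, class = c("mrmquant_not_found", "mrmquant_error")))
}
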