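#' The human C-peptide sequence
#'
#' The 31-residue connecting peptide of proinsulin, the measurand of the
#' assay.
#'
#' @return Character scalar.
#' @export
cpeptide_sequence <- function() "EAEDLQVGQVELGGGPGAGSLQPLALEGSLQ"

#' The isotope-labeled C-peptide internal standard
#'
#' The commercially labeled material carries uniformly 13C-labeled leucine
#' (13C6) at residues 26 and 30 of the C-peptide sequence. Spiked into serum
#' before digestion, it tracks the native analyte through preparation,
#' digestion and ionization.
#'
#' @return A [peptide()] with two `13C6` labels.
#' @export
cpeptide_labeled <- function() {
  peptide(cpeptide_sequence(), labels = c("26:13C6", "30:13C6"))
}

#' The Glu-C quantitation peptide
#'
#' Of the Glu-C digestion products of C-peptide, LGGGPGAGSLQPLALE (residues
#' 12-27 of the parent) is the one carrying a label in the labeled material
#' (13C6-leucine at its position 15), so it is the peptide used for
#' quantitation.
#'
#' @param labeled If `TRUE`, return the labeled form (13C6 at position 15).
#' @return A [peptide()].
#' @export
quantitation_peptide <- function(labeled = FALSE) {
  peptide("LGGGPGAGSLQPLALE",
          labels = if (labeled) "15:13C6" else NULL,
          origin_span = c(12L, 27L))
}

#' The assay's canonical MRM transition table
#'
#' Eight transitions: doubly charged precursor to b11 (quantifier), y2,
#' doubly charged b12, and b14, for both the native and the labeled
#' quantitation peptide.
#'
#' @param conv A [mass_convention()] (default monoisotopic).
#' @return Transition table data frame; see [build_transition_table()].
#' @examples
#' cpeptide_transitions()
#' @export
cpeptide_transitions <- function(conv = mass_convention()) {
  build_transition_table(
    native = quantitation_peptide(labeled = FALSE),
    labeled = quantitation_peptide(labeled = TRUE),
    fragments = parse_fragments(c("b11", "y2", "b12^2", "b14")),
    precursor_charge = 2L,
    conv = conv,
    quantifier = fragment_ion("b", 11))
}
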