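#' Construct a peptide, optionally with isotope labels
#'
#' A peptide is a string of one-letter residue codes plus an optional set of
#' residue-level isotope labels (e.g. a uniformly 13C-labeled leucine) and,
#' for digestion products, the span it occupies within its parent sequence.
#'
#' @param sequence Character scalar of one-letter residue codes.
#' @param labels Labels as a data frame with columns `position` (1-based
#'   residue index) and `kind` (e.g. `"13C6"`), or a character vector of
#'   `"position:kind"` entries such as `c("26:13C6", "30:13C6")`.
#' @param origin_span Optional integer pair `(start, end)`: 1-based
#'   inclusive positions within a parent sequence.
#' @return An object of class `peptide`.
#' @examples
#' peptide("LGGGPGAGSLQPLALE", labels = "15:13C6")
#' @export
peptide <- function(sequence, labels = NULL, origin_span = NULL) {
  if (!is.character(sequence) || length(sequence) != 1L || is.na(sequence) ||
      nchar(sequence) == 0L)
    .stop_invalid("sequence must be a non-empty character scalar")
  residues <- strsplit(sequence, "", fixed = TRUE)[[1]]
  bad <- setdiff(residues, residue_alphabet())
  if (length(bad))
    .stop_invalid(sprintf("unknown residue code(s): %s",
                          paste(unique(bad), collapse = ", ")))
  labels <- parse_labels(labels)
  if (nrow(labels)) {
    if (any(labels$position < 1L | labels$position > nchar(sequence)))
      .stop_invalid("label position outside the sequence")
    if (anyDuplicated(labels$position))
      .stop_invalid("label positions must be unique")
  }
  if (!is.null(origin_span)) {
    if (length(origin_span) != 2L || origin_span[1] > origin_span[2])
      .stop_invalid("origin_span must be (start, end) with start <= end")
    origin_span <- as.integer(origin_span)
  }
  structure(list(sequence = sequence, labels = labels,
                 origin_span = origin_span),
            class = "peptide")
}

parse_labels <- function(labels) {
  empty <- data.frame(position = integer(), kind = character(),
                      stringsAsFactors = FALSE)
  if (is.null(labels) || (is.data.frame(labels) && nrow(labels) == 0L) ||
      (is.character(labels) && length(labels) == 0L))
    return(empty)
  if (is.character(labels)) {
    parts <- strsplit(labels, ":", fixed = TRUE)
    if (any(lengths(parts) != 2L))
      .stop_invalid("label spec entries must look like \"15:13C6\"")
    labels <- data.frame(position = as.integer(vapply(parts, `[`, "", 1L)),
                         kind = vapply(parts, `[`, "", 2L),
                         stringsAsFactors = FALSE)
  }
  if (!all(c("position", "kind") %in% names(labels)))
    .stop_invalid("labels need columns 'position' and 'kind'")
  data.frame(position = as.integer(labels$position),
             kind = as.character(labels$kind), stringsAsFactors = FALSE)
}

#' @export
print.peptide <- function(x, ...) {
  lab <- if (nrow(x$labels))
    paste0(" [", paste(sprintf("%d:%s", x$labels$position, x$labels$kind),
                       collapse = "; "), "]") else ""
  span <- if (!is.null(x$origin_span))
    sprintf(" (parent %d-%d)", x$origin_span[1], x$origin_span[2]) else ""
  cat(sprintf("<peptide %s%s%s>\n", x$sequence, lab, span))
  invisible(x)
}

#' @export
length.peptide <- function(x) nchar(x$sequence)

#' Protease digestion rule
#'
#' Glu-C in ammonium bicarbonate buffer cleaves C-terminal to glutamic acid
#' (E); in phosphate buffers it additionally cleaves after aspartic acid
#' (D). The default reflects the bicarbonate condition: cleave after E only,
#' allowing up to two missed cleavage sites.
#'
#' @param cleave_after Character vector of residue codes cleaved after
#'   (default `"E"`); use `c("E", "D")` for dual specificity.
#' @param max_missed_cleavages Non-negative integer, at most 10 (default 2).
#' @param min_length Minimum product length to report (default 1).
#' @return An object of class `digestion_rule`.
#' @export
digestion_rule <- function(cleave_after = "E", max_missed_cleavages = 2L,
                           min_length = 1L) {
  cleave_after <- unique(as.character(cleave_after))
  if (length(cleave_after) == 0L || !all(cleave_after %in% residue_alphabet()))
    .stop_invalid("cleave_after must name residue codes")
  max_missed_cleavages <- as.integer(max_missed_cleavages)
  if (is.na(max_missed_cleavages) || max_missed_cleavages < 0L ||
      max_missed_cleavages > 10L)
    .stop_invalid("max_missed_cleavages must be in 0..10")
  min_length <- as.integer(min_length)
  if (is.na(min_length) || min_length < 0L)
    .stop_invalid("min_length must be non-negative")
  structure(list(cleave_after = cleave_after,
                 max_missed_cleavages = max_missed_cleavages,
                 min_length = min_length),
            class = "digestion_rule")
}

#' In-silico protease digestion
#'
#' Cleaves `parent` on the C-terminal side of each residue in
#' `rule$cleave_after`, producing every product with 0 to
#' `rule$max_missed_cleavages` internal missed sites. Each product records
#' its span within the parent and inherits the parent's labels that fall
#' inside that span, re-indexed to the product's own coordinates. A site at
#' the final residue produces no cleavage (the C-terminal cut is a no-op).
#'
#' @param parent A [peptide()].
#' @param rule A [digestion_rule()].
#' @return List of `peptide` products in N-to-C order (by start, then end);
#'   products shorter than `rule$min_length` are dropped; no duplicate spans.
#' @examples
#' cp <- peptide(cpeptide_sequence())
#' digest(cp, digestion_rule(max_missed_cleavages = 0))
#' @export
digest <- function(parent, rule = digestion_rule()) {
  stopifnot(inherits(parent, "peptide"), inherits(rule, "digestion_rule"))
  residues <- strsplit(parent$sequence, "", fixed = TRUE)[[1]]
  n <- length(residues)
  sites <- which(residues %in% rule$cleave_after)
  sites <- sites[sites < n]           # cutting after the last residue is a no-op
  bounds <- c(0L, sites, n)           # segment i spans bounds[i]+1 .. bounds[i+1]
  nseg <- length(bounds) - 1L
  out <- list()
  for (i in seq_len(nseg)) {
    for (k in 0:rule$max_missed_cleavages) {
      j <- i + k
      if (j > nseg) break
      start <- bounds[i] + 1L
      end <- bounds[j + 1L]
      if (end - start + 1L < rule$min_length) next
      seq_ik <- substr(parent$sequence, start, end)
      keep <- parent$labels$position >= start & parent$labels$position <= end
      labs <- parent$labels[keep, , drop = FALSE]
      labs$position <- labs$position - start + 1L
      out[[length(out) + 1L]] <- peptide(seq_ik, labels = labs,
                                         origin_span = c(start, end))
    }
  }
  starts <- vapply(out, function(p) p$origin_span[1], 1L)
  ends <- vapply(out, function(p) p$origin_span[2], 1L)
  out <- out[!duplicated(cbind(starts, ends))]
  ord <- order(vapply(out, function(p) p$origin_span[1], 1L),
               vapply(out, function(p) p$origin_span[2], 1L))
  out[ord]
}

#' Neutral peptide mass
#'
#' Sum of residue masses plus water plus the shifts of any isotope labels,
#' under the chosen mass convention.
#'
#' @param p A [peptide()].
#' @param conv A [mass_convention()].
#' @return Neutral mass in Da.
#' @examples
#' peptide_mass(peptide("LGGGPGAGSLQPLALE"), mass_convention("monoisotopic"))
#' @export
peptide_mass <- function(p, conv = mass_convention()) {
  stopifnot(inherits(p, "peptide"), inherits(conv, "mass_convention"))
  residues <- strsplit(p$sequence, "", fixed = TRUE)[[1]]
  m <- sum(conv$residue_table[residues]) + conv$water_mass
  m + .label_shift_sum(p$labels, conv)
}

.label_shift_sum <- function(labels, conv) {
  if (!nrow(labels)) return(0)
  unknown <- setdiff(labels$kind, names(conv$label_shift_table))
  if (length(unknown))
    .stop_invalid(sprintf("unknown label kind(s): %s",
                          paste(unique(unknown), collapse = ", ")))
  sum(conv$label_shift_table[labels$kind])
}

#' Construct a backbone fragment ion
#'
#' @param series `"b"` (N-terminal) or `"y"` (C-terminal).
#' @param ordinal Number of residues in the fragment (counted from the
#'   relevant terminus); must be smaller than the peptide length when used.
#' @param charge Fragment charge state, 1-3 (default 1).
#' @return An object of class `fragment_ion`.
#' @examples
#' fragment_ion("b", 11)
#' @export
fragment_ion <- function(series = c("b", "y"), ordinal, charge = 1L) {
  series <- match.arg(series)
  ordinal <- as.integer(ordinal)
  charge <- as.integer(charge)
  if (is.na(ordinal) || ordinal < 1L)
    .stop_invalid("fragment ordinal must be a positive integer")
  if (is.na(charge) || !charge %in% 1:3)
    .stop_invalid("fragment charge must be 1, 2, or 3")
  structure(list(series = series, ordinal = ordinal, charge = charge),
            class = "fragment_ion")
}

#' Parse fragment-ion shorthand
#'
#' Accepts strings like `"b11"`, `"y2"` (singly charged) or `"b12^2"` for a
#' doubly charged b12 ion.
#'
#' @param x Character vector of fragment specs, or a list of
#'   [fragment_ion()] objects (returned unchanged).
#' @return List of `fragment_ion` objects.
#' @examples
#' parse_fragments(c("b11", "y2", "b12^2", "b14"))
#' @export
parse_fragments <- function(x) {
  if (is.list(x) && all(vapply(x, inherits, TRUE, "fragment_ion"))) return(x)
  if (inherits(x, "fragment_ion")) return(list(x))
  m <- regmatches(x, regexec("^([by])([0-9]+)(\\^([0-9]+)\\+?)?$", x))
  lapply(seq_along(x), function(i) {
    g <- m[[i]]
    if (length(g) == 0L)
      .stop_invalid(sprintf("cannot parse fragment spec '%s'", x[i]))
    fragment_ion(g[2], as.integer(g[3]),
                 if (g[5] == "") 1L else as.integer(g[5]))
  })
}

fragment_label <- function(ion) paste0(ion$series, ion$ordinal)

#' m/z of a b or y fragment ion
#'
#' b_n is the sum of the first n residue masses (plus any label shifts whose
#' positions fall in 1..n) plus z protons, divided by z; y_n is the sum of
#' the last n residue masses (plus applicable label shifts) plus water plus
#' z protons, divided by z. A label contributes only when the labeled
#' position lies inside the fragment's span.
#'
#' @param p A [peptide()].
#' @param ion A [fragment_ion()]; `ion$ordinal` must be `< length(p)`.
#' @param conv A [mass_convention()].
#' @return Fragment m/z in Da (unrounded; round only for display).
#' @examples
#' q <- peptide("LGGGPGAGSLQPLALE")
#' fragment_mz(q, fragment_ion("y", 2), mass_convention("average"))
#' @export
fragment_mz <- function(p, ion, conv = mass_convention()) {
  stopifnot(inherits(p, "peptide"), inherits(ion, "fragment_ion"),
            inherits(conv, "mass_convention"))
  n <- nchar(p$sequence)
  if (ion$ordinal >= n)
    .stop_invalid(sprintf("fragment ordinal %d must be below peptide length %d",
                          ion$ordinal, n))
  residues <- strsplit(p$sequence, "", fixed = TRUE)[[1]]
  span <- if (ion$series == "b") seq_len(ion$ordinal)
          else seq.int(n - ion$ordinal + 1L, n)
  labs <- p$labels[p$labels$position %in% span, , drop = FALSE]
  m <- sum(conv$residue_table[residues[span]]) + .label_shift_sum(labs, conv)
  if (ion$series == "y") m <- m + conv$water_mass
  (m + ion$charge * conv$proton_mass) / ion$charge
}

#' Precursor m/z of a peptide
#'
#' @param p A [peptide()].
#' @param charge Precursor charge state.
#' @param conv A [mass_convention()].
#' @return `(neutral mass + charge * proton) / charge` in Da.
#' @export
precursor_mz <- function(p, charge = 2L, conv = mass_convention()) {
  charge <- as.integer(charge)
  if (is.na(charge) || charge < 1L)
    .stop_invalid("precursor charge must be a positive integer")
  (peptide_mass(p, conv) + charge * conv$proton_mass) / charge
}
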