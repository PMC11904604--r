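#' Build an MRM transition table for a native/labeled peptide pair
#'
#' Emits one native-channel and one labeled-channel transition per fragment
#' ion: Q1 is the precursor m/z of the channel's peptide at
#' `precursor_charge`, Q3 the fragment m/z. Exactly one fragment per
#' channel is assigned the `quantifier` role; the rest are `qualifier`s
#' monitored for identity confirmation.
#'
#' @param native,labeled [peptide()]s sharing the same sequence; `labeled`
#'   carries the isotope labels.
#' @param fragments List of [fragment_ion()]s (or shorthand accepted by
#'   [parse_fragments()]).
#' @param precursor_charge Precursor charge state (default 2).
#' @param conv A [mass_convention()].
#' @param quantifier The [fragment_ion()] to mark as quantifier; must be
#'   one of `fragments`.
#' @return Data frame with columns `transition_id, channel, sequence,
#'   labels, precursor_charge, series, ordinal, fragment_charge, q1_mz,
#'   q3_mz, role`. Transition ids are `<channel>_<series><ordinal>`.
#' @examples
#' build_transition_table(
#'   quantitation_peptide(), quantitation_peptide(labeled = TRUE),
#'   parse_fragments(c("b11", "y2")), quantifier = fragment_ion("b", 11))
#' @export
build_transition_table <- function(native, labeled, fragments,
                                   precursor_charge = 2L,
                                   conv = mass_convention(),
                                   quantifier) {
  stopifnot(inherits(native, "peptide"), inherits(labeled, "peptide"))
  if (native$sequence != labeled$sequence)
    .stop_invalid("native and labeled peptides must share the same sequence")
  fragments <- parse_fragments(fragments)
  if (length(fragments) == 0L) return(.empty_transition_table())
  quantifier <- parse_fragments(list(quantifier))[[1]]
  is_quant <- vapply(fragments, function(f)
    identical(unclass(f), unclass(quantifier)), TRUE)
  if (sum(is_quant) != 1L)
    .stop_invalid("quantifier must match exactly one entry of fragments")
  channels <- list(native = native, labeled = labeled)
  rows <- list()
  for (ch in names(channels)) {
    p <- channels[[ch]]
    q1 <- precursor_mz(p, precursor_charge, conv)
    for (i in seq_along(fragments)) {
      f <- fragments[[i]]
      rows[[length(rows) + 1L]] <- data.frame(
        transition_id = paste(ch, fragment_label(f), sep = "_"),
        channel = ch,
        sequence = p$sequence,
        labels = .format_labels(p$labels),
        precursor_charge = as.integer(precursor_charge),
        series = f$series,
        ordinal = f$ordinal,
        fragment_charge = f$charge,
        q1_mz = q1,
        q3_mz = fragment_mz(p, f, conv),
        role = if (is_quant[i]) "quantifier" else "qualifier",
        stringsAsFactors = FALSE)
    }
  }
  do.call(rbind, rows)
}

.format_labels <- function(labels) {
  if (!nrow(labels)) return("")
  paste(sprintf("%d:%s", labels$position, labels$kind), collapse = ";")
}

.empty_transition_table <- function() {
  data.frame(transition_id = character(), channel = character(),
             sequence = character(), labels = character(),
             precursor_charge = integer(), series = character(),
             ordinal = integer(), fragment_charge = integer(),
             q1_mz = numeric(), q3_mz = numeric(), role = character(),
             stringsAsFactors = FALSE)
}

.transition_columns <- c("transition_id", "channel", "sequence", "labels",
                         "precursor_charge", "series", "ordinal",
                         "fragment_charge", "q1_mz", "q3_mz", "role")

#' Write / read a transition table CSV
#'
#' The on-disk schema is
#' `channel,sequence,labels,precursor_charge,series,ordinal,fragment_charge,q1_mz,q3_mz,role`
#' (plus a `transition_id` column), UTF-8, header required. Labels are
#' encoded `pos:kind`, semicolon-separated.
#'
#' @param transitions Transition table data frame.
#' @param path File path.
#' @param ... Passed to [write_assay_csv()] (e.g. `header_comment`).
#' @return `read_transition_table()` returns the table; the writer returns
#'   `path` invisibly.
#' @export
write_transition_table <- function(transitions, path, ...) {
  .check_columns(transitions, .transition_columns, "transition table")
  write_assay_csv(transitions, path, ...)
}

#' @rdname write_transition_table
#' @export
read_transition_table <- function(path) {
  df <- read_assay_csv(path, required = .transition_columns,
                       numeric_cols = c("precursor_charge", "ordinal",
                                        "fragment_charge", "q1_mz", "q3_mz"))
  df
}
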