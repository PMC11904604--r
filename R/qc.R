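#' Qualifier-ion ratio specification
#'
#' The identity check of the assay monitors four area ratios among the b11
#' quantifier and the y2, b14 and b12 qualifier ions. The defaults are the
#' assay's established means and SDs: b11/y2 = 2.62 (0.39), y2/b14 = 1.09
#' (0.17), b14/b12 = 0.87 (0.16), b12/b11 = 0.43 (0.10). A sample's ratio
#' is acceptable when its z-score against the mean is within
#' `tolerance_multiplier` SDs.
#'
#' Note the four ratios telescope: their product is exactly 1 for any
#' single sample, whereas the product of the four means is ~1.07 (means of
#' ratios are not ratios of means), so no sample can sit exactly on all
#' four means at once.
#'
#' @param ratios Data frame with columns `numerator`, `denominator`,
#'   `mean`, `sd` (one row per monitored ratio, in reporting order).
#' @param tolerance_multiplier Acceptance band in SD units (default 3).
#' @return An object of class `ion_ratio_spec`.
#' @export
ion_ratio_spec <- function(ratios = NULL, tolerance_multiplier = 3) {
  if (is.null(ratios))
    ratios <- data.frame(
      numerator   = c("b11", "y2", "b14", "b12"),
      denominator = c("y2", "b14", "b12", "b11"),
      mean = c(2.62, 1.09, 0.87, 0.43),
      sd   = c(0.39, 0.17, 0.16, 0.10),
      stringsAsFactors = FALSE)
  .check_columns(ratios, c("numerator", "denominator", "mean", "sd"),
                 "ion ratio spec")
  if (any(ratios$sd <= 0) || any(ratios$mean <= 0))
    .stop_invalid("ratio means and SDs must be positive")
  if (tolerance_multiplier <= 0)
    .stop_invalid("tolerance_multiplier must be positive")
  structure(list(ratios = ratios,
                 tolerance_multiplier = tolerance_multiplier),
            class = "ion_ratio_spec")
}

#' Monitored qualifier-ion ratios of one sample
#'
#' @param areas Named numeric vector of fragment areas (names `b11`, `y2`,
#'   `b14`, `b12`, ...).
#' @param spec An [ion_ratio_spec()] defining which ratios to form and in
#'   what order.
#' @return Numeric vector of ratios in the spec's order, named
#'   `<num>_<den>`; a missing or non-positive denominator yields `NA`
#'   (ratio unavailable) rather than an error.
#' @examples
#' ion_ratios(c(b11 = 262, y2 = 100, b14 = 91.7, b12 = 112.7))
#' @export
ion_ratios <- function(areas, spec = ion_ratio_spec()) {
  stopifnot(inherits(spec, "ion_ratio_spec"))
  r <- spec$ratios
  out <- vapply(seq_len(nrow(r)), function(i) {
    num <- areas[[r$numerator[i]]] %||% NA_real_
    den <- areas[[r$denominator[i]]] %||% NA_real_
    if (!is.finite(den) || den <= 0 || !is.finite(num)) NA_real_
    else num / den
  }, numeric(1))
  names(out) <- paste(r$numerator, r$denominator, sep = "_")
  out
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Per-sample quality-control evaluation
#'
#' Applies the assay's acceptance checks to one sample's integrated peaks:
#' every monitored apex (both channels) must fall inside the
#' retention-time window; each qualifier ratio's z-score against the
#' established mean must be within the tolerance multiplier; and the
#' labeled quantifier (internal standard) must be present. Failures are
#' expressed as report flags, never exceptions: per the assay's practice,
#' ratio deviations trigger review, not automatic batch rejection.
#'
#' @param peaks Named list of [find_peak()] results (or lists with `apex_rt`
#'   and `area`), keyed `<channel>_<fragment>`, e.g. `native_b11`. Ratios
#'   are computed on the native channel; the labeled quantifier is used for
#'   the internal-standard presence check.
#' @param spec An [ion_ratio_spec()].
#' @param rt_window Numeric pair `(lo, hi)` minutes (default
#'   `c(11.4, 11.7)`, the assay's elution window).
#' @param quantifier Quantifier fragment name (default `"b11"`).
#' @param sample_id Identifier carried into the report.
#' @param low_signal If `TRUE`, the sample is known to sit below the LLOQ;
#'   undefined ratios then emit a "low-signal" message instead of failing
#'   `ratio_ok`.
#' @return A list of class `qc_report`: `sample_id`, `rt_ok`, `ratio_z`
#'   (named numeric), `ratio_ok`, `is_present`, `overall_pass`, `messages`.
#'   `overall_pass` is the conjunction of the three checks.
#' @export
evaluate_qc <- function(peaks, spec = ion_ratio_spec(),
                        rt_window = c(11.4, 11.7), quantifier = "b11",
                        sample_id = "sample", low_signal = FALSE) {
  stopifnot(inherits(spec, "ion_ratio_spec"))
  messages <- character()
  apexes <- vapply(peaks, function(p) p$apex_rt, numeric(1))
  rt_ok <- all(apexes >= rt_window[1] & apexes <= rt_window[2])
  if (!rt_ok)
    messages <- c(messages, sprintf(
      "apex outside %.2f-%.2f min window: %s", rt_window[1], rt_window[2],
      paste(names(apexes)[apexes < rt_window[1] | apexes > rt_window[2]],
            collapse = ", ")))
  native_names <- grep("^native_", names(peaks), value = TRUE)
  areas <- stats::setNames(
    vapply(peaks[native_names], function(p) p$area, numeric(1)),
    sub("^native_", "", native_names))
  obs <- ion_ratios(as.list(areas), spec)
  z <- (obs - spec$ratios$mean) / spec$ratios$sd
  undefined <- !is.finite(obs)
  if (any(undefined)) {
    if (low_signal) {
      messages <- c(messages,
                    "low-signal: qualifier ratio(s) unavailable below LLOQ")
      ratio_ok <- all(abs(z[!undefined]) <= spec$tolerance_multiplier)
    } else {
      messages <- c(messages, sprintf("ratio(s) undefined: %s",
                                      paste(names(obs)[undefined],
                                            collapse = ", ")))
      ratio_ok <- FALSE
    }
  } else {
    ratio_ok <- all(abs(z) <= spec$tolerance_multiplier)
  }
  if (!ratio_ok && !any(undefined))
    messages <- c(messages, sprintf(
      "ratio z-score beyond %.1f SD: %s", spec$tolerance_multiplier,
      paste(names(z)[abs(z) > spec$tolerance_multiplier], collapse = ", ")))
  lab_q <- peaks[[paste0("labeled_", quantifier)]]
  is_present <- !is.null(lab_q) && is.finite(lab_q$area) && lab_q$area > 0
  if (!is_present)
    messages <- c(messages, "internal standard quantifier absent")
  structure(list(sample_id = sample_id, rt_ok = rt_ok, ratio_z = z,
                 ratio_ok = ratio_ok, is_present = is_present,
                 overall_pass = rt_ok && ratio_ok && is_present,
                 messages = messages),
            class = "qc_report")
}

#' @export
print.qc_report <- function(x, ...) {
  cat(sprintf("<qc %s: rt %s, ratios %s, IS %s => %s>\n", x$sample_id,
              x$rt_ok, x$ratio_ok, x$is_present,
              if (x$overall_pass) "PASS" else "REVIEW"))
  if (length(x$messages)) cat(paste0("  - ", x$messages, "\n"), sep = "")
  invisible(x)
}

#' Blank carryover check
#'
#' Blanks are run before low-concentration samples to guard against
#' carryover. The blank's quantifier area must not exceed `max_fraction` of
#' a reference sample's area (boundary inclusive).
#'
#' @param blank_area Quantifier area measured in the blank.
#' @param reference_area Quantifier area of the reference sample (> 0).
#' @param max_fraction Maximum acceptable blank/reference fraction
#'   (default 0.2).
#' @return `TRUE` if the blank is acceptable.
#' @export
blank_check <- function(blank_area, reference_area, max_fraction = 0.2) {
  if (!is.finite(reference_area) || reference_area <= 0)
    .stop_invalid("reference_area must be positive")
  blank_area / reference_area <= max_fraction
}

#' Flatten QC reports into the report table
#'
#' @param reports List of `qc_report` objects from [evaluate_qc()].
#' @return Data frame with one row per sample: `sample_id, rt_ok`, one
#'   `z_<num>_<den>` column per monitored ratio, `ratio_ok, is_present,
#'   overall_pass, messages` (semicolon-joined).
#' @export
qc_report_table <- function(reports) {
  rows <- lapply(reports, function(r) {
    z <- as.list(r$ratio_z)
    names(z) <- paste0("z_", names(r$ratio_z))
    cbind(data.frame(sample_id = r$sample_id, rt_ok = r$rt_ok,
                     stringsAsFactors = FALSE),
          as.data.frame(z),
          data.frame(ratio_ok = r$ratio_ok, is_present = r$is_present,
                     overall_pass = r$overall_pass,
                     messages = paste(r$messages, collapse = "; "),
                     stringsAsFactors = FALSE))
  })
  do.call(rbind, rows)
}
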