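#' Native/labeled response ratio
#'
#' The isotope-dilution measurement signal: the ratio of the native
#' quantifier peak area to the labeled (internal standard) quantifier peak
#' area. Because both species co-elute and share preparation, ionization and
#' matrix effects, the ratio is robust to everything that scales both
#' channels together.
#'
#' @param native_area Native quantifier area (>= 0).
#' @param labeled_area Labeled quantifier area (> 0).
#' @return `native_area / labeled_area`.
#' @export
response_ratio <- function(native_area, labeled_area) {
  if (any(labeled_area <= 0))
    stop(errorCondition(
      "internal standard signal absent: labeled quantifier area must be > 0",
      class = c("mrmquant_is_failure", "mrmquant_error")))
  if (any(native_area < 0))
    .stop_invalid("native area must be non-negative")
  native_area / labeled_area
}

#' Fit a calibration curve of response ratio on molar ratio
#'
#' Ordinary least squares of the measured response ratio on the gravimetric
#' native:labeled molar ratio of CRM-traceable calibrators. The routine
#' two-point design (molar ratios 1:1 and 1:6) yields an exact line through
#' both points; a matrix-matched multi-point design is fitted the same way.
#'
#' @param points Data frame with columns `molar_ratio` and
#'   `response_ratio`, both positive; at least two distinct molar ratios.
#' @return An object of class `calibration_curve`: `slope`, `intercept`,
#'   `n_points`, `r_squared` (exactly 1 for two points).
#' @examples
#' fit_calibration(data.frame(molar_ratio = c(1, 6),
#'                            response_ratio = c(0.9, 5.9)))
#' @export
fit_calibration <- function(points) {
  if (!is.data.frame(points) ||
      !all(c("molar_ratio", "response_ratio") %in% names(points)))
    .stop_invalid("points needs columns 'molar_ratio' and 'response_ratio'")
  if (length(unique(points$molar_ratio)) < 2L)
    .stop_invalid("calibration needs at least 2 distinct molar ratios")
  if (any(points$molar_ratio <= 0) || any(points$response_ratio <= 0))
    .stop_invalid("calibration ratios must be positive")
  fit <- stats::lm(response_ratio ~ molar_ratio, data = points)
  r2 <- if (nrow(points) == 2L) 1 else
    stats::cor(points$molar_ratio, points$response_ratio)^2
  structure(list(slope = unname(stats::coef(fit)[2]),
                 intercept = unname(stats::coef(fit)[1]),
                 n_points = nrow(points), r_squared = r2),
            class = "calibration_curve")
}

#' @export
print.calibration_curve <- function(x, ...) {
  cat(sprintf(
    "<calibration: rr = %.4f * ratio + %.4f; n = %d, r^2 = %.5f>\n",
    x$slope, x$intercept, x$n_points, x$r_squared))
  invisible(x)
}

#' Assay parameters for the concentration calculation
#'
#' The numeric constants of the wet protocol that convert a molar ratio to
#' a serum concentration: spike volume and concentration of the labeled
#' internal standard, serum sample volume, and the molecular weight of the
#' labeled material. The default molecular weight is computed from the
#' intact labeled C-peptide (average masses, two 13C6 labels), since the
#' internal standard is spiked as the intact polypeptide before digestion.
#'
#' @param spike_volume_mL Internal-standard spike volume, mL (default
#'   0.020).
#' @param spike_concentration_g_mL Spike concentration, g/mL (default
#'   1e-7).
#' @param sample_volume_mL Serum volume, mL (default 0.200).
#' @param labeled_mw_g_mol Molecular weight of the labeled material, g/mol;
#'   default the intact labeled C-peptide average mass (~3032.2). Pass the
#'   released labeled peptide mass instead to base moles on the digestion
#'   product.
#' @return An object of class `assay_parameters`.
#' @export
assay_parameters <- function(spike_volume_mL = 0.020,
                             spike_concentration_g_mL = 1e-7,
                             sample_volume_mL = 0.200,
                             labeled_mw_g_mol = NULL) {
  if (is.null(labeled_mw_g_mol))
    labeled_mw_g_mol <- peptide_mass(cpeptide_labeled(),
                                     mass_convention("average"))
  vals <- c(spike_volume_mL, spike_concentration_g_mL, sample_volume_mL,
            labeled_mw_g_mol)
  if (any(!is.finite(vals)) || any(vals <= 0))
    .stop_invalid("all assay parameters must be positive")
  structure(list(spike_volume_mL = spike_volume_mL,
                 spike_concentration_g_mL = spike_concentration_g_mL,
                 sample_volume_mL = sample_volume_mL,
                 labeled_mw_g_mol = labeled_mw_g_mol),
            class = "assay_parameters")
}

#' Concentration-equivalent of the internal-standard spike
#'
#' Moles of labeled C-peptide spiked, expressed as a concentration in the
#' serum sample volume: `spike_volume * spike_concentration / labeled_mw /
#' sample_volume`, in nmol/L. With the default parameters (2 ng into 0.2
#' mL) this is ~3.30 nmol/L, so a sample at molar ratio 1 reads ~3.30
#' nmol/L.
#'
#' @param params An [assay_parameters()].
#' @return nmol/L.
#' @export
labeled_equiv_concentration <- function(params = assay_parameters()) {
  stopifnot(inherits(params, "assay_parameters"))
  moles <- params$spike_volume_mL * params$spike_concentration_g_mL /
    params$labeled_mw_g_mol
  moles / (params$sample_volume_mL / 1000) * 1e9
}

#' Convert response ratios to serum concentrations
#'
#' Inverse prediction through the calibration curve: `molar_ratio = (rr -
#' intercept) / slope`, then `concentration = molar_ratio *` the
#' internal-standard concentration-equivalent (see
#' [labeled_equiv_concentration()]). Negative back-calculated ratios (blank
#' samples with baseline noise) are floored at zero and flagged rather than
#' raising an error.
#'
#' @param rr Numeric vector of response ratios.
#' @param curve A [calibration_curve][fit_calibration()] with positive
#'   slope.
#' @param params An [assay_parameters()].
#' @return Data frame with columns `response_ratio`, `molar_ratio`,
#'   `concentration_nmol_L`, `flag_negative_ratio`.
#' @examples
#' curve <- fit_calibration(data.frame(molar_ratio = c(1, 6),
#'                                     response_ratio = c(1, 6)))
#' quantify(1.0, curve)
#' @export
quantify <- function(rr, curve, params = assay_parameters()) {
  stopifnot(inherits(curve, "calibration_curve"))
  if (!is.finite(curve$slope) || curve$slope <= 0)
    stop(errorCondition("calibration curve unusable: slope must be > 0",
                        class = c("mrmquant_unusable_curve", "mrmquant_error")))
  ratio <- (rr - curve$intercept) / curve$slope
  flagged <- ratio < 0
  ratio[flagged] <- 0
  conc <- ratio * labeled_equiv_concentration(params)
  data.frame(response_ratio = rr, molar_ratio = ratio,
             concentration_nmol_L = conc, flag_negative_ratio = flagged)
}

#' Quantify a batch of integrated samples
#'
#' Takes per-sample quantifier areas for both channels, forms response
#' ratios, and converts them to concentrations. Samples whose internal
#' standard is absent get `NA` concentration and `qc_pass = FALSE` instead
#' of aborting the batch.
#'
#' @param areas Data frame with columns `sample_id`, `native_area`,
#'   `labeled_area` (quantifier transition areas).
#' @param curve A calibration curve from [fit_calibration()].
#' @param params An [assay_parameters()].
#' @return Data frame `sample_id, response_ratio, molar_ratio,
#'   concentration_nmol_L, qc_pass, flags`.
#' @export
quantify_batch <- function(areas, curve, params = assay_parameters()) {
  .check_columns(areas, c("sample_id", "native_area", "labeled_area"),
                 "area table")
  out <- lapply(seq_len(nrow(areas)), function(i) {
    row <- areas[i, ]
    if (!is.finite(row$labeled_area) || row$labeled_area <= 0) {
      return(data.frame(sample_id = row$sample_id, response_ratio = NA_real_,
                        molar_ratio = NA_real_,
                        concentration_nmol_L = NA_real_, qc_pass = FALSE,
                        flags = "internal-standard-failure",
                        stringsAsFactors = FALSE))
    }
    q <- quantify(response_ratio(row$native_area, row$labeled_area), curve,
                  params)
    data.frame(sample_id = row$sample_id, response_ratio = q$response_ratio,
               molar_ratio = q$molar_ratio,
               concentration_nmol_L = q$concentration_nmol_L,
               qc_pass = TRUE,
               flags = if (q$flag_negative_ratio) "negative-ratio-floored"
                       else "",
               stringsAsFactors = FALSE)
  })
  do.call(rbind, out)
}
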