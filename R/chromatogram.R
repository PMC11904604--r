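#' Default per-transition relative responses
#'
#' Fragment-ion responses relative to the b11 quantifier, chosen so that the
#' simulated qualifier ratios b11/y2 and y2/b14 and b14/b12 sit at the
#' assay's established ion-ratio means (the fourth ratio, b12/b11, is then
#' fixed by the telescoping identity and lands well within its tolerance).
#'
#' @return Named numeric vector over fragments `b11, y2, b12, b14`.
#' @export
default_relative_responses <- function() {
  y2 <- 1 / 2.62
  b14 <- y2 / 1.09
  b12 <- b14 / 0.87
  c(b11 = 1, y2 = y2, b12 = b12, b14 = b14)
}

#' Specify a synthetic MRM acquisition
#'
#' Defines the conditions under which [simulate_chromatograms()] draws
#' co-eluting Gaussian native/labeled transition traces. Peak areas are
#' proportional to concentration, relative fragment response and any
#' channel-selective suppression factor; a single multiplicative lognormal
#' perturbation per channel (CV `noise_cv`) emulates preparation and
#' ionization variability shared by a channel's transitions, and additive
#' Gaussian baseline noise (`baseline_sd`) emulates detector noise, which
#' dominates and inflates the CV at low concentration.
#'
#' @param transitions Named numeric vector of relative responses per
#'   transition id (ids of the form `<channel>_<fragment>`, e.g.
#'   `native_b11`), or a transition table data frame from
#'   [build_transition_table()], in which case
#'   [default_relative_responses()] are applied per fragment. Default: the
#'   canonical eight C-peptide transitions.
#' @param apex_rt Peak apex retention time, minutes (default 11.55, the
#'   center of the assay's acceptance window).
#' @param peak_sigma Gaussian peak width (standard deviation), minutes
#'   (default 0.05).
#' @param native_concentration Native C-peptide concentration, nmol/L
#'   (default 1.58, a mid-range serum level).
#' @param labeled_amount_response Integrated area of the labeled quantifier
#'   at relative response 1, counts*min (default 1000).
#' @param labeled_equiv_nmol_L Concentration-equivalent of the internal
#'   standard spike in the sample, nmol/L; defaults to the value implied by
#'   [assay_parameters()] (2 ng of labeled C-peptide in 0.2 mL). The true
#'   simulated molar ratio is `native_concentration / labeled_equiv_nmol_L`.
#' @param noise_cv Coefficient of variation of the per-channel lognormal
#'   area perturbation (default 0); must be < 1.
#' @param baseline_sd Additive baseline noise SD, counts (default 0).
#' @param suppression Named numeric vector of factors in (0, 1] applied to
#'   individual transitions to emulate matrix suppression (default none).
#' @param rt_range Sampling window, minutes (default `c(11.0, 12.2)`;
#'   widened automatically to cover `apex_rt` +/- 6 sigma).
#' @param dwell Sampling interval, minutes (default 0.02, i.e. 1.2 s).
#' @param seed Integer seed; all stochastic draws flow from it.
#' @return An object of class `simulation_spec`.
#' @export
simulation_spec <- function(transitions = cpeptide_transitions(),
                            apex_rt = 11.55, peak_sigma = 0.05,
                            native_concentration = 1.58,
                            labeled_amount_response = 1000,
                            labeled_equiv_nmol_L = NULL,
                            noise_cv = 0, baseline_sd = 0,
                            suppression = NULL,
                            rt_range = c(11.0, 12.2), dwell = 0.02,
                            seed = 1L) {
  if (is.data.frame(transitions)) {
    rel <- default_relative_responses()
    frag <- paste0(transitions$series, transitions$ordinal)
    unknown <- setdiff(frag, names(rel))
    if (length(unknown))
      .stop_invalid(sprintf(
        "no default relative response for fragment(s) %s; pass a named vector",
        paste(unique(unknown), collapse = ", ")))
    transitions <- stats::setNames(rel[frag], transitions$transition_id)
  }
  if (is.null(names(transitions)) || any(!nzchar(names(transitions))))
    .stop_invalid("transitions must be a named numeric vector")
  if (any(transitions <= 0))
    .stop_invalid("relative responses must be positive")
  if (!all(grepl("^(native|labeled)_", names(transitions))))
    .stop_invalid("transition ids must start with 'native_' or 'labeled_'")
  if (peak_sigma <= 0) .stop_invalid("peak_sigma must be positive")
  if (noise_cv < 0 || noise_cv >= 1)
    .stop_invalid("noise_cv must be in [0, 1)")
  if (baseline_sd < 0) .stop_invalid("baseline_sd must be non-negative")
  if (native_concentration < 0)
    .stop_invalid("native_concentration must be non-negative")
  if (labeled_amount_response <= 0)
    .stop_invalid("labeled_amount_response must be positive")
  if (is.null(labeled_equiv_nmol_L))
    labeled_equiv_nmol_L <- labeled_equiv_concentration(assay_parameters())
  supp <- rep(1, length(transitions))
  names(supp) <- names(transitions)
  if (!is.null(suppression)) {
    if (any(suppression <= 0 | suppression > 1))
      .stop_invalid("suppression factors must be in (0, 1]")
    unknown <- setdiff(names(suppression), names(transitions))
    if (length(unknown))
      .stop_invalid(sprintf("suppression names not in transitions: %s",
                            paste(unknown, collapse = ", ")))
    supp[names(suppression)] <- suppression
  }
  rt_range <- c(min(rt_range[1], apex_rt - 6 * peak_sigma),
                max(rt_range[2], apex_rt + 6 * peak_sigma))
  structure(list(transitions = transitions, apex_rt = apex_rt,
                 peak_sigma = peak_sigma,
                 native_concentration = native_concentration,
                 labeled_amount_response = labeled_amount_response,
                 labeled_equiv_nmol_L = labeled_equiv_nmol_L,
                 noise_cv = noise_cv, baseline_sd = baseline_sd,
                 suppression = supp, rt_range = rt_range, dwell = dwell,
                 seed = as.integer(seed)),
            class = "simulation_spec")
}

#' Simulate MRM chromatograms
#'
#' Draws one trace per transition in `spec`: a Gaussian peak of area
#' `labeled_amount_response * relative_response * suppression` for the
#' labeled channel, scaled additionally by the molar ratio
#' `native_concentration / labeled_equiv_nmol_L` for the native channel,
#' perturbed by one lognormal area factor per channel (mean 1, CV
#' `noise_cv`) and additive baseline noise; intensities are clipped at zero.
#' Identical specs (including seed) give bit-identical traces.
#'
#' @param spec A [simulation_spec()].
#' @return Long data frame with columns `transition_id, time_min,
#'   intensity`; time is a regular grid of spacing `spec$dwell` over
#'   `spec$rt_range`.
#' @examples
#' traces <- simulate_chromatograms(simulation_spec(noise_cv = 0))
#' head(traces)
#' @export
simulate_chromatograms <- function(spec) {
  stopifnot(inherits(spec, "simulation_spec"))
  set.seed(spec$seed)
  tgrid <- seq(spec$rt_range[1], spec$rt_range[2], by = spec$dwell)
  molar_ratio <- spec$native_concentration / spec$labeled_equiv_nmol_L
  # one shared multiplicative draw per channel
  chan_factor <- c(native = 1, labeled = 1)
  if (spec$noise_cv > 0) {
    sdlog <- sqrt(log(1 + spec$noise_cv^2))
    chan_factor <- stats::setNames(
      stats::rlnorm(2, meanlog = -sdlog^2 / 2, sdlog = sdlog),
      c("native", "labeled"))
  }
  shape <- exp(-(tgrid - spec$apex_rt)^2 / (2 * spec$peak_sigma^2))
  amp_unit <- 1 / (spec$peak_sigma * sqrt(2 * pi))
  out <- vector("list", length(spec$transitions))
  ids <- names(spec$transitions)
  for (i in seq_along(ids)) {
    id <- ids[i]
    channel <- sub("_.*$", "", id)
    area <- spec$labeled_amount_response * spec$transitions[[id]] *
      spec$suppression[[id]]
    if (channel == "native") area <- area * molar_ratio
    area <- area * chan_factor[[channel]]
    intensity <- area * amp_unit * shape
    if (spec$baseline_sd > 0)
      intensity <- intensity + stats::rnorm(length(tgrid), 0, spec$baseline_sd)
    intensity <- pmax(intensity, 0)
    out[[i]] <- data.frame(transition_id = id, time_min = tgrid,
                           intensity = intensity, stringsAsFactors = FALSE)
  }
  do.call(rbind, out)
}

.check_trace <- function(trace) {
  if (!is.data.frame(trace) ||
      !all(c("time_min", "intensity") %in% names(trace)))
    .stop_invalid("a trace needs columns 'time_min' and 'intensity'")
  if (nrow(trace) < 2L) .stop_invalid("a trace needs at least 2 points")
  if (any(diff(trace$time_min) <= 0))
    .stop_invalid("trace time must be strictly increasing")
  trace
}

#' Locate a peak inside a retention-time window
#'
#' The apex is the maximum intensity inside the window. Bounds extend
#' outward from the apex to the first local minimum or to the first point
#' where intensity falls below 1% of the apex height, whichever comes
#' first. The area is the trapezoidal integral between the bounds.
#'
#' @param trace Data frame with columns `time_min`, `intensity` (one
#'   transition's trace).
#' @param rt_window Numeric pair `(lo, hi)` minutes, inside the trace range.
#' @param height_floor_frac Fraction of apex height at which a bound is
#'   drawn (default 0.01).
#' @return A list of class `mrm_peak`: `apex_rt`, `left_bound`,
#'   `right_bound`, `area` (counts*min), `height` (counts). An all-zero
#'   window returns a zero-area peak with apex at the window midpoint.
#' @export
find_peak <- function(trace, rt_window, height_floor_frac = 0.01) {
  trace <- .check_trace(trace)
  if (length(rt_window) != 2L || rt_window[1] >= rt_window[2])
    .stop_invalid("rt_window must be (lo, hi) with lo < hi")
  inside <- which(trace$time_min >= rt_window[1] &
                  trace$time_min <= rt_window[2])
  if (length(inside) == 0L)
    .stop_not_found("no sample points inside the retention-time window")
  apex_i <- inside[which.max(trace$intensity[inside])]
  height <- trace$intensity[apex_i]
  if (height <= 0) {
    mid <- mean(rt_window)
    return(structure(list(apex_rt = mid, left_bound = rt_window[1],
                          right_bound = rt_window[2], area = 0,
                          height = 0), class = "mrm_peak"))
  }
  floor_h <- height_floor_frac * height
  y <- trace$intensity
  left <- apex_i
  while (left > 1L) {
    if (y[left] <= floor_h) break
    if (y[left - 1L] > y[left]) break    # valley: next-outward point rises
    left <- left - 1L
  }
  right <- apex_i
  n <- nrow(trace)
  while (right < n) {
    if (y[right] <= floor_h) break
    if (y[right + 1L] > y[right]) break
    right <- right + 1L
  }
  bounds <- c(trace$time_min[left], trace$time_min[right])
  structure(list(apex_rt = trace$time_min[apex_i],
                 left_bound = bounds[1], right_bound = bounds[2],
                 area = integrate_peak(trace, bounds), height = height),
            class = "mrm_peak")
}

#' @export
print.mrm_peak <- function(x, ...) {
  cat(sprintf("<peak: apex %.3f min [%.3f, %.3f], area %.4g, height %.4g>\n",
              x$apex_rt, x$left_bound, x$right_bound, x$area, x$height))
  invisible(x)
}

#' Trapezoidal peak integration
#'
#' Integrates a trace's intensity over `[lo, hi]` by the trapezoid rule,
#' interpolating linearly at the bounds if they fall between samples.
#'
#' @param trace Data frame with columns `time_min`, `intensity`.
#' @param bounds Numeric pair `(lo, hi)` with `lo <= hi`, inside the trace
#'   time range.
#' @return Area in counts*min (0 for zero-width bounds).
#' @export
integrate_peak <- function(trace, bounds) {
  trace <- .check_trace(trace)
  if (length(bounds) != 2L || bounds[1] > bounds[2])
    .stop_invalid("bounds must be (lo, hi) with lo <= hi")
  lo <- bounds[1]; hi <- bounds[2]
  rng <- range(trace$time_min)
  if (lo < rng[1] || hi > rng[2])
    .stop_invalid("integration bounds outside the trace time range")
  if (lo == hi) return(0)
  keep <- trace$time_min > lo & trace$time_min < hi
  tt <- c(lo, trace$time_min[keep], hi)
  yy <- c(stats::approx(trace$time_min, trace$intensity, lo)$y,
          trace$intensity[keep],
          stats::approx(trace$time_min, trace$intensity, hi)$y)
  sum(diff(tt) * (utils::head(yy, -1L) + utils::tail(yy, -1L)) / 2)
}

#' Integrate every transition of a long chromatogram table
#'
#' Convenience wrapper: splits a long chromatogram data frame by
#' `transition_id`, runs [find_peak()] on each, and returns areas and
#' apexes.
#'
#' @param traces Long data frame (`transition_id, time_min, intensity`).
#' @param rt_window Retention-time window passed to [find_peak()].
#' @return Data frame with one row per transition: `transition_id,
#'   apex_rt, area, height`.
#' @export
integrate_chromatograms <- function(traces, rt_window) {
  pieces <- split(traces, traces$transition_id)
  rows <- lapply(names(pieces), function(id) {
    pk <- find_peak(pieces[[id]], rt_window)
    data.frame(transition_id = id, apex_rt = pk$apex_rt, area = pk$area,
               height = pk$height, stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}
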