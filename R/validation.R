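#' Precision variance components by one-way ANOVA
#'
#' Implements the CLSI EP15-A3 decomposition of a balanced day-by-replicate
#' precision experiment. With d days and n replicates per day:
#' `MS_within = sum((x - day mean)^2) / (d (n - 1))`,
#' `MS_between = n * sum((day mean - grand mean)^2) / (d - 1)`,
#' within-day variance `V_w = MS_within`, between-day component
#' `V_b = max((MS_between - MS_within) / n, 0)` (negative estimates
#' truncated to zero, the standard handling), total `V_t = V_w + V_b`.
#' CVs are `100 * sqrt(V) / grand mean`: "intra-day" is repeatability,
#' "inter-day" the between-day component, "total" the within-laboratory
#' precision, so `cv_total^2 = cv_intraday^2 + cv_interday^2` by
#' construction.
#'
#' @param panel Numeric matrix of concentrations (nmol/L), rows = days,
#'   columns = replicates; or a data frame with columns `day`, `replicate`,
#'   `concentration_nmol_L` describing a balanced design.
#' @return A list of class `precision_result`: `grand_mean`, `cv_intraday`,
#'   `cv_interday`, `cv_total` (all %), and `variance_components`
#'   (`within`, `between`).
#' @examples
#' set.seed(1)
#' panel <- matrix(2.88 * (1 + rnorm(25, 0, 0.08)), nrow = 5)
#' precision_anova(panel)
#' @export
precision_anova <- function(panel) {
  if (is.data.frame(panel)) panel <- .panel_to_matrix(panel)
  if (!is.matrix(panel) || !is.numeric(panel))
    .stop_invalid("panel must be a numeric day x replicate matrix")
  if (anyNA(panel))
    .stop_invalid("panel must be complete (balanced design required)")
  d <- nrow(panel); n <- ncol(panel)
  if (d < 2L || n < 2L)
    .stop_invalid("panel needs at least 2 days and 2 replicates")
  grand <- mean(panel)
  if (grand == 0)
    stop(errorCondition("grand mean is zero: CV undefined",
                        class = c("mrmquant_undefined_cv", "mrmquant_error")))
  day_means <- rowMeans(panel)
  ms_within <- sum((panel - day_means)^2) / (d * (n - 1))
  ms_between <- n * sum((day_means - grand)^2) / (d - 1)
  v_within <- ms_within
  v_between <- max((ms_between - ms_within) / n, 0)
  v_total <- v_within + v_between
  structure(list(grand_mean = grand,
                 cv_intraday = 100 * sqrt(v_within) / grand,
                 cv_interday = 100 * sqrt(v_between) / grand,
                 cv_total = 100 * sqrt(v_total) / grand,
                 variance_components = c(within = v_within,
                                         between = v_between)),
            class = "precision_result")
}

.panel_to_matrix <- function(df) {
  .check_columns(df, c("day", "replicate", "concentration_nmol_L"),
                 "precision panel")
  tab <- table(df$day)
  if (length(unique(tab)) != 1L)
    .stop_invalid("unbalanced panel: every day needs the same replicate count")
  days <- sort(unique(df$day))
  t(vapply(days, function(dd) {
    sub <- df[df$day == dd, ]
    sub$concentration_nmol_L[order(sub$replicate)]
  }, numeric(tab[[1]])))
}

#' @export
print.precision_result <- function(x, ...) {
  cat(sprintf(
    "<precision: mean %.3f; CV intra %.2f%%, inter %.2f%%, total %.2f%%>\n",
    x$grand_mean, x$cv_intraday, x$cv_interday, x$cv_total))
  invisible(x)
}

#' Lower limit of quantitation from a CV profile
#'
#' The LLOQ is the lowest tested concentration at which the replicate CV is
#' below the threshold *and stays below it at every higher tested
#' concentration* (a single clean level below a noisy one does not
#' qualify; the sub-threshold run must persist to the top of the profile).
#'
#' @param profile Data frame with columns `nominal_nmol_L` and
#'   `measured_nmol_L` (at least 3 replicate rows per level), or a
#'   pre-summarized data frame with columns `nominal_nmol_L` and `cv_pct`.
#' @param threshold_pct CV threshold in percent (default 20).
#' @return A list of class `lloq_result`: `lloq` (nmol/L, or `NA` when no
#'   level qualifies), `determinable`, and `profile` (per-level CVs).
#' @examples
#' prof <- data.frame(nominal_nmol_L = rep(c(0.1, 0.2), each = 3),
#'                    measured_nmol_L = c(0.09, 0.13, 0.08, 0.2, 0.21, 0.19))
#' lloq_from_profile(prof)
#' @export
lloq_from_profile <- function(profile, threshold_pct = 20) {
  if (!is.data.frame(profile) || !"nominal_nmol_L" %in% names(profile))
    .stop_invalid("profile needs a 'nominal_nmol_L' column")
  if ("cv_pct" %in% names(profile)) {
    summ <- profile[order(profile$nominal_nmol_L),
                    c("nominal_nmol_L", "cv_pct")]
  } else {
    .check_columns(profile, c("nominal_nmol_L", "measured_nmol_L"),
                   "CV profile")
    levels <- sort(unique(profile$nominal_nmol_L))
    summ <- do.call(rbind, lapply(levels, function(cc) {
      x <- profile$measured_nmol_L[profile$nominal_nmol_L == cc]
      if (length(x) < 3L)
        .stop_invalid(sprintf("level %g has fewer than 3 replicates", cc))
      data.frame(nominal_nmol_L = cc,
                 cv_pct = 100 * stats::sd(x) / mean(x))
    }))
  }
  if (nrow(summ) == 0L) .stop_invalid("empty CV profile")
  below <- summ$cv_pct < threshold_pct
  run_to_top <- rev(cumprod(rev(below))) == 1    # below threshold here and above
  lloq <- if (any(run_to_top)) summ$nominal_nmol_L[which(run_to_top)[1]]
          else NA_real_
  structure(list(lloq = lloq, determinable = !is.na(lloq), profile = summ),
            class = "lloq_result")
}

#' @export
print.lloq_result <- function(x, ...) {
  if (x$determinable) cat(sprintf("<LLOQ: %.3f nmol/L>\n", x$lloq))
  else cat("<LLOQ: not determinable at this threshold>\n")
  invisible(x)
}

#' Linearity of measured against nominal concentration
#'
#' Ordinary least squares of measured on nominal over a dilution series.
#'
#' @param points Data frame with columns `nominal` and `measured` (>= 3
#'   points, nominal not all equal).
#' @return List: `slope`, `intercept`, `r_squared`, `range` (min, max
#'   nominal), `n`.
#' @export
linearity <- function(points) {
  .check_columns(points, c("nominal", "measured"), "linearity series")
  if (nrow(points) < 3L) .stop_invalid("linearity needs at least 3 points")
  if (length(unique(points$nominal)) < 2L)
    .stop_invalid("nominal concentrations must not all be equal")
  fit <- stats::lm(measured ~ nominal, data = points)
  list(slope = unname(stats::coef(fit)[2]),
       intercept = unname(stats::coef(fit)[1]),
       r_squared = stats::cor(points$nominal, points$measured)^2,
       range = range(points$nominal), n = nrow(points))
}

#' Interference recovery
#'
#' Recovery of the measured concentration in an interferent-spiked sample
#' relative to the unspiked baseline: `100 * spiked / baseline` percent. A
#' recovery outside the limits (default 80-120%, inclusive) flags
#' interference.
#'
#' @param baseline_conc Unspiked concentration, nmol/L (> 0).
#' @param spiked_conc Concentration measured after interferent spiking.
#' @param limits_pct Acceptance limits in percent (default `c(80, 120)`).
#' @param interferent,level Optional annotations (interferent name and
#'   level, e.g. mg/dL) carried into the result.
#' @return List of class `recovery_result`: `interferent`, `level`,
#'   `recovery_pct`, `within_limits`.
#' @examples
#' interference_recovery(1.58, 1.2166, interferent = "triglycerides",
#'                       level = 617)
#' @export
interference_recovery <- function(baseline_conc, spiked_conc,
                                  limits_pct = c(80, 120),
                                  interferent = NA_character_,
                                  level = NA_real_) {
  if (!is.finite(baseline_conc) || baseline_conc <= 0)
    .stop_invalid("baseline concentration must be positive")
  if (spiked_conc < 0) .stop_invalid("spiked concentration must be >= 0")
  rec <- 100 * spiked_conc / baseline_conc
  structure(list(interferent = interferent, level = level,
                 recovery_pct = rec,
                 within_limits = rec >= limits_pct[1] & rec <= limits_pct[2]),
            class = "recovery_result")
}

#' Stability percent change
#'
#' Absolute percent change of a sample's concentration across storage:
#' `100 * |after - before| / before`.
#'
#' @param before Concentration before storage, nmol/L (> 0).
#' @param after Concentration after storage, nmol/L.
#' @return Percent change (unsigned).
#' @export
stability_change <- function(before, after) {
  if (any(!is.finite(before)) || any(before <= 0))
    .stop_invalid("'before' concentration must be positive")
  100 * abs(after - before) / before
}

#' Method-comparison regression
#'
#' Regression of candidate-method results on reference-method results over
#' shared samples. `model = "ols"` (default) is ordinary least squares;
#' `model = "deming"` is Deming regression with error-variance ratio 1,
#' appropriate when both methods carry comparable measurement error (OLS
#' attenuates the slope in that case).
#'
#' @param pairs Data frame with columns `reference` (x) and `candidate`
#'   (y); at least 3 pairs, x not degenerate.
#' @param model `"ols"` or `"deming"`.
#' @param lambda Deming error-variance ratio `var(error_y)/var(error_x)`
#'   (default 1: equal error in both methods). Scaling y by c while
#'   scaling `lambda` by c^2 scales the Deming slope by c.
#' @return List of class `comparison_result`: `slope`, `intercept`,
#'   `r_squared` (squared Pearson correlation), `n`, `model`.
#' @export
method_comparison <- function(pairs, model = c("ols", "deming"),
                              lambda = 1) {
  model <- match.arg(model)
  .check_columns(pairs, c("reference", "candidate"), "comparison pairs")
  if (nrow(pairs) < 3L) .stop_invalid("method comparison needs >= 3 pairs")
  x <- pairs$reference; y <- pairs$candidate
  if (stats::var(x) == 0)
    .stop_invalid("reference values are degenerate (zero variance)")
  if (model == "ols") {
    fit <- stats::lm(y ~ x)
    slope <- unname(stats::coef(fit)[2])
    intercept <- unname(stats::coef(fit)[1])
  } else {
    sxx <- stats::var(x); syy <- stats::var(y); sxy <- stats::cov(x, y)
    slope <- (syy - lambda * sxx +
                sqrt((syy - lambda * sxx)^2 + 4 * lambda * sxy^2)) /
      (2 * sxy)
    intercept <- mean(y) - slope * mean(x)
  }
  structure(list(slope = slope, intercept = intercept,
                 r_squared = stats::cor(x, y)^2, n = nrow(pairs),
                 model = model),
            class = "comparison_result")
}

#' @export
print.comparison_result <- function(x, ...) {
  cat(sprintf("<%s comparison: y = %.4f x + %.4f; r^2 = %.5f, n = %d>\n",
              x$model, x$slope, x$intercept, x$r_squared, x$n))
  invisible(x)
}
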