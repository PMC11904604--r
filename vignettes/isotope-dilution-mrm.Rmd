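---
title: "Isotope-dilution MRM quantitation of C-peptide: models and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Isotope-dilution MRM quantitation of C-peptide: models and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(mrmquant)
```

## The measurement problem

C-peptide is co-secreted with insulin in equimolar amounts and, being
cleared more slowly, is the preferred serum proxy for endogenous insulin
production. Clinical C-peptide immunoassays disagree enough that results
are hard to compare across laboratories, so reference measurement systems
anchor the analyte to a certified reference material (CRM) through mass
spectrometry. A selected-ion-monitoring (SIM) measurement of the intact
peptide filters only the precursor m/z and is therefore vulnerable to
isobaric interference in serum; multiple reaction monitoring (MRM)
additionally filters a fragment m/z in the collision cell's third
quadrupole, which makes it far more specific. `mrmquant` implements the
computational core of an MRM assay in which C-peptide is digested with
Glu-C, the released peptide LGGGPGAGSLQPLALE is monitored through eight
precursor-to-fragment transitions (native and ¹³C₆-labeled channels), and
the concentration is obtained by isotope dilution against a two-point
CRM-traceable calibration.

## Digestion model

Glu-C cleaves on the C-terminal side of glutamic acid (E); in phosphate
buffers it also cleaves after aspartic acid (D). The assay's digestion
buffer is ammonium bicarbonate, so the default `digestion_rule()` cleaves
after E only, with cleavage after D available as an option. C-peptide
(`EAEDLQVGQVELGGGPGAGSLQPLALEGSLQ`) has glutamic acids at positions 1, 3,
11 and 27; the complete (zero-missed-cleavage) digest is therefore
`E | AE | DLQVGQVE | LGGGPGAGSLQPLALE | GSLQ`, and allowing up to two
missed cleavage sites (the default) additionally yields products such as
`EAEDLQVGQVE`, the longest species observed alongside `DLQVGQVE` and the
quantitation peptide in the assay's discovery runs. Cleavage after the
final residue is a no-op; each product records its parent span and
inherits any isotope labels re-indexed into its own coordinates. The
labeled C-peptide internal standard carries ¹³C₆-leucine at parent
positions 26 and 30; after digestion the quantitation peptide (parent
residues 12-27) carries the label at its position 15, which is the reason
this product, and only this product, can serve as the quantitation
peptide.

## Mass conventions and the printed transitions

Fragment m/z arithmetic is elementary but convention-sensitive, so both
monoisotopic and average (chemical) masses are supported, each derived
from residue elemental compositions: monoisotopic from exact isotope
masses, average from the CIAAW abridged standard atomic weights
(C 12.011, H 1.008, N 14.007, O 15.999, S 32.06). The proton is
1.00728 Da. The ¹³C₆ label shift is the physically correct difference per
convention: +6.0201 Da against ¹²C (monoisotopic) and +5.9541 Da against
natural-abundance carbon (average).

b ions sum the first *n* residues plus *z* protons; y ions sum the last
*n* residues plus water plus *z* protons; a label contributes only when
its position falls inside the fragment span, which is why the labeled
channel's b11, b12 and b14 coincide with the native channel's (the label
sits at position 15) while y2 is shifted by the full label mass.

The assay's published transition list mixes conventions and contains
instrument-tuned set points: y2 at 261.3/267.3 Da matches the average
convention, b14 at 1176.6 Da matches monoisotopic, while the precursor
(718.7/721.7) and b11 (895.3) and b12²⁺ (496.9) settings sit 0.1-0.6 Da
from any single convention — normal for unit-resolution quadrupole tuning.
The package therefore treats those values as set points to be matched
within the 0.7 Da unit-resolution window rather than reproduced exactly;
under the monoisotopic convention all eight computed values fall within
that window. Display rounding is half-up at one decimal, the convention of
instrument software (relevant at the labeled y2, whose average-mass value
267.2514 rounds to the printed 267.3).

## Synthetic chromatograms

`simulate_chromatograms()` is the package's fixture engine: it emulates
what the LC-MS acquisition hands to the integration step, not the
instrument physics. Each transition's trace is a Gaussian peak sampled on
a regular grid (default 1.2 s dwell over 11.0-12.2 min, about 15 points
across a peak of the default σ = 0.05 min; the window widens automatically
to cover apex ± 6σ). Peak area is proportional to concentration ×
relative fragment response × an optional per-transition suppression
factor in (0, 1] that emulates channel-selective matrix effects. Two noise
sources act on top:

* one multiplicative lognormal draw **per channel** (CV `noise_cv`,
  mean 1) shared by all of that channel's transitions — preparation and
  ionization variability, which cancels in qualifier ratios within a
  channel but not in the native/labeled response ratio;
* additive Gaussian baseline noise per point (`baseline_sd`), the
  detector-noise floor that dominates the CV at low concentration.

Intensities are clipped at zero (counts are non-negative). All draws flow
from a single `seed`; identical specs give bit-identical traces. The
default native concentration, 1.58 nmol/L, is a mid-range serum level from
the assay's interference study; the default `noise_cv` of 0.05 per channel
produces total response-ratio CVs in the 7-8 % range, matching the assay's
observed intra-day imprecision. The default relative fragment responses
are set so the three leading qualifier ratios sit exactly at their
established means (the fourth is then fixed by the telescoping identity,
see below, and lands within 0.3 SD of its mean).

What the simulator does **not** emulate: peak tailing and retention drift,
co-eluting interferences with their own elution profiles, detector
saturation, and carryover (a blank scenario plus `blank_check()` stands in
for the gradient-based carryover control of the real method). Passing
tests on these synthetic traces therefore validate the integration,
calibration and QC arithmetic — not robustness to pathological peak
shapes, which the real assay handles by manual review.

Peak detection uses a deterministic rule in place of vendor integration:
the apex is the maximum inside the retention-time window, and each bound
extends outward to the first local minimum or the first point below 1 % of
apex height, whichever comes first. Truncating a Gaussian at the 1 % height
(±3.03σ) loses 0.24 % of its area, within the 0.5 % recovery tolerance the
tests assert; integration is trapezoidal with linear interpolation at the
bounds.

## Quantitation chain and units

The measurement signal is the response ratio `rr = native b11 area /
labeled b11 area` — the quantifier transition only; qualifiers are never
summed into the signal. Calibration regresses `rr` on the gravimetric
molar ratio of CRM to labeled material; the routine design uses the two
points 1:1 and 1:6, through which the fitted line passes exactly, and the
same code fits a matrix-matched multi-point curve (on noise-free synthetic
calibrators the two agree to well under 1 %, mirroring the assay's finding
that the simple two-point curve suffices). Quantitation is inverse
prediction, `ratio = (rr - intercept)/slope`, floored at zero with a flag
for blank-sample noise rather than an error.

The molar-ratio-to-concentration conversion uses the internal-standard
amount: 20 µL of 10⁻⁷ g/mL labeled C-peptide (2 ng) spiked into 200 µL of
serum. Moles are computed from the **intact** labeled C-peptide molecular
weight (average convention, two ¹³C₆ labels, ≈ 3032.2 g/mol), because the
standard is spiked as the intact polypeptide before digestion and
digestion losses affect both channels identically; the parameter is
exposed (`assay_parameters(labeled_mw_g_mol = ...)`) for users who prefer
the released-peptide basis. The resulting concentration-equivalent is
≈ 3.30 nmol/L, i.e. a sample at molar ratio 1 reads 3.30 nmol/L.

## Quality control

Three per-sample gates, all reported as flags (quantitation proceeds with
`qc_pass = FALSE`; in this assay's practice ratio deviations usually trace
to integration imperfections and call for review, not automatic
rejection):

1. **Retention time**: every monitored apex, both channels, inside
   11.4-11.7 min — co-elution of native and labeled species is intrinsic
   to isotope dilution.
2. **Qualifier ratios**: b11/y2, y2/b14, b14/b12, b12/b11 with
   established means (SD) 2.62 (0.39), 1.09 (0.17), 0.87 (0.16),
   0.43 (0.10), gated at |z| ≤ 3 (configurable; the assay itself states no
   numeric gate, and 3 SD is the conventional choice). The four ratios
   telescope — their product is identically 1 for any sample — so the four
   means (product ≈ 1.07) cannot be hit simultaneously; the package
   asserts the identity and checks that a sample sitting on three means
   stays within 3 SD on the fourth. z-scores are invariant under common
   scaling of all areas.
3. **Internal standard present**: labeled quantifier area > 0.

Undefined ratios (zero denominator) fail the ratio gate unless the caller
marks the sample as below the LLOQ, in which case a "low-signal" message
is emitted instead — low-level samples legitimately lose their weakest
qualifiers into the baseline.

## Validation statistics

**Precision** follows the CLSI EP15-A3 one-way ANOVA decomposition of a
balanced day × replicate experiment: `MS_within` is repeatability
("intra-day"), the between-day component is
`max((MS_between - MS_within)/n, 0)` (negative estimates truncated to
zero, the guideline's handling), and total within-laboratory variance is
their sum, so `cv_total² = cv_intraday² + cv_interday²` by construction.
The implementation is verified against a brute-force sums-of-squares
oracle to 10⁻¹⁰ and, on 200 simulated 5×5 panels with true within-day CV
8 % and between-day CV 5 % (the design of the assay's imprecision study,
at its observed magnitudes), recovers both medians within 2 percentage
points.

**LLOQ** is the lowest tested concentration whose replicate CV is below
20 % *and stays below it at every higher tested level* — the run-to-top
rule resolves non-monotone CV profiles, where a single clean level below a
noisy one should not qualify. The simulated dilution series uses the
assay's nine nominal levels (0.05-0.75 nmol/L) in triplicate with
per-level CVs: the lowest level fully noise-dominated (CV ≈ 100 %, the
behavior of integration picking up baseline rather than analyte below the
detection floor) and every quantifiable level at the assay's typical 7 %.
The true CV therefore crosses 20 % between the two lowest levels and the
designed answer is the second level; with triplicate sampling the
empirical CV of a clean level still exceeds 20 % occasionally (the
sample CV of n = 3 draws has roughly half the true CV as its own
sampling SD), which is why the identification-rate check is set at 90 %,
a level a design-time power calculation puts the scenario comfortably
above (~94 %).

**Linearity** is ordinary least squares of measured on nominal over the
0.5-9.5 nmol/L series. **Interference recovery** is
`100 × spiked/baseline` with 80-120 % inclusive limits ("within 20 %");
the worked example is the assay's triglyceride case, 77 % recovery at a
1.58 nmol/L baseline, correctly flagged. **Stability** is unsigned percent
change before/after storage. **Method comparison** offers OLS and Deming
regression; Deming (closed form, error-variance ratio `lambda`, default 1)
is appropriate when the comparator carries similar measurement error, the
errors-in-variables setting in which OLS attenuates the slope. The exact
scale-equivariance of the Deming slope (scale y by c, scale `lambda` by
c²) is exposed and tested; with `lambda` fixed, equivariance is only
approximate.

None of these are hypothesis tests; no multiplicity machinery applies.
The assay's own headline numbers (CVs of 7.6-12.0 %, LLOQ 0.058 nmol/L,
the n = 47 comparison) came from real instrument data and are not targets
of the synthetic validation — the package reproduces the *procedures* and
validates them by oracle equivalence and simulation recovery.

## Problem sizes and numerical choices

The test suite and validation runs use deliberately modest sizes chosen
for statistical adequacy: 100 random peptides for the fragment-identity
properties, 100 random panels/profiles for oracle equivalence, 200
simulated panels for precision recovery, 100 seeds for the LLOQ
identification rate, 500 simulated acquisitions for the QC pass-rate
check, and 20 × 200 pairs for the Deming bias check. Tolerances: mass
identities at 10⁻⁶ Da (complementarity) and 10⁻⁹ Da (additivity); ANOVA
vs oracle at 10⁻¹⁰; trapezoid area recovery at 0.5 %; end-to-end
noise-free concentration recovery at 2 %.

Degenerate inputs are handled explicitly: empty sequences, unknown
residues and out-of-range labels are classed input errors; an all-zero
window yields a zero-area peak at the window midpoint rather than an
error; a missing internal standard flags the sample and never aborts the
batch; a grand mean of zero makes CVs undefined (classed error); ties at
the peak apex resolve to the first maximum on the grid.

## Known limitations

* The simulator's Gaussian-plus-noise model cannot probe integration
  robustness to tailing, shoulders or co-eluting interferents.
* Digestion efficiency is not modeled; isotope dilution makes the
  concentration estimate insensitive to it, but absolute signal levels in
  the simulator are arbitrary units.
* The ion-ratio gate and the blank-carryover threshold (20 % of a
  reference area) are configurable conventions, not assay-established
  constants.
* Only uniform ¹³C residue labels are supported; no other modifications,
  no spectral intensity prediction, no vendor file formats.
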