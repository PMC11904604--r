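# mrmquant

Computational toolkit for an isotope-dilution MRM (multiple reaction
monitoring) LC-MS assay of serum C-peptide.

C-peptide, co-secreted 1:1 with insulin and cleared more slowly, is the
standard serum proxy for endogenous insulin production, but commercial
immunoassays disagree enough to need CRM-traceable mass-spectrometry
anchoring. This package implements the computational side of an MRM assay
built on Glu-C digestion: the measurand is the released peptide
LGGGPGAGSLQPLALE (residues 12–27 of C-peptide), monitored as eight
transitions — doubly charged precursor to b₁₁ (quantifier), y₂, b₁₂²⁺ and
b₁₄ — in parallel native and ¹³C₆-labeled channels. It is aimed at
laboratory scientists developing or auditing targeted quantitative
LC-MS/MS assays who need the arithmetic between the instrument and the
reported concentration to be explicit, testable and reproducible.

## What it computes

* **In-silico Glu-C digestion** with missed cleavages, label bookkeeping
  and parent-span tracking (`digest()`).
* **Fragment-ion m/z** under monoisotopic or average mass conventions:
  bₙ = Σ residues(1..n) + z·H⁺, yₙ = Σ residues(N−n+1..N) + H₂O + z·H⁺,
  each divided by z, with isotope-label shifts applied only when the
  labeled position lies inside the fragment (`fragment_mz()`,
  `build_transition_table()`).
* **Synthetic chromatograms and peak integration**: Gaussian traces with
  per-channel lognormal area noise, additive baseline noise and optional
  matrix suppression; deterministic valley-or-1%-height peak bounds and
  trapezoidal integration (`simulate_chromatograms()`, `find_peak()`).
* **Isotope-dilution quantitation**: response ratio
  rr = A(native b₁₁)/A(labeled b₁₁), two-point calibration (molar ratios
  1:1 and 1:6 of CRM to labeled standard), inverse prediction, and
  conversion to nmol/L through the 2 ng internal-standard spike
  (`fit_calibration()`, `quantify()`).
* **Quality control**: 11.4–11.7 min retention window, qualifier-ion
  ratios b₁₁/y₂, y₂/b₁₄, b₁₄/b₁₂, b₁₂/b₁₁ gated at 3 SD around their
  established means, internal-standard presence (`evaluate_qc()`).
* **Assay validation**: CLSI EP15-A3 precision ANOVA
  (intra-day/inter-day/total CV), CV-profile LLOQ at the 20 % threshold,
  linearity, interference recovery with 80–120 % limits, stability percent
  change, and OLS/Deming method comparison (`precision_anova()`,
  `lloq_from_profile()`, `method_comparison()`, ...).

See `vignettes/isotope-dilution-mrm.Rmd` for the models, assumptions and
design decisions.

## Worked example

```r
library(mrmquant)

tab <- cpeptide_transitions()                    # monoisotopic by default
tab$q1_mz <- round_half_up(tab$q1_mz)
tab$q3_mz <- round_half_up(tab$q3_mz)
tab[, c("transition_id", "q1_mz", "q3_mz", "role")]
#>  transition_id q1_mz  q3_mz       role
#>     native_b11 718.9  895.5 quantifier
#>      native_y2 718.9  261.1  qualifier
#>     native_b12 718.9  496.8  qualifier
#>     native_b14 718.9 1176.6  qualifier
#>    labeled_b11 721.9  895.5 quantifier
#>     labeled_y2 721.9  267.2  qualifier
#>    labeled_b12 721.9  496.8  qualifier
#>    labeled_b14 721.9 1176.6  qualifier
```

The labeled channel's precursor is 3.01 Da/2 higher (one ¹³C₆ leucine on
the doubly charged 16-mer); b₁₁, b₁₂ and b₁₄ coincide between channels
because the label at position 15 lies outside those fragments, while y₂
carries the full +6 Da shift. Under the average convention
`fragment_mz()` gives y₂ = 261.3 / 267.3 — the printed set points of the
assay.

End-to-end, noise off (the generator is the oracle):

```r
run <- run_pipeline(default_run_config(seed = 7))
run$calibration
#> <calibration: rr = 1.0000 * ratio + 0.0000; n = 2, r^2 = 1.00000>
run$results[, c("sample_id", "response_ratio", "concentration_nmol_L", "qc_pass")]
#>   sample_id response_ratio concentration_nmol_L qc_pass
#>   low_serum      0.1607072                 0.53    TRUE
#>  high_serum      0.8732771                 2.88    TRUE
```

The two unknowns were simulated at 0.53 and 2.88 nmol/L (the assay's low
and high imprecision sera) and are recovered exactly: a response ratio of
0.1607 times the internal-standard concentration-equivalent (3.298 nmol/L,
from 2 ng of labeled C-peptide, MW ≈ 3032.2 g/mol, in 0.2 mL) gives
0.53 nmol/L.

Validation statistics on simulated panels:

```r
precision_anova(simulate_precision_panel(truth = 2.88, seed = 11))
#> <precision: mean 2.745; CV intra 5.38%, inter 4.46%, total 6.99%>
lloq_from_profile(simulate_cv_profile(seed = 11))
#> <LLOQ: 0.080 nmol/L>
```

A command-line wrapper over the same functions lives in
`inst/cli/mrmquant.R`:

```sh
Rscript inst/cli/mrmquant.R digest --sequence EAEDLQVGQVELGGGPGAGSLQPLALEGSLQ --missed 2
Rscript inst/cli/mrmquant.R transitions --sequence LGGGPGAGSLQPLALE \
    --labels 15:13C6 --convention mono --out transitions.csv
Rscript inst/cli/mrmquant.R run --seed 7 --out run_outputs/
```

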