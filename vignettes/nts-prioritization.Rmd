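---
title: "Methods: risk-based prioritization of LC-HRMS screening data"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: risk-based prioritization of LC-HRMS screening data}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(ntsprio)
```

`ntsprio` turns aligned LC-ESI-HRMS feature tables into a ranked shortlist
of chemicals of concern: quality filtering, suspect screening, consensus
annotation, semi-quantification and hazard-quotient ranking. This vignette
documents the models behind each stage, the parameters that matter, the
numerical conventions, and what the synthetic test bed does and does not
establish about real data.

## Mass arithmetic

Formulas are restricted to C, H, O, N, P, S, F, Cl, Br — the element set
typical of electrospray-amenable organics and of formula-generation engines
— plus Si, needed for the siloxanes common in textile extracts. Principal-
isotope masses are pinned in source (¹²C exactly 12; the others IUPAC
values to ≥ 6 decimals) so results are bit-stable across platforms.

Ion masses use the proton-mass convention: m/z([M+H]⁺) = M + 1.007276 Da
(hydrogen atom minus electron), [M−H]⁻ subtracts the same, and [M+Cl]⁻
adds a chlorine atom plus an electron (34.969402 Da). Charge states beyond
|z| = 1 and molecular ions [M]⁺ are out of scope: quaternary ammonium
compounds and other permanently charged species will not be found.

Reported masses are rounded half away from zero to 4 decimals; comparisons
use ±0.0001 Da so a value whose fifth decimal is 5 (e.g. CHF₃O₃S at
149.95985) is accepted against either printed rounding.

## The filter cascade

Stages run in a fixed order — intensity, replicate RSD, blank ratio, peak
quality, componentization, MS² assembly — and each output is a subset of
its input, recorded in a `filter_trace`. Conventions the user should know:

* **Intensity** (default 100,000 positive / 50,000 negative, instrument
  units): the *maximum* replicate intensity is compared **inclusively**
  (a feature exactly at the threshold survives — "threshold" reads as a
  floor).
* **Replicate RSD** (default ≤ 50%): RSD = 100·sd/mean with the sample
  (n−1) standard deviation, computed on raw (not blank-subtracted)
  intensities. A feature survives if *any one sample* has it present in
  every replicate within the RSD bound — detection frequencies below 100%
  are expected in heterogeneous samples, so presence in all samples is not
  required.
* **Blank ratio** (default 3): the best sample's replicate mean must
  **strictly** exceed 3 × the blank replicate mean ("exceed by a factor
  of 3"); absent intensities count as zero, so a feature absent from
  blanks always survives. With no blanks in the design the stage passes
  everything with a warning rather than silently.
* **Peak quality**: neural-network EIC classifiers are replaced by a
  pluggable contract (`function(feature, eic) -> "high"|"low"`). The
  shipped heuristic calls a trace high-quality iff it has ≥ 5 points above
  half-maximum and a single local maximum — transparent, and about the
  minimum a chromatographer would accept as a real peak. Features without
  EIC data pass with a warning.
* **Componentization** (±5 s co-elution, ±2 mDa delta match): co-eluting
  features whose m/z difference matches a ¹³C, Na−H, K−H or NH₃ delta are
  grouped and only the lowest-mass member — the protonated/deprotonated
  ion — is kept. This is deliberately a delta-mass/retention-time
  grouping, not full isotope-pattern annotation: only the
  keep-one-representative behaviour is needed downstream.
* **MS² assembly**: the 0.4 Da precursor and 5 s retention-time windows
  are interpreted as **full widths** (±0.2 Da, ±2.5 s), the convention of
  quadrupole isolation widths. Spectra are normalized to base peak 100 per
  collision energy, fragments clustered within ±5 mDa, relative
  intensities averaged over all collected spectra (absent fragments
  contribute zero), and fragments at ≤ 5% mean relative intensity pruned.

Internal time is seconds throughout; the CSV readers accept `rt_min`
columns and convert on input.

## Suspect screening and the RTI filter

Suspect lists (NORMAN Suspect List Exchange export style) are expanded to
[M+H]⁺ in positive mode and [M−H]⁻ plus [M+Cl]⁻ in negative mode, and
matched within ±2 mDa, inclusive at the boundary (a 10⁻¹² Da epsilon
absorbs floating-point representation of values exactly at the tolerance).
Multi-matched features are never discarded: every candidate is carried with
flags, because the retention-time filter is the mechanism that resolves
them.

The RTI model is ordinary least squares of calibrant RTI on measured
retention time; prediction *inverts* the fit,
`predicted RT = (RTI − intercept)/slope`. The text this workflow follows
fits RTI against RT and then predicts retention times, so fit-and-invert is
the faithful reading; with the well-conditioned calibrant sets involved the
difference from regressing RT on RTI is negligible. The filter passes
matches within ±120 s, inclusive. A companion RTI-unit window (≈ ±56 RTI at
the default slope) is documentation of the fitted slope, not a second
filter — the seconds window is authoritative because the RTI↔seconds
conversion depends on the data-specific regression. Suspects lacking an RTI
pass the filter flagged rather than silently dropping list-coverage gaps.

## Consensus annotation

The cosine score pairs fragments greedily (largest intensity product
first, each peak used once) within ±5 mDa — a tolerance the source text
does not fix; ±5 mDa matches the fragment-clustering tolerance and is
configurable. Unmatched peaks contribute to the norms, so the score is
symmetric and penalizes unexplained intensity.

Clause order, with the gates strict as written ("> 0.5", "> 2 peaks",
"> 0.8"):

1. library candidate with cosine > 0.5 and ≥ 3 matched fragments →
   **Level 2b** (online spectral library match);
2. else top forward and top inverse in-silico candidates each with ≥ 3
   matched fragments and mutual fingerprint Tanimoto > 0.8 → **Level 3**,
   taking the forward engine's structure;
3. else a single (unequivocal) formula candidate → **Level 4**;
4. else **Level 5** (unknown).

Two design points were genuinely open. First, engine-native scores are not
comparable across engines, so "use the highest score" is implemented as
within-source ranking plus the Tanimoto agreement gate — the agreement rule
itself, applied where a cross-engine comparison would otherwise be needed.
Second, when both the library and the in-silico clause could fire, the
library wins (clause order): a spectral match is the stronger evidence
class on the confidence scale. Level 5 is added for unannotated features,
consistent with the underlying confidence scheme; Level 1 (confirmed by
local reference standard) is never emitted by a purely computational
pipeline. Every annotation carries an evidence trace recording which
clauses fired.

## Quantification and priority scoring

Response factors are fitted by least squares **through the origin** (a
blank must give zero area) on concentrations converted from ng/mL to µM;
curves detected at fewer than 5 of the 10 levels are rejected. The molar
mass used for the conversion is the formula's monoisotopic mass — within
~0.1% of the average molecular weight for the organics concerned, and
exactly consistent with the synthetic generator's own conversion.

The ionization-efficiency transfer is OLS of log₁₀(RF) on predicted
log IE over the accepted calibration chemicals; an unknown's concentration
is `area / 10^(a·logIE + b)` in µM, reported in mM. The priority score is
the predicted hazard quotient, concentration/LC₅₀ (both mM). Toxicity
prediction is an interface (`lc50_lookup()`, `lc50_constant()`); trained
structure-to-LC₅₀ models are out of scope and plug in through the same
contract. Ranking is by descending score with ties broken by lower LC₅₀
then feature id; records without a concentration (e.g. negative-mode
features, for which no transfer is fitted) remain rankable by toxicity
alone. Priority scores compare features *to one another*; they are not
absolute risk estimates, and the documentation deliberately repeats that
caveat.

## Validation metrics

TPR = TP/(TP+FN), precision = TP/(TP+FP), F1 = 2·TPR·P/(TPR+P). The
counting convention differs from the textbook confusion matrix and is
applied exactly as the screening literature defines it: a feature annotated
with a wrong structure increments **both** FN and FP, an unannotated
feature only FN. Consequently TP+FN equals the evaluable universe, which is
what makes the per-mode metric grids internally consistent. Undefined
metrics (zero denominators) are reported as `NA`, never silently zero.
Report values are rounded half away from zero to 2 decimals; full precision
is retained internally.

## The synthetic test bed

`simulate_experiment()` emulates the targeted study design: 13 samples in
triplicate plus 3 method blanks, 38 spiked chemicals, and a ten-level
calibration series from 1 to 1000 ng/mL. Where the emulated design fixes
no value, defaults were chosen once at field-realistic levels and are not
tuned: log-normal replicate noise σ = 0.2 (≈ 20% RSD, well under the 50%
gate), between-sample variation σ = 0.1, m/z error σ = 0.3 mDa, RTI slope
0.4666 RTI/s (the conventional ±120 s ↔ ±56 RTI correspondence) with
jitter σ = 20 RTI, log IE ~ N(3, 1) with transfer slope 0.9 and intercept
2 (response factors around 10⁴–10⁶ area/µM), LC₅₀ log-normal around
0.3 mM, and true extract concentrations log-uniform on 0.001–1 mM
(rescaled upward where the implied area would sit below twice the
intensity threshold, keeping truth and areas consistent with the response
model). Fragment fingerprints are 256-bit vectors with directly controlled
overlap — no cheminformatics dependency — and each chemical's six-fragment
MS² profile varies smoothly with collision energy and always includes a
sub-5% fragment to exercise pruning.

Every generated feature carries exactly one intended fate (pass, fail one
named filter, or be removed as a sodiated satellite), and one root seed is
split into per-component streams so adding a component never perturbs
another's draws.

What passing tests show — and don't. On the noise-free bundle the cascade
realises every intended fate, screening recall on spiked suspects is 1.0,
annotation clause attribution is 100%, and predicted concentrations match
generative truth within 1% (within a factor of two under log-IE predictor
error σ = 0.3). That establishes the *machinery* is correct: the
predicates, regressions and inversions do what they claim. It does not
establish performance on real extracts, where peak shapes, ion
suppression, co-elution, isotope interference and library coverage are all
harsher than the generator's log-normal world. The generator deliberately
omits matrix effects beyond log-normal noise, realistic fragmentation
chemistry and retention-time drift.

Problem sizes in the shipped tests (tens of chemicals, ≤ 10³×10³ matching
instances, 20-seed stability loops) were chosen as the smallest sizes at
which every property is non-trivially exercised; all generators scale by
configuration.

## Numerical conventions and degenerate inputs

* Tolerances written "±x" are inclusive at the boundary throughout.
* Rounding of reported values is half away from zero (base R's
  `round()` is round-half-even).
* Degenerate regressions (all-equal predictors) raise errors; a zero RTI
  slope cannot be inverted and errors rather than returning infinities.
* Tanimoto of two all-zero fingerprints is defined as 1.
* Empty inputs flow through: an empty feature table produces an empty
  result and a trace of zeros; an empty suspect list produces zero
  matches.
* `run_workflow()` on a fixed bundle is deterministic and repeated runs
  are identical.

## Known limitations

* No raw-data (mzML) ingestion: peak picking, alignment and EIC
  extraction happen upstream; the package starts at the aligned feature
  table.
* Componentization recognises a fixed delta table; unusual adducts or
  multimers pass through as independent features.
* Only [M+H]⁺, [M−H]⁻ and [M+Cl]⁻ are supported; molecular ions and
  multiply charged species are not.
* In-silico fragmentation, formula generation and fingerprint/toxicity
  prediction are consumed as inputs behind interfaces, not computed.
* Concentrations are semi-quantitative (ionization-efficiency transfer,
  no matrix correction); the hazard-quotient ranking is comparative only.
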