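---
title: "Methods: stable-isotope tracing and ester hydrolysis analysis with kgtrace"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: stable-isotope tracing and ester hydrolysis analysis with kgtrace}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(kgtrace)
```

# Scope and scientific setting

Alpha-ketoglutarate (KG) is a TCA-cycle intermediate and the obligatory
co-substrate of the KG-dependent dioxygenases. Because KG is widely assumed
membrane-impermeable, cell biology experiments commonly supply it as
cell-permeable esters such as dimethyl-KG (DMKG) or 1-octyl-KG. Those esters
hydrolyze spontaneously in aqueous media — DMKG loses its ester proximal to
the alpha-ketone quickly, yielding 5-methyl-KG, which then hydrolyzes slowly
to KG — releasing an alpha-keto acid whose deprotonation acidifies the
medium. Quantifying what actually reaches cells therefore requires
accurate-mass identification of esters and their hydrolysis products,
isotope-tracer accounting of which carbon source feeds which metabolite
pool, and a kinetic model of the hydrolysis cascade itself. `kgtrace`
implements that computational stack end to end, together with
ground-truth synthetic-data generators so every stage can be validated
against known answers.

# Formula and mass calculus

Formulas are parsed from Hill-style strings into element-count vectors, and
masses come from an editable element table (IUPAC monoisotopic masses and
natural abundances; `element_table()`, with a delimited copy under
`inst/extdata/isotopes.tsv`).

Two ion m/z conventions are implemented deliberately:

* **physical** (default, used for all peak matching): `[M−H]⁻` is the
  neutral monoisotopic mass minus one proton, so electron bookkeeping is
  exact.
* **reported**: neutral mass minus one hydrogen *atom* (electron neglected),
  rounded to four decimals and then truncated to three. Three-decimal
  published values of this compound family mix what look like "rounded" and
  "truncated" last digits; this rule — the natural consequence of computing
  from four-decimal mass tables — regenerates all of them
  (159.029 for mono-methyl-KG C6H8O5, 173.045 for DMKG C7H10O5, 131.034 for
  methyl-succinate C5H8O4, 129.018 for methyl-fumarate C5H6O4) and is kept
  as a labeled reporting convention only, never for matching.

GC-MS derivatives follow the standard methoxyamine + MTBSTFA chemistry:
each methoximation contributes net +C+3H+N (the keto oxygen is replaced by
N–OCH3), each TBDMS silylation net −H+C6H15Si. The diagnostic `[M−57]`
fragment is the nominal mass after loss of tert-butyl (C4H9):

```{r derivative}
deriv <- apply_derivative("C6H8O5", derivative_spec(1, 1))
deriv
fragment_nominal_mz(deriv, "C4H9")
```

Methoximation is modeled for ketones only, with no syn/anti isomer
distinction — the isomers differ chromatographically, not in formula.
Adducts beyond `[M±H]` and isotope fine structure within a nominal mass are
out of scope.

# Feature detection and library quantitation

`detect_features()` re-creates the untargeted MS1 strategy of pooling all
samples' centroided peaks and seeding features greedily by descending
intensity. A seed must reach the minimum intensity (default 1e5) and the
minimum signal-to-noise ratio (default 10); all unassigned peaks within the
m/z discrimination threshold (default 20 ppm) and the retention-time
co-grouping threshold (default 2 min) of the seed are absorbed, so features
are disjoint over peaks and each sample contributes its apex intensity.
Two interpretation choices were genuinely open:

* The 2-minute "retention time threshold" is read as the cross-sample RT
  co-grouping half-width, consistent with detecting one feature across all
  samples; it is a parameter (`rt_group_min`), not a constant.
* A minimum S/N rule does not by itself pin down a noise estimator, so
  `estimate_snr()` uses a robust median estimator: the noise under a
  candidate is the median intensity of peaks within ±50 ppm across the
  whole run, excluding ±0.2 min around the candidate so its own
  chromatographic peak is not counted as noise. Both widths are parameters.

Targeted quantitation (`quantify_library()`) matches an accurate-mass /
retention-time library at ±5 ppm and ±0.5 min, takes the per-sample apex,
forms the consensus apex time as the median across samples and accepts a
sample only within ±7.5 s of that consensus. The quantified value is apex
intensity, not integrated area, matching the upstream definition of peak
intensity. Blank correction (`blank_correct()`) thresholds at
`max(3 × mean blank, 1e5)`; both replacement policies in use downstream are
implemented — threshold replacement for group-wise comparisons and zero
replacement for models where imputing the threshold would create false
positives — selected by a flag. Ties in greedy seeding are broken by lower
m/z then earlier retention time, for determinism. Chromatographic peak-shape
modeling, deconvolution and MS2 identification are out of scope.

# Natural-abundance correction and MPE

A measured mass isotopologue distribution (MID) is distorted by naturally
occurring heavy isotopes of every atom in the measured fragment — for
TBDMS derivatives, very much including silicon (²⁹Si, ³⁰Si). The forward
distortion is linear: column *j* of the correction matrix is the mass-shift
distribution of a molecule with *j* tracer-labeled carbons, i.e. a
binomial(j, purity) label shift convolved with the natural-shift
distribution of the remaining atoms (fragment minus *j* carbons), truncated
to shifts 0…n. `correct_mid()` inverts it by non-negative least squares and
renormalizes; NNLS was preferred to plain inversion because inversion
produces negative fractions on noisy data, while NNLS is the conservative
standard. The construction is validated entry-wise (1e−10) against a
brute-force multinomial-enumeration oracle in the test suite.

Tracer purity defaults to 1.0 — replicating analyses that do not model
purity — with 0.99-style commercial purities available through
`tracer_spec()` for sensitivity analysis. Corrections for GC-MS use the
complete derivatized fragment formula; LC-MS corrections use the
underivatized ion formula. Dual-element tracers and positional isotopomers
are out of scope.

Mole percent enrichment is the carbon-weighted average of the corrected
MID, `MPE = 100 · Σ i·Mᵢ / n`. The denominator is the fixed traceable
carbon count *n*, so the value is *not* invariant under padding the MID
with extra zero entries; the functions therefore insist on length n+1.

# Stable-isotope dilution inference

With intracellular pools labeled by a steady ¹³C₅-glutamine tracer, an
unlabeled carbon source (KG or DMKG supplement) dilutes labeling of every
pool it reaches. Its percent contribution is the drop in MPE,
`MPE_control − MPE_treated`; the equivalent phrasing as a difference in
percent-unlabeled carbon, `Δ%(100−MPE)`, is implemented and labeled, and
the two agree in magnitude identically (a tested property). Dispersion is
propagated as the standard error of a difference of independent replicate
means, `√(sd₁²/n₁ + sd₂²/n₂)` — a stated convention, since "mean ± s.d."
plots do not pin down a propagation rule. Estimates are clamped to
[−100, 100] but small negative values are reported, not zeroed: they are
informative noise around a null contribution.

The compartmentalized readout uses 2-hydroxyglutarate produced by mutant
IDH1-R132H (cytosolic) or IDH2-R172K (mitochondrial) as a 5-carbon sensor
of its compartment's KG pool; `compartment_contribution()` applies the same
arithmetic and tags the compartment from the construct identity.

Supporting calculus: internal-standard absolute quantitation
(`absolute_quant()`: signal ratio × spiked nmol / aliquot µl = mM),
reference normalization to norvaline-style extraction standards,
percent-of-baseline normalization of respirometry series (default: the
mean of the first three basal readings), vehicle background subtraction of
milli-pH traces, and the 7× injection-port dilution arithmetic
(`injection_stock()`).

Group statistics (`group_stats()`) use per-metabolite two-sided Welch
t-tests with Benjamini–Hochberg adjustment and the volcano rule
(|log₂FC| ≥ 1 and adjusted p < 0.05). A negative-binomial covariate model
for intensities was deliberately not replicated: that machinery targets
counts, and Welch + BH preserves the decision rule while staying
appropriate for intensity data. ANOVA/Dunnett post-hoc replication and
flux (MFA) modeling are non-goals; contributions here are pool-level label
dilution only.

# Hydrolysis kinetics

The minimal mechanistic model consistent with fast proximal and slow
distal ester hydrolysis is consecutive first-order kinetics
E → M → P (di-ester → monoester → acid):

$$E(t) = E_0 e^{-k_1 t},\quad
M(t) = E_0 \frac{k_1}{k_2 - k_1}\left(e^{-k_1 t} - e^{-k_2 t}\right),\quad
P(t) = E_0 - E - M,$$

with the equal-rate limit `M = E0·k1·t·exp(−k1 t)` applied when
|k₂ − k₁| is numerically negligible; mass conservation holds to 1e−10 at
every parameterization and the closed form matches an ODE integration
oracle to 1e−8 (both tested). This is a modeling choice layered on
observed time courses, not a fitted law asserted by the original
measurements; adequacy on real data should be judged from residual
diagnostics. Mono-esters use the single-step model. Rate fitting
(`fit_consecutive()`) is Levenberg–Marquardt least squares over any subset
of observed species (≥3 distinct time points each), with confidence
intervals from the residual-variance-scaled Jacobian cross-product;
non-convergence raises an error carrying the optimizer diagnostics.
Regioselective branching of the first hydrolysis step (5MKG ≈ 16× 1MKG)
is deliberately lumped into a single monoester pool in the default model.

`ph_after_acid_addition()` models hydrolysis-driven acidification: a
monoprotic buffer (HEPES 5 mM, pKa 7.55 defaults) is first calibrated to
the initial pH by solving for the strong-ion difference, the neutral
polyprotic acid (alpha-ketoglutaric acid defaults, pKa 2.5 and 4.7) is
added, and the charge balance is re-solved by bracketed root finding on
pH ∈ [0, 14] (cross-checked against a 1e−5-step grid scan). The model
intentionally omits CO₂/bicarbonate chemistry (it targets
bicarbonate-free HEPES media) and the amino-acid buffering of complete
media, so its absolute ΔmpH overstates acidification in rich media; its
tested guarantees are the null case, the oracle agreement and
monotonicity in added acid.

# Synthetic data: what it does and does not emulate

The generators plant known truth and return it alongside the data, so
pipeline tests compare against recorded, never re-derived, truth:

* `gen_peaklists()` — planted features with configurable ppm / RT /
  intensity jitter plus uniform sub-threshold background peaks in a
  67–1000 m/z scan range.
* `gen_labeling_experiment()` — the central tracer scenario: the 5-carbon
  KG backbone measured as its methoxime di-TBDMS [M−57] fragment
  (C14H28NO5Si2), full tracer enrichment, a true supplement contribution
  *c*, 3 replicates per condition and 2% multiplicative noise per
  isotopologue. The true corrected MID (a two-component unlabeled/fully
  labeled mixture, or a user-supplied partial-labeling pattern) is
  forward-distorted by the correction matrix, perturbed, and renormalized.
* `gen_timecourse()` — consecutive-model curves with multiplicative noise.

A single multiplicative CV stands in for both biological and technical
replicate noise, which real designs separate; there are no chromatographic
peak shapes, instrument drift, saturation or missingness mechanisms.
Passing the recovery tests therefore demonstrates correctness of the
calculus and estimators under the stated noise model — not robustness to
every artifact of real acquisitions.

```{r pipeline}
lab <- gen_labeling_experiment(contribution = 0.40, cv = 0.02, seed = 1)
A <- lab$truth$A
mids <- lab$mids
mpe_of <- function(cond) {
  rows <- mids[mids$condition == cond, paste0("M", 0:5)]
  apply(rows, 1, function(r) mpe(correct_mid(as.numeric(r), A)))
}
contribution(mpe_of("control"), mpe_of("supplemented"))
```

# Numerical choices and problem sizes

Tolerances used throughout were chosen to sit well below scientific
meaning and well above floating-point noise: 1e−10 for correction-matrix
agreement with the enumeration oracle, 1e−6 for noiseless NNLS round
trips, 1e−4 relative for noiseless rate recovery, 1e−4 pH for the
equilibrium root. Greedy seeding ties break deterministically (lower m/z,
then earlier RT). Degenerate inputs fail loudly: all-zero MIDs, empty
replicate sets, zero internal-standard signal and unknown reporter
constructs are errors, while an unparseable library formula yields a
per-entry error record so one bad row cannot abort a batch.

The validation suite runs at deliberately modest sizes — tens of planted
features, three replicates, 20–100 simulation seeds for the stochastic
properties — sizes at which the oracles (exhaustive isotope enumeration,
ODE integration, grid scans) are exact and fast while still exercising
every code path of the estimators.
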