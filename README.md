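# kgtrace

Quantitative stable-isotope tracing metabolomics for alpha-ketoglutarate
(KG) and its cell-permeable esters.

KG fuels both mitochondrial TCA-cycle metabolism and the large family of
KG-dependent dioxygenases, and is routinely supplied to cells as esters
(dimethyl-KG, 1-octyl-KG) on the assumption that free KG cannot cross
membranes. Those esters hydrolyze spontaneously in aqueous media — the
ester proximal to the alpha-ketone first and fast, the distal one slowly —
releasing alpha-keto acids that acidify the medium and mono-esters that
enter cells on their own. Disentangling what actually happens requires
accurate-mass identification of esters and hydrolysis products,
isotope-tracer arithmetic for which carbon source feeds which pool, and a
kinetic model of the hydrolysis cascade. `kgtrace` provides that stack for
analysts working with centroided LC-MS peak tables and GC-MS isotopologue
data:

* **Formula/mass calculus** — Hill-formula parsing, monoisotopic and
  nominal masses, `[M±H]` ion m/z under an exact physical convention and a
  reproducible three-decimal reporting convention, methoxime/TBDMS
  derivative formulas and diagnostic `[M−57]` fragment masses.
* **Feature detection and library quantitation** — greedy
  intensity-descending MS1 feature detection across samples (20 ppm, 1e5
  intensity floor, S/N 10, 2-min RT co-grouping), accurate-mass /
  retention-time library quantitation (±5 ppm, ±0.5 min, ±7.5 s apex
  tolerance) and 3×-blank correction with a 1e5 floor.
* **Isotopologue correction and MPE** — natural-isotope-abundance
  correction matrices for arbitrary (including silylated) fragments,
  inverted by non-negative least squares; mole percent enrichment
  `MPE = 100·Σ i·Mᵢ/n`.
* **Tracer inference** — stable-isotope dilution contribution estimates
  (`ΔMPE` / `Δ%(100−MPE)`), compartment-specific readouts via the
  IDH1-R132H / IDH2-R172K 2-hydroxyglutarate reporter, internal-standard
  absolute quantitation, baseline/reference normalizations, Welch-t +
  Benjamini–Hochberg volcano statistics.
* **Hydrolysis kinetics** — closed-form consecutive first-order model
  (di-ester → monoester → acid), Levenberg–Marquardt rate fitting with
  confidence intervals, and a buffered polyprotic-acid pH equilibrium
  model of hydrolysis-driven acidification.
* **Synthetic data** — seeded generators for peak lists, labeling
  experiments and time courses that return their ground truth, so the
  whole pipeline is testable without instrument data.

The model at the core of the tracer inference: with pools labeled by a
steady ¹³C₅-glutamine tracer, an unlabeled supplement contributing
fraction *c* of a pool's carbon dilutes its labeling, so
`c = MPE_control − MPE_treated` after natural-abundance correction of the
measured MIDs (`raw = A·x`, `x ≥ 0`, column *j* of `A` being the isotope
pattern of a *j*-times-labeled molecule).

## Worked example

```r
library(kgtrace)

## theoretical [M-H] of mono-methyl-KG, printed reporting convention
theoretical_mz("C6H8O5", "negative", "reported")
#> [1] 159.029

## GC-MS derivative of KG and its diagnostic fragment
deriv <- apply_derivative("C5H6O5", derivative_spec(1, 2))
deriv
#> <formula> C18H37NO5Si2
fragment_nominal_mz(deriv, "C4H9")
#> [1] 346

## a synthetic labeling experiment with a planted 40% contribution,
## recovered through correction -> MPE -> dilution arithmetic
lab <- gen_labeling_experiment(contribution = 0.40, cv = 0.02, seed = 1)
mids <- lab$mids; A <- lab$truth$A
mpe_of <- function(cond) {
  rows <- mids[mids$condition == cond, paste0("M", 0:5)]
  apply(rows, 1, function(r) mpe(correct_mid(as.numeric(r), A)))
}
contribution(mpe_of("control"), mpe_of("supplemented"))
#> <contribution_estimate> 40.75% (delta %MPE, se 0.375)
#>   MPE control 100.00% (n=3)  treated 59.25% (n=3)

## fit hydrolysis rates to a noisy synthetic DMKG time course
tc <- gen_timecourse(E0 = 1, k1 = 5, k2 = 0.02, cv = 0.05, seed = 2)
fit_consecutive(tc$data)
#> <rate_fit> consecutive first-order hydrolysis
#>    estimate         se   lower    upper
#> E0 1.008300 0.00619680 0.99596 1.020600
#> k1 4.799100 0.13608000 4.52860 5.069600
#> k2 0.020231 0.00039296 0.01945 0.021012
#> residual deviance: 0.072842
```

The contribution estimate reads: the supplement supplies ~40% of the
pool's carbon (truth: 40%), with the dispersion propagated from replicate
MPEs. The rate fit recovers the fast proximal hydrolysis (k₁ ≈ 5/h) and
slow distal hydrolysis (k₂ ≈ 0.02/h) from 5%-noise data.

A full account of the models, parameter meanings, design choices and
limitations is in `vignettes/kg-ester-tracing.Rmd`.

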