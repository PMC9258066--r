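---
title: "Methods: SIP label calling and radiotracer rate estimation"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: SIP label calling and radiotracer rate estimation}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(methylosip)
```

## The problem

RNA stable isotope probing (SIP) identifies which members of a microbial
community assimilate a specific substrate. A community is fed a
^13^C-labelled substrate (here methanol) alongside a ^12^C control;
organisms that incorporate the label synthesize isotopically heavy rRNA,
which reaches equilibrium at a higher buoyant density in an isopycnic
CsTFA gradient. After ultracentrifugation the gradient is split into
fractions, each fraction's density is read by refractometry, the RNA is
sequenced per fraction, and taxa enriched in the *heavy* fractions of the
^13^C treatment — but not of the ^12^C control — are called labelled.

The companion measurement is a ^14^C radiotracer incubation: plant
material is exposed to ^14^C-methanol, respired ^14^CO~2~ is caught in
NaOH traps exchanged at fixed intervals, and the slope of cumulative
trapped activity over time, normalized by specific activity and dry
biomass, gives a *potential* methanol consumption rate in
nmol g dry wt^-1^ h^-1^.

This package implements the full inference chain for both measurements,
plus the supporting operations (refractometry conversion, fraction
classing, diversity summaries, delta-^13^C normalization) and a
synthetic-data generator with known ground truth, so that every stage is
testable without any sequencing download.

## The labelling criteria

For each taxon $i$, with $h^{13}_i$ its relative abundance in the heavy
fraction of the ^13^C gradient, $\ell^{13}_i$ in the light fraction of the
same gradient, and $h^{12}_i$ in the heavy fraction of the paired ^12^C
control, the taxon is called ^13^C-labelled iff all three hold:

1. $h^{13}_i > h^{12}_i$ — enrichment above the control's heavy fraction
   (strict);
2. $h^{13}_i > K\,\ell^{13}_i$ with $K = 2$ — heavy-over-light enrichment
   within the ^13^C gradient (strict). $K$ is deliberately low: in short
   incubations only part of a consumer's RNA pool is replaced, so heavy
   enrichment is partial;
3. $h^{13}_i \ge 0.05\%$ — an abundance floor that removes noise-level
   calls (non-strict).

The strict/non-strict placement follows the criteria's wording exactly and
is pinned by boundary tests. Both $K$ and the floor are configurable
(`sip_config()`); the labelled set is provably non-increasing in each,
which the test suite checks over a $K \in \{1,2,4,8\}$ by
floor $\in \{0, 0.05\%, 0.5\%\}$ grid.

**Zero light-fraction abundance.** Criterion 2 is undefined when a taxon is
absent from the light fraction. We substitute a pseudo-abundance, by
default $1/(2D_\ell)$ where $D_\ell$ is the pooled light-fraction read
depth — half a read's worth. This keeps the rule monotone in $K$, scales
with sequencing depth (deeper light fractions make absence more
informative), and is overridable via `pseudo_abundance`.

**Pooling.** When several fractions of one gradient fall in the same
density class, their counts are summed *before* normalization, so "the
heavy fraction" is always one profile per gradient. Pooling raw counts
(not averaging proportions) weights fractions by their evidence.

**Pairing.** Gradients are paired by (species, compartment, timepoint);
a ^13^C gradient without a matching ^12^C control is an error, never a
silent average. The species field is optional in the metadata and drops
out of the key when absent.

**Rank of evaluation.** All three criteria are applied at the same (OTU)
level; aggregation to a lineage rank is a separate, explicit step
(`summarize_calls()`), which renormalizes heavy-fraction abundances over
the labelled set so that profiles from pairs with different overall
labelling strength remain comparable.

## Gradient geometry

Buoyant density is recovered from refractometry by a linear calibration
`density = slope * nD + intercept`. The package default
(slope 11.43, intercept −13.907 g mL^-1^) is a documented convention
anchored at unlabelled rRNA banding near 1.775 g mL^-1^ (nD ≈ 1.3720) and
fully labelled rRNA near 1.815 g mL^-1^ (nD ≈ 1.3755), consistent with
standard CsTFA RNA-SIP practice; laboratories should override it with
their own calibration, which is why it lives in the configuration rather
than in code. Refractive indices outside a plausibility window (default
1.35–1.42) are rejected outright, because the most common data error —
swapped nD and density columns — produces exactly such values.

Default density windows are heavy `[1.795, 1.825]` and light
`[1.760, 1.780]` g mL^-1^, symmetric around the expected labelled and
unlabelled banding densities. Every fraction receives exactly one class
(heavy, light, middle for the gap between the windows, unassigned
elsewhere), and classification is a pure function of density and windows.

## Rate estimation

`fit_turnover_slope()` is ordinary least squares of cumulative trapped
activity on time **with a free intercept**: the intercept absorbs trap
lag and is reported so it can be audited, rather than forcing the line
through the origin. The rate is

$$\mathrm{rate} = \frac{\mathrm{slope}}{\mathrm{specific\ activity}
\times \mathrm{dry\ mass}}$$

in nmol g dry wt^-1^ h^-1^. The molar specific activity (Bq nmol^-1^) is
a **mandatory** user input with no default — any default would be an
invented constant. A negative fitted slope is reported as rate 0 with an
explicit `clamped` flag (consumption is physically non-negative) while the
raw slope is retained. Flat and exactly collinear series are assigned
$R^2 = 1$: the line fits them perfectly, and the usual $0/0$ is a
convention choice we make explicit. Rates are *potential* rates: no
isotope-dilution correction for unlabelled endogenous methanol pools is
attempted, and none of the traps' quench behaviour is modelled.

Mass-balance bookkeeping reports the fractions of administered activity
recovered as trapped CO~2~ and as volatilized methanol; totals above 1
raise a QC flag, not an error. The BaCO~3~ cross-check reports the summed
percent excess of precipitate activities over NaOH activities and the
$R^2$ of their paired regression.

## The synthetic-data generator

`simulate_gradient_experiment()` draws, for each taxon, a Gaussian rRNA
mass profile over buoyant density centred at a taxon-specific mean
(N(1.772, 0.002) g mL^-1^ by default, emulating GC-content variation),
with within-gradient spread 0.008 g mL^-1^. In ^13^C gradients, labelled
taxa carry a second component: a fraction `label_fraction` (default 0.8)
of their RNA shifted up by `density_shift` (default 0.03 g mL^-1^, the
order of magnitude of full ^13^C labelling of RNA — a configurable
convention, not an asserted literature value). On top of the peaks, a
fraction `background_smear` (default 5%) of every taxon's RNA is spread
uniformly across the gradient. The smear is essential, not cosmetic: real
gradients carry RNA in every fraction, and that background is the
physical premise of criterion 1 — it makes the control's heavy fraction
resemble the overall community. Without it, the control heavy fraction is
composed purely of extreme Gaussian tails and its composition is
dominated by whichever taxon happens to have the highest density mean, a
regime far more hostile than real data. Sequencing is multinomial with a
fixed per-fraction depth (default 50,000 reads), preserving compositional
closure.

The mixture construction (partial labelling via `label_fraction`) keeps
criterion 2 genuinely discriminative: a labelled taxon still has most of
a light-fraction presence, so the heavy/light ratio is finite and the
$K$ threshold does real work.

`make_study_design()` emits the full paired layout: 2 plant species × 3
compartments (phyllosphere, roots, rhizosphere soil) × {^12^C, ^13^C} × 2
timepoints (8 h, 24 h) = 24 gradients. Each ^13^C gradient contributes
its heavy, middle and light fractions and each control its heavy and
light fractions — 60 sequenced samples. The per-gradient fraction count
is not dictated by the design being emulated, so this 3 + 2 split is a
package convention chosen to exercise the middle class.

What the generator does **not** emulate: chimeras and OTU-clustering
artefacts, taxon-correlated sequencing error, overdispersion beyond
multinomial (real amplicon data are overdispersed), isotope cross-feeding,
and any relationship between incubation time and labelling strength
(`label_fraction` is per-run, not per-timepoint). Passing the recovery
tests therefore demonstrates correctness of the *inference chain* under a
fair generative model, not field performance on real amplicon data.

`simulate_trap_series()` generates cumulative trap activities
`trap_efficiency * slope * t` plus Gaussian noise (default SD 2 Bq),
clipped non-negative and forced non-decreasing as a cumulative reading
must be; defaults mirror the reference incubation (631 kBq administered,
3.5 h, 30-min intervals, dry mass 0.05 g). The methanol trap receives
`methanol_volatile_fraction` (default 0.965) of the administered
activity, which together with `trap_efficiency = 0.97` yields total
recoveries near 97%. Because the generator attenuates the slope by the
trap efficiency, the estimand of the OLS fit is the *trapped-CO~2~* rate;
recovery tests therefore measure estimator bias against
`trap_efficiency × true_rate`, and exactness is checked at efficiency 1.

## Diversity operations

* Singleton removal drops taxa with **dataset-wide** total count 1 (not
  per-sample); idempotent by construction.
* Shannon uses the natural logarithm by default (configurable to any
  base); zeros contribute nothing.
* Chao1 uses the bias-corrected form
  $S_{obs} + F_1(F_1-1)/(2(F_2+1))$ so $F_2 = 0$ is well defined.
* Rarefaction is the analytic hypergeometric expectation
  $\sum_i [1 - \binom{N-N_i}{d}/\binom{N}{d}]$, evaluated on log scale
  (`lchoose`) for stability, and is cross-checked in the tests against
  both Monte-Carlo subsampling and `vegan::rarefy`.
* The asymptotic richness fit $r(d) = n_{max} d/(k+d)$ uses
  Levenberg–Marquardt (`minpack.lm::nlsLM`), which converges on
  zero-residual (noiseless) data where Gauss–Newton steps fail. The
  half-saturation start value is solved from the first curve point rather
  than set to the median depth: for already saturated curves the true $k$
  lies far below every sampled depth, and a median-depth start leaves the
  solver outside its basin of attraction.
* Bray–Curtis is provided for feeding external ordinations; NMS/NMDS
  itself is out of scope (standard package territory). Note Bray–Curtis
  is a semimetric — it can violate the triangle inequality — so the tests
  assert symmetry, range and closed forms, not metric axioms.

## Determinism and the pipeline

All simulators take explicit seeds, restore the caller's RNG state, and
are bit-reproducible. `run_pipeline()` writes its four result tables and
a manifest that records the effective configuration, a config hash, MD5
checksums of every output and all collected warnings — and deliberately
no timestamps, so a rerun with the same seed and configuration is
byte-identical, which the test suite verifies with checksums.

## Problem sizes used in the tests

The test and acceptance workloads are sized for a laptop-class single
core: 1,000 random gradient pairs (up to 50 taxa) for the caller/oracle
equivalence, 200 null-regime pairs for the false-positive calibration,
1,000 simulated incubations per rate regime (10, 50, 150
nmol g^-1^ h^-1^), 10,000 Monte-Carlo subsamples for the rarefaction
oracle, and two full pipeline runs for the determinism check. The whole
suite completes in well under a minute.

## Known limitations

* The labelling criteria are deterministic filters; no false-discovery
  control or uncertainty on the labelled set is computed (matching the
  method being implemented).
* Quantitative enrichment (qSIP-style atom-fraction-excess from density
  shifts) is out of scope.
* The default CsTFA calibration and density windows are conventions;
  results on real gradients depend on supplying the laboratory's own
  calibration.
* delta-^13^C handling covers delta computation and two-point VPDB
  normalization only — no drift or ^17^O corrections.
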