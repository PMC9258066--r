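# methylosip

Identify ¹³C-labelled methanol-utilizing bacteria from RNA stable isotope
probing (SIP) gradient data, and estimate potential methanol consumption
rates from ¹⁴C radiotracer incubations.

## Who this is for

Microbial ecologists running substrate-SIP experiments on plant-associated
(phyllosphere / rhizosphere) or other communities: you have per-fraction
amplicon count tables from paired ¹³C-treatment and ¹²C-control density
gradients, refractometry readings per fraction, and scintillation time
series from ¹⁴C trap incubations — and you want reproducible labelled-taxon
calls and biomass-normalized turnover rates, with the supporting diversity
summaries and δ¹³C scale normalization.

## The method

**Label calling.** For each taxon *i*, let *h¹³ᵢ* be its relative abundance
in the pooled heavy fraction of the ¹³C gradient, *ℓ¹³ᵢ* in the light
fraction of the same gradient, and *h¹²ᵢ* in the heavy fraction of the
paired ¹²C control. The taxon is called ¹³C-labelled iff

1. *h¹³ᵢ* > *h¹²ᵢ*  (above the control's heavy fraction),
2. *h¹³ᵢ* > K·*ℓ¹³ᵢ* with K = 2  (heavy-over-light enrichment; K is low
   because short incubations label RNA only partially),
3. *h¹³ᵢ* ≥ 0.05 %  (abundance floor).

Gradients are paired by (species, compartment, timepoint); fraction heavy /
light classes come from buoyant density windows, with refractometry
converted by a linear, configurable calibration. A taxon absent from the
light fraction is compared against a depth-aware pseudo-abundance
(1 / (2 × light read depth)) in criterion 2.

**Rate estimation.** Cumulative trapped ¹⁴CO₂ activity is regressed on
time (ordinary least squares, free intercept); the potential consumption
rate is `slope / (specific_activity × dry_mass)` in nmol g dry wt⁻¹ h⁻¹,
with trap mass-balance bookkeeping and the NaOH/BaCO₃ cross-check as QC.

A synthetic-data generator (`simulate_gradient_experiment()`,
`simulate_trap_series()`, `make_study_design()`) emulates the full paired
study design with known ground truth, so the whole chain is testable
end-to-end. See the methods vignette
(`vignettes/methylosip-methods.Rmd`) for the generative model and every
numerical convention.

## Worked example

```r
library(methylosip)

# simulate one paired gradient experiment with 5 truly labelled taxa
sim  <- simulate_gradient_experiment(sip_sim_params(seed = 42))
meta <- classify_fractions(sim$meta)
pair <- build_gradient_pairs(sim$table, meta)[[1]]
calls <- call_labelled(pair)
calls
#> 13C label calls [T_officinale, phyllosphere, 24 h]
#>   20 taxa evaluated (K = 2, floor = 0.05%); 5 labelled
#>  taxon_id abund_heavy_c13 abund_heavy_c12 abund_light_c13
#>    OTU001          0.3766          0.0790          0.0209
#>    OTU002          0.0461          0.0109          0.0034
#>    OTU003          0.1358          0.0300          0.0082
#>    OTU004          0.1975          0.0458          0.0092
#>    OTU005          0.1632          0.0450          0.0075
```

Each listed taxon passed all three criteria: its heavy-fraction abundance
exceeds the control's (column 3), is more than twice its own
light-fraction abundance (column 4), and clears the 0.05 % floor. Here the
caller recovered exactly the 5 taxa the generator labelled.

```r
summarize_calls(calls, sim$truth$taxonomy)
#>                 group labelled_abundance n_taxa
#> 2 Alphaproteobacteria          0.6245322      2
#> 3 Gammaproteobacteria          0.2277178      2
#> 1      Actinobacteria          0.1477500      1
```

The labelled community profile: shares of the heavy-fraction abundance,
renormalized over labelled taxa, aggregated at class level.

```r
inc <- simulate_trap_series(trap_sim_params(true_rate = 149, seed = 7),
                            label = list(species = "T_officinale",
                                         compartment = "phyllosphere",
                                         replicate = "rep1"))
fit_turnover(inc$series)
#> Methanol turnover fit [T_officinale, phyllosphere, rep1]
#>   slope:      722.022 Bq/h (intercept 0.917 Bq, R^2 = 1.0000)
#>   rate:       144.40 nmol g dry wt^-1 h^-1
#>   recovery:   CO2 0.40%, methanol 96.50%, total 96.90%
```

The fitted rate (144.4) is the trapped-CO₂ rate: the generator's NaOH
traps catch 97 % of released CO₂, and 0.97 × 149 ≈ 144.5. Recovery lines
report the trap mass balance as percentages of the administered activity.

`run_pipeline("out/", sip_config(rng_seed = 1))` chains every stage and
writes `calls.tsv`, `summary_by_class.tsv`, `rates.tsv`, `diversity.tsv`
and a checksummed `manifest.json`; reruns with the same seed and
configuration are byte-identical. A thin command-line wrapper lives at
`inst/scripts/methylosip.R`.

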