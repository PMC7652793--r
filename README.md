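# herbivoc

Analysis pipeline for insect-herbivory effects on plant volatile (BVOC)
emissions measured by branch-enclosure sampling, from raw GC–MS peak tables
to publication-level statistics: emission rates, dose–response and
mixed-model treatment tests, blend composition, and phenotypic integration of
the volatile blend.

## Scientific problem

Insect feeding changes not only *how much* volatile material a plant emits
but how *coordinated* the blend is. In subarctic mountain birch exposed to
geometrid-moth larvae, green leaf volatiles, the homoterpene DMNT and
monoterpenes are strongly induced by feeding damage, while the correlation
structure of the blend loosens: branches with low feeding damage show high
*phenotypic integration* (tightly intercorrelated compound emissions) and
branches with high damage show low integration. Quantifying both effects from
enclosure experiments requires a chain of processing steps — blank
correction, compound filtering, proxy quantification, leaf-area normalised
emission rates, randomized-block mixed models, and eigenvalue-based
integration indices — that this package implements end to end.

## The model

**Emission rate.** For a branch enclosed in a chamber with clean inflowing
air, the emission rate of a compound is

```
ER = (C_out − C_in) · Q / LA,        C_in = 0
```

where `C_out` is the compound concentration in the sampled air (collected
cartridge mass divided by the air volume pulled through the cartridge), `Q`
the chamber inflow rate and `LA` the branch leaf area. `emission_rate()`
returns ng cm⁻² h⁻¹; 90 ng collected over 15 min at 200 mL min⁻¹ cartridge
flow, 300 mL min⁻¹ inflow and 200 cm² leaf area gives exactly 2.7.

**Treatment statistics.** Per-compound-group emission totals are tested
against larval density with a linear mixed model on `log(x+1)`-transformed
rates (density fixed, block random, ML) and Tukey-letter displays
(`fit_density_effect()`), and regressed on the realised percentage of leaf
area eaten (`regress_on_damage()`).

**Phenotypic integration.** Within a damage group, `integration_index()`
computes the variance of the eigenvalues of the compound correlation matrix,
`Σ(λᵢ − 1)² / (p − 1)` — 0 for independent compounds, `p` when all
correlations are ±1. `relative_integration()` subtracts the random-covariation
reference `(p − 1)/n` and expresses the result as a percentage of the maximum
`p`; `connectance()` is the fraction of compound pairs with significant
pairwise correlations. `compare_pi()` contrasts low- vs high-damage groups
across experiments with a two-group F test.

**Synthetic data.** `synthetic_truth()` + `simulate_experiment()` generate
full raw datasets (cartridge masses, sample/leaf/compound metadata, blanks)
from a documented generative model: randomized complete blocks, density-driven
feeding damage, class-specific induction, and a damage-group-dependent
latent-factor correlation structure (strong common factor under low damage,
weak under high). Defaults emulate a subarctic birch larval-density
experiment; `study_truth()` provides the three field-design presets.

## Worked example

```r
library(herbivoc)

truth <- study_truth("Abisko1")
sim <- simulate_experiment(truth, seed = 42)
sim
#> Synthetic enclosure experiment Abisko1
#> BVOC dataset: 23 cartridges x 23 compounds
#>   samples: 20 branch, 3 blank; experiments: Abisko1
#>   blank subtracted: FALSE
#>   damage groups: low=13, high=7

ct <- aggregate_groups(sim$emissions, sim$data$compounds)
pct <- sim$data$leaves$percent_eaten

regress_on_damage(ct$total, pct)
#> Damage regression: slope 0.623 +/- 0.0442 ng cm-2 h-1 per % eaten
#>   (r2 = 0.92, p = 3.65e-11, n = 20)

branch <- sim$data$samples[sim$data$samples$sample_type == "branch", ]
fit_density_effect(ct$total, branch$larval_density, branch$block_id)
#> Larval-density effect (log(x+1) LMM)
#>   overall F-test p = 0.000411
#>   Tukey letters:
#>   0   5  15  30  50
#> "a" "a" "a" "a" "b"

integrate_group(sim$emissions[sim$groups == "low", ], "low")
#> Phenotypic integration [low]: n = 13, p = 23
#>   int_raw = 12.270 (random expectation 1.692)
#>   relative integration = 46.0% of maximum
#>   connectance = 0.77

integrate_group(sim$emissions[sim$groups == "high", ], "high")
#> Phenotypic integration [high]: n = 7, p = 23
#>   int_raw = 6.053 (random expectation 3.143)
#>   relative integration = 12.7% of maximum
#>   connectance = 0.15
```

Comparing integration across the three experiment presets:

```r
pis <- sapply(c("Abisko1", "Abisko2", "Tromso"), function(e) {
  s <- simulate_experiment(study_truth(e), seed = 42)
  c(low  = integrate_group(s$emissions[s$groups == "low", ],  "low")$int_relative,
    high = integrate_group(s$emissions[s$groups == "high", ], "high")$int_relative)
})
round(pis, 1)
#>      Abisko1 Abisko2 Tromso
#> low     46.0    44.5   32.0
#> high    12.7    20.7    7.7

compare_pi(pis["low", ], pis["high", ])
#> PI comparison over 3 experiments
#>   low:  40.85 +/- 4.42
#>   high: 13.66 +/- 3.79
#>   F(1,4) = 21.80, p = 0.00952
```

Feeding damage raises emissions (total slope 0.62 ng cm⁻² h⁻¹ per % eaten)
while integration drops from ~41% to ~14% of maximum — the qualitative
signature the pipeline is designed to detect.

The full pipeline (preprocessing → emission rates → statistics →
integration, with all result tables written to disk) runs from a single
config:

```r
run_pipeline(list(simulate = TRUE, outdir = "results"), seed = 1)
```

or from the command line via `inst/cli/herbivoc.R`:

```sh
Rscript inst/cli/herbivoc.R all --config config.yaml --seed 1 --outdir results
```

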