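---
title: "Nitrifier abundance balance in oxic marine sediments: methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Nitrifier abundance balance in oxic marine sediments: methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(nitribalance)
```

## The scientific question

Nitrification proceeds in two coupled steps: ammonia-oxidizing archaea
(AOA) convert ammonia to nitrite, and nitrite-oxidizing bacteria (NOB)
convert nitrite to nitrate. In a well-oxygenated environment where nitrite
does not accumulate, the bulk rates of the two steps must balance, which
ties the standing cell abundances of the two guilds to their physiology.
If AOA synthesize $y$ times the biomass per mole of nitrogen oxidized and
carry $q$ times the carbon per cell relative to NOB, the expected
cell-abundance ratio is

$$ \frac{[\mathrm{AOA}]}{[\mathrm{NOB}]} \;=\; \frac{y}{q}. $$

With isolate-derived trait ranges for marine nitrifiers — yield ratio
1.6–3.1 (mean 2.3) and cell-quota ratio 0.20–0.63 (mean 0.30) — the
established theoretical band is roughly 2.6–15.8 with a central value
near 6.9. Observed AOA:NOB ratios in oxic deep-sea sediments often exceed
this band badly when only the canonical NOB families (Nitrospiraceae,
Nitrospinaceae) are counted as nitrite oxidizers. The package quantifies
that mismatch and how far it is resolved by reattributing a candidate NOB
lineage (an uncultivated phylum whose OTUs are classified inconsistently
across reference databases) to the nitrite-oxidizer guild.

## The analysis pipeline

1. **Guild assignment** (`assign_guilds()`): OTUs are mapped to guilds by
   case-insensitive exact match of lineage names at stated ranks. The
   candidate lineage is a *verification filter*: only an explicit,
   user-supplied list of independently verified OTU ids is counted, because
   the lineage's database taxonomy is unstable. An OTU matching two guild
   patterns is a hard error; we refuse to resolve such conflicts silently.
2. **Abundance reconstruction** (`relative_abundances()`,
   `absolute_abundances()`): a guild's relative abundance in a sample is
   the sum of its member OTUs' count fractions; its absolute abundance is
   that fraction times the total cell number, operationalized as the sum of
   archaeal and bacterial 16S qPCR copies per gram. No 16S copy-number
   correction is applied — the estimate is deliberately the simple product,
   so qPCR noise cancels exactly in AOA:NOB ratios taken within a sample.
3. **Redox zoning** (`infer_opd()`, `split_redox_zones()`): the oxic zone
   is delimited by the oxygen penetration depth (OPD). A measured OPD
   always takes precedence; otherwise the OPD is inferred as the shallowest
   depth where linearly interpolated porewater O2 crosses a threshold
   (default 1 µM — a conventional microsensor detection-limit scale; the
   inference is insensitive to the exact value when O2 declines steeply).
   The boundary is closed: a sample exactly at the OPD is oxic.
4. **Ratio statistics** (`sample_ratios()`, `summarize_ratios()`,
   `fit_abundance_regression()`): per-sample AOA:NOB ratios in the oxic
   zone are summarised by their median with a seeded percentile bootstrap
   confidence interval, plus counts of samples above/below the band edges.
   Ordinary least squares of AOA on NOB on the raw (untransformed) scale
   provides the complementary slope estimate; both intercept conventions
   are reported because neither is canonical for this design.
5. **Reattribution** (`reattribution_analysis()`): all of step 4 is run
   twice on the identical oxic sample set — NOB as the canonical families
   only, and NOB including the candidate lineage. If the candidate truly
   carries a fraction $f$ of NOB cells, excluding it inflates every ratio
   by exactly $1/(1-f)$, so the ratio of the two medians is itself an
   estimate of the candidate's share.
6. **Composition** (`nob_composition()`): per-sample fractions of the
   three NOB lineages among total NOB, and their depth-averaged values per
   core, computed by trapezoidal integration over the sampled oxic depths
   divided by the sampled span.
7. **Occurrence screening** (`screen_sample()`): reads match a query 16S
   sequence iff strictly longer than 200 bp and strictly above 95%
   identity; samples with fewer than 10 matching reads are discarded, and
   only samples whose matching-read relative abundance strictly exceeds
   0.1% are retained for mapping. All boundaries follow the strict
   phrasing of the screening protocol; the identity denominator is the
   documented overlap convention below, a stated stand-in for whatever the
   original screening service used internally.

## Sequence identity convention

`pairwise_identity()` uses semi-global (free end-gap) alignment — match
+1, mismatch −1, linear gap −2, terminal overhangs free — and defines
identity as matches divided by aligned columns, excluding terminal gap
columns. A short amplicon against a full-length gene is therefore scored
over the overlap only. The implementation is
`Biostrings::pairwiseAlignment(type = "overlap")` with PID1 identity; the
test suite checks it against an exhaustive dynamic-programming oracle on
short words. Reads are screened in both orientations and the better strand
is taken. MAG-to-OTU links take the best-identity OTU, with ties broken by
longer alignment and then lexicographic id, and require a configurable
minimum identity (default 95%).

## The synthetic-data generator

`generate_dataset()` builds multi-core datasets with exactly the
structure the analysis assumes, so every stage is testable without any
download:

* **Depth structure.** All nitrifier abundances decay exponentially with
  depth at `decay_per_cm` (default 0.03 cm⁻¹). An exponential is the
  simplest monotone profile and makes the trapezoid stage checkable
  against closed-form integrals. Real profiles are not exponential; no
  test here certifies profile *shape* recovery on real data.
* **The oxic-zone ratio.** Inside the oxic zone the true AOA:total-NOB
  cell ratio is exactly `r_true` (default 10) and the candidate lineage
  carries `f_candidate` (default 0.65) of all NOB cells, split between an
  oxic-specialist species and an anaerotolerant species. Both defaults sit
  in the middle of the ranges reported for oxic deep-sea sediments.
* **Anoxic behaviour.** Below the OPD, AOA and canonical NOB are
  attenuated by a further exponential (`anoxic_attenuation`, 0.2 cm⁻¹)
  while the anaerotolerant candidate species persists at a constant floor
  (`candidate_floor_frac`, 0.5 of its abundance at the OPD). This is an
  illustrative, not mechanistic, rendering of candidate persistence in
  anoxic sediment; nothing downstream depends on its exact form because
  the balance analysis is restricted to the oxic zone.
* **Observation model.** Amplicon counts are one multinomial draw per
  sample at `read_depth` (default 30,000 reads, a realistic modern run);
  qPCR totals get multiplicative lognormal noise (`qpcr_sigma`, default
  0.3 — roughly the replicate scatter typical of sediment qPCR). Setting
  `amplicon_model = "expected"` replaces the multinomial by its
  expectation so that "all noise off" is genuinely deterministic; the
  expected counts are real-valued but still sum to the read depth.
* **Background community.** `background_otus` non-nitrifier OTUs with
  lognormal surface abundances (sdlog 1) around `background_mean_cells`
  (2 × 10⁷ cells g⁻¹ each, i.e. a community of order 10⁹ cells g⁻¹ with
  nitrifiers at a few percent, as in organic-poor oxic sediment).
* **Reproducibility.** One root seed; each core draws from a derived
  sub-stream, so adding a core never changes earlier cores.

What the generator does *not* emulate: compositional correlations among
background taxa, chimeras/contamination, primer bias, depth-dependent
read depth, and bioturbated or non-monotone profiles. Passing tests
demonstrate the statistical machinery is correct under the stated model,
not that the model captures every feature of field data.

## Numerical and design choices

* **Band provenance.** `theoretical_band()` defaults to the literature
  constants (2.6, 6.9, 15.8) because the band computed from the *rounded*
  published traits — low $=1.6/0.63$, central $=2.3/0.30$, high
  $=3.1/0.20$, i.e. (2.540, 7.667, 15.500) — does not reproduce them
  exactly; the unrounded trait values behind the published band are not
  available. Both modes are exposed and the discrepancy is flagged
  whenever the computed band is printed.
* **Confidence interval.** Percentile bootstrap of the median, default
  10,000 resamples, always seeded. A percentile bootstrap was chosen
  because the ratio distribution is strongly right-skewed and the interval
  is reported on the median, not the mean; its empirical coverage is
  verified in the test suite at the 90% level over 500 replicates of 100
  lognormal ratios.
* **Zero-NOB samples** have no finite ratio and are excluded from ratio
  statistics (and reported), but a zero is a legitimate regression point,
  so they are retained in the OLS fits. This asymmetry is deliberate.
* **Depth averaging** integrates over the sampled span only — no
  extrapolation to the sediment surface or to the OPD — to avoid
  inventing unobserved data; with fewer than two in-zone samples it
  refuses rather than guessing.
* **Degenerate inputs** fail loudly: all-zero samples, non-increasing
  depth grids, zero-variance regressors, empty read sets and empty
  candidate guilds each raise a classed error or warning naming the
  offending sample, core or field.

## Problem sizes

The shipped tests and the acceptance script run on synthetic studies of
2–5 cores with 5–20 depths per core (up to 100 oxic samples), 30,000
reads per sample, 10,000-resample bootstraps for reported intervals, and
a 500-replicate coverage study with 400-resample bootstraps — sizes
chosen to mirror the scale of published sediment-core compilations while
keeping a full run in minutes on one CPU.

## A worked example

```{r example, eval = FALSE}
cfg <- system.file("extdata", "synthetic_config.yaml", package = "nitribalance")
result <- run_pipeline(cfg, out_dir = "nitribalance_out")
result                      # plain-text report
tidy(result$reattribution)  # both arms as a tibble
plot_ratio_arms(result$reattribution)
```

## Known limitations

* Absolute abundances inherit every bias of the qPCR totals and of 16S
  copy-number variation; ratios within a sample are robust to the former
  but not the latter.
* The theoretical band assumes tightly coupled, balanced ammonia and
  nitrite oxidation; it is not expected to hold in anoxic or strongly
  fluctuating settings, which is why the analysis is restricted to the
  oxic zone.
* Candidate-lineage membership rests entirely on the user-supplied
  verified OTU list; the package cannot re-derive that phylogenetic
  verification.
* The screening identity convention is a documented stand-in for the
  original screening service's internal definition; absolute retained
  counts may differ even when the threshold logic is identical.
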