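# resptyper

Time-resolved analysis of how soil bacterial and archaeal populations
respond to **top-down control** (grazing by a bacterivorous nematode,
"A") crossed with **bottom-up control** (maize litter amendment, "M") in
factorial soil microcosm experiments sampled over ~32 days. The package
is aimed at microbial ecologists working with 16S rRNA gene ASV count
tables plus qPCR totals from such designs, and at anyone who wants a
fully synthetic, ground-truthed testbed for trajectory-based community
analysis.

## What it computes

Given an ASV × sample read-count table, per-sample treatment metadata,
and qPCR-measured total 16S copies g⁻¹ dry soil:

1. **Absolute abundances** — counts are scaled per sample so that
   `value(i,s) = count(i,s)/depth(s) · total(s)`; columns sum to the
   qPCR totals.
2. **Selection cascade** — ASVs must be *dominant* in ≥ 1 sample (the
   per-sample dominant set has size ²D, the Hill number of order 2 /
   inverse Simpson, rounded half-up), *prevalent* (detected in ≥ 2/3
   replicates of every treatment × day cell, shared day-0 baselines
   counting for both nematode arms), and *responsive* (Pareto rule: the
   top-scoring prefix holding 80 % of the summed trajectory ranges).
3. **Response typing** — per-(ASV, treatment) replicate-mean
   trajectories are screened for temporal stability, z-scored, pooled
   across treatments and clustered (k-means, k = 9, 25 restarts), then
   merged onto five canonical archetypes by template correlation:
   **A** steady decline, **B** minimum at day 8 with recovery,
   **C** steady increase, **D** peak at day 4, **E** peak at day 8 —
   or **STABLE**.
4. **Patterns & succession** — the ordered 4-tuple of an ASV's types
   over (−A/−M, −A/+M, +A/−M, +A/+M) is its response pattern; patterns
   are ranked by summed median abundance, and grazing-susceptible ASVs
   are split into succession groups I/II/III by their type under
   combined grazing + litter.
5. **Compositional beta diversity** — Bayesian-multiplicative zero
   replacement, centred log-ratio transform, Aitchison-distance PCA and
   adjusted-R² variance partitioning over maize / nematode / day.
6. **Soil respiration** — alkali-trap titration records convert to
   rates via `(HCl_blank − HCl_sample) · 2.2 · 1000 / (soil DW · h)`
   (µg CO₂ g⁻¹ h⁻¹), with a kernel-smoothed peak-day estimate.

A seeded synthetic generator (`simulateDataset()`,
`simulateRespiration()`) produces complete datasets with planted
response types, baselines and respiration peaks, so every stage is
testable end-to-end without external data.

## Worked example

```r
library(resptyper)

sim <- simulateDataset(simConfig(preset = "recovery"), seed = 7)
x   <- sim$experiment          # AsvExperiment: 200 ASVs x 54 samples

sel <- selectResponsiveAsvs(x)
sel
#> SelectionReport
#>   dominant in >=1 sample: 86 ASVs
#>   prevalent:              157 ASVs
#>   responsive (Pareto 80%): 37 ASVs (coverage 0.801)

a <- assignResponseTypes(x, sel, seed = 42)
table(a$response_type)
#>      A      B      C      D      E STABLE
#>      8     12     31     54     41      2

p <- assemblePatterns(a, x)
head(rankPatterns(p, coverage = 0.8)$table[, c("pattern", "n_asvs")], 2)
#>         pattern n_asvs
#> D,D,D,D D,D,D,D      6
#> E,E,E,E E,E,E,E      5

rsim <- simulateRespiration(respConfig(), seed = 7)
respirationSummary(rsim$titrations)$peaks
#>   treatment peak_day peak_rate
#> 1     -A/-M     12.0 0.6617671
#> 2     -A/+M     12.0 1.1407546
#> 3     +A/-M      6.0 0.6700271
#> 4     +A/+M      5.5 1.1586458
```

Reading the output: of 200 simulated ASVs, 37 survive the
dominance → prevalence → Pareto cascade (their summed trajectory ranges
cover 80.1 % of the community's responsiveness). Their 148 trajectories
are dominated by litter-driven peaks (types D and E); the most abundant
cross-treatment patterns are the uniform `D,D,D,D` and `E,E,E,E`. The
respiration peak sits near day 12 without the nematode and near day 6
with it — the planted top-down signal, recovered by the smoother.

The full pipeline (selection → typing → patterns → composition →
respiration, with TSV outputs and a YAML run manifest) runs as:

```r
runPipeline(pipelineConfig(), "out/", seed = 42)
```

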