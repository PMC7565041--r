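# flimfret

Quantification of nanoscale chromatin compaction from FLIM-FRET
microscopy, for germline imaging assays in which two tagged histone H2B
copies — a GFP donor and an mCherry acceptor — report nucleosome
proximity: compaction brings donor and acceptor within FRET range
(<10 nm), quenching the donor and shortening its fluorescence lifetime.

The package is aimed at microscopists and computational biologists who
want a tested, scriptable version of the standard TCSPC analysis chain:

* **Simulation** — TCSPC photon cubes for synthetic gonad fields with
  known per-pixel FRET ground truth (`genotypePreset()`,
  `simulateScene()`): multinomial shot noise at realistic photon budgets,
  optional Gaussian IRF and uniform background, contiguous compaction
  domains per nucleus, and genotype presets realizing a
  wildtype-vs-COMPASS-mutant contrast.
* **Decay fitting** — per-pixel mono-/bi-exponential fits by Poisson
  maximum likelihood (`fitMono()`, `fitBi()`, `fitMap()`), with masked
  3×3 spatial binning, photon thresholds, model-corrected tail
  background, and a vectorized map fitter.
* **FRET mapping** — donor-only reference τ_D from mono-exponential fits
  (`donorReference()`), per-pixel efficiency

  E = 1 − τ_DA / τ_D

  (`fretEfficiency()`, `fretMap()`), and decomposition into the four
  FRET populations *sub-low / low / intermediate / high*
  (`classifyFret()`) used as compaction proxies.
* **Statistics** — per-gonad two-tailed unpaired t tests
  (`tTestGroups()`), Bonferroni, Kruskal–Wallis-gated Wilcoxon,
  chi-square + Benjamini–Hochberg FDR for phenotype tables, and qPCR
  relative quantification with two reference genes (`qpcrFoldChange()`).
* **Pipeline** — `runPipeline(runConfig(...))` ties
  simulate → fit → fret → classify → compare together with CSV/TIFF
  outputs, YAML configs, full seed determinism, and a run log embedding
  the resolved configuration. A thin CLI wrapper lives at
  `inst/scripts/flimfret.R`.

## Worked example

A small synthetic genotype contrast (3 gonads per genotype, 96×96
fields at the standard photon density):

```r
library(flimfret)
cfg <- runConfig(seed = 42, nGonads = 3L, nDonorGonads = 2L,
                 imageShape = c(96L, 96L), nNuclei = 5L,
                 outDir = tempfile())
res <- runPipeline(cfg)
res$donorReference
#> DonorReference: tauD = 2.4913 ns (sd 0.01012, n = 10 ROIs)
res$statsTable
#>         metric        group1              group2 mean1  mean2 statistic  p.value
#> 1        meanE wildtype-like compass-mutant-like 0.125 0.0847     22.86 2.17e-05
#> 2      sub-low wildtype-like compass-mutant-like 0.242 0.4217    -26.18 1.26e-05
#> 3          low wildtype-like compass-mutant-like 0.351 0.3625     -1.23 2.85e-01
#> 4 intermediate wildtype-like compass-mutant-like 0.266 0.1553     13.45 1.77e-04
#> 5         high wildtype-like compass-mutant-like 0.141 0.0605     20.49 3.35e-05
```

Reading the table: the mutant's per-gonad mean FRET efficiency drops
(0.125 → 0.085, i.e. less compact chromatin), its sub-low population
roughly doubles, and the intermediate and high populations shrink —
while the low class does not change significantly. Each row is a
two-tailed unpaired t test across per-gonad values. The per-gonad and
per-nucleus tables (`res$gonadTable`, `res$roiTable`) and a run log are
written under `cfg$outDir`.

The methods — the decay model, fitting objective, class-boundary
calibration, and what the simulations do and do not emulate — are
documented in `vignettes/flim-fret-methods.Rmd`.

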