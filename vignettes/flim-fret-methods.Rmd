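---
title: "Quantifying nanoscale chromatin compaction by FLIM-FRET: models and methods"
author: "flimfret"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Quantifying nanoscale chromatin compaction by FLIM-FRET}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(flimfret)
```

## The assay

In germ cells co-expressing two tagged copies of histone H2B — a GFP donor
and an mCherry acceptor — Förster resonance energy transfer (FRET) between
neighbouring nucleosomes reports on nanoscale chromatin compaction: energy
transfer is efficient only when donor and acceptor sit within roughly
10 nm, so denser packing quenches the donor. Quenching shortens the donor's
excited-state lifetime, and fluorescence lifetime imaging microscopy (FLIM)
by time-correlated single photon counting (TCSPC) measures that lifetime in
every pixel: each detected photon is timed relative to the laser pulse, and
each pixel accumulates a decay histogram over the acquisition.

The per-pixel FRET efficiency is

$$E = 1 - \tau_{DA} / \tau_D,$$

where $\tau_{DA}$ is the mean donor lifetime in the presence of the
acceptor and $\tau_D$ the unquenched donor lifetime measured in a
donor-only strain. Pixels are then grouped into operational FRET
populations — *sub-low*, *low*, *intermediate*, *high* — that serve as
proxies for increasing compaction, and genotypes are compared on per-gonad
mean $E$ and per-gonad class fractions.

This package implements the full computational chain — TCSPC simulation
with known ground truth, per-pixel decay fitting, efficiency mapping,
class decomposition, and the group statistics — so that the genotype
contrast (e.g. wildtype vs a COMPASS/SET1 mutant with decompacted
chromatin) can be validated end to end against known truth.

## The decay model and its fitting

A mono-exponential decay sampled at bin centres $t_i$ over one laser
period $T$ gives bin probabilities

$$q_i(\tau) \propto (1-\beta)\, e^{-t_i/\tau} + \beta / W,$$

with $\beta$ a uniform-in-time background fraction over the $W$ bins of
the fit window. With the per-pixel total fixed by the acquisition time,
bin counts are multinomial, and the package's default estimator maximizes
the corresponding Poisson/multinomial log-likelihood
$\sum_i n_i \log q_i(\tau)$ — the correct noise model at TCSPC photon
counts, where least-squares weights are unreliable. Weighted least squares
is retained as an option (`method = "ls"`).

Numerical choices:

* **Fit window.** Without an instrument response function (IRF) the fit is
  a tail fit from the histogram maximum; with a Gaussian IRF
  (`irf = list(sigmaNs, centerNs)`) the full window is fit through the
  convolution model. The IRF is parametric-Gaussian only — enough to test
  fitter robustness without modelling detector afterpulsing.
* **Optimization.** The mono fit is a 1-d likelihood optimization
  (`optimize` with a local polish to ~1e-8 ns); map fitting vectorizes the
  same objective across all masked pixels (coarse log-spaced lifetime grid
  via one matrix product, then bracketed golden-section refinement to
  well below 1e-3 ns). The bi-exponential fit uses Nelder–Mead on
  log-lifetimes and a logit amplitude, initialized from the mono fit at
  $(0.5\hat\tau_0, 1.5\hat\tau_0)$ with equal amplitudes.
* **Background.** $\beta$ defaults to a model-corrected tail estimate: the
  observed mean of the last 5% of bins minus the fitted decay's own
  expected tail, clipped to $[0, 0.5]$. A naive tail average would book
  the decay's tail as background and bias $\tau$ low by ~1%; the
  correction keeps the bias well below that. Co-estimation
  (`background = "fit"`) and none are available. Map fits use a single
  field-level $\beta$ from the pooled masked histogram: the uniform
  background is a property of the acquisition, and the pooled estimate is
  both more stable than per-pixel tails and fully vectorizable.
* **Mean lifetime.** For multi-component fits the reported
  $\tau_m = \sum a_i \tau_i / \sum a_i$ is amplitude-weighted, the
  convention behind "mean fluorescence lifetime" maps; the
  intensity-weighted alternative can be derived from the reported
  components.
* **Degeneracy.** A bi-exponential fit collapses to mono (flagged) when
  its lifetimes coincide within 5% or when the likelihood-ratio against
  the nested mono fit falls below the $\chi^2_2$ 0.99 quantile — either
  way the data carry no evidence for a second component.
* **Thresholds.** Fits with fewer than 500 photons in the window error
  out (maps mark those pixels missing rather than using them). At the
  emulated count rates (~$10^5$ photons/s, 60 s, $256^2$ pixels, i.e.
  ~90 photons per raw pixel) single pixels are photon-poor, so maps
  default to 3×3 spatial binning (`binRadius = 1`).
* **Masked binning.** Binning windows sum in-mask neighbours only
  (default). ROI outlines exist to exclude extra-nuclear signal; letting
  edge windows absorb out-of-mask background photons biases edge
  lifetimes up and, through the donor reference, shifts every efficiency.
  With masked binning the donor reference is unbiased to within
  ~0.1%.

The Poisson-MLE fit is validated in the test suite against an independent
dense grid search of the same likelihood (1 fs grid) and recovers
$\tau = 2.5$ ns at $10^4$ photons with |bias| < 1% and SD < 5%.

## The synthetic scene generator

`simulateScene()` renders a ground-truth scene description
(`sceneSpec()`/`genotypePreset()`) into a photon cube:

1. Nuclei are disks (pachytene-like, radius ≈ field/14, 6–12 per field)
   placed on a jittered grid; overlapping nuclei resolve to the later
   nucleus in the table, and nuclei must lie fully inside the field.
2. Each nuclear pixel gets a FRET class. By default classes form
   **contiguous domains**: a Gaussian-smoothed noise field
   (`domainSigmaPx`, default 6 px) is cut at the quantiles of the
   nucleus's mixing fractions, which makes per-nucleus class fractions
   exact and reproduces the discrete compaction regions seen in real
   nuclei. Independent per-pixel assignment (`classField = "iid"`) is
   available, but note that under spatial binning iid classes are
   unresolvable by construction — every binned window then mixes classes.
3. The field photon budget (default 5e6 ≈ 8.5 × 10^4 photons/s over a
   60 s acquisition, within the emulated instrument's count-rate band) is
   split over pixels by one multinomial draw, with nuclear pixels at
   plateau weight 1 and outside pixels at `outsideIntensity` (default
   0.02) receiving pure uniform-in-time background. Each pixel's photons
   are then multinomially distributed over time bins according to its
   class's expected decay. Total photons equal the budget exactly.
   Independent-Poisson bins are available per pixel via
   `simulatePixel(poissonBins = TRUE)`.
4. The cube records the full ground truth (class labels, true E, nucleus
   labels) and the seed; generation is a pure function of the spec.

**Class efficiencies.** The four class E values default to
(0.0125, 0.0875, 0.1625, 0.3375). The classification boundaries
(0.05 / 0.125 / 0.25) are then each exactly midway between their two
neighbouring class efficiencies. This placement is deliberate: threshold
classification of a noisy $E$ estimate exchanges pixels across each
boundary, and with boundary-centred classes the exchange is symmetric, so
recovered class fractions are free of systematic drift between classes.
The gaps also exceed ~2.5 standard deviations of the per-pixel $E$ noise
at the default photon budget ("well-separated"). Absolute class
efficiencies in the source assay are instrument- and construct-specific;
these values are package configuration, not measured constants, and both
the scheme and the class E values are plain arguments.

**Genotype presets.** Presets encode only the qualitative contrast the
assay reports: relative to `"wildtype-like"` mixing fractions
(0.25, 0.35, 0.25, 0.15), the `"compass-mutant-like"` preset
(0.42, 0.36, 0.15, 0.07) raises the sub-low fraction and depletes the
intermediate and high fractions, lowering mean E. The exact numbers are
configuration chosen to give a clear but not caricatured contrast.
`"donor-only"` sets every pixel to the unquenched donor (E = 0 in all
classes) and is used both for the $\tau_D$ reference and as an end-to-end
null control.

**What the generator does not emulate.** No acceptor-channel photons,
spectral bleed-through, photobleaching, diffraction/PSF optics (nuclei
are intensity masks), detector afterpulsing, or autofluorescence. Passing
tests therefore validate the estimation chain under the stated noise
model — they do not certify performance against optical artefacts real
samples can show.

## FRET mapping and class profiles

The donor reference $\tau_D$ is the arithmetic mean of per-ROI mean
lifetimes across donor-only samples, mono-exponential fits only (a
bi-exponential donor-only input is rejected as a contract violation);
its dispersion is reported. $\tau_D$ is global per batch — the donor-only
strain is measured separately from the FRET samples — with a per-gonad
option available by building one reference per gonad.

Efficiency maps apply $E = 1 - \tau_m/\tau_D$ pixelwise. Negative values
(noise around $E = 0$) are retained: clamping at zero would bias the
per-ROI mean E, the assay's headline statistic; the class scheme's lowest
class is unbounded below so such pixels land in sub-low. Class intervals
are left-closed and right-open.

Per-gonad values — pixel-count-weighted means over the gonad's nuclei —
are the sampling unit for genotype comparisons, matching how the assay
counts its n (gonads, not pixels or nuclei).

## Statistics

The comparison layer mirrors the assay's published analyses, delegating
the standard tests to base R and keeping the configuration explicit in
the outputs:

* `tTestGroups()` — two-tailed unpaired t test on per-gonad values;
  Student's equal-variance by default (the conventional reading of an
  "unpaired t test" with no stated variance assumption), Welch
  recommended when variances differ.
* `bonferroni()` — $p \cdot m$ clipped at 1, for small families of
  planned comparisons (e.g. brood sizes across temperatures).
* `kruskalThenWilcoxon()` — pairwise rank-sum tests gated on a
  significant Kruskal–Wallis omnibus (α = 0.05 by default, recorded in
  the result); midrank tie handling; with two groups the omnibus is
  skipped with a warning.
* `chisqFdr()` — Pearson chi-square without continuity correction on
  2 × k phenotype count tables, Benjamini–Hochberg FDR across the
  comparison family; expected counts below 1 trigger an exact-test
  recommendation.
* `qpcrFoldChange()` — relative quantification with amplification
  efficiency 2 and two reference genes (pmp-3, cdc-42 by default).
  Per-well quantity $2^{-C_t}$; the normalizer is the geometric mean of
  the two reference quantities (standard multi-reference practice; the
  arithmetic mean is an option); fold changes are condition means of
  normalized quantities relative to the control condition, and
  replicate-level values are retained for t tests.

Each of these is cross-checked in the test suite against an independent
oracle: full permutation enumeration for the t test (n = 3 + 3), exact
rank-sum enumeration at n = 10 + 10, the direct
$\sum (O-E)^2/E$ expansion, BH monotonicity, and an independently coded
two-reference ΔΔCt implementation.

## The pipeline and reproducibility

`runPipeline(runConfig(...))` orchestrates simulate → fit → FRET →
classify → compare, writing per-ROI and per-gonad CSV tables, the
genotype-comparison table, optional float-TIFF lifetime/FRET maps, and a
run log embedding the fully resolved configuration and package version.
Every stochastic stage derives its seed deterministically from the master
seed, so identical configurations reproduce output tables bit for bit.
Configurations can be loaded from YAML (`readRunConfig()`), and photon
cubes round-trip through an on-disk container of multi-page TIFF plus
JSON metadata (`writePhotonCube()`/`readPhotonCube()`), with masks as
16-bit label TIFF/PNG. Pixel conventions are 0-based, row-major (y, x) in
all file I/O.

Automated nucleus segmentation (`segmentNuclei()`: Otsu threshold,
connected components, distance-map watershed, small-object removal, via
EBImage) is a convenience fallback; manual masks are the first-class
input, and segmented masks carry a `"segmented"` source flag into
downstream tables. On default synthetic scenes the class profiles from
segmented vs ground-truth masks agree within 0.05 per class.

## Problem sizes

Validation and the bundled analyses run on 128 × 128 fields with the
photon budget scaled to keep the default per-pixel photon density
(5e6 photons per 256 × 256 field), 6 nuclei per field, and 10–20 gonads
per genotype — the fit-noise regime per binned pixel is then identical to
the full-size configuration while a complete genotype contrast runs in a
few minutes on one core.

## Known limitations

* The mono-exponential map fit reports an effective mean lifetime for
  pixels that genuinely mix FRET states; binned windows straddling domain
  boundaries blur class assignment (quantified in the tests, and the
  reason boundary-centred class placement matters).
* The Gaussian IRF is a convenience model; measured IRFs are not
  supported.
* Incomplete-decay wrap-around is off by default
  (τ/T ≈ 0.2 makes the truncation error negligible); a periodic wrap
  option exists on the forward model.
* No reader for proprietary TCSPC vendor formats; import goes through
  the documented TIFF + JSON container.
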