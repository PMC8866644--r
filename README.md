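# nirsnet

Block-design fNIRS activation, connectivity and brain-network analysis in R.

## What this package is for

Functional near-infrared spectroscopy (fNIRS) measures cortical hemoglobin
concentration changes through light attenuation at two wavelengths, one
series per source–detector channel. In clinical neuromodulation studies a
block-design fNIRS session answers three questions: *which channel is most
activated by the task* (the stimulation target, e.g. for high-frequency
rTMS over language cortex), *how channels co-fluctuate* (functional
connectivity), and *how hemispheric network topology changes across
treatment timepoints*. `nirsnet` implements that full pipeline for
researchers analysing such recordings — and, because clinical recordings
are rarely shareable, ships a forward simulator with known ground truth so
every stage is testable.

The pipeline stages, each exposed as ordinary functions:

1. **Optics** — modified Beer–Lambert law. Per channel and wavelength,
   `ΔOD(t,c,λ) = L_c · DPF_λ · [ε_HbO(λ) ΔC_HbO + ε_HbR(λ) ΔC_HbR]` with
   `ΔOD = −log10(I/I0)`; the two-wavelength 2×2 system is solved exactly
   (`hemoglobinFromOD()`), and the forward map is its exact inverse.
2. **Preprocessing** — automated spike/discontinuity detection and repair,
   then zero-phase Butterworth band-pass (0.01–0.2 Hz) of the oxyHb series.
3. **Activation** — per-channel GLM with a canonical double-gamma HRF,
   DCT drift basis, HRF precoloring with sandwich variance and Satterthwaite
   effective degrees of freedom; the *hotspot* is the channel maximising
   `|t|` among channels with `p < α`, with `α` relaxed from 0.05 in 0.001
   steps until a channel passes.
4. **Connectivity** — pairwise Pearson correlations, Fisher z-transform
   (`z = atanh r`), group-averaged z matrices, strong edges at `z > 1.0`
   (the upper 15.87% of a standard normal).
5. **Networks** — hemispheric graphs binarized over the whole sparsity
   range; clustering coefficient and global efficiency profiles; paired
   Wilcoxon comparisons across sessions reported as significant sparsity
   ranges (`p < 0.1` per point).
6. **Group statistics** — asymptotic tie-corrected Wilcoxon signed-rank and
   Friedman tests, the conventions that reproduce printed clinical p-values
   for small longitudinal cohorts.

See the methods vignette (`vignettes/fnirs-network-pipeline.Rmd`) for the
models, parameter defaults with units, and the simulator's scope.

## Worked example

The packaged clinical fixture holds the five-patient K-WAB scores of the
motivating cohort (aphasia quotient AQ and language quotient LQ at T0 =
pre-treatment, T1 = one day post, T2 = one month post):

```r
library(nirsnet)
scores <- loadClinicalScores()
aq <- scoreMatrix(scores, "AQ")
wilcoxonSignedRank(aq[, "T0"], aq[, "T1"])
#> 	Wilcoxon signed-rank test (asymptotic, tie-corrected, no continuity
#> 	correction)
#> data:  aq[, "T0"] vs aq[, "T1"]
#> W+ = 15, n = 5, p-value = 0.04311
friedmanRankTest(aq)$p.value
#> [1] 0.04978707
```

All five patients improved from T0 to T1 (`W+ = 15`, the maximum possible
rank sum), significant at p = 0.043; across all three timepoints the
Friedman test gives p = 0.0498 (0.049 at three truncated decimals). The
same calls on LQ give p = 0.042 (two equal differences engage the tie
correction) and p = 0.0498.

Simulating a study-sized cohort (5 subjects × 3 sessions, 26 channels,
480 s block design) and running the full pipeline:

```r
cohort <- simulateCohort(seed = 42)
config <- pipelineConfig(sparsityGrid = seq(0.05, 1, by = 0.05), seed = 42L)
report <- runPipeline(config, cohort, clinical = scores)
report
#> nirsnet pipeline report
#>   hotspots:
#>    subject session channel alphaUsed
#> 1      S01      T0       5      0.05
#> 2      S01      T1       5      0.05
#> ...
#> 13     S05      T0      11      0.05
#>   T0: 0 strong edges
#>   network comparisons: 8, 5 with significant ranges
```

Every subject-session's hotspot is exactly the channel the simulator
activated (5, 8, 10, 10, 11 — the default per-subject sites), at the
starting threshold α = 0.05. With the default moderate latent correlations
no group-mean edge exceeds z = 1.0, and the "significant" sparsity ranges
between statistically identical sessions illustrate exactly what the
per-point α = 0.1 convention without multiplicity correction can produce —
the report documents both behaviours rather than hiding them.
`writeReport(report, "out/")` writes `results.json` plus per-stage TSV
tables; reruns with the same seed are byte-identical.

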