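---
title: "Block-design fNIRS activation, connectivity and network analysis with nirsnet"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Block-design fNIRS activation, connectivity and network analysis with nirsnet}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(nirsnet)
options(nirsnet.quiet = TRUE)
```

# The analysis problem

Continuous-wave fNIRS instruments record light attenuation at two
wavelengths (here 760 and 850 nm) for each source-detector pair
("channel"). In a block-design language experiment — an initial rest
period followed by task blocks alternating with control blocks — those
recordings support three analyses that `nirsnet` implements end to end:

1. **Activation mapping**: which channel responds most strongly to the task?
   In therapeutic settings this "hotspot" becomes the target of
   neuromodulation (e.g. high-frequency rTMS over the most activated
   language-related channel).
2. **Functional connectivity**: which channel pairs co-fluctuate, summarized
   as a Fisher-z correlation matrix and its strong-edge graph?
3. **Network topology**: how do hemispheric graph metrics — clustering
   coefficient and global efficiency — change across treatment timepoints,
   profiled over the whole range of graph sparsity?

Because clinical recordings of this kind are rarely shareable, the package
pairs every stage with a forward simulator whose ground truth (activation
amplitudes, latent correlation structure, noise composition, seeds) is
known, so each algorithm's recovery behaviour is testable.

# Models and procedures

## Optical conversion (modified Beer-Lambert law)

For channel $c$ with source-detector separation $L_c$ (cm) and
differential path-length factor $\mathrm{DPF}_\lambda$, an optical-density
change relates to chromophore concentration changes (mol/L) by

$$\Delta OD(t, c, \lambda) = L_c \,\mathrm{DPF}_\lambda
  \left[\varepsilon_{HbO}(\lambda)\,\Delta C_{HbO}(t,c) +
        \varepsilon_{HbR}(\lambda)\,\Delta C_{HbR}(t,c)\right],$$

with $\Delta OD = -\log_{10}(I/I_0)$. Two wavelengths give an exactly
solvable $2 \times 2$ linear system per sample (`hemoglobinFromOD()`), and
the forward map (`odFromHemoglobin()`) is its exact inverse — the round
trip is tested to machine precision. Defaults pin DPF to 7.25/6.38 at
760/850 nm and the extinction coefficients to the Gratzer/Prahl
compilation; because published compilations differ, the table id is
recorded in every `OpticsParams` and the condition number of the
extinction matrix is logged. Absolute agreement with any particular
instrument's vendor constants is therefore not a goal; all downstream
statistics are invariant to a fixed linear rescaling of concentrations.

## Preprocessing

Analysis uses oxyHb, the component most sensitive to cortical blood-flow
change. Artifact screening is automated (clinical practice often does this
manually): spikes are samples deviating from a 2 s moving median by more
than 5 robust SDs, discontinuities are first differences beyond 5 robust
SDs *that leave the signal level shifted* — large differences that revert
immediately are spikes, which is what distinguishes an impulse from a step.
Two numerical details matter: the uncentered moving-median windows at the
recording edges are excluded from spike detection (they would false-alarm
on any curved signal; the jump detector still covers the edges), and spike
flags within half a window of a detected discontinuity are attributed to
the discontinuity, whose median residual they reflect. Flagged spans are
repaired by linear interpolation between clean neighbours (boundary spans
copy the nearest clean value).

Band-pass filtering is a cascade of 4th-order Butterworth high-pass
(0.01 Hz) and low-pass (0.2 Hz) sections, each applied forward-backward,
so the net filter has zero phase and the pass band is flat; a single
band-pass design with a normalized low edge of ~0.005 would be numerically
fragile. The block fundamental (1/60 Hz for 30 s alternating blocks) lies
comfortably in band; cardiac (~1 Hz) and respiratory (~0.25 Hz) components
are rejected, while Mayer waves (~0.1 Hz) are in-band by construction —
an acknowledged limitation of this conventional band choice. Filtering is
applied to concentrations; since both the MBLL and the filter are linear,
the order of conversion and filtering is mathematically immaterial.
Recordings shorter than three high-pass time constants ($3/f_{low}$) are
refused rather than filtered badly.

## GLM activation and the hotspot rule

The task regressor is the task-minus-control boxcar convolved with a
canonical double-gamma HRF. Each gamma is parameterized by its **mode**
(`shape = delay/dispersion + 1`, `scale = dispersion`), so the kernel peak
falls exactly at the nominal 6 s peak delay (with a 16 s undershoot of
relative weight 1/6 and 32 s support, normalized to unit peak). Slow drift
is modelled by a discrete-cosine basis with $K = \lfloor 2T/128\,\mathrm{s}
\rfloor$ components, plus an intercept.

Inference uses *precoloring*: data and design are smoothed with the HRF
kernel $S$, imposing a known temporal covariance $V = SS^{\top}$ that
dominates any residual intrinsic autocorrelation. The task t-statistic
uses the sandwich variance
$\widehat{\mathrm{Var}}(c^\top\hat\beta) = \hat\sigma^2\, c^\top (X^{*\top}
X^*)^{-1} X^{*\top} V X^* (X^{*\top} X^*)^{-1} c$ with $X^* = SX$,
$\hat\sigma^2 = r^\top r / \mathrm{tr}(RV)$, and Satterthwaite effective
degrees of freedom $\mathrm{tr}(RV)^2/\mathrm{tr}(RVRV)$. The naive OLS
variance would be miscalibrated under the covariance the method itself
imposes; with the sandwich form the empirical type-I error at nominal 0.05
stays inside its binomial band in the null simulations the test suite
runs. With an identity kernel the machinery reduces to ordinary OLS with
$df = n - p$, which the tests check against the correlation closed form.
Everything about the (design, kernel) pair — including the $O(n^2)$
covariance traces — is precomputed once in `glmOperator()` and shared
across channels, subjects and simulations.

The hotspot is the channel with the largest $|t|$ among channels with
$p < \alpha$, starting at $\alpha = 0.05$ and relaxing in steps of 0.001
until non-empty. Three conventions are deliberate: the strict inequality
$p < \alpha$; sign-blind $|t|$ (a strong deactivation can be selected, and
the pipeline report flags when it is); and ties on $|t|$ breaking to the
lowest channel id, logged. The strict inequality is evaluated with a
$10^{-12}$ guard so p-values lying exactly on the alpha grid do not pass
through floating-point representation accidents (0.06 must fail at
$\alpha = 0.060$ and pass at $0.061$).

## Connectivity

Pearson correlations between all unordered channel pairs of the processed
oxyHb series, Fisher-transformed ($z = \mathrm{atanh}\, r$) before any
averaging or thresholding. The correlation window defaults to the full
processed recording; a `task_blocks` option concatenates task blocks only
(which window the field's studies use is often unstated, so both are
provided). Group averages are elementwise means of $z$ across subjects
with pairwise exclusion of undefined entries. Edges with mean $z$ above
1.0 count as strong connectivity; for standard-normal edge weights that
cut retains the upper $1 - \Phi(1) = 15.87\%$, which the suite verifies by
simulation. An alternative reading of "z-scores" — standardizing the
observed z distribution so the threshold is its upper 15.87% point — is
possible; this package implements the Fisher-transform reading and keeps
the threshold configurable rather than claiming either convention as
canonical.

## Hemispheric networks over sparsity

A weight matrix is binarized at sparsity $S$ by retaining the
$\mathrm{round}(S\,n(n-1)/2)$ largest-weight pairs. Ranking uses the
signed z (most positive first): a positive threshold on "strength of
connectivity" implies positive coupling; ranking by $|z|$ is available as
an option. Ties at the cut resolve by lexicographic pair order,
deterministically. Thresholding is nested — the edge set at $S_1$ is
contained in the edge set at $S_2 \ge S_1$ — which makes global efficiency
non-decreasing in $S$, a property the tests assert.

Hemispheric profiles restrict the weights to one hemisphere's channels and
re-rank within the subgraph (sparsity is hemisphere-local, matching
per-hemisphere reporting); a whole-montage option exists. Metrics are the
binary variants: clustering coefficient
$C = \mathrm{mean}_i\, 2t_i/(k_i(k_i-1))$ (zero for degree < 2) computed
from the adjacency cube's diagonal, and global efficiency
$E = \mathrm{mean}_{i \ne j}\, 1/d_{ij}$ with BFS hop distances and zero
contribution from disconnected pairs. Both are verified *exactly* against
brute-force triangle enumeration and Floyd-Warshall on random graphs up to
$n = 8$ — the oracles deliberately share no code with the implementation.

Between-session comparison runs a paired two-sided Wilcoxon signed-rank
test across subjects at every grid point (default grid 0.01–1.00 in 0.01
steps) and reports contiguous runs of $p < 0.1$ as significant sparsity
ranges with their p extremes and direction. The per-point alpha of 0.1
with no multiplicity correction across sparsity mirrors how such profile
ranges are conventionally reported, and is flagged as such: ranges are
descriptive, not family-wise error controlled.

## Group statistics

`wilcoxonSignedRank()` and `friedmanRankTest()` implement the asymptotic,
tie-corrected, no-continuity-correction conventions: zero differences
dropped before ranking; Wilcoxon variance
$n(n+1)(2n+1)/24 - \sum(t^3-t)/48$ over tied-rank groups $t$; Friedman
statistic $(k-1)\sum_j (R_j - n(k+1)/2)^2 / (\sum r_{ij}^2 -
nk(k+1)^2/4)$ with within-subject midranks. These are the only
conventions under which the packaged five-patient worked example
reproduces its printed trio of p-values (0.043 and 0.042 for the
T0-vs-T1 Wilcoxon tests on AQ and LQ — the LQ case engages the tie
correction through two equal differences — and 0.049 for both Friedman
tests, where the printed three-decimal value reflects truncation of the
computed 0.0498). Both functions are cross-checked in the suite against
the independent base-R implementations (`wilcox.test(exact = FALSE,
correct = FALSE)`, `friedman.test`) and, for the two-condition Friedman
case, against an exhaustive sign-permutation null.

# The synthetic cohort generator

`simulateCohort()` emulates the motivating study design: 5 subjects,
3 sessions (T0/T1/T2), 26 channels from 12 sources and 10 detectors at
3 cm separation over Broca, Wernicke and adjacent areas (13 channels per
hemisphere in the default symmetric montage), 2 min initial rest followed
by six 30 s task blocks alternating with six 30 s control blocks (480 s
total). The sampling rate is never hard-coded; the default is 3.91 Hz,
typical of LED arrays time-multiplexing this many sources.

Each subject's oxyHb is
$\beta_c \cdot (\mathrm{boxcar} \otimes \mathrm{HRF})(t)$ plus: AR(1)
noise (coefficient 0.3, innovation SD $2\times10^{-7}$ mol/L) whose
innovations are correlated across channels through the Cholesky factor of
a target correlation matrix, making latent correlations exact in
expectation; sinusoidal physiological confounds (cardiac 1.0 Hz at
$10^{-7}$, respiration 0.25 Hz at $8\times10^{-8}$, Mayer 0.1 Hz at
$5\times10^{-8}$ mol/L, each with channel-specific random phase); linear
drift ($4\times10^{-10}$ mol/L/s); and sparse motion spikes added in the
*optical-density* domain (0.5/min, 0.05 OD), where motion artifacts
physically arise. Surrogate deoxyHb is $-0.3 \times$ oxyHb plus small
independent noise — a simulation convenience, not a physiological claim;
the analysis consumes oxyHb only. Intensities are produced by the exact
MBLL inverse, so the conversion stage has a machine-precision ground
truth. The default activation amplitude $5\times10^{-8}$ mol/L per
regressor unit yields ~1 µM peak responses, the realistic scale; each
default subject's single active channel follows the study's stimulation
sites (channels 5, 8, 10, 10, 11).

The latent correlation structure is **modular below the hemisphere
level**: one module per hemisphere-region block (broca/wernicke/adjacent
× left/right), within-module correlation 0.3, between-module 0.1. This
matters: sparsity thresholding is rank-based and therefore invariant to a
uniform rescaling of a hemisphere's correlations, so a hemisphere-wide
uniform block could never change the thresholded topology. Only
sub-hemispheric modularity lets a within-module correlation increase
raise the clustering coefficient at fixed sparsity — which is also the
realistic structure of regional cortical coupling. Session overrides
(e.g. raising the left-hemisphere modules' $r_w$ from 0.3 to 0.6 at a
later session) emulate a treatment-induced network change with a known
direction, and the recovery experiment in the acceptance suite detects a
significant higher-left-clustering range in nearly all replicate cohorts.

What the generator does **not** emulate: photon transport and partial
volume effects, scalp/systemic components and short-separation channels,
subject motion beyond additive OD impulses, session-to-session optode
repositioning, and non-stationary or task-correlated noise. Passing
recovery tests therefore demonstrate algorithmic correctness under the
stated statistical model, not robustness to everything real recordings
contain.

# Problem sizes and numerical choices

Test and acceptance experiments use these sizes, chosen to give stable
rates at interactive runtimes: 200–250 null simulations for GLM
calibration (binomial 95% band ±0.03 around 0.05); 100 recovery runs at
the default activation amplitude plus 40 each at $1\times10^{-9}$ and
$2\times10^{-9}$ mol/L to probe the monotone recovery transition; 20
replicate 5-subject two-session cohorts for the network-change
experiment, profiled on a 0.05-step sparsity grid; 50–60 random graphs
($n \le 8$) for the exact metric oracles; $n = 10{,}000$ samples for
latent-correlation consistency (±0.05).

Other numerical decisions, collected: PSD repair of infeasible latent
correlation targets by eigenvalue clipping with renormalized diagonal,
logged, with an entrywise repair tolerance of 0.05 before erroring;
undefined (NA) correlations excluded pairwise from group averages and
ranked last (never selected before any defined weight) in thresholding;
perfect correlations ($|r| = 1$) masked rather than propagated as
infinite z; the DCT basis is orthogonal by construction and drift
components added to data leave the task t-statistic unchanged to
numerical precision; all channel indices are 1-based in montage order;
every stochastic routine requires an explicit seed, and cohort
subject-session seeds derive deterministically from the master seed, so a
pipeline run is a pure function of (config, data, seed) — reports are
byte-identical across reruns.

# Known limitations

Hotspot p-values are per-channel uncorrected (no correction across the 26
channels), matching field practice for target selection; the sign-blind
hotspot rule can select deactivations (flagged in the report); the
network-range alpha of 0.1 is per-point and descriptive; with 5 subjects
the paired Wilcoxon's asymptotic p at an all-positive difference pattern
is ~0.043 (~0.025 with tied magnitudes), so range detection at alpha 0.1
is feasible but coarse; SNIRF/HDF5 recordings are out of scope — the
supported on-disk dialect is the documented wide CSV plus TSV montage;
and weighted graph metrics, partial correlations, lagged connectivity,
short-separation regression and wavelet motion correction are
deliberately not provided.
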