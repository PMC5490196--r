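---
title: "Shifting level models for copy-number segmentation: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Shifting level models for copy-number segmentation: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(slmcnv)
```

## The model and its assumptions

A log2-ratio genomic profile $x = (x_1, \dots, x_N)$ is modelled as a
piecewise-constant latent mean observed through Gaussian white noise:

$$x_i = m_i + \varepsilon_i, \qquad \varepsilon_i \sim N(0, \sigma^2_\varepsilon),$$
$$m_i = (1 - z_{i-1})\, m_{i-1} + z_{i-1} (\mu + \delta_i), \qquad
  \delta_i \sim N(0, \sigma^2_m),$$

with i.i.d. jump indicators $z_i \in \{0, 1\}$,
$\eta = \Pr(z_i = 1)$. The model assumes (i) additive, homoscedastic,
uncorrelated Gaussian noise on the log2 scale; (ii) rare jumps
($\eta \ll 1$), each resetting the level independently of its past; and
(iii) a single chromosome per profile — the Markov chain has no meaning
across chromosome boundaries, so multi-chromosome inputs are split
first.

Because the level process is Markov and the emission is conditionally
independent given the level, this is a hidden Markov model, and the
jointly most probable level path is computed exactly by the Viterbi
algorithm. The heterogeneous variant replaces $\eta$ by a per-step
probability
$\eta(d_i) = \theta + (1-\theta)\exp\{\log(\theta)/(d_i/d_{Norm})\}$
driven by the genomic gap $d_i$ between adjacent windows: $\eta(d)$
increases continuously from $\theta$ (at $d \ll d_{Norm}$) toward 1,
letting distant windows (sparse exome targets) change level freely while
adjacent windows remain tightly coupled.

## State-space discretisation

The continuous level process is embedded as a $K$-level HMM. Candidate
levels are the data quantiles between 0.005 and 0.995 (default
$K = 41$), deduplicated and re-spaced evenly over the same range if
quantiles collapse. Quantile placement adapts resolution to where the
data mass actually sits: a profile containing a deletion devotes grid
levels to the deleted cluster without any prior knowledge of copy
states. The prior over levels is the $N(\mu, \sigma^2_m)$ density
evaluated at the grid, floored at `1e-300` and renormalised so every
state keeps positive mass.

Jumps land on level $k$ with prior probability $\pi_k$ independently of
the origin, giving the transition matrix
$A[j,k] = (1-\eta)\,\mathbf{1}[j{=}k] + \eta\,\pi_k$. This structure
makes the Viterbi recursion $O(NK)$ instead of $O(NK^2)$: the best
predecessor of state $k$ is either $k$ itself (stay) or the globally
best-scoring state (jump). The recursion is implemented in C++ and its
log-domain arithmetic matches sums over the dense matrix entries
bitwise, which is how the exhaustive-enumeration oracle tests verify it.

## Parameter estimation

Estimation is a single moment pass (no expectation–maximisation loop, to
keep results reproducible and fast):

* $\mu$ = median of the data.
* $\sigma^2_\varepsilon$ = $\mathrm{MAD}(\Delta x)^2 / 2$, the squared
  normal-consistent median absolute deviation of the first differences,
  halved. First differences cancel the piecewise-constant mean
  everywhere except at breakpoints, and the MAD ignores the rare
  shift-crossing differences, so this scale identifies the *white-noise*
  variance specifically. Identifying it as the total variance instead
  would hand the decoder an emission variance several-fold too small
  whenever most of the signal is noise, and pure-noise profiles would be
  shredded into spurious segments; this identification was the one
  genuinely open design choice in the estimator, and the package
  resolves it in favour of the noise interpretation.
* $\omega$ (default 0.3) is the assumed noise share of the total model
  variance: $\sigma^2_{total} = \sigma^2_\varepsilon / \omega$ and
  $\sigma^2_m = (1-\omega)\,\sigma^2_{total}$, so
  $\sigma^2_\varepsilon : \sigma^2_m = \omega : (1-\omega)$. $\omega$
  only shapes the level prior's width; the decoder's emission variance
  is the directly estimated $\sigma^2_\varepsilon$.
* Degenerate inputs (constant profiles) are flagged and short-circuit to
  a single segment. Noise-free step profiles, where the MAD of
  differences is exactly zero, fall back to the overall variance so the
  decode still runs.

## Tunable parameters

| Parameter | Default | Units | Role |
|---|---|---|---|
| `eta` | `1e-5` | probability/step | SLM jump rate; smaller = fewer, larger segments |
| `theta` | `1e-5` | probability/step | HSLM baseline jump rate at zero gap |
| `d_norm` | `1e5` | bp | gap scale where $\eta(d)$ starts rising toward 1 |
| `omega` | 0.3 | fraction | assumed noise share of total variance (prior width) |
| `n_levels` | 41 | count | level-grid size $K$ |
| `min_seg_windows` | 1 | windows | post-hoc merge threshold (1 = raw model output) |
| `loss/gain thresholds` | −0.5 / +0.3 | log2 | CNV calling cutoffs around −1 and +0.585 |

`eta` and `theta` default to the rare-jump regime the model assumes;
they are the natural sensitivity knobs and are what the ROC sweep
varies. `d_norm = 100` kb keeps typical intra-gene target gaps (1–10 kb)
in the coupled regime while inter-gene deserts decouple. The calling
thresholds bracket the theoretical diploid one-copy (−1) and three-copy
(+0.585) log2 levels with margin for noise on segment means.

Held fixed by design: $\eta$ is not re-estimated (the single-pass
estimator plus Viterbi is deterministic; an iterative re-fit would add a
schedule without adding information the tests could check), and decoded
paths are mapped to *empirical* segment means — the arithmetic mean of
each segment's observed values — rather than to grid levels, since the
grid is a numerical device whose spacing should not quantise reported
effect sizes.

## Numerical choices

* All decoding happens in log space; $\eta(d)$ evaluates the exponent as
  $\log(\theta)\, d_{Norm}/d$, and $d = 0$ returns the analytic limit
  $\theta$. For $d \lesssim d_{Norm}/10$ the exponential underflows
  below double resolution and $\eta(d)$ equals $\theta$ exactly — which
  is the stated small-distance limit, not an error.
* Viterbi ties break toward the lower level index, via smallest-index
  argmax at every step and at the final state; the decoded path is the
  reverse-lexicographically smallest optimum, and the brute-force oracle
  applies the same rule.
* Inter-window distance is the gap `start_i − end_{i−1}`, floored at 0,
  so contiguous tilings reduce HSLM to SLM bit-identically.
* Segments shorter than `min_seg_windows` are absorbed into the
  neighbour with the closer mean (left neighbour on exact ties), means
  recomputed from the pooled windows.
* Zero read counts take a half-count pseudo-count before the log2
  transform and are flagged, keeping deep deletions visible as strongly
  negative finite values.
* Tables are written with 17 significant digits so round-trips are
  bit-exact.

## What the simulator emulates — and what it does not

`simulate_profile()` reproduces the structure of a standard read-depth
benchmark: 10000 contiguous windows, one embedded event of $N$ windows
shifted by the theoretical one-copy (−1) or three-copy (+0.585) log2
level, Gaussian noise of configurable standard deviation, uniformly
random event placement with at least one background window per flank.
`coverage_noise_sd()` ties the noise scale to sequencing parameters via
the Poisson delta method: at coverage $c$, window size $w$ and read
length 100, $\lambda = c\,w/100$ and
$\mathrm{sd} = 1/(\ln 2\,\sqrt{\lambda})$, flagged below
$\lambda = 10$ where the Gaussian approximation degrades.
`simulate_sparse_profile()` adds log-uniform inter-window gaps on
$[1, \text{max\_gap}]$ for exome-like data, drawing values before gaps
so the same seed yields the same signal at any sparsity.

Deliberately not emulated: resampling of real read counts (the noise
here is exactly the Gaussian the model assumes), GC and mappability
bias structure of real genomes, correlated or heavy-tailed noise,
replication artefacts, and multiple events per profile (single event by
default, matching the one-event-in-10000-windows recipe). Passing tests
therefore demonstrate correctness of the algorithms under their own
model and calibrated noise scales — not performance on real sequencing
data, where normalization residuals and non-Gaussian noise will erode
the margins.

## Evaluation conventions

Viterbi produces hard calls without scores, so ROC operating points are
generated by sweeping the jump probability (the model's own sensitivity
knob). A true breakpoint counts as detected if a prediction lies within
a tolerance (default 2 windows); the FPR denominator is the number of
candidate breakpoint positions not within tolerance of any true
breakpoint, making the negative class explicit and counts comparable
across runs. The curve is anchored at (0,0) and (1,1) and integrated by
trapezoid, so a segmenter that never predicts scores exactly 0.5.
CNV-level evaluation uses the any-overlap rule — one shared base pair
makes a call a true positive — with the stricter default that the call's
direction (LOSS/GAIN) must match the truth; a flag relaxes this to pure
overlap. Precision and recall are stratified by truth-interval length
into Small (< 20 kb), Medium (20–100 kb) and Large (≥ 100 kb), and the
F-measure is the harmonic mean.

## Problem sizes used by the test suite

The packaged checks run at sizes chosen to exercise the full study
structure while staying desk-scale: exhaustive-enumeration oracles on
200 random instances with $N \le 8$, $K \le 4$; breakpoint recovery and
false-positive control on 100 seeded 10000-window profiles each;
detection-rate trends over event sizes $\{2, 5, 10, 50, 100\}$ at 100
replicates; ROC sweeps of $\eta \in \{10^{-7}, \dots, 10^{-2}\}$ over up
to 100 profiles; 20-seed parameter-recovery checks at $N = 10^4$.

## Known limitations

* Single-sample, univariate segmentation only; no joint multi-sample
  model.
* Normalization is a generic stratified-median GC correction with a
  mappability cutoff, not a replacement for a platform-specific
  pipeline; it assumes covariates are supplied per window.
* The Gaussian emission is sensitive to heavy-tailed outliers only
  through the robust variance estimate; isolated extreme windows can
  still nucleate one-window segments at permissive `eta`
  (`min_seg_windows` exists for exactly that case).
* On pure-noise profiles with no true structure the quantile grid spans
  noise quantiles; detection there is controlled by `eta`, and the
  packaged checks verify the default keeps such profiles whole.
* The HSLM gap convention (gap, not centre-to-centre distance) matters
  only for overlapping or bookended windows, where it floors at zero.
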