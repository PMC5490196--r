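# slmcnv

Segmentation of genomic profiles for copy-number variant (CNV) detection
with **shifting level models** (SLM), including the **heterogeneous**
variant (HSLM) for spatially sparse data such as exome read counts.

Read-depth and array signals for CNV calling are mathematically alike:
an ordered, noisy sequence of window values (read counts or log2-ratios)
in which deletions and duplications appear as sudden shifts of the local
mean. The decisive analysis step is segmentation — finding the boundaries
(breakpoints) of regions with shifted mean and estimating each region's
level. `slmcnv` implements this for single log2-ratio profiles, together
with read-count normalization, a synthetic-profile simulator and
evaluation metrics, plus a command-line interface.

## The model

The observed signal is the sum of two independent processes:

    x_i = m_i + eps_i,                      eps_i ~ N(0, sigma2_eps)
    m_i = (1 - z_{i-1}) m_{i-1} + z_{i-1} (mu + delta_i),
                                            delta_i ~ N(0, sigma2_m)

`m_i` is an unobserved piecewise-constant mean level: it stays put while
the i.i.d. jump indicator `z_i` is 0 and, with probability
`eta = Pr(z_i = 1)`, resets to a fresh draw around the grand mean `mu`.
This is a hidden Markov model, so the most probable level path — and with
it the breakpoints — is recovered exactly by Viterbi dynamic programming
over a grid of candidate levels placed at data quantiles.

The heterogeneous model replaces the constant jump probability by a
function of the genomic distance `d_i` between adjacent windows:

    Pr(z_i = 1) = eta(d_i) = theta + (1 - theta) * exp( log(theta) / (d_i / d_Norm) )

`theta` is the baseline jump probability; `d_Norm` sets the distance at
which the probability starts growing from `theta` toward 1. Windows that
are far apart (e.g. consecutive exome targets on different genes) are
thereby allowed to change level much more freely than adjacent windows.
On contiguously tiled data all `d_i = 0` and HSLM reduces exactly to SLM
with `eta = theta`.

## Worked example

```r
library(slmcnv)

# a 10000-window profile with a 100-window one-copy deletion, log2 noise 0.2
sim <- simulate_profile(n_altered = 100, total_windows = 10000,
                        noise_sd = 0.2, seed = 42)
seg <- slm_segment(sim$profile)
seg
#> slm_segmentation: 10000 windows, 3 segments, 2 breakpoints
#>   start   end n_windows   mean_level
#> 1     1  2369      2369  0.004199557
#> 2  2370  2469       100 -0.977452047
#> 3  2470 10000      7531 -0.002836600

call_cnvs(seg, sim$profile)
#>   chrom   start     end copy_state mean_level n_windows
#> 1  chrS 2369000 2469000       LOSS  -0.977452       100

sim$truth$breakpoints
#> [1] 2370 2470
breakpoint_distances(seg$breakpoints, sim$truth)$truth_to_pred
#> [1] 0 0
```

The decoder finds exactly three segments; the middle one sits at a mean
of −0.98 (theoretical one-copy level: −1) and both breakpoints land on
the true positions. `call_cnvs()` converts segments to LOSS/GAIN calls
using log2 thresholds (−0.5, +0.3 by default) that bracket the diploid
one-copy (−1) and three-copy (+0.585) levels.

For sparse profiles use `hslm_segment(profile, theta, d_norm)`; the
inter-window distances come from the window coordinates. For raw read
counts, `normalize_profile()` applies GC-content median-ratio correction,
a mappability filter and the log2 transform first.

## Command line

```sh
slmcnv simulate --n-altered 100 --total 10000 --seed 7 --out sim
slmcnv segment  --mode slm --in sim.profile.tsv --out seg
slmcnv evaluate --calls seg.cnv.bed --truth sim.truth.bed
```

(`slmcnv` is installed under `<library>/slmcnv/exec/slmcnv`.)

## File formats

All tables are tab-delimited with 0-based half-open (BED-style)
coordinates. Profiles: `chrom  start  end  value` (optional `gc`,
`mappability` columns; gzip transparent; header optional). Segment
tables: `chrom  start  end  n_windows  mean_level`. CNV calls:
`chrom  start  end  copy_state  mean_level`. Numeric values are written
with 17 significant digits, so write/read round-trips are bit-exact.
Multi-chromosome inputs are split and segmented per chromosome.

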