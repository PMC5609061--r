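---
title: "Read-depth CNV calling with rdcnv: models, parameters and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Read-depth CNV calling with rdcnv}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(rdcnv)
```

# The read-depth model

If sequencing sampled fragments uniformly from the genome, the number of
reads whose leftmost mapping position falls into a window of fixed size
would be Poisson, with a mean proportional to the local copy number. Two
facts complicate this picture. First, real window counts are
overdispersed: their index of dispersion (variance/mean) is well above 1,
and a negative binomial fits the empirical distribution visibly better
than a Poisson (compare `ks_fit_distance()` under the two families on any
simulated or real profile). Second, the mean itself is biased by local GC
content (a unimodal effect of the amplification chemistry, maximal at
intermediate GC) and by mappability (ambiguous alignments depress
apparent coverage in repetitive regions).

`rdcnv` therefore works with the classical read-count pipeline:

1. tile the genome into consecutive non-overlapping windows
   (`build_windows()`), annotated with integer GC percent and a 0.1-step
   mappability bin (`annotate_gc()`, `annotate_mappability()`);
2. extract a raw per-window signal from a BAM file — read counts
   (`count_reads()`) for short reads, or mean depth of coverage
   (`mean_depth()`) when reads are longer than windows, where counting
   read starts would leave most windows nearly empty;
3. remove the two biases by *median normalization*
   (`median_normalize()`): each window value is scaled by `m / m_bin`,
   the ratio of the genome-wide median to the median of all windows in
   the same covariate bin, first for GC, then for mappability;
4. rescale so the genome-wide median equals 2 and take
   `log2(value / 2)`, putting the diploid state at 0
   (`normalize_two_copy()`);
5. segment the log2 signal with a shifting level model
   (`slm_segment()`) and classify segments into five copy-number states
   (`fit_call_model()`, `call_segments()`), optionally genotyping
   absolute copy numbers from the two-copy-scaled medians
   (`genotype_absolute()`).

Three experimental designs are wrapped by `run_analysis()`: `nocontrol`
(single sample on the absolute two-copy scale, suited to germline and
population studies), `paired` (log2 ratio of test over matched control,
the tumor/normal design — each sample is bias-corrected independently
before the ratio, so residual artefacts common to both cancel), and
`pooling` (ratio against the window-wise sum of several controls).

# Median normalization: choices that matter

*Bin granularity.* GC bins are the integer percents 0..100; mappability
bins are 0, 0.1, ..., 1. GC percent excludes ambiguous bases from both
numerator and denominator, and an all-N window is flagged unusable.
Positions absent from the mappability track count as 0 (unmappable),
which is the conservative reading of an absent annotation.

*Sparse bins.* A median over a handful of windows is unstable, and
correcting by it injects noise instead of removing bias. Bins with fewer
than `min_bin_count = 30` windows borrow the median of the nearest
well-populated bin. The correction is exactly scale-equivariant and, on
bias-free data with well-populated bins, changes values by well under 5%.

*Masking.* Windows that are unusable (all-N, short trailing window below
half the window size, zero-median bin, non-positive normalized value)
keep their coordinates but are excluded from segmentation input, so
segments may span them.

# The shifting level model

The log2 signal is modeled as `x_i = m_i + e_i`: a hidden mean level
`m_i` that persists between windows and, with a small probability `eta`
per step, jumps to a new value drawn from `N(mu, sigma2_mu)`; `e_i` is
Gaussian white noise with variance `sigma2_eps`. Discretizing the level
space turns this into a hidden Markov model with states = candidate
levels, transition matrix `(1 - eta) I + eta * 1 w'` (where `w_j` is the
normalized density of level `j` under the level process), Gaussian
emissions, and initial distribution `w`. The rank-one-plus-diagonal
transition structure admits an O(nK) Viterbi pass, which `viterbi()`
exploits; the decoder is tested for exactness against exhaustive path
enumeration on small instances.

Parameter choices (all exposed through `run_config()` /
`estimate_params()`):

- **Candidate levels**: `K = min(40, #distinct smoothed values)` equally
  spaced points spanning the range of the 5-window running-median
  smoothed signal. Smoothing keeps single-window outliers from
  stretching the grid, while events of 3+ windows still extend it to
  their level.
- **`mu` and the variance split**: `mu` is the signal mean and the total
  variance `s2` is split as `sigma2_eps = 0.9 * s2` (noise) and
  `sigma2_mu = max(0.1 * s2, (span/4)^2)`, where `span` is the spread of
  the level grid. The floor is essential: on a mostly-diploid genome,
  `s2` is almost entirely noise, and a level prior as narrow as
  `0.1 * s2` would assign astronomically small prior mass to the
  duplication level at +0.58 — jumps to it would be priced out no matter
  how strong the evidence, and duplication sensitivity would collapse to
  zero. With `span/4`, every candidate level sits within two prior
  standard deviations.
- **`eta = 1e-3`** by default. The jump penalty enters the Viterbi
  score once per breakpoint, so `eta` trades sensitivity to short events
  against false segments on noise. At `1e-3` a two-breakpoint event
  needs roughly 14 log-units of evidence; simulated noise-only
  chromosomes of 1000 windows yield on the order of 0.03 spurious
  aberrant segments each, while 10-window events at 10x coverage are
  recovered reliably. Raising `eta` further buys little sensitivity and
  multiplies false positives; the breakpoint count is empirically
  monotone in `eta` (a property the test suite checks).
- **Ties** in the Viterbi maximization are broken toward staying in the
  current state, favoring longer segments. Chromosomes are segmented
  independently; chromosomes with fewer than 10 usable windows or a
  constant signal short-circuit to a single segment.
- **Baum-Welch refinement** (off by default) re-estimates `eta` and
  `sigma2_eps` by EM sweeps with monotone log-likelihood; the
  method-of-moments initialization is the estimate otherwise. In our
  simulations refinement changes decoded segments rarely; it is provided
  for unusually structured signals.

Each segment reports both the decoded hidden level (`mean_log2`, used
for calling) and the empirical mean of its windows (`emp_mean`).

# Five-state calling and cellularity

Segment means are modeled as a mixture of five Gaussians — double loss,
loss, neutral, gain, multiple gain — whose means are anchored at the
copy-number expectations under cellularity `c` (the fraction of cells
carrying the alteration):

```
mu_k(c) = log2(max(c * CN_k + 2 * (1 - c), 0.1) / 2),   CN_k = 0..4
```

The 0.1-copy floor keeps the double-loss mean finite; real homozygous
deletions retain residual mis-mapped coverage. Each component is
truncated and renormalized to its own bracket, delimited by the
cellularity-adjusted *copy-number-space midpoints* (0.5, 1.5, 2.5, 3.5
copies, log2-transformed). At `c = 1` these bounds reproduce the
raw-scale calling thresholds — a region whose two-copy-scaled median is
at or below 1.5 is a loss, at or above 2.5 a gain — which log2-space
midpoints of the anchors would not (they would put the loss/neutral cut
at -0.5, letting a median of 1.45 copies pass as neutral). Because the
brackets are disjoint, classification reduces to thresholding the
segment mean — that is what makes the caller fast — and the reported
posterior is concentrated on the assigned state. The free parameters
(state weights, shared sd, and `c` when not fixed) are estimated by
maximum likelihood with segments weighted by their window counts;
cellularity is searched on the grid 0.1, ..., 1.0. With fewer than five
segments there is nothing to fit and fixed thresholds
(-1.5, -0.42, 0.32, 1.0) are used.

Multiple-gain segments are genotyped as `round(2 * 2^mean_log2)` when
`c = 1`, supporting 4, 5, 6+ copies. In the `nocontrol` design,
`genotype_absolute()` additionally re-estimates every call's copy number
as the rounded median of the two-copy-scaled values over the region;
when this disagrees with the five-state label, the copy number wins and
the label is re-derived, keeping the state/CN correspondence exact.

# The synthetic-data generator

The simulator reproduces the structure the benchmarks rely on, not read-
level realism. Window counts are negative binomial with mean
`base_mean * cn/2 * gc_bias(gc) * map_bias(map)` and variance
`phi * mean`:

- `base_mean = coverage_x * window_size / read_length` (read length 100
  bp), so 30x coverage with 100 bp windows gives a two-copy mean of 30;
- `phi = 3` by default — overdispersion is clearly present in real data
  but moderate; `phi = 1` recovers the Poisson limit exactly;
- the default GC bias is a unimodal factor peaking at 45% GC and falling
  by 40% at the extremes; the default mappability bias is linear from
  0.5 at mappability 0 to 1 at 1. Both default to *flat* in
  `make_synthetic_chromosome()`, which generates the benchmark unit: a
  1000-window chromosome with one deletion or duplication of N
  consecutive windows at a uniform random position.

What the generator does **not** emulate: correlated noise along the
genome, breakpoint micro-homology and imprecision, reference errors,
segmental-duplication pile-ups, or multi-event chromosomes. Passing the
synthetic benchmarks therefore demonstrates the statistical machinery —
bias removal, segmentation resolution, state assignment — under the
stated noise model, not performance on any particular real cohort.

# Evaluation statistics

`score_calls()` implements reciprocal-overlap matching: a truth event is
a true positive when some call overlaps it by at least 50% of both
lengths (the threshold test is inclusive). One truth event yields at most
one TP; extra calls matching the same event are neither TP nor FP; calls
matching nothing are FPs. Precision is NA (not 0) when there are no
calls. The pipeline benchmarks additionally require the call direction
(deletion vs duplication) to agree with the truth event.
`breakpoint_distance()` reports per-boundary distances of the
closest prediction, `cn_concordance()` the Pearson r, regression slope
and correct-classification rate of integer genotypes, and
`ks_fit_distance()` the distribution-fit distance described above.

# Benchmarks reproduced in the test suite

The acceptance tests regenerate, at reduced but statistically adequate
scale, the claims the package is built around (problem sizes chosen to
keep the full suite under a couple of minutes): 200 synthetic
chromosomes per resolution setting (5 kb events at 30x with 100 bp
windows; 10 kb events at 10x with 1000 bp windows), 100 simulations per
event size for the deletion/duplication sensitivity asymmetry (deletions
are easier: on the log2 scale their shift is larger, 1 versus 0.58, and
overdispersed noise grows with the mean), 10^5 windows for the
distribution-fit and bias-removal checks, exhaustive Viterbi
verification on 200 random small instances, copy-number genotyping of
CN 0–6 regions at 30x, and a self-paired null of 10^5 windows that must
produce no aberrant call. `scripts/acceptance.R` re-runs the headline
5 kb/30x benchmark end to end and writes the measured TPR as JSON.

# Known limitations

- The five-state model assumes a single dominant clone; subclonal
  mixtures beyond the scalar cellularity, and allele-specific copy
  number, are out of scope.
- Cellularity is searched on a coarse 0.1 grid and is not a substitute
  for joint purity/ploidy estimation.
- Median normalization corrects each covariate sequentially (GC, then
  mappability), not jointly; strong covariate interaction would leave
  residual bias.
- The segmenter assumes homoscedastic noise on the log2 scale; the true
  per-window variance depends on copy number, which is part of why
  deletions are detected more sensitively than duplications.
- Breakpoints are resolved at window granularity; no split-read or
  paired-end refinement is attempted.
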