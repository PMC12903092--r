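---
title: "Network burst analysis and fingerprinting of MEA recordings"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Network burst analysis and fingerprinting of MEA recordings}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(meaburst)
```

## Overview

meaburst analyses spontaneous activity of cultured neuronal networks
recorded on multiwell micro-electrode arrays (MEAs): 48-well plates with 16
extracellular electrodes per well (4 × 4 grid, 50 µm diameter, 350 µm
pitch), sampled at 12.5 kHz for 5-minute sessions. The pipeline starts from
spike timestamps (spike sorting and raw-voltage handling are upstream of
this package) and produces, per well, electrode bursts, classified network
bursts, and a 39-parameter activity fingerprint, together with the
multivariate analyses used to compare genotypes or treatments:
PCA/UMAP fingerprinting with loading-based parameter selection, and
burst-duration distribution comparison via an empirical-quantile exceedance
procedure.

Because real patient-derived recordings cannot ship with a package, every
stage is paired with a synthetic spike-train generator that plants known
bursts, so detectors and extractors are verified against ground truth
rather than against themselves.

## Electrode burst detection

Bursts on a single electrode are detected with the maximum-ISI algorithm:
consecutive spikes whose inter-spike interval (ISI) is at most `max_isi`
(default 0.1 s) form a candidate burst; candidates separated by less than
`merge_gap` (0.05 s) are merged; the survivors must contain at least
`min_spikes` (5) spikes and last longer than `min_duration` (0.05 s). Burst
edges are the first and last spike times, unpadded.

Three boundary conventions are fixed deliberately: an ISI *equal* to
`max_isi` joins the burst (≤), a gap *equal* to `merge_gap` does *not* merge
(<), and the duration filter is strict (>). The order of operations is
group → merge → filter. The merge rule exists so that physiologically
contiguous firing interrupted by one long ISI is not penalized; applying it
before the spike-count filter lets the merged burst pass a filter its halves
would fail, which is the rule's purpose. The alternative order (filter
first) would silently delete such bursts. The test suite checks the whole
detector against a brute-force rule interpreter on thousands of random
trains, so the semantics above are pinned, not incidental.

## Network burst detection

Well-level synchronized events are detected from the population signal:

1. spike timestamps are binned at 2 ms (half-open bins; an edge spike falls
   into the later bin);
2. each electrode's binned train is smoothed with a unit-sum truncated
   Gaussian kernel whose *total support* is the 70 ms window (35 bins), with
   σ = window/6 and reflect padding. "Window" is read as total support —
   the common DSP convention for a windowed kernel; σ and support are both
   exposed as parameters, so the ±3σ truncation is a default, not a
   hard-wired choice;
3. the smoothed signals are z-scored per electrode over the whole recording
   (a baseline-segment alternative would need a defined baseline, which a
   spontaneously bursting culture does not have), averaged across
   electrodes — the mean rather than the sum, so the combined signal does
   not change scale with the number of active electrodes — and smoothed
   again with the same kernel. Zero-variance (silent) electrodes are
   dropped with a message;
4. the combined signal is binarized at the Otsu threshold: 256 equal-width
   histogram bins over the signal range, threshold at the bin edge
   maximizing the between-class variance w₀w₁(μ₀−μ₁)², with class means
   computed from the actual signal values. Ties resolve to the lowest edge,
   making the threshold deterministic;
5. supra-threshold runs become candidate intervals (bin-edge aligned,
   half-open). A candidate is kept when (a) at least 25% of the well's
   electrodes spike inside it, (b) it lasts longer than 0.1 s, and (c) at
   least 25% of the actively participating electrodes (those with ≥ 1
   in-interval spike) sustain ≥ 12 Hz inside it. Both 25% counts round up.

### Fragmented network bursts

Short network bursts (< 0.32 s) that trail a main burst by no more than
1.1 s are classified as *fragments* — the fragmented-synchronization
signature associated with presynaptic calcium-channel gain-of-function and
seizurogenic-like activity. Classification runs left to right: a burst of
at least 0.32 s is a main and anchors a chain; a shorter burst whose gap to
the preceding burst of the chain is ≤ 1.1 s becomes a fragment anchored at
the nearest preceding main, and fragments may chain through fragments. A
short burst with no qualifying predecessor is kept as a (short) main and
anchors from there on; imposing a minimum duration on anchors was tried and
rejected, because it turns a long burst occasionally split by a brief
sub-threshold dip into two tiny-gap "mains", which distorts the network
inter-burst-interval statistics, whereas the anchor-any-main rule absorbs
the second piece as a fragment. The gap is measured to the immediately
preceding burst of the chain by default; measuring it to the anchor main
only is available via `chain_gap_mode = "main"`. Boundary ties: a duration
of exactly 0.32 s is a main; a gap of exactly 1.1 s qualifies.

## The 39-parameter feature catalogue

`feature_catalogue()` defines the per-well parameters: 8 spike-level, 14
electrode-burst-level, 12 network-burst-level and 5 fragmentation-level.
Conventions that matter:

* an electrode is *active* if it has at least one spike; well-level means
  weight electrodes equally, not by spike count;
* burst percentage and in-burst ISI are summarized as the well mean over
  electrodes, with the SD across electrodes as the companion parameter
  (that SD is itself one of the informative parameters for genotype
  contrasts);
* "IBI" at the headline level is the *network* inter-burst interval — the
  end-to-start gap between consecutive *main* network bursts — consistent
  with its use alongside the other network-level parameters; the
  electrode-level IBI is a separate named parameter;
* network burst frequency is the count of main bursts scaled to 5 minutes;
  fragments are analyzed separately and never influence main-burst
  parameters (a property the tests enforce);
* statistics needing more events than observed (e.g. an IBI with fewer than
  two bursts) are missing, never zero.

The catalogue is a data frame, so the exact published parameter list of any
particular lab can be swapped in without code changes.

## Fingerprinting and parameter selection

Feature tables are column z-scored (`scale_features`; rows with missing
values and zero-variance columns are dropped with messages), decomposed
with standard SVD-based PCA (`prcomp`), and the PCs explaining more than
2.5% of the variance are retained (use 5% for small single-cell property
tables). The retained scores are embedded in 2-D with UMAP (uwot;
neighbors 15, min_dist 0.1, single-threaded so a seed makes it
deterministic). Each PC's sign is fixed so its largest-magnitude loading is
positive, making loadings comparable across runs.

The selection chain isolates parameters by contribution: the top 10
parameters by |loading| on each of the first two retained PCs form the
*variable* set, the top 10 on each of the last two retained PCs the
*stable* set ("last" means last of the *retained* PCs, matching the
retention rule used for the embedding). Stable sets from several control
(rescue) datasets are intersected, and parameters also appearing in the
variable set are removed (`exclusive_selection`), leaving parameters that
are reliably invariant in controls yet not driven by the main axes of
patient variability. Ties in |loading| break by catalogue order, and all
selection operations are permutation-invariant and deterministic.

### The planted-structure benchmark

Verifying this chain needs tables where the right answer is known. Planting
"stable" parameters as low-variance columns does not work: column scaling
erases raw variance, so a near-constant column becomes unit-variance
independent noise and lands in the middle of the eigenvalue spectrum, not
on the trailing PCs. What actually places a parameter on the trailing PCs
of a correlation-matrix PCA is *redundancy*. `simulate_selection_tables`
therefore plants, in the rescue-like tables, two moderately correlated
parameter pairs (r = 0.30 and 0.35): each pair's difference direction has
eigenvalue 1 − r, which is the smallest retained eigenvalue by
construction, and loads only on the pair. In the patient-like table, two
10-parameter factor blocks (one driven by a two-group contrast) dominate
PC1 and PC2, so the variable set is exactly the 20 block parameters and the
planted pair parameters are excluded from it. The rescue tables use 3000
rows so that the trailing sample eigenvalues of the 20-dimensional noise
block (which scatter below 1 by roughly (1−√(p/n))²) stay clearly above the
planted 0.65–0.70 minors; the pair correlations sit where 1 − r is small
enough to be last yet still above the 2.5% retention threshold. With this
geometry the chain recovers exactly the planted parameters in essentially
every seeded replicate, which is what the acceptance checks assert.

## Burst-duration distributions and the exceedance procedure

Average-based comparisons can hide heterogeneity — for example when only a
subpopulation of neurons has undergone the developmental GABA shift — so
treatment responses are also quantified on the full distribution of main
network-burst durations. The procedure: pool basal durations per group,
take each group's nearest-rank 97.5th percentile, and set the threshold to
the *maximum* over groups. This guarantees, by construction, that at most
2.5% of basal durations exceed the threshold in *every* group (the pooled
variant is available via `mode = "pooled"`); the treated exceedance
percentage is then read off per group. The 2.5% bound is an *in-sample*
property of the basal data that defined the threshold: a fresh sample from
an unchanged network hovers around 2.5% and crosses it in roughly a quarter
of realizations, because the sample quantile's true tail probability is
Beta-distributed around the nominal level. The verification suite therefore
models a vehicle treatment as what it is biologically — no change to the
network, hence the basal duration sample itself — while the treated
condition plants a genuine tail shift. The nearest-rank quantile is used
because it is deterministic and makes the ≤ 2.5% guarantee exact; an
interpolated quantile would not. Distribution pairs are compared with the
two-sided Wilcoxon rank-sum test with continuity correction, and paired
pre/post firing rates use MFR = total spikes / (active electrodes ×
duration) — the active-electrode denominator keeps silent electrodes from
diluting the rate; it is a documented choice, not the only defensible one.

## The synthetic generator

`simulate_well` plants network-burst onsets with a Gamma renewal process
(shape 1/CoV², scale mean·CoV²), which decouples the mean inter-onset gap
(60/`nb_rate` seconds) from its regularity (`ibi_cov`) — the two quantities
the analyses contrast. Main-burst durations are log-normal
(natural-scale mean/SD parameters); each electrode joins a burst with
`participation_prob` and fires a homogeneous Poisson train at
`in_burst_rate` inside it (a boxcar profile; no within-burst rate shape is
asserted by the analyses, so none is simulated); background activity is
Poisson at `background_rate` throughout. With probability `frag_prob` a
main burst is trailed by `1 + Poisson(frag_count_mean − 1)` fragments with
uniform durations inside (0.1, 0.32) s and uniform gaps inside (0, 1.1] s,
measured from the preceding burst of the chain. Chains that would collide
with the next onset are redrawn (capped at 1000 attempts), keeping the
ground truth unambiguous. Spike times are quantized to the 12.5 kHz grid
and duplicate timestamps are dropped, so a seed reproduces a recording
bit-for-bit through a write/read round trip.

Defaults describe a mature, moderately synchronized culture: 0.5 Hz
background, 3 network bursts/min with CoV 0.3, 0.6 ± 0.15 s durations, 85%
participation, 40 Hz in-burst firing. What the generator does *not*
emulate: burst rise/decay shapes, inter-electrode latency structure within
a burst (no propagation), electrode-specific excitability, non-stationarity
over the 5 minutes, and recording artifacts. Passing recovery tests
therefore shows the detectors implement their definitions correctly under
realistic counting statistics — not that the definitions are optimal for
every biological regime.

## Problem sizes and numerical choices

The verification suite runs at deliberate sizes: oracle equivalence on
1000 random spike trains (≤ 200 spikes), 500 random signals (≤ 64 histogram
bins) and 1000 random interval lists; planted-burst recovery on 8 wells of
5-minute recordings (F1 ≥ 0.95, mean boundary error ≤ 70 ms — the smoothing
window — and fragment-label accuracy ≥ 0.9); simulator-target recovery over
20 wells per condition (within 15%); 100 seeded replicates of the selection
benchmark; and 50 replicates of the exceedance experiment with 800 bursts
per group (roughly the pooled count of a 12-well group). Degenerate inputs
are defined, not accidental: a constant signal has no Otsu threshold
(error), a silent well yields no network bursts, an empty basal group stops
the exceedance procedure, and all-silent electrode sets raise "no active
electrodes".

## Known limitations

* The Otsu threshold is recomputed per recording, so extremely sparse or
  extremely dense activity shifts the operating point; very long continuous
  high activity (no bimodality) degrades it by design.
* Long bursts are occasionally split by a brief sub-threshold dip; the
  fragment classifier absorbs the second piece, but a split into two
  ≥ 0.32 s pieces remains two mains.
* The 39-parameter catalogue fixes one reasonable operationalization of
  the common MEA parameter set; labs differ in details (weighting,
  denominators), which is why the catalogue is data, not code.
* UMAP coordinates are reproducible only under the packaged single-threaded
  settings and a fixed seed; embeddings are for inspection, not inference.
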