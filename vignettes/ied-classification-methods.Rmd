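---
title: "Methods: unsupervised IED classification and agreement analysis"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: unsupervised IED classification and agreement analysis}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

This vignette explains the models and procedures implemented in `iedclust`,
the assumptions behind them, the parameters that matter, and the design
choices we made where the method left room. It states no empirical claims
beyond what the package's own test suite computes.

## The problem

Interictal epileptiform discharges (IEDs) are transient, high-amplitude EEG
deflections with a sharp component of roughly 40–100 ms, often followed by a
slower wave. On intracranial recordings a patient typically produces several
morphologically and topographically distinct IED *classes*. Grouping a set
of detected events into classes is routinely done by eye, and different
reviewers produce appreciably different partitions. The package provides
(1) an unsupervised classifier for this task and (2) a statistical framework
for deciding whether the automated partition is distinguishable from human
partitions, given that no gold standard exists.

## Classification pipeline

### Preprocessing and alignment

Recordings are band-pass filtered 2–70 Hz with a 4th-order Butterworth
applied forward–backward (`signal::filtfilt`). Zero phase matters: any phase
distortion would shift spike peaks differently at different frequencies and
corrupt both alignment and morphology. Recordings at higher rates are
resampled (polyphase FIR with unity DC gain) to 250 Hz, which comfortably
covers the 2–70 Hz band.

Markers are assumed to sit *near* each event's peak. All epochs must share an
identical peak-relative time grid, so each marker is moved to the sample of
maximal global field power — the across-channel population standard
deviation of the instantaneous field — within ±50 ms, computed over the
channels of interest only. Ties break to the earliest sample, which makes
realignment deterministic and idempotent. The 50 ms half-width is a
compromise: wide enough to absorb human marking latitude, narrow enough that
a neighbouring background fluctuation rarely outcompetes the true peak.

Epochs run from 100 ms before to 200 ms after the aligned peak (75 samples
at 250 Hz), and the per-channel epochs are concatenated channel-block by
channel-block into one *meta-IED* vector per event. A single vector per
event lets one clustering pass use morphology and spatial field jointly —
two classes may share a waveform but differ in field, or vice versa.

### Features

Each meta-IED is decomposed with a 4-level Haar discrete wavelet transform.
Vectors are padded to the next multiple of 2⁴ by edge replication; zero
padding would manufacture a spurious step at the boundary, and the Haar
family is maximally sensitive to steps. All coefficients are retained as
candidate features.

Ten features are then selected by deviation from normality: for each
coefficient, the Lilliefors (Kolmogorov–Smirnov with estimated moments)
statistic across events. The logic: a coefficient that separates classes is
multimodal across events, while a coefficient carrying only noise is
approximately Gaussian; deviation from normality therefore ranks
class-informative coordinates without knowing the classes.

Before scoring, each coefficient is trimmed of extreme outliers — values
beyond 3 robust standard deviations (median/MAD), but never more than 10% of
events. Both halves of this rule earn their place. Without any trim, a
modest contingent of high-amplitude artifact events dominates the
Kolmogorov–Smirnov distance and the selection wastes coordinates on
artifact-driven tails. With an uncapped robust trim, the opposite failure
appears: a genuine class holding ~30% of events can lie entirely beyond
3 MAD-sd of the median and be trimmed away wholesale, making its
coordinates look Gaussian and leaving that class unrepresented in the
selected space (where it then sits at the origin and attracts everything
else near the origin). Capping the trimmed fraction at 10% removes rare
extremes while provably never erasing a class-sized mode.

### Superparamagnetic clustering

Events are clustered with a q = 20 state Potts model on the symmetrized
11-nearest-neighbour graph in selected-feature space. Neighbours i, j
interact with

$$ J_{ij} = \frac{1}{\hat K}\exp\!\left(-\frac{d_{ij}^2}{2a^2}\right), $$

where $d_{ij}$ is Euclidean distance, $a$ the mean nearest-neighbour
distance (the local scale), and $\hat K$ the mean degree. At each
temperature on the grid 0 to 0.25 in steps of 0.01 the model is simulated
with 500 Swendsen–Wang sweeps (first 20% discarded as burn-in; at T = 0 all
aligned-spin bonds freeze). Two neighbours are *linked* when their spins
coincide in more than half of the retained sweeps, and clusters are the
connected components of the linked graph. Physically: at low temperature the
whole (connected) graph orders ferromagnetically into one cluster; in the
superparamagnetic regime, dense groups align internally but fluctuate
independently of each other; at high temperature everything decouples. The
Monte Carlo runs on R's RNG, so clustering is bit-reproducible given a seed.

### Choosing the number of classes

For each temperature we count clusters holding at least
`max(5, ⌈0.05·n⌉)` events. The working temperature T* is the **highest**
temperature attaining the maximal count. Within a stable plateau the cluster
cores are invariant, but at the top of the plateau loosely attached
points — precisely the artifact-like events — have already detached, so the
accepted clusters are purest there. (The lower end of the plateau yields
identical classes with more hangers-on; we prefer the conservative cores and
let the forced-assignment step recover true members.) Accepted clusters
become classes named "A", "B", … in descending size order.

### Forced assignment and non-IED rejection

Events in no accepted cluster are compared with each class in
selected-feature space: an event joins the nearest class centroid if its
distance is at most 3× that class's median event-to-centroid distance, and
is otherwise labelled `NON_IED`. The multiplier 3 on a *median* radius is a
deliberately permissive boundary — genuine class members displaced by noise
are recovered, and only events far outside the class cloud are rejected.
All of the above (wavelet family and depth, number of features, K, the
temperature grid, sweeps, coincidence threshold, minimum cluster size,
radius factor) is exposed as configuration on `wc_classify()`.

A file-driven `apply_manual_review()` stands in for the visual verification
step of practice: it replaces listed labels and keeps an audit log; there is
no GUI. `class_average()` produces the per-class mean waveforms (default
window −50 ms to +150 ms, i.e. 200 ms) used to eyeball class identity.

## Agreement analysis

### Variation of information

Two classifications X, Y of the same N events (each including its non-IED
class as an ordinary class) are summarized by a contingency table with
counts $r_{ij}$ and marginals $p_i, q_j$, from which

$$ VI(X,Y) = -\sum_{i,j} r_{ij}\left[\log_2\frac{r_{ij}}{p_i} +
\log_2\frac{r_{ij}}{q_j}\right], $$

with $0\log 0 = 0$. Note the counts enter **unnormalized**: this VI scales
with N (it equals $N(H(X)+H(Y)-2I(X;Y))$ in bits) and is what all thresholds
and reports in this package use; a per-event variant is available via
`normalized = TRUE` but never substituted. VI is zero exactly at perfect
agreement (up to relabelling), symmetric, and obeys the triangle
inequality — properties the test suite checks against an independent
entropy-based implementation.

### Bootstrap, pooling, null model

Because each comparison rests on a small event sample, every pair gets a
non-parametric bootstrap: events are resampled with replacement and VI
recomputed, 1000 times. Automated–human pairs pool into `WC_all`,
human–human pairs into `H_all`, and the two pooled distributions are
compared by the Bhattacharyya coefficient over 50 shared equal-width bins
spanning their pooled range, reported as a percentage (100 = identical
histograms). Bin count and bounds are configuration; 50 bins keeps
~60 points per bin for three pooled pairs at the default sizes.

Chance agreement is calibrated by surrogate observers: each of 50 artificial
observers labels every event independently and uniformly into k classes, k
drawn uniformly from 2–9 per observer (covering one to eight IED classes
plus a non-IED class). VI over all 1225 surrogate pairs yields a null
sample; two real classifications are *similar* if their VI falls below the
null mean − 2 SD. A smoothed one-sided empirical p, (r+1)/(n+1), is reported
alongside, since the mean−2SD rule alone has no attached p-value.

### Silver standard, sensitivity/specificity, kappa, overlap

With exactly three human reviewers (any odd panel works), an event is a
"true" IED if at least two reviewers gave it a non-`NON_IED` label. Each
classifier's binary IED/non-IED reduction is then scored for sensitivity and
specificity against this silver standard; a statistic whose denominator is
empty (e.g. specificity when the panel rejected nothing) is *undefined* and
reported as JSON `null`, never 0. Pairwise Cohen's kappa on the binary
reduction is reported with the conventional κ > 0.4 cut for high agreement;
when both raters are constant, kappa is 1 if they agree and 0 otherwise, by
documented convention. Classification-overlap matrices give, for each
automated class i and human class j, the percentage
$A_{ij} = r_{ij}/|\mathrm{ref}_i|\times 100$ (rows sum to 100), with the
best-matching human class per row noted, ties reported in full.

## The synthetic data generator

`simulate_dataset()` is the package's test bed and defines the conditions
under which the classifier's guarantees are asserted. It emulates:

* **Spike classes.** Each class has a biphasic template: a raised-cosine
  sharp component whose FWHM is drawn from 40–100 ms, followed by an
  opposite-polarity slow wave of 100–200 ms width and 0.4–0.7× the spike
  amplitude — the classic spike-and-slow-wave complex, where the slow wave
  commonly rivals the spike in size. Templates peak exactly at t = 0.
* **Spatial fields.** Each class is prominent (weights 0.6–1, maximum
  normalized to 1) on 2–4 of the channels and near-silent elsewhere; class
  fields are redrawn until all pairwise correlations are below 0.3, i.e.
  classes are topographically distinct.
* **Event statistics.** Events sit on a 0.8 s grid with 4 ms latency jitter
  (so no two events overlap within the 300 ms epoch scale — the pipeline
  assumes isolated events) and lognormal amplitude jitter of 15%.
* **Background.** Independent per-channel 1/f noise, closer to EEG spectra
  than white noise, scaled so that the 2–70 Hz in-band standard deviation
  equals amplitude/SNR (default SNR 5 at 100 µV spikes → 20 µV in-band
  noise).
* **Artifacts.** Candidate events that are not discharges: each involves a
  random subset of 4–8 channels, and each involved channel gets its own 2–5
  raised-cosine bumps with random widths (30–200 ms), signs and latencies,
  at 3× the spike amplitude. This models muscle bursts and electrode
  transients: *large*, temporally disorganized, and with no coherent
  spatial template — as opposed to a cortical discharge, whose field is a
  fixed pattern scaled over channels. We model artifacts this way because
  events that survive human pre-screening as IED candidates are
  typically high-amplitude sharp transients; an early design with
  spike-amplitude rank-1 artifacts produced events statistically inside the
  class clouds, which is not what a reviewer would forward as a candidate
  and not what "artifact" means here.

What the generator does **not** emulate: dipolar field geometry and volume
conduction (fields are arbitrary sparse weight vectors), spatially
correlated background noise, polyspike trains, ictal activity, non-stationary
noise, and electrode drift. Passing tests on this generator therefore
demonstrate the pipeline's mechanics — alignment, feature selection,
clustering, rejection, agreement statistics — under controlled conditions;
they are not a clinical validation.

`simulate_observer()` corrupts the ground truth the way reviewer panels
disagree: each event is independently relabelled `NON_IED` with probability
m, else moved to a uniformly chosen different label with probability e, and
optional class merges/splits emulate observers working at coarser or finer
granularity. Mean VI between observer and truth rises monotonically with e
(a property the suite verifies).

## Numerical and edge-case conventions

* Sample indices are 0-based everywhere; marker files state the sampling
  rate they index against in a `# fs=` comment.
* Epoch windows are half-open with `round(duration × fs)` samples and the
  peak at index `round(pre × fs)`.
* Realignment ties break to the earliest sample; a flat (zero-GFP) window
  therefore maps the marker to the window start.
* All-identical feature vectors short-circuit SPC to a single cluster at
  every temperature; an all-constant feature matrix yields an empty
  selection with a warning.
* Undefined statistics serialize as `null`; reports use a fixed key order
  and list-shaped arrays so that parse → re-serialize is byte-identical.
* Every stochastic step (event sampling, SPC sweeps, bootstrap, surrogates,
  observer simulation) funnels through one seeded RNG interface; identical
  seeds give bit-identical outputs.
* Out-of-bounds epochs or search windows drop the event with a warning by
  default; `policy = "fail"` escalates to an error.

## Problem sizes in the test suite

The suite exercises the full pipeline on the generator's default conditions
(10 channels, 250 Hz, 3 classes × 40 events + 20 artifacts, SNR 5) across a
handful of seeds, uses 100–1000 bootstrap replicates and 10–50 surrogate
observers per statistical check, and verifies the VI identity on hundreds of
random tables. These sizes were chosen so the whole suite runs in well under
a minute while every check retains clear statistical margin.

## Known limitations

* Artifact rejection uses a single permissive radius rule in a 10-dimension
  feature space; artifacts that mimic a class's field and timing on all
  selected coordinates will be absorbed. Expect rejection sensitivity
  around 0.75–0.95 on the default synthetic conditions, not 1.
* The Lilliefors selector can under-represent a class whose coefficients
  are weakly bimodal; the bounded trim mitigates but does not eliminate
  this.
* BrainVision support covers the common dialect only (binary, multiplexed,
  INT_16 / IEEE_FLOAT_32); EDF support is uniform-rate, single-segment.
* The CLI validates configuration keys strictly and will refuse unknown
  keys rather than guess.
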