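---
title: "Day-scale variability of EEG functional networks: methods and conventions"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Day-scale variability of EEG functional networks: methods and conventions}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

This vignette documents the models, conventions and numerical choices
behind `eegnetvar`, in the spirit of a methods section: what each stage
computes, which decisions were genuinely open, and what the synthetic
cohort does and does not emulate.

## The analysis chain

A patient contributes five resting-state sessions (T1..T5, nominally
15 min each, recorded at two-hour intervals across one day) on the
30-channel 10/10 montage Fp1 ... O2. The pipeline reduces each session
to a wPLI connectivity pattern and network metrics, then quantifies how
much those change between sessions:

1. **Preprocessing** (`preprocess_recording()`): polyphase resampling
   to 500 Hz; zero-phase band-pass 1–45 Hz (Hamming-window FIR applied
   by FFT convolution with exact group-delay compensation — zero phase
   matters because wPLI is a pure phase statistic); 10-s non-overlapping
   epochs (floor rule, remainder discarded); statistical bad-channel
   detection; spherical-spline interpolation of bad channels; epoch
   rejection by an amplitude-probability criterion; common average
   reference. If more than 30% of epochs are rejected — strictly more,
   a rejected fraction of exactly 0.30 keeps the recording — the whole
   recording is unusable and the patient is excluded from group
   statistics (with the reason logged).
2. **Connectivity** (`session_connectivity()`): wPLI per 10-s epoch
   from 2-s Hann windows with 1-s overlap, pooling imaginary
   cross-spectral samples over windows x in-band frequency bins of the
   broadband (1–45 Hz) analytic signal; epoch matrices averaged into
   the session pattern.
3. **Graph metrics** (`network_metrics()`): characteristic path length,
   weighted clustering coefficient, betweenness centrality and node
   degree on the unthresholded weighted graph.
4. **Variability** (`patient_variability()`): NMI between module
   partitions of neighbouring session patterns, GEV of the mean
   pattern, and the CV (sd/mean, n−1 denominator) of each metric across
   the five sessions, globally and per electrode.
5. **Group statistics** (`group_statistics()`): Kruskal–Wallis omnibus,
   pairwise Mann–Whitney with Bonferroni (3 comparisons), per-electrode
   contrasts with Benjamini–Hochberg FDR at Q = 0.05, and Kendall
   tau-b correlations with the CRS-R score.

Graph metrics are computed on the epoch-averaged session pattern; an
epoch-resolved variant is available by applying `network_metrics()` to
the epoch-level matrices directly.

## Conventions that the literature leaves open

**Degree as a sum.** The per-node degree is the *sum* of a node's wPLI
weights (a mean over the 29 neighbours is exposed via `mean = TRUE`).
Reported group-level degree values in this literature exceed 1, which
is only possible for a sum of weights bounded by 1.

**wPLI estimation.** The expectation pools all (window x frequency bin)
cross-spectral samples of the Hann-tapered analytic signal within
1–45 Hz. Pairs whose imaginary cross-spectrum is identically zero
(self-pairs, exactly zero-lag pairs) are assigned wPLI 0: no consistent
nonzero-lag phase relation means no connection. The Hann taper is
standard leakage control.

**Weighted clustering.** The printed triangle-fraction formula is
binary; on unthresholded weighted graphs we use the
geometric-mean-of-triangles generalisation on max-normalised weights,
`t_i = 1/2 Σ (ŵ_ij ŵ_ih ŵ_jh)^{1/3}`, which reduces exactly to the
binary formula on 0/1 matrices (a regression test enforces this).
`C_i = 0` for nodes with fewer than two neighbours.

**Shortest paths.** Edge length is `1/wPLI` (strong coupling = short
distance), the convention of the standard connectivity toolboxes; no
thresholding anywhere. Unreachable pairs are excluded from the CPL
average with a warning (`disconnected = "inf"` propagates infinity
instead).

**Betweenness normalisation** uses ordered-pair counting with the
`1/((n−1)(n−2))` factor, and ties are counted fractionally.

**Module partitions for NMI.** How connectivity patterns become module
partitions is not fixed by the formula; we use greedy modularity
maximisation on the weighted graph (the field default), and the
partitioner is injectable in `session_nmi()` for sensitivity analyses.
NMI is computed at the *session* (recording) level: the four
neighbouring pairs T1–T2 ... T4–T5. Identical trivial partitions (both
single-module) get NMI 1 by convention.

**GEV.** The global explained variance is the microstate-literature
form: patterns vectorised (upper triangle), template = mean pattern,
`GEV = Σ corr(p_k, g)² ||p_k||² / Σ ||p_k||²`. The package reports GEV
neutrally and encodes no direction of "more variable".

**CV.** Sample (n−1) standard deviation over the arithmetic mean; the
population variant is a switch. Per-electrode CV vectors report `NA`
for an electrode whose metric is identically zero across sessions
(possible for betweenness), and such electrodes are reported untested
in per-electrode contrasts.

**Statistics.** All tests are two-sided. The per-electrode
between-group contrast defaults to Kruskal–Wallis (Mann–Whitney for two
groups); the repeated-measures reading of electrode-level testing —
sessions as the within factor, patients as blocks — is provided
separately as `per_electrode_friedman()`, because a between-group
Friedman test is formally a repeated-measures procedure and the two
readings answer different questions. FDR correction is
Benjamini–Hochberg step-up at Q = 0.05 across the 30 electrodes.

## Preprocessing thresholds

The clinical workflow this pipeline models uses visual inspection in
two places (bad-epoch confirmation and ICA component selection); both
are replaced by deterministic rules for reproducibility, and ICA
removal is omitted entirely (the synthetic data carries no ocular or
cardiac sources). Channels are flagged when the robust z-score
(median/MAD) of either their log total power or their kurtosis exceeds
3; epochs when any channel's log-RMS robust z-score exceeds 5. Both
thresholds are configurable. Two numerical details matter:

* MAD scales are floored (0.75 log-power units for channels, 0.1
  log-RMS units for epochs, 0.5 for kurtosis) so that near-degenerate
  inputs — a montage whose hub regions genuinely run hotter, or a set
  of near-identical clean epochs — do not generate spurious flags. A
  channel must deviate far beyond what static montage heterogeneity
  explains to be flagged on power; spike and transient contamination is
  caught by the kurtosis and RMS criteria.
* Spherical-spline interpolation follows the classical scalp-spline
  construction (stiffness m = 4, 20 Legendre terms, ridge 1e-5) on the
  montage's unit-sphere positions.

On the injected-artifact benchmark (20 seeds, two contaminated channels
each, default thresholds) the suite requires channel recall at least
0.9 with a false-flag rate at most 0.1.

## The synthetic cohort

No patient EEG ships with the package, so `simulate_cohort()` generates
the study conditions: three diagnosis groups (VS/UWS, MCS, EMCS) with
CRS-R ranges 3–7, 6–13 and 17–23 (matching the reported cohort means of
5.0 ± 1.2, 9.2 ± 2.8 and 20.6 ± 2.6), five sessions per patient, 30
channels. The desk-scale default protocol is 150 s per session at
500 Hz — 15 clean 10-s epochs, the same epoch count structure as the
clinical 15-min protocol at a tractable compute cost; `duration_s`
scales it up.

**Signal model.** Each coupled electrode pair shares a band-limited
oscillatory source (frequency uniform on 2–40 Hz) injected into both
channels with a fixed, nonzero phase lag (magnitude pi/4 to 3pi/4,
random sign) — the only structure wPLI responds to. A zero-lag common
component (8–12 Hz, per-channel gains 0.5–1.5) is deliberately included
as a volume-conduction surrogate that wPLI must ignore, and each
channel receives pink (1/f) background noise. Frequencies, lags and
source phases are patient-level structure (drawn from the patient
seed); sessions differ through the perturbations below, the common
component and the noise. In the fully quiet limit (no jitter, no
rotation, no noise, no common component) the five sessions are
identical by construction — the degeneracy the test suite checks.

**Topology.** The latent coupling is tiered (`default_base_coupling()`):
a saturating short-range backbone (amplitude 3.2 between electrodes
closer than 0.60 rad — a cutoff that includes the vertex ring around
Cz), mid-amplitude (0.5) edges linking the
centro-parietal hub set (Cz, C3, C4, CP1, CP2, Pz, P3, P4) to
electrodes within 1.4 rad, and a uniform weak bulk (0.35 within
1.3 rad). The uniform within-tier amplitudes are deliberate: a global
gain then moves each tier coherently, so integration and segregation
metrics respond to arousal-level fluctuations without reshuffling
shortest-path routes, and the saturated backbone pins the maximum
weight that normalises the clustering coefficient.

**Between-session variability knobs.** Two per-group parameters control
the planted effects:

* `coupling_jitter_sd` — a session-global log-normal gain on the whole
  coupling matrix (arousal-level fluctuation). It drives the CV of path
  length and clustering. A global gain was chosen over i.i.d. edgewise
  noise because independent edge perturbations average out over the
  ~10² edges of the graph and leave session-level metrics almost
  unchanged. Jitter decreases with the level of consciousness
  (VS/UWS 0.70 > MCS 0.38 > EMCS 0.05).
* `hub_rotation_sd` — session-to-session relocation and rescaling of
  the centro-parietal hub weights: per-hub log-normal factors (SD 0.6x
  the knob) with geometric mean one redistribute hub weight spatially,
  a hub-level factor (SD 1x the knob) rescales the tier, and the matrix
  total is renormalised so overall coupling is conserved.
  Centralisation — how much traffic funnels through the hubs — varies,
  so betweenness carries the variability, most visibly at the hub
  electrodes. Rotation increases with the level of consciousness
  (0.05 < 0.22 < 0.45), which plants the positive relation between
  betweenness variability and the CRS-R score. Recovery of this sign
  validates the *pipeline*, not the biology.

Coupling strength increases with consciousness (0.65/0.90/1.15),
ordering the signal-to-noise ratio — and hence the mean degree — across
groups in the direction the clinical cohort reports (lower summed wPLI
per node for VS/UWS than for EMCS), and, through estimation noise,
contributing a realistic extra share of metric variability to the
weaker-coupled groups.

**What the generator does not emulate** — and hence what passing tests
do not establish about real data: no volume conduction beyond the
single common component, no ocular/cardiac/muscle sources (artifact
injection is a separate, explicit operation), no drowsiness or
circadian structure across T1..T5, no biophysical head model, and a
jitter mechanism that preserves relative network structure — one
plausible mechanism for within-day state transitions among many. Two
consequences are worth naming. First, because the gain jitter preserves
community structure, the NMI of the synthetic VS/UWS group is *not*
depressed relative to EMCS the way the clinical cohort's is; the NMI
and GEV estimators are validated by their own degeneracy and oracle
tests instead. Second, the clinical effect magnitudes (CV values,
correlation strengths) are not targets — only the sign and ordering
structure is planted, and only that is checked.

**Seed discipline.** The master seed derives per-patient seeds, which
derive per-session seeds, through a deterministic integer recurrence
(all below 2^31); identical configuration and seed give byte-identical
cohorts, materialised or lazy (`lazy = TRUE` defers signal generation
to analysis time and keeps one patient in memory at a time).

## Problem sizes

The test suite exercises the full pipeline at two scales chosen for a
single-CPU workflow: unit and property tests use short sessions (30 s
at 200 Hz, montage-complete) where the property under test does not
depend on protocol length, and the parameter-recovery acceptance test
runs the complete default cohort — 3 groups x 20 patients x 5 sessions
of 150 s at 500 Hz — through simulation, preprocessing, connectivity,
graph metrics, variability and statistics. Statistical calibration
(type-I error of the omnibus test at 500 null replicates; the
per-electrode FDR procedure over 20 null cohorts) operates on
metric-level tables, which is the level at which those procedures are
defined.

## Known limitations

* The wPLI expectation pools broadband bins; narrowband sources
  therefore compete with all in-band noise bins, which compresses the
  dynamic range of the estimator. This matches the broadband protocol
  modelled here but understates the contrast a band-resolved analysis
  would show.
* The positive relation between betweenness variability and the
  consciousness score is recovered *spatially* — the per-electrode
  contrast flags the full planted centro-parietal set — but not by the
  network-average scalar: under conditions where arousal-gain
  fluctuation produces the path-length and clustering variability
  orderings, the CV of mean betweenness inherits a weak negative score
  correlation through the estimator's nonlinear response (shortest-path
  routes reshuffle when overall coupling shifts). The scalar and the
  spatial signature answer different questions here, and only the
  spatial one carries the planted positive effect through this
  estimator stack.
* Greedy modularity maximisation is deterministic but resolution-blind;
  on near-uniform graphs the partition (and hence NMI) is weakly
  determined. The partitioner is injectable for that reason.
* The Friedman fidelity mode tests session effects within a group,
  which is a different hypothesis from the between-group electrode
  contrast; both are provided because the clinical description of the
  electrode-level test admits both readings.
* CPL's treatment of disconnected pairs (exclusion with a warning) is a
  convention; fully disconnected session graphs are an error, which on
  wPLI matrices (strictly positive off-diagonal in practice) does not
  arise.
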