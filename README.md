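# eegnetvar

Large-timescale variability of EEG functional brain networks in
disorders of consciousness (DOC).

Patients with DOC — vegetative state / unresponsive wakefulness syndrome
(VS/UWS), minimally conscious state (MCS), and emergence from MCS
(EMCS) — fluctuate over the course of a day, which is one reason
single-session assessments misdiagnose them. `eegnetvar` implements an
analysis of that fluctuation at the network level: each patient is
recorded five times in one day (sessions T1..T5 at two-hour intervals),
every session is reduced to a functional connectivity pattern and a set
of graph metrics, and the *variability of the network across sessions*
is quantified and related to the behavioural consciousness score
(CRS-R, 0–23).

## The measures

**Connectivity.** The weighted phase lag index between channels *i* and
*j*,

    wPLI_ij = |E{Im(X_i X_j*)}| / E{|Im(X_i X_j*)|},

where `X_i` is the (Hilbert-based) spectral representation of channel
*i* in 1–45 Hz and the expectation pools 2-s Hann windows (1-s overlap)
and in-band frequency bins. wPLI uses only the imaginary cross-spectrum,
so zero-lag (volume-conducted) coupling cannot inflate it. Epoch-level
matrices (10-s epochs) are averaged into one session pattern.

**Graph metrics** on the unthresholded weighted graph (edge length
`1/wPLI`): characteristic path length `L = (1/n) Σ_i Σ_{j≠i} d_ij/(n−1)`
(integration), the weighted clustering coefficient
`C_i = 2 t_i / (k_i (k_i − 1))` with geometric-mean triangle intensity
`t_i` on max-normalised weights (segregation; `C_i = 0` for `k_i < 2`),
and betweenness centrality
`b_i = 1/((n−1)(n−2)) Σ_{h≠j≠i} ρ_hj(i)/ρ_hj` (centrality), plus the
node degree (sum of a node's wPLI weights).

**Variability across the five sessions.** Normalised mutual information
(NMI) between module partitions of neighbouring session patterns
(0 = independent, 1 = identical), the global explained variance (GEV) of
the mean pattern, and the relative coefficient of variation
`CV = sd/mean` of every metric — globally and per electrode.

**Statistics.** Kruskal–Wallis omnibus and pairwise Mann–Whitney tests
with Bonferroni correction across the three diagnosis groups,
per-electrode contrasts with Benjamini–Hochberg FDR correction
(Q = 0.05), and Kendall correlations of the CV measures with the CRS-R
score.

Because no patient EEG is distributed with the package, a synthetic
cohort generator (`simulate_cohort()`) produces session-resolved
recordings from phase-lagged coupled oscillators with pink noise, with
the between-session variability of each diagnosis group controlled by
two knobs: a global coupling gain jitter (arousal-level fluctuation)
and a centro-parietal hub-weight rescaling (session-varying
centralisation). See the methods vignette
(`vignettes/network-variability.Rmd`) for the generative model and all
conventions.

## Worked example

```r
library(eegnetvar)

# a small synthetic cohort: 2 patients per group, 30-s sessions
profiles <- default_group_profiles()
cohort <- simulate_cohort(profiles, n_per_group = 2,
                          duration_s = 30, fs = 200, seed = 9)
an <- run_pipeline(cohort, pipeline_config(target_fs = 200))
print(an)
```

```
<cohort_analysis> 6 patients analysed, 0 excluded by QC
   group avg_degree  cpl    cc bc_mean nmi_mean cv_cpl  cv_cc cv_bc_mean
1   EMCS       6.40 3.89 0.215  0.0293    0.596 0.0143 0.0461     0.0449
2    MCS       5.71 4.31 0.194  0.0339    0.734 0.0716 0.0552     0.0509
3 VS/UWS       5.38 4.93 0.209  0.0299    0.759 0.2896 0.0799     0.0969
```

Each row shows group medians: the VS/UWS patients have a sparser, less
integrated network (lower average degree, higher characteristic path
length) and far more variable integration and segregation across the
day (higher CV of path length and clustering) than the EMCS patients.
`summary(an)` adds the Kendall correlations
of each CV measure with the CRS-R score and the omnibus group tests;
`an$stats$per_electrode` holds the FDR-corrected per-electrode
contrasts used for topographic maps. (Small cohorts like this 6-patient
example fluctuate; the defaults — 20 patients per group, 150-s sessions
at 500 Hz — give the stable version of this table.)

A single recording can also be taken through the stages by hand:
`preprocess_recording()` → `session_connectivity()` →
`network_metrics()`, and five session patterns through
`patient_variability()`.

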