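# Synthetic cohort generator: phase-lagged coupled oscillators + 1/f noise.
#
# The generator stands in for undeposited patient EEG. Each session is a
# mixture of band-limited oscillatory sources shared pairwise between
# channels with a fixed nonzero phase lag (the only structure wPLI is
# sensitive to), a zero-lag common component emulating volume conduction
# (which wPLI must ignore), and pink background noise. Between-session
# variability is controlled per diagnosis group by a multiplicative
# coupling jitter and by relocation of centro-parietal hub weights.

#' Diagnosis-group generative profile
#'
#' Bundles the group-level parameters of the synthetic cohort generator:
#' the behavioural score range and the knobs controlling coupling
#' strength and session-to-session network variability.
#'
#' @param label Group label, e.g. `"VS/UWS"`, `"MCS"`, `"EMCS"`.
#' @param crsr_range Integer interval (length-2 vector) within 0..23 from
#'   which patient CRS-R scores are drawn uniformly.
#' @param coupling_strength Mean phase-coupling gain (dimensionless, >= 0).
#' @param coupling_jitter_sd SD of the log-normal multiplicative
#'   session-to-session perturbation of the coupling matrix (>= 0),
#'   realised as a session-global gain: overall coupling strength
#'   fluctuates between sessions (integration and segregation metrics
#'   move coherently), while relative network structure is preserved.
#' @param hub_rotation_sd SD of the log-normal session-to-session
#'   rescaling of the centro-parietal hub weights (>= 0). The hub tier
#'   is rescaled jointly and the matrix total is then renormalised, so
#'   weight shifts between the hub tier and the rest of the network:
#'   centralisation (betweenness) varies across sessions while total
#'   coupling -- hence overall integration -- is approximately
#'   preserved.
#' @param noise_sd SD of the pink (1/f) background noise, in signal units.
#' @return An object of class `group_profile`.
#' @export
group_profile <- function(label, crsr_range, coupling_strength,
                          coupling_jitter_sd, hub_rotation_sd, noise_sd) {
  crsr_range <- as.integer(round(crsr_range))
  if (length(crsr_range) != 2 || crsr_range[1] > crsr_range[2] ||
      crsr_range[1] < 0 || crsr_range[2] > 23)
    stopf("`crsr_range` must be an integer interval within [0, 23]")
  for (nm in c("coupling_strength", "coupling_jitter_sd",
               "hub_rotation_sd", "noise_sd")) {
    v <- get(nm)
    if (!is.numeric(v) || length(v) != 1 || v < 0)
      stopf("`%s` must be a single non-negative number", nm)
  }
  structure(list(label = label, crsr_range = crsr_range,
                 coupling_strength = coupling_strength,
                 coupling_jitter_sd = coupling_jitter_sd,
                 hub_rotation_sd = hub_rotation_sd,
                 noise_sd = noise_sd),
            class = "group_profile")
}

#' Default group profiles of the synthetic cohort
#'
#' The study conditions emulated by default: three diagnosis groups with
#' score ranges matching the reported cohort (VS/UWS 5.0 +/- 1.2,
#' MCS 9.2 +/- 2.8, EMCS 20.6 +/- 2.6), coupling strength increasing and
#' coupling jitter decreasing with the level of consciousness, and
#' centro-parietal hub rotation increasing with the level of
#' consciousness (the mechanism injecting the positive relation between
#' betweenness-centrality variability and the behavioural score).
#'
#' @return Named list of three [group_profile()] objects.
#' @export
default_group_profiles <- function() {
  list(
    "VS/UWS" = group_profile("VS/UWS", c(3, 7),
                             coupling_strength = 0.65,
                             coupling_jitter_sd = 0.70,
                             hub_rotation_sd = 0.05,
                             noise_sd = 1),
    "MCS" = group_profile("MCS", c(6, 13),
                          coupling_strength = 0.90,
                          coupling_jitter_sd = 0.38,
                          hub_rotation_sd = 0.22,
                          noise_sd = 1),
    "EMCS" = group_profile("EMCS", c(17, 23),
                           coupling_strength = 1.15,
                           coupling_jitter_sd = 0.05,
                           hub_rotation_sd = 0.45,
                           noise_sd = 1))
}

#' Default latent coupling topology
#'
#' A tiered coupling layout on the unit-sphere montage, expressed as
#' source amplitudes relative to unit background noise:
#'
#' * a short-range *local backbone* (electrode pairs closer than
#'   `local_cut` radians) strong enough that its wPLI saturates -- these
#'   edges pin the maximum weight, stabilising the max-normalised
#'   clustering coefficient;
#' * *hub edges* from the centro-parietal set to electrodes within
#'   `hub_cut`, at a mid-range amplitude where wPLI responds to gain --
#'   the session-to-session hub rotation operates on this tier;
#' * a uniform weak *bulk* tier (pairs within `bulk_cut`) providing the
#'   dense background connectivity of scalp EEG. Its uniform amplitude
#'   makes the global arousal gain move all bulk links coherently, so
#'   path-length and clustering metrics shift without reshuffling
#'   shortest-path routes (betweenness stays comparatively quiet under
#'   gain).
#'
#' @param montage Montage data frame (see [doc_montage()]).
#' @param local_amp,local_cut Amplitude and angular cutoff (radians) of
#'   the local backbone tier.
#' @param hub_amp,hub_cut Amplitude and cutoff of the hub tier.
#' @param bulk_amp,bulk_cut Amplitude and cutoff of the bulk tier.
#' @param hubs Character vector of hub channel names.
#' @return Symmetric non-negative matrix with zero diagonal (source
#'   amplitude per unit coupling strength).
#' @export
default_base_coupling <- function(montage = doc_montage(),
                                  local_amp = 3.2, local_cut = 0.60,
                                  hub_amp = 0.5, hub_cut = 1.4,
                                  bulk_amp = 0.35, bulk_cut = 1.3,
                                  hubs = centro_parietal_electrodes()) {
  d <- montage_distances(montage)
  h <- as.numeric(montage$name %in% hubs)
  hubmask <- outer(h, h, pmax)
  w <- matrix(0, nrow(montage), nrow(montage))
  dimnames(w) <- list(montage$name, montage$name)
  w[d < bulk_cut] <- bulk_amp
  w[hubmask > 0 & d < hub_cut] <- hub_amp
  w[d < local_cut] <- local_amp
  diag(w) <- 0
  w
}

# Pink (1/f) noise, one row per channel, each scaled to the requested SD.
pink_noise_matrix <- function(nch, n, sd) {
  if (sd == 0) return(matrix(0, nch, n))
  nf <- stats::nextn(n, 2)       # power-of-2 FFT, then truncate
  x <- matrix(stats::rnorm(nch * nf), nf, nch)
  X <- stats::mvfft(x)
  k <- c(0, seq_len(nf - 1))
  k <- pmin(k, nf - k)           # symmetric bin index -> Hermitian output
  amp <- 1 / sqrt(pmax(k, 1))
  amp[1] <- 0                    # no DC
  y <- Re(stats::mvfft(X * amp, inverse = TRUE))[seq_len(n), , drop = FALSE] / nf
  t(y) * (sd / apply(y, 2, stats::sd))
}

pink_noise <- function(n, sd) drop(pink_noise_matrix(1, n, sd))

# Edge structure fixed at the patient level: which pairs are coupled, at
# what frequency, with what (nonzero) phase lag, and with what source
# phase. Keeping phases at the patient level makes the zero-perturbation
# limit exactly degenerate (identical sessions) and keeps the
# cross-talk floor of uncoupled pairs stable across a patient's
# sessions; wPLI itself is blind to absolute phase either way.
edge_structure <- function(base_coupling, structure_seed) {
  idx <- which(upper.tri(base_coupling) & base_coupling > 0, arr.ind = TRUE)
  with_seed(structure_seed, {
    n_e <- nrow(idx)
    list(i = idx[, 1], j = idx[, 2],
         freq = stats::runif(n_e, 2, 40),
         lag = sample(c(-1, 1), n_e, replace = TRUE) *
           stats::runif(n_e, pi / 4, 3 * pi / 4),
         phase = stats::runif(n_e, 0, 2 * pi))
  })
}

#' Simulate one EEG session
#'
#' Generates a 30-channel session of phase-lagged coupled oscillators
#' mixed through a session-perturbed coupling matrix, plus a zero-lag
#' common component (volume-conduction surrogate) and pink noise. The
#' realized session coupling matrix is recorded as ground truth.
#'
#' @param profile A [group_profile()].
#' @param base_coupling 30 x 30 symmetric, zero-diagonal, non-negative
#'   latent coupling matrix (see [default_base_coupling()]).
#' @param session_index Session number 1..5 (labels T1..T5).
#' @param duration_s Session duration in seconds (>= 30).
#' @param fs Sampling rate in Hz (>= 200).
#' @param seed Session seed (controls phases, perturbations, noise).
#' @param structure_seed Seed fixing the patient-level edge structure
#'   (frequencies and lags); defaults to `seed`. Sessions of one patient
#'   share `structure_seed` and differ in `seed`.
#' @param common_amp Amplitude of the zero-lag common signal.
#' @param amp_scale Global source amplitude per unit coupling gain.
#' @param montage Montage data frame.
#' @param patient_id Patient identifier stored in the recording.
#' @return A [raw_recording()] with `ground_truth` set to the realized
#'   session coupling matrix.
#' @export
simulate_session <- function(profile, base_coupling, session_index,
                             duration_s = 150, fs = 500, seed = 1,
                             structure_seed = seed, common_amp = 0.5,
                             amp_scale = 1, montage = doc_montage(),
                             patient_id = "sim") {
  if (!is_symmetric_matrix(base_coupling))
    stopf("`base_coupling` must be a symmetric matrix")
  if (nrow(base_coupling) != nrow(montage))
    stopf("`base_coupling` must be %d x %d", nrow(montage), nrow(montage))
  if (any(diag(base_coupling) != 0)) stopf("`base_coupling` diagonal must be zero")
  if (any(base_coupling < 0)) stopf("`base_coupling` entries must be >= 0")
  if (duration_s < 30) stopf("`duration_s` must be >= 30 s (one epoch plus margin)")
  if (fs < 200) stopf("`fs` must be >= 200 Hz")
  if (!session_index %in% 1:5) stopf("`session_index` must be in 1..5")

  nch <- nrow(montage)
  n <- round(duration_s * fs)
  tt <- (seq_len(n) - 1) / fs
  es <- edge_structure(base_coupling, structure_seed)

  with_seed(seed, {
    # Session perturbations.
    #
    # Coupling jitter: a session-global log-normal gain (arousal-level
    # fluctuation of overall coupling strength). A global gain moves
    # integration and segregation metrics coherently -- i.i.d. edgewise
    # noise would average out over ~10^2 edges -- while betweenness,
    # being invariant to a global rescaling of the weights, is left to
    # the hub rotation.
    gain <- exp(stats::rnorm(1, sd = profile$coupling_jitter_sd))
    # Hub rotation, two coupled components scaled by hub_rotation_sd:
    # (a) relocation -- per-hub log-normal factors (SD 0.6x the knob)
    # with geometric mean one, multiplying every edge touching the hub
    # set by the product of its endpoint factors, so WHICH electrode
    # carries the centro-parietal weight changes between sessions;
    # (b) a hub-level swing (SD 1x the knob) rescaling the whole hub
    # tier. The matrix total is then renormalised, so weight shifts
    # between the hub tier and the rest while total coupling -- hence
    # overall integration -- is approximately preserved; the network's
    # centralisation, and with it betweenness (globally and at the hub
    # electrodes), carries the session-to-session variability.
    hubs <- centro_parietal_electrodes()
    coupling <- base_coupling
    g <- stats::setNames(rep(1, nch), montage$name)
    raw <- exp(stats::rnorm(length(hubs),
                            sd = 0.6 * profile$hub_rotation_sd))
    lvl <- exp(stats::rnorm(1, sd = profile$hub_rotation_sd))
    if (profile$hub_rotation_sd > 0) {
      g[hubs] <- raw / exp(mean(log(raw)))
      coupling <- coupling * outer(g, g)
      hub_flag <- montage$name %in% hubs
      hub_edge <- outer(hub_flag, hub_flag, `|`)
      coupling[hub_edge] <- coupling[hub_edge] * lvl
      coupling <- coupling * (sum(base_coupling) / sum(coupling))
    }
    coupling <- profile$coupling_strength * gain * coupling
    dimnames(coupling) <- list(montage$name, montage$name)

    # accumulate samples x channels (column-contiguous), transpose once
    acc <- matrix(0, n, nch)
    if (length(es$i)) {
      amps <- amp_scale * coupling[cbind(es$i, es$j)]
      for (e in seq_along(es$i)) {
        if (amps[e] == 0) next
        arg <- 2 * pi * es$freq[e] * tt + es$phase[e]
        s <- sin(arg)
        # lagged copy via the angle-addition identity (one extra cos only)
        s_lag <- s * cos(es$lag[e]) - cos(arg) * sin(es$lag[e])
        acc[, es$i[e]] <- acc[, es$i[e]] + amps[e] * s
        acc[, es$j[e]] <- acc[, es$j[e]] + amps[e] * s_lag
      }
    }
    if (common_amp > 0) {
      fc <- stats::runif(1, 8, 12)
      cphase <- stats::runif(1, 0, 2 * pi)
      gains <- stats::runif(nch, 0.5, 1.5)
      acc <- acc + common_amp * sin(2 * pi * fc * tt + cphase) %o% gains
    }
    data <- t(acc)
    if (profile$noise_sd > 0)
      data <- data + pink_noise_matrix(nch, n, profile$noise_sd)

    raw_recording(data, fs, montage,
                  session_label = paste0("T", session_index),
                  patient_id = patient_id, ground_truth = coupling)
  })
}

#' Simulate a full synthetic cohort
#'
#' Draws `n_per_group` patients from each [group_profile()]; each patient
#' receives a CRS-R score uniform on the group's range and five sessions
#' (T1..T5) generated by [simulate_session()] with per-patient and
#' per-session seeds derived deterministically from the master seed.
#'
#' @param profiles List of [group_profile()] objects with unique labels.
#' @param n_per_group Patients per group (>= 2).
#' @param duration_s,fs Session protocol passed to [simulate_session()].
#' @param seed Master seed.
#' @param lazy If `TRUE`, session signal blocks are not materialised;
#'   [realize_sessions()] (or the pipeline) generates them on demand.
#'   Results are identical either way; lazy cohorts keep the memory
#'   footprint of large protocols to one patient at a time.
#' @param base_coupling Latent topology; defaults to
#'   [default_base_coupling()].
#' @param amp_scale,common_amp Passed to [simulate_session()].
#' @return An object of class `synthetic_cohort`.
#' @export
simulate_cohort <- function(profiles, n_per_group, duration_s = 150,
                            fs = 500, seed = 1, lazy = FALSE,
                            base_coupling = NULL, amp_scale = 1,
                            common_amp = 0.5) {
  labels <- vapply(profiles, function(p) p$label, character(1))
  if (anyDuplicated(labels)) stopf("group labels must be unique")
  if (n_per_group < 2) stopf("`n_per_group` must be >= 2")
  montage <- doc_montage()
  base_coupling <- base_coupling %||% default_base_coupling(montage)

  patients <- list()
  for (gi in seq_along(profiles)) {
    prof <- profiles[[gi]]
    short <- gsub("[^A-Za-z0-9]", "", prof$label)
    for (k in seq_len(n_per_group)) {
      pseed <- derive_seed(seed, gi * 1000 + k)
      crsr <- with_seed(pseed,
                        sample(seq(prof$crsr_range[1], prof$crsr_range[2]), 1))
      specs <- lapply(1:5, function(s) list(
        profile = prof, session_index = s,
        seed = derive_seed(pseed, s), structure_seed = pseed))
      pat <- structure(
        list(patient_id = sprintf("%s_%02d", short, k),
             group = prof$label, crsr = crsr,
             sessions = NULL, session_specs = specs),
        class = "synthetic_patient")
      patients[[length(patients) + 1]] <- pat
    }
  }
  cohort <- structure(
    list(patients = patients, profiles = profiles,
         base_coupling = base_coupling,
         params = list(duration_s = duration_s, fs = fs,
                       amp_scale = amp_scale, common_amp = common_amp),
         seed = seed, montage = montage),
    class = "synthetic_cohort")
  if (!lazy)
    cohort$patients <- lapply(cohort$patients,
                              function(p) realize_sessions(p, cohort))
  cohort
}

#' Materialise the five sessions of a synthetic patient
#'
#' @param patient A `synthetic_patient` from [simulate_cohort()].
#' @param cohort The owning `synthetic_cohort` (provides protocol
#'   parameters and the base coupling).
#' @return The patient with `sessions` filled (list of 5 recordings).
#' @export
realize_sessions <- function(patient, cohort) {
  if (!is.null(patient$sessions)) return(patient)
  patient$sessions <- lapply(patient$session_specs, function(sp)
    simulate_session(sp$profile, cohort$base_coupling, sp$session_index,
                     duration_s = cohort$params$duration_s,
                     fs = cohort$params$fs, seed = sp$seed,
                     structure_seed = sp$structure_seed,
                     common_amp = cohort$params$common_amp,
                     amp_scale = cohort$params$amp_scale,
                     montage = cohort$montage,
                     patient_id = patient$patient_id))
  patient
}

#' @export
print.synthetic_cohort <- function(x, ...) {
  labs <- vapply(x$patients, function(p) p$group, character(1))
  cat(sprintf("<synthetic_cohort> %d patients (%s); %g s @ %g Hz x 5 sessions; seed %d\n",
              length(x$patients),
              paste(sprintf("%s n=%d", names(table(labs)), table(labs)),
                    collapse = ", "),
              x$params$duration_s, x$params$fs, x$seed))
  invisible(x)
}

#' Inject channel and epoch artifacts into a recording
#'
#' Adds high-kurtosis spike trains to designated channels and
#' large-amplitude low-frequency transients to a random fraction of
#' epochs, returning contamination bookkeeping for QC-recall tests.
#'
#' @param rec A [raw_recording()].
#' @param bad_channel_ids Channel names to contaminate.
#' @param bad_epoch_fraction Fraction of epochs to contaminate, in
#'   `[0, 1]`; the contaminated count is `round(fraction * n_epochs)`.
#' @param seed RNG seed.
#' @param epoch_length_s Epoch grid used to place epoch transients.
#' @return The recording with an `artifacts` bookkeeping list
#'   (`bad_channels`, `bad_epochs`, `epoch_length_s`).
#' @export
inject_artifacts <- function(rec, bad_channel_ids = character(),
                             bad_epoch_fraction = 0, seed = 1,
                             epoch_length_s = 10) {
  if (bad_epoch_fraction < 0 || bad_epoch_fraction > 1)
    stopf("`bad_epoch_fraction` must be in [0, 1]")
  unknown <- setdiff(bad_channel_ids, rec$montage$name)
  if (length(unknown))
    stopf("unknown channel id(s): %s", paste(unknown, collapse = ", "))

  n <- ncol(rec$data)
  fs <- rec$fs
  spe <- round(epoch_length_s * fs)
  n_epochs <- floor(n / spe)
  n_bad_ep <- round(bad_epoch_fraction * n_epochs)

  with_seed(seed, {
    for (ch in bad_channel_ids) {
      ci <- match(ch, rec$montage$name)
      s <- stats::sd(rec$data[ci, ])
      if (s == 0) s <- 1
      n_spk <- max(5, round(0.01 * n))
      pos <- sample.int(n, n_spk)
      rec$data[ci, pos] <- rec$data[ci, pos] +
        sample(c(-1, 1), n_spk, TRUE) * stats::runif(n_spk, 10, 20) * s
    }
    bad_eps <- integer(0)
    if (n_bad_ep > 0) {
      bad_eps <- sort(sample.int(n_epochs, n_bad_ep))
      amp <- 10 * stats::median(apply(rec$data, 1, stats::sd))
      if (amp == 0) amp <- 10
      for (e in bad_eps) {
        idx <- ((e - 1) * spe + 1):(e * spe)
        tt <- (seq_along(idx) - 1) / fs
        burst <- amp * sin(2 * pi * 3 * tt) * sin(pi * seq_along(idx) / length(idx))^2
        rec$data[, idx] <- sweep(rec$data[, idx], 2, burst, `+`)
      }
    }
    rec$artifacts <- list(bad_channels = bad_channel_ids,
                          bad_epochs = bad_eps,
                          epoch_length_s = epoch_length_s)
    rec
  })
}
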