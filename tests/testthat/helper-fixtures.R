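# Shared fixtures: small, fast synthetic objects built in code.

# Montage and a quiet profile reused across tests.
MONTAGE <- doc_montage()
N_CH <- nrow(MONTAGE)

quiet_profile <- function(jitter = 0, hub = 0, noise = 1, strength = 0.8,
                          crsr = c(3, 7), label = "TEST") {
  group_profile(label, crsr, coupling_strength = strength,
                coupling_jitter_sd = jitter, hub_rotation_sd = hub,
                noise_sd = noise)
}

# A dense all-pairs coupling matrix (keeps graphs connected even with
# noiseless generation).
dense_coupling <- function(value = 0.5) {
  w <- matrix(value, N_CH, N_CH)
  diag(w) <- 0
  dimnames(w) <- list(MONTAGE$name, MONTAGE$name)
  w
}

# Coupling with a single nonzero edge between two named channels.
single_edge_coupling <- function(a = "Fp1", b = "O2", value = 1) {
  w <- matrix(0, N_CH, N_CH)
  dimnames(w) <- list(MONTAGE$name, MONTAGE$name)
  w[a, b] <- w[b, a] <- value
  w
}

# Small multichannel recording of independent white noise.
noise_recording <- function(duration_s = 30, fs = 200, seed = 1, sd = 1) {
  n <- duration_s * fs
  data <- with_seed_test(seed, matrix(stats::rnorm(N_CH * n), N_CH))
  raw_recording(data * sd, fs, MONTAGE)
}

kurtosis_test <- function(x) {
  x <- x - mean(x)
  mean(x^4) / mean(x^2)^2
}

is_symmetric_matrix_test <- function(m) max(abs(m - t(m))) < 1e-10

eegenv_scale_cm <- function(w, scale) {
  eegnetvar:::new_connectivity_matrix(w * scale, rownames(w), "session")
}

with_seed_test <- function(seed, code) {
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, envir = globalenv()))
  set.seed(seed)
  force(code)
}

# Random symmetric nonnegative weight matrix with zero diagonal.
random_weights <- function(n, density = 0.7) {
  w <- matrix(0, n, n)
  ut <- upper.tri(w)
  vals <- stats::runif(sum(ut))
  vals[stats::runif(sum(ut)) > density] <- 0
  w[ut] <- vals
  w + t(w)
}

# Epoch array straight from a matrix of channels x samples.
quick_epochs <- function(data, fs, epoch_length_s = 2) {
  epoch_recording(raw_recording(data, fs, MONTAGE), epoch_length_s)
}
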