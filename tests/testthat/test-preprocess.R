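test_that("band-pass preserves in-band tones, removes DC and out-of-band tones", {
  fs <- 500
  t <- (0:(4 * fs - 1)) / fs
  mk <- function(sig) raw_recording(matrix(rep(sig, N_CH), N_CH,
                                           byrow = TRUE), fs, MONTAGE)
  in_band <- resample_filter(mk(sin(2 * pi * 10 * t)))
  expect_equal(stats::sd(in_band$data[1, ]), stats::sd(sin(2 * pi * 10 * t)),
               tolerance = 0.05)
  out_band <- resample_filter(mk(sin(2 * pi * 60 * t)))
  expect_lt(sqrt(mean(out_band$data[1, ]^2)) /
              sqrt(mean(sin(2 * pi * 60 * t)^2)), 0.1)
  dc <- resample_filter(mk(rep(5, length(t))))
  expect_lt(max(abs(dc$data)), 0.05)
  expect_error(resample_filter(mk(sin(t)), target_fs = 500, band = c(1, 300)),
               "Nyquist")
  expect_error(resample_filter(mk(sin(t)), target_fs = 1000), "exceed")
})

test_that("resampling halves the rate and keeps a tone's frequency", {
  fs <- 1000
  t <- (0:(2 * fs - 1)) / fs
  rec <- raw_recording(matrix(rep(sin(2 * pi * 10 * t), N_CH), N_CH,
                              byrow = TRUE), fs, MONTAGE)
  out <- resample_filter(rec, target_fs = 500)
  expect_equal(out$fs, 500)
  expect_equal(ncol(out$data), 1000)
  # dominant frequency still 10 Hz
  spec <- Mod(stats::fft(out$data[1, ]))[1:500]
  expect_equal(which.max(spec[-1]), 10 * 2)  # 2 s of data -> bin 20
})

test_that("epoching follows the floor rule and rejects short recordings", {
  fs <- 100
  mk <- function(secs) raw_recording(matrix(stats::rnorm(N_CH * secs * fs),
                                            N_CH), fs, MONTAGE)
  ep <- epoch_recording(with_seed_test(1, mk(150)), 10)
  expect_equal(dim(ep$epochs), c(15, N_CH, 1000))
  ep2 <- epoch_recording(with_seed_test(1, mk(154)), 10)
  expect_equal(dim(ep2$epochs)[1], 15)
  expect_error(epoch_recording(with_seed_test(1, mk(9)), 10), "shorter")
  # epochs tile the source contiguously
  rec <- with_seed_test(2, mk(30))
  ep3 <- epoch_recording(rec, 10)
  expect_equal(ep3$epochs[2, 5, ], unname(rec$data[5, 1001:2000]))
})

test_that("bad-channel detection flags spike channels and nothing else", {
  fs <- 200
  t <- (0:(30 * fs - 1)) / fs
  same <- raw_recording(matrix(rep(sin(2 * pi * 8 * t), N_CH), N_CH,
                               byrow = TRUE), fs, MONTAGE)
  expect_identical(detect_bad_channels(epoch_recording(same, 10)),
                   character(0))
  rec <- noise_recording(duration_s = 30, fs = fs, seed = 4)
  rec <- inject_artifacts(rec, "CP1", 0, seed = 9)
  flagged <- detect_bad_channels(epoch_recording(rec, 10))
  expect_identical(flagged, "CP1")
  expect_identical(detect_bad_channels(epoch_recording(rec, 10),
                                       z_threshold = Inf), character(0))
})

test_that("spherical-spline interpolation reconstructs a corrupted channel", {
  # smooth spatial field: value depends on scalp position -> channel is
  # predictable from its neighbours
  fs <- 100; n <- 10 * fs
  base <- sin(2 * pi * 6 * (0:(n - 1)) / fs)
  gains <- 1 + MONTAGE$x + 0.5 * MONTAGE$y
  data <- gains %o% base
  truth <- data["Pz" == MONTAGE$name, ]
  corrupted <- data
  corrupted[MONTAGE$name == "Pz", ] <- 10 * stats::rnorm(n)
  ep <- quick_epochs(corrupted, fs, 10)
  fixed <- interpolate_channels(ep, "Pz")
  err <- sqrt(mean((fixed$epochs[1, MONTAGE$name == "Pz", ] - truth)^2))
  corruption <- sqrt(mean((corrupted[MONTAGE$name == "Pz", ] - truth)^2))
  expect_lt(err, 0.2 * corruption)
  expect_true(fixed$qc$interpolated[["Pz"]])
  # untouched channels bit-identical
  expect_equal(fixed$epochs[1, 1, ], ep$epochs[1, 1, ])
  # no-op and precondition
  expect_identical(interpolate_channels(ep, character(0)), ep)
  expect_error(interpolate_channels(ep, MONTAGE$name), "good channels")
})

test_that("epoch rejection applies the strict 30% recording rule", {
  rec <- noise_recording(duration_s = 100, fs = 200, seed = 6)
  clean <- reject_bad_epochs(epoch_recording(rec, 10))
  expect_equal(sum(!clean$qc$keep), 0)
  expect_true(clean$qc$usable)

  four <- inject_artifacts(rec, character(), 0.4, seed = 2)
  ep4 <- reject_bad_epochs(epoch_recording(four, 10))
  expect_equal(which(!ep4$qc$keep), four$artifacts$bad_epochs)
  expect_false(ep4$qc$usable)
  expect_error(rereference_average(ep4), "unusable")

  three <- inject_artifacts(rec, character(), 0.3, seed = 2)
  ep3 <- reject_bad_epochs(epoch_recording(three, 10))
  expect_equal(sum(!ep3$qc$keep), 3)
  expect_true(ep3$qc$usable)  # 30% is not over 30%
})

test_that("common average reference zeroes the channel mean and is idempotent", {
  ep <- quick_epochs(matrix(stats::rnorm(N_CH * 400), N_CH) + 3, 100, 2)
  ref <- rereference_average(ep)
  expect_equal(ref$reference, "common_average")
  expect_lt(max(abs(colMeans(ref$epochs[1, , ]))), 1e-9)
  twice <- rereference_average(ref)
  expect_equal(twice$epochs, ref$epochs)
  # constant offset across channels vanishes entirely
  const <- quick_epochs(matrix(7, N_CH, 400), 100, 2)
  expect_lt(max(abs(rereference_average(const)$epochs)), 1e-12)
})

test_that("QC benchmark: channel recall and false-flag rate on injected artifacts", {
  hits <- 0; false_flags <- 0; trials <- 0
  for (seed in 1:20) {
    set.seed(seed)
    rec <- noise_recording(duration_s = 30, fs = 200, seed = 100 + seed)
    bad <- sample(MONTAGE$name, 2)
    rec <- inject_artifacts(rec, bad, 0, seed = seed)
    flagged <- detect_bad_channels(epoch_recording(rec, 10))
    hits <- hits + length(intersect(flagged, bad))
    false_flags <- false_flags + length(setdiff(flagged, bad))
    trials <- trials + 1
  }
  expect_gte(hits / (2 * trials), 0.9)
  expect_lte(false_flags / (28 * trials), 0.1)
})

test_that("preprocessing decisions are reproducible on identical input", {
  rec <- noise_recording(duration_s = 30, fs = 200, seed = 12)
  rec <- inject_artifacts(rec, "F3", 0.1, seed = 5)
  e1 <- preprocess_recording(rec, pipeline_config(target_fs = 200))
  e2 <- preprocess_recording(rec, pipeline_config(target_fs = 200))
  expect_identical(e1, e2)
})
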