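planted_two_clique <- function(n_half = 15, eps = 0) {
  n <- 2 * n_half
  w <- matrix(eps, n, n)
  w[1:n_half, 1:n_half] <- 1
  w[(n_half + 1):n, (n_half + 1):n] <- 1
  diag(w) <- 0
  dimnames(w) <- list(paste0("c", 1:n), paste0("c", 1:n))
  w
}

test_that("community detection recovers planted cliques and is deterministic", {
  w <- planted_two_clique()
  p <- partition_modules(w)
  expect_equal(p$n_modules, 2)
  expect_equal(length(unique(p$assignment[1:15])), 1)
  expect_equal(length(unique(p$assignment[16:30])), 1)
  expect_false(p$assignment[1] == p$assignment[16])
  expect_identical(partition_modules(w, seed = 3), partition_modules(w, seed = 3))
  # degenerate uniform graph: partition returned without error
  u <- matrix(0.5, 10, 10); diag(u) <- 0
  expect_s3_class(partition_modules(u), "module_partition")
  expect_error(partition_modules(matrix(0, 5, 5)), "empty")
})

test_that("NMI matches its printed-formula anchors and the entropy oracle", {
  expect_equal(nmi(c(1, 1, 2, 2), c(1, 1, 2, 2)), 1)
  expect_equal(nmi(c(1, 1, 2, 2), c(2, 2, 1, 1)), 1)  # label permutation
  expect_equal(nmi(c(1, 1, 2, 2), c(1, 2, 1, 2)), 0)  # uniform contingency
  a <- c(1, 1, 1, 2, 2, 2); b <- c(1, 1, 2, 2, 2, 2)
  expect_equal(nmi(a, b), nmi_oracle(a, b), tolerance = 1e-12)
  expect_equal(nmi(a, b), nmi(b, a))
  # against igraph's independent implementation
  set.seed(99)
  for (k in 1:20) {
    x <- sample(1:4, 30, replace = TRUE)
    y <- sample(1:3, 30, replace = TRUE)
    expect_equal(nmi(x, y), igraph::compare(x, y, method = "nmi"),
                 tolerance = 1e-12)
  }
  expect_error(nmi(c(1, 2), c(1, 2, 3)), "node set")
})

test_that("NMI is symmetric, bounded, and exactly 1 on identical partitions", {
  set.seed(17)
  for (k in 1:200) {
    n <- sample(10:40, 1)
    a <- sample(seq_len(sample(2:5, 1)), n, replace = TRUE)
    b <- sample(seq_len(sample(2:5, 1)), n, replace = TRUE)
    v <- nmi(a, b)
    expect_gte(v, 0); expect_lte(v, 1)
    expect_equal(v, nmi(b, a))
    expect_equal(nmi(a, a), 1)
  }
})

test_that("session NMI handles the 5-session contract", {
  w <- planted_two_clique(eps = 0.01)
  cms <- lapply(1:5, function(i)
    eegnetvar:::new_connectivity_matrix(w, rownames(w), "session"))
  sn <- session_nmi(cms)
  expect_length(sn$series, 4)
  expect_equal(unname(sn$series), rep(1, 4))
  expect_equal(sn$mean, 1)
  expect_error(session_nmi(cms[1:4]), "5 session")
  # alternating orthogonal plants: every neighbouring pair compares the
  # same two partitions
  w2 <- w[c(seq(1, 30, 2), seq(2, 30, 2)), c(seq(1, 30, 2), seq(2, 30, 2))]
  dimnames(w2) <- dimnames(w)
  alt <- lapply(1:5, function(i) eegnetvar:::new_connectivity_matrix(
    if (i %% 2) w else w2, rownames(w), "session"))
  sn2 <- session_nmi(alt)
  expect_equal(unname(sn2$series), rep(sn2$series[[1]], 4))
  expect_equal(sn2$mean,
               nmi(partition_modules(w), partition_modules(w2)))
})

test_that("GEV matches a step-by-step two-pattern evaluation and its bounds", {
  mk <- function(v) { m <- matrix(0, 3, 3); m[upper.tri(m)] <- v; m + t(m) }
  p1 <- mk(c(1, 2, 3)); p2 <- mk(c(2, 3, 5))
  g <- (c(1, 2, 3) + c(2, 3, 5)) / 2
  expected <- (stats::cor(c(1, 2, 3), g)^2 * sum(c(1, 2, 3)^2) +
                 stats::cor(c(2, 3, 5), g)^2 * sum(c(2, 3, 5)^2)) /
    (sum(c(1, 2, 3)^2) + sum(c(2, 3, 5)^2))
  expect_equal(gev(list(p1, p2)), expected, tolerance = 1e-12)
  expect_equal(gev(list(p1, p1, p1)), 1)
  expect_error(gev(list(p1)), "at least 2")
  expect_error(gev(list(mk(c(1, 1, 1)), mk(c(1, 1, 1)))), "zero-variance")
})

test_that("GEV decreases monotonically along a noise ladder", {
  # fixed noise realisations, scaled up step by step: the ladder isolates
  # the noise level from sampling variation
  set.seed(23)
  base <- random_weights(20, density = 1)
  noise <- lapply(1:5, function(k) {
    e <- matrix(0, 20, 20)
    e[upper.tri(e)] <- stats::rnorm(sum(upper.tri(e)))
    e + t(e)
  })
  gevs <- vapply(seq(0.05, 0.95, by = 0.1), function(s) {
    gev(lapply(1:5, function(k) base + s * noise[[k]]))
  }, numeric(1))
  expect_true(all(diff(gevs) < 0))
  expect_true(all(gevs >= 0 & gevs <= 1))
})

test_that("the coefficient of variation follows its definition", {
  expect_equal(cv(c(3, 3, 3)), 0)
  expect_equal(cv(1:5), sqrt(2.5) / 3)
  x <- with_seed_test(3, stats::runif(10, 1, 2))
  expect_equal(cv(7 * x), cv(x))  # scale invariance
  expect_equal(cv(1:5, population = TRUE), sqrt(2) / 3)
  expect_error(cv(c(-1, 1)), "zero")
  expect_error(cv(5), "at least 2")
  expect_true(is.na(cv(c(0, 0, 0), zero_mean = "na")))
})

test_that("a zero-variability patient yields near-zero CVs and NMI near 1", {
  # fully quiet configuration: no jitter, no hub rotation, no background
  # noise and no common component; the only session-to-session freedom
  # left is the source phases, which wPLI is blind to. The structured
  # default topology keeps the module partition well-defined.
  prof <- quiet_profile(jitter = 0, hub = 0, noise = 0, strength = 1)
  sessions <- lapply(1:5, function(s)
    simulate_session(prof, default_base_coupling(), s, duration_s = 30,
                     fs = 200, seed = 200 + s, structure_seed = 9,
                     common_amp = 0))
  res <- analyze_patient_sessions(sessions,
                                  pipeline_config(target_fs = 200))
  expect_equal(res$status, "ok")
  v <- res$variability
  expect_lte(v$cv_cpl, 0.02)
  expect_lte(v$cv_cc, 0.02)
  expect_lte(v$cv_bc_mean, 0.02)
  expect_gte(v$nmi_mean, 0.9)
  expect_length(v$cv_degree, 30)
  expect_length(v$cv_bc, 30)
})

test_that("patient variability is deterministic and validates session counts", {
  set.seed(71)
  w <- random_weights(30, density = 0.8)
  dimnames(w) <- list(MONTAGE$name, MONTAGE$name)
  cms <- lapply(1:5, function(i) eegenv_scale_cm(w, 1 + 0.01 * i))
  ms <- lapply(cms, network_metrics)
  v1 <- patient_variability(ms, cms, seed = 4)
  v2 <- patient_variability(ms, cms, seed = 4)
  expect_identical(v1, v2)
  expect_error(patient_variability(ms[1:4], cms), "5 sessions")
})
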