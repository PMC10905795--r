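make_table <- function(values_by_group, score = NULL) {
  groups <- rep(names(values_by_group), lengths(values_by_group))
  data.frame(patient_id = paste0("p", seq_along(groups)), group = groups,
             metric = unname(unlist(values_by_group)),
             crsr = if (is.null(score)) seq_along(groups) else score,
             stringsAsFactors = FALSE)
}

test_that("Kruskal-Wallis separates ranked groups and validates inputs", {
  tab <- make_table(list(A = c(1, 2, 3), B = c(11, 12, 13),
                         C = c(21, 22, 23)))
  res <- kruskal_wallis(tab, "metric")
  expect_lt(res$p, 0.05)
  expect_equal(res$test, "kruskal-wallis")
  same <- make_table(list(A = c(1, 2, 3), B = c(1, 2, 3)))
  expect_gt(kruskal_wallis(same, "metric")$p, 0.9)
  small <- make_table(list(A = c(1, 2), B = 3))
  expect_error(kruskal_wallis(small, "metric"), "2 observations")
})

test_that("pairwise Mann-Whitney applies the exact test and the Bonferroni cap", {
  tab <- make_table(list(A = c(1, 2, 3), B = c(4, 5, 6)))
  res <- pairwise_mwu_bonferroni(tab, "metric")
  expect_equal(nrow(res), 1)
  expect_equal(res$statistic, 0)       # U = 0, complete separation
  expect_equal(res$p, 0.1)             # exact two-sided 2/20
  expect_equal(res$p_adjusted, 0.1)    # one comparison here
  tab3 <- make_table(list(A = c(1, 2, 3), B = c(4, 5, 6), C = c(2, 3, 4)))
  res3 <- pairwise_mwu_bonferroni(tab3, "metric")
  expect_equal(nrow(res3), 3)
  below_cap <- res3$p * 3 <= 1
  expect_equal(res3$p_adjusted[below_cap], 3 * res3$p[below_cap])
  expect_true(all(res3$p_adjusted <= 1))
  expect_true(all(res3$p_adjusted >= res3$p))
  ident <- make_table(list(A = rep(1:3, 2), B = rep(1:3, 2)))
  expect_equal(pairwise_mwu_bonferroni(ident, "metric")$p_adjusted, 1)
})

test_that("per-electrode contrast controls FDR under the null", {
  set.seed(14)
  counts <- vapply(1:20, function(s) {
    tab <- data.frame(patient_id = paste0("p", 1:30),
                      group = rep(c("A", "B", "C"), each = 10))
    for (ch in MONTAGE$name)
      tab[[paste0("cv_degree_", ch)]] <- stats::rnorm(30)
    sum(per_electrode_contrast(tab, "cv_degree")$significant)
  }, numeric(1))
  expect_lte(mean(counts), 1.5)
})

test_that("per-electrode contrast recovers a planted centro-parietal effect", {
  hubs <- centro_parietal_electrodes()
  set.seed(15)
  hit_rate <- vapply(1:20, function(s) {
    tab <- data.frame(patient_id = paste0("p", 1:30),
                      group = rep(c("A", "B", "C"), each = 10))
    for (ch in MONTAGE$name) {
      eff <- if (ch %in% hubs) rep(c(0, 1.5, 3), each = 10) else 0
      tab[[paste0("cv_degree_", ch)]] <- stats::rnorm(30, sd = 0.5) + eff
    }
    res <- per_electrode_contrast(tab, "cv_degree")
    mean(res$significant[res$electrode %in% hubs])
  }, numeric(1))
  expect_gte(mean(hit_rate), 0.9)
})

test_that("BH adjusted p-values are monotone in the raw p-values", {
  set.seed(16)
  tab <- data.frame(patient_id = paste0("p", 1:20),
                    group = rep(c("A", "B"), each = 10))
  for (ch in MONTAGE$name)
    tab[[paste0("cv_bc_", ch)]] <- stats::rnorm(20) +
      rep(c(0, stats::runif(1, 0, 2)), each = 10)
  res <- per_electrode_contrast(tab, "cv_bc")
  ord <- order(res$p)
  expect_true(all(diff(res$p_adjusted[ord]) >= -1e-12))
  expect_true(all(res$p_adjusted >= res$p - 1e-12))
})

test_that("Friedman fidelity mode runs per electrode within a group", {
  set.seed(44)
  st <- expand.grid(patient_id = paste0("p", 1:8), session = paste0("T", 1:5),
                    stringsAsFactors = FALSE)
  st$group <- "MCS"
  for (ch in MONTAGE$name)
    st[[paste0("degree_", ch)]] <- stats::rnorm(nrow(st)) +
      if (ch == "Cz") as.integer(factor(st$session)) else 0
  res <- per_electrode_friedman(st, "degree", "MCS")
  expect_equal(nrow(res), 30)
  expect_true(res$significant[res$electrode == "Cz"])
  expect_lte(sum(res$significant), 3)
})

test_that("Kendall correlation matches the pair-counting oracle and signs", {
  tab <- data.frame(patient_id = paste0("p", 1:5), group = "A",
                    metric = c(1, 2, 3, 4, 5), crsr = c(2, 4, 6, 8, 10))
  expect_equal(kendall_correlation(tab, "metric")$tau, 1)
  tab$metric <- rev(tab$metric)
  expect_equal(kendall_correlation(tab, "metric")$tau, -1)
  # hand-picked ties
  tab2 <- data.frame(patient_id = paste0("p", 1:6), group = "A",
                     metric = c(1, 1, 2, 3, 3, 4), crsr = c(5, 7, 7, 9, 11, 11))
  expect_equal(kendall_correlation(tab2, "metric")$tau,
               tau_oracle(tab2$metric, tab2$crsr), tolerance = 1e-12)
  set.seed(21)
  for (k in 1:10) {
    x <- sample(1:5, 12, replace = TRUE)
    y <- sample(1:6, 12, replace = TRUE)
    if (stats::sd(x) == 0 || stats::sd(y) == 0) next
    tabk <- data.frame(patient_id = paste0("p", 1:12), group = "A",
                       metric = x, crsr = y)
    expect_equal(kendall_correlation(tabk, "metric")$tau, tau_oracle(x, y),
                 tolerance = 1e-12)
  }
  const <- data.frame(patient_id = paste0("p", 1:4), group = "A",
                      metric = rep(1, 4), crsr = 1:4)
  expect_error(kendall_correlation(const, "metric"), "constant")
})

test_that("Kruskal-Wallis type-I error is near nominal under the null", {
  set.seed(18)
  rejections <- vapply(1:500, function(r) {
    tab <- data.frame(patient_id = paste0("p", 1:60),
                      group = rep(c("A", "B", "C"), each = 20),
                      metric = stats::rnorm(60))
    kruskal_wallis(tab, "metric")$p < 0.05
  }, logical(1))
  expect_gte(mean(rejections), 0.03)
  expect_lte(mean(rejections), 0.07)
})
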