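make_table <- function(M, metric = "m", band = "b", region = "global") {
  metrics_table(
    subject_id = rep(rownames(M), 3),
    condition = rep(colnames(M), each = nrow(M)),
    band = band, region = region, metric = metric, value = as.vector(M))
}

cond_matrix <- function(values, n) {
  M <- matrix(values, n, 3, dimnames = list(paste0("s", 1:n),
                                            c("rest", "pMED", "pMS")))
  M
}

test_that("Friedman test matches the rank formula and handles ties", {
  # identical values across conditions: statistic 0, p 1
  M <- cond_matrix(rep(1:5, 3), 5)
  res <- friedman_conditions(make_table(M), "m", "b", "global")
  expect_equal(res$statistic, 0)
  expect_equal(res$p, 1)
  # fixed fixture vs the textbook statistic computed from scratch
  set.seed(1)
  M2 <- cond_matrix(rnorm(15), 5)
  res2 <- friedman_conditions(make_table(M2), "m", "b", "global")
  R <- t(apply(M2, 1, rank))
  n <- 5; k <- 3
  stat <- 12 / (n * k * (k + 1)) * sum(colSums(R)^2) - 3 * n * (k + 1)
  expect_equal(res2$statistic, stat, tolerance = 1e-12)
  expect_equal(res2$p, pchisq(stat, k - 1, lower.tail = FALSE),
               tolerance = 1e-12)
  # incomplete block errors with the subject named
  tb <- make_table(M2)
  expect_error(friedman_conditions(tb[-1, ], "m", "b", "global"), "s1")
})

test_that("Wilcoxon signed-rank matches exhaustive sign enumeration at n = 6", {
  set.seed(2)
  x <- rnorm(6); y <- rnorm(6)
  res <- wilcoxon_signed_rank(x, y)
  d <- x - y
  r <- rank(abs(d))
  v_obs <- sum(r[d > 0])
  # all 2^6 sign assignments
  signs <- expand.grid(rep(list(c(0, 1)), 6))
  vs <- as.matrix(signs) %*% r
  p_exact <- mean(abs(vs - 10.5) >= abs(v_obs - 10.5) - 1e-12)
  expect_equal(res$statistic, v_obs)
  expect_equal(res$p, p_exact, tolerance = 1e-12)
})

test_that("Wilcoxon handles degenerate and shifted inputs", {
  res <- wilcoxon_signed_rank(rep(1, 8), rep(1, 8))
  expect_true(res$degenerate)
  expect_equal(res$p, 1)
  set.seed(3)
  x <- rnorm(20)
  expect_lt(wilcoxon_signed_rank(x + 2, x)$p, 0.01)
})

test_that("Benjamini-Hochberg adjustment follows the step-up formula", {
  expect_equal(fdr_adjust(c(0.01, 0.02, 0.03, 0.04)), rep(0.04, 4))
  expect_equal(fdr_adjust(0.37), 0.37)
  set.seed(4)
  p <- runif(30)
  adj <- fdr_adjust(p)
  expect_true(all(adj >= p))
  expect_true(all(adj <= 1))
  expect_equal(order(adj[order(p)]), 1:30)  # order-preserving
})

test_that("the cascade gates pairwise tests on the adjusted Friedman p", {
  set.seed(5)
  n <- 15
  eff <- cond_matrix(c(rnorm(n), rnorm(n) + 3, rnorm(n)), n)
  nul <- cond_matrix(rnorm(3 * n), n)
  tb <- rbind(make_table(eff, metric = "hit"), make_table(nul, metric = "miss"))
  res <- compare_conditions(tb, alpha = 0.05)
  hit <- res[res$metric == "hit", ]
  miss <- res[res$metric == "miss", ]
  expect_lt(hit$friedman_p_adj, 0.05)
  expect_false(is.na(hit$p_rest_pMED_adj))
  expect_lt(hit$p_rest_pMED_adj, 0.05)
  expect_gt(hit$p_rest_pMS_adj, 0.05)
  expect_true(is.na(miss$p_rest_pMED))
  expect_true(all(res$friedman_p_adj >= res$friedman_p))
})

test_that("the cascade holds its type-I error rate under the null", {
  set.seed(6)
  n_sim <- 400
  rejections <- sapply(1:n_sim, function(i) {
    M <- cond_matrix(rnorm(60), 20)
    stats::friedman.test(M)$p.value < 0.05
  })
  rate <- mean(rejections)
  ci <- qbinom(c(0.005, 0.995), n_sim, 0.05) / n_sim
  expect_gte(rate, ci[1])
  expect_lte(rate, ci[2])
})

test_that("static-dynamic correlations behave as Pearson correlations should", {
  set.seed(7)
  n <- 20
  sfc <- rnorm(n)
  tb <- metrics_table(
    subject_id = rep(paste0("s", 1:n), 2),
    condition = "rest", band = "beta2",
    region = rep(c("global", "NEZ"), each = n),
    metric = rep(c("global_strength", "dwell_time"), each = n),
    value = c(sfc, 3 - 2 * sfc))
  res <- correlate_sfc_dfc(tb, sfc_metrics = "global_strength",
                           dfc_metrics = "dwell_time",
                           conditions = "rest", bands = "beta2")
  expect_equal(res$r, -1, tolerance = 1e-12)
  # affine rescaling leaves r unchanged
  tb2 <- tb
  tb2$value[tb2$metric == "dwell_time"] <-
    tb2$value[tb2$metric == "dwell_time"] * 7 + 2
  res2 <- correlate_sfc_dfc(tb2, sfc_metrics = "global_strength",
                            dfc_metrics = "dwell_time",
                            conditions = "rest", bands = "beta2")
  expect_equal(res2$r, res$r, tolerance = 1e-12)
  # independent metrics rarely correlate strongly at n = 39
  set.seed(8)
  rs <- sapply(1:200, function(i) cor(rnorm(39), rnorm(39)))
  expect_gt(mean(abs(rs) < 0.4), 0.95)
})
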