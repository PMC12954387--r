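test_that("strength normalization is exact, idempotent and scale-invariant", {
  set.seed(1)
  W <- matrix(runif(25), 5, 5); W <- (W + t(W)) / 2; diag(W) <- 0
  Wn <- normalize_strength(W)
  expect_equal(sum(Wn[upper.tri(Wn)]), 1)
  expect_equal(normalize_strength(Wn), Wn)
  expect_equal(normalize_strength(7 * W), Wn)
  expect_error(normalize_strength(matrix(0, 3, 3)), "all-zero")
})

test_that("metrics on canonical small graphs match hand computation", {
  # unit-weight triangle
  W <- matrix(1, 3, 3); diag(W) <- 0
  gm <- compute_metrics(W)
  expect_equal(gm$global_strength, 3)
  expect_equal(gm$clustering, rep(1, 3))
  expect_equal(gm$betweenness, rep(0, 3))
  expect_equal(gm$char_path_length, 1)
  # unit-weight path a-b-c
  P <- matrix(0, 3, 3); P[1, 2] <- P[2, 1] <- 1; P[2, 3] <- P[3, 2] <- 1
  gp <- compute_metrics(P)
  expect_equal(gp$betweenness, c(0, 1, 0))
  expect_equal(gp$char_path_length, 4 / 3)
  expect_false(gp$disconnected)
})

test_that("metrics equal the brute-force oracle on random weighted graphs", {
  set.seed(99)
  for (i in 1:25) {
    n <- sample(4:8, 1)
    W <- matrix(0, n, n)
    W[upper.tri(W)] <- runif(n * (n - 1) / 2) * rbinom(n * (n - 1) / 2, 1, 0.7)
    W <- W + t(W)
    el <- sample(c("inv", "one_minus"), 1)
    gm <- compute_metrics(W, edge_length = el)
    or <- oracle_graph_metrics(W, edge_length = el)
    for (f in c("global_strength", "strength", "betweenness", "clustering",
                "nodal_path_length", "char_path_length")) {
      expect_equal(gm[[f]], or[[f]], tolerance = 1e-9,
                   info = paste("metric", f, "iter", i))
    }
  }
})

test_that("bootstrap downsampling reduces to full-graph metrics when exact", {
  set.seed(4)
  n <- 10
  W <- matrix(0, n, n)
  W[upper.tri(W)] <- runif(45) + 0.05
  W <- W + t(W)
  ez <- c(rep(TRUE, 3), rep(FALSE, 7))
  bm <- bootstrap_downsample(W, ez, target = c(3, 7), reps = 5, seed = 1)
  gm <- compute_metrics(normalize_strength(W))
  agg <- metaseeg:::region_aggregates(gm, ez)
  expect_equal(bm$global_strength, sum(W[upper.tri(W)]))
  for (m in rownames(bm$region)) {
    expect_equal(unname(bm$region[m, "EZ"]), unname(agg[[m]]["EZ"]))
    expect_equal(unname(bm$region[m, "NEZ"]), unname(agg[[m]]["NEZ"]))
  }
  # determinism and stratum-size validation
  b1 <- bootstrap_downsample(W, ez, target = c(2, 5), reps = 20, seed = 7)
  b2 <- bootstrap_downsample(W, ez, target = c(2, 5), reps = 20, seed = 7)
  expect_identical(b1, b2)
  expect_error(bootstrap_downsample(W, ez, target = c(4, 7), reps = 2, seed = 1),
               "not enough nodes")
})

test_that("nodal metrics are invariant to global rescaling after normalization", {
  set.seed(8)
  W <- matrix(0, 8, 8)
  W[upper.tri(W)] <- runif(28)
  W <- W + t(W)
  ez <- c(TRUE, TRUE, rep(FALSE, 6))
  a <- bootstrap_downsample(W, ez, target = c(2, 4), reps = 10, seed = 3)
  b <- bootstrap_downsample(W * 5.5, ez, target = c(2, 4), reps = 10, seed = 3)
  expect_equal(a$region, b$region, tolerance = 1e-12)
  expect_equal(b$global_strength, 5.5 * a$global_strength)
})

test_that("bootstrap mean variance shrinks roughly like 1/reps", {
  set.seed(21)
  n <- 60
  W <- matrix(0, n, n)
  W[upper.tri(W)] <- runif(n * (n - 1) / 2)
  W <- W + t(W)
  ez <- c(rep(TRUE, 10), rep(FALSE, 50))
  est <- function(reps, seed) {
    bootstrap_downsample(W, ez, target = c(4, 20), reps = reps,
                         seed = seed)$region["strength", "NEZ"]
  }
  v_small <- var(sapply(1:12, function(s) est(2L, 1000 + s)))
  v_large <- var(sapply(1:12, function(s) est(32L, 2000 + s)))
  expect_lt(v_large, v_small / 4)
})
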