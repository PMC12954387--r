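# Shared fixtures and independent oracles used across the test files.

# adjusted Rand index between two labelings (independent of any package code)
ari <- function(a, b) {
  tab <- table(a, b)
  n <- sum(tab)
  sum_ij <- sum(choose(tab, 2))
  sum_a <- sum(choose(rowSums(tab), 2))
  sum_b <- sum(choose(colSums(tab), 2))
  expected <- sum_a * sum_b / choose(n, 2)
  (sum_ij - expected) / ((sum_a + sum_b) / 2 - expected)
}

# a small recording of band-limited noise (no planted structure)
noise_recording <- function(nc = 4, nt = 1500, fs = 250, seed = 1,
                            ez = c(TRUE, rep(FALSE, nc - 1))) {
  set.seed(seed)
  recording(matrix(rnorm(nc * nt), nc, nt), fs, ez_mask = ez,
            condition = "rest", subject_id = "fix")
}

# brute-force weighted graph metrics oracle: Floyd-Warshall all-pairs
# shortest paths with path counting (Brandes-style fractional betweenness),
# direct triangle enumeration for the Onnela clustering coefficient.
oracle_graph_metrics <- function(W, edge_length = "inv") {
  n <- nrow(W)
  L <- matrix(Inf, n, n)
  pos <- W > 0
  L[pos] <- if (edge_length == "inv") 1 / W[pos] else 1 - W[pos]
  diag(L) <- 0
  D <- L
  cnt <- ifelse(is.finite(L) & L > 0, 1, 0)  # shortest path counts
  diag(cnt) <- 0
  for (k in seq_len(n)) for (i in seq_len(n)) for (j in seq_len(n)) {
    if (i == j || i == k || j == k) next
    alt <- D[i, k] + D[k, j]
    if (alt < D[i, j] - 1e-12) {
      D[i, j] <- alt
      cnt[i, j] <- cnt[i, k] * cnt[k, j]
    } else if (is.finite(alt) && abs(alt - D[i, j]) <= 1e-12) {
      cnt[i, j] <- cnt[i, j] + cnt[i, k] * cnt[k, j]
    }
  }
  btw <- numeric(n)
  for (v in seq_len(n)) {
    for (i in seq_len(n)) for (j in seq_len(n)) {
      if (i >= j || i == v || j == v) next
      if (!is.finite(D[i, j]) || cnt[i, j] == 0) next
      via <- D[i, v] + D[v, j]
      if (is.finite(via) && abs(via - D[i, j]) <= 1e-12) {
        btw[v] <- btw[v] + cnt[i, v] * cnt[v, j] / cnt[i, j]
      }
    }
  }
  mx <- max(W)
  cl <- numeric(n)
  if (mx > 0) {
    Wh <- (W / mx)^(1 / 3)
    for (i in seq_len(n)) {
      s <- 0
      for (j in seq_len(n)) for (k in seq_len(n)) {
        if (j == i || k == i || j == k) next
        s <- s + Wh[i, j] * Wh[i, k] * Wh[j, k]
      }
      deg <- sum(W[i, ] > 0)
      cl[i] <- if (deg > 1) s / (deg * (deg - 1)) else 0
    }
  }
  Dof <- D
  diag(Dof) <- NA
  Dof[is.infinite(Dof)] <- NA
  list(global_strength = sum(W[upper.tri(W)]),
       strength = rowSums(W),
       betweenness = btw,
       clustering = cl,
       nodal_path_length = rowMeans(Dof, na.rm = TRUE),
       char_path_length = mean(Dof[upper.tri(Dof)], na.rm = TRUE))
}

# independent LZ76 oracle: repeatedly take the shortest prefix of the
# remainder that cannot be copied from anywhere in the already-seen part of
# the sequence (history grows inside the current phrase, LZ76 style)
oracle_lz76 <- function(s) {
  s <- as.integer(s)
  n <- length(s)
  stopifnot(n >= 1)
  n_phrases <- 0L
  pos <- 1L
  while (pos <= n) {
    len <- 1L
    repeat {
      if (pos + len - 1L > n) break
      sub <- s[pos:(pos + len - 1L)]
      found <- FALSE
      if (pos > 1L) {
        for (st in 1L:(pos - 1L)) {  # copy source may extend into the phrase
          if (all(s[st:(st + len - 1L)] == sub)) { found <- TRUE; break }
        }
      }
      if (!found) break
      len <- len + 1L
    }
    n_phrases <- n_phrases + 1L
    if (pos + len - 1L > n) break   # sequence exhausted mid-phrase
    pos <- pos + len
  }
  n_phrases
}

# signed (two-null-term) modularity oracle, straight from the definition
oracle_signed_modularity <- function(A, membership) {
  Ap <- pmax(A, 0); An <- pmax(-A, 0)
  part <- function(M) {
    tot <- sum(M)
    if (tot == 0) return(0)
    s <- rowSums(M)
    q <- 0
    for (c in unique(membership)) {
      idx <- membership == c
      q <- q + sum(M[idx, idx]) / tot - (sum(s[idx]) / tot)^2
    }
    q
  }
  Mp <- sum(Ap); Mn <- sum(An)
  if (Mp + Mn == 0) return(0)
  (Mp * part(Ap) - Mn * part(An)) / (Mp + Mn)
}

# stationary linear Gaussian null: statically correlated white noise, no
# amplitude modulation whatsoever (AAFT surrogates are then equivalent in
# distribution, so surrogate-normalized dynamics must sit near 1)
linear_null_recording <- function(nc = 8, nt = 15000, fs = 250, rho = 0.3,
                                  seed = 1) {
  set.seed(seed)
  S <- matrix(rho, nc, nc); diag(S) <- 1
  data <- crossprod(chol(S), matrix(rnorm(nc * nt), nc, nt))
  recording(data, fs, ez_mask = rep(FALSE, nc), condition = "rest",
            subject_id = "null")
}

# small standard cohort used by pipeline-level tests
tiny_cohort_spec <- function(n_subjects = 2, seed = 5) {
  cohort_spec(n_subjects = n_subjects, n_ez = 2, n_nez = 6,
              dynamic_bands = "beta2", seed = seed)
}
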