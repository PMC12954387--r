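# Weighted graph topology of static connectivity matrices.
#
# Networks of different sizes and densities are made comparable in two steps:
# every metric except global strength is computed on a matrix rescaled to
# total (upper-triangle) strength 1, and node counts are equalized by
# bootstrap downsampling to a fixed EZ / NEZ split before averaging metrics
# over repetitions.

as_weight_matrix <- function(M) {
  W <- if (inherits(M, "connectivity_matrix")) M$weights else M
  if (!is.matrix(W) || nrow(W) != ncol(W)) stopf("expected a square weight matrix")
  if (max(abs(W - t(W))) > 1e-10) stopf("weight matrix must be symmetric")
  if (any(diag(W) != 0)) stopf("weight matrix must have a zero diagonal")
  if (anyNA(W)) stopf("weight matrix contains missing pairs")
  if (any(W < 0)) stopf("graph metrics need nonnegative weights (rectify the adjacency)")
  W
}

#' Rescale a connectivity matrix to unit total strength
#'
#' Divides all weights by the sum of the upper triangle, so that the global
#' (total) network strength equals 1 exactly. Idempotent and invariant to
#' global rescaling of the input.
#'
#' @param M a `connectivity_matrix` or symmetric weight matrix.
#' @return object of the same kind with rescaled weights.
#' @export
normalize_strength <- function(M) {
  W <- as_weight_matrix(M)
  s <- sum(W[upper.tri(W)])
  if (s <= 0) stopf("cannot normalize an all-zero connectivity matrix")
  Wn <- W / s
  if (inherits(M, "connectivity_matrix")) { M$weights <- Wn; M } else Wn
}

# Onnela weighted clustering coefficient: weights scaled by the graph
# maximum, geometric-mean triangle intensity over binary-degree pairs.
clustering_onnela <- function(W) {
  mx <- max(W)
  if (mx == 0) return(rep(0, nrow(W)))
  Wh <- (W / mx)^(1 / 3)
  num <- diag(Wh %*% Wh %*% Wh)
  k <- rowSums(W > 0)
  out <- ifelse(k > 1, num / (k * (k - 1)), 0)
  as.numeric(out)
}

#' Weighted graph metrics of a connectivity matrix
#'
#' Computes, on the matrix exactly as given: global strength (sum of the
#' upper triangle), nodal strength (row sums), betweenness centrality
#' (weighted shortest paths, raw pair counts), the Onnela weighted clustering
#' coefficient (weights rescaled by the graph maximum), and nodal / global
#' characteristic path length (mean shortest-path distance over finite
#' pairs). Shortest-path edge lengths are `1/w` by default or `1 - w`.
#'
#' @param M a `connectivity_matrix` or symmetric nonnegative weight matrix
#'   with zero diagonal.
#' @param edge_length `"inv"` or `"one_minus"`.
#' @return a list of class `graph_metrics`: `global_strength`, `strength`,
#'   `betweenness`, `clustering`, `nodal_path_length`, `char_path_length`,
#'   `disconnected` (flag: some pairs unreachable).
#' @export
compute_metrics <- function(M, edge_length = c("inv", "one_minus")) {
  edge_length <- match.arg(edge_length)
  W <- as_weight_matrix(M)
  n <- nrow(W)
  strength <- rowSums(W)
  global_strength <- sum(W[upper.tri(W)])
  L <- W
  pos <- W > 0
  L[pos] <- if (edge_length == "inv") 1 / W[pos] else 1 - W[pos]
  if (edge_length == "one_minus" && any(L[pos] < 0)) {
    stopf("edge length 1 - w requires weights <= 1")
  }
  g <- igraph::graph_from_adjacency_matrix(L, mode = "undirected",
                                           weighted = TRUE, diag = FALSE)
  ew <- igraph::E(g)$weight
  btw <- igraph::betweenness(g, weights = ew, directed = FALSE)
  D <- igraph::distances(g, weights = ew)
  diag(D) <- NA
  disconnected <- any(is.infinite(D), na.rm = TRUE)
  D[is.infinite(D)] <- NA
  nodal_pl <- rowMeans(D, na.rm = TRUE)
  nodal_pl[is.nan(nodal_pl)] <- NA_real_
  finite_pairs <- D[upper.tri(D)]
  structure(list(
    global_strength = global_strength,
    strength = strength,
    betweenness = as.numeric(btw),
    clustering = clustering_onnela(W),
    nodal_path_length = nodal_pl,
    char_path_length = mean(finite_pairs, na.rm = TRUE),
    disconnected = disconnected,
    n_nodes = n), class = "graph_metrics")
}

nodal_metric_names <- function() c("strength", "betweenness", "clustering", "path_length")

# region means of the nodal metrics of a graph_metrics object
region_aggregates <- function(gm, ez_mask) {
  vals <- list(strength = gm$strength, betweenness = gm$betweenness,
               clustering = gm$clustering, path_length = gm$nodal_path_length)
  out <- list()
  for (m in names(vals)) {
    out[[m]] <- c(EZ = if (any(ez_mask)) mean(vals[[m]][ez_mask], na.rm = TRUE) else NA_real_,
                  NEZ = if (any(!ez_mask)) mean(vals[[m]][!ez_mask], na.rm = TRUE) else NA_real_)
  }
  out
}

#' Bootstrap node-downsampled graph metrics
#'
#' Equalizes network size across subjects: each repetition samples a fixed
#' number of EZ and NEZ nodes without replacement (stratified), rescales the
#' subgraph to unit total strength, computes all graph metrics (global
#' strength on the raw subgraph) and aggregates nodal metrics as EZ / NEZ
#' means. Results are averaged across repetitions.
#'
#' @param M a `connectivity_matrix` (carrying its EZ mask) or weight matrix.
#' @param ez_mask logical EZ mask, required for plain matrix input.
#' @param target `c(ez, nez)` node counts to sample.
#' @param reps number of repetitions.
#' @param seed seed for the node sampling; per-repetition streams are derived
#'   by counter so results are reproducible.
#' @param edge_length passed to [compute_metrics()].
#' @return list of class `bootstrap_metrics`: `global_strength`,
#'   `char_path_length`, `region` (matrix metric x EZ/NEZ of means),
#'   `reps`, `target`.
#' @export
bootstrap_downsample <- function(M, ez_mask = NULL, target = c(4L, 44L),
                                 reps = 100L, seed = 1L,
                                 edge_length = c("inv", "one_minus")) {
  edge_length <- match.arg(edge_length)
  if (inherits(M, "connectivity_matrix") && is.null(ez_mask)) ez_mask <- M$ez_mask
  W <- as_weight_matrix(M)
  if (is.null(ez_mask) || length(ez_mask) != nrow(W)) {
    stopf("ez_mask must be supplied with one entry per node")
  }
  ez_idx <- which(ez_mask); nez_idx <- which(!ez_mask)
  need <- c(ez = as.integer(target[1]), nez = as.integer(target[2]))
  if (length(ez_idx) < need["ez"] || length(nez_idx) < need["nez"]) {
    stopf("not enough nodes to downsample: have %d EZ / %d NEZ, need %d / %d",
          length(ez_idx), length(nez_idx), need["ez"], need["nez"])
  }
  rs <- restore_rng(); on.exit(rs())
  metric_names <- nodal_metric_names()
  region_acc <- matrix(0, length(metric_names), 2,
                       dimnames = list(metric_names, c("EZ", "NEZ")))
  gs_acc <- 0; pl_acc <- 0; any_disconnected <- FALSE
  for (r in seq_len(reps)) {
    set.seed(derive_seed(seed, r))
    keep <- sort(c(
      if (length(ez_idx) == need["ez"]) ez_idx else sample(ez_idx, need["ez"]),
      if (length(nez_idx) == need["nez"]) nez_idx else sample(nez_idx, need["nez"])))
    Ws <- W[keep, keep, drop = FALSE]
    gs_acc <- gs_acc + sum(Ws[upper.tri(Ws)])
    gm <- compute_metrics(normalize_strength(Ws), edge_length = edge_length)
    any_disconnected <- any_disconnected || gm$disconnected
    pl_acc <- pl_acc + gm$char_path_length
    agg <- region_aggregates(gm, ez_mask[keep])
    for (m in metric_names) region_acc[m, ] <- region_acc[m, ] + agg[[m]]
  }
  structure(list(global_strength = gs_acc / reps,
                 char_path_length = pl_acc / reps,
                 region = region_acc / reps,
                 disconnected = any_disconnected,
                 reps = reps, target = need), class = "bootstrap_metrics")
}
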