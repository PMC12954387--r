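# Three-condition nonparametric comparison with false-discovery-rate control
# and the static/dynamic metric correlation analysis.
#
# The cascade mirrors the standard two-stage design: a Friedman test per
# (metric, band, region) cell, Benjamini-Hochberg correction across the cells
# of one analysis family (all bands x all metrics within a layer), and post
# hoc pairwise Wilcoxon signed-rank tests — themselves BH-corrected within
# their own family — only where the adjusted Friedman p falls below alpha.

CONDITIONS <- c("rest", "pMED", "pMS")

# subjects x conditions wide matrix for one metric/band/region cell
cell_matrix <- function(table, metric, band, region) {
  sub <- table[table$metric == metric & table$band == band &
                 table$region == region, , drop = FALSE]
  if (!nrow(sub)) stopf("no rows for metric=%s band=%s region=%s", metric, band, region)
  subjects <- sort(unique(sub$subject_id))
  M <- matrix(NA_real_, length(subjects), length(CONDITIONS),
              dimnames = list(subjects, CONDITIONS))
  for (r in seq_len(nrow(sub))) {
    M[sub$subject_id[r], sub$condition[r]] <- sub$value[r]
  }
  bad <- rownames(M)[!stats::complete.cases(M)]
  if (length(bad)) {
    stopf("incomplete condition block for subject(s): %s", paste(bad, collapse = ", "))
  }
  M
}

#' Friedman test across the three conditions
#'
#' Rank-based Friedman chi-square (midranks for ties) over complete
#' subject x condition blocks of one (metric, band, region) cell of a
#' metrics table.
#'
#' @param table a metrics table ([metrics_table()]).
#' @param metric,band,region cell selectors.
#' @return list with `statistic`, `p`, `n` (subjects), `df`.
#' @export
friedman_conditions <- function(table, metric, band, region) {
  M <- cell_matrix(table, metric, band, region)
  if (all(apply(M, 1L, function(r) max(r) - min(r)) == 0)) {
    # every block fully tied: no rank information at all
    return(list(statistic = 0, p = 1, n = nrow(M), df = ncol(M) - 1))
  }
  ft <- stats::friedman.test(M)
  list(statistic = unname(ft$statistic), p = ft$p.value,
       n = nrow(M), df = unname(ft$parameter))
}

#' Paired Wilcoxon signed-rank test
#'
#' Two-sided test on paired differences: exact sign-assignment enumeration
#' when at most 12 non-zero differences and no tied magnitudes, normal
#' approximation with tie correction otherwise. Zero differences are dropped
#' (standard practice); if all differences are zero the result is the
#' degenerate p = 1 with `degenerate = TRUE`.
#'
#' @param x,y paired numeric vectors.
#' @return list with `statistic` (V), `p`, `n` (non-zero pairs),
#'   `degenerate`.
#' @export
wilcoxon_signed_rank <- function(x, y) {
  if (length(x) != length(y)) stopf("paired vectors must have equal length")
  d <- x - y
  d <- d[d != 0]
  if (!length(d)) return(list(statistic = 0, p = 1, n = 0L, degenerate = TRUE))
  exact <- length(d) <= 12L && !anyDuplicated(abs(d))
  wt <- suppressWarnings(stats::wilcox.test(d, exact = exact,
                                            correct = FALSE))
  list(statistic = unname(wt$statistic), p = wt$p.value,
       n = length(d), degenerate = FALSE)
}

#' Benjamini-Hochberg FDR adjustment
#'
#' Step-up adjusted p-values: monotone, capped at 1, order-preserving.
#'
#' @param p numeric vector of p-values.
#' @return adjusted p-values of the same length.
#' @export
fdr_adjust <- function(p) stats::p.adjust(p, method = "BH")

#' Friedman / FDR / Wilcoxon comparison of the three conditions
#'
#' Runs the full statistical cascade over one analysis family: every
#' (metric, band, region) cell present in `table` (optionally restricted by
#' the selector arguments). Friedman p-values are BH-adjusted across all
#' cells of the family; pairwise Wilcoxon signed-rank tests (rest-pMED,
#' rest-pMS, pMED-pMS) are run only for cells whose adjusted Friedman p is
#' below `alpha` and are BH-adjusted within their own family.
#'
#' @param table a metrics table with all three conditions per subject.
#' @param metrics,bands,regions optional restrictions (default: everything
#'   in the table).
#' @param alpha significance level gating the post hoc tests.
#' @return a `data.frame` with one row per cell: Friedman statistic, raw and
#'   adjusted p, and raw / adjusted pairwise p-values (`NA` where gated out).
#' @export
compare_conditions <- function(table, metrics = NULL, bands = NULL,
                               regions = NULL, alpha = 0.05) {
  table <- validate_metrics_table(table)
  metrics <- metrics %||% unique(table$metric)
  bands <- bands %||% unique(table$band)
  regions <- regions %||% unique(table$region)
  cells <- expand.grid(metric = metrics, band = bands, region = regions,
                       stringsAsFactors = FALSE)
  present <- vapply(seq_len(nrow(cells)), function(i) {
    any(table$metric == cells$metric[i] & table$band == cells$band[i] &
          table$region == cells$region[i])
  }, logical(1))
  cells <- cells[present, , drop = FALSE]
  if (!nrow(cells)) stopf("no matching cells in the metrics table")
  fr <- lapply(seq_len(nrow(cells)), function(i) {
    friedman_conditions(table, cells$metric[i], cells$band[i], cells$region[i])
  })
  out <- cells
  out$n <- vapply(fr, `[[`, numeric(1), "n")
  out$friedman_chisq <- vapply(fr, `[[`, numeric(1), "statistic")
  out$friedman_p <- vapply(fr, `[[`, numeric(1), "p")
  out$friedman_p_adj <- fdr_adjust(out$friedman_p)
  pair_names <- c("rest_pMED", "rest_pMS", "pMED_pMS")
  pairs <- list(c("rest", "pMED"), c("rest", "pMS"), c("pMED", "pMS"))
  for (pn in pair_names) {
    out[[paste0("p_", pn)]] <- NA_real_
    out[[paste0("p_", pn, "_adj")]] <- NA_real_
  }
  sig <- which(out$friedman_p_adj < alpha)
  if (length(sig)) {
    raw <- matrix(NA_real_, length(sig), 3L)
    for (si in seq_along(sig)) {
      i <- sig[si]
      M <- cell_matrix(table, out$metric[i], out$band[i], out$region[i])
      for (pi in 1:3) {
        raw[si, pi] <- wilcoxon_signed_rank(M[, pairs[[pi]][1]],
                                            M[, pairs[[pi]][2]])$p
      }
    }
    adj <- matrix(fdr_adjust(as.vector(raw)), nrow = length(sig))
    for (pi in 1:3) {
      out[sig, paste0("p_", pair_names[pi])] <- raw[, pi]
      out[sig, paste0("p_", pair_names[pi], "_adj")] <- adj[, pi]
    }
  }
  rownames(out) <- NULL
  out
}

#' Pearson correlation between static and dynamic metrics
#'
#' Across-subject Pearson correlations between each dynamic meta-state
#' activation metric and each static graph metric, per condition and band.
#'
#' @param table a metrics table holding both metric families.
#' @param sfc_metrics,dfc_metrics metric names, given as `region:metric`
#'   pairs via the `sfc_regions` / `dfc_regions` arguments.
#' @param sfc_regions,dfc_regions regions the metric families live in.
#' @param conditions,bands cells to evaluate.
#' @return data.frame with columns `dfc_metric`, `sfc_metric`, `condition`,
#'   `band`, `r`, `p`, `n`; cells with zero variance are `NA`.
#' @export
correlate_sfc_dfc <- function(table,
                              sfc_metrics = c("global_strength", "strength",
                                              "betweenness", "clustering",
                                              "path_length"),
                              dfc_metrics = c("dwell_time", "tas_complexity"),
                              sfc_regions = c(global_strength = "global",
                                              strength = "NEZ",
                                              betweenness = "NEZ",
                                              clustering = "NEZ",
                                              path_length = "NEZ"),
                              dfc_regions = c(dwell_time = "NEZ",
                                              tas_complexity = "NEZ"),
                              conditions = CONDITIONS,
                              bands = unique(table$band)) {
  table <- validate_metrics_table(table)
  grab <- function(metric, region, cond, band) {
    sub <- table[table$metric == metric & table$region == region &
                   table$condition == cond & table$band == band, ]
    stats::setNames(sub$value, sub$subject_id)
  }
  rows <- list()
  for (band in bands) for (cond in conditions) {
    for (dm in dfc_metrics) for (sm in sfc_metrics) {
      dv <- grab(dm, dfc_regions[[dm]], cond, band)
      sv <- grab(sm, sfc_regions[[sm]], cond, band)
      common <- intersect(names(dv), names(sv))
      if (length(common) < 3L) next
      dv <- dv[common]; sv <- sv[common]
      if (stats::sd(dv) == 0 || stats::sd(sv) == 0) {
        r <- NA_real_; p <- NA_real_
      } else {
        ct <- stats::cor.test(dv, sv, method = "pearson")
        r <- unname(ct$estimate); p <- ct$p.value
      }
      rows[[length(rows) + 1L]] <- data.frame(
        dfc_metric = dm, sfc_metric = sm, condition = cond, band = band,
        r = r, p = p, n = length(common), stringsAsFactors = FALSE)
    }
  }
  if (!length(rows)) stopf("no overlapping subjects between metric families")
  do.call(rbind, rows)
}
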