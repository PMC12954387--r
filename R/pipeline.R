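# Cohort-level drivers: run the static and dynamic analyses over a cohort of
# three-condition recordings and collect a long-format metrics table for the
# statistics layer.

cohort_conditions <- function(subject) names(subject$segments)

#' Static connectivity analysis of a cohort
#'
#' For every subject x condition x band: band-pass, epoch-averaged
#' orthogonalized amplitude envelope correlation, then bootstrap
#' node-downsampled graph metrics. Emits global strength (raw graph) plus
#' EZ / NEZ means of strength, betweenness centrality, clustering
#' coefficient and characteristic path length.
#'
#' @param cohort list of subjects as returned by [simulate_cohort()] (each
#'   with `subject_id` and a named list `segments` whose elements carry a
#'   `recording`), or a list of named `seeg_recording` lists.
#' @param config an [analysis_config()].
#' @param bands band names to analyse (default: all configured bands).
#' @param downsample logical: apply the bootstrap node downsampling (needs
#'   at least `target_nodes` in each stratum). When `FALSE`, metrics come
#'   from the full strength-normalized graph.
#' @return a metrics table (`data.frame`).
#' @export
run_sfc_analysis <- function(cohort, config = analysis_config(),
                             bands = names(config$bands),
                             downsample = TRUE) {
  rows <- list()
  for (subject in cohort) {
    sid <- subject$subject_id
    for (cond in cohort_conditions(subject)) {
      rec <- subject$segments[[cond]]$recording %||% subject$segments[[cond]]
      for (band in bands) {
        msg_stage(sid, " ", cond, " ", band, ": static adjacency")
        adj <- static_adjacency(rec, band, config)
        if (downsample) {
          bm <- bootstrap_downsample(adj, target = config$target_nodes,
                                     reps = config$n_bootstrap,
                                     seed = derive_seed(config$seed, 31L,
                                                        match(band, bands)),
                                     edge_length = config$edge_length)
          gs <- bm$global_strength
          region <- bm$region
        } else {
          gm <- compute_metrics(normalize_strength(adj$weights),
                                edge_length = config$edge_length)
          gs <- sum(adj$weights[upper.tri(adj$weights)])
          agg <- region_aggregates(gm, rec$ez_mask)
          region <- do.call(rbind, agg)
          colnames(region) <- c("EZ", "NEZ")
        }
        add <- data.frame(
          subject_id = sid, condition = cond, band = band,
          region = c("global", rep(c("EZ", "NEZ"), each = nrow(region))),
          metric = c("global_strength", rownames(region), rownames(region)),
          value = c(gs, region[, "EZ"], region[, "NEZ"]),
          stringsAsFactors = FALSE)
        rows[[length(rows) + 1L]] <- add[is.finite(add$value), , drop = FALSE]
      }
    }
  }
  validate_metrics_table(do.call(rbind, rows))
}

#' Dynamic connectivity analysis of a cohort
#'
#' For every subject x band x region: per-condition IAC tensors and
#' data-driven windows, meta-states on the concatenated conditions, and the
#' per-condition dwell time and TAS complexity. With
#' `surrogate_normalize = TRUE` the AAFT-normalized variants (`*_norm`) are
#' added.
#'
#' @param cohort as in [run_sfc_analysis()].
#' @param config an [analysis_config()].
#' @param bands band names to analyse.
#' @param regions subset of `c("global", "NEZ")`.
#' @param surrogate_normalize also emit surrogate-normalized metrics (runs
#'   the full pipeline on `config$n_surrogates` surrogate ensembles per
#'   subject x band x region — expensive).
#' @return a metrics table (`data.frame`).
#' @export
run_dfc_analysis <- function(cohort, config = analysis_config(),
                             bands = names(config$bands),
                             regions = c("global", "NEZ"),
                             surrogate_normalize = FALSE) {
  rows <- list()
  for (si in seq_along(cohort)) {
    subject <- cohort[[si]]
    sid <- subject$subject_id
    segments <- lapply(subject$segments, function(s) s$recording %||% s)
    for (band in bands) {
      for (region in regions) {
        seed <- derive_seed(config$seed, 53L, si, match(band, bands),
                            match(region, c("global", "NEZ")))
        if (surrogate_normalize) {
          res <- surrogate_normalized_dfc(segments, band, config,
                                          region = region, seed = seed)
          obs <- res$observed
        } else {
          obs <- dfc_subject(segments, band, config, region = region,
                             seed = seed)
        }
        conds <- names(segments)
        add <- data.frame(
          subject_id = sid, condition = rep(conds, 2L), band = band,
          region = region,
          metric = rep(c("dwell_time", "tas_complexity"), each = length(conds)),
          value = c(obs$dwell, obs$lzc), stringsAsFactors = FALSE)
        if (surrogate_normalize) {
          add <- rbind(add, data.frame(
            subject_id = sid, condition = rep(conds, 2L), band = band,
            region = region,
            metric = rep(c("dwell_time_norm", "tas_complexity_norm"),
                         each = length(conds)),
            value = c(res$normalized$dwell_norm, res$normalized$lzc_norm),
            stringsAsFactors = FALSE))
        }
        rows[[length(rows) + 1L]] <- add
      }
    }
  }
  validate_metrics_table(do.call(rbind, rows))
}
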