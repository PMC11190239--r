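# End-to-end orchestration: simulate (or load) -> filter -> windows ->
# nightly features -> periods -> phenotype labels -> transition graph ->
# per-condition static-vs-dynamic comparison. Individuals are processed
# in batches so epoch-level data never has to be held for the whole
# population at once.

#' Pipeline configuration
#'
#' @param generator A [generator_config()] (the input source when
#'   simulating), or NULL when `nights` are supplied to [run_pipeline()].
#' @param labeller `"rules"` (deterministic, embedding-free; Cluster 0 is
#'   not subdivided) or `"landscape"` (UMAP + DBSCAN with geometric
#'   Cluster-0 subdivision).
#' @param embed_method,n_neighbors,min_dist,eps,min_pts,min_periods
#'   Landscape parameters (see [fit_landscape()]).
#' @param periphery_fraction Cluster-0 periphery share
#'   (see [subdivide_cluster0()]).
#' @param smooth_min,gap_min,gap_rule,short_h Window-construction
#'   parameters (see [build_windows()]).
#' @param max_nonwear_h,min_nights Period exclusion thresholds.
#' @param pseudocount Passed to the per-condition chi-square tests
#'   (see [chi_square_test()]); default 0 (off).
#' @param batch_size Individuals simulated/processed per batch.
#' @param out_dir Optional directory: stage tables and the resolved
#'   config are written there as CSV/JSON.
#' @return A `pipeline_config`.
#' @export
pipeline_config <- function(generator = generator_config(),
                            labeller = c("rules", "landscape"),
                            embed_method = "umap",
                            n_neighbors = 15L, min_dist = 0.1,
                            eps = 0.5, min_pts = 15L, min_periods = 500L,
                            periphery_fraction = 0.084,
                            smooth_min = 10, gap_min = 60, gap_rule = "lt",
                            short_h = 3,
                            max_nonwear_h = 5, min_nights = 3L,
                            pseudocount = 0,
                            batch_size = 100L, out_dir = NULL) {
  labeller <- match.arg(labeller)
  structure(as.list(environment()), class = "pipeline_config")
}

#' Run the full pipeline
#'
#' @param config A [pipeline_config()].
#' @param nights Optional pre-loaded nights table (individual_id,
#'   night_date, sleep_onset, stages list-column, nonwear_hours); when
#'   NULL the synthetic generator in `config$generator` is used.
#' @param survey,symptoms Condition tables when `nights` is supplied.
#' @return A `sleep_pipeline_result` list: night_features, periods,
#'   labelled periods, landscape (or NULL), transition graph, grouped
#'   transition summaries, per-condition health comparisons, drop
#'   accounting, and the resolved config.
#' @export
run_pipeline <- function(config = pipeline_config(), nights = NULL,
                         survey = NULL, symptoms = NULL) {
  stopifnot(inherits(config, "pipeline_config"))
  truth <- NULL
  dropped_nights <- c(filtered = 0L)
  if (is.null(nights)) {
    if (is.null(config$generator))
      stopf("no input nights and no generator configured")
    truth <- generate_truth(config$generator)
    survey <- truth$survey
    symptoms <- truth$symptoms
    ids <- truth$individual_ids
    batches <- split(ids, ceiling(seq_along(ids) / config$batch_size))
    nf_list <- vector("list", length(batches))
    for (b in seq_along(batches)) {
      pop <- generate_population(config$generator, truth, batches[[b]])
      filt <- filter_nights(pop$nights)
      dropped_nights["filtered"] <- dropped_nights["filtered"] +
        nrow(pop$nights) - nrow(filt)
      nf_list[[b]] <- compute_night_features(
        filt, smooth_min = config$smooth_min, gap_min = config$gap_min,
        gap_rule = config$gap_rule, short_h = config$short_h)
    }
    night_features <- rbindlist(nf_list)
  } else {
    filt <- filter_nights(as.data.table(nights))
    dropped_nights["filtered"] <- nrow(as.data.table(nights)) - nrow(filt)
    night_features <- compute_night_features(
      filt, smooth_min = config$smooth_min, gap_min = config$gap_min,
      gap_rule = config$gap_rule, short_h = config$short_h)
  }

  per <- assemble_periods(night_features, config$max_nonwear_h, config$min_nights)
  if (is.null(per$periods)) stopf("no periods survived the exclusion criteria")

  landscape <- NULL
  if (config$labeller == "landscape") {
    landscape <- fit_landscape(
      per$periods, method = config$embed_method,
      n_neighbors = config$n_neighbors, min_dist = config$min_dist,
      eps = config$eps, min_pts = config$min_pts,
      seed = config$generator$seed %||% 42L,
      min_periods = config$min_periods)
  }
  labelled <- assign_phenotypes(per$periods, landscape,
                                periphery_fraction = config$periphery_fraction)
  pairs <- extract_transition_pairs(labelled)
  graph <- if (nrow(pairs)) build_ctp(pairs) else NULL
  summaries <- if (!is.null(graph) &&
                   any(!is.na(phenotype_catalog()$fracture_group[
                     match(graph$nodes, phenotype_catalog()$subcluster)])))
    tryCatch(transition_summaries(graph), error = function(e) NULL) else NULL

  health <- list()
  effects <- config$generator$condition_effects %||% list()
  for (eff in effects) {
    design <- cohort_design(eff$type, eff$condition,
                            during_window = eff$during_window %||% c(-14L, 14L))
    health[[eff$condition]] <- static_vs_dynamic(
      labelled, pairs, design, survey = survey, symptoms = symptoms,
      pseudocount = config$pseudocount)
  }

  result <- structure(
    list(night_features = night_features, periods = labelled,
         period_nights = per$nights, landscape = landscape,
         graph = graph, transition_summaries = summaries, health = health,
         dropped = list(nights = dropped_nights, periods = per$dropped),
         truth = truth, config = config),
    class = "sleep_pipeline_result")
  if (!is.null(config$out_dir)) write_pipeline_result(result, config$out_dir)
  result
}

#' @export
print.sleep_pipeline_result <- function(x, ...) {
  cat(sprintf("<sleep_pipeline_result: %d nights, %d periods, %d transition pairs>\n",
              nrow(x$night_features), nrow(x$periods),
              if (is.null(x$graph)) 0L else x$graph$n_pairs))
  if (length(x$health))
    for (h in x$health)
      cat(sprintf("  %s (%s): chi2 p = %.3g (static) / %.3g (dynamic), IG ratio %.2f\n",
                  h$condition, h$mode, h$chi_static$p_value,
                  h$chi_dynamic$p_value, h$ig_ratio))
  invisible(x)
}

write_pipeline_result <- function(result, out_dir) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  fwrite(result$night_features, file.path(out_dir, "night_features.csv"))
  fwrite(result$periods, file.path(out_dir, "periods_labelled.csv"))
  if (!is.null(result$graph)) {
    ctp <- as.data.table(result$graph$ctp, keep.rownames = "from")
    fwrite(ctp, file.path(out_dir, "ctp_matrix.csv"))
    cnt <- as.data.table(result$graph$counts, keep.rownames = "from")
    fwrite(cnt, file.path(out_dir, "transition_counts.csv"))
    edges <- as.data.table(as.table(result$graph$counts))
    setnames(edges, c("from", "to", "count"))
    edges[, ctp := as.vector(t(result$graph$ctp))[
      (match(from, result$graph$nodes) - 1L) * length(result$graph$nodes) +
        match(to, result$graph$nodes)]]
    fwrite(edges[count > 0], file.path(out_dir, "transition_edges.csv"))
  }
  if (!is.null(result$transition_summaries))
    fwrite(result$transition_summaries,
           file.path(out_dir, "transition_summaries.csv"))
  if (length(result$health)) {
    hs <- rbindlist(lapply(result$health, function(h) data.table(
      condition = h$condition, mode = h$mode,
      chi2_static = h$chi_static$statistic, p_static = h$chi_static$p_value,
      chi2_dynamic = h$chi_dynamic$statistic, p_dynamic = h$chi_dynamic$p_value,
      ig_static = h$ig_static, ig_dynamic = h$ig_dynamic,
      ig_ratio = h$ig_ratio)))
    fwrite(hs, file.path(out_dir, "health_comparison.csv"))
  }
  cfg <- result$config
  cfg_ser <- lapply(cfg[setdiff(names(cfg), "generator")], identity)
  gen <- cfg$generator
  if (!is.null(gen)) {
    cfg_ser$generator <- list(
      archetypes = names(gen$archetypes),
      transition_matrix = gen$transition_matrix,
      initial_distribution = gen$initial_distribution,
      n_individuals = gen$n_individuals, n_nights = gen$n_nights,
      missing_night_prob = gen$missing_night_prob,
      nonwear_mean_h = gen$nonwear_mean_h, sd_scale = gen$sd_scale,
      start_date = as.character(gen$start_date), seed = gen$seed)
  }
  jsonlite::write_json(cfg_ser, file.path(out_dir, "config.json"),
                       auto_unbox = TRUE, digits = NA, force = TRUE)
  invisible(out_dir)
}
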