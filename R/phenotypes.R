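# The 13 sleep phenotypes: high-level clusters 0-4, rule-based
# subdivision of Cluster 1 (1-a / 1-b / 1-c), and geometry-based
# subdivision of Cluster 0 into a centre and six 60-degree peripheral
# sectors (0-A..0-F). "rec" (the recommended monophasic phenotype) is the
# Cluster-0 centre.

#' Phenotype catalogue
#'
#' The 13 subcluster labels with their parent cluster, recommended /
#' insomnia-like flags (insomnia-like: fragmented or short sleep per
#' DSM-5-TR-motivated criteria, plus the two low-sleep-percentage
#' peripheral monophasic phenotypes 0-E and 0-F), and the total-sleep-time
#' grouping of the insomnia-like phenotypes into short-fractured
#' (1-a, 1-b, 4) vs long-fractured (1-c, 2, 3).
#'
#' @param insomnia_peripheral Peripheral Cluster-0 subclusters counted as
#'   insomnia-like (config-overridable; default `c("0-E", "0-F")`).
#' @return data.table: subcluster, cluster, is_recommended,
#'   is_insomnia_like, fracture_group ("short", "long" or NA).
#' @export
phenotype_catalog <- function(insomnia_peripheral = c("0-E", "0-F")) {
  dt <- data.table(subcluster = PHENOTYPE_LEVELS)
  dt[, cluster := c(0L, rep(0L, 6), 1L, 1L, 1L, 2L, 3L, 4L)]
  dt[, is_recommended := subcluster == "rec"]
  dt[, is_insomnia_like := subcluster %in%
       c("1-a", "1-b", "1-c", "2", "3", "4", insomnia_peripheral)]
  dt[, fracture_group := ifelse(subcluster %in% c("1-a", "1-b", "4"), "short",
                         ifelse(subcluster %in% c("1-c", "2", "3"), "long",
                                NA_character_))]
  dt[]
}

#' Rule-based high-level cluster of each period
#'
#' Classifies periods into clusters 0-4 from night composition alone,
#' with precedence: all nights short-only -> 4; any short-only night -> 1;
#' any long+short night -> 2; any multi-long-window night -> 3; else 0.
#' This classifier is deterministic and embedding-free; it also anchors
#' the semantic mapping of DBSCAN clusters.
#'
#' @param periods Period table from [assemble_periods()] (needs the
#'   composition flag columns).
#' @return Integer vector of cluster ids 0-4.
#' @export
rule_cluster <- function(periods) {
  p <- as.data.table(periods)
  ifelse(p$all_short_only, 4L,
  ifelse(p$any_short_only, 1L,
  ifelse(p$any_long_short, 2L,
  ifelse(p$any_multi_lw, 3L, 0L))))
}

#' Subdivide Cluster 1 by night-composition rules
#'
#' Precedence: 1-c if any night has more than one long window; else 1-b
#' if any night has more than one short window; else 1-a.
#'
#' @param periods Period rows belonging to Cluster 1.
#' @return Character vector of subcluster labels.
#' @export
subdivide_cluster1 <- function(periods) {
  p <- as.data.table(periods)
  ifelse(p$any_multi_lw, "1-c", ifelse(p$any_multi_sw, "1-b", "1-a"))
}

#' Subdivide Cluster 0 by periphery geometry
#'
#' The centroid is the mean (x, y) of Cluster-0 periods in the embedding.
#' Periods whose radial distance is at or above the
#' `1 - periphery_fraction` quantile form the periphery, split into six
#' 60-degree sectors by the angle from the centroid: sector k (labels
#' 0-A..0-F) covers `[-180 + 60k, -120 + 60k)` degrees, counter-clockwise
#' from -180. Everything else is the centre ("rec").
#'
#' @param embedding n x 2 matrix of Cluster-0 embedding coordinates.
#' @param periphery_fraction Fraction of periods treated as peripheral.
#'   Default 0.084, back-calculated from published subcluster sizes
#'   (54,628 peripheral of 650,339 Cluster-0 periods).
#' @return Character vector: "rec" or "0-A".."0-F" per row.
#' @export
subdivide_cluster0 <- function(embedding, periphery_fraction = 0.084) {
  if (periphery_fraction <= 0 || periphery_fraction >= 0.5)
    stopf("periphery_fraction must be in (0, 0.5)")
  emb <- as.matrix(embedding)
  ctr <- colMeans(emb)
  dx <- emb[, 1] - ctr[1]; dy <- emb[, 2] - ctr[2]
  r <- sqrt(dx^2 + dy^2)
  cut <- stats::quantile(r, 1 - periphery_fraction, names = FALSE, type = 7)
  peripheral <- r >= cut & r > 0
  theta <- atan2(dy, dx) * 180 / pi          # [-180, 180)
  theta[theta >= 180] <- -180
  sector <- pmin(pmax(floor((theta + 180) / 60), 0), 5)
  out <- rep("rec", nrow(emb))
  out[peripheral] <- paste0("0-", LETTERS[sector[peripheral] + 1L])
  out
}

#' Assign the 13 phenotype labels
#'
#' Combines the landscape's semantic clusters with the Cluster-1 rules
#' and the Cluster-0 periphery geometry. When no landscape is given
#' (rule-only mode), all Cluster-0 periods are labelled "rec" and the
#' phenotype set collapses to 7 labels; this mode is fully deterministic
#' and used when embedding nondeterminism must be avoided.
#'
#' @param periods Period table from [assemble_periods()].
#' @param landscape Optional `sleep_landscape` fitted on these periods.
#' @param periphery_fraction Passed to [subdivide_cluster0()].
#' @param insomnia_peripheral Passed to [phenotype_catalog()].
#' @return The period table with `cluster`, `subcluster`,
#'   `is_recommended`, `is_insomnia_like` and `fracture_group` columns
#'   added.
#' @export
assign_phenotypes <- function(periods, landscape = NULL,
                              periphery_fraction = 0.084,
                              insomnia_peripheral = c("0-E", "0-F")) {
  p <- copy(as.data.table(periods))
  if (is.null(landscape)) {
    p[, cluster := rule_cluster(p)]
  } else {
    ch <- characterize_clusters(landscape, p)
    p[, cluster := ch$semantic]
  }
  sub <- character(nrow(p))
  sub[p$cluster == 4L] <- "4"
  sub[p$cluster == 3L] <- "3"
  sub[p$cluster == 2L] <- "2"
  if (any(p$cluster == 1L))
    sub[p$cluster == 1L] <- subdivide_cluster1(p[cluster == 1L])
  if (any(p$cluster == 0L)) {
    if (is.null(landscape)) {
      sub[p$cluster == 0L] <- "rec"
    } else {
      sub[p$cluster == 0L] <- subdivide_cluster0(
        landscape$embedding[p$cluster == 0L, , drop = FALSE],
        periphery_fraction)
    }
  }
  p[, subcluster := sub]
  cat <- phenotype_catalog(insomnia_peripheral)
  p[cat, on = "subcluster",
    `:=`(is_recommended = i.is_recommended,
         is_insomnia_like = i.is_insomnia_like,
         fracture_group = i.fracture_group)]
  p[]
}

#' Per-subcluster feature summary
#'
#' Mean (SD) of the key sleep features by subcluster, in the layout of the
#' published per-phenotype tables: window counts and sleep percentage are
#' period-feature means (zero-filled); window lengths and long-window
#' sleep/wake times are CONDITIONAL nightly means, i.e. averaged over the
#' nights that actually contain a window of that kind (absent kinds are
#' reported as NA, not 0). Empty subclusters are omitted with a warning.
#'
#' @param labelled_periods Output of [assign_phenotypes()].
#' @param nights Retained-night table from [assemble_periods()] (with
#'   `period_id`), used for the conditional length columns.
#' @return data.table: subcluster, n_periods, then mean/sd columns.
#' @export
phenotype_report <- function(labelled_periods, nights) {
  p <- as.data.table(labelled_periods)
  nights <- as.data.table(nights)
  nights <- nights[p[, .(period_id, subcluster)], on = "period_id"]
  levels_present <- PHENOTYPE_LEVELS[PHENOTYPE_LEVELS %in% p$subcluster]
  missing_lv <- setdiff(unique(p$subcluster), PHENOTYPE_LEVELS)
  if (length(missing_lv)) levels_present <- c(levels_present, missing_lv)
  empty <- setdiff(PHENOTYPE_LEVELS, p$subcluster)
  if (length(empty))
    warnf("empty subcluster(s) omitted: %s", paste(empty, collapse = ", "))
  per <- p[, .(n_periods = .N,
               lw_count_mean = mean(mean_lw_count), lw_count_sd = stats::sd(mean_lw_count),
               sw_count_mean = mean(mean_sw_count), sw_count_sd = stats::sd(mean_sw_count),
               sleep_percent_mean = mean(mean_sleep_percent),
               sleep_percent_sd = stats::sd(mean_sleep_percent)),
           by = subcluster]
  cond <- nights[, .(
    lw_length_mean = if (any(lw_count > 0)) mean(lw_length[lw_count > 0]) else NA_real_,
    lw_length_sd = if (sum(lw_count > 0) > 1) stats::sd(lw_length[lw_count > 0]) else NA_real_,
    sw_length_mean = if (any(sw_count > 0)) mean(sw_length[sw_count > 0]) else NA_real_,
    sw_length_sd = if (sum(sw_count > 0) > 1) stats::sd(sw_length[sw_count > 0]) else NA_real_,
    st_long_mean = if (any(lw_count > 0)) mean(st_long[lw_count > 0]) else NA_real_,
    wt_long_mean = if (any(lw_count > 0)) mean(wt_long[lw_count > 0]) else NA_real_,
    total_sleep_h = mean(st_long + st_short)),
    by = subcluster]
  out <- per[cond, on = "subcluster"]
  out[, subcluster := factor(subcluster, levels = levels_present)]
  setorder(out, subcluster)
  out[, subcluster := as.character(subcluster)]
  out[]
}
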