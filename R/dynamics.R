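# Temporal dynamics: within-individual transitions between the phenotypes
# of successive sleep periods, and the conditional transition probability
# (CTP) graph over them: CTP(A, B) = P(next = B | current = A), estimated
# as count(A -> B) / count(A -> *).

#' Extract within-individual transition pairs
#'
#' Every pair of successive retained periods of one individual (ordered by
#' period start date) forms a transition; individuals with fewer than two
#' periods contribute none. By default "successive" ignores calendar gaps
#' between the periods; `require_adjacent` restricts pairs to periods
#' whose 6-day blocks are calendar-adjacent.
#'
#' @param labelled_periods Output of [assign_phenotypes()] (needs
#'   `individual_id`, `period_id`, `start_date`, `subcluster`).
#' @param require_adjacent Only pair periods exactly 6 days apart.
#' @return data.table: individual_id, from_period, to_period, from, to,
#'   from_start, to_start.
#' @export
extract_transition_pairs <- function(labelled_periods, require_adjacent = FALSE) {
  p <- as.data.table(labelled_periods)
  if (anyDuplicated(p$period_id))
    stopf("duplicate period keys in input")
  setorder(p, individual_id, start_date)
  pairs <- p[, if (.N >= 2L) data.table(
    from_period = period_id[-.N], to_period = period_id[-1L],
    from = subcluster[-.N], to = subcluster[-1L],
    from_start = start_date[-.N], to_start = start_date[-1L]),
    by = individual_id]
  if (!nrow(pairs)) return(pairs)
  if (require_adjacent)
    pairs <- pairs[as.integer(to_start - from_start) == 6L]
  pairs[]
}

#' Build the conditional transition probability graph
#'
#' @param pairs Output of [extract_transition_pairs()].
#' @param nodes Ordered node labels (default: the phenotype levels present
#'   in the pairs, in catalogue order).
#' @return A `transition_graph`: `nodes`, integer `counts` matrix, `ctp`
#'   matrix (rows with outgoing transitions sum to 1; rows without are
#'   all-zero and listed in `empty_rows`).
#' @export
build_ctp <- function(pairs, nodes = NULL) {
  pairs <- as.data.table(pairs)
  if (!nrow(pairs)) stopf("no transition pairs")
  if (is.null(nodes)) {
    seen <- unique(c(pairs$from, pairs$to))
    nodes <- c(PHENOTYPE_LEVELS[PHENOTYPE_LEVELS %in% seen],
               sort(setdiff(seen, PHENOTYPE_LEVELS)))
  }
  unknown <- setdiff(unique(c(pairs$from, pairs$to)), nodes)
  if (length(unknown))
    stopf("unknown labels in pairs: %s", paste(unknown, collapse = ", "))
  counts <- table(factor(pairs$from, nodes), factor(pairs$to, nodes))
  counts <- matrix(as.integer(counts), length(nodes), length(nodes),
                   dimnames = list(from = nodes, to = nodes))
  out_tot <- rowSums(counts)
  ctp <- counts / ifelse(out_tot > 0, out_tot, 1)
  ctp[out_tot == 0, ] <- 0
  structure(list(nodes = nodes, counts = counts, ctp = ctp,
                 n_pairs = nrow(pairs),
                 empty_rows = nodes[out_tot == 0]),
            class = "transition_graph")
}

#' @export
print.transition_graph <- function(x, ...) {
  cat(sprintf("<transition_graph: %d nodes, %d pairs>\n",
              length(x$nodes), x$n_pairs))
  print(round(x$ctp, 3))
  invisible(x)
}

#' Grouped transition probabilities and relative reductions
#'
#' For each insomnia-like source phenotype, sums the CTP mass flowing into
#' its own fracture group (short: 1-a, 1-b, 4; long: 1-c, 2, 3) and into
#' the opposite group, and reports the relative reduction
#' `rr = 100 * (p_same - p_other) / p_same` (NA when `p_same` is 0).
#'
#' @param graph A `transition_graph` over subcluster labels.
#' @param catalog Phenotype catalogue (default [phenotype_catalog()]).
#' @return data.table: from, group, p_same_group, p_other_group,
#'   relative_reduction_pct.
#' @export
transition_summaries <- function(graph, catalog = phenotype_catalog()) {
  grp <- stats::setNames(catalog$fracture_group, catalog$subcluster)
  sources <- graph$nodes[!is.na(grp[graph$nodes])]
  if (!length(sources)) stopf("no fractured-phenotype sources in graph")
  short_nodes <- graph$nodes[grp[graph$nodes] %in% "short"]
  long_nodes <- graph$nodes[grp[graph$nodes] %in% "long"]
  rows <- lapply(sources, function(s) {
    g <- grp[[s]]
    same <- if (g == "short") short_nodes else long_nodes
    other <- if (g == "short") long_nodes else short_nodes
    p_same <- sum(graph$ctp[s, same])
    p_other <- sum(graph$ctp[s, other])
    data.table(from = s, group = g, p_same_group = p_same,
               p_other_group = p_other,
               relative_reduction_pct =
                 if (p_same > 0) 100 * (p_same - p_other) / p_same else NA_real_)
  })
  rbindlist(rows)
}
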