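# Health-condition cohorts and the static-vs-dynamic model comparison.
#
# Chronic conditions split individuals by baseline survey response
# (positive vs negative; no-answer excluded). Acute conditions split an
# individual's own timeline: "during" covers period start dates within 14
# days either side of the report; "baseline" covers start dates more than
# 50 days before it; the gap zone in between belongs to neither. The two
# models are compared on category-by-group contingency tables: the static
# model's categories are phenotype memberships of periods, the dynamic
# model's are ordered phenotype pairs of transitions (assigned to windows
# by the FROM period's start date).

#' Cohort design
#'
#' @param mode `"chronic"` or `"acute"`.
#' @param condition Condition name (matched against survey/symptom tables).
#' @param during_window Acute: inclusive day offsets of the during window
#'   (default `c(-14, 14)`).
#' @param baseline_before_days Acute: baseline is strictly more than this
#'   many days before the report (default 50).
#' @return A `cohort_design`.
#' @export
cohort_design <- function(mode = c("chronic", "acute"), condition,
                          during_window = c(-14L, 14L),
                          baseline_before_days = 50L) {
  mode <- match.arg(mode)
  if (during_window[1] > during_window[2])
    stopf("during_window must be ordered")
  if (-baseline_before_days >= during_window[1])
    stopf("baseline and during windows must be disjoint")
  structure(list(mode = mode, condition = condition,
                 during_window = as.integer(during_window),
                 baseline_before_days = as.integer(baseline_before_days)),
            class = "cohort_design")
}

#' Assign analysis units to cohort groups
#'
#' Units are periods (static model) or transition pairs (dynamic model);
#' each unit needs `individual_id` and a reference date: `start_date` for
#' periods, `from_start` for pairs. Chronic: groups are `positive` /
#' `negative` individuals (no-answer excluded). Acute: groups are
#' `during` / `baseline` windows of reporting individuals; individuals
#' with another report in the 50 days before a report are excluded, as
#' are reports with no baseline data.
#'
#' @param units data.table of periods or pairs.
#' @param design A [cohort_design()].
#' @param survey data.table (individual_id, condition, response) for
#'   chronic designs.
#' @param symptoms data.table (individual_id, condition, report_date) for
#'   acute designs.
#' @return The units with a `group` column, rows outside both groups
#'   dropped; attribute `"log"` records exclusions.
#' @export
assign_cohort <- function(units, design, survey = NULL, symptoms = NULL) {
  u <- copy(as.data.table(units))
  ref_col <- if ("from_start" %in% names(u)) "from_start" else "start_date"
  log <- character()
  if (design$mode == "chronic") {
    if (is.null(survey)) stopf("chronic design needs a survey table")
    sv <- as.data.table(survey)[condition == design$condition]
    if (!nrow(sv)) stopf("no survey rows for condition '%s'", design$condition)
    sv <- sv[response %in% c("positive", "negative")]
    u[, group := sv$response[match(individual_id, sv$individual_id)]]
    log <- sprintf("chronic '%s': %d positive, %d negative individuals; no-answer excluded",
                   design$condition, sum(sv$response == "positive"),
                   sum(sv$response == "negative"))
    u <- u[!is.na(group)]
  } else {
    if (is.null(symptoms)) stopf("acute design needs a symptoms table")
    sy <- as.data.table(symptoms)[condition == design$condition]
    if (!nrow(sy)) stopf("no symptom reports for condition '%s'", design$condition)
    all_sy <- as.data.table(symptoms)
    # clean rule: no other acute report in the 50 d before this report
    dirty <- vapply(seq_len(nrow(sy)), function(i) {
      o <- all_sy[individual_id == sy$individual_id[i] &
                  !(condition == sy$condition[i] & report_date == sy$report_date[i])]
      any(o$report_date < sy$report_date[i] &
          o$report_date >= sy$report_date[i] - design$baseline_before_days)
    }, logical(1))
    if (any(dirty))
      log <- c(log, sprintf("excluded %d report(s) with another report in the prior 50 d",
                            sum(dirty)))
    sy <- sy[!dirty]
    u[, group := NA_character_]
    kept_any <- logical(nrow(sy))
    for (i in seq_len(nrow(sy))) {
      sel <- u$individual_id == sy$individual_id[i]
      off <- as.numeric(u[[ref_col]] - sy$report_date[i])
      during <- sel & off >= design$during_window[1] & off <= design$during_window[2]
      base <- sel & off < -design$baseline_before_days
      if (!any(base)) {
        log <- c(log, sprintf("individual %s dropped: no baseline data before report",
                              sy$individual_id[i]))
        next
      }
      kept_any[i] <- TRUE
      u[during, group := "during"]
      u[base, group := "baseline"]
    }
    u <- u[!is.na(group)]
  }
  setattr(u, "log", log)
  u[]
}

#' Category-by-group contingency table
#'
#' @param units Grouped units from [assign_cohort()].
#' @param category_col Column holding the categorical model variable
#'   (`"subcluster"` for the static model; use [transition_category()] for
#'   the dynamic model).
#' @return Integer matrix categories x groups.
#' @export
contingency_table <- function(units, category_col = "subcluster") {
  u <- as.data.table(units)
  tab <- table(u[[category_col]], u$group)
  matrix(as.integer(tab), nrow(tab), ncol(tab),
         dimnames = list(category = rownames(tab), group = colnames(tab)))
}

#' Ordered-pair transition categories
#'
#' @param pairs Transition pairs with `from` and `to` labels.
#' @return Character vector "from>to".
#' @export
transition_category <- function(pairs) paste0(pairs$from, ">", pairs$to)

#' Goodness-of-fit chi-square between two cohort distributions
#'
#' The observed group's category counts are tested against the expected
#' group's category proportions scaled to the observed total
#' (`X^2 = sum (O - E)^2 / E`, dof = categories - 1, upper-tail p).
#' Categories with zero counts in both groups are dropped (dof reduced);
#' a category observed but with zero expected raises an error unless a
#' `pseudocount` is supplied (added to every expected cell before
#' scaling) - silent infinities are worse than loud failures.
#'
#' @param tab Categories x groups matrix from [contingency_table()].
#' @param observed,expected Group (column) names; defaults: the
#'   positive/during column observed, negative/baseline expected.
#' @param pseudocount Added to expected-group counts (default 0 = off).
#' @return List: statistic, dof, p_value, n_categories, dropped.
#' @export
chi_square_test <- function(tab, observed = NULL, expected = NULL,
                            pseudocount = 0) {
  grps <- colnames(tab)
  if (is.null(observed))
    observed <- intersect(c("positive", "during"), grps)[1]
  if (is.null(expected))
    expected <- intersect(c("negative", "baseline"), grps)[1]
  if (is.na(observed) || is.na(expected) || observed == expected)
    stopf("need two distinct groups; have: %s", paste(grps, collapse = ", "))
  O <- tab[, observed]; En <- tab[, expected]
  both_zero <- O == 0L & En == 0L
  dropped <- rownames(tab)[both_zero]
  O <- O[!both_zero]; En <- En[!both_zero]
  if (length(O) < 2) stopf("need >= 2 categories after filtering")
  En <- En + pseudocount
  if (any(En == 0 & O > 0))
    stopf("category observed but expected count 0 (%s); enable a pseudocount or regroup",
          paste(names(O)[En == 0 & O > 0], collapse = ", "))
  E <- En / sum(En) * sum(O)
  keep <- E > 0
  stat <- sum((O[keep] - E[keep])^2 / E[keep])
  dof <- length(O) - 1L
  list(statistic = stat, dof = dof,
       p_value = stats::pchisq(stat, dof, lower.tail = FALSE),
       n_categories = length(O), dropped = dropped)
}

#' Information gain of a category variable about group membership
#'
#' `IG(P, C) = H[P] - H[P | C]` in bits, computed from the joint counts:
#' `H[P]` is the entropy of the group margins and `H[P|C]` the
#' count-weighted entropy of groups within each category. Empty
#' categories contribute nothing; the result is non-negative up to
#' floating-point error.
#'
#' @param tab Categories x groups count matrix (>= 2 groups).
#' @return Information gain in bits.
#' @export
information_gain <- function(tab) {
  if (ncol(tab) < 2) stopf("information gain needs >= 2 groups")
  n <- sum(tab)
  if (n == 0) stopf("empty table")
  ent <- function(p) { p <- p[p > 0]; -sum(p * log2(p)) }
  h_p <- ent(colSums(tab) / n)
  p_c <- rowSums(tab) / n
  h_p_given_c <- sum(vapply(seq_len(nrow(tab)), function(i) {
    if (p_c[i] == 0) return(0)
    p_c[i] * ent(tab[i, ] / sum(tab[i, ]))
  }, numeric(1)))
  h_p - h_p_given_c
}

#' Compare the static and dynamic models for one condition
#'
#' Builds the static (period-phenotype) and dynamic (transition-pair)
#' contingency tables under one cohort design, runs the chi-square test
#' on each, computes both information gains and their ratio
#' `IG(P, C) / IG(P, S)` (how many times more information the transition
#' dynamics carry than static membership).
#'
#' @param labelled_periods Output of [assign_phenotypes()].
#' @param pairs Output of [extract_transition_pairs()] on the same periods.
#' @param design A [cohort_design()].
#' @param survey,symptoms Condition tables (as applicable).
#' @param pseudocount Passed to [chi_square_test()].
#' @return List: condition, static/dynamic tables, chi-square results,
#'   ig_static, ig_dynamic, ig_ratio (NA with a note when ig_static = 0),
#'   cohort sizes, exclusion logs.
#' @export
static_vs_dynamic <- function(labelled_periods, pairs, design,
                              survey = NULL, symptoms = NULL,
                              pseudocount = 0) {
  per_u <- assign_cohort(as.data.table(labelled_periods), design, survey, symptoms)
  pair_u <- assign_cohort(as.data.table(pairs), design, survey, symptoms)
  pair_u[, transition := transition_category(pair_u)]
  tab_s <- contingency_table(per_u, "subcluster")
  tab_d <- contingency_table(pair_u, "transition")
  chi_s <- chi_square_test(tab_s, pseudocount = pseudocount)
  chi_d <- chi_square_test(tab_d, pseudocount = pseudocount)
  ig_s <- information_gain(tab_s)
  ig_d <- information_gain(tab_d)
  list(condition = design$condition, mode = design$mode,
       static_table = tab_s, dynamic_table = tab_d,
       chi_static = chi_s, chi_dynamic = chi_d,
       ig_static = ig_s, ig_dynamic = ig_d,
       ig_ratio = if (ig_s > 0) ig_d / ig_s else NA_real_,
       cohort_sizes = list(periods = colSums(tab_s), pairs = colSums(tab_d)),
       log = c(attr(per_u, "log"), attr(pair_u, "log")))
}
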