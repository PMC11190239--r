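# Cohort assembly, chi-square goodness of fit, information gain, and the
# static-vs-dynamic comparison.

mk_survey <- function(...) {
  v <- c(...)
  data.table::data.table(individual_id = names(v), condition = "apnea",
                         response = unname(v))
}

test_that("chronic cohorts keep positive/negative and exclude no-answer", {
  periods <- mk_labelled_sequence(list(a = c("rec", "2"), b = c("rec", "rec"),
                                       c = c("4", "4")))
  sv <- mk_survey(a = "positive", b = "negative", c = "no_answer")
  d <- cohort_design("chronic", "apnea")
  u <- assign_cohort(periods, d, survey = sv)
  expect_setequal(unique(u$group), c("positive", "negative"))
  expect_false("c" %in% u$individual_id)
  expect_equal(sum(u$group == "positive"), 2L)
})

test_that("acute windows split during / baseline with a gap zone", {
  report <- as.Date("2020-06-01")
  starts <- report + c(13, -13, 0, -30, -51, -80, 14, 15)
  periods <- data.table::data.table(
    individual_id = "a", period_id = paste0("p", seq_along(starts)),
    start_date = starts, subcluster = "rec")
  sy <- data.table::data.table(individual_id = "a", condition = "flu",
                               report_date = report)
  d <- cohort_design("acute", "flu")
  u <- assign_cohort(periods, d, symptoms = sy)
  got <- stats::setNames(u$group, u$period_id)
  expect_equal(unname(got[c("p1", "p2", "p3", "p7")]), rep("during", 4))
  expect_equal(unname(got[c("p5", "p6")]), rep("baseline", 2))
  expect_false("p4" %in% names(got))  # -30 d: gap zone
  expect_false("p8" %in% names(got))  # +15 d: past the during window
})

test_that("acute clean rule and missing-baseline exclusions apply", {
  periods <- data.table::data.table(
    individual_id = c("a", "a", "b"),
    period_id = c("a1", "a2", "b1"),
    start_date = as.Date(c("2020-02-01", "2020-06-01", "2020-06-01")),
    subcluster = "rec")
  sy <- data.table::data.table(
    individual_id = c("a", "a", "b"), condition = "flu",
    report_date = as.Date(c("2020-05-25", "2020-06-20", "2020-06-05")))
  d <- cohort_design("acute", "flu")
  u <- assign_cohort(periods, d, symptoms = sy)
  # a's 2020-06-20 report has another report 26 d before: excluded;
  # its 2020-05-25 report stands: a1 baseline, a2 during
  expect_equal(u[u$individual_id == "a", ]$group[order(u[u$individual_id == "a", ]$period_id)],
               c("baseline", "during"))
  # b has no data before report-50d: dropped and logged
  expect_false("b" %in% u$individual_id)
  expect_true(any(grepl("no baseline", attr(u, "log"))))
})

test_that("transition pairs are windowed by the FROM period start date", {
  report <- as.Date("2020-06-01")
  pairs <- data.table::data.table(
    individual_id = "a", from_period = c("f1", "f2"), to_period = c("t1", "t2"),
    from = "rec", to = "2",
    from_start = report + c(-60, 10), to_start = report + c(-54, 16))
  sy <- data.table::data.table(individual_id = "a", condition = "flu",
                               report_date = report)
  u <- assign_cohort(pairs, cohort_design("acute", "flu"), symptoms = sy)
  expect_equal(u$group[match(c("f1", "f2"), u$from_period)],
               c("baseline", "during"))
})

test_that("chi-square follows the scaled-expected formula", {
  tab <- matrix(c(12L, 8L, 10L, 10L), 2, 2,
                dimnames = list(category = c("A", "B"),
                                group = c("positive", "negative")))
  res <- chi_square_test(tab)
  expect_equal(res$statistic, 0.8)
  expect_equal(res$dof, 1L)
  expect_equal(res$p_value, stats::pchisq(0.8, 1, lower.tail = FALSE))
  expect_equal(res$p_value, 0.3711, tolerance = 1e-3)
  # identical distributions give statistic 0, p 1
  tab0 <- matrix(c(5L, 5L, 5L, 5L), 2, 2,
                 dimnames = list(c("A", "B"), c("positive", "negative")))
  res0 <- chi_square_test(tab0)
  expect_equal(res0$statistic, 0)
  expect_equal(res0$p_value, 1)
})

test_that("chi-square matches stats::chisq.test goodness of fit on random tables", {
  set.seed(14)
  for (r in 1:50) {
    k <- sample(3:8, 1)
    O <- stats::rmultinom(1, 500, stats::runif(k, 0.5, 2))[, 1]
    En <- stats::rmultinom(1, 800, stats::runif(k, 0.5, 2))[, 1] + 1L
    tab <- cbind(positive = O, negative = En)
    rownames(tab) <- paste0("c", seq_len(k))
    got <- chi_square_test(tab)
    want <- suppressWarnings(stats::chisq.test(O, p = En / sum(En)))
    expect_equal(got$statistic, unname(want$statistic), tolerance = 1e-12)
    expect_equal(got$p_value, unname(want$p.value), tolerance = 1e-9)
  }
})

test_that("zero-cell handling: drop both-zero rows, error on observed-only", {
  tab <- matrix(c(10L, 0L, 5L, 8L, 0L, 7L), 3, 2,
                dimnames = list(c("A", "B", "C"), c("positive", "negative")))
  res <- chi_square_test(tab)
  expect_equal(res$dropped, "B")
  expect_equal(res$n_categories, 2L)
  tab2 <- matrix(c(10L, 3L, 8L, 0L), 2, 2,
                 dimnames = list(c("A", "B"), c("positive", "negative")))
  expect_error(chi_square_test(tab2), "pseudocount")
  expect_silent(chi_square_test(tab2, pseudocount = 0.5))
  expect_error(chi_square_test(matrix(c(1L, 1L), 1, 2,
                                      dimnames = list("A", c("positive", "negative")))),
               ">= 2 categories")
})

test_that("information gain: independence, perfect association, bounds", {
  ind <- outer(c(10, 20, 30), c(2, 3))
  expect_lt(abs(information_gain(ind)), 1e-12)
  diag2 <- matrix(c(10, 0, 0, 10), 2, 2)
  expect_equal(information_gain(diag2), 1)
  set.seed(15)
  for (r in 1:200) {
    tab <- matrix(stats::rpois(8, 5), 4, 2)
    if (any(colSums(tab) == 0)) next
    ig <- information_gain(tab)
    h <- function(q) { q <- q[q > 0]; -sum(q / sum(q) * log2(q / sum(q))) }
    expect_gte(ig, -1e-12)
    expect_lte(ig, min(h(colSums(tab)), h(rowSums(tab))) + 1e-12)
  }
  expect_error(information_gain(matrix(1:3, 3, 1)), ">= 2 groups")
})

test_that("information gain matches the mutual-information oracle to 1e-12", {
  set.seed(16)
  for (r in 1:1000) {
    nr <- sample(2:6, 1)
    tab <- matrix(stats::rpois(nr * 2, sample(1:8, 1)), nr, 2)
    if (any(colSums(tab) == 0) || sum(tab) == 0) next
    expect_lt(abs(information_gain(tab) - oracle_mutual_information(tab)),
              1e-12)
  }
})

test_that("static_vs_dynamic separates dynamics-only from prevalence-only effects", {
  set.seed(18)
  # dynamics-only: symmetric chains with equal stationary distributions
  sample_chain <- function(P, n) {
    s <- integer(n); s[1] <- sample(1:2, 1)
    for (t in 2:n) s[t] <- sample(1:2, 1, prob = P[s[t - 1], ])
    c("rec", "1-a")[s]
  }
  P_pos <- matrix(c(0.9, 0.1, 0.1, 0.9), 2, 2)
  P_neg <- matrix(c(0.6, 0.4, 0.4, 0.6), 2, 2)
  seqs <- c(lapply(stats::setNames(1:60, sprintf("p%02d", 1:60)),
                   function(i) sample_chain(P_pos, 12)),
            lapply(stats::setNames(1:60, sprintf("n%02d", 1:60)),
                   function(i) sample_chain(P_neg, 12)))
  periods <- mk_labelled_sequence(seqs)
  pairs <- extract_transition_pairs(periods)
  sv <- data.table::data.table(
    individual_id = names(seqs), condition = "apnea",
    response = rep(c("positive", "negative"), each = 60))
  res <- static_vs_dynamic(periods, pairs, cohort_design("chronic", "apnea"),
                           survey = sv)
  expect_gt(res$ig_ratio, 1)
  expect_lt(res$chi_dynamic$p_value, 0.01)

  # prevalence-only: shared next-state kernel, different current margins
  draw_pairs <- function(id, margin, n) {
    K <- matrix(c(0.8, 0.2, 0.5, 0.5), 2, 2, byrow = TRUE)
    from <- sample(1:2, n, replace = TRUE, prob = margin)
    to <- vapply(from, function(f) sample(1:2, 1, prob = K[f, ]), integer(1))
    data.table::data.table(
      individual_id = id, from_period = paste0(id, "f", 1:n),
      to_period = paste0(id, "t", 1:n),
      from = c("rec", "1-a")[from], to = c("rec", "1-a")[to],
      from_start = as.Date("2020-01-01"), to_start = as.Date("2020-01-07"),
      subcluster = c("rec", "1-a")[from],
      period_id = paste0(id, "f", 1:n), start_date = as.Date("2020-01-01"))
  }
  pos <- draw_pairs("pos", c(0.8, 0.2), 4000)
  neg <- draw_pairs("neg", c(0.4, 0.6), 4000)
  both <- rbind(pos, neg)
  sv2 <- data.table::data.table(individual_id = c("pos", "neg"),
                                condition = "apnea",
                                response = c("positive", "negative"))
  res2 <- static_vs_dynamic(both, both, cohort_design("chronic", "apnea"),
                            survey = sv2)
  expect_lt(abs(res2$ig_ratio - 1), 0.25)
})
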