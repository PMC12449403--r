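# Descriptive statistics and nonparametric tests.

test_that("median and quartiles use linear interpolation", {
  s <- median_iqr(c(1, 2, 3, 4))
  expect_equal(c(s$median, s$q25, s$q75), c(2.5, 1.75, 3.25))
  s <- median_iqr(c(5, 5, 5))
  expect_equal(c(s$median, s$q25, s$q75), c(5, 5, 5))
  s <- median_iqr(c(0.4, 1.6, 6.6))
  expect_equal(s$median, 1.6)
  expect_error(median_iqr(numeric(0)), "nonempty")
})

test_that("Mann-Whitney U is exact for small untied samples", {
  res <- mann_whitney_u(c(1, 2), c(3, 4))
  expect_equal(res$statistic, 0)
  expect_equal(res$p_value, 1 / 3, tolerance = 1e-12)
  x <- c(1.2, 3.4, 2.2, 5.1, 0.3)
  same <- mann_whitney_u(x, x)
  expect_gte(same$p_value, 0.99)
})

test_that("Mann-Whitney U is symmetric in its samples", {
  set.seed(21)
  for (i in 1:10) {
    x <- rnorm(12); y <- rnorm(15, 0.3)
    expect_equal(mann_whitney_u(x, y)$p_value,
                 mann_whitney_u(y, x)$p_value, tolerance = 1e-12)
  }
})

test_that("Kruskal-Wallis reproduces hand-computed ranks and edge cases", {
  res <- kruskal_wallis(list(c(1, 2, 3), c(4, 5, 6), c(7, 8, 9)))
  expect_equal(res$statistic, 7.2, tolerance = 1e-12)
  expect_equal(res$p_value, stats::pchisq(7.2, df = 2, lower.tail = FALSE),
               tolerance = 1e-12)
  same <- kruskal_wallis(list(rep(2, 4), rep(2, 5), rep(2, 3)))
  expect_equal(same$statistic, 0)
  expect_equal(same$p_value, 1)
  expect_error(kruskal_wallis(list(c(1, 2))), ">= 2")
})

test_that("Bonferroni multiplies, caps and never decreases", {
  expect_equal(bonferroni_adjust(0.01, m = 3), 0.03)
  expect_equal(bonferroni_adjust(0.5, m = 3), 1)
  set.seed(2)
  p <- runif(10)
  expect_true(all(bonferroni_adjust(p, m = 12) >= p))
  expect_error(bonferroni_adjust(p, m = 5), "at least")
})

test_that("categorical association switches to Fisher for sparse 2x2", {
  res <- categorical_association(matrix(c(3, 1, 1, 3), 2))
  expect_equal(res$test, "fisher_exact")
  expect_equal(res$p_value, 0.4857143, tolerance = 1e-6)
  flat <- categorical_association(matrix(c(10, 10, 10, 10), 2))
  expect_equal(flat$test, "chi_square")
  expect_equal(flat$statistic, 0)
  expect_equal(flat$p_value, 1)
  m <- matrix(c(3, 1, 2, 4), 2)
  expect_equal(categorical_association(m)$p_value,
               categorical_association(t(m))$p_value, tolerance = 1e-12)
  expect_error(categorical_association(matrix(c(0, 0, 3, 4), 2)),
               "zero margin")
})

test_that("role comparison flags separated roles and skips empty ones", {
  set.seed(31)
  ct <- data.frame(
    network_id = "g", provider_id = sprintf("p%d", 1:60),
    role = rep(c("registered_nurse", "physician"), each = 30L),
    degree = 1L,
    betweenness = c(runif(30, 0, 0.2), runif(30, 0.5, 1)),
    closeness = runif(60), eigenvector = runif(60),
    stringsAsFactors = FALSE)
  expect_warning(cmp <- compare_roles_within_network(ct),
                 "zero nodes")
  pw <- cmp$pairwise
  sep <- pw[pw$measure == "betweenness", ]
  expect_lt(sep$adjusted_p, 0.001)
  expect_true(all(cmp$pairwise$adjusted_p >= cmp$pairwise$p_value))
})

test_that("null role comparisons keep the omnibus near uniform", {
  set.seed(32)
  p <- replicate(100, {
    ct <- data.frame(role = rep(c("a", "b", "c"), each = 12L),
                     betweenness = rnorm(36), closeness = rnorm(36),
                     eigenvector = rnorm(36), stringsAsFactors = FALSE)
    compare_roles_within_network(ct, roles = c("a", "b", "c"),
                                 measures = "betweenness")$omnibus$p_value
  })
  expect_gt(mean(p < 0.05), 0)
  expect_lt(mean(p < 0.05), 0.12)
  expect_gt(mean(p), 0.35)   # roughly uniform under the null
})

test_that("deterioration stratum comparison recovers a planted shift", {
  set.seed(33)
  base <- function(n, det) data.frame(
    role = "frontline_provider", deterioration = det,
    betweenness = runif(n), closeness = runif(n),
    eigenvector = runif(n), stringsAsFactors = FALSE)
  det <- base(100L, TRUE)
  det$eigenvector <- det$eigenvector + 0.25
  nodes <- rbind(det, base(1000L, FALSE))
  res <- compare_det_vs_free(nodes, roles = "frontline_provider")
  ev <- res[res$measure == "eigenvector", ]
  expect_lt(ev$p_value, 0.05)
  expect_gt(ev$median_det, ev$median_free)
  # identical strata: no signal
  dup <- rbind(base(50L, TRUE), base(50L, FALSE))
  dup$betweenness <- rep(runif(50), 2L)
  dup$closeness <- rep(runif(50), 2L)
  dup$eigenvector <- rep(runif(50), 2L)
  res2 <- compare_det_vs_free(dup, roles = "frontline_provider")
  expect_true(all(res2$p_value >= 0.99))
  expect_error(compare_det_vs_free(base(10L, TRUE)), "strata")
})

test_that("epoch comparison is null on a shared fixture and drops empties", {
  ns <- data.frame(window = rep(c("[-36,-24)", "[-24,-12)", "[-12,0)"),
                   each = 10L),
                   n_nodes = rep(5:14, 3L), n_edges = rep(7:16, 3L),
                   clustering = rep(seq(0, 0.9, 0.1), 3L),
                   diameter = rep(1:10, 3L), radius = rep(1L, 30L),
                   stringsAsFactors = FALSE)
  cmp <- compare_epochs(ns)
  expect_true(all(cmp$tests$p_value[cmp$tests$measure != "radius"] == 1))
  ns2 <- ns[ns$window != "[-24,-12)", ]
  expect_warning(cmp2 <- compare_epochs(ns2), "dropped")
  expect_equal(sort(unique(cmp2$descriptives$window)),
               sort(c("[-36,-24)", "[-12,0)")))
})

test_that("cohort percentages follow the declared display rounding", {
  cs <- cohort_summary_counts(
    n_total_encounters = 200L, n_linked_encounters = 94L,
    n_det_encounters = 5L, days_det = 40, days_total = 480,
    msgs_det = 99, msgs_total = 1000, n_post_only = 2L)
  expect_equal(cs$pct_linked, 47)
  expect_equal(cs$prop_linked, 94 / 200)
  expect_equal(cs$pct_days, 8.3)
  expect_equal(cs$pct_msgs, 9.9)
  expect_equal(cs$n_subnetworks_analyzed, 92L)
  none <- cohort_summary_counts(100L, 50L, 0L, 0, 0, 0, 10, 0L)
  expect_true(is.na(none$pct_days))
})

test_that("cohort summary raw proportions are exact on a built cohort", {
  co <- generate_cohort(sim_config(n_total_encounters = 60L,
                                   p_deterioration = 0.2, seed = 14))
  cs <- cohort_summary(co)
  expect_equal(cs$prop_linked, cs$n_linked_encounters / 60)
  expect_equal(cs$prop_msgs, cs$msgs_det / cs$msgs_total)
  expect_equal(cs$prop_days, cs$cohort_days_det / cs$cohort_days_total)
  expect_equal(cs$n_subnetworks_analyzed +
                 cs$n_subnetworks_excluded_post_only,
               cs$n_linked_encounters)
})

test_that("role flow counts delivered pairs with dual marginals", {
  prov <- make_providers(c("r1", "f1", "f2"),
                         c("registered_nurse", "frontline_provider",
                           "frontline_provider"))
  msgs <- make_messages("r1", list(c("f1", "f2")),
                        ts_utc("2022-10-01T10:00"), "E1")
  rf <- role_flow_matrix(msgs, prov)
  expect_equal(rf$matrix["registered_nurse", "frontline_provider"], 2L)
  expect_equal(sum(rf$matrix), 2L)
  expect_equal(unname(rf$sender_share_messages["registered_nurse"]), 1)
  expect_equal(unname(rf$recipient_share_pairs["frontline_provider"]), 1)
  co <- generate_cohort(sim_config(n_total_encounters = 40L, seed = 15))
  rf2 <- role_flow_matrix(co$messages, co$providers)
  pairs <- sum(lengths(co$messages$recipient_ids)) -
    sum(mapply(function(s, r) sum(r == s), co$messages$sender_id,
               co$messages$recipient_ids))
  expect_equal(rf2$n_pairs, pairs)
  expect_equal(sum(rf2$sender_share_messages), 1)
})
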