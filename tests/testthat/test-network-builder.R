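# Graph construction: pair expansion, weighting, partitioning, Time 0
# filtering, epoch windows, projection and serialization.

t_base <- ts_utc("2022-10-05T12:00")

test_that("a multi-recipient message expands to one edge per recipient", {
  msgs <- make_messages("p1", list(c("p2", "p3")), t_base, "E1")
  g <- build_global_network(msgs, make_providers(c("p1", "p2", "p3")))
  expect_equal(nrow(g$nodes), 3L)
  expect_equal(g$edges[, c("from", "to", "weight")],
               data.frame(from = c("p1", "p1"), to = c("p2", "p3"),
                          weight = c(1L, 1L), stringsAsFactors = FALSE))
})

test_that("repeated sender-recipient pairs accumulate weight", {
  msgs <- make_messages(c("p1", "p1"), list("p2", "p2"),
                        t_base + c(0, 60), "E1")
  g <- build_global_network(msgs, make_providers(c("p1", "p2")))
  expect_equal(g$edges$weight, 2L)
  expect_equal(nrow(g$edges), 1L)
})

test_that("self-recipients produce no edges and no isolated nodes", {
  msgs <- make_messages(c("p1", "p1"), list("p1", c("p1", "p2")),
                        t_base + c(0, 60), "E1")
  g <- build_global_network(msgs, make_providers(c("p1", "p2")))
  expect_equal(nrow(g$edges), 1L)
  expect_equal(g$edges$from, "p1")
  expect_equal(g$edges$to, "p2")
  expect_equal(nrow(g$nodes), 2L)   # p1 appears via the delivered pair only
})

test_that("edge weights equal a brute-force tally on a random fixture", {
  set.seed(42)
  prov <- make_providers(sprintf("p%d", 1:6))
  sender <- sample(prov$provider_id, 20L, replace = TRUE)
  rcpt <- lapply(seq_len(20L), function(i)
    sample(setdiff(prov$provider_id, sender[i]), sample(1:3, 1L)))
  msgs <- make_messages(sender, rcpt, t_base + 60 * (1:20), "E1")
  g <- build_global_network(msgs, prov)
  hand <- table(paste(rep(sender, lengths(rcpt)), unlist(rcpt)))
  got <- stats::setNames(g$edges$weight, paste(g$edges$from, g$edges$to))
  expect_equal(sort(names(got)), sort(names(hand)))
  expect_equal(as.integer(hand[names(got)]), unname(got))
  # weight conservation: total weight = delivered pairs (no self pairs here)
  expect_equal(sum(g$edges$weight), sum(lengths(rcpt)))
})

test_that("messages without an encounter link are excluded from stage one", {
  msgs <- make_messages(c("p1", "p2"), list("p2", "p1"),
                        t_base + c(0, 60), c("E1", NA))
  g <- build_global_network(msgs, make_providers(c("p1", "p2")))
  expect_equal(sum(g$edges$weight), 1L)
})

test_that("encounter partitioning is by message, not provider", {
  prov <- make_providers(c("p1", "p2", "p3"))
  msgs <- make_messages(c("p1", "p1", "p2"), list("p2", "p3", "p3"),
                        t_base + 60 * (0:2), c("E1", "E2", "E2"))
  enc <- make_encounters(c("E1", "E2"),
                         rep(t_base - 3600, 2L), rep(t_base + 86400, 2L))
  nets <- build_encounter_subnetworks(msgs, enc, prov)
  expect_named(nets, c("E1", "E2"))
  expect_equal(nrow(nets$E1$nodes), 2L)
  expect_equal(nrow(nets$E2$nodes), 3L)
  expect_true("p1" %in% nets$E1$nodes$provider_id &&
                "p1" %in% nets$E2$nodes$provider_id)
  # conservation: per-encounter weights sum to all delivered pairs
  expect_equal(sum(vapply(nets, function(g) sum(g$edges$weight), 1)), 3)
})

test_that("pre-deterioration filtering is strictly before Time 0", {
  enc <- make_encounters("E1", t_base - 86400, t_base + 86400,
                         det = list(t_base))
  msgs <- make_messages(rep("p1", 3L), rep(list("p2"), 3L),
                        c(t_base - 600, t_base, t_base + 300),
                        rep("E1", 3L))
  kept <- filter_pre_deterioration(msgs, enc[1L, , drop = FALSE])
  expect_equal(nrow(kept), 1L)
  expect_equal(kept$sent_at, t_base - 600)
  enc_free <- make_encounters("E2", t_base, t_base + 3600)
  expect_error(
    filter_pre_deterioration(msgs, enc_free[1L, , drop = FALSE]),
    "Time 0")
})

test_that("deterioration cohorts split into pre-window and post-only sets", {
  # 120 deteriorating encounters; 14 have messages only at/after Time 0
  n <- 120L
  ids <- sprintf("D%03d", seq_len(n))
  admit <- rep(t_base - 86400, n)
  enc <- make_encounters(ids, admit, rep(t_base + 86400, n),
                         det = rep(list(t_base), n))
  post_only <- seq_len(14L)
  sent <- ifelse(seq_len(n) %in% post_only, t_base + 600, t_base - 600)
  msgs <- make_messages(rep("p1", n), rep(list("p2"), n),
                        as.POSIXct(sent, origin = "1970-01-01", tz = "UTC"),
                        ids)
  co <- new_cohort(make_providers(c("p1", "p2")), enc, msgs, n)
  ect <- encounter_centrality_tables(co)
  expect_equal(ect$n_det_subnetworks, 106L)
  expect_equal(ect$n_post_only_excluded, 14L)
  cs <- cohort_summary(co)
  expect_equal(cs$n_subnetworks_excluded_post_only, 14L)
  expect_equal(cs$n_subnetworks_analyzed, 120L - 14L)
})

test_that("epoch windows are half-open [lower, upper) against Time 0", {
  enc <- make_encounters("E1", t_base - 40 * 3600, t_base + 3600,
                         det = list(t_base))
  prov <- make_providers(c("p1", "p2"))
  at_h <- function(h) t_base + h * 3600
  msgs <- make_messages(rep("p1", 4L), rep(list("p2"), 4L),
                        c(at_h(-12), at_h(-36), at_h(-36.01), at_h(0)),
                        rep("E1", 4L))
  nets <- build_epoch_subnetworks(msgs, enc[1L, , drop = FALSE],
                                  epoch_spec(), prov)
  expect_named(nets, c("[-36,-24)", "[-12,0)"))
  expect_equal(sum(nets[["[-12,0)"]]$edges$weight), 1L)   # the -12 h message
  expect_equal(sum(nets[["[-36,-24)"]]$edges$weight), 1L) # the -36 h message
  msgs2 <- make_messages(rep("p1", 3L), rep(list("p2"), 3L),
                         c(at_h(-30), at_h(-18), at_h(-3)), rep("E1", 3L))
  nets2 <- build_epoch_subnetworks(msgs2, enc[1L, , drop = FALSE],
                                   epoch_spec(), prov)
  expect_length(nets2, 3L)
  expect_true(all(vapply(nets2, function(g) nrow(g$edges), 1L) == 1L))
})

test_that("malformed epoch specifications are rejected", {
  expect_error(epoch_spec(list(c(-24, -36))), "lower < upper")
  expect_error(epoch_spec(list(c(-12, 6))), "lower < upper")
  expect_error(epoch_spec(list(c(-36, -20), c(-24, 0))), "contiguous")
})

test_that("undirected projection merges reciprocal edges", {
  g <- make_graph(edge_df(c("a", "b"), c("b", "a"), c(2L, 3L)))
  pr <- undirected_projection(g)
  expect_equal(pr$edges$weight, 5L)
  g2 <- make_graph(edge_df("a", "b", 1L))
  expect_equal(undirected_projection(g2)$edges$weight, 1L)
  set.seed(8)
  for (i in 1:5) {
    gr <- random_graph(10L)
    pr <- undirected_projection(gr)
    pairs <- unique(paste(pmin(gr$edges$from, gr$edges$to),
                          pmax(gr$edges$from, gr$edges$to)))
    expect_equal(nrow(pr$edges), length(pairs))
  }
})

test_that("graph construction is invariant to message row order", {
  set.seed(3)
  prov <- make_providers(sprintf("p%d", 1:5))
  sender <- sample(prov$provider_id, 15L, replace = TRUE)
  rcpt <- lapply(seq_len(15L), function(i)
    sample(setdiff(prov$provider_id, sender[i]), 2L))
  msgs <- make_messages(sender, rcpt, t_base + 60 * (1:15), "E1")
  g1 <- build_global_network(msgs, prov)
  perm <- msgs[sample.int(15L), , drop = FALSE]
  g2 <- build_global_network(perm, prov)
  expect_equal(g1$edges, g2$edges)
  expect_equal(g1$nodes, g2$nodes)
})

test_that("GraphML and edge-list exports round-trip", {
  roles <- c(a = "registered_nurse", b = "physician", c = "other")
  g <- make_graph(edge_df(c("a", "b", "a"), c("b", "c", "c"),
                          c(2L, 1L, 4L)), roles = roles, network_id = "fix")
  path <- withr::local_tempfile(fileext = ".graphml")
  export_graph(g, path, "graphml")
  g2 <- import_graph(path, "graphml")
  expect_equal(g2$network_id, "fix")
  expect_equal(g2$nodes, g$nodes)
  expect_equal(g2$edges, g$edges)

  empty <- make_graph(NULL, network_id = "none")
  path0 <- withr::local_tempfile(fileext = ".graphml")
  export_graph(empty, path0, "graphml")
  expect_equal(nrow(import_graph(path0, "graphml")$nodes), 0L)

  pathe <- withr::local_tempfile(fileext = ".csv")
  export_graph(g, pathe, "edgelist")
  expect_equal(nrow(utils::read.csv(pathe)), nrow(g$edges))
  prov <- make_providers(names(roles), unname(roles))
  g3 <- import_graph(pathe, "edgelist", providers = prov,
                     network_id = "fix")
  expect_equal(g3$edges, g$edges)
  expect_error(export_graph(g, pathe, "dot"))
})
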