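# Directed weighted provider graphs built from message records.
#
# A message with k recipients contributes one unit of weight to each of
# the k directed (sender -> recipient) edges; recipients equal to the
# sender are dropped (no self-loops).  Node sets are message-derived: a
# provider appears only if they sent or received at least one delivered
# (message, recipient) pair.

#' Construct a provider graph
#'
#' @param network_id Identifier string.
#' @param nodes data.frame with `provider_id`, `role`.
#' @param edges data.frame with `from`, `to`, `weight` (positive integer
#'   message counts); no self-loops; endpoints must be nodes.
#' @return Object of class `"provider_graph"`.
#' @export
provider_graph <- function(network_id, nodes, edges) {
  stopifnot(is.data.frame(nodes), is.data.frame(edges))
  if (nrow(edges)) {
    if (any(edges$from == edges$to))
      stop("provider_graph: self-loop edges are not allowed", call. = FALSE)
    if (!all(c(edges$from, edges$to) %in% nodes$provider_id))
      stop("provider_graph: edge endpoint not in node set", call. = FALSE)
    if (any(edges$weight < 1) || any(edges$weight != round(edges$weight)))
      stop("provider_graph: weights must be positive integers",
           call. = FALSE)
    if (anyDuplicated(paste(edges$from, edges$to, sep = "\r")))
      stop("provider_graph: duplicate directed edge", call. = FALSE)
  }
  structure(list(network_id = as.character(network_id),
                 nodes = nodes[order(nodes$provider_id), , drop = FALSE],
                 edges = edges),
            class = "provider_graph")
}

#' @export
print.provider_graph <- function(x, ...) {
  cat(sprintf("<provider_graph '%s'> %d nodes, %d directed edges, total weight %d\n",
              x$network_id, nrow(x$nodes), nrow(x$edges),
              if (nrow(x$edges)) sum(x$edges$weight) else 0L))
  invisible(x)
}

# expand messages into delivered (sender, recipient) pairs, dropping
# self-recipient pairs; returns data.frame(from, to) plus the count of
# dropped self pairs as an attribute
expand_delivered_pairs <- function(messages) {
  k <- lengths(messages$recipient_ids)
  from <- rep(messages$sender_id, k)
  to <- unlist(messages$recipient_ids, use.names = FALSE)
  if (is.null(to)) to <- character(0)
  self <- from == to
  out <- data.frame(from = from[!self], to = to[!self],
                    stringsAsFactors = FALSE)
  attr(out, "n_self_pairs_dropped") <- sum(self)
  out
}

build_graph_from_pairs <- function(pairs, providers, network_id) {
  if (nrow(pairs) == 0L) {
    nodes <- data.frame(provider_id = character(0), role = character(0),
                        stringsAsFactors = FALSE)
    edges <- data.frame(from = character(0), to = character(0),
                        weight = integer(0), stringsAsFactors = FALSE)
    return(provider_graph(network_id, nodes, edges))
  }
  ids <- sort(unique(c(pairs$from, pairs$to)))
  i1 <- match(pairs$from, ids)
  i2 <- match(pairs$to, ids)
  code <- (i1 - 1) * length(ids) + i2
  tab <- table(code)
  ucode <- as.numeric(names(tab))
  edges <- data.frame(
    from = ids[(ucode - 1) %/% length(ids) + 1],
    to = ids[(ucode - 1) %% length(ids) + 1],
    weight = as.integer(tab),
    stringsAsFactors = FALSE)
  edges <- edges[order(edges$from, edges$to), , drop = FALSE]
  rownames(edges) <- NULL
  role <- providers$role[match(ids, providers$provider_id)]
  if (anyNA(role))
    stop(sprintf("unknown provider(s) in messages: %s",
                 paste(ids[is.na(role)], collapse = ", ")), call. = FALSE)
  nodes <- data.frame(provider_id = ids, role = role,
                      stringsAsFactors = FALSE)
  provider_graph(network_id, nodes, edges)
}

#' Build the global provider network
#'
#' Stage one of the analysis: one network over all encounter-linked
#' messages.  Messages without an encounter link are excluded.
#'
#' @param messages Message record data.frame (see [read_message_log()]).
#' @param providers Provider table.
#' @param network_id Identifier (default "global").
#' @return A [provider_graph()]; empty input gives a 0-node graph.
#' @export
build_global_network <- function(messages, providers,
                                 network_id = "global") {
  linked <- messages[!is.na(messages$encounter_id), , drop = FALSE]
  build_graph_from_pairs(expand_delivered_pairs(linked), providers,
                         network_id)
}

#' Build one subnetwork per encounter
#'
#' Stage two: messages are partitioned by encounter and each partition is
#' built into its own graph.  Encounters with zero linked messages are
#' absent from the result.
#'
#' @inheritParams build_global_network
#' @param encounters Encounter table; only encounters present here are
#'   built.
#' @return Named list `encounter_id -> provider_graph`.
#' @export
build_encounter_subnetworks <- function(messages, encounters, providers) {
  linked <- messages[!is.na(messages$encounter_id) &
                       messages$encounter_id %in% encounters$encounter_id, ,
                     drop = FALSE]
  if (nrow(linked) == 0L) return(stats::setNames(list(), character(0)))
  parts <- split(seq_len(nrow(linked)), linked$encounter_id)
  out <- lapply(names(parts), function(eid)
    build_graph_from_pairs(
      expand_delivered_pairs(linked[parts[[eid]], , drop = FALSE]),
      providers, eid))
  stats::setNames(out, names(parts))
}

#' Restrict an encounter's messages to those sent before Time 0
#'
#' Keeps messages with `sent_at` strictly before the encounter's first
#' deterioration.  An encounter whose every message is at or after Time 0
#' yields an empty set; such post-only subnetworks are excluded from the
#' deterioration stratum downstream.
#'
#' @param messages Message records (any encounters).
#' @param encounter One encounter row; must have at least one
#'   deterioration.
#' @return The retained message records.
#' @export
filter_pre_deterioration <- function(messages, encounter) {
  t0 <- time_zero(encounter)
  if (is.na(t0))
    stop(sprintf("encounter %s has no deterioration; Time 0 is undefined",
                 encounter$encounter_id[[1L]]), call. = FALSE)
  sel <- !is.na(messages$encounter_id) &
    messages$encounter_id == encounter$encounter_id[[1L]] &
    messages$sent_at < t0
  messages[sel, , drop = FALSE]
}

#' Epoch window specification
#'
#' Ordered, contiguous, non-overlapping half-open windows `[lower, upper)`
#' in hours relative to Time 0, all ending at or before Time 0.  The
#' default covers the 36 hours before deterioration in 12-hour increments.
#'
#' @param windows List of length-2 numeric vectors `c(lower_h, upper_h)`.
#' @return Object of class `"epoch_spec"`.
#' @export
epoch_spec <- function(windows = list(c(-36, -24), c(-24, -12), c(-12, 0))) {
  lo <- vapply(windows, `[`, numeric(1), 1L)
  hi <- vapply(windows, `[`, numeric(1), 2L)
  if (any(hi <= lo) || any(hi > 0))
    stop("epoch windows must satisfy lower < upper <= 0", call. = FALSE)
  if (is.unsorted(lo, strictly = TRUE) ||
      any(abs(hi[-length(hi)] - lo[-1L]) > 1e-9))
    stop("epoch windows must be ordered and contiguous", call. = FALSE)
  structure(list(lower_h = lo, upper_h = hi,
                 labels = sprintf("[%g,%g)", lo, hi)),
            class = "epoch_spec")
}

#' Build 12-hour epoch subnetworks anchored at Time 0
#'
#' Stage three: each message of the encounter is assigned to the window
#' `[lower, upper)` containing its offset from Time 0 in hours; windows
#' with no messages yield no graph (this is how the number of analysable
#' subnetworks shrinks for the earlier windows).
#'
#' @param messages Message records.
#' @param encounter Encounter row with a deterioration.
#' @param epochs An [epoch_spec()].
#' @param providers Provider table.
#' @return Named list `window label -> provider_graph` (possibly empty).
#' @export
build_epoch_subnetworks <- function(messages, encounter,
                                    epochs = epoch_spec(),
                                    providers) {
  if (!inherits(epochs, "epoch_spec"))
    stop("epochs must be an epoch_spec object", call. = FALSE)
  t0 <- time_zero(encounter)
  if (is.na(t0))
    stop(sprintf("encounter %s has no deterioration; Time 0 is undefined",
                 encounter$encounter_id[[1L]]), call. = FALSE)
  sel <- !is.na(messages$encounter_id) &
    messages$encounter_id == encounter$encounter_id[[1L]]
  msgs <- messages[sel, , drop = FALSE]
  off_h <- as.numeric(msgs$sent_at - t0, units = "hours")
  out <- list()
  for (w in seq_along(epochs$lower_h)) {
    in_w <- off_h >= epochs$lower_h[w] & off_h < epochs$upper_h[w]
    if (!any(in_w)) next
    gid <- sprintf("%s%s", encounter$encounter_id[[1L]], epochs$labels[w])
    out[[epochs$labels[w]]] <- build_graph_from_pairs(
      expand_delivered_pairs(msgs[in_w, , drop = FALSE]), providers, gid)
  }
  out
}

#' Undirected weighted projection of a provider graph
#'
#' The undirected edge \{a, b\} exists iff either directed edge exists;
#' its weight is the sum of the two directed weights.  Distance-based
#' metrics run on this projection (unweighted), eigenvector centrality on
#' its weights.
#'
#' @param graph A [provider_graph()].
#' @return List with `nodes` (as in the graph) and `edges`
#'   (`a`, `b`, `weight` with `a < b`).
#' @export
undirected_projection <- function(graph) {
  e <- graph$edges
  if (nrow(e) == 0L) {
    return(list(nodes = graph$nodes,
                edges = data.frame(a = character(0), b = character(0),
                                   weight = integer(0),
                                   stringsAsFactors = FALSE)))
  }
  a <- pmin(e$from, e$to)
  b <- pmax(e$from, e$to)
  key <- paste(a, b, sep = "\r")
  w <- tapply(e$weight, key, sum)
  parts <- strsplit(names(w), "\r", fixed = TRUE)
  ed <- data.frame(a = vapply(parts, `[`, character(1), 1L),
                   b = vapply(parts, `[`, character(1), 2L),
                   weight = as.integer(w), stringsAsFactors = FALSE)
  ed <- ed[order(ed$a, ed$b), , drop = FALSE]
  rownames(ed) <- NULL
  list(nodes = graph$nodes, edges = ed)
}
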