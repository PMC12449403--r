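# Graph construction helpers for tests.

# graph from a directed edge data.frame (from, to, weight); roles default
# to "other" unless supplied as a named vector id -> role
make_graph <- function(edges, roles = NULL, network_id = "test") {
  if (is.null(edges) || nrow(edges) == 0L) {
    nodes <- data.frame(provider_id = character(0), role = character(0),
                        stringsAsFactors = FALSE)
    edges <- data.frame(from = character(0), to = character(0),
                        weight = integer(0), stringsAsFactors = FALSE)
    return(provider_graph(network_id, nodes, edges))
  }
  if (is.null(edges$weight)) edges$weight <- 1L
  ids <- sort(unique(c(edges$from, edges$to)))
  role <- if (is.null(roles)) rep("other", length(ids)) else
    unname(roles[ids])
  nodes <- data.frame(provider_id = ids, role = role,
                      stringsAsFactors = FALSE)
  edges <- edges[order(edges$from, edges$to), , drop = FALSE]
  rownames(edges) <- NULL
  provider_graph(network_id, nodes, edges)
}

edge_df <- function(from, to, weight = 1L) {
  data.frame(from = from, to = to, weight = as.integer(weight),
             stringsAsFactors = FALSE)
}

# undirected path / star / cycle generators over n nodes (unit weights,
# directed edges a->b only; the undirected projection is the shape)
path_graph <- function(n) {
  ids <- sprintf("v%02d", seq_len(n))
  make_graph(edge_df(ids[-n], ids[-1L]))
}

star_graph <- function(n) {   # hub v01 + (n-1) leaves
  ids <- sprintf("v%02d", seq_len(n))
  make_graph(edge_df(rep(ids[1L], n - 1L), ids[-1L]))
}

# random directed weighted graph on up to n_max nodes
random_graph <- function(n_max = 7L, p = 0.35) {
  n <- sample(2:n_max, 1L)
  ids <- sprintf("v%02d", seq_len(n))
  pairs <- expand.grid(from = ids, to = ids, stringsAsFactors = FALSE)
  pairs <- pairs[pairs$from != pairs$to, ]
  keep <- stats::runif(nrow(pairs)) < p
  if (!any(keep)) keep[sample.int(nrow(pairs), 1L)] <- TRUE
  e <- pairs[keep, , drop = FALSE]
  e$weight <- sample(1:3, nrow(e), replace = TRUE)
  make_graph(e)
}

# minimal message record table; recipients given as list of character
# vectors; times as POSIXct
make_messages <- function(sender, recipients, sent_at, encounter_id) {
  n <- length(sender)
  df <- data.frame(message_id = sprintf("m%03d", seq_len(n)),
                   stringsAsFactors = FALSE)
  df$sent_at <- sent_at
  df$sender_id <- sender
  df$recipient_ids <- recipients
  df$encounter_id <- encounter_id
  df$minutes_to_first_read <- rep(1, n)
  df$char_count <- rep(10L, n)
  df
}

make_providers <- function(ids, roles = NULL) {
  data.frame(provider_id = ids,
             role = if (is.null(roles)) rep("other", length(ids)) else roles,
             stringsAsFactors = FALSE)
}

ts_utc <- function(x) as.POSIXct(x, format = "%Y-%m-%dT%H:%M", tz = "UTC")

make_encounters <- function(ids, admit, discharge, det = NULL) {
  df <- data.frame(encounter_id = ids, stringsAsFactors = FALSE)
  df$admit_at <- admit
  df$discharge_at <- discharge
  df$deteriorations <- if (is.null(det))
    rep(list(as.POSIXct(character(0), tz = "UTC")), length(ids)) else det
  df$indication <- rep(NA_character_, length(ids))
  df$activating_service <- rep(NA_character_, length(ids))
  df
}
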