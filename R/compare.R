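# Role-stratified and epoch comparisons, cohort accounting and role-flow
# aggregation.  Node-level comparisons pool node-in-subnetwork values
# (each node in each subnetwork is one observation).

.measures <- c("betweenness", "closeness", "eigenvector")

#' Compare centrality measures across roles within one network
#'
#' Per measure: a Kruskal-Wallis test across roles, followed by pairwise
#' Mann-Whitney tests Bonferroni-adjusted with m equal to the number of
#' pairs actually tested in that measure family.  Roles with no nodes are
#' skipped with a warning.
#'
#' @param centralities A [centrality_table()] data.frame (one or more
#'   networks pooled).
#' @param roles Roles to compare (default [care_roles()]).
#' @param measures Measure columns to compare.
#' @return List with `omnibus` (data.frame measure, H, p) and `pairwise`
#'   (data.frame measure, role_a, role_b, U, p, adjusted_p, medians).
#' @export
compare_roles_within_network <- function(centralities,
                                         roles = care_roles(),
                                         measures = .measures) {
  present <- roles[roles %in% centralities$role]
  absent <- setdiff(roles, present)
  if (length(absent))
    warning(sprintf("role(s) with zero nodes skipped: %s",
                    paste(absent, collapse = ", ")), call. = FALSE)
  if (length(present) < 2L)
    stop("need at least two roles with nodes", call. = FALSE)
  omnibus <- do.call(rbind, lapply(measures, function(ms) {
    groups <- lapply(present, function(r)
      centralities[[ms]][centralities$role == r])
    kw <- kruskal_wallis(groups)
    data.frame(measure = ms, statistic = kw$statistic,
               p_value = kw$p_value, stringsAsFactors = FALSE)
  }))
  pairs <- utils::combn(present, 2L, simplify = FALSE)
  pairwise <- do.call(rbind, lapply(measures, function(ms) {
    rows <- do.call(rbind, lapply(pairs, function(pr) {
      xa <- centralities[[ms]][centralities$role == pr[1L]]
      xb <- centralities[[ms]][centralities$role == pr[2L]]
      mw <- mann_whitney_u(xa, xb)
      data.frame(measure = ms, role_a = pr[1L], role_b = pr[2L],
                 median_a = stats::median(xa), median_b = stats::median(xb),
                 statistic = mw$statistic, p_value = mw$p_value,
                 stringsAsFactors = FALSE)
    }))
    rows$adjusted_p <- bonferroni_adjust(rows$p_value, m = length(pairs))
    rows
  }))
  list(omnibus = omnibus, pairwise = pairwise)
}

#' Centrality tables for encounter subnetworks, stratified by deterioration
#'
#' Builds one subnetwork per encounter; for encounters with a clinical
#' deterioration only messages sent strictly before Time 0 enter the
#' graph, and encounters whose messages are all at or after Time 0
#' (post-only) are excluded from the deterioration stratum.
#'
#' @param cohort A [new_cohort()] object.
#' @return List with `nodes` (pooled centrality table with a
#'   `deterioration` flag), `n_det_subnetworks`, `n_free_subnetworks`,
#'   `n_post_only_excluded`, and `network_stats` (per-subnetwork summary
#'   rows with the flag).
#' @export
encounter_centrality_tables <- function(cohort) {
  enc <- cohort$encounters
  has_det <- vapply(enc$deteriorations, length, 1L) > 0L
  msgs <- cohort$messages[!is.na(cohort$messages$encounter_id), ,
                          drop = FALSE]
  node_rows <- list()
  stat_rows <- list()
  n_det <- n_free <- n_post_only <- 0L
  for (i in seq_len(nrow(enc))) {
    eid <- enc$encounter_id[i]
    emsg <- msgs[msgs$encounter_id == eid, , drop = FALSE]
    if (nrow(emsg) == 0L) next
    if (has_det[i]) {
      pre <- filter_pre_deterioration(emsg, enc[i, , drop = FALSE])
      if (nrow(pre) == 0L) {           # post-only subnetwork: excluded
        n_post_only <- n_post_only + 1L
        next
      }
      emsg <- pre
      n_det <- n_det + 1L
    } else {
      n_free <- n_free + 1L
    }
    gr <- build_graph_from_pairs(expand_delivered_pairs(emsg),
                                 cohort$providers, eid)
    if (nrow(gr$nodes) == 0L) next
    ct <- centrality_table(gr)
    ct$deterioration <- has_det[i]
    node_rows[[length(node_rows) + 1L]] <- ct
    ns <- network_summary(gr)
    stat_rows[[length(stat_rows) + 1L]] <- data.frame(
      network_id = eid, deterioration = has_det[i],
      n_nodes = ns$n_nodes, n_edges = ns$n_edges, density = ns$density,
      diameter = ns$diameter, radius = ns$radius,
      clustering = ns$clustering, stringsAsFactors = FALSE)
  }
  list(nodes = do.call(rbind, node_rows),
       network_stats = do.call(rbind, stat_rows),
       n_det_subnetworks = n_det, n_free_subnetworks = n_free,
       n_post_only_excluded = n_post_only)
}

#' Compare deterioration vs deterioration-free subnetworks by role
#'
#' Per role and measure, a Mann-Whitney test between node-level values
#' pooled over deterioration subnetworks (pre-Time-0 messages only,
#' post-only encounters excluded) and deterioration-free subnetworks,
#' with median (q25, q75) descriptives for both strata.
#'
#' @param nodes Pooled centrality table with a logical `deterioration`
#'   column (see [encounter_centrality_tables()]).
#' @param roles Roles to compare.
#' @param measures Measure columns.
#' @return data.frame; roles absent from one stratum are recorded with NA
#'   statistics and skipped from testing.
#' @export
compare_det_vs_free <- function(nodes, roles = care_roles(),
                                measures = .measures) {
  if (!any(nodes$deterioration) || all(nodes$deterioration))
    stop("both strata must be nonempty", call. = FALSE)
  out <- list()
  for (r in roles) {
    for (ms in measures) {
      xd <- nodes[[ms]][nodes$role == r & nodes$deterioration]
      xf <- nodes[[ms]][nodes$role == r & !nodes$deterioration]
      row <- data.frame(role = r, measure = ms,
                        n_det = length(xd), n_free = length(xf),
                        median_det = NA_real_, q25_det = NA_real_,
                        q75_det = NA_real_, median_free = NA_real_,
                        q25_free = NA_real_, q75_free = NA_real_,
                        statistic = NA_real_, p_value = NA_real_,
                        stringsAsFactors = FALSE)
      if (length(xd) && length(xf)) {
        sd_ <- median_iqr(xd, "det"); sf_ <- median_iqr(xf, "free")
        mw <- mann_whitney_u(xd, xf)
        row$median_det <- sd_$median; row$q25_det <- sd_$q25
        row$q75_det <- sd_$q75
        row$median_free <- sf_$median; row$q25_free <- sf_$q25
        row$q75_free <- sf_$q75
        row$statistic <- mw$statistic; row$p_value <- mw$p_value
      }
      out[[length(out) + 1L]] <- row
    }
  }
  res <- do.call(rbind, out)
  skipped <- res$role[is.na(res$p_value)]
  if (length(skipped))
    warning(sprintf("comparison skipped for role(s) absent in a stratum: %s",
                    paste(unique(skipped), collapse = ", ")), call. = FALSE)
  res
}

#' Epoch subnetwork tables for all deteriorating encounters
#'
#' For every encounter with a deterioration, builds the epoch subnetworks
#' of [build_epoch_subnetworks()] and collects network-level summaries
#' and (optionally) node-level centralities per window.
#'
#' @param cohort A [new_cohort()] object.
#' @param epochs An [epoch_spec()].
#' @param node_level Also compute per-node centralities (default TRUE).
#' @return List with `network_stats` (window, encounter_id, n_nodes,
#'   n_edges, density, diameter, radius, clustering) and `node_stats`
#'   (window + centrality table columns; NULL when `node_level = FALSE`).
#' @export
epoch_network_tables <- function(cohort, epochs = epoch_spec(),
                                 node_level = TRUE) {
  enc <- cohort$encounters
  has_det <- vapply(enc$deteriorations, length, 1L) > 0L
  msgs <- cohort$messages[!is.na(cohort$messages$encounter_id), ,
                          drop = FALSE]
  stat_rows <- list()
  node_rows <- list()
  for (i in which(has_det)) {
    nets <- build_epoch_subnetworks(msgs, enc[i, , drop = FALSE], epochs,
                                    cohort$providers)
    for (w in names(nets)) {
      gr <- nets[[w]]
      ns <- network_summary(gr)
      stat_rows[[length(stat_rows) + 1L]] <- data.frame(
        window = w, encounter_id = enc$encounter_id[i],
        n_nodes = ns$n_nodes, n_edges = ns$n_edges, density = ns$density,
        diameter = ns$diameter, radius = ns$radius,
        clustering = ns$clustering, stringsAsFactors = FALSE)
      if (node_level) {
        ct <- centrality_table(gr)
        ct$window <- w
        node_rows[[length(node_rows) + 1L]] <- ct
      }
    }
  }
  list(network_stats = do.call(rbind, stat_rows),
       node_stats = if (node_level) do.call(rbind, node_rows) else NULL)
}

#' Compare epoch windows
#'
#' Kruskal-Wallis across epoch windows for the network-level measures
#' (nodes, edges, clustering, diameter, radius) and, when node-level
#' tables are supplied, the three pooled node-level centralities, with
#' median (q25, q75) descriptives per window.  Windows with zero
#' subnetworks are dropped with a warning.
#'
#' @param network_stats,node_stats Tables from [epoch_network_tables()].
#' @param epochs The [epoch_spec()] used to build them.
#' @return List with `tests` (measure, level, H, p) and `descriptives`
#'   (measure, window, n, median, q25, q75).
#' @export
compare_epochs <- function(network_stats, node_stats = NULL,
                           epochs = epoch_spec()) {
  windows <- epochs$labels
  have <- windows[windows %in% network_stats$window]
  if (length(have) < length(windows))
    warning(sprintf("window(s) with zero subnetworks dropped: %s",
                    paste(setdiff(windows, have), collapse = ", ")),
            call. = FALSE)
  if (length(have) < 2L)
    stop("need at least two windows with subnetworks", call. = FALSE)
  net_measures <- c(n_nodes = "n_nodes", n_edges = "n_edges",
                    clustering = "clustering", diameter = "diameter",
                    radius = "radius")
  tests <- list(); desc <- list()
  run_kw <- function(df, col, level) {
    groups <- lapply(have, function(w) df[[col]][df$window == w])
    kw <- kruskal_wallis(groups)
    tests[[length(tests) + 1L]] <<- data.frame(
      measure = col, level = level, statistic = kw$statistic,
      p_value = kw$p_value, stringsAsFactors = FALSE)
    for (j in seq_along(have)) {
      s <- median_iqr(groups[[j]], have[j])
      desc[[length(desc) + 1L]] <<- data.frame(
        measure = col, window = have[j], n = s$n, median = s$median,
        q25 = s$q25, q75 = s$q75, stringsAsFactors = FALSE)
    }
  }
  for (col in net_measures) run_kw(network_stats, col, "network")
  if (!is.null(node_stats))
    for (col in .measures) run_kw(node_stats, col, "node")
  list(tests = do.call(rbind, tests), descriptives = do.call(rbind, desc))
}

# display rounding declared once: integer percent for encounter linkage,
# one decimal elsewhere; raw proportions always retained
.pct <- function(num, den, digits) {
  if (is.na(den) || den == 0) return(list(raw = NA_real_, disp = NA_real_))
  list(raw = num / den, disp = round(100 * num / den, digits))
}

#' Cohort accounting summary
#'
#' Computes the headline cohort ratios from raw counts: the share of
#' encounters linked to messaging (integer percent), and the share of
#' hospital days and of message volume attributable to the deterioration
#' cohort (one decimal), plus the number of analysable subnetworks after
#' excluding post-only deterioration subnetworks.  Raw proportions are
#' retained alongside the display values.
#'
#' @param n_total_encounters,n_linked_encounters,n_det_encounters Counts.
#' @param days_det,days_total Hospital days (deterioration cohort, all
#'   linked encounters).
#' @param msgs_det,msgs_total Message counts.
#' @param n_post_only Deterioration encounters whose messages all follow
#'   Time 0 (excluded subnetworks).
#' @return List of class `"cohort_summary"`.
#' @export
cohort_summary_counts <- function(n_total_encounters, n_linked_encounters,
                                  n_det_encounters, days_det, days_total,
                                  msgs_det, msgs_total, n_post_only = 0L) {
  linked <- .pct(n_linked_encounters, n_total_encounters, 0)
  det <- .pct(n_det_encounters, n_linked_encounters, 1)
  days <- .pct(days_det, days_total, 1)
  msgs <- .pct(msgs_det, msgs_total, 1)
  structure(list(
    n_total_encounters = n_total_encounters,
    n_linked_encounters = n_linked_encounters,
    pct_linked = linked$disp, prop_linked = linked$raw,
    n_det_encounters = n_det_encounters,
    pct_det_of_linked = det$disp, prop_det_of_linked = det$raw,
    cohort_days_det = days_det, cohort_days_total = days_total,
    pct_days = days$disp, prop_days = days$raw,
    msgs_det = msgs_det, msgs_total = msgs_total,
    pct_msgs = msgs$disp, prop_msgs = msgs$raw,
    n_subnetworks_analyzed = n_linked_encounters - n_post_only,
    n_subnetworks_excluded_post_only = n_post_only),
    class = "cohort_summary")
}

#' @rdname cohort_summary_counts
#' @param cohort A [new_cohort()] object; counts are derived from it
#'   (hospital days as discharge minus admit in days; message and day
#'   totals over message-linked encounters; post-only exclusions from the
#'   pre-Time-0 rule).
#' @export
cohort_summary <- function(cohort) {
  v <- validate_cohort(cohort)
  enc <- cohort$encounters
  msgs <- cohort$messages
  linked_ids <- unique(msgs$encounter_id[!is.na(msgs$encounter_id)])
  is_linked <- enc$encounter_id %in% linked_ids
  has_det <- vapply(enc$deteriorations, length, 1L) > 0L & is_linked
  days <- as.numeric(enc$discharge_at - enc$admit_at, units = "days")
  det_ids <- enc$encounter_id[has_det]
  msg_linked <- msgs[!is.na(msgs$encounter_id), , drop = FALSE]
  n_post_only <- 0L
  for (i in which(has_det)) {
    emsg <- msg_linked[msg_linked$encounter_id == enc$encounter_id[i], ,
                       drop = FALSE]
    if (nrow(emsg) &&
        nrow(filter_pre_deterioration(emsg, enc[i, , drop = FALSE])) == 0L)
      n_post_only <- n_post_only + 1L
  }
  cohort_summary_counts(
    n_total_encounters = cohort$n_total_encounters,
    n_linked_encounters = sum(is_linked),
    n_det_encounters = sum(has_det),
    days_det = sum(days[has_det]),
    days_total = sum(days[is_linked]),
    msgs_det = sum(msg_linked$encounter_id %in% det_ids),
    msgs_total = nrow(msg_linked),
    n_post_only = n_post_only)
}

#' @export
print.cohort_summary <- function(x, ...) {
  cat(sprintf(paste0(
    "<cohort_summary> %d/%d encounters linked to messaging (%s%%)\n",
    "  deterioration: %d encounters (%s%% of linked), %s%% of cohort days, ",
    "%s%% of messages\n  %d analysable subnetworks ",
    "(%d post-only excluded)\n"),
    x$n_linked_encounters, x$n_total_encounters, x$pct_linked,
    x$n_det_encounters, x$pct_det_of_linked, x$pct_days, x$pct_msgs,
    x$n_subnetworks_analyzed, x$n_subnetworks_excluded_post_only))
  invisible(x)
}

#' Role-to-role message flow matrix
#'
#' Each delivered (message, recipient) pair increments the cell (sender
#' role, recipient role).  Sender marginal shares are computed over
#' messages (each message counted once by its sender's role); recipient
#' marginal shares over delivered pairs -- the two framings differ
#' because multi-recipient messages deliver several pairs.
#'
#' @param messages Message records (only encounter-linked rows are used).
#' @param providers Provider table.
#' @return List with `matrix` (role x role delivered-pair counts),
#'   `sender_share_messages` and `recipient_share_pairs` (named
#'   proportions over [role_levels()]), and `n_pairs`, `n_messages`.
#' @export
role_flow_matrix <- function(messages, providers) {
  linked <- messages[!is.na(messages$encounter_id), , drop = FALSE]
  role_of <- stats::setNames(providers$role, providers$provider_id)
  lv <- role_levels()
  pairs <- expand_delivered_pairs(linked)
  m <- table(factor(role_of[pairs$from], levels = lv),
             factor(role_of[pairs$to], levels = lv))
  m <- unclass(m)
  names(dimnames(m)) <- c("sender", "recipient")
  sender_msgs <- table(factor(role_of[linked$sender_id], levels = lv))
  list(matrix = m,
       sender_share_messages =
         stats::setNames(as.numeric(sender_msgs) / max(1L, nrow(linked)), lv),
       recipient_share_pairs =
         stats::setNames(colSums(m) / max(1L, sum(m)), lv),
       n_pairs = sum(m), n_messages = nrow(linked))
}
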