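# End-to-end orchestration: simulate (or ingest) -> build the three
# network stages -> metrics -> comparisons, with a run manifest whose
# counts satisfy the conservation identities of the earlier stages.

default_run_config <- function() {
  list(simulate = TRUE,
       seed = 1L,
       sim = list(),             # overrides for sim_config()
       input_dir = NULL,         # used when simulate = FALSE
       epochs = list(c(-36, -24), c(-24, -12), c(-12, 0)),
       roles_of_interest = care_roles(),
       clustering = "transitivity")
}

#' Read a pipeline run configuration from YAML or JSON
#'
#' @param path File path; fields override [default_run_config()].
#' @return Configuration list.
#' @export
read_run_config <- function(path) {
  raw <- if (grepl("\\.json$", path, ignore.case = TRUE)) {
    jsonlite::read_json(path, simplifyVector = TRUE)
  } else {
    yaml::read_yaml(path)
  }
  cfg <- utils::modifyList(default_run_config(), raw)
  if (!is.null(raw$epochs)) cfg$epochs <- lapply(raw$epochs, as.numeric)
  cfg
}

write_table <- function(df, dir, name) {
  path <- file.path(dir, name)
  utils::write.csv(df, path, row.names = FALSE)
  path
}

#' Run the full three-stage analysis
#'
#' Produces, in order: the global network with its role-stratified
#' centrality comparisons; the encounter subnetwork tables stratified by
#' deterioration (post-only subnetworks excluded); the epoch tables
#' anchored at Time 0; the cohort summary; the role-flow matrix; the
#' degree-frequency table; and a JSON manifest with the configuration
#' snapshot, input checksums, per-stage record counts and output list.
#' Identical seed and configuration give byte-identical outputs.
#'
#' @param config A configuration list (see [default_run_config()]) or the
#'   path to a YAML/JSON file.
#' @param out_dir Output directory, created if needed.
#' @return The manifest, invisibly; all tables are written to `out_dir`.
#' @export
run_full_analysis <- function(config = list(), out_dir) {
  if (is.character(config)) config <- read_run_config(config)
  cfg <- utils::modifyList(default_run_config(), config)
  # modifyList merges unnamed lists elementwise; epoch windows replace
  if (!is.null(config$epochs)) cfg$epochs <- config$epochs
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  stage <- "ingest"
  manifest <- list(config = cfg[setdiff(names(cfg), "input_dir")],
                   seed = cfg$seed)
  tryCatch({
    if (isTRUE(cfg$simulate)) {
      sim_cfg <- do.call(sim_config, c(cfg$sim, list(seed = cfg$seed)))
      data_dir <- file.path(out_dir, "data")
      cohort <- simulate_cohort(sim_cfg, data_dir)
    } else {
      if (is.null(cfg$input_dir))
        stop("input_dir required when simulate is FALSE", call. = FALSE)
      data_dir <- cfg$input_dir
      cohort <- read_cohort(data_dir)
    }
    inputs <- file.path(data_dir,
                        c("providers.csv", "encounters.csv", "messages.csv"))
    manifest$input_checksums <- as.list(tools::md5sum(inputs))
    validation <- validate_cohort(cohort)
    manifest$counts <- validation
    outputs <- character(0)

    stage <- "global_network"
    global <- build_global_network(cohort$messages, cohort$providers)
    global_ct <- centrality_table(global)
    outputs <- c(outputs,
                 write_table(global_ct, out_dir, "global_centrality.csv"))
    gs <- network_summary(global, clustering = cfg$clustering)
    manifest$global_network <- list(n_nodes = gs$n_nodes,
                                    n_edges = gs$n_edges,
                                    density = gs$density,
                                    diameter = gs$diameter,
                                    radius = gs$radius,
                                    clustering = gs$clustering)
    roles_cmp <- compare_roles_within_network(
      global_ct, roles = intersect(cfg$roles_of_interest, global_ct$role))
    outputs <- c(outputs,
                 write_table(roles_cmp$omnibus, out_dir,
                             "global_role_tests.csv"),
                 write_table(roles_cmp$pairwise, out_dir,
                             "global_role_pairwise.csv"),
                 write_table(degree_frequency(global), out_dir,
                             "degree_frequency.csv"))

    stage <- "encounter_subnetworks"
    ect <- encounter_centrality_tables(cohort)
    manifest$subnetworks <- list(
      n_det = ect$n_det_subnetworks,
      n_free = ect$n_free_subnetworks,
      n_post_only_excluded = ect$n_post_only_excluded)
    outputs <- c(outputs,
                 write_table(ect$network_stats, out_dir,
                             "encounter_network_stats.csv"))
    if (ect$n_det_subnetworks > 0L && ect$n_free_subnetworks > 0L) {
      dvf <- suppressWarnings(
        compare_det_vs_free(ect$nodes, roles = cfg$roles_of_interest))
      outputs <- c(outputs,
                   write_table(dvf, out_dir, "det_vs_free.csv"))
    }

    stage <- "epoch_subnetworks"
    epochs <- epoch_spec(cfg$epochs)
    ept <- epoch_network_tables(cohort, epochs)
    if (!is.null(ept$network_stats) && nrow(ept$network_stats)) {
      outputs <- c(outputs,
                   write_table(ept$network_stats, out_dir,
                               "epoch_network_stats.csv"),
                   write_table(ept$node_stats, out_dir,
                               "epoch_node_stats.csv"))
      if (length(unique(ept$network_stats$window)) >= 2L) {
        ecmp <- suppressWarnings(
          compare_epochs(ept$network_stats, ept$node_stats, epochs))
        outputs <- c(outputs,
                     write_table(ecmp$tests, out_dir, "epoch_tests.csv"),
                     write_table(ecmp$descriptives, out_dir,
                                 "epoch_descriptives.csv"))
      }
    }

    stage <- "summaries"
    cs <- cohort_summary(cohort)
    outputs <- c(outputs,
                 write_table(as.data.frame(unclass(cs)), out_dir,
                             "cohort_summary.csv"))
    rf <- role_flow_matrix(cohort$messages, cohort$providers)
    flow_df <- as.data.frame.table(rf$matrix, responseName = "n_pairs")
    outputs <- c(outputs,
                 write_table(flow_df, out_dir, "role_flow.csv"),
                 write_table(data.frame(
                   role = names(rf$sender_share_messages),
                   sender_share_messages = rf$sender_share_messages,
                   recipient_share_pairs = rf$recipient_share_pairs,
                   row.names = NULL, stringsAsFactors = FALSE),
                   out_dir, "role_shares.csv"))

    manifest$outputs <- basename(outputs)
    manifest$output_checksums <- as.list(tools::md5sum(outputs))
    manifest_path <- file.path(out_dir, "manifest.json")
    jsonlite::write_json(manifest, manifest_path, auto_unbox = TRUE,
                         digits = NA, pretty = TRUE)
    invisible(manifest)
  }, error = function(e) {
    stop(sprintf("pipeline failed at stage '%s': %s", stage,
                 conditionMessage(e)), call. = FALSE)
  })
}
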