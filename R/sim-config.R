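#' Default simulation configuration
#'
#' The defaults encode the statistical structure of a year of inpatient
#' secure messaging in a quaternary children's hospital: role mix of the
#' provider pool (41% registered nurses, 13% frontline providers, 10%
#' physicians), 47% of encounters linked to messaging, a deterioration in
#' about 2.8% of message-linked encounters (120/4328), lognormal
#' admission-to-deterioration times with median 1.6 days and sigma 2.1
#' (calibrated so the quartiles land near 0.4 and 6.6 days), sender-role
#' message shares (35% registered nurse, 29% frontline provider), and a
#' Pareto-weighted shared provider pool that yields the heavy-tailed
#' degree distribution seen in real hospital messaging networks.
#' Message volume follows a homogeneous per-encounter process whose rate
#' ramps linearly up to `escalation_multiplier` times the base rate at
#' Time 0 over the `escalation_window_h` (default 36) hours before a
#' deterioration, emulating the escalating communication observed as a
#' deterioration approaches.
#'
#' @param seed Integer seed; a single stream drives the whole run.
#' @return A list of class `"carenet_sim_config"`.
#' @export
default_config <- function(seed = 1L) {
  cfg <- list(
    seed = as.integer(seed),
    n_providers_by_role = c(
      registered_nurse = 164L, frontline_provider = 52L, physician = 40L,
      nursing_assistant = 48L, pharmacist = 24L,
      respiratory_therapist = 32L, other = 40L),
    n_total_encounters = 800L,
    p_message_linked_encounter = 0.47,
    p_deterioration = 120 / 4328,
    los_log_mean = log(2.5),      # median length of stay 2.5 days
    los_log_sd = 1.0,
    det_time_log_median = 1.6,    # days, admission -> deterioration
    det_time_log_sd = 2.1,        # ln(6.6/1.6)/0.6745
    sender_share_by_role = c(
      registered_nurse = 0.35, frontline_provider = 0.29, physician = 0.10,
      nursing_assistant = 0.08, pharmacist = 0.06,
      respiratory_therapist = 0.05, other = 0.07),
    base_rate = 0.75,             # messages per encounter-hour
    escalation_multiplier = 2.0,
    escalation_window_h = 36,
    recipient_count_p = 0.6,      # extra recipients ~ geometric(p)
    # team sizes reflect shift turnover over a multi-day stay
    team_size_by_role = c(
      registered_nurse = 8L, frontline_provider = 5L, physician = 3L,
      nursing_assistant = 3L, pharmacist = 2L,
      respiratory_therapist = 2L, other = 2L),
    activity_shape = 1.2,         # Pareto tail of provider selection weights
    char_log_mean = log(40),
    char_log_sd = 0.9,
    read_log_mean = log(2),
    read_log_sd = 1.1)
  class(cfg) <- "carenet_sim_config"
  cfg
}

#' Build a simulation configuration with overrides
#'
#' @param ... Named fields overriding [default_config()].
#' @param seed Integer seed.
#' @return Validated `"carenet_sim_config"` list.
#' @export
sim_config <- function(..., seed = 1L) {
  cfg <- default_config(seed)
  dots <- list(...)
  unknown <- setdiff(names(dots), names(cfg))
  if (length(unknown))
    stop(sprintf("unknown configuration field(s): %s",
                 paste(unknown, collapse = ", ")), call. = FALSE)
  for (nm in names(dots)) {
    if (is.null(names(cfg[[nm]])) || is.null(names(dots[[nm]]))) {
      cfg[[nm]] <- dots[[nm]]
    } else {                      # named vectors merge by element
      v <- cfg[[nm]]
      v[names(dots[[nm]])] <- dots[[nm]]
      cfg[[nm]] <- v
    }
  }
  validate_sim_config(cfg)
}

#' Validate a simulation configuration
#'
#' @param cfg A configuration list.
#' @return The configuration, invisibly usable, after checks; errors on an
#'   infeasible configuration (e.g. a messaging role whose care team has
#'   no members, or a total team smaller than two).
#' @export
validate_sim_config <- function(cfg) {
  probs <- c(cfg$p_message_linked_encounter, cfg$p_deterioration,
             cfg$recipient_count_p)
  if (any(probs < 0 | probs > 1))
    stop("probabilities must lie in [0, 1]", call. = FALSE)
  if (abs(sum(cfg$sender_share_by_role) - 1) > 1e-9)
    stop("sender_share_by_role must sum to 1", call. = FALSE)
  if (any(cfg$sender_share_by_role < 0))
    stop("sender_share_by_role must be non-negative", call. = FALSE)
  if (any(cfg$n_providers_by_role < 0) || sum(cfg$n_providers_by_role) < 2)
    stop("n_providers_by_role must be non-negative with total >= 2",
         call. = FALSE)
  if (cfg$n_total_encounters < 1)
    stop("n_total_encounters must be positive", call. = FALSE)
  if (cfg$base_rate <= 0 || cfg$escalation_multiplier <= 0 ||
      cfg$escalation_window_h <= 0)
    stop("rates, multipliers and windows must be positive", call. = FALSE)
  if (cfg$det_time_log_median <= 0 || cfg$det_time_log_sd <= 0 ||
      cfg$los_log_sd <= 0)
    stop("lognormal parameters must be positive", call. = FALSE)
  roles <- role_levels()
  for (fld in c("n_providers_by_role", "sender_share_by_role",
                "team_size_by_role")) {
    miss <- setdiff(roles, names(cfg[[fld]]))
    if (length(miss))
      stop(sprintf("%s is missing role(s): %s", fld,
                   paste(miss, collapse = ", ")), call. = FALSE)
  }
  team <- pmin(cfg$team_size_by_role[roles],
               cfg$n_providers_by_role[roles])
  if (sum(team) < 2)
    stop("infeasible configuration: care team smaller than 2", call. = FALSE)
  active <- names(cfg$sender_share_by_role)[cfg$sender_share_by_role > 0]
  starved <- active[team[active] < 1]
  if (length(starved))
    stop(sprintf(
      "infeasible configuration: sender role(s) with no team members: %s",
      paste(starved, collapse = ", ")), call. = FALSE)
  class(cfg) <- "carenet_sim_config"
  cfg
}

#' Read a simulation configuration from YAML or JSON
#'
#' Fields mirror [default_config()]; absent fields keep their defaults.
#'
#' @param path File path (`.yaml`/`.yml` or `.json`).
#' @param seed Optional seed override.
#' @return Validated configuration.
#' @export
read_sim_config <- function(path, seed = NULL) {
  raw <- if (grepl("\\.json$", path, ignore.case = TRUE)) {
    jsonlite::read_json(path, simplifyVector = TRUE)
  } else {
    yaml::read_yaml(path)
  }
  for (fld in c("n_providers_by_role", "sender_share_by_role",
                "team_size_by_role"))
    if (!is.null(raw[[fld]])) raw[[fld]] <- unlist(raw[[fld]])
  if (!is.null(seed)) raw$seed <- as.integer(seed)
  if (is.null(raw$seed)) raw$seed <- 1L
  do.call(sim_config, c(raw[setdiff(names(raw), "seed")],
                        list(seed = raw$seed)))
}
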