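# Seeded synthetic cohort generator.  One pseudo-random stream per run,
# seeded once from the configuration; a fixed iteration order makes the
# same seed reproduce a byte-identical cohort.

# sample() treats a length-1 numeric vector as 1:n; always index instead
resample <- function(x, size, replace = FALSE, prob = NULL) {
  x[sample.int(length(x), size, replace = replace, prob = prob)]
}

round_minute <- function(t) {
  as.POSIXct(round(as.numeric(t) / 60) * 60, origin = "1970-01-01",
             tz = "UTC")
}

#' Draw admission-to-deterioration times
#'
#' Raw (untruncated) lognormal draws of the time from admission to the
#' first rapid-response/code activation, in days.  At the defaults
#' (median 1.6 days, sigma 2.1) the quartiles fall near 0.4 and 6.6 days.
#'
#' @param n Number of draws.
#' @param config A [sim_config()]; only the lognormal fields are used.
#' @return Numeric vector of days.
#' @export
rdet_time <- function(n, config = default_config()) {
  stats::rlnorm(n, meanlog = log(config$det_time_log_median),
                sdlog = config$det_time_log_sd)
}

# truncated-resampled deterioration offset (days) within (0, los_days);
# resampling (not clipping) avoids a probability mass at discharge
draw_det_offset <- function(config, los_days, max_attempts = 1000L) {
  for (i in seq_len(max_attempts)) {
    t <- rdet_time(1L, config)
    if (t > 1 / 1440 && t < los_days - 1 / 1440) return(t)
  }
  stats::runif(1L, 1 / 1440, max(2 / 1440, los_days - 1 / 1440))
}

#' Generate a synthetic cohort
#'
#' Simulates a provider pool, inpatient encounters, care teams and a
#' message log with the structure described in [default_config()]:
#' providers carry Pareto-distributed selection weights shared across
#' encounters (recurring providers become the hubs of the global
#' network); each message-linked encounter gets a weighted care team;
#' messages arrive as a homogeneous process per encounter-hour whose rate
#' ramps linearly to `escalation_multiplier` times the base rate at
#' Time 0 across the escalation window of a deteriorating encounter.
#' Senders are drawn by role
#' share then by weight within the team; recipients (1 + geometric,
#' capped at team size minus one) are drawn weight-proportionally without
#' replacement from the remaining team.
#'
#' @param config A [sim_config()] object.
#' @return A [new_cohort()] object; all messages are encounter-linked.
#' @export
generate_cohort <- function(config = default_config()) {
  cfg <- validate_sim_config(config)
  set.seed(cfg$seed)
  roles <- role_levels()

  counts <- cfg$n_providers_by_role[roles]
  n_prov <- sum(counts)
  providers <- data.frame(
    provider_id = sprintf("P%04d", seq_len(n_prov)),
    role = rep(roles, counts),
    stringsAsFactors = FALSE)
  weight <- stats::runif(n_prov)^(-1 / cfg$activity_shape)
  by_role_idx <- split(seq_len(n_prov), providers$role)

  n_enc <- cfg$n_total_encounters
  study_start <- as.POSIXct("2022-10-01T00:00", format = "%Y-%m-%dT%H:%M",
                            tz = "UTC")
  admit <- round_minute(study_start + stats::runif(n_enc) * 365 * 86400)
  los_days <- pmax(stats::rlnorm(n_enc, cfg$los_log_mean, cfg$los_log_sd),
                   2 / 24)
  discharge <- round_minute(admit + los_days * 86400)
  discharge <- pmax(discharge, admit + 120)   # >= 2 minutes of stay
  los_days <- as.numeric(discharge - admit, units = "days")
  linked <- stats::runif(n_enc) < cfg$p_message_linked_encounter
  det <- linked & stats::runif(n_enc) < cfg$p_deterioration

  det_list <- rep(list(as.POSIXct(character(0), tz = "UTC")), n_enc)
  indication <- rep(NA_character_, n_enc)
  service <- rep(NA_character_, n_enc)
  for (i in which(det)) {
    off <- draw_det_offset(cfg, los_days[i])
    t0 <- round_minute(admit[i] + off * 86400)
    t0 <- min(max(t0, admit[i] + 60), discharge[i] - 60)
    det_list[[i]] <- t0
    indication[i] <- resample(
      c("respiratory", "seizure", "sepsis", "cardiac", "neurologic"), 1L,
      prob = c(0.54, 0.12, 0.12, 0.11, 0.11))
    service[i] <- resample(
      c("hospitalist", "intensive_care", "surgery", "emergency"), 1L,
      prob = c(0.45, 0.30, 0.15, 0.10))
  }

  encounters <- data.frame(encounter_id = sprintf("E%05d", seq_len(n_enc)),
                           stringsAsFactors = FALSE)
  encounters$admit_at <- admit
  encounters$discharge_at <- discharge
  encounters$deteriorations <- det_list
  encounters$indication <- indication
  encounters$activating_service <- service

  share <- cfg$sender_share_by_role[roles]
  msg_enc <- msg_sender <- character(0)
  msg_time <- numeric(0)
  msg_rcpt <- list()
  for (i in which(linked)) {
    team_idx <- integer(0)
    for (r in roles) {
      k <- min(cfg$team_size_by_role[[r]], counts[[r]])
      if (k > 0L)
        team_idx <- c(team_idx,
                      resample(by_role_idx[[r]], k, prob = weight[by_role_idx[[r]]]))
    }
    team_roles <- providers$role[team_idx]
    team_w <- weight[team_idx]
    n_team <- length(team_idx)

    hours <- los_days[i] * 24
    n1 <- stats::rpois(1L, cfg$base_rate * hours)
    t <- as.numeric(admit[i]) + stats::runif(n1) * los_days[i] * 86400
    if (length(det_list[[i]]) && cfg$escalation_multiplier != 1) {
      # escalation: the rate ramps linearly from base_rate at the start
      # of the escalation window to base_rate * multiplier at Time 0;
      # sampled by superposing triangular-density extra arrivals on the
      # homogeneous base process, restricted to the in-stay overlap
      t0 <- as.numeric(det_list[[i]][1L])
      w_sec <- cfg$escalation_window_h * 3600
      w_lo <- max(as.numeric(admit[i]), t0 - w_sec)
      s_a <- (w_lo - (t0 - w_sec)) / w_sec       # ramp height at overlap start
      extra_mean <- cfg$base_rate * (cfg$escalation_multiplier - 1) *
        cfg$escalation_window_h * (1 - s_a^2) / 2
      n2 <- stats::rpois(1L, max(0, extra_mean))
      if (n2 > 0L) {
        s <- sqrt(s_a^2 + stats::runif(n2) * (1 - s_a^2))
        t <- c(t, t0 - w_sec * (1 - s))
      }
    }
    n_msg <- length(t)
    if (n_msg == 0L) next
    t <- round(t / 60) * 60

    avail <- roles[roles %in% team_roles & share > 0]
    p_avail <- share[avail] / sum(share[avail])
    srole <- resample(avail, n_msg, replace = TRUE, prob = p_avail)
    sender <- integer(n_msg)
    for (r in unique(srole)) {
      members <- team_idx[team_roles == r]
      sel <- which(srole == r)
      sender[sel] <- resample(members, length(sel), replace = TRUE,
                              prob = weight[members])
    }
    k_rcpt <- pmin(1L + stats::rgeom(n_msg, cfg$recipient_count_p),
                   n_team - 1L)
    rcpts <- vector("list", n_msg)
    for (j in seq_len(n_msg)) {
      pool <- team_idx[team_idx != sender[j]]
      rcpts[[j]] <- providers$provider_id[
        resample(pool, k_rcpt[j], prob = weight[pool])]
    }
    msg_enc <- c(msg_enc, rep(encounters$encounter_id[i], n_msg))
    msg_time <- c(msg_time, t)
    msg_sender <- c(msg_sender, providers$provider_id[sender])
    msg_rcpt <- c(msg_rcpt, rcpts)
  }

  n_msg <- length(msg_time)
  messages <- data.frame(message_id = character(n_msg),
                         stringsAsFactors = FALSE)
  messages$sent_at <- as.POSIXct(msg_time, origin = "1970-01-01", tz = "UTC")
  messages$sender_id <- msg_sender
  messages$recipient_ids <- msg_rcpt
  messages$encounter_id <- msg_enc
  messages$minutes_to_first_read <-
    round(stats::rlnorm(n_msg, cfg$read_log_mean, cfg$read_log_sd), 1)
  messages$char_count <-
    pmax(1L, as.integer(round(stats::rlnorm(n_msg, cfg$char_log_mean,
                                            cfg$char_log_sd))))
  ord <- order(messages$sent_at, messages$encounter_id, messages$sender_id)
  messages <- messages[ord, , drop = FALSE]
  messages$message_id <- sprintf("M%07d", seq_len(n_msg))
  rownames(messages) <- NULL

  new_cohort(providers, encounters, messages, n_enc)
}

#' Generate a cohort and optionally write it to disk
#'
#' @param config A [sim_config()].
#' @param out_dir Optional directory; when given, the three CSVs of
#'   [write_cohort()] are written there.
#' @return The cohort, invisibly when written.
#' @export
simulate_cohort <- function(config = default_config(), out_dir = NULL) {
  cohort <- generate_cohort(config)
  if (!is.null(out_dir)) {
    write_cohort(cohort, out_dir)
    return(invisible(cohort))
  }
  cohort
}
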