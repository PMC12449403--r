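#' Assemble a message-log cohort
#'
#' A cohort bundles the three tables the analysis runs on: a provider
#' directory, an encounter table (with any clinical deterioration
#' timestamps), and the message log.  `n_total_encounters` counts all
#' inpatient encounters in the study window, including those with no
#' linked messages, so linkage percentages can be computed.
#'
#' @param providers data.frame with columns `provider_id`, `role`.
#' @param encounters data.frame with columns `encounter_id`, `admit_at`,
#'   `discharge_at` (POSIXct, UTC, minute resolution), `deteriorations`
#'   (list column of sorted POSIXct vectors, possibly length 0),
#'   `indication`, `activating_service`.
#' @param messages data.frame with columns `message_id`, `sent_at`
#'   (POSIXct), `sender_id`, `recipient_ids` (list column of character
#'   vectors, each length >= 1), `encounter_id` (NA when unlinked),
#'   `minutes_to_first_read` (NA allowed), `char_count`.
#' @param n_total_encounters Integer count of all inpatient encounters;
#'   defaults to `nrow(encounters)`.
#' @return An object of class `"carenet_cohort"`.
#' @export
new_cohort <- function(providers, encounters, messages,
                       n_total_encounters = nrow(encounters)) {
  stopifnot(is.data.frame(providers), is.data.frame(encounters),
            is.data.frame(messages))
  req <- function(df, cols, what) {
    miss <- setdiff(cols, names(df))
    if (length(miss))
      stop(sprintf("%s table is missing column(s): %s",
                   what, paste(miss, collapse = ", ")), call. = FALSE)
  }
  req(providers, c("provider_id", "role"), "provider")
  req(encounters, c("encounter_id", "admit_at", "discharge_at",
                    "deteriorations"), "encounter")
  req(messages, c("message_id", "sent_at", "sender_id", "recipient_ids",
                  "encounter_id", "minutes_to_first_read", "char_count"),
      "message")
  if (anyDuplicated(providers$provider_id))
    stop("provider_id values must be unique within a cohort", call. = FALSE)
  if (anyDuplicated(encounters$encounter_id))
    stop("encounter_id values must be unique within a cohort", call. = FALSE)
  if (n_total_encounters < nrow(encounters))
    stop("n_total_encounters cannot be smaller than the encounter table",
         call. = FALSE)
  structure(
    list(providers = providers, encounters = encounters, messages = messages,
         n_total_encounters = as.integer(n_total_encounters)),
    class = "carenet_cohort")
}

#' @export
print.carenet_cohort <- function(x, ...) {
  n_det <- sum(vapply(x$encounters$deteriorations, length, 1L) > 0L)
  cat(sprintf(paste0(
    "<carenet_cohort> %d providers, %d encounters (%d total incl. unlinked),\n",
    "  %d messages, %d encounter(s) with a clinical deterioration\n"),
    nrow(x$providers), nrow(x$encounters), x$n_total_encounters,
    nrow(x$messages), n_det))
  invisible(x)
}

#' Time 0 of an encounter
#'
#' Time 0 is the timestamp of the first clinical deterioration (rapid
#' response or code team activation) of the encounter; later activations
#' in the same encounter are not used for epoch anchoring.
#'
#' @param encounter One row of a cohort encounter table (data.frame).
#' @return POSIXct scalar, or `NA` if the encounter has no deterioration.
#' @export
time_zero <- function(encounter) {
  det <- encounter$deteriorations[[1L]]
  if (length(det) == 0L) return(as.POSIXct(NA, tz = "UTC"))
  det[[1L]]
}

#' Validate cohort integrity and tally linkage
#'
#' Checks that every message resolves its sender, recipients and (when
#' present) encounter, and reports the bookkeeping counts used throughout
#' the analysis: linked vs unlinked messages, encounters with and without
#' messages, and provider role tallies.
#'
#' @param cohort A [new_cohort()] object.
#' @return A list with elements `n_messages`, `n_linked`, `n_unlinked`,
#'   `n_encounters_with_messages`, `n_encounters_without_messages`,
#'   `role_tally` (named integer vector over [role_levels()]), and
#'   `n_deterioration_encounters`.
#' @export
validate_cohort <- function(cohort) {
  stopifnot(inherits(cohort, "carenet_cohort"))
  pids <- cohort$providers$provider_id
  bad_send <- setdiff(unique(cohort$messages$sender_id), pids)
  bad_rcpt <- setdiff(unique(unlist(cohort$messages$recipient_ids)), pids)
  dangling <- union(bad_send, bad_rcpt)
  if (length(dangling))
    stop(sprintf("dangling provider reference(s): %s",
                 paste(sort(dangling), collapse = ", ")), call. = FALSE)
  enc_ref <- cohort$messages$encounter_id
  linked <- !is.na(enc_ref)
  bad_enc <- setdiff(unique(enc_ref[linked]), cohort$encounters$encounter_id)
  if (length(bad_enc))
    stop(sprintf("message(s) reference unknown encounter(s): %s",
                 paste(sort(bad_enc), collapse = ", ")), call. = FALSE)
  with_msg <- cohort$encounters$encounter_id %in% enc_ref[linked]
  tally <- table(factor(cohort$providers$role, levels = role_levels()))
  list(
    n_messages = nrow(cohort$messages),
    n_linked = sum(linked),
    n_unlinked = sum(!linked),
    n_encounters_with_messages = sum(with_msg),
    n_encounters_without_messages =
      cohort$n_total_encounters - sum(with_msg),
    role_tally = stats::setNames(as.integer(tally), names(tally)),
    n_deterioration_encounters =
      sum(vapply(cohort$encounters$deteriorations, length, 1L) > 0L))
}
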