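# Delimited-file ingest/egest for the three cohort tables.  All files are
# UTF-8 CSV with a header row; multi-valued cells (recipient lists,
# deterioration timestamps) use ';' as a sub-delimiter; timestamps are
# ISO-8601 at minute resolution (YYYY-MM-DDTHH:MM, UTC).

.ts_fmt <- "%Y-%m-%dT%H:%M"

format_ts <- function(x) format(x, .ts_fmt, tz = "UTC")

parse_ts <- function(x, what = "timestamp") {
  out <- as.POSIXct(x, format = .ts_fmt, tz = "UTC")
  bad <- which(!is.na(x) & nzchar(x) & is.na(out))
  if (length(bad))
    stop(sprintf("unparseable %s in row(s): %s (expected YYYY-MM-DDTHH:MM)",
                 what, paste(utils::head(bad, 5L), collapse = ", ")),
         call. = FALSE)
  out
}

.check_cols <- function(df, required, path) {
  miss <- setdiff(required, names(df))
  if (length(miss))
    stop(sprintf("%s: missing required column(s): %s",
                 basename(path), paste(miss, collapse = ", ")), call. = FALSE)
}

split_multi <- function(x) {
  x <- ifelse(is.na(x), "", x)
  lapply(strsplit(x, ";", fixed = TRUE),
         function(v) v[nzchar(trimws(v))])
}

#' Read a provider directory
#'
#' @param path CSV with columns `provider_id`, `role`; role labels are
#'   normalized via [normalize_roles()].
#' @return data.frame with `provider_id`, `role`.
#' @export
read_provider_table <- function(path) {
  df <- utils::read.csv(path, colClasses = "character",
                        stringsAsFactors = FALSE)
  .check_cols(df, c("provider_id", "role"), path)
  data.frame(provider_id = df$provider_id,
             role = normalize_roles(df$role),
             stringsAsFactors = FALSE)
}

#' Read a message log
#'
#' Rows with an empty recipient list are dropped (only messages with at
#' least one recipient enter the analysis); the number dropped is attached
#' as attribute `n_dropped_no_recipient`.  Rows whose `encounter_id` does
#' not resolve against `encounters` (when supplied) keep a missing link
#' and are excluded later from encounter-linked analyses.
#'
#' @param path CSV with columns `message_id`, `sent_at`, `sender_id`,
#'   `recipient_ids` (';'-joined), `encounter_id` (may be blank),
#'   `minutes_to_first_read` (may be blank), `char_count`.
#' @param providers Optional provider table; when given, sender and
#'   recipient ids are checked to resolve.
#' @return data.frame of message records (recipient_ids is a list column)
#'   with attribute `n_dropped_no_recipient`.
#' @export
read_message_log <- function(path, providers = NULL) {
  df <- utils::read.csv(path, colClasses = "character",
                        stringsAsFactors = FALSE)
  .check_cols(df, c("message_id", "sent_at", "sender_id", "recipient_ids",
                    "encounter_id", "minutes_to_first_read", "char_count"),
              path)
  rcpt <- split_multi(df$recipient_ids)
  keep <- lengths(rcpt) >= 1L
  n_dropped <- sum(!keep)
  df <- df[keep, , drop = FALSE]
  rcpt <- rcpt[keep]
  out <- data.frame(message_id = df$message_id,
                    sent_at = parse_ts(df$sent_at, "sent_at"),
                    sender_id = df$sender_id,
                    stringsAsFactors = FALSE)
  out$recipient_ids <- rcpt
  out$encounter_id <- ifelse(nzchar(df$encounter_id), df$encounter_id,
                             NA_character_)
  out$minutes_to_first_read <-
    suppressWarnings(as.numeric(df$minutes_to_first_read))
  if (any(out$minutes_to_first_read < 0, na.rm = TRUE))
    stop("minutes_to_first_read must be non-negative", call. = FALSE)
  out$char_count <- as.integer(df$char_count)
  if (any(is.na(out$char_count)) || any(out$char_count <= 0L))
    stop("char_count must be a positive integer for every row", call. = FALSE)
  if (!is.null(providers)) {
    bad <- setdiff(union(out$sender_id, unlist(out$recipient_ids)),
                   providers$provider_id)
    if (length(bad))
      stop(sprintf("message log references unknown provider(s): %s",
                   paste(sort(bad), collapse = ", ")), call. = FALSE)
  }
  attr(out, "n_dropped_no_recipient") <- n_dropped
  out
}

#' Read an encounter table
#'
#' Deterioration timestamps are stored sorted ascending; a deterioration
#' outside the admission window, or an admit time not strictly before
#' discharge, rejects the row with an error naming the encounter.
#'
#' @param path CSV with columns `encounter_id`, `admit_at`, `discharge_at`,
#'   `deterioration_times` (';'-joined, may be blank), `indication`,
#'   `activating_service`.
#' @return data.frame with a `deteriorations` list column of POSIXct.
#' @export
read_encounter_table <- function(path) {
  df <- utils::read.csv(path, colClasses = "character",
                        stringsAsFactors = FALSE)
  .check_cols(df, c("encounter_id", "admit_at", "discharge_at",
                    "deterioration_times", "indication",
                    "activating_service"), path)
  admit <- parse_ts(df$admit_at, "admit_at")
  disch <- parse_ts(df$discharge_at, "discharge_at")
  bad <- which(!(admit < disch))
  if (length(bad))
    stop(sprintf("admit_at must precede discharge_at for encounter(s): %s",
                 paste(df$encounter_id[bad], collapse = ", ")), call. = FALSE)
  det <- lapply(seq_len(nrow(df)), function(i) {
    cells <- split_multi(df$deterioration_times[i])[[1L]]
    if (length(cells) == 0L)
      return(as.POSIXct(character(0), tz = "UTC"))
    ts <- sort(parse_ts(cells, "deterioration_times"))
    if (any(ts < admit[i] | ts > disch[i]))
      stop(sprintf("deterioration outside admission window for encounter %s",
                   df$encounter_id[i]), call. = FALSE)
    ts
  })
  out <- data.frame(encounter_id = df$encounter_id,
                    stringsAsFactors = FALSE)
  out$admit_at <- admit
  out$discharge_at <- disch
  out$deteriorations <- det
  out$indication <- ifelse(nzchar(df$indication), df$indication,
                           NA_character_)
  out$activating_service <- ifelse(nzchar(df$activating_service),
                                   df$activating_service, NA_character_)
  out
}

#' Read a full cohort from a directory
#'
#' Expects `providers.csv`, `encounters.csv` and `messages.csv` as written
#' by [write_cohort()].
#'
#' @param dir Directory path.
#' @param n_total_encounters Optional override of the total encounter
#'   count (defaults to the number of rows in `encounters.csv`).
#' @return A [new_cohort()] object.
#' @export
read_cohort <- function(dir, n_total_encounters = NULL) {
  providers <- read_provider_table(file.path(dir, "providers.csv"))
  encounters <- read_encounter_table(file.path(dir, "encounters.csv"))
  messages <- read_message_log(file.path(dir, "messages.csv"), providers)
  if (is.null(n_total_encounters)) n_total_encounters <- nrow(encounters)
  new_cohort(providers, encounters, messages, n_total_encounters)
}

#' Write a cohort to a directory as three CSV files
#'
#' Inverse of [read_cohort()]: timestamps at minute resolution round-trip
#' exactly.
#'
#' @param cohort A [new_cohort()] object.
#' @param dir Output directory (created if needed).
#' @return Invisibly, the paths written.
#' @export
write_cohort <- function(cohort, dir) {
  stopifnot(inherits(cohort, "carenet_cohort"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  paths <- file.path(dir, c("providers.csv", "encounters.csv",
                            "messages.csv"))
  utils::write.csv(cohort$providers, paths[1L], row.names = FALSE)
  enc <- cohort$encounters
  utils::write.csv(data.frame(
    encounter_id = enc$encounter_id,
    admit_at = format_ts(enc$admit_at),
    discharge_at = format_ts(enc$discharge_at),
    deterioration_times = vapply(enc$deteriorations, function(ts)
      paste(format_ts(ts), collapse = ";"), character(1)),
    indication = ifelse(is.na(enc$indication), "", enc$indication),
    activating_service = ifelse(is.na(enc$activating_service), "",
                                enc$activating_service),
    stringsAsFactors = FALSE), paths[2L], row.names = FALSE)
  msg <- cohort$messages
  utils::write.csv(data.frame(
    message_id = msg$message_id,
    sent_at = format_ts(msg$sent_at),
    sender_id = msg$sender_id,
    recipient_ids = vapply(msg$recipient_ids, paste, character(1),
                           collapse = ";"),
    encounter_id = ifelse(is.na(msg$encounter_id), "", msg$encounter_id),
    minutes_to_first_read = ifelse(is.na(msg$minutes_to_first_read), "",
                                   as.character(msg$minutes_to_first_read)),
    char_count = msg$char_count,
    stringsAsFactors = FALSE), paths[3L], row.names = FALSE)
  invisible(paths)
}
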