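#' Canonical provider role vocabulary
#'
#' The analysis stratifies healthcare providers into a closed set of roles.
#' Advanced practice providers and housestaff (residents and fellows) are
#' analysed together as frontline providers; attending physicians are the
#' `physician` role.  Every other job title falls into `other`.
#'
#' @return Character vector of the seven canonical role labels.
#' @export
role_levels <- function() {
  c("registered_nurse", "frontline_provider", "physician",
    "nursing_assistant", "pharmacist", "respiratory_therapist", "other")
}

# alias -> canonical label; applied after lowercasing and squashing
# whitespace/hyphens to underscores
.role_aliases <- c(
  registered_nurse       = "registered_nurse",
  rn                     = "registered_nurse",
  nurse                  = "registered_nurse",
  frontline_provider     = "frontline_provider",
  flp                    = "frontline_provider",
  advanced_practice_provider = "frontline_provider",
  app                    = "frontline_provider",
  nurse_practitioner     = "frontline_provider",
  physician_assistant    = "frontline_provider",
  housestaff             = "frontline_provider",
  resident               = "frontline_provider",
  fellow                 = "frontline_provider",
  physician              = "physician",
  attending              = "physician",
  attending_physician    = "physician",
  nursing_assistant      = "nursing_assistant",
  pharmacist             = "pharmacist",
  respiratory_therapist  = "respiratory_therapist",
  rt                     = "respiratory_therapist",
  other                  = "other"
)

#' Normalize free-text role labels to the canonical vocabulary
#'
#' Unknown labels map to `"other"` with a single consolidated warning,
#' mirroring the catch-all bucket used for the several dozen minor roles
#' present in real messaging directories.
#'
#' @param x Character vector of role labels.
#' @return Character vector of canonical labels (see [role_levels()]).
#' @export
normalize_roles <- function(x) {
  key <- gsub("[ -]+", "_", tolower(trimws(as.character(x))))
  out <- unname(.role_aliases[key])
  unknown <- is.na(out) & !is.na(key) & nzchar(key)
  if (any(unknown)) {
    warning(sprintf("mapping %d unknown role label(s) to 'other': %s",
                    sum(unknown),
                    paste(utils::head(unique(key[unknown]), 5L), collapse = ", ")),
            call. = FALSE)
    out[unknown] <- "other"
  }
  out[is.na(key) | !nzchar(key)] <- "other"
  out
}

#' Roles directly engaged in bedside patient care
#'
#' The comparative analyses focus on these six roles; `other` is excluded.
#'
#' @return Character vector of six role labels.
#' @export
care_roles <- function() {
  setdiff(role_levels(), "other")
}
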