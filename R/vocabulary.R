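#' Annotation label vocabulary
#'
#' Canonical label tokens for scoring annotations. Sleep stages follow the
#' AASM five-stage alphabet (W, N1, N2, N3, R); event labels cover the four
#' scoring tasks (leg movements per leg, apneic-related respiratory events,
#' EEG arousals, oxygen desaturations) plus the lights-off/lights-on markers
#' that delimit the time in bed (TIB).
#'
#' @format Character vector of canonical tokens.
#' @export
psg_vocabulary <- c(
  "lights-off", "lights-on",
  "stage-W", "stage-N1", "stage-N2", "stage-N3", "stage-R",
  "lm-left", "lm-right",
  "apnea-obstructive", "apnea-central", "apnea-mixed",
  "hypopnea", "rera",
  "arousal",
  "desaturation"
)

#' Sleep stage alphabet (ordered)
#' @export
psg_stages <- c("W", "N1", "N2", "N3", "R")

# label groups used by the event tasks
.apnea_labels <- c("apnea-obstructive", "apnea-central", "apnea-mixed")
.respiratory_labels <- c(.apnea_labels, "hypopnea", "rera")
.stage_labels <- paste0("stage-", psg_stages)
.marker_labels <- c("lights-off", "lights-on")

#' Default alias map from free-text annotation strings to canonical tokens
#'
#' Annotation files exported by scoring software carry free-text labels;
#' this user-editable map normalizes common spellings to the canonical
#' vocabulary. Extend it with [register_aliases()] when loading files whose
#' label strings are not covered.
#'
#' @return Named character vector: names are lower-cased free-text strings,
#'   values canonical tokens.
#' @export
default_alias_map <- function() {
  c(
    "lights off" = "lights-off", "lights_off" = "lights-off",
    "lights-off" = "lights-off", "lightsoff" = "lights-off",
    "lights on" = "lights-on", "lights_on" = "lights-on",
    "lights-on" = "lights-on", "lightson" = "lights-on",
    "sleep stage w" = "stage-W", "wake" = "stage-W", "w" = "stage-W",
    "sleep stage n1" = "stage-N1", "n1" = "stage-N1",
    "sleep stage n2" = "stage-N2", "n2" = "stage-N2",
    "sleep stage n3" = "stage-N3", "n3" = "stage-N3",
    "sleep stage r" = "stage-R", "rem" = "stage-R", "r" = "stage-R",
    "limb movement left" = "lm-left", "lm left" = "lm-left",
    "limb movement right" = "lm-right", "lm right" = "lm-right",
    "obstructive apnea" = "apnea-obstructive",
    "central apnea" = "apnea-central",
    "mixed apnea" = "apnea-mixed",
    "hypopnea" = "hypopnea",
    "rera" = "rera",
    "eeg arousal" = "arousal", "arousal" = "arousal",
    "desaturation" = "desaturation", "spo2 desaturation" = "desaturation",
    stats::setNames(psg_vocabulary, tolower(psg_vocabulary))
  )
}

#' Extend an alias map
#'
#' @param map Existing alias map (named character vector).
#' @param ... Named arguments `"free text" = "canonical-token"`.
#' @return Updated alias map.
#' @export
register_aliases <- function(map, ...) {
  extra <- c(...)
  if (length(extra) == 0L) return(map)
  if (is.null(names(extra)) || any(names(extra) == "")) {
    stop("aliases must be named: alias = canonical token", call. = FALSE)
  }
  bad <- setdiff(unname(extra), psg_vocabulary)
  if (length(bad) > 0L) {
    stop("unknown canonical token(s): ", paste(bad, collapse = ", "),
         call. = FALSE)
  }
  map[tolower(names(extra))] <- unname(extra)
  map
}

# Map raw label strings to canonical tokens, erroring on unknown strings.
canonicalize_labels <- function(labels, alias_map = default_alias_map()) {
  hit <- alias_map[tolower(trimws(labels))]
  unknown <- unique(labels[is.na(hit)])
  if (length(unknown) > 0L) {
    stop("unknown annotation label(s): ",
         paste(shQuote(unknown), collapse = ", "),
         "; extend the alias map with register_aliases()", call. = FALSE)
  }
  unname(hit)
}
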