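#' Build an annotation table
#'
#' Annotations are labeled half-open time intervals `[onset, onset + duration)`
#' in seconds from recording start. Lights markers may have zero duration;
#' any other zero-duration annotation is rejected because it cannot overlap
#' a mini-epoch.
#'
#' @param label Character vector of canonical label tokens.
#' @param onset Numeric vector, seconds from recording start (>= 0).
#' @param duration Numeric vector, seconds (>= 0).
#' @return A `data.frame` with columns `label`, `onset`, `duration`, sorted
#'   by onset (ties by label), of class `psg_annotations`.
#' @export
annotations <- function(label = character(), onset = numeric(),
                        duration = numeric()) {
  stopifnot(length(label) == length(onset), length(onset) == length(duration))
  label <- as.character(label)
  onset <- as.numeric(onset)
  duration <- as.numeric(duration)
  bad <- setdiff(label, psg_vocabulary)
  if (length(bad) > 0L) {
    stop("label(s) outside the registered vocabulary: ",
         paste(bad, collapse = ", "), call. = FALSE)
  }
  if (any(onset < 0)) stop("onsets must be non-negative", call. = FALSE)
  if (any(duration < 0)) stop("durations must be non-negative", call. = FALSE)
  zero <- duration == 0 & !(label %in% .marker_labels)
  if (any(zero)) {
    stop("zero-duration event annotation(s) at onset ",
         paste(onset[zero], collapse = ", "),
         " (only lights markers may have zero duration)", call. = FALSE)
  }
  ord <- order(onset, label)
  structure(
    data.frame(label = label[ord], onset = onset[ord],
               duration = duration[ord], stringsAsFactors = FALSE),
    class = c("psg_annotations", "data.frame")
  )
}

#' Build a hypnogram
#'
#' A hypnogram is an ordered sequence of fixed-duration sleep-stage epochs
#' (30 s by convention) anchored at lights-off.
#'
#' @param stages Character vector over `W, N1, N2, N3, R`.
#' @param lights_off Anchor time in seconds from recording start.
#' @param epoch_duration Epoch length in seconds (default 30).
#' @return Object of class `hypnogram`.
#' @export
hypnogram <- function(stages, lights_off = 0, epoch_duration = 30) {
  stages <- as.character(stages)
  bad <- setdiff(stages, psg_stages)
  if (length(bad) > 0L) {
    stop("invalid sleep stage(s): ", paste(bad, collapse = ", "),
         call. = FALSE)
  }
  stopifnot(epoch_duration > 0, lights_off >= 0)
  structure(
    list(stages = stages, lights_off = as.numeric(lights_off),
         epoch_duration = as.numeric(epoch_duration)),
    class = "hypnogram"
  )
}

#' @export
length.hypnogram <- function(x) length(x$stages)

#' @export
print.hypnogram <- function(x, ...) {
  cat(sprintf("<hypnogram> %d x %gs epochs from t=%gs\n",
              length(x$stages), x$epoch_duration, x$lights_off))
  invisible(x)
}

#' Build a scored recording
#'
#' One cell of the study design: the annotations produced by one scorer,
#' for one recording, under one method (manual or semi-automatic), within
#' one scoring task. Event annotations are clipped to the time in bed
#' `[lights_off, lights_on)`; zero-length residues are dropped. For the
#' staging task the stage annotations are also materialized as a
#' [hypnogram()].
#'
#' @param recording_id,scorer_id Identifiers.
#' @param method `"manual"` or `"semiauto"`.
#' @param task One of `"staging"`, `"leg_movements"`, `"respiratory"`,
#'   `"arousals"`.
#' @param lights_off,lights_on TIB boundaries, seconds from recording start.
#' @param annotations Annotation table from [annotations()] (events only;
#'   lights markers are carried in the dedicated fields).
#' @param context_hypnogram Pre-filled clinical hypnogram supplied to all
#'   scorers for non-staging tasks (and used for wake/sleep context masks).
#' @param context_events Optional annotation table of contextual events
#'   (e.g. clinical respiratory events for respiratory-related LM flagging).
#' @return Object of class `scored_recording`.
#' @export
scored_recording <- function(recording_id, scorer_id = "clinical",
                             method = c("manual", "semiauto"),
                             task = c("staging", "leg_movements",
                                      "respiratory", "arousals"),
                             lights_off, lights_on,
                             annotations = psgagree::annotations(),
                             context_hypnogram = NULL,
                             context_events = NULL) {
  method <- match.arg(method)
  task <- match.arg(task)
  lights_off <- as.numeric(lights_off)
  lights_on <- as.numeric(lights_on)
  if (!(lights_on > lights_off)) {
    stop("lights_on must be strictly after lights_off", call. = FALSE)
  }
  ann <- clip_annotations(annotations, lights_off, lights_on)
  hyp <- NULL
  if (task == "staging") {
    hyp <- stages_to_hypnogram(ann, lights_off, lights_on)
    ann <- ann[!(ann$label %in% .stage_labels), , drop = FALSE]
  } else {
    hyp <- context_hypnogram
  }
  structure(
    list(recording_id = as.character(recording_id),
         scorer_id = as.character(scorer_id),
         method = method, task = task,
         lights_off = lights_off, lights_on = lights_on,
         annotations = ann,
         context_hypnogram = hyp,
         context_events = context_events),
    class = "scored_recording"
  )
}

#' @export
print.scored_recording <- function(x, ...) {
  cat(sprintf(
    "<scored_recording> %s / %s / %s / %s: TIB [%g, %g)s, %d annotation(s)\n",
    x$recording_id, x$scorer_id, x$method, x$task,
    x$lights_off, x$lights_on, nrow(x$annotations)))
  invisible(x)
}

#' Time in bed of a scored recording, in seconds
#' @param rec A [scored_recording()].
#' @export
tib_seconds <- function(rec) rec$lights_on - rec$lights_off

#' Clip annotations to the time in bed
#'
#' Intersects every event interval with `[lights_off, lights_on)` and drops
#' zero-length residues. Lights markers and stage annotations are kept as-is
#' (stages are epoch-aligned by construction).
#'
#' @param ann Annotation table.
#' @param lights_off,lights_on TIB boundaries in seconds.
#' @return Clipped annotation table.
#' @export
clip_annotations <- function(ann, lights_off, lights_on) {
  if (nrow(ann) == 0L) return(ann)
  keepasis <- ann$label %in% c(.marker_labels, .stage_labels)
  s <- pmax(ann$onset, lights_off)
  e <- pmin(ann$onset + ann$duration, lights_on)
  s[keepasis] <- ann$onset[keepasis]
  e[keepasis] <- ann$onset[keepasis] + ann$duration[keepasis]
  keep <- keepasis | (e - s) > 0
  annotations(ann$label[keep], s[keep], (e - s)[keep])
}

# Convert stage-* annotations into a hypnogram anchored at lights_off.
# Stage records must form a contiguous 30 s (or uniform) grid from lights_off.
stages_to_hypnogram <- function(ann, lights_off, lights_on) {
  st <- ann[ann$label %in% .stage_labels, , drop = FALSE]
  if (nrow(st) == 0L) {
    stop("staging task requires stage annotations", call. = FALSE)
  }
  st <- st[order(st$onset), , drop = FALSE]
  dur <- unique(st$duration)
  if (length(dur) != 1L) {
    stop("stage epochs must share one duration; found: ",
         paste(dur, collapse = ", "), call. = FALSE)
  }
  rel <- st$onset - lights_off
  expect <- seq(0, by = dur, length.out = nrow(st))
  if (any(abs(rel - expect) > 1e-6)) {
    stop("stage annotations do not form a contiguous epoch grid from ",
         "lights-off", call. = FALSE)
  }
  hypnogram(sub("^stage-", "", st$label), lights_off = lights_off,
            epoch_duration = dur)
}

#' Build a scoring-time record table
#'
#' Active scoring times (minutes of scorer interaction) per study cell.
#'
#' @param recording_id,scorer_id,method,task Vectors describing the cells.
#' @param active_minutes Positive scoring times in minutes.
#' @return `data.frame` of class `timing_records`.
#' @export
timing_records <- function(recording_id, scorer_id, method, task,
                           active_minutes) {
  if (any(active_minutes <= 0)) {
    stop("active scoring times must be positive", call. = FALSE)
  }
  ok_method <- method %in% c("manual", "semiauto")
  if (!all(ok_method)) stop("method must be manual or semiauto", call. = FALSE)
  structure(
    data.frame(recording_id = as.character(recording_id),
               scorer_id = as.character(scorer_id),
               method = as.character(method), task = as.character(task),
               active_minutes = as.numeric(active_minutes),
               stringsAsFactors = FALSE),
    class = c("timing_records", "data.frame")
  )
}
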