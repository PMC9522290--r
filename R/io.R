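#' Read a scoring annotation file
#'
#' Two dialects are supported. `"tabular"` is UTF-8 CSV with header
#' `label,onset_s,duration_s`. `"edfplus"` is the EDF+ annotation (TAL)
#' syntax: each annotation is an onset offset prefixed with `+`/`-`, an
#' optional duration after a 0x15 byte, and the label text terminated by
#' 0x14 bytes; TALs are separated by 0x00. Only the annotation track is
#' handled — no waveform signals.
#'
#' The file must contain `lights-off` and `lights-on` markers; events are
#' clipped to the time in bed and, for the staging task, stage annotations
#' are materialized as a [hypnogram()].
#'
#' @param path File path.
#' @param dialect `"tabular"` or `"edfplus"`.
#' @param recording_id,scorer_id,method,task Study-cell metadata for the
#'   returned [scored_recording()].
#' @param alias_map Label alias map (see [default_alias_map()]).
#' @param context_hypnogram,context_events Passed through to
#'   [scored_recording()].
#' @return A [scored_recording()].
#' @export
read_annotation_file <- function(path, dialect = c("tabular", "edfplus"),
                                 recording_id = "rec", scorer_id = "scorer",
                                 method = "manual", task = "leg_movements",
                                 alias_map = default_alias_map(),
                                 context_hypnogram = NULL,
                                 context_events = NULL) {
  dialect <- match.arg(dialect)
  if (!file.exists(path)) stop("no such file: ", path, call. = FALSE)
  raw <- switch(dialect,
                tabular = parse_tabular(path),
                edfplus = parse_tal(path))
  raw$label <- canonicalize_labels(raw$label, alias_map)
  is_off <- raw$label == "lights-off"
  is_on <- raw$label == "lights-on"
  if (sum(is_off) != 1L || sum(is_on) != 1L) {
    stop("file must contain exactly one lights-off and one lights-on ",
         "marker: ", path, call. = FALSE)
  }
  lights_off <- raw$onset[is_off]
  lights_on <- raw$onset[is_on]
  ev <- raw[!(is_off | is_on), , drop = FALSE]
  scored_recording(
    recording_id = recording_id, scorer_id = scorer_id,
    method = method, task = task,
    lights_off = lights_off, lights_on = lights_on,
    annotations = annotations(ev$label, ev$onset, ev$duration),
    context_hypnogram = context_hypnogram,
    context_events = context_events
  )
}

#' Write a scoring annotation file
#'
#' Emits the recording's lights markers, hypnogram (staging task) and event
#' annotations in the chosen dialect. The output re-reads to an equal
#' [scored_recording()] (round-trip identity) and is byte-stable across
#' writes of the same input.
#'
#' @param rec A [scored_recording()].
#' @param path Output path.
#' @param dialect `"tabular"` or `"edfplus"`.
#' @return `path`, invisibly.
#' @export
write_annotation_file <- function(rec, path,
                                  dialect = c("tabular", "edfplus")) {
  dialect <- match.arg(dialect)
  tab <- recording_to_table(rec)
  switch(dialect,
         tabular = emit_tabular(tab, path),
         edfplus = emit_tal(tab, path))
  invisible(path)
}

# Flatten a scored_recording into one label/onset/duration table, lights
# markers included, stages re-expanded onto their epoch grid.
recording_to_table <- function(rec) {
  lab <- c("lights-off", "lights-on")
  ons <- c(rec$lights_off, rec$lights_on)
  dur <- c(0, 0)
  if (rec$task == "staging" && !is.null(rec$context_hypnogram)) {
    h <- rec$context_hypnogram
    lab <- c(lab, paste0("stage-", h$stages))
    ons <- c(ons, h$lights_off + (seq_along(h$stages) - 1L) * h$epoch_duration)
    dur <- c(dur, rep(h$epoch_duration, length(h$stages)))
  }
  lab <- c(lab, rec$annotations$label)
  ons <- c(ons, rec$annotations$onset)
  dur <- c(dur, rec$annotations$duration)
  ord <- order(ons, lab)
  data.frame(label = lab[ord], onset = ons[ord], duration = dur[ord],
             stringsAsFactors = FALSE)
}

## ---- tabular dialect ------------------------------------------------------

parse_tabular <- function(path) {
  lines <- readLines(path, encoding = "UTF-8")
  if (length(lines) == 0L) stop("empty annotation file: ", path, call. = FALSE)
  header <- strsplit(lines[[1L]], ",", fixed = TRUE)[[1L]]
  if (!identical(trimws(header), c("label", "onset_s", "duration_s"))) {
    stop("tabular dialect requires header 'label,onset_s,duration_s': ",
         path, call. = FALSE)
  }
  body <- lines[-1L]
  body <- body[nzchar(trimws(body))]
  if (length(body) == 0L) {
    return(data.frame(label = character(), onset = numeric(),
                      duration = numeric(), stringsAsFactors = FALSE))
  }
  parts <- strsplit(body, ",", fixed = TRUE)
  nfield <- lengths(parts)
  if (any(nfield != 3L)) {
    stop("malformed row (need 3 fields) at line ",
         which(nfield != 3L)[1L] + 1L, " of ", path, call. = FALSE)
  }
  m <- matrix(trimws(unlist(parts)), ncol = 3L, byrow = TRUE)
  onset <- suppressWarnings(as.numeric(m[, 2L]))
  duration <- suppressWarnings(as.numeric(m[, 3L]))
  bad <- which(is.na(onset) | is.na(duration))
  if (length(bad) > 0L) {
    stop("malformed timestamp at line ", bad[1L] + 1L, " of ", path,
         call. = FALSE)
  }
  data.frame(label = m[, 1L], onset = onset, duration = duration,
             stringsAsFactors = FALSE)
}

emit_tabular <- function(tab, path) {
  con <- file(path, open = "wb")
  on.exit(close(con))
  writeLines(c("label,onset_s,duration_s",
               sprintf("%s,%s,%s", tab$label,
                       format_seconds(tab$onset),
                       format_seconds(tab$duration))),
             con, useBytes = TRUE)
}

# fixed-precision, locale-independent second stamps (EDF+ style, trailing
# zeros trimmed); 4 decimals is finer than the 0.5 s analysis grid
format_seconds <- function(x) {
  s <- sprintf("%.4f", x)
  s <- sub("0+$", "", s)
  sub("\\.$", "", s)
}

## ---- EDF+ TAL dialect -----------------------------------------------------

TAL_DUR <- as.raw(0x15)
TAL_END <- as.raw(0x14)
TAL_SEP <- as.raw(0x00)

parse_tal <- function(path) {
  bytes <- readBin(path, what = "raw", n = file.info(path)$size)
  if (length(bytes) == 0L) stop("empty annotation file: ", path, call. = FALSE)
  # split the stream on the 0x00 TAL separators
  brk <- which(bytes == TAL_SEP)
  starts <- c(1L, brk + 1L)
  ends <- c(brk - 1L, length(bytes))
  lab <- character(); ons <- numeric(); dur <- numeric()
  rec_no <- 0L
  for (i in seq_along(starts)) {
    if (starts[i] > ends[i]) next
    chunk <- bytes[starts[i]:ends[i]]
    chunk <- chunk[!(chunk %in% as.raw(c(0x0a, 0x0d)))]
    if (length(chunk) == 0L) next
    rec_no <- rec_no + 1L
    fields <- split_raw(chunk, TAL_END)
    head <- fields[[1L]]
    if (length(fields) < 2L || length(head) == 0L) {
      stop("malformed TAL record ", rec_no, " in ", path, call. = FALSE)
    }
    timing <- split_raw(head, TAL_DUR)
    onset_txt <- rawToChar(timing[[1L]])
    if (!grepl("^[+-]", onset_txt)) {
      stop("malformed timestamp (missing +/- prefix) in TAL record ",
           rec_no, " of ", path, call. = FALSE)
    }
    onset <- suppressWarnings(as.numeric(onset_txt))
    d <- if (length(timing) > 1L) {
      suppressWarnings(as.numeric(rawToChar(timing[[2L]])))
    } else 0
    if (is.na(onset) || is.na(d)) {
      stop("malformed timestamp in TAL record ", rec_no, " of ", path,
           call. = FALSE)
    }
    texts <- vapply(fields[-1L], rawToChar, character(1))
    texts <- texts[nzchar(texts)]
    for (txt in texts) {
      lab <- c(lab, txt); ons <- c(ons, onset); dur <- c(dur, d)
    }
  }
  data.frame(label = lab, onset = ons, duration = dur,
             stringsAsFactors = FALSE)
}

split_raw <- function(x, sep) {
  idx <- which(x == sep)
  starts <- c(1L, idx + 1L)
  ends <- c(idx - 1L, length(x))
  lapply(seq_along(starts), function(i) {
    if (starts[i] > ends[i]) raw(0) else x[starts[i]:ends[i]]
  })
}

emit_tal <- function(tab, path) {
  con <- file(path, open = "wb")
  on.exit(close(con))
  for (i in seq_len(nrow(tab))) {
    onset <- tab$onset[i]
    stamp <- paste0(if (onset < 0) "" else "+", format_seconds(onset))
    writeBin(charToRaw(stamp), con)
    if (tab$duration[i] > 0) {
      writeBin(c(TAL_DUR, charToRaw(format_seconds(tab$duration[i]))), con)
    }
    writeBin(c(TAL_END, charToRaw(tab$label[i]), TAL_END, TAL_SEP,
               charToRaw("\n")), con)
  }
}

## ---- timing logs ----------------------------------------------------------

#' Read or write an active-scoring-time log
#'
#' CSV with header `recording_id,scorer_id,method,task,active_minutes`.
#'
#' @param path File path.
#' @return [timing_records()] table.
#' @export
read_timing_log <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("recording_id", "scorer_id", "method", "task", "active_minutes")
  if (!all(need %in% names(df))) {
    stop("timing log must have columns ", paste(need, collapse = ","),
         call. = FALSE)
  }
  timing_records(df$recording_id, df$scorer_id, df$method, df$task,
                 df$active_minutes)
}

#' @rdname read_timing_log
#' @param times A [timing_records()] table.
#' @export
write_timing_log <- function(times, path) {
  utils::write.csv(as.data.frame(times), path, row.names = FALSE,
                   quote = FALSE)
  invisible(path)
}
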