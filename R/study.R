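#' Assemble scored recordings into a study
#'
#' A scoring set is the study's cross-classified collection of
#' [scored_recording()]s over recordings, scorers, methods and tasks
#' (recordings are selected per task, so the cross is
#' recordings-within-task x scorers x methods). The expected design is the
#' full cross of the levels present per task; missing cells are reported in
#' `$gaps`, never silently dropped.
#'
#' @param recordings List of [scored_recording()] objects.
#' @param timing Optional [timing_records()] table.
#' @return Object of class `scoring_set` with elements `cells` (named list,
#'   keys `task/method/recording/scorer`), `design` (data.frame of present
#'   cells), `gaps` (data.frame of expected-but-missing cells), `timing`.
#' @export
scoring_set <- function(recordings, timing = NULL) {
  keys <- vapply(recordings, cell_key, character(1))
  if (anyDuplicated(keys)) {
    stop("duplicate study cell(s): ",
         paste(unique(keys[duplicated(keys)]), collapse = ", "),
         call. = FALSE)
  }
  names(recordings) <- keys
  design <- do.call(rbind, lapply(recordings, function(r) {
    data.frame(task = r$task, method = r$method,
               recording_id = r$recording_id, scorer_id = r$scorer_id,
               stringsAsFactors = FALSE)
  }))
  rownames(design) <- NULL
  # lights markers must agree across all scorings of one recording x task
  for (tk in unique(design$task)) {
    sub <- design[design$task == tk, , drop = FALSE]
    for (rid in unique(sub$recording_id)) {
      ks <- keys[design$task == tk & design$recording_id == rid]
      offs <- vapply(recordings[ks], `[[`, numeric(1), "lights_off")
      ons <- vapply(recordings[ks], `[[`, numeric(1), "lights_on")
      if (length(unique(offs)) > 1L || length(unique(ons)) > 1L) {
        stop("inconsistent lights markers across scorers for recording ",
             rid, ", task ", tk, call. = FALSE)
      }
    }
  }
  gaps <- design_gaps(design)
  structure(list(cells = recordings, design = design, gaps = gaps,
                 timing = timing),
            class = "scoring_set")
}

cell_key <- function(rec) {
  paste(rec$task, rec$method, rec$recording_id, rec$scorer_id, sep = "/")
}

design_gaps <- function(design) {
  out <- list()
  for (tk in unique(design$task)) {
    sub <- design[design$task == tk, , drop = FALSE]
    full <- expand.grid(task = tk, method = unique(sub$method),
                        recording_id = unique(sub$recording_id),
                        scorer_id = unique(sub$scorer_id),
                        stringsAsFactors = FALSE)
    have <- paste(sub$method, sub$recording_id, sub$scorer_id)
    want <- paste(full$method, full$recording_id, full$scorer_id)
    out[[tk]] <- full[!(want %in% have), , drop = FALSE]
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

#' @export
print.scoring_set <- function(x, ...) {
  cat(sprintf("<scoring_set> %d cell(s), %d reported gap(s)\n",
              length(x$cells), nrow(x$gaps)))
  tab <- table(x$design$task, x$design$method)
  print(tab)
  invisible(x)
}

#' Retrieve one cell of a scoring set
#' @param set A [scoring_set()].
#' @param task,method,recording_id,scorer_id Cell coordinates.
#' @export
get_cell <- function(set, task, method, recording_id, scorer_id) {
  key <- paste(task, method, recording_id, scorer_id, sep = "/")
  cell <- set$cells[[key]]
  if (is.null(cell)) stop("no such study cell: ", key, call. = FALSE)
  cell
}

#' Load a study from a directory and a YAML manifest
#'
#' The manifest enumerates the study cells and their annotation files:
#' ```yaml
#' dialect: tabular        # or edfplus; may be overridden per cell
#' timing_log: timing.csv  # optional
#' context:                # optional clinical staging files, keyed by
#'   rec01: clinical/rec01.csv   # recording id (hypnogram context for
#' cells:                        # non-staging tasks)
#'   - {recording: rec01, scorer: s01, method: manual, task: staging,
#'      path: staging/manual/rec01_s01.csv}
#' ```
#' Paths are relative to `root_dir`.
#'
#' @param root_dir Study directory.
#' @param manifest Path to the manifest, default `manifest.yaml` inside
#'   `root_dir`.
#' @param alias_map Label alias map for file parsing.
#' @return A [scoring_set()].
#' @export
load_study <- function(root_dir, manifest = file.path(root_dir, "manifest.yaml"),
                       alias_map = default_alias_map()) {
  man <- yaml::read_yaml(manifest)
  if (is.null(man$cells) || length(man$cells) == 0L) {
    stop("manifest lists no cells: ", manifest, call. = FALSE)
  }
  dialect <- man$dialect %||% "tabular"
  contexts <- list()
  for (rid in names(man$context %||% list())) {
    crec <- read_annotation_file(
      file.path(root_dir, man$context[[rid]]), dialect = dialect,
      recording_id = rid, scorer_id = "clinical", task = "staging",
      alias_map = alias_map)
    contexts[[rid]] <- crec$context_hypnogram
  }
  recs <- lapply(man$cells, function(cell) {
    need <- c("recording", "scorer", "method", "task", "path")
    if (!all(need %in% names(cell))) {
      stop("manifest cell missing field(s): ",
           paste(setdiff(need, names(cell)), collapse = ", "), call. = FALSE)
    }
    read_annotation_file(
      file.path(root_dir, cell$path),
      dialect = cell$dialect %||% dialect,
      recording_id = cell$recording, scorer_id = cell$scorer,
      method = cell$method, task = cell$task, alias_map = alias_map,
      context_hypnogram = contexts[[cell$recording]])
  })
  timing <- NULL
  if (!is.null(man$timing_log)) {
    timing <- read_timing_log(file.path(root_dir, man$timing_log))
  }
  scoring_set(recs, timing = timing)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
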