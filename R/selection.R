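#' Automatic-vs-clinical agreement for one recording
#'
#' Cohen's kappa between an automatic scoring and the clinical scoring of
#' the same recording, computed with the task's exact discretization (30 s
#' five-class grid for staging, 0.5 s binary mini-epochs otherwise; the
#' leg-movement task averages the per-leg kappas).
#'
#' @param auto_events,clinical_events [scored_recording()]s covering the
#'   same TIB.
#' @param task Scoring task; defaults to the recordings' task.
#' @param step Mini-epoch duration for event tasks.
#' @return A `kappa_result` (the recording's K_ac).
#' @export
compute_kac <- function(auto_events, clinical_events,
                        task = auto_events$task, step = 0.5) {
  if (!isTRUE(all.equal(auto_events$lights_off,
                        clinical_events$lights_off)) ||
      !isTRUE(all.equal(auto_events$lights_on, clinical_events$lights_on))) {
    stop("TIB mismatch between automatic and clinical scorings",
         call. = FALSE)
  }
  pair <- c(auto_events$scorer_id, clinical_events$scorer_id)
  if (task == "staging") {
    a <- discretize_stages(auto_events$context_hypnogram)
    b <- discretize_stages(clinical_events$context_hypnogram)
    return(cohen_kappa(build_contingency(a, b), pair = pair))
  }
  if (task == "leg_movements") {
    ks <- lapply(c("lm-left", "lm-right"), function(lbl) {
      a <- discretize_events(auto_events, lbl, step)
      b <- discretize_events(clinical_events, lbl, step)
      cohen_kappa(build_contingency(a, b), pair = pair)
    })
    return(average_channel_kappa(ks[[1]], ks[[2]]))
  }
  labels <- if (task == "respiratory") .respiratory_labels else "arousal"
  a <- discretize_events(auto_events, labels, step)
  b <- discretize_events(clinical_events, labels, step)
  cohen_kappa(build_contingency(a, b), pair = pair)
}

#' Percentile-stratified recording selection
#'
#' Selects study recordings spread over the distribution of
#' automatic-vs-clinical agreement values (K_ac): for each target
#' percentile of the distribution (default the middle of each
#' inter-quartile half plus the median: 12.5, 37.5, 50, 62.5, 87.5), the
#' not-yet-selected recording whose K_ac is nearest the percentile value is
#' chosen (ties broken by lower recording id), proceeding in ascending
#' percentile order. This avoids sampling extreme outlier recordings by
#' chance.
#'
#' @param kac_values Named numeric vector of K_ac per recording id.
#' @param percentiles Target percentiles in (0, 100).
#' @param n_target Required number of selections (must equal
#'   `length(percentiles)`).
#' @return Object of class `selection_result`: `percentiles`,
#'   `percentile_values`, `selected` (recording ids ordered by percentile),
#'   `kac_values`.
#' @export
select_recordings <- function(kac_values,
                              percentiles = c(12.5, 37.5, 50, 62.5, 87.5),
                              n_target = length(percentiles)) {
  if (length(percentiles) != n_target) {
    stop("n_target must match the number of target percentiles",
         call. = FALSE)
  }
  ids <- names(kac_values)
  if (is.null(ids)) stop("kac_values must be named by recording id",
                         call. = FALSE)
  if (length(kac_values) < n_target) {
    stop("fewer recordings (", length(kac_values),
         ") than selection targets (", n_target, ")", call. = FALSE)
  }
  percentiles <- sort(percentiles)
  pv <- stats::quantile(kac_values, percentiles / 100, names = FALSE,
                        type = 7)
  selected <- character(0)
  for (i in seq_along(percentiles)) {
    pool <- setdiff(ids, selected)
    dist <- abs(kac_values[pool] - pv[i])
    best <- pool[dist == min(dist)]
    selected <- c(selected, sort(best)[1])
  }
  structure(list(percentiles = percentiles, percentile_values = pv,
                 selected = selected, kac_values = kac_values),
            class = "selection_result")
}

#' @export
print.selection_result <- function(x, ...) {
  cat("<selection_result>\n")
  print(data.frame(percentile = x$percentiles,
                   target_kac = round(x$percentile_values, 4),
                   recording = x$selected,
                   kac = round(x$kac_values[x$selected], 4),
                   row.names = NULL))
  invisible(x)
}

#' Export K_ac values and the selected subset as CSV
#' @param x A [select_recordings()] result.
#' @param path Output path.
#' @export
write_selection <- function(x, path) {
  utils::write.csv(
    data.frame(recording_id = names(x$kac_values),
               kac = as.numeric(x$kac_values),
               selected = names(x$kac_values) %in% x$selected),
    path, row.names = FALSE, quote = FALSE)
  invisible(path)
}
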