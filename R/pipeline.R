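#' Analysis configuration
#'
#' Settings for the full agreement analysis: which tasks and contexts to
#' analyze, the mini-epoch step, the significance level, and how the
#' baseline r0 of the semi-automatic ICC test is chosen
#' (`"manual_baseline"` tests the semi-automatic ICC against the ICC
#' achieved under manual scoring; `"zero"` tests both methods against 0).
#'
#' @param tasks Tasks to analyze.
#' @param step Mini-epoch duration for event tasks, seconds.
#' @param alpha Significance level in (0, 1).
#' @param icc_r0_policy `"manual_baseline"` or `"zero"`.
#' @return Object of class `analysis_config`.
#' @export
analysis_config <- function(tasks = c("staging", "leg_movements",
                                      "respiratory", "arousals"),
                            step = 0.5, alpha = 0.05,
                            icc_r0_policy = c("manual_baseline", "zero")) {
  stopifnot(alpha > 0, alpha < 1, step > 0)
  structure(list(tasks = tasks, step = step, alpha = alpha,
                 icc_r0_policy = match.arg(icc_r0_policy)),
            class = "analysis_config")
}

# context definitions per task: list of (name, mask_context, labels)
task_contexts <- function(task) {
  switch(task,
    staging = list(list(name = "TIB", mask = "tib", labels = NULL)),
    leg_movements = list(
      list(name = "TIB", mask = "tib", labels = c("lm-left", "lm-right")),
      list(name = "Wake", mask = "wake", labels = c("lm-left", "lm-right")),
      list(name = "Sleep", mask = "sleep", labels = c("lm-left", "lm-right"))
    ),
    respiratory = list(
      list(name = "Apnea, Hypopnea, RERA (TIB)", mask = "tib",
           labels = .respiratory_labels),
      list(name = "Apneas (TIB)", mask = "tib", labels = .apnea_labels),
      list(name = "Hypopneas (TIB)", mask = "tib", labels = "hypopnea")
    ),
    arousals = list(list(name = "TIB", mask = "tib", labels = "arousal"))
  )
}

# indices derived per task (column names of event_index_set / summary)
task_indices <- function(task) {
  switch(task,
    staging = c("SE", "SOL", "WASO"),
    leg_movements = c("LMI", "PLMI"),
    respiratory = c("AHI", "AI", "HI", "ODI"),
    arousals = c("ArI"))
}

#' Run the full inter-scorer agreement analysis
#'
#' For every configured task this computes, per recording and method, all
#' pairwise scorer kappas on the task's discretization (with wake/sleep and
#' event-subtype contexts where defined, and left/right channel averaging
#' for leg movements), pairs them across methods by scorer pair x
#' recording, and runs the paired Wilcoxon test and Cohen's d. Scoring
#' times are compared per task (paired by scorer x recording) with gain
#' factors. Diagnostic indices are derived per scorer and compared across
#' scorers with ICC(A,1), the semi-automatic condition tested against the
#' manual baseline per the r0 policy, plus paired Wilcoxon and
#' Brown-Forsythe tests on the pooled index values.
#'
#' @param study A [scoring_set()] (timing records attached or passed
#'   separately).
#' @param cfg An [analysis_config()].
#' @param timing Optional [timing_records()] overriding `study$timing`.
#' @return Object of class `agreement_report` with data.frames `kappa`
#'   (per task/context comparison), `timing` (per task with gain factors),
#'   `indices` (per index ICC comparison), `kappa_raw` (every pairwise
#'   kappa), and the `config`.
#' @export
run_agreement_analysis <- function(study, cfg = NULL,
                                   timing = study$timing) {
  design <- study$design
  if (is.null(cfg)) {
    # default to the tasks the study actually contains, canonical order
    cfg <- analysis_config(tasks = intersect(
      c("staging", "leg_movements", "respiratory", "arousals"),
      unique(design$task)))
  }
  missing_tasks <- setdiff(cfg$tasks, unique(design$task))
  if (length(missing_tasks) > 0L) {
    stop("study has no cells for task(s): ",
         paste(missing_tasks, collapse = ", "), call. = FALSE)
  }
  gaps <- study$gaps[study$gaps$task %in% cfg$tasks, , drop = FALSE]
  if (nrow(gaps) > 0L) {
    stop("incomplete study design; first missing cell: ",
         paste(gaps[1, ], collapse = "/"), call. = FALSE)
  }

  kappa_raw <- list()
  kappa_samples <- list()
  index_rows <- list()
  for (task in cfg$tasks) {
    sub <- design[design$task == task, , drop = FALSE]
    recordings <- sort(unique(sub$recording_id))
    scorers <- sort(unique(sub$scorer_id))
    contexts <- task_contexts(task)
    # per-recording, per-method pairwise kappas
    kap <- list()  # [[context]][[method]] -> data.frame rows
    idx <- list()  # [[index]][[method]] -> recordings x scorers matrix
    for (ind in task_indices(task)) {
      idx[[ind]] <- list(
        manual = matrix(NA_real_, length(recordings), length(scorers),
                        dimnames = list(recordings, scorers)),
        semiauto = matrix(NA_real_, length(recordings), length(scorers),
                          dimnames = list(recordings, scorers)))
    }
    for (rid in recordings) {
      for (method in c("manual", "semiauto")) {
        cells <- lapply(scorers, function(sid)
          get_cell(study, task, method, rid, sid))
        names(cells) <- scorers
        res <- analyze_recording(cells, task, contexts, cfg$step)
        for (cx in names(res$kappas)) {
          df <- kappa_table(res$kappas[[cx]])
          df$task <- task; df$method <- method; df$recording_id <- rid
          kap[[cx]][[method]][[rid]] <- df
        }
        for (ind in names(res$indices)) {
          idx[[ind]][[method]][rid, ] <- res$indices[[ind]]
        }
      }
    }
    # paired kappa samples per context
    for (cx in vapply(contexts, `[[`, character(1), "name")) {
      man <- do.call(rbind, kap[[cx]][["manual"]])
      sem <- do.call(rbind, kap[[cx]][["semiauto"]])
      key <- function(d) paste(d$recording_id, d$scorer_a, d$scorer_b)
      sem <- sem[match(key(man), key(sem)), , drop = FALSE]
      kappa_samples[[paste0(task, " / ", cx)]] <-
        paired_sample(man$kappa, sem$kappa, unit = "kappa",
                      matching_key = "scorer pair x recording")
      kappa_raw[[length(kappa_raw) + 1L]] <- rbind(man, sem)
    }
    # index ICC rows
    for (ind in names(idx)) {
      index_rows[[length(index_rows) + 1L]] <-
        index_comparison_row(task, ind, idx[[ind]], cfg)
    }
  }

  kappa_cmp <- build_comparison_table(kappa_samples, with_gain = FALSE,
                                      alpha = cfg$alpha)
  timing_cmp <- if (!is.null(timing)) {
    timing_comparison(timing, cfg)
  } else NULL
  indices_cmp <- do.call(rbind, index_rows)
  if (!is.null(indices_cmp)) rownames(indices_cmp) <- NULL

  structure(list(kappa = kappa_cmp, timing = timing_cmp,
                 indices = indices_cmp,
                 kappa_raw = do.call(rbind, kappa_raw), config = cfg),
            class = "agreement_report")
}

# pairwise kappas (all contexts) and per-scorer indices for one
# recording x method panel
analyze_recording <- function(cells, task, contexts, step) {
  scorers <- names(cells)
  kappas <- list()
  if (task == "staging") {
    seqs <- lapply(cells, function(c) discretize_stages(c$context_hypnogram))
    kappas[["TIB"]] <- pairwise_kappa(seqs, context = "TIB")
  } else {
    hyp <- cells[[1]]$context_hypnogram
    if (is.null(hyp)) {
      stop("non-staging task needs the shared clinical context hypnogram",
           call. = FALSE)
    }
    n_mini <- floor(tib_seconds(cells[[1]]) / step)
    for (cx in contexts) {
      mask <- context_mask(hyp, cx$mask, step = step, n_epochs = n_mini)
      if (task == "leg_movements") {
        per_leg <- lapply(c("lm-left", "lm-right"), function(lbl) {
          seqs <- lapply(cells, discretize_events, labels_of_interest = lbl,
                         step = step)
          pairwise_kappa(seqs, mask = mask, context = cx$name)
        })
        kappas[[cx$name] ] <- Map(average_channel_kappa,
                                  per_leg[[1]], per_leg[[2]])
      } else {
        seqs <- lapply(cells, discretize_events,
                       labels_of_interest = cx$labels, step = step)
        kappas[[cx$name]] <- pairwise_kappa(seqs, mask = mask,
                                            context = cx$name)
      }
    }
  }
  indices <- recording_indices(cells, task)
  list(kappas = kappas, indices = indices)
}

recording_indices <- function(cells, task) {
  scorers <- names(cells)
  out <- list()
  if (task == "staging") {
    vals <- lapply(cells, function(c)
      summarize_hypnogram(c$context_hypnogram, tib = tib_seconds(c)))
    out$SE <- vapply(vals, `[[`, numeric(1), "se_pct")
    out$SOL <- vapply(vals, `[[`, numeric(1), "sol_min")
    out$WASO <- vapply(vals, `[[`, numeric(1), "waso_min")
  } else {
    eis <- lapply(cells, event_indices)
    grab <- function(f) vapply(eis, `[[`, numeric(1), f)
    if (task == "leg_movements") {
      out$LMI <- grab("lmi"); out$PLMI <- grab("plmi")
    } else if (task == "respiratory") {
      out$AHI <- grab("ahi"); out$AI <- grab("ai")
      out$HI <- grab("hi"); out$ODI <- grab("odi")
    } else {
      out$ArI <- grab("ari")
    }
  }
  out
}

index_comparison_row <- function(task, ind, mats, cfg) {
  man <- mats$manual; sem <- mats$semiauto
  man_v <- as.numeric(man); sem_v <- as.numeric(sem)
  mq <- median_iqr(man_v); sq <- median_iqr(sem_v)
  icc_m <- icc_a1(man, r0 = 0)
  r0 <- if (cfg$icc_r0_policy == "manual_baseline") {
    max(0, min(icc_m$icc, 1 - 1e-9))
  } else 0
  icc_s <- icc_a1(sem, r0 = r0)
  wt <- wilcoxon_paired(paired_sample(man_v, sem_v))
  bf <- brown_forsythe(man_v, sem_v)
  data.frame(task = task, index = ind,
             manual_median = mq["median"], manual_q1 = mq["q1"],
             manual_q3 = mq["q3"],
             semiauto_median = sq["median"], semiauto_q1 = sq["q1"],
             semiauto_q3 = sq["q3"],
             manual_icc = icc_m$icc, manual_ci_low = icc_m$ci_low,
             manual_ci_high = icc_m$ci_high,
             manual_p_r0_zero = icc_m$p_value,
             semiauto_icc = icc_s$icc, semiauto_ci_low = icc_s$ci_low,
             semiauto_ci_high = icc_s$ci_high,
             r0 = r0, icc_p_value = icc_s$p_value,
             icc_significant = icc_s$p_value < cfg$alpha,
             wilcoxon_p = wt$p_value, brown_forsythe_p = bf$p_value,
             stringsAsFactors = FALSE, row.names = NULL)
}

timing_comparison <- function(timing, cfg) {
  samples <- list()
  for (task in intersect(cfg$tasks, unique(timing$task))) {
    sub <- timing[timing$task == task, , drop = FALSE]
    man <- sub[sub$method == "manual", , drop = FALSE]
    sem <- sub[sub$method == "semiauto", , drop = FALSE]
    key <- function(d) paste(d$recording_id, d$scorer_id)
    sem <- sem[match(key(man), key(sem)), , drop = FALSE]
    if (anyNA(sem$active_minutes)) {
      stop("timing records not matched across methods for task ", task,
           call. = FALSE)
    }
    samples[[task]] <- paired_sample(man$active_minutes, sem$active_minutes,
                                     unit = "minutes",
                                     matching_key = "scorer x recording")
  }
  # total per-scorer time across tasks, paired by scorer x recording index
  tasks <- intersect(cfg$tasks, unique(timing$task))
  if (length(tasks) > 1L) {
    # recordings are task-specific; pair totals by the recording's rank
    # within its task (r-th recording of each task, summed over tasks)
    rec_rank <- integer(nrow(timing))
    for (tk in unique(timing$task)) {
      sel <- timing$task == tk
      ids <- sort(unique(timing$recording_id[sel]))
      rec_rank[sel] <- match(timing$recording_id[sel], ids)
    }
    timing$rec_rank <- rec_rank
    tot <- stats::aggregate(
      active_minutes ~ scorer_id + method + rec_rank,
      data = timing, FUN = sum)
    man <- tot[tot$method == "manual", , drop = FALSE]
    sem <- tot[tot$method == "semiauto", , drop = FALSE]
    key <- function(d) paste(d$scorer_id, d$rec_rank)
    sem <- sem[match(key(man), key(sem)), , drop = FALSE]
    samples[["all_tasks"]] <- paired_sample(
      man$active_minutes, sem$active_minutes, unit = "minutes",
      matching_key = "scorer x recording index, summed over tasks")
  }
  build_comparison_table(samples, with_gain = TRUE, alpha = cfg$alpha)
}

#' @export
print.agreement_report <- function(x, ...) {
  cat("== Scoring time (minutes) ==\n")
  if (!is.null(x$timing)) print(x$timing) else cat("(no timing records)\n")
  cat("\n== Pairwise kappa agreement ==\n")
  print(x$kappa)
  cat("\n== Diagnostic indices: ICC(A,1) ==\n")
  if (!is.null(x$indices)) {
    fmt <- sprintf(
      "%-14s %-5s ICC %.2f (%.2f-%.2f) -> %.2f (%.2f-%.2f), r0 %.2f, p %s%s",
      x$indices$task, x$indices$index, x$indices$manual_icc,
      x$indices$manual_ci_low, x$indices$manual_ci_high,
      x$indices$semiauto_icc, x$indices$semiauto_ci_low,
      x$indices$semiauto_ci_high, x$indices$r0,
      format_p(x$indices$icc_p_value),
      ifelse(x$indices$icc_significant, "*", ""))
    cat(fmt, sep = "\n")
  }
  invisible(x)
}

#' Write an agreement report to CSV files and a text summary
#'
#' @param report A [run_agreement_analysis()] result.
#' @param dir Output directory.
#' @return `dir`, invisibly.
#' @export
write_report <- function(report, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  utils::write.csv(report$kappa, file.path(dir, "kappa_comparison.csv"),
                   row.names = FALSE)
  if (!is.null(report$timing)) {
    utils::write.csv(report$timing, file.path(dir, "timing_comparison.csv"),
                     row.names = FALSE)
  }
  if (!is.null(report$indices)) {
    utils::write.csv(report$indices, file.path(dir, "index_icc.csv"),
                     row.names = FALSE)
  }
  utils::write.csv(report$kappa_raw, file.path(dir, "kappa_raw.csv"),
                   row.names = FALSE)
  txt <- c(
    "Inter-scorer agreement report",
    sprintf("alpha = %g, per-test (no multiple-testing correction)",
            report$config$alpha),
    "", "Scoring time (minutes):",
    if (!is.null(report$timing)) format(report$timing) else "(none)",
    "", "Pairwise kappa:", format(report$kappa))
  writeLines(txt, file.path(dir, "report.txt"))
  invisible(dir)
}
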