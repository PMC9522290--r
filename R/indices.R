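#' Summarize a hypnogram into sleep-quality parameters
#'
#' Derives time in bed (TIB), total sleep time (TST = summed duration of
#' N1/N2/N3/R epochs), sleep onset latency (SOL = time to first non-W
#' epoch), stage-R latency (first R epoch relative to sleep onset), wake
#' after sleep onset (WASO = TIB - SOL - TST) and sleep efficiency
#' (SE = 100 TST / TIB). With no sleep epochs, SOL and R latency are
#' undefined (`NA`) and SE is 0.
#'
#' @param h A [hypnogram()].
#' @param tib Time in bed in seconds; defaults to the hypnogram span.
#' @return Object of class `hypnogram_summary`: `tib_h`, `tst_h` (hours),
#'   `sol_min`, `rem_latency_min`, `waso_min` (minutes), `se_pct`.
#' @export
summarize_hypnogram <- function(h, tib = length(h$stages) * h$epoch_duration) {
  if (length(h$stages) == 0L) stop("empty hypnogram", call. = FALSE)
  ed <- h$epoch_duration
  sleep <- h$stages != "W"
  tst_s <- sum(sleep) * ed
  first_sleep <- which(sleep)[1]
  first_rem <- which(h$stages == "R")[1]
  sol_s <- if (is.na(first_sleep)) NA_real_ else (first_sleep - 1L) * ed
  rem_s <- if (is.na(first_sleep) || is.na(first_rem)) NA_real_
           else (first_rem - first_sleep) * ed
  waso_s <- if (is.na(sol_s)) tib else tib - sol_s - tst_s
  structure(list(tib_h = tib / 3600, tst_h = tst_s / 3600,
                 sol_min = sol_s / 60, rem_latency_min = rem_s / 60,
                 waso_min = waso_s / 60,
                 se_pct = 100 * tst_s / tib),
            class = "hypnogram_summary")
}

#' @export
print.hypnogram_summary <- function(x, ...) {
  cat(sprintf(
    "TIB %.2f h, TST %.2f h, SOL %.1f min, R latency %.1f min, WASO %.1f min, SE %.1f%%\n",
    x$tib_h, x$tst_h, x$sol_min, x$rem_latency_min, x$waso_min, x$se_pct))
  invisible(x)
}

#' Combine per-leg movements into a bilateral leg-movement train
#'
#' WASM2016-style bilateral combination: movements on opposite legs whose
#' end-to-onset gap is shorter than `gap_threshold` are merged into one
#' bilateral movement spanning both. Overlapping movements within one leg
#' are merged first (with a warning). After combination, monolateral
#' movements shorter than `min_duration` are discarded, monolateral
#' movements are capped at `mono_cap` seconds and bilateral ones at
#' `bilateral_cap` seconds.
#'
#' @param left_lms,right_lms Annotation tables (or data.frames with `onset`,
#'   `duration`) for each leg, time-ordered.
#' @param gap_threshold Maximum end-to-onset gap for merging, seconds.
#' @param min_duration Minimum movement duration kept, seconds.
#' @param mono_cap,bilateral_cap Maximum candidate durations, seconds;
#'   longer movements are dropped per WASM2016.
#' @return Object of class `lm_train`: data.frame `movements` with columns
#'   `onset`, `duration`, `laterality`, plus logical columns `periodic` and
#'   `respiratory_related` (filled by [mark_periodic()] and
#'   [flag_respiratory_lms()]).
#' @export
combine_bilateral <- function(left_lms, right_lms, gap_threshold = 0.5,
                              min_duration = 0.5, mono_cap = 10,
                              bilateral_cap = 15) {
  l <- merge_within_leg(left_lms, "left")
  r <- merge_within_leg(right_lms, "right")
  pool <- rbind(l, r)
  pool <- pool[order(pool$onset, pool$laterality), , drop = FALSE]
  out <- list()
  i <- 1L
  while (i <= nrow(pool)) {
    cur <- pool[i, ]
    j <- i + 1L
    while (j <= nrow(pool) &&
           pool$onset[j] - (cur$onset + cur$duration) < gap_threshold) {
      if (pool$laterality[j] != cur$laterality || cur$laterality == "bilateral") {
        cur$duration <- max(cur$onset + cur$duration,
                            pool$onset[j] + pool$duration[j]) - cur$onset
        cur$laterality <- "bilateral"
        j <- j + 1L
      } else break
    }
    out[[length(out) + 1L]] <- cur
    i <- j
  }
  mv <- if (length(out) > 0L) do.call(rbind, out) else
    data.frame(onset = numeric(), duration = numeric(),
               laterality = character(), stringsAsFactors = FALSE)
  keep <- mv$duration >= min_duration &
    ifelse(mv$laterality == "bilateral", mv$duration <= bilateral_cap,
           mv$duration <= mono_cap)
  mv <- mv[keep, , drop = FALSE]
  rownames(mv) <- NULL
  mv$periodic <- logical(nrow(mv))
  mv$respiratory_related <- logical(nrow(mv))
  structure(list(movements = mv), class = "lm_train")
}

merge_within_leg <- function(lms, side) {
  df <- as.data.frame(lms)[, c("onset", "duration"), drop = FALSE]
  df <- df[order(df$onset), , drop = FALSE]
  if (nrow(df) > 1L) {
    ends <- cumsum_max(df$onset + df$duration)
    overlap <- df$onset[-1L] < ends[-nrow(df)]
    if (any(overlap)) {
      warning("overlapping leg movements within the ", side,
              " leg merged", call. = FALSE)
      grp <- cumsum(c(TRUE, !overlap))
      df <- do.call(rbind, lapply(split(df, grp), function(g) {
        data.frame(onset = min(g$onset),
                   duration = max(g$onset + g$duration) - min(g$onset))
      }))
    }
  }
  if (nrow(df) == 0L) {
    return(data.frame(onset = numeric(), duration = numeric(),
                      laterality = character(), stringsAsFactors = FALSE))
  }
  data.frame(onset = df$onset, duration = df$duration, laterality = side,
             stringsAsFactors = FALSE)
}

cumsum_max <- function(x) {
  for (i in seq_along(x)[-1]) x[i] <- max(x[i - 1], x[i])
  x
}

#' Flag periodic leg movements
#'
#' Onset-to-onset inter-movement intervals (IMIs) are computed over the
#' combined train; every movement belonging to a maximal run of at least
#' `min_run` consecutive movements whose successive IMIs all lie in
#' `[imi_min, imi_max]` is flagged periodic (WASM2016).
#'
#' @param train An [combine_bilateral()] train.
#' @param imi_min,imi_max IMI bounds in seconds (default 10 and 90).
#' @param min_run Minimum run length (default 4).
#' @return The train with `movements$periodic` filled in.
#' @export
mark_periodic <- function(train, imi_min = 10, imi_max = 90, min_run = 4) {
  mv <- train$movements
  n <- nrow(mv)
  periodic <- logical(n)
  if (n >= min_run) {
    imi <- diff(mv$onset)
    ok <- imi >= imi_min & imi <= imi_max
    run_start <- 1L
    for (i in seq_len(n - 1L)) {
      if (!ok[i]) {
        if (i - run_start + 1L >= min_run) periodic[run_start:i] <- TRUE
        run_start <- i + 1L
      }
    }
    if (n - run_start + 1L >= min_run) periodic[run_start:n] <- TRUE
  }
  train$movements$periodic <- periodic
  train
}

#' Flag respiratory-related leg movements
#'
#' A movement is respiratory-related when its onset falls inside a window
#' around the end of a scored apnea or hypopnea, from `pre` seconds before
#' to `post` seconds after (WASM2016 defaults: 2.0 s before to 10.25 s
#' after).
#'
#' @param train An [combine_bilateral()] train.
#' @param resp_events Annotation table of apneas/hypopneas.
#' @param pre,post Window bounds in seconds.
#' @return The train with `movements$respiratory_related` filled in.
#' @export
flag_respiratory_lms <- function(train, resp_events, pre = 2.0, post = 10.25) {
  mv <- train$movements
  flag <- logical(nrow(mv))
  resp <- resp_events[resp_events$label %in%
                        c(.apnea_labels, "hypopnea"), , drop = FALSE]
  if (nrow(resp) > 0L && nrow(mv) > 0L) {
    ends <- resp$onset + resp$duration
    for (i in seq_len(nrow(mv))) {
      flag[i] <- any(mv$onset[i] >= ends - pre & mv$onset[i] <= ends + post)
    }
  }
  train$movements$respiratory_related <- flag
  train
}

#' Diagnostic event indices of a scored recording
#'
#' Events per hour of total sleep time: apnea index (AI), hypopnea index
#' (HI), their sum AHI (RERAs are never counted in the AHI), oxygen
#' desaturation index (ODI), arousal index (ArI), leg-movement index (LMI,
#' movements >= 0.5 s after bilateral combination) and periodic leg-movement
#' index (PLMI). `plmi_include_respiratory` keeps respiratory-related
#' movements in the PLMI counts (default on, matching the WASM2016-based
#' center convention followed here); switch it off for the conventional
#' exclusion.
#'
#' @param rec A [scored_recording()]; the wake/sleep structure comes from
#'   its context hypnogram.
#' @param summary Optional [summarize_hypnogram()] result; computed from the
#'   context hypnogram when absent.
#' @param plmi_include_respiratory Include respiratory-related LMs in PLMI.
#' @param lm_opts List of arguments forwarded to [combine_bilateral()] /
#'   [mark_periodic()] / [flag_respiratory_lms()].
#' @return Object of class `event_index_set`: `ahi`, `ai`, `hi`, `odi`,
#'   `ari`, `lmi`, `plmi` (all `NA` with `undefined = TRUE` when TST = 0).
#' @export
event_indices <- function(rec, summary = NULL,
                          plmi_include_respiratory = TRUE,
                          lm_opts = list()) {
  if (is.null(summary)) {
    if (is.null(rec$context_hypnogram)) {
      stop("event_indices needs a hypnogram (context or summary)",
           call. = FALSE)
    }
    summary <- summarize_hypnogram(rec$context_hypnogram,
                                   tib = tib_seconds(rec))
  }
  tst <- summary$tst_h
  if (!is.finite(tst) || tst <= 0) {
    return(structure(list(ahi = NA_real_, ai = NA_real_, hi = NA_real_,
                          odi = NA_real_, ari = NA_real_, lmi = NA_real_,
                          plmi = NA_real_, undefined = TRUE),
                     class = "event_index_set"))
  }
  ann <- rec$annotations
  n_ap <- sum(ann$label %in% .apnea_labels)
  n_hyp <- sum(ann$label == "hypopnea")
  n_odi <- sum(ann$label == "desaturation")
  n_ari <- sum(ann$label == "arousal")

  train <- do.call(combine_bilateral, c(
    list(left_lms = ann[ann$label == "lm-left", , drop = FALSE],
         right_lms = ann[ann$label == "lm-right", , drop = FALSE]),
    lm_opts[intersect(names(lm_opts),
                      c("gap_threshold", "min_duration", "mono_cap",
                        "bilateral_cap"))]))
  train <- do.call(mark_periodic, c(
    list(train = train),
    lm_opts[intersect(names(lm_opts), c("imi_min", "imi_max", "min_run"))]))
  resp_ctx <- rec$context_events %||%
    ann[ann$label %in% c(.apnea_labels, "hypopnea"), , drop = FALSE]
  train <- do.call(flag_respiratory_lms, c(
    list(train = train, resp_events = resp_ctx),
    lm_opts[intersect(names(lm_opts), c("pre", "post"))]))

  mv <- train$movements
  n_lm <- nrow(mv)
  per <- mv$periodic
  if (!plmi_include_respiratory) per <- per & !mv$respiratory_related
  structure(list(ahi = (n_ap + n_hyp) / tst, ai = n_ap / tst,
                 hi = n_hyp / tst, odi = n_odi / tst, ari = n_ari / tst,
                 lmi = n_lm / tst, plmi = sum(per) / tst,
                 undefined = FALSE),
            class = "event_index_set")
}

#' @export
print.event_index_set <- function(x, ...) {
  if (isTRUE(x$undefined)) {
    cat("<event_index_set> undefined (TST = 0)\n")
  } else {
    cat(sprintf(
      "AHI %.2f (AI %.2f + HI %.2f), ODI %.2f, ArI %.2f, LMI %.2f, PLMI %.2f /h TST\n",
      x$ahi, x$ai, x$hi, x$odi, x$ari, x$lmi, x$plmi))
  }
  invisible(x)
}
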