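#' Ground-truth physiology model for synthetic recordings
#'
#' Parameters of the synthetic ground truth: a first-order Markov chain on
#' 30 s sleep-stage epochs (starting in W at lights-off), homogeneous
#' Poisson event processes over sleep time at configured rates (events per
#' hour of sleep, matching how diagnostic indices are normalized), explicit
#' periodic leg-movement trains, and desaturations coupled to respiratory
#' events.
#'
#' Default event rates are chosen to land the derived indices in ranges
#' typical of a mixed clinical sleep-lab population (AHI around 5-10,
#' LMI around 20-40, PLMI around 10-25 per hour of sleep).
#'
#' @param tib_hours Time in bed, hours.
#' @param stage_transition 5x5 row-stochastic matrix over W,N1,N2,N3,R.
#' @param event_rates Named rates per hour of sleep: `apnea`, `hypopnea`,
#'   `rera`, `arousal`, `desaturation` (baseline desats not coupled to
#'   respiratory events).
#' @param lm_isolated_rate Isolated leg movements per hour of sleep, per leg.
#' @param lm_train_rate Periodic LM trains per hour of sleep.
#' @param lm_run_range Min/max movements per periodic train.
#' @param lm_imi_range Min/max onset-to-onset interval within trains,
#'   seconds (within the 10-90 s periodicity band).
#' @param lm_bilateral_prob Probability a train movement fires on both legs.
#' @param lm_wake_fraction Fraction of leg movements placed during wake
#'   epochs (leg activity persists into wakefulness, unlike the other
#'   event types which are generated during sleep).
#' @param duration_params Per-type log-normal duration parameters
#'   `(meanlog, sdlog, min, max)` in seconds.
#' @param desat_coupling Probability a respiratory event spawns a
#'   desaturation.
#' @return Object of class `truth_model`.
#' @export
truth_model <- function(tib_hours = 7.3,
                        stage_transition = default_stage_transition(),
                        event_rates = c(apnea = 2.0, hypopnea = 4.5,
                                        rera = 1.0, arousal = 13,
                                        desaturation = 2.0),
                        lm_isolated_rate = 5,
                        lm_train_rate = 1.6,
                        lm_run_range = c(4, 12),
                        lm_imi_range = c(15, 45),
                        lm_bilateral_prob = 0.25,
                        lm_wake_fraction = 0.2,
                        duration_params = default_duration_params(),
                        desat_coupling = 0.7) {
  st <- as.matrix(stage_transition)
  if (any(dim(st) != 5) || any(abs(rowSums(st) - 1) > 1e-8) || any(st < 0)) {
    stop("stage_transition must be a 5x5 row-stochastic matrix",
         call. = FALSE)
  }
  if (any(event_rates < 0)) stop("event rates must be >= 0", call. = FALSE)
  if (lm_imi_range[1] < 10 || lm_imi_range[2] > 90) {
    stop("lm_imi_range must lie within [10, 90] s for periodic trains",
         call. = FALSE)
  }
  structure(list(tib_hours = tib_hours, stage_transition = st,
                 event_rates = event_rates,
                 lm_isolated_rate = lm_isolated_rate,
                 lm_train_rate = lm_train_rate,
                 lm_run_range = lm_run_range, lm_imi_range = lm_imi_range,
                 lm_bilateral_prob = lm_bilateral_prob,
                 lm_wake_fraction = lm_wake_fraction,
                 duration_params = duration_params,
                 desat_coupling = desat_coupling),
            class = "truth_model")
}

default_stage_transition <- function() {
  m <- matrix(c(
    # W     N1     N2     N3     R
    0.85, 0.15, 0.00, 0.00, 0.00,   # W
    0.07, 0.50, 0.41, 0.00, 0.02,   # N1
    0.03, 0.04, 0.81, 0.09, 0.03,   # N2
    0.02, 0.00, 0.12, 0.86, 0.00,   # N3
    0.05, 0.03, 0.07, 0.00, 0.85    # R
  ), nrow = 5, byrow = TRUE, dimnames = list(psg_stages, psg_stages))
  m
}

default_duration_params <- function() {
  list(
    apnea = c(meanlog = log(20), sdlog = 0.35, min = 10, max = 80),
    hypopnea = c(meanlog = log(22), sdlog = 0.35, min = 10, max = 80),
    rera = c(meanlog = log(15), sdlog = 0.3, min = 10, max = 40),
    arousal = c(meanlog = log(8), sdlog = 0.4, min = 3, max = 25),
    desaturation = c(meanlog = log(18), sdlog = 0.35, min = 8, max = 60),
    lm = c(meanlog = log(2), sdlog = 0.45, min = 0.5, max = 8)
  )
}

#' Scorer corruption model
#'
#' How one scorer's output deviates from its input scoring (the ground
#' truth for manual scoring; the shared automatic draft for semi-automatic
#' scoring). Stage epochs are resampled from
#' `(1 - e) * delta_input + e * kernel_row`; events are kept with
#' probability `event_sensitivity`, their boundaries jittered with
#' independent zero-mean Gaussian noise, and false positives added as a
#' Poisson process with uniform positions and input-like durations.
#'
#' @param stage_error_rate Probability a stage epoch is resampled.
#' @param stage_confusion_kernel 5x5 row-stochastic resampling kernel
#'   (default: uniform over the four other stages).
#' @param event_sensitivity Probability an input event is kept.
#' @param false_positive_rate Spurious events per hour of TIB.
#' @param boundary_jitter_sd SD of onset/offset jitter, seconds.
#' @param label_sensitivity Optional named multipliers on
#'   `event_sensitivity` per label (capped at 1); e.g. scorers identify
#'   apneas more reliably than hypopneas.
#' @param label_jitter Optional named multipliers on `boundary_jitter_sd`
#'   per label.
#' @return Object of class `scorer_model`.
#' @export
scorer_model <- function(stage_error_rate = 0.09,
                         stage_confusion_kernel = uniform_confusion(),
                         event_sensitivity = 0.9,
                         false_positive_rate = 1,
                         boundary_jitter_sd = 0.5,
                         label_sensitivity = NULL,
                         label_jitter = NULL) {
  k <- as.matrix(stage_confusion_kernel)
  if (any(dim(k) != 5) || any(abs(rowSums(k) - 1) > 1e-8) || any(k < 0)) {
    stop("stage_confusion_kernel must be 5x5 row-stochastic", call. = FALSE)
  }
  stopifnot(stage_error_rate >= 0, stage_error_rate <= 1,
            event_sensitivity >= 0, event_sensitivity <= 1,
            false_positive_rate >= 0, boundary_jitter_sd >= 0)
  structure(list(stage_error_rate = stage_error_rate,
                 stage_confusion_kernel = k,
                 event_sensitivity = event_sensitivity,
                 false_positive_rate = false_positive_rate,
                 boundary_jitter_sd = boundary_jitter_sd,
                 label_sensitivity = label_sensitivity,
                 label_jitter = label_jitter),
            class = "scorer_model")
}

uniform_confusion <- function() {
  k <- matrix(1 / 4, 5, 5, dimnames = list(psg_stages, psg_stages))
  diag(k) <- 0
  k
}

# Deterministic substream seed derived from a master seed and a key path.
# Linear-congruential fold over the key bytes; stays below 2^31.
derive_seed <- function(master, ...) {
  key <- paste(..., sep = "/")
  h <- as.numeric(master) %% 2147483647
  for (ch in utf8ToInt(key)) h <- (h * 69069 + ch) %% 2147483647
  as.integer(h)
}

#' Generate a ground-truth scored recording
#'
#' @param model A [truth_model()].
#' @param recording_id Identifier for the recording.
#' @param task Task whose annotation set to generate (`"staging"` produces
#'   only the hypnogram; event tasks produce the relevant event lists plus
#'   the context hypnogram).
#' @param seed Integer seed; fixed seed gives identical output.
#' @return A [scored_recording()] holding the ground truth (scorer id
#'   `"truth"`).
#' @export
generate_truth <- function(model, recording_id = "rec", task = "staging",
                           seed = 1) {
  set.seed(derive_seed(seed, "truth", recording_id, task))
  tib <- model$tib_hours * 3600
  n_ep <- floor(tib / 30)
  stages <- character(n_ep)
  cur <- "W"
  for (i in seq_len(n_ep)) {
    stages[i] <- cur
    cur <- sample(psg_stages, 1, prob = model$stage_transition[cur, ])
  }
  hyp <- hypnogram(stages, lights_off = 0)
  sleep_ep <- which(stages != "W")
  tst_h <- length(sleep_ep) * 30 / 3600

  lab <- character(); ons <- numeric(); dur <- numeric()
  add <- function(label, onset, duration) {
    lab <<- c(lab, label); ons <<- c(ons, onset); dur <<- c(dur, duration)
  }
  draw_dur <- function(type, n) {
    p <- model$duration_params[[type]]
    pmin(pmax(stats::rlnorm(n, p["meanlog"], p["sdlog"]), p["min"]), p["max"])
  }
  sleep_onsets <- function(n) {
    if (n == 0L || length(sleep_ep) == 0L) return(numeric(0))
    (sample(sleep_ep, n, replace = TRUE) - 1L) * 30 + stats::runif(n, 0, 30)
  }
  wake_ep <- which(stages == "W")
  lm_onsets <- function(n) {
    # leg activity persists into wake; other event types stay sleep-bound
    if (n == 0L) return(numeric(0))
    in_wake <- stats::runif(n) < model$lm_wake_fraction &
      length(wake_ep) > 0L
    o <- numeric(n)
    o[!in_wake] <- sleep_onsets(sum(!in_wake))
    if (any(in_wake)) {
      o[in_wake] <- (sample(wake_ep, sum(in_wake), replace = TRUE) - 1L) *
        30 + stats::runif(sum(in_wake), 0, 30)
    }
    o
  }

  context_events <- NULL
  if (task %in% c("respiratory", "leg_movements")) {
    # respiratory events: scored annotations for the respiratory task;
    # clinical context (for respiratory-related LM flagging) for the LM task
    rlab <- character(); rons <- numeric(); rdur <- numeric()
    for (type in c("apnea", "hypopnea", "rera")) {
      rate <- model$event_rates[[type]]
      n <- stats::rpois(1, rate * tst_h)
      o <- sleep_onsets(n)
      d <- draw_dur(if (type == "apnea") "apnea" else type, n)
      label <- if (type == "apnea") {
        sample(.apnea_labels, n, replace = TRUE, prob = c(0.7, 0.2, 0.1))
      } else rep(type, n)
      rlab <- c(rlab, label); rons <- c(rons, o); rdur <- c(rdur, d)
    }
    if (task == "respiratory") {
      add(rlab, rons, rdur)
    } else {
      keep <- rons >= 0 & rons + rdur <= tib
      context_events <- annotations(rlab[keep], rons[keep], rdur[keep])
    }
  }
  if (task == "respiratory") {
    resp <- which(lab %in% c(.apnea_labels, "hypopnea"))
    coupled <- resp[stats::runif(length(resp)) < model$desat_coupling]
    if (length(coupled) > 0) {
      add(rep("desaturation", length(coupled)),
          ons[coupled] + dur[coupled] + stats::runif(length(coupled), 5, 25),
          draw_dur("desaturation", length(coupled)))
    }
    n_base <- stats::rpois(1, model$event_rates[["desaturation"]] * tst_h)
    if (n_base > 0) {
      add(rep("desaturation", n_base), sleep_onsets(n_base),
          draw_dur("desaturation", n_base))
    }
  }
  if (task == "arousals") {
    n <- stats::rpois(1, model$event_rates[["arousal"]] * tst_h)
    if (n > 0) add(rep("arousal", n), sleep_onsets(n), draw_dur("arousal", n))
  }
  if (task == "leg_movements") {
    # isolated movements, per leg
    for (leg in c("lm-left", "lm-right")) {
      n <- stats::rpois(1, model$lm_isolated_rate * tst_h)
      if (n > 0) add(rep(leg, n), lm_onsets(n), draw_dur("lm", n))
    }
    # periodic trains
    n_tr <- stats::rpois(1, model$lm_train_rate * tst_h)
    for (t in seq_len(n_tr)) {
      run <- sample(model$lm_run_range[1]:model$lm_run_range[2], 1)
      start <- lm_onsets(1)
      if (length(start) == 0L) next
      imis <- stats::runif(run - 1, model$lm_imi_range[1],
                           model$lm_imi_range[2])
      onsets <- start + c(0, cumsum(imis))
      durs <- draw_dur("lm", run)
      legs <- sample(c("lm-left", "lm-right"), run, replace = TRUE)
      bil <- stats::runif(run) < model$lm_bilateral_prob
      add(legs, onsets, durs)
      if (any(bil)) {
        other <- ifelse(legs[bil] == "lm-left", "lm-right", "lm-left")
        add(other, onsets[bil] + stats::runif(sum(bil), 0, 0.3),
            durs[bil] * stats::runif(sum(bil), 0.7, 1))
      }
    }
  }

  keep <- ons >= 0 & ons < tib
  scored_recording(
    recording_id = recording_id, scorer_id = "truth", method = "manual",
    task = task, lights_off = 0, lights_on = tib,
    annotations = if (task == "staging") {
      annotations(paste0("stage-", stages),
                  (seq_len(n_ep) - 1) * 30, rep(30, n_ep))
    } else {
      annotations(lab[keep], ons[keep], dur[keep])
    },
    context_hypnogram = if (task == "staging") NULL else hyp,
    context_events = context_events)
}

#' Corrupt a scoring with a scorer model
#'
#' Applies the [scorer_model()] noise channel to an input scoring: the
#' identity limit (no stage error, full sensitivity, zero jitter, no false
#' positives) reproduces the input exactly.
#'
#' @param truth Input [scored_recording()] (ground truth or shared draft).
#' @param scorer A [scorer_model()].
#' @param scorer_id Identifier for the output.
#' @param method Method tag for the output.
#' @param seed Integer seed.
#' @return A [scored_recording()].
#' @export
corrupt_scoring <- function(truth, scorer, scorer_id = "s01",
                            method = "manual", seed = 1) {
  set.seed(derive_seed(seed, "scorer", truth$recording_id, truth$task,
                       scorer_id, method))
  tib <- tib_seconds(truth)
  if (truth$task == "staging") {
    stages <- truth$context_hypnogram$stages
    flip <- stats::runif(length(stages)) < scorer$stage_error_rate
    if (any(flip)) {
      stages[flip] <- vapply(stages[flip], function(s) {
        sample(psg_stages, 1, prob = scorer$stage_confusion_kernel[s, ])
      }, character(1))
    }
    n_ep <- length(stages)
    return(scored_recording(
      recording_id = truth$recording_id, scorer_id = scorer_id,
      method = method, task = "staging",
      lights_off = truth$lights_off, lights_on = truth$lights_on,
      annotations = annotations(paste0("stage-", stages),
                                truth$lights_off + (seq_len(n_ep) - 1) * 30,
                                rep(30, n_ep))))
  }
  ann <- truth$annotations
  mult_for <- function(mults, labels) {
    m <- rep(1, length(labels))
    if (!is.null(mults)) {
      # apnea subtypes share the "apnea" entry when present
      key <- ifelse(labels %in% .apnea_labels & "apnea" %in% names(mults),
                    "apnea", labels)
      hit <- mults[key]
      m[!is.na(hit)] <- hit[!is.na(hit)]
    }
    m
  }
  sens <- pmin(1, scorer$event_sensitivity *
                 mult_for(scorer$label_sensitivity, ann$label))
  kept <- ann[stats::runif(nrow(ann)) < sens, , drop = FALSE]
  jit <- scorer$boundary_jitter_sd *
    mult_for(scorer$label_jitter, kept$label)
  if (nrow(kept) > 0 && any(jit > 0)) {
    on_j <- kept$onset + stats::rnorm(nrow(kept), 0, jit)
    end_j <- kept$onset + kept$duration +
      stats::rnorm(nrow(kept), 0, jit)
    end_j <- pmax(end_j, on_j + pmax(0.2, 0.1 * kept$duration))
    kept$onset <- pmax(on_j, truth$lights_off)
    kept$duration <- end_j - kept$onset
  }
  n_fp <- stats::rpois(1, scorer$false_positive_rate * tib / 3600)
  if (n_fp > 0) {
    src_labels <- if (nrow(ann) > 0) {
      sample(ann$label, n_fp, replace = TRUE)
    } else rep(task_default_label(truth$task), n_fp)
    src_dur <- if (nrow(ann) > 0) {
      sample(ann$duration, n_fp, replace = TRUE) *
        stats::runif(n_fp, 0.6, 1.4)
    } else stats::runif(n_fp, 1, 20)
    fp <- data.frame(label = src_labels,
                     onset = truth$lights_off + stats::runif(n_fp, 0, tib),
                     duration = src_dur, stringsAsFactors = FALSE)
    kept <- rbind(kept[, c("label", "onset", "duration")], fp)
  }
  scored_recording(
    recording_id = truth$recording_id, scorer_id = scorer_id,
    method = method, task = truth$task,
    lights_off = truth$lights_off, lights_on = truth$lights_on,
    annotations = annotations(kept$label, kept$onset, kept$duration),
    context_hypnogram = truth$context_hypnogram,
    context_events = truth$context_events)
}

task_default_label <- function(task) {
  switch(task, leg_movements = "lm-left", respiratory = "hypopnea",
         arousals = "arousal", "arousal")
}

#' Full study configuration for the synthetic generator
#'
#' The defaults reproduce the study design the analysis targets: 12
#' scorers, 2 methods, 4 tasks, 5 recordings per task (40 exercises per
#' scorer). Scorer-corruption parameters per task and method are calibrated
#' so the simulated agreement levels approximate [kappa_reference()]; the
#' semi-automatic condition is modeled as all scorers independently editing
#' one shared automatic draft, which induces the between-scorer correlation
#' that raises agreement. Scoring times are log-normal with medians and
#' spreads taken from [scoring_time_reference()].
#'
#' @param n_scorers Number of scorers.
#' @param n_recordings Recordings per task.
#' @param tasks Scoring tasks simulated.
#' @param truth A [truth_model()].
#' @param manual_models,edit_models,draft_models Named lists (by task) of
#'   [scorer_model()]s: corruption of truth under manual scoring, of the
#'   draft under semi-automatic editing, and of truth by the automatic
#'   draft itself.
#' @param timing Data frame with columns task, method, median_min, q1_min,
#'   q3_min parameterizing the log-normal scoring times.
#' @return Object of class `study_config`.
#' @export
study_config <- function(n_scorers = 12, n_recordings = 5,
                         tasks = c("staging", "leg_movements",
                                   "respiratory", "arousals"),
                         truth = truth_model(),
                         manual_models = default_manual_models(),
                         edit_models = default_edit_models(),
                         draft_models = default_draft_models(),
                         timing = scoring_time_reference()) {
  structure(list(n_scorers = n_scorers, n_recordings = n_recordings,
                 tasks = tasks, truth = truth,
                 manual_models = manual_models, edit_models = edit_models,
                 draft_models = draft_models, timing = timing),
            class = "study_config")
}

default_manual_models <- function() {
  list(
    staging = scorer_model(stage_error_rate = 0.09),
    leg_movements = scorer_model(event_sensitivity = 0.90,
                                 false_positive_rate = 2,
                                 boundary_jitter_sd = 0.35),
    respiratory = scorer_model(event_sensitivity = 0.80,
                               false_positive_rate = 1.4,
                               boundary_jitter_sd = 3.6,
                               label_sensitivity = c(apnea = 1.18,
                                                     hypopnea = 0.90,
                                                     rera = 0.9),
                               label_jitter = c(apnea = 0.45,
                                                hypopnea = 1.3)),
    arousals = scorer_model(event_sensitivity = 0.87,
                            false_positive_rate = 1.4,
                            boundary_jitter_sd = 1.9)
  )
}

default_edit_models <- function() {
  list(
    staging = scorer_model(stage_error_rate = 0.075),
    leg_movements = scorer_model(event_sensitivity = 0.97,
                                 false_positive_rate = 0.3,
                                 boundary_jitter_sd = 0.12),
    respiratory = scorer_model(event_sensitivity = 0.84,
                               false_positive_rate = 0.9,
                               boundary_jitter_sd = 2.6,
                               label_sensitivity = c(apnea = 1.14,
                                                     hypopnea = 0.94,
                                                     rera = 0.95),
                               label_jitter = c(apnea = 0.45,
                                                hypopnea = 1.2)),
    arousals = scorer_model(event_sensitivity = 0.87,
                            false_positive_rate = 1.0,
                            boundary_jitter_sd = 1.2)
  )
}

default_draft_models <- function() {
  list(
    staging = scorer_model(stage_error_rate = 0.12),
    leg_movements = scorer_model(event_sensitivity = 0.92,
                                 false_positive_rate = 1.5,
                                 boundary_jitter_sd = 0.3),
    respiratory = scorer_model(event_sensitivity = 0.85,
                               false_positive_rate = 1.2,
                               boundary_jitter_sd = 3,
                               label_sensitivity = c(apnea = 1.1,
                                                     hypopnea = 0.95),
                               label_jitter = c(apnea = 0.5)),
    arousals = scorer_model(event_sensitivity = 0.82,
                            false_positive_rate = 1.6,
                            boundary_jitter_sd = 2)
  )
}

#' Draw a recording-specific truth model
#'
#' Real study recordings come from different patients, so the diagnostic
#' indices vary widely between recordings (this between-recording variance
#' is what makes inter-scorer ICC meaningful). Starting from a base
#' [truth_model()], this draws per-recording severity factors: a
#' log-normal respiratory severity (scaling apnea/hypopnea/RERA/
#' desaturation rates, with a random apnea share of the apnea+hypopnea
#' total), a log-normal leg-movement severity, a log-normal arousal
#' propensity, and a wake propensity (W-epoch persistence and return rate
#' to W) governing sleep efficiency.
#'
#' @param base A [truth_model()].
#' @param seed Master seed.
#' @param key Substream key (e.g. the recording id).
#' @param resp_sdlog,lm_sdlog,arousal_sdlog Log-normal severity spreads.
#' @param wake_persist_range Range of the W-to-W transition probability.
#' @return A [truth_model()] with recording-specific parameters.
#' @export
sample_recording_model <- function(base, seed, key,
                                   resp_sdlog = 0.9, lm_sdlog = 0.8,
                                   arousal_sdlog = 0.5,
                                   wake_persist_range = c(0.78, 0.93)) {
  set.seed(derive_seed(seed, "recmodel", key))
  m <- base
  resp_total <- (base$event_rates[["apnea"]] + base$event_rates[["hypopnea"]]) *
    stats::rlnorm(1, 0, resp_sdlog)
  apnea_share <- stats::rbeta(1, 2, 4)
  m$event_rates[["apnea"]] <- resp_total * apnea_share
  m$event_rates[["hypopnea"]] <- resp_total * (1 - apnea_share)
  resp_f <- stats::rlnorm(1, 0, resp_sdlog / 2)
  m$event_rates[["rera"]] <- base$event_rates[["rera"]] * resp_f
  m$event_rates[["desaturation"]] <- base$event_rates[["desaturation"]] *
    resp_f
  lm_f <- stats::rlnorm(1, 0, lm_sdlog)
  m$lm_isolated_rate <- base$lm_isolated_rate * lm_f
  m$lm_train_rate <- base$lm_train_rate * lm_f
  m$event_rates[["arousal"]] <- base$event_rates[["arousal"]] *
    stats::rlnorm(1, 0, arousal_sdlog)
  w_stay <- stats::runif(1, wake_persist_range[1], wake_persist_range[2])
  st <- m$stage_transition
  st["W", ] <- c(w_stay, 1 - w_stay, 0, 0, 0)
  w_return <- stats::runif(1, 0.5, 2)
  for (s in c("N1", "N2", "N3", "R")) {
    st[s, "W"] <- min(0.5, st[s, "W"] * w_return)
    st[s, ] <- st[s, ] / sum(st[s, ])
  }
  m$stage_transition <- st
  m
}

#' Generate a complete synthetic multi-scorer study
#'
#' Ground truths per recording x task, per-scorer manual scorings
#' (independent corruptions of the truth), per-scorer semi-automatic
#' scorings (independent edits of one shared automatic draft per
#' recording), and log-normal active-scoring-time records. All randomness
#' flows from the master seed through named per-cell substreams, so a fixed
#' seed yields an identical study.
#'
#' @param cfg A [study_config()].
#' @param seed Master seed (integer).
#' @return List with elements `study` (a [scoring_set()] with timing
#'   attached), `truths` and `drafts` (named lists of
#'   [scored_recording()]s).
#' @export
generate_study <- function(cfg = study_config(), seed = 1) {
  scorer_ids <- sprintf("s%02d", seq_len(cfg$n_scorers))
  cells <- list()
  truths <- list()
  drafts <- list()
  tim <- list()
  for (task in cfg$tasks) {
    for (r in seq_len(cfg$n_recordings)) {
      rid <- sprintf("%s-r%02d", abbreviate_task(task), r)
      rec_model <- sample_recording_model(cfg$truth, seed,
                                          paste(task, rid, sep = "/"))
      truth <- generate_truth(rec_model, recording_id = rid, task = task,
                              seed = seed)
      truths[[paste(task, rid, sep = "/")]] <- truth
      draft <- corrupt_scoring(truth, cfg$draft_models[[task]],
                               scorer_id = "autodraft", method = "semiauto",
                               seed = derive_seed(seed, "draft"))
      drafts[[paste(task, rid, sep = "/")]] <- draft
      for (sid in scorer_ids) {
        cells[[length(cells) + 1L]] <-
          corrupt_scoring(truth, cfg$manual_models[[task]],
                          scorer_id = sid, method = "manual", seed = seed)
        cells[[length(cells) + 1L]] <-
          corrupt_scoring(draft, cfg$edit_models[[task]],
                          scorer_id = sid, method = "semiauto", seed = seed)
      }
      tim[[length(tim) + 1L]] <- simulate_timing(cfg$timing, task, rid,
                                                 scorer_ids, seed)
    }
  }
  timing <- do.call(rbind, tim)
  class(timing) <- c("timing_records", "data.frame")
  list(study = scoring_set(cells, timing = timing), truths = truths,
       drafts = drafts)
}

abbreviate_task <- function(task) {
  c(staging = "stg", leg_movements = "lm", respiratory = "resp",
    arousals = "aro")[[task]]
}

# log-normal scoring times: meanlog = log(reference median), sdlog from the
# reference IQR ratio (q3/q1 of a log-normal = exp(2 * 0.6745 * sdlog)).
# Per-scorer log-normal speed and per-scorer-per-task skill factors are
# shared across the two methods (scorers have a consistent pace and
# task-specific proficiency), with the residual spread reduced so the
# marginal spread still matches the reference IQR. The shared factors
# cancel in the paired manual-vs-semiauto differences, mirroring how
# within-scorer pairing gains power in the real design.
simulate_timing <- function(timing_ref, task, rid, scorer_ids, seed,
                            scorer_speed_sdlog = 0.35,
                            scorer_skill_sdlog = 0.3) {
  speed <- vapply(scorer_ids, function(sid) {
    set.seed(derive_seed(seed, "scorerspeed", sid))
    stats::rnorm(1, 0, scorer_speed_sdlog)
  }, numeric(1))
  skill <- vapply(scorer_ids, function(sid) {
    set.seed(derive_seed(seed, "scorerskill", sid, task))
    stats::rnorm(1, 0, scorer_skill_sdlog)
  }, numeric(1))
  rows <- lapply(c("manual", "semiauto"), function(m) {
    ref <- timing_ref[timing_ref$task == task & timing_ref$method == m, ]
    if (nrow(ref) != 1L) stop("no timing reference for ", task, "/", m)
    sdlog <- log(ref$q3_min / ref$q1_min) / (2 * stats::qnorm(0.75))
    resid <- sqrt(max(sdlog^2 - scorer_speed_sdlog^2 - scorer_skill_sdlog^2,
                      0.01))
    set.seed(derive_seed(seed, "timing", task, rid, m))
    timing_records(rid, scorer_ids, m, task,
                   exp(log(ref$median_min) + speed + skill +
                         stats::rnorm(length(scorer_ids), 0, resid)))
  })
  do.call(rbind, rows)
}

#' Write a synthetic study to disk
#'
#' Emits one annotation file per cell, a timing CSV and a
#' `manifest.yaml`, all consumable by [load_study()].
#'
#' @param sim A [generate_study()] result.
#' @param dir Output directory (created if needed).
#' @param dialect Annotation dialect for the files.
#' @return `dir`, invisibly.
#' @export
write_study <- function(sim, dir, dialect = "tabular") {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  ext <- if (dialect == "tabular") "csv" else "tal"
  man_cells <- list()
  for (key in names(sim$study$cells)) {
    rec <- sim$study$cells[[key]]
    rel <- file.path(rec$task, rec$method,
                     sprintf("%s_%s.%s", rec$recording_id, rec$scorer_id,
                             ext))
    dir.create(file.path(dir, dirname(rel)), recursive = TRUE,
               showWarnings = FALSE)
    write_annotation_file(rec, file.path(dir, rel), dialect = dialect)
    man_cells[[length(man_cells) + 1L]] <-
      list(recording = rec$recording_id, scorer = rec$scorer_id,
           method = rec$method, task = rec$task, path = rel)
  }
  ctx <- list()
  for (key in names(sim$truths)) {
    truth <- sim$truths[[key]]
    if (truth$task == "staging" || is.null(truth$context_hypnogram)) next
    rel <- file.path("clinical", sprintf("%s.%s", truth$recording_id, ext))
    dir.create(file.path(dir, "clinical"), showWarnings = FALSE)
    ctx_rec <- scored_recording(
      recording_id = truth$recording_id, scorer_id = "clinical",
      method = "manual", task = "staging",
      lights_off = truth$lights_off, lights_on = truth$lights_on,
      annotations = hypnogram_annotations(truth$context_hypnogram))
    write_annotation_file(ctx_rec, file.path(dir, rel), dialect = dialect)
    ctx[[truth$recording_id]] <- rel
  }
  if (!is.null(sim$study$timing)) {
    write_timing_log(sim$study$timing, file.path(dir, "timing.csv"))
  }
  yaml::write_yaml(
    list(dialect = dialect,
         timing_log = if (is.null(sim$study$timing)) NULL else "timing.csv",
         context = ctx, cells = man_cells),
    file.path(dir, "manifest.yaml"))
  invisible(dir)
}

hypnogram_annotations <- function(h) {
  n <- length(h$stages)
  annotations(paste0("stage-", h$stages),
              h$lights_off + (seq_len(n) - 1) * h$epoch_duration,
              rep(h$epoch_duration, n))
}
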