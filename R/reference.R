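#' Reference scoring-time summary per task and method
#'
#' Median and interquartile range of active scoring times (minutes) for
#' each PSG scoring task under the manual and semi-automatic conditions.
#' These summaries define the scoring-time conditions the synthetic study
#' generator emulates (its log-normal timing distributions are parameterized
#' from them), and the per-task gain factors — the ratio of median manual to
#' median semi-automatic time — are recomputed from them by the analysis
#' scripts. The `all_tasks` row summarizes total per-scorer time over the
#' four tasks.
#'
#' @return `data.frame` with columns `task`, `method`, `median_min`,
#'   `q1_min`, `q3_min`.
#' @export
scoring_time_reference <- function() {
  data.frame(
    task = rep(c("staging", "leg_movements", "respiratory", "arousals",
                 "all_tasks"), each = 2),
    method = rep(c("manual", "semiauto"), 5),
    median_min = c(32.62, 24.54, 44.53, 18.50, 23.81, 14.58,
                   27.50, 21.78, 134.92, 80.59),
    q1_min = c(21.74, 16.25, 31.00, 12.63, 17.62, 10.46,
               21.22, 15.96, 113.08, 66.75),
    q3_min = c(48.64, 39.81, 65.30, 26.73, 46.72, 20.68,
               37.65, 28.59, 187.65, 107.89),
    stringsAsFactors = FALSE
  )
}

#' Reference inter-scorer kappa agreement levels per task and method
#'
#' Median pairwise Cohen's kappa levels typical of a panel of experienced
#' scorers from one center, per task and scoring condition. The synthetic
#' generator's default scorer-corruption parameters are calibrated so that
#' a full-scale simulated study reproduces approximately these agreement
#' levels (TIB context).
#'
#' @return `data.frame` with columns `task`, `method`, `kappa`.
#' @export
kappa_reference <- function() {
  data.frame(
    task = rep(c("staging", "leg_movements", "respiratory", "arousals"),
               each = 2),
    method = rep(c("manual", "semiauto"), 4),
    kappa = c(0.76, 0.80, 0.72, 0.91, 0.55, 0.66, 0.58, 0.65),
    stringsAsFactors = FALSE
  )
}
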