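test_that("hypnogram summary matches epoch arithmetic", {
  h <- hypnogram(c(rep("W", 10), rep("N2", 10)))
  s <- summarize_hypnogram(h, tib = 600)
  expect_equal(s$sol_min, 5)
  expect_equal(s$tst_h, 300 / 3600)
  expect_equal(s$se_pct, 50)
  expect_equal(s$waso_min, 0)
  awake <- summarize_hypnogram(hypnogram(rep("W", 20)), tib = 600)
  expect_equal(awake$se_pct, 0)
  expect_true(is.na(awake$sol_min))
  expect_true(is.na(awake$rem_latency_min))
  # REM latency is measured from sleep onset
  h2 <- hypnogram(c("W", "W", "N1", "N2", "R"))
  expect_equal(summarize_hypnogram(h2)$rem_latency_min, 2 * 30 / 60)
})

test_that("TIB = SOL + TST + WASO on random hypnograms", {
  for (seed in 1:10) {
    h <- random_hypnogram(seed, n = 60)
    tib <- 60 * 30
    s <- summarize_hypnogram(h, tib = tib)
    if (!is.na(s$sol_min)) {
      expect_equal(s$sol_min + s$waso_min + s$tst_h * 60, tib / 60,
                   tolerance = 1e-9)
    }
    expect_gte(s$se_pct, 0); expect_lte(s$se_pct, 100)
  }
})

lmdf <- function(onset, duration) data.frame(onset = onset,
                                             duration = duration)

test_that("bilateral combination merges opposite-leg movements under the gap", {
  t1 <- combine_bilateral(lmdf(10, 2), lmdf(12.2, 0.8))
  expect_equal(nrow(t1$movements), 1L)
  expect_equal(t1$movements$laterality, "bilateral")
  expect_equal(t1$movements$onset, 10)
  expect_equal(t1$movements$duration, 3)
  # gap of 1.0 s >= 0.5 stays two movements
  t2 <- combine_bilateral(lmdf(10, 2), lmdf(13, 1))
  expect_equal(nrow(t2$movements), 2L)
  expect_equal(t2$movements$laterality, c("left", "right"))
  # single leg passes through
  t3 <- combine_bilateral(lmdf(c(5, 50), c(2, 3)), lmdf(numeric(), numeric()))
  expect_equal(t3$movements$onset, c(5, 50))
  expect_true(all(t3$movements$laterality == "left"))
})

test_that("combination applies duration filters and merges overlaps", {
  # monolateral movement under 0.5 s is discarded
  short <- combine_bilateral(lmdf(10, 0.3), lmdf(numeric(), numeric()))
  expect_equal(nrow(short$movements), 0L)
  # monolateral over the 10 s cap is dropped; bilateral cap is 15 s
  long <- combine_bilateral(lmdf(10, 12), lmdf(numeric(), numeric()))
  expect_equal(nrow(long$movements), 0L)
  expect_warning(
    over <- combine_bilateral(lmdf(c(10, 11), c(3, 3)),
                              lmdf(numeric(), numeric())),
    "overlapping")
  expect_equal(nrow(over$movements), 1L)
  expect_equal(over$movements$duration, 4)
})

test_that("periodicity flags follow the IMI and run-length rules", {
  mk <- function(onsets) {
    t <- combine_bilateral(lmdf(onsets, rep(2, length(onsets))),
                           lmdf(numeric(), numeric()))
    mark_periodic(t)
  }
  expect_true(all(mk(c(0, 20, 40, 60, 80))$movements$periodic))  # run of 5
  expect_false(any(mk(c(0, 20, 40))$movements$periodic))         # run of 3
  expect_false(any(mk(c(0, 5, 10, 15, 20))$movements$periodic))  # IMI 5 < 10
  expect_false(any(mk(c(0, 100, 200, 300, 400))$movements$periodic))
  # a qualifying run embedded in a longer train is flagged exactly
  tr <- mk(c(0, 20, 40, 60, 300, 320))
  expect_equal(tr$movements$periodic, c(TRUE, TRUE, TRUE, TRUE, FALSE, FALSE))
})

test_that("respiratory-related flags use the WASM2016 window", {
  t <- combine_bilateral(lmdf(c(100, 200), c(2, 2)),
                         lmdf(numeric(), numeric()))
  resp <- annotations("apnea-obstructive", 80, 21)  # ends at 101
  t <- flag_respiratory_lms(t, resp)
  expect_equal(t$movements$respiratory_related, c(TRUE, FALSE))
  # window edges: [end - 2.0, end + 10.25]
  t2 <- combine_bilateral(lmdf(c(98.9, 111.3), c(2, 2)),
                          lmdf(numeric(), numeric()))
  t2 <- flag_respiratory_lms(t2, resp)
  expect_equal(t2$movements$respiratory_related, c(FALSE, FALSE))
})

test_that("event indices normalize counts per TST hour", {
  hyp <- hypnogram(rep("N2", 720))  # 6 h sleep
  mk_rec <- function(ann) scored_recording(
    "r1", "s1", task = "respiratory", lights_off = 0, lights_on = 720 * 30,
    annotations = ann, context_hypnogram = hyp)
  set.seed(2)
  resp <- annotations(
    c(rep("apnea-obstructive", 12), rep("hypopnea", 24), rep("rera", 6)),
    sort(runif(42, 0, 21000)), rep(15, 42))
  ei <- event_indices(mk_rec(resp))
  expect_equal(ei$ai, 2)
  expect_equal(ei$hi, 4)
  expect_equal(ei$ahi, 6)  # RERAs excluded
  # LMI: 30 combined movements over 6 h sleep
  lm_rec <- scored_recording(
    "r1", "s1", task = "leg_movements", lights_off = 0,
    lights_on = 720 * 30,
    annotations = annotations(rep("lm-left", 30),
                              seq(1000, by = 300, length.out = 30),
                              rep(2, 30)),
    context_hypnogram = hyp)
  expect_equal(event_indices(lm_rec)$lmi, 5)
})

test_that("AHI = AI + HI on random event sets", {
  for (seed in 1:5) {
    rec <- random_recording(seed, task = "respiratory", tib = 21600,
                            n_events = 50)
    rec$context_hypnogram <- hypnogram(rep("N2", 720))
    ei <- event_indices(rec)
    expect_equal(ei$ahi, ei$ai + ei$hi, tolerance = 1e-9)
    expect_true(all(unlist(ei[c("ahi", "ai", "hi", "odi", "ari",
                                "lmi", "plmi")]) >= 0))
  }
})

test_that("PLMI never exceeds LMI and scales inversely with TST", {
  set.seed(33)
  onsets <- sort(c(seq(1000, by = 25, length.out = 12),
                   runif(20, 5000, 20000)))
  ann <- annotations(rep("lm-left", 32), onsets, rep(2, 32))
  mk <- function(n_sleep) scored_recording(
    "r1", "s1", task = "leg_movements", lights_off = 0, lights_on = 21600,
    annotations = ann,
    context_hypnogram = hypnogram(c(rep("N2", n_sleep),
                                    rep("W", 720 - n_sleep))))
  e1 <- event_indices(mk(360))
  expect_lte(e1$plmi, e1$lmi)
  e2 <- event_indices(mk(720))  # double the TST, same events
  expect_equal(e2$lmi, e1$lmi / 2, tolerance = 1e-9)
  expect_equal(e2$plmi, e1$plmi / 2, tolerance = 1e-9)
})

test_that("respiratory-related movements can be excluded from the PLMI", {
  # a periodic train right after an apnea: compatibility flag keeps it
  hyp <- hypnogram(rep("N2", 720))
  train_onsets <- c(101, 121, 141, 161, 181)
  rec <- scored_recording(
    "r1", "s1", task = "leg_movements", lights_off = 0, lights_on = 21600,
    annotations = annotations(rep("lm-left", 5), train_onsets, rep(2, 5)),
    context_hypnogram = hyp,
    context_events = annotations("apnea-obstructive", 80, 22))
  on <- event_indices(rec, plmi_include_respiratory = TRUE)
  off <- event_indices(rec, plmi_include_respiratory = FALSE)
  expect_gt(on$plmi, off$plmi)
  expect_equal(on$lmi, off$lmi)
})

test_that("indices are flagged undefined when there is no sleep", {
  rec <- scored_recording(
    "r1", "s1", task = "arousals", lights_off = 0, lights_on = 600,
    annotations = annotations("arousal", 100, 10),
    context_hypnogram = hypnogram(rep("W", 20)))
  ei <- event_indices(rec)
  expect_true(ei$undefined)
  expect_true(is.na(ei$ari))
})
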