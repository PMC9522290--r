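test_that("truth generation is deterministic under a fixed seed", {
  tm <- truth_model(tib_hours = 2)
  for (task in c("staging", "leg_movements", "respiratory", "arousals")) {
    a <- generate_truth(tm, "r1", task, seed = 9)
    b <- generate_truth(tm, "r1", task, seed = 9)
    expect_equal(a$annotations, b$annotations)
    expect_equal(a$context_hypnogram$stages, b$context_hypnogram$stages)
    c <- generate_truth(tm, "r1", task, seed = 10)
    expect_false(identical(a$annotations, c$annotations) &&
                   identical(a$context_hypnogram$stages,
                             c$context_hypnogram$stages))
  }
})

test_that("zero event rates generate no events", {
  tm <- truth_model(tib_hours = 2,
                    event_rates = c(apnea = 0, hypopnea = 0, rera = 0,
                                    arousal = 0, desaturation = 0),
                    lm_isolated_rate = 0, lm_train_rate = 0)
  for (task in c("leg_movements", "respiratory", "arousals")) {
    tr <- generate_truth(tm, "r1", task, seed = 1)
    expect_equal(nrow(tr$annotations), 0L)
  }
})

test_that("Poisson event counts concentrate around rate x sleep time", {
  tm <- truth_model(tib_hours = 8,
                    event_rates = c(apnea = 0, hypopnea = 0, rera = 0,
                                    arousal = 10, desaturation = 0))
  err <- vapply(1:50, function(s) {
    tr <- generate_truth(tm, "r1", "arousals", seed = s)
    tst_h <- sum(tr$context_hypnogram$stages != "W") * 30 / 3600
    nrow(tr$annotations) - 10 * tst_h
  }, numeric(1))
  # mean count error over 50 runs well inside 3 * sqrt(lambda)
  expect_lt(abs(mean(err)), 3 * sqrt(10 * 8) / sqrt(50) * 3)
  expect_lt(max(abs(err)), 5 * sqrt(10 * 8))
})

test_that("the identity-limit scorer reproduces its input exactly", {
  ident <- scorer_model(stage_error_rate = 0, event_sensitivity = 1,
                        false_positive_rate = 0, boundary_jitter_sd = 0)
  tm <- truth_model(tib_hours = 2)
  tr_e <- generate_truth(tm, "r1", "leg_movements", seed = 2)
  out <- corrupt_scoring(tr_e, ident, "s01", seed = 2)
  expect_equal(out$annotations, tr_e$annotations)
  tr_s <- generate_truth(tm, "r1", "staging", seed = 2)
  out_s <- corrupt_scoring(tr_s, ident, "s01", seed = 2)
  expect_equal(out_s$context_hypnogram$stages,
               tr_s$context_hypnogram$stages)
  # zero sensitivity and no false positives empties the scoring
  blind <- scorer_model(event_sensitivity = 0, false_positive_rate = 0)
  expect_equal(nrow(corrupt_scoring(tr_e, blind, "s01",
                                    seed = 2)$annotations), 0L)
})

test_that("two identity scorers agree perfectly through the full pipeline", {
  ident <- scorer_model(stage_error_rate = 0, event_sensitivity = 1,
                        false_positive_rate = 0, boundary_jitter_sd = 0)
  tm <- truth_model(tib_hours = 2)
  tr <- generate_truth(tm, "r1", "arousals", seed = 6)
  s1 <- corrupt_scoring(tr, ident, "s01", seed = 6)
  s2 <- corrupt_scoring(tr, ident, "s02", seed = 6)
  seqs <- list(s01 = discretize_events(s1, "arousal"),
               s02 = discretize_events(s2, "arousal"))
  expect_equal(pairwise_kappa(seqs)[[1]]$kappa, 1)
})

test_that("agreement degrades with boundary jitter and false positives", {
  tm <- truth_model(tib_hours = 4)
  mean_kappa <- function(jitter, fp) {
    ks <- vapply(1:4, function(s) {
      tr <- generate_truth(tm, paste0("r", s), "arousals", seed = s)
      mdl <- scorer_model(event_sensitivity = 1,
                          false_positive_rate = fp,
                          boundary_jitter_sd = jitter)
      a <- corrupt_scoring(tr, mdl, "s01", seed = s)
      b <- corrupt_scoring(tr, mdl, "s02", seed = s)
      sa <- discretize_events(a, "arousal")
      sb <- discretize_events(b, "arousal")
      cohen_kappa(build_contingency(sa, sb))$kappa
    }, numeric(1))
    mean(ks)
  }
  expect_gt(mean_kappa(0.1, 0), mean_kappa(2.5, 0))
  expect_gt(mean_kappa(0.1, 0.2), mean_kappa(0.1, 6))
})

test_that("observed staging kappa matches the symmetric-noise closed form", {
  # two independent scorers flipping each epoch with probability e to a
  # uniformly chosen other stage: p_o = (1-e)^2 + e^2/4; the chance term
  # comes from the mixture marginal over the truth's stage distribution
  e <- 0.15
  tm <- truth_model(tib_hours = 7.3)
  mdl <- scorer_model(stage_error_rate = e)
  ks <- c(); p_truth <- NULL
  for (s in 1:3) {
    tr <- generate_truth(tm, paste0("r", s), "staging", seed = s)
    cells <- lapply(sprintf("s%02d", 1:8), function(id)
      corrupt_scoring(tr, mdl, id, seed = s))
    names(cells) <- sprintf("s%02d", 1:8)
    seqs <- lapply(cells, function(c) discretize_stages(c$context_hypnogram))
    ks <- c(ks, vapply(pairwise_kappa(seqs), `[[`, numeric(1), "kappa"))
    p <- table(factor(tr$context_hypnogram$stages, psg_stages)) /
      length(tr$context_hypnogram$stages)
    p_truth <- rbind(p_truth, as.numeric(p))
  }
  p <- colMeans(p_truth)
  m <- (1 - e) * p + e * (1 - p) / 4   # scorer marginal
  p_o <- (1 - e)^2 + e^2 / 4
  p_e <- sum(m^2)
  expected <- (p_o - p_e) / (1 - p_e)
  expect_equal(mean(ks), expected, tolerance = 0.02)
})

test_that("generated diagnostic indices stay in the configured bands", {
  tm <- truth_model(tib_hours = 6)
  ok <- vapply(1:20, function(s) {
    tr <- generate_truth(tm, "r1", "respiratory", seed = s)
    hyp_sum <- summarize_hypnogram(tr$context_hypnogram,
                                   tib = tib_seconds(tr))
    ei <- event_indices(tr, summary = hyp_sum)
    ei$ahi > 2 && ei$ahi < 16 && hyp_sum$se_pct > 55
  }, logical(1))
  expect_gte(mean(ok), 0.95)
})

test_that("a generated study has the full design and is reproducible", {
  cfg <- study_config(n_scorers = 4, n_recordings = 2,
                      tasks = c("staging", "arousals"),
                      truth = truth_model(tib_hours = 0.5))
  sim1 <- generate_study(cfg, seed = 3)
  expect_equal(length(sim1$study$cells), 4 * 2 * 2 * 2)
  expect_equal(nrow(sim1$study$gaps), 0L)
  expect_equal(nrow(sim1$study$timing), 2 * 2 * 2 * 4)
  sim2 <- generate_study(cfg, seed = 3)
  expect_equal(sim1$study$cells[[5]]$annotations,
               sim2$study$cells[[5]]$annotations)
  expect_equal(sim1$study$timing$active_minutes,
               sim2$study$timing$active_minutes)
  # written studies are byte-identical under the same master seed
  d1 <- tempfile(); d2 <- tempfile()
  write_study(sim1, d1); write_study(sim2, d2)
  f1 <- list.files(d1, recursive = TRUE)
  expect_setequal(f1, list.files(d2, recursive = TRUE))
  for (f in f1) {
    expect_identical(readBin(file.path(d1, f), "raw",
                             file.size(file.path(d1, f))),
                     readBin(file.path(d2, f), "raw",
                             file.size(file.path(d2, f))),
                     label = f)
  }
})

test_that("simulated timing recovers the configured medians and gain", {
  ids <- sprintf("s%04d", 1:5000)
  tim <- psgagree:::simulate_timing(scoring_time_reference(),
                                    "leg_movements", "r01", ids, seed = 4)
  man <- tim$active_minutes[tim$method == "manual"]
  sem <- tim$active_minutes[tim$method == "semiauto"]
  expect_equal(median(man), 44.53, tolerance = 0.05 * 44.53)
  expect_equal(median(sem), 18.50, tolerance = 0.05 * 18.50)
  expect_equal(median(man) / median(sem), 2.41, tolerance = 0.05 * 2.41)
})
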