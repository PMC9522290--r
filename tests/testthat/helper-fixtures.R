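# shared fixtures, built in code

# random event-task recording for round-trip / clipping properties
random_recording <- function(seed, task = "leg_movements", tib = 3600,
                             n_events = 30) {
  set.seed(seed)
  labels <- switch(task,
    leg_movements = c("lm-left", "lm-right"),
    respiratory = c("apnea-obstructive", "apnea-central", "hypopnea",
                    "rera", "desaturation"),
    arousals = "arousal")
  onset <- sort(round(runif(n_events, 0, tib - 30), 4))
  duration <- round(runif(n_events, 0.5, 25), 4)
  scored_recording(
    recording_id = sprintf("r%02d", seed), scorer_id = "s01", task = task,
    lights_off = 0, lights_on = tib,
    annotations = annotations(sample(labels, n_events, replace = TRUE),
                              onset, duration))
}

random_hypnogram <- function(seed, n = 40) {
  set.seed(seed)
  hypnogram(sample(psg_stages, n, replace = TRUE,
                   prob = c(0.2, 0.1, 0.4, 0.15, 0.15)))
}

# write a tabular annotation file from raw rows
write_rows <- function(rows, path = tempfile(fileext = ".csv")) {
  writeLines(c("label,onset_s,duration_s", rows), path)
  path
}

# binary label_sequence straight from a character vector
seq_from_labels <- function(labels, step = 0.5, start = 0,
                            alphabet = c("absent", "present")) {
  grid <- psgagree:::epoch_grid(start, step, length(labels), alphabet)
  psgagree:::label_sequence(grid, labels)
}

# independently coded ICC(A,1) oracle: two-way ANOVA via aov(), then the
# mean-squares formula applied from scratch
icc_a1_oracle <- function(m) {
  n <- nrow(m); k <- ncol(m)
  df <- data.frame(y = as.vector(m),
                   subj = factor(rep(seq_len(n), k)),
                   rater = factor(rep(seq_len(k), each = n)))
  tab <- summary(stats::aov(y ~ subj + rater, data = df))[[1]]
  msr <- tab["subj", "Mean Sq"]
  msc <- tab["rater", "Mean Sq"]
  mse <- tab["Residuals", "Mean Sq"]
  (msr - mse) / (msr + (k - 1) * mse + (k / n) * (msc - mse))
}

# exhaustive signed-rank oracle over all 2^n sign assignments
wilcoxon_enum_oracle <- function(d) {
  d <- d[d != 0]
  n <- length(d)
  r <- rank(abs(d))
  w <- sum(r[d > 0])
  signs <- expand.grid(rep(list(c(FALSE, TRUE)), n))
  sums <- apply(signs, 1, function(s) sum(r[as.logical(s)]))
  p_le <- mean(sums <= w + 1e-9)
  p_ge <- mean(sums >= w - 1e-9)
  min(1, 2 * min(p_le, p_ge))
}

# independently coded Levene/Brown-Forsythe (median-centered) oracle
levene_median_oracle <- function(g1, g2) {
  z1 <- abs(g1 - median(g1)); z2 <- abs(g2 - median(g2))
  z <- c(z1, z2); grp <- rep(1:2, c(length(z1), length(z2)))
  k <- 2; n <- length(z)
  zbar <- mean(z); zg <- tapply(z, grp, mean)
  num <- sum(table(grp) * (zg - zbar)^2) / (k - 1)
  den <- sum((z - zg[grp])^2) / (n - k)
  f <- num / den
  list(statistic = f, p_value = pf(f, k - 1, n - k, lower.tail = FALSE))
}
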