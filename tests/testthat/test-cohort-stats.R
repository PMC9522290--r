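test_that("median and IQR use linear interpolation", {
  expect_equal(median_iqr(c(1, 2, 3, 4, 5)),
               c(median = 3, q1 = 2, q3 = 4))
  expect_equal(median_iqr(7), c(median = 7, q1 = 7, q3 = 7))
  for (seed in 1:5) {
    set.seed(seed)
    q <- median_iqr(rnorm(37))
    expect_lte(q["q1"], q["median"]); expect_lte(q["median"], q["q3"])
  }
  expect_error(median_iqr(numeric()), "empty")
})

test_that("gain factors are ratios of median scoring times", {
  ref <- scoring_time_reference()
  g <- function(task) {
    m <- ref[ref$task == task, ]
    gain_factor(m$median_min[m$method == "manual"],
                m$median_min[m$method == "semiauto"])
  }
  expect_equal(g("leg_movements"), 2.41)
  expect_equal(g("staging"), 1.33)
  expect_equal(gain_factor(c(1, 2, 3), c(1, 2, 3)), 1)
  expect_error(gain_factor(1, 0), "zero")
})

test_that("exact Wilcoxon p equals the 2^n enumeration oracle for n <= 10", {
  set.seed(21)
  for (i in 1:12) {
    n <- sample(4:10, 1)
    man <- round(rnorm(n, 10, 3), if (i %% 2) 3 else 0)  # force some ties
    sem <- round(rnorm(n, 9, 3), if (i %% 2) 3 else 0)
    s <- paired_sample(man, sem)
    if (all(man == sem)) next
    got <- wilcoxon_paired(s)
    expect_equal(got$p_value, wilcoxon_enum_oracle(man - sem),
                 tolerance = 1e-12,
                 label = sprintf("case %d (n=%d)", i, n))
  }
})

test_that("Wilcoxon agrees with the reference implementation off the enumeration range", {
  set.seed(5)
  # untied case in the signed-rank-distribution range
  man <- rnorm(20, 10, 2); sem <- rnorm(20, 9, 2)
  got <- wilcoxon_paired(paired_sample(man, sem))
  ref <- wilcox.test(man, sem, paired = TRUE, exact = TRUE)
  expect_equal(got$p_value, ref$p.value, tolerance = 1e-12)
  # large-sample normal approximation with continuity correction
  man2 <- rnorm(60, 10, 2); sem2 <- rnorm(60, 9.5, 2)
  got2 <- wilcoxon_paired(paired_sample(man2, sem2))
  ref2 <- wilcox.test(man2, sem2, paired = TRUE, exact = FALSE,
                      correct = TRUE)
  expect_equal(got2$p_value, ref2$p.value, tolerance = 1e-10)
  expect_equal(got2$method, "normal-approx")
})

test_that("zero differences are dropped; all-zero is degenerate", {
  s <- paired_sample(c(1, 2, 3, 4), c(1, 2, 3, 4))
  r <- wilcoxon_paired(s)
  expect_true(r$degenerate)
  expect_equal(r$p_value, 1)
  expect_equal(r$statistic, 0)
  # zeros dropped before ranking
  s2 <- paired_sample(c(5, 2, 3, 9, 8, 1), c(5, 1, 5, 2, 3, 4))
  expect_equal(wilcoxon_paired(s2)$n_used, 5L)
})

test_that("paired Cohen's d is the standardized mean difference", {
  s <- paired_sample(c(2, 4, 6, 8), c(1, 2, 3, 4))  # diffs 1,2,3,4
  expect_equal(cohens_d_paired(s)$d, 2.5 / sd(c(1, 2, 3, 4)),
               tolerance = 1e-12)
  # antisymmetry
  s_sw <- paired_sample(c(1, 2, 3, 4), c(2, 4, 6, 8))
  expect_equal(cohens_d_paired(s_sw)$d, -cohens_d_paired(s)$d)
  # constant shift has zero difference variance
  shift <- paired_sample(c(3, 5, 9) + 1, c(3, 5, 9))
  r <- cohens_d_paired(shift)
  expect_true(r$degenerate)
  expect_true(is.na(r$d))
})

test_that("Brown-Forsythe matches the median-centered Levene oracle", {
  # constant group against an alternating one: within-group deviation
  # variance vanishes, so the statistic diverges
  got <- brown_forsythe(c(1, 1, 1, 1), c(0, 2, 0, 2))
  oracle <- levene_median_oracle(c(1, 1, 1, 1), c(0, 2, 0, 2))
  expect_equal(got$statistic, oracle$statistic)  # both infinite
  expect_equal(got$p_value, 0)
  set.seed(8)
  for (i in 1:5) {
    a <- rlnorm(12, 3, 0.5); b <- rlnorm(15, 2.5, 0.9)
    got <- brown_forsythe(a, b)
    oracle <- levene_median_oracle(a / mean(a), b / mean(b))
    expect_equal(got$statistic, oracle$statistic, tolerance = 1e-10)
    expect_equal(got$p_value, oracle$p_value, tolerance = 1e-10)
    # second independent route: car's Levene test on normalized values
    y <- c(a / mean(a), b / mean(b))
    g <- factor(rep(1:2, c(12, 15)))
    lev <- car::leveneTest(y, g, center = median)
    expect_equal(got$statistic, lev[1, "F value"], tolerance = 1e-10)
    expect_equal(got$p_value, lev[1, "Pr(>F)"], tolerance = 1e-10)
  }
})

test_that("mean normalization makes the variance test scale-invariant", {
  set.seed(14)
  a <- rlnorm(20, 3, 0.4); b <- rlnorm(20, 3, 0.8)
  base <- brown_forsythe(a, b)
  scaled <- brown_forsythe(a * 7.3, b)
  expect_equal(scaled$statistic, base$statistic, tolerance = 1e-10)
  # identical groups give F = 0, p = 1
  same <- brown_forsythe(a, a)
  expect_equal(same$statistic, 0)
  expect_equal(same$p_value, 1)
  expect_error(brown_forsythe(c(-1, 1), c(1, 2)), "zero group mean")
})

test_that("comparison tables assemble all statistics with significance stars", {
  set.seed(31)
  samples <- list(
    "task A" = paired_sample(rlnorm(60, log(40), 0.5),
                             rlnorm(60, log(18), 0.5), unit = "minutes"),
    "task B" = paired_sample(rlnorm(60, log(25), 0.5),
                             rlnorm(60, log(24), 0.5), unit = "minutes"))
  tab <- build_comparison_table(samples, with_gain = TRUE)
  expect_equal(nrow(tab), 2L)
  expect_equal(tab$n, c(60L, 60L))
  expect_true(tab$significant[1])
  expect_equal(tab$gain_factor[1],
               round(median(samples[["task A"]]$manual) /
                       median(samples[["task A"]]$semiauto), 2))
  expect_true(all(tab$manual_q1 <= tab$manual_median &
                    tab$manual_median <= tab$manual_q3))
  # empty input gives an empty table
  expect_equal(nrow(build_comparison_table(list())), 0L)
  # the expected-n design check names the offending row
  expect_error(build_comparison_table(samples, expected_n = 59),
               "design error in 'task A'")
})
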