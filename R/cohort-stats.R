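#' Median and interquartile range
#'
#' 25th/50th/75th percentiles with linear interpolation between order
#' statistics (quantile type 7).
#'
#' @param x Non-empty numeric vector.
#' @return Named numeric vector `(median, q1, q3)`.
#' @export
median_iqr <- function(x) {
  if (length(x) == 0L) stop("empty sample", call. = FALSE)
  q <- stats::quantile(x, c(0.5, 0.25, 0.75), names = FALSE, type = 7)
  c(median = q[1], q1 = q[2], q3 = q[3])
}

#' Scoring-time gain factor
#'
#' Ratio of the median manual scoring time to the median semi-automatic
#' scoring time, reported to two decimals.
#'
#' @param manual_times,semiauto_times Non-empty numeric vectors (minutes).
#' @param digits Rounding for the reported ratio (default 2).
#' @return Numeric gain factor.
#' @export
gain_factor <- function(manual_times, semiauto_times, digits = 2) {
  if (length(manual_times) == 0L || length(semiauto_times) == 0L) {
    stop("empty sample", call. = FALSE)
  }
  ms <- stats::median(semiauto_times)
  if (ms == 0) stop("zero semi-automatic median time", call. = FALSE)
  round(stats::median(manual_times) / ms, digits)
}

#' Paired sample container
#'
#' Matched manual/semi-automatic observations (matched by scorer, or by
#' scorer-pair x recording for kappa scores).
#'
#' @param manual,semiauto Equal-length numeric vectors, matched elementwise.
#' @param unit Measurement unit token.
#' @param matching_key Description of the matching.
#' @return Object of class `paired_sample`.
#' @export
paired_sample <- function(manual, semiauto, unit = "",
                          matching_key = "") {
  if (length(manual) != length(semiauto)) {
    stop("paired sample requires equal lengths", call. = FALSE)
  }
  structure(list(manual = as.numeric(manual),
                 semiauto = as.numeric(semiauto),
                 unit = unit, matching_key = matching_key),
            class = "paired_sample")
}

#' Paired Wilcoxon signed-rank test
#'
#' Two-sided signed-rank test on the within-pair differences. Zero
#' differences are dropped (classical Wilcoxon convention); the exact null
#' distribution is used for n <= 25 remaining pairs (full sign-assignment
#' enumeration up to n = 16 so tied ranks stay exact, the signed-rank
#' distribution otherwise), and the normal approximation with continuity
#' correction above. All differences zero yields statistic 0, p = 1,
#' flagged degenerate.
#'
#' @param s A [paired_sample()] (or anything with `$manual`, `$semiauto`).
#' @return List `(statistic, p_value, n_used, degenerate, method)`.
#' @export
wilcoxon_paired <- function(s) {
  d <- s$manual - s$semiauto
  d <- d[d != 0]
  n <- length(d)
  if (n == 0L) {
    return(list(statistic = 0, p_value = 1, n_used = 0L,
                degenerate = TRUE, method = "degenerate"))
  }
  r <- rank(abs(d))
  w <- sum(r[d > 0])
  if (n <= 16L) {
    p <- signed_rank_enum_p(r, w)
    method <- "exact-enumeration"
  } else if (n <= 25L && !anyDuplicated(r)) {
    mu <- n * (n + 1) / 4
    p <- if (w > mu) {
      2 * stats::psignrank(w - 1, n, lower.tail = FALSE)
    } else {
      2 * stats::psignrank(w, n)
    }
    p <- min(1, p)
    method <- "exact-signrank"
  } else {
    mu <- n * (n + 1) / 4
    ties <- table(r)
    sigma2 <- n * (n + 1) * (2 * n + 1) / 24 - sum(ties^3 - ties) / 48
    z <- (w - mu - sign(w - mu) * 0.5) / sqrt(sigma2)
    p <- min(1, 2 * stats::pnorm(-abs(z)))
    method <- "normal-approx"
  }
  list(statistic = w, p_value = p, n_used = n, degenerate = FALSE,
       method = method)
}

# exact two-sided p by enumerating all 2^n sign assignments of the ranks;
# doubling convention: p = min(1, 2 min(P(W <= w), P(W >= w)))
signed_rank_enum_p <- function(ranks, w) {
  n <- length(ranks)
  sums <- 0
  for (rk in ranks) sums <- c(sums, sums + rk)  # all subset sums
  p_le <- mean(sums <= w + 1e-9)
  p_ge <- mean(sums >= w - 1e-9)
  min(1, 2 * min(p_le, p_ge))
}

#' Paired Cohen's d effect size
#'
#' Standardized mean difference of the paired differences,
#' `d = mean(manual - semiauto) / sd(manual - semiauto)` (sample sd, n-1).
#' Positive d means the quantity is larger under manual scoring. Zero
#' difference variance makes d undefined (`NA`, flagged).
#'
#' @param s A [paired_sample()].
#' @return List `(d, degenerate)`.
#' @export
cohens_d_paired <- function(s) {
  d <- s$manual - s$semiauto
  if (length(d) < 2L) stop("need at least two pairs", call. = FALSE)
  sdd <- stats::sd(d)
  if (sdd == 0) return(list(d = NA_real_, degenerate = TRUE))
  list(d = mean(d) / sdd, degenerate = FALSE)
}

#' Brown-Forsythe variance comparison with mean normalization
#'
#' Each group is first divided by its own mean (removing location bias so
#' only dispersion is compared), then the Brown-Forsythe test — the Levene
#' statistic with median centering — is applied: a one-way ANOVA on the
#' absolute deviations from the group medians. Degenerate edges are
#' resolved explicitly: zero between- and within-group deviation variance
#' (e.g. identical groups after normalization) gives `F = 0, p = 1`; zero
#' within-group variance with a real between-group difference gives
#' `F = Inf, p = 0`.
#'
#' @param manual,semiauto Numeric vectors, each with >= 2 values and
#'   non-zero mean.
#' @return List `(statistic, p_value, df1, df2)`.
#' @export
brown_forsythe <- function(manual, semiauto) {
  if (length(manual) < 2L || length(semiauto) < 2L) {
    stop("need >= 2 values per group", call. = FALSE)
  }
  if (mean(manual) == 0 || mean(semiauto) == 0) {
    stop("zero group mean: mean normalization undefined", call. = FALSE)
  }
  z1 <- abs_dev_from_median(manual / mean(manual))
  z2 <- abs_dev_from_median(semiauto / mean(semiauto))
  n1 <- length(z1); n2 <- length(z2); n <- n1 + n2
  zbar <- mean(c(z1, z2))
  ss_between <- n1 * (mean(z1) - zbar)^2 + n2 * (mean(z2) - zbar)^2
  ss_within <- sum((z1 - mean(z1))^2) + sum((z2 - mean(z2))^2)
  df1 <- 1; df2 <- n - 2
  if (ss_within <= 1e-14 * max(1, ss_between)) {
    if (ss_between <= 1e-14) {
      return(list(statistic = 0, p_value = 1, df1 = df1, df2 = df2))
    }
    return(list(statistic = Inf, p_value = 0, df1 = df1, df2 = df2))
  }
  f <- (ss_between / df1) / (ss_within / df2)
  list(statistic = f, p_value = stats::pf(f, df1, df2, lower.tail = FALSE),
       df1 = df1, df2 = df2)
}

abs_dev_from_median <- function(x) abs(x - stats::median(x))

#' Build a manual vs semi-automatic comparison table
#'
#' One row per task/context: median and IQR under each method, optional
#' gain factor (for scoring times), paired Wilcoxon p-value, paired Cohen's
#' d, and a significance star at `alpha`.
#'
#' @param per_task_samples Named list of [paired_sample()] objects (names
#'   become row labels).
#' @param with_gain Compute gain factors (TRUE for scoring-time tables).
#' @param alpha Significance level (default 0.05).
#' @param expected_n Optional expected sample size; a mismatch is a design
#'   error naming the offending row.
#' @return `data.frame` of class `comparison_table`.
#' @export
build_comparison_table <- function(per_task_samples, with_gain = FALSE,
                                   alpha = 0.05, expected_n = NULL) {
  if (length(per_task_samples) == 0L) {
    return(structure(
      data.frame(label = character(), n = integer(),
                 manual_median = numeric(), manual_q1 = numeric(),
                 manual_q3 = numeric(), semiauto_median = numeric(),
                 semiauto_q1 = numeric(), semiauto_q3 = numeric(),
                 gain_factor = numeric(), p_value = numeric(),
                 effect_size = numeric(), significant = logical(),
                 stringsAsFactors = FALSE),
      class = c("comparison_table", "data.frame")))
  }
  rows <- lapply(names(per_task_samples), function(lbl) {
    s <- per_task_samples[[lbl]]
    if (!is.null(expected_n) && length(s$manual) != expected_n) {
      stop("design error in '", lbl, "': expected n = ", expected_n,
           ", got ", length(s$manual), call. = FALSE)
    }
    mq <- median_iqr(s$manual)
    sq <- median_iqr(s$semiauto)
    wt <- wilcoxon_paired(s)
    es <- cohens_d_paired(s)
    data.frame(label = lbl, n = length(s$manual),
               manual_median = mq["median"], manual_q1 = mq["q1"],
               manual_q3 = mq["q3"],
               semiauto_median = sq["median"], semiauto_q1 = sq["q1"],
               semiauto_q3 = sq["q3"],
               gain_factor = if (with_gain)
                 gain_factor(s$manual, s$semiauto) else NA_real_,
               p_value = wt$p_value, effect_size = es$d,
               significant = wt$p_value < alpha,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  class(out) <- c("comparison_table", "data.frame")
  out
}

#' Render a comparison table as aligned text
#' @param x A [build_comparison_table()] result.
#' @param ... Unused.
#' @export
format.comparison_table <- function(x, ...) {
  if (nrow(x) == 0L) return("(empty comparison table)")
  fmt_iqr <- function(m, a, b) sprintf("%.2f [%.2f, %.2f]", m, a, b)
  lines <- sprintf(
    "%-34s %-24s %-24s %6s  %-9s %8s",
    x$label,
    fmt_iqr(x$manual_median, x$manual_q1, x$manual_q3),
    fmt_iqr(x$semiauto_median, x$semiauto_q1, x$semiauto_q3),
    ifelse(is.na(x$gain_factor), "", sprintf("%.2f", x$gain_factor)),
    paste0(format_p(x$p_value), ifelse(x$significant, "*", "")),
    ifelse(is.na(x$effect_size), "", sprintf("%.4f", x$effect_size)))
  header <- sprintf("%-34s %-24s %-24s %6s  %-9s %8s",
                    "label", "manual", "semi-auto", "gain", "p", "d")
  c(header, lines)
}

format_p <- function(p) {
  ifelse(p < 1e-4, "<0.0001", sprintf("%.4f", p))
}

#' @export
print.comparison_table <- function(x, ...) {
  cat(format(x), sep = "\n")
  invisible(x)
}
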