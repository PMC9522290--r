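#' Cohen's kappa from a contingency table
#'
#' Chance-corrected agreement between two categorical raters:
#' `kappa = (p_o - p_e) / (1 - p_e)` with observed agreement
#' `p_o = sum(diag) / n` and chance agreement
#' `p_e = sum(row_i * col_i) / n^2`. When `p_e = 1` (both raters constant
#' on the same category) kappa is defined as 1 if agreement is perfect and
#' 0 otherwise. Results where either rater is constant are flagged
#' degenerate — this arises for all-absent event sequences on quiet
#' recordings (a constant rater against a mixed one yields kappa 0 from
#' the ordinary formula).
#'
#' @param t A [build_contingency()] table.
#' @param pair Optional scorer-id pair attached to the result.
#' @param context Optional context token (`tib`, `wake`, `sleep`, ...).
#' @return Object of class `kappa_result` with fields `kappa`, `p_observed`,
#'   `p_expected`, `n`, `pair`, `context`, `degenerate`.
#' @export
cohen_kappa <- function(t, pair = c(NA_character_, NA_character_),
                        context = "tib") {
  n <- sum(t$counts)
  if (n == 0) stop("empty contingency table", call. = FALSE)
  p_o <- sum(diag(t$counts)) / n
  p_e <- sum(rowSums(t$counts) * colSums(t$counts)) / n^2
  degenerate <- sum(rowSums(t$counts) > 0) == 1L ||
    sum(colSums(t$counts) > 0) == 1L
  kappa <- if (p_e >= 1 - 1e-12) {
    if (p_o >= 1 - 1e-12) 1 else 0
  } else {
    (p_o - p_e) / (1 - p_e)
  }
  structure(list(kappa = kappa, p_observed = p_o, p_expected = p_e,
                 n = n, pair = pair, context = context,
                 degenerate = degenerate),
            class = "kappa_result")
}

#' @export
print.kappa_result <- function(x, ...) {
  cat(sprintf("kappa = %.4f (p_o = %.4f, p_e = %.4f, n = %d)%s\n",
              x$kappa, x$p_observed, x$p_expected, x$n,
              if (x$degenerate) " [degenerate]" else ""))
  invisible(x)
}

#' Pairwise kappa over a panel of scorers
#'
#' Computes Cohen's kappa for every unordered scorer pair on a shared grid
#' (12 scorers give choose(12, 2) = 66 pairs). Pairs are ordered
#' lexicographically by scorer id.
#'
#' @param sequences Named list of `label_sequence` objects, one per scorer.
#' @param mask Optional logical context mask.
#' @param context Context token stored on each result.
#' @return List of `kappa_result`, length `choose(m, 2)`.
#' @export
pairwise_kappa <- function(sequences, mask = NULL, context = "tib") {
  m <- length(sequences)
  if (m < 2L) stop("need at least two scorers", call. = FALSE)
  ids <- names(sequences)
  if (is.null(ids)) stop("sequences must be named by scorer id", call. = FALSE)
  ids_sorted <- sort(ids)
  out <- vector("list", choose(m, 2))
  pos <- 0L
  for (i in seq_len(m - 1L)) {
    for (j in (i + 1L):m) {
      pos <- pos + 1L
      a <- ids_sorted[i]; b <- ids_sorted[j]
      tab <- build_contingency(sequences[[a]], sequences[[b]], mask)
      out[[pos]] <- cohen_kappa(tab, pair = c(a, b), context = context)
    }
  }
  out
}

#' Average left/right channel kappas for the leg-movement task
#'
#' Per-channel (left / right leg) kappa scores for one scorer pair are
#' averaged into a single result before downstream statistics; the attached
#' `n` is the sum of the per-channel epoch counts.
#'
#' @param left,right `kappa_result` objects for the same pair and context.
#' @return A combined `kappa_result`.
#' @export
average_channel_kappa <- function(left, right) {
  if (!identical(left$pair, right$pair) ||
      !identical(left$context, right$context)) {
    stop("channel kappas belong to different pairs or contexts",
         call. = FALSE)
  }
  structure(list(kappa = mean(c(left$kappa, right$kappa)),
                 p_observed = mean(c(left$p_observed, right$p_observed)),
                 p_expected = mean(c(left$p_expected, right$p_expected)),
                 n = left$n + right$n, pair = left$pair,
                 context = left$context,
                 degenerate = left$degenerate || right$degenerate),
            class = "kappa_result")
}

#' Intraclass correlation ICC(A,1) with confidence interval and r0 test
#'
#' Two-way, absolute-agreement, single-measures intraclass correlation
#' (McGraw & Wong case A,1) on a complete subjects x raters matrix. With
#' two-way ANOVA mean squares MSR (rows/subjects), MSC (columns/raters) and
#' MSE (error),
#' `ICC(A,1) = (MSR - MSE) / (MSR + (k-1) MSE + (k/n)(MSC - MSE))`.
#' The 95% confidence interval and the one-sided significance test of
#' `H0: ICC = r0` against `ICC > r0` use the case-A,1 F approximation with
#' Satterthwaite degrees of freedom. Setting `r0` to the agreement achieved
#' under a baseline condition (e.g. manual scoring) tests whether a second
#' condition exceeds that baseline.
#'
#' @param data Numeric matrix, subjects (recordings) in rows, raters
#'   (scorers) in columns; complete, n >= 2 subjects, k >= 2 raters.
#' @param r0 Baseline ICC under the null hypothesis, in `[0, 1)`.
#' @param conf_level Confidence level (default 0.95).
#' @return Object of class `icc_result` with fields `icc`, `ci_low`,
#'   `ci_high`, `r0`, `p_value`, `n_subjects`, `k_raters`, `mean_squares`
#'   (MSR, MSC, MSE).
#' @export
icc_a1 <- function(data, r0 = 0, conf_level = 0.95) {
  data <- as.matrix(data)
  if (anyNA(data)) stop("ICC requires a complete matrix", call. = FALSE)
  n <- nrow(data); k <- ncol(data)
  if (n < 2 || k < 2) stop("need >= 2 subjects and >= 2 raters", call. = FALSE)
  if (r0 < 0 || r0 >= 1) stop("r0 must lie in [0, 1)", call. = FALSE)
  if (diff(range(data)) == 0) {
    stop("ICC undefined: all measurements identical (no subject variance)",
         call. = FALSE)
  }
  grand <- mean(data)
  row_m <- rowMeans(data); col_m <- colMeans(data)
  ssr <- k * sum((row_m - grand)^2)
  ssc <- n * sum((col_m - grand)^2)
  sse <- sum((data - outer(row_m, rep(1, k)) -
                outer(rep(1, n), col_m) + grand)^2)
  msr <- ssr / (n - 1)
  msc <- ssc / (k - 1)
  mse <- sse / ((n - 1) * (k - 1))
  icc <- (msr - mse) / (msr + (k - 1) * mse + (k / n) * (msc - mse))

  alpha <- 1 - conf_level
  # Satterthwaite df at the point estimate, for the confidence bounds
  ci <- icc_a1_ci(icc, msr, msc, mse, n, k, alpha)
  # one-sided test of H0: ICC = r0 vs ICC > r0
  a <- k * r0 / (n * (1 - r0))
  b <- 1 + k * r0 * (n - 1) / (n * (1 - r0))
  fval <- msr / (a * msc + b * mse)
  v <- (a * msc + b * mse)^2 /
    ((a * msc)^2 / (k - 1) + (b * mse)^2 / ((n - 1) * (k - 1)))
  p <- stats::pf(fval, n - 1, v, lower.tail = FALSE)

  structure(list(icc = icc, ci_low = ci[1], ci_high = ci[2], r0 = r0,
                 p_value = p, n_subjects = n, k_raters = k,
                 mean_squares = c(MSR = msr, MSC = msc, MSE = mse),
                 f_value = fval, df1 = n - 1, df2 = v),
            class = "icc_result")
}

icc_a1_ci <- function(icc, msr, msc, mse, n, k, alpha) {
  a <- k * icc / (n * (1 - icc))
  b <- 1 + k * icc * (n - 1) / (n * (1 - icc))
  if (!is.finite(a) || !is.finite(b)) return(c(icc, icc))  # icc == 1
  v <- (a * msc + b * mse)^2 /
    ((a * msc)^2 / (k - 1) + (b * mse)^2 / ((n - 1) * (k - 1)))
  f_l <- stats::qf(1 - alpha / 2, n - 1, v)
  f_u <- stats::qf(1 - alpha / 2, v, n - 1)
  low <- n * (msr - f_l * mse) /
    (f_l * (k * msc + (k * n - k - n) * mse) + n * msr)
  high <- n * (f_u * msr - mse) /
    (k * msc + (k * n - k - n) * mse + n * f_u * msr)
  c(max(-1, min(low, icc)), min(1, max(high, icc)))
}

#' @export
print.icc_result <- function(x, ...) {
  cat(sprintf(
    "ICC(A,1) = %.4f, 95%% CI (%.4f, %.4f), H0: ICC = %.2f, p = %.4g\n",
    x$icc, x$ci_low, x$ci_high, x$r0, x$p_value))
  invisible(x)
}

#' Tabulate kappa results
#'
#' @param results List of `kappa_result` objects.
#' @return `data.frame` with one row per result (scorer_a, scorer_b,
#'   context, kappa, p_observed, p_expected, n, degenerate).
#' @export
kappa_table <- function(results) {
  do.call(rbind, lapply(results, function(r) {
    data.frame(scorer_a = r$pair[1], scorer_b = r$pair[2],
               context = r$context, kappa = r$kappa,
               p_observed = r$p_observed, p_expected = r$p_expected,
               n = r$n, degenerate = r$degenerate,
               stringsAsFactors = FALSE)
  }))
}
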