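#' Mini-epoch grids and label sequences
#'
#' Agreement analysis discretizes the time in bed into non-overlapping
#' analysis epochs: 30 s five-class epochs for sleep staging, 0.5 s binary
#' mini-epochs for the event tasks. A trailing partial epoch (TIB not
#' divisible by the step) is dropped; all scorers share the TIB so no pair
#' is misaligned.
#'
#' @param start Grid origin in seconds (= lights-off).
#' @param step Epoch duration in seconds.
#' @param n_epochs Number of epochs.
#' @param alphabet Ordered label set (the five stages, or absent/present).
#' @return Object of class `epoch_grid`.
#' @export
epoch_grid <- function(start, step, n_epochs, alphabet) {
  stopifnot(step > 0, n_epochs >= 0)
  structure(list(start = as.numeric(start), step = as.numeric(step),
                 n_epochs = as.integer(n_epochs),
                 alphabet = as.character(alphabet)),
            class = "epoch_grid")
}

same_grid <- function(a, b) {
  isTRUE(all.equal(a$start, b$start)) && isTRUE(all.equal(a$step, b$step)) &&
    a$n_epochs == b$n_epochs && identical(a$alphabet, b$alphabet)
}

label_sequence <- function(grid, labels) {
  if (length(labels) != grid$n_epochs) {
    stop("label sequence length ", length(labels),
         " does not match grid (", grid$n_epochs, " epochs)", call. = FALSE)
  }
  bad <- setdiff(unique(labels), grid$alphabet)
  if (length(bad) > 0L) {
    stop("labels outside the grid alphabet: ", paste(bad, collapse = ", "),
         call. = FALSE)
  }
  structure(list(grid = grid, labels = labels), class = "label_sequence")
}

#' @export
print.label_sequence <- function(x, ...) {
  cat(sprintf("<label_sequence> %d epochs x %gs, alphabet {%s}\n",
              x$grid$n_epochs, x$grid$step,
              paste(x$grid$alphabet, collapse = ", ")))
  invisible(x)
}

#' Discretize event annotations onto a binary mini-epoch grid
#'
#' Each mini-epoch of the TIB takes value `present` iff it has a
#' positive-length intersection with at least one event whose label is in
#' `labels_of_interest` (half-open intervals: an event ending exactly at an
#' epoch's start does not mark it).
#'
#' @param rec A [scored_recording()].
#' @param labels_of_interest Character vector of canonical event labels.
#' @param step Mini-epoch duration in seconds (default 0.5).
#' @return A binary `label_sequence` over `{absent, present}`.
#' @export
discretize_events <- function(rec, labels_of_interest, step = 0.5) {
  tib <- tib_seconds(rec)
  n <- floor(tib / step)
  if (n < 1L) stop("empty TIB: no analysis epochs", call. = FALSE)
  grid <- epoch_grid(rec$lights_off, step, n, c("absent", "present"))
  present <- logical(n)
  ev <- rec$annotations[rec$annotations$label %in% labels_of_interest, ,
                        drop = FALSE]
  if (nrow(ev) > 0L) {
    rel_on <- ev$onset - rec$lights_off
    rel_end <- rel_on + ev$duration
    lo <- pmax(floor(rel_on / step), 0)
    hi <- pmin(ceiling(rel_end / step) - 1, n - 1)
    for (i in seq_len(nrow(ev))) {
      if (lo[i] <= hi[i]) present[(lo[i]:hi[i]) + 1L] <- TRUE
    }
  }
  label_sequence(grid, ifelse(present, "present", "absent"))
}

#' Discretize a hypnogram onto its 30 s staging grid
#'
#' @param h A [hypnogram()].
#' @return A five-class `label_sequence` anchored at lights-off.
#' @export
discretize_stages <- function(h) {
  if (length(h$stages) == 0L) stop("empty hypnogram", call. = FALSE)
  grid <- epoch_grid(h$lights_off, h$epoch_duration, length(h$stages),
                     psg_stages)
  label_sequence(grid, h$stages)
}

#' Wake/sleep context mask on a mini-epoch grid
#'
#' Marks each mini-epoch by the stage of its containing 30 s hypnogram
#' epoch: `wake` selects W epochs, `sleep` selects non-W epochs, `tib`
#' selects everything. Non-staging tasks use the shared pre-filled clinical
#' hypnogram so the mask is identical for every scorer.
#'
#' @param h A [hypnogram()].
#' @param context `"tib"`, `"wake"` or `"sleep"`.
#' @param step Mini-epoch duration in seconds.
#' @param n_epochs Grid length; defaults to the hypnogram's full span.
#' @return Logical vector of length `n_epochs`.
#' @export
context_mask <- function(h, context = c("tib", "wake", "sleep"), step = 0.5,
                         n_epochs = floor(length(h$stages) *
                                            h$epoch_duration / step)) {
  context <- match.arg(context)
  if (n_epochs * step > length(h$stages) * h$epoch_duration + 1e-9) {
    stop("analysis grid extends beyond hypnogram coverage", call. = FALSE)
  }
  if (context == "tib") return(rep(TRUE, n_epochs))
  # stage of the 30 s epoch containing each mini-epoch midpoint
  mid <- (seq_len(n_epochs) - 0.5) * step
  idx <- pmin(floor(mid / h$epoch_duration) + 1L, length(h$stages))
  wake <- h$stages[idx] == "W"
  if (context == "wake") wake else !wake
}

#' Build a rater-pair contingency table
#'
#' Counts mini-epochs by the joint labels of two scorers on a shared grid:
#' `counts[i, j]` is the number of (masked) epochs where scorer A produced
#' `alphabet[i]` and scorer B `alphabet[j]`.
#'
#' @param a,b `label_sequence` objects on the same grid.
#' @param mask Optional logical vector restricting the compared epochs.
#' @return Object of class `contingency_table` with fields `alphabet` and
#'   `counts` (k x k integer matrix, rows = A, columns = B).
#' @export
build_contingency <- function(a, b, mask = NULL) {
  if (!same_grid(a$grid, b$grid)) {
    stop("label sequences are on different grids", call. = FALSE)
  }
  ai <- match(a$labels, a$grid$alphabet)
  bi <- match(b$labels, b$grid$alphabet)
  if (!is.null(mask)) {
    if (length(mask) != a$grid$n_epochs) {
      stop("mask length does not match grid", call. = FALSE)
    }
    ai <- ai[mask]; bi <- bi[mask]
  }
  k <- length(a$grid$alphabet)
  counts <- matrix(tabulate((bi - 1L) * k + ai, nbins = k * k), nrow = k,
                   dimnames = list(A = a$grid$alphabet, B = a$grid$alphabet))
  structure(list(alphabet = a$grid$alphabet, counts = counts),
            class = "contingency_table")
}

#' @export
print.contingency_table <- function(x, ...) {
  print(x$counts)
  invisible(x)
}

#' Export a label sequence as a debug CSV
#' @param x A `label_sequence`.
#' @param path Output path.
#' @export
write_label_sequence <- function(x, path) {
  utils::write.csv(
    data.frame(epoch_index = seq_len(x$grid$n_epochs) - 1L,
               label = x$labels),
    path, row.names = FALSE, quote = FALSE)
  invisible(path)
}
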