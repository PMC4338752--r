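#' Extract event-locked epochs
#'
#' Cuts fixed-length windows from a (preprocessed) recording around event
#' onsets. Windows are half-open, `[onset - pre_ms, onset + post_ms)`, and
#' the default 350 + 350 ms gives the 700 ms phoneme-locked analysis
#' window. Windows extending past either recording edge are dropped (never
#' padded) and the dropped count is recorded. Adjacent events closer than
#' the window length yield overlapping epochs; all are kept.
#'
#' @param rec An `ecog_recording` (typically of log gamma power).
#' @param onsets Event onset times in seconds.
#' @param pre_ms,post_ms Window extent before/after the onset, ms.
#' @return An `ecog_epochs` object: `samples` (epochs x channels x samples
#'   array), `fs`, `pre_ms`, `post_ms`, `onsets` (those kept), `kept`
#'   (indices into the input onsets) and `dropped` (count).
#' @export
extract_epochs <- function(rec, onsets, pre_ms = 350, post_ms = 350) {
  stopifnot(inherits(rec, "ecog_recording"))
  fs <- rec$fs
  n_pre <- round(pre_ms / 1000 * fs)
  n_post <- round(post_ms / 1000 * fs)
  n_win <- n_pre + n_post
  n_samp <- ncol(rec$data)
  starts <- round(onsets * fs) - n_pre + 1L # 1-based, half-open right edge
  ok <- starts >= 1L & (starts + n_win - 1L) <= n_samp
  dropped <- sum(!ok)
  if (dropped > 0) {
    message(dropped, " epoch(s) dropped at recording edges")
  }
  keep <- which(ok)
  arr <- array(NA_real_, dim = c(length(keep), nrow(rec$data), n_win))
  for (i in seq_along(keep)) {
    s <- starts[keep[i]]
    arr[i, , ] <- rec$data[, s:(s + n_win - 1L)]
  }
  structure(
    list(
      samples = arr, fs = fs, pre_ms = pre_ms, post_ms = post_ms,
      onsets = onsets[keep], kept = keep, dropped = dropped
    ),
    class = "ecog_epochs"
  )
}

#' @export
print.ecog_epochs <- function(x, ...) {
  cat(sprintf(
    "<ecog_epochs> %d epochs x %d channels x %d samples (%d + %d ms @ %g Hz), %d dropped\n",
    dim(x$samples)[1], dim(x$samples)[2], dim(x$samples)[3],
    x$pre_ms, x$post_ms, x$fs, x$dropped
  ))
  invisible(x)
}

#' Bin epoch power into overlapping time windows
#'
#' Averages per-sample log gamma power within sliding bins across each
#' epoch. With the 700 ms window, 50 ms bins stepped by 25 ms (25 ms
#' overlap) give the 27 features per electrode used by the spatial
#' analysis; stepping by 10 ms (40 ms overlap) gives the 66 bins used by
#' the temporal analysis. Bin centers are reported at the bin's temporal
#' midpoint relative to the event onset.
#'
#' @param epochs An `ecog_epochs` object from [extract_epochs()].
#' @param bin_ms Bin length, ms.
#' @param step_ms Step between successive bin starts, ms (overlap =
#'   `bin_ms - step_ms`).
#' @param labels Optional per-epoch factor with levels `-`, `+`.
#' @return An `epoch_set`: `power` (epochs x channels x bins array),
#'   `labels`, `bin_centers` (ms relative to onset), `window`
#'   (`c(pre_ms, post_ms)`), `bin_ms`, `step_ms`.
#' @export
bin_power <- function(epochs, bin_ms = 50, step_ms = 25, labels = NULL) {
  stopifnot(inherits(epochs, "ecog_epochs"))
  fs <- epochs$fs
  win_ms <- epochs$pre_ms + epochs$post_ms
  if (bin_ms > win_ms) stop("bin_ms longer than the epoch window")
  n_bin <- round(bin_ms / 1000 * fs)
  n_step <- round(step_ms / 1000 * fs)
  if (n_step < 1 || abs(n_step - step_ms / 1000 * fs) > 1e-9) {
    stop("step_ms must map to a whole number of samples at fs = ", fs)
  }
  n_win <- dim(epochs$samples)[3]
  n_bins <- (n_win - n_bin) %/% n_step + 1L
  starts <- (seq_len(n_bins) - 1L) * n_step
  centers <- -epochs$pre_ms + starts / fs * 1000 + bin_ms / 2
  pw <- array(NA_real_, dim = c(dim(epochs$samples)[1], dim(epochs$samples)[2], n_bins))
  for (b in seq_len(n_bins)) {
    idx <- (starts[b] + 1L):(starts[b] + n_bin)
    pw[, , b] <- rowMeans(epochs$samples[, , idx, drop = FALSE], dims = 2)
  }
  if (!is.null(labels)) {
    labels <- factor(labels, levels = c("-", "+"))
    if (length(labels) != dim(pw)[1]) stop("labels must have one entry per epoch")
  }
  structure(
    list(
      power = pw, labels = labels, bin_centers = centers,
      window = c(pre_ms = epochs$pre_ms, post_ms = epochs$post_ms),
      bin_ms = bin_ms, step_ms = step_ms
    ),
    class = "epoch_set"
  )
}

#' @export
print.epoch_set <- function(x, ...) {
  cat(sprintf(
    "<epoch_set> %d epochs x %d channels x %d bins (%g ms bins, %g ms step)\n",
    dim(x$power)[1], dim(x$power)[2], dim(x$power)[3], x$bin_ms, x$step_ms
  ))
  if (!is.null(x$labels)) {
    cat("  labels:", sum(x$labels == "+"), "+ /", sum(x$labels == "-"), "-\n")
  }
  invisible(x)
}

#' Number of time bins for a window/bin/step combination
#'
#' `floor((window - bin) / step) + 1`; e.g. a 700 ms window with 50 ms bins
#' stepped 25 ms gives 27, stepped 10 ms gives 66.
#'
#' @param window_ms Epoch window length, ms.
#' @param bin_ms Bin length, ms.
#' @param step_ms Step, ms.
#' @return Integer bin count.
#' @export
n_time_bins <- function(window_ms = 700, bin_ms = 50, step_ms = 25) {
  as.integer((window_ms - bin_ms) %/% step_ms + 1L)
}
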