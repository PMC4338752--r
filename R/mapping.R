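#' Apply the screening rule to a table of AUC values
#'
#' Subject inclusion is decided by the speech-vs-silence cross-validated
#' AUC exceeding a threshold (default 0.8; chance is 0.5).
#'
#' @param auc Named or unnamed numeric vector of per-subject AUCs.
#' @param subjects Subject identifiers (defaults to names of `auc` or
#'   letters).
#' @param threshold Inclusion threshold (strict `>`).
#' @return Tibble with columns `subject`, `auc`, `passed`.
#' @export
#' @examples
#' screening_from_auc(c(A = 0.57, B = 0.81, C = 0.51, D = 0.68,
#'                      E = 0.91, F = 0.87, G = 0.91))
screening_from_auc <- function(auc, subjects = NULL, threshold = 0.8) {
  if (is.null(subjects)) {
    subjects <- if (!is.null(names(auc))) names(auc) else LETTERS[seq_along(auc)]
  }
  tibble::tibble(subject = subjects, auc = unname(auc), passed = auc > threshold)
}

# candidate non-overlapping 700 ms silence-window centers inside the gaps
# between consecutive words (and before the first / after the last word)
silence_window_centers <- function(words, duration_s, window_s = 0.7,
                                   margin_s = 0.05) {
  gaps_lo <- c(0, words$offset)
  gaps_hi <- c(words$onset, duration_s)
  centers <- numeric(0)
  for (i in seq_along(gaps_lo)) {
    lo <- gaps_lo[i] + margin_s
    hi <- gaps_hi[i] - margin_s
    if (hi - lo >= window_s) {
      k <- floor((hi - lo) / window_s)
      centers <- c(centers, lo + window_s / 2 + (seq_len(k) - 1) * window_s)
    }
  }
  centers
}

#' Speech-vs-silence subject screening
#'
#' Classifies word-locked vs. silence 700 ms epochs to decide whether a
#' recording carries enough task-related signal for the feature analyses.
#' Word epochs are centered on word onsets; silence epochs are drawn
#' (seeded, without replacement) from non-overlapping 700 ms windows in
#' the pauses between words. Classes are balanced by subsampling the
#' larger one. All electrodes' 27 time bins are pooled into one feature
#' matrix, mRMR selects `k_select` features per training fold, and the
#' shrinkage-LDA 5-fold CV AUC is compared to the threshold.
#'
#' @param rec A raw `ecog_recording`.
#' @param words Word-boundary tibble (`word`, `onset`, `offset`).
#' @param k_select mRMR features (default 50).
#' @param threshold Inclusion threshold on the CV AUC (default 0.8).
#' @param n_folds CV folds.
#' @param seed Seed for silence placement and fold assignment.
#' @param subject Optional subject identifier carried in the result.
#' @return A `screening_result`: `auc`, `passed`, `n_speech`, `n_silence`,
#'   `threshold`, plus the underlying `rlda_cv` fit.
#' @export
screen_subject <- function(rec, words, k_select = 50, threshold = 0.8,
                           n_folds = 5, seed = 1, subject = NA_character_) {
  stopifnot(inherits(rec, "ecog_recording"))
  if (nrow(words) < 10) stop("need at least 10 words for screening")
  duration_s <- ncol(rec$data) / rec$fs
  centers <- silence_window_centers(words, duration_s)
  if (length(centers) < 10) {
    stop("insufficient silence: only ", length(centers),
         " non-overlapping 700 ms silence window(s) available")
  }
  prep <- preprocess_recording(rec)
  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old), add = TRUE)
  set.seed(seed)
  n_use <- min(nrow(words), length(centers))
  word_onsets <- sort(sample(words$onset, n_use))
  sil_centers <- sort(sample(centers, n_use))
  ep_speech <- bin_power(extract_epochs(prep, word_onsets))
  ep_sil <- bin_power(extract_epochs(prep, sil_centers))
  flatten <- function(es) {
    d <- dim(es$power)
    matrix(es$power, d[1], d[2] * d[3])
  }
  X <- rbind(flatten(ep_speech), flatten(ep_sil))
  y <- factor(rep(c("+", "-"), c(dim(ep_speech$power)[1], dim(ep_sil$power)[1])),
              levels = c("-", "+"))
  cv <- cross_validate(X, y, k_select = k_select, n_folds = n_folds, seed = seed)
  structure(
    list(
      subject = subject, auc = cv$auc_mean, passed = cv$auc_mean > threshold,
      threshold = threshold,
      n_speech = sum(y == "+"), n_silence = sum(y == "-"), cv = cv
    ),
    class = "screening_result"
  )
}

#' @export
print.screening_result <- function(x, ...) {
  cat(sprintf(
    "<screening_result> speech-vs-silence CV AUC = %.3f (threshold %.2f): %s\n",
    x$auc, x$threshold, if (x$passed) "PASSED" else "not passed"
  ))
  invisible(x)
}

#' Build phoneme-locked binned epochs from a preprocessed recording
#'
#' Extracts 700 ms epochs at every phoneme onset of the alignment table,
#' bins the log gamma power, and carries the alignment rows of the kept
#' epochs so per-dimension labels can be attached later. Epochs that run
#' past the recording edges are dropped and counted.
#'
#' @param prep A preprocessed `ecog_recording` (log gamma power, see
#'   [preprocess_recording()]).
#' @param alignments Alignment tibble.
#' @param bin_ms,step_ms Binning parameters: 50/25 for the spatial
#'   analysis (27 bins), 50/10 for the temporal analysis (66 bins).
#' @param pre_ms,post_ms Epoch window, ms.
#' @return An `epoch_set` whose `"alignments"` attribute holds the kept
#'   alignment rows.
#' @export
phoneme_epochs <- function(prep, alignments, bin_ms = 50, step_ms = 25,
                           pre_ms = 350, post_ms = 350) {
  ep <- extract_epochs(prep, alignments$onset, pre_ms = pre_ms, post_ms = post_ms)
  es <- bin_power(ep, bin_ms = bin_ms, step_ms = step_ms)
  attr(es, "alignments") <- alignments[ep$kept, , drop = FALSE]
  es
}

epoch_labels <- function(es, dimension, feature_table = build_feature_table()) {
  al <- attr(es, "alignments")
  if (is.null(al)) stop("epoch set carries no alignment rows; use phoneme_epochs()")
  label_for_feature(al, feature_table, dimension)$label
}

#' Spatial topography analysis
#'
#' Per-electrode discrimination of one segmental-feature contrast ("+" vs.
#' "-" along `dimension`) from the 27 binned gamma-power features of each
#' phoneme-locked epoch: mRMR selects `k_select` (default 10) time bins
#' per training fold, shrinkage-LDA is cross-validated, and the mean
#' test-fold AUC is converted to a Hanley-McNeil p-value,
#' Benjamini-Hochberg adjusted over the multiplicity family `m` (default:
#' the electrodes tested; pass subjects x electrodes when pooling), and
#' thresholded into an activation index. Place contrasts are run once per
#' place feature (labial/coronal/dorsal, one-vs-rest); manner, voicing and
#' the phonological class are single binary contrasts.
#'
#' @param es An `epoch_set` from [phoneme_epochs()] (50/25 ms binning).
#' @param dimension One of [feature_dimensions].
#' @param feature_table Feature table.
#' @param k_select mRMR features per electrode (default 10).
#' @param n_folds CV folds.
#' @param seed Fold-assignment seed (shared across electrodes).
#' @param m Multiplicity family size (default: number of electrodes).
#' @param ai_threshold Activation-index threshold on the adjusted p.
#' @param coords Optional electrode coordinates (`channel`, `x`, `y`).
#' @param subject Optional subject identifier column.
#' @return An `activation_map` tibble: `subject`, `electrode`, `x`, `y`,
#'   `dimension`, `auc`, `se`, `p`, `p_adj`, `ai`, `significant`.
#' @export
spatial_analysis <- function(es, dimension, feature_table = build_feature_table(),
                             k_select = 10, n_folds = 5, seed = 1, m = NULL,
                             ai_threshold = 0.01, coords = NULL,
                             subject = NA_character_) {
  stopifnot(inherits(es, "epoch_set"))
  y <- epoch_labels(es, dimension, feature_table)
  if (length(unique(y)) < 2) {
    stop("single-class labels for dimension '", dimension, "'")
  }
  n_elec <- dim(es$power)[2]
  auc <- vapply(seq_len(n_elec), function(e) {
    X <- es$power[, e, ]
    cross_validate(X, y, k_select = k_select, n_folds = n_folds,
                   seed = seed)$auc_mean
  }, 0)
  stats_tab <- auc_significance(
    auc, n_pos = sum(y == "+"), n_neg = sum(y == "-"),
    m = if (is.null(m)) n_elec else m, ai_threshold = ai_threshold
  )
  out <- tibble::tibble(
    subject = subject, electrode = seq_len(n_elec),
    dimension = dimension
  )
  if (!is.null(coords)) {
    out$x <- coords$x[match(out$electrode, coords$channel)]
    out$y <- coords$y[match(out$electrode, coords$channel)]
  } else {
    out$x <- NA_real_
    out$y <- NA_real_
  }
  out <- dplyr::bind_cols(out, stats_tab)
  out$significant <- out$ai > 0
  class(out) <- c("activation_map", class(out))
  attr(out, "n_pos") <- sum(y == "+")
  attr(out, "n_neg") <- sum(y == "-")
  out
}

# strict local maxima of a series after 3-bin moving-average smoothing,
# with a minimum topographic prominence
local_maxima <- function(ai, centers, smooth_bins = 3, min_prominence = 0.5) {
  n <- length(ai)
  if (n < 3) return(numeric(0))
  sm <- stats::filter(ai, rep(1 / smooth_bins, smooth_bins), sides = 2)
  sm[is.na(sm)] <- ai[is.na(sm)]
  sm <- as.numeric(sm)
  peaks <- which(diff(sign(diff(sm))) == -2) + 1L
  keep <- vapply(peaks, function(i) {
    h <- sm[i]
    left <- sm[seq_len(i - 1)]
    right <- sm[(i + 1):n]
    higher_l <- which(left >= h)
    higher_r <- which(right >= h)
    valley_l <- if (length(higher_l)) min(left[(max(higher_l) + 1):(i - 1)]) else min(left)
    valley_r <- if (length(higher_r)) min(right[seq_len(min(higher_r) - 1)]) else min(right)
    h - max(valley_l, valley_r) >= min_prominence
  }, logical(1))
  centers[peaks[keep]]
}

#' Temporal dynamics analysis
#'
#' Restricted to electrodes found significant by [spatial_analysis()],
#' discriminates the contrast from one time bin at a time: per (electrode,
#' bin of 66 at 50/10 ms binning) a single-feature LDA is cross-validated
#' (no feature selection or regularization is needed in one dimension),
#' the AUC is converted to a p-value, BH-adjusted over the family
#' `m` (default: significant electrodes x bins; pass subjects x bins x
#' electrodes when pooling) and mapped to an activation index. The profile
#' is the mean AI across electrodes per latency bin; its peak and strict
#' local maxima (3-bin moving average, prominence >= 0.5 AI units) are
#' reported at the bin-center resolution.
#'
#' @param es An `epoch_set` from [phoneme_epochs()] with 50/10 ms binning.
#' @param dimension One of [feature_dimensions].
#' @param electrodes Significant electrodes from the spatial analysis.
#' @param feature_table Feature table.
#' @param n_folds CV folds.
#' @param seed Fold-assignment seed.
#' @param m Multiplicity family size (default `length(electrodes) * bins`).
#' @param ai_threshold Activation-index threshold.
#' @return A `temporal_profile`: `profile` tibble (`latency_ms`, `ai`),
#'   `by_electrode` tibble, `peak_ai`, `peak_latency_ms`, `local_maxima`,
#'   `dimension`.
#' @export
temporal_analysis <- function(es, dimension, electrodes,
                              feature_table = build_feature_table(),
                              n_folds = 5, seed = 1, m = NULL,
                              ai_threshold = 0.01) {
  stopifnot(inherits(es, "epoch_set"))
  if (length(electrodes) < 1) stop("no significant electrodes to analyze")
  y <- epoch_labels(es, dimension, feature_table)
  n_bins <- dim(es$power)[3]
  grid <- tidyr::expand_grid(electrode = electrodes, bin = seq_len(n_bins))
  auc <- vapply(seq_len(nrow(grid)), function(i) {
    X <- matrix(es$power[, grid$electrode[i], grid$bin[i]], ncol = 1)
    cross_validate(X, y, k_select = NULL, n_folds = n_folds,
                   seed = seed)$auc_mean
  }, 0)
  stats_tab <- auc_significance(
    auc, n_pos = sum(y == "+"), n_neg = sum(y == "-"),
    m = if (is.null(m)) nrow(grid) else m, ai_threshold = ai_threshold
  )
  by_electrode <- dplyr::bind_cols(
    grid,
    tibble::tibble(latency_ms = es$bin_centers[grid$bin]),
    stats_tab
  )
  profile <- by_electrode |>
    dplyr::group_by(.data$bin, .data$latency_ms) |>
    dplyr::summarise(ai = mean(.data$ai), .groups = "drop") |>
    dplyr::arrange(.data$latency_ms)
  peak_idx <- which.max(profile$ai)
  structure(
    list(
      profile = profile[, c("latency_ms", "ai")],
      by_electrode = by_electrode,
      peak_ai = profile$ai[peak_idx],
      peak_latency_ms = profile$latency_ms[peak_idx],
      local_maxima = local_maxima(profile$ai, profile$latency_ms),
      dimension = dimension,
      electrodes = electrodes
    ),
    class = "temporal_profile"
  )
}

#' @export
print.temporal_profile <- function(x, ...) {
  cat(sprintf(
    "<temporal_profile> '%s', %d electrodes: peak AI %.2f at %+g ms\n",
    x$dimension, length(x$electrodes), x$peak_ai, x$peak_latency_ms
  ))
  if (length(x$local_maxima)) {
    cat("  local maxima at:", paste(sprintf("%+g", x$local_maxima), collapse = ", "), "ms\n")
  }
  invisible(x)
}

#' Pool activation maps across subjects
#'
#' Stacks per-subject activation maps (which must share a coordinate
#' frame) into one map for rendering, and tallies significant electrodes
#' per feature dimension.
#'
#' @param maps A list of `activation_map` tibbles (or a single one).
#' @return A `pooled_activation_map` tibble (the stacked rows) whose
#'   `"counts"` attribute is a tibble of significant-electrode counts per
#'   dimension.
#' @export
accumulate_across_subjects <- function(maps) {
  if (inherits(maps, "activation_map")) maps <- list(maps)
  pooled <- dplyr::bind_rows(maps)
  counts <- pooled |>
    dplyr::group_by(.data$dimension) |>
    dplyr::summarise(n_significant = sum(.data$significant), .groups = "drop")
  class(pooled) <- c("pooled_activation_map", setdiff(class(pooled), "activation_map"))
  attr(pooled, "counts") <- counts
  pooled
}
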