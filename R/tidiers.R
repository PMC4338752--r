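#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' Tidy a cross-validation fit
#'
#' @param x An `rlda_cv` object.
#' @param ... Unused.
#' @return One row per fold: `fold`, `auc`, `n_test`, `n_selected`.
#' @method tidy rlda_cv
#' @export
tidy.rlda_cv <- function(x, ...) {
  tibble::tibble(
    fold = seq_len(x$n_folds),
    auc = x$fold_auc,
    n_test = as.integer(table(factor(x$fold_assignment, levels = seq_len(x$n_folds)))),
    n_selected = lengths(x$selected)
  )
}

#' @rdname tidy.rlda_cv
#' @method glance rlda_cv
#' @export
glance.rlda_cv <- function(x, ...) {
  se <- hanley_mcneil_se(x$auc_mean, x$n_pos, x$n_neg)
  tibble::tibble(
    auc_mean = x$auc_mean,
    se = se,
    p = auc_pvalue(x$auc_mean, se),
    n_pos = x$n_pos, n_neg = x$n_neg,
    n_folds = x$n_folds, k_select = x$k_select
  )
}

#' Tidy a temporal profile
#'
#' @param x A `temporal_profile`.
#' @param ... Unused.
#' @return The latency/AI profile tibble (`latency_ms`, `ai`).
#' @method tidy temporal_profile
#' @export
tidy.temporal_profile <- function(x, ...) x$profile

#' @rdname tidy.temporal_profile
#' @method glance temporal_profile
#' @export
glance.temporal_profile <- function(x, ...) {
  tibble::tibble(
    dimension = x$dimension,
    peak_ai = x$peak_ai,
    peak_latency_ms = x$peak_latency_ms,
    n_local_maxima = length(x$local_maxima),
    n_electrodes = length(x$electrodes)
  )
}

#' Tidy a screening result
#'
#' @param x A `screening_result`.
#' @param ... Unused.
#' @return One-row tibble: `subject`, `auc`, `passed`, `n_speech`,
#'   `n_silence`.
#' @method tidy screening_result
#' @export
tidy.screening_result <- function(x, ...) {
  tibble::tibble(
    subject = x$subject, auc = x$auc, passed = x$passed,
    n_speech = x$n_speech, n_silence = x$n_silence
  )
}
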