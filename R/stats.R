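#' ROC area under the curve
#'
#' Computed as the normalized Mann-Whitney U statistic: the fraction of
#' (positive, negative) score pairs ranked correctly, counting ties as
#' one half. The "+" level of `labels` is the positive class; invariant to
#' any strictly monotone transform of the scores.
#'
#' @param scores Numeric decision values (higher = more "+").
#' @param labels Factor or vector with two classes; the `+` level (or
#'   `TRUE`) is positive.
#' @return AUC in `[0, 1]`.
#' @export
roc_auc <- function(scores, labels) {
  pos <- labels == "+" | labels == TRUE
  n_pos <- sum(pos)
  n_neg <- sum(!pos)
  if (n_pos == 0 || n_neg == 0) stop("both classes must be present")
  r <- rank(scores) # average ranks handle ties as 1/2
  (sum(r[pos]) - n_pos * (n_pos + 1) / 2) / (n_pos * n_neg)
}

#' Hanley-McNeil standard error of an AUC
#'
#' Closed-form standard error of a trapezoidal AUC `A` given the class
#' sizes, using the exponential-distribution approximation
#' `Q1 = A/(2-A)`, `Q2 = 2A^2/(1+A)`:
#' `se = sqrt((A(1-A) + (n_pos-1)(Q1-A^2) + (n_neg-1)(Q2-A^2)) /
#' (n_pos n_neg))`.
#'
#' @param auc AUC value in `[0, 1]`.
#' @param n_pos,n_neg Positive/negative class sizes (>= 1).
#' @return Standard error (0 when `auc` is exactly 1).
#' @export
hanley_mcneil_se <- function(auc, n_pos, n_neg) {
  stopifnot(n_pos >= 1, n_neg >= 1, auc >= 0, auc <= 1)
  q1 <- auc / (2 - auc)
  q2 <- 2 * auc^2 / (1 + auc)
  v <- (auc * (1 - auc) + (n_pos - 1) * (q1 - auc^2) +
          (n_neg - 1) * (q2 - auc^2)) / (n_pos * n_neg)
  sqrt(pmax(v, 0))
}

#' P-value for an AUC against chance
#'
#' Normal-approximation test of `AUC = 0.5` using the Hanley-McNeil
#' standard error. One-sided by default (above-chance discrimination is
#' the hypothesis of interest); an AUC at or below 0.5 yields `p >= 0.5`.
#'
#' @param auc Observed AUC.
#' @param se Its standard error (e.g. [hanley_mcneil_se()]).
#' @param alternative `"greater"` (default) or `"two.sided"`.
#' @return P-value.
#' @export
auc_pvalue <- function(auc, se, alternative = c("greater", "two.sided")) {
  alternative <- match.arg(alternative)
  z <- ifelse(se > 0, (auc - 0.5) / se,
              ifelse(auc > 0.5, Inf, ifelse(auc < 0.5, -Inf, 0)))
  p <- stats::pnorm(z, lower.tail = FALSE)
  if (alternative == "two.sided") p <- pmin(1, 2 * pmin(p, 1 - p))
  p
}

#' Benjamini-Hochberg FDR adjustment
#'
#' Step-up adjusted p-values, optionally against a multiplicity family
#' larger than the vector supplied (e.g. subjects x electrodes pooled
#' across analyses run separately).
#'
#' @param pvals P-values in `[0, 1]`.
#' @param m Family size (default `length(pvals)`).
#' @return Adjusted p-values, monotone and clipped at 1.
#' @export
fdr_adjust <- function(pvals, m = length(pvals)) {
  stopifnot(all(pvals >= 0 & pvals <= 1), m >= length(pvals))
  stats::p.adjust(pvals, method = "BH", n = m)
}

#' Activation index
#'
#' Thresholded log-significance: `-ln(p)` when `p < threshold`
#' (strictly), else 0. Applied to FDR-adjusted p-values, it is the
#' per-electrode (spatial) or per-latency-bin (temporal) magnitude plotted
#' in activation maps and profiles.
#'
#' @param p_adj Adjusted p-value(s) in `[0, 1]`.
#' @param threshold Significance threshold (default 0.01, strict `<`).
#' @return Activation index, `>= 0` (natural-log units).
#' @export
activation_index <- function(p_adj, threshold = 0.01) {
  stopifnot(all(p_adj >= 0 & p_adj <= 1))
  ifelse(p_adj < threshold, -log(p_adj), 0)
}

# BH step-up on the log scale: log-adjusted p-values for log p-values,
# numerically exact where exp() would underflow
fdr_adjust_log <- function(lp, m = length(lp)) {
  n <- length(lp)
  o <- order(lp)
  la <- lp[o] + log(m) - log(seq_len(n))
  la <- rev(cummin(rev(la)))
  la <- pmin(la, 0)
  out <- numeric(n)
  out[o] <- la
  out
}

#' Full AUC significance summary
#'
#' Bundles AUC, Hanley-McNeil SE, p-value, BH adjustment (over a caller-
#' specified family) and activation index for a vector of AUCs sharing the
#' same class sizes per entry. Internally the normal tail and the BH
#' step-up run on the log scale, so strong effects whose p-values
#' underflow double precision still receive finite activation indices
#' (`ai = -ln p_adj`).
#'
#' @param auc AUC values.
#' @param n_pos,n_neg Class sizes (recycled).
#' @param m Multiplicity family size.
#' @param ai_threshold Activation-index threshold on the adjusted p.
#' @return Tibble with columns `auc`, `se`, `p`, `p_adj`, `ai`.
#' @export
auc_significance <- function(auc, n_pos, n_neg, m = length(auc),
                             ai_threshold = 0.01) {
  se <- hanley_mcneil_se(auc, n_pos, n_neg)
  z <- ifelse(se > 0, (auc - 0.5) / se,
              ifelse(auc > 0.5, Inf, ifelse(auc < 0.5, -Inf, 0)))
  lp <- stats::pnorm(z, lower.tail = FALSE, log.p = TRUE)
  lp_adj <- fdr_adjust_log(lp, m)
  tibble::tibble(
    auc = auc, se = se, p = exp(lp), p_adj = exp(lp_adj),
    ai = ifelse(lp_adj < log(ai_threshold), -lp_adj, 0)
  )
}
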