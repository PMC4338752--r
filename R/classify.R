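#' Quantile discretization
#'
#' Maps each column of a numeric matrix to integer levels `1..n_levels` by
#' its own quantile breaks (used by the mutual-information computations in
#' [mrmr_select()]). Constant columns collapse to a single level.
#'
#' @param X Numeric matrix (observations x features).
#' @param n_levels Number of levels (default 3).
#' @param breaks Optional precomputed break list (one vector per column),
#'   e.g. from training data, to apply to new data.
#' @return List with `codes` (integer matrix) and `breaks`.
#' @keywords internal
discretize_quantile <- function(X, n_levels = 3, breaks = NULL) {
  d <- ncol(X)
  if (is.null(breaks)) {
    probs <- seq_len(n_levels - 1) / n_levels
    breaks <- lapply(seq_len(d), function(j) {
      unique(stats::quantile(X[, j], probs = probs, names = FALSE, type = 7))
    })
  }
  codes <- matrix(1L, nrow(X), d)
  for (j in seq_len(d)) {
    if (length(breaks[[j]]) > 0) {
      codes[, j] <- findInterval(X[, j], breaks[[j]], left.open = TRUE) + 1L
    }
  }
  list(codes = codes, breaks = breaks)
}

# plug-in mutual information (nats) between two integer-coded variables
mi_discrete <- function(x, y, nx, ny) {
  joint <- tabulate(x + nx * (y - 1L), nbins = nx * ny) / length(x)
  px <- tabulate(x, nbins = nx) / length(x)
  py <- tabulate(y, nbins = ny) / length(y)
  pp <- outer(px, py)
  nz <- joint > 0
  sum(joint[nz] * log(joint[nz] / pp[nz]))
}

#' Minimum-redundancy maximum-relevance feature selection
#'
#' Greedy forward selection of `k` features using the difference (MID)
#' criterion: at each step the feature maximizing
#' `MI(feature; label) - mean MI(feature; already selected)` is added.
#' Mutual information is the discrete plug-in estimate on 3-level
#' quantile-discretized features (nats). Ties are broken toward the lowest
#' feature index, so selection is deterministic.
#'
#' @param X Numeric matrix, observations x features.
#' @param y Binary labels (factor with levels `-`, `+`, or any
#'   two-level vector).
#' @param k Number of features to select.
#' @param n_levels Discretization levels.
#' @return Integer vector of `k` feature indices in selection order.
#' @export
mrmr_select <- function(X, y, k, n_levels = 3) {
  X <- as.matrix(X)
  d <- ncol(X)
  if (k > d) stop("k (", k, ") exceeds the number of features (", d, ")")
  yl <- as.integer(factor(y))
  ny <- max(yl)
  if (ny < 2) stop("y must have two classes")
  codes <- discretize_quantile(X, n_levels)$codes
  nx <- n_levels
  relevance <- vapply(seq_len(d), function(j) mi_discrete(codes[, j], yl, nx, ny), 0)
  selected <- integer(0)
  # pairwise MI with already-selected features, filled lazily column by column
  redund <- matrix(NA_real_, d, k)
  for (step in seq_len(k)) {
    if (step == 1) {
      score <- relevance
    } else {
      score <- relevance - rowMeans(redund[, seq_len(step - 1), drop = FALSE])
    }
    score[selected] <- -Inf
    pick <- which.max(score) # first maximum = lowest index on ties
    selected <- c(selected, pick)
    if (step < k) {
      redund[, step] <- vapply(
        seq_len(d),
        function(j) mi_discrete(codes[, j], codes[, pick], nx, nx), 0
      )
    }
  }
  selected
}

#' Ledoit-Wolf shrunk covariance
#'
#' Shrinks the empirical covariance `S` (maximum-likelihood, divisor `n`)
#' toward the scaled identity `nu * I`, `nu = trace(S)/d`, with the
#' Ledoit-Wolf optimal intensity estimated from the data and clipped to
#' `[0, 1]`:  `Sigma = (1 - lambda) S + lambda nu I`. Designed for the
#' small-sample, high-dimension regime where `S` is ill-conditioned.
#'
#' @param X Numeric matrix of observations (rows). Centered internally
#'   unless `center = FALSE` (used for pooled within-class residuals,
#'   which already have zero mean).
#' @param center Subtract column means before estimating.
#' @return List with `sigma` (shrunk covariance), `lambda` (intensity),
#'   `nu` (shrinkage target scale) and `s` (empirical covariance).
#' @export
ledoit_wolf_cov <- function(X, center = TRUE) {
  X <- as.matrix(X)
  n <- nrow(X)
  d <- ncol(X)
  if (n < 2) stop("need at least 2 observations")
  if (center) X <- sweep(X, 2, colMeans(X))
  S <- crossprod(X) / n
  nu <- sum(diag(S)) / d
  # normalized Frobenius norm ||A||^2 = tr(A A')/d
  d2 <- sum((S - diag(nu, d))^2) / d
  if (d2 < .Machine$double.eps) {
    return(list(sigma = S, lambda = 0, nu = nu, s = S))
  }
  xtx <- rowSums(X^2)
  # sum_k ||x_k x_k' - S||^2 = sum (x'x)^2 - 2 sum x'Sx + n ||S||^2
  quad <- rowSums((X %*% S) * X)
  b2bar <- (sum(xtx^2) - 2 * sum(quad) + n * sum(S^2)) / (n^2 * d)
  b2 <- min(b2bar, d2)
  lambda <- max(0, min(1, b2 / d2))
  sigma <- (1 - lambda) * S + lambda * diag(nu, d)
  list(sigma = sigma, lambda = lambda, nu = nu, s = S)
}

#' Train a shrinkage-regularized LDA classifier
#'
#' Linear discriminant analysis with the pooled within-class covariance
#' replaced by its Ledoit-Wolf shrunk estimate: the discriminant direction
#' is `w = Sigma^-1 (mu+ - mu-)` and the decision value of an observation
#' `x` is `w'x + b`, with the bias set from empirical class priors. The
#' "+" class scores high. AUC-based evaluation is threshold-free, so `b`
#' affects only hard predictions.
#'
#' @param X Numeric matrix, observations x features.
#' @param y Labels, factor with levels `-`, `+` (coerced).
#' @param lambda Optional fixed shrinkage intensity in `[0, 1]`; by default
#'   the Ledoit-Wolf estimate from the pooled within-class residuals.
#' @return A `trained_rlda` object with `weights`, `bias`, `shrinkage`,
#'   class means and the feature count.
#' @export
train_rlda <- function(X, y, lambda = NULL) {
  X <- as.matrix(X)
  y <- factor(y, levels = c("-", "+"))
  if (any(is.na(y))) stop("labels must be '-'/'+'")
  n_pos <- sum(y == "+")
  n_neg <- sum(y == "-")
  if (n_pos < 2 || n_neg < 2) stop("each class needs at least 2 observations")
  mu_pos <- colMeans(X[y == "+", , drop = FALSE])
  mu_neg <- colMeans(X[y == "-", , drop = FALSE])
  resid <- X
  resid[y == "+", ] <- sweep(X[y == "+", , drop = FALSE], 2, mu_pos)
  resid[y == "-", ] <- sweep(X[y == "-", , drop = FALSE], 2, mu_neg)
  lw <- ledoit_wolf_cov(resid, center = FALSE)
  if (!is.null(lambda)) {
    stopifnot(lambda >= 0, lambda <= 1)
    lw$lambda <- lambda
    lw$sigma <- (1 - lambda) * lw$s + lambda * diag(lw$nu, ncol(X))
  }
  w <- drop(solve(lw$sigma, mu_pos - mu_neg))
  b <- -0.5 * sum(w * (mu_pos + mu_neg)) + log(n_pos / n_neg)
  structure(
    list(
      weights = w, bias = b, shrinkage = lw$lambda,
      mu_pos = mu_pos, mu_neg = mu_neg, n_features = ncol(X)
    ),
    class = "trained_rlda"
  )
}

#' @export
#' @rdname train_rlda
#' @param object A `trained_rlda`.
#' @param newdata Matrix of observations to score.
#' @param ... Unused.
predict.trained_rlda <- function(object, newdata, ...) {
  newdata <- as.matrix(newdata)
  if (ncol(newdata) != object$n_features) stop("feature count mismatch")
  drop(newdata %*% object$weights) + object$bias
}

#' Cross-validated mRMR + shrinkage-LDA
#'
#' Stratified k-fold cross-validation of the full classification engine.
#' Within every training fold (and only there) features are selected by
#' [mrmr_select()] and the shrinkage-LDA classifier is fitted; held-out
#' observations are scored with the fold's model. Performance is the mean
#' over folds of the test-fold ROC AUC ("+" is the positive class).
#'
#' @param X Numeric matrix, observations x features.
#' @param y Labels with levels `-`, `+`.
#' @param k_select Number of mRMR-selected features per fold; `NULL` or
#'   `>= ncol(X)` disables selection.
#' @param n_folds Number of folds (default 5).
#' @param seed Integer seed controlling the stratified fold assignment.
#' @param lambda Optional fixed shrinkage intensity (see [train_rlda()]).
#' @return An `rlda_cv` object: per-observation `scores` tibble
#'   (`obs`, `fold`, `score`, `label`), `fold_assignment`, per-fold
#'   `fold_auc` and `selected` feature lists, and `auc_mean`.
#' @export
cross_validate <- function(X, y, k_select = NULL, n_folds = 5, seed = 1,
                           lambda = NULL) {
  X <- as.matrix(X)
  y <- factor(y, levels = c("-", "+"))
  if (any(is.na(y))) stop("labels must be '-'/'+'")
  n <- nrow(X)
  if (min(table(y)) < n_folds) {
    stop("smallest class (", min(table(y)), ") cannot be stratified into ",
         n_folds, " folds")
  }
  folds <- integer(n)
  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old), add = TRUE)
  set.seed(seed)
  for (cl in levels(y)) {
    idx <- sample(which(y == cl))
    folds[idx] <- rep_len(seq_len(n_folds), length(idx))
  }
  do_select <- !is.null(k_select) && k_select < ncol(X)
  fold_auc <- numeric(n_folds)
  selected <- vector("list", n_folds)
  scores <- numeric(n)
  for (f in seq_len(n_folds)) {
    tr <- folds != f
    te <- !tr
    sel <- if (do_select) mrmr_select(X[tr, , drop = FALSE], y[tr], k_select)
           else seq_len(ncol(X))
    selected[[f]] <- sel
    model <- train_rlda(X[tr, sel, drop = FALSE], y[tr], lambda = lambda)
    scores[te] <- predict(model, X[te, sel, drop = FALSE])
    fold_auc[f] <- roc_auc(scores[te], y[te])
  }
  structure(
    list(
      scores = tibble::tibble(
        obs = seq_len(n), fold = folds, score = scores, label = y
      ),
      fold_assignment = folds,
      fold_auc = fold_auc,
      selected = selected,
      auc_mean = mean(fold_auc),
      n_pos = sum(y == "+"), n_neg = sum(y == "-"),
      k_select = if (do_select) k_select else ncol(X),
      n_folds = n_folds, seed = seed
    ),
    class = "rlda_cv"
  )
}

#' @export
print.rlda_cv <- function(x, ...) {
  cat(sprintf(
    "<rlda_cv> %d-fold CV, %d features/fold: mean test AUC = %.3f\n",
    x$n_folds, x$k_select, x$auc_mean
  ))
  invisible(x)
}

#' Per-fold selected features of a cross-validation run
#'
#' @param cv An `rlda_cv` object.
#' @return Tibble with columns `fold`, `rank`, `feature` (ready for a
#'   debug CSV dump via [readr::write_csv()]).
#' @export
cv_selected_features <- function(cv) {
  stopifnot(inherits(cv, "rlda_cv"))
  purrr::map_dfr(seq_along(cv$selected), function(f) {
    tibble::tibble(
      fold = f,
      rank = seq_along(cv$selected[[f]]),
      feature = cv$selected[[f]]
    )
  })
}

# save/restore the global RNG state so seeded internals do not disturb the
# caller's stream
.Random.seed_save <- function() {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    get(".Random.seed", envir = globalenv())
  } else NULL
}
.Random.seed_restore <- function(old) {
  if (!is.null(old)) assign(".Random.seed", old, envir = globalenv())
}
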