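# brute-force greedy mRMR oracle: quantile-discretized plug-in MI, difference
# criterion, evaluated exhaustively at every step
oracle_mrmr <- function(X, y, k, n_levels = 3) {
  disc <- function(v) {
    br <- unique(stats::quantile(v, seq_len(n_levels - 1) / n_levels, names = FALSE))
    findInterval(v, br, left.open = TRUE) + 1L
  }
  mi <- function(a, b) {
    tab <- table(a, b) / length(a)
    pa <- rowSums(tab); pb <- colSums(tab)
    s <- 0
    for (i in seq_along(pa)) for (j in seq_along(pb)) {
      if (tab[i, j] > 0) s <- s + tab[i, j] * log(tab[i, j] / (pa[i] * pb[j]))
    }
    s
  }
  codes <- apply(X, 2, disc)
  yl <- as.integer(factor(y))
  rel <- apply(codes, 2, mi, b = yl)
  sel <- integer(0)
  for (step in seq_len(k)) {
    cand <- setdiff(seq_len(ncol(X)), sel)
    score <- vapply(cand, function(j) {
      red <- if (length(sel)) mean(vapply(sel, function(s) mi(codes[, j], codes[, s]), 0)) else 0
      rel[j] - red
    }, 0)
    sel <- c(sel, cand[which.max(score)])
  }
  sel
}

test_that("mRMR ranks a label-aligned feature first and avoids redundant copies", {
  set.seed(10)
  n <- 150
  y <- factor(rep_len(c("-", "+"), n), levels = c("-", "+"))
  informative <- as.numeric(y) + rnorm(n, sd = 0.05)
  X <- cbind(informative, matrix(rnorm(n * 4), n))
  expect_equal(mrmr_select(X, y, 2)[1], 1L)

  # a duplicate of the first pick is maximally redundant: with another
  # informative, non-redundant feature available the copy is not chosen second
  informative2 <- as.numeric(y) * 0.8 + rnorm(n, sd = 0.4)
  X4 <- cbind(informative, informative, informative2, rnorm(n))
  sel <- mrmr_select(X4, y, 2)
  expect_equal(sel[1], 1L)
  expect_false(sel[2] == 2L)
  expect_equal(sel, oracle_mrmr(X4, y, 2))
})

# per-step candidate scores of the greedy criterion given a selection prefix,
# recomputed independently with table-based MI estimates
oracle_step_scores <- function(X, y, prefix, n_levels = 3) {
  disc <- function(v) {
    br <- unique(stats::quantile(v, seq_len(n_levels - 1) / n_levels, names = FALSE))
    findInterval(v, br, left.open = TRUE) + 1L
  }
  mi <- function(a, b) {
    tab <- table(a, b) / length(a)
    pa <- rowSums(tab); pb <- colSums(tab)
    s <- 0
    for (i in seq_along(pa)) for (j in seq_along(pb)) {
      if (tab[i, j] > 0) s <- s + tab[i, j] * log(tab[i, j] / (pa[i] * pb[j]))
    }
    s
  }
  codes <- apply(X, 2, disc)
  yl <- as.integer(factor(y))
  cand <- setdiff(seq_len(ncol(X)), prefix)
  scores <- vapply(cand, function(j) {
    red <- if (length(prefix)) {
      mean(vapply(prefix, function(s) mi(codes[, j], codes[, s]), 0))
    } else 0
    mi(codes[, j], yl) - red
  }, 0)
  stats::setNames(scores, cand)
}

test_that("mRMR agrees with an exhaustive greedy oracle and handles edge cases", {
  # exact MI ties between unrelated features are broken by index in the
  # implementation but by float summation order in the oracle, so assert the
  # defining greedy property: every pick attains the step's maximal score
  for (seed in 1:5) {
    set.seed(seed)
    n <- 80
    y <- factor(sample(rep_len(c("-", "+"), n)), levels = c("-", "+"))
    X <- matrix(rnorm(n * 6), n)
    X[, 2] <- X[, 2] + 0.8 * as.numeric(y)
    got <- mrmr_select(X, y, 6)
    for (step in 1:6) {
      scores <- oracle_step_scores(X, y, got[seq_len(step - 1)])
      expect_gte(scores[as.character(got[step])], max(scores) - 1e-9)
    }
  }
  set.seed(6)
  X <- matrix(rnorm(40 * 3), 40)
  X[, 2] <- 1 # constant feature: MI 0, still rankable
  y <- factor(rep_len(c("-", "+"), 40), levels = c("-", "+"))
  expect_equal(sort(mrmr_select(X, y, 3)), 1:3)
  expect_error(mrmr_select(X, y, 4), "exceeds")
})

# direct loop evaluation of the Ledoit-Wolf formula (normalized Frobenius
# norms over per-observation outer products)
oracle_lw <- function(X, center = TRUE) {
  n <- nrow(X); d <- ncol(X)
  if (center) X <- sweep(X, 2, colMeans(X))
  S <- crossprod(X) / n
  nu <- mean(diag(S))
  d2 <- sum((S - diag(nu, d))^2) / d
  b2bar <- 0
  for (k in seq_len(n)) {
    b2bar <- b2bar + sum((tcrossprod(X[k, ]) - S)^2) / d
  }
  b2bar <- b2bar / n^2
  lambda <- if (d2 < .Machine$double.eps) 0 else max(0, min(1, min(b2bar, d2) / d2))
  list(sigma = (1 - lambda) * S + lambda * diag(nu, d), lambda = lambda)
}

test_that("Ledoit-Wolf matches a brute-force evaluation of the formula", {
  for (seed in 1:5) {
    set.seed(seed)
    X <- matrix(rnorm(12 * 4), 12)
    got <- ledoit_wolf_cov(X)
    want <- oracle_lw(X)
    expect_equal(got$lambda, want$lambda, tolerance = 1e-12)
    expect_equal(got$sigma, want$sigma, tolerance = 1e-12)
  }
})

test_that("Ledoit-Wolf shrinks correctly in the large-n and small-n regimes", {
  # large n, distinctly non-spherical truth: almost no shrinkage
  set.seed(20)
  X <- matrix(rnorm(10000 * 5), 10000) %*% diag(c(1, 2, 3, 4, 5))
  lw <- ledoit_wolf_cov(X)
  expect_lt(lw$lambda, 0.05)
  expect_lt(max(abs(lw$sigma - diag(c(1, 4, 9, 16, 25)))), 1.0)
  # n = 2, d = 50 (known mean): heavy shrinkage, well-conditioned output
  set.seed(21)
  X2 <- matrix(rnorm(2 * 50), 2)
  lw2 <- ledoit_wolf_cov(X2, center = FALSE)
  expect_gt(lw2$lambda, 0.2)
  expect_lt(kappa(lw2$sigma), 1e3)
  # exactly spherical empirical covariance: target equals S, so sigma = S
  Xs <- rbind(c(1, 0), c(-1, 0), c(0, 1), c(0, -1))
  lws <- ledoit_wolf_cov(Xs)
  expect_equal(lws$sigma, lws$s)
})

test_that("shrinkage-LDA separates well-separated classes and matches the 1-d closed form", {
  set.seed(30)
  n <- 200
  X <- rbind(matrix(rnorm(n * 2), n), matrix(rnorm(n * 2, mean = 6), n))
  y <- factor(rep(c("-", "+"), each = n), levels = c("-", "+"))
  model <- train_rlda(X, y)
  expect_gte(roc_auc(predict(model, X), y), 0.999)

  # d = 1: weights proportional to (mu+ - mu-)/pooled variance
  set.seed(31)
  x1 <- matrix(rnorm(30, 2, 1.5), ncol = 1)
  x0 <- matrix(rnorm(25, 0, 1.5), ncol = 1)
  X1 <- rbind(x0, x1)
  y1 <- factor(rep(c("-", "+"), c(25, 30)), levels = c("-", "+"))
  m1 <- train_rlda(X1, y1, lambda = 0)
  s2 <- (sum((x0 - mean(x0))^2) + sum((x1 - mean(x1))^2)) / 55
  expect_equal(unname(m1$weights), (mean(x1) - mean(x0)) / s2, tolerance = 1e-10)
})

test_that("with identical class distributions the training AUC sits at chance", {
  aucs <- vapply(1:20, function(seed) {
    set.seed(seed)
    X <- matrix(rnorm(400 * 3), 400)
    y <- factor(rep_len(c("-", "+"), 400), levels = c("-", "+"))
    m <- train_rlda(X, y)
    roc_auc(predict(m, X), y)
  }, 0)
  expect_lt(abs(mean(aucs) - 0.5), 0.05)
})

test_that("lambda = 0 reproduces plug-in LDA on small instances", {
  for (seed in 1:5) {
    set.seed(seed)
    d <- sample(1:3, 1)
    n <- sample(12:30, 1)
    y <- factor(rep_len(c("-", "+"), n), levels = c("-", "+"))
    X <- matrix(rnorm(n * d), n) + as.numeric(y)
    m <- train_rlda(X, y, lambda = 0)
    # plug-in oracle: pooled MLE covariance of class-centered residuals
    mu1 <- colMeans(X[y == "+", , drop = FALSE])
    mu0 <- colMeans(X[y == "-", , drop = FALSE])
    R <- rbind(
      sweep(X[y == "+", , drop = FALSE], 2, mu1),
      sweep(X[y == "-", , drop = FALSE], 2, mu0)
    )
    S <- crossprod(R) / n
    w <- solve(S, mu1 - mu0)
    expect_equal(unname(m$weights), unname(drop(w)), tolerance = 1e-8)
  }
})

test_that("cross-validation is stratified, deterministic, and leak-free", {
  set.seed(40)
  n <- 100
  y <- factor(rep_len(c("-", "+", "+"), n), levels = c("-", "+")) # unbalanced
  X <- matrix(rnorm(n * 8), n)
  cv <- cross_validate(X, y, k_select = 4, seed = 7)
  # folds partition the data and roughly preserve class balance
  expect_equal(sort(unique(cv$fold_assignment)), 1:5)
  per_fold_pos <- tapply(y == "+", cv$fold_assignment, mean)
  expect_true(all(abs(per_fold_pos - mean(y == "+")) < 0.15))
  # same seed -> identical result
  cv2 <- cross_validate(X, y, k_select = 4, seed = 7)
  expect_identical(cv$auc_mean, cv2$auc_mean)
  expect_identical(cv$selected, cv2$selected)
  # replacing test-fold rows of X cannot change in-fold selections (no leak)
  X3 <- X
  test1 <- cv$fold_assignment == 1
  X3[test1, ] <- matrix(rnorm(sum(test1) * 8), sum(test1))
  cv3 <- cross_validate(X3, y, k_select = 4, seed = 7)
  expect_identical(cv$selected[[1]], cv3$selected[[1]])
})

test_that("cross-validated AUC hits the ceiling for separable data and chance for permuted labels", {
  set.seed(50)
  n <- 100
  X <- rbind(matrix(rnorm(n), n / 2), matrix(rnorm(n, mean = 8), n / 2))
  y <- factor(rep(c("-", "+"), each = n / 2), levels = c("-", "+"))
  cv <- cross_validate(X, y, seed = 1)
  expect_equal(cv$auc_mean, 1.0)
  # permuted labels: null AUC per replicate
  aucs <- vapply(1:20, function(seed) {
    set.seed(seed)
    Xn <- matrix(rnorm(300 * 6), 300)
    yn <- factor(sample(rep_len(c("-", "+"), 300)), levels = c("-", "+"))
    cross_validate(Xn, yn, k_select = 3, seed = seed)$auc_mean
  }, 0)
  expect_true(all(aucs > 0.35 & aucs < 0.65))
  expect_lt(abs(mean(aucs) - 0.5), 0.03)
  # degenerate selection (k = all features) equals plain CV
  set.seed(51)
  Xs <- matrix(rnorm(100 * 4), 100)
  ys <- factor(rep_len(c("-", "+"), 100), levels = c("-", "+"))
  expect_equal(
    cross_validate(Xs, ys, k_select = 4, seed = 2)$auc_mean,
    cross_validate(Xs, ys, k_select = NULL, seed = 2)$auc_mean
  )
})

test_that("cv tidiers summarise folds and overall performance", {
  set.seed(60)
  X <- matrix(rnorm(80 * 5), 80)
  y <- factor(rep_len(c("-", "+"), 80), levels = c("-", "+"))
  cv <- cross_validate(X, y, k_select = 2, seed = 1)
  td <- tidy(cv)
  expect_equal(nrow(td), 5)
  expect_equal(mean(td$auc), cv$auc_mean)
  expect_true(all(td$n_selected == 2))
  gl <- glance(cv)
  expect_equal(gl$auc_mean, cv$auc_mean)
  expect_equal(gl$n_pos + gl$n_neg, 80L)
  sel <- cv_selected_features(cv)
  expect_equal(nrow(sel), 10)
  expect_equal(unique(sel$rank), 1:2)
})
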