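test_that("the screening rule reproduces threshold arithmetic on an AUC table", {
  res <- screening_from_auc(
    c(A = 0.57, B = 0.81, C = 0.51, D = 0.68, E = 0.91, F = 0.87, G = 0.91)
  )
  expect_equal(sum(res$passed), 4)
  expect_equal(res$subject[res$passed], c("B", "E", "F", "G"))
  # the threshold is strict: exactly 0.8 does not pass
  expect_false(screening_from_auc(0.8)$passed)
})

test_that("screening discriminates speech from silence when effects are strong", {
  eff <- sim_effect("all", electrodes = c(2, 5, 9), gain = 3, duration_ms = 80)
  cfg <- sim_config(n_electrodes = 12, duration_s = 90, seed = 21,
                    effects = list(eff))
  sess <- simulate_session(cfg)
  scr <- screen_subject(sess$recording, sess$words, seed = 1)
  expect_gte(scr$auc, 0.9)
  expect_true(scr$passed)
  expect_equal(scr$n_speech, scr$n_silence)
  td <- tidy(scr)
  expect_true(td$passed)
})

test_that("screening sits at chance without any speech-locked effect", {
  cfg <- sim_config(n_electrodes = 12, duration_s = 90, seed = 22)
  sess <- simulate_session(cfg)
  scr <- screen_subject(sess$recording, sess$words, seed = 1)
  expect_lt(abs(scr$auc - 0.5), 0.15)
  expect_false(scr$passed)
})

test_that("screening errors when silence is insufficient, listing the count", {
  cfg <- sim_config(n_electrodes = 2, duration_s = 30, seed = 23)
  sess <- simulate_session(cfg)
  # words abutting each other leave no usable gaps
  dense_words <- tibble::tibble(
    word = paste0("w", 1:20), onset = 1 + (0:19) * 1.2,
    offset = 1 + (0:19) * 1.2 + 1.19
  )
  expect_error(screen_subject(sess$recording, dense_words, seed = 1),
               "insufficient silence")
})

test_that("spatial analysis flags label-coupled channels and only those", {
  es <- toy_epoch_set(n_epochs = 150, n_channels = 8,
                      effect_channels = c(2, 5), delta = 1.2, seed = 101)
  amap <- spatial_analysis(es, "sonorant", seed = 1)
  expect_s3_class(amap, "activation_map")
  expect_equal(nrow(amap), 8)
  sig <- amap$electrode[amap$significant]
  expect_true(all(c(2, 5) %in% sig))
  expect_lte(length(setdiff(sig, c(2, 5))), 1)
  expect_true(all(amap$ai >= 0))
  expect_equal(amap$significant, amap$ai > 0)
})

test_that("spatial analysis rejects single-class labelings", {
  es <- toy_epoch_set(n_epochs = 60, n_channels = 3, seed = 7)
  attr(es, "alignments")$phoneme <- "m" # everything sonorant+
  expect_error(spatial_analysis(es, "sonorant", seed = 1), "single-class")
})

test_that("temporal analysis localizes the informative bins and averages electrodes", {
  es <- toy_epoch_set(n_epochs = 200, n_channels = 4, n_bins = 20,
                      effect_channels = c(1, 3), effect_bins = 9:11,
                      delta = 1.5, seed = 55)
  tp <- temporal_analysis(es, "sonorant", electrodes = c(1, 3), seed = 1)
  expect_s3_class(tp, "temporal_profile")
  peak_bin <- which.max(tp$profile$ai)
  expect_true(peak_bin %in% 9:11)
  expect_equal(tp$peak_ai, max(tp$profile$ai))
  expect_equal(tp$profile$ai[peak_bin], tp$peak_ai)
  # outside the informative bins the AI is (essentially) zero
  expect_true(all(tp$profile$ai[c(1:5, 16:20)] == 0))
  # a single electrode's profile is that electrode's AI series
  tp1 <- temporal_analysis(es, "sonorant", electrodes = 3, seed = 1)
  one <- tp1$by_electrode[tp1$by_electrode$electrode == 3, ]
  expect_equal(tp1$profile$ai, one$ai[order(one$latency_ms)])
  expect_error(temporal_analysis(es, "sonorant", electrodes = integer(0)),
               "no significant electrodes")
})

test_that("local maxima detection respects smoothing and prominence", {
  centers <- seq(-325, 325, by = 10)
  ai <- rep(0, 66)
  ai[10:14] <- c(2, 5, 8, 5, 2)   # prominent bump
  ai[40:42] <- c(0.2, 0.35, 0.2)  # sub-prominence ripple
  got <- ecogseg:::local_maxima(ai, centers)
  expect_equal(got, centers[12])
})

test_that("maps pool across subjects with summed disjoint counts", {
  es1 <- toy_epoch_set(150, 6, effect_channels = 2, seed = 61)
  es2 <- toy_epoch_set(150, 6, effect_channels = 5, seed = 62)
  coords <- tibble::tibble(channel = 1:6, x = (0:5) * 10, y = 0)
  m1 <- spatial_analysis(es1, "sonorant", seed = 1, coords = coords, subject = "S1")
  m2 <- spatial_analysis(es2, "sonorant", seed = 1, coords = coords, subject = "S2")
  pooled1 <- accumulate_across_subjects(m1)
  expect_equal(nrow(pooled1), nrow(m1))
  expect_equal(attr(pooled1, "counts")$n_significant, sum(m1$significant))
  pooled <- accumulate_across_subjects(list(m1, m2))
  expect_equal(nrow(pooled), 12)
  expect_equal(attr(pooled, "counts")$n_significant,
               sum(m1$significant) + sum(m2$significant))
  # plots build without error
  expect_s3_class(ggplot2::autoplot(pooled), "ggplot")
})

test_that("temporal profile tidiers and plot expose the headline numbers", {
  es <- toy_epoch_set(150, 3, n_bins = 12, effect_channels = 1,
                      effect_bins = 6:8, seed = 71)
  tp <- temporal_analysis(es, "sonorant", electrodes = 1, seed = 1)
  gl <- glance(tp)
  expect_equal(gl$peak_ai, tp$peak_ai)
  expect_equal(gl$peak_latency_ms, tp$peak_latency_ms)
  expect_equal(tidy(tp), tp$profile)
  expect_s3_class(ggplot2::autoplot(tp), "ggplot")
})
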