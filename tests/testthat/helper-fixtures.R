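# shared in-code fixtures for the test suite

# sinusoid recording: one channel per (freq, amp) pair
sine_recording <- function(freqs, amps = rep(1, length(freqs)), fs = 1200,
                           dur_s = 4) {
  tt <- (seq_len(fs * dur_s) - 1) / fs
  data <- t(mapply(function(f, a) a * sin(2 * pi * f * tt), freqs, amps))
  new_recording(matrix(data, nrow = length(freqs)), fs = fs)
}

# small alignment table over given phonemes, contiguous 100 ms segments
toy_alignments <- function(phonemes, start = 1, dur = 0.1) {
  onsets <- start + (seq_along(phonemes) - 1) * dur
  tibble::tibble(
    phoneme = phonemes, onset = onsets, offset = onsets + dur,
    word = 1L
  )
}

# epoch_set built directly in bin space with label-dependent channel means;
# bypasses signal synthesis for fast classification-level tests
toy_epoch_set <- function(n_epochs = 120, n_channels = 8, n_bins = 27,
                          effect_channels = integer(0), effect_bins = NULL,
                          delta = 1.5, seed = 1) {
  set.seed(seed)
  if (is.null(effect_bins)) effect_bins <- seq_len(n_bins)
  y <- factor(rep_len(c("-", "+"), n_epochs), levels = c("-", "+"))
  pw <- array(rnorm(n_epochs * n_channels * n_bins), c(n_epochs, n_channels, n_bins))
  for (ch in effect_channels) {
    pw[y == "+", ch, effect_bins] <- pw[y == "+", ch, effect_bins] + delta
  }
  centers <- -350 + (seq_len(n_bins) - 1) * (700 - 50) / (n_bins - 1) + 25
  es <- structure(
    list(power = pw, labels = y, bin_centers = centers,
         window = c(pre_ms = 350, post_ms = 350), bin_ms = 50,
         step_ms = (700 - 50) / (n_bins - 1)),
    class = "epoch_set"
  )
  # attach pseudo-alignments whose phoneme encodes the label: "m" (sonorant+)
  # for "+", "t" (sonorant-) for "-"
  attr(es, "alignments") <- tibble::tibble(
    phoneme = ifelse(y == "+", "m", "t"),
    onset = seq_len(n_epochs), offset = seq_len(n_epochs) + 0.1,
    word = 1L
  )
  es
}
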