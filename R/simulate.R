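#' Simulation configuration
#'
#' Defines a synthetic recording session with known ground truth. The
#' generated signal is, per channel: 1/f background noise + a per-grid
#' shared (common-mode) component + power-line sinusoids at 60/120/180 Hz
#' + for each configured effect a band-limited (70-170 Hz) gamma burst
#' added in the window `[onset + latency, onset + latency + duration)` of
#' every phoneme carrying the effect's feature dimension, with amplitude
#' `gain` times the channel's in-band background amplitude.
#'
#' Phonemes are sampled with per-class weights giving a vowel fraction of
#' 39.2% and English-like consonant frequencies (labial ~23%, coronal
#' ~65%, dorsal ~12% among consonants); contiguous phonemes form words of
#' 2-8 phonemes separated by short gaps, with longer silent pauses
#' interspersed so the speech-vs-silence screening has silence windows to
#' draw on.
#'
#' @param n_electrodes Number of channels (default 48, one 8 x 6 grid at
#'   10 mm pitch).
#' @param n_grids Number of electrode grids (channels split evenly).
#' @param fs Sampling rate, Hz.
#' @param duration_s Session length, seconds.
#' @param phoneme_rate Phonemes per second of speech (default 10).
#' @param background List with `exponent` (PSD ~ 1/f^exponent) and
#'   `amplitude` (channel SD, a.u.).
#' @param line_noise Named amplitudes (a.u.) of 50/60 Hz-family sinusoids;
#'   names are frequencies in Hz.
#' @param common_mode Amplitude (a.u.) of the per-grid shared component.
#' @param effects List of effects from [sim_effect()].
#' @param seed Integer seed; every draw in the generator is derived from it.
#' @return A `sim_config` list.
#' @export
sim_config <- function(n_electrodes = 48, n_grids = 1, fs = 1200,
                       duration_s = 120, phoneme_rate = 10,
                       background = list(exponent = 1.5, amplitude = 20),
                       line_noise = c("60" = 5, "120" = 2, "180" = 1),
                       common_mode = 15,
                       effects = list(),
                       seed = 1) {
  if (fs <= 2 * 170) stop("fs must exceed twice the gamma-band upper edge")
  for (ef in effects) {
    if (!inherits(ef, "sim_effect")) stop("effects must be built with sim_effect()")
    if (ef$gain < 0) stop("effect gains must be >= 0")
    if (any(ef$electrodes < 1 | ef$electrodes > n_electrodes)) {
      stop("effect electrodes must lie in 1..n_electrodes")
    }
  }
  structure(
    list(
      n_electrodes = n_electrodes, n_grids = n_grids, fs = fs,
      duration_s = duration_s, phoneme_rate = phoneme_rate,
      background = background, line_noise = line_noise,
      common_mode = common_mode, effects = effects, seed = seed
    ),
    class = "sim_config"
  )
}

#' @rdname sim_config
#' @param dimension Feature dimension the effect is locked to (one of
#'   [feature_dimensions] or `"all"` for every phoneme).
#' @param gain In-band amplitude of the burst relative to the channel's
#'   background gamma-band amplitude (0 = no effect).
#' @param latency_ms Burst start relative to phoneme onset, ms.
#' @param duration_ms Burst length, ms.
#' @param electrodes Channels carrying the effect.
#' @export
sim_effect <- function(dimension, electrodes, gain = 2, latency_ms = 0,
                       duration_ms = 100) {
  dimension <- match.arg(dimension, c(feature_dimensions, "all"))
  structure(
    list(
      dimension = dimension, electrodes = as.integer(electrodes),
      gain = gain, latency_ms = latency_ms, duration_ms = duration_ms
    ),
    class = "sim_effect"
  )
}

# per-phoneme sampling weights; consonant weights approximate the target
# place fractions among consonants (labial ~.23, dorsal ~.12)
.consonant_weights <- c(
  p = .040, b = .045, t = .095, d = .075, k = .050, g = .040,
  ch = .012, jh = .012, f = .030, v = .030, th = .022, dh = .048,
  s = .080, z = .040, sh = .016, zh = .004, hh = .020,
  m = .048, n = .095, ng = .012, l = .065, r = .065, w = .034, y = .030
)
.vowel_weights <- c(
  ah = .18, ih = .12, iy = .10, eh = .09, ae = .08, aa = .07, er = .07,
  ey = .06, ow = .06, ay = .06, uw = .04, uh = .03, aw = .02, oy = .01,
  ao = .01
)
.vowel_fraction <- 0.392

#' Sample a phoneme alignment and word-boundary table
#'
#' Draws a phoneme sequence from the inventory (vowel fraction 39.2%,
#' per-phoneme weights as documented in [sim_config()]), groups contiguous
#' phonemes into words of 2-8 phonemes, and separates words by short gaps
#' (150-350 ms) or, with probability 0.3, longer silent pauses
#' (0.9-1.8 s). Phoneme durations are jittered around `1/phoneme_rate`.
#' Fully seeded from `cfg$seed`.
#'
#' @param cfg A [sim_config()].
#' @return List with `alignments` (phoneme, onset, offset, word) and
#'   `words` (word, onset, offset) tibbles.
#' @export
sample_alignments <- function(cfg) {
  stopifnot(inherits(cfg, "sim_config"))
  if (cfg$phoneme_rate <= 0) stop("phoneme_rate must be positive")
  if (cfg$phoneme_rate * cfg$duration_s < 50) {
    stop("phoneme_rate x duration_s must be at least 50")
  }
  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old), add = TRUE)
  set.seed(cfg$seed)
  cons <- .consonant_weights / sum(.consonant_weights)
  vow <- .vowel_weights / sum(.vowel_weights)
  t_cur <- 1.0 # leave room for the 350 ms pre-window
  rows <- list()
  word_rows <- list()
  w_idx <- 0L
  while (TRUE) {
    n_ph <- sample(2:8, 1)
    durs <- stats::runif(n_ph, 0.7, 1.3) / cfg$phoneme_rate
    if (t_cur + sum(durs) > cfg$duration_s - 1.0) break
    w_idx <- w_idx + 1L
    is_vowel <- stats::runif(n_ph) < .vowel_fraction
    ph <- character(n_ph)
    ph[is_vowel] <- sample(names(vow), sum(is_vowel), replace = TRUE, prob = vow)
    ph[!is_vowel] <- sample(names(cons), sum(!is_vowel), replace = TRUE, prob = cons)
    onsets <- t_cur + cumsum(c(0, durs[-n_ph]))
    rows[[w_idx]] <- tibble::tibble(
      phoneme = ph, onset = onsets, offset = onsets + durs, word = w_idx
    )
    word_rows[[w_idx]] <- tibble::tibble(
      word = paste0("w", w_idx), onset = t_cur, offset = t_cur + sum(durs)
    )
    gap <- if (stats::runif(1) < 0.3) stats::runif(1, 0.9, 1.8)
           else stats::runif(1, 0.15, 0.35)
    t_cur <- t_cur + sum(durs) + gap
  }
  list(
    alignments = dplyr::bind_rows(rows),
    words = dplyr::bind_rows(word_rows)
  )
}

# 1/f^exponent noise via spectral shaping (flat below 1 Hz), unit SD
pink_noise <- function(n, exponent, fs) {
  half <- (n - 1) %/% 2
  f <- (1:half) * fs / n
  mag <- pmax(f, 1)^(-exponent / 2)
  spec <- complex(real = stats::rnorm(half), imaginary = stats::rnorm(half)) * mag
  full <- complex(length.out = n)
  full[2:(half + 1)] <- spec
  full[n + 1 - (1:half)] <- Conj(spec)
  if (n %% 2 == 0) {
    fn <- (fs / 2)^(-exponent / 2)
    full[half + 2] <- complex(real = stats::rnorm(1) * fn, imaginary = 0)
  }
  x <- Re(stats::fft(full, inverse = TRUE)) / n
  x / stats::sd(x)
}

# default planar electrode layout: rows of 8 at 10 mm pitch, grids offset in x
default_coords <- function(n_electrodes, grid) {
  coords <- tibble::tibble(
    channel = seq_len(n_electrodes),
    grid = grid
  )
  coords <- dplyr::group_by(coords, grid) |>
    dplyr::mutate(
      x = ((dplyr::row_number() - 1) %% 8) * 10 + (match(grid, unique(coords$grid))[1] - 1) * 100,
      y = ((dplyr::row_number() - 1) %/% 8) * 10
    ) |>
    dplyr::ungroup()
  coords[, c("channel", "x", "y", "grid")]
}

#' Synthesize a recording with known ground truth
#'
#' Builds the multi-channel signal described in [sim_config()]. All noise
#' sources are drawn for every channel regardless of effect gains, so a
#' configuration with all gains 0 produces, at the same seed, exactly the
#' signal of a pure-noise session: effects are invisible at gain 0.
#'
#' @param cfg A [sim_config()].
#' @param alignments Alignment/word list from [sample_alignments()]
#'   (generated from `cfg` if missing).
#' @return List with `recording` (an `ecog_recording` with coordinates),
#'   `ground_truth` (tibble: dimension, electrode, gain, latency_ms,
#'   duration_ms, expected_peak_ms), plus the `alignments` and `words`
#'   tibbles used.
#' @export
synthesize_recording <- function(cfg, alignments = NULL) {
  stopifnot(inherits(cfg, "sim_config"))
  if (is.null(alignments)) alignments <- sample_alignments(cfg)
  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old), add = TRUE)
  set.seed(cfg$seed + 500000L)
  n <- round(cfg$duration_s * cfg$fs)
  n_ch <- cfg$n_electrodes
  grid <- sort(rep_len(seq_len(cfg$n_grids), n_ch))
  tt <- (seq_len(n) - 1) / cfg$fs
  data <- matrix(0, n_ch, n)
  for (ch in seq_len(n_ch)) {
    data[ch, ] <- pink_noise(n, cfg$background$exponent, cfg$fs) *
      cfg$background$amplitude
  }
  # per-grid shared component (removed by CAR up to the per-channel average);
  # drawn even at amplitude 0 so the RNG stream is invariant to the setting
  for (g in unique(grid)) {
    cm <- pink_noise(n, cfg$background$exponent, cfg$fs) * cfg$common_mode
    data[grid == g, ] <- sweep(data[grid == g, , drop = FALSE], 2, cm, "+")
  }
  if (length(cfg$line_noise) > 0) {
    for (j in seq_along(cfg$line_noise)) {
      f0 <- as.numeric(names(cfg$line_noise)[j])
      phase <- stats::runif(1, 0, 2 * pi)
      amp <- cfg$line_noise[j] * stats::runif(n_ch, 0.5, 1.5)
      data <- data + outer(amp, sin(2 * pi * f0 * tt + phase))
    }
  }
  # phoneme-locked band-limited gamma bursts
  gt <- list()
  if (length(cfg$effects) > 0) {
    ft <- build_feature_table()
    bp <- signal::butter(4, c(70, 170) / (cfg$fs / 2), type = "pass")
    for (ef in cfg$effects) {
      lab <- label_for_feature(alignments$alignments, ft, ef$dimension)
      pos <- lab[lab$label == "+", ]
      env <- numeric(n)
      if (nrow(pos) > 0) {
        a <- round((pos$onset + ef$latency_ms / 1000) * cfg$fs) + 1L
        b <- round((pos$onset + (ef$latency_ms + ef$duration_ms) / 1000) * cfg$fs)
        for (i in seq_along(a)) {
          lo <- max(1L, a[i]); hi <- min(n, b[i])
          if (lo <= hi) env[lo:hi] <- 1
        }
      }
      for (e in ef$electrodes) {
        burst <- signal::filtfilt(bp, stats::rnorm(n))
        bg_inband <- stats::sd(signal::filtfilt(bp, data[e, ]))
        data[e, ] <- data[e, ] +
          ef$gain * (bg_inband / stats::sd(burst)) * burst * env
      }
      gt[[length(gt) + 1L]] <- tibble::tibble(
        dimension = ef$dimension, electrode = ef$electrodes,
        gain = ef$gain, latency_ms = ef$latency_ms,
        duration_ms = ef$duration_ms,
        expected_peak_ms = ef$latency_ms + ef$duration_ms / 2
      )
    }
  }
  rec <- new_recording(
    data, fs = cfg$fs, grid = grid,
    coords = default_coords(n_ch, grid)
  )
  list(
    recording = rec,
    ground_truth = if (length(gt)) dplyr::bind_rows(gt) else
      tibble::tibble(
        dimension = character(), electrode = integer(), gain = numeric(),
        latency_ms = numeric(), duration_ms = numeric(),
        expected_peak_ms = numeric()
      ),
    alignments = alignments$alignments,
    words = alignments$words
  )
}

#' Simulate a full session
#'
#' Convenience wrapper: [sample_alignments()] then
#' [synthesize_recording()].
#'
#' @param cfg A [sim_config()].
#' @return See [synthesize_recording()].
#' @export
simulate_session <- function(cfg) {
  synthesize_recording(cfg, sample_alignments(cfg))
}

#' Write a seed-reproducible fixture to disk
#'
#' Writes the recording container (`recording.rds`), the alignment and
#' word-boundary tables (`alignments.tsv`, `words.tsv`) and the
#' ground-truth sidecar (`ground_truth.tsv`). Text outputs are
#' byte-identical across runs at the same seed.
#'
#' @param cfg A [sim_config()].
#' @param dir Writable output directory (created if needed).
#' @return Invisibly, the list of written paths.
#' @export
write_fixture <- function(cfg, dir) {
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  sess <- simulate_session(cfg)
  paths <- list(
    recording = file.path(dir, "recording.rds"),
    alignments = file.path(dir, "alignments.tsv"),
    words = file.path(dir, "words.tsv"),
    ground_truth = file.path(dir, "ground_truth.tsv")
  )
  write_recording(sess$recording, paths$recording)
  write_alignments(sess$alignments, paths$alignments)
  write_words(sess$words, paths$words)
  readr::write_tsv(sess$ground_truth, paths$ground_truth)
  invisible(paths)
}
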