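#' Multi-channel ECoG recording
#'
#' Container for a continuous multi-channel recording: a channels-by-samples
#' numeric matrix with its sampling rate, a per-channel grid identifier
#' (common-average referencing is applied within grids), and optional 2-D or
#' 3-D electrode coordinates.
#'
#' @param data Numeric matrix, channels x samples. Microvolt-scale arbitrary
#'   units; no NaN/Inf.
#' @param fs Sampling rate in Hz (nominal 1200).
#' @param grid Grid identifier per channel (defaults to a single grid).
#' @param coords Optional tibble with columns `channel`, `x`, `y` (and
#'   optionally `z`).
#' @return An object of class `ecog_recording`.
#' @export
new_recording <- function(data, fs, grid = rep(1L, nrow(data)), coords = NULL) {
  data <- as.matrix(data)
  if (!is.numeric(data)) stop("recording data must be numeric")
  if (!all(is.finite(data))) stop("recording data contains NaN/Inf")
  if (!is.numeric(fs) || length(fs) != 1 || fs <= 0) stop("fs must be a positive scalar")
  if (length(grid) != nrow(data)) stop("grid must have one entry per channel")
  if (!is.null(coords)) {
    coords <- tibble::as_tibble(coords)
    if (!all(c("channel", "x", "y") %in% names(coords))) {
      stop("coords needs columns channel, x, y")
    }
  }
  structure(
    list(data = data, fs = fs, grid = grid, coords = coords),
    class = "ecog_recording"
  )
}

#' @export
print.ecog_recording <- function(x, ...) {
  cat(sprintf(
    "<ecog_recording> %d channels x %d samples @ %g Hz (%.1f s), %d grid(s)\n",
    nrow(x$data), ncol(x$data), x$fs, ncol(x$data) / x$fs,
    length(unique(x$grid))
  ))
  invisible(x)
}

#' @export
dim.ecog_recording <- function(x) dim(x$data)

# Zero-phase (forward-backward) IIR filtering with odd-extension padding and
# exact steady-state initial conditions, so locally-constant signal ends leave
# no edge transients. The channel mean is routed through the filter's DC gain
# analytically, avoiding the catastrophic cancellation a large offset causes
# in high-pass recursions.
zero_phase <- function(flt, x) {
  b <- flt$b
  a <- flt$a
  nb <- length(b)
  na_ <- length(a)
  p <- 3 * (max(na_, nb) - 1)
  n <- length(x)
  if (n <= p + 1) stop("signal shorter than filter pad length")
  g <- sum(b) / sum(a) # DC gain
  mu <- mean(x)
  xc <- x - mu
  ext <- c(2 * xc[1] - xc[(p + 1):2], xc, 2 * xc[n] - xc[(n - 1):(n - p)])
  one_pass <- function(z) {
    v <- z[1]
    as.numeric(signal::filter(b, a, z,
                              init.x = rep(v, nb - 1),
                              init.y = rep(v * g, na_ - 1)))
  }
  y <- rev(one_pass(rev(one_pass(ext))))
  y[(p + 1):(p + n)] + mu * g * g
}

filtfilt_rows <- function(data, flt) {
  t(apply(data, 1, function(ch) zero_phase(flt, ch)))
}

#' High-pass filter a recording
#'
#' Zero-phase (forward-backward) Butterworth high-pass, removing DC and slow
#' drift before referencing and band-power estimation.
#'
#' @param rec An [new_recording()] object.
#' @param cutoff_hz Cutoff frequency in Hz.
#' @param order Butterworth order (applied forward and backward, so the
#'   effective magnitude response is squared).
#' @return A filtered `ecog_recording`.
#' @export
highpass <- function(rec, cutoff_hz = 0.5, order = 4) {
  stopifnot(inherits(rec, "ecog_recording"))
  if (rec$fs <= 2 * cutoff_hz) stop("sampling rate too low for this cutoff")
  if (ncol(rec$data) < 3 * (order + 1)) stop("signal shorter than filter pad length")
  flt <- signal::butter(order, cutoff_hz / (rec$fs / 2), type = "high")
  rec$data <- filtfilt_rows(rec$data, flt)
  rec
}

# RBJ/Orfanidis second-order digital notch: unit gain away from f0,
# -3 dB bandwidth bw = f0/Q.
design_notch <- function(f0_hz, q, fs) {
  w0 <- 2 * pi * f0_hz / fs
  bw <- w0 / q
  beta <- tan(bw / 2)
  gain <- 1 / (1 + beta)
  b <- gain * c(1, -2 * cos(w0), 1)
  a <- c(1, -2 * gain * cos(w0), 2 * gain - 1)
  signal::Arma(b = b, a = a)
}

#' Notch filter a recording
#'
#' Zero-phase second-order IIR notch. The default removes the 120 Hz power
#' line harmonic, the only line component inside the 70-170 Hz gamma band;
#' 60 Hz and harmonics above 170 Hz are deliberately left untouched.
#'
#' @param rec An `ecog_recording`.
#' @param f0_hz Notch center frequency in Hz.
#' @param q Quality factor q = f0/bandwidth (default 35, bandwidth ~3.4 Hz).
#' @return A filtered `ecog_recording`.
#' @export
notch <- function(rec, f0_hz = 120, q = 35) {
  stopifnot(inherits(rec, "ecog_recording"))
  if (rec$fs <= 2 * f0_hz) stop("sampling rate too low for this notch frequency")
  flt <- design_notch(f0_hz, q, rec$fs)
  rec$data <- filtfilt_rows(rec$data, flt)
  rec
}

#' Common-average reference per grid
#'
#' Subtracts, at every sample, the mean across the channels of each grid
#' from the channels of that grid. Grids are referenced independently, so a
#' shared (common-mode) component within one grid never leaks into another.
#'
#' @param rec An `ecog_recording`.
#' @return A re-referenced `ecog_recording`.
#' @export
car_per_grid <- function(rec) {
  stopifnot(inherits(rec, "ecog_recording"))
  if (anyNA(rec$grid)) stop("every channel must be assigned to a grid")
  for (g in unique(rec$grid)) {
    idx <- which(rec$grid == g)
    mu <- colMeans(rec$data[idx, , drop = FALSE])
    rec$data[idx, ] <- sweep(rec$data[idx, , drop = FALSE], 2, mu)
  }
  rec
}

#' Gamma-band log power
#'
#' Band-pass filters each channel (zero-phase Butterworth), squares the
#' result, and takes the natural log of the instantaneous power. A small
#' floor `eps` (signal-units squared) is added before the log so exact
#' zeros map to `log(eps)` rather than -Inf; the default is far below any
#' physiological power.
#'
#' @param rec An `ecog_recording` (already high-passed, notched and
#'   re-referenced in the standard chain).
#' @param band Band edges in Hz, default `c(70, 170)`.
#' @param order Butterworth order.
#' @param eps Power floor before the log.
#' @return An `ecog_recording` whose `data` holds per-sample log power.
#' @export
gamma_log_power <- function(rec, band = c(70, 170), order = 4, eps = 1e-12) {
  stopifnot(inherits(rec, "ecog_recording"))
  if (rec$fs <= 2 * max(band)) stop("sampling rate too low for this band")
  flt <- signal::butter(order, band / (rec$fs / 2), type = "pass")
  bp <- filtfilt_rows(rec$data, flt)
  rec$data <- log(bp^2 + eps)
  rec
}

#' Standard preprocessing chain
#'
#' Applies, in order: 0.5 Hz high-pass (Butterworth order 4, zero-phase),
#' 120 Hz notch (Q = 35), common-average reference per grid, and 70-170 Hz
#' gamma-band log power.
#'
#' @param rec A raw `ecog_recording`.
#' @inheritParams gamma_log_power
#' @return An `ecog_recording` of per-sample log gamma power.
#' @export
preprocess_recording <- function(rec, band = c(70, 170)) {
  rec |>
    highpass() |>
    notch() |>
    car_per_grid() |>
    gamma_log_power(band = band)
}
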