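# Morlet-wavelet time-frequency decomposition and theta-power extraction.

#' Complex Morlet wavelet
#'
#' Gaussian-windowed complex exponential with `sigma_t = n_cycles / (2 pi f)`
#' and amplitude normalization `A = sigma_t^(-1/2) * pi^(-1/4)`, truncated at
#' `+/- 3 sigma_t` (capped at `max_half` seconds when the epoch is shorter).
#'
#' @param f frequency, Hz.
#' @param n_cycles cycles at this frequency.
#' @param fs sampling rate, Hz.
#' @param max_half maximum half-length in seconds (optional cap).
#' @return complex vector of odd length (centre sample = t 0).
#' @export
morlet_wavelet <- function(f, n_cycles, fs, max_half = Inf) {
  sigma_t <- n_cycles / (2 * pi * f)
  half <- min(3 * sigma_t, max_half)
  t <- seq(-half, half, by = 1 / fs)
  A <- sigma_t^(-1 / 2) * pi^(-1 / 4)
  A * exp(-t^2 / (2 * sigma_t^2)) * exp(2i * pi * f * t)
}

#' Trial-averaged Morlet time-frequency power
#'
#' Convolves every kept trial of `condition` with complex Morlet wavelets
#' (cycles increasing linearly from 3 at the lowest to 10 at the highest
#' frequency by default), averages squared magnitudes over trials and samples
#' the result on a coarse time grid. Grid points closer to an epoch edge than
#' one wavelet half-length are flagged as edge-contaminated per frequency and
#' excluded from window statistics downstream.
#'
#' @param epochs `eeg_epochs`, long enough for the lowest frequency (the task
#'   analysis re-epochs to +/- 1.2 s around onset).
#' @param condition trials to average (`NULL`: all kept trials).
#' @param freqs frequencies, Hz (default 1-18 in 1 Hz bins).
#' @param n_cycles per-frequency cycle counts (default linear 3 to 10).
#' @param t_step output time-bin width, seconds.
#' @param channels channel subset to decompose (default: all).
#' @return object of class `eeg_tfr`: `power` (channels x freqs x times),
#'   `freqs`, `times`, `n_cycles`, `edge` (freqs x times logical),
#'   `baseline_mode` (`"raw"`), `n_trials`, `condition`.
#' @export
morlet_tfr <- function(epochs, condition = NULL, freqs = 1:18,
                       n_cycles = seq(3, 10, length.out = length(freqs)),
                       t_step = 0.05, channels = NULL) {
  stopifnot(length(n_cycles) == length(freqs))
  if (any(freqs >= epochs$fs / 2)) stop("frequency above Nyquist")
  fs <- epochs$fs
  sel <- which(epochs$kept & (if (is.null(condition)) TRUE else
    epochs$condition %in% c(condition, paste0(condition, c("_low", "_high")))))
  if (!length(sel)) stop("no kept trials")
  channels <- channels %||% epochs$channel_labels
  ci <- match(channels, epochs$channel_labels)
  if (anyNA(ci)) stop("unknown channel(s)")
  times_full <- epoch_time_axis(epochs)
  n <- length(times_full)
  epoch_half <- (times_full[n] - times_full[1]) / 2
  t_grid <- seq(ceiling(times_full[1] / t_step) * t_step,
                floor(times_full[n] / t_step) * t_step, by = t_step)
  grid_idx <- vapply(t_grid, function(t0) which.min(abs(times_full - t0)), integer(1))

  nfft <- stats::nextn(2 * n, 2)
  power <- array(0, c(length(ci), length(freqs), length(t_grid)))
  edge <- matrix(FALSE, length(freqs), length(t_grid))
  for (fi in seq_along(freqs)) {
    w <- morlet_wavelet(freqs[fi], n_cycles[fi], fs, max_half = epoch_half)
    L <- length(w); half <- (L - 1) / 2
    half_s <- half / fs
    edge[fi, ] <- (t_grid - times_full[1] < half_s) |
      (times_full[n] - t_grid < half_s)
    W <- stats::fft(c(w, rep(0, nfft - L)))
    for (k in seq_along(ci)) {
      acc <- numeric(length(t_grid))
      for (tr in sel) {
        x <- epochs$data[tr, ci[k], ]
        X <- stats::fft(c(x, rep(0, nfft - n)))
        conv <- stats::fft(X * W, inverse = TRUE) / nfft / fs
        # sample t of the zero-phase convolution sits at full index t + half
        acc <- acc + Mod(conv[grid_idx + half])^2
      }
      power[k, fi, ] <- acc / length(sel)
    }
  }
  structure(list(
    power = power, freqs = freqs, times = t_grid, n_cycles = n_cycles,
    edge = edge, baseline_mode = "raw", n_trials = length(sel),
    condition = condition %||% "all", channel_labels = channels,
    fs = fs
  ), class = "eeg_tfr")
}

#' @export
print.eeg_tfr <- function(x, ...) {
  cat(sprintf(
    "<eeg_tfr> '%s' (%d trials, %s): %d channels x %d freqs (%g-%g Hz) x %d times [%g, %g] s\n",
    x$condition, x$n_trials, x$baseline_mode, length(x$channel_labels),
    length(x$freqs), min(x$freqs), max(x$freqs), length(x$times),
    min(x$times), max(x$times)
  ))
  invisible(x)
}

#' Decibel baseline correction of a time-frequency map
#'
#' Per channel and frequency, divides power by its mean over the baseline
#' window (edge-flagged bins excluded) and takes `10 * log10`. Invariant to
#' global rescaling of the raw signal.
#'
#' @param tfr a raw `eeg_tfr`.
#' @param baseline `(from, to)` seconds.
#' @return the dB-corrected `eeg_tfr` (`baseline_mode = "dB"`).
#' @export
db_baseline <- function(tfr, baseline = c(-0.600, -0.300)) {
  if (tfr$baseline_mode != "raw") stop("tfr already baseline-corrected")
  bl <- time_window_idx(tfr$times, baseline[1], baseline[2])
  if (!length(bl)) stop("baseline outside time range")
  for (fi in seq_along(tfr$freqs)) {
    use <- bl[!tfr$edge[fi, bl]]
    if (!length(use)) { tfr$power[, fi, ] <- NA_real_; next }
    base <- apply(tfr$power[, fi, use, drop = FALSE], 1, mean)
    if (any(base <= 0)) stop("zero baseline power")
    tfr$power[, fi, ] <- 10 * log10(tfr$power[, fi, , drop = FALSE] /
                                      rep(base, times = length(tfr$times)))
  }
  tfr$baseline_mode <- "dB"
  tfr$baseline <- baseline
  tfr
}

#' Extract event-related theta power
#'
#' Means the dB-corrected power over the theta band (4-8 Hz bins, inclusive)
#' and the post-stimulus window (inclusive) at the analysis channel, excluding
#' edge-flagged bins, for the deviant and standard maps and their difference.
#'
#' @param tfr_dev,tfr_std dB-corrected `eeg_tfr` maps.
#' @param channel channel label.
#' @param band `(lo, hi)` Hz, inclusive.
#' @param window `(from, to)` seconds, inclusive.
#' @return list `theta_dev`, `theta_std`, `theta_diff` (dB).
#' @export
extract_theta <- function(tfr_dev, tfr_std, channel, band = c(4, 8),
                          window = c(0.100, 0.300)) {
  if (band[1] >= band[2]) stop("invalid band")
  if (tfr_dev$baseline_mode != "dB" || tfr_std$baseline_mode != "dB") {
    stop("inputs must be dB baseline-corrected")
  }
  one <- function(tfr) {
    ci <- match(channel, tfr$channel_labels)
    if (is.na(ci)) stop("channel not present: ", channel)
    fi <- which(tfr$freqs >= band[1] & tfr$freqs <= band[2])
    ti <- time_window_idx(tfr$times, window[1], window[2])
    if (!length(fi) || !length(ti)) stop("band/window out of range")
    vals <- c()
    for (f in fi) {
      use <- ti[!tfr$edge[f, ti]]
      vals <- c(vals, tfr$power[ci, f, use])
    }
    if (!length(vals)) stop("all requested bins are edge-contaminated")
    mean(vals)
  }
  dev <- one(tfr_dev); std <- one(tfr_std)
  list(theta_dev = dev, theta_std = std, theta_diff = dev - std)
}
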