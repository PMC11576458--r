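# Epoched data container: trials x channels x samples, with per-trial
# condition labels and a monotone kept-mask (rejection only ever flips
# TRUE -> FALSE).

new_epochs <- function(data, fs, tmin, layout, condition, events = NULL,
                       kept = rep(TRUE, dim(data)[1]), bads = character(0),
                       system = attr(layout, "system"), provenance = character(0)) {
  stopifnot(length(dim(data)) == 3, dim(data)[2] == nrow(layout),
            length(condition) == dim(data)[1])
  dimnames(data)[[2]] <- layout$label
  structure(list(
    data = data, fs = fs, tmin = tmin, layout = layout,
    channel_labels = layout$label, condition = condition,
    events = events, kept = kept, bads = bads, system = system,
    provenance = provenance
  ), class = "eeg_epochs")
}

#' @export
print.eeg_epochs <- function(x, ...) {
  d <- dim(x$data)
  cat(sprintf(
    "<eeg_epochs> %d trials (%d kept) x %d channels x %d samples @ %g Hz, t = [%.3f, %.3f) s\n",
    d[1], sum(x$kept), d[2], d[3], x$fs, x$tmin, x$tmin + d[3] / x$fs
  ))
  tab <- table(x$condition)
  cat("  conditions:", paste(sprintf("%s=%d", names(tab), tab), collapse = ", "), "\n")
  if (length(x$provenance)) cat("  steps:", paste(x$provenance, collapse = " -> "), "\n")
  invisible(x)
}

epoch_time_axis <- function(epochs) {
  epoch_times(epochs$tmin, dim(epochs$data)[3], epochs$fs)
}

log_step <- function(x, step) {
  x$provenance <- c(x$provenance, step)
  x
}

#' Cut a continuous recording into epochs
#'
#' Task mode (`events` given): one epoch per stimulus event spanning
#' `[tmin, tmax)` seconds around onset (half-open sample convention, so a
#' -0.1 to 0.5 s epoch at 1024 Hz has exactly 614 samples). Events whose
#' epoch would run past either end of the recording are dropped with a
#' warning. Rest mode (`events = NULL`): consecutive non-overlapping windows
#' of `rest_len` seconds; the remainder is dropped.
#'
#' @param rec an [eeg_recording()].
#' @param events an [oddball_sequence()] or `NULL` for rest.
#' @param tmin,tmax epoch window in seconds relative to stimulus onset.
#' @param rest_len rest epoch length in seconds.
#' @return an `eeg_epochs` object; task epochs carry the tone label as
#'   condition plus the habituation / follows-deviant flags, rest epochs are
#'   labelled `"rest"`.
#' @export
epoch_recording <- function(rec, events = rec$events, tmin = -0.1, tmax = 0.5,
                            rest_len = 8) {
  fs <- rec$fs
  n_total <- ncol(rec$data)
  if (is.null(events)) {
    n <- n_epoch_samples(0, rest_len, fs)
    n_ep <- floor(n_total / n)
    if (n_ep < 1) stop("recording shorter than one rest epoch")
    data <- array(0, c(n_ep, nrow(rec$data), n))
    for (i in seq_len(n_ep)) {
      data[i, , ] <- rec$data[, ((i - 1) * n + 1):(i * n)]
    }
    ep <- new_epochs(data, fs, 0, rec$layout, rep("rest", n_ep),
                     bads = rec$bads,
                     provenance = c(attr(rec, "provenance") %||% character(0)))
  } else {
    n <- n_epoch_samples(tmin, tmax, fs)
    first <- events$onset_sample + round(tmin * fs)
    ok <- first >= 1 & first + n - 1 <= n_total
    if (any(!ok)) warning(sprintf("%d events outside recording bounds dropped", sum(!ok)))
    events <- events[ok, , drop = FALSE]
    if (nrow(events) == 0) stop("no events within recording bounds")
    data <- array(0, c(nrow(events), nrow(rec$data), n))
    for (i in seq_len(nrow(events))) {
      s0 <- events$onset_sample[i] + round(tmin * fs)
      data[i, , ] <- rec$data[, s0:(s0 + n - 1)]
    }
    ep <- new_epochs(data, fs, tmin, rec$layout, events$tone, events = events,
                     bads = rec$bads,
                     provenance = c(attr(rec, "provenance") %||% character(0)))
  }
  ep$system <- rec$system
  log_step(ep, "epoch")
}

#' Resample epochs by an integer factor
#'
#' Downsamples to `target_fs` (which must divide `fs`) by zero-phase
#' frequency-domain anti-alias filtering (raised-cosine roll-off from 80% of
#' the new Nyquist) followed by decimation. Event-relative timing of the first
#' sample is preserved.
#'
#' @param epochs an `eeg_epochs`.
#' @param target_fs new sampling rate, Hz; `target_fs == fs` is the identity.
#' @return resampled `eeg_epochs`.
#' @export
resample_epochs <- function(epochs, target_fs = 512) {
  if (target_fs > epochs$fs) stop("upsampling is not supported")
  if (target_fs == epochs$fs) return(epochs)
  q <- epochs$fs / target_fs
  if (abs(q - round(q)) > 1e-9) stop("fs / target_fs must be an integer")
  q <- round(q)
  d <- dim(epochs$data)
  n <- d[3]
  flat <- matrix(aperm(epochs$data, c(3, 1, 2)), nrow = n)  # samples x (trials*channels)
  filt <- fft_lowpass_matrix(flat, epochs$fs, 0.8 * target_fs / 2, target_fs / 2)
  keep <- seq(1, n, by = q)
  out <- array(aperm(array(filt[keep, ], c(length(keep), d[1], d[2])), c(2, 3, 1)),
               c(d[1], d[2], length(keep)))
  epochs$data <- out
  dimnames(epochs$data)[[2]] <- epochs$channel_labels
  epochs$fs <- target_fs
  log_step(epochs, sprintf("resample:%g", target_fs))
}

# zero-phase low-pass on the columns of a samples x series matrix:
# unity below f_pass, raised-cosine to zero at f_stop. Columns are
# reflection-padded to a power-of-two FFT length (fast and non-circular).
fft_lowpass_matrix <- function(m, fs, f_pass, f_stop) {
  n <- nrow(m)
  np <- stats::nextn(n, 2)
  if (np > n) {
    k <- min(np - n, n - 1)
    pad <- 2 * m[rep(n, k), , drop = FALSE] - m[n - seq_len(k), , drop = FALSE]
    if (k < np - n) pad <- rbind(pad, matrix(0, np - n - k, ncol(m)))
    mp <- rbind(m, pad)
  } else {
    mp <- m
  }
  f <- seq(0, fs - fs / np, by = fs / np)
  f <- pmin(f, fs - f)
  gain <- rep(1, np)
  trans <- f > f_pass & f < f_stop
  gain[trans] <- 0.5 * (1 + cos(pi * (f[trans] - f_pass) / (f_stop - f_pass)))
  gain[f >= f_stop] <- 0
  out <- Re(stats::mvfft(stats::mvfft(mp) * gain, inverse = TRUE)) / np
  out[seq_len(n), , drop = FALSE]
}
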