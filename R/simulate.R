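# Synthetic paired-system EEG: oddball task and resting-state recordings with
# known injected effects (see ground_truth()).

# 1/f-shaped Gaussian noise, one row per channel, scaled to a target RMS.
# Shaping is done in the frequency domain: white noise spectra are multiplied
# by f^(-exponent/2) (amplitude), DC excluded. Draws from the caller's RNG.
noise_1f <- function(n_channels, n_samples, fs, rms_scale, exponent = 1) {
  if (rms_scale <= 0 || n_channels == 0) {
    return(matrix(0, n_channels, n_samples))
  }
  # generate on a power-of-two grid (mixed-radix FFTs are slow on awkward
  # lengths) and keep the first n_samples
  m <- stats::nextn(n_samples, 2)
  freqs <- seq(0, fs - fs / m, by = fs / m)
  half <- freqs > 0 & freqs <= fs / 2
  shape <- numeric(m)
  shape[half] <- freqs[half]^(-exponent / 2)
  # mirror onto negative frequencies for a real signal
  idx <- which(half)
  shape[m + 2 - idx[idx > 1]] <- shape[idx[idx > 1]]
  out <- matrix(0, n_channels, n_samples)
  for (ch in seq_len(n_channels)) {
    X <- stats::fft(stats::rnorm(m)) * shape
    x <- Re(stats::fft(X, inverse = TRUE) / m)[seq_len(n_samples)]
    out[ch, ] <- x / rms(x) * rms_scale
  }
  out
}

# RMS of a signal restricted to a frequency band, via Parseval on the FFT of
# its leading power-of-two portion (an estimate; avoids slow FFT lengths).
band_rms_fft <- function(x, fs, lo, hi) {
  n <- 2^floor(log2(length(x)))
  X <- stats::fft(x[seq_len(n)]) / n
  f <- seq(0, fs - fs / n, by = fs / n)
  f <- pmin(f, fs - f)  # two-sided
  sqrt(sum(Mod(X[f >= lo & f <= hi])^2))
}

# obligatory auditory response added to every tone (difference of Gaussians:
# N1-like trough at 100 ms, P2-like peak at 200 ms)
template_evoked <- function(t, truth) {
  truth$n1_amplitude * exp(-(t - 0.100)^2 / (2 * 0.030^2)) +
    truth$p2_amplitude * exp(-(t - 0.200)^2 / (2 * 0.045^2))
}

# deviant-only mismatch component: Gaussian of full width `mmn_width`
template_mmn <- function(t, truth) {
  sd <- truth$mmn_width / 2
  truth$mmn_amplitude * exp(-(t - truth$mmn_latency)^2 / (2 * sd^2))
}

blink_envelope <- function(fs, duration = 0.3) {
  n <- round(duration * fs)
  sin(pi * (seq_len(n) - 0.5) / n)
}

# blink forward gains onto scalp channels: 0.3 at the eyes, decaying with
# chord distance from the left-eye pole
blink_gains <- function(layout) {
  eye <- grid_position(85, -20)
  d <- sqrt((layout$x - eye["x"])^2 + (layout$y - eye["y"])^2 + (layout$z - eye["z"])^2)
  g <- 0.3 * exp(-d / 0.6)
  g[layout$type != "scalp"] <- 0
  g
}

#' Simulate an oddball task recording
#'
#' Generates a continuous multichannel recording at 1024 Hz implementing the
#' injected effects of a [ground_truth()] object: 1/f background noise at the
#' system's noise floor, an N1/P2-like response to every tone at fronto-central
#' channels, a negative mismatch deflection plus a 4-8 Hz burst added to
#' deviant tones, seeded blinks on the EOG channels propagated to frontal
#' scalp sites, and - for the dry system - seeded step ("jump") artifacts.
#'
#' @param seq an [oddball_sequence()].
#' @param truth an [ground_truth()] object.
#' @param layout layout name (see [channel_layout()]) or a layout data.frame.
#' @param system `"wet"` or `"dry"`.
#' @param duration_pad seconds of recording kept after the last stimulus onset.
#' @param seed integer seed; identical seeds give bit-identical recordings.
#' @param blinks set `FALSE` to disable ocular artifacts.
#' @return an [eeg_recording()] with the sequence attached as `events`.
#' @export
simulate_task_recording <- function(seq, truth, layout = "wet64",
                                    system = c("wet", "dry"),
                                    duration_pad = 2, seed = 1L,
                                    blinks = TRUE) {
  system <- match.arg(system)
  if (is.character(layout)) layout <- channel_layout(layout)
  if (nrow(seq) == 0) stop("sequence must be non-empty")
  if (sum(layout$type == "scalp") < 8) stop("layout must provide >= 8 scalp channels")
  fs <- 1024
  # pad both ends so that wide analysis epochs around the first/last tone fit
  seq$onset_s <- seq$onset_s + duration_pad
  seq$onset_sample <- seq$onset_sample + round(duration_pad * fs)
  n_samples <- round((max(seq$onset_s) + duration_pad) * fs)
  n_ch <- nrow(layout)
  scale <- truth$noise_scale[[system]]

  with_seed(seed, {
    data <- noise_1f(n_ch, n_samples, fs, scale, truth$noise_exponent)
    # mastoids: quieter (they sit off the scalp noise field and act as reference)
    data[layout$type == "mastoid", ] <- data[layout$type == "mastoid", ] * 0.5

    fc <- attr(layout, "frontocentral")
    fc_idx <- match(names(fc), layout$label)
    t_resp <- seq(0, 0.5 - 1 / fs, by = 1 / fs)
    ev_base <- template_evoked(t_resp, truth)
    ev_mmn <- template_mmn(t_resp, truth)
    n_resp <- length(t_resp)

    # deviant theta burst calibrated against the background theta floor at the
    # analysis channel: burst RMS^2 = floor RMS^2 * (10^(gain/10) - 1)
    mmn_ch <- match(attr(layout, "mmn_channel"), layout$label)
    theta_floor <- band_rms_fft(data[mmn_ch, ], fs, 4, 8)
    burst_amp <- theta_floor * sqrt(2 * (10^(truth$theta_burst_gain / 10) - 1))
    burst_idx <- which(t_resp >= 0.1 & t_resp <= 0.3)
    burst_env <- sin(pi * seq(0, 1, length.out = length(burst_idx)))

    for (k in seq_len(nrow(seq))) {
      s0 <- seq$onset_sample[k]
      if (s0 + n_resp - 1 > n_samples) next
      idx <- s0:(s0 + n_resp - 1)
      wave <- ev_base
      if (seq$tone[k] != "standard") {
        wave <- wave + ev_mmn
        if (burst_amp > 0) {
          burst <- numeric(n_resp)
          burst[burst_idx] <- burst_amp * burst_env *
            sin(2 * pi * 6 * t_resp[burst_idx] + stats::runif(1, 0, 2 * pi))
          wave <- wave + burst
        }
      }
      data[fc_idx, idx] <- data[fc_idx, idx] + outer(unname(fc), wave)
    }

    if (blinks && truth$blink_rate > 0) {
      n_blinks <- stats::rpois(1, truth$blink_rate * n_samples / fs)
      env <- blink_envelope(fs)
      gains <- blink_gains(layout)
      emap <- attr(layout, "eog_map")
      above <- match("EOGa", layout$label)
      below <- match("EOGb", layout$label)
      if (n_blinks > 0) {
        starts <- sort(sample.int(n_samples - length(env), n_blinks))
        for (s0 in starts) {
          idx <- s0:(s0 + length(env) - 1)
          amp <- 100e-6 * stats::runif(1, 0.8, 1.2)
          if (!is.na(above)) data[above, idx] <- data[above, idx] + amp / 2 * env
          if (!is.na(below)) data[below, idx] <- data[below, idx] - amp / 2 * env
          data[, idx] <- data[, idx] + outer(gains * amp, env)
        }
      }
    }

    if (system == "dry" && truth$jump_rate > 0) {
      n_jumps <- stats::rpois(1, truth$jump_rate * n_samples / fs / 60)
      scalp_idx <- which(layout$type == "scalp")
      for (j in seq_len(n_jumps)) {
        ch <- sample(scalp_idx, 1)
        dur <- round(stats::runif(1, 0.5, 2) * fs)
        s0 <- sample.int(max(1, n_samples - dur), 1)
        amp <- sample(c(-1, 1), 1) * stats::runif(1, 200e-6, 500e-6)
        data[ch, s0:(s0 + dur - 1)] <- data[ch, s0:(s0 + dur - 1)] + amp
      }
    }

    eeg_recording(data, fs, layout, system = system, events = seq,
                  reference = "mastoid (recording)")
  })
}

# brick-wall narrowband noise within [lo, hi] Hz, unit RMS; generated on a
# power-of-two grid and truncated
narrowband_noise <- function(n_samples, fs, lo, hi) {
  m <- stats::nextn(n_samples, 2)
  X <- stats::fft(stats::rnorm(m))
  f <- seq(0, fs - fs / m, by = fs / m)
  f <- pmin(f, fs - f)
  X[f < lo | f > hi] <- 0
  x <- Re(stats::fft(X, inverse = TRUE) / m)[seq_len(n_samples)]
  x / rms(x)
}

# delay x by a constant phase `lag` (radians) at all frequencies, via rotation
# of its analytic signal; positive lag means the output lags x
phase_shift <- function(x, lag) Re(analytic_signal(x) * exp(-1i * lag))

#' Simulate a resting-state recording with known phase-coupling structure
#'
#' Each scalp channel is a sum over the four analysis bands (delta 0.5-4,
#' theta 4-8, alpha 8-13, beta 13-20 Hz) of a narrow-band noise oscillator,
#' plus a weak 1/f floor at the system's noise scale. For every channel pair
#' listed in `truth$resting_phase_lags[[band]]` (indices into the scalp
#' channel set), the receiving channel's band component mixes a
#' constant-phase-lagged copy of the sending channel's component (weight
#' `coupling`) with independent narrow-band noise (weight `1 - coupling`), so
#' the pairwise phase lag index has a known, monotonically coupled target.
#'
#' @inheritParams simulate_task_recording
#' @param duration seconds (>= 16, i.e. at least two 8 s epochs).
#' @return an [eeg_recording()] without events.
#' @export
simulate_rest_recording <- function(truth, layout = "wet64",
                                    system = c("wet", "dry"),
                                    duration = 300, seed = 1L) {
  system <- match.arg(system)
  if (is.character(layout)) layout <- channel_layout(layout)
  if (duration < 16) stop("duration must be >= 16 s (two 8 s epochs)")
  fs <- 1024
  n_samples <- round(duration * fs)
  n_ch <- nrow(layout)
  scalp_idx <- which(layout$type == "scalp")
  bands <- band_definitions()
  # per-band RMS mix (volts): alpha-dominant spectrum typical of eyes-open rest
  band_amp <- c(delta = 4e-6, theta = 3e-6, alpha = 6e-6, beta = 2e-6)

  with_seed(seed, {
    data <- noise_1f(n_ch, n_samples, fs, truth$noise_scale[[system]] * 0.25,
                     truth$noise_exponent)
    data[layout$type == "mastoid", ] <- data[layout$type == "mastoid", ] * 0.5
    for (b in names(bands)) {
      lo <- bands[[b]][1]; hi <- bands[[b]][2]
      comp <- matrix(0, length(scalp_idx), n_samples)
      for (i in seq_along(scalp_idx)) {
        comp[i, ] <- narrowband_noise(n_samples, fs, lo, hi)
      }
      pairs <- truth$resting_phase_lags[[b]]
      if (!is.null(pairs) && nrow(pairs)) {
        for (r in seq_len(nrow(pairs))) {
          i <- pairs$ch1[r]; j <- pairs$ch2[r]
          if (max(i, j) > length(scalp_idx)) next
          c_ij <- pairs$coupling[r]
          lagged <- phase_shift(comp[i, ], pairs$lag[r])
          comp[j, ] <- c_ij * lagged + sqrt(max(0, 1 - c_ij^2)) * comp[j, ]
        }
      }
      data[scalp_idx, ] <- data[scalp_idx, ] + band_amp[[b]] * comp
    }
    eeg_recording(data, fs, layout, system = system,
                  reference = "mastoid (recording)")
  })
}

#' Simulate one subject's paired wet/dry session
#'
#' Convenience wrapper generating, per system, an oddball task recording and a
#' resting-state recording from a single subject-level seed. All stage seeds
#' are derived deterministically from `seed` and `subject_id`.
#'
#' @param subject_id integer or string identifier.
#' @param truth a [ground_truth()].
#' @param systems character vector among `"wet"`, `"dry"`.
#' @param seq an [oddball_sequence()]; the same tone order is used for both
#'   systems (as in a cross-over session the order differs, but sharing it
#'   keeps the paired comparison tight; pass per-system sequences by calling
#'   [simulate_task_recording()] directly).
#' @param rest_duration rest length in seconds.
#' @param seed study master seed.
#' @return nested list `[[system]]$task` / `$rest` of [eeg_recording()]s.
#' @export
simulate_subject <- function(subject_id, truth, systems = c("wet", "dry"),
                             seq = oddball_sequence(seed = derive_seed(seed, subject_id, "seq")),
                             rest_duration = 300, seed = 1L) {
  out <- list()
  for (sys in systems) {
    lay <- if (sys == "wet") "wet64" else "dry64"
    out[[sys]] <- list(
      task = simulate_task_recording(
        seq, truth, layout = lay, system = sys,
        seed = derive_seed(seed, subject_id, sys, "task")
      ),
      rest = simulate_rest_recording(
        truth, layout = lay, system = sys, duration = rest_duration,
        seed = derive_seed(seed, subject_id, sys, "rest")
      )
    )
  }
  out
}
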