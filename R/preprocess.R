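# Preprocessing chain, in the order applied by the analysis:
# re-reference -> bad-channel detection -> band-pass -> epoch -> resample ->
# EOG derivation -> ICA -> interpolation -> peak-to-peak rejection.

#' Re-reference a recording to the average of the two mastoids
#'
#' Subtracts the mean of the mastoid channels from every scalp and EOG
#' channel. Mastoid channels themselves are retained (flagged by channel type
#' in the layout). Idempotent up to the mastoids' own mean: applying it twice
#' equals applying it once because the re-referenced mastoid average is zero.
#'
#' @param rec an [eeg_recording()].
#' @param on_missing `"error"` (default) or `"skip"` (return the input with a
#'   warning) when the layout has no mastoid pair.
#' @return the re-referenced recording.
#' @export
rereference_mastoids <- function(rec, on_missing = c("error", "skip")) {
  on_missing <- match.arg(on_missing)
  m <- attr(rec$layout, "mastoids") %||% rec$layout$label[rec$layout$type == "mastoid"]
  m <- intersect(m, rec$channel_labels)
  if (length(m) < 2) {
    if (on_missing == "error") stop("mastoid channels missing")
    warning("mastoid channels missing; skipping re-referencing")
    return(rec)
  }
  ref <- colMeans(rec$data[m, , drop = FALSE])
  keep <- !(rec$channel_labels %in% m)
  rec$data[keep, ] <- sweep(rec$data[keep, , drop = FALSE], 2, ref)
  rec$data[m, ] <- sweep(rec$data[m, , drop = FALSE], 2, ref)
  rec$reference <- "average mastoids"
  attr(rec, "provenance") <- c(attr(rec, "provenance"), "rereference:mastoids")
  rec
}

#' Flag flat or outlying channels
#'
#' Automated surrogate for visual bad-channel marking: a scalp channel is
#' flagged when its RMS falls below `flat_threshold` (dead channel) or when
#' the robust z-score of its log-RMS (median/MAD over scalp channels) exceeds
#' `z_threshold` in absolute value (noisy or disconnected channel).
#'
#' @param rec an [eeg_recording()].
#' @param flat_threshold volts RMS below which a channel counts as flat.
#' @param z_threshold robust z cut-off on log-RMS.
#' @return character vector of flagged channel labels (possibly empty).
#' @export
detect_bad_channels <- function(rec, flat_threshold = 1e-7, z_threshold = 5) {
  scalp <- scalp_channels(rec)
  r <- apply(rec$data[scalp, , drop = FALSE], 1, rms)
  flat <- r < flat_threshold
  lr <- log(pmax(r, .Machine$double.xmin))
  med <- stats::median(lr[!flat])
  s <- stats::mad(lr[!flat])
  z <- if (s > 0) (lr - med) / s else rep(0, length(lr))
  scalp[flat | abs(z) > z_threshold]
}

#' Zero-phase FIR band-pass filter
#'
#' Applies a Hamming-window FIR band-pass as a high-pass / low-pass cascade
#' with independent transition bandwidths (defaults: 0.1 Hz at the low edge,
#' 6 Hz at the high edge, so the 0.1-25 Hz analysis band keeps 50 Hz mains
#' more than 20 dB down one octave above the edge). Kernels are linear-phase
#' and applied by FFT convolution with reflection padding and group-delay
#' compensation, giving a zero-phase response. Kernel length is 3.3 /
#' transition-bandwidth seconds, capped at a third of the signal.
#'
#' @param x an [eeg_recording()] or `eeg_epochs`.
#' @param low,high band edges in Hz (`0 < low < high < fs/2`).
#' @param tbw_low,tbw_high transition bandwidths, Hz.
#' @return object of the same class, filtered per channel.
#' @export
eeg_bandpass <- function(x, low = 0.1, high = 25, tbw_low = 0.1, tbw_high = 6) {
  UseMethod("eeg_bandpass")
}

#' @export
eeg_bandpass.eeg_recording <- function(x, low = 0.1, high = 25,
                                       tbw_low = 0.1, tbw_high = 6) {
  check_band(low, high, x$fs)
  x$data <- t(fir_bandpass_matrix(t(x$data), x$fs, low, high, tbw_low, tbw_high))
  attr(x, "provenance") <- c(attr(x, "provenance"), sprintf("bandpass:%g-%g", low, high))
  x
}

#' @export
eeg_bandpass.eeg_epochs <- function(x, low = 0.1, high = 25,
                                    tbw_low = 0.1, tbw_high = 6) {
  check_band(low, high, x$fs)
  d <- dim(x$data)
  flat <- matrix(aperm(x$data, c(3, 1, 2)), nrow = d[3])
  flat <- fir_bandpass_matrix(flat, x$fs, low, high, tbw_low, tbw_high)
  x$data <- aperm(array(flat, c(d[3], d[1], d[2])), c(2, 3, 1))
  dimnames(x$data)[[2]] <- x$channel_labels
  log_step(x, sprintf("bandpass:%g-%g", low, high))
}

check_band <- function(low, high, fs) {
  if (!(low > 0 && low < high && high < fs / 2)) {
    stop("band edges must satisfy 0 < low < high < fs/2")
  }
}

# columns of m are series; returns filtered columns. The high-pass and
# low-pass kernels are combined by convolution into one symmetric band-pass
# kernel so the data is traversed once.
fir_bandpass_matrix <- function(m, fs, low, high, tbw_low, tbw_high) {
  hp <- fir_kernel(fs, low, "high", tbw_low, nrow(m))
  lp <- fir_kernel(fs, high, "low", tbw_high, nrow(m))
  nf <- stats::nextn(length(hp) + length(lp) - 1, 2)
  bp <- Re(stats::fft(stats::fft(c(hp, rep(0, nf - length(hp)))) *
                        stats::fft(c(lp, rep(0, nf - length(lp)))),
                      inverse = TRUE) / nf)[seq_len(length(hp) + length(lp) - 1)]
  fir_apply(m, bp)
}

fir_kernel <- function(fs, cutoff, type, tbw, n_samples) {
  len <- round(3.3 / tbw * fs)
  len <- min(len, max(3, floor((n_samples - 1) / 3)))
  if (len %% 2 == 0) len <- len + 1  # odd => symmetric, integer group delay
  signal::fir1(len - 1, cutoff / (fs / 2), type = type,
               window = signal::hamming(len))
}

# zero-phase application of a symmetric odd-length kernel to the columns of m,
# with reflection padding of half the kernel length at both ends. Columns are
# processed in blocks to bound the size of the complex FFT workspace.
fir_apply <- function(m, b, block = 8L) {
  L <- length(b)
  half <- (L - 1) / 2
  n <- nrow(m)
  pad_top <- m[rev(seq_len(min(half, n - 1))) + 1, , drop = FALSE]
  pad_bot <- m[n - seq_len(min(half, n - 1)), , drop = FALSE]
  mp <- rbind(pad_top, m, pad_bot)
  np <- nrow(mp)
  nfft <- stats::nextn(np + L - 1, 2)
  B <- stats::fft(c(b, rep(0, nfft - L)))
  start <- nrow(pad_top) + half + 1
  out <- m
  for (j0 in seq(1, ncol(m), by = block)) {
    cols <- j0:min(ncol(m), j0 + block - 1)
    MP <- stats::mvfft(rbind(mp[, cols, drop = FALSE],
                             matrix(0, nfft - np, length(cols))))
    conv <- Re(stats::mvfft(MP * B, inverse = TRUE)) / nfft
    out[, cols] <- conv[start:(start + n - 1), , drop = FALSE]
  }
  out
}

#' Derive bipolar EOG channels
#'
#' Adds `vEOG` and `hEOG` channels by re-referencing the layout's periocular
#' electrodes against their partners (wet: above-eye minus below-eye, lateral
#' minus F7; dry: below-eye and lateral electrodes each against their frontal
#' grid references). The raw EOG electrodes are removed from the channel set.
#'
#' @param x [eeg_recording()] or `eeg_epochs`.
#' @return same class with `vEOG`/`hEOG` appended and raw EOG channels dropped.
#' @export
derive_bipolar_eog <- function(x) {
  layout <- x$layout
  emap <- attr(layout, "eog_map")
  if (is.null(emap)) stop("layout carries no EOG derivation map")
  need <- unlist(emap)
  missing <- setdiff(need, x$channel_labels)
  if (length(missing)) stop("missing channels for EOG derivation: ",
                            paste(missing, collapse = ", "))
  ch <- function(lab) match(lab, x$channel_labels)
  is_rec <- inherits(x, "eeg_recording")
  pick <- function(lab) if (is_rec) x$data[ch(lab), ] else x$data[, ch(lab), ]
  veog <- pick(emap$veog[1]) - pick(emap$veog[2])
  heog <- pick(emap$heog[1]) - pick(emap$heog[2])

  drop <- which(layout$type == "eog")
  new_layout <- rbind(
    layout[-drop, ],
    data.frame(label = c("vEOG", "hEOG"), x = 0, y = 1, z = 0,
               type = "eog_derived", stringsAsFactors = FALSE)
  )
  for (a in c("system", "mmn_channel", "frontocentral", "eog_map", "mastoids")) {
    attr(new_layout, a) <- attr(layout, a)
  }
  if (is_rec) {
    x$data <- rbind(x$data[-drop, , drop = FALSE], vEOG = veog, hEOG = heog)
    attr(x, "provenance") <- c(attr(x, "provenance"), "eog:bipolar")
  } else {
    d <- dim(x$data)
    nd <- array(0, c(d[1], d[2] - length(drop) + 2, d[3]))
    nd[, seq_len(d[2] - length(drop)), ] <- x$data[, -drop, , drop = FALSE]
    nd[, d[2] - length(drop) + 1, ] <- veog
    nd[, d[2] - length(drop) + 2, ] <- heog
    x$data <- nd
    x <- log_step(x, "eog:bipolar")
  }
  x$layout <- new_layout
  x$channel_labels <- new_layout$label
  if (!is_rec) dimnames(x$data)[[2]] <- new_layout$label
  if (is_rec) rownames(x$data) <- new_layout$label
  x
}

#' Reject trials on peak-to-peak amplitude
#'
#' Marks any kept trial whose maximum peak-to-peak amplitude across scalp
#' channels exceeds `threshold` as rejected (`kept = FALSE`; the mask is
#' monotone). The default keeps the published threshold of 150 mV literally;
#' `ptp_uv_preset()` returns the 150 µV value a practitioner would use.
#'
#' @param epochs an `eeg_epochs`.
#' @param threshold volts peak-to-peak.
#' @return list with elements `epochs` (updated mask) and `n_rejected`.
#' @export
reject_epochs_ptp <- function(epochs, threshold = 0.15) {
  if (threshold < 0) stop("threshold must be >= 0")
  scalp <- intersect(scalp_channels(epochs), epochs$channel_labels)
  idx <- match(scalp, epochs$channel_labels)
  bad <- logical(dim(epochs$data)[1])
  for (i in which(epochs$kept)) {
    seg <- epochs$data[i, idx, , drop = FALSE]
    ptp <- max(apply(seg[1, , , drop = TRUE], 1, function(v) diff(range(v))))
    bad[i] <- ptp > threshold
  }
  n_rej <- sum(bad & epochs$kept)
  epochs$kept <- epochs$kept & !bad
  epochs <- log_step(epochs, sprintf("ptp_reject:%g", threshold))
  list(epochs = epochs, n_rejected = n_rej)
}

#' @rdname reject_epochs_ptp
#' @export
ptp_uv_preset <- function() 150e-6

#' Preprocess one recording end to end
#'
#' Runs the full chain in its fixed order (re-reference to average mastoids,
#' automated bad-channel detection, 0.1-25 Hz band-pass, epoching, resampling
#' to 512 Hz, bipolar EOG derivation, EOG-correlated ICA component rejection,
#' spherical-spline interpolation of bad channels, and - for task data -
#' peak-to-peak trial rejection) and returns the cleaned epochs plus a
#' report. Inclusion (`report$included`) additionally requires the
#' plus-minus SNR computed downstream; [apply_inclusion_rule()] finalizes it.
#'
#' @param rec an [eeg_recording()] (task recordings must carry `events`).
#' @param mode `"task"` or `"rest"`.
#' @param params list of thresholds; see [preproc_defaults()].
#' @param seed seed for the ICA initialisation.
#' @return list `epochs` (cleaned `eeg_epochs`) and `report` (fields
#'   `n_channels_rejected`, `n_components_rejected`, `n_trials_rejected`,
#'   `fraction_trials_retained`, `included`, `reasons`).
#' @export
preprocess_recording <- function(rec, mode = c("task", "rest"),
                                 params = preproc_defaults(), seed = 1L) {
  mode <- match.arg(mode)
  rec <- rereference_mastoids(rec)
  bads <- detect_bad_channels(rec, params$flat_threshold, params$z_threshold)
  rec$bads <- bads
  rec <- eeg_bandpass(rec, params$band[1], params$band[2])
  epochs <- if (mode == "task") {
    epoch_recording(rec, rec$events, params$tmin, params$tmax)
  } else {
    epoch_recording(rec, NULL, rest_len = params$rest_len)
  }
  epochs <- resample_epochs(epochs, params$target_fs)
  epochs <- derive_bipolar_eog(epochs)
  ica <- ica_reject_eog(epochs, n_components = params$ica_components,
                        corr_threshold = params$ica_corr_threshold, seed = seed)
  epochs <- ica$epochs
  epochs <- interpolate_bad_channels(epochs, bads)
  n_trials_rejected <- 0L
  if (mode == "task") {
    pr <- reject_epochs_ptp(epochs, params$ptp_threshold)
    epochs <- pr$epochs
    n_trials_rejected <- pr$n_rejected
  }
  frac <- mean(epochs$kept)
  report <- list(
    n_channels_rejected = length(bads),
    n_components_rejected = ica$n_rejected,
    n_trials_rejected = n_trials_rejected,
    fraction_trials_retained = frac,
    included = NA,  # finalized once SNR is known (task) / trivially (rest)
    snr = NA_real_,
    reasons = character(0)
  )
  list(epochs = epochs, report = report)
}

#' Default preprocessing parameters
#'
#' `ptp_threshold` defaults to the 150 µV practitioner preset; pass
#' `0.15` to use the published 150 mV value literally.
#' @return named list of thresholds used by [preprocess_recording()].
#' @export
preproc_defaults <- function() {
  list(
    band = c(0.1, 25),
    tmin = -0.1, tmax = 0.5,
    rest_len = 8,
    target_fs = 512,
    flat_threshold = 1e-7, z_threshold = 5,
    ica_components = 15, ica_corr_threshold = 0.2,
    ptp_threshold = ptp_uv_preset()
  )
}

#' Finalize the subject-inclusion decision
#'
#' A subject's task data enters the analysis only with more than 70% of
#' trials retained and a plus-minus SNR above 1.
#'
#' @param report a report from [preprocess_recording()].
#' @param snr the subject's plus-minus SNR.
#' @param min_fraction,min_snr inclusion thresholds.
#' @return the report with `included`, `snr` and `reasons` filled in.
#' @export
apply_inclusion_rule <- function(report, snr, min_fraction = 0.7, min_snr = 1) {
  report$snr <- snr
  reasons <- character(0)
  if (!(report$fraction_trials_retained > min_fraction)) {
    reasons <- c(reasons, sprintf("trials retained %.2f <= %.2f",
                                  report$fraction_trials_retained, min_fraction))
  }
  if (!(snr > min_snr)) {
    reasons <- c(reasons, sprintf("SNR %.2f <= %g", snr, min_snr))
  }
  report$included <- length(reasons) == 0
  report$reasons <- reasons
  report
}
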