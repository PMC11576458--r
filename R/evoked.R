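# Condition-wise ERPs, mismatch-negativity metrics and the plus-minus SNR.

#' Select and equalize trials for ERP averaging
#'
#' Applies the averaging exclusions: habituation standards and standards
#' immediately following a deviant are dropped; both deviant types are pooled
#' into a single `"deviant"` condition (per-type analysis via
#' `pool_deviants = FALSE`); the larger condition is then subsampled (seeded,
#' uniform, without replacement) so standard and deviant counts match. When
#' comparing systems, pass `n_per_condition` (e.g. the minimum equalized
#' count across systems) to equalize across systems as well.
#'
#' @param epochs task `eeg_epochs` whose `events` carry the habituation and
#'   follows-deviant flags.
#' @param seed seed for the subsampling.
#' @param n_per_condition optional cap on the per-condition count.
#' @param pool_deviants pool `deviant_low`/`deviant_high` into `"deviant"`.
#' @return `eeg_epochs` with non-selected trials removed from the kept mask
#'   and pooled condition labels.
#' @export
select_trials <- function(epochs, seed = 1L, n_per_condition = NULL,
                          pool_deviants = TRUE) {
  ev <- epochs$events
  if (is.null(ev)) stop("epochs carry no event table")
  cond <- epochs$condition
  if (pool_deviants) cond[cond %in% c("deviant_low", "deviant_high")] <- "deviant"
  eligible <- epochs$kept & !ev$is_habituation &
    !(cond == "standard" & ev$follows_deviant)
  conds <- if (pool_deviants) c("standard", "deviant") else
    c("standard", "deviant_low", "deviant_high")
  counts <- vapply(conds, function(cc) sum(eligible & cond == cc), integer(1))
  if (any(counts == 0)) {
    stop("no trials left in condition(s): ", paste(conds[counts == 0], collapse = ", "))
  }
  n_target <- min(counts, n_per_condition %||% Inf)
  keep <- logical(length(cond))
  with_seed(seed, {
    for (cc in conds) {
      pool <- which(eligible & cond == cc)
      keep[sample(pool, n_target)] <- TRUE
    }
  })
  epochs$kept <- epochs$kept & keep
  epochs$condition <- cond
  log_step(epochs, sprintf("select_trials:%d", n_target))
}

#' Average kept trials of one condition into an evoked response
#'
#' Per-channel mean over the kept trials of `condition`, baseline-corrected by
#' subtracting each channel's mean over the baseline window.
#'
#' @param epochs an `eeg_epochs`.
#' @param condition condition label to average.
#' @param baseline `(from, to)` seconds of the baseline window.
#' @return object of class `eeg_evoked`: `data` (channels x samples), `fs`,
#'   `tmin`, `n_trials`, `condition`, `baseline`.
#' @export
condition_average <- function(epochs, condition, baseline = c(-0.1, 0)) {
  sel <- which(epochs$kept & epochs$condition == condition)
  if (length(sel) == 0) stop("no kept trials of condition ", condition)
  avg <- apply(epochs$data[sel, , , drop = FALSE], c(2, 3), mean)
  times <- epoch_time_axis(epochs)
  bl <- time_window_idx(times, baseline[1], baseline[2] - 1e-9)
  if (length(bl)) avg <- avg - rowMeans(avg[, bl, drop = FALSE])
  structure(list(
    data = avg, fs = epochs$fs, tmin = epochs$tmin, n_trials = length(sel),
    condition = condition, baseline = baseline,
    channel_labels = epochs$channel_labels, layout = epochs$layout,
    system = epochs$system
  ), class = "eeg_evoked")
}

#' @export
print.eeg_evoked <- function(x, ...) {
  cat(sprintf("<eeg_evoked> '%s' (%d trials): %d channels x %d samples @ %g Hz\n",
              x$condition, x$n_trials, nrow(x$data), ncol(x$data), x$fs))
  invisible(x)
}

#' Mismatch-negativity metrics from a deviant and a standard evoked response
#'
#' Forms the difference wave (deviant minus standard) at the analysis channel
#' and extracts the window-mean amplitude plus the peak amplitude and latency
#' within the window. The peak is the most negative sample by default
#' (`mode = "neg"`, the mismatch response being a negativity); `mode = "abs"`
#' takes the sample of largest magnitude. Ties resolve to the earliest sample.
#'
#' @param evoked_dev,evoked_std `eeg_evoked` objects on identical grids.
#' @param channel analysis channel (defaults to the layout's MMN channel).
#' @param window `(from, to)` seconds, inclusive.
#' @param mode `"neg"` or `"abs"` peak definition.
#' @return list of class `mmn_result`: `mean_amplitude`, `peak_amplitude`,
#'   `peak_latency`, `channel`, `n_trials_used`, and `snr` (filled by the
#'   caller from [plus_minus_snr()]).
#' @export
mmn_metrics <- function(evoked_dev, evoked_std,
                        channel = attr(evoked_dev$layout, "mmn_channel"),
                        window = c(0.100, 0.150), mode = c("neg", "abs")) {
  mode <- match.arg(mode)
  if (!identical(evoked_dev$fs, evoked_std$fs) ||
      !identical(evoked_dev$tmin, evoked_std$tmin)) {
    stop("evoked responses must share fs and tmin")
  }
  ci <- match(channel, evoked_dev$channel_labels)
  cj <- match(channel, evoked_std$channel_labels)
  if (is.na(ci) || is.na(cj)) stop("channel not present: ", channel)
  diffw <- evoked_dev$data[ci, ] - evoked_std$data[cj, ]
  times <- epoch_times(evoked_dev$tmin, length(diffw), evoked_dev$fs)
  win <- time_window_idx(times, window[1], window[2])
  if (!length(win)) stop("window outside epoch")
  seg <- diffw[win]
  peak_rel <- switch(mode,
    neg = which.min(seg),          # earliest minimum on ties (which.min contract)
    abs = which.max(abs(seg))
  )
  structure(list(
    mean_amplitude = mean(seg),
    peak_amplitude = seg[peak_rel],
    peak_latency = times[win[peak_rel]],
    channel = channel,
    n_trials_used = min(evoked_dev$n_trials, evoked_std$n_trials),
    window = window,
    snr = NA_real_
  ), class = "mmn_result")
}

#' @export
print.mmn_result <- function(x, ...) {
  cat(sprintf(
    "<mmn_result> channel %s: mean %.2f uV, peak %.2f uV @ %d ms (n = %d, SNR %.2f)\n",
    x$channel, x$mean_amplitude * 1e6, x$peak_amplitude * 1e6,
    round(x$peak_latency * 1000), x$n_trials_used, x$snr
  ))
  invisible(x)
}

#' Plus-minus signal-to-noise ratio
#'
#' Signal: average of all kept deviant trials at the analysis channel,
#' restricted to the analysis window. Noise estimate: the same average after
#' flipping the polarity of every other kept trial (the 2nd, 4th, ... in
#' chronological kept order), which cancels time-locked activity while
#' preserving the noise level. Returns `RMS(signal) / RMS(noise)`; a zero
#' noise RMS yields `Inf` with a warning.
#'
#' @param epochs task `eeg_epochs` (deviant trials taken from the kept mask).
#' @param channel analysis channel label.
#' @param window `(from, to)` seconds, inclusive.
#' @param condition condition whose trials enter the estimate.
#' @return the SNR (dimensionless).
#' @export
plus_minus_snr <- function(epochs, channel = attr(epochs$layout, "mmn_channel"),
                           window = c(0.100, 0.150), condition = "deviant") {
  sel <- which(epochs$kept & epochs$condition %in%
                 c(condition, paste0(condition, c("_low", "_high"))))
  if (length(sel) < 2) stop("need at least 2 kept trials")
  ci <- match(channel, epochs$channel_labels)
  if (is.na(ci)) stop("channel not present: ", channel)
  times <- epoch_time_axis(epochs)
  win <- time_window_idx(times, window[1], window[2])
  trials <- epochs$data[sel, ci, win, drop = TRUE]
  if (is.null(dim(trials))) trials <- matrix(trials, nrow = length(sel))
  signs <- rep(c(1, -1), length.out = length(sel))
  sig <- colMeans(trials)
  noise <- colMeans(trials * signs)
  nr <- rms(noise)
  if (nr == 0) {
    warning("zero noise RMS; returning Inf")
    return(Inf)
  }
  rms(sig) / nr
}
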