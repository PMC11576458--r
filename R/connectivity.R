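# Sensor-level resting-state connectivity: band filtering, phase lag index,
# PLI -> distance transform, minimum spanning tree and normalized diameter.

#' Analysis frequency bands
#'
#' Delta 0.5-4, theta 4-8, alpha 8-13 and lower beta 13-20 Hz (beta capped at
#' 20 Hz to limit muscle-artifact leakage).
#' @return named list of `c(lo, hi)` pairs.
#' @export
band_definitions <- function() {
  list(delta = c(0.5, 4), theta = c(4, 8), alpha = c(8, 13), beta = c(13, 20))
}

#' Re-reference epochs to the common average
#'
#' Subtracts the instantaneous mean over scalp channels from every scalp
#' channel; EOG and mastoid channels are left untouched.
#'
#' @param epochs an `eeg_epochs`.
#' @return re-referenced `eeg_epochs`.
#' @export
average_reference <- function(epochs) {
  scalp <- intersect(scalp_channels(epochs), epochs$channel_labels)
  if (length(scalp) < 2) stop("need at least two scalp channels")
  idx <- match(scalp, epochs$channel_labels)
  for (tr in seq_len(dim(epochs$data)[1])) {
    seg <- epochs$data[tr, idx, , drop = TRUE]
    epochs$data[tr, idx, ] <- sweep(seg, 2, colMeans(seg))
  }
  log_step(epochs, "rereference:average")
}

# zero-phase 4th-order Butterworth band-pass with reflection padding
butter_bandpass <- function(x, fs, lo, hi, pad_s = 1) {
  if (hi >= fs / 2) stop("band above Nyquist")
  bf <- signal::butter(4, c(lo, hi) / (fs / 2), type = "pass")
  np <- min(round(pad_s * fs), length(x) - 1)
  xp <- c(2 * x[1] - rev(x[2:(np + 1)]), x,
          2 * x[length(x)] - rev(x[(length(x) - np):(length(x) - 1)]))
  y <- signal::filtfilt(bf, xp)
  y[(np + 1):(np + length(x))]
}

#' Phase lag index between two signals
#'
#' `PLI = | mean_t sign( phi_x(t) - phi_y(t) ) |`, with instantaneous phases
#' from the analytic (Hilbert) signal. Samples with an exactly zero wrapped
#' phase difference contribute 0 ("equal in leading and lagging"). Symmetric
#' in its arguments and invariant to amplitude scaling; 1 means complete
#' phase locking at a consistent non-zero lag, 0 means no consistent lead/lag
#' asymmetry.
#'
#' @param x,y numeric vectors of equal length (band-limited signals).
#' @param fs sampling rate, needed only when `edge_trim > 0`.
#' @param edge_trim seconds discarded from both ends of the phase series
#'   (Hilbert edge effects).
#' @return PLI in `[0, 1]`.
#' @export
pli_pair <- function(x, y, fs = NULL, edge_trim = 0) {
  if (length(x) != length(y)) stop("inputs must have equal length")
  if (length(x) < 64) stop("inputs too short (need >= 64 samples)")
  if (stats::sd(x) == 0 || stats::sd(y) == 0) stop("constant input")
  ax <- analytic_signal(x)
  ay <- analytic_signal(y)
  dphi <- Arg(ax * Conj(ay))
  if (edge_trim > 0) {
    if (is.null(fs)) stop("fs required for edge trimming")
    k <- round(edge_trim * fs)
    if (2 * k >= length(dphi)) stop("edge trim longer than signal")
    dphi <- dphi[(k + 1):(length(dphi) - k)]
  }
  abs(mean(sign(dphi)))
}

# analytic-signal matrix (channels x samples) -> PLI matrix, edge-trimmed.
# sign of the wrapped phase difference equals sign(sin(phi_i - phi_j)) =
# sign(sin_i cos_j - cos_i sin_j), which vectorizes without rewrapping.
pli_matrix_from_phases <- function(adata, trim_idx) {
  phi <- Arg(adata[, trim_idx, drop = FALSE])
  S <- sin(phi); C <- cos(phi)
  n_ch <- nrow(phi)
  out <- matrix(0, n_ch, n_ch)
  for (i in seq_len(n_ch - 1)) {
    rows <- (i + 1):n_ch
    d <- S[rows, , drop = FALSE] * rep(C[i, ], each = length(rows)) -
      C[rows, , drop = FALSE] * rep(S[i, ], each = length(rows))
    out[i, rows] <- abs(rowMeans(sign(d)))
  }
  out + t(out)
}

#' Subject-level PLI for one frequency band
#'
#' Re-references to the common average, band-passes every 8 s rest epoch
#' (zero-phase 4th-order Butterworth, 1 s reflection padding), computes the
#' PLI for all scalp channel pairs per epoch (discarding 0.5 s of phase
#' samples at each epoch edge) and averages over epochs. The subject's scalar
#' mean PLI averages the upper-triangle pairs within each epoch first, then
#' over epochs.
#'
#' @param epochs rest `eeg_epochs`.
#' @param band `c(lo, hi)` Hz or a name from [band_definitions()].
#' @param edge_trim seconds of phase series dropped at each epoch edge.
#' @param average_ref apply the common-average re-reference first.
#' @return list of class `pli_result`: `matrix` (channels x channels, mean
#'   over epochs), `mean_pli`, `band`, `n_epochs`, `labels`.
#' @export
subject_pli <- function(epochs, band = "alpha", edge_trim = 0.5,
                        average_ref = TRUE) {
  if (is.character(band)) band <- band_definitions()[[band]] %||%
      stop("unknown band name")
  if (average_ref) epochs <- average_reference(epochs)
  kept <- which(epochs$kept)
  if (!length(kept)) stop("no kept rest epochs")
  scalp <- intersect(scalp_channels(epochs), epochs$channel_labels)
  idx <- match(scalp, epochs$channel_labels)
  n_s <- dim(epochs$data)[3]
  k <- round(edge_trim * epochs$fs)
  trim_idx <- (k + 1):(n_s - k)
  acc <- matrix(0, length(idx), length(idx))
  mean_per_epoch <- numeric(length(kept))
  for (e in seq_along(kept)) {
    seg <- epochs$data[kept[e], idx, , drop = TRUE]
    a <- matrix(0i, length(idx), n_s)
    for (ch in seq_len(length(idx))) {
      a[ch, ] <- analytic_signal(butter_bandpass(seg[ch, ], epochs$fs,
                                                 band[1], band[2]))
    }
    p <- pli_matrix_from_phases(a, trim_idx)
    acc <- acc + p
    mean_per_epoch[e] <- mean(p[upper.tri(p)])
  }
  structure(list(
    matrix = acc / length(kept),
    mean_pli = mean(mean_per_epoch),
    band = band, n_epochs = length(kept), labels = scalp
  ), class = "pli_result")
}

#' Transform PLI values into distances
#'
#' Strong coupling must become short distance for the minimum spanning tree.
#' Default `"one_minus"` uses `1 - PLI` (bounded, defined at PLI = 0);
#' `"inverse"` uses `1 / PLI` with `Inf` for zero entries. Both are strictly
#' decreasing in PLI, so they induce the same edge ordering and hence the
#' same tree.
#'
#' @param pli a `pli_result` or a symmetric PLI matrix in `[0, 1]`.
#' @param method `"one_minus"` or `"inverse"`.
#' @return distance matrix (diagonal 0).
#' @export
pli_to_distance <- function(pli, method = c("one_minus", "inverse")) {
  method <- match.arg(method)
  m <- if (inherits(pli, "pli_result")) pli$matrix else pli
  if (any(m < 0 | m > 1)) stop("PLI values must lie in [0, 1]")
  d <- switch(method, one_minus = 1 - m, inverse = 1 / m)
  diag(d) <- 0
  if (inherits(pli, "pli_result") && !is.null(pli$labels)) {
    dimnames(d) <- list(pli$labels, pli$labels)
  }
  d
}

#' Minimum spanning tree and normalized diameter
#'
#' Builds the MST of the complete weighted graph by Kruskal's algorithm with
#' deterministic tie-breaking (ties in weight resolve by lexicographic edge
#' label order), then computes the tree diameter `d` (longest within-tree
#' path, counted in links, by breadth-first search from every node), the link
#' count `M = N - 1` and the normalized diameter `D = d / M`.
#'
#' @param distances symmetric matrix of finite non-negative weights.
#' @param labels node labels (defaults to the matrix dimnames or indices).
#' @return list of class `mst_summary`: `edges` (data.frame `from`, `to`,
#'   `distance`), `d`, `M`, `D`.
#' @export
mst_diameter <- function(distances, labels = NULL) {
  n <- nrow(distances)
  labels <- labels %||% rownames(distances) %||% as.character(seq_len(n))
  if (any(!is.finite(distances[upper.tri(distances)]))) {
    stop("graph has non-finite weights")
  }
  ii <- which(upper.tri(distances), arr.ind = TRUE)
  w <- distances[upper.tri(distances)]
  ord <- order(w, labels[ii[, 1]], labels[ii[, 2]], method = "radix")
  parent <- seq_len(n)
  find <- function(a) { while (parent[a] != a) { parent[a] <<- parent[parent[a]]; a <- parent[a] }; a }
  adj <- vector("list", n)
  edges <- data.frame(from = character(0), to = character(0), distance = numeric(0))
  for (e in ord) {
    a <- ii[e, 1]; b <- ii[e, 2]
    ra <- find(a); rb <- find(b)
    if (ra != rb) {
      parent[ra] <- rb
      adj[[a]] <- c(adj[[a]], b); adj[[b]] <- c(adj[[b]], a)
      edges <- rbind(edges, data.frame(from = labels[a], to = labels[b],
                                       distance = w[e]))
      if (nrow(edges) == n - 1) break
    }
  }
  if (nrow(edges) != n - 1) stop("graph is disconnected")
  ecc <- function(start) {
    dist <- rep(-1L, n); dist[start] <- 0L; queue <- start
    while (length(queue)) {
      v <- queue[1]; queue <- queue[-1]
      for (u in adj[[v]]) if (dist[u] < 0) { dist[u] <- dist[v] + 1L; queue <- c(queue, u) }
    }
    max(dist)
  }
  d <- max(vapply(seq_len(n), ecc, integer(1)))
  structure(list(edges = edges, d = d, M = n - 1L, D = d / (n - 1L)),
            class = "mst_summary")
}

#' @export
print.mst_summary <- function(x, ...) {
  cat(sprintf("<mst_summary> %d links, diameter d = %d, D = d/M = %.3f\n",
              x$M, x$d, x$D))
  invisible(x)
}
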