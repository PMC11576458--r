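# Symmetric FastICA (tanh contrast) with PCA whitening, and EOG-correlated
# component rejection. Deterministic given the seed.

# X: variables x observations (rows = channels). Returns unmixing pieces:
#   K (ncomp x nvar) whitening, W (ncomp x ncomp) orthogonal rotation,
#   A (nvar x ncomp) mixing so that Xc ~ A %*% S + PCA residual,
#   S (ncomp x nobs) activations.
fastica_symm <- function(X, n_comp, seed = 1L, max_iter = 200, tol = 1e-6) {
  nv <- nrow(X); nobs <- ncol(X)
  if (n_comp > nv) stop("more components than channels")
  mu <- rowMeans(X)
  Xc <- X - mu
  cv <- tcrossprod(Xc) / nobs
  eg <- eigen(cv, symmetric = TRUE)
  if (eg$values[n_comp] < 1e-20 * eg$values[1]) stop("rank-deficient data")
  K <- diag(1 / sqrt(eg$values[1:n_comp])) %*% t(eg$vectors[, 1:n_comp, drop = FALSE])
  Z <- K %*% Xc
  W <- with_seed(seed, {
    qr.Q(qr(matrix(stats::rnorm(n_comp^2), n_comp)))
  })
  sym_orth <- function(W) {
    s <- svd(W)
    s$u %*% t(s$v)
  }
  W <- sym_orth(W)
  for (it in seq_len(max_iter)) {
    WZ <- W %*% Z
    G <- tanh(WZ)
    gprime <- rowMeans(1 - G^2)
    W1 <- sym_orth(tcrossprod(G, Z) / nobs - diag(gprime) %*% W)
    delta <- max(abs(1 - abs(rowSums(W1 * W))))
    W <- W1
    if (delta < tol) break
  }
  S <- W %*% Z
  A <- eg$vectors[, 1:n_comp, drop = FALSE] %*% diag(sqrt(eg$values[1:n_comp])) %*% t(W)
  list(K = K, W = W, A = A, S = S, mean = mu, n_iter = it)
}

#' Remove EOG-correlated independent components
#'
#' Fits a 15-component ICA (PCA whitening + symmetric FastICA, tanh contrast,
#' seeded initial rotation) on the good scalp channels of the kept epochs,
#' concatenated in time. Components whose activation time course correlates
#' with the bipolar vertical or horizontal EOG beyond `corr_threshold`
#' (absolute Pearson r) are subtracted from the data; everything else,
#' including the PCA residual, is left untouched, so `corr_threshold = 1`
#' reconstructs the input exactly. Before correlating, the EOG reference is
#' restricted to the 1-10 Hz blink band (standard practice in ICA-EOG
#' detection: the ocular waveform lives there, while unfiltered EOG is
#' dominated by slow drift that would produce spurious correlations).
#'
#' @param epochs an `eeg_epochs` after [derive_bipolar_eog()].
#' @param n_components number of components (must not exceed the data rank).
#' @param eog_channels channels to correlate against.
#' @param corr_threshold absolute correlation above which a component is
#'   rejected.
#' @param seed seed for the initial rotation.
#' @return list `epochs` (cleaned), `n_rejected`, `rejected` (indices),
#'   `correlations` (components x EOG matrix of r values).
#' @export
ica_reject_eog <- function(epochs, n_components = 15,
                           eog_channels = c("vEOG", "hEOG"),
                           corr_threshold = 0.2, seed = 1L) {
  eog_channels <- intersect(eog_channels, epochs$channel_labels)
  if (length(eog_channels) == 0) stop("no EOG channel available")
  scalp <- setdiff(intersect(scalp_channels(epochs), epochs$channel_labels),
                   epochs$bads)
  idx <- match(scalp, epochs$channel_labels)
  kept <- which(epochs$kept)
  d <- dim(epochs$data)
  # concatenate kept epochs: channels x (trials * samples)
  X <- matrix(aperm(epochs$data[kept, idx, , drop = FALSE], c(2, 3, 1)),
              nrow = length(idx))
  fit <- fastica_symm(X, n_components, seed = seed)
  eog <- vapply(eog_channels, function(ch) {
    x <- as.vector(aperm(epochs$data[kept, match(ch, epochs$channel_labels), ,
                                     drop = FALSE], c(2, 3, 1)))
    butter_bandpass(x, epochs$fs, 1, 10)  # blink band
  }, numeric(ncol(X)))
  cors <- stats::cor(t(fit$S), eog)
  rejected <- which(apply(abs(cors) > corr_threshold, 1, any))
  if (length(rejected)) {
    removed <- fit$A[, rejected, drop = FALSE] %*% fit$S[rejected, , drop = FALSE]
    Xclean <- X - removed
    arr <- aperm(array(Xclean, c(length(idx), d[3], length(kept))), c(3, 1, 2))
    epochs$data[kept, idx, ] <- arr
  }
  epochs <- log_step(epochs, sprintf("ica:%d-%d", n_components, length(rejected)))
  list(epochs = epochs, n_rejected = length(rejected), rejected = rejected,
       correlations = cors)
}
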