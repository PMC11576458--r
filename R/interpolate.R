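# Spherical-spline channel interpolation (Perrin-style): interpolation order
# m = 4, Legendre series truncated at degree 7, ridge regularization 1e-5.

legendre_poly <- function(x, degree) {
  # returns matrix length(x) x degree with P_1..P_degree via recurrence
  out <- matrix(0, length(x), degree)
  p0 <- rep(1, length(x)); p1 <- x
  out[, 1] <- p1
  for (l in 2:degree) {
    p2 <- ((2 * l - 1) * x * p1 - (l - 1) * p0) / l
    out[, l] <- p2
    p0 <- p1; p1 <- p2
  }
  out
}

spline_g <- function(cosang, m = 4, degree = 7) {
  l <- seq_len(degree)
  coef <- (2 * l + 1) / (l * (l + 1))^m
  P <- legendre_poly(pmin(1, pmax(-1, cosang)), degree)
  as.vector(P %*% coef) / (4 * pi)
}

# interpolation matrix mapping good-channel values to bad-channel estimates
spline_interp_matrix <- function(pos_good, pos_bad, m = 4, degree = 7,
                                 lambda = 1e-5) {
  ng <- nrow(pos_good)
  G <- matrix(spline_g(tcrossprod(pos_good)), ng, ng) + diag(lambda, ng)
  Gb <- matrix(spline_g(pos_bad %*% t(pos_good)), nrow(pos_bad), ng)
  # augmented system enforcing the zero-sum constraint on the spline weights
  Aug <- rbind(cbind(G, 1), c(rep(1, ng), 0))
  sol <- solve(Aug, rbind(diag(ng), 0))   # (ng+1) x ng: [C; c0] per channel
  C <- sol[1:ng, , drop = FALSE]
  c0 <- sol[ng + 1, ]
  Gb %*% C + matrix(c0, nrow(pos_bad), ng, byrow = TRUE)
}

#' Interpolate bad channels with spherical splines
#'
#' Replaces each flagged scalp channel by a Perrin-style spherical-spline
#' estimate computed from the remaining good scalp channels (interpolation
#' order m = 4, Legendre series truncated at degree 7, regularization 1e-5).
#' Constant potentials are reproduced exactly; good channels are untouched.
#'
#' @param epochs an `eeg_epochs`.
#' @param bads channel labels to interpolate (defaults to `epochs$bads`).
#' @return the epochs with interpolated data and an emptied bad list.
#' @export
interpolate_bad_channels <- function(epochs, bads = epochs$bads) {
  bads <- intersect(bads, epochs$channel_labels)
  if (length(bads) == 0) return(log_step(epochs, "interpolate:0"))
  scalp <- intersect(scalp_channels(epochs), epochs$channel_labels)
  good <- setdiff(scalp, bads)
  if (length(good) < 4) stop("too few good channels for interpolation")
  lay <- epochs$layout
  pos <- as.matrix(lay[match(c(good, bads), lay$label), c("x", "y", "z")])
  M <- spline_interp_matrix(pos[seq_along(good), , drop = FALSE],
                            pos[length(good) + seq_along(bads), , drop = FALSE])
  gi <- match(good, epochs$channel_labels)
  bi <- match(bads, epochs$channel_labels)
  for (tr in seq_len(dim(epochs$data)[1])) {
    epochs$data[tr, bi, ] <- M %*% epochs$data[tr, gi, ]
  }
  epochs$bads <- setdiff(epochs$bads, bads)
  log_step(epochs, sprintf("interpolate:%d", length(bads)))
}
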