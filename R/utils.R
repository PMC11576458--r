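#' @keywords internal
"_PACKAGE"

# Run code under a local RNG state: the caller's RNG stream is untouched and
# the same `seed` always reproduces the same draws.
with_seed <- function(seed, code) {
  if (!is.null(seed)) {
    old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      get(".Random.seed", envir = globalenv())
    } else NULL
    on.exit({
      if (is.null(old)) {
        rm(".Random.seed", envir = globalenv())
      } else {
        assign(".Random.seed", old, envir = globalenv())
      }
    }, add = TRUE)
    set.seed(seed)
  }
  force(code)
}

# Derive a child seed from (seed, tag) so that stages draw from independent,
# reproducible streams. Kept below 2^31 - 1.
derive_seed <- function(seed, ...) {
  tag <- paste(c(seed, ...), collapse = "/")
  raw <- utils::head(charToRaw(digest_string(tag)), 7)
  as.integer(sum(as.integer(raw) * 31L^(seq_along(raw) - 1L)) %% 2147483629)
}

# Tiny deterministic string hash (FNV-1a, hex); used for seed derivation and
# pipeline manifests. Not cryptographic.
digest_string <- function(x) {
  bytes <- as.integer(charToRaw(paste(x, collapse = "\n")))
  h <- 2166136261
  for (b in bytes) {
    h <- bitwXor(as.integer(h %% 2^31), b)
    h <- (h * 16777619) %% 2^32
  }
  sprintf("%08x", as.integer(h %% 2^31))
}

rms <- function(x) sqrt(mean(x^2))

#' Analytic signal via the frequency domain
#'
#' Computes the analytic signal `x + i * H(x)` (Hilbert transform in the
#' imaginary part) by zeroing negative frequencies of the FFT. The instantaneous
#' phase used by the phase lag index is `Arg()` of this signal.
#'
#' @param x numeric vector.
#' @return complex vector of the same length.
#' @export
analytic_signal <- function(x) {
  n <- length(x)
  if (n < 2) stop("analytic_signal() needs at least 2 samples")
  X <- stats::fft(x)
  h <- numeric(n)
  if (n %% 2 == 0) {
    h[1] <- 1; h[n / 2 + 1] <- 1
    h[2:(n / 2)] <- 2
  } else {
    h[1] <- 1
    h[2:((n + 1) / 2)] <- 2
  }
  stats::fft(X * h, inverse = TRUE) / n
}

# index of the sample grid: epochs use the half-open convention [tmin, tmax),
# so an epoch covers n = round((tmax - tmin) * fs) samples.
n_epoch_samples <- function(tmin, tmax, fs) as.integer(round((tmax - tmin) * fs))

epoch_times <- function(tmin, n, fs) tmin + (seq_len(n) - 1L) / fs

# inclusive index window [from, to] on a time axis
time_window_idx <- function(times, from, to, tol = 1e-9) {
  which(times >= from - tol & times <= to + tol)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
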