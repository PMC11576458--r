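#' Generate a pseudo-randomized auditory oddball stimulus sequence
#'
#' Builds the tone sequence of a passive auditory oddball block: frequent
#' standard tones interspersed with two rare deviant types, preceded by a short
#' habituation run of standards. Deviants are placed by sampling the number of
#' standards between consecutive deviants uniformly from
#' `min_gap:max_gap` and repairing the total standard count by seeded
#' decrements/increments of randomly chosen gaps; standards left over after the
#' gap budget are split between a lead-in before the first deviant and a tail
#' after the last one (those two runs are unconstrained). Deviant subtype
#' (low/high) is assigned uniformly at random to the deviant slots.
#'
#' Defaults reproduce the study design: 612 standards, 102 deviants of each
#' type (816 experimental tones), gaps of 2-4 standards between deviants,
#' a stimulus-onset asynchrony of 1.555 s and 10 habituation standards.
#'
#' @param n_standards number of experimental standard tones.
#' @param n_deviants_per_type number of deviants of each of the two types.
#' @param min_gap,max_gap minimum/maximum number of standards between two
#'   consecutive deviants (of either type).
#' @param soa stimulus-onset asynchrony in seconds.
#' @param n_habituation standards delivered before the experimental block.
#' @param seed integer seed; the same seed gives an identical sequence.
#' @param fs sampling rate (Hz) used to derive `onset_sample`.
#' @return an object of class `oddball_sequence`: a data.frame with columns
#'   `onset_s`, `onset_sample`, `tone` (`standard`, `deviant_low`,
#'   `deviant_high`), `is_habituation`, `follows_deviant`, with attributes
#'   `soa` and `fs`. `follows_deviant` marks experimental events whose
#'   immediately preceding experimental event was a deviant.
#' @export
oddball_sequence <- function(n_standards = 612L, n_deviants_per_type = 102L,
                             min_gap = 2L, max_gap = 4L, soa = 1.555,
                             n_habituation = 10L, seed = 1L, fs = 1024) {
  if (soa <= 0) stop("soa must be positive")
  if (min_gap > max_gap || min_gap < 0) stop("invalid gap bounds")
  n_dev <- 2L * as.integer(n_deviants_per_type)
  n_gaps <- max(0L, n_dev - 1L)
  if (n_dev > 0L && n_standards < min_gap * n_gaps) {
    stop(sprintf(
      "infeasible constraints: %d standards cannot fill %d inter-deviant gaps of at least %d",
      n_standards, n_gaps, min_gap
    ))
  }

  tones <- with_seed(seed, {
    if (n_dev == 0L) {
      rep("standard", n_standards)
    } else {
      gaps <- if (n_gaps > 0) sample(seq.int(min_gap, max_gap), n_gaps, replace = TRUE) else integer(0)
      # repair: shrink/grow random eligible gaps until the gap budget fits
      while (sum(gaps) > n_standards) {
        i <- sample(which(gaps > min_gap), 1L)
        gaps[i] <- gaps[i] - 1L
      }
      spare <- n_standards - sum(gaps)
      lead <- if (spare > 0) sample(0:spare, 1L) else 0L
      tail_run <- spare - lead
      dev_types <- sample(rep(c("deviant_low", "deviant_high"), n_deviants_per_type))
      out <- c(rep("standard", lead), dev_types[1L])
      for (i in seq_len(n_gaps)) {
        out <- c(out, rep("standard", gaps[i]), dev_types[i + 1L])
      }
      c(out, rep("standard", tail_run))
    }
  })

  tone <- c(rep("standard", n_habituation), tones)
  n <- length(tone)
  is_hab <- c(rep(TRUE, n_habituation), rep(FALSE, length(tones)))
  onset_s <- (seq_len(n) - 1L) * soa
  is_dev <- tone != "standard"
  follows <- c(FALSE, is_dev[-n]) & !is_hab
  # the first experimental event follows habituation standards, never a deviant
  if (n_habituation > 0 && length(tones) > 0) follows[n_habituation + 1L] <- FALSE

  ev <- data.frame(
    onset_s = onset_s,
    onset_sample = as.integer(round(onset_s * fs)) + 1L,
    tone = tone,
    is_habituation = is_hab,
    follows_deviant = follows,
    stringsAsFactors = FALSE
  )
  structure(ev, soa = soa, fs = fs, class = c("oddball_sequence", "data.frame"))
}

#' Validate an oddball sequence against the design constraints
#'
#' Independent checker used by the test-suite and callers that load sequences
#' from disk: verifies tone counts, habituation placement, the gap bounds
#' between consecutive deviants, constant SOA spacing and the
#' `follows_deviant` flags.
#'
#' @param seq an `oddball_sequence` (or equivalent data.frame with the same
#'   columns and `soa` attribute).
#' @param n_standards,n_deviants_per_type,min_gap,max_gap,n_habituation
#'   expected design parameters.
#' @return invisibly `TRUE`; stops with an informative message on violation.
#' @export
validate_oddball_sequence <- function(seq, n_standards = 612L,
                                      n_deviants_per_type = 102L,
                                      min_gap = 2L, max_gap = 4L,
                                      n_habituation = 10L) {
  soa <- attr(seq, "soa")
  hab <- seq$is_habituation
  if (sum(hab) != n_habituation) stop("wrong habituation count")
  if (any(which(hab) != seq_len(n_habituation))) stop("habituation events must precede the block")
  if (n_habituation > 0 && any(seq$tone[hab] != "standard")) stop("habituation events must be standards")
  exp_tone <- seq$tone[!hab]
  if (sum(exp_tone == "standard") != n_standards) stop("wrong standard count")
  if (sum(exp_tone == "deviant_low") != n_deviants_per_type) stop("wrong deviant_low count")
  if (sum(exp_tone == "deviant_high") != n_deviants_per_type) stop("wrong deviant_high count")
  dev_pos <- which(exp_tone != "standard")
  if (length(dev_pos) > 1) {
    gaps <- diff(dev_pos) - 1L
    if (any(gaps < min_gap) || any(gaps > max_gap)) {
      stop(sprintf("inter-deviant gaps outside [%d, %d]", min_gap, max_gap))
    }
  }
  if (nrow(seq) > 1 && any(abs(diff(seq$onset_s) - soa) > 1e-9)) stop("onsets not SOA-spaced")
  is_dev <- seq$tone != "standard"
  expect_follows <- c(FALSE, is_dev[-nrow(seq)]) & !hab
  if (n_habituation > 0 && nrow(seq) > n_habituation) expect_follows[n_habituation + 1L] <- FALSE
  if (any(expect_follows != seq$follows_deviant)) stop("follows_deviant flags inconsistent")
  invisible(TRUE)
}

#' @export
print.oddball_sequence <- function(x, ...) {
  hab <- sum(x$is_habituation)
  tab <- table(x$tone[!x$is_habituation])
  cat(sprintf(
    "Oddball sequence: %d events (%d habituation + %d experimental), SOA %.3f s\n",
    nrow(x), hab, nrow(x) - hab, attr(x, "soa")
  ))
  print(tab)
  invisible(x)
}
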