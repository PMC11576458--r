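# Shared fixtures: a compact layout and constructors for synthetic epochs,
# kept small so unit tests stay fast.

# 16 scalp channels on an upper-hemisphere spiral plus EOG and mastoids;
# carries the same metadata attributes as the shipped layouts.
mini_layout <- function(n_scalp = 16) {
  k <- seq_len(n_scalp)
  z <- 1 - (k - 1) / n_scalp * 0.8
  r <- sqrt(1 - z^2)
  phi <- k * 2.399963  # golden angle
  lay <- data.frame(
    label = paste0("S", k),
    x = r * sin(phi), y = r * cos(phi), z = z,
    type = "scalp", stringsAsFactors = FALSE
  )
  extra <- data.frame(
    label = c("EOGa", "EOGb", "EOGl", "M1", "M2"),
    x = c(-0.3, -0.3, -0.55, -0.95, 0.95),
    y = c(0.92, 0.9, 0.8, -0.25, -0.25),
    z = c(0.25, 0.05, 0.1, -0.2, -0.2),
    type = c("eog", "eog", "eog", "mastoid", "mastoid"),
    stringsAsFactors = FALSE
  )
  out <- rbind(lay, extra)
  fc <- c(1, 0.8, 0.6); names(fc) <- c("S1", "S2", "S3")
  attr(out, "system") <- "wet"
  attr(out, "mmn_channel") <- "S1"
  attr(out, "frontocentral") <- fc
  attr(out, "eog_map") <- list(veog = c("EOGa", "EOGb"), heog = c("EOGl", "S4"))
  attr(out, "mastoids") <- c("M1", "M2")
  out
}

# epochs straight from an array (bypasses the continuous stage)
make_epochs <- function(data, fs, tmin, layout, condition, events = NULL) {
  eegagree:::new_epochs(data, fs, tmin, layout, condition, events = events)
}

# task epochs holding pure injected templates (no noise): standards get the
# obligatory response, deviants additionally the mismatch component
template_epochs <- function(truth, layout = mini_layout(), fs = 512,
                            n_std = 6, n_dev = 6, tmin = -0.1, tmax = 0.5) {
  n <- round((tmax - tmin) * fs)
  t <- tmin + (seq_len(n) - 1) / fs
  resp <- ifelse(t >= 0, eegagree:::template_evoked(pmax(t, 0), truth), 0)
  mmn <- ifelse(t >= 0, eegagree:::template_mmn(pmax(t, 0), truth), 0)
  fc <- attr(layout, "frontocentral")
  fi <- match(names(fc), layout$label)
  dat <- array(0, c(n_std + n_dev, nrow(layout), n))
  for (tr in seq_len(n_std + n_dev)) {
    wave <- if (tr > n_std) resp + mmn else resp
    dat[tr, fi, ] <- outer(unname(fc), wave)
  }
  cond <- c(rep("standard", n_std), rep("deviant", n_dev))
  ev <- data.frame(
    onset_s = seq_len(n_std + n_dev) * 2, onset_sample = seq_len(n_std + n_dev),
    tone = cond, is_habituation = FALSE, follows_deviant = FALSE
  )
  make_epochs(dat, fs, tmin, layout, cond, events = ev)
}

# a recording of given data matrix on the mini layout
mini_recording <- function(data, fs = 512, layout = mini_layout(),
                           events = NULL, system = "wet") {
  eeg_recording(data, fs, layout, system = system, events = events)
}
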