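#' Construct a continuous multichannel EEG recording
#'
#' @param data numeric matrix, channels x samples, in volts.
#' @param fs sampling rate in Hz.
#' @param layout a layout data.frame from [channel_layout()]; rows must match
#'   the rows of `data`.
#' @param system `"wet"` or `"dry"`.
#' @param events optional [oddball_sequence()] attached to task recordings.
#' @param reference free-text description of the recording reference.
#' @return an object of class `eeg_recording`.
#' @export
eeg_recording <- function(data, fs, layout, system = attr(layout, "system"),
                          events = NULL, reference = "common") {
  stopifnot(is.matrix(data), fs > 0, nrow(data) == nrow(layout))
  rownames(data) <- layout$label
  structure(list(
    data = data, fs = fs, layout = layout,
    channel_labels = layout$label, system = system,
    events = events, reference = reference,
    bads = character(0)
  ), class = "eeg_recording")
}

#' @export
print.eeg_recording <- function(x, ...) {
  cat(sprintf(
    "<eeg_recording> %s system: %d channels x %d samples @ %g Hz (%.1f s), reference: %s\n",
    x$system, nrow(x$data), ncol(x$data), x$fs, ncol(x$data) / x$fs, x$reference
  ))
  if (!is.null(x$events)) cat(sprintf("  %d attached events\n", nrow(x$events)))
  if (length(x$bads)) cat("  bad channels:", paste(x$bads, collapse = ", "), "\n")
  invisible(x)
}

scalp_channels <- function(x) {
  layout <- if (inherits(x, c("eeg_recording", "eeg_epochs", "eeg_evoked"))) x$layout else x
  layout$label[layout$type == "scalp"]
}

#' Write / read a recording as a documented plain-text container
#'
#' The container is a directory with `header.json` (sampling rate, system,
#' reference, channel table with positions and types, in µV physical units)
#' and `data.tsv` (samples x channels, microvolts, tab-separated). Events, if
#' present, go to `events.tsv` with columns `onset_sample`, `onset_s`, `tone`,
#' `is_habituation`, `follows_deviant`.
#'
#' @param rec an `eeg_recording`.
#' @param path directory to create.
#' @return `write_recording()` the path, invisibly; `read_recording()` an
#'   `eeg_recording`.
#' @export
write_recording <- function(rec, path) {
  dir.create(path, recursive = TRUE, showWarnings = FALSE)
  hdr <- list(
    fs = rec$fs, system = rec$system, reference = rec$reference,
    unit = "uV", n_samples = ncol(rec$data),
    channels = rec$layout
  )
  jsonlite::write_json(hdr, file.path(path, "header.json"),
                       auto_unbox = TRUE, digits = NA, dataframe = "columns")
  utils::write.table(
    round(t(rec$data) * 1e6, 6), file.path(path, "data.tsv"),
    sep = "\t", row.names = FALSE, col.names = rec$channel_labels, quote = FALSE
  )
  if (!is.null(rec$events)) {
    utils::write.table(rec$events, file.path(path, "events.tsv"),
                       sep = "\t", row.names = FALSE, quote = FALSE)
  }
  invisible(path)
}

#' @rdname write_recording
#' @param path directory written by `write_recording()`.
#' @export
read_recording <- function(path) {
  hdr <- jsonlite::read_json(file.path(path, "header.json"), simplifyVector = TRUE)
  layout <- as.data.frame(hdr$channels, stringsAsFactors = FALSE)
  dat <- utils::read.table(file.path(path, "data.tsv"), sep = "\t", header = TRUE,
                           check.names = FALSE)
  events <- NULL
  evf <- file.path(path, "events.tsv")
  if (file.exists(evf)) {
    events <- utils::read.table(evf, sep = "\t", header = TRUE, stringsAsFactors = FALSE)
    attr(events, "fs") <- hdr$fs
    class(events) <- c("oddball_sequence", "data.frame")
    if (nrow(events) > 1) attr(events, "soa") <- diff(events$onset_s[1:2])
  }
  # if the channel table matches a shipped layout, use it so that derived
  # metadata (analysis channel, EOG map, mastoids) survives the round-trip
  for (nm in c("wet64", "dry64")) {
    shipped <- channel_layout(nm)
    if (identical(shipped$label, layout$label)) { layout <- shipped; break }
  }
  eeg_recording(t(as.matrix(dat)) * 1e-6, fs = hdr$fs, layout = layout,
                system = hdr$system, events = events, reference = hdr$reference)
}
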