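# Core containers: Recording (continuous multichannel EEG) and EpochSet
# (fixed-length labeled segments).

#' Construct a Recording
#'
#' A `Recording` holds a continuous multichannel EEG signal in microvolts, its
#' channel labels (normalized via [normalize_channel_names()]), sampling rate,
#' an opaque patient identifier and optional annotations (a data frame with
#' columns `onset_s`, `duration_s`, `label`).
#'
#' @param signal numeric matrix, channels x samples.
#' @param channel_names character vector, one label per signal row.
#' @param fs sampling rate in Hz (> 0).
#' @param patient_id opaque string identifying the patient.
#' @param annotations optional data frame (`onset_s`, `duration_s`, `label`).
#' @return object of class `Recording`.
#' @export
recording <- function(signal, channel_names, fs, patient_id = "unknown",
                      annotations = NULL) {
  signal <- as.matrix(signal)
  channel_names <- normalize_channel_names(channel_names)
  if (nrow(signal) != length(channel_names))
    stopf("signal has %d rows but %d channel names given",
          nrow(signal), length(channel_names))
  if (!is.numeric(fs) || length(fs) != 1 || fs <= 0)
    stopf("fs must be a single positive number")
  if (!is.null(annotations)) {
    annotations <- as.data.frame(annotations)
    req <- c("onset_s", "duration_s", "label")
    if (!all(req %in% names(annotations)))
      stopf("annotations need columns onset_s, duration_s, label")
    dur <- ncol(signal) / fs
    if (any(annotations$onset_s < 0) ||
        any(annotations$onset_s + annotations$duration_s > dur + 1e-9))
      stopf("annotation intervals fall outside the recording (duration %.3f s)", dur)
  }
  structure(list(signal = signal, channel_names = channel_names, fs = fs,
                 patient_id = as.character(patient_id),
                 annotations = annotations),
            class = "Recording")
}

#' @export
print.Recording <- function(x, ...) {
  cat(sprintf("<Recording> %d channels x %d samples @ %g Hz (%.1f s), patient %s\n",
              nrow(x$signal), ncol(x$signal), x$fs,
              ncol(x$signal) / x$fs, x$patient_id))
  cat("  channels:", paste(x$channel_names, collapse = " "), "\n")
  if (!is.null(x$annotations))
    cat(sprintf("  %d annotation(s)\n", nrow(x$annotations)))
  invisible(x)
}

#' Construct an EpochSet
#'
#' Fixed-length labeled EEG segments. Epochs are stored as a
#' channels x samples x epochs array; every epoch carries a binary label and a
#' patient id.
#'
#' @param epochs numeric array `C x T x n_epochs`.
#' @param labels integer/numeric vector of 0/1, length `n_epochs`.
#' @param patient_ids character vector, length `n_epochs`.
#' @param fs sampling rate in Hz.
#' @param channel_names character vector of length `C`.
#' @param epoch_length_s epoch duration in seconds; `T` must equal
#'   `fs * epoch_length_s` exactly.
#' @return object of class `EpochSet`.
#' @export
epoch_set <- function(epochs, labels, patient_ids, fs, channel_names,
                      epoch_length_s = dim(epochs)[2] / fs) {
  d <- dim(epochs)
  if (length(d) != 3) stopf("epochs must be a 3-d array (C x T x n)")
  if (d[1] != length(channel_names))
    stopf("epoch array has %d channels but %d channel names", d[1],
          length(channel_names))
  if (length(labels) != d[3])
    stopf("%d labels for %d epochs", length(labels), d[3])
  if (length(patient_ids) != d[3])
    stopf("%d patient ids for %d epochs", length(patient_ids), d[3])
  if (!all(labels %in% c(0, 1))) stopf("labels must be 0/1")
  if (abs(d[2] - fs * epoch_length_s) > 1e-9)
    stopf("T = %d does not equal fs * epoch_length_s = %g", d[2],
          fs * epoch_length_s)
  structure(list(epochs = epochs, labels = as.integer(labels),
                 patient_ids = as.character(patient_ids), fs = fs,
                 channel_names = normalize_channel_names(channel_names),
                 epoch_length_s = epoch_length_s),
            class = "EpochSet")
}

#' @export
print.EpochSet <- function(x, ...) {
  d <- dim(x$epochs)
  cat(sprintf("<EpochSet> %d epochs of %d channels x %d samples @ %g Hz; %d positive, %d patients\n",
              d[3], d[1], d[2], x$fs, sum(x$labels),
              length(unique(x$patient_ids))))
  invisible(x)
}

#' Number of epochs in an EpochSet
#' @param es an `EpochSet`.
#' @return integer count.
#' @export
n_epochs <- function(es) dim(es$epochs)[3]
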