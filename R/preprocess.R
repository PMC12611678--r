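# Standardization pipeline: channel selection, resampling, bandpass filtering,
# average reference, z-score normalization and 5-second epoching.

#' Preprocessing configuration
#'
#' Defaults follow the standard spasm-detection pipeline: the 16-channel
#' referential 10-20 montage, 250 Hz, a 0.7-40 Hz passband (suppressing both
#' slow drift and line/EMG artifacts while keeping ictal waveforms) and
#' 5-second epochs.
#'
#' @param target_channels canonical ordered channel labels.
#' @param target_fs target sampling rate in Hz.
#' @param band numeric length-2, bandpass edges in Hz.
#' @param epoch_length_s epoch duration in seconds.
#' @param eps stabilizer added to the per-channel standard deviation in the
#'   z-score; keeps degenerate (constant) channels finite.
#' @param min_overlap_frac fraction of the epoch that must overlap an annotated
#'   event for a positive label; 0 means any strictly positive overlap.
#' @return list of class `preprocess_config`.
#' @export
preprocess_config <- function(target_channels = montage_channels(),
                              target_fs = 250,
                              band = c(0.7, 40),
                              epoch_length_s = 5,
                              eps = 1e-8,
                              min_overlap_frac = 0) {
  if (!(band[1] > 0 && band[2] > band[1] && band[2] < target_fs / 2))
    stopf("need 0 < low < high < target_fs/2")
  if (epoch_length_s <= 0) stopf("epoch_length_s must be positive")
  if (eps <= 0) stopf("eps must be positive")
  structure(list(target_channels = normalize_channel_names(target_channels),
                 target_fs = target_fs, band = band,
                 epoch_length_s = epoch_length_s, eps = eps,
                 min_overlap_frac = min_overlap_frac),
            class = "preprocess_config")
}

#' Select and order montage channels
#'
#' Restricts a recording to the configured target channels, in canonical
#' order. Aliased modern names (T7/T8/P7/P8) are already normalized at
#' construction time.
#'
#' @param rec a [recording()].
#' @param cfg a [preprocess_config()].
#' @return a `Recording` with exactly the target channels.
#' @export
select_channels <- function(rec, cfg = preprocess_config()) {
  idx <- match(cfg$target_channels, rec$channel_names)
  if (anyNA(idx))
    stopf("missing channel(s): %s",
          paste(cfg$target_channels[is.na(idx)], collapse = ", "))
  recording(rec$signal[idx, , drop = FALSE], cfg$target_channels, rec$fs,
            rec$patient_id, rec$annotations)
}

#' Resample a recording
#'
#' Fourier-domain resampling to `target_fs`; the output sample count is
#' `round(T * target_fs / fs)`. Downsampling is anti-aliased by spectral
#' truncation. A recording already at the target rate is returned unchanged.
#'
#' @param rec a `Recording`.
#' @param target_fs target sampling rate in Hz.
#' @return resampled `Recording`.
#' @export
resample_recording <- function(rec, target_fs = 250) {
  if (!is.numeric(target_fs) || target_fs <= 0)
    stopf("target_fs must be positive")
  if (target_fs == rec$fs) return(rec)
  n_out <- round(ncol(rec$signal) * target_fs / rec$fs)
  sig <- t(apply(rec$signal, 1, fft_resample, n_out = n_out))
  recording(sig, rec$channel_names, target_fs, rec$patient_id, rec$annotations)
}

#' Zero-phase bandpass filter a recording
#'
#' 4th-order Butterworth bandpass applied forward-backward (zero phase), so
#' epoch timing is not shifted; the DC component is removed by the passband.
#'
#' @param rec a `Recording`.
#' @param band numeric length-2 band edges in Hz.
#' @param order Butterworth prototype order.
#' @return filtered `Recording`.
#' @export
bandpass_recording <- function(rec, band = c(0.7, 40), order = 4) {
  filt <- butter_bandpass(band[1], band[2], rec$fs, order = order)
  sig <- t(apply(rec$signal, 1, function(x) filtfilt_zero_phase(filt, x)))
  recording(sig, rec$channel_names, rec$fs, rec$patient_id, rec$annotations)
}

#' Re-reference to the common average
#'
#' Subtracts the instantaneous mean across channels from every channel, so the
#' channel mean of the output is zero at every sample.
#'
#' @param rec a `Recording` with at least two channels.
#' @return re-referenced `Recording`.
#' @export
average_reference <- function(rec) {
  if (nrow(rec$signal) < 2)
    stopf("average reference needs at least 2 channels")
  sig <- sweep(rec$signal, 2, colMeans(rec$signal))
  recording(sig, rec$channel_names, rec$fs, rec$patient_id, rec$annotations)
}

#' Per-channel z-score standardization
#'
#' Standardizes each row to zero mean and (population) unit standard
#' deviation; `eps` in the denominator keeps constant rows finite (they map
#' to all zeros).
#'
#' @param x numeric matrix, channels x samples.
#' @param eps small positive stabilizer.
#' @return standardized matrix of the same shape.
#' @export
zscore_channels <- function(x, eps = 1e-8) {
  m <- rowMeans(x)
  s <- sqrt(pmax(rowMeans(x * x) - m * m, 0))
  (x - m) / (s + eps)
}

#' Segment a recording into labeled epochs
#'
#' Cuts non-overlapping consecutive epochs of exactly
#' `fs * epoch_length_s` samples (trailing remainder discarded). An epoch is
#' labeled 1 iff its time interval overlaps any annotated event by more than
#' `min_overlap_frac` of the epoch length (any strictly positive overlap when
#' the fraction is 0).
#'
#' @param rec a `Recording`.
#' @param cfg a [preprocess_config()].
#' @param annotations optional data frame overriding `rec$annotations`.
#' @return an [epoch_set()]; empty (with a warning) if the recording is
#'   shorter than one epoch.
#' @export
segment_epochs <- function(rec, cfg = preprocess_config(), annotations = NULL) {
  ann <- annotations %||% rec$annotations
  Tn <- round(rec$fs * cfg$epoch_length_s)
  C <- nrow(rec$signal)
  n <- floor(ncol(rec$signal) / Tn)
  if (n < 1) {
    warning("recording shorter than one epoch; returning empty EpochSet")
    return(epoch_set(array(0, dim = c(C, Tn, 0)), integer(0), character(0),
                     rec$fs, rec$channel_names, cfg$epoch_length_s))
  }
  arr <- array(rec$signal[, seq_len(n * Tn), drop = FALSE], dim = c(C, Tn, n))
  starts <- (seq_len(n) - 1) * cfg$epoch_length_s
  labels <- integer(n)
  if (!is.null(ann) && nrow(ann) > 0) {
    thresh <- cfg$min_overlap_frac * cfg$epoch_length_s
    for (e in seq_len(n)) {
      lo <- starts[e]
      hi <- lo + cfg$epoch_length_s
      ov <- pmin(hi, ann$onset_s + ann$duration_s) - pmax(lo, ann$onset_s)
      if (any(ov > max(thresh, 0))) labels[e] <- 1L
    }
  }
  epoch_set(arr, labels, rep(rec$patient_id, n), rec$fs, rec$channel_names,
            cfg$epoch_length_s)
}

#' Run the full preprocessing pipeline
#'
#' Fixed stage order: channel selection, resampling, bandpass, average
#' reference, epoching, per-epoch z-score. The z-score is applied per epoch
#' (the classifier consumes standardized 5-second segment matrices).
#'
#' @param rec a `Recording`.
#' @param cfg a [preprocess_config()].
#' @param annotations optional annotation data frame.
#' @return an `EpochSet` of standardized epochs.
#' @export
preprocess_recording <- function(rec, cfg = preprocess_config(),
                                 annotations = NULL) {
  rec <- select_channels(rec, cfg)
  rec <- resample_recording(rec, cfg$target_fs)
  rec <- bandpass_recording(rec, cfg$band)
  rec <- average_reference(rec)
  es <- segment_epochs(rec, cfg, annotations)
  for (e in seq_len(n_epochs(es)))
    es$epochs[, , e] <- zscore_channels(es$epochs[, , e], cfg$eps)
  es
}
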