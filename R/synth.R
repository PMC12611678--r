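# Synthetic multichannel EEG with controlled spasm-like events: colored
# background noise with mild shared-source mixing, plus high-amplitude slow
# transients with superimposed fast bursts confined to known channels. The
# generator's job is statistical structure (class-conditional spectral and
# connectivity differences in known channels), not clinical realism.

#' Synthetic-data configuration
#'
#' Defaults emulate the data regime the detector targets: 16-channel
#' referential EEG at 250 Hz in 5-second epochs, 1/f background noise with a
#' weak shared source, and spasm-like events (2 Hz high-amplitude slow wave
#' with a 20 Hz burst, amplitude `event_snr` times the unit background
#' standard deviation) confined to a fronto-central + anterior-temporal
#' channel subset.
#'
#' @param n_patients number of synthetic patients.
#' @param epochs_per_patient epochs generated per patient.
#' @param spasm_fraction fraction of epochs carrying an event (labeled 1).
#' @param fs sampling rate in Hz.
#' @param channel_names montage labels (defaults to the 16-channel montage).
#' @param background_exponent spectral slope beta of the 1/f^beta background.
#' @param event_channels channels carrying the discriminative event.
#' @param slow_wave_hz,burst_hz event component frequencies.
#' @param event_snr event amplitude relative to the unit background SD.
#' @param mixing_weight shared-source mixing weight for baseline
#'   connectivity.
#' @param epoch_length_s epoch duration in seconds.
#' @param gain_sd log-normal sigma of the per-patient gain.
#' @param jitter_prob probability that one event channel is swapped for a
#'   non-event channel in a given patient.
#' @param seed integer seed.
#' @return list of class `synth_config`.
#' @export
synth_config <- function(n_patients = 10, epochs_per_patient = 40,
                         spasm_fraction = 0.25, fs = 250,
                         channel_names = montage_channels(),
                         background_exponent = 1,
                         event_channels = c("F3", "F4", "C3", "C4", "T3", "T4"),
                         slow_wave_hz = 2, burst_hz = 20, event_snr = 3,
                         mixing_weight = 0.2, epoch_length_s = 5,
                         gain_sd = 0.2, jitter_prob = 0.3, seed = 1L) {
  if (spasm_fraction <= 0 || spasm_fraction >= 1)
    stopf("spasm_fraction must lie in (0, 1)")
  event_channels <- normalize_channel_names(event_channels)
  channel_names <- normalize_channel_names(channel_names)
  if (!all(event_channels %in% channel_names))
    stopf("event_channels must be a subset of channel_names")
  if (event_snr <= 0) stopf("event_snr must be positive")
  structure(list(n_patients = n_patients,
                 epochs_per_patient = epochs_per_patient,
                 spasm_fraction = spasm_fraction, fs = fs,
                 channel_names = channel_names,
                 background_exponent = background_exponent,
                 event_channels = event_channels,
                 slow_wave_hz = slow_wave_hz, burst_hz = burst_hz,
                 event_snr = event_snr, mixing_weight = mixing_weight,
                 epoch_length_s = epoch_length_s, gain_sd = gain_sd,
                 jitter_prob = jitter_prob, seed = as.integer(seed)),
            class = "synth_config")
}

# One channel of 1/f^beta noise via spectral shaping of white noise,
# normalized to unit standard deviation.
.colored_noise <- function(n, beta) {
  x <- rnorm(n)
  if (beta != 0) {
    X <- fft(x)
    f <- c(0, seq_len(n - 1))
    f <- pmin(f, n - f)            # symmetric bin distances
    sc <- c(0, 1 / f[-1]^(beta / 2))
    x <- Re(fft(X * sc, inverse = TRUE)) / n
  }
  s <- sd(x)
  if (s > 0) x / s else x
}

#' Generate background EEG noise
#'
#' Per-channel 1/f^beta Gaussian noise with a weak shared source (mixing
#' weight `cfg$mixing_weight`) so baseline connectivity is non-trivial; each
#' channel is normalized to unit standard deviation. Deterministic given the
#' seed.
#'
#' @param cfg a [synth_config()].
#' @param n_samples samples per channel.
#' @param seed seed (defaults to `cfg$seed`); pass `NULL` to draw from the
#'   current RNG stream.
#' @return matrix C x n_samples.
#' @export
generate_background <- function(cfg, n_samples, seed = cfg$seed) {
  if (!is.null(seed)) set.seed(seed)
  C <- length(cfg$channel_names)
  shared <- .colored_noise(n_samples, cfg$background_exponent)
  out <- matrix(0, C, n_samples)
  for (c in seq_len(C)) {
    own <- .colored_noise(n_samples, cfg$background_exponent)
    x <- own + cfg$mixing_weight * shared
    out[c, ] <- x / sd(x)
  }
  rownames(out) <- cfg$channel_names
  out
}

#' Inject a spasm-like event
#'
#' Adds, to the event channels only, a high-amplitude slow wave with a
#' superimposed fast burst over a random 1-3 s sub-interval (Hann-tapered),
#' scaled to `cfg$event_snr`. Non-event channels are returned bit-identical.
#' The event interval and channels are attached as attributes
#' `event_interval` (onset_s, duration_s) and `event_channels`.
#'
#' @param background matrix C x T from [generate_background()].
#' @param cfg a [synth_config()]; `cfg$event_channels` may be
#'   patient-specific.
#' @return matrix C x T with the event added.
#' @export
inject_event <- function(background, cfg) {
  Tn <- ncol(background)
  fs <- cfg$fs
  dur_s <- runif(1, 1, min(3, Tn / fs))
  onset_s <- runif(1, 0, Tn / fs - dur_s)
  i0 <- floor(onset_s * fs) + 1
  i1 <- min(Tn, i0 + round(dur_s * fs) - 1)
  n <- i1 - i0 + 1
  t <- (seq_len(n) - 1) / fs
  taper <- 0.5 - 0.5 * cos(2 * pi * (seq_len(n) - 1) / (n - 1))
  phase <- runif(1, 0, 2 * pi)
  wave <- cfg$event_snr * sin(2 * pi * cfg$slow_wave_hz * t + phase) * taper +
    0.5 * cfg$event_snr * sin(2 * pi * cfg$burst_hz * t) * taper
  out <- background
  idx <- match(cfg$event_channels, cfg$channel_names)
  for (c in idx) out[c, i0:i1] <- out[c, i0:i1] + wave
  attr(out, "event_interval") <- c(onset_s = (i0 - 1) / fs,
                                   duration_s = n / fs)
  attr(out, "event_channels") <- cfg$event_channels
  out
}

#' Generate a labeled synthetic dataset
#'
#' Per patient: a log-normal gain, possibly one event channel swapped with a
#' non-event channel (probability `cfg$jitter_prob`), and
#' `epochs_per_patient` epochs of which a fraction `spasm_fraction` carry an
#' injected event (label 1). Fully reproducible given `cfg$seed`.
#'
#' @param cfg a [synth_config()].
#' @return list with `epochs` (an [epoch_set()]) and `truth` (per-patient
#'   event channels, per-epoch event intervals and labels).
#' @export
generate_dataset <- function(cfg = synth_config()) {
  set.seed(cfg$seed)
  C <- length(cfg$channel_names)
  Tn <- round(cfg$fs * cfg$epoch_length_s)
  n_total <- cfg$n_patients * cfg$epochs_per_patient
  arr <- array(0, dim = c(C, Tn, n_total))
  labels <- integer(n_total)
  patient_ids <- character(n_total)
  truth_channels <- list()
  truth_intervals <- vector("list", n_total)
  e <- 0
  for (p in seq_len(cfg$n_patients)) {
    pid <- sprintf("P%02d", p)
    gain <- exp(rnorm(1, 0, cfg$gain_sd))
    ev_ch <- cfg$event_channels
    if (runif(1) < cfg$jitter_prob) {
      drop_ch <- sample(ev_ch, 1)
      add_ch <- sample(setdiff(cfg$channel_names, ev_ch), 1)
      ev_ch <- c(setdiff(ev_ch, drop_ch), add_ch)
    }
    truth_channels[[pid]] <- ev_ch
    pcfg <- cfg
    pcfg$event_channels <- ev_ch
    n_pos <- round(cfg$spasm_fraction * cfg$epochs_per_patient)
    pos <- sample(cfg$epochs_per_patient, n_pos)
    for (k in seq_len(cfg$epochs_per_patient)) {
      e <- e + 1
      x <- generate_background(cfg, Tn, seed = NULL)
      if (k %in% pos) {
        x <- inject_event(x, pcfg)
        labels[e] <- 1L
        truth_intervals[[e]] <- attr(x, "event_interval")
      }
      arr[, , e] <- gain * x
      patient_ids[e] <- pid
    }
  }
  es <- epoch_set(arr, labels, patient_ids, cfg$fs, cfg$channel_names,
                  cfg$epoch_length_s)
  list(epochs = es,
       truth = list(event_channels = truth_channels,
                    intervals = truth_intervals, labels = labels,
                    config = cfg))
}

#' Synthetic 40-patient cohort table
#'
#' A deterministic patient-level table (spasm counts and recording hours)
#' spanning the clinically typical range, used to exercise the grouped
#' splitting protocols at cohort scale.
#'
#' @param n_patients cohort size.
#' @param seed integer seed.
#' @return data frame with `patient_id`, `spasms`, `hours`.
#' @export
synth_patient_table <- function(n_patients = 40, seed = 1L) {
  set.seed(seed)
  spasms <- pmin(pmax(round(exp(rnorm(n_patients, log(15), 0.45))), 5), 45)
  hours <- round(runif(n_patients, 3, 12.5), 1)
  data.frame(patient_id = sprintf("P%02d", seq_len(n_patients)),
             spasms = spasms, hours = hours, stringsAsFactors = FALSE)
}
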