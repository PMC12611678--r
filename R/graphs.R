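# Per-epoch graph construction: temporal graphs from sliding-window Pearson
# dynamic functional connectivity, spectral graphs from the weighted phase lag
# index (wPLI), and per-band spectral node features.

#' Graph-construction configuration
#'
#' Defaults assume 5-second epochs at 250 Hz: 1-second correlation windows
#' with 0.5-second steps give K = 9 windows per epoch (balancing temporal
#' resolution against correlation stability); wPLI uses Welch cross-spectra
#' with 1-second Hann segments at 50% overlap, pooled over the broadband
#' 0.7-40 Hz range. Band definitions are half-open intervals `[low, high)`.
#'
#' @param window_len_samples sliding-window length L for the dynamic
#'   correlations.
#' @param step_samples window step S.
#' @param eps stabilizer added to the product of window standard deviations.
#' @param wpli_segment_len Welch segment length for the cross-spectra.
#' @param wpli_overlap Welch segment overlap fraction.
#' @param bands named list of frequency intervals (Hz) for node features.
#' @param broadband frequency interval pooled for the wPLI edge weights.
#' @return list of class `graph_config`.
#' @export
graph_config <- function(window_len_samples = 250, step_samples = 125,
                         eps = 1e-8, wpli_segment_len = 250,
                         wpli_overlap = 0.5,
                         bands = list(delta = c(0.7, 4), theta = c(4, 8),
                                      alpha = c(8, 13), beta = c(13, 30),
                                      gamma = c(30, 40)),
                         broadband = c(0.7, 40)) {
  if (window_len_samples < 1 || step_samples < 1)
    stopf("window and step lengths must be >= 1")
  structure(list(window_len_samples = window_len_samples,
                 step_samples = step_samples, eps = eps,
                 wpli_segment_len = wpli_segment_len,
                 wpli_overlap = wpli_overlap, bands = bands,
                 broadband = broadband),
            class = "graph_config")
}

#' Construct a ChannelGraph
#'
#' One epoch's graph: node features, a symmetric zero-diagonal edge-weight
#' matrix over all channel pairs (fully connected, no self-loops) and a
#' modality tag.
#'
#' @param node_features numeric matrix C x F.
#' @param weights numeric symmetric C x C matrix, zero diagonal.
#' @param modality `"temporal"` or `"spectral"`.
#' @param channel_names optional labels (length C).
#' @param validate check the invariants (default TRUE).
#' @return object of class `ChannelGraph`.
#' @export
channel_graph <- function(node_features, weights,
                          modality = c("temporal", "spectral"),
                          channel_names = NULL, validate = TRUE) {
  modality <- match.arg(modality)
  if (validate) {
    if (nrow(node_features) != nrow(weights))
      stopf("node_features and weights disagree on channel count")
    if (max(abs(weights - t(weights))) > 1e-8)
      stopf("weights must be symmetric")
    if (max(abs(diag(weights))) > 1e-12)
      stopf("weights must have a zero diagonal")
    if (modality == "temporal" && max(abs(weights)) > 1 + 1e-9)
      stopf("temporal weights must lie in [-1, 1]")
    if (modality == "spectral" &&
        (min(weights) < -1e-12 || max(weights) > 1 + 1e-9))
      stopf("spectral weights must lie in [0, 1]")
  }
  if (is.null(channel_names))
    channel_names <- paste0("CH", seq_len(nrow(weights)))
  structure(list(node_features = node_features, weights = weights,
                 modality = modality,
                 channel_names = normalize_channel_names(channel_names)),
            class = "ChannelGraph")
}

#' @export
print.ChannelGraph <- function(x, ...) {
  cat(sprintf("<ChannelGraph:%s> %d nodes, %d node features, %d weighted pairs\n",
              x$modality, nrow(x$weights), ncol(x$node_features),
              nrow(x$weights) * (nrow(x$weights) - 1) / 2))
  invisible(x)
}

#' Number of sliding windows
#'
#' `K = floor((T - L) / S) + 1` for signal length `T`, window `L`, step `S`.
#'
#' @param T,L,S sample counts.
#' @return integer K.
#' @export
window_count <- function(T, L, S) {
  if (T < L) stopf("signal shorter than window (T=%d < L=%d)", T, L)
  if (S < 1) stopf("step must be >= 1")
  as.integer(floor((T - L) / S) + 1)
}

#' Sliding-window Pearson correlations
#'
#' For each of the K windows, the sample correlation matrix of the (already
#' standardized) input, with `eps` stabilizing the product of window standard
#' deviations so constant windows give near-zero correlation instead of an
#' error.
#'
#' @param z numeric matrix C x T, standardized per channel.
#' @param cfg a [graph_config()].
#' @return array C x C x K of window correlation matrices.
#' @export
windowed_pearson <- function(z, cfg = graph_config()) {
  C <- nrow(z)
  Tn <- ncol(z)
  L <- cfg$window_len_samples
  S <- cfg$step_samples
  K <- window_count(Tn, L, S)
  out <- array(0, dim = c(C, C, K))
  for (k in seq_len(K)) {
    w <- z[, ((k - 1) * S + 1):((k - 1) * S + L), drop = FALSE]
    wc <- w - rowMeans(w)
    cv <- tcrossprod(wc) / (L - 1)
    sdv <- sqrt(pmax(diag(cv), 0))
    out[, , k] <- cv / (outer(sdv, sdv) + cfg$eps)
  }
  out
}

#' Build a temporal connectivity graph for one epoch
#'
#' Edge weight between channels i and j is the mean of the K sliding-window
#' Pearson correlations; the diagonal is zeroed (no self-loops). Node features
#' are the standardized time series themselves.
#'
#' @param epoch numeric matrix C x T, standardized per channel.
#' @param cfg a [graph_config()].
#' @param channel_names optional channel labels.
#' @return a `ChannelGraph` with modality `"temporal"`.
#' @export
build_temporal_graph <- function(epoch, cfg = graph_config(),
                                 channel_names = NULL) {
  rp <- windowed_pearson(epoch, cfg)
  w <- apply(rp, c(1, 2), mean)
  w <- (w + t(w)) / 2
  diag(w) <- 0
  w[w > 1] <- 1
  w[w < -1] <- -1
  channel_graph(epoch, w, "temporal", channel_names)
}

# Welch-style segmentation: Hann-windowed FFTs of each channel per segment.
# Returns complex array (n_freq x C x K) plus frequencies and the window used.
welch_fft <- function(x, fs, seg_len, overlap) {
  C <- nrow(x)
  Tn <- ncol(x)
  if (seg_len > Tn) stopf("Welch segment length %d exceeds signal length %d",
                          seg_len, Tn)
  step <- max(1, round(seg_len * (1 - overlap)))
  K <- window_count(Tn, seg_len, step)
  win <- 0.5 - 0.5 * cos(2 * pi * (seq_len(seg_len) - 1) / seg_len)
  Z <- array(0i, dim = c(seg_len, C, K))
  for (k in seq_len(K)) {
    seg <- x[, ((k - 1) * step + 1):((k - 1) * step + seg_len), drop = FALSE]
    Z[, , k] <- stats::mvfft(t(seg * rep(win, each = C)))
  }
  list(Z = Z, freqs = (seq_len(seg_len) - 1) * fs / seg_len, win = win, K = K)
}

.band_bins <- function(freqs, low, high, fs, closed_high = TRUE) {
  oneside <- freqs <= fs / 2 + 1e-12
  if (closed_high) which(oneside & freqs >= low - 1e-12 & freqs <= high + 1e-12)
  else which(oneside & freqs >= low - 1e-12 & freqs < high - 1e-12)
}

#' Weighted phase lag index matrix
#'
#' Debiased-free wPLI over Welch cross-spectra: for each channel pair,
#' `|mean Im S| / mean |Im S|`, pooled jointly over Hann-windowed overlapping
#' segments and all in-band frequency bins (`0/0` defined as 0). Insensitive
#' to zero-lag coupling; entries lie in `[0, 1]`.
#'
#' @param epoch numeric matrix C x T.
#' @param fs sampling rate in Hz.
#' @param cfg a [graph_config()].
#' @param band frequency interval pooled (defaults to `cfg$broadband`).
#' @return symmetric C x C matrix with zero diagonal.
#' @export
wpli <- function(epoch, fs, cfg = graph_config(), band = cfg$broadband) {
  C <- nrow(epoch)
  wf <- welch_fft(epoch, fs, cfg$wpli_segment_len, cfg$wpli_overlap)
  bins <- .band_bins(wf$freqs, band[1], band[2], fs)
  iu <- rep(seq_len(C - 1), times = (C - 1):1)
  ju <- unlist(lapply(seq_len(C - 1), function(i) (i + 1):C))
  num <- den <- numeric(length(iu))
  for (k in seq_len(wf$K)) {
    A <- Re(wf$Z[bins, , k, drop = FALSE])
    B <- Im(wf$Z[bins, , k, drop = FALSE])
    dim(A) <- dim(B) <- c(length(bins), C)
    # Im(z_i * conj(z_j)) = Im_i * Re_j - Re_i * Im_j
    im <- B[, iu, drop = FALSE] * A[, ju, drop = FALSE] -
      A[, iu, drop = FALSE] * B[, ju, drop = FALSE]
    num <- num + colSums(im)
    den <- den + colSums(abs(im))
  }
  v <- ifelse(den > 0, abs(num) / den, 0)
  w <- matrix(0, C, C)
  w[cbind(iu, ju)] <- v
  w <- w + t(w)
  w
}

#' Per-band spectral node features
#'
#' For each channel, the log of the band-integrated Welch power (one-sided
#' Hann-windowed periodogram averaged over segments, summed over in-band bins
#' times the bin width) in each configured band. All-zero channels are floored
#' at the smallest representable power with a warning.
#'
#' @param epoch numeric matrix C x T.
#' @param fs sampling rate in Hz.
#' @param cfg a [graph_config()].
#' @return matrix C x B of log band powers.
#' @export
spectral_node_features <- function(epoch, fs, cfg = graph_config()) {
  C <- nrow(epoch)
  wf <- welch_fft(epoch, fs, cfg$wpli_segment_len, cfg$wpli_overlap)
  L <- cfg$wpli_segment_len
  u <- sum(wf$win^2)
  # one-sided Welch PSD, averaged over segments
  P <- matrix(0, L, C)
  for (k in seq_len(wf$K)) P <- P + Mod(wf$Z[, , k])^2
  P <- P / (wf$K * fs * u)
  half <- floor(L / 2) + 1
  P <- P[seq_len(half), , drop = FALSE]
  dbl <- 2:(if (L %% 2 == 0) half - 1 else half)
  P[dbl, ] <- 2 * P[dbl, , drop = FALSE]
  freqs <- wf$freqs[seq_len(half)]
  df <- fs / L
  out <- matrix(0, C, length(cfg$bands),
                dimnames = list(NULL, names(cfg$bands)))
  for (b in seq_along(cfg$bands)) {
    bins <- .band_bins(freqs, cfg$bands[[b]][1], cfg$bands[[b]][2], fs,
                       closed_high = FALSE)
    out[, b] <- colSums(P[bins, , drop = FALSE]) * df
  }
  if (any(out <= 0)) {
    warning("zero band power encountered; flooring at machine tiny")
    out[out <= 0] <- .Machine$double.xmin
  }
  log(out)
}

#' Build a spectral connectivity graph for one epoch
#'
#' Edge weights are the broadband wPLI; node features are the per-band log
#' Welch powers from [spectral_node_features()].
#'
#' @param epoch numeric matrix C x T.
#' @param fs sampling rate in Hz.
#' @param cfg a [graph_config()].
#' @param channel_names optional channel labels.
#' @return a `ChannelGraph` with modality `"spectral"`.
#' @export
build_spectral_graph <- function(epoch, fs, cfg = graph_config(),
                                 channel_names = NULL) {
  channel_graph(spectral_node_features(epoch, fs, cfg),
                wpli(epoch, fs, cfg), "spectral", channel_names)
}

#' Build temporal and spectral graphs for every epoch of an EpochSet
#'
#' Applies the per-epoch z-score (the final preprocessing stage) when
#' requested, then builds both graphs per epoch.
#'
#' @param es an [epoch_set()].
#' @param cfg a [graph_config()].
#' @param zscore standardize each epoch first (default TRUE; set FALSE if the
#'   epochs already come out of [preprocess_recording()]).
#' @param eps z-score stabilizer.
#' @return list (length `n_epochs`) of `list(temporal =, spectral =)` graphs.
#' @export
build_graph_set <- function(es, cfg = graph_config(), zscore = TRUE,
                            eps = 1e-8) {
  lapply(seq_len(n_epochs(es)), function(e) {
    x <- es$epochs[, , e]
    if (zscore) x <- zscore_channels(x, eps)
    list(temporal = build_temporal_graph(x, cfg, es$channel_names),
         spectral = build_spectral_graph(x, es$fs, cfg, es$channel_names))
  })
}
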