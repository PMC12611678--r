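# Shared fixtures: tiny recordings, graphs and model instances built in code.

# A small model configuration whose kernel branches keep toy epochs cheap.
tiny_model_config <- function(C = 6, D = 8, H = 2, regions = 3,
                              spectral_dim = 5) {
  model_config(kernel_sizes = c(12, 8, 5), hidden_width = D, n_heads = H,
               regions = regions, edge_mlp_hidden = 6, classifier_hidden = 10,
               dropout_rate = 0, conv_channels = 3, spectral_dim = spectral_dim)
}

tiny_region_map <- function() {
  stats::setNames(c("frontal", "frontal", "central", "central",
                    "temporal", "temporal"), paste0("CH", 1:6))
}

# Random symmetric zero-diagonal weight matrix in [-1, 1] (or [0, 1]).
random_weights <- function(C, nonneg = FALSE) {
  W <- matrix(rnorm(C * C), C, C)
  W <- (W + t(W)) / 2
  if (nonneg) W <- abs(W)
  W <- W / max(abs(W))
  diag(W) <- 0
  W
}

# Matched random temporal/spectral graph pair on the tiny 6-channel montage.
tiny_graph_pair <- function(Tn = 60, B = 5) {
  ch <- paste0("CH", 1:6)
  tg <- channel_graph(matrix(rnorm(6 * Tn), 6, Tn), random_weights(6),
                      "temporal", ch)
  sg <- channel_graph(matrix(rnorm(6 * B), 6, B), random_weights(6, TRUE),
                      "spectral", ch)
  list(tg = tg, sg = sg)
}

# A sinusoid-mix recording for preprocessing tests.
make_recording <- function(C = 4, fs = 250, dur_s = 10,
                           channels = paste0("CH", seq_len(C)),
                           patient_id = "P01", annotations = NULL) {
  t <- seq_len(fs * dur_s) / fs
  sig <- t(vapply(seq_len(C), function(c)
    10 * sin(2 * pi * (4 + c) * t) + rnorm(length(t)), numeric(length(t))))
  recording(sig, channels, fs, patient_id, annotations)
}

# 20-channel recording containing the full 16-channel montage plus extras,
# in shuffled order.
montage_recording <- function(fs = 250, dur_s = 6, shuffle_seed = 3) {
  set.seed(shuffle_seed)
  chans <- sample(c(montage_channels(), "A1", "A2", "FZ", "CZ"))
  make_recording(C = length(chans), fs = fs, dur_s = dur_s, channels = chans)
}
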