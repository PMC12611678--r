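# Synthetic EEG generator: background spectra, event injection, dataset
# assembly and the statistical structure the rest of the suite relies on.

test_that("generate_background is deterministic and unit-scaled", {
  cfg <- synth_config(seed = 7)
  b1 <- generate_background(cfg, 1250)
  b2 <- generate_background(cfg, 1250)
  expect_identical(b1, b2)
  expect_equal(dim(b1), c(16, 1250))
  expect_equal(unname(apply(b1, 1, stats::sd)), rep(1, 16),
               tolerance = 1e-9)
})

test_that("background with zero spectral slope is white", {
  # Welch log-log slope averaged over seeds stays near zero
  slopes <- vapply(1:20, function(s) {
    cfg <- synth_config(background_exponent = 0, mixing_weight = 0,
                        channel_names = "C3", event_channels = "C3",
                        seed = 400 + s)
    x <- generate_background(cfg, 5000)
    f <- spasmgraph:::welch_fft(x, 250, 250, 0.5)
    P <- rowMeans(vapply(seq_len(f$K), function(k) Mod(f$Z[, 1, k])^2,
                         numeric(250)))
    bins <- 2:100
    stats::coef(stats::lm(log(P[bins]) ~ log(f$freqs[bins])))[2]
  }, 0)
  expect_lt(abs(mean(slopes)), 0.2)
})

test_that("zero mixing weight leaves channels uncorrelated", {
  cfg <- synth_config(mixing_weight = 0, seed = 8)
  x <- generate_background(cfg, 5000)
  cm <- stats::cor(t(x))
  expect_lt(mean(abs(cm[upper.tri(cm)])), 0.1)
})

test_that("inject_event touches only event channels with in-band power", {
  cfg <- synth_config(seed = 9)
  bg <- generate_background(cfg, 1250)
  set.seed(9)
  out <- inject_event(bg, cfg)
  non_ev <- setdiff(cfg$channel_names, cfg$event_channels)
  expect_identical(out[non_ev, ], bg[non_ev, ])
  expect_false(identical(out[cfg$event_channels[1], ],
                         bg[cfg$event_channels[1], ]))
  iv <- attr(out, "event_interval")
  expect_gte(iv["duration_s"], 1 - 1e6 * .Machine$double.eps)
  expect_lte(iv["onset_s"] + iv["duration_s"], 5 + 0.01)

  # burst-band power strictly exceeds background on event channels
  f_out <- spectral_node_features(out[cfg$event_channels, , drop = FALSE], cfg$fs)
  f_bg <- spectral_node_features(bg[cfg$event_channels, , drop = FALSE], cfg$fs)
  expect_true(all(f_out[, "beta"] > f_bg[, "beta"]))

  # vanishing amplitude limit
  cfg0 <- cfg; cfg0$event_snr <- 1e-10
  set.seed(9)
  out0 <- inject_event(bg, cfg0)
  expect_lt(max(abs(out0 - bg)), 1e-9)
})

test_that("generate_dataset produces the configured layout reproducibly", {
  cfg <- synth_config(n_patients = 10, epochs_per_patient = 40,
                      spasm_fraction = 0.25, seed = 1)
  ds <- generate_dataset(cfg)
  expect_equal(n_epochs(ds$epochs), 400)
  expect_equal(sum(ds$epochs$labels), 100)
  expect_equal(length(unique(ds$epochs$patient_ids)), 10)
  # every patient holds the same positive fraction
  per_pat <- tapply(ds$epochs$labels, ds$epochs$patient_ids, sum)
  expect_true(all(per_pat == 10))
  # ground truth lines up with labels
  expect_identical(ds$truth$labels, ds$epochs$labels)
  has_iv <- !vapply(ds$truth$intervals, is.null, TRUE)
  expect_identical(as.integer(has_iv), ds$epochs$labels)
  expect_length(ds$truth$event_channels, 10)

  ds2 <- generate_dataset(cfg)
  expect_identical(ds$epochs$epochs, ds2$epochs$epochs)
  expect_identical(ds$truth$event_channels, ds2$truth$event_channels)
})

test_that("event channels carry the class signal; shuffled labels destroy it", {
  # class-conditional burst-band power difference vanishes under label
  # permutation in at least 90% of seeds
  n_sig <- 0
  n_null_ok <- 0
  for (s in 1:20) {
    cfg <- synth_config(n_patients = 2, epochs_per_patient = 20,
                        spasm_fraction = 0.5, jitter_prob = 0,
                        seed = 500 + s)
    ds <- generate_dataset(cfg)
    ev_idx <- match(cfg$event_channels, ds$epochs$channel_names)
    pw <- vapply(seq_len(n_epochs(ds$epochs)), function(e)
      mean(spectral_node_features(
        ds$epochs$epochs[ev_idx, , e], cfg$fs)[, "beta"]), 0)
    real_p <- stats::t.test(pw[ds$epochs$labels == 1],
                            pw[ds$epochs$labels == 0])$p.value
    set.seed(9000 + s)
    sh <- sample(ds$epochs$labels)
    null_p <- stats::t.test(pw[sh == 1], pw[sh == 0])$p.value
    n_sig <- n_sig + (real_p < 0.05)
    n_null_ok <- n_null_ok + (null_p >= 0.05)
  }
  expect_gte(n_sig, 18)
  expect_gte(n_null_ok, 18)
})

test_that("patient jitter swaps at most one event channel", {
  cfg <- synth_config(n_patients = 8, epochs_per_patient = 2,
                      jitter_prob = 1, seed = 11)
  ds <- generate_dataset(cfg)
  for (ev in ds$truth$event_channels) {
    expect_length(ev, length(cfg$event_channels))
    expect_equal(length(setdiff(cfg$event_channels, ev)), 1)
  }
})

test_that("synth_patient_table is deterministic with clinical-range counts", {
  t1 <- synth_patient_table(40)
  t2 <- synth_patient_table(40)
  expect_identical(t1, t2)
  expect_equal(nrow(t1), 40)
  expect_true(all(t1$spasms >= 5 & t1$spasms <= 45))
  expect_true(all(t1$hours >= 3 & t1$hours <= 12.5))
})

test_that("held-out AUC is monotone in event_snr (scaled-down benchmark)", {
  # Scaled down for runtime, but large enough (100 held-out epochs) that the
  # AUC estimate has statistical power: 10 patients x 20 epochs, one grouped
  # split, 12 training epochs, D = 16. The trend over event_snr in
  # {0.5, 1, 2, 4} must be non-decreasing up to one small inversion.
  aucs <- vapply(c(0.5, 1, 2, 4), function(snr) {
    cfg <- synth_config(n_patients = 10, epochs_per_patient = 20,
                        spasm_fraction = 0.25, event_snr = snr, seed = 21)
    ds <- generate_dataset(cfg)
    graphs <- build_graph_set(ds$epochs)
    pids <- unique(ds$epochs$patient_ids)
    train_idx <- which(ds$epochs$patient_ids %in% pids[1:5])
    test_idx <- which(ds$epochs$patient_ids %in% pids[6:10])
    mcfg <- model_config(hidden_width = 16, n_heads = 4)
    tcfg <- train_config(epochs = 12, seed = 3)
    ridx <- spasmgraph:::make_region_index(default_region_map(),
                                           ds$epochs$channel_names)
    fit <- spasmgraph:::train_fold(ds$epochs, graphs, train_idx, test_idx,
                                   tcfg, mcfg, ridx, seed = 3)
    fit$metrics$auc
  }, 0)
  d <- diff(aucs)
  expect_lte(sum(d < 0), 1)       # at most one inversion
  expect_gte(min(d), -0.02)       # and only within sampling noise
})
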