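# Forward operations of the network, each against an independent oracle, plus
# end-to-end differentiability and symmetry properties.

test_that("multiscale_encode has the right shape and linear zero behavior", {
  set.seed(31)
  cfg <- tiny_model_config()
  params <- init_model_params(cfg, seed = 1)
  x <- matrix(rnorm(6 * 60), 6, 60)
  H <- multiscale_encode(x, params, cfg)
  expect_equal(dim(H), c(6, cfg$hidden_width))

  # zero input, zero biases, inference BN with zero mean / unit variance
  p0 <- params
  for (b in seq_along(p0$conv)) p0$conv[[b]]$beta <- rep(0, cfg$conv_channels)
  p0$phi$b <- rep(0, cfg$hidden_width)
  H0 <- multiscale_encode(matrix(0, 6, 60), p0, cfg, training = FALSE)
  expect_equal(max(abs(H0)), 0)
})

test_that("multiscale_encode is shift-invariant for periodic inputs", {
  # period 10 divides every branch's pooled length (T=110, kernels 11/21/31)
  cfg <- model_config(kernel_sizes = c(11, 21, 31), hidden_width = 8,
                      n_heads = 2, regions = 3, edge_mlp_hidden = 6,
                      classifier_hidden = 10, dropout_rate = 0,
                      conv_channels = 3, spectral_dim = 5)
  params <- init_model_params(cfg, seed = 2)
  t <- seq_len(110)
  x <- rbind(sin(2 * pi * t / 10), cos(2 * pi * t / 10) + sin(2 * pi * t / 5))
  xs <- rbind(sin(2 * pi * (t + 10) / 10),
              cos(2 * pi * (t + 10) / 10) + sin(2 * pi * (t + 10) / 5))
  H1 <- multiscale_encode(x, params, cfg, training = TRUE)
  H2 <- multiscale_encode(xs, params, cfg, training = TRUE)
  expect_lt(max(abs(H1 - H2)), 1e-5)
})

test_that("project_nodes is the documented affine map", {
  cfg <- tiny_model_config()
  params <- init_model_params(cfg, seed = 3)
  D <- cfg$hidden_width
  # identity weights, zero bias
  params$proj$t$W <- diag(D)
  params$proj$t$b <- rep(0, D)
  X <- matrix(rnorm(6 * D), 6, D)
  expect_equal(project_nodes(X, params, "temporal"), X)
  # zero input broadcasts the bias
  params$proj$s$b <- seq_len(D) / 10
  Z <- project_nodes(matrix(0, 6, cfg$spectral_dim), params, "spectral")
  expect_equal(Z, matrix(seq_len(D) / 10, 6, D, byrow = TRUE))
  # random case equals the dense-algebra oracle
  set.seed(32)
  params <- init_model_params(cfg, seed = 4)
  F0 <- matrix(rnorm(6 * cfg$spectral_dim), 6)
  expect_equal(project_nodes(F0, params, "spectral"),
               F0 %*% params$proj$s$W +
                 matrix(params$proj$s$b, 6, D, byrow = TRUE),
               tolerance = 1e-6)
  expect_error(project_nodes(matrix(0, 6, 3), params, "spectral"), "width")
})

test_that("edge_conditioned_conv matches the explicit double-loop oracle", {
  set.seed(33)
  for (trial in 1:5) {
    C <- sample(3:4, 1)
    D <- sample(c(4, 8), 1)
    cfg <- model_config(kernel_sizes = c(5, 4, 3), hidden_width = D,
                        n_heads = 2, regions = 2, edge_mlp_hidden = 5,
                        classifier_hidden = 8, dropout_rate = 0,
                        conv_channels = 2, spectral_dim = 5)
    params <- init_model_params(cfg, seed = 100 + trial)
    Xh <- matrix(rnorm(C * D), C, D)
    A <- random_weights(C)
    Z <- edge_conditioned_conv(Xh, A, params, cfg, "temporal")
    Zo <- oracle_ecc(Xh, A, params$edge$t, params$ln$t, cfg$ln_eps)
    expect_lt(max(abs(Z - Zo)), 1e-5)
  }
})

test_that("edge_conditioned_conv symmetry and identity-kernel cases", {
  cfg <- tiny_model_config()
  params <- init_model_params(cfg, seed = 5)
  D <- cfg$hidden_width
  # equal edges and equal node features give identical output rows
  Xh <- matrix(rep(seq_len(D) / D, each = 6), 6, D)
  A <- matrix(0.5, 6, 6); diag(A) <- 0
  Z <- edge_conditioned_conv(Xh, A, params, cfg, "temporal")
  expect_lt(max(abs(sweep(Z, 2, Z[1, ]))), 1e-10)

  # MLP frozen to the flattened identity: pre-activation aggregate equals the
  # neighbor mean
  p2 <- params
  p2$edge$t$w1 <- rep(0, length(p2$edge$t$w1))
  p2$edge$t$b1 <- rep(0, length(p2$edge$t$b1))
  p2$edge$t$W2 <- matrix(0, nrow(p2$edge$t$W2), D * D)
  p2$edge$t$b2 <- as.numeric(diag(D))
  set.seed(34)
  Xr <- matrix(rnorm(6 * D), 6, D)
  Ar <- random_weights(6)
  fw <- spasmgraph:::.ecc_fwd(Xr, Ar, p2$edge$t, p2$ln$t, cfg)
  agg <- fw$cache$maskS * 0  # placeholder shape
  for (i in 1:6) agg[i, ] <- colMeans(Xr[-i, , drop = FALSE])
  S <- spasmgraph:::ecc_msg_fwd_cpp(
    matrix(as.numeric(diag(D)), 15, D * D, byrow = TRUE), Xr,
    spasmgraph:::pair_index(6)$i, spasmgraph:::pair_index(6)$j) / 5
  expect_lt(max(abs(S - agg)), 1e-10)

  # NaN edge attribute is a validation error
  Anan <- Ar; Anan[1, 2] <- Anan[2, 1] <- NaN
  expect_error(edge_conditioned_conv(Xr, Anan, params, cfg, "temporal"),
               "NA/NaN")
})

test_that("region_attention_pool matches its softmax oracle and edge cases", {
  set.seed(35)
  cfg <- tiny_model_config()
  params <- init_model_params(cfg, seed = 6)
  rmap <- tiny_region_map()
  Z <- matrix(rnorm(6 * cfg$hidden_width), 6)
  rf <- region_attention_pool(Z, rmap, params, "temporal")
  expect_s3_class(rf, "RegionFeatures")
  for (al in rf$alphas) {
    expect_true(all(al > 0))
    expect_equal(sum(al), 1, tolerance = 1e-6)
  }
  ridx <- spasmgraph:::make_region_index(rmap, names(rmap))
  expect_lt(max(abs(rf$U - oracle_region_pool(Z, ridx, params$att$t))), 1e-6)

  # singleton region returns that channel's embedding exactly
  rmap1 <- stats::setNames(c("frontal", "central", "central",
                             "temporal", "temporal", "temporal"),
                           paste0("CH", 1:6))
  rf1 <- region_attention_pool(Z, rmap1, params, "temporal")
  expect_equal(rf1$U[1, ], Z[1, ])

  # zero scores give uniform attention
  p0 <- params
  p0$att$t <- matrix(0, cfg$regions, cfg$hidden_width)
  rf0 <- region_attention_pool(Z, rmap, p0, "temporal")
  expect_equal(rf0$alphas$frontal, rep(0.5, 2))

  # a region named by the map but missing from the input is a config error
  expect_error(region_attention_pool(Z[1:4, ], rmap, params, "temporal",
                                     channel_names = paste0("CH", 1:4)),
               "no channels")
})

test_that("16-channel region pooling matches the oracle on the real montage", {
  set.seed(36)
  cfg <- model_config(hidden_width = 16, n_heads = 4)
  params <- init_model_params(cfg, seed = 7)
  Z <- matrix(rnorm(16 * 16), 16)
  rf <- region_attention_pool(Z, default_region_map(), params, "spectral",
                              channel_names = montage_channels())
  ridx <- spasmgraph:::make_region_index(default_region_map(),
                                         montage_channels())
  expect_lt(max(abs(rf$U - oracle_region_pool(Z, ridx, params$att$s))), 1e-6)
})

test_that("cross_modal_attention normalizes, degenerates and matches its oracle", {
  set.seed(37)
  cfg <- tiny_model_config(D = 8, H = 2, regions = 3)
  params <- init_model_params(cfg, seed = 8)
  U_t <- matrix(rnorm(3 * 8), 3)
  U_s <- matrix(rnorm(3 * 8), 3)
  out <- cross_modal_attention(U_t, U_s, params, cfg)
  for (Aw in attr(out$temporal, "attention"))
    expect_equal(rowSums(Aw), rep(1, 3), tolerance = 1e-6)

  # H=2 random case equals the per-head dense-algebra oracle
  expect_lt(max(abs(out$temporal -
                      oracle_cross_attention(U_t, U_s, params$ca$ts, 2))), 1e-5)
  expect_lt(max(abs(out$spectral -
                      oracle_cross_attention(U_s, U_t, params$ca$st, 2))), 1e-5)

  # H=1 with identity projections and identical value rows collapses to that row
  cfg1 <- tiny_model_config(D = 4, H = 1, regions = 3)
  p1 <- init_model_params(cfg1, seed = 9)
  p1$ca$ts[c("WQ", "WK", "WV", "WO")] <- list(diag(4), diag(4), diag(4), diag(4))
  Us_same <- matrix(rep(c(1, 2, 3, 4), each = 3), 3)
  out1 <- cross_modal_attention(matrix(rnorm(12), 3), Us_same, p1, cfg1)
  expect_lt(max(abs(sweep(out1$temporal, 2, c(1, 2, 3, 4)))), 1e-10)
})

test_that("gated_fusion blends convexly with the documented limits", {
  set.seed(38)
  cfg <- tiny_model_config()
  params <- init_model_params(cfg, seed = 10)
  R <- cfg$regions; D <- cfg$hidden_width
  raw <- matrix(rnorm(R * D), R)
  enh <- matrix(rnorm(R * D), R)
  # gate driven to 0 returns raw; to 1 returns enhanced
  p0 <- params
  p0$gate$t$W <- matrix(0, 2 * D, D); p0$gate$t$b <- rep(-1e3, D)
  expect_equal(gated_fusion(raw, enh, p0, "temporal"), raw, tolerance = 1e-12)
  p0$gate$t$b <- rep(1e3, D)
  expect_equal(gated_fusion(raw, enh, p0, "temporal"), enh, tolerance = 1e-12)
  # convexity: outputs inside the elementwise [min, max] envelope
  fu <- gated_fusion(raw, enh, params, "temporal")
  expect_true(all(fu >= pmin(raw, enh) - 1e-12 & fu <= pmax(raw, enh) + 1e-12))
})

test_that("classify outputs calibrated probabilities deterministically", {
  cfg <- tiny_model_config()
  params <- init_model_params(cfg, seed = 11)
  R <- cfg$regions; D <- cfg$hidden_width
  Ft <- matrix(rnorm(R * D), R); Fs <- matrix(rnorm(R * D), R)
  p <- classify(Ft, Fs, params, cfg)
  expect_gt(p, 0); expect_lt(p, 1)
  expect_identical(as.numeric(classify(Ft, Fs, params, cfg)), as.numeric(p))

  p0 <- params
  p0$cls$W1 <- p0$cls$W1 * 0; p0$cls$b1 <- p0$cls$b1 * 0
  p0$cls$W2 <- p0$cls$W2 * 0; p0$cls$b2 <- 0
  expect_equal(as.numeric(classify(Ft, Fs, p0, cfg)), 0.5)
})

test_that("model_forward composes, differentiates and validates", {
  set.seed(39)
  cfg <- tiny_model_config()
  params <- init_model_params(cfg, seed = 12)
  g <- tiny_graph_pair()
  rmap <- tiny_region_map()
  p <- model_forward(g$tg, g$sg, params, cfg, rmap)
  expect_gt(as.numeric(p), 0); expect_lt(as.numeric(p), 1)

  # all parameter gradients finite
  ridx <- spasmgraph:::make_region_index(rmap, names(rmap))
  fw <- spasmgraph:::nn_forward(g$tg, g$sg, params, cfg, ridx)
  bw <- spasmgraph:::nn_backward(fw$cache, params, cfg, 1, want_input_grads = TRUE)
  for (leaf in spasmgraph:::flatten_leaves(bw$grads))
    expect_true(all(is.finite(leaf)))

  # finite-difference directional derivative w.r.t. one input channel
  eps <- 1e-5
  dirn <- matrix(0, 6, 60); dirn[3, ] <- rnorm(60)
  tg_p <- g$tg; tg_p$node_features <- tg_p$node_features + eps * dirn
  tg_m <- g$tg; tg_m$node_features <- tg_m$node_features - eps * dirn
  fd <- (attr(model_forward(tg_p, g$sg, params, cfg, rmap), "logit") -
           attr(model_forward(tg_m, g$sg, params, cfg, rmap), "logit")) / (2 * eps)
  ad <- sum(bw$dXt * dirn)
  expect_lt(abs(fd - ad) / max(abs(fd), abs(ad)), 1e-3)

  # channel-set mismatch between the graphs is a validation error
  sg_bad <- g$sg; sg_bad$channel_names <- rev(sg_bad$channel_names)
  expect_error(model_forward(g$tg, sg_bad, params, cfg, rmap), "disagree")
})

test_that("model_forward is invariant to channel permutations within a region", {
  set.seed(40)
  cfg <- tiny_model_config()
  params <- init_model_params(cfg, seed = 13)
  g <- tiny_graph_pair()
  rmap <- tiny_region_map()
  p1 <- model_forward(g$tg, g$sg, params, cfg, rmap)
  # swap CH1/CH2 (both frontal) consistently everywhere
  perm <- c(2, 1, 3, 4, 5, 6)
  tg2 <- channel_graph(g$tg$node_features[perm, ],
                       g$tg$weights[perm, perm], "temporal",
                       g$tg$channel_names)
  sg2 <- channel_graph(g$sg$node_features[perm, ],
                       g$sg$weights[perm, perm], "spectral",
                       g$sg$channel_names)
  p2 <- model_forward(tg2, sg2, params, cfg, rmap)
  expect_lt(abs(as.numeric(p1) - as.numeric(p2)), 1e-5)
})
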