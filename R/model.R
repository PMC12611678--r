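# The cross-modal temporal-spectral graph network: multi-scale temporal
# encoding, shared-width projection, edge-conditioned graph convolution,
# region attention pooling, bidirectional multi-head cross-modal attention,
# gated fusion and classification.
#
# Exposed operations are thin wrappers around internal cached forward passes
# (.ms_fwd, .ecc_fwd, ...) shared with the analytic backward pass in
# backprop.R.

#' Model configuration
#'
#' Architecture hyper-parameters. Kernel sizes \{100, 50, 25\} capture long-,
#' medium- and short-range temporal structure at 250 Hz; the remaining widths
#' are engineering defaults (the architecture fixes none of them) and are all
#' configurable.
#'
#' @param kernel_sizes 1-D convolution kernel lengths for the three parallel
#'   branches.
#' @param hidden_width shared embedding width D.
#' @param n_heads attention heads H (must divide D).
#' @param regions number of anatomical regions R (5).
#' @param edge_mlp_hidden hidden width of the scalar-edge-to-kernel MLP.
#' @param classifier_hidden hidden width of the final classifier.
#' @param dropout_rate classifier dropout probability (training only).
#' @param conv_channels output channels per convolution branch.
#' @param spectral_dim width of the spectral node features (number of bands).
#' @param bn_momentum running-statistics momentum for batch normalization.
#' @param bn_eps,ln_eps numerical stabilizers for batch/layer normalization.
#' @return list of class `model_config`.
#' @export
model_config <- function(kernel_sizes = c(100, 50, 25), hidden_width = 64,
                         n_heads = 4, regions = 5, edge_mlp_hidden = 64,
                         classifier_hidden = 128, dropout_rate = 0.5,
                         conv_channels = 8, spectral_dim = 5,
                         bn_momentum = 0.9, bn_eps = 1e-5, ln_eps = 1e-5) {
  if (hidden_width %% n_heads != 0)
    stopf("hidden_width (%d) must be divisible by n_heads (%d)",
          hidden_width, n_heads)
  if (any(c(kernel_sizes, hidden_width, n_heads, regions, edge_mlp_hidden,
            classifier_hidden, conv_channels) < 1))
    stopf("all sizes must be positive")
  structure(list(kernel_sizes = kernel_sizes, hidden_width = hidden_width,
                 n_heads = n_heads, head_dim = hidden_width %/% n_heads,
                 regions = regions, edge_mlp_hidden = edge_mlp_hidden,
                 classifier_hidden = classifier_hidden,
                 dropout_rate = dropout_rate, conv_channels = conv_channels,
                 spectral_dim = spectral_dim, bn_momentum = bn_momentum,
                 bn_eps = bn_eps, ln_eps = ln_eps),
            class = "model_config")
}

#' Default channel-to-region assignment for the 16-channel 10-20 montage
#'
#' Channels are grouped into the five anatomical regions (frontal, central,
#' parietal, occipital, temporal); F7/F8 are frontal per 10-20 nomenclature.
#' The assignment ships as a JSON config file, not code.
#'
#' @return named character vector: channel label -> region.
#' @export
default_region_map <- function() {
  path <- system.file("extdata", "region_map_1020.json",
                      package = "spasmgraph")
  m <- jsonlite::read_json(path, simplifyVector = TRUE)
  unlist(m)
}

#' Canonical region order
#' @return character vector of the five region names.
#' @export
region_names <- function() {
  c("frontal", "central", "parietal", "occipital", "temporal")
}

# Resolve a region map against a channel list: list of per-region channel
# index vectors in canonical region order (regions absent from the map are
# dropped, so reduced montages and toy models work). Every channel must be
# assigned and every region named by the map must be non-empty.
make_region_index <- function(rmap, channel_names) {
  channel_names <- normalize_channel_names(channel_names)
  names(rmap) <- normalize_channel_names(names(rmap))
  missing <- setdiff(channel_names, names(rmap))
  if (length(missing))
    stopf("region map does not cover channel(s): %s",
          paste(missing, collapse = ", "))
  regs <- c(intersect(region_names(), unique(rmap)),
            setdiff(unique(rmap), region_names()))
  idx <- lapply(regs, function(r)
    which(channel_names %in% names(rmap)[rmap == r]))
  names(idx) <- regs
  empty <- names(idx)[vapply(idx, length, 1L) == 0]
  if (length(empty))
    stopf("region(s) with no channels: %s", paste(empty, collapse = ", "))
  idx
}

# Glorot-uniform weight matrix.
glorot <- function(fin, fout) {
  lim <- sqrt(6 / (fin + fout))
  matrix(runif(fin * fout, -lim, lim), fin, fout)
}

#' Initialize model parameters
#'
#' Glorot-uniform weights, zero biases, unit batch/layer-norm gains. Batch
#' normalization running statistics (`run_mean`, `run_var`) live alongside the
#' trainable tensors but are excluded from optimization.
#'
#' @param cfg a [model_config()].
#' @param seed optional integer seed for reproducible initialization.
#' @return nested parameter list.
#' @export
init_model_params <- function(cfg, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  D <- cfg$hidden_width
  Fc <- cfg$conv_channels
  Hm <- cfg$edge_mlp_hidden
  R <- cfg$regions
  conv <- lapply(cfg$kernel_sizes, function(k)
    list(K = glorot(k, Fc), gamma = rep(1, Fc), beta = rep(0, Fc),
         run_mean = rep(0, Fc), run_var = rep(1, Fc)))
  names(conv) <- paste0("br", seq_along(cfg$kernel_sizes))
  edge_mod <- function()
    list(w1 = drop(glorot(1, Hm)), b1 = rep(0, Hm),
         W2 = glorot(Hm, D * D), b2 = rep(0, D * D))
  ca_dir <- function()
    list(WQ = glorot(D, D), WK = glorot(D, D), WV = glorot(D, D),
         WO = glorot(D, D))
  list(
    conv = conv,
    phi = list(W = glorot(length(cfg$kernel_sizes) * Fc, D), b = rep(0, D)),
    proj = list(t = list(W = glorot(D, D), b = rep(0, D)),
                s = list(W = glorot(cfg$spectral_dim, D), b = rep(0, D))),
    edge = list(t = edge_mod(), s = edge_mod()),
    ln = list(t = list(g = rep(1, D), b = rep(0, D)),
              s = list(g = rep(1, D), b = rep(0, D))),
    att = list(t = glorot(R, D) * sqrt((R + D) / (1 + D)),
               s = glorot(R, D) * sqrt((R + D) / (1 + D))),
    ca = list(ts = ca_dir(), st = ca_dir()),
    gate = list(t = list(W = glorot(2 * D, D), b = rep(0, D)),
                s = list(W = glorot(2 * D, D), b = rep(0, D))),
    cls = list(W1 = glorot(2 * R * D, cfg$classifier_hidden),
               b1 = rep(0, cfg$classifier_hidden),
               W2 = glorot(cfg$classifier_hidden, 1),
               b2 = 0)
  )
}

# --- multi-scale temporal encoder -------------------------------------------

.ms_fwd <- function(X, params, cfg, training = FALSE) {
  C <- nrow(X)
  Tn <- ncol(X)
  if (max(cfg$kernel_sizes) > Tn)
    stopf("epoch length %d shorter than largest kernel %d", Tn,
          max(cfg$kernel_sizes))
  Xt <- t(X)
  pooled <- list()
  caches <- list()
  for (b in seq_along(cfg$kernel_sizes)) {
    pb <- params$conv[[b]]
    fw <- conv_branch_fwd_cpp(Xt, pb$K, pb$gamma, pb$beta, pb$run_mean,
                              pb$run_var, cfg$bn_momentum, cfg$bn_eps,
                              training)
    if (training) {
      params$conv[[b]]$run_mean <- drop(fw$run_mean)
      params$conv[[b]]$run_var <- drop(fw$run_var)
    }
    pooled[[b]] <- fw$pooled
    caches[[b]] <- list(xhat = fw$xhat, inv_sd = drop(fw$inv_sd),
                        k = cfg$kernel_sizes[b], training = training)
  }
  Hc <- do.call(cbind, pooled)
  H <- Hc %*% params$phi$W + row_bcast(params$phi$b, C)
  list(H = H, cache = list(X = X, Xt = Xt, Hc = Hc, branches = caches),
       params = params)
}

#' Multi-scale temporal encoding
#'
#' Three parallel valid (no-padding, stride-1) 1-D convolutions per channel
#' with batch normalization and ReLU, global average pooling over the
#' remaining time axis per branch, concatenation across branches and an
#' affine map to the shared width D.
#'
#' @param x numeric matrix N x T (channels as rows).
#' @param params model parameters.
#' @param cfg a [model_config()].
#' @param training use batch statistics (TRUE) or running statistics (FALSE)
#'   in batch normalization.
#' @return N x D embedding matrix.
#' @export
multiscale_encode <- function(x, params, cfg, training = FALSE) {
  .ms_fwd(x, params, cfg, training)$H
}

# --- node projection --------------------------------------------------------

.proj_fwd <- function(Feat, pm) {
  list(out = Feat %*% pm$W + row_bcast(pm$b, nrow(Feat)),
       cache = list(Feat = Feat))
}

#' Project node features to the shared width
#'
#' Affine map of each node's feature vector to width D; the temporal branch
#' projects the multi-scale embeddings, the spectral branch the per-band
#' powers.
#'
#' @param features numeric matrix C x F.
#' @param params model parameters.
#' @param modality `"temporal"` or `"spectral"`.
#' @return C x D matrix.
#' @export
project_nodes <- function(features, params,
                          modality = c("temporal", "spectral")) {
  modality <- match.arg(modality)
  pm <- params$proj[[substr(modality, 1, 1)]]
  if (ncol(features) != nrow(pm$W))
    stopf("feature width %d does not match projection input width %d",
          ncol(features), nrow(pm$W))
  .proj_fwd(features, pm)$out
}

# --- edge-conditioned graph convolution -------------------------------------

# Unordered upper-triangle pair indices for C nodes.
pair_index <- function(C) {
  iu <- rep(seq_len(C - 1), times = (C - 1):1)
  ju <- unlist(lapply(seq_len(C - 1), function(i) (i + 1):C))
  list(i = iu, j = ju)
}

.ecc_fwd <- function(Xh, W, pm, pln, cfg) {
  C <- nrow(Xh)
  D <- ncol(Xh)
  pr <- pair_index(C)
  a <- W[cbind(pr$i, pr$j)]
  if (anyNA(a)) stopf("edge attributes contain NA/NaN")
  E <- length(a)
  H1pre <- outer(a, pm$w1) + row_bcast(pm$b1, E)
  H1 <- relu(H1pre)
  Wflat <- H1 %*% pm$W2 + row_bcast(pm$b2, E)
  S <- ecc_msg_fwd_cpp(Wflat, Xh, pr$i, pr$j) / (C - 1)
  maskS <- S > 0
  Zr <- S * maskS
  mu <- rowMeans(Zr)
  va <- rowMeans(Zr * Zr) - mu * mu
  inv_sd <- 1 / sqrt(va + cfg$ln_eps)
  xh <- (Zr - mu) * inv_sd
  Z <- xh * row_bcast(pln$g, C) + row_bcast(pln$b, C)
  list(Z = Z,
       cache = list(Xh = Xh, a = a, H1pre = H1pre, H1 = H1, Wflat = Wflat,
                    maskS = maskS, xh = xh, inv_sd = inv_sd, pr = pr))
}

#' Edge-conditioned graph convolution
#'
#' Each scalar edge attribute is mapped by an MLP to a D x D kernel; node
#' features are updated by mean aggregation of kernel-transformed neighbor
#' features over the fully connected neighborhood, followed by ReLU and
#' LayerNorm.
#'
#' @param nodes numeric matrix C x D of projected node features.
#' @param weights symmetric C x C edge-weight matrix (zero diagonal).
#' @param params model parameters.
#' @param cfg a [model_config()].
#' @param modality `"temporal"` or `"spectral"` (selects the edge MLP).
#' @return C x D matrix of updated node features.
#' @export
edge_conditioned_conv <- function(nodes, weights, params, cfg,
                                  modality = c("temporal", "spectral")) {
  modality <- match.arg(modality)
  m <- substr(modality, 1, 1)
  .ecc_fwd(nodes, weights, params$edge[[m]], params$ln[[m]], cfg)$Z
}

# --- region attention pooling -----------------------------------------------

.pool_fwd <- function(Z, ridx, wm) {
  R <- length(ridx)
  D <- ncol(Z)
  U <- matrix(0, R, D)
  alphas <- vector("list", R)
  for (r in seq_len(R)) {
    idx <- ridx[[r]]
    s <- drop(Z[idx, , drop = FALSE] %*% wm[r, ])
    al <- softmax_vec(s)
    U[r, ] <- colSums(Z[idx, , drop = FALSE] * al)
    alphas[[r]] <- al
  }
  list(U = U, alphas = alphas)
}

#' Region attention pooling
#'
#' Within each anatomical region, channel embeddings are scored against a
#' learnable region vector, softmax-normalized, and summed with the resulting
#' attention weights, yielding one embedding per region.
#'
#' @param nodes numeric matrix C x D of node embeddings.
#' @param rmap named channel -> region map (see [default_region_map()]).
#' @param params model parameters.
#' @param modality `"temporal"` or `"spectral"`.
#' @param channel_names labels for the rows of `nodes`.
#' @return object of class `RegionFeatures`: list with `U` (R x D) and
#'   `alphas` (per-region attention weights, each summing to 1).
#' @export
region_attention_pool <- function(nodes, rmap, params,
                                  modality = c("temporal", "spectral"),
                                  channel_names = names(rmap)) {
  modality <- match.arg(modality)
  ridx <- make_region_index(rmap, channel_names)
  out <- .pool_fwd(nodes, ridx, params$att[[substr(modality, 1, 1)]])
  names(out$alphas) <- names(ridx)
  structure(out, class = "RegionFeatures")
}

# --- cross-modal attention --------------------------------------------------

# One direction of scaled dot-product multi-head attention: queries from Uq,
# keys/values from Ukv.
.ca_fwd <- function(Uq, Ukv, pd, cfg) {
  H <- cfg$n_heads
  dh <- cfg$head_dim
  Q <- Uq %*% pd$WQ
  K <- Ukv %*% pd$WK
  V <- Ukv %*% pd$WV
  R <- nrow(Uq)
  O <- matrix(0, R, cfg$hidden_width)
  Aw <- vector("list", H)
  for (h in seq_len(H)) {
    cols <- ((h - 1) * dh + 1):(h * dh)
    P <- tcrossprod(Q[, cols, drop = FALSE], K[, cols, drop = FALSE]) / sqrt(dh)
    Aw[[h]] <- softmax_rows(P)
    O[, cols] <- Aw[[h]] %*% V[, cols, drop = FALSE]
  }
  list(out = O %*% pd$WO,
       cache = list(Uq = Uq, Ukv = Ukv, Q = Q, K = K, V = V, Aw = Aw, O = O))
}

#' Bidirectional multi-head cross-modal attention
#'
#' Temporal region features attend to spectral ones (queries from the temporal
#' matrix, keys/values from the spectral matrix) and vice versa, with scaled
#' dot-product attention per head over the R region positions, concatenated
#' heads and an output projection.
#'
#' @param U_t,U_s R x D region-feature matrices (or `RegionFeatures`).
#' @param params model parameters.
#' @param cfg a [model_config()].
#' @return list with enhanced matrices `temporal` and `spectral`, each with
#'   an `"attention"` attribute holding the per-head softmax weights.
#' @export
cross_modal_attention <- function(U_t, U_s, params, cfg) {
  if (inherits(U_t, "RegionFeatures")) U_t <- U_t$U
  if (inherits(U_s, "RegionFeatures")) U_s <- U_s$U
  ts <- .ca_fwd(U_t, U_s, params$ca$ts, cfg)
  st <- .ca_fwd(U_s, U_t, params$ca$st, cfg)
  list(temporal = structure(ts$out, attention = ts$cache$Aw),
       spectral = structure(st$out, attention = st$cache$Aw))
}

# --- gated fusion -----------------------------------------------------------

.gate_fwd <- function(U, Ue, pg) {
  cat2 <- cbind(U, Ue)
  G <- sigmoid(cat2 %*% pg$W + row_bcast(pg$b, nrow(U)))
  list(out = G * Ue + (1 - G) * U, cache = list(U = U, Ue = Ue, G = G))
}

#' Gated fusion of raw and attention-enhanced features
#'
#' An elementwise sigmoid gate computed from the concatenated inputs blends
#' the raw and enhanced region features convexly:
#' `g * enhanced + (1 - g) * raw`.
#'
#' @param raw,enh R x D matrices.
#' @param params model parameters.
#' @param modality `"temporal"` or `"spectral"` (selects the gate weights).
#' @return fused R x D matrix.
#' @export
gated_fusion <- function(raw, enh, params,
                         modality = c("temporal", "spectral")) {
  modality <- match.arg(modality)
  if (!all(dim(raw) == dim(enh))) stopf("raw and enhanced shapes differ")
  .gate_fwd(raw, enh, params$gate[[substr(modality, 1, 1)]])$out
}

# --- classifier -------------------------------------------------------------

.cls_fwd <- function(Ft, Fs, pc, cfg, training = FALSE) {
  f <- c(as.vector(t(Ft)), as.vector(t(Fs)))
  hpre <- drop(f %*% pc$W1) + pc$b1
  h <- relu(hpre)
  if (training && cfg$dropout_rate > 0) {
    mask <- (runif(length(h)) >= cfg$dropout_rate) / (1 - cfg$dropout_rate)
  } else {
    mask <- rep(1, length(h))
  }
  hd <- h * mask
  logit <- drop(sum(hd * pc$W2)) + pc$b2
  list(logit = logit, prob = sigmoid(logit),
       cache = list(f = f, hpre = hpre, mask = mask, hd = hd))
}

#' Final classification head
#'
#' Concatenates both modalities' fused region features (flattened to length
#' 2 * R * D), applies a two-layer fully connected network with ReLU and
#' dropout (active only during training), and a sigmoid output.
#'
#' @param fused_t,fused_s R x D fused region features per modality.
#' @param params model parameters.
#' @param cfg a [model_config()].
#' @param training enable dropout.
#' @return probability in (0, 1) with attribute `"logit"`.
#' @export
classify <- function(fused_t, fused_s, params, cfg, training = FALSE) {
  out <- .cls_fwd(fused_t, fused_s, params$cls, cfg, training)
  structure(out$prob, logit = out$logit)
}

# --- full forward -----------------------------------------------------------

# Full cached forward pass. `ridx` is a resolved region index
# (make_region_index). Returns probability, logit, the cache needed by
# nn_backward, and (possibly updated, when training) params.
nn_forward <- function(tg, sg, params, cfg, ridx, training = FALSE) {
  ms <- .ms_fwd(tg$node_features, params, cfg, training)
  params <- ms$params
  pt <- .proj_fwd(ms$H, params$proj$t)
  ps <- .proj_fwd(sg$node_features, params$proj$s)
  et <- .ecc_fwd(pt$out, tg$weights, params$edge$t, params$ln$t, cfg)
  es <- .ecc_fwd(ps$out, sg$weights, params$edge$s, params$ln$s, cfg)
  rt <- .pool_fwd(et$Z, ridx, params$att$t)
  rs <- .pool_fwd(es$Z, ridx, params$att$s)
  ats <- .ca_fwd(rt$U, rs$U, params$ca$ts, cfg)
  ast <- .ca_fwd(rs$U, rt$U, params$ca$st, cfg)
  gt <- .gate_fwd(rt$U, ats$out, params$gate$t)
  gs <- .gate_fwd(rs$U, ast$out, params$gate$s)
  cl <- .cls_fwd(gt$out, gs$out, params$cls, cfg, training)
  list(prob = cl$prob, logit = cl$logit, params = params,
       cache = list(ms = ms$cache, pt = pt$cache, ps = ps$cache,
                    et = et$cache, es = es$cache, rt = rt, rs = rs,
                    ats = ats$cache, ast = ast$cache, gt = gt$cache,
                    gs = gs$cache, cl = cl$cache, ridx = ridx,
                    Zt = et$Z, Zs = es$Z, H = ms$H,
                    training = training))
}

#' Full model forward pass
#'
#' Composition of the whole network: multi-scale encoding and projection of
#' the temporal node features, projection of the spectral node features,
#' edge-conditioned graph convolution per modality, region attention pooling,
#' bidirectional cross-modal attention, gated fusion and classification.
#'
#' @param temporal_graph,spectral_graph `ChannelGraph` objects sharing the
#'   same channel set.
#' @param params model parameters (see [init_model_params()]).
#' @param cfg a [model_config()].
#' @param rmap channel -> region map.
#' @param training enable training-mode batch statistics and dropout.
#' @return probability in (0, 1) with attribute `"logit"`.
#' @export
model_forward <- function(temporal_graph, spectral_graph, params, cfg,
                          rmap = default_region_map(), training = FALSE) {
  if (!identical(temporal_graph$channel_names, spectral_graph$channel_names))
    stopf("temporal and spectral graphs disagree on channels")
  ridx <- make_region_index(rmap, temporal_graph$channel_names)
  out <- nn_forward(temporal_graph, spectral_graph, params, cfg, ridx,
                    training)
  structure(out$prob, logit = out$logit)
}
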