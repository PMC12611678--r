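# Analytic reverse-mode gradients for the full network. Mirrors nn_forward()
# stage by stage; every formula here is checked against finite differences in
# the test suite.

.gate_bwd <- function(dF, cc, pg) {
  D <- ncol(cc$U)
  dG <- dF * (cc$Ue - cc$U)
  dUe <- dF * cc$G
  dU <- dF * (1 - cc$G)
  dpre <- dG * cc$G * (1 - cc$G)
  gW <- crossprod(cbind(cc$U, cc$Ue), dpre)
  gb <- colSums(dpre)
  dcat <- tcrossprod(dpre, pg$W)
  list(dU = dU + dcat[, 1:D, drop = FALSE],
       dUe = dUe + dcat[, (D + 1):(2 * D), drop = FALSE],
       grads = list(W = gW, b = gb))
}

.ca_bwd <- function(dOut, cc, pd, cfg) {
  H <- cfg$n_heads
  dh <- cfg$head_dim
  gWO <- crossprod(cc$O, dOut)
  dO <- tcrossprod(dOut, pd$WO)
  R <- nrow(dOut)
  dQ <- matrix(0, R, cfg$hidden_width)
  dK <- matrix(0, R, cfg$hidden_width)
  dV <- matrix(0, R, cfg$hidden_width)
  for (h in seq_len(H)) {
    cols <- ((h - 1) * dh + 1):(h * dh)
    Ah <- cc$Aw[[h]]
    dOh <- dO[, cols, drop = FALSE]
    dAw <- tcrossprod(dOh, cc$V[, cols, drop = FALSE])
    dV[, cols] <- crossprod(Ah, dOh)
    dP <- (dAw - rowSums(dAw * Ah)) * Ah
    dQ[, cols] <- dP %*% cc$K[, cols, drop = FALSE] / sqrt(dh)
    dK[, cols] <- crossprod(dP, cc$Q[, cols, drop = FALSE]) / sqrt(dh)
  }
  list(dUq = tcrossprod(dQ, pd$WQ),
       dUkv = tcrossprod(dK, pd$WK) + tcrossprod(dV, pd$WV),
       grads = list(WQ = crossprod(cc$Uq, dQ), WK = crossprod(cc$Ukv, dK),
                    WV = crossprod(cc$Ukv, dV), WO = gWO))
}

.pool_bwd <- function(dU, pool, Z, ridx, wm) {
  C <- nrow(Z)
  D <- ncol(Z)
  dZ <- matrix(0, C, D)
  gwm <- matrix(0, nrow(wm), D)
  for (r in seq_along(ridx)) {
    idx <- ridx[[r]]
    al <- pool$alphas[[r]]
    Zr <- Z[idx, , drop = FALSE]
    du <- dU[r, ]
    dal <- drop(Zr %*% du)
    ds <- (dal - sum(dal * al)) * al
    dZ[idx, ] <- dZ[idx, ] + outer(al, du) + outer(ds, wm[r, ])
    gwm[r, ] <- drop(crossprod(Zr, ds))
  }
  list(dZ = dZ, gwm = gwm)
}

.ecc_bwd <- function(dZ, cc, pm, pln, cfg) {
  C <- nrow(dZ)
  D <- ncol(dZ)
  pr <- cc$pr
  # layer norm
  gln_g <- colSums(dZ * cc$xh)
  gln_b <- colSums(dZ)
  dxh <- dZ * row_bcast(pln$g, C)
  dZr <- (dxh - rowMeans(dxh) - cc$xh * rowMeans(dxh * cc$xh)) * cc$inv_sd
  dS <- dZr * cc$maskS
  msg <- ecc_msg_bwd_cpp(dS / (C - 1), cc$Wflat, cc$Xh, pr$i, pr$j)
  dWflat <- msg$dWflat
  dXh <- msg$dXh
  gW2 <- crossprod(cc$H1, dWflat)
  gb2 <- colSums(dWflat)
  dH1 <- tcrossprod(dWflat, pm$W2)
  dH1pre <- dH1 * (cc$H1pre > 0)
  list(dXh = dXh,
       grads = list(w1 = colSums(dH1pre * cc$a), b1 = colSums(dH1pre),
                    W2 = gW2, b2 = gb2),
       ln_grads = list(g = gln_g, b = gln_b))
}

.ms_bwd <- function(dH, cc, params, cfg, want_input_grad = FALSE) {
  C <- nrow(cc$X)
  Fc <- cfg$conv_channels
  gphiW <- crossprod(cc$Hc, dH)
  gphib <- colSums(dH)
  dHc <- tcrossprod(dH, params$phi$W)
  conv_grads <- list()
  dXt <- if (want_input_grad) matrix(0, ncol(cc$X), C) else NULL
  for (b in seq_along(cfg$kernel_sizes)) {
    bc <- cc$branches[[b]]
    pb <- params$conv[[b]]
    dpooled <- dHc[, ((b - 1) * Fc + 1):(b * Fc), drop = FALSE]
    bw <- conv_branch_bwd_cpp(cc$Xt, pb$K, bc$xhat, bc$inv_sd, pb$gamma,
                              pb$beta, dpooled, bc$training, want_input_grad)
    conv_grads[[names(params$conv)[b]]] <-
      list(K = bw$gK, gamma = drop(bw$ggamma), beta = drop(bw$gbeta))
    if (want_input_grad) dXt <- dXt + bw$dXt
  }
  list(conv = conv_grads, phi = list(W = gphiW, b = gphib),
       dX = if (want_input_grad) t(dXt) else NULL)
}

# Full backward pass. `dlogit` is dLoss/dlogit; returns gradients for every
# trainable tensor (nested list mirroring the params layout, batch-norm
# running statistics excluded) and, optionally, gradients with respect to the
# temporal input series and spectral node features.
nn_backward <- function(cache, params, cfg, dlogit, want_input_grads = FALSE) {
  pc <- params$cls
  cl <- cache$cl
  R <- cfg$regions
  D <- cfg$hidden_width
  # classifier
  gW2 <- matrix(cl$hd * dlogit, ncol = 1)
  gb2 <- dlogit
  dhd <- drop(pc$W2) * dlogit
  dhpre <- dhd * cl$mask * (cl$hpre > 0)
  gW1 <- outer(cl$f, dhpre)
  gb1 <- dhpre
  df <- drop(pc$W1 %*% dhpre)
  nt <- R * D
  dFt <- matrix(df[1:nt], R, D, byrow = TRUE)
  dFs <- matrix(df[(nt + 1):(2 * nt)], R, D, byrow = TRUE)
  # gated fusion
  bgt <- .gate_bwd(dFt, cache$gt, params$gate$t)
  bgs <- .gate_bwd(dFs, cache$gs, params$gate$s)
  # cross attention (enhanced outputs feed the gates)
  bts <- .ca_bwd(bgt$dUe, cache$ats, params$ca$ts, cfg)
  bst <- .ca_bwd(bgs$dUe, cache$ast, params$ca$st, cfg)
  dUt <- bgt$dU + bts$dUq + bst$dUkv
  dUs <- bgs$dU + bst$dUq + bts$dUkv
  # region pooling
  bpt <- .pool_bwd(dUt, cache$rt, cache$Zt, cache$ridx, params$att$t)
  bps <- .pool_bwd(dUs, cache$rs, cache$Zs, cache$ridx, params$att$s)
  # edge-conditioned convolutions
  bet <- .ecc_bwd(bpt$dZ, cache$et, params$edge$t, params$ln$t, cfg)
  bes <- .ecc_bwd(bps$dZ, cache$es, params$edge$s, params$ln$s, cfg)
  # projections
  gproj_t <- list(W = crossprod(cache$pt$Feat, bet$dXh),
                  b = colSums(bet$dXh))
  dHms <- tcrossprod(bet$dXh, params$proj$t$W)
  gproj_s <- list(W = crossprod(cache$ps$Feat, bes$dXh),
                  b = colSums(bes$dXh))
  dXs <- if (want_input_grads) tcrossprod(bes$dXh, params$proj$s$W) else NULL
  # multiscale encoder
  bms <- .ms_bwd(dHms, cache$ms, params, cfg, want_input_grads)
  grads <- list(
    conv = bms$conv,
    phi = bms$phi,
    proj = list(t = gproj_t, s = gproj_s),
    edge = list(t = bet$grads, s = bes$grads),
    ln = list(t = bet$ln_grads, s = bes$ln_grads),
    att = list(t = bpt$gwm, s = bps$gwm),
    ca = list(ts = bts$grads, st = bst$grads),
    gate = list(t = bgt$grads, s = bgs$grads),
    cls = list(W1 = gW1, b1 = gb1, W2 = gW2, b2 = gb2)
  )
  list(grads = grads, dXt = bms$dX, dXs = dXs)
}
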