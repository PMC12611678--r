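# Independent brute-force oracles. These deliberately mirror the mathematical
# definitions with explicit loops and stay independent of the package's
# vectorized / compiled implementation paths.

# Sliding-window Pearson correlations by explicit per-window loops.
oracle_windowed_pearson <- function(z, L, S, eps = 0) {
  C <- nrow(z)
  K <- floor((ncol(z) - L) / S) + 1
  out <- array(0, dim = c(C, C, K))
  for (k in seq_len(K)) {
    w <- z[, ((k - 1) * S + 1):((k - 1) * S + L)]
    for (i in seq_len(C)) {
      for (j in seq_len(C)) {
        xi <- w[i, ]; xj <- w[j, ]
        cv <- sum((xi - mean(xi)) * (xj - mean(xj))) / (L - 1)
        out[i, j, k] <- cv / (stats::sd(xi) * stats::sd(xj) + eps)
      }
    }
  }
  out
}

# Temporal edge weights: mean of window correlations, zero diagonal.
oracle_temporal_weights <- function(z, L, S, eps = 0) {
  r <- oracle_windowed_pearson(z, L, S, eps)
  w <- apply(r, c(1, 2), mean)
  diag(w) <- 0
  w
}

# wPLI by explicit loops over pairs, Welch segments and in-band bins.
oracle_wpli <- function(x, fs, seg_len, overlap, band) {
  C <- nrow(x)
  Tn <- ncol(x)
  step <- max(1, round(seg_len * (1 - overlap)))
  K <- floor((Tn - seg_len) / step) + 1
  win <- 0.5 - 0.5 * cos(2 * pi * (seq_len(seg_len) - 1) / seg_len)
  freqs <- (seq_len(seg_len) - 1) * fs / seg_len
  bins <- which(freqs >= band[1] - 1e-12 & freqs <= band[2] + 1e-12 &
                  freqs <= fs / 2 + 1e-12)
  W <- matrix(0, C, C)
  for (i in seq_len(C - 1)) {
    for (j in (i + 1):C) {
      num <- 0; den <- 0
      for (k in seq_len(K)) {
        idx <- ((k - 1) * step + 1):((k - 1) * step + seg_len)
        Xi <- stats::fft(x[i, idx] * win)
        Xj <- stats::fft(x[j, idx] * win)
        for (b in bins) {
          im <- Im(Xi[b] * Conj(Xj[b]))
          num <- num + im
          den <- den + abs(im)
        }
      }
      W[i, j] <- W[j, i] <- if (den > 0) abs(num) / den else 0
    }
  }
  W
}

# Edge-conditioned convolution by explicit double loops (dense algebra only).
oracle_ecc <- function(Xh, A, pm, pln, ln_eps) {
  C <- nrow(Xh)
  D <- ncol(Xh)
  Z <- matrix(0, C, D)
  for (i in seq_len(C)) {
    acc <- rep(0, D)
    for (j in seq_len(C)) {
      if (j == i) next
      a <- A[i, j]
      h1 <- pmax(a * pm$w1 + pm$b1, 0)
      wf <- drop(h1 %*% pm$W2) + pm$b2
      Wij <- matrix(wf, D, D)          # column-major, matches reshape()
      acc <- acc + drop(Wij %*% Xh[j, ])
    }
    z <- pmax(acc / (C - 1), 0)
    mu <- mean(z)
    va <- mean(z^2) - mu^2
    Z[i, ] <- (z - mu) / sqrt(va + ln_eps) * pln$g + pln$b
  }
  Z
}

# Region attention pooling: explicit softmax-weighted sum.
oracle_region_pool <- function(Z, ridx, wm) {
  U <- matrix(0, length(ridx), ncol(Z))
  for (r in seq_along(ridx)) {
    idx <- ridx[[r]]
    s <- vapply(idx, function(i) sum(wm[r, ] * Z[i, ]), 0)
    al <- exp(s - max(s)); al <- al / sum(al)
    for (q in seq_along(idx)) U[r, ] <- U[r, ] + al[q] * Z[idx[q], ]
  }
  U
}

# One direction of multi-head scaled dot-product attention, per-head dense
# algebra with explicit loops over query positions.
oracle_cross_attention <- function(Uq, Ukv, pd, H) {
  D <- ncol(Uq)
  dh <- D / H
  R <- nrow(Uq)
  Q <- Uq %*% pd$WQ; K <- Ukv %*% pd$WK; V <- Ukv %*% pd$WV
  O <- matrix(0, R, D)
  for (h in seq_len(H)) {
    cols <- ((h - 1) * dh + 1):(h * dh)
    for (r in seq_len(R)) {
      sc <- vapply(seq_len(R), function(m)
        sum(Q[r, cols] * K[m, cols]) / sqrt(dh), 0)
      al <- exp(sc - max(sc)); al <- al / sum(al)
      for (m in seq_len(R)) O[r, cols] <- O[r, cols] + al[m] * V[m, cols]
    }
  }
  O %*% pd$WO
}

# Pairwise-concordance AUC with ties counted one half.
oracle_auc_pairwise <- function(scores, labels) {
  pos <- scores[labels == 1]
  neg <- scores[labels == 0]
  tot <- 0
  for (p in pos) for (q in neg)
    tot <- tot + if (p > q) 1 else if (p == q) 0.5 else 0
  tot / (length(pos) * length(neg))
}
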