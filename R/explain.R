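# Gradient x input attribution, cross-modal fusion of channel scores,
# region-level evidence and topographic rendering.

#' Gradient x input attribution
#'
#' Scores each input element by the elementwise product of the input with the
#' gradient of the scorer's (pre-sigmoid) output with respect to that input.
#' `model_fn` must return a list with `value` (scalar) and `gradient` (same
#' shape as the input); the package's own model exposes such a scorer through
#' [model_input_gradients()].
#'
#' @param model_fn differentiable scorer.
#' @param input numeric vector/matrix/array.
#' @return attribution tensor of the same shape as `input`.
#' @export
gradient_x_input <- function(model_fn, input) {
  out <- model_fn(input)
  if (!is.list(out) || is.null(out$gradient))
    stopf("model_fn must return list(value =, gradient =)")
  g <- out$gradient
  if (!all(is.finite(g)))
    stopf("non-finite gradients encountered (value = %g)", out$value)
  if (length(g) != length(input))
    stopf("gradient shape does not match input")
  input * g
}

#' Gradients of the model logit with respect to its inputs
#'
#' Runs an inference-mode forward pass and the analytic backward pass with
#' respect to the temporal node features (the standardized time series) and
#' the spectral node features; graph edge weights are treated as constants.
#'
#' @param temporal_graph,spectral_graph `ChannelGraph` inputs.
#' @param params model parameters.
#' @param cfg a [model_config()].
#' @param rmap channel -> region map.
#' @return list with `prob`, `logit`, `d_temporal` (C x T) and
#'   `d_spectral` (C x B).
#' @export
model_input_gradients <- function(temporal_graph, spectral_graph, params, cfg,
                                  rmap = default_region_map()) {
  ridx <- make_region_index(rmap, temporal_graph$channel_names)
  fw <- nn_forward(temporal_graph, spectral_graph, params, cfg, ridx,
                   training = FALSE)
  bw <- nn_backward(fw$cache, params, cfg, dlogit = 1,
                    want_input_grads = TRUE)
  list(prob = fw$prob, logit = fw$logit, d_temporal = bw$dXt,
       d_spectral = bw$dXs)
}

#' Per-channel scores from an attribution matrix
#'
#' Averages the attribution over the non-channel axis (time for the temporal
#' modality, frequency bands for the spectral one).
#'
#' @param attr numeric matrix C x T or C x F.
#' @return length-C vector of channel scores.
#' @export
channel_scores <- function(attr) rowMeans(as.matrix(attr))

#' Fuse temporal and spectral channel scores
#'
#' Convex combination `lam * temporal + (1 - lam) * spectral`.
#'
#' @param t_scores,s_scores length-C score vectors.
#' @param lam fusion coefficient in `[0, 1]` (0.5 weights both modalities
#'   equally).
#' @return fused length-C vector.
#' @export
fuse_attributions <- function(t_scores, s_scores, lam = 0.5) {
  if (lam < 0 || lam > 1) stopf("lam must lie in [0, 1]")
  lam * t_scores + (1 - lam) * s_scores
}

#' Region-level evidence
#'
#' Sums fused channel scores within each anatomical region; aggregation
#' conserves total evidence.
#'
#' @param scores length-C channel scores.
#' @param rmap channel -> region map.
#' @param channel_names labels matching `scores`.
#' @return named length-R vector of region evidence.
#' @export
region_evidence <- function(scores, rmap = default_region_map(),
                            channel_names = names(rmap)) {
  ridx <- make_region_index(rmap, channel_names)
  vapply(ridx, function(idx) sum(scores[idx]), 0)
}

#' Full attribution for one epoch
#'
#' Gradient x input per modality, temporal/band averaging to channel scores,
#' fixed-coefficient fusion, region aggregation and a min-max normalization
#' record for display.
#'
#' @param temporal_graph,spectral_graph `ChannelGraph` inputs.
#' @param params model parameters.
#' @param cfg a [model_config()].
#' @param rmap channel -> region map.
#' @param lam fusion coefficient (default 0.5).
#' @return object of class `AttributionResult`.
#' @export
explain_epoch <- function(temporal_graph, spectral_graph, params, cfg,
                          rmap = default_region_map(), lam = 0.5) {
  g <- model_input_gradients(temporal_graph, spectral_graph, params, cfg, rmap)
  temporal_attr <- temporal_graph$node_features * g$d_temporal
  spectral_attr <- spectral_graph$node_features * g$d_spectral
  t_scores <- channel_scores(temporal_attr)
  s_scores <- channel_scores(spectral_attr)
  fused <- fuse_attributions(t_scores, s_scores, lam)
  ev <- region_evidence(fused, rmap, temporal_graph$channel_names)
  rng <- range(fused)
  structure(list(temporal_attr = temporal_attr, spectral_attr = spectral_attr,
                 t_scores = t_scores, s_scores = s_scores,
                 fused_channel_scores = fused, region_evidence = ev,
                 lambda = lam,
                 normalization = list(scheme = "minmax_per_sample",
                                      min = rng[1], max = rng[2]),
                 channel_names = temporal_graph$channel_names,
                 prob = g$prob, logit = g$logit),
            class = "AttributionResult")
}

#' @export
print.AttributionResult <- function(x, ...) {
  cat(sprintf("<AttributionResult> p = %.4f (logit %.3f), lambda = %.2f\n",
              x$prob, x$logit, x$lambda))
  cat("  region evidence:\n")
  for (r in names(x$region_evidence))
    cat(sprintf("    %-10s %+.4f\n", r, x$region_evidence[r]))
  invisible(x)
}

# Schematic 2-D projections of the 10-20 electrode positions (x right,
# y anterior; head circle of radius 1).
electrode_positions <- function() {
  pos <- rbind(
    FP1 = c(-0.31, 0.95), FP2 = c(0.31, 0.95),
    F7 = c(-0.81, 0.59), F8 = c(0.81, 0.59),
    F3 = c(-0.41, 0.48), F4 = c(0.41, 0.48), FZ = c(0, 0.5),
    T3 = c(-1, 0), C3 = c(-0.5, 0), CZ = c(0, 0), C4 = c(0.5, 0),
    T4 = c(1, 0),
    T5 = c(-0.81, -0.59), P3 = c(-0.41, -0.48), PZ = c(0, -0.5),
    P4 = c(0.41, -0.48), T6 = c(0.81, -0.59),
    O1 = c(-0.31, -0.95), O2 = c(0.31, -0.95)
  )
  colnames(pos) <- c("x", "y")
  pos
}

#' Render a topographic scalp map
#'
#' Min-max normalizes the channel scores (recorded in the returned
#' normalization record), interpolates them over the scalp disc
#' (inverse-distance weighting), and writes a PNG with the head outline and
#' electrode markers.
#'
#' @param scores length-C channel scores.
#' @param channel_names channel labels with known 10-20 coordinates.
#' @param out output image path.
#' @param grid_n interpolation grid resolution per axis.
#' @return invisibly, list with `path` and the `normalization` record.
#' @export
render_topomap <- function(scores, channel_names, out, grid_n = 80) {
  channel_names <- normalize_channel_names(channel_names)
  pos <- electrode_positions()
  unknown <- setdiff(channel_names, rownames(pos))
  if (length(unknown))
    stopf("no montage coordinates for channel(s): %s",
          paste(unknown, collapse = ", "))
  xy <- pos[channel_names, , drop = FALSE]
  rng <- range(scores)
  norm <- if (rng[2] > rng[1]) (scores - rng[1]) / (rng[2] - rng[1])
          else rep(0.5, length(scores))
  gx <- seq(-1.05, 1.05, length.out = grid_n)
  gy <- seq(-1.05, 1.05, length.out = grid_n)
  z <- matrix(NA_real_, grid_n, grid_n)
  for (i in seq_len(grid_n)) {
    for (j in seq_len(grid_n)) {
      if (gx[i]^2 + gy[j]^2 > 1.1^2) next
      d2 <- (xy[, "x"] - gx[i])^2 + (xy[, "y"] - gy[j])^2
      if (any(d2 < 1e-12)) {
        z[i, j] <- norm[which.min(d2)]
      } else {
        w <- 1 / d2^1.5
        z[i, j] <- sum(w * norm) / sum(w)
      }
    }
  }
  pal <- colorRampPalette(c("#2166ac", "#f7f7f7", "#b2182b"))(64)
  png(out, width = 480, height = 480)
  op <- graphics::par(mar = c(1, 1, 2, 1))
  image(gx, gy, z, col = pal, zlim = c(0, 1), axes = FALSE, asp = 1,
        xlab = "", ylab = "", main = "Fused attribution")
  th <- seq(0, 2 * pi, length.out = 200)
  lines(cos(th), sin(th), lwd = 2)
  lines(c(-0.1, 0, 0.1), c(0.995, 1.1, 0.995), lwd = 2)  # nose
  points(xy[, "x"], xy[, "y"], pch = 21, bg = "white", cex = 1.4)
  text(xy[, "x"], xy[, "y"] - 0.1, channel_names, cex = 0.7)
  graphics::par(op)
  dev.off()
  invisible(list(path = out,
                 normalization = list(scheme = "minmax_per_sample",
                                      min = rng[1], max = rng[2])))
}
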