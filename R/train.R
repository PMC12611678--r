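# Focal-loss training with Adam and patient-grouped cross-validation.

#' Training configuration
#'
#' Adam with learning rate 0.01, batch size 32 and 150 epochs are the
#' reference training settings; focal-loss parameters default to the standard
#' alpha = 0.25, gamma = 2.
#'
#' @param learning_rate Adam learning rate.
#' @param batch_size minibatch size.
#' @param epochs training epochs.
#' @param focal_alpha class-balance weight in (0, 1).
#' @param focal_gamma focusing exponent (>= 0).
#' @param seed integer seed controlling initialization, shuffling and dropout.
#' @param decision_threshold probability threshold for the positive class.
#' @return list of class `train_config`.
#' @export
train_config <- function(learning_rate = 0.01, batch_size = 32, epochs = 150,
                         focal_alpha = 0.25, focal_gamma = 2.0, seed = 1L,
                         decision_threshold = 0.5) {
  if (learning_rate <= 0) stopf("learning_rate must be positive")
  if (focal_gamma < 0) stopf("focal_gamma must be >= 0")
  if (focal_alpha <= 0 || focal_alpha >= 1) stopf("focal_alpha must be in (0,1)")
  if (batch_size < 1) stopf("batch_size must be >= 1")
  structure(list(learning_rate = learning_rate, batch_size = batch_size,
                 epochs = epochs, focal_alpha = focal_alpha,
                 focal_gamma = focal_gamma, seed = as.integer(seed),
                 decision_threshold = decision_threshold),
            class = "train_config")
}

.focal_clamp <- function(p) pmin(pmax(p, 1e-7), 1 - 1e-7)

#' Focal loss
#'
#' With `p_t = p_hat` for positives and `1 - p_hat` for negatives, and
#' `alpha_t` the matching class weight, the per-sample loss is
#' `-alpha_t * (1 - p_t)^gamma * log(p_t)`; the batch loss is the mean.
#' Probabilities are clamped to `[1e-7, 1 - 1e-7]` before the log.
#'
#' @param p_hat predicted probabilities.
#' @param y binary labels.
#' @param alpha class-balance weight.
#' @param gamma focusing exponent.
#' @return mean loss (non-negative scalar).
#' @export
focal_loss <- function(p_hat, y, alpha = 0.25, gamma = 2.0) {
  p <- .focal_clamp(p_hat)
  pt <- ifelse(y == 1, p, 1 - p)
  at <- ifelse(y == 1, alpha, 1 - alpha)
  mean(-at * (1 - pt)^gamma * log(pt))
}

# dLoss/dlogit for a single sample (p is the sigmoid of the logit).
focal_loss_dlogit <- function(p_hat, y, alpha, gamma) {
  p <- .focal_clamp(p_hat)
  pt <- if (y == 1) p else 1 - p
  at <- if (y == 1) alpha else 1 - alpha
  term <- if (gamma > 0) gamma * (1 - pt)^(gamma - 1) * log(pt) else 0
  dl_dpt <- at * (term - (1 - pt)^gamma / pt)
  dpt_dz <- if (y == 1) p * (1 - p) else -p * (1 - p)
  dl_dpt * dpt_dz
}

# --- cross-validation splits ------------------------------------------------

new_fold_split <- function(folds) {
  tests <- unlist(lapply(folds, `[[`, "test"))
  if (anyDuplicated(tests))
    stopf("a patient appears in more than one test fold")
  for (f in folds)
    if (length(intersect(f$train, f$test)))
      stopf("train and test patients overlap within a fold")
  structure(list(folds = folds), class = "FoldSplit")
}

#' @export
print.FoldSplit <- function(x, ...) {
  cat(sprintf("<FoldSplit> %d folds; test sizes: %s\n", length(x$folds),
              paste(vapply(x$folds, function(f) length(f$test), 1L),
                    collapse = ", ")))
  invisible(x)
}

.patient_frame <- function(patients) {
  if (is.data.frame(patients)) {
    if (!all(c("patient_id", "spasms") %in% names(patients)))
      stopf("patient table needs columns patient_id and spasms")
    data.frame(patient_id = as.character(patients$patient_id),
               spasms = patients$spasms, stringsAsFactors = FALSE)
  } else if (!is.null(names(patients))) {
    data.frame(patient_id = names(patients), spasms = as.numeric(patients),
               stringsAsFactors = FALSE)
  } else {
    data.frame(patient_id = as.character(patients),
               spasms = rep(0, length(patients)), stringsAsFactors = FALSE)
  }
}

#' Grouped, stratified k-fold split at the patient level
#'
#' Patients are ordered by descending spasm count (ties broken by patient id)
#' and dealt round-robin into k folds, so each fold approximates the global
#' spasm/non-spasm ratio while no patient is ever split across folds.
#'
#' @param patients data frame with columns `patient_id` and `spasms`, or a
#'   named numeric vector of spasm counts.
#' @param k number of folds.
#' @param seed unused (the dealing is deterministic); kept for interface
#'   stability.
#' @return a `FoldSplit` with k folds.
#' @export
grouped_stratified_kfold <- function(patients, k = 5, seed = NULL) {
  pf <- .patient_frame(patients)
  if (k > nrow(pf))
    stopf("k = %d exceeds the number of patients (%d)", k, nrow(pf))
  ord <- order(-pf$spasms, pf$patient_id)
  fold_of <- rep_len(seq_len(k), nrow(pf))
  ids <- pf$patient_id[ord]
  folds <- lapply(seq_len(k), function(f)
    list(train = ids[fold_of != f], test = ids[fold_of == f]))
  new_fold_split(folds)
}

#' Leave-one-patient-out split
#'
#' One fold per patient; fold i tests patient i and trains on all others.
#'
#' @param patients patient table or vector of patient ids.
#' @return a `FoldSplit` with `n_patients` folds.
#' @export
leave_one_patient_out <- function(patients) {
  pf <- .patient_frame(patients)
  if (nrow(pf) < 2) stopf("leave-one-patient-out needs at least 2 patients")
  folds <- lapply(pf$patient_id, function(p)
    list(train = setdiff(pf$patient_id, p), test = p))
  new_fold_split(folds)
}

# --- optimizer --------------------------------------------------------------

# Leaves of the parameter tree that Adam updates (batch-norm running
# statistics are state, not parameters).
trainable_names <- function(leaves) {
  names(leaves)[!grepl("\\.run_(mean|var)$", names(leaves))]
}

adam_init <- function(leaves) {
  nm <- trainable_names(leaves)
  list(m = lapply(stats::setNames(nm, nm), function(n) leaves[[n]] * 0),
       v = lapply(stats::setNames(nm, nm), function(n) leaves[[n]] * 0),
       t = 0L)
}

adam_step <- function(leaves, grad_leaves, state, lr,
                      beta1 = 0.9, beta2 = 0.999, eps = 1e-8) {
  state$t <- state$t + 1L
  bc1 <- 1 - beta1^state$t
  bc2 <- 1 - beta2^state$t
  for (nm in names(state$m)) {
    g <- grad_leaves[[nm]]
    state$m[[nm]] <- beta1 * state$m[[nm]] + (1 - beta1) * g
    state$v[[nm]] <- beta2 * state$v[[nm]] + (1 - beta2) * g * g
    leaves[[nm]] <- leaves[[nm]] -
      lr * (state$m[[nm]] / bc1) / (sqrt(state$v[[nm]] / bc2) + eps)
  }
  list(leaves = leaves, state = state)
}

# --- training ---------------------------------------------------------------

#' Predict epoch probabilities with a trained model
#'
#' @param params model parameters.
#' @param mcfg a [model_config()].
#' @param graphs list of per-epoch `list(temporal =, spectral =)` graphs.
#' @param idx epoch indices to score (default all).
#' @param rmap channel -> region map.
#' @return numeric vector of probabilities.
#' @export
predict_proba <- function(params, mcfg, graphs, idx = seq_along(graphs),
                          rmap = default_region_map()) {
  ridx <- make_region_index(rmap, graphs[[idx[1]]]$temporal$channel_names)
  vapply(idx, function(i)
    nn_forward(graphs[[i]]$temporal, graphs[[i]]$spectral, params, mcfg,
               ridx, training = FALSE)$prob, 0)
}

# Train on one fold's training epochs; deterministic given `seed`.
train_fold <- function(es, graphs, train_idx, test_idx, tcfg, mcfg, ridx,
                       seed, verbose = FALSE) {
  if (length(train_idx) == 0) stopf("empty training fold")
  # patient-leakage audit at batch-assembly level
  if (length(intersect(es$patient_ids[train_idx], es$patient_ids[test_idx])))
    stopf("patient leakage: a test patient appears in the training fold")
  set.seed(seed)
  params <- init_model_params(mcfg)
  leaves <- flatten_leaves(params)
  state <- adam_init(leaves)
  history <- numeric(tcfg$epochs)
  for (ep in seq_len(tcfg$epochs)) {
    ord <- sample(train_idx)
    nb <- ceiling(length(ord) / tcfg$batch_size)
    ep_loss <- 0
    for (b in seq_len(nb)) {
      batch <- ord[((b - 1) * tcfg$batch_size + 1):
                     min(b * tcfg$batch_size, length(ord))]
      gsum <- NULL
      for (i in batch) {
        fw <- nn_forward(graphs[[i]]$temporal, graphs[[i]]$spectral, params,
                         mcfg, ridx, training = TRUE)
        params <- fw$params
        y <- es$labels[i]
        ep_loss <- ep_loss + focal_loss(fw$prob, y, tcfg$focal_alpha,
                                        tcfg$focal_gamma)
        dz <- focal_loss_dlogit(fw$prob, y, tcfg$focal_alpha,
                                tcfg$focal_gamma)
        gl <- flatten_leaves(nn_backward(fw$cache, params, mcfg, dz)$grads)
        if (is.null(gsum)) {
          gsum <- gl
        } else {
          for (nm in names(gsum)) gsum[[nm]] <- gsum[[nm]] + gl[[nm]]
        }
      }
      for (nm in names(gsum)) gsum[[nm]] <- gsum[[nm]] / length(batch)
      leaves <- flatten_leaves(params)
      upd <- adam_step(leaves, gsum, state, tcfg$learning_rate)
      state <- upd$state
      params <- unflatten_leaves(upd$leaves)
    }
    history[ep] <- ep_loss / length(ord)
    if (verbose)
      message(sprintf("epoch %3d/%d  loss %.5f", ep, tcfg$epochs, history[ep]))
  }
  scores <- if (length(test_idx)) {
    vapply(test_idx, function(i)
      nn_forward(graphs[[i]]$temporal, graphs[[i]]$spectral, params, mcfg,
                 ridx, training = FALSE)$prob, 0)
  } else {
    numeric(0)
  }
  metrics <- NULL
  if (length(test_idx)) {
    yhat <- as.integer(scores >= tcfg$decision_threshold)
    metrics <- confusion_metrics(es$labels[test_idx], yhat)
    metrics$auc <- if (length(unique(es$labels[test_idx])) == 2)
      auc_rank(scores, es$labels[test_idx]) else NA_real_
  }
  list(params = params, metrics = metrics, history = history,
       scores = scores, test_idx = test_idx)
}

#' Train with patient-grouped cross-validation
#'
#' For each fold of the split, initializes a fresh model, trains with Adam on
#' the focal loss over the fold's training patients, and evaluates on the
#' held-out patients at the configured decision threshold. Fully
#' deterministic given `tcfg$seed`.
#'
#' @param es an [epoch_set()].
#' @param graphs per-epoch graphs from [build_graph_set()].
#' @param split a `FoldSplit` over the patient ids of `es`.
#' @param tcfg a [train_config()].
#' @param mcfg a [model_config()].
#' @param rmap channel -> region map.
#' @param verbose print per-epoch losses.
#' @return list of class `cv_result`: per-fold list(params, metrics, history,
#'   scores, test_idx).
#' @export
train_cv <- function(es, graphs, split, tcfg = train_config(),
                     mcfg = model_config(), rmap = default_region_map(),
                     verbose = FALSE) {
  ridx <- make_region_index(rmap, es$channel_names)
  folds <- lapply(seq_along(split$folds), function(f) {
    fd <- split$folds[[f]]
    train_idx <- which(es$patient_ids %in% fd$train)
    test_idx <- which(es$patient_ids %in% fd$test)
    train_fold(es, graphs, train_idx, test_idx, tcfg, mcfg, ridx,
               seed = tcfg$seed + 7919L * (f - 1L), verbose = verbose)
  })
  structure(list(folds = folds, tcfg = tcfg, mcfg = mcfg), class = "cv_result")
}

#' Pooled cross-validation metrics
#'
#' Concatenates every fold's held-out scores and labels and computes one
#' report over all held-out epochs.
#'
#' @param cv a `cv_result` from [train_cv()].
#' @param es the `EpochSet` it was trained on.
#' @return a `MetricsReport` with `auc`.
#' @export
cv_pooled_metrics <- function(cv, es) {
  scores <- unlist(lapply(cv$folds, `[[`, "scores"))
  idx <- unlist(lapply(cv$folds, `[[`, "test_idx"))
  labels <- es$labels[idx]
  m <- confusion_metrics(labels,
                         as.integer(scores >= cv$tcfg$decision_threshold))
  m$auc <- auc_rank(scores, labels)
  m
}
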