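# Focal loss, metrics, grouped splits and the training loop.

test_that("focal loss reduces to scaled cross-entropy and matches arithmetic", {
  set.seed(41)
  p <- runif(100, 0.01, 0.99)
  y <- rbinom(100, 1, 0.5)
  bce <- -ifelse(y == 1, log(p), log(1 - p))
  for (i in seq_along(p))
    expect_equal(focal_loss(p[i], y[i], alpha = 0.5, gamma = 0), 0.5 * bce[i],
                 tolerance = 1e-10)

  expect_equal(focal_loss(0.9, 1, alpha = 0.25, gamma = 2),
               0.25 * 0.1^2 * (-log(0.9)), tolerance = 1e-7)
  expect_lt(abs(focal_loss(0.9, 1, alpha = 0.25, gamma = 2) - 2.634e-4),
            1e-7)

  # loss vanishes as a confident correct prediction saturates
  expect_lt(focal_loss(1 - 1e-9, 1), 1e-10)

  # monotone decreasing in p_t for positives
  ps <- seq(0.05, 0.95, by = 0.05)
  ls <- vapply(ps, focal_loss, 0, y = 1)
  expect_true(all(diff(ls) < 0))

  # exact 0/1 probabilities are clamped, not infinite
  expect_true(is.finite(focal_loss(0, 1)))
  expect_true(is.finite(focal_loss(1, 0)))
})

test_that("focal loss logit-gradient matches finite differences", {
  fd <- function(z, y, a, g, eps = 1e-6) {
    (focal_loss(spasmgraph:::sigmoid(z + eps), y, a, g) -
       focal_loss(spasmgraph:::sigmoid(z - eps), y, a, g)) / (2 * eps)
  }
  set.seed(42)
  for (i in 1:20) {
    z <- rnorm(1, 0, 2); y <- rbinom(1, 1, 0.5)
    a <- runif(1, 0.1, 0.9); g <- sample(c(0, 1, 2, 5), 1)
    an <- spasmgraph:::focal_loss_dlogit(spasmgraph:::sigmoid(z), y, a, g)
    expect_equal(an, fd(z, y, a, g), tolerance = 1e-5)
  }
})

test_that("confusion_metrics reproduces the worked example and edge cases", {
  labels <- c(rep(1, 45), rep(0, 55))
  preds <- c(rep(1, 40), rep(0, 5), rep(1, 10), rep(0, 45))
  m <- confusion_metrics(labels, preds)
  expect_equal(c(m$tp, m$fp, m$fn, m$tn), c(40, 10, 5, 45))
  expect_equal(m$accuracy, 0.85, tolerance = 1e-4)
  expect_equal(m$precision, 0.80, tolerance = 1e-4)
  expect_equal(m$recall, 0.8889, tolerance = 1e-4)
  expect_equal(m$specificity, 0.8182, tolerance = 1e-4)
  expect_equal(m$f1, 0.8421, tolerance = 1e-4)
  expect_false(m$degenerate)

  perfect <- confusion_metrics(labels, labels)
  expect_equal(c(perfect$accuracy, perfect$precision, perfect$recall,
                 perfect$specificity, perfect$f1), rep(1, 5))

  allneg <- confusion_metrics(labels, rep(0, 100))
  expect_equal(allneg$recall, 0)
  expect_equal(allneg$specificity, 1)
  expect_true(allneg$degenerate)

  expect_error(confusion_metrics(c(0, 1), c(0, 1, 1)), "length")
})

test_that("auc_rank agrees with the pairwise oracle including ties", {
  expect_equal(auc_rank(c(0.9, 0.8, 0.3, 0.1), c(1, 1, 0, 0)), 1)
  expect_equal(auc_rank(rep(0.5, 6), c(1, 0, 1, 0, 1, 0)), 0.5)
  set.seed(43)
  for (i in 1:200) {
    n <- sample(3:8, 1)
    labels <- c(0, 1, rbinom(n - 2, 1, 0.5))
    scores <- sample(c(0.1, 0.5, 0.9), n, replace = TRUE)
    expect_equal(auc_rank(scores, labels),
                 oracle_auc_pairwise(scores, labels), tolerance = 1e-12)
  }
  expect_error(auc_rank(c(1, 2), c(1, 1)), "undefined")
})

test_that("grouped_stratified_kfold deals round-robin by descending spasms", {
  counts <- c(32, 27, 24, 21, 19, 17, 15, 13, 12, 9)
  pts <- data.frame(patient_id = sprintf("P%02d", 1:10), spasms = counts)
  ks <- grouped_stratified_kfold(pts, k = 3)
  # explicit dealing oracle: order by count desc (ids already ordered), deal
  ord <- order(-counts)
  deal <- split(sprintf("P%02d", 1:10)[ord], rep_len(1:3, 10))
  for (f in 1:3)
    expect_setequal(ks$folds[[f]]$test, deal[[f]])
  # fold spasm totals match the dealing oracle
  tot <- vapply(ks$folds, function(f)
    sum(counts[match(f$test, pts$patient_id)]), 0)
  oracle_tot <- vapply(deal, function(ids)
    sum(counts[match(ids, pts$patient_id)]), 0)
  expect_equal(tot, as.numeric(oracle_tot))

  expect_error(grouped_stratified_kfold(pts, k = 11), "exceeds")
})

test_that("fold splits partition patients and stay roughly stratified", {
  tab <- synth_patient_table(40)
  split <- grouped_stratified_kfold(tab, k = 5)
  sizes <- vapply(split$folds, function(f) length(f$test), 1L)
  expect_equal(sizes, rep(8L, 5))
  all_test <- unlist(lapply(split$folds, `[[`, "test"))
  expect_setequal(all_test, tab$patient_id)
  expect_equal(anyDuplicated(all_test), 0L)
  for (f in split$folds)
    expect_length(intersect(f$train, f$test), 0)
  # each fold's spasm fraction within +/- 20% relative of the global fraction
  global <- sum(tab$spasms) / 40
  for (f in split$folds) {
    fold_mean <- sum(tab$spasms[tab$patient_id %in% f$test]) / 8
    expect_lt(abs(fold_mean - global) / global, 0.2)
  }
})

test_that("leave_one_patient_out builds one clean fold per patient", {
  tab <- synth_patient_table(40)
  split <- leave_one_patient_out(tab)
  expect_length(split$folds, 40)
  for (f in split$folds) {
    expect_length(f$test, 1)
    expect_false(f$test %in% f$train)
    expect_length(f$train, 39)
  }
  expect_setequal(unlist(lapply(split$folds, `[[`, "test")), tab$patient_id)
  expect_error(leave_one_patient_out(tab[1, ]), "at least 2")
})

# Tiny 6-channel trainable dataset at 50 Hz: class 1 carries a strong 20 Hz
# burst on half the channels. Band definitions are rescaled to the toy
# Nyquist so every band holds at least one Welch bin.
make_toy_trainset <- function(n_per_class = 12, Tn = 60, seed = 44) {
  set.seed(seed)
  ch <- paste0("CH", 1:6)
  n <- 2 * n_per_class
  graphs <- vector("list", n)
  labels <- integer(n)
  arr <- array(0, dim = c(6, Tn, n))
  gcfg <- graph_config(window_len_samples = 20, step_samples = 10,
                       wpli_segment_len = 20,
                       bands = list(low = c(0.7, 10), mid = c(10, 20),
                                    high = c(20, 25)),
                       broadband = c(0.7, 24))
  for (e in seq_len(n)) {
    x <- matrix(rnorm(6 * Tn), 6, Tn)
    if (e > n_per_class) {
      x[1:3, ] <- x[1:3, ] + 4 * sin(2 * pi * 20 * seq_len(Tn) / 50)
      labels[e] <- 1L
    }
    x <- zscore_channels(x)
    arr[, , e] <- x
    graphs[[e]] <- list(
      temporal = build_temporal_graph(x, gcfg, ch),
      spectral = build_spectral_graph(x, 50, gcfg, ch))
  }
  pid <- rep(c("A", "B", "C", "D"), length.out = n)
  es <- epoch_set(arr, labels, pid, 50, ch, Tn / 50)
  list(es = es, graphs = graphs)
}

test_that("training reduces the loss on a separable toy problem, deterministically", {
  toy <- make_toy_trainset()
  cfg <- tiny_model_config(spectral_dim = 3)
  ridx <- spasmgraph:::make_region_index(tiny_region_map(), toy$es$channel_names)
  tcfg <- train_config(learning_rate = 0.002, batch_size = 8, epochs = 5,
                       seed = 1)
  fit <- spasmgraph:::train_fold(toy$es, toy$graphs,
                                 train_idx = seq_len(n_epochs(toy$es)),
                                 test_idx = integer(0), tcfg, cfg, ridx,
                                 seed = 1)
  expect_true(all(diff(fit$history) < 0))   # strictly decreasing over 5 epochs

  fit2 <- spasmgraph:::train_fold(toy$es, toy$graphs,
                                  train_idx = seq_len(n_epochs(toy$es)),
                                  test_idx = integer(0), tcfg, cfg, ridx,
                                  seed = 1)
  expect_identical(fit$history, fit2$history)
  p1 <- spasmgraph:::flatten_leaves(fit$params)
  p2 <- spasmgraph:::flatten_leaves(fit2$params)
  for (nm in names(p1)) expect_identical(p1[[nm]], p2[[nm]])
})

test_that("train_cv evaluates held-out patients and audits leakage", {
  toy <- make_toy_trainset()
  counts <- tapply(toy$es$labels, toy$es$patient_ids, sum)
  split <- grouped_stratified_kfold(
    data.frame(patient_id = names(counts), spasms = as.numeric(counts)), k = 2)
  tcfg <- train_config(learning_rate = 0.002, batch_size = 8, epochs = 3,
                       seed = 2)
  cv <- train_cv(toy$es, toy$graphs, split, tcfg, tiny_model_config(spectral_dim = 3),
                 rmap = tiny_region_map())
  expect_length(cv$folds, 2)
  for (f in cv$folds) {
    expect_s3_class(f$metrics, "MetricsReport")
    expect_length(f$scores, length(f$test_idx))
    expect_true(all(f$scores > 0 & f$scores < 1))
  }
  # leakage audit fires when train and test share a patient
  ridx <- spasmgraph:::make_region_index(tiny_region_map(), toy$es$channel_names)
  expect_error(
    spasmgraph:::train_fold(toy$es, toy$graphs, train_idx = 1:10,
                            test_idx = 5:12, tcfg, tiny_model_config(spectral_dim = 3), ridx,
                            seed = 1),
    "leakage")
  expect_error(
    spasmgraph:::train_fold(toy$es, toy$graphs, train_idx = integer(0),
                            test_idx = 1:4, tcfg, tiny_model_config(spectral_dim = 3), ridx,
                            seed = 1),
    "empty training fold")
})
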