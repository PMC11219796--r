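# Losses, augmentation, the training schedule, metrics, splits.

test_that("masked MSE matches the brute-force formula", {
  a <- array(1, c(10, 10, 10)); b <- array(1, c(10, 10, 10))
  m <- array(TRUE, c(10, 10, 10))
  expect_equal(masked_mse(a, b, m), 0)
  # error exactly 1.0 on 5 masked voxels, garbage elsewhere
  pred <- array(rnorm(1000), c(10, 10, 10))
  targ <- pred + 7
  mask <- array(FALSE, c(10, 10, 10))
  mask[c(1, 50, 300, 700, 999)] <- TRUE
  targ[mask] <- pred[mask] - 1
  expect_equal(masked_mse(pred, targ, mask), 1.0)
  set.seed(1)
  for (i in 1:20) {
    p <- array(rnorm(1000), c(10, 10, 10))
    t <- array(rnorm(1000), c(10, 10, 10))
    mk <- array(runif(1000) < 0.4, c(10, 10, 10))
    if (!any(mk)) next
    expect_equal(masked_mse(p, t, mk), sum((p[mk] - t[mk])^2) / sum(mk),
                 tolerance = 1e-12)
  }
  expect_equal(masked_mse(p, t, array(TRUE, c(10, 10, 10))), mean((p - t)^2))
  expect_error(masked_mse(p, t, array(FALSE, c(10, 10, 10))), "empty mask")
})

test_that("weighted cross-entropy matches hand computation", {
  d <- c(6, 6, 6)
  y <- array(0, d); y[1:20] <- 1
  perfect <- array(0, c(d, 2))
  perfect[, , , 1] <- 1e-7 + (1 - 2e-7) * (y == 0)
  perfect[, , , 2] <- 1e-7 + (1 - 2e-7) * (y == 1)
  expect_lt(weighted_cross_entropy(perfect, y), 1e-5)
  uniform <- array(0.5, c(d, 2))
  n1 <- sum(y); n0 <- length(y) - n1
  want <- (0.05 * n0 + 0.95 * n1) * log(2) / (0.05 * n0 + 0.95 * n1)
  expect_equal(weighted_cross_entropy(uniform, y), want, tolerance = 1e-12)
  # swapping weights matters on imbalanced data, not on balanced
  set.seed(2)
  p <- array(runif(prod(d)), d)
  probs <- array(0, c(d, 2)); probs[, , , 1] <- 1 - p; probs[, , , 2] <- p
  imb <- weighted_cross_entropy(probs, y, c(0.05, 0.95))
  imb_swap <- weighted_cross_entropy(probs, y, c(0.95, 0.05))
  expect_gt(abs(imb - imb_swap), 1e-6)
  ybal <- array(rep(c(0, 1), length.out = prod(d)), d)
  # balanced truth with symmetric probabilities: swap leaves loss unchanged
  psym <- array(0.5, c(d, 2))
  expect_equal(weighted_cross_entropy(psym, ybal, c(0.05, 0.95)),
               weighted_cross_entropy(psym, ybal, c(0.95, 0.05)),
               tolerance = 1e-12)
  bad <- probs; bad[1] <- 1.5
  expect_error(weighted_cross_entropy(bad, y), "\\[0, 1\\]")
})

make_box <- function(seed = 1, C = 2) {
  set.seed(seed)
  sb <- list(channels = array(runif(40^3 * C), c(40, 40, 40, C)),
             label = array(rnorm(1000), c(10, 10, 10)),
             mask = array(runif(1000) < 0.3, c(10, 10, 10)),
             occ = array(as.integer(runif(40^3) < 0.1), c(40, 40, 40)),
             grid_index = c(0, 0, 0))
  class(sb) <- "sample_box"
  sb
}

test_that("augmentation yields 8 involutive flips applied jointly", {
  sb <- make_box(3)
  aug <- augment_box(sb)
  expect_length(aug, 8)
  expect_identical(aug[[1]]$channels, sb$channels)   # identity included
  # all 8 distinct for generic input
  expect_equal(length(unique(lapply(aug, function(a) a$channels[1:50]))), 8)
  # each transform applied twice returns the original
  for (i in 1:8) {
    back <- augment_box(aug[[i]])[[i]]
    expect_identical(back$channels, sb$channels)
    expect_identical(back$label, sb$label)
    expect_identical(back$mask, sb$mask)
    expect_identical(back$occ, sb$occ)
  }
  const <- sb
  const$channels <- array(0.5, c(40, 40, 40, 2))
  const$label <- array(1, c(10, 10, 10))
  const$mask <- array(TRUE, c(10, 10, 10))
  const$occ <- NULL
  caug <- augment_box(const)
  for (a in caug) expect_identical(a$channels, const$channels)
})

test_that("a flip-equivariant stub predictor has flip-invariant loss", {
  # predictor: centre crop of the first channel is the prediction
  stub_predict <- function(sb) center_crop(sb$channels[, , , 1])
  sb <- make_box(4)
  base_loss <- masked_mse(stub_predict(sb), sb$label, sb$mask)
  for (a in augment_box(sb)) {
    expect_equal(masked_mse(stub_predict(a), a$label, a$mask), base_loss,
                 tolerance = 1e-12)
  }
})

# ---- schedule test on a stub model with scripted validation losses ----
# (register_stub lives in helper-stub.R)

test_that("constant validation loss halves lr at 10 and 20 and stops at 30", {
  s <- register_stub(rep(1.0, 100))
  sb <- make_box(5)
  fit <- train_network(s$model, list(sb), list(sb),
                       train_config(epochs = 100, batch = 1, lr = 0.004,
                                    seed = 1, augment = FALSE))
  h <- fit$history
  # epoch 1 is the only improvement (1.0 < Inf); 30 stagnant epochs follow
  expect_equal(nrow(h), 31)
  expect_equal(h$event[1], "best")
  expect_equal(h$event[11], "lr_halved_to_0.002")   # stagnant epoch 10
  expect_equal(h$event[21], "lr_halved_to_0.001")   # stagnant epoch 20
  expect_equal(h$event[31], "stop")                 # stagnant epoch 30
  expect_equal(h$lr[10], 0.004)
  expect_equal(h$lr[11], 0.002)
  expect_equal(h$lr[21], 0.001)
  # min-validation checkpoint (epoch 1) is restored
  expect_equal(s$env$restored$at_epoch, 1L)
  # the fit calls actually used the halved rates
  expect_equal(unique(s$env$lrs), c(0.004, 0.002, 0.001))
})

test_that("the minimum-validation checkpoint is restored, not the last", {
  vl <- c(1.0, 0.8, 0.5, 0.9, 0.7, rep(1.2, 40))
  s <- register_stub(vl)
  sb <- make_box(6)
  fit <- train_network(s$model, list(sb), list(sb),
                       train_config(epochs = 100, batch = 1, seed = 1,
                                    augment = FALSE))
  expect_equal(s$env$restored$at_epoch, 3L)          # val loss 0.5
  expect_equal(nrow(fit$history), 33)                # 3 + 30 stagnant
})

test_that("training a real network is seed-deterministic and can overfit", {
  samples <- lapply(1:12, function(i) make_box(100 + i))
  cfg <- train_config(epochs = 6, batch = 4, lr = 0.004, seed = 7,
                      augment = FALSE)
  f1 <- train_network(tiny_rmsf_net(seed = 3), samples[1:8], samples[9:12], cfg)
  f2 <- train_network(tiny_rmsf_net(seed = 3), samples[1:8], samples[9:12], cfg)
  expect_identical(tail(f1$history$val_loss, 1), tail(f2$history$val_loss, 1))
  expect_identical(tail(f1$history$train_loss, 1), tail(f2$history$train_loss, 1))
})

test_that("a capacity-sufficient model overfits a small labelled set", {
  # one entry's boxes with a learnable signal: label = smoothed channel
  set.seed(8)
  samples <- lapply(1:10, function(i) {
    sb <- make_box(200 + i)
    sb$label <- center_crop(sb$channels[, , , 1]) * 2
    sb$mask <- array(TRUE, c(10, 10, 10))
    sb
  })
  net <- tiny_rmsf_net(base = 4, seed = 9)
  fit <- train_network(net, samples, samples[1],
                       train_config(epochs = 25, batch = 5, lr = 0.004,
                                    seed = 1, augment = FALSE))
  h <- fit$history
  expect_lt(min(h$train_loss), 0.5 * h$train_loss[1])
})

test_that("pearson_cc matches the hand formula and rejects degenerate input", {
  expect_equal(pearson_cc(c(1, 2, 3), c(1, 2, 3)), 1.0)
  expect_equal(pearson_cc(c(1, 2, 3), -c(1, 2, 3)), -1.0)
  a <- c(1, 2, 3, 4); b <- c(2, 1, 4, 3)
  want <- sum((a - mean(a)) * (b - mean(b))) /
    sqrt(sum((a - mean(a))^2) * sum((b - mean(b))^2))
  expect_equal(pearson_cc(a, b), want)   # = 0.6 by hand
  expect_equal(want, 0.6)
  expect_error(pearson_cc(c(1, 1, 1), c(1, 2, 3)), "constant")
  expect_error(pearson_cc(1, 2), "length")
})

test_that("evaluate_entry computes voxel and residue correlations", {
  m <- random_rmsf_map(c(15, 15, 15), 30, seed = 10)
  res <- c(a = 1, b = 2, c = 3)
  truth <- list(rmsf_map = m, residue_rmsf = res)
  expect_equal(evaluate_entry(truth, truth)$voxel_cc, 1.0)
  expect_equal(evaluate_entry(truth, truth)$residue_cc, 1.0)
  # affine rescaling of predictions leaves Pearson unchanged
  m2 <- rmsf_map(voxel_grid(2 * m$values$values + 1, 1.5), m$mask)
  pred <- list(rmsf_map = m2, residue_rmsf = 2 * res + 1)
  ev <- evaluate_entry(pred, truth)
  expect_equal(ev$voxel_cc, 1.0, tolerance = 1e-12)
  expect_equal(ev$residue_cc, 1.0, tolerance = 1e-12)
  # two-residue toy by hand: correlation of 2-vectors is +-1
  t2 <- list(rmsf_map = m, residue_rmsf = c(r1 = 1, r2 = 3))
  p2 <- list(rmsf_map = m, residue_rmsf = c(r1 = 0.5, r2 = 0.9))
  expect_equal(evaluate_entry(p2, t2)$residue_cc, 1.0)
  # voxel-level ignores voxels outside the mask
  m3 <- rmsf_map(voxel_grid(m$values$values + 100 * (!m$mask), 1.5), m$mask)
  expect_equal(evaluate_entry(list(rmsf_map = m3, residue_rmsf = res),
                              truth)$voxel_cc, 1.0)
})

test_that("kfold split covers entries exactly once with 3:1 train:val", {
  entries <- paste0("e", 1:20)
  folds <- kfold_split(entries, k = 5, seed = 3)
  expect_length(folds, 5)
  test_union <- sort(unlist(lapply(folds, `[[`, "test")))
  expect_identical(test_union, 1:20)            # every entry tested once
  for (f in folds) {
    expect_length(f$test, 4)
    expect_length(f$train, 12)
    expect_length(f$val, 4)
    expect_length(intersect(f$test, c(f$train, f$val)), 0)
    expect_length(intersect(f$train, f$val), 0)
  }
  expect_error(kfold_split(1:3, k = 5), "fewer")
})

test_that("occupancy metrics follow the confusion counts at 6 thresholds", {
  y <- c(1, 1, 1, 0, 0, 0, 0, 0)
  perfect <- as.numeric(y)
  tab <- occ_metrics(perfect, y)
  expect_equal(nrow(tab), 6)
  expect_equal(tab$threshold, seq(0.3, 0.8, 0.1))
  expect_true(all(tab$precision == 1 & tab$recall == 1 & tab$f1 == 1))
  # TP=2, FP=1, FN=1 at threshold 0.5
  p <- c(0.9, 0.8, 0.1, 0.7, 0.2, 0.1, 0.1, 0.1)
  row <- occ_metrics(p, y, thresholds = 0.5)
  expect_equal(row$precision, 2 / 3)
  expect_equal(row$recall, 2 / 3)
  expect_equal(row$f1, 2 / 3)
  # all-negative predictions are flagged, not an error
  row0 <- occ_metrics(rep(0, 8), y, thresholds = 0.5)
  expect_true(row0$flagged)
  expect_equal(row0$precision, 0)
})
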