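# Losses, augmentation, training schedule, cross-validation, metrics and
# the end-to-end prediction pipeline.

#' Training configuration
#'
#' Defaults follow standard practice for this architecture: Adam at learning
#' rate 0.004, batches of 32 boxes, up to 100 epochs; the learning rate is
#' halved after 10 epochs without validation improvement and training stops
#' after 30, returning the parameters with minimum validation loss; Kaiming
#' initialisation; entries split 3:1 into training and validation.
#'
#' @param epochs maximum epochs.
#' @param batch batch size (boxes).
#' @param lr initial Adam learning rate.
#' @param lr_patience stagnant epochs before each halving.
#' @param stop_patience stagnant epochs before early stop.
#' @param seed global seed for shuffling and batching.
#' @param augment apply eightfold flip augmentation to the training set
#'   (offline expansion).
#' @param class_weights (unoccupied, occupied) weights for the occupancy
#'   classifier's cross-entropy; 0.05:0.95 counteracts class imbalance.
#' @return Object of class `train_config`.
#' @export
train_config <- function(epochs = 100L, batch = 32L, lr = 0.004,
                         lr_patience = 10L, stop_patience = 30L, seed = 1L,
                         augment = TRUE, class_weights = c(0.05, 0.95)) {
  stopifnot(epochs >= 1, batch >= 1, lr > 0, lr_patience >= 1,
            stop_patience >= 1, length(class_weights) == 2,
            all(class_weights > 0))
  structure(list(epochs = as.integer(epochs), batch = as.integer(batch),
                 lr = lr, lr_patience = as.integer(lr_patience),
                 stop_patience = as.integer(stop_patience),
                 seed = as.integer(seed), augment = isTRUE(augment),
                 class_weights = class_weights),
            class = "train_config")
}

# ---------------------------------------------------------------- losses

#' Masked mean squared error
#'
#' Mean of the squared prediction error over masked (labelled) voxels only;
#' unlabelled voxels contribute nothing.
#'
#' @param pred,target numeric arrays of one shape.
#' @param mask logical array of the same shape; at least one `TRUE`.
#' @return Scalar loss.
#' @export
masked_mse <- function(pred, target, mask) {
  if (!identical(dim(pred), dim(target)) ||
      (!is.null(dim(mask)) && !identical(dim(pred), dim(mask))))
    stop("pred, target and mask must share one shape")
  mask <- as.logical(mask)
  if (!any(mask)) stop("empty mask: masked MSE is undefined")
  mean((pred[mask] - target[mask])^2)
}

#' Class-weighted cross-entropy for voxel occupancy
#'
#' `loss = sum_v w(y_v) * (-log p_v(y_v)) / sum_v w(y_v)`: the per-voxel
#' negative log-likelihood of the true class, weighted per class and
#' normalised by the total weight.
#'
#' @param probs array with final dimension 2 holding class probabilities
#'   (unoccupied, occupied), e.g. `(40,40,40,2)`.
#' @param truth binary array (1 = occupied) matching the spatial shape.
#' @param weights class weights (unoccupied, occupied).
#' @return Scalar loss.
#' @export
weighted_cross_entropy <- function(probs, truth, weights = c(0.05, 0.95)) {
  d <- dim(probs)
  nd <- length(d)
  if (d[nd] != 2L) stop("probs must have 2 classes in the final dimension")
  p0 <- as.numeric(slice_last(probs, 1L)); p1 <- as.numeric(slice_last(probs, 2L))
  if (any(p0 < -1e-9 | p0 > 1 + 1e-9 | p1 < -1e-9 | p1 > 1 + 1e-9))
    stop("probabilities must lie in [0, 1]")
  y <- as.numeric(truth)
  if (length(y) != length(p0)) stop("truth shape does not match probs")
  w <- ifelse(y > 0, weights[2], weights[1])
  ptrue <- ifelse(y > 0, p1, p0)
  sum(w * -log(pmax(ptrue, 1e-12))) / sum(w)
}

slice_last <- function(arr, i) {
  d <- dim(arr)
  idx <- c(rep(list(quote(expr = )), length(d) - 1L), list(i))
  do.call(`[`, c(list(arr), idx))
}

# ------------------------------------------------------------ augmentation

#' Eightfold flip augmentation of a sample box
#'
#' Applies the 8 combinations of axis mirror flips (identity included)
#' identically to every channel, the label, the mask and the occupancy
#' block, expanding the training data eightfold to compensate for the
#' network's lack of built-in mirror symmetry. Each transform is an
#' involution.
#'
#' @param sample a `sample_box`.
#' @return List of 8 `sample_box`es (the first is the original).
#' @export
augment_box <- function(sample) {
  stopifnot(inherits(sample, "sample_box"))
  flips <- expand.grid(x = c(FALSE, TRUE), y = c(FALSE, TRUE),
                       z = c(FALSE, TRUE))
  lapply(seq_len(nrow(flips)), function(i) {
    f <- as.logical(flips[i, ])
    s <- sample
    s$channels <- flip_array(sample$channels, f)
    if (!is.null(s$label)) s$label <- flip_array(sample$label, f)
    if (!is.null(s$mask)) s$mask <- flip_array(sample$mask, f)
    if (!is.null(s$occ)) s$occ <- flip_array(sample$occ, f)
    s
  })
}

flip_array <- function(arr, flips) {
  d <- dim(arr)
  ix <- if (flips[1]) rev(seq_len(d[1])) else seq_len(d[1])
  iy <- if (flips[2]) rev(seq_len(d[2])) else seq_len(d[2])
  iz <- if (flips[3]) rev(seq_len(d[3])) else seq_len(d[3])
  if (length(d) == 3L) arr[ix, iy, iz, drop = FALSE]
  else arr[ix, iy, iz, , drop = FALSE]
}

# ---------------------------------------------------------------- training

#' Train a model with validation-driven scheduling
#'
#' Runs mini-batch optimisation with the schedule: if the validation loss
#' does not strictly improve for `lr_patience` consecutive epochs the
#' learning rate is halved (possible twice by default); after
#' `stop_patience` stagnant epochs training stops. The returned model holds
#' the parameters with minimum validation loss. Fully reproducible given
#' the config seed.
#'
#' @param model a model implementing [vf_fit_batch] (e.g. `vf_network`).
#' @param train_samples,val_samples non-empty lists of `sample_box`es.
#' @param config a [train_config].
#' @return List with `model` (best-validation parameters restored) and
#'   `history` (data frame: epoch, train_loss, val_loss, lr, event).
#' @export
train_network <- function(model, train_samples, val_samples,
                          config = train_config()) {
  stopifnot(inherits(config, "train_config"))
  if (length(train_samples) < 1L || length(val_samples) < 1L)
    stop("need at least one training and one validation sample")
  if (config$augment)
    train_samples <- unlist(lapply(train_samples, augment_box),
                            recursive = FALSE)
  set.seed(config$seed)
  lr <- config$lr
  best_val <- Inf
  best_state <- NULL
  stagnant <- 0L
  hist <- list()
  n <- length(train_samples)
  for (epoch in seq_len(config$epochs)) {
    ord <- sample.int(n)
    batch_starts <- seq(1L, n, by = config$batch)
    tloss <- 0
    for (bs in batch_starts) {
      sel <- ord[bs:min(bs + config$batch - 1L, n)]
      tloss <- tloss + vf_fit_batch(model, train_samples[sel], lr, config) *
        length(sel)
    }
    tloss <- tloss / n
    vloss <- vf_val_loss(model, val_samples, config)
    event <- ""
    if (vloss < best_val) {
      best_val <- vloss
      best_state <- vf_checkpoint(model)
      stagnant <- 0L
      event <- "best"
    } else {
      stagnant <- stagnant + 1L
      if (stagnant >= config$stop_patience) {
        event <- "stop"
      } else if (stagnant %% config$lr_patience == 0L) {
        lr <- lr / 2
        event <- sprintf("lr_halved_to_%g", lr)
      }
    }
    hist[[epoch]] <- data.frame(epoch = epoch, train_loss = tloss,
                                val_loss = vloss, lr = lr, event = event,
                                stringsAsFactors = FALSE)
    if (event == "stop") break
  }
  if (!is.null(best_state)) vf_restore(model, best_state)
  if (inherits(model, "vf_network") || inherits(model, "vf_occ2rmsf"))
    model$trained <- TRUE
  list(model = model, history = do.call(rbind, hist))
}

# ---------------------------------------------------------------- metrics

#' Pearson correlation coefficient
#'
#' @param a,b equal-length numeric vectors (length >= 2, both
#'   non-constant).
#' @return Correlation in `[-1, 1]`.
#' @export
pearson_cc <- function(a, b) {
  if (length(a) != length(b) || length(a) < 2L)
    stop("need two equal-length vectors of length >= 2")
  if (sd_pop(a) == 0 || sd_pop(b) == 0)
    stop("correlation undefined for constant input")
  cor(a, b)
}

#' Evaluate a prediction against ground truth
#'
#' Voxel-level correlation is the Pearson correlation of the two RMSF maps
#' over the intersection of their masks; residue-level correlation compares
#' the per-residue vectors (residue value = mean over the residue's atoms).
#'
#' @param pred,truth lists with fields `rmsf_map` (an [rmsf_map]) and
#'   `residue_rmsf` (named numeric vector), e.g. a [predict_rmsf_map]
#'   result and a dataset entry.
#' @return List with `voxel_cc` and `residue_cc`.
#' @export
evaluate_entry <- function(pred, truth) {
  common <- pred$rmsf_map$mask & truth$rmsf_map$mask
  if (!any(common)) stop("no labelled voxels in common; cannot evaluate")
  voxel_cc <- pearson_cc(pred$rmsf_map$values$values[common],
                         truth$rmsf_map$values$values[common])
  residue_cc <- NA_real_
  if (!is.null(pred$residue_rmsf) && !is.null(truth$residue_rmsf)) {
    keys <- intersect(names(pred$residue_rmsf), names(truth$residue_rmsf))
    residue_cc <- pearson_cc(pred$residue_rmsf[keys], truth$residue_rmsf[keys])
  }
  list(voxel_cc = voxel_cc, residue_cc = residue_cc)
}

#' K-fold cross-validation split at entry level
#'
#' Splits entries (maps), never boxes, to keep train/validation/test sets
#' independent: k disjoint test folds covering all entries exactly once;
#' the remaining entries of each fold are split `ratio` into training and
#' validation.
#'
#' @param entries vector or list of entry identifiers.
#' @param k number of folds.
#' @param ratio train:validation ratio as a length-2 vector (default 3:1).
#' @param seed shuffle seed.
#' @return List of k lists with `train`, `val`, `test` index vectors
#'   (indices into `entries`).
#' @export
kfold_split <- function(entries, k = 5L, ratio = c(3, 1), seed = 1L) {
  n <- length(entries)
  if (n < k) stop("fewer entries than folds")
  set.seed(seed)
  ord <- sample.int(n)
  folds <- split(ord, rep(seq_len(k), length.out = n))
  lapply(seq_len(k), function(f) {
    test <- sort(folds[[f]])
    rest <- ord[!(ord %in% test)]
    n_val <- max(1L, round(length(rest) * ratio[2] / sum(ratio)))
    list(train = sort(rest[-seq_len(n_val)]), val = sort(rest[seq_len(n_val)]),
         test = test)
  })
}

#' Occupancy classification metrics over thresholds
#'
#' For each threshold a voxel is predicted occupied iff
#' `P(occupied) >= threshold`; precision, recall and F1 of the positive
#' (structure-occupied) class follow from the confusion counts. Zero
#' denominators yield 0 with `flagged = TRUE`.
#'
#' @param probs numeric vector/array of occupied-class probabilities, or a
#'   (40,40,40,2,n) probability array from [forward_network].
#' @param truth binary vector/array of the same spatial size.
#' @param thresholds classification thresholds (default 0.3 to 0.8).
#' @return Data frame with columns `threshold`, `precision`, `recall`,
#'   `f1`, `flagged`.
#' @export
occ_metrics <- function(probs, truth, thresholds = seq(0.3, 0.8, by = 0.1)) {
  if (is.array(probs) && length(dim(probs)) == 5L)
    probs <- probs[, , , 2, ]             # occupied channel
  p <- as.numeric(probs); y <- as.numeric(truth) > 0
  if (length(p) != length(y)) stop("probs and truth sizes differ")
  rows <- lapply(thresholds, function(th) {
    pos <- p >= th
    tp <- sum(pos & y); fp <- sum(pos & !y); fn <- sum(!pos & y)
    flagged <- FALSE
    prec <- if (tp + fp > 0) tp / (tp + fp) else { flagged <- TRUE; 0 }
    rec <- if (tp + fn > 0) tp / (tp + fn) else { flagged <- TRUE; 0 }
    f1 <- if (prec + rec > 0) 2 * prec * rec / (prec + rec) else { flagged <- TRUE; 0 }
    data.frame(threshold = th, precision = prec, recall = rec, f1 = f1,
               flagged = flagged)
  })
  do.call(rbind, rows)
}

# ------------------------------------------------------------- prediction

variant_channels_for <- function(variant, cryo_grid, sim_grid) {
  switch(variant,
    cryo = list(cryo_grid),
    pdb = list(sim_grid),
    pdb01 = {
      b <- binarize_simulated_map(sim_grid)
      oh <- one_hot_encode(b$grid)
      list(oh$ch0, oh$ch1)
    },
    dual = list(cryo_grid, sim_grid),
    occ = list(cryo_grid),
    occ2rmsf = list(cryo_grid),
    stop("unknown variant: ", variant))
}

#' End-to-end RMSF prediction for a map/model pair
#'
#' Pipeline: resample the map to 1.5 Angstrom voxels, simulate the model
#' density on the same grid, assemble the variant's input channels, segment
#' into screened normalised boxes (screening by the model's occupancy
#' footprint), run the network, merge the predicted subboxes, then read
#' per-atom values at each atom's nearest voxel and average them per
#' residue.
#'
#' @param net a trained `vf_network` (regression variant) or `vf_occ2rmsf`.
#' @param cryo_map experimental density [voxel_grid].
#' @param model fitted [atomic_model].
#' @param resolution simulation resolution in Angstrom (use the map's
#'   reported resolution; default 5).
#' @param spec a [box_spec].
#' @param chunk evaluation batch size.
#' @return List of class `rmsf_prediction` with `rmsf_map` (an
#'   [rmsf_map] masked on the occupancy footprint), `atom_rmsf` and
#'   `residue_rmsf`.
#' @export
predict_rmsf_map <- function(net, cryo_map, model, resolution = 5,
                             spec = box_spec(), chunk = 16L) {
  stopifnot(is_voxel_grid(cryo_map), is_atomic_model(model))
  variant <- if (inherits(net, "vf_occ2rmsf")) "occ2rmsf" else net$config$variant
  if (variant == "occ") stop("predict_rmsf_map requires a regression variant")
  if (!isTRUE(net$trained)) stop("network has not been trained")
  grid <- resample_to_voxel_size(cryo_map, 1.5)
  sim <- simulate_density(model, grid, resolution)
  occ <- occupancy_annotation(model, grid)
  channels <- variant_channels_for(variant, grid, sim)
  expected <- if (variant == "occ2rmsf") 1L else net$config$in_channels
  if (length(channels) != expected)
    stop("variant/channel mismatch: ", variant, " provides ", length(channels),
         " channels, network expects ", expected)
  boxes <- segment_boxes(channels, labels = NULL, mask = occ, spec = spec)
  if (length(boxes) == 0L) stop("no atoms inside the map: nothing to predict")
  pred <- forward_network(net, boxes, chunk = chunk)
  preds <- lapply(seq_along(boxes), function(i)
    list(grid_index = boxes[[i]]$grid_index, values = pred[, , , i]))
  merged <- merge_subboxes(preds, grid, spec,
                           masks = lapply(boxes, function(b) b$mask))
  out_map <- rmsf_map(merged$values, occ$values > 0)
  idx <- world_to_voxel(grid, coords_matrix(model))
  atom_rmsf <- voxel_value(out_map$values, idx)
  atom_rmsf[is.na(atom_rmsf)] <- 0
  residue_rmsf <- aggregate_to_residues(atom_rmsf, model)
  structure(list(rmsf_map = out_map, atom_rmsf = atom_rmsf,
                 residue_rmsf = residue_rmsf, variant = variant),
            class = "rmsf_prediction")
}
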