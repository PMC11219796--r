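# Network construction and the model interface used by the trainer.
#
# All variants share one 3D Unet++(L3) backbone (channels base * {1,2,4,8},
# 3^3 convolutions + batch norm + ReLU, max-pool down / trilinear up, dense
# nested skip pathways); only the input channel count differs:
#   cryo = 1 (experimental map), pdb = 1 (simulated map),
#   pdb01 = 2 (one-hot thresholded simulated map), dual = 2 (cryo + pdb).
# The regression variants end in two 1-kernel convolutions and a centre
# crop to the 10^3 subbox; the occupancy classifier (occ) keeps the full
# 40^3 output with a 2-class softmax head. For the regression variants the
# implementation evaluates exactly the receptive field of the central
# subbox (valid convolutions on centred crops), which is the restriction of
# the full-box network to the voxels the loss can see; normalisation
# statistics are taken over that active region.

VARIANT_CHANNELS <- c(cryo = 1L, pdb = 1L, pdb01 = 2L, dual = 2L,
                      occ = 1L, occ2rmsf = 2L)

#' Network configuration
#'
#' @param variant one of `"cryo"`, `"pdb"`, `"pdb01"`, `"dual"`, `"occ"`,
#'   `"occ2rmsf"`; fixes the input channel count (1, 1, 2, 2, 1, 2).
#' @param base_channels channels at the highest resolution level, doubled at
#'   each of the 3 down-samplings (default 16).
#' @param seed integer seed for Kaiming weight initialisation.
#' @return Object of class `network_config`.
#' @export
network_config <- function(variant = "dual", base_channels = 16L, seed = 1L) {
  variant <- match.arg(variant, names(VARIANT_CHANNELS))
  if (base_channels < 2L) stop("base_channels must be >= 2")
  structure(list(variant = variant,
                 in_channels = VARIANT_CHANNELS[[variant]],
                 base_channels = as.integer(base_channels),
                 depth = 3L, seed = as.integer(seed)),
            class = "network_config")
}

#' Build the RMSF regression network
#'
#' Maps C x 40^3 normalised density boxes to the 10^3 central subbox of
#' per-voxel RMSF predictions (Angstrom).
#'
#' @param config a [network_config] with a regression variant (`cryo`,
#'   `pdb`, `pdb01`, `dual` or `occ2rmsf` for the stage-2 head).
#' @return A `vf_network` predictor object.
#' @export
build_rmsf_network <- function(config) {
  stopifnot(inherits(config, "network_config"))
  if (config$variant == "occ") stop("use build_occ_network for the occupancy variant")
  ptr <- .cpp_nn_create(config$in_channels, config$base_channels, TRUE, 1L,
                        FALSE, config$seed)
  structure(list(ptr = ptr, config = config, kind = "rmsf", trained = FALSE),
            class = "vf_network")
}

#' Build the occupancy classifier
#'
#' Maps 1 x 40^3 map boxes to 2 x 40^3 per-voxel class probabilities
#' (unoccupied, occupied) summing to one; no crop.
#'
#' @param config a [network_config] with `variant = "occ"`.
#' @return A `vf_network` classifier object.
#' @export
build_occ_network <- function(config) {
  stopifnot(inherits(config, "network_config"))
  if (config$in_channels != 1L) stop("occupancy network takes a single input channel")
  ptr <- .cpp_nn_create(1L, config$base_channels, FALSE, 2L, TRUE, config$seed)
  structure(list(ptr = ptr, config = config, kind = "occ", trained = FALSE),
            class = "vf_network")
}

#' @export
print.vf_network <- function(x, ...) {
  cat(sprintf("<vf_network> %s variant, base %d, %s parameters%s\n",
              x$config$variant, x$config$base_channels,
              format(network_nparams(x), big.mark = ","),
              if (isTRUE(x$trained)) " (trained)" else ""))
  invisible(x)
}

#' Number of trainable parameters
#' @param net a `vf_network`.
#' @return Integer parameter count.
#' @export
network_nparams <- function(net) as.integer(.cpp_nn_nparams(net$ptr))

#' Compose a trained occupancy classifier with an RMSF head
#'
#' Stage 1 (the frozen occupancy classifier) turns a 1 x 40^3 map box into
#' 2 x 40^3 occupancy probabilities; stage 2 (a fresh 2-channel regression
#' network) predicts RMSF on the central 10^3 voxels from those
#' probabilities. During stage-2 training only the head's parameters move.
#'
#' @param occ a trained occupancy `vf_network`.
#' @param config a [network_config] for the head (variant `"occ2rmsf"`).
#' @return Object of class `vf_occ2rmsf` with fields `occ` and `rmsf`.
#' @export
compose_occ2rmsf <- function(occ, config = network_config("occ2rmsf",
                                                          occ$config$base_channels,
                                                          occ$config$seed)) {
  stopifnot(inherits(occ, "vf_network"), occ$kind == "occ")
  if (!isTRUE(occ$trained)) stop("occupancy network must be trained before composition")
  if (config$in_channels != 2L) stop("stage-2 head takes the 2 probability channels")
  head <- build_rmsf_network(config)
  structure(list(occ = occ, rmsf = head, kind = "rmsf", trained = FALSE),
            class = c("vf_occ2rmsf"))
}

#' Centre crop of a 40-voxel field
#'
#' Returns indices 15..24 (0-based) of each spatial axis: the central 10^3
#' subbox of a 40^3 box. Accepts a 3D array or a 4D (spatial x channel)
#' array.
#'
#' @param field array with spatial edge 40.
#' @return The cropped array.
#' @export
center_crop <- function(field) {
  d <- dim(field)
  if (is.null(d) || !(length(d) %in% c(3L, 4L)) || any(d[1:3] != 40L))
    stop("center_crop expects a 40^3 spatial field")
  if (length(d) == 3L) field[16:25, 16:25, 16:25]
  else field[16:25, 16:25, 16:25, , drop = FALSE]
}

# ---------------------------------------------------------------- batching

stack_channels <- function(samples) {
  n <- length(samples)
  cdim <- dim(samples[[1]]$channels)
  arr <- array(0, dim = c(cdim, n))
  for (i in seq_len(n)) arr[, , , , i] <- samples[[i]]$channels
  arr
}

stack_labels <- function(samples) {
  n <- length(samples)
  se <- dim(samples[[1]]$label)[1]
  lab <- array(0, dim = c(se, se, se, n))
  msk <- array(FALSE, dim = c(se, se, se, n))
  for (i in seq_len(n)) {
    lab[, , , i] <- samples[[i]]$label
    msk[, , , i] <- samples[[i]]$mask
  }
  list(label = lab, mask = msk)
}

stack_occ <- function(samples) {
  n <- length(samples)
  be <- dim(samples[[1]]$occ)[1]
  occ <- array(0L, dim = c(be, be, be, n))
  for (i in seq_len(n)) occ[, , , i] <- samples[[i]]$occ
  occ
}

#' Forward pass of a network over sample boxes
#'
#' Deterministic (evaluation-mode) forward pass. For regression networks
#' returns an array (10, 10, 10, n); for the occupancy classifier an array
#' (40, 40, 40, 2, n) of class probabilities.
#'
#' @param net a `vf_network` or `vf_occ2rmsf`.
#' @param samples list of `sample_box`es (or a ready (40,40,40,C,n) array).
#' @param chunk evaluation batch size.
#' @return Prediction array.
#' @export
forward_network <- function(net, samples, chunk = 16L) {
  UseMethod("forward_network")
}

#' @export
forward_network.vf_network <- function(net, samples, chunk = 16L) {
  arr <- if (is.array(samples)) samples else stack_channels(samples)
  n <- dim(arr)[5]
  outs <- vector("list", ceiling(n / chunk))
  for (b in seq_along(outs)) {
    sel <- ((b - 1L) * chunk + 1L):min(b * chunk, n)
    outs[[b]] <- .cpp_nn_forward(net$ptr, arr[, , , , sel, drop = FALSE])
  }
  od <- dim(outs[[1]])
  res <- array(0, dim = c(od[1:4], n))
  pos <- 0L
  for (o in outs) {
    k <- dim(o)[5]
    res[, , , , pos + seq_len(k)] <- o
    pos <- pos + k
  }
  if (net$kind == "rmsf") array(res[, , , 1, ], dim = c(od[1:3], n)) else res
}

#' @export
forward_network.vf_occ2rmsf <- function(net, samples, chunk = 16L) {
  probs <- forward_network(net$occ, samples, chunk)
  forward_network(net$rmsf, probs, chunk)
}

# -------------------------------------------------- trainer model interface
# The trainer only touches models through these generics, so schedule tests
# can plug in stubs and composed models train their trainable part only.

#' Model interface used by the trainer
#'
#' `vf_fit_batch` performs one optimiser step on a batch and returns the
#' batch loss; `vf_val_loss` evaluates the loss without updating;
#' `vf_checkpoint`/`vf_restore` snapshot and restore parameters.
#'
#' @param model a model object (e.g. `vf_network`).
#' @param samples list of `sample_box`es.
#' @param lr learning rate.
#' @param config a `train_config` (class weights for the classifier).
#' @param state a checkpoint from `vf_checkpoint`.
#' @return `vf_fit_batch`/`vf_val_loss`: scalar loss; `vf_checkpoint`: an
#'   opaque state object; `vf_restore`: the model, invisibly.
#' @export
vf_fit_batch <- function(model, samples, lr, config) UseMethod("vf_fit_batch")

#' @rdname vf_fit_batch
#' @export
vf_val_loss <- function(model, samples, config) UseMethod("vf_val_loss")

#' @rdname vf_fit_batch
#' @export
vf_checkpoint <- function(model) UseMethod("vf_checkpoint")

#' @rdname vf_fit_batch
#' @export
vf_restore <- function(model, state) UseMethod("vf_restore")

#' @export
vf_fit_batch.vf_network <- function(model, samples, lr, config) {
  arr <- stack_channels(samples)
  if (model$kind == "rmsf") {
    lb <- stack_labels(samples)
    .cpp_nn_train_mse(model$ptr, arr, lb$label, lb$mask, lr)
  } else {
    occ <- stack_occ(samples)
    w <- config$class_weights
    .cpp_nn_train_ce(model$ptr, arr, occ, w[1], w[2], lr)
  }
}

#' @export
vf_val_loss.vf_network <- function(model, samples, config) {
  arr <- stack_channels(samples)
  if (model$kind == "rmsf") {
    lb <- stack_labels(samples)
    .cpp_nn_loss_mse(model$ptr, arr, lb$label, lb$mask)
  } else {
    occ <- stack_occ(samples)
    w <- config$class_weights
    .cpp_nn_loss_ce(model$ptr, arr, occ, w[1], w[2])
  }
}

#' @export
vf_checkpoint.vf_network <- function(model) .cpp_nn_get_state(model$ptr)

#' @export
vf_restore.vf_network <- function(model, state) {
  .cpp_nn_set_state(model$ptr, state)
  invisible(model)
}

# the composed model trains its stage-2 head on occupancy probabilities;
# stage-1 parameters never move
#' @export
vf_fit_batch.vf_occ2rmsf <- function(model, samples, lr, config) {
  probs <- forward_network(model$occ, samples)
  lb <- stack_labels(samples)
  .cpp_nn_train_mse(model$rmsf$ptr, probs, lb$label, lb$mask, lr)
}

#' @export
vf_val_loss.vf_occ2rmsf <- function(model, samples, config) {
  probs <- forward_network(model$occ, samples)
  lb <- stack_labels(samples)
  .cpp_nn_loss_mse(model$rmsf$ptr, probs, lb$label, lb$mask)
}

#' @export
vf_checkpoint.vf_occ2rmsf <- function(model) vf_checkpoint(model$rmsf)

#' @export
vf_restore.vf_occ2rmsf <- function(model, state) {
  vf_restore(model$rmsf, state)
  invisible(model)
}

# ---------------------------------------------------------------- storage

#' Save / load network weights
#'
#' The checkpoint embeds a copy of the configuration so the architecture is
#' rebuilt faithfully on load.
#'
#' @param net a `vf_network`.
#' @param path file path.
#' @return `load_network` returns the restored `vf_network`.
#' @export
save_network <- function(net, path) {
  stopifnot(inherits(net, "vf_network"))
  saveRDS(list(config = net$config, kind = net$kind, trained = net$trained,
               state = vf_checkpoint(net)), path)
  invisible(path)
}

#' @rdname save_network
#' @export
load_network <- function(path) {
  obj <- readRDS(path)
  net <- if (obj$kind == "occ") build_occ_network(obj$config)
         else build_rmsf_network(obj$config)
  vf_restore(net, obj$state)
  net$trained <- obj$trained
  net
}
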