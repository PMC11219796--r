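# Simulated density rendering, thresholding/one-hot encoding, occupancy
# annotation and map-model fitness.

#' Render a simulated density map from an atomic model
#'
#' Each atom contributes an isotropic 3D Gaussian centred at its coordinate
#' with standard deviation `0.225 * resolution` and peak amplitude equal to
#' its atomic mass, truncated at 4 standard deviations (the convention of
#' molmap-style simulated maps). Contributions are summed on the grid.
#'
#' @param model an [atomic_model].
#' @param grid a [voxel_grid] supplying the geometry (its values are
#'   ignored), or `NULL` to build a grid enclosing the model.
#' @param resolution nominal resolution in Angstrom (> 0); for experimental
#'   maps use the reported map resolution.
#' @param voxel_size,margin grid geometry when `grid` is `NULL`: voxel edge
#'   (Angstrom) and margin (voxels) around the model's bounding box.
#' @return A [voxel_grid] of simulated density.
#' @export
simulate_density <- function(model, grid = NULL, resolution = 5,
                             voxel_size = 1.5, margin = 10) {
  stopifnot(is_atomic_model(model))
  if (!is.numeric(resolution) || resolution <= 0)
    stop("resolution must be positive")
  if (is.null(grid)) grid <- bounding_grid(coords_matrix(model), voxel_size, margin)
  sigma <- 0.225 * resolution
  vals <- .cpp_simulate_density(coords_matrix(model), model$atoms$mass,
                                as.integer(dim(grid$values)),
                                grid$voxel_size, grid$origin, sigma)
  voxel_grid(array(vals, dim = dim(grid$values)), grid$voxel_size, grid$origin)
}

# an empty grid whose voxel centres cover the coordinates plus a margin
bounding_grid <- function(coords, voxel_size = 1.5, margin = 10) {
  lo <- apply(coords, 2, min) - margin * voxel_size
  hi <- apply(coords, 2, max) + margin * voxel_size
  d <- pmax(1L, as.integer(ceiling((hi - lo) / voxel_size)) + 1L)
  voxel_grid(array(0, dim = d), voxel_size, lo)
}

#' Threshold a simulated map at 3 sigma
#'
#' `sigma` is the (population) standard deviation of all density values
#' about their mean; voxels with density above `3 * sigma` are encoded as 1,
#' the rest as 0. An all-constant map (sigma 0) yields an all-zero binary
#' map.
#'
#' @param grid a simulated-density [voxel_grid].
#' @return List with `grid` (binary [voxel_grid]) and `stats`
#'   (`sigma`, `threshold`).
#' @export
binarize_simulated_map <- function(grid) {
  stopifnot(is_voxel_grid(grid))
  sigma <- sd_pop(as.numeric(grid$values))
  thr <- 3 * sigma
  b <- if (sigma == 0) array(0, dim = dim(grid$values))
       else (grid$values > thr) * 1
  list(grid = voxel_grid(b, grid$voxel_size, grid$origin),
       stats = list(sigma = sigma, threshold = thr))
}

#' One-hot encode a binary grid into two channels
#'
#' Channel 0 marks unoccupied voxels (`1 - b`), channel 1 occupied (`b`);
#' the channels sum to one at every voxel.
#'
#' @param binary a binary [voxel_grid] (values 0/1 only).
#' @return List of two [voxel_grid] channels `ch0`, `ch1`.
#' @export
one_hot_encode <- function(binary) {
  stopifnot(is_voxel_grid(binary))
  if (!all(binary$values %in% c(0, 1)))
    stop("one_hot_encode requires a binary grid")
  list(ch0 = voxel_grid(1 - binary$values, binary$voxel_size, binary$origin),
       ch1 = binary)
}

#' Decode a one-hot pair back to the binary grid
#' @param onehot list as returned by [one_hot_encode].
#' @return The binary [voxel_grid] (channel 1).
#' @export
one_hot_decode <- function(onehot) onehot$ch1

#' Structure-occupancy annotation of a grid
#'
#' A voxel is occupied (1) iff at least one heavy atom's nearest voxel
#' (see [world_to_voxel]) is that voxel. Ground truth for the occupancy
#' classifier and the screening footprint at inference.
#'
#' @param model an [atomic_model].
#' @param grid a [voxel_grid] sharing the model's world frame.
#' @return A binary [voxel_grid].
#' @export
occupancy_annotation <- function(model, grid) {
  stopifnot(is_atomic_model(model), is_voxel_grid(grid))
  idx <- world_to_voxel(grid, coords_matrix(model))
  occ <- array(0, dim = dim(grid$values))
  ok <- !is.na(idx[, 1])
  if (any(ok)) occ[idx[ok, , drop = FALSE] + 1L] <- 1
  voxel_grid(occ, grid$voxel_size, grid$origin)
}

#' Map-model fitness
#'
#' Pearson correlation over all voxels between a model's simulated map and
#' the experimental map on the same grid; values above about 0.7 indicate a
#' well-fitting map/model pair.
#'
#' @param simulated,experimental [voxel_grid]s of identical shape and voxel
#'   size.
#' @return Correlation in `[-1, 1]`.
#' @export
map_model_fitness <- function(simulated, experimental) {
  stopifnot(is_voxel_grid(simulated), is_voxel_grid(experimental))
  if (!identical(dim(simulated$values), dim(experimental$values)))
    stop("grids must have identical shape")
  a <- as.numeric(simulated$values); b <- as.numeric(experimental$values)
  if (sd_pop(a) == 0 || sd_pop(b) == 0)
    stop("correlation undefined: zero variance in a map")
  cor(a, b)
}
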