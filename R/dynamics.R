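# Ground-truth flexibility labels: Kabsch superposition, ensemble RMSF,
# projection onto voxels and residues, z-score normalisation.

#' Construct a conformation ensemble
#'
#' @param frames numeric array of dimension (N, 3, F): F frames of N atoms
#'   sharing one topology with an [atomic_model].
#' @return An object of class `conformation_ensemble`.
#' @export
conformation_ensemble <- function(frames) {
  frames <- as.array(frames)
  if (length(dim(frames)) != 3L || dim(frames)[2] != 3L)
    stop("frames must be an (N, 3, F) array")
  if (dim(frames)[3] < 1L) stop("ensemble needs at least one frame")
  if (!all(is.finite(frames))) stop("frame coordinates must be finite")
  structure(list(frames = frames), class = "conformation_ensemble")
}

#' @export
print.conformation_ensemble <- function(x, ...) {
  d <- dim(x$frames)
  cat(sprintf("<conformation_ensemble> %d atoms x %d frames\n", d[1], d[3]))
  invisible(x)
}

#' Read an ensemble from a multi-model PDB
#'
#' Heavy atoms only, same filtering as [read_atomic_model]; all models must
#' share the atom topology.
#'
#' @param path path to a multi-model PDB file.
#' @return A [conformation_ensemble].
#' @export
read_ensemble <- function(path) {
  pdb <- parse_structure(path, multi = TRUE)
  at <- pdb$atom
  el <- element_from_bio3d(at$elesy, at$elety)
  keep <- at$type == "ATOM" & !(el %in% c("H", "D"))
  if (!any(keep)) stop("no heavy protein atoms found in ", path)
  xyz <- pdb$xyz
  if (is.null(dim(xyz))) xyz <- matrix(xyz, nrow = 1)
  cols <- bio3d::atom2xyz(which(keep))
  xyz <- xyz[, cols, drop = FALSE]
  nf <- nrow(xyz); na <- sum(keep)
  frames <- array(0, dim = c(na, 3, nf))
  for (f in seq_len(nf)) frames[, , f] <- matrix(xyz[f, ], ncol = 3, byrow = TRUE)
  conformation_ensemble(frames)
}

#' Kabsch superposition
#'
#' Least-squares rigid alignment of `mobile` onto `reference`: returns the
#' proper rotation (determinant +1) and translation minimising the RMSD over
#' all rigid transforms, via SVD of the cross-covariance matrix.
#'
#' @param mobile,reference N x 3 coordinate matrices, N >= 3,
#'   non-collinear.
#' @return List with `rotation` (3 x 3), `translation` (length 3) and
#'   `rmsd` (Angstrom); `rotation %*% x + translation` maps mobile points
#'   onto the reference frame.
#' @export
kabsch_superpose <- function(mobile, reference) {
  mobile <- as.matrix(mobile); reference <- as.matrix(reference)
  if (nrow(mobile) < 3L || !identical(dim(mobile), dim(reference)))
    stop("need matching point sets with at least 3 points")
  mc <- colMeans(mobile); rc <- colMeans(reference)
  X <- sweep(mobile, 2, mc); Y <- sweep(reference, 2, rc)
  C <- crossprod(X, Y)                      # 3x3 cross-covariance
  sv <- svd(C)
  if (sv$d[2] < 1e-10 * max(sv$d[1], 1e-300))
    stop("degenerate (collinear) point set: rotation is not determined")
  d <- sign(det(sv$v %*% t(sv$u)))
  S <- diag(c(1, 1, d))
  R <- sv$v %*% S %*% t(sv$u)
  tr <- rc - as.numeric(R %*% mc)
  fitted <- sweep(tcrossprod(mobile, R), 2, tr, "+")
  rmsd <- sqrt(mean(rowSums((fitted - reference)^2)))
  list(rotation = R, translation = tr, rmsd = rmsd)
}

apply_rigid <- function(coords, rotation, translation) {
  sweep(tcrossprod(coords, rotation), 2, translation, "+")
}

#' Root-mean-square fluctuation of an ensemble
#'
#' Removes global translation/rotation and measures each atom's fluctuation
#' about the ensemble mean structure: (1) align all frames to the first
#' frame, (2) compute the heavy-atom mean structure, (3) re-align all frames
#' to the mean and recompute it, twice, then (4)
#' `RMSF_i = sqrt(mean_t ||x_i(t) - xbar_i||^2)`.
#'
#' @param ensemble a [conformation_ensemble] with at least 2 frames.
#' @return Numeric vector of per-atom RMSF (Angstrom), aligned to the
#'   topology's atom order.
#' @export
ensemble_rmsf <- function(ensemble) {
  stopifnot(inherits(ensemble, "conformation_ensemble"))
  fr <- ensemble$frames
  nf <- dim(fr)[3]
  if (nf < 2L) stop("RMSF requires at least 2 frames")
  aligned <- fr
  ref <- fr[, , 1]
  for (f in seq_len(nf)) {
    k <- kabsch_superpose(aligned[, , f], ref)
    aligned[, , f] <- apply_rigid(aligned[, , f], k$rotation, k$translation)
  }
  for (pass in 1:2) {
    mean_structure <- apply(aligned, c(1, 2), mean)
    for (f in seq_len(nf)) {
      k <- kabsch_superpose(aligned[, , f], mean_structure)
      aligned[, , f] <- apply_rigid(aligned[, , f], k$rotation, k$translation)
    }
  }
  mean_structure <- apply(aligned, c(1, 2), mean)
  dev2 <- sweep(aligned, c(1, 2), mean_structure)^2
  sqrt(apply(dev2, 1, function(a) mean(colSums(matrix(a, nrow = 3)))))
}

#' Construct an RMSF map
#' @param values [voxel_grid] of RMSF values.
#' @param mask logical array of the same shape marking labelled voxels.
#' @return Object of class `rmsf_map`.
#' @export
rmsf_map <- function(values, mask) {
  stopifnot(is_voxel_grid(values))
  mask <- array(as.logical(mask), dim = dim(values$values))
  if (!identical(dim(mask), dim(values$values)))
    stop("mask and values must have the same shape")
  if (any(!is.finite(values$values[mask])))
    stop("RMSF values must be finite on the mask")
  structure(list(values = values, mask = mask), class = "rmsf_map")
}

#' @export
print.rmsf_map <- function(x, ...) {
  cat(sprintf("<rmsf_map> %s voxels, %d labelled\n",
              paste(dim(x$values$values), collapse = " x "), sum(x$mask)))
  invisible(x)
}

#' Project per-atom RMSF onto grid voxels
#'
#' Each atom deposits its RMSF in its nearest voxel; voxels receiving
#' several atoms hold the arithmetic mean. The mask is true exactly on
#' receiving voxels.
#'
#' @param profile per-atom RMSF vector aligned to `model`.
#' @param model an [atomic_model].
#' @param grid a [voxel_grid] giving the target geometry.
#' @return An [rmsf_map].
#' @export
rmsf_to_voxels <- function(profile, model, grid) {
  stopifnot(is_atomic_model(model), is_voxel_grid(grid),
            length(profile) == n_atoms(model))
  idx <- world_to_voxel(grid, coords_matrix(model))
  ok <- !is.na(idx[, 1])
  vals <- array(0, dim = dim(grid$values))
  mask <- array(FALSE, dim = dim(grid$values))
  if (!any(ok)) {
    warning("no atom falls inside the grid; empty mask")
  } else {
    lin <- 1L + idx[ok, 1] + dim(vals)[1] * (idx[ok, 2] + dim(vals)[2] * idx[ok, 3])
    sums <- tapply(profile[ok], lin, sum)
    counts <- tapply(rep(1, sum(ok)), lin, sum)
    where <- as.integer(names(sums))
    vals[where] <- sums / counts
    mask[where] <- TRUE
  }
  rmsf_map(voxel_grid(vals, grid$voxel_size, grid$origin), mask)
}

#' Average atom values per residue
#'
#' @param atom_values numeric vector, one value per atom of `model`.
#' @param model an [atomic_model].
#' @return Named numeric vector, one value per distinct (chain, residue)
#'   pair in order of first appearance; value = mean over the residue's
#'   atoms.
#' @export
aggregate_to_residues <- function(atom_values, model) {
  stopifnot(is_atomic_model(model), length(atom_values) == n_atoms(model))
  key <- paste(model$atoms$chain, model$atoms$resno, sep = "_")
  ord <- unique(key)
  out <- vapply(split(atom_values, factor(key, levels = ord)), mean, numeric(1))
  out[ord]
}

#' Normalise RMSF values to z-scores
#'
#' Subtracts the mean and divides by the population standard deviation of
#' the model's values (the convention used to colour structures and compare
#' residue profiles across proteins). A constant vector returns all zeros.
#'
#' @param values numeric vector.
#' @return Numeric vector of z-scores.
#' @export
normalize_rmsf <- function(values) {
  if (length(values) < 1L) stop("need at least one value")
  s <- sd_pop(values)
  if (s == 0) return(rep(0, length(values)))
  (values - mean(values)) / s
}
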