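# Synthetic study system: pseudo-proteins, fluctuation ensembles with known
# per-atom amplitudes, heterogeneity-blurred noisy maps, and packaged
# dataset entries. Every stage of the pipeline is testable against closed
# forms: an atom with isotropic per-axis fluctuation sigma has expected
# RMSF sigma * sqrt(3).

#' Synthetic data specification
#'
#' @param n_atoms atoms per pseudo-protein (one pseudo-residue each).
#' @param bond_length fixed step of the self-avoiding walk (3.8 Angstrom,
#'   the C-alpha virtual bond).
#' @param min_dist minimum non-bonded atom distance (Angstrom).
#' @param sigma_min,sigma_max per-axis fluctuation amplitude range
#'   (Angstrom); amplitudes grow with distance from the centroid so the
#'   periphery is the most flexible, as in globular proteins.
#' @param n_frames ensemble frames.
#' @param resolution simulated-map resolution (Angstrom).
#' @param noise map noise level as a fraction of the noise-free maximum.
#' @param voxel_size map voxel size (Angstrom).
#' @param margin map margin around the ensemble bounding box (voxels).
#' @param seed generation seed.
#' @return Object of class `synthetic_spec`.
#' @export
synthetic_spec <- function(n_atoms = 300L, bond_length = 3.8, min_dist = 3.0,
                           sigma_min = 0.3, sigma_max = 1.2, n_frames = 300L,
                           resolution = 5.0, noise = 0.05, voxel_size = 1.5,
                           margin = 10L, seed = 1L) {
  stopifnot(n_atoms >= 1, bond_length > 0, min_dist > 0,
            sigma_min <= sigma_max, sigma_min >= 0, n_frames >= 2,
            noise >= 0, resolution > 0)
  structure(list(n_atoms = as.integer(n_atoms), bond_length = bond_length,
                 min_dist = min_dist, sigma_min = sigma_min,
                 sigma_max = sigma_max, n_frames = as.integer(n_frames),
                 resolution = resolution, noise = noise,
                 voxel_size = voxel_size, margin = as.integer(margin),
                 seed = as.integer(seed)),
            class = "synthetic_spec")
}

#' Generate a pseudo-protein
#'
#' A self-avoiding random walk with fixed `bond_length` steps, confined to
#' a sphere sized from the atom count (packing fraction ~0.25) so the chain
#' stays globular; one chain, one pseudo-residue (carbon) per atom.
#' Reproducible given the spec seed.
#'
#' @param spec a [synthetic_spec].
#' @return An [atomic_model].
#' @export
generate_pseudo_protein <- function(spec = synthetic_spec()) {
  set.seed(spec$seed)
  n <- spec$n_atoms
  radius <- max(2 * spec$min_dist,
                (spec$min_dist / 2) * (n / 0.15)^(1 / 3))
  for (attempt in 1:25) {
    coords <- matrix(NA_real_, n, 3)
    coords[1, ] <- c(0, 0, 0)
    i <- 1L
    budget <- 400L * n      # total placement attempts before a full restart
    while (i < n && budget > 0L) {
      placed <- FALSE
      for (try in 1:60) {
        budget <- budget - 1L
        dir <- rnorm(3)
        dir <- dir / sqrt(sum(dir^2))
        cand <- coords[i, ] + spec$bond_length * dir
        if (sum(cand^2) > radius^2) next
        if (i > 1) {
          d2 <- rowSums(sweep(coords[seq_len(i - 1), , drop = FALSE], 2, cand)^2)
          if (min(d2) < spec$min_dist^2) next
        }
        coords[i + 1, ] <- cand
        i <- i + 1L
        placed <- TRUE
        break
      }
      if (!placed) {
        # dead end: backtrack a few steps and regrow
        drop <- min(i - 1L, 5L)
        if (drop > 0L) {
          coords[(i - drop + 1L):i, ] <- NA_real_
          i <- i - drop
        }
      }
    }
    if (i == n) {
      return(atomic_model(data.frame(
        element = "C", mass = ATOMIC_MASSES[["C"]],
        x = coords[, 1], y = coords[, 2], z = coords[, 3],
        resno = seq_len(n), chain = "A", stringsAsFactors = FALSE)))
    }
  }
  stop("self-avoiding walk failed after bounded retries; relax the spec")
}

#' Generate a fluctuation ensemble with known amplitudes
#'
#' Per-atom per-axis amplitude `sigma_i = sigma_min + (sigma_max -
#' sigma_min) * d_i / max(d)` where `d_i` is the atom's distance from the
#' structure centroid (periphery more flexible). Frames are the mean
#' structure plus i.i.d. isotropic Gaussian displacements, so the expected
#' RMSF of atom i is `sigma_i * sqrt(3)`. Uses the current RNG state.
#'
#' @param model an [atomic_model] (the mean structure).
#' @param spec a [synthetic_spec].
#' @return List with `ensemble` (a [conformation_ensemble]) and `sigma`
#'   (true per-atom amplitudes).
#' @export
generate_ensemble <- function(model, spec = synthetic_spec()) {
  stopifnot(is_atomic_model(model))
  xyz <- coords_matrix(model)
  d <- sqrt(rowSums(sweep(xyz, 2, colMeans(xyz))^2))
  dmax <- max(d, 1e-12)
  sigma <- spec$sigma_min + (spec$sigma_max - spec$sigma_min) * d / dmax
  n <- nrow(xyz)
  frames <- array(0, dim = c(n, 3, spec$n_frames))
  for (f in seq_len(spec$n_frames)) {
    frames[, , f] <- xyz + matrix(rnorm(3 * n), n, 3) * sigma
  }
  list(ensemble = conformation_ensemble(frames), sigma = sigma)
}

#' Generate a heterogeneity-blurred noisy map from an ensemble
#'
#' The map is the mean over frames of each frame's simulated density plus
#' white Gaussian noise with standard deviation `noise * max(clean map)` -
#' emulating a reconstruction that averages many instantaneous
#' conformations, so flexible regions are blurred (lower, wider peaks).
#' The grid encloses all frames with `margin` voxels of padding. Uses the
#' current RNG state.
#'
#' @param ensemble a [conformation_ensemble].
#' @param spec a [synthetic_spec].
#' @param masses per-atom masses (default: carbon).
#' @return A [voxel_grid].
#' @export
generate_heterogeneous_map <- function(ensemble, spec = synthetic_spec(),
                                       masses = NULL) {
  stopifnot(inherits(ensemble, "conformation_ensemble"))
  fr <- ensemble$frames
  n <- dim(fr)[1]; nf <- dim(fr)[3]
  if (is.null(masses)) masses <- rep(ATOMIC_MASSES[["C"]], n)
  all_xy <- matrix(aperm(fr, c(1, 3, 2)), ncol = 3)
  grid <- bounding_grid(all_xy, spec$voxel_size, spec$margin)
  sigma <- 0.225 * spec$resolution
  acc <- array(0, dim = dim(grid$values))
  for (f in seq_len(nf)) {
    acc <- acc + array(
      .cpp_simulate_density(fr[, , f], masses, as.integer(dim(acc)),
                            grid$voxel_size, grid$origin, sigma),
      dim = dim(acc))
  }
  acc <- acc / nf
  if (spec$noise > 0) {
    acc <- acc + rnorm(length(acc), sd = spec$noise * max(acc))
  }
  voxel_grid(acc, grid$voxel_size, grid$origin)
}

#' Generate a packaged synthetic dataset
#'
#' Each entry holds a cryo-like heterogeneity-blurred noisy map, the mean
#' atomic model, the simulated (noise-free, single-conformation) map on the
#' same grid, the ensemble-derived RMSF ground truth projected onto voxels
#' and residues, and the true amplitudes. Entries are generated with
#' derived per-entry seeds recorded in the manifest, so any entry can be
#' regenerated bit-identically.
#'
#' @param n_entries number of entries.
#' @param template a [synthetic_spec]; its seed is replaced per entry.
#' @param seed dataset seed.
#' @return List with `entries` (list) and `manifest` (data frame).
#' @export
make_dataset <- function(n_entries, template = synthetic_spec(), seed = 1L) {
  stopifnot(n_entries >= 1)
  entries <- vector("list", n_entries)
  man <- vector("list", n_entries)
  for (i in seq_len(n_entries)) {
    entry_seed <- (seed * 1009L + i * 7919L) %% 2147483647L
    entries[[i]] <- make_entry(template, entry_seed, id = sprintf("synth%03d", i))
    man[[i]] <- data.frame(id = entries[[i]]$id, seed = entry_seed,
                           n_atoms = template$n_atoms,
                           n_frames = template$n_frames,
                           resolution = template$resolution,
                           noise = template$noise,
                           stringsAsFactors = FALSE)
  }
  list(entries = entries, manifest = do.call(rbind, man))
}

make_entry <- function(template, entry_seed, id = "synth") {
  spec <- template
  spec$seed <- entry_seed
  model <- generate_pseudo_protein(spec)     # seeds the RNG
  ens <- generate_ensemble(model, spec)
  map <- generate_heterogeneous_map(ens$ensemble, spec, model$atoms$mass)
  sim <- simulate_density(model, map, spec$resolution)
  profile <- ensemble_rmsf(ens$ensemble)
  truth <- rmsf_to_voxels(profile, model, map)
  residue <- aggregate_to_residues(profile, model)
  list(id = id, seed = entry_seed, spec = spec, map = map, sim_map = sim,
       model = model, sigma = ens$sigma, atom_rmsf = profile,
       rmsf_map = truth, residue_rmsf = residue)
}

#' Build training sample boxes from a dataset entry
#'
#' Assembles the variant's input channels from the entry's maps, attaches
#' the RMSF labels (and, for the occupancy classifier, the occupancy
#' ground-truth boxes) and segments into screened boxes.
#'
#' @param entry an entry from [make_dataset].
#' @param variant network variant (see [network_config]).
#' @param spec a [box_spec].
#' @return List of `sample_box`es.
#' @export
prepare_samples <- function(entry, variant = "dual", spec = box_spec()) {
  channels <- variant_channels_for(variant, entry$map, entry$sim_map)
  occ <- NULL
  if (variant == "occ") {
    occ <- occupancy_annotation(entry$model, entry$map)
  }
  segment_boxes(channels, labels = entry$rmsf_map, occupancy = occ,
                spec = spec)
}

#' Write a dataset entry to disk
#'
#' Maps as MRC2014, the model as PDB, per-atom truth as a two-column text
#' table, and the entry spec as a manifest row.
#'
#' @param entry an entry from [make_dataset].
#' @param dir output directory (created if needed).
#' @return Invisibly, the directory.
#' @export
write_entry <- function(entry, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  write_density_map(entry$map, file.path(dir, "map.mrc"))
  write_density_map(entry$sim_map, file.path(dir, "sim_map.mrc"))
  write_model_bfactor(entry$model, entry$atom_rmsf, file.path(dir, "model.pdb"))
  utils::write.table(
    data.frame(atom = seq_along(entry$atom_rmsf), rmsf = entry$atom_rmsf),
    file.path(dir, "atom_rmsf.tsv"), sep = "\t", row.names = FALSE,
    quote = FALSE)
  jsonlite::write_json(
    list(id = entry$id, seed = entry$seed,
         spec = unclass(entry$spec)),
    file.path(dir, "entry.json"), auto_unbox = TRUE)
  invisible(dir)
}
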