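# Synthetic generator: pseudo-proteins, ensembles with known amplitudes,
# heterogeneity-blurred maps, packaged entries.

test_that("pseudo-protein walks honour bond length, self-avoidance and seed", {
  m <- generate_pseudo_protein(small_spec(seed = 2))
  co <- as.matrix(m$atoms[, c("x", "y", "z")])
  steps <- sqrt(rowSums(diff(co)^2))
  expect_lt(max(abs(steps - 3.8)), 1e-9)
  dmat <- as.matrix(dist(co))
  diag(dmat) <- Inf
  # non-bonded minimum distance (bonded pairs are at 3.8 > 3.0 anyway)
  expect_gte(min(dmat), 3.0 - 1e-9)
  m2 <- generate_pseudo_protein(small_spec(seed = 2))
  expect_identical(m$atoms, m2$atoms)
  single <- generate_pseudo_protein(synthetic_spec(n_atoms = 1))
  expect_equal(n_atoms(single), 1)
  expect_equal(unlist(single$atoms[1, c("x", "y", "z")], use.names = FALSE),
               c(0, 0, 0))
})

test_that("ensembles have centroid-graded amplitudes with sigma*sqrt(3) RMSF", {
  spec <- small_spec(n_frames = 500L, seed = 3)
  model <- generate_pseudo_protein(spec)
  ens <- generate_ensemble(model, spec)
  co <- as.matrix(model$atoms[, c("x", "y", "z")])
  d <- sqrt(rowSums(sweep(co, 2, colMeans(co))^2))
  want_sigma <- spec$sigma_min + (spec$sigma_max - spec$sigma_min) * d / max(d)
  expect_equal(ens$sigma, want_sigma, tolerance = 1e-12)
  # per-atom sample std (pooled over the 3 axes) recovers sigma within 10%
  mean_xyz <- apply(ens$ensemble$frames, c(1, 2), mean)
  dev <- sweep(ens$ensemble$frames, c(1, 2), mean_xyz)
  pooled_sd <- sqrt(apply(dev^2, 1, mean))
  expect_lt(max(abs(pooled_sd - ens$sigma) / ens$sigma), 0.10)
  r <- ensemble_rmsf(ens$ensemble)
  rel <- abs(r - ens$sigma * sqrt(3)) / (ens$sigma * sqrt(3))
  expect_lt(mean(rel), 0.05)
  # zero amplitude: all frames identical
  z <- generate_ensemble(model, small_spec(sigma_min = 0, sigma_max = 0))
  expect_identical(z$ensemble$frames[, , 1], z$ensemble$frames[, , 5])
})

test_that("a degenerate ensemble map equals the simulated mean-model map", {
  spec <- small_spec(n_atoms = 25L, n_frames = 5L, sigma_min = 0,
                     sigma_max = 0, noise = 0, seed = 4)
  model <- generate_pseudo_protein(spec)
  ens <- generate_ensemble(model, spec)
  map <- generate_heterogeneous_map(ens$ensemble, spec, model$atoms$mass)
  sim <- simulate_density(model, map, spec$resolution)
  expect_lt(max(abs(map$values - sim$values)), 1e-6)
})

test_that("flexible atoms are blurred: lower peak than rigid atoms", {
  # two equal-mass atoms far apart; one rigid, one jittering
  nf <- 200
  set.seed(5)
  frames <- array(0, dim = c(2, 3, nf))
  frames[1, , ] <- c(0, 0, 0)
  frames[2, 1, ] <- 20 + rnorm(nf, sd = 1.2)
  frames[2, 2, ] <- rnorm(nf, sd = 1.2)
  frames[2, 3, ] <- rnorm(nf, sd = 1.2)
  spec <- small_spec(noise = 0)
  map <- generate_heterogeneous_map(conformation_ensemble(frames), spec)
  # oracle: direct frame-averaged peak comparison at the two atom sites
  i1 <- world_to_voxel(map, c(0, 0, 0))
  i2 <- world_to_voxel(map, c(20, 0, 0))
  expect_gt(voxel_value(map, i1), voxel_value(map, i2))
})

test_that("map generation is seed-reproducible", {
  spec <- small_spec(n_atoms = 20L, n_frames = 10L, seed = 6)
  e1 <- voxflex:::make_entry(spec, 123L)
  e2 <- voxflex:::make_entry(spec, 123L)
  expect_identical(e1$map$values, e2$map$values)
  expect_identical(e1$atom_rmsf, e2$atom_rmsf)
})

test_that("blur carries the flexibility signal: density anti-correlates with sigma", {
  spec <- small_spec(seed = 7)
  model <- generate_pseudo_protein(spec)
  ens <- generate_ensemble(model, spec)
  map <- generate_heterogeneous_map(ens$ensemble, spec, model$atoms$mass)
  co <- as.matrix(model$atoms[, c("x", "y", "z")])
  dens_at_atom <- voxel_value(map, world_to_voxel(map, co))
  rho <- cor(ens$sigma, dens_at_atom, method = "spearman")
  expect_lt(rho, 0)
})

test_that("packaged entries are complete, regenerable and well-fitting", {
  ds <- make_dataset(3, small_spec(), seed = 11)
  expect_length(ds$entries, 3)
  expect_equal(nrow(ds$manifest), 3)
  for (e in ds$entries) {
    expect_true(sum(e$rmsf_map$mask) > 0)
    expect_true(all(dim(e$map$values) <= 64))
    expect_identical(dim(e$sim_map$values), dim(e$map$values))
    expect_length(e$atom_rmsf, n_atoms(e$model))
    # screening criterion: simulated mean-model map fits the blurred map
    expect_gt(map_model_fitness(e$sim_map, e$map), 0.7)
  }
  # regeneration from the manifest seed is bit-identical
  re <- voxflex:::make_entry(small_spec(), ds$manifest$seed[2],
                             id = ds$entries[[2]]$id)
  expect_identical(re$map$values, ds$entries[[2]]$map$values)
  expect_identical(re$rmsf_map$values$values, ds$entries[[2]]$rmsf_map$values$values)
})

test_that("prepare_samples builds screened labelled boxes per variant", {
  ds <- make_dataset(1, small_spec(n_atoms = 40L, n_frames = 20L), seed = 12)
  e <- ds$entries[[1]]
  dual <- prepare_samples(e, "dual")
  expect_gt(length(dual), 0)
  expect_identical(dim(dual[[1]]$channels)[4], 2L)
  expect_true(all(vapply(dual, function(b) any(b$mask), logical(1))))
  occ <- prepare_samples(e, "occ")
  expect_identical(dim(occ[[1]]$channels)[4], 1L)
  expect_false(is.null(occ[[1]]$occ))
  expect_true(all(occ[[1]]$occ %in% c(0, 1)))
  pdb01 <- prepare_samples(e, "pdb01")
  expect_identical(dim(pdb01[[1]]$channels)[4], 2L)
})
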