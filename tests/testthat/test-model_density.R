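# Model parsing, simulated density, thresholding, occupancy and fitness.

test_that("a hand-written PDB fixture parses to heavy atoms only", {
  path <- write_pdb_fixture()
  m <- read_atomic_model(path)
  expect_equal(n_atoms(m), 9)            # hydrogen and water dropped
  expect_equal(n_residues(m), 3)
  expect_true(all(m$atoms$chain == "A"))
  expect_equal(m$atoms$element[1:3], c("N", "C", "C"))
  expect_equal(m$atoms$mass[2], 12.011)
  unlink(path)
})

test_that("a file with only waters errors as an empty model", {
  path <- write_pdb_fixture(c(
    "HETATM    1  O   HOH A   1       0.000   0.000   0.000  1.00  0.00           O",
    "END"))
  expect_error(read_atomic_model(path), "no heavy protein atoms")
  unlink(path)
})

test_that("multi-model files yield the first model", {
  lines <- c("MODEL        1", PDB_3RES[1:10], "ENDMDL",
             "MODEL        2",
             sub("0.000   0.000   0.000", "9.000   9.000   9.000", PDB_3RES[1:10]),
             "ENDMDL", "END")
  path <- write_pdb_fixture(lines)
  m <- read_atomic_model(path)
  expect_equal(n_atoms(m), 9)
  expect_equal(m$atoms$x[1], 0)
  unlink(path)
})

test_that("a single atom at a voxel centre gives a symmetric peak there", {
  g <- voxel_grid(array(0, c(15, 15, 15)), 1.5)
  m <- toy_model(matrix(c(7, 7, 7) * 1.5, 1))   # voxel (7,7,7) centre
  sim <- simulate_density(m, g, resolution = 5)
  peak <- which(sim$values == max(sim$values), arr.ind = TRUE)
  expect_equal(unname(peak[1, ]), c(8, 8, 8))
  # reflection symmetry about the peak
  expect_equal(sim$values[8 + 3, 8, 8], sim$values[8 - 3, 8, 8], tolerance = 1e-12)
  expect_equal(sim$values[8, 8 + 2, 8 - 1], sim$values[8, 8 - 2, 8 + 1],
               tolerance = 1e-12)
})

test_that("well-separated atoms reproduce the brute-force per-voxel sum", {
  g <- voxel_grid(array(0, c(30, 12, 12)), 1.5)
  coords <- rbind(c(6, 8, 8), c(37.5, 8, 8))    # voxel centres, > 8 sd apart
  m <- toy_model(coords)
  sim <- simulate_density(m, g, resolution = 5)
  # independent dense double loop (no truncation)
  sigma <- 0.225 * 5
  want <- array(0, dim = dim(g$values))
  cx <- (0:29) * 1.5; cy <- (0:11) * 1.5
  for (a in 1:2) for (i in 1:30) for (j in 1:12) for (k in 1:12) {
    r2 <- (cx[i] - coords[a, 1])^2 + (cy[j] - coords[a, 2])^2 + (cy[k] - coords[a, 3])^2
    if (r2 <= (4 * sigma)^2)
      want[i, j, k] <- want[i, j, k] + 12.011 * exp(-r2 / (2 * sigma^2))
  }
  expect_lt(max(abs(sim$values - want)), 1e-9)
  # two equal local maxima matching the single-atom peak
  half1 <- max(sim$values[1:15, , ]); half2 <- max(sim$values[16:30, , ])
  single <- simulate_density(toy_model(coords[1, , drop = FALSE]), g, 5)
  expect_equal(half1, half2, tolerance = 1e-6)
  expect_equal(half1, max(single$values), tolerance = 1e-6)
})

test_that("total simulated density matches the analytic Gaussian integral", {
  g <- voxel_grid(array(0, c(24, 24, 24)), 1.0)
  m <- toy_model(rbind(c(12, 12, 12), c(9, 14, 12)))
  res <- 4
  sim <- simulate_density(m, g, resolution = res)
  sigma <- 0.225 * res
  total <- sum(sim$values) * 1.0^3
  want <- 2 * 12.011 * (2 * pi * sigma^2)^(3 / 2)
  expect_lt(abs(total - want) / want, 0.02)
})

test_that("simulated density is linear in the atom list and translation-covariant", {
  g <- voxel_grid(array(0, c(16, 16, 16)), 1.5)
  set.seed(3)
  ca <- matrix(runif(9, 6, 18), 3)
  cb <- matrix(runif(6, 6, 18), 2)
  sa <- simulate_density(toy_model(ca), g, 5)
  sb <- simulate_density(toy_model(cb), g, 5)
  sab <- simulate_density(toy_model(rbind(ca, cb)), g, 5)
  expect_lt(max(abs(sab$values - (sa$values + sb$values))), 1e-6)
  shift <- c(4.5, -3, 7.5)
  g2 <- voxel_grid(g$values, g$voxel_size, g$origin + shift)
  s2 <- simulate_density(toy_model(sweep(ca, 2, shift, "+")), g2, 5)
  expect_lt(max(abs(s2$values - sa$values)), 1e-9)
})

sd_pop_ref <- function(x) sqrt(mean((x - mean(x))^2))

test_that("3-sigma thresholding matches brute force and handles degeneracy", {
  z <- voxel_grid(array(0, c(5, 5, 5)), 1.5)
  bz <- binarize_simulated_map(z)
  expect_true(all(bz$grid$values == 0))
  vals <- array(0, c(10, 10, 10)); vals[777] <- 10
  g <- voxel_grid(vals, 1.5)
  b <- binarize_simulated_map(g)
  v <- as.numeric(vals)
  sig <- sqrt(mean((v - mean(v))^2))
  expect_equal(b$stats$sigma, sig)
  expect_identical(which(b$grid$values == 1), 777L)
  expect_true(all(b$grid$values %in% c(0, 1)))
  # positive count is non-increasing in the threshold multiplier
  set.seed(4)
  r <- voxel_grid(array(rexp(1000), c(10, 10, 10)), 1.5)
  counts <- sapply(c(1, 2, 3, 4), function(k)
    sum(r$values > k * sd_pop_ref(as.numeric(r$values))))
  expect_true(all(diff(counts) <= 0))
})

test_that("one-hot encoding partitions unity and round-trips", {
  set.seed(5)
  b <- voxel_grid(array(as.numeric(runif(216) < 0.4), c(6, 6, 6)), 1.5)
  oh <- one_hot_encode(b)
  expect_true(all(oh$ch0$values + oh$ch1$values == 1))
  expect_identical(one_hot_decode(oh)$values, b$values)
  ones <- voxel_grid(array(1, c(3, 3, 3)), 1.5)
  oh1 <- one_hot_encode(ones)
  expect_true(all(oh1$ch1$values == 1) && all(oh1$ch0$values == 0))
  expect_error(one_hot_encode(rand_grid()), "binary")
})

test_that("occupancy annotation marks nearest voxels, idempotently", {
  g <- voxel_grid(array(0, c(12, 12, 12)), 1.5)
  one <- occupancy_annotation(toy_model(matrix(c(6, 6, 6) * 1.5, 1)), g)
  expect_equal(sum(one$values), 1)
  expect_equal(one$values[7, 7, 7], 1)
  two <- occupancy_annotation(
    toy_model(rbind(c(9, 9, 9), c(9.3, 9.2, 8.9))), g)
  expect_equal(sum(two$values), 1)   # same nearest voxel
  set.seed(6)
  coords <- matrix(runif(60, 2, 15), 20)
  occ <- occupancy_annotation(toy_model(coords), g)
  want <- array(0, dim = dim(g$values))
  for (a in 1:20) {
    i <- floor(coords[a, ] / 1.5 + 0.5)
    want[i[1] + 1, i[2] + 1, i[3] + 1] <- 1
  }
  expect_identical(occ$values, want)
})

test_that("map-model fitness is Pearson correlation with its edge cases", {
  set.seed(7)
  a <- rand_grid(c(6, 6, 6), seed = 7)
  expect_equal(map_model_fitness(a, a), 1.0)
  neg <- voxel_grid(-a$values, a$voxel_size, a$origin)
  expect_equal(map_model_fitness(a, neg), -1.0)
  noisy <- voxel_grid(a$values + array(rnorm(216, sd = 0.3), dim = c(6, 6, 6)),
                      1.5)
  x <- as.numeric(a$values); y <- as.numeric(noisy$values)
  want <- sum((x - mean(x)) * (y - mean(y))) /
    sqrt(sum((x - mean(x))^2) * sum((y - mean(y))^2))
  expect_equal(map_model_fitness(a, noisy), want, tolerance = 1e-12)
  expect_error(map_model_fitness(a, rand_grid(c(5, 6, 6))), "shape")
  expect_error(map_model_fitness(a, voxel_grid(array(1, c(6, 6, 6)), 1.5)),
               "variance")
})
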