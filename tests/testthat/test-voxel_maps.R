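# Map I/O, resampling and voxel indexing.

test_that("write/read round trip preserves shape, voxel size, origin and values", {
  for (g in list(rand_grid(c(8, 8, 8)),
                 rand_grid(c(5, 7, 9), voxel = 1.1, origin = c(-3, 2.5, 10), seed = 2),
                 voxel_grid(array(0, c(8, 8, 8)), 1.5),
                 voxel_grid(array(4.2, c(1, 1, 1)), 2.0, c(1, 2, 3)))) {
    path <- tempfile(fileext = ".mrc")
    write_density_map(g, path)
    g2 <- read_density_map(path)
    expect_identical(dim(g2$values), dim(g$values))
    expect_equal(g2$voxel_size, g$voxel_size, tolerance = 1e-6)
    expect_equal(g2$origin, g$origin, tolerance = 1e-5)
    expect_equal(g2$values, g$values, tolerance = 1e-6)  # float32 round trip
    unlink(path)
  }
})

test_that("written header records the voxel size and mode 2", {
  g <- voxel_grid(array(1.5, c(4, 4, 4)), 1.5)
  path <- tempfile(fileext = ".mrc")
  write_density_map(g, path)
  con <- file(path, "rb")
  hdr_int <- readBin(con, "integer", 10, size = 4, endian = "little")
  cella <- readBin(con, "numeric", 3, size = 4, endian = "little")
  close(con)
  expect_identical(hdr_int[4], 2L)                       # mode
  expect_equal(cella / hdr_int[8:10], rep(1.5, 3), tolerance = 1e-6)
  unlink(path)
})

test_that("permuted axis-order headers are normalised to x,y,z", {
  # 8^3 volume stored with columns along world y, rows along world x
  # (mapc=2, mapr=1, maps=3); one marked voxel at world index (2,3,4),
  # i.e. data index (col=3, row=2, sec=4) applying the header spec by hand
  d <- c(8L, 8L, 8L)
  a <- array(0, dim = d)
  a[3 + 1, 2 + 1, 4 + 1] <- 7   # (col, row, sec), 0-based (3, 2, 4)
  path <- tempfile(fileext = ".mrc")
  con <- file(path, "wb")
  writeBin(d, con, size = 4, endian = "little")
  writeBin(2L, con, size = 4, endian = "little")
  writeBin(c(2L, 0L, 0L), con, size = 4, endian = "little")  # col start = 2
  writeBin(d, con, size = 4, endian = "little")
  writeBin(d * 1.5, con, size = 4, endian = "little")
  writeBin(c(90, 90, 90), con, size = 4, endian = "little")
  writeBin(c(2L, 1L, 3L), con, size = 4, endian = "little")  # mapc mapr maps
  writeBin(c(0, 7, 0.01), con, size = 4, endian = "little")
  writeBin(c(1L, 0L), con, size = 4, endian = "little")
  writeBin(raw(100), con)
  writeBin(c(0, 0, 0), con, size = 4, endian = "little")     # no origin record
  writeBin(charToRaw("MAP "), con)
  writeBin(as.raw(c(0x44, 0x41, 0, 0)), con)
  writeBin(0.01, con, size = 4, endian = "little")
  writeBin(0L, con, size = 4, endian = "little")
  writeBin(raw(800), con)
  writeBin(as.numeric(a), con, size = 4, endian = "little")
  close(con)
  g <- read_density_map(path)
  expect_equal(g$values[2 + 1, 3 + 1, 4 + 1], 7)
  expect_equal(sum(g$values != 0), 1)
  # column start index 2 lies on world axis y
  expect_equal(g$origin, c(0, 2 * 1.5, 0))
  unlink(path)
})

test_that("reading a nonexistent or malformed file errors", {
  expect_error(read_density_map(tempfile()), "not found")
  bad <- tempfile()
  writeBin(as.integer(c(-5, 8, 8, 2)), bad, size = 4)
  expect_error(read_density_map(bad), "header|truncated")
  unlink(bad)
})

test_that("resampling is a no-op at the source voxel size", {
  g <- rand_grid(c(12, 10, 8))
  g2 <- resample_to_voxel_size(g, 1.5)
  expect_identical(g2$values, g$values)
})

test_that("resampling preserves constant fields and applies shape arithmetic", {
  g <- voxel_grid(array(2.7, c(30, 30, 30)), 1.0)
  g2 <- resample_to_voxel_size(g, 1.5)
  expect_identical(dim(g2$values), c(20L, 20L, 20L))   # 30 * (1.0 / 1.5)
  expect_lt(max(abs(g2$values - 2.7)), 1e-6)
  expect_equal(g2$voxel_size, 1.5)
  expect_equal(g2$origin, g$origin)
  # upsampling too
  g3 <- resample_to_voxel_size(voxel_grid(array(-1.3, c(8, 8, 8)), 3.0), 1.5)
  expect_identical(dim(g3$values), c(16L, 16L, 16L))
  expect_lt(max(abs(g3$values + 1.3)), 1e-6)
})

test_that("resampling a smooth field approximates the underlying function", {
  d <- c(24, 24, 24)
  f <- function(x, y, z) sin(x / 4) * cos(y / 5) + z / 20
  idx <- expand.grid(x = 0:23, y = 0:23, z = 0:23)
  g <- voxel_grid(array(f(idx$x, idx$y, idx$z), dim = d), 1.0)
  g2 <- resample_to_voxel_size(g, 2.0)
  idx2 <- expand.grid(x = 0:11, y = 0:11, z = 0:11)
  want <- array(f(idx2$x * 2, idx2$y * 2, idx2$z * 2), dim = c(12, 12, 12))
  expect_lt(max(abs(g2$values - want)), 0.02)
})

test_that("non-positive target voxel size errors", {
  expect_error(resample_to_voxel_size(rand_grid(), 0), "positive")
  expect_error(resample_to_voxel_size(rand_grid(), -1.5), "positive")
})

test_that("world_to_voxel implements nearest-voxel-centre indexing", {
  g <- voxel_grid(array(0, c(10, 10, 10)), 1.5, c(0, 0, 0))
  expect_identical(world_to_voxel(g, c(0, 0, 0)), c(0L, 0L, 0L))
  expect_identical(world_to_voxel(g, c(3.0, 0.1, 4.4)), c(2L, 0L, 3L))
  expect_true(all(is.na(world_to_voxel(g, c(1000, 0, 0)))))
  expect_true(all(is.na(world_to_voxel(g, c(-10, 0, 0)))))
})

test_that("world_to_voxel inverts voxel centres over the whole grid", {
  g <- voxel_grid(array(0, c(6, 5, 4)), 0.8, c(-2, 3, 0.5))
  idx <- as.matrix(expand.grid(0:5, 0:4, 0:3))
  centres <- sweep(idx * g$voxel_size, 2, g$origin, "+")
  got <- world_to_voxel(g, centres)
  expect_identical(unname(got), unname(idx) + 0L)
})

test_that("grid invariants are enforced", {
  expect_error(voxel_grid(array(0, c(2, 2)), 1), "3D")
  expect_error(voxel_grid(array(NA_real_, c(2, 2, 2)), 1), "finite")
  expect_error(voxel_grid(array(0, c(2, 2, 2)), -1), "positive")
})
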