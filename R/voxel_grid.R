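#' Construct a voxel grid
#'
#' A `voxel_grid` is a 3D scalar field (density in map units, probability, or
#' RMSF in Angstrom) with an isotropic physical voxel size and a world origin.
#' The origin is the world coordinate (Angstrom) of the *centre* of voxel
#' (0,0,0); voxel indices are 0-based throughout.
#'
#' @param values 3D numeric array (x, y, z ascending).
#' @param voxel_size voxel edge length in Angstrom (> 0).
#' @param origin length-3 numeric, world coordinate of voxel (0,0,0).
#' @return An object of class `voxel_grid`.
#' @export
voxel_grid <- function(values, voxel_size, origin = c(0, 0, 0)) {
  values <- as.array(values)
  if (length(dim(values)) != 3L) stop("values must be a 3D array")
  if (any(dim(values) < 1L)) stop("all grid dimensions must be >= 1")
  if (!is.numeric(voxel_size) || length(voxel_size) != 1L || voxel_size <= 0)
    stop("voxel_size must be a single positive number")
  if (length(origin) != 3L || !all(is.finite(origin)))
    stop("origin must be a finite 3-vector")
  if (!all(is.finite(values))) stop("grid values must be finite")
  structure(
    list(values = values, voxel_size = as.numeric(voxel_size),
         origin = as.numeric(origin)),
    class = "voxel_grid")
}

#' @export
print.voxel_grid <- function(x, ...) {
  d <- dim(x$values)
  cat(sprintf("<voxel_grid> %d x %d x %d voxels, %.3f A/voxel, origin (%.2f, %.2f, %.2f)\n",
              d[1], d[2], d[3], x$voxel_size, x$origin[1], x$origin[2], x$origin[3]))
  cat(sprintf("  values in [%.4g, %.4g]\n", min(x$values), max(x$values)))
  invisible(x)
}

is_voxel_grid <- function(x) inherits(x, "voxel_grid")

# ---------------------------------------------------------------- MRC I/O

#' Read a density map in MRC2014/CCP4 format
#'
#' Axis order is normalised to (x, y, z) regardless of the header's axis
#' correspondence fields (MAPC/MAPR/MAPS). The world origin is taken from the
#' ORIGIN header record if any component is non-zero, otherwise from the
#' start indices times the voxel size (the two dialects found in EMDB
#' deposits). Data modes 0 (int8), 1 (int16), 2 (float32) and 6 (uint16) are
#' supported.
#'
#' @param path path to an MRC/CCP4 volume.
#' @return A [voxel_grid].
#' @export
read_density_map <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  con <- file(path, "rb")
  on.exit(close(con))
  nxyz <- readBin(con, "integer", 3, size = 4, endian = "little")
  mode <- readBin(con, "integer", 1, size = 4, endian = "little")
  nstart <- readBin(con, "integer", 3, size = 4, endian = "little")
  m <- readBin(con, "integer", 3, size = 4, endian = "little")
  cella <- readBin(con, "numeric", 3, size = 4, endian = "little")
  readBin(con, "numeric", 3, size = 4, endian = "little")  # cell angles
  mapcrs <- readBin(con, "integer", 3, size = 4, endian = "little")
  readBin(con, "numeric", 3, size = 4, endian = "little")  # dmin dmax dmean
  readBin(con, "integer", 1, size = 4, endian = "little")  # ispg
  nsymbt <- readBin(con, "integer", 1, size = 4, endian = "little")
  readBin(con, "raw", 100)                                 # extra words 25-49
  org <- readBin(con, "numeric", 3, size = 4, endian = "little")
  readBin(con, "raw", 4)                                   # 'MAP '
  readBin(con, "raw", 4)                                   # machine stamp
  readBin(con, "numeric", 1, size = 4, endian = "little")  # rms
  readBin(con, "raw", 4 + 800)                             # nlabl + labels
  if (any(nxyz < 1L) || any(!is.finite(nxyz)))
    stop("invalid MRC header: bad dimensions")
  if (!setequal(mapcrs, 1:3))
    stop("invalid MRC header: axis correspondence fields are not a permutation of 1:3")
  if (!(mode %in% c(0L, 1L, 2L, 6L)))
    stop("unsupported MRC mode: ", mode)
  if (nsymbt > 0) readBin(con, "raw", nsymbt)
  n <- prod(nxyz)
  vals <- switch(as.character(mode),
    "0" = as.numeric(readBin(con, "integer", n, size = 1, signed = TRUE)),
    "1" = as.numeric(readBin(con, "integer", n, size = 2, signed = TRUE,
                             endian = "little")),
    "2" = readBin(con, "numeric", n, size = 4, endian = "little"),
    "6" = as.numeric(readBin(con, "integer", n, size = 2, signed = FALSE,
                             endian = "little")))
  if (length(vals) != n)
    stop("truncated MRC file: expected ", n, " voxels, read ", length(vals))
  a <- array(vals, dim = nxyz)  # (columns, rows, sections)
  # world axis j is stored along data axis match(j, mapcrs)
  perm <- match(1:3, mapcrs)
  a <- aperm(a, perm)
  # voxel sizes along world axes
  mw <- m; mw[mw == 0L] <- nxyz[mw == 0L]
  vx <- cella / mw
  vx[!is.finite(vx) | vx <= 0] <- 1
  if (max(vx) - min(vx) > 1e-3 * max(vx))
    stop("anisotropic voxel sizes are not supported: ", paste(signif(vx, 5), collapse = ", "))
  voxel_size <- mean(vx)
  if (any(org != 0)) {
    origin <- org
  } else {
    # start indices are recorded per data axis (columns/rows/sections);
    # ns_world[mapcrs] places each one on its world axis
    ns_world <- numeric(3)
    ns_world[mapcrs] <- nstart
    origin <- ns_world * voxel_size
  }
  voxel_grid(a, voxel_size, origin)
}

#' Write a density map as MRC2014 (mode 2, float32)
#'
#' @param grid a [voxel_grid].
#' @param path output path.
#' @return Invisibly, `path`.
#' @export
write_density_map <- function(grid, path) {
  stopifnot(is_voxel_grid(grid))
  con <- tryCatch(file(path, "wb"), error = function(e)
    stop("cannot open for writing: ", path))
  on.exit(close(con))
  d <- dim(grid$values)
  v <- as.numeric(grid$values)
  writeBin(as.integer(d), con, size = 4, endian = "little")          # nx ny nz
  writeBin(2L, con, size = 4, endian = "little")                     # mode
  writeBin(integer(3), con, size = 4, endian = "little")             # nstart
  writeBin(as.integer(d), con, size = 4, endian = "little")          # mx my mz
  writeBin(as.numeric(d) * grid$voxel_size, con, size = 4, endian = "little")
  writeBin(c(90, 90, 90), con, size = 4, endian = "little")          # angles
  writeBin(1:3, con, size = 4, endian = "little")                    # mapc/r/s
  writeBin(c(min(v), max(v), mean(v)), con, size = 4, endian = "little")
  writeBin(c(1L, 0L), con, size = 4, endian = "little")              # ispg, nsymbt
  writeBin(raw(100), con)                                            # extra
  writeBin(as.numeric(grid$origin), con, size = 4, endian = "little")
  writeBin(charToRaw("MAP "), con)
  writeBin(as.raw(c(0x44, 0x41, 0x00, 0x00)), con)                   # little-endian stamp
  writeBin(sd_pop(v), con, size = 4, endian = "little")              # rms
  writeBin(1L, con, size = 4, endian = "little")                     # nlabl
  lab <- sprintf("%-80s", "voxflex")
  writeBin(charToRaw(lab), con)
  writeBin(raw(720), con)
  writeBin(v, con, size = 4, endian = "little")
  invisible(path)
}

sd_pop <- function(x) {
  m <- mean(x)
  sqrt(mean((x - m)^2))
}

# ------------------------------------------------------------- resampling

#' Resample a grid to a target voxel size
#'
#' Cubic B-spline interpolation (with the standard recursive prefilter) on a
#' grid whose output voxel centre `i` lies at input coordinate
#' `i * target / original` along each axis; the world origin is preserved.
#' Output shape is `round(shape * original / target)`. Evaluation outside the
#' input domain is mirror-reflected, so constant fields are preserved exactly.
#'
#' @param grid a [voxel_grid].
#' @param target target voxel size in Angstrom (default 1.5, roughly the
#'   footprint of one heavy atom).
#' @return A [voxel_grid] with `voxel_size == target`.
#' @export
resample_to_voxel_size <- function(grid, target = 1.5) {
  stopifnot(is_voxel_grid(grid))
  if (!is.numeric(target) || length(target) != 1L || target <= 0)
    stop("target voxel size must be a single positive number")
  if (abs(target - grid$voxel_size) < 1e-9) return(grid)
  d <- dim(grid$values)
  out_dim <- pmax(1L, as.integer(round(d * grid$voxel_size / target)))
  ratio <- target / grid$voxel_size
  vals <- .cpp_spline_zoom(as.numeric(grid$values), as.integer(d),
                           out_dim, ratio)
  voxel_grid(array(vals, dim = out_dim), target, grid$origin)
}

# ------------------------------------------------------------- indexing

#' Map a world coordinate to its nearest voxel index
#'
#' Returns the 0-based index triple of the voxel whose centre is nearest to
#' `coord` (`floor((coord - origin)/voxel_size + 0.5)`), or a triple of `NA`
#' if the coordinate falls outside the grid (out-of-bounds is a value, not an
#' error).
#'
#' @param grid a [voxel_grid].
#' @param coord numeric 3-vector (Angstrom), or an n x 3 matrix.
#' @return Integer 3-vector (or n x 3 matrix) of 0-based indices; `NA` marks
#'   out-of-bounds coordinates.
#' @export
world_to_voxel <- function(grid, coord) {
  stopifnot(is_voxel_grid(grid))
  cm <- if (is.matrix(coord)) coord else matrix(coord, nrow = 1)
  if (ncol(cm) != 3L) stop("coord must have 3 columns")
  d <- dim(grid$values)
  idx <- floor(sweep(cm, 2, grid$origin) / grid$voxel_size + 0.5)
  oob <- idx[, 1] < 0 | idx[, 1] > d[1] - 1 |
         idx[, 2] < 0 | idx[, 2] > d[2] - 1 |
         idx[, 3] < 0 | idx[, 3] > d[3] - 1
  idx[oob, ] <- NA_integer_
  storage.mode(idx) <- "integer"
  if (is.matrix(coord)) idx else idx[1, ]
}

#' Value of a grid at a 0-based voxel index
#' @param grid a [voxel_grid].
#' @param idx integer 3-vector or n x 3 matrix of 0-based indices.
#' @return Numeric vector of values (`NA` for `NA` indices).
#' @export
voxel_value <- function(grid, idx) {
  im <- if (is.matrix(idx)) idx else matrix(idx, nrow = 1)
  out <- rep(NA_real_, nrow(im))
  ok <- !is.na(im[, 1])
  if (any(ok)) out[ok] <- grid$values[im[ok, , drop = FALSE] + 1L]
  out
}
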