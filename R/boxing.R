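# Box segmentation, screening, normalisation and merging.
#
# Grids are zero-padded by `pad` voxels per side plus whatever is needed for
# the central subboxes to tile the original grid exactly once (stride ==
# subbox edge), so merging is exact and overlap-free.

#' Box segmentation geometry
#'
#' @param box_edge input box edge in voxels (default 40).
#' @param subbox_edge central subbox edge = stride (default 10).
#' @return Object of class `box_spec` with fields `box_edge`, `stride`,
#'   `subbox_edge`, `pad`.
#' @export
box_spec <- function(box_edge = 40L, subbox_edge = 10L) {
  box_edge <- as.integer(box_edge); subbox_edge <- as.integer(subbox_edge)
  pad <- (box_edge - subbox_edge) / 2L
  if (pad != as.integer(pad) || pad < 0)
    stop("(box_edge - subbox_edge) must be even and non-negative")
  structure(list(box_edge = box_edge, stride = subbox_edge,
                 subbox_edge = subbox_edge, pad = as.integer(pad)),
            class = "box_spec")
}

pad_to_tiles <- function(values, spec) {
  d <- dim(values)
  tiles <- ceiling(d / spec$stride)
  full <- tiles * spec$stride + 2L * spec$pad
  out <- array(0, dim = full)
  out[spec$pad + seq_len(d[1]), spec$pad + seq_len(d[2]), spec$pad + seq_len(d[3])] <- values
  out
}

#' Normalise a density box to [0, 1]
#'
#' Negative densities are set to zero, then the box is divided by its
#' maximum; an all-non-positive box becomes all zeros. Mitigates density
#' scale variation across maps.
#'
#' @param box numeric array.
#' @return Array of the same shape with values in `[0, 1]`.
#' @export
normalize_box <- function(box) {
  box[box < 0] <- 0
  m <- max(box)
  if (m > 0) box <- box / m
  box
}

#' Segment grids into screened, normalised sample boxes
#'
#' Places `box_edge`^3 boxes at every `stride` offset of the padded grid so
#' that the central subboxes tile the original grid exactly once. A box is
#' retained iff its central subbox contains at least one masked voxel: the
#' label mask during training, or an occupancy mask (e.g. from
#' [occupancy_annotation]) at inference. Channel boxes are normalised with
#' [normalize_box]. Boxes are enumerated in ascending (z, y, x) tile order.
#'
#' @param channels list of [voxel_grid]s sharing one shape/frame (the input
#'   channels, e.g. experimental map and simulated map).
#' @param labels an [rmsf_map] for training, or `NULL` at inference.
#' @param mask screening mask when `labels` is `NULL`: a binary
#'   [voxel_grid] or logical array.
#' @param occupancy optional binary [voxel_grid]; when given, each sample
#'   additionally carries the unnormalised `box_edge`^3 occupancy box
#'   (classifier ground truth).
#' @param spec a [box_spec].
#' @return List of `sample_box` objects with fields `channels`
#'   (box_edge^3 x C array), `label`, `mask` (subbox arrays or `NULL`),
#'   `occ` (optional) and `grid_index` (0-based tile triple).
#' @export
segment_boxes <- function(channels, labels = NULL, mask = NULL,
                          occupancy = NULL, spec = box_spec()) {
  if (is_voxel_grid(channels)) channels <- list(channels)
  stopifnot(length(channels) >= 1L)
  d <- dim(channels[[1]]$values)
  for (ch in channels) {
    if (!identical(dim(ch$values), d)) stop("channel grids must share one shape")
  }
  if (!is.null(labels)) {
    stopifnot(inherits(labels, "rmsf_map"))
    if (!identical(dim(labels$values$values), d))
      stop("labels must share the channel grid shape")
    mask_arr <- labels$mask
    label_arr <- labels$values$values
  } else {
    if (is.null(mask)) stop("supply labels or a screening mask")
    mask_arr <- if (is_voxel_grid(mask)) mask$values != 0 else as.array(mask) != 0
    if (!identical(dim(mask_arr), d)) stop("mask must share the channel grid shape")
    label_arr <- NULL
  }
  occ_arr <- NULL
  if (!is.null(occupancy)) {
    occ_arr <- if (is_voxel_grid(occupancy)) occupancy$values else as.array(occupancy)
    if (!identical(dim(occ_arr), d)) stop("occupancy must share the channel grid shape")
    occ_pad <- pad_to_tiles(occ_arr, spec)
  }
  ch_pad <- lapply(channels, function(g) pad_to_tiles(g$values, spec))
  mask_pad <- pad_to_tiles(mask_arr * 1, spec) > 0
  if (!is.null(label_arr)) label_pad <- pad_to_tiles(label_arr, spec)
  tiles <- ceiling(d / spec$stride)
  be <- spec$box_edge; se <- spec$subbox_edge; pad <- spec$pad
  out <- list()
  for (tz in 0:(tiles[3] - 1)) for (ty in 0:(tiles[2] - 1)) for (tx in 0:(tiles[1] - 1)) {
    sx <- tx * spec$stride; sy <- ty * spec$stride; sz <- tz * spec$stride
    sub_ix <- sx + pad + seq_len(se); sub_iy <- sy + pad + seq_len(se)
    sub_iz <- sz + pad + seq_len(se)
    msub <- mask_pad[sub_ix, sub_iy, sub_iz]
    if (!any(msub)) next
    box_ix <- sx + seq_len(be); box_iy <- sy + seq_len(be); box_iz <- sz + seq_len(be)
    chan <- array(0, dim = c(be, be, be, length(ch_pad)))
    for (ci in seq_along(ch_pad)) {
      chan[, , , ci] <- normalize_box(ch_pad[[ci]][box_ix, box_iy, box_iz])
    }
    sb <- list(channels = chan,
               label = if (!is.null(label_arr)) label_pad[sub_ix, sub_iy, sub_iz] else NULL,
               mask = msub,
               occ = if (!is.null(occ_arr)) occ_pad[box_ix, box_iy, box_iz] else NULL,
               grid_index = c(tx, ty, tz))
    class(sb) <- "sample_box"
    out[[length(out) + 1L]] <- sb
  }
  out
}

#' Merge predicted subboxes back into a map
#'
#' Writes each `subbox_edge`^3 block at its tile position (tiles never
#' overlap since stride equals the subbox edge), removes the padding, and
#' returns an [rmsf_map] on the original grid. Unwritten voxels are 0 with
#' mask `FALSE`.
#'
#' @param predictions list of `sample_box`es (their `label` field holds the
#'   values) or of lists with `grid_index` and `values`.
#' @param grid a [voxel_grid] providing the original geometry.
#' @param spec a [box_spec].
#' @param masks optional list of logical subbox arrays, parallel to
#'   `predictions`; when omitted, every written voxel is masked.
#' @return An [rmsf_map].
#' @export
merge_subboxes <- function(predictions, grid, spec = box_spec(), masks = NULL) {
  stopifnot(is_voxel_grid(grid))
  d <- dim(grid$values)
  vals <- array(0, dim = d)
  mk <- array(FALSE, dim = d)
  seen <- character(0)
  se <- spec$subbox_edge
  for (pi in seq_along(predictions)) {
    p <- predictions[[pi]]
    gi <- p$grid_index
    v <- if (!is.null(p$values)) p$values else p$label
    if (is.null(gi) || is.null(v)) stop("each prediction needs grid_index and values")
    key <- paste(gi, collapse = ",")
    if (key %in% seen) stop("duplicate grid index: ", key)
    seen <- c(seen, key)
    # subbox covers original voxels [gi*stride, gi*stride + subbox) per axis
    ix <- gi[1] * spec$stride + seq_len(se); iy <- gi[2] * spec$stride + seq_len(se)
    iz <- gi[3] * spec$stride + seq_len(se)
    kx <- ix <= d[1]; ky <- iy <= d[2]; kz <- iz <= d[3]
    if (!any(kx) || !any(ky) || !any(kz)) next
    vals[ix[kx], iy[ky], iz[kz]] <- v[kx, ky, kz]
    msub <- if (!is.null(masks)) masks[[pi]] else
      if (!is.null(p$mask)) p$mask else array(TRUE, dim = c(se, se, se))
    mk[ix[kx], iy[ky], iz[kz]] <- msub[kx, ky, kz]
  }
  rmsf_map(voxel_grid(vals, grid$voxel_size, grid$origin), mk)
}
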