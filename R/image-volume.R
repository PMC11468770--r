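#' 3-D image volumes
#'
#' An `image_volume` wraps a 3-D array of unsigned-integer intensities
#' (`data[x, y, z]`) together with the anisotropic voxel size in micrometers,
#' the bit depth (8 or 16) and the 0-based voxel offset (`origin`) of the
#' block inside the whole-volume frame, so crops round-trip their
#' coordinates: the whole-frame coordinate of a voxel is `origin + local
#' index` (0-based).
#'
#' @param data 3-D numeric array of intensities.
#' @param voxel_size Micrometers per voxel along x, y, z.
#' @param origin 0-based offset of this block in whole-volume voxels.
#' @param bit_depth 8 or 16.
#' @return An `image_volume`.
#' @export
image_volume <- function(data, voxel_size = c(1, 1, 1), origin = c(0, 0, 0),
                         bit_depth = 16) {
  stopifnot(length(dim(data)) == 3, all(dim(data) >= 1),
            bit_depth %in% c(8, 16), length(voxel_size) == 3,
            length(origin) == 3)
  structure(
    list(
      data = data,
      voxel_size = as.double(voxel_size),
      origin = as.double(origin),
      bit_depth = as.integer(bit_depth)
    ),
    class = "image_volume"
  )
}

#' @export
print.image_volume <- function(x, ...) {
  d <- dim(x$data)
  cat(sprintf(
    "# image_volume: %d x %d x %d voxels, %d-bit, voxel size (%g, %g, %g) um, origin (%g, %g, %g)\n",
    d[1], d[2], d[3], x$bit_depth,
    x$voxel_size[1], x$voxel_size[2], x$voxel_size[3],
    x$origin[1], x$origin[2], x$origin[3]
  ))
  invisible(x)
}

#' @rdname image_volume
#' @param x An object.
#' @export
is_image_volume <- function(x) inherits(x, "image_volume")

#' Read / write an image volume as a multi-page TIFF
#'
#' Pages are z-slices; within a page the first array axis (x) maps to rows.
#' Intensities are stored as unsigned integers at the volume's bit depth.
#'
#' @param path TIFF file path.
#' @inheritParams image_volume
#' @return `read_volume_tiff()` returns an `image_volume`;
#'   `write_volume_tiff()` returns `path` invisibly.
#' @export
read_volume_tiff <- function(path, voxel_size = c(1, 1, 1), origin = c(0, 0, 0)) {
  slices <- tiff::readTIFF(path, all = TRUE, as.is = TRUE)
  if (!is.list(slices)) slices <- list(slices)
  d <- dim(slices[[1]])
  data <- array(0L, dim = c(d[1], d[2], length(slices)))
  for (z in seq_along(slices)) data[, , z] <- slices[[z]]
  bit_depth <- if (max(data) > 255) 16L else attr(slices[[1]], "bits.per.sample")
  if (is.null(bit_depth)) bit_depth <- if (max(data) > 255) 16L else 8L
  image_volume(data, voxel_size = voxel_size, origin = origin,
               bit_depth = bit_depth)
}

#' @rdname read_volume_tiff
#' @param volume An `image_volume`.
#' @export
write_volume_tiff <- function(volume, path) {
  maxval <- 2^volume$bit_depth - 1
  slices <- lapply(seq_len(dim(volume$data)[3]), function(z) {
    pmin(pmax(volume$data[, , z], 0), maxval) / maxval
  })
  tiff::writeTIFF(slices, path, bits.per.sample = volume$bit_depth)
  invisible(path)
}

#' Tile a volume shape into blocks
#'
#' Splits a voxel grid into axis-aligned blocks of approximately
#' `block` voxels per side (edge blocks may be smaller). The blocks are
#' pairwise disjoint half-open 0-based ranges whose union is the full volume.
#'
#' @param shape Integer length-3 volume shape in voxels.
#' @param block Target block side length (default 256).
#' @return A tibble with columns `x0`, `x1`, `y0`, `y1`, `z0`, `z1`
#'   (half-open: `x0 <= x < x1`).
#' @export
partition_blocks <- function(shape, block = 256) {
  stopifnot(length(shape) == 3, all(shape >= 1), block >= 1)
  cuts <- lapply(shape, function(n) {
    lo <- seq(0L, n - 1L, by = block)
    tibble::tibble(lo = lo, hi = pmin(lo + block, n))
  })
  grid <- expand.grid(ix = seq_len(nrow(cuts[[1]])), iy = seq_len(nrow(cuts[[2]])),
                      iz = seq_len(nrow(cuts[[3]])))
  tibble::tibble(
    x0 = cuts[[1]]$lo[grid$ix], x1 = cuts[[1]]$hi[grid$ix],
    y0 = cuts[[2]]$lo[grid$iy], y1 = cuts[[2]]$hi[grid$iy],
    z0 = cuts[[3]]$lo[grid$iz], z1 = cuts[[3]]$hi[grid$iz]
  )
}

#' Extract a sub-block of a volume
#'
#' `crop_block()` cuts a `size`-per-side block centred on a whole-frame voxel
#' coordinate, clipped at the volume borders (so blocks near an edge are
#' smaller). For an even `size` the centring is asymmetric and fixed for
#' reproducibility: `size - size %/% 2 - 1` voxels before the centre and
#' `size %/% 2` after. The crop's `origin` records its offset so whole-frame
#' coordinates round-trip.
#'
#' @param volume An `image_volume`.
#' @param center 0-based whole-frame voxel coordinate; must lie inside the
#'   volume.
#' @param size Block side length (default 128).
#' @return An `image_volume`.
#' @export
crop_block <- function(volume, center, size = 128) {
  stopifnot(length(center) == 3, size >= 1)
  d <- dim(volume$data)
  o <- volume$origin
  center <- as.double(center)
  if (any(center < o) || any(center > o + d - 1)) {
    rlang::abort("`center` lies outside the volume")
  }
  before <- size - size %/% 2 - 1
  after <- size %/% 2
  lo <- pmax(o, center - before)
  hi <- pmin(o + d - 1, center + after)
  li <- lo - o + 1 # 1-based local
  hiI <- hi - o + 1
  image_volume(
    volume$data[li[1]:hiI[1], li[2]:hiI[2], li[3]:hiI[3], drop = FALSE],
    voxel_size = volume$voxel_size, origin = lo, bit_depth = volume$bit_depth
  )
}

# size^3 crop with zero padding outside the volume; center in whole frame
pad_crop <- function(volume, center, size) {
  d <- dim(volume$data)
  o <- volume$origin
  before <- size - size %/% 2 - 1
  after <- size %/% 2
  lo <- center - before
  out <- array(0, dim = rep(size, 3))
  src_lo <- pmax(lo, o)
  src_hi <- pmin(center + after, o + d - 1)
  if (all(src_lo <= src_hi)) {
    sl <- src_lo - o + 1
    sh <- src_hi - o + 1
    tl <- src_lo - lo + 1
    th <- src_hi - lo + 1
    out[tl[1]:th[1], tl[2]:th[2], tl[3]:th[3]] <-
      volume$data[sl[1]:sh[1], sl[2]:sh[2], sl[3]:sh[3]]
  }
  list(data = out, origin = lo)
}
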