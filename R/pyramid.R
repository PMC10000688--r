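# Tiled pyramidal TIFF I/O.
#
# Classic little-endian TIFF, one IFD per pyramid level (NewSubfileType
# 1 for reduced levels), tile tags 322-325, resolution tags in
# pixels-per-centimeter, and a key=value ImageDescription carrying the
# exact um/px, magnification label, tile size and JPEG quality.  Tiles
# are either uncompressed chunky RGB or complete JFIF streams written
# by libjpeg (PhotometricInterpretation 6), which standard readers
# (libtiff, tifffile) decode directly.  Coordinates are 0-based,
# top-left origin, half-open.

w_u16 <- function(x) writeBin(as.integer(x), raw(), size = 2, endian = "little")
# unsigned 32-bit little-endian, tolerating values above .Machine$integer.max
w_u32 <- function(x) {
  x <- as.numeric(x)
  lo <- x %% 65536
  hi <- ((x - lo) / 65536) %% 65536
  out <- raw(4 * length(x))
  for (i in seq_along(x)) {
    out[(4 * i - 3):(4 * i)] <- c(w_u16(lo[i]), w_u16(hi[i]))
  }
  out
}

r_u16 <- function(r, off) {  # off is 0-based
  as.integer(r[off + 1]) + 256L * as.integer(r[off + 2])
}
r_u32 <- function(r, off) {
  as.numeric(r[off + 1]) + 256 * as.numeric(r[off + 2]) +
    65536 * as.numeric(r[off + 3]) + 16777216 * as.numeric(r[off + 4])
}

tiff_entry <- function(tag, type, count, value4) {
  c(w_u16(tag), w_u16(type), w_u32(count), value4)
}

encode_tile_none <- function(tile) as.raw(as.integer(aperm(tile, c(3, 2, 1))))
decode_tile_none <- function(bytes, tw, th) {
  aperm(array(as.integer(bytes), c(3L, tw, th)), c(3, 2, 1))
}

# pad a tile to full tile_size by edge replication (TIFF tiles must be
# complete; replication avoids JPEG ringing at slide borders)
pad_tile <- function(tile, th, tw) {
  d <- dim(tile)
  if (d[1] == th && d[2] == tw) return(tile)
  tile[pmin(seq_len(th), d[1]), pmin(seq_len(tw), d[2]), , drop = FALSE]
}

#' Downsample an image by 2x average pooling
#'
#' Each output pixel is the mean of its 2x2 parent block (edge rows and
#' columns are replicated when a dimension is odd), rounded half-up.
#' Output dimensions are `ceiling(input / 2)`.
#'
#' @param image RGB array.
#' @return RGB array of halved dimensions.
#' @export
pool2 <- function(image) {
  image <- as_rgb_image(image)
  h <- dim(image)[1]; w <- dim(image)[2]
  ho <- ceiling(h / 2); wo <- ceiling(w / 2)
  yi <- pmin(1:(2 * ho), h); xi <- pmin(1:(2 * wo), w)
  x <- image[yi, xi, , drop = FALSE]
  odd_y <- seq(1, 2 * ho, 2); odd_x <- seq(1, 2 * wo, 2)
  out <- (x[odd_y, odd_x, , drop = FALSE] + x[odd_y + 1, odd_x, , drop = FALSE] +
          x[odd_y, odd_x + 1, , drop = FALSE] + x[odd_y + 1, odd_x + 1, , drop = FALSE]) / 4
  round_half_up(out)
}

#' Write a tiled pyramidal TIFF
#'
#' Writes level 0 plus successive 2x average-pooled levels until both
#' dimensions fit in a single tile. Resolution metadata (um/px) is
#' stored both in standard TIFF resolution tags (pixels per
#' centimeter) and, exactly, in the ImageDescription; the file parses
#' with generic TIFF readers.
#'
#' @param image RGB array, the full-resolution plane.
#' @param path output path.
#' @param tile_size tile edge in pixels (default 256).
#' @param compression `"jpeg"` (lossy, per-tile JFIF streams) or
#'   `"none"` (bit-exact round trip).
#' @param jpeg_quality quality factor in `[1, 100]` (default 80).
#' @param microns_per_pixel physical pixel size of level 0.
#' @param magnification optional label, e.g. `"200x"`.
#' @return the written file re-opened as a `"tile_pyramid"`.
#' @export
write_pyramid <- function(image, path, tile_size = 256L,
                          compression = c("jpeg", "none"),
                          jpeg_quality = 80L, microns_per_pixel,
                          magnification = NULL) {
  image <- as_rgb_image(image)
  compression <- match.arg(compression)
  if (jpeg_quality < 1 || jpeg_quality > 100)
    sn_validation_error("jpeg_quality must be in [1, 100]")
  if (missing(microns_per_pixel) || !is.finite(microns_per_pixel) ||
      microns_per_pixel <= 0)
    sn_metadata_error("microns_per_pixel must be a positive number")
  tile_size <- as.integer(tile_size)

  levels <- list(image)
  while (any(dim(levels[[length(levels)]])[1:2] > tile_size))
    levels[[length(levels) + 1L]] <- pool2(levels[[length(levels)]])
  nlev <- length(levels)

  if (is.null(magnification)) magnification <- ""
  desc <- sprintf(
    "stainnorm_pyramid=1;microns_per_pixel=%.12g;magnification=%s;tile_size=%d;jpeg_quality=%d;levels=%d",
    microns_per_pixel, magnification, tile_size, as.integer(jpeg_quality), nlev)
  descr <- c(charToRaw(desc), as.raw(0))
  desc_count <- length(descr)
  if (desc_count %% 2) descr <- c(descr, as.raw(0))

  # JPEG tiles are written planar (PlanarConfiguration 2): one full-
  # resolution grayscale JFIF stream per channel per tile, i.e. no
  # chroma subsampling -- stain color carries the signal here.
  planar <- compression == "jpeg"
  tiledata <- vector("list", nlev)
  tdims <- vector("list", nlev)
  for (li in seq_len(nlev)) {
    img <- levels[[li]]
    h <- dim(img)[1]; w <- dim(img)[2]
    ntx <- ceiling(w / tile_size); nty <- ceiling(h / tile_size)
    n_sp <- ntx * nty
    tl <- vector("list", if (planar) 3L * n_sp else n_sp)
    k <- 1L
    for (plane in seq_len(if (planar) 3L else 1L))
      for (ty in seq_len(nty)) for (tx in seq_len(ntx)) {
        ys <- ((ty - 1L) * tile_size + 1L):min(ty * tile_size, h)
        xs <- ((tx - 1L) * tile_size + 1L):min(tx * tile_size, w)
        t_ <- pad_tile(img[ys, xs, , drop = FALSE], tile_size, tile_size)
        tl[[k]] <- if (planar)
          jpeg::writeJPEG(t_[, , plane] / 255, raw(),
                          quality = jpeg_quality / 100)
        else encode_tile_none(t_)
        k <- k + 1L
      }
    tiledata[[li]] <- tl
    tdims[[li]] <- list(w = w, h = h, n_tiles = length(tl))
  }

  # layout: header | all tile data (even-aligned) | per level: aux arrays, IFD
  pos <- 8
  tile_offsets <- vector("list", nlev)
  for (li in seq_len(nlev)) {
    sizes <- lengths(tiledata[[li]])
    offs <- numeric(length(sizes))
    for (k in seq_along(sizes)) {
      offs[k] <- pos
      pos <- pos + sizes[k] + (sizes[k] %% 2)
    }
    tile_offsets[[li]] <- offs
  }
  n_entries <- 16L
  aux <- vector("list", nlev)
  ifd_off <- numeric(nlev)
  for (li in seq_len(nlev)) {
    n_tiles <- tdims[[li]]$n_tiles
    a <- list()
    a$bps <- pos;  pos <- pos + 8                  # 3 shorts + pad
    a$desc <- pos; pos <- pos + length(descr)
    a$xres <- pos; pos <- pos + 8
    a$yres <- pos; pos <- pos + 8
    if (n_tiles > 1) {
      a$toff <- pos; pos <- pos + 4 * n_tiles
      a$tbc <- pos;  pos <- pos + 4 * n_tiles
    }
    aux[[li]] <- a
    ifd_off[li] <- pos
    pos <- pos + 2 + 12 * n_entries + 4
  }

  ppcm_num <- 1e9
  ppcm_den <- max(1, round(microns_per_pixel * 1e5))
  con <- file(path, "wb")
  on.exit(close(con))
  writeBin(c(charToRaw("II"), as.raw(c(42, 0)), w_u32(ifd_off[1])), con)
  for (li in seq_len(nlev)) for (k in seq_along(tiledata[[li]])) {
    r <- tiledata[[li]][[k]]
    writeBin(r, con)
    if (length(r) %% 2) writeBin(as.raw(0), con)
  }
  comp_code <- if (compression == "jpeg") 7L else 1L
  for (li in seq_len(nlev)) {
    d <- tdims[[li]]; a <- aux[[li]]
    sizes <- lengths(tiledata[[li]])
    writeBin(c(w_u16(c(8, 8, 8)), w_u16(0)), con)
    writeBin(descr, con)
    den <- ppcm_den * 2^(li - 1)
    writeBin(c(w_u32(ppcm_num), w_u32(den)), con)
    writeBin(c(w_u32(ppcm_num), w_u32(den)), con)
    if (d$n_tiles > 1) {
      writeBin(w_u32(tile_offsets[[li]]), con)
      writeBin(w_u32(sizes), con)
    }
    e <- list(
      tiff_entry(254, 4, 1, w_u32(if (li == 1) 0 else 1)),
      tiff_entry(256, 4, 1, w_u32(d$w)),
      tiff_entry(257, 4, 1, w_u32(d$h)),
      tiff_entry(258, 3, 3, w_u32(a$bps)),
      tiff_entry(259, 3, 1, c(w_u16(comp_code), w_u16(0))),
      tiff_entry(262, 3, 1, c(w_u16(2), w_u16(0))),
      tiff_entry(270, 2, desc_count, w_u32(a$desc)),
      tiff_entry(277, 3, 1, c(w_u16(3), w_u16(0))),
      tiff_entry(282, 5, 1, w_u32(a$xres)),
      tiff_entry(283, 5, 1, w_u32(a$yres)),
      tiff_entry(284, 3, 1, c(w_u16(if (planar) 2 else 1), w_u16(0))),
      tiff_entry(296, 3, 1, c(w_u16(3), w_u16(0))),
      tiff_entry(322, 4, 1, w_u32(tile_size)),
      tiff_entry(323, 4, 1, w_u32(tile_size)),
      tiff_entry(324, 4, d$n_tiles,
                 if (d$n_tiles == 1) w_u32(tile_offsets[[li]][1]) else w_u32(a$toff)),
      tiff_entry(325, 4, d$n_tiles,
                 if (d$n_tiles == 1) w_u32(sizes[1]) else w_u32(a$tbc))
    )
    writeBin(w_u16(length(e)), con)
    for (ee in e) writeBin(ee, con)
    writeBin(w_u32(if (li < nlev) ifd_off[li + 1] else 0), con)
  }
  close(con)
  on.exit()
  open_pyramid(path)
}

tiff_type_size <- c(1, 1, 2, 4, 8)

read_tag_values <- function(r, type, count, val_off) {
  # val_off = 0-based offset of the 4 value bytes within file raw `r`
  size <- tiff_type_size[type]
  total <- size * count
  off <- if (total <= 4) val_off else r_u32(r, val_off)
  if (type == 2) {  # ASCII
    bytes <- r[(off + 1):(off + count)]
    return(rawToChar(bytes[bytes != as.raw(0)]))
  }
  vals <- numeric(count)
  for (i in seq_len(count)) {
    o <- off + (i - 1) * size
    vals[i] <- switch(as.character(type),
      "1" = as.numeric(r[o + 1]),
      "3" = r_u16(r, o),
      "4" = r_u32(r, o),
      "5" = r_u32(r, o) / r_u32(r, o + 4))
  }
  vals
}

parse_description <- function(desc) {
  if (is.null(desc) || !nzchar(desc)) return(list())
  parts <- strsplit(desc, ";", fixed = TRUE)[[1]]
  kv <- strsplit(parts, "=", fixed = TRUE)
  vals <- lapply(kv, function(x) if (length(x) > 1) x[2] else "")
  names(vals) <- vapply(kv, `[`, "", 1)
  vals
}

#' Open a tiled pyramidal TIFF for random access
#'
#' Parses the IFD chain of a tiled TIFF written by [write_pyramid()]
#' (or any compatible tiled multi-resolution TIFF using uncompressed or
#' per-tile-JPEG RGB) and returns a handle for [read_region()].
#'
#' @param path TIFF file path.
#' @return an object of class `"tile_pyramid"`: `levels` (list of
#'   width/height/downsample/tile geometry per level), `tile_size`,
#'   `compression`, `jpeg_quality`, `microns_per_pixel`,
#'   `magnification_label`, `path`.
#' @export
open_pyramid <- function(path) {
  if (!file.exists(path)) sn_io_error(paste0("no such file: ", path))
  r <- readBin(path, raw(), file.size(path))
  if (length(r) < 8 || rawToChar(r[1:2]) != "II" || r_u16(r, 2) != 42L)
    sn_format_error("not a little-endian classic TIFF")
  levels <- list()
  desc <- NULL
  next_ifd <- r_u32(r, 4)
  while (next_ifd != 0) {
    n <- r_u16(r, next_ifd)
    tags <- list()
    for (i in seq_len(n)) {
      eo <- next_ifd + 2 + (i - 1) * 12
      tag <- r_u16(r, eo); type <- r_u16(r, eo + 2)
      count <- r_u32(r, eo + 4)
      tags[[as.character(tag)]] <- list(type = type, count = count,
                                        val_off = eo + 8)
    }
    gv <- function(tag) {
      t_ <- tags[[as.character(tag)]]
      if (is.null(t_)) return(NULL)
      read_tag_values(r, t_$type, t_$count, t_$val_off)
    }
    if (is.null(gv(322)))
      sn_format_error("TIFF is not tiled (no TileWidth tag)")
    lvl <- list(width = gv(256), height = gv(257),
                tile_width = gv(322), tile_height = gv(323),
                compression = gv(259), photometric = gv(262),
                planar_config = if (is.null(gv(284))) 1 else gv(284),
                offsets = gv(324), bytecounts = gv(325),
                x_resolution = gv(282),
                resolution_unit = if (is.null(gv(296))) 2 else gv(296))
    if (is.null(desc)) desc <- gv(270)
    levels[[length(levels) + 1L]] <- lvl
    next_ifd <- r_u32(r, next_ifd + 2 + 12 * n)
  }
  if (!length(levels)) sn_format_error("TIFF contains no images")
  meta <- parse_description(desc)
  mpp <- NA_real_
  if (!is.null(meta$microns_per_pixel))
    mpp <- as.numeric(meta$microns_per_pixel)
  else if (!is.null(levels[[1]]$x_resolution) &&
           levels[[1]]$resolution_unit == 3)
    mpp <- 1e4 / levels[[1]]$x_resolution
  w0 <- levels[[1]]$width
  for (li in seq_along(levels))
    levels[[li]]$downsample <- w0 / levels[[li]]$width
  structure(list(
    path = path, levels = levels,
    tile_size = levels[[1]]$tile_width,
    compression = if (levels[[1]]$compression == 7) "jpeg" else "none",
    jpeg_quality = if (!is.null(meta$jpeg_quality))
      as.integer(meta$jpeg_quality) else NA_integer_,
    microns_per_pixel = mpp,
    magnification_label = if (!is.null(meta$magnification))
      meta$magnification else ""),
    class = "tile_pyramid")
}

#' @export
print.tile_pyramid <- function(x, ...) {
  cat(sprintf("<tile_pyramid %s: %d level(s), tile %d, %s, %.4g um/px>\n",
              basename(x$path), length(x$levels), x$tile_size,
              x$compression, x$microns_per_pixel))
  for (li in seq_along(x$levels))
    cat(sprintf("  level %d: %d x %d (downsample %g)\n", li,
                x$levels[[li]]$width, x$levels[[li]]$height,
                x$levels[[li]]$downsample))
  invisible(x)
}

#' Read a rectangular region from a pyramid level
#'
#' Coordinates are 0-based, top-left origin, half-open
#' `[x, x + w) x [y, y + h)`, in the pixel grid of the requested level.
#'
#' @param pyramid a `"tile_pyramid"`.
#' @param level 1-based level index (1 = full resolution).
#' @param x,y region origin (0-based).
#' @param w,h region width and height in pixels.
#' @return RGB array `h x w x 3`.
#' @export
read_region <- function(pyramid, level, x, y, w, h) {
  if (!inherits(pyramid, "tile_pyramid"))
    sn_validation_error("pyramid must be a tile_pyramid")
  if (level < 1 || level > length(pyramid$levels))
    sn_range_error(sprintf("level %d does not exist", level))
  lvl <- pyramid$levels[[level]]
  if (w <= 0 || h <= 0 || x < 0 || y < 0 ||
      x + w > lvl$width || y + h > lvl$height)
    sn_range_error("requested region exceeds level bounds")
  tw <- lvl$tile_width; th <- lvl$tile_height
  ntx <- ceiling(lvl$width / tw)
  tx0 <- floor(x / tw); tx1 <- floor((x + w - 1) / tw)
  ty0 <- floor(y / th); ty1 <- floor((y + h - 1) / th)
  n_sp <- ntx * ceiling(lvl$height / th)    # spatial tiles per plane
  out <- array(0, c(h, w, 3L))
  con <- file(pyramid$path, "rb")
  on.exit(close(con))
  fetch <- function(idx) {
    off <- lvl$offsets[idx]; nb <- lvl$bytecounts[idx]
    if (is.na(off) || is.na(nb) || nb <= 0)
      sn_io_error(sprintf("missing tile %d at level %d", idx, level))
    seek(con, off)
    bytes <- readBin(con, raw(), nb)
    if (length(bytes) < nb)
      sn_io_error(sprintf("corrupt tile %d at level %d (short read)",
                          idx, level))
    bytes
  }
  for (ty in ty0:ty1) for (tx in tx0:tx1) {
    idx <- ty * ntx + tx + 1
    tile <- if (lvl$compression == 7 && lvl$planar_config == 2) {
      # one grayscale JFIF stream per channel (no chroma subsampling)
      planes <- lapply(0:2, function(p) {
        t_ <- jpeg::readJPEG(fetch(idx + p * n_sp))
        if (!is.matrix(t_)) t_ <- t_[, , 1]
        t_
      })
      round_half_up(array(unlist(planes), c(th, tw, 3L)) * 255)
    } else if (lvl$compression == 7) {
      t_ <- jpeg::readJPEG(fetch(idx))
      if (is.matrix(t_)) t_ <- array(rep(t_, 3), c(dim(t_), 3L))
      round_half_up(t_[, , 1:3, drop = FALSE] * 255)
    } else if (lvl$compression == 1) {
      decode_tile_none(fetch(idx), tw, th)
    } else sn_io_error(sprintf("unsupported compression %d", lvl$compression))
    # intersection of tile with the request, in level coordinates
    ly0 <- max(y, ty * th); ly1 <- min(y + h, (ty + 1) * th) - 1
    lx0 <- max(x, tx * tw); lx1 <- min(x + w, (tx + 1) * tw) - 1
    out[(ly0 - y + 1):(ly1 - y + 1), (lx0 - x + 1):(lx1 - x + 1), ] <-
      tile[(ly0 - ty * th + 1):(ly1 - ty * th + 1),
           (lx0 - tx * tw + 1):(lx1 - tx * tw + 1), , drop = FALSE]
  }
  out
}

#' Bring an image to 200x-equivalent resolution
#'
#' Output is always 200x-class (~0.47 um/px): input finer than
#' 0.35 um/px (400x-class, ~0.23 um/px) is 2x average-pooled and its
#' pixel size doubled; 200x-class input passes through unchanged. The
#' 0.35 um/px cutoff is the midpoint between the two scanner classes.
#'
#' @param image RGB array (e.g. a full level read from a pyramid).
#' @param microns_per_pixel physical pixel size of `image`; required.
#' @return list with elements `image` and `microns_per_pixel`.
#' @export
resample_to_200x <- function(image, microns_per_pixel) {
  if (missing(microns_per_pixel) || is.null(microns_per_pixel) ||
      !is.finite(microns_per_pixel) || microns_per_pixel <= 0)
    sn_metadata_error(
      "microns_per_pixel metadata is required (supply the pixel size)")
  if (microns_per_pixel < 0.35)
    list(image = pool2(image), microns_per_pixel = 2 * microns_per_pixel)
  else
    list(image = as_rgb_image(image), microns_per_pixel = microns_per_pixel)
}
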