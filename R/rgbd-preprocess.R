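#' Registered depth/color image pair
#'
#' Container for one RGB-D frame: a depth map in millimetres (integer, 0
#' marks a pixel with no depth reading, the usual structured-light dropout
#' sentinel) and a color image on the same pixel grid. Registration
#' (depth-to-color alignment) is assumed to have been done upstream by the
#' sensor SDK; only equal dimensions are checked here.
#'
#' @param depth integer matrix `[rows, cols]` of depth values in mm; 0 = no
#'   reading. Row 1 is the top image row.
#' @param color numeric array `[rows, cols, 3]` with values in `[0, 1]`.
#' @param meta optional free-text metadata (camera id, timestamp, ...).
#' @return An object of class `rgbd_pair`.
#' @export
rgbd_pair <- function(depth, color, meta = NULL) {
  depth <- as.matrix(depth)
  if (any(depth < 0, na.rm = TRUE))
    stopf("tomstem_value_error", "depth values must be non-negative")
  if (length(dim(color)) != 3L || dim(color)[3] != 3L)
    stopf("tomstem_value_error", "color must be an [rows, cols, 3] array")
  if (!identical(dim(depth), dim(color)[1:2]))
    stopf("tomstem_dim_error",
          "depth (%d x %d) and color (%d x %d) dimensions differ",
          nrow(depth), ncol(depth), dim(color)[1], dim(color)[2])
  structure(list(depth = depth, color = color, meta = meta),
            class = "rgbd_pair")
}

#' @export
print.rgbd_pair <- function(x, ...) {
  cat(sprintf("<rgbd_pair> %d x %d px, depth range %d-%d mm, %.1f%% valid\n",
              nrow(x$depth), ncol(x$depth),
              min(x$depth[x$depth > 0], 0), max(x$depth),
              100 * mean(x$depth > 0)))
  invisible(x)
}

#' Foreground mask from a depth window
#'
#' Marks as foreground every pixel whose depth reading is valid (non-zero)
#' and falls inside the closed interval `[near_mm, far_mm]`. With the plant
#' pot standing 0.9-1.0 m from the camera, the default 800-1500 mm window
#' removes the cluttered background entirely while keeping the whole plant;
#' masking never consults the color channel, so it is independent of
#' illumination.
#'
#' @param pair an [rgbd_pair].
#' @param near_mm,far_mm depth window bounds in millimetres.
#' @return Logical matrix of class `foreground_mask` with attributes
#'   `near_mm` and `far_mm`.
#' @export
depth_mask <- function(pair, near_mm = 800, far_mm = 1500) {
  stopifnot(inherits(pair, "rgbd_pair"))
  if (!(near_mm < far_mm))
    stopf("tomstem_value_error", "near_mm (%s) must be < far_mm (%s)",
          near_mm, far_mm)
  m <- pair$depth != 0L & pair$depth >= near_mm & pair$depth <= far_mm
  structure(m, class = c("foreground_mask", "matrix", "array"),
            near_mm = near_mm, far_mm = far_mm)
}

as_mask <- function(m) {
  m <- m != 0
  if (!inherits(m, "foreground_mask"))
    class(m) <- c("foreground_mask", "matrix", "array")
  m
}

# --- Zhang-Suen thinning ----------------------------------------------------
#
# The two sub-iteration deletion criteria depend only on the 8-neighbourhood
# (P2..P9 clockwise from north), so each is precomputed as a 256-entry
# lookup table over the neighbourhood bit code; one thinning pass is then
# two vectorized table lookups over the whole image.

zs_luts <- local({
  tabs <- NULL
  function() {
    if (!is.null(tabs)) return(tabs)
    t1 <- logical(256); t2 <- logical(256)
    for (code in 0:255) {
      p <- as.integer(bitwAnd(bitwShiftR(code, 0:7), 1L))  # P2..P9
      b <- sum(p)
      a <- sum(p == 0 & p[c(2:8, 1)] == 1)                 # 0->1 transitions
      ok <- b >= 2 && b <= 6 && a == 1
      t1[code + 1] <- ok && p[1] * p[3] * p[5] == 0 && p[3] * p[5] * p[7] == 0
      t2[code + 1] <- ok && p[1] * p[3] * p[7] == 0 && p[1] * p[5] * p[7] == 0
    }
    tabs <<- list(t1, t2)
    tabs
  }
})

# 8-neighbourhood bit code of every pixel of logical matrix `img`
# (already padded with a 1-pixel FALSE border).
zs_codes <- function(img) {
  h <- nrow(img); w <- ncol(img)
  sh <- function(dr, dc) img[(2 + dr):(h - 1 + dr), (2 + dc):(w - 1 + dc)]
  # P2=N, P3=NE, P4=E, P5=SE, P6=S, P7=SW, P8=W, P9=NW
  sh(-1, 0) * 1L + sh(-1, 1) * 2L + sh(0, 1) * 4L + sh(1, 1) * 8L +
    sh(1, 0) * 16L + sh(1, -1) * 32L + sh(0, -1) * 64L + sh(-1, -1) * 128L
}

#' Skeletonize a binary mask by Zhang-Suen thinning
#'
#' Iteratively peels boundary pixels in two alternating sub-passes until no
#' pixel changes, producing a one-pixel-wide skeleton. The algorithm is
#' purely local, so it handles the sparse, fragmented masks typical of
#' structured-light depth images of thin plant structures: every connected
#' foreground component thins to a connected curve and isolated fragments
#' thin independently. Holes left by sensor dropout are not filled before
#' thinning.
#'
#' @param mask logical matrix (a [depth_mask] result or any 0/1 matrix).
#' @return Logical matrix of class `skeleton_image`, a subset of `mask`.
#' @export
skeletonize <- function(mask) {
  m <- unclass(as_mask(mask)); attributes(m) <- attributes(m)["dim"]
  h <- nrow(m); w <- ncol(m)
  luts <- zs_luts()
  pad <- matrix(FALSE, h + 2, w + 2)
  pad[2:(h + 1), 2:(w + 1)] <- m
  repeat {
    changed <- FALSE
    for (s in 1:2) {
      inner <- pad[2:(h + 1), 2:(w + 1)]
      del <- inner & luts[[s]][zs_codes(pad) + 1L]
      if (any(del)) {
        inner[del] <- FALSE
        pad[2:(h + 1), 2:(w + 1)] <- inner
        changed <- TRUE
      }
    }
    if (!changed) break
  }
  structure(pad[2:(h + 1), 2:(w + 1)],
            class = c("skeleton_image", "matrix", "array"))
}

# --- PNG I/O ---------------------------------------------------------------
# Depth images travel as 16-bit single-channel PNG whose raw value is the
# depth in millimetres; color as 8-bit RGB PNG; masks/skeletons as 0/255.

#' Read and write depth, color and mask PNG images
#'
#' `read_depth_png`/`write_depth_png` use 16-bit grayscale PNG with the pixel
#' value equal to depth in millimetres (0 = no reading).
#' `read_color_png`/`write_color_png` use 8-bit RGB. `write_mask_png` stores
#' a logical matrix as 0/255. All functions use the `[row, col]` convention
#' with row 1 at the top.
#'
#' @param path file path.
#' @param depth integer matrix of millimetres.
#' @param color numeric `[rows, cols, 3]` array in `[0, 1]`.
#' @param mask logical matrix.
#' @return Readers return the matrix/array; writers return `path` invisibly.
#' @name rgbd_io
NULL

#' @rdname rgbd_io
#' @export
read_depth_png <- function(path) {
  if (!file.exists(path)) stopf("tomstem_io_error", "no such file: %s", path)
  img <- EBImage::imageData(EBImage::readImage(path))
  if (length(dim(img)) == 3L) img <- img[, , 1]
  d <- t(img)                    # EBImage stores [x, y]
  storage.mode(d) <- "integer"
  d[] <- as.integer(round(t(img) * 65535))
  d
}

#' @rdname rgbd_io
#' @export
write_depth_png <- function(depth, path) {
  if (max(depth) > 65535) stopf("tomstem_value_error", "depth exceeds 16-bit range")
  write_png16_gray(depth, path)
  invisible(path)
}

# --- minimal 16-bit grayscale PNG encoder ---------------------------------
# None of the available image packages writes 16-bit PNG, and millimetre
# depth does not survive an 8-bit round trip, so the container is written
# directly: IHDR/IDAT/IEND chunks around the zlib stream produced by
# memCompress (R's "gzip" flavour is RFC 1950 zlib, usable as IDAT as-is).

crc32_table <- local({
  tab <- NULL
  function() {
    if (!is.null(tab)) return(tab)
    t <- integer(256)
    for (i in 0:255) {
      c <- i
      for (k in 1:8)
        c <- if (bitwAnd(c, 1L)) bitwXor(-306674912L, bitwShiftR(c, 1)) else
          bitwShiftR(c, 1)
      t[i + 1] <- c
    }
    tab <<- t
    tab
  }
})

crc32_raw <- function(bytes) {
  tab <- crc32_table()
  crc <- -1L
  for (b in as.integer(bytes))
    crc <- bitwXor(bitwShiftR(crc, 8),
                   tab[bitwAnd(bitwXor(crc, b), 255L) + 1L])
  writeBin(bitwXor(crc, -1L), raw(), size = 4, endian = "big")
}

be32 <- function(x) writeBin(as.integer(x), raw(), size = 4, endian = "big")

png_chunk <- function(type, data) {
  body <- c(charToRaw(type), data)
  c(be32(length(data)), body, crc32_raw(body))
}

write_png16_gray <- function(depth, path) {
  h <- nrow(depth); w <- ncol(depth)
  hi <- matrix(as.raw(depth %/% 256L), h, w)
  lo <- matrix(as.raw(depth %% 256L), h, w)
  scan <- vapply(seq_len(h), function(j)
    c(as.raw(0L), as.vector(rbind(hi[j, ], lo[j, ]))),
    raw(1L + 2L * w))
  stream <- as.vector(scan)
  idat <- memCompress(stream, "gzip")          # zlib stream, valid IDAT
  ihdr <- c(be32(w), be32(h), as.raw(c(16L, 0L, 0L, 0L, 0L)))
  con <- file(path, "wb"); on.exit(close(con))
  writeBin(as.raw(c(0x89, 0x50, 0x4e, 0x47, 0x0d, 0x0a, 0x1a, 0x0a)), con)
  writeBin(png_chunk("IHDR", ihdr), con)
  writeBin(png_chunk("IDAT", idat), con)
  writeBin(png_chunk("IEND", raw(0)), con)
  invisible(path)
}

#' @rdname rgbd_io
#' @export
read_color_png <- function(path) {
  if (!file.exists(path)) stopf("tomstem_io_error", "no such file: %s", path)
  img <- EBImage::imageData(EBImage::readImage(path))
  if (length(dim(img)) == 2L) img <- array(rep(img, 3), c(dim(img), 3))
  aperm(img[, , 1:3, drop = FALSE], c(2, 1, 3))
}

#' @rdname rgbd_io
#' @export
write_color_png <- function(color, path) {
  EBImage::writeImage(EBImage::Image(aperm(color, c(2, 1, 3)),
                                     colormode = "Color"),
                      path, type = "png", bits = 8)
  invisible(path)
}

#' @rdname rgbd_io
#' @export
write_mask_png <- function(mask, path) {
  EBImage::writeImage(EBImage::Image(t(unclass(mask) * 1)), path,
                      type = "png", bits = 8)
  invisible(path)
}

#' @rdname rgbd_io
#' @export
read_mask_png <- function(path) {
  if (!file.exists(path)) stopf("tomstem_io_error", "no such file: %s", path)
  img <- EBImage::imageData(EBImage::readImage(path))
  if (length(dim(img)) == 3L) img <- img[, , 1]
  as_mask(t(img) > 0.5)
}

#' Load an RGB-D pair from a depth and a color PNG
#'
#' @param depth_path 16-bit depth PNG (millimetres).
#' @param color_path 8-bit RGB PNG on the same pixel grid.
#' @return An [rgbd_pair].
#' @export
read_rgbd <- function(depth_path, color_path) {
  rgbd_pair(read_depth_png(depth_path), read_color_png(color_path))
}
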