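#' Texture patch
#'
#' An RGBA image patch of one plant organ: `image` is a `[rows, cols, 4]`
#' array in `[0, 1]` whose alpha channel marks the organ's foreground.
#'
#' @param image RGBA array.
#' @param organ `"stem"`, `"leaf"` or `"compound_leaf"`.
#' @param variety `"cherry"` or `"ordinary"`.
#' @param growth_phase free-form phase label (default `"p1"`).
#' @param source_segment_id optional id of the detected segment the patch
#'   came from.
#' @return Object of class `texture_patch`.
#' @export
texture_patch <- function(image, organ, variety, growth_phase = "p1",
                          source_segment_id = NULL) {
  organ <- match.arg(organ, c("stem", "leaf", "compound_leaf"))
  variety <- match.arg(variety, c("cherry", "ordinary"))
  if (length(dim(image)) != 3L || dim(image)[3] != 4L)
    stopf("tomstem_value_error", "patch image must be [rows, cols, 4] RGBA")
  if (!any(image[, , 4] > 0))
    stopf("tomstem_empty_patch", "patch has empty alpha support")
  structure(list(image = image, organ = organ, variety = variety,
                 growth_phase = growth_phase,
                 source_segment_id = source_segment_id),
            class = "texture_patch")
}

#' Cut a stem texture patch at a detected segment
#'
#' Crops the axis-aligned bounding box of the segment, dilated by
#' `margin_px` and clamped to the image, from the color frame; the alpha
#' channel is the foreground mask restricted to the crop, so background
#' around the stem stays transparent.
#'
#' @param color `[rows, cols, 3]` color array.
#' @param seg a `stem_segment`.
#' @param mask foreground mask (same grid); `NULL` for fully opaque.
#' @param margin_px bounding-box dilation in pixels.
#' @param variety,growth_phase patch metadata.
#' @return A [texture_patch] with `organ = "stem"`.
#' @export
extract_stem_patch <- function(color, seg, mask = NULL, margin_px = 6L,
                               variety = "ordinary", growth_phase = "p1") {
  h <- dim(color)[1]; w <- dim(color)[2]
  cols <- range(seg$p0[1], seg$p1[1]); rows <- range(seg$p0[2], seg$p1[2])
  r0 <- max(1L, floor(rows[1] - margin_px)); r1 <- min(h, ceiling(rows[2] + margin_px))
  c0 <- max(1L, floor(cols[1] - margin_px)); c1 <- min(w, ceiling(cols[2] + margin_px))
  if (r0 > r1 || c0 > c1)
    stopf("tomstem_value_error", "segment outside image bounds")
  crop <- color[r0:r1, c0:c1, , drop = FALSE]
  alpha <- if (is.null(mask)) matrix(1, nrow(crop), ncol(crop))
           else unclass(mask)[r0:r1, c0:c1] * 1
  if (!any(alpha > 0))
    stopf("tomstem_empty_patch", "crop contains no foreground pixels")
  img <- array(0, c(dim(crop)[1:2], 4))
  img[, , 1:3] <- crop; img[, , 4] <- alpha
  texture_patch(img, "stem", variety, growth_phase,
                source_segment_id = seg$id)
}

#' Segment a leaf photographed on a uniform background
#'
#' Color-based segmentation with the excess-green index `ExG = 2G - R - B`
#' (8-bit scale): pixels with `ExG > tau` are leaf candidates, and the
#' largest connected component becomes the alpha support. Works for any
#' uniform background whose ExG stays below `tau`.
#'
#' @param color `[rows, cols, 3]` color array in `[0, 1]`.
#' @param tau ExG threshold on the 0-255 scale.
#' @param organ `"leaf"` or `"compound_leaf"`.
#' @param variety,growth_phase patch metadata.
#' @return A [texture_patch] cropped to the leaf's bounding box.
#' @export
segment_leaf <- function(color, tau = 20, organ = "leaf",
                         variety = "ordinary", growth_phase = "p1") {
  exg <- 255 * (2 * color[, , 2] - color[, , 1] - color[, , 3])
  cand <- exg > tau
  if (!any(cand)) stopf("tomstem_no_leaf", "no pixel passes the ExG threshold")
  lab <- EBImage::bwlabel(EBImage::Image(t(cand * 1)))
  lab <- t(EBImage::imageData(lab))
  sizes <- tabulate(lab[lab > 0])
  keep <- lab == which.max(sizes)
  px <- which(keep, arr.ind = TRUE)
  r <- range(px[, 1]); c <- range(px[, 2])
  img <- array(0, c(diff(r) + 1L, diff(c) + 1L, 4L))
  img[, , 1:3] <- color[r[1]:r[2], c[1]:c[2], ]
  img[, , 4] <- keep[r[1]:r[2], c[1]:c[2]] * 1
  texture_patch(img, organ, variety, growth_phase)
}

#' Open or create an on-disk texture database
#'
#' Layout: `root/<variety>/<organ>/<phase>/NNN.png` (RGBA) with a JSON
#' index at `root/index.json` listing every patch record. Writes are
#' atomic (temp file + rename) and the index always matches the files on
#' disk.
#'
#' @param root database directory (created if missing).
#' @return Object of class `texture_db`.
#' @export
texture_db <- function(root) {
  dir.create(root, recursive = TRUE, showWarnings = FALSE)
  idx_path <- file.path(root, "index.json")
  index <- if (file.exists(idx_path))
    jsonlite::read_json(idx_path, simplifyVector = FALSE) else list()
  structure(list(root = root, index = index), class = "texture_db")
}

db_index_path <- function(db) file.path(db$root, "index.json")

db_files <- function(db, organ, variety) {
  recs <- Filter(function(r) r$organ == organ && r$variety == variety,
                 db$index)
  vapply(recs, function(r) file.path(db$root, r$file), "")
}

#' Write a patch into the database
#'
#' @param db a [texture_db].
#' @param patch a [texture_patch].
#' @return The updated `texture_db` (with the new record appended).
#' @export
db_write <- function(db, patch) {
  sub <- file.path(patch$variety, patch$organ, patch$growth_phase)
  dir.create(file.path(db$root, sub), recursive = TRUE, showWarnings = FALSE)
  nn <- length(db$index) + 1L
  rel <- file.path(sub, sprintf("%03d.png", nn))
  tmp <- file.path(db$root, sprintf(".tmp_%03d.png", nn))
  EBImage::writeImage(EBImage::Image(aperm(patch$image, c(2, 1, 3)),
                                     colormode = "Color"),
                      tmp, type = "png", bits = 8)
  file.rename(tmp, file.path(db$root, rel))
  rec <- list(file = rel, organ = patch$organ, variety = patch$variety,
              phase = patch$growth_phase,
              source_segment_id = patch$source_segment_id)
  db$index[[nn]] <- rec
  jsonlite::write_json(db$index, db_index_path(db), auto_unbox = TRUE,
                       digits = NA, null = "null")
  db
}

#' Sample a patch uniformly from a database category
#'
#' @param db a [texture_db].
#' @param organ,variety category selectors.
#' @param seed integer seed; the same seed always picks the same patch.
#' @return A [texture_patch] re-read from disk.
#' @export
db_sample <- function(db, organ, variety, seed = 1L) {
  files <- db_files(db, organ, variety)
  if (length(files) == 0)
    stopf("tomstem_empty_db", "no '%s' patches for variety '%s'",
          organ, variety)
  pick <- with_seed(seed, sample.int(length(files), 1))
  img <- EBImage::imageData(EBImage::readImage(files[pick]))
  if (length(dim(img)) == 2L) img <- array(c(img, img, img, img * 0 + 1),
                                           c(dim(img), 4))
  if (dim(img)[3] == 3L) img <- array(c(img, img[, , 1] * 0 + 1),
                                      c(dim(img)[1:2], 4))
  texture_patch(aperm(img, c(2, 1, 3)), organ, variety)
}
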