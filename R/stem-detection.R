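#' Parameters for the progressive probabilistic Hough transform
#'
#' The accumulator resolution, vote threshold, minimum segment length and
#' maximum bridgeable gap of the randomized line-segment detector used on
#' skeleton images. The detector samples skeleton points in a random order,
#' so the whole random stream is owned by `seed`: the same seed on the same
#' input yields a byte-identical segment list.
#'
#' The defaults (1 px / 1 degree resolution, 20 votes, 20 px minimum length,
#' 5 px gap at 640x480) deliberately over-detect: canopy and pot false
#' positives are expected here and removed later by the breadth-histogram
#' valley filter, not by any orientation prior.
#'
#' @param rho_px accumulator distance resolution in pixels.
#' @param theta_deg accumulator angle resolution in degrees; must divide 180.
#' @param votes accumulator threshold to trigger a line walk.
#' @param min_len_px minimum Euclidean length of a reported segment.
#' @param max_gap_px largest run of missing pixels bridged along a line.
#' @param seed integer seed owning the point-sampling stream.
#' @return An object of class `ppht_params`.
#' @export
ppht_params <- function(rho_px = 1, theta_deg = 1, votes = 20,
                        min_len_px = 20, max_gap_px = 5, seed = 1L) {
  if (any(c(rho_px, theta_deg, votes, min_len_px, max_gap_px) <= 0))
    stopf("tomstem_value_error", "all PPHT parameters must be positive")
  if (180 %% theta_deg != 0)
    stopf("tomstem_value_error", "theta_deg must divide 180 evenly")
  structure(list(rho_px = rho_px, theta_deg = theta_deg, votes = votes,
                 min_len_px = min_len_px, max_gap_px = max_gap_px,
                 seed = as.integer(seed)),
            class = "ppht_params")
}

new_segment <- function(p0, p1, id = NA_integer_) {
  # canonical ordering: p0 is the upper endpoint (smaller row)
  if (p0[2] > p1[2] || (p0[2] == p1[2] && p0[1] > p1[1])) { t <- p0; p0 <- p1; p1 <- t }
  structure(list(id = id, p0 = as.numeric(p0), p1 = as.numeric(p1),
                 length_px = sqrt(sum((p1 - p0)^2))),
            class = "stem_segment")
}

#' @export
print.stem_segment <- function(x, ...) {
  cat(sprintf("<segment %s> (%g,%g)-(%g,%g) len %.1f px\n",
              x$id, x$p0[1], x$p0[2], x$p1[1], x$p1[2], x$length_px))
  invisible(x)
}

#' Detect candidate stem segments on a skeleton image
#'
#' Progressive probabilistic Hough transform: skeleton points are visited in
#' a seeded random order; each point votes for all quantized line normals
#' through it; when some accumulator bin reaches the vote threshold the
#' corresponding line is walked in both directions along the image raster,
#' bridging gaps up to `max_gap_px`, and the supporting pixels are removed
#' from the image and un-voted. Runs at least `min_len_px` long are reported
#' as segments. This is the canonical progressive variant with immediate
#' line retrieval and un-voting of consumed points.
#'
#' @param skel logical skeleton matrix (see [skeletonize]).
#' @param params a [ppht_params] object.
#' @return A list of `stem_segment` objects in canonical order (sorted by
#'   upper endpoint row, then column), each with fields `id`, `p0 = c(col,
#'   row)`, `p1`, `length_px`. Empty list for an empty skeleton.
#' @export
detect_segments <- function(skel, params = ppht_params()) {
  stopifnot(inherits(params, "ppht_params"))
  img <- unclass(skel) != 0
  pts <- which(img, arr.ind = TRUE)           # [row, col]
  if (nrow(pts) == 0L) return(list())
  h <- nrow(img); w <- ncol(img)

  thetas <- seq(0, 180 - params$theta_deg, by = params$theta_deg) * pi / 180
  nt <- length(thetas)
  ct <- cos(thetas); st <- sin(thetas)
  diag_px <- ceiling(sqrt(h^2 + w^2))
  nr <- 2L * ceiling(diag_px / params$rho_px) + 1L
  r0 <- ceiling(diag_px / params$rho_px) + 1L  # rho = 0 bin
  acc <- matrix(0L, nt, nr)
  voted <- matrix(FALSE, h, w)

  rho_idx <- function(x, y) r0 + as.integer(round((x * ct + y * st) / params$rho_px))

  segs <- list()
  ord <- with_seed(params$seed, sample.int(nrow(pts)))
  for (k in ord) {
    y <- pts[k, 1]; x <- pts[k, 2]
    if (!img[y, x]) next
    idx <- cbind(seq_len(nt), rho_idx(x, y))
    acc[idx] <- acc[idx] + 1L
    voted[y, x] <- TRUE
    vals <- acc[idx]
    if (max(vals) < params$votes) next
    ti <- which.max(vals)                     # line normal angle
    dx <- -st[ti]; dy <- ct[ti]               # direction along the line

    walk <- function(sgn) {
      # follow the raster line from (x, y), collecting present pixels and
      # tolerating up to max_gap_px consecutive misses
      hits <- matrix(integer(0), 0, 2)
      gap <- 0L; t <- 0
      repeat {
        t <- t + 1
        px <- as.integer(round(x + sgn * t * dx))
        py <- as.integer(round(y + sgn * t * dy))
        if (px < 1 || px > w || py < 1 || py > h) break
        found <- FALSE
        if (img[py, px]) { found <- TRUE } else {
          # skeleton pixels rattle around the ideal line by up to a pixel
          for (o in list(c(0L, 1L), c(0L, -1L), c(1L, 0L), c(-1L, 0L))) {
            qy <- py + o[1]; qx <- px + o[2]
            if (qy >= 1 && qy <= h && qx >= 1 && qx <= w && img[qy, qx] &&
                abs((qx - x) * dy - (qy - y) * dx) <= 1) {
              py <- qy; px <- qx; found <- TRUE; break
            }
          }
        }
        if (found) { gap <- 0L; hits <- rbind(hits, c(py, px)) }
        else { gap <- gap + 1L; if (gap > params$max_gap_px) break }
      }
      hits
    }
    up <- walk(-1); down <- walk(1)
    line <- rbind(up[rev(seq_len(nrow(up))), , drop = FALSE],
                  c(y, x), down)

    # consume the supporting pixels: remove from image, cancel their votes
    for (i in seq_len(nrow(line))) {
      py <- line[i, 1]; px <- line[i, 2]
      if (!img[py, px]) next
      img[py, px] <- FALSE
      if (voted[py, px]) {
        j <- cbind(seq_len(nt), rho_idx(px, py))
        acc[j] <- acc[j] - 1L
      }
    }
    a <- line[1, ]; b <- line[nrow(line), ]
    if (sqrt(sum((a - b)^2)) >= params$min_len_px)
      segs[[length(segs) + 1L]] <- new_segment(c(a[2], a[1]), c(b[2], b[1]))
  }

  if (length(segs)) {
    o <- order(vapply(segs, function(s) s$p0[2], 0),
               vapply(segs, function(s) s$p0[1], 0),
               vapply(segs, function(s) s$p1[2], 0))
    segs <- segs[o]
    for (i in seq_along(segs)) segs[[i]]$id <- i
  }
  segs
}

#' Serialize / deserialize detected segments as JSON
#'
#' Each segment becomes `{"id", "p0": [col, row], "p1": [col, row],
#' "length_px"}`.
#'
#' @param segs list of `stem_segment` objects.
#' @param path JSON file path.
#' @return `segments_to_json` returns `path` invisibly;
#'   `segments_from_json` returns the segment list.
#' @export
segments_to_json <- function(segs, path) {
  out <- lapply(segs, function(s)
    list(id = s$id, p0 = s$p0, p1 = s$p1, length_px = s$length_px))
  jsonlite::write_json(out, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname segments_to_json
#' @export
segments_from_json <- function(path) {
  raw <- jsonlite::read_json(path, simplifyVector = TRUE)
  if (length(raw) == 0 || (is.data.frame(raw) && nrow(raw) == 0)) return(list())
  lapply(seq_len(nrow(raw)), function(i)
    new_segment(unlist(raw$p0[i]), unlist(raw$p1[i]), id = raw$id[i]))
}
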