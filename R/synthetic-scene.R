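#' Pinhole camera model of the depth sensor
#'
#' Defaults emulate a first-generation structured-light depth camera at VGA
#' resolution (640x480, ~575 px focal length) with the potted plant
#' standing 0.9-1.0 m away, the acquisition geometry the detection pipeline
#' is designed for.
#'
#' @param width,height image size in pixels.
#' @param focal_px focal length in pixels (same for both axes).
#' @param cx,cy principal point (defaults to the image centre).
#' @param distance_mm camera-to-plant-axis distance.
#' @return Object of class `camera_model`.
#' @export
camera_model <- function(width = 640L, height = 480L, focal_px = 575,
                         cx = width / 2, cy = height / 2,
                         distance_mm = 950) {
  if (focal_px <= 0) stopf("tomstem_value_error", "focal_px must be > 0")
  structure(list(width = as.integer(width), height = as.integer(height),
                 focal_px = focal_px, cx = cx, cy = cy,
                 distance_mm = distance_mm),
            class = "camera_model")
}

#' Depth noise model
#'
#' Reproduces the characteristic degradations of consumer structured-light
#' depth maps that leave plant masks sparse and fragmented: per-pixel
#' dropout (depth reads 0), millimetre quantization of the range values and
#' erosion of silhouette edges where the projected pattern is lost.
#'
#' @param dropout_prob per-pixel probability of losing the reading.
#' @param quant_mm depth quantization step in millimetres.
#' @param edge_erosion_px silhouette erosion radius in pixels.
#' @param seed integer seed of the dropout pattern.
#' @return Object of class `noise_model`.
#' @export
noise_model <- function(dropout_prob = 0.05, quant_mm = 2,
                        edge_erosion_px = 1L, seed = 1L) {
  if (dropout_prob < 0 || dropout_prob >= 1)
    stopf("tomstem_value_error", "dropout_prob must lie in [0, 1)")
  if (quant_mm < 1) stopf("tomstem_value_error", "quant_mm must be >= 1")
  structure(list(dropout_prob = dropout_prob, quant_mm = quant_mm,
                 edge_erosion_px = as.integer(edge_erosion_px),
                 seed = as.integer(seed)),
            class = "noise_model")
}

# --- surface point sampling ------------------------------------------------
# Primitives are rasterized by sampling their surfaces at ~step cm spacing
# (finer than one pixel at 1 m) and z-buffering the projected points.

sample_cylinder <- function(base, frame, len, r, step) {
  if (len <= 0) return(NULL)
  nl <- max(2L, ceiling(len / step))
  na <- max(6L, ceiling(2 * pi * max(r, step) / step))
  t <- seq(0, len, length.out = nl)
  th <- seq(0, 2 * pi, length.out = na + 1L)[-(na + 1L)]
  g <- expand.grid(t = t, th = th)
  sweep(outer(g$t, frame[, 1]) + outer(r * cos(g$th), frame[, 2]) +
          outer(r * sin(g$th), frame[, 3]), 2, base, "+")
}

sample_sphere <- function(center, r, step) {
  n <- max(8L, ceiling(pi * r / step))
  la <- seq(0, pi, length.out = n)
  pts <- NULL
  for (a in la) {
    m <- max(3L, ceiling(2 * pi * r * sin(a) / step))
    th <- seq(0, 2 * pi, length.out = m + 1L)[-(m + 1L)]
    pts <- rbind(pts, cbind(r * sin(a) * cos(th), r * sin(a) * sin(th),
                            r * cos(a)))
  }
  sweep(pts, 2, center, "+")
}

sample_cone <- function(base, r0, r1, hgt, step) {
  nl <- max(2L, ceiling(hgt / step))
  t <- seq(0, 1, length.out = nl)
  pts <- NULL
  for (ti in t) {
    r <- r0 + ti * (r1 - r0)
    m <- max(8L, ceiling(2 * pi * r / step))
    th <- seq(0, 2 * pi, length.out = m + 1L)[-(m + 1L)]
    pts <- rbind(pts, cbind(r * cos(th), r * sin(th), rep(ti * hgt, m)))
  }
  sweep(pts, 2, base, "+")
}

sample_leaf_surface <- function(base, frame, size, step) {
  ctrl <- leaf_control_grid(size)
  n <- max(4L, ceiling(size / step))
  t <- seq(0, 1, length.out = n)
  Bu <- bernstein3(t); Bv <- bernstein3(t)
  px <- Bu %*% ctrl[, , 1] %*% t(Bv)
  py <- Bu %*% ctrl[, , 2] %*% t(Bv)
  pz <- Bu %*% ctrl[, , 3] %*% t(Bv)
  local <- cbind(as.numeric(px), as.numeric(py), as.numeric(pz))
  sweep(local %*% t(frame), 2, base, "+")
}

sample_node_points <- function(n, step) {
  switch(n$kind,
         stem = ,
         stalk = sample_cylinder(n$base, n$frame, n$len, n$r0, step),
         pot = sample_cone(n$base, n$r0, n$r1, n$len, step),
         leaf = sample_leaf_surface(n$base, n$frame, n$size, step),
         fruit = ,
         bud = sample_sphere(n$base + n$frame[, 1] * n$size, n$size, step),
         flower = sample_sphere(n$base + n$frame[, 1] * 0.5, n$size / 2, step),
         NULL)
}

#' Render a scene graph into a synthetic RGB-D pair with ground truth
#'
#' Surface points of every primitive are projected through the pinhole
#' model onto a z-buffer; depth is reported in millimetres, quantized to
#' `quant_mm`, with silhouette edges eroded and a seeded dropout pattern
#' setting pixels to 0 (no reading). The color channel renders each
#' organ's diffuse color over a black (depth-0) background. The returned
#' ground truth contains the projected main-stem axis polylines.
#'
#' The scene's world frame is x right, y toward the camera, z up; the
#' camera looks along -y from `distance_mm`, vertically centred on the
#' scene bounding box.
#'
#' @param scene a `scene_graph`.
#' @param cam a [camera_model].
#' @param noise a [noise_model]; use `dropout_prob = 0`,
#'   `edge_erosion_px = 0` for clean renders.
#' @param step_cm surface sampling pitch.
#' @return List with `pair` (an [rgbd_pair]) and `truth` (a
#'   [ground_truth]).
#' @export
render_rgbd <- function(scene, cam = camera_model(),
                        noise = noise_model(), step_cm = 0.12) {
  bb <- scene_bbox(scene)
  z_eye <- mean(bb[, 3])
  dist_cm <- cam$distance_mm / 10
  fx <- cam$focal_px

  project <- function(pts) {
    zc <- dist_cm - pts[, 2]
    if (any(zc <= 1))
      stopf("tomstem_projection_error", "scene reaches behind the camera")
    list(col = round(fx * pts[, 1] / zc + cam$cx),
         row = round(fx * (z_eye - pts[, 3]) / zc + cam$cy),
         depth_mm = zc * 10)
  }

  h <- cam$height; w <- cam$width
  depth <- matrix(0, h, w)
  colr <- matrix(0, h, w); colg <- matrix(0, h, w); colb <- matrix(0, h, w)
  all_pts <- NULL; all_col <- NULL
  for (n in scene$nodes) {
    pts <- sample_node_points(n, step_cm)
    if (is.null(pts) || nrow(pts) == 0) next
    all_pts <- rbind(all_pts, pts)
    all_col <- rbind(all_col, matrix(n$color, nrow(pts), 3, byrow = TRUE))
  }
  if (!is.null(all_pts)) {
    pr <- project(all_pts)
    keep <- pr$col >= 1 & pr$col <= w & pr$row >= 1 & pr$row <= h
    idx <- (pr$col[keep] - 1) * h + pr$row[keep]
    d <- pr$depth_mm[keep]; cl <- all_col[keep, , drop = FALSE]
    ord <- order(d, decreasing = TRUE)       # nearest point written last
    depth[idx[ord]] <- d[ord]
    colr[idx[ord]] <- cl[ord, 1]; colg[idx[ord]] <- cl[ord, 2]
    colb[idx[ord]] <- cl[ord, 3]
  }

  depth <- round(depth / noise$quant_mm) * noise$quant_mm
  if (noise$edge_erosion_px > 0) {
    br <- EBImage::makeBrush(2L * noise$edge_erosion_px + 1L, "box")
    er <- t(EBImage::imageData(EBImage::erode(EBImage::Image(t((depth > 0) * 1)), br)))
    depth[er < 0.5] <- 0
  }
  if (noise$dropout_prob > 0) {
    nz <- which(depth > 0)
    drop <- with_seed(noise$seed, nz[runif(length(nz)) < noise$dropout_prob])
    depth[drop] <- 0
  }
  colr[depth == 0] <- 0; colg[depth == 0] <- 0; colb[depth == 0] <- 0
  storage.mode(depth) <- "integer"

  stems <- Filter(function(n) isTRUE(n$is_main_stem), scene$nodes)
  groups <- split(stems, vapply(stems, function(n) n$stem_group %||% 1L, 0L))
  polylines <- lapply(groups, function(g) {
    g <- g[order(vapply(g, `[[`, 0L, "id"))]
    pts <- do.call(rbind, lapply(g, function(n) rbind(n$base)))
    last <- g[[length(g)]]
    pts <- rbind(pts, last$base + last$frame[, 1] * last$len)
    pr <- project(pts)
    cbind(pr$col, pr$row)
  })

  list(pair = rgbd_pair(depth,
                        array(c(colr, colg, colb), c(h, w, 3))),
       truth = ground_truth(unname(polylines)))
}

#' Parametric potted-tomato scene with the fat-thin-fat silhouette
#'
#' Builds a scene graph directly (no L-system) that reproduces the
#' geometry the stem detector targets: a wide pot at the bottom, one to
#' three bare near-vertical main stems through a thin waist, and a dense
#' leaf canopy on top -- the bimodal "fat-thin-fat" breadth profile of a
#' potted tomato seen from the side. The `hard` difficulty thins the
#' canopy; sensor degradation is chosen separately via [noise_model].
#'
#' @param variety `"cherry"` (smaller leaves) or `"ordinary"`.
#' @param seed integer seed for the structural draw.
#' @param difficulty `"easy"` (dense canopy, clear waist) or `"hard"`
#'   (sparse, partial canopy).
#' @return A `scene_graph` whose main-stem nodes carry ground-truth flags.
#' @export
potted_plant_scene <- function(variety = c("ordinary", "cherry"), seed = 1L,
                               difficulty = c("easy", "hard")) {
  variety <- match.arg(variety)
  difficulty <- match.arg(difficulty)
  nodes <- list()
  add <- function(n) { n$id <- length(nodes) + 1L; nodes[[n$id]] <<- n; n$id }
  blank <- list(kind = "ground", letter = "", base = c(0, 0, 0),
                frame = diag(3), len = 0, r0 = 0, r1 = 0, size = 0,
                color = c(0, 0, 0), age = Inf, texture = NULL, parent = 0L,
                depth = 0L, branch_path = integer(0), is_main_stem = FALSE)
  root <- add(blank)

  with_seed(seed, {
    # squat pot, long bare waist, dense canopy: the pot reads as a compact
    # bottom peak of the breadth histogram, the waist as a long thin valley
    pot_h <- 9; pot_r <- 10
    pot <- blank
    pot$kind <- "pot"; pot$len <- pot_h; pot$r0 <- 7; pot$r1 <- pot_r
    pot$color <- c(0.6, 0.33, 0.18); pot$parent <- root
    add(pot)

    n_stems <- sample(1:3, 1, prob = c(0.25, 0.5, 0.25))
    stem_len <- runif(1, 32, 40)
    canopy_lo <- pot_h + 0.6 * stem_len
    canopy_hi <- pot_h + stem_len + 8

    up <- function(tilt_deg, az) {
      h <- c(sin(tilt_deg * pi / 180) * cos(az),
             sin(tilt_deg * pi / 180) * sin(az), cos(tilt_deg * pi / 180))
      l <- c(cos(az + pi / 2), sin(az + pi / 2), 0)
      u <- c(h[2] * l[3] - h[3] * l[2], h[3] * l[1] - h[1] * l[3],
             h[1] * l[2] - h[2] * l[1])
      cbind(h, l, u)
    }
    for (si in seq_len(n_stems)) {
      # stems lean visibly to one side of the gravity axis, as trained
      # greenhouse stems do, so valley rows keep a small non-zero breadth
      # (a stem dead on the axis column would read as an empty row)
      off_x <- sample(c(-1, 1), 1) * runif(1, 1.5, 3.5)
      stm <- blank
      stm$kind <- "stem"; stm$letter <- "F"
      stm$base <- c(off_x, runif(1, -2, 2), pot_h)
      stm$frame <- up(runif(1, 1.5, 3.5), runif(1, 0, 2 * pi))
      stm$len <- stem_len + runif(1, -2, 2)
      # the first stem is mature and thick enough for reliable capture;
      # additional stems vary in maturity down to the sensor's thin-structure
      # limit, the marginal cases behind the detection trade-off
      r <- if (si == 1L) runif(1, 0.5, 0.6) else runif(1, 0.3, 0.55)
      stm$r0 <- r; stm$r1 <- 0.9 * r
      stm$color <- c(0.45, 0.55, 0.3); stm$parent <- root
      stm$is_main_stem <- TRUE; stm$stem_group <- si
      add(stm)
    }

    n_leaf <- if (difficulty == "easy") 130L else 55L
    leaf_sz <- if (variety == "cherry") c(3.5, 5) else c(4.5, 6.5)
    for (k in seq_len(n_leaf)) {
      u <- c(runif(1, -1, 1), runif(1, -1, 1), runif(1, -1, 1))
      u <- u / max(sqrt(sum(u^2)), 1e-9) * runif(1)^(1 / 3)
      ctr <- c(u[1] * 16, u[2] * 9,
               (canopy_lo + canopy_hi) / 2 + u[3] * (canopy_hi - canopy_lo) / 2)
      lf <- blank
      lf$kind <- "leaf"; lf$letter <- "L"
      lf$base <- ctr
      lf$frame <- up(runif(1, 20, 90), runif(1, 0, 2 * pi))
      lf$size <- runif(1, leaf_sz[1], leaf_sz[2])
      lf$color <- c(0.15 + runif(1, 0, 0.1), 0.45 + runif(1, 0, 0.2), 0.15)
      lf$parent <- root
      add(lf)
    }
    # short lateral branchlets inside the canopy: realistic line features
    for (k in seq_len(5L)) {
      br <- blank
      br$kind <- "stem"; br$letter <- "f"
      br$base <- c(runif(1, -8, 8), runif(1, -5, 5),
                   runif(1, canopy_lo + 2, canopy_hi - 6))
      br$frame <- up(runif(1, 50, 90), runif(1, 0, 2 * pi))
      br$len <- runif(1, 6, 12); br$r0 <- 0.35; br$r1 <- 0.3
      br$color <- c(0.42, 0.5, 0.28); br$parent <- root
      add(br)
    }
  })
  structure(list(nodes = nodes, gp = NULL, variety = variety),
            class = "scene_graph")
}

#' Generate a benchmark dataset of synthetic RGB-D scenes
#'
#' Renders `n_scenes` potted-plant scenes into a dataset directory:
#' `depth_NNN.png` (16-bit, millimetres), `color_NNN.png`, `gt_NNN.json`
#' (main-stem polylines) and `manifest.json` recording every per-scene
#' seed, so the dataset is byte-reproducible from the manifest. `easy`
#' scenes have a dense canopy, a clear thin waist and 5% dropout; `hard`
#' scenes a sparse canopy and 20% dropout. The camera-to-plant distance is
#' drawn per scene from 900-1000 mm.
#'
#' @param variety `"cherry"` or `"ordinary"`.
#' @param n_scenes number of scenes (>= 1).
#' @param difficulty `"easy"` or `"hard"`.
#' @param seed master seed; scene k uses `seed * 1000 + k`.
#' @param out_dir dataset directory (created).
#' @return The manifest, invisibly.
#' @export
make_benchmark <- function(variety = c("ordinary", "cherry"), n_scenes = 5L,
                           difficulty = c("easy", "hard"), seed = 1L,
                           out_dir) {
  variety <- match.arg(variety)
  difficulty <- match.arg(difficulty)
  stopifnot(n_scenes >= 1)
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  entries <- list()
  for (k in seq_len(n_scenes)) {
    sk <- as.integer(seed) * 1000L + k
    scene <- potted_plant_scene(variety, seed = sk, difficulty = difficulty)
    cam <- camera_model(distance_mm = with_seed(sk + 1L, runif(1, 900, 1000)))
    nm <- noise_model(dropout_prob = if (difficulty == "easy") 0.05 else 0.2,
                      quant_mm = 2, edge_erosion_px = 1L, seed = sk + 2L)
    r <- render_rgbd(scene, cam, nm)
    fd <- sprintf("depth_%03d.png", k); fc <- sprintf("color_%03d.png", k)
    fg <- sprintf("gt_%03d.json", k)
    write_depth_png(r$pair$depth, file.path(out_dir, fd))
    write_color_png(r$pair$color, file.path(out_dir, fc))
    r$truth$image_id <- sprintf("%03d", k)
    gt_to_json(r$truth, file.path(out_dir, fg))
    entries[[k]] <- list(depth = fd, color = fc, gt = fg, seed = sk,
                         distance_mm = cam$distance_mm)
  }
  manifest <- list(variety = variety, difficulty = difficulty,
                   n_scenes = n_scenes, seed = seed, scenes = entries)
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(manifest)
}
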