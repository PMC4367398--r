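#' Geometric interpretation parameters
#'
#' All lengths are centimetres, angles degrees. The turtle defaults follow
#' typical indeterminate tomato habit: ~5 cm internodes, 40 degree branch
#' insertion, 30 degree leaf insertion, 137.5 degree roll between
#' successive branches (phyllotactic spacing around the stem) and a slight
#' random deflection of the main stem per growth stage. `jitter` holds the
#' ranges of the four stochastic perturbation mechanisms applied during
#' rendering: (1) leaf/flower stalk insertion angle, (2) azimuthal position
#' of each branch around the main stem, (3) lateral branch length scale,
#' (4) leaf count on a branch (random leaf drop). All randomness flows from
#' `seed`; zero-width ranges give the identity.
#'
#' @param internode_cm main-stem internode length.
#' @param radius_cm main-stem radius; decays by `radius_decay` per
#'   branching depth.
#' @param radius_decay multiplicative radius decay per bracket depth.
#' @param branch_angle_deg default `&` rotation (branch insertion).
#' @param leaf_angle_deg default `#` rotation (leaf insertion).
#' @param plus_minus_deg default `+`/`-` rotation.
#' @param roll_deg default `/` roll about the heading.
#' @param main_deflect_deg upper bound of the per-stage random main-stem
#'   deflection (0 disables it).
#' @param curvature_coef branch bending, degrees of downward tip deflection
#'   per cm of branch length (0 disables bending).
#' @param curvature_cap_deg bending cap.
#' @param leaf_cm,fruit_cm,stalk_cm organ sizes at maturity.
#' @param pot_height_cm,pot_radius_cm pot dimensions (ordinary variety).
#' @param jitter list of perturbation ranges: `stalk_angle_deg`,
#'   `branch_roll_deg`, `branch_len_frac`, `leaf_drop_prob`.
#' @param seed integer seed owning all interpretation randomness.
#' @return Object of class `geom_params`.
#' @export
geom_params <- function(internode_cm = 5, radius_cm = 0.5,
                        radius_decay = 0.92,
                        branch_angle_deg = 40, leaf_angle_deg = 30,
                        plus_minus_deg = 25, roll_deg = 137.5,
                        main_deflect_deg = 3,
                        curvature_coef = 1.5, curvature_cap_deg = 85,
                        leaf_cm = 6, fruit_cm = 2, stalk_cm = 2.5,
                        pot_height_cm = 12, pot_radius_cm = 10,
                        jitter = list(stalk_angle_deg = 8,
                                      branch_roll_deg = 25,
                                      branch_len_frac = 0.15,
                                      leaf_drop_prob = 0.1),
                        seed = 1L) {
  for (a in c(branch_angle_deg, leaf_angle_deg, plus_minus_deg))
    if (a <= 0 || a >= 180)
      stopf("tomstem_value_error", "insertion angles must lie in (0, 180)")
  if (curvature_coef < 0)
    stopf("tomstem_value_error", "curvature_coef must be >= 0")
  structure(list(internode_cm = internode_cm, radius_cm = radius_cm,
                 radius_decay = radius_decay,
                 branch_angle_deg = branch_angle_deg,
                 leaf_angle_deg = leaf_angle_deg,
                 plus_minus_deg = plus_minus_deg, roll_deg = roll_deg,
                 main_deflect_deg = main_deflect_deg,
                 curvature_coef = curvature_coef,
                 curvature_cap_deg = curvature_cap_deg,
                 leaf_cm = leaf_cm, fruit_cm = fruit_cm,
                 stalk_cm = stalk_cm,
                 pot_height_cm = pot_height_cm, pot_radius_cm = pot_radius_cm,
                 jitter = jitter, seed = as.integer(seed)),
            class = "geom_params")
}

#' Reseed the stochastic rendering mechanisms
#'
#' Returns a copy of `gp` whose perturbation stream is owned by `seed`.
#' Exactly four quantities are perturbed during interpretation, each within
#' its configured range: stalk insertion angles, branch azimuth around the
#' main stem, lateral branch lengths, and the number of leaves per branch.
#'
#' @param gp a [geom_params].
#' @param seed integer seed.
#' @return The perturbed-input parameter set.
#' @export
randomize_geometry <- function(gp, seed) {
  gp$seed <- as.integer(seed)
  gp
}

rot_about <- function(axis, theta_deg) {
  a <- axis / sqrt(sum(axis^2))
  th <- theta_deg * pi / 180
  c_ <- cos(th); s_ <- sin(th); C <- 1 - c_
  matrix(c(a[1]^2 * C + c_,        a[1] * a[2] * C + a[3] * s_, a[1] * a[3] * C - a[2] * s_,
           a[1] * a[2] * C - a[3] * s_, a[2]^2 * C + c_,        a[2] * a[3] * C + a[1] * s_,
           a[1] * a[3] * C + a[2] * s_, a[2] * a[3] * C - a[1] * s_, a[3]^2 * C + c_),
         3, 3)
}

# growth factor: organ size relative to its mature size
growth_scale <- function(age, maturity) {
  if (!is.finite(age)) 1 else min(1, (age + 1) / (maturity + 1))
}

#' Smooth green-to-red ripening color of a fruit
#'
#' Linear hue interpolation on the HSV circle from green (120 degrees) at
#' age 0 down to red (0 degrees) at `max_age`; ages beyond `max_age` clamp
#' to red. The hue is strictly decreasing in age, so a riper fruit is
#' always redder.
#'
#' @param age integer fruit age (>= 0).
#' @param max_age age at full ripeness.
#' @return Numeric RGB triple in `[0, 1]`.
#' @export
ripen_color <- function(age, max_age = 6) {
  stopifnot(age >= 0, max_age > 0)
  f <- min(1, age / max_age)
  hue <- (1 - f) * 120 / 360
  as.numeric(grDevices::col2rgb(grDevices::hsv(hue, 0.85, 0.9))) / 255
}

#' Interpret an L-string as a 3D scene graph
#'
#' Standard turtle interpretation: the turtle carries an orthonormal
#' heading/left/up frame; `F`, `S`, `f`, `h` extrude tapered stem
#' internodes and advance the turtle; `P`/`Y` extrude thin stalks; `L`/`l`
#' emit Bezier-surface leaves (never flat planes), `G` fruit spheres with
#' ripening color, `H` flowers, `y` buds; `[`/`]` push and pop the state to
#' form branching structures; `+ - & # /` rotate the frame by their
#' parameter or the configured default. Control characters have no
#' geometric entity. Organ sizes scale with the age parameter, so a growth
#' sequence renders as a plant that gets taller and fuller. A ground root
#' node anchors the graph; the ordinary variety also gets a pot.
#'
#' @param s a bracket-balanced `lstring`.
#' @param gp a [geom_params].
#' @return Object of class `scene_graph`: list with `nodes` (list of organ
#'   primitives, each with kind, base, frame, dimensions, color, parent,
#'   bracket depth and branch path) and `gp`.
#' @export
interpret_lstring <- function(s, gp = geom_params()) {
  stopifnot(inherits(s, "lstring"))
  if (!lstring_balanced(s))
    stopf("tomstem_structure_error", "unbalanced L-string")
  variety <- attr(s, "variety") %||% "ordinary"
  mat <- default_maturity()
  jt <- gp$jitter

  nodes <- list()
  add_node <- function(kind, letter, base, frame, len = 0, r0 = 0, r1 = 0,
                       size = 0, color = c(0.4, 0.6, 0.3), age = Inf,
                       parent, depth, branch_path, is_main = FALSE) {
    id <- length(nodes) + 1L
    nodes[[id]] <<- list(id = id, kind = kind, letter = letter, base = base,
                         frame = frame, len = len, r0 = r0, r1 = r1,
                         size = size, color = color, age = age,
                         texture = NULL, parent = parent, depth = depth,
                         branch_path = branch_path, is_main_stem = is_main)
    id
  }

  root <- add_node("ground", "", c(0, 0, 0), diag(3), parent = 0L,
                   depth = 0L, branch_path = integer(0))
  base_z <- 0
  if (identical(variety, "ordinary")) {
    add_node("pot", "", c(0, 0, 0), diag(3), len = gp$pot_height_cm,
             r0 = 0.8 * gp$pot_radius_cm, r1 = gp$pot_radius_cm,
             color = c(0.65, 0.35, 0.2), parent = root, depth = 0L,
             branch_path = integer(0))
    base_z <- gp$pot_height_cm
  }

  with_seed(gp$seed, {
    st <- list(pos = c(0, 0, base_z),
               frame = cbind(c(0, 0, 1), c(1, 0, 0), c(0, 1, 0)),  # H, L, U
               parent = root, depth = 0L, branch_path = integer(0),
               len_scale = 1)
    stack <- list()
    branch_counter <- 0L
    stem_color <- c(0.38, 0.5, 0.25)

    for (tk in s) {
      letter <- tk$letter
      p1 <- if (length(tk$params)) tk$params[1] else NA_real_
      if (letter == "[") {
        stack[[length(stack) + 1L]] <- st
        branch_counter <- branch_counter + 1L
        st$depth <- st$depth + 1L
        st$branch_path <- c(st$branch_path, branch_counter)
        if (jt$branch_len_frac > 0)
          st$len_scale <- st$len_scale *
            (1 + runif(1, -jt$branch_len_frac, jt$branch_len_frac))
      } else if (letter == "]") {
        st <- stack[[length(stack)]]
        stack[[length(stack)]] <- NULL
      } else if (letter == "+") {
        st$frame <- rot_about(st$frame[, 3], if (is.na(p1)) gp$plus_minus_deg else p1) %*% st$frame
      } else if (letter == "-") {
        st$frame <- rot_about(st$frame[, 3], -(if (is.na(p1)) gp$plus_minus_deg else p1)) %*% st$frame
      } else if (letter == "&") {
        ang <- (if (is.na(p1)) gp$branch_angle_deg else p1) +
          (if (jt$stalk_angle_deg > 0) runif(1, -jt$stalk_angle_deg, jt$stalk_angle_deg) else 0)
        st$frame <- rot_about(st$frame[, 2], ang) %*% st$frame
      } else if (letter == "#") {
        ang <- (if (is.na(p1)) gp$leaf_angle_deg else p1) +
          (if (jt$stalk_angle_deg > 0) runif(1, -jt$stalk_angle_deg, jt$stalk_angle_deg) else 0)
        st$frame <- rot_about(st$frame[, 2], ang) %*% st$frame
      } else if (letter == "/") {
        ang <- (if (is.na(p1)) gp$roll_deg else p1) +
          (if (jt$branch_roll_deg > 0) runif(1, -jt$branch_roll_deg, jt$branch_roll_deg) else 0)
        st$frame <- rot_about(st$frame[, 1], ang) %*% st$frame
      } else if (letter %in% c("F", "S", "f", "h")) {
        lscale <- switch(letter, F = 1, S = 0.5, f = 0.8, h = 0.8)
        len <- gp$internode_cm * lscale * growth_scale(p1, mat[[letter]]) *
          st$len_scale
        r <- gp$radius_cm * gp$radius_decay^st$depth
        id <- add_node("stem", letter, st$pos, st$frame, len = len,
                       r0 = r, r1 = 0.85 * r, color = stem_color, age = p1,
                       parent = st$parent, depth = st$depth,
                       branch_path = st$branch_path,
                       is_main = letter == "F" && st$depth == 0L)
        st$pos <- st$pos + st$frame[, 1] * len
        st$parent <- id
      } else if (letter %in% c("P", "Y")) {
        len <- gp$stalk_cm * growth_scale(p1, 3)
        id <- add_node("stalk", letter, st$pos, st$frame, len = len,
                       r0 = 0.08, r1 = 0.06, color = c(0.45, 0.55, 0.3),
                       age = p1, parent = st$parent, depth = st$depth,
                       branch_path = st$branch_path)
        st$pos <- st$pos + st$frame[, 1] * len
        st$parent <- id
      } else if (letter %in% c("L", "l")) {
        if (jt$leaf_drop_prob > 0 && runif(1) < jt$leaf_drop_prob) next
        size <- gp$leaf_cm * (if (letter == "l") 0.8 else 1) *
          growth_scale(p1, mat[[letter]])
        add_node("leaf", letter, st$pos, st$frame, size = size,
                 color = c(0.2, 0.55, 0.2), age = p1, parent = st$parent,
                 depth = st$depth, branch_path = st$branch_path)
      } else if (letter == "G") {
        size <- gp$fruit_cm * growth_scale(p1, mat[["G"]])
        add_node("fruit", letter, st$pos, st$frame, size = size,
                 color = ripen_color(if (is.finite(p1)) p1 else mat[["G"]],
                                     mat[["G"]]),
                 age = p1, parent = st$parent, depth = st$depth,
                 branch_path = st$branch_path)
      } else if (letter == "H") {
        add_node("flower", letter, st$pos, st$frame, size = 1.2,
                 color = c(1, 0.88, 0.25), age = p1, parent = st$parent,
                 depth = st$depth, branch_path = st$branch_path)
      } else if (letter == "y") {
        add_node("bud", letter, st$pos, st$frame, size = 0.4,
                 color = c(0.3, 0.6, 0.25), age = p1, parent = st$parent,
                 depth = st$depth, branch_path = st$branch_path)
      }
      # control characters A, B, C, D: no geometric entity
    }
  })
  structure(list(nodes = nodes, gp = gp, variety = variety),
            class = "scene_graph")
}

#' @export
print.scene_graph <- function(x, ...) {
  kinds <- table(vapply(x$nodes, `[[`, "", "kind"))
  cat("<scene_graph>", paste(names(kinds), kinds, sep = ":", collapse = " "),
      "\n")
  invisible(x)
}

scene_bbox <- function(scene) {
  pts <- do.call(rbind, lapply(scene$nodes, function(n)
    rbind(n$base, n$base + n$frame[, 1] * n$len)))
  rbind(apply(pts, 2, min), apply(pts, 2, max))
}

#' Bend branches downward and wobble the main stem
#'
#' Real lateral branches sag under their own weight: every branch is bent
#' toward gravity by a tip deflection equal to `curvature_coef` degrees per
#' cm of branch length, capped at `curvature_cap_deg`, so longer branches
#' always sag more. The main stem, loaded unevenly by its branches, is
#' additionally deflected by a small random angle (up to
#' `main_deflect_deg`) at each internode. Both effects are rigid subtree
#' rotations, reproducible under the parameter seed; with
#' `curvature_coef = 0` and `main_deflect_deg = 0` the scene is returned
#' unchanged.
#'
#' @param scene a [interpret_lstring] scene graph.
#' @param gp a [geom_params]; defaults to the scene's own.
#' @return The bent `scene_graph`.
#' @export
apply_bending <- function(scene, gp = scene$gp) {
  nodes <- scene$nodes
  rotate_subtree <- function(ids, origin, R) {
    for (i in ids) {
      nodes[[i]]$base <<- as.numeric(origin + R %*% (nodes[[i]]$base - origin))
      nodes[[i]]$frame <<- R %*% nodes[[i]]$frame
    }
  }
  if (gp$curvature_coef > 0) {
    paths <- lapply(nodes, `[[`, "branch_path")
    branch_ids <- sort(unique(unlist(paths)))
    for (b in branch_ids) {
      members <- which(vapply(paths, function(p) b %in% p, NA))
      if (length(members) == 0) next
      root <- nodes[[min(members)]]
      own <- members[vapply(members, function(i)
        tail(nodes[[i]]$branch_path, 1) == b &&
          nodes[[i]]$kind %in% c("stem", "stalk"), NA)]
      blen <- sum(vapply(own, function(i) nodes[[i]]$len, 0))
      if (blen <= 0) next
      theta <- min(gp$curvature_cap_deg, gp$curvature_coef * blen)
      h0 <- root$frame[, 1]
      axis <- c(-h0[2], h0[1], 0)                  # h0 x down, down = -z
      if (sqrt(sum(axis^2)) < 1e-9) axis <- root$frame[, 2]
      rotate_subtree(members, root$base, rot_about(axis, theta))
    }
  }
  if (gp$main_deflect_deg > 0) {
    main_ids <- which(vapply(nodes, function(n)
      isTRUE(n$is_main_stem) && n$kind == "stem", NA))
    with_seed(gp$seed + 1L, {
      for (k in main_ids) {
        theta <- runif(1, 0, gp$main_deflect_deg)
        az <- runif(1, 0, 2 * pi)
        above <- which(vapply(nodes, function(n) n$id > k &&
                                !n$kind %in% c("ground", "pot"), NA))
        tip <- nodes[[k]]$base + nodes[[k]]$frame[, 1] * nodes[[k]]$len
        rotate_subtree(above, tip, rot_about(c(cos(az), sin(az), 0), theta))
      }
    })
  }
  scene$nodes <- nodes
  scene
}

#' Map database textures onto a scene graph
#'
#' Every stem internode references a stem texture patch sampled uniformly
#' from the database, and every leaf a leaf patch (compound-leaf patches
#' count as leaves); fruits, flowers and buds keep their procedural colors.
#' Sampling is reproducible under `seed`.
#'
#' @param scene a `scene_graph`.
#' @param db a [texture_db].
#' @param seed integer seed.
#' @return The scene with `texture` fields set to patch file paths.
#' @export
assign_textures <- function(scene, db, seed = 1L) {
  variety <- if (identical(scene$variety, "cherry")) "cherry" else "ordinary"
  stem_files <- db_files(db, "stem", variety)
  leaf_files <- c(db_files(db, "leaf", variety),
                  db_files(db, "compound_leaf", variety))
  need_leaf <- any(vapply(scene$nodes, function(n) n$kind == "leaf", NA))
  if (length(stem_files) == 0)
    stopf("tomstem_empty_db", "no stem textures for variety '%s'", variety)
  if (need_leaf && length(leaf_files) == 0)
    stopf("tomstem_empty_db", "no leaf textures for variety '%s'", variety)
  with_seed(seed, {
    for (i in seq_along(scene$nodes)) {
      k <- scene$nodes[[i]]$kind
      if (k == "stem")
        scene$nodes[[i]]$texture <- stem_files[sample.int(length(stem_files), 1)]
      else if (k == "leaf")
        scene$nodes[[i]]$texture <- leaf_files[sample.int(length(leaf_files), 1)]
    }
  })
  scene
}

# --- meshes ----------------------------------------------------------------

mesh_frustum <- function(base, frame, len, r0, r1, nsides = 12L) {
  th <- seq(0, 2 * pi, length.out = nsides + 1L)[-(nsides + 1L)]
  ring <- function(r, t) {
    sweep(outer(cos(th), frame[, 2] * r) + outer(sin(th), frame[, 3] * r),
          2, base + frame[, 1] * (t * len), "+")
  }
  v <- rbind(ring(r0, 0), ring(r1, 1))
  uv <- rbind(cbind(seq(0, 1, length.out = nsides + 1)[-(nsides + 1)], 0),
              cbind(seq(0, 1, length.out = nsides + 1)[-(nsides + 1)], 1))
  f <- NULL
  for (i in seq_len(nsides)) {
    j <- i %% nsides + 1L
    f <- rbind(f, c(i, j, nsides + j), c(i, nsides + j, nsides + i))
  }
  list(v = v, vt = uv, f = f)
}

mesh_sphere <- function(center, r, nlat = 8L, nlon = 8L) {
  la <- seq(0, pi, length.out = nlat + 1L)
  lo <- seq(0, 2 * pi, length.out = nlon + 1L)[-(nlon + 1L)]
  v <- NULL; uv <- NULL
  for (a in la) for (b in lo) {
    v <- rbind(v, center + r * c(sin(a) * cos(b), sin(a) * sin(b), cos(a)))
    uv <- rbind(uv, c(b / (2 * pi), a / pi))
  }
  f <- NULL
  for (i in seq_len(nlat)) for (j in seq_len(nlon)) {
    j2 <- j %% nlon + 1L
    a0 <- (i - 1L) * nlon; a1 <- i * nlon
    f <- rbind(f, c(a0 + j, a0 + j2, a1 + j2), c(a0 + j, a1 + j2, a1 + j))
  }
  list(v = v, vt = uv, f = f)
}

bernstein3 <- function(t) cbind((1 - t)^3, 3 * t * (1 - t)^2,
                                3 * t^2 * (1 - t), t^3)

# 4x4 Bezier control grid of a leaf blade in the leaf's local frame:
# x along the midrib, y across the blade, z droops along the length; the
# two mid-rib control columns are lowered so the blade curves.
leaf_control_grid <- function(size) {
  xs <- c(0, 0.33, 0.66, 1) * size
  half <- 0.3 * size
  ys <- c(-half, -0.33 * half, 0.33 * half, half)
  ctrl <- array(0, c(4, 4, 3))
  width_prof <- c(0.25, 1, 1, 0.3)          # narrow base and tip
  for (i in 1:4) for (j in 1:4) {
    ctrl[i, j, 1] <- xs[i]
    ctrl[i, j, 2] <- ys[j] * width_prof[i]
    droop <- -0.3 * size * (xs[i] / size)^2
    rib <- if (j %in% 2:3) -0.06 * size else 0.05 * size
    ctrl[i, j, 3] <- droop + rib
  }
  ctrl
}

mesh_leaf <- function(base, frame, size, ngrid = 6L) {
  ctrl <- leaf_control_grid(size)
  t <- seq(0, 1, length.out = ngrid)
  Bu <- bernstein3(t); Bv <- bernstein3(t)
  v <- NULL; uv <- NULL
  for (i in seq_len(ngrid)) for (j in seq_len(ngrid)) {
    p_local <- vapply(1:3, function(d)
      as.numeric(Bu[i, , drop = FALSE] %*% ctrl[, , d] %*% t(Bv[j, , drop = FALSE])), 0)
    p <- base + frame %*% p_local
    v <- rbind(v, as.numeric(p))
    uv <- rbind(uv, c(t[i], t[j]))
  }
  f <- NULL
  for (i in seq_len(ngrid - 1L)) for (j in seq_len(ngrid - 1L)) {
    a <- (i - 1L) * ngrid + j
    f <- rbind(f, c(a, a + 1L, a + ngrid + 1L), c(a, a + ngrid + 1L, a + ngrid))
  }
  list(v = v, vt = uv, f = f)
}

node_mesh <- function(n) {
  switch(n$kind,
         stem = ,
         stalk = mesh_frustum(n$base, n$frame, n$len, n$r0, n$r1),
         pot = mesh_frustum(n$base, n$frame, n$len, n$r0, n$r1, nsides = 16L),
         leaf = mesh_leaf(n$base, n$frame, n$size),
         fruit = ,
         bud = mesh_sphere(n$base + n$frame[, 1] * n$size, n$size),
         flower = mesh_sphere(n$base + n$frame[, 1] * 0.5, n$size / 2,
                              nlat = 4L, nlon = 6L),
         NULL)
}

#' Export a scene graph as a Wavefront OBJ bundle
#'
#' Writes `<path>.obj` and `<path>.mtl`; texture-mapped nodes reference
#' their patch PNGs (copied next to the OBJ), untextured nodes get diffuse
#' color materials. Output is deterministic: identical scenes produce
#' byte-identical files.
#'
#' @param scene a `scene_graph`.
#' @param path output path without extension.
#' @return Invisibly, the OBJ path.
#' @export
export_obj <- function(scene, path) {
  obj_path <- paste0(path, ".obj")
  mtl_path <- paste0(path, ".mtl")
  dir.create(dirname(obj_path), recursive = TRUE, showWarnings = FALSE)
  obj <- c(sprintf("mtllib %s", basename(mtl_path)))
  mtl <- character(0)
  seen_mat <- character(0)
  voff <- 0L
  for (n in scene$nodes) {
    m <- node_mesh(n)
    if (is.null(m)) next
    if (!is.null(n$texture)) {
      mat <- paste0("tex_", tools::file_path_sans_ext(basename(n$texture)))
      if (!mat %in% seen_mat) {
        tgt <- file.path(dirname(obj_path), basename(n$texture))
        if (!file.exists(tgt)) file.copy(n$texture, tgt)
        mtl <- c(mtl, sprintf("newmtl %s", mat), "Kd 1.000000 1.000000 1.000000",
                 sprintf("map_Kd %s", basename(n$texture)), "")
        seen_mat <- c(seen_mat, mat)
      }
    } else {
      mat <- sprintf("col_%02x%02x%02x", round(n$color[1] * 255),
                     round(n$color[2] * 255), round(n$color[3] * 255))
      if (!mat %in% seen_mat) {
        mtl <- c(mtl, sprintf("newmtl %s", mat),
                 sprintf("Kd %.6f %.6f %.6f", n$color[1], n$color[2], n$color[3]),
                 "")
        seen_mat <- c(seen_mat, mat)
      }
    }
    obj <- c(obj, sprintf("o node_%d", n$id), sprintf("usemtl %s", mat),
             sprintf("v %.6f %.6f %.6f", m$v[, 1], m$v[, 2], m$v[, 3]),
             sprintf("vt %.6f %.6f", m$vt[, 1], m$vt[, 2]),
             sprintf("f %d/%d %d/%d %d/%d",
                     m$f[, 1] + voff, m$f[, 1] + voff,
                     m$f[, 2] + voff, m$f[, 2] + voff,
                     m$f[, 3] + voff, m$f[, 3] + voff))
    voff <- voff + nrow(m$v)
  }
  writeLines(obj, obj_path)
  writeLines(mtl, mtl_path)
  invisible(obj_path)
}

#' Read back an OBJ file (summary)
#'
#' Minimal reader for round-trip checks: counts vertices and faces and
#' collects the materials used.
#'
#' @param path an OBJ file.
#' @return List with `n_vertices`, `n_faces`, `materials`.
#' @export
read_obj <- function(path) {
  lines <- readLines(path)
  list(n_vertices = sum(startsWith(lines, "v ")),
       n_faces = sum(startsWith(lines, "f ")),
       materials = unique(sub("^usemtl ", "", grep("^usemtl ", lines,
                                                   value = TRUE))))
}
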