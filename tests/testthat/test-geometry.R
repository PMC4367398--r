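# jitter-free parameters give fully determinate turtle geometry
gp0 <- geom_params(jitter = list(stalk_angle_deg = 0, branch_roll_deg = 0,
                                 branch_len_frac = 0, leaf_drop_prob = 0),
                   main_deflect_deg = 0, curvature_coef = 0, seed = 1)

scene_of <- function(txt, gp = gp0, variety = "cherry") {
  s <- parse_lstring(txt)
  attr(s, "variety") <- variety                 # cherry: no pot node
  interpret_lstring(s, gp)
}

stem_nodes <- function(sc) Filter(function(n) n$kind == "stem", sc$nodes)

test_that("a single internode extrudes one cylinder along the heading", {
  sc <- scene_of("F(r)")
  st <- stem_nodes(sc)
  expect_length(st, 1)
  expect_equal(st[[1]]$base, c(0, 0, 0))
  expect_equal(st[[1]]$len, gp0$internode_cm)
  expect_equal(st[[1]]$frame[, 1], c(0, 0, 1))  # initial heading is up
  expect_equal(st[[1]]$r0, gp0$radius_cm)
  expect_true(st[[1]]$is_main_stem)
})

test_that("opposite rotations give mirror-symmetric branches", {
  sc <- scene_of("[+F(r)][-F(r)]")
  st <- stem_nodes(sc)
  expect_length(st, 2)
  h1 <- st[[1]]$frame[, 1]; h2 <- st[[2]]$frame[, 1]
  expect_equal(h1[3], h2[3])                    # same vertical component
  expect_equal(h1[1:2], -h2[1:2])               # opposite lateral
  expect_false(st[[1]]$is_main_stem)            # bracketed = lateral
})

test_that("brackets change attachment depth but not the turtle path", {
  a <- stem_nodes(scene_of("F(r)F(r)"))
  b <- stem_nodes(scene_of("F(r)[F(r)]"))
  tip <- function(n) n$base + n$frame[, 1] * n$len
  expect_equal(tip(a[[2]]), tip(b[[2]]))
  expect_identical(a[[2]]$depth, 0L)
  expect_identical(b[[2]]$depth, 1L)
  expect_error(interpret_lstring(parse_lstring("[F(1)", validate = FALSE)),
               class = "tomstem_structure_error")
})

test_that("interpretation is total and linear in organ symbols", {
  states <- lsys_grow(make_axiom(c(2, 1, 3, 5), "cherry"), 9)
  prev_h <- -Inf
  for (s in states) {
    sc <- interpret_lstring(s, gp0)
    organs <- sum(vapply(s, function(tk)
      tk$letter %in% tomstem:::LSYS_ORGANS, NA))
    expect_identical(length(sc$nodes) - 1L, organs)  # nodes = organs + root
    h <- tomstem:::scene_bbox(sc)[2, 3]
    expect_gte(h, prev_h)                       # plants never shrink
    prev_h <- h
  }
})

test_that("longer branches bend more, capped, and zero coefficient is identity", {
  gp <- gp0
  sc <- scene_of("F(r)[&S(r)][&h(r)h(r)h(r)h(r)]F(r)")
  tipz <- function(scene) {
    st <- stem_nodes(scene)
    lat <- Filter(function(n) n$depth > 0, st)
    vapply(lat, function(n) (n$base + n$frame[, 1] * n$len)[3], 0)
  }
  z0 <- tipz(sc)
  gp$curvature_coef <- 2
  bent <- apply_bending(sc, gp)
  z1 <- tipz(bent)
  drop_short <- z0[1] - z1[1]
  drop_long <- max(z0[-1] - z1[-1])
  expect_gt(drop_long, drop_short)              # longer branch sags more
  expect_gt(drop_short, 0)

  gp$curvature_coef <- 0
  same <- apply_bending(sc, gp)
  expect_equal(same$nodes, sc$nodes)            # identity limit

  # deflection never exceeds the cap for any length
  gp$curvature_coef <- 50
  capped <- apply_bending(sc, gp)
  root <- Filter(function(n) n$depth > 0, stem_nodes(sc))[[2]]
  root_b <- Filter(function(n) n$depth > 0, stem_nodes(capped))[[2]]
  ang <- acos(sum(root$frame[, 1] * root_b$frame[, 1])) * 180 / pi
  expect_lte(ang, 85 + 1e-6)
})

test_that("fruit color ripens monotonically from green to red", {
  g <- ripen_color(0, 6)
  r <- ripen_color(6, 6)
  expect_gt(g[2], g[1])                         # green anchor
  expect_gt(r[1], r[2])                         # red anchor
  expect_equal(ripen_color(9, 6), r)            # clamp past max age
  hue <- vapply(0:6, function(a) {
    rgb <- ripen_color(a, 6)
    grDevices::rgb2hsv(rgb[1] * 255, rgb[2] * 255, rgb[3] * 255)[1] * 360
  }, 0)
  expect_true(all(diff(hue) < 0))               # hue 120 -> 0, strictly
  expect_equal(hue[1], 120, tolerance = 1)
  expect_equal(hue[7], 0, tolerance = 1)
})

test_that("all rendering randomness flows from the seed", {
  s <- lsys_grow(make_axiom(c(2, 2, 1, 5), "ordinary"), 8)[[9]]
  gp <- randomize_geometry(geom_params(), 5)
  a <- interpret_lstring(s, gp)
  b <- interpret_lstring(s, gp)
  expect_equal(a$nodes, b$nodes)                # same seed, same scene

  lens <- function(sc) vapply(Filter(function(n) n$kind == "stem" && n$depth > 0,
                                     sc$nodes), `[[`, 0, "len")
  differs <- vapply(1:10, function(k) {
    c1 <- interpret_lstring(s, randomize_geometry(geom_params(), k))
    c2 <- interpret_lstring(s, randomize_geometry(geom_params(), k + 100))
    any(abs(lens(c1) - lens(c2)) > 1e-9)
  }, NA)
  expect_true(all(differs))                     # branch lengths perturbed

  # zero-width ranges are the identity regardless of seed
  z1 <- interpret_lstring(s, randomize_geometry(gp0, 1))
  z2 <- interpret_lstring(s, randomize_geometry(gp0, 999))
  expect_equal(z1$nodes, z2$nodes)
})

test_that("OBJ export round-trips counts and is byte-stable", {
  s <- lsys_grow(make_axiom(c(2, 1, 4), "ordinary"), 7)[[8]]
  sc <- apply_bending(interpret_lstring(s, randomize_geometry(geom_params(), 3)))
  d1 <- withr::local_tempdir(); d2 <- withr::local_tempdir()
  export_obj(sc, file.path(d1, "plant"))
  sc2 <- apply_bending(interpret_lstring(s, randomize_geometry(geom_params(), 3)))
  export_obj(sc2, file.path(d2, "plant"))
  expect_identical(readLines(file.path(d1, "plant.obj")),
                   readLines(file.path(d2, "plant.obj")))

  info <- read_obj(file.path(d1, "plant.obj"))
  expect_gt(info$n_vertices, 0)
  expect_gt(info$n_faces, 0)
  # re-import reproduces the vertex/face counts of a re-export
  export_obj(sc, file.path(d1, "copy"))
  info2 <- read_obj(file.path(d1, "copy.obj"))
  expect_identical(info$n_vertices, info2$n_vertices)
  expect_identical(info$n_faces, info2$n_faces)
  expect_identical(info$materials, info2$materials)
})

test_that("texture assignment samples the database per node kind", {
  root <- withr::local_tempdir()
  db <- texture_db(root)
  img <- array(runif(16 * 8 * 4), c(16, 8, 4)); img[, , 4] <- 1
  for (k in 1:3) db <- db_write(db, texture_patch(img, "stem", "ordinary"))
  db <- db_write(db, texture_patch(img, "leaf", "ordinary"))

  s <- lsys_grow(make_axiom(c(2, 1, 4), "ordinary"), 7)[[8]]
  sc <- interpret_lstring(s, gp0)
  tx <- assign_textures(sc, db, seed = 1)
  stems <- Filter(function(n) n$kind == "stem", tx$nodes)
  expect_true(all(vapply(stems, function(n) !is.null(n$texture), NA)))
  tx2 <- assign_textures(sc, db, seed = 1)
  expect_identical(lapply(tx$nodes, `[[`, "texture"),
                   lapply(tx2$nodes, `[[`, "texture"))

  db_empty <- texture_db(withr::local_tempdir())
  expect_error(assign_textures(sc, db_empty, seed = 1),
               class = "tomstem_empty_db")
})
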