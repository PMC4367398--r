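single_cylinder_scene <- function(r = 1, len = 30) {
  blank <- list(id = 1L, kind = "ground", letter = "", base = c(0, 0, 0),
                frame = diag(3), len = 0, r0 = 0, r1 = 0, size = 0,
                color = c(0, 0, 0), age = Inf, texture = NULL, parent = 0L,
                depth = 0L, branch_path = integer(0), is_main_stem = FALSE)
  cyl <- blank
  cyl$id <- 2L
  cyl$frame <- cbind(c(0, 0, 1), c(1, 0, 0), c(0, 1, 0))  # heading straight up
  cyl$kind <- "stem"; cyl$len <- len; cyl$r0 <- r; cyl$r1 <- r
  cyl$color <- c(0.3, 0.6, 0.3); cyl$is_main_stem <- TRUE; cyl$stem_group <- 1L
  structure(list(nodes = list(blank, cyl), gp = NULL, variety = "cherry"),
            class = "scene_graph")
}

test_that("a vertical cylinder projects to a centred column at its range", {
  cam <- camera_model(distance_mm = 950)
  r <- render_rgbd(single_cylinder_scene(), cam,
                   noise_model(dropout_prob = 0, edge_erosion_px = 0,
                               quant_mm = 1))
  d <- r$pair$depth
  nz <- which(d > 0, arr.ind = TRUE)
  expect_gt(nrow(nz), 0)
  # depth of the lit surface: 950 mm to the axis, +/- the 10 mm radius
  # (silhouette pixels may catch the far side of the cylinder)
  expect_true(all(d[d > 0] >= 935 & d[d > 0] <= 965))
  # all lit pixels hug the image centre column (cylinder radius ~6 px)
  expect_true(all(abs(nz[, 2] - cam$cx) <= 8))
  expect_true(all(d[cbind(nz[1, 1], c(1:300)[abs(c(1:300) - cam$cx) > 10])] == 0))
})

test_that("ground truth reprojects onto the rendered stem axis", {
  cam <- camera_model()
  r <- render_rgbd(single_cylinder_scene(), cam,
                   noise_model(dropout_prob = 0, edge_erosion_px = 0))
  poly <- r$truth$main_stems[[1]]
  expect_true(all(abs(poly[, 1] - cam$cx) <= 1))  # axis column
  d <- r$pair$depth
  for (i in seq_len(nrow(poly))) {
    rr <- round(poly[i, 2]); cc <- round(poly[i, 1])
    rr <- min(max(rr, 1), nrow(d))
    expect_true(any(d[rr, max(1, cc - 2):min(ncol(d), cc + 2)] > 0))
  }
})

test_that("depth is quantized and dropout is seeded and reproducible", {
  scn <- single_cylinder_scene()
  clean <- render_rgbd(scn, camera_model(),
                       noise_model(dropout_prob = 0, edge_erosion_px = 0,
                                   quant_mm = 2))
  expect_true(all(clean$pair$depth %% 2 == 0))

  n1 <- render_rgbd(scn, camera_model(),
                    noise_model(dropout_prob = 0.2, seed = 5))
  n2 <- render_rgbd(scn, camera_model(),
                    noise_model(dropout_prob = 0.2, seed = 5))
  expect_identical(n1$pair$depth, n2$pair$depth)
  n3 <- render_rgbd(scn, camera_model(),
                    noise_model(dropout_prob = 0.2, seed = 6))
  expect_false(identical(n1$pair$depth, n3$pair$depth))
  expect_lt(sum(n1$pair$depth > 0), sum(clean$pair$depth > 0))
})

test_that("scenes behind the camera raise a projection error", {
  scn <- single_cylinder_scene()
  expect_error(render_rgbd(scn, camera_model(distance_mm = -100)),
               class = "tomstem_projection_error")
})

test_that("benchmarks are byte-reproducible with a resolvable manifest", {
  d1 <- withr::local_tempdir(); d2 <- withr::local_tempdir()
  make_benchmark("cherry", 2, "easy", seed = 11, out_dir = d1)
  make_benchmark("cherry", 2, "easy", seed = 11, out_dir = d2)
  sums <- function(d) vapply(sort(list.files(d)), function(f)
    unname(tools::md5sum(file.path(d, f))), "")
  expect_identical(sums(d1), sums(d2))

  man <- jsonlite::read_json(file.path(d1, "manifest.json"),
                             simplifyVector = FALSE)
  expect_length(man$scenes, 2)
  for (sc in man$scenes) {
    expect_true(file.exists(file.path(d1, sc$depth)))
    expect_true(file.exists(file.path(d1, sc$color)))
    expect_true(file.exists(file.path(d1, sc$gt)))
    expect_true(sc$distance_mm >= 900 && sc$distance_mm <= 1000)
  }
})

test_that("easy scenes show the fat-thin-fat bimodal breadth profile", {
  for (seed in c(301, 302, 303)) {
    scn <- potted_plant_scene("ordinary", seed = seed, difficulty = "easy")
    r <- render_rgbd(scn, camera_model(),
                     noise_model(dropout_prob = 0.05, seed = seed))
    h <- median_smooth(breadth_histogram(build_grid(depth_mask(r$pair))))
    L <- h$L
    third <- floor(L / 3)
    top <- max(h$n[1:third])
    mid <- min(h$n[(third + 1):(2 * third)])
    bot <- max(h$n[(2 * third + 1):L])
    expect_gte(top, 2 * mid)
    expect_gte(bot, 2 * mid)
  }
})
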