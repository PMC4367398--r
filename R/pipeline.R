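#' Default pipeline configuration
#'
#' All tunables of the digitization pipeline, grouped by stage. Every value
#' can be overridden from a YAML file ([load_config]); unknown keys are
#' rejected so typos never silently fall back to defaults.
#'
#' @return Nested named list of class `tomstem_config`.
#' @export
default_config <- function() {
  structure(list(
    preprocess = list(near_mm = 800, far_mm = 1500),
    detect = list(rho_px = 1, theta_deg = 1, votes = 20, min_len_px = 20,
                  max_gap_px = 5),
    region = list(cell_px = 8, min_valid_frac = 0.2, median_window = 5,
                  balance_ratio = 1.5, pot_breadth_max = 4),
    texture = list(margin_px = 6, exg_tau = 20),
    metrics = list(match_dist_px = 5),
    seed = 1L
  ), class = "tomstem_config")
}

merge_validate <- function(defaults, user, path = "") {
  for (k in names(user)) {
    full <- if (nzchar(path)) paste0(path, ".", k) else k
    if (!k %in% names(defaults))
      stopf("tomstem_config_error", "unknown configuration key '%s'", full)
    if (is.list(defaults[[k]])) {
      if (!is.list(user[[k]]))
        stopf("tomstem_config_error", "'%s' must be a mapping", full)
      defaults[[k]] <- merge_validate(defaults[[k]], user[[k]], full)
    } else {
      v <- user[[k]]
      if (!is.numeric(v) || length(v) != 1)
        stopf("tomstem_config_error", "'%s' must be a single number", full)
      defaults[[k]] <- v
    }
  }
  defaults
}

#' Load and validate a YAML configuration
#'
#' @param path YAML file; `NULL` returns the defaults.
#' @return A validated `tomstem_config`.
#' @export
load_config <- function(path = NULL) {
  cfg <- default_config()
  if (is.null(path)) return(cfg)
  if (!file.exists(path)) stopf("tomstem_io_error", "no such config: %s", path)
  user <- yaml::read_yaml(path)
  structure(merge_validate(unclass(cfg), user), class = "tomstem_config")
}

#' Run the full stem digitization pipeline on one RGB-D pair
#'
#' Chains the four digitization steps: depth-window masking and
#' skeletonization, Hough segment detection, breadth-histogram valley
#' localization by iterated Otsu, and geometric false-positive removal.
#'
#' @param pair an [rgbd_pair].
#' @param config a `tomstem_config` (defaults used when `NULL`).
#' @return List with every intermediate product: `mask`, `skel`,
#'   `segments_all`, `grid`, `hist_raw`, `hist` (smoothed), `interval` and
#'   the surviving `segments`.
#' @export
digitize_pair <- function(pair, config = NULL) {
  cfg <- config %||% default_config()
  mask <- depth_mask(pair, cfg$preprocess$near_mm, cfg$preprocess$far_mm)
  skel <- skeletonize(mask)
  segs_all <- detect_segments(skel, ppht_params(
    rho_px = cfg$detect$rho_px, theta_deg = cfg$detect$theta_deg,
    votes = cfg$detect$votes, min_len_px = cfg$detect$min_len_px,
    max_gap_px = cfg$detect$max_gap_px, seed = cfg$seed))
  grid <- build_grid(mask, cfg$region$cell_px, cfg$region$min_valid_frac)
  hist_raw <- breadth_histogram(grid)
  hist <- median_smooth(hist_raw, cfg$region$median_window)
  interval <- valley_interval(hist, cfg$region$balance_ratio)
  segments <- filter_segments(segs_all, interval, grid,
                              cfg$region$pot_breadth_max)
  list(mask = mask, skel = skel, segments_all = segs_all, grid = grid,
       hist_raw = hist_raw, hist = hist, interval = interval,
       segments = segments)
}

exit_code_for <- function(e) {
  if (inherits(e, "tomstem_io_error")) 2L
  else if (inherits(e, "tomstem_empty_plant") ||
           inherits(e, "tomstem_degenerate_histogram")) 3L
  else 1L
}

#' Digitize one depth/color pair and write all artifacts
#'
#' Runs [digitize_pair] and writes the foreground mask, skeleton, detected
#' and filtered segments (JSON), the stem interval with its histogram
#' (JSON), a debug overlay PNG, a log of every threshold actually used,
#' and one stem texture patch per surviving segment under `patches/`.
#'
#' @param depth_path,color_path input PNGs.
#' @param config_path optional YAML config.
#' @param out_dir output directory (created).
#' @return Invisible integer exit code: 0 success, 2 I/O error, 3 empty
#'   plant or degenerate histogram, 1 other failure.
#' @export
cmd_digitize <- function(depth_path, color_path, config_path = NULL,
                         out_dir = ".") {
  code <- tryCatch({
    cfg <- load_config(config_path)
    pair <- read_rgbd(depth_path, color_path)
    res <- digitize_pair(pair, cfg)
    dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    write_mask_png(res$mask, file.path(out_dir, "mask.png"))
    write_mask_png(res$skel, file.path(out_dir, "skeleton.png"))
    segments_to_json(res$segments_all, file.path(out_dir, "segments_all.json"))
    segments_to_json(res$segments, file.path(out_dir, "segments.json"))
    interval_to_json(res$interval, file.path(out_dir, "interval.json"),
                     h = res$hist)
    write_overlay_png(pair$color, res$grid, res$interval, res$segments,
                      file.path(out_dir, "overlay.png"))
    jsonlite::write_json(
      list(config = unclass(cfg),
           axis_col = res$grid$axis_col, k_star = res$interval$k_star,
           passes = res$interval$passes,
           valley = c(res$interval$lo, res$interval$hi),
           n_candidates = length(res$segments_all),
           n_kept = length(res$segments)),
      file.path(out_dir, "log.json"), auto_unbox = TRUE, digits = NA)
    pdir <- file.path(out_dir, "patches")
    dir.create(pdir, showWarnings = FALSE)
    for (s in res$segments) {
      p <- tryCatch(extract_stem_patch(pair$color, s, res$mask,
                                       cfg$texture$margin_px),
                    tomstem_empty_patch = function(e) NULL)
      if (!is.null(p))
        EBImage::writeImage(EBImage::Image(aperm(p$image, c(2, 1, 3)),
                                           colormode = "Color"),
                            file.path(pdir, sprintf("stem_%02d.png", s$id)),
                            type = "png", bits = 8)
    }
    0L
  }, tomstem_error = function(e) {
    message("digitize failed: ", conditionMessage(e))
    exit_code_for(e)
  })
  invisible(code)
}

#' Grow a virtual tomato plant and export the stage sequence
#'
#' Draws a random choice string, grows the variety's L-system for
#' `stages` steps and exports one OBJ bundle per stage
#' (`stage_00` ... `stage_NN`), optionally texture-mapped from a database.
#'
#' @param variety `"ordinary"` or `"cherry"`.
#' @param stages number of growth stages.
#' @param seed master seed (axiom, geometry perturbations, textures).
#' @param texture_db_root optional [texture_db] root with stem and leaf
#'   patches.
#' @param out_dir output directory.
#' @return Invisible integer exit code.
#' @export
cmd_grow <- function(variety = "ordinary", stages = 5L, seed = 1L,
                     texture_db_root = NULL, out_dir = ".") {
  code <- tryCatch({
    dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    axiom <- make_axiom(random_choice(seed), variety)
    states <- lsys_grow(axiom, stages)
    gp <- randomize_geometry(geom_params(), seed)
    db <- if (!is.null(texture_db_root)) texture_db(texture_db_root)
    for (k in seq_along(states)) {
      scene <- apply_bending(interpret_lstring(states[[k]], gp))
      if (!is.null(db)) scene <- assign_textures(scene, db, seed)
      export_obj(scene, file.path(out_dir, sprintf("stage_%02d", k - 1L)))
    }
    writeLines(vapply(states, lstring_to_string, ""),
               file.path(out_dir, "stages.txt"))
    0L
  }, tomstem_error = function(e) {
    message("grow failed: ", conditionMessage(e)); exit_code_for(e)
  })
  invisible(code)
}

#' Generate a synthetic benchmark dataset
#'
#' Thin wrapper over [make_benchmark] with exit-code semantics.
#'
#' @param variety,n,difficulty,seed,out_dir see [make_benchmark].
#' @return Invisible integer exit code.
#' @export
cmd_synth <- function(variety = "ordinary", n = 5L, difficulty = "easy",
                      seed = 1L, out_dir = ".") {
  code <- tryCatch({
    make_benchmark(variety, n, difficulty, seed, out_dir)
    0L
  }, tomstem_error = function(e) {
    message("synth failed: ", conditionMessage(e)); exit_code_for(e)
  })
  invisible(code)
}

#' Evaluate predicted segments against ground truth
#'
#' Pairs every `gt_NNN.json` in `truth_dir` with `segments_NNN.json` in
#' `pred_dir`, counts FN/TP/FP/SD per image and writes the pooled rates as
#' `report.json` plus a Markdown table.
#'
#' @param pred_dir directory of per-image segment JSON files.
#' @param truth_dir directory of ground-truth JSON files.
#' @param out_dir report directory (defaults to `pred_dir`).
#' @param match_dist_px matching tolerance, see [count_events].
#' @return Invisible integer exit code.
#' @export
cmd_eval <- function(pred_dir, truth_dir, out_dir = pred_dir,
                     match_dist_px = 5) {
  code <- tryCatch({
    gts <- sort(list.files(truth_dir, pattern = "^gt_[0-9]+\\.json$"))
    if (length(gts) == 0) stopf("tomstem_io_error", "no gt_*.json in %s",
                                truth_dir)
    batch <- list()
    for (g in gts) {
      id <- sub("^gt_([0-9]+)\\.json$", "\\1", g)
      pf <- file.path(pred_dir, sprintf("segments_%s.json", id))
      if (!file.exists(pf))
        stopf("tomstem_io_error", "missing predictions: %s", pf)
      truth <- gt_from_json(file.path(truth_dir, g))
      segs <- segments_from_json(pf)
      batch[[id]] <- count_events(truth, segs, match_dist_px = match_dist_px)
    }
    r <- rates(batch)
    dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    jsonlite::write_json(
      list(per_image = lapply(batch, unclass), rates = r),
      file.path(out_dir, "report.json"), auto_unbox = TRUE, digits = NA)
    writeLines(c("| metric | value |", "|---|---|",
                 sprintf("| FNR | %s |", percent1(r$FNR)),
                 sprintf("| TPR | %s |", percent1(r$TPR)),
                 sprintf("| ER | %s |", percent1(r$ER)),
                 sprintf("| Ac | %s |", percent1(r$Ac))),
               file.path(out_dir, "report.md"))
    0L
  }, tomstem_error = function(e) {
    message("eval failed: ", conditionMessage(e)); exit_code_for(e)
  })
  invisible(code)
}

#' Run the detection pipeline over a benchmark and pool the rates
#'
#' The closed loop used for benchmarking: every scene of a
#' [make_benchmark] dataset is digitized with [digitize_pair] and scored
#' against its ground truth inside the per-image valley interval.
#'
#' @param bench_dir a benchmark dataset directory.
#' @param config optional `tomstem_config`.
#' @param match_dist_px matching tolerance.
#' @return List with `rates` (pooled) and `per_image` counts.
#' @export
evaluate_benchmark <- function(bench_dir, config = NULL, match_dist_px = 5) {
  manifest <- jsonlite::read_json(file.path(bench_dir, "manifest.json"),
                                  simplifyVector = FALSE)
  batch <- list()
  for (sc in manifest$scenes) {
    pair <- read_rgbd(file.path(bench_dir, sc$depth),
                      file.path(bench_dir, sc$color))
    res <- digitize_pair(pair, config)
    truth <- gt_from_json(file.path(bench_dir, sc$gt))
    batch[[sc$gt]] <- count_events(truth, res$segments, res$interval,
                                   res$grid, match_dist_px)
  }
  list(rates = rates(batch), per_image = batch)
}
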