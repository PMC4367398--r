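#' Ground-truth main-stem annotation
#'
#' Manual annotation of the main stems of one image: a list of polylines in
#' pixel coordinates (each an n x 2 matrix of `(col, row)` vertices).
#'
#' @param main_stems list of numeric matrices (n >= 2 rows, 2 columns).
#' @param image_id free-text image identifier.
#' @return Object of class `ground_truth`.
#' @export
ground_truth <- function(main_stems, image_id = NA_character_) {
  main_stems <- lapply(main_stems, function(p) {
    p <- matrix(as.numeric(unlist(p)), ncol = 2,
                byrow = !is.matrix(p))
    if (nrow(p) < 2) stopf("tomstem_value_error", "polyline needs >= 2 points")
    p
  })
  structure(list(main_stems = main_stems, image_id = image_id),
            class = "ground_truth")
}

#' Read / write ground truth JSON
#'
#' Format: `{"image": id, "main_stems": [[[col,row], ...], ...]}`.
#'
#' @param gt a [ground_truth] object.
#' @param path JSON file path.
#' @return `gt_to_json` returns `path` invisibly; `gt_from_json` a
#'   `ground_truth`.
#' @export
gt_to_json <- function(gt, path) {
  jsonlite::write_json(
    list(image = gt$image_id,
         main_stems = lapply(gt$main_stems, function(p)
           lapply(seq_len(nrow(p)), function(i) p[i, ]))),
    path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname gt_to_json
#' @export
gt_from_json <- function(path) {
  raw <- jsonlite::read_json(path, simplifyVector = FALSE)
  stems <- lapply(raw$main_stems, function(p)
    do.call(rbind, lapply(p, function(q) as.numeric(unlist(q)))))
  ground_truth(stems, raw$image %||% NA_character_)
}

# minimum distance from points (n x 2, col/row) to a polyline (m x 2)
dist_to_polyline <- function(pts, poly) {
  best <- rep(Inf, nrow(pts))
  for (i in seq_len(nrow(poly) - 1L)) {
    a <- poly[i, ]; b <- poly[i + 1L, ]
    ab <- b - a; len2 <- sum(ab^2)
    if (len2 == 0) {
      d <- sqrt((pts[, 1] - a[1])^2 + (pts[, 2] - a[2])^2)
    } else {
      t <- pmin(1, pmax(0, ((pts[, 1] - a[1]) * ab[1] +
                            (pts[, 2] - a[2]) * ab[2]) / len2))
      d <- sqrt((pts[, 1] - (a[1] + t * ab[1]))^2 +
                (pts[, 2] - (a[2] + t * ab[2]))^2)
    }
    best <- pmin(best, d)
  }
  best
}

seg_points <- function(s) {
  np <- max(2L, ceiling(s$length_px) + 1L)
  t <- seq(0, 1, length.out = np)
  cbind(s$p0[1] + t * (s$p1[1] - s$p0[1]),
        s$p0[2] + t * (s$p1[2] - s$p0[2]))
}

#' Count detection events against annotated main stems
#'
#' Segment-level scoring inside the bounded valley region. A detected
#' segment whose mean distance to some annotated main-stem polyline is at
#' most `match_dist_px` is a *successful detection* (SD); otherwise it is a
#' *false positive* (FP). A main stem covered by at least one matching
#' segment is a *true positive* (TP); a main stem covered by none is a
#' *false negative* (FN). Only stems and segments whose grid-row span
#' intersects the valley `[lo, hi]` are considered; pass `interval = NULL`
#' (with `grid = NULL`) to score everything.
#'
#' @param truth a [ground_truth].
#' @param segs list of detected `stem_segment`s.
#' @param interval optional [valley_interval] result restricting the rows
#'   considered.
#' @param grid the [build_grid] result defining the interval's row frame
#'   (required when `interval` is given).
#' @param match_dist_px matching tolerance in pixels (about one stem width).
#' @return Object of class `eval_counts`: `FN`, `TP`, `FP`, `SD`,
#'   `n_main_stems`, `n_detected`, satisfying `FN + TP == n_main_stems` and
#'   `FP + SD == n_detected`.
#' @export
count_events <- function(truth, segs, interval = NULL, grid = NULL,
                         match_dist_px = 5) {
  stopifnot(inherits(truth, "ground_truth"))
  in_valley_rows <- function(rows) {
    # the row *span* must intersect [lo, hi]: a stem passing through the
    # valley counts even if no annotated vertex falls inside it
    if (is.null(interval)) return(TRUE)
    i <- hist_index_of_row(grid, rows)
    min(i) <= interval$hi && max(i) >= interval$lo
  }
  stems <- Filter(function(p) in_valley_rows(p[, 2]), truth$main_stems)
  segs <- Filter(function(s) in_valley_rows(c(s$p0[2], s$p1[2])), segs)

  covered <- rep(FALSE, length(stems))
  sd_n <- 0L
  for (s in segs) {
    pts <- seg_points(s)
    d <- vapply(stems, function(p) mean(dist_to_polyline(pts, p)), 0)
    hit <- which(d <= match_dist_px)
    if (length(hit)) {
      sd_n <- sd_n + 1L
      covered[hit[which.min(d[hit])]] <- TRUE
    }
  }
  new_eval_counts(FN = sum(!covered), TP = sum(covered),
                  FP = length(segs) - sd_n, SD = sd_n,
                  n_main_stems = length(stems), n_detected = length(segs))
}

new_eval_counts <- function(FN, TP, FP, SD, n_main_stems = FN + TP,
                            n_detected = FP + SD) {
  v <- c(FN = FN, TP = TP, FP = FP, SD = SD)
  if (any(v < 0)) stopf("tomstem_value_error", "counts must be non-negative")
  if (FN + TP != n_main_stems || FP + SD != n_detected)
    stopf("tomstem_value_error",
          "inconsistent counts: FN+TP must equal n_main_stems and FP+SD n_detected")
  structure(list(FN = FN, TP = TP, FP = FP, SD = SD,
                 n_main_stems = n_main_stems, n_detected = n_detected),
            class = "eval_counts")
}

#' Per-image detection counts
#'
#' Construct an `eval_counts` record directly from tallied events, e.g. when
#' transcribing a manual evaluation.
#'
#' @param FN,TP,FP,SD non-negative event counts.
#' @param n_main_stems,n_detected totals; default to `FN + TP` and
#'   `FP + SD`.
#' @return Object of class `eval_counts`.
#' @export
eval_counts <- new_eval_counts

#' Batch detection rates
#'
#' Pools a batch of per-image counts and computes the four rates: the false
#' negative rate `FNR = sum(FN) / sum(n_main_stems)`, the true positive rate
#' `TPR = sum(TP) / sum(n_main_stems)` (so `TPR + FNR = 1`), the error rate
#' `ER = sum(FP) / sum(n_detected)` and the accuracy
#' `Ac = sum(SD) / sum(n_detected) = 1 - ER`.
#'
#' @param batch list of `eval_counts` (or a single one).
#' @return Named list `FNR`, `TPR`, `ER`, `Ac` (proportions in `[0, 1]`),
#'   plus the pooled totals.
#' @export
rates <- function(batch) {
  if (inherits(batch, "eval_counts")) batch <- list(batch)
  tot <- function(f) sum(vapply(batch, `[[`, 0, f))
  stems <- tot("n_main_stems"); det <- tot("n_detected")
  if (stems == 0 || det == 0)
    stopf("tomstem_undefined_rate",
          "rates undefined: %d main stems, %d detections", stems, det)
  list(FNR = tot("FN") / stems, TPR = tot("TP") / stems,
       ER = tot("FP") / det, Ac = tot("SD") / det,
       n_main_stems = stems, n_detected = det)
}

#' Format a proportion as a percentage, half-up at one decimal
#'
#' Matches the conventional presentation of detection tables (e.g. 0.78 ->
#' `"78.0%"`). Rounding is half-up, not banker's.
#'
#' @param x proportion(s) in `[0, 1]`.
#' @return Character vector like `"78.0%"`.
#' @export
percent1 <- function(x) {
  sprintf("%.1f%%", floor(x * 1000 + 0.5) / 10)
}

#' Bundled per-phase evaluation counts for two tomato varieties
#'
#' Loads the package's example table of manually tallied stem-detection
#' events: for each variety (cherry, ordinary) and growth phase, the number
#' of test image pairs, annotated main stems, detected segments, and the
#' FN/TP/FP/SD event counts from a greenhouse-style evaluation. Useful for
#' exercising [rates] and [eval_report] without images.
#'
#' @return A data.frame with columns `variety`, `phase`, `n_images`,
#'   `n_main_stems`, `n_detected`, `FN`, `TP`, `FP`, `SD`.
#' @export
example_eval_counts <- function() {
  utils::read.csv(system.file("extdata", "tomato_eval_counts.csv",
                              package = "tomstem"),
                  stringsAsFactors = FALSE)
}

counts_from_row <- function(row) {
  new_eval_counts(FN = row$FN, TP = row$TP, FP = row$FP, SD = row$SD,
                  n_main_stems = row$n_main_stems, n_detected = row$n_detected)
}

#' Phase-by-phase evaluation report
#'
#' Builds the standard report for a counts table shaped like
#' [example_eval_counts]: one column per growth phase and per variety with
#' the raw counts and FNR/TPR/ER/Ac, plus pooled per-variety totals.
#'
#' @param counts data.frame as returned by [example_eval_counts].
#' @return A list with `per_phase` (data.frame incl. rate columns) and
#'   `totals` (per-variety pooled [rates]).
#' @export
eval_report <- function(counts) {
  per <- counts
  r <- lapply(seq_len(nrow(per)), function(i) rates(list(counts_from_row(per[i, ]))))
  per$FNR <- vapply(r, `[[`, 0, "FNR"); per$TPR <- vapply(r, `[[`, 0, "TPR")
  per$ER <- vapply(r, `[[`, 0, "ER");  per$Ac <- vapply(r, `[[`, 0, "Ac")
  totals <- lapply(split(per, per$variety), function(df)
    rates(lapply(seq_len(nrow(df)), function(i) counts_from_row(df[i, ]))))
  list(per_phase = per, totals = totals)
}

#' Write an evaluation report as JSON and a Markdown table
#'
#' @param report an [eval_report] result.
#' @param json_path,md_path output paths (`NULL` to skip either).
#' @return `report`, invisibly.
#' @export
write_eval_report <- function(report, json_path = NULL, md_path = NULL) {
  if (!is.null(json_path))
    jsonlite::write_json(report, json_path, auto_unbox = TRUE, digits = NA)
  if (!is.null(md_path)) {
    per <- report$per_phase
    lines <- c("| variety | phase | images | stems | detected | FN | TP | FP | SD | FNR | TPR | ER | Ac |",
               "|---|---|---|---|---|---|---|---|---|---|---|---|---|")
    for (i in seq_len(nrow(per)))
      lines <- c(lines, sprintf(
        "| %s | %s | %d | %d | %d | %d | %d | %d | %d | %s | %s | %s | %s |",
        per$variety[i], per$phase[i], per$n_images[i], per$n_main_stems[i],
        per$n_detected[i], per$FN[i], per$TP[i], per$FP[i], per$SD[i],
        percent1(per$FNR[i]), percent1(per$TPR[i]),
        percent1(per$ER[i]), percent1(per$Ac[i])))
    for (v in names(report$totals)) {
      t <- report$totals[[v]]
      lines <- c(lines, sprintf(
        "| %s | total | | %d | %d | | | | | %s | %s | %s | %s |",
        v, t$n_main_stems, t$n_detected, percent1(t$FNR), percent1(t$TPR),
        percent1(t$ER), percent1(t$Ac)))
    }
    writeLines(lines, md_path)
  }
  invisible(report)
}
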