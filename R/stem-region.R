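#' Build the uniform grid system around the plant axis
#'
#' Tessellates the image into square cells of `cell_px` pixels. A cell is
#' *valid* when at least `min_valid_frac` of its pixels are foreground. The
#' plant axis is the direction of gravity through the pot centre: it is
#' estimated as the centroid column of the foreground pixels in the bottom
#' 15% of the foreground rows (the pot band), falling back to the whole-mask
#' centroid when that band is empty. The grid-row origin is placed on the
#' axis just above the topmost valid cell, so breadth-histogram index 1 is
#' the first row the plant occupies and indices increase downward.
#'
#' @param mask a [depth_mask] result (logical matrix).
#' @param cell_px grid spacing in pixels (>= 2).
#' @param min_valid_frac fraction of a cell's pixels that must be foreground
#'   for the cell to count as valid.
#' @return An object of class `grid_system` with fields `cell_px`,
#'   `axis_col` (pixels), `axis_gc` (grid column), `valid` (grid-cell
#'   logical matrix), `origin_row`, `bottom_row` (grid rows), and the image
#'   dimensions.
#' @export
build_grid <- function(mask, cell_px = 8L, min_valid_frac = 0.2) {
  if (cell_px < 2) stopf("tomstem_value_error", "cell_px must be >= 2")
  m <- unclass(as_mask(mask)); attributes(m) <- attributes(m)["dim"]
  fg <- which(m, arr.ind = TRUE)
  if (nrow(fg) == 0L) stopf("tomstem_empty_plant", "mask has no foreground pixels")

  rows <- sort(unique(fg[, 1]))
  band_lo <- stats::quantile(fg[, 1], 0.85, names = FALSE, type = 1)
  in_band <- fg[, 1] >= band_lo
  axis_col <- if (any(in_band)) mean(fg[in_band, 2]) else mean(fg[, 2])

  gr <- nrow(m) %/% cell_px; gc <- ncol(m) %/% cell_px
  cr <- (fg[, 1] - 1L) %/% cell_px + 1L
  cc <- (fg[, 2] - 1L) %/% cell_px + 1L
  keep <- cr <= gr & cc <= gc
  counts <- matrix(tabulate((cc[keep] - 1L) * gr + cr[keep], nbins = gr * gc),
                   gr, gc)
  valid <- counts >= min_valid_frac * cell_px^2

  axis_gc <- min(max(1L, (ceiling(axis_col) - 1L) %/% cell_px + 1L), gc)
  vrows <- which(rowSums(valid) > 0)
  if (length(vrows) == 0L)
    stopf("tomstem_empty_plant", "no grid cell reaches min_valid_frac")
  structure(list(cell_px = as.integer(cell_px), axis_col = axis_col,
                 axis_gc = axis_gc, valid = valid,
                 origin_row = min(vrows) - 1L, bottom_row = max(vrows),
                 img_rows = nrow(m), img_cols = ncol(m)),
            class = "grid_system")
}

# breadth-histogram index of an image pixel row (1 = topmost plant row)
hist_index_of_row <- function(grid, pixel_row) {
  (pmin(pmax(ceiling(pixel_row), 1), grid$img_rows) - 1L) %/% grid$cell_px +
    1L - grid$origin_row
}

# full plant width (count of valid cells) of each histogram row
row_widths <- function(grid) {
  rowSums(grid$valid)[(grid$origin_row + 1L):grid$bottom_row]
}

#' Plant breadth histogram down the plant axis
#'
#' For each grid row spanned by the plant, the breadth is the number of grid
#' cells between the plant axis and the farthest valid cell on that row.
#' Rows with zero breadth (sensor dropout or irregular structure) take the
#' breadth of the nearest non-zero row above, or below when no non-zero row
#' exists above. For a potted plant viewed from the side the profile is
#' "fat-thin-fat": wide canopy, thin main-stem waist, wide pot -- a bimodal
#' shape whose valley is where the main stems live.
#'
#' @param grid a [build_grid] result.
#' @return Object of class `breadth_histogram`: list with `n` (integer
#'   breadths, top to bottom), `L = length(n)` and `N = sum(n)`.
#' @export
breadth_histogram <- function(grid) {
  stopifnot(inherits(grid, "grid_system"))
  idx <- (grid$origin_row + 1L):grid$bottom_row
  n <- vapply(idx, function(r) {
    v <- which(grid$valid[r, ])
    if (length(v) == 0L) 0L else as.integer(max(abs(v - grid$axis_gc)))
  }, 0L)
  nz <- which(n > 0L)
  if (length(nz)) {
    for (i in seq_along(n)) {
      if (n[i] > 0L) next
      above <- nz[nz < i]
      n[i] <- if (length(above)) n[max(above)] else n[min(nz[nz > i])]
    }
  }
  new_breadth_histogram(n)
}

new_breadth_histogram <- function(n) {
  n <- as.integer(round(n))
  if (any(n < 0)) stopf("tomstem_value_error", "breadths must be non-negative")
  structure(list(n = n, L = length(n), N = sum(n)),
            class = "breadth_histogram")
}

#' @export
print.breadth_histogram <- function(x, ...) {
  cat(sprintf("<breadth_histogram> L=%d, N=%d\n", x$L, x$N))
  cat(" ", paste(x$n, collapse = " "), "\n")
  invisible(x)
}

#' Median-smooth a breadth histogram
#'
#' Running median with replicate-padded edges; the bar total `N` is
#' recomputed. Smoothing suppresses single-row spikes so the bimodal shape
#' dominates before thresholding.
#'
#' @param h a [breadth_histogram].
#' @param window odd window length >= 3.
#' @return A smoothed `breadth_histogram`.
#' @export
median_smooth <- function(h, window = 5L) {
  stopifnot(inherits(h, "breadth_histogram"))
  if (window %% 2 == 0 || window < 3)
    stopf("tomstem_value_error", "window must be odd and >= 3")
  if (window >= 2 * h$L)
    stopf("tomstem_degenerate_window", "window %d >= 2L = %d", window, 2 * h$L)
  k <- (window - 1L) %/% 2L
  padded <- c(rep(h$n[1], k), h$n, rep(h$n[h$L], k))
  sm <- vapply(seq_len(h$L), function(i) median(padded[i:(i + window - 1L)]), 0)
  new_breadth_histogram(sm)
}

#' Otsu threshold of a breadth histogram
#'
#' Exhaustive scan of the split index k: class C0 holds bars 1..k and C1
#' bars k+1..L; with bar proportions p_i = n_i / N, class weights
#' w0 = sum(p_1..p_k), w1 = 1 - w0 and class means mu0, mu1 over bar
#' positions, the between-class variance is
#' `sigma_B^2(k) = w0 * w1 * (mu1 - mu0)^2`, and the threshold k* maximizes
#' it (equivalently minimizes the within-class variance). Ties take the
#' smallest k.
#'
#' @param h a [breadth_histogram] with mass in at least two distinct bars.
#' @return Object of class `otsu_result`: `k_star`, `sigma_b2`, `omega0`,
#'   `omega1`, `mu0`, `mu1`.
#' @export
otsu_histogram <- function(h) {
  stopifnot(inherits(h, "breadth_histogram"))
  n <- as.numeric(h$n); L <- h$L
  if (sum(n > 0) < 2)
    stopf("tomstem_degenerate_histogram",
          "histogram mass concentrated in fewer than two bars")
  p <- n / sum(n)
  i <- seq_len(L)
  w0 <- cumsum(p)                 # omega0(k), k = 1..L
  mu_cum <- cumsum(i * p)         # sum_{i<=k} i p_i
  mu_tot <- mu_cum[L]
  best_k <- NA_integer_; best <- -Inf
  for (k in seq_len(L - 1L)) {
    if (w0[k] <= 0 || w0[k] >= 1) next
    mu0 <- mu_cum[k] / w0[k]
    mu1 <- (mu_tot - mu_cum[k]) / (1 - w0[k])
    sb <- w0[k] * (1 - w0[k]) * (mu1 - mu0)^2
    # require a genuine improvement: exact ties (which floating point can
    # order either way) keep the smallest k
    if (sb > best + 1e-10 * max(1, best)) { best <- sb; best_k <- k }
  }
  k <- best_k
  structure(list(k_star = k, sigma_b2 = best,
                 omega0 = w0[k], omega1 = 1 - w0[k],
                 mu0 = mu_cum[k] / w0[k],
                 mu1 = (mu_tot - mu_cum[k]) / (1 - w0[k])),
            class = "otsu_result")
}

weighted_sd <- function(pos, wt) {
  if (sum(wt) == 0) return(0)
  mu <- sum(pos * wt) / sum(wt)
  sqrt(sum(wt * (pos - mu)^2) / sum(wt))
}

#' Locate the main-stem valley by iterated Otsu thresholding
#'
#' A first Otsu split of the breadth histogram lands near the valley only
#' when the canopy and pot classes carry comparable mass; when one side is
#' much heavier the threshold is dragged toward it. In that case
#' (mass(heavier)/mass(lighter) > `balance_ratio`) Otsu is applied a second
#' time to the sub-histogram on the side of the first threshold that holds
#' the *lighter* class, and that sub-threshold (re-expressed as a global
#' index) becomes the final k*. Two passes are always enough. The valley is
#' then the interval `[k* - sigma0, k* + sigma1]` where sigma0/sigma1 are
#' the within-class standard deviations of bar positions (weighted by bar
#' height) on each side of the final k*; the lower bound is floored and the
#' upper ceiled so the sigma bounds never shrink the region.
#'
#' @param h a [breadth_histogram] (typically median-smoothed).
#' @param balance_ratio mass-imbalance ratio that triggers the second pass;
#'   `Inf` degenerates to a single Otsu application.
#' @return Object of class `stem_interval`: `k_star`, `k1` (first-pass
#'   threshold), `sigma0`, `sigma1`, `lo`, `hi`, `passes`.
#' @export
valley_interval <- function(h, balance_ratio = 1.5) {
  stopifnot(inherits(h, "breadth_histogram"))
  n <- as.numeric(h$n); L <- h$L
  first <- otsu_histogram(h)
  k1 <- first$k_star
  m0 <- sum(n[1:k1]); m1 <- sum(n) - m0
  passes <- 1L; k_star <- k1
  if (is.finite(balance_ratio) &&
      max(m0, m1) / max(min(m0, m1), .Machine$double.eps) > balance_ratio) {
    weaker_left <- m0 < m1
    sub <- if (weaker_left) n[1:k1] else n[(k1 + 1L):L]
    if (sum(sub > 0) >= 2 && length(sub) >= 2) {
      k2 <- otsu_histogram(new_breadth_histogram(sub))$k_star
      k_star <- if (weaker_left) k2 else k1 + k2
      passes <- 2L
    }
  }
  i <- seq_len(L)
  sigma0 <- weighted_sd(i[i <= k_star], n[i <= k_star])
  sigma1 <- weighted_sd(i[i > k_star], n[i > k_star])
  structure(list(k_star = k_star, k1 = k1, sigma0 = sigma0, sigma1 = sigma1,
                 lo = max(1L, as.integer(floor(k_star - sigma0))),
                 hi = min(L, as.integer(ceiling(k_star + sigma1))),
                 passes = passes, L = L),
            class = "stem_interval")
}

#' @export
print.stem_interval <- function(x, ...) {
  cat(sprintf("<stem_interval> k*=%d (pass %d, k1=%d), valley [%d, %d] of %d rows\n",
              x$k_star, x$passes, x$k1, x$lo, x$hi, x$L))
  invisible(x)
}

#' Remove false-positive segments outside the stem valley
#'
#' A candidate segment survives when (a) its grid-row span intersects the
#' valley `[lo, hi]` -- at least part of it falls in the stem interval --
#' and (b) if its midpoint lies below the threshold k* (the pot side), the
#' mean full plant width over its spanned rows, counted in valid grid
#' cells, does not exceed `pot_breadth_max`: cross-sections in the pot
#' region are much wider than around a main stem, which is how pot-rim
#' false positives that sneak into the valley are rejected.
#'
#' @param segs list of `stem_segment` (same pixel frame as `grid`).
#' @param interval a [valley_interval] result.
#' @param grid the [build_grid] result the interval was computed on.
#' @param pot_breadth_max largest admissible mean cross-section, in grid
#'   cells, for a segment in the lower region.
#' @return The surviving subset of `segs` (ids preserved).
#' @export
filter_segments <- function(segs, interval, grid, pot_breadth_max = 4) {
  stopifnot(inherits(interval, "stem_interval"), inherits(grid, "grid_system"))
  widths <- row_widths(grid)
  keep <- vapply(segs, function(s) {
    i0 <- hist_index_of_row(grid, s$p0[2])
    i1 <- hist_index_of_row(grid, s$p1[2])
    span <- sort(c(i0, i1))
    if (span[2] < interval$lo || span[1] > interval$hi) return(FALSE)
    mid <- hist_index_of_row(grid, (s$p0[2] + s$p1[2]) / 2)
    if (mid > interval$k_star) {
      rows <- max(span[1], 1L):min(span[2], length(widths))
      if (length(rows) == 0L) return(TRUE)
      if (mean(widths[rows]) > pot_breadth_max) return(FALSE)
    }
    TRUE
  }, NA)
  segs[keep]
}

#' Serialize a stem interval (with its histogram) to JSON
#'
#' @param interval a [valley_interval] result.
#' @param h the [breadth_histogram] it was computed from (optional).
#' @param path output file.
#' @return `path`, invisibly.
#' @export
interval_to_json <- function(interval, path, h = NULL) {
  out <- list(k_star = interval$k_star, k1 = interval$k1,
              sigma0 = interval$sigma0, sigma1 = interval$sigma1,
              lo = interval$lo, hi = interval$hi, passes = interval$passes)
  if (!is.null(h)) out$histogram <- h$n
  jsonlite::write_json(out, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' Debug overlay of grid, axis, threshold and detections
#'
#' Writes a PNG of the color image overlaid with the grid (gray), the plant
#' axis (red), the final Otsu threshold row (blue), the valley bounds
#' (green) and the detected segments (blue with yellow endpoints).
#'
#' @param color `[rows, cols, 3]` color array.
#' @param grid,interval,segs pipeline results (any may be `NULL`).
#' @param path output PNG path.
#' @return `path`, invisibly.
#' @export
write_overlay_png <- function(color, grid, interval, segs, path) {
  img <- color
  h <- dim(img)[1]; w <- dim(img)[2]
  set_px <- function(r, c, col) {
    ok <- r >= 1 & r <= h & c >= 1 & c <= w
    r <- r[ok]; c <- c[ok]
    for (ch in 1:3) img[cbind(r, c, ch)] <<- col[ch]
  }
  if (!is.null(grid)) {
    for (gc in seq(grid$cell_px, w, by = grid$cell_px))
      set_px(seq_len(h), rep(gc, h), c(0.35, 0.35, 0.35))
    for (gr in seq(grid$cell_px, h, by = grid$cell_px))
      set_px(rep(gr, w), seq_len(w), c(0.35, 0.35, 0.35))
    ac <- round(grid$axis_col)
    set_px(seq_len(h), rep(ac, h), c(1, 0, 0))
    if (!is.null(interval)) {
      row_of <- function(i) min(h, (grid$origin_row + i) * grid$cell_px)
      set_px(rep(row_of(interval$k_star), w), seq_len(w), c(0.2, 0.4, 1))
      set_px(rep(row_of(interval$lo - 1L) + 1L, w), seq_len(w), c(0, 0.9, 0))
      set_px(rep(row_of(interval$hi), w), seq_len(w), c(0, 0.9, 0))
    }
  }
  for (s in segs %||% list()) {
    np <- max(2L, ceiling(s$length_px))
    t <- seq(0, 1, length.out = np)
    set_px(round(s$p0[2] + t * (s$p1[2] - s$p0[2])),
           round(s$p0[1] + t * (s$p1[1] - s$p0[1])), c(0.2, 0.5, 1))
    for (p in list(s$p0, s$p1))
      set_px(round(p[2]) + rep(-1:1, 3), round(p[1]) + rep(-1:1, each = 3),
             c(1, 1, 0))
  }
  write_color_png(img, path)
}
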