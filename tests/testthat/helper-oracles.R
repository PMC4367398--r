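# Independent oracles and small fixture builders shared across the suite.

# Brute-force Otsu oracle: direct evaluation of the class-probability
# definitions with explicit loops, kept independent of the package's
# cumulative-sum implementation.
brute_otsu <- function(n) {
  n <- as.numeric(n); L <- length(n); N <- sum(n)
  p <- n / N
  best_k <- NA_integer_; best <- -Inf
  for (k in seq_len(L - 1)) {
    w0 <- sum(p[1:k]); w1 <- 1 - w0
    if (w0 <= 0 || w1 <= 0) next
    mu0 <- sum((1:k) * p[1:k]) / w0
    mu1 <- sum(((k + 1):L) * p[(k + 1):L]) / w1
    sb <- w0 * w1 * (mu1 - mu0)^2
    if (sb > best) { best <- sb; best_k <- k }
  }
  # the argmax may be tied up to floating-point noise; report the tie set
  ks <- integer(0)
  for (k in seq_len(L - 1)) {
    w0 <- sum(p[1:k]); w1 <- 1 - w0
    if (w0 <= 0 || w1 <= 0) next
    mu0 <- sum((1:k) * p[1:k]) / w0
    mu1 <- sum(((k + 1):L) * p[(k + 1):L]) / w1
    if (w0 * w1 * (mu1 - mu0)^2 >= best * (1 - 1e-9)) ks <- c(ks, k)
  }
  list(k_star = best_k, sigma_b2 = best, tie_set = ks)
}

# between/within-class variance decomposition at a given split
variance_parts <- function(n, k) {
  n <- as.numeric(n); L <- length(n); p <- n / sum(n); i <- seq_len(L)
  w0 <- sum(p[1:k]); w1 <- 1 - w0
  mu0 <- if (w0 > 0) sum(i[1:k] * p[1:k]) / w0 else 0
  mu1 <- if (w1 > 0) sum(i[(k + 1):L] * p[(k + 1):L]) / w1 else 0
  muT <- sum(i * p)
  v0 <- if (w0 > 0) sum(p[1:k] * (i[1:k] - mu0)^2) / w0 else 0
  v1 <- if (w1 > 0) sum(p[(k + 1):L] * (i[(k + 1):L] - mu1)^2) / w1 else 0
  list(between = w0 * w1 * (mu1 - mu0)^2,
       within = w0 * v0 + w1 * v1,
       total = sum(p * (i - muT)^2))
}

# random histogram with mass in >= 2 distinct bars
random_histogram <- function(L) {
  repeat {
    n <- rpois(L, lambda = sample(1:8, 1))
    if (sum(n > 0) >= 2) return(n)
  }
}

# hand-built grid_system for breadth tests: one valid cell per (row, col)
toy_grid <- function(valid, axis_gc, cell_px = 8L) {
  structure(list(cell_px = cell_px, axis_col = axis_gc * cell_px - cell_px / 2,
                 axis_gc = axis_gc, valid = valid,
                 origin_row = 0L, bottom_row = nrow(valid),
                 img_rows = nrow(valid) * cell_px,
                 img_cols = ncol(valid) * cell_px),
            class = "grid_system")
}

# grid whose rows i have breadth raw[i] (valid cell at axis_gc + raw[i]),
# with zero-rows left empty
grid_with_breadths <- function(raw, axis_gc = 10L, ncol_g = 20L) {
  valid <- matrix(FALSE, length(raw), ncol_g)
  for (i in seq_along(raw)) {
    if (raw[i] > 0) {
      valid[i, axis_gc + raw[i]] <- TRUE     # farthest valid cell
      valid[i, axis_gc] <- TRUE              # row is occupied at the axis
    }                                        # raw 0 -> empty (dropout) row
  }
  toy_grid(valid, axis_gc)
}

new_hist <- function(n) tomstem:::new_breadth_histogram(n)

make_seg <- function(p0, p1, id = 1L) tomstem:::new_segment(p0, p1, id)

# one small rendered scene reused by pipeline tests (built once per run)
demo_render <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) {
      scn <- potted_plant_scene("ordinary", seed = 401, difficulty = "easy")
      cache <<- render_rgbd(scn, camera_model(),
                            noise_model(dropout_prob = 0.05, seed = 402))
    }
    cache
  }
})
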