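# Fixtures shared across test files; everything is generated in code.

# Filled disk mask of given radius centred in an n x n grid (1-based centre).
disk_mask <- function(n, radius, center = c((n + 1) / 2, (n + 1) / 2)) {
  rr <- matrix(seq_len(n), n, n)
  cc <- t(rr)
  sqrt((rr - center[1])^2 + (cc - center[2])^2) <= radius
}

# Tight bounding box around a mask plus a fixed margin, as an adx_bbox.
mask_bbox <- function(mask, margin = 4) {
  rows <- range(which(rowSums(mask) > 0))
  cols <- range(which(colSums(mask) > 0))
  make_bbox(max(0, rows[1] - 1 - margin), max(0, cols[1] - 1 - margin),
            min(nrow(mask), rows[2] + margin), min(ncol(mask), cols[2] + margin))
}

# A small noise-free phantom spec used by several files.
quiet_spec <- function(canvas = 64, seed = 1) {
  phantom_spec(canvas_size = canvas, axes = c(0.28, 0.2) * canvas,
               speckle = FALSE, component_layout = list(), seed = seed)
}

# Two-component phantom with a generously sized bright blob, for component
# recovery checks at unit-test scale.
two_level_spec <- function(canvas = 128, seed = 1) {
  phantom_spec(canvas_size = canvas,
               component_layout = list(list(type = "blob",
                                            center = c(0.25, -0.2),
                                            axes = c(0.55, 0.6))),
               seed = seed)
}

# One-pixel 8-neighbourhood erosion (used to peel the in-mask rim band).
erode1 <- function(m) {
  p <- rbind(FALSE, cbind(FALSE, m, FALSE), FALSE)
  h <- nrow(m); w <- ncol(m)
  out <- m
  for (dr in 0:2) for (dc in 0:2)
    out <- out & p[dr + seq_len(h), dc + seq_len(w)]
  out
}

# Brute-force average Hausdorff oracle: explicit double loop over all pairs.
ah_oracle <- function(a, b) {
  mins_ab <- numeric(nrow(a))
  for (i in seq_len(nrow(a))) {
    best <- Inf
    for (j in seq_len(nrow(b)))
      best <- min(best, sqrt((a[i, 1] - b[j, 1])^2 + (a[i, 2] - b[j, 2])^2))
    mins_ab[i] <- best
  }
  mins_ba <- numeric(nrow(b))
  for (j in seq_len(nrow(b))) {
    best <- Inf
    for (i in seq_len(nrow(a)))
      best <- min(best, sqrt((a[i, 1] - b[j, 1])^2 + (a[i, 2] - b[j, 2])^2))
    mins_ba[j] <- best
  }
  (mean(mins_ab) + mean(mins_ba)) / 2
}
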