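# Independent brute-force oracles for the ring decomposition.
#
# Erosion depth with a 4-connected (cross) structuring element equals the
# city-block distance to the nearest background pixel (pixels outside the
# frame count as background) minus one. Computed here by plain per-pixel
# minimisation, no morphology.

oracle_erosion_depth <- function(mask) {
  nr <- nrow(mask); nc <- ncol(mask)
  fg <- which(mask > 0, arr.ind = TRUE)
  bg <- which(mask == 0, arr.ind = TRUE)
  depth <- matrix(NA_integer_, nr, nc)
  for (k in seq_len(nrow(fg))) {
    i <- fg[k, 1]; j <- fg[k, 2]
    d_frame <- min(i, j, nr + 1 - i, nc + 1 - j)
    d_bg <- if (nrow(bg)) min(abs(bg[, 1] - i) + abs(bg[, 2] - j)) else Inf
    depth[i, j] <- min(d_frame, d_bg) - 1L
  }
  depth
}

# ring pixel counts implied by the oracle, in the peel_rings convention
oracle_ring_counts <- function(mask, n_in = 10) {
  depth <- oracle_erosion_depth(mask)
  ring <- ifelse(depth >= n_in, -n_in, -depth)
  tab <- table(factor(ring[!is.na(ring)], levels = -(0:n_in)))
  data.frame(ring = -(0:n_in), npix = as.integer(tab))
}

# a small library of masks within a given frame
oracle_mask_set <- function(side = 41) {
  disk <- function(r, cx = (side + 1) / 2, cy = cx) {
    d <- sqrt(outer((1:side - cx)^2, (1:side - cy)^2, "+"))
    (d <= r) * 1L
  }
  ellipse <- function(a, b, cx = (side + 1) / 2, cy = cx) {
    v <- outer(((1:side - cx) / a)^2, ((1:side - cy) / b)^2, "+")
    (v <= 1) * 1L
  }
  blob <- function(seed) {
    set.seed(seed)
    m <- disk(runif(1, 6, 14))
    holes <- matrix(runif(side * side) < 0.03, side, side)
    m[holes] <- 0L
    m
  }
  square <- matrix(0L, side, side); square[10:30, 8:34] <- 1L
  border_touch <- disk(12, cx = 3, cy = (side + 1) / 2)
  c(lapply(c(3, 5, 8, 12, 16, 19), disk),
    list(ellipse(15, 9), ellipse(8, 18), square, border_touch),
    lapply(1:4, blob))
}
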