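# Independent brute-force oracles used to validate the FFT / incremental
# implementations. These deliberately use plain array shifting and full
# recomputation, not the package's fast paths.

oracle_ball_offsets <- function(diameter) {
  r <- floor(diameter / 2 + 1e-9)
  s <- (-r):r
  g <- expand.grid(z = s, y = s, x = s)
  g[g$z^2 + g$y^2 + g$x^2 <= (diameter / 2)^2 + 1e-9, , drop = FALSE]
}

# Direct-space correlation: weighted mean of p over the ball at every
# voxel, zero padding outside, computed by explicit array shifts.
oracle_correlate <- function(p, diameter) {
  d <- dim(p)
  off <- oracle_ball_offsets(diameter)
  w <- 1 / nrow(off)
  out <- array(0, d)
  for (i in seq_len(nrow(off))) {
    oz <- off$z[i]; oy <- off$y[i]; ox <- off$x[i]
    zs <- max(1, 1 - oz):min(d[1], d[1] - oz)
    ys <- max(1, 1 - oy):min(d[2], d[2] - oy)
    xs <- max(1, 1 - ox):min(d[3], d[3] - ox)
    out[zs, ys, xs] <- out[zs, ys, xs] +
      w * p[zs + oz, ys + oy, xs + ox, drop = FALSE]
  }
  out
}

# argmax with the same tie rule as the implementation: among values
# within 1e-9 of the maximum, smallest (z, y, x) lexicographic index.
oracle_argmax <- function(cc) {
  d <- dim(cc)
  m <- max(cc)
  idx <- which(cc >= m - 1e-9)
  i0 <- idx - 1
  z <- i0 %% d[1]
  y <- (i0 %/% d[1]) %% d[2]
  x <- i0 %/% (d[1] * d[2])
  o <- order(z, y, x)[1]
  list(value = cc[idx[o]], index = c(z[o], y[o], x[o]))
}

# Full greedy oracle: recompute the complete direct-space correlation at
# every iteration, take the argmax, zero out a ball in p, repeat.
oracle_detect <- function(p, diameter, stop_threshold, max_iter = 50,
                          zero_diameter = diameter) {
  zoff <- oracle_ball_offsets(zero_diameter)
  d <- dim(p)
  out <- NULL
  for (it in seq_len(max_iter)) {
    cc <- oracle_correlate(p, diameter)
    am <- oracle_argmax(cc)
    if (am$value < stop_threshold) break
    out <- rbind(out, data.frame(z = am$index[1], y = am$index[2],
                                 x = am$index[3], score = am$value))
    pos <- sweep(as.matrix(zoff), 2, am$index, "+")
    keep <- pos[, 1] >= 0 & pos[, 1] < d[1] & pos[, 2] >= 0 &
      pos[, 2] < d[2] & pos[, 3] >= 0 & pos[, 3] < d[3]
    pos <- pos[keep, , drop = FALSE]
    p[pos + 1] <- 0
  }
  out
}

# A smooth random probability map in [0, 1] (blurred white noise),
# plausible input for a cell probability map.
random_prob_map <- function(dims, sigma = 2, seed = 1) {
  set.seed(seed)
  a <- array(runif(prod(dims)), dims)
  a <- gauss_blur3(a, sigma)
  rng <- range(a)
  a <- (a - rng[1]) / (rng[2] - rng[1])
  dim(a) <- dims
  a
}

# Binary ball of ones centered at `center` (0-based) in a zero volume.
ball_volume <- function(dims, center, diameter) {
  a <- array(0, dims)
  off <- as.matrix(oracle_ball_offsets(diameter))
  pos <- sweep(off, 2, as.integer(center), "+")
  keep <- pos[, 1] >= 0 & pos[, 1] < dims[1] & pos[, 2] >= 0 &
    pos[, 2] < dims[2] & pos[, 3] >= 0 & pos[, 3] < dims[3]
  a[pos[keep, , drop = FALSE] + 1] <- 1
  a
}
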