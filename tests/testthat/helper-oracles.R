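# Independent brute-force oracles used across the suite. These deliberately
# use explicit loops and definitions only, never the package's fast paths.

# Boundary set by definition: foreground pixels with a 4-connected
# background neighbour.
oracle_boundary <- function(mask) {
  H <- nrow(mask); W <- ncol(mask)
  out <- matrix(0L, H, W)
  for (i in seq_len(H)) for (j in seq_len(W)) {
    if (mask[i, j] == 0) next
    nb <- c(if (i > 1) mask[i - 1, j] else 1L,
            if (i < H) mask[i + 1, j] else 1L,
            if (j > 1) mask[i, j - 1] else 1L,
            if (j < W) mask[i, j + 1] else 1L)
    if (any(nb == 0)) out[i, j] <- 1L
  }
  out
}

# Exhaustive signed distance: minimum Euclidean distance over every
# boundary pixel, negated strictly inside, clipped at the image diagonal.
oracle_signed_distance <- function(mask, spacing = c(1, 1)) {
  H <- nrow(mask); W <- ncol(mask)
  b <- which(oracle_boundary(mask) == 1L, arr.ind = TRUE)
  d_max <- sqrt((H * spacing[1])^2 + (W * spacing[2])^2)
  if (nrow(b) == 0) return(matrix(d_max, H, W))
  out <- matrix(0, H, W)
  for (i in seq_len(H)) for (j in seq_len(W)) {
    d <- sqrt(min(((b[, 1] - i) * spacing[1])^2 +
                    ((b[, 2] - j) * spacing[2])^2))
    on_b <- any(b[, 1] == i & b[, 2] == j)
    out[i, j] <- if (mask[i, j] != 0 && !on_b) -d else d
  }
  out[out > d_max] <- d_max
  out[out < -d_max] <- -d_max
  out
}

# Loop-based finite differences: central differences, replicated edges,
# mixed derivative as the a-derivative of the b-derivative.
oracle_derivatives <- function(f) {
  H <- nrow(f); W <- ncol(f)
  at <- function(i, j) f[min(max(i, 1), H), min(max(j, 1), W)]
  ga <- gb <- gaa <- gbb <- matrix(0, H, W)
  for (i in seq_len(H)) for (j in seq_len(W)) {
    ga[i, j] <- (at(i + 1, j) - at(i - 1, j)) / 2
    gb[i, j] <- (at(i, j + 1) - at(i, j - 1)) / 2
    gaa[i, j] <- at(i + 1, j) + at(i - 1, j) - 2 * at(i, j)
    gbb[i, j] <- at(i, j + 1) + at(i, j - 1) - 2 * at(i, j)
  }
  gab <- matrix(0, H, W)
  gbat <- function(i, j) gb[min(max(i, 1), H), min(max(j, 1), W)]
  for (i in seq_len(H)) for (j in seq_len(W))
    gab[i, j] <- (gbat(i + 1, j) - gbat(i - 1, j)) / 2
  list(ga = ga, gb = gb, gaa = gaa, gbb = gbb, gab = gab)
}

# Curvature from the oracle derivatives (same analytic expression, applied
# to independently computed derivatives).
oracle_curvature <- function(s, eps = 1e-8) {
  d <- oracle_derivatives(s)
  ((1 + d$ga^2) * d$gbb + (1 + d$gb^2) * d$gaa - 2 * d$ga * d$gb * d$gab) /
    (2 * (1 + d$ga^2 + d$gb^2)^1.5 + eps)
}

# All-pairs average symmetric surface distance.
oracle_asd <- function(a, b, spacing = c(1, 1)) {
  ba <- which(oracle_boundary(a) == 1L, arr.ind = TRUE)
  bb <- which(oracle_boundary(b) == 1L, arr.ind = TRUE)
  if (nrow(ba) == 0 || nrow(bb) == 0) return(NA_real_)
  dmat <- matrix(0, nrow(ba), nrow(bb))
  for (p in seq_len(nrow(ba))) for (q in seq_len(nrow(bb)))
    dmat[p, q] <- sqrt(((ba[p, 1] - bb[q, 1]) * spacing[1])^2 +
                         ((ba[p, 2] - bb[q, 2]) * spacing[2])^2)
  (mean(apply(dmat, 1, min)) + mean(apply(dmat, 2, min))) / 2
}

# Loop-based cross-entropy with the 1/(H*W*C) normalization.
oracle_ce <- function(p, y, clip = 1e-12) {
  s <- 0
  d <- dim(p)
  for (i in seq_len(d[1])) for (j in seq_len(d[2])) for (k in seq_len(d[3]))
    s <- s + y[i, j, k] * log(max(p[i, j, k], clip))
  -s / prod(d)
}

rand_mask <- function(H, W, p = 0.4) matrix(rbinom(H * W, 1, p), H, W)

disk_mask <- function(size, cy, cx, r) {
  outer((seq_len(size) - cy)^2, (seq_len(size) - cx)^2, "+") <= r^2
}

small_circle_cfg <- function(size = 48, n = 10, steps = 40, seed = 3,
                             base = 4, depth = 2, ...) {
  run_config(
    architecture = arch_config(input_size = c(size, size), depth = depth,
                               base_channels = base, aux_enabled = FALSE, ...),
    data = circle_dataset_spec(n_images = n, image_size = c(size, size),
                               radius_range = c(5, size / 4), seed = seed),
    seed = seed, steps = steps, batch_size = 2)
}
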