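# Shared helpers: small deterministic inputs and independent brute-force
# oracles used across the suite.

rand_map <- function(H, W, seed) {
  set.seed(seed)
  matrix(runif(H * W), H, W)
}

# Edge map taking exactly `levels` equispaced values in [0, 1].
leveled_map <- function(H, W, levels, seed) {
  set.seed(seed)
  vals <- seq(0, 1, length.out = levels)
  matrix(sample(vals, H * W, replace = TRUE), H, W)
}

# Independent brute-force MCONVEF: plain triple loop over output pixels and
# window offsets, written with scalar index arithmetic only (no shifts, no
# vectorized tricks), so it shares nothing with the implementation under
# test.
mconvef_loop_oracle <- function(f, t, h, k) {
  H <- nrow(f); W <- ncol(f)
  u <- v <- matrix(0, H, W)
  for (r0 in seq_len(H)) {
    for (c0 in seq_len(W)) {
      su <- sv <- 0
      for (dy in -t:t) {
        for (dx in -t:t) {
          if (dx == 0 && dy == 0) next
          r <- r0 + dy; c <- c0 + dx
          if (r < 1 || r > H || c < 1 || c > W) next
          g <- 1 / (1 + ((f[r, c] - f[r0, c0]) / k)^2)
          w <- g * f[r, c] / (dx^2 + dy^2 + h)^1.5
          su <- su + dx * w
          sv <- sv + dy * w
        }
      }
      u[r0, c0] <- su
      v[r0, c0] <- sv
    }
  }
  list(u = u, v = v)
}

# Discrete GVF energy of a field against an edge map (rectangle rule, unit
# spacing, forward differences with replicate boundary).
gvf_energy <- function(field, f, mu) {
  fwdx <- function(m) cbind(m[, -1], m[, ncol(m)]) - m
  fwdy <- function(m) rbind(m[-1, ], m[nrow(m), ]) - m
  g <- snakefields:::image_gradient(f)
  b <- g$fx^2 + g$fy^2
  smooth <- fwdx(field$u)^2 + fwdy(field$u)^2 + fwdx(field$v)^2 + fwdy(field$v)^2
  fid <- b * ((field$u - g$fx)^2 + (field$v - g$fy)^2)
  sum(mu * smooth + fid)
}

max_abs_diff <- function(a, b) max(abs(a$u - b$u), abs(a$v - b$v))

# Canonical noise seed used by the end-to-end benchmark tests.
BENCH_SEED <- 7L
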