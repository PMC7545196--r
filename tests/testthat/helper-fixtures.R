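# Shared fixtures, built in code.

# regular n-gon inscribed in a circle of radius r
regularPolygon <- function(n, r = 1, center = c(0, 0)) {
  th <- seq(0, 2 * pi, length.out = n + 1L)[-(n + 1L)]
  cbind(center[1L] + r * cos(th), center[2L] + r * sin(th))
}

# planar circular arc of radius R and total arc length L in the xy plane,
# starting at the origin heading along +x
arcPoints <- function(R, L, n) {
  s <- seq(0, L, length.out = n)
  cbind(R * sin(s / R), R * (1 - cos(s / R)), 0)
}

# random rigid transform (rotation + translation) applied to rows of P
rigidTransform <- function(P, seed) {
  set.seed(seed)
  # QR of a random matrix gives a uniform-ish rotation
  qr0 <- qr(matrix(rnorm(9), 3L))
  Q <- qr.Q(qr0)
  if (det(Q) < 0) Q[, 1L] <- -Q[, 1L]
  tr <- rnorm(3L, 0, 10)
  sweep(P %*% Q, 2L, -tr)
}

# small synthetic slice: Gaussian background plus a bright disk
diskSlice <- function(n = 64L, px = 0.253, r = 2, level = c(bg = 700,
                                                            disk = 3000),
                      noiseSd = 0, seed = 1L) {
  set.seed(seed)
  ctr <- (n - 1L) / 2 * px
  x <- (seq_len(n) - 1L) * px
  d2 <- outer(x, x, function(a, b) (a - ctr)^2) +
    t(outer(x, x, function(a, b) (a - ctr)^2))
  m <- matrix(level[["bg"]], n, n)
  m[d2 <= r^2] <- level[["disk"]]
  if (noiseSd > 0) m <- m + matrix(rnorm(n * n, 0, noiseSd), n, n)
  list(slice = m, center = c(ctr, ctr), px = px)
}

# tiny phantom spec for fast tests: coarser grid, same geometry
fastSpec <- function(...) PhantomSpec(spacing = c(0.4, 0.4, 1), ...)
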