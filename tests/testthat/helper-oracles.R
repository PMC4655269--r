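# Independent brute-force oracles used across the suite. These deliberately
# avoid the package's own code paths.

# --- B-spline by iterated numeric convolution -------------------------------
# B_1 is the exact overlap length of (x-1/2, x+1/2) with (-1/2, 1/2) — the
# direct convolution of the unit box with itself. Each higher order is the
# sliding integral of the previous level over a unit window, computed with
# the composite trapezoid rule via cumulative sums (O(n) per level, so a very
# fine dyadic step is affordable). All knots are half-integers, hence exact
# grid points: the trapezoid rule is exact on the piecewise-linear hat, and
# for the C^1 higher orders its composite error is ~ delta^2/12 * TV(B') —
# about 1e-11 at the default step. Returns values on the grid.
bspline_conv_oracle <- function(k_max = 4, delta = 1 / 65536, lim = 4) {
  x <- seq(-lim, lim, by = delta)
  n <- length(x)
  m <- round(0.5 / delta)                # half-window in samples
  levels <- vector("list", k_max)
  levels[[1]] <- pmax(0, pmin(x + 0.5, 0.5) - pmax(x - 0.5, -0.5))
  for (k in seq_len(k_max)[-1]) {
    v <- levels[[k - 1]]
    S <- cumsum(v)
    out <- numeric(n)
    j <- (m + 1):(n - m)                 # windows fully inside the grid
    # trapezoid over [x_j - 1/2, x_j + 1/2]
    out[j] <- delta * (S[j + m] - S[j - m]) - delta * (v[j + m] - v[j - m]) / 2
    levels[[k]] <- out
  }
  list(x = x, B = levels)                # B[[k]] is order-k values on x
}

# --- dense 2D oracles -------------------------------------------------------

# direct sliding-window 2D convolution, complex kernel, zero or mirror padding
conv2_brute <- function(f, kern, padding = "zero") {
  s <- nrow(kern)
  h <- (s - 1L) %/% 2L
  nr <- nrow(f); nc <- ncol(f)
  if (padding == "reflect") {
    ri <- c(h:1, 1:nr, nr:(nr - h + 1L))
    ci <- c(h:1, 1:nc, nc:(nc - h + 1L))
    fp <- f[ri, ci]
  } else {
    fp <- matrix(0, nr + 2L * h, nc + 2L * h)
    fp[(h + 1L):(h + nr), (h + 1L):(h + nc)] <- f
  }
  kflip <- kern[s:1, s:1]                # convolution = correlation w/ flip
  out <- matrix(0 + 0i, nr, nc)
  for (r in seq_len(nr)) {
    for (c in seq_len(nc)) {
      win <- fp[r:(r + s - 1L), c:(c + s - 1L)]
      out[r, c] <- sum(win * kflip)
    }
  }
  out
}

# bilinear rotation about the matrix centre (outside samples -> 0)
rotate_bilinear <- function(m, theta) {
  nr <- nrow(m); nc <- ncol(m)
  cy <- (nr + 1) / 2; cx <- (nc + 1) / 2
  out <- matrix(0, nr, nc)
  ct <- cos(theta); st <- sin(theta)
  for (r in seq_len(nr)) {
    for (c in seq_len(nc)) {
      dy <- r - cy; dx <- c - cx
      # source point = target rotated back by theta
      sy <- cy + ( ct * dy - st * dx)
      sx <- cx + ( st * dy + ct * dx)
      r0 <- floor(sy); c0 <- floor(sx)
      if (r0 < 1 || c0 < 1 || r0 + 1 > nr || c0 + 1 > nc) next
      fy <- sy - r0; fx <- sx - c0
      out[r, c] <- (1 - fy) * (1 - fx) * m[r0, c0] +
        (1 - fy) * fx * m[r0, c0 + 1] +
        fy * (1 - fx) * m[r0 + 1, c0] +
        fy * fx * m[r0 + 1, c0 + 1]
    }
  }
  out
}

# per-pixel minimum over the third axis, exhaustive loops
min_fuse_brute <- function(arr) {
  out <- matrix(Inf, dim(arr)[1], dim(arr)[2])
  for (r in seq_len(dim(arr)[1])) {
    for (c in seq_len(dim(arr)[2])) {
      for (i in seq_len(dim(arr)[3])) {
        if (arr[r, c, i] < out[r, c]) out[r, c] <- arr[r, c, i]
      }
    }
  }
  out
}

# literal scan of the threshold definition; NA if no level qualifies
threshold_brute <- function(img, h) {
  H <- rep(0L, 256)
  for (v in as.integer(img)) H[v + 1L] <- H[v + 1L] + 1L
  g_min <- which(H == max(H))[1L] - 1L
  for (i in g_min:255L) {
    if (H[i + 1L] < h) return(i)
  }
  NA_integer_
}

# pixel-by-pixel confusion enumeration
confusion_brute <- function(pred, truth) {
  TN <- 0L; BN <- 0L; FN <- 0L; Nvp <- 0L; Nuvp <- 0L
  for (j in seq_along(pred)) {
    p <- pred[j] != 0; t <- truth[j] != 0
    if (t) Nvp <- Nvp + 1L else Nuvp <- Nuvp + 1L
    if (p && t) TN <- TN + 1L
    if (!p && !t) BN <- BN + 1L
    if (p && !t) FN <- FN + 1L
  }
  list(TN = TN, BN = BN, FN = FN, Nvp = Nvp, Nuvp = Nuvp)
}

# smallest angular distance between two line orientations (mod pi), radians
line_angle_dist <- function(a, b) {
  d <- abs(a - b) %% pi
  min(d, pi - d)
}
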