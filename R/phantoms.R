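# Deterministic synthetic vessel phantoms with ground truth: dark curvilinear
# structures of known width and orientation on a brighter background, so every
# pipeline stage is testable without external image databases.
#
# Conventions: spatial angle is measured from the +x (column) axis toward +y
# (rows, downward); width is the full width at half contrast (FWHM) of the
# Gaussian cross-section; gray levels are on the 0-255 scale.

fwhm_to_sigma <- function(width) width / (2 * sqrt(2 * log(2)))

check_phantom_levels <- function(contrast, background_level, noise_sigma,
                                 width = 1) {
  if (width < 1) stop("'width' must be >= 1 pixel")
  if (contrast < 0 || contrast > background_level || background_level > 255) {
    stop("need 0 <= contrast <= background_level <= 255")
  }
  if (noise_sigma < 0) stop("'noise_sigma' must be >= 0")
}

#' Additive Gaussian noise
#'
#' Adds seeded i.i.d. Gaussian noise and clips to the 0-255 range.
#' `sigma = 0` returns the input unchanged (no RNG draw).
#'
#' @param img numeric matrix on the 0-255 scale.
#' @param sigma noise standard deviation in gray levels, `>= 0`.
#' @param seed integer RNG seed.
#' @return numeric matrix, `dim(img)`.
#' @export
add_noise <- function(img, sigma, seed = 1L) {
  if (length(sigma) != 1L || !is.finite(sigma) || sigma < 0) {
    stop("'sigma' must be >= 0")
  }
  if (sigma == 0) return(img)
  noisy <- withr::with_seed(seed, img + stats::rnorm(length(img), sd = sigma))
  noisy[noisy < 0] <- 0
  noisy[noisy > 255] <- 255
  dim(noisy) <- dim(img)
  noisy
}

#' Straight-bar phantom
#'
#' A dark straight band of given FWHM `width` and orientation through the
#' image centre on a uniform background, with a Gaussian cross-section
#' (emulating fundus blur) and optional additive noise. Ground truth marks
#' pixels within half the width of the centreline; a separate centreline mask
#' marks pixels within half a pixel of it.
#'
#' @param shape `(rows, cols)`.
#' @param angle bar orientation in degrees (0 = horizontal, increasing toward
#'   the downward row axis).
#' @param width full width at half contrast, pixels (>= 1).
#' @param contrast background minus vessel-centre gray level.
#' @param background_level uniform background gray.
#' @param noise_sigma additive Gaussian noise, gray levels.
#' @param seed integer RNG seed (noise only; geometry is deterministic).
#' @return list with `image` (matrix), `truth` (0/1 matrix), `centerline`
#'   (0/1 matrix), and `spec` (the arguments).
#' @export
make_bar <- function(shape = c(128L, 128L), angle = 0, width = 5,
                     contrast = 60, background_level = 180,
                     noise_sigma = 3, seed = 1L) {
  check_phantom_levels(contrast, background_level, noise_sigma, width)
  nr <- shape[1L]; nc <- shape[2L]
  cy <- (nr + 1) / 2; cx <- (nc + 1) / 2
  # sinpi/cospi are exact at multiples of 90 degrees, so axis-aligned bars
  # have bit-exact symmetric geometry
  sa <- sinpi(angle / 180); ca <- cospi(angle / 180)
  X <- matrix(seq_len(nc), nr, nc, byrow = TRUE) - cx
  Y <- matrix(seq_len(nr), nr, nc) - cy
  d <- abs(-sa * X + ca * Y)              # perpendicular distance to centreline
  img <- background_level - contrast * exp(-d^2 / (2 * fwhm_to_sigma(width)^2))
  img <- add_noise(img, noise_sigma, seed)
  vessel_present <- contrast > 0          # zero contrast means no vessel
  list(
    image = img,
    truth = (d <= width / 2) * vessel_present,
    centerline = (d <= 0.5) * vessel_present,
    spec = list(shape = shape, kind = "bar", angle = angle, width = width,
                contrast = contrast, background_level = background_level,
                noise_sigma = noise_sigma, seed = seed)
  )
}

#' Blank (vessel-free) phantom
#'
#' A uniform background with optional additive noise and an empty truth mask;
#' the specificity floor for the pipeline.
#'
#' @inheritParams make_bar
#' @return list with `image`, `truth` (all zeros), `spec`.
#' @export
make_blank <- function(shape = c(256L, 256L), background_level = 180,
                       noise_sigma = 0, seed = 1L) {
  check_phantom_levels(0, background_level, noise_sigma)
  img <- matrix(background_level, shape[1L], shape[2L])
  img <- add_noise(img, noise_sigma, seed)
  list(
    image = img,
    truth = matrix(0, shape[1L], shape[2L]),
    spec = list(shape = shape, kind = "blank",
                background_level = background_level,
                noise_sigma = noise_sigma, seed = seed)
  )
}

# Stamp a Gaussian-profiled disk (and its half-width truth disk) at one
# centreline sample point into the accumulators, by maximum blending.
stamp_point <- function(depth, truth, py, px, w, contrast) {
  nr <- nrow(depth); nc <- ncol(depth)
  sigma <- fwhm_to_sigma(w)
  R <- ceiling(2.5 * sigma + 1)
  r0 <- max(1L, floor(py - R)); r1 <- min(nr, ceiling(py + R))
  c0 <- max(1L, floor(px - R)); c1 <- min(nc, ceiling(px + R))
  if (r0 > r1 || c0 > c1) return(list(depth = depth, truth = truth))
  rr <- r0:r1; cc <- c0:c1
  d2 <- outer((rr - py)^2, (cc - px)^2, `+`)
  depth[rr, cc] <- pmax(depth[rr, cc], contrast * exp(-d2 / (2 * sigma^2)))
  truth[rr, cc] <- pmax(truth[rr, cc], (d2 <= (w / 2)^2) * 1)
  list(depth = depth, truth = truth)
}

#' Branching vessel-tree phantom
#'
#' A seeded recursive branching network emulating a fundus frame: three
#' generations of smoothly curving branches with tapering widths (default
#' FWHM 7, 3, 1.5 px), darker than the background in the green channel, a
#' mild radial illumination falloff, and additive Gaussian noise. The
#' returned RGB image has a near-saturated low-contrast red channel and a
#' dark blue channel, with all vessel contrast in the green plane (stored
#' separately in `gray`, to which the green channel is identical). Fully
#' reproducible from the seed; the truth mask does not depend on
#' `noise_sigma`.
#'
#' @inheritParams make_bar
#' @param n_roots number of root vessels entering from the frame border.
#' @param widths FWHM per generation, pixels (length = number of generations).
#' @return list with `rgb` (`rows x cols x 3` array), `gray` (the green
#'   plane), `truth` (0/1 matrix), `spec`.
#' @export
make_tree <- function(shape = c(256L, 256L), seed = 1L, contrast = 60,
                      background_level = 180, noise_sigma = 3,
                      n_roots = 2L, widths = c(7, 3, 1.5)) {
  check_phantom_levels(contrast, background_level, noise_sigma,
                       width = min(widths))
  nr <- shape[1L]; nc <- shape[2L]
  depth <- matrix(0, nr, nc)
  truth <- matrix(0, nr, nc)
  m <- min(nr, nc)

  geom <- withr::with_seed(seed, {
    # each branch: start point, heading, length, generation
    queue <- list()
    for (r in seq_len(n_roots)) {
      side <- sample(4L, 1L)
      pos <- switch(side,
        c(1, stats::runif(1, 0.2, 0.8) * nc),
        c(nr, stats::runif(1, 0.2, 0.8) * nc),
        c(stats::runif(1, 0.2, 0.8) * nr, 1),
        c(stats::runif(1, 0.2, 0.8) * nr, nc))
      to_centre <- atan2(nr / 2 - pos[1L], nc / 2 - pos[2L])
      heading <- to_centre + stats::runif(1, -pi / 6, pi / 6)
      queue[[length(queue) + 1L]] <- list(
        pos = pos, heading = heading, gen = 1L,
        len = stats::runif(1, 0.55, 0.8) * m)
    }
    segments <- list()
    gen_len <- c(1, 0.45, 0.3)           # length factors per generation
    while (length(queue) > 0L) {
      br <- queue[[1L]]; queue[[1L]] <- NULL
      w <- widths[br$gen]
      curv <- stats::rnorm(1, 0, 0.006)  # rad per px, per-branch bias
      pts <- matrix(NA_real_, ceiling(br$len / 0.5), 2L)
      pos <- br$pos; heading <- br$heading
      n_pts <- 0L
      travelled <- 0
      while (travelled < br$len) {
        pos <- pos + 0.5 * c(sin(heading), cos(heading))
        heading <- heading + 0.5 * (curv + stats::rnorm(1, 0, 0.01))
        travelled <- travelled + 0.5
        if (pos[1L] < -5 || pos[1L] > nr + 5 ||
            pos[2L] < -5 || pos[2L] > nc + 5) break
        n_pts <- n_pts + 1L
        pts[n_pts, ] <- pos
      }
      if (n_pts > 0L) {
        segments[[length(segments) + 1L]] <-
          list(pts = pts[seq_len(n_pts), , drop = FALSE], w = w)
      }
      if (br$gen < length(widths) && n_pts > 0L) {
        split <- stats::runif(1, 0.35, 0.7) * pi / 4   # half-angle of the fork
        for (s in c(-1, 1)) {
          queue[[length(queue) + 1L]] <- list(
            pos = pos, heading = heading + s * split, gen = br$gen + 1L,
            len = stats::runif(1, 0.8, 1.2) * gen_len[br$gen + 1L] * m)
        }
      }
    }
    segments
  })

  for (seg in geom) {
    for (j in seq_len(nrow(seg$pts))) {
      st <- stamp_point(depth, truth, seg$pts[j, 1L], seg$pts[j, 2L],
                        seg$w, contrast)
      depth <- st$depth; truth <- st$truth
    }
  }

  # mild radial illumination falloff of the background
  cy <- (nr + 1) / 2; cx <- (nc + 1) / 2
  RY <- matrix(seq_len(nr), nr, nc) - cy
  RX <- matrix(seq_len(nc), nr, nc, byrow = TRUE) - cx
  # mild falloff, saturating at the inscribed circle (max 12% everywhere)
  r2 <- (RY^2 + RX^2) / ((m / 2)^2)
  bg <- background_level * (1 - 0.12 * pmin(r2, 1))

  gray <- bg - depth
  gray <- add_noise(gray, noise_sigma, seed + 1000000L)

  red <- pmin(255, 150 + 0.4 * gray)
  blue <- pmax(0, 0.3 * gray)
  rgb <- array(c(red, gray, blue), c(nr, nc, 3L))

  list(
    rgb = rgb, gray = gray, truth = truth,
    spec = list(shape = shape, kind = "tree", contrast = contrast,
                background_level = background_level,
                noise_sigma = noise_sigma, seed = seed,
                n_roots = n_roots, widths = widths)
  )
}
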