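# helper: radial coordinate of every sample of an (nr, nc) DFT grid,
# recomputed independently of the package internals
grid_rho <- function(nr, nc) {
  sf <- function(n) ((0:(n - 1) + n %/% 2) %% n) - n %/% 2
  FY <- matrix(sf(nr), nr, nc)
  FX <- matrix(sf(nc), nr, nc, byrow = TRUE)
  2 * sqrt(FY^2 + FX^2) / min(nr, nc)
}

test_that("cake samples compose the angular and radial factors", {
  N <- 8; k <- 3
  cake <- build_fourier_cake(c(32, 32), 0, N = N, k = k)
  # channel 0 detects horizontal lines: wedge centred on the +fy axis,
  # sampled exactly at (fy = 3, fx = 0) -> row 4, col 1 in DFT order
  rho <- 2 * 3 / 32
  expect_equal(cake$grid[4, 1], bspline(0, k) * radial_profile(rho))
  # DC is shared equally between channels
  expect_equal(cake$grid[1, 1], 1 / N)
  # values confined to [0, 1]
  expect_true(all(cake$grid >= 0 & cake$grid <= 1))
})

test_that("samples outside the B-spline wedge are zero", {
  N <- 8; k <- 3
  s_theta <- 2 * pi / N
  cake <- build_fourier_cake(c(32, 32), 2, N = N, k = k)
  sf <- function(n) ((0:(n - 1) + n %/% 2) %% n) - n %/% 2
  FY <- matrix(sf(32), 32, 32)
  FX <- matrix(sf(32), 32, 32, byrow = TRUE)
  phi <- atan2(FY, FX)
  dphi <- (phi - (2 * s_theta + pi / 2) + pi) %% (2 * pi) - pi
  outside <- abs(dphi) >= (k + 1) * s_theta / 2
  outside[1, 1] <- FALSE
  expect_true(all(cake$grid[outside] == 0))
})

test_that("the N cakes tile the plane: sum equals the radial profile", {
  for (case in list(c(2, 3), c(8, 3), c(16, 1), c(32, 3))) {
    N <- case[1]; k <- case[2]
    total <- Reduce(`+`, lapply(0:(N - 1), function(i) {
      build_fourier_cake(c(48, 64), i, N = N, k = k)$grid
    }))
    expected <- radial_profile(grid_rho(48, 64))
    err <- abs(total - expected)
    err[1, 1] <- 0                       # DC handled by equal sharing
    expect_lt(max(err), 1e-6)
    expect_equal(total[1, 1], radial_profile(0))
  }
})

test_that("spatial kernels are quadrature pairs (real even, imaginary odd)", {
  for (params in list(list(N = 8, k = 3, t = 0.05, q = 8),
                      list(N = 16, k = 1, t = 0.1, q = 4))) {
    bank <- build_filter_bank(
      c(64, 64), seg_config(N = params$N, k = params$k, t = params$t,
                            q = params$q))
    for (kern in bank$kernels) {
      s <- nrow(kern$real)
      flip <- function(m) m[s:1, s:1]
      scale <- max(abs(kern$real))
      expect_lt(max(abs(kern$real - flip(kern$real))), 1e-8 * scale)
      expect_lt(max(abs(kern$imag + flip(kern$imag))), 1e-8 * scale)
    }
  }
})

test_that("kernels are rotated copies of channel 0", {
  bank <- build_filter_bank(c(64, 64), seg_config(N = 8, support = 33))
  k0 <- bank$kernels[[1]]$real
  for (i in c(2, 3, 5)) {
    theta <- bank$channel_angles[i]
    rot <- rotate_bilinear(k0, theta)
    rel <- sqrt(sum((bank$kernels[[i]]$real - rot)^2) / sum(k0^2))
    # bilinear interpolation attenuates the oscillatory pattern at oblique
    # angles (~16% L2 at 45 degrees); axis rotations are near-exact
    expect_lt(rel, 0.25)
  }
})

test_that("bank structure is ordered and complete", {
  bank <- build_filter_bank(c(64, 64), seg_config(N = 8))
  expect_length(bank$kernels, 8)
  expect_length(bank$cakes, 8)
  expect_identical(vapply(bank$cakes, `[[`, 0L, "orientation_index"), 0:7)
  expect_identical(vapply(bank$kernels, `[[`, 0L, "orientation_index"), 0:7)
  expect_true(all(diff(bank$channel_angles) > 0))
  expect_true(all(bank$channel_angles >= 0 & bank$channel_angles < 2 * pi))
  # smallest admissible bank
  expect_length(build_filter_bank(c(32, 32), seg_config(N = 2))$kernels, 2)
})

test_that("N = 2 wedges are antipodal", {
  c0 <- build_fourier_cake(c(33, 33), 0, N = 2, k = 1)$grid
  c1 <- build_fourier_cake(c(33, 33), 1, N = 2, k = 1)$grid
  # on an odd grid, frequency negation is index reversal about DC
  idx <- c(1, 33:2)
  expect_equal(c1, c0[idx, idx], tolerance = 1e-12)
})

test_that("a bank round-trips through its container file", {
  bank <- build_filter_bank(c(32, 32), seg_config(N = 4))
  path <- withr::local_tempfile(fileext = ".rds")
  bank_save(bank, path)
  expect_equal(bank_load(path), bank)
  other <- withr::local_tempfile(fileext = ".rds")
  saveRDS(1:3, other)
  expect_error(bank_load(other), "not a saved bank")
})

test_that("construction errors are reported", {
  expect_error(build_fourier_cake(c(2, 2), 0), "4 x 4")
  expect_error(build_fourier_cake(c(32, 32), 9, N = 8), "orientation_index")
  expect_error(build_fourier_cake(c(32, 32), -1, N = 8), "orientation_index")
  cake <- build_fourier_cake(c(32, 32), 0, N = 8)
  expect_error(build_spatial_kernel(cake, 4, 10), "odd")
  expect_error(build_spatial_kernel(cake, -1, 9), "sigma_s")
  expect_error(build_spatial_kernel(cake, 4, 65), "extent")
})
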