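# Orientation scores: per-channel complex responses U_f(x, theta) lifting a
# 2D image to position-orientation space.

# Reflect-pad a matrix by p pixels on every side (edge-inclusive mirror).
pad_reflect <- function(x, p) {
  if (p == 0L) return(x)
  nr <- nrow(x); nc <- ncol(x)
  if (p > nr || p > nc) stop("padding exceeds image extent")
  ri <- c(p:1, 1:nr, nr:(nr - p + 1L))
  ci <- c(p:1, 1:nc, nc:(nc - p + 1L))
  x[ri, ci, drop = FALSE]
}

pad_zero <- function(x, p) {
  if (p == 0L) return(x)
  out <- matrix(0, nrow(x) + 2L * p, ncol(x) + 2L * p)
  out[(p + 1L):(p + nrow(x)), (p + 1L):(p + ncol(x))] <- x
  out
}

# Embed a (2h+1)^2 kernel into an nr x nc grid with its centre at [1, 1]
# (wrap-around), ready for FFT-based circular convolution.
embed_kernel <- function(kern, nr, nc) {
  s <- nrow(kern)
  h <- (s - 1L) %/% 2L
  out <- matrix(0 + 0i, nr, nc)
  ri <- ((-h:h) %% nr) + 1L
  ci <- ((-h:h) %% nc) + 1L
  out[ri, ci] <- kern
  out
}

#' Complex response of an image to one cake kernel
#'
#' Computes the 2D convolution `psi_theta * f` (kernel flipped, per the
#' convolution definition) with the requested boundary handling, returning a
#' complex response of the same shape as the input. The convolution runs in
#' the Fourier domain after padding by half the kernel support, which is where
#' the filters are defined anyway; reflect padding suppresses wrap-around at
#' the fundus border.
#'
#' @param f numeric matrix (grayscale image).
#' @param kernel a `cake_kernel` from [build_spatial_kernel()].
#' @param padding `"reflect"` (default) or `"zero"`.
#' @return complex matrix, `dim(f)`.
#' @export
orientation_score <- function(f, kernel, padding = c("reflect", "zero")) {
  padding <- match.arg(padding)
  stopifnot(inherits(kernel, "cake_kernel"))
  if (!is.matrix(f) || !is.numeric(f)) stop("'f' must be a numeric matrix")
  s <- nrow(kernel$real)
  if (s > nrow(f) || s > ncol(f)) stop("kernel support exceeds image extent")
  p <- (s - 1L) %/% 2L
  padded <- switch(padding, reflect = pad_reflect(f, p), zero = pad_zero(f, p))
  nr <- nrow(padded); nc <- ncol(padded)
  kc <- complex(real = kernel$real, imaginary = kernel$imag)
  dim(kc) <- dim(kernel$real)
  K <- fft(embed_kernel(kc, nr, nc))
  Fp <- fft(padded)
  conv <- fft(Fp * K, inverse = TRUE) / (nr * nc)
  conv[(p + 1L):(p + nrow(f)), (p + 1L):(p + ncol(f)), drop = FALSE]
}

#' Orientation-score stack of an image under a filter bank
#'
#' Applies every kernel of the bank to the image, producing the stack of
#' complex responses indexed by position and orientation channel. On a dark
#' vessel, the real component of the channel aligned with the vessel takes
#' the most negative values, which is what the downstream minimum fusion
#' exploits.
#'
#' @param f numeric matrix (grayscale image).
#' @param bank a `cake_bank`.
#' @param padding boundary mode, see [orientation_score()].
#' @return object of class `orientation_stack`: list with `real` and `imag`
#'   (`rows x cols x N` arrays) and `channel_angles` (radians, strictly
#'   increasing in `[0, 2*pi)`).
#' @export
compute_stack <- function(f, bank, padding = c("reflect", "zero")) {
  padding <- match.arg(padding)
  stopifnot(inherits(bank, "cake_bank"))
  N <- length(bank$kernels)
  re <- array(0, c(dim(f), N))
  im <- array(0, c(dim(f), N))
  # the padded image transform is shared by all channels
  s <- nrow(bank$kernels[[1]]$real)
  if (s > nrow(f) || s > ncol(f)) stop("kernel support exceeds image extent")
  p <- (s - 1L) %/% 2L
  padded <- switch(padding, reflect = pad_reflect(f, p), zero = pad_zero(f, p))
  nr <- nrow(padded); nc <- ncol(padded)
  Fp <- fft(padded)
  rows <- (p + 1L):(p + nrow(f))
  cols <- (p + 1L):(p + ncol(f))
  for (i in seq_len(N)) {
    kern <- bank$kernels[[i]]
    kc <- complex(real = kern$real, imaginary = kern$imag)
    dim(kc) <- dim(kern$real)
    u <- fft(Fp * fft(embed_kernel(kc, nr, nc)), inverse = TRUE) / (nr * nc)
    re[, , i] <- Re(u[rows, cols])
    im[, , i] <- Im(u[rows, cols])
  }
  structure(
    list(real = re, imag = im, channel_angles = bank$channel_angles),
    class = "orientation_stack"
  )
}
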