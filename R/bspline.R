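#' Centered cardinal B-spline
#'
#' Evaluates the centered cardinal B-spline of order `k`, defined recursively
#' as `B_k = B_{k-1} * B_0` (convolution), where `B_0` is the indicator of the
#' open interval (-1/2, 1/2). `B_k` is nonnegative, supported on
#' `(-(k+1)/2, (k+1)/2)`, and its integer shifts form a partition of unity.
#' Used here as the angular profile of the cake filters: dividing the angular
#' coordinate by the channel spacing turns the partition of unity over integer
#' shifts into an exact tiling of the frequency plane by the wedges.
#'
#' The implementation uses the closed-form divided-difference expansion
#' `B_k(x) = 1/k! * sum_j (-1)^j C(k+1, j) (x + (k+1)/2 - j)_+^k` rather than
#' the recursion, which is exact and vectorises.
#'
#' @param x numeric vector of evaluation points.
#' @param k non-negative integer spline order; `k = 0` is the unit box,
#'   `k = 3` the cubic spline used by the default bank.
#' @return numeric vector of `B_k(x)`, same length as `x`.
#' @examples
#' bspline(0, 0)            # 1 (inside the box)
#' bspline(0.5, 1)          # 0.5 (hat function)
#' bspline(0, 3)            # 2/3 (cubic spline peak)
#' @export
bspline <- function(x, k) {
  if (length(k) != 1L || !is.finite(k) || k < 0 || k != round(k)) {
    stop("'k' must be a single non-negative integer")
  }
  if (!is.numeric(x) || anyNA(x) || any(!is.finite(x))) {
    stop("'x' must be finite numeric")
  }
  k <- as.integer(k)
  if (k == 0L) {
    # half-open indicator [-1/2, 1/2): the endpoint convention is measure-zero
    # but half-open keeps the integer-shift partition of unity exact
    return(as.numeric(x >= -0.5 & x < 0.5))
  }
  out <- numeric(length(x))
  for (j in 0:(k + 1L)) {
    out <- out + (-1)^j * choose(k + 1L, j) * pmax(x + (k + 1L) / 2 - j, 0)^k
  }
  out <- out / factorial(k)
  # the alternating sum cancels to rounding dust outside the support;
  # the exact function is 0 there and nonnegative everywhere
  out[abs(x) >= (k + 1L) / 2] <- 0
  pmax(out, 0)
}
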