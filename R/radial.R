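#' Radial frequency profile: Gaussian over its truncated Taylor series
#'
#' The radial factor of every cake filter, `M_t(rho) = G_t(rho) / P_q(rho)`,
#' where `G_t(rho) = exp(-rho^2 / 4t) / (2 pi t)` and `P_q` is the order-`q`
#' Taylor polynomial of `G_t` about `rho = 0`. Because `G_t` is even in `rho`,
#' only even Taylor orders survive and the `1/(2 pi t)` prefactor cancels:
#'
#'   `M_t(rho) = exp(-u) / sum_{m=0}^{floor(q/2)} (-u)^m / m!`,  `u = rho^2/(4t)`
#'
#' The profile equals 1 exactly at `rho = 0`, stays near 1 on a low-frequency
#' plateau, and rolls off toward the band edge; smaller `t` makes the rolloff
#' steeper. Frequencies are normalized
#' so `rho = 1` is the inscribed Nyquist circle of the image.
#'
#' @param rho numeric vector of normalized radial frequencies, `>= 0`.
#' @param t radial scale, `> 0`; smaller decays faster (default 0.05).
#' @param q non-negative integer Taylor truncation order (default 8; even
#'   orders are natural since odd derivatives of a Gaussian vanish at 0).
#' @return numeric vector in (0, 1], same length as `rho`.
#' @examples
#' radial_profile(0)                 # exactly 1
#' radial_profile(c(0.5, 1, 1.5))    # monotone rolloff
#' @export
radial_profile <- function(rho, t = 0.05, q = 8) {
  if (length(t) != 1L || !is.finite(t) || t <= 0) stop("'t' must be > 0")
  if (length(q) != 1L || !is.finite(q) || q < 0 || q != round(q)) {
    stop("'q' must be a single non-negative integer")
  }
  if (!is.numeric(rho) || anyNA(rho)) stop("'rho' must be numeric")
  if (any(rho < 0)) stop("'rho' must be non-negative")
  u <- rho^2 / (4 * t)
  denom <- numeric(length(u))
  for (m in 0:(floor(q / 2))) {
    denom <- denom + (-u)^m / factorial(m)
  }
  if (any(denom <= 0)) {
    stop("Taylor polynomial of the Gaussian is non-positive at some 'rho'; ",
         "increase 'q' (even orders keep it positive) or reduce the band")
  }
  exp(-u) / denom
}
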