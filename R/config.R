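#' Segmentation configuration
#'
#' Collects every tunable of the pipeline, with the published operating point
#' as defaults: `N = 32` orientation channels and histogram-count parameter
#' `h = 1500` (calibrated on 700 x 605 = 423,500-pixel fundus frames; the
#' effective count is rescaled to the pixel count of the image at hand).
#' Filter-shape parameters the source method leaves unstated get documented
#' defaults: cubic B-spline angular profile (`k = 3`), radial scale `t = 0.05`
#' with Taylor order `q = 8`, spatial support `2*floor(min(shape)/8) + 1`
#' pixels with Gaussian window scale `sigma_s = support/4`.
#'
#' @param N number of orientation channels over the full circle (>= 2).
#' @param k B-spline order of the angular profile (non-negative integer).
#' @param t radial scale of [radial_profile()] (> 0).
#' @param q Taylor truncation order of [radial_profile()].
#' @param sigma_s Gaussian window scale in pixels, or `NULL` to derive
#'   `support/4` from the image shape.
#' @param support odd kernel support in pixels, or `NULL` to derive
#'   `2*floor(min(shape)/8) + 1`.
#' @param stretch_lo,stretch_hi percentiles (0-100) defining the gray-stretch
#'   anchor levels `a` and `b`; defaults 2 and 98 realize "the grayscale of
#'   most pixels".
#' @param h histogram count parameter of the adaptive threshold (> 0).
#' @param h_reference_pixels pixel count at which `h` is calibrated.
#' @param padding boundary mode for the convolutions; `"reflect"` (mirror) or
#'   `"zero"`.
#' @return an object of class `seg_config` (a validated list).
#' @seealso [segment_vessels()], [build_filter_bank()]
#' @export
seg_config <- function(N = 32L, k = 3L, t = 0.05, q = 8L,
                       sigma_s = NULL, support = NULL,
                       stretch_lo = 2, stretch_hi = 98,
                       h = 1500, h_reference_pixels = 423500,
                       padding = c("reflect", "zero")) {
  padding <- match.arg(padding)
  if (length(N) != 1L || !is.finite(N) || N < 2 || N != round(N)) {
    stop("'N' must be an integer >= 2")
  }
  if (!is.null(support)) {
    if (length(support) != 1L || support < 1 || support %% 2 != 1) {
      stop("'support' must be an odd positive integer")
    }
    support <- as.integer(support)
  }
  if (!is.null(sigma_s) && (length(sigma_s) != 1L || sigma_s <= 0)) {
    stop("'sigma_s' must be > 0")
  }
  if (!(stretch_lo >= 0 && stretch_lo < stretch_hi && stretch_hi <= 100)) {
    stop("need 0 <= stretch_lo < stretch_hi <= 100")
  }
  if (length(h) != 1L || !is.finite(h) || h <= 0) stop("'h' must be > 0")
  if (h_reference_pixels <= 0) stop("'h_reference_pixels' must be > 0")
  # k, t, q are validated by bspline()/radial_profile() at use
  structure(
    list(N = as.integer(N), k = as.integer(k), t = t, q = as.integer(q),
         sigma_s = sigma_s, support = support,
         stretch_lo = stretch_lo, stretch_hi = stretch_hi,
         h = h, h_reference_pixels = h_reference_pixels, padding = padding),
    class = "seg_config"
  )
}

#' @export
print.seg_config <- function(x, ...) {
  cat("Cake-filter segmentation config\n")
  cat(sprintf("  channels N = %d, B-spline order k = %d\n", x$N, x$k))
  cat(sprintf("  radial t = %g, Taylor order q = %d\n", x$t, x$q))
  cat(sprintf("  support = %s px, sigma_s = %s px, padding = %s\n",
              if (is.null(x$support)) "auto" else x$support,
              if (is.null(x$sigma_s)) "auto" else format(x$sigma_s),
              x$padding))
  cat(sprintf("  stretch percentiles [%g, %g], h = %g (ref %g px)\n",
              x$stretch_lo, x$stretch_hi, x$h, x$h_reference_pixels))
  invisible(x)
}

# Resolve the shape-dependent defaults for a concrete image shape.
resolve_config <- function(config, shape) {
  support <- config$support
  if (is.null(support)) support <- 2L * (min(shape) %/% 8L) + 1L
  if (support > min(shape)) {
    stop("kernel support (", support, ") exceeds image extent (",
         min(shape), ")")
  }
  sigma_s <- config$sigma_s
  if (is.null(sigma_s)) sigma_s <- support / 4
  config$support <- as.integer(support)
  config$sigma_s <- sigma_s
  config
}
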