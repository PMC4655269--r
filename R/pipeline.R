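# End-to-end vessel segmentation: green channel -> gray stretch -> orientation
# scores -> real-component minimum fusion -> invert -> adaptive histogram
# threshold -> binary vessel mask.

#' Extract the green channel of a colour fundus image
#'
#' The green channel of a fundus photograph carries the highest
#' vessel/background contrast (red is near-saturated, blue is dark and
#' noisy), so the pipeline works on it alone. A grayscale input is passed
#' through unchanged with a notice.
#'
#' @param img `rows x cols x 3` numeric array (R, G, B planes) or a numeric
#'   matrix (already grayscale).
#' @return numeric matrix (the green plane).
#' @export
extract_green <- function(img) {
  if (is.matrix(img) && is.numeric(img)) {
    message("extract_green: input is already grayscale; passing through")
    return(img)
  }
  if (!is.array(img) || length(dim(img)) != 3L) {
    stop("'img' must be a rows x cols x 3 array or a matrix")
  }
  if (dim(img)[3L] != 3L) {
    stop("'img' has ", dim(img)[3L], " channels; expected 3 (RGB)")
  }
  img[, , 2L]
}

#' Linear gray stretch
#'
#' Maps the anchor interval `[a, b]` affinely onto `[0, 255]`:
#' `g = (f - a) / (b - a) * 255`, clipping values outside `[a, b]` to the
#' endpoints. The anchors are normally the low/high percentiles of the green
#' channel, stretching "the grayscale of most pixels" to the full range.
#'
#' @param g numeric matrix.
#' @param a,b anchor gray levels, `a < b`.
#' @return numeric matrix with values in `[0, 255]` (not rounded).
#' @export
gray_stretch <- function(g, a, b) {
  if (!is.matrix(g) || !is.numeric(g)) stop("'g' must be a numeric matrix")
  if (length(a) != 1L || length(b) != 1L || !is.finite(a) || !is.finite(b) ||
      a >= b) {
    stop("need finite anchors with a < b")
  }
  out <- (g - a) / (b - a) * 255
  out[out < 0] <- 0
  out[out > 255] <- 255
  out
}

#' Fuse an orientation stack by the per-pixel minimum of real components
#'
#' At each pixel, takes the minimum over the `N` channels of the real
#' component of the orientation score. Vessels drive the aligned channel
#' strongly negative while noise does not align with any channel, so the
#' minimum enhances vessels of every orientation in a single image.
#'
#' @param stack an `orientation_stack` from [compute_stack()].
#' @return numeric matrix of per-pixel minima.
#' @export
fuse_real_min <- function(stack) {
  stopifnot(inherits(stack, "orientation_stack"))
  re <- stack$real
  if (length(dim(re)) != 3L || dim(re)[3L] < 1L) stop("empty stack")
  apply(re, c(1L, 2L), min)
}

#' Rescale a fused response to 0-255 and invert
#'
#' Min-max rescales to integer gray levels 0..255 and complements
#' (`v -> 255 - v`) so that vessels — the most negative fused responses —
#' receive the highest gray levels, ready for histogram thresholding.
#' A constant input yields an all-zero image with a notice.
#'
#' @param fused numeric matrix (fused real-component minima).
#' @return integer-valued numeric matrix in `[0, 255]`.
#' @export
rescale_and_invert <- function(fused) {
  if (!is.matrix(fused) || !is.numeric(fused)) {
    stop("'fused' must be a numeric matrix")
  }
  rng <- range(fused)
  # constant up to floating-point dust: rescaling would amplify rounding
  # noise of an analytically flat response to full range
  if (rng[2L] - rng[1L] <= 1e-8 * max(abs(rng), 1)) {
    message("rescale_and_invert: constant image; returning all zeros")
    return(matrix(0, nrow(fused), ncol(fused)))
  }
  v <- round((fused - rng[1L]) / (rng[2L] - rng[1L]) * 255)
  255 - v
}

#' Adaptive histogram threshold
#'
#' Implements `T = min{ i | H(i) < h }, i = g_min, ..., 255`, where `H(i)` is
#' the count of pixels at integer gray level `i` and `g_min` the level with
#' the largest count (the background mode; ties broken toward the smallest
#' level). Scanning upward from the mode, the threshold is the first level
#' whose population falls below `h`: the point where the heavily-populated
#' background mode gives way to the sparse vessel tail.
#'
#' @param img integer-valued numeric matrix in `[0, 255]` (vessels bright,
#'   i.e. already inverted).
#' @param h positive count parameter; counts below `h` mark the end of the
#'   background mode. For images whose pixel count differs from the
#'   calibration frame, pass the rescaled effective value (see
#'   [segment_vessels()]).
#' @return the threshold gray level `T` (integer).
#' @export
adaptive_threshold <- function(img, h) {
  if (!is.matrix(img) || !is.numeric(img)) stop("'img' must be a numeric matrix")
  if (any(img != round(img)) || any(img < 0) || any(img > 255)) {
    stop("'img' must be integer-valued in [0, 255]")
  }
  if (length(h) != 1L || !is.finite(h) || h <= 0) stop("'h' must be > 0")
  H <- tabulate(as.integer(img) + 1L, nbins = 256L)
  g_min <- which.max(H) - 1L            # ties: smallest level
  for (i in g_min:255L) {
    if (H[i + 1L] < h) return(i)
  }
  stop("adaptive_threshold: no gray level in [", g_min,
       ", 255] has fewer than h = ", h, " pixels; threshold not found")
}

#' Binarize at a threshold
#'
#' @param img numeric matrix.
#' @param T threshold gray level; pixels with `value >= T` become vessel (1).
#' @return numeric 0/1 matrix (vessel = 1).
#' @export
binarize <- function(img, T) {
  if (length(T) != 1L || !is.finite(T)) stop("'T' must be a single number")
  (img >= T) * 1
}

#' Segment retinal vessels with the cake-filter pipeline
#'
#' Runs the full chain: green-channel extraction, percentile gray stretch,
#' orientation scores under an `N`-channel cake filter bank, per-pixel
#' minimum fusion of the real components, min-max rescale + inversion, and
#' the adaptive histogram threshold. The count parameter `h` is rescaled by
#' `n_pixels / h_reference_pixels` since histogram counts scale with image
#' area. All derived quantities (stretch anchors `a`, `b`, effective `h`,
#' threshold `T`) are recorded in the returned provenance.
#'
#' @param image RGB array, grayscale matrix (0-255 scale), or a file path
#'   readable by [read_image()].
#' @param config a [seg_config()].
#' @param fov optional 0/1 matrix restricting the stretch-percentile and
#'   histogram computations to the field of view.
#' @param bank optional pre-built `cake_bank` matching the image shape and
#'   config (rebuilt otherwise).
#' @return object of class `vessel_segmentation`: list with `mask` (0/1
#'   matrix, 1 = vessel) and `provenance` (effective parameters, derived
#'   values, input checksum, timestamp).
#' @examples
#' ph <- make_tree(shape = c(128, 128), seed = 1)
#' seg <- segment_vessels(ph$rgb, seg_config(N = 8))
#' mean(seg$mask)   # vessel-pixel fraction
#' @export
segment_vessels <- function(image, config = seg_config(), fov = NULL,
                            bank = NULL) {
  stopifnot(inherits(config, "seg_config"))
  input_md5 <- NA_character_
  if (is.character(image) && length(image) == 1L) {
    input_md5 <- unname(tools::md5sum(image))
    image <- read_image(image)
  }
  g <- if (is.matrix(image)) image else extract_green(image)
  if (!is.null(fov)) {
    if (!all(dim(fov) == dim(g))) stop("segment_vessels: FOV shape mismatch")
    sel <- g[fov != 0]
  } else {
    sel <- g
  }
  cfg <- resolve_config(config, dim(g))

  ab <- stats::quantile(sel, c(cfg$stretch_lo, cfg$stretch_hi) / 100,
                        names = FALSE)
  a <- ab[1L]; b <- ab[2L]
  if (a < b) {
    stretched <- gray_stretch(g, a, b)
  } else {
    message("segment_vessels: degenerate gray range (a == b); skipping stretch")
    stretched <- g
  }

  if (is.null(bank)) bank <- build_filter_bank(dim(g), cfg)
  stack <- compute_stack(stretched, bank, cfg$padding)
  fused <- fuse_real_min(stack)
  inv <- rescale_and_invert(fused)

  h_eff <- cfg$h * length(g) / cfg$h_reference_pixels
  hist_img <- inv
  if (!is.null(fov)) {
    # histogram restricted to the FOV: pixels outside are excluded by
    # thresholding only inside
    H_vals <- inv[fov != 0]
    T <- adaptive_threshold_vec(H_vals, h_eff)
  } else {
    T <- adaptive_threshold(hist_img, h_eff)
  }
  mask <- binarize(inv, T)
  if (!is.null(fov)) mask[fov == 0] <- 0

  prov <- list(
    tool = "cakefilter",
    version = as.character(utils::packageVersion("cakefilter")),
    config = cfg[setdiff(names(cfg), NULL)],
    derived = list(a = a, b = b, h_effective = h_eff, threshold = T),
    input_md5 = input_md5,
    fov_used = !is.null(fov),
    timestamp = format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z")
  )
  structure(list(mask = mask, provenance = prov),
            class = "vessel_segmentation")
}

# adaptive threshold on a bare vector of integer gray values (FOV-restricted)
adaptive_threshold_vec <- function(vals, h) {
  adaptive_threshold(matrix(vals, nrow = 1L), h)
}

#' @export
print.vessel_segmentation <- function(x, ...) {
  d <- x$provenance$derived
  cat(sprintf(
    "Vessel segmentation: %d x %d mask, %.2f%% vessel pixels\n",
    nrow(x$mask), ncol(x$mask), 100 * mean(x$mask)))
  cat(sprintf("  stretch anchors a = %.1f, b = %.1f; effective h = %.1f; T = %d\n",
              d$a, d$b, d$h_effective, d$threshold))
  invisible(x)
}
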