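# Image I/O on the 0-255 scale. PNG/TIFF/JPEG go through the dedicated
# readers; PPM/PGM (P2/P3/P5/P6, the STARE container format) are parsed here.

#' Read an image file
#'
#' Reads PPM/PGM (ASCII `P2`/`P3` and binary `P5`/`P6` dialects), PNG, TIFF,
#' or JPEG into a numeric matrix (grayscale) or a `rows x cols x 3` array
#' (RGB; any alpha plane is dropped), scaled to 0-255.
#'
#' @param path file path; format is detected from the magic bytes with the
#'   extension as fallback.
#' @return numeric matrix or 3-channel array with attribute `range = c(0, 255)`.
#' @export
read_image <- function(path) {
  if (!file.exists(path)) stop("read_image: file not found: ", path)
  magic <- readBin(path, "raw", n = 4L)
  img <- if (length(magic) >= 2L && magic[1L] == as.raw(0x50) &&
             magic[2L] %in% as.raw(c(0x32, 0x33, 0x35, 0x36))) {
    read_ppm(path)
  } else if (length(magic) >= 4L && all(magic == as.raw(c(0x89, 0x50, 0x4e, 0x47)))) {
    png::readPNG(path) * 255
  } else if (length(magic) >= 2L && (all(magic[1:2] == as.raw(c(0x49, 0x49))) ||
                                     all(magic[1:2] == as.raw(c(0x4d, 0x4d))))) {
    tiff::readTIFF(path) * 255
  } else if (length(magic) >= 2L && all(magic[1:2] == as.raw(c(0xff, 0xd8)))) {
    jpeg::readJPEG(path) * 255
  } else {
    stop("read_image: unsupported or corrupt format in '", path,
         "' (magic bytes ", paste(magic, collapse = " "), ")")
  }
  if (length(dim(img)) == 3L) {
    if (dim(img)[3L] == 1L) {
      img <- img[, , 1L]
    } else if (dim(img)[3L] >= 3L) {
      img <- img[, , 1:3, drop = FALSE]
    }
  }
  attr(img, "range") <- c(0, 255)
  img
}

# Parse PPM/PGM. Returns matrix (PGM) or rows x cols x 3 array (PPM), 0-255.
read_ppm <- function(path) {
  raw <- readBin(path, "raw", n = file.info(path)$size)
  n <- length(raw)
  pos <- 1L
  # tokenizer skipping whitespace and '#' comments
  next_token <- function() {
    repeat {
      while (pos <= n && raw[pos] %in% as.raw(c(0x20, 0x09, 0x0a, 0x0d, 0x0b, 0x0c))) {
        pos <<- pos + 1L
      }
      if (pos <= n && raw[pos] == as.raw(0x23)) {      # comment to end of line
        while (pos <= n && raw[pos] != as.raw(0x0a)) pos <<- pos + 1L
      } else break
    }
    if (pos > n) stop("read_ppm: truncated header in '", path, "'")
    start <- pos
    while (pos <= n && !(raw[pos] %in% as.raw(c(0x20, 0x09, 0x0a, 0x0d, 0x0b, 0x0c, 0x23)))) {
      pos <<- pos + 1L
    }
    rawToChar(raw[start:(pos - 1L)])
  }
  type <- next_token()
  if (!type %in% c("P2", "P3", "P5", "P6")) {
    stop("read_ppm: unsupported PNM type '", type, "' in '", path, "'")
  }
  w <- as.integer(next_token())
  h <- as.integer(next_token())
  maxval <- as.integer(next_token())
  if (anyNA(c(w, h, maxval)) || w < 1 || h < 1 || maxval < 1 || maxval > 65535) {
    stop("read_ppm: malformed header in '", path, "'")
  }
  channels <- if (type %in% c("P3", "P6")) 3L else 1L
  n_vals <- w * h * channels
  if (type %in% c("P5", "P6")) {
    pos <- pos + 1L                       # exactly one whitespace after maxval
    bpv <- if (maxval > 255L) 2L else 1L
    if (n - pos + 1L < n_vals * bpv) {
      stop("read_ppm: truncated pixel data in '", path, "'")
    }
    vals <- readBin(raw[pos:(pos + n_vals * bpv - 1L)], "integer",
                    n = n_vals, size = bpv, signed = FALSE, endian = "big")
  } else {
    txt <- rawToChar(raw[pos:n])
    txt <- gsub("#[^\n]*", " ", txt)
    vals <- suppressWarnings(as.numeric(strsplit(trimws(txt), "\\s+")[[1L]]))
    if (length(vals) < n_vals || anyNA(vals[seq_len(n_vals)])) {
      stop("read_ppm: truncated or malformed pixel data in '", path, "'")
    }
    vals <- vals[seq_len(n_vals)]
  }
  vals <- vals / maxval * 255
  if (channels == 1L) {
    matrix(vals, nrow = h, ncol = w, byrow = TRUE)
  } else {
    # interleaved RGB, row-major
    arr <- array(0, c(h, w, 3L))
    for (ch in 1:3) {
      arr[, , ch] <- matrix(vals[seq(ch, n_vals, by = 3L)],
                            nrow = h, ncol = w, byrow = TRUE)
    }
    arr
  }
}

#' Write a binary mask as an 8-bit PNG
#'
#' Vessel pixels (nonzero) are written as 255, background as 0; the file
#' round-trips through [read_mask()].
#'
#' @param mask 0/1 numeric matrix.
#' @param path output path (PNG).
#' @return `path`, invisibly.
#' @export
write_mask <- function(mask, path) {
  if (!is.matrix(mask) || !all(mask %in% c(0, 1))) {
    stop("write_mask: 'mask' must be a 0/1 matrix")
  }
  png::writePNG(matrix(as.numeric(mask), nrow(mask)), path)
  invisible(path)
}

#' Read a binary mask from an image file
#'
#' Any supported image is binarized by a nonzero test (any channel nonzero
#' counts as vessel), which covers STARE-style ground-truth files.
#'
#' @param path image file path.
#' @return 0/1 numeric matrix.
#' @export
read_mask <- function(path) {
  img <- read_image(path)
  if (length(dim(img)) == 3L) img <- apply(img, c(1L, 2L), max)
  m <- (img != 0) * 1
  attr(m, "range") <- NULL
  m
}
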