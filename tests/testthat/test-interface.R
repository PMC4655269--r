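# hand-written PNM fixture bytes
write_p6 <- function(path) {
  con <- file(path, "wb")
  writeBin(charToRaw("P6\n2 2\n255\n"), con)
  writeBin(as.raw(c(10, 200, 30,  0, 0, 0,  255, 255, 255,  1, 2, 3)), con)
  close(con)
}

test_that("P6 and P3 fixtures decode to exact pixel values", {
  p6 <- withr::local_tempfile(fileext = ".ppm")
  write_p6(p6)
  img <- read_image(p6)
  expect_equal(dim(img), c(2, 2, 3))
  expect_equal(img[1, 1, ], c(10, 200, 30))
  expect_equal(img[2, 1, ], c(255, 255, 255))
  expect_equal(img[2, 2, ], c(1, 2, 3))

  p3 <- withr::local_tempfile(fileext = ".ppm")
  writeLines(c("P3", "# a comment", "2 2", "255",
               "10 200 30  0 0 0", "255 255 255 1 2 3"), p3)
  expect_equal(read_image(p3), img, ignore_attr = TRUE)
})

test_that("P5 and P2 grayscale dialects decode and scale by maxval", {
  p5 <- withr::local_tempfile(fileext = ".pgm")
  con <- file(p5, "wb")
  writeBin(charToRaw("P5\n3 2\n255\n"), con)
  writeBin(as.raw(c(0, 128, 255, 7, 8, 9)), con)
  close(con)
  img <- read_image(p5)
  expect_true(is.matrix(img))
  expect_equal(img[1, ], c(0, 128, 255))
  expect_equal(img[2, ], c(7, 8, 9))

  p2 <- withr::local_tempfile(fileext = ".pgm")
  writeLines(c("P2", "2 1", "100", "50 100"), p2)
  expect_equal(as.numeric(read_image(p2)), c(127.5, 255))
})

test_that("PNG round trip and grayscale flagging", {
  g <- matrix(seq(0, 1, length.out = 12), 3, 4)
  path <- withr::local_tempfile(fileext = ".png")
  png::writePNG(g, path)
  img <- read_image(path)
  expect_true(is.matrix(img))
  expect_equal(img, g * 255, tolerance = 0.5, ignore_attr = TRUE)
})

test_that("truncated and unknown files are rejected with the path named", {
  bad <- withr::local_tempfile(fileext = ".ppm")
  writeBin(charToRaw("P6\n4 4\n255\n\001\002"), bad)
  expect_error(read_image(bad), "truncated")
  junk <- withr::local_tempfile(fileext = ".img")
  writeBin(as.raw(1:10), junk)
  expect_error(read_image(junk), "unsupported")
  expect_error(read_image("no/such/file.png"), "not found")
})

test_that("masks round-trip through PNG with vessel = 255", {
  withr::with_seed(13, mask <- matrix(rbinom(64, 1, 0.4), 8, 8))
  path <- withr::local_tempfile(fileext = ".png")
  write_mask(mask, path)
  expect_identical(read_mask(path), mask * 1)
  raw_px <- png::readPNG(path)
  expect_true(all(raw_px %in% c(0, 1)))   # bytes are exactly 0 / 255
  # empty mask writes an all-zero file
  write_mask(matrix(0, 4, 4), path)
  expect_true(all(read_mask(path) == 0))
  # deterministic bytes for a fixed checkerboard
  cb <- (outer(1:4, 1:4, `+`) %% 2) * 1
  f1 <- withr::local_tempfile(fileext = ".png")
  f2 <- withr::local_tempfile(fileext = ".png")
  write_mask(cb, f1); write_mask(cb, f2)
  expect_identical(readBin(f1, "raw", 1e4), readBin(f2, "raw", 1e4))
  expect_identical(read_mask(f1), cb)
  expect_error(write_mask(matrix(0.5, 2, 2), path), "0/1")
})

test_that("the CLI dispatches, reports usage, and fails loudly", {
  expect_message(code <- run_cli(character()), "usage")
  expect_identical(code, 1L)
  expect_message(code <- run_cli("frobnicate"), "unknown subcommand")
  expect_identical(code, 1L)
  expect_message(code <- run_cli(c("segment", "--input")), "needs a value")
  expect_identical(code, 1L)
})

test_that("synth -> segment -> eval runs end to end", {
  dir <- withr::local_tempdir()
  img <- file.path(dir, "tree.png")
  truth <- file.path(dir, "truth.png")
  mask <- file.path(dir, "mask.png")
  expect_identical(suppressMessages(run_cli(c(
    "synth", "--kind", "tree", "--shape", "96x96", "--seed", "5",
    "--out-image", img, "--out-truth", truth))), 0L)
  expect_true(file.exists(img) && file.exists(truth))
  expect_true(file.exists(paste0(img, ".spec.json")))

  cfg <- file.path(dir, "run.cfg")
  writeLines(c("N = 8", "h = 1500"), cfg)
  expect_identical(suppressMessages(run_cli(c(
    "segment", "--input", img, "--output", mask, "--config", cfg))), 0L)
  expect_true(file.exists(mask))
  prov <- jsonlite::read_json(paste0(mask, ".provenance.json"))
  expect_equal(prov$config$N, 8)         # config file value applied
  expect_true(is.numeric(prov$derived$threshold))

  out <- file.path(dir, "report.json")
  log <- utils::capture.output(
    code <- suppressMessages(run_cli(c(
      "eval", "--pred", mask, "--truth", truth,
      "--out", out, "--format", "json"))))
  expect_identical(code, 0L)
  expect_match(paste(log, collapse = " "), "accuracy")
  rep <- jsonlite::read_json(out)
  expect_true(rep$TPR >= 0 && rep$TPR <= 1)

  # mismatched shapes surface as a nonzero exit naming the shapes
  small <- file.path(dir, "small.png")
  write_mask(matrix(0:1, 4, 4), small)
  msgs <- capture_messages(code <- run_cli(c(
    "eval", "--pred", small, "--truth", truth)))
  expect_identical(code, 1L)
  expect_match(paste(msgs, collapse = " "), "shape mismatch")
})

test_that("the bank subcommand renders kernel panels", {
  dir <- withr::local_tempdir()
  prefix <- file.path(dir, "bank")
  expect_identical(suppressMessages(run_cli(c(
    "bank", "--shape", "64x64", "--N", "8", "--out-prefix", prefix,
    "--save", file.path(dir, "bank.rds")))), 0L)
  pngs <- list.files(dir, pattern = "\\.png$")
  expect_gte(length(pngs), 9)            # >= 3 channels x 3 panels
  expect_s3_class(bank_load(file.path(dir, "bank.rds")), "cake_bank")
})
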