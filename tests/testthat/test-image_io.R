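test_that("TIFF round-trip is pixel-identical and readable by an independent reader", {
  set.seed(1)
  img <- matrix(sample(0:255, 48 * 64, replace = TRUE), 48, 64)
  f <- tempfile(fileext = ".tif")
  write_tiff(img, f)
  expect_identical(read_tiff(f), img)
  # independent oracle: the Python tifffile reader from the same environment
  out <- tempfile(fileext = ".csv")
  status <- system2("python", c("-c", shQuote(sprintf(
    "import tifffile, numpy; a = tifffile.imread('%s'); numpy.savetxt('%s', a, fmt='%%d', delimiter=',')",
    f, out))))
  expect_equal(status, 0L)
  oracle <- as.matrix(read.csv(out, header = FALSE))
  dimnames(oracle) <- NULL
  expect_equal(oracle, img, ignore_attr = TRUE)
})

test_that("read_tiff rejects malformed input and out-of-range writes", {
  f <- tempfile()
  writeLines("not a tiff", f)
  expect_error(read_tiff(f), "TIFF")
  expect_error(write_tiff(matrix(300, 4, 4), tempfile()), "255")
  expect_error(write_tiff(matrix(1.5, 4, 4), tempfile()), "integers")
})

clamp8_oracle <- function(x) {
  x <- round(x); x[x < 0] <- 0; x[x > 255] <- 255
  storage.mode(x) <- "integer"
  x
}

test_that("16-bit input converts to 8-bit with a warning only when allowed", {
  img16 <- matrix(as.integer(seq(0, 65535, length.out = 64)), 8, 8)
  f <- tempfile(fileext = ".tif")
  myoquant:::.write_tiff_impl(img16, f, bits = 16L)
  expect_error(read_tiff(f), "convert")
  expect_warning(img8 <- read_tiff(f, convert = TRUE), "rescaled")
  expect_true(all(img8 >= 0 & img8 <= 255))
  expect_equal(img8, clamp8_oracle(img16 / 257))
})

test_that("read_stack resolves channels from file names and validates them", {
  d <- tempfile()
  dir.create(d)
  set.seed(2)
  imgs <- lapply(1:3, function(i) matrix(sample(0:255, 32 * 32, TRUE), 32, 32))
  names(imgs) <- c("dapi", "green", "red")
  for (nm in names(imgs))
    write_tiff(imgs[[nm]], file.path(d, paste0("matrigel_1_w1_f1_", nm, ".tif")))
  st <- read_stack(list.files(d, full.names = TRUE))
  expect_s3_class(st, "channel_stack")
  expect_setequal(names(st$channels), c("dapi", "green", "red"))
  expect_identical(st$channels$green, imgs$green)
  # missing dapi is a format error
  expect_error(read_stack(file.path(d, "matrigel_1_w1_f1_green.tif")), "dapi")
  # shape mismatch is a format error
  write_tiff(matrix(0L, 16, 16), file.path(d, "other_dapi.tif"))
  expect_error(read_stack(c(file.path(d, "other_dapi.tif"),
                            file.path(d, "matrigel_1_w1_f1_green.tif"))),
               "shape mismatch")
})

test_that("write_stack / read_stack round-trips a generated field", {
  fg <- generate_field(tiny_params(seed = 3))
  d <- tempfile()
  paths <- write_stack(fg$stack, d, "matrigel_1_w1_f1")
  st <- read_stack(paths)
  expect_identical(st$channels[names(fg$stack$channels)], fg$stack$channels)
})

test_that("split_channels returns pixel-identical planes and conserves intensity", {
  fg <- generate_field(tiny_params(seed = 4))
  chans <- split_channels(fg$stack)
  expect_equal(length(chans), length(fg$stack$channels))
  for (nm in names(chans)) {
    expect_identical(chans[[nm]], fg$stack$channels[[nm]])
    expect_identical(sum(chans[[nm]]), sum(fg$stack$channels[[nm]]))
  }
})

test_that("sample_fields crops at the closed-form five-spot positions", {
  img <- matrix(sample(0:255, 900 * 900, TRUE), 900, 900)
  st <- channel_stack(list(dapi = img))
  crops <- sample_fields(st, 300)
  expect_named(crops, c("center", "north", "south", "west", "east"))
  # oracle: 0-based centers (450,450),(150,450),(750,450),(450,150),(450,750)
  # crop = center - field/2 .. + field/2 (half-open), 1-based rows start+1
  centers <- list(center = c(450, 450), north = c(150, 450),
                  south = c(750, 450), west = c(450, 150),
                  east = c(450, 750))
  for (nm in names(centers)) {
    r0 <- centers[[nm]][1] - 150
    c0 <- centers[[nm]][2] - 150
    expect_identical(crops[[nm]]$channels$dapi,
                     img[r0 + 1:300, c0 + 1:300], info = nm)
  }
})

test_that("sample_fields crops are pairwise disjoint and deterministic", {
  img <- matrix(0L, 640, 640)
  st <- channel_stack(list(dapi = img))
  # mark each crop's pixels and verify no pixel is claimed twice
  cover <- matrix(0L, 640, 640)
  f <- 200L
  cr <- 640L %/% 2L; cc <- cr
  offs <- list(c(0, 0), c(-f, 0), c(f, 0), c(0, -f), c(0, f))
  for (o in offs) {
    r0 <- cr + o[1] - f %/% 2L
    c0 <- cc + o[2] - f %/% 2L
    cover[r0 + 1:f, c0 + 1:f] <- cover[r0 + 1:f, c0 + 1:f] + 1L
  }
  expect_true(all(cover <= 1L))
  a <- sample_fields(st, f)
  b <- sample_fields(st, f)
  expect_identical(lapply(a, `[[`, "channels"), lapply(b, `[[`, "channels"))
})

test_that("sample_fields rejects fields too large for the well image", {
  st <- channel_stack(list(dapi = matrix(0L, 900, 900)))
  expect_error(sample_fields(st, 400), "too small")
})

test_that("channel_stack enforces shared shape and 8-bit range", {
  expect_error(channel_stack(list(dapi = matrix(0L, 4, 4),
                                  green = matrix(0L, 5, 4))), "identical")
  expect_error(channel_stack(list(dapi = matrix(-1L, 4, 4))), "0, 255")
  expect_error(channel_stack(list(matrix(0L, 4, 4))), "named")
})
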