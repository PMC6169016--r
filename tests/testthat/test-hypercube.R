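test_that("ENVI round trip is exact and interleave-independent", {
  cube <- toy_cube(7, 5, 6)
  tmp <- withr::local_tempdir()
  paths <- file.path(tmp, paste0("c_", c("bil", "bip", "bsq"), ".envi"))
  for (i in 1:3) write_envi_cube(cube, paths[i], c("bil", "bip", "bsq")[i])
  back <- lapply(paths, read_envi_cube)
  # float32 quantization happens once; a second trip is bit-identical
  expect_equal(back[[1]]$data, cube$data, tolerance = 1e-6)
  expect_identical(back[[1]]$data, back[[2]]$data)
  expect_identical(back[[1]]$data, back[[3]]$data)
  expect_equal(back[[1]]$wavelengths, cube$wavelengths)
  p2 <- file.path(tmp, "c2.envi")
  write_envi_cube(back[[1]], p2, "bil")
  expect_identical(read_envi_cube(p2)$data, back[[1]]$data)
})

test_that("malformed ENVI input is a hard error", {
  cube <- toy_cube()
  tmp <- withr::local_tempdir()
  p <- file.path(tmp, "c.envi")
  write_envi_cube(cube, p)
  hdr <- readLines(paste0(p, ".hdr"))
  # header/binary size mismatch: truncate the binary by one band plane
  bin <- readBin(p, "raw", file.size(p))
  writeBin(bin[seq_len(length(bin) - 4L)], p)
  expect_error(read_envi_cube(p), "does not match")
  writeBin(bin, p)
  # missing wavelength list
  writeLines(grep("wavelength", hdr, invert = TRUE, value = TRUE),
             paste0(p, ".hdr"))
  expect_error(read_envi_cube(p), "wavelength")
})

test_that("normalization anchors: white -> 1, dark -> 0, midpoint -> 0.5", {
  set.seed(1)
  nc <- 4; nb <- 5
  W <- array(rep(matrix(8000 + runif(nc * nb) * 4000, nc, nb), each = 3),
             c(3, nc, nb))
  D <- array(rep(matrix(500 + runif(nc * nb) * 100, nc, nb), each = 3),
             c(3, nc, nb))
  cal <- calibration_frames(W, D)
  wl <- seq(1000, 1400, length.out = nb)
  mk_raw <- function(cb) {
    # rows all equal to the per-column/band counts cb (cols x bands)
    hypercube(aperm(array(rep(cb, each = 6), c(6, nc, nb)), c(1, 2, 3)), wl)
  }
  expect_equal(normalize_cube(mk_raw(cal$white), cal)$data,
               array(1, c(6, nc, nb)))
  expect_equal(normalize_cube(mk_raw(cal$dark), cal)$data,
               array(0, c(6, nc, nb)))
  expect_equal(normalize_cube(mk_raw((cal$white + cal$dark) / 2), cal)$data,
               array(0.5, c(6, nc, nb)))
})

test_that("degenerate calibration cells are flagged, not fatal", {
  W <- matrix(1000, 3, 4); D <- matrix(100, 3, 4)
  W[2, 3] <- D[2, 3] # white == dark at one (col, band)
  cal <- calibration_frames(W, D)
  raw <- hypercube(array(500, c(5, 3, 4)), seq(1000, 1300, length.out = 4))
  expect_warning(out <- normalize_cube(raw, cal), "white == dark")
  expect_equal(unique(out$data[, 2, 3]), 0)
  expect_equal(unique(as.vector(out$data[, 1, ])), 400 / 900)
})

test_that("trim_bands keeps 224 of 256 equally spaced 900-1700 nm bands", {
  wl <- seq(900, 1700, length.out = 256)
  cube <- hypercube(array(0, c(2, 2, 256)), wl)
  trimmed <- trim_bands(cube, 1000, 1700)
  expect_equal(n_bands <- dim(trimmed$data)[3], 224)
  expect_true(all(trimmed$wavelengths >= 1000 & trimmed$wavelengths <= 1700))
  # identity trim and empty trim
  expect_equal(trim_bands(cube, 900, 1700)$data, cube$data)
  expect_error(trim_bands(cube, 1800, 1900), "no bands")
})

test_that("dead-pixel masking flags injected spikes and is stable", {
  set.seed(3)
  nb <- 30
  base <- sin(seq(0, 3, length.out = nb))
  arr <- array(rep(base, each = 20 * 20), c(20, 20, nb)) +
    array(rnorm(20 * 20 * nb, 0, 0.01), c(20, 20, nb))
  arr[7, 9, ] <- base + rep(c(-10, 10), length.out = nb) # alternating spikes
  cube <- hypercube(arr, seq(1000, 1700, length.out = nb))
  out <- mask_dead_pixels(cube, k_mad = 5)
  expect_false(out$valid_mask[7, 9])
  expect_equal(out$meta$n_dead_flagged, 1)
  expect_true(all(out$data[7, 9, ] == 0))
  # already-masked pixels stay masked (idempotence)
  out2 <- mask_dead_pixels(out, k_mad = 5)
  expect_false(out2$valid_mask[7, 9])
  # spatially constant cube flags nothing (MAD = 0 with all-equal scores)
  const <- hypercube(array(0.7, c(8, 8, 10)), seq(1000, 1700, length.out = 10))
  expect_equal(mask_dead_pixels(const)$meta$n_dead_flagged, 0)
})

test_that("dead-pixel masking is monotone in k_mad", {
  set.seed(11)
  arr <- array(rnorm(15 * 15 * 20, 0, 0.05), c(15, 15, 20)) +
    array(rep(seq(0.2, 0.8, length.out = 20), each = 225), c(15, 15, 20))
  cube <- hypercube(arr, seq(1000, 1700, length.out = 20))
  flagged <- vapply(c(0.5, 1, 2, 3, 5),
                    function(k) mask_dead_pixels(cube, k)$meta$n_dead_flagged,
                    numeric(1))
  expect_true(all(diff(flagged) <= 0))
})

test_that("hypercube invariants are enforced", {
  expect_error(hypercube(array(0, c(2, 2, 3)), c(1100, 1000, 1200)),
               "increasing")
  expect_error(hypercube(array(0, c(2, 2, 3)), c(1000, 1100)), "bands")
  # masked pixels are zeroed at construction
  vm <- matrix(TRUE, 2, 2); vm[1, 1] <- FALSE
  cb <- hypercube(array(1, c(2, 2, 3)), c(1000, 1100, 1200), vm)
  expect_true(all(cb$data[1, 1, ] == 0))
})

test_that("mask and wavelength-table files round-trip", {
  tmp <- withr::local_tempdir()
  m <- matrix(c(TRUE, FALSE, TRUE, TRUE), 2, 2)
  p <- file.path(tmp, "m.png")
  write_mask_png(m, p)
  expect_identical(read_mask_png(p), m)
  wl <- seq(1000, 1700, length.out = 16)
  pw <- file.path(tmp, "wl.csv")
  write_wavelength_table(wl, pw)
  expect_equal(read_wavelength_table(pw), wl)
})
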