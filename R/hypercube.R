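#' Hyperspectral reflectance cube
#'
#' The central container of the pipeline: a `rows x cols x bands` numeric
#' array of reflectance (or raw detector counts, before [normalize_cube()])
#' together with its wavelength axis and a per-pixel validity mask.
#' Coordinates follow the push-broom convention: row = along-scan (y),
#' col = across-track (x); band indices follow the wavelength axis.
#' Invalid ("black-masked") pixels are stored as exactly 0 at all bands.
#'
#' @param data numeric 3-D array indexed `[row, col, band]`.
#' @param wavelengths numeric vector of band-centre wavelengths in nm,
#'   strictly increasing, `length(wavelengths) == dim(data)[3]`.
#' @param valid_mask logical `rows x cols` matrix; `FALSE` marks black-masked
#'   pixels. Defaults to all valid.
#' @param meta named list of free-form metadata (stride index, mm_per_px,
#'   integration time, source path, ...).
#' @return An object of class `hypercube`.
#' @export
hypercube <- function(data, wavelengths, valid_mask = NULL, meta = list()) {
  if (length(dim(data)) != 3L)
    stop("`data` must be a 3-D array [row, col, band]")
  storage.mode(data) <- "double"
  wavelengths <- as.numeric(wavelengths)
  if (length(wavelengths) != dim(data)[3])
    stop("length(wavelengths) must equal the number of bands")
  if (length(wavelengths) > 1 && any(diff(wavelengths) <= 0))
    stop("`wavelengths` must be strictly increasing")
  if (is.null(valid_mask))
    valid_mask <- matrix(TRUE, dim(data)[1], dim(data)[2])
  valid_mask <- as.matrix(valid_mask)
  storage.mode(valid_mask) <- "logical"
  if (!all(dim(valid_mask) == dim(data)[1:2]))
    stop("`valid_mask` must be rows x cols")
  if (any(!valid_mask)) {
    # enforce the black-mask invariant
    data[rep_len(!valid_mask, length(data))] <- 0
  }
  structure(list(data = data, wavelengths = wavelengths,
                 valid_mask = valid_mask, meta = meta),
            class = "hypercube")
}

#' @export
print.hypercube <- function(x, ...) {
  d <- dim(x$data)
  cat(sprintf("<hypercube> %d x %d px, %d bands (%.1f-%.1f nm), %d masked px\n",
              d[1], d[2], d[3], min(x$wavelengths), max(x$wavelengths),
              sum(!x$valid_mask)))
  invisible(x)
}

#' @export
dim.hypercube <- function(x) dim(x$data)

n_bands <- function(cube) dim(cube$data)[3]

#' Extract valid-pixel spectra as a matrix
#'
#' @param cube a [hypercube].
#' @return list with `spectra` (n_valid x bands matrix) and `idx`
#'   (linear indices of the valid pixels in the rows x cols plane).
#' @keywords internal
cube_spectra <- function(cube) {
  d <- dim(cube$data)
  idx <- which(cube$valid_mask)
  flat <- matrix(cube$data, d[1] * d[2], d[3])
  list(spectra = flat[idx, , drop = FALSE], idx = idx)
}

# write spectra (n_valid x bands) back into a copy of the cube
cube_with_spectra <- function(cube, spectra, idx) {
  d <- dim(cube$data)
  flat <- matrix(0, d[1] * d[2], d[3])
  flat[idx, ] <- spectra
  hypercube(array(flat, d), cube$wavelengths, cube$valid_mask, cube$meta)
}

#' Calibration frames (white and dark standards)
#'
#' Short scans of the Spectralon white tile and of the shuttered sensor,
#' used to convert raw counts to reflectance. Frames are averaged over
#' their scan lines (rows) before use, the push-broom convention for
#' standards imaged before each scan.
#'
#' @param white numeric array `[row, col, band]` (or `col x band` matrix)
#'   of white-standard counts.
#' @param dark same geometry, dark-current counts.
#' @return An object of class `calibration_frames` with per-column,
#'   per-band mean `white` and `dark` matrices (`cols x bands`).
#' @export
calibration_frames <- function(white, dark) {
  avg <- function(x) {
    if (length(dim(x)) == 3L) apply(x, c(2, 3), mean)
    else as.matrix(x)
  }
  w <- avg(white); d <- avg(dark)
  if (!all(dim(w) == dim(d)))
    stop("white and dark frames are not conformable")
  structure(list(white = w, dark = d), class = "calibration_frames")
}

#' Normalize raw counts to reflectance
#'
#' Per pixel i and band \eqn{\lambda}:
#' \eqn{N_{i\lambda} = (R_{i\lambda} - D_{i\lambda}) / (W_{i\lambda} - D_{i\lambda})},
#' where W and D are the column-averaged white and dark standards. Values
#' are not clipped to \[0, 1\] (specular pixels may exceed 1).
#'
#' @param raw a [hypercube] of raw counts.
#' @param cal a [calibration_frames] object conformable with `raw`
#'   (same cols and bands).
#' @return A [hypercube] of reflectance. Any (col, band) cell where
#'   `white == dark` is set to 0 and recorded in
#'   `meta$degenerate_calibration`, with a warning.
#' @export
normalize_cube <- function(raw, cal) {
  stopifnot(inherits(raw, "hypercube"), inherits(cal, "calibration_frames"))
  d <- dim(raw$data)
  if (nrow(cal$white) != d[2] || ncol(cal$white) != d[3])
    stop("calibration frames not conformable with raw cube (cols x bands)")
  den <- cal$white - cal$dark
  bad <- den == 0
  if (any(bad)) {
    warning(sprintf("%d (col, band) cells have white == dark; set to 0", sum(bad)))
    den[bad] <- 1
  }
  # broadcast cols x bands over rows
  N <- array(0, d)
  for (b in seq_len(d[3])) {
    N[, , b] <- sweep(sweep(raw$data[, , b, drop = FALSE][, , 1],
                            2, cal$dark[, b], "-"),
                      2, den[, b], "/")
    if (any(bad[, b])) N[, bad[, b], b] <- 0
  }
  meta <- raw$meta
  meta$normalized <- TRUE
  if (any(bad)) meta$degenerate_calibration <- which(bad, arr.ind = TRUE)
  hypercube(N, raw$wavelengths, raw$valid_mask, meta)
}

#' Trim the wavelength axis
#'
#' Retains bands with centre wavelength in `[lo, hi]` (inclusive). Used to
#' drop the noisy low-sensitivity detector edge, keeping 1000-1700 nm.
#'
#' @param cube a [hypercube].
#' @param lo,hi wavelength bounds in nm, `lo < hi`.
#' @return The trimmed [hypercube]; error if no band survives.
#' @export
trim_bands <- function(cube, lo = 1000, hi = 1700) {
  stopifnot(inherits(cube, "hypercube"), lo < hi)
  keep <- cube$wavelengths >= lo & cube$wavelengths <= hi
  if (!any(keep)) stop(sprintf("no bands in [%g, %g] nm", lo, hi))
  hypercube(cube$data[, , keep, drop = FALSE], cube$wavelengths[keep],
            cube$valid_mask, cube$meta)
}

#' Mask dead pixels and spikes
#'
#' Scores each pixel by the standard deviation over bands of its difference
#' spectrum \eqn{N_{i,\lambda} - N_{i,\lambda+1}}. Pixels whose score
#' exceeds `median(s) + k_mad * MAD(s)` (computed over currently valid
#' pixels; MAD with the usual 1.4826 consistency constant) are black-masked.
#' An absolute threshold can replace the robust rule.
#'
#' @param cube a [hypercube] with at least 3 bands.
#' @param k_mad robust-threshold multiplier (default 5).
#' @param abs_threshold optional absolute score threshold overriding the
#'   robust rule.
#' @return A [hypercube] with newly flagged pixels masked;
#'   `meta$n_dead_flagged` holds the count of newly flagged pixels.
#' @export
mask_dead_pixels <- function(cube, k_mad = 5, abs_threshold = NULL) {
  stopifnot(inherits(cube, "hypercube"))
  d <- dim(cube$data)
  if (d[3] < 3) stop("need at least 3 bands")
  dd <- cube$data[, , -1, drop = FALSE] - cube$data[, , -d[3], drop = FALSE]
  nb <- d[3] - 1
  mu <- rowMeans(matrix(dd, d[1] * d[2], nb))
  s2 <- rowMeans(matrix(dd, d[1] * d[2], nb)^2) - mu^2
  s <- matrix(sqrt(pmax(s2, 0)), d[1], d[2])
  valid <- cube$valid_mask
  sv <- s[valid]
  thr <- if (!is.null(abs_threshold)) abs_threshold
         else stats::median(sv) + k_mad * stats::mad(sv)
  flag <- valid & s > thr
  n_flag <- sum(flag)
  new_valid <- valid & !flag
  meta <- cube$meta
  meta$n_dead_flagged <- n_flag
  hypercube(cube$data, cube$wavelengths, new_valid, meta)
}
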