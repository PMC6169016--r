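#' Read an ENVI-format hyperspectral cube
#'
#' ENVI stores a cube as a raw binary file plus a text header
#' (`<path>.hdr`). Supported interleaves: BIL, BIP, BSQ; supported data
#' types: 2 (int16), 4 (float32), 12 (uint16). Data are promoted to
#' double on read. The header must carry a `wavelength` list; its absence
#' is a hard error, as is any size mismatch between header and binary.
#'
#' @param path path to the binary cube file (header at `<path>.hdr`).
#' @return A [hypercube].
#' @seealso [write_envi_cube()]
#' @export
read_envi_cube <- function(path) {
  hdr_path <- paste0(path, ".hdr")
  if (!file.exists(hdr_path))
    hdr_path <- sub("\\.[^.]+$", ".hdr", path)
  if (!file.exists(path)) stop("cube file not found: ", path)
  if (!file.exists(hdr_path)) stop("ENVI header not found for: ", path)
  hdr <- parse_envi_header(hdr_path)
  for (k in c("samples", "lines", "bands", "interleave", "data type"))
    if (is.null(hdr[[k]])) stop("ENVI header missing key: ", k)
  if (is.null(hdr$wavelength))
    stop("ENVI header has no wavelength list")
  ns <- as.integer(hdr$samples); nl <- as.integer(hdr$lines)
  nb <- as.integer(hdr$bands)
  wl <- as.numeric(hdr$wavelength)
  if (length(wl) != nb) stop("wavelength list length != bands")
  dtype <- as.integer(hdr[["data type"]])
  itemsize <- switch(as.character(dtype), "2" = 2L, "12" = 2L, "4" = 4L,
                     stop("unsupported ENVI data type: ", dtype))
  n_elem <- as.numeric(ns) * nl * nb
  expected <- n_elem * itemsize
  actual <- file.size(path)
  if (actual != expected)
    stop(sprintf("binary size %d does not match header (%d expected)",
                 actual, expected))
  endian <- if (identical(hdr[["byte order"]], "1")) "big" else "little"
  con <- file(path, "rb")
  on.exit(close(con))
  v <- switch(as.character(dtype),
    "2" = as.double(readBin(con, integer(), n_elem, size = 2,
                            signed = TRUE, endian = endian)),
    "12" = as.double(readBin(con, integer(), n_elem, size = 2,
                             signed = FALSE, endian = endian)),
    "4" = readBin(con, double(), n_elem, size = 4, endian = endian))
  interleave <- tolower(hdr$interleave)
  # R arrays are column-major; first dim varies fastest
  arr <- switch(interleave,
    bsq = aperm(array(v, c(ns, nl, nb)), c(2, 1, 3)),
    bil = aperm(array(v, c(ns, nb, nl)), c(3, 1, 2)),
    bip = aperm(array(v, c(nb, ns, nl)), c(3, 2, 1)),
    stop("unsupported interleave: ", hdr$interleave))
  meta <- list(source_path = path, interleave = interleave)
  for (k in setdiff(names(hdr), c("samples", "lines", "bands", "interleave",
                                  "data type", "byte order", "wavelength",
                                  "header offset", "file type")))
    meta[[k]] <- hdr[[k]]
  hypercube(arr, wl, meta = meta)
}

#' Write a hypercube in ENVI format
#'
#' Writes `<path>` (raw binary, float32 little-endian) and `<path>.hdr`.
#' The validity mask is not stored in the file pair; black-masked pixels
#' are zero at all bands by the container invariant, so a round trip
#' preserves the data exactly in float32 precision.
#'
#' @param cube a [hypercube].
#' @param path output binary path.
#' @param interleave one of `"bil"`, `"bip"`, `"bsq"`.
#' @return `path`, invisibly.
#' @export
write_envi_cube <- function(cube, path, interleave = c("bil", "bip", "bsq")) {
  stopifnot(inherits(cube, "hypercube"))
  interleave <- match.arg(interleave)
  d <- dim(cube$data)
  arr <- switch(interleave,
    bsq = aperm(cube$data, c(2, 1, 3)),
    bil = aperm(cube$data, c(2, 3, 1)),
    bip = aperm(cube$data, c(3, 2, 1)))
  con <- file(path, "wb")
  writeBin(as.vector(arr), con, size = 4, endian = "little")
  close(con)
  hdr <- c(
    "ENVI",
    "description = {rhizospec hyperspectral cube}",
    sprintf("samples = %d", d[2]),
    sprintf("lines = %d", d[1]),
    sprintf("bands = %d", d[3]),
    "header offset = 0",
    "file type = ENVI Standard",
    "data type = 4",
    sprintf("interleave = %s", interleave),
    "byte order = 0",
    sprintf("wavelength = {%s}",
            paste(format(cube$wavelengths, trim = TRUE, digits = 10),
                  collapse = ", ")))
  writeLines(hdr, paste0(path, ".hdr"))
  invisible(path)
}

# Parse an ENVI text header into a named list of strings / vectors.
# Braced values may span lines; list values are split on commas.
parse_envi_header <- function(path) {
  lines <- readLines(path, warn = FALSE)
  out <- list()
  for (ln in strsplit(collapse_braces(lines), "\n")[[1]]) {
    if (!grepl("=", ln, fixed = TRUE)) next
    key <- tolower(trimws(sub("=.*", "", ln)))
    val <- trimws(sub("^[^=]*=", "", ln))
    if (grepl("^\\{", val)) {
      val <- gsub("[{}]", "", val)
      val <- trimws(strsplit(val, ",")[[1]])
    }
    out[[key]] <- val
  }
  out
}

# merge lines so that {...} groups become a single line
collapse_braces <- function(lines) {
  out <- character(0)
  buf <- NULL
  for (ln in lines) {
    if (is.null(buf)) {
      if (grepl("\\{", ln) && !grepl("\\}", ln)) buf <- ln
      else out <- c(out, ln)
    } else {
      buf <- paste(buf, ln)
      if (grepl("\\}", ln)) { out <- c(out, buf); buf <- NULL }
    }
  }
  if (!is.null(buf)) out <- c(out, buf)
  paste(out, collapse = "\n")
}

#' Read / write a binary mask as PNG
#'
#' Masks are single-channel PNG with foreground = 255, background = 0.
#'
#' @param path PNG path.
#' @return `read_mask_png`: a logical matrix. `write_mask_png`: `path`,
#'   invisibly.
#' @export
read_mask_png <- function(path) {
  img <- png::readPNG(path)
  if (length(dim(img)) == 3L) img <- img[, , 1]
  img > 0.5
}

#' @param mask logical matrix.
#' @rdname read_mask_png
#' @export
write_mask_png <- function(mask, path) {
  png::writePNG(matrix(as.numeric(mask), nrow(mask), ncol(mask)), path)
  invisible(path)
}

#' Read / write a band-wavelength table
#'
#' CSV with columns `band_index` (0-based, by external convention) and
#' `wavelength_nm`.
#'
#' @param path CSV path.
#' @return `read_wavelength_table`: numeric vector of wavelengths (nm).
#' @export
read_wavelength_table <- function(path) {
  df <- utils::read.csv(path)
  stopifnot(all(c("band_index", "wavelength_nm") %in% names(df)))
  df$wavelength_nm[order(df$band_index)]
}

#' @param wavelengths numeric vector (nm).
#' @rdname read_wavelength_table
#' @export
write_wavelength_table <- function(wavelengths, path) {
  utils::write.csv(data.frame(band_index = seq_along(wavelengths) - 1L,
                              wavelength_nm = wavelengths),
                   path, row.names = FALSE)
  invisible(path)
}
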