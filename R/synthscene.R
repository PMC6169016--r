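#' Synthetic scene parameters
#'
#' The `"paper"` preset mirrors the study geometry: 320-px-wide strides
#' with 10% overlap, 0.1 mm/px, 256 bands spanning 900-1700 nm, 14-bit
#' counts at ~85% dynamic range. The `"ci"` preset scales the scene to
#' 600 x 160 px with 64 bands for fast tests; spectral physics and noise
#' are unchanged.
#'
#' @param preset `"ci"` or `"paper"`.
#' @param ... overrides for individual fields.
#' @return named list of generator parameters.
#' @export
scene_params <- function(preset = c("ci", "paper"), ...) {
  preset <- match.arg(preset)
  base <- list(
    rows = 600, cols = 160, n_bands = 64,
    wl_lo = 900, wl_hi = 1700,
    stride_width = 84, overlap = 0.1,
    mm_per_px = 0.1,
    n_primary = 2, lateral_rate = 0.015, curvature = 0.15,
    primary_width_px = 5, lateral_width_px = 3,
    root_fraction_range = c(0.02, 0.12),
    # spectral model
    soil_base = 0.40, soil_slope = 0.10, root_base = 0.52,
    water_depth = 0.28, water2_depth = 0.12, struct_depth = 0.10,
    stele_water_boost = 1.5,
    soil_texture_sd = 0.05, soil_texture_scale_px = 8,
    noise_sd = 0.01,
    dead_pixel_rate = 5e-4,
    # counts model (14-bit)
    full_scale = 16383, dynamic_fraction = 0.85, dark_level = 600,
    integration_us = 4500)
  if (preset == "paper") {
    base$rows <- 3000; base$cols <- 2912; base$n_bands <- 256
    base$stride_width <- 320
    base$n_primary <- 6; base$primary_width_px <- 9
  }
  utils::modifyList(base, list(...))
}

# Gaussian absorption dip
gauss_dip <- function(wl, center, width) exp(-0.5 * ((wl - center) / width)^2)

# smooth spatially correlated field via separable moving-average blur
correlated_field <- function(nr, nc, scale_px) {
  z <- matrix(stats::rnorm(nr * nc), nr, nc)
  k <- max(3L, 2L * as.integer(scale_px) + 1L)
  w <- stats::dnorm(seq(-3, 3, length.out = k))
  w <- w / sum(w)
  z <- apply(z, 2, function(v) stats::filter(v, w, circular = TRUE))
  z <- t(apply(z, 1, function(v) stats::filter(v, w, circular = TRUE)))
  z / stats::sd(z)
}

# stamp a disk of radius rad around (r, c) into mask
stamp_disk <- function(mask, r, c, rad) {
  rr <- max(1, r - rad):min(nrow(mask), r + rad)
  cc <- max(1, c - rad):min(ncol(mask), c + rad)
  sub <- outer(rr - r, cc - c, function(a, b) a^2 + b^2) <= rad^2
  mask[rr, cc] <- mask[rr, cc] | sub
  mask
}

# Grow one root axis as a smooth persistent walk: the heading follows an
# AR(1) curvature process, so axes bend over mm scales but are straight
# at the pixel (0.1 mm) scale, as real root axes are. Returns the
# rounded path (r, c).
grow_axis <- function(start_r, start_c, angle0, nr, nc, curvature,
                      max_len = nr * 2) {
  r <- start_r; c <- start_c; ang <- angle0
  curv <- 0
  path <- matrix(NA_real_, max_len, 2)
  n <- 0
  while (r >= 1 && r <= nr && c >= 1 && c <= nc && n < max_len) {
    n <- n + 1
    path[n, ] <- c(r, c)
    curv <- 0.9 * curv + stats::rnorm(1, 0, curvature / 25)
    ang <- ang + curv - 0.02 * ang # weak gravitropic pull toward vertical
    ang <- max(min(ang, pi / 2.2), -pi / 2.2) # keep heading downward
    r <- r + cos(ang)
    c <- c + sin(ang)
  }
  round(path[seq_len(n), , drop = FALSE])
}

path_length_cm <- function(path, mm_per_px) {
  if (nrow(path) < 2) return(0)
  d <- sqrt(rowSums(diff(path)^2))
  sum(d) * mm_per_px / 10
}

#' Generate a synthetic rhizobox scene with ground truth
#'
#' Builds a root network (primary axes plus stochastic laterals) over a
#' scattering soil background, renders per-pixel NIR reflectance with
#' water absorption features (~1450 and ~1050 nm) and a
#' structural-carbohydrate feature (~1630-1690 nm), distinguishes stele
#' from cortex by water-band depth, then converts to 14-bit raw counts
#' through synthetic white/dark standards, adds noise, and injects dead
#' pixels, so the full normalization-to-analysis chain is exercised.
#'
#' @param params a [scene_params()] list.
#' @param seed RNG seed; the same seed reproduces the scene exactly.
#' @param decay_day optional day after clipping; scales the water-band
#'   depth by `exp(-decay_rate * day)` and the structural band by
#'   `exp(-decay_rate/4 * day)`.
#' @param decay_rate water-band decay rate per day.
#' @return object of class `scene_truth`: `raw` (counts [hypercube]),
#'   `cal` ([calibration_frames()]), `reflectance` (noiseless designed
#'   reflectance array), `mask` (truth root mask), `skeleton_length_cm`,
#'   `tissue` (matrix: 0 soil, 1 cortex, 2 stele), `dead_pixels`
#'   (index matrix), `stride_offsets`, `params`, `decay`.
#' @export
generate_scene <- function(params = scene_params(), seed = 1,
                           decay_day = 0, decay_rate = 0.012) {
  set.seed(seed)
  nr <- params$rows; nc <- params$cols; nb <- params$n_bands
  wl <- seq(params$wl_lo, params$wl_hi, length.out = nb)

  ## ---- geometry: root network ----
  mask <- matrix(FALSE, nr, nc)
  skel_len <- 0
  paths <- list()
  for (i in seq_len(params$n_primary)) {
    c0 <- round(nc * (i - 0.5) / params$n_primary +
                  stats::rnorm(1, 0, nc * 0.03))
    c0 <- min(max(c0, 2), nc - 1)
    p <- grow_axis(1, c0, stats::rnorm(1, 0, 0.1), nr, nc, params$curvature)
    paths[[length(paths) + 1]] <- list(path = p,
                                       width = params$primary_width_px)
    # laterals branch off the primary
    n_lat <- stats::rpois(1, params$lateral_rate * nrow(p))
    if (n_lat > 0) {
      at <- sample(nrow(p), n_lat)
      for (j in at) {
        side <- sample(c(-1, 1), 1)
        q <- grow_axis(p[j, 1], p[j, 2], side * stats::runif(1, 0.6, 1.2),
                       nr, nc, params$curvature * 2,
                       max_len = round(stats::runif(1, 30, 100)))
        paths[[length(paths) + 1]] <- list(path = q,
                                           width = params$lateral_width_px)
      }
    }
  }
  # Truth length counts the marginal centerline each axis adds: path
  # steps already covered by previously stamped axes (a lateral's origin
  # inside its parent, or a crossing) are part of the shared skeleton
  # and must not be double-counted.
  for (ax in paths) {
    rad <- max(0L, as.integer((ax$width - 1) / 2))
    p <- ax$path
    covered <- mask[cbind(p[, 1], p[, 2])]
    if (nrow(p) >= 2) {
      d <- sqrt(rowSums(diff(p)^2))
      new_step <- !(covered[-1] & covered[-length(covered)])
      skel_len <- skel_len + sum(d[new_step]) * params$mm_per_px / 10
    }
    for (s in seq_len(nrow(p)))
      mask <- stamp_disk(mask, p[s, 1], p[s, 2], rad)
  }
  frac <- mean(mask)
  if (frac < params$root_fraction_range[1] ||
      frac > params$root_fraction_range[2])
    stop(sprintf("infeasible root density: fraction %.3f outside [%g, %g]",
                 frac, params$root_fraction_range[1],
                 params$root_fraction_range[2]))

  ## ---- tissue: stele = inner core along each axis ----
  tissue <- matrix(0L, nr, nc)
  tissue[mask] <- 1L
  for (ax in paths) {
    rad <- max(0L, as.integer((ax$width - 1) / 4))
    p <- ax$path
    core <- matrix(FALSE, nr, nc)
    for (s in seq_len(nrow(p)))
      core <- stamp_disk(core, p[s, 1], p[s, 2], rad)
    tissue[core & mask] <- 2L
  }

  ## ---- spectra ----
  w_scale <- exp(-decay_rate * decay_day)
  s_scale <- exp(-decay_rate / 4 * decay_day)
  dip_w1 <- gauss_dip(wl, 1450, 30)
  dip_w2 <- gauss_dip(wl, 1050, 20)
  dip_st <- gauss_dip(wl, 1660, 25)
  base_t <- (wl - params$wl_lo) / (params$wl_hi - params$wl_lo)
  soil_spec <- params$soil_base + params$soil_slope * base_t
  root_cortex <- params$root_base + 0.05 * base_t -
    w_scale * (params$water_depth * dip_w1 + params$water2_depth * dip_w2) -
    s_scale * params$struct_depth * dip_st
  root_stele <- params$root_base + 0.05 * base_t -
    w_scale * params$stele_water_boost *
      (params$water_depth * dip_w1 + params$water2_depth * dip_w2) -
    s_scale * params$struct_depth * dip_st

  texture <- correlated_field(nr, nc, params$soil_texture_scale_px)
  mult <- 1 + params$soil_texture_sd * texture # multiplicative scatter
  refl <- array(0, c(nr, nc, nb))
  soil_px <- tissue == 0L
  cortex_px <- tissue == 1L
  stele_px <- tissue == 2L
  # scatter is a surface-geometry effect and multiplies root and soil
  # alike; it is what the multiplicative pre-treatments exist to remove
  for (b in seq_len(nb)) {
    plane <- matrix(0, nr, nc)
    plane[soil_px] <- soil_spec[b]
    plane[cortex_px] <- root_cortex[b]
    plane[stele_px] <- root_stele[b]
    refl[, , b] <- plane * mult
  }

  ## ---- counts through white/dark standards ----
  top <- params$dark_level
  span <- params$full_scale * params$dynamic_fraction - top
  # smooth illumination profile across track, band-dependent lamp spectrum
  illum_col <- 1 - 0.15 * ((seq_len(nc) - (nc + 1) / 2) / nc)^2 * 4
  lamp <- 0.75 + 0.25 * sin(pi * base_t)
  white_cb <- outer(illum_col, lamp) * span + top # cols x bands
  dark_cb <- matrix(top, nc, nb) + outer(rep(1, nc), 40 * base_t)
  n_cal_rows <- 8
  white_frame <- array(rep(white_cb, each = n_cal_rows),
                       c(n_cal_rows, nc, nb)) +
    array(stats::rnorm(n_cal_rows * nc * nb, 0, 2), c(n_cal_rows, nc, nb))
  dark_frame <- array(rep(dark_cb, each = n_cal_rows),
                      c(n_cal_rows, nc, nb)) +
    array(stats::rnorm(n_cal_rows * nc * nb, 0, 1), c(n_cal_rows, nc, nb))
  cal <- calibration_frames(white_frame, dark_frame)

  raw <- array(0, c(nr, nc, nb))
  noise_counts <- params$noise_sd * mean(white_cb - dark_cb)
  for (b in seq_len(nb)) {
    den <- white_cb[, b] - dark_cb[, b]
    raw[, , b] <- sweep(sweep(refl[, , b], 2, den, "*"), 2, dark_cb[, b], "+") +
      matrix(stats::rnorm(nr * nc, 0, noise_counts), nr, nc)
  }
  raw <- round(pmin(pmax(raw, 0), params$full_scale))

  ## ---- dead pixels / spikes ----
  n_dead <- stats::rbinom(1, nr * nc, params$dead_pixel_rate)
  dead_idx <- NULL
  if (n_dead > 0) {
    lin <- sample(nr * nc, n_dead)
    dead_idx <- cbind((lin - 1L) %% nr + 1L, (lin - 1L) %/% nr + 1L)
    spike <- rep(c(0, params$full_scale), length.out = nb)
    for (i in seq_len(n_dead))
      raw[dead_idx[i, 1], dead_idx[i, 2], ] <- spike
  }

  ## ---- stride layout ----
  sw <- params$stride_width
  ov <- round(params$overlap * sw)
  step <- sw - ov
  starts <- seq(1, max(nc - sw + 1, 1), by = step)
  if (starts[length(starts)] + sw - 1 < nc)
    starts <- c(starts, nc - sw + 1)

  raw_cube <- hypercube(raw, wl,
                        meta = list(mm_per_px = params$mm_per_px,
                                    integration_us = params$integration_us,
                                    seed = seed))
  structure(list(raw = raw_cube, cal = cal, reflectance = refl,
                 mask = mask, skeleton_length_cm = skel_len,
                 tissue = tissue, dead_pixels = dead_idx,
                 stride_offsets = starts, stride_width = sw,
                 params = params,
                 decay = list(day = decay_day, rate = decay_rate,
                              water_scale = w_scale,
                              struct_scale = s_scale)),
            class = "scene_truth")
}

#' @export
print.scene_truth <- function(x, ...) {
  cat(sprintf("<scene_truth> %d x %d x %d, root %.1f%%, skeleton %.1f cm, %d strides\n",
              dim(x$raw$data)[1], dim(x$raw$data)[2], dim(x$raw$data)[3],
              100 * mean(x$mask), x$skeleton_length_cm,
              length(x$stride_offsets)))
  invisible(x)
}

#' Cut a scene into overlapping stride cubes
#'
#' @param scene a `scene_truth`.
#' @return list of raw-count [hypercube]s, one per stride, with stride
#'   index and offset in `meta`.
#' @export
cut_strides <- function(scene) {
  lapply(seq_along(scene$stride_offsets), function(i) {
    s <- scene$stride_offsets[i]
    cols <- s:(s + scene$stride_width - 1)
    hypercube(scene$raw$data[, cols, , drop = FALSE],
              scene$raw$wavelengths,
              scene$raw$valid_mask[, cols, drop = FALSE],
              utils::modifyList(scene$raw$meta,
                                list(stride = i, col_offset = s)))
  })
}

#' Calibration frames subset for a stride
#'
#' @param scene a `scene_truth`.
#' @param stride stride index.
#' @return [calibration_frames()] covering the stride's columns.
#' @export
stride_calibration <- function(scene, stride) {
  s <- scene$stride_offsets[stride]
  cols <- s:(s + scene$stride_width - 1)
  structure(list(white = scene$cal$white[cols, , drop = FALSE],
                 dark = scene$cal$dark[cols, , drop = FALSE]),
            class = "calibration_frames")
}

#' Truth-derived ROI set
#'
#' Samples a labelled fraction of pixels (default 0.6%, the study's
#' labelling effort) split between root (from the eroded truth mask) and
#' soil (away from the mask).
#'
#' @param scene a `scene_truth` (or list with `mask`).
#' @param fraction total labelled fraction of image pixels.
#' @param seed RNG seed.
#' @return a [roi_set()].
#' @export
truth_rois <- function(scene, fraction = 0.006, seed = 1) {
  mask <- scene$mask
  set.seed(seed)
  n_total <- round(fraction * length(mask))
  n_root <- max(20L, round(n_total / 2))
  n_soil <- max(20L, n_total - n_root)
  root_all <- which(mask)
  soil_all <- which(!mask)
  ri <- sample(root_all, min(n_root, length(root_all)))
  si <- sample(soil_all, min(n_soil, length(soil_all)))
  nr <- nrow(mask)
  to_rc <- function(i) cbind((i - 1L) %% nr + 1L, (i - 1L) %/% nr + 1L)
  roi_set(to_rc(ri), to_rc(si), source = "synthetic truth")
}

#' Generate a root-decay time series of scenes
#'
#' The same root geometry (same seed) imaged at successive days after
#' clipping: the water-band depth decays as `exp(-k t)` while the
#' structural-carbohydrate band decays four times slower, so a
#' first-derivative difference between a structural band (~1650 nm) and
#' a water band (~1450 nm region) carries the decay signal.
#'
#' @param times positive ascending days.
#' @param k water-band decay rate per day.
#' @param params a [scene_params()] list.
#' @param seed RNG seed (geometry is shared across days).
#' @return named list (names = days) of `scene_truth` objects; attribute
#'   `k` stores the truth rate.
#' @export
generate_decay_series <- function(times = c(14, 28, 47, 94, 101, 201),
                                  k = 0.012, params = scene_params(),
                                  seed = 1) {
  stopifnot(all(times > 0), !is.unsorted(times, strictly = TRUE))
  out <- lapply(times, function(t_)
    generate_scene(params, seed = seed, decay_day = t_, decay_rate = k))
  names(out) <- as.character(times)
  attr(out, "k") <- k
  # The feature whose mean over root pixels decays as exp(-k t) with no
  # constant offset: first-derivative difference between the water-band
  # inflection (~1480 nm) and a reference band in the featureless window
  # (~1250 nm). The linear part of the base reflectance contributes the
  # same constant to both derivatives and cancels in the difference.
  wl <- out[[1]]$raw$wavelengths
  b1 <- which.min(abs(wl - 1480))
  b2 <- which.min(abs(wl - 1250))
  attr(out, "designed_feature") <- structure(
    list(transform = "sg_deriv1", type = "difference",
         wavelength_nm = c(wl[b1], wl[b2]), bands = c(b1, b2),
         distance = NA_real_),
    class = "decay_feature")
  out
}

#' Root-pixel reflectance spectra of a scene
#'
#' Normalizes the scene's raw counts with its calibration frames and
#' extracts the truth-mask root spectra (used for decay analysis).
#'
#' @param scene a `scene_truth`.
#' @param n_max optional subsample size for speed.
#' @param seed subsample seed.
#' @return pixels x bands matrix.
#' @export
scene_root_spectra <- function(scene, n_max = NULL, seed = 1) {
  cube <- normalize_cube(scene$raw, scene$cal)
  d <- dim(cube$data)
  idx <- which(scene$mask)
  if (!is.null(n_max) && length(idx) > n_max) {
    set.seed(seed)
    idx <- sort(sample(idx, n_max))
  }
  matrix(cube$data, d[1] * d[2], d[3])[idx, , drop = FALSE]
}
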