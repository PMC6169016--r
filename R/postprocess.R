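#' Phase-correlation registration of an image pair
#'
#' Computes the peak of the inverse FFT of the normalized cross-power
#' spectrum of `img_a` and `img_b` and returns the integer shift
#' `(dy, dx)` by which `img_b` is displaced relative to `img_a`
#' (`img_b(y, x) = img_a(y - dy, x - dx)`); translating `img_b` back by
#' `(-dy, -dx)` aligns it with `img_a`. Peak indices wrap to signed
#' shifts. Flat (spectrally empty) images yield a zero-confidence flag.
#'
#' @param img_a,img_b numeric matrices of equal size.
#' @param eps floor for the cross-power magnitude.
#' @param expected_shift optional `c(dy, dx)`; with `search_radius`,
#'   restricts the peak search to a neighbourhood of the expected
#'   displacement (used when a nominal offset is known, e.g. stride
#'   overlap), suppressing spurious sidelobes from weakly overlapping
#'   windows.
#' @param search_radius half-width of the restricted search, in px.
#' @return list: `dy`, `dx` (integers), `score` (correlation peak value
#'   in \[0, 1\]-ish range), `flat` (logical).
#' @export
register_pair <- function(img_a, img_b, eps = 1e-12,
                          expected_shift = NULL, search_radius = NULL) {
  stopifnot(all(dim(img_a) == dim(img_b)))
  FA <- stats::fft(img_a)
  FB <- stats::fft(img_b)
  R <- FA * Conj(FB)
  mag <- Mod(R)
  flat <- all(mag[-1] < eps) # only DC present
  R <- R / pmax(mag, eps)
  r <- Re(stats::fft(R, inverse = TRUE)) / length(R)
  nr <- nrow(r); nc <- ncol(r)
  if (!is.null(expected_shift) && !is.null(search_radius)) {
    # peak position for displacement (dy, dx) is (-dy, -dx) mod size
    keep <- matrix(FALSE, nr, nc)
    dys <- (-expected_shift[1] + (-search_radius:search_radius)) %% nr
    dxs <- (-expected_shift[2] + (-search_radius:search_radius)) %% nc
    keep[dys + 1, dxs + 1] <- TRUE
    r[!keep] <- -Inf
  }
  pk <- which(r == max(r), arr.ind = TRUE)[1, ]
  dy <- pk[1] - 1L; dx <- pk[2] - 1L
  if (dy > nr / 2) dy <- dy - nr
  if (dx > nc / 2) dx <- dx - nc
  # the correlation peak sits at minus the displacement of b w.r.t. a
  list(dy = as.integer(-dy), dx = as.integer(-dx),
       score = if (flat) 0 else max(r), flat = flat)
}

shift_image <- function(img, dy, dx, fill = 0) {
  out <- matrix(fill, nrow(img), ncol(img))
  src_r <- seq_len(nrow(img)) - dy
  src_c <- seq_len(ncol(img)) - dx
  ok_r <- src_r >= 1 & src_r <= nrow(img)
  ok_c <- src_c >= 1 & src_c <= ncol(img)
  out[ok_r, ok_c] <- img[src_r[ok_r], src_c[ok_c]]
  out
}

#' Stitch scan strides into a whole-box image
#'
#' Strides are ordered left to right with a nominal fractional column
#' overlap. Each adjacent pair is registered by phase correlation of its
#' nominal overlap region (plus a search margin); if the registration
#' confidence falls below `score_floor` the nominal offset is used with a
#' warning. Overlapping pixels are fused by logical OR for binary
#' strides (preserves thin axes crossing seams) and by the mean for
#' grayscale strides.
#'
#' @param strides list of numeric or logical matrices with equal row
#'   count, ordered left to right.
#' @param nominal_overlap fractional column overlap in (0, 0.5).
#' @param score_floor minimum registration peak score.
#' @param margin extra columns around the nominal overlap used for
#'   registration.
#' @return list: `image` (stitched matrix; logical if all strides were),
#'   `layout` (data.frame of per-stride row/col offsets and peak
#'   scores).
#' @export
stitch_strides <- function(strides, nominal_overlap = 0.1,
                           score_floor = 0.05, margin = 8) {
  stopifnot(length(strides) >= 1, nominal_overlap > 0, nominal_overlap < 0.5)
  binary <- all(vapply(strides, is.logical, logical(1)))
  strides_n <- lapply(strides, function(s) {
    s <- as.matrix(s); storage.mode(s) <- "double"; s
  })
  n <- length(strides_n)
  offs <- data.frame(stride = seq_len(n), row_off = 0L, col_off = 0L,
                     score = NA_real_)
  if (n > 1) {
    for (i in 2:n) {
      a <- strides_n[[i - 1]]; b <- strides_n[[i]]
      ov <- max(2L, round(nominal_overlap * ncol(b)))
      w <- min(ncol(a), ncol(b), ov + margin)
      ra <- a[, (ncol(a) - w + 1):ncol(a), drop = FALSE]
      rb <- b[, 1:w, drop = FALSE]
      # rb's nominal displacement w.r.t. ra is (0, ov - w)
      reg <- register_pair(ra, rb, expected_shift = c(0, ov - w),
                           search_radius = margin)
      nominal_col <- offs$col_off[i - 1] + ncol(a) - ov
      if (reg$flat || reg$score < score_floor) {
        warning(sprintf("stride %d: low registration confidence, using nominal offset", i))
        offs$row_off[i] <- offs$row_off[i - 1]
        offs$col_off[i] <- nominal_col
      } else {
        # rb displaced by (dy, dx) w.r.t. ra, whose left edge sits at
        # global column col_off[i-1] + ncol(a) - w
        offs$row_off[i] <- offs$row_off[i - 1] - reg$dy
        offs$col_off[i] <- offs$col_off[i - 1] + (ncol(a) - w) - reg$dx
        offs$score[i] <- reg$score
      }
    }
  }
  # canvas bounds
  r0 <- min(offs$row_off); offs$row_off <- offs$row_off - r0
  nr <- max(offs$row_off + vapply(strides_n, nrow, integer(1)))
  nc <- max(offs$col_off + vapply(strides_n, ncol, integer(1)))
  acc <- matrix(0, nr, nc)
  cnt <- matrix(0L, nr, nc)
  for (i in seq_len(n)) {
    rr <- offs$row_off[i] + seq_len(nrow(strides_n[[i]]))
    cc <- offs$col_off[i] + seq_len(ncol(strides_n[[i]]))
    if (binary) {
      acc[rr, cc] <- pmax(acc[rr, cc], strides_n[[i]])
    } else {
      acc[rr, cc] <- acc[rr, cc] + strides_n[[i]]
      cnt[rr, cc] <- cnt[rr, cc] + 1L
    }
  }
  img <- if (binary) acc > 0 else acc / pmax(cnt, 1L)
  list(image = img, layout = offs)
}

#' Root mask with physical scale
#'
#' @param mask logical matrix.
#' @param mm_per_px pixel pitch in mm.
#' @return object of class `root_mask` with `length_cm` (filled by
#'   [estimate_root_length()]) and connected-component stats.
#' @export
root_mask <- function(mask, mm_per_px = 0.1) {
  storage.mode(mask) <- "logical"
  structure(list(mask = mask, mm_per_px = mm_per_px,
                 length_cm = NA_real_, components = NULL),
            class = "root_mask")
}

#' @export
print.root_mask <- function(x, ...) {
  cat(sprintf("<root_mask> %d x %d px @ %.3g mm/px, %d root px, length %s cm\n",
              nrow(x$mask), ncol(x$mask), x$mm_per_px, sum(x$mask),
              if (is.na(x$length_cm)) "?" else sprintf("%.2f", x$length_cm)))
  invisible(x)
}

# component stats: area, bounding box, ellipse major-axis length
component_stats <- function(mask) {
  lab <- cc_label_(mask)
  k <- max(lab)
  if (k == 0)
    return(data.frame(label = integer(0), area = integer(0),
                      major_axis = numeric(0)))
  idx <- which(lab > 0)
  l <- lab[idx]
  rr <- (idx - 1L) %% nrow(mask) + 1L
  cc <- (idx - 1L) %/% nrow(mask) + 1L
  out <- lapply(seq_len(k), function(j) {
    sel <- l == j
    r <- rr[sel]; c <- cc[sel]
    n <- length(r)
    # image-ellipse convention: major axis = 4 * sqrt(largest eigenvalue
    # of the central second-moment matrix)
    mr <- mean(r); mc <- mean(c)
    crr <- mean((r - mr)^2) + 1 / 12 # pixel-extent correction
    ccc <- mean((c - mc)^2) + 1 / 12
    crc <- mean((r - mr) * (c - mc))
    tr <- crr + ccc
    det <- crr * ccc - crc^2
    lmax <- tr / 2 + sqrt(pmax(tr^2 / 4 - det, 0))
    data.frame(label = j, area = n, major_axis = 4 * sqrt(lmax))
  })
  do.call(rbind, out)
}

#' Remove small noise objects
#'
#' Deletes 8-connected components that are both short (ellipse
#' major-axis length below `min_extent_px`) and small (area below
#' `min_area_px`). Elongated components survive regardless of area, so
#' thin root axes are never filtered out.
#'
#' @param mask logical matrix (or `root_mask`).
#' @param min_extent_px minimum major-axis length in px.
#' @param min_area_px minimum area in px.
#' @param mm_per_px scale for the returned [root_mask()].
#' @return a [root_mask()] with `components` holding the surviving
#'   component stats.
#' @export
remove_noise_objects <- function(mask, min_extent_px = 10, min_area_px = 20,
                                 mm_per_px = 0.1) {
  if (inherits(mask, "root_mask")) { mm_per_px <- mask$mm_per_px; mask <- mask$mask }
  storage.mode(mask) <- "logical"
  lab <- cc_label_(mask)
  st <- component_stats(mask)
  drop <- st$label[st$major_axis < min_extent_px & st$area < min_area_px]
  keep_mask <- mask & !(lab %in% drop)
  dim(keep_mask) <- dim(mask)
  out <- root_mask(keep_mask, mm_per_px)
  out$components <- st[!(st$label %in% drop), , drop = FALSE]
  out
}

#' Skeletonize a binary mask
#'
#' Zhang-Suen thinning to an 8-connected, 1-px-wide medial-axis
#' approximation.
#'
#' @param mask logical matrix.
#' @return logical skeleton matrix.
#' @export
skeletonize <- function(mask) {
  storage.mode(mask) <- "logical"
  thin_mask_(mask)
}

#' Estimate root length from a mask
#'
#' Skeletonizes the mask and counts adjacency steps along the skeleton:
#' length = (N_orthogonal + sqrt(2) * N_diagonal) * mm_per_px, where
#' orthogonal steps are right/down neighbour pairs and diagonal steps are
#' down-right/down-left pairs (each pair counted once).
#'
#' @param mask a [root_mask()] or logical matrix.
#' @param mm_per_px pixel pitch (ignored when a `root_mask` is given).
#' @return length in cm (0 for an empty mask). When a `root_mask` is
#'   passed, the updated object is returned invisibly via attribute-free
#'   convention: use the returned scalar and assign if needed.
#' @export
estimate_root_length <- function(mask, mm_per_px = 0.1) {
  if (inherits(mask, "root_mask")) { mm_per_px <- mask$mm_per_px; mask <- mask$mask }
  if (!any(mask)) return(0)
  sk <- skeletonize(mask)
  skeleton_step_length_cm(sk, mm_per_px)
}

# step-count length of an already-thin skeleton
skeleton_step_length_cm <- function(sk, mm_per_px) {
  nr <- nrow(sk); nc <- ncol(sk)
  right <- sk[, -nc, drop = FALSE] & sk[, -1, drop = FALSE]
  down <- sk[-nr, , drop = FALSE] & sk[-1, , drop = FALSE]
  dr <- sk[-nr, -nc, drop = FALSE] & sk[-1, -1, drop = FALSE]
  dl <- sk[-nr, -1, drop = FALSE] & sk[-1, -nc, drop = FALSE]
  n_orth <- sum(right) + sum(down)
  n_diag <- sum(dr) + sum(dl)
  (n_orth + sqrt(2) * n_diag) * mm_per_px / 10
}
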