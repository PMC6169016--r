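#' Root / soil regions of interest
#'
#' Hand-labelled (or truth-derived) foreground and background pixel sets
#' used for histogram-based separability scoring and supervised
#' segmentation.
#'
#' @param root_pixels,soil_pixels two-column matrices of (row, col)
#'   indices (1-based).
#' @param source optional provenance string (e.g. mask path).
#' @return An object of class `roi_set`.
#' @export
roi_set <- function(root_pixels, soil_pixels, source = NULL) {
  root_pixels <- as.matrix(root_pixels); soil_pixels <- as.matrix(soil_pixels)
  if (nrow(root_pixels) == 0 || nrow(soil_pixels) == 0)
    stop("both ROI classes must be non-empty")
  key <- function(m) paste(m[, 1], m[, 2])
  if (length(intersect(key(root_pixels), key(soil_pixels))) > 0)
    stop("root and soil ROIs overlap")
  structure(list(root_pixels = root_pixels, soil_pixels = soil_pixels,
                 source = source), class = "roi_set")
}

# ROI pixel values from a 2-D image or a band of a cube
roi_values <- function(img, pixels) img[cbind(pixels[, 1], pixels[, 2])]

#' Bhattacharyya distance between two samples
#'
#' Histograms both samples on a shared equal-width binning over the pooled
#' min-max range (default 128 bins), then computes
#' \eqn{D = -\ln \sum_i \sqrt{p_i q_i}}. Identical samples give 0;
#' disjoint supports give `Inf`. A zero-width pooled range means both
#' histograms are identical, giving 0.
#'
#' @param a,b numeric samples (non-empty).
#' @param n_bins number of histogram bins.
#' @return non-negative distance (unitless).
#' @export
bhattacharyya_distance <- function(a, b, n_bins = 128) {
  stopifnot(length(a) > 0, length(b) > 0)
  rng <- range(c(a, b), finite = TRUE)
  if (diff(rng) == 0) return(0)
  brk <- seq(rng[1], rng[2], length.out = n_bins + 1)
  p <- hist_counts(a, brk) / length(a)
  q <- hist_counts(b, brk) / length(b)
  bc <- sum(sqrt(p * q))
  if (bc <= 0) return(Inf)
  max(-log(bc), 0)
}

# fast fixed-breaks histogram (values outside [brk1, brkN] clamped)
hist_counts <- function(x, breaks) {
  n_bins <- length(breaks) - 1
  i <- findInterval(x, breaks, rightmost.closed = TRUE)
  i[i < 1] <- 1; i[i > n_bins] <- n_bins
  tabulate(i, n_bins)
}

#' Non-Gaussianity indicators of a sample
#'
#' Six scalar criteria measuring deviation from white noise: population
#' skewness (3rd standardized moment), excess kurtosis, Shannon histogram
#' entropy (bits, 128 equal-width bins), negentropy (entropy of a
#' moment-matched Gaussian discretized on the same bins minus sample
#' entropy), signal-to-noise ratio (mean / sd) and Kullback-Leibler
#' divergence of the sample histogram from the fitted Gaussian (bits).
#'
#' @param x numeric sample, `n >= 10`, non-zero variance.
#' @param n_bins histogram bins for the entropy-type criteria.
#' @return named numeric vector `skewness`, `kurtosis`, `entropy`,
#'   `negentropy`, `snr`, `kl_divergence`.
#' @export
non_gaussian_scores <- function(x, n_bins = 128) {
  x <- x[is.finite(x)]
  if (length(x) < 10) stop("need at least 10 finite values")
  mu <- mean(x)
  s2 <- mean((x - mu)^2)
  if (s2 <= 0) stop("zero-variance sample: scores undefined")
  s <- sqrt(s2)
  skew <- mean((x - mu)^3) / s^3
  kurt <- mean((x - mu)^4) / s2^2 - 3
  rng <- range(x)
  if (diff(rng) == 0) stop("zero-variance sample: scores undefined")
  brk <- seq(rng[1], rng[2], length.out = n_bins + 1)
  p <- hist_counts(x, brk) / length(x)
  H <- -sum(ifelse(p > 0, p * log2(p), 0))
  # moment-matched Gaussian on the same bins
  q <- diff(stats::pnorm(brk, mu, s))
  q <- q / sum(q)
  Hg <- -sum(ifelse(q > 0, q * log2(q), 0))
  negent <- Hg - H
  kl <- sum(ifelse(p > 0, p * log2(p / pmax(q, 1e-12)), 0))
  c(skewness = skew, kurtosis = kurt, entropy = H, negentropy = negent,
    snr = mu / s, kl_divergence = kl)
}

#' Per-band ROI Bhattacharyya distances
#'
#' @param cube a [hypercube].
#' @param rois a [roi_set()].
#' @param n_bins histogram bins.
#' @return numeric vector, one distance per band.
#' @export
band_scores_roi <- function(cube, rois, n_bins = 128) {
  vapply(seq_len(n_bands(cube)), function(b) {
    img <- cube$data[, , b]
    bhattacharyya_distance(roi_values(img, rois$root_pixels),
                           roi_values(img, rois$soil_pixels), n_bins)
  }, numeric(1))
}

#' Difference-spectrum ROI Bhattacharyya distances
#'
#' Scores every band pair (n, m), n > m, by the ROI separability of the
#' difference image \eqn{N_{\lambda_n} - N_{\lambda_m}}. The matrix is
#' filled symmetrically (the distance of a sign-flipped sample on
#' symmetric pooled binning is equal up to binning; both triangles store
#' the n > m value).
#'
#' @param cube a [hypercube].
#' @param rois a [roi_set()].
#' @param n_bins histogram bins.
#' @param band_stride compute every `band_stride`-th band pair (1 = all).
#' @return `bands x bands` matrix (NA where skipped, 0 diagonal).
#' @export
diff_band_scores <- function(cube, rois, n_bins = 128, band_stride = 1) {
  nb <- n_bands(cube)
  root_sp <- t(apply(cube$data, 3, roi_values, pixels = rois$root_pixels))
  soil_sp <- t(apply(cube$data, 3, roi_values, pixels = rois$soil_pixels))
  # rows = bands, cols = roi pixels
  D <- matrix(NA_real_, nb, nb)
  diag(D) <- 0
  bands <- seq(1, nb, by = band_stride)
  for (i in seq_along(bands)) {
    bi <- bands[i]
    for (j in seq_len(i - 1L)) {
      bj <- bands[j]
      d <- bhattacharyya_distance(root_sp[bi, ] - root_sp[bj, ],
                                  soil_sp[bi, ] - soil_sp[bj, ], n_bins)
      D[bi, bj] <- D[bj, bi] <- d
    }
  }
  D
}

# per-band non-Gaussian scores over all valid pixels of a cube;
# returns bands x 6 matrix
nongauss_band_scores <- function(cube, n_bins = 128) {
  cs <- cube_spectra(cube)
  t(vapply(seq_len(n_bands(cube)), function(b) {
    v <- cs$spectra[, b]
    if (stats::var(v) <= 0 || length(v) < 10)
      return(rep(NA_real_, 6))
    non_gaussian_scores(v, n_bins)
  }, numeric(6)))
}

# collapse per-band six-score matrix to the "best band": the band
# maximizing the average standardized score (each criterion oriented so
# larger = farther from white noise: |skew|, |kurt|, -entropy, negentropy,
# snr, kl)
best_band_nongauss <- function(score_mat) {
  oriented <- cbind(abs(score_mat[, "skewness"]), abs(score_mat[, "kurtosis"]),
                    -score_mat[, "entropy"], score_mat[, "negentropy"],
                    score_mat[, "snr"], score_mat[, "kl_divergence"])
  z <- scale(oriented)
  z[!is.finite(z)] <- 0
  which.max(rowMeans(z))
}

#' Rank pre-treatments by information criteria
#'
#' For each pre-treated cube computes (a) the six non-Gaussian indicators
#' at the whole image's best band and their average rank across criteria,
#' (b) the maximum single-band ROI Bhattacharyya distance, and (c) the
#' maximum band-pair difference-spectrum Bhattacharyya distance. Ranks use
#' midranks for ties. Specs producing non-finite images are excluded with
#' a message.
#'
#' @param cubes_by_spec named list of pre-treated [hypercube]s (names =
#'   spec labels).
#' @param rois a [roi_set()].
#' @param n_bins histogram bins.
#' @param band_stride pair subsampling passed to [diff_band_scores()].
#' @return list with `table` (data.frame: spec, avg_rank_nongauss,
#'   bhattacharyya_single (+ rank), bhattacharyya_diff (+ rank), best
#'   bands) and `candidates` (union of top-3 specs per criterion).
#' @export
rank_pretreatments <- function(cubes_by_spec, rois, n_bins = 128,
                               band_stride = 1) {
  stopifnot(length(cubes_by_spec) >= 2)
  ok <- vapply(cubes_by_spec, function(cb) all(is.finite(cb$data)), logical(1))
  if (any(!ok))
    message("excluding non-finite spec(s): ",
            paste(names(cubes_by_spec)[!ok], collapse = ", "))
  cubes <- cubes_by_spec[ok]
  ng <- lapply(cubes, function(cb) {
    sm <- nongauss_band_scores(cb, n_bins)
    b <- best_band_nongauss(sm)
    list(best_band = b, scores = sm[b, ])
  })
  ng_mat <- do.call(rbind, lapply(ng, `[[`, "scores"))
  oriented <- cbind(abs(ng_mat[, "skewness"]), abs(ng_mat[, "kurtosis"]),
                    -ng_mat[, "entropy"], ng_mat[, "negentropy"],
                    ng_mat[, "snr"], ng_mat[, "kl_divergence"])
  ranks <- apply(-oriented, 2, rank, ties.method = "average")
  if (is.null(dim(ranks))) ranks <- matrix(ranks, nrow = 1)
  avg_rank <- rowMeans(ranks)

  singles <- lapply(cubes, function(cb) band_scores_roi(cb, rois, n_bins))
  d_single <- vapply(singles, max, numeric(1))
  best_single_band <- vapply(singles, function(s) as.numeric(which.max(s)),
                             numeric(1))
  d_diff <- vapply(cubes, function(cb) {
    M <- diff_band_scores(cb, rois, n_bins, band_stride)
    max(M, na.rm = TRUE)
  }, numeric(1))

  tab <- data.frame(
    spec = names(cubes),
    avg_rank_nongauss = avg_rank,
    rank_nongauss = rank(avg_rank, ties.method = "average"),
    bhattacharyya_single = d_single,
    rank_single = rank(-d_single, ties.method = "average"),
    best_single_band = best_single_band,
    bhattacharyya_diff = d_diff,
    rank_diff = rank(-d_diff, ties.method = "average"),
    stringsAsFactors = FALSE)
  top3 <- function(r) tab$spec[order(r)][seq_len(min(3, nrow(tab)))]
  cand <- unique(c(top3(tab$rank_nongauss), top3(tab$rank_single),
                   top3(tab$rank_diff)))
  list(table = tab, candidates = cand)
}

#' Format a ranking table as "distance (rank)" strings
#'
#' Mirrors the published layout: absolute Bhattacharyya distance with the
#' method rank in brackets.
#'
#' @param ranking result of [rank_pretreatments()].
#' @return data.frame of formatted strings.
#' @export
format_ranking_table <- function(ranking) {
  tab <- ranking$table
  data.frame(
    spec = tab$spec,
    nongauss_rank = sprintf("%d", as.integer(round(tab$rank_nongauss))),
    bhattacharyya_single = sprintf("%.2f (%d)", tab$bhattacharyya_single,
                                   as.integer(round(tab$rank_single))),
    bhattacharyya_diff = sprintf("%.2f (%d)", tab$bhattacharyya_diff,
                                 as.integer(round(tab$rank_diff))),
    stringsAsFactors = FALSE)
}

#' Select the most informative bands by nomination frequency
#'
#' Each criterion's per-band score vector nominates its `k` best bands
#' (largest score); bands are then ranked by how many criteria nominated
#' them, ties broken by mean rank across nominating criteria, then by
#' lower wavelength (band index).
#'
#' @param score_tables named list of per-band score vectors (larger =
#'   better), all the same length.
#' @param k number of bands to return (and to nominate per criterion).
#' @return integer vector of band indices, best first. If fewer than `k`
#'   distinct bands are nominated, all are returned with a warning.
#' @export
select_top_bands <- function(score_tables, k = 10) {
  stopifnot(k >= 1, length(score_tables) >= 1)
  nb <- length(score_tables[[1]])
  freq <- integer(nb)
  rank_sum <- numeric(nb)
  for (sc in score_tables) {
    stopifnot(length(sc) == nb)
    ord <- order(sc, decreasing = TRUE)
    nom <- ord[seq_len(min(k, sum(is.finite(sc))))]
    freq[nom] <- freq[nom] + 1L
    rank_sum[nom] <- rank_sum[nom] + seq_along(nom)
  }
  cand <- which(freq > 0)
  mean_rank <- rank_sum[cand] / freq[cand]
  ord <- cand[order(-freq[cand], mean_rank, cand)]
  if (length(ord) < k) {
    warning(sprintf("only %d distinct bands nominated (k = %d)",
                    length(ord), k))
    return(ord)
  }
  ord[seq_len(k)]
}

#' Reduce cube dimensionality for segmentation
#'
#' Modes: `best1` (single most informative band image), `mean10` (mean
#' over the selected bands), `pca1` (principal-component score image with
#' the highest ROI Bhattacharyya contrast), `stack10` (3-D stack of the
#' selected bands) and `pca_k` (first `k` score images, e.g. k = 5 for
#' chemometrics).
#'
#' @param cube a [hypercube].
#' @param bands integer band indices (best first); used by `best1`,
#'   `mean10`, `stack10`.
#' @param mode reduction mode.
#' @param rois optional [roi_set()]; required to pick the `pca1`
#'   component by ROI contrast (falls back to PC1 if missing).
#' @param k number of components for `pca_k`.
#' @return a matrix (2-D modes), 3-D array (`stack10`) or list of score
#'   matrices plus variance record (`pca_k`).
#' @export
reduce_dims <- function(cube, bands = NULL,
                        mode = c("best1", "mean10", "pca1", "stack10", "pca_k"),
                        rois = NULL, k = 5) {
  mode <- match.arg(mode)
  d <- dim(cube$data)
  if (mode %in% c("best1", "mean10", "stack10")) {
    stopifnot(!is.null(bands), all(bands >= 1), all(bands <= d[3]))
  }
  switch(mode,
    best1 = cube$data[, , bands[1]],
    mean10 = {
      sub <- cube$data[, , bands, drop = FALSE]
      apply(sub, c(1, 2), mean)
    },
    stack10 = cube$data[, , bands, drop = FALSE],
    pca1 = {
      sc <- cube_pca_scores(cube, min(k, d[3]))
      pick <- 1L
      if (!is.null(rois)) {
        dists <- vapply(seq_len(ncol(sc$scores)), function(j) {
          img <- score_image(cube, sc, j)
          bhattacharyya_distance(roi_values(img, rois$root_pixels),
                                 roi_values(img, rois$soil_pixels))
        }, numeric(1))
        pick <- which.max(dists)
      }
      score_image(cube, sc, pick)
    },
    pca_k = {
      if (d[3] < k) stop("cube has fewer bands than requested components")
      sc <- cube_pca_scores(cube, k)
      list(images = lapply(seq_len(k), function(j) score_image(cube, sc, j)),
           explained_variance = sc$explained_variance)
    })
}

# PCA of valid-pixel spectra; returns scores (n_valid x k), idx, rotation
cube_pca_scores <- function(cube, k) {
  cs <- cube_spectra(cube)
  pc <- stats::prcomp(cs$spectra, center = TRUE, scale. = FALSE, rank. = k)
  list(scores = pc$x[, seq_len(k), drop = FALSE], idx = cs$idx,
       rotation = pc$rotation,
       explained_variance = (pc$sdev^2 / sum(pc$sdev^2))[seq_len(k)])
}

score_image <- function(cube, sc, j) {
  d <- dim(cube$data)
  img <- matrix(0, d[1], d[2])
  img[sc$idx] <- sc$scores[, j]
  img
}
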