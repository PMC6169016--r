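#' Segmentation result container
#'
#' @param mask logical root mask.
#' @param algorithm algorithm id string.
#' @param spec_id pre-treatment label, if any.
#' @param failed logical; quality gate (see [evaluate_segmentation()]).
#' @param extra named list of algorithm-specific extras.
#' @return object of class `segmentation_result` with fields `mask`,
#'   `algorithm`, `spec_id`, `skewness`, `root_length_cm` (filled by
#'   post-processing), `failed`.
#' @export
segmentation_result <- function(mask, algorithm, spec_id = NA_character_,
                                failed = FALSE, extra = list()) {
  storage.mode(mask) <- "logical"
  sk <- binary_mask_skewness(mask)
  structure(c(list(mask = mask, algorithm = algorithm, spec_id = spec_id,
                   skewness = sk, root_length_cm = NA_real_,
                   failed = failed), extra),
            class = "segmentation_result")
}

#' @export
print.segmentation_result <- function(x, ...) {
  cat(sprintf("<segmentation_result> %s: %d root px (%.2f%%), skewness %.2f%s\n",
              x$algorithm, sum(x$mask), 100 * mean(x$mask), x$skewness,
              if (isTRUE(x$failed)) " [FAILED]" else ""))
  invisible(x)
}

#' Population skewness of a binary image
#'
#' For a 0/1 image with foreground fraction p this equals
#' \eqn{(1 - 2p) / \sqrt{p (1 - p)}}; computed from the population
#' moments of the actual mask values.
#'
#' @param mask logical or 0/1 matrix.
#' @return skewness (NaN for an empty or full mask).
#' @export
binary_mask_skewness <- function(mask) {
  x <- as.numeric(mask)
  mu <- mean(x)
  s2 <- mean((x - mu)^2)
  if (s2 <= 0) return(NaN)
  mean((x - mu)^3) / s2^1.5
}

#' Multilevel Otsu thresholds
#'
#' Exhaustively maximizes between-class variance over an equal-width
#' histogram. Exact for 2 and 3 classes at `n_bins` bins; for 4 classes
#' the histogram is coarsened to 64 bins to keep the search exhaustive.
#'
#' @param values numeric sample.
#' @param n_classes 2, 3 or 4.
#' @param n_bins histogram bins.
#' @return numeric thresholds (length `n_classes - 1`), or `NULL` for a
#'   constant sample.
#' @export
otsu_thresholds <- function(values, n_classes = 3, n_bins = 256) {
  stopifnot(n_classes >= 2, n_classes <= 4)
  values <- values[is.finite(values)]
  rng <- range(values)
  if (diff(rng) == 0) return(NULL)
  if (n_classes == 4) n_bins <- min(n_bins, 64)
  brk <- seq(rng[1], rng[2], length.out = n_bins + 1)
  cnt <- hist_counts(values, brk)
  mids <- (brk[-1] + brk[-length(brk)]) / 2
  p <- cnt / sum(cnt)
  # cumulative weight and mean for O(1) class stats
  cw <- cumsum(p)
  cm <- cumsum(p * mids)
  class_stat <- function(i, j) { # bins i..j (1-based, inclusive)
    w <- cw[j] - if (i > 1) cw[i - 1] else 0
    m <- cm[j] - if (i > 1) cm[i - 1] else 0
    c(w, m)
  }
  bcv <- function(cuts) { # cuts: last bin index of each class but the final
    bounds <- c(0, cuts, n_bins)
    s <- 0
    for (k in seq_len(length(bounds) - 1)) {
      st <- class_stat(bounds[k] + 1, bounds[k + 1])
      if (st[1] > 0) s <- s + st[2]^2 / st[1]
    }
    s
  }
  cut_sets <- switch(as.character(n_classes),
    "2" = matrix(seq_len(n_bins - 1), ncol = 1),
    "3" = t(utils::combn(n_bins - 1, 2)),
    "4" = t(utils::combn(n_bins - 1, 3)))
  scores <- apply(cut_sets, 1, bcv)
  best <- cut_sets[which.max(scores), ]
  brk[best + 1] # threshold at the upper edge of the last bin of each class
}

# root class = class/cluster whose (multivariate) mean is farthest from
# the image mode; ties broken toward the smaller class
pick_root_class <- function(centers, sizes, mode_vec) {
  centers <- as.matrix(centers)
  d <- sqrt(rowSums(sweep(centers, 2, mode_vec)^2))
  mx <- max(d)
  cand <- which(abs(d - mx) < 1e-12)
  if (length(cand) > 1) cand <- cand[which.min(sizes[cand])]
  cand[1]
}

# histogram mode (per column for feature matrices)
feature_mode <- function(X, n_bins = 256) {
  apply(as.matrix(X), 2, function(v) {
    rng <- range(v, finite = TRUE)
    if (diff(rng) == 0) return(rng[1])
    brk <- seq(rng[1], rng[2], length.out = n_bins + 1)
    cnt <- hist_counts(v[is.finite(v)], brk)
    mids <- (brk[-1] + brk[-length(brk)]) / 2
    mids[which.max(cnt)]
  })
}

#' Multilevel-threshold segmentation
#'
#' Otsu multilevel thresholding of a dimensionality-reduced image; the
#' root class is the one whose mean is most distant from the image mode
#' (roots are sparse and contrast-extreme), ties toward the smaller
#' class. A constant image yields a failed result rather than an error.
#'
#' @param image 2-D numeric matrix.
#' @param n_classes number of classes (default 3: root, soil, mixed).
#' @param valid_mask optional logical matrix restricting the pixels used.
#' @param spec_id provenance label.
#' @return a [segmentation_result()].
#' @export
segment_threshold <- function(image, n_classes = 3, valid_mask = NULL,
                              spec_id = NA_character_) {
  if (is.null(valid_mask)) valid_mask <- matrix(TRUE, nrow(image), ncol(image))
  vals <- image[valid_mask]
  thr <- otsu_thresholds(vals, n_classes)
  if (is.null(thr)) {
    return(segmentation_result(matrix(FALSE, nrow(image), ncol(image)),
                               "threshold", spec_id, failed = TRUE))
  }
  cls <- findInterval(image, thr) + 1L
  sizes <- tabulate(cls[valid_mask], n_classes)
  centers <- vapply(seq_len(n_classes), function(k) {
    v <- image[valid_mask & cls == k]
    if (length(v)) mean(v) else Inf
  }, numeric(1))
  mode_v <- feature_mode(matrix(vals, ncol = 1))
  root_k <- pick_root_class(matrix(centers, ncol = 1), sizes, mode_v)
  mask <- cls == root_k & valid_mask
  segmentation_result(mask, "threshold", spec_id,
                      extra = list(thresholds = thr, root_class = root_k))
}

# features argument -> n x d matrix + index bookkeeping
flatten_features <- function(features, valid_mask = NULL) {
  if (is.matrix(features)) {
    nr <- nrow(features); nc <- ncol(features)
    X <- matrix(as.vector(features), nr * nc, 1)
  } else {
    d <- dim(features)
    nr <- d[1]; nc <- d[2]
    X <- matrix(features, nr * nc, d[3])
  }
  if (is.null(valid_mask)) valid_mask <- matrix(TRUE, nr, nc)
  idx <- which(valid_mask)
  list(X = X[idx, , drop = FALSE], idx = idx, nr = nr, nc = nc)
}

# k-means++ initial centers
kmeanspp_init <- function(X, k) {
  n <- nrow(X)
  centers <- matrix(NA_real_, k, ncol(X))
  centers[1, ] <- X[sample.int(n, 1), ]
  d2 <- rowSums(sweep(X, 2, centers[1, ])^2)
  for (j in seq_len(k - 1) + 1) {
    pr <- d2 / sum(d2)
    if (!all(is.finite(pr)) || sum(pr) <= 0) pr <- rep(1 / n, n)
    centers[j, ] <- X[sample.int(n, 1, prob = pr), ]
    d2 <- pmin(d2, rowSums(sweep(X, 2, centers[j, ])^2))
  }
  centers
}

pairwise_sqdist <- function(X, C) {
  # n x k squared Euclidean distances
  outer(rowSums(X^2), rep(1, nrow(C))) - 2 * X %*% t(C) +
    outer(rep(1, nrow(X)), rowSums(C^2))
}

#' K-means segmentation
#'
#' Lloyd iterations from a k-means++ initialization (seeded, hence
#' deterministic). Empty clusters are re-initialized to the point
#' farthest from its centroid.
#'
#' @param features 2-D matrix or 3-D stacked-band array.
#' @param k number of clusters (default 3).
#' @param seed RNG seed for the initialization.
#' @param max_iter,tol Lloyd iteration controls.
#' @param valid_mask optional logical matrix.
#' @param spec_id provenance label.
#' @return a [segmentation_result()].
#' @export
segment_kmeans <- function(features, k = 3, seed = 1, max_iter = 300,
                           tol = 1e-4, valid_mask = NULL,
                           spec_id = NA_character_) {
  stopifnot(k >= 2)
  ff <- flatten_features(features, valid_mask)
  X <- ff$X
  set.seed(seed)
  C <- kmeanspp_init(X, k)
  assign <- rep(0L, nrow(X))
  for (it in seq_len(max_iter)) {
    D2 <- pairwise_sqdist(X, C)
    assign <- max.col(-D2, ties.method = "first")
    Cnew <- C
    for (j in seq_len(k)) {
      sel <- assign == j
      if (!any(sel)) {
        # re-seed an empty cluster at the globally worst-fit point
        worst <- which.max(D2[cbind(seq_len(nrow(X)), assign)])
        Cnew[j, ] <- X[worst, ]
      } else {
        Cnew[j, ] <- colMeans(X[sel, , drop = FALSE])
      }
    }
    shift <- max(sqrt(rowSums((Cnew - C)^2)))
    C <- Cnew
    if (shift < tol) break
  }
  sizes <- tabulate(assign, k)
  mode_v <- feature_mode(X)
  root_k <- pick_root_class(C, sizes, mode_v)
  mask <- matrix(FALSE, ff$nr, ff$nc)
  mask[ff$idx] <- assign == root_k
  segmentation_result(mask, "kmeans", spec_id,
                      extra = list(centers = C, root_class = root_k,
                                   iterations = it))
}

#' Fuzzy c-means segmentation
#'
#' Standard fuzzy c-means: memberships
#' \eqn{u_{ij} \propto d_{ij}^{-2/(m-1)}} (normalized per pixel),
#' centroids as \eqn{u^m}-weighted means. Converges when the largest
#' membership change is below `tol` or after `max_iter` iterations. A
#' pixel coincident with a centroid gets membership 1 to it. The hard
#' mask is by maximum membership; the root cluster follows the
#' mode-distance rule.
#'
#' @param features 2-D matrix or 3-D stacked-band array.
#' @param c_clusters number of clusters (default 3).
#' @param m fuzzifier (> 1, default 2).
#' @param seed RNG seed for the initial centroids (k-means++).
#' @param max_iter,tol convergence controls.
#' @param valid_mask optional logical matrix.
#' @param spec_id provenance label.
#' @return a [segmentation_result()]; `extra` carries the final
#'   memberships' objective trace `objective` (non-increasing).
#' @export
segment_fuzzy_cmeans <- function(features, c_clusters = 3, m = 2, seed = 1,
                                 max_iter = 100, tol = 1e-5,
                                 valid_mask = NULL, spec_id = NA_character_) {
  stopifnot(c_clusters >= 2, m > 1)
  ff <- flatten_features(features, valid_mask)
  X <- ff$X
  n <- nrow(X)
  set.seed(seed)
  C <- kmeanspp_init(X, c_clusters)
  U <- matrix(1 / c_clusters, n, c_clusters)
  obj <- numeric(0)
  for (it in seq_len(max_iter)) {
    D2 <- pmax(pairwise_sqdist(X, C), 0)
    zero <- D2 < 1e-300
    Unew <- D2^(-1 / (m - 1))
    Unew[!is.finite(Unew)] <- 0
    has_zero <- rowSums(zero) > 0
    if (any(has_zero)) {
      Unew[has_zero, ] <- 0
      Unew[has_zero, ] <- zero[has_zero, , drop = FALSE] * 1
    }
    Unew <- Unew / rowSums(Unew)
    obj <- c(obj, sum(Unew^m * D2))
    delta <- max(abs(Unew - U))
    U <- Unew
    Um <- U^m
    C <- t(Um) %*% X / colSums(Um)
    if (delta < tol) break
  }
  assign <- max.col(U, ties.method = "first")
  sizes <- tabulate(assign, c_clusters)
  mode_v <- feature_mode(X)
  root_k <- pick_root_class(C, sizes, mode_v)
  mask <- matrix(FALSE, ff$nr, ff$nc)
  mask[ff$idx] <- assign == root_k
  segmentation_result(mask, "fcm", spec_id,
                      extra = list(centers = C, memberships = U,
                                   root_class = root_k, objective = obj,
                                   iterations = it))
}

# linear SVM (hinge loss, L1 regularized dual, C = cost) via dual
# coordinate descent; deterministic sweep order. y in {-1, +1}.
linear_svm_fit <- function(X, y, cost = 1, max_epochs = 200, tol = 1e-4) {
  n <- nrow(X); d <- ncol(X)
  Xa <- cbind(X, 1) # bias folded into weights
  alpha <- numeric(n)
  w <- numeric(d + 1)
  qii <- rowSums(Xa^2)
  for (ep in seq_len(max_epochs)) {
    max_change <- 0
    for (i in seq_len(n)) {
      g <- y[i] * sum(w * Xa[i, ]) - 1
      pg <- g
      if (alpha[i] <= 0) pg <- min(g, 0)
      if (alpha[i] >= cost) pg <- max(g, 0)
      if (abs(pg) > 1e-12) {
        a_old <- alpha[i]
        alpha[i] <- min(max(alpha[i] - g / qii[i], 0), cost)
        w <- w + (alpha[i] - a_old) * y[i] * Xa[i, ]
        max_change <- max(max_change, abs(alpha[i] - a_old))
      }
    }
    if (max_change < tol) break
  }
  list(w = w[seq_len(d)], b = w[d + 1])
}

#' Two-class SVM segmentation
#'
#' Linear support vector machine (C = 1 by default) trained on ROI
#' pixels (root = +1, soil = -1) with features standardized by the
#' training statistics, then applied to every valid pixel.
#'
#' @param features 2-D matrix or 3-D stacked-band array.
#' @param rois a [roi_set()]; each class needs at least 20 pixels.
#' @param cost SVM cost parameter.
#' @param valid_mask optional logical matrix.
#' @param spec_id provenance label.
#' @return a [segmentation_result()].
#' @export
segment_svm <- function(features, rois, cost = 1, valid_mask = NULL,
                        spec_id = NA_character_) {
  ff <- flatten_features(features, valid_mask)
  nr <- ff$nr
  lin_idx <- function(px) (px[, 2] - 1L) * nr + px[, 1]
  all_flat <- if (is.matrix(features)) matrix(as.vector(features), ncol = 1)
              else matrix(features, nr * ff$nc, dim(features)[3])
  i_root <- lin_idx(rois$root_pixels)
  i_soil <- lin_idx(rois$soil_pixels)
  if (length(i_root) < 20 || length(i_soil) < 20)
    stop("each ROI class needs at least 20 pixels")
  Xtr <- rbind(all_flat[i_root, , drop = FALSE],
               all_flat[i_soil, , drop = FALSE])
  ytr <- c(rep(1, length(i_root)), rep(-1, length(i_soil)))
  mu <- colMeans(Xtr)
  sdv <- apply(Xtr, 2, stats::sd)
  sdv[sdv == 0] <- 1
  Xs <- sweep(sweep(Xtr, 2, mu), 2, sdv, "/")
  fit <- linear_svm_fit(Xs, ytr, cost)
  score_all <- sweep(sweep(all_flat, 2, mu), 2, sdv, "/") %*% fit$w + fit$b
  mask <- matrix(FALSE, nr, ff$nc)
  mask[ff$idx] <- score_all[ff$idx] > 0
  train_acc <- mean(sign(Xs %*% fit$w + fit$b) == ytr)
  segmentation_result(mask, "svm", spec_id,
                      extra = list(weights = fit$w, bias = fit$b,
                                   train_accuracy = train_acc))
}

#' Quality-gate a segmentation
#'
#' Computes the binary-image skewness and flags the result as failed when
#' skewness falls below the noise threshold (default 2.5) or the mask is
#' empty or full. With a reference length, reports the length ratio.
#'
#' @param result a [segmentation_result()] (with `root_length_cm` filled
#'   if a length ratio is wanted).
#' @param reference_length_cm optional reference root length (cm).
#' @param skew_threshold noise threshold on binary-image skewness.
#' @return list: `skewness`, `failed`, `root_fraction`, and
#'   `length_ratio` when a reference is given.
#' @export
evaluate_segmentation <- function(result, reference_length_cm = NULL,
                                  skew_threshold = 2.5) {
  mask <- result$mask
  p <- mean(mask)
  sk <- binary_mask_skewness(mask)
  failed <- p == 0 || p == 1 || !is.finite(sk) || sk < skew_threshold
  out <- list(skewness = sk, failed = failed, root_fraction = p)
  if (!is.null(reference_length_cm) && is.finite(result$root_length_cm))
    out$length_ratio <- result$root_length_cm / reference_length_cm
  out
}
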