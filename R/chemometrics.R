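#' Radial class specification
#'
#' Eight radial classes by distance from the root centre (medial axis):
#' 0-0.1 mm, then 0.2 mm increments (0.1-0.3, ..., 1.1-1.3), and an
#' open-ended class beyond 1.3 mm. At 0.1 mm/px the increments are 2 px.
#'
#' @param mm_per_px pixel pitch in mm.
#' @return object of class `radial_class_spec` with `edges_mm` (upper
#'   class edges, length 7) and `n_classes = 8`.
#' @export
radial_class_spec <- function(mm_per_px = 0.1) {
  structure(list(edges_mm = c(0.1, 0.3, 0.5, 0.7, 0.9, 1.1, 1.3),
                 n_classes = 8L, mm_per_px = mm_per_px),
            class = "radial_class_spec")
}

#' Label root pixels by radial class
#'
#' Each root pixel is assigned the distance to the nearest skeleton
#' (medial-axis) pixel, converted to mm and binned by the radial class
#' edges; class 8 is open-ended (> 1.3 mm).
#'
#' @param mask a [root_mask()] or logical matrix.
#' @param spec a [radial_class_spec()].
#' @return integer matrix of class labels (NA outside the root).
#' @export
label_radial_classes <- function(mask, spec = radial_class_spec()) {
  if (inherits(mask, "root_mask")) {
    spec$mm_per_px <- mask$mm_per_px
    mask <- mask$mask
  }
  out <- matrix(NA_integer_, nrow(mask), ncol(mask))
  if (!any(mask)) return(out)
  sk <- skeletonize(mask)
  if (!any(sk)) sk <- mask # degenerate: single-px objects
  q <- which(mask, arr.ind = TRUE)
  r <- which(sk, arr.ind = TRUE)
  d_px <- nearest_dist_(q, r)
  d_mm <- d_px * spec$mm_per_px
  # left-closed bins: a pixel exactly 0.1 mm (1 px) from the axis is the
  # first flanking pixel and belongs to class 2
  cls <- findInterval(d_mm, spec$edges_mm) + 1L
  # arr.ind order of which() matches column-major logical assignment order
  out[mask] <- cls
  out
}

#' ALS-corrected PCA features for chemometrics
#'
#' Applies ALS baseline (shape) correction to every root-pixel spectrum,
#' then PCA over root pixels only, returning the first `n_pc` score
#' columns.
#'
#' @param cube a [hypercube] aligned with `mask`.
#' @param mask a [root_mask()] or logical matrix of root pixels.
#' @param n_pc number of principal components (default 5).
#' @param als_lambda,als_p,als_iter ALS parameters.
#' @return list: `features` (root pixels x n_pc), `idx` (linear pixel
#'   indices, column-major), `explained_variance`, `rotation`, `center`.
#' @export
prepare_chemometric_features <- function(cube, mask, n_pc = 5,
                                         als_lambda = 1e4, als_p = 1e-3,
                                         als_iter = 10) {
  if (inherits(mask, "root_mask")) mask <- mask$mask
  d <- dim(cube$data)
  stopifnot(all(dim(mask) == d[1:2]))
  if (d[3] < n_pc) stop("cube has fewer bands than requested components")
  idx <- which(mask & cube$valid_mask)
  flat <- matrix(cube$data, d[1] * d[2], d[3])
  X <- flat[idx, , drop = FALSE]
  Xc <- als_correct_rows(X, als_lambda, als_p, als_iter)
  pc <- stats::prcomp(Xc, center = TRUE, scale. = FALSE, rank. = n_pc)
  list(features = pc$x[, seq_len(n_pc), drop = FALSE], idx = idx,
       explained_variance = (pc$sdev^2 / sum(pc$sdev^2))[seq_len(n_pc)],
       rotation = pc$rotation, center = pc$center)
}

## ---- depth-limited CART (Gini) binary decision tree -------------------

# X: n x d numeric, y: integer 0/1. Returns a flat-list tree.
cart_fit <- function(X, y, max_depth = 10, min_split = 10, min_bucket = 5) {
  nodes <- list()
  grow <- function(idx, depth) {
    n <- length(idx)
    p1 <- mean(y[idx])
    node <- list(leaf = TRUE, pred = as.integer(p1 >= 0.5), prob = p1)
    if (depth >= max_depth || n < min_split || p1 == 0 || p1 == 1) {
      nodes[[length(nodes) + 1]] <<- node
      return(length(nodes))
    }
    best <- NULL
    for (j in seq_len(ncol(X))) {
      xs <- X[idx, j]
      o <- order(xs)
      xo <- xs[o]; yo <- y[idx][o]
      c1 <- cumsum(yo); ctot <- c1[n]
      nl <- seq_len(n - 1)
      # candidate splits only between distinct consecutive values
      ok <- xo[-n] < xo[-1]
      if (!any(ok)) next
      p1l <- c1[nl] / nl
      p1r <- (ctot - c1[nl]) / (n - nl)
      gini <- nl * p1l * (1 - p1l) + (n - nl) * p1r * (1 - p1r)
      gini[!ok] <- Inf
      gini[nl < min_bucket | (n - nl) < min_bucket] <- Inf
      b <- which.min(gini)
      if (is.finite(gini[b]) && (is.null(best) || gini[b] < best$gini))
        best <- list(gini = gini[b], var = j,
                     cut = (xo[b] + xo[b + 1]) / 2)
    }
    base_gini <- n * p1 * (1 - p1)
    if (is.null(best) || best$gini >= base_gini - 1e-12) {
      nodes[[length(nodes) + 1]] <<- node
      return(length(nodes))
    }
    go_left <- X[idx, best$var] <= best$cut
    left_id <- grow(idx[go_left], depth + 1)
    right_id <- grow(idx[!go_left], depth + 1)
    nodes[[length(nodes) + 1]] <<- list(leaf = FALSE, var = best$var,
                                        cut = best$cut, left = left_id,
                                        right = right_id)
    length(nodes)
  }
  root <- grow(seq_along(y), 0)
  structure(list(nodes = nodes, root = root), class = "cart_tree")
}

cart_predict <- function(tree, X) {
  n <- nrow(X)
  out <- integer(n)
  for (i in seq_len(n)) {
    id <- tree$root
    repeat {
      nd <- tree$nodes[[id]]
      if (nd$leaf) { out[i] <- nd$pred; break }
      id <- if (X[i, nd$var] <= nd$cut) nd$left else nd$right
    }
  }
  out
}

## ---- one-vs-one ECOC over decision trees ------------------------------

#' Train the radial ECOC classifier
#'
#' Stratified 50/50 train/validation split, then a one-vs-one
#' error-correcting output code ensemble of depth-limited decision trees
#' (Gini splits). Reports the Pearson correlation between labelled and
#' predicted class index on both halves and the validation allocation
#' matrix (percent of each labelled class assigned to each predicted
#' class; columns sum to 100).
#'
#' @param features numeric matrix (pixels x features).
#' @param labels integer class labels (1-based).
#' @param split_seed RNG seed for the stratified split.
#' @param max_depth tree depth limit (default 10).
#' @param min_per_class classes with fewer pixels are dropped with a
#'   warning (default 2).
#' @return object of class `radial_model`: `trees` (pairwise), `classes`,
#'   `train_idx`, `valid_idx`, `r_train`, `r_valid`,
#'   `allocation_matrix` (rows = predicted class, columns = labelled
#'   class, bottom row `pct_total` = share of total pixels per class).
#' @export
train_radial_model <- function(features, labels, split_seed = 1,
                               max_depth = 10, min_per_class = 2) {
  features <- as.matrix(features)
  labels <- as.integer(labels)
  stopifnot(nrow(features) == length(labels))
  tab <- table(labels)
  small <- as.integer(names(tab)[tab < min_per_class])
  if (length(small)) {
    warning("dropping classes with < ", min_per_class, " pixels: ",
            paste(small, collapse = ", "))
    keep <- !(labels %in% small)
    features <- features[keep, , drop = FALSE]
    labels <- labels[keep]
  }
  classes <- sort(unique(labels))
  if (length(classes) < 2) stop("need at least 2 classes")
  set.seed(split_seed)
  train_idx <- unlist(lapply(classes, function(k) {
    idx <- which(labels == k)
    sample(idx, floor(length(idx) / 2))
  }))
  valid_idx <- setdiff(seq_along(labels), train_idx)
  Xtr <- features[train_idx, , drop = FALSE]; ytr <- labels[train_idx]
  pairs <- utils::combn(classes, 2)
  trees <- lapply(seq_len(ncol(pairs)), function(p) {
    a <- pairs[1, p]; b <- pairs[2, p]
    sel <- ytr %in% c(a, b)
    cart_fit(Xtr[sel, , drop = FALSE], as.integer(ytr[sel] == b),
             max_depth = max_depth)
  })
  model <- structure(list(trees = trees, pairs = pairs, classes = classes,
                          train_idx = train_idx, valid_idx = valid_idx,
                          max_depth = max_depth),
                     class = "radial_model")
  pred_tr <- predict_radial(model, Xtr)
  pred_va <- predict_radial(model, features[valid_idx, , drop = FALSE])
  yva <- labels[valid_idx]
  model$r_train <- safe_cor(ytr, pred_tr)
  model$r_valid <- safe_cor(yva, pred_va)
  model$allocation_matrix <- allocation_matrix(yva, pred_va, classes)
  model
}

safe_cor <- function(a, b) {
  if (stats::sd(a) == 0 || stats::sd(b) == 0) return(NA_real_)
  stats::cor(a, b)
}

#' Predict radial classes with a trained model
#'
#' One-vs-one voting; ties go to the lower class index.
#'
#' @param model a `radial_model`.
#' @param features pixels x features matrix.
#' @return integer vector of predicted class labels.
#' @export
predict_radial <- function(model, features) {
  features <- as.matrix(features)
  n <- nrow(features)
  votes <- matrix(0L, n, length(model$classes),
                  dimnames = list(NULL, model$classes))
  for (p in seq_along(model$trees)) {
    a <- model$pairs[1, p]; b <- model$pairs[2, p]
    pr <- cart_predict(model$trees[[p]], features)
    win <- ifelse(pr == 1L, b, a)
    for (k in c(a, b)) {
      sel <- win == k
      votes[sel, as.character(k)] <- votes[sel, as.character(k)] + 1L
    }
  }
  model$classes[max.col(votes, ties.method = "first")]
}

# percent of each labelled class (columns) allocated to each predicted
# class (rows); bottom row = percent of all pixels in each labelled class
allocation_matrix <- function(labelled, predicted, classes) {
  M <- matrix(0, length(classes) + 1, length(classes),
              dimnames = list(c(as.character(classes), "pct_total"),
                              as.character(classes)))
  for (j in seq_along(classes)) {
    sel <- labelled == classes[j]
    if (!any(sel)) next
    cnt <- table(factor(predicted[sel], levels = classes))
    M[seq_along(classes), j] <- 100 * as.numeric(cnt) / sum(sel)
    M["pct_total", j] <- 100 * sum(sel) / length(labelled)
  }
  M
}

## ---- root decay -------------------------------------------------------

#' Select the most decay-discriminative spectral feature
#'
#' Searches transforms (raw reflectance and Savitzky-Golay first
#' derivative) crossed with single wavelengths and wavelength-pair
#' differences, scoring each candidate by the Bhattacharyya distance
#' between the initial and final time-point distributions over root
#' pixels, and keeps the argmax.
#'
#' @param spectra_by_time named list (names = days) of root-pixel
#'   spectra matrices (pixels x bands), ordered by time; the first and
#'   last entries are the initial and final states.
#' @param wavelengths band-centre wavelengths (nm).
#' @param transforms subset of `c("raw", "sg_deriv1")`.
#' @param n_bins histogram bins for the distances.
#' @param max_pairs cap on the number of band pairs searched per
#'   transform (pairs are subsampled on a band grid if needed).
#' @return object of class `decay_feature`: `transform`, `type`
#'   (`"single"` or `"difference"`), `wavelength_nm` (length 1 or 2,
#'   difference = first minus second), `distance`, and `scores`
#'   (data.frame of all scored candidates).
#' @export
select_decay_feature <- function(spectra_by_time, wavelengths,
                                 transforms = c("raw", "sg_deriv1"),
                                 n_bins = 128, max_pairs = 50000) {
  stopifnot(length(spectra_by_time) >= 2)
  A <- spectra_by_time[[1]]
  B <- spectra_by_time[[length(spectra_by_time)]]
  nb <- length(wavelengths)
  stopifnot(ncol(A) == nb, ncol(B) == nb)
  rows <- list()
  best <- list(distance = -Inf)
  for (tr in transforms) {
    TA <- if (tr == "sg_deriv1") sg_first_derivative(A) else A
    TB <- if (tr == "sg_deriv1") sg_first_derivative(B) else B
    for (b in seq_len(nb)) {
      d <- bhattacharyya_distance(TA[, b], TB[, b], n_bins)
      rows[[length(rows) + 1]] <- data.frame(
        transform = tr, type = "single", wl1 = wavelengths[b],
        wl2 = NA_real_, distance = d)
      if (d > best$distance)
        best <- list(transform = tr, type = "single",
                     wavelength_nm = wavelengths[b], distance = d,
                     bands = b)
    }
    stride <- max(1L, ceiling(nb / floor(sqrt(2 * max_pairs))))
    bands <- seq(1L, nb, by = stride)
    for (i in seq_along(bands)) for (j in seq_len(i - 1L)) {
      bi <- bands[i]; bj <- bands[j] # feature = x[bi] - x[bj], bi > bj
      d <- bhattacharyya_distance(TA[, bi] - TA[, bj],
                                  TB[, bi] - TB[, bj], n_bins)
      rows[[length(rows) + 1]] <- data.frame(
        transform = tr, type = "difference", wl1 = wavelengths[bi],
        wl2 = wavelengths[bj], distance = d)
      if (d > best$distance)
        best <- list(transform = tr, type = "difference",
                     wavelength_nm = c(wavelengths[bi], wavelengths[bj]),
                     distance = d, bands = c(bi, bj))
    }
  }
  if (is.na(best$distance) || best$distance <= 0)
    stop("no discriminative feature: initial and final distributions coincide")
  best$scores <- do.call(rbind, rows)
  class(best) <- "decay_feature"
  best
}

#' Evaluate a decay feature on spectra
#'
#' Applies the feature's transform and extracts the single-band value or
#' band-pair difference.
#'
#' @param feature a `decay_feature` (from [select_decay_feature()] or a
#'   generator's designed feature).
#' @param spectra pixels x bands matrix.
#' @return numeric vector, one value per pixel.
#' @export
eval_decay_feature <- function(feature, spectra) {
  X <- if (feature$transform == "sg_deriv1") sg_first_derivative(spectra)
       else spectra
  if (feature$type == "single") X[, feature$bands[1]]
  else X[, feature$bands[1]] - X[, feature$bands[2]]
}

#' Fit the exponential root-decay model
#'
#' Forward direction (default): decay duration as a function of the
#' spectral feature, \eqn{t = a e^{b x}}, fitted by least squares on
#' \eqn{\ln t} versus x. The alternative direction
#' (`direction = "feature_decay"`) fits \eqn{x = c e^{-k t}} by least
#' squares on \eqn{\ln |x|} versus t and reports the decay rate `k`;
#' use it when the feature itself decays exponentially in time.
#'
#' @param feature_values numeric feature value per time point.
#' @param times days after clipping (positive).
#' @param holdout_days time points excluded from fitting and reported as
#'   validation residuals.
#' @param direction `"time_from_feature"` (t = a exp(b x)) or
#'   `"feature_decay"` (x = c exp(-k t)).
#' @param feature optional [select_decay_feature()] result stored with
#'   the model (needed by [map_decay_image()]).
#' @return object of class `decay_model`: `a`, `b` (forward direction)
#'   or `c0`, `k` (alternative), `r_squared` (of the fitted log-linear
#'   regression), `holdout` (data.frame of held-out predictions),
#'   `degenerate` flag.
#' @export
fit_decay_model <- function(feature_values, times, holdout_days = NULL,
                            direction = c("time_from_feature",
                                          "feature_decay"),
                            feature = NULL) {
  direction <- match.arg(direction)
  stopifnot(length(feature_values) == length(times))
  if (any(times <= 0)) stop("times must be positive")
  hold <- times %in% (holdout_days %||% numeric(0))
  x <- feature_values[!hold]; t_ <- times[!hold]
  if (length(t_) < 3) stop("need at least 3 training time points")
  model <- list(direction = direction, times = times,
                holdout_days = holdout_days, feature = feature,
                degenerate = FALSE)
  if (direction == "time_from_feature") {
    if (stats::sd(x) == 0) {
      model$degenerate <- TRUE
      model$a <- NA_real_; model$b <- NA_real_; model$r_squared <- NA_real_
      class(model) <- "decay_model"
      return(model)
    }
    fit <- stats::lm(log(t_) ~ x)
    model$a <- exp(unname(stats::coef(fit)[1]))
    model$b <- unname(stats::coef(fit)[2])
    model$r_squared <- lm_r_squared(fit)
    if (any(hold)) {
      pred <- pmax(model$a * exp(model$b * feature_values[hold]), 0)
      model$holdout <- data.frame(day = times[hold], predicted = pred,
                                  residual = pred - times[hold])
    }
  } else {
    if (any(x == 0) || stats::sd(log(abs(x))) == 0) {
      model$degenerate <- TRUE
      model$c0 <- NA_real_; model$k <- NA_real_; model$r_squared <- NA_real_
      class(model) <- "decay_model"
      return(model)
    }
    sgn <- sign(x[1])
    fit <- stats::lm(log(abs(x)) ~ t_)
    model$c0 <- sgn * exp(unname(stats::coef(fit)[1]))
    model$k <- -unname(stats::coef(fit)[2])
    model$r_squared <- lm_r_squared(fit)
    if (any(hold)) {
      pred <- model$c0 * exp(-model$k * times[hold])
      model$holdout <- data.frame(day = times[hold],
                                  predicted_feature = pred,
                                  residual = pred - feature_values[hold])
    }
  }
  class(model) <- "decay_model"
  model
}

# r^2 without summary.lm's perfect-fit warning
lm_r_squared <- function(fit) {
  y <- fit$model[[1]]
  tss <- sum((y - mean(y))^2)
  if (tss == 0) return(NA_real_)
  1 - sum(stats::residuals(fit)^2) / tss
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Predict decay duration from feature values
#'
#' @param model a fitted `decay_model` (forward direction).
#' @param x feature values.
#' @return predicted days, clipped at 0.
#' @export
predict_decay_time <- function(model, x) {
  stopifnot(inherits(model, "decay_model"),
            model$direction == "time_from_feature", !model$degenerate)
  pmax(model$a * exp(model$b * x), 0)
}

#' Map predicted decay duration onto root pixels
#'
#' Evaluates the model's spectral feature on every root-pixel spectrum of
#' the cube and writes the predicted decay day as a float image;
#' background pixels are NA.
#'
#' @param cube a [hypercube] (reflectance; the feature's transform is
#'   applied internally).
#' @param mask a [root_mask()] or logical matrix.
#' @param model a forward-direction `decay_model` carrying its `feature`.
#' @return numeric matrix of predicted days (NA outside the root).
#' @export
map_decay_image <- function(cube, mask, model) {
  stopifnot(inherits(model, "decay_model"))
  if (is.null(model$feature)) stop("model carries no spectral feature")
  if (inherits(mask, "root_mask")) mask <- mask$mask
  d <- dim(cube$data)
  feat <- model$feature
  wl_need <- feat$wavelength_nm
  tol <- max(diff(cube$wavelengths)) / 2
  bands <- vapply(wl_need, function(w) {
    b <- which.min(abs(cube$wavelengths - w))
    if (abs(cube$wavelengths[b] - w) > tol)
      stop(sprintf("wavelength %.1f nm missing from cube", w))
    b
  }, integer(1))
  feat$bands <- bands
  idx <- which(mask & cube$valid_mask)
  flat <- matrix(cube$data, d[1] * d[2], d[3])
  x <- eval_decay_feature(feat, flat[idx, , drop = FALSE])
  out <- matrix(NA_real_, d[1], d[2])
  out[idx] <- predict_decay_time(model, x)
  out
}
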