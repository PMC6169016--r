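# Independent oracles and shared fixtures. Oracles deliberately use
# different computational routes than the package code they check.

## ---- cached CI scene (built once per test run) ------------------------
.fixture_env <- new.env(parent = emptyenv())

ci_scene <- function(seed = 1) {
  key <- paste0("scene_", seed)
  if (is.null(.fixture_env[[key]]))
    .fixture_env[[key]] <- generate_scene(scene_params("ci"), seed)
  .fixture_env[[key]]
}

ci_pretreated <- function() {
  if (is.null(.fixture_env$pre)) {
    s <- ci_scene()
    cube <- mask_dead_pixels(trim_bands(normalize_cube(s$raw, s$cal)),
                             abs_threshold = 0.3)
    .fixture_env$cube <- cube
    .fixture_env$rois <- truth_rois(s)
    .fixture_env$pre <- apply_pretreatment(
      cube, pretreatment_spec("log_inv", "als", "none"))
  }
  list(scene = ci_scene(), cube = .fixture_env$cube,
       rois = .fixture_env$rois, pre = .fixture_env$pre)
}

## ---- small cube builders ----------------------------------------------
toy_cube <- function(nr = 6, nc = 5, nb = 8, seed = 42,
                     wl = seq(1000, 1700, length.out = nb)) {
  set.seed(seed)
  hypercube(array(runif(nr * nc * nb), c(nr, nc, nb)), wl)
}

# ROI-contrast fixture with strong multiplicative scatter: raw ROI
# histograms overlap, log + ALS isolates the absorption dip.
scatter_fixture <- function(seed = 7, nr = 48, nc = 48, nb = 40) {
  set.seed(seed)
  wl <- seq(1000, 1700, length.out = nb)
  dip <- exp(-0.5 * ((wl - 1450) / 40)^2)
  root_rows <- 21:28
  scatter <- exp(matrix(rnorm(nr * nc, 0, 0.25), nr, nc))
  arr <- array(0, c(nr, nc, nb))
  base_soil <- 0.45 + 0.05 * (wl - 1000) / 700
  base_root <- 0.50 - 0.25 * dip
  for (b in seq_len(nb)) {
    plane <- matrix(base_soil[b], nr, nc)
    plane[root_rows, ] <- base_root[b]
    arr[, , b] <- plane * scatter + rnorm(nr * nc, 0, 0.02)
  }
  rois <- roi_set(as.matrix(expand.grid(root_rows, seq(2, nc, by = 2))),
                  as.matrix(expand.grid(c(4:11), seq(2, nc, by = 2))))
  list(cube = hypercube(arr, wl), rois = rois)
}

line_mask <- function(angle_deg, len = 200, width = 5, n = 260) {
  th <- angle_deg * pi / 180
  m <- matrix(FALSE, n, n)
  ctr <- n / 2
  h <- width %/% 2
  for (t in seq(-len / 2, len / 2, by = 0.25)) {
    r <- round(ctr + t * cos(th)); c <- round(ctr + t * sin(th))
    for (dr in -h:h) for (dc in -h:h)
      if (dr^2 + dc^2 <= (width / 2)^2) m[r + dr, c + dc] <- TRUE
  }
  m
}

## ---- oracles -----------------------------------------------------------

# dense penalized-least-squares ALS reference (explicit matrix algebra)
oracle_als_dense <- function(y, lam = 1e4, p = 1e-3, n_iter = 10) {
  n <- length(y)
  D <- diff(diag(n), differences = 2)
  P <- lam * t(D) %*% D
  w <- rep(1, n)
  z <- y
  for (i in seq_len(n_iter)) {
    z <- solve(diag(w) + P, w * y)
    w <- ifelse(y > z, p, 1 - p)
  }
  z
}

# closed-form Bhattacharyya distance between two Gaussians
oracle_bhatt_gauss <- function(mu1, s1, mu2, s2) {
  0.25 * log(0.25 * (s1^2 / s2^2 + s2^2 / s1^2 + 2)) +
    0.25 * (mu1 - mu2)^2 / (s1^2 + s2^2)
}

# brute-force 2-class Otsu on a sample: maximize between-class variance
# over every unique-value threshold
oracle_otsu2 <- function(values) {
  u <- sort(unique(values))
  best <- NULL; best_s <- -Inf
  for (t in u[-length(u)]) {
    lo <- values[values <= t]; hi <- values[values > t]
    s <- length(lo) * mean(lo)^2 + length(hi) * mean(hi)^2
    if (s > best_s) { best_s <- s; best <- t }
  }
  best
}

# exhaustive minimum-SSE 2-partition of a small point set
oracle_min_sse_2part <- function(X) {
  X <- as.matrix(X)
  n <- nrow(X)
  best <- Inf
  for (code in 1:(2^(n - 1) - 1)) {
    g <- as.logical(bitwAnd(code, 2^(0:(n - 1))))
    if (!any(g) || all(g)) next
    sse <- sum(sweep(X[g, , drop = FALSE], 2,
                     colMeans(X[g, , drop = FALSE]))^2) +
      sum(sweep(X[!g, , drop = FALSE], 2,
                colMeans(X[!g, , drop = FALSE]))^2)
    best <- min(best, sse)
  }
  best
}

kmeans_sse <- function(X, assign) {
  X <- as.matrix(X)
  sum(vapply(unique(assign), function(k) {
    sum(sweep(X[assign == k, , drop = FALSE], 2,
              colMeans(X[assign == k, , drop = FALSE]))^2)
  }, numeric(1)))
}

# brute-force nearest Euclidean distance (R route)
oracle_nearest <- function(query, ref) {
  apply(query, 1, function(q)
    sqrt(min((ref[, 1] - q[1])^2 + (ref[, 2] - q[2])^2)))
}

binary_skew_formula <- function(p) (1 - 2 * p) / sqrt(p * (1 - p))
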