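test_that("radial classes follow skeleton distance with left-closed bins", {
  # 1-px-wide root: every pixel is its own skeleton, all class 1
  m <- matrix(FALSE, 20, 60); m[10, 5:55] <- TRUE
  lab <- label_radial_classes(root_mask(m, 0.1))
  expect_true(all(lab[m] == 1))
  expect_true(all(is.na(lab[!m])))
  # 3-px-wide horizontal root: centre row class 1, flanking rows class 2
  # (thinning erodes a couple of pixels at the bar ends, so test the
  # interior away from the tips)
  m3 <- matrix(FALSE, 21, 60); m3[9:11, 5:55] <- TRUE
  lab3 <- label_radial_classes(root_mask(m3, 0.1))
  expect_true(all(lab3[10, 8:52] == 1))
  expect_true(all(lab3[c(9, 11), 8:52] == 2))
  # disk of radius 15 px (1.5 mm): rim pixels beyond 1.3 mm exist
  dm <- matrix(FALSE, 41, 41)
  dm <- rhizospec:::stamp_disk(dm, 21, 21, 15)
  labd <- label_radial_classes(root_mask(dm, 0.1))
  expect_true(any(labd[dm] == 8))
  expect_true(any(labd[dm] == 1))
  # empty mask
  expect_true(all(is.na(label_radial_classes(root_mask(matrix(FALSE, 4, 4))))))
})

test_that("radial class is non-decreasing in exact distance to skeleton", {
  set.seed(40)
  m <- matrix(FALSE, 64, 64)
  m[20:28, 5:60] <- TRUE # 9-px-wide bar
  m <- rhizospec:::stamp_disk(m, 45, 30, 11)
  sk <- skeletonize(m)
  q <- which(m, arr.ind = TRUE)
  d_pkg <- rhizospec:::nearest_dist_(q, which(sk, arr.ind = TRUE))
  d_oracle <- oracle_nearest(q, which(sk, arr.ind = TRUE))
  expect_equal(d_pkg, d_oracle, tolerance = 1e-12)
  lab <- label_radial_classes(root_mask(m, 0.1))
  cls <- lab[m]
  o <- order(d_oracle)
  expect_true(all(diff(cls[o]) >= 0))
})

test_that("chemometric features: rank-1 spectra, row counts, PCA oracle", {
  set.seed(41)
  nb <- 12
  wl <- seq(1000, 1700, length.out = nb)
  shape <- 0.5 + 0.3 * exp(-0.5 * ((wl - 1450) / 60)^2)
  m <- matrix(FALSE, 15, 15); m[4:12, 4:12] <- TRUE
  scale_px <- matrix(runif(225, 0.5, 1.5), 15, 15)
  arr <- array(0, c(15, 15, nb))
  for (b in seq_len(nb)) arr[, , b] <- scale_px * shape[b]
  cube <- hypercube(arr, wl)
  f <- prepare_chemometric_features(cube, m, n_pc = 5)
  expect_equal(nrow(f$features), sum(m))
  expect_gt(f$explained_variance[1], 0.999)
  # scores match dense eigendecomposition up to sign
  set.seed(42)
  arr2 <- array(rnorm(15 * 15 * nb), c(15, 15, nb))
  cube2 <- hypercube(arr2, wl)
  f2 <- prepare_chemometric_features(cube2, m, n_pc = 5)
  X <- t(apply(arr2, 3, function(p) p[m]))
  X <- t(X) # pixels x bands
  Xc <- rhizospec:::als_correct_rows(X)
  Xc <- sweep(Xc, 2, colMeans(Xc))
  eig <- eigen(crossprod(Xc) / (nrow(Xc) - 1), symmetric = TRUE)
  oracle <- Xc %*% eig$vectors[, 1:5]
  for (j in 1:5) {
    d <- min(max(abs(f2$features[, j] - oracle[, j])),
             max(abs(f2$features[, j] + oracle[, j])))
    expect_lt(d, 1e-8)
  }
  expect_error(prepare_chemometric_features(
    hypercube(arr2[, , 1:3], wl[1:3]), m), "fewer bands")
})

test_that("ECOC decision-tree model: separation, nulls, allocation sums", {
  set.seed(43)
  # perfectly separated classes
  n <- 800
  y <- sample(1:4, n, TRUE)
  X <- cbind(y * 10 + rnorm(n, 0, 0.1), matrix(rnorm(n * 4), n, 4))
  m <- train_radial_model(X, y, split_seed = 1)
  expect_equal(m$r_train, 1.0)
  expect_gt(m$r_valid, 0.999)
  # allocation columns sum to 100 (+- rounding slack)
  cs <- colSums(m$allocation_matrix[seq_along(m$classes), ])
  expect_true(all(abs(cs - 100) < 0.2))
  expect_equal(sum(m$allocation_matrix["pct_total", ]), 100, tolerance = 0.2)
  # permuted labels carry no signal
  set.seed(44)
  n2 <- 10000
  X2 <- matrix(rnorm(n2 * 5), n2, 5)
  y2 <- sample(rep(1:8, length.out = n2))
  m2 <- train_radial_model(X2, y2, split_seed = 2)
  expect_lt(abs(m2$r_valid), 0.1)
  # class with < 2 pixels is dropped with a warning
  y3 <- c(rep(1, 50), rep(2, 50), 3)
  X3 <- cbind(c(rnorm(50), rnorm(50, 5), 99), rnorm(101))
  expect_warning(m3 <- train_radial_model(X3, y3, split_seed = 3),
                 "dropping")
  expect_equal(m3$classes, c(1, 2))
})

test_that("ECOC separates synthetic two-tissue roots (stele vs cortex)", {
  fx <- ci_pretreated()
  s <- fx$scene
  cube <- trim_bands(normalize_cube(s$raw, s$cal))
  feats <- prepare_chemometric_features(cube, root_mask(s$mask, 0.1))
  tis <- s$tissue[feats$idx]
  sel <- tis > 0
  m <- train_radial_model(feats$features[sel, ],
                          ifelse(tis[sel] == 2, 2, 1), split_seed = 7)
  expect_gte(m$r_valid, 0.8)
})

test_that("decay-feature selection finds the designed band pair", {
  set.seed(45)
  nb <- 20
  wl <- seq(1000, 1700, length.out = nb)
  ba <- 6; bb <- 14
  # per-pixel multiplicative scatter swamps single bands; band-to-band
  # noise keeps incidental pairs overlapping; only the designed pair,
  # where the time signal enters with opposite signs, separates cleanly
  mk <- function(delta, n = 400) {
    scatter <- runif(n, 0.7, 1.3)
    X <- outer(scatter, rep(0.5, nb)) + matrix(rnorm(n * nb, 0, 0.04), n, nb)
    X[, ba] <- X[, ba] + delta
    X[, bb] <- X[, bb] - delta
    X
  }
  series <- list(`0` = mk(0.02), `50` = mk(0.10))
  feat <- select_decay_feature(series, wl, transforms = "raw")
  expect_equal(feat$type, "difference")
  expect_setequal(feat$bands, c(ba, bb))
  # identical initial and final distributions: hard error
  same <- mk(0.05)
  expect_error(select_decay_feature(list(a = same, b = same), wl,
                                    transforms = "raw"),
               "no discriminative feature")
})

test_that("exponential decay fit: exact recovery and log-linear closed form", {
  x <- seq(-1, 1, length.out = 6)
  t_ <- 5 * exp(2 * x)
  m <- fit_decay_model(x, t_)
  expect_equal(m$a, 5, tolerance = 1e-9)
  expect_equal(m$b, 2, tolerance = 1e-9)
  expect_equal(m$r_squared, 1, tolerance = 1e-12)
  # closed-form slope/intercept of the log-linear regression
  slope <- cov(x, log(t_)) / var(x)
  intercept <- mean(log(t_)) - slope * mean(x)
  expect_equal(m$b, slope, tolerance = 1e-10)
  expect_equal(m$a, exp(intercept), tolerance = 1e-10)
  # degenerate: constant feature
  md <- fit_decay_model(rep(0.3, 6), t_)
  expect_true(md$degenerate)
  expect_error(fit_decay_model(x, c(-1, t_[-1])), "positive")
  # holdout points are excluded from the fit and reported
  mh <- fit_decay_model(x, t_, holdout_days = t_[c(2, 5)])
  expect_equal(nrow(mh$holdout), 2)
  expect_equal(mh$b, 2, tolerance = 1e-9)
})

test_that("decay slope is recovered under noise at the sampling days", {
  # Monte-Carlo: t = a exp(b x) with 5% noise on t, 6 sampling days
  days <- c(14, 28, 47, 94, 101, 201)
  b_true <- 2
  x <- log(days / 5) / b_true # so that 5 * exp(b x) = days exactly
  set.seed(46)
  rel_err <- vapply(1:200, function(i) {
    t_noisy <- days * exp(rnorm(6, 0, 0.05))
    m <- fit_decay_model(x, t_noisy)
    abs(m$b - b_true) / b_true
  }, numeric(1))
  expect_lt(median(rel_err), 0.10)
})

test_that("decay map inverts the model on root pixels only", {
  nb <- 16
  wl <- seq(1000, 1700, length.out = nb)
  ba <- which.min(abs(wl - 1650)); bb <- which.min(abs(wl - 1450))
  feat <- structure(list(transform = "raw", type = "difference",
                         wavelength_nm = c(wl[ba], wl[bb]),
                         bands = c(ba, bb), distance = 1),
                    class = "decay_feature")
  x <- seq(0.1, 0.6, length.out = 6)
  t_ <- 4 * exp(3 * x)
  model <- fit_decay_model(x, t_, feature = feat)
  # uniform root spectra whose feature value equals the day-28-like point
  x28 <- x[3]
  spec <- rep(0.5, nb); spec[ba] <- 0.5 + x28; spec[bb] <- 0.5
  m <- matrix(FALSE, 10, 10); m[3:7, 3:7] <- TRUE
  arr <- array(rep(spec, each = 100), c(10, 10, nb))
  cube <- hypercube(arr, wl)
  img <- map_decay_image(cube, m, model)
  expect_equal(unique(img[m]), t_[3], tolerance = 1e-9)
  expect_true(all(is.na(img[!m])))
  # radial gradient in the feature produces a monotone day gradient
  dm <- matrix(FALSE, 31, 31); dm <- rhizospec:::stamp_disk(dm, 16, 16, 12)
  dist <- matrix(0, 31, 31)
  for (r in 1:31) for (c in 1:31) dist[r, c] <- sqrt((r - 16)^2 + (c - 16)^2)
  arr2 <- array(rep(0.5, 31 * 31 * nb), c(31, 31, nb))
  arr2[, , ba] <- 0.5 + 0.1 + 0.03 * dist # deeper feature toward rim
  cube2 <- hypercube(arr2, wl)
  img2 <- map_decay_image(cube2, dm, model)
  vals <- img2[dm]; dd <- dist[dm]
  expect_gt(cor(vals, dd, method = "spearman"), 0.999)
  # wavelengths missing from the cube are an error
  cube3 <- hypercube(arr2[, , 1:4], wl[1:4])
  expect_error(map_decay_image(cube3, dm, model), "missing")
})
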