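test_that("Bhattacharyya distance: anchors and Gaussian closed form", {
  set.seed(12)
  x <- rnorm(2000)
  expect_equal(bhattacharyya_distance(x, x), 0)
  expect_equal(bhattacharyya_distance(1:100, 201:300), Inf)
  a <- rnorm(1e5, 0, 1); b <- rnorm(1e5, 1, 1)
  expect_equal(bhattacharyya_distance(a, b), oracle_bhatt_gauss(0, 1, 1, 1),
               tolerance = 0.02 / 0.125)
  # zero-width pooled range
  expect_equal(bhattacharyya_distance(rep(2, 5), rep(2, 7)), 0)
})

test_that("Bhattacharyya distance is symmetric, non-negative and monotone
           in mean separation", {
  set.seed(13)
  a <- rnorm(5000)
  ds <- vapply(c(0.5, 1, 2, 3), function(mu) {
    b <- rnorm(5000, mu)
    d1 <- bhattacharyya_distance(a, b)
    expect_equal(d1, bhattacharyya_distance(b, a))
    expect_gte(d1, 0)
    d1
  }, numeric(1))
  expect_true(all(diff(ds) > 0))
})

test_that("non-Gaussian indicators: Gaussian null and Bernoulli skewness", {
  set.seed(14)
  g <- rnorm(1e5)
  sc <- non_gaussian_scores(g)
  expect_lt(abs(sc["skewness"]), 0.05)
  expect_lt(abs(sc["kurtosis"]), 0.1)
  expect_lt(abs(sc["negentropy"]), 0.05)
  expect_lt(abs(sc["kl_divergence"]), 0.05)
  bern <- rbinom(2e5, 1, 0.1)
  expect_equal(unname(non_gaussian_scores(bern)["skewness"]),
               (1 - 0.2) / sqrt(0.1 * 0.9), tolerance = 0.05 / 2.667)
  # scale invariance of everything computed on standardized/histogram form
  x <- rexp(5000)
  s1 <- non_gaussian_scores(x); s2 <- non_gaussian_scores(2 * x)
  expect_equal(s1[c("skewness", "kurtosis", "entropy", "negentropy",
                    "kl_divergence")],
               s2[c("skewness", "kurtosis", "entropy", "negentropy",
                    "kl_divergence")], tolerance = 1e-10)
  expect_error(non_gaussian_scores(rep(1, 100)), "variance")
})

test_that("rank_pretreatments ranks a perfectly separating spec first", {
  set.seed(15)
  nb <- 6
  wl <- seq(1000, 1700, length.out = nb)
  mk <- function(root_mu, soil_mu, sd) {
    arr <- array(rnorm(20 * 20 * nb, soil_mu, sd), c(20, 20, nb))
    arr[8:12, , ] <- rnorm(5 * 20 * nb, root_mu, sd)
    hypercube(arr, wl)
  }
  rois <- roi_set(as.matrix(expand.grid(8:12, 1:20)),
                  as.matrix(expand.grid(1:5, 1:20)))
  cubes <- list(separated = mk(10, 0, 0.1), overlap1 = mk(0.3, 0, 1),
                overlap2 = mk(0.1, 0, 1))
  rk <- rank_pretreatments(cubes, rois)
  tab <- rk$table
  expect_equal(tab$rank_single[tab$spec == "separated"], 1)
  expect_equal(tab$rank_diff[tab$spec == "separated"], 1)
  expect_true("separated" %in% rk$candidates)
  # identical cubes tie at midrank
  rk2 <- rank_pretreatments(list(a = cubes$overlap1, b = cubes$overlap1),
                            rois)
  expect_equal(rk2$table$rank_single, c(1.5, 1.5))
  # formatted table mirrors "distance (rank)"
  fmt <- format_ranking_table(rk)
  expect_match(fmt$bhattacharyya_single[1], "^[0-9.]+|Inf \\([0-9]+\\)$")
})

test_that("select_top_bands uses frequency, then mean rank, then wavelength", {
  s1 <- c(5, 4, 3, 2, 1, 0)   # nominates 1,2,3 at k=3
  s2 <- c(5, 4, 0, 3, 1, 0)   # nominates 1,2,4
  s3 <- c(5, 0, 4, 3, 1, 0)   # nominates 1,3,4
  out <- select_top_bands(list(s1, s2, s3), k = 3)
  expect_equal(out[1], 1) # nominated by every criterion
  # bands 2,3,4 all have frequency 2; mean ranks: b2 = 2, b3 = 2.5, b4 = 2.5
  expect_equal(out[2], 2)
  expect_equal(out[3], 3) # tie vs band 4 broken by lower band index
  expect_warning(out2 <- select_top_bands(list(c(1, 0)), k = 3),
                 "nominated")
  expect_equal(out2, c(1L, 2L))
})

test_that("selected bands concentrate in the water absorption region", {
  fx <- ci_pretreated()
  sc_single <- band_scores_roi(fx$pre, fx$rois)
  sm <- rhizospec:::nongauss_band_scores(fx$pre)
  oriented <- cbind(abs(sm[, "skewness"]), abs(sm[, "kurtosis"]),
                    -sm[, "entropy"], sm[, "negentropy"], sm[, "snr"],
                    sm[, "kl_divergence"])
  z <- scale(oriented); z[!is.finite(z)] <- 0
  bands <- select_top_bands(list(single = sc_single, ng = rowMeans(z)), 10)
  wl <- fx$pre$wavelengths[bands]
  expect_gte(sum(wl >= 1400 & wl <= 1500), 5)
})

test_that("reduce_dims identities and PCA oracle", {
  cube <- toy_cube(12, 10, 8, wl = seq(1000, 1700, length.out = 8))
  expect_equal(reduce_dims(cube, c(3, 3, 3), "mean10"), cube$data[, , 3])
  expect_equal(reduce_dims(cube, 5, "best1"), cube$data[, , 5])
  st <- reduce_dims(cube, c(2, 4), "stack10")
  expect_equal(dim(st), c(12, 10, 2))
  # rank-1 cube: pca1 reproduces the spatial pattern up to sign/scale
  set.seed(16)
  pattern <- matrix(rnorm(12 * 10), 12, 10)
  load <- runif(8, 0.5, 1)
  r1 <- hypercube(outer(pattern, load), seq(1000, 1700, length.out = 8))
  img <- reduce_dims(r1, mode = "pca1")
  cp <- cor(as.vector(img), as.vector(pattern))
  expect_gt(abs(cp), 0.999999)
  # pca scores match a dense eigendecomposition on a 20x20x10 cube
  set.seed(17)
  cube2 <- hypercube(array(rnorm(20 * 20 * 10), c(20, 20, 10)),
                     seq(1000, 1700, length.out = 10))
  sc <- rhizospec:::cube_pca_scores(cube2, 10)
  X <- matrix(cube2$data, 400, 10)
  Xc <- sweep(X, 2, colMeans(X))
  eig <- eigen(crossprod(Xc) / (400 - 1), symmetric = TRUE)
  oracle_scores <- Xc %*% eig$vectors
  for (j in 1:10) {
    d <- min(max(abs(sc$scores[, j] - oracle_scores[, j])),
             max(abs(sc$scores[, j] + oracle_scores[, j])))
    expect_lt(d, 1e-8)
  }
  expect_error(reduce_dims(cube, 1, "pca_k", k = 99), "fewer bands")
})
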