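test_that("the factorial bank enumerates the 16 table rows in order", {
  specs <- enumerate_pretreatments()
  expect_length(specs, 16)
  expect_equal(length(unique(vapply(specs, format, character(1)))), 16)
  row <- function(i) unlist(specs[[i]][c("linearization", "detrend",
                                         "multiplicative")])
  expect_equal(unname(row(1)), c("none", "none", "none"))
  expect_equal(unname(row(12)), c("log_inv", "als", "none"))
  expect_equal(unname(row(16)), c("log_inv", "als", "snv"))
  # linearization is slowest-varying
  lins <- vapply(specs, `[[`, character(1), "linearization")
  expect_equal(unname(lins), rep(c("none", "log_inv"), each = 8))
})

test_that("log linearization maps known reflectances to absorbance", {
  out <- log_linearize(c(1, 0.1, 0.5))
  expect_equal(as.vector(out), c(0, 1, log10(2)), tolerance = 1e-12)
  flo <- log_linearize(c(-0.2, 0, 0.5))
  expect_equal(attr(flo, "n_floored"), 2)
  expect_true(all(is.finite(flo)))
})

test_that("polynomial de-trending is an exact residual projector", {
  wl <- seq(1000, 1700, length.out = 20)
  quad <- 2e-6 * wl^2 - 0.003 * wl + 1.4
  expect_lt(max(abs(detrend_poly(quad, wl))), 1e-9)
  set.seed(5)
  x <- rnorm(20)
  # adding any quadratic leaves the residual unchanged (idempotence)
  expect_equal(detrend_poly(x + quad, wl), detrend_poly(x, wl),
               tolerance = 1e-9)
  # 5-point toy vector equals the explicit normal-equations solution
  wl5 <- c(1000, 1100, 1250, 1400, 1700)
  y5 <- c(0.3, 0.5, 0.2, 0.8, 0.4)
  X <- cbind(1, wl5, wl5^2)
  resid_oracle <- y5 - X %*% solve(t(X) %*% X, t(X) %*% y5)
  expect_equal(detrend_poly(y5, wl5), as.vector(resid_oracle),
               tolerance = 1e-8)
})

test_that("Savitzky-Golay first derivative matches analytic derivatives", {
  n <- 30
  i <- seq_len(n)
  expect_equal(sg_first_derivative(0.05 * i + 2), rep(0.05, n),
               tolerance = 1e-10)
  expect_equal(sg_first_derivative(rep(3, n)), rep(0, n), tolerance = 1e-12)
  quad <- 0.01 * i^2 - 0.3 * i
  d <- sg_first_derivative(quad)
  interior <- 4:(n - 3)
  expect_equal(d[interior], (0.02 * i - 0.3)[interior], tolerance = 1e-9)
  expect_error(sg_first_derivative(quad, window = 6), "odd")
  expect_error(sg_first_derivative(quad, window = 3, polyorder = 3),
               "polyorder")
})

test_that("ALS baseline: anchors, bounded baseline, peak recovery", {
  const <- rep(2.5, 60)
  r <- als_baseline(const)
  expect_equal(r$baseline, const, tolerance = 1e-6)
  expect_equal(r$corrected, rep(0, 60), tolerance = 1e-6)
  # smooth slope + one positive Gaussian peak
  x <- seq_len(120)
  peak <- 0.8 * exp(-0.5 * ((x - 60) / 6)^2)
  y <- 0.002 * x + 0.5 + peak
  r2 <- als_baseline(y)
  rec <- max(r2$corrected)
  expect_lt(abs(rec - 0.8) / 0.8, 0.10)
  # a roughness-penalized baseline may undershoot the data slightly at
  # curvature changes; bounded within 1% of the data amplitude
  slack <- 0.01 * diff(range(y))
  expect_true(all(r2$baseline >= min(y) - slack &
                    r2$baseline <= max(y) + slack))
})

test_that("ALS iterative solvers agree with the dense reference", {
  set.seed(9)
  y <- cumsum(rnorm(50, 0, 0.1)) + exp(-0.5 * ((1:50 - 25) / 3)^2)
  dense <- oracle_als_dense(y)
  sparse <- als_baseline(y)$baseline
  expect_equal(sparse, dense, tolerance = 1e-6)
  # batched banded C++ route agrees too
  Y <- rbind(y, y * 0.7 + 0.1)
  corr <- rhizospec:::als_correct_rows(Y)
  expect_equal(corr[1, ], y - dense, tolerance = 1e-6)
  expect_equal(corr[2, ],
               (y * 0.7 + 0.1) - oracle_als_dense(y * 0.7 + 0.1),
               tolerance = 1e-6)
})

test_that("SNV standardizes with population moments", {
  expect_equal(snv(c(0, 2))[1:2], c(-1, 1))
  set.seed(4)
  x <- rnorm(64, 5, 2)
  expect_equal(snv(3 * x + 7)[seq_along(x)], snv(x)[seq_along(x)],
               tolerance = 1e-10)
  out <- snv(x)
  expect_lt(abs(mean(out)), 1e-10)
  expect_equal(mean(out^2), 1, tolerance = 1e-10)
  z <- snv(rep(1, 10))
  expect_equal(as.vector(z)[1:10], rep(0, 10))
  expect_equal(attr(z, "n_degenerate"), 1)
})

test_that("apply_pretreatment composes correctly and respects the mask", {
  cube <- toy_cube(10, 8, 20, wl = seq(1000, 1700, length.out = 20))
  cube$valid_mask[3, 4] <- FALSE
  cube$data[3, 4, ] <- 0
  ident <- apply_pretreatment(cube, pretreatment_spec())
  expect_equal(ident$data, cube$data)
  # SNV idempotence through the cube path
  s1 <- apply_pretreatment(cube, pretreatment_spec(multiplicative = "snv"))
  s2 <- apply_pretreatment(s1, pretreatment_spec(multiplicative = "snv"))
  expect_equal(s1$data, s2$data, tolerance = 1e-10)
  # masked pixels stay exactly zero under every spec
  for (spec in enumerate_pretreatments()) {
    out <- apply_pretreatment(cube, spec)
    expect_true(all(out$data[3, 4, ] == 0), label = format(spec))
  }
})

test_that("all 16 specs produce finite output on a 64x64x50 cube", {
  set.seed(21)
  cube <- hypercube(array(runif(64 * 64 * 50, 0.05, 0.9), c(64, 64, 50)),
                    seq(1000, 1700, length.out = 50))
  for (spec in enumerate_pretreatments()) {
    out <- apply_pretreatment(cube, spec)
    expect_true(all(is.finite(out$data)), label = format(spec))
  }
})

test_that("log + ALS raises ROI separability on a scatter-dominated scene", {
  fx <- scatter_fixture()
  d_raw <- max(band_scores_roi(fx$cube, fx$rois))
  pre <- apply_pretreatment(fx$cube, pretreatment_spec("log_inv", "als", "none"))
  d_pre <- max(band_scores_roi(pre, fx$rois))
  expect_true(is.finite(d_raw))
  expect_gt(d_pre, d_raw)
})

test_that("MSC removes multiplicative scatter against a reference", {
  set.seed(2)
  ref <- 0.5 + 0.3 * sin(seq(0, 3, length.out = 40))
  X <- t(vapply(1:8, function(i) runif(1, 0.6, 1.4) * ref + runif(1, -0.1, 0.1),
                numeric(40)))
  out <- msc(X, ref)
  expect_lt(max(abs(sweep(out, 2, ref))), 1e-8)
})
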