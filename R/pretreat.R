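#' Spectral pre-treatment specification
#'
#' One cell of the factorial pre-treatment bank: a linearization, a
#' de-trending method and a multiplicative correction, applied per pixel
#' along the spectral axis in that order.
#'
#' @param linearization `"none"` or `"log_inv"` (absorbance, log10(1/R)).
#' @param detrend `"none"`, `"poly2"` (2nd-order polynomial centring),
#'   `"sg_deriv1"` (Savitzky-Golay 1st derivative) or `"als"`
#'   (asymmetric least squares baseline correction).
#' @param multiplicative `"none"` or `"snv"` (standard normal variate).
#' @param params named list of method parameters: `als_lambda`, `als_p`,
#'   `als_iter`, `sg_window`, `sg_polyorder`, `poly_degree`.
#' @return An object of class `pretreatment_spec`.
#' @export
pretreatment_spec <- function(linearization = "none", detrend = "none",
                              multiplicative = "none", params = list()) {
  linearization <- match.arg(linearization, c("none", "log_inv"))
  detrend <- match.arg(detrend, c("none", "poly2", "sg_deriv1", "als"))
  multiplicative <- match.arg(multiplicative, c("none", "snv"))
  defaults <- list(als_lambda = 1e4, als_p = 1e-3, als_iter = 10,
                   sg_window = 7, sg_polyorder = 2, poly_degree = 2)
  params <- utils::modifyList(defaults, params)
  structure(list(linearization = linearization, detrend = detrend,
                 multiplicative = multiplicative, params = params),
            class = "pretreatment_spec")
}

#' @export
format.pretreatment_spec <- function(x, ...) {
  paste(x$linearization, x$detrend, x$multiplicative, sep = "+")
}

#' @export
print.pretreatment_spec <- function(x, ...) {
  cat("<pretreatment_spec>", format(x), "\n"); invisible(x)
}

#' Enumerate the factorial pre-treatment bank
#'
#' All 16 combinations of linearization (none, log 1/R) x de-trending
#' (none, 2nd-order polynomial, Savitzky-Golay 1st derivative, ALS) x
#' multiplicative correction (none, SNV), in the canonical table order:
#' linearization slowest-varying, then multiplicative, then de-trending.
#' Row 1 is (none, none, none); row 16 is (log_inv, als, snv).
#'
#' @param params shared parameter list passed to each
#'   [pretreatment_spec()].
#' @return list of 16 `pretreatment_spec` objects, names `"1"`..`"16"`.
#' @export
enumerate_pretreatments <- function(params = list()) {
  specs <- list()
  i <- 0
  for (lin in c("none", "log_inv"))
    for (mult in c("none", "snv"))
      for (det in c("none", "poly2", "sg_deriv1", "als")) {
        i <- i + 1
        specs[[as.character(i)]] <-
          pretreatment_spec(lin, det, mult, params)
      }
  specs
}

#' Response linearization: absorbance transform
#'
#' \eqn{A_\lambda = \log_{10}(1 / R_\lambda)}. Reflectance can come out
#' of normalization at or below zero in deep shadow; such values are
#' floored at `eps` before the log, and the number of floored values is
#' attached as attribute `n_floored`.
#'
#' @param x reflectance vector or matrix (spectra in rows).
#' @param eps floor for non-positive reflectance.
#' @return absorbance, same shape.
#' @export
log_linearize <- function(x, eps = 1e-6) {
  n_floored <- sum(x <= 0)
  x <- pmax(x, eps)
  out <- -log10(x)
  attr(out, "n_floored") <- n_floored
  out
}

# residual projector for polynomial de-trending (I - X (X'X)^-1 X')
poly_residual_projector <- function(wavelengths, degree = 2) {
  X <- stats::poly(wavelengths, degree = degree, raw = FALSE)
  X <- cbind(1, X)
  diag(length(wavelengths)) - X %*% solve(crossprod(X), t(X))
}

#' Polynomial de-trending (2nd order centring)
#'
#' Returns the residual of a least-squares polynomial fit of the spectrum
#' against wavelength.
#'
#' @param x spectrum vector, or matrix with spectra in rows.
#' @param wavelengths band-centre wavelengths (nm).
#' @param degree polynomial degree (default 2).
#' @return residual spectrum/spectra, same shape as `x`.
#' @export
detrend_poly <- function(x, wavelengths, degree = 2) {
  P <- poly_residual_projector(wavelengths, degree)
  if (is.matrix(x)) x %*% t(P) else as.vector(P %*% x)
}

# Savitzky-Golay operator matrix (n x n): local polynomial least squares,
# derivative `deriv` w.r.t. band index; edges use the polynomial fitted in
# the first/last window evaluated at the edge offsets.
sg_operator <- function(n, window = 7, polyorder = 2, deriv = 1) {
  if (window %% 2 == 0) stop("Savitzky-Golay window must be odd")
  if (window < polyorder + 1) stop("window must be >= polyorder + 1")
  if (n < window) stop("spectrum shorter than Savitzky-Golay window")
  h <- (window - 1) / 2
  X <- outer(-h:h, 0:polyorder, "^")
  C <- solve(crossprod(X), t(X))         # (polyorder+1) x window
  # row of coefficients evaluating the deriv-th derivative at offset t
  eval_row <- function(t) {
    pw <- 0:polyorder
    co <- ifelse(pw >= deriv, factorial(pw) / factorial(pmax(pw - deriv, 0)) *
                   t^pmax(pw - deriv, 0), 0)
    as.vector(co %*% C)
  }
  S <- matrix(0, n, n)
  central <- eval_row(0)
  for (i in (h + 1):(n - h)) S[i, (i - h):(i + h)] <- central
  for (i in 1:h) {
    S[i, 1:window] <- eval_row(i - h - 1)
    S[n - i + 1, (n - window + 1):n] <- eval_row(h - i + 1)
  }
  S
}

#' Savitzky-Golay first derivative
#'
#' First derivative with respect to band index via local polynomial
#' least squares (default window 7, polynomial order 2). Edge points use
#' the edge-window polynomial evaluated at their offset.
#'
#' @param x spectrum vector, or matrix with spectra in rows.
#' @param window odd filter window length.
#' @param polyorder polynomial order, `window >= polyorder + 1`.
#' @return derivative spectrum/spectra, same shape.
#' @export
sg_first_derivative <- function(x, window = 7, polyorder = 2) {
  n <- if (is.matrix(x)) ncol(x) else length(x)
  S <- sg_operator(n, window, polyorder, deriv = 1)
  if (is.matrix(x)) x %*% t(S) else as.vector(S %*% x)
}

#' Asymmetric least squares baseline correction
#'
#' Iterative baseline estimation: minimizes
#' \eqn{\sum_i w_i (y_i - z_i)^2 + \lambda \sum_i (\Delta^2 z_i)^2} with
#' asymmetric weights (`p` above the baseline, `1 - p` below), re-weighted
#' for a fixed number of iterations. Fixed iteration count; non-convergence
#' is not an error.
#'
#' @param y spectrum vector.
#' @param lam smoothness penalty (> 0), default `1e4`.
#' @param p asymmetry (0 < p < 1), default `1e-3`.
#' @param n_iter number of reweighting iterations, default 10.
#' @return list with `baseline` and `corrected` (= `y - baseline`).
#' @export
als_baseline <- function(y, lam = 1e4, p = 1e-3, n_iter = 10) {
  stopifnot(lam > 0, p > 0, p < 1)
  n <- length(y)
  if (n < 3) stop("ALS needs at least 3 bands")
  D <- Matrix::bandSparse(n - 2, n, k = 0:2,
                          diagonals = list(rep(1, n - 2), rep(-2, n - 2),
                                           rep(1, n - 2)))
  P <- lam * Matrix::crossprod(D)
  w <- rep(1, n)
  z <- y
  for (i in seq_len(n_iter)) {
    A <- Matrix::Diagonal(x = w) + P
    z <- as.vector(Matrix::solve(A, w * y))
    w <- ifelse(y > z, p, 1 - p)
  }
  list(baseline = z, corrected = y - z)
}

# batched ALS over spectra rows via the banded C++ solver
als_correct_rows <- function(X, lam = 1e4, p = 1e-3, n_iter = 10) {
  Z <- als_batch_(t(X), lam, p, n_iter)
  X - t(Z)
}

#' Standard normal variate
#'
#' Per-spectrum standardization: subtract the mean, divide by the
#' population standard deviation (divide by n). Removes multiplicative
#' scatter. Zero-variance spectra are returned as all zeros and counted
#' in attribute `n_degenerate`.
#'
#' @param x spectrum vector, or matrix with spectra in rows.
#' @return standardized spectrum/spectra, same shape.
#' @export
snv <- function(x) {
  if (!is.matrix(x)) {
    out <- snv(matrix(x, 1))
    v <- as.vector(out)
    attr(v, "n_degenerate") <- attr(out, "n_degenerate")
    return(v)
  }
  mu <- rowMeans(x)
  sd_pop <- sqrt(rowMeans(x^2) - mu^2)
  bad <- sd_pop <= 0 | !is.finite(sd_pop)
  sd_pop[bad] <- 1
  out <- (x - mu) / sd_pop
  out[bad, ] <- 0
  attr(out, "n_degenerate") <- sum(bad)
  out
}

#' Multiplicative scatter correction (optional, non-default)
#'
#' Regresses each spectrum on a reference spectrum (default: mean of the
#' supplied spectra) and returns `(x - intercept) / slope`. Provided for
#' completeness; it is not part of the default factorial bank.
#'
#' @param x matrix with spectra in rows.
#' @param reference reference spectrum; default column mean of `x`.
#' @return corrected spectra matrix.
#' @export
msc <- function(x, reference = NULL) {
  stopifnot(is.matrix(x))
  if (is.null(reference)) reference <- colMeans(x)
  rc <- reference - mean(reference)
  denom <- sum(rc^2)
  slope <- as.vector((x - rowMeans(x)) %*% rc) / denom
  slope[slope == 0] <- 1
  intercept <- rowMeans(x) - slope * mean(reference)
  (x - intercept) / slope
}

#' Apply a pre-treatment spec to a cube
#'
#' Ordered composition linearization -> de-trending -> multiplicative,
#' applied to every valid pixel's spectrum. Black-masked pixels remain
#' exactly zero.
#'
#' @param cube a [hypercube].
#' @param spec a [pretreatment_spec()].
#' @return the pre-treated [hypercube] (`meta$pretreatment` records the
#'   spec label).
#' @export
apply_pretreatment <- function(cube, spec) {
  stopifnot(inherits(cube, "hypercube"), inherits(spec, "pretreatment_spec"))
  cs <- cube_spectra(cube)
  X <- cs$spectra
  p <- spec$params
  if (spec$linearization == "log_inv") X <- log_linearize(X)
  X <- switch(spec$detrend,
    none = X,
    poly2 = detrend_poly(X, cube$wavelengths, p$poly_degree),
    sg_deriv1 = sg_first_derivative(X, p$sg_window, p$sg_polyorder),
    als = als_correct_rows(X, p$als_lambda, p$als_p, p$als_iter))
  if (spec$multiplicative == "snv") X <- snv(X)
  attr(X, "n_floored") <- NULL
  attr(X, "n_degenerate") <- NULL
  out <- cube_with_spectra(cube, X, cs$idx)
  out$meta$pretreatment <- format(spec)
  out
}
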