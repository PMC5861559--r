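## Sum-of-Gaussians model evaluation. `par` is c(baseline, A1, c1, s1, A2, ...).
multigauss_eval <- function(x, par) {
  b <- par[1]
  k <- (length(par) - 1) / 3
  y <- rep(b, length(x))
  for (i in seq_len(k)) {
    A <- par[3 * i - 1]; cen <- par[3 * i]; s <- par[3 * i + 1]
    y <- y + A * exp(-(x - cen)^2 / (2 * s^2))
  }
  y
}

#' Fit a sum of signed Gaussians to a line-spread function
#'
#' Fits `baseline + sum_i A_i exp(-(x - c_i)^2 / (2 s_i^2))` to a derivative
#' profile by Levenberg-Marquardt nonlinear least squares.  Each edge
#' transition of a bar pattern contributes one signed peak; the fitted widths
#' approximate the PSF (a Gaussian is used as a first approximation to the
#' Airy profile).
#'
#' Initialization: candidate peaks are the alternating-sign local extrema of
#' the derivative whose amplitude exceeds `snr_threshold` times a robust
#' noise estimate (1.4826 x the median absolute deviation of the profile
#' tails); initial centers are the sub-pixel-refined extremum locations,
#' initial widths half the distance to the nearest neighboring extremum, and
#' initial amplitudes the extremum values.
#'
#' @param deriv A [line_profile], normally from [differentiate].
#' @param expected_peaks Number of peaks, or `NULL` to accept all detected
#'   extrema.  If fewer extrema than `expected_peaks` are detected the fit
#'   fails with a `lenschar_fit_error`.
#' @param snr_threshold Detection threshold in units of the robust noise
#'   estimate.
#' @param tail_frac Fraction of samples at each end treated as signal-free
#'   tails for the noise estimate.
#' @param max_iter Iteration cap for the optimizer.
#' @param tol Relative convergence tolerance on the residual norm.
#' @return An object of class `multigauss_fit` with components `peaks` (a
#'   data.frame with `center`, `sigma`, `amplitude`, `fwhm`, sorted by
#'   center), `baseline`, `profile`, `fitted`, `rss`, `noise_sd`, `info`,
#'   `niter`.  Supports `print`, `summary`, `coef`, `predict`, `fitted`,
#'   `residuals` and `plot`.
#' @examples
#' x <- seq(-10, 10, by = 0.2)
#' lp <- line_profile(x + 10, 2 * exp(-(x - 1)^2 / (2 * 1.5^2)))
#' fit <- fit_multi_gaussian(lp)
#' coef(fit)
#' @export
fit_multi_gaussian <- function(deriv, expected_peaks = NULL,
                               snr_threshold = 5, tail_frac = 0.1,
                               max_iter = 500, tol = 1e-8) {
  stopifnot(inherits(deriv, "line_profile"))
  x <- deriv$positions; y <- deriv$intensities
  n <- length(x)
  if (n < 7) stop_domain("derivative profile too short to fit")

  nt <- max(3L, ceiling(tail_frac * n))
  tails <- c(y[seq_len(nt)], y[seq(n - nt + 1, n)])
  b0 <- median(tails)
  noise_sd <- mad(tails)
  ## numerical floor so noiseless profiles still threshold sensibly
  thr <- max(snr_threshold * noise_sd, 1e-3 * max(abs(y - b0)))

  imax <- local_extrema_idx(y, maxima = TRUE)
  imin <- local_extrema_idx(y, maxima = FALSE)
  cand <- sort(c(imax[y[imax] - b0 > thr], imin[y[imin] - b0 < -thr]))
  if (!length(cand)) {
    stop_fit("no local extremum exceeds 5x the robust noise estimate")
  }
  ## enforce alternating signs: within a same-sign run keep the strongest
  sgn <- sign(y[cand] - b0)
  keep <- rep(TRUE, length(cand))
  last <- 1L
  for (i in seq_along(cand)[-1]) {
    if (sgn[i] == sgn[last]) {
      if (abs(y[cand[i]] - b0) > abs(y[cand[last]] - b0)) {
        keep[last] <- FALSE; last <- i
      } else keep[i] <- FALSE
    } else last <- i
  }
  cand <- cand[keep]
  if (!is.null(expected_peaks)) {
    if (length(cand) < expected_peaks) {
      stop_fit(sprintf("detected %d usable extrema but %d peaks were expected",
                       length(cand), expected_peaks))
    }
    if (length(cand) > expected_peaks) {
      ord <- order(abs(y[cand] - b0), decreasing = TRUE)
      cand <- sort(cand[ord[seq_len(expected_peaks)]])
    }
  }

  k <- length(cand)
  centers0 <- vapply(cand, function(i) {
    fi <- parabolic_refine(y, i)
    x[1] + (fi - 1) * deriv$spacing
  }, numeric(1))
  amps0 <- y[cand] - b0
  ## width of each peak's own half-maximum support, walking out from the apex
  halfmax_sigma <- vapply(seq_len(k), function(i) {
    ctr <- cand[i]; half <- abs(amps0[i]) / 2
    lo <- ctr; while (lo > 1 && abs(y[lo - 1] - b0) > half &&
                      sign(y[lo - 1] - b0) == sign(amps0[i])) lo <- lo - 1
    hi <- ctr; while (hi < n && abs(y[hi + 1] - b0) > half &&
                      sign(y[hi + 1] - b0) == sign(amps0[i])) hi <- hi + 1
    max(hi - lo + 1, 2) * deriv$spacing / FWHM_FACTOR
  }, numeric(1))
  sig0 <- if (k > 1) {
    d <- diff(centers0)
    nb <- vapply(seq_len(k), function(i) {
      if (i == 1) d[1] else if (i == k) d[k - 1] else min(d[i - 1], d[i])
    }, numeric(1))
    pmin(nb / 2, halfmax_sigma)
  } else {
    halfmax_sigma
  }
  sig0 <- pmax(sig0, deriv$spacing / 2)

  par0 <- c(b0, rbind(amps0, centers0, sig0))
  lower <- c(-Inf, rep(c(-Inf, min(x), deriv$spacing / 10), k))
  upper <- c(Inf, rep(c(Inf, max(x), diff(range(x))), k))
  fit <- minpack.lm::nls.lm(
    par = par0,
    fn = function(p) y - multigauss_eval(x, p),
    lower = lower, upper = upper,
    control = minpack.lm::nls.lm.control(
      maxiter = max_iter, maxfev = 100 * (length(par0) + 1),
      ftol = tol, ptol = 1e-10))
  if (fit$info == 0 || fit$info == 5) {
    stop_fit(sprintf(
      "multi-Gaussian fit did not converge (info %d after %d iterations, deviance %.3g)",
      fit$info, fit$niter, fit$deviance))
  }
  p <- fit$par
  peaks <- data.frame(
    amplitude = p[seq(2, length(p), by = 3)],
    center = p[seq(3, length(p), by = 3)],
    sigma = abs(p[seq(4, length(p), by = 3)]))
  peaks$fwhm <- sigma_to_fwhm(peaks$sigma)
  peaks <- peaks[order(peaks$center), c("center", "sigma", "amplitude", "fwhm")]
  rownames(peaks) <- NULL
  fitted_y <- multigauss_eval(x, p)
  structure(
    list(peaks = peaks, baseline = p[1], profile = deriv, fitted = fitted_y,
         rss = sum((y - fitted_y)^2), noise_sd = noise_sd,
         info = fit$info, niter = fit$niter),
    class = "multigauss_fit")
}

#' @export
print.multigauss_fit <- function(x, ...) {
  cat(sprintf("<multigauss_fit> %d peak(s), baseline %.4g, RSS %.4g (%d iterations)\n",
              nrow(x$peaks), x$baseline, x$rss, x$niter))
  print(x$peaks, digits = 4)
  invisible(x)
}

#' @export
coef.multigauss_fit <- function(object, ...) {
  k <- nrow(object$peaks)
  out <- c(baseline = object$baseline)
  for (i in seq_len(k)) {
    v <- unlist(object$peaks[i, c("amplitude", "center", "sigma")])
    names(v) <- paste0(c("amplitude", "center", "sigma"), i)
    out <- c(out, v)
  }
  out
}

#' @export
fitted.multigauss_fit <- function(object, ...) object$fitted

#' @export
residuals.multigauss_fit <- function(object, ...) {
  object$profile$intensities - object$fitted
}

#' @export
predict.multigauss_fit <- function(object, positions = NULL, ...) {
  if (is.null(positions)) return(object$fitted)
  par <- c(object$baseline,
           rbind(object$peaks$amplitude, object$peaks$center,
                 object$peaks$sigma))
  multigauss_eval(positions, par)
}

#' @export
summary.multigauss_fit <- function(object, ...) {
  out <- list(
    peaks = object$peaks,
    baseline = object$baseline,
    fwhm_mean = mean(object$peaks$fwhm),
    fwhm_sd = if (nrow(object$peaks) > 1) sd(object$peaks$fwhm) else 0,
    rss = object$rss,
    rmse = sqrt(object$rss / length(object$fitted)),
    noise_sd = object$noise_sd,
    niter = object$niter)
  class(out) <- "summary.multigauss_fit"
  out
}

#' @export
print.summary.multigauss_fit <- function(x, ...) {
  cat(sprintf("Multi-peak Gaussian fit: %d peak(s)\n", nrow(x$peaks)))
  print(x$peaks, digits = 4)
  cat(sprintf("FWHM mean %.4g +/- %.4g um; baseline %.4g; RMSE %.4g (%d iterations)\n",
              x$fwhm_mean, x$fwhm_sd, x$baseline, x$rmse, x$niter))
  invisible(x)
}

#' @export
plot.multigauss_fit <- function(x, ...) {
  px <- x$profile$positions
  graphics::plot(px, x$profile$intensities, type = "p", pch = 16, cex = 0.5,
                 col = "grey40",
                 xlab = sprintf("position (um, %s plane)", x$profile$plane),
                 ylab = "dI/dx", ...)
  xfine <- seq(min(px), max(px), length.out = 8 * length(px))
  graphics::lines(xfine, predict(x, xfine), col = "red", lwd = 1.5)
  for (i in seq_len(nrow(x$peaks))) {
    graphics::lines(xfine, x$baseline + x$peaks$amplitude[i] *
                      exp(-(xfine - x$peaks$center[i])^2 /
                            (2 * x$peaks$sigma[i]^2)),
                    col = "steelblue", lty = 3)
  }
  invisible(x)
}
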