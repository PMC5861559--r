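#' Estimate the grid period along one axis
#'
#' Projects the image onto the chosen axis and measures the mean spacing of
#' detected grid-line centers.  To minimize distortion bias, detection starts
#' in the central third of the field and the region grows outward only when
#' fewer than three lines are found there.  Line centers are located as
#' extrema of the intensity projection with sub-pixel parabolic
#' interpolation; line polarity (dark-on-bright or bright-on-dark) is
#' detected automatically.
#'
#' @param image A [raster_image] of a grid target.
#' @param axis `"x"` measures spacing along columns (between vertical lines),
#'   `"y"` along rows.
#' @return A list with `period_px`, `uncertainty` (standard error of the mean
#'   spacing, in pixels; `NA` with a single gap), `centers_px` (0-based
#'   sub-pixel line-center coordinates) and `n_lines`.
#' @export
estimate_grid_period <- function(image, axis = c("x", "y")) {
  axis <- match.arg(axis)
  stopifnot(inherits(image, "raster_image"))
  m <- as_grayscale(image)$intensities
  nr <- nrow(m); nc <- ncol(m)

  frac <- 1 / 3
  repeat {
    rs <- central_span(nr, frac); cs <- central_span(nc, frac)
    sub <- m[rs, cs, drop = FALSE]
    proj <- if (axis == "x") colMeans(sub) else rowMeans(sub)
    off <- if (axis == "x") cs[1] - 1L else rs[1] - 1L  # 0-based offset
    centers <- detect_line_centers(proj)
    if (length(centers) >= 3 || frac >= 1) break
    frac <- min(1, frac * 1.5)
  }
  if (length(centers) < 3) {
    stop_insufficient(sprintf(
      "fewer than 3 grid lines detected along %s; need >= 2 periods in view",
      axis))
  }
  gaps <- diff(centers)
  ## drop gaps from missed lines (far from the median spacing)
  ok <- abs(gaps - median(gaps)) < 0.25 * median(gaps)
  gaps <- gaps[ok]
  if (!length(gaps)) stop_insufficient("grid line spacing is too irregular")
  list(period_px = mean(gaps),
       uncertainty = if (length(gaps) > 1) sd(gaps) / sqrt(length(gaps)) else NA_real_,
       centers_px = centers + off - 1,  # to 0-based image coordinates
       n_lines = length(centers))
}

central_span <- function(n, frac) {
  len <- max(3L, floor(n * frac))
  start <- (n - len) %/% 2 + 1L
  seq(start, start + len - 1L)
}

## 1-based sub-pixel line-center positions in a 1D projection.  Each line is
## an above-threshold run of the (polarity-corrected) projection; narrow
## peaks are refined parabolically, wide plateaued lines (thick lines, where
## a parabola through the plateau top is ill-conditioned) by the weighted
## centroid of the run.
detect_line_centers <- function(proj) {
  s <- proj - median(proj)
  if (max(abs(s)) <= 0) return(numeric(0))
  dark <- abs(min(s)) > abs(max(s))
  q <- if (dark) -s else s
  thr <- 0.5 * max(q)
  above <- q > thr
  runs <- rle(above)
  ends <- cumsum(runs$lengths)
  starts <- ends - runs$lengths + 1
  centers <- numeric(0)
  for (k in which(runs$values)) {
    i0 <- starts[k]; i1 <- ends[k]
    ## a run touching the window edge is a truncated line; its centroid
    ## would be biased inward, so it is discarded
    if (i0 == 1 || i1 == length(q)) next
    if (i1 - i0 + 1 <= 5) {
      imax <- i0 - 1 + which.max(q[i0:i1])
      centers <- c(centers, parabolic_refine(q, imax))
    } else {
      w <- q[i0:i1] - thr
      centers <- c(centers, sum((i0:i1) * w) / sum(w))
    }
  }
  centers
}

#' Estimate magnification from a grid-target image
#'
#' With a target of known period, the sample-to-sensor magnification along
#' each axis is `M = period_px * pixel_pitch / known_period`.
#'
#' @param image A [raster_image] of the grid target (sensor plane).
#' @param known_period True grid period in micrometers.
#' @param pixel_pitch Sensor pixel pitch in micrometers (defaults to the
#'   image metadata).
#' @return An object of class `magnification_estimate`: list with `mx`, `my`,
#'   `period_px_x`, `period_px_y` and `uncertainty` (1 SD, unitless).
#' @export
estimate_magnification <- function(image, known_period,
                                   pixel_pitch = image$pixel_pitch) {
  check_positive_scalar(known_period, "known_period")
  check_positive_scalar(pixel_pitch, "pixel_pitch")
  px <- estimate_grid_period(image, "x")
  py <- estimate_grid_period(image, "y")
  mx <- px$period_px * pixel_pitch / known_period
  my <- py$period_px * pixel_pitch / known_period
  unc <- mean(c(px$uncertainty, py$uncertainty), na.rm = TRUE) *
    pixel_pitch / known_period
  structure(list(mx = mx, my = my,
                 period_px_x = px$period_px, period_px_y = py$period_px,
                 uncertainty = if (is.finite(unc)) unc else NA_real_),
            class = "magnification_estimate")
}

#' @export
print.magnification_estimate <- function(x, ...) {
  cat(sprintf("<magnification_estimate> Mx %.4f, My %.4f (periods %.2f / %.2f px, +/- %.4g)\n",
              x$mx, x$my, x$period_px_x, x$period_px_y, x$uncertainty))
  invisible(x)
}

#' Estimate radial distortion from a grid-target image
#'
#' Fits the one-coefficient Brown model `r' = r (1 + k1 (r/Rn)^2)` (radius
#' normalized by the image half-diagonal, center fixed at the geometric image
#' center, `k1 > 0` = pincushion) to the displacements of detected grid
#' intersections from an ideal lattice.  Intersections are located by
#' iteratively re-centered darkness centroids, marching outward from the
#' image center so that the running fit predicts where distortion has pushed
#' the outer intersections.
#'
#' @param image A [raster_image] of a grid target whose intersections are
#'   visible over most of the field.
#' @param known_period True grid period in micrometers (used only to seed the
#'   lattice spacing; the fitted scale absorbs magnification error).
#' @param pixel_pitch Sensor pixel pitch in micrometers.
#' @return An object of class `distortion_estimate`: list with `k1`, `center`
#'   (0-based row, col), `residual` (RMS, pixels), `scale` and `n_points`.
#' @export
estimate_distortion <- function(image, known_period,
                                pixel_pitch = image$pixel_pitch) {
  stopifnot(inherits(image, "raster_image"))
  m <- as_grayscale(image)$intensities
  nr <- nrow(m); nc <- ncol(m)
  Px <- estimate_grid_period(image, "x")$period_px
  Py <- estimate_grid_period(image, "y")$period_px
  cr <- (nr - 1) / 2; cc <- (nc - 1) / 2
  Rn <- sqrt(cr^2 + cc^2)
  hw <- max(4L, floor(0.3 * min(Px, Py)))

  ## lattice nodes ordered by radius, marching outward
  irange <- -floor((cr - hw) / Py):floor((cr - hw) / Py)
  jrange <- -floor((cc - hw) / Px):floor((cc - hw) / Px)
  nodes <- expand.grid(i = irange, j = jrange)
  u_row <- nodes$i * Py; u_col <- nodes$j * Px
  ord <- order(u_row^2 + u_col^2)
  a <- 1; b <- 0
  U <- NULL; Mm <- NULL
  contrast <- diff(range(m))
  for (idx in ord) {
    u <- c(u_row[idx], u_col[idx])
    rn2 <- sum(u^2) / Rn^2
    pred <- c(cr, cc) + u * (a + b * rn2)
    p <- refine_intersection(m, pred, hw)
    if (is.null(p)) next
    if (p$depth < 0.2 * contrast) next
    U <- rbind(U, u); Mm <- rbind(Mm, p$pos - c(cr, cc))
    if (nrow(U) >= 6) {
      rn2v <- rowSums(U^2) / Rn^2
      X <- cbind(c(U[, 1], U[, 2]), c(U[, 1] * rn2v, U[, 2] * rn2v))
      yv <- c(Mm[, 1], Mm[, 2])
      beta <- qr.solve(X, yv)
      a <- beta[1]; b <- beta[2]
    }
  }
  if (is.null(U) || nrow(U) < 6) {
    stop_insufficient("too few grid intersections detected to fit distortion")
  }
  rn2v <- rowSums(U^2) / Rn^2
  fitted <- U * (a + b * rn2v)
  res <- sqrt(mean(rowSums((Mm - fitted)^2)))
  structure(list(k1 = b / a, center = c(cr, cc), residual = res,
                 scale = a, n_points = nrow(U)),
            class = "distortion_estimate")
}

## Locate a grid intersection near a predicted position.  A re-centered 2-D
## darkness centroid homes in on the crossing; the final sub-pixel estimate
## comes from the marginal darkness profiles with the flat pedestal of the
## crossing line's arm subtracted, so each line is located independently of
## the other's mass.
refine_intersection <- function(m, pos, hw) {
  nr <- nrow(m); nc <- ncol(m)
  win <- NULL
  for (it in 1:6) {
    r0 <- round(pos[1]) - hw; r1 <- round(pos[1]) + hw
    c0 <- round(pos[2]) - hw; c1 <- round(pos[2]) + hw
    if (r0 < 0 || c0 < 0 || r1 > nr - 1 || c1 > nc - 1) return(NULL)
    win <- m[(r0:r1) + 1, (c0:c1) + 1]
    thr <- (max(win) + min(win)) / 2
    wgt <- pmax(thr - win, 0)
    tot <- sum(wgt)
    if (tot <= 0) return(NULL)
    rows <- r0:r1; cols <- c0:c1
    if (it <= 3) {
      new_pos <- c(sum(rowSums(wgt) * rows), sum(colSums(wgt) * cols)) / tot
    } else {
      new_pos <- c(marginal_center(rowSums(wgt), rows),
                   marginal_center(colSums(wgt), cols))
    }
    if (any(!is.finite(new_pos))) return(NULL)
    shift <- sqrt(sum((new_pos - pos)^2))
    pos <- new_pos
    if (it > 3 && shift < 0.02) break
  }
  list(pos = pos, depth = max(win) - min(win))
}

## pedestal-subtracted centroid of a 1-D darkness marginal
marginal_center <- function(marg, coords) {
  w <- pmax(marg - median(marg), 0)
  s <- sum(w)
  if (s <= 0) return(NA_real_)
  sum(coords * w) / s
}

#' @export
print.distortion_estimate <- function(x, ...) {
  kind <- if (x$k1 > 0) "pincushion" else if (x$k1 < 0) "barrel" else "none"
  cat(sprintf("<distortion_estimate> k1 %.4g (%s), residual %.3g px RMS over %d intersections\n",
              x$k1, kind, x$residual, x$n_points))
  invisible(x)
}
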