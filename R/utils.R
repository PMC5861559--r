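# Internal helpers shared across the package.

#' @importFrom stats median mad dnorm pnorm quantile sd rnorm rpois setNames
#' @importFrom utils modifyList read.csv write.csv
NULL

## Error constructors: typed conditions so callers can distinguish a scene that
## cannot be analysed from a programming error.
stop_lenschar <- function(msg, class, call = sys.call(-1)) {
  stop(errorCondition(msg, class = c(class, "lenschar_error"), call = call))
}

stop_degenerate <- function(msg) stop_lenschar(msg, "lenschar_degenerate_scene")
stop_insufficient <- function(msg) stop_lenschar(msg, "lenschar_insufficient_structure")
stop_fit <- function(msg) stop_lenschar(msg, "lenschar_fit_error")
stop_geometry <- function(msg) stop_lenschar(msg, "lenschar_geometry_error")
stop_domain <- function(msg) stop_lenschar(msg, "lenschar_domain_error")

## Gaussian FWHM <-> sigma. FWHM = 2*sqrt(2*log(2)) * sigma.
FWHM_FACTOR <- 2 * sqrt(2 * log(2))

fwhm_to_sigma <- function(fwhm) fwhm / FWHM_FACTOR
sigma_to_fwhm <- function(sigma) sigma * FWHM_FACTOR

## Run code with a temporary RNG state seeded from `seed`, restoring the
## caller's state afterwards so rendering never perturbs a user's simulation.
with_local_seed <- function(seed, code) {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  } else {
    on.exit(suppressWarnings(rm(".Random.seed", envir = globalenv())), add = TRUE)
  }
  set.seed(seed)
  force(code)
}

## 32-bit FNV-1a hash of a serialized R object, reported as 8 hex digits.
## Used to stamp reports with a configuration fingerprint; not cryptographic.
config_hash <- function(x) {
  bytes <- as.integer(serialize(x, NULL, version = 2))
  h <- 2166136261
  for (b in bytes) {
    ## xor into the low byte (h may exceed the integer range, so do it
    ## arithmetically), then 32-bit multiply by the FNV prime 16777619
    low <- h %% 256
    h <- h - low + bitwXor(as.integer(low), b)
    h <- (h * 403 + (h %% 256) * 16777216) %% 4294967296
  }
  sprintf("%08x", h)
}

## Bilinear interpolation of matrix `m` at fractional 0-based (row, col)
## coordinates. Points outside the grid take the nearest edge value.
bilinear_sample <- function(m, row, col) {
  nr <- nrow(m); nc <- ncol(m)
  r <- pmin(pmax(row, 0), nr - 1)
  c <- pmin(pmax(col, 0), nc - 1)
  r0 <- pmin(floor(r), nr - 2); c0 <- pmin(floor(c), nc - 2)
  r0 <- pmax(r0, 0); c0 <- pmax(c0, 0)
  fr <- r - r0; fc <- c - c0
  i00 <- r0 + 1 + c0 * nr
  v00 <- m[i00];      v10 <- m[i00 + 1]
  v01 <- m[i00 + nr]; v11 <- m[i00 + nr + 1]
  (1 - fr) * (1 - fc) * v00 + fr * (1 - fc) * v10 +
    (1 - fr) * fc * v01 + fr * fc * v11
}

## Strict interior local extrema of a numeric vector; returns indices.
local_extrema_idx <- function(v, maxima = TRUE) {
  n <- length(v)
  if (n < 3) return(integer(0))
  core <- v[2:(n - 1)]
  if (maxima) {
    idx <- which(core > v[1:(n - 2)] & core >= v[3:n]) + 1L
  } else {
    idx <- which(core < v[1:(n - 2)] & core <= v[3:n]) + 1L
  }
  idx
}

## Sub-pixel refinement of an extremum at index i of v by fitting a parabola
## through (i-1, i, i+1). Returns the fractional index (1-based).
parabolic_refine <- function(v, i) {
  n <- length(v)
  if (i <= 1 || i >= n) return(as.numeric(i))
  d1 <- v[i - 1]; d2 <- v[i]; d3 <- v[i + 1]
  denom <- d1 - 2 * d2 + d3
  if (abs(denom) < .Machine$double.eps * max(abs(c(d1, d2, d3)), 1)) {
    return(as.numeric(i))
  }
  i + 0.5 * (d1 - d3) / denom
}

is_scalar_number <- function(x) is.numeric(x) && length(x) == 1L && is.finite(x)

check_positive_scalar <- function(x, name) {
  if (!is_scalar_number(x) || x <= 0) {
    stop_domain(sprintf("`%s` must be a single positive finite number", name))
  }
  invisible(x)
}
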