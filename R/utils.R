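# Internal helpers shared across modules.

#' Sample from a truncated normal distribution
#'
#' Inverse-CDF sampler for a normal distribution truncated to
#' \code{[lower, upper]}.
#'
#' @param n number of draws.
#' @param mean,sd parameters of the untruncated normal.
#' @param lower,upper truncation bounds (may be infinite).
#' @return numeric vector of length \code{n}.
#' @keywords internal
#' @noRd
rtruncnorm <- function(n, mean = 0, sd = 1, lower = -Inf, upper = Inf) {
  stopifnot(sd >= 0, lower < upper)
  if (sd == 0) {
    if (mean < lower || mean > upper)
      stop("degenerate truncated normal: mean outside bounds")
    return(rep(mean, n))
  }
  plo <- stats::pnorm(lower, mean, sd)
  phi <- stats::pnorm(upper, mean, sd)
  u <- stats::runif(n, plo, phi)
  stats::qnorm(u, mean, sd)
}

# Mean and sd of a truncated normal (analytic).
truncnormMoments <- function(mean, sd, lower, upper) {
  if (sd == 0) return(list(mean = mean, sd = 0))
  a <- (lower - mean) / sd
  b <- (upper - mean) / sd
  # compute the mass in whichever tail keeps precision
  z <- if (a + b > 0)
    stats::pnorm(a, lower.tail = FALSE) - stats::pnorm(b, lower.tail = FALSE)
  else stats::pnorm(b) - stats::pnorm(a)
  da <- stats::dnorm(a)
  db <- stats::dnorm(b)
  m <- mean + sd * (da - db) / z
  aa <- ifelse(is.finite(a), a, 0)
  bb <- ifelse(is.finite(b), b, 0)
  v <- sd^2 * (1 + (aa * da - bb * db) / z - ((da - db) / z)^2)
  list(mean = m, sd = sqrt(max(v, 0)))
}

# Deterministic per-eye seed derivation; keeps results < 2^31.
deriveSeed <- function(base, index) {
  as.integer((as.double(base) * 48271 + as.double(index) * 16807) %%
               2147483587)
}

# Evaluate an expression under a temporary RNG seed, restoring the caller's
# RNG state afterwards.
withSeed <- function(seed, expr) {
  has <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (has) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (!is.null(old)) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  eval.parent(substitute(expr))
}

# Separable Gaussian smoothing of a matrix with per-row kernel
# renormalisation at the edges (no padding artefacts).
gaussianBlurMatrix <- function(m, sigma) {
  if (sigma <= 0) return(m)
  half <- max(1L, as.integer(ceiling(3 * sigma)))
  x <- seq(-half, half)
  w <- exp(-x^2 / (2 * sigma^2))
  smooth1 <- function(nn) {
    K <- matrix(0, nn, nn)
    for (j in seq_along(x)) {
      d <- x[j]
      i <- seq_len(nn)
      ok <- i + d >= 1 & i + d <= nn
      K[cbind(i[ok], (i + d)[ok])] <- w[j]
    }
    K / rowSums(K)
  }
  Kr <- smooth1(nrow(m))
  Kc <- smooth1(ncol(m))
  Kr %*% m %*% t(Kc)
}

# Chebyshev (8-neighbourhood) dilation of a logical matrix by r pixels.
dilateMask <- function(mask, r = 1L) {
  out <- mask
  nr <- nrow(mask); nc <- ncol(mask)
  for (dr in -r:r) {
    rs <- max(1, 1 - dr):min(nr, nr - dr)
    for (dc in -r:r) {
      if (dr == 0 && dc == 0) next
      cs <- max(1, 1 - dc):min(nc, nc - dc)
      out[rs + dr, cs + dc] <- out[rs + dr, cs + dc] | mask[rs, cs]
    }
  }
  out
}

# Linear-index neighbours within an nr x nc grid.
neighbourOffsets <- function(connectivity, nr) {
  if (connectivity == 4) {
    list(dr = c(-1L, 1L, 0L, 0L), dc = c(0L, 0L, -1L, 1L))
  } else {
    list(dr = c(-1L, 1L, 0L, 0L, -1L, -1L, 1L, 1L),
         dc = c(0L, 0L, -1L, 1L, -1L, 1L, -1L, 1L))
  }
}

assertScalarInRange <- function(x, lo, hi, what) {
  if (!is.numeric(x) || length(x) != 1L || is.na(x) || x < lo || x > hi)
    stop(sprintf("%s must be a single value in [%s, %s]", what, lo, hi),
         call. = FALSE)
  invisible(x)
}
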