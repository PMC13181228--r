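#' @include AllClasses.R
NULL

# Deterministic per-stage substream seed: lets stages be rerun independently
# yet reproducibly from one global seed. Full-precision modular arithmetic
# (exact in doubles below 2^53) so distinct (seed, stage) pairs do not
# collide in practice. Kept below 2^31 - 1.
stageSeed <- function(seed, stage) {
  cp <- utf8ToInt(stage)
  h <- 0
  for (c in cp) h <- (h * 131 + c) %% 2147483647
  as.integer((as.numeric(seed) %% 2147483647 * 48271 + h + 1) %% 2147483647)
}

# Evaluate expr under a fixed seed without disturbing the caller's RNG state.
withSeed <- function(seed, expr) {
  has <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (has) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (has) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(as.integer(seed))
  expr
}

#' Otsu threshold of an intensity sample
#'
#' Histogram-based Otsu threshold (maximal between-class variance) on a
#' plain numeric vector, so it can be restricted to arbitrary pixel subsets
#' such as the pixels of a single nucleus. The threshold scales with the
#' data, so downstream masks are invariant to a global multiplicative gain.
#'
#' @param x Numeric vector of intensities.
#' @param nbins Number of histogram bins (default 256).
#' @return Threshold value; pixels strictly above it are foreground.
#'   \code{NA} when the sample is degenerate (constant or empty).
#' @examples
#' th <- otsuThreshold(c(rnorm(100, 1), rnorm(100, 10)))
#' th > 1 && th < 10
#' @export
otsuThreshold <- function(x, nbins = 256L) {
  x <- x[is.finite(x)]
  if (!length(x)) return(NA_real_)
  rng <- range(x)
  if (diff(rng) <= 0) return(NA_real_)
  br <- seq(rng[1], rng[2], length.out = nbins + 1L)
  h <- tabulate(findInterval(x, br, rightmost.closed = TRUE,
                             all.inside = TRUE), nbins)
  p <- h / sum(h)
  omega <- cumsum(p)
  mids <- (br[-1L] + br[-(nbins + 1L)]) / 2
  mu <- cumsum(p * mids)
  muT <- mu[nbins]
  denom <- omega * (1 - omega)
  sb <- ifelse(denom > 0, (muT * omega - mu)^2 / denom, 0)
  k <- which.max(sb)
  br[k + 1L]
}

# Bounding-box crop helper: rows/cols of the TRUE support padded by `pad`,
# clipped to the raster. Returns NULL for empty masks.
maskBBox <- function(mask, pad = 1L) {
  idx <- which(mask, arr.ind = TRUE)
  if (!nrow(idx)) return(NULL)
  list(rows = max(1L, min(idx[, 1]) - pad):min(nrow(mask), max(idx[, 1]) + pad),
       cols = max(1L, min(idx[, 2]) - pad):min(ncol(mask), max(idx[, 2]) + pad))
}

# Intersection-over-union of two binary masks.
maskIoU <- function(a, b) {
  u <- sum(a | b)
  if (u == 0) return(NA_real_)
  sum(a & b) / u
}
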