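#' @keywords internal
"_PACKAGE"

#' @importFrom stats aov density mad median rbinom rlnorm rnorm runif sd setNames t.test
#' @importFrom utils read.csv write.csv packageVersion
NULL

# Round half away from zero at `digits` decimals. base::round() rounds half to
# even, which would turn a mean of 9.25 into 9.2 instead of the conventional
# 9.3 used when reporting ratios.
round_half_away <- function(x, digits = 0) {
  m <- 10^digits
  sign(x) * floor(abs(x) * m + 0.5) / m
}

# One-dimensional Otsu threshold on a numeric vector: histogram at `levels`
# bins, threshold maximizing between-class variance. Returns the bin-edge
# threshold; values >= threshold are "positive". EBImage::otsu() serves images;
# MFI vectors are not images, hence this scalar version.
otsu_1d <- function(x, levels = 256L) {
  stopifnot(all(is.finite(x)))
  rng <- range(x)
  if (diff(rng) <= 0) {
    return(structure(rng[1], degenerate = TRUE))
  }
  breaks <- seq(rng[1], rng[2], length.out = levels + 1L)
  h <- tabulate(findInterval(x, breaks, rightmost.closed = TRUE), nbins = levels)
  p <- h / sum(h)
  mids <- (breaks[-1] + breaks[-length(breaks)]) / 2
  w1 <- cumsum(p)
  mu <- cumsum(p * mids)
  mu_t <- mu[levels]
  # between-class variance for threshold after bin k
  bcv <- (mu_t * w1 - mu)^2 / (w1 * (1 - w1))
  bcv[!is.finite(bcv)] <- 0
  if (max(bcv) <= 0) {
    return(structure(mids[which.max(h)], degenerate = TRUE))
  }
  k <- which.max(bcv)
  structure(breaks[k + 1L], degenerate = FALSE)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

abort_missing_cols <- function(df, cols, what) {
  miss <- setdiff(cols, names(df))
  if (length(miss)) {
    stop(sprintf("%s: missing required column(s): %s", what,
                 paste(miss, collapse = ", ")), call. = FALSE)
  }
}
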