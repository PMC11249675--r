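#' @include AllClasses.R AllGenerics.R
NULL

# FrameStack -> npix x nFrames matrix (column-major pixel order)
.stackMatrix <- function(stack) {
  d <- dim(stack@frames)
  matrix(stack@frames, d[1L] * d[2L], d[3L])
}

.asImage <- function(v, stack) {
  d <- dim(stack@frames)
  matrix(v, d[1L], d[2L])
}

#' Mean intensity image of a movie
#'
#' Per-pixel arithmetic mean over time — the conventional (diffraction
#' limited) intensity image against which cumulant images are compared.
#'
#' @param stack a [FrameStack-class]
#' @return numeric matrix of the frame shape
#' @export
meanImage <- function(stack) {
  stopifnot(is(stack, "FrameStack"))
  if (nFrames(stack) < 1L) stop("empty stack")
  .asImage(rowMeans(.stackMatrix(stack)), stack)
}

#' Second-order temporal cumulant image
#'
#' The SOFI signal: per pixel, with `dI(t) = I(t) - mean(I)`, lag 0
#' gives the unbiased sample variance `sum(dI^2)/(n-1)`; lag `tau > 0`
#' gives the sample autocovariance
#' `sum_t dI(t) dI(t+tau) / (n - tau - 1)`. A positive lag suppresses
#' the shot-noise bias (Poisson noise is uncorrelated across frames) at
#' the cost of attenuation by the blinking autocorrelation; the default
#' is the plain per-pixel variance (lag 0). Constant (non-fluctuating)
#' signal, such as out-of-focus background, contributes zero.
#'
#' @param stack a [FrameStack-class] with at least `lag + 2` frames
#' @param lag frame lag, integer >= 0
#' @return a [CumulantImage-class] of order 2
#' @examples
#' st <- frameStack(array(c(0, 10, 0, 10), c(1, 1, 4)))
#' as.matrix(cumulant2(st))  # 100/3
#' @export
cumulant2 <- function(stack, lag = 0L) {
  stopifnot(is(stack, "FrameStack"))
  lag <- as.integer(lag)
  if (lag < 0L) stop("lag must be >= 0")
  n <- nFrames(stack)
  if (n < lag + 2L)
    stop(sprintf("need at least %d frames for lag %d (have %d)",
                 lag + 2L, lag, n))
  M <- .stackMatrix(stack)
  D <- M - rowMeans(M)
  img <- if (lag == 0L) {
    rowSums(D * D) / (n - 1)
  } else {
    i1 <- seq_len(n - lag)
    rowSums(D[, i1, drop = FALSE] * D[, i1 + lag, drop = FALSE]) /
      (n - lag - 1)
  }
  new("CumulantImage", order = 2L, lag = lag, image = .asImage(img, stack),
      nFramesUsed = as.integer(n),
      metadata = list(estimator = if (lag == 0L)
        "unbiased sample variance, divisor n-1" else
        "sample autocovariance, divisor n-lag-1",
        source = stack@metadata))
}

#' Third-order temporal cumulant image
#'
#' Per pixel, the unbiased third k-statistic at zero lag:
#' `k3 = n * sum(dI^3) / ((n-1)(n-2))`. Values can be negative (the
#' third cumulant of a blinking pixel changes sign at ON fraction 0.5).
#'
#' @param stack a [FrameStack-class] with at least 3 frames
#' @return a [CumulantImage-class] of order 3
#' @examples
#' st <- frameStack(array(c(0, 0, 10), c(1, 1, 3)))
#' as.matrix(cumulant3(st))  # 1000/3
#' @export
cumulant3 <- function(stack) {
  stopifnot(is(stack, "FrameStack"))
  n <- nFrames(stack)
  if (n < 3L) stop("need at least 3 frames for the third cumulant")
  M <- .stackMatrix(stack)
  D <- M - rowMeans(M)
  img <- n * rowSums(D^3) / ((n - 1) * (n - 2))
  new("CumulantImage", order = 3L, lag = 0L, image = .asImage(img, stack),
      nFramesUsed = as.integer(n),
      metadata = list(estimator = "unbiased k3, factor n/((n-1)(n-2))",
                      source = stack@metadata))
}

#' Cumulant images of a z-scan series
#'
#' Computes one cumulant image per defocus position, in order.
#'
#' @param series a [ZScanSeries-class]
#' @param order cumulant order, 2 or 3
#' @param lag frame lag (order 2 only)
#' @return list of [CumulantImage-class], one per defocus
#' @export
sofiZStack <- function(series, order = 2L, lag = 0L) {
  stopifnot(is(series, "ZScanSeries"), length(series) >= 1L)
  order <- as.integer(order)
  if (!order %in% c(2L, 3L)) stop("order must be 2 or 3")
  lapply(series@stacks, function(st) {
    if (order == 2L) cumulant2(st, lag = lag) else cumulant3(st)
  })
}

#' Fluctuation-versus-trend diagnostic of a movie
#'
#' Confirms that cumulant contrast comes from optical fluctuations
#' (blinking) and not from slow time-dependent effects such as
#' bleaching. For each pixel a linear trend is fitted to the intensity
#' trace and the fraction of temporal variance explained by the trend is
#' recorded; the global verdict is `"fluctuation-dominated"` when the
#' median fraction over the assessed pixels is below `threshold`,
#' otherwise `"trend-dominated"`. Optionally restrict the verdict to
#' pixels whose temporal mean exceeds `minMean` (background pixels carry
#' no information about the sample's dynamics).
#'
#' @param stack a [FrameStack-class] with at least 10 frames
#' @param threshold verdict threshold on the median trend fraction
#' @param minMean only pixels with temporal mean > `minMean` enter the
#'   verdict (`NULL` = all pixels)
#' @return a [FluctuationReport-class]
#' @export
fluctuationDiagnostic <- function(stack, threshold = 0.5, minMean = NULL) {
  stopifnot(is(stack, "FrameStack"))
  n <- nFrames(stack)
  if (n < 10L) stop("need at least 10 frames for the trend diagnostic")
  M <- .stackMatrix(stack)
  tc <- seq_len(n) - (n + 1) / 2  # centered time
  D <- M - rowMeans(M)
  beta <- as.vector(D %*% tc) / sum(tc^2)
  ssTrend <- beta^2 * sum(tc^2)
  ssTot <- rowSums(D * D)
  frac <- ifelse(ssTot > 0, pmin(ssTrend / ssTot, 1), 0)
  sel <- if (is.null(minMean)) rep(TRUE, length(frac)) else
    rowMeans(M) > minMean
  med <- if (any(sel)) stats::median(frac[sel]) else NA_real_
  new("FluctuationReport",
      trendFraction = .asImage(frac, stack),
      medianFraction = med,
      verdict = if (!is.na(med) && med < threshold)
        "fluctuation-dominated" else "trend-dominated",
      threshold = threshold, nFrames = as.integer(n))
}
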