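#' Equal-width intensity histogram
#'
#' Builds the 256-bin (by default) equal-width histogram over the observed
#' intensity range that both automatic threshold algorithms operate on,
#' mirroring the 8-bit convention of the reference implementations. Values
#' equal to the maximum fall in the last bin. A constant input produces a
#' single populated bin with all edges equal to that value, which downstream
#' threshold selection reports as degenerate.
#'
#' @param x Numeric vector, matrix or array of intensities (NAs not allowed).
#' @param bins Number of equal-width bins (default 256).
#' @param range Length-2 numeric giving the histogram support; defaults to
#'   `range(x)`.
#' @return Object of class `intensity_histogram`: list with integer `counts`
#'   (length `bins`) and `bin_edges` (length `bins + 1`).
#' @export
intensity_histogram <- function(x, bins = 256L, range = NULL) {
  x <- as.numeric(x)
  if (length(x) == 0L) stop("no pixels to histogram")
  if (anyNA(x)) stop("intensities must not contain NA")
  bins <- as.integer(bins)
  if (bins < 1L) stop("`bins` must be >= 1")
  if (is.null(range)) range <- base::range(x)
  lo <- range[1]; hi <- range[2]
  if (hi < lo) stop("invalid histogram range")
  if (hi == lo) {
    counts <- c(length(x), rep.int(0L, bins - 1L))
    edges <- rep.int(lo, bins + 1L)
  } else {
    edges <- seq(lo, hi, length.out = bins + 1L)
    idx <- findInterval(x, edges, rightmost.closed = TRUE)
    idx[idx < 1L] <- 1L
    idx[idx > bins] <- bins
    counts <- tabulate(idx, nbins = bins)
  }
  structure(list(counts = as.integer(counts), bin_edges = edges),
            class = "intensity_histogram")
}

#' @export
print.intensity_histogram <- function(x, ...) {
  cat(sprintf("<intensity_histogram> %d bins over [%.4g, %.4g], %d pixels\n",
              length(x$counts), x$bin_edges[1],
              x$bin_edges[length(x$bin_edges)], sum(x$counts)))
  invisible(x)
}

bin_midpoints <- function(hist) {
  e <- hist$bin_edges
  (e[-1] + e[-length(e)]) / 2
}

# Shared bookkeeping for split-based threshold selection. Returns NULL when
# the histogram is non-degenerate, otherwise the degenerate result.
degenerate_threshold <- function(hist) {
  populated <- which(hist$counts > 0L)
  if (length(populated) >= 2L) return(NULL)
  # one populated bin (or none): threshold at that bin's upper edge so the
  # foreground (> t) is empty; flagged, not an error, so batch runs over
  # blank control images complete.
  j <- if (length(populated) == 1L) populated else length(hist$counts)
  list(threshold = hist$bin_edges[j + 1L], degenerate = TRUE)
}

#' Otsu threshold from a histogram
#'
#' Selects the bin split maximizing the between-class variance
#' \eqn{\sigma^2_B = \omega_0 \omega_1 (\mu_0 - \mu_1)^2} over all possible
#' splits, and returns the corresponding upper bin edge. Foreground is
#' defined as intensity strictly greater than the returned threshold. Ties
#' are broken toward the smallest threshold. Histograms with fewer than two
#' populated bins yield a degenerate result (empty foreground, flag set).
#'
#' @param hist An [intensity_histogram()].
#' @return List with `threshold` (numeric) and `degenerate` (logical).
#' @export
otsu_threshold <- function(hist) {
  stopifnot(inherits(hist, "intensity_histogram"))
  deg <- degenerate_threshold(hist)
  if (!is.null(deg)) return(deg)
  p <- hist$counts / sum(hist$counts)
  mid <- bin_midpoints(hist)
  B <- length(p)
  w0 <- cumsum(p)[-B]
  m0 <- cumsum(p * mid)[-B]
  mT <- sum(p * mid)
  w1 <- 1 - w0
  sigma_b <- (mT * w0 - m0)^2 / (w0 * w1)
  sigma_b[w0 <= 0 | w1 <= 0] <- -Inf
  k <- first_argmax(sigma_b)
  list(threshold = hist$bin_edges[k + 1L], degenerate = FALSE)
}

#' Kapur maximum-entropy threshold from a histogram
#'
#' Selects the bin split maximizing the sum of Shannon entropies of the
#' renormalized background and foreground histograms (Kapur's criterion),
#' the algorithm used for the dense-core amyloid (MeX04) channel. Same
#' conventions as [otsu_threshold()]: upper bin edge returned, foreground is
#' strictly greater than the threshold, ties break to the smallest
#' threshold, degenerate histograms are flagged.
#'
#' @inheritParams otsu_threshold
#' @return List with `threshold` and `degenerate`.
#' @export
maxentropy_threshold <- function(hist) {
  stopifnot(inherits(hist, "intensity_histogram"))
  deg <- degenerate_threshold(hist)
  if (!is.null(deg)) return(deg)
  p <- hist$counts / sum(hist$counts)
  B <- length(p)
  plogp <- ifelse(p > 0, p * log(p), 0)
  P0 <- cumsum(p)[-B]
  S0 <- cumsum(plogp)[-B]
  P1 <- 1 - P0
  S1 <- sum(plogp) - S0
  # H0 = log P0 - S0/P0 ; H1 = log P1 - S1/P1 (entropy of renormalized side)
  crit <- rep.int(-Inf, B - 1L)
  ok <- P0 > 0 & P1 > 0
  crit[ok] <- (log(P0[ok]) - S0[ok] / P0[ok]) +
    (log(P1[ok]) - S1[ok] / P1[ok])
  k <- first_argmax(crit)
  list(threshold = hist$bin_edges[k + 1L], degenerate = FALSE)
}

# Smallest-threshold tie-break, robust to the infinitesimal drift the
# cumulative-sum formulation accrues across analytically tied splits
# (e.g. runs of empty bins): first index within a tiny relative
# tolerance of the maximum.
first_argmax <- function(x) {
  m <- max(x)
  which(x >= m - 1e-10 * max(1, abs(m)))[1]
}

#' Binarize an image at a threshold
#'
#' Foreground is strictly greater than `t` (the package-wide convention,
#' consistent with the threshold selectors' returned bin edges).
#'
#' @param image Numeric matrix or 3-D array; a [calibrated_stack()] is also
#'   accepted.
#' @param t Threshold intensity (or the list returned by a threshold
#'   selector, whose `$threshold` is used).
#' @param pixel_size_um Calibration to attach when `image` is a bare
#'   matrix/array without one; defaults to the `pixel_size_um` attribute of
#'   `image` if present.
#' @return A [binary_mask()].
#' @export
binarize <- function(image, t, pixel_size_um = NULL) {
  if (is.list(t)) t <- t$threshold
  if (inherits(image, "calibrated_stack")) {
    px <- image$pixel_size_um
    image <- image$voxels
  } else {
    px <- pixel_size_um %||% attr(image, "pixel_size_um")
  }
  if (is.null(px)) stop("pixel size unknown; supply `pixel_size_um`")
  bits <- image > t
  attributes(bits) <- list(dim = dim(image))
  binary_mask(bits, px)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# Convenience: build the per-ROI histogram and threshold in one step.
# `pixels` is the numeric vector of intensities inside the analysis region.
auto_threshold <- function(pixels, method = c("otsu", "maxentropy"),
                           bins = 256L) {
  method <- match.arg(method)
  h <- intensity_histogram(pixels, bins = bins)
  if (method == "otsu") otsu_threshold(h) else maxentropy_threshold(h)
}
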