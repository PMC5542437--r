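#' Resample an annulus onto polar coordinates
#'
#' Samples the image by bilinear interpolation at \code{nRings} radii
#' uniformly spaced over \code{[rMinPx, rMaxPx]} and \code{nAngles} angles
#' \code{theta_j = 2*pi*(j-1)/nAngles}, about the given center.  A k-fold
#' ring becomes a signal periodic in angle with period \code{2*pi/k}.
#'
#' @param image a [ParticleImage-class]
#' @param center named numeric \code{c(cx, cy)} (0-based pixel coordinates)
#' @param rMinPx,rMaxPx annulus bounds in pixels (\code{rMinPx >= 1},
#'   annulus must lie inside the box)
#' @param nRings,nAngles polar grid size
#' @return a [PolarImage-class]
#' @export
toPolar <- function(image, center, rMinPx, rMaxPx, nRings = 32L,
                    nAngles = 360L) {
  m <- image@pixels
  box <- nrow(m)
  cx <- center[["cx"]]; cy <- center[["cy"]]
  if (rMinPx < 1) stop("parameter error: rMinPx must be >= 1")
  if (rMaxPx <= rMinPx) stop("parameter error: rMaxPx must exceed rMinPx")
  if (cx - rMaxPx < 0 || cx + rMaxPx > box - 1 ||
      cy - rMaxPx < 0 || cy + rMaxPx > box - 1)
    stop("parameter error: annulus extends outside the image")
  radii <- seq(rMinPx, rMaxPx, length.out = nRings)
  theta <- 2 * pi * (seq_len(nAngles) - 1) / nAngles
  xs <- cx + outer(radii, cos(theta))
  ys <- cy + outer(radii, sin(theta))
  x0 <- pmin(floor(xs), box - 2); y0 <- pmin(floor(ys), box - 2)
  fx <- xs - x0; fy <- ys - y0
  i00 <- x0 + 1 + y0 * box
  vals <- m[i00]       * (1 - fx) * (1 - fy) +
          m[i00 + 1]   * fx       * (1 - fy) +
          m[i00 + box] * (1 - fx) * fy +
          m[i00 + 1 + box] * fx   * fy
  new("PolarImage", values = matrix(vals, nRings, nAngles),
      rMinPx = rMinPx, rMaxPx = rMaxPx)
}

#' Collapse a polar image to a mean-subtracted angular profile
#'
#' The profile at angle j is the (optionally weighted) mean over rings of
#' the polar samples, minus the overall mean, so the profile always sums
#' to zero.  Weighting the rings by the particle's own radial profile acts
#' as a matched radial filter: rings that carry ring density contribute,
#' near-empty rings at the annulus edges do not.
#'
#' @param polar a [PolarImage-class]
#' @param weights optional nonnegative per-ring weights (length nRings);
#'   default equal weights
#' @return numeric vector of length nAngles, zero-sum
#' @export
angularProfile <- function(polar, weights = NULL) {
  v <- polar@values
  if (is.null(weights)) {
    f <- colMeans(v)
  } else {
    stopifnot(length(weights) == nrow(v), all(weights >= 0))
    if (sum(weights) == 0) weights <- rep(1, nrow(v))
    f <- colSums(v * weights) / sum(weights)
  }
  f - mean(f)
}

#' Circular autocorrelation of an angular profile
#'
#' \deqn{c(m) = \sum_j f_j f_{(j+m) \bmod N} / \sum_j f_j^2}
#' computed via FFT; \code{c(0) = 1} and \code{c(m) = c(N-m)}.
#'
#' @param profile zero-mean numeric vector (not identically zero)
#' @return numeric vector of autocorrelation values over lags
#'   \code{2*pi*m/N}, m = 0..N-1
#' @export
circularAutocorrelation <- function(profile) {
  ss <- sum(profile^2)
  if (ss == 0)
    stop("degenerate input: angular profile is identically zero")
  F <- stats::fft(profile)
  Re(stats::fft(Mod(F)^2, inverse = TRUE)) / length(profile) / ss
}

#' Rotational-symmetry power spectrum of an autocorrelation curve
#'
#' Power at order k is the magnitude of the k-th discrete Fourier
#' coefficient of the autocorrelation; by the Wiener-Khinchin relation this
#' equals the squared magnitude of the profile's k-th Fourier coefficient
#' divided by the profile's total power.
#'
#' @param acf autocorrelation curve from [circularAutocorrelation()]
#' @param kMax largest order to retain (capped at N/2)
#' @return a [SymmetrySpectrum-class]
#' @export
symmetrySpectrum <- function(acf, kMax = 16L) {
  N <- length(acf)
  kMax <- min(as.integer(kMax), N %/% 2L)
  p <- Mod(stats::fft(acf))[seq_len(kMax + 1L)]
  names(p) <- as.character(0:kMax)
  new("SymmetrySpectrum", power = p, nAngles = as.integer(N))
}

# spectrum of one polar image under either ACF mode; degenerate rows are
# skipped in per-radius mode
.polarSpectrum <- function(polar, kMax = 16L, acfMode = "collapse",
                           weights = NULL) {
  if (acfMode == "collapse")
    return(symmetrySpectrum(
      circularAutocorrelation(angularProfile(polar, weights = weights)),
      kMax = kMax))
  rows <- polar@values
  acfs <- list()
  for (i in seq_len(nrow(rows))) {
    f <- rows[i, ] - mean(rows[i, ])
    if (sum(f^2) > 0) acfs[[length(acfs) + 1L]] <- circularAutocorrelation(f)
  }
  if (length(acfs) == 0L)
    stop("degenerate input: every polar ring is constant")
  symmetrySpectrum(Reduce(`+`, acfs) / length(acfs), kMax = kMax)
}

#' Assign a rotational symmetry order from a spectrum
#'
#' \code{kBest} is the argmax of the power over \code{kMin..kMax}, ties
#' broken toward smaller k.  The call is flagged low-confidence when any of
#' the following holds:
#' \itemize{
#'   \item the best-to-runner-up power ratio falls below
#'     \code{confidenceRatioMin} (default 1.5);
#'   \item the score (best power over total candidate-range power) falls
#'     below \code{scoreMin} (default 0.4);
#'   \item power at an order below the candidate band but above 1 (i.e.
#'     k = 2 for the default band) exceeds the in-band peak -- the
#'     signature of elongated, non-ring particles such as ring side views
#'     (k = 1 is ignored, since center error and background ramps load it);
#'   \item \code{angularVarianceRatio} (the variance of the angular profile
#'     over the variance of the polar samples, supplied by the caller) lies
#'     below \code{angularVarianceMin} (default 1e-6), meaning the angular
#'     signal is numerically empty.  Score and ratio are scale-free, so
#'     without this floor a rotationally featureless object (a uniform
#'     annulus, say), whose profile is pure grid-interpolation residue,
#'     could still look decisive.
#' }
#'
#' @param spectrum a [SymmetrySpectrum-class]
#' @param kMin,kMax candidate order range (defaults 3..8)
#' @param confidenceRatioMin,scoreMin low-confidence thresholds
#' @param angularVarianceRatio optional absolute-scale diagnostic from the
#'   polar stage (NA disables the floor)
#' @param angularVarianceMin numerically-empty-signal floor
#' @param particleIdent identifier carried on the assignment
#' @return a [SymmetryAssignment-class]
#' @export
assignSymmetry <- function(spectrum, kMin = 3L, kMax = 8L,
                           confidenceRatioMin = 1.5, scoreMin = 0.4,
                           angularVarianceRatio = NA_real_,
                           angularVarianceMin = 1e-6,
                           particleIdent = "") {
  kMin <- as.integer(kMin); kMax <- as.integer(kMax)
  if (kMin < 1L || kMax < kMin)
    stop("empty candidate range: require 1 <= kMin <= kMax")
  kAll <- as.integer(names(spectrum@power))
  if (kMax > max(kAll))
    stop("spectrum holds orders up to ", max(kAll), "; kMax = ", kMax)
  p <- spectrum@power[as.character(kMin:kMax)]
  total <- sum(p)
  if (total <= 0)
    stop("degenerate input: no power in the candidate range")
  best <- unname(which.max(p))             # first max: ties go to smaller k
  score <- unname(p[best] / total)
  second <- if (length(p) > 1L) max(p[-best]) else 0
  ratio <- if (second > 0) unname(p[best] / second) else Inf
  # the DFT of the normalized ACF sums to nAngles exactly, so the band
  # share of total angular power needs no access to out-of-band orders
  bandFraction <- min(1, 2 * total / spectrum@nAngles)
  elongated <- kMin > 2L &&
    max(spectrum@power[as.character(2:(kMin - 1L))]) > p[best]
  numericallyEmpty <- !is.na(angularVarianceRatio) &&
    angularVarianceRatio < angularVarianceMin
  new("SymmetryAssignment", particleId = particleIdent,
      kBest = kMin + best - 1L, score = score, confidenceRatio = ratio,
      bandFraction = bandFraction,
      lowConfidence = ratio < confidenceRatioMin || score < scoreMin ||
        elongated || numericallyEmpty)
}

#' Estimate the ring radius from the radial intensity profile
#'
#' Rotationally averages the image about the center (pixels binned by
#' rounded radius), takes the argmax of the profile, and refines it by
#' quadratic interpolation around the discrete peak.  The profile is
#' computed on a lightly Gaussian-smoothed copy of the image
#' (\code{smoothSigmaPx}), which suppresses spurious peaks in the
#' small-radius bins, where only a handful of pixels are averaged; set
#' \code{smoothSigmaPx = 0} for the raw profile.  The diameter is also
#' reported in nm via the pixel size.
#'
#' When the thresholded density supports a circle fit (see
#' [estimateCenter()]), the peak search is confined to radii within 30
#' percent of the fitted circle radius, which keeps spurious noise bumps at
#' small radii (where a bin averages only a handful of pixels) from
#' capturing the argmax.
#'
#' @param image a normalized [ParticleImage-class]
#' @param center named numeric \code{c(cx, cy)}
#' @param smoothSigmaPx smoothing s.d. before radial averaging
#' @return list with \code{radiusPx}, \code{diameterNm}, and the discrete
#'   radial \code{profile}
#' @export
estimateRingRadius <- function(image, center, smoothSigmaPx = 2) {
  m <- if (smoothSigmaPx > 0)
    EBImage::gblur(image@pixels, sigma = smoothSigmaPx) else image@pixels
  box <- nrow(m)
  g <- .coordGrids(box)
  r <- sqrt((g$x - center[["cx"]])^2 + (g$y - center[["cy"]])^2)
  bin <- as.integer(round(r))
  rmax <- box %/% 2L - 1L
  keep <- bin >= 1L & bin <= rmax
  prof <- as.vector(rowsum(m[keep], bin[keep])) /
    as.vector(table(factor(bin[keep], levels = seq_len(rmax))))
  if (all(!is.finite(prof)) || max(prof, na.rm = TRUE) <= 0)
    stop("estimation error: no positive radial peak")
  fit <- .kasaCircle(pmax(m - max(0, 3 * stats::mad(m)), 0), g)
  window <- seq_len(rmax)
  if (!is.null(fit) && fit[3] >= 2 && fit[3] <= rmax) {
    lo <- max(1L, floor(0.7 * fit[3])); hi <- min(rmax, ceiling(1.3 * fit[3]))
    if (any(prof[lo:hi] > 0, na.rm = TRUE)) window <- lo:hi
  }
  b0 <- window[which.max(prof[window])]
  radius <- as.numeric(b0)
  if (b0 > 1L && b0 < rmax) {
    pm <- prof[b0 - 1L]; p0 <- prof[b0]; pp <- prof[b0 + 1L]
    den <- pm - 2 * p0 + pp
    if (is.finite(den) && den < 0) radius <- b0 + 0.5 * (pm - pp) / den
  }
  list(radiusPx = radius,
       diameterNm = 2 * radius * image@pixelSizeA / 10,
       profile = prof)
}
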