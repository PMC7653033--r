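## PSD cake-ratio undulation indicator for SHG micrographs.
##
## Pipeline: 2D FFT -> power spectral density -> principal symmetry axes by
## PCA of the PSD-weighted frequency coordinates -> cake integration about
## both principal axes at a narrow and a wide opening angle -> ratio curve
## wide/narrow -> RMS of (ratio - 1) over a frequency band. Straight
## striation concentrates spectral mass on the striation axis, so widening
## the cake dilutes the peak and the ratio deviates strongly from 1;
## undulation spreads mass azimuthally and drives the ratio toward 1. The
## scalar therefore decreases with increasing undulation.

.fftshift2 <- function(m) {
  d <- dim(m)
  s1 <- floor(d[1] / 2); s2 <- floor(d[2] / 2)
  m[c((s1 + 1):d[1], seq_len(s1)), c((s2 + 1):d[2], seq_len(s2))]
}

#' Power spectral density of a micrograph
#'
#' Mean-subtracts the image, optionally applies a Hann window (default on;
#' suppresses edge-leakage anisotropy that would bias the principal axes),
#' re-centers, and returns the squared modulus of the 2D DFT divided by the
#' pixel count, zero-frequency centered with the DC bin zeroed. With this
#' normalization Parseval's identity reads sum(PSD) = sum(x^2) for the
#' windowed, mean-subtracted image x.
#'
#' @param image numeric matrix, both dimensions at least 64
#' @param window apply a Hann window
#' @return centered PSD matrix; attribute \code{degenerate} is TRUE for a
#'   constant input (all-zero PSD)
#' @export
computePsd <- function(image, window = TRUE) {
  if (!is.matrix(image) || min(dim(image)) < 64L)
    stop("image must be a matrix with both dimensions >= 64")
  x <- image - mean(image)
  degenerate <- all(abs(x) < .Machine$double.eps * max(1, abs(mean(image))))
  if (window) {
    d <- dim(x)
    hr <- 0.5 * (1 - cos(2 * pi * (seq_len(d[1]) - 1) / (d[1] - 1)))
    hc <- 0.5 * (1 - cos(2 * pi * (seq_len(d[2]) - 1) / (d[2] - 1)))
    x <- x * outer(hr, hc)
    x <- x - mean(x)
  }
  P <- Mod(stats::fft(x))^2 / length(x)
  P <- .fftshift2(P)
  ctr <- floor(dim(P) / 2) + 1L
  P[ctr[1], ctr[2]] <- 0
  attr(P, "degenerate") <- degenerate
  P
}

.freqCoords <- function(psd) {
  d <- dim(psd)
  ctr <- floor(d / 2) + 1L
  fy <- matrix(seq_len(d[1]) - ctr[1], d[1], d[2])
  fx <- matrix(seq_len(d[2]) - ctr[2], d[1], d[2], byrow = TRUE)
  list(fx = fx, fy = fy, r = sqrt(fx^2 + fy^2))
}

#' Principal symmetry axes of a PSD
#'
#' Eigen-decomposition of the PSD-weighted second-moment tensor of the
#' frequency coordinates (the PCA of the spectral mass), excluding a small
#' disc around DC. Returns the major and minor axis directions in degrees
#' modulo 180; near-isotropic spectra (eigenvalue ratio below 1.05) are
#' flagged unstable.
#'
#' @param psd centered PSD from \code{\link{computePsd}}
#' @param dcExclusionRadius radius (bins) excluded around DC
#' @return list: angles = c(major, minor) degrees mod 180, eigenvalues,
#'   unstable flag
#' @export
principalAxes <- function(psd, dcExclusionRadius = 3) {
  if (isTRUE(attr(psd, "degenerate")))
    stop("degenerate (constant-image) PSD has no symmetry axes")
  fc <- .freqCoords(psd)
  w <- as.vector(psd)
  keep <- as.vector(fc$r) > dcExclusionRadius
  w <- w[keep]
  fx <- as.vector(fc$fx)[keep]; fy <- as.vector(fc$fy)[keep]
  W <- sum(w)
  M <- matrix(c(sum(w * fx * fx), sum(w * fx * fy),
                sum(w * fx * fy), sum(w * fy * fy)), 2, 2) / W
  e <- eigen(M, symmetric = TRUE)
  major <- (atan2(e$vectors[2, 1], e$vectors[1, 1]) * 180 / pi) %% 180
  # The inertia tensor weights pixels by P r^2, which lets broadband noise
  # at high frequency tilt the eigenvector by a degree or two -- enough to
  # de-center a narrow cake sector. Refine the direction with the axial
  # (doubled-angle) spectral mean, which drops the r^2 weighting and is
  # unbiased for a centrosymmetric PSD; keep the eigenvalues for the
  # stability flag.
  phi <- atan2(fy, fx)
  z <- sum(w * exp(2i * phi))
  if (Mod(z) > .Machine$double.eps * W)
    major <- (Arg(z) / 2 * 180 / pi) %% 180
  list(angles = c(major, (major + 90) %% 180),
       eigenvalues = e$values,
       unstable = e$values[1] / max(e$values[2], .Machine$double.eps) < 1.05)
}

#' Cake integration of a PSD about its principal axes
#'
#' Mean PSD per radial-frequency bin over the union of four sectors of full
#' width \code{openingAngle} centered on both directions of both principal
#' axes (a four-armed cross). Radial bins are one frequency pixel wide; bins
#' without pixels are flagged invalid.
#'
#' @param psd centered PSD (square)
#' @param axes principal axes as returned by \code{\link{principalAxes}}
#'   (list or the angles vector)
#' @param openingAngle full sector width, degrees, in (0, 45]
#' @param maxRadius largest radial bin (defaults to the Nyquist bin,
#'   half the image size)
#' @return list: r (bin centers, frequency pixels), value, n (pixel counts),
#'   valid
#' @export
cakeProfile <- function(psd, axes, openingAngle, maxRadius = NULL) {
  if (openingAngle <= 0 || openingAngle > 45)
    stop("openingAngle must lie in (0, 45] degrees")
  if (is.list(axes)) axes <- axes$angles
  d <- dim(psd)
  if (d[1] != d[2]) stop("cake integration expects a square PSD")
  fc <- .freqCoords(psd)
  phi <- atan2(fc$fy, fc$fx) * 180 / pi
  dax <- pmin(axialDistance(phi, axes[1]), axialDistance(phi, axes[2]))
  if (is.null(maxRadius)) maxRadius <- floor(min(d) / 2)
  bin <- as.integer(round(fc$r))
  sel <- dax <= openingAngle / 2 & bin >= 1L & bin <= maxRadius
  s <- rowsum(as.vector(psd)[sel], bin[sel])
  n <- tabulate(bin[sel], maxRadius)
  val <- rep(NA_real_, maxRadius)
  val[as.integer(rownames(s))] <- s
  val <- val / ifelse(n > 0, n, NA_real_)
  list(r = seq_len(maxRadius), value = val, n = n, valid = n > 0L)
}

#' PSD undulation indicator of one micrograph
#'
#' Ratio of the wide-angle cake curve to the narrow-angle cake curve per
#' radial bin, and the RMS of (ratio - 1) over the frequency band (by
#' default from 2 bins above DC to 0.8 of the Nyquist bin). A straight
#' striation yields a large scalar; undulation (partial rotational
#' averaging) drives the ratio toward 1 and the scalar toward 0. The scalar
#' is invariant to multiplicative rescaling of the image.
#'
#' By default the RMS runs over the signal band: radial bins between 2 bins
#' above DC and 0.8 of the Nyquist bin whose narrow-cake value exceeds
#' \code{bandThreshold} times the median narrow-cake value (the bins where
#' directional spectral mass stands above the isotropic floor). Off-signal
#' bins hold the ratio of two few-sample averages of the noise PSD, whose
#' sampling scatter would otherwise swamp the morphology signal; an image
#' with no directional signal (no bin above threshold) scores exactly 0.
#' Pass \code{band} explicitly to force a fixed band instead.
#'
#' @param psd centered PSD from \code{\link{computePsd}}
#' @param axes from \code{\link{principalAxes}}; computed when NULL
#' @param narrowAngle,wideAngle full sector widths, degrees
#' @param band integer radial-bin indices of the RMS band, or NULL for the
#'   signal-adaptive default
#' @param bandThreshold signal-band threshold on the narrow cake curve,
#'   relative to its median
#' @param maxFraction second signal-band threshold, relative to the narrow
#'   cake maximum
#' @param dcExclusionRadius passed to \code{\link{principalAxes}}
#' @return a \linkS4class{PSDIndicatorResult}
#' @export
undulationIndicator <- function(psd, axes = NULL, narrowAngle = 5,
                                wideAngle = 20, band = NULL,
                                bandThreshold = 10, maxFraction = 2e-3,
                                dcExclusionRadius = 3) {
  if (wideAngle <= narrowAngle)
    stop("wideAngle must exceed narrowAngle")
  if (is.null(axes)) axes <- principalAxes(psd, dcExclusionRadius)
  narrow <- cakeProfile(psd, axes, narrowAngle)
  wide <- cakeProfile(psd, axes, wideAngle)
  curve <- wide$value / narrow$value
  curve[!narrow$valid | !wide$valid | narrow$value <= 0] <- NA_real_
  nyq <- length(curve)
  searchBand <- seq(3L, max(3L, floor(0.8 * nyq)))
  if (is.null(band)) {
    nv <- narrow$value[searchBand]
    ok <- is.finite(nv) & nv > 0
    ref <- stats::median(nv[ok])
    # two-part rule: above the isotropic floor (median multiple) AND not a
    # skirt bin orders of magnitude below the spectral peak, where the
    # ratio of two near-empty sector means is numerically unstable
    thr <- max(bandThreshold * ref, maxFraction * max(nv[ok]))
    band <- searchBand[ok & nv > thr]
  }
  bandVals <- curve[band]
  bandVals <- bandVals[is.finite(bandVals)]
  if (length(band) && !length(bandVals))
    stop("indicator curve fully invalid over the requested band")
  scalar <- if (length(bandVals)) sqrt(mean((bandVals - 1)^2)) else 0
  new("PSDIndicatorResult", psd = psd,
      axes = if (is.list(axes)) axes$angles else axes,
      axesUnstable = if (is.list(axes)) axes$unstable else FALSE,
      radialBins = as.numeric(narrow$r),
      cakeCurves = stats::setNames(list(narrow$value, wide$value),
                                   paste0("deg", c(narrowAngle, wideAngle))),
      indicatorCurve = curve, indicatorScalar = scalar,
      band = as.integer(band),
      openingAngles = c(narrowAngle, wideAngle))
}

#' Full SHG indicator pipeline for one image
#'
#' Center-crops to a square (512 x 512 by default, for comparability across
#' images of different sizes), computes the windowed PSD, the principal
#' axes and the cake-ratio indicator.
#'
#' @param image an \linkS4class{SHGImage} or a numeric matrix
#' @param crop square crop size in pixels (NULL: largest centered square)
#' @param window Hann window flag
#' @param ... passed to \code{\link{undulationIndicator}}
#' @return a \linkS4class{PSDIndicatorResult}
#' @export
shgIndicator <- function(image, crop = 512L, window = TRUE, ...) {
  m <- if (is(image, "SHGImage")) image@pixels else image
  d <- dim(m)
  side <- min(d, if (is.null(crop)) Inf else crop)
  r0 <- floor((d[1] - side) / 2); c0 <- floor((d[2] - side) / 2)
  m <- m[r0 + seq_len(side), c0 + seq_len(side)]
  psd <- computePsd(m, window = window)
  undulationIndicator(psd, ...)
}

#' Two-tailed paired Student t-test (closed form)
#'
#' \eqn{t = \bar{d} / (s_d/\sqrt{n})} with \eqn{n - 1} degrees of freedom
#' and the two-tailed p-value from the t distribution. Zero-variance
#' differences are flagged degenerate (p undefined) rather than reported.
#'
#' @param a,b paired samples of equal length (n >= 2)
#' @return list: t, dof, p, n, meanDiff, degenerate
#' @export
pairedTTest <- function(a, b) {
  if (length(a) != length(b)) stop("paired samples must have equal length")
  n <- length(a)
  if (n < 2L) stop("paired t-test requires at least 2 pairs")
  d <- a - b
  sd_d <- stats::sd(d)
  if (sd_d == 0)
    return(list(t = NA_real_, dof = n - 1L, p = NA_real_, n = n,
                meanDiff = mean(d), degenerate = TRUE))
  t <- mean(d) / (sd_d / sqrt(n))
  list(t = t, dof = n - 1L, p = 2 * stats::pt(-abs(t), n - 1),
       n = n, meanDiff = mean(d), degenerate = FALSE)
}

#' Group comparison of per-image indicators with per-heart averaging
#'
#' Averages the per-image indicator scalars within each heart, pairs the
#' per-heart means across the two groups by heart order, and applies the
#' two-tailed paired t-test. The pairing is by index (heart rank within
#' group); n and dof are reported explicitly.
#'
#' @param scalars numeric per-image indicator values
#' @param group character/factor group label per image (exactly 2 levels)
#' @param heart heart identifier per image
#' @return list: perHeart (data.frame heart, group, mean, nImages), test
#'   (from \code{\link{pairedTTest}})
#' @export
groupIndicatorTest <- function(scalars, group, heart) {
  stopifnot(length(scalars) == length(group),
            length(scalars) == length(heart))
  df <- data.frame(scalar = scalars, group = as.character(group),
                   heart = as.character(heart))
  lev <- sort(unique(df$group))
  if (length(lev) != 2L) stop("exactly two groups are required")
  agg <- stats::aggregate(scalar ~ heart + group, df, mean)
  cnt <- stats::aggregate(scalar ~ heart + group, df, length)
  agg$nImages <- cnt$scalar
  a <- agg[agg$group == lev[1], ]; a <- a[order(a$heart), ]
  b <- agg[agg$group == lev[2], ]; b <- b[order(b$heart), ]
  if (nrow(a) != nrow(b))
    stop("paired design requires equal numbers of hearts per group")
  list(perHeart = agg, groups = lev,
       test = pairedTTest(a$scalar, b$scalar))
}
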