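# Texture features of a nucleus: first-order intensity statistics (Mean,
# Deviation) on the raw 8-bit values, plus six descriptors of the
# gray-level co-occurrence matrix (GLCM) accumulated symmetrically over
# unit offsets in four directions.

#' First-order intensity statistics
#'
#' `intensityMean()` is the arithmetic mean gray value over the region
#' pixels; `intensityDeviation()` is the population standard deviation
#' `sqrt(sum((g - Mean)^2) / Num)`.
#'
#' @param pixels numeric vector of region intensities (>= 1 value).
#' @return A single numeric value.
#' @export
intensityMean <- function(pixels) {
  if (length(pixels) < 1L) stop("empty region")
  mean(pixels)
}

#' @rdname intensityMean
#' @export
intensityDeviation <- function(pixels) {
  if (length(pixels) < 1L) stop("empty region")
  sqrt(mean((pixels - mean(pixels))^2))
}

#' Default GLCM offsets
#'
#' Distance-1 displacements at 0, 45, 90 and 135 degrees, as (drow, dcol)
#' pairs; with symmetric accumulation these cover all 8 unit directions.
#'
#' @return List of length-2 integer vectors.
#' @export
defaultGlcmOffsets <- function() {
  list(c(0L, 1L), c(-1L, 1L), c(-1L, 0L), c(-1L, -1L))
}

#' Gray-level co-occurrence matrix of a region
#'
#' Region intensities are linearly quantized to `levels` bins over the
#' region's own \[min, max\] range; pair counts are accumulated over the
#' given offsets (and their opposites when `symmetric`) with both
#' endpoints required to lie inside the mask, then normalized to
#' probabilities.
#'
#' @param img a [GrayImage-class] (or matrix).
#' @param region a [NucleusRegion-class].
#' @param levels number of quantization levels (>= 2), default 32.
#' @param offsets list of (drow, dcol) displacement pairs, default
#'   [defaultGlcmOffsets()].
#' @param symmetric also count each pair in the opposite direction
#'   (default TRUE), making the matrix symmetric.
#' @return List with `P` (levels x levels probability matrix), `levels`
#'   and `offsets`.
#' @export
buildGLCM <- function(img, region, levels = 32L,
                      offsets = defaultGlcmOffsets(), symmetric = TRUE) {
  m <- asIntensityMatrix(img)
  levels <- as.integer(levels)
  if (levels < 2L) stop("'levels' must be >= 2")
  mc <- maskCoords(region)
  g <- m[mc]
  gmin <- min(g); gmax <- max(g)
  lev <- if (gmax == gmin) rep(1L, length(g))
         else pmin(levels, floor((g - gmin) / ((gmax - gmin + 1) / levels)) + 1L)
  r0 <- min(mc[, 1L]); c0 <- min(mc[, 2L])
  nr <- max(mc[, 1L]) - r0 + 1L
  nc <- max(mc[, 2L]) - c0 + 1L
  LM <- matrix(NA_integer_, nr, nc)
  LM[cbind(mc[, 1L] - r0 + 1L, mc[, 2L] - c0 + 1L)] <- lev
  counts <- numeric(levels * levels)
  for (off in offsets) {
    dr <- off[1L]; dc <- off[2L]
    r1 <- max(1L, 1L - dr):min(nr, nr - dr)
    c1 <- max(1L, 1L - dc):min(nc, nc - dc)
    if (!length(r1) || !length(c1)) next
    A <- LM[r1, c1, drop = FALSE]
    B <- LM[r1 + dr, c1 + dc, drop = FALSE]
    ok <- !is.na(A) & !is.na(B)
    if (!any(ok)) next
    i <- A[ok]; j <- B[ok]
    counts <- counts + tabulate((i - 1L) * levels + j, levels * levels)
    if (symmetric)
      counts <- counts + tabulate((j - 1L) * levels + i, levels * levels)
  }
  tot <- sum(counts)
  if (tot == 0) stop("region too small for any co-occurrence pair")
  list(P = matrix(counts / tot, levels, levels, byrow = TRUE),
       levels = levels, offsets = offsets)
}

#' Haralick-style descriptors of a co-occurrence matrix
#'
#' With `p[i, j]` the normalized co-occurrence probabilities and marginal
#' means/sds `mu_i, mu_j, sigma_i, sigma_j`:
#' `Energy = sum(p^2)`; `Contrast = sum((i - j)^2 * p)`;
#' `Homogeneity = sum(p / (1 + |i - j|))`;
#' `Correlation = sum((i - mu_i) * (j - mu_j) * p) / (sigma_i * sigma_j)`
#' (defined as 1 with a warning for a constant region);
#' `Entropy = -sum(p * log2(p))` over nonzero cells.
#'
#' `Anisotropy` is a reconstruction (the original reference is not
#' recoverable): with `e_k = -q_k * log2(q_k)` the entropy contributions
#' of the marginal level distribution `q`, `k*` is the smallest level at
#' which the cumulative entropy reaches half the total, and
#' `Anisotropy = -k* / L`, a value in \[-1, 0\] near -0.5 for symmetric
#' level histograms.
#'
#' @param glcm result of [buildGLCM()].
#' @return Named list with `Energy`, `Correlation`, `Homogeneity`,
#'   `Contrast`, `Entropy`, `Anisotropy`.
#' @export
haralickSubset <- function(glcm) {
  P <- glcm$P
  L <- glcm$levels
  iIdx <- matrix(seq_len(L), L, L)
  jIdx <- t(iIdx)
  pi_ <- rowSums(P); pj_ <- colSums(P)
  mui <- sum(seq_len(L) * pi_); muj <- sum(seq_len(L) * pj_)
  sdi <- sqrt(sum((seq_len(L) - mui)^2 * pi_))
  sdj <- sqrt(sum((seq_len(L) - muj)^2 * pj_))
  energy <- sum(P^2)
  contrast <- sum((iIdx - jIdx)^2 * P)
  homog <- sum(P / (1 + abs(iIdx - jIdx)))
  correl <- if (sdi * sdj == 0) {
    warning("constant region: correlation defined as 1")
    1
  } else sum((iIdx - mui) * (jIdx - muj) * P) / (sdi * sdj)
  nz <- P[P > 0]
  entropy <- -sum(nz * log2(nz))
  ek <- ifelse(pi_ > 0, -pi_ * log2(pi_), 0)
  Etot <- sum(ek)
  kstar <- if (Etot > 0) which(cumsum(ek) >= Etot / 2)[1L] else 1L
  list(Energy = energy, Correlation = correl, Homogeneity = homog,
       Contrast = contrast, Entropy = entropy, Anisotropy = -kstar / L)
}

#' All 8 texture features of a nucleus
#'
#' Combines the first-order statistics (raw 8-bit intensities) with the
#' six GLCM descriptors of [haralickSubset()].
#'
#' @inheritParams buildGLCM
#' @return Named list with `Mean`, `Deviation`, `Energy`, `Correlation`,
#'   `Homogeneity`, `Contrast`, `Entropy`, `Anisotropy`.
#' @export
extractTexture <- function(img, region, levels = 32L,
                           offsets = defaultGlcmOffsets(),
                           symmetric = TRUE) {
  m <- asIntensityMatrix(img)
  g <- m[maskCoords(region)]
  h <- haralickSubset(buildGLCM(m, region, levels, offsets, symmetric))
  c(list(Mean = intensityMean(g), Deviation = intensityDeviation(g)), h)
}
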