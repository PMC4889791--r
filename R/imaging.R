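# Preprocessing and segmentation of stained-nucleus images.
#
# Nuclei are the stain-dark phase on a lighter background (Feulgen-thionin
# style); segmentation keeps pixels <= threshold unless polarity = "light".

#' Read an image file as a GrayImage
#'
#' Reads PNG, TIFF or JPEG. Color images are converted to luminance with
#' ITU-R 601 weights (0.299 R + 0.587 G + 0.114 B) and rounded to 8-bit.
#'
#' @param path image file path; format inferred from the extension.
#' @return A [GrayImage-class].
#' @export
readGrayImage <- function(path) {
  ext <- tolower(tools::file_ext(path))
  a <- switch(ext,
    png  = png::readPNG(path),
    tif  = ,
    tiff = tiff::readTIFF(path),
    jpg  = ,
    jpeg = {
      if (!requireNamespace("jpeg", quietly = TRUE))
        stop("reading JPEG requires the 'jpeg' package")
      jpeg::readJPEG(path)
    },
    stop("unsupported image format: '", ext, "'"))
  if (length(dim(a)) == 3L) {
    nc <- dim(a)[3L]
    a <- if (nc >= 3L)
      0.299 * a[, , 1L] + 0.587 * a[, , 2L] + 0.114 * a[, , 3L]
    else a[, , 1L]
  }
  grayImage(round(a * 255))
}

#' Write / read a labeled segmentation mask as PNG
#'
#' Labels are stored losslessly across the red (high byte) and green (low
#' byte) channels of an RGB PNG, giving 16-bit label capacity;
#' `readMaskPNG()` reverses the encoding.
#'
#' @param labels integer matrix of region labels (0 = background).
#' @param path output PNG path.
#' @export
writeMaskPNG <- function(labels, path) {
  if (max(labels) > 65535L) stop("more than 65535 labels")
  arr <- array(0, c(nrow(labels), ncol(labels), 3L))
  arr[, , 1L] <- (labels %/% 256L) / 255
  arr[, , 2L] <- (labels %% 256L) / 255
  png::writePNG(arr, path)
  invisible(path)
}

#' @rdname writeMaskPNG
#' @export
readMaskPNG <- function(path) {
  a <- png::readPNG(path)
  if (length(dim(a)) != 3L) stop("not a label-encoded mask PNG")
  matrix(as.integer(round(a[, , 1L] * 255) * 256L +
                    round(a[, , 2L] * 255)),
         dim(a)[1L], dim(a)[2L])
}

#' Write region contours as CSV
#'
#' One row per contour point: `region_id, row, col, order`.
#'
#' @param regions list of [NucleusRegion-class].
#' @param path output CSV path.
#' @export
writeContoursCSV <- function(regions, path) {
  rows <- lapply(regions, function(r) {
    cn <- contourCoords(r)
    data.frame(region_id = regionLabel(r), row = cn[, 1L], col = cn[, 2L],
               order = seq_len(nrow(cn)))
  })
  utils::write.csv(do.call(rbind, rows), path, row.names = FALSE)
  invisible(path)
}

# replicate-pad a matrix by p pixels on every side
padReplicate <- function(m, p) {
  ri <- pmin(pmax(seq_len(nrow(m) + 2L * p) - p, 1L), nrow(m))
  ci <- pmin(pmax(seq_len(ncol(m) + 2L * p) - p, 1L), ncol(m))
  m[ri, ci, drop = FALSE]
}

# vectorized odd-even transposition sort across the columns of X,
# returning the middle column (the per-row median for odd ncol)
rowMedianSortNet <- function(X) {
  k <- ncol(X)
  for (pass in seq_len(k)) {
    start <- if (pass %% 2L == 1L) 1L else 2L
    js <- seq.int(start, k - 1L, by = 2L)
    for (j in js) {
      a <- X[, j]; b <- X[, j + 1L]
      X[, j] <- pmin(a, b); X[, j + 1L] <- pmax(a, b)
    }
  }
  X[, (k + 1L) %/% 2L]
}

#' Median denoising filter
#'
#' Each output pixel is the median of its `window` x `window` neighborhood;
#' borders are replicate-padded so the image keeps its size. Median
#' filtering suppresses salt-and-pepper noise while preserving edges.
#'
#' @param img a [GrayImage-class] (or plain matrix).
#' @param window odd integer window side, >= 3.
#' @return A [GrayImage-class] of the same dimensions.
#' @export
medianDenoise <- function(img, window = 3L) {
  m <- asIntensityMatrix(img)
  window <- as.integer(window)
  if (window < 3L || window %% 2L == 0L)
    stop("'window' must be an odd integer >= 3")
  p <- (window - 1L) %/% 2L
  mp <- padReplicate(m, p)
  nr <- nrow(m); nc <- ncol(m)
  X <- matrix(0, nr * nc, window * window)
  k <- 0L
  for (dc in 0L:(window - 1L)) for (dr in 0L:(window - 1L)) {
    k <- k + 1L
    X[, k] <- mp[(1L + dr):(nr + dr), (1L + dc):(nc + dc)]
  }
  grayImage(matrix(rowMedianSortNet(X), nr, nc))
}

# accept GrayImage or a bare matrix; returns the numeric matrix
asIntensityMatrix <- function(img) {
  if (is(img, "GrayImage")) return(img@.Data)
  if (is.matrix(img) && is.numeric(img)) return(img)
  stop("expected a GrayImage or numeric matrix")
}

# map intensities through the classical equalization transfer function
equalizeMap <- function(m) {
  n <- length(m)
  h <- tabulate(as.integer(m) + 1L, 256L)
  cdf <- cumsum(h)
  cdfmin <- cdf[which(h > 0L)[1L]]
  if (n == cdfmin) return(m)           # single occupied level: leave as is
  lut <- round(255 * (cdf - cdfmin) / (n - cdfmin))
  matrix(lut[as.integer(m) + 1L], nrow(m), ncol(m))
}

#' Detail-preserving histogram equalization
#'
#' Splits the image into a base layer (median blur of radius
#' `detailRadius`) and a detail layer (input minus base), applies global
#' histogram equalization to the base, and adds the detail back, clipping
#' to \[0, 255\]. Storing the fine detail before equalization and restoring
#' it afterwards boosts global contrast without erasing local structure
#' such as chromatin texture and nuclear borders.
#'
#' @param img a [GrayImage-class].
#' @param detailRadius positive integer radius of the median-blur base
#'   layer (window `2 * detailRadius + 1`). Default 3.
#' @return A [GrayImage-class] of the same dimensions.
#' @export
equalizeWithDetail <- function(img, detailRadius = 3L) {
  m <- asIntensityMatrix(img)
  if (length(m) == 0L) stop("empty image")
  detailRadius <- as.integer(detailRadius)
  if (detailRadius < 1L) stop("'detailRadius' must be >= 1")
  base <- asIntensityMatrix(medianDenoise(m, 2L * detailRadius + 1L))
  detail <- m - base
  out <- pmin(pmax(equalizeMap(base) + detail, 0), 255)
  grayImage(round(out))
}

# moving-average smoothing of a 256-bin histogram, window width 5
smoothHistogram <- function(h, width = 5L) {
  p <- (width - 1L) %/% 2L
  n <- length(h)
  vapply(seq_len(n), function(i)
    mean(h[max(1L, i - p):min(n, i + p)]), numeric(1))
}

# peak prominence: height minus the higher of the two valley floors
# separating the peak from higher ground (or the series end)
peakProminences <- function(s, peaks) {
  vapply(peaks, function(i) {
    lmin <- s[i]; j <- i
    while (j > 1L && s[j - 1L] <= s[i]) { j <- j - 1L; lmin <- min(lmin, s[j]) }
    rmin <- s[i]; j <- i
    n <- length(s)
    while (j < n && s[j + 1L] <= s[i]) { j <- j + 1L; rmin <- min(rmin, s[j]) }
    s[i] - max(lmin, rmin)
  }, numeric(1))
}

# exhaustive between-class-variance scan (ties -> lowest threshold)
otsuThreshold <- function(m) {
  h <- tabulate(as.integer(m) + 1L, 256L)
  n <- sum(h)
  lv <- 0:255
  w0 <- cumsum(h)
  s0 <- cumsum(h * lv)
  stot <- s0[256L]
  w1 <- n - w0
  mu0 <- ifelse(w0 > 0, s0 / w0, 0)
  mu1 <- ifelse(w1 > 0, (stot - s0) / w1, 0)
  bcv <- w0 * w1 * (mu0 - mu1)^2
  lv[which.max(bcv)]
}

#' Adaptive threshold from the histogram valley
#'
#' Returns the segmentation cutoff between nuclei and background: the
#' valley intensity between the two dominant peaks of the smoothed
#' intensity histogram (moving average width 5; peaks are local maxima
#' with prominence at least 1\% of the pixel count; the valley is the
#' minimum bin strictly between the two tallest peaks, ties broken toward
#' the lower intensity). When fewer than two such peaks exist, falls back
#' to the exhaustive between-class-variance (Otsu) optimum. The two
#' selected peaks must be at least 16 gray levels apart (nucleus and
#' background modes are far more separated in practice); near-coincident
#' noise peaks inside one mode are thereby never mistaken for the two
#' histogram modes. A constant image returns its constant value.
#'
#' @param img a [GrayImage-class].
#' @return Integer threshold in \[0, 255\].
#' @export
adaptiveThreshold <- function(img) {
  m <- asIntensityMatrix(img)
  if (length(m) == 0L) stop("empty image")
  if (min(m) == max(m)) return(as.integer(m[1L]))
  h <- tabulate(as.integer(m) + 1L, 256L)
  s <- smoothHistogram(h, 5L)
  n <- length(m)
  sp <- c(-Inf, s, -Inf)
  cand <- which(sp[2:257] > sp[1:256] & sp[2:257] >= sp[3:258])
  if (length(cand)) {
    prom <- peakProminences(s, cand)
    cand <- cand[prom >= 0.01 * n]
  }
  if (length(cand) >= 2L) {
    o <- cand[order(-s[cand], cand)]    # tallest; ties toward lower intensity
    p1 <- o[1L]
    far <- o[abs(o - p1) >= 16L]        # second peak: a distinct mode
    if (length(far)) {
      two <- sort(c(p1, far[1L]))
      between <- seq.int(two[1L] + 1L, two[2L] - 1L)
      return(as.integer(between[which.min(s[between])] - 1L))
    }
  }
  as.integer(otsuThreshold(m))
}

# 8-connected component labeling via frontier-vectorized flood fill.
# Returns list(labels = integer matrix, pixels = list of linear-index vectors).
labelComponents8 <- function(fg) {
  nr <- nrow(fg); nc <- ncol(fg)
  lab <- matrix(0L, nr, nc)
  todo <- which(fg)
  pixels <- list()
  ptr <- 1L; k <- 0L
  off <- expand.grid(dr = -1:1, dc = -1:1)
  off <- off[!(off$dr == 0L & off$dc == 0L), ]
  while (ptr <= length(todo)) {
    seed <- todo[ptr]; ptr <- ptr + 1L
    if (lab[seed] != 0L) next
    k <- k + 1L
    lab[seed] <- k
    frontier <- seed
    acc <- seed
    while (length(frontier)) {
      fr <- ((frontier - 1L) %% nr) + 1L
      fc <- ((frontier - 1L) %/% nr) + 1L
      nbr <- integer(0)
      for (i in seq_len(nrow(off))) {
        r2 <- fr + off$dr[i]; c2 <- fc + off$dc[i]
        ok <- r2 >= 1L & r2 <= nr & c2 >= 1L & c2 <= nc
        if (any(ok)) nbr <- c(nbr, (c2[ok] - 1L) * nr + r2[ok])
      }
      nbr <- unique(nbr)
      nbr <- nbr[fg[nbr] & lab[nbr] == 0L]
      lab[nbr] <- k
      acc <- c(acc, nbr)
      frontier <- nbr
    }
    pixels[[k]] <- acc
  }
  list(labels = lab, pixels = pixels)
}

# Moore boundary tracing with Jacob's stopping criterion: 8-connectivity,
# clockwise, starting at the topmost-then-leftmost mask pixel. `inside` is
# a logical matrix. Returns an n x 2 (row, col) matrix of boundary pixels.
traceContour <- function(inside) {
  nr <- nrow(inside); nc <- ncol(inside)
  idx <- which(inside)
  rr <- ((idx - 1L) %% nr) + 1L
  cc <- ((idx - 1L) %/% nr) + 1L
  o <- order(rr, cc)
  start <- c(rr[o[1L]], cc[o[1L]])
  if (length(idx) == 1L) return(matrix(start, 1L, 2L))
  # clockwise neighbor directions 0..7 (row down): N, NE, E, SE, S, SW, W, NW
  drs <- c(-1L, -1L, 0L, 1L, 1L, 1L, 0L, -1L)
  dcs <- c(0L, 1L, 1L, 1L, 0L, -1L, -1L, -1L)
  isIn <- function(r, c)
    r >= 1L && r <= nr && c >= 1L && c <= nc && inside[r, c]
  cur <- start
  arrival <- 2L   # as if arrived moving east: scan starts at N, the west
                  # and north neighbors of the start pixel are background
  pts <- matrix(0L, 4L * length(idx) + 8L, 2L)
  np <- 0L
  firstMove <- NA_integer_
  maxSteps <- 4L * length(idx) + 8L
  repeat {
    np <- np + 1L
    pts[np, ] <- cur
    found <- FALSE
    scanStart <- (arrival + 6L) %% 8L
    for (s in 0:7) {
      d <- (scanStart + s) %% 8L
      r2 <- cur[1L] + drs[d + 1L]; c2 <- cur[2L] + dcs[d + 1L]
      if (isIn(r2, c2)) {
        if (np > 1L && all(cur == start) && d == firstMove) {
          np <- np - 1L               # drop the duplicated start point
          return(pts[seq_len(np), , drop = FALSE])
        }
        if (np == 1L) firstMove <- d
        arrival <- d
        cur <- c(r2, c2)
        found <- TRUE
        break
      }
    }
    if (!found || np >= maxSteps)
      return(pts[seq_len(np), , drop = FALSE])
  }
}

#' Build a NucleusRegion from a pixel mask
#'
#' Traces the closed boundary (Moore tracing, clockwise) and computes the
#' centroid. The mask must be a single 8-connected component.
#'
#' @param mask logical matrix, or an n x 2 (row, col) coordinate matrix.
#' @param dim image dimensions (required when `mask` is a coordinate
#'   matrix).
#' @param label integer region id.
#' @return A [NucleusRegion-class].
#' @export
regionFromMask <- function(mask, dim = NULL, label = 1L) {
  if (is.logical(mask) && is.matrix(mask)) {
    inside <- mask
  } else {
    if (is.null(dim)) stop("'dim' is required for coordinate masks")
    inside <- matrix(FALSE, dim[1L], dim[2L])
    inside[cbind(mask[, 1L], mask[, 2L])] <- TRUE
  }
  if (!any(inside)) stop("mask is empty")
  comp <- labelComponents8(inside)
  if (length(comp$pixels) != 1L)
    stop("mask must be a single 8-connected component")
  nr <- nrow(inside)
  idx <- comp$pixels[[1L]]
  coords <- cbind(((idx - 1L) %% nr) + 1L, ((idx - 1L) %/% nr) + 1L)
  coords <- coords[order(coords[, 1L], coords[, 2L]), , drop = FALSE]
  storage.mode(coords) <- "integer"
  new("NucleusRegion", mask = coords, contour = traceContour(inside),
      centroid = colMeans(coords), label = as.integer(label))
}

#' Segment nuclei from a thresholded image
#'
#' Pixels on the stain-dark side of the threshold (`<= threshold`; use
#' `polarity = "light"` for the opposite) are grouped into 8-connected
#' components; components smaller than `minArea` are discarded. Each kept
#' region carries a traced closed contour and its centroid. Touching or
#' overlapping nuclei are not split (such clumps are the "junk" class).
#'
#' @param img a [GrayImage-class].
#' @param threshold integer cutoff in \[0, 255\], e.g. from
#'   [adaptiveThreshold()].
#' @param minArea minimum component area in pixels (default 50).
#' @param polarity `"dark"` (default) keeps pixels `<= threshold`,
#'   `"light"` keeps pixels `>= threshold`.
#' @return List of [NucleusRegion-class]; may be empty.
#' @export
segmentNuclei <- function(img, threshold, minArea = 50L,
                          polarity = c("dark", "light")) {
  m <- asIntensityMatrix(img)
  polarity <- match.arg(polarity)
  if (threshold < 0 || threshold > 255) stop("'threshold' must be in [0, 255]")
  fg <- if (polarity == "dark") m <= threshold else m >= threshold
  comp <- labelComponents8(fg)
  keep <- which(vapply(comp$pixels, length, integer(1)) >= minArea)
  nr <- nrow(m)
  out <- vector("list", length(keep))
  for (i in seq_along(keep)) {
    idx <- comp$pixels[[keep[i]]]
    inside <- matrix(FALSE, nr, ncol(m))
    inside[idx] <- TRUE
    coords <- cbind(((idx - 1L) %% nr) + 1L, ((idx - 1L) %/% nr) + 1L)
    coords <- coords[order(coords[, 1L], coords[, 2L]), , drop = FALSE]
    storage.mode(coords) <- "integer"
    out[[i]] <- new("NucleusRegion", mask = coords,
                    contour = traceContour(inside),
                    centroid = colMeans(coords), label = i)
  }
  out
}

#' Labeled mask matrix from segmented regions
#'
#' @param regions list of [NucleusRegion-class].
#' @param dim image dimensions `c(nrow, ncol)`.
#' @return Integer matrix with each region's label, 0 elsewhere.
#' @export
labelMatrix <- function(regions, dim) {
  lab <- matrix(0L, dim[1L], dim[2L])
  for (r in regions) lab[maskCoords(r)] <- regionLabel(r)
  lab
}
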