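# Morphologic features of a segmented nucleus: contour-distance statistics
# (Roundness, Sides), perimeter-based Compactness, central second moments
# and their principal values, equivalent-ellipse shape factors, and basic
# size/shape descriptors. 20 features in all.
#
# Conventions: x = column, y = row; moments are geometric (pixel
# coordinates, mean-subtracted), not intensity-weighted; Sigma and
# Deviation use the population (divide-by-n) form.

#' Contour-to-centroid distance statistics
#'
#' `Distance` is the mean Euclidean distance from the traced boundary
#' points to the region centroid; `Sigma` is the population standard
#' deviation of those distances. Malignant transformation perturbs the
#' nuclear outline, which shows up as a larger `Sigma` relative to
#' `Distance`.
#'
#' @param region a [NucleusRegion-class] with at least 3 contour points.
#' @return List with elements `Distance` and `Sigma` (pixels).
#' @export
contourDistanceStats <- function(region) {
  cn <- contourCoords(region)
  if (nrow(cn) < 3L)
    stop("degenerate region: need at least 3 contour points")
  ctr <- centroid(region)
  d <- sqrt((cn[, 1L] - ctr[1L])^2 + (cn[, 2L] - ctr[2L])^2)
  m <- mean(d)
  list(Distance = m, Sigma = sqrt(mean((d - m)^2)))
}

#' Roundness from contour-distance statistics
#'
#' `Roundness = 1 - Sigma / Distance`: 1 for a perfect circle, decreasing
#' as the boundary-distance spread grows.
#'
#' @param distance mean contour-to-centroid distance (> 0).
#' @param sigma standard deviation of contour-to-centroid distances.
#' @return Roundness (dimensionless, <= 1).
#' @examples
#' roundness(17.397, 1.16761)   # 0.932884
#' @export
roundness <- function(distance, sigma) {
  if (any(distance <= 0)) stop("'distance' must be > 0")
  1 - sigma / distance
}

#' Equivalent polygon side count
#'
#' `Sides = 1.4111 * (Distance / Sigma)^0.4724` estimates the number of
#' sides of the equilateral polygon with the same boundary-distance
#' statistics; the rounder the nucleus, the more sides. A zero `sigma`
#' (perfect circle) returns `Inf`.
#'
#' @inheritParams roundness
#' @return Side count estimate (dimensionless).
#' @examples
#' sides(17.397, 1.16761)   # 5.05552
#' @export
sides <- function(distance, sigma) {
  out <- ifelse(sigma == 0, Inf, 1.4111 * (distance / sigma)^0.4724)
  if (length(out) == 1L) out[[1L]] else out
}

#' Isoperimetric compactness
#'
#' `Compactness = P^2 / (4 * pi * Area)`: 1 for a continuous circle,
#' larger for every other shape.
#'
#' @param perimeter contour length (> 0).
#' @param area region area (> 0).
#' @return Compactness (dimensionless, >= ~1).
#' @examples
#' compactness(121.983, 1071)   # 1.1056
#' @export
compactness <- function(perimeter, area) {
  if (any(perimeter <= 0) || any(area <= 0))
    stop("'perimeter' and 'area' must be > 0")
  perimeter^2 / (4 * pi * area)
}

#' Central second moments of a region
#'
#' Geometric (unit-weight) central moments over the mask pixels:
#' `M20 = sum((x - xbar)^2)`, `M02 = sum((y - ybar)^2)`,
#' `M11 = sum((x - xbar) * (y - ybar))` with x = column, y = row, plus
#' `h = (M20 + M02) / 2`.
#'
#' @param region a [NucleusRegion-class].
#' @return List with `M20`, `M02`, `M11`, `h`.
#' @export
regionMoments <- function(region) {
  mc <- maskCoords(region)
  y <- mc[, 1L] - mean(mc[, 1L])
  x <- mc[, 2L] - mean(mc[, 2L])
  M20 <- sum(x^2); M02 <- sum(y^2); M11 <- sum(x * y)
  list(M20 = M20, M02 = M02, M11 = M11, h = (M20 + M02) / 2)
}

#' Principal second moments
#'
#' Eigenvalues of the 2x2 second-moment matrix `[[M20, M11], [M11, M02]]`:
#' `I_a = h + sqrt(h^2 - M20 * M02 + M11^2)` and `I_b = h - sqrt(...)`
#' with `h = (M20 + M02) / 2`. Always `I_a >= I_b` and
#' `I_a + I_b = M20 + M02`. Tiny negative discriminants from floating
#' point are clamped to zero.
#'
#' @param m20,m02,m11 central second moments (see [regionMoments()]).
#' @return Named numeric `c(Ia = ..., Ib = ...)`.
#' @examples
#' principalMoments(105447, 79455.2, 5434.79)   # 106538, 78364.5
#' @export
principalMoments <- function(m20, m02, m11) {
  h <- (m20 + m02) / 2
  disc <- h^2 - m20 * m02 + m11^2
  disc <- pmax(disc, 0)
  s <- sqrt(disc)
  c(Ia = h + s, Ib = h - s)
}

#' Equivalent-ellipse shape factors
#'
#' From the principal moments the semi-axes of the ellipse with the same
#' second moments and area are `Ra = 2 * sqrt(I_a / Area)` and
#' `Rb = 2 * sqrt(I_b / Area)` (`Ra >= Rb`). Then
#' `Anisometry = Ra / Rb` (axis ratio, >= 1),
#' `Bulkiness = pi * Ra * Rb / Area` (ellipse-to-region area ratio, 1 for
#' a perfect ellipse) and
#' `StructureFactor = Anisometry * Bulkiness - 1` (exact identity).
#'
#' @param region a [NucleusRegion-class] with area >= 2.
#' @return List with `Anisometry`, `Bulkiness`, `StructureFactor`.
#' @export
ellipseShapeFactors <- function(region) {
  area <- nrow(maskCoords(region))
  if (area < 2L) stop("degenerate region: area must be >= 2")
  m <- regionMoments(region)
  pm <- principalMoments(m$M20, m$M02, m$M11)
  if (pm[["Ib"]] <= 0)
    stop("degenerate region: minor principal moment is zero")
  Ra <- 2 * sqrt(pm[["Ia"]] / area)
  Rb <- 2 * sqrt(pm[["Ib"]] / area)
  anis <- Ra / Rb
  bulk <- pi * Ra * Rb / area
  list(Anisometry = anis, Bulkiness = bulk,
       StructureFactor = anis * bulk - 1)
}

# contour length with diagonal steps counting sqrt(2), including the
# closing step from the last point back to the first
contourLength <- function(cn) {
  if (nrow(cn) < 2L) return(0)
  nxt <- rbind(cn[-1L, , drop = FALSE], cn[1L, , drop = FALSE])
  step <- abs(nxt - cn)
  sum(ifelse(step[, 1L] + step[, 2L] == 2L, sqrt(2), 1))
}

# shoelace area of a polygon given as an n x 2 (row, col) matrix
polygonArea <- function(p) {
  n <- nrow(p)
  if (n < 3L) return(0)
  x <- p[, 2L]; y <- p[, 1L]
  abs(sum(x * c(y[-1L], y[1L]) - c(x[-1L], x[1L]) * y)) / 2
}

# convex hull (as an ordered polygon) of the pixel-corner cloud of a mask:
# each pixel contributes its four unit-square corners, so hull area matches
# the pixel area of convex shapes instead of undercutting by half a pixel
cornerHull <- function(mc) {
  pts <- rbind(
    cbind(mc[, 1L] - 0.5, mc[, 2L] - 0.5),
    cbind(mc[, 1L] - 0.5, mc[, 2L] + 0.5),
    cbind(mc[, 1L] + 0.5, mc[, 2L] - 0.5),
    cbind(mc[, 1L] + 0.5, mc[, 2L] + 0.5))
  pts[grDevices::chull(pts[, 2L], pts[, 1L]), , drop = FALSE]
}

# minimum-area enclosing rectangle by rotating calipers over hull edges
minAreaRectangle <- function(hull) {
  n <- nrow(hull)
  if (n < 3L) return(0)
  best <- Inf
  for (i in seq_len(n)) {
    j <- if (i == n) 1L else i + 1L
    e <- hull[j, ] - hull[i, ]
    len <- sqrt(sum(e^2))
    if (len == 0) next
    u <- e / len
    v <- c(-u[2L], u[1L])
    pu <- hull %*% u
    pv <- hull %*% v
    a <- (max(pu) - min(pu)) * (max(pv) - min(pv))
    if (a < best) best <- a
  }
  best
}

# smallest enclosing circle, O(n^3)-worst incremental on the convex hull
# (hulls of digital contours are small, so exactness beats asymptotics)
smallestEnclosingCircle <- function(pts) {
  hull <- pts[grDevices::chull(pts[, 2L], pts[, 1L]), , drop = FALSE]
  n <- nrow(hull)
  circ2 <- function(a, b) {
    ctr <- (a + b) / 2
    list(c = ctr, r2 = sum((a - ctr)^2))
  }
  circ3 <- function(a, b, c) {
    # circumcircle via perpendicular bisector intersection
    d <- 2 * (a[1L] * (b[2L] - c[2L]) + b[1L] * (c[2L] - a[2L]) +
              c[1L] * (a[2L] - b[2L]))
    if (abs(d) < 1e-12) return(NULL)
    ux <- (sum(a^2) * (b[2L] - c[2L]) + sum(b^2) * (c[2L] - a[2L]) +
           sum(c^2) * (a[2L] - b[2L])) / d
    uy <- (sum(a^2) * (c[1L] - b[1L]) + sum(b^2) * (a[1L] - c[1L]) +
           sum(c^2) * (b[1L] - a[1L])) / d
    ctr <- c(ux, uy)
    list(c = ctr, r2 = sum((a - ctr)^2))
  }
  inC <- function(cc, p) sum((p - cc$c)^2) <= cc$r2 * (1 + 1e-10) + 1e-10
  if (n == 1L) return(list(c = hull[1L, ], r = 0))
  cc <- circ2(hull[1L, ], hull[2L, ])
  if (n >= 3L) for (i in 3:n) {
    p <- hull[i, ]
    if (inC(cc, p)) next
    cc <- circ2(hull[1L, ], p)
    for (j in 2:(i - 1L)) {
      q <- hull[j, ]
      if (inC(cc, q)) next
      cc <- circ2(p, q)
      for (k in seq_len(j - 1L)) {
        r <- hull[k, ]
        if (inC(cc, r)) next
        c3 <- circ3(p, q, r)
        if (!is.null(c3)) cc <- c3
      }
    }
  }
  list(c = cc$c, r = sqrt(cc$r2))
}

#' Basic size and shape descriptors
#'
#' `Area` is the mask pixel count; `ContLength` the traced contour length
#' (diagonal steps count sqrt(2)); `Diameter` the maximum pairwise
#' distance between contour points; `Radius` the radius of the smallest
#' circle enclosing the contour; `Convexity` the ratio of `Area` to the
#' area of the convex hull of the mask (hull taken over pixel corners);
#' `Rectangularity` the ratio of `Area` to the area of the minimum-area
#' enclosing rectangle; `Circularity = Area / (pi * maxdist^2)` with
#' `maxdist` the maximum contour-to-centroid distance (a circle-similarity
#' score bounded by ~1).
#'
#' @param region a [NucleusRegion-class].
#' @return List with `Area`, `ContLength`, `Diameter`, `Radius`,
#'   `Convexity`, `Rectangularity`, `Circularity`.
#' @export
basicShape <- function(region) {
  mc <- maskCoords(region)
  cn <- contourCoords(region)
  area <- nrow(mc)
  ctr <- centroid(region)
  hullPts <- cn[grDevices::chull(cn[, 2L], cn[, 1L]), , drop = FALSE]
  diam <- if (nrow(hullPts) >= 2L)
    sqrt(max(stats::dist(hullPts)^2)) else 0
  sec <- smallestEnclosingCircle(cn)
  chull2 <- cornerHull(mc)
  hullArea <- polygonArea(chull2)
  rectArea <- minAreaRectangle(chull2)
  maxd <- sqrt(max((cn[, 1L] - ctr[1L])^2 + (cn[, 2L] - ctr[2L])^2))
  list(Area = area,
       ContLength = contourLength(cn),
       Diameter = diam,
       Radius = sec$r,
       Convexity = if (hullArea > 0) area / hullArea else 1,
       Rectangularity = if (rectArea > 0) area / rectArea else 1,
       Circularity = if (maxd > 0) area / (pi * maxd^2) else 1)
}

#' All 20 morphologic features of a nucleus
#'
#' Aggregates [basicShape()], [contourDistanceStats()] (with
#' [roundness()] and [sides()]), [compactness()], [regionMoments()],
#' [principalMoments()] and [ellipseShapeFactors()] into one named list.
#' Deterministic for a fixed region.
#'
#' @param region a [NucleusRegion-class].
#' @param umPerPx physical scale (micrometres per pixel). Scales `Area`
#'   (squared), `ContLength`, `Diameter` and `Radius`; all other features
#'   are dimensionless. Default 1 (report in pixels).
#' @return Named list of the 20 morphologic features.
#' @export
extractMorphology <- function(region, umPerPx = 1) {
  bs <- basicShape(region)
  st <- contourDistanceStats(region)
  mom <- regionMoments(region)
  pm <- principalMoments(mom$M20, mom$M02, mom$M11)
  esf <- ellipseShapeFactors(region)
  list(
    Area = bs$Area * umPerPx^2,
    Circularity = bs$Circularity,
    Distance = st$Distance,
    Sigma = st$Sigma,
    Roundness = roundness(st$Distance, st$Sigma),
    Sides = sides(st$Distance, st$Sigma),
    Convexity = bs$Convexity,
    M11 = mom$M11,
    M20 = mom$M20,
    M02 = mom$M02,
    Ia = pm[["Ia"]],
    Ib = pm[["Ib"]],
    Compactness = compactness(bs$ContLength, bs$Area),
    ContLength = bs$ContLength * umPerPx,
    Diameter = bs$Diameter * umPerPx,
    Radius = bs$Radius * umPerPx,
    Rectangularity = bs$Rectangularity,
    Anisometry = esf$Anisometry,
    Bulkiness = esf$Bulkiness,
    StructureFactor = esf$StructureFactor)
}
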