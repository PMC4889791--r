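# Morphologic features: contour statistics, moments, shape factors.

test_that("contour distances of a rasterized circle are tight around the radius", {
  reg <- diskRegion(20)
  st <- contourDistanceStats(reg)
  expect_equal(st$Distance, 20, tolerance = 0.5 / 20)
  expect_lte(st$Sigma, 0.5)
  expect_error(contourDistanceStats(regionFromMask(matrix(c(TRUE), 1, 1))),
               "degenerate")
})

test_that("square contour distance matches direct summation and the analytic mean", {
  a <- 15   # half side
  reg <- rectRegion(2 * a, 2 * a)
  st <- contourDistanceStats(reg)
  # direct summation over the traced contour points
  cn <- contourCoords(reg); ctr <- centroid(reg)
  d <- sqrt((cn[, 1] - ctr[1])^2 + (cn[, 2] - ctr[2])^2)
  expect_equal(st$Distance, mean(d))
  expect_equal(st$Sigma, sqrt(mean((d - mean(d))^2)))
  # analytic mean boundary distance of a continuous square whose side
  # spans the pixel centers (effective half side a - 1/2)
  analytic <- (a - 0.5) * (sqrt(2) + log(1 + sqrt(2))) / 2
  expect_equal(st$Distance, analytic, tolerance = 0.01)
})

test_that("roundness and sides reproduce closed-form values", {
  expect_equal(roundness(17.397, 1.16761), 0.932884, tolerance = 1e-6)
  expect_equal(roundness(15.8119, 5.60155), 0.645737, tolerance = 1e-5)
  expect_equal(roundness(10, 0), 1)
  expect_error(roundness(0, 1), "> 0")

  expect_equal(sides(17.397, 1.16761), 5.05552, tolerance = 1e-5)
  expect_equal(sides(10.2599, 0.546327), 5.63962, tolerance = 1e-5)
  expect_equal(sides(3, 3), 1.4111)
  expect_identical(sides(10, 0), Inf)
  # strictly increasing in distance/sigma
  ratios <- seq(1, 20, by = 0.5)
  vals <- sides(ratios, 1)
  expect_true(all(diff(vals) > 0))
})

test_that("compactness reproduces closed-form values and the circle limit", {
  expect_equal(compactness(256.35, 972), 5.38011, tolerance = 1e-5)
  expect_equal(compactness(121.983, 1071), 1.1056, tolerance = 1e-4)
  r <- 5
  expect_equal(compactness(2 * pi * r, pi * r^2), 1)
  expect_error(compactness(0, 10), "> 0")
})

test_that("region moments match brute-force summation and closed forms", {
  single <- regionFromMask(matrix(TRUE, 1, 1))
  m1 <- regionMoments(single)
  expect_equal(c(m1$M20, m1$M02, m1$M11), c(0, 0, 0))

  # horizontal 1 x n segment: x = column varies
  n <- 9
  seg <- regionFromMask(rectMask(1, n))
  ms <- regionMoments(seg)
  expect_equal(ms$M20, n * (n^2 - 1) / 12)
  expect_equal(ms$M02, 0)
  expect_equal(ms$M11, 0)

  blob <- blobRegion(20, seed = 17)
  mb <- regionMoments(blob)
  mc <- maskCoords(blob)
  M20 <- 0; M02 <- 0; M11 <- 0
  xb <- mean(mc[, 2]); yb <- mean(mc[, 1])
  for (i in seq_len(nrow(mc))) {
    dx <- mc[i, 2] - xb; dy <- mc[i, 1] - yb
    M20 <- M20 + dx^2; M02 <- M02 + dy^2; M11 <- M11 + dx * dy
  }
  expect_equal(mb$M20, M20); expect_equal(mb$M02, M02)
  expect_equal(mb$M11, M11)
  expect_equal(mb$h, (M20 + M02) / 2)
})

test_that("principal moments equal the 2x2 eigenvalues and satisfy the trace identity", {
  pm <- principalMoments(105447, 79455.2, 5434.79)
  expect_equal(pm[["Ia"]], 106538, tolerance = 1 / 106538)
  expect_equal(pm[["Ib"]], 78364.5, tolerance = 1 / 78364.5)

  expect_equal(principalMoments(4, 4, 0), c(Ia = 4, Ib = 4))

  set.seed(23)
  for (i in 1:25) {
    m20 <- runif(1, 0, 1e5); m02 <- runif(1, 0, 1e5)
    m11 <- runif(1, -1, 1) * sqrt(m20 * m02)   # valid moment sets
    pm <- principalMoments(m20, m02, m11)
    ev <- eigen(matrix(c(m20, m11, m11, m02), 2, 2), symmetric = TRUE)$values
    expect_equal(unname(pm), ev, tolerance = 1e-10)
    expect_equal(sum(pm), m20 + m02)           # trace identity
    expect_gte(pm[["Ia"]], pm[["Ib"]])
  }
})

test_that("ellipse shape factors: identity, isotropy, axis-ratio recovery", {
  for (seed in 1:5) {
    reg <- blobRegion(60, seed = seed)
    esf <- ellipseShapeFactors(reg)
    expect_identical(esf$StructureFactor,
                     esf$Anisometry * esf$Bulkiness - 1)
    expect_gte(esf$Anisometry, 1)
  }
  disk <- diskRegion(15)
  esf <- ellipseShapeFactors(disk)
  expect_equal(esf$Anisometry, 1, tolerance = 0.02)
  expect_equal(esf$Bulkiness, 1, tolerance = 0.02)

  ell <- regionFromMask(ellipseMask(40, 10))
  expect_equal(ellipseShapeFactors(ell)$Anisometry, 4, tolerance = 0.12)
})

test_that("basic shape descriptors behave on rectangles and disks", {
  rect <- rectRegion(20, 34)
  bs <- basicShape(rect)
  expect_gte(bs$Rectangularity, 0.95); expect_lte(bs$Rectangularity, 1.0)
  expect_gte(bs$Convexity, 0.95); expect_lte(bs$Convexity, 1.0)

  r <- 12
  disk <- diskRegion(r)
  bd <- basicShape(disk)
  expect_gte(bd$Diameter, 2 * r - 2); expect_lte(bd$Diameter, 2 * r + 2)
  expect_gte(bd$Circularity, 0.9); expect_lte(bd$Circularity, 1.0)
  # enclosing circle: contains every contour point, radius near r
  cn <- contourCoords(disk)
  expect_gte(bd$Radius, max(sqrt((cn[, 1] - centroid(disk)[1])^2 +
                                 (cn[, 2] - centroid(disk)[2])^2)) - 1e-6)
  expect_lte(bd$Radius, r + 1)
})

test_that("diameter equals the brute-force max over contour point pairs", {
  for (seed in c(2, 31)) {
    reg <- blobRegion(40, seed = seed)
    cn <- contourCoords(reg)
    best <- 0
    for (i in seq_len(nrow(cn) - 1)) for (j in (i + 1):nrow(cn)) {
      d <- sqrt(sum((cn[i, ] - cn[j, ])^2))
      if (d > best) best <- d
    }
    expect_equal(basicShape(reg)$Diameter, best)
  }
})

test_that("compactness of rasterized convex shapes respects the digital bound", {
  shapes <- list(diskRegion(10), rectRegion(12, 12), rectRegion(8, 25),
                 regionFromMask(ellipseMask(14, 8)))
  for (reg in shapes) {
    bs <- basicShape(reg)
    expect_gte(compactness(bs$ContLength, bs$Area), 0.9)
  }
})

test_that("roundness and sides are scale invariant; 90-degree rotation is exact", {
  small <- regionFromMask(ellipseMask(20, 13, angle = 0.4))
  big <- regionFromMask(ellipseMask(40, 26, angle = 0.4))
  fs <- extractMorphology(small); fb <- extractMorphology(big)
  expect_lt(abs(fs$Roundness - fb$Roundness) / abs(fs$Roundness), 0.02)
  expect_lt(abs(fs$Sides - fb$Sides) / abs(fs$Sides), 0.02)

  m <- ellipseMask(15, 9, angle = 0.3)
  rot <- t(m)[ncol(m):1, ]                 # exact 90-degree rotation
  f0 <- extractMorphology(regionFromMask(m))
  f90 <- extractMorphology(regionFromMask(rot))
  expect_identical(f0$Area, f90$Area)
  expect_equal(f0$Roundness, f90$Roundness)
  expect_equal(f0$Anisometry, f90$Anisometry)
  expect_equal(f0$Compactness, f90$Compactness)
})

test_that("arbitrary rotation changes shape features by under 3% on large shapes", {
  f0 <- extractMorphology(regionFromMask(ellipseMask(25, 14, angle = 0)))
  f1 <- extractMorphology(regionFromMask(ellipseMask(25, 14, angle = 0.7)))
  for (nm in c("Area", "Roundness", "Anisometry", "Compactness")) {
    expect_lt(abs(f0[[nm]] - f1[[nm]]) / abs(f0[[nm]]), 0.03)
  }
})

test_that("extractMorphology aggregates consistently", {
  disk <- diskRegion(14)
  f <- extractMorphology(disk)
  expect_named(f, c("Area", "Circularity", "Distance", "Sigma", "Roundness",
                    "Sides", "Convexity", "M11", "M20", "M02", "Ia", "Ib",
                    "Compactness", "ContLength", "Diameter", "Radius",
                    "Rectangularity", "Anisometry", "Bulkiness",
                    "StructureFactor"))
  expect_gt(f$Roundness, 0.95)
  expect_lt(f$StructureFactor, 0.05)
  expect_lt(f$Compactness, 1.2)
  expect_identical(f$StructureFactor, f$Anisometry * f$Bulkiness - 1)
  expect_equal(f$Ia + f$Ib, f$M20 + f$M02)
  # physical scaling applies to lengths and areas only
  fu <- extractMorphology(disk, umPerPx = 0.5)
  expect_equal(fu$Area, f$Area * 0.25)
  expect_equal(fu$ContLength, f$ContLength * 0.5)
  expect_equal(fu$Roundness, f$Roundness)
})
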