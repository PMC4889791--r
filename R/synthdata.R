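# Seeded synthetic grayscale cell images with ground-truth masks, standing
# in for stained liquid-based-cytology crops: four coarse classes
# (epithelial, lymphoid, neutrophil, junk) and two epithelial subtypes
# (normal, abnormal). Class recipes target the published inter-class
# ordering of nuclear area, shape regularity and intensity statistics;
# exact physical values are not emulated (1 px = 1 unit).

# evaluate code under a fixed seed, restoring the caller's RNG state
withSeed <- function(seed, code) {
  if (exists(".Random.seed", envir = .GlobalEnv, inherits = FALSE)) {
    old <- get(".Random.seed", envir = .GlobalEnv)
    on.exit(assign(".Random.seed", old, envir = .GlobalEnv))
  } else {
    on.exit(rm(".Random.seed", envir = .GlobalEnv), add = TRUE)
  }
  set.seed(as.integer(seed %% .Machine$integer.max))
  force(code)
}

#' Default class recipes
#'
#' One recipe per cell class, chosen to reproduce the characteristic
#' inter-class ordering of stained cervical-cytology nuclei: lymphoid
#' nuclei are small, round and darkly stained; neutrophils small and
#' 2-3-lobed; junk objects (debris, clumps) large with very irregular
#' boundaries; normal epithelial nuclei medium-sized and regular;
#' abnormal epithelial nuclei much larger with coarse, granular
#' chromatin. Fields per recipe: `name`, `coarse`, `fine`, `areaMean` /
#' `areaSd` (px^2), `shape` (`ellipse` / `lobed` / `irregular`),
#' `axisRatioMean` / `axisRatioSd`, `boundaryNoise` (radial perturbation
#' amplitude), `intensityMean` / `intensityMeanSd` (8-bit gray, cell
#' mean), `interiorSd` (within-nucleus pixel sd), `grain` (`smooth` /
#' `granular`).
#'
#' @return Named list of five recipes: `lymphoid`, `neutrophil`, `junk`,
#'   `normal-epithelial`, `abnormal-epithelial`.
#' @export
defaultRecipes <- function() {
  recipe <- function(name, coarse, fine, areaMean, areaSd, shape,
                     axisRatioMean, axisRatioSd, boundaryNoise,
                     intensityMean, intensityMeanSd, interiorSd, grain) {
    list(name = name, coarse = coarse, fine = fine, areaMean = areaMean,
         areaSd = areaSd, shape = shape, axisRatioMean = axisRatioMean,
         axisRatioSd = axisRatioSd, boundaryNoise = boundaryNoise,
         intensityMean = intensityMean, intensityMeanSd = intensityMeanSd,
         interiorSd = interiorSd, grain = grain)
  }
  list(
    "lymphoid" = recipe("lymphoid", "lymphoid", NA_character_,
      403, 55, "ellipse", 1.05, 0.03, 0.02, 80, 6, 28, "granular"),
    "neutrophil" = recipe("neutrophil", "neutrophil", NA_character_,
      342, 50, "lobed", 1.30, 0.10, 0.04, 100, 6, 28, "granular"),
    "junk" = recipe("junk", "junk", NA_character_,
      972, 240, "irregular", 1.35, 0.15, 0.30, 128, 10, 24, "granular"),
    "normal-epithelial" = recipe("normal-epithelial", "epithelial",
      "normal", 538, 75, "ellipse", 1.25, 0.08, 0.035, 118, 6, 24,
      "smooth"),
    "abnormal-epithelial" = recipe("abnormal-epithelial", "epithelial",
      "abnormal", 2455, 330, "ellipse", 1.10, 0.04, 0.012, 123, 6, 34,
      "granular"))
}

# smooth a matrix with a 3x3 box mean (replicate borders)
boxSmooth3 <- function(m) {
  mp <- padReplicate(m, 1L)
  nr <- nrow(m); nc <- ncol(m)
  acc <- matrix(0, nr, nc)
  for (dr in 0:2) for (dc in 0:2)
    acc <- acc + mp[(1L + dr):(nr + dr), (1L + dc):(nc + dc)]
  acc / 9
}

# radial perturbation factor f(theta) = 1 + a * sum_k c_k cos(k theta + phi_k),
# harmonics k = 2..6 with unit-norm seeded coefficients, clamped >= 0.25
radialFactor <- function(theta, a, coefs, phases) {
  f <- rep(1, length(theta))
  ks <- seq_along(coefs) + 1L
  for (i in seq_along(ks))
    f <- f + a * coefs[i] * cos(ks[i] * theta + phases[i])
  pmax(f, 0.25)
}

#' Render one synthetic nucleus
#'
#' The shape is an ellipse with a seeded radial boundary perturbation
#' (`radius(theta) = R * (1 + a * sum c_k cos(k theta + phi_k))`,
#' harmonics k = 2..6); the `lobed` family is a union of 2-3 overlapping
#' ellipses and the `irregular` family a high-amplitude perturbation. The
#' interior is filled with Gaussian intensities; `grain = "smooth"`
#' low-pass filters the noise field, `"granular"` leaves it pixelwise.
#' Deterministic for a fixed seed.
#'
#' @param recipe a recipe from [defaultRecipes()] (fields may be
#'   overridden).
#' @param seed integer seed for this cell.
#' @return List with `mask` (logical matrix), `patch` (numeric intensity
#'   matrix, meaningful inside the mask) and `area` (pixels).
#' @export
renderCell <- function(recipe, seed) {
  if (recipe$areaMean < 9) stop("degenerate recipe: area mean < 9 px")
  withSeed(seed, {
    A <- max(25, stats::rnorm(1, recipe$areaMean, recipe$areaSd))
    ratio <- max(1, stats::rnorm(1, recipe$axisRatioMean,
                                 recipe$axisRatioSd))
    rot <- stats::runif(1, 0, 2 * pi)
    a <- recipe$boundaryNoise
    coefs <- stats::runif(5, -1, 1)
    coefs <- coefs / sqrt(sum(coefs^2))
    phases <- stats::runif(5, 0, 2 * pi)
    p <- sqrt(A * ratio / pi)       # major semi-axis
    q <- p / ratio
    H <- ceiling(p * (1 + 2.5 * a)) + 2L
    n <- 2L * H + 1L
    dr <- matrix(rep(-H:H, n), n, n)
    dc <- t(dr)
    xr <- cos(rot) * dc + sin(rot) * dr
    yr <- -sin(rot) * dc + cos(rot) * dr
    if (recipe$shape == "lobed") {
      nl <- sample(2:3, 1)
      lobeA <- A / nl * 1.45
      pl <- sqrt(lobeA * 1.15 / pi); ql <- pl / 1.15
      d0 <- 0.75 * pl
      angs <- stats::runif(1, 0, 2 * pi) + 2 * pi * seq_len(nl) / nl
      mask <- matrix(FALSE, n, n)
      for (i in seq_len(nl)) {
        cx <- d0 * cos(angs[i]); cy <- d0 * sin(angs[i])
        mask <- mask | (((xr - cx) / pl)^2 + ((yr - cy) / ql)^2 <= 1)
      }
    } else {
      rr <- sqrt((xr / p)^2 + (yr / q)^2)
      theta <- atan2(yr / q, xr / p)
      mask <- rr <= radialFactor(theta, a, coefs, phases)
    }
    mu <- stats::rnorm(1, recipe$intensityMean, recipe$intensityMeanSd)
    noise <- matrix(stats::rnorm(n * n, 0, recipe$interiorSd), n, n)
    if (recipe$grain == "smooth") noise <- boxSmooth3(noise) * 1.6
    patch <- pmin(pmax(round(mu + noise), 0), 210)
    list(mask = mask, patch = patch, area = sum(mask))
  })
}

#' Generate a seeded synthetic dataset
#'
#' `layout = "isolated"` renders each cell on its own small canvas;
#' `layout = "scattered"` places several cells per larger canvas without
#' mask overlap (bounded retries, then error). Backgrounds are light and
#' noisy (Gaussian around 230, sd 8, clipped), emulating a clean
#' liquid-based-cytology background. Class balance is exact and the whole
#' dataset is a pure function of `(recipes, nPerClass, seed)`.
#'
#' @param nPerClass cells per class (>= 1).
#' @param seed master integer seed.
#' @param layout `"isolated"` (default) or `"scattered"`.
#' @param recipes named list of recipes, default [defaultRecipes()].
#' @param canvas canvas side for the scattered layout (default 300).
#' @param cellsPerScene cells per scattered scene (default 8).
#' @return List of scenes; each scene is a list with `image`
#'   ([GrayImage-class]), `masks` (list of logical matrices), `coarse`,
#'   `fine` (character vectors per cell), `class` (full class names) and
#'   `seed`.
#' @export
generateDataset <- function(nPerClass, seed = 1L,
                            layout = c("isolated", "scattered"),
                            recipes = defaultRecipes(), canvas = 300L,
                            cellsPerScene = 8L) {
  layout <- match.arg(layout)
  if (nPerClass < 1L) stop("'nPerClass' must be >= 1")
  classes <- names(recipes)
  total <- nPerClass * length(classes)
  cellSeeds <- withSeed(seed, sample.int(2^30, total))
  cellClass <- rep(classes, each = nPerClass)
  bgFor <- function(n, m, sd = 8, bgSeed) withSeed(bgSeed, {
    pmin(pmax(round(matrix(stats::rnorm(n * m, 230, sd), n, m)), 0), 255)
  })
  if (layout == "isolated") {
    scenes <- vector("list", total)
    for (i in seq_len(total)) {
      rc <- recipes[[cellClass[i]]]
      cell <- renderCell(rc, cellSeeds[i])
      n <- nrow(cell$mask)
      margin <- 10L
      N <- n + 2L * margin
      img <- bgFor(N, N, bgSeed = cellSeeds[i] + 1)
      sel <- (margin + 1L):(margin + n)
      sub <- img[sel, sel]
      sub[cell$mask] <- cell$patch[cell$mask]
      img[sel, sel] <- sub
      mask <- matrix(FALSE, N, N)
      mask[sel, sel] <- cell$mask
      scenes[[i]] <- list(image = grayImage(img), masks = list(mask),
                          coarse = rc$coarse, fine = rc$fine,
                          class = rc$name, seed = cellSeeds[i])
    }
    return(scenes)
  }
  # scattered: fixed canvas, sequential placement without mask overlap
  order <- withSeed(seed + 1, sample(total))
  nScenes <- ceiling(total / cellsPerScene)
  scenes <- vector("list", nScenes)
  k <- 0L
  for (s in seq_len(nScenes)) {
    idx <- order[(k + 1L):min(k + cellsPerScene, total)]
    k <- k + length(idx)
    img <- bgFor(canvas, canvas, bgSeed = seed + 1000 + s)
    occupied <- matrix(FALSE, canvas, canvas)
    masks <- list(); coarse <- character(0); fine <- character(0)
    cls <- character(0)
    for (i in idx) {
      rc <- recipes[[cellClass[i]]]
      cell <- renderCell(rc, cellSeeds[i])
      n <- nrow(cell$mask)
      placed <- FALSE
      tries <- withSeed(cellSeeds[i] + 2,
        cbind(sample.int(canvas - n - 2L, 60, replace = TRUE),
              sample.int(canvas - n - 2L, 60, replace = TRUE)))
      for (t in seq_len(nrow(tries))) {
        r0 <- tries[t, 1L]; c0 <- tries[t, 2L]
        rows <- r0:(r0 + n - 1L); cols <- c0:(c0 + n - 1L)
        if (any(occupied[rows, cols] & cell$mask)) next
        sub <- img[rows, cols]
        sub[cell$mask] <- cell$patch[cell$mask]
        img[rows, cols] <- sub
        occ <- occupied[rows, cols]
        occupied[rows, cols] <- occ | cell$mask
        mask <- matrix(FALSE, canvas, canvas)
        mask[rows, cols] <- cell$mask
        masks <- c(masks, list(mask))
        coarse <- c(coarse, rc$coarse); fine <- c(fine, rc$fine)
        cls <- c(cls, rc$name)
        placed <- TRUE
        break
      }
      if (!placed)
        stop("could not place a cell without overlap; use a larger canvas")
    }
    scenes[[s]] <- list(image = grayImage(img), masks = masks,
                        coarse = coarse, fine = fine, class = cls,
                        seed = seed + s)
  }
  scenes
}
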