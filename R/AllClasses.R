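#' @import methods
NULL

#' GrayImage: an 8-bit grayscale image
#'
#' A `GrayImage` is a numeric matrix of integer-valued intensities in
#' \[0, 255\], row index increasing downward, 0-based intensities. It is the
#' unit of all imaging operations in the package. The class extends
#' `matrix`, so ordinary subsetting and arithmetic work; use
#' [grayImage()] to construct one with validation.
#'
#' @slot .Data numeric matrix of intensities in \[0, 255\].
#' @seealso [grayImage()], [readGrayImage()]
#' @export
setClass("GrayImage", contains = "matrix", validity = function(object) {
  m <- object@.Data
  if (!is.numeric(m)) return("intensities must be numeric")
  if (length(m) == 0L || nrow(m) < 1L || ncol(m) < 1L)
    return("image must have height and width >= 1")
  if (anyNA(m)) return("intensities must not contain NA")
  if (min(m) < 0 || max(m) > 255) return("intensities must lie in [0, 255]")
  if (max(abs(m - round(m))) > 1e-8) return("intensities must be integer-valued")
  TRUE
})

#' Construct a GrayImage
#'
#' @param x numeric matrix with integer-valued entries in \[0, 255\].
#' @return A [GrayImage-class] object.
#' @examples
#' img <- grayImage(matrix(128, 8, 8))
#' @export
grayImage <- function(x) {
  if (is(x, "GrayImage")) return(x)
  if (!is.matrix(x)) stop("'x' must be a matrix")
  new("GrayImage", x)
}

setMethod("show", "GrayImage", function(object) {
  m <- object@.Data
  cat(sprintf("GrayImage %d x %d, intensity range [%d, %d]\n",
              nrow(m), ncol(m), as.integer(min(m)), as.integer(max(m))))
})

#' NucleusRegion: a segmented nucleus
#'
#' Holds the pixel mask, the ordered closed boundary contour (Moore-traced,
#' 8-connected, clockwise from the topmost-then-leftmost boundary pixel),
#' the centroid (mean of mask coordinates) and an integer region label.
#' All coordinates are (row, col), 1-based, row increasing downward.
#'
#' @slot mask integer matrix, one (row, col) pair per mask pixel.
#' @slot contour integer matrix, ordered closed boundary (row, col) pairs;
#'   consecutive points (and last-to-first) are 8-adjacent.
#' @slot centroid numeric length-2 (row, col), mean of the mask coordinates.
#' @slot label integer region identifier.
#' @seealso [segmentNuclei()], [regionFromMask()]
#' @export
setClass("NucleusRegion",
  representation(mask = "matrix", contour = "matrix",
                 centroid = "numeric", label = "integer"),
  validity = function(object) {
    if (nrow(object@mask) < 1L) return("mask must be non-empty")
    if (ncol(object@mask) != 2L || ncol(object@contour) != 2L)
      return("mask and contour must be 2-column (row, col) matrices")
    if (length(object@centroid) != 2L) return("centroid must have length 2")
    ctr <- colMeans(object@mask)
    if (max(abs(ctr - object@centroid)) > 1e-8)
      return("centroid must equal the mean of the mask coordinates")
    cn <- object@contour
    if (nrow(cn) > 1L) {
      nxt <- rbind(cn[-1L, , drop = FALSE], cn[1L, , drop = FALSE])
      step <- abs(nxt - cn)
      if (max(step) > 1L)
        return("consecutive contour points must be 8-adjacent (closed)")
    }
    TRUE
  })

setMethod("show", "NucleusRegion", function(object) {
  cat(sprintf(
    "NucleusRegion #%d: area %d px, %d contour points, centroid (%.2f, %.2f)\n",
    object@label, nrow(object@mask), nrow(object@contour),
    object@centroid[1L], object@centroid[2L]))
})

#' @rdname NucleusRegion-accessors
#' @export
setGeneric("maskCoords", function(object) standardGeneric("maskCoords"))
#' @rdname NucleusRegion-accessors
#' @export
setGeneric("contourCoords", function(object) standardGeneric("contourCoords"))
#' @rdname NucleusRegion-accessors
#' @export
setGeneric("centroid", function(object) standardGeneric("centroid"))
#' @rdname NucleusRegion-accessors
#' @export
setGeneric("regionLabel", function(object) standardGeneric("regionLabel"))

#' Accessors for NucleusRegion
#'
#' `maskCoords()` returns the (row, col) pixel coordinates of the mask,
#' `contourCoords()` the ordered closed boundary, `centroid()` the (row,
#' col) centroid and `regionLabel()` the integer label.
#'
#' @param object a [NucleusRegion-class].
#' @name NucleusRegion-accessors
#' @export
setMethod("maskCoords", "NucleusRegion", function(object) object@mask)
#' @rdname NucleusRegion-accessors
#' @export
setMethod("contourCoords", "NucleusRegion", function(object) object@contour)
#' @rdname NucleusRegion-accessors
#' @export
setMethod("centroid", "NucleusRegion", function(object) object@centroid)
#' @rdname NucleusRegion-accessors
#' @export
setMethod("regionLabel", "NucleusRegion", function(object) object@label)

#' CascadeModel: the trained two-level classifier
#'
#' Level 1 is a gain-ratio decision tree assigning the coarse class
#' (epithelial / lymphoid / neutrophil / junk); level 2 is a penalized
#' logistic regression separating normal from abnormal epithelial nuclei.
#' `rates` holds the per-level correct rates (c1, c2) measured on held-out
#' data, whose product is the composed cascade rate (see [composeRates()]).
#'
#' @slot level1 a `gainRatioTree` fitted by [trainTree()].
#' @slot level2 a `ridgeLogistic` fitted by [trainLogistic()].
#' @slot rates numeric, named per-level correct rates (possibly empty until
#'   evaluated).
#' @slot config list of the hyperparameters and seed used for training.
#' @export
setClass("CascadeModel",
  representation(level1 = "list", level2 = "list",
                 rates = "numeric", config = "list"),
  validity = function(object) {
    if (!all(c("root", "classes") %in% names(object@level1)))
      return("level1 must be a gain-ratio tree (root + classes)")
    if (!all(c("coef", "center", "scale") %in% names(object@level2)))
      return("level2 must be a logistic model (coef + standardization)")
    if (length(object@rates) &&
        (min(object@rates) < 0 || max(object@rates) > 1))
      return("rates must lie in [0, 1]")
    TRUE
  })

setMethod("show", "CascadeModel", function(object) {
  cat("CascadeModel\n")
  cat(sprintf("  level 1: gain-ratio tree, %d leaves, classes: %s\n",
              countLeaves(object@level1$root),
              paste(object@level1$classes, collapse = ", ")))
  cat(sprintf("  level 2: logistic regression (lambda = %g), positive: %s\n",
              object@level2$lambda, object@level2$positive))
  if (length(object@rates))
    cat(sprintf("  held-out stage rates: %s -> composed %.5f\n",
                paste(sprintf("%.5f", object@rates), collapse = ", "),
                prod(object@rates)))
})
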