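# Two-level cascade classifier: a gain-ratio (C4.5-style) decision tree
# for the rough classes (epithelial / lymphoid / neutrophil / junk),
# followed by an L2-penalized logistic regression separating normal from
# abnormal epithelial nuclei. All 28 features are continuous, so the tree
# uses binary threshold splits with candidate cuts at midpoints between
# consecutive distinct sorted values.

entropyOf <- function(counts) {
  p <- counts[counts > 0] / sum(counts)
  -sum(p * log2(p))
}

# best (threshold, gain ratio) for one feature column; vectorized over all
# candidate cuts. Returns NULL when no admissible split exists.
bestSplitForFeature <- function(x, yInt, nClass, minLeaf) {
  o <- order(x)
  xs <- x[o]; ys <- yInt[o]
  n <- length(x)
  cuts <- which(xs[-n] < xs[-1L])
  if (!length(cuts)) return(NULL)
  # cumulative class counts at each prefix
  cum <- vapply(seq_len(nClass), function(k) cumsum(ys == k), numeric(n))
  cum <- matrix(cum, nrow = n)
  total <- cum[n, ]
  H <- entropyOf(total)
  nl <- cuts
  nr <- n - nl
  ok <- nl >= minLeaf & nr >= minLeaf
  if (!any(ok)) return(NULL)
  cuts <- cuts[ok]; nl <- nl[ok]; nr <- nr[ok]
  lC <- cum[cuts, , drop = FALSE]
  rC <- matrix(total, nrow(lC), nClass, byrow = TRUE) - lC
  entRows <- function(M, nn) {
    p <- M / nn
    e <- ifelse(p > 0, -p * log2(p), 0)
    rowSums(e)
  }
  Hl <- entRows(lC, nl)
  Hr <- entRows(rC, nr)
  gain <- H - (nl / n) * Hl - (nr / n) * Hr
  pl <- nl / n
  splitInfo <- -(pl * log2(pl) + (1 - pl) * log2(1 - pl))
  gr <- ifelse(splitInfo > 0 & gain > 1e-12, gain / splitInfo, -Inf)
  if (all(gr == -Inf)) return(NULL)
  b <- which.max(gr)          # which.max takes the first (lowest threshold)
  thr <- (xs[cuts[b]] + xs[cuts[b] + 1L]) / 2
  list(threshold = thr, gainRatio = gr[b], gain = gain[b])
}

growNode <- function(X, yInt, nClass, minLeaf, maxDepth, depth) {
  counts <- tabulate(yInt, nClass)
  leaf <- function() list(leaf = TRUE, n = sum(counts),
                          probs = counts / sum(counts))
  if (sum(counts > 0) < 2L || depth >= maxDepth || sum(counts) < 2L * minLeaf)
    return(leaf())
  best <- NULL; bestJ <- 0L
  for (j in seq_len(ncol(X))) {
    sp <- bestSplitForFeature(X[, j], yInt, nClass, minLeaf)
    if (is.null(sp)) next
    if (is.null(best) || sp$gainRatio > best$gainRatio + 1e-12) {
      best <- sp; bestJ <- j
    }
  }
  if (is.null(best)) return(leaf())
  left <- X[, bestJ] <= best$threshold
  list(leaf = FALSE, feature = colnames(X)[bestJ], index = bestJ,
       threshold = best$threshold, gainRatio = best$gainRatio,
       n = sum(counts),
       left = growNode(X[left, , drop = FALSE], yInt[left], nClass,
                       minLeaf, maxDepth, depth + 1L),
       right = growNode(X[!left, , drop = FALSE], yInt[!left], nClass,
                        minLeaf, maxDepth, depth + 1L))
}

countLeaves <- function(node) {
  if (node$leaf) 1L else countLeaves(node$left) + countLeaves(node$right)
}

#' Train a gain-ratio decision tree
#'
#' C4.5-style induction on continuous features: at each node the binary
#' threshold split maximizing the information gain ratio (information gain
#' divided by the split's intrinsic information) is chosen, with candidate
#' thresholds at midpoints between consecutive distinct sorted values.
#' Growth stops at `minLeaf`, `maxDepth` or zero gain; leaves store class
#' proportions. Ties in gain ratio are broken toward the lower feature
#' index, then the lower threshold, making training deterministic.
#'
#' @param X numeric matrix or data frame of features (no missing values).
#' @param y factor of class labels.
#' @param minLeaf minimum samples in each child (default 5).
#' @param maxDepth maximum tree depth (default 12).
#' @return A `gainRatioTree` (list with `root`, `classes`, `features`).
#' @export
trainTree <- function(X, y, minLeaf = 5L, maxDepth = 12L) {
  X <- as.matrix(X)
  if (anyNA(X)) stop("missing feature values are not supported")
  y <- factor(y)
  yInt <- as.integer(y)
  root <- growNode(X, yInt, nlevels(y), as.integer(minLeaf),
                   as.integer(maxDepth), 0L)
  structure(list(root = root, classes = levels(y),
                 features = colnames(X), minLeaf = minLeaf,
                 maxDepth = maxDepth),
            class = "gainRatioTree")
}

routeTree <- function(node, X, idx, P) {
  if (node$leaf) {
    P[idx, ] <- matrix(node$probs, length(idx), length(node$probs),
                       byrow = TRUE)
    return(P)
  }
  left <- X[idx, node$index] <= node$threshold
  if (any(left)) P <- routeTree(node$left, X, idx[left], P)
  if (any(!left)) P <- routeTree(node$right, X, idx[!left], P)
  P
}

#' Predict from a gain-ratio tree
#'
#' @param tree a `gainRatioTree` from [trainTree()].
#' @param X feature matrix/data frame with the training columns.
#' @param type `"class"` (default) for the majority class at the reached
#'   leaf (ties toward the earlier class level), or `"prob"` for the leaf
#'   class proportions.
#' @return Factor of predictions, or a probability matrix.
#' @export
predictTree <- function(tree, X, type = c("class", "prob")) {
  type <- match.arg(type)
  X <- as.matrix(X)
  if (!is.null(tree$features)) {
    if (!is.null(colnames(X)) && all(tree$features %in% colnames(X)))
      X <- X[, tree$features, drop = FALSE]
    else if (ncol(X) != length(tree$features))
      stop("feature columns do not match the trained tree")
  }
  P <- matrix(0, nrow(X), length(tree$classes))
  P <- routeTree(tree$root, X, seq_len(nrow(X)), P)
  colnames(P) <- tree$classes
  if (type == "prob") return(P)
  factor(tree$classes[max.col(P, ties.method = "first")],
         levels = tree$classes)
}

#' Train an L2-penalized logistic regression
#'
#' Features are standardized internally (mean 0, sd 1; constant columns
#' left unscaled); the binomial log-likelihood with penalty
#' `lambda / 2 * sum(beta^2)` (intercept unpenalized) is maximized by
#' iteratively reweighted least squares with step halving, to penalized
#' gradient norm `tol`. The small default penalty keeps the weights
#' finite on separable data.
#'
#' @param X numeric matrix/data frame of features.
#' @param y factor with two levels; the second level is modelled as the
#'   positive class.
#' @param lambda ridge penalty on standardized features (default 1e-4).
#' @param tol gradient-norm convergence tolerance (default 1e-8).
#' @param maxit maximum IRLS iterations (default 100); non-convergence
#'   warns and returns the best iterate.
#' @return A `ridgeLogistic` (list with standardized-scale coefficients,
#'   centers/scales, levels, deviance path).
#' @export
trainLogistic <- function(X, y, lambda = 1e-4, tol = 1e-8, maxit = 100L) {
  X <- as.matrix(X)
  y <- factor(y)
  if (nlevels(y) != 2L) stop("'y' must have exactly two levels")
  yy <- as.numeric(y == levels(y)[2L])
  ctr <- colMeans(X)
  scl <- apply(X, 2L, stats::sd)
  scl[scl == 0 | !is.finite(scl)] <- 1
  Z <- cbind(1, sweep(sweep(X, 2L, ctr), 2L, scl, "/"))
  p1 <- ncol(Z)
  pen <- c(0, rep(lambda, p1 - 1L))
  beta <- numeric(p1)
  negll <- function(b) {
    eta <- drop(Z %*% b)
    sum(log1p(exp(-abs(eta))) + pmax(eta, 0) - yy * eta) +
      sum(pen * b^2) / 2
  }
  dev <- negll(beta)
  devPath <- dev
  converged <- FALSE
  iter <- 0L
  while (iter < maxit) {
    iter <- iter + 1L
    eta <- drop(Z %*% beta)
    mu <- stats::plogis(eta)
    grad <- drop(crossprod(Z, yy - mu)) - pen * beta
    if (sqrt(sum(grad^2)) < tol) { converged <- TRUE; break }
    w <- pmax(mu * (1 - mu), 1e-10)
    Hmat <- crossprod(Z * w, Z) + diag(pen, p1)
    step <- solve(Hmat, grad)
    s <- 1
    repeat {
      cand <- beta + s * step
      d2 <- negll(cand)
      if (d2 <= dev + 1e-12 || s < 1e-8) break
      s <- s / 2
    }
    beta <- beta + s * step
    dev <- negll(beta)
    devPath <- c(devPath, dev)
  }
  if (!converged && iter >= maxit)
    warning("IRLS did not converge in ", maxit, " iterations")
  structure(list(coef = beta, center = ctr, scale = scl,
                 levels = levels(y), positive = levels(y)[2L],
                 lambda = lambda, converged = converged,
                 iterations = iter, deviancePath = devPath,
                 features = colnames(X)),
            class = "ridgeLogistic")
}

#' Predicted positive-class probabilities from a logistic model
#'
#' @param model a `ridgeLogistic` from [trainLogistic()].
#' @param X feature matrix/data frame with the training columns.
#' @return Numeric vector of probabilities of the positive (second) level.
#' @export
predictLogistic <- function(model, X) {
  X <- as.matrix(X)
  if (!is.null(model$features) && !is.null(colnames(X)) &&
      all(model$features %in% colnames(X)))
    X <- X[, model$features, drop = FALSE]
  Z <- cbind(1, sweep(sweep(X, 2L, model$center), 2L, model$scale, "/"))
  stats::plogis(drop(Z %*% model$coef))
}

#' Train the two-level cascade
#'
#' Fits the level-1 gain-ratio tree on the coarse labels (all samples) and
#' the level-2 logistic regression on the epithelial subset's fine labels.
#'
#' @param X feature matrix/data frame (28 features).
#' @param coarse factor of rough labels; must contain the level named by
#'   `epithelialClass`.
#' @param fine factor with levels `normal`/`abnormal` for epithelial
#'   samples (`NA` elsewhere).
#' @param epithelialClass name of the coarse class routed to level 2
#'   (default `"epithelial"`).
#' @param minLeaf,maxDepth tree hyperparameters (see [trainTree()]).
#' @param lambda logistic ridge penalty (see [trainLogistic()]).
#' @param decisionThreshold level-2 probability cutoff for calling
#'   abnormal (default 0.5; ties go to abnormal, favoring screening
#'   sensitivity).
#' @return A [CascadeModel-class].
#' @export
trainCascade <- function(X, coarse, fine, epithelialClass = "epithelial",
                         minLeaf = 5L, maxDepth = 12L, lambda = 1e-4,
                         decisionThreshold = 0.5) {
  coarse <- factor(coarse)
  if (!epithelialClass %in% levels(coarse))
    stop("'", epithelialClass, "' is not a coarse class")
  epi <- coarse == epithelialClass
  fineEpi <- factor(fine[epi], levels = c("normal", "abnormal"))
  if (anyNA(fineEpi)) stop("epithelial samples must carry a fine label")
  lvl1 <- trainTree(X, coarse, minLeaf = minLeaf, maxDepth = maxDepth)
  lvl2 <- trainLogistic(as.matrix(X)[epi, , drop = FALSE], fineEpi,
                        lambda = lambda)
  new("CascadeModel", level1 = unclass(lvl1), level2 = unclass(lvl2),
      rates = numeric(0),
      config = list(epithelialClass = epithelialClass, minLeaf = minLeaf,
                    maxDepth = maxDepth, lambda = lambda,
                    decisionThreshold = decisionThreshold))
}

#' Predict with the cascade
#'
#' The level-1 tree assigns a coarse class; non-epithelial predictions are
#' final, epithelial predictions are forwarded to the level-2 logistic
#' model, whose probability `>= decisionThreshold` yields
#' `abnormal-epithelial` and otherwise `normal-epithelial`.
#'
#' @param model a [CascadeModel-class].
#' @param X feature matrix/data frame.
#' @return Factor over the non-epithelial coarse classes plus
#'   `normal-epithelial` / `abnormal-epithelial`.
#' @export
cascadePredict <- function(model, X) {
  lvl1 <- structure(model@level1, class = "gainRatioTree")
  lvl2 <- structure(model@level2, class = "ridgeLogistic")
  epiClass <- model@config$epithelialClass
  thr <- model@config$decisionThreshold
  coarse <- as.character(predictTree(lvl1, X))
  out <- coarse
  epi <- coarse == epiClass
  if (any(epi)) {
    p <- predictLogistic(lvl2, as.matrix(X)[epi, , drop = FALSE])
    out[epi] <- ifelse(p >= thr, "abnormal-epithelial",
                       "normal-epithelial")
  }
  lvls <- c(setdiff(lvl1$classes, epiClass),
            "normal-epithelial", "abnormal-epithelial")
  factor(out, levels = lvls)
}

#' Compose cascade stage rates
#'
#' The overall rate of a two-stage cascade whose stages pass a sample
#' independently with rates `c1` and `c2` is their product
#' (`method = "product"`, the default): 0.97185 x 0.9858 = 0.95805, the
#' published overall accuracy. The additive variant (`method = "sum"`) is
#' provided for fidelity with the printed stage-rate equations but can
#' exceed 1.
#'
#' @param c1,c2 stage rates in \[0, 1\].
#' @param method `"product"` (default) or `"sum"`.
#' @return The composed rate.
#' @examples
#' composeRates(0.97185, 0.9858)   # 0.95805
#' @export
composeRates <- function(c1, c2, method = c("product", "sum")) {
  method <- match.arg(method)
  if (any(c(c1, c2) < 0) || any(c(c1, c2) > 1))
    stop("rates must lie in [0, 1]")
  if (method == "product") c1 * c2 else c1 + c2
}

#' Flat 5-class baseline tree
#'
#' A single gain-ratio tree over all five labels (lymphoid, neutrophil,
#' junk, normal-epithelial, abnormal-epithelial), used only to compare the
#' cascade against a one-shot classifier.
#'
#' @inheritParams trainTree
#' @export
trainFlatBaseline <- function(X, y, minLeaf = 5L, maxDepth = 12L) {
  trainTree(X, y, minLeaf = minLeaf, maxDepth = maxDepth)
}

treeToList <- function(node) {
  if (node$leaf)
    list(leaf = TRUE, n = node$n, probs = as.list(node$probs))
  else
    list(leaf = FALSE, feature = node$feature, index = node$index,
         threshold = node$threshold, gainRatio = node$gainRatio,
         n = node$n, left = treeToList(node$left),
         right = treeToList(node$right))
}

treeFromList <- function(x) {
  if (isTRUE(x$leaf))
    list(leaf = TRUE, n = x$n, probs = unlist(x$probs))
  else
    list(leaf = FALSE, feature = x$feature, index = x$index,
         threshold = x$threshold, gainRatio = x$gainRatio, n = x$n,
         left = treeFromList(x$left), right = treeFromList(x$right))
}

#' Save / load a cascade model as JSON
#'
#' The whole model (nested tree nodes, logistic weights with their
#' standardization constants, configuration echo and rates) round-trips
#' through a single JSON document.
#'
#' @param model a [CascadeModel-class].
#' @param path JSON file path.
#' @return `saveCascadeModel()` returns `path` invisibly;
#'   `readCascadeModel()` returns the [CascadeModel-class].
#' @export
saveCascadeModel <- function(model, path) {
  lvl2 <- model@level2
  doc <- list(
    format = "cytocascade-model",
    version = 1L,
    level1 = list(root = treeToList(model@level1$root),
                  classes = model@level1$classes,
                  features = model@level1$features,
                  minLeaf = model@level1$minLeaf,
                  maxDepth = model@level1$maxDepth),
    level2 = list(coef = lvl2$coef, center = lvl2$center,
                  scale = lvl2$scale, levels = lvl2$levels,
                  positive = lvl2$positive, lambda = lvl2$lambda,
                  converged = lvl2$converged,
                  iterations = lvl2$iterations,
                  features = lvl2$features),
    rates = model@rates,
    config = model@config)
  jsonlite::write_json(doc, path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  invisible(path)
}

#' @rdname saveCascadeModel
#' @export
readCascadeModel <- function(path) {
  doc <- jsonlite::read_json(path, simplifyVector = TRUE,
                             simplifyDataFrame = FALSE)
  l1 <- doc$level1
  lvl1 <- list(root = treeFromList(l1$root), classes = l1$classes,
               features = l1$features, minLeaf = l1$minLeaf,
               maxDepth = l1$maxDepth)
  l2 <- doc$level2
  lvl2 <- list(coef = as.numeric(l2$coef), center = as.numeric(l2$center),
               scale = as.numeric(l2$scale), levels = l2$levels,
               positive = l2$positive, lambda = l2$lambda,
               converged = l2$converged, iterations = l2$iterations,
               deviancePath = numeric(0), features = l2$features)
  new("CascadeModel", level1 = lvl1, level2 = lvl2,
      rates = if (length(doc$rates)) as.numeric(doc$rates) else numeric(0),
      config = doc$config)
}
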