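# Gain-ratio tree, penalized logistic regression, cascade composition.

# independent oracle: exhaustive gain ratio over all features & midpoints
bruteBestGainRatio <- function(X, y) {
  ent <- function(v) {
    p <- table(v) / length(v); p <- p[p > 0]
    -sum(p * log2(p))
  }
  best <- -Inf
  H <- ent(y)
  for (j in seq_len(ncol(X))) {
    xs <- sort(unique(X[, j]))
    if (length(xs) < 2) next
    for (k in seq_len(length(xs) - 1)) {
      thr <- (xs[k] + xs[k + 1]) / 2
      l <- X[, j] <= thr
      nl <- sum(l); nr <- sum(!l)
      gain <- H - nl / length(y) * ent(y[l]) - nr / length(y) * ent(y[!l])
      pl <- nl / length(y)
      si <- -(pl * log2(pl) + (1 - pl) * log2(1 - pl))
      if (gain > 1e-12 && si > 0) best <- max(best, gain / si)
    }
  }
  best
}

collectSplits <- function(node) {
  if (node$leaf) return(numeric(0))
  c(node$gainRatio, collectSplits(node$left), collectSplits(node$right))
}

test_that("tree separates trivially separable 1-D data with one split", {
  X <- matrix(c(1, 2, 3, 10, 11, 12), ncol = 1,
              dimnames = list(NULL, "x"))
  y <- factor(c("A", "A", "A", "B", "B", "B"))
  tr <- trainTree(X, y, minLeaf = 1, maxDepth = 5)
  expect_false(tr$root$leaf)
  expect_true(tr$root$left$leaf && tr$root$right$leaf)
  expect_gt(tr$root$threshold, 3); expect_lt(tr$root$threshold, 10)
  expect_equal(as.character(predictTree(tr, X)), as.character(y))
})

test_that("root gain ratio equals the exhaustive all-splits oracle", {
  set.seed(14)
  for (rep in 1:4) {
    n <- 40
    X <- cbind(a = round(rnorm(n, rep(c(0, 3), each = n / 2)), 1),
               b = round(runif(n, 0, 5), 1))
    y <- factor(rep(c("u", "v"), each = n / 2)[sample(n)])
    tr <- trainTree(X, y, minLeaf = 1, maxDepth = 1)
    if (!tr$root$leaf)
      expect_equal(tr$root$gainRatio, bruteBestGainRatio(X, y),
                   tolerance = 1e-10)
  }
})

test_that("every induced split has non-negative gain ratio; training is deterministic", {
  set.seed(30)
  n <- 240
  mus <- matrix(c(0, 0, 4, 0, 0, 4, 4, 4), 4, 2, byrow = TRUE)
  X <- do.call(rbind, lapply(1:4, function(k)
    cbind(rnorm(n / 4, mus[k, 1], 0.7), rnorm(n / 4, mus[k, 2], 0.7))))
  colnames(X) <- c("f1", "f2")
  y <- factor(rep(letters[1:4], each = n / 4))
  tr1 <- trainTree(X, y)
  tr2 <- trainTree(X, y)
  expect_identical(tr1, tr2)
  expect_true(all(collectSplits(tr1$root) >= 0))
  acc <- mean(predictTree(tr1, X) == y)
  expect_gte(acc, 0.95)
  # single-class input collapses to one leaf
  t1 <- trainTree(X[1:20, ], factor(rep("a", 20)))
  expect_true(t1$root$leaf)
})

test_that("logistic regression separates separable data and shrinks under heavy penalty", {
  set.seed(9)
  n <- 60
  X <- cbind(x1 = c(runif(n / 2, -3, -1), runif(n / 2, 1, 3)),
             x2 = rnorm(n))
  y <- factor(rep(c("neg", "pos"), each = n / 2))
  m <- trainLogistic(X, y, lambda = 1e-4)
  expect_true(all(is.finite(m$coef)))
  pred <- predictLogistic(m, X) >= 0.5
  expect_equal(mean(pred == (y == "pos")), 1)
  expect_true(all(diff(m$deviancePath) <= 1e-9))   # monotone IRLS

  # labels independent of features: heavy penalty kills all slopes
  set.seed(10)
  Xn <- matrix(rnorm(200), 100, 2, dimnames = list(NULL, c("a", "b")))
  yn <- factor(sample(c("neg", "pos"), 100, replace = TRUE))
  mn <- trainLogistic(Xn, yn, lambda = 1e6)
  expect_lt(max(abs(mn$coef[-1])), 1e-3)
})

test_that("logistic fit matches a generic convex-optimizer oracle", {
  set.seed(21)
  n <- 20
  X <- cbind(u = rnorm(n), v = rnorm(n))
  y <- factor(ifelse(X[, 1] + 0.5 * X[, 2] + rnorm(n, 0, 0.8) > 0,
                     "pos", "neg"), levels = c("neg", "pos"))
  lam <- 0.01
  m <- trainLogistic(X, y, lambda = lam)
  # oracle: BFGS on the identical penalized objective (standardized design)
  ctr <- colMeans(X); scl <- apply(X, 2, sd)
  Z <- cbind(1, sweep(sweep(X, 2, ctr), 2, scl, "/"))
  yy <- as.numeric(y == "pos")
  pen <- c(0, lam, lam)
  nll <- function(b) {
    eta <- drop(Z %*% b)
    sum(log1p(exp(-abs(eta))) + pmax(eta, 0) - yy * eta) + sum(pen * b^2) / 2
  }
  opt <- optim(rep(0, 3), nll, method = "BFGS",
               control = list(maxit = 1000, reltol = 1e-14))
  pOracle <- plogis(drop(Z %*% opt$par))
  expect_equal(predictLogistic(m, X), pOracle, tolerance = 1e-5)
})

test_that("cascade prediction equals the manual composition of both levels", {
  set.seed(33)
  n <- 80
  classes <- c("epithelial", "lymphoid", "neutrophil", "junk")
  coarse <- factor(rep(classes, each = n / 4), levels = classes)
  X <- cbind(size = rnorm(n, rep(c(30, 10, 12, 20), each = n / 4), 1.5),
             tone = rnorm(n, rep(c(120, 80, 100, 128), each = n / 4), 3))
  fine <- rep(NA_character_, n)
  epi <- coarse == "epithelial"
  fine[epi] <- rep(c("normal", "abnormal"), length.out = sum(epi))
  X[epi & fine == "abnormal", "size"] <- X[epi & fine == "abnormal", "size"] + 15
  model <- trainCascade(X, coarse, fine, minLeaf = 2)
  pred <- cascadePredict(model, X)

  lvl1 <- structure(model@level1, class = "gainRatioTree")
  lvl2 <- structure(model@level2, class = "ridgeLogistic")
  manual <- as.character(predictTree(lvl1, X))
  isEpi <- manual == "epithelial"
  p <- predictLogistic(lvl2, X[isEpi, , drop = FALSE])
  manual[isEpi] <- ifelse(p >= 0.5, "abnormal-epithelial",
                          "normal-epithelial")
  expect_equal(as.character(pred), manual)
  # non-epithelial level-1 decisions are final
  expect_true(all(as.character(pred)[!isEpi] %in%
                    c("lymphoid", "neutrophil", "junk")))
  # high-probability epithelial samples are called abnormal
  hi <- which(isEpi)[p >= 0.9]
  if (length(hi))
    expect_true(all(as.character(pred)[hi] == "abnormal-epithelial"))
})

test_that("cascade prediction is invariant to the order of non-epithelial labels", {
  set.seed(44)
  n <- 60
  X <- cbind(f = rnorm(n, rep(c(0, 5, 10, 15), each = n / 4), 0.5))
  coarseA <- factor(rep(c("epithelial", "lymphoid", "neutrophil", "junk"),
                        each = n / 4),
                    levels = c("epithelial", "lymphoid", "neutrophil", "junk"))
  coarseB <- factor(coarseA,
                    levels = c("epithelial", "junk", "neutrophil", "lymphoid"))
  fine <- ifelse(coarseA == "epithelial",
                 rep(c("normal", "abnormal"), length.out = n), NA)
  mA <- trainCascade(X, coarseA, fine, minLeaf = 2)
  mB <- trainCascade(X, coarseB, fine, minLeaf = 2)
  expect_equal(as.character(cascadePredict(mA, X)),
               as.character(cascadePredict(mB, X)))
})

test_that("rate composition reproduces the published overall rates", {
  expect_equal(composeRates(0.97185, 0.9858), 0.95805, tolerance = 1e-5)
  expect_equal(composeRates(0.97, 0.986), 0.95642, tolerance = 1e-10)
  expect_equal(composeRates(1, 0.73), 0.73)
  expect_equal(composeRates(0.5, 0.4, method = "sum"), 0.9)
  expect_error(composeRates(1.2, 0.5), "\\[0, 1\\]")
})

test_that("flat baseline trains on five labels and is deterministic", {
  set.seed(55)
  n <- 100
  X <- cbind(f = rnorm(n, rep(seq(0, 40, by = 10), each = n / 5), 1))
  y <- factor(rep(c("lymphoid", "neutrophil", "junk",
                    "normal-epithelial", "abnormal-epithelial"),
                  each = n / 5))
  b1 <- trainFlatBaseline(X, y)
  b2 <- trainFlatBaseline(X, y)
  expect_identical(b1, b2)
  expect_gte(mean(predictTree(b1, X) == y), 0.95)
  single <- trainFlatBaseline(X[1:10, , drop = FALSE],
                              factor(rep("junk", 10)))
  expect_true(single$root$leaf)
})

test_that("cascade model round-trips through JSON with identical predictions", {
  set.seed(66)
  n <- 80
  classes <- c("epithelial", "lymphoid", "neutrophil", "junk")
  coarse <- factor(rep(classes, each = n / 4), levels = classes)
  X <- cbind(size = rnorm(n, rep(c(30, 10, 14, 22), each = n / 4), 1),
             tone = rnorm(n, rep(c(120, 80, 100, 128), each = n / 4), 2))
  fine <- ifelse(coarse == "epithelial",
                 rep(c("normal", "abnormal"), length.out = n), NA)
  X[coarse == "epithelial" & fine == "abnormal", "size"] <-
    X[coarse == "epithelial" & fine == "abnormal", "size"] + 12
  model <- trainCascade(X, coarse, fine, minLeaf = 2)
  path <- tempfile(fileext = ".json")
  saveCascadeModel(model, path)
  back <- readCascadeModel(path)
  expect_equal(as.character(cascadePredict(back, X)),
               as.character(cascadePredict(model, X)))
  lvl2 <- structure(back@level2, class = "ridgeLogistic")
  expect_equal(predictLogistic(lvl2, X[1:10, , drop = FALSE]),
               predictLogistic(structure(model@level2,
                                         class = "ridgeLogistic"),
                               X[1:10, , drop = FALSE]),
               tolerance = 1e-12)
})
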