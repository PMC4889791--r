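# End-to-end wiring: configuration, per-image feature extraction, the
# train/predict pipeline, and feature-table I/O.

#' The 28 feature names
#'
#' Fixed column order of every feature table: 20 morphologic then 8
#' texture features.
#'
#' @return Character vector of length 28.
#' @export
featureNames <- function() {
  c("Area", "Circularity", "Distance", "Sigma", "Roundness", "Sides",
    "Convexity", "M11", "M20", "M02", "Ia", "Ib", "Compactness",
    "ContLength", "Diameter", "Radius", "Rectangularity", "Anisometry",
    "Bulkiness", "StructureFactor",
    "Mean", "Deviation", "Energy", "Correlation", "Homogeneity",
    "Contrast", "Entropy", "Anisotropy")
}

#' PipelineConfig: parameters of the whole pipeline
#'
#' Collects the preprocessing, segmentation, texture and classifier
#' parameters plus the seed and physical scale; serializes losslessly to
#' YAML via [writePipelineConfig()] / [readPipelineConfig()].
#'
#' @slot detailRadius median-blur radius of the equalization base layer.
#' @slot medianWindow odd median-filter window (>= 3).
#' @slot equalize apply detail-preserving equalization before denoising.
#' @slot threshold `"auto"` or an integer cutoff as character.
#' @slot minArea minimum region area (px).
#' @slot polarity `"dark"` or `"light"` nuclei.
#' @slot glcmLevels GLCM quantization levels.
#' @slot minLeaf,maxDepth level-1 tree hyperparameters.
#' @slot lambda level-2 ridge penalty.
#' @slot decisionThreshold level-2 abnormal cutoff.
#' @slot trainFraction stratified training fraction.
#' @slot seed integer seed.
#' @slot umPerPx micrometres per pixel (1 = report pixels).
#' @export
setClass("PipelineConfig",
  representation(detailRadius = "integer", medianWindow = "integer",
                 equalize = "logical", threshold = "character",
                 minArea = "integer", polarity = "character",
                 glcmLevels = "integer", minLeaf = "integer",
                 maxDepth = "integer", lambda = "numeric",
                 decisionThreshold = "numeric", trainFraction = "numeric",
                 seed = "integer", umPerPx = "numeric"),
  validity = function(object) {
    if (object@detailRadius < 1L) return("detailRadius must be >= 1")
    if (object@medianWindow < 3L || object@medianWindow %% 2L == 0L)
      return("medianWindow must be odd and >= 3")
    if (!object@polarity %in% c("dark", "light"))
      return("polarity must be 'dark' or 'light'")
    if (object@threshold != "auto" &&
        is.na(suppressWarnings(as.integer(object@threshold))))
      return("threshold must be 'auto' or an integer")
    if (object@glcmLevels < 2L) return("glcmLevels must be >= 2")
    if (object@minArea < 1L) return("minArea must be >= 1")
    if (object@lambda < 0) return("lambda must be >= 0")
    if (object@decisionThreshold < 0 || object@decisionThreshold > 1)
      return("decisionThreshold must be in [0, 1]")
    if (object@trainFraction <= 0 || object@trainFraction >= 1)
      return("trainFraction must be in (0, 1)")
    if (object@umPerPx <= 0) return("umPerPx must be > 0")
    TRUE
  })

#' Build a PipelineConfig
#'
#' @param detailRadius,medianWindow,equalize,threshold,minArea,polarity
#'   imaging parameters (see [equalizeWithDetail()], [medianDenoise()],
#'   [adaptiveThreshold()], [segmentNuclei()]). Equalization is off by
#'   default: it targets unevenly stained slides and distorts the
#'   per-class intensity statistics of well-exposed images.
#' @param glcmLevels GLCM quantization levels (see [buildGLCM()]).
#' @param minLeaf,maxDepth,lambda,decisionThreshold classifier
#'   hyperparameters (see [trainCascade()]).
#' @param trainFraction stratified train split fraction (default 0.7).
#' @param seed integer seed for the split.
#' @param umPerPx physical scale (default 1).
#' @return A [PipelineConfig-class].
#' @export
pipelineConfig <- function(detailRadius = 3L, medianWindow = 3L,
                           equalize = FALSE, threshold = "auto",
                           minArea = 50L, polarity = "dark",
                           glcmLevels = 32L, minLeaf = 5L, maxDepth = 12L,
                           lambda = 1e-4, decisionThreshold = 0.5,
                           trainFraction = 0.7, seed = 1L, umPerPx = 1) {
  new("PipelineConfig",
      detailRadius = as.integer(detailRadius),
      medianWindow = as.integer(medianWindow),
      equalize = isTRUE(equalize), threshold = as.character(threshold),
      minArea = as.integer(minArea), polarity = polarity,
      glcmLevels = as.integer(glcmLevels), minLeaf = as.integer(minLeaf),
      maxDepth = as.integer(maxDepth), lambda = lambda,
      decisionThreshold = decisionThreshold,
      trainFraction = trainFraction, seed = as.integer(seed),
      umPerPx = umPerPx)
}

setMethod("show", "PipelineConfig", function(object) {
  cat("PipelineConfig\n")
  for (s in slotNames(object))
    cat(sprintf("  %-18s %s\n", s, as.character(slot(object, s))))
})

configToList <- function(cfg) {
  out <- lapply(slotNames(cfg), function(s) slot(cfg, s))
  names(out) <- slotNames(cfg)
  out
}

#' Serialize / read a PipelineConfig as YAML
#'
#' @param cfg a [PipelineConfig-class].
#' @param path YAML file path.
#' @export
writePipelineConfig <- function(cfg, path) {
  yaml::write_yaml(configToList(cfg), path)
  invisible(path)
}

#' @rdname writePipelineConfig
#' @export
readPipelineConfig <- function(path) {
  do.call(pipelineConfig, yaml::read_yaml(path))
}

#' Preprocess an image according to a config
#'
#' Optional detail-preserving equalization, then median denoising.
#'
#' @param img a [GrayImage-class].
#' @param config a [PipelineConfig-class].
#' @return A [GrayImage-class].
#' @export
preprocessImage <- function(img, config = pipelineConfig()) {
  if (config@equalize)
    img <- equalizeWithDetail(img, config@detailRadius)
  medianDenoise(img, config@medianWindow)
}

#' Extract the 28-feature table of an image
#'
#' Runs [extractMorphology()] and [extractTexture()] on every region and
#' binds the results into a data frame with `region_id` (and optionally
#' `image_id`) columns followed by the 28 feature columns in the
#' [featureNames()] order.
#'
#' @param img a [GrayImage-class] (the intensity source for texture).
#' @param regions list of [NucleusRegion-class].
#' @param config a [PipelineConfig-class].
#' @param imageId optional image identifier column value.
#' @return Data frame, one row per region.
#' @export
extractFeatures <- function(img, regions, config = pipelineConfig(),
                            imageId = NULL) {
  rows <- lapply(regions, function(r) {
    c(list(region_id = regionLabel(r)),
      extractMorphology(r, umPerPx = config@umPerPx),
      extractTexture(img, r, levels = config@glcmLevels))
  })
  df <- do.call(rbind, lapply(rows, function(x)
    as.data.frame(x, check.names = FALSE)))
  df <- df[, c("region_id", featureNames())]
  if (!is.null(imageId)) df <- cbind(image_id = imageId, df)
  df
}

#' Write / read a feature table CSV
#'
#' @param features data frame from [extractFeatures()].
#' @param path CSV path.
#' @export
writeFeatureCSV <- function(features, path) {
  utils::write.csv(features, path, row.names = FALSE)
  invisible(path)
}

#' @rdname writeFeatureCSV
#' @export
readFeatureCSV <- function(path) {
  utils::read.csv(path, check.names = FALSE)
}

# deterministic stratified split: within each stratum the first
# round(fraction * n) of a seeded permutation go to training
stratifiedSplit <- function(labels, fraction, seed) {
  train <- logical(length(labels))
  withSeed(seed, {
    for (lv in unique(labels)) {
      idx <- which(labels == lv)
      nTr <- max(1L, round(fraction * length(idx)))
      train[sample(idx)[seq_len(nTr)]] <- TRUE
    }
  })
  train
}

# intersection-over-union of two logical masks
maskIoU <- function(a, b) sum(a & b) / sum(a | b)

#' Segment scenes and label regions by ground truth
#'
#' Preprocesses and segments every scene, extracts the 28 features of
#' every recovered region, and (when ground-truth masks are present)
#' assigns each region the label of the ground-truth cell it best
#' overlaps, requiring intersection-over-union of at least `minIoU`.
#'
#' @param scenes list of scenes from [generateDataset()] (or lists with
#'   an `image` and optional `masks`/`class` fields).
#' @param config a [PipelineConfig-class].
#' @param minIoU minimum mask IoU for a ground-truth match (default 0.5).
#' @return Data frame of features with `image_id`, `region_id`, and when
#'   ground truth is available `class`, `coarse`, `fine`, `iou` columns.
#' @export
segmentAndExtract <- function(scenes, config = pipelineConfig(),
                              minIoU = 0.5) {
  out <- vector("list", length(scenes))
  for (s in seq_along(scenes)) {
    sc <- scenes[[s]]
    img <- preprocessImage(sc$image, config)
    thr <- if (config@threshold == "auto") adaptiveThreshold(img)
           else as.integer(config@threshold)
    regions <- segmentNuclei(img, thr, minArea = config@minArea,
                             polarity = config@polarity)
    if (!length(regions)) next
    df <- extractFeatures(img, regions, config, imageId = s)
    if (!is.null(sc$masks)) {
      dims <- dim(sc$image@.Data)
      cls <- rep(NA_character_, nrow(df))
      crs <- rep(NA_character_, nrow(df))
      fin <- rep(NA_character_, nrow(df))
      iou <- rep(NA_real_, nrow(df))
      for (i in seq_along(regions)) {
        rmask <- matrix(FALSE, dims[1L], dims[2L])
        rmask[maskCoords(regions[[i]])] <- TRUE
        ious <- vapply(sc$masks, maskIoU, numeric(1), a = rmask)
        j <- which.max(ious)
        if (length(j) && ious[j] >= minIoU) {
          cls[i] <- sc$class[j]
          crs[i] <- sc$coarse[j]
          fin[i] <- sc$fine[j]
          iou[i] <- ious[j]
        }
      }
      df$class <- cls; df$coarse <- crs; df$fine <- fin; df$iou <- iou
    }
    out[[s]] <- df
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

#' Run the full detection pipeline
#'
#' Train mode: preprocess, segment, extract the 28 features, stratified
#' train/test split, train the two-level cascade and the flat 5-class
#' baseline, and evaluate (level-1 confusion and metrics, level-2
#' accuracy and ROC/AUC, end-to-end cascade accuracy and abnormal recall,
#' composed stage rates). Predict mode: the same imaging and feature
#' stages, then per-region cascade predictions from a supplied model.
#'
#' @param scenes list of scenes (see [segmentAndExtract()]).
#' @param config a [PipelineConfig-class].
#' @param mode `"train"` or `"predict"`.
#' @param model a [CascadeModel-class] (predict mode).
#' @return Train mode: list with `model`, `features`, `report`,
#'   `trainIndex`. Predict mode: list with `features`, `predictions`.
#' @export
runPipeline <- function(scenes, config = pipelineConfig(),
                        mode = c("train", "predict"), model = NULL) {
  mode <- match.arg(mode)
  feats <- segmentAndExtract(scenes, config)
  if (is.null(feats) || !nrow(feats)) stop("segmentation produced no regions")
  X <- as.matrix(feats[, featureNames()])
  if (mode == "predict") {
    if (is.null(model)) stop("predict mode requires a model")
    return(list(features = feats,
                predictions = cascadePredict(model, X)))
  }
  labeled <- !is.na(feats$class)
  if (!any(labeled)) stop("train mode requires ground-truth labels")
  feats <- feats[labeled, , drop = FALSE]
  X <- X[labeled, , drop = FALSE]
  train <- stratifiedSplit(feats$class, config@trainFraction, config@seed)
  coarse <- factor(feats$coarse,
                   levels = c("epithelial", "lymphoid", "neutrophil", "junk"))
  fine5 <- factor(feats$class,
                  levels = c("lymphoid", "neutrophil", "junk",
                             "normal-epithelial", "abnormal-epithelial"))
  model <- trainCascade(X[train, , drop = FALSE], coarse[train],
                        feats$fine[train],
                        minLeaf = config@minLeaf,
                        maxDepth = config@maxDepth,
                        lambda = config@lambda,
                        decisionThreshold = config@decisionThreshold)
  flat <- trainFlatBaseline(X[train, , drop = FALSE], fine5[train],
                            minLeaf = config@minLeaf,
                            maxDepth = config@maxDepth)
  # held-out evaluation
  Xte <- X[!train, , drop = FALSE]
  lvl1 <- structure(model@level1, class = "gainRatioTree")
  coarsePred <- predictTree(lvl1, Xte)
  cm1 <- confusionCounts(coarse[!train], coarsePred,
                         classes = levels(coarse))
  acc1 <- classificationAccuracy(cm1)
  epiTest <- coarse[!train] == "epithelial"
  lvl2 <- structure(model@level2, class = "ridgeLogistic")
  p2 <- predictLogistic(lvl2, Xte[epiTest, , drop = FALSE])
  fineTruth <- factor(feats$fine[!train][epiTest],
                      levels = c("normal", "abnormal"))
  finePred <- factor(ifelse(p2 >= config@decisionThreshold,
                            "abnormal", "normal"),
                     levels = c("normal", "abnormal"))
  cm2 <- confusionCounts(fineTruth, finePred,
                         classes = c("normal", "abnormal"))
  acc2 <- classificationAccuracy(cm2)
  roc2 <- rocAuc(p2, fineTruth, positive = "abnormal")
  casPred <- cascadePredict(model, Xte)
  cmC <- confusionCounts(fine5[!train], casPred, classes = levels(fine5))
  accC <- classificationAccuracy(cmC)
  abn <- fine5[!train] == "abnormal-epithelial"
  recallAbn <- mean(casPred[abn] == "abnormal-epithelial")
  flatPred <- predictTree(flat, Xte)
  accFlat <- classificationAccuracy(
    confusionCounts(fine5[!train], flatPred, classes = levels(fine5)))
  model@rates <- c(level1 = acc1, level2 = acc2)
  report <- evaluationReport(
    level1 = list(confusion = cm1, accuracy = acc1,
                  perClass = precisionRecallF(cm1)),
    level2 = list(confusion = cm2, accuracy = acc2, roc = roc2),
    cascade = list(confusion = cmC, accuracy = accC,
                   abnormalRecall = recallAbn, flatAccuracy = accFlat))
  list(model = model, features = feats, report = report,
       trainIndex = train)
}
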