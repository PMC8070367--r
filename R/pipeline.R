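.pipelineModes <- c("text", "image", "intermediate", "late_avg", "late_max",
                    "mlb")

# per-mode default SVD component count: 100 for the image single view and
# late integration, 50 inside intermediate integration
.defaultSvdK <- function(mode) if (mode == "intermediate") 50L else 100L

#' Train a multi-view standardization pipeline
#'
#' Trains the artifacts a prediction mode needs on the given training rows
#' of a cohort: the text model (supervised character n-gram classifier,
#' 200-dim embeddings), the truncated SVD of the geometric features (k = 50
#' inside intermediate integration, k = 100 for the image view and late
#' integration) and the random-forest classifier for the chosen feature
#' space. The SVD is fitted on training rows only; held-out rows are
#' transformed with the frozen basis.
#'
#' @param cohort a [StructCohort-class].
#' @param trainIdx integer indices (manifest rows) of the training records.
#' @param mode one of `"text"`, `"image"`, `"intermediate"`, `"late_avg"`,
#'   `"late_max"`, `"mlb"`.
#' @param svdK SVD components; default 50 (intermediate) or 100 (image/late).
#' @param embedDim text embedding dimension (default 200).
#' @param numTrees random-forest size (default 100).
#' @param seed integer seed governing all stochastic stages.
#' @param includeBone concatenate bony anatomy to the geometric features.
#' @param X optional precomputed [featurizeGeometry()] matrix for the whole
#'   cohort (avoids re-rasterizing when training several modes).
#' @return A [PipelineBundle-class].
#' @export
trainPipeline <- function(cohort, trainIdx, mode = .pipelineModes,
                          svdK = NULL, embedDim = 200L, numTrees = 100L,
                          seed = 1L, includeBone = FALSE, X = NULL) {
  mode <- match.arg(mode)
  labelSet <- cohort@labelSet
  labels <- cohort@manifest$true_label[trainIdx]
  nmText <- preprocessName(cohort@manifest$given_name[trainIdx])
  if (is.null(svdK)) svdK <- .defaultSvdK(mode)

  textModel <- NULL
  svdModel <- NULL
  classifier <- NULL
  mlb <- NULL
  needText <- mode %in% c("text", "intermediate", "late_avg", "late_max")
  needGeom <- mode %in% c("image", "intermediate", "late_avg", "late_max")

  if (needText)
    textModel <- trainTextModel(nmText, labels, labelSet, dim = embedDim,
                                seed = .deriveSeed(seed, "text"))
  if (needGeom) {
    if (is.null(X)) X <- featurizeGeometry(cohort, includeBone)
    Xtr <- X[trainIdx, , drop = FALSE]
    svdModel <- fitTruncatedSvd(Xtr, svdK, seed = .deriveSeed(seed, "svd"))
    reduced <- svdTransform(svdModel, Xtr)
    feats <- if (mode == "intermediate")
      buildIntermediateFeature(embedName(textModel, nmText), reduced)
    else reduced
    classifier <- trainClassifier(feats, labels, labelSet,
                                  numTrees = numTrees,
                                  seed = .deriveSeed(seed, "forest"))
  }
  if (mode == "mlb") mlb <- majorityLabelBaseline(labels, labelSet)

  new("PipelineBundle", mode = mode, labelSet = labelSet,
      textModel = textModel, svdModel = svdModel, classifier = classifier,
      mlb = mlb,
      config = list(gridShape = cohort@gridShape, box = cohort@box,
                    includeBone = includeBone, svdK = svdK,
                    embedDim = embedDim, numTrees = numTrees, seed = seed))
}

.requireArtifact <- function(bundle, slotName) {
  a <- slot(bundle, slotName)
  if (is.null(a))
    stop("missing artifact for mode '", bundle@mode, "': ", slotName)
  a
}

#' Predict standard names with a trained pipeline
#'
#' Composes preprocess -> embed (text view) and rasterize -> reduce ->
#' classify (image view), then fuses per the bundle's mode. Deterministic
#' given the artifacts.
#'
#' @param bundle a [PipelineBundle-class].
#' @param cohort the [StructCohort-class] holding the records.
#' @param idx integer manifest rows to predict (default: all).
#' @param X optional precomputed [featurizeGeometry()] matrix.
#' @return list with `class` (character) and `proba` (records x classes
#'   matrix; for `late_max` these are the raw fused maxima, otherwise a
#'   distribution per row).
#' @export
predictPipeline <- function(bundle, cohort, idx = NULL, X = NULL) {
  if (is.null(idx)) idx <- seq_len(nrow(cohort@manifest))
  mode <- bundle@mode
  if (!mode %in% .pipelineModes) stop("unknown mode: ", mode)
  cn <- classNames(bundle@labelSet)
  nmText <- preprocessName(cohort@manifest$given_name[idx])

  textP <- NULL
  if (mode %in% c("text", "intermediate", "late_avg", "late_max")) {
    tm <- .requireArtifact(bundle, "textModel")
    if (mode != "intermediate")
      textP <- predictTextProba(tm, nmText)
    if (length(idx) == 1 && !is.null(textP)) textP <- t(as.matrix(textP))
  }

  geomP <- NULL
  reduced <- NULL
  if (mode %in% c("image", "intermediate", "late_avg", "late_max")) {
    svdm <- .requireArtifact(bundle, "svdModel")
    clf <- .requireArtifact(bundle, "classifier")
    if (is.null(X)) X <- featurizeGeometry(cohort,
                                           bundle@config$includeBone)
    reduced <- svdTransform(svdm, X[idx, , drop = FALSE])
    if (mode != "intermediate")
      geomP <- predictClassifierProba(clf, reduced)
  }

  proba <- switch(mode,
    text = textP,
    image = geomP,
    intermediate = {
      tm <- .requireArtifact(bundle, "textModel")
      clf <- .requireArtifact(bundle, "classifier")
      docs <- embedName(tm, nmText)
      if (length(idx) == 1) docs <- t(as.matrix(docs))
      predictClassifierProba(clf, buildIntermediateFeature(docs, reduced))
    },
    late_avg = fuseAvg(list(textP, geomP)),
    late_max = fuseMax(list(textP, geomP))$scores,
    mlb = {
      m <- .requireArtifact(bundle, "mlb")
      p <- matrix(0, length(idx), length(cn), dimnames = list(NULL, cn))
      p[, m@label] <- 1
      p
    })
  if (is.null(dim(proba))) proba <- t(as.matrix(proba))
  cls <- cn[apply(proba, 1, which.max)]
  list(class = cls, proba = proba)
}

#' @describeIn predictPipeline predict a single [StructureRecord-class]
#'   (rasterized against the bundle's stored grid geometry).
#' @param record a [StructureRecord-class].
#' @export
predictRecord <- function(bundle, record) {
  man <- data.frame(structure_id = "r1", patient_id = record@patientId,
    center_id = record@centerId, given_name = record@givenName,
    true_label = record@trueLabel, stringsAsFactors = FALSE)
  if (isTRUE(bundle@config$includeBone))
    stop("single-record prediction requires structure-only geometry")
  mini <- new("StructCohort", manifest = man, structures = list(record),
    boneRows = Matrix::sparseMatrix(i = integer(0), j = integer(0),
      x = numeric(0), dims = c(0, prod(bundle@config$gridShape))),
    patientIds = record@patientId, box = bundle@config$box,
    gridShape = bundle@config$gridShape, labelSet = bundle@labelSet,
    disease = "prostate", config = list())
  out <- predictPipeline(bundle, mini, idx = 1L)
  list(class = out$class[1], proba = out$proba[1, ])
}

#' Save / load a pipeline bundle
#'
#' The bundle directory holds one RDS per artifact plus `manifest.json`
#' recording mode, dimensions, seeds and package version.
#'
#' @param bundle a [PipelineBundle-class].
#' @param path bundle directory.
#' @return `loadBundle()` returns the [PipelineBundle-class].
#' @export
saveBundle <- function(bundle, path) {
  if (!dir.exists(path) &&
      !dir.create(path, recursive = TRUE, showWarnings = FALSE))
    stop("cannot create bundle directory: ", path)
  for (s in c("textModel", "svdModel", "classifier", "mlb")) {
    a <- slot(bundle, s)
    if (!is.null(a)) saveRDS(a, file.path(path, paste0(s, ".rds")))
  }
  saveRDS(bundle@labelSet, file.path(path, "labelSet.rds"))
  saveRDS(bundle@config, file.path(path, "config.rds"))
  jsonlite::write_json(list(mode = bundle@mode,
    classes = classNames(bundle@labelSet), svd_k = bundle@config$svdK,
    embed_dim = bundle@config$embedDim, num_trees = bundle@config$numTrees,
    seed = bundle@config$seed, grid_shape = bundle@config$gridShape,
    package_version = as.character(packageVersion("structviews"))),
    file.path(path, "manifest.json"), auto_unbox = TRUE)
  invisible(path)
}

#' @rdname saveBundle
#' @export
loadBundle <- function(path) {
  man <- jsonlite::read_json(file.path(path, "manifest.json"),
                             simplifyVector = TRUE)
  get1 <- function(s) {
    f <- file.path(path, paste0(s, ".rds"))
    if (file.exists(f)) readRDS(f) else NULL
  }
  new("PipelineBundle", mode = man$mode,
      labelSet = readRDS(file.path(path, "labelSet.rds")),
      textModel = get1("textModel"), svdModel = get1("svdModel"),
      classifier = get1("classifier"), mlb = get1("mlb"),
      config = readRDS(file.path(path, "config.rds")))
}
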