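## Central S4 data model. Contours are kept as plain lists (z + point matrix)
## inside StructureRecord: a patient easily holds hundreds of them and per-
## contour S4 dispatch would dominate runtime for no gain.

#' Ordered label set for a standardization task
#'
#' Fixed, ordered list of standard class names for one disease site. The
#' order is frozen at task creation: probability vectors, confusion matrices
#' and argmax tie-breaking all follow it. Every label set contains the
#' catch-all class `"other"`.
#'
#' @slot classNames character vector of unique class names including "other".
#' @seealso [prostateLabels()], [lungLabels()]
#' @export
setClass("LabelSet", representation(classNames = "character"),
  validity = function(object) {
    cn <- object@classNames
    if (anyDuplicated(cn)) return("class names must be unique")
    if (!"other" %in% cn) return("label set must contain 'other'")
    if (length(cn) < 2) return("need at least two classes")
    TRUE
  })

#' Prostate / lung label sets
#'
#' The prostate task has eight classes (seven OAR/PTV plus "other"), the lung
#' task six (five OAR/PTV plus "other").
#'
#' @return A [LabelSet-class] object.
#' @examples
#' classNames(prostateLabels())
#' @export
prostateLabels <- function() {
  new("LabelSet", classNames = c("Femur_L", "Femur_R", "Bowel_Large",
    "Bowel_Small", "Bladder", "Rectum", "PTV", "other"))
}

#' @rdname prostateLabels
#' @export
lungLabels <- function() {
  new("LabelSet", classNames = c("Esophagus", "SpinalCord", "Brachial_Plexus",
    "Heart", "PTV", "other"))
}

#' Label set for a disease site
#' @param disease `"prostate"` or `"lung"`.
#' @return A [LabelSet-class].
#' @export
diseaseLabels <- function(disease = c("prostate", "lung")) {
  disease <- match.arg(disease)
  if (disease == "prostate") prostateLabels() else lungLabels()
}

#' A 3D CT image series in patient coordinates
#'
#' Voxels hold Hounsfield Units (air about -1000, water 0, dense bone above
#' 1000). Geometry follows the DICOM LPS patient coordinate system in
#' millimetres; only axial series (identity orientation) are supported.
#'
#' @slot voxels integer 3D array, dims (nx, ny, nz), in HU.
#' @slot origin numeric(3), mm position of the centre of voxel (1,1,1).
#' @slot spacing numeric(3), mm per voxel along x, y, z; all > 0.
#' @slot orientation numeric(6) direction cosines of rows then columns.
#' @slot slicePositions numeric(nz) strictly increasing slice z (mm).
#' @slot patientId opaque patient identifier.
#' @slot frameOfReferenceUID DICOM frame-of-reference UID ("" if unknown).
#' @export
setClass("ImageSeries",
  representation(voxels = "array", origin = "numeric", spacing = "numeric",
    orientation = "numeric", slicePositions = "numeric",
    patientId = "character", frameOfReferenceUID = "character"),
  prototype(orientation = c(1, 0, 0, 0, 1, 0), frameOfReferenceUID = ""),
  validity = function(object) {
    d <- dim(object@voxels)
    if (length(d) != 3 || any(d < 1)) return("voxels must be a 3D array")
    if (length(object@spacing) != 3 || any(object@spacing <= 0))
      return("spacing must be 3 positive values")
    if (length(object@origin) != 3) return("origin must have length 3")
    sp <- object@slicePositions
    if (length(sp) != d[3]) return("one slice position per z-plane required")
    if (d[3] > 1 && any(diff(sp) <= 0))
      return("slice positions must be strictly increasing")
    TRUE
  })

#' @export
ImageSeries <- function(voxels, origin, spacing, slicePositions = NULL,
                        patientId = "anon", orientation = c(1, 0, 0, 0, 1, 0),
                        frameOfReferenceUID = "") {
  storage.mode(voxels) <- "integer"
  if (is.null(slicePositions))
    slicePositions <- origin[3] + (seq_len(dim(voxels)[3]) - 1) * spacing[3]
  new("ImageSeries", voxels = voxels, origin = as.numeric(origin),
    spacing = as.numeric(spacing), orientation = as.numeric(orientation),
    slicePositions = as.numeric(slicePositions), patientId = patientId,
    frameOfReferenceUID = frameOfReferenceUID)
}

#' One delineated structure
#'
#' Holds the verbatim physician-given name (byte-for-byte as read; any
#' preprocessing is an explicit later step) and the per-slice closed contour
#' polygons in patient coordinates. Each element of `contours` is a list with
#' `z` (slice position, mm) and `points` (n x 2 matrix of x,y mm; closure is
#' implicit, the first point is not repeated).
#'
#' @slot givenName verbatim structure name.
#' @slot contours list of contours (possibly empty).
#' @slot trueLabel standard class name, or NA when unknown.
#' @slot patientId,centerId opaque identifiers.
#' @export
setClass("StructureRecord",
  representation(givenName = "character", contours = "list",
    trueLabel = "character", patientId = "character", centerId = "character"),
  prototype(trueLabel = NA_character_, centerId = NA_character_),
  validity = function(object) {
    for (ct in object@contours) {
      if (!is.list(ct) || is.null(ct$points) || is.null(ct$z))
        return("each contour needs $z and $points")
      p <- ct$points
      if (!is.matrix(p) || ncol(p) != 2) return("contour points must be n x 2")
      if (nrow(p) >= 2 && all(p[1, ] == p[nrow(p), ]))
        return("contour closure must be implicit (first point not repeated)")
    }
    TRUE
  })

#' @export
StructureRecord <- function(givenName, contours = list(),
                            trueLabel = NA_character_, patientId = "anon",
                            centerId = NA_character_) {
  new("StructureRecord", givenName = givenName, contours = contours,
    trueLabel = trueLabel, patientId = patientId, centerId = centerId)
}

#' All structures delineated for one patient
#' @slot records list of [StructureRecord-class], all for the same patient.
#' @slot patientId the shared patient id.
#' @export
setClass("StructureSet",
  representation(records = "list", patientId = "character"),
  validity = function(object) {
    ok <- vapply(object@records, function(r)
      is(r, "StructureRecord") && identical(r@patientId, object@patientId),
      logical(1))
    if (!all(ok)) return("every record must reference the set's patientId")
    TRUE
  })

#' @export
StructureSet <- function(records, patientId) {
  new("StructureSet", records = records, patientId = patientId)
}

#' Axis-aligned bounding box in patient coordinates (mm)
#' @slot minCorner,maxCorner numeric(3), max strictly greater than min.
#' @export
setClass("BoundingBox",
  representation(minCorner = "numeric", maxCorner = "numeric"),
  validity = function(object) {
    if (length(object@minCorner) != 3 || length(object@maxCorner) != 3)
      return("corners must have length 3")
    if (any(object@maxCorner <= object@minCorner))
      return("maxCorner must exceed minCorner componentwise")
    TRUE
  })

#' @export
BoundingBox <- function(minCorner, maxCorner)
  new("BoundingBox", minCorner = as.numeric(minCorner),
      maxCorner = as.numeric(maxCorner))

#' Binary occupancy volume on a fixed grid
#'
#' A 3D 0/1 grid (default 96 x 96 x 48) spanning a bounding box. Produced by
#' [rasterizeStructure()] and [extractBonyAnatomy()]; flattened into the
#' geometric feature vector by [flattenVolume()].
#'
#' @slot bits integer 3D array of 0/1.
#' @slot box the [BoundingBox-class] the grid spans.
#' @export
setClass("BinaryVolume",
  representation(bits = "array", box = "BoundingBox"),
  validity = function(object) {
    if (length(dim(object@bits)) != 3) return("bits must be a 3D array")
    if (!all(object@bits %in% c(0L, 1L))) return("bits must be 0/1")
    TRUE
  })

#' Supervised character n-gram text embedding classifier
#'
#' A linear softmax classifier over mean-pooled embeddings of hashed
#' character n-grams, trained by SGD on cross-entropy. Only hash buckets seen
#' during training are stored; unseen n-grams embed to zero, and a fully
#' out-of-vocabulary name yields the uniform distribution.
#'
#' @slot embeddings V x dim matrix, one row per occupied hash bucket.
#' @slot vocabIds sorted integer hash-bucket ids matching embedding rows.
#' @slot outputWeights C x dim softmax weight matrix.
#' @slot classNames ordered class labels.
#' @slot config hyperparameters (nMin, nMax, buckets, dim, epochs, lr, seed).
#' @export
setClass("TextModel",
  representation(embeddings = "matrix", vocabIds = "integer",
    outputWeights = "matrix", classNames = "character", config = "list"),
  validity = function(object) {
    if (nrow(object@embeddings) != length(object@vocabIds))
      return("one embedding row per vocab id required")
    if (ncol(object@embeddings) != ncol(object@outputWeights))
      return("embedding and output dimensions must agree")
    if (nrow(object@outputWeights) != length(object@classNames))
      return("one output row per class required")
    TRUE
  })

#' Truncated SVD model
#'
#' Top-k right singular subspace of an n x d feature matrix, fitted without
#' mean-centering (the inputs are sparse binary occupancy vectors). Rows of
#' `components` are orthonormal; the sign of each component is fixed so its
#' largest-magnitude entry is positive, making serialized models stable.
#'
#' @slot components k x d matrix of right singular vectors.
#' @slot singularValues k nonnegative values, descending.
#' @slot k,d integer dimensions.
#' @slot seed integer recorded for provenance.
#' @export
setClass("SvdModel",
  representation(components = "matrix", singularValues = "numeric",
    k = "integer", d = "integer", seed = "integer"),
  validity = function(object) {
    if (nrow(object@components) != object@k) return("k rows required")
    if (ncol(object@components) != object@d) return("d columns required")
    if (is.unsorted(rev(object@singularValues)))
      return("singular values must be descending")
    if (any(object@singularValues < 0))
      return("singular values must be nonnegative")
    TRUE
  })

#' Random-forest ensemble with class-probability output
#' @slot fit the underlying ranger probability forest.
#' @slot classNames full ordered label set (probability columns follow it).
#' @slot config hyperparameters (numTrees, seed, ...).
#' @export
setClass("EnsembleClassifier",
  representation(fit = "ANY", classNames = "character", config = "list"))

#' Constant majority-label classifier
#' @slot label the majority training label.
#' @slot classNames ordered label set used for tie-breaking.
#' @export
setClass("MLBClassifier",
  representation(label = "character", classNames = "character"))

#' Evaluation report: confusion matrix plus macro metrics
#'
#' Macro precision/recall/F1 average per-class scores with equal weight over
#' the N classes present in truth or prediction (union-label convention);
#' zero-denominator per-class ratios count as 0. Accuracy is trace/total.
#'
#' @slot confusion |L| x |L| count matrix, rows = truth, columns = prediction.
#' @slot perClass per-class TP/FP/FN/TN and precision/recall/F1 table.
#' @slot macroPrecision,macroRecall,macroF1,accuracy metrics in [0,1].
#' @slot nEvaluated number N of labels entering the macro averages.
#' @export
setClass("EvaluationReport",
  representation(confusion = "matrix", perClass = "data.frame",
    macroPrecision = "numeric", macroRecall = "numeric",
    macroF1 = "numeric", accuracy = "numeric", nEvaluated = "integer"),
  validity = function(object) {
    m <- c(object@macroPrecision, object@macroRecall, object@macroF1,
           object@accuracy)
    if (any(m < 0 | m > 1)) return("metrics must lie in [0,1]")
    if (object@nEvaluated < 1) return("need at least one evaluated label")
    TRUE
  })

#' Train/validation/test split plan
#' @slot scheme "kfold5", "center_loo" or "center_holdout".
#' @slot splits list of splits, each a list of disjoint integer index vectors
#'   (train plus validation or test) covering the input records.
#' @export
setClass("SplitPlan", representation(scheme = "character", splits = "list"))

#' Synthetic multi-center cohort
#'
#' In-memory result of [generateCohort()]: the per-structure manifest, the
#' structure records, per-patient bony-anatomy feature rows (sparse), and the
#' shared phantom geometry.
#'
#' @slot manifest data.frame with structure_id, patient_id, center_id,
#'   given_name, true_label.
#' @slot structures list of [StructureRecord-class], one per manifest row.
#' @slot boneRows sparse patients x d 0/1 matrix (0-row when geometry off).
#' @slot patientIds row order of `boneRows`.
#' @slot box shared [BoundingBox-class] of all phantoms.
#' @slot gridShape integer(3) occupancy grid shape.
#' @slot labelSet task [LabelSet-class].
#' @slot disease "prostate" or "lung".
#' @slot config the generating config list.
#' @export
setClass("StructCohort",
  representation(manifest = "data.frame", structures = "list",
    boneRows = "ANY", patientIds = "character", box = "BoundingBox",
    gridShape = "integer", labelSet = "LabelSet", disease = "character",
    config = "list"))

#' Trained multi-view pipeline bundle
#'
#' Holds the artifacts one prediction mode needs: `text` a TextModel;
#' `image` an SvdModel (k = 100) + geometry classifier; `intermediate` a
#' TextModel + SvdModel (k = 50) + classifier on the 250-dim concatenation;
#' `late_avg`/`late_max` both single-view stacks; `mlb` the majority label.
#'
#' @slot mode one of text, image, intermediate, late_avg, late_max, mlb.
#' @slot labelSet task [LabelSet-class].
#' @slot textModel,svdModel,classifier,mlb artifacts (NULL when unused).
#' @slot config geometry grid, box, k, seeds.
#' @export
setClass("PipelineBundle",
  representation(mode = "character", labelSet = "LabelSet",
    textModel = "ANY", svdModel = "ANY", classifier = "ANY", mlb = "ANY",
    config = "list"))
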