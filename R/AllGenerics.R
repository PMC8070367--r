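#' Accessors for structviews classes
#'
#' Small accessor generics so user code never reaches into slots.
#'
#' @param x an object.
#' @return The slot value.
#' @name accessors
NULL

#' @rdname accessors
#' @export
setGeneric("classNames", function(x) standardGeneric("classNames"))
#' @rdname accessors
#' @export
setMethod("classNames", "LabelSet", function(x) x@classNames)
#' @rdname accessors
#' @export
setMethod("classNames", "TextModel", function(x) x@classNames)
#' @rdname accessors
#' @export
setMethod("classNames", "EnsembleClassifier", function(x) x@classNames)

#' @rdname accessors
#' @export
setGeneric("voxels", function(x) standardGeneric("voxels"))
#' @rdname accessors
#' @export
setMethod("voxels", "ImageSeries", function(x) x@voxels)

#' @rdname accessors
#' @export
setGeneric("spacing", function(x) standardGeneric("spacing"))
#' @rdname accessors
#' @export
setMethod("spacing", "ImageSeries", function(x) x@spacing)

#' @rdname accessors
#' @export
setGeneric("origin", function(x) standardGeneric("origin"))
#' @rdname accessors
#' @export
setMethod("origin", "ImageSeries", function(x) x@origin)

#' @rdname accessors
#' @export
setGeneric("givenName", function(x) standardGeneric("givenName"))
#' @rdname accessors
#' @export
setMethod("givenName", "StructureRecord", function(x) x@givenName)

#' @rdname accessors
#' @export
setGeneric("contours", function(x) standardGeneric("contours"))
#' @rdname accessors
#' @export
setMethod("contours", "StructureRecord", function(x) x@contours)

#' @rdname accessors
#' @export
setGeneric("trueLabel", function(x) standardGeneric("trueLabel"))
#' @rdname accessors
#' @export
setMethod("trueLabel", "StructureRecord", function(x) x@trueLabel)

#' @rdname accessors
#' @export
setGeneric("records", function(x) standardGeneric("records"))
#' @rdname accessors
#' @export
setMethod("records", "StructureSet", function(x) x@records)

#' @rdname accessors
#' @export
setGeneric("bits", function(x) standardGeneric("bits"))
#' @rdname accessors
#' @export
setMethod("bits", "BinaryVolume", function(x) x@bits)

#' @rdname accessors
#' @export
setGeneric("manifest", function(x) standardGeneric("manifest"))
#' @rdname accessors
#' @export
setMethod("manifest", "StructCohort", function(x) x@manifest)

#' @rdname accessors
#' @export
setGeneric("singularValues", function(x) standardGeneric("singularValues"))
#' @rdname accessors
#' @export
setMethod("singularValues", "SvdModel", function(x) x@singularValues)

#' @rdname accessors
#' @export
setGeneric("macroMetrics", function(x) standardGeneric("macroMetrics"))
#' @rdname accessors
#' @export
setMethod("macroMetrics", "EvaluationReport", function(x)
  c(precision = x@macroPrecision, recall = x@macroRecall,
    f1 = x@macroF1, accuracy = x@accuracy))

#' @rdname accessors
#' @export
setGeneric("confusion", function(x) standardGeneric("confusion"))
#' @rdname accessors
#' @export
setMethod("confusion", "EvaluationReport", function(x) x@confusion)

#' @rdname accessors
#' @export
setGeneric("perClassMetrics", function(x) standardGeneric("perClassMetrics"))
#' @rdname accessors
#' @export
setMethod("perClassMetrics", "EvaluationReport", function(x) x@perClass)

setMethod("show", "LabelSet", function(object) {
  cat("LabelSet with", length(object@classNames), "classes:",
      paste(object@classNames, collapse = ", "), "\n")
})

setMethod("show", "ImageSeries", function(object) {
  d <- dim(object@voxels)
  cat(sprintf("ImageSeries %s: %d x %d x %d voxels, spacing %.3g x %.3g x %.3g mm, HU range [%d, %d]\n",
    object@patientId, d[1], d[2], d[3], object@spacing[1], object@spacing[2],
    object@spacing[3], min(object@voxels), max(object@voxels)))
})

setMethod("show", "StructureRecord", function(object) {
  cat(sprintf("StructureRecord \"%s\" (label %s): %d contour(s), patient %s\n",
    object@givenName, object@trueLabel, length(object@contours),
    object@patientId))
})

setMethod("show", "StructureSet", function(object) {
  cat(sprintf("StructureSet for patient %s with %d structure(s)\n",
    object@patientId, length(object@records)))
  nm <- vapply(object@records, givenName, character(1))
  if (length(nm)) cat("  names:", paste(head(nm, 8), collapse = " | "),
                      if (length(nm) > 8) "..." else "", "\n")
})

setMethod("show", "BoundingBox", function(object) {
  cat(sprintf("BoundingBox [%.2f, %.2f] x [%.2f, %.2f] x [%.2f, %.2f] mm\n",
    object@minCorner[1], object@maxCorner[1], object@minCorner[2],
    object@maxCorner[2], object@minCorner[3], object@maxCorner[3]))
})

setMethod("show", "BinaryVolume", function(object) {
  d <- dim(object@bits)
  cat(sprintf("BinaryVolume %d x %d x %d, %d occupied voxel(s)\n",
    d[1], d[2], d[3], sum(object@bits)))
})

setMethod("show", "TextModel", function(object) {
  cat(sprintf("TextModel: %d classes, embedding dim %d, %d occupied buckets\n",
    length(object@classNames), ncol(object@embeddings),
    nrow(object@embeddings)))
})

setMethod("show", "SvdModel", function(object) {
  cat(sprintf("SvdModel: k = %d of d = %d, leading singular value %.4g\n",
    object@k, object@d, object@singularValues[1]))
})

setMethod("show", "EvaluationReport", function(object) {
  cat(sprintf(
    "EvaluationReport over %d labels: macro P %.3f / R %.3f / F1 %.3f, accuracy %.3f\n",
    object@nEvaluated, object@macroPrecision, object@macroRecall,
    object@macroF1, object@accuracy))
})

setMethod("show", "SplitPlan", function(object) {
  cat(sprintf("SplitPlan '%s' with %d split(s)\n", object@scheme,
              length(object@splits)))
})

setMethod("show", "StructCohort", function(object) {
  cat(sprintf("StructCohort (%s): %d structures, %d patients, %d centers\n",
    object@disease, nrow(object@manifest),
    length(unique(object@manifest$patient_id)),
    length(unique(object@manifest$center_id))))
})

setMethod("show", "PipelineBundle", function(object) {
  cat(sprintf("PipelineBundle mode '%s' over %d classes\n", object@mode,
    length(classNames(object@labelSet))))
})
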