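#' @include AllClasses.R
NULL

#' Accessors for EHRDataset tables
#'
#' @param x an \linkS4class{EHRDataset}.
#' @return the requested table as a data.frame, or the system label.
#' @name EHRDataset-accessors
#' @aliases persons events notes observationPeriods systemId
NULL

#' @rdname EHRDataset-accessors
#' @export
setGeneric("persons", function(x) standardGeneric("persons"))
#' @rdname EHRDataset-accessors
#' @export
setGeneric("events", function(x) standardGeneric("events"))
#' @rdname EHRDataset-accessors
#' @export
setGeneric("notes", function(x) standardGeneric("notes"))
#' @rdname EHRDataset-accessors
#' @export
setGeneric("observationPeriods", function(x) standardGeneric("observationPeriods"))
#' @rdname EHRDataset-accessors
#' @export
setGeneric("systemId", function(x) standardGeneric("systemId"))

#' @rdname EHRDataset-accessors
setMethod("persons", "EHRDataset", function(x) x@persons)
#' @rdname EHRDataset-accessors
setMethod("events", "EHRDataset", function(x) x@events)
#' @rdname EHRDataset-accessors
setMethod("notes", "EHRDataset", function(x) x@notes)
#' @rdname EHRDataset-accessors
setMethod("observationPeriods", "EHRDataset", function(x) x@observationPeriods)
#' @rdname EHRDataset-accessors
setMethod("systemId", "EHRDataset", function(x) x@systemId)

setMethod("show", "EHRDataset", function(object) {
  cat("EHRDataset (system ", object@systemId, ")\n", sep = "")
  cat("  persons:             ", nrow(object@persons), "\n")
  cat("  events:              ", nrow(object@events), "\n")
  cat("  notes:               ", nrow(object@notes), "\n")
  cat("  observation periods: ", nrow(object@observationPeriods), "\n")
})

#' Accessors for FeatureMatrix
#'
#' @param x a \linkS4class{FeatureMatrix}.
#' @return \code{featureValues}: the sparse \code{dgCMatrix};
#'   \code{featureInfo}: the per-column provenance data.frame;
#'   \code{observationKeys}: the per-row cohort key data.frame.
#' @name FeatureMatrix-accessors
#' @aliases featureValues featureInfo observationKeys
NULL

#' @rdname FeatureMatrix-accessors
#' @export
setGeneric("featureValues", function(x) standardGeneric("featureValues"))
#' @rdname FeatureMatrix-accessors
#' @export
setGeneric("featureInfo", function(x) standardGeneric("featureInfo"))
#' @rdname FeatureMatrix-accessors
#' @export
setGeneric("observationKeys", function(x) standardGeneric("observationKeys"))

#' @rdname FeatureMatrix-accessors
setMethod("featureValues", "FeatureMatrix", function(x) x@values)
#' @rdname FeatureMatrix-accessors
setMethod("featureInfo", "FeatureMatrix", function(x) x@featureInfo)
#' @rdname FeatureMatrix-accessors
setMethod("observationKeys", "FeatureMatrix", function(x) x@observations)

#' @rdname FeatureMatrix-accessors
#' @export
setMethod("dim", "FeatureMatrix", function(x) dim(x@values))

setMethod("show", "FeatureMatrix", function(object) {
  sets <- table(object@featureInfo$source_set)
  cat("FeatureMatrix: ", nrow(object@values), " observations x ",
      ncol(object@values), " features\n", sep = "")
  if (length(sets)) {
    cat("  sets: ", paste(sprintf("%s=%d", names(sets), as.integer(sets)),
                          collapse = ", "), "\n", sep = "")
  }
  cat("  density: ",
      signif(Matrix::nnzero(object@values) / max(1, prod(dim(object@values))), 3),
      "\n", sep = "")
})

setMethod("show", "TextPipeline", function(object) {
  cat("TextPipeline (", object@representation, ")\n", sep = "")
  cat("  vocabulary: ", length(object@vocabulary), " terms, fitted on ",
      object@nDocs, " documents\n", sep = "")
  cat("  df bounds:  [", object@minDf, ", ", object@maxDf, "] x N\n", sep = "")
  cat("  window:     ", object@textWindowDays, " days\n", sep = "")
})
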