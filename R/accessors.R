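## Accessors and show methods. Slots are never reached into by user code.

#' @rdname ParcelAtlas-class
#' @param x,object a ParcelAtlas.
#' @export
setGeneric("regionIds", function(x) standardGeneric("regionIds"))
#' @rdname ParcelAtlas-class
#' @export
setMethod("regionIds", "ParcelAtlas", function(x) x@regionId)
#' @rdname ParcelAtlas-class
#' @export
setMethod("regionIds", "Connectome", function(x) x@regionId)
#' @rdname ParcelAtlas-class
#' @export
setMethod("regionIds", "WScoreModel", function(x) x@regionId)
#' @rdname ParcelAtlas-class
#' @export
setMethod("regionIds", "SpinNulls", function(x) x@regionId)

#' @rdname ParcelAtlas-class
#' @export
setGeneric("hemispheres", function(x) standardGeneric("hemispheres"))
#' @rdname ParcelAtlas-class
#' @export
setMethod("hemispheres", "ParcelAtlas", function(x) x@hemisphere)

#' @rdname ParcelAtlas-class
#' @export
setGeneric("centroids", function(x) standardGeneric("centroids"))
#' @rdname ParcelAtlas-class
#' @export
setMethod("centroids", "ParcelAtlas", function(x) {
  m <- x@centroid
  rownames(m) <- x@regionId
  colnames(m) <- c("x", "y", "z")
  m
})

#' @rdname ParcelAtlas-class
#' @export
setGeneric("networks", function(x) standardGeneric("networks"))
#' @rdname ParcelAtlas-class
#' @export
setMethod("networks", "ParcelAtlas", function(x) stats::setNames(x@network, x@regionId))

#' @rdname ParcelAtlas-class
#' @export
setGeneric("corticalTypes", function(x) standardGeneric("corticalTypes"))
#' @rdname ParcelAtlas-class
#' @export
setMethod("corticalTypes", "ParcelAtlas", function(x) stats::setNames(x@corticalType, x@regionId))

#' @rdname ParcelAtlas-class
#' @export
setGeneric("nRegions", function(x) standardGeneric("nRegions"))
#' @rdname ParcelAtlas-class
#' @export
setMethod("nRegions", "ParcelAtlas", function(x) length(x@regionId))
#' @rdname ParcelAtlas-class
#' @export
setMethod("nRegions", "Connectome", function(x) length(x@regionId))

setMethod("show", "ParcelAtlas", function(object) {
  cat("ParcelAtlas with", length(object@regionId), "regions (",
      sum(object@hemisphere == "L"), "L /", sum(object@hemisphere == "R"), "R )\n")
  cat("  networks:", paste(levels(object@network), collapse = ", "), "\n")
  cat("  cortical types:", paste(levels(object@corticalType), collapse = ", "), "\n")
})

#' @rdname CohortTable-class
#' @param x,object a CohortTable.
#' @export
setGeneric("demographics", function(x) standardGeneric("demographics"))
#' @rdname CohortTable-class
#' @export
setMethod("demographics", "CohortTable", function(x) x@demographics)

#' @rdname CohortTable-class
#' @export
setGeneric("deformationValues", function(x) standardGeneric("deformationValues"))
#' @rdname CohortTable-class
#' @export
setMethod("deformationValues", "CohortTable", function(x) x@values)

#' Subset a cohort by group and/or session
#'
#' @param x a CohortTable.
#' @param group optional group to keep (`"HC"` or `"PD"`).
#' @param session optional session to keep.
#' @return a CohortTable with the selected rows.
#' @export
subsetCohort <- function(x, group = NULL, session = NULL) {
  stopifnot(is(x, "CohortTable"))
  keep <- rep(TRUE, nrow(x@demographics))
  if (!is.null(group)) keep <- keep & x@demographics$group %in% group
  if (!is.null(session)) keep <- keep & x@demographics$session %in% session
  CohortTable(x@demographics[keep, , drop = FALSE],
              x@values[keep, , drop = FALSE])
}

setMethod("show", "CohortTable", function(object) {
  d <- object@demographics
  cat("CohortTable:", nrow(d), "subject-sessions,",
      length(unique(d$subjectId)), "subjects,",
      ncol(object@values), "regions\n")
  print(table(group = d$group, session = d$session))
})

#' @rdname Connectome-class
#' @param x,object a Connectome.
#' @export
setGeneric("structuralMatrix", function(x) standardGeneric("structuralMatrix"))
#' @rdname Connectome-class
#' @export
setMethod("structuralMatrix", "Connectome", function(x) x@sc)

#' @rdname Connectome-class
#' @export
setGeneric("functionalMatrix", function(x) standardGeneric("functionalMatrix"))
#' @rdname Connectome-class
#' @export
setMethod("functionalMatrix", "Connectome", function(x) x@fc)

setMethod("show", "Connectome", function(object) {
  n <- length(object@regionId)
  dens <- sum(object@sc > 0) / (n * (n - 1))
  cat(sprintf("Connectome over %d regions; structural density %.3f\n", n, dens))
})

#' @rdname WScoreModel-class
#' @param x,object a WScoreModel.
#' @export
setGeneric("modelCoefficients", function(x) standardGeneric("modelCoefficients"))
#' @rdname WScoreModel-class
#' @export
setMethod("modelCoefficients", "WScoreModel", function(x) {
  m <- x@coefficients
  rownames(m) <- x@regionId
  m
})

#' @rdname WScoreModel-class
#' @export
setGeneric("residualSd", function(x) standardGeneric("residualSd"))
#' @rdname WScoreModel-class
#' @export
setMethod("residualSd", "WScoreModel", function(x) stats::setNames(x@residSd, x@regionId))

#' @rdname WScoreModel-class
#' @export
setGeneric("nControls", function(x) standardGeneric("nControls"))
#' @rdname WScoreModel-class
#' @export
setMethod("nControls", "WScoreModel", function(x) x@nControls)

setMethod("show", "WScoreModel", function(object) {
  cat("WScoreModel:", length(object@regionId), "regions fitted on",
      object@nControls, "controls\n")
  cat(sprintf("  median residual SD: %.4g\n", stats::median(object@residSd)))
})

#' @rdname SpinNulls-class
#' @param x,object a SpinNulls.
#' @export
setGeneric("spinAssignments", function(x) standardGeneric("spinAssignments"))
#' @rdname SpinNulls-class
#' @export
setMethod("spinAssignments", "SpinNulls", function(x) x@assignment)

#' @rdname SpinNulls-class
#' @export
setGeneric("nSpins", function(x) standardGeneric("nSpins"))
#' @rdname SpinNulls-class
#' @export
setMethod("nSpins", "SpinNulls", function(x) nrow(x@assignment))

setMethod("show", "SpinNulls", function(object) {
  cat(sprintf("SpinNulls: %d spins x %d regions (method=%s, seed=%d)\n",
              nrow(object@assignment), ncol(object@assignment),
              object@method, object@seed))
})
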