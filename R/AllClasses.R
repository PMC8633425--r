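#' @import methods
NULL

#' ParcelAtlas: a spherical brain parcellation
#'
#' Holds one row per cortical parcel: a region identifier, hemisphere, a
#' unit-sphere centroid used by the spin permutation machinery, a
#' resting-state network label and a cortical cytoarchitectonic type
#' (paralimbic / heteromodal / unimodal / idiotypic).
#'
#' @slot regionId character vector of unique region identifiers.
#' @slot hemisphere factor with levels `L`, `R`.
#' @slot centroid numeric matrix (regions x 3) of unit vectors.
#' @slot network factor of network labels.
#' @slot corticalType factor of cortical-type labels.
#' @export
setClass("ParcelAtlas",
  representation(regionId = "character", hemisphere = "factor",
                 centroid = "matrix", network = "factor",
                 corticalType = "factor"))

setValidity("ParcelAtlas", function(object) {
  n <- length(object@regionId)
  msg <- character()
  if (anyDuplicated(object@regionId)) msg <- c(msg, "duplicate region_id")
  if (length(object@hemisphere) != n || nrow(object@centroid) != n ||
      length(object@network) != n || length(object@corticalType) != n)
    msg <- c(msg, "field lengths differ")
  if (ncol(object@centroid) != 3L) msg <- c(msg, "centroid must be n x 3")
  if (!all(levels(object@hemisphere) %in% c("L", "R")))
    msg <- c(msg, "hemisphere levels must be L/R")
  if (n > 0) {
    norms <- sqrt(rowSums(object@centroid^2))
    if (any(abs(norms - 1) > 1e-9))
      msg <- c(msg, "centroids must have unit norm (within 1e-9)")
  }
  if (anyNA(object@hemisphere) || anyNA(object@network) ||
      anyNA(object@corticalType))
    msg <- c(msg, "missing labels")
  if (length(msg)) msg else TRUE
})

#' Construct a ParcelAtlas
#'
#' Centroids whose norm is within 1e-6 of 1 are renormalized to exact unit
#' length; centroids further from the sphere are an error, and zero vectors
#' are rejected as degenerate.
#'
#' @param regionId character region ids.
#' @param hemisphere character/factor of `L`/`R`.
#' @param centroid numeric matrix (regions x 3).
#' @param network character/factor network labels.
#' @param corticalType character/factor cortical-type labels.
#' @return a [ParcelAtlas-class] object.
#' @export
ParcelAtlas <- function(regionId, hemisphere, centroid, network, corticalType) {
  centroid <- as.matrix(centroid)
  storage.mode(centroid) <- "double"
  norms <- sqrt(rowSums(centroid^2))
  if (any(norms < 1e-8))
    stop("degenerate centroid: zero vector has no direction (region ",
         regionId[which(norms < 1e-8)[1L]], ")")
  if (any(abs(norms - 1) > 1e-6))
    stop("non-unit centroid beyond tolerance (region ",
         regionId[which(abs(norms - 1) > 1e-6)[1L]], ")")
  centroid <- centroid / norms
  hemisphere <- as.character(hemisphere)
  if (!all(hemisphere %in% c("L", "R")))
    stop("unknown hemisphere code: ",
         paste(unique(setdiff(hemisphere, c("L", "R"))), collapse = ", "))
  obj <- new("ParcelAtlas", regionId = as.character(regionId),
             hemisphere = factor(hemisphere, levels = c("L", "R")),
             centroid = centroid,
             network = factor(as.character(network)),
             corticalType = factor(as.character(corticalType)))
  validObject(obj)
  obj
}

#' CohortTable: longitudinal deformation observations
#'
#' One row per subject-session: demographics plus the full regional
#' deformation vector (expansion/contraction ratios relative to template,
#' unitless).
#'
#' @slot demographics data.frame with columns subjectId, group (PD/HC),
#'   session (ordered bl < y1 < y2 < y4), age (years), sex (0 = female,
#'   1 = male), site.
#' @slot values numeric matrix (subject-sessions x regions), columns named
#'   by region id in atlas order.
#' @export
setClass("CohortTable",
  representation(demographics = "data.frame", values = "matrix"))

setValidity("CohortTable", function(object) {
  d <- object@demographics
  msg <- character()
  need <- c("subjectId", "group", "session", "age", "sex", "site")
  if (!all(need %in% names(d)))
    msg <- c(msg, paste("demographics must contain:", paste(need, collapse = ", ")))
  else {
    if (anyDuplicated(paste(d$subjectId, d$session)))
      msg <- c(msg, "(subjectId, session) must be unique")
    if (any(d$age <= 0)) msg <- c(msg, "age must be positive")
    if (!all(d$sex %in% c(0, 1))) msg <- c(msg, "sex must be coded 0/1")
    if (!all(as.character(d$group) %in% c("PD", "HC")))
      msg <- c(msg, "group must be PD or HC")
  }
  if (nrow(object@values) != nrow(d))
    msg <- c(msg, "values rows must match demographics rows")
  if (is.null(colnames(object@values)))
    msg <- c(msg, "values columns must be named by region")
  if (length(msg)) msg else TRUE
})

sessionLevels <- c("bl", "y1", "y2", "y4")

#' Construct a CohortTable
#' @param demographics data.frame (see [CohortTable-class]).
#' @param values numeric matrix, one column per region.
#' @return a [CohortTable-class] object.
#' @export
CohortTable <- function(demographics, values) {
  demographics$session <- factor(as.character(demographics$session),
                                 levels = sessionLevels, ordered = TRUE)
  demographics$group <- factor(as.character(demographics$group),
                               levels = c("HC", "PD"))
  obj <- new("CohortTable", demographics = demographics,
             values = as.matrix(values))
  validObject(obj)
  obj
}

#' Connectome: structural and functional connectivity over an atlas
#'
#' @slot sc symmetric non-negative structural adjacency (binary or weighted),
#'   zero diagonal.
#' @slot fc symmetric functional weight matrix with entries in \[-1, 1\],
#'   zero diagonal.
#' @slot regionId region ids fixing row/column order.
#' @export
setClass("Connectome",
  representation(sc = "matrix", fc = "matrix", regionId = "character"))

setValidity("Connectome", function(object) {
  msg <- character()
  n <- length(object@regionId)
  for (nm in c("sc", "fc")) {
    m <- slot(object, nm)
    if (!all(dim(m) == n)) msg <- c(msg, paste(nm, "shape must match atlas"))
    else {
      if (max(abs(m - t(m))) > 1e-8) msg <- c(msg, paste(nm, "must be symmetric"))
      if (any(diag(m) != 0)) msg <- c(msg, paste(nm, "diagonal must be zero"))
    }
  }
  if (any(object@sc < 0)) msg <- c(msg, "sc must be non-negative")
  if (any(abs(object@fc) > 1 + 1e-8)) msg <- c(msg, "fc must lie in [-1, 1]")
  if (length(msg)) msg else TRUE
})

#' Construct a Connectome
#' @param sc structural adjacency matrix.
#' @param fc functional weight matrix.
#' @param regionId region ids in matrix order.
#' @return a [Connectome-class] object.
#' @export
Connectome <- function(sc, fc, regionId) {
  sc <- as.matrix(sc); fc <- as.matrix(fc)
  dimnames(sc) <- dimnames(fc) <- list(regionId, regionId)
  obj <- new("Connectome", sc = sc, fc = fc, regionId = as.character(regionId))
  validObject(obj)
  obj
}

#' WScoreModel: per-region normative regression of deformation on age and sex
#'
#' For each region, deformation in healthy controls is modelled as
#' `beta_age * age + beta_sex * sex + beta_intercept + eps`, and the residual
#' standard deviation (denominator n - 3) standardizes patient deviations
#' into W-scores.
#'
#' @slot coefficients numeric matrix (regions x 3), columns
#'   `beta_age`, `beta_sex`, `beta_intercept`.
#' @slot residSd numeric vector of control residual SDs, all positive.
#' @slot nControls integer number of controls used for the fit.
#' @slot regionId character region ids.
#' @export
setClass("WScoreModel",
  representation(coefficients = "matrix", residSd = "numeric",
                 nControls = "integer", regionId = "character"))

setValidity("WScoreModel", function(object) {
  msg <- character()
  n <- length(object@regionId)
  if (nrow(object@coefficients) != n || length(object@residSd) != n)
    msg <- c(msg, "coefficient rows and residSd must match regions")
  if (!identical(colnames(object@coefficients),
                 c("beta_age", "beta_sex", "beta_intercept")))
    msg <- c(msg, "coefficient columns must be beta_age, beta_sex, beta_intercept")
  if (any(object@residSd <= 0)) msg <- c(msg, "residSd must be positive")
  if (object@nControls < 4L) msg <- c(msg, "nControls must be >= 4")
  if (length(msg)) msg else TRUE
})

#' SpinNulls: spatial rotation-based null assignments
#'
#' Each row maps region index -> source region index under one random
#' rotation of the spherical parcel centroids (sampled on the left
#' hemisphere, mirrored to the right).
#'
#' @slot assignment integer matrix (nSpins x nRegions).
#' @slot method `"nearest"` (duplicates allowed) or `"bijective"`.
#' @slot seed integer seed the spins were generated from.
#' @slot regionId character region ids.
#' @export
setClass("SpinNulls",
  representation(assignment = "matrix", method = "character",
                 seed = "integer", regionId = "character"))

setValidity("SpinNulls", function(object) {
  msg <- character()
  n <- length(object@regionId)
  a <- object@assignment
  if (ncol(a) != n) msg <- c(msg, "assignment columns must match regions")
  if (any(a < 1L) || any(a > n)) msg <- c(msg, "assignment entries out of range")
  if (!object@method %in% c("nearest", "bijective"))
    msg <- c(msg, "method must be nearest or bijective")
  if (object@method == "bijective" && nrow(a) > 0 &&
      !all(apply(a, 1L, function(r) identical(sort(r), seq_len(n)))))
    msg <- c(msg, "bijective rows must be permutations")
  if (length(msg)) msg else TRUE
})
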