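#' Generate spatially autocorrelated regional gene expression
#'
#' Each gene is a Gaussian random field on the sphere (squared-exponential
#' kernel `exp(-d^2 / (2 * lengthscale^2))` on great-circle distance) plus
#' white noise, z-scored per gene across regions — emulating donor-averaged
#' microarray expression mapped to a parcellation. Two kinds of structure
#' are planted for recovery tests:
#'
#' * **Cell-class sets.** Seven marker-gene sets (astrocytes, endothelial
#'   cells, microglia, excitatory/inhibitory neurons, oligodendrocytes,
#'   OPCs) whose genes share a common latent spatial pattern with loading
#'   `classLoading`; the latent patterns are returned so generators can
#'   couple regional vulnerability to a class (e.g. a protective
#'   endothelial gradient).
#' * **Annotation terms.** If `signalMap` is given, `nSignalGenes` genes
#'   track it with loading `signalLoading`, and the annotation GMT gains a
#'   positive-control term (`T_SIGNAL`, drawn from those genes) alongside a
#'   matched random negative-control term (`T_RANDOM`) and further random
#'   terms.
#'
#' @param atlas a [ParcelAtlas-class].
#' @param nGenes total genes (>= 20).
#' @param lengthscale kernel length scale in radians; values below 1e-6
#'   give spatially white fields.
#' @param nPerClass genes per cell-class set.
#' @param classLoading correlation of a class gene with its latent pattern.
#' @param signalMap optional per-region vector the signal genes track.
#' @param nSignalGenes number of signal genes (0 if `signalMap` is NULL).
#' @param signalLoading loading of signal genes on `signalMap`.
#' @param noiseSd SD of the white-noise component added to every gene.
#' @param nTerms total annotation terms (including the two controls).
#' @param termSize genes per annotation term.
#' @param classLatent optional regions x 7 matrix of latent class patterns
#'   (unit variance) to use instead of drawing them; lets a caller couple
#'   other generated quantities (e.g. regional vulnerability) to a class.
#' @param seed integer seed.
#' @return list with elements `expr` (regions x genes, z-scored),
#'   `cellSets` (named list of 7 gene sets), `annotation` (named list of
#'   term gene sets), and `truth` (class latent patterns, signal gene ids).
#' @export
makeExpression <- function(atlas, nGenes = 1000L, lengthscale = 0.3,
                           nPerClass = 25L, classLoading = 0.6,
                           signalMap = NULL, nSignalGenes = 50L,
                           signalLoading = 0.7, noiseSd = 0.5,
                           nTerms = 10L, termSize = 40L,
                           classLatent = NULL, seed = 1L) {
  stopifnot(is(atlas, "ParcelAtlas"))
  if (nGenes < 20L) stop("nGenes must be >= 20")
  classes <- c("Astro", "Endo", "Micro", "Neuro-Ex", "Neuro-In",
               "Oligo", "OPC")
  if (is.null(signalMap)) nSignalGenes <- 0L
  nPlanted <- length(classes) * nPerClass + nSignalGenes
  if (nPlanted > nGenes)
    stop("planted sets larger than nGenes (", nPlanted, " > ", nGenes, ")")
  n <- nRegions(atlas)

  old <- .Random.seed_save(); on.exit(.Random.seed_restore(old))
  set.seed(childSeed(seed, "expression"))

  sampleField <- if (lengthscale < 1e-6) {
    function(k) matrix(stats::rnorm(n * k), n, k)
  } else {
    d <- .greatCircle(centroids(atlas))
    kmat <- exp(-d^2 / (2 * lengthscale^2)) + diag(1e-8, n)
    cholK <- chol(kmat)
    function(k) crossprod(cholK, matrix(stats::rnorm(n * k), n, k))
  }

  own <- sampleField(nGenes)
  if (is.null(classLatent)) {
    latent <- scale(sampleField(length(classes)))   # unit-variance latents
  } else {
    if (!all(dim(classLatent) == c(n, length(classes))))
      stop("classLatent must be regions x ", length(classes))
    latent <- scale(classLatent)
  }
  colnames(latent) <- classes

  geneNames <- sprintf("G%05d", seq_len(nGenes))
  expr <- own
  gi <- 0L
  cellSets <- list()
  for (ci in seq_along(classes)) {
    idx <- gi + seq_len(nPerClass); gi <- gi + nPerClass
    expr[, idx] <- classLoading * latent[, ci] +
      sqrt(1 - classLoading^2) * own[, idx]
    cellSets[[classes[ci]]] <- geneNames[idx]
  }
  signalGenes <- character()
  if (nSignalGenes > 0L) {
    idx <- gi + seq_len(nSignalGenes); gi <- gi + nSignalGenes
    sm <- as.vector(scale(signalMap))
    expr[, idx] <- signalLoading * sm +
      sqrt(1 - signalLoading^2) * own[, idx]
    signalGenes <- geneNames[idx]
  }
  expr <- expr + matrix(stats::rnorm(n * nGenes, sd = noiseSd), n, nGenes)
  expr <- scale(expr)              # z-score per gene across regions
  attr(expr, "scaled:center") <- NULL
  attr(expr, "scaled:scale") <- NULL
  dimnames(expr) <- list(regionIds(atlas), geneNames)

  annotation <- list()
  if (nSignalGenes > 0L) {
    annotation[["T_SIGNAL"]] <- sample(signalGenes,
                                       min(termSize, nSignalGenes))
    annotation[["T_RANDOM"]] <- sample(setdiff(geneNames, signalGenes),
                                       min(termSize, nGenes - nSignalGenes))
  }
  while (length(annotation) < nTerms) {
    annotation[[sprintf("T_%03d", length(annotation) + 1L)]] <-
      sample(geneNames, min(termSize, nGenes))
  }
  list(expr = expr, cellSets = cellSets, annotation = annotation,
       truth = list(classLatent = latent[, , drop = FALSE],
                    signalGenes = signalGenes))
}

## Sample k Gaussian random fields on the atlas sphere (squared-exponential
## kernel on great-circle distance). Used by makeExpression internally and
## by makeStudyData to draw class latents that other generated quantities
## (vulnerability) can be coupled to.
.sphericalFields <- function(atlas, k, lengthscale, seed) {
  n <- nRegions(atlas)
  old <- .Random.seed_save(); on.exit(.Random.seed_restore(old))
  set.seed(seed)
  if (lengthscale < 1e-6) return(matrix(stats::rnorm(n * k), n, k))
  d <- .greatCircle(centroids(atlas))
  kmat <- exp(-d^2 / (2 * lengthscale^2)) + diag(1e-8, n)
  crossprod(chol(kmat), matrix(stats::rnorm(n * k), n, k))
}
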