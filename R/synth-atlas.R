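#' Generate a synthetic spherical parcel atlas
#'
#' Parcels are placed on a Fibonacci lattice covering each unit hemisphere
#' (sagittal plane x = 0; left hemisphere x < 0), so the right hemisphere is
#' the exact mirror image of the left. Network labels are spatially
#' contiguous Voronoi patches around `nNetworks` random seed directions
#' (mirrored across hemispheres); cortical types follow a smooth
#' latitude-like gradient quantized into four classes, ordered
#' idiotypic -> unimodal -> heteromodal -> paralimbic from the inferior to
#' the superior pole. This emulates the geometry the spin-permutation null
#' assumes: parcel centroids on a sphere with mirror-symmetric hemispheres.
#'
#' @param nPerHemisphere number of parcels per hemisphere (>= 4).
#' @param nNetworks number of network patches (default 7).
#' @param seed integer seed; the construction is deterministic given it.
#' @return a [ParcelAtlas-class] with `2 * nPerHemisphere` regions.
#' @export
makeAtlas <- function(nPerHemisphere, nNetworks = 7L, seed = 1L) {
  if (nPerHemisphere < 4L) stop("nPerHemisphere must be >= 4")
  if (nNetworks > nPerHemisphere)
    stop("nNetworks must not exceed nPerHemisphere")
  n <- as.integer(nPerHemisphere)
  i <- seq_len(n)
  # Fibonacci lattice on the hemisphere around the -x axis: uniform in area.
  cosTheta <- 1 - (i - 0.5) / n            # in (0, 1): strictly x < 0
  sinTheta <- sqrt(1 - cosTheta^2)
  golden <- (1 + sqrt(5)) / 2
  phi <- 2 * pi * i / golden
  left <- cbind(x = -cosTheta, y = sinTheta * cos(phi), z = sinTheta * sin(phi))
  right <- left
  right[, 1L] <- -right[, 1L]

  withr_seed <- childSeed(seed, "atlas-networks")
  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old))
  set.seed(withr_seed)
  seedIdx <- sample.int(n, nNetworks)
  dSeed <- .greatCircle(left, left[seedIdx, , drop = FALSE])
  netLeft <- max.col(-dSeed, ties.method = "first")

  # latitude gradient shared by mirrored pairs -> symmetric type bands
  zq <- stats::quantile(left[, 3L], probs = c(0.25, 0.5, 0.75))
  typeNames <- c("idiotypic", "unimodal", "heteromodal", "paralimbic")
  typeLeft <- typeNames[findInterval(left[, 3L], zq) + 1L]

  ParcelAtlas(
    regionId = c(sprintf("L%03d", i), sprintf("R%03d", i)),
    hemisphere = rep(c("L", "R"), each = n),
    centroid = rbind(left, right),
    network = sprintf("N%d", c(netLeft, netLeft)),
    corticalType = c(typeLeft, typeLeft))
}

## Save/restore the global RNG state so generators do not perturb the
## caller's stream beyond their own seeded draws.
.Random.seed_save <- function() {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
    get(".Random.seed", envir = globalenv())
  else NULL
}

.Random.seed_restore <- function(old) {
  if (is.null(old)) {
    if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  } else {
    assign(".Random.seed", old, envir = globalenv())
  }
}
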