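#' Generate a synthetic structural + functional connectome
#'
#' Structural edges are sampled with probability proportional to
#' `exp(-d / decayLength)` where `d` is the great-circle distance between
#' parcel centroids, calibrated so the realized density lands within 10% of
#' `targetDensity`; sampling is repeated (up to 10 draws) until the graph is
#' connected. The functional matrix is the degree-normalized communicability
#' of the structural graph (`G_ij / sqrt(G_ii G_jj)` with `G = expm(A)`),
#' plus symmetric Gaussian noise, rescaled into \[-1, 1\] with zero
#' diagonal. This mirrors the empirical observation that functional
#' connectivity is constrained by, but noisier than, structural paths.
#'
#' @param atlas a [ParcelAtlas-class].
#' @param targetDensity edge density in (0, 1).
#' @param decayLength distance decay scale in radians; `Inf` gives
#'   distance-independent (uniform) edge probabilities.
#' @param fcNoiseSd SD of the Gaussian noise added to the functional
#'   matrix before rescaling; 0 makes FC a deterministic function of SC.
#' @param seed integer seed.
#' @param maxTries resampling attempts for connectedness (default 10).
#' @return a [Connectome-class] with binary `sc` and `fc` in \[-1, 1\].
#' @export
makeConnectome <- function(atlas, targetDensity = 0.10, decayLength = 1.0,
                           fcNoiseSd = 0.1, seed = 1L, maxTries = 10L) {
  stopifnot(is(atlas, "ParcelAtlas"))
  if (targetDensity <= 0 || targetDensity >= 1)
    stop("targetDensity must be in (0, 1)")
  n <- nRegions(atlas)
  d <- .greatCircle(centroids(atlas))
  k <- if (is.infinite(decayLength)) matrix(1, n, n) else exp(-d / decayLength)
  diag(k) <- 0
  ut <- upper.tri(k)
  kv <- k[ut]
  # calibrate c so mean(min(1, c * k)) over pairs equals targetDensity
  f <- function(cc) mean(pmin(1, cc * kv)) - targetDensity
  cc <- stats::uniroot(f, lower = 0, upper = 1 / max(kv) / targetDensity * 10,
                       extendInt = "upX", tol = 1e-12)$root
  p <- pmin(1, cc * kv)

  old <- .Random.seed_save(); on.exit(.Random.seed_restore(old))
  set.seed(childSeed(seed, "connectome-sc"))
  a <- NULL
  for (try in seq_len(maxTries)) {
    av <- as.numeric(stats::runif(length(p)) < p)
    m <- matrix(0, n, n)
    m[ut] <- av
    m <- m + t(m)
    dens <- sum(m) / (n * (n - 1))
    if (abs(dens - targetDensity) > 0.1 * targetDensity) next
    g <- igraph::graph_from_adjacency_matrix(m, mode = "undirected")
    if (igraph::components(g)$no == 1L) { a <- m; break }
  }
  if (is.null(a))
    stop("could not generate a connected graph at this density; ",
         "increase targetDensity or decayLength")

  gcom <- as.matrix(Matrix::expm(Matrix::Matrix(a, sparse = FALSE)))
  fc <- gcom / sqrt(outer(diag(gcom), diag(gcom)))
  diag(fc) <- 0
  if (fcNoiseSd > 0) {
    set.seed(childSeed(seed, "connectome-fc"))
    e <- matrix(0, n, n)
    e[ut] <- stats::rnorm(sum(ut), sd = fcNoiseSd)
    fc <- fc + e + t(e)
  }
  off <- max(abs(fc[row(fc) != col(fc)]))
  if (off > 0) fc <- fc / off
  diag(fc) <- 0
  Connectome(sc = a, fc = fc, regionId = regionIds(atlas))
}

#' Simulate linear accumulation spread on a structural network
#'
#' A minimal network-propagation process standing in for trans-neuronal
#' spread of a pathogenic agent: starting from unit load on the seed
#' regions, every step each region accrues
#' `eta * vulnerability_i * sum_j (A_ij / deg_i) * a_j`, i.e. transfer along
#' structural edges normalized by the receiving region's degree and scaled
#' by its local vulnerability. Accumulated load is monotonically
#' non-decreasing in both step count and `eta`. Isolated regions simply
#' never accrue load.
#'
#' @param sc symmetric non-negative structural adjacency with region-id
#'   dimnames (or unnamed; then integer indices are used).
#' @param seedRegions character ids or integer indices of seed regions.
#' @param eta per-step transfer rate (>= 0).
#' @param nSteps number of steps (>= 0).
#' @param vulnerability positive per-region multipliers, default 1.
#' @return named numeric vector of accumulated load (>= 0).
#' @export
simulateSpread <- function(sc, seedRegions, eta, nSteps, vulnerability = 1) {
  sc <- as.matrix(sc)
  if (anyNA(sc)) stop("NaN/NA in structural matrix")
  if (eta < 0) stop("eta must be >= 0")
  if (nSteps < 0) stop("nSteps must be >= 0")
  n <- nrow(sc)
  ids <- rownames(sc)
  if (is.null(ids)) ids <- as.character(seq_len(n))
  if (is.character(seedRegions)) {
    idx <- match(seedRegions, ids)
    if (anyNA(idx)) stop("seed region not in atlas: ",
                         seedRegions[which(is.na(idx))[1L]])
  } else idx <- as.integer(seedRegions)
  if (length(idx) == 0L) stop("seedRegions must be nonempty")
  vulnerability <- rep_len(vulnerability, n)
  if (any(vulnerability <= 0)) stop("vulnerability must be positive")

  deg <- rowSums(sc)
  anorm <- sc / ifelse(deg > 0, deg, 1)
  anorm[deg == 0, ] <- 0
  a <- numeric(n)
  a[idx] <- 1
  for (t in seq_len(nSteps))
    a <- a + eta * vulnerability * as.vector(anorm %*% a)
  stats::setNames(a, ids)
}
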