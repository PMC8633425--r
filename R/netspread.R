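#' Neighbourhood-atrophy estimators
#'
#' For each region, the collective atrophy of a neighbourhood:
#'
#' * `dSc` — unweighted mean over structurally connected neighbours;
#' * `dFcSc` — FC-weighted mean over structurally connected neighbours;
#' * `dFcNonSc` — FC-weighted mean over structurally *unconnected* regions;
#' * `dFcAll` — FC-weighted mean over all other regions.
#'
#' The region itself is always excluded. FC weights are used raw by
#' default; `weightMode = "clipped_fc"` clips negative weights to zero.
#' A region whose neighbourhood is empty, or whose weight sum has
#' magnitude below 1e-8, is flagged (NA estimate) rather than silently
#' zeroed; an error is raised only if every region is flagged.
#'
#' @param atrophy per-region atrophy/progression vector.
#' @param conn a [Connectome-class].
#' @param weightMode `"raw_fc"` or `"clipped_fc"`.
#' @return data.frame with the four estimates, neighbour counts `nSc`,
#'   and logical flag columns `flagSc`, `flagFcSc`, `flagFcNonSc`,
#'   `flagFcAll`.
#' @export
neighbourEstimates <- function(atrophy, conn,
                               weightMode = c("raw_fc", "clipped_fc")) {
  stopifnot(is(conn, "Connectome"))
  weightMode <- match.arg(weightMode)
  n <- nRegions(conn)
  if (length(atrophy) != n) stop("atrophy length must match connectome")
  ws <- .neighbourWeights(conn, weightMode)
  est <- lapply(ws, function(w) as.vector(w$mat %*% atrophy))
  for (k in names(est)) est[[k]][ws[[k]]$flag] <- NA_real_
  if (all(ws$dSc$flag & ws$dFcSc$flag & ws$dFcNonSc$flag & ws$dFcAll$flag))
    stop("all regions flagged: no usable neighbourhoods")
  data.frame(region = regionIds(conn),
             dSc = est$dSc, dFcSc = est$dFcSc,
             dFcNonSc = est$dFcNonSc, dFcAll = est$dFcAll,
             nSc = ws$dSc$count,
             flagSc = ws$dSc$flag, flagFcSc = ws$dFcSc$flag,
             flagFcNonSc = ws$dFcNonSc$flag, flagFcAll = ws$dFcAll$flag,
             row.names = NULL)
}

## Row-normalized weight matrices for the four estimators. The flags and
## normalizations depend only on the network, not on the atrophy map, so
## they can be reused across spins.
.neighbourWeights <- function(conn, weightMode) {
  sc <- structuralMatrix(conn)
  fc <- functionalMatrix(conn)
  if (weightMode == "clipped_fc") fc <- pmax(fc, 0)
  n <- nrow(sc)
  off <- matrix(TRUE, n, n); diag(off) <- FALSE
  masks <- list(dSc = sc > 0,
                dFcSc = sc > 0,
                dFcNonSc = (sc == 0) & off,
                dFcAll = off)
  weights <- list(dSc = (sc > 0) * 1,
                  dFcSc = fc * (sc > 0),
                  dFcNonSc = fc * ((sc == 0) & off),
                  dFcAll = fc * off)
  lapply(stats::setNames(names(masks), names(masks)), function(k) {
    w <- weights[[k]]
    count <- rowSums(masks[[k]])
    denom <- rowSums(w)
    flag <- count == 0L | abs(denom) < 1e-8
    safe <- ifelse(flag, 1, denom)
    list(mat = w / safe, count = count, flag = flag)
  })
}

#' Node-neighbourhood correlation with spin significance
#'
#' Pearson correlation, over unflagged regions, between each region's
#' atrophy and its collective neighbourhood atrophy — computed for each
#' requested estimator. The null distribution spins the atrophy *map*
#' (the network stays fixed) and recomputes both the node values and the
#' neighbourhood estimates from the spun map; p-values are two-tailed by
#' default.
#'
#' @param atrophy per-region atrophy/progression vector.
#' @param conn a [Connectome-class].
#' @param spins a [SpinNulls-class] on the same atlas.
#' @param weightMode see [neighbourEstimates()].
#' @param estimators subset of `c("dSc", "dFcSc", "dFcNonSc", "dFcAll")`.
#' @param tails,convention passed to [spinPValue()].
#' @return data.frame (one row per estimator) with `r`, `pSpin`,
#'   `nRegions`; the per-spin null correlations are attached as the
#'   `"nulls"` attribute (matrix nSpins x estimators).
#' @export
nodeNeighbourCorrelation <- function(atrophy, conn, spins,
                                     weightMode = c("raw_fc", "clipped_fc"),
                                     estimators = c("dSc", "dFcSc",
                                                    "dFcNonSc", "dFcAll"),
                                     tails = "two",
                                     convention = "add_one") {
  stopifnot(is(conn, "Connectome"), is(spins, "SpinNulls"))
  weightMode <- match.arg(weightMode)
  estimators <- match.arg(estimators, several.ok = TRUE)
  n <- nRegions(conn)
  if (length(atrophy) != n) stop("atrophy length must match connectome")
  ws <- .neighbourWeights(conn, weightMode)[estimators]

  a <- spinAssignments(spins)
  spun <- matrix(atrophy[t(a)], n, nrow(a))      # regions x spins
  out <- lapply(names(ws), function(k) {
    w <- ws[[k]]
    ok <- !w$flag
    if (sum(ok) < 10L) stop("fewer than 10 unflagged regions for ", k)
    nodes <- atrophy[ok]
    est <- as.vector(w$mat %*% atrophy)[ok]
    if (stats::sd(nodes) == 0 || stats::sd(est) == 0)
      stop("zero variance in ", k, " correlation inputs")
    r <- stats::cor(nodes, est)
    nullEst <- (w$mat %*% spun)[ok, , drop = FALSE]
    nullR <- .pairedColCors(spun[ok, , drop = FALSE], nullEst)
    p <- spinPValue(r, nullR, tails = tails, convention = convention)
    list(row = data.frame(estimator = k, r = r, pSpin = p,
                          nRegions = sum(ok)),
         nulls = nullR)
  })
  res <- do.call(rbind, lapply(out, `[[`, "row"))
  attr(res, "nulls") <- do.call(cbind, stats::setNames(
    lapply(out, `[[`, "nulls"), names(ws)))
  res
}

#' Zou confidence interval for the difference of two overlapping
#' dependent correlations
#'
#' Both correlations share the variable the maps are correlated with
#' (e.g. regional atrophy vs two different neighbourhood estimates);
#' `r12` is the correlation between the two predictor vectors. Fisher-z
#' confidence limits for each correlation are back-transformed and
#' combined with the estimated correlation between the two sample
#' correlations:
#' `c = ((r12 - r1 r2 / 2) (1 - r1^2 - r2^2 - r12^2) + r12^3) /
#' ((1 - r1^2)(1 - r2^2))`.
#'
#' @param r1,r2 the two dependent correlations (|r| < 1).
#' @param r12 correlation between the two predictor vectors (|r12| < 1).
#' @param n sample size (> 4).
#' @param level confidence level (default 0.95).
#' @return named numeric `c(lower, upper)` for `r1 - r2`.
#' @export
zouDifferenceCI <- function(r1, r2, r12, n, level = 0.95) {
  if (any(abs(c(r1, r2, r12)) >= 1)) stop("correlations must satisfy |r| < 1")
  if (n <= 4) stop("n must be > 4")
  zcrit <- stats::qnorm(1 - (1 - level) / 2)
  fisher <- function(r) atanh(r)
  if (!all(is.finite(fisher(c(r1, r2))))) stop("non-finite Fisher transform")
  se <- 1 / sqrt(n - 3)
  l1 <- tanh(fisher(r1) - zcrit * se); u1 <- tanh(fisher(r1) + zcrit * se)
  l2 <- tanh(fisher(r2) - zcrit * se); u2 <- tanh(fisher(r2) + zcrit * se)
  cnum <- (r12 - r1 * r2 / 2) * (1 - r1^2 - r2^2 - r12^2) + r12^3
  cc <- cnum / ((1 - r1^2) * (1 - r2^2))
  lower <- r1 - r2 -
    sqrt((r1 - l1)^2 + (u2 - r2)^2 - 2 * cc * (r1 - l1) * (u2 - r2))
  upper <- r1 - r2 +
    sqrt((u1 - r1)^2 + (r2 - l2)^2 - 2 * cc * (u1 - r1) * (r2 - l2))
  c(lower = lower, upper = upper)
}

#' Degree-preserving rewiring of a binary structural network
#'
#' Maslov-Sneppen double-edge swaps via [igraph::rewire()]
#' (`keeping_degseq`): the degree sequence is preserved exactly, with no
#' self-loops or multi-edges. Used as a negative-control network for the
#' spread-recovery analyses.
#'
#' @param sc binary symmetric adjacency matrix.
#' @param nSwapPerEdge swap attempts per edge (default 10).
#' @param seed integer seed.
#' @return rewired adjacency matrix with the same dimnames.
#' @export
rewireDegreePreserving <- function(sc, nSwapPerEdge = 10L, seed = 1L) {
  sc <- as.matrix(sc)
  if (!all(sc %in% c(0, 1))) stop("sc must be binary")
  if (max(abs(sc - t(sc))) > 0) stop("sc must be symmetric")
  g <- igraph::graph_from_adjacency_matrix(sc, mode = "undirected")
  m <- igraph::ecount(g)
  if (m < 2L) stop("too few edges to swap")
  old <- .Random.seed_save(); on.exit(.Random.seed_restore(old))
  set.seed(childSeed(seed, "rewire"))
  rg <- igraph::rewire(g, igraph::keeping_degseq(niter = nSwapPerEdge * m))
  out <- as.matrix(igraph::as_adjacency_matrix(rg, sparse = FALSE))
  dimnames(out) <- dimnames(sc)
  out
}
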