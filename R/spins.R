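#' Generate spatial spin-permutation nulls
#'
#' For each spin a uniform random 3D rotation `R` is drawn and applied to
#' the left-hemisphere centroids; the right hemisphere receives the
#' mirrored rotation `M R M` (sagittal mirror `M = diag(-1, 1, 1)`), so
#' both hemispheres rotate as mirror images — the rotation is sampled in
#' one hemisphere and mirrored to the other. Each region is then
#' reassigned the value of the nearest rotated same-hemisphere centroid
#' (`method = "nearest"`, duplicates allowed; distance ties break to the
#' lowest region index) or by greedy one-to-one matching in order of
#' increasing distance (`method = "bijective"`, every row a permutation).
#' Rotations are isometries, so the null preserves the spatial
#' autocorrelation structure of any map they are applied to.
#'
#' @param atlas a [ParcelAtlas-class]; each hemisphere needs >= 2 regions.
#' @param nSpins number of spins (>= 1).
#' @param method `"nearest"` (default) or `"bijective"`.
#' @param seed integer seed.
#' @param rotations optional list of 3x3 rotation matrices overriding the
#'   random draws (test hook; e.g. identity rotations).
#' @return a [SpinNulls-class].
#' @export
generateSpins <- function(atlas, nSpins, method = c("nearest", "bijective"),
                          seed = 1L, rotations = NULL) {
  stopifnot(is(atlas, "ParcelAtlas"))
  method <- match.arg(method)
  if (nSpins < 1L) stop("nSpins must be >= 1")
  hemi <- hemispheres(atlas)
  if (any(table(hemi) < 2L)) stop("need >= 2 regions per hemisphere")
  cen <- centroids(atlas)
  idxL <- which(hemi == "L"); idxR <- which(hemi == "R")
  mir <- diag(c(-1, 1, 1))

  old <- .Random.seed_save(); on.exit(.Random.seed_restore(old))
  set.seed(childSeed(seed, "spins"))
  n <- nRegions(atlas)
  assign <- matrix(NA_integer_, nSpins, n)
  for (s in seq_len(nSpins)) {
    rot <- if (is.null(rotations)) .randomRotation() else rotations[[s]]
    rotL <- cen[idxL, , drop = FALSE] %*% t(rot)
    rotR <- cen[idxR, , drop = FALSE] %*% t(mir %*% rot %*% mir)
    assign[s, idxL] <- idxL[.assignHemisphere(cen[idxL, , drop = FALSE],
                                              rotL, method)]
    assign[s, idxR] <- idxR[.assignHemisphere(cen[idxR, , drop = FALSE],
                                              rotR, method)]
  }
  new("SpinNulls", assignment = assign, method = method,
      seed = as.integer(seed), regionId = regionIds(atlas))
}

## original (rows) vs rotated (cols) within one hemisphere; returns for each
## original region the index of the source region whose rotated centroid it
## takes its value from.
.assignHemisphere <- function(orig, rotated, method) {
  d <- .greatCircle(orig, rotated)
  if (method == "nearest")
    return(max.col(-d, ties.method = "first"))
  # greedy one-to-one: process candidate pairs by increasing distance
  n <- nrow(d)
  ord <- order(d)
  res <- integer(n)
  usedOrig <- logical(n); usedRot <- logical(n)
  left <- n
  for (k in ord) {
    i <- (k - 1L) %% n + 1L
    j <- (k - 1L) %/% n + 1L
    if (!usedOrig[i] && !usedRot[j]) {
      res[i] <- j
      usedOrig[i] <- TRUE; usedRot[j] <- TRUE
      left <- left - 1L
      if (left == 0L) break
    }
  }
  res
}

#' Permutation p-value from a spin null distribution
#'
#' Default convention includes the observed statistic:
#' `p = (1 + k) / (1 + nSpins)` with `k` the number of null values at
#' least as extreme as the observed one, guaranteeing `p > 0`. Two-tailed
#' compares `|null| >= |observed|`; one-tailed compares `null >= observed`
#' (negate the statistic for the lower tail). `convention = "raw"` gives
#' the plain fraction `k / nSpins`.
#'
#' @param observed observed statistic (finite scalar).
#' @param nulls numeric vector of null statistics (all finite).
#' @param tails `"two"` or `"one"`.
#' @param convention `"add_one"` (default) or `"raw"`.
#' @return p-value in `[1 / (1 + nSpins), 1]` (add-one) or `[0, 1]` (raw).
#' @export
spinPValue <- function(observed, nulls, tails = c("two", "one"),
                       convention = c("add_one", "raw")) {
  tails <- match.arg(tails)
  convention <- match.arg(convention)
  if (length(nulls) < 1L) stop("need at least one null value")
  if (anyNA(nulls) || any(!is.finite(nulls))) stop("non-finite null values")
  if (!is.finite(observed)) stop("observed statistic must be finite")
  k <- if (tails == "two") sum(abs(nulls) >= abs(observed))
       else sum(nulls >= observed)
  if (convention == "add_one") (1 + k) / (1 + length(nulls))
  else k / length(nulls)
}

#' Label means against a spin null
#'
#' Observed mean of the map within each label class, tested against a null
#' distribution obtained by recomputing the class means after applying each
#' spin assignment to the *label* vector (the map stays fixed), two-tailed.
#' With `method = "nearest"` a label can vanish under some spins; those
#' spins are skipped for that label and the p-value denominator
#' renormalized (the number of contributing spins is reported).
#'
#' @param values numeric per-region map.
#' @param labels per-region labels (factor or character).
#' @param spins a [SpinNulls-class] over the same atlas.
#' @param convention p-value convention, see [spinPValue()].
#' @return data.frame with columns `label, mean, nRegions, nSpinsUsed,
#'   pSpin`.
#' @export
spinLabelMeans <- function(values, labels, spins,
                           convention = c("add_one", "raw")) {
  stopifnot(is(spins, "SpinNulls"))
  convention <- match.arg(convention)
  labels <- as.factor(labels)
  n <- length(values)
  if (length(labels) != n || ncol(spinAssignments(spins)) != n)
    stop("values, labels and spins must cover the same regions")
  if (any(table(labels) == 0L)) stop("every label needs >= 1 region")
  levs <- levels(labels)
  obs <- vapply(levs, function(l) mean(values[labels == l]), numeric(1L))

  a <- spinAssignments(spins)
  nulls <- matrix(NA_real_, nrow(a), length(levs),
                  dimnames = list(NULL, levs))
  for (s in seq_len(nrow(a))) {
    spunLab <- labels[a[s, ]]
    m <- tapply(values, spunLab, mean)
    nulls[s, names(m)] <- m
  }
  skipped <- colSums(is.na(nulls))
  if (any(skipped > 0))
    message("label absent in ", sum(skipped),
            " spin(s); denominators renormalized")
  p <- vapply(seq_along(levs), function(i) {
    nv <- nulls[!is.na(nulls[, i]), i]
    spinPValue(obs[i], nv, tails = "two", convention = convention)
  }, numeric(1L))
  data.frame(label = levs, mean = unname(obs),
             nRegions = as.vector(table(labels)[levs]),
             nSpinsUsed = nrow(a) - skipped[levs],
             pSpin = p, row.names = NULL)
}

#' Spin test of the correlation between two regional maps
#'
#' Observed Pearson (or Spearman) correlation between `x` and `y`,
#' tested against the null distribution obtained by applying each spin
#' assignment to `x` and re-correlating with the fixed `y`.
#'
#' @param x,y per-region numeric maps.
#' @param spins a [SpinNulls-class] on the same atlas.
#' @param method `"pearson"` or `"spearman"`.
#' @param tails,convention passed to [spinPValue()].
#' @return list with `r`, `pSpin`, and the null vector `nulls`.
#' @export
spinCorrelation <- function(x, y, spins, method = c("pearson", "spearman"),
                            tails = "two", convention = "add_one") {
  stopifnot(is(spins, "SpinNulls"))
  method <- match.arg(method)
  if (length(x) != length(y)) stop("maps must have equal length")
  if (stats::sd(x) == 0 || stats::sd(y) == 0) stop("zero variance map")
  if (method == "spearman") { x <- rank(x); y <- rank(y) }
  r <- stats::cor(x, y)
  a <- spinAssignments(spins)
  spun <- matrix(x[t(a)], length(x), nrow(a))
  if (method == "spearman") spun <- apply(spun, 2L, rank)
  nulls <- as.vector(stats::cor(spun, y))
  list(r = r, pSpin = spinPValue(r, nulls, tails = tails,
                                 convention = convention),
       nulls = nulls)
}
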