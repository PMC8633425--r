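#' Spread-process parameters
#'
#' @param seedRegions character ids or integer indices where load starts.
#' @param eta per-step transfer rate (>= 0).
#' @param nStepsPerYear propagation steps per follow-up year (>= 0);
#'   a session at year `y` uses `y * nStepsPerYear` steps.
#' @param vulnerability positive per-region multipliers (recycled).
#' @return list of class `SpreadParams`.
#' @export
spreadParams <- function(seedRegions, eta = 0.3, nStepsPerYear = 2L,
                         vulnerability = 1) {
  if (length(seedRegions) == 0L) stop("seedRegions must be nonempty")
  if (eta < 0) stop("eta must be >= 0")
  if (nStepsPerYear < 0) stop("nStepsPerYear must be >= 0")
  structure(list(seedRegions = seedRegions, eta = eta,
                 nStepsPerYear = as.integer(nStepsPerYear),
                 vulnerability = vulnerability),
            class = "SpreadParams")
}

#' Cohort-generator parameters
#'
#' Defaults reproduce the study conditions of the cohort being emulated:
#' 74 patients with imaging at all four sessions and 157 baseline-only
#' controls, ages centred on 60 years (SD 9.4, truncated to 30-85),
#' roughly 70% male, four acquisition sites. Deformation values sit near 1
#' (template-relative volume ratio) and shrink slowly with age.
#'
#' @param nHC healthy controls (baseline only; >= 4).
#' @param nPD patients (all four sessions).
#' @param ageMean,ageSd,ageRange age distribution (years).
#' @param sexRatio fraction male (sex coded 1 = male, 0 = female).
#' @param nSites number of acquisition sites.
#' @param betaAge,betaSex,betaIntercept deformation-model coefficients.
#' @param noiseSd residual SD of the deformation noise (> 0).
#' @param diseaseEffectScale multiplier mapping the (max-normalized) spread
#'   pattern to deformation loss, in units of `noiseSd`; 0 plants no effect.
#' @return list of class `CohortParams`.
#' @export
cohortParams <- function(nHC = 157L, nPD = 74L, ageMean = 60, ageSd = 9.4,
                         ageRange = c(30, 85), sexRatio = 0.7, nSites = 4L,
                         betaAge = -0.003, betaSex = 0.02,
                         betaIntercept = 1.0, noiseSd = 0.05,
                         diseaseEffectScale = 1.5) {
  if (nHC < 4L) stop("nHC must be >= 4 (model unidentifiable)")
  if (noiseSd <= 0) stop("noiseSd must be positive")
  structure(list(nHC = as.integer(nHC), nPD = as.integer(nPD),
                 ageMean = ageMean, ageSd = ageSd, ageRange = ageRange,
                 sexRatio = sexRatio, nSites = as.integer(nSites),
                 betaAge = betaAge, betaSex = betaSex,
                 betaIntercept = betaIntercept, noiseSd = noiseSd,
                 diseaseEffectScale = diseaseEffectScale),
            class = "CohortParams")
}

.truncNorm <- function(n, mean, sd, lo, hi) {
  x <- stats::rnorm(n, mean, sd)
  while (any(bad <- x < lo | x > hi))
    x[bad] <- stats::rnorm(sum(bad), mean, sd)
  x
}

#' Generate a synthetic longitudinal deformation cohort
#'
#' Baseline deformation for every subject and region is
#' `betaIntercept + betaAge * age + betaSex * sex + N(0, noiseSd)`.
#' Controls are simulated at baseline only (the normative reference design);
#' patients get four sessions (baseline, 1, 2 and 4 years) with age
#' advancing accordingly and, at follow-ups, a subtracted disease effect
#' `diseaseEffectScale * noiseSd * spread_y`, where `spread_y` is the
#' network-spread pattern after `y * nStepsPerYear` steps, normalized by
#' the maximum of the year-4 pattern so `diseaseEffectScale` is the peak
#' planted effect in residual-SD units. `diseaseEffectScale = 0` yields a
#' null cohort whose follow-ups are identical in law to baseline.
#'
#' @param atlas a [ParcelAtlas-class].
#' @param sc structural adjacency used by the spread process.
#' @param params a [cohortParams()] list.
#' @param spread a [spreadParams()] list.
#' @param seed integer seed.
#' @return a [CohortTable-class].
#' @export
makeCohort <- function(atlas, sc, params = cohortParams(),
                       spread, seed = 1L) {
  stopifnot(is(atlas, "ParcelAtlas"), inherits(params, "CohortParams"),
            inherits(spread, "SpreadParams"))
  n <- nRegions(atlas)
  ids <- regionIds(atlas)
  years <- c(bl = 0, y1 = 1, y2 = 2, y4 = 4)

  # deterministic disease-effect patterns per follow-up year
  spreadBy <- lapply(years[-1L], function(y)
    simulateSpread(sc, spread$seedRegions, spread$eta,
                   y * spread$nStepsPerYear, spread$vulnerability))
  peak <- max(spreadBy[[length(spreadBy)]])
  if (peak > 0) spreadBy <- lapply(spreadBy, function(v) v / peak)

  old <- .Random.seed_save(); on.exit(.Random.seed_restore(old))
  set.seed(childSeed(seed, "cohort"))
  simGroup <- function(nSub, group, prefix) {
    age0 <- .truncNorm(nSub, params$ageMean, params$ageSd,
                       params$ageRange[1L], params$ageRange[2L])
    sex <- stats::rbinom(nSub, 1L, params$sexRatio)
    site <- sample(sprintf("site%d", seq_len(params$nSites)), nSub,
                   replace = TRUE)
    sess <- if (group == "HC") "bl" else names(years)
    rows <- expand.grid(subject = seq_len(nSub), session = sess,
                        stringsAsFactors = FALSE)
    dem <- data.frame(
      subjectId = sprintf("%s%04d", prefix, rows$subject),
      group = group, session = rows$session,
      age = age0[rows$subject] + years[rows$session],
      sex = sex[rows$subject], site = site[rows$subject],
      stringsAsFactors = FALSE)
    pred <- params$betaIntercept + params$betaAge * dem$age +
      params$betaSex * dem$sex
    vals <- matrix(pred, nrow(dem), n) +
      matrix(stats::rnorm(nrow(dem) * n, sd = params$noiseSd), nrow(dem), n)
    if (group == "PD" && params$diseaseEffectScale != 0) {
      for (s in names(spreadBy)) {
        r <- which(dem$session == s)
        vals[r, ] <- vals[r, ] - rep(params$diseaseEffectScale *
          params$noiseSd * spreadBy[[s]], each = length(r))
      }
    }
    colnames(vals) <- ids
    list(dem = dem, vals = vals)
  }
  hc <- simGroup(params$nHC, "HC", "HC")
  pd <- simGroup(params$nPD, "PD", "PD")
  CohortTable(rbind(hc$dem, pd$dem), rbind(hc$vals, pd$vals))
}
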