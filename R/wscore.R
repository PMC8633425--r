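#' Fit the control normative W-score model
#'
#' Per-region ordinary least squares of deformation on age, sex and an
#' intercept, using healthy-control baseline rows only. The residual SD is
#' computed with denominator `n - 3` (unbiased under the three-parameter
#' model). Training residuals sum to zero per region by the OLS normal
#' equations, so training-control W-scores have mean exactly 0.
#'
#' @param cohort a [CohortTable-class]; only HC baseline rows are used.
#' @return a [WScoreModel-class].
#' @export
fitWScoreModel <- function(cohort) {
  stopifnot(is(cohort, "CohortTable"))
  hc <- subsetCohort(cohort, group = "HC", session = "bl")
  d <- demographics(hc)
  y <- deformationValues(hc)
  nSub <- nrow(d)
  if (nSub < 4L) stop("need >= 4 healthy-control baseline subjects")
  if (length(unique(d$sex)) < 2L)
    stop("single-sex control cohort: sex coefficient inestimable")
  x <- cbind(age = d$age, sex = d$sex, intercept = 1)
  qx <- qr(x)
  beta <- qr.coef(qx, y)                       # 3 x regions
  resid <- qr.resid(qx, y)
  rsd <- sqrt(colSums(resid^2) / (nSub - 3L))
  if (any(rsd < 1e-12))
    stop("degenerate control data: zero residual SD in region ",
         colnames(y)[which(rsd < 1e-12)[1L]])
  coef <- t(beta)
  colnames(coef) <- c("beta_age", "beta_sex", "beta_intercept")
  new("WScoreModel", coefficients = coef, residSd = unname(rsd),
      nControls = nSub, regionId = colnames(y))
}

#' Convert deformation values to W-scores
#'
#' `W_i = (DBM_i - (beta_age * age + beta_sex * sex + beta_intercept)) /
#' residSd_i` per region. Negative W means atrophy (less volume than the
#' age/sex-expected control value); positive means expansion. W-scores are
#' invariant to a common affine rescaling of the deformation unit applied
#' to both controls and subjects.
#'
#' @param model a fitted [WScoreModel-class].
#' @param cohort a [CohortTable-class] (any rows); ages outside \[0, 120\]
#'   trigger an extrapolation warning, not an error.
#' @return numeric matrix (subject-sessions x regions) of W-scores, with
#'   the cohort's `subjectId:session` row names.
#' @export
computeWScores <- function(model, cohort) {
  stopifnot(is(model, "WScoreModel"), is(cohort, "CohortTable"))
  d <- demographics(cohort)
  vals <- deformationValues(cohort)
  if (!identical(colnames(vals), regionIds(model)))
    stop("cohort regions do not match model regions")
  if (any(d$age < 0 | d$age > 120))
    warning("age outside [0, 120]: extrapolating the normative model")
  cf <- modelCoefficients(model)
  pred <- outer(d$age, cf[, "beta_age"]) + outer(d$sex, cf[, "beta_sex"]) +
    matrix(cf[, "beta_intercept"], nrow(d), nrow(cf), byrow = TRUE)
  w <- sweep(vals - pred, 2L, residualSd(model), "/")
  rownames(w) <- paste(d$subjectId, d$session, sep = ":")
  w
}
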