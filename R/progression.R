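#' Atrophy-progression map between two sessions
#'
#' `score_i = -(W_followup_i - W_baseline_i)`: since negative W means
#' atrophy, a positive progression score means atrophy accrued between the
#' sessions. Swapping the sessions negates the map.
#'
#' @param wBaseline,wFollowup W-score matrices (subjects x regions) with
#'   matching subject row order (row names are checked when present).
#' @param aggregate `"subject"` for per-subject maps, `"group-mean"` for
#'   the subject-mean map.
#' @return matrix (subjects x regions) or named vector (group mean).
#' @export
progressionMap <- function(wBaseline, wFollowup,
                           aggregate = c("subject", "group-mean")) {
  aggregate <- match.arg(aggregate)
  if (!all(dim(wBaseline) == dim(wFollowup)))
    stop("session matrices have mismatched dimensions")
  bsub <- sub(":.*$", "", rownames(wBaseline))
  fsub <- sub(":.*$", "", rownames(wFollowup))
  if (!is.null(rownames(wBaseline)) && !identical(bsub, fsub))
    stop("mismatched subject sets between sessions")
  score <- -(wFollowup - wBaseline)
  rownames(score) <- bsub
  if (aggregate == "group-mean") colMeans(score) else score
}

## Repeated-measures one-way F per region from a subjects x sessions x
## regions array, via the within-subject decomposition:
## SS_within = SS_time + SS_error, F = (SS_time/df_t) / (SS_error/df_e).
.rmF <- function(y) {
  ns <- dim(y)[1L]; nt <- dim(y)[2L]; nr <- dim(y)[3L]
  subjMean <- apply(y, c(1L, 3L), mean)            # ns x nr
  sessMean <- apply(y, c(2L, 3L), mean)            # nt x nr
  grand <- colMeans(subjMean)                      # nr
  ssWithin <- apply(sweep(y, c(1L, 3L), subjMean)^2, 3L, sum)
  ssTime <- ns * colSums(sweep(sessMean, 2L, grand)^2)
  ssErr <- pmax(ssWithin - ssTime, 0)
  dfT <- nt - 1L; dfE <- (ns - 1L) * (nt - 1L)
  f <- (ssTime / dfT) / (ssErr / dfE)
  f[ssTime <= .Machine$double.eps * pmax(ssWithin, 1)] <- 0
  list(F = f, dfT = dfT, dfE = dfE, ssWithin = ssWithin)
}

#' Regional atrophy-progression test with permutation FWE control
#'
#' Per region: W-scores are residualized on between-subject covariates
#' (sex and acquisition site), then a one-way repeated-measures ANOVA
#' across sessions (subjects as blocks) yields an F statistic.
#' Familywise-error control uses max-statistic permutation over
#' within-subject session relabelings; Benjamini-Hochberg FDR on the
#' parametric p-values is reported alongside. Post-hoc one-tailed paired
#' t contrasts (baseline vs each follow-up, alternative: atrophy
#' worsening, i.e. W decreasing) are returned per region.
#'
#' @param w 3-d array `subjects x sessions x regions` of W-scores
#'   (dimnames on sessions used for post-hoc labels; first session is the
#'   baseline).
#' @param sex per-subject 0/1 vector.
#' @param site per-subject site factor; sites with a single subject are
#'   dropped from the residualization with a warning.
#' @param nPerm number of session permutations (default 1000).
#' @param alpha significance level for the flags.
#' @param seed integer seed for the permutations.
#' @param trend if `TRUE` use the linear-in-time trend contrast F (1 df)
#'   instead of the omnibus session-factor F.
#' @param years numeric session times used by the trend contrast.
#' @return list with `table` (data.frame: region, F, pParametric, pFWE,
#'   pFDR, sigFWE, sigFDR), `posthoc` (list per follow-up of data.frames
#'   with t and one-tailed p), `nPerm`, `dfT`, `dfE`.
#' @export
regionalProgressionTest <- function(w, sex, site, nPerm = 1000L,
                                    alpha = 0.05, seed = 1L,
                                    trend = FALSE,
                                    years = c(0, 1, 2, 4)) {
  stopifnot(length(dim(w)) == 3L)
  ns <- dim(w)[1L]; nt <- dim(w)[2L]; nr <- dim(w)[3L]
  if (nt < 2L) stop("need >= 2 sessions")
  if (ns < 6L) stop("need >= 6 subjects")
  sessions <- dimnames(w)[[2L]]
  if (is.null(sessions)) sessions <- paste0("s", seq_len(nt))
  regions <- dimnames(w)[[3L]]
  if (is.null(regions)) regions <- paste0("r", seq_len(nr))

  site <- as.factor(site)
  singleton <- names(which(table(site) < 2L))
  if (length(singleton)) {
    warning("site(s) with a single subject dropped from residualization: ",
            paste(singleton, collapse = ", "))
    site <- factor(ifelse(as.character(site) %in% singleton, NA,
                          as.character(site)))
  }
  x <- cbind(1, sex)
  if (nlevels(site) > 1L) {
    sm <- stats::model.matrix(~site)[, -1L, drop = FALSE]
    full <- matrix(0, ns, ncol(sm))
    full[!is.na(site), ] <- sm
    x <- cbind(x, full)
  }
  qx <- qr(x)
  # residualize on the subject-level covariates: the coefficients are fit
  # once per region on the stacked data (covariates are constant within
  # subject, so this equals fitting on the subject means) and the same
  # fitted value is removed from every session, preserving within-subject
  # session differences
  fit <- qr.fitted(qx, apply(w, c(1L, 3L), mean))   # ns x nr
  yr <- w
  for (t in seq_len(nt)) yr[, t, ] <- w[, t, ] - fit

  ct <- years[seq_len(nt)] - mean(years[seq_len(nt)])
  trendF <- function(est) {
    # est: ns x nr matrix of per-subject slope estimates
    tt <- colMeans(est) / (apply(est, 2L, stats::sd) / sqrt(ns))
    tt[!is.finite(tt)] <- 0
    tt^2
  }
  if (trend) {
    est <- apply(yr, 3L, function(m) m %*% ct) / sum(ct^2)
    fObs <- trendF(matrix(est, ns, nr)); dfT <- 1L; dfE <- ns - 1L
  } else {
    dec <- .rmF(yr)
    fObs <- dec$F; dfT <- dec$dfT; dfE <- dec$dfE
  }
  pPar <- stats::pf(fObs, dfT, dfE, lower.tail = FALSE)

  old <- .Random.seed_save(); on.exit(.Random.seed_restore(old))
  set.seed(childSeed(seed, "progression-fwe"))
  # per-session slices for fast permuted session statistics
  slices <- lapply(seq_len(nt), function(t) yr[, t, ])
  subjMean <- apply(yr, c(1L, 3L), mean)
  ssWithin <- apply(sweep(yr, c(1L, 3L), subjMean)^2, 3L, sum)
  grand <- colMeans(subjMean)
  maxF <- numeric(nPerm)
  for (pp in seq_len(nPerm)) {
    perm <- t(vapply(seq_len(ns), function(s) sample.int(nt), integer(nt)))
    if (trend) {
      est <- matrix(0, ns, nr)
      for (t in seq_len(nt)) for (u in seq_len(nt)) {
        rows <- which(perm[, t] == u)
        if (length(rows))
          est[rows, ] <- est[rows, ] + ct[t] * slices[[u]][rows, , drop = FALSE]
      }
      maxF[pp] <- max(trendF(est / sum(ct^2)))
    } else {
      sess <- matrix(0, nt, nr)
      for (t in seq_len(nt)) {
        acc <- numeric(nr)
        for (u in seq_len(nt)) {
          rows <- which(perm[, t] == u)
          if (length(rows) == 1L) acc <- acc + slices[[u]][rows, ]
          else if (length(rows) > 1L)
            acc <- acc + colSums(slices[[u]][rows, , drop = FALSE])
        }
        sess[t, ] <- acc / ns
      }
      ssTime <- ns * colSums(sweep(sess, 2L, grand)^2)
      ssErr <- pmax(ssWithin - ssTime, 0)
      fp <- (ssTime / (nt - 1L)) / (ssErr / ((ns - 1L) * (nt - 1L)))
      fp[!is.finite(fp)] <- 0
      maxF[pp] <- max(fp)
    }
  }
  pFWE <- (1 + vapply(fObs, function(f) sum(maxF >= f), numeric(1L))) /
    (1 + nPerm)
  pFDR <- stats::p.adjust(pPar, "BH")

  posthoc <- lapply(seq_len(nt)[-1L], function(t) {
    dif <- w[, t, ] - w[, 1L, ]            # W change; negative = worsening
    m <- colMeans(dif)
    se <- apply(dif, 2L, stats::sd) / sqrt(ns)
    tt <- m / se
    data.frame(region = regions, t = tt,
               p = stats::pt(tt, ns - 1L),  # lower tail: W decreasing
               row.names = NULL)
  })
  names(posthoc) <- sessions[-1L]

  list(table = data.frame(region = regions, F = fObs, pParametric = pPar,
                          pFWE = pFWE, pFDR = pFDR,
                          sigFWE = pFWE < alpha, sigFDR = pFDR < alpha,
                          row.names = NULL),
       posthoc = posthoc, nPerm = nPerm, dfT = dfT, dfE = dfE)
}

#' One-way ANOVA of a progression map across cortical types
#'
#' Regions are the observations; the four cortical classes the groups.
#' Pairwise Welch two-sample t-tests are Bonferroni-adjusted over the
#' number of pairs.
#'
#' @param progression per-region progression map.
#' @param types per-region cortical-type labels.
#' @return list with `F`, `p`, `df`, `classMeans`, and `pairwise`
#'   data.frame (pair, t, pRaw, pBonferroni).
#' @export
corticalTypeAnova <- function(progression, types) {
  types <- droplevels(as.factor(types))
  if (nlevels(types) < 2L) stop("need >= 2 cortical classes")
  if (any(table(types) < 2L)) stop("every class needs >= 2 regions")
  withinVar <- tapply(progression, types, stats::var)
  if (all(withinVar == 0)) stop("zero within-class variance in all classes")
  fit <- stats::aov(progression ~ types)
  an <- summary(fit)[[1L]]
  levs <- levels(types)
  pairs <- utils::combn(levs, 2L)
  pw <- apply(pairs, 2L, function(pr) {
    tt <- stats::t.test(progression[types == pr[1L]],
                        progression[types == pr[2L]])
    c(t = unname(tt$statistic), p = tt$p.value)
  })
  pairwise <- data.frame(pair = paste(pairs[1L, ], pairs[2L, ], sep = " vs "),
                         t = pw["t", ], pRaw = pw["p", ],
                         pBonferroni = pmin(pw["p", ] * ncol(pairs), 1),
                         row.names = NULL)
  list(F = an[["F value"]][1L], p = an[["Pr(>F)"]][1L],
       df = an[["Df"]],
       classMeans = tapply(progression, types, mean),
       pairwise = pairwise)
}

#' Partial Spearman correlation
#'
#' All variables are rank-transformed (average ranks for ties); x and y
#' ranks are residualized on the covariate ranks (with intercept) and the
#' Pearson correlation of the residuals is returned, with a two-tailed
#' t-approximation p-value on `n - 2 - k` degrees of freedom. With no
#' covariates this is exactly the Spearman rank correlation.
#'
#' @param x,y numeric vectors.
#' @param covariates optional numeric matrix/data.frame of covariates.
#' @return list with `rho`, `p`, `n`, `df`.
#' @export
partialSpearman <- function(x, y, covariates = NULL) {
  ok <- stats::complete.cases(x, y,
                              if (is.null(covariates)) rep(TRUE, length(x))
                              else covariates)
  x <- x[ok]; y <- y[ok]
  n <- length(x)
  if (n < 10L) stop("need >= 10 complete cases")
  if (stats::sd(x) == 0 || stats::sd(y) == 0) stop("zero rank variance")
  rx <- rank(x); ry <- rank(y)
  k <- 0L
  if (!is.null(covariates)) {
    cv <- as.matrix(as.data.frame(covariates)[ok, , drop = FALSE])
    k <- ncol(cv)
    rc <- apply(cv, 2L, rank)
    qz <- qr(cbind(1, rc))
    rx <- qr.resid(qz, rx)
    ry <- qr.resid(qz, ry)
    if (stats::sd(rx) == 0 || stats::sd(ry) == 0) stop("zero rank variance")
  }
  rho <- stats::cor(rx, ry)
  df <- n - 2L - k
  tt <- rho * sqrt(df / (1 - rho^2))
  list(rho = rho, p = 2 * stats::pt(-abs(tt), df), n = n, df = df)
}

#' Battery of partial Spearman correlations with FDR adjustment
#'
#' Every column of `imaging` is correlated with every column of
#' `clinical`, given the covariates, and Benjamini-Hochberg adjustment is
#' applied across the whole battery.
#'
#' @param imaging data.frame/matrix of imaging summaries (columns = maps).
#' @param clinical data.frame/matrix of clinical change scores.
#' @param covariates optional covariate data.frame (e.g. age, sex,
#'   education).
#' @param alpha significance level for the flag column.
#' @return data.frame with imaging, clinical, rho, n, pRaw, pFDR, sigFDR.
#' @export
partialSpearmanBattery <- function(imaging, clinical, covariates = NULL,
                                   alpha = 0.05) {
  imaging <- as.data.frame(imaging)
  clinical <- as.data.frame(clinical)
  grid <- expand.grid(imaging = names(imaging), clinical = names(clinical),
                      stringsAsFactors = FALSE)
  res <- lapply(seq_len(nrow(grid)), function(i) {
    r <- partialSpearman(imaging[[grid$imaging[i]]],
                         clinical[[grid$clinical[i]]], covariates)
    data.frame(imaging = grid$imaging[i], clinical = grid$clinical[i],
               rho = r$rho, n = r$n, pRaw = r$p)
  })
  out <- do.call(rbind, res)
  out$pFDR <- stats::p.adjust(out$pRaw, "BH")
  out$sigFDR <- out$pFDR < alpha
  out
}

#' Multiple-testing adjustment
#'
#' Thin wrapper over [stats::p.adjust()] exposing the three procedures
#' used across the pipeline under their conventional names.
#'
#' @param p numeric p-values in \[0, 1\].
#' @param method `"bonferroni"`, `"holm"` or `"bh_fdr"`.
#' @return adjusted p-values, clipped at 1.
#' @export
adjustPValues <- function(p, method = c("bonferroni", "holm", "bh_fdr")) {
  method <- match.arg(method)
  if (any(p < 0 | p > 1, na.rm = TRUE)) stop("p-values must lie in [0, 1]")
  stats::p.adjust(p, switch(method, bonferroni = "bonferroni",
                            holm = "holm", bh_fdr = "BH"))
}

#' Repeated-measures ANOVA for a clinical measure over sessions
#'
#' One-way repeated-measures ANOVA with subjects as blocks over complete
#' cases, followed by paired two-tailed t-tests of baseline vs each
#' follow-up with Holm adjustment. With exactly two sessions the F
#' statistic equals the squared paired-t statistic.
#'
#' @param values matrix subjects x sessions (first column = baseline);
#'   rows with missing values are dropped.
#' @return list with `F`, `p`, `dfT`, `dfE`, `n`, and `posthoc`
#'   data.frame (session, t, pRaw, pHolm).
#' @export
rmAnovaClinical <- function(values) {
  values <- as.matrix(values)
  values <- values[stats::complete.cases(values), , drop = FALSE]
  ns <- nrow(values); nt <- ncol(values)
  if (ns < 3L) stop("need >= 3 complete subjects")
  y <- array(values, dim = c(ns, nt, 1L))
  dec <- .rmF(y)
  p <- stats::pf(dec$F, dec$dfT, dec$dfE, lower.tail = FALSE)
  sess <- colnames(values)
  if (is.null(sess)) sess <- paste0("s", seq_len(nt))
  ph <- lapply(seq_len(nt)[-1L], function(t) {
    tt <- stats::t.test(values[, t], values[, 1L], paired = TRUE)
    data.frame(session = sess[t], t = unname(tt$statistic), pRaw = tt$p.value)
  })
  ph <- do.call(rbind, ph)
  ph$pHolm <- stats::p.adjust(ph$pRaw, "holm")
  list(F = dec$F, p = p, dfT = dec$dfT, dfE = dec$dfE, n = ns, posthoc = ph)
}
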