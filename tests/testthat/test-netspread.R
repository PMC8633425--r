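test_that("neighbourhood estimators reproduce hand-computed path-graph values", {
  cn <- pathConnectome(fc12 = 0.5, fc23 = 0.25)
  a <- c(0.1, 0.2, 0.3)
  est <- neighbourEstimates(a, cn)
  expect_equal(est$dSc, c(0.2, 0.2, 0.2))
  # FC-weighted at node 2: (0.1*0.5 + 0.3*0.25) / 0.75 = 1/6
  expect_equal(est$dFcSc[2], 1 / 6)
  expect_equal(est$nSc, c(1, 2, 1))
  # non-SC neighbourhood of node 1 is {3} but fc(1,3) = 0 -> flagged
  expect_true(est$flagFcNonSc[1])
})

test_that("estimators match a per-node brute-force loop on random graphs", {
  set.seed(1)
  for (draw in 1:20) {
    n <- 50
    sc <- matrix(rbinom(n * n, 1, 0.2), n, n)
    sc[lower.tri(sc)] <- t(sc)[lower.tri(sc)]
    diag(sc) <- 0
    fc <- matrix(runif(n * n, -1, 1), n, n)
    fc[lower.tri(fc)] <- t(fc)[lower.tri(fc)]
    diag(fc) <- 0
    cn <- Connectome(sc, fc, sprintf("r%02d", 1:n))
    a <- rnorm(n)
    est <- neighbourEstimates(a, cn)
    for (i in sample(n, 8)) {
      nb <- which(sc[i, ] > 0)
      if (length(nb) > 0)
        expect_equal(est$dSc[i], mean(a[nb]), tolerance = 1e-12)
      w <- fc[i, nb]
      if (length(nb) > 0 && abs(sum(w)) >= 1e-8)
        expect_equal(est$dFcSc[i], sum(a[nb] * w) / sum(w),
                     tolerance = 1e-12)
      non <- setdiff(which(sc[i, ] == 0), i)
      wn <- fc[i, non]
      if (length(non) > 0 && abs(sum(wn)) >= 1e-8)
        expect_equal(est$dFcNonSc[i], sum(a[non] * wn) / sum(wn),
                     tolerance = 1e-12)
      all_ <- setdiff(1:n, i)
      wa <- fc[i, all_]
      if (abs(sum(wa)) >= 1e-8)
        expect_equal(est$dFcAll[i], sum(a[all_] * wa) / sum(wa),
                     tolerance = 1e-12)
    }
  }
})

test_that("estimators are linear in the atrophy vector", {
  at <- makeAtlas(25, 4, seed = 2)
  cn <- makeConnectome(at, 0.25, seed = 2)
  set.seed(2)
  a <- rnorm(50); b <- rnorm(50)
  ea <- neighbourEstimates(a, cn); eb <- neighbourEstimates(b, cn)
  ec <- neighbourEstimates(2 * a - 3 * b, cn)
  for (col in c("dSc", "dFcSc", "dFcNonSc", "dFcAll")) {
    ok <- !is.na(ea[[col]]) & !is.na(eb[[col]]) & !is.na(ec[[col]])
    expect_equal(ec[[col]][ok], (2 * ea[[col]] - 3 * eb[[col]])[ok],
                 tolerance = 1e-10)
  }
})

test_that("node-neighbour correlation is exact on a constructed fixture", {
  at <- makeAtlas(25, 4, seed = 3)
  cn <- makeConnectome(at, 0.25, seed = 3)
  sp <- generateSpins(at, 50, seed = 3)
  set.seed(3)
  base <- rnorm(50)
  # atrophy equal to its own structural neighbourhood mean -> r = 1
  est <- neighbourEstimates(base, cn)
  res <- nodeNeighbourCorrelation(est$dSc, cn, sp, estimators = "dSc")
  fix <- neighbourEstimates(est$dSc, cn)
  expect_equal(res$r, cor(est$dSc, fix$dSc))

  expect_error(nodeNeighbourCorrelation(rep(1, 50), cn, sp,
                                        estimators = "dSc"),
               "zero variance")
})

test_that("spread-generated atrophy correlates with its neighbourhood beyond rewired nulls", {
  at <- makeAtlas(55, 7, seed = 4)
  cn <- makeConnectome(at, seed = 4)
  sc <- structuralMatrix(cn)
  sp <- generateSpins(at, 200, seed = 4)
  atr <- simulateSpread(sc, regionIds(at)[c(3, 40)], eta = 0.3, nSteps = 6)
  res <- nodeNeighbourCorrelation(atr, cn, sp, estimators = "dSc")
  expect_gt(res$r, 0.4)
  expect_lt(res$pSpin, 0.05)

  rw <- rewireDegreePreserving(sc, 10, seed = 4)
  cnr <- Connectome(rw, functionalMatrix(cn), regionIds(at))
  resR <- nodeNeighbourCorrelation(atr, cnr, sp, estimators = "dSc")
  expect_gt(res$r, resR$r)
})

test_that("degree-preserving rewiring keeps degrees and edge count exactly", {
  at <- makeAtlas(30, 4, seed = 5)
  sc <- structuralMatrix(makeConnectome(at, 0.2, seed = 5))
  rw <- rewireDegreePreserving(sc, 10, seed = 5)
  expect_equal(rowSums(rw), rowSums(sc))
  expect_equal(sum(rw), sum(sc))
  expect_true(all(diag(rw) == 0))
  expect_false(identical(rw, sc))
  expect_error(rewireDegreePreserving(matrix(0, 3, 3)), "too few edges")
})

test_that("Zou interval is symmetric for equal correlations and matches the formula", {
  ci <- zouDifferenceCI(0.5, 0.5, 0.3, n = 100)
  expect_lt(ci["lower"], 0); expect_gt(ci["upper"], 0)
  expect_equal(unname(ci["upper"] + ci["lower"]), 0, tolerance = 1e-12)

  # independent step-by-step recomputation of the published formula
  r1 <- 0.62; r2 <- 0.33; r12 <- 0.41; n <- 448
  z <- qnorm(0.975)
  l1 <- tanh(atanh(r1) - z / sqrt(n - 3)); u1 <- tanh(atanh(r1) + z / sqrt(n - 3))
  l2 <- tanh(atanh(r2) - z / sqrt(n - 3)); u2 <- tanh(atanh(r2) + z / sqrt(n - 3))
  cc <- ((r12 - r1 * r2 / 2) * (1 - r1^2 - r2^2 - r12^2) + r12^3) /
    ((1 - r1^2) * (1 - r2^2))
  lo <- r1 - r2 - sqrt((r1 - l1)^2 + (u2 - r2)^2 -
                         2 * cc * (r1 - l1) * (u2 - r2))
  hi <- r1 - r2 + sqrt((u1 - r1)^2 + (r2 - l2)^2 -
                         2 * cc * (u1 - r1) * (r2 - l2))
  expect_equal(unname(zouDifferenceCI(r1, r2, r12, n)),
               c(lo, hi), tolerance = 1e-12)

  # r12 = 0 reduces c to the no-overlap-dependence form
  cc0 <- (-0.5 * r1 * r2 * (1 - r1^2 - r2^2)) / ((1 - r1^2) * (1 - r2^2))
  ci0 <- zouDifferenceCI(r1, r2, 0, n)
  lo0 <- r1 - r2 - sqrt((r1 - l1)^2 + (u2 - r2)^2 -
                          2 * cc0 * (r1 - l1) * (u2 - r2))
  expect_equal(unname(ci0["lower"]), lo0, tolerance = 1e-12)

  expect_error(zouDifferenceCI(1, 0.5, 0.2, 50), "< 1")
  expect_error(zouDifferenceCI(0.5, 0.4, 0.2, 4), "> 4")
})

test_that("spin null of the node-neighbour test controls type-I error on independent maps", {
  at <- makeAtlas(55, 7, seed = 6)
  cn <- makeConnectome(at, seed = 6)
  sp <- generateSpins(at, 200, method = "bijective", seed = 6)
  d <- acos(pmin(pmax(tcrossprod(centroids(at)), -1), 1))
  k <- exp(-d^2 / (2 * 0.3^2)) + diag(1e-8, 110)
  ck <- chol(k)
  set.seed(6)
  ps <- replicate(100, {
    x <- as.vector(crossprod(ck, rnorm(110)))
    nodeNeighbourCorrelation(x, cn, sp, estimators = "dSc")$pSpin
  })
  # a spatially autocorrelated but network-independent map should not
  # reject in excess of the nominal level
  expect_lte(mean(ps < 0.05), 0.1)
  expect_gt(median(ps), 0.2)
})

test_that("FC-weighted SC correlations dominate non-SC ones on spread data", {
  at <- makeAtlas(224, 7, seed = 8)            # 448-region scale
  set.seed(8)
  ok <- logical(10)
  for (i in 1:10) {
    cn <- makeConnectome(at, seed = 8000 + i)
    sc <- structuralMatrix(cn)
    atr <- simulateSpread(sc, sample(regionIds(at), 3), 0.3, 6)
    est <- neighbourEstimates(atr, cn)
    okBoth <- !est$flagFcSc & !est$flagFcNonSc
    r1 <- cor(atr[okBoth], est$dFcSc[okBoth])
    r2 <- cor(atr[okBoth], est$dFcNonSc[okBoth])
    ci <- zouDifferenceCI(r1, r2, cor(est$dFcSc[okBoth], est$dFcNonSc[okBoth]),
                          sum(okBoth))
    ok[i] <- (r1 > r2) && (ci["lower"] > 0 || ci["upper"] < 0)
  }
  expect_gte(mean(ok), 0.8)
})
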