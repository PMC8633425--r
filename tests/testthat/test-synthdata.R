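test_that("synthetic atlases are mirror-symmetric unit lattices", {
  at <- makeAtlas(34, 7, seed = 1)
  expect_equal(nRegions(at), 68L)
  expect_equal(as.vector(table(hemispheres(at))), c(34L, 34L))
  cen <- centroids(at)
  expect_true(all(abs(sqrt(rowSums(cen^2)) - 1) < 1e-12))
  # mirrored pairs: right centroid = sagittal reflection of left
  left <- cen[hemispheres(at) == "L", ]
  right <- cen[hemispheres(at) == "R", ]
  expect_equal(unname(right), unname(left %*% diag(c(-1, 1, 1))),
               tolerance = 1e-9)
  expect_identical(makeAtlas(34, 7, seed = 1), at)   # determinism
  expect_error(makeAtlas(8, 9), "nNetworks")
  expect_error(makeAtlas(3), ">= 4")
})

test_that("atlas labels are complete and networks contiguous per construction", {
  at <- makeAtlas(50, 5, seed = 3)
  expect_equal(nlevels(networks(at)), 5L)
  expect_equal(sort(levels(corticalTypes(at))),
               sort(c("idiotypic", "unimodal", "heteromodal", "paralimbic")))
  expect_false(anyNA(networks(at)))
})

test_that("connectome density, connectivity and FC construction behave", {
  at <- makeAtlas(34, 7, seed = 4)
  cn <- makeConnectome(at, targetDensity = 0.15, seed = 4)
  sc <- structuralMatrix(cn)
  dens <- sum(sc > 0) / (68 * 67)
  expect_gte(dens, 0.135); expect_lte(dens, 0.165)
  g <- igraph::graph_from_adjacency_matrix(sc, mode = "undirected")
  expect_equal(igraph::components(g)$no, 1L)
  expect_equal(sc, t(sc))
  expect_true(all(diag(sc) == 0))
  fc <- functionalMatrix(cn)
  expect_true(all(abs(fc) <= 1))

  # infinite decay length: distance no longer predicts edges
  at2 <- makeAtlas(224, 7, seed = 5)
  cn2 <- makeConnectome(at2, 0.1, decayLength = Inf, seed = 5)
  d <- acos(pmin(pmax(tcrossprod(centroids(at2)), -1), 1))
  ut <- upper.tri(d)
  r <- cor(d[ut], structuralMatrix(cn2)[ut])
  expect_lt(abs(r), 0.1)
})

test_that("noise-free FC is a deterministic monotone image of communicability", {
  at <- makeAtlas(20, 4, seed = 6)
  cn <- makeConnectome(at, 0.3, fcNoiseSd = 0, seed = 6)
  # independent oracle: normalized communicability from the matrix exponential
  a <- structuralMatrix(cn)
  g <- as.matrix(Matrix::expm(Matrix::Matrix(a)))
  gn <- g / sqrt(outer(diag(g), diag(g)))
  off <- row(a) != col(a)
  expect_equal(cor(functionalMatrix(cn)[off], gn[off], method = "spearman"),
               1, tolerance = 1e-12)
  expect_identical(makeConnectome(at, 0.3, fcNoiseSd = 0, seed = 6), cn)
})

test_that("spread follows the degree-normalized accumulation rule", {
  sc <- matrix(0, 3, 3)
  sc[1, 2] <- sc[2, 1] <- sc[2, 3] <- sc[3, 2] <- 1
  rownames(sc) <- colnames(sc) <- c("n1", "n2", "n3")

  # eta = 0: seed indicator unchanged
  expect_equal(unname(simulateSpread(sc, "n1", eta = 0, nSteps = 5)),
               c(1, 0, 0))
  # one step from a single seed reaches exactly the neighbourhood
  one <- simulateSpread(sc, "n1", eta = 0.5, nSteps = 1)
  expect_identical(which(one > 0), c(n1 = 1L, n2 = 2L))
  # hand iteration: node 2 gains eta * (1/deg2) * a1 = 0.5 * 0.5 * 1
  expect_equal(unname(one), c(1, 0.25, 0))

  expect_error(simulateSpread(matrix(NaN, 2, 2), 1, 0.1, 1), "NaN")
})

test_that("spread is monotone in steps and eta, with isolated regions inert", {
  set.seed(11)
  for (rep in 1:5) {
    n <- 15
    sc <- matrix(rbinom(n * n, 1, 0.25), n, n)
    sc[lower.tri(sc)] <- t(sc)[lower.tri(sc)]
    diag(sc) <- 0
    sc[n, ] <- sc[, n] <- 0                      # isolated region
    prev <- simulateSpread(sc, 1, eta = 0.3, nSteps = 0)
    for (k in 1:4) {
      cur <- simulateSpread(sc, 1, eta = 0.3, nSteps = k)
      expect_true(all(cur >= prev - 1e-12))
      prev <- cur
    }
    lo <- simulateSpread(sc, 1, eta = 0.1, nSteps = 4)
    hi <- simulateSpread(sc, 1, eta = 0.6, nSteps = 4)
    expect_true(all(hi >= lo - 1e-12))
    expect_equal(unname(lo[n]), 0)
  }
})

test_that("cohorts encode the planted age/sex law and disease effect", {
  at <- makeAtlas(10, 2, seed = 8)
  cn <- makeConnectome(at, 0.35, seed = 8)
  sc <- structuralMatrix(cn)
  sp <- spreadParams(regionIds(at)[1:2], eta = 0.4, nStepsPerYear = 2)

  # near-zero noise + zero effect: values equal the deterministic prediction
  p0 <- cohortParams(nHC = 6, nPD = 3, noiseSd = 1e-9,
                     diseaseEffectScale = 0)
  co <- makeCohort(at, sc, p0, sp, seed = 8)
  d <- demographics(co)
  pred <- p0$betaIntercept + p0$betaAge * d$age + p0$betaSex * d$sex
  expect_equal(unname(deformationValues(co)),
               matrix(pred, nrow(d), nRegions(at)), tolerance = 1e-6)

  # planted spread: regions with high true spread progress more
  p1 <- cohortParams(nHC = 20, nPD = 25, noiseSd = 0.05,
                     diseaseEffectScale = 3)
  co1 <- makeCohort(at, sc, p1, sp, seed = 9)
  pdBl <- subsetCohort(co1, group = "PD", session = "bl")
  pdY4 <- subsetCohort(co1, group = "PD", session = "y4")
  prog <- colMeans(deformationValues(pdBl)) -
    colMeans(deformationValues(pdY4))
  truth <- simulateSpread(sc, sp$seedRegions, sp$eta, 8)
  top <- truth >= median(truth)
  expect_gt(mean(prog[top]), mean(prog[!top]))

  expect_error(cohortParams(nHC = 3), ">= 4")
})

test_that("expression fields are z-scored with planted class structure", {
  at <- makeAtlas(30, 4, seed = 10)
  ex <- makeExpression(at, nGenes = 300, nPerClass = 10, seed = 10)
  expect_equal(unname(colMeans(ex$expr)), rep(0, 300), tolerance = 1e-9)
  expect_equal(unname(apply(ex$expr, 2, sd)), rep(1, 300), tolerance = 1e-9)
  expect_equal(length(ex$cellSets), 7L)

  # same planted class genes correlate more than random pairs on average
  classGenes <- ex$cellSets$Endo
  sameCor <- cor(ex$expr[, classGenes])
  off <- row(sameCor) != col(sameCor)
  unplanted <- setdiff(colnames(ex$expr), unlist(ex$cellSets))
  randCor <- cor(ex$expr[, unplanted[1:10]])
  expect_gt(mean(sameCor[off]), mean(randCor[row(randCor) != col(randCor)]))

  expect_error(makeExpression(at, nGenes = 30, nPerClass = 10),
               "planted sets larger")
})

test_that("vanishing lengthscale removes spatial autocorrelation (Moran's I)", {
  skip_if_not_installed("ape")
  at <- makeAtlas(224, 7, seed = 12)
  ex <- makeExpression(at, nGenes = 100, lengthscale = 0, nPerClass = 5,
                       seed = 12)
  d <- acos(pmin(pmax(tcrossprod(centroids(at)), -1), 1))
  w <- 1 / d; diag(w) <- 0
  mi <- vapply(1:100, function(g)
    ape::Moran.I(ex$expr[, g], w)$observed, numeric(1))
  expect_lt(abs(mean(mi)), 0.05)

  # and a long lengthscale yields clearly autocorrelated maps
  ex2 <- makeExpression(at, nGenes = 20, lengthscale = 0.5, nPerClass = 2,
                        noiseSd = 0.1, seed = 12)
  mi2 <- vapply(1:20, function(g)
    ape::Moran.I(ex2$expr[, g], w)$observed, numeric(1))
  expect_gt(mean(mi2), 0.1)
})
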