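test_that("progression maps follow the sign convention and are linear", {
  wb <- matrix(c(-0.5, 0.2), 1, 2, dimnames = list("S1", c("r1", "r2")))
  wf <- matrix(c(-1.0, 0.2), 1, 2, dimnames = list("S1", c("r1", "r2")))
  pm <- progressionMap(wb, wf)
  expect_equal(unname(pm[1, ]), c(0.5, 0))       # worsening is positive
  expect_equal(unname(progressionMap(wb, wb)[1, ]), c(0, 0))
  # antisymmetry under session swap
  expect_equal(progressionMap(wf, wb), -pm)

  set.seed(1)
  wb2 <- matrix(rnorm(40), 8, 5, dimnames = list(paste0("S", 1:8), NULL))
  wf2 <- matrix(rnorm(40), 8, 5, dimnames = list(paste0("S", 1:8), NULL))
  gm <- progressionMap(wb2, wf2, "group-mean")
  expect_equal(gm, colMeans(progressionMap(wb2, wf2)), tolerance = 1e-12)
  expect_error(progressionMap(wb2[1:4, ], wf2[1:5, ]), "mismatch")
})

test_that("identical sessions give zero F and no significant regions", {
  set.seed(2)
  ns <- 10; nr <- 6
  base <- matrix(rnorm(ns * nr), ns, nr)
  w <- array(rep(base, 3), c(ns, 3, nr))
  w <- aperm(array(rep(base, each = 1), c(ns, nr, 3)), c(1, 3, 2))
  res <- regionalProgressionTest(w, sex = rep_len(0:1, ns),
                                 site = rep("a", ns), nPerm = 50, seed = 2)
  expect_equal(res$table$F, rep(0, nr))
  expect_false(any(res$table$sigFWE))
})

test_that("planted regional decline is flagged with FWE control", {
  ns <- 40; nt <- 4; nr <- 60
  noise <- 0.5
  planted <- 1:10
  effect <- c(0, 0.5, 1.0, 1.5) * noise    # 1.5 noise-SD decline by the end
  detected <- clean <- logical(10)
  for (rep in 1:10) {
    set.seed(300 + rep)
    w <- array(rnorm(ns * nt * nr, sd = noise), c(ns, nt, nr),
               dimnames = list(paste0("S", 1:ns),
                               c("bl", "y1", "y2", "y4"), paste0("r", 1:nr)))
    for (t in 1:nt) w[, t, planted] <- w[, t, planted] - effect[t]
    res <- regionalProgressionTest(w, sex = rbinom(ns, 1, 0.5),
                                   site = sample(c("a", "b"), ns, TRUE),
                                   nPerm = 300, seed = 300 + rep)
    detected[rep] <- sum(res$table$sigFWE[planted]) >= 8
    clean[rep] <- sum(res$table$sigFWE[-planted]) == 0
    if (rep == 1)
      expect_lt(median(res$posthoc$y4$p[planted]), 0.01)
  }
  expect_gte(mean(detected & clean), 0.8)
})

test_that("singleton sites are dropped with a warning", {
  set.seed(4)
  ns <- 12
  w <- array(rnorm(ns * 2 * 4), c(ns, 2, 4))
  expect_warning(
    regionalProgressionTest(w, sex = rep_len(0:1, ns),
                            site = c(rep("a", 11), "lonely"),
                            nPerm = 20, seed = 4),
    "single subject")
})

test_that("cortical-type ANOVA matches hand-computed decompositions", {
  # equal class means with variance: F ~ 0
  x <- c(1, 2, 3, 1, 2, 3, 1, 2, 3)
  cls <- rep(c("a", "b", "c"), each = 3)
  res <- corticalTypeAnova(x, cls)
  expect_lt(res$F, 1e-10)
  expect_gt(res$p, 0.99)

  # hand decomposition: SSB = 6 (df 2), SSW = 6 (df 6) -> F = 3
  y <- c(1, 2, 3, 2, 3, 4, 3, 4, 5)
  res2 <- corticalTypeAnova(y, cls)
  expect_equal(res2$F, 3, tolerance = 1e-12)
  expect_equal(res2$df, c(2, 6))
  expect_equal(nrow(res2$pairwise), 3L)
  expect_true(all(res2$pairwise$pBonferroni >= res2$pairwise$pRaw))

  expect_silent(corticalTypeAnova(c(1, 1.5, 2, 2.7),
                                  rep(c("a", "b"), each = 2)))
  expect_error(corticalTypeAnova(rep(1, 8), rep(c("a", "b"), each = 4)),
               "zero within-class variance")
})

test_that("a planted idiotypic-sparing gradient yields the expected ANOVA ordering", {
  at <- makeAtlas(110, 7, seed = 5)
  types <- corticalTypes(at)
  set.seed(5)
  # idiotypic regions progress less; smooth noise elsewhere
  prog <- rnorm(220, mean = 0.3, sd = 0.1)
  prog[types == "idiotypic"] <- rnorm(sum(types == "idiotypic"),
                                      mean = 0.05, sd = 0.1)
  res <- corticalTypeAnova(prog, types)
  expect_equal(names(which.min(res$classMeans)), "idiotypic")
  expect_true(any(res$pairwise$pBonferroni < 0.05))
})

test_that("partial Spearman reduces to Spearman and controls covariates", {
  set.seed(6)
  x <- rnorm(60); z <- rnorm(60)
  expect_equal(partialSpearman(x, x, cbind(z))$rho, 1, tolerance = 1e-12)

  # no covariates: exact agreement with brute-force rank correlation
  for (r in 1:10) {
    a <- sample(rnorm(40)); b <- a + rnorm(40)
    expect_equal(partialSpearman(a, b)$rho,
                 cor(a, b, method = "spearman"), tolerance = 1e-12)
  }

  # y = covariate, x independent: partial correlation near zero
  set.seed(7)
  zc <- rnorm(200); xi <- rnorm(200)
  expect_lt(abs(partialSpearman(xi, zc, cbind(zc))$rho), 0.15)
  expect_error(partialSpearman(rep(1, 20), rnorm(20)), "zero rank variance")
})

test_that("the correlation battery adjusts across all pairs", {
  set.seed(8)
  img <- data.frame(a = rnorm(50), b = rnorm(50))
  cli <- data.frame(u = rnorm(50), v = rnorm(50), w = rnorm(50))
  res <- partialSpearmanBattery(img, cli, covariates = data.frame(rnorm(50)))
  expect_equal(nrow(res), 6L)
  expect_equal(res$pFDR, p.adjust(res$pRaw, "BH"))
})

test_that("p-value adjustment reproduces the standard stepwise arithmetic", {
  expect_equal(adjustPValues(c(0.01, 0.04, 0.03), "holm"),
               c(0.03, 0.06, 0.06))
  expect_equal(adjustPValues(c(0.01, 0.02, 0.03), "bh_fdr"),
               c(0.03, 0.03, 0.03))
  for (m in c("bonferroni", "holm", "bh_fdr"))
    expect_equal(adjustPValues(0.2, m), 0.2)
  # dominance: bonferroni >= holm >= raw, elementwise
  set.seed(9)
  for (r in 1:10) {
    p <- runif(15)
    bf <- adjustPValues(p, "bonferroni")
    hl <- adjustPValues(p, "holm")
    expect_true(all(bf >= hl - 1e-15))
    expect_true(all(hl >= p - 1e-15))
  }
  expect_error(adjustPValues(c(0.2, 1.4), "holm"), "0, 1")
})

test_that("clinical repeated-measures ANOVA has the paired-t identity", {
  vals <- matrix(rep(c(3, 3, 3), each = 6), 6, 3)
  res <- rmAnovaClinical(vals)
  expect_equal(res$F, 0)
  expect_equal(res$p, 1)

  set.seed(10)
  two <- matrix(rnorm(24), 12, 2)
  res2 <- rmAnovaClinical(two)
  tt <- t.test(two[, 2], two[, 1], paired = TRUE)$statistic
  expect_equal(res2$F, unname(tt^2), tolerance = 1e-9)

  # planted monotone worsening, about 1 SD by the end, n = 74
  hits <- 0L
  for (r in 1:20) {
    set.seed(100 + r)
    base <- rnorm(74)
    m <- cbind(base, base + 0.33 + rnorm(74, sd = 0.5),
               base + 0.66 + rnorm(74, sd = 0.5),
               base + 1 + rnorm(74, sd = 0.5))
    hits <- hits + (rmAnovaClinical(m)$p < 0.05)
  }
  expect_gte(hits / 20, 0.95)
  expect_error(rmAnovaClinical(matrix(1, 2, 3)), ">= 3")
})
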