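## Small fixtures built in code, shared across test files.

# four axis-aligned parcels, two per hemisphere
tinyAtlas <- function() {
  ParcelAtlas(regionId = c("L1", "L2", "R1", "R2"),
              hemisphere = c("L", "L", "R", "R"),
              centroid = rbind(c(-1, 0, 0), c(0, 1, 0),
                               c(1, 0, 0), c(0, -1, 0)),
              network = c("A", "B", "A", "B"),
              corticalType = c("idiotypic", "unimodal",
                               "idiotypic", "unimodal"))
}

# path graph 1-2-3 embedded in a larger identity-fc connectome
pathConnectome <- function(fc12 = 0.5, fc23 = 0.25) {
  sc <- matrix(0, 3, 3)
  sc[1, 2] <- sc[2, 1] <- 1
  sc[2, 3] <- sc[3, 2] <- 1
  fc <- matrix(0, 3, 3)
  fc[1, 2] <- fc[2, 1] <- fc12
  fc[2, 3] <- fc[3, 2] <- fc23
  Connectome(sc = sc, fc = fc, regionId = c("r1", "r2", "r3"))
}

# HC-baseline cohort following a known linear law
linearCohort <- function(n, betaAge = -0.01, betaSex = 0.05,
                         intercept = 1.0, noiseSd = 0.1, nRegions = 5,
                         seed = 1, group = "HC") {
  set.seed(seed)
  age <- runif(n, 40, 80)
  sex <- rep_len(c(0, 1), n)
  pred <- intercept + betaAge * age + betaSex * sex
  vals <- matrix(pred, n, nRegions) +
    matrix(rnorm(n * nRegions, sd = noiseSd), n, nRegions)
  colnames(vals) <- paste0("reg", seq_len(nRegions))
  CohortTable(data.frame(subjectId = sprintf("S%03d", seq_len(n)),
                         group = group, session = "bl", age = age,
                         sex = sex, site = "site1",
                         stringsAsFactors = FALSE),
              vals)
}

expect_setequal_sorted <- function(a, b) {
  testthat::expect_identical(sort(a), sort(b))
}
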