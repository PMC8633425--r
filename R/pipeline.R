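#' Generate a complete synthetic study dataset
#'
#' Bundles the generators into one call reproducing the emulated study
#' design: a mirror-symmetric spherical atlas, a distance-decaying
#' structural connectome with a communicability-derived functional
#' matrix, a longitudinal cohort (controls at baseline only; patients at
#' baseline, 1, 2 and 4 years) whose follow-up atrophy follows a
#' network-spread process modulated by a planted protective cell-class
#' gradient, and spatially autocorrelated expression with marker sets and
#' annotation terms.
#'
#' The protective gradient multiplies spread increments by
#' `exp(-gammaProtect * endothelial latent)`, planting the inverse
#' relationship between endothelial prevalence and atrophy progression
#' that the cell-type decoding is expected to recover.
#'
#' @param seed master seed; all stages derive child seeds from it.
#' @param nPerHemisphere parcels per hemisphere (default 110, i.e. a
#'   220-region atlas).
#' @param nNetworks network patches (default 7).
#' @param targetDensity,decayLength,fcNoiseSd connectome parameters.
#' @param params a [cohortParams()] list.
#' @param eta,nStepsPerYear,nSeeds spread parameters; seed regions are
#'   drawn at random.
#' @param gammaProtect strength of the protective endothelial gradient
#'   (0 disables it).
#' @param nGenes,lengthscale,exprArgs expression generator parameters
#'   (`exprArgs` is a list of further [makeExpression()] arguments).
#' @return list with `atlas`, `connectome`, `cohort`, `expression`
#'   (the [makeExpression()] bundle), `spread` (the spreadParams used),
#'   and `vulnerability`.
#' @export
makeStudyData <- function(seed = 1L, nPerHemisphere = 110L, nNetworks = 7L,
                          targetDensity = 0.10, decayLength = 1.0,
                          fcNoiseSd = 0.1, params = cohortParams(),
                          eta = 0.3, nStepsPerYear = 2L, nSeeds = 3L,
                          gammaProtect = 1, nGenes = 1000L,
                          lengthscale = 0.3, exprArgs = list()) {
  atlas <- makeAtlas(nPerHemisphere, nNetworks, seed = childSeed(seed, "atlas"))
  conn <- makeConnectome(atlas, targetDensity, decayLength, fcNoiseSd,
                         seed = childSeed(seed, "conn"))

  old <- .Random.seed_save(); on.exit(.Random.seed_restore(old))
  set.seed(childSeed(seed, "study-seeds"))
  seedRegions <- sample(regionIds(atlas), nSeeds)

  # class latents first: the protective gradient couples the spread to the
  # endothelial pattern, and the gene-screen signal genes are planted on
  # the resulting (vulnerability-modulated) disease pattern
  latent <- scale(.sphericalFields(atlas, 7L, lengthscale,
                                   childSeed(seed, "class-latents")))
  vulnerability <- exp(-gammaProtect * latent[, 2L])   # endothelial column
  sc <- structuralMatrix(conn)
  diseaseMap <- simulateSpread(sc, seedRegions, eta, 4L * nStepsPerYear,
                               vulnerability)
  expression <- do.call(makeExpression, c(list(
    atlas = atlas, nGenes = nGenes, lengthscale = lengthscale,
    signalMap = diseaseMap, classLatent = latent,
    seed = childSeed(seed, "expr")), exprArgs))

  spread <- spreadParams(seedRegions, eta, nStepsPerYear, vulnerability)
  cohort <- makeCohort(atlas, sc, params, spread,
                       seed = childSeed(seed, "cohort"))
  list(atlas = atlas, connectome = conn, cohort = cohort,
       expression = expression, spread = spread,
       vulnerability = vulnerability)
}

#' Run the full analysis pipeline
#'
#' Executes every stage on one dataset: W-score normative modelling on
#' control baselines, atrophy-progression maps for each follow-up
#' interval, cortical-type ANOVA, network-label spin means, the regional
#' repeated-measures progression test, node-neighbourhood correlations
#' with Zou comparisons of the dependent correlations, cell-class
#' correlations, and the gene screen with overrepresentation analysis.
#' Outputs are written as TSV tables plus a JSON summary carrying every
#' statistic, p-value, the spin count and the seed. Given identical
#' inputs and seed the outputs are byte-identical across runs.
#'
#' @param config either a YAML file path or a list; recognized fields:
#'   `seed`, `n_spins` (>= 1), `alpha`, `tails` (`"one"`/`"two"`),
#'   `spin_method`, `n_perm`, and either `simulate:` (arguments to
#'   [makeStudyData()]) or `inputs:` with paths `atlas`, `cohort`,
#'   `structural`, `functional`, `expression`, `cell_sets`, `annotation`.
#' @param outDir output directory (created if needed).
#' @return invisibly, the summary list (also written to
#'   `summary.json`).
#' @export
runPipeline <- function(config, outDir) {
  if (is.character(config)) config <- yaml::read_yaml(config)
  seed <- as.integer(config$seed %||% 1L)
  nSpin <- as.integer(config$n_spins %||% 1000L)
  if (nSpin < 1L) stop("n_spins must be >= 1")
  alpha <- config$alpha %||% 0.05
  tails <- config$tails %||% "two"
  spinMethod <- config$spin_method %||% "nearest"
  nPerm <- as.integer(config$n_perm %||% 1000L)
  dir.create(outDir, showWarnings = FALSE, recursive = TRUE)

  data <- .stopStage("inputs", {
    if (!is.null(config$inputs)) {
      ip <- config$inputs
      atlas <- loadAtlas(ip$atlas)
      list(atlas = atlas,
           connectome = Connectome(
             loadMatrix(ip$structural, atlas, "structural"),
             loadMatrix(ip$functional, atlas, "functional"),
             regionIds(atlas)),
           cohort = loadCohort(ip$cohort, atlas),
           expression = list(expr = loadExpression(ip$expression, atlas),
                             cellSets = parseGMT(ip$cell_sets),
                             annotation = parseGMT(ip$annotation)))
    } else {
      do.call(makeStudyData,
              c(list(seed = seed), config$simulate %||% list()))
    }
  })
  atlas <- data$atlas

  wmod <- .stopStage("wscore", fitWScoreModel(data$cohort))
  pd <- subsetCohort(data$cohort, group = "PD")
  wAll <- .stopStage("wscore", computeWScores(wmod, pd))
  dem <- demographics(pd)
  sess <- sort(unique(as.character(dem$session)))
  bySession <- lapply(stats::setNames(sess, sess), function(s) {
    rows <- which(dem$session == s)
    w <- wAll[rows, , drop = FALSE]
    rownames(w) <- dem$subjectId[rows]
    w[order(rownames(w)), , drop = FALSE]
  })
  followups <- setdiff(sess, "bl")

  spins <- .stopStage("spins",
    generateSpins(atlas, nSpin, method = spinMethod,
                  seed = childSeed(seed, "pipeline-spins")))

  progMaps <- .stopStage("progression", {
    lapply(stats::setNames(followups, followups), function(s)
      progressionMap(bySession[["bl"]], bySession[[s]],
                     aggregate = "group-mean"))
  })
  for (s in followups)
    .writeTSV(data.frame(region = regionIds(atlas),
                         progression = progMaps[[s]]),
              file.path(outDir, sprintf("progression_bl_%s.tsv", s)))

  ctypes <- corticalTypes(atlas)
  anovaByInterval <- .stopStage("cortical-type", {
    lapply(progMaps, function(m) corticalTypeAnova(m, ctypes))
  })
  networkMeans <- .stopStage("network-means", {
    lapply(progMaps, function(m)
      spinLabelMeans(m, networks(atlas), spins))
  })
  for (s in followups)
    .writeTSV(networkMeans[[s]], file.path(outDir,
                                           sprintf("network_means_%s.tsv", s)))

  subj <- rownames(bySession[[1L]])
  warr <- array(NA_real_, c(length(subj), length(sess), nRegions(atlas)),
                dimnames = list(subj, sess, regionIds(atlas)))
  for (s in sess) warr[, s, ] <- bySession[[s]]
  demB <- dem[match(subj, dem$subjectId), ]
  regional <- .stopStage("regional-test",
    regionalProgressionTest(warr, sex = demB$sex, site = demB$site,
                            nPerm = nPerm, alpha = alpha,
                            seed = childSeed(seed, "pipeline-fwe")))
  .writeTSV(regional$table, file.path(outDir, "regional_test.tsv"))

  network <- .stopStage("network", {
    lapply(stats::setNames(followups, followups), function(s) {
      res <- nodeNeighbourCorrelation(progMaps[[s]], data$connectome, spins,
                                      tails = tails)
      nulls <- attr(res, "nulls")
      est <- neighbourEstimates(progMaps[[s]], data$connectome)
      okBoth <- !est$flagFcSc & !est$flagFcNonSc
      r12 <- stats::cor(est$dFcSc[okBoth], est$dFcNonSc[okBoth])
      ciNon <- zouDifferenceCI(res$r[res$estimator == "dFcSc"],
                               res$r[res$estimator == "dFcNonSc"],
                               r12, sum(okBoth))
      okAll <- !est$flagFcSc & !est$flagFcAll
      r12a <- stats::cor(est$dFcSc[okAll], est$dFcAll[okAll])
      ciAll <- zouDifferenceCI(res$r[res$estimator == "dFcSc"],
                               res$r[res$estimator == "dFcAll"],
                               r12a, sum(okAll))
      list(correlations = res, zouNonSc = ciNon, zouAll = ciAll,
           estimates = est)
    })
  })
  for (s in followups) {
    .writeTSV(network[[s]]$correlations,
              file.path(outDir, sprintf("network_correlations_%s.tsv", s)))
    .writeTSV(network[[s]]$estimates,
              file.path(outDir, sprintf("neighbour_estimates_%s.tsv", s)))
  }

  hasExpr <- !is.null(data$expression)
  celltype <- geneScreens <- enrich <- NULL
  if (hasExpr) {
    scores <- .stopStage("celltype",
      cellTypeScores(data$expression$expr, data$expression$cellSets))
    celltype <- .stopStage("celltype", {
      lapply(progMaps, function(m)
        cellTypeCorrelations(scores, m, spins, tails = tails))
    })
    for (s in followups)
      .writeTSV(celltype[[s]],
                file.path(outDir, sprintf("celltype_correlations_%s.tsv", s)))
    geneScreens <- .stopStage("gene-screen", {
      lapply(progMaps, function(m)
        geneScreen(data$expression$expr, m, spins, fdrAlpha = alpha))
    })
    enrich <- .stopStage("enrichment", {
      lapply(geneScreens, function(gs) {
        if (length(gs$positive) == 0L) return(NULL)
        overrepresentation(gs$positive, gs$table$gene,
                           data$expression$annotation)
      })
    })
    for (s in followups) {
      .writeTSV(geneScreens[[s]]$table,
                file.path(outDir, sprintf("gene_screen_%s.tsv", s)))
      if (!is.null(enrich[[s]]))
        .writeTSV(enrich[[s]],
                  file.path(outDir, sprintf("enrichment_%s.tsv", s)))
    }
  }

  summary <- list(
    seed = seed, n_spins = nSpin, alpha = alpha, tails = tails,
    sex_coding = "0=female,1=male",
    n_regions = nRegions(atlas),
    n_controls = nControls(wmod),
    n_patients = length(subj),
    regional_test = list(
      n_significant_fwe = sum(regional$table$sigFWE),
      n_significant_fdr = sum(regional$table$sigFDR),
      n_perm = regional$nPerm),
    cortical_type_anova = lapply(anovaByInterval, function(a)
      list(F = a$F, p = a$p, class_means = as.list(a$classMeans))),
    network_means = lapply(networkMeans, function(nm)
      stats::setNames(lapply(seq_len(nrow(nm)), function(i)
        list(mean = nm$mean[i], p_spin = nm$pSpin[i])), nm$label)),
    network = lapply(network, function(x) list(
      r = stats::setNames(as.list(x$correlations$r),
                          x$correlations$estimator),
      p_spin = stats::setNames(as.list(x$correlations$pSpin),
                               x$correlations$estimator),
      zou_ci_sc_vs_nonsc = as.list(x$zouNonSc),
      zou_ci_sc_vs_all = as.list(x$zouAll))),
    celltype = if (hasExpr) lapply(celltype, function(ct)
      stats::setNames(lapply(seq_len(nrow(ct)), function(i)
        list(r = ct$r[i], p_spin = ct$pSpin[i])), ct$class)),
    gene_screen = if (hasExpr) lapply(geneScreens, function(gs)
      list(n_positive = length(gs$positive),
           n_negative = length(gs$negative))),
    enrichment = if (hasExpr) lapply(enrich, function(e)
      if (is.null(e)) NULL else list(
        top_term = e$term[1L],
        top_fold = e$foldEnrichment[1L],
        top_p_bonferroni = e$pBonferroni[1L])))
  jsonlite::write_json(summary, file.path(outDir, "summary.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE,
                       null = "null")
  invisible(summary)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
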