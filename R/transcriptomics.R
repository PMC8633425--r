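#' Cell-class expression scores per region
#'
#' Virtual histology: the score of a cell class in a region is the mean
#' (z-scored) expression of the class's marker genes available in the
#' matrix. Markers absent from the matrix are skipped with a message; a
#' class with no available markers is an error.
#'
#' @param expr regions x genes expression matrix (gene column names).
#' @param sets named list of marker gene sets (typically the 7 classes:
#'   astrocytes, endothelial, microglia, excitatory/inhibitory neurons,
#'   oligodendrocytes, OPCs).
#' @return matrix regions x classes of mean expression scores.
#' @export
cellTypeScores <- function(expr, sets) {
  expr <- as.matrix(expr)
  scores <- vapply(names(sets), function(cl) {
    genes <- intersect(sets[[cl]], colnames(expr))
    if (length(genes) == 0L)
      stop("cell class '", cl, "' has no genes in the expression matrix")
    missing <- setdiff(sets[[cl]], genes)
    if (length(missing))
      message(length(missing), " marker(s) of '", cl,
              "' absent from expression matrix; skipped")
    rowMeans(expr[, genes, drop = FALSE])
  }, numeric(nrow(expr)))
  rownames(scores) <- rownames(expr)
  scores
}

#' Cell-class correlations with atrophy progression
#'
#' Pearson correlation between the progression map and each cell-class
#' score, tested against a spin null that permutes the progression map.
#'
#' @param scores regions x classes matrix from [cellTypeScores()].
#' @param progression per-region progression map.
#' @param spins a [SpinNulls-class].
#' @param tails,convention passed to [spinPValue()].
#' @return data.frame with class, r, pSpin; null correlations in the
#'   `"nulls"` attribute.
#' @export
cellTypeCorrelations <- function(scores, progression, spins,
                                 tails = "two", convention = "add_one") {
  stopifnot(is(spins, "SpinNulls"))
  scores <- as.matrix(scores)
  if (nrow(scores) != length(progression))
    stop("scores and progression must cover the same regions")
  sds <- apply(scores, 2L, stats::sd)
  if (any(sds == 0))
    stop("zero-variance score column: ", colnames(scores)[sds == 0][1L])
  if (stats::sd(progression) == 0) stop("zero variance in progression map")
  a <- spinAssignments(spins)
  spun <- matrix(progression[t(a)], length(progression), nrow(a))
  r <- as.vector(stats::cor(progression, scores))
  nullR <- stats::cor(spun, scores)                 # nSpins x classes
  p <- vapply(seq_along(r), function(i)
    spinPValue(r[i], nullR[, i], tails = tails, convention = convention),
    numeric(1L))
  out <- data.frame(class = colnames(scores), r = r, pSpin = p,
                    row.names = NULL)
  attr(out, "nulls") <- nullR
  out
}

#' Gene-wise correlation screen against atrophy progression
#'
#' Every gene's regional expression is correlated with the progression
#' map (Pearson by default). A gene survives the screen iff its
#' Benjamini-Hochberg FDR-adjusted parametric p-value is below `fdrAlpha`
#' AND its spin p-value (shared spin nulls of the progression map,
#' two-tailed) is below `spinAlpha`. Survivors are split by the sign of
#' the correlation. Constant gene columns are excluded with a warning.
#'
#' @param expr regions x genes expression matrix.
#' @param progression per-region progression map (>= 10 regions).
#' @param spins a [SpinNulls-class].
#' @param fdrAlpha FDR threshold (default 0.05).
#' @param spinAlpha spin threshold (default 0.05).
#' @param method `"pearson"` (default) or `"spearman"`.
#' @param convention p-value convention, see [spinPValue()].
#' @return list with `table` (gene, r, pRaw, pFDR, pSpin, direction,
#'   survives), `positive`, `negative` (gene id vectors).
#' @export
geneScreen <- function(expr, progression, spins, fdrAlpha = 0.05,
                       spinAlpha = 0.05, method = c("pearson", "spearman"),
                       convention = "add_one") {
  stopifnot(is(spins, "SpinNulls"))
  method <- match.arg(method)
  expr <- as.matrix(expr)
  n <- length(progression)
  if (n < 10L) stop("need >= 10 regions")
  if (nrow(expr) != n) stop("expression rows must match progression length")
  sds <- apply(expr, 2L, stats::sd)
  if (any(sds == 0)) {
    warning(sum(sds == 0), " constant gene(s) excluded from the screen")
    expr <- expr[, sds > 0, drop = FALSE]
  }
  if (method == "spearman") {
    expr <- apply(expr, 2L, rank)
    prog <- rank(progression)
  } else prog <- progression

  r <- as.vector(stats::cor(prog, expr))
  tt <- r * sqrt((n - 2) / (1 - r^2))
  pRaw <- 2 * stats::pt(-abs(tt), n - 2)
  pFDR <- stats::p.adjust(pRaw, "BH")

  a <- spinAssignments(spins)
  spun <- matrix(prog[t(a)], n, nrow(a))
  nullR <- stats::cor(spun, expr)                  # nSpins x genes
  exceed <- colSums(abs(nullR) >= matrix(abs(r), nrow(a), length(r),
                                         byrow = TRUE))
  pSpin <- if (convention == "add_one") (1 + exceed) / (1 + nrow(a))
           else exceed / nrow(a)

  survives <- pFDR < fdrAlpha & pSpin < spinAlpha
  tab <- data.frame(gene = colnames(expr), r = r, pRaw = pRaw,
                    pFDR = pFDR, pSpin = pSpin,
                    direction = ifelse(r >= 0, "positive", "negative"),
                    survives = survives, row.names = NULL)
  list(table = tab,
       positive = tab$gene[survives & tab$r > 0],
       negative = tab$gene[survives & tab$r < 0])
}

#' Overrepresentation analysis of a target gene list
#'
#' For every annotation term with at least `minTermSize` background genes:
#' observed overlap with the target list, expected overlap
#' `|target| * |term| / |background|`, fold enrichment
#' `observed / expected`, hypergeometric upper-tail p-value and one-sided
#' Fisher exact p-value (identical tails; both reported), with Bonferroni
#' adjustment of the hypergeometric p over the tested terms.
#'
#' @param targetGenes character vector, must be a subset of the background.
#' @param backgroundGenes character vector of all screened genes.
#' @param annotation named list term -> gene vector (intersected with the
#'   background).
#' @param minTermSize minimum background genes per tested term (default 5).
#' @return data.frame sorted by Bonferroni-adjusted p: term, termSize,
#'   observed, expected, foldEnrichment, pHypergeometric, pFisher,
#'   pBonferroni.
#' @export
overrepresentation <- function(targetGenes, backgroundGenes, annotation,
                               minTermSize = 5L) {
  backgroundGenes <- unique(backgroundGenes)
  targetGenes <- unique(targetGenes)
  if (length(backgroundGenes) == 0L) stop("empty background")
  if (!all(targetGenes %in% backgroundGenes))
    stop("target genes must be a subset of the background")
  nBg <- length(backgroundGenes)
  nT <- length(targetGenes)
  rows <- lapply(names(annotation), function(term) {
    genes <- intersect(unique(annotation[[term]]), backgroundGenes)
    m <- length(genes)
    if (m < minTermSize) return(NULL)
    obs <- length(intersect(genes, targetGenes))
    expd <- nT * m / nBg
    pHyp <- stats::phyper(obs - 1L, m, nBg - m, nT, lower.tail = FALSE)
    pFis <- stats::fisher.test(
      matrix(c(obs, m - obs, nT - obs, nBg - m - nT + obs), 2L),
      alternative = "greater")$p.value
    data.frame(term = term, termSize = m, observed = obs, expected = expd,
               foldEnrichment = if (expd > 0) obs / expd else NA_real_,
               pHypergeometric = pHyp, pFisher = pFis)
  })
  out <- do.call(rbind, rows)
  if (is.null(out)) stop("no terms meet minTermSize in the background")
  out$pBonferroni <- pmin(out$pHypergeometric * nrow(out), 1)
  out[order(out$pBonferroni, out$pHypergeometric), , drop = FALSE]
}
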