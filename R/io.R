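## Readers and writers for the package's plain-text interchange formats.
## All tables are TSV; gene sets use the GMT convention
## (name <TAB> description <TAB> gene1 <TAB> gene2 ...).

#' Read a parcel atlas from a TSV file
#'
#' Expected header: `region_id, hemisphere, x, y, z, network, cortical_type`.
#' Centroids must be unit vectors within 1e-6 (renormalized on load).
#'
#' @param path file path.
#' @return a [ParcelAtlas-class].
#' @export
loadAtlas <- function(path) {
  d <- utils::read.delim(path, stringsAsFactors = FALSE)
  need <- c("region_id", "hemisphere", "x", "y", "z", "network", "cortical_type")
  if (!all(need %in% names(d)))
    stop("atlas file must have columns: ", paste(need, collapse = ", "))
  if (anyDuplicated(d$region_id))
    stop("duplicate region_id in atlas file")
  ParcelAtlas(d$region_id, d$hemisphere,
              cbind(d$x, d$y, d$z), d$network, d$cortical_type)
}

#' Write a parcel atlas to TSV
#' @param atlas a [ParcelAtlas-class].
#' @param path output path.
#' @return `path`, invisibly.
#' @export
writeAtlas <- function(atlas, path) {
  stopifnot(is(atlas, "ParcelAtlas"))
  cen <- centroids(atlas)
  .writeTSV(data.frame(region_id = regionIds(atlas),
                       hemisphere = as.character(hemispheres(atlas)),
                       x = cen[, 1L], y = cen[, 2L], z = cen[, 3L],
                       network = as.character(networks(atlas)),
                       cortical_type = as.character(corticalTypes(atlas))),
            path)
}

#' Read a cohort table from TSV
#'
#' Long format: one row per subject-session with columns
#' `subject_id, group, session, age, sex, site` followed by one deformation
#' column per region, in atlas order.
#'
#' @param path file path.
#' @param atlas the [ParcelAtlas-class] fixing region order.
#' @return a [CohortTable-class].
#' @export
loadCohort <- function(path, atlas) {
  d <- utils::read.delim(path, stringsAsFactors = FALSE, check.names = FALSE)
  meta <- c("subject_id", "group", "session", "age", "sex", "site")
  if (!all(meta %in% names(d)))
    stop("cohort file must have columns: ", paste(meta, collapse = ", "))
  ids <- regionIds(atlas)
  if (!all(ids %in% names(d)))
    stop("cohort file lacks one column per atlas region")
  vals <- as.matrix(d[, ids, drop = FALSE])
  CohortTable(data.frame(subjectId = d$subject_id, group = d$group,
                         session = d$session, age = d$age, sex = d$sex,
                         site = as.character(d$site),
                         stringsAsFactors = FALSE),
              vals)
}

#' Write a cohort table to TSV
#' @param cohort a [CohortTable-class].
#' @param path output path.
#' @return `path`, invisibly.
#' @export
writeCohort <- function(cohort, path) {
  stopifnot(is(cohort, "CohortTable"))
  d <- demographics(cohort)
  out <- data.frame(subject_id = d$subjectId, group = as.character(d$group),
                    session = as.character(d$session), age = d$age,
                    sex = d$sex, site = as.character(d$site),
                    stringsAsFactors = FALSE, check.names = FALSE)
  out <- cbind(out, as.data.frame(deformationValues(cohort),
                                  check.names = FALSE))
  .writeTSV(out, path)
}

#' Read a dense connectivity matrix from TSV
#'
#' The matrix must be square in atlas order. Asymmetries within 1e-8 are
#' symmetrized by averaging; larger asymmetries are an error. The diagonal
#' is forced to zero. Functional matrices must have entries in \[-1, 1\]
#' (violations beyond 1e-8 are an error; smaller ones are clipped).
#'
#' @param path file path (TSV, no header, no row names).
#' @param atlas the [ParcelAtlas-class] fixing the order.
#' @param kind `"structural"` or `"functional"`.
#' @return numeric matrix with region-id dimnames.
#' @export
loadMatrix <- function(path, atlas, kind = c("structural", "functional")) {
  kind <- match.arg(kind)
  m <- as.matrix(utils::read.table(path, sep = "\t", header = FALSE))
  if (nrow(m) != ncol(m)) stop("connectivity matrix is non-square")
  if (nrow(m) != nRegions(atlas))
    stop("matrix size does not match atlas (", nrow(m), " vs ",
         nRegions(atlas), ")")
  if (max(abs(m - t(m))) > 1e-8) stop("asymmetric matrix beyond tolerance")
  m <- (m + t(m)) / 2
  diag(m) <- 0
  if (kind == "functional") {
    if (any(abs(m) > 1 + 1e-8))
      stop("functional entry outside [-1, 1] beyond tolerance")
    m <- pmin(pmax(m, -1), 1)
  } else if (any(m < 0)) {
    stop("structural matrix must be non-negative")
  }
  dimnames(m) <- list(regionIds(atlas), regionIds(atlas))
  m
}

#' Write a dense matrix to TSV (no header)
#' @param m numeric matrix.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
writeMatrix <- function(m, path) {
  utils::write.table(format(m, digits = 17, scientific = TRUE, trim = TRUE),
                     path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' Parse a GMT gene-set file
#'
#' Each line is `name<TAB>description<TAB>gene1<TAB>gene2...`. Duplicate
#' genes within a set are removed with a warning; duplicate set names and
#' truncated lines are errors.
#'
#' @param path GMT file path.
#' @return named list of character gene vectors.
#' @export
parseGMT <- function(path) {
  lines <- readLines(path)
  lines <- lines[nzchar(lines)]
  parts <- strsplit(lines, "\t", fixed = TRUE)
  short <- which(lengths(parts) < 3L)
  if (length(short))
    stop("GMT line ", short[1L], " has fewer than 3 fields")
  nms <- vapply(parts, `[[`, character(1L), 1L)
  if (anyDuplicated(nms))
    stop("duplicate gene-set name: ", nms[duplicated(nms)][1L])
  sets <- lapply(parts, function(p) {
    g <- p[-(1:2)]
    u <- unique(g)
    if (length(u) < length(g))
      warning("duplicate genes within set '", p[1L], "' removed",
              call. = FALSE)
    u
  })
  names(sets) <- nms
  sets
}

#' Write gene sets to GMT
#' @param sets named list of character vectors.
#' @param path output path.
#' @param descriptions optional character descriptions, recycled.
#' @return `path`, invisibly.
#' @export
writeGMT <- function(sets, path, descriptions = "na") {
  descriptions <- rep_len(descriptions, length(sets))
  lines <- mapply(function(nm, de, genes)
    paste(c(nm, de, genes), collapse = "\t"),
    names(sets), descriptions, sets)
  writeLines(unname(lines), path)
  invisible(path)
}

#' Read a regions-by-genes expression table from TSV
#'
#' Header row of gene ids; first column `region_id` in atlas order.
#'
#' @param path file path.
#' @param atlas the [ParcelAtlas-class] fixing region order.
#' @return numeric matrix (regions x genes).
#' @export
loadExpression <- function(path, atlas) {
  d <- utils::read.delim(path, stringsAsFactors = FALSE, check.names = FALSE)
  if (names(d)[1L] != "region_id") stop("first column must be region_id")
  if (!identical(d$region_id, regionIds(atlas)))
    stop("expression rows must match atlas region order")
  m <- as.matrix(d[, -1L, drop = FALSE])
  rownames(m) <- d$region_id
  m
}

#' Write an expression matrix to TSV
#' @param expr regions-by-genes matrix with dimnames.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
writeExpression <- function(expr, path) {
  .writeTSV(cbind(data.frame(region_id = rownames(expr)),
                  as.data.frame(expr, check.names = FALSE)), path)
}
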