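## Internal helpers shared across modules.

#' Derive a child seed from a master seed
#'
#' Every stochastic stage of the pipeline draws its own seed from the master
#' seed and a stage tag, so stages can be re-run independently and adding a
#' stage never perturbs the streams of the others. The result is always a
#' valid 32-bit integer seed.
#'
#' @param seed master integer seed.
#' @param tag character stage tag.
#' @return integer seed, deterministic in `(seed, tag)`.
#' @export
childSeed <- function(seed, tag) {
  stopifnot(is.numeric(seed), length(seed) == 1L, is.character(tag))
  v <- utf8ToInt(tag)
  h <- sum(v * seq_along(v)) %% 100003L
  as.integer((abs(seed) %% 20000003L) * 100L + h) %% 2147483587L
}

## Great-circle distance matrix between rows of unit-vector matrices.
.greatCircle <- function(a, b = a) {
  d <- tcrossprod(a, b)
  acos(pmin(pmax(d, -1), 1))
}

## Column-wise Pearson correlation between paired columns of X and Y.
.pairedColCors <- function(x, y) {
  x <- sweep(x, 2L, colMeans(x))
  y <- sweep(y, 2L, colMeans(y))
  sx <- sqrt(colSums(x^2))
  sy <- sqrt(colSums(y^2))
  colSums(x * y) / (sx * sy)
}

## Uniform random rotation in SO(3) via QR with sign correction.
.randomRotation <- function() {
  m <- matrix(stats::rnorm(9L), 3L, 3L)
  qrm <- qr(m)
  q <- qr.Q(qrm)
  q <- q %*% diag(sign(diag(qr.R(qrm))))
  if (det(q) < 0) q[, 1L] <- -q[, 1L]
  q
}

.stopStage <- function(stage, expr) {
  tryCatch(expr, error = function(e) {
    stop(sprintf("pipeline stage '%s' failed: %s", stage, conditionMessage(e)),
         call. = FALSE)
  })
}

## write.table wrapper keeping full double precision for round-trips.
.writeTSV <- function(df, path, row.names = FALSE) {
  num <- vapply(df, is.double, logical(1L))
  df[num] <- lapply(df[num], function(x) sprintf("%.17g", x))
  utils::write.table(df, path, sep = "\t", quote = FALSE,
                     row.names = row.names, col.names = TRUE)
  invisible(path)
}
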