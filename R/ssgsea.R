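#' Single-sample gene set enrichment score
#'
#' Computes the rank-weighted ECDF enrichment score of one gene set in one
#' sample. Measured genes are sorted by decreasing expression (ties broken
#' deterministically by gene identifier); the gene at sorted position
#' \eqn{j} of \eqn{N} receives rank weight \eqn{w_j = (N - j + 1)^\alpha}.
#' The score is
#' \deqn{ES = \sum_{j=1}^{N} \left[ P_{in}(j) - P_{out}(j) \right]}
#' where \eqn{P_{in}(j)} is the weighted fraction of set members at or above
#' position \eqn{j} (weights normalized over all members) and
#' \eqn{P_{out}(j)} the unweighted fraction of non-members at or above
#' \eqn{j}. Genes with \code{NA} expression are excluded before ranking, so
#' every sample is scored on its own measured-gene universe.
#'
#' Internally the sum is evaluated in closed form from the member positions
#' \eqn{r_1, \dots, r_m}:
#' \deqn{ES = \frac{\sum_i (N - r_i + 1) w_{r_i}}{\sum_i w_{r_i}}
#'        - \frac{N(N+1)/2 - \sum_i (N - r_i + 1)}{N - m}}
#' which is algebraically identical to the cumulative-sum form above.
#'
#' @param expr named numeric vector of (log2) expression values for one
#'   sample; \code{NA} marks unmeasured genes.
#' @param geneSet character vector of member gene IDs.
#' @param alpha rank-weight exponent (default 0.25, the conventional
#'   single-sample GSEA weight).
#' @return A single numeric raw enrichment score.
#' @seealso [ssgseaMatrix()] to score a collection over a cohort,
#'   [normalizeScores()], [callEnriched()].
#' @export
ssgseaScore <- function(expr, geneSet, alpha = 0.25) {
  if (is.null(names(expr))) stop("'expr' must be a named vector of genes")
  expr <- expr[!is.na(expr)]
  n <- length(expr)
  if (n < 2L) stop("need at least 2 measured genes")
  inSet <- names(expr) %in% geneSet
  m <- sum(inSet)
  if (m == 0L || m == n)
    stop("degenerate gene set: set must intersect the measured genes ",
         "and be a proper subset of them")
  ord <- order(-expr, names(expr), method = "radix")
  r <- which(inSet[ord])            # member positions in sorted order
  tail <- n - r + 1                  # how many positions each member covers
  w <- tail^alpha
  sumPin <- sum(tail * w) / sum(w)
  sumPout <- (n * (n + 1) / 2 - sum(tail)) / (n - m)
  sumPin - sumPout
}

#' Score a gene-set collection across all samples of a cohort
#'
#' Applies [ssgseaScore()] to every (signature, sample) combination. Each
#' sample is scored on its own measured genes (\code{NA} entries dropped per
#' sample). Signatures that are degenerate for a sample (no member measured,
#' or the members exhaust the measured genes) yield \code{NA} in that cell.
#'
#' @param expr gene-by-sample numeric matrix (rownames = gene IDs) or a
#'   \linkS4class{SummarizedExperiment} whose first assay is such a matrix.
#' @param collection a \linkS4class{SignatureCollection}.
#' @param alpha rank-weight exponent passed to [ssgseaScore()].
#' @return Numeric signature-by-sample matrix of raw enrichment scores.
#' @export
ssgseaMatrix <- function(expr, collection, alpha = 0.25) {
  expr <- .asExprMatrix(expr)
  if (length(collection) == 0L) stop("empty signature collection")
  sets <- geneSets(collection)
  genes <- rownames(expr)
  setIdx <- lapply(sets, function(s) which(genes %in% s))
  out <- matrix(NA_real_, nrow = length(sets), ncol = ncol(expr),
                dimnames = list(names(sets), colnames(expr)))
  for (j in seq_len(ncol(expr))) {
    v <- expr[, j]
    measured <- which(!is.na(v))
    n <- length(measured)
    if (n < 2L) next
    vm <- v[measured]
    ord <- order(-vm, genes[measured], method = "radix")
    pos <- integer(length(genes))         # 0 = unmeasured
    pos[measured[ord]] <- seq_len(n)
    wAll <- (n - seq_len(n) + 1)^alpha
    totalTail <- n * (n + 1) / 2
    for (i in seq_along(setIdx)) {
      r <- pos[setIdx[[i]]]
      r <- r[r > 0L]
      m <- length(r)
      if (m == 0L || m == n) next         # degenerate for this sample
      tail <- n - r + 1
      w <- wAll[r]
      out[i, j] <- sum(tail * w) / sum(w) -
        (totalTail - sum(tail)) / (n - m)
    }
  }
  out
}

.asExprMatrix <- function(expr) {
  if (is(expr, "SummarizedExperiment"))
    expr <- SummarizedExperiment::assay(expr)
  expr <- as.matrix(expr)
  if (is.null(rownames(expr))) stop("expression matrix needs gene rownames")
  expr
}

#' Normalize raw enrichment scores to unit global range
#'
#' Divides every entry of the raw score matrix by the range
#' (max - min) over all finite entries of the whole matrix, so that after
#' normalization the global range equals 1. The denominator is global (one
#' rescaling per cohort run), which keeps the downstream absolute score
#' threshold comparable across signatures.
#'
#' @param raw numeric matrix of raw scores (\code{NA} entries preserved).
#' @return Matrix of the same shape, globally rescaled.
#' @export
normalizeScores <- function(raw) {
  fin <- raw[is.finite(raw)]
  if (length(fin) < 2L) stop("need at least 2 finite scores to normalize")
  rng <- max(fin) - min(fin)
  if (rng == 0) stop("cannot normalize a constant score matrix (zero range)")
  raw / rng
}

#' Call cohort-enriched signatures
#'
#' A signature is enriched when its normalized score is \code{>= scoreMin}
#' in at least a fraction \code{prevalenceMin} of cohort samples. \code{NA}
#' scores (degenerate signature/sample pairs) count as non-passing samples.
#'
#' @param normalized signature-by-sample matrix of normalized scores.
#' @param scoreMin absolute score threshold (default 0.5).
#' @param prevalenceMin minimum passing-sample fraction, inclusive
#'   (default 0.8).
#' @return An \linkS4class{EnrichmentResult}.
#' @export
callEnriched <- function(normalized, scoreMin = 0.5, prevalenceMin = 0.8) {
  stopifnot(is.matrix(normalized),
            scoreMin >= 0, prevalenceMin >= 0, prevalenceMin <= 1)
  enriched <- .enrichedCalls(normalized, scoreMin, prevalenceMin)
  names(enriched) <- rownames(normalized)
  new("EnrichmentResult", scores = normalized, enriched = enriched,
      scoreMin = scoreMin, prevalenceMin = prevalenceMin)
}

#' Drop samples with too few measured genes
#'
#' Sparse samples (e.g. single cells with heavy dropout) are excluded from
#' enrichment scoring when fewer than \code{minMeasured} genes carry a
#' non-missing value.
#'
#' @param expr gene-by-sample matrix or SummarizedExperiment; \code{NA}
#'   encodes "not measured".
#' @param minMeasured inclusive minimum measured-gene count (default 3000).
#' @return The input matrix restricted to retained sample columns.
#' @export
filterSparseSamples <- function(expr, minMeasured = 3000) {
  expr <- .asExprMatrix(expr)
  keep <- colSums(!is.na(expr)) >= minMeasured
  expr[, keep, drop = FALSE]
}

#' Remove cell-of-origin signatures from the tumor-enriched set
#'
#' Signatures enriched in the tumor cohort that are also enriched in its
#' cell of origin reflect the originating cell type rather than the
#' malignant transformation, and are excluded: the result is the set
#' difference tumor \\ origin.
#'
#' @param tumorEnriched,originEnriched character vectors of signature names.
#' @return Character vector of retained signature names.
#' @export
subtractOriginSignatures <- function(tumorEnriched, originEnriched) {
  setdiff(tumorEnriched, originEnriched)
}

#' Union of member genes over retained signatures
#'
#' @param retained character vector of signature names (must exist in
#'   \code{collection}).
#' @param collection a \linkS4class{SignatureCollection}.
#' @return A list with \code{genes} (character union) and \code{membership}
#'   (named list: gene -> signatures containing it).
#' @export
signatureGeneUnion <- function(retained, collection) {
  unknown <- setdiff(retained, names(collection))
  if (length(unknown))
    stop("unknown signature name(s): ", paste(unknown, collapse = ", "))
  sets <- geneSets(collection)[retained]
  genes <- as.character(unique(unlist(sets, use.names = FALSE)))
  membership <- lapply(stats::setNames(genes, genes), function(g)
    names(sets)[vapply(sets, function(s) g %in% s, logical(1))])
  list(genes = genes, membership = membership)
}
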