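#' Intersect peptide source genes with enriched-signature genes
#'
#' The candidate gene set is the intersection of the source genes of
#' tumor-exclusive peptides with the union of genes from the tumor-enriched
#' signatures (after cell-of-origin subtraction).
#'
#' @param sourceGenes character vector of peptide source genes.
#' @param signatureGenes character vector (the signature gene union).
#' @return Character vector of candidate genes.
#' @export
intersectCandidates <- function(sourceGenes, signatureGenes) {
  intersect(sourceGenes, signatureGenes)
}

#' Re-validate candidate membership in a second cohort
#'
#' After re-running enrichment on the validation cohort, a candidate gene is
#' retained if it belongs to at least one signature that is enriched there;
#' genes exclusively included in signatures that failed re-enrichment are
#' removed.
#'
#' @param candidates character vector of candidate genes.
#' @param validationEnriched character vector of signature names enriched in
#'   the validation cohort.
#' @param collection the \linkS4class{SignatureCollection} the signatures
#'   come from.
#' @return Character vector of retained candidates.
#' @export
revalidateMembership <- function(candidates, validationEnriched, collection) {
  keepGenes <- unique(unlist(geneSets(collection)[
    intersect(validationEnriched, names(collection))], use.names = FALSE))
  candidates[candidates %in% keepGenes]
}

#' Minimal expression threshold from a kernel density estimate
#'
#' Fits a Gaussian kernel density estimate (bandwidth by Silverman's rule of
#' thumb) to the distribution of per-gene mean log2 expression over the
#' validation tumors. Genome-wide mean expression is typically bimodal (a
#' non-expressed and an expressed mode); the threshold is placed at the
#' lowest density minimum between the two highest modes, separating the two.
#' If the density has no interior minimum between two modes the distribution
#' is treated as unimodal and no threshold is returned.
#'
#' @param meanExpr numeric vector of per-gene mean log2 expression
#'   (at least 2 distinct values).
#' @param n grid size of the density evaluation (default 512).
#' @return List with \code{threshold} (numeric, or \code{NA} under the
#'   no-threshold condition) and \code{density} (the \code{stats::density}
#'   fit).
#' @export
expressionThreshold <- function(meanExpr, n = 512) {
  meanExpr <- meanExpr[is.finite(meanExpr)]
  if (length(unique(meanExpr)) < 2L)
    stop("need at least 2 distinct values to estimate a density")
  d <- stats::density(meanExpr, bw = "nrd0", n = n)
  y <- d$y
  # interior local maxima and minima of the density grid
  curvature <- diff(sign(diff(y)))
  maxima <- which(curvature == -2) + 1L
  minima <- which(curvature == 2) + 1L
  if (length(maxima) < 2L || length(minima) == 0L)
    return(list(threshold = NA_real_, density = d))
  top2 <- maxima[order(y[maxima], decreasing = TRUE)][1:2]
  lo <- min(top2); hi <- max(top2)
  between <- minima[minima > lo & minima < hi]
  if (length(between) == 0L)
    return(list(threshold = NA_real_, density = d))
  valley <- between[which.min(y[between])]
  list(threshold = d$x[valley], density = d)
}

#' Tumor-versus-normal induction filter
#'
#' Tests each gene for positive induction in the validation tumors relative
#' to normal tissue, in both an unpaired analysis (all tumors versus all
#' normals, Welch two-sample t-test) and a paired analysis (matched
#' tumor/normal pairs, paired t-test). The log2 fold change is the mean
#' tumor minus mean normal log2 expression (paired: mean within-pair
#' difference). A gene passes when the fold change is positive and
#' \code{p < pMax} in both analyses.
#'
#' @param tumorExpr,normalExpr gene-by-sample log2 expression matrices with
#'   shared gene rownames; column names are sample IDs.
#' @param pairing data.frame with columns \code{tumor}, \code{normal} giving
#'   the matched sample IDs of each patient pair.
#' @param genes genes to test (default: all rows of \code{tumorExpr}).
#' @param pMax p-value threshold (default 0.05).
#' @return data.frame with one row per gene: \code{log2FCUnpaired},
#'   \code{pUnpaired}, \code{log2FCPaired}, \code{pPaired}, \code{pass}.
#'   Genes with fewer than 2 samples in any required group fail with
#'   \code{NA} statistics.
#' @export
inductionFilter <- function(tumorExpr, normalExpr, pairing,
                            genes = rownames(tumorExpr), pMax = 0.05) {
  stopifnot(all(c("tumor", "normal") %in% names(pairing)))
  tIdx <- match(pairing$tumor, colnames(tumorExpr))
  nIdx <- match(pairing$normal, colnames(normalExpr))
  if (anyNA(tIdx) || anyNA(nIdx))
    stop("pairing refers to samples absent from the expression matrices")
  out <- data.frame(gene = genes,
                    log2FCUnpaired = NA_real_, pUnpaired = NA_real_,
                    log2FCPaired = NA_real_, pPaired = NA_real_,
                    pass = FALSE, row.names = genes)
  for (g in genes) {
    tv <- tumorExpr[g, ]
    nv <- normalExpr[g, ]
    tv <- tv[!is.na(tv)]; nv <- nv[!is.na(nv)]
    dp <- tumorExpr[g, tIdx] - normalExpr[g, nIdx]
    dp <- dp[!is.na(dp)]
    if (length(tv) < 2L || length(nv) < 2L || length(dp) < 2L) next
    tu <- stats::t.test(tv, nv, var.equal = FALSE)
    tp <- stats::t.test(dp)
    out[g, "log2FCUnpaired"] <- mean(tv) - mean(nv)
    out[g, "pUnpaired"] <- tu$p.value
    out[g, "log2FCPaired"] <- mean(dp)
    out[g, "pPaired"] <- tp$p.value
    out[g, "pass"] <- out[g, "log2FCUnpaired"] > 0 &&
      out[g, "log2FCPaired"] > 0 &&
      tu$p.value < pMax && tp$p.value < pMax
  }
  out
}

#' Expression-stability (coefficient of variation) filter
#'
#' Per gene, the coefficient of variation is
#' \code{CV\% = 100 * sd / mean} of log2 expression across the validation
#' tumors. Genes with \code{CV\% >= cvMax} are removed; candidates with a
#' non-positive mean have an undefined CV and fail with a warning.
#'
#' @param tumorExpr gene-by-sample log2 expression matrix (>= 2 tumors).
#' @param genes genes to evaluate.
#' @param cvMax exclusive CV threshold in percent (default 10).
#' @return data.frame with columns \code{gene}, \code{cvPercent},
#'   \code{pass}.
#' @export
cvFilter <- function(tumorExpr, genes = rownames(tumorExpr), cvMax = 10) {
  if (ncol(tumorExpr) < 2L) stop("need at least 2 tumor samples")
  cv <- vapply(genes, function(g) {
    v <- tumorExpr[g, ]
    v <- v[!is.na(v)]
    mu <- mean(v)
    if (mu <= 0) return(NA_real_)
    100 * stats::sd(v) / mu
  }, numeric(1))
  if (anyNA(cv))
    warning(sum(is.na(cv)), " gene(s) with non-positive mean expression: ",
            "CV undefined, gene(s) fail the filter")
  data.frame(gene = genes, cvPercent = cv,
             pass = !is.na(cv) & cv < cvMax, row.names = genes)
}

#' Assemble the candidate ledger
#'
#' Materializes the full filter funnel as one table with a row per gene ever
#' considered (the source genes of tumor-exclusive peptides), every filter
#' outcome as a column, and \code{finalCandidate} as the conjunction of all
#' stage flags.
#'
#' @param sourceGenes character vector: genes with tumor-exclusive peptides.
#' @param peptidesByGene named list of supporting peptides per gene.
#' @param signatureGenes genes of the retained tumor-enriched signatures.
#' @param revalidated genes retained after validation-cohort re-enrichment.
#' @param meanExpr named per-gene mean log2 expression in validation tumors.
#' @param exprThreshold minimal expression threshold (\code{NA} disables the
#'   expression filter, every gene passes it).
#' @param induction data.frame from [inductionFilter()].
#' @param cv data.frame from [cvFilter()].
#' @return data.frame (the candidate ledger).
#' @export
assembleLedger <- function(sourceGenes, peptidesByGene, signatureGenes,
                           revalidated, meanExpr, exprThreshold,
                           induction, cv) {
  genes <- sort(sourceGenes)
  stray <- setdiff(c(rownames(induction), rownames(cv)), genes)
  if (length(stray))
    stop("gene namespace mismatch between stages: ",
         paste(utils::head(stray, 5), collapse = ", "))
  grab <- function(tab, col) {
    v <- tab[match(genes, rownames(tab)), col]
    v
  }
  led <- data.frame(
    gene = genes,
    hasExclusivePeptide = rep(TRUE, length(genes)),
    nSupportingPeptides = lengths(peptidesByGene[genes]),
    inEnrichedSignature = genes %in% signatureGenes,
    passedRevalidation = genes %in% revalidated,
    meanLog2Expression = unname(meanExpr[genes]),
    passedMinExpression = if (is.na(exprThreshold)) rep(TRUE, length(genes))
      else !is.na(meanExpr[genes]) & meanExpr[genes] >= exprThreshold,
    log2FCUnpaired = grab(induction, "log2FCUnpaired"),
    pUnpaired = grab(induction, "pUnpaired"),
    log2FCPaired = grab(induction, "log2FCPaired"),
    pPaired = grab(induction, "pPaired"),
    passedInduction = genes %in% rownames(induction)[induction$pass],
    cvPercent = grab(cv, "cvPercent"),
    passedCV = genes %in% rownames(cv)[cv$pass],
    row.names = genes)
  led$finalCandidate <- led$hasExclusivePeptide & led$inEnrichedSignature &
    led$passedRevalidation & led$passedMinExpression &
    led$passedInduction & led$passedCV
  led
}
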