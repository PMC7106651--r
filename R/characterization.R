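#' Methylation-expression association
#'
#' For every CpG mapped to a candidate gene, computes the Spearman
#' correlation of its beta value with the gene's log2 expression across the
#' shared tumor samples, the correlation p-value, and the mean beta
#' difference between tumors and normals. A gene is flagged as potentially
#' methylation-regulated when at least one of its CpGs is significantly
#' anticorrelated (\code{rho < rhoMax} and \code{p < pMax}); under
#' \code{aggregate = "all"} every mapped CpG must pass, under
#' \code{"best"} only the most anticorrelated CpG is evaluated. Genes with
#' no mapped CpG are unevaluable (flag \code{NA}, not \code{FALSE}).
#'
#' @param betaTumor,betaNormal CpG-by-sample beta matrices (values in
#'   \[0, 1\]); \code{betaNormal} may be \code{NULL} (beta difference then
#'   \code{NA}).
#' @param tumorExpr gene-by-sample log2 expression matrix; its columns are
#'   matched to \code{betaTumor} columns by name.
#' @param probeMap data.frame with columns \code{cpg}, \code{gene}.
#' @param genes genes to evaluate.
#' @param rhoMax Spearman threshold, exclusive (default -0.3).
#' @param pMax p-value threshold (default 0.05).
#' @param aggregate CpG-to-gene aggregation: \code{"any"} (default),
#'   \code{"all"} or \code{"best"}.
#' @return List with \code{geneFlags} (named logical, \code{NA} =
#'   unevaluable) and \code{cpgStats} (data.frame: cpg, gene, rho, p,
#'   betaDiff, pass).
#' @export
methylationAssociation <- function(betaTumor, betaNormal, tumorExpr,
                                   probeMap, genes,
                                   rhoMax = -0.3, pMax = 0.05,
                                   aggregate = c("any", "all", "best")) {
  aggregate <- match.arg(aggregate)
  stopifnot(all(c("cpg", "gene") %in% names(probeMap)))
  shared <- intersect(colnames(betaTumor), colnames(tumorExpr))
  if (length(shared) < 3L)
    stop("need at least 3 shared tumor samples between beta and expression")
  pm <- probeMap[probeMap$gene %in% genes &
                   probeMap$cpg %in% rownames(betaTumor), , drop = FALSE]
  stats <- data.frame(cpg = character(0), gene = character(0),
                      rho = numeric(0), p = numeric(0),
                      betaDiff = numeric(0), pass = logical(0))
  if (nrow(pm)) {
    rows <- lapply(seq_len(nrow(pm)), function(i) {
      cpg <- pm$cpg[i]; g <- pm$gene[i]
      b <- betaTumor[cpg, shared]
      e <- tumorExpr[g, shared]
      ok <- !is.na(b) & !is.na(e)
      if (sum(ok) < 3L)
        return(data.frame(cpg = cpg, gene = g, rho = NA_real_, p = NA_real_,
                          betaDiff = NA_real_, pass = FALSE))
      ct <- suppressWarnings(
        stats::cor.test(b[ok], e[ok], method = "spearman",
                        exact = sum(ok) < 10))
      bd <- if (is.null(betaNormal) || !cpg %in% rownames(betaNormal))
        NA_real_
      else mean(betaTumor[cpg, ], na.rm = TRUE) -
        mean(betaNormal[cpg, ], na.rm = TRUE)
      data.frame(cpg = cpg, gene = g, rho = unname(ct$estimate),
                 p = ct$p.value, betaDiff = bd,
                 pass = !is.na(ct$estimate) && ct$estimate < rhoMax &&
                   ct$p.value < pMax)
    })
    stats <- do.call(rbind, rows)
  }
  geneFlags <- vapply(genes, function(g) {
    s <- stats[stats$gene == g, , drop = FALSE]
    if (nrow(s) == 0L) return(NA)
    switch(aggregate,
           any = any(s$pass),
           all = all(s$pass),
           best = s$pass[which.min(s$rho)])
  }, logical(1))
  list(geneFlags = geneFlags, cpgStats = stats)
}

#' Somatic mutation summaries for candidate genes
#'
#' Per candidate gene: the number of distinct mutated patients and the
#' cohort frequency in percent (one decimal); plus the list of variant
#' identifiers shared by two or more patients.
#'
#' @param mutations data.frame with columns \code{gene}, \code{patient},
#'   \code{variant} (and optionally \code{proteinChange}, \code{class}).
#' @param genes candidate genes to summarize.
#' @param cohortSize number of patients with mutation data (>= 1).
#' @return List with \code{perGene} (data.frame: gene, nPatients,
#'   percent, maxFrequencyPercent attribute) and \code{sharedVariants}
#'   (character vector).
#' @export
mutationSummary <- function(mutations, genes, cohortSize) {
  if (cohortSize < 1) stop("'cohortSize' must be at least 1")
  mut <- mutations[mutations$gene %in% genes, , drop = FALSE]
  nPat <- vapply(genes, function(g)
    length(unique(mut$patient[mut$gene == g])), integer(1))
  perGene <- data.frame(gene = genes, nPatients = nPat,
                        percent = round(100 * nPat / cohortSize, 1),
                        row.names = genes)
  varPatients <- tapply(mutations$patient, mutations$variant,
                        function(p) length(unique(p)))
  shared <- names(varPatients)[varPatients >= 2]
  list(perGene = perGene,
       maxFrequencyPercent = if (length(nPat)) max(perGene$percent) else 0,
       sharedVariants = if (is.null(shared)) character(0) else shared)
}

#' Generalized log2 transform
#'
#' \code{glog2(x) = log2(x + sqrt(x^2 + 1))}: finite at zero
#' (\code{glog2(0) = 0}), strictly increasing, and asymptotically
#' \code{log2(x) + 1} for large \code{x}. Applied to absolute metabolite
#' quantifications before correlation analysis.
#'
#' @param x non-negative numeric vector or matrix.
#' @return Transformed values of the same shape.
#' @export
glog2 <- function(x) {
  if (any(x < 0, na.rm = TRUE)) stop("glog2 is defined for non-negative input")
  log2(x + sqrt(x^2 + 1))
}

#' Metabolite-class association of a candidate gene
#'
#' A gene is associated with a metabolite class when (i) at least a fraction
#' \code{memberFrac} of the class members correlate with the gene's
#' expression at Pearson \code{rho > rhoMin} with \code{p < pMax}, and (ii)
#' the median correlation over all class members is \code{>= rhoMin}. Both
#' boundaries are inclusive for the member fraction and the median.
#'
#' @param geneExpr named numeric vector: the gene's log2 expression over the
#'   shared samples.
#' @param abundance metabolite-by-sample matrix (glog2 scale); columns
#'   matched to \code{names(geneExpr)} by name.
#' @param classMap data.frame with columns \code{metabolite}, \code{class}.
#' @param rhoMin correlation threshold (default 0.3).
#' @param pMax p-value threshold (default 0.05).
#' @param memberFrac minimum passing-member fraction, inclusive
#'   (default 0.25).
#' @return data.frame with one row per class: \code{class}, \code{n},
#'   \code{fracPassing}, \code{medianRho}, \code{minRho}, \code{maxRho},
#'   \code{associated}.
#' @export
metaboliteAssociation <- function(geneExpr, abundance, classMap,
                                  rhoMin = 0.3, pMax = 0.05,
                                  memberFrac = 0.25) {
  .groupAssociation(geneExpr, abundance, classMap$metabolite, classMap$class,
                    rhoMin = rhoMin, pMax = pMax, memberFrac = memberFrac,
                    fracStrict = FALSE, requireMedian = TRUE,
                    groupKind = "class")
}

#' Immune-marker process association of a candidate gene
#'
#' A gene is associated with an immuno-oncological process when strictly
#' more than \code{memberFrac} of the process markers correlate with the
#' gene's expression at Pearson \code{rho > rhoMin} with \code{p < 0.05}.
#' No median criterion applies, and a gene may associate with several
#' processes (markers can belong to more than one group).
#'
#' @param geneExpr named numeric vector of the gene's expression over the
#'   shared samples.
#' @param npx marker-by-sample NPX matrix; columns matched by name.
#' @param processMap data.frame with columns \code{marker}, \code{process}.
#' @param rhoMin correlation threshold (default 0.3).
#' @param pMax p-value threshold (default 0.05).
#' @param memberFrac passing-marker fraction, strict lower bound
#'   (default 0.25).
#' @return data.frame as in [metaboliteAssociation()] (without the median
#'   criterion entering the call).
#' @export
markerAssociation <- function(geneExpr, npx, processMap,
                              rhoMin = 0.3, pMax = 0.05, memberFrac = 0.25) {
  .groupAssociation(geneExpr, npx, processMap$marker, processMap$process,
                    rhoMin = rhoMin, pMax = pMax, memberFrac = memberFrac,
                    fracStrict = TRUE, requireMedian = FALSE,
                    groupKind = "process")
}

.groupAssociation <- function(geneExpr, mat, members, groups, rhoMin, pMax,
                              memberFrac, fracStrict, requireMedian,
                              groupKind) {
  shared <- intersect(names(geneExpr), colnames(mat))
  if (length(shared) < 3L) stop("need at least 3 shared samples")
  e <- geneExpr[shared]
  res <- lapply(split(as.character(members), as.character(groups)),
                function(mem) {
    mem <- intersect(mem, rownames(mat))
    if (length(mem) == 0L) return(NULL)
    rho <- numeric(length(mem)); p <- numeric(length(mem))
    for (i in seq_along(mem)) {
      v <- mat[mem[i], shared]
      ok <- !is.na(v) & !is.na(e)
      if (sum(ok) < 3L) { rho[i] <- NA; p[i] <- NA; next }
      ct <- stats::cor.test(e[ok], v[ok], method = "pearson")
      rho[i] <- unname(ct$estimate); p[i] <- ct$p.value
    }
    passing <- !is.na(rho) & rho > rhoMin & !is.na(p) & p < pMax
    frac <- mean(passing)
    med <- stats::median(rho, na.rm = TRUE)
    fracOK <- if (fracStrict) frac > memberFrac else frac >= memberFrac
    data.frame(n = length(mem), fracPassing = frac, medianRho = med,
               minRho = min(rho, na.rm = TRUE),
               maxRho = max(rho, na.rm = TRUE),
               associated = fracOK && (!requireMedian || med >= rhoMin))
  })
  empty <- names(res)[vapply(res, is.null, logical(1))]
  if (length(empty))
    warning("skipping ", groupKind, " group(s) with no measured members: ",
            paste(empty, collapse = ", "))
  res <- res[!vapply(res, is.null, logical(1))]
  out <- do.call(rbind, res)
  out <- cbind(data.frame(group = names(res)), out)
  rownames(out) <- NULL
  out
}

#' Two-group comparison of per-sample scores
#'
#' Compares a per-sample score (e.g. an immune-infiltration enrichment
#' score) between two groups of samples -- typically peptide-positive versus
#' peptide-negative tumors -- with a two-sided Wilcoxon rank-sum test, and
#' reports the direction of the median difference.
#'
#' @param scores named numeric vector of per-sample scores.
#' @param group logical or two-level factor over the same samples
#'   (\code{TRUE}/first level = positive group).
#' @param test \code{"wilcoxon"} (default) or \code{"t"}.
#' @return List with \code{p}, \code{direction} (sign of median(positive) -
#'   median(negative)) and \code{medianDifference}.
#' @export
twoGroupScoreTest <- function(scores, group, test = c("wilcoxon", "t")) {
  test <- match.arg(test)
  if (is.factor(group) || is.character(group))
    group <- group == levels(factor(group))[1]
  a <- scores[group]; b <- scores[!group]
  if (length(a) == 0L || length(b) == 0L)
    stop("both groups must be non-empty")
  p <- if (test == "wilcoxon")
    suppressWarnings(stats::wilcox.test(a, b, exact = NULL)$p.value)
  else stats::t.test(a, b)$p.value
  md <- stats::median(a) - stats::median(b)
  list(p = p, direction = sign(md), medianDifference = md)
}

#' Pooled standard deviation over replicate experiments
#'
#' \code{sqrt((sd1^2 + ... + sdn^2) / n)}: the root mean square of the
#' per-replicate standard deviations.
#'
#' @param sds numeric vector of replicate standard deviations (all >= 0).
#' @return Single numeric pooled value.
#' @export
pooledSD <- function(sds) {
  if (length(sds) == 0L) stop("need at least one standard deviation")
  if (any(sds < 0)) stop("standard deviations must be non-negative")
  sqrt(mean(sds^2))
}

#' Benjamini-Hochberg adjusted p-values
#'
#' Step-up false-discovery-rate adjustment (delegates to
#' \code{stats::p.adjust(method = "BH")} after a domain check).
#'
#' @param p numeric vector of raw p-values in \[0, 1\].
#' @return Adjusted p-values, capped at 1.
#' @export
bhAdjust <- function(p) {
  if (any(is.na(p)) || any(p < 0) || any(p > 1))
    stop("p-values must lie in [0, 1]")
  stats::p.adjust(p, method = "BH")
}
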