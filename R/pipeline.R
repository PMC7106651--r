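#' Pipeline thresholds
#'
#' Collects every tunable threshold of the candidate-selection workflow,
#' with the workflow's standard values as defaults: PSM FDR 0.05 at rank 1
#' with class-specific length windows (8-12 / 9-25), ligand predictor
#' criteria (percentile rank < 2, affinity <= 500 nM, motif fraction >=
#' 0.6), tumor exclusivity in >= 3 tumors, enrichment score >= 0.5 in >=
#' 80\% of samples, >= 3000 measured genes for sparse samples, induction
#' p < 0.05, CV < 10\%, methylation Spearman rho < -0.3, association
#' Pearson rho > 0.3 with member fraction 0.25.
#'
#' @param fdrMax,classILengths,classIILengths PSM filter thresholds.
#' @param rankMax,affinityMax,motifMin ligand-call thresholds.
#' @param minTumors tumor-exclusivity threshold.
#' @param alpha ssGSEA rank-weight exponent.
#' @param scoreMin,prevalenceMin enrichment-call thresholds.
#' @param minMeasured sparse-sample filter (single-cell data).
#' @param pMax induction-test p-value threshold.
#' @param cvMax CV threshold in percent (exclusive).
#' @param rhoMaxMethylation Spearman threshold for methylation regulation.
#' @param rhoMin,memberFrac association-rule thresholds.
#' @param manualExpressionThreshold optional override used when the mean
#'   expression density has no interior minimum (\code{NA}: use the KDE
#'   threshold, or no expression filter if none is found).
#' @return A list of class \code{"PipelineConfig"}.
#' @export
pipelineConfig <- function(fdrMax = 0.05,
                           classILengths = c(8L, 12L),
                           classIILengths = c(9L, 25L),
                           rankMax = 2, affinityMax = 500, motifMin = 0.6,
                           minTumors = 3,
                           alpha = 0.25,
                           scoreMin = 0.5, prevalenceMin = 0.8,
                           minMeasured = 3000,
                           pMax = 0.05,
                           cvMax = 10,
                           rhoMaxMethylation = -0.3,
                           rhoMin = 0.3, memberFrac = 0.25,
                           manualExpressionThreshold = NA_real_) {
  cfg <- as.list(environment())
  inRange <- function(f, lo, hi)
    if (cfg[[f]] < lo || cfg[[f]] > hi)
      stop(sprintf("threshold '%s' outside its valid range [%g, %g]",
                   f, lo, hi), call. = FALSE)
  inRange("fdrMax", 0, 1); inRange("prevalenceMin", 0, 1)
  inRange("memberFrac", 0, 1); inRange("pMax", 0, 1)
  if (cfg$minTumors < 1) stop("threshold 'minTumors' must be at least 1")
  structure(cfg, class = "PipelineConfig")
}

#' Build a peptide detection matrix from filtered observations
#'
#' Collapses an observation table (one row per detection event) to unique
#' (sequence, HLA class) peptide rows over the full sample panel; source
#' proteins are unioned over a peptide's observations.
#'
#' @param observations filtered observation data.frame (see [filterPSM()]),
#'   with \code{sourceProteins} as \code{";"}-separated accessions.
#' @param samples data.frame with columns \code{sampleId},
#'   \code{tissueClass}, \code{patientId}; defines the matrix columns,
#'   including samples without any detection.
#' @return A \linkS4class{PeptideDetection}.
#' @export
detectionFromObservations <- function(observations, samples) {
  .checkObsColumns(observations, c("sequence", "hlaClass", "sampleId"))
  stopifnot(all(c("sampleId", "tissueClass") %in% names(samples)))
  key <- paste0(observations$sequence, "_", observations$hlaClass)
  peps <- !duplicated(key)
  pepKey <- key[peps]
  m <- matrix(FALSE, nrow = length(pepKey), ncol = nrow(samples),
              dimnames = list(pepKey, samples$sampleId))
  sIdx <- match(observations$sampleId, samples$sampleId)
  if (anyNA(sIdx))
    stop("observation sample(s) missing from the sample table: ",
         paste(unique(observations$sampleId[is.na(sIdx)])[1:5],
               collapse = ", "))
  m[cbind(match(key, pepKey), sIdx)] <- TRUE
  prots <- if ("sourceProteins" %in% names(observations))
    lapply(split(observations$sourceProteins, match(key, pepKey)),
           function(x) unique(unlist(strsplit(x, ";", fixed = TRUE))))
  else NULL
  if (!is.null(prots)) prots <- prots[as.character(seq_along(pepKey))]
  PeptideDetection(m,
                   sequence = observations$sequence[peps],
                   hlaClass = observations$hlaClass[peps],
                   tissueClass = samples$tissueClass,
                   patientId = if ("patientId" %in% names(samples))
                     samples$patientId else NA_character_,
                   sourceProteins = prots)
}

#' Run the full candidate-selection pipeline on a cohort bundle
#'
#' Executes the stages in order: PSM filtering and ligand annotation;
#' tumor-exclusive peptide calling and source-gene mapping; discovery-cohort
#' enrichment; cell-of-origin enrichment and signature subtraction;
#' intersection of peptide source genes with signature genes;
#' validation-cohort re-enrichment; minimal-expression, induction and CV
#' filters; and multi-omic characterization of the final candidates. The
#' run is a pure function of (inputs, thresholds): repeated runs are
#' identical.
#'
#' @param bundle a \code{CohortBundle} from [simulateCohort()] or an
#'   equivalent list read with [readCohort()].
#' @param config a [pipelineConfig()].
#' @param characterize run the characterization stage (default TRUE).
#' @param verbose print per-stage survivor counts.
#' @return A list with \code{ledger} (the candidate table),
#'   \code{finalCandidates}, \code{stageCounts}, \code{purity},
#'   \code{expressionThreshold}, \code{enrichment} (discovery / origin /
#'   validation \linkS4class{EnrichmentResult}s) and
#'   \code{characterization}.
#' @export
runPipeline <- function(bundle, config = pipelineConfig(),
                        characterize = TRUE, verbose = FALSE) {
  stopifnot(inherits(config, "PipelineConfig"))
  say <- function(...) if (verbose) message(sprintf(...))
  counts <- c()
  note <- function(stage, n) {
    counts[[stage]] <<- n
    say("%-24s %d", stage, n)
  }

  ## --- ligandome ---
  obs <- filterPSM(bundle$observations, fdrMax = config$fdrMax,
                   classILengths = config$classILengths,
                   classIILengths = config$classIILengths)
  ligand <- callLigands(obs, rankMax = config$rankMax,
                        affinityMax = config$affinityMax,
                        motifMin = config$motifMin)
  purity <- samplePurity(obs, ligand)
  det <- detectionFromObservations(obs[ligand, , drop = FALSE],
                                   bundle$ligandomeSamples)
  note("filteredObservations", nrow(obs))
  exclusive <- tumorExclusivePeptides(det, minTumors = config$minTumors)
  note("exclusivePeptides", length(exclusive))
  mapping <- peptidesToGenes(det, exclusive, bundle$proteinToGene)
  sourceGenes <- mapping$union
  note("sourceGenes", length(sourceGenes))

  ## --- discovery + origin enrichment ---
  rawD <- ssgseaMatrix(bundle$discoveryExpr, bundle$signatures,
                       alpha = config$alpha)
  enrD <- callEnriched(normalizeScores(rawD), config$scoreMin,
                       config$prevalenceMin)
  tumorEnriched <- enrichedSignatures(enrD)
  note("tumorEnrichedSignatures", length(tumorEnriched))

  originKept <- filterSparseSamples(bundle$originExpr, config$minMeasured)
  enrO <- if (ncol(originKept) > 0) {
    rawO <- ssgseaMatrix(originKept, bundle$signatures, alpha = config$alpha)
    callEnriched(normalizeScores(rawO), config$scoreMin,
                 config$prevalenceMin)
  } else NULL
  originEnriched <- if (is.null(enrO)) character(0)
  else enrichedSignatures(enrO)
  retained <- subtractOriginSignatures(tumorEnriched, originEnriched)
  note("retainedSignatures", length(retained))
  sgu <- signatureGeneUnion(retained, bundle$signatures)
  note("signatureGenes", length(sgu$genes))

  candidates <- intersectCandidates(sourceGenes, sgu$genes)
  note("intersectedCandidates", length(candidates))

  ## --- validation cohort ---
  valCD <- colData(bundle$validationExpr)
  valMat <- SummarizedExperiment::assay(bundle$validationExpr)
  valTumor <- valMat[, valCD$tissueClass == "tumor", drop = FALSE]
  valNormal <- valMat[, valCD$tissueClass != "tumor", drop = FALSE]

  rawV <- ssgseaMatrix(valTumor, bundle$signatures, alpha = config$alpha)
  enrV <- callEnriched(normalizeScores(rawV), config$scoreMin,
                       config$prevalenceMin)
  valEnriched <- intersect(enrichedSignatures(enrV), retained)
  revalidated <- revalidateMembership(candidates, valEnriched,
                                      bundle$signatures)
  note("revalidatedCandidates", length(revalidated))

  meanExpr <- rowMeans(valTumor, na.rm = TRUE)
  thr <- if (!is.na(config$manualExpressionThreshold))
    config$manualExpressionThreshold
  else expressionThreshold(meanExpr)$threshold
  candExpr <- if (is.na(thr)) revalidated
  else revalidated[!is.na(meanExpr[revalidated]) &
                     meanExpr[revalidated] >= thr]
  note("passedMinExpression", length(candExpr))

  induction <- if (length(candExpr))
    inductionFilter(valTumor, valNormal, bundle$pairing,
                    genes = candExpr, pMax = config$pMax)
  else data.frame(gene = character(0), log2FCUnpaired = numeric(0),
                  pUnpaired = numeric(0), log2FCPaired = numeric(0),
                  pPaired = numeric(0), pass = logical(0))
  candInd <- rownames(induction)[induction$pass]
  note("passedInduction", length(candInd))

  cv <- if (length(candInd)) cvFilter(valTumor, genes = candInd,
                                      cvMax = config$cvMax)
  else data.frame(gene = character(0), cvPercent = numeric(0),
                  pass = logical(0))
  final <- rownames(cv)[cv$pass]
  note("finalCandidates", length(final))

  ledger <- assembleLedger(sourceGenes, mapping$peptidesByGene, sgu$genes,
                           revalidated, meanExpr, thr, induction, cv)

  ## --- characterization of final candidates ---
  chr <- NULL
  if (characterize && length(final)) {
    meth <- methylationAssociation(
      bundle$methylation$betaTumor, bundle$methylation$betaNormal,
      valTumor, bundle$methylation$probeMap, final,
      rhoMax = config$rhoMaxMethylation, pMax = config$pMax)
    mut <- mutationSummary(bundle$mutations, final,
                           bundle$mutationCohortSize)
    metab <- glog2(bundle$metabolites$abundance)
    metClasses <- lapply(stats::setNames(final, final), function(g) {
      tab <- metaboliteAssociation(valTumor[g, ], metab,
                                   bundle$metabolites$classMap,
                                   rhoMin = config$rhoMin,
                                   pMax = config$pMax,
                                   memberFrac = config$memberFrac)
      tab$group[tab$associated]
    })
    mrkProcs <- lapply(stats::setNames(final, final), function(g) {
      tab <- markerAssociation(valTumor[g, ], bundle$markers$npx,
                               bundle$markers$processMap,
                               rhoMin = config$rhoMin, pMax = config$pMax,
                               memberFrac = config$memberFrac)
      tab$group[tab$associated]
    })
    chr <- list(methylation = meth, mutations = mut,
                metaboliteClasses = metClasses,
                markerProcesses = mrkProcs)
    ledger$methylationRegulated <- NA
    ledger[final, "methylationRegulated"] <- meth$geneFlags[final]
    ledger$mutatedPatients <- NA_integer_
    ledger[final, "mutatedPatients"] <- mut$perGene[final, "nPatients"]
    ledger$mutationPercent <- NA_real_
    ledger[final, "mutationPercent"] <- mut$perGene[final, "percent"]
    ledger$metaboliteClasses <- NA_character_
    ledger[final, "metaboliteClasses"] <-
      vapply(metClasses[final], paste, character(1), collapse = ",")
    ledger$markerProcesses <- NA_character_
    ledger[final, "markerProcesses"] <-
      vapply(mrkProcs[final], paste, character(1), collapse = ",")
  }

  list(ledger = ledger, finalCandidates = final,
       stageCounts = unlist(counts), purity = purity,
       expressionThreshold = thr,
       enrichment = list(discovery = enrD, origin = enrO, validation = enrV),
       characterization = chr)
}

#' Recovery of planted candidates by a pipeline run
#'
#' @param result output of [runPipeline()].
#' @param truth the \code{$truth} element of the simulated bundle.
#' @return List with \code{sensitivity}, \code{precision}, \code{nFinal},
#'   \code{nPlanted}. With nothing planted and nothing called, both rates
#'   are 1; precision is \code{NaN} if candidates were called from an empty
#'   truth.
#' @export
recoveryStats <- function(result, truth) {
  planted <- truth$plantedCandidateGenes
  final <- result$finalCandidates
  tp <- length(intersect(final, planted))
  sens <- if (length(planted) == 0L) 1 else tp / length(planted)
  prec <- if (length(final) == 0L) {
    if (length(planted) == 0L) 1 else 0
  } else tp / length(final)
  list(sensitivity = sens, precision = prec,
       nFinal = length(final), nPlanted = length(planted))
}
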