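#' Configuration of the synthetic multi-omics cohort
#'
#' Builds and validates the parameter set of the cohort generator. Defaults
#' emulate a mid-sized immunopeptidomics study: a discovery tumor cohort
#' with paired adjacent tissue and a benign-tissue comparison pool, an
#' independent validation cohort with paired normals, a sparse
#' cell-of-origin single-cell matrix, a gene-set collection with a small
#' number of planted tumor programs, and matched methylation, mutation,
#' metabolite and immune-marker data with planted associations.
#'
#' @param seed integer seed; fully determines the generated bundle.
#' @param nTumors tumors per cohort (discovery and validation).
#' @param nPairedNormals validation patients with a paired normal.
#' @param nBenignSamples benign-tissue samples in the ligandome comparison
#'   pool (85\% benign organ, 15\% leukocyte preparations).
#' @param nOriginCells cells in the cell-of-origin single-cell matrix.
#' @param nGenes size of the gene universe.
#' @param nSignatures gene sets in the collection.
#' @param signatureSizeRange inclusive (min, max) set sizes.
#' @param nPlantedCandidates number of planted candidate genes.
#' @param nPlantedSignatures planted tumor-program signatures (every planted
#'   candidate belongs to at least one of them).
#' @param nOriginSignatures signatures shifted in the origin cells, of which
#'   \code{nSharedOriginSignatures} are also shifted in tumors (and are
#'   therefore subtracted by the pipeline).
#' @param nSharedOriginSignatures see above.
#' @param pathwayShift additive mean shift (log2 units) on the member genes
#'   of a shifted signature in the affected samples.
#' @param inductionShift extra tumor-versus-normal induction (log2 units) of
#'   the planted candidate genes.
#' @param peptideDetectionProbTumor per-tumor detection probability of a
#'   planted peptide.
#' @param peptideBackgroundProb per-sample detection probability of a
#'   background peptide (any tissue).
#' @param nBackgroundPeptides background peptides in the universe.
#' @param peptidesPerCandidate planted peptides per candidate gene (two
#'   class I 9-mers and the rest class II 15-mers).
#' @param binderProb probability that a background peptide carries binding
#'   annotations for the sample allotypes. Planted peptides are always
#'   binders; the default is calibrated so that the cohort-mean ligand
#'   purity is approximately 0.90 under the default detection rates.
#' @param methylationEffect beta-scale effect size of the planted
#'   methylation regulation (tumor-normal beta difference; also scales the
#'   anticorrelation slope).
#' @param mutationRate per-gene per-patient somatic mutation probability.
#' @param nMetabolites metabolites (split over 9 classes).
#' @param nMarkers immune-marker proteins (split over 6 process groups).
#' @param noiseSD residual log2 expression standard deviation.
#' @return A validated list of class \code{"CohortConfig"}.
#' @export
cohortConfig <- function(seed = 1L,
                         nTumors = 60L,
                         nPairedNormals = 40L,
                         nBenignSamples = 200L,
                         nOriginCells = 120L,
                         nGenes = 5000L,
                         nSignatures = 300L,
                         signatureSizeRange = c(20L, 60L),
                         nPlantedCandidates = 20L,
                         nPlantedSignatures = 8L,
                         nOriginSignatures = 5L,
                         nSharedOriginSignatures = 3L,
                         pathwayShift = 3,
                         inductionShift = 1,
                         peptideDetectionProbTumor = 0.6,
                         peptideBackgroundProb = 0.05,
                         nBackgroundPeptides = 800L,
                         peptidesPerCandidate = 3L,
                         binderProb = 0.89,
                         methylationEffect = 0.4,
                         mutationRate = 0.002,
                         nMetabolites = 90L,
                         nMarkers = 48L,
                         noiseSD = 0.5) {
  cfg <- list(seed = seed, nTumors = nTumors,
              nPairedNormals = nPairedNormals,
              nBenignSamples = nBenignSamples, nOriginCells = nOriginCells,
              nGenes = nGenes, nSignatures = nSignatures,
              signatureSizeRange = signatureSizeRange,
              nPlantedCandidates = nPlantedCandidates,
              nPlantedSignatures = nPlantedSignatures,
              nOriginSignatures = nOriginSignatures,
              nSharedOriginSignatures = nSharedOriginSignatures,
              pathwayShift = pathwayShift, inductionShift = inductionShift,
              peptideDetectionProbTumor = peptideDetectionProbTumor,
              peptideBackgroundProb = peptideBackgroundProb,
              nBackgroundPeptides = nBackgroundPeptides,
              peptidesPerCandidate = peptidesPerCandidate,
              binderProb = binderProb,
              methylationEffect = methylationEffect,
              mutationRate = mutationRate, nMetabolites = nMetabolites,
              nMarkers = nMarkers, noiseSD = noiseSD)
  .configError <- function(field, why)
    stop(sprintf("invalid configuration field '%s': %s", field, why),
         call. = FALSE)
  counts <- c("nTumors", "nPairedNormals", "nBenignSamples", "nOriginCells",
              "nGenes", "nSignatures", "nBackgroundPeptides",
              "nMetabolites", "nMarkers")
  for (f in counts)
    if (!is.numeric(cfg[[f]]) || length(cfg[[f]]) != 1L || cfg[[f]] < 1)
      .configError(f, "must be a positive count")
  for (f in c("nPlantedCandidates", "nPlantedSignatures",
              "nOriginSignatures", "nSharedOriginSignatures",
              "peptidesPerCandidate"))
    if (!is.numeric(cfg[[f]]) || cfg[[f]] < 0)
      .configError(f, "must be a non-negative count")
  probs <- c("peptideDetectionProbTumor", "peptideBackgroundProb",
             "binderProb", "mutationRate")
  for (f in probs)
    if (!is.numeric(cfg[[f]]) || cfg[[f]] < 0 || cfg[[f]] > 1)
      .configError(f, "must be a probability in [0, 1]")
  if (cfg$nPlantedCandidates > cfg$nGenes)
    .configError("nPlantedCandidates", "cannot exceed nGenes")
  if (cfg$nPairedNormals > cfg$nTumors)
    .configError("nPairedNormals", "cannot exceed nTumors")
  if (length(cfg$signatureSizeRange) != 2L ||
      cfg$signatureSizeRange[1] < 2 ||
      cfg$signatureSizeRange[2] < cfg$signatureSizeRange[1])
    .configError("signatureSizeRange", "must be an increasing (min, max) pair with min >= 2")
  if (cfg$signatureSizeRange[2] >= cfg$nGenes)
    .configError("signatureSizeRange", "maximum size must be below nGenes")
  if (cfg$nSharedOriginSignatures > cfg$nOriginSignatures)
    .configError("nSharedOriginSignatures", "cannot exceed nOriginSignatures")
  if (cfg$nPlantedSignatures + cfg$nOriginSignatures > cfg$nSignatures)
    .configError("nPlantedSignatures",
                 "planted plus origin signatures cannot exceed nSignatures")
  if (cfg$nPlantedCandidates > 0 && cfg$nPlantedSignatures == 0)
    .configError("nPlantedSignatures",
                 "need at least one planted signature to host candidates")
  if (!is.numeric(cfg$noiseSD) || cfg$noiseSD <= 0)
    .configError("noiseSD", "must be positive")
  if (!is.numeric(cfg$methylationEffect) || cfg$methylationEffect < 0 ||
      cfg$methylationEffect > 1)
    .configError("methylationEffect", "must be a beta-scale effect in [0, 1]")
  structure(cfg, class = "CohortConfig")
}

.AA <- strsplit("ACDEFGHIKLMNPQRSTVWY", "")[[1]]

.randomPeptides <- function(n, len, existing = character(0)) {
  out <- character(0)
  while (length(out) < n) {
    need <- n - length(out)
    cand <- vapply(seq_len(need), function(i)
      paste(sample(.AA, len, replace = TRUE), collapse = ""), character(1))
    cand <- setdiff(unique(cand), c(existing, out))
    out <- c(out, cand)
  }
  out
}

#' Generate a random gene-set collection with planted sets
#'
#' Draws \code{nSignatures} overlapping gene sets from a gene universe with
#' sizes uniform in \code{sizeRange}. Sets listed in \code{plantedMembers}
#' have those members forced in (padded with random genes from
#' \code{fillPool}) and receive the collection label \code{"planted"};
#' the remaining sets get labels drawn from MSigDB-like collection names.
#'
#' @param genes character gene universe.
#' @param nSignatures number of sets.
#' @param sizeRange inclusive (min, max) set sizes (max below
#'   \code{length(genes)}).
#' @param plantedMembers named list: signature name -> forced member genes.
#'   Names must be a subset of the generated signature names
#'   \code{"SIG0001"...}.
#' @param fillPool genes used to pad planted sets (default: whole universe).
#' @return A \linkS4class{SignatureCollection}.
#' @export
simulateSignatures <- function(genes, nSignatures, sizeRange,
                               plantedMembers = list(),
                               fillPool = genes) {
  if (sizeRange[2] >= length(genes))
    stop("invalid configuration field 'signatureSizeRange': ",
         "maximum size must be below the gene universe size")
  nm <- sprintf("SIG%04d", seq_len(nSignatures))
  unknown <- setdiff(names(plantedMembers), nm)
  if (length(unknown))
    stop("planted signature name(s) outside the collection: ",
         paste(unknown, collapse = ", "))
  pool <- c("hallmark", "kegg", "reactome", "biocarta", "c4", "c6", "immune")
  labels <- sample(pool, nSignatures, replace = TRUE)
  names(labels) <- nm
  sizes <- sizeRange[1] +
    sample.int(sizeRange[2] - sizeRange[1] + 1L, nSignatures,
               replace = TRUE) - 1L
  sets <- vector("list", nSignatures)
  names(sets) <- nm
  for (i in seq_len(nSignatures)) {
    s <- nm[i]
    if (s %in% names(plantedMembers)) {
      forced <- unique(plantedMembers[[s]])
      pad <- max(sizes[i] - length(forced), 0L)
      sets[[i]] <- c(forced,
                     sample(setdiff(fillPool, forced), pad))
      labels[s] <- "planted"
    } else {
      sets[[i]] <- sample(genes, sizes[i])
    }
  }
  SignatureCollection(sets, labels)
}

#' Generate a synthetic multi-omics cohort with planted ground truth
#'
#' Produces every input the candidate-selection pipeline consumes --
#' peptide observations with predictor annotations, a protein-to-gene map,
#' discovery / validation / cell-of-origin expression matrices, a gene-set
#' collection, methylation, mutation, metabolite and immune-marker tables --
#' plus a truth object recording what was planted, so pipeline recovery can
#' be measured. Identical configurations produce identical bundles; the RNG
#' state of the session is restored on exit.
#'
#' Planted candidate genes have tumor-exclusive peptides detected in
#' multiple tumors and in no benign tissue, belong to tumor-program
#' signatures whose member genes are shifted upward in every tumor sample of
#' both cohorts, are positively induced relative to paired normals, and have
#' a low expression coefficient of variation across validation tumors.
#'
#' @param config a \code{\link{cohortConfig}} object.
#' @return A list of class \code{"CohortBundle"}; see the package vignette
#'   for the element-by-element description. The planted truth is in
#'   \code{$truth}.
#' @export
simulateCohort <- function(config = cohortConfig()) {
  if (!inherits(config, "CohortConfig"))
    config <- do.call(cohortConfig, as.list(config))
  if (!exists(".Random.seed", envir = globalenv())) runif(1)
  oldSeed <- get(".Random.seed", envir = globalenv())
  on.exit(assign(".Random.seed", oldSeed, envir = globalenv()))
  set.seed(config$seed, kind = "Mersenne-Twister")
  cfg <- config

  genes <- sprintf("G%05d", seq_len(cfg$nGenes))
  ## bimodal baseline: a non-expressed and an expressed mode
  lowMode <- stats::runif(cfg$nGenes) < 0.35
  baseline <- ifelse(lowMode, stats::rnorm(cfg$nGenes, 2.5, 0.8),
                     stats::rnorm(cfg$nGenes, 8.0, 1.2))
  names(baseline) <- genes
  expressed <- genes[!lowMode & baseline >= 6]

  ## planted candidates: well-expressed genes
  candidatePool <- genes[!lowMode & baseline >= 7.5 & baseline <= 9]
  candidates <- sort(sample(candidatePool, cfg$nPlantedCandidates))

  ## signature roles
  nm <- sprintf("SIG%04d", seq_len(cfg$nSignatures))
  plantedSigs <- if (cfg$nPlantedSignatures > 0)
    nm[seq_len(cfg$nPlantedSignatures)] else character(0)
  originSigs <- if (cfg$nOriginSignatures > 0)
    nm[cfg$nPlantedSignatures + seq_len(cfg$nOriginSignatures)]
  else character(0)
  sharedOriginSigs <- if (cfg$nSharedOriginSignatures > 0)
    originSigs[seq_len(cfg$nSharedOriginSignatures)] else character(0)

  plantedMembers <- list()
  if (length(plantedSigs)) {
    assignment <- rep(plantedSigs, length.out = cfg$nPlantedCandidates)
    plantedMembers <- split(candidates, assignment)[plantedSigs]
    plantedMembers <- plantedMembers[!vapply(plantedMembers, is.null,
                                             logical(1))]
    plantedSigs <- names(plantedMembers)
  }
  ## origin signatures draw from expressed genes too (a cell-type program),
  ## but never contain planted candidates
  originPool <- setdiff(expressed, candidates)
  drawSize <- function() cfg$signatureSizeRange[1] +
    sample.int(cfg$signatureSizeRange[2] - cfg$signatureSizeRange[1] + 1L,
               1L) - 1L
  originMembers <- lapply(stats::setNames(originSigs, originSigs),
                          function(s) sample(originPool, drawSize()))
  forced <- c(plantedMembers,
              lapply(originMembers, identity))
  signatures <- simulateSignatures(
    genes, cfg$nSignatures, cfg$signatureSizeRange,
    plantedMembers = forced,
    fillPool = setdiff(expressed, candidates))
  ## relabel origin signatures (simulateSignatures marks all forced sets
  ## "planted")
  labels <- collectionLabels(signatures)
  labels[originSigs] <- "origin"
  signatures@collection <- labels

  ## gene-level shifts
  tumorProgramGenes <- unique(unlist(
    geneSets(signatures)[c(plantedSigs, sharedOriginSigs)],
    use.names = FALSE))
  originProgramGenes <- unique(unlist(geneSets(signatures)[originSigs],
                                      use.names = FALSE))
  tumorShift <- ifelse(genes %in% tumorProgramGenes, cfg$pathwayShift, 0)
  tumorShift <- tumorShift + ifelse(genes %in% candidates,
                                    cfg$inductionShift, 0)
  originShift <- ifelse(genes %in% originProgramGenes, cfg$pathwayShift, 0)

  exprMat <- function(nSamp, shift, prefix) {
    m <- matrix(stats::rnorm(cfg$nGenes * nSamp, sd = cfg$noiseSD),
                nrow = cfg$nGenes) + baseline + shift
    dimnames(m) <- list(genes, sprintf("%s%02d", prefix, seq_len(nSamp)))
    m
  }

  ## discovery cohort (tumors only; ligandome shares its patients)
  discPatients <- sprintf("DP%02d", seq_len(cfg$nTumors))
  discTumor <- exprMat(cfg$nTumors, tumorShift, "D_T")
  discoveryExpr <- SummarizedExperiment(
    assays = list(log2expr = discTumor),
    colData = DataFrame(patientId = discPatients,
                        tissueClass = "tumor",
                        row.names = colnames(discTumor)))

  ## validation cohort: tumors plus paired normals
  valPatients <- sprintf("VP%02d", seq_len(cfg$nTumors))
  valTumor <- exprMat(cfg$nTumors, tumorShift, "V_T")
  valNormal <- exprMat(cfg$nPairedNormals, 0, "V_N")
  validationExpr <- SummarizedExperiment(
    assays = list(log2expr = cbind(valTumor, valNormal)),
    colData = DataFrame(
      patientId = c(valPatients, valPatients[seq_len(cfg$nPairedNormals)]),
      tissueClass = rep(c("tumor", "adjacent_normal"),
                        c(cfg$nTumors, cfg$nPairedNormals)),
      row.names = c(colnames(valTumor), colnames(valNormal))))
  pairing <- data.frame(
    patient = valPatients[seq_len(cfg$nPairedNormals)],
    tumor = colnames(valTumor)[seq_len(cfg$nPairedNormals)],
    normal = colnames(valNormal))

  ## cell-of-origin single cells: Bernoulli dropout straddling the
  ## sparse-sample filter at 3000 measured genes
  originFull <- exprMat(cfg$nOriginCells, originShift, "SC")
  dropRate <- stats::runif(cfg$nOriginCells, 0.32, 0.48)
  for (j in seq_len(cfg$nOriginCells)) {
    drop <- stats::runif(cfg$nGenes) < dropRate[j]
    originFull[drop, j] <- NA_real_
  }
  originExpr <- SummarizedExperiment(
    assays = list(log2expr = originFull),
    colData = DataFrame(tissueClass = rep("benign_organ", cfg$nOriginCells),
                        patientId = NA_character_,
                        row.names = colnames(originFull)))

  ## peptide universe
  nCand <- cfg$nPlantedCandidates
  ppc <- cfg$peptidesPerCandidate
  plantedPeps <- data.frame(sequence = character(0), hlaClass = character(0),
                            gene = character(0))
  if (nCand > 0 && ppc > 0) {
    cls <- rep(c(rep("I", min(2L, ppc)), rep("II", max(ppc - 2L, 0L))),
               nCand)
    genesRep <- rep(candidates, each = ppc)
    seqs <- character(length(cls))
    seqs[cls == "I"] <- .randomPeptides(sum(cls == "I"), 9L)
    seqs[cls == "II"] <- .randomPeptides(sum(cls == "II"), 15L,
                                         existing = seqs)
    plantedPeps <- data.frame(sequence = seqs, hlaClass = cls,
                              gene = genesRep)
  }
  nBg <- cfg$nBackgroundPeptides
  bgClass <- sample(c("I", "II"), nBg, replace = TRUE, prob = c(0.7, 0.3))
  bgSeq <- character(nBg)
  lenI <- sample(8:12, sum(bgClass == "I"), replace = TRUE)
  lenII <- sample(9:25, sum(bgClass == "II"), replace = TRUE)
  existing <- plantedPeps$sequence
  iSeqs <- character(0)
  for (L in unique(lenI)) {
    k <- sum(lenI == L)
    s <- .randomPeptides(k, L, existing = existing)
    existing <- c(existing, s)
    iSeqs <- c(iSeqs, s)
  }
  bgSeq[bgClass == "I"] <- iSeqs
  iiSeqs <- character(0)
  for (L in unique(lenII)) {
    k <- sum(lenII == L)
    s <- .randomPeptides(k, L, existing = existing)
    existing <- c(existing, s)
    iiSeqs <- c(iiSeqs, s)
  }
  bgSeq[bgClass == "II"] <- iiSeqs
  bgGene <- sample(genes, nBg, replace = TRUE)
  peptides <- rbind(plantedPeps,
                    data.frame(sequence = bgSeq, hlaClass = bgClass,
                               gene = bgGene))
  peptides$planted <- c(rep(TRUE, nrow(plantedPeps)), rep(FALSE, nBg))
  ## protein accessions: one protein per gene; ~5% of background peptides
  ## multi-map to a second protein/gene
  proteinOf <- stats::setNames(sub("^G", "PR", genes), genes)
  peptides$proteins <- lapply(seq_len(nrow(peptides)), function(i) {
    p <- proteinOf[[peptides$gene[i]]]
    if (!peptides$planted[i] && stats::runif(1) < 0.05)
      p <- c(p, proteinOf[[sample(genes, 1)]])
    unique(p)
  })
  proteinToGene <- data.frame(protein = unname(proteinOf), gene = genes)
  ## binder status fixes the predictor annotations (and hence purity)
  peptides$binder <- peptides$planted |
    stats::runif(nrow(peptides)) < cfg$binderProb

  ## ligandome samples
  nBenOrg <- round(0.85 * cfg$nBenignSamples)
  nLeuko <- cfg$nBenignSamples - nBenOrg
  ligSamples <- data.frame(
    sampleId = c(colnames(discTumor),
                 sprintf("D_N%02d", seq_len(cfg$nTumors)),
                 sprintf("B%03d", seq_len(nBenOrg)),
                 sprintf("L%02d", seq_len(nLeuko))),
    tissueClass = rep(c("tumor", "adjacent_normal", "benign_organ",
                        "leukocyte"),
                      c(cfg$nTumors, cfg$nTumors, nBenOrg, nLeuko)),
    patientId = c(discPatients, discPatients,
                  rep(NA_character_, cfg$nBenignSamples)))

  ## detection events
  nPep <- nrow(peptides)
  nSamp <- nrow(ligSamples)
  isTumorSamp <- ligSamples$tissueClass == "tumor"
  detProb <- matrix(cfg$peptideBackgroundProb, nPep, nSamp)
  detProb[peptides$planted, ] <- 0
  detProb[peptides$planted, isTumorSamp] <- cfg$peptideDetectionProbTumor
  detected <- matrix(stats::runif(nPep * nSamp) < detProb, nPep, nSamp)

  obsIdx <- which(detected, arr.ind = TRUE)
  obs <- data.frame(
    sequence = peptides$sequence[obsIdx[, 1]],
    hlaClass = peptides$hlaClass[obsIdx[, 1]],
    sampleId = ligSamples$sampleId[obsIdx[, 2]],
    psmRank = 1L,
    fdrQ = stats::runif(nrow(obsIdx), 0, 0.045),
    stringsAsFactors = FALSE)
  binder <- peptides$binder[obsIdx[, 1]]
  nObs <- nrow(obs)
  obs$predictorRank <- ifelse(binder, stats::runif(nObs, 0.05, 1.9),
                              stats::runif(nObs, 2.5, 60))
  obs$predictorAffinity <- ifelse(binder, stats::runif(nObs, 5, 450),
                                  stats::runif(nObs, 600, 5000))
  obs$motifScoreFraction <- ifelse(binder, stats::runif(nObs, 0.6, 0.95),
                                   stats::runif(nObs, 0.1, 0.55))
  obs$sourceProteins <- vapply(obsIdx[, 1], function(i)
    paste(peptides$proteins[[i]], collapse = ";"), character(1))
  ## decoys removed by the PSM filter: rank-2 matches and high-q hits
  nDecoy <- max(20L, round(0.03 * nObs))
  decoyRows <- sample(nObs, nDecoy, replace = TRUE)
  decoys <- obs[decoyRows, , drop = FALSE]
  half <- seq_len(floor(nDecoy / 2))
  decoys$psmRank[half] <- 2L
  decoys$fdrQ[-half] <- stats::runif(nDecoy - length(half), 0.06, 0.3)
  obs <- rbind(obs, decoys)
  rownames(obs) <- NULL

  ## methylation: validation tumors + normals; a subset of candidates is
  ## methylation-regulated (hypomethylated in tumors, beta anticorrelated
  ## with expression)
  nMethGenes <- floor(0.4 * nCand)
  methGenes <- if (nMethGenes > 0) candidates[seq_len(nMethGenes)]
  else character(0)
  cpgGenes <- c(rep(methGenes, each = 3L),
                sample(genes, 120L, replace = TRUE))
  cpgIds <- sprintf("cg%07d", seq_along(cpgGenes))
  probeMap <- data.frame(cpg = cpgIds, gene = cpgGenes)
  nT <- cfg$nTumors; nN <- cfg$nPairedNormals
  betaTumor <- matrix(stats::runif(length(cpgIds) * nT, 0.15, 0.85),
                      length(cpgIds), nT,
                      dimnames = list(cpgIds, colnames(valTumor)))
  betaNormal <- matrix(stats::runif(length(cpgIds) * nN, 0.15, 0.85),
                       length(cpgIds), nN,
                       dimnames = list(cpgIds, colnames(valNormal)))
  for (k in seq_along(methGenes)) {
    g <- methGenes[k]
    rows <- which(probeMap$gene == g)[1:2]  # 2 of 3 CpGs carry the signal
    z <- scale(valTumor[g, ])[, 1]
    for (r in rows) {
      b <- 0.45 - 0.25 * cfg$methylationEffect * z +
        stats::rnorm(nT, sd = 0.03)
      betaTumor[r, ] <- pmin(pmax(b, 0), 1)
      betaNormal[r, ] <- pmin(pmax(
        0.45 + cfg$methylationEffect / 2 + stats::rnorm(nN, sd = 0.05),
        0), 1)
    }
  }

  ## somatic mutations: sparse, mostly private variants plus a few shared
  mutCohort <- valPatients
  nMut <- stats::rbinom(1, cfg$nGenes * length(mutCohort), cfg$mutationRate)
  mutGene <- sample(genes, nMut, replace = TRUE)
  mutPatient <- sample(mutCohort, nMut, replace = TRUE)
  mutations <- data.frame(
    gene = mutGene, patient = mutPatient,
    variant = sprintf("%s:c.%dA>G", mutGene,
                      sample(100:5000, nMut, replace = TRUE)),
    proteinChange = sprintf("p.A%dT", sample(30:1500, nMut, replace = TRUE)),
    class = sample(c("missense", "nonsense", "frameshift"), nMut,
                   replace = TRUE, prob = c(0.8, 0.1, 0.1)))
  mutations <- mutations[!duplicated(mutations[c("gene", "patient",
                                                 "variant")]), ]
  if (nMut > 0) {
    nShared <- min(5L, nrow(mutations))
    sharedIdx <- sample(nrow(mutations), nShared)
    extra <- mutations[sharedIdx, , drop = FALSE]
    extra$patient <- vapply(extra$patient, function(p)
      sample(setdiff(mutCohort, p), 1), character(1))
    mutations <- rbind(mutations, extra)
  }
  rownames(mutations) <- NULL

  ## metabolites: 9 classes, block-correlated; some candidates drive a class
  metClasses <- c("acylcarnitines", "amino_acids", "biogenic_amines",
                  "diacyl_PC", "acyl_alkyl_PC", "lyso_PC", "sphingomyelins",
                  "hydroxy_SM", "energy_metabolism")
  metIds <- sprintf("MET%03d", seq_len(cfg$nMetabolites))
  metClassOf <- rep(metClasses, length.out = cfg$nMetabolites)
  classMap <- data.frame(metabolite = metIds, class = metClassOf)
  metSamples <- colnames(valTumor)[seq_len(min(30L, nT))]
  nMetAssoc <- min(5L, nCand)
  metAssoc <- if (nMetAssoc > 0)
    stats::setNames(sample(metClasses, nMetAssoc),
                    candidates[nCand - seq_len(nMetAssoc) + 1L])
  else stats::setNames(character(0), character(0))
  latentMet <- matrix(NA_real_, cfg$nMetabolites, length(metSamples),
                      dimnames = list(metIds, metSamples))
  classFactor <- lapply(stats::setNames(metClasses, metClasses), function(cl) {
    driver <- names(metAssoc)[metAssoc == cl]
    if (length(driver)) scale(valTumor[driver[1], metSamples])[, 1]
    else stats::rnorm(length(metSamples))
  })
  for (i in seq_len(cfg$nMetabolites)) {
    u <- stats::runif(1, 0.5, 0.85)
    latentMet[i, ] <- u * classFactor[[metClassOf[i]]] +
      sqrt(1 - u^2) * stats::rnorm(length(metSamples))
  }
  metAbundance <- 2^(latentMet + 5)   # raw scale; pipeline glog2-transforms

  ## immune markers: 6 process groups, same factor construction (NPX scale)
  markerProcs <- c("chemotaxis", "suppression_of_tumor_immunity",
                   "promotion_of_tumor_immunity", "metabolism_autophagy",
                   "vascular_tissue_remodeling", "apoptosis_cell_killing")
  markerIds <- sprintf("MRK%03d", seq_len(cfg$nMarkers))
  markerProcOf <- rep(markerProcs, length.out = cfg$nMarkers)
  processMap <- data.frame(marker = markerIds, process = markerProcOf)
  mrkSamples <- colnames(valTumor)[seq_len(min(37L, nT))]
  nMrkAssoc <- min(4L, nCand)
  mrkAssoc <- if (nMrkAssoc > 0)
    stats::setNames(sample(markerProcs, nMrkAssoc),
                    candidates[seq_len(nMrkAssoc)])
  else stats::setNames(character(0), character(0))
  npx <- matrix(NA_real_, cfg$nMarkers, length(mrkSamples),
                dimnames = list(markerIds, mrkSamples))
  procFactor <- lapply(stats::setNames(markerProcs, markerProcs),
                       function(pr) {
    driver <- names(mrkAssoc)[mrkAssoc == pr]
    if (length(driver)) scale(valTumor[driver[1], mrkSamples])[, 1]
    else stats::rnorm(length(mrkSamples))
  })
  for (i in seq_len(cfg$nMarkers)) {
    u <- stats::runif(1, 0.5, 0.85)
    npx[i, ] <- u * procFactor[[markerProcOf[i]]] +
      sqrt(1 - u^2) * stats::rnorm(length(mrkSamples))
  }

  truth <- list(
    plantedCandidateGenes = candidates,
    plantedEnrichedSignatures = plantedSigs,
    plantedOriginSignatures = originSigs,
    sharedOriginSignatures = sharedOriginSigs,
    plantedMethylationGenes = methGenes,
    plantedMetaboliteAssociations = metAssoc,
    plantedMarkerAssociations = mrkAssoc,
    plantedPeptides = paste0(plantedPeps$sequence, "_", plantedPeps$hlaClass))

  structure(list(
    config = cfg,
    observations = obs,
    ligandomeSamples = ligSamples,
    proteinToGene = proteinToGene,
    discoveryExpr = discoveryExpr,
    validationExpr = validationExpr,
    pairing = pairing,
    originExpr = originExpr,
    signatures = signatures,
    methylation = list(betaTumor = betaTumor, betaNormal = betaNormal,
                       probeMap = probeMap),
    mutations = mutations,
    mutationCohortSize = length(mutCohort),
    metabolites = list(abundance = metAbundance, classMap = classMap),
    markers = list(npx = npx, processMap = processMap),
    truth = truth), class = "CohortBundle")
}

#' @export
print.CohortBundle <- function(x, ...) {
  cfg <- x$config
  cat("Synthetic multi-omics cohort (seed ", cfg$seed, ")\n", sep = "")
  cat("  genes:", cfg$nGenes,
      "| discovery tumors:", cfg$nTumors,
      "| validation tumors:", cfg$nTumors,
      "(+", cfg$nPairedNormals, "paired normals)\n")
  cat("  signatures:", cfg$nSignatures,
      "| planted candidates:", length(x$truth$plantedCandidateGenes), "\n")
  cat("  peptide observations:", nrow(x$observations), "\n")
  invisible(x)
}
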