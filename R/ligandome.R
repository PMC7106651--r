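#' Filter peptide-spectrum-match records
#'
#' Restricts an immunopeptidome observation table to confident peptide
#' identifications: PSM rank 1 (the best match per spectrum), FDR q-value at
#' or below \code{fdrMax}, and a class-specific peptide-length window
#' (defaults: 8-12 amino acids for HLA class I, 9-25 for class II).
#'
#' @param observations data.frame with at least the columns
#'   \code{sequence}, \code{hlaClass} (\code{"I"}/\code{"II"}),
#'   \code{sampleId}, \code{psmRank}, \code{fdrQ}.
#' @param fdrMax maximum FDR q-value (default 0.05).
#' @param classILengths,classIILengths inclusive (min, max) length windows.
#' @return The retained rows of \code{observations}.
#' @export
filterPSM <- function(observations, fdrMax = 0.05,
                      classILengths = c(8L, 12L),
                      classIILengths = c(9L, 25L)) {
  .checkObsColumns(observations,
                   c("sequence", "hlaClass", "sampleId", "psmRank", "fdrQ"))
  cls <- observations$hlaClass
  if (!all(cls %in% c("I", "II")))
    stop("unknown hlaClass value(s): ",
         paste(unique(setdiff(cls, c("I", "II"))), collapse = ", "))
  len <- nchar(observations$sequence)
  lo <- ifelse(cls == "I", classILengths[1], classIILengths[1])
  hi <- ifelse(cls == "I", classILengths[2], classIILengths[2])
  keep <- observations$psmRank == 1L &
    observations$fdrQ <= fdrMax &
    len >= lo & len <= hi
  observations[keep, , drop = FALSE]
}

#' Flag HLA ligands among filtered peptide observations
#'
#' A peptide observation is annotated as an HLA ligand when at least one of
#' the predictor criteria holds for at least one of the patient's HLA
#' allotypes: predicted binding percentile rank below \code{rankMax},
#' predicted affinity at or below \code{affinityMax} nM, or a motif score of
#' at least \code{motifMin} of the allele's maximal score. The observation
#' table carries, per row, the best value of each annotation over the
#' sample's allotypes; missing annotations (\code{NA}) are legal and count
#' as non-passing.
#'
#' @param observations data.frame with optional numeric columns
#'   \code{predictorRank} (percentile), \code{predictorAffinity} (nM) and
#'   \code{motifScoreFraction} (fraction of maximal score).
#' @param rankMax exclusive percentile-rank threshold (default 2).
#' @param affinityMax inclusive affinity threshold in nM (default 500).
#' @param motifMin inclusive motif-score fraction threshold (default 0.6).
#' @return Logical vector, one flag per observation row.
#' @export
callLigands <- function(observations, rankMax = 2, affinityMax = 500,
                        motifMin = 0.6) {
  n <- nrow(observations)
  getcol <- function(nm)
    if (nm %in% names(observations)) observations[[nm]] else rep(NA_real_, n)
  rank <- getcol("predictorRank")
  aff <- getcol("predictorAffinity")
  motif <- getcol("motifScoreFraction")
  passNA <- function(x) !is.na(x) & x
  passNA(rank < rankMax) | passNA(aff <= affinityMax) | passNA(motif >= motifMin)
}

#' Per-sample ligand purity
#'
#' Purity of a sample is the fraction of its identified peptides that carry
#' an HLA binding motif for the patient's allotypes, i.e. the share of
#' ligand-flagged peptides among all identified peptides. It is a quality
#' measure of the immunoaffinity purification.
#'
#' @param observations observation data.frame (must contain \code{sampleId}
#'   and \code{sequence}).
#' @param ligand logical ligand flag per row, e.g. from [callLigands()].
#' @return Named numeric vector of per-sample purities in \[0, 1\]
#'   (unique peptides counted once per sample).
#' @export
samplePurity <- function(observations, ligand) {
  stopifnot(nrow(observations) == length(ligand))
  if (nrow(observations) == 0L)
    stop("purity is undefined for a sample with zero peptides")
  key <- paste(observations$sampleId, observations$sequence,
               observations$hlaClass)
  first <- !duplicated(key)
  obs <- observations[first, , drop = FALSE]
  lig <- ligand[first]
  tapply(lig, obs$sampleId, mean)
}

#' Tumor-exclusive peptides
#'
#' Returns the peptides detected in at least \code{minTumors} tumor samples
#' and in none of the non-tumor samples (adjacent normal tissue, benign
#' tissues from other organs, and leukocyte preparations all count as
#' non-tumor).
#'
#' @param det a \linkS4class{PeptideDetection}.
#' @param minTumors inclusive minimum tumor-sample count (default 3).
#' @return Character vector of peptide row keys (rownames of \code{det}).
#' @export
tumorExclusivePeptides <- function(det, minTumors = 3) {
  if (minTumors < 1) stop("'minTumors' must be at least 1")
  m <- detectedMatrix(det)
  tumor <- colData(det)$tissueClass == "tumor"
  nTum <- rowSums(m[, tumor, drop = FALSE])
  nBen <- rowSums(m[, !tumor, drop = FALSE])
  rownames(m)[nTum >= minTumors & nBen == 0L]
}

#' Map a peptide set to its possible source genes
#'
#' Every source protein of a peptide contributes all of its mapped genes
#' ("possible source genes"): a multi-mapping peptide contributes to every
#' gene it can originate from. Class I and class II gene sets are reported
#' separately together with their union and, per gene, the supporting
#' peptides. Protein accessions absent from the map are skipped with a
#' message.
#'
#' @param det a \linkS4class{PeptideDetection} whose rowData carries
#'   \code{sourceProteins}.
#' @param peptides character vector of peptide row keys (subset of
#'   \code{rownames(det)}).
#' @param proteinToGene data.frame with columns \code{protein}, \code{gene}.
#' @return List with \code{classI}, \code{classII}, \code{union} (character
#'   gene sets) and \code{peptidesByGene} (named list gene -> supporting
#'   peptide keys).
#' @export
peptidesToGenes <- function(det, peptides, proteinToGene) {
  if (is.null(proteinToGene) || nrow(proteinToGene) == 0L)
    stop("empty protein-to-gene map")
  stopifnot(all(c("protein", "gene") %in% names(proteinToGene)))
  missing <- setdiff(peptides, rownames(det))
  if (length(missing))
    stop("peptides not present in the detection matrix: ",
         paste(utils::head(missing, 5), collapse = ", "))
  rd <- rowData(det)[peptides, , drop = FALSE]
  prots <- rd$sourceProteins
  allProts <- unique(unlist(prots, use.names = FALSE))
  unresolved <- setdiff(allProts, proteinToGene$protein)
  if (length(unresolved))
    message(length(unresolved), " source protein accession(s) not in the map; skipped")
  lookup <- split(as.character(proteinToGene$gene),
                  as.character(proteinToGene$protein))
  genesPerPeptide <- lapply(seq_along(peptides), function(i)
    unique(unlist(lookup[intersect(prots[[i]], names(lookup))],
                  use.names = FALSE)))
  names(genesPerPeptide) <- peptides
  classOf <- rd$hlaClass
  geneSetFor <- function(cls)
    sort(unique(unlist(genesPerPeptide[classOf == cls], use.names = FALSE)))
  union <- sort(unique(unlist(genesPerPeptide, use.names = FALSE)))
  peptidesByGene <- lapply(stats::setNames(union, union), function(g)
    peptides[vapply(genesPerPeptide, function(gs) g %in% gs, logical(1))])
  list(classI = geneSetFor("I"), classII = geneSetFor("II"),
       union = union, peptidesByGene = peptidesByGene)
}

#' Patient coverage of a peptide subset
#'
#' Counts the tumor patients in whom at least one peptide of the subset was
#' detected, and the corresponding percentage of the tumor cohort (reported
#' to one decimal).
#'
#' @param det a \linkS4class{PeptideDetection}.
#' @param peptides character vector of peptide row keys (may be empty).
#' @param cohortSize tumor-cohort size; defaults to the number of distinct
#'   tumor patients in \code{det}.
#' @return List with \code{count} and \code{percent}.
#' @export
patientCoverage <- function(det, peptides, cohortSize = NULL) {
  tumor <- colData(det)$tissueClass == "tumor"
  patients <- colData(det)$patientId[tumor]
  if (is.null(cohortSize)) cohortSize <- length(unique(patients))
  if (cohortSize < 1) stop("empty tumor cohort")
  if (length(peptides) == 0L) return(list(count = 0L, percent = 0))
  m <- detectedMatrix(det)[peptides, tumor, drop = FALSE]
  hit <- colSums(m) > 0L
  count <- length(unique(patients[hit]))
  list(count = count, percent = round(100 * count / cohortSize, 1))
}

#' Cohort summaries of a peptide detection matrix
#'
#' Computes per-sample detected-peptide counts, the median and range of
#' tumor-exclusive peptides per tumor patient (overall and per HLA class),
#' and the overlap of the tumor peptidome with each non-tumor tissue class:
#' \code{100 * |tumor peptides intersect class-T peptides| / |tumor peptides|}.
#'
#' @param det a \linkS4class{PeptideDetection}.
#' @param minTumors passed to [tumorExclusivePeptides()].
#' @return List with \code{perSampleCounts} (named vector),
#'   \code{exclusivePerPatient} (list of per-class summaries with
#'   \code{median} and \code{range}), and \code{tissueOverlapPercent}
#'   (named vector over non-tumor tissue classes).
#' @export
summarizeLigandome <- function(det, minTumors = 3) {
  m <- detectedMatrix(det)
  if (nrow(m) == 0L || ncol(m) == 0L) stop("empty detection matrix")
  cd <- colData(det)
  tumor <- cd$tissueClass == "tumor"
  perSampleCounts <- colSums(m)
  exclusive <- tumorExclusivePeptides(det, minTumors = minTumors)
  cls <- rowData(det)$hlaClass
  names(cls) <- rownames(m)
  perPatient <- function(pep) {
    if (length(pep) == 0L)
      return(list(median = 0, range = c(0, 0)))
    counts <- tapply(
      colSums(m[pep, tumor, drop = FALSE]),
      cd$patientId[tumor], sum)
    list(median = stats::median(counts), range = range(counts))
  }
  exclusivePerPatient <- list(
    all = perPatient(exclusive),
    classI = perPatient(exclusive[cls[exclusive] == "I"]),
    classII = perPatient(exclusive[cls[exclusive] == "II"]))
  tumorPeps <- rownames(m)[rowSums(m[, tumor, drop = FALSE]) > 0L]
  overlaps <- vapply(.NONTUMOR_CLASSES, function(tc) {
    cols <- cd$tissueClass == tc
    if (!any(cols) || length(tumorPeps) == 0L) return(NA_real_)
    tcPeps <- rownames(m)[rowSums(m[, cols, drop = FALSE]) > 0L]
    100 * length(intersect(tumorPeps, tcPeps)) / length(tumorPeps)
  }, numeric(1))
  list(perSampleCounts = perSampleCounts,
       exclusivePerPatient = exclusivePerPatient,
       tissueOverlapPercent = overlaps)
}

.checkObsColumns <- function(observations, cols) {
  missing <- setdiff(cols, names(observations))
  if (length(missing))
    stop("observation table lacks column(s): ",
         paste(missing, collapse = ", "))
}
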