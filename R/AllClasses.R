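#' @import methods
#' @importFrom S4Vectors DataFrame metadata metadata<-
#' @importFrom SummarizedExperiment SummarizedExperiment assay rowData colData
#' @importFrom IRanges CharacterList
NULL

.TISSUE_CLASSES <- c("tumor", "adjacent_normal", "benign_organ", "leukocyte")
.NONTUMOR_CLASSES <- c("adjacent_normal", "benign_organ", "leukocyte")

#' PeptideDetection: peptide-by-sample presence calls
#'
#' A \linkS4class{SummarizedExperiment} subclass holding a logical
#' peptide-by-sample detection matrix (assay \code{"detected"}). Rows are
#' peptide entities identified by the pair (sequence, HLA class) -- the same
#' sequence observed as a class I and a class II peptide is two distinct
#' rows. \code{rowData} carries \code{sequence}, \code{hlaClass} and a
#' \code{sourceProteins} \code{CharacterList}; \code{colData} carries
#' \code{tissueClass} (one of tumor, adjacent_normal, benign_organ,
#' leukocyte) and \code{patientId}.
#'
#' @export
setClass("PeptideDetection", contains = "SummarizedExperiment")

setValidity("PeptideDetection", function(object) {
  msg <- NULL
  if (!"detected" %in% SummarizedExperiment::assayNames(object))
    msg <- c(msg, "assay 'detected' is required")
  else if (!is.logical(assay(object, "detected")))
    msg <- c(msg, "assay 'detected' must be logical")
  rd <- rowData(object)
  cd <- colData(object)
  if (!all(c("sequence", "hlaClass") %in% colnames(rd)))
    msg <- c(msg, "rowData must contain 'sequence' and 'hlaClass'")
  else {
    if (!all(rd$hlaClass %in% c("I", "II")))
      msg <- c(msg, "hlaClass must be 'I' or 'II'")
    if (anyDuplicated(paste(rd$sequence, rd$hlaClass)))
      msg <- c(msg, "duplicate (sequence, hlaClass) rows are not allowed")
  }
  if (!"tissueClass" %in% colnames(cd))
    msg <- c(msg, "colData must contain 'tissueClass'")
  else if (!all(cd$tissueClass %in% .TISSUE_CLASSES))
    msg <- c(msg, sprintf("tissueClass values must be one of: %s",
                          paste(.TISSUE_CLASSES, collapse = ", ")))
  if (is.null(msg)) TRUE else msg
})

#' Construct a PeptideDetection object
#'
#' @param detected logical peptide-by-sample matrix; rownames are internal
#'   peptide keys (ignored; regenerated from \code{sequence}/\code{hlaClass}).
#' @param sequence,hlaClass per-row peptide sequence and HLA class
#'   (\code{"I"} or \code{"II"}).
#' @param tissueClass per-column tissue class; one of \code{"tumor"},
#'   \code{"adjacent_normal"}, \code{"benign_organ"}, \code{"leukocyte"}.
#' @param patientId per-column patient identifier (\code{NA} allowed for
#'   unpaired benign tissues).
#' @param sourceProteins optional \code{CharacterList} (or plain list) of
#'   source protein accessions per peptide row.
#' @return A \linkS4class{PeptideDetection}.
#' @export
PeptideDetection <- function(detected, sequence, hlaClass, tissueClass,
                             patientId = NA_character_, sourceProteins = NULL) {
  detected <- as.matrix(detected)
  storage.mode(detected) <- "logical"
  if (is.null(sourceProteins))
    sourceProteins <- CharacterList(rep(list(character(0)), nrow(detected)))
  if (!is(sourceProteins, "CharacterList"))
    sourceProteins <- CharacterList(sourceProteins)
  rd <- DataFrame(sequence = sequence, hlaClass = hlaClass,
                  sourceProteins = sourceProteins)
  cd <- DataFrame(tissueClass = tissueClass,
                  patientId = rep_len(patientId, ncol(detected)))
  rownames(detected) <- paste0(sequence, "_", hlaClass)
  se <- SummarizedExperiment(assays = list(detected = detected),
                             rowData = rd, colData = cd)
  new("PeptideDetection", se)
}

#' @describeIn PeptideDetection logical detection matrix accessor
#' @param x a \code{PeptideDetection}
#' @export
detectedMatrix <- function(x) assay(x, "detected")

#' SignatureCollection: named gene sets with collection labels
#'
#' Container for a gene-set collection (GMT-compatible): a named list of
#' character member vectors plus a per-set collection label (e.g. the MSigDB
#' sub-collection a signature came from, or \code{"planted"} for synthetic
#' signatures carrying simulated signal).
#'
#' @slot sets named list of character vectors (gene IDs).
#' @slot collection named character vector of per-set labels.
#' @export
setClass("SignatureCollection",
         representation(sets = "list", collection = "character"))

setValidity("SignatureCollection", function(object) {
  msg <- NULL
  if (is.null(names(object@sets)) || anyDuplicated(names(object@sets)))
    msg <- c(msg, "set names must be present and unique")
  if (any(lengths(object@sets) == 0L))
    msg <- c(msg, "gene sets must be non-empty")
  if (length(object@collection) != length(object@sets))
    msg <- c(msg, "one collection label per set is required")
  if (is.null(msg)) TRUE else msg
})

#' Construct a SignatureCollection
#'
#' @param sets named list of character vectors of gene IDs.
#' @param collection per-set labels; a single value is recycled.
#' @return A \linkS4class{SignatureCollection}.
#' @export
SignatureCollection <- function(sets, collection = "custom") {
  collection <- rep_len(as.character(collection), length(sets))
  names(collection) <- names(sets)
  new("SignatureCollection", sets = lapply(sets, as.character),
      collection = collection)
}

#' @describeIn SignatureCollection the named list of member vectors
#' @param x a \code{SignatureCollection}
#' @export
geneSets <- function(x) x@sets

#' @describeIn SignatureCollection per-set collection labels
#' @export
collectionLabels <- function(x) x@collection

#' @export
setMethod("length", "SignatureCollection", function(x) length(x@sets))

#' @export
setMethod("names", "SignatureCollection", function(x) names(x@sets))

#' @param i set names or indices
#' @param j,drop,... ignored
#' @rdname SignatureCollection-class
#' @export
setMethod("[", "SignatureCollection", function(x, i, j, ..., drop = FALSE) {
  if (is.character(i) && !all(i %in% names(x@sets)))
    stop("unknown signature name(s): ",
         paste(setdiff(i, names(x@sets)), collapse = ", "))
  new("SignatureCollection", sets = x@sets[i], collection = x@collection[i])
})

#' @rdname SignatureCollection-class
#' @export
setMethod("[[", "SignatureCollection", function(x, i) x@sets[[i]])

setMethod("show", "SignatureCollection", function(object) {
  cat("SignatureCollection with", length(object@sets), "gene sets\n")
  sz <- lengths(object@sets)
  if (length(sz))
    cat("  set sizes:", min(sz), "-", max(sz), "\n")
  tab <- table(object@collection)
  cat("  collections:",
      paste(sprintf("%s (%d)", names(tab), tab), collapse = ", "), "\n")
})

#' EnrichmentResult: normalized enrichment scores and cohort-level calls
#'
#' Holds the signature-by-sample matrix of normalized single-sample
#' enrichment scores together with the cohort enrichment call per signature:
#' a signature is enriched when its normalized score is at least
#' \code{scoreMin} in at least a fraction \code{prevalenceMin} of samples
#' (missing scores count as non-passing).
#'
#' @slot scores numeric signature-by-sample matrix (normalized; may contain
#'   \code{NA} for degenerate signature/sample combinations).
#' @slot enriched named logical vector, one entry per signature.
#' @slot scoreMin,prevalenceMin the thresholds the calls were made with.
#' @export
setClass("EnrichmentResult",
         representation(scores = "matrix", enriched = "logical",
                        scoreMin = "numeric", prevalenceMin = "numeric"))

setValidity("EnrichmentResult", function(object) {
  msg <- NULL
  if (length(object@enriched) != nrow(object@scores))
    msg <- c(msg, "one enriched flag per signature row is required")
  if (!identical(names(object@enriched), rownames(object@scores)))
    msg <- c(msg, "enriched names must match score rownames")
  recomputed <- .enrichedCalls(object@scores, object@scoreMin,
                               object@prevalenceMin)
  if (!identical(unname(recomputed), unname(object@enriched)))
    msg <- c(msg, "enriched flags are not reproducible from scores and thresholds")
  if (is.null(msg)) TRUE else msg
})

.enrichedCalls <- function(scores, scoreMin, prevalenceMin) {
  pass <- !is.na(scores) & scores >= scoreMin
  rowMeans(pass) >= prevalenceMin
}

#' @describeIn EnrichmentResult normalized score matrix accessor
#' @param x an \code{EnrichmentResult}
#' @export
enrichmentScores <- function(x) x@scores

#' @describeIn EnrichmentResult names of signatures called enriched
#' @export
enrichedSignatures <- function(x) names(x@enriched)[x@enriched]

setMethod("show", "EnrichmentResult", function(object) {
  cat("EnrichmentResult:", nrow(object@scores), "signatures x",
      ncol(object@scores), "samples\n")
  cat(sprintf("  enriched (score >= %g in >= %g%% of samples): %d\n",
              object@scoreMin, 100 * object@prevalenceMin,
              sum(object@enriched)))
})
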