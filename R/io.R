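#' Read a gene-set collection from a GMT file
#'
#' GMT dialect: one set per line, tab-separated fields
#' \code{name<TAB>description<TAB>member1<TAB>member2...}. The description
#' field is kept as the set's collection label.
#'
#' @param path file path.
#' @return A \linkS4class{SignatureCollection}; an empty file yields an
#'   empty collection.
#' @export
readGMT <- function(path) {
  lines <- readLines(path)
  lines <- lines[nzchar(lines)]
  if (length(lines) == 0L)
    return(new("SignatureCollection", sets = structure(list(),
                                                       names = character(0)),
               collection = character(0)))
  fields <- strsplit(lines, "\t", fixed = TRUE)
  bad <- which(lengths(fields) < 3L)
  if (length(bad))
    stop("GMT parse error at line ", bad[1], ": fewer than 3 fields")
  sets <- lapply(fields, function(f) f[-(1:2)])
  names(sets) <- vapply(fields, `[`, character(1), 1L)
  labels <- vapply(fields, `[`, character(1), 2L)
  SignatureCollection(sets, labels)
}

#' Write a gene-set collection to a GMT file
#'
#' @param collection a \linkS4class{SignatureCollection}.
#' @param path file path.
#' @return \code{path}, invisibly.
#' @export
writeGMT <- function(collection, path) {
  sets <- geneSets(collection)
  labels <- collectionLabels(collection)
  lines <- vapply(names(sets), function(nm)
    paste(c(nm, labels[[nm]], sets[[nm]]), collapse = "\t"), character(1))
  writeLines(lines, path)
  invisible(path)
}

#' Read a labelled numeric matrix from TSV
#'
#' Expects a rectangular tab-separated table with a header row and a
#' leading row-label column. Cells equal to \code{missingToken} are marked
#' missing (\code{NA}), not zero.
#'
#' @param path file path.
#' @param missingToken string encoding missing values (default "NA").
#' @return Numeric matrix with dimnames.
#' @export
readMatrixTSV <- function(path, missingToken = "NA") {
  lines <- readLines(path)
  fields <- strsplit(lines, "\t", fixed = TRUE)
  ncols <- length(fields[[1]])
  ragged <- which(lengths(fields) != ncols)
  if (length(ragged))
    stop("ragged TSV: row ", ragged[1], " has ", lengths(fields)[ragged[1]],
         " fields, expected ", ncols)
  header <- fields[[1]][-1]
  body <- fields[-1]
  rowLabels <- vapply(body, `[`, character(1), 1L)
  vals <- vapply(body, function(f) {
    v <- f[-1]
    v[v == missingToken] <- NA_character_
    as.numeric(v)
  }, numeric(ncols - 1L))
  m <- if (is.matrix(vals)) t(vals) else matrix(vals, nrow = length(body))
  dimnames(m) <- list(rowLabels, header)
  m
}

#' Write a labelled numeric matrix to TSV
#'
#' Values are printed with \code{\%.17g} so a write/read round trip
#' reproduces them exactly; \code{NA} is written as \code{missingToken}.
#'
#' @param m numeric matrix with dimnames.
#' @param path file path.
#' @param missingToken string to write for \code{NA} (default "NA").
#' @param idColumn name of the leading row-label column.
#' @return \code{path}, invisibly.
#' @export
writeMatrixTSV <- function(m, path, missingToken = "NA", idColumn = "id") {
  fmt <- function(x) {
    out <- sprintf("%.17g", x)
    out[is.na(x)] <- missingToken
    out
  }
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(paste(c(idColumn, colnames(m)), collapse = "\t"), con)
  for (i in seq_len(nrow(m)))
    writeLines(paste(c(rownames(m)[i], fmt(m[i, ])), collapse = "\t"), con)
  invisible(path)
}

.writeTSV <- function(df, path)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)

.readTSV <- function(path)
  utils::read.delim(path, stringsAsFactors = FALSE)

#' Write a synthetic cohort bundle to a directory of plain-text tables
#'
#' Emits every table of the bundle in the TSV/GMT dialects the pipeline
#' readers consume; the planted truth is serialized as a two-column
#' (entity, role) TSV.
#'
#' @param bundle a \code{CohortBundle} from [simulateCohort()].
#' @param dir output directory (created if needed).
#' @return \code{dir}, invisibly.
#' @export
writeCohort <- function(bundle, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  p <- function(f) file.path(dir, f)
  .writeTSV(bundle$observations, p("observations.tsv"))
  .writeTSV(bundle$ligandomeSamples, p("ligandome_samples.tsv"))
  .writeTSV(bundle$proteinToGene, p("protein_to_gene.tsv"))
  writeMatrixTSV(SummarizedExperiment::assay(bundle$discoveryExpr),
                 p("discovery_expression.tsv"), idColumn = "gene")
  writeMatrixTSV(SummarizedExperiment::assay(bundle$validationExpr),
                 p("validation_expression.tsv"), idColumn = "gene")
  .writeTSV(as.data.frame(colData(bundle$validationExpr)),
            p("validation_samples.tsv"))
  .writeTSV(bundle$pairing, p("pairing.tsv"))
  writeMatrixTSV(SummarizedExperiment::assay(bundle$originExpr),
                 p("origin_expression.tsv"), idColumn = "gene")
  writeGMT(bundle$signatures, p("signatures.gmt"))
  writeMatrixTSV(bundle$methylation$betaTumor, p("beta_tumor.tsv"),
                 idColumn = "cpg")
  writeMatrixTSV(bundle$methylation$betaNormal, p("beta_normal.tsv"),
                 idColumn = "cpg")
  .writeTSV(bundle$methylation$probeMap, p("probe_map.tsv"))
  .writeTSV(bundle$mutations, p("mutations.tsv"))
  writeMatrixTSV(bundle$metabolites$abundance, p("metabolites.tsv"),
                 idColumn = "metabolite")
  .writeTSV(bundle$metabolites$classMap, p("metabolite_classes.tsv"))
  writeMatrixTSV(bundle$markers$npx, p("markers.tsv"), idColumn = "marker")
  .writeTSV(bundle$markers$processMap, p("marker_processes.tsv"))
  tr <- bundle$truth
  truthTab <- rbind(
    data.frame(entity = tr$plantedCandidateGenes, role = "candidate_gene"),
    data.frame(entity = tr$plantedEnrichedSignatures,
               role = "enriched_signature"),
    data.frame(entity = tr$plantedOriginSignatures,
               role = "origin_signature"),
    data.frame(entity = tr$sharedOriginSignatures,
               role = "shared_origin_signature"),
    data.frame(entity = tr$plantedMethylationGenes,
               role = "methylation_gene"),
    data.frame(entity = names(tr$plantedMetaboliteAssociations),
               role = paste0("metabolite_association:",
                             tr$plantedMetaboliteAssociations)),
    data.frame(entity = names(tr$plantedMarkerAssociations),
               role = paste0("marker_association:",
                             tr$plantedMarkerAssociations)),
    data.frame(entity = tr$plantedPeptides, role = "planted_peptide"))
  .writeTSV(truthTab, p("truth.tsv"))
  .writeTSV(data.frame(field = "mutationCohortSize",
                       value = bundle$mutationCohortSize),
            p("cohort_info.tsv"))
  invisible(dir)
}

#' Read a cohort bundle back from a directory written by [writeCohort()]
#'
#' @param dir directory path.
#' @return A list with the same structure as the output of
#'   [simulateCohort()] (without the \code{config} element).
#' @export
readCohort <- function(dir) {
  p <- function(f) file.path(dir, f)
  valSamples <- .readTSV(p("validation_samples.tsv"))
  valMat <- readMatrixTSV(p("validation_expression.tsv"))
  validationExpr <- SummarizedExperiment(
    assays = list(log2expr = valMat),
    colData = DataFrame(valSamples, row.names = colnames(valMat)))
  discMat <- readMatrixTSV(p("discovery_expression.tsv"))
  discoveryExpr <- SummarizedExperiment(
    assays = list(log2expr = discMat),
    colData = DataFrame(patientId = sprintf("DP%02d", seq_len(ncol(discMat))),
                        tissueClass = "tumor",
                        row.names = colnames(discMat)))
  originMat <- readMatrixTSV(p("origin_expression.tsv"))
  originExpr <- SummarizedExperiment(
    assays = list(log2expr = originMat),
    colData = DataFrame(tissueClass = rep("benign_organ", ncol(originMat)),
                        patientId = NA_character_,
                        row.names = colnames(originMat)))
  truthTab <- .readTSV(p("truth.tsv"))
  byRole <- function(role) truthTab$entity[truthTab$role == role]
  assocOf <- function(prefix) {
    rows <- grepl(paste0("^", prefix, ":"), truthTab$role)
    stats::setNames(sub(paste0("^", prefix, ":"), "", truthTab$role[rows]),
                    truthTab$entity[rows])
  }
  info <- .readTSV(p("cohort_info.tsv"))
  list(
    observations = .readTSV(p("observations.tsv")),
    ligandomeSamples = .readTSV(p("ligandome_samples.tsv")),
    proteinToGene = .readTSV(p("protein_to_gene.tsv")),
    discoveryExpr = discoveryExpr,
    validationExpr = validationExpr,
    pairing = .readTSV(p("pairing.tsv")),
    originExpr = originExpr,
    signatures = readGMT(p("signatures.gmt")),
    methylation = list(betaTumor = readMatrixTSV(p("beta_tumor.tsv")),
                       betaNormal = readMatrixTSV(p("beta_normal.tsv")),
                       probeMap = .readTSV(p("probe_map.tsv"))),
    mutations = .readTSV(p("mutations.tsv")),
    mutationCohortSize = as.integer(
      info$value[info$field == "mutationCohortSize"]),
    metabolites = list(abundance = readMatrixTSV(p("metabolites.tsv")),
                       classMap = .readTSV(p("metabolite_classes.tsv"))),
    markers = list(npx = readMatrixTSV(p("markers.tsv")),
                   processMap = .readTSV(p("marker_processes.tsv"))),
    truth = list(
      plantedCandidateGenes = byRole("candidate_gene"),
      plantedEnrichedSignatures = byRole("enriched_signature"),
      plantedOriginSignatures = byRole("origin_signature"),
      sharedOriginSignatures = byRole("shared_origin_signature"),
      plantedMethylationGenes = byRole("methylation_gene"),
      plantedMetaboliteAssociations = assocOf("metabolite_association"),
      plantedMarkerAssociations = assocOf("marker_association"),
      plantedPeptides = byRole("planted_peptide")))
}
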