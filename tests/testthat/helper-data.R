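# Shared small fixtures, built in code.

smallCohortConfig <- function(seed = 42, ...) {
  defaults <- list(seed = seed, nTumors = 20L, nPairedNormals = 12L,
                   nBenignSamples = 60L, nOriginCells = 40L, nGenes = 800L,
                   nSignatures = 60L, signatureSizeRange = c(10L, 25L),
                   nPlantedCandidates = 8L, nPlantedSignatures = 4L,
                   nBackgroundPeptides = 200L)
  do.call(cohortConfig, utils::modifyList(defaults, list(...)))
}

smallPipelineConfig <- function(...) pipelineConfig(minMeasured = 450, ...)

# Memoise one small bundle + run per test session (generation is seeded, so
# this is purely a speed measure).
.cache <- new.env()
smallBundle <- function() {
  if (is.null(.cache$bundle)) .cache$bundle <- simulateCohort(smallCohortConfig())
  .cache$bundle
}
smallRun <- function() {
  if (is.null(.cache$run))
    .cache$run <- runPipeline(smallBundle(), smallPipelineConfig())
  .cache$run
}

# Minimal observation table covering both HLA classes.
toyObservations <- function() {
  data.frame(
    sequence = c("AAAAAAAAA", "BBBBBBBBBBBBB", "CCCCCCCCC",
                 "DDDDDDDDDDDDDDD", "EEEEEEEEE"),
    hlaClass = c("I", "I", "II", "II", "I"),
    sampleId = c("S1", "S1", "S1", "S2", "S2"),
    psmRank = c(1L, 1L, 2L, 1L, 1L),
    fdrQ = c(0.01, 0.01, 0.01, 0.02, 0.2),
    predictorRank = c(1.5, 5, 5, NA, 1.0),
    predictorAffinity = c(NA, 400, 800, NA, 100),
    motifScoreFraction = c(NA, NA, 0.55, 0.7, 0.9),
    sourceProteins = c("PA", "PB", "PC", "PA;PB", "PD"),
    stringsAsFactors = FALSE)
}
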