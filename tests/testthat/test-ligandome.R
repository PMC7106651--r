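test_that("PSM filter enforces rank, FDR and class length windows", {
  obs <- data.frame(
    sequence = c("AAAAAAAAA", "AAAAAAAAAAAAA", "AAAAAAAAA", "AAAAAAAA",
                 "AAAAAAAAAAAA", "AAAAAAAAA"),
    hlaClass = c("I", "I", "II", "I", "I", "I"),
    sampleId = "S1",
    psmRank = c(1L, 1L, 2L, 1L, 1L, 1L),
    fdrQ = c(0.01, 0.01, 0.01, 0.05, 0.01, 0.06))
  kept <- filterPSM(obs)
  # class I length 9 rank 1 q 0.01 -> retained; length 13 -> removed;
  # class II rank 2 -> removed; q = 0.05 boundary -> retained (inclusive);
  # length 12 -> retained; q 0.06 -> removed
  expect_identical(which(seq_len(6) %in% as.integer(rownames(kept))),
                   c(1L, 4L, 5L))
  expect_error(filterPSM(transform(obs, hlaClass = "III")), "hlaClass")
})

test_that("ligand calling is an OR over predictor criteria with NA failing", {
  obs <- data.frame(
    sequence = rep("AAAAAAAAA", 4), hlaClass = "I", sampleId = "S1",
    psmRank = 1L, fdrQ = 0.01,
    predictorRank = c(1.5, 5, 5, NA),
    predictorAffinity = c(NA, 400, 800, NA),
    motifScoreFraction = c(NA, NA, 0.55, NA))
  expect_identical(callLigands(obs), c(TRUE, TRUE, FALSE, FALSE))
  # boundary conventions: rank strict, affinity and motif inclusive
  obs2 <- data.frame(predictorRank = c(2, NA, NA),
                     predictorAffinity = c(NA, 500, NA),
                     motifScoreFraction = c(NA, NA, 0.6))
  expect_identical(callLigands(obs2), c(FALSE, TRUE, TRUE))
})

test_that("purity is the ligand fraction per sample", {
  obs <- data.frame(sequence = paste0(strrep("A", 9), letters[1:10]),
                    hlaClass = "I",
                    sampleId = rep("S1", 10), psmRank = 1L, fdrQ = 0.01)
  expect_equal(unname(samplePurity(obs, c(rep(TRUE, 9), FALSE))["S1"]), 0.9)
  expect_equal(unname(samplePurity(obs, rep(TRUE, 10))["S1"]), 1.0)
  expect_error(samplePurity(obs[0, ], logical(0)), "zero peptides")
})

test_that("tumor exclusivity matches brute force, is antitone and order-invariant", {
  set.seed(31)
  for (i in 1:15) {
    det <- randomDetection()
    got <- tumorExclusivePeptides(det, minTumors = 3)
    want <- exclusiveBrute(detectedMatrix(det),
                           SummarizedExperiment::colData(det)$tissueClass, 3)
    expect_setequal(got, want)
    # raising minTumors never enlarges the set
    expect_true(all(tumorExclusivePeptides(det, 5) %in% got))
    # permuting samples leaves the answer unchanged
    perm <- sample(ncol(det))
    expect_setequal(tumorExclusivePeptides(det[, perm], 3), got)
  }
  expect_error(tumorExclusivePeptides(randomDetection(), 0), "at least 1")
})

test_that("peptides present in >= 3 tumors and absent from benign are kept", {
  m <- rbind(nine = c(rep(TRUE, 9), rep(FALSE, 3)),
             two = c(TRUE, TRUE, rep(FALSE, 10)),
             leaky = c(rep(TRUE, 5), rep(FALSE, 6), TRUE))
  det <- PeptideDetection(m, sequence = c("FLLSLIDRL", "AAAAAAAAA",
                                          "CCCCCCCCC"),
                          hlaClass = "I",
                          tissueClass = c(rep("tumor", 9), "adjacent_normal",
                                          "benign_organ", "leukocyte"),
                          patientId = paste0("P", 1:12))
  excl <- tumorExclusivePeptides(det)
  expect_identical(excl, "FLLSLIDRL_I")  # 9 tumors, no benign
})

test_that("source-gene mapping applies the multiplicity rule and unions classes", {
  m <- matrix(TRUE, 3, 2)
  det <- PeptideDetection(m, sequence = c("AAAAAAAAA", "CCCCCCCCC",
                                          "DDDDDDDDDDDDDDD"),
                          hlaClass = c("I", "I", "II"),
                          tissueClass = c("tumor", "tumor"),
                          patientId = c("P1", "P2"),
                          sourceProteins = list(c("PA", "PB"), "PC",
                                                c("PC", "PX")))
  map <- data.frame(protein = c("PA", "PB", "PC"),
                    gene = c("GA", "GB", "GC"))
  expect_message(res <- peptidesToGenes(det, rownames(det), map),
                 "not in the map")
  expect_setequal(res$classI, c("GA", "GB", "GC"))   # multi-map: both genes
  expect_identical(res$classII, "GC")
  expect_setequal(res$union, c("GA", "GB", "GC"))
  expect_setequal(res$peptidesByGene$GC,
                  c("CCCCCCCCC_I", "DDDDDDDDDDDDDDD_II"))
  expect_error(peptidesToGenes(det, rownames(det), map[0, ]), "empty")
})

test_that("patient coverage reproduces the printed arithmetic and is monotone", {
  # 24 positive patients of a 55-patient cohort -> 43.6%
  m <- matrix(FALSE, 2, 55)
  m[1, 1:24] <- TRUE
  det <- PeptideDetection(m, sequence = c("AAAAAAAAA", "CCCCCCCCC"),
                          hlaClass = "I",
                          tissueClass = rep("tumor", 55),
                          patientId = paste0("P", 1:55))
  cov <- patientCoverage(det, rownames(det)[1])
  expect_identical(cov$count, 24L)
  expect_equal(cov$percent, 43.6)
  expect_equal(patientCoverage(det, character(0)),
               list(count = 0L, percent = 0))
  set.seed(41)
  for (i in 1:10) {
    det2 <- randomDetection()
    peps <- sample(rownames(det2), 10)
    base <- patientCoverage(det2, peps)$count
    expect_gte(patientCoverage(det2, c(peps, sample(rownames(det2), 5)))$count,
               base)
  }
})

test_that("ligandome summaries equal set arithmetic", {
  set.seed(51)
  det <- randomDetection(nPep = 40, nSamp = 25, p = 0.3)
  s <- summarizeLigandome(det)
  m <- detectedMatrix(det)
  cd <- SummarizedExperiment::colData(det)
  tumorPeps <- rownames(m)[rowSums(m[, cd$tissueClass == "tumor"]) > 0]
  for (tc in c("adjacent_normal", "benign_organ", "leukocyte")) {
    if (!any(cd$tissueClass == tc)) next
    tp <- rownames(m)[rowSums(m[, cd$tissueClass == tc, drop = FALSE]) > 0]
    expect_equal(s$tissueOverlapPercent[[tc]],
                 100 * length(intersect(tumorPeps, tp)) / length(tumorPeps))
  }
  expect_true(all(s$perSampleCounts == colSums(m)))
  # full overlap and disjoint cases
  m2 <- matrix(TRUE, 2, 4)
  det2 <- PeptideDetection(m2, sequence = c("AAAAAAAAA", "CCCCCCCCC"),
                           hlaClass = "I",
                           tissueClass = c("tumor", "tumor",
                                           "adjacent_normal", "benign_organ"),
                           patientId = paste0("P", 1:4))
  expect_equal(summarizeLigandome(det2)$tissueOverlapPercent[["adjacent_normal"]],
               100)
  m3 <- rbind(c(TRUE, TRUE, FALSE, FALSE), c(FALSE, FALSE, TRUE, TRUE))
  det3 <- PeptideDetection(m3, sequence = c("AAAAAAAAA", "CCCCCCCCC"),
                           hlaClass = "I",
                           tissueClass = c("tumor", "tumor",
                                           "adjacent_normal", "benign_organ"),
                           patientId = paste0("P", 1:4))
  expect_equal(unname(summarizeLigandome(det3)$tissueOverlapPercent[
    c("adjacent_normal", "benign_organ")]), c(0, 0))
})

test_that("purity and coverage stay in their natural ranges", {
  set.seed(61)
  det <- randomDetection()
  cov <- patientCoverage(det, sample(rownames(det), 20))
  expect_gte(cov$percent, 0); expect_lte(cov$percent, 100)
  obs <- toyObservations()
  pur <- samplePurity(obs, callLigands(obs))
  expect_true(all(pur >= 0 & pur <= 1))
})
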