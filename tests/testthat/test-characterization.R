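test_that("perfect anticorrelation flags a gene as methylation-regulated", {
  n <- 30
  expr <- matrix(seq(5, 12, length.out = n), 1, n,
                 dimnames = list("G1", paste0("T", 1:n)))
  beta <- matrix(seq(0.9, 0.1, length.out = n), 1, n,
                 dimnames = list("cg1", colnames(expr)))
  pm <- data.frame(cpg = "cg1", gene = "G1")
  res <- methylationAssociation(beta, NULL, expr, pm, "G1")
  expect_equal(res$cpgStats$rho, -1)
  expect_true(res$geneFlags[["G1"]])
  # monotone transform of either variable leaves the Spearman flag unchanged
  res2 <- methylationAssociation(beta^3, NULL, 2^expr, pm, "G1")
  expect_equal(res2$cpgStats$rho, -1)
})

test_that("weak anticorrelation and unmapped genes are handled", {
  set.seed(111)
  n <- 40
  expr <- matrix(rnorm(n), 1, n, dimnames = list("G1", paste0("T", 1:n)))
  # construct a CpG with Spearman rho around -0.2: mostly noise
  b <- -0.2 * scale(expr[1, ])[, 1] + rnorm(n)
  beta <- matrix((b - min(b)) / diff(range(b)), 1, n,
                 dimnames = list("cg1", colnames(expr)))
  pm <- data.frame(cpg = "cg1", gene = "G1")
  res <- methylationAssociation(beta, NULL, expr, pm, c("G1", "G2"))
  ct <- suppressWarnings(cor.test(beta[1, ], expr[1, ], method = "spearman", exact = FALSE))
  expect_equal(res$cpgStats$rho, unname(ct$estimate))
  if (ct$estimate >= -0.3 || ct$p.value >= 0.05)
    expect_false(res$geneFlags[["G1"]])
  expect_true(is.na(res$geneFlags[["G2"]]))  # no CpG: unevaluable, not FALSE
})

test_that("methylation rule matches a naive per-CpG loop on random data", {
  set.seed(121)
  for (i in 1:25) {
    n <- 25; nCpg <- 6
    expr <- matrix(rnorm(2 * n), 2, n,
                   dimnames = list(c("GA", "GB"), paste0("T", 1:n)))
    beta <- matrix(runif(nCpg * n), nCpg, n,
                   dimnames = list(paste0("cg", 1:nCpg), colnames(expr)))
    pm <- data.frame(cpg = paste0("cg", 1:nCpg),
                     gene = sample(c("GA", "GB"), nCpg, replace = TRUE))
    res <- methylationAssociation(beta, NULL, expr, pm, c("GA", "GB"))
    for (g in c("GA", "GB")) {
      cpgs <- pm$cpg[pm$gene == g]
      if (length(cpgs) == 0L) { expect_true(is.na(res$geneFlags[[g]])); next }
      flags <- vapply(cpgs, function(cg) {
        ct <- suppressWarnings(cor.test(beta[cg, ], expr[g, ],
                                        method = "spearman", exact = FALSE))
        ct$estimate < -0.3 && ct$p.value < 0.05
      }, logical(1))
      expect_identical(res$geneFlags[[g]], any(flags))
    }
  }
})

test_that("mutation summaries count distinct patients and shared variants", {
  mut <- data.frame(
    gene = c("GA", "GA", "GA", "GB", "GB"),
    patient = c("P1", "P2", "P3", "P4", "P5"),
    variant = c("v1", "v1", "v1", "v2", "v3"))
  res <- mutationSummary(mut, c("GA", "GB", "GC"), cohortSize = 392)
  expect_identical(res$perGene["GA", "nPatients"], 3L)
  expect_identical(res$sharedVariants, "v1")   # one shared, two private
  expect_identical(res$perGene["GC", "nPatients"], 0L)
  # 8 mutated patients of 392 -> 2.0%
  mut8 <- data.frame(gene = "GX", patient = paste0("P", 1:8),
                     variant = paste0("v", 1:8))
  expect_equal(mutationSummary(mut8, "GX", 392)$perGene["GX", "percent"], 2.0)
  empty <- mutationSummary(mut[0, ], c("GA"), 10)
  expect_identical(empty$perGene["GA", "nPatients"], 0L)
  expect_length(empty$sharedVariants, 0)
})

test_that("glog2 is anchored at zero, monotone, and asymptotically log2 + 1", {
  expect_equal(glog2(0), 0)
  x <- sort(runif(50, 0, 100))
  expect_true(all(diff(glog2(x)) > 0))
  expect_lt(abs(glog2(2^20) - (20 + 1)), 1e-6)
  expect_error(glog2(-1), "non-negative")
})

test_that("metabolite class rule honours both criteria with inclusive fraction", {
  set.seed(131)
  n <- 30
  e <- setNames(rnorm(n), paste0("S", 1:n))
  # strong class: all 8 members highly correlated
  strong <- t(vapply(1:8, function(i) 0.9 * e + 0.1 * rnorm(n), numeric(n)))
  # weak class: 2 of 8 pass but median near zero
  weak <- t(vapply(1:8, function(i) {
    if (i <= 2) 0.9 * e + 0.1 * rnorm(n) else rnorm(n)
  }, numeric(n)))
  mat <- rbind(strong, weak)
  rownames(mat) <- paste0("M", 1:16)
  colnames(mat) <- names(e)
  cm <- data.frame(metabolite = rownames(mat),
                   class = rep(c("strong", "weak"), each = 8))
  res <- metaboliteAssociation(e, mat, cm)
  expect_true(res$associated[res$group == "strong"])
  expect_false(res$associated[res$group == "weak"])  # median criterion fails
})

test_that("marker process rule uses a strict member fraction", {
  set.seed(141)
  n <- 37
  e <- setNames(rnorm(n), paste0("S", 1:n))
  # exactly 25% of 8 markers passing -> NOT associated (strict inequality)
  mk <- t(vapply(1:8, function(i) {
    if (i <= 2) 0.95 * e + sqrt(1 - 0.95^2) * rnorm(n) else
      0.001 * e + rnorm(n)
  }, numeric(n)))
  rownames(mk) <- paste0("K", 1:8); colnames(mk) <- names(e)
  pmap <- data.frame(marker = rownames(mk), process = "proc")
  res <- markerAssociation(e, mk, pmap)
  if (res$fracPassing == 0.25) expect_false(res$associated)
  # all markers strongly correlated -> associated
  mkAll <- t(vapply(1:8, function(i) 0.95 * e + 0.05 * rnorm(n), numeric(n)))
  dimnames(mkAll) <- dimnames(mk)
  expect_true(markerAssociation(e, mkAll, pmap)$associated)
})

test_that("association rules equal the naive per-member loop on random data", {
  set.seed(151)
  for (i in 1:20) {
    n <- 20
    e <- setNames(rnorm(n), paste0("S", 1:n))
    nm <- 18
    mat <- matrix(rnorm(nm * n) + rep(rnorm(nm, sd = 0.5), n) *
                    rep(e, each = nm) * runif(nm, 0, 1.5),
                  nm, n, dimnames = list(paste0("m", 1:nm), names(e)))
    mp <- data.frame(metabolite = rownames(mat),
                     class = sample(paste0("cl", 1:3), nm, replace = TRUE))
    got <- metaboliteAssociation(e, mat, mp)
    want <- groupAssocOracle(e, mat, mp, "class", "metabolite",
                             rhoMin = 0.3, pMax = 0.05, memberFrac = 0.25,
                             fracStrict = FALSE, requireMedian = TRUE)
    expect_identical(setNames(got$associated, got$group), want)
    mp2 <- data.frame(marker = rownames(mat), process = mp$class)
    got2 <- markerAssociation(e, mat, mp2)
    want2 <- groupAssocOracle(e, mat, mp2, "process", "marker",
                              rhoMin = 0.3, pMax = 0.05, memberFrac = 0.25,
                              fracStrict = TRUE, requireMedian = FALSE)
    expect_identical(setNames(got2$associated, got2$group), want2)
  }
})

test_that("two-group score test separates groups and matches permutation", {
  expect_equal(twoGroupScoreTest(c(1, 2, 3, 1, 2, 3),
                                 c(TRUE, TRUE, TRUE, FALSE, FALSE, FALSE))$p,
               1)
  set.seed(161)
  a <- rnorm(20, 10); b <- rnorm(20, 0)
  res <- twoGroupScoreTest(c(a, b), rep(c(TRUE, FALSE), each = 20))
  expect_lt(res$p, 1e-6)
  expect_identical(res$direction, 1)
  for (i in 1:5) {
    x <- sample(seq(1, 100), 14)   # distinct values: exact rank-sum applies
    grp <- rep(c(TRUE, FALSE), each = 7)
    got <- twoGroupScoreTest(x, grp)$p
    expect_equal(got, rankSumPermutation(x[grp], x[!grp]), tolerance = 1e-9)
  }
  expect_error(twoGroupScoreTest(1:5, rep(TRUE, 5)), "non-empty")
})

test_that("pooled SD is the root mean square of replicate SDs", {
  expect_equal(pooledSD(c(3, 4)), sqrt(12.5))
  expect_equal(pooledSD(c(2, 2, 2)), 2)
  expect_equal(pooledSD(5), 5)
  expect_error(pooledSD(numeric(0)), "at least one")
  expect_error(pooledSD(c(1, -1)), "non-negative")
})

test_that("BH adjustment follows the step-up procedure", {
  expect_equal(bhAdjust(0.03), 0.03)
  expect_equal(bhAdjust(c(0.01, 0.02, 0.03, 0.04)), rep(0.04, 4))
  set.seed(171)
  p <- runif(50)
  adj <- bhAdjust(p)
  expect_true(all(adj >= p - 1e-15))
  expect_true(all(adj <= 1))
  expect_error(bhAdjust(c(0.5, 1.2)), "\\[0, 1\\]")
})
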