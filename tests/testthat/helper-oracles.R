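# Independent oracles, written as literal transcriptions of the definitions
# and kept free of the package's closed-form shortcuts.

# Brute-force single-sample enrichment score: explicit cumulative sums over
# the sorted gene list.
ssgseaBrute <- function(expr, geneSet, alpha = 0.25) {
  expr <- expr[!is.na(expr)]
  ord <- order(-expr, names(expr), method = "radix")
  sorted <- names(expr)[ord]
  n <- length(sorted)
  inSet <- sorted %in% geneSet
  m <- sum(inSet)
  stopifnot(m > 0, m < n)
  w <- (n - seq_len(n) + 1)^alpha
  wIn <- w * inSet
  pin <- cumsum(wIn) / sum(wIn)
  pout <- cumsum(!inSet) / (n - m)
  sum(pin - pout)
}

# Set-comprehension definition of tumor exclusivity over matrix rows.
exclusiveBrute <- function(mat, tissueClass, minTumors) {
  tumor <- tissueClass == "tumor"
  keep <- vapply(seq_len(nrow(mat)), function(i) {
    sum(mat[i, tumor]) >= minTumors && sum(mat[i, !tumor]) == 0
  }, logical(1))
  rownames(mat)[keep]
}

# Naive per-member loop for the correlation association rules.
groupAssocOracle <- function(geneExpr, mat, memberMap, groupCol, memberCol,
                             rhoMin, pMax, memberFrac, fracStrict,
                             requireMedian) {
  shared <- intersect(names(geneExpr), colnames(mat))
  groups <- unique(memberMap[[groupCol]])
  out <- logical(0)
  for (gr in sort(groups)) {
    mem <- memberMap[[memberCol]][memberMap[[groupCol]] == gr]
    mem <- mem[mem %in% rownames(mat)]
    if (length(mem) == 0L) next
    rhos <- numeric(length(mem)); ps <- numeric(length(mem))
    for (k in seq_along(mem)) {
      ct <- stats::cor.test(geneExpr[shared], mat[mem[k], shared])
      rhos[k] <- unname(ct$estimate); ps[k] <- ct$p.value
    }
    nPass <- sum(rhos > rhoMin & ps < pMax)
    frac <- nPass / length(mem)
    ok <- if (fracStrict) frac > memberFrac else frac >= memberFrac
    if (requireMedian) ok <- ok && stats::median(rhos) >= rhoMin
    out[gr] <- ok
  }
  out
}

# Exhaustive two-sided permutation p-value for the rank-sum statistic.
rankSumPermutation <- function(a, b) {
  pooled <- c(a, b)
  n <- length(pooled); n1 <- length(a)
  obs <- sum(rank(pooled)[seq_len(n1)])
  combos <- utils::combn(n, n1)
  stats <- apply(combos, 2, function(idx) sum(rank(pooled)[idx]))
  mu <- n1 * (n + 1) / 2
  mean(abs(stats - mu) >= abs(obs - mu) - 1e-9)
}

# Small random detection matrix with a mixed sample panel.
randomDetection <- function(nPep = 50, nSamp = 30, p = 0.2) {
  tissue <- sample(c("tumor", "adjacent_normal", "benign_organ", "leukocyte"),
                   nSamp, replace = TRUE, prob = c(0.5, 0.2, 0.2, 0.1))
  m <- matrix(runif(nPep * nSamp) < p, nPep, nSamp)
  seqs <- vapply(seq_len(nPep), function(i)
    paste(sample(LETTERS[1:20], 9, replace = TRUE), collapse = ""),
    character(1))
  seqs <- make.unique(seqs, sep = "")
  PeptideDetection(m, sequence = seqs,
                   hlaClass = sample(c("I", "II"), nPep, replace = TRUE),
                   tissueClass = tissue,
                   patientId = paste0("P", seq_len(nSamp)))
}
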