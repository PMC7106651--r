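test_that("toy score matches the stepwise cumulative-sum computation", {
  # 6 genes, descending expression a > b > ... > f, set {a, d}:
  # P_in steps at positions 1 and 4 with weights 6^0.25 and 3^0.25,
  # P_out accumulates 1/4 per non-member; summing the differences by hand
  # gives 13.3387295.../2.8811585... - 3 = 1.6296...
  expr <- setNames(c(6, 5, 4, 3, 2, 1), letters[1:6])
  s <- ssgseaScore(expr, c("a", "d"), alpha = 0.25)
  expect_equal(s, 1.62963, tolerance = 1e-5)
  expect_equal(s, ssgseaBrute(expr, c("a", "d")), tolerance = 1e-12)
})

test_that("score is a function of the expression vector only", {
  set.seed(1)
  expr <- setNames(rnorm(40), paste0("g", 1:40))
  gs <- sample(names(expr), 8)
  expect_identical(ssgseaScore(expr, gs), ssgseaScore(expr, gs))
  expect_equal(ssgseaScore(expr, gs), ssgseaScore(expr[sample(40)], gs))
})

test_that("closed form equals the brute-force oracle on random instances", {
  set.seed(7)
  for (i in 1:25) {
    n <- sample(10:300, 1)
    expr <- setNames(rnorm(n), paste0("g", seq_len(n)))
    gs <- sample(names(expr), sample(2:(n - 2), 1))
    expect_equal(ssgseaScore(expr, gs), ssgseaBrute(expr, gs),
                 tolerance = 1e-10)
  }
})

test_that("top-ranks placement maximizes and bottom-ranks minimizes (exhaustive)", {
  for (n in 3:8) {
    expr <- setNames(seq(n, 1), sprintf("g%02d", seq_len(n)))
    for (m in 1:(n - 1)) {
      scores <- apply(utils::combn(n, m), 2, function(idx)
        ssgseaScore(expr, names(expr)[idx]))
      expect_equal(max(scores), ssgseaScore(expr, names(expr)[1:m]),
                   tolerance = 1e-12)
      expect_equal(min(scores),
                   ssgseaScore(expr, names(expr)[(n - m + 1):n]),
                   tolerance = 1e-12)
    }
  }
})

test_that("scores are invariant under strictly increasing transforms", {
  set.seed(11)
  expr <- setNames(runif(100, 1, 10), paste0("g", 1:100))
  gs <- sample(names(expr), 15)
  base <- ssgseaScore(expr, gs)
  expect_equal(ssgseaScore(2^expr, gs), base, tolerance = 1e-12)
  expect_equal(ssgseaScore(log(expr), gs), base, tolerance = 1e-12)
  expect_equal(ssgseaScore(expr^3 + 5 * expr, gs), base, tolerance = 1e-12)
})

test_that("degenerate sets are rejected", {
  expr <- setNames(1:5, letters[1:5])
  expect_error(ssgseaScore(expr, c("x", "y")), "degenerate")
  expect_error(ssgseaScore(expr, letters[1:5]), "degenerate")
})

test_that("ssgseaMatrix composes per-sample scores and respects missingness", {
  set.seed(3)
  m <- matrix(rnorm(200), 50, 4,
              dimnames = list(paste0("g", 1:50), paste0("s", 1:4)))
  coll <- SignatureCollection(list(A = paste0("g", 1:10),
                                   B = paste0("g", 30:45)))
  sc <- ssgseaMatrix(m, coll)
  expect_identical(dim(sc), c(2L, 4L))
  expect_equal(sc["A", "s2"], ssgseaScore(m[, "s2"], geneSets(coll)$A))
  # column permutation permutes scores
  perm <- c(3, 1, 4, 2)
  expect_equal(ssgseaMatrix(m[, perm], coll), sc[, perm])
  # NA genes are excluded from that sample's universe only
  m2 <- m
  m2[1:20, 1] <- NA
  sc2 <- ssgseaMatrix(m2, coll)
  expect_equal(sc2["B", "s1"],
               ssgseaScore(m2[!is.na(m2[, 1]), 1], geneSets(coll)$B))
  expect_equal(sc2[, 2:4], sc[, 2:4])
  # signature fully lost to dropout gives NA, not an error
  expect_true(is.na(sc2["A", "s1"]) ||
                sum(!is.na(m2[1:10, 1])) > 0)
})

test_that("normalization rescales to unit global range and is idempotent", {
  m <- matrix(c(0, 1, 3, 4), 2, 2, dimnames = list(c("a", "b"), c("x", "y")))
  nm <- normalizeScores(m)
  expect_equal(nm, m / 4)
  expect_equal(max(nm) - min(nm), 1)
  expect_equal(normalizeScores(nm), nm)
  set.seed(5)
  for (i in 1:20) {
    r <- matrix(rnorm(60, sd = runif(1, 0.1, 50)), 6, 10)
    fin <- normalizeScores(r)
    expect_equal(max(fin) - min(fin), 1, tolerance = 1e-12)
  }
  expect_error(normalizeScores(matrix(2, 2, 2)), "zero range")
})

test_that("enrichment calling uses inclusive thresholds and counts NA as failing", {
  m <- rbind(eight = c(rep(0.6, 8), rep(0.2, 2)),
             seven = c(rep(0.6, 7), rep(0.2, 3)),
             missing = c(rep(0.6, 8), NA, 0.2))
  colnames(m) <- paste0("s", 1:10)
  er <- callEnriched(m)
  expect_true("eight" %in% enrichedSignatures(er))
  expect_false("seven" %in% enrichedSignatures(er))
  expect_true("missing" %in% enrichedSignatures(er))   # 8/10 still passes
  # direct per-row counting oracle on random matrices + threshold monotonicity
  set.seed(9)
  for (i in 1:20) {
    r <- matrix(runif(120), 12, 10, dimnames = list(paste0("S", 1:12), NULL))
    got <- enrichedSignatures(callEnriched(r, 0.5, 0.8))
    want <- rownames(r)[vapply(seq_len(12), function(k)
      sum(r[k, ] >= 0.5) / 10 >= 0.8, logical(1))]
    expect_identical(got, want)
    stricter <- enrichedSignatures(callEnriched(r, 0.6, 0.8))
    expect_true(all(stricter %in% got))
    stricter2 <- enrichedSignatures(callEnriched(r, 0.5, 0.9))
    expect_true(all(stricter2 %in% got))
  }
})

test_that("sparse-sample filter applies an inclusive boundary", {
  m <- matrix(rnorm(3001 * 3), 3001, 3,
              dimnames = list(paste0("g", 1:3001), c("full", "edge", "below")))
  m[1, "edge"] <- NA    # 3000 measured: retained (inclusive boundary)
  m[1:2, "below"] <- NA # 2999 measured: removed
  kept <- filterSparseSamples(m, minMeasured = 3000)
  expect_identical(colnames(kept), c("full", "edge"))
  # brute-force count filter on a random sparse matrix
  set.seed(21)
  r <- matrix(rnorm(200 * 8), 200, 8, dimnames = list(NULL, paste0("c", 1:8)))
  r[sample(length(r), 600)] <- NA
  rownames(r) <- paste0("g", 1:200)
  expect_identical(colnames(filterSparseSamples(r, 130)),
                   colnames(r)[colSums(!is.na(r)) >= 130])
})

test_that("origin subtraction and signature gene union follow set arithmetic", {
  tumor <- paste0("sig", 1:53)
  origin <- c(paste0("sig", 1:3), "other1", "other2")
  expect_length(subtractOriginSignatures(tumor, origin), 50)
  expect_identical(subtractOriginSignatures(c("a", "b"), character(0)),
                   c("a", "b"))
  expect_length(subtractOriginSignatures(c("a", "b"), c("a", "b", "c")), 0)

  coll <- SignatureCollection(list(S1 = c("A", "B"), S2 = c("B", "C")))
  u <- signatureGeneUnion(c("S1", "S2"), coll)
  expect_setequal(u$genes, c("A", "B", "C"))
  expect_setequal(u$membership$B, c("S1", "S2"))
  expect_identical(signatureGeneUnion(character(0), coll)$genes, character(0))
  expect_error(signatureGeneUnion("nope", coll), "unknown signature")
  set.seed(13)
  sets <- lapply(1:15, function(i) sample(paste0("g", 1:60), sample(3:12, 1)))
  names(sets) <- paste0("R", 1:15)
  coll2 <- SignatureCollection(sets)
  pick <- sample(names(sets), 7)
  expect_setequal(signatureGeneUnion(pick, coll2)$genes,
                  Reduce(union, geneSets(coll2)[pick]))
})
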