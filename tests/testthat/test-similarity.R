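test_that("Pearson similarity matches hand-computed values", {
  g <- toyPixelGene("g", res = 20, seed = 1)
  expect_equal(pearsonSimilarity(g, g), 1)
  comp <- pixelGene("c", 1L - bits(g))
  expect_equal(pearsonSimilarity(g, comp), -1)
  # fixed 4x4 toy matrices against the textbook formula
  a <- pixelGene("a", matrix(c(1L,0L,0L,1L, 1L,1L,0L,0L,
                               0L,0L,1L,1L, 1L,0L,1L,0L), 4, 4))
  b <- pixelGene("b", matrix(c(1L,1L,0L,0L, 0L,1L,1L,0L,
                               0L,0L,1L,1L, 1L,0L,0L,1L), 4, 4))
  expect_equal(pearsonSimilarity(a, b),
               oraclePearson(as.double(bits(a)), as.double(bits(b))))
  expect_error(pearsonSimilarity(g, toyPixelGene("h", res = 10)), "shape")
})

test_that("zero-variance rasters register as dissimilar by convention", {
  flat <- pixelGene("flat", matrix(0L, 20, 20))
  full <- pixelGene("full", matrix(1L, 20, 20))
  g <- toyPixelGene("g", res = 20)
  expect_equal(pearsonSimilarity(flat, g), 0)
  expect_equal(pearsonSimilarity(flat, full), 0)
  expect_equal(pearsonSimilarity(flat, g, zeroVariance = NA_real_),
               NA_real_)
})

test_that("similarity matrix equals the brute-force double loop", {
  genes <- lapply(1:12, function(s) toyPixelGene(paste0("g", s), 25, s))
  S <- similarityMatrix(genes)
  expect_true(isSymmetric(S))
  expect_equal(unname(diag(S)), rep(1, 12))
  for (i in 1:12) for (j in 1:12) {
    if (i == j) next
    expect_equal(S[i, j],
                 oraclePearson(as.double(bits(genes[[i]])),
                               as.double(bits(genes[[j]]))),
                 tolerance = 1e-12)
  }
})

test_that("total similarity is the absolute off-diagonal row sum", {
  S <- matrix(c(1, 0.5, -0.5, 0.5, 1, 0, -0.5, 0, 1), 3, 3,
              dimnames = list(c("a", "b", "c"), c("a", "b", "c")))
  expect_equal(totalSimilarity("a", S), 1)
  expect_equal(totalSimilarity("b", S), 0.5)
  expect_error(totalSimilarity("zz", S), "unknown")
  genes <- lapply(1:10, function(s) toyPixelGene(paste0("g", s), 25, s))
  Sg <- similarityMatrix(genes)
  for (id in rownames(Sg))
    expect_equal(totalSimilarity(id, Sg),
                 sum(abs(Sg[id, setdiff(rownames(Sg), id)])))
  expect_equal(unname(totalSimilarityAll(Sg)["g3"]), totalSimilarity("g3", Sg))
})

test_that("greedy diversity filter reproduces the replay oracle", {
  # 40-gene stream engineered to span low and high correlations: random
  # genes plus noisy copies of earlier ones
  set.seed(7)
  genes <- list()
  for (i in 1:40) {
    if (i > 4 && runif(1) < 0.4) {
      base <- bits(genes[[sample(i - 1, 1)]])
      flip <- sample(length(base), round(0.04 * length(base)))
      base[flip] <- 1L - base[flip]
      genes[[i]] <- pixelGene(sprintf("s%02d", i), base)
    } else {
      genes[[i]] <- toyPixelGene(sprintf("s%02d", i), res = 30,
                                 seed = 100 + i, fill = runif(1, .2, .6))
    }
  }
  absR <- abs(similarityMatrix(genes))
  expected <- oracleGreedyFilter(absR, quota = 10)
  got <- diversityFilter(genes, quota = 10, blockSize = 7)
  expect_identical(got$selection$streamIndex, expected$index)
  expect_identical(got$selection$pool, expected$pool)
  # block size must not affect the result
  got1 <- diversityFilter(genes, quota = 10, blockSize = 64)
  expect_identical(got1$selection, got$selection)
})

test_that("diversity filter honors admission rules and edge cases", {
  g1 <- toyPixelGene("g1", 30, 1)
  dup <- pixelGene("dup", bits(g1))
  g2 <- toyPixelGene("g2", 30, 2)
  out <- diversityFilter(list(g1, dup, g2), quota = 2)
  # first candidate always enters the dissimilar pool; an identical copy
  # (r = 1) is rejected
  expect_identical(out$selection$designId, c("g1", "g2"))
  expect_identical(out$selection$pool[1], "dissimilar")
  expect_false("dup" %in% out$selection$designId)
  # exhausted stream warns and returns a partial result
  expect_warning(short <- diversityFilter(list(g1, dup), quota = 4),
                 "exhausted")
  expect_identical(nrow(short$selection), 1L)
  # admission-time invariants from the recorded max |r|
  set.seed(11)
  genes <- lapply(1:30, function(s) toyPixelGene(paste0("x", s), 25,
                                                 400 + s, fill = 0.4))
  res <- diversityFilter(genes, quota = 12)
  d <- res$selection
  expect_true(all(d$maxAbsCor[d$pool == "dissimilar"] < 0.5 |
                  !is.finite(d$maxAbsCor[d$pool == "dissimilar"])))
  expect_true(all(d$maxAbsCor[d$pool == "similar"] < 0.9))
  # accepted predicate vetoes candidates without consuming quota
  res2 <- diversityFilter(genes, quota = 4,
                          accept = function(g) designId(g) != "x1")
  expect_false("x1" %in% res2$selection$designId)
  expect_identical(nrow(res2$selection), 4L)
})

test_that("reference designs constrain admission but never enter the pools", {
  g <- toyPixelGene("g", 30, 5)
  near <- bits(g)
  flip <- sample(length(near), 20)
  near[flip] <- 1L - near[flip]
  cand <- pixelGene("near", near)
  other <- toyPixelGene("other", 30, 99)
  # without reference the near-copy of g is admitted first
  expect_identical(
    diversityFilter(list(cand, other), quota = 2)$selection$designId[1],
    "near")
  # with g as reference it correlates ~1 and is rejected outright
  out <- suppressWarnings(
    diversityFilter(list(cand, other), quota = 2, reference = list(g)))
  expect_false("near" %in% out$selection$designId)
})
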