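test_that("eigenimages match a brute-force Gram eigendecomposition", {
  genes <- lapply(1:10, function(s) toyPixelGene(paste0("g", s), 16, s))
  eig <- pcaEigenimages(genes, 5)
  # independent dual-PCA oracle on the 10x10 Gram matrix
  X <- t(vapply(genes, function(g) as.double(t(bits(g))), double(256)))
  Xc <- sweep(X, 2, colMeans(X))
  e <- eigen(tcrossprod(Xc), symmetric = TRUE)
  expect_equal(eig@explainedVariance, e$values[1:5] / 9, tolerance = 1e-8)
  for (j in 1:5) {
    v <- crossprod(Xc, e$vectors[, j]) / sqrt(e$values[j])
    got <- as.vector(t(eig@components[[j]]))
    expect_equal(abs(sum(got * v)), 1, tolerance = 1e-8)  # same axis
  }
})

test_that("eigenimages are orthonormal with non-increasing variance", {
  genes <- lapply(1:20, function(s) toyPixelGene(paste0("g", s), 20,
                                                 30 + s, fill = 0.4))
  eig <- pcaEigenimages(genes, 7)
  V <- vapply(eig@components, function(m) as.vector(t(m)), double(400))
  G <- crossprod(V)
  expect_equal(G, diag(7), tolerance = 1e-8, ignore_attr = TRUE)
  expect_true(all(diff(eig@explainedVariance) <= 1e-8))
  # full-rank reconstruction recovers every design to numerical tolerance
  full <- pcaEigenimages(genes, 19)
  for (i in c(1, 8, 20)) {
    recon <- full@meanImage
    for (j in seq_along(full@components))
      recon <- recon + full@weights[i, j] * full@components[[j]]
    expect_equal(recon, bits(genes[[i]]) + 0, tolerance = 1e-6,
                 ignore_attr = TRUE)
  }
  expect_error(pcaEigenimages(genes[1:3], 5), "at least")
})

test_that("a library of identical designs is reported as degenerate", {
  g <- toyPixelGene("g", 16, 1)
  same <- lapply(1:6, function(i) pixelGene(paste0("g", i), bits(g)))
  expect_warning(eig <- pcaEigenimages(same, 2), "zero total variance")
  expect_equal(sum(eig@explainedVariance), 0, tolerance = 1e-10)
})

test_that("occupancy maps count material per pixel", {
  ones <- lapply(1:3, function(i) pixelGene(paste0("o", i),
                                            matrix(1L, 15, 15)))
  expect_identical(occupancyMap(ones), matrix(3L, 15, 15))
  g <- toyPixelGene("g", 15, 2)
  expect_identical(occupancyMap(list(g)), bits(g))
  group <- lapply(1:9, function(s) toyPixelGene(paste0("g", s), 15, s))
  m <- occupancyMap(group, groupLabel = "demo")
  expect_identical(sum(m), sum(vapply(group, function(g)
    sum(bits(g)), integer(1))))
  expect_true(all(m >= 0 & m <= 9))
  expect_identical(attr(m, "group"), "demo")
  expect_error(occupancyMap(list()), "empty")
})

test_that("the 2D embedding is seeded and recovers coarse structure", {
  # three structural clusters (a base pattern per cluster plus small
  # random flips) must separate in the embedding
  set.seed(4)
  bases <- lapply(c(101, 202, 303), function(s) bits(toyPixelGene("b", 24,
                                                                  s, 0.4)))
  mk <- function(k, tag) lapply(1:8, function(i) {
    b <- bases[[k]]
    flip <- sample(length(b), 20)
    b[flip] <- 1L - b[flip]
    pixelGene(sprintf("%s%d", tag, i), b)
  })
  genes <- c(mk(1, "lo"), mk(2, "mid"), mk(3, "hi"))
  emb <- embedLibrary(genes, nPcs = 10, seed = 11)
  expect_identical(emb$designId, vapply(genes, designId, character(1)))
  emb2 <- embedLibrary(genes, nPcs = 10, seed = 11)
  expect_identical(emb, emb2)
  labels <- rep(1:3, each = 8)
  sil <- cluster::silhouette(labels, dist(cbind(emb$x, emb$y)))
  expect_gt(mean(sil[, "sil_width"]), 0.5)
  # identical designs embed (near-)coincidentally
  g <- toyPixelGene("a", 24, 9)
  twins <- c(list(g, pixelGene("a2", bits(g))),
             lapply(1:10, function(s) toyPixelGene(paste0("r", s), 24,
                                                   700 + s)))
  e <- embedLibrary(twins, nPcs = 8, seed = 3)
  dtwin <- sqrt(sum((e[1, c("x", "y")] - e[2, c("x", "y")])^2))
  alld <- as.vector(dist(cbind(e$x, e$y)))
  expect_lte(dtwin, quantile(alld, 0.01))
})

test_that("parent-progeny accounting matches a brute-force recount", {
  study <- makeMiniStudy(poolSize = 100, nParents = 15, seed = 9)
  cyc <- breedingCycle(lapply(study$parents, rasterize), study$context,
                       seed = 21, representation = "pixel")
  st <- parentProgenyStats(cyc@lineage, names(study$parents))
  expect_identical(st$theoreticalMax, 225L)
  expect_identical(st$crossoverChildren, 100L)
  expect_identical(sum(st$pairMatrix), 100L)
  expect_identical(st$uniquePairs, 100L)  # all ordered pairs of 10 distinct
  # brute-force recount per parent
  cx <- cyc@lineage[!cyc@lineage$elite, ]
  for (p in names(study$parents))
    expect_identical(unname(st$progenyPerParent[p]),
                     sum(cx$parentA == p | cx$parentB == p))
  # an 81-parent pool has 6561 ordered pairs
  fake <- data.frame(childId = "c1", parentA = "p001", parentB = "p002",
                     selectionAlgorithm = "Random", crossoverOperator = "x",
                     mutations = "", representation = "pixel",
                     rateRegime = 0.2, cycle = 1L, round = 1L,
                     elite = FALSE)
  st81 <- parentProgenyStats(fake, sprintf("p%03d", 1:81))
  expect_identical(st81$theoreticalMax, 6561L)
  expect_error(parentProgenyStats(fake[0, ]), "empty")
})

test_that("selection usage tabulates algorithms by representation", {
  study <- makeMiniStudy(poolSize = 100, nParents = 15, seed = 9)
  arch <- runGeneration(study$parents, study$context,
                        targetCandidates = 440, rounds = 2, seed = 13)
  us <- selectionUsage(arch@lineage)
  expect_identical(sum(us$Freq), sum(!arch@lineage$elite))
  expect_true(all(us$algorithm %in% selectionAlgorithms()))
})
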