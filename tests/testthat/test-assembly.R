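study <- makeMiniStudy(poolSize = 120, nParents = 20, seed = 42)
parentsPix <- lapply(study$parents, rasterize)

test_that("one breeding cycle yields 110 candidates with full lineage", {
  cyc <- breedingCycle(parentsPix, study$context, seed = 7,
                       representation = "pixel", cycle = 1L)
  expect_length(cyc@genes, 110L)
  lin <- cyc@lineage
  expect_identical(sum(lin$elite), 10L)
  # elites carry empty crossover and mutation logs
  expect_true(all(lin$crossoverOperator[lin$elite] == ""))
  expect_true(all(lin$mutations[lin$elite] == ""))
  # the crossover entries cover all ordered pairs of the 10 selected parents
  cx <- lin[!lin$elite, ]
  expect_identical(nrow(cx), 100L)
  sel <- unique(cx$parentA)
  expect_length(sel, 10L)
  expect_setequal(paste(cx$parentA, cx$parentB),
                  as.vector(outer(sel, sel, paste)))
  # elites are the 10 highest-fitness parents of the pool
  rec <- study$context@records
  best <- rec$designId[order(-rec$alpIntensity, rec$designId)][1:10]
  expect_setequal(lin$parentA[lin$elite], best)
  expect_error(breedingCycle(parentsPix[1:5], study$context, seed = 1,
                             representation = "pixel"), "smaller")
})

test_that("breeding cycles are bit-identical under a fixed seed", {
  c1 <- breedingCycle(parentsPix, study$context, seed = 99,
                      representation = "pixel", cycle = 3L)
  c2 <- breedingCycle(parentsPix, study$context, seed = 99,
                      representation = "pixel", cycle = 3L)
  expect_identical(c1@lineage, c2@lineage)
  expect_identical(lapply(c1@genes, bits), lapply(c2@genes, bits))
  c3 <- breedingCycle(parentsPix, study$context, seed = 100,
                      representation = "pixel", cycle = 3L)
  expect_false(identical(lapply(c1@genes, bits), lapply(c3@genes, bits)))
})

test_that("generation runs partition cycles across rounds and mix representations", {
  arch <- runGeneration(study$parents, study$context,
                        targetCandidates = 220, rounds = 1, seed = 5)
  expect_length(arch@genes, 220L)
  expect_identical(length(unique(arch@lineage$cycle)), 2L)
  arch4 <- runGeneration(study$parents, study$context,
                         targetCandidates = 440, rounds = 4, seed = 5)
  expect_identical(sort(unique(arch4@lineage$round)), 1:4)
  expect_setequal(unique(arch4@lineage$representation),
                  c("pixel", "primitive"))
  # per-round candidate counts sum to the archive size
  expect_identical(sum(table(arch4@lineage$round)), 440L)
})

test_that("minimum pillar diameter matches the distance-transform oracle", {
  expect_identical(minPillarDiameter(pixelGene("z", matrix(0L, 200, 200))),
                   Inf)
  # single disc of radius 25 px at 0.1 um/px: 5 um within a pixel quantum
  d1 <- minPillarDiameter(pixelGene("d", oracleRasterCircle(10, 10, 2.5,
                                                            200, 0.1)))
  expect_lt(abs(d1 - 5), 0.21)
  # two discs: the 10 px one governs
  two <- pmax(oracleRasterCircle(3, 3, 1, 200, 0.1),
              oracleRasterCircle(13, 13, 4, 200, 0.1))
  d2 <- minPillarDiameter(pixelGene("t", two))
  expect_lt(abs(d2 - 2), 0.21)
  # diagonal-touching pixels are one 8-connected component
  m <- matrix(0L, 50, 50); m[10, 10] <- 1L; m[11, 11] <- 1L
  expect_identical(max(TopoEvolve:::pillarComponents(m)), 1L)
})

test_that("pillar repair erases only sub-threshold components", {
  two <- pmax(oracleRasterCircle(3, 3, 1, 200, 0.1),
              oracleRasterCircle(13, 13, 4, 200, 0.1))
  rep <- repairSmallPillars(pixelGene("t", two), minDiameter = 4)
  expect_identical(bits(rep), oracleRasterCircle(13, 13, 4, 200, 0.1))
  expect_gte(minPillarDiameter(rep), 4)
})

test_that("control set has 5 flats and 31 simple designs", {
  ctl <- makeControls()
  expect_identical(sum(ctl$meta$category == "flat"), 5L)
  expect_identical(sum(ctl$meta$category == "simple_control"), 31L)
  expect_true(all(ctl$meta$replicates[ctl$meta$category ==
                                        "simple_control"] == 3L))
  # 7 size variants of the hit design
  expect_identical(sum(grepl("^hit_", ctl$meta$designId)), 7L)
  # 4 um grating: all stripes exactly 40 px wide
  g4 <- bits(ctl$genes[["line_04"]])
  runs <- rle(g4[1, ])
  expect_true(all(runs$lengths == 40L))
  expect_identical(sum(g4[1, ]), 120L)
  # square arrays are the outer product of the stripe pattern
  s4 <- bits(ctl$genes[["square_04"]])
  expect_identical(s4, outer(g4[1, ], g4[1, ], function(a, b)
    as.integer(a & b)))
  # hit variants scale a common pattern
  h1 <- ctl$genes[["hit_100"]]
  expect_identical(bits(rasterize(h1)), bits(rasterize(makeHitDesign())))
})

test_that("finalized chips satisfy the layout count identity", {
  arch <- runGeneration(study$parents, study$context,
                        targetCandidates = 900, rounds = 2, seed = 31)
  layout <- finalizeChip(arch, study$parents, quotaChildren = 60, seed = 9)
  u <- layout@units
  tab <- table(u$category)
  expect_identical(layout@capacity,
                   60L + length(study$parents) + 5L + 93L)
  expect_identical(nrow(u), layout@capacity)
  expect_identical(unname(tab["parent"]), as.integer(length(study$parents)))
  expect_identical(unname(tab["flat"]), 5L)
  expect_identical(unname(tab["simple_control"]), 93L)
  expect_identical(unname(tab["pixel_child"] + tab["primitive_child"]), 60L)
  # positions are a permutation and the shuffle is seed-reproducible
  expect_setequal(u$position, seq_len(nrow(u)))
  layout2 <- finalizeChip(arch, study$parents, quotaChildren = 60, seed = 9)
  expect_identical(layout2@units, u)
  # every placed child passes the fabrication screen
  childIds <- u$designId[u$category %in% c("pixel_child", "primitive_child")]
  dmins <- vapply(layout@designs[childIds],
                  function(g) minPillarDiameter(g), numeric(1))
  expect_true(all(dmins >= 4))
  # elite candidates are never placed as children
  lin <- arch@lineage
  expect_length(intersect(childIds, lin$childId[lin$elite]), 0L)
  # chip export writes layout and manifest
  d <- tempfile("chip")
  exportChipLayout(layout, d)
  expect_true(file.exists(file.path(d, "chip_layout.csv")))
  man <- jsonlite::read_json(file.path(d, "chip_manifest.json"))
  expect_equal(man$capacity, layout@capacity)
})

test_that("chip assembly fails loudly when the archive cannot fill the quota", {
  arch <- runGeneration(study$parents, study$context,
                        targetCandidates = 110, rounds = 1, seed = 3)
  expect_error(finalizeChip(arch, study$parents, quotaChildren = 150),
               "more non-elite")
  expect_error(
    suppressWarnings(finalizeChip(arch, study$parents, quotaChildren = 99,
                                  seed = 2)),
    "shortfall|exhausted")
})
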