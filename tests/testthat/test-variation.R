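test_that("crossover with identical parents reproduces the parent design", {
  pg <- toyPixelGene("p", res = 40, seed = 3, fill = 0.35)
  pg2 <- pixelGene("p2", bits(pg))
  for (op in crossoverOperators("pixel")) {
    child <- crossoverGene(op, pg, pg2, seed = 11)
    expect_identical(bits(child), bits(pg))
  }
  gg <- toyPrimitiveGene("q", seed = 5, n = 6)
  gg2 <- primitiveGene("q2", featureSize(gg), primitives(gg))
  orderPreserving <- c("onePoint", "twoPoint", "typeStratified",
                       "uniformPerPrimitive", "countBalancedMerge",
                       "donorSubsetInsertion")
  ras <- bits(rasterize(gg))
  for (op in crossoverOperators("primitive")) {
    child <- crossoverGene(op, gg, gg2, seed = 11)
    # all operators preserve the design phenotypically ...
    expect_identical(bits(rasterize(child)), ras)
    # ... and the positional ones preserve the gene exactly
    if (op %in% orderPreserving)
      expect_identical(lapply(primitives(child), function(p) p@points),
                       lapply(primitives(gg), function(p) p@points))
  }
})

test_that("pixel crossover masks behave as specified", {
  ones <- pixelGene("one", matrix(1L, 200, 200))
  zeros <- pixelGene("zero", matrix(0L, 200, 200))
  # vertical-half swap of all-ones and all-zero: one filled half
  v <- crossoverGene("verticalHalf", ones, zeros, seed = 1)
  expect_identical(sum(bits(v)), 20000L)
  expect_true(all(bits(v)[, 1:100] == 1L))
  h <- crossoverGene("horizontalHalf", zeros, ones, seed = 1)
  expect_true(all(bits(h)[101:200, ] == 1L))
  # one-point crossover: the child is exactly prefix-of-A + suffix-of-B at
  # the replayed cut index (cut 0 would give parent B outright)
  a <- toyPixelGene("a", 200, 1); b <- toyPixelGene("b", 200, 2)
  for (s in c(2, 9, 31)) {
    k <- withr::with_seed(s, sample(0:40000, 1L))
    child <- crossoverGene("onePoint", a, b, seed = s)
    fa <- flattenGene(a); fb <- flattenGene(b)
    expect_identical(flattenGene(child),
                     c(fa[seq_len(k)], fb[seq_len(40000 - k) + k]))
  }
  # every child pixel is attributable to a parent
  for (op in crossoverOperators("pixel")) {
    ch <- bits(crossoverGene(op, a, b, seed = 9))
    expect_true(all(ch == bits(a) | ch == bits(b)))
    expect_identical(ch, bits(crossoverGene(op, a, b, seed = 9)))
  }
})

test_that("uniform primitive exchange follows the seeded mask", {
  mkP <- function(xs) lapply(xs, function(x) circle(c(x, 10), 2.5))
  a <- primitiveGene("a", 20, mkP(c(3, 9, 15)))
  b <- primitiveGene("b", 20, mkP(c(5, 11, 17)))
  seed <- 21
  mask <- withr::with_seed(seed, runif(3) < 0.5)  # TRUE = from b
  child <- crossoverGene("uniformPerPrimitive", a, b, seed = seed)
  want <- ifelse(mask, c(5, 11, 17), c(3, 9, 15))
  expect_equal(vapply(primitives(child), function(p) p@points[1, 1],
                      numeric(1)), want)
})

test_that("representation and operator mismatches are rejected", {
  pg <- toyPixelGene("p", 30, 1)
  gg <- toyPrimitiveGene("g", seed = 1)
  expect_error(crossoverGene("onePoint", pg, gg), "representation")
  expect_error(crossoverGene("bogus", pg, pg), "unknown")
  expect_error(mutateGene("roughness", gg, 0.1), "pixel-only")
  expect_error(mutateGene("bogus", pg, 0.1), "unknown")
})

test_that("mutations respect the changed-fraction bound and small-rate identity", {
  pg <- toyPixelGene("p", res = 200, seed = 6, fill = 0.3)
  gg <- toyPrimitiveGene("g", seed = 7, n = 8)
  for (op in mutationOperators("pixel")) {
    for (rate in c(0.2, 0.5)) {
      m <- mutateGene(op, pg, rate, seed = 31)
      expect_lte(mean(bits(m) != bits(pg)), rate)
    }
    # rate below one pixel's worth of change: identity
    tiny <- mutateGene(op, pg, 1 / 80000, seed = 31)
    expect_identical(bits(tiny), bits(pg))
  }
  for (op in mutationOperators("primitive")) {
    m <- mutateGene(op, gg, 0.5, seed = 31)
    expect_s4_class(m, "PrimitiveGene")
    # altered/added/removed primitives bounded by rate * n
    expect_lte(abs(length(primitives(m)) - 8), floor(0.5 * 8))
    tiny <- mutateGene(op, gg, 0.01, seed = 31)
    expect_identical(length(primitives(tiny)), 8L)
  }
  # deletion on an empty gene is a logged no-op
  empty <- primitiveGene("e", 20, list())
  expect_identical(length(primitives(mutateGene("deletion", empty, 0.5))), 0L)
})

test_that("pixel insertion of a disc matches the brute-force count", {
  zero <- pixelGene("z", matrix(0L, 200, 200))
  # drive the insertion operator until it draws a circle, then check the
  # painted pixel count against the per-pixel point-in-disc oracle
  checked <- FALSE
  for (s in 1:30) {
    params <- withr::with_seed(s, {
      kind <- sample(c("C", "T", "R"), 1L)
      sMax <- min(100, sqrt(0.2 * 40000 / (pi / 4)))
      sz <- runif(1, 45, sMax)
      list(kind = kind, r = sz / 2,
           ctr = runif(2, sz / 2, 200 - sz / 2 + 1))
    })
    if (params$kind != "C") next
    m <- mutateGene("insertion", zero, 0.2, seed = s)
    oracle <- sum(oracleRasterCircle(params$ctr[1], params$ctr[2],
                                     params$r, 200, 1))
    expect_identical(sum(bits(m)), oracle)
    checked <- TRUE
    break
  }
  expect_true(checked)
})

test_that("roughness flips only pixels adjacent to the boundary", {
  solid <- matrix(0L, 100, 100)
  solid[30:70, 30:70] <- 1L
  g <- pixelGene("sq", solid)
  m <- mutateGene("roughness", g, 0.2, seed = 4)
  changed <- which(bits(m) != solid)
  expect_gt(length(changed), 0L)
  expect_lte(length(changed) / length(solid), 0.2)
  # boundary-band oracle: pixels with both material and void in their
  # 3x3 neighbourhood
  inBand <- function(idx) {
    r <- (idx - 1L) %% 100L + 1L; cc <- (idx - 1L) %/% 100L + 1L
    nb <- expand.grid(dr = -1:1, dc = -1:1)
    vals <- mapply(function(dr, dc) {
      rr <- r + dr; c2 <- cc + dc
      if (rr < 1 || rr > 100 || c2 < 1 || c2 > 100) 0L else solid[rr, c2]
    }, nb$dr, nb$dc)
    any(vals == 1L) && any(vals == 0L)
  }
  expect_true(all(vapply(changed, inBand, logical(1))))
})

test_that("mutation schedules draw 0-3 distinct operators at bounded rates", {
  gg <- toyPrimitiveGene("g", seed = 8, n = 10)
  out <- mutationSchedule(gg, seed = 55, regime = 0.2)
  expect_identical(out$log,
                   mutationSchedule(gg, seed = 55, regime = 0.2)$log)
  expect_identical(bits(rasterize(out$gene)),
                   bits(rasterize(mutationSchedule(gg, seed = 55,
                                                   regime = 0.2)$gene)))
  # multinomial check of the realized mutation-count distribution
  small <- toyPixelGene("s", res = 20, seed = 2)
  counts <- vapply(1:1500, function(s)
    nrow(mutationSchedule(small, seed = s, regime = 0.2)$log), integer(1))
  tab <- tabulate(counts + 1L, 4L) / 1500
  for (i in 1:4) {
    p <- c(0.15, 0.6, 0.2, 0.05)[i]
    expect_lt(abs(tab[i] - p), 3.5 * sqrt(p * (1 - p) / 1500))
  }
  # schedules log distinct operators and bounded rates
  pg <- toyPixelGene("p", res = 60, seed = 9)
  for (s in c(3, 14, 27, 58, 91)) {
    for (regime in c(0.2, 0.5)) {
      sched <- mutationSchedule(pg, seed = s, regime = regime)
      expect_lte(nrow(sched$log), 3L)
      expect_false(anyDuplicated(sched$log$operator) > 0)
      expect_true(all(sched$log$rate > 0 & sched$log$rate <= regime))
    }
  }
  # zero-count schedules leave the gene untouched
  s0 <- NULL
  for (s in 1:200)
    if (withr::with_seed(s, sample(0:3, 1L,
                                   prob = c(0.15, 0.6, 0.2, 0.05))) == 0L) {
      s0 <- s; break
    }
  expect_false(is.null(s0))
  sch <- mutationSchedule(pg, seed = s0, regime = 0.5)
  expect_identical(nrow(sch$log), 0L)
  expect_identical(bits(sch$gene), bits(pg))
})
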