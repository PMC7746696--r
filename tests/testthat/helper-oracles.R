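# Independent brute-force oracles. These deliberately avoid the package's
# vectorized code paths: scalar per-pixel loops and textbook formulas only.

# per-pixel point-in-disc rasterizer (closed boundary), scale um/px
oracleRasterCircle <- function(cx, cy, r, res, scale) {
  m <- matrix(0L, res, res)
  for (row in seq_len(res)) for (col in seq_len(res)) {
    x <- (col - 0.5) * scale; y <- (row - 0.5) * scale
    if ((x - cx)^2 + (y - cy)^2 <= r^2 + 1e-9) m[row, col] <- 1L
  }
  m
}

# per-pixel point-in-triangle via signed areas (closed boundary)
oracleRasterTriangle <- function(p1, p2, p3, res, scale) {
  cross <- function(o, a, b)
    (a[1] - o[1]) * (b[2] - o[2]) - (a[2] - o[2]) * (b[1] - o[1])
  m <- matrix(0L, res, res)
  for (row in seq_len(res)) for (col in seq_len(res)) {
    p <- c((col - 0.5) * scale, (row - 0.5) * scale)
    d1 <- cross(p1, p2, p); d2 <- cross(p2, p3, p); d3 <- cross(p3, p1, p)
    eps <- 1e-9
    if ((d1 >= -eps && d2 >= -eps && d3 >= -eps) ||
        (d1 <= eps && d2 <= eps && d3 <= eps)) m[row, col] <- 1L
  }
  m
}

# textbook sample Pearson correlation
oraclePearson <- function(x, y) {
  mx <- mean(x); my <- mean(y)
  sum((x - mx) * (y - my)) / sqrt(sum((x - mx)^2) * sum((y - my)^2))
}

# plain-loop replay of the greedy half/half admission rule on a
# precomputed |r| matrix (candidates in stream order)
oracleGreedyFilter <- function(absR, quota, dTh = 0.5, sTh = 0.9) {
  qd <- ceiling(quota / 2); qs <- quota - qd
  accepted <- integer(0); pool <- character(0)
  for (i in seq_len(nrow(absR))) {
    if (sum(pool == "dissimilar") >= qd && sum(pool == "similar") >= qs) break
    mx <- if (length(accepted)) max(absR[i, accepted]) else -Inf
    if (mx < dTh && sum(pool == "dissimilar") < qd) {
      accepted <- c(accepted, i); pool <- c(pool, "dissimilar")
    } else if (mx < sTh && sum(pool == "similar") < qs) {
      accepted <- c(accepted, i); pool <- c(pool, "similar")
    }
  }
  data.frame(index = accepted, pool = pool)
}

# brute-force Pareto front (both objectives minimized)
oracleParetoFront <- function(F) {
  n <- nrow(F)
  which(vapply(seq_len(n), function(i) {
    !any(vapply(seq_len(n), function(j)
      j != i && all(F[j, ] <= F[i, ]) && any(F[j, ] < F[i, ]), logical(1)))
  }, logical(1)))
}

# small deterministic pixel gene with given fill pattern seed
toyPixelGene <- function(id, res = 20, seed = 1, fill = 0.3) {
  set.seed(seed)
  pixelGene(id, matrix(as.integer(runif(res * res) < fill), res, res))
}

# a small fabricable primitive gene
toyPrimitiveGene <- function(id, L = 20, seed = 1, n = 5) {
  set.seed(seed)
  prims <- lapply(seq_len(n), function(i) {
    ctr <- pmin(L - 3, pmax(3, rnorm(2, L / 2, L / 3)))
    if (i %% 2 == 0) circle(ctr, runif(1, 2.25, 2.75))
    else {
      R <- 8.2 / sqrt(3)
      a <- runif(1, 0, 2 * pi) + c(0, 2, 4) * pi / 3
      triangle(pmin(L, pmax(0, ctr + R * c(cos(a[1]), sin(a[1])))),
               pmin(L, pmax(0, ctr + R * c(cos(a[2]), sin(a[2])))),
               pmin(L, pmax(0, ctr + R * c(cos(a[3]), sin(a[3])))))
    }
  })
  primitiveGene(id, L, prims)
}

# small shared fixture: pool, fitness, normalized parents and context
makeMiniStudy <- function(poolSize = 120, nParents = 20, seed = 42) {
  cfg <- seedConfig(poolSize = poolSize, seed = seed)
  pool <- generatePool(cfg)
  rec <- syntheticAlp(pool, cfg)
  norm <- normalizePool(pool)
  names(norm) <- vapply(norm, designId, character(1))
  nr <- rec[rec$designId %in% names(norm), ]
  parents <- norm[head(nr$designId[order(-nr$alpIntensity, nr$designId)],
                       nParents)]
  ctx <- selectionContext(nr[nr$designId %in% names(parents), ],
                          similarityMatrix(lapply(parents, rasterize)))
  list(cfg = cfg, pool = pool, records = rec, normalized = norm,
       parents = parents, context = ctx)
}
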