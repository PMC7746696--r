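geneMatrix <- function(genes) {
  p <- length(genes[[1]]@bits)
  X <- t(vapply(genes, function(g) as.double(flattenGene(g)), double(p)))
  rownames(X) <- vapply(genes, designId, character(1))
  X
}

# dual (Gram-matrix) PCA of rows of X: returns loadings (p x k), scores
# (n x k) and variances, with the deterministic sign convention that the
# largest-magnitude loading of each component is positive
dualPCA <- function(X, k) {
  n <- nrow(X)
  mu <- colMeans(X)
  Xc <- sweep(X, 2, mu)
  K <- tcrossprod(Xc)
  e <- eigen(K, symmetric = TRUE)
  lam <- pmax(e$values, 0)
  k <- min(k, n - 1L)
  V <- matrix(0, ncol(X), k)
  S <- matrix(0, n, k)
  for (j in seq_len(k)) {
    if (lam[j] > 1e-12 * max(lam[1], 1)) {
      v <- crossprod(Xc, e$vectors[, j]) / sqrt(lam[j])
      if (v[which.max(abs(v))] < 0) v <- -v
      V[, j] <- v
      S[, j] <- Xc %*% v
    }
  }
  rownames(S) <- rownames(X)
  list(loadings = V, scores = S, variance = lam[seq_len(k)] / (n - 1),
       mean = mu)
}

#' Eigenimage PCA of a pattern library
#'
#' Principal component analysis of the mean-centered flattened rasters,
#' computed by the dual (Gram-matrix) route, with each component reshaped
#' back to image form -- the "eigenimages" of the library, the direct
#' analogue of eigenfaces. Every design is reconstructed as the mean image
#' plus its weighted sum of eigenimages; the weights are returned per
#' design.
#'
#' @param genes list of \linkS4class{PixelGene} objects of identical shape
#'   (primitive genes are rasterized first); at least
#'   \code{nComponents + 1}.
#' @param nComponents number of eigenimages to return (e.g. 7).
#' @return an \linkS4class{EigenimageSet}.
#' @export
#' @seealso [embedLibrary()]
pcaEigenimages <- function(genes, nComponents) {
  genes <- lapply(genes, rasterize)
  if (length(genes) < nComponents + 1L)
    stop("need at least nComponents + 1 designs")
  X <- geneMatrix(genes)
  pc <- dualPCA(X, nComponents)
  if (sum(pc$variance) <= 1e-12)
    warning("library has zero total variance (all designs identical); ",
            "eigenimages are degenerate")
  side <- nrow(genes[[1]]@bits)
  comps <- lapply(seq_len(ncol(pc$loadings)), function(j)
    matrix(pc$loadings[, j], side, side, byrow = TRUE))
  new("EigenimageSet", components = comps,
      explainedVariance = pc$variance,
      meanImage = matrix(pc$mean, side, side, byrow = TRUE),
      weights = pc$scores)
}

#' Pixel-occupancy map of a design group
#'
#' Entrywise sum of the binary rasters of a group: the value at (i, j) is
#' the number of designs carrying material at that pixel. Used to compare
#' how different library groups (first generation, pixel children,
#' primitive children, ...) populate the feature frame.
#'
#' @param genes non-empty list of \linkS4class{PixelGene} objects (or
#'   primitive genes, rasterized first) of identical shape.
#' @param groupLabel optional label attached as an attribute.
#' @return integer count matrix of the raster shape.
#' @export
occupancyMap <- function(genes, groupLabel = NULL) {
  if (!length(genes)) stop("empty design group")
  genes <- lapply(genes, rasterize)
  m <- Reduce(`+`, lapply(genes, function(g) g@bits))
  if (!is.null(groupLabel)) attr(m, "group") <- groupLabel
  m
}

## ---- exact t-SNE (small libraries) ------------------------------------

# conditional affinities at a fixed perplexity via per-point binary search
tsneAffinities <- function(D2, perplexity) {
  n <- nrow(D2)
  target <- log(perplexity)
  P <- matrix(0, n, n)
  for (i in seq_len(n)) {
    di <- D2[i, -i]
    lo <- -Inf; hi <- Inf; beta <- 1
    for (it in 1:64) {
      w <- exp(-di * beta)
      sw <- sum(w)
      if (sw <= 0) { H <- 0 } else {
        pj <- w / sw
        H <- -sum(pj[pj > 0] * log(pj[pj > 0]))
      }
      if (abs(H - target) < 1e-5) break
      if (H > target) { lo <- beta; beta <- if (is.finite(hi)) (beta + hi) / 2 else beta * 2 }
      else { hi <- beta; beta <- if (is.finite(lo)) (beta + lo) / 2 else beta / 2 }
    }
    P[i, -i] <- w / max(sum(w), .Machine$double.eps)
  }
  P <- (P + t(P)) / (2 * n)
  pmax(P, 1e-12)
}

tsneExact <- function(X, seed, perplexity = 30, maxIter = 600,
                      eta = NULL) {
  n <- nrow(X)
  perplexity <- max(2, min(perplexity, (n - 1) / 3))
  if (is.null(eta)) eta <- max(2, n / 4)   # small libraries need cool steps
  D2 <- as.matrix(stats::dist(X))^2
  P <- tsneAffinities(D2, perplexity)
  withSeed(seed, {
    Y <- matrix(stats::rnorm(n * 2, sd = 1e-4), n, 2)
    dY <- matrix(0, n, 2)
    gains <- matrix(1, n, 2)
    for (iter in seq_len(maxIter)) {
      Pe <- if (iter <= 100) P * 12 else P       # early exaggeration
      sq <- rowSums(Y^2)
      num <- 1 / (1 + outer(sq, sq, `+`) - 2 * tcrossprod(Y))
      diag(num) <- 0
      Q <- num / sum(num)
      L <- (Pe - pmax(Q, 1e-12)) * num
      grad <- 4 * (diag(rowSums(L)) - L) %*% Y
      gains <- pmax(0.01, ifelse(sign(grad) != sign(dY),
                                 gains + 0.2, gains * 0.8))
      mom <- if (iter < 250) 0.5 else 0.8
      dY <- mom * dY - eta * gains * grad
      Y <- Y + dY
      Y <- sweep(Y, 2, colMeans(Y))
    }
    Y
  })
}

#' Two-dimensional embedding of a design library
#'
#' Reduces the flattened rasters by PCA (dual route) to at most
#' \code{nPcs} components, then embeds the scores in 2D with a seeded exact
#' t-SNE (perplexity 30 by default, capped for small libraries). Identical
#' designs map to coincident points; the embedding is reproducible under
#' the seed.
#'
#' @param genes list of \linkS4class{PixelGene} (or primitive) designs.
#' @param nPcs number of principal components fed to t-SNE (default 5000;
#'   capped at the library size minus one).
#' @param seed integer seed.
#' @param perplexity t-SNE perplexity.
#' @param meta optional data.frame of per-design metadata (e.g. category),
#'   cbind-ed to the coordinates.
#' @return data.frame with \code{designId}, \code{x}, \code{y} (plus
#'   \code{meta} columns).
#' @export
embedLibrary <- function(genes, nPcs = 5000L, seed = 1L, perplexity = 30,
                         meta = NULL) {
  if (length(genes) < 3L) stop("need at least 3 designs to embed")
  genes <- lapply(genes, rasterize)
  X <- geneMatrix(genes)
  k <- min(nPcs, nrow(X) - 1L, ncol(X))
  pc <- dualPCA(X, k)
  Y <- tsneExact(pc$scores, seed = seed, perplexity = perplexity)
  out <- data.frame(designId = rownames(X), x = Y[, 1], y = Y[, 2],
                    stringsAsFactors = FALSE)
  if (!is.null(meta)) out <- cbind(out, meta)
  rownames(out) <- NULL
  out
}

#' Parent and progeny accounting from lineage records
#'
#' Summarizes a breeding run's provenance: how many crossover children each
#' parent produced, the ordered parent-pair count matrix, the number of
#' unique pairs realized, and the theoretical maximum (pool size squared).
#'
#' @param lineage lineage data.frame from a \linkS4class{CandidateArchive}
#'   (elite rows are ignored).
#' @param parentIds ids defining the pool (default: all parents seen).
#' @return list with \code{progenyPerParent} (named integer vector),
#'   \code{pairMatrix} (ordered pairs, rows = parent A), \code{uniquePairs},
#'   \code{theoreticalMax} and \code{crossoverChildren}.
#' @export
parentProgenyStats <- function(lineage, parentIds = NULL) {
  if (!nrow(lineage)) stop("empty lineage")
  cx <- lineage[!lineage$elite, , drop = FALSE]
  if (is.null(parentIds))
    parentIds <- sort(unique(c(cx$parentA, cx$parentB)))
  M <- matrix(0L, length(parentIds), length(parentIds),
              dimnames = list(parentIds, parentIds))
  for (r in seq_len(nrow(cx)))
    M[cx$parentA[r], cx$parentB[r]] <- M[cx$parentA[r], cx$parentB[r]] + 1L
  prog <- vapply(parentIds, function(p)
    sum(cx$parentA == p | cx$parentB == p), integer(1))
  list(progenyPerParent = prog, pairMatrix = M,
       uniquePairs = sum(M > 0L),
       theoreticalMax = length(parentIds) * length(parentIds),
       crossoverChildren = nrow(cx))
}

#' Frequency table of selection-algorithm usage
#'
#' @param lineage lineage data.frame.
#' @return data.frame of algorithm name vs number of placed/generated
#'   children, split by representation.
#' @export
selectionUsage <- function(lineage) {
  cx <- lineage[!lineage$elite, , drop = FALSE]
  as.data.frame(table(algorithm = cx$selectionAlgorithm,
                      representation = cx$representation),
                stringsAsFactors = FALSE)
}
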