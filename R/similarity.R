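# correlation of binary vectors from sufficient statistics:
# n, sums sa/sb and the dot product d; zero variance -> 0 by convention
binaryCor <- function(n, sa, sb, d) {
  # promote to double (dim-preserving) to avoid integer overflow
  n <- n * 1.0; sa <- sa * 1.0; sb <- sb * 1.0; d <- d * 1.0
  va <- n * sa - sa * sa
  vb <- n * sb - sb * sb
  r <- (n * d - sa * sb) / sqrt(va * vb)
  r[va <= 0 | vb <= 0] <- 0
  r
}

#' Pearson similarity between two pixel genes
#'
#' The similarity between two feature designs is the sample Pearson
#' correlation of their flattened binary rasters. For a zero-variance raster
#' (all 0 or all 1) the correlation is undefined and is returned as 0, so
#' flat candidates register as maximally dissimilar; set
#' \code{zeroVariance} to change that convention.
#'
#' @param a,b \linkS4class{PixelGene} objects of identical shape.
#' @param zeroVariance value returned when either raster has zero variance.
#' @return a number in \[-1, 1\].
#' @export
#' @examples
#' g <- pixelGene("g", diag(4L))
#' pearsonSimilarity(g, g)
#' pearsonSimilarity(g, pixelGene("h", 1L - diag(4L)))
pearsonSimilarity <- function(a, b, zeroVariance = 0) {
  if (!identical(dim(a@bits), dim(b@bits)))
    stop("genes must have identical raster shape")
  n <- length(a@bits)
  sa <- sum(a@bits); sb <- sum(b@bits)
  if (sa %in% c(0L, n) || sb %in% c(0L, n)) return(zeroVariance)
  binaryCor(n, sa, sb, sum(a@bits * b@bits))
}

#' Pairwise similarity matrix of a design set
#'
#' @param genes list of \linkS4class{PixelGene} objects of identical shape.
#' @return symmetric numeric matrix with design ids as dimnames; unit
#'   diagonal for non-degenerate genes.
#' @export
similarityMatrix <- function(genes) {
  ids <- vapply(genes, designId, character(1))
  X <- vapply(genes, function(g) as.double(g@bits), double(length(genes[[1]]@bits)))
  n <- nrow(X)
  s <- colSums(X)
  D <- crossprod(X)
  S <- binaryCor(n, matrix(s, length(s), length(s)),
                 matrix(s, length(s), length(s), byrow = TRUE), D)
  ok <- s > 0 & s < n
  diag(S) <- ifelse(ok, 1, 0)
  dimnames(S) <- list(ids, ids)
  S
}

#' Total similarity of one design to the rest of its set
#'
#' The per-design diversity score used by the multi-objective selection
#' algorithms: the sum of absolute Pearson similarities of one design to
#' every other design (diagonal excluded). Low total similarity marks a
#' design that adds diversity.
#'
#' @param id design identifier present in the matrix.
#' @param similarity matrix from [similarityMatrix()].
#' @return nonnegative number.
#' @export
totalSimilarity <- function(id, similarity) {
  if (!id %in% rownames(similarity))
    stop("unknown design id: ", id)
  row <- similarity[id, ]
  sum(abs(row[names(row) != id]))
}

#' @rdname totalSimilarity
#' @param ids optional subset of ids (default all).
#' @return \code{totalSimilarityAll}: named numeric vector.
#' @export
totalSimilarityAll <- function(similarity, ids = rownames(similarity)) {
  tot <- rowSums(abs(similarity)) - abs(diag(similarity))
  tot[ids]
}

#' Greedy half-similar / half-dissimilar diversity filter
#'
#' Streams candidate designs in order and tests each against the designs
#' already accepted. A candidate whose maximum absolute correlation to all
#' accepted designs is below \code{dissimilarThreshold} joins the dissimilar
#' pool; failing that, below \code{similarThreshold} it joins the similar
#' pool; otherwise it is rejected. Each pool holds half the quota (an odd
#' quota gives the dissimilar pool the extra slot); when the dissimilar pool
#' is full a sub-threshold candidate falls through to the similar pool. The
#' scan stops when both pools are full or the stream is exhausted (the
#' latter with a warning and a partial result).
#'
#' Comparisons use the absolute correlation by default
#' (\code{useAbs = FALSE} switches to signed). Only the accepted set is
#' compared against; \code{reference} optionally adds fixed designs (e.g.
#' the parents) to the comparison set without consuming quota.
#'
#' @param candidates list of genes (primitive genes are rasterized on the
#'   fly), or a zero-argument function returning the next gene or
#'   \code{NULL} when exhausted.
#' @param quota total number of designs to accept.
#' @param dissimilarThreshold,similarThreshold admission thresholds on the
#'   max absolute correlation (defaults 0.5 and 0.9).
#' @param useAbs compare \code{|r|} (default) or signed \code{r}.
#' @param reference optional list of \linkS4class{PixelGene} compared
#'   against but never accepted.
#' @param accept optional predicate \code{function(PixelGene) -> logical};
#'   a candidate passing the similarity rule but failing the predicate is
#'   rejected before consuming a quota slot (used for the manufacturability
#'   screen during chip assembly).
#' @param blockSize internal batching width for the BLAS-based correlation
#'   computation; does not affect results.
#' @return list with \code{selection} (data.frame: designId, pool, the
#'   admission-time max absolute correlation \code{maxAbsCor}, and the
#'   1-based stream index) and \code{genes} (the accepted
#'   \linkS4class{PixelGene} objects, in admission order).
#' @export
diversityFilter <- function(candidates, quota,
                            dissimilarThreshold = 0.5,
                            similarThreshold = 0.9,
                            useAbs = TRUE, reference = NULL,
                            accept = NULL, blockSize = 64L) {
  stopifnot(quota >= 1,
            dissimilarThreshold > 0, similarThreshold < 1,
            dissimilarThreshold < similarThreshold)
  qd <- as.integer(ceiling(quota / 2)); qs <- as.integer(quota) - qd

  nextGene <- if (is.function(candidates)) {
    candidates
  } else {
    i <- 0L
    function() {
      i <<- i + 1L
      if (i > length(candidates)) NULL else candidates[[i]]
    }
  }

  npix <- NULL
  chunkW <- 256L
  chunks <- list()          # finalized 40000 x chunkW accepted blocks
  cur <- NULL; curN <- 0L   # growing block
  sAcc <- numeric(0)        # accepted column sums (chunks then cur)
  nd <- 0L; ns <- 0L
  outId <- character(0); outPool <- character(0)
  outCor <- numeric(0); outIdx <- integer(0)
  genes <- vector("list", qd + qs); nAcc <- 0L

  refX <- NULL; sRef <- numeric(0)
  if (length(reference)) {
    refX <- vapply(reference, function(g) as.double(g@bits),
                   double(length(reference[[1]]@bits)))
    sRef <- colSums(refX)
  }

  commit <- function(v, g) {
    if (is.null(cur)) cur <<- matrix(0, npix, chunkW)
    curN <<- curN + 1L
    cur[, curN] <<- v
    if (curN == chunkW) { chunks[[length(chunks) + 1L]] <<- cur; cur <<- NULL; curN <<- 0L }
    sAcc <<- c(sAcc, sum(v))
    nAcc <<- nAcc + 1L
    genes[[nAcc]] <<- g
  }

  streamIdx <- 0L
  exhausted <- FALSE
  while (!exhausted && (nd < qd || ns < qs)) {
    # pull a block of candidates
    block <- list(); idx <- integer(0)
    while (length(block) < blockSize) {
      g <- nextGene()
      if (is.null(g)) { exhausted <- TRUE; break }
      streamIdx <- streamIdx + 1L
      block[[length(block) + 1L]] <- rasterize(g)
      idx <- c(idx, streamIdx)
    }
    if (!length(block)) break
    if (is.null(npix)) npix <- length(block[[1]]@bits)
    X <- vapply(block, function(g) as.double(g@bits), double(npix))
    sX <- colSums(X)

    # dot products against all committed designs (chunked dgemm)
    D <- NULL
    if (length(chunks))
      D <- do.call(rbind, lapply(chunks, function(ch) crossprod(ch, X)))
    if (curN > 0L)
      D <- rbind(D, crossprod(cur[, seq_len(curN), drop = FALSE], X))
    Dref <- if (!is.null(refX)) crossprod(refX, X) else NULL
    W <- crossprod(X)   # within-block dot products

    blockAccepted <- integer(0)  # block-local column indices committed
    for (j in seq_along(block)) {
      if (nd >= qd && ns >= qs) break
      a0 <- length(sAcc) - length(blockAccepted)  # accepted before block
      rs <- numeric(0)
      if (a0 > 0L)
        rs <- binaryCor(npix, sAcc[seq_len(a0)], sX[j], D[seq_len(a0), j])
      if (length(blockAccepted))
        rs <- c(rs, binaryCor(npix, sX[blockAccepted], sX[j],
                              W[blockAccepted, j]))
      if (!is.null(Dref))
        rs <- c(rs, binaryCor(npix, sRef, sX[j], Dref[, j]))
      if (useAbs) rs <- abs(rs)
      mx <- if (length(rs)) max(rs) else -Inf
      pool <- if (mx < dissimilarThreshold && nd < qd) "dissimilar"
              else if (mx < similarThreshold && ns < qs) "similar"
              else NA_character_
      if (is.na(pool)) next
      g <- block[[j]]
      if (!is.null(accept) && !isTRUE(accept(g))) next
      if (pool == "dissimilar") nd <- nd + 1L else ns <- ns + 1L
      commit(X[, j], g)
      blockAccepted <- c(blockAccepted, j)
      outId <- c(outId, designId(g)); outPool <- c(outPool, pool)
      outCor <- c(outCor, mx); outIdx <- c(outIdx, idx[j])
    }
  }
  if (nd < qd || ns < qs)
    warning(sprintf(
      "candidate stream exhausted before quota: %d/%d dissimilar, %d/%d similar",
      nd, qd, ns, qs))
  list(selection = data.frame(designId = outId, pool = outPool,
                              maxAbsCor = outCor, streamIndex = outIdx,
                              stringsAsFactors = FALSE),
       genes = genes[seq_len(nAcc)])
}

#' Export a similarity matrix as CSV
#'
#' @param similarity matrix from [similarityMatrix()].
#' @param path output file.
#' @return \code{path}, invisibly.
#' @export
writeSimilarityCSV <- function(similarity, path) {
  utils::write.csv(as.data.frame(similarity), path, row.names = TRUE)
  invisible(path)
}
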