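SELECTION_ALGORITHMS <- c("Roulette", "Random", "Tournament", "NSGA2",
                          "Best", "Worst", "SPEA2")

#' Build a selection context
#'
#' @param records data.frame with columns \code{designId},
#'   \code{alpIntensity}.
#' @param similarity optional similarity matrix over (at least) the same
#'   ids, required by the multi-objective algorithms NSGA2 and SPEA2.
#' @return a \linkS4class{SelectionContext}.
#' @export
selectionContext <- function(records, similarity = matrix(numeric(), 0, 0)) {
  new("SelectionContext",
      records = data.frame(designId = as.character(records$designId),
                           alpIntensity = as.numeric(records$alpIntensity),
                           stringsAsFactors = FALSE),
      similarity = similarity)
}

#' Select the high-fitness parent pool by percentile
#'
#' Parents are the designs whose ALP mean integrated intensity is strictly
#' greater than the stated percentile (default 95) of all intensities. With
#' continuous intensities this yields approximately the top 5 percent of the
#' pool. Returns an empty pool with a warning when no intensity exceeds the
#' threshold (e.g. all intensities tied).
#'
#' @param records fitness data.frame (\code{designId}, \code{alpIntensity}).
#' @param percentile threshold percentile in (0, 100).
#' @return character vector of parent design ids, ordered by decreasing
#'   intensity (ties broken by id).
#' @export
#' @examples
#' rec <- data.frame(designId = sprintf("d%03d", 1:100), alpIntensity = 1:100)
#' selectParentPool(rec)  # the 5 designs above the 95th percentile
selectParentPool <- function(records, percentile = 95) {
  if (!nrow(records)) stop("empty fitness table")
  stopifnot(percentile > 0, percentile < 100)
  thr <- stats::quantile(records$alpIntensity, percentile / 100,
                         names = FALSE)
  keep <- records$alpIntensity > thr
  if (!any(keep)) {
    warning("no intensity exceeds the ", percentile, "th percentile")
    return(character(0))
  }
  sel <- records[keep, ]
  sel$designId[order(-sel$alpIntensity, sel$designId)]
}

# Pareto helpers on objective matrix F (rows = designs, both minimized)
dominates <- function(F, i, j) {
  all(F[i, ] <= F[j, ]) && any(F[i, ] < F[j, ])
}

# fast non-dominated sort; returns integer front index per design
nonDominatedFronts <- function(F) {
  n <- nrow(F)
  ndom <- integer(n)
  domSet <- vector("list", n)
  for (i in seq_len(n)) {
    for (j in seq_len(n)) {
      if (i == j) next
      if (dominates(F, i, j)) domSet[[i]] <- c(domSet[[i]], j)
      else if (dominates(F, j, i)) ndom[i] <- ndom[i] + 1L
    }
  }
  front <- integer(n)
  current <- which(ndom == 0L)
  f <- 1L
  while (length(current)) {
    front[current] <- f
    nxt <- integer(0)
    for (i in current) for (j in domSet[[i]]) {
      ndom[j] <- ndom[j] - 1L
      if (ndom[j] == 0L) nxt <- c(nxt, j)
    }
    current <- unique(nxt)
    f <- f + 1L
  }
  front
}

crowdingDistance <- function(F) {
  n <- nrow(F)
  d <- numeric(n)
  for (m in seq_len(ncol(F))) {
    o <- order(F[, m])
    d[o[c(1, n)]] <- Inf
    rng <- F[o[n], m] - F[o[1], m]
    if (n > 2 && rng > 0)
      d[o[2:(n - 1)]] <- d[o[2:(n - 1)]] +
        (F[o[3:n], m] - F[o[1:(n - 2)], m]) / rng
  }
  d
}

# objective matrix: minimize (-ALP, total similarity)
objectiveMatrix <- function(context, ids) {
  rec <- context@records
  alp <- rec$alpIntensity[match(ids, rec$designId)]
  if (!length(context@similarity))
    stop("NSGA2/SPEA2 require a similarity matrix in the context")
  ts <- totalSimilarityAll(context@similarity, ids)
  cbind(-alp, ts)
}

nsga2Select <- function(context, ids, k) {
  F <- objectiveMatrix(context, ids)
  front <- nonDominatedFronts(F)
  sel <- character(0)
  for (f in sort(unique(front))) {
    members <- which(front == f)
    if (length(sel) + length(members) <= k) {
      sel <- c(sel, ids[members][order(ids[members])])
    } else {
      cd <- crowdingDistance(F[members, , drop = FALSE])
      o <- order(-cd, ids[members])
      sel <- c(sel, ids[members][o][seq_len(k - length(sel))])
    }
    if (length(sel) >= k) break
  }
  sel
}

spea2Select <- function(context, ids, k) {
  F <- objectiveMatrix(context, ids)
  n <- nrow(F)
  S <- integer(n)                     # strength: count dominated
  dom <- matrix(FALSE, n, n)
  for (i in seq_len(n)) for (j in seq_len(n))
    if (i != j && dominates(F, i, j)) { dom[i, j] <- TRUE; S[i] <- S[i] + 1L }
  R <- vapply(seq_len(n), function(j) sum(S[dom[, j]]), numeric(1))
  # density: k-th nearest neighbour in normalized objective space
  Fs <- apply(F, 2, function(x) {
    r <- diff(range(x)); if (r > 0) (x - min(x)) / r else x * 0
  })
  Dist <- as.matrix(stats::dist(Fs))
  kk <- max(1L, as.integer(round(sqrt(n))))
  sigma <- apply(Dist, 1, function(d) sort(d)[min(kk + 1L, n)])
  fit <- R + 1 / (sigma + 2)
  nondom <- which(fit < 1)
  if (length(nondom) >= k) {
    # environmental truncation: iteratively drop the most crowded
    keep <- nondom
    while (length(keep) > k) {
      sub <- Dist[keep, keep, drop = FALSE]
      diag(sub) <- Inf
      nearest <- apply(sub, 1, min)
      drop <- which(nearest == min(nearest))
      drop <- drop[order(ids[keep][drop])][1]  # deterministic tie-break
      keep <- keep[-drop]
    }
    ids[keep][order(ids[keep])]
  } else {
    o <- order(fit, ids)
    ids[o][seq_len(k)]
  }
}

#' Select parents with one of the seven selection algorithms
#'
#' \describe{
#'   \item{Best / Worst}{the k highest / lowest ALP intensities (ties broken
#'     by design id).}
#'   \item{Random}{uniform sample without replacement.}
#'   \item{Roulette}{fitness-proportional sampling without replacement;
#'     nonpositive intensities are shifted above zero first.}
#'   \item{Tournament}{k tournaments of \code{tournamentSize} designs, each
#'     won by the highest intensity; winners are removed from the pool so
#'     the k selected ids are distinct.}
#'   \item{NSGA2 / SPEA2}{canonical non-dominated selection on two
#'     objectives, maximize ALP intensity and minimize total Pearson
#'     similarity (NSGA-II crowding distance; SPEA2 strength/raw fitness
#'     with nearest-neighbour density and environmental truncation).}
#' }
#'
#' @param algorithm one of \code{Roulette}, \code{Random}, \code{Tournament},
#'   \code{NSGA2}, \code{Best}, \code{Worst}, \code{SPEA2}.
#' @param context a \linkS4class{SelectionContext}.
#' @param k number of parents to select (default 10).
#' @param seed integer seed for the stochastic algorithms.
#' @param tournamentSize tournament size (default 3).
#' @param ids optional subset of the context's designs to select from.
#' @return character vector of k distinct design ids.
#' @export
selectParents <- function(algorithm, context, k = 10L, seed = 1L,
                          tournamentSize = 3L,
                          ids = context@records$designId) {
  if (!algorithm %in% SELECTION_ALGORITHMS)
    stop("unknown selection algorithm: ", algorithm)
  rec <- context@records
  ids <- as.character(ids)
  if (!all(ids %in% rec$designId)) stop("ids absent from context records")
  if (k > length(ids)) stop("k exceeds the candidate pool")
  alp <- rec$alpIntensity[match(ids, rec$designId)]
  o <- switch(algorithm,
    Best  = ids[order(-alp, ids)][seq_len(k)],
    Worst = ids[order(alp, ids)][seq_len(k)],
    Random = withSeed(seed, sample(ids, k)),
    Roulette = withSeed(seed, {
      w <- alp
      if (any(w <= 0)) w <- w - min(w) + 1e-6 * max(diff(range(w)), 1)
      pool <- ids; pw <- w; out <- character(0)
      for (i in seq_len(k)) {
        pick <- sample.int(length(pool), 1L, prob = pw)
        out <- c(out, pool[pick])
        pool <- pool[-pick]; pw <- pw[-pick]
      }
      out
    }),
    Tournament = withSeed(seed, {
      pool <- ids; pa <- alp; out <- character(0)
      for (i in seq_len(k)) {
        m <- min(tournamentSize, length(pool))
        cand <- sample.int(length(pool), m)
        win <- cand[order(-pa[cand], pool[cand])][1]
        out <- c(out, pool[win])
        pool <- pool[-win]; pa <- pa[-win]
      }
      out
    }),
    NSGA2 = nsga2Select(context, ids, k),
    SPEA2 = spea2Select(context, ids, k))
  o
}

#' Draw a selection algorithm uniformly at random
#'
#' Each breeding cycle picks its selection algorithm by a uniform draw over
#' the seven registered names; the draw is logged in the cycle's lineage.
#'
#' @param seed integer seed.
#' @return one algorithm name.
#' @export
pickSelectionAlgorithm <- function(seed) {
  withSeed(seed, sample(SELECTION_ALGORITHMS, 1L))
}

#' Registered selection algorithm names
#' @return character vector of the seven names.
#' @export
selectionAlgorithms <- function() SELECTION_ALGORITHMS
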