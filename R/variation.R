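## ---- pixel morphology helpers ----------------------------------------

shiftMat <- function(m, dr, dc, fill = 0L) {
  n <- nrow(m); p <- ncol(m)
  out <- matrix(fill, n, p)
  rs <- seq_len(n) - dr; cs <- seq_len(p) - dc
  ok_r <- rs >= 1 & rs <= n; ok_c <- cs >= 1 & cs <= p
  out[ok_r, ok_c] <- m[rs[ok_r], cs[ok_c]]
  out
}

dilate3x3 <- function(m) {
  out <- m
  for (dr in -1:1) for (dc in -1:1)
    if (dr || dc) out <- pmax(out, shiftMat(m, dr, dc))
  out
}

erode3x3 <- function(m) {
  out <- m
  for (dr in -1:1) for (dc in -1:1)
    if (dr || dc) out <- pmin(out, shiftMat(m, dr, dc, fill = 0L))
  out
}

# pixels adjacent to the material/void boundary (either side)
boundaryBand <- function(m) dilate3x3(m) != erode3x3(m)

discMask <- function(n, cr, cc, radius) {
  R <- matrix(seq_len(n), n, n)
  C <- matrix(seq_len(n), n, n, byrow = TRUE)
  (R - cr)^2 + (C - cc)^2 <= radius^2
}

# enforce the changed-fraction bound: revert a random subset of the
# changed pixels so that at most floor(rate * npix) differ from `old`
capChanges <- function(old, new, rate) {
  changed <- which(new != old)
  cap <- floor(rate * length(old))
  if (length(changed) > cap) {
    keep <- if (cap > 0) sample(changed, cap) else integer(0)
    revert <- setdiff(changed, keep)
    new[revert] <- old[revert]
  }
  new
}

## ---- pixel crossover registry ----------------------------------------
# Each operator takes two bit matrices (RNG already seeded) and returns the
# child's bit matrix. All are mask-based, so identical parents reproduce
# themselves exactly. Registry order is the package's diversity ladder: the
# expected child-parent Hamming distance grows down the list.

pixelCrossoverOps <- list(
  onePoint = function(A, B) {
    fa <- as.integer(t(A)); fb <- as.integer(t(B))
    k <- sample(0:length(fa), 1L)
    v <- c(fa[seq_len(k)], fb[seq_len(length(fb) - k) + k])
    matrix(v, nrow(A), ncol(A), byrow = TRUE)
  },
  twoPoint = function(A, B) {
    fa <- as.integer(t(A)); fb <- as.integer(t(B))
    ks <- sort(sample(0:length(fa), 2L))
    v <- fa
    if (ks[2] > ks[1]) {
      idx <- (ks[1] + 1L):ks[2]
      v[idx] <- fb[idx]
    }
    matrix(v, nrow(A), ncol(A), byrow = TRUE)
  },
  horizontalHalf = function(A, B) {
    h <- nrow(A) %/% 2L
    rbind(A[seq_len(h), , drop = FALSE],
          B[(h + 1L):nrow(B), , drop = FALSE])
  },
  verticalHalf = function(A, B) {
    h <- ncol(A) %/% 2L
    cbind(A[, seq_len(h), drop = FALSE],
          B[, (h + 1L):ncol(B), drop = FALSE])
  },
  quadrantSwap = function(A, B) {
    n <- nrow(A); h <- n %/% 2L
    src <- sample(c(TRUE, FALSE), 4L, replace = TRUE)  # TRUE = from B
    out <- A
    qs <- list(list(1:h, 1:h), list(1:h, (h + 1L):n),
               list((h + 1L):n, 1:h), list((h + 1L):n, (h + 1L):n))
    for (q in seq_len(4L)) if (src[q])
      out[qs[[q]][[1]], qs[[q]][[2]]] <- B[qs[[q]][[1]], qs[[q]][[2]]]
    out
  },
  blockMosaic = function(A, B) {
    n <- nrow(A); g <- 4L
    cuts <- round(seq(0, n, length.out = g + 1L))
    src <- matrix(sample(c(TRUE, FALSE), g * g, replace = TRUE), g, g)
    out <- A
    for (i in seq_len(g)) for (j in seq_len(g)) if (src[i, j]) {
      ri <- (cuts[i] + 1L):cuts[i + 1L]; cj <- (cuts[j] + 1L):cuts[j + 1L]
      out[ri, cj] <- B[ri, cj]
    }
    out
  },
  uniformPixel = function(A, B) {
    mask <- matrix(stats::runif(length(A)) < 0.5, nrow(A))
    out <- A
    out[mask] <- B[mask]
    out
  },
  connectedMaskBlend = function(A, B) {
    n <- nrow(A)
    mask <- matrix(FALSE, n, n)
    for (i in seq_len(3L))
      mask <- mask | discMask(n, stats::runif(1, 1, n), stats::runif(1, 1, n),
                              stats::runif(1, 0.1 * n, 0.35 * n))
    out <- A
    out[mask] <- B[mask]
    out
  }
)

## ---- primitive crossover registry ------------------------------------

primKey <- function(p) {
  paste(p@kind, paste(round(p@points, 9), collapse = ","),
        paste(round(p@radius, 9), collapse = ","),
        paste(round(p@strokeWidth, 9), collapse = ","))
}

primCentroid <- function(p) colMeans(p@points)

primitiveCrossoverOps <- list(
  onePoint = function(pa, pb, L) {
    k <- sample(0:max(length(pa), length(pb)), 1L)
    head_a <- pa[seq_len(min(k, length(pa)))]
    tail_b <- if (k < length(pb)) pb[(k + 1L):length(pb)] else list()
    c(head_a, tail_b)
  },
  twoPoint = function(pa, pb, L) {
    n <- max(length(pa), length(pb))
    ks <- sort(sample(0:n, 2L))
    seg <- function(pp, from, to)
      if (from <= min(to, length(pp)) && from <= length(pp))
        pp[from:min(to, length(pp))] else list()
    c(seg(pa, 1L, ks[1]), seg(pb, ks[1] + 1L, ks[2]),
      seg(pa, ks[2] + 1L, length(pa)))
  },
  typeStratified = function(pa, pb, L) {
    kind <- sample(PRIMITIVE_KINDS, 1L)
    ia <- which(vapply(pa, function(p) p@kind, character(1)) == kind)
    donors <- pb[vapply(pb, function(p) p@kind, character(1)) == kind]
    out <- pa
    m <- min(length(ia), length(donors))
    if (m > 0) for (i in seq_len(m)) out[[ia[i]]] <- donors[[i]]
    if (length(donors) > m) out <- c(out, donors[(m + 1L):length(donors)])
    if (length(ia) > m) out <- out[-ia[(m + 1L):length(ia)]]
    out
  },
  spatialHalf = function(pa, pb, L) {
    left <- function(p) primCentroid(p)[1] < L / 2
    c(pa[vapply(pa, left, logical(1))],
      pb[!vapply(pb, left, logical(1))])
  },
  uniformPerPrimitive = function(pa, pb, L) {
    n <- max(length(pa), length(pb))
    pick_b <- stats::runif(n) < 0.5
    out <- list()
    for (i in seq_len(n)) {
      src <- if (pick_b[i]) pb else pa
      alt <- if (pick_b[i]) pa else pb
      if (i <= length(src)) out[[length(out) + 1L]] <- src[[i]]
      else if (i <= length(alt)) out[[length(out) + 1L]] <- alt[[i]]
    }
    out
  },
  countBalancedMerge = function(pa, pb, L) {
    ka <- ceiling(length(pa) / 2)
    kb <- floor(length(pb) / 2)
    c(pa[seq_len(ka)],
      if (kb > 0) pb[(length(pb) - kb + 1L):length(pb)] else list())
  },
  donorSubsetInsertion = function(pa, pb, L) {
    keys <- vapply(pa, primKey, character(1))
    fresh <- pb[!vapply(pb, primKey, character(1)) %in% keys]
    if (length(fresh)) {
      m <- sample(seq_along(fresh), sample(seq_along(fresh), 1L))
      c(pa, fresh[sort(m)])
    } else pa
  },
  shuffleMerge = function(pa, pb, L) {
    keys <- vapply(pa, primKey, character(1))
    merged <- c(pa, pb[!vapply(pb, primKey, character(1)) %in% keys])
    merged[sample(seq_along(merged))]
  }
)

#' Crossover and mutation operator registries
#'
#' Eight crossover operators exist per genome representation, ordered by
#' increasing genetic diversity (expected child-parent Hamming distance).
#' Pixel operators cut through shapes freely (half a raster circle can be
#' inherited); primitive operators exchange whole primitives only. Mutation
#' operators are \code{polygon} (perturb shapes/sizes), \code{deletion},
#' \code{insertion}, and, for rasters only, \code{roughness}.
#'
#' @param representation \code{"pixel"} or \code{"primitive"}.
#' @return character vector of operator names, in diversity order.
#' @export
crossoverOperators <- function(representation = c("pixel", "primitive")) {
  representation <- match.arg(representation)
  names(if (representation == "pixel") pixelCrossoverOps
        else primitiveCrossoverOps)
}

#' @rdname crossoverOperators
#' @export
mutationOperators <- function(representation = c("pixel", "primitive")) {
  representation <- match.arg(representation)
  if (representation == "pixel") c("polygon", "deletion", "insertion", "roughness")
  else c("polygon", "deletion", "insertion")
}

geneRepresentation <- function(gene) {
  if (is(gene, "PixelGene")) "pixel"
  else if (is(gene, "PrimitiveGene")) "primitive"
  else stop("not a topography gene")
}

#' Cross two parent genes
#'
#' Applies a registered crossover operator to two parents of the same
#' representation. Every operator is mask- or position-based, so crossing a
#' gene with itself reproduces the parent design.
#'
#' @param operator operator name from [crossoverOperators()].
#' @param parentA,parentB genes of the same class.
#' @param seed integer seed (all operator randomness is local to the call).
#' @param childId identifier for the child (default
#'   \code{"<A>x<B>"}).
#' @return a child gene of the parents' class.
#' @export
#' @examples
#' a <- pixelGene("a", matrix(1L, 8, 8)); b <- pixelGene("b", matrix(0L, 8, 8))
#' sum(bits(crossoverGene("verticalHalf", a, b, seed = 1)))
crossoverGene <- function(operator, parentA, parentB, seed = 1L,
                          childId = paste0(designId(parentA), "x",
                                           designId(parentB))) {
  rep <- geneRepresentation(parentA)
  if (geneRepresentation(parentB) != rep)
    stop("parents must share a representation")
  if (rep == "pixel") {
    op <- pixelCrossoverOps[[operator]]
    if (is.null(op)) stop("unknown pixel crossover operator: ", operator)
    if (!identical(dim(parentA@bits), dim(parentB@bits)))
      stop("pixel parents must have identical raster shape")
    bitsM <- withSeed(seed, op(parentA@bits, parentB@bits))
    pixelGene(childId, bitsM)
  } else {
    op <- primitiveCrossoverOps[[operator]]
    if (is.null(op)) stop("unknown primitive crossover operator: ", operator)
    if (!isTRUE(all.equal(parentA@featureSize, parentB@featureSize)))
      stop("primitive parents must share a feature size")
    prims <- withSeed(seed, op(parentA@primitives, parentB@primitives,
                               parentA@featureSize))
    primitiveGene(childId, parentA@featureSize, prims,
                  upscale = parentA@upscale)
  }
}

## ---- mutation operators -----------------------------------------------

# random insertable shape with characteristic width `s` um centered at `ctr`;
# rectangles are encoded as two abutting triangles (the primitive alphabet
# has no rectangle kind); returns a list of primitives
newShapePrimitives <- function(kindChoice, s, ctr, L) {
  clamp <- function(v) pmin(L, pmax(0, v))
  if (kindChoice == "C") {
    list(circle(clamp(ctr), s / 2))
  } else if (kindChoice == "T") {
    side <- s * sqrt(3)         # equilateral: incircle diameter = side/sqrt(3)
    ang <- stats::runif(1, 0, 2 * pi) + c(0, 2, 4) * pi / 3
    list(triangle(clamp(ctr + side / sqrt(3) * c(cos(ang[1]), sin(ang[1]))),
                  clamp(ctr + side / sqrt(3) * c(cos(ang[2]), sin(ang[2]))),
                  clamp(ctr + side / sqrt(3) * c(cos(ang[3]), sin(ang[3])))))
  } else {                      # rectangle s x (1..2)s as two triangles
    w <- s; h <- s * stats::runif(1, 1, 2)
    p1 <- clamp(ctr + c(-w, -h) / 2); p2 <- clamp(ctr + c(w, -h) / 2)
    p3 <- clamp(ctr + c(w, h) / 2);   p4 <- clamp(ctr + c(-w, h) / 2)
    list(triangle(p1, p2, p3), triangle(p1, p3, p4))
  }
}

perturbPrimitive <- function(p, L) {
  clamp <- function(v) pmin(L, pmax(0, v))
  shift <- stats::rnorm(2, 0, 0.05 * L)
  if (p@kind == "C") {
    r <- p@radius * stats::runif(1, 0.8, 1.25)
    r <- max(r, min(p@radius, 2.25))   # fabricable circles stay fabricable
    circle(clamp(p@points[1, ] + shift), r)
  } else if (p@kind == "L") {
    w <- p@strokeWidth * stats::runif(1, 0.9, 1.2)
    w <- max(w, min(p@strokeWidth, 4.5))
    jit <- matrix(stats::rnorm(4, 0, 0.02 * L), 2)
    lineSeg(clamp(p@points[1, ] + shift + jit[1, ]),
            clamp(p@points[2, ] + shift + jit[2, ]), w)
  } else {
    # rigid translation keeps the triangle's thickness unchanged
    triangle(clamp(p@points[1, ] + shift), clamp(p@points[2, ] + shift),
             clamp(p@points[3, ] + shift))
  }
}

mutatePixel <- function(operator, bitsM, rate) {
  n <- nrow(bitsM); npix <- length(bitsM)
  new <- switch(operator,
    polygon = {
      region <- discMask(n, stats::runif(1, 1, n), stats::runif(1, 1, n),
                         stats::runif(1, 0.05 * n, 0.3 * n))
      morph <- if (stats::runif(1) < 0.5) dilate3x3(bitsM) else erode3x3(bitsM)
      out <- bitsM
      out[region] <- morph[region]
      out
    },
    deletion = {
      rmax <- sqrt(rate * npix / pi)
      region <- discMask(n, stats::runif(1, 1, n), stats::runif(1, 1, n),
                         stats::runif(1, 0.2, 1) * rmax)
      out <- bitsM
      out[region] <- 0L
      out
    },
    insertion = {
      # inserted elements are pillar-scale (4.5-10 um = 45-100 px at the
      # working pitch); the whole shape must fit the rate budget
      kindChoice <- sample(c("C", "T", "R"), 1L)
      areaFactor <- c(C = pi / 4, T = 3 * sqrt(3) / 4, R = 2)[[kindChoice]]
      sMax <- min(100, sqrt(rate * npix / areaFactor))
      if (sMax < 45) bitsM             # budget below one fabricable pillar
      else {
        s <- stats::runif(1, 45, sMax)
        ctr <- stats::runif(2, s / 2, n - s / 2 + 1)
        prims <- newShapePrimitives(kindChoice, s, ctr, n)
        paintPrimitives(bitsM, prims, scale = 1)
      }
    },
    roughness = {
      band <- which(boundaryBand(bitsM))
      out <- bitsM
      if (length(band)) {
        flips <- band[stats::runif(length(band)) < 0.5]
        out[flips] <- 1L - out[flips]
      }
      out
    },
    stop("unknown pixel mutation operator: ", operator))
  capChanges(bitsM, new, rate)
}

mutatePrimitiveList <- function(operator, prims, rate, L) {
  n <- length(prims)
  switch(operator,
    polygon = {
      k <- floor(rate * n)
      if (k < 1L || n == 0L) return(prims)
      idx <- sample(n, k)
      for (i in idx) prims[[i]] <- perturbPrimitive(prims[[i]], L)
      prims
    },
    deletion = {
      k <- floor(rate * n)
      if (k < 1L || n == 0L) return(prims)
      prims[-sample(n, k)]
    },
    insertion = {
      k <- floor(rate * max(n, 1L))
      if (k < 1L) return(prims)
      added <- 0L
      while (added < k) {
        s <- stats::runif(1, 4.5, 10)
        kindChoice <- sample(c("C", "T", if (k - added >= 2L) "R"), 1L)
        ctr <- pmin(L - s / 2, pmax(s / 2, stats::rnorm(2, L / 2, L / 5)))
        np <- newShapePrimitives(kindChoice, s, ctr, L)
        prims <- c(prims, np)
        added <- added + length(np)
      }
      prims
    },
    roughness = stop("roughness mutation is pixel-only"),
    stop("unknown primitive mutation operator: ", operator))
}

#' Mutate a gene with a registered operator
#'
#' Applies one mutation at a bounded intensity: for pixel genes at most
#' \code{floor(rate * 40000)} pixels change; for primitive genes at most
#' \code{floor(rate * n)} primitives are altered, removed or added. In the
#' \code{rate -> 0} limit every operator is the identity.
#'
#' @param operator name from [mutationOperators()].
#' @param gene a pixel or primitive gene.
#' @param rate upper bound on the altered fraction, in (0, 1].
#' @param seed integer seed.
#' @return a mutated gene of the same class (design id preserved).
#' @export
mutateGene <- function(operator, gene, rate, seed = 1L) {
  stopifnot(rate > 0, rate <= 1)
  if (is(gene, "PixelGene")) {
    bitsM <- withSeed(seed, mutatePixel(operator, gene@bits, rate))
    pixelGene(gene@designId, bitsM)
  } else {
    prims <- withSeed(seed,
      mutatePrimitiveList(operator, gene@primitives, rate, gene@featureSize))
    primitiveGene(gene@designId, gene@featureSize, prims,
                  upscale = gene@upscale)
  }
}

#' Apply a random 0-3 step mutation schedule
#'
#' Draws a mutation count in \{0, 1, 2, 3\} (weights default to
#' \code{c(0.15, 0.6, 0.2, 0.05)}, skewed toward a single mutation), draws
#' that many \emph{distinct} operator types for the gene's representation,
#' and applies them sequentially, each at an intensity drawn uniformly below
#' the regime bound (\code{< 20\%} or \code{< 50\%} of the gene).
#'
#' @param gene a pixel or primitive gene.
#' @param seed integer seed.
#' @param regime per-application rate upper bound, 0.2 or 0.5.
#' @param countWeights probabilities for 0, 1, 2, 3 mutations.
#' @return list with \code{gene} (the mutated gene) and \code{log}
#'   (data.frame of applied \code{operator}, \code{rate}, in order; zero
#'   rows when no mutation was drawn).
#' @export
mutationSchedule <- function(gene, seed, regime = 0.2,
                             countWeights = c(0.15, 0.6, 0.2, 0.05)) {
  stopifnot(regime %in% c(0.2, 0.5) || (regime > 0 && regime <= 1))
  ops <- mutationOperators(geneRepresentation(gene))
  plan <- withSeed(seed, {
    k <- sample(0:3, 1L, prob = countWeights)
    k <- min(k, length(ops))
    chosen <- if (k > 0) sample(ops, k) else character(0)
    data.frame(operator = chosen,
               rate = if (k > 0) pmax(stats::runif(k, 0, regime), 1e-9)
                      else numeric(0),
               stringsAsFactors = FALSE)
  })
  g <- gene
  for (i in seq_len(nrow(plan)))
    g <- mutateGene(plan$operator[i], g, plan$rate[i],
                    seed = deriveSeed(seed, plan$operator[i], i))
  list(gene = g, log = plan)
}
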