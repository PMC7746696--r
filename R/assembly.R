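emptyLineage <- function() {
  data.frame(childId = character(), parentA = character(),
             parentB = character(), selectionAlgorithm = character(),
             crossoverOperator = character(), mutations = character(),
             representation = character(), rateRegime = numeric(),
             cycle = integer(), round = integer(), elite = logical(),
             stringsAsFactors = FALSE)
}

#' Run one breeding cycle
#'
#' One cycle selects 10 parents from the pool with a (randomly drawn or
#' forced) selection algorithm, forms all 10 x 10 ordered parent pairs
#' (self-pairs included), applies one seeded crossover plus a 0-3 step
#' mutation schedule to each pair, and appends the 10 best parents of the
#' pool unchanged (elitism) -- 110 candidates in total, each with a full
#' lineage record.
#'
#' @param parents named list of genes (all pixel or all primitive), names =
#'   design ids; at least 10.
#' @param context \linkS4class{SelectionContext} covering the parent ids.
#' @param seed integer cycle seed; all draws derive from it.
#' @param representation \code{"pixel"} or \code{"primitive"} (must match
#'   the parent genes).
#' @param regime mutation-rate regime (0.2 or 0.5).
#' @param algorithm optional forced selection algorithm; default draws one
#'   uniformly from the seven registered names.
#' @param k number of parents selected per cycle (default 10).
#' @param cycle,round bookkeeping indices recorded in the lineage.
#' @return a \linkS4class{CandidateArchive} of \code{k^2 + k} candidates.
#' @export
breedingCycle <- function(parents, context, seed,
                          representation = c("pixel", "primitive"),
                          regime = 0.2, algorithm = NULL, k = 10L,
                          cycle = 1L, round = 1L) {
  representation <- match.arg(representation)
  if (length(parents) < k) stop("parent pool smaller than k")
  ids <- names(parents)
  if (is.null(algorithm))
    algorithm <- pickSelectionAlgorithm(deriveSeed(seed, "algo", cycle))
  sel <- selectParents(algorithm, context, k = k,
                       seed = deriveSeed(seed, "select", cycle), ids = ids)

  genes <- list(); lin <- list()
  pair <- 0L
  xops <- crossoverOperators(representation)
  for (a in sel) for (b in sel) {
    pair <- pair + 1L
    childId <- sprintf("r%dc%d_%03d", round, cycle, pair)
    op <- xops[[withSeed(deriveSeed(seed, "xop", pair),
                         sample.int(length(xops), 1L))]]
    child <- crossoverGene(op, parents[[a]], parents[[b]],
                           seed = deriveSeed(seed, "xover", pair),
                           childId = childId)
    ms <- mutationSchedule(child, deriveSeed(seed, "mutate", pair),
                           regime = regime)
    genes[[childId]] <- ms$gene
    lin[[pair]] <- data.frame(
      childId = childId, parentA = a, parentB = b,
      selectionAlgorithm = algorithm, crossoverOperator = op,
      mutations = paste(ms$log$operator, collapse = ";"),
      representation = representation, rateRegime = regime,
      cycle = cycle, round = round, elite = FALSE,
      stringsAsFactors = FALSE)
  }
  # elitism: the k best original parents of the pool, unchanged
  rec <- context@records
  alp <- rec$alpIntensity[match(ids, rec$designId)]
  best <- ids[order(-alp, ids)][seq_len(k)]
  for (i in seq_along(best)) {
    childId <- sprintf("r%dc%d_e%02d", round, cycle, i)
    g <- parents[[best[i]]]
    designId(g) <- childId
    genes[[childId]] <- g
    lin[[length(lin) + 1L]] <- data.frame(
      childId = childId, parentA = best[i], parentB = best[i],
      selectionAlgorithm = algorithm, crossoverOperator = "",
      mutations = "", representation = representation,
      rateRegime = regime, cycle = cycle, round = round, elite = TRUE,
      stringsAsFactors = FALSE)
  }
  new("CandidateArchive", genes = genes,
      lineage = do.call(rbind, lin))
}

#' Run generation rounds until a target candidate count
#'
#' Repeats [breedingCycle()] -- alternating pixel- and primitive-based
#' representation at the configured share -- until the archive holds at
#' least \code{targetCandidates}, partitioning the cycles evenly across the
#' stated number of rounds. Each cycle draws its own selection algorithm and
#' mutation-rate regime (uniformly from \code{regimes}).
#'
#' @param parents named list of \linkS4class{PrimitiveGene} parents.
#' @param context \linkS4class{SelectionContext} covering the parent ids.
#' @param targetCandidates archive size to reach (rounded up to whole
#'   cycles of 110).
#' @param rounds number of generation rounds (default 4).
#' @param seed integer run seed.
#' @param pixelShare fraction of cycles bred in pixel representation
#'   (default 0.5).
#' @param regimes mutation-rate regimes sampled per cycle.
#' @param k parents per cycle.
#' @return a \linkS4class{CandidateArchive}.
#' @export
runGeneration <- function(parents, context, targetCandidates,
                          rounds = 4L, seed = 1L, pixelShare = 0.5,
                          regimes = c(0.2, 0.5), k = 10L) {
  stopifnot(targetCandidates >= 1)
  perCycle <- k * k + k
  nCycles <- ceiling(targetCandidates / perCycle)
  perRound <- ceiling(nCycles / rounds)
  parentsPix <- NULL
  # primitive crossover needs a common frame: expand 2x2-flagged designs
  parentsPrim <- lapply(parents, expandUpscale)
  genes <- list(); lins <- vector("list", nCycles)
  for (i in seq_len(nCycles)) {
    rep_i <- if (floor(i * pixelShare) > floor((i - 1) * pixelShare))
      "pixel" else "primitive"
    if (rep_i == "pixel" && is.null(parentsPix))
      parentsPix <- lapply(parents, rasterize)
    regime <- regimes[[withSeed(deriveSeed(seed, "regime", i),
                                sample.int(length(regimes), 1L))]]
    cyc <- breedingCycle(
      if (rep_i == "pixel") parentsPix else parentsPrim,
      context, seed = deriveSeed(seed, "cycle", i),
      representation = rep_i, regime = regime,
      k = k, cycle = i, round = as.integer(ceiling(i / perRound)))
    genes <- c(genes, cyc@genes)
    lins[[i]] <- cyc@lineage
  }
  new("CandidateArchive", genes = genes, lineage = do.call(rbind, lins))
}

## ---- manufacturability ------------------------------------------------

# 8-connected component labels of the set pixels; returns integer vector
# (one label per set pixel, in `which(bits == 1L)` order)
pillarComponents <- function(bitsM) {
  set <- which(bitsM == 1L)
  if (!length(set)) return(integer(0))
  n <- nrow(bitsM)
  vid <- integer(length(bitsM))
  vid[set] <- seq_along(set)
  Mb <- bitsM == 1L
  edges <- list()
  for (d in list(c(0L, 1L), c(1L, 0L), c(1L, 1L), c(1L, -1L))) {
    dr <- d[1]; dc <- d[2]
    r <- seq_len(n - dr)
    cset <- if (dc >= 0) seq_len(n - dc) else (1L - dc):n
    both <- Mb[r, cset, drop = FALSE] &
            Mb[r + dr, cset + dc, drop = FALSE]
    hit <- which(both)
    if (length(hit)) {
      rr <- (hit - 1L) %% length(r) + 1L
      cc <- (hit - 1L) %/% length(r) + 1L
      i1 <- (cset[cc] - 1L) * n + r[rr]
      i2 <- (cset[cc] + dc - 1L) * n + r[rr] + dr
      edges[[length(edges) + 1L]] <- rbind(vid[i1], vid[i2])
    }
  }
  g <- igraph::make_empty_graph(n = length(set), directed = FALSE)
  if (length(edges))
    g <- igraph::add_edges(g, as.vector(do.call(cbind, edges)))
  as.integer(igraph::components(g)$membership)
}

#' Minimum pillar diameter of a raster design
#'
#' The fabrication screen metric: over all 8-connected components of set
#' pixels, the thickness of each component is twice the maximum of the
#' Euclidean distance transform within it, converted to micrometres; the
#' minimum over components is returned. An all-zero raster has no pillar
#' and returns \code{Inf} (it passes the screen). The image border is not
#' treated as a material/void boundary: features tile periodically across
#' the chip, so a pillar touching the frame edge is not artificially thin.
#'
#' @param gene \linkS4class{PixelGene} (a primitive gene is rasterized
#'   first).
#' @param scale micrometres per pixel (default 0.1, i.e. 20 um / 200 px).
#' @return minimum pillar diameter in micrometres.
#' @export
#' @examples
#' g <- rasterize(primitiveGene("d", 20, list(circle(c(10, 10), 2.5))))
#' minPillarDiameter(g)  # ~ 5 um
minPillarDiameter <- function(gene, scale = 0.1) {
  g <- rasterize(gene)
  bitsM <- g@bits
  set <- which(bitsM == 1L)
  if (!length(set)) return(Inf)
  memb <- pillarComponents(bitsM)
  dm <- EBImage::distmap(bitsM)
  dmax <- vapply(split(dm[set], memb), max, numeric(1))
  2 * min(dmax) * scale
}

#' Remove sub-threshold pillars from a raster design
#'
#' Repair mode of the fabrication screen: clears every 8-connected
#' component thinner than \code{minDiameter} instead of rejecting the whole
#' design.
#'
#' @inheritParams minPillarDiameter
#' @param minDiameter fabrication limit in micrometres (default 4).
#' @return the repaired \linkS4class{PixelGene}.
#' @export
repairSmallPillars <- function(gene, scale = 0.1, minDiameter = 4) {
  g <- rasterize(gene)
  bitsM <- g@bits
  set <- which(bitsM == 1L)
  if (!length(set)) return(g)
  memb <- pillarComponents(bitsM)
  dm <- EBImage::distmap(bitsM)
  dmax <- vapply(split(dm[set], memb), max, numeric(1))
  bad <- as.integer(names(dmax))[2 * dmax * scale < minDiameter]
  bitsM[set[memb %in% bad]] <- 0L
  pixelGene(g@designId, bitsM)
}

## ---- control surfaces -------------------------------------------------

#' Generate the flat and simple control surfaces
#'
#' Returns the control set of the assembled chip: 5 flat (all-zero) designs
#' plus 31 simple designs in triplicate -- 12 line gratings and 12
#' square-pillar arrays with feature size 4 to 15 um in 1 um steps (stripe
#' or pillar width equal to the gap), and 7 size variants of the hit design
#' from the first-generation screen.
#'
#' @param resolution raster side in pixels (default 200).
#' @param featureSize frame size in micrometres (default 20).
#' @param sizes line/square feature sizes in micrometres.
#' @param hitScales the 7 scale factors applied to the hit design.
#' @param hit the hit design (default [makeHitDesign()]).
#' @return data.frame-like list: \code{genes} (named list),
#'   \code{meta} (data.frame designId, category, replicates).
#' @export
makeControls <- function(resolution = 200L, featureSize = 20,
                         sizes = 4:15,
                         hitScales = c(0.5, 0.75, 1, 1.25, 1.5, 1.75, 2),
                         hit = makeHitDesign()) {
  scalePx <- featureSize / resolution
  genes <- list(); meta <- list()
  addDesign <- function(g, category, replicates) {
    genes[[designId(g)]] <<- g
    meta[[length(meta) + 1L]] <<- data.frame(
      designId = designId(g), category = category,
      replicates = replicates, stringsAsFactors = FALSE)
  }
  for (i in 1:5)
    addDesign(pixelGene(sprintf("flat_%d", i),
                        matrix(0L, resolution, resolution)), "flat", 1L)
  for (s in sizes) {
    w <- round(s / scalePx)
    stripe <- (floor((seq_len(resolution) - 1L) / w) %% 2L) == 0L
    addDesign(pixelGene(sprintf("line_%02d", s),
                        matrix(as.integer(stripe), resolution, resolution,
                               byrow = TRUE)),
              "simple_control", 3L)
    addDesign(pixelGene(sprintf("square_%02d", s),
                        outer(stripe, stripe, function(a, b)
                          as.integer(a & b))),
              "simple_control", 3L)
  }
  for (s in hitScales) {
    g <- scaleDesign(hit, s)
    designId(g) <- sprintf("hit_%03d", round(100 * s))
    addDesign(g, "simple_control", 3L)
  }
  list(genes = genes, meta = do.call(rbind, meta))
}

#' Scale a primitive design about its frame center
#'
#' @param gene \linkS4class{PrimitiveGene}.
#' @param factor scale factor applied to primitive positions (about the
#'   frame center) and sizes; coordinates are clamped to the frame.
#' @return the scaled \linkS4class{PrimitiveGene}.
#' @export
scaleDesign <- function(gene, factor) {
  L <- gene@featureSize
  ctr <- c(L / 2, L / 2)
  prims <- lapply(gene@primitives, function(p) {
    pts <- sweep(sweep(p@points, 2, ctr) * factor, 2, ctr, `+`)
    pts <- pmax(pmin(pts, L), 0)   # matrix-first pmin/pmax keeps dims
    if (p@kind == "C") circle(pts[1, ], p@radius * factor)
    else if (p@kind == "L") lineSeg(pts[1, ], pts[2, ],
                                    p@strokeWidth * factor)
    else triangle(pts[1, ], pts[2, ], pts[3, ])
  })
  primitiveGene(gene@designId, L, prims, upscale = gene@upscale)
}

## ---- chip finalization ------------------------------------------------

#' Assemble the final chip layout
#'
#' Shuffles the archive's non-elite candidates (seeded) and streams them
#' through the half-dissimilar / half-similar Pearson filter, screening each
#' admissible candidate against the 4 um minimum pillar diameter before it
#' consumes a quota slot; appends the parents, the 5 flat controls and the
#' 31 simple controls in triplicate; and shuffles the unit order with the
#' given seed. Elite candidates (unmodified parent copies carried through
#' cycles for fitness assessment) are not placed as children -- the parents
#' occupy their own chip units.
#'
#' @param archive \linkS4class{CandidateArchive} from [runGeneration()].
#' @param parents named list of parent genes (ids = names).
#' @param quotaChildren number of new designs to place (default 4177).
#' @param controls control set from [makeControls()].
#' @param seed integer seed for the final shuffle.
#' @param scale micrometres per pixel (default 0.1).
#' @param minDiameter fabrication limit in micrometres (default 4).
#' @param dissimilarThreshold,similarThreshold diversity-filter thresholds.
#' @param repair if \code{TRUE}, sub-threshold pillars are erased from a
#'   design instead of excluding it.
#' @return a \linkS4class{ChipLayout} of
#'   \code{quotaChildren + length(parents) + 5 + 3 * 31} units under the
#'   default controls.
#' @export
finalizeChip <- function(archive, parents, quotaChildren = 4177L,
                         controls = makeControls(), seed = 1L,
                         scale = 0.1, minDiameter = 4,
                         dissimilarThreshold = 0.5,
                         similarThreshold = 0.9, repair = FALSE) {
  lin <- archive@lineage
  candIds <- lin$childId[!lin$elite]
  candidates <- archive@genes[candIds]
  # generated surfaces are shuffled before the final selection, decorrelating
  # the stream from the cycle structure (siblings no longer adjacent)
  candidates <- candidates[withSeed(deriveSeed(seed, "stream"),
                                    sample.int(length(candidates)))]
  if (length(candidates) <= quotaChildren)
    stop("archive must hold more non-elite candidates than the child quota")

  i <- 0L
  stream <- function() {
    i <<- i + 1L
    if (i > length(candidates)) return(NULL)
    g <- candidates[[i]]
    if (repair) g <- repairSmallPillars(rasterize(g), scale, minDiameter)
    g
  }
  ok <- function(g) {
    d <- minPillarDiameter(g, scale)
    is.infinite(d) || d >= minDiameter
  }
  flt <- diversityFilter(stream, quota = quotaChildren,
                         dissimilarThreshold = dissimilarThreshold,
                         similarThreshold = similarThreshold,
                         accept = ok)
  nAcc <- nrow(flt$selection)
  if (nAcc < quotaChildren)
    stop(sprintf("archive exhausted: %d accepted, shortfall %d",
                 nAcc, quotaChildren - nAcc))

  rep_of <- lin$representation[match(flt$selection$designId, lin$childId)]
  childCat <- ifelse(rep_of == "pixel", "pixel_child", "primitive_child")

  units <- rbind(
    data.frame(designId = flt$selection$designId, category = childCat,
               replicate = 1L, stringsAsFactors = FALSE),
    data.frame(designId = names(parents), category = "parent",
               replicate = 1L, stringsAsFactors = FALSE),
    do.call(rbind, lapply(seq_len(nrow(controls$meta)), function(j) {
      m <- controls$meta[j, ]
      data.frame(designId = m$designId, category = m$category,
                 replicate = seq_len(m$replicates),
                 stringsAsFactors = FALSE)
    })))
  perm <- withSeed(deriveSeed(seed, "shuffle"),
                   sample.int(nrow(units)))
  units <- units[perm, ]
  units$position <- seq_len(nrow(units))
  rownames(units) <- NULL

  designs <- c(stats::setNames(flt$genes, flt$selection$designId),
               parents, controls$genes)
  new("ChipLayout", units = units[, c("position", "designId",
                                      "category", "replicate")],
      capacity = nrow(units), designs = designs)
}

#' Export a chip layout
#'
#' Writes the unit table as CSV, a JSON manifest of category counts, and
#' optionally the design rasters as a PNG bundle.
#'
#' @param layout \linkS4class{ChipLayout}.
#' @param dir output directory (created if needed).
#' @param png write one lossless PNG per unique design.
#' @return \code{dir}, invisibly.
#' @export
exportChipLayout <- function(layout, dir, png = FALSE) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  utils::write.csv(layout@units, file.path(dir, "chip_layout.csv"),
                   row.names = FALSE, quote = FALSE)
  cnt <- as.list(table(layout@units$category))
  jsonlite::write_json(
    list(capacity = layout@capacity, categories = cnt,
         uniqueDesigns = length(layout@designs)),
    file.path(dir, "chip_manifest.json"), auto_unbox = TRUE)
  if (png) {
    pdir <- file.path(dir, "designs")
    dir.create(pdir, showWarnings = FALSE)
    for (g in layout@designs) writeGenePNG(g, pdir)
  }
  invisible(dir)
}
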