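#' Build a validated pipeline configuration
#'
#' Collects every tunable of the design engine in a single document. The
#' defaults reproduce the stated second-generation chip parameterization:
#' 2176-design seed pool, 95th-percentile fitness threshold, an 81-parent
#' pool, 110 candidates per cycle over 4 generation rounds, 0.5 / 0.9
#' Pearson admission thresholds, mutation-rate regimes of 20% and 50%, a
#' 4 um pillar limit at 0.1 um/px, and 4177 child designs on a 4356-unit
#' chip. \code{targetCandidates} (archive size before final selection)
#' defaults to \code{margin * quotaChildren}; the published run generated
#' candidates at far larger scale, which only increases the selection's
#' freedom.
#'
#' @param poolSize,sizeWeights,primitiveRange,coefficients,noiseSd seed-pool
#'   settings, see [seedConfig()].
#' @param percentile parent-selection fitness percentile.
#' @param nParents number of parents placed on the chip (81).
#' @param quotaChildren new designs placed on the chip (4177).
#' @param rounds generation rounds (4).
#' @param targetCandidates archive size to breed; default
#'   \code{ceiling(margin * quotaChildren)}.
#' @param margin archive head-room factor over the child quota. The default
#'   (240) mirrors the roughly 1e6-offspring funnel that feeds 4177 placed
#'   designs: the dissimilar half of the final selection is extremely
#'   selective, so the archive must dwarf the quota (see the vignette).
#'   Reduced-scale runs should reduce \code{quotaChildren} along with
#'   \code{targetCandidates}.
#' @param pixelShare fraction of cycles bred in pixel representation.
#' @param regimes mutation-rate regimes drawn per cycle.
#' @param dissimilarThreshold,similarThreshold diversity-filter thresholds.
#' @param scale micrometres per pixel.
#' @param minDiameter pillar fabrication limit (um).
#' @param analysisComponents eigenimages computed in the analysis stage.
#' @param analysisSample designs subsampled for the embedding stage.
#' @param seed master run seed; all stage seeds derive from it.
#' @return a \code{RunConfig} list.
#' @export
runConfig <- function(poolSize = 2176L,
                      sizeWeights = c(`10` = 1/3, `20` = 1/3, `28` = 1/3),
                      primitiveRange = c(3L, 20L),
                      coefficients = c(intercept = 100, coverage = 40,
                                       count = 20, width = 20),
                      noiseSd = 15,
                      percentile = 95, nParents = 81L,
                      quotaChildren = 4177L, rounds = 4L,
                      targetCandidates = NULL, margin = 240,
                      pixelShare = 0.5, regimes = c(0.2, 0.5),
                      dissimilarThreshold = 0.5, similarThreshold = 0.9,
                      scale = 0.1, minDiameter = 4,
                      analysisComponents = 7L, analysisSample = 300L,
                      seed = 17L) {
  if (is.null(targetCandidates))
    targetCandidates <- as.integer(ceiling(margin * quotaChildren))
  cfg <- list(poolSize = as.integer(poolSize), sizeWeights = sizeWeights,
              primitiveRange = primitiveRange, coefficients = coefficients,
              noiseSd = noiseSd, percentile = percentile,
              nParents = as.integer(nParents),
              quotaChildren = as.integer(quotaChildren),
              rounds = as.integer(rounds),
              targetCandidates = as.integer(targetCandidates),
              margin = margin, pixelShare = pixelShare, regimes = regimes,
              dissimilarThreshold = dissimilarThreshold,
              similarThreshold = similarThreshold, scale = scale,
              minDiameter = minDiameter,
              analysisComponents = as.integer(analysisComponents),
              analysisSample = as.integer(analysisSample),
              seed = as.integer(seed))
  stopifnot(cfg$quotaChildren >= 1, cfg$nParents >= 10,
            cfg$targetCandidates > cfg$quotaChildren,
            cfg$dissimilarThreshold < cfg$similarThreshold)
  structure(cfg, class = "RunConfig")
}

#' Write lineage records as JSON lines
#'
#' @param lineage lineage data.frame.
#' @param path output file (one JSON object per child).
#' @return \code{path}, invisibly.
#' @export
writeLineageJSONL <- function(lineage, path) {
  con <- file(path, "w")
  on.exit(close(con))
  for (i in seq_len(nrow(lineage)))
    writeLines(jsonlite::toJSON(as.list(lineage[i, ]), auto_unbox = TRUE),
               con)
  invisible(path)
}

stage <- function(name, expr) {
  tryCatch(expr, error = function(e)
    stop(sprintf("pipeline stage '%s' failed: %s", name,
                 conditionMessage(e)), call. = FALSE))
}

#' Run the full design pipeline
#'
#' Executes seed pool generation, the synthetic fitness screen, size
#' normalization, parent selection, the generation rounds, chip
#' finalization and the characterization analyses, writing all artifacts
#' and a manifest of per-stage counts to \code{outDir}. Every random draw
#' derives from \code{config$seed} through named sub-streams, so two runs
#' with the same configuration are identical.
#'
#' Parent choice: the fitness threshold is the configured percentile
#' ([selectParentPool()]), but the chip hosts a fixed number of parent
#' units, so the pool placed is the \code{nParents} highest-fitness
#' designs among the size-normalized survivors (see the package vignette
#' for the rationale).
#'
#' @param config a [runConfig()].
#' @param outDir artifact directory (created if needed).
#' @return invisibly, a list with the \code{manifest}, the
#'   \linkS4class{ChipLayout} and the \linkS4class{CandidateArchive}.
#' @export
runAll <- function(config = runConfig(), outDir = tempfile("gtopo")) {
  stopifnot(inherits(config, "RunConfig"))
  dir.create(outDir, showWarnings = FALSE, recursive = TRUE)
  manifest <- list(config = unclass(config))

  sc <- seedConfig(poolSize = config$poolSize,
                   sizeWeights = config$sizeWeights,
                   primitiveRange = config$primitiveRange,
                   coefficients = config$coefficients,
                   noiseSd = config$noiseSd,
                   seed = deriveSeed(config$seed, "seedpool"))
  pool <- stage("seed", generatePool(sc))
  records <- stage("seed", syntheticAlp(pool, sc))
  writeDesignJSON(pool, file.path(outDir, "designs.json"))
  writeFitnessCSV(records, file.path(outDir, "fitness.csv"))
  manifest$seed <- list(poolSize = length(pool))

  normalized <- stage("normalize", normalizePool(pool))
  names(normalized) <- vapply(normalized, designId, character(1))
  manifest$normalize <- list(retained = length(normalized),
                             excluded28 = length(pool) - length(normalized))

  manifest$parents <- stage("parents", {
    aboveThr <- selectParentPool(records, config$percentile)
    normRec <- records[records$designId %in% names(normalized), ]
    ord <- normRec$designId[order(-normRec$alpIntensity, normRec$designId)]
    parentIds <- utils::head(ord, config$nParents)
    list(abovePercentile = length(aboveThr),
         abovePercentileNormalized = sum(aboveThr %in% names(normalized)),
         placed = length(parentIds), ids = parentIds)
  })
  parents <- normalized[manifest$parents$ids]
  context <- selectionContext(
    records[records$designId %in% names(parents), ],
    similarityMatrix(lapply(parents, rasterize)))

  archive <- stage("evolve",
    runGeneration(parents, context,
                  targetCandidates = config$targetCandidates,
                  rounds = config$rounds,
                  seed = deriveSeed(config$seed, "evolve"),
                  pixelShare = config$pixelShare,
                  regimes = config$regimes))
  writeLineageJSONL(archive@lineage, file.path(outDir, "lineage.jsonl"))
  manifest$evolve <- list(
    candidates = length(archive@genes),
    cycles = length(unique(archive@lineage$cycle)),
    perRound = as.list(table(archive@lineage$round)))

  layout <- stage("assemble",
    finalizeChip(archive, parents,
                 quotaChildren = config$quotaChildren,
                 seed = deriveSeed(config$seed, "assemble"),
                 scale = config$scale, minDiameter = config$minDiameter,
                 dissimilarThreshold = config$dissimilarThreshold,
                 similarThreshold = config$similarThreshold))
  exportChipLayout(layout, outDir)
  manifest$assemble <- c(list(capacity = layout@capacity),
                         as.list(table(layout@units$category)))

  manifest$analyze <- stage("analyze", {
    childIds <- layout@units$designId[
      layout@units$category %in% c("pixel_child", "primitive_child")]
    sampleIds <- utils::head(childIds, config$analysisSample)
    sampleGenes <- lapply(layout@designs[sampleIds], rasterize)
    eig <- pcaEigenimages(sampleGenes, config$analysisComponents)
    utils::write.csv(
      data.frame(component = seq_along(eig@explainedVariance),
                 variance = eig@explainedVariance),
      file.path(outDir, "eigen_variance.csv"), row.names = FALSE)
    emb <- embedLibrary(sampleGenes,
                        seed = deriveSeed(config$seed, "embed"))
    utils::write.csv(emb, file.path(outDir, "embedding.csv"),
                     row.names = FALSE)
    occ <- occupancyMap(sampleGenes)
    utils::write.csv(occ, file.path(outDir, "occupancy.csv"),
                     row.names = FALSE)
    stats <- parentProgenyStats(archive@lineage, names(parents))
    list(analyzed = length(sampleGenes),
         uniquePairs = stats$uniquePairs,
         theoreticalMaxPairs = stats$theoreticalMax)
  })

  jsonlite::write_json(manifest, file.path(outDir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(list(manifest = manifest, layout = layout, archive = archive,
                 outDir = outDir))
}
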