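#' @import methods
NULL

PRIMITIVE_KINDS <- c("T", "C", "L")
CHIP_CATEGORIES <- c("parent", "pixel_child", "primitive_child", "flat",
                     "simple_control")

#' Geometric primitive of a topographical feature
#'
#' An elementary shape whose filled area contributes pillar material to a
#' feature design. Three kinds exist: \code{"T"} (filled triangle, three
#' vertices), \code{"C"} (filled disc, one center point plus a radius) and
#' \code{"L"} (line segment, two endpoints, dilated to a stroke width).
#' Coordinates are micrometres within the square feature frame, origin at the
#' top-left corner, x rightward, y downward.
#'
#' @slot kind single character, one of \code{"T"}, \code{"C"}, \code{"L"}.
#' @slot points numeric matrix with columns x, y (micrometres); 3 rows for a
#'   triangle, 2 for a line, 1 (the center) for a circle.
#' @slot radius numeric of length 1 for circles, length 0 otherwise (um).
#' @slot strokeWidth numeric of length 1 for lines, length 0 otherwise (um).
#' @name Primitive-class
#' @rdname Primitive-class
#' @exportClass Primitive
setClass("Primitive",
  representation(kind = "character", points = "matrix",
                 radius = "numeric", strokeWidth = "numeric"))

setValidity("Primitive", function(object) {
  msg <- character()
  if (length(object@kind) != 1L || !object@kind %in% PRIMITIVE_KINDS)
    msg <- c(msg, "kind must be one of 'T', 'C', 'L'")
  else {
    need <- c(T = 3L, C = 1L, L = 2L)[[object@kind]]
    if (nrow(object@points) != need || ncol(object@points) != 2L)
      msg <- c(msg, sprintf("kind '%s' requires %d (x, y) points",
                            object@kind, need))
    if (object@kind == "C") {
      if (length(object@radius) != 1L || object@radius < 0)
        msg <- c(msg, "circle requires a single nonnegative radius")
    } else if (length(object@radius) != 0L)
      msg <- c(msg, "radius only allowed for circles")
    if (object@kind == "L") {
      if (length(object@strokeWidth) != 1L || object@strokeWidth <= 0)
        msg <- c(msg, "line requires a single positive strokeWidth")
    } else if (length(object@strokeWidth) != 0L)
      msg <- c(msg, "strokeWidth only allowed for lines")
  }
  if (!all(is.finite(object@points)))
    msg <- c(msg, "points must be finite")
  if (length(msg)) msg else TRUE
})

#' Vector (primitive-based) topography gene
#'
#' Encodes one feature design as an ordered list of geometric primitives, the
#' vector analogue of a raster image. List order is meaningful: positions act
#' like gene domains and are what positional crossover operators cut between.
#'
#' @slot designId single character identifier.
#' @slot featureSize side length of the square feature frame in micrometres
#'   (10, 20 or 28 in seed pools).
#' @slot primitives list of \linkS4class{Primitive} objects.
#' @slot upscale logical; \code{TRUE} marks a 10 um design that is to be
#'   rasterized at half resolution and tiled 2x2 to the standard raster size
#'   (size normalization of mixed-size pools).
#' @seealso [rasterize()], [normalizePool()]
#' @name PrimitiveGene-class
#' @rdname PrimitiveGene-class
#' @exportClass PrimitiveGene
setClass("PrimitiveGene",
  representation(designId = "character", featureSize = "numeric",
                 primitives = "list", upscale = "logical"),
  prototype(upscale = FALSE))

setValidity("PrimitiveGene", function(object) {
  msg <- character()
  if (length(object@designId) != 1L || is.na(object@designId) ||
      !nzchar(object@designId))
    msg <- c(msg, "designId must be a single non-empty string")
  if (length(object@featureSize) != 1L || object@featureSize <= 0)
    msg <- c(msg, "featureSize must be a single positive number")
  if (length(object@upscale) != 1L)
    msg <- c(msg, "upscale must be a single logical")
  for (p in object@primitives) {
    if (!is(p, "Primitive")) { msg <- c(msg, "primitives must be Primitive objects"); break }
    v <- validObject(p, test = TRUE)
    if (is.character(v)) { msg <- c(msg, v); break }
    if (any(p@points < 0) || any(p@points > object@featureSize)) {
      msg <- c(msg, "primitive coordinates must lie in [0, featureSize]")
      break
    }
  }
  if (length(msg)) msg else TRUE
})

#' Raster (pixel-based) topography gene
#'
#' Encodes one feature design as a square binary matrix, 1 marking pillar
#' material and 0 no pillar. The standard working size is 200 x 200 pixels
#' (0.1 um per pixel for a 20 um feature); 100 x 100 rasters occur transiently
#' before 2x2 upscaling.
#'
#' @slot designId single character identifier.
#' @slot bits integer matrix of 0/1 values, square.
#' @seealso [flattenGene()], [upscale2x2()], [pearsonSimilarity()]
#' @name PixelGene-class
#' @rdname PixelGene-class
#' @exportClass PixelGene
setClass("PixelGene",
  representation(designId = "character", bits = "matrix"))

setValidity("PixelGene", function(object) {
  msg <- character()
  if (length(object@designId) != 1L || is.na(object@designId) ||
      !nzchar(object@designId))
    msg <- c(msg, "designId must be a single non-empty string")
  b <- object@bits
  if (!is.integer(b))
    msg <- c(msg, "bits must be an integer matrix")
  else if (nrow(b) != ncol(b))
    msg <- c(msg, "bits must be square")
  else if (anyNA(b) || any(b != 0L & b != 1L))
    msg <- c(msg, "bits entries must all be 0 or 1")
  if (length(msg)) msg else TRUE
})

#' Fitness and similarity context for parent selection
#'
#' Bundles the fitness table (ALP mean integrated intensity per design) with
#' the Pearson similarity matrix over the same designs, as consumed by the
#' multi-objective selection algorithms.
#'
#' @slot records data.frame with columns \code{designId}, \code{alpIntensity}.
#' @slot similarity numeric matrix with design ids as dimnames; may be
#'   0 x 0 when only single-objective algorithms are used.
#' @seealso [selectionContext()], [selectParents()]
#' @name SelectionContext-class
#' @rdname SelectionContext-class
#' @exportClass SelectionContext
setClass("SelectionContext",
  representation(records = "data.frame", similarity = "matrix"))

setValidity("SelectionContext", function(object) {
  msg <- character()
  r <- object@records
  if (!all(c("designId", "alpIntensity") %in% names(r)))
    msg <- c(msg, "records needs columns designId, alpIntensity")
  else {
    if (anyDuplicated(r$designId))
      msg <- c(msg, "one record per designId required")
    if (any(r$alpIntensity < 0))
      msg <- c(msg, "alpIntensity must be nonnegative")
    s <- object@similarity
    if (length(s)) {
      if (is.null(rownames(s)) || !all(r$designId %in% rownames(s)))
        msg <- c(msg, "every fitness id must appear in the similarity matrix")
    }
  }
  if (length(msg)) msg else TRUE
})

#' Archive of candidate genes with lineage
#'
#' Accumulates the offspring of breeding cycles together with full provenance:
#' one lineage row per candidate records its parents, the selection algorithm
#' and crossover operator that produced it, and the ordered mutation list.
#'
#' @slot genes named list of \linkS4class{PixelGene} /
#'   \linkS4class{PrimitiveGene} objects, names = child ids.
#' @slot lineage data.frame with one row per candidate; columns
#'   \code{childId}, \code{parentA}, \code{parentB},
#'   \code{selectionAlgorithm}, \code{crossoverOperator}, \code{mutations}
#'   (";"-separated operator names, "" for none), \code{representation},
#'   \code{rateRegime}, \code{cycle}, \code{round}, \code{elite}.
#' @name CandidateArchive-class
#' @rdname CandidateArchive-class
#' @exportClass CandidateArchive
setClass("CandidateArchive",
  representation(genes = "list", lineage = "data.frame"))

setValidity("CandidateArchive", function(object) {
  if (length(object@genes) != nrow(object@lineage))
    return("one lineage row per gene required")
  if (!identical(names(object@genes), object@lineage$childId))
    return("gene names must match lineage childId, in order")
  TRUE
})

#' Assembled topography chip layout
#'
#' The final library: an ordered list of chip units, each carrying a design id
#' and one of five categories (parent, pixel_child, primitive_child, flat,
#' simple_control), plus the gene objects placed.
#'
#' @slot units data.frame with columns \code{position}, \code{designId},
#'   \code{category}, \code{replicate}.
#' @slot capacity total number of units (4356 under defaults).
#' @slot designs named list of gene objects (one entry per unique design).
#' @seealso [finalizeChip()], [makeControls()]
#' @name ChipLayout-class
#' @rdname ChipLayout-class
#' @exportClass ChipLayout
setClass("ChipLayout",
  representation(units = "data.frame", capacity = "integer",
                 designs = "list"))

setValidity("ChipLayout", function(object) {
  msg <- character()
  u <- object@units
  if (!all(c("position", "designId", "category", "replicate") %in% names(u)))
    msg <- c(msg, "units needs columns position, designId, category, replicate")
  else {
    if (nrow(u) != object@capacity)
      msg <- c(msg, "number of units must equal capacity")
    if (!all(u$category %in% CHIP_CATEGORIES))
      msg <- c(msg, "unknown unit category")
    if (!setequal(u$position, seq_len(nrow(u))))
      msg <- c(msg, "positions must be a permutation of 1..capacity")
  }
  if (length(msg)) msg else TRUE
})

#' Eigenimage decomposition of a pattern library
#'
#' Principal components of mean-centered flattened rasters, reshaped back to
#' image form ("eigenimages"), with explained variances and per-design weight
#' vectors. Any library member is reconstructed as the mean image plus its
#' weighted sum of eigenimages.
#'
#' @slot components list of real matrices (one per component, image-shaped).
#' @slot explainedVariance numeric, non-increasing, one value per component.
#' @slot meanImage real matrix, the library mean.
#' @slot weights numeric matrix, designs x components; rownames = design ids.
#' @seealso [pcaEigenimages()]
#' @name EigenimageSet-class
#' @rdname EigenimageSet-class
#' @exportClass EigenimageSet
setClass("EigenimageSet",
  representation(components = "list", explainedVariance = "numeric",
                 meanImage = "matrix", weights = "matrix"))

setValidity("EigenimageSet", function(object) {
  msg <- character()
  k <- length(object@components)
  if (length(object@explainedVariance) != k)
    msg <- c(msg, "one explainedVariance per component required")
  else if (k > 1L && any(diff(object@explainedVariance) > 1e-8))
    msg <- c(msg, "explainedVariance must be non-increasing")
  if (ncol(object@weights) != k)
    msg <- c(msg, "weights must have one column per component")
  if (length(msg)) msg else TRUE
})
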