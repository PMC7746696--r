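#' @rdname accessors
#' @export
setGeneric("designId", function(x) standardGeneric("designId"))
#' @rdname accessors
#' @export
setGeneric("designId<-", function(x, value) standardGeneric("designId<-"))
#' @rdname accessors
#' @export
setGeneric("bits", function(x) standardGeneric("bits"))
#' @rdname accessors
#' @export
setGeneric("featureSize", function(x) standardGeneric("featureSize"))
#' @rdname accessors
#' @export
setGeneric("primitives", function(x) standardGeneric("primitives"))
#' @rdname rasterize
#' @export
setGeneric("rasterize", function(x, resolution = 200L) standardGeneric("rasterize"))

#' Accessors for topography gene objects
#'
#' \code{designId} returns (or replaces) the design identifier; \code{bits}
#' the binary matrix of a \linkS4class{PixelGene}; \code{featureSize} the
#' frame size in micrometres and \code{primitives} the primitive list of a
#' \linkS4class{PrimitiveGene}.
#'
#' @param x a gene object.
#' @param value replacement identifier.
#' @return the corresponding slot value.
#' @name accessors
#' @aliases designId bits featureSize primitives designId<-
NULL

setMethod("designId", "PixelGene", function(x) x@designId)
setMethod("designId", "PrimitiveGene", function(x) x@designId)
setReplaceMethod("designId", "PixelGene", function(x, value) {
  x@designId <- as.character(value); validObject(x); x
})
setReplaceMethod("designId", "PrimitiveGene", function(x, value) {
  x@designId <- as.character(value); validObject(x); x
})
setMethod("bits", "PixelGene", function(x) x@bits)
setMethod("featureSize", "PrimitiveGene", function(x) x@featureSize)
setMethod("primitives", "PrimitiveGene", function(x) x@primitives)

setMethod("show", "Primitive", function(object) {
  extra <- switch(object@kind,
    C = sprintf(", r=%.2f um", object@radius),
    L = sprintf(", stroke=%.2f um", object@strokeWidth),
    "")
  cat(sprintf("Primitive <%s> at (%s)%s\n", object@kind,
      paste(sprintf("%.1f,%.1f", object@points[, 1], object@points[, 2]),
            collapse = " "), extra))
})

setMethod("show", "PrimitiveGene", function(object) {
  kinds <- vapply(object@primitives, function(p) p@kind, character(1))
  cat(sprintf("PrimitiveGene '%s': %d um frame, %d primitives (%s)%s\n",
      object@designId, object@featureSize, length(kinds),
      paste(sprintf("%s=%d", names(table(kinds)), table(kinds)),
            collapse = ", "),
      if (object@upscale) " [2x2 upscale]" else ""))
})

setMethod("show", "PixelGene", function(object) {
  n <- nrow(object@bits)
  cat(sprintf("PixelGene '%s': %d x %d, fill %.3f\n", object@designId,
      n, n, mean(object@bits)))
})

setMethod("show", "SelectionContext", function(object) {
  cat(sprintf("SelectionContext: %d fitness records%s\n",
      nrow(object@records),
      if (length(object@similarity))
        sprintf(", %d x %d similarity matrix", nrow(object@similarity),
                ncol(object@similarity)) else ", no similarity matrix"))
})

setMethod("show", "CandidateArchive", function(object) {
  el <- sum(object@lineage$elite)
  cat(sprintf("CandidateArchive: %d candidates (%d elites) over %d cycle(s)\n",
      length(object@genes), el,
      length(unique(object@lineage$cycle))))
})

setMethod("show", "ChipLayout", function(object) {
  cat(sprintf("ChipLayout: %d units\n", object@capacity))
  print(table(object@units$category))
})

setMethod("show", "EigenimageSet", function(object) {
  ev <- object@explainedVariance
  cat(sprintf("EigenimageSet: %d eigenimages (%d x %d), top variance share %.3f\n",
      length(object@components), nrow(object@meanImage),
      ncol(object@meanImage),
      if (sum(ev) > 0) ev[1] / sum(ev) else NA_real_))
})
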