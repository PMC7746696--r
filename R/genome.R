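#' Construct geometric primitives
#'
#' Helper constructors for the three primitive kinds of the vector genome.
#' Coordinates are micrometres within the feature frame (origin top-left,
#' x rightward, y downward).
#'
#' @param p1,p2,p3 numeric length-2 (x, y) vertices / endpoints.
#' @param center numeric length-2 circle center.
#' @param radius circle radius in micrometres.
#' @param strokeWidth line stroke width in micrometres. The default of 2 um
#'   is a project-wide convention; fabrication-constrained generators pass
#'   wider strokes explicitly.
#' @return a \linkS4class{Primitive}.
#' @export
#' @examples
#' triangle(c(0, 0), c(20, 0), c(0, 20))
#' circle(c(10, 10), 5)
#' lineSeg(c(2, 2), c(18, 18), strokeWidth = 4)
triangle <- function(p1, p2, p3) {
  new("Primitive", kind = "T", points = rbind(p1, p2, p3, deparse.level = 0),
      radius = numeric(), strokeWidth = numeric())
}

#' @rdname triangle
#' @export
circle <- function(center, radius) {
  new("Primitive", kind = "C", points = rbind(center, deparse.level = 0),
      radius = as.numeric(radius), strokeWidth = numeric())
}

#' @rdname triangle
#' @export
lineSeg <- function(p1, p2, strokeWidth = 2) {
  new("Primitive", kind = "L", points = rbind(p1, p2, deparse.level = 0),
      radius = numeric(), strokeWidth = as.numeric(strokeWidth))
}

#' Construct topography genes
#'
#' @param designId single character identifier.
#' @param featureSize frame side length in micrometres.
#' @param primitives list of \linkS4class{Primitive} objects.
#' @param upscale logical; mark for 2x2 upscaling at rasterization.
#' @param bits 0/1 matrix (coerced to integer).
#' @return a \linkS4class{PrimitiveGene} or \linkS4class{PixelGene}.
#' @export
primitiveGene <- function(designId, featureSize, primitives,
                          upscale = FALSE) {
  new("PrimitiveGene", designId = as.character(designId),
      featureSize = as.numeric(featureSize), primitives = primitives,
      upscale = upscale)
}

#' @rdname primitiveGene
#' @export
pixelGene <- function(designId, bits) {
  storage.mode(bits) <- "integer"
  new("PixelGene", designId = as.character(designId), bits = bits)
}

# vectorized point-in-primitive test; xs, ys are pixel-center coordinates (um)
# closed boundary: centers exactly on an edge count as inside
insideMask <- function(p, xs, ys) {
  nx <- length(xs); ny <- length(ys)
  X <- matrix(xs, ny, nx, byrow = TRUE)
  Y <- matrix(ys, ny, nx)
  eps <- 1e-9
  if (p@kind == "C") {
    cx <- p@points[1, 1]; cy <- p@points[1, 2]
    (X - cx)^2 + (Y - cy)^2 <= p@radius^2 + eps
  } else if (p@kind == "T") {
    a <- p@points[1, ]; b <- p@points[2, ]; cc <- p@points[3, ]
    d1 <- (X - a[1]) * (b[2] - a[2]) - (Y - a[2]) * (b[1] - a[1])
    d2 <- (X - b[1]) * (cc[2] - b[2]) - (Y - b[2]) * (cc[1] - b[1])
    d3 <- (X - cc[1]) * (a[2] - cc[2]) - (Y - cc[2]) * (a[1] - cc[1])
    (d1 >= -eps & d2 >= -eps & d3 >= -eps) |
      (d1 <= eps & d2 <= eps & d3 <= eps)
  } else {
    a <- p@points[1, ]; b <- p@points[2, ]
    vx <- b[1] - a[1]; vy <- b[2] - a[2]
    len2 <- vx^2 + vy^2
    if (len2 == 0) {
      d2 <- (X - a[1])^2 + (Y - a[2])^2
    } else {
      t <- pmin(1, pmax(0, ((X - a[1]) * vx + (Y - a[2]) * vy) / len2))
      d2 <- (X - (a[1] + t * vx))^2 + (Y - (a[2] + t * vy))^2
    }
    d2 <= (p@strokeWidth / 2)^2 + eps
  }
}

# rasterize a primitive list into an existing integer matrix (OR semantics)
paintPrimitives <- function(bits, prims, scale) {
  res <- nrow(bits)
  xs <- (seq_len(res) - 0.5) * scale
  ys <- xs
  for (p in prims) {
    # bounding box in pixel indices keeps the mask evaluation local
    ext <- switch(p@kind,
      C = p@radius, T = 0, L = p@strokeWidth / 2)
    xr <- range(p@points[, 1]); yr <- range(p@points[, 2])
    c0 <- max(1L, floor((xr[1] - ext) / scale)); c1 <- min(res, ceiling((xr[2] + ext) / scale) + 1L)
    r0 <- max(1L, floor((yr[1] - ext) / scale)); r1 <- min(res, ceiling((yr[2] + ext) / scale) + 1L)
    if (c0 > c1 || r0 > r1) next
    m <- insideMask(p, xs[c0:c1], ys[r0:r1])
    sub <- bits[r0:r1, c0:c1, drop = FALSE]
    sub[m] <- 1L
    bits[r0:r1, c0:c1] <- sub
  }
  bits
}

#' Rasterize a primitive gene to a binary pixel gene
#'
#' Converts the vector genome to the raster genome: a pixel is set to 1 iff
#' its center lies inside any primitive (filled triangle, filled disc, or
#' line segment dilated to its stroke width; boundaries closed). Pixel pitch
#' is \code{featureSize / resolution} micrometres (0.1 um/px for a 20 um
#' feature at 200 px). Genes flagged for upscaling (10 um designs after
#' [normalizePool()]) are rasterized at half resolution and tiled 2x2, which
#' preserves the physical 0.1 um pitch.
#'
#' @param x a \linkS4class{PrimitiveGene} (a \linkS4class{PixelGene} is
#'   returned unchanged).
#' @param resolution pixels per feature side (default 200).
#' @return a \linkS4class{PixelGene} with the same design id.
#' @seealso [upscale2x2()]
#' @export
#' @examples
#' g <- primitiveGene("d1", 20, list(circle(c(10, 10), 5)))
#' mean(bits(rasterize(g)))  # ~ pi * 5^2 / 400
#' @rdname rasterize
setMethod("rasterize", "PrimitiveGene", function(x, resolution = 200L) {
  stopifnot(resolution >= 1L)
  res <- as.integer(if (x@upscale) resolution / 2L else resolution)
  scale <- x@featureSize / res
  bitsM <- paintPrimitives(matrix(0L, res, res), x@primitives, scale)
  g <- pixelGene(x@designId, bitsM)
  if (x@upscale) g <- upscale2x2(g)
  g
})

#' @rdname rasterize
setMethod("rasterize", "PixelGene", function(x, resolution = 200L) x)

#' Flatten a pixel gene to a binary vector (and back)
#'
#' The raster genome used by crossover and similarity is the row-major
#' flattening of the binary matrix: rows are stacked left to right, top to
#' bottom, giving a length \code{n^2} vector (40000 at 200 x 200). The round
#' trip through [unflattenGene()] is lossless.
#'
#' @param gene a \linkS4class{PixelGene}.
#' @param v binary integer vector of square length.
#' @param designId identifier for the rebuilt gene.
#' @return \code{flattenGene}: integer 0/1 vector; \code{unflattenGene}: a
#'   \linkS4class{PixelGene}.
#' @export
#' @examples
#' g <- pixelGene("x", matrix(c(0L, 1L, 0L, 0L), 2, 2))
#' unflattenGene(flattenGene(g), "x")
flattenGene <- function(gene) {
  as.integer(t(gene@bits))
}

#' @rdname flattenGene
#' @export
unflattenGene <- function(v, designId = "unflattened") {
  n <- as.integer(round(sqrt(length(v))))
  if (n * n != length(v))
    stop("vector length must be a perfect square")
  pixelGene(designId, matrix(as.integer(v), n, n, byrow = TRUE))
}

#' Upscale a raster by 2x2 tiling
#'
#' Size normalization for 10 um designs in a 20 um library: the input raster
#' is tiled 2 x 2, doubling the matrix side while preserving the physical
#' pixel pitch. Fill fraction is conserved exactly.
#'
#' @param gene a \linkS4class{PixelGene} (typically 100 x 100).
#' @return a \linkS4class{PixelGene} twice the side length.
#' @export
upscale2x2 <- function(gene) {
  b <- gene@bits
  pixelGene(gene@designId, rbind(cbind(b, b), cbind(b, b)))
}

#' Normalize a mixed-size design pool to a common raster size
#'
#' Seed pools mix 10, 20 and 28 um features. To breed designs across sizes at
#' a common 200 x 200 raster, 28 um designs are excluded outright (cropping
#' would distort pillar spacing) and 10 um designs are flagged for 2x2
#' upscaling at rasterization; 20 um designs pass through unchanged.
#'
#' @param designs list of \linkS4class{PrimitiveGene} objects with feature
#'   sizes in \{10, 20, 28\}.
#' @return the surviving designs (10 um ones flagged \code{upscale = TRUE}).
#'   Warns if nothing survives.
#' @export
normalizePool <- function(designs) {
  sizes <- vapply(designs, featureSize, numeric(1))
  if (!all(sizes %in% c(10, 20, 28)))
    stop("unknown feature size; expected 10, 20 or 28 um")
  kept <- designs[sizes != 28]
  if (!length(kept)) {
    warning("all designs were 28 um; normalized pool is empty")
    return(kept)
  }
  lapply(kept, function(g) {
    if (g@featureSize == 10) g@upscale <- TRUE
    g
  })
}

#' Expand an upscale-flagged gene to its full-frame equivalent
#'
#' The primitive-space analogue of [upscale2x2()]: a 10 um design flagged
#' for upscaling becomes a 20 um design whose primitives are replicated at
#' the four 2x2 tile offsets. Rasterizing the expanded gene reproduces the
#' tiled raster, and it lets primitive-based crossover pair designs of
#' originally different feature sizes in a common frame.
#'
#' @param gene a \linkS4class{PrimitiveGene}; returned unchanged unless
#'   flagged \code{upscale = TRUE}.
#' @return a \linkS4class{PrimitiveGene} with \code{upscale = FALSE}.
#' @export
expandUpscale <- function(gene) {
  if (!gene@upscale) return(gene)
  L <- gene@featureSize
  offs <- list(c(0, 0), c(L, 0), c(0, L), c(L, L))
  prims <- unlist(lapply(offs, function(o) {
    lapply(gene@primitives, function(p) {
      p@points <- sweep(p@points, 2, o, `+`)
      p
    })
  }), recursive = FALSE)
  primitiveGene(gene@designId, 2 * L, prims, upscale = FALSE)
}

## ---- external formats -------------------------------------------------

#' Read and write design files and fitness tables
#'
#' The design file is a JSON array of objects \code{\{design_id,
#' feature_size, primitives: [\{kind, points, radius?, stroke_width?\}]\}};
#' the fitness table is a CSV with header \code{design_id,alp_intensity}.
#'
#' @param path file path.
#' @param designs list of \linkS4class{PrimitiveGene} objects.
#' @param records data.frame with columns \code{designId},
#'   \code{alpIntensity}.
#' @return \code{readDesignJSON} a list of genes; \code{readFitnessCSV} a
#'   records data.frame; the writers return \code{path} invisibly.
#' @export
writeDesignJSON <- function(designs, path) {
  out <- lapply(designs, function(g) {
    prims <- lapply(g@primitives, function(p) {
      o <- list(kind = p@kind,
                points = lapply(seq_len(nrow(p@points)),
                                function(i) as.numeric(p@points[i, ])))
      if (p@kind == "C") o$radius <- p@radius
      if (p@kind == "L") o$stroke_width <- p@strokeWidth
      o
    })
    list(design_id = g@designId, feature_size = g@featureSize,
         primitives = prims)
  })
  jsonlite::write_json(out, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname writeDesignJSON
#' @export
readDesignJSON <- function(path) {
  raw <- jsonlite::read_json(path)
  lapply(raw, function(d) {
    prims <- lapply(d$primitives, function(p) {
      pts <- do.call(rbind, lapply(p$points, unlist))
      switch(p$kind,
        T = triangle(pts[1, ], pts[2, ], pts[3, ]),
        C = circle(pts[1, ], p$radius),
        L = lineSeg(pts[1, ], pts[2, ], p$stroke_width))
    })
    primitiveGene(d$design_id, d$feature_size, prims)
  })
}

#' @rdname writeDesignJSON
#' @export
writeFitnessCSV <- function(records, path) {
  utils::write.csv(
    data.frame(design_id = records$designId,
               alp_intensity = records$alpIntensity),
    path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname writeDesignJSON
#' @export
readFitnessCSV <- function(path) {
  d <- utils::read.csv(path, stringsAsFactors = FALSE)
  data.frame(designId = as.character(d$design_id),
             alpIntensity = as.numeric(d$alp_intensity))
}

#' Write a gene raster as a lossless PNG
#'
#' @param gene \linkS4class{PixelGene} or \linkS4class{PrimitiveGene}
#'   (rasterized first).
#' @param dir output directory; the file is named \code{<designId>.png}.
#' @return the file path, invisibly.
#' @export
writeGenePNG <- function(gene, dir = ".") {
  g <- rasterize(gene)
  path <- file.path(dir, paste0(designId(g), ".png"))
  png::writePNG(matrix(as.double(g@bits), nrow(g@bits)), path)
  invisible(path)
}
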