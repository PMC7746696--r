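#' Configuration of the synthetic first-generation pool
#'
#' The original first-generation library (2176 randomly generated designs
#' at 10/20/28 um feature sizes) and its ALP screen are not distributed
#' with this package; this module emulates both so the whole pipeline runs
#' self-contained. Primitive coordinates are drawn from a Normal
#' distribution centered on the feature center (truncated to the frame),
#' and all generated shapes respect the 4 um fabrication limit by
#' construction (circle radius >= 2.25 um, line stroke >= 4.5 um,
#' equilateral-ish triangles with incircle >= 4.6 um).
#'
#' The synthetic ALP intensity is a known linear model of interpretable
#' design descriptors (area coverage, primitive count, mean feature width)
#' plus Gaussian noise, so selection behaviour is verifiable end to end;
#' it does not model real structure-ALP biology.
#'
#' @param poolSize number of designs (default 2176).
#' @param sizeWeights sampling proportions over the 10 / 20 / 28 um
#'   feature sizes (must sum to 1).
#' @param primitiveRange inclusive range of primitives per design at the
#'   largest (28 um) frame; smaller frames carry proportionally fewer
#'   (area-scaled), and 10 um frames hold 1-3 circles.
#' @param coefficients named numeric: \code{intercept}, \code{coverage},
#'   \code{count}, \code{width} -- the fitness model (arbitrary
#'   fluorescence units).
#' @param noiseSd Gaussian noise scale of the synthetic screen.
#' @param seed integer RNG seed for the pool and the screen.
#' @return a \code{SeedConfig} list.
#' @export
seedConfig <- function(poolSize = 2176L,
                       sizeWeights = c(`10` = 1/3, `20` = 1/3, `28` = 1/3),
                       primitiveRange = c(3L, 20L),
                       coefficients = c(intercept = 100, coverage = 40,
                                        count = 20, width = 20),
                       noiseSd = 15, seed = 101L) {
  stopifnot(poolSize >= 1, abs(sum(sizeWeights) - 1) < 1e-8,
            primitiveRange[1] >= 1, primitiveRange[2] >= primitiveRange[1])
  structure(list(poolSize = as.integer(poolSize),
                 sizeWeights = sizeWeights,
                 primitiveRange = as.integer(primitiveRange),
                 coefficients = coefficients, noiseSd = noiseSd,
                 seed = as.integer(seed)),
            class = "SeedConfig")
}

# one random fabricable primitive; center positions ~ Normal(L/2, L/3),
# clamped so the shape (mostly) fits the frame. Small frames (10 um) only
# carry circles: the fabrication floor (4 um) leaves no room for the
# triangle and line geometries used in larger frames.
randomPrimitive <- function(L) {
  kind <- if (L < 12) "C" else sample(PRIMITIVE_KINDS, 1L)
  clampc <- function(v, m) pmin(max(L - m, L / 2), pmax(min(m, L / 2), v))
  if (kind == "C") {
    r <- stats::runif(1, 2.25, 2.75)
    circle(clampc(stats::rnorm(2, L / 2, L / 3), r), r)
  } else if (kind == "L") {
    w <- stats::runif(1, 4.5, 5)
    ctr <- clampc(stats::rnorm(2, L / 2, L / 3), w)
    ang <- stats::runif(1, 0, pi)
    half <- stats::runif(1, 2.5, min(3.5, L / 2.2))
    p1 <- pmin(L, pmax(0, ctr + half * c(cos(ang), sin(ang))))
    p2 <- pmin(L, pmax(0, ctr - half * c(cos(ang), sin(ang))))
    lineSeg(p1, p2, w)
  } else {
    side <- stats::runif(1, 8, 8.6)
    R <- side / sqrt(3)
    ctr <- clampc(stats::rnorm(2, L / 2, L / 3), R)
    ang <- stats::runif(1, 0, 2 * pi) + c(0, 2, 4) * pi / 3
    vs <- lapply(ang, function(a)
      pmin(L, pmax(0, ctr + R * c(cos(a), sin(a)))))
    triangle(vs[[1]], vs[[2]], vs[[3]])
  }
}

#' Generate the synthetic first-generation design pool
#'
#' @param config a [seedConfig()].
#' @return list of \code{poolSize} \linkS4class{PrimitiveGene} objects with
#'   ids \code{tc0001, tc0002, ...}; byte-stable under the config seed.
#' @export
#' @examples
#' pool <- generatePool(seedConfig(poolSize = 10))
#' length(pool)
generatePool <- function(config) {
  stopifnot(inherits(config, "SeedConfig"))
  sizes <- as.numeric(names(config$sizeWeights))
  withSeed(deriveSeed(config$seed, "pool"), {
    lapply(seq_len(config$poolSize), function(i) {
      L <- sample(sizes, 1L, prob = config$sizeWeights)
      # primitive budget scales with frame area: the largest frame carries
      # the full configured range, smaller frames proportionally fewer;
      # 10 um frames hold 1-3 pillars (the fabrication floor caps density)
      lo <- config$primitiveRange[1]; hi <- config$primitiveRange[2]
      hi <- max(lo, round(hi * (L / max(sizes))^2))
      if (L < 12) { lo <- 1L; hi <- 3L }
      n <- sample(lo:hi, 1L)
      primitiveGene(sprintf("tc%04d", i), L,
                    lapply(seq_len(n), function(j) randomPrimitive(L)))
    })
  })
}

# analytic design descriptors (no rasterization): per-primitive area and
# characteristic width, ignoring overlap
primArea <- function(p) {
  if (p@kind == "C") pi * p@radius^2
  else if (p@kind == "L") {
    len <- sqrt(sum((p@points[2, ] - p@points[1, ])^2))
    len * p@strokeWidth + pi * (p@strokeWidth / 2)^2
  } else {
    a <- p@points
    abs((a[2, 1] - a[1, 1]) * (a[3, 2] - a[1, 2]) -
        (a[3, 1] - a[1, 1]) * (a[2, 2] - a[1, 2])) / 2
  }
}

primWidth <- function(p) {
  if (p@kind == "C") 2 * p@radius
  else if (p@kind == "L") p@strokeWidth
  else {
    a <- p@points
    s <- (sqrt(sum((a[2, ] - a[1, ])^2)) + sqrt(sum((a[3, ] - a[2, ])^2)) +
          sqrt(sum((a[1, ] - a[3, ])^2))) / 2
    if (s > 0) 2 * primArea(p) / s else 0   # incircle diameter
  }
}

#' Design descriptors used by the synthetic fitness model
#'
#' @param gene a \linkS4class{PrimitiveGene}.
#' @return named numeric: \code{coverage} (summed primitive area over frame
#'   area, capped at 1, overlap ignored), \code{count} (primitives),
#'   \code{width} (mean characteristic feature width, um).
#' @export
designDescriptors <- function(gene) {
  prims <- gene@primitives
  L <- gene@featureSize
  if (!length(prims))
    return(c(coverage = 0, count = 0, width = 0))
  c(coverage = min(1, sum(vapply(prims, primArea, numeric(1))) / L^2),
    count = length(prims),
    width = mean(vapply(prims, primWidth, numeric(1))))
}

#' Synthetic ALP screen of a design pool
#'
#' Assigns each design an ALP mean integrated intensity from the
#' configured linear descriptor model plus Gaussian noise (clipped at 0).
#' With \code{noiseSd = 0} the intensities reproduce the model exactly,
#' which makes selection behaviour assertable end to end.
#'
#' @param genes list of \linkS4class{PrimitiveGene} objects.
#' @param config a [seedConfig()] (supplies coefficients, noise and seed).
#' @return fitness data.frame with columns \code{designId},
#'   \code{alpIntensity}.
#' @export
syntheticAlp <- function(genes, config = seedConfig()) {
  b <- config$coefficients
  mu <- vapply(genes, function(g) {
    d <- designDescriptors(g)
    b[["intercept"]] + b[["coverage"]] * d[["coverage"]] +
      b[["count"]] * d[["count"]] / 20 + b[["width"]] * d[["width"]] / 10
  }, numeric(1))
  eps <- if (config$noiseSd > 0)
    withSeed(deriveSeed(config$seed, "alp"),
             stats::rnorm(length(mu), 0, config$noiseSd))
  else 0
  data.frame(designId = vapply(genes, designId, character(1)),
             alpIntensity = pmax(0, mu + eps),
             stringsAsFactors = FALSE)
}

#' The hit-design stand-in
#'
#' A fixed, deterministic multi-pillar design used wherever "the ALP hit
#' surface" from the first-generation screen is required (the 7-size
#' control series and progeny demonstrations). The published hit geometry
#' is not available; this synthetic stand-in is five 8 um pillars (four
#' near the corners, one central) in a 20 um frame, all comfortably above
#' the 4 um fabrication limit across the control size variants.
#'
#' @return a \linkS4class{PrimitiveGene} with id \code{"hit"}.
#' @export
makeHitDesign <- function() {
  primitiveGene("hit", 20, list(
    circle(c(5.5, 5.5), 4), circle(c(14.5, 5.5), 4),
    circle(c(5.5, 14.5), 4), circle(c(14.5, 14.5), 4),
    circle(c(10, 10), 4)))
}
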