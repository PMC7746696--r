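---
title: "Evolutionary design of micro-topography libraries: models and methods"
author: "TopoEvolve"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Evolutionary design of micro-topography libraries: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(TopoEvolve)
```

## The design problem

Surface micro-topography steers cell fate: arrays of micrometre-scale
pillars on an implant coating can up- or down-regulate osteogenic markers
such as alkaline phosphatase (ALP) in mesenchymal stem cells. The space of
possible topographies is astronomically large, so exhaustive screening is
impossible. TopoEvolve implements a genetic-algorithm design engine that
breeds a second-generation library from the high-ALP "parents" of a
first-generation screen: encode each topography as a gene, select fit
parents, recombine and mutate them, filter the offspring for diversity and
manufacturability, and assemble a new chip layout together with control
surfaces.

## Genome representations

A topographical feature is a square frame (10, 20 or 28 µm across) whose
pillar material is described in two interchangeable ways:

* **Pixel gene** (`PixelGene`): a 200 × 200 binary matrix, 1 = pillar
  material, at 0.1 µm per pixel for a 20 µm frame. The gene proper is the
  row-major flattening to a length-40 000 vector. Crossover can cut
  through shapes: half a raster circle is inheritable.
* **Primitive gene** (`PrimitiveGene`): an ordered list of geometric
  primitives — filled triangles (3 vertices), filled discs (center +
  radius) and stroked line segments (2 endpoints + width). List positions
  act like gene domains; crossover exchanges whole primitives only.

Conventions fixed package-wide: origin at the top-left corner, x
rightward, y downward; pixel centers at `(i - 0.5) * scale`; a pixel is
material iff its center lies inside a primitive, with closed boundaries
(a center exactly on an edge counts as inside). Lines carry an explicit
stroke width (constructor default 2 µm) because a mathematical segment
has no area.

Mixed-size pools are normalized before breeding: 28 µm designs are
excluded (cropping would distort pillar spacing), and 10 µm designs are
rasterized at 100 × 100 and tiled 2 × 2 (`upscale2x2()`), preserving the
0.1 µm pitch. `expandUpscale()` performs the same normalization in
primitive space by replicating primitives at the four tile offsets, so
primitive crossover can pair designs of originally different sizes.

## Fitness and parent selection

Fitness is the ALP mean integrated intensity per design. Parents are the
designs whose intensity strictly exceeds the 95th percentile of the screen
(`selectParentPool()`). The chip itself hosts a fixed block of 81 parent
units; because the strict percentile of a 2176-design screen yields ~109
designs and size normalization then removes the 28 µm ones, the pipeline
places the 81 highest-fitness designs among the normalized survivors.
This reconciles the percentile rule with the fixed 81-parent layout; both
functions are exposed separately so either convention can be used.

Each breeding cycle selects 10 parents with one of seven algorithms, drawn
uniformly at random per cycle (`pickSelectionAlgorithm()`):

| algorithm | rule |
|---|---|
| Best / Worst | k highest / lowest ALP (ties by design id) |
| Random | uniform, without replacement |
| Roulette | ALP-proportional, without replacement; nonpositive fitness shifted above zero |
| Tournament | k tournaments of size 3 (configurable); winners removed, so ids are distinct |
| NSGA-II | non-dominated sort + crowding distance on (max ALP, min total similarity) |
| SPEA2 | strength/raw fitness + k-NN density, environmental truncation |

"Total similarity" of a design is the sum of absolute Pearson correlations
to every other design in the set — the diversity objective of the
multi-objective algorithms. NSGA-II and SPEA2 follow their canonical
published forms; all stochastic selections are reproducible from
`(algorithm, seed, context)` and ties are broken lexicographically by id.

## Breeding cycles and variation operators

One cycle forms all 10 × 10 ordered parent pairs (self-pairs included),
applies one seeded crossover and a mutation schedule per pair, and appends
the 10 highest-ALP parents of the pool unchanged (elitism) — 110
candidates. Note the elites are the pool's best parents, not the 10
selected ones; the selected set only determines the crossover pairs.

Eight crossover operators are registered per representation, ordered by
increasing expected child–parent distance (the "diversity ladder"). The
concrete ladder is this package's own: pixel — one-point (flattened),
two-point, horizontal/vertical half swap, quadrant swap, 4 × 4 block
mosaic, uniform per-pixel, random-connected-mask blend; primitive —
one-point, two-point, type-stratified swap, spatial-half swap, uniform
per-primitive, count-balanced merge, donor-subset insertion,
shuffle-merge. Every operator is mask- or position-based, so crossing a
design with itself reproduces it (exactly for the order-preserving
operators, and as an identical raster for the two that reorder or
deduplicate primitive lists).

Mutation operators are `polygon` (perturb shape positions/sizes),
`deletion`, `insertion` and, for rasters, `roughness` (stochastic flips of
boundary-adjacent pixels). A schedule draws 0–3 *distinct* operators
(weights 0.15/0.6/0.2/0.05 — most children get exactly one mutation) and
applies them sequentially, each at an intensity drawn uniformly below the
cycle's rate regime (20% or 50% of the gene, drawn per cycle). "Rate" is a
hard upper bound on the altered fraction: pixel operators cap the number
of changed pixels, primitive operators the number of altered primitives.
Inserted elements are pillar-scale — 4.5–10 µm characteristic width, the
lower bound being just above the 4 µm fabrication floor — in both
representations; rectangles are encoded as two abutting triangles since
the primitive alphabet has no rectangle kind.

## Diversity filter and manufacturability

The final selection streams candidates (in seeded-shuffled order) against
the already-accepted set. A candidate whose maximum absolute Pearson
correlation to all accepted designs is below 0.5 joins the *dissimilar*
half; failing that, below 0.9, the *similar* half; otherwise it is
rejected. Each half holds half the quota (an odd quota such as the default
4177 gives the dissimilar half the extra slot); a sub-0.5 candidate falls
through to the similar half once the dissimilar one is full. Comparisons
use |r| by default (`useAbs = FALSE` switches to signed r) and include
only accepted *new* designs, not the parents (a `reference` argument adds
them). Zero-variance rasters (flat or solid) have undefined correlation
and are scored 0, i.e. maximally dissimilar — documented and configurable.

Manufacturability: a design is fabricable if every 8-connected pillar
component is at least 4 µm thick, measured as twice the maximum of the
Euclidean distance transform within the component (`minPillarDiameter()`).
The image border is *not* treated as background, because features tile
periodically across the chip — an edge-touching pillar is not artificially
thin. During assembly the screen runs as an admission predicate inside the
diversity filter: a candidate that passes the similarity rule but fails
the 4 µm rule is rejected *before* consuming a quota slot, so the placed
chip always carries its exact advertised counts. (Applying the screen
after quota selection, the literal reading of the flow, would leave the
chip short.) A repair mode (`repair = TRUE`, or `repairSmallPillars()`)
erases offending components instead of excluding the design.

### How selective is the dissimilar half?

This is the engine's dominant cost, and worth quantifying. Let `p` be the
probability that two unrelated children correlate above 0.5 in absolute
value. A candidate is admitted to the dissimilar half only if it clears
*all* `m` previously accepted designs, which happens with probability
roughly `(1 - p)^m`; integrating, an archive of `N` candidates saturates
at about `M = (1/p) * log(1 + p N)` dissimilar designs. Under this
package's synthetic study conditions `p` measures a few times `1e-3`
(it is dominated by the 2 × 2-tiled 10 µm designs, whose rasters have a
quarter of the effective degrees of freedom, and by density — which is why
the generator keeps fills near 0.3 and insertions pillar-scale). Filling
the default dissimilar half of 2089 designs therefore requires an archive
on the order of **10⁶ candidates** — matching the roughly one-million
offspring funnel that feeds 4177 placed designs in the workflow this
package automates. `runConfig()`'s default `margin = 240` reflects that
scale; reduced-scale experiments should shrink `quotaChildren` and
`targetCandidates` together (the package's tests place 40–600 children
from archives of 500–10⁴). This selectivity analysis, not compute
convenience, is why the similar half always fills quickly while the
dissimilar half is the binding constraint.

## Chip assembly

The assembled layout holds five unit categories: the placed children
(pixel- or primitive-bred), the 81 parents, 5 flat (all-zero) controls,
and 31 simple controls in triplicate — 12 line gratings and 12
square-pillar arrays with feature size equal to gap, 4–15 µm in 1 µm
steps, plus 7 size variants (×0.5 … ×2) of the hit design. The 4–15 µm
range (12 steps) is chosen over the nominal "4–16 µm" because only
12 + 12 + 7 = 31 reconciles the stated 31 controls and the capacity
identity 4177 + 81 + 5 + 93 = 4356. The published hit geometry is not
available, so `makeHitDesign()` supplies a documented synthetic stand-in
(five 8 µm pillars) used wherever the hit surface is required. Unit order
is shuffled with the run seed; elites are never placed as children (the
parents occupy their own units).

## Library characterization

* `pcaEigenimages()` — PCA of mean-centered flattened rasters via the
  dual (Gram-matrix) eigendecomposition, which is exact and cheap for
  libraries far smaller than 40 000 pixels. Components are reshaped to
  images ("eigenimages"); the sign convention makes each component's
  largest-magnitude loading positive, removing eigenvector sign ambiguity
  from regression tests. Any design is reconstructed as the mean image
  plus its weighted component sum.
* `occupancyMap()` — per-pixel counts of material across a design group.
* `embedLibrary()` — PCA scores (up to 5000 components, capped at n − 1)
  followed by a seeded exact t-SNE, implemented in the package (perplexity
  binary search, early exaggeration ×12 for 100 iterations, momentum
  0.5 → 0.8, adaptive gains, learning rate scaled to the library size).
  Exact t-SNE is the right algorithm at the few-hundred-design scale this
  package embeds; perplexity defaults to 30 and is capped at (n − 1)/3.
* `parentProgenyStats()` — per-parent progeny counts, the ordered
  parent-pair matrix (81 × 81 → 6561 cells), realized unique pairs, and
  the crossover-child total.

## The synthetic seed module

No first-generation design file or ALP screen ships with the package, so
`generatePool()`/`syntheticAlp()` emulate both. The generator draws, per
design, a feature size (10/20/28 µm, equal weights), a primitive budget
(3–20 at the 28 µm frame, scaled by frame area; 1–3 circles at 10 µm where
the fabrication floor leaves no room for larger shapes), and primitives
whose centers follow a Normal distribution centered on the frame
(sd = L/3, truncated to the frame) — so the library's variance
concentrates centrally, which is exactly what the first principal
component of such libraries shows. All generated shapes respect the 4 µm
floor by construction (circle radius ≥ 2.25 µm, stroke ≥ 4.5 µm,
equilateral-ish triangles with incircle ≥ 4.6 µm), and sizes sit near
that floor so fills stay around 0.3 — the sparse many-small-pillars
texture of real topography libraries.

The synthetic screen is a *known* linear model of three interpretable
descriptors — analytic area coverage, primitive count, mean feature
width — plus Gaussian noise (sd 15 against an intercept of 100, i.e. a
weak structure–activity coupling, as is realistic for ALP screens). With
the noise at 0 the model is exact, which makes GA behaviour assertable
end to end: elitism provably carries the pool maximum into every cycle,
and Best- vs Worst-selection cycles differ measurably. What passing tests
on this synthetic screen do *not* show is anything about real
structure–ALP biology: the fitness landscape is a stand-in with known
ground truth, not a surrogate model.

## Reproducibility

Every random draw flows from a single run seed through named sub-streams
(`deriveSeed(seed, label, index)` — a multiplicative string hash folded
into 2³¹ − 1): selection, per-pair crossover operator and mask, mutation
schedules, the candidate-stream shuffle and the unit shuffle all have
their own streams, so stages re-run bit-identically and independently.
`runAll()` archives its resolved configuration and a per-stage count
manifest next to the artifacts.

## Problem sizes and limitations

The test suite exercises the engine at reduced scale by choice: seed pools
of 100–2176 designs, archives of 500–10⁴ candidates, chips of 40–600
children, oracle comparisons at 50 × 50 rasters. Known limitations:
similarity is not rotation- or translation-invariant (rotationally related
designs count as distinct, visible as rotated near-duplicate eigenimages);
the synthetic fitness is descriptor-linear; crossover between the two
representations is not supported; and the full 4177-child dissimilar half
requires archives on the 10⁶ scale, as derived above.
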