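---
title: "Connectome reconstruction on honeycomb micropatterns: models and methods"
author: "hexconnectome"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Connectome reconstruction on honeycomb micropatterns}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(hexconnectome)
```

## The platform in brief

Cultured hippocampal neurons on a honeycomb array of cell-permissive
hexagons (poly-L-lysine) separated by repulsive gaps (Sema3F) form simple,
analysable circuits: dendrites stay essentially within the patterns a cell
occupies (its *receptive pattern areas*, RPAs), axons hop between patterns,
and synapses form almost exclusively inside patterns where an axon meets
another cell's dendrites. Because synapse formation is confined to patterns,
an annotation of *which cell has which component in which pattern* suffices
to reconstruct the directed connectome: cell $i$ is presynaptic to cell $j$
whenever

$$\mathrm{axon}(i) \cap \mathrm{dendrites}(j) \neq \varnothing .$$

This package implements that pipeline end to end: lattice geometry, a
synthetic-circuit generator, raster registration (rotation + template
matching), connectome reconstruction, graph metrics with hub classification,
and a 13-class three-node motif census.

## Lattice geometry

Hexagons are flat-top with edge length $L$ (micrometres) and gap $D$, the
perpendicular distance between facing flat edges, so edge-adjacent centres
are $s = \sqrt{3}L + D$ apart. The characteristic distances are closed
forms:

| quantity | formula | meaning |
|---|---|---|
| apothem | $\frac{\sqrt3}{2}L$ | centre to flat edge |
| spacing | $\sqrt3 L + D$ | adjacent centre-to-centre |
| $l_1$ | $\frac{\sqrt3}{2}L + D$ | centre to nearest edge of a neighbour |
| $l_2$ | $\frac{3\sqrt3}{2}L + D$ | centre to farthest edge of a neighbour |
| $r_1$ | $s + L$ | circle covering the first neighbour ring |
| $r_2$ | $\sqrt3\,s + L$ | circle covering the second-nearest class |

For the study lattice ($L = 55$, $D = 70$) these give
$l_1 = 117.63\,\mu m$ and $l_2 = 212.89\,\mu m$; quoted pattern dimensions
truncate at $0.1\,\mu m$ (117.6 / 212.8). Note $l_2 - l_1 = \sqrt3 L$, two
apothems, independently of $D$.

Two geometric conventions were genuinely open and are resolved as follows:

* **$r_1$/$r_2$.** No closed form is conventionally printed for the
  neighbour-circle radii; we define them as the smallest circles containing
  the full first ring ($r_1 = s + L$) and the second-nearest distance class
  (the six ring-2 hexagons at $\sqrt3 s$; $r_2 = \sqrt3 s + L$). The other
  six ring-2 hexagons lie at $2s$ and are not covered; both radii are merely
  reporting conventions and configurable.
* **Boundaries.** Points exactly on a hexagon boundary belong to the
  hexagon (boundary-inclusive, tolerance $10^{-9}L$); ties at shared
  vertices (possible only at $D = 0$) go to the lowest serial pattern id.

Patterns are indexed by axial coordinates $(q, r)$ with centres at
$x = \frac{\sqrt3}{2} s\, q$, $y = s (q/2 + r)$, and enumerated row-major
into 1-based serial ids; positions in the gap are the OUTSIDE sentinel
(`NA`).

## The synthetic-circuit generator

`simulateCircuit()` emulates the occupancy statistics of mature (DIV 21)
cultures; its defaults *are* the study conditions and are not tuned per
experiment:

* **Soma placement.** Each soma is inside a uniformly chosen pattern with
  probability 0.643 (the reported 64.3% in-pattern rate), else uniform in
  the gap; somata repel below 15 um (a soma diameter), with placement
  failure reported when the density makes this impossible.
* **Cell count.** The default 106 cells on a 20 x 20 array reproduces the
  scale of a representative reconstruction (~0.27 traceable cells per
  pattern), which together with the in-pattern rate yields the reported
  ~15.7% of patterns holding a cell body. `nCellsForDensity()` converts a
  seeding density (the cultures used 39.5-78.9 cells/mm^2; only a fraction
  is labeled and traceable) into a count.
* **RPAs.** The per-cell RPA count is categorical on 1..5 with masses
  (0.462, 0.300, 0.140, 0.068, 0.030), putting 76.2% on one-or-two RPAs as
  reported. Patterns are drawn locally: the soma's pattern first, then
  shuffled shell-1 neighbours, extending outward by distance only when the
  drawn count exceeds the local pool (so the configured law is recovered
  exactly in expectation). A gap soma draws from all patterns whose centre
  is within $l_1$ -- such cells can reach more patterns, echoing the
  observation that off-pattern cells form more RPAs.
* **Axon territory.** A random walk on the lattice adjacency from the soma
  pattern, stopped when the number of distinct visited patterns reaches a
  draw from the coverage law: $1 + \mathrm{NB}(\text{size}=4.980,
  \mu=5.704)$ truncated to 1..25. The two parameters were solved once from
  the two reported constraints -- mean coverage 6.7 patterns and 80.8% of
  cells below 10 -- and then frozen. The walk is phenomenological: it
  reproduces coverage statistics and spatial locality ("long but trapped"
  axons), not growth-cone mechanics or time-lapse escape dynamics.
* **Synapse noise.** Each axon-dendrite co-occupancy becomes a truth-graph
  edge with probability 0.9 (reflecting that >90% of co-occupied patterns
  show synapse markers). The reconstruction itself treats contact as
  connection deterministically, so the simulator's sub-unity default
  deliberately injects label noise for robustness tests; set
  `pSynapseGivenContact = 1` for exact truth-recovery checks.
* **Colors.** Each cell draws an exponential-weight composition over the
  fluorophore channels, redrawn until one channel exceeds 0.3, mimicking
  stochastic multicolor labeling; near-identical colors of neighbours are
  allowed, as in the real system.

All randomness derives from one seed through five named substreams
(placement, RPAs, axon walks, colors, synapse thinning), so identical
parameters and seed give byte-identical outputs and stages are individually
reproducible.

**What the generator does not emulate.** Uniform soma placement gives mean
3-nearest-neighbour distances around 230 um at default density, larger than
the 60-120 um band most cultured cells fall in -- real somata cluster.
Fluorescence optics (bleed-through, intensity variation along neurites),
astrocyte contamination and biophysical neurite outgrowth are out of scope.
Passing tests therefore certify the analysis chain and the configured
occupancy laws, not these spatial correlations of real cultures.

## Raster rendering and registration

`renderImage()` rasterizes a lattice plus annotation into a multi-channel
image (pattern mask; per-fluorophore cell channels painting soma discs,
RPA fills and thin axon traces along the walk polyline), with optional
global rotation and additive Gaussian noise -- a fixture generator matched
to the registration stage.

`estimateRotation()` recovers the lattice angle from the 2D power spectrum:
Hann window, mean removal, zero-padding (x3, rounded to a power of two) for
frequency-domain oversampling, exclusion of the DC lobe, then the circular
mean over the strongest first-order peaks of their sub-bin-refined angles,
folded into $[-30°, 30°)$ by the 60-degree lattice symmetry. A flat or
aperiodic image (peak below 200x the median non-DC power) raises a
no-lattice error rather than returning a number.

`detectPatterns()` computes zero-normalized cross-correlation (scores in
$[-1, 1]$) against a hexagon template synthesized from the lattice spec at
the image scale, takes strict local maxima above 0.5 separated by at least
0.8 spacings, refines peaks by quadratic 3 x 3 interpolation, and
least-squares-fits the accepted centres to the lattice model (origin
offset, known basis) to assign axial indices. "Circle detection" on the
correlation surface is realized as this peak picking; no Hough transform is
needed. Correlation normalization and the 0.5 / 0.8 defaults are
implementation choices (the upstream processing did not specify them) and
are exposed as arguments. Fewer than four accepted peaks is an error, not
an empty result.

Pixel coordinates are (row, col), 1-based, row 1 at top; micrometre y
points up. The px/um scale enters exactly once, and the px-to-um transform
is recorded in the `RegistrationResult`.

## Connectome reconstruction

`buildGraph()` applies the contact rule to an annotation, producing a
simple directed graph (presynaptic to postsynaptic):

* **Autapses excluded** by default -- a cell's axon meeting its own
  dendrites is not an edge; the path-based metrics below presuppose
  distinct nodes. `keepSelfLoops = TRUE` retains them for completeness.
* **Unweighted edges.** Multiple shared patterns collapse into one edge;
  the contact count and pattern ids are kept as edge evidence for optional
  weighting or review.
* **Reciprocal pairs** are retained as two directed edges whenever both
  contact conditions hold; the bidirectional motif classes require this.
* Somata in the gap contribute edges exactly like in-pattern somata: only
  the pattern sets matter.

`graphComponents()` partitions the graph into weakly connected *network
segments* (size >= 2, ordered by size then smallest member) and isolated
nodes, mirroring how cultured reconstructions are reported.

## Graph metrics and hub roles

All metrics operate on the unweighted directed graph via per-source BFS
with shortest-path counting; betweenness uses the pair decomposition
$\sigma_{st}(n) = \sigma_{sn}\,\sigma_{nt}\,[d_{sn} + d_{nt} = d_{st}]$.

* **Eccentricity** $e(n) = \max_m d(n, m)$ over reachable $m$; a node
  reaching nothing reports 0, and radius/diameter (min/max eccentricity)
  are taken over nodes with positive finite eccentricity.
* **Closeness.** The textbook $CC(n) = N / \sum_m d(n, m)$ degenerates on
  fragmented graphs: any unreachable node makes the sum infinite and would
  zero nearly every node of a multi-segment culture network -- contradicting
  reported values such as a driver cell with closeness exactly 1. We
  therefore sum over reachable nodes only, with the reachable count as
  numerator: $CC(n) = R(n) / \sum_{m \in \mathrm{reach}(n)} d(n, m)$, 0 for
  an isolated node. A hub whose whole reachable set sits at distance 1
  scores exactly 1 under this convention.
* **Betweenness** $C_B(n) = \sum_{s \neq n \neq t} \sigma_{st}(n) /
  \sigma_{st}$ over ordered pairs, endpoint-excluding, unnormalized (the
  defining formula carries no normalization).
* **Density** is reported both as edges-per-node $|E|/N$ (the $D = k/N$
  convention with $k$ read as total degree count) and as the standard
  directed density $|E| / (N(N-1))$ (`density_std`), since the former
  reading cannot be cross-checked against a printed value.

`classifyHubs()` tags *integrator* ($k_{in} \geq 5$) and *distributor*
($k_{out} \geq 5$) hubs, *pacemakers* (distributor hubs at or above the
0.9 closeness quantile -- cells that can drive many neighbours with short
access to the rest of the network), *bottlenecks* (positive betweenness at
or above the 0.9 betweenness quantile) and *connectors* (bottlenecks with
$k_{out} \geq 4$). Degree cut-offs of 4-5 "depending on the network" are
the observed practice; the quantile form makes the secondary thresholds
per-network, and everything is configurable.

## Three-node motif census

All 64 labeled three-node digraphs (each unordered pair in one of four
states) collapse under the six node permutations into 16 isomorphism
classes, 13 of which are weakly connected -- the motif alphabet. A triad's
canonical code is the minimum of its 6-bit adjacency signature over the
permutations; classes are ordered by ascending edge count, ties by
canonical code, and then anchored so that the feedforward triangle
($A{\to}B, B{\to}C, A{\to}C$) is class 5 and the feedback cycle
($A{\to}B{\to}C{\to}A$) class 6, the two conventionally fixed positions.
The remaining ordinal positions are this package's deterministic
convention; cross-package comparisons should key on canonical codes, which
`triadClasses()` exports, rather than ordinal ids.

`motifProfile()` classifies every induced triad (all edges among the
triplet count) in $O(N^3)$, fine for the tens-to-hundreds of nodes these
circuits produce, and reports counts, frequencies over connected triads,
and the disconnected remainder -- their sum is always $\binom{N}{3}$.
Degree-preserving null-model z-scores are deliberately absent: the profile
is reported raw, as in the culture analyses.

```{r motif-table}
triadClasses()
```

## Numerical and testing choices

* Quantiles use R's default type 7; hub thresholds are data quantiles of
  the per-network metric vectors.
* The suite cross-checks centralities against two independent oracles:
  exhaustive simple-path enumeration on *all* digraphs with 2 to 4 nodes
  (4,164 graphs) plus 150 sampled 5-node digraphs, and igraph on larger
  random graphs. Full enumeration at 5 nodes (about one million graphs)
  buys no additional structural coverage over this and is omitted.
* Simulator parameter recovery is asserted within 3 Monte-Carlo standard
  errors at $n = 5000$ cells; registration round trips use an 8 x 8 array
  at 0.3 px/um, where sub-pixel peak refinement holds centre errors well
  under a pixel and rotation errors near 0.01 degrees.
* Degenerate inputs have defined behaviour: empty annotations give empty
  graphs; an empty graph has density 0 and undefined (NA) diameter;
  fewer than four cells make the 3-nearest-neighbour statistic NA; a blank
  image is an error in both registration stages.

## Known limitations

* The contact rule is deterministic; biological false negatives (contact
  without synapse) exist only in the simulator's truth graph, so
  reconstruction overestimates edges relative to a noisy truth by design.
* The closeness convention reproduces the reported behaviour on fragmented
  directed graphs but is not uniquely determined by the printed formula;
  other tools may differ on disconnected pairs.
* Rendered axon traces connect pattern centres with straight segments --
  adequate for registration fixtures, not a morphological model.
* The census is $O(N^3)$ and intended for single-culture scales, not
  whole-brain graphs.
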