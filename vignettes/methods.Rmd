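---
title: "Methods: consensus RNA diagrams in rnasketch"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: consensus RNA diagrams in rnasketch}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(rnasketch)
```

rnasketch turns an annotated Stockholm alignment into a consensus
secondary-structure diagram. This vignette documents the model and the
numerical choices, in pipeline order.

## Input model

A document must carry sequence rows and a `#=GC SS_cons` line whose matched
`<`/`>` brackets define a properly nested consensus structure. Pseudoknots,
which cross the nested structure, are carried on separate, independently
nested `#=GC SS_cons_pk<NAME>` lines. `#=GC R2R_LABEL` assigns
single-character names to columns, and `#=GF R2R` lines carry layout
commands that refer to columns through those labels. Wrapped (interleaved)
blocks are concatenated on read, and `write_stockholm()` round-trips every
parsed document.

## Sequence weights

Redundant sequences would otherwise dominate the consensus, so columns are
summarized with Gerstein–Sonnhammer–Chothia (GSC) weights. Pairwise
distances are one minus the fractional identity over shared non-gap
columns; a rooted guide tree is built by UPGMA (`stats::hclust`, average
linkage), each edge's ultrametric length is shared equally among the leaves
below it, and a leaf's weight is the sum of its shares up to the root,
normalized to sum to one. Two identical sequences and one distant sequence
give weights (¼, ¼, ½):

```{r}
d <- matrix(c(0, 0, 1, 0, 0, 1, 1, 1, 0), 3, 3)
gsc_weights(d)
```

When every edge is zero (all sequences identical) the weights fall back to
uniform.

## Consensus annotation

Each column is classified by a weighted cascade with strict ("exceeds")
comparisons: a specific nucleotide when its frequency among non-gap rows
exceeds 75% (tiered at 75/90/97%); else `R`/`Y` when the purine or
pyrimidine class exceeds 75%; else a presence-only call tiered at
50/75/90/97% of the weighted non-gap fraction, or *absent* at or below 50%.
Thresholds are overridable per file with a `thresholds` command.

Each annotated pair is classified from the weighted rows: if the
non-canonical fraction (anything outside the six Watson–Crick and wobble
types, including gaps) exceeds 10% the pair is *unshaded*; otherwise two
observed canonical types differing at both positions make it *covarying*,
at exactly one position *compatible*, and a single type *invariant*.

All of these boundaries are measured, not asserted, by the acceptance
suite: bisection against the installed functions recovers 75, 50, 97 and
10 percent to 0.01%.

## Layout

Every nucleotide is placed in the plane with a strictly constant backbone
spacing `d_nt` (the internal unit); pairs sit `d_bp = 1.6` units apart.
Stems are parallel ladders. A loop of chords $d_1..d_m$ (backbone steps,
plus the closing pair span) lies on the circle where the subtended angles
$2\arcsin(d_i/2r)$ sum to $2\pi$; the sum is monotone in $r$, so the radius
is found by bisection bracketed at $\max d_i/2$. Internal-loop and bulge
sides use the same solver with a half-circle total. Degenerately asymmetric
internal loops fall back to a bubble layout (the helix continues straight
and the long side bows out). `turn` commands bend the exterior backbone;
`var_backbone_range` spans are replaced by a dashed arc spanning a fixed
three backbone units, labelled with the observed `min–max nt` range.

## Multistem junctions

Without a command, a junction's elements are placed on a plain circle. A
`multistem_junction` command fixes each child stem's outward direction and
poses a small constrained non-linear program; three formulations express
"the junction approximately follows a circle":

1. unpaired nucleotides exactly on a common circle with pair chords
   intersecting it — the variables are the radius, a start angle, one
   chord-intersection parameter per stem and one length per variable
   region; positions follow in closed form, the single structural equality
   is the $360°$ sweep closure, and the objective penalizes sudden radial
   jumps at the pair chords;
2. nothing pinned to the circle: each segment lies on its own circle
   (radius eliminated analytically by 1-D bisection from its flanking
   positions), and the objective is the squared radial deviation of
   $N + 2 + 3V$ sample points per segment from the best common circle;
3. like 2 but penalizing slope deviations via the cosine between center
   vectors.

Problems are solved with SLSQP (`nloptr::slsqp`, `xtol_rel` $10^{-10}$,
800 evaluations) from a warm start on the chord-fit circle plus eight
seeded Gaussian restarts ($\sigma = 0.1\,r_0$); a solution is accepted only
below a $10^{-6}$ feasibility tolerance, and formulation-1 solutions get a
1-D root-finding polish on $r$ that drives the closure to machine
precision. Segment over-stretch is expressed as a smooth inequality
$D - m\,d_{nt} \le 0$ rather than a kinked equality, which SLSQP stalls on.
Optional `align`/`align_centroid` clauses add scalar-projection equalities
(equal coordinates along a chosen axis normal).

One subtlety: the placement engine walks junction interiors clockwise
while the formulations are posed counterclockwise, so the engine poses the
spec in a y-mirrored frame (all angles negated) and reflects the solution
back — an exact transformation, verified in the tests by the commanded stem
directions reappearing in the final coordinates to $10^{-4}$ degrees.

```{r}
spec <- junction_spec(dirs_deg = c(0, 120, 240), seg_n = 3)
sol <- solve_junction(junction_nlp(spec, formulation = 2))
glance(sol)
```

## Pseudoknots, modular structures, rendering

Pseudoknot pairs are added to the finished layout either *in-line* (rungs
drawn between the placed nucleotides, accepted only when every rung stays
at least $0.4\,d_{nt}$ clear of all other glyph centers — otherwise the
error suggests the callout) or as a *callout*: the duplex redrawn as a
small ladder panel beside the drawing, joined by a dashed connector
labelled "pseudoknot". `modular`/`var_hairpin` commands redraw an optional
element as a sub-panel labelled with its weighted percent frequency over
rows matching a predicate (a restricted expression language over sequence
names and labelled columns).

The renderer first produces renderer-neutral primitives in fixed z-order
(shades, rungs, backbone, arcs, glyphs, panels, texts), then serializes to
SVG 1.1 with the y axis flipped, a fitted viewBox, and fixed 4-decimal
formatting, so output is byte-deterministic and scales as a pure homothety
in the style map's `scale`. A JSON style file can override any palette
entry; `skeleton` reduces the drawing to one path per contiguous backbone
run.

## Synthetic fixtures

`generate_fixture()` builds seeded miniature families (hairpin, internal
loop, 3- and 4-stem junctions, pseudoknot) whose expected annotation is
known by construction: pairs start as G–C and `covary_rate` substitutes the
doubly-different A–U type into an exact number of rows, so the covariation
class is forced; `modular_frac` appends a 3' hairpin carried by an exact
row count. The generator restores the caller's random state.

## Limitations

* Layout commands are a documented subset of the original markup language;
  unknown verbs are rejected rather than ignored.
* The junction solver's restarts make infeasibility (contradictory
  alignment constraints) cost a few seconds before the error is raised.
* Tie-breaking inside UPGMA follows `stats::hclust`, which is
  deterministic for a given input but not a documented lexicographic rule.
* Variable-length arcs always sweep three backbone units; very long hidden
  ranges are conveyed only by the label.
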