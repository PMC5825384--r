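---
title: "Methods: protected-area connectivity indicators"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: protected-area connectivity indicators}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(protconn)
```

## The model

A country's protected areas (PAs) are abstracted as the nodes of a spatial
graph. Each node is one contiguous terrestrial PA polygon with area
$a_i$ (km²); each admissible pair of nodes carries a direct dispersal
probability given by a negative-exponential kernel of the edge-to-edge
distance $d_{ij}$,

$$p_{ij} = 0.5^{\,d_{ij}/d_{med}},$$

calibrated so that dispersal succeeds with probability 0.5 at the median
dispersal distance $d_{med}$. Indirect movement through stepping stones is
captured by the maximum-product path probability $p^*_{ij}$ — the maximum,
over all paths between $i$ and $j$, of the product of link probabilities —
computed exactly as a shortest path on $-\log p$ weights. With
$p^*_{ii} = 1$ (movement within a PA is assumed unrestricted), network
connectivity is summarised by the Equivalent Connected Area

$$\mathrm{ECA} = \sqrt{\sum_i \sum_j a_i\, a_j\, p^*_{ij}},$$

the size of a single PA that would provide the same connectivity value as
the whole network, and

$$\mathrm{ProtConn} = 100 \cdot \mathrm{ECA} / A_L,$$

the percent of the country's land area $A_L$ that is both protected and
reachable. The square root is required for the identity
ProtConn = Prot in a fully connected system (and for the merge invariance
below); the package adopts it throughout, consistent with the ECA lineage
of the indicator.

Transboundary PAs — foreign PAs within a buffer of the focal country's PAs
— participate in the graph with attribute $a = 0$: they contribute no
protected area of their own but can raise $p^*$ between the country's PAs
by acting as corridors or stepping stones.

### Admissible links

Two barrier rules restrict which direct links exist:

* **Sea.** Links never cross landmasses: terrestrial dispersal cannot
  traverse the sea, whatever the distance.
* **Foreign land.** Two focal PAs in different *land portions* of the
  country (portions are separated by sea or by foreign territory) are not
  directly linked; they can only be connected through foreign protected
  stepping stones. A link is admissible within a portion, or when at least
  one endpoint is a transboundary protected node.

A *landmass* is a connected component of all land; a *land portion* is a
connected component of one country's land. Portion membership is
topological: a pair of PAs in one portion remains directly linkable even if
the straight segment between them crosses foreign land, because what the
portion expresses is that unprotected movement can stay within the
country's territory.

### The four ProtConn fractions

Four nested link scenarios decompose ProtConn by the kind of land that
movement relies on: `WITHIN` (no inter-PA links), `CONTIG` (only
contiguous focal PAs, boundary distance at most the contiguity tolerance),
`COUNTRY` (all admissible focal–focal links) and `FULL` (adding
transboundary nodes). With $P_1 \le P_2 \le P_3 \le P_4$ the ProtConn
values of the four networks,

* ProtConn[Within] $= 100\,P_1/P_4$,
* ProtConn[Contig] $= 100\,(P_2-P_1)/P_4$,
* ProtConn[Unprot] $= 100\,(P_3-P_2)/P_4$,
* ProtConn[Trans] $= 100\,(P_4-P_3)/P_4$,

which are non-negative by nestedness and sum to 100 whenever ProtConn > 0.
When a country has no connected protected land the fractions are reported
as zeros with a `no_connected_land` flag, which keeps area-weighted
aggregation well defined.

### Partitioning isolation by cause, and ProtConn_Bound

Protected-but-unconnected land, ProtUnconn = Prot − ProtConn, is split by
cause through two intermediate network levels:

1. **Portion level.** For each land portion $g$, the ECA of the subnetwork
   of that portion's focal nodes plus the same-landmass transboundary
   nodes. Then $\mathrm{ProtConn}_{Bound} = 100 \sum_g \mathrm{ECA}_g /
   A_L$: the connectivity the country could reach if sea and foreign-land
   isolation did not exist, i.e. the part it can influence by design.
2. **Landmass level.** Same with portions replaced by landmasses:
   $\mathrm{ProtConn}_{LM} = 100 \sum_m \mathrm{ECA}_m / A_L$.

The differences telescope:

* ProtUnconn[Design] = Prot − ProtConn_Bound,
* ProtUnconn[Outland] = ProtConn_Bound − ProtConn_LM,
* ProtUnconn[Sea] = ProtConn_LM − ProtConn,

so Sea + Outland + Design = ProtUnconn exactly, and ProtConn ≤
ProtConn_LM ≤ ProtConn_Bound ≤ Prot term by term (the first inequality is
the sub-additivity of the square root over disjoint landmass blocks; the
property suite asserts all of them on randomized cohorts). Ordering the
levels this way — sea outermost, foreign land in between, design innermost
— attributes inter-landmass isolation to the sea and intra-landmass,
inter-portion isolation to foreign territory, which matches the intended
reading of both causes. Transboundary stepping stones are allowed inside
the per-portion ECAs; without them a country whose portions are bridged by
foreign PAs would see that bridge counted as a design deficiency, which it
is not.

Two useful consequences, both property-tested: merging two contiguous
focal PAs (boundary distance 0) leaves ECA unchanged, so the indicator
cannot be gamed by subdividing or re-labelling polygons; and designating a
new PA never decreases ProtConn_Bound.

## Parameters

| Parameter | Default | Units | Meaning |
|---|---|---|---|
| `d_med` | 1, 10, 30, 100 | km | median dispersal distance ladder; 10 km is the reference (the central value of the log-range) |
| `buffer_km` | 500 | km | transboundary search radius; dispersal at 500 km has probability ≈ 0.03 even at `d_med` = 100, so more distant PAs cannot matter |
| `min_area_km2` | 1 | km² | minimum retained PA polygon after clipping |
| `simplify_m` | 100 | m | Douglas–Peucker vertex-thinning tolerance |
| `contig_tol_m` | 0 | m | boundary distance at or below which PAs count as contiguous; raise to 1–100 m for noisy real-world layers |
| `target` | 17 | % | coverage-and-connectivity target used in classification |

All are exposed through `run_config()`; the defaults are the reference
parameterisation of the method.

## Priority classification

At the reference `d_med`, a country with ProtConn_Bound below the target
is class A (new PAs are needed): A1 when `(target − Prot) >
ProtUnconn[Design]` (coverage itself is the bottleneck), A2 otherwise
(strategic placement is the bottleneck). Countries at or above the target
are class B; among them, B1 (landscape permeability) and B2 (coordinated
management of contiguous PAs) require the respective fraction to be
*strictly above* the median of the B cohort, and B3 is the remainder.
Flag C (transboundary coordination) is given to countries whose
ProtConn[Trans] lies in the top third over the whole cohort — the
nearest-rank cut, compared inclusively (`>=` the cut value). Two
deliberate numerical choices: C additionally requires ProtConn[Trans] > 0,
so cohorts where a third of the countries have no transboundary
dependence at all are not flagged wholesale; and the `>= target`
comparison uses a 1e-9 tolerance so a system sitting exactly at the target
(up to float rounding of polygon areas) is classed as meeting it.

## The synthetic generator

Synthetic worlds are planar (flat km coordinates): rectangular landmasses
separated by sea, partitioned into rectangular territories; a country
owning territories on several landmasses has island portions, and a
foreign strip between two territories of one country creates an enclave.
PAs are squares or regular-polygon discs of exact area, placed either
deterministically or by seeded rejection sampling that forbids overlap
within a country (overlapping designations are exercised separately by
dedicated dissolve fixtures). Three presets have closed-form indicator
values: `single_pa` (Prot = ProtConn = ProtConn_Bound = 17), `two_islands`
(ProtConn $= 100\,a\sqrt{2}/A_L$, all residual isolation due to the sea)
and `enclave` (same form, all residual isolation due to foreign land).

The generator emulates the *topological* situations the indicators must
distinguish — multiple landmasses, enclaves, transboundary stepping
stones, contiguity, overlap dissolution — with known ground truth. It
does not emulate realistic coastlines, polygon dirtiness, projection
error, or the size/shape distributions of real PA inventories, so passing
tests demonstrate the correctness of the indicator mathematics and the
preprocessing rules, not robustness to messy real-world geodata. Real
layers additionally pass through geodesic machinery (geodesic point
buffers matched to reported areas; equal-area evaluation through an
ellipsoidal Mollweide projection) that the planar tests bypass by design,
to keep the indicator arithmetic separate from projection error.

For property testing, `random_scenario()` draws 1–3 landmasses, 1–3
territory strips each from a small country pool, and 0–4 PAs per country
(30–930 km², squares or discs). The identity suite runs until 200 country
instances have been generated, each evaluated at all four `d_med` values —
small enough to keep the whole test run under a minute, large enough that
every identity is exercised across islands, enclaves and transboundary
configurations.

## Numerical choices

* Links weaker than $p = 10^{-6}$ (beyond ≈ 20 `d_med`) are pruned before
  the path search; the induced ECA error is orders of magnitude below the
  0.1-percentage-point reporting precision. Pruning by probability keeps
  monotonicity in `d_med` intact.
* Maximum-product paths run on `-log p` weights through igraph's
  Dijkstra; weights of $-\log 1 = 0$ (contiguous PAs) are valid.
* Node iteration, node ids and CSV output follow deterministic sort
  orders, and layer/CSV writers use fixed number formatting, so identical
  configurations reproduce byte-identical outputs.
* The dissolve step groups overlapping polygons into components and takes
  the exact union area by inclusion–exclusion over convex members
  (iterated convex clipping). Overlapping groups must therefore consist of
  convex polygons — true for everything the generator emits; non-convex
  overlapping inputs raise an error rather than silently double counting.
* Border-straddling node slivers inherit the labels of the land polygon
  with the majority overlap area; ties break by lexicographic ISO3.
* Degenerate inputs are defined, not exceptional: a country with no PAs
  yields an all-zero indicator row flagged `no_connected_land`; a
  disconnected pair has $p^* = 0$; an empty scenario network has ECA 0.
* The partition components are ordered projections
  (ProtConn ≤ LM ≤ Bound ≤ Prot is enforced within 1e-9 and violations
  beyond that raise an error naming the inconsistency, since they would
  signal a broken admissibility rule rather than rounding).

## Limitations

* The unprotected matrix is treated as uniformly hostile: no resistance
  surfaces or least-cost paths, and no species- or habitat-specific
  variants. These are out of scope by design.
* PAs are assumed effectively managed for connectivity; the indicators
  measure the design of the system, not its management.
* Geodesic support covers point buffering and area evaluation; inter-PA
  distances are planar within a per-country projection, as in the
  reference workflow. Countries spanning hemispheric extents inherit the
  distortion of any single planar projection.
* The dissolve step's exact-union machinery requires convex members in
  overlapping groups (see above).
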