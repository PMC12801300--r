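---
title: "Computing solvent-excluded surfaces by patch-based ray tracing"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Computing solvent-excluded surfaces by patch-based ray tracing}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(sesray)
```

## The model

The solvent-excluded surface (SES) of a molecule is the boundary traced by
the inward face of a spherical probe (water: radius $r_p = 1.4$ Å) rolling
over the atom spheres. It decomposes into three analytic patch families:

* **convex spherical** patches, the parts of atom spheres the probe can
  touch;
* **toroidal** patches, swept by the probe surface while it rolls tangent to
  an atom pair: a torus whose axis is the interatomic direction, whose ring
  radius is the distance from the axis to the probe-centre locus, and whose
  tube radius is $r_p$;
* **concave spherical** patches, parts of the probe sphere where the probe
  rests fixed on three atoms.

`sesray` builds this patch set analytically, samples it with axis-aligned
rays, classifies grid nodes inside/outside by crossing parity, and extracts
a triangle mesh whose regular vertices lie *exactly* on the analytic
surface.

## The contact complex

Which pairs and triples of atoms carry toroidal and concave patches is
decided by probe tangency. For a pair $(i, j)$ the candidate probe centres
form a circle (the intersection of spheres of radius $r_i + r_p$ and
$r_j + r_p$); the pair is in contact iff some point of that circle clears
every other inflated atom. Each occluding atom blocks one angular arc of
the circle, computable in closed form, so the test reduces to an exact
union-of-arcs computation — no sampling is involved. A triple is in contact
iff one of the two probe "tripod" positions (intersection of three inflated
spheres, found by trilateration) is unoccluded.

These tangency conditions are the *definition* of the contact complex here.
An equivalent construction filters a regular (weighted Delaunay)
triangulation; we deliberately compute the contacts directly because the
direct test is exact in double precision, whereas a hand-built 4-D lifting
would reintroduce the robustness problems that make exact-arithmetic
libraries necessary in the first place. Exactly coincident atom centres are
resolved by a deterministic symbolic perturbation ($10^{-10}$ Å steps along
a fixed direction cycle) so degenerate input never crashes and rebuilds are
reproducible.

Surface exposure of an atom (whether it keeps a convex patch) is decided by
probing 512 deterministic quasi-uniform directions (a Fibonacci sphere); a
buried atom whose entire inflated sphere is covered contributes no patch.
This is the one sampled decision in the build; 512 directions resolve caps
down to roughly $10^{-2}$ steradian, far below anything the toy systems and
typical packings produce.

## Trimming

Every patch carries a trimming solid whose axis-aligned bounding box drives
ray lookup, and exact clipping predicates applied to each candidate hit:

* convex patches keep a surface point iff the probe placed tangent there
  clears all inflated neighbours (this subsumes the classical cap planes);
* toroidal patches keep points in the axial band between the two tangency
  circles, on the inner belt (distance from the axis at most the ring
  radius), whose associated probe centre clears all occluders — on the
  contact circle that occlusion condition is a half-space in the probe
  centre;
* concave patches keep points inside the trihedral cone spanned by the
  three tangency directions from the probe centre.

All predicates use a $10^{-9}$ Å tolerance, kept *inclusive* so a ray
crossing a patch seam is reported by both patches; the duplicate pair is
then removed by two-point skipping, and the rare unpaired seam hit is
healed by parity repair. The trimming-solid record itself stores the
bounding-box half-spaces and the per-type vertex set (atom-cube corners,
tangency-circle box corners, or the atom-centres-plus-probe-centre
tetrahedron); the bottom vertex of that set decides slab ownership during
deduplication.

## Slabs and halos

The SES build is decomposed along Y into `slab_count` slabs, each at least
12 Å thick (the requested count is capped accordingly), with boundaries
picked on 1 Å "mini-slab" bins so atom counts balance. Each slab is built
over its own atoms plus a halo layer (default 12 Å) on each side; a patch
is kept only by the slab containing the minimum-Y vertex of its trimming
solid, with half-open intervals (the outer slabs open towards infinity) so
ownership is total and exclusive. Because every geometric ingredient of a
patch lies within the halo of its owning slab, multi-slab builds reproduce
the single-slab patch multiset exactly — the package's determinism
contract, which the tests check both as patch censuses and as
six-significant-digit agreement of area and volume. The decomposition is
implemented for these semantics; it may be executed concurrently but the
package does not require threads.

## Patch-based ray tracing

Rather than iterating over rays and asking which patches each one pierces
(which needs spatial indexing), the tracer iterates over patches: the
trimming-solid bounding box selects the pixels of each of the three
edge-ray families (rays through grid nodes along X, Y, Z) plus the X
cell-ray family (rays through cell centres), and each selected ray is
intersected analytically — quadratic formula for spheres, the quartic
solver below for tori. Records accumulate under the ray's pixel identifier
and are sorted along the ray afterwards.

Grid spacing is $h = 1/s$ for scale $s$ (default $2$ Å$^{-1}$); the grid
box is the atom set inflated by each radius plus the probe plus a
$\max(r_p, 2h)$ margin, so every ray starts and ends outside the surface
and must cross it an even number of times.

Three mitigations keep the parity invariant honest:

* **two-point skipping** (default): an entry/exit pair closer than
  $10^{-7}$ Å is dropped entirely, which cannot change parity; the older
  one-point strategy (drop the exit only) is available;
* **parity repair**: a ray left with an odd record count is flagged failed
  and inherits the records of the previously processed ray of its family
  (raster order, the first ray falling back to empty), which keeps the
  surface locally constant and manifold;
* **majority colouring**: each edge-ray family votes independently on every
  node; a node is inside when at least two of the three families say so.
  The merge rule is the package's choice; disagreements are confined to a
  one-voxel band near the surface and are counted in the logs.

Volume is the mean of four estimates — inside-segment lengths times $h^2$
summed per family for the three edge families, plus the cell-ray family.
The fourth estimate uses X-direction cell rays only; one extra estimate is
what the averaging scheme calls for, and the direction choice is
immaterial after the mean. Area is the summed triangle area of the raw
mesh. Both statistics are computed before smoothing, which is a cosmetic
output step.

## The quartic solver

Ray-torus intersection reduces to a monic quartic
$x^4 + bx^3 + cx^2 + dx + e = 0$ obtained by substituting the parametric
ray into the torus implicit equation. The solver follows Ferrari: depress
the quartic, find the largest positive root $m$ of the resolvent cubic by
Cardano's method (trigonometric branch for three real roots, real cube
roots otherwise — no complex arithmetic, no divisions by quantities that
can vanish), and split into two quadratics whose slightly-negative
discriminants are clamped when the quartic discriminant certifies a real
pair. Guard constants the method text leaves open are fixed here as:

* $|m| \le 10^{-12}\max(1, |p|)$ treats the resolvent root as zero and
  falls back to the biquadratic branch;
* rescaling to $\hat x = 4e(x - d)$ engages when
  $\max(|c|, |d|, |\Delta|) > 10^8$ and $|e| > 10^{-300}$; since that
  trigger is a heuristic, the solver computes both the plain and the
  rescaled answer and keeps whichever has the smaller residual, so the
  rescue can never make a well-conditioned case worse;
* every root receives up to six Newton polish steps on the original
  quartic, each accepted only if it shrinks the residual (so multiple roots
  are left alone).

Validation against a companion-matrix eigenvalue oracle on $10^4$ seeded
random ray-torus configurations (ring and tube radii uniform in
$[0.2, 3]$ Å, arbitrary axis, axis-aligned rays) is run by
`scripts/acceptance.R` and the test suite; the tolerance asks for fewer
than 0.09% of roots off by more than $10^{-8}$. One caveat discovered
during validation: for exactly repeated roots such as $(x-2)^4$ the
companion matrix scatters its eigenvalue cluster by about $10^{-4}$ with
nonzero imaginary parts, so the oracle's strict realness filter may certify
only part of the multiplicity; the corresponding test asserts the certified
subset.

## Storage

The in/out map is a bilevel grid: a coarse grid at one quarter resolution
whose cells hold nothing by default and lazily allocate a $4^3$ fine block
(2 bits per voxel) on first write — equivalent in behaviour to a dense
array, which the tests enforce under $10^5$ randomised interleaved
operations. Boolean buffers pack 32 values per word. Mesh vertices and
normals are indexed jointly by three direction-indexed bilevel grids (one
per edge direction) with a write-once contract per edge. Edge blocks at
dimensions not divisible by 4 are full blocks with unused lanes.

## Marching Cubes and smoothing

Cells whose corners mix statuses are polygonised by assembling the cut
segments of their six faces into closed loops and fan-triangulating. Each
face is resolved independently by a marching-squares rule with a *fixed*
choice for the two diagonal ambiguous cases (the face centre is treated as
outside); since the two cells sharing a face apply the same rule to the
same four corners, their segment sets agree edge-for-edge and the global
mesh is closed and manifold *by construction*, for any input field. This
is equivalent to the classic 15-case table with one grid-consistent
sub-case choice, without the table's adjacent-complement holes.

Vertices on edges where the tracer recorded an intersection take the exact
analytic position and patch normal (when several records fall on one edge,
the one nearest the edge midpoint wins, ties to the lower parameter —
deterministic regardless of patch order). Edges that flip status without a
record (possible after repair) get a midpoint vertex flagged *dangling*;
after triangulation their normals are rebuilt as the normalised mean of
incident-face normals, with auxiliary storage allocated only for the
flagged vertices.

Laplacian smoothing (umbrella weights, displacement factor 1, default one
iteration) exploits closedness: scanning the triangle list once and adding
each directed edge's neighbour contribution with no neighbour list and no
duplicate check doubles every sum and count, so the new position is the
accumulated sum over twice the neighbour count. The implementation adds the
two copies of each contribution first — an exact doubling in binary
floating point — and reduces in neighbour-index order, which makes the
result provably bitwise identical to an explicit neighbour-list average
(the identities $\mathrm{fl}(2a + 2b) = 2\,\mathrm{fl}(a+b)$ and
$(2S)/(2n) = S/n$ are exact). An edge not shared by exactly two triangles
violates the doubling identity and raises an error.

## Pockets

A pocket is a region accessible to the small probe but not to a bigger one
(default 3.0 Å). The pipeline runs twice on one shared grid; voxels inside
the big-probe SES and outside the small-probe SES form the differential
map (kept dense — it is read and written continuously). Components are
isolated by an iterative 6-connected flood fill; components below 8 voxels
at $s = 2$ (scaled as $(s/2)^3$) are discarded as surface-shell noise —
the size filter and the connectivity are artifact choices. Each pocket is
triangulated by Marching Cubes on its binary mask (midpoint vertices; the
alternative skin-surface triangulation of virtual probes is out of scope),
and its voxel-count volume is cross-checked against the mesh's
divergence-theorem volume in the tests.

## Fixtures and what passing means

The test fixtures are toy systems with known facts: a single atom (closed
forms), a pair (2 convex + 1 torus), an equilateral triple (3 + 3 + 2, the
probe tripod existing on both sides), a tetrahedron, a 9-atom ring that
encloses a pocket the 1.4 Å probe enters but a 3 Å probe cannot, and
seeded random clusters (up to 200 atoms, centres uniform in a 15 Å cube
with 2.4 Å minimum separation, radii uniform in 1.2–1.9 Å — protein-like
heavy-atom packing). At 200 atoms that density exceeds what rejection
sampling can reach, so the generator tops up from a jittered grid
(spacing 2.5 Å, jitter ±0.05 Å) after an attempt budget; determinism per
seed is preserved. The tetrahedral fixture's radii (1.5 Å) match the other
regular fixtures.

The fixtures exercise every patch type, seams, pockets and parity repair,
but they are far smaller and more regular than proteins: passing says the
geometry, parity and storage logic are right, not that the halo default
suffices for every million-atom assembly (the 12 Å default is chosen
conservatively for exactly that reason). Problem sizes in the routine test
runs — grid scales 1–4 Å$^{-1}$, up to 200 atoms, $10^4$-sample solver
corpora — are the package's choice of desk-scale validation conditions.

## Known limitations

* Spindle tori (ring radius below tube radius) are built and traced but
  their self-intersection is not removed beyond what trimming provides.
* The ray-centric tracer, companion-matrix solver and sampling membership
  field ship as exported `oracle_*` functions for validation; they are not
  production paths.
* No PDB reading, hydrogen addition or force-field radius assignment:
  inputs are xyzr/pqr.
* Pocket triangulation has midpoint (not analytic) vertices by design.
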