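# sesray

Analytical solvent-excluded surface (SES) triangulation for molecules, with
patch-based ray tracing and dual-probe pocket detection.

The SES is the boundary traced by the inward face of a spherical probe
(water: radius 1.4 Å) rolling over a molecule's atom spheres. It splits into
three analytic patch families — convex spherical (probe touching one atom),
toroidal (probe rolling tangent to two atoms; a torus with axis along the
interatomic direction, ring radius the distance from the axis to the
probe-centre locus, tube radius *r<sub>p</sub>*), and concave spherical
(probe resting on three atoms). `sesray` is for structural-bioinformatics
and molecular-modelling work that needs watertight SES meshes, volumes,
areas or pockets from atomic coordinates and radii: it

* builds the patch set analytically from the probe contact complex, with a
  slab/halo decomposition whose result is independent of the slab count;
* samples the surface by **patch-based ray tracing**: it iterates over
  patches and finds the axis-aligned rays piercing each patch's bounding
  box, instead of iterating over rays — no spatial acceleration structures;
* solves ray–torus intersections **analytically** (Ferrari/Cardano quartic
  with numerical-care guards, validated against a companion-matrix
  eigenvalue oracle);
* classifies grid nodes inside/outside by crossing parity (with two-point
  skipping of near entry/exit pairs and odd-parity ray repair) on a
  bilevel, bit-packed status grid;
* extracts a closed manifold mesh by Marching Cubes whose regular vertices
  lie exactly on the analytic surface, reconstructs normals of the rare
  midpoint ("dangling") vertices, and smooths with a doubled-count
  Laplacian pass;
* estimates volume as the mean of four per-direction ray estimates and
  reports the mesh area;
* detects **pockets** — regions accessible to the water probe but not to a
  bigger probe (default 3.0 Å) — as the volumetric difference of two SES
  builds, isolated by flood fill and triangulated per pocket.

## Worked example

```r
library(sesray)

fx   <- make_fixture("triple")        # equilateral 3-atom toy molecule
surf <- compute_surface(fx$atoms, surface_config(grid_scale = 2))
print(surf)
```

```
stage: SES buildup
build_ses: slab 1/1: 3 atoms (+0 halo), 8 patches
stage: ray tracing (25 x 24 x 19 grid)
trace_patches: 8 patches, 588 intersection records
skipping (two_point): 0 records removed
repair_failed_rays: 0 rays repaired
stage: grid coloring
coloring: 382 inside nodes, 456 boundary cells, 0 family disagreements
stage: Marching Cubes
marching_cubes: 454 vertices (0 dangling), 904 triangles
stage: smoothing (1 iterations)
<ses_surface> probe 1.4 A, scale 2 1/A
  patches: 3 convex, 3 torus, 2 concave
  mesh: 454 vertices, 904 triangles (closed)
  volume 47.4607 A^3, area 73.9647 A^2
```

The three atoms yield exactly 3 convex, 3 toroidal and 2 concave patches
(the probe tripod exists above and below the triangle plane). The mesh
passes the closed-manifold census — every edge shared by exactly two
triangles — and the volume/area are the ray-parity and triangle-area
estimates at grid scale 2 Å⁻¹ (grid spacing 0.5 Å). Writing the mesh and
detecting pockets:

```r
write_mesh(surf$mesh, "triple.off", "OFF")
pk <- detect_pockets(make_fixture("ring_pocket")$atoms, surface_config())
pocket_summary(pk)
```

A command-line driver is installed under `exec/`:

```sh
Rscript exec/surf.R --atoms mol.xyzr --scale 2 --probe 1.4 --out mol.off --pockets
```

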