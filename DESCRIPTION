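Package: sesray
Title: Solvent-Excluded Molecular Surface Triangulation via Patch-Based Ray Tracing
Version: 1.0.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Computes the analytical solvent-excluded surface (SES) of a molecule
    from atomic coordinates and radii. SES patches (convex spherical, toroidal,
    concave spherical) are built from the probe contact complex with a slab/halo
    parallel-decomposition semantics, sampled by patch-based axis-aligned ray
    tracing with an analytical quartic ray-torus solver, colored onto a bilevel
    in/out grid by parity, and triangulated with Marching Cubes using exact
    on-surface vertices, followed by doubled-count Laplacian smoothing. Includes
    dual-probe pocket detection, xyzr/pqr readers, OFF/PLY mesh writers, a
    keyword configuration dialect, and a command-line driver.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports: stats, utils
Suggests: testthat (>= 3.0.0), optparse, jsonlite, withr
Config/testthat/edition: 3
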