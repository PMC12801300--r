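# Top-level pipeline: SES buildup -> patch-based ray tracing -> skipping ->
# parity repair -> grid coloring -> Marching Cubes -> normals approximation
# -> smoothing, with volume/area estimation along the way.

#' Compute the solvent-excluded surface of an atom set
#'
#' Runs the full pipeline: analytical SES patch construction
#' ([build_ses()]), patch-based ray tracing of three edge-ray families plus
#' the X cell-ray family ([trace_patches()]), near-pair skipping, odd-parity
#' ray repair, parity coloring onto a bilevel status map, Marching-Cubes
#' triangulation with exact on-surface vertices, dangling-normal
#' reconstruction, and Laplacian smoothing.  Volume is the mean of four
#' ray-based estimates and the area is the summed triangle area of the raw
#' (pre-smoothing) mesh.
#'
#' @param atoms An [atom_set()].
#' @param config A [surface_config()].
#' @param grid Optional [ray_grid()] override (used by pocket detection to
#'   put two builds on one grid).
#' @return An object of class `ses_surface`: fields `mesh` (smoothed),
#'   `raw_mesh`, `patches`, `status`, `rays`, `grid`, `volume`, `area`,
#'   `volume_estimates`, `config`, `atoms`.
#' @export
compute_surface <- function(atoms, config = surface_config(), grid = NULL) {
  stopifnot(inherits(atoms, "atom_set"), inherits(config, "surface_config"))
  message("stage: SES buildup")
  patches <- build_ses(atoms, config)
  if (is.null(grid))
    grid <- ray_grid(atoms, config$grid_scale, config$probe_radius)
  message(sprintf("stage: ray tracing (%d x %d x %d grid)",
                  grid$dims[1], grid$dims[2], grid$dims[3]))
  rays <- trace_patches(patches, grid)
  rays <- skip_ray_set(rays, config$skip_strategy, config$skip_eps)
  rays <- repair_failed_rays(rays)
  message("stage: grid coloring")
  status <- color_status_map(rays, grid)
  message("stage: Marching Cubes")
  vmap <- vertex_index_map(grid$dims)
  raw_mesh <- marching_cubes(status, vmap, rays, grid)
  est <- estimate_volume_area(rays, raw_mesh, grid)
  message(sprintf("stage: smoothing (%d iterations)", config$smoothing_iterations))
  mesh <- if (nrow(raw_mesh$triangles) > 0L)
    smooth_mesh(raw_mesh, config$smoothing_iterations) else raw_mesh
  structure(list(mesh = mesh, raw_mesh = raw_mesh, patches = patches,
                 status = status, rays = rays, grid = grid,
                 volume = est$volume, area = est$area,
                 volume_estimates = est$volume_estimates,
                 config = config, atoms = atoms),
            class = "ses_surface")
}

#' @export
print.ses_surface <- function(x, ...) {
  cen <- patch_census(x$patches)
  st <- mesh_statistics(x$mesh)
  cat(sprintf(paste0(
    "<ses_surface> probe %.3g A, scale %.3g 1/A\n",
    "  patches: %d convex, %d torus, %d concave\n",
    "  mesh: %d vertices, %d triangles (%s)\n",
    "  volume %.6g A^3, area %.6g A^2\n"),
    x$config$probe_radius, x$config$grid_scale,
    cen[1], cen[2], cen[3], st$n_vertices, st$n_triangles,
    if (st$is_closed) "closed" else "OPEN", x$volume, x$area))
  invisible(x)
}
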