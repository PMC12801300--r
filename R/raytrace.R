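# Patch-based ray tracing.  Instead of iterating over rays and asking which
# patches they pierce (which needs spatial acceleration structures), the
# tracer iterates over patches, finds the axis-aligned rays passing through
# each trimming-solid bounding box, and stores intersections in a ray-based
# layout.  Per-ray lists are then sorted, near entry/exit pairs skipped,
# odd-parity rays repaired, and the grid parity-colored.

#' Axis-aligned ray grid
#'
#' A cubic-lattice node grid enclosing the inflated atoms, with three
#' edge-ray families (rays through grid nodes along X, Y, Z) and cell-ray
#' families (through cell centres).  The bounding box is the atom set
#' inflated by each radius plus the probe plus a `max(probe, 2h)` margin, so
#' rays always start and finish outside the surface.
#'
#' @param atoms An [atom_set()].
#' @param grid_scale Grid scale `s` (1/Angstrom); spacing `h = 1/s`.
#' @param probe_radius Probe radius used for the margin, Angstrom.
#' @return An object of class `ray_grid` with `origin`, `h`, `dims`.
#' @export
ray_grid <- function(atoms, grid_scale, probe_radius = 0) {
  stopifnot(inherits(atoms, "atom_set"), grid_scale > 0)
  h <- 1 / grid_scale
  margin <- probe_radius + max(probe_radius, 2 * h)
  lo <- apply(atoms$centers - atoms$radii, 2, min) - margin
  hi <- apply(atoms$centers + atoms$radii, 2, max) + margin
  dims <- as.integer(ceiling((hi - lo) / h)) + 1L
  structure(list(origin = lo, h = h, dims = dims,
                 scale = grid_scale), class = "ray_grid")
}

#' @export
print.ray_grid <- function(x, ...) {
  cat(sprintf("<ray_grid> %d x %d x %d nodes, h = %.4g A\n",
              x$dims[1], x$dims[2], x$dims[3], x$h))
  invisible(x)
}

# cross-axis indices of each ray family (rays travel along `family`)
.cross_axes <- list(c(2L, 3L), c(1L, 3L), c(1L, 2L))

#' Pixels whose rays pierce a bounding box
#'
#' For one ray family, returns the pixels (node or cell-centre coordinates on
#' the face orthogonal to the family axis) whose ray line intersects the
#' closed box.
#'
#' @param bbox 2 x 3 matrix, rows = min and max corners.
#' @param grid A [ray_grid()].
#' @param family Ray direction, 1 (X), 2 (Y) or 3 (Z).
#' @param class `"edge_ray"` (through nodes) or `"cell_ray"` (cell centres).
#' @return Integer matrix with columns `u`, `v`: 0-based pixel indices along
#'   the two cross axes; zero rows when the box lies outside the grid.
#' @export
rays_through_bbox <- function(bbox, grid, family, class = c("edge_ray", "cell_ray")) {
  class <- match.arg(class)
  ax <- .cross_axes[[family]]
  off <- if (class == "edge_ray") 0 else grid$h / 2
  nmax <- grid$dims[ax] - if (class == "edge_ray") 1L else 2L
  rng <- lapply(1:2, function(m) {
    a <- ax[m]
    lo <- ceiling((bbox[1, a] - grid$origin[a] - off) / grid$h - 1e-9)
    hi <- floor((bbox[2, a] - grid$origin[a] - off) / grid$h + 1e-9)
    lo <- max(0L, as.integer(lo)); hi <- min(nmax[m], as.integer(hi))
    if (lo > hi) integer(0) else lo:hi
  })
  if (length(rng[[1]]) == 0L || length(rng[[2]]) == 0L)
    return(matrix(integer(0), ncol = 2, dimnames = list(NULL, c("u", "v"))))
  as.matrix(expand.grid(u = rng[[1]], v = rng[[2]]))
}

# world origin and unit direction of a ray
.ray_geom <- function(grid, family, u, v, class) {
  ax <- .cross_axes[[family]]
  off <- if (class == "edge_ray") 0 else grid$h / 2
  o <- grid$origin
  o[ax[1]] <- o[ax[1]] + u * grid$h + off
  o[ax[2]] <- o[ax[2]] + v * grid$h + off
  d <- c(0, 0, 0); d[family] <- 1
  list(origin = o, dir = d)
}

# trimming predicate per patch kind, vectorised over candidate points (n x 3)
.trim_keep <- function(patch, pts, tol = 1e-9) {
  n <- nrow(pts)
  if (n == 0L) return(logical(0))
  if (patch$kind == "convex_sphere") {
    omega <- sweep(pts, 2, patch$center, "-") / patch$radius
    y <- sweep(omega * patch$inflated_radius, 2, patch$center, "+")
    .probe_clear(y, patch$occ_centers, patch$occ_R, skip = integer(0), tol = tol)
  } else if (patch$kind == "torus") {
    pr <- sweep(pts, 2, patch$center, "-")
    z <- as.vector(pr %*% patch$axis)
    perp <- pr - outer(z, patch$axis)
    w <- sqrt(rowSums(perp^2))
    keep <- z >= patch$band[1] - tol & z <= patch$band[2] + tol &
      w <= patch$ring_radius + tol
    if (any(keep) && length(patch$occ_R) > 0L) {
      wk <- pmax(w[keep], 1e-300)
      pc <- sweep(perp[keep, , drop = FALSE] / wk * patch$ring_radius,
                  2, patch$center, "+")
      keep[keep] <- .probe_clear(pc, patch$occ_centers, patch$occ_R,
                                 skip = integer(0), tol = tol)
    }
    keep
  } else {
    rel <- sweep(pts, 2, patch$center, "-")
    keep <- rep(TRUE, n)
    for (m in 1:3) keep <- keep & (rel %*% patch$cone[m, ] >= -tol * patch$radius)
    as.vector(keep)
  }
}

# outward unit normals at points of a patch (n x 3)
.patch_normals <- function(patch, pts) {
  if (patch$kind == "convex_sphere") {
    sweep(pts, 2, patch$center, "-") / patch$radius
  } else if (patch$kind == "concave_sphere") {
    -sweep(pts, 2, patch$center, "-") / patch$radius
  } else {
    pr <- sweep(pts, 2, patch$center, "-")
    z <- as.vector(pr %*% patch$axis)
    perp <- pr - outer(z, patch$axis)
    S <- rowSums(pr^2) + patch$ring_radius^2 - patch$radius^2
    grad <- 4 * (S * pr - 2 * patch$ring_radius^2 * perp)
    nr <- -grad / sqrt(rowSums(grad^2))
    nr
  }
}

#' Intersect one patch with one ray
#'
#' Spherical patches use the quadratic formula, toroidal patches the
#' analytical quartic of [ray_torus_intersect()]; each candidate parameter is
#' kept iff the hit point passes the patch's trimming predicates (tolerance
#' 1e-9 Angstrom).  Normals are outward radial for convex patches, toward
#' the probe centre for concave ones, and the outward-oriented gradient of
#' the implicit torus function for toroidal ones.
#'
#' @param patch A `ses_patch`.
#' @param ray List with `origin` (length 3) and unit `dir` (length 3).
#' @return Matrix with columns `t`, `nx`, `ny`, `nz` (one row per hit,
#'   ascending `t`).
#' @export
intersect_patch <- function(patch, ray) {
  o <- ray$origin; d <- ray$dir
  ts <- if (patch$kind == "torus") {
    tor <- structure(list(center = patch$center, axis = patch$axis,
                          ring_radius = patch$ring_radius,
                          tube_radius = patch$radius), class = "torus")
    ray_torus_intersect(o, d, tor)
  } else {
    oc <- o - patch$center
    bq <- sum(d * oc)
    cq <- sum(oc * oc) - patch$radius^2
    disc <- bq * bq - cq
    if (disc < 0) numeric(0) else {
      sq <- sqrt(disc)
      sort(c(-bq - sq, -bq + sq))
    }
  }
  if (length(ts) == 0L)
    return(matrix(numeric(0), ncol = 4, dimnames = list(NULL, c("t", "nx", "ny", "nz"))))
  pts <- matrix(o, length(ts), 3, byrow = TRUE) + outer(ts, d)
  keep <- .trim_keep(patch, pts)
  ts <- ts[keep]; pts <- pts[keep, , drop = FALSE]
  if (length(ts) == 0L)
    return(matrix(numeric(0), ncol = 4, dimnames = list(NULL, c("t", "nx", "ny", "nz"))))
  nr <- .patch_normals(patch, pts)
  out <- cbind(t = ts, nx = nr[, 1], ny = nr[, 2], nz = nr[, 3])
  out[order(out[, 1]), , drop = FALSE]
}

.empty_records <- function() {
  matrix(numeric(0), ncol = 5, dimnames = list(NULL, c("t", "nx", "ny", "nz", "patch")))
}

# family descriptors traced by default: three edge families plus the X cell
# family (the fourth, cell-ray volume estimate)
.default_families <- function() {
  list(list(dir = 1L, class = "edge_ray"),
       list(dir = 2L, class = "edge_ray"),
       list(dir = 3L, class = "edge_ray"),
       list(dir = 1L, class = "cell_ray"))
}

#' Trace all patches onto the ray grid
#'
#' For every patch: bounding box -> [rays_through_bbox()] for each ray
#' family -> [intersect_patch()] -> append records under the ray's pixel
#' identifier; then every ray's records are sorted ascending in `t`.
#'
#' @param patches A `patch_set` from [build_ses()].
#' @param grid A [ray_grid()].
#' @param families List of family descriptors (`dir`, `class`); the default
#'   traces the three edge families and the X cell family.
#' @return An object of class `ray_set`: per-family pixel-indexed record
#'   lists plus `failed` flags (all `FALSE` until [repair_failed_rays()]).
#' @export
trace_patches <- function(patches, grid, families = .default_families()) {
  stopifnot(inherits(grid, "ray_grid"))
  fams <- lapply(families, function(f) {
    ax <- .cross_axes[[f$dir]]
    np <- grid$dims[ax] - if (f$class == "edge_ray") 0L else 1L
    list(dir = f$dir, class = f$class, npix = np,
         rays = vector("list", np[1] * np[2]),
         failed = logical(np[1] * np[2]))
  })
  n_rec <- 0L
  acc_id <- lapply(fams, function(f) list())
  acc_rec <- lapply(fams, function(f) list())
  for (p in patches$patches) {
    bbox <- p$trim$bbox
    for (fi in seq_along(fams)) {
      f <- fams[[fi]]
      pix <- rays_through_bbox(bbox, grid, f$dir, f$class)
      if (nrow(pix) == 0L) next
      for (r in seq_len(nrow(pix))) {
        ray <- .ray_geom(grid, f$dir, pix[r, 1], pix[r, 2], f$class)
        hits <- intersect_patch(p, ray)
        if (nrow(hits) == 0L) next
        id <- 1L + pix[r, 1] + f$npix[1] * pix[r, 2]
        k <- length(acc_id[[fi]]) + 1L
        acc_id[[fi]][[k]] <- id
        acc_rec[[fi]][[k]] <- cbind(hits, patch = p$id)
        n_rec <- n_rec + nrow(hits)
      }
    }
  }
  # consolidate under the ray pixel identifiers and sort each ray by t
  for (fi in seq_along(fams)) {
    if (length(acc_id[[fi]]) == 0L) {
      fams[[fi]]$rays <- rep(list(.empty_records()), length(fams[[fi]]$rays))
      next
    }
    ids <- unlist(acc_id[[fi]])
    grouped <- split(acc_rec[[fi]], ids)
    rays_out <- rep(list(.empty_records()), length(fams[[fi]]$rays))
    for (g in seq_along(grouped)) {
      m <- do.call(rbind, grouped[[g]])
      rays_out[[as.integer(names(grouped)[g])]] <- m[order(m[, 1]), , drop = FALSE]
    }
    fams[[fi]]$rays <- rays_out
  }
  message(sprintf("trace_patches: %d patches, %d intersection records",
                  length(patches$patches), n_rec))
  structure(list(grid = grid, families = fams), class = "ray_set")
}

#' Skip near entry/exit intersection pairs
#'
#' Scans a sorted record list as consecutive entry-exit pairs; when a pair's
#' gap is below `eps`, `"one_point"` drops the exit only while `"two_point"`
#' drops both members, preserving any parity the list already had.
#'
#' @param records Record matrix sorted ascending in `t`.
#' @param strategy `"one_point"` or `"two_point"`.
#' @param eps Gap threshold, Angstrom.
#' @return Filtered record matrix.
#' @export
apply_skipping <- function(records, strategy = c("two_point", "one_point"),
                           eps = 1e-7) {
  strategy <- match.arg(strategy)
  n <- nrow(records)
  if (n < 2L) return(records)
  drop <- logical(n)
  i <- 1L
  while (i < n) {
    if (records[i + 1L, 1] - records[i, 1] < eps) {
      if (strategy == "two_point") drop[c(i, i + 1L)] <- TRUE
      else drop[i + 1L] <- TRUE
    }
    i <- i + 2L
  }
  records[!drop, , drop = FALSE]
}

#' Apply skipping to every ray of a ray set
#'
#' @param rays A `ray_set`.
#' @param strategy,eps See [apply_skipping()].
#' @return The filtered `ray_set`.
#' @export
skip_ray_set <- function(rays, strategy = c("two_point", "one_point"),
                         eps = 1e-7) {
  strategy <- match.arg(strategy)
  n_drop <- 0L
  for (fi in seq_along(rays$families)) {
    rays$families[[fi]]$rays <- lapply(rays$families[[fi]]$rays, function(m) {
      out <- apply_skipping(m, strategy, eps)
      n_drop <<- n_drop + (nrow(m) - nrow(out))
      out
    })
  }
  message(sprintf("skipping (%s): %d records removed", strategy, n_drop))
  rays
}

#' Repair rays with odd intersection counts
#'
#' A ray whose record count is odd after skipping has missed an intersection;
#' it is flagged failed and its records are replaced by those of the
#' previously processed ray of the same family (raster order; the first ray
#' falls back to an empty list, i.e. all outside).  This produces a locally
#' constant, manifold-consistent surface.
#'
#' @param rays A `ray_set`.
#' @return The repaired `ray_set`, every ray holding an even record count.
#' @export
repair_failed_rays <- function(rays) {
  n_failed <- 0L
  for (fi in seq_along(rays$families)) {
    f <- rays$families[[fi]]
    prev <- .empty_records()
    for (id in seq_along(f$rays)) {
      m <- f$rays[[id]]
      if (nrow(m) %% 2L == 1L) {
        f$rays[[id]] <- prev
        f$failed[id] <- TRUE
        n_failed <- n_failed + 1L
      } else {
        prev <- f$rays[[id]]
      }
    }
    rays$families[[fi]] <- f
  }
  message(sprintf("repair_failed_rays: %d rays repaired", n_failed))
  rays
}

# per-family dense logical inside-mask over grid nodes
.family_inside_mask <- function(f, grid) {
  dims <- grid$dims
  h <- grid$h
  mask <- array(FALSE, dim = dims)
  ax <- .cross_axes[[f$dir]]
  nd <- dims[f$dir]
  for (id in seq_along(f$rays)) {
    m <- f$rays[[id]]
    if (nrow(m) == 0L) next
    u <- (id - 1L) %% f$npix[1]
    v <- (id - 1L) %/% f$npix[1]
    idx3 <- c(NA_integer_, NA_integer_, NA_integer_)
    idx3[ax[1]] <- u + 1L; idx3[ax[2]] <- v + 1L
    for (pr in seq_len(nrow(m) %/% 2L)) {
      t1 <- m[2L * pr - 1L, 1]; t2 <- m[2L * pr, 1]
      mlo <- as.integer(floor(t1 / h)) + 1L
      mhi <- as.integer(ceiling(t2 / h)) - 1L
      mlo <- max(mlo, 0L); mhi <- min(mhi, nd - 1L)
      if (mlo > mhi) next
      sel <- idx3
      for (node in mlo:mhi) {
        sel[f$dir] <- node + 1L
        mask[sel[1], sel[2], sel[3]] <- TRUE
      }
    }
  }
  mask
}

#' Parity-color the grid into a bilevel status map
#'
#' Walks each edge ray: nodes between an odd and the following even
#' intersection are inside.  The three edge families vote independently and
#' a node is inside when at least two families agree (disagreements occur
#' only near failed rays; ties resolve to outside).  Cells with mixed corner
#' statuses are flagged as boundary cells in a packed bit buffer.
#'
#' @param rays A repaired `ray_set`.
#' @param grid The [ray_grid()] (defaults to the set's own grid).
#' @return A [status_map()]; its environment also carries `boundary_cells`
#'   (a [bit_buffer()] over cell linear ids), `inside_array` (the dense
#'   logical vote result, kept for meshing) and `n_disagreements`.
#' @export
color_status_map <- function(rays, grid = rays$grid) {
  edge_fams <- Filter(function(f) f$class == "edge_ray", rays$families)
  stopifnot(length(edge_fams) == 3L)
  votes <- lapply(edge_fams, .family_inside_mask, grid = grid)
  nvote <- votes[[1]] + votes[[2]] + votes[[3]]
  inside <- nvote >= 2L
  n_disagree <- sum(nvote == 1L | nvote == 2L)
  map <- status_map(grid$dims)
  idx <- which(inside, arr.ind = TRUE)
  if (nrow(idx))
    for (r in seq_len(nrow(idx)))
      status_set(map, idx[r, 1] - 1L, idx[r, 2] - 1L, idx[r, 3] - 1L,
                 ses_status[["inside"]])
  cdims <- grid$dims - 1L
  bb <- bit_buffer(prod(cdims))
  if (all(cdims >= 1L)) {
    # a cell is boundary iff its 8 corners mix statuses
    corner_sum <- array(0L, dim = cdims)
    for (dx in 0:1) for (dy in 0:1) for (dz in 0:1)
      corner_sum <- corner_sum +
        inside[(1:cdims[1]) + dx, (1:cdims[2]) + dy, (1:cdims[3]) + dz]
    mixed <- which(corner_sum > 0L & corner_sum < 8L)
    if (length(mixed)) bit_set(bb, mixed - 1L, TRUE)
  }
  map$boundary_cells <- bb
  map$inside_array <- inside
  map$n_disagreements <- n_disagree
  message(sprintf("coloring: %d inside nodes, %d boundary cells, %d family disagreements",
                  sum(inside), if (exists("mixed")) length(mixed) else 0L, n_disagree))
  map
}

#' Volume and area estimates
#'
#' The volume is the mean of four estimates: one per edge-ray family (sum of
#' inside-segment lengths times `h^2` per ray) plus one from the cell rays
#' (rays through cell centres).  The area is the summed triangle area of the
#' extracted mesh.
#'
#' @param rays A repaired `ray_set` holding three edge families and at least
#'   one cell family.
#' @param mesh The extracted [tri_mesh()] (`NULL` gives `NA` area).
#' @param grid The [ray_grid()].
#' @return List with `volume` (Angstrom^3), `area` (Angstrom^2) and the four
#'   per-family `volume_estimates`.
#' @export
estimate_volume_area <- function(rays, mesh = NULL, grid = rays$grid) {
  h <- grid$h
  est <- vapply(rays$families, function(f) {
    tot <- 0
    for (m in f$rays) {
      if (nrow(m) == 0L) next
      k <- nrow(m) %/% 2L
      tot <- tot + sum(m[2 * seq_len(k), 1] - m[2 * seq_len(k) - 1L, 1])
    }
    tot * h * h
  }, numeric(1))
  area <- if (is.null(mesh)) NA_real_ else mesh_statistics(mesh)$area
  list(volume = mean(est), area = area, volume_estimates = est)
}
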