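# Deterministic toy-molecule fixtures and the brute-force validation oracles
# the production path is cross-checked against: a ray-centric tracer (tests
# every ray against every patch, no bounding-box lookup), a companion-matrix
# polynomial root finder, and a sampling-based in/out membership field.

#' Deterministic toy-molecule fixtures
#'
#' Named generators with known analytic facts:
#' * `single_atom`: one atom, radius 2, at the origin (volume `4/3*pi*8`).
#' * `pair`: two atoms 3 Angstrom apart, radii 1.5 (census 2 convex, 1
#'   torus, 0 concave at probe 1.4).
#' * `triple`: equilateral triangle, side 3, radii 1.5 (3 convex, 3 torus,
#'   2 concave).
#' * `tetrahedral`: regular tetrahedron, side 3.2, radii 1.5.
#' * `ring_pocket`: six atoms of radius 1.8 on a circle of radius 3.5 plus
#'   three capping atoms sealing one side, leaving a central pocket the
#'   1.4 Angstrom probe enters but a 3 Angstrom probe cannot.
#' * `random_cluster`: `n` atoms with centres uniform in a 15 Angstrom cube
#'   at minimum separation 2.4 Angstrom and radii uniform in (1.2, 1.9);
#'   rejection sampling with a jittered-grid fallback at packing densities
#'   rejection alone cannot reach.  Bitwise reproducible for a given seed.
#'
#' @param name Fixture name.
#' @param n Atom count (`random_cluster` only, <= 200).
#' @param seed RNG seed (`random_cluster` only).
#' @return A `fixture`: list with `name`, `atoms` ([atom_set()]), `expected`
#'   (known analytic facts) and `seed`.
#' @export
make_fixture <- function(name = c("single_atom", "pair", "triple",
                                  "tetrahedral", "ring_pocket",
                                  "random_cluster"),
                         n = 50L, seed = 1L) {
  name <- match.arg(name)
  out <- switch(name,
    single_atom = list(
      atoms = atom_set(matrix(c(0, 0, 0), 1), 2),
      expected = list(volume = 4 / 3 * pi * 8, area = 16 * pi,
                      census = c(convex_sphere = 1L, torus = 0L,
                                 concave_sphere = 0L))),
    pair = list(
      atoms = atom_set(rbind(c(0, 0, 0), c(3, 0, 0)), c(1.5, 1.5)),
      expected = list(census = c(convex_sphere = 2L, torus = 1L,
                                 concave_sphere = 0L))),
    triple = list(
      atoms = atom_set(rbind(c(0, 0, 0), c(3, 0, 0),
                             c(1.5, 3 * sqrt(3) / 2, 0)), rep(1.5, 3)),
      expected = list(census = c(convex_sphere = 3L, torus = 3L,
                                 concave_sphere = 2L))),
    tetrahedral = list(
      atoms = {
        s <- 3.2
        v <- rbind(c(1, 1, 1), c(1, -1, -1), c(-1, 1, -1), c(-1, -1, 1))
        atom_set(v * s / (2 * sqrt(2)), rep(1.5, 4))
      },
      expected = list()),
    ring_pocket = list(
      atoms = {
        ang <- 2 * pi * (0:5) / 6
        ring <- cbind(3.5 * cos(ang), 3.5 * sin(ang), 0)
        cap_ang <- 2 * pi * (0:2) / 3 + pi / 6
        cap <- cbind(1.75 * cos(cap_ang), 1.75 * sin(cap_ang), -2.2)
        atom_set(rbind(ring, cap), rep(1.8, 9))
      },
      expected = list()),
    random_cluster = {
      stopifnot(n >= 1L, n <= 200L)
      old_seed <- if (exists(".Random.seed", globalenv()))
        get(".Random.seed", globalenv()) else NULL
      on.exit(if (!is.null(old_seed))
        assign(".Random.seed", old_seed, globalenv()), add = TRUE)
      set.seed(seed)
      centers <- matrix(NA_real_, n, 3)
      placed <- 0L
      attempts <- 0L
      while (placed < n && attempts < 2000L * n) {
        cand <- runif(3, 0, 15)
        attempts <- attempts + 1L
        if (placed == 0L ||
            min(sqrt(rowSums(sweep(centers[seq_len(placed), , drop = FALSE],
                                   2, cand)^2))) >= 2.4) {
          placed <- placed + 1L
          centers[placed, ] <- cand
        }
      }
      if (placed < n) {
        # jittered-grid fallback: spacing 2.5, jitter 0.05 keeps 2.4 apart
        gpts <- as.matrix(expand.grid(x = seq(1.25, 13.75, by = 2.5),
                                      y = seq(1.25, 13.75, by = 2.5),
                                      z = seq(1.25, 13.75, by = 2.5)))
        gpts <- gpts[sample(nrow(gpts)), , drop = FALSE]
        for (g in seq_len(nrow(gpts))) {
          if (placed >= n) break
          cand <- gpts[g, ] + runif(3, -0.05, 0.05)
          if (min(sqrt(rowSums(sweep(centers[seq_len(placed), , drop = FALSE],
                                     2, cand)^2))) >= 2.4) {
            placed <- placed + 1L
            centers[placed, ] <- cand
          }
        }
      }
      if (placed < n) stop("random_cluster: could not place ", n, " atoms")
      radii <- runif(n, 1.2, 1.9)
      list(atoms = atom_set(centers, radii), expected = list())
    })
  structure(list(name = name, atoms = out$atoms, expected = out$expected,
                 seed = seed), class = "fixture")
}

#' Ray-centric brute-force tracer (validation oracle)
#'
#' The pre-patch-based scheme, kept as an independent cross-check: for every
#' ray of every family, every patch is tested (no bounding-box lookup; only
#' an exact bounding-sphere miss test), intersections collected and sorted.
#'
#' @param patches A `patch_set`.
#' @param grid A [ray_grid()].
#' @param families Family descriptors as in [trace_patches()].
#' @return A `ray_set` with the same layout as [trace_patches()].
#' @export
oracle_ray_centric_trace <- function(patches, grid,
                                     families = .default_families()) {
  fams <- lapply(families, function(f) {
    ax <- .cross_axes[[f$dir]]
    np <- grid$dims[ax] - if (f$class == "edge_ray") 0L else 1L
    list(dir = f$dir, class = f$class, npix = np,
         rays = rep(list(.empty_records()), np[1] * np[2]),
         failed = logical(np[1] * np[2]))
  })
  plist <- patches$patches
  if (length(plist)) {
    centers <- t(vapply(plist, `[[`, numeric(3), "center"))
    bound <- vapply(plist, function(p)
      if (p$kind == "torus") p$ring_radius + p$radius else p$radius, numeric(1))
  }
  for (fi in seq_along(fams)) {
    f <- fams[[fi]]
    ax <- .cross_axes[[f$dir]]
    for (v in 0:(f$npix[2] - 1L)) {
      for (u in 0:(f$npix[1] - 1L)) {
        id <- 1L + u + f$npix[1] * v
        ray <- .ray_geom(grid, f$dir, u, v, f$class)
        if (length(plist) == 0L) next
        d2 <- (centers[, ax[1]] - ray$origin[ax[1]])^2 +
              (centers[, ax[2]] - ray$origin[ax[2]])^2
        cand <- which(d2 <= (bound + 1e-9)^2)
        if (length(cand) == 0L) next
        recs <- list()
        for (pi_ in cand) {
          hits <- intersect_patch(plist[[pi_]], ray)
          if (nrow(hits)) recs[[length(recs) + 1L]] <-
              cbind(hits, patch = plist[[pi_]]$id)
        }
        if (length(recs)) {
          m <- do.call(rbind, recs)
          fams[[fi]]$rays[[id]] <- m[order(m[, 1]), , drop = FALSE]
        }
      }
    }
  }
  structure(list(grid = grid, families = fams), class = "ray_set")
}

#' Companion-matrix polynomial roots (validation oracle)
#'
#' Real roots of a monic polynomial of degree 3 or 4 as eigenvalues of its
#' companion matrix; eigenvalues with `|Im| <= 1e-10 * (1 + |Re|)` count as
#' real.  This is the reference the analytical solvers are validated
#' against.
#'
#' @param coeffs Numeric vector of the non-leading coefficients, highest
#'   degree first (length 3 for a cubic, 4 for a quartic).
#' @return Sorted numeric vector of real roots.
#' @export
oracle_companion_roots <- function(coeffs) {
  n <- length(coeffs)
  stopifnot(n %in% c(3L, 4L))
  M <- matrix(0, n, n)
  M[1, ] <- -coeffs
  if (n > 1L) M[cbind(2:n, 1:(n - 1L))] <- 1
  ev <- eigen(M, only.values = TRUE)$values
  re <- Re(ev); im <- Im(ev)
  sort(re[abs(im) <= 1e-10 * (1 + abs(re))])
}

#' Sampling-based in/out membership field (validation oracle)
#'
#' Approximate independent oracle for the SES interior: a node is inside iff
#' it lies in an atom sphere, or lies in an inflated atom and no admissible
#' probe sphere (probe centres sampled at `h/2` resolution, each at least
#' `r_i + r_p` from every atom) covers it.  Accurate away from the surface;
#' consumers allow a one-voxel tolerance band.
#'
#' @param atoms An [atom_set()].
#' @param config A [surface_config()].
#' @param grid Optional [ray_grid()] (defaults to the pipeline grid).
#' @param probe_radius Probe override (defaults to `config$probe_radius`).
#' @return Logical array over the grid nodes (`TRUE` = inside).
#' @export
oracle_dense_status <- function(atoms, config, grid = NULL,
                                probe_radius = config$probe_radius) {
  if (is.null(grid)) grid <- ray_grid(atoms, config$grid_scale, probe_radius)
  h <- grid$h
  dims <- grid$dims
  nodes <- list(grid$origin[1] + (0:(dims[1] - 1L)) * h,
                grid$origin[2] + (0:(dims[2] - 1L)) * h,
                grid$origin[3] + (0:(dims[3] - 1L)) * h)
  R <- atoms$radii + probe_radius

  dist_field <- function(coords, centers, radii) {
    # min_i (|p - c_i| - r_i) on the tensor grid
    dmin <- array(Inf, dim = vapply(coords, length, integer(1)))
    for (i in seq_len(nrow(centers))) {
      dx2 <- (coords[[1]] - centers[i, 1])^2
      dy2 <- (coords[[2]] - centers[i, 2])^2
      dz2 <- (coords[[3]] - centers[i, 3])^2
      di <- sqrt(outer(outer(dx2, dy2, "+"), dz2, "+")) - radii[i]
      dmin <- pmin(dmin, di)
    }
    dmin
  }

  in_atom <- dist_field(nodes, atoms$centers, atoms$radii) < 0
  in_inflated <- dist_field(nodes, atoms$centers, R) < 0
  if (probe_radius <= 0) return(in_atom)

  # probe centres on a half-spacing lattice; admissible iff clear of all
  # inflated atoms
  fine <- lapply(1:3, function(a)
    seq(grid$origin[a], grid$origin[a] + (dims[a] - 1L) * h, by = h / 2))
  clear <- dist_field(fine, atoms$centers, R) >= 0
  # dilate the admissible set by the probe radius onto the node lattice:
  # node covered iff some clear centre within probe_radius
  covered <- array(FALSE, dim = dims)
  steps <- as.integer(floor(probe_radius / (h / 2)))
  fdims <- dim(clear)
  for (ox in -steps:steps) for (oy in -steps:steps) for (oz in -steps:steps) {
    if ((ox^2 + oy^2 + oz^2) * (h / 2)^2 > probe_radius^2) next
    # node (i,j,k) maps to fine index (2i, 2j, 2k) (1-based: 2i-1)
    fx <- 2L * (1:dims[1]) - 1L + ox
    fy <- 2L * (1:dims[2]) - 1L + oy
    fz <- 2L * (1:dims[3]) - 1L + oz
    okx <- fx >= 1L & fx <= fdims[1]
    oky <- fy >= 1L & fy <= fdims[2]
    okz <- fz >= 1L & fz <= fdims[3]
    covered[okx, oky, okz] <- covered[okx, oky, okz] |
      clear[fx[okx], fy[oky], fz[okz], drop = FALSE]
  }
  in_atom | (in_inflated & !covered)
}
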