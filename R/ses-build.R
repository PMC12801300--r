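# Analytical SES patch construction.  The contact complex (which atom pairs
# and triples the rolling probe can touch) is computed directly from its
# defining tangency conditions with exact arc-occlusion arithmetic, the three
# patch families (convex spherical, toroidal, concave spherical) are derived
# from it, and a slab/halo decomposition with duplicate-patch removal gives
# build results independent of the slab count.

# deterministic symbolic perturbation for exactly coincident centres: the k-th
# duplicate is nudged by 1e-10 * k along a fixed direction cycle, so the
# complex is reproducible and never crashes on degenerate input
.resolve_degeneracy <- function(atoms) {
  n <- atoms$count
  if (n < 2L) return(atoms)
  key <- apply(round(atoms$centers / 1e-9), 1, paste, collapse = ",")
  dup <- duplicated(key)
  if (!any(dup)) return(atoms)
  dirs <- matrix(c(1, 0, 0, 0, 1, 0, 0, 0, 1, 1, 1, 1), ncol = 3, byrow = TRUE)
  dirs <- dirs / sqrt(rowSums(dirs^2))
  centers <- atoms$centers
  which_dup <- which(dup)
  for (m in seq_along(which_dup)) {
    i <- which_dup[m]
    centers[i, ] <- centers[i, ] + 1e-10 * m * dirs[(m - 1L) %% 4L + 1L, ]
  }
  atom_set(centers, atoms$radii)
}

# 512 deterministic quasi-uniform directions (Fibonacci sphere), used for the
# surface-exposure test of convex patches
.fib_directions <- local({
  n <- 512L
  i <- seq_len(n) - 0.5
  z <- 1 - 2 * i / n
  r <- sqrt(pmax(0, 1 - z^2))
  phi <- i * pi * (3 - sqrt(5))
  cbind(r * cos(phi), r * sin(phi), z)
})

# contact circle of the probe rolling on atoms i and j; NULL when the probe
# cannot touch both simultaneously
.contact_circle <- function(ci, cj, Ri, Rj) {
  dvec <- cj - ci
  d <- sqrt(sum(dvec^2))
  if (d <= 1e-12) return(NULL)
  if (d >= Ri + Rj || d <= abs(Ri - Rj)) return(NULL)
  u <- dvec / d
  x <- (d * d + Ri * Ri - Rj * Rj) / (2 * d)
  rho2 <- Ri * Ri - x * x
  if (rho2 <= 0) return(NULL)
  list(center = ci + x * u, axis = u, radius = sqrt(rho2), x = x, d = d)
}

# orthonormal in-plane frame for a unit axis
.plane_frame <- function(u) {
  ref <- if (abs(u[1]) < 0.9) c(1, 0, 0) else c(0, 1, 0)
  e1 <- ref - sum(ref * u) * u
  e1 <- e1 / sqrt(sum(e1^2))
  list(e1 = e1, e2 = c(u[2] * e1[3] - u[3] * e1[2],
                       u[3] * e1[1] - u[1] * e1[3],
                       u[1] * e1[2] - u[2] * e1[1]))
}

# Is any point of the circle of probe centres free of all inflated occluders?
# Exact arc union: each occluder blocks one angular interval; free iff the
# merged intervals fail to cover the full circle.
.circle_has_free_arc <- function(circle, occ_centers, occ_R) {
  if (length(occ_R) == 0L) return(TRUE)
  fr <- .plane_frame(circle$axis)
  rho <- circle$radius
  ivs <- NULL
  for (m in seq_along(occ_R)) {
    w <- occ_centers[m, ] - circle$center
    C <- (rho * rho + sum(w * w) - occ_R[m]^2) / (2 * rho)
    A <- sum(fr$e1 * w); B <- sum(fr$e2 * w)
    M <- sqrt(A * A + B * B)
    if (M < 1e-300) {
      if (C < 0) return(FALSE)      # concentric occluder swallows the circle
      next
    }
    ratio <- C / M
    if (ratio >= 1) next            # occluder never reaches the circle
    if (ratio <= -1) return(FALSE)  # occluder covers the whole circle
    phi0 <- atan2(B, A)
    alpha <- acos(ratio)
    ivs <- rbind(ivs, c(phi0 - alpha, phi0 + alpha))
  }
  if (is.null(ivs)) return(TRUE)
  # normalise to [0, 2pi), split wrap-around intervals, merge, test coverage
  lo <- ivs[, 1] %% (2 * pi); hi <- lo + (ivs[, 2] - ivs[, 1])
  wrap <- hi > 2 * pi
  segs <- cbind(lo[!wrap], hi[!wrap])
  if (any(wrap))
    segs <- rbind(segs, cbind(lo[wrap], 2 * pi), cbind(rep(0, sum(wrap)), hi[wrap] - 2 * pi))
  segs <- segs[order(segs[, 1]), , drop = FALSE]
  cover_end <- 0
  for (r in seq_len(nrow(segs))) {
    if (segs[r, 1] > cover_end + 1e-12) return(TRUE)   # gap => free arc
    cover_end <- max(cover_end, segs[r, 2])
  }
  cover_end < 2 * pi - 1e-12
}

# probe tripod positions tangent to atoms i, j, k (0, 1 or 2 points)
.tripod_positions <- function(ci, cj, ck, Ri, Rj, Rk) {
  u1 <- cj - ci; u2 <- ck - ci
  g11 <- sum(u1 * u1); g12 <- sum(u1 * u2); g22 <- sum(u2 * u2)
  det <- g11 * g22 - g12 * g12
  if (det <= 1e-12 * g11 * g22) return(NULL)   # collinear centres
  e1 <- (g11 + Ri * Ri - Rj * Rj) / 2
  e2 <- (g22 + Ri * Ri - Rk * Rk) / 2
  a <- (e1 * g22 - e2 * g12) / det
  b <- (e2 * g11 - e1 * g12) / det
  w <- a * u1 + b * u2
  h2 <- Ri * Ri - sum(w * w)
  if (h2 <= 0) return(NULL)
  nvec <- c(u1[2] * u2[3] - u1[3] * u2[2],
            u1[3] * u2[1] - u1[1] * u2[3],
            u1[1] * u2[2] - u1[2] * u2[1])
  nvec <- nvec / sqrt(sum(nvec^2))
  h <- sqrt(h2)
  rbind(ci + w + h * nvec, ci + w - h * nvec)
}

# clearance of probe centre(s) y (n x 3) against inflated atoms, excluding
# `skip` indices; returns TRUE where min_k (|y - c_k| - R_k) >= -tol
.probe_clear <- function(y, centers, R, skip, tol = 1e-9) {
  y <- matrix(y, ncol = 3)
  ok <- rep(TRUE, nrow(y))
  for (k in seq_along(R)) {
    if (k %in% skip) next
    dk <- sqrt(rowSums((y - matrix(centers[k, ], nrow(y), 3, byrow = TRUE))^2))
    ok <- ok & (dk >= R[k] - tol)
  }
  ok
}

#' Build the probe contact complex
#'
#' Computes the vertices, edges and triangles of the zero-alpha complex of
#' the atoms weighted by their inflated radii \eqn{(r_i + r_p)^2}: an edge
#' `(i, j)` is present iff a probe sphere of radius `probe_radius` can be
#' placed tangent to atoms i and j with no other inflated atom occluding the
#' whole circle of candidate probe centres (exact arc-union arithmetic); a
#' triangle `(i, j, k)` is present iff at least one of the two probe tripod
#' positions tangent to all three atoms is unoccluded.  Coincident atom
#' centres are resolved by a deterministic symbolic perturbation.
#'
#' @param atoms An [atom_set()].
#' @param probe_radius Probe radius, Angstrom (>= 0).
#' @return List with `vertices` (atom indices), `edges` (m x 2), `triangles`
#'   (m x 3), and `tripods` (probe centres per triangle row pair).
#' @export
build_alpha_complex <- function(atoms, probe_radius) {
  stopifnot(inherits(atoms, "atom_set"), probe_radius >= 0)
  atoms <- .resolve_degeneracy(atoms)
  n <- atoms$count
  C <- atoms$centers
  R <- atoms$radii + probe_radius
  edges <- matrix(integer(0), ncol = 2)
  triangles <- matrix(integer(0), ncol = 3)
  tripods <- list()
  if (n >= 2L) {
    for (i in 1:(n - 1L)) {
      for (j in (i + 1L):n) {
        circ <- .contact_circle(C[i, ], C[j, ], R[i], R[j])
        if (is.null(circ)) next
        occ <- setdiff(which(sqrt(rowSums((C - matrix(circ$center, n, 3,
                 byrow = TRUE))^2)) < R + circ$radius), c(i, j))
        if (.circle_has_free_arc(circ, C[occ, , drop = FALSE], R[occ]))
          edges <- rbind(edges, c(i, j))
      }
    }
  }
  if (nrow(edges) >= 3L) {
    adj <- matrix(FALSE, n, n)
    adj[edges] <- TRUE; adj[edges[, 2:1, drop = FALSE]] <- TRUE
    for (r in seq_len(nrow(edges))) {
      i <- edges[r, 1]; j <- edges[r, 2]
      ks <- which(adj[i, ] & adj[j, ])
      ks <- ks[ks > j]
      for (k in ks) {
        pos <- .tripod_positions(C[i, ], C[j, ], C[k, ], R[i], R[j], R[k])
        if (is.null(pos)) next
        free <- .probe_clear(pos, C, R, skip = c(i, j, k))
        if (any(free)) {
          triangles <- rbind(triangles, c(i, j, k))
          tripods[[nrow(triangles)]] <- pos[free, , drop = FALSE]
        }
      }
    }
  }
  list(vertices = seq_len(n), edges = edges, triangles = triangles,
       tripods = tripods, atoms = atoms, probe_radius = probe_radius)
}

.bbox_planes <- function(bbox) {
  # six half-spaces (outward normal, offset) of an axis-aligned box
  rbind(c(-1, 0, 0, -bbox[1, 1]), c(1, 0, 0, bbox[2, 1]),
        c(0, -1, 0, -bbox[1, 2]), c(0, 1, 0, bbox[2, 2]),
        c(0, 0, -1, -bbox[1, 3]), c(0, 0, 1, bbox[2, 3]))
}

.trim_solid <- function(vertices, bbox) {
  list(half_spaces = .bbox_planes(bbox), vertices = vertices, bbox = bbox)
}

# world-frame half-extents of a circle (centre q, unit axis u, radius rho)
.circle_extents <- function(u, rho) rho * sqrt(pmax(0, 1 - u^2))

.circle_bbox_corners <- function(q, u, rho) {
  he <- .circle_extents(u, rho)
  sgn <- as.matrix(expand.grid(c(-1, 1), c(-1, 1), c(-1, 1)))
  sweep(sgn %*% diag(he), 2, q, "+")
}

#' Derive the SES patch set from a contact complex
#'
#' One convex spherical patch per surface-exposed atom, one toroidal patch
#' per contact edge (axis along the interatomic direction, ring radius the
#' distance from the axis to the probe-centre locus, tube radius the probe
#' radius), and one concave spherical patch per unoccluded fixed-probe
#' position of each contact triangle (two when the probe fits on both sides).
#' Every patch carries a trimming solid whose bounding box encloses the patch
#' geometry; the exact clipping predicates (probe-clearance, axial band and
#' inner-belt conditions, tangency cone) are stored on the patch and applied
#' during ray tracing.  With `probe_radius = 0` the toroidal and concave
#' families degenerate and only convex (van der Waals) patches are emitted.
#'
#' @param complex Output of [build_alpha_complex()].
#' @param atoms The same [atom_set()] the complex was built from.
#' @param probe_radius Probe radius, Angstrom.
#' @return A `patch_set`: list of patches plus `probe_radius`.
#' @export
build_patches <- function(complex, atoms, probe_radius) {
  atoms <- .resolve_degeneracy(atoms)
  n <- atoms$count
  C <- atoms$centers
  R <- atoms$radii + probe_radius
  patches <- list()
  reach <- 2 * max(R)

  occluders_near <- function(point, radius, skip) {
    d <- sqrt(rowSums((C - matrix(point, n, 3, byrow = TRUE))^2))
    setdiff(which(d < radius + R + 1e-9), skip)
  }

  # convex patches: exposure via deterministic direction sampling
  for (i in seq_len(n)) {
    occ <- occluders_near(C[i, ], R[i], skip = i)
    probe_pts <- sweep(.fib_directions * R[i], 2, C[i, ], "+")
    if (!any(.probe_clear(probe_pts, C[occ, , drop = FALSE], R[occ],
                          skip = integer(0)))) next
    bbox <- rbind(C[i, ] - atoms$radii[i], C[i, ] + atoms$radii[i])
    corners <- as.matrix(expand.grid(bbox[, 1], bbox[, 2], bbox[, 3]))
    patches[[length(patches) + 1L]] <- structure(list(
      kind = "convex_sphere", center = C[i, ], radius = atoms$radii[i],
      axis = NULL, ring_radius = NULL,
      atom = i, inflated_radius = R[i],
      occ_centers = C[occ, , drop = FALSE], occ_R = R[occ],
      trim = .trim_solid(corners, bbox), id = NA_integer_),
      class = "ses_patch")
  }

  if (probe_radius > 0) {
    # toroidal patches, one per contact edge
    if (nrow(complex$edges) > 0L) {
      for (r in seq_len(nrow(complex$edges))) {
        i <- complex$edges[r, 1]; j <- complex$edges[r, 2]
        circ <- .contact_circle(C[i, ], C[j, ], R[i], R[j])
        if (is.null(circ)) next
        u <- circ$axis; q <- circ$center; rho <- circ$radius
        z_i <- -circ$x * probe_radius / R[i]
        z_j <- (circ$d - circ$x) * probe_radius / R[j]
        band <- sort(c(z_i, z_j))
        t_rho_i <- rho * atoms$radii[i] / R[i]
        t_rho_j <- rho * atoms$radii[j] / R[j]
        verts <- rbind(.circle_bbox_corners(q + z_i * u, u, t_rho_i),
                       .circle_bbox_corners(q + z_j * u, u, t_rho_j))
        he <- .circle_extents(u, rho) + abs(u) * max(abs(band))
        bbox <- rbind(pmin(q - he, apply(verts, 2, min)),
                      pmax(q + he, apply(verts, 2, max)))
        occ <- occluders_near(q, rho, skip = c(i, j))
        patches[[length(patches) + 1L]] <- structure(list(
          kind = "torus", center = q, radius = probe_radius, axis = u,
          ring_radius = rho, band = band, atom_pair = c(i, j),
          occ_centers = C[occ, , drop = FALSE], occ_R = R[occ],
          trim = .trim_solid(verts, bbox), id = NA_integer_),
          class = "ses_patch")
      }
    }
    # concave patches, one per unoccluded tripod position
    if (nrow(complex$triangles) > 0L) {
      for (r in seq_len(nrow(complex$triangles))) {
        ijk <- complex$triangles[r, ]
        pos <- complex$tripods[[r]]
        for (m in seq_len(nrow(pos))) {
          pc <- pos[m, ]
          tang <- t(vapply(ijk, function(a)
            pc + probe_radius * (C[a, ] - pc) / R[a], numeric(3)))
          # trihedral cone planes through the probe centre: keep x with
          # (x - pc) . n_ab >= 0, n_ab oriented toward the third tangency
          cone <- matrix(NA_real_, 3, 3)
          pairs <- rbind(c(1, 2), c(2, 3), c(3, 1))
          for (pidx in 1:3) {
            ta <- tang[pairs[pidx, 1], ] - pc
            tb <- tang[pairs[pidx, 2], ] - pc
            nv <- c(ta[2] * tb[3] - ta[3] * tb[2],
                    ta[3] * tb[1] - ta[1] * tb[3],
                    ta[1] * tb[2] - ta[2] * tb[1])
            tc <- tang[setdiff(1:3, pairs[pidx, ]), ] - pc
            if (sum(nv * tc) < 0) nv <- -nv
            cone[pidx, ] <- nv / sqrt(sum(nv^2))
          }
          verts <- rbind(C[ijk[1], ], C[ijk[2], ], C[ijk[3], ], pc)
          bbox <- rbind(pmin(apply(verts, 2, min), pc - probe_radius),
                        pmax(apply(verts, 2, max), pc + probe_radius))
          patches[[length(patches) + 1L]] <- structure(list(
            kind = "concave_sphere", center = pc, radius = probe_radius,
            axis = NULL, ring_radius = NULL, atom_triple = ijk,
            cone = cone, trim = .trim_solid(verts, bbox), id = NA_integer_),
            class = "ses_patch")
        }
      }
    }
  }

  for (m in seq_along(patches)) patches[[m]]$id <- m
  structure(list(patches = patches, probe_radius = probe_radius),
            class = "patch_set")
}

#' Patch census by kind
#'
#' @param ps A `patch_set`.
#' @return Named integer vector with counts of `convex_sphere`, `torus`,
#'   `concave_sphere` patches.
#' @export
patch_census <- function(ps) {
  kinds <- vapply(ps$patches, `[[`, character(1), "kind")
  c(convex_sphere = sum(kinds == "convex_sphere"),
    torus = sum(kinds == "torus"),
    concave_sphere = sum(kinds == "concave_sphere"))
}

#' @export
print.patch_set <- function(x, ...) {
  cen <- patch_census(x)
  cat(sprintf("<patch_set> %d patches (%d convex, %d torus, %d concave), probe %.3g A\n",
              length(x$patches), cen[1], cen[2], cen[3], x$probe_radius))
  invisible(x)
}

#' Partition atoms into Y slabs with halo layers
#'
#' Atoms are counted in 1-Angstrom mini-slab bins along Y; slab boundaries
#' are chosen on bin edges so per-slab atom counts are as equal as the
#' binning permits.  The slab count is capped so every slab is at least 12
#' Angstrom thick (`N = min(requested, floor(Y_extent / 12))`, but at least
#' 1).  Halo lists contain atoms within `halo` of a slab's boundaries but
#' outside the slab.
#'
#' @param atoms An [atom_set()].
#' @param requested_slabs Requested slab count (>= 1).
#' @param halo Halo-layer thickness, Angstrom.
#' @return List with `n_slabs`, `boundaries` (length N+1), `halo`,
#'   `per_slab_atom_ids`, `per_slab_halo_ids`.
#' @export
slab_partition <- function(atoms, requested_slabs, halo = 12) {
  stopifnot(inherits(atoms, "atom_set"), requested_slabs >= 1)
  y <- atoms$centers[, 2]
  ylo <- min(y); yhi <- max(y)
  extent <- yhi - ylo
  N <- max(1L, min(as.integer(requested_slabs), as.integer(floor(extent / 12))))
  if (N == 1L) {
    return(list(n_slabs = 1L, boundaries = c(ylo, yhi + 1e-9), halo = halo,
                per_slab_atom_ids = list(seq_len(atoms$count)),
                per_slab_halo_ids = list(integer(0))))
  }
  nb <- max(N, as.integer(ceiling(extent)))   # 1 A mini-slabs
  edges <- seq(ylo, yhi, length.out = nb + 1L)
  edges[nb + 1L] <- yhi + 1e-9
  counts <- tabulate(findInterval(y, edges, rightmost.closed = TRUE), nbins = nb)
  cum <- cumsum(counts)
  total <- atoms$count
  boundaries <- numeric(N + 1L)
  boundaries[1] <- edges[1]; boundaries[N + 1L] <- edges[nb + 1L]
  for (k in seq_len(N - 1L)) {
    target <- total * k / N
    cand <- which.min(abs(cum - target))        # bin edge after bin `cand`
    b <- edges[cand + 1L]
    # enforce the 12 A minimum thickness, keeping room for remaining slabs
    b <- max(b, boundaries[k] + 12)
    b <- min(b, boundaries[N + 1L] - 12 * (N - k))
    boundaries[k + 1L] <- b
  }
  slab_of <- findInterval(y, boundaries, rightmost.closed = TRUE)
  slab_of[slab_of < 1L] <- 1L; slab_of[slab_of > N] <- N
  per_slab <- lapply(seq_len(N), function(s) which(slab_of == s))
  per_halo <- lapply(seq_len(N), function(s) {
    lo <- boundaries[s]; hi <- boundaries[s + 1L]
    which(slab_of != s & y >= lo - halo & y < hi + halo)
  })
  list(n_slabs = N, boundaries = boundaries, halo = halo,
       per_slab_atom_ids = per_slab, per_slab_halo_ids = per_halo)
}

#' Remove duplicate patches across slabs
#'
#' A patch built by a slab is retained iff the minimum-Y vertex of its
#' trimming solid lies inside that slab's half-open `[lower, upper)`
#' Y-interval (the first slab's interval is open below, the last open
#' above, so ownership is total).  Retained patches get unique contiguous
#' ids.
#'
#' @param per_slab_patchsets List of `patch_set`s, one per slab.
#' @param partition Output of [slab_partition()].
#' @return A single deduplicated `patch_set`.
#' @export
dedup_patches <- function(per_slab_patchsets, partition) {
  N <- partition$n_slabs
  stopifnot(length(per_slab_patchsets) == N)
  kept <- list()
  for (s in seq_len(N)) {
    lo <- if (s == 1L) -Inf else partition$boundaries[s]
    hi <- if (s == N) Inf else partition$boundaries[s + 1L]
    for (p in per_slab_patchsets[[s]]$patches) {
      ymin <- min(p$trim$vertices[, 2])
      if (ymin >= lo && ymin < hi) kept[[length(kept) + 1L]] <- p
    }
  }
  for (m in seq_along(kept)) kept[[m]]$id <- m
  structure(list(patches = kept,
                 probe_radius = per_slab_patchsets[[1]]$probe_radius),
            class = "patch_set")
}

#' Build the SES patch set of an atom set
#'
#' Composition of [slab_partition()], per-slab [build_alpha_complex()] +
#' [build_patches()] over slab-plus-halo atoms, and [dedup_patches()].  The
#' result is independent of the configured slab count (the determinism
#' contract of the parallel decomposition): each patch is built, identically,
#' by the slab owning its trimming solid's bottom vertex, because the halo
#' layer (default 12 Angstrom) exceeds any patch's reach across a boundary.
#'
#' @param atoms An [atom_set()].
#' @param config A [surface_config()].
#' @return A `patch_set`.
#' @export
build_ses <- function(atoms, config) {
  stopifnot(inherits(atoms, "atom_set"), inherits(config, "surface_config"))
  atoms <- .resolve_degeneracy(atoms)
  part <- slab_partition(atoms, config$slab_count, config$halo_thickness)
  if (part$n_slabs < config$slab_count)
    message(sprintf("build_ses: slab count capped to %d (Y extent %.1f A)",
                    part$n_slabs, diff(range(atoms$centers[, 2]))))
  slabsets <- vector("list", part$n_slabs)
  for (s in seq_len(part$n_slabs)) {
    ids <- sort(c(part$per_slab_atom_ids[[s]], part$per_slab_halo_ids[[s]]))
    sub <- atom_set(atoms$centers[ids, , drop = FALSE], atoms$radii[ids])
    cpx <- build_alpha_complex(sub, config$probe_radius)
    ps <- build_patches(cpx, sub, config$probe_radius)
    # record global atom ids so trimming data is slab-independent
    for (m in seq_along(ps$patches)) {
      p <- ps$patches[[m]]
      if (!is.null(p$atom)) p$atom <- ids[p$atom]
      if (!is.null(p$atom_pair)) p$atom_pair <- ids[p$atom_pair]
      if (!is.null(p$atom_triple)) p$atom_triple <- ids[p$atom_triple]
      ps$patches[[m]] <- p
    }
    slabsets[[s]] <- ps
    message(sprintf("build_ses: slab %d/%d: %d atoms (+%d halo), %d patches",
                    s, part$n_slabs, length(part$per_slab_atom_ids[[s]]),
                    length(part$per_slab_halo_ids[[s]]), length(ps$patches)))
  }
  dedup_patches(slabsets, part)
}
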