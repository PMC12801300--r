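# Shared test oracles and utilities.  These deliberately use naive
# algorithms (explicit neighbour lists, dense sampling plus bisection,
# breadth-first flood fill) independent of the production code paths.

quiet <- function(expr) suppressMessages(expr)

`%||%` <- function(a, b) if (is.null(a)) b else a

# explicit neighbour-list Laplacian smoothing: scan triangles, build
# per-vertex neighbour lists with a duplicate check, average neighbours
oracle_smooth <- function(mesh, iterations = 1L) {
  tris <- mesh$triangles
  nv <- nrow(mesh$vertices)
  nbrs <- vector("list", nv)
  for (tr in seq_len(nrow(tris))) {
    for (pair in list(c(1, 2), c(2, 1), c(2, 3), c(3, 2), c(3, 1), c(1, 3))) {
      a <- tris[tr, pair[1]]; b <- tris[tr, pair[2]]
      if (!(b %in% nbrs[[a]])) nbrs[[a]] <- c(nbrs[[a]], b)
    }
  }
  nbrs <- lapply(nbrs, sort)
  V <- mesh$vertices; Nn <- mesh$normals
  for (it in seq_len(iterations)) {
    newV <- V; newN <- Nn
    for (v in seq_len(nv)) {
      sP <- c(0, 0, 0); sN <- c(0, 0, 0)
      for (nb in nbrs[[v]]) { sP <- sP + V[nb, ]; sN <- sN + Nn[nb, ] }
      newV[v, ] <- sP / length(nbrs[[v]])
      newN[v, ] <- sN / length(nbrs[[v]])
    }
    nrm <- sqrt(rowSums(newN^2)); nrm[nrm == 0] <- 1
    V <- newV; Nn <- newN / nrm
  }
  mesh$vertices <- V; mesh$normals <- Nn
  mesh
}

# compare two ray sets: per-ray record counts must match and sorted t-lists
# agree within tol; returns c(mismatching_rays, worst_dt)
compare_ray_sets <- function(a, b, tol = 1e-9) {
  mismatch <- 0L; worst <- 0
  for (fi in seq_along(a$families)) {
    ra <- a$families[[fi]]$rays; rb <- b$families[[fi]]$rays
    stopifnot(length(ra) == length(rb))
    for (id in seq_along(ra)) {
      if (nrow(ra[[id]]) != nrow(rb[[id]])) { mismatch <- mismatch + 1L; next }
      if (nrow(ra[[id]]))
        worst <- max(worst, max(abs(ra[[id]][, 1] - rb[[id]][, 1])))
    }
  }
  c(mismatch = mismatch, worst_dt = worst)
}

# dense-sampling + bisection ray-torus oracle: bracket sign changes of the
# quartic on [0, tmax] at n_samples points, refine each bracket by bisection
oracle_bisect_torus <- function(origin, direction, tor, tmax = 40,
                                n_samples = 10000L) {
  q <- ray_torus_quartic(origin, direction, tor)
  f <- function(t) (((t + q$b) * t + q$c) * t + q$d) * t + q$e
  ts <- seq(0, tmax, length.out = n_samples)
  fv <- f(ts)
  sc <- which(fv[-1] * fv[-n_samples] < 0)
  roots <- numeric(0)
  for (i in sc) {
    lo <- ts[i]; hi <- ts[i + 1]
    for (k in 1:60) {
      mid <- (lo + hi) / 2
      if (f(lo) * f(mid) <= 0) hi <- mid else lo <- mid
    }
    roots <- c(roots, (lo + hi) / 2)
  }
  roots
}

# breadth-first 6-connected components of a logical 3-D array
oracle_components <- function(mask) {
  dims <- dim(mask)
  labels <- array(0L, dim = dims)
  lab <- 0L
  offs <- rbind(c(1, 0, 0), c(-1, 0, 0), c(0, 1, 0),
                c(0, -1, 0), c(0, 0, 1), c(0, 0, -1))
  for (seed in which(mask)) {
    if (labels[seed] != 0L) next
    lab <- lab + 1L
    queue <- seed
    labels[seed] <- lab
    while (length(queue)) {
      cur <- queue[1]; queue <- queue[-1]
      ci <- arrayInd(cur, dims)
      for (nb in 1:6) {
        p <- ci + offs[nb, ]
        if (any(p < 1L) || any(p > dims)) next
        lin <- p[1] + dims[1] * ((p[2] - 1L) + dims[2] * (p[3] - 1L))
        if (mask[lin] && labels[lin] == 0L) {
          labels[lin] <- lab
          queue <- c(queue, lin)
        }
      }
    }
  }
  labels
}

# signed volume of a closed, outward-oriented mesh (divergence theorem)
mesh_signed_volume <- function(mesh) {
  v1 <- mesh$vertices[mesh$triangles[, 1], , drop = FALSE]
  v2 <- mesh$vertices[mesh$triangles[, 2], , drop = FALSE]
  v3 <- mesh$vertices[mesh$triangles[, 3], , drop = FALSE]
  sum(v1[, 1] * (v2[, 2] * v3[, 3] - v2[, 3] * v3[, 2]) -
      v1[, 2] * (v2[, 1] * v3[, 3] - v2[, 3] * v3[, 1]) +
      v1[, 3] * (v2[, 1] * v3[, 2] - v2[, 2] * v3[, 1])) / 6
}

# count odd-parity rays of a ray set (before repair)
count_odd_rays <- function(rs) {
  n <- 0L
  for (f in rs$families)
    for (m in f$rays) if (nrow(m) %% 2L == 1L) n <- n + 1L
  n
}

# analytic torus inside field on a node grid (for topology fixtures)
torus_inside_field <- function(grid, R, r) {
  xs <- grid$origin[1] + (0:(grid$dims[1] - 1)) * grid$h
  ys <- grid$origin[2] + (0:(grid$dims[2] - 1)) * grid$h
  zs <- grid$origin[3] + (0:(grid$dims[3] - 1)) * grid$h
  inside <- array(FALSE, dim = grid$dims)
  for (k in seq_along(zs))
    inside[, , k] <- outer(xs, ys, function(x, y)
      (x^2 + y^2 + zs[k]^2 + R^2 - r^2)^2 - 4 * R^2 * (x^2 + y^2) < 0)
  inside
}
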