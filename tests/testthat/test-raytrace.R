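test_that("rays_through_bbox finds exactly the pixels whose lines hit the box", {
  one <- make_fixture("single_atom")$atoms
  g <- ray_grid(one, 1, 0)   # unit spacing
  # unit box aligned with the pixel lattice: 2 x 2 edge-ray pixels
  bbox <- rbind(g$origin + c(0, 0, 0), g$origin + c(1, 1, 1))
  pix <- rays_through_bbox(bbox, g, 1, "edge_ray")
  expect_equal(nrow(pix), 4L)
  # degenerate zero-thickness box: only pixels on that line
  bboxd <- rbind(g$origin + c(0, 1, 1), g$origin + c(2, 1, 1))
  pixd <- rays_through_bbox(bboxd, g, 1, "edge_ray")
  expect_equal(nrow(pixd), 1L)
  expect_equal(unname(as.matrix(pixd)[1, ]), c(1L, 1L))
  # box outside the grid
  far <- rbind(g$origin - c(50, 50, 50), g$origin - c(40, 40, 40))
  expect_equal(nrow(rays_through_bbox(far, g, 2, "edge_ray")), 0L)

  # random boxes versus brute force over all pixels
  set.seed(13)
  for (rep in 1:50) {
    lo <- g$origin + runif(3, -2, 5)
    hi <- lo + runif(3, 0.2, 4)
    bb <- rbind(lo, hi)
    for (fam in 1:3) {
      ax <- sesray:::.cross_axes[[fam]]
      got <- rays_through_bbox(bb, g, fam, "edge_ray")
      want <- list()
      for (u in 0:(g$dims[ax[1]] - 1)) for (v in 0:(g$dims[ax[2]] - 1)) {
        cu <- g$origin[ax[1]] + u * g$h
        cv <- g$origin[ax[2]] + v * g$h
        if (cu >= lo[ax[1]] - 1e-9 && cu <= hi[ax[1]] + 1e-9 &&
            cv >= lo[ax[2]] - 1e-9 && cv <= hi[ax[2]] + 1e-9)
          want[[length(want) + 1L]] <- c(u, v)
      }
      want <- if (length(want)) do.call(rbind, want) else matrix(integer(0), ncol = 2)
      got_m <- unname(as.matrix(got))
      expect_equal(got_m[order(got_m[, 2], got_m[, 1]), , drop = FALSE],
                   want[order(want[, 2], want[, 1]), , drop = FALSE])
    }
  }
})

test_that("patch intersection honors the quadratic, the torus quartic and trimming", {
  # full sphere radius 3 at the origin (probe 0: trim always passes)
  sphere <- structure(list(kind = "convex_sphere", center = c(0, 0, 0),
                           radius = 3, inflated_radius = 3,
                           occ_centers = matrix(numeric(0), ncol = 3),
                           occ_R = numeric(0), id = 1L),
                      class = "ses_patch")
  hit <- intersect_patch(sphere, list(origin = c(-10, 0, 0), dir = c(1, 0, 0)))
  expect_equal(hit[, "t"], c(7, 13))
  expect_equal(unname(hit[, c("nx", "ny", "nz")]),
               rbind(c(-1, 0, 0), c(1, 0, 0)))
  miss <- intersect_patch(sphere, list(origin = c(-10, 0, 3.5), dir = c(1, 0, 0)))
  expect_equal(nrow(miss), 0L)

  # trimmed hemisphere: an occluder blocks the x > 0 half, single hit at x = -3
  hemi <- sphere
  hemi$occ_centers <- matrix(c(6.1, 0, 0), 1)
  hemi$occ_R <- 3.2
  hit1 <- intersect_patch(hemi, list(origin = c(-10, 0, 0), dir = c(1, 0, 0)))
  expect_equal(unname(hit1[, "t"]), 7)

  # torus patch band/inner-belt trimming: hits on the inner belt only
  fx <- make_fixture("pair")
  ps <- build_patches(build_alpha_complex(fx$atoms, 1.4), fx$atoms, 1.4)
  tor <- Filter(function(p) p$kind == "torus", ps$patches)[[1]]
  # ray through the waist plane, along Y at the torus centre
  hits <- intersect_patch(tor, list(origin = c(1.5, -10, 0), dir = c(0, 1, 0)))
  expect_equal(nrow(hits), 2L)
  # waist radius = ring_radius - tube radius
  expect_equal(abs(-10 + hits[, "t"]), rep(tor$ring_radius - 1.4, 2),
               tolerance = 1e-9)
  # normals unit length
  expect_equal(rowSums(hits[, 2:4]^2), rep(1, 2), tolerance = 1e-9)
})

test_that("patch-based tracing equals the ray-centric oracle on fixtures", {
  for (nm in c("single_atom", "pair", "triple")) {
    fx <- make_fixture(nm)
    ps <- quiet(build_ses(fx$atoms, surface_config(grid_scale = 2)))
    g <- ray_grid(fx$atoms, 2, 1.4)
    got <- quiet(trace_patches(ps, g))
    ref <- oracle_ray_centric_trace(ps, g)
    cmp <- compare_ray_sets(got, ref, 1e-9)
    expect_equal(unname(cmp[1]), 0)
    expect_lt(cmp[2], 1e-9)
  }
  # empty patch set regions: rays missing all bboxes carry zero records
  fx <- make_fixture("single_atom")
  ps <- quiet(build_ses(fx$atoms, surface_config(grid_scale = 2, probe_radius = 0)))
  g <- ray_grid(fx$atoms, 2, 0)
  rs <- quiet(trace_patches(ps, g))
  corner <- rs$families[[1]]$rays[[1]]
  expect_equal(nrow(corner), 0L)
})

test_that("near-pair skipping drops records per strategy and keeps parity", {
  rec <- cbind(t = c(1.0, 1.0 + 1e-9, 5.0, 7.0), nx = 0, ny = 0, nz = 1, patch = 1)
  expect_equal(apply_skipping(rec, "two_point")[, "t"], c(5, 7))
  expect_equal(apply_skipping(rec, "one_point")[, "t"], c(1, 5, 7))
  empty <- rec[0, , drop = FALSE]
  expect_equal(nrow(apply_skipping(empty, "two_point")), 0L)
  # two_point never changes parity
  set.seed(3)
  for (rep in 1:200) {
    n <- sample(0:12, 1)
    ts <- sort(runif(n, 0, 10))
    if (n >= 2 && runif(1) < 0.5) ts[2] <- ts[1] + 1e-9   # inject a near pair
    m <- cbind(t = ts, nx = 0, ny = 0, nz = 1, patch = 1)
    out <- apply_skipping(m, "two_point")
    expect_equal(nrow(out) %% 2L, nrow(m) %% 2L)
  }
})

test_that("repair replaces odd rays with the previous ray and reaches full parity", {
  fx <- make_fixture("single_atom")
  ps <- quiet(build_ses(fx$atoms, surface_config(probe_radius = 0, grid_scale = 4)))
  g <- ray_grid(fx$atoms, 4, 0)
  rs <- quiet(trace_patches(ps, g))
  # spec rule: a 3-record ray inherits the previous ray's 2 records
  f1 <- rs$families[[1]]
  ids <- which(vapply(f1$rays, nrow, integer(1)) == 2L)
  id <- ids[ids > 1][1]
  prev_rec <- f1$rays[[id - 1L]]
  bad <- rbind(f1$rays[[id]], f1$rays[[id]][1, , drop = FALSE])
  rs$families[[1]]$rays[[id]] <- bad[order(bad[, 1]), , drop = FALSE]
  rep1 <- quiet(repair_failed_rays(rs))
  expect_identical(rep1$families[[1]]$rays[[id]], prev_rec)
  expect_true(rep1$families[[1]]$failed[id])
  expect_equal(count_odd_rays(rep1), 0L)

  # all-even input is the identity with zero failures
  rs2 <- quiet(trace_patches(ps, g))
  rep2 <- quiet(repair_failed_rays(rs2))
  expect_equal(sum(vapply(rep2$families, function(f) sum(f$failed), integer(1))), 0L)

  # random fault injection still ends fully even
  set.seed(9)
  rs3 <- quiet(trace_patches(ps, g))
  for (k in 1:25) {
    fi <- sample(seq_along(rs3$families), 1)
    nz <- which(vapply(rs3$families[[fi]]$rays, nrow, integer(1)) > 0)
    id <- sample(nz, 1)
    m <- rs3$families[[fi]]$rays[[id]]
    rs3$families[[fi]]$rays[[id]] <- m[-sample(nrow(m), 1), , drop = FALSE]
  }
  rep3 <- quiet(repair_failed_rays(rs3))
  expect_equal(count_odd_rays(rep3), 0L)
})

test_that("the analytical torus solver fails fewer rays than a degraded solver", {
  fx <- make_fixture("triple")
  ps <- quiet(build_ses(fx$atoms, surface_config(grid_scale = 2)))
  g <- ray_grid(fx$atoms, 2, 1.4)
  rs <- quiet(skip_ray_set(trace_patches(ps, g)))
  analytic_failed <- count_odd_rays(rs)

  # degraded backend: coarse sampling with a handful of bisection steps
  degraded_torus <- function(origin, direction, tor) {
    q <- ray_torus_quartic(origin, direction, tor)
    f <- function(t) (((t + q$b) * t + q$c) * t + q$d) * t + q$e
    ts <- seq(0, 30, length.out = 60)   # deliberately loose
    fv <- f(ts)
    sc <- which(fv[-1] * fv[-60] < 0)
    vapply(sc, function(i) {
      lo <- ts[i]; hi <- ts[i + 1]
      for (k in 1:6) { mid <- (lo + hi) / 2
        if (f(lo) * f(mid) <= 0) hi <- mid else lo <- mid }
      (lo + hi) / 2
    }, numeric(1))
  }
  degraded_failed <- 0L
  for (f in rs$families) {
    for (id in seq_along(f$rays)) {
      u <- (id - 1L) %% f$npix[1]; v <- (id - 1L) %/% f$npix[1]
      ray <- sesray:::.ray_geom(g, f$dir, u, v, f$class)
      nrec <- 0L
      for (p in ps$patches) {
        if (p$kind == "torus") {
          tor <- torus(p$center, p$axis, p$ring_radius, p$radius)
          ts <- degraded_torus(ray$origin, ray$dir, tor)
          if (length(ts)) {
            pts <- matrix(ray$origin, length(ts), 3, byrow = TRUE) +
              outer(ts, ray$dir)
            nrec <- nrec + sum(sesray:::.trim_keep(p, pts))
          }
        } else {
          nrec <- nrec + nrow(intersect_patch(p, ray))
        }
      }
      if (nrec %% 2L == 1L) degraded_failed <- degraded_failed + 1L
    }
  }
  expect_lte(analytic_failed, degraded_failed)
})

test_that("parity coloring marks nodes between odd and even intersections", {
  # hand-built ray set: one X-ray with hits at t = 2.2 and 7.8 on unit spacing
  g <- structure(list(origin = c(0, 0, 0), h = 1, dims = c(10L, 3L, 3L),
                      scale = 1), class = "ray_grid")
  mk_fam <- function(dirn) {
    ax <- sesray:::.cross_axes[[dirn]]
    np <- g$dims[ax]
    list(dir = dirn, class = "edge_ray", npix = np,
         rays = rep(list(sesray:::.empty_records()), np[1] * np[2]),
         failed = logical(np[1] * np[2]))
  }
  fams <- list(mk_fam(1L), mk_fam(2L), mk_fam(3L))
  rec <- cbind(t = c(2.2, 7.8), nx = c(-1, 1), ny = 0, nz = 0, patch = 1)
  id <- 1L + 1L + 3L * 1L     # pixel (1,1)
  fams[[1]]$rays[[id]] <- rec
  rs <- structure(list(grid = g, families = fams), class = "ray_set")
  mask <- sesray:::.family_inside_mask(fams[[1]], g)
  expect_equal(which(mask[, 2, 2]), 3:7 + 1L)   # nodes 3..7 (0-based)
  # no intersections anywhere: all outside
  expect_false(any(sesray:::.family_inside_mask(fams[[2]], g)))
})

test_that("colored sphere matches analytic membership away from the surface", {
  fx <- make_fixture("single_atom")
  cfg <- surface_config(probe_radius = 0, grid_scale = 4)
  surf <- quiet(compute_surface(fx$atoms, cfg))
  g <- surf$grid
  inside <- surf$status$inside_array
  h <- g$h
  xs <- g$origin[1] + (0:(g$dims[1] - 1)) * h
  ys <- g$origin[2] + (0:(g$dims[2] - 1)) * h
  zs <- g$origin[3] + (0:(g$dims[3] - 1)) * h
  rad <- sqrt(outer(outer(xs^2, ys^2, "+"), zs^2, "+"))
  off_surface <- abs(rad - 2) > h   # skip the one-voxel band at the surface
  expect_identical(inside[off_surface], (rad < 2)[off_surface])
  # the status map agrees with the dense vote field
  expect_identical(to_dense(surf$status) == ses_status[["inside"]], inside)
})

test_that("the three ray families almost always agree on node status", {
  fx <- make_fixture("triple")
  surf <- quiet(compute_surface(fx$atoms, surface_config(grid_scale = 2)))
  edge_fams <- Filter(function(f) f$class == "edge_ray", surf$rays$families)
  votes <- lapply(edge_fams, sesray:::.family_inside_mask, grid = surf$grid)
  nv <- votes[[1]] + votes[[2]] + votes[[3]]
  agree <- mean(nv == 0L | nv == 3L)
  expect_gt(agree, 0.999)
})

test_that("translating atoms by grid multiples translates the inside set", {
  fx <- make_fixture("pair")
  cfg <- surface_config(grid_scale = 2)
  h <- 1 / cfg$grid_scale
  s1 <- quiet(compute_surface(fx$atoms, cfg))
  shifted <- atom_set(sweep(fx$atoms$centers, 2, c(h, 2 * h, 3 * h), "+"),
                      fx$atoms$radii)
  s2 <- quiet(compute_surface(shifted, cfg))
  expect_identical(dim(s1$status$inside_array), dim(s2$status$inside_array))
  expect_identical(s1$status$inside_array, s2$status$inside_array)
  expect_equal(s2$grid$origin - s1$grid$origin, c(h, 2 * h, 3 * h))
})

test_that("volume averages four estimates and converges on the sphere", {
  fx <- make_fixture("single_atom")
  s4 <- quiet(compute_surface(fx$atoms, surface_config(probe_radius = 0,
                                                       grid_scale = 4)))
  expect_equal(length(s4$volume_estimates), 4L)
  truth <- 4 / 3 * pi * 8
  expect_lt(abs(s4$volume - truth) / truth, 0.01)
  s8 <- quiet(compute_surface(fx$atoms, surface_config(probe_radius = 0,
                                                       grid_scale = 8)))
  expect_lte(abs(s8$volume - truth), abs(s4$volume - truth))
  # empty intersection set: zero volume
  g <- ray_grid(fx$atoms, 2, 0)
  fams <- lapply(sesray:::.default_families(), function(f) {
    ax <- sesray:::.cross_axes[[f$dir]]
    np <- g$dims[ax] - if (f$class == "edge_ray") 0L else 1L
    list(dir = f$dir, class = f$class, npix = np,
         rays = rep(list(sesray:::.empty_records()), np[1] * np[2]),
         failed = logical(np[1] * np[2]))
  })
  rs0 <- structure(list(grid = g, families = fams), class = "ray_set")
  expect_equal(estimate_volume_area(rs0, NULL, g)$volume, 0)
})
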